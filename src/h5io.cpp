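// Minimal HDF5 cohort container, written against the libhdf5 C API.
// Layout: /patient_order (string vector), /volumes/<id> (1-D double dataset
// with an integer "dim" attribute), /survival/<id>/{time,event,age,kps} scalar
// doubles and {sex,race,radiotherapy,chemotherapy} scalar strings.
#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Hid {
  hid_t id = -1;
  herr_t (*closer)(hid_t) = nullptr;
  Hid(hid_t i, herr_t (*c)(hid_t)) : id(i), closer(c) {}
  ~Hid() { if (id >= 0 && closer) closer(id); }
  operator hid_t() const { return id; }
};

void silence_h5() { H5Eset_auto2(H5E_DEFAULT, nullptr, nullptr); }

hid_t strtype(size_t n) {
  hid_t t = H5Tcopy(H5T_C_S1);
  H5Tset_size(t, n + 1);
  H5Tset_strpad(t, H5T_STR_NULLTERM);
  return t;
}

void write_scalar_double(hid_t grp, const char* name, double val) {
  Hid sp(H5Screate(H5S_SCALAR), H5Sclose);
  Hid ds(H5Dcreate2(grp, name, H5T_NATIVE_DOUBLE, sp, H5P_DEFAULT, H5P_DEFAULT,
                    H5P_DEFAULT), H5Dclose);
  if (ds < 0) stop("HDF5: cannot create dataset '%s'", name);
  H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &val);
}

void write_scalar_string(hid_t grp, const char* name, const std::string& s) {
  Hid ty(strtype(s.size()), H5Tclose);
  Hid sp(H5Screate(H5S_SCALAR), H5Sclose);
  Hid ds(H5Dcreate2(grp, name, ty, sp, H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT),
         H5Dclose);
  if (ds < 0) stop("HDF5: cannot create dataset '%s'", name);
  std::vector<char> buf(s.begin(), s.end());
  buf.push_back('\0');
  H5Dwrite(ds, ty, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
}

double read_scalar_double(hid_t grp, const char* name) {
  Hid ds(H5Dopen2(grp, name, H5P_DEFAULT), H5Dclose);
  if (ds < 0) stop("HDF5: missing dataset '%s'", name);
  double val = 0;
  if (H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &val) < 0)
    stop("HDF5: failed reading '%s'", name);
  return val;
}

std::string read_scalar_string(hid_t grp, const char* name) {
  Hid ds(H5Dopen2(grp, name, H5P_DEFAULT), H5Dclose);
  if (ds < 0) stop("HDF5: missing dataset '%s'", name);
  Hid ty(H5Dget_type(ds), H5Tclose);
  const size_t n = H5Tget_size(ty);
  std::vector<char> buf(n + 1, '\0');
  if (H5Dread(ds, ty, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data()) < 0)
    stop("HDF5: failed reading '%s'", name);
  return std::string(buf.data());
}

} // namespace

// [[Rcpp::export(name = ".cd_h5_write")]]
void cd_h5_write(std::string path, CharacterVector ids, List volumes,
                 List survival) {
  silence_h5();
  const int n = ids.size();
  Hid file(H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT),
           H5Fclose);
  if (file < 0) stop("HDF5: cannot create file '%s'", path.c_str());

  // patient order
  size_t maxlen = 1;
  for (int i = 0; i < n; ++i)
    maxlen = std::max(maxlen, (size_t)LENGTH(STRING_ELT(ids, i)));
  {
    Hid ty(strtype(maxlen), H5Tclose);
    hsize_t dim = (hsize_t)n;
    Hid sp(H5Screate_simple(1, &dim, nullptr), H5Sclose);
    Hid ds(H5Dcreate2(file, "patient_order", ty, sp, H5P_DEFAULT, H5P_DEFAULT,
                      H5P_DEFAULT), H5Dclose);
    std::vector<char> buf((maxlen + 1) * n, '\0');
    for (int i = 0; i < n; ++i) {
      const std::string s = as<std::string>(ids[i]);
      std::copy(s.begin(), s.end(), buf.begin() + (maxlen + 1) * i);
    }
    H5Dwrite(ds, ty, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
  }

  Hid gvol(H5Gcreate2(file, "volumes", H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT),
           H5Gclose);
  Hid gsur(H5Gcreate2(file, "survival", H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT),
           H5Gclose);

  for (int i = 0; i < n; ++i) {
    const std::string id = as<std::string>(ids[i]);
    NumericVector vol = volumes[i];
    IntegerVector dim = vol.attr("dim");
    hsize_t len = (hsize_t)vol.size();
    {
      Hid sp(H5Screate_simple(1, &len, nullptr), H5Sclose);
      Hid ds(H5Dcreate2(gvol, id.c_str(), H5T_NATIVE_DOUBLE, sp, H5P_DEFAULT,
                        H5P_DEFAULT, H5P_DEFAULT), H5Dclose);
      if (ds < 0) stop("HDF5: cannot create volume dataset for '%s'", id.c_str());
      H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &vol[0]);
      hsize_t dlen = (hsize_t)dim.size();
      Hid asp(H5Screate_simple(1, &dlen, nullptr), H5Sclose);
      Hid att(H5Acreate2(ds, "dim", H5T_NATIVE_INT, asp, H5P_DEFAULT,
                         H5P_DEFAULT), H5Aclose);
      H5Awrite(att, H5T_NATIVE_INT, &dim[0]);
    }
    List rec = survival[i];
    Hid grp(H5Gcreate2(gsur, id.c_str(), H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT),
            H5Gclose);
    write_scalar_double(grp, "time", as<double>(rec["time"]));
    write_scalar_double(grp, "event", as<double>(rec["event"]));
    write_scalar_double(grp, "age", as<double>(rec["age"]));
    write_scalar_double(grp, "kps", as<double>(rec["kps"]));
    write_scalar_string(grp, "sex", as<std::string>(rec["sex"]));
    write_scalar_string(grp, "race", as<std::string>(rec["race"]));
    write_scalar_string(grp, "radiotherapy", as<std::string>(rec["radiotherapy"]));
    write_scalar_string(grp, "chemotherapy", as<std::string>(rec["chemotherapy"]));
  }
}

// [[Rcpp::export(name = ".cd_h5_read")]]
List cd_h5_read(std::string path) {
  silence_h5();
  Hid file(H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT), H5Fclose);
  if (file < 0)
    stop("HDF5: '%s' is not a readable HDF5 file (missing or corrupt)",
         path.c_str());

  Hid ds(H5Dopen2(file, "patient_order", H5P_DEFAULT), H5Dclose);
  if (ds < 0) stop("HDF5: '%s' lacks a /patient_order dataset", path.c_str());
  Hid ty(H5Dget_type(ds), H5Tclose);
  Hid sp(H5Dget_space(ds), H5Sclose);
  hsize_t n = 0;
  H5Sget_simple_extent_dims(sp, &n, nullptr);
  const size_t slen = H5Tget_size(ty);
  std::vector<char> buf(slen * n, '\0');
  if (H5Dread(ds, ty, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data()) < 0)
    stop("HDF5: failed reading patient order from '%s'", path.c_str());

  CharacterVector ids((int)n);
  List volumes((int)n), survival((int)n);
  for (hsize_t i = 0; i < n; ++i) {
    const std::string id(buf.data() + slen * i);
    ids[(int)i] = id;
    {
      Hid vds(H5Dopen2(file, ("volumes/" + id).c_str(), H5P_DEFAULT), H5Dclose);
      if (vds < 0) stop("HDF5: missing volume for patient '%s'", id.c_str());
      Hid vsp(H5Dget_space(vds), H5Sclose);
      hsize_t len = 0;
      H5Sget_simple_extent_dims(vsp, &len, nullptr);
      NumericVector vol((int)len);
      if (H5Dread(vds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                  &vol[0]) < 0)
        stop("HDF5: failed reading volume for '%s'", id.c_str());
      Hid att(H5Aopen(vds, "dim", H5P_DEFAULT), H5Aclose);
      if (att >= 0) {
        Hid asp(H5Aget_space(att), H5Sclose);
        hsize_t dlen = 0;
        H5Sget_simple_extent_dims(asp, &dlen, nullptr);
        IntegerVector dim((int)dlen);
        H5Aread(att, H5T_NATIVE_INT, &dim[0]);
        vol.attr("dim") = dim;
      }
      volumes[(int)i] = vol;
    }
    Hid grp(H5Gopen2(file, ("survival/" + id).c_str(), H5P_DEFAULT), H5Gclose);
    if (grp < 0) stop("HDF5: missing survival record for patient '%s'", id.c_str());
    survival[(int)i] = List::create(
      _["patient_id"] = id,
      _["time"] = read_scalar_double(grp, "time"),
      _["event"] = read_scalar_double(grp, "event"),
      _["age"] = read_scalar_double(grp, "age"),
      _["kps"] = read_scalar_double(grp, "kps"),
      _["sex"] = read_scalar_string(grp, "sex"),
      _["race"] = read_scalar_string(grp, "race"),
      _["radiotherapy"] = read_scalar_string(grp, "radiotherapy"),
      _["chemotherapy"] = read_scalar_string(grp, "chemotherapy"));
  }
  return List::create(_["ids"] = ids, _["volumes"] = volumes,
                      _["survival"] = survival);
}
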