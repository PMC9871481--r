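test_that("NIfTI round trip preserves volumes and labels exactly", {
  vol <- toy_volume("rt1")
  dir <- withr::local_tempdir()
  paths <- write_case(vol, dir)
  back <- read_case(paths["t1"], paths["t2"], paths["t1ce"], paths["flair"],
                    paths["seg"], patient_id = "rt1")
  expect_identical(dim(back$channels), dim(vol$channels))
  expect_equal(back$channels, vol$channels, tolerance = 0)
  expect_identical(back$seg, vol$seg)
  m <- tumor_masks(back)
  expect_true(all(m$core[m$enhancing]))   # enhancing subset of core
  expect_true(all(m$whole[m$core]))       # core subset of whole tumour
})

test_that("read_case rejects shape mismatches and unknown label codes", {
  vol <- toy_volume("bad1")
  dir <- withr::local_tempdir()
  paths <- write_case(vol, dir)
  small <- vol
  small$channels <- vol$channels[1:10, , , , drop = FALSE]
  small$seg <- vol$seg[1:10, , ]
  small$patient_id <- "bad2"
  p2 <- write_case(small, dir)
  expect_error(
    read_case(p2["t1"], paths["t2"], paths["t1ce"], paths["flair"],
              paths["seg"]),
    "shape mismatch.*bad2_t1")
  weird <- vol
  weird$seg[1, 1, 1] <- 7L
  p3 <- write_case(weird, dir)
  expect_error(
    read_case(p3["t1"], p3["t2"], p3["t1ce"], p3["flair"], p3["seg"]),
    "unknown segmentation label.*7")
})

test_that("normalization maps the percentile anchors to 0 and 1", {
  vol <- toy_volume("nm1", d = c(6L, 6L, 6L))
  vals <- seq(100, 900, length.out = 10)
  ch <- array(0, dim = c(6, 6, 6))
  ch[1:10] <- vals
  for (k in 1:4) vol$channels[, , , k] <- ch
  out <- normalize_modalities(vol)
  q <- quantile(vals, c(0.01, 0.99), names = FALSE)
  expected <- pmin(pmax((vals - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out$channels[, , , 2][1:10], expected)
  expect_equal(out$channels[, , , 1][11], 0)       # background stays zero
  # anchors map to the ends, interior is linear
  expect_equal(out$channels[, , , 1][1], 0)
  expect_equal(out$channels[, , , 1][10], 1)
  mid <- (vals[5] - q[1]) / (q[2] - q[1])
  expect_equal(out$channels[, , , 1][5], mid)
})

test_that("normalization is idempotent up to clipping on a matched range", {
  vol <- toy_volume("nm2", d = c(6L, 6L, 6L))
  set.seed(3)
  for (k in 1:4) {
    ch <- array(runif(216), dim = c(6, 6, 6))
    vol$channels[, , , k] <- ch
  }
  once <- normalize_modalities(vol)
  twice <- normalize_modalities(once)
  expect_lt(max(abs(once$channels - twice$channels)), 0.05)
})

test_that("normalization rejects constant nonzero channels", {
  vol <- toy_volume("nm3", d = c(6L, 6L, 6L))
  vol$channels[, , , 3] <- array(5, dim = c(6, 6, 6))
  expect_error(normalize_modalities(vol), "constant")
})

test_that("extract_voi centres a point tumour and errors on empty masks", {
  d <- c(24L, 24L, 24L)
  seg <- array(0L, dim = d)
  seg[10, 10, 10] <- 1L
  ch <- array(0, dim = c(d, 4L))
  ch[10, 10, 10, ] <- c(0.1, 0.2, 0.3, 0.4)
  vol <- coxdae:::new_volume("pt", ch, c(1, 1, 1), seg)
  voi <- extract_voi(vol, c(16L, 16L, 16L))
  expect_equal(voi$data[8, 8, 8, ], c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(voi$data != 0), 4L)

  vol$seg[] <- 0L
  expect_error(extract_voi(vol, c(16L, 16L, 16L)), "empty")
})

test_that("extract_voi with a full mask and matching target is the identity", {
  d <- c(8L, 8L, 8L)
  set.seed(5)
  ch <- array(runif(prod(d) * 4), dim = c(d, 4L))
  seg <- array(1L, dim = d)
  vol <- coxdae:::new_volume("full", ch, c(1, 1, 1), seg)
  voi <- extract_voi(vol, d)
  expect_equal(voi$data, ch)
})

test_that("extract_voi output satisfies the VOI invariants on random input", {
  shapes <- list(c(16L, 16L, 16L), c(16L, 24L, 8L))
  for (s in seq_along(shapes)) {
    cfg <- sim_config(n_patients = 2, vol_shape = c(26L, 30L, 28L),
                      seed = 20 + s)
    cs <- simulate_case(cfg, 1)
    voi <- extract_voi(normalize_modalities(cs$volume), shapes[[s]])
    expect_identical(dim(voi$data), c(shapes[[s]], 4L))
    expect_gte(min(voi$data), 0)
    expect_lte(max(voi$data), 1)
  }
})

test_that("extract_voi validates the target shape and input range", {
  vol <- toy_volume("shp")
  expect_error(extract_voi(vol, c(15L, 16L, 16L)), "divisible by 8")
  expect_error(extract_voi(vol, c(16L, 16L, 16L)), "normalize")
})

test_that("augmentation is deterministic, shape- and mean-preserving", {
  voi <- toy_voi("aug", d = c(8L, 8L, 8L))
  a1 <- augment_voi(voi, seed = 7)
  a2 <- augment_voi(voi, seed = 7)
  expect_identical(a1$data, a2$data)
  expect_identical(dim(a1$data), dim(voi$data))
  for (k in 1:4) {
    expect_equal(mean(a1$data[, , , k]), mean(voi$data[, , , k]))
    expect_equal(sort(as.numeric(a1$data[, , , k])),
                 sort(as.numeric(voi$data[, , , k])))
  }
  a3 <- augment_voi(voi, seed = 8)
  expect_false(identical(a1$data, a3$data))
})

test_that("axis mirroring is an involution", {
  voi <- toy_voi("inv")
  for (ax in 1:3)
    expect_identical(coxdae:::flip_axis(coxdae:::flip_axis(voi$data, ax), ax),
                     voi$data)
})

test_that("HDF5 pack/unpack round-trips arrays and records losslessly", {
  cases <- list(toy_case("p1", seed = 1, time = 120.5, event = 1),
                toy_case("p2", seed = 2, time = 300, event = 0),
                toy_case("p3", seed = 3, time = 45, event = 1))
  cases[[2]]$record$age <- NA_real_          # missing covariates survive
  cases[[2]]$record$race <- NA_character_
  path <- withr::local_tempfile(fileext = ".h5")
  pack_h5(cases, path)
  back <- unpack_h5(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$voi$patient_id, cases[[i]]$voi$patient_id)
    expect_equal(back[[i]]$voi$data, cases[[i]]$voi$data, tolerance = 0)
    expect_identical(back[[i]]$record, cases[[i]]$record)
  }
})

test_that("packing rejects empty lists and missing records", {
  expect_error(pack_h5(list(), tempfile()), "empty")
  cs <- toy_case("p1")
  cs$record <- NULL
  expect_error(pack_h5(list(cs), tempfile()), "missing survival record")
})

test_that("unpacking a truncated file raises a structured error", {
  cases <- list(toy_case("p1"), toy_case("p2"))
  path <- withr::local_tempfile(fileext = ".h5")
  pack_h5(cases, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(bytes[1:200], path)
  expect_error(unpack_h5(path), "HDF5")
  expect_error(unpack_h5(tempfile()), "not found")
})

test_that("cohort split reproduces 143/31/31 at n = 205 and partitions ids", {
  ids <- sprintf("pt%03d", 1:205)
  sp <- split_cohort(ids, seed = 4)
  expect_length(sp$train, 143L)
  expect_length(sp$val, 31L)
  expect_length(sp$test, 31L)
  expect_identical(sp, split_cohort(ids, seed = 4))
  expect_false(identical(sp, split_cohort(ids, seed = 5)))
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  expect_error(split_cohort(ids[1:3], c(0.98, 0.01, 0.01)), "empty")
  expect_error(split_cohort(ids, c(0.5, 0.2, 0.2)), "sum to 1")
})
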