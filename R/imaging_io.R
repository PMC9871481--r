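#' Read one multimodal MRI case from NIfTI files
#'
#' Loads the four MRI modalities (T1, T2, T1ce, FLAIR) together with the
#' tumour segmentation into a single multimodal volume. The segmentation uses
#' the BraTS label convention: 0 = background, 1 = necrotic / non-enhancing
#' tumour core, 2 = peritumoural edema, 4 = enhancing tumour, which defines
#' three nested regions (whole tumour = 1+2+4, tumour core = 1+4, enhancing
#' tumour = 4).
#'
#' @param t1_path,t2_path,t1ce_path,flair_path Paths to the modality NIfTI
#'   files (`.nii` or `.nii.gz`), one 3-D volume each.
#' @param seg_path Path to the segmentation NIfTI file with integer labels.
#' @param patient_id Identifier attached to the case; defaults to the common
#'   file-name prefix of `t1_path`.
#' @return A `coxdae_volume`: list with `patient_id`, `channels` (4-D array
#'   `d1 x d2 x d3 x 4`, modality order T1, T2, T1ce, FLAIR), `spacing`
#'   (mm/voxel) and `seg` (3-D integer label array).
#' @export
read_case <- function(t1_path, t2_path, t1ce_path, flair_path, seg_path,
                      patient_id = NULL) {
  paths <- c(T1 = t1_path, T2 = t2_path, T1ce = t1ce_path, FLAIR = flair_path,
             seg = seg_path)
  for (p in paths)
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  imgs <- lapply(paths, function(p) RNifti::readNifti(p))
  arrs <- lapply(imgs, function(im) {
    a <- as.array(im)
    if (length(dim(a)) != 3L)
      stop("expected a 3-D NIfTI volume", call. = FALSE)
    a
  })
  ref <- dim(arrs[[1L]])
  for (k in seq_along(arrs))
    if (!identical(dim(arrs[[k]]), ref))
      stop(sprintf("shape mismatch: '%s' is %s but '%s' is %s",
                   paths[[k]], paste(dim(arrs[[k]]), collapse = "x"),
                   paths[[1L]], paste(ref, collapse = "x")), call. = FALSE)
  seg <- arrs[[5L]]
  codes <- sort(unique(as.integer(seg)))
  if (!all(codes %in% c(0L, 1L, 2L, 4L)))
    stop("unknown segmentation label code(s): found {",
         paste(codes, collapse = ", "), "}, expected subset of {0, 1, 2, 4}",
         call. = FALSE)
  channels <- array(0, dim = c(ref, 4L))
  for (k in 1:4) channels[, , , k] <- arrs[[k]]
  spacing <- tryCatch(RNifti::pixdim(imgs[[1L]])[1:3],
                      error = function(e) c(1, 1, 1))
  if (is.null(patient_id))
    patient_id <- sub("(_t1)?\\.nii(\\.gz)?$", "", basename(t1_path))
  new_volume(patient_id, channels, spacing, array(as.integer(seg), dim = ref))
}

new_volume <- function(patient_id, channels, spacing, seg) {
  stopifnot(length(dim(channels)) == 4L, dim(channels)[4L] == 4L,
            identical(dim(seg), dim(channels)[1:3]))
  structure(list(patient_id = patient_id, channels = channels,
                 spacing = spacing, seg = seg),
            class = "coxdae_volume")
}

#' @export
print.coxdae_volume <- function(x, ...) {
  cat("<coxdae_volume> patient", x$patient_id, "|",
      paste(dim(x$seg), collapse = "x"),
      "| whole-tumour voxels:", sum(x$seg > 0L), "\n")
  invisible(x)
}

#' Nested tumour region masks
#'
#' @param vol A `coxdae_volume`.
#' @return List of logical arrays `whole`, `core`, `enhancing`, satisfying
#'   `whole >= core >= enhancing` (set inclusion).
#' @export
tumor_masks <- function(vol) {
  seg <- vol$seg
  list(whole = seg == 1L | seg == 2L | seg == 4L,
       core = seg == 1L | seg == 4L,
       enhancing = seg == 4L)
}

#' Per-modality intensity normalization
#'
#' Each channel is independently rescaled to \[0, 1\] by an affine map fixed
#' at robust percentiles of its nonzero (brain) voxels, then clipped. Zero
#' voxels (background outside the head) remain exactly 0. The \[0, 1\] range is
#' required downstream because the decoder ends in a sigmoid.
#'
#' @param vol A `coxdae_volume`.
#' @param probs Lower/upper percentile anchors of the affine map
#'   (default 1st and 99th, robust against hot voxels).
#' @return The volume with normalized channels.
#' @export
normalize_modalities <- function(vol, probs = c(0.01, 0.99)) {
  stopifnot(inherits(vol, "coxdae_volume"), length(probs) == 2L,
            probs[1L] < probs[2L])
  ch <- vol$channels
  for (k in 1:4) {
    a <- ch[, , , k]
    nz <- a != 0
    if (!any(nz))
      stop("channel ", k, " has no nonzero voxels", call. = FALSE)
    q <- quantile(a[nz], probs, names = FALSE)
    if (q[2L] <= q[1L])
      stop("channel ", k, " has (near-)constant nonzero intensities; ",
           "cannot normalize", call. = FALSE)
    s <- (a - q[1L]) / (q[2L] - q[1L])
    s[s < 0] <- 0
    s[s > 1] <- 1
    s[!nz] <- 0
    ch[, , , k] <- s
  }
  vol$channels <- ch
  vol
}

#' Extract the tumour volume of interest
#'
#' Crops the bounding box of the whole-tumour mask, centres it inside the
#' target shape with zero padding (centre-cropping with a warning if the
#' tumour is larger than the target along an axis), and zeroes every voxel
#' outside the whole-tumour region, so that only the lesion enters the model.
#'
#' @param vol A normalized `coxdae_volume` (all intensities in \[0, 1\]).
#' @param shape Integer target shape, each axis `>= 8` and divisible by 8
#'   (three 2x downsamplings). Default `c(64, 64, 128)`.
#' @return A `coxdae_voi`: list with `patient_id` and `data`, a
#'   `shape x 4` array in \[0, 1\].
#' @export
extract_voi <- function(vol, shape = c(64L, 64L, 128L)) {
  stopifnot(inherits(vol, "coxdae_volume"), length(shape) == 3L)
  shape <- as.integer(shape)
  if (any(shape < 8L) || any(shape %% 8L != 0L))
    stop("VOI shape must have every axis >= 8 and divisible by 8",
         call. = FALSE)
  rng <- range(vol$channels)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("volume intensities outside [0, 1]; call normalize_modalities() ",
         "before extract_voi()", call. = FALSE)
  whole <- vol$seg > 0L
  if (!any(whole))
    stop("whole-tumour mask is empty for patient ", vol$patient_id,
         call. = FALSE)
  idx <- which(whole, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  hi <- apply(idx, 2L, max)
  ext <- hi - lo + 1L
  if (any(ext > shape)) {
    warning("tumour bounding box (", paste(ext, collapse = "x"),
            ") exceeds VOI shape (", paste(shape, collapse = "x"),
            ") for patient ", vol$patient_id, "; centre-cropping",
            call. = FALSE)
    ctr <- as.integer(floor((lo + hi) / 2))
    w <- pmin(shape, dim(vol$seg))
    start <- pmax(1L, pmin(ctr - w %/% 2L + 1L, dim(vol$seg) - w + 1L))
    lo <- start
    hi <- start + w - 1L
    ext <- w
  }
  off <- pmax(0L, as.integer(floor((shape - ext) / 2)))
  out <- array(0, dim = c(shape, 4L))
  src1 <- lo
  src2 <- lo + pmin(ext, shape) - 1L
  dst1 <- off + 1L
  dst2 <- off + pmin(ext, shape)
  sub_mask <- whole[src1[1]:src2[1], src1[2]:src2[2], src1[3]:src2[3],
                    drop = FALSE]
  for (k in 1:4) {
    sub <- vol$channels[src1[1]:src2[1], src1[2]:src2[2], src1[3]:src2[3], k,
                        drop = FALSE]
    dim(sub) <- dim(sub)[1:3]
    sub[!sub_mask] <- 0
    out[dst1[1]:dst2[1], dst1[2]:dst2[2], dst1[3]:dst2[3], k] <- sub
  }
  new_voi(vol$patient_id, out)
}

new_voi <- function(patient_id, data) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4L] == 4L)
  if (min(data) < 0 || max(data) > 1)
    stop("VOI intensities must lie in [0, 1]", call. = FALSE)
  structure(list(patient_id = patient_id, data = data), class = "coxdae_voi")
}

#' @export
print.coxdae_voi <- function(x, ...) {
  cat("<coxdae_voi> patient", x$patient_id, "|",
      paste(dim(x$data)[1:3], collapse = "x"), "x 4 channels\n")
  invisible(x)
}

#' Online augmentation: axis mirroring and right-angle rotation
#'
#' Applies an independent 50% mirror along each spatial axis and one rotation
#' by a random multiple of 90 degrees in a randomly chosen axis pair,
#' identically across the four channels. Rotations are restricted to right
#' angles so that no interpolation touches the intensities (the multiset of
#' voxel values per channel is preserved exactly); if the two axes of the
#' chosen pair differ in length, only the 180-degree rotation is available.
#'
#' @param voi A `coxdae_voi`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return The augmented `coxdae_voi`.
#' @export
augment_voi <- function(voi, seed) {
  stopifnot(inherits(voi, "coxdae_voi"))
  a <- voi$data
  d <- dim(a)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  for (ax in 1:3)
    if (runif(1) < 0.5)
      a <- flip_axis(a, ax)
  pair <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[sample.int(3L, 1L)]]
  k <- sample.int(4L, 1L) - 1L               # 0, 90, 180, 270 degrees
  if (d[pair[1L]] != d[pair[2L]] && k %% 2L == 1L) k <- 2L
  a <- rotate90(a, pair, k)
  voi$data <- a
  voi
}

# save/restore the global RNG stream so augmentation is a pure function of
# its seed
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

flip_axis <- function(a, axis) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), 4L)
  idx[[axis]] <- d[axis]:1L
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

rotate90 <- function(a, pair, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    perm <- 1:4
    perm[pair] <- rev(pair)
    a <- aperm(a, perm)
    a <- flip_axis(a, pair[1L])
  }
  a
}

#' Pack a preprocessed cohort into an HDF5 container
#'
#' Stores each case's 4-channel VOI under `/volumes/<id>` and its survival
#' record under `/survival/<id>`, with `/patient_order` fixing a stable
#' ordering. The round trip through [unpack_h5()] is lossless.
#'
#' @param cases List of cases, each a list with elements `voi`
#'   (a `coxdae_voi`) and `record` (a survival record, see
#'   [survival_record()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
pack_h5 <- function(cases, path) {
  if (length(cases) == 0L) stop("empty case list", call. = FALSE)
  ids <- character(length(cases))
  vols <- vector("list", length(cases))
  recs <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (is.null(cs$voi) || !inherits(cs$voi, "coxdae_voi"))
      stop("case ", i, " lacks a VOI", call. = FALSE)
    if (is.null(cs$record))
      stop("missing survival record for packed volume '",
           cs$voi$patient_id, "'", call. = FALSE)
    rec <- validate_record(cs$record)
    ids[i] <- cs$voi$patient_id
    vols[[i]] <- cs$voi$data
    recs[[i]] <- lapply(rec, function(v) {
      if (is.character(v) && is.na(v)) "" else v
    })
  }
  .cd_h5_write(path.expand(path), ids, vols, recs)
  invisible(path)
}

#' @rdname pack_h5
#' @export
unpack_h5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- .cd_h5_read(path.expand(path))
  lapply(seq_along(raw$ids), function(i) {
    rec <- raw$survival[[i]]
    for (f in c("sex", "race", "radiotherapy", "chemotherapy"))
      if (identical(rec[[f]], "")) rec[f] <- list(NA_character_)
    for (f in c("age", "kps"))
      if (is.nan(rec[[f]])) rec[f] <- list(NA_real_)
    list(voi = new_voi(raw$ids[[i]], raw$volumes[[i]]),
         record = do.call(survival_record, rec))
  })
}

#' Construct and validate a survival record
#'
#' @param patient_id Identifier.
#' @param time Survival or censoring time in days, strictly positive.
#' @param event 1 = death observed, 0 = censored.
#' @param age,kps Numeric covariates (may be `NA`).
#' @param sex,race,radiotherapy,chemotherapy Categorical covariates (may be
#'   `NA`).
#' @return A named list of class `coxdae_record`.
#' @export
survival_record <- function(patient_id, time, event, age = NA_real_,
                            kps = NA_real_, sex = NA_character_,
                            race = NA_character_,
                            radiotherapy = NA_character_,
                            chemotherapy = NA_character_) {
  rec <- structure(list(patient_id = as.character(patient_id),
                        time = as.numeric(time), event = as.numeric(event),
                        age = as.numeric(age), kps = as.numeric(kps),
                        sex = as.character(sex), race = as.character(race),
                        radiotherapy = as.character(radiotherapy),
                        chemotherapy = as.character(chemotherapy)),
                   class = "coxdae_record")
  validate_record(rec)
}

validate_record <- function(rec) {
  if (!is.finite(rec$time) || rec$time <= 0)
    stop("survival time must be strictly positive (patient '",
         rec$patient_id, "')", call. = FALSE)
  if (!rec$event %in% c(0, 1))
    stop("event indicator must be 0 or 1 (patient '", rec$patient_id, "')",
         call. = FALSE)
  rec
}

#' Read a clinical covariate table
#'
#' Expects a CSV with header columns `patient_id, time_days, event, age, sex,
#' race, kps, radiotherapy, chemotherapy`.
#'
#' @param path CSV file path.
#' @return A data frame with one validated row per patient.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event", "age", "sex", "race", "kps",
            "radiotherapy", "chemotherapy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$time_days)) || any(df$time_days <= 0))
    stop("all survival times must be strictly positive", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 or 1", call. = FALSE)
  df
}

#' Reproducible train/validation/test split
#'
#' Randomly partitions patient ids. Validation and test sizes are
#' `round(n * fraction)` with every remaining case assigned to training, so a
#' 205-patient cohort under the default 70/15/15 split yields 143/31/31.
#'
#' @param ids Character vector of patient ids (or a data frame with a
#'   `patient_id` column).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed making the split reproducible.
#' @return List with character vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (is.data.frame(ids)) ids <- ids$patient_id
  ids <- as.character(ids)
  stopifnot(length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  perm <- sample(ids)
  n_val <- round(n * fractions[2L])
  n_test <- round(n * fractions[3L])
  n_train <- n - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop("split produces an empty subset (n = ", n, ")", call. = FALSE)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Write a multimodal case to NIfTI files
#'
#' Fixture-writer companion of [read_case()]: emits the four modality volumes
#' and the segmentation as `.nii.gz` files named `<id>_<modality>.nii.gz`.
#'
#' @param vol A `coxdae_volume`.
#' @param dir Output directory.
#' @return Named character vector of the five file paths.
#' @export
write_case <- function(vol, dir) {
  stopifnot(inherits(vol, "coxdae_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mods <- c("t1", "t2", "t1ce", "flair")
  paths <- c()
  for (k in 1:4) {
    p <- file.path(dir, paste0(vol$patient_id, "_", mods[k], ".nii.gz"))
    arr <- vol$channels[, , , k]
    dim(arr) <- dim(vol$seg)
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = vol$spacing), p)
    paths[mods[k]] <- p
  }
  p <- file.path(dir, paste0(vol$patient_id, "_seg.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(vol$seg + 0, pixdim = vol$spacing), p)
  paths["seg"] <- p
  paths
}
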