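#' Model configuration
#'
#' Architecture of the denoising autoencoder with survival branch: a
#' three-stage encoder producing 16, 32 and 64 feature maps (3x3x3
#' convolutions, LeakyReLU, 2x max-pooling), a mirrored three-stage decoder
#' (convolution, LeakyReLU, 2x nearest-neighbour upsampling; final
#' convolution to 4 channels with sigmoid), and a survival branch on the
#' flattened 64-channel hidden matrix: dense 1024 -> dropout -> dense 128 ->
#' dropout -> single linear output without bias (the prognostic index; a bias
#' would be unidentifiable under the partial likelihood's shift invariance).
#' Batch normalization and voxel "corruption" dropout are applied once at the
#' input, making the autoencoder denoising.
#'
#' @param voi_shape Input spatial shape; every axis must be a multiple of 8.
#'   The default `c(64, 64, 128)` makes the flattened hidden matrix exactly
#'   `64 * prod(voi_shape) / 512 = 65536` features.
#' @param input_dropout_rate Fraction of input voxels randomly zeroed during
#'   training (the denoising corruption).
#' @param branch_dropout_rates Dropout after the 1024- and 128-unit dense
#'   layers.
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param recon_reduction Reduction of the reconstruction loss:
#'   `"case_sum"` sums squared voxel errors per case and averages over the
#'   batch (the mean-squared-error written per case); `"mean"` additionally
#'   divides by the number of voxel entries, putting the loss on a scale
#'   comparable with the partial-likelihood term.
#' @return A `coxdae_model_config`.
#' @export
model_config <- function(voi_shape = c(64L, 64L, 128L),
                         input_dropout_rate = 0.2,
                         branch_dropout_rates = c(0.5, 0.3),
                         leaky_slope = 0.1,
                         recon_reduction = c("case_sum", "mean")) {
  recon_reduction <- match.arg(recon_reduction)
  voi_shape <- as.integer(voi_shape)
  stopifnot(length(voi_shape) == 3L, length(branch_dropout_rates) == 2L)
  if (any(voi_shape < 8L) || any(voi_shape %% 8L != 0L))
    stop("every VOI axis must be >= 8 and divisible by 8 ",
         "(three 2x downsamplings)", call. = FALSE)
  rates <- c(input_dropout_rate, branch_dropout_rates)
  if (any(rates < 0) || any(rates >= 1))
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  structure(list(voi_shape = voi_shape,
                 encoder_channels = c(16L, 32L, 64L),
                 decoder_channels = c(64L, 32L, 16L),
                 dense_dims = c(1024L, 128L),
                 input_dropout_rate = input_dropout_rate,
                 branch_dropout_rates = branch_dropout_rates,
                 leaky_slope = leaky_slope,
                 recon_reduction = recon_reduction),
            class = "coxdae_model_config")
}

#' Create a DAE-Cox model
#'
#' @param config A [model_config()].
#' @param seed Seed for weight initialization and the model's internal
#'   dropout/corruption stream.
#' @return A `coxdae_model` holding the network state.
#' @export
dae_cox_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "coxdae_model_config"))
  ptr <- .cd_net_create(config$voi_shape, config$leaky_slope,
                        config$input_dropout_rate,
                        config$branch_dropout_rates[1L],
                        config$branch_dropout_rates[2L], as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "coxdae_model")
}

#' @export
print.coxdae_model <- function(x, ...) {
  cat("<coxdae_model>", paste(x$config$voi_shape, collapse = "x"),
      "x4 input | encoder", paste(x$config$encoder_channels, collapse = "-"),
      "| flatten", flatten_length(x),
      "| params", format(.cd_net_n_params(x$ptr), big.mark = ","), "\n")
  invisible(x)
}

#' Length of the flattened hidden feature matrix
#'
#' After three 2x downsamplings the 64-channel hidden matrix flattens to
#' `64 * prod(voi_shape) / 512` features (65,536 at the default
#' 64 x 64 x 128 input).
#'
#' @param x A `coxdae_model` or `coxdae_model_config`.
#' @return Integer feature count.
#' @export
flatten_length <- function(x) {
  if (inherits(x, "coxdae_model")) return(.cd_net_flat_dim(x$ptr))
  stopifnot(inherits(x, "coxdae_model_config"))
  as.integer(64 * prod(x$voi_shape) / 512)
}

# accept a coxdae_voi, a 4-D array (one case) or a 5-D array (batch);
# returns a 5-D batch array
as_batch_array <- function(x, voi_shape) {
  if (inherits(x, "coxdae_voi")) x <- x$data
  if (is.list(x)) {
    arrs <- lapply(x, function(v) if (inherits(v, "coxdae_voi")) v$data else v)
    x <- array(unlist(arrs, use.names = FALSE),
               dim = c(dim(arrs[[1L]]), length(arrs)))
  }
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (length(d) != 5L || d[4L] != 4L ||
      !identical(as.integer(d[1:3]), as.integer(voi_shape)))
    stop("input batch does not match the model's VOI shape (",
         paste(voi_shape, collapse = "x"), " x 4 channels)", call. = FALSE)
  x
}

#' Forward pass
#'
#' @param model A `coxdae_model`.
#' @param x A `coxdae_voi`, list of them, or a 4-D/5-D array.
#' @param training If `TRUE`, input corruption and branch dropout are active
#'   and batch normalization uses batch statistics; inference
#'   (`training = FALSE`) is fully deterministic.
#' @return List with `recon` (reconstructions in (0, 1), same shape as the
#'   batch) and `risk` (one prognostic-index scalar per case, the log
#'   relative hazard).
#' @export
forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "coxdae_model"))
  xb <- as_batch_array(x, model$config$voi_shape)
  .cd_net_forward(model$ptr, xb, isTRUE(training))
}

#' Reconstruction loss
#'
#' Mean over the batch of the squared reconstruction error per case
#' (`reduction = "case_sum"`, the printed formula
#' `L_r = (1/n) sum_i || x_i - psi(phi(x_i)) ||^2`), or the overall per-entry
#' mean (`reduction = "mean"`).
#'
#' @param x,recon Arrays of identical shape (4-D single case or 5-D batch).
#' @param reduction `"case_sum"` or `"mean"`.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x, recon, reduction = c("case_sum", "mean")) {
  reduction <- match.arg(reduction)
  if (inherits(x, "coxdae_voi")) x <- x$data
  if (inherits(recon, "coxdae_voi")) recon <- recon$data
  if (!identical(dim(x), dim(recon)))
    stop("x and recon shapes differ", call. = FALSE)
  if (length(x) == 0L) stop("empty batch", call. = FALSE)
  n <- if (length(dim(x)) == 5L) dim(x)[5L] else 1L
  total <- sum((as.numeric(x) - as.numeric(recon))^2)
  if (reduction == "case_sum") total / n else total / length(x)
}

#' Cox partial-likelihood loss
#'
#' Negative log partial likelihood of the risk scores,
#' `L_s = -sum_i delta_i ( r_i - log sum_{j in R(t_i)} exp(r_j) )`,
#' with the risk set `R(t_i) = { j : t_j >= t_i }` computed within the batch.
#' Tied event times are handled by the Breslow convention (every tied event
#' uses the same full risk set) and the log-sum-exp is stabilized. Returns 0
#' when no event is present.
#'
#' @param risk Numeric risk scores (log relative hazards), one per case.
#' @param time Survival times in days, strictly positive.
#' @param event Event indicators (1 = death, 0 = censored).
#' @return Scalar loss.
#' @export
cox_loss <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  if (any(time <= 0)) stop("all times must be strictly positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 or 1", call. = FALSE)
  .cd_cox_npll(as.numeric(risk), as.numeric(time), as.integer(event),
               FALSE)$loss
}

#' Gradient of [cox_loss()] with respect to the risk scores
#'
#' @inheritParams cox_loss
#' @return Numeric gradient vector.
#' @export
cox_loss_grad <- function(risk, time, event) {
  if (any(time <= 0)) stop("all times must be strictly positive", call. = FALSE)
  .cd_cox_npll(as.numeric(risk), as.numeric(time), as.integer(event),
               TRUE)$grad
}

#' Loss weights of the hybrid objective
#'
#' @param alpha Weight of the reconstruction term.
#' @param beta Weight of the Cox term. `alpha + beta` must equal 1; the
#'   default 0.7/0.3 is the 7:3 weighting.
#' @return A `coxdae_loss_weights`.
#' @export
loss_weights <- function(alpha = 0.7, beta = 0.3) {
  if (alpha < 0 || beta < 0)
    stop("loss weights must be non-negative", call. = FALSE)
  if (abs(alpha + beta - 1) > 1e-9)
    stop("alpha + beta must equal 1 (got ", alpha + beta, ")", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "coxdae_loss_weights")
}

#' Hybrid training loss
#'
#' `L_hybrid = alpha * L_r + beta * L_s`.
#'
#' @inheritParams reconstruction_loss
#' @inheritParams cox_loss
#' @param weights A [loss_weights()].
#' @return Scalar loss.
#' @export
hybrid_loss <- function(x, recon, risk, time, event,
                        weights = loss_weights(),
                        reduction = c("case_sum", "mean")) {
  stopifnot(inherits(weights, "coxdae_loss_weights"))
  weights$alpha * reconstruction_loss(x, recon, match.arg(reduction)) +
    weights$beta * cox_loss(risk, time, event)
}

#' Extract / restore a model checkpoint
#'
#' A checkpoint bundles every network weight, the batch-normalization running
#' statistics and the model configuration, and is a plain R list (suitable
#' for `saveRDS()`).
#'
#' @param model A `coxdae_model`.
#' @return A `coxdae_checkpoint`.
#' @export
model_checkpoint <- function(model) {
  stopifnot(inherits(model, "coxdae_model"))
  structure(list(state = .cd_net_get_state(model$ptr),
                 config = model$config, seed = model$seed),
            class = "coxdae_checkpoint")
}

#' @param checkpoint A `coxdae_checkpoint`.
#' @rdname model_checkpoint
#' @export
model_from_checkpoint <- function(checkpoint) {
  stopifnot(inherits(checkpoint, "coxdae_checkpoint"))
  model <- dae_cox_model(checkpoint$config, seed = checkpoint$seed)
  .cd_net_set_state(model$ptr, checkpoint$state)
  model
}
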