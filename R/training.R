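#' Training configuration
#'
#' @param batch_size Cases per batch (default 26; at least 2, below which
#'   within-batch risk sets degenerate).
#' @param lr Initial Adam learning rate (default 5e-4).
#' @param epochs Scheduled training epochs (default 200).
#' @param max_epochs Absolute cap on epochs (default 300).
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is halved (default 10).
#' @param plateau_factor Multiplicative learning-rate decay (default 0.5).
#' @param loss_weights A [loss_weights()]; default 0.7/0.3.
#' @param augment Apply online mirror/rotation augmentation to training
#'   batches.
#' @param seed Seed controlling batch shuffling, augmentation and the
#'   model's corruption stream.
#' @return A `coxdae_train_config`.
#' @export
train_config <- function(batch_size = 26L, lr = 5e-4, epochs = 200L,
                         max_epochs = 300L, plateau_patience = 10L,
                         plateau_factor = 0.5,
                         loss_weights = coxdae::loss_weights(),
                         augment = TRUE, seed = 1L) {
  stopifnot(batch_size >= 2L, lr > 0, epochs >= 1L, plateau_patience >= 1L,
            plateau_factor > 0, plateau_factor < 1,
            inherits(loss_weights, "coxdae_loss_weights"))
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs),
                 max_epochs = as.integer(max_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 loss_weights = loss_weights, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "coxdae_train_config")
}

#' Build time-sorted training batches
#'
#' Cases are randomly partitioned into batches (reshuffled per call under the
#' seed) and each batch is then sorted ascending by survival time, so that
#' for a batch in this order the risk set of case `i` is the suffix
#' `{i, ..., n}` up to ties. A final short batch is kept if it has at least 2
#' cases including at least one event, and is otherwise merged into the
#' previous batch. An all-censored batch is allowed (its partial-likelihood
#' term is 0) and reported via a message.
#'
#' @param times Survival times of the cases.
#' @param events Event indicators.
#' @param batch_size Cases per batch.
#' @param seed Shuffle seed.
#' @return List of integer index vectors, each sorted ascending in time.
#' @export
make_batches <- function(times, events, batch_size, seed = 1L) {
  n <- length(times)
  stopifnot(length(events) == n)
  if (n < batch_size && n < 2L)
    stop("need at least 2 cases to form a batch", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  perm <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) perm[s:min(s + batch_size - 1L, n)])
  last <- batches[[length(batches)]]
  if (length(batches) > 1L &&
      (length(last) < 2L || sum(events[last]) < 1L)) {
    batches[[length(batches) - 1L]] <- c(batches[[length(batches) - 1L]], last)
    batches[[length(batches)]] <- NULL
  }
  batches <- lapply(batches, function(b) b[order(times[b])])
  for (b in batches)
    if (sum(events[b]) == 0L)
      message("all-censored batch of ", length(b),
              " cases (contributes no partial-likelihood term)")
  batches
}

# plateau learning-rate state machine: the rate is halved at epoch e when
# e - marker >= patience, where marker is the epoch of the last improvement
# or the last decay; so with no improvement after epoch 1 the rate halves at
# epochs 1 + patience, 1 + 2 * patience, ...
.plateau_step <- function(state, epoch) {
  if (epoch - state$marker >= state$patience) {
    state$lr <- state$lr * state$factor
    state$marker <- epoch
  }
  state
}

.plateau_observe <- function(state, epoch, val_loss) {
  if (is.finite(val_loss) && val_loss < state$best - 1e-12) {
    state$best <- val_loss
    state$marker <- epoch
    state$improved <- TRUE
  } else state$improved <- FALSE
  state
}

#' Learning-rate sequence implied by a validation-loss history
#'
#' Pure replay of the plateau schedule used by [train_dae_cox()]: starting
#' from `lr0`, the rate is multiplied by `factor` whenever `patience` epochs
#' pass without a strict improvement of the validation loss (the decay epoch
#' itself restarts the count).
#'
#' @param val_losses Validation losses, one per epoch.
#' @param lr0 Initial learning rate.
#' @param patience Epochs without improvement before decay.
#' @param factor Decay factor.
#' @return Data frame with `epoch`, `lr` (the rate in force during that
#'   epoch) and `val_loss`.
#' @export
plateau_schedule <- function(val_losses, lr0 = 5e-4, patience = 10L,
                             factor = 0.5) {
  state <- list(lr = lr0, best = Inf, marker = 1L,
                patience = as.integer(patience), factor = factor)
  lr <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    state <- .plateau_step(state, e)
    lr[e] <- state$lr
    state <- .plateau_observe(state, e, val_losses[e])
  }
  data.frame(epoch = seq_along(val_losses), lr = lr, val_loss = val_losses)
}

# convert a case list (elements with $voi and $record) into batch tensors
cohort_tensors <- function(cases) {
  stopifnot(length(cases) >= 1L)
  d <- dim(cases[[1L]]$voi$data)
  x <- array(0, dim = c(d, length(cases)))
  for (i in seq_along(cases)) x[, , , , i] <- cases[[i]]$voi$data
  list(x = x,
       id = vapply(cases, function(cs) cs$record$patient_id, ""),
       time = vapply(cases, function(cs) cs$record$time, 0),
       event = vapply(cases, function(cs) cs$record$event, 0))
}

#' Train the DAE-Cox model
#'
#' Optimizes the hybrid loss with Adam on randomly scrambled, time-sorted
#' batches, with online augmentation and input corruption active. After each
#' epoch the hybrid loss is evaluated on the validation set (corruption and
#' dropout off); the learning rate is halved after `plateau_patience`
#' non-improving epochs and the best-validation checkpoint is retained.
#'
#' @param model A `coxdae_model`.
#' @param train_cases,val_cases Case lists (elements with `$voi` and
#'   `$record`), as produced by [unpack_h5()] or [simulate_cohort()].
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `coxdae_fit`: list with `checkpoint` (best validation),
#'   `history` (per-epoch data frame with loss components and learning
#'   rate) and `best_epoch`.
#' @export
train_dae_cox <- function(model, train_cases, val_cases,
                          cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "coxdae_model"),
            inherits(cfg, "coxdae_train_config"))
  tr <- cohort_tensors(train_cases)
  va <- cohort_tensors(val_cases)
  if (length(intersect(tr$id, va$id)))
    stop("train and validation sets overlap", call. = FALSE)
  w <- cfg$loss_weights
  red <- model$config$recon_reduction
  n_epochs <- min(cfg$epochs, cfg$max_epochs)

  .cd_net_seed(model$ptr, cfg$seed)
  state <- list(lr = cfg$lr, best = Inf, marker = 1L,
                patience = cfg$plateau_patience, factor = cfg$plateau_factor)
  best_state <- NULL
  best_epoch <- NA_integer_
  hist <- vector("list", n_epochs)

  for (e in seq_len(n_epochs)) {
    state <- .plateau_step(state, e)
    batches <- make_batches(tr$time, tr$event, cfg$batch_size,
                            seed = cfg$seed * 1000L + e)
    tl <- c(l_r = 0, l_s = 0, hybrid = 0)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      xb <- tr$x[, , , , b, drop = FALSE]
      if (cfg$augment) {
        for (j in seq_along(b)) {
          v <- new_voi("aug", xb[, , , , j])
          v <- augment_voi(v, seed = cfg$seed * 100000L + e * 1000L +
                             bi * 40L + j)
          xb[, , , , j] <- v$data
        }
      }
      res <- .cd_net_train_batch(model$ptr, xb, tr$time[b],
                                 as.integer(tr$event[b]), w$alpha, w$beta,
                                 state$lr, red)
      tl <- tl + unlist(res)[c("l_r", "l_s", "hybrid")] * length(b)
    }
    tl <- tl / length(tr$id)
    vl <- .cd_net_eval_loss(model$ptr, va$x, va$time, as.integer(va$event),
                            w$alpha, w$beta, red)
    state <- .plateau_observe(state, e, vl$hybrid)
    if (isTRUE(state$improved) || is.null(best_state)) {
      best_state <- .cd_net_get_state(model$ptr)
      best_epoch <- e
    }
    hist[[e]] <- data.frame(epoch = e, lr = state$lr,
                            train_l_r = tl[["l_r"]], train_l_s = tl[["l_s"]],
                            train_hybrid = tl[["hybrid"]],
                            val_l_r = vl$l_r, val_l_s = vl$l_s,
                            val_hybrid = vl$hybrid)
    if (verbose)
      cat(sprintf("epoch %3d lr %.2e train %.5f val %.5f%s\n", e, state$lr,
                  tl[["hybrid"]], vl$hybrid,
                  if (isTRUE(state$improved)) " *" else ""))
  }
  checkpoint <- structure(list(state = best_state, config = model$config,
                               seed = model$seed),
                          class = "coxdae_checkpoint")
  structure(list(checkpoint = checkpoint, history = do.call(rbind, hist),
                 best_epoch = best_epoch),
            class = "coxdae_fit")
}

#' @export
print.coxdae_fit <- function(x, ...) {
  h <- x$history
  cat("<coxdae_fit>", nrow(h), "epochs | best epoch", x$best_epoch,
      "| val hybrid", signif(min(h$val_hybrid), 5), "\n")
  invisible(x)
}

#' Prognostic index of each patient
#'
#' Deterministic inference: corruption, dropout and augmentation are
#' disabled and batch normalization uses its running statistics, so the PI
#' of a case does not depend on which other cases are in its batch.
#'
#' @param fit A `coxdae_fit`, `coxdae_checkpoint` or `coxdae_model`.
#' @param cases Case list (elements with `$voi` and `$record`).
#' @param chunk_size Cases per forward pass (memory control only).
#' @return Data frame with `patient_id`, `pi`, `time`, `event`.
#' @export
predict_pi <- function(fit, cases, chunk_size = 8L) {
  model <- if (inherits(fit, "coxdae_fit"))
    model_from_checkpoint(fit$checkpoint)
  else if (inherits(fit, "coxdae_checkpoint")) model_from_checkpoint(fit)
  else if (inherits(fit, "coxdae_model")) fit
  else stop("fit must be a coxdae_fit, checkpoint or model", call. = FALSE)
  te <- cohort_tensors(cases)
  if (!identical(as.integer(dim(te$x)[1:3]),
                 as.integer(model$config$voi_shape)))
    stop("case VOI shape ", paste(dim(te$x)[1:3], collapse = "x"),
         " does not match checkpoint VOI shape ",
         paste(model$config$voi_shape, collapse = "x"), call. = FALSE)
  n <- length(te$id)
  pi_hat <- numeric(n)
  for (s in seq(1L, n, by = chunk_size)) {
    idx <- s:min(s + chunk_size - 1L, n)
    out <- .cd_net_forward(model$ptr, te$x[, , , , idx, drop = FALSE], FALSE)
    pi_hat[idx] <- out$risk
  }
  data.frame(patient_id = te$id, pi = pi_hat, time = te$time,
             event = te$event, stringsAsFactors = FALSE)
}
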