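test_that("batches are time-sorted, seeded and sized as configured", {
  times <- c(5, 1, 9, 2, 7, 3)
  events <- c(1, 1, 0, 1, 1, 1)
  b1 <- make_batches(times, events, batch_size = 3, seed = 1)
  expect_length(b1, 2L)
  for (b in b1) expect_false(is.unsorted(times[b]))
  expect_identical(b1, make_batches(times, events, 3, seed = 1))
  expect_setequal(unlist(b1), 1:6)

  # batch size 26 with 26 cases: one ascending batch
  set.seed(2)
  t26 <- rexp(26, 0.01)
  b26 <- make_batches(t26, rep(1, 26), 26, seed = 3)
  expect_length(b26, 1L)
  expect_identical(b26[[1]], order(t26))
  expect_false(is.unsorted(t26[b26[[1]]]))
})

test_that("a degenerate final batch is merged backwards", {
  times <- c(10, 20, 30, 40, 5)
  events <- c(1, 1, 1, 1, 0)
  # any partition leaving a single case (or an all-censored pair with the
  # censored case) at the end must merge it into the previous batch
  for (seed in 1:5) {
    bs <- make_batches(times, events, batch_size = 4, seed = seed)
    expect_true(all(lengths(bs) >= 2L))
    for (b in bs) expect_false(is.unsorted(times[b]))
  }
})

test_that("the plateau schedule halves the rate at the stated boundaries", {
  sched <- plateau_schedule(rep(1, 25), lr0 = 5e-4, patience = 10,
                            factor = 0.5)
  expect_equal(sched$lr[1:10], rep(5e-4, 10))
  expect_equal(sched$lr[11:20], rep(2.5e-4, 10))
  expect_equal(sched$lr[21:25], rep(1.25e-4, 5))
  # an improvement resets the patience counter
  vl <- c(1, 0.9, rep(0.95, 12))
  s2 <- plateau_schedule(vl, lr0 = 5e-4, patience = 10, factor = 0.5)
  expect_equal(s2$lr[11], 5e-4)      # improvement at epoch 2 pushed decay out
  expect_equal(s2$lr[12], 2.5e-4)    # 10 stale epochs after epoch 2
})

test_that("a short smoke training run produces history and a usable checkpoint", {
  cases <- lapply(1:10, function(i)
    toy_case(sprintf("c%02d", i), d = c(8L, 8L, 8L), seed = i,
             time = 30 * i, event = as.numeric(i %% 3 != 0)))
  m <- dae_cox_model(model_config(c(8L, 8L, 8L), recon_reduction = "mean"),
                     seed = 6)
  cfg <- train_config(batch_size = 4, epochs = 2, seed = 6, augment = TRUE)
  fit <- suppressMessages(train_dae_cox(m, cases[1:8], cases[9:10], cfg))
  expect_s3_class(fit, "coxdae_fit")
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$val_hybrid)))
  p <- predict_pi(fit, cases)
  expect_identical(p$patient_id, sapply(cases, function(cs) cs$voi$patient_id))
  expect_true(all(is.finite(p$pi)))
})

test_that("identical seeds give identical training histories and predictions", {
  cases <- lapply(1:8, function(i)
    toy_case(sprintf("d%02d", i), d = c(8L, 8L, 8L), seed = 100 + i,
             time = 20 * i + 3, event = 1))
  run <- function() {
    m <- dae_cox_model(model_config(c(8L, 8L, 8L), recon_reduction = "mean"),
                       seed = 9)
    fit <- suppressMessages(train_dae_cox(m, cases[1:6], cases[7:8],
                                          train_config(batch_size = 3,
                                                       epochs = 3, seed = 9)))
    list(h = fit$history, p = predict_pi(fit, cases)$pi)
  }
  a <- run()
  b <- run()
  expect_identical(a$h, b$h)
  expect_identical(a$p, b$p)
})

test_that("prediction is case-independent (no cross-case leakage)", {
  m <- dae_cox_model(model_config(c(8L, 8L, 8L)), seed = 10)
  cases <- lapply(1:3, function(i) toy_case(paste0("e", i), seed = 200 + i))
  alone <- predict_pi(m, cases[1])$pi
  together <- predict_pi(m, cases, chunk_size = 3)$pi
  expect_equal(together[1], alone)
  dup <- predict_pi(m, cases[c(1, 1, 2)])$pi
  expect_equal(dup[1], dup[2])
})

test_that("with beta = 0 the survival branch receives no gradient", {
  cases <- lapply(1:6, function(i)
    toy_case(paste0("f", i), seed = 300 + i, time = 50 * i, event = 1))
  m <- dae_cox_model(model_config(c(8L, 8L, 8L), recon_reduction = "mean"),
                     seed = 11)
  before <- coxdae:::.cd_net_get_state(m$ptr)
  cfg <- train_config(batch_size = 3, epochs = 2, seed = 11,
                      loss_weights = loss_weights(1, 0))
  fit <- suppressMessages(train_dae_cox(m, cases[1:4], cases[5:6], cfg))
  after <- coxdae:::.cd_net_get_state(m$ptr)
  for (nm in c("fc1_W", "fc1_b", "fc2_W", "fc2_b", "fc3_W"))
    expect_identical(after[[nm]], before[[nm]])
  expect_false(identical(after$enc1_W, before$enc1_W))  # DAE still learns
  expect_true(all(is.finite(fit$history$val_l_s)))      # reported regardless
})

test_that("training lowers the training objective in at least 9 of 10 seeds", {
  co <- simulate_cohort(sim_config(n_patients = 30, vol_shape = c(24L, 24L, 24L),
                                   seed = 77),
                        voi_shape = c(16L, 16L, 16L))
  tr <- coxdae:::cohort_tensors(co$vois[1:26])
  eval_train <- function(m)
    coxdae:::.cd_net_eval_loss(m$ptr, tr$x, tr$time, as.integer(tr$event),
                               0.7, 0.3, "mean")$hybrid
  wins <- 0L
  for (seed in 1:10) {
    m <- dae_cox_model(model_config(c(16L, 16L, 16L),
                                    recon_reduction = "mean"),
                       seed = seed)
    before <- eval_train(m)
    suppressMessages(
      train_dae_cox(m, co$vois[1:26], co$vois[27:30],
                    train_config(batch_size = 13, epochs = 10, seed = seed)))
    if (eval_train(m) < before) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("prediction rejects mismatched VOI shapes", {
  m <- dae_cox_model(model_config(c(8L, 8L, 8L)), seed = 12)
  cases <- list(toy_case("h1", d = c(16L, 16L, 16L)))
  expect_error(predict_pi(m, cases), "does not match")
})
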