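test_that("flatten length follows 64 * prod(voi) / 512", {
  expect_identical(flatten_length(model_config(c(64L, 64L, 128L))), 65536L)
  expect_identical(flatten_length(model_config(c(32L, 32L, 32L))), 4096L)
  m <- dae_cox_model(model_config(c(16L, 16L, 16L)), seed = 1)
  expect_identical(flatten_length(m), 512L)
  expect_error(model_config(c(30L, 32L, 32L)), "divisible by 8")
})

test_that("reconstruction loss matches hand evaluation and both reductions", {
  x <- array(0.75, dim = c(2L, 1L, 1L, 4L))
  r <- array(0.25, dim = c(2L, 1L, 1L, 4L))
  expect_equal(reconstruction_loss(x, r), 0.25 * 8)      # per-case sum
  expect_equal(reconstruction_loss(x, r, "mean"), 0.25)  # per-entry mean
  expect_equal(reconstruction_loss(x, x), 0)
  # duplicating the batch leaves the batch-mean loss unchanged
  xb <- array(c(x, x), dim = c(2L, 1L, 1L, 4L, 2L))
  rb <- array(c(r, r), dim = c(2L, 1L, 1L, 4L, 2L))
  expect_equal(reconstruction_loss(xb, rb), reconstruction_loss(x, r))
})

test_that("cox loss matches the hand-evaluated partial likelihood", {
  # 3 cases, times (1,2,3), all events, risks zero: log 3 + log 2
  expect_equal(cox_loss(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)), log(3) + log(2))
  r <- c(0.5, -1, 2)
  expected <- -((r[1] - log(sum(exp(r)))) +
                (r[2] - log(exp(r[2]) + exp(r[3]))) +
                (r[3] - r[3]))
  expect_equal(cox_loss(r, c(1, 2, 3), c(1, 1, 1)), expected)
  expect_equal(cox_loss(r, c(1, 2, 3), c(0, 0, 0)), 0)   # all censored
  expect_error(cox_loss(r, c(0, 2, 3), c(1, 1, 1)), "positive")
})

test_that("cox loss is shift-invariant and equals brute-force enumeration", {
  set.seed(42)
  for (rep in 1:50) {
    b <- random_batch(sample(2:10, 1))
    expect_equal(cox_loss(b$risk, b$time, b$event),
                 brute_cox_npll(b$risk, b$time, b$event), tolerance = 1e-12)
    expect_lt(abs(cox_loss(b$risk + 5.3, b$time, b$event) -
                  cox_loss(b$risk, b$time, b$event)), 1e-9)
  }
})

test_that("cox loss is invariant under batch permutation (risk-set correctness)", {
  set.seed(43)
  b <- random_batch(12)
  o <- order(b$time)      # ascending-time batch as used in training
  expect_equal(cox_loss(b$risk[o], b$time[o], b$event[o]),
               cox_loss(b$risk, b$time, b$event))
})

test_that("analytic cox-loss gradient matches central finite differences", {
  set.seed(44)
  for (rep in 1:10) {
    b <- random_batch(5)
    g <- cox_loss_grad(b$risk, b$time, b$event)
    h <- 1e-6
    for (k in 1:5) {
      rp <- b$risk; rp[k] <- rp[k] + h
      rm <- b$risk; rm[k] <- rm[k] - h
      fd <- (cox_loss(rp, b$time, b$event) -
             cox_loss(rm, b$time, b$event)) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-4)
    }
  }
})

test_that("hybrid loss reduces to its parts at degenerate weights", {
  set.seed(45)
  x <- array(runif(8 * 4 * 2), dim = c(2L, 2L, 2L, 4L, 2L))
  r <- array(runif(8 * 4 * 2), dim = c(2L, 2L, 2L, 4L, 2L))
  risk <- rnorm(2); tm <- c(3, 9); ev <- c(1, 1)
  expect_equal(hybrid_loss(x, r, risk, tm, ev, loss_weights(1, 0)),
               reconstruction_loss(x, r))
  expect_equal(hybrid_loss(x, r, risk, tm, ev, loss_weights(0, 1)),
               cox_loss(risk, tm, ev))
  expect_equal(hybrid_loss(x, r, risk, tm, ev, loss_weights(0.7, 0.3)),
               0.7 * reconstruction_loss(x, r) + 0.3 * cox_loss(risk, tm, ev))
  expect_error(loss_weights(0.7, 0.4), "equal 1")
})

test_that("encoder/decoder shape contract holds across VOI shapes", {
  for (shape in list(c(8L, 8L, 8L), c(16L, 8L, 24L))) {
    m <- dae_cox_model(model_config(shape), seed = 2)
    n <- 3L
    x <- array(runif(prod(shape) * 4 * n), dim = c(shape, 4L, n))
    out <- forward(m, x)
    expect_identical(dim(out$recon), dim(x))
    expect_length(out$risk, n)
    expect_true(all(out$recon > 0 & out$recon < 1))
    expect_true(all(is.finite(out$risk)))
  }
})

test_that("inference is deterministic and training-mode corruption is not", {
  m <- dae_cox_model(model_config(c(8L, 8L, 8L), input_dropout_rate = 0.2),
                     seed = 3)
  x <- array(0, dim = c(8L, 8L, 8L, 4L, 2L))
  a <- forward(m, x)
  b <- forward(m, x)
  expect_identical(a$recon, b$recon)
  expect_identical(a$risk, b$risk)
})

test_that("corruption zeroes approximately the configured voxel fraction", {
  p <- 0.2
  m <- dae_cox_model(model_config(c(8L, 8L, 8L), input_dropout_rate = p),
                     seed = 4)
  set.seed(5)
  x <- array(runif(8^3 * 4 * 4), dim = c(8L, 8L, 8L, 4L, 4L))
  fracs <- replicate(20, coxdae:::.cd_net_corruption_fraction(m$ptr, x))
  n_total <- 8^3 * 4 * 4 * 20
  se <- sqrt(p * (1 - p) / n_total)
  expect_lt(abs(mean(fracs) - p), 3 * se)
})
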