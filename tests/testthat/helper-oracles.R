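# Independent brute-force oracles: deliberately loop-based, no vectorization,
# no shared code with the package implementations they check.

# negative log partial likelihood, explicit risk-set enumeration, Breslow ties
brute_cox_npll <- function(risk, time, event) {
  loss <- 0
  for (i in seq_along(risk)) {
    if (event[i] != 1) next
    riskset <- c()
    for (j in seq_along(risk)) if (time[j] >= time[i]) riskset <- c(riskset, j)
    loss <- loss - (risk[i] - log(sum(exp(risk[riskset]))))
  }
  loss
}

# Harrell C by enumeration over all ordered pairs
brute_cindex <- function(pi, time, event) {
  num <- 0
  den <- 0
  for (i in seq_along(pi)) for (j in seq_along(pi)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (pi[i] > pi[j]) num <- num + 1
      else if (pi[i] == pi[j]) num <- num + 0.5
    }
  }
  num / den
}

# plain empirical AUC of the dichotomized outcome (cases vs controls)
brute_auc <- function(score, is_case) {
  ca <- score[is_case]
  co <- score[!is_case]
  s <- 0
  for (a in ca) for (b in co) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(ca) * length(co))
}

# random censored survival batch for oracle comparisons (with ties)
random_batch <- function(n, tie_prob = 0.3, censor_prob = 0.3) {
  time <- sample(1:5, n, replace = TRUE) +
    ifelse(runif(n) < tie_prob, 0, runif(n))
  list(risk = rnorm(n), time = time,
       event = as.numeric(runif(n) > censor_prob))
}

# small synthetic multimodal volume with nested labels, for io tests
toy_volume <- function(id = "toy1", d = c(12L, 12L, 12L), seed = 1L) {
  set.seed(seed)
  seg <- array(0L, dim = d)
  ctr <- d / 2
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    r <- sqrt(sum((c(x, y, z) - ctr)^2))
    if (r <= 1.5) seg[x, y, z] <- 1L
    else if (r <= 2.5) seg[x, y, z] <- 4L
    else if (r <= 4) seg[x, y, z] <- 2L
  }
  channels <- array(runif(prod(d) * 4, 100, 900), dim = c(d, 4L))
  coxdae:::new_volume(id, channels, c(1, 1, 1), seg)
}

toy_voi <- function(id = "v1", d = c(8L, 8L, 8L), seed = 1L) {
  set.seed(seed)
  coxdae:::new_voi(id, array(runif(prod(d) * 4), dim = c(d, 4L)))
}

toy_case <- function(id, d = c(8L, 8L, 8L), seed = 1L, time = 100,
                     event = 1) {
  list(voi = toy_voi(id, d, seed),
       record = survival_record(id, time, event, age = 60, kps = 80,
                                sex = "male", race = "white",
                                radiotherapy = "yes", chemotherapy = "yes"))
}
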