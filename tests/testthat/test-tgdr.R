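test_that("log partial likelihood matches closed forms and an independent Cox fitter", {
  # two subjects, both events: risk sets of size 2 then 1
  Z <- matrix(c(1, 0), 2, 1)
  expect_equal(log_partial_likelihood(0, Z, c(1, 2), c(1, 1)), -log(2), tolerance = 1e-12)

  # beta = 0 closed form: -sum over events of log |risk set|
  set.seed(30)
  n <- 25
  time <- runif(n, 1, 10); status <- rbinom(n, 1, 0.7); status[1] <- 1L
  Zr <- matrix(rnorm(n * 3), n, 3)
  rs <- vapply(which(status == 1), function(i) sum(time >= time[i]), numeric(1))
  expect_equal(log_partial_likelihood(rep(0, 3), Zr, time, status),
               -sum(log(rs)), tolerance = 1e-10)

  # bounded above by the maximised partial likelihood from survival::coxph,
  # and equal to it at the coxph estimate
  fit <- survival::coxph(survival::Surv(time, status) ~ Zr, ties = "breslow")
  beta_hat <- unname(coef(fit))
  expect_equal(log_partial_likelihood(beta_hat, Zr, time, status),
               fit$loglik[2], tolerance = 1e-8)
  for (k in 1:5) {
    b <- rnorm(3, sd = 0.5)
    expect_lte(log_partial_likelihood(b, Zr, time, status), fit$loglik[2] + 1e-10)
  }
})

test_that("the analytic gradient matches hand evaluation and finite differences", {
  Z <- matrix(c(1, 0), 2, 1)
  expect_equal(unname(cox_gradient(0, Z, c(1, 2), c(1, 1))), 0.5, tolerance = 1e-12)

  set.seed(31)
  n <- 30
  time <- runif(n, 1, 5); status <- rbinom(n, 1, 0.6); status[2] <- 1L
  Zr <- cbind(rnorm(n), rnorm(n), rep(2, n), rnorm(n)) # one constant column
  beta <- rnorm(4, sd = 0.3)
  g <- cox_gradient(beta, Zr, time, status)
  expect_equal(unname(g[3]), 0, tolerance = 1e-10) # constant feature: zero gradient
  h <- 1e-6
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h
    fd <- (log_partial_likelihood(beta + e, Zr, time, status) -
           log_partial_likelihood(beta - e, Zr, time, status)) / (2 * h)
    expect_equal(unname(g[j]), fd, tolerance = 1e-4)
  }

  # Breslow ties: gradient still matches finite differences with tied times
  time_t <- rep(c(1, 2, 3), each = 10)
  g2 <- cox_gradient(beta, Zr, time_t, status)
  for (j in c(1, 2, 4)) {
    e <- numeric(4); e[j] <- h
    fd <- (log_partial_likelihood(beta + e, Zr, time_t, status) -
           log_partial_likelihood(beta - e, Zr, time_t, status)) / (2 * h)
    expect_equal(unname(g2[j]), fd, tolerance = 1e-4)
  }
})

test_that("gradient thresholding keeps components at or above tau times the max", {
  expect_equal(threshold_vector(c(0.1, -0.2), 0), c(TRUE, TRUE))
  expect_equal(threshold_vector(c(0.1, -0.2), 1), c(FALSE, TRUE))
  expect_equal(threshold_vector(c(0.1, -0.2, 0.09), 0.5), c(TRUE, TRUE, FALSE))
  expect_equal(threshold_vector(c(0, 0), 0.5), c(FALSE, FALSE))
  expect_error(threshold_vector(c(1, 2), 1.5), "in \\[0, 1\\]")
})

test_that("heredity thresholding forces parents of selected products", {
  # features: (0,1), (0,2), (1,1), (1,2), (2,2)
  index <- tibble::tibble(i = c(0L, 0L, 1L, 1L, 2L),
                          j = c(1L, 2L, 1L, 2L, 2L))
  # only the (1,2) product passes on its own; parents pulled in
  g <- c(0.01, 0.02, 0.03, 1.0, 0.04)
  f <- threshold_vector_heredity(g, 0.5, index)
  expect_equal(f, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  # no second-order selected: reduces to the plain rule
  g2 <- c(1.0, 0.9, 0.01, 0.02, 0.03)
  expect_equal(threshold_vector_heredity(g2, 0.5, index),
               threshold_vector(g2, 0.5))

  # random instances against exhaustive rule evaluation
  set.seed(32)
  P <- 4L
  pairs <- expand.grid(i = 1:P, j = 1:P)
  pairs <- pairs[pairs$i <= pairs$j, ]
  idx <- tibble::tibble(i = c(rep(0L, P), as.integer(pairs$i)),
                        j = c(1:P, as.integer(pairs$j)))
  for (r in 1:25) {
    gr <- rnorm(nrow(idx))
    tau <- sample(c(0, 0.3, 0.6, 0.9, 1), 1)
    expect_equal(threshold_vector_heredity(gr, tau, idx),
                 heredity_rule_oracle(gr, tau, idx))
  }
})

test_that("TGDR iterates plain gradient ascent at tau = 0 and starts from zero", {
  set.seed(33)
  n <- 40
  Z <- matrix(rnorm(n * 3), n, 3)
  time <- runif(n, 1, 8); status <- rbinom(n, 1, 0.7); status[1] <- 1L

  f0 <- tgdr_fit(Z, time, status, tau = 0.5, K = 0)
  expect_equal(unname(f0$beta), c(0, 0, 0))

  # tau = 0, unstandardized: exact equality with an R gradient-ascent loop
  K <- 7
  fit <- tgdr_fit(Z, time, status, tau = 0, K = K, standardize = FALSE)
  b <- rep(0, 3)
  for (k in seq_len(K)) b <- b + 1e-3 * cox_gradient(b, Z, time, status)
  expect_equal(unname(fit$beta), unname(b), tolerance = 1e-12)

  # tau = 1 with one iteration updates exactly the top-gradient feature
  f1 <- tgdr_fit(Z, time, status, tau = 1, K = 1)
  expect_identical(sum(f1$beta != 0), 1L)
})

test_that("TGDR at tau = 0 converges to the unpenalized Cox estimate", {
  set.seed(34)
  n <- 60
  Z <- matrix(rnorm(n * 2), n, 2)
  lp <- Z %*% c(0.8, -0.5)
  time <- rexp(n, rate = 0.5 * exp(lp))
  status <- as.integer(time <= rexp(n, 0.3))
  ref <- survival::coxph(survival::Surv(time, status) ~ Z, ties = "breslow")
  fit <- tgdr_fit(Z, time, status, tau = 0, K = 30000)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-2)
})

test_that("the log partial likelihood ascends monotonely along the TGDR path", {
  set.seed(35)
  for (r in 1:3) {
    d <- make_sim_dataset(kind = "R2", seed = 40 + r)
    fit <- tgdr_fit(d$features, d$surv$time, d$surv$status, tau = 0.4, K = 150)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
})

test_that("the modified variant keeps heredity at every iteration and at termination", {
  for (r in 1:3) {
    d <- make_sim_dataset(kind = "R2", seed = 50 + r)
    fit <- tgdr_fit(d$features, d$surv$time, d$surv$status,
                    tau = 0.7, K = 200, variant = "modified")
    expect_true(fit$heredity_ok)
    idx <- fit$index
    sec <- which(idx$i >= 1 & fit$selected)
    first_pos <- match(seq_len(max(idx$j)),
                       ifelse(idx$i == 0L, idx$j, NA_integer_))
    for (s in sec) {
      expect_true(fit$selected[first_pos[idx$i[s]]])
      expect_true(fit$selected[first_pos[idx$j[s]]])
    }
  }
})

test_that("cross-validated tuning is seeded, rejects noise and finds real signal", {
  set.seed(36)
  n <- 80
  # pure noise: criterion should keep the model near zero
  Zn <- matrix(rnorm(n * 6), n, 6)
  tn <- rexp(n, 0.5); sn <- as.integer(tn <= rexp(n, 1 / 3))
  if (sum(sn) < 5) sn[1:5] <- 1L
  fit_n <- tgdr_tune(Zn, tn, sn, v = 3, tau_grid = c(1, 0.5, 0), k_max = 150, seed = 4)
  expect_lt(max(abs(fit_n$beta)), 0.25)

  # one strong feature among noise: it is selected
  Zs <- matrix(rnorm(n * 6), n, 6)
  lp <- 1.5 * Zs[, 3]
  ts <- rexp(n, 0.5 * exp(lp)); ss <- as.integer(ts <= rexp(n, 1 / 3))
  fit_s <- tgdr_tune(Zs, ts, ss, v = 3, tau_grid = c(1, 0.5, 0), k_max = 300, seed = 5)
  expect_true(fit_s$selected[3])

  # determinism: identical folds and tuned parameters under the same seed
  fit_s2 <- tgdr_tune(Zs, ts, ss, v = 3, tau_grid = c(1, 0.5, 0), k_max = 300, seed = 5)
  expect_identical(fit_s$cv$folds, fit_s2$cv$folds)
  expect_identical(c(fit_s$cv$tau, fit_s$cv$K), c(fit_s2$cv$tau, fit_s2$cv$K))
  expect_identical(fit_s$beta, fit_s2$beta)

  # tidy/glance accessors
  td <- tidy(fit_s)
  expect_identical(nrow(td), 6L)
  expect_identical(glance(fit_s)$K, fit_s$K)
})
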