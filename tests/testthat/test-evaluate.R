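test_that("logrank statistic agrees with survival::survdiff and hand cases", {
  # identical outcome patterns in both groups: exactly zero
  time <- c(1, 2, 1, 2); status <- c(1L, 1L, 1L, 1L)
  z <- logrank_two_group(c(TRUE, TRUE, FALSE, FALSE), time, status)
  expect_equal(z$statistic, 0)

  # 4-subject toy against the survival package
  t4 <- c(2, 5, 3, 8); s4 <- c(1L, 0L, 1L, 1L); g4 <- c(TRUE, TRUE, FALSE, FALSE)
  ours <- logrank_two_group(g4, t4, s4)
  ref <- survival::survdiff(survival::Surv(t4, s4) ~ g4)
  expect_equal(ours$statistic, unname(ref$chisq), tolerance = 1e-10)

  # random datasets, continuous times
  set.seed(60)
  for (r in 1:5) {
    n <- 50
    tt <- runif(n, 0.1, 10); ss <- rbinom(n, 1, 0.7); ss[1:3] <- 1L
    sc <- rnorm(n)
    ours <- logrank_median_split(sc, tt, ss)
    ref <- survival::survdiff(survival::Surv(tt, ss) ~ I(sc > median(sc)))
    expect_equal(ours$statistic, unname(ref$chisq), tolerance = 1e-10)
    expect_equal(ours$p_value, pchisq(ours$statistic, 1, lower.tail = FALSE))
  }

  # median split is invariant under strictly monotone score transforms
  sc <- rnorm(30); tt <- runif(30, 1, 5); ss <- rep(1L, 30)
  expect_equal(logrank_median_split(exp(sc) + 5, tt, ss)$statistic,
               logrank_median_split(sc, tt, ss)$statistic)
  expect_error(logrank_median_split(rep(1, 30), tt, ss), "degenerate")
})

test_that("concordance index matches brute force, survival::concordance, and its symmetries", {
  # perfect ranking without censoring
  tt <- c(5, 3, 8, 1, 9, 2); ss <- rep(1L, 6)
  expect_equal(concordance_index(-tt, tt, ss), 1)
  expect_equal(concordance_index(rep(0, 6), tt, ss), 0.5)

  # 6-subject toy with one censored subject vs exhaustive enumeration
  sc <- c(0.3, -1.2, 0.8, 0.1, 0.1, -0.5)
  ss2 <- c(1L, 1L, 0L, 1L, 1L, 1L)
  expect_equal(concordance_index(sc, tt, ss2), concordance_oracle(sc, tt, ss2))

  set.seed(61)
  for (r in 1:5) {
    n <- 40
    tt <- runif(n, 0.1, 10); ss <- rbinom(n, 1, 0.6); ss[1] <- 1L
    sc <- rnorm(n)
    ours <- concordance_index(sc, tt, ss)
    expect_equal(ours, concordance_oracle(sc, tt, ss))
    ref <- survival::concordance(survival::Surv(tt, ss) ~ sc, reverse = TRUE)
    expect_equal(ours, unname(ref$concordance), tolerance = 1e-10)
    # antisymmetry: negating scores flips concordance around 1/2
    expect_equal(concordance_index(-sc, tt, ss), 1 - ours, tolerance = 1e-12)
  }
})

test_that("cross-validated prediction is seeded, null on noise and strong on signal", {
  d <- make_sim_dataset(seed = 70)
  ev1 <- cv_predict(d$x, d$surv$time, d$surv$status, kind = "R1", v = 5, seed = 3,
                    min_module_size = 5, tau_grid = c(1, 0.5, 0), k_max = 200,
                    inner_v = 3)
  ev2 <- cv_predict(d$x, d$surv$time, d$surv$status, kind = "R1", v = 5, seed = 3,
                    min_module_size = 5, tau_grid = c(1, 0.5, 0), k_max = 200,
                    inner_v = 3)
  expect_identical(ev1$scores, ev2$scores) # determinism
  expect_gt(ev1$concordance, 0.65)          # real signal
  expect_identical(nrow(ev1$scores), ncol(d$x))
  expect_identical(sort(unique(ev1$scores$fold)), 1:5)
  g <- glance(ev1)
  expect_identical(g$kind, "R1")
  expect_equal(g$concordance, ev1$concordance)

  # survival independent of expression: concordance near 1/2
  cfg <- d$cfg
  surv_null <- withr::with_seed(99, {
    tt <- rexp(ncol(d$x), 0.5)
    list(time = tt, status = as.integer(tt <= rexp(ncol(d$x), 1 / 3)))
  })
  evn <- cv_predict(d$x, surv_null$time, surv_null$status, kind = "R1", v = 5,
                    seed = 3, min_module_size = 5, tau_grid = c(1, 0.5, 0),
                    k_max = 200, inner_v = 3)
  expect_gt(evn$concordance, 0.33)
  expect_lt(evn$concordance, 0.67)
})

test_that("per-fold feature rebuilding evaluates without reusing held-out samples", {
  d <- make_sim_dataset(seed = 71)
  ev <- cv_predict(d$x, d$surv$time, d$surv$status, kind = "R1", v = 3, seed = 5,
                   min_module_size = 5, tau_grid = c(1, 0.5, 0), k_max = 150,
                   inner_v = 3, rebuild_features = TRUE)
  expect_identical(nrow(ev$scores), ncol(d$x))
  expect_true(is.finite(ev$concordance))
})

test_that("gene-level expansion reproduces feature-level risk scores exactly", {
  d <- make_sim_dataset(kind = "R2", seed = 72)
  fit <- tgdr_fit(d$features, d$surv$time, d$surv$status,
                  tau = 0.6, K = 250, variant = "modified")
  expect_gt(sum(fit$selected), 0)
  gm <- gene_level_coefficients(fit, d$features, d$pcas)
  sc_gene <- gene_level_scores(gm, d$x)
  sc_feat <- drop(d$features$Z %*% fit$beta)
  expect_equal(unname(sc_gene), unname(sc_feat), tolerance = 1e-6)
  expect_lte(nrow(gm$ranked), 20)
  expect_identical(tidy(gm), gm$ranked)
})

test_that("gene-level terms of elementary fits have the expected closed form", {
  d <- make_sim_dataset(kind = "R2", seed = 73)
  idx <- d$features$index
  base <- tgdr_fit(d$features, d$surv$time, d$surv$status, tau = 0, K = 0)

  # single linear feature (0,1): coefficients proportional to module 1 loadings
  f_lin <- base
  f_lin$beta[] <- 0
  f_lin$beta[which(idx$i == 0 & idx$j == 1)] <- 2
  f_lin$selected <- f_lin$beta != 0
  gm1 <- gene_level_coefficients(f_lin, d$features, d$pcas)
  w1 <- d$pcas[[d$features$provenance$module[1]]]$loadings[, 1]
  expect_equal(gm1$linear[names(w1)], 2 * w1, tolerance = 1e-12)
  expect_identical(nrow(gm1$pairwise), 0L)
  expect_equal(sum(gm1$quadratic != 0), 0L)

  # single quadratic (1,1): rank-one form within module 1
  f_quad <- base
  f_quad$beta[] <- 0
  f_quad$beta[which(idx$i == 1 & idx$j == 1)] <- 1.5
  f_quad$selected <- f_quad$beta != 0
  gm2 <- gene_level_coefficients(f_quad, d$features, d$pcas)
  expect_equal(gm2$quadratic[names(w1)], 1.5 * w1^2, tolerance = 1e-12)
  expect_true(all(gm2$pairwise$gene1 %in% names(w1)))
  expect_true(all(gm2$pairwise$gene2 %in% names(w1)))
  # and the expansion still scores identically
  expect_equal(unname(gene_level_scores(gm2, d$x)),
               unname(drop(d$features$Z %*% f_quad$beta)), tolerance = 1e-6)
})
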