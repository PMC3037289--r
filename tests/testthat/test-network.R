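test_that("similarity is the absolute Pearson correlation", {
  set.seed(3)
  base <- rnorm(10)
  x <- rbind(g1 = base, g2 = base, g3 = -base, g4 = rnorm(10))
  colnames(x) <- paste0("s", 1:10)
  S <- gene_similarity(x)$similarity
  expect_equal(S["g1", "g2"], 1)
  expect_equal(S["g1", "g3"], 1) # sign-invariant
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 4))

  # textbook covariance/sigma ratio on two fixed 5-vectors
  a <- c(1, 3, 2, 5, 4); b <- c(2, 2, 4, 7, 3)
  xs <- rbind(ga = a, gb = b); colnames(xs) <- paste0("s", 1:5)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(gene_similarity(xs)$similarity["ga", "gb"], abs(r_hand), tolerance = 1e-12)

  xc <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3)); colnames(xc) <- paste0("s", 1:3)
  expect_error(gene_similarity(xc), "constant")
})

test_that("adjacency is the elementwise power of similarity and decreases in b", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  net <- manual_network(S)
  expect_equal(gene_adjacency(net, 6)$adjacency["g1", "g2"], 0.5^6)
  expect_equal(gene_adjacency(net, 3)$adjacency["g1", "g1"], 1) # S = 1 fixed point

  set.seed(9)
  Sr <- abs(cor(matrix(rnorm(200), 20, 10)))
  netr <- manual_network(Sr)
  a6 <- gene_adjacency(netr, 6)$adjacency
  # scalar loop oracle
  for (k in 1:10) for (j in 1:10) expect_equal(a6[k, j], Sr[k, j]^6)
  a2 <- gene_adjacency(netr, 2)$adjacency
  off <- upper.tri(Sr)
  expect_true(all(a6[off] <= a2[off] + 1e-15)) # monotone in b since S <= 1
  expect_error(gene_adjacency(netr, 0), "positive")
})

test_that("connectivity sums off-diagonal adjacencies", {
  A2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  expect_equal(connectivity(manual_network(A2)), c(g1 = 0.4, g2 = 0.4))
  expect_equal(unname(connectivity(manual_network(diag(2)))), c(0, 0))

  A3 <- diag(3)
  A3[1, 2] <- A3[2, 1] <- 0.5
  A3[1, 3] <- A3[3, 1] <- 0.2
  A3[2, 3] <- A3[3, 2] <- 0.1
  expect_equal(unname(connectivity(manual_network(A3))), c(0.7, 0.6, 0.3))
  # literal sums include the unit self-term
  expect_equal(unname(connectivity(manual_network(A3), literal_sums = TRUE)),
               c(1.7, 1.6, 1.3))
})

test_that("topological overlap dissimilarity matches hand evaluation and stays in [0,1]", {
  A1 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  expect_equal(tom_dissimilarity(manual_network(A1))["g1", "g2"], 0) # perfect overlap
  expect_equal(tom_dissimilarity(manual_network(diag(2)))[1, 2], 1)  # isolated pair

  A3 <- diag(3)
  A3[1, 2] <- A3[2, 1] <- 0.5
  A3[1, 3] <- A3[3, 1] <- 0.2
  A3[2, 3] <- A3[3, 2] <- 0.1
  D <- tom_dissimilarity(manual_network(A3))
  # l12 = a13 a23 = 0.02; omega = (0.02 + 0.5) / (0.6 + 1 - 0.5)
  expect_equal(D[1, 2], 1 - 0.52 / 1.1, tolerance = 1e-12)
  expect_equal(unname(diag(D)), rep(0, 3))

  set.seed(21)
  for (rep in 1:8) {
    M <- matrix(runif(64), 8, 8)
    S <- (M + t(M)) / 2
    diag(S) <- 1
    Dr <- tom_dissimilarity(gene_adjacency(manual_network(S), 3))
    expect_true(all(Dr >= 0 & Dr <= 1))
    expect_true(isSymmetric(Dr))
  }
})

test_that("soft-threshold power selection follows the scale-free criterion", {
  set.seed(5)
  cfg <- test_sim_config()
  x <- gen_expression(cfg, seed = 17, n_samples = 80)
  net <- gene_similarity(x)
  pick <- pick_power(net, candidates = 1:6)
  expect_identical(nrow(pick$fits), 6L)
  expect_true(all(pick$fits$r_squared >= 0 & pick$fits$r_squared <= 1))
  # smallest candidate qualifying under a trivially low bar
  expect_equal(pick_power(net, candidates = 1:6, r2_target = 1e-6)$power, 1)
  # unreachable bar: fallback to the conventional power 6 ...
  expect_equal(pick_power(net, candidates = 1:6, r2_target = 0.999999)$power, 6)
  # ... or, without the fallback, the best-fitting candidate
  nofb <- pick_power(net, candidates = 1:6, r2_target = 0.999999, fallback = FALSE)
  expect_equal(nofb$power, nofb$fits$power[which.max(nofb$fits$r_squared)])

  # independent regression oracle for one candidate's fit
  b <- 4
  A <- net$similarity^b; diag(A) <- 1
  C <- rowSums(A) - diag(A)
  Cp <- C[C > 0]
  br <- seq(min(Cp), max(Cp), length.out = 11)
  bin <- cut(Cp, breaks = br, include.lowest = TRUE)
  km <- tapply(Cp, bin, mean); fr <- tapply(Cp, bin, length) / length(Cp)
  keep <- !is.na(km)
  r2_ind <- suppressWarnings(
    summary(stats::lm(log10(fr[keep]) ~ log10(km[keep])))$r.squared)
  expect_equal(pick$fits$r_squared[pick$fits$power == b], r2_ind, tolerance = 1e-10)
})

test_that("module detection recovers separable and planted blocks, rejects degenerate input", {
  # two perfect blocks
  D <- matrix(1, 10, 10)
  D[1:5, 1:5] <- 0
  D[6:10, 6:10] <- 0
  diag(D) <- 0
  dimnames(D) <- list(paste0("g", 1:10), paste0("g", 1:10))
  mods <- detect_modules(D, min_module_size = 3)
  expect_identical(mods$n_modules, 2L)
  expect_identical(length(unique(mods$labels[1:5])), 1L)
  expect_identical(length(unique(mods$labels[6:10])), 1L)
  expect_true(all(mods$labels > 0))

  # all-ones dissimilarity: no structure below the top merge
  D1 <- matrix(1, 8, 8); diag(D1) <- 0
  dimnames(D1) <- list(paste0("g", 1:8), paste0("g", 1:8))
  expect_identical(detect_modules(D1, min_module_size = 3)$n_modules, 0L)

  # planted partition with noise: adjusted Rand = 1 for distinct blocks
  cfg <- sim_config(n_genes = 30, n_modules = 3, module_sizes = rep(10, 3),
                    background_fraction = 0, n_factors = 1,
                    factor_loading_range = c(0.85, 0.95),
                    min_module_size = 5, n_replicates = 1, seed = 1)
  x <- gen_expression(cfg, seed = 33, n_samples = 150)
  net <- build_network(x, power = 6)
  mods2 <- detect_modules(net, min_module_size = 5)
  expect_identical(mods2$n_modules, 3L)
  expect_equal(adjusted_rand(mods2$labels, attr(x, "true_module")), 1)

  expect_warning(detect_modules(D1[1:2, 1:2], min_module_size = 5), "fewer genes")
})

test_that("network quantities and module labels are equivariant under gene permutation", {
  set.seed(12)
  cfg <- sim_config(n_genes = 24, n_modules = 3, module_sizes = rep(7, 3),
                    n_factors = 1, factor_loading_range = c(0.8, 0.95),
                    min_module_size = 4, n_replicates = 1, seed = 2)
  x <- gen_expression(cfg, seed = 8, n_samples = 60)
  perm <- sample(nrow(x))
  n1 <- build_network(x, power = 6)
  n2 <- build_network(x[perm, ], power = 6)
  expect_equal(n2$similarity, n1$similarity[perm, perm])
  expect_equal(n2$adjacency, n1$adjacency[perm, perm])
  expect_equal(n2$connectivity, n1$connectivity[perm])
  expect_equal(n2$tom_dissimilarity, n1$tom_dissimilarity[perm, perm])
  m1 <- detect_modules(n1, min_module_size = 4)
  m2 <- detect_modules(n2, min_module_size = 4)
  # identical partitions up to label names
  co1 <- outer(m1$labels[perm], m1$labels[perm], "==") & m1$labels[perm] > 0
  co2 <- outer(m2$labels, m2$labels, "==") & m2$labels > 0
  expect_identical(co1, co2)
})
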