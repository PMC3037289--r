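#' Configuration for the module-structured survival simulator
#'
#' Defines the synthetic study: a block latent-factor expression model (each
#' module driven by a few shared factors with geometrically decaying strength,
#' plus independent background genes), survival times from a Cox model with
#' constant baseline hazard, and independent exponential censoring calibrated
#' to a target censoring rate. Defaults mirror the simulation design the
#' package is built around: 200 subjects split 100/100 into training and
#' testing, 10 prognosis-associated representative features with coefficients
#' drawn from Unif\[-0.5, 0.5\], baseline hazard 0.5, and ~40% censoring.
#'
#' @param n_samples Total subjects (default 200).
#' @param n_train Training subjects (default 100; the rest form the test set).
#' @param n_genes Total genes (default 500).
#' @param n_modules Number of coexpression modules (default 10).
#' @param module_sizes Genes per module; default splits
#'   `(1 - background_fraction) * n_genes` evenly.
#' @param background_fraction Fraction of genes left unstructured
#'   (default 0.2).
#' @param n_factors Latent factors per module (default 3).
#' @param factor_decay Geometric decay of factor strengths (default 0.6).
#' @param factor_loading_range Range of the uniform per-gene factor loading
#'   (default c(0.3, 0.9)): the correlation between a gene and its module's
#'   combined factor signal.
#' @param generating_kind Which feature set carries the true signal
#'   (default "R1").
#' @param n_true_features Number of prognosis-associated features
#'   (default 10).
#' @param coef_range Range of the uniform coefficient draw
#'   (default c(-0.5, 0.5)).
#' @param baseline_hazard Constant baseline hazard (default 0.5).
#' @param target_censoring Target censoring rate (default 0.40).
#' @param n_replicates Study replicates (default 500; scale down for quick
#'   runs).
#' @param seed Master seed; all replicate-level randomness derives from it.
#' @param power,min_module_size,cut_height,xi Network/feature controls used
#'   when the study pipeline is run on simulated data.
#' @param fit_v,tau_grid,k_max,delta_nu TGDR tuning controls.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_train = 100, n_genes = 500,
                       n_modules = 10, module_sizes = NULL,
                       background_fraction = 0.2, n_factors = 3,
                       factor_decay = 0.6, factor_loading_range = c(0.3, 0.9),
                       generating_kind = "R1", n_true_features = 10,
                       coef_range = c(-0.5, 0.5), baseline_hazard = 0.5,
                       target_censoring = 0.40, n_replicates = 500, seed = NULL,
                       power = 6, min_module_size = NULL, cut_height = NULL,
                       xi = 80, fit_v = 5, tau_grid = seq(1, 0, by = -0.05),
                       k_max = 2500, delta_nu = 1e-3) {
  if (is.null(module_sizes)) {
    structured <- round((1 - background_fraction) * n_genes)
    module_sizes <- rep(floor(structured / n_modules), n_modules)
  }
  if (is.null(min_module_size)) min_module_size <- max(3L, floor(min(module_sizes) / 2))
  cfg <- list(n_samples = n_samples, n_train = n_train, n_genes = n_genes,
              n_modules = n_modules, module_sizes = module_sizes,
              background_fraction = background_fraction, n_factors = n_factors,
              factor_decay = factor_decay, factor_loading_range = factor_loading_range,
              generating_kind = match.arg(generating_kind, c("R1", "R2", "R3", "R4")),
              n_true_features = n_true_features, coef_range = coef_range,
              baseline_hazard = baseline_hazard, target_censoring = target_censoring,
              n_replicates = n_replicates, seed = seed, power = power,
              min_module_size = min_module_size, cut_height = cut_height, xi = xi,
              fit_v = fit_v, tau_grid = tau_grid, k_max = k_max, delta_nu = delta_nu)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (sum(module_sizes) > n_genes) stopf("module sizes sum beyond `n_genes`")
    if (length(module_sizes) != n_modules) stopf("`module_sizes` must have `n_modules` entries")
    if (any(module_sizes < 2)) stopf("modules need at least 2 genes")
    if (target_censoring <= 0 || target_censoring >= 1) stopf("`target_censoring` must be in (0, 1)")
    if (n_train >= n_samples) stopf("`n_train` must be below `n_samples`")
    if (baseline_hazard <= 0) stopf("`baseline_hazard` must be positive")
    if (factor_loading_range[1] < 0 || factor_loading_range[2] > 1 ||
        factor_loading_range[1] > factor_loading_range[2])
      stopf("`factor_loading_range` must be an increasing range inside [0, 1]")
  })
  invisible(cfg)
}

#' Generate module-structured expression data
#'
#' For each module, per-sample latent factors are drawn as standard normals
#' with geometrically decaying strengths; each member gene loads on a random
#' unit direction through those factors with a loading drawn uniformly from
#' `factor_loading_range` (so the gene carries that squared share of variance
#' on the factors), plus independent Gaussian noise. Background genes are pure noise. Rows are then rescaled to
#' zero median and unit variance, matching the preprocessing applied to real
#' data.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @param n_samples Override of `cfg$n_samples`.
#' @return A genes x samples matrix with attribute `"true_module"` (integer
#'   per gene; 0 = background).
#' @export
gen_expression <- function(cfg, seed = cfg$seed, n_samples = cfg$n_samples) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- n_samples
  with_seed(seed, {
    blocks <- vector("list", cfg$n_modules + 1L)
    truth <- integer(0)
    strengths <- cfg$factor_decay^(seq_len(cfg$n_factors) - 1)
    for (m in seq_len(cfg$n_modules)) {
      sz <- cfg$module_sizes[m]
      FF <- matrix(rnorm(n * cfg$n_factors), n, cfg$n_factors)
      dirs <- matrix(rnorm(sz * cfg$n_factors), cfg$n_factors, sz)
      dirs[1, ] <- abs(dirs[1, ])               # shared dominant factor: coherent module
      dirs <- dirs * strengths
      dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
      rho <- runif(sz, cfg$factor_loading_range[1], cfg$factor_loading_range[2])
      signal <- FF %*% dirs                     # n x sz, unit-variance columns
      noise <- matrix(rnorm(n * sz), n, sz)
      blocks[[m]] <- t(signal %*% diag(rho, sz) + noise %*% diag(sqrt(1 - rho^2), sz))
      truth <- c(truth, rep(m, sz))
    }
    n_bg <- cfg$n_genes - sum(cfg$module_sizes)
    if (n_bg > 0) {
      blocks[[cfg$n_modules + 1L]] <- matrix(rnorm(n_bg * n), n_bg, n)
      truth <- c(truth, rep(0L, n_bg))
    }
    x <- do.call(rbind, blocks)
    dimnames(x) <- list(sprintf("g%04d", seq_len(nrow(x))), sprintf("s%04d", seq_len(n)))
    x <- rescale_expression(x)
    attr(x, "true_module") <- truth
    x
  })
}

#' Draw the true prognosis model over a feature set
#'
#' Selects `cfg$n_true_features` features uniformly without replacement and
#' draws their coefficients i.i.d. uniformly from `cfg$coef_range`; all other
#' coefficients are zero.
#'
#' @param features A `feature_set`.
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return List with `true_idx` (column positions) and `beta_true` (full
#'   coefficient vector).
#' @export
draw_true_model <- function(features, cfg, seed = cfg$seed) {
  stopifnot(inherits(features, "feature_set"), inherits(cfg, "sim_config"))
  p <- ncol(features$Z)
  if (p < cfg$n_true_features)
    stopf("feature set has %d features; cannot select %d true ones", p, cfg$n_true_features)
  with_seed(seed, {
    idx <- sort(sample.int(p, cfg$n_true_features))
    beta <- numeric(p)
    beta[idx] <- runif(cfg$n_true_features, cfg$coef_range[1], cfg$coef_range[2])
    list(true_idx = idx, beta_true = beta)
  })
}

#' Calibrate the exponential censoring rate to a target censoring fraction
#'
#' With event times exponential at rate \eqn{\lambda_0 e^{lp}} and independent
#' exponential censoring at rate \eqn{\lambda_c}, a subject is censored with
#' probability \eqn{\lambda_c / (\lambda_c + \lambda_0 e^{lp})}. The rate
#' \eqn{\lambda_c} is found by monotone root-finding so that this probability,
#' averaged over the supplied linear predictors, equals `target`.
#'
#' @param linpred Linear predictors \eqn{\beta'Z} of the simulated subjects.
#' @param lambda0 Baseline hazard.
#' @param target Target censoring fraction in (0, 1).
#' @param tol Calibration tolerance on the censoring fraction (default 1e-6).
#' @return The calibrated censoring rate.
#' @export
calibrate_censoring <- function(linpred, lambda0 = 0.5, target = 0.40, tol = 1e-6) {
  if (any(!is.finite(linpred))) stopf("non-finite linear predictors")
  if (target <= 0 || target >= 1) stopf("`target` must be in (0, 1)")
  rate <- lambda0 * exp(linpred)
  f <- function(log_lc) mean(exp(log_lc) / (exp(log_lc) + rate)) - target
  sol <- uniroot(f, interval = c(-45, 45), tol = 1e-12)
  lc <- exp(sol$root)
  if (abs(f(sol$root)) > tol) stopf("censoring calibration did not reach the target rate")
  lc
}

#' Generate right-censored survival from a Cox model over features
#'
#' Event times are exponential with subject-specific rate
#' \eqn{\lambda_0 \exp(\beta'Z)} (constant baseline hazard); censoring times
#' are exponential with the rate calibrated by [calibrate_censoring()] and
#' independent of the event times.
#'
#' @param features A `feature_set` (or a plain samples x features matrix).
#' @param beta_true Coefficient vector aligned to the features.
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return A tibble with columns `sample`, `time`, `status`, and attributes
#'   `"linpred"` and `"lambda_censor"`.
#' @export
gen_survival <- function(features, beta_true, cfg, seed = cfg$seed) {
  Z <- if (inherits(features, "feature_set")) features$Z else as.matrix(features)
  stopifnot(length(beta_true) == ncol(Z))
  lp <- drop(Z %*% beta_true)
  lc <- calibrate_censoring(lp, lambda0 = cfg$baseline_hazard, target = cfg$target_censoring)
  with_seed(seed, {
    Tt <- rexp(length(lp), rate = cfg$baseline_hazard * exp(lp))
    Cc <- rexp(length(lp), rate = lc)
    out <- tibble::tibble(sample = rownames(Z) %||% paste0("s", seq_along(lp)),
                          time = pmin(Tt, Cc),
                          status = as.integer(Tt <= Cc))
    attr(out, "linpred") <- lp
    attr(out, "lambda_censor") <- lc
    out
  })
}

#' Run the cross-specification simulation study
#'
#' For each replicate: generate expression for all subjects; split into
#' training and test sets; build the network, modules, principal components
#' and all four representative-feature sets on the *training* samples only
#' (test features by projection); draw the true model under
#' `cfg$generating_kind` and simulate survival for every subject; fit each of
#' the four feature sets on the training set with cross-validated TGDR
#' (modified variant for R2/R4); and record the test-set median-split logrank
#' statistic and concordance index. Replicate-level failures (for instance a
#' replicate whose detected modules cannot host the requested number of true
#' features) are resampled with a perturbed seed, up to `max_retry` attempts.
#'
#' @param cfg A [sim_config()].
#' @param fitted_kinds Feature sets to fit (default all four).
#' @param max_retry Resampling attempts per replicate (default 3).
#' @param verbose Print per-replicate progress.
#' @return An object of class `sim_result`: list with `per_replicate` (tibble:
#'   replicate, generating_kind, fitted_kind, logrank, concordance,
#'   n_modules, seed) and `aggregate` (mean logrank/concordance per fitted
#'   kind).
#' @export
run_study <- function(cfg, fitted_kinds = c("R1", "R2", "R3", "R4"),
                      max_retry = 3, verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  fitted_kinds <- match.arg(fitted_kinds, c("R1", "R2", "R3", "R4"), several.ok = TRUE)
  rows <- vector("list", cfg$n_replicates)
  for (rep_i in seq_len(cfg$n_replicates)) {
    res <- NULL
    for (attempt in seq_len(max_retry)) {
      rep_seed <- child_seed(cfg$seed %||% 1L, rep_i * 10L + attempt)
      res <- tryCatch(run_replicate(cfg, rep_seed, fitted_kinds),
                      error = function(e) {
                        warning(sprintf("replicate %d attempt %d failed: %s",
                                        rep_i, attempt, conditionMessage(e)))
                        NULL
                      })
      if (!is.null(res)) break
    }
    if (is.null(res)) stopf("replicate %d failed after %d attempts", rep_i, max_retry)
    res$replicate <- rep_i
    rows[[rep_i]] <- res
    if (verbose) {
      message(sprintf("replicate %d/%d done", rep_i, cfg$n_replicates))
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  aggregate <- per_rep |>
    dplyr::group_by(.data$generating_kind, .data$fitted_kind) |>
    dplyr::summarise(logrank = mean(.data$logrank),
                     concordance = mean(.data$concordance), .groups = "drop")
  structure(list(per_replicate = per_rep, aggregate = aggregate, config = cfg),
            class = "sim_result")
}

run_replicate <- function(cfg, rep_seed, fitted_kinds) {
  x <- gen_expression(cfg, seed = rep_seed)
  split <- with_seed(child_seed(rep_seed, 1), sample.int(cfg$n_samples, cfg$n_train))
  x_tr <- x[, sort(split), drop = FALSE]
  x_te <- x[, setdiff(seq_len(cfg$n_samples), sort(split)), drop = FALSE]
  net <- build_network(x_tr, power = cfg$power)
  mods <- detect_modules(net, min_module_size = cfg$min_module_size,
                         cut_height = cfg$cut_height)
  if (mods$n_modules < 1) stopf("no modules detected")
  pcas <- module_pca(x_tr, mods)
  kinds <- unique(c(cfg$generating_kind, fitted_kinds))
  feats_tr <- lapply(setNames(kinds, kinds), function(k) build_features(pcas, kind = k, xi = cfg$xi))
  feats_te <- lapply(feats_tr, function(fs) project_features(x_te, pcas, fs))
  truth <- draw_true_model(feats_tr[[cfg$generating_kind]], cfg, seed = child_seed(rep_seed, 2))
  Z_all <- rbind(feats_tr[[cfg$generating_kind]]$Z, feats_te[[cfg$generating_kind]]$Z)
  surv <- gen_survival(Z_all, truth$beta_true, cfg, seed = child_seed(rep_seed, 3))
  n_tr <- nrow(feats_tr[[cfg$generating_kind]]$Z)
  tr_idx <- seq_len(n_tr)
  out <- vector("list", length(fitted_kinds))
  for (ki in seq_along(fitted_kinds)) {
    k <- fitted_kinds[ki]
    fit <- tgdr_tune(feats_tr[[k]], surv$time[tr_idx], surv$status[tr_idx],
                     v = cfg$fit_v, tau_grid = cfg$tau_grid, k_max = cfg$k_max,
                     delta_nu = cfg$delta_nu, seed = child_seed(rep_seed, 4 + ki))
    sc <- drop(feats_te[[k]]$Z %*% fit$beta)
    if (diff(range(sc)) == 0) {
      # null tuned fit: a constant score separates nothing (logrank 0) and
      # ranks every usable pair as a tie (concordance exactly 1/2)
      lr <- list(statistic = 0, df = 1L, p_value = 1)
      ci <- 0.5
    } else {
      lr <- logrank_median_split(sc, surv$time[-tr_idx], surv$status[-tr_idx])
      ci <- concordance_index(sc, surv$time[-tr_idx], surv$status[-tr_idx])
    }
    out[[ki]] <- tibble::tibble(generating_kind = cfg$generating_kind,
                                fitted_kind = k, logrank = lr$statistic,
                                concordance = ci, n_modules = mods$n_modules,
                                seed = rep_seed)
  }
  dplyr::bind_rows(out)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation study:", x$config$n_replicates, "replicates, truth =",
      x$config$generating_kind, "\n")
  print(x$aggregate)
  invisible(x)
}

#' @rdname run_study
#' @param x A `sim_result`.
#' @param ... Unused.
#' @export
tidy.sim_result <- function(x, ...) x$per_replicate

#' @rdname run_study
#' @export
glance.sim_result <- function(x, ...) x$aggregate
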