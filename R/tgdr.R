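#' Cox log partial likelihood
#'
#' Log partial likelihood of a Cox proportional-hazards model at coefficient
#' vector `beta`, with Breslow handling of tied event times (the risk set at
#' time \eqn{Y_i} is every subject with \eqn{Y_k \ge Y_i}). Internally guarded
#' against overflow by max-subtraction in the log-sum-exp.
#'
#' @param beta Coefficient vector (length = ncol(Z)).
#' @param Z Samples x features design matrix.
#' @param time Positive follow-up times.
#' @param status Event indicators (1 = event, 0 = censored).
#' @return A single finite number.
#' @export
log_partial_likelihood <- function(beta, Z, time, status) {
  Z <- as.matrix(Z)
  validate_survival(time, status)
  stopifnot(length(beta) == ncol(Z), nrow(Z) == length(time))
  cox_loglik_cpp(Z, as.numeric(beta), as.numeric(time), as.integer(status))
}

#' Gradient of the Cox log partial likelihood
#'
#' @inheritParams log_partial_likelihood
#' @return Numeric vector: for feature j,
#'   \eqn{g_j = \sum_i \delta_i (Z_{ij} - } weighted risk-set mean of
#'   \eqn{Z_j)}, with weights proportional to \eqn{\exp(\beta'Z_k)}.
#' @export
cox_gradient <- function(beta, Z, time, status) {
  Z <- as.matrix(Z)
  validate_survival(time, status)
  stopifnot(length(beta) == ncol(Z), nrow(Z) == length(time))
  g <- cox_gradient_cpp(Z, as.numeric(beta), as.numeric(time), as.integer(status))
  setNames(drop(g), colnames(Z))
}

#' Gradient thresholding vector
#'
#' `f_j = |g_j| >= tau * max_l |g_l|`. At `tau = 0` every component passes; at
#' `tau = 1` only the largest-magnitude components pass. A zero gradient
#' returns all `FALSE` (convergence signal).
#'
#' @param g Gradient vector.
#' @param tau Threshold in \[0, 1\].
#' @return Logical vector.
#' @export
threshold_vector <- function(g, tau) {
  if (!is.numeric(tau) || tau < 0 || tau > 1) stopf("`tau` must be in [0, 1]")
  m <- max(abs(g))
  if (m == 0) return(rep(FALSE, length(g)))
  abs(g) >= tau * m
}

#' Thresholding vector with strong heredity for second-order features
#'
#' Second-order features (index (i, j) with i >= 1) are thresholded by the
#' plain rule; a first-order feature (0, j) passes if its own gradient passes
#' the plain rule OR some selected second-order feature has j as a parent, so
#' that selecting a product always selects both parents.
#'
#' @inheritParams threshold_vector
#' @param index Tibble/data frame with integer columns `i`, `j`, one row per
#'   feature: (0, j) for first-order features, (i, j) with 1 <= i <= j for
#'   products of first-order features i and j.
#' @return Logical vector.
#' @export
threshold_vector_heredity <- function(g, tau, index) {
  check_feature_index(index, length(g))
  f <- threshold_vector(g, tau)
  if (!any(f)) return(f)
  second <- which(index$i >= 1L)
  first_pos <- match(seq_len(max(index$j)), ifelse(index$i == 0L, index$j, NA_integer_))
  for (s in second[f[second]]) {
    f[first_pos[index$i[s]]] <- TRUE
    f[first_pos[index$j[s]]] <- TRUE
  }
  f
}

check_feature_index <- function(index, p) {
  if (is.null(index) || !all(c("i", "j") %in% colnames(index)))
    stopf("`index` must have columns `i` and `j`")
  if (nrow(index) != p) stopf("`index` must have one row per feature")
  first <- index$j[index$i == 0L]
  second <- index[index$i >= 1L, , drop = FALSE]
  if (nrow(second)) {
    if (any(second$i > second$j)) stopf("second-order index pairs must have i <= j")
    if (!all(c(second$i, second$j) %in% first))
      stopf("every second-order feature needs both parent first-order features present")
  }
  invisible(index)
}

# Map feature index pairs to 0-based parent column positions for the C++
# engine: -1 for first-order features.
parent_columns <- function(index) {
  p <- nrow(index)
  par1 <- par2 <- rep(-1L, p)
  if (any(index$i >= 1L)) {
    first_pos <- match(seq_len(max(index$j)), ifelse(index$i == 0L, index$j, NA_integer_))
    sec <- which(index$i >= 1L)
    par1[sec] <- first_pos[index$i[sec]] - 1L
    par2[sec] <- first_pos[index$j[sec]] - 1L
  }
  list(par1 = as.integer(par1), par2 = as.integer(par2))
}

#' Fit a Cox model by threshold gradient directed regularization
#'
#' Starting from `beta = 0`, each of `K` iterations recomputes the gradient of
#' the log partial likelihood at the current estimate, thresholds it at
#' `tau` times its largest absolute component (with the strong-heredity rule
#' when `variant = "modified"`), and moves the passing components by
#' `delta_nu` times their gradient. Features are centred and scaled to unit
#' norm internally so that gradient magnitudes are comparable across features;
#' coefficients are mapped back to the input scale on output.
#'
#' @param Z Samples x features matrix, or a [feature_set].
#' @param time,status Survival outcome (see [log_partial_likelihood()]).
#' @param tau Threshold in \[0, 1\].
#' @param K Number of iterations (`K = 0` returns the zero fit).
#' @param delta_nu Step-size increment (default 1e-3).
#' @param variant `"plain"` or `"modified"` (strong heredity; requires
#'   `index`). Defaults to `"modified"` when `Z` is a feature set containing
#'   second-order columns.
#' @param index Feature index (see [threshold_vector_heredity()]); taken from
#'   `Z` when it is a `feature_set`.
#' @param standardize Standardize features internally (default `TRUE`).
#' @return An object of class `tgdr_fit` with elements `beta` (input scale),
#'   `selected`, `tau`, `K`, `delta_nu`, `variant`, `index`,
#'   `loglik_trace` (length K+1, training log partial likelihood at every
#'   iterate), `heredity_ok`, `iterations`, `standardization`.
#' @export
tgdr_fit <- function(Z, time, status, tau, K, delta_nu = 1e-3,
                     variant = NULL, index = NULL, standardize = TRUE) {
  if (inherits(Z, "feature_set")) {
    if (is.null(index)) index <- Z$index
    if (is.null(variant)) variant <- if (any(Z$index$i >= 1L)) "modified" else "plain"
    Z <- Z$Z
  }
  Z <- as.matrix(Z)
  if (is.null(variant)) variant <- "plain"
  variant <- match.arg(variant, c("plain", "modified"))
  validate_survival(time, status)
  if (!is.numeric(tau) || tau < 0 || tau > 1) stopf("`tau` must be in [0, 1]")
  if (!is.numeric(K) || K < 0 || K != round(K)) stopf("`K` must be a nonnegative integer")
  p <- ncol(Z)
  if (is.null(index)) index <- tibble::tibble(i = 0L, j = seq_len(p))
  check_feature_index(index, p)
  if (variant == "modified" && !any(index$i >= 1L))
    variant <- "plain" # no second-order terms: the rules coincide
  std <- standardize_columns(Z, standardize)
  par <- if (variant == "modified") parent_columns(index) else list(par1 = rep(-1L, p), par2 = rep(-1L, p))
  res <- tgdr_engine(std$Z, as.numeric(time), as.integer(status),
                     tau, as.integer(K), delta_nu, variant == "modified",
                     par$par1, par$par2,
                     FALSE, matrix(0, 0, p), numeric(0), integer(0))
  beta <- drop(res$beta) / std$scale
  names(beta) <- colnames(Z)
  structure(list(beta = beta, selected = beta != 0, tau = tau, K = as.integer(K),
                 delta_nu = delta_nu, variant = variant, index = index,
                 loglik_trace = drop(res$loglik_trace),
                 heredity_ok = res$heredity_ok,
                 iterations = res$iterations,
                 standardization = tibble::tibble(center = std$center, scale = std$scale),
                 cv = NULL),
            class = "tgdr_fit")
}

standardize_columns <- function(Z, standardize) {
  p <- ncol(Z)
  if (!standardize) return(list(Z = Z, center = rep(0, p), scale = rep(1, p)))
  center <- colMeans(Z)
  Zc <- sweep(Z, 2, center)
  scale <- sqrt(colSums(Zc^2))
  scale[scale < 1e-12] <- 1
  list(Z = sweep(Zc, 2, scale, "/"), center = center, scale = scale)
}

#' Tune TGDR by V-fold cross-validation
#'
#' Grid search over `tau_grid` x 0..`k_max`. Folds are a seeded random
#' partition stratified on the event indicator. For each `tau` and fold the
#' whole iteration path is run once on the training split and the
#' cross-validated partial-likelihood criterion (Verweij-van Houwelingen)
#' \eqn{\sum_v [R_{full}(\beta^{(-v)}) - R_{-v}(\beta^{(-v)})]} is recorded at
#' every iteration count; the returned `(tau, K)` maximises the summed
#' criterion (ties: larger `tau`, then smaller `K`).
#'
#' @inheritParams tgdr_fit
#' @param v Number of folds (default 5).
#' @param tau_grid Thresholds to search (default 1.0, 0.95, ..., 0.05, 0).
#' @param k_max Largest iteration count considered (default 2500).
#' @param seed Seed for the fold partition.
#' @param refit If `TRUE` (default) refit on the full data at the tuned
#'   `(tau, K)` and return the fit with the tuning trace attached; otherwise
#'   return the tuning summary only.
#' @return A `tgdr_fit` (when `refit`) whose `cv` element holds `tau`, `K`,
#'   the criterion trace tibble and fold assignment; otherwise that list.
#' @export
tgdr_tune <- function(Z, time, status, v = 5, tau_grid = seq(1, 0, by = -0.05),
                      k_max = 2500, delta_nu = 1e-3, variant = NULL, index = NULL,
                      seed = NULL, standardize = TRUE, refit = TRUE) {
  if (inherits(Z, "feature_set")) {
    if (is.null(index)) index <- Z$index
    if (is.null(variant)) variant <- if (any(Z$index$i >= 1L)) "modified" else "plain"
    Z <- Z$Z
  }
  Z <- as.matrix(Z)
  if (is.null(variant)) variant <- "plain"
  variant <- match.arg(variant, c("plain", "modified"))
  validate_survival(time, status)
  p <- ncol(Z)
  if (is.null(index)) index <- tibble::tibble(i = 0L, j = seq_len(p))
  check_feature_index(index, p)
  if (variant == "modified" && !any(index$i >= 1L)) variant <- "plain"
  folds <- stratified_folds(status, v, seed = seed)
  par <- if (variant == "modified") parent_columns(index) else list(par1 = rep(-1L, p), par2 = rep(-1L, p))

  best <- list(cvl = -Inf, tau = tau_grid[1], K = 0L)
  trace <- vector("list", length(tau_grid))
  for (t_i in seq_along(tau_grid)) {
    tau <- tau_grid[t_i]
    cvl <- numeric(k_max + 1)
    for (fold in seq_len(v)) {
      tr <- folds != fold
      std <- standardize_columns(Z[tr, , drop = FALSE], TRUE)
      # full-data likelihood needs features on the same scale as the fold fit;
      # centring shifts the linear predictor by a constant, which the partial
      # likelihood ignores, so rescaling alone suffices.
      Z_all <- sweep(Z, 2, std$scale, "/")
      res <- tgdr_engine(std$Z, as.numeric(time[tr]), as.integer(status[tr]),
                         tau, as.integer(k_max), delta_nu, variant == "modified",
                         par$par1, par$par2,
                         TRUE, Z_all, as.numeric(time), as.integer(status))
      cvl <- cvl + drop(res$cvl_trace)
    }
    trace[[t_i]] <- tibble::tibble(tau = tau, K = 0:k_max, cvl = cvl)
    k_best <- which.max(cvl) - 1L
    if (cvl[k_best + 1L] > best$cvl + 1e-12) {
      best <- list(cvl = cvl[k_best + 1L], tau = tau, K = k_best)
    }
  }
  tuning <- list(tau = best$tau, K = best$K, criterion = best$cvl,
                 cv_trace = dplyr::bind_rows(trace), folds = folds, v = v, seed = seed)
  if (!refit) return(tuning)
  fit <- tgdr_fit(Z, time, status, tau = best$tau, K = best$K, delta_nu = delta_nu,
                  variant = variant, index = index, standardize = standardize)
  fit$cv <- tuning
  fit
}

#' @export
print.tgdr_fit <- function(x, ...) {
  cat(sprintf("TGDR Cox fit (%s): %d features, %d selected; tau = %.2f, K = %d\n",
              x$variant, length(x$beta), sum(x$selected), x$tau, x$K))
  invisible(x)
}

#' Tidy a TGDR fit
#'
#' @param x A `tgdr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `term`, `i`, `j`, `estimate`,
#'   `selected`.
#' @export
tidy.tgdr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta) %||% paste0("z", x$index$i, ".", x$index$j),
                 i = x$index$i, j = x$index$j,
                 estimate = unname(x$beta), selected = unname(x$selected))
}

#' @rdname tidy.tgdr_fit
#' @return For `glance`: a one-row tibble with `tau`, `K`, `n_selected`,
#'   `log_partial_likelihood`, `variant`.
#' @export
glance.tgdr_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, K = x$K, n_selected = sum(x$selected),
                 log_partial_likelihood = x$loglik_trace[length(x$loglik_trace)],
                 variant = x$variant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
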