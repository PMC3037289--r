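#' Two-group logrank statistic from a median split of risk scores
#'
#' Dichotomizes scores at their median (scores equal to the median go to the
#' low-risk group), then computes the standard two-group logrank chi-square
#' statistic: the squared sum of observed-minus-expected events in the
#' high-risk group over distinct event times, divided by the summed
#' hypergeometric variance. Under no association the statistic is chi-square
#' with 1 degree of freedom.
#'
#' @param scores Numeric risk scores, one per subject.
#' @param time,status Survival outcome.
#' @return A list with `statistic`, `df` (1) and `p_value`.
#' @export
logrank_median_split <- function(scores, time, status) {
  validate_survival(time, status)
  stopifnot(length(scores) == length(time))
  med <- median(scores)
  high <- scores > med
  if (!any(high) || all(high)) stopf("degenerate median split: all scores on one side")
  logrank_two_group(high, time, status)
}

# Two-group logrank chi-square; `group` is the high-risk indicator.
logrank_two_group <- function(group, time, status) {
  ev_times <- sort(unique(time[status == 1]))
  O1 <- E1 <- V <- 0
  for (tt in ev_times) {
    at <- time >= tt
    n <- sum(at)
    n1 <- sum(at & group)
    d <- sum(time == tt & status == 1)
    d1 <- sum(time == tt & status == 1 & group)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) stopf("zero variance in logrank statistic (no usable event times)")
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, df = 1L, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index for censored survival
#'
#' Fraction of usable subject pairs where the higher risk score belongs to the
#' subject with the shorter survival. A pair is usable when the smaller
#' observed time is an event time (pairs with tied observed times are not
#' used); tied scores count 1/2.
#'
#' @inheritParams logrank_median_split
#' @return A number in \[0, 1\]; 0.5 corresponds to random scores.
#' @export
concordance_index <- function(scores, time, status) {
  validate_survival(time, status)
  n <- length(scores)
  stopifnot(n == length(time))
  Ti <- matrix(time, n, n)
  Si <- matrix(scores, n, n)
  usable <- (Ti < t(Ti)) & (status == 1)     # subject i (rows) fails first
  if (!any(usable)) stopf("no usable pairs for the concordance index")
  conc <- Si > t(Si)
  tied <- Si == t(Si)
  (sum(usable & conc) + 0.5 * sum(usable & tied)) / sum(usable)
}

#' Cross-validated prediction evaluation of network features
#'
#' The evaluation loop for a preprocessed expression matrix with survival
#' outcomes: partition samples into `v` folds; for each fold, tune and fit the
#' TGDR Cox model (inner cross-validation) on the remaining samples and score
#' the held-out samples with the fitted coefficients; finally summarise the
#' out-of-fold risk scores by the median-split logrank statistic and the
#' concordance index.
#'
#' By default the network, modules and features are built once on the full
#' data (the construction is unsupervised) and only tuning/estimation is
#' repeated per fold; `rebuild_features = TRUE` instead rebuilds the network
#' and features from each fold's training samples and projects the held-out
#' samples onto them, which avoids any reuse of held-out samples at the cost
#' of refitting the network `v` times.
#'
#' @param x Preprocessed genes x samples matrix.
#' @param time,status Survival outcome aligned to `colnames(x)`.
#' @param kind Representative-feature set: `"R1"`, `"R2"`, `"R3"`, `"R4"`.
#' @param v Number of outer folds (default 5).
#' @param seed Seed controlling fold partitions (outer and inner).
#' @param power Soft-threshold power (default 6).
#' @param min_module_size,cut_height Module detection controls
#'   (see [detect_modules()]).
#' @param xi Variance percentage for R3/R4 (default 80).
#' @param inner_v Folds for inner tuning (default 5).
#' @param tau_grid,k_max,delta_nu TGDR tuning controls (see [tgdr_tune()]).
#' @param rebuild_features Rebuild network/features inside each fold
#'   (default `FALSE`).
#' @return An object of class `cv_evaluation`: list with `scores` (tibble:
#'   sample, fold, score), `logrank`, `concordance`, `per_fold_fits`, `kind`,
#'   `fold_assignment`.
#' @export
cv_predict <- function(x, time, status, kind = c("R1", "R2", "R3", "R4"),
                       v = 5, seed = NULL, power = 6, min_module_size = 25,
                       cut_height = NULL, xi = 80, inner_v = 5,
                       tau_grid = seq(1, 0, by = -0.05), k_max = 2500,
                       delta_nu = 1e-3, rebuild_features = FALSE) {
  kind <- match.arg(kind)
  validate_expression(x)
  validate_survival(time, status)
  stopifnot(ncol(x) == length(time))
  folds <- stratified_folds(status, v, seed = seed)

  build <- function(train_x) {
    net <- build_network(train_x, power = power)
    mods <- detect_modules(net, min_module_size = min_module_size, cut_height = cut_height)
    if (mods$n_modules < 1) stopf("no modules detected; loosen `min_module_size` or `cut_height`")
    pcas <- module_pca(train_x, mods)
    list(features = build_features(pcas, kind = kind, xi = xi), pcas = pcas, modules = mods)
  }

  full <- if (!rebuild_features) build(x) else NULL
  scores <- numeric(ncol(x))
  fits <- vector("list", v)
  for (fold in seq_len(v)) {
    tr <- folds != fold
    if (rebuild_features) {
      fb <- build(x[, tr, drop = FALSE])
      Z_tr <- fb$features
      Z_te <- project_features(x[, !tr, drop = FALSE], fb$pcas, fb$features)$Z
    } else {
      Z_tr <- full$features
      Z_tr <- structure(list(kind = kind, Z = full$features$Z[tr, , drop = FALSE],
                             index = full$features$index, provenance = full$features$provenance,
                             P = full$features$P, xi = full$features$xi),
                        class = "feature_set")
      Z_te <- full$features$Z[!tr, , drop = FALSE]
    }
    fit <- tgdr_tune(Z_tr, time[tr], status[tr], v = inner_v, tau_grid = tau_grid,
                     k_max = k_max, delta_nu = delta_nu,
                     seed = child_seed(seed, 1000 + fold))
    scores[!tr] <- drop(Z_te %*% fit$beta)
    fits[[fold]] <- fit
  }
  lr <- logrank_median_split(scores, time, status)
  structure(list(scores = tibble::tibble(sample = colnames(x), fold = folds, score = scores),
                 logrank = lr,
                 concordance = concordance_index(scores, time, status),
                 per_fold_fits = fits, kind = kind, fold_assignment = folds,
                 time = time, status = status, seed = seed),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (%s, %d folds): logrank %.2f (p = %.3g), concordance %.3f\n",
              x$kind, max(x$fold_assignment), x$logrank$statistic, x$logrank$p_value, x$concordance))
  invisible(x)
}

#' @rdname cv_predict
#' @param x A `cv_evaluation`.
#' @param ... Unused.
#' @return For `glance`: one-row tibble with `kind`, `logrank_statistic`,
#'   `logrank_p`, `concordance`.
#' @export
glance.cv_evaluation <- function(x, ...) {
  tibble::tibble(kind = x$kind, logrank_statistic = x$logrank$statistic,
                 logrank_p = x$logrank$p_value, concordance = x$concordance)
}

#' @rdname cv_predict
#' @export
tidy.cv_evaluation <- function(x, ...) x$scores

#' Rewrite a fitted feature-level model at the gene level
#'
#' Module principal components are linear combinations of the genes in their
#' module, so any fitted model in representative features can be expanded
#' into a gene-level risk score: a linear coefficient per gene, a quadratic
#' coefficient per gene and an interaction coefficient per unordered gene
#' pair. Because component scores are computed from centred expression, the
#' expansion also carries the induced constant offset, and the gene-level
#' score reproduces the feature-level score \eqn{\beta'Z} exactly.
#'
#' @param fit A `tgdr_fit` aligned to `features`.
#' @param features The `feature_set` the model was fitted on.
#' @param pcas The `module_pca_set` that produced the features.
#' @param n_top Number of top-magnitude terms to rank (default 20).
#' @return An object of class `gene_level_model`: list with `linear` (named
#'   per-gene coefficients), `quadratic` (named per-gene coefficients of
#'   squared expression), `pairwise` (tibble gene1, gene2, coefficient),
#'   `offset`, and `ranked` (tibble of the `n_top` largest-magnitude terms).
#' @export
gene_level_coefficients <- function(fit, features, pcas, n_top = 20) {
  stopifnot(inherits(fit, "tgdr_fit"), inherits(features, "feature_set"),
            inherits(pcas, "module_pca_set"))
  if (length(fit$beta) != ncol(features$Z)) stopf("fit and feature set are not aligned")
  genes <- sort(unique(unlist(lapply(pcas, function(p) p$genes))))
  gpos <- setNames(seq_along(genes), genes)
  prov <- features$provenance
  P <- features$P
  # per first-order feature: full-length weight vector w and offset a
  W <- matrix(0, length(genes), P)
  a <- numeric(P)
  for (r in seq_len(P)) {
    pca <- pcas[[prov$module[r]]]
    vload <- pca$loadings[, prov$pc[r]]
    W[gpos[pca$genes], r] <- vload
    a[r] <- -sum(pca$center * vload)
  }
  beta <- unname(fit$beta)
  idx <- features$index
  lin <- numeric(length(genes))
  offset <- 0
  Q <- matrix(0, length(genes), length(genes))
  for (k in which(beta != 0)) {
    i <- idx$i[k]; j <- idx$j[k]; b <- beta[k]
    if (i == 0L) {
      lin <- lin + b * W[, j]
      offset <- offset + b * a[j]
    } else {
      Q <- Q + b * (tcrossprod(W[, i], W[, j]) + tcrossprod(W[, j], W[, i])) / 2
      lin <- lin + b * (a[j] * W[, i] + a[i] * W[, j])
      offset <- offset + b * a[i] * a[j]
    }
  }
  names(lin) <- genes
  quad <- setNames(diag(Q), genes)
  ut <- which(upper.tri(Q) & Q != 0, arr.ind = TRUE)
  pairwise <- tibble::tibble(gene1 = genes[ut[, 1]], gene2 = genes[ut[, 2]],
                             coefficient = 2 * Q[ut])
  ranked <- dplyr::bind_rows(
    tibble::tibble(term = genes, type = "gene", coefficient = unname(lin)),
    tibble::tibble(term = paste0(genes, "^2"), type = "quadratic", coefficient = unname(quad)),
    tibble::tibble(term = paste(pairwise$gene1, pairwise$gene2, sep = ":"),
                   type = "interaction", coefficient = pairwise$coefficient))
  ranked <- ranked[ranked$coefficient != 0, , drop = FALSE]
  ranked <- ranked[order(-abs(ranked$coefficient)), , drop = FALSE]
  ranked <- head(ranked, n_top)
  structure(list(linear = lin, quadratic = quad, pairwise = pairwise,
                 offset = offset, ranked = tibble::as_tibble(ranked), genes = genes),
            class = "gene_level_model")
}

#' @rdname gene_level_coefficients
#' @param x For `tidy`/`gene_level_scores`: a `gene_level_model`; for
#'   `gene_level_scores`, also an expression matrix.
#' @param ... Unused.
#' @export
tidy.gene_level_model <- function(x, ...) x$ranked

#' Risk scores from a gene-level model
#'
#' @param model A `gene_level_model`.
#' @param x Genes x samples matrix containing every gene of the model.
#' @return Numeric risk score per sample, equal to the feature-level
#'   \eqn{\beta'Z} of the originating fit.
#' @export
gene_level_scores <- function(model, x) {
  stopifnot(inherits(model, "gene_level_model"))
  miss <- setdiff(model$genes, rownames(x))
  if (length(miss)) stopf("expression matrix is missing gene(s): %s", paste(head(miss, 5), collapse = ", "))
  U <- x[model$genes, , drop = FALSE]          # genes x samples
  lin_part <- drop(crossprod(U, model$linear))
  quad_part <- colSums(U * (quad_matrix(model) %*% U))
  lin_part + quad_part + model$offset
}

quad_matrix <- function(model) {
  g <- length(model$genes)
  Q <- matrix(0, g, g, dimnames = list(model$genes, model$genes))
  diag(Q) <- model$quadratic
  if (nrow(model$pairwise)) {
    i <- match(model$pairwise$gene1, model$genes)
    j <- match(model$pairwise$gene2, model$genes)
    Q[cbind(i, j)] <- Q[cbind(i, j)] + model$pairwise$coefficient / 2
    Q[cbind(j, i)] <- Q[cbind(j, i)] + model$pairwise$coefficient / 2
  }
  Q
}

#' @export
print.gene_level_model <- function(x, ...) {
  cat("Gene-level expansion over", length(x$genes), "genes;",
      sum(x$linear != 0), "linear,", sum(x$quadratic != 0), "quadratic,",
      nrow(x$pairwise), "pairwise terms\n")
  print(x$ranked)
  invisible(x)
}
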