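#' Build a weighted gene-coexpression network
#'
#' Constructs, from a preprocessed genes x samples matrix, the absolute-
#' correlation similarity \eqn{S(k,j) = |cor(k,j)|}, the soft-thresholded
#' adjacency \eqn{a_{k,j} = S(k,j)^b}, per-gene connectivity
#' \eqn{C_k = \sum_{u \ne k} a_{k,u}} and the topological-overlap
#' dissimilarity matrix. By default self-terms are excluded (the adjacency
#' diagonal is treated as 0), which keeps the overlap in \eqn{[0,1]};
#' `literal_sums = TRUE` instead evaluates the sums over all indices
#' including self-terms.
#'
#' @param x Genes x samples numeric matrix (no missing values, no constant
#'   gene, at least 3 samples).
#' @param power Soft-threshold exponent `b`; `NULL` selects it with
#'   [pick_power()].
#' @param literal_sums Include self-adjacency terms in connectivity and shared-
#'   neighbour sums (default `FALSE`).
#' @param ... Passed to [pick_power()] when `power` is `NULL`.
#' @return An object of class `gene_network`: list with `gene_ids`,
#'   `similarity`, `power`, `adjacency`, `connectivity`, `tom_dissimilarity`,
#'   and (when the power was selected automatically) `power_fits`.
#' @export
build_network <- function(x, power = 6, literal_sums = FALSE, ...) {
  net <- gene_similarity(x)
  if (is.null(power)) {
    pick <- pick_power(net, ...)
    net$power_fits <- pick$fits
    power <- pick$power
  }
  net <- gene_adjacency(net, power)
  net$connectivity <- connectivity(net, literal_sums = literal_sums)
  net$tom_dissimilarity <- tom_dissimilarity(net, literal_sums = literal_sums)
  net
}

#' Absolute-correlation similarity matrix
#'
#' @inheritParams build_network
#' @return A `gene_network` object with the `similarity` field populated.
#' @export
gene_similarity <- function(x) {
  validate_expression(x)
  if (ncol(x) < 3) stopf("need at least 3 samples to estimate correlations")
  s <- apply(x, 1, sd)
  if (any(s == 0)) stopf("constant gene row(s) have undefined correlation: %s",
                         paste(head(rownames(x)[s == 0], 5), collapse = ", "))
  S <- abs(cor(t(x)))
  S[S > 1] <- 1
  diag(S) <- 1
  structure(list(gene_ids = rownames(x), similarity = S, power = NULL,
                 adjacency = NULL, connectivity = NULL, tom_dissimilarity = NULL),
            class = "gene_network")
}

#' Soft-thresholded adjacency
#'
#' Raises the similarity matrix elementwise to the power `b`.
#'
#' @param net A `gene_network` with similarity populated.
#' @param power Positive exponent `b`.
#' @return The network with `adjacency` and `power` populated.
#' @export
gene_adjacency <- function(net, power) {
  stopifnot(inherits(net, "gene_network"))
  if (!is.numeric(power) || length(power) != 1 || power <= 0) stopf("`power` must be a positive number")
  net$adjacency <- net$similarity^power
  diag(net$adjacency) <- 1
  net$power <- power
  net
}

#' Per-gene connectivity
#'
#' Row sums of the adjacency matrix; by default the self-term is excluded.
#'
#' @inheritParams gene_adjacency
#' @param literal_sums Include the self-adjacency term (default `FALSE`).
#' @return Numeric vector of connectivities, named by gene.
#' @export
connectivity <- function(net, literal_sums = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  if (is.null(net$adjacency)) stopf("adjacency not populated; call gene_adjacency() first")
  C <- rowSums(net$adjacency) - if (literal_sums) 0 else diag(net$adjacency)
  setNames(C, net$gene_ids)
}

#' Topological-overlap dissimilarity
#'
#' Computes \eqn{d_{k,j} = 1 - \omega_{k,j}} with
#' \eqn{\omega_{k,j} = (l_{k,j} + a_{k,j}) / (\min(C_k, C_j) + 1 - a_{k,j})}
#' and \eqn{l_{k,j} = \sum_u a_{k,u} a_{j,u}}. By default the shared-neighbour
#' sum excludes \eqn{u \in \{k, j\}} and connectivity excludes the self-term,
#' which guarantees \eqn{\omega \in [0,1]}; `literal_sums = TRUE` evaluates the
#' sums over every index instead. The diagonal of the result is 0 and entries
#' are clipped into \eqn{[0,1]}.
#'
#' @inheritParams connectivity
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
tom_dissimilarity <- function(net, literal_sums = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  if (is.null(net$adjacency)) stopf("adjacency not populated; call gene_adjacency() first")
  A <- net$adjacency
  if (!literal_sums) diag(A) <- 0 # zero diagonal makes A %*% A exclude u in {k, j}
  L <- A %*% A
  C <- rowSums(A)
  minC <- outer(C, C, pmin)
  denom <- minC + 1 - A
  if (any(denom <= 0)) stopf("non-positive denominator in topological overlap; adjacency outside [0,1)?")
  W <- (L + A) / denom
  D <- 1 - W
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  D[D > 1] <- 1
  diag(D) <- 0
  dimnames(D) <- list(net$gene_ids, net$gene_ids)
  D
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power the connectivity distribution is binned into
#' `n_bins` equal-width bins; the model fit regresses log10(frequency) on
#' log10(mean bin connectivity) and records R-squared. Returns the smallest
#' candidate whose fit reaches `r2_target`; if none qualifies, the fallback
#' power (6, the value commonly used for coexpression networks) when
#' `fallback` is set, otherwise the candidate with the best fit.
#'
#' @param net A `gene_network` with similarity populated.
#' @param candidates Candidate powers (default 1..10).
#' @param r2_target Required scale-free fit R-squared (default 0.8).
#' @param n_bins Number of equal-width connectivity bins (default 10; empty
#'   bins are dropped).
#' @param fallback If `TRUE` (default), return power 6 when no candidate
#'   reaches `r2_target`.
#' @return A list with `power` and `fits` (tibble of power, r_squared).
#' @export
pick_power <- function(net, candidates = 1:10, r2_target = 0.8, n_bins = 10, fallback = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  if (length(candidates) < 1) stopf("`candidates` must be nonempty")
  r2 <- vapply(candidates, function(b) {
    A <- net$similarity^b
    diag(A) <- 1
    C <- rowSums(A) - diag(A)
    scale_free_r2(C, n_bins = n_bins)
  }, numeric(1))
  fits <- tibble::tibble(power = candidates, r_squared = r2)
  ok <- which(r2 >= r2_target)
  power <- if (length(ok)) {
    candidates[min(ok)]
  } else if (fallback) {
    6
  } else {
    candidates[which.max(r2)]
  }
  list(power = power, fits = fits)
}

# R^2 of log10(frequency) ~ log10(mean connectivity) over equal-width bins.
scale_free_r2 <- function(C, n_bins = 10) {
  C <- C[C > 0]
  if (length(C) < 2) stopf("all connectivities are zero; cannot assess scale-free fit")
  br <- unique(seq(min(C), max(C), length.out = n_bins + 1))
  if (length(br) < 3) return(0)
  bin <- cut(C, breaks = br, include.lowest = TRUE)
  kmean <- tapply(C, bin, mean)
  freq <- tapply(C, bin, length) / length(C)
  keep <- !is.na(kmean) & freq > 0
  if (sum(keep) < 3) return(0)
  lx <- log10(kmean[keep]); ly <- log10(freq[keep])
  if (sd(lx) == 0 || sd(ly) == 0) return(0)
  cor(lx, ly)^2 # R^2 of the simple regression log10(freq) ~ log10(connectivity)
}

#' Detect network modules by clustering the dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity, cut at a fixed height; branches of at least
#' `min_module_size` genes become modules, labelled 1..M in decreasing size
#' order (ties by smallest member index); all other genes get label 0.
#'
#' When `cut_height` is not supplied it is chosen adaptively but
#' deterministically: candidate heights (midpoints between consecutive
#' distinct merge heights, strictly below the top merge) are scanned and the
#' one producing the most branches of at least `min_module_size` genes is
#' used, ties resolved towards the largest height so that module membership
#' is as inclusive as possible. Topological-overlap dissimilarities
#' concentrate just below 1 whenever connectivities are small, so a cut at a
#' fixed fraction of the maximum height cannot separate branches there; the
#' scan adapts to the scale of the dendrogram at hand.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal, or a
#'   `gene_network` with `tom_dissimilarity` populated.
#' @param min_module_size Minimum genes per module (default 25).
#' @param cut_height Dendrogram cut height; default chosen by the branch-count
#'   scan described above.
#' @return A `module_assignment`: list with `gene_ids`, `labels` (integer,
#'   0 = unassigned), `n_modules`, `min_module_size`, `cut_height`, `hclust`.
#' @export
detect_modules <- function(D, min_module_size = 25, cut_height = NULL) {
  if (inherits(D, "gene_network")) D <- D$tom_dissimilarity
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stopf("`D` must be symmetric with zero diagonal")
  genes <- rownames(D)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(D)))
  if (nrow(D) < min_module_size) {
    warning("fewer genes than `min_module_size`; no modules assigned")
    return(new_module_assignment(genes, integer(nrow(D)), min_module_size, NA_real_, NULL))
  }
  hc <- hclust(as.dist(D), method = "average")
  if (is.null(cut_height)) cut_height <- scan_cut_height(hc, min_module_size)
  if (is.na(cut_height)) {
    return(new_module_assignment(genes, integer(nrow(D)), min_module_size, NA_real_, hc))
  }
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(length(raw))
  if (length(keep)) {
    first_idx <- vapply(keep, function(k) min(which(raw == k)), integer(1))
    ord <- keep[order(-as.integer(sizes[as.character(keep)]), first_idx)]
    for (m in seq_along(ord)) labels[raw == ord[m]] <- m
  }
  new_module_assignment(genes, labels, min_module_size, cut_height, hc)
}

# Deterministic static-cut selection: the candidate height giving the most
# branches of valid size; ties towards the largest height. Returns NA when no
# cut below the top merge yields any valid module.
scan_cut_height <- function(hc, min_module_size) {
  hs <- sort(unique(hc$height))
  if (length(hs) < 2) return(NA_real_)
  cand <- (hs[-1] + hs[-length(hs)]) / 2
  cl <- cutree(hc, h = cand)
  if (is.null(dim(cl))) cl <- matrix(cl, ncol = 1)
  counts <- apply(cl, 2, function(lab) sum(table(lab) >= min_module_size))
  if (max(counts) == 0) return(NA_real_)
  cand[max(which(counts == max(counts)))]
}

new_module_assignment <- function(gene_ids, labels, min_module_size, cut_height, hc) {
  structure(list(gene_ids = gene_ids, labels = as.integer(labels),
                 n_modules = max(0L, as.integer(labels)),
                 min_module_size = min_module_size,
                 cut_height = cut_height, hclust = hc),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("Module assignment:", length(x$gene_ids), "genes,", x$n_modules, "modules,",
      sum(x$labels == 0), "unassigned\n")
  if (x$n_modules > 0) {
    sz <- table(factor(x$labels[x$labels > 0], levels = seq_len(x$n_modules)))
    cat("Module sizes:", paste(as.integer(sz), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname detect_modules
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(gene = x$gene_ids, module = x$labels)
}
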