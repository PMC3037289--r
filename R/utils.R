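# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# Derive a reproducible child seed from a master seed and a stream label,
# keeping the result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 11 * stream) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x > 0

# V-fold assignment stratified on the event indicator so every fold keeps
# events; retried with perturbed seeds if a fold ends up without any event.
stratified_folds <- function(status, v, seed = NULL, max_retry = 25L) {
  n <- length(status)
  if (v < 2) stopf("`v` must be at least 2")
  for (attempt in seq_len(max_retry)) {
    folds <- with_seed(if (is.null(seed)) NULL else child_seed(seed, attempt), {
      f <- integer(n)
      for (grp in unique(status)) {
        idx <- which(status == grp)
        f[idx] <- sample(rep_len(seq_len(v), length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(v), function(k) {
      sum(status[folds != k] == 1) >= 1 && sum(folds == k) >= 1
    }, logical(1)))
    if (ok) return(folds)
  }
  stopf("could not build %d folds with at least one event in every training split", v)
}
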