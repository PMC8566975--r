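#' @keywords internal
"_PACKAGE"

# Fisher z-transform with a cap just inside |r| = 1 so that degenerate
# perfectly-correlated pairs stay finite.
fisher_z <- function(r, cap = 1 - 1e-6) {
  r <- pmin(pmax(r, -cap), cap)
  atanh(r)
}

fisher_inv <- function(z) tanh(z)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < .Machine$double.eps) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# Column z-scoring with an informative error on zero spread.
zscore_cols <- function(x, what = "column") {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad) > 0) {
    stop("zero standard deviation in ", what, " ", paste(bad, collapse = ", "),
         "; z-scoring undefined")
  }
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

# Derive a reproducible child seed from a master seed and a stage tag.
# Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
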