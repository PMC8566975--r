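# Group connectivity contrasts: depressed and control correlational
# models built independently, Cohen's d of edge correlation strengths per
# module pair (intramodular on the diagonal), and permutation
# significance from shuffled nodal module assignments.

#' Group-wise correlational models
#'
#' Applies the population aggregation separately to the expanded subject
#' models of each group.
#'
#' @param models named list of expanded subject `ndp_model`s.
#' @param labels two-class labels in the same order as `models`.
#' @return list with elements `depressed` and `control` (`ndp_model`s of
#'   scope `"group"`).
#' @export
group_models <- function(models, labels) {
  labels <- as_labels(labels)
  stopifnot(length(models) == length(labels))
  out <- list()
  for (grp in c("depressed", "control")) {
    lv <- if (grp == "depressed") levels(labels)[2] else levels(labels)[1]
    idx <- which(labels == lv)
    if (length(idx) < 2) stop("group '", grp, "' has < 2 subjects")
    out[[grp]] <- aggregate_population_model(models[idx], scope = "group")
  }
  out
}

# Edge values (r scale) for one module pair from a correlation matrix.
pair_edges <- function(R, assignment, a, b) {
  if (a == b) {
    idx <- which(assignment == a)
    if (length(idx) < 2) return(numeric(0))
    R[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  } else {
    as.numeric(R[assignment == a, assignment == b])
  }
}

# d matrix over all module pairs for a given assignment.
pairwise_d <- function(Rd, Rc, assignment, mods) {
  M <- length(mods)
  d <- matrix(NA_real_, M, M, dimnames = list(mods, mods))
  n_edges <- matrix(0L, M, M, dimnames = list(mods, mods))
  for (i in seq_len(M)) {
    for (j in i:M) {
      ed <- pair_edges(Rd, assignment, mods[i], mods[j])
      ec <- pair_edges(Rc, assignment, mods[i], mods[j])
      n_edges[i, j] <- n_edges[j, i] <- length(ed)
      if (length(ed) >= 2) {
        sp <- sqrt((stats::var(ed) + stats::var(ec)) / 2)
        if (sp > 0) {
          d[i, j] <- d[j, i] <- (mean(ed) - mean(ec)) / sp
        }
      }
    }
  }
  list(d = d, n_edges = n_edges)
}

#' Cohen's d of edge correlations per module pair
#'
#' For every unordered module pair (a, b) — with a = b giving the
#' intramodular case — collects the correlation-scale edges with one
#' endpoint in each module from the depressed and control group models
#' and computes `d = (mean_dep - mean_ctl) / pooled SD` (sign convention
#' depressed minus control). Pairs with fewer than 2 edges are masked.
#'
#' @param model_d,model_c group `ndp_model`s over the same locations.
#' @param assignment module id per electrode.
#' @return list of class `ndp_contrast`: `d` (module x module, symmetric),
#'   `n_edges`.
#' @export
module_pair_cohens_d <- function(model_d, model_c, assignment) {
  stopifnot(nrow(model_d$z) == nrow(model_c$z),
            length(assignment) == nrow(model_d$z))
  Rd <- model_correlation(model_d)
  Rc <- model_correlation(model_c)
  mods <- sort(unique(assignment))
  res <- pairwise_d(Rd, Rc, assignment, mods)
  structure(list(d = res$d, n_edges = res$n_edges, modules = mods),
            class = "ndp_contrast")
}

#' Permutation significance of module-pair contrasts
#'
#' Null distribution per pair from permuting the electrode-to-module
#' assignment (one permutation applied identically to both group models),
#' two-sided p per pair, significance at `alpha` (the stated
#' multiple-comparison criterion) plus a Bonferroni-adjusted mask over
#' the M(M+1)/2 pairs as a conservative check.
#'
#' @inheritParams module_pair_cohens_d
#' @param n_perm number of permutations (>= 100).
#' @param alpha per-pair significance threshold (default 0.001).
#' @param seed integer seed.
#' @return `ndp_contrast` with `d`, `n_edges`, `p`, `significant`,
#'   `significant_bonferroni`.
#' @export
permutation_significance <- function(model_d, model_c, assignment,
                                     n_perm = 1000, alpha = 0.001,
                                     seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- module_pair_cohens_d(model_d, model_c, assignment)
  Rd <- model_correlation(model_d)
  Rc <- model_correlation(model_c)
  mods <- obs$modules
  set.seed(seed)
  exceed <- matrix(0, length(mods), length(mods))
  valid <- matrix(0, length(mods), length(mods))
  for (b in seq_len(n_perm)) {
    perm <- sample(assignment)
    dn <- pairwise_d(Rd, Rc, perm, mods)$d
    ok <- !is.na(dn) & !is.na(obs$d)
    exceed[ok] <- exceed[ok] + (abs(dn[ok]) >= abs(obs$d[ok]))
    valid[ok] <- valid[ok] + 1
  }
  p <- (1 + exceed) / (1 + valid)
  p[is.na(obs$d)] <- NA
  dimnames(p) <- dimnames(obs$d)
  n_pairs <- length(mods) * (length(mods) + 1) / 2
  structure(list(d = obs$d, n_edges = obs$n_edges, p = p,
                 significant = !is.na(p) & p < alpha,
                 significant_bonferroni = !is.na(p) & p < alpha / n_pairs,
                 alpha = alpha, modules = mods),
            class = "ndp_contrast")
}

#' @export
print.ndp_contrast <- function(x, ...) {
  cat("Module-pair connectivity contrast (", length(x$modules),
      " modules)\n", sep = "")
  print(round(x$d, 3))
  if (!is.null(x$significant)) {
    cat("significant pairs at alpha=", x$alpha, ": ",
        sum(x$significant[upper.tri(x$significant, diag = TRUE)]),
        "\n", sep = "")
  }
  invisible(x)
}

#' Contrast table export
#'
#' Long-format table of the module-pair contrast, suitable for CSV.
#'
#' @param contrast `ndp_contrast`.
#' @return data.frame: module_a, module_b, n_edges, d, p, significant.
#' @export
contrast_table <- function(contrast) {
  mods <- contrast$modules
  rows <- list()
  for (i in seq_along(mods)) {
    for (j in i:length(mods)) {
      rows[[length(rows) + 1]] <- data.frame(
        module_a = mods[i], module_b = mods[j],
        n_edges = contrast$n_edges[i, j], d = contrast$d[i, j],
        p = if (is.null(contrast$p)) NA_real_ else contrast$p[i, j],
        significant = if (is.null(contrast$significant)) NA else
          contrast$significant[i, j])
    }
  }
  do.call(rbind, rows)
}
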