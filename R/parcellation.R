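# Functional-module parcellation of the population correlational model:
# Louvain maximization of Newman-Girvan modularity with a resolution
# parameter, allegiance across repeated runs, similarity to an anatomical
# atlas with a permutation null, a resolution sweep with peak selection,
# and hub identification via participation coefficients.

# Nonnegative working matrix: negative correlations thresholded to 0
# (Newman-Girvan null assumes nonnegative weights), zero diagonal.
prep_adjacency <- function(K, negatives = c("zero", "abs")) {
  negatives <- match.arg(negatives)
  K <- unname(as.matrix(K))
  stopifnot(isSymmetric(K))
  K <- if (negatives == "zero") pmax(K, 0) else abs(K)
  diag(K) <- 0
  K
}

#' Modularity of a partition (direct summation)
#'
#' `Q = sum over ordered same-module pairs (i != j) of
#' (K_ij - gamma * k_i k_j / (2W))` with the weighted Newman-Girvan null,
#' `k` the node strengths and `2W = sum(K)`. Unnormalized; matches the
#' quantity Louvain maximizes up to the constant factor `1/(2W)`.
#'
#' @param K symmetric nonneg. correlation matrix (negatives thresholded).
#' @param assignment integer module id per node.
#' @param gamma resolution parameter.
#' @return numeric Q.
#' @export
modularity_q <- function(K, assignment, gamma = 1) {
  K <- prep_adjacency(K)
  k <- rowSums(K)
  twoW <- sum(K)
  if (twoW == 0) stop("all-zero adjacency")
  same <- outer(assignment, assignment, "==")
  diag(same) <- FALSE
  P <- outer(k, k) / twoW
  sum((K - gamma * P)[same])
}

#' Louvain partition of a correlation matrix
#'
#' Community detection by Louvain optimization of resolution-weighted
#' Newman-Girvan modularity, with restarts; the best partition by
#' [modularity_q()] is returned. Module ids are contiguous from 1.
#'
#' @param K symmetric correlation matrix (negative entries thresholded to
#'   zero by default).
#' @param gamma resolution parameter; larger values give more, smaller
#'   modules.
#' @param seed integer seed (Louvain sweeps nodes in random order).
#' @param n_restarts number of restarts.
#' @param negatives `"zero"` (default) or `"abs"`.
#' @return list of class `ndp_parcellation`: `assignment`, `Q`,
#'   `n_modules`, `gamma`, `seed`.
#' @export
louvain_partition <- function(K, gamma = 1, seed = 1L, n_restarts = 10,
                              negatives = "zero") {
  A <- prep_adjacency(K, negatives)
  if (sum(A) == 0) stop("all-zero adjacency")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, paste0("louvain", r)))
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    mem <- as.integer(igraph::membership(cl))
    q <- modularity_q(A, mem, gamma)
    if (q > best_q) { best_q <- q; best <- mem }
  }
  mem <- as.integer(factor(best, levels = unique(best)))
  structure(list(assignment = mem, Q = best_q,
                 n_modules = length(unique(mem)), gamma = gamma,
                 seed = seed),
            class = "ndp_parcellation")
}

#' @export
print.ndp_parcellation <- function(x, ...) {
  cat("Parcellation: ", x$n_modules, " modules at gamma=", x$gamma,
      " (Q=", signif(x$Q, 4), ")\n", sep = "")
  invisible(x)
}

#' Module allegiance across repeated Louvain runs
#'
#' Probability, over `n_runs` independent Louvain runs, that each node
#' pair is co-assigned. Symmetric with unit diagonal.
#'
#' @inheritParams louvain_partition
#' @param n_runs number of repetitions (paper-scale default 100).
#' @return n x n allegiance matrix.
#' @export
allegiance <- function(K, gamma = 1, n_runs = 100, seed = 1L) {
  stopifnot(n_runs >= 2)
  n <- nrow(K)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    p <- louvain_partition(K, gamma, seed = derive_seed(seed, paste0("alg", r)),
                           n_restarts = 1)
    acc <- acc + outer(p$assignment, p$assignment, "==")
  }
  a <- acc / n_runs
  diag(a) <- 1
  a
}

#' Similarity of a parcellation to an atlas, with permutation null
#'
#' Adjusted Rand index between the module assignment and atlas labels;
#' the null distribution is obtained by randomly permuting the
#' electrode-to-module assignment, with a two-tailed test at `alpha`.
#'
#' @param assignment module id per electrode.
#' @param atlas_labels atlas region label per electrode.
#' @param n_perm number of permutations.
#' @param alpha two-tailed significance level.
#' @param seed integer seed.
#' @return list: `similarity`, `null_ci` (the alpha/2 and 1-alpha/2
#'   quantiles), `significant`, `degenerate` (single-module flag).
#' @export
atlas_similarity <- function(assignment, atlas_labels, n_perm = 1000,
                             alpha = 0.05, seed = 1L) {
  stopifnot(length(assignment) == length(atlas_labels))
  obs <- adjusted_rand_index(assignment, atlas_labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    adjusted_rand_index(sample(assignment), atlas_labels), numeric(1))
  ci <- stats::quantile(null, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(similarity = obs, null_ci = ci,
       significant = (obs < ci[1] | obs > ci[2]),
       degenerate = length(unique(assignment)) == 1)
}

#' Resolution (gamma) sweep with similarity-peak selection
#'
#' Partitions the model at each gamma, records modularity, number of
#' modules, allegiance stability (mean over pairs of
#' `max(allegiance, 1 - allegiance)`) and atlas similarity, then selects
#' the similarity peak with the fewest modules (the most parsimonious
#' granularity). With no interior peak the global maximum is returned
#' with a warning.
#'
#' @inheritParams louvain_partition
#' @param gamma_grid numeric grid (>= 3 points), default 0.5..2.1.
#' @param atlas_labels atlas region label per electrode.
#' @param n_runs allegiance repetitions per gamma.
#' @return list: `table` (one row per gamma: gamma, n_modules, Q,
#'   stability, similarity), `selected_gamma`, `selected`
#'   (`ndp_parcellation` at the selected gamma, with `allegiance`).
#' @export
gamma_sweep <- function(K, gamma_grid = seq(0.5, 2.1, by = 0.1),
                        atlas_labels, n_runs = 20, n_restarts = 10,
                        seed = 1L) {
  stopifnot(length(gamma_grid) >= 3)
  rows <- vector("list", length(gamma_grid))
  parts <- vector("list", length(gamma_grid))
  for (i in seq_along(gamma_grid)) {
    gm <- gamma_grid[i]
    p <- louvain_partition(K, gm, seed = seed, n_restarts = n_restarts)
    a <- allegiance(K, gm, n_runs = n_runs, seed = seed)
    stab <- mean(pmax(a, 1 - a)[upper.tri(a)])
    sim <- adjusted_rand_index(p$assignment, atlas_labels)
    rows[[i]] <- data.frame(gamma = gm, n_modules = p$n_modules, Q = p$Q,
                            stability = stab, similarity = sim)
    p$allegiance <- a
    parts[[i]] <- p
  }
  tab <- do.call(rbind, rows)
  s <- tab$similarity
  n <- length(s)
  is_peak <- rep(FALSE, n)
  if (n >= 3) {
    for (i in 2:(n - 1)) is_peak[i] <- s[i] >= s[i - 1] && s[i] >= s[i + 1] &&
        (s[i] > s[i - 1] || s[i] > s[i + 1])
  }
  if (!any(is_peak)) {
    warning("no interior similarity peak; returning global maximum")
    sel <- which.max(s)
  } else {
    peaks <- which(is_peak)
    sel <- peaks[which.min(tab$n_modules[peaks])]
  }
  list(table = tab, selected_gamma = gamma_grid[sel],
       selected = parts[[sel]])
}

#' Participation coefficients
#'
#' `y_i = 1 - sum_c (k_i(c) / k_i)^2` where `k_i(c)` is node i's edge
#' weight into module c and `k_i` its total strength. 0 when all weight
#' is intramodular (provincial), approaching `1 - 1/C` for an even spread
#' (connector).
#'
#' @param K symmetric correlation matrix (negatives thresholded to zero).
#' @param assignment module id per node.
#' @return list: `y` (PaC per node), `k_module` (nodes x modules strength),
#'   `k_total`.
#' @export
participation_coefficients <- function(K, assignment) {
  A <- prep_adjacency(K)
  mods <- sort(unique(assignment))
  k_mod <- vapply(mods, function(m)
    rowSums(A[, assignment == m, drop = FALSE]), numeric(nrow(A)))
  colnames(k_mod) <- mods
  k_tot <- rowSums(k_mod)
  iso <- k_tot == 0
  if (any(iso)) warning(sum(iso), " isolated node(s); PaC set to 0")
  frac <- k_mod / ifelse(k_tot == 0, 1, k_tot)
  y <- 1 - rowSums(frac^2)
  y[iso] <- 0
  list(y = y, k_module = k_mod, k_total = k_tot)
}

#' Hub weights per (atlas region, module)
#'
#' Electrodes in the bottom (provincial) and top (connector) `tail`
#' fraction of participation coefficients are selected; each
#' (region, module, kind) cell is scored `R = N * (N / T)` where N is the
#' number of selected electrodes of that region in that module and T the
#' region's total electrode count. Regions with fewer than
#' `min_electrodes` electrodes are dropped. Modules holding less than
#' `small_module_frac` of all electrodes skip tail selection and use all
#' their member electrodes. Hub locations are the mean coordinates of the
#' contributing electrodes.
#'
#' @param pac result of [participation_coefficients()].
#' @param assignment module id per electrode.
#' @param region_labels atlas region per electrode.
#' @param coords electrodes x 3 coordinate matrix (MNI mm).
#' @param tail tail fraction (default 0.10).
#' @param min_electrodes minimum region size retained.
#' @param small_module_frac threshold below which a module uses all its
#'   electrodes.
#' @return data.frame: region_label, module, hub_kind, n_selected,
#'   n_region_total, hub_weight, x_mm, y_mm, z_mm.
#' @export
hub_weights <- function(pac, assignment, region_labels, coords,
                        tail = 0.10, min_electrodes = 3,
                        small_module_frac = 0.01) {
  y <- pac$y
  n <- length(y)
  stopifnot(length(assignment) == n, length(region_labels) == n,
            nrow(coords) == n)
  lo <- stats::quantile(y, tail)
  hi <- stats::quantile(y, 1 - tail)
  sel <- list(provincial = y <= lo, connector = y >= hi)
  if (!any(sel$provincial) || !any(sel$connector)) {
    stop("empty tail selection at tail = ", tail)
  }
  small <- names(which(table(assignment) < small_module_frac * n))
  for (kind in names(sel)) {
    sel[[kind]][assignment %in% as.integer(small)] <- TRUE
  }
  reg_total <- table(region_labels)
  keep_regions <- names(reg_total)[reg_total >= min_electrodes]
  out <- list()
  for (kind in names(sel)) {
    s <- sel[[kind]]
    for (m in sort(unique(assignment))) {
      in_mod <- assignment == m
      for (rg in intersect(unique(region_labels[in_mod]), keep_regions)) {
        members <- which(in_mod & region_labels == rg & s)
        N <- length(members)
        T_ <- as.integer(reg_total[rg])
        xyz <- if (N > 0) colMeans(coords[members, , drop = FALSE]) else
          rep(NA_real_, 3)
        out[[length(out) + 1]] <- data.frame(
          region_label = rg, module = m, hub_kind = kind,
          n_selected = N, n_region_total = T_,
          hub_weight = N * (N / T_),
          x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3])
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$hub_kind, res$module, -res$hub_weight), ]
}
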