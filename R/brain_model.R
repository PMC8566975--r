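# Correlational whole-brain model: subject-level Fisher-z correlation
# matrices over observed electrodes, radial-basis-function expansion to
# the full electrode set, evidence-weighted population averaging, and
# Gaussian-process (kriging) reconstruction of activity at unsampled
# locations, with held-out and shuffled-model validation.

new_correlation_model <- function(z, weights, locations, scope) {
  stopifnot(isSymmetric(unname(z)), isSymmetric(unname(weights)),
            all(weights >= 0, na.rm = TRUE))
  structure(list(z = z, weights = weights, locations = locations,
                 scope = scope),
            class = "ndp_model")
}

#' @export
print.ndp_model <- function(x, ...) {
  cat("Correlational model (", x$scope, "): ", nrow(x$z),
      " locations\n", sep = "")
  invisible(x)
}

#' Subject-level correlational model
#'
#' Pearson correlations between all observed channel pairs over the full
#' series, Fisher z-transformed (|r| capped at 1 - 1e-6); unit evidence
#' weight on every observed pair.
#'
#' @param x channels x samples matrix (rownames = electrode ids).
#' @param locations data.frame with electrode coordinates for the rows of
#'   `x` (columns x_mm, y_mm, z_mm and electrode_id or global_id).
#' @return `ndp_model` with scope `"subject"`.
#' @export
subject_correlation_model <- function(x, locations) {
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 channels and >= 2 samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance channel(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(x))
  z <- fisher_z(r)
  diag(z) <- Inf  # sentinel: r = 1, excluded from averaging
  w <- matrix(1, nrow(x), nrow(x), dimnames = dimnames(z))
  new_correlation_model(z, w, locations, "subject")
}

#' Expand a subject model to the full electrode set by RBF averaging
#'
#' Estimates the Fisher-z correlation for every pair (a, b) of full
#' locations as the RBF-weighted average of observed-pair correlations,
#' `z_ab = sum_{i != j} w(a,i) w(b,j) z_ij / sum_{i != j} w(a,i) w(b,j)`
#' with `w(a,i) = exp(-||a - i||^2 / width^2)`. The denominator sums are
#' retained as evidence weights; pairs whose weights underflow to zero are
#' marked weight-0 (excluded from population averaging), not errors.
#'
#' @param model a scope-`"subject"` `ndp_model`.
#' @param full_locations data.frame of all global electrodes (columns
#'   global_id/electrode_id, x_mm, y_mm, z_mm).
#' @param width_mm RBF length scale in millimetres (default 20).
#' @return `ndp_model` over the full location set (scope `"subject"`).
#' @export
rbf_expand <- function(model, full_locations, width_mm = 20) {
  if (width_mm <= 0) stop("width_mm must be > 0")
  obs_xyz <- as.matrix(model$locations[, c("x_mm", "y_mm", "z_mm")])
  full_xyz <- as.matrix(full_locations[, c("x_mm", "y_mm", "z_mm")])
  G <- nrow(full_xyz); n <- nrow(obs_xyz)
  d2 <- outer(rowSums(full_xyz^2), rowSums(obs_xyz^2), "+") -
    2 * full_xyz %*% t(obs_xyz)
  W <- exp(-pmax(d2, 0) / width_mm^2)              # G x n
  Z0 <- model$z
  diag(Z0) <- 0
  ones0 <- matrix(1, n, n); diag(ones0) <- 0
  num <- W %*% Z0 %*% t(W)
  den <- W %*% ones0 %*% t(W)
  z <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  z <- (z + t(z)) / 2
  w <- (den + t(den)) / 2
  ids <- full_locations$electrode_id %||% full_locations$global_id
  dimnames(z) <- dimnames(w) <- list(ids, ids)
  diag(z) <- Inf
  new_correlation_model(z, w, full_locations, "subject")
}

#' Aggregate expanded subject models into a population or group model
#'
#' Evidence-weighted mean of Fisher-z entries across subjects; the model's
#' correlation matrix is `tanh` of the pooled z. All models must share the
#' same full location set.
#'
#' @param models list of expanded `ndp_model`s.
#' @param scope label for the result (`"population"` or `"group"`).
#' @return `ndp_model` whose weights are the summed evidence.
#' @export
aggregate_population_model <- function(models, scope = "population") {
  stopifnot(length(models) >= 1)
  G <- nrow(models[[1]]$z)
  for (m in models) {
    if (nrow(m$z) != G) stop("models cover different location sets")
  }
  num <- matrix(0, G, G); den <- matrix(0, G, G)
  for (m in models) {
    z <- m$z; w <- m$weights
    off <- row(z) != col(z)
    num[off] <- num[off] + (w * z)[off]
    den[off] <- den[off] + w[off]
  }
  off <- !diag(TRUE, G)
  if (any(den[off] == 0)) {
    stop("insufficient coverage: some location pair has zero total weight")
  }
  z <- num / pmax(den, .Machine$double.xmin)
  diag(z) <- Inf
  dimnames(z) <- dimnames(den) <- dimnames(models[[1]]$z)
  new_correlation_model(z, den, models[[1]]$locations, scope)
}

# Correlation matrix (r scale, unit diagonal) of a model.
model_correlation <- function(model) {
  r <- fisher_inv(model$z)
  r[!is.finite(model$z)] <- 1
  diag(r) <- 1
  r
}

# Note: RBF-averaged correlation matrices are not guaranteed positive
# semi-definite. The kriging solve below uses the smoothed matrix as-is
# (plus ridge), as the reference imputation method does; eigenvalue
# clipping was evaluated and rejected because it systematically biases
# the permuted-model chance control away from zero.

#' Uniformly permute a model's off-diagonal correlations
#'
#' The chance-level null for reconstruction validation: upper-triangle
#' entries are permuted uniformly and mirrored, preserving symmetry.
#'
#' @param model `ndp_model`.
#' @param seed integer seed.
#' @return permuted `ndp_model`.
#' @export
shuffle_model <- function(model, seed = 1L) {
  set.seed(seed)
  z <- model$z
  ut <- upper.tri(z)
  z[ut] <- sample(z[ut])
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  model$z <- z
  model
}

#' Reconstruct whole-brain activity by kriging
#'
#' Per time sample, activity at unobserved locations u is the Gaussian
#' conditional mean `K_uo (K_oo + eps I)^-1 y_o` under the model's
#' correlation matrix; observed channels are z-scored and passed through
#' unchanged (estimates are in z units).
#'
#' @param model population/group `ndp_model` over the full location set.
#' @param observed channels x samples matrix for the observed electrodes.
#' @param observed_idx integer indices of the observed electrodes within
#'   the model's location set.
#' @param ridge ridge added to `K_oo` (default `1e-6 * trace/n`, i.e.
#'   1e-6 on the correlation scale).
#' @return list: `data` (full locations x samples), `observed_mask`
#'   (logical), `observed_idx`.
#' @export
reconstruct_timeseries <- function(model, observed, observed_idx,
                                   ridge = NULL) {
  K <- model_correlation(model)
  G <- nrow(K)
  stopifnot(length(observed_idx) == nrow(observed),
            all(observed_idx >= 1 & observed_idx <= G))
  ridge <- ridge %||% (1e-6 * sum(diag(K)) / G)
  u <- setdiff(seq_len(G), observed_idx)
  y_o <- t(scale(t(observed)))  # z-score each observed channel
  y_o[is.nan(y_o)] <- 0
  Koo <- K[observed_idx, observed_idx, drop = FALSE] +
    diag(ridge, length(observed_idx))
  Kuo <- K[u, observed_idx, drop = FALSE]
  sol <- tryCatch(solve(Koo, y_o),
                  error = function(e) stop("K_oo singular despite ridge ",
                                           ridge, "; increase `ridge`"))
  out <- matrix(0, G, ncol(observed))
  out[observed_idx, ] <- y_o
  if (length(u) > 0) out[u, ] <- Kuo %*% sol
  rn <- rownames(model$z)
  if (!is.null(rn)) rownames(out) <- rn
  mask <- rep(FALSE, G); mask[observed_idx] <- TRUE
  list(data = out, observed_mask = mask, observed_idx = observed_idx)
}

#' Held-out (leave-one-patient-out) reconstruction validation
#'
#' For each subject, a population model is built from all other subjects;
#' each of the subject's electrodes is then reconstructed from the
#' subject's *remaining* electrodes (the target is never among its own
#' predictors) and correlated with the truth. With `shuffle = TRUE` the
#' model's off-diagonal correlations are uniformly permuted first — the
#' chance-level null. Per-patient accuracies are Fisher-averaged; a
#' one-sample t-test of the patient-level Fisher means against 0 is
#' reported.
#'
#' @param series named list of channels x samples matrices (cleaned).
#' @param electrodes electrode table (subject_id, electrode_id, global_id,
#'   x_mm, y_mm, z_mm).
#' @param full_locations data.frame of the global electrode set.
#' @param width_mm RBF width (mm).
#' @param shuffle permute model correlations before reconstruction.
#' @param seed seed for the shuffle.
#' @return list: `per_electrode` (data.frame subject, electrode, r),
#'   `per_patient` (data.frame subject, mean_z, mean_r), `mean_r` (mean of
#'   patient-level back-transformed means), `t`, `p`.
#' @export
holdout_validate <- function(series, electrodes, full_locations,
                             width_mm = 20, shuffle = FALSE, seed = 1L) {
  subjects <- names(series)
  if (length(subjects) < 3) stop("need >= 3 subjects")
  expanded <- lapply(subjects, function(sid) {
    loc <- electrodes[electrodes$subject_id == sid, , drop = FALSE]
    m <- subject_correlation_model(series[[sid]], loc)
    rbf_expand(m, full_locations, width_mm)
  })
  names(expanded) <- subjects
  per_el <- list(); per_pat <- list()
  for (sid in subjects) {
    loc <- electrodes[electrodes$subject_id == sid, , drop = FALSE]
    if (nrow(loc) < 2) {
      warning("subject ", sid, " has < 2 electrodes; skipped")
      next
    }
    pop <- aggregate_population_model(expanded[subjects != sid])
    if (shuffle) pop <- shuffle_model(pop, seed = derive_seed(seed, sid))
    x <- series[[sid]]
    gidx <- loc$global_id
    rs <- numeric(nrow(loc))
    for (e in seq_len(nrow(loc))) {
      pred <- setdiff(seq_len(nrow(loc)), e)
      stopifnot(!(e %in% pred))  # leakage guard
      rec <- reconstruct_timeseries(pop, x[pred, , drop = FALSE],
                                    gidx[pred])
      est <- rec$data[gidx[e], ]
      rs[e] <- if (stats::sd(est) == 0) 0 else stats::cor(est, x[e, ])
    }
    per_el[[sid]] <- data.frame(subject_id = sid,
                                electrode_id = loc$electrode_id, r = rs)
    mz <- mean(fisher_z(rs))
    per_pat[[sid]] <- data.frame(subject_id = sid, mean_z = mz,
                                 mean_r = fisher_inv(mz))
  }
  pat <- do.call(rbind, per_pat)
  tt <- stats::t.test(pat$mean_z, mu = 0)
  list(per_electrode = do.call(rbind, per_el), per_patient = pat,
       mean_r = mean(pat$mean_r), t = unname(tt$statistic),
       p = tt$p.value)
}
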