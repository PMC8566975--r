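# Network expression patterns (NEPs): back-projection of the classifier
# into feature space as per-subject log-odds impacts, hierarchical
# biclustering of the thresholded impacts into feature (NEP) and subject
# groups, and a withhold-one-NEP sensitivity analysis attributing
# classification probability to each pattern.

#' Per-subject, per-feature log-odds impacts
#'
#' Back-projects the PCA + logistic model:
#' `w_f = sum_c beta_c * L_fc * 1[|L_fc| >= loading_min]` and
#' `impact(s, f) = w_f * x_std(s, f)`. With both thresholds at zero the
#' impact rows sum (plus intercept) to the model's linear predictor.
#' Impacts with `|impact| < logodds_min` are zeroed in the copy used for
#' clustering.
#'
#' @param classifier `ndp_classifier` (its all-data `final` model is
#'   used) or a list with `std`, `loadings`, `coefs`.
#' @param features the subjects x features matrix the model was fit on.
#' @param loading_min PCA loading threshold (default 0.2).
#' @param logodds_min log-odds impact threshold (default 0.15).
#' @return list of class `ndp_logodds`: `impact` (raw), `thresholded`,
#'   `w` (per-feature weight), `intercept`, `thresholds`.
#' @export
feature_logodds <- function(classifier, features, loading_min = 0.2,
                            logodds_min = 0.15) {
  final <- if (inherits(classifier, "ndp_classifier")) classifier$final
           else classifier
  x <- if (inherits(features, "ndp_features")) features$x else features
  L <- final$loadings
  if (nrow(L) != ncol(x) ||
      !is.null(rownames(L)) && !identical(rownames(L), colnames(x))) {
    stop("feature labels of model and matrix do not match")
  }
  beta <- final$coefs[-1]
  Lthr <- L * (abs(L) >= loading_min)
  w <- as.numeric(Lthr %*% beta)
  names(w) <- colnames(x)
  xs <- std_apply(x, final$std)
  impact <- sweep(xs, 2, w, "*")
  thresholded <- impact * (abs(impact) >= logodds_min)
  structure(list(impact = impact, thresholded = thresholded, w = w,
                 intercept = final$coefs[1],
                 thresholds = c(loading_min = loading_min,
                                logodds_min = logodds_min)),
            class = "ndp_logodds")
}

#' Bicluster log-odds impacts into NEPs and subject groups
#'
#' Agglomerative hierarchical clustering (default Ward on Euclidean
#' distance) of the thresholded impact matrix: feature vectors (over
#' subjects) yield the network expression patterns, subject vectors yield
#' subject groups. All-zero features are left unassigned.
#'
#' @param logodds `ndp_logodds` from [feature_logodds()].
#' @param n_clusters number of NEPs (default 2).
#' @param linkage hclust method (default `"ward.D2"`).
#' @return list of class `ndp_nep`: `feature_nep` (named NEP1/NEP2/NA per
#'   feature), `subject_group` (integer), `feature_tree`, `subject_tree`.
#' @export
cluster_neps <- function(logodds, n_clusters = 2, linkage = "ward.D2") {
  imp <- logodds$thresholded
  nonzero <- colSums(imp != 0) > 0
  if (sum(nonzero) < max(2, n_clusters)) {
    stop("need >= ", max(2, n_clusters), " nonzero feature columns")
  }
  ft <- stats::hclust(stats::dist(t(imp[, nonzero, drop = FALSE])),
                      method = linkage)
  cl <- stats::cutree(ft, k = n_clusters)
  # deterministic NEP numbering: by first feature index in each cluster
  first <- vapply(seq_len(n_clusters), function(k) min(which(cl == k)), 1L)
  relab <- match(seq_len(n_clusters), order(first))
  feature_nep <- rep(NA_character_, ncol(imp))
  names(feature_nep) <- colnames(imp)
  feature_nep[nonzero] <- paste0("NEP", relab[cl])
  st <- stats::hclust(stats::dist(imp), method = linkage)
  subject_group <- stats::cutree(st, k = min(n_clusters, nrow(imp) - 1))
  structure(list(feature_nep = feature_nep, subject_group = subject_group,
                 feature_tree = ft, subject_tree = st),
            class = "ndp_nep")
}

#' Withhold-one-NEP sensitivity analysis
#'
#' For each subject, the probability of depression is computed from the
#' final model in full and with each NEP's features withheld (set to the
#' population mean, i.e. zero in z-space, before PCA projection); the
#' decrement is that NEP's probability contribution. Contributions need
#' not sum to the total probability. Subjects are tagged NEP1-/NEP2-driven
#' when one contribution exceeds the other by more than
#' `dominance_margin` (and is itself above the margin), `mixed`
#' otherwise, or `misclassified` when the full-model prediction
#' contradicts the label.
#'
#' @param classifier `ndp_classifier` with its `final` model.
#' @param features subjects x features matrix the model was fit on.
#' @param feature_nep named NEP assignment per feature (from
#'   [cluster_neps()]).
#' @param labels optional true labels (for the misclassified tag).
#' @param dominance_margin probability margin for the driven/mixed call.
#' @return data.frame: subject, p_full, one contribution column per NEP,
#'   profile.
#' @export
nep_sensitivity <- function(classifier, features, feature_nep,
                            labels = NULL, dominance_margin = 0.05) {
  final <- classifier$final
  x <- if (inherits(features, "ndp_features")) features$x else features
  xs <- std_apply(x, final$std)
  eta <- function(z) final$coefs[1] +
    as.numeric((z %*% final$loadings) %*% final$coefs[-1])
  p_full <- sigmoid(eta(xs))
  neps <- sort(unique(stats::na.omit(feature_nep)))
  contrib <- matrix(0, nrow(x), length(neps),
                    dimnames = list(rownames(x), neps))
  for (np in neps) {
    idx <- which(feature_nep == np)
    if (length(idx) == 0) {
      warning("empty NEP ", np, "; contribution 0")
      next
    }
    x0 <- xs
    x0[, idx] <- 0
    contrib[, np] <- p_full - sigmoid(eta(x0))
  }
  profile <- rep("mixed", nrow(x))
  if (length(neps) >= 2) {
    top <- apply(contrib, 1, which.max)
    top_c <- contrib[cbind(seq_len(nrow(x)), top)]
    second <- apply(contrib, 1, function(r) max(r[-which.max(r)]))
    driven <- (top_c - second > dominance_margin) & (top_c > dominance_margin)
    profile[driven] <- paste0(neps[top[driven]], "-driven")
  }
  if (!is.null(labels)) {
    y01 <- as.integer(as_labels(labels)) - 1L
    profile[(p_full >= 0.5) != (y01 == 1)] <- "misclassified"
  }
  out <- data.frame(subject = rownames(x) %||% seq_len(nrow(x)),
                    p_full = p_full, contrib, profile,
                    row.names = NULL, check.names = FALSE)
  out
}
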