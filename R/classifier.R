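# Depression-status classification from spectral-spatial features:
# leave-one-out cross-validated PCA + L1-regularized logistic regression,
# a label-permutation null, alternate models without PCA, and the
# line-length (epileptiform burden) control.

# Coerce labels to a control/depressed factor; positive class = depressed
# (the second level).
as_labels <- function(labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if ("depressed" %in% levels(labels)) {
    labels <- stats::relevel(labels, ref = setdiff(levels(labels),
                                                   "depressed")[1])
  }
  labels
}

balanced_accuracy <- function(truth01, pred01) {
  recalls <- vapply(c(0, 1), function(cl) {
    idx <- truth01 == cl
    if (!any(idx)) return(NA_real_)
    mean(pred01[idx] == cl)
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}

# Standardize train columns; zero-variance columns are dropped to 0.
std_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf  # column becomes all-zero
  list(mu = mu, sd = sdv)
}
std_apply <- function(x, st) sweep(sweep(x, 2, st$mu, "-"), 2, st$sd, "/")

# Fit L1/L2/EN logistic at a single fixed penalty; returns coef vector
# (intercept first) or NULL when the design is degenerate. Observations
# are class-balanced (weights n / (2 n_class)): leave-one-out training
# folds are always unbalanced by one subject, and without re-weighting an
# intercept-only fit anti-predicts the held-out subject's class, which
# drags the label-permutation null well below 50% balanced accuracy.
glmnet_fit <- function(x, y01, alpha, l1_c) {
  if (all(apply(x, 2, stats::sd) == 0)) return(NULL)
  n <- length(y01)
  tab <- table(factor(y01, levels = c(0, 1)))
  w <- n / (2 * as.numeric(tab[as.character(y01)]))
  lambda <- 1 / (n * l1_c)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y01, family = "binomial", alpha = alpha,
                   lambda = lambda, standardize = FALSE, weights = w),
    warning = function(wn) {
      # benign at desk scale; the permutation machinery exercises tiny folds
      if (grepl("fewer than 8", conditionMessage(wn)))
        invokeRestart("muffleWarning")
    })
  as.numeric(stats::coef(fit))
}

glmnet_prob <- function(coefs, x) {
  if (is.null(coefs)) return(rep(0.5, nrow(x)))
  sigmoid(coefs[1] + as.numeric(x %*% coefs[-1]))
}

# One PCA+logistic fold: fit on (x_tr, y_tr), return predictor closure
# pieces. PCA loadings columns are unit-norm by construction (prcomp).
fit_pca_logistic <- function(x_tr, y_tr, n_components, l1_c) {
  st <- std_fit(x_tr)
  xs <- std_apply(x_tr, st)
  ncp <- min(n_components, ncol(xs), nrow(xs) - 1)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  L <- pc$rotation[, seq_len(ncp), drop = FALSE]
  scores <- xs %*% L
  coefs <- glmnet_fit(scores, y_tr, alpha = 1, l1_c = l1_c)
  list(std = st, loadings = L, coefs = coefs)
}

predict_pca_logistic <- function(model, x_new) {
  s <- std_apply(x_new, model$std) %*% model$loadings
  glmnet_prob(model$coefs, s)
}

#' LOOCV PCA + L1-logistic classification
#'
#' Per fold, PCA and the logistic fit are computed on the training
#' subjects only (no leakage); the held-out subject is projected and
#' scored. Accuracy is balanced to group size (mean of per-class
#' recalls). A final model fit on all subjects is also returned for the
#' downstream network-expression-pattern analysis.
#'
#' @param features subjects x features matrix (or `ndp_features`).
#' @param labels two-class labels; the `depressed` level (or the second
#'   level) is the positive class.
#' @param n_components number of principal components (default 4).
#' @param l1_c inverse regularization strength C (lambda = 1/(n*C)).
#' @param seed integer seed (kept for API symmetry; the fit is
#'   deterministic).
#' @return list of class `ndp_classifier`: `probabilities` (held-out, per
#'   subject), `predicted`, `balanced_accuracy`, `folds` (per-fold
#'   loadings/coefficients/train indices), `final` (all-data model with
#'   `std`, `loadings`, `coefs`, `probabilities`), `labels`.
#' @export
loocv_classify <- function(features, labels, n_components = 4,
                           l1_c = 1.0, seed = 1L) {
  x <- if (inherits(features, "ndp_features")) features$x else features
  labels <- as_labels(labels)
  y01 <- as.integer(labels) - 1L
  n <- nrow(x)
  stopifnot(length(y01) == n)
  if (min(table(factor(y01, levels = c(0, 1)))) < 2) {
    stop("need >= 2 subjects per class")
  }
  if (n_components > min(n - 2, ncol(x))) {
    stop("n_components too large for ", n, " subjects / ", ncol(x),
         " features")
  }
  probs <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y01[tr])) < 2) stop("class absent from training fold ", i)
    m <- fit_pca_logistic(x[tr, , drop = FALSE], y01[tr], n_components, l1_c)
    probs[i] <- predict_pca_logistic(m, x[i, , drop = FALSE])
    folds[[i]] <- list(train = tr, loadings = m$loadings, coefs = m$coefs)
  }
  pred01 <- as.integer(probs >= 0.5)
  final <- fit_pca_logistic(x, y01, n_components, l1_c)
  final$probabilities <- predict_pca_logistic(final, x)
  names(final$probabilities) <- rownames(x)
  structure(list(probabilities = stats::setNames(probs, rownames(x)),
                 predicted = pred01,
                 balanced_accuracy = balanced_accuracy(y01, pred01),
                 folds = folds, final = final, labels = labels,
                 n_components = n_components, l1_c = l1_c),
            class = "ndp_classifier")
}

#' @export
print.ndp_classifier <- function(x, ...) {
  cat("LOOCV PCA + L1-logistic: balanced accuracy ",
      sprintf("%.1f%%", 100 * x$balanced_accuracy), " (n=",
      length(x$probabilities), ")\n", sep = "")
  invisible(x)
}

# Fast LOOCV balanced accuracy (no model storage) for permutations.
loocv_balacc <- function(x, y01, n_components, l1_c) {
  n <- nrow(x)
  pred01 <- integer(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    m <- fit_pca_logistic(x[tr, , drop = FALSE], y01[tr], n_components, l1_c)
    pred01[i] <- as.integer(predict_pca_logistic(m, x[i, , drop = FALSE]) >= 0.5)
  }
  balanced_accuracy(y01, pred01)
}

#' Label-permutation null for the LOOCV pipeline
#'
#' Re-runs the complete LOOCV PCA + logistic pipeline on `n_perm`
#' uniformly permuted label vectors.
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams loocv_classify
#' @param n_perm number of permutations (>= 100).
#' @return list: `observed` (balanced accuracy), `null` (numeric vector),
#'   `mean_null`, `p_value`.
#' @export
permutation_null <- function(features, labels, n_components = 4,
                             l1_c = 1.0, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  x <- if (inherits(features, "ndp_features")) features$x else features
  y01 <- as.integer(as_labels(labels)) - 1L
  observed <- loocv_balacc(x, y01, n_components, l1_c)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b)
    loocv_balacc(x, sample(y01), n_components, l1_c), numeric(1))
  list(observed = observed, null = null, mean_null = mean(null),
       p_value = (1 + sum(null >= observed)) / (n_perm + 1))
}

#' Alternate LOOCV models without PCA
#'
#' L1, L2 and elastic-net logistic regression plus a random forest, under
#' the same leave-one-out protocol on the raw (standardized) features.
#'
#' @inheritParams loocv_classify
#' @param n_trees random-forest size.
#' @return data.frame with one row per model: `model`,
#'   `balanced_accuracy`.
#' @export
alternate_models <- function(features, labels, l1_c = 1.0,
                             n_trees = 100, seed = 1L) {
  x <- if (inherits(features, "ndp_features")) features$x else features
  y01 <- as.integer(as_labels(labels)) - 1L
  n <- nrow(x)
  specs <- list(L1 = 1, L2 = 0, elastic_net = 0.5)
  pred <- matrix(NA_integer_, n, 4,
                 dimnames = list(NULL, c(names(specs), "random_forest")))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    st <- std_fit(x[tr, , drop = FALSE])
    xtr <- std_apply(x[tr, , drop = FALSE], st)
    xte <- std_apply(x[i, , drop = FALSE], st)
    for (nm in names(specs)) {
      cf <- glmnet_fit(xtr, y01[tr], alpha = specs[[nm]], l1_c = l1_c)
      pred[i, nm] <- as.integer(glmnet_prob(cf, xte) >= 0.5)
    }
    rf <- rf_fit(xtr, y01[tr], n_trees = n_trees,
                 seed = derive_seed(seed, paste0("rf", i)))
    pred[i, "random_forest"] <- as.integer(rf_predict(rf, xte) >= 0.5)
  }
  data.frame(model = colnames(pred),
             balanced_accuracy = apply(pred, 2, balanced_accuracy,
                                       truth01 = y01),
             row.names = NULL)
}

#' Line length per electrode
#'
#' Mean absolute successive difference, a standard proxy for residual
#' epileptiform burden.
#'
#' @param x channels x samples matrix.
#' @return numeric per channel.
#' @export
line_length <- function(x) {
  apply(x, 1, function(ch) mean(abs(diff(ch))))
}

#' Line-length control regression
#'
#' Logistic regression of depression status on per-module mean line
#' length; reports McFadden R^2 and the likelihood-ratio p-value. A
#' significant fit would indicate that residual epileptiform activity,
#' not network physiology, drives the classification.
#'
#' @param series named list (per subject) of channels x samples matrices
#'   over the full electrode set.
#' @param assignment module id per electrode.
#' @param labels two-class labels, same order as `series`.
#' @return list: `r2` (McFadden), `p` (LR test), `coefficients`,
#'   `separation` (glm convergence flag), `module_linelength` (subjects x
#'   modules matrix).
#' @export
linelength_control <- function(series, assignment, labels) {
  labels <- as_labels(labels)
  y01 <- as.integer(labels) - 1L
  if (min(table(factor(y01, levels = c(0, 1)))) < 2) {
    stop("need >= 2 subjects per class")
  }
  mods <- sort(unique(assignment))
  ll <- t(vapply(series, function(x) {
    el <- line_length(x)
    vapply(mods, function(m) mean(el[assignment == m]), numeric(1))
  }, numeric(length(mods))))
  colnames(ll) <- paste0("m", mods)
  dat <- data.frame(y = y01, ll)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  fit0 <- stats::glm(y ~ 1, data = dat, family = stats::binomial())
  r2 <- 1 - as.numeric(stats::logLik(fit) / stats::logLik(fit0))
  lr <- 2 * as.numeric(stats::logLik(fit) - stats::logLik(fit0))
  p <- stats::pchisq(lr, df = length(mods), lower.tail = FALSE)
  list(r2 = r2, p = p, coefficients = stats::coef(fit),
       separation = separation, module_linelength = ll)
}
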