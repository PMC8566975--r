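# A hand-built "final model" for closed-form checks: identity
# standardization, given loadings and coefficients.
toy_model <- function(loadings, coefs, p = nrow(loadings)) {
  structure(list(final = list(std = list(mu = rep(0, p), sd = rep(1, p)),
                              loadings = loadings, coefs = coefs)),
            class = "ndp_classifier")
}

test_that("log-odds impacts follow the thresholded dot product", {
  # one component, one supra-threshold loading 0.5, beta 2, x 1.5
  L <- matrix(c(0.5, 0.1), 2, 1)
  m <- toy_model(L, c(0, 2))
  x <- matrix(c(1.5, 3), 1, 2)
  lo <- feature_logodds(m, x, loading_min = 0.2, logodds_min = 0)
  expect_equal(unname(lo$impact[1, 1]), 1.5 * (2 * 0.5))
  expect_equal(unname(lo$impact[1, 2]), 0)  # sub-threshold loading dropped

  # all-zero coefficients -> all-zero impacts
  m0 <- toy_model(L, c(0.3, 0))
  lo0 <- feature_logodds(m0, x, loading_min = 0, logodds_min = 0)
  expect_true(all(lo0$impact == 0))
})

test_that("with zero thresholds impacts decompose the linear predictor", {
  sim <- simulate_feature_matrix(18, effect_size = 2, seed = 50)
  clf <- loocv_classify(sim$features, sim$labels, n_components = 3)
  lo <- feature_logodds(clf, sim$features, loading_min = 0,
                        logodds_min = 0)
  eta <- lo$intercept + rowSums(lo$impact)
  expect_equal(unname(sigmoid(eta)), unname(clf$final$probabilities),
               tolerance = 1e-9)
  # impact threshold zeroes small entries in the clustering copy only
  lo2 <- feature_logodds(clf, sim$features, loading_min = 0,
                         logodds_min = 0.15)
  expect_true(all(lo2$thresholded[abs(lo2$impact) < 0.15] == 0))
  expect_equal(lo2$impact, lo$impact)
})

test_that("biclustering recovers planted orthogonal blocks exactly", {
  # noiseless impact matrix: two orthogonal feature blocks over two
  # subject groups
  imp <- matrix(0, 10, 8,
                dimnames = list(sprintf("S%02d", 1:10), paste0("f", 1:8)))
  imp[1:5, 1:4] <- 2
  imp[6:10, 5:8] <- -1.5
  lo <- structure(list(impact = imp, thresholded = imp,
                       w = rep(1, 8), intercept = 0), class = "ndp_logodds")
  cl <- cluster_neps(lo)
  expect_equal(unname(cl$feature_nep),
               rep(c("NEP1", "NEP2"), each = 4))
  expect_equal(adjusted_rand_index(cl$subject_group,
                                   rep(1:2, each = 5)), 1)

  # duplicated feature columns land in the same cluster
  imp2 <- imp; imp2[, 5] <- imp2[, 1]
  lo2 <- lo; lo2$thresholded <- imp2
  cl2 <- cluster_neps(lo2)
  expect_equal(cl2$feature_nep[["f5"]], cl2$feature_nep[["f1"]])

  # all-zero features stay unassigned; single cluster collects the rest
  imp3 <- imp; imp3[, 8] <- 0
  lo3 <- lo; lo3$thresholded <- imp3
  cl3 <- cluster_neps(lo3, n_clusters = 1)
  expect_true(is.na(cl3$feature_nep[["f8"]]))
  expect_true(all(cl3$feature_nep[1:7] == "NEP1"))

  lo_zero <- lo; lo_zero$thresholded[] <- 0
  expect_error(cluster_neps(lo_zero), "nonzero feature columns")
})

test_that("sensitivity contribution matches the logistic closed form", {
  # single feature, eta = 1 for the subject: sigma(1) - sigma(0) = 0.2311
  m <- toy_model(matrix(1, 1, 1), c(0, 1), p = 1)
  class(m) <- "ndp_classifier"
  x <- matrix(1, 1, 1, dimnames = list("S1", "f1"))
  sens <- nep_sensitivity(m, x, c(f1 = "NEP1"))
  expect_equal(sens$NEP1, sigmoid(1) - sigmoid(0), tolerance = 1e-9)
  expect_equal(round(sens$NEP1, 4), 0.2311)
})

test_that("withholding every feature recovers the intercept probability", {
  sim <- simulate_feature_matrix(18, effect_size = 2, seed = 51)
  clf <- loocv_classify(sim$features, sim$labels, n_components = 3)
  nep_all <- stats::setNames(rep("NEP1", 36), colnames(sim$features))
  sens <- nep_sensitivity(clf, sim$features, nep_all)
  p_wh <- sens$p_full - sens$NEP1
  expect_equal(p_wh, rep(sigmoid(clf$final$coefs[1]), 18),
               tolerance = 1e-9)
})

test_that("contributions are invariant to feature column order", {
  sim <- simulate_feature_matrix(15, effect_size = 2, seed = 52)
  clf <- loocv_classify(sim$features, sim$labels, n_components = 3)
  lo <- feature_logodds(clf, sim$features)
  cl <- cluster_neps(lo)
  s1 <- nep_sensitivity(clf, sim$features, cl$feature_nep,
                        labels = sim$labels)
  perm <- sample(36)
  clf_p <- clf
  clf_p$final$std$mu <- clf$final$std$mu[perm]
  clf_p$final$std$sd <- clf$final$std$sd[perm]
  clf_p$final$loadings <- clf$final$loadings[perm, ]
  s2 <- nep_sensitivity(clf_p, sim$features[, perm],
                        cl$feature_nep[perm], labels = sim$labels)
  expect_equal(s1$NEP1, s2$NEP1, tolerance = 1e-9)
  expect_equal(s1$NEP2, s2$NEP2, tolerance = 1e-9)
  expect_equal(s1$profile, s2$profile)
})

test_that("a NEP whose features carry no model weight contributes zero", {
  # feature 2 has zero loading on the only component -> w_f = 0
  L <- matrix(c(1, 0), 2, 1)
  m <- toy_model(L, c(0.5, 1))
  class(m) <- "ndp_classifier"
  x <- matrix(c(2, 3), 1, 2, dimnames = list("S1", c("f1", "f2")))
  sens <- nep_sensitivity(m, x, c(f1 = "NEP1", f2 = "NEP2"))
  expect_equal(sens$NEP2, 0)
  expect_gt(sens$NEP1, 0)
})

test_that("planted NEP recovery works end-to-end at strong effect size", {
  agree <- vapply(1:3, function(s) {
    sim <- simulate_feature_matrix(40, effect_size = 3,
                                   nep_proportions = c(0.5, 0.5, 0),
                                   seed = s)
    clf <- loocv_classify(sim$features, sim$labels)
    lo <- feature_logodds(clf, sim$features)
    cl <- cluster_neps(lo)
    sens <- nep_sensitivity(clf, sim$features, cl$feature_nep,
                            labels = sim$labels)
    pure <- which(!is.na(sim$nep_assignment) &
                    sens$profile != "misclassified")
    truth <- sim$nep_assignment[pure]
    tags <- sens$profile[pure]
    swap <- c(NEP1 = "NEP2", NEP2 = "NEP1")
    max(mean(tags == paste0(truth, "-driven")),
        mean(tags == paste0(swap[truth], "-driven")))
  }, numeric(1))
  expect_gte(mean(agree), 0.8)
})
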