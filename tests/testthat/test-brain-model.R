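loc_df <- function(xyz, ids = sprintf("E%02d", seq_len(nrow(xyz)))) {
  data.frame(electrode_id = ids, global_id = seq_len(nrow(xyz)),
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             stringsAsFactors = FALSE)
}

test_that("subject correlation model is the Fisher-z of sample correlations", {
  x <- channels_with_correlation(0.5, n = 2048)
  m <- subject_correlation_model(x, loc_df(matrix(0, 2, 3)))
  expect_equal(m$z[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(m$weights[1, 2], 1)

  # identical channels: capped at atanh(1 - 1e-6)
  x2 <- rbind(x[1, ], x[1, ])
  m2 <- subject_correlation_model(x2, loc_df(matrix(0, 2, 3)))
  expect_equal(m2$z[1, 2], atanh(1 - 1e-6))

  # independent channels at n = 61440: |r| < 0.02 almost surely
  set.seed(10)
  x3 <- matrix(rnorm(2 * 61440), 2)
  m3 <- subject_correlation_model(x3, loc_df(matrix(0, 2, 3)))
  expect_lt(abs(tanh(m3$z[1, 2])), 0.02)

  x4 <- rbind(x[1, ], rep(1, 2048))
  expect_error(subject_correlation_model(x4, loc_df(matrix(0, 2, 3))),
               "zero-variance")
})

test_that("rbf expansion reproduces observed pairs in the small-width limit", {
  set.seed(11)
  xyz <- matrix(runif(12, -50, 50), 4, 3)
  x <- matrix(rnorm(4 * 512), 4)
  m <- subject_correlation_model(x, loc_df(xyz))
  ex <- rbf_expand(m, loc_df(xyz), width_mm = 1e-3)
  off <- upper.tri(m$z)
  expect_equal(ex$z[off], m$z[off], tolerance = 1e-9)
})

test_that("rbf expansion of constant correlations is constant", {
  xyz <- matrix(runif(9, -50, 50), 3, 3)
  m <- structure(list(z = matrix(0.4, 3, 3), weights = matrix(1, 3, 3),
                      locations = loc_df(xyz), scope = "subject"),
                 class = "ndp_model")
  diag(m$z) <- Inf
  full <- loc_df(rbind(xyz, matrix(runif(6, -50, 50), 2, 3)))
  ex <- rbf_expand(m, full, width_mm = 20)
  off <- upper.tri(ex$z)
  expect_equal(unname(ex$z[off]), rep(0.4, sum(off)), tolerance = 1e-9)
})

test_that("rbf expansion matches the brute-force double sum", {
  # 3 observed electrodes on a line, one target midway, width 20 mm
  obs_xyz <- cbind(c(0, 10, 40), 0, 0)
  tgt_xyz <- rbind(obs_xyz, c(25, 0, 0))
  set.seed(12)
  x <- matrix(rnorm(3 * 1024), 3)
  m <- subject_correlation_model(x, loc_df(obs_xyz))
  ex <- rbf_expand(m, loc_df(tgt_xyz), width_mm = 20)
  w <- function(a, i) exp(-sum((tgt_xyz[a, ] - obs_xyz[i, ])^2) / 20^2)
  # brute-force evaluation of the stated double sum for pair (4, 1)
  num <- 0; den <- 0
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      num <- num + w(4, i) * w(1, j) * m$z[i, j]
      den <- den + w(4, i) * w(1, j)
    }
  }
  expect_equal(ex$z[4, 1], num / den, tolerance = 1e-9)
  expect_equal(ex$weights[4, 1], den, tolerance = 1e-9)
})

test_that("population aggregation is a weighted mean of z entries", {
  xyz <- matrix(runif(6, -50, 50), 2, 3)
  mk <- function(z, w) {
    zz <- matrix(z, 2, 2); diag(zz) <- Inf
    structure(list(z = zz, weights = matrix(w, 2, 2),
                   locations = loc_df(xyz), scope = "subject"),
              class = "ndp_model")
  }
  pop <- aggregate_population_model(list(mk(0.2, 1), mk(0.6, 3)))
  expect_equal(pop$z[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(pop$weights[1, 2], 4)

  one <- aggregate_population_model(list(mk(0.3, 2)))
  expect_equal(one$z[1, 2], 0.3)

  # permutation invariance in subject order
  p1 <- aggregate_population_model(list(mk(0.1, 1), mk(0.5, 2), mk(0.9, 1)))
  p2 <- aggregate_population_model(list(mk(0.9, 1), mk(0.1, 1), mk(0.5, 2)))
  expect_equal(p1$z, p2$z)

  z0 <- mk(0.2, 0)
  expect_error(aggregate_population_model(list(z0)), "zero total weight")
})

test_that("kriging reconstruction matches the Gaussian conditional mean", {
  # known 4x4 covariance; reconstruct channel 4 from 1:3
  S <- matrix(c(1, .6, .3, .5,
                .6, 1, .2, .4,
                .3, .2, 1, .1,
                .5, .4, .1, 1), 4, 4)
  model <- structure(list(z = atanh(pmin(S, 1 - 1e-9)),
                          weights = matrix(1, 4, 4),
                          locations = loc_df(matrix(0, 4, 3)),
                          scope = "population"), class = "ndp_model")
  diag(model$z) <- Inf
  set.seed(13)
  L <- chol(S)
  y <- t(L) %*% matrix(rnorm(4 * 20000), 4)
  y_obs <- t(scale(t(y[1:3, ])))
  rec <- reconstruct_timeseries(model, y[1:3, ], 1:3, ridge = 0)
  oracle <- oracle_conditional_mean(S, y_obs, 1:3)
  expect_equal(rec$data[4, ], as.numeric(oracle), tolerance = 1e-9)
  # observed channels pass through (z-scored) unchanged
  expect_equal(rec$data[1:3, ], y_obs, ignore_attr = TRUE)
  # residual orthogonality: residuals uncorrelated with observations
  resid <- y[4, ] - mean(y[4, ])
  resid <- resid / stats::sd(resid) - rec$data[4, ]
  for (i in 1:3) expect_lt(abs(stats::cor(resid, y[i, ])), 0.05)
})

test_that("kriging degenerate cases behave as specified", {
  # unit correlation to a single observed electrode -> copy of it
  S <- diag(3); S[1, 3] <- S[3, 1] <- 1 - 1e-9
  model <- structure(list(z = fisher_z(S), weights = matrix(1, 3, 3),
                          locations = loc_df(matrix(0, 3, 3)),
                          scope = "population"), class = "ndp_model")
  diag(model$z) <- Inf
  set.seed(14)
  y <- matrix(rnorm(2 * 1000), 2)
  rec <- reconstruct_timeseries(model, y, 1:2)
  expect_equal(rec$data[3, ], rec$data[1, ], tolerance = 1e-4)
  # zero K_uo row -> prior mean (zero)
  S2 <- diag(3)
  model2 <- model; model2$z <- fisher_z(S2); diag(model2$z) <- Inf
  rec2 <- reconstruct_timeseries(model2, y, 1:2)
  expect_equal(max(abs(rec2$data[3, ])), 0)
})

test_that("held-out validation beats its shuffled null and guards leakage", {
  fx <- fixture_cohort()
  series <- lapply(fx$clean, `[[`, "data")
  v_true <- holdout_validate(series, fx$cohort$electrodes,
                             fx$full_locations, 20, shuffle = FALSE)
  v_null <- holdout_validate(series, fx$cohort$electrodes,
                             fx$full_locations, 20, shuffle = TRUE, seed = 2)
  expect_gt(v_true$mean_r, v_null$mean_r)
  expect_gt(v_true$mean_r, 0.2)
  expect_lt(abs(v_null$mean_r), 0.15)
  expect_equal(nrow(v_true$per_patient), 8)
  expect_true(all(abs(v_true$per_electrode$r) <= 1))
  # shuffle preserves the multiset of off-diagonal entries
  pop <- aggregate_population_model(fx$expanded)
  sh <- shuffle_model(pop, seed = 3)
  expect_equal(sort(sh$z[upper.tri(sh$z)]), sort(pop$z[upper.tri(pop$z)]))
  expect_true(isSymmetric(unname(sh$z)))
})
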