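test_that("louvain recovers disconnected cliques at the exhaustive optimum", {
  K <- two_clique_matrix(5)
  p <- louvain_partition(K, gamma = 1, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(adjusted_rand_index(p$assignment, rep(1:2, each = 5)), 1)
  oracle <- oracle_best_partition(K, gamma = 1)
  expect_equal(p$Q, oracle$Q, tolerance = 1e-12)
})

test_that("returned Q equals independent direct summation", {
  set.seed(20)
  K <- matrix(runif(144, -0.2, 1), 12); K <- (K + t(K)) / 2; diag(K) <- 1
  for (gm in c(0.7, 1, 1.6)) {
    p <- louvain_partition(K, gamma = gm, seed = 2)
    expect_equal(p$Q, oracle_modularity(K, p$assignment, gm),
                 tolerance = 1e-9)
  }
})

test_that("resolution limits: single module and all-singletons", {
  K <- matrix(0.5, 8, 8); diag(K) <- 0
  p_lo <- louvain_partition(K, gamma = 0.01, seed = 1)
  expect_equal(p_lo$n_modules, 1)
  p_hi <- louvain_partition(K, gamma = 50, seed = 1)
  expect_equal(p_hi$n_modules, 8)
  expect_error(louvain_partition(matrix(0, 4, 4), 1), "all-zero")
})

test_that("allegiance is exact on deterministic structure and bounded", {
  K <- two_clique_matrix(4)
  a <- allegiance(K, gamma = 1, n_runs = 10, seed = 1)
  lab <- rep(1:2, each = 4)
  same <- outer(lab, lab, "==")
  expect_true(all(a[same] == 1))
  expect_true(all(a[!same] == 0))
  set.seed(21)
  K2 <- matrix(runif(64), 8); K2 <- (K2 + t(K2)) / 2; diag(K2) <- 1
  a2 <- allegiance(K2, gamma = 1.2, n_runs = 5, seed = 2)
  expect_true(all(a2 >= 0 & a2 <= 1))
  expect_true(isSymmetric(a2))
  expect_true(all(diag(a2) == 1))
})

test_that("atlas similarity: identity, chance and closed-form tables", {
  assignment <- rep(1:4, each = 10)
  s <- atlas_similarity(assignment, assignment, n_perm = 200, seed = 1)
  expect_equal(s$similarity, 1)
  expect_true(s$significant)

  set.seed(22)
  rnd <- sample(1:4, 200, replace = TRUE)
  atl <- sample(letters[1:6], 200, replace = TRUE)
  s2 <- atlas_similarity(rnd, atl, n_perm = 200, seed = 2)
  expect_lt(abs(s2$similarity), 0.05)
  expect_false(s2$significant)

  # printed 2x2 contingency tables vs the closed form
  a <- rep(1:2, each = 10); b <- a
  expect_equal(adjusted_rand_index(a, b),
               oracle_ari_from_table(table(a, b)))
  expect_equal(adjusted_rand_index(a, b), 1)
  b2 <- rep(c(1, 2), 10)  # contingency [[5,5],[5,5]]
  expect_equal(adjusted_rand_index(a, b2),
               oracle_ari_from_table(table(a, b2)))
  # closed form for the all-5s table: (40 - 8100/190)/(90 - 8100/190)
  expect_equal(adjusted_rand_index(a, b2), -1 / 18, tolerance = 1e-12)
})

test_that("gamma sweep recovers a planted 6-block structure", {
  bm <- block_matrix(rep(5, 6), within = 0.8, between = 0.1)
  atlas <- paste0("R", bm$labels, rep(letters[1:2], 15))
  sw <- gamma_sweep(bm$K, seq(0.5, 2.1, by = 0.2), atlas, n_runs = 5,
                    n_restarts = 3, seed = 1)
  expect_equal(nrow(sw$table), length(seq(0.5, 2.1, by = 0.2)))
  expect_equal(sw$selected$n_modules, 6)
  expect_equal(adjusted_rand_index(sw$selected$assignment, bm$labels), 1)
})

test_that("gamma sweep warns when similarity is monotone", {
  K <- two_clique_matrix(5)
  atlas <- rep(c("a", "b"), each = 5)
  # with a fixed 2-module optimum everywhere similarity is flat;
  # flat curves have no strict interior peak
  expect_warning(gamma_sweep(K, c(0.8, 1.0, 1.2), atlas, n_runs = 2,
                             n_restarts = 2, seed = 1),
                 "no interior similarity peak")
})

test_that("participation coefficients follow the squared-share formula", {
  # node 9 connects evenly to 2 modules; bounded by 1 - 1/m
  K <- matrix(0, 9, 9)
  K[1:4, 1:4] <- 0.8; K[5:8, 5:8] <- 0.8; diag(K) <- 0
  K[9, c(1, 5)] <- K[c(1, 5), 9] <- 0.5
  assignment <- c(rep(1, 4), rep(2, 4), 1)
  pac <- participation_coefficients(K, assignment)
  expect_equal(unname(pac$y[9]), 0.5, tolerance = 1e-12)
  expect_equal(unname(pac$y[2]), 0, tolerance = 1e-12)  # all weight intramodular

  # even 4-way split -> 1 - 1/4
  K4 <- matrix(0, 9, 9)
  for (m in 0:3) K4[9, 2 * m + 1] <- K4[2 * m + 1, 9] <- 0.3
  K4[1:2, 1:2] <- K4[3:4, 3:4] <- K4[5:6, 5:6] <- K4[7:8, 7:8] <- 0.6
  diag(K4) <- 0
  asg4 <- c(rep(1:4, each = 2), 1)
  pac4 <- participation_coefficients(K4, asg4)
  expect_equal(unname(pac4$y[9]), 0.75, tolerance = 1e-12)

  # conservation and bounds on a random matrix
  set.seed(23)
  Kr <- matrix(runif(100), 10); Kr <- (Kr + t(Kr)) / 2; diag(Kr) <- 1
  asg <- sample(1:3, 10, replace = TRUE)
  while (length(unique(asg)) < 3) asg <- sample(1:3, 10, replace = TRUE)
  pr <- participation_coefficients(Kr, asg)
  expect_equal(unname(rowSums(pr$k_module)), unname(pr$k_total),
               tolerance = 1e-12)
  expect_true(all(pr$y >= 0 & pr$y <= 1 - 1/3 + 1e-12))
})

test_that("hub weights score regions by N^2 / T with tail selection", {
  set.seed(24)
  n <- 40
  bm <- block_matrix(c(20, 20), within = 0.8, between = 0.1)
  asg <- bm$labels
  pac <- participation_coefficients(bm$K, asg)
  regions <- rep(c("A", "B", "C", "D"), each = 10)
  coords <- matrix(rnorm(n * 3), n, 3)
  hw <- hub_weights(pac, asg, regions, coords, tail = 0.25)
  expect_true(all(hw$hub_weight >= 0))
  expect_true(all(hw$hub_kind %in% c("provincial", "connector")))
  # weight formula check against a row's own counts
  expect_equal(hw$hub_weight, hw$n_selected^2 / hw$n_region_total)
  # hub coordinate is the mean of contributing electrodes
  coords2 <- rbind(c(0, 0, 0), c(2, 2, 2))
  pac2 <- list(y = c(0.1, 0.1), k_module = matrix(1, 2, 1),
               k_total = c(1, 1))
  hw2 <- hub_weights(pac2, c(1, 1), c("A", "A"), coords2,
                     tail = 0.5, min_electrodes = 2,
                     small_module_frac = 0)
  prov <- hw2[hw2$hub_kind == "provincial" & hw2$n_selected == 2, ]
  expect_equal(unname(unlist(prov[, c("x_mm", "y_mm", "z_mm")])),
               c(1, 1, 1))
})
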