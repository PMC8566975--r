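# Shared fixtures, built once per test run. Sizes are desk-scale: small
# enough that the whole suite stays inside its runtime budget, large
# enough that the statistical assertions are stable.

# Small cohort + expanded subject models + population model used by the
# brain-model, parcellation and pipeline-adjacent tests.
ndp_fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (!is.null(ndp_fixture_env$cohort)) return(ndp_fixture_env$cohort)
  cfg <- synthetic_config(n_subjects = 8, n_global_electrodes = 24,
                          n_modules = 6, electrodes_per_subject = c(10, 14),
                          duration = 60, artifact_rate = 0, rng_seed = 42)
  co <- generate_cohort(cfg)
  clean <- lapply(names(co$recordings), function(sid)
    preprocess_subject(co$recordings[[sid]], co$fs, subject_id = sid))
  names(clean) <- names(co$recordings)
  fl <- co$electrodes[!duplicated(co$electrodes$global_id), ]
  fl <- fl[order(fl$global_id), ]
  expanded <- lapply(names(clean), function(sid) {
    loc <- co$electrodes[co$electrodes$subject_id == sid, ]
    rbf_expand(subject_correlation_model(clean[[sid]]$data, loc), fl, 20)
  })
  names(expanded) <- names(clean)
  pop <- aggregate_population_model(expanded)
  K <- tanh(pop$z); diag(K) <- 1
  ndp_fixture_env$cohort <- list(cohort = co, clean = clean,
                                 full_locations = fl, expanded = expanded,
                                 population = pop, K = K)
  ndp_fixture_env$cohort
}

# Two disjoint weighted cliques (clique_size nodes each, weight w).
two_clique_matrix <- function(clique_size = 5, w = 1) {
  n <- 2 * clique_size
  K <- matrix(0, n, n)
  K[seq_len(clique_size), seq_len(clique_size)] <- w
  K[(clique_size + 1):n, (clique_size + 1):n] <- w
  diag(K) <- 0
  K
}

# Planted block correlation matrix (exact, noiseless).
block_matrix <- function(sizes, within = 0.8, between = 0.1) {
  lab <- rep(seq_along(sizes), sizes)
  K <- matrix(between, sum(sizes), sum(sizes))
  for (m in seq_along(sizes)) K[lab == m, lab == m] <- within
  diag(K) <- 1
  list(K = K, labels = lab)
}

# Small fixture graphs (n <= 8) for the Louvain-vs-exhaustive oracle.
fixture_graphs <- function() {
  set.seed(99)
  r1 <- matrix(runif(49), 7); r1 <- (r1 + t(r1)) / 2; diag(r1) <- 0
  r2 <- matrix(runif(64), 8); r2 <- (r2 + t(r2)) / 2; diag(r2) <- 0
  ring <- matrix(0, 8, 8)
  for (i in 1:8) { j <- i %% 8 + 1; ring[i, j] <- ring[j, i] <- 1 }
  star <- matrix(0, 7, 7); star[1, 2:7] <- star[2:7, 1] <- 1
  list(two_cliques_4 = two_clique_matrix(4),
       random_7 = r1, random_8 = r2, ring_8 = ring, star_7 = star)
}
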