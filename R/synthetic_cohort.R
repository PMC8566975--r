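# Synthetic multi-subject iEEG cohort with planted ground truth.
#
# The generator emulates the structure the analysis chain is designed to
# recover: a global electrode set in a common (MNI-like) coordinate space,
# partial per-subject coverage, a latent block (module) correlation
# structure shared across subjects, band-limited oscillatory power whose
# group differences follow two planted network expression patterns (NEPs),
# group-specific module-pair connectivity shifts, and sparse high-amplitude
# artifact transients for kurtosis screening.
#
# Mixing model (closed form, so correlation targets are exact in
# expectation): electrode i of a subject in group g is
#   x_i(t) = sqrt(w_i^g) * z_{m(i)}(t) + sqrt(1 - w_i^g) * e_i(t)
# with unit-variance module latents z_m whose cross-module correlation
# S_pq^g = (between + inter_shift_pq^g) / sqrt(Wbar_p^g Wbar_q^g), and
# unit-variance private components e_i carrying the band-limited
# oscillators. Then corr(x_i, x_j) = sqrt(w_i w_j) within a module and
# sqrt(w_i w_j) S_pq between modules p and q.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the desk-scale stated world used throughout the test
#' suite: 20 subjects drawn from a 40-electrode global set (15-25 electrodes
#' each), 6 latent modules, 120 s at 512 Hz, within-module correlation 0.8
#' and between-module correlation 0.1.
#'
#' @param n_subjects number of subjects.
#' @param n_global_electrodes size of the global electrode set.
#' @param n_modules number of planted functional modules.
#' @param electrodes_per_subject length-2 integer range of per-subject
#'   electrode counts (sampled uniformly).
#' @param sampling_rate sampling rate in Hz (>= 512).
#' @param duration recording length in seconds.
#' @param within_module_correlation,between_module_correlation target
#'   inter-electrode correlations inside / across modules; must satisfy
#'   `within > between >= 0`.
#' @param loading_jitter_sd SD of per-electrode jitter on the within-module
#'   loading; gives module blocks realistic edge-weight heterogeneity.
#' @param band_amplitudes named amplitude of each oscillator band in the
#'   private component (delta..gammaH); the broadband floor has amplitude
#'   `noise_sd`.
#' @param noise_sd amplitude of the broadband (pink) private noise.
#' @param effect_strength fractional amplitude change applied by the
#'   planted NEP band effects (0.5 means +/-50% amplitude).
#' @param connectivity_shift additive correlation shift magnitude used by
#'   the planted group contrasts.
#' @param prop_depressed proportion of (non-boundary) subjects in the
#'   depressed group; default mirrors a 23:18 depressed:control mixture.
#' @param nep_proportions length-3 numeric (NEP1, NEP2, mixed) mixture of
#'   depressed subjects.
#' @param n_boundary number of extra boundary subjects (PHQ-9 6-9),
#'   excluded from the two groups.
#' @param artifact_rate probability that a subject receives one spike
#'   artifact block.
#' @param rng_seed integer seed; the whole cohort is a deterministic
#'   function of the config.
#' @return A list of class `ndp_config`.
#' @export
synthetic_config <- function(n_subjects = 20,
                             n_global_electrodes = 40,
                             n_modules = 6,
                             electrodes_per_subject = c(15, 25),
                             sampling_rate = 512,
                             duration = 120,
                             within_module_correlation = 0.8,
                             between_module_correlation = 0.1,
                             loading_jitter_sd = 0.04,
                             band_amplitudes = c(delta = 1.0, theta = 0.8,
                                                 alpha = 0.7, beta = 0.5,
                                                 gammaL = 0.3, gammaH = 0.2),
                             noise_sd = 1.0,
                             effect_strength = 0.5,
                             connectivity_shift = 0.12,
                             prop_depressed = 23 / 41,
                             nep_proportions = c(0.4, 0.5, 0.1),
                             n_boundary = 0,
                             artifact_rate = 0.3,
                             rng_seed = 1L) {
  cfg <- list(n_subjects = n_subjects,
              n_global_electrodes = n_global_electrodes,
              n_modules = n_modules,
              electrodes_per_subject = electrodes_per_subject,
              sampling_rate = sampling_rate,
              duration = duration,
              within_module_correlation = within_module_correlation,
              between_module_correlation = between_module_correlation,
              loading_jitter_sd = loading_jitter_sd,
              band_amplitudes = band_amplitudes,
              noise_sd = noise_sd,
              effect_strength = effect_strength,
              connectivity_shift = connectivity_shift,
              prop_depressed = prop_depressed,
              nep_proportions = nep_proportions,
              n_boundary = n_boundary,
              artifact_rate = artifact_rate,
              rng_seed = rng_seed)
  class(cfg) <- "ndp_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (!(within_module_correlation > between_module_correlation &&
          between_module_correlation >= 0)) {
      stop("require within_module_correlation > between_module_correlation >= 0")
    }
    if (sampling_rate < 512) stop("sampling_rate must be >= 512 Hz")
    if (max(electrodes_per_subject) > n_global_electrodes) {
      stop("electrodes_per_subject exceeds n_global_electrodes")
    }
    if (n_modules < 2 || n_modules > n_global_electrodes) {
      stop("n_modules must be in [2, n_global_electrodes]")
    }
    if (duration < 1) stop("duration must be >= 1 s")
  })
  invisible(cfg)
}

# ---- spectral building blocks -------------------------------------------

# Unit-variance pink (1/f power) noise of length n at rate fs.
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  amp <- ifelse(f < 1, 1, 1 / sqrt(f))
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  as.numeric(scale(y))
}

# Unit-variance band-limited Gaussian noise in [f1, f2] Hz.
band_noise <- function(n, fs, f1, f2) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= f1 & f <= f2
  y <- Re(stats::fft(X * keep, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("empty band [", f1, ", ", f2, "] at fs=", fs)
  (y - mean(y)) / s
}

# Canonical 6-band scheme used throughout the package.
#' Frequency band scheme (delta..gammaH)
#'
#' The canonical six non-overlapping bands: delta 1-4, theta 5-8,
#' alpha 9-12, beta 13-30, low gamma 31-70, high gamma 71-150 Hz.
#' The 4-5 Hz (etc.) gaps between integer band edges are intentional.
#'
#' @return data.frame with columns band, f_lo, f_hi.
#' @export
band_scheme <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gammaL", "gammaH"),
             f_lo = c(1, 5, 9, 13, 31, 71),
             f_hi = c(4, 8, 12, 30, 70, 150),
             stringsAsFactors = FALSE)
}

# ---- planted effect maps -------------------------------------------------

# Planted NEP band-effect definitions: multiplicative amplitude effects on
# (band, module) cells, one pattern per NEP. Modules are 1-based.
default_nep_effects <- function(effect_strength, n_modules) {
  e <- effect_strength
  m2 <- min(2, n_modules); m4 <- min(4, n_modules)
  m1 <- 1; m3 <- min(3, n_modules)
  nep1 <- data.frame(band = c("beta", "alpha", "alpha", "delta"),
                     module = c(m2, m2, m4, m2),
                     multiplier = c(1 + e, 1 + e, 1 + e, 1 - e / 2))
  nep2 <- data.frame(band = c("theta", "theta", "alpha", "alpha",
                              "delta", "delta"),
                     module = c(m1, m3, m1, m3, m1, m3),
                     multiplier = c(1 - e, 1 - e, 1 - e, 1 - e,
                                    1 + e, 1 + e))
  list(NEP1 = nep1, NEP2 = nep2)
}

# Planted group connectivity shifts (depressed - control), mirroring the
# qualitative pattern of interest: frontal (modules 1,3) intramodular
# hyperconnectivity, occipitotemporal/frontotemporal (2,4) intramodular
# hypoconnectivity, increased 1-3 and decreased 2-4 intermodular coupling.
default_connectivity_shifts <- function(shift, n_modules) {
  m <- function(k) min(k, n_modules)
  df <- data.frame(module_a = c(1, m(3), m(2), m(4), 1, m(2)),
                   module_b = c(1, m(3), m(2), m(4), m(3), m(4)),
                   shift = c(shift, shift, -shift, -shift,
                             shift * 0.8, -shift * 0.7))
  df[!duplicated(df[, c("module_a", "module_b")]), ]
}

# ---- generator -----------------------------------------------------------

#' Generate a synthetic multi-subject iEEG cohort
#'
#' Returns recordings (channels x samples, microvolts), an electrode table,
#' subject metadata (PHQ-9), and the full planted ground truth. The output
#' is a deterministic function of `config` (including its `rng_seed`).
#'
#' @param config an [synthetic_config()] object.
#' @return A list of class `ndp_cohort` with elements `recordings` (named
#'   list of channels x samples matrices with electrode-id rownames),
#'   `fs`, `electrodes` (data.frame: subject_id, electrode_id, global_id,
#'   x_mm, y_mm, z_mm, region_label), `subjects` (data.frame: subject_id,
#'   phq9, group), `ground_truth` and `config`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$rng_seed)
  G <- config$n_global_electrodes
  M <- config$n_modules
  fs <- config$sampling_rate
  n_samp <- round(config$duration * fs)
  bands <- band_scheme()

  # global electrode geometry: module centroids at well-separated
  # positions in a 140x180x120 mm box (anatomical modules occupy distinct
  # territories; coincident centroids would defeat the RBF expansion's
  # spatial signal), electrodes scattered around their module centroid
  corners <- cbind(rep(c(-45, 45), 4),
                   rep(c(-60, -60, 60, 60), 2),
                   rep(c(-40, 40), each = 4))
  if (M > nrow(corners)) stop("at most ", nrow(corners), " modules supported")
  centroids <- corners[seq_len(M), , drop = FALSE] +
    matrix(stats::rnorm(M * 3, sd = 8), M, 3)
  module_labels <- rep(seq_len(M), length.out = G)
  module_labels <- sort(module_labels)
  coords <- centroids[module_labels, , drop = FALSE] +
    matrix(stats::rnorm(G * 3, sd = 15), G, 3)
  global_ids <- sprintf("E%02d", seq_len(G))
  # atlas-like region labels: refine each module into groups of <= 4
  region_label <- character(G)
  for (m in seq_len(M)) {
    idx <- which(module_labels == m)
    region_label[idx] <- sprintf("R%d%s", m, letters[((seq_along(idx) - 1) %/% 4) + 1])
  }

  # per-electrode within-module loading jitter (shared across groups)
  jitter <- stats::rnorm(G, sd = config$loading_jitter_sd)

  # subjects, groups, PHQ-9
  n_core <- config$n_subjects
  n_dep <- round(n_core * config$prop_depressed)
  n_ctl <- n_core - n_dep
  if (n_dep < 2 || n_ctl < 2) stop("need >= 2 subjects per group")
  group <- c(rep("depressed", n_dep), rep("control", n_ctl),
             rep("boundary", config$n_boundary))
  n_total <- length(group)
  subject_ids <- sprintf("S%02d", seq_len(n_total))
  phq9 <- integer(n_total)
  phq9[group == "depressed"] <- sample(10:24, n_dep, replace = TRUE)
  phq9[group == "control"] <- sample(0:5, n_ctl, replace = TRUE)
  phq9[group == "boundary"] <- sample(6:9, config$n_boundary, replace = TRUE)

  # NEP assignment for depressed subjects
  nep_assignment <- rep(NA_character_, n_total)
  pp <- config$nep_proportions / sum(config$nep_proportions)
  nep_assignment[group == "depressed"] <-
    sample(c("NEP1", "NEP2", "mixed"), n_dep, replace = TRUE, prob = pp)

  nep_effects <- default_nep_effects(config$effect_strength, M)
  conn_shifts <- default_connectivity_shifts(config$connectivity_shift, M)

  # group-specific correlation targets at module-block level
  rho_w <- config$within_module_correlation
  rho_b <- config$between_module_correlation
  block_target <- function(grp) {
    W <- rep(rho_w, M)                      # within-module diagonal
    B <- matrix(rho_b, M, M)
    if (grp == "depressed") {
      for (k in seq_len(nrow(conn_shifts))) {
        a <- conn_shifts$module_a[k]; b <- conn_shifts$module_b[k]
        s <- conn_shifts$shift[k]
        if (a == b) W[a] <- W[a] + s else {
          B[a, b] <- B[a, b] + s; B[b, a] <- B[b, a] + s
        }
      }
    }
    if (any(W >= 1 | W <= 0)) stop("intramodular shift leaves correlation outside (0,1)")
    if (any(abs(B) >= 1)) stop("intermodular shift leaves correlation outside (-1,1)")
    list(W = W, B = B)
  }
  targets <- list(depressed = block_target("depressed"),
                  control = block_target("control"),
                  boundary = block_target("control"))

  # latent correlation matrices S_g with unit diagonal, plus chol factors
  chol_factors <- lapply(targets, function(tg) {
    S <- tg$B / sqrt(outer(tg$W, tg$W))
    diag(S) <- 1
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) stop("latent module correlation matrix not positive definite")
    t(chol(S))
  })

  # per-subject electrode coverage
  epsr <- config$electrodes_per_subject
  coverage <- lapply(seq_len(n_total), function(s) {
    k <- if (epsr[1] == epsr[2]) epsr[1] else sample(epsr[1]:epsr[2], 1)
    sort(sample(G, k))
  })

  # artifact schedule: (subject, channel, block) single-sample spikes
  n_blocks <- floor(config$duration / 60)
  artifact_schedule <- list()
  if (n_blocks >= 1 && config$artifact_rate > 0) {
    for (s in seq_len(n_total)) {
      if (stats::runif(1) < config$artifact_rate) {
        artifact_schedule[[length(artifact_schedule) + 1]] <-
          list(subject = subject_ids[s],
               channel = sample(length(coverage[[s]]), 1),
               block = sample(n_blocks, 1))
      }
    }
  }

  # band-effect map realized per subject: amplitude multiplier per
  # (band, module); controls and boundary get all-ones
  subject_multiplier <- function(s) {
    mult <- matrix(1, nrow(bands), M, dimnames = list(bands$band, NULL))
    if (group[s] == "depressed") {
      pats <- switch(nep_assignment[s],
                     NEP1 = list(list(eff = nep_effects$NEP1, w = 1)),
                     NEP2 = list(list(eff = nep_effects$NEP2, w = 1)),
                     mixed = list(list(eff = nep_effects$NEP1, w = 0.5),
                                  list(eff = nep_effects$NEP2, w = 0.5)))
      for (p in pats) {
        for (k in seq_len(nrow(p$eff))) {
          b <- p$eff$band[k]; m <- p$eff$module[k]
          mult[b, m] <- mult[b, m] * (1 + p$w * (p$eff$multiplier[k] - 1))
        }
      }
    }
    mult
  }

  amp <- config$band_amplitudes[bands$band]
  recordings <- vector("list", n_total)
  names(recordings) <- subject_ids
  for (s in seq_len(n_total)) {
    grp <- group[s]
    tg <- targets[[grp]]
    L <- chol_factors[[grp]]
    obs <- coverage[[s]]
    mult <- subject_multiplier(s)

    # module latents: pink broadband sources mixed to correlation S_g
    U <- vapply(seq_len(M), function(m) pink_noise(n_samp, fs),
                numeric(n_samp))
    Z <- U %*% t(L)

    X <- matrix(0, length(obs), n_samp)
    for (ci in seq_along(obs)) {
      gidx <- obs[ci]
      m <- module_labels[gidx]
      w <- min(max(tg$W[m] + jitter[gidx], 0.05), 0.95)
      # private component: band oscillators (NEP-modulated) + pink floor
      a_b <- amp * mult[, m]
      priv <- config$noise_sd * pink_noise(n_samp, fs)
      for (b in seq_len(nrow(bands))) {
        if (a_b[b] > 0) {
          priv <- priv + a_b[b] *
            band_noise(n_samp, fs, bands$f_lo[b], bands$f_hi[b])
        }
      }
      priv <- priv / sqrt(sum(a_b^2) + config$noise_sd^2)
      X[ci, ] <- sqrt(w) * Z[, m] + sqrt(1 - w) * priv
    }
    X <- X * 50  # microvolt scale
    # artifacts: 20x-SD bursts of 8 samples (~16 ms at 512 Hz, the width
    # of a typical interictal spike). A single-sample deflection would
    # only raise the Pearson kurtosis of a 60 s block to ~3 + 20^4/30720
    # ~ 8.2, below the screening threshold of 10; the burst gives ~45.
    for (a in artifact_schedule) {
      if (a$subject == subject_ids[s]) {
        t0 <- (a$block - 1) * 60 * fs + sample(60 * fs - 8, 1)
        idx <- t0:(t0 + 7)
        X[a$channel, idx] <- X[a$channel, idx] + 20 * stats::sd(X[a$channel, ])
      }
    }
    rownames(X) <- global_ids[obs]
    recordings[[s]] <- X
  }

  electrodes <- do.call(rbind, lapply(seq_len(n_total), function(s) {
    obs <- coverage[[s]]
    data.frame(subject_id = subject_ids[s],
               electrode_id = global_ids[obs],
               global_id = obs,
               x_mm = coords[obs, 1], y_mm = coords[obs, 2],
               z_mm = coords[obs, 3],
               region_label = region_label[obs],
               stringsAsFactors = FALSE)
  }))

  subjects <- data.frame(subject_id = subject_ids, phq9 = phq9,
                         group = group, stringsAsFactors = FALSE)
  stopifnot(all((subjects$group == "depressed") == (subjects$phq9 >= 10)),
            all((subjects$group == "control") == (subjects$phq9 <= 5)))

  band_effect_map <- do.call(rbind, lapply(c("NEP1", "NEP2"), function(np) {
    df <- nep_effects[[np]]
    df$nep <- np
    df$group <- "depressed"
    df
  }))

  ground_truth <- list(
    module_labels = module_labels,
    global_ids = global_ids,
    coords = coords,
    region_label = region_label,
    group_label = stats::setNames(group, subject_ids),
    phq9_score = stats::setNames(phq9, subject_ids),
    nep_assignment = stats::setNames(nep_assignment, subject_ids),
    band_effect_map = band_effect_map,
    connectivity_shift_map = conn_shifts,
    artifact_schedule = artifact_schedule,
    block_targets = targets,
    loading_jitter = jitter)

  structure(list(recordings = recordings, fs = fs, electrodes = electrodes,
                 subjects = subjects, ground_truth = ground_truth,
                 config = config, start_time = "08:00:00"),
            class = "ndp_cohort")
}

#' @export
print.ndp_cohort <- function(x, ...) {
  cat("Synthetic iEEG cohort:", length(x$recordings), "subjects,",
      x$config$n_global_electrodes, "global electrodes,",
      x$config$n_modules, "modules,", x$config$duration, "s at",
      x$fs, "Hz\n")
  print(table(x$subjects$group))
  invisible(x)
}

# ---- feature-level simulator (desk-scale classifier world) ---------------

#' Simulate a z-scored spectral-spatial feature matrix directly
#'
#' Bypasses signal generation: draws a subjects x (6 bands x n_modules)
#' feature matrix with standard-normal baseline and additive planted NEP
#' effects on the depressed subjects, in feature (z-score) units. Used for
#' classifier-scale experiments where the full signal pipeline is not the
#' object under test.
#'
#' @param n_subjects number of subjects (balanced groups by default).
#' @param n_modules number of modules (6 gives the canonical 36 features).
#' @param effect_size additive shift, in SD units, applied to a subject's
#'   active NEP features.
#' @param prop_depressed proportion of depressed subjects.
#' @param nep_proportions mixture (NEP1, NEP2, mixed) among depressed.
#' @param seed integer seed.
#' @return list with `features` (matrix with band_module colnames),
#'   `labels` (factor control/depressed), `nep_assignment`, and
#'   `nep_features` (named list of signed feature index vectors).
#' @export
simulate_feature_matrix <- function(n_subjects = 40, n_modules = 6,
                                    effect_size = 1.5,
                                    prop_depressed = 0.5,
                                    nep_proportions = c(0.4, 0.5, 0.1),
                                    seed = 1L) {
  set.seed(seed)
  bands <- band_scheme()$band
  feat_names <- as.vector(outer(bands, seq_len(n_modules),
                                function(b, m) paste0(b, "_m", m)))
  p <- length(feat_names)
  n_dep <- round(n_subjects * prop_depressed)
  n_ctl <- n_subjects - n_dep
  labels <- factor(c(rep("depressed", n_dep), rep("control", n_ctl)),
                   levels = c("control", "depressed"))
  x <- matrix(stats::rnorm(n_subjects * p), n_subjects, p,
              dimnames = list(sprintf("S%02d", seq_len(n_subjects)),
                              feat_names))
  effs <- default_nep_effects(1, n_modules)
  signed_idx <- function(df) {
    idx <- match(paste0(df$band, "_m", df$module), feat_names)
    stats::setNames(sign(df$multiplier - 1), feat_names[idx])
  }
  nep_features <- lapply(effs, signed_idx)
  pp <- nep_proportions / sum(nep_proportions)
  nep_assignment <- rep(NA_character_, n_subjects)
  nep_assignment[seq_len(n_dep)] <-
    sample(c("NEP1", "NEP2", "mixed"), n_dep, replace = TRUE, prob = pp)
  for (s in seq_len(n_dep)) {
    pats <- switch(nep_assignment[s],
                   NEP1 = list(c("NEP1", 1)), NEP2 = list(c("NEP2", 1)),
                   mixed = list(c("NEP1", 0.5), c("NEP2", 0.5)))
    for (pt in pats) {
      sgn <- nep_features[[pt[1]]]
      w <- as.numeric(pt[2])
      x[s, names(sgn)] <- x[s, names(sgn)] + w * effect_size * sgn
    }
  }
  # z-score across subjects, as the real feature stage guarantees
  x <- zscore_cols(x, "feature")
  list(features = x, labels = labels,
       nep_assignment = stats::setNames(nep_assignment, rownames(x)),
       nep_features = nep_features)
}
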