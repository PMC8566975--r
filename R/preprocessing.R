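# Cleaning of raw recordings: 2-250 Hz band-pass, line-noise notches at
# 60/120/180/240 Hz, resampling to 512 Hz, common average referencing;
# then 60 s segmentation with kurtosis artifact screening and random
# sampling of daytime blocks.
#
# No IIR-design library is available in the target environment, so the
# zero-phase filters are applied in the frequency domain using the exact
# squared-magnitude response of the nominal designs (4th-order Butterworth
# band-pass, 2nd-order Q=30 notches). Forward-backward (filtfilt)
# application of an IIR filter IS a zero-phase filter with response
# |H(f)|^2; applying |H(f)|^2 directly on a reflection-padded signal gives
# the same steady-state result without the transient.

# |H(f)|^2 of an order-n Butterworth band-pass (single pass), evaluated
# at frequencies f (Hz).
butter_bp_mag2 <- function(f, f1, f2, order = 4) {
  w <- 2 * pi * f
  w1 <- 2 * pi * f1; w2 <- 2 * pi * f2
  w0sq <- w1 * w2; B <- w2 - w1
  ratio <- ifelse(w == 0, Inf, (w^2 - w0sq) / (B * w))
  1 / (1 + ratio^(2 * order))
}

# |H(f)|^2 of a second-order notch at f0 with quality factor Q.
notch_mag2 <- function(f, f0, Q = 30) {
  w <- 2 * pi * f
  w0 <- 2 * pi * f0
  num <- (w^2 - w0^2)^2
  num / (num + (w0 * w / Q)^2)
}

# Zero-phase filtering of one channel by a gain curve, with reflection
# padding against circular edge effects.
apply_fft_gain <- function(x, fs, gain_fun) {
  n <- length(x)
  pad <- min(n, as.integer(fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1, n)]))
  np <- length(xp)
  f <- c(0, seq_len(np - 1)) * fs / np
  f <- pmin(f, fs - f)
  g <- gain_fun(f)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / np
  y[seq(pad + 1, pad + n)]
}

# Exact band-limited (Fourier) resampling to n_out samples.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nh <- min(n, n_out)
  keep <- floor((nh - 1) / 2)
  Y[1] <- X[1]
  if (keep > 0) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
  }
  if (nh %% 2 == 0) {
    # split the Nyquist bin symmetrically
    ny <- nh / 2 + 1
    if (n_out < n) Y[ny] <- X[ny] + Conj(X[ny]) else {
      Y[ny] <- X[ny] / 2
      Y[n_out - nh / 2 + 1] <- Conj(X[ny]) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Band-pass, notch, resample and re-reference a raw recording
#'
#' Applies (zero-phase) a 2-250 Hz band-pass and notches at 60, 120, 180
#' and 240 Hz, resamples to 512 Hz, and common-average references
#' (subtracts the per-sample mean over all channels).
#'
#' @param raw channels x samples numeric matrix (microvolts); rownames are
#'   electrode ids.
#' @param fs sampling rate of `raw` in Hz (>= 512).
#' @param subject_id optional id carried through.
#' @param start_time wall-clock start, "HH:MM:SS" (used by the daytime
#'   sampler downstream).
#' @param band,notches,notch_q filter parameters; defaults are the
#'   standard iEEG choices.
#' @return A `ndp_clean` list: `data` (channels x samples at 512 Hz),
#'   `fs = 512`, `provenance` (character log), `subject_id`, `start_time`.
#' @export
filter_and_reference <- function(raw, fs, subject_id = NULL,
                                 start_time = "08:00:00",
                                 band = c(2, 250),
                                 notches = c(60, 120, 180, 240),
                                 notch_q = 30) {
  if (!is.matrix(raw) || nrow(raw) < 2) {
    stop("need >= 2 channels (common average reference undefined)")
  }
  if (fs < 512) stop("sampling rate ", fs, " < 512 Hz")
  notches <- notches[notches < fs / 2]
  gain <- function(f) {
    g <- butter_bp_mag2(f, band[1], band[2])
    for (f0 in notches) g <- g * notch_mag2(f, f0, notch_q)
    g
  }
  filtered <- t(apply(raw, 1, apply_fft_gain, fs = fs, gain_fun = gain))
  n_out <- round(ncol(raw) * 512 / fs)
  if (fs != 512) {
    filtered <- t(apply(filtered, 1, resample_fft, n_out = n_out))
  }
  # common average reference
  filtered <- sweep(filtered, 2, colMeans(filtered), "-")
  rownames(filtered) <- rownames(raw)
  structure(list(data = filtered, fs = 512,
                 provenance = c(sprintf("bandpass %g-%g Hz (zero-phase butterworth^2, order 4)",
                                        band[1], band[2]),
                                sprintf("notch %s Hz (Q=%g)",
                                        paste(notches, collapse = "/"), notch_q),
                                sprintf("resample %g -> 512 Hz (fourier)", fs),
                                "common average reference"),
                 subject_id = subject_id, start_time = start_time),
            class = "ndp_clean")
}

# Pearson kurtosis (not excess): m4 / m2^2, population moments.
kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2
}

#' Segment into 60 s blocks and screen by kurtosis
#'
#' Splits the cleaned recording into non-overlapping blocks (partial
#' trailing block dropped) and retains blocks whose maximum per-channel
#' Pearson kurtosis is at most `kurtosis_max`. Retained blocks are exact
#' slices of the input, in order.
#'
#' @param clean a `ndp_clean` object.
#' @param block_s block length in seconds (60).
#' @param kurtosis_max rejection threshold (Pearson kurtosis; Gaussian
#'   noise is ~3, a sinusoid 1.5, spike-contaminated blocks >> 10).
#' @return list with `blocks` (list of channels x samples matrices),
#'   `start_s` (block starts in seconds from recording start),
#'   `time_of_day_s` (seconds after midnight), `kurtosis` (per-block max).
#' @export
segment_and_kurtosis_filter <- function(clean, block_s = 60,
                                        kurtosis_max = 10) {
  x <- clean$data
  fs <- clean$fs
  spb <- round(block_s * fs)
  n_blocks <- floor(ncol(x) / spb)
  if (n_blocks < 1) stop("recording shorter than one ", block_s, " s block")
  t0 <- to_seconds_of_day(clean$start_time %||% "08:00:00")
  kmax <- numeric(n_blocks)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- seq((b - 1) * spb + 1, b * spb)
    blk <- x[, idx, drop = FALSE]
    kmax[b] <- max(apply(blk, 1, kurtosis))
    blocks[[b]] <- blk
  }
  keep <- which(kmax <= kurtosis_max)
  if (length(keep) == 0) {
    stop("no usable data: all ", n_blocks,
         " blocks exceeded kurtosis threshold ", kurtosis_max)
  }
  list(blocks = blocks[keep],
       start_s = (keep - 1) * block_s,
       time_of_day_s = t0 + (keep - 1) * block_s,
       kurtosis = kmax[keep])
}

to_seconds_of_day <- function(hms) {
  p <- as.numeric(strsplit(hms, ":")[[1]])
  sum(p * c(3600, 60, 1)[seq_along(p)])
}

#' Randomly sample daytime blocks and concatenate
#'
#' Uniform sampling without replacement of exactly `target_hours * 60`
#' one-minute blocks among those timestamped between 08:00 and 22:00,
#' concatenated in chronological order. Deterministic given `seed`.
#'
#' @param segmented output of [segment_and_kurtosis_filter()].
#' @param target_hours hours of data to assemble (2 gives 120 blocks).
#' @param seed integer seed.
#' @param day_window numeric length-2, seconds after midnight defining
#'   daytime (default 08:00-22:00).
#' @return list with `data` (channels x samples), `selected` (indices into
#'   the retained-block list, chronological).
#' @export
sample_daytime_blocks <- function(segmented, target_hours = 2, seed = 1L,
                                  day_window = c(8, 22) * 3600) {
  need <- round(target_hours * 60)
  day <- which(segmented$time_of_day_s >= day_window[1] &
               segmented$time_of_day_s < day_window[2])
  if (length(day) < need) {
    stop("insufficient daytime blocks: ", length(day), " < ", need)
  }
  set.seed(seed)
  pick <- sort(sample(day, need))
  list(data = do.call(cbind, segmented$blocks[pick]), selected = pick)
}

#' One-call preprocessing of a raw recording
#'
#' Filter + re-reference, kurtosis-screen 60 s blocks, and concatenate
#' either all retained blocks (`target_hours = NULL`, the desk-scale
#' default) or a random daytime sample of the requested length.
#'
#' @inheritParams filter_and_reference
#' @inheritParams segment_and_kurtosis_filter
#' @param target_hours hours to sample (NULL = keep all retained blocks).
#' @param seed seed for the daytime sampler.
#' @return `ndp_clean` whose `data` holds the concatenated retained blocks.
#' @export
preprocess_subject <- function(raw, fs, subject_id = NULL,
                               start_time = "08:00:00",
                               kurtosis_max = 10, block_s = 60,
                               target_hours = NULL, seed = 1L) {
  clean <- filter_and_reference(raw, fs, subject_id, start_time)
  seg <- segment_and_kurtosis_filter(clean, block_s, kurtosis_max)
  if (is.null(target_hours)) {
    dat <- do.call(cbind, seg$blocks)
    sel <- seq_along(seg$blocks)
  } else {
    smp <- sample_daytime_blocks(seg, target_hours, seed)
    dat <- smp$data; sel <- smp$selected
  }
  clean$data <- dat
  clean$provenance <- c(clean$provenance,
                        sprintf("kurtosis screen (max %g): kept %d blocks",
                                kurtosis_max, length(sel)))
  clean$retained_blocks <- seg$start_s[sel]
  clean
}
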