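# Per-window feature extraction for each physiological indicator, attribute
# encoding, and assembly of the fused feature matrices.
#
# Window statistics use the population standard deviation (divide by n);
# heart-rate-variability statistics follow the HRV convention (SDNN divides
# by n-1). Every degenerate case (flat signal, too few beats) maps to zeros
# plus a flag rather than NaN.

#' Basic window statistics
#'
#' @param x numeric vector (length >= 1).
#' @return named vector `(mean, std, max, min)`; `std` is the population
#'   standard deviation (divide by n).
#' @export
basic_stats <- function(x) {
  if (length(x) < 1) stop_data("basic_stats: empty input")
  m <- mean(x)
  c(mean = m, std = sqrt(mean((x - m)^2)), max = max(x), min = min(x))
}

#' SDNN: standard deviation of NN (inter-beat) intervals
#'
#' @param nn_intervals_ms numeric vector of inter-beat intervals in ms
#'   (length >= 2).
#' @return SDNN in ms (sample standard deviation, divide by n-1).
#' @export
hrv_sdnn <- function(nn_intervals_ms) {
  if (length(nn_intervals_ms) < 2) stop_data("SDNN needs >= 2 intervals")
  stats::sd(nn_intervals_ms)
}

#' RMSSD: root mean square of successive NN-interval differences
#'
#' @inheritParams hrv_sdnn
#' @return RMSSD in ms.
#' @export
hrv_rmssd <- function(nn_intervals_ms) {
  if (length(nn_intervals_ms) < 2) stop_data("RMSSD needs >= 2 intervals")
  sqrt(mean(diff(nn_intervals_ms)^2))
}

#' Detect local-maximum peaks with prominence and distance constraints
#'
#' Candidate peaks are strict local maxima; each must have topographic
#' prominence at least `min_prominence`; peaks closer than `min_distance_s`
#' are suppressed greedily, keeping the higher peak.
#'
#' @param x numeric signal.
#' @param sampling_rate Hz.
#' @param min_distance_s minimum separation between kept peaks in seconds.
#' @param min_prominence minimum prominence (same units as `x`).
#' @return integer vector of peak indices (possibly empty), strictly
#'   increasing.
#' @export
detect_peaks <- function(x, sampling_rate, min_distance_s = 0.4,
                         min_prominence = 0) {
  if (min_distance_s <= 0) stop_config("min_distance_s must be positive")
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    cand <- cand[prom >= min_prominence]
    if (!length(cand)) return(integer(0))
  }
  # Greedy suppression: visit candidates from highest to lowest.
  min_gap <- round(min_distance_s * sampling_rate)
  keep <- logical(length(cand))
  taken <- integer(0)
  for (j in order(-x[cand], cand)) {
    if (!length(taken) || all(abs(cand[j] - taken) >= min_gap)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  sort(cand[keep])
}

# Topographic prominence of a local maximum: height above the higher of the
# two bases (minimum between the peak and the nearest higher terrain on each
# side, or the signal edge).
peak_prominence <- function(x, i) {
  n <- length(x)
  left <- x[seq_len(i - 1)]
  higher_l <- which(left > x[i])
  lmin <- min(x[seq(if (length(higher_l)) max(higher_l) else 1L, i)])
  right <- x[seq(i + 1, n)]
  higher_r <- which(right > x[i])
  rmin <- min(x[seq(i, if (length(higher_r)) i + min(higher_r) else n)])
  x[i] - max(lmin, rmin)
}

#' Decompose an electrodermal window into tonic, phasic and driver components
#'
#' `tonic` is a 0.05 Hz zero-phase low-pass of the window (computed at a
#' decimated rate when the channel is sampled above 20 Hz), `phasic` is the
#' residual (`tonic + phasic` reconstructs the window exactly), and `driver`
#' is the positive part of the first difference of the phasic component times
#' the sampling rate — an event-rate signal supported around
#' skin-conductance responses. Rising stretches where the phasic deflection
#' is below 1% of its window peak are not counted as events, so slow tonic
#' leakage does not register in the driver.
#'
#' @param window numeric EDA slice (>= 4 s of samples).
#' @param sampling_rate Hz.
#' @return list with `tonic`, `phasic`, `driver`, each the window's length.
#' @export
eda_decompose <- function(window, sampling_rate) {
  n <- length(window)
  if (n < 4 * sampling_rate) stop_data("EDA window shorter than 4 s")
  if (sampling_rate > 20) {
    dec <- floor(sampling_rate / 4)
    idx <- seq(1, n, by = dec)
    low <- tonic_lowpass(window[idx], sampling_rate / dec)
    tonic <- stats::approx(idx, low, xout = seq_len(n), rule = 2)$y
  } else {
    tonic <- tonic_lowpass(window, sampling_rate)
  }
  phasic <- window - tonic
  driver <- pmax(c(0, diff(phasic)) * sampling_rate, 0)
  pk <- max(phasic)
  if (pk > 0) driver[phasic < 0.01 * pk] <- 0
  list(tonic = tonic, phasic = phasic, driver = driver)
}

tonic_lowpass <- function(x, rate, cutoff = 0.05) {
  butterworth_lowpass(x, rate, min(cutoff, 0.45 * rate / 2), order = 2)
}

# Sub-sample peak refinement: a three-point parabola around each detected
# peak; returns fractional sample positions. Essential for HRV statistics,
# which would otherwise be quantised to the sampling grid.
refine_peaks <- function(x, pk) {
  vapply(pk, function(i) {
    if (i <= 1 || i >= length(x)) return(as.numeric(i))
    den <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (abs(den) < 1e-12) return(as.numeric(i))
    as.numeric(i) + clamp(0.5 * (x[i - 1] - x[i + 1]) / den, -0.5, 0.5)
  }, numeric(1))
}

# ---- per-indicator extractors ------------------------------------------------

named_stats <- function(x, prefix) {
  s <- basic_stats(x)
  names(s) <- paste(prefix, names(s), sep = "_")
  s
}

#' Accelerometer window features
#'
#' Basic statistics per axis plus statistics of the per-sample net channel.
#' The net channel is the literal sum x+y+z by default (`acc_net = "l2"`
#' selects the Euclidean norm instead).
#'
#' @param window list of three equal-length numeric slices (x, y, z).
#' @param sampling_rate Hz (unused, kept for a uniform extractor signature).
#' @param acc_net `"sum"` or `"l2"`.
#' @return named numeric vector of 16 features.
#' @export
extract_acc <- function(window, sampling_rate = NA, acc_net = "sum") {
  if (length(unique(lengths(window))) != 1L)
    stop_data("ACC axes must have equal length")
  x <- window[[1]]; y <- window[[2]]; z <- window[[3]]
  net <- if (acc_net == "l2") sqrt(x^2 + y^2 + z^2) else x + y + z
  c(named_stats(x, "ACC_x"), named_stats(y, "ACC_y"),
    named_stats(z, "ACC_z"), named_stats(net, "ACC_net"))
}

#' Electrodermal window features
#'
#' Low-pass denoises the window at 1 Hz (when the rate permits), decomposes
#' it into tonic/phasic/driver and returns the basic statistics of each
#' component.
#'
#' @param window numeric EDA slice.
#' @param sampling_rate Hz.
#' @return named numeric vector of 12 features.
#' @export
extract_eda <- function(window, sampling_rate) {
  if (1 < 0.45 * sampling_rate)
    window <- butterworth_lowpass(window, sampling_rate, 1, order = 2)
  d <- eda_decompose(window, sampling_rate)
  c(named_stats(d$tonic, "EDA_tonic"), named_stats(d$phasic, "EDA_phasic"),
    named_stats(d$driver, "EDA_driver"))
}

#' Blood-volume-pulse window features
#'
#' Detects pulse peaks (min distance 0.4 s, prominence half the window SD)
#' and reports the peak frequency plus SDNN and RMSSD of the inter-peak
#' intervals. With fewer than 3 peaks all features are 0 and the
#' `low_peaks` attribute is set.
#'
#' @param window numeric BVP slice.
#' @param sampling_rate Hz.
#' @return named numeric vector `(BVP_peak_freq_hz, BVP_sdnn_ms,
#'   BVP_rmssd_ms)`.
#' @export
extract_bvp <- function(window, sampling_rate) {
  T <- length(window) / sampling_rate
  pk <- detect_peaks(window, sampling_rate, min_distance_s = 0.4,
                     min_prominence = 0.5 * stats::sd(window))
  if (length(pk) < 3) {
    out <- c(BVP_peak_freq_hz = 0, BVP_sdnn_ms = 0, BVP_rmssd_ms = 0)
    attr(out, "low_peaks") <- TRUE
    return(out)
  }
  ibi <- diff(refine_peaks(window, pk)) / sampling_rate * 1000
  c(BVP_peak_freq_hz = length(pk) / T, BVP_sdnn_ms = hrv_sdnn(ibi),
    BVP_rmssd_ms = hrv_rmssd(ibi))
}

#' Electrocardiogram window features
#'
#' R peaks are located Pan-Tompkins style: zero-phase band-pass 5-15 Hz,
#' squaring, 150 ms moving-average integration, adaptive threshold, then
#' peak refinement on the raw signal. Features are SDNN and RMSSD of the NN
#' intervals; with fewer than 3 peaks both are 0 and `low_peaks` is set.
#'
#' @param window numeric ECG slice.
#' @param sampling_rate Hz.
#' @return named numeric vector `(ECG_sdnn_ms, ECG_rmssd_ms)`.
#' @export
extract_ecg <- function(window, sampling_rate) {
  pk <- detect_r_peaks(window, sampling_rate)
  if (length(pk) < 3) {
    out <- c(ECG_sdnn_ms = 0, ECG_rmssd_ms = 0)
    attr(out, "low_peaks") <- TRUE
    return(out)
  }
  nn <- diff(refine_peaks(window, pk)) / sampling_rate * 1000
  c(ECG_sdnn_ms = hrv_sdnn(nn), ECG_rmssd_ms = hrv_rmssd(nn))
}

detect_r_peaks <- function(x, sampling_rate) {
  if (stats::sd(x) < 1e-12) return(integer(0))
  high <- min(15, 0.45 * sampling_rate)
  low <- min(5, high / 2)
  bp <- butterworth_bandpass(x, sampling_rate, low, high, order = 2)
  sq <- bp^2
  w <- max(1L, round(0.150 * sampling_rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.3 * max(integ) + 0.1 * mean(integ)
  pk <- detect_peaks(integ, sampling_rate, min_distance_s = 0.3,
                     min_prominence = thr * 0.5)
  pk <- pk[integ[pk] >= thr]
  # refine each detection to the raw-signal maximum within +/- 100 ms
  half <- round(0.1 * sampling_rate)
  refined <- vapply(pk, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(refined))
}

#' Skin-temperature window features
#'
#' Basic statistics plus the least-squares slope in units per second.
#'
#' @param window numeric TEMP slice.
#' @param sampling_rate Hz.
#' @return named numeric vector of 5 features.
#' @export
extract_temp <- function(window, sampling_rate) {
  t <- (seq_along(window) - 1) / sampling_rate
  slope <- if (length(window) > 1)
    sum((t - mean(t)) * (window - mean(window))) / sum((t - mean(t))^2)
  else 0
  c(named_stats(window, "TEMP"), TEMP_slope = slope)
}

#' Electromyography window features
#'
#' Low-pass denoise (250 Hz or 0.45 x Nyquist, whichever is lower) then
#' basic statistics.
#'
#' @param window numeric EMG slice.
#' @param sampling_rate Hz.
#' @return named numeric vector of 4 features.
#' @export
extract_emg <- function(window, sampling_rate) {
  cut <- min(250, 0.45 * sampling_rate)
  if (cut > 0 && cut < sampling_rate / 2)
    window <- butterworth_lowpass(window, sampling_rate, cut, order = 4)
  named_stats(window, "EMG")
}

#' Respiration window features
#'
#' Basic statistics of the (low-pass denoised) respiration signal; a derived
#' breaths-per-minute feature is added when `breaths_per_min = TRUE`.
#'
#' @param window numeric RESP slice.
#' @param sampling_rate Hz.
#' @param breaths_per_min add a breath-rate feature from peak counting.
#' @return named numeric vector of 4 (or 5) features.
#' @export
extract_resp <- function(window, sampling_rate, breaths_per_min = FALSE) {
  cut <- min(1, 0.45 * sampling_rate)
  flt <- if (cut > 0 && cut < sampling_rate / 2)
    butterworth_lowpass(window, sampling_rate, cut, order = 2) else window
  out <- named_stats(flt, "RESP")
  if (breaths_per_min) {
    pk <- detect_peaks(flt, sampling_rate, min_distance_s = 1.5,
                       min_prominence = 0.3 * stats::sd(flt))
    out <- c(out, RESP_rate_bpm = length(pk) /
               (length(window) / sampling_rate) * 60)
  }
  out
}

# ---- attribute encoding ------------------------------------------------------

attribute_schema <- function() {
  list(continuous = c("age", "height", "weight"),
       categorical = list(gender = c("female", "male"),
                          smoker = c("FALSE", "TRUE"),
                          exercised_today = c("FALSE", "TRUE")))
}

#' Encode subject attributes as a numeric vector
#'
#' Continuous attributes pass through raw; categorical and boolean
#' attributes are one-hot encoded with a fixed global ordering, so the
#' encoded length is `#continuous + sum(levels)`.
#'
#' @param attributes named list with fields `age`, `gender`, `height`,
#'   `weight`, `smoker`, `exercised_today`.
#' @return named numeric vector of length k = 9 under the default schema.
#' @export
encode_attributes <- function(attributes) {
  sch <- attribute_schema()
  cont <- vapply(sch$continuous, function(f) {
    v <- attributes[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop_data("attribute ", f, " missing or non-positive")
    as.numeric(v)
  }, numeric(1))
  onehot <- unlist(lapply(names(sch$categorical), function(f) {
    lv <- sch$categorical[[f]]
    v <- as.character(attributes[[f]])
    if (!v %in% lv) stop_data("attribute ", f, " has unknown level ", v)
    out <- as.numeric(lv == v)
    names(out) <- paste(f, lv, sep = ".")
    out
  }))
  c(cont, onehot)
}

# ---- assembly ----------------------------------------------------------------

channel_indicator <- function(ch) sub("_[xyz]$", "", ch)

#' Extract the per-indicator feature matrices for one subject
#'
#' Runs the per-modality extractor on every kept window and assembles the
#' indicator feature matrices `B[[indicator]]` (kept-windows x features), the
#' encoded attribute vector `A`, and the fused matrix `PF = [A | B]` with `A`
#' replicated across rows.
#'
#' @param window_set a labelled `window_set` (see [assign_window_labels()]).
#' @param attributes optional attribute list; defaults to the window set's.
#' @param options list of extractor options (`acc_net`, `breaths_per_min`).
#' @return object of class `feature_set` with fields `B`, `A`, `PF`,
#'   `labels`, `manifest` (indicator -> feature names), `subject_id`.
#' @export
assemble_feature_tensors <- function(window_set, attributes = NULL,
                                     options = list()) {
  attributes <- attributes %||% window_set$attributes
  kept <- which(window_set$kept_mask)
  if (!length(kept)) stop_data("no kept windows for subject ",
                               window_set$subject_id)
  chans <- names(window_set$windows)
  indicators <- unique(channel_indicator(chans))
  rates <- window_set$rates
  B <- list()
  for (ind in indicators) {
    rows <- lapply(kept, function(q) {
      if (ind == "ACC") {
        axes <- lapply(c("ACC_x", "ACC_y", "ACC_z"),
                       function(a) window_set$windows[[a]][[q]])
        extract_acc(axes, rates[["ACC_x"]],
                    acc_net = options$acc_net %||% "sum")
      } else {
        w <- window_set$windows[[ind]][[q]]
        r <- rates[[ind]]
        switch(ind,
               BVP = extract_bvp(w, r),
               EDA = extract_eda(w, r),
               ECG = extract_ecg(w, r),
               EMG = extract_emg(w, r),
               TEMP = extract_temp(w, r),
               RESP = extract_resp(w, r,
                 breaths_per_min = isTRUE(options$breaths_per_min)),
               stop_data("no extractor for indicator ", ind))
      }
    })
    mat <- do.call(rbind, lapply(rows, as.numeric))
    colnames(mat) <- names(rows[[1]])
    if (any(!is.finite(mat))) stop_data("non-finite feature for ", ind)
    B[[ind]] <- mat
  }
  A <- encode_attributes(attributes)
  Ball <- do.call(cbind, B)
  PF <- cbind(matrix(A, nrow = length(kept), ncol = length(A), byrow = TRUE,
                     dimnames = list(NULL, names(A))), Ball)
  manifest <- list(attributes = names(A),
                   indicators = lapply(B, colnames))
  structure(list(subject_id = window_set$subject_id, B = B, A = A, PF = PF,
                 labels = window_set$window_labels[kept], manifest = manifest),
            class = "feature_set")
}

#' Featurize a whole cohort
#'
#' Denoise, segment, label and extract features for every subject.
#'
#' @param cohort list of `subject_record`s.
#' @param window_s window length in seconds.
#' @param cutoffs denoising cutoffs, see [denoise_subject()].
#' @param label_rule `"purity"` or `"majority"`.
#' @param options extractor options passed to [assemble_feature_tensors()].
#' @return list of `feature_set`s.
#' @export
featurize_cohort <- function(cohort, window_s = 30,
                             cutoffs = default_cutoffs(),
                             label_rule = "purity", options = list()) {
  lapply(cohort, function(subj) {
    subj <- denoise_subject(subj, cutoffs)
    ws <- segment_windows(subj, window_s)
    ws <- assign_window_labels(subj$labels, ws, rule = label_rule)
    assemble_feature_tensors(ws, options = options)
  })
}
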