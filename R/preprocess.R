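# Segmentation of multi-rate records into non-overlapping windows and
# window-label assignment. Windows use the half-open convention
# [(q-1)T, qT): window q at rate r covers samples (q-1)*round(T*r)+1 ...
# q*round(T*r), so windows are disjoint and jointly cover the first
# floor(L/T)*T seconds of every channel.

#' Denoise the channels of a subject record
#'
#' Applies the zero-phase Butterworth low-pass to each channel that has a
#' configured cutoff. Defaults: EDA 1 Hz; EMG 250 Hz or 0.45 x Nyquist,
#' whichever is lower; other channels pass through unchanged.
#'
#' @param subject a `subject_record`.
#' @param cutoffs named list channel -> cutoff Hz (NA = no filtering).
#' @param order Butterworth order.
#' @return the subject record with filtered channel samples.
#' @export
denoise_subject <- function(subject, cutoffs = default_cutoffs(), order = 4) {
  for (ch in names(subject$channels)) {
    cut <- cutoffs[[ch]]
    if (is.null(cut) || is.na(cut)) next
    r <- subject$channels[[ch]]$sampling_rate
    cut <- min(cut, 0.45 * r)
    subject$channels[[ch]]$samples <-
      butterworth_lowpass(subject$channels[[ch]]$samples, r, cut, order)
  }
  subject
}

#' @rdname denoise_subject
#' @export
default_cutoffs <- function() list(EDA = 1, EMG = 250)

#' Segment a subject record into fixed-length windows
#'
#' The common duration L is the minimum channel duration in whole seconds;
#' the record is cut into `xi = floor(L / T)` non-overlapping windows of
#' `T` seconds and the trailing remainder is discarded. Each channel's
#' window slice has `round(T * rate)` samples.
#'
#' @param subject a `subject_record`.
#' @param window_length_s window length T in seconds.
#' @return object of class `window_set` with fields `window_length_s`,
#'   `n_windows`, `windows` (channel -> list of slices), `rates`,
#'   `window_labels` and `kept_mask` (filled by [assign_window_labels()]).
#' @export
segment_windows <- function(subject, window_length_s) {
  T <- window_length_s
  if (T <= 0) stop_config("window_length_s must be positive")
  durs <- vapply(subject$channels, function(ch)
    floor(length(ch$samples) / ch$sampling_rate), numeric(1))
  L <- min(durs)
  xi <- floor(L / T)
  if (xi < 1) stop_data("no complete window: duration ", L, " s < T = ", T)
  windows <- lapply(subject$channels, function(ch) {
    len <- round(T * ch$sampling_rate)
    lapply(seq_len(xi), function(q)
      ch$samples[seq((q - 1) * len + 1, q * len)])
  })
  rates <- vapply(subject$channels, `[[`, numeric(1), "sampling_rate")
  structure(list(subject_id = subject$subject_id,
                 attributes = subject$attributes,
                 window_length_s = T, n_windows = xi,
                 windows = windows, rates = rates,
                 window_labels = rep(NA_integer_, xi),
                 kept_mask = rep(TRUE, xi)),
            class = "window_set")
}

#' Assign one label per window
#'
#' A window is kept iff all label samples falling inside it agree; kept
#' windows receive that code, mixed windows are masked out. (Majority vote is
#' available via `rule = "majority"`.)
#'
#' @param labels a label stream: `list(sampling_rate=, codes=)` or a
#'   `subject_record` (its `$labels` is used).
#' @param window_set a `window_set` from [segment_windows()].
#' @param rule `"purity"` (default) or `"majority"`.
#' @return the window set with `window_labels` and `kept_mask` filled; the
#'   attribute `any_kept` is FALSE when every window was masked.
#' @export
assign_window_labels <- function(labels, window_set, rule = c("purity",
                                                              "majority")) {
  rule <- match.arg(rule)
  if (inherits(labels, "subject_record")) labels <- labels$labels
  T <- window_set$window_length_s
  xi <- window_set$n_windows
  r <- labels$sampling_rate
  len <- round(T * r)
  if (length(labels$codes) < xi * len)
    stop_data("label stream shorter than the segmented span")
  lab <- rep(NA_integer_, xi)
  kept <- rep(FALSE, xi)
  for (q in seq_len(xi)) {
    codes <- labels$codes[seq((q - 1) * len + 1, q * len)]
    if (rule == "purity") {
      if (length(unique(codes)) == 1L) { lab[q] <- codes[1]; kept[q] <- TRUE }
    } else {
      tab <- table(codes)
      lab[q] <- as.integer(names(tab)[which.max(tab)])
      kept[q] <- TRUE
    }
  }
  window_set$window_labels <- lab
  window_set$kept_mask <- kept
  attr(window_set, "any_kept") <- any(kept)
  window_set
}
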