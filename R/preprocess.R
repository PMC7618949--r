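#' Standardise a time course
#'
#' Z-transforms a single time course to mean 0, SD 1 (sample SD).  Spectral
#' and connectivity metrics downstream all operate on standardised parcel
#' time courses, which makes densities integrate to ~1 and removes amplitude
#' differences between parcels.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return The standardised vector.
#' @examples
#' zscore_timecourse(c(1, 2, 3))
#' @export
zscore_timecourse <- function(x) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant time course (zero variance)", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, so amplitude
#' envelopes downstream carry no group-delay distortion.  The effective
#' attenuation is twice the single-pass order.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param lo,hi Band edges, Hz; requires `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (default 5).
#' @return Filtered vector of the same length.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 250))
#' y <- bandpass(x, fs = 250, lo = 7, hi = 13)
#' @export
bandpass <- function(x, fs, lo, hi, order = 5) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= fs / 2) stop("upper edge must be below the Nyquist frequency",
                         call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect bad segments by windowed variance
#'
#' Splits the recording into consecutive non-overlapping windows and flags a
#' window when the z-score of its log-variance, taken across windows, exceeds
#' `z_thresh`.  Log-variance symmetrises the heavy right tail of variance
#' estimates, so the threshold acts on a roughly Gaussian quantity for clean
#' data.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 1).
#' @param z_thresh Flagging threshold on the log-variance z-score (default 3).
#' @return A `segment_mask`: tibble with 0-based half-open sample intervals
#'   (`start`, `end`) of flagged windows, merged when adjacent.
#' @export
detect_bad_segments <- function(x, fs, window_s = 1, z_thresh = 3) {
  wlen <- round(window_s * fs)
  if (wlen < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (wlen > length(x)) stop("window longer than the recording", call. = FALSE)
  n_win <- floor(length(x) / wlen)
  v <- vapply(seq_len(n_win), function(i) {
    stats::var(x[((i - 1) * wlen + 1):(i * wlen)])
  }, numeric(1))
  if (any(v == 0) || stats::sd(log(v)) == 0) {
    stop("windowed variance is degenerate (constant signal)", call. = FALSE)
  }
  z <- (log(v) - mean(log(v))) / stats::sd(log(v))
  flagged <- which(z > z_thresh)
  mask <- tibble::tibble(start = (flagged - 1L) * wlen,
                         end = flagged * wlen)
  merge_intervals(mask)
}

# Merge adjacent/overlapping half-open intervals; keeps the mask canonical.
merge_intervals <- function(mask) {
  if (nrow(mask) <= 1) return(mask)
  mask <- mask[order(mask$start), ]
  out <- mask[1, ]
  for (i in 2:nrow(mask)) {
    if (mask$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], mask$end[i])
    } else {
      out <- rbind(out, mask[i, ])
    }
  }
  out
}

#' Drop flagged segments from a time course
#'
#' Removes the samples covered by a segment mask and concatenates the
#' remaining data.  An empty mask returns the input unchanged.
#'
#' @param x Numeric vector.
#' @param mask A `segment_mask` tibble from [detect_bad_segments()].
#' @return The cleaned vector.
#' @export
drop_bad_segments <- function(x, mask) {
  if (nrow(mask) == 0) return(x)
  stopifnot(all(mask$start >= 0), all(mask$end <= length(x)),
            all(mask$end > mask$start))
  bad <- unlist(purrr::map2(mask$start, mask$end,
                            function(s, e) (s + 1):e))
  x[-bad]
}

#' Clean one subject's parcel time courses
#'
#' Per parcel: z-score, band-pass filter, detect and drop bad segments (the
#' union of per-parcel masks is removed from every parcel so all parcels stay
#' sample-aligned for connectivity), then re-z-score.
#'
#' @param subject A `parcel_timecourses` object.
#' @param lo,hi Band-pass edges, Hz (defaults 1 and 80).
#' @param window_s,z_thresh Bad-segment detection settings.
#' @return The cleaned `parcel_timecourses`, with the applied mask attached
#'   as attribute `"segment_mask"`.
#' @export
preprocess_subject <- function(subject, lo = 1, hi = 80,
                               window_s = 1, z_thresh = 3) {
  tc <- subject$timecourses
  filtered <- t(apply(tc, 1, function(x) {
    bandpass(zscore_timecourse(x), subject$fs, lo, hi)
  }))
  masks <- purrr::map(seq_len(nrow(filtered)), function(p) {
    detect_bad_segments(filtered[p, ], subject$fs, window_s, z_thresh)
  })
  mask <- merge_intervals(dplyr::bind_rows(masks))
  cleaned <- t(apply(filtered, 1, function(x) {
    zscore_timecourse(drop_bad_segments(x, mask))
  }))
  rownames(cleaned) <- rownames(tc)
  out <- subject
  out$timecourses <- cleaned
  attr(out, "segment_mask") <- mask
  out
}
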