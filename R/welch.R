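#' Welch power spectral density
#'
#' One-sided Welch estimate with a Hann window (default 2 s, so the frequency
#' grid has 0.5 Hz spacing) and 50% overlap, no detrending (inputs are
#' z-scored upstream).  Scaling is density (power per Hz): for a z-scored
#' signal the density integrates to ~1 over 0 to Nyquist (Parseval).
#'
#' Accepts a single time course or a parcels x samples matrix; in the matrix
#' case one density column is returned per parcel.
#'
#' @param x Numeric vector or parcels x samples matrix.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 2).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @return A `parcel_psd` object: list with `freqs` (Hz) and `density`
#'   (frequencies x parcels matrix, power per Hz).
#' @examples
#' x <- zscore_timecourse(rnorm(5000))
#' psd <- welch_psd(x, fs = 250)
#' sum(psd$density) * (psd$freqs[2] - psd$freqs[1])  # ~1
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  if (is.matrix(x)) {
    per <- apply(x, 1, function(row) welch_psd(row, fs, window_s, overlap),
                 simplify = FALSE)
    dens <- do.call(cbind, purrr::map(per, "density"))
    colnames(dens) <- rownames(x)
    return(structure(list(freqs = per[[1]]$freqs, density = dens, fs = fs),
                     class = "parcel_psd"))
  }
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("recording shorter than one window", call. = FALSE)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / nwin)  # periodic Hann
  scale <- fs * sum(w^2)
  nfreq <- nwin %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * w
    p <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 / scale
    acc <- acc + p
  }
  dens <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nwin is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nfreq] <- 1
  dens <- dens * dbl
  freqs <- seq(0, fs / 2, length.out = nfreq)
  structure(list(freqs = freqs, density = matrix(dens, ncol = 1), fs = fs),
            class = "parcel_psd")
}

#' Mean band power from a PSD
#'
#' Summarises a power spectrum over a frequency band as the mean density over
#' bins with `lo <= f < hi` (half-open, so adjacent canonical bands share no
#' bin).  The mean, rather than the integral, keeps bands of different widths
#' comparable.
#'
#' @param psd A `parcel_psd`.
#' @param band Band name from [canonical_bands()] or a numeric `(lo, hi)`.
#' @return Named numeric vector, one value per parcel.
#' @examples
#' psd <- welch_psd(zscore_timecourse(rnorm(5000)), fs = 250)
#' band_power(psd, "alpha")
#' @export
band_power <- function(psd, band) {
  b <- resolve_band(band)
  if (b$lo < min(psd$freqs) || b$hi > max(psd$freqs) + 1e-9) {
    stop("band [", b$lo, ", ", b$hi, ") outside the PSD frequency grid",
         call. = FALSE)
  }
  sel <- psd$freqs >= b$lo & psd$freqs < b$hi
  colMeans(psd$density[sel, , drop = FALSE])
}

#' Band powers for all canonical bands
#'
#' @param psd A `parcel_psd`.
#' @param bands Band definition tibble (default [canonical_bands()]).
#' @return Tibble: `parcel`, `band`, `power` (long format).
#' @export
band_power_table <- function(psd, bands = canonical_bands()) {
  labels <- colnames(psd$density)
  if (is.null(labels)) labels <- sprintf("parcel_%02d", seq_len(ncol(psd$density)))
  purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    tibble::tibble(parcel = labels, band = bands$band[i],
                   power = unname(band_power(psd, bands$band[i])))
  })
}

#' @export
print.parcel_psd <- function(x, ...) {
  cat("<parcel_psd> ", ncol(x$density), " parcel(s), ",
      length(x$freqs), " frequencies (",
      min(x$freqs), "-", max(x$freqs), " Hz, d f = ",
      signif(x$freqs[2] - x$freqs[1], 3), " Hz)\n", sep = "")
  invisible(x)
}
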