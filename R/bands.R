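#' Canonical frequency bands
#'
#' The six canonical bands used throughout resting-state MEG analysis:
#' delta (1-4 Hz), theta (4-7 Hz), alpha (7-13 Hz), beta (13-30 Hz),
#' low-gamma (30-48 Hz) and high-gamma (52-80 Hz).  The 48-52 Hz gap between
#' the gamma bands excludes the line-noise notch region.  Band membership is
#' half-open, `lo <= f < hi`, so adjacent bands never share a frequency bin.
#'
#' @return A tibble with columns `band`, `lo` and `hi` (Hz).
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    lo   = c(1, 4, 7, 13, 30, 52),
    hi   = c(4, 7, 13, 30, 48, 80)
  )
}

# Look up one band row; accepts a band name or a (lo, hi) pair.
resolve_band <- function(band, bands = canonical_bands()) {
  if (is.character(band)) {
    row <- bands[bands$band == band, ]
    if (nrow(row) != 1L) {
      stop("unknown band '", band, "'; known bands: ",
           paste(bands$band, collapse = ", "), call. = FALSE)
    }
    return(list(name = row$band, lo = row$lo, hi = row$hi))
  }
  if (is.numeric(band) && length(band) == 2L && band[1] < band[2]) {
    return(list(name = paste0(band[1], "-", band[2], "Hz"),
                lo = band[1], hi = band[2]))
  }
  stop("`band` must be a band name or a numeric (lo, hi) pair", call. = FALSE)
}
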