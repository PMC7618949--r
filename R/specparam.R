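#' Parameterise a power spectrum into aperiodic and periodic parts
#'
#' Decomposes a PSD over `f_range` (default 1-70 Hz; higher frequencies are
#' excluded to limit spectral-plateau bias) into a fixed-mode aperiodic
#' component, `log10 P(f) = offset - exponent * log10 f`, plus Gaussian
#' oscillatory peaks in log10 power.  The algorithm:
#'
#' 1. Robust aperiodic fit: an initial least-squares line in log-log space is
#'    refined on the frequency bins least contaminated by peaks (bins whose
#'    positive residual is below its 2.5th percentile).
#' 2. Iterative peak extraction from the flattened spectrum: the tallest
#'    residual point seeds a Gaussian whose width is guessed from the
#'    half-height span; extraction stops when the tallest candidate falls
#'    below `max(min_peak_height, peak_threshold * SD(flattened))`.
#' 3. All Gaussians are refined jointly by bounded least squares; peaks are
#'    retained only with height >= `min_peak_height` and bandwidth within
#'    `peak_width_limits`.
#' 4. The aperiodic line is refit on the peak-removed spectrum, giving the
#'    final offset and exponent.
#'
#' @param psd A `parcel_psd` (single-parcel) or a list with `freqs` and a
#'   density vector/one-column matrix.
#' @param f_range Fit range in Hz (default `c(1, 70)`).
#' @param peak_width_limits Allowed Gaussian bandwidth (2 SD) range in Hz.
#' @param max_n_peaks Safety cap on extracted peaks (default 20).
#' @param min_peak_height Minimum peak height in log10 power (default 0.05).
#' @param peak_threshold Relative detection threshold in SD units of the
#'   flattened spectrum (default 2).
#' @return A `spectral_fit`: offset, exponent, `peaks` tibble (`cf`, `pw`,
#'   `bw`), the periodic (flattened) spectrum on the fit grid -- log10 power
#'   above the aperiodic fit -- plus the fitted log10 model and the mean
#'   absolute log residual (`fit_error`).
#' @examples
#' f <- seq(1, 70, by = 0.5)
#' dens <- 10^(0.5 - 1.5 * log10(f))
#' fit <- parameterize_spectrum(list(freqs = f, density = dens))
#' fit$exponent
#' @export
parameterize_spectrum <- function(psd, f_range = c(1, 70),
                                  peak_width_limits = c(0.5, 12),
                                  max_n_peaks = 20,
                                  min_peak_height = 0.05,
                                  peak_threshold = 2) {
  dens <- psd$density
  if (is.matrix(dens)) {
    if (ncol(dens) != 1) stop("pass one parcel at a time", call. = FALSE)
    dens <- dens[, 1]
  }
  sel <- psd$freqs >= f_range[1] & psd$freqs <= f_range[2]
  f <- psd$freqs[sel]
  dens <- dens[sel]
  if (length(f) < 5) stop("frequency grid does not cover the fit range",
                          call. = FALSE)
  if (any(dens <= 0)) stop("non-positive spectral density in the fit range",
                           call. = FALSE)
  y <- log10(dens)
  logf <- log10(f)
  sd_lim <- peak_width_limits / 2

  ap <- robust_aperiodic_fit(logf, y)
  flat <- y - aperiodic_value(ap, logf)

  guesses <- extract_peak_guesses(f, flat, max_n_peaks, min_peak_height,
                                  peak_threshold, sd_lim)
  peaks <- refine_peaks(f, flat, guesses, sd_lim, min_peak_height, f_range)

  peak_model <- gaussian_model(f, peaks)
  ap <- simple_aperiodic_fit(logf, y - peak_model)
  fitted_log <- aperiodic_value(ap, logf) + peak_model

  structure(
    list(freqs = f, offset = unname(ap[1]), exponent = unname(ap[2]),
         peaks = peaks,
         # flattened spectrum: log10 power above the aperiodic fit, the
         # "peaks-only" spectrum the oscillatory-speed summary consumes
         periodic = y - aperiodic_value(ap, logf),
         fitted_log = fitted_log, log_density = y,
         fit_error = mean(abs(y - fitted_log)),
         settings = list(f_range = f_range,
                         peak_width_limits = peak_width_limits,
                         min_peak_height = min_peak_height,
                         peak_threshold = peak_threshold)),
    class = "spectral_fit"
  )
}

# Aperiodic parameters are (offset, exponent); model = offset - exponent*logf.
aperiodic_value <- function(ap, logf) ap[1] - ap[2] * logf

simple_aperiodic_fit <- function(logf, y) {
  co <- stats::lm.fit(cbind(1, logf), y)$coefficients
  c(offset = unname(co[1]), exponent = -unname(co[2]))
}

# Refit the line on bins least affected by peaks: keep bins whose positive
# residual from the initial fit is below the 2.5th percentile of positive
# residuals.
robust_aperiodic_fit <- function(logf, y) {
  ap <- simple_aperiodic_fit(logf, y)
  flat <- y - aperiodic_value(ap, logf)
  flat[flat < 0] <- 0
  keep <- flat <= stats::quantile(flat, 0.025)
  if (sum(keep) < 3) return(ap)
  simple_aperiodic_fit(logf[keep], y[keep])
}

gaussian_model <- function(f, peaks) {
  m <- numeric(length(f))
  for (i in seq_len(nrow(peaks))) {
    m <- m + peaks$pw[i] *
      exp(-((f - peaks$cf[i])^2) / (2 * (peaks$bw[i] / 2)^2))
  }
  m
}

extract_peak_guesses <- function(f, flat, max_n_peaks, min_peak_height,
                                 peak_threshold, sd_lim) {
  guesses <- tibble::tibble(cf = numeric(), pw = numeric(), sd = numeric())
  work <- flat
  for (k in seq_len(max_n_peaks)) {
    i <- which.max(work)
    h <- work[i]
    if (h < min_peak_height || h < peak_threshold * stats::sd(work)) break
    # half-height span estimates the Gaussian SD (FWHM = 2.355 sd)
    half <- h / 2
    li <- i; while (li > 1 && work[li] > half) li <- li - 1
    ri <- i; while (ri < length(work) && work[ri] > half) ri <- ri + 1
    fwhm <- f[ri] - f[li]
    sd_g <- max(min(fwhm / 2.355, sd_lim[2]), sd_lim[1])
    guesses <- dplyr::bind_rows(guesses,
                                tibble::tibble(cf = f[i], pw = h, sd = sd_g))
    work <- work - h * exp(-((f - f[i])^2) / (2 * sd_g^2))
  }
  guesses
}

# Joint bounded least-squares refinement of all Gaussian guesses against the
# flattened spectrum; drops peaks failing the height floor or sliding outside
# the fit range.
refine_peaks <- function(f, flat, guesses, sd_lim, min_peak_height, f_range) {
  empty <- tibble::tibble(cf = numeric(), pw = numeric(), bw = numeric())
  if (nrow(guesses) == 0) return(empty)
  par0 <- as.vector(t(as.matrix(guesses)))
  lower <- as.vector(t(cbind(pmax(guesses$cf - 2 * guesses$sd, f_range[1]),
                             1e-6, sd_lim[1])))
  upper <- as.vector(t(cbind(pmin(guesses$cf + 2 * guesses$sd, f_range[2]),
                             Inf, sd_lim[2])))
  obj <- function(p) {
    m <- matrix(p, ncol = 3, byrow = TRUE)
    model <- numeric(length(f))
    for (i in seq_len(nrow(m))) {
      model <- model + m[i, 2] * exp(-((f - m[i, 1])^2) / (2 * m[i, 3]^2))
    }
    sum((flat - model)^2)
  }
  fit <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
  m <- matrix(fit$par, ncol = 3, byrow = TRUE)
  peaks <- tibble::tibble(cf = m[, 1], pw = m[, 2], bw = 2 * m[, 3])
  peaks <- peaks[peaks$pw >= min_peak_height &
                   peaks$cf >= f_range[1] & peaks$cf <= f_range[2], ]
  peaks[order(peaks$cf), ]
}

#' Aperiodic exponent of a spectral fit
#'
#' The 1/f exponent: the magnitude of the log10-log10 slope of the aperiodic
#' component.  Larger values mean a steeper spectrum (interpreted as reduced
#' signal complexity).
#'
#' @param fit A `spectral_fit`.
#' @return Numeric scalar.
#' @export
exponent <- function(fit) {
  stopifnot(inherits(fit, "spectral_fit"))
  unname(fit$exponent)
}

#' Centre of energy of the periodic spectrum
#'
#' The oscillatory-speed summary: the frequency at which the summed power of
#' the periodic (flattened, peaks-only) spectrum below equals the summed
#' power above.  Computed as the smallest frequency, linearly interpolated
#' between grid bins, where the cumulative periodic power reaches half the
#' total.  A leftward CoE shift indicates oscillatory slowing.  Negative
#' periodic values (aperiodic-fit overshoot) are floored at zero first.
#'
#' @param fit A `spectral_fit`.
#' @param method `"balance"` (default; the equal-power split) or `"mean"`
#'   (power-weighted mean frequency, for sensitivity analysis).
#' @return Frequency in Hz, or `NA` when the periodic spectrum carries no
#'   power (no oscillations).
#' @export
centre_of_energy <- function(fit, method = c("balance", "mean")) {
  stopifnot(inherits(fit, "spectral_fit"))
  method <- match.arg(method)
  p <- pmax(fit$periodic, 0)
  total <- sum(p)
  if (total <= 0) return(NA_real_)
  if (method == "mean") return(sum(fit$freqs * p) / total)
  cum <- cumsum(p)
  k <- which(cum >= total / 2)[1]
  df <- fit$freqs[2] - fit$freqs[1]
  prev <- if (k == 1) 0 else cum[k - 1]
  # each bin's mass is spread over [f_k - df/2, f_k + df/2), so a symmetric
  # peak balances exactly at its centre bin
  fit$freqs[k] - df / 2 + (total / 2 - prev) / (cum[k] - prev) * df
}

#' Select the dominant peak in a band
#'
#' Among retained peaks with centre frequency in `[lo, hi)`, returns the one
#' with the highest power; ties are broken towards the lower frequency.
#'
#' @param fit A `spectral_fit`.
#' @param band `"alpha"`, `"beta"`, or any band resolvable by
#'   [canonical_bands()] / a `(lo, hi)` pair.
#' @return One-row tibble `freq`, `power`; values `NA` when no peak lies in
#'   the band.
#' @export
select_band_peak <- function(fit, band) {
  stopifnot(inherits(fit, "spectral_fit"))
  b <- resolve_band(band)
  pk <- fit$peaks[fit$peaks$cf >= b$lo & fit$peaks$cf < b$hi, ]
  if (nrow(pk) == 0) {
    return(tibble::tibble(freq = NA_real_, power = NA_real_))
  }
  pk <- pk[order(-pk$pw, pk$cf), ]
  tibble::tibble(freq = pk$cf[1], power = pk$pw[1])
}

#' Impute missing band peaks across a cohort
#'
#' Replaces a missing peak frequency/power for a subject in a given parcel
#' and band with the mean over all participants with a detected peak in that
#' parcel and band, flagging imputed cells.  Cells missing for every subject
#' stay missing with a warning (they are excluded from group models).
#'
#' @param peak_tbl Tibble with columns `subject_id`, `parcel`, `band`,
#'   `freq`, `power`.
#' @return The table with imputed values and a logical `imputed` column.
#' @export
impute_missing_peaks <- function(peak_tbl) {
  out <- peak_tbl |>
    dplyr::group_by(.data$parcel, .data$band) |>
    dplyr::mutate(
      imputed = is.na(.data$freq),
      freq = ifelse(is.na(.data$freq),
                    mean(.data$freq, na.rm = TRUE), .data$freq),
      power = ifelse(is.na(.data$power),
                     mean(.data$power, na.rm = TRUE), .data$power)
    ) |>
    dplyr::ungroup()
  out$freq[is.nan(out$freq)] <- NA_real_
  out$power[is.nan(out$power)] <- NA_real_
  if (any(is.na(out$freq))) {
    warning("some parcel/band cells have no detected peak in any subject; ",
            "left missing")
  }
  out
}

#' Count missing peaks per subject and band
#'
#' The number of parcels in which no peak was detected, per subject and band,
#' computed before imputation; used to compare peak detectability between
#' groups.
#'
#' @param peak_tbl Tibble as in [impute_missing_peaks()] (pre-imputation).
#' @return Tibble `subject_id`, `band`, `n_missing`.
#' @export
count_missing_peaks <- function(peak_tbl) {
  peak_tbl |>
    dplyr::group_by(.data$subject_id, .data$band) |>
    dplyr::summarise(n_missing = sum(is.na(.data$freq)), .groups = "drop")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("<spectral_fit> offset ", signif(x$offset, 4), ", exponent ",
      signif(x$exponent, 4), ", ", nrow(x$peaks), " peak(s), fit error ",
      signif(x$fit_error, 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectral fit: one row per retained peak
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return Tibble `cf`, `pw`, `bw`.
#' @export
tidy.spectral_fit <- function(x, ...) x$peaks

#' One-row summary of a spectral fit
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return Tibble with offset, exponent, peak count, centre of energy and
#'   mean absolute log residual.
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble::tibble(offset = x$offset, exponent = x$exponent,
                 n_peaks = nrow(x$peaks), coe = centre_of_energy(x),
                 fit_error = x$fit_error)
}
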