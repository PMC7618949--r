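#' Define a synthetic cohort
#'
#' A cohort specification fixes the sampling design of a simulated study:
#' group sizes and labels, the age range, sex balance, scanner mix, and the
#' recording geometry (number of parcels, sampling rate, duration).  The
#' defaults mirror a typical parcellated resting-state MEG study: 52 cortical
#' parcels sampled at 250 Hz for 5 minutes.
#'
#' @param n_per_group Subjects per group.
#' @param groups Character vector of group labels (no duplicates).
#' @param age_range Length-2 numeric, years; ages are drawn uniformly.
#' @param sex_ratio Fraction of male subjects in `[0, 1]`.
#' @param n_parcels Number of cortical parcels (>= 2).
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param scanners Scanner type labels, sampled uniformly per subject.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across calls.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_per_group = 5, groups = c("HC", "AD"), seed = 1)
#' @export
cohort_spec <- function(n_per_group, groups = c("HC", "AD"),
                        age_range = c(50, 80), sex_ratio = 0.5,
                        n_parcels = 52, fs = 250, duration = 300,
                        scanners = c("scannerA", "scannerB"), seed = 1) {
  stopifnot(n_per_group >= 1, n_parcels >= 2, fs > 0, duration > 0,
            length(age_range) == 2, age_range[1] <= age_range[2],
            sex_ratio >= 0, sex_ratio <= 1)
  if (anyDuplicated(groups)) stop("duplicate group labels", call. = FALSE)
  if (duration * fs < 2 * 2 * fs) {
    stop("recording must cover at least two 2-s analysis windows", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         age_range = age_range, sex_ratio = sex_ratio,
         n_parcels = as.integer(n_parcels), fs = fs, duration = duration,
         scanners = scanners, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Ground truth for the synthetic spectral model
#'
#' Each parcel time course is built as aperiodic 1/f^chi background noise plus
#' oscillatory components, each a narrow-band carrier multiplied by a slow
#' positive amplitude envelope.  Within a subject, each component's envelope is
#' a mixture `w * shared + (1 - w) * independent` of a process shared across
#' the parcels carrying that component and a parcel-specific process, so the
#' envelope-sharing weight `w` sets the amplitude-envelope correlation between
#' those parcels.
#'
#' Covariate effects are linear and additive on the aperiodic exponent, on
#' log10 component amplitude, and on component centre frequency, matching the
#' linear model used downstream for inference.
#'
#' @param n_parcels Number of parcels the truth describes.
#' @param exponent Aperiodic exponent chi (scalar, recycled, or per parcel);
#'   the log10-log10 PSD slope magnitude. Must be >= 0.
#' @param offset Aperiodic offset in log10 power (cosmetic once time courses
#'   are z-scored; kept for completeness).
#' @param components Tibble with one row per oscillatory component: `name`,
#'   `cf` (centre frequency, Hz), `bw` (spectral bandwidth, Hz), `amp`
#'   (amplitude in units of background SD), `share_w` (envelope-sharing
#'   weight in `[0, 1]`), and optionally a `parcels` list-column of parcel
#'   indices carrying the component (`NULL` = all parcels).
#' @param effects Tibble of covariate effects with columns `covariate`
#'   (`"age"`, `"sex"`, `"gm_volume"`, or `"group:<label>"` for a group
#'   indicator), `target` (`"exponent"`, `"log_amp"` or `"cf"`), `component`
#'   (component name; `NA` for exponent effects) and `value` (effect per unit
#'   of the covariate; age is centred at the cohort age-range midpoint before
#'   application).
#'
#' @return An object of class `ground_truth`.
#' @examples
#' ground_truth(n_parcels = 4, exponent = 1.2)
#' @export
ground_truth <- function(n_parcels = 52, exponent = 1.2, offset = 0,
                         components = default_components(),
                         effects = NULL) {
  exponent <- rep_len(exponent, n_parcels)
  stopifnot(all(exponent >= 0))
  if (!is.null(components) && nrow(components)) {
    stopifnot(all(components$amp >= 0),
              all(components$share_w >= 0 & components$share_w <= 1),
              all(components$cf > 0), all(components$bw > 0),
              !anyDuplicated(components$name))
    if (!"parcels" %in% names(components)) {
      components$parcels <- vector("list", nrow(components))
    }
  } else {
    components <- default_components()[0, ]
    components$parcels <- list()
  }
  if (is.null(effects)) {
    effects <- tibble::tibble(covariate = character(), target = character(),
                              component = character(), value = numeric())
  }
  bad <- setdiff(effects$target, c("exponent", "log_amp", "cf"))
  if (length(bad)) stop("unknown effect target(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(n_parcels = as.integer(n_parcels), exponent = exponent,
         offset = offset, components = components, effects = effects),
    class = "ground_truth"
  )
}

#' Default oscillatory components
#'
#' An alpha component at 10 Hz and a beta component at 20 Hz carried by every
#' parcel, with moderate envelope sharing.  Amplitudes are in units of the
#' aperiodic background SD.
#'
#' @return A tibble of components suitable for [ground_truth()].
#' @export
default_components <- function() {
  tibble::tibble(
    name    = c("alpha", "beta"),
    cf      = c(10, 20),
    bw      = c(2.4, 5),
    amp     = c(0.9, 0.6),
    share_w = c(0.5, 0.5)
  )
}

#' Default covariate effects emulating ageing and neurodegeneration
#'
#' Effect directions observed in resting-state MEG cohorts: with age, beta
#' amplitude rises and the aperiodic exponent falls (spectral flattening);
#' a neurodegeneration-like group (`"AD"` by default) shows reduced beta
#' amplitude, an increased exponent and a leftward alpha peak shift
#' (oscillatory slowing).  Magnitudes are chosen to give effects of roughly
#' 1-2 within-group SD at the default recording length.
#'
#' @param group Label of the affected group.
#' @return An effects tibble for [ground_truth()].
#' @export
default_effects <- function(group = "AD") {
  g <- paste0("group:", group)
  tibble::tibble(
    covariate = c("age", "age", g, g, g),
    target    = c("log_amp", "exponent", "log_amp", "exponent", "cf"),
    component = c("beta", NA, "beta", NA, "alpha"),
    value     = c(0.004, -0.004, -0.06, 0.15, -1.0)
  )
}

# Deterministic per-subject sub-seed below 2^31.
subject_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(idx) * 9973) %% 2147483629)
}

# Effective (covariate-adjusted) truth parameters for one subject.
# cov_row: one-row data frame with age, sex ("M"/"F"), group, gm_volume.
# age_mid: centre used for the age covariate.
effective_truth <- function(truth, cov_row, age_mid) {
  cov_value <- function(name) {
    if (name == "age") return(cov_row$age - age_mid)
    if (name == "sex") return(as.numeric(cov_row$sex == "M"))
    if (name == "gm_volume") return(cov_row$gm_volume)
    if (startsWith(name, "group:")) {
      return(as.numeric(cov_row$group == sub("^group:", "", name)))
    }
    stop("unknown covariate in effects: ", name, call. = FALSE)
  }
  exponent <- truth$exponent
  comps <- truth$components
  if (nrow(truth$effects)) {
    for (i in seq_len(nrow(truth$effects))) {
      ef <- truth$effects[i, ]
      x <- cov_value(ef$covariate)
      if (ef$target == "exponent") {
        exponent <- exponent + ef$value * x
      } else {
        j <- match(ef$component, comps$name)
        if (is.na(j)) stop("effect references unknown component '",
                           ef$component, "'", call. = FALSE)
        if (ef$target == "log_amp") {
          comps$amp[j] <- comps$amp[j] * 10^(ef$value * x)
        } else {
          comps$cf[j] <- comps$cf[j] + ef$value * x
        }
      }
    }
  }
  if (any(exponent < 0)) {
    warning("covariate effects drove an exponent below 0; clipped")
    exponent <- pmax(exponent, 0)
  }
  if (nrow(comps) && any(comps$cf < 0.5)) {
    warning("covariate effects drove a centre frequency below 0.5 Hz; clipped")
    comps$cf <- pmax(comps$cf, 0.5)
  }
  list(exponent = exponent, components = comps)
}

# Colour white noise to a target PSD shape: proportional to f^(-chi) above
# 1 Hz and flat below; output scaled to unit variance.
shaped_noise <- function(n, fs, chi) {
  f <- fft_freqs(n, fs)
  shape <- ifelse(abs(f) >= 1, abs(f)^(-chi / 2), 1)
  shape[1] <- 0  # no DC
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE))
  x / stats::sd(x)
}

# Narrow-band carrier: Gaussian spectral profile centred at cf, SD bw/2.
narrowband_carrier <- function(n, fs, cf, bw) {
  f <- fft_freqs(n, fs)
  shape <- exp(-((abs(f) - cf)^2) / (2 * (bw / 2)^2))
  shape[1] <- 0
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE))
  x / stats::sd(x)
}

# Slow unit-SD Gaussian process: white noise low-passed below `cutoff` Hz.
slow_process <- function(n, fs, cutoff = 1) {
  f <- fft_freqs(n, fs)
  keep <- abs(f) < cutoff & abs(f) > 0
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * keep, inverse = TRUE))
  x / stats::sd(x)
}

# Two-sided FFT frequency grid for length n at rate fs.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Simulate one subject's parcel time courses
#'
#' Generates spectrally shaped aperiodic noise per parcel plus each
#' oscillatory component as a band-limited carrier modulated by a positive
#' slow envelope, mixes shared and independent envelopes by the component's
#' sharing weight, applies covariate effects from the ground truth, and
#' z-scores each parcel.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [ground_truth()] with `n_parcels` matching `spec`.
#' @param cov_row One-row data frame of this subject's covariates
#'   (`subject_id`, `group`, `age`, `sex`, `gm_volume`).
#' @param subject_index 1-based index used to derive the deterministic
#'   per-subject sub-seed from `spec$seed`.
#'
#' @return A `parcel_timecourses` object: list with `subject_id`,
#'   `timecourses` (parcels x samples matrix), `fs`, and `parcels` labels.
#' @export
simulate_subject <- function(spec, truth, cov_row, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"),
            truth$n_parcels == spec$n_parcels)
  n <- round(spec$duration * spec$fs)
  if (n <= 0) stop("non-positive recording length", call. = FALSE)
  set.seed(subject_seed(spec$seed, subject_index))

  eff <- effective_truth(truth, cov_row, mean(spec$age_range))
  comps <- eff$components
  # One shared envelope process per component, common to this subject's
  # parcels; drawn first so parcel order cannot perturb it.
  shared <- lapply(seq_len(nrow(comps)),
                   function(i) slow_process(n, spec$fs))

  tc <- matrix(0, nrow = spec$n_parcels, ncol = n)
  for (p in seq_len(spec$n_parcels)) {
    x <- shaped_noise(n, spec$fs, eff$exponent[p])
    if (nrow(comps)) {
      for (i in seq_len(nrow(comps))) {
        carries <- is.null(comps$parcels[[i]]) || p %in% comps$parcels[[i]]
        if (!carries || comps$amp[i] <= 0) next
        w <- comps$share_w[i]
        own <- slow_process(n, spec$fs)
        env <- pmax(1 + w * shared[[i]] + (1 - w) * own, 0)
        osc <- narrowband_carrier(n, spec$fs, comps$cf[i], comps$bw[i]) * env
        x <- x + comps$amp[i] * osc / stats::sd(osc)
      }
    }
    tc[p, ] <- (x - mean(x)) / stats::sd(x)
  }
  rownames(tc) <- parcel_labels(spec$n_parcels)
  structure(
    list(subject_id = cov_row$subject_id, timecourses = tc, fs = spec$fs,
         parcels = rownames(tc)),
    class = "parcel_timecourses"
  )
}

parcel_labels <- function(n) sprintf("parcel_%02d", seq_len(n))

#' Simulate a full cohort with known ground truth
#'
#' Samples covariates per the cohort spec (ages uniform over the range, sex
#' Bernoulli at the requested male fraction, scanner uniform over scanner
#' types, grey-matter volume linear in age plus Gaussian noise) and generates
#' every subject's parcel time courses from the ground truth.  With a fixed
#' `spec$seed` the whole cohort is reproduced identically.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [ground_truth()].
#'
#' @return A list of class `synthetic_cohort`: `subjects` (list of
#'   `parcel_timecourses`), `covariates` (tibble: subject_id, group, age,
#'   sex, scanner, gm_volume), `truth` and `spec`.
#' @examples
#' spec <- cohort_spec(n_per_group = 2, groups = c("HC", "AD"),
#'                     n_parcels = 4, duration = 20, seed = 7)
#' cohort <- simulate_cohort(spec, ground_truth(n_parcels = 4))
#' cohort$covariates
#' @export
simulate_cohort <- function(spec, truth = ground_truth(spec$n_parcels)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- spec$n_per_group * length(spec$groups)
  set.seed(spec$seed)
  covariates <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    group = rep(spec$groups, each = spec$n_per_group),
    age = stats::runif(n_sub, spec$age_range[1], spec$age_range[2]),
    sex = ifelse(stats::rbinom(n_sub, 1, spec$sex_ratio) == 1, "M", "F"),
    scanner = sample(spec$scanners, n_sub, replace = TRUE),
    gm_volume = NA_real_
  )
  # Grey matter shrinks roughly linearly with age in later adulthood.
  covariates$gm_volume <- 780 - 2.2 * (covariates$age - 60) +
    stats::rnorm(n_sub, sd = 25)

  subjects <- purrr::map(seq_len(n_sub), function(i) {
    simulate_subject(spec, truth, covariates[i, ], i)
  })
  names(subjects) <- covariates$subject_id
  structure(
    list(subjects = subjects, covariates = covariates, truth = truth,
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' Expected Welch band power under the synthetic model
#'
#' Deterministic mapping from ground-truth parameters and a subject's
#' covariates to the expected Welch mean spectral density in a band, for a
#' standardised time course.  The expectation combines the normalised
#' aperiodic shape (`f^-chi` above 1 Hz, flat below) with each component's
#' Gaussian spectral profile weighted by its squared effective amplitude.
#' When the pipeline band-pass filters before re-standardising (the default
#' preprocessing), the out-of-band variance is removed and the retained
#' densities inflate accordingly; `filter_range` reproduces that
#' renormalisation.  Used as the analytic truth in effect-recovery checks.
#'
#' @param truth A [ground_truth()].
#' @param covariates Covariate tibble (one row per subject).
#' @param band Band name or `(lo, hi)` pair.
#' @param spec The [cohort_spec()] supplying fs and the age centring.
#' @param parcel Parcel index at which to evaluate (default 1).
#' @param window_s Welch window length in seconds (sets the frequency grid).
#' @param filter_range Band edges of the preprocessing filter, Hz (default
#'   `c(1, 80)` matching [preprocess_subject()]); `NULL` for unfiltered data.
#'
#' @return Numeric vector of expected mean densities, one per subject.
#' @export
expected_band_power <- function(truth, covariates, band, spec,
                                parcel = 1, window_s = 2,
                                filter_range = c(1, 80)) {
  b <- resolve_band(band)
  f <- seq(0, spec$fs / 2, by = 1 / window_s)
  df <- 1 / window_s
  vapply(seq_len(nrow(covariates)), function(i) {
    eff <- effective_truth(truth, covariates[i, ], mean(spec$age_range))
    ap <- ifelse(f >= 1, f^(-eff$exponent[parcel]), 1)
    ap[1] <- 0
    dens <- ap / (sum(ap) * df)          # unit-variance background
    comps <- eff$components
    for (j in seq_len(nrow(comps))) {
      carries <- is.null(comps$parcels[[j]]) || parcel %in% comps$parcels[[j]]
      if (!carries || comps$amp[j] <= 0) next
      g <- exp(-((f - comps$cf[j])^2) / ((comps$bw[j] / 2)^2))
      dens <- dens + comps$amp[j]^2 * g / (sum(g) * df)
    }
    if (!is.null(filter_range)) {
      # forward-backward order-5 Butterworth power response of the
      # preprocessing filter (amplitude |H|^2, power |H|^4)
      bf <- signal::butter(5, filter_range / (spec$fs / 2), type = "pass")
      w <- 2 * pi * f / spec$fs
      E_b <- exp(-1i * outer(w, seq_along(bf$b) - 1))
      E_a <- exp(-1i * outer(w, seq_along(bf$a) - 1))
      H <- as.vector(E_b %*% bf$b) / as.vector(E_a %*% bf$a)
      dens <- dens * Mod(H)^4
    }
    # standardisation after (optional) filtering forces unit total variance
    dens <- dens / (sum(dens) * df)
    sel <- f >= b$lo & f < b$hi
    mean(dens[sel])
  }, numeric(1))
}
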