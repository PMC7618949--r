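test_that("an exact aperiodic spectrum is recovered with no peaks", {
  fit <- parameterize_spectrum(synth_psd(offset = 0.5, chi = 1.5))
  expect_equal(fit$exponent, 1.5, tolerance = 0.01)
  expect_equal(fit$offset, 0.5, tolerance = 0.01)
  expect_equal(nrow(fit$peaks), 0)
  expect_lt(fit$fit_error, 1e-6)
  # periodic spectrum of a pure aperiodic input is ~0 everywhere
  expect_lt(max(abs(fit$periodic)), 1e-6)
})

test_that("a single Gaussian peak is recovered, cross-checked by a grid-search oracle", {
  peaks <- tibble::tibble(cf = 10, pw = 0.5, bw = 2)
  psd <- synth_psd(offset = 0.5, chi = 1.5, peaks = peaks)
  fit <- parameterize_spectrum(psd)
  expect_equal(nrow(fit$peaks), 1)
  expect_equal(fit$peaks$cf, 10, tolerance = 0.25)
  expect_equal(fit$peaks$pw, 0.5, tolerance = 0.05)
  expect_equal(fit$exponent, 1.5, tolerance = 0.02)

  oracle <- gaussian_grid_oracle(psd)
  expect_lt(abs(fit$peaks$cf - oracle$cf), 0.25)
  expect_lt(abs(fit$peaks$pw - oracle$pw), 0.05)
})

test_that("peaks below the minimum height are not retained", {
  psd <- synth_psd(peaks = tibble::tibble(cf = 10, pw = 0.02, bw = 2))
  fit <- parameterize_spectrum(psd)
  expect_equal(nrow(fit$peaks), 0)
})

test_that("exponent accessor behaves on flat, steep and rescaled spectra", {
  flat <- parameterize_spectrum(synth_psd(offset = 0, chi = 0))
  expect_equal(exponent(flat), 0, tolerance = 0.01)

  fits <- vapply(c(0.5, 1, 2), function(chi)
    exponent(parameterize_spectrum(synth_psd(chi = chi))), numeric(1))
  expect_equal(fits, c(0.5, 1, 2), tolerance = 0.01)
  expect_true(all(diff(fits) > 0))

  base <- synth_psd(offset = 0.5, chi = 1.2)
  scaled <- list(freqs = base$freqs, density = 100 * base$density)
  f1 <- parameterize_spectrum(base)
  f2 <- parameterize_spectrum(scaled)
  expect_equal(exponent(f2), exponent(f1), tolerance = 1e-6)
  expect_equal(f2$offset - f1$offset, 2, tolerance = 1e-6)

  expect_error(parameterize_spectrum(list(freqs = base$freqs,
                                          density = -base$density)),
               "non-positive")
})

test_that("centre of energy sits at a symmetric peak and follows the smallest-crossing rule", {
  one <- parameterize_spectrum(
    synth_psd(peaks = tibble::tibble(cf = 10, pw = 0.6, bw = 2)))
  expect_lt(abs(centre_of_energy(one) - 10), 0.25)

  # two equal-power narrow peaks: the >= (smallest-crossing) convention
  # assigns the equal-split point to the lower peak
  two <- one
  two$periodic <- numeric(length(two$freqs))
  two$periodic[two$freqs %in% c(8, 20)] <- 0.6
  cum <- cumsum(pmax(two$periodic, 0)) / sum(pmax(two$periodic, 0))
  oracle <- two$freqs[which(cum >= 0.5)[1]]   # cumulative-sum oracle
  expect_equal(oracle, 8)
  expect_lt(abs(centre_of_energy(two) - 8), 0.5)

  # leftward peak shift strictly decreases the CoE (oscillatory slowing)
  at8 <- parameterize_spectrum(
    synth_psd(peaks = tibble::tibble(cf = 8, pw = 0.6, bw = 2)))
  expect_lt(centre_of_energy(at8), centre_of_energy(one))

  # invariant to rescaling the periodic spectrum
  sc <- one
  sc$periodic <- 3.7 * one$periodic
  expect_equal(centre_of_energy(sc), centre_of_energy(one))

  # no periodic power -> missing
  none <- parameterize_spectrum(synth_psd())
  none$periodic <- rep(0, length(none$freqs))
  expect_true(is.na(centre_of_energy(none)))
})

test_that("refitting a synthesised spectrum round-trips the parameters", {
  truth <- tibble::tibble(cf = c(10, 22), pw = c(0.5, 0.3), bw = c(2, 3))
  fit <- parameterize_spectrum(synth_psd(offset = 0.3, chi = 1.1,
                                         peaks = truth))
  resynth <- list(freqs = fit$freqs, density = 10^fit$fitted_log)
  refit <- parameterize_spectrum(resynth)
  expect_equal(refit$exponent, fit$exponent, tolerance = 0.02)
  expect_equal(refit$offset, fit$offset, tolerance = 0.02)
  expect_equal(nrow(refit$peaks), nrow(fit$peaks))
  expect_equal(sort(refit$peaks$cf), sort(fit$peaks$cf), tolerance = 0.25)
})

test_that("band peak selection takes the highest power and breaks ties low", {
  # peaks narrow enough to stay bimodal (heavily overlapping Gaussians merge
  # into one bump for any residual-peak extractor)
  fit <- parameterize_spectrum(
    synth_psd(peaks = tibble::tibble(cf = c(9, 11), pw = c(0.3, 0.5),
                                     bw = 1.5)))
  sel <- select_band_peak(fit, "alpha")
  expect_lt(abs(sel$freq - 11), 0.25)
  expect_lt(abs(sel$power - 0.5), 0.05)
  expect_true(is.na(select_band_peak(fit, "beta")$freq))

  single <- parameterize_spectrum(
    synth_psd(peaks = tibble::tibble(cf = 10, pw = 0.4, bw = 2)))
  expect_equal(select_band_peak(single, "alpha")$freq, 10, tolerance = 0.25)

  # tie broken towards the lower frequency
  fake <- single
  fake$peaks <- tibble::tibble(cf = c(9, 11), pw = c(0.4, 0.4), bw = 2)
  expect_equal(select_band_peak(fake, "alpha")$freq, 9)
})

test_that("peak imputation fills missing cells with the participant mean", {
  tbl <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    parcel = "p1",
    band = rep(c("alpha", "beta"), 3),
    freq = c(10, 20, 12, NA, NA, 22),
    power = c(0.5, 0.2, 0.3, NA, NA, 0.4)
  )
  imp <- impute_missing_peaks(tbl)
  expect_equal(imp$freq[imp$subject_id == "c" & imp$band == "alpha"], 11)
  expect_equal(imp$freq[imp$subject_id == "b" & imp$band == "beta"], 21)
  expect_true(all(imp$imputed == is.na(tbl$freq)))
  # non-missing values untouched; their mean unchanged
  expect_equal(imp$freq[!imp$imputed], tbl$freq[!is.na(tbl$freq)])

  # no missing -> identity
  full <- tbl[!is.na(tbl$freq), ]
  expect_equal(impute_missing_peaks(full)$freq, full$freq)

  # an all-missing cell stays missing with a warning
  allna <- tibble::tibble(subject_id = c("a", "b"), parcel = "p1",
                          band = "alpha", freq = NA_real_, power = NA_real_)
  expect_warning(out <- impute_missing_peaks(allna), "no detected peak")
  expect_true(all(is.na(out$freq)))
})

test_that("missing-peak counts match imputed cells", {
  tbl <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 3),
    parcel = rep(c("p1", "p2", "p3"), 2),
    band = "beta",
    freq = c(20, NA, NA, 21, 22, 23),
    power = c(0.2, NA, NA, 0.3, 0.2, 0.1)
  )
  counts <- count_missing_peaks(tbl)
  expect_equal(counts$n_missing[counts$subject_id == "a"], 2)
  expect_equal(counts$n_missing[counts$subject_id == "b"], 0)
  imp <- impute_missing_peaks(tbl)
  expect_equal(sum(imp$imputed), sum(counts$n_missing))
})

test_that("tidy and glance summarise a spectral fit", {
  fit <- parameterize_spectrum(
    synth_psd(peaks = tibble::tibble(cf = 10, pw = 0.5, bw = 2)))
  expect_named(tidy(fit), c("cf", "pw", "bw"))
  g <- glance(fit)
  expect_equal(g$n_peaks, 1)
  expect_equal(g$exponent, 1.5, tolerance = 0.02)
  expect_equal(g$coe, 10, tolerance = 0.25)
})
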