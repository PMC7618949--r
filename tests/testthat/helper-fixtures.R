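# Shared fixtures: everything is generated in code at test time.

# A small cohort for structural tests: 2 groups, few parcels, short records.
tiny_cohort <- function(n_per_group = 2, n_parcels = 4, duration = 30,
                        seed = 42, truth = NULL, groups = c("HC", "AD")) {
  spec <- cohort_spec(n_per_group = n_per_group, groups = groups,
                      n_parcels = n_parcels, duration = duration, seed = seed)
  if (is.null(truth)) truth <- ground_truth(n_parcels)
  simulate_cohort(spec, truth)
}

# Exact synthetic log10 PSD on a 0.5 Hz grid: aperiodic line plus optional
# Gaussian peaks given as rows (cf, pw, bw).
synth_psd <- function(offset = 0.5, chi = 1.5, peaks = NULL,
                      f = seq(1, 70, by = 0.5)) {
  y <- offset - chi * log10(f)
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      y <- y + peaks$pw[i] *
        exp(-((f - peaks$cf[i])^2) / (2 * (peaks$bw[i] / 2)^2))
    }
  }
  list(freqs = f, density = 10^y)
}

# Independent oracle for the aperiodic slope: least-squares line on
# log10 density vs log10 frequency over [lo, hi].
slope_oracle <- function(x, fs, lo = 2, hi = 40) {
  psd <- welch_psd(zscore_timecourse(x), fs)
  sel <- psd$freqs >= lo & psd$freqs <= hi
  unname(coef(lm(log10(psd$density[sel, 1]) ~ log10(psd$freqs[sel])))[2])
}

# Independent oracle for single-Gaussian recovery: grid search over
# (cf, pw, bw); for each candidate Gaussian the aperiodic line is the exact
# least-squares fit of the remainder, so the oracle is full joint least
# squares on a lattice.
gaussian_grid_oracle <- function(psd) {
  f <- psd$freqs
  y <- log10(psd$density)
  X <- cbind(1, log10(f))
  grid <- expand.grid(cf = seq(6, 28, by = 0.25),
                      pw = seq(0.1, 1, by = 0.05),
                      bw = seq(1, 4, by = 0.5))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid$pw[i] * exp(-((f - grid$cf[i])^2) / (2 * (grid$bw[i] / 2)^2))
    sum(lm.fit(X, y - g)$residuals^2)
  }, numeric(1))
  grid[which.min(sse), ]
}

# Covariate table with no simulation attached, for design/GLM tests.
fake_records <- function(n_per_group = 10, groups = c("HC", "AD"),
                         seed = 1, scanners = c("A", "B")) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(groups, each = n_per_group),
    age = runif(n, 50, 80),
    sex = sample(c("M", "F"), n, replace = TRUE),
    scanner = sample(scanners, n, replace = TRUE),
    gm_volume = rnorm(n, 780, 25)
  )
}
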