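#' Compute the full metric table for a cohort
#'
#' Runs the metric stack over every subject: optional preprocessing
#' (band-pass + bad-segment removal + re-standardisation), Welch PSD, band
#' powers, spectral parameterisation (exponent, centre of energy, alpha/beta
#' peak selection with cohort-mean imputation) and band-wise global AEC
#' connectivity.
#'
#' @param cohort A `synthetic_cohort` or list with `subjects` (list of
#'   `parcel_timecourses`) and `covariates`.
#' @param metrics Which metric families to compute: any of `"power"`,
#'   `"specparam"`, `"aec"`.
#' @param bands Band definition tibble (default [canonical_bands()]).
#' @param preprocess Apply [preprocess_subject()] first (default TRUE).
#' @param window_s Welch window length, seconds.
#' @param aec_bands Bands for connectivity (default all of `bands`).
#' @param ... Passed to [parameterize_spectrum()].
#' @return A `metric_table`: list with `metrics` (long tibble: subject_id,
#'   parcel, metric, band, value, imputed), `peaks` (pre-imputation peak
#'   table) and `missing_peaks` (per-subject missing-peak counts).
#' @export
compute_metrics <- function(cohort, metrics = c("power", "specparam", "aec"),
                            bands = canonical_bands(), preprocess = TRUE,
                            window_s = 2, aec_bands = bands$band, ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- list()
  peak_rows <- list()
  for (id in names(cohort$subjects)) {
    subj <- cohort$subjects[[id]]
    if (preprocess) {
      subj <- with_stage("preprocess", id, preprocess_subject(subj))
    }
    psd <- with_stage("welch", id,
                      welch_psd(subj$timecourses, subj$fs, window_s))
    if ("power" %in% metrics) {
      bp <- band_power_table(psd, bands)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = id, parcel = bp$parcel, metric = "power",
        band = bp$band, value = bp$power)
    }
    if ("specparam" %in% metrics) {
      for (p in seq_len(ncol(psd$density))) {
        fit <- with_stage("specparam", id, parameterize_spectrum(
          list(freqs = psd$freqs, density = psd$density[, p]), ...))
        lab <- colnames(psd$density)[p]
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = id, parcel = lab,
          metric = c("exponent", "coe"), band = NA_character_,
          value = c(exponent(fit), centre_of_energy(fit)))
        for (bnd in c("alpha", "beta")) {
          pk <- select_band_peak(fit, bnd)
          peak_rows[[length(peak_rows) + 1]] <- tibble::tibble(
            subject_id = id, parcel = lab, band = bnd,
            freq = pk$freq, power = pk$power)
        }
      }
    }
    if ("aec" %in% metrics) {
      for (bnd in aec_bands) {
        gc <- with_stage("aec", id, global_connectivity(
          aec_matrix(subj$timecourses, subj$fs, bnd)))
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = id, parcel = gc$parcel, metric = "global_aec",
          band = bnd, value = gc$global_aec)
      }
    }
  }
  metrics_tbl <- dplyr::bind_rows(rows)
  metrics_tbl$imputed <- FALSE
  peaks <- dplyr::bind_rows(peak_rows)
  missing <- NULL
  if (nrow(peaks)) {
    missing <- count_missing_peaks(peaks)
    imp <- impute_missing_peaks(peaks)
    peak_metrics <- imp |>
      tidyr::pivot_longer(c("freq", "power"), names_to = "which",
                          values_to = "value") |>
      dplyr::mutate(metric = paste0(.data$band, "_peak_", .data$which),
                    band = NA_character_) |>
      dplyr::select("subject_id", "parcel", "metric", "band", "value",
                    "imputed")
    metrics_tbl <- dplyr::bind_rows(metrics_tbl, peak_metrics)
    miss_metrics <- missing |>
      dplyr::transmute(subject_id = .data$subject_id, parcel = "all",
                       metric = paste0("missing_", .data$band, "_peaks"),
                       band = NA_character_,
                       value = as.numeric(.data$n_missing), imputed = FALSE)
    metrics_tbl <- dplyr::bind_rows(metrics_tbl, miss_metrics)
  }
  structure(list(metrics = metrics_tbl, peaks = peaks,
                 missing_peaks = missing,
                 covariates = cohort$covariates),
            class = "metric_table")
}

# Run an expression as a named pipeline stage; failures abort with the stage
# and subject so partial runs are diagnosable.
with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed for subject ", subject_id, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.metric_table <- function(x, ...) {
  cat("<metric_table> ", dplyr::n_distinct(x$metrics$subject_id),
      " subjects, ",
      dplyr::n_distinct(setdiff(x$metrics$parcel, "all")), " parcels, ",
      "metrics: ", paste(unique(x$metrics$metric), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a metric table
#'
#' @param x A `metric_table`.
#' @param ... Unused.
#' @return The long metrics tibble.
#' @export
tidy.metric_table <- function(x, ...) x$metrics

#' Reshape metrics into a subjects x cells matrix for the GLM
#'
#' Each column is one (metric, band, parcel) cell, named
#' `metric|band|parcel`; rows follow the covariate table's subject order.
#' Cells that are missing for any subject (e.g. a never-detected peak) are
#' dropped with a warning.
#'
#' @param mt A `metric_table`.
#' @param metrics Metric names to include (default: all present).
#' @param bands Bands to include for banded metrics (default: all present).
#' @return Numeric matrix, subjects x cells.
#' @export
metric_matrix <- function(mt, metrics = NULL, bands = NULL) {
  tbl <- mt$metrics
  if (!is.null(metrics)) tbl <- tbl[tbl$metric %in% metrics, ]
  if (!is.null(bands)) tbl <- tbl[is.na(tbl$band) | tbl$band %in% bands, ]
  tbl$cell <- paste(tbl$metric, ifelse(is.na(tbl$band), "-", tbl$band),
                    tbl$parcel, sep = "|")
  wide <- tbl |>
    dplyr::select("subject_id", "cell", "value") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
  ord <- match(mt$covariates$subject_id, wide$subject_id)
  Y <- as.matrix(wide[ord, -1])
  rownames(Y) <- mt$covariates$subject_id
  bad <- colSums(is.na(Y)) > 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " cell(s) with missing values")
    Y <- Y[, !bad, drop = FALSE]
  }
  Y
}

#' Write / read a simulated cohort on disk
#'
#' Layout: `subjects/<id>.rds` (one parcels x samples matrix with fs and
#' parcel labels), `covariates.csv`, `ground_truth.json`.  Round-trip
#' preserves integers exactly and floats bit-for-bit (RDS) / to 1e-12 (CSV).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    saveRDS(cohort$subjects[[id]], file.path(dir, "subjects",
                                             paste0(id, ".rds")))
  }
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(n_parcels = truth$n_parcels, exponent = truth$exponent,
         offset = truth$offset, components = truth$components,
         effects = truth$effects),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param check_complete Error if a subject listed in the covariates has no
#'   data file (default TRUE).
#' @export
read_cohort <- function(dir, check_complete = TRUE) {
  cov <- readr::read_csv(file.path(dir, "covariates.csv"),
                         show_col_types = FALSE)
  required <- c("subject_id", "group", "age", "sex", "scanner", "gm_volume")
  missing_cols <- setdiff(required, names(cov))
  if (length(missing_cols)) {
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(cov[required])) {
    bad <- which(rowSums(is.na(cov[required])) > 0)
    stop("missing covariate values in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  subjects <- list()
  for (id in cov$subject_id) {
    path <- file.path(dir, "subjects", paste0(id, ".rds"))
    if (!file.exists(path)) {
      if (check_complete) stop("no data file for subject ", id, call. = FALSE)
      next
    }
    s <- readRDS(path)
    if (is.null(s$fs)) stop("sampling rate missing for subject ", id,
                            call. = FALSE)
    if (length(s$parcels) != nrow(s$timecourses)) {
      stop("parcel label count does not match matrix rows for subject ", id,
           call. = FALSE)
    }
    subjects[[id]] <- s
  }
  list(subjects = subjects, covariates = cov)
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by [run_pipeline()].
#' Can also be loaded from YAML with [load_config()].
#'
#' @param output_dir Where all stage outputs are written.
#' @param seed Root seed; all stage randomness derives from it.
#' @param cohort Named list of [cohort_spec()] arguments.
#' @param metrics Metric families to compute.
#' @param bands Character vector of band names (must be canonical).
#' @param analyses GLM analyses to run (see [build_design()]).
#' @param glm_metrics Metric families entering each GLM (default `"power"`).
#' @param n_perm Permutations for the max-t null.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1,
                            cohort = list(n_per_group = 10,
                                          groups = c("HC", "AD"),
                                          n_parcels = 8, duration = 60),
                            metrics = c("power", "specparam", "aec"),
                            bands = canonical_bands()$band,
                            analyses = "group_compare",
                            glm_metrics = "power",
                            n_perm = 1000) {
  config <- list(output_dir = output_dir, seed = as.integer(seed),
                 cohort = cohort, metrics = metrics, bands = bands,
                 analyses = analyses, glm_metrics = glm_metrics,
                 n_perm = as.integer(n_perm))
  validate_config(config)
}

#' @rdname pipeline_config
#' @param path YAML file with the same fields.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

validate_config <- function(config) {
  required <- c("output_dir", "seed", "cohort", "metrics", "bands",
                "analyses", "n_perm")
  missing_f <- setdiff(required, names(config))
  if (length(missing_f)) {
    stop("config lacks field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(config$bands, canonical_bands()$band)
  if (length(unknown)) {
    stop("unknown band name(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad_an <- setdiff(config$analyses,
                    c("ageing", "group_compare", "beta_ageing_by_group"))
  if (length(bad_an)) {
    stop("unknown analysis: ", paste(bad_an, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$glm_metrics)) config$glm_metrics <- "power"
  structure(config, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulate (or reuse) a cohort, compute the metric table, run the requested
#' permutation GLMs and write everything under the configured output
#' directory: `covariates.csv`, per-subject data, `metrics.csv`, one
#' `glm_<analysis>.tsv` per analysis and a `manifest.json` recording the
#' config hash, seed and MD5 checksums of every output.  Identical config and
#' seed reproduce identical checksums.
#'
#' @param config A `pipeline_config`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  truth <- if (!is.null(config$truth)) config$truth else
    ground_truth(spec$n_parcels)
  cohort <- simulate_cohort(spec, truth)
  write_cohort(cohort, config$output_dir)

  bands <- canonical_bands()[canonical_bands()$band %in% config$bands, ]
  mt <- compute_metrics(cohort, metrics = config$metrics, bands = bands,
                        aec_bands = bands$band)
  readr::write_csv(mt$metrics, file.path(config$output_dir, "metrics.csv"))

  results <- list()
  for (analysis in config$analyses) {
    design <- build_design(cohort$covariates, analysis)
    Y <- metric_matrix(mt, metrics = config$glm_metrics)
    res <- maxt_permutation(Y, design, n_perm = config$n_perm,
                            seed = config$seed + 1L)
    out <- tidy(res)
    readr::write_tsv(out, file.path(config$output_dir,
                                    paste0("glm_", analysis, ".tsv")))
    results[[analysis]] <- res
  }

  files <- list.files(config$output_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("megmetrics")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(manifest = manifest, metrics = mt, glm = results))
}
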