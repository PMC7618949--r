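#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectral density
#'
#' Log10 density against frequency, one line per parcel.
#'
#' @param object A `parcel_psd`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parcel_psd <- function(object, ...) {
  labels <- colnames(object$density)
  if (is.null(labels)) labels <- sprintf("parcel_%02d",
                                         seq_len(ncol(object$density)))
  df <- tibble::tibble(
    freq = rep(object$freqs, times = ncol(object$density)),
    density = as.vector(object$density),
    parcel = rep(labels, each = length(object$freqs))
  ) |> dplyr::filter(.data$freq > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$density,
                                   colour = .data$parcel)) +
    ggplot2::geom_line(show.legend = ncol(object$density) <= 8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power density (1/Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a spectral parameterisation
#'
#' The observed log10 spectrum, the fitted aperiodic component and the full
#' (aperiodic + peaks) model over the fit range.
#'
#' @param object A `spectral_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_fit <- function(object, ...) {
  ap <- object$offset - object$exponent * log10(object$freqs)
  df <- tibble::tibble(
    freq = rep(object$freqs, 3),
    value = c(object$log_density, ap, object$fitted_log),
    component = rep(c("observed", "aperiodic", "model"),
                    each = length(object$freqs))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$value,
                                   colour = .data$component,
                                   linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power density") +
    ggplot2::theme_minimal()
}

#' Plot an AEC connectivity matrix
#'
#' @param object An `aec_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map.
#' @export
autoplot.aec_matrix <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(
    from = rep(rownames(m), times = ncol(m)),
    to = rep(colnames(m), each = nrow(m)),
    aec = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$aec)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = paste("AEC,", object$band, "band"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot max-t GLM effects
#'
#' Copes per cell and contrast, with FWE-significant cells highlighted.
#'
#' @param object A `maxt_glm`.
#' @param alpha Significance threshold on the corrected p-value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maxt_glm <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::mutate(significant = .data$p_fwe < alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$cope,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~contrast, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Contrast of parameter estimates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6))
}
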