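# ggplot2 visualizations of the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a probe design report
#'
#' Probe position along the 16S gene against self-fold MFE, sized by Tm and
#' colored by the mismatch margin to the nearest non-target.
#'
#' @param object A `probe_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.probe_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$start, y = .data$self_mfe,
    color = factor(.data$min_mismatch_nontarget), size = .data$tm_c
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "probe 5' position on 16S sense strand (nt)",
      y = "self-fold MFE (kcal/mol)",
      color = "min mismatches\nto non-targets",
      size = "Tm (°C)",
      title = paste0("Passing probes: ", attr(object, "target_species"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an in-silico staining matrix
#'
#' Probes x taxa tile plot of predicted FISH staining.
#'
#' @param object A `stain_matrix` from [predict_staining()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stain_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$taxon, y = .data$probe, fill = .data$stained
  )) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "darkgreen")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "stained") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot QC rejection reasons
#'
#' @param object A `qc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_result <- function(object, ...) {
  df <- tibble::tibble(
    reason = names(object$counts),
    count = as.integer(object$counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reason, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "rejection reason", y = "reads",
      title = sprintf(
        "QC (%s): kept %d / %d", object$profile,
        nrow(object$kept), object$input_n
      )
    ) +
    ggplot2::theme_minimal()
}
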