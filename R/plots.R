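#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Traffic-light plot of an integration report
#'
#' Tiles features (rows) against datasets (columns): filled green/amber/red
#' by the feature's overall status where the dataset carries the feature,
#' grey where it is absent (absence itself demotes the feature to AMBER).
#'
#' @param object A `tgx_integration_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tgx_integration_report
#' @export
autoplot.tgx_integration_report <- function(object, ...) {
  fr <- object$feature_rows
  long <- dplyr::bind_rows(lapply(seq_len(nrow(fr)), function(i) {
    pres <- fr$presence[[i]]
    tibble::tibble(feature = fr$feature[[i]], dataset = names(pres),
                   present = unname(pres), status = fr$status[[i]])
  }))
  long$fill <- ifelse(long$present, long$status, "ABSENT")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$feature,
                                     fill = .data$fill)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.8) +
    ggplot2::scale_fill_manual(values = c(
      GREEN = "#2e7d32", AMBER = "#f9a825", RED = "#c62828",
      ABSENT = "grey80"), name = "status") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Integration consistency by feature and dataset") +
    ggplot2::theme_minimal()
}

#' Proposal-outcome plot of a curation state
#'
#' Stacked bar of proposal statuses per proposal kind — a quick view of how
#' much of the table the vocabulary resolved and how much needed a human.
#'
#' @param object A `tgx_curation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tgx_curation
#' @export
autoplot.tgx_curation <- function(object, ...) {
  p <- object$proposals
  ggplot2::ggplot(p, ggplot2::aes(x = .data$kind, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "proposals",
                  title = sprintf("Curation proposals — dataset '%s'",
                                  dataset_id(object$original))) +
    ggplot2::theme_minimal()
}
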