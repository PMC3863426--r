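#' Bar plot of CNV fraction per phylostratum
#'
#' @param x A `duplirep_report` or a table from [cnv_by_age_table()].
#' @return A ggplot object.
#' @export
plot_cnv_by_age <- function(x) {
  tab <- if (inherits(x, "duplirep_report")) x$cnv_by_age else x
  tab <- dplyr::mutate(
    tab, label = factor(.data$age_class_label,
                        levels = .data$age_class_label[order(.data$age_class)]))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label,
                                    y = .data$cnv_fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Age class (oldest to youngest)",
                  y = "Fraction of genes in CNV regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Box plot of replication-timing rank by phylostratum
#'
#' Larger order-of-replication means later replication; the headline
#' pattern is a rising trend toward younger classes.
#'
#' @param x A `duplirep_report` or its `$master` table.
#' @return A ggplot object.
#' @export
plot_rt_by_age <- function(x) {
  m <- if (inherits(x, "duplirep_report")) x$master else x
  m <- dplyr::filter(m, .data$status == "PDG",
                     !is.na(.data$order_of_replication))
  m$label <- factor(m$age_class_label,
                    levels = unique(m$age_class_label[order(m$age_class)]))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$label,
                                  y = .data$order_of_replication)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = "Age class (oldest to youngest)",
                  y = "Order of replication (rank; larger = later)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a duplirep report
#'
#' @param object A `duplirep_report`.
#' @param type `"cnv_by_age"` (default) or `"rt_by_age"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot duplirep_report
#' @export
autoplot.duplirep_report <- function(object, type = c("cnv_by_age",
                                                      "rt_by_age"), ...) {
  switch(match.arg(type),
         cnv_by_age = plot_cnv_by_age(object),
         rt_by_age = plot_rt_by_age(object))
}
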