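#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' @export
ggplot2::autoplot

#' Bar plot of germline gene usage
#'
#' @param usage A [gene_usage()] tibble.
#' @return A ggplot.
#' @export
plot_gene_usage <- function(usage) {
  ggplot(usage, aes(x = .data$gene, y = .data$freq)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "frequency") +
    ggplot2::theme_minimal()
}

#' Bar plot of a CDRH3 length distribution
#'
#' @param ld A [length_distribution()] tibble.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(ld) {
  ggplot(ld, aes(x = factor(.data$length), y = .data$freq)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "CDRH3 length (aa)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Line plot of a site-specific entropy profile
#'
#' @param profile A [shannon_entropy_profile()] tibble.
#' @return A ggplot.
#' @export
plot_entropy_profile <- function(profile) {
  ggplot(profile, aes(x = .data$position, y = .data$H)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(aes(colour = .data$H), size = 1.5) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "alignment position", y = "Shannon entropy (bits)",
                  colour = "H") +
    ggplot2::theme_minimal()
}

#' Heatmap of a position frequency matrix
#'
#' @param pfm A [frequency_logo_matrix()] long tibble.
#' @return A ggplot.
#' @export
plot_logo_matrix <- function(pfm) {
  ggplot(pfm, aes(x = .data$position, y = .data$residue,
                  fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = "position", y = NULL, fill = "freq") +
    ggplot2::theme_minimal()
}

#' @describeIn cross_profiles Bar plot of per-bait retained percentages.
#' @param object A `cross_profiles` object (for `autoplot`).
#' @method autoplot cross_profiles
#' @export
autoplot.cross_profiles <- function(object, ...) {
  ggplot(object$per_bait,
         aes(x = .data$bait, y = .data$pct_retained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(aes(label = .data$pct_retained), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = "parallel sort bait",
                  y = "% of primary-reactive clones retained") +
    ggplot2::theme_minimal()
}

#' @describeIn escape_logo_contrast Tile plot of the binding-vs-escape
#'   frequency differences.
#' @param object A `logo_contrast` (for `autoplot`).
#' @method autoplot logo_contrast
#' @export
autoplot.logo_contrast <- function(object, ...) {
  ggplot(object$delta, aes(x = .data$position, y = .data$residue,
                           fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "loop position", y = NULL,
                  fill = "escape - binding") +
    ggplot2::theme_minimal()
}

#' Stacked composition-by-round plot
#'
#' @param composition A [composition_by_round()] tibble.
#' @return A ggplot.
#' @export
plot_composition <- function(composition) {
  ggplot(composition, aes(x = .data$round, y = .data$fraction,
                          fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of reads", fill = "family") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot for one or more groups
#'
#' @param records Survival records (`group`, `time_h`, `event`).
#' @param horizon_h Observation horizon drawn on the x axis (default 24 h).
#' @return A ggplot.
#' @export
plot_survival <- function(records, horizon_h = 24) {
  records <- check_survival_records(records)
  km <- purrr::map_dfr(unique(records$group), function(g) {
    dplyr::mutate(km_proportions(records, g), group = g, .before = 1)
  })
  start <- tibble(group = unique(records$group), time_h = 0, survival = 1)
  ggplot(km, aes(x = .data$time_h, y = .data$survival,
                 colour = .data$group)) +
    ggplot2::geom_step(data = dplyr::bind_rows(
      start, km[, c("group", "time_h", "survival")]
    )) +
    ggplot2::coord_cartesian(xlim = c(0, horizon_h), ylim = c(0, 1)) +
    ggplot2::labs(x = "time (h)", y = "proportion surviving",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
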