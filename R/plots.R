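#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of a contact map
#'
#' @param object a `contact_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- tidy.contact_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "contact\nfreq") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue index k", y = "residue index j",
                  title = sprintf("Mean contact map (cutoff %g Å)",
                                  attr(object, "cutoff"))) +
    ggplot2::theme_minimal()
}

#' Stacked bars of per-residue secondary-structure fractions
#'
#' @param object an `ss_fractions` table.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ss_fractions <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(ss_states()),
                              names_to = "state", values_to = "fraction")
  long$state <- factor(long$state, levels = rev(ss_states()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$res_index,
                                     y = .data$fraction,
                                     fill = .data$state)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_brewer(palette = "Spectral", name = "state") +
    ggplot2::labs(x = "residue (internal index)", y = "state fraction") +
    ggplot2::theme_minimal()
}

#' Fragment-resolved ligand contact profile bars
#'
#' @param object a `fragment_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fragment_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$fragment <- factor(df$fragment,
                        levels = c("Cys", "A-ring", "B-ring", "stem"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_index,
                                   y = .data$contact_pct,
                                   fill = .data$fragment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(preserve = "single"),
                      na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(Cys = "grey80", `A-ring` = "red3",
                                          `B-ring` = "green4",
                                          stem = "navy")) +
    ggplot2::labs(x = "residue (internal index)",
                  y = "contact ratio × 100%") +
    ggplot2::theme_minimal()
}

#' Scatter plot of an embedding
#'
#' Works for `contact_pca`, `contact_embed`, and the labelled tibble
#' returned by [joint_embed()].
#'
#' @param x an embedding result.
#' @param colour optional vector colouring the frames (e.g. ensemble label
#'   or block); for [joint_embed()] output the ensemble label is used
#'   automatically.
#' @return a ggplot.
#' @export
plot_embedding <- function(x, colour = NULL) {
  if (inherits(x, "contact_pca")) df <- x$scores
  else if (inherits(x, "contact_embed")) df <- x$coords
  else df <- tibble::as_tibble(x)
  dims <- setdiff(names(df), c("frame", "ensemble"))
  if (is.null(colour) && "ensemble" %in% names(df)) colour <- df$ensemble
  df$.colour <- if (is.null(colour)) "frames" else colour
  if (length(dims) == 1) df$.y <- 0 else df$.y <- df[[dims[2]]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[dims[1]]], y = .data$.y,
                                   colour = .data$.colour)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = dims[1], y = if (length(dims) > 1) dims[2] else "",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
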