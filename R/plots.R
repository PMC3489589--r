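#' Plot a junction-anchored pairing profile
#'
#' Line plot of per-position base-pairing frequency with dotted vertical
#' lines at the ligation junctions and, when several profiles are given,
#' one coloured line per library.
#'
#' @param ... named `pairing_profile` objects (names become the legend).
#' @param ribbon optional tibble from [combine_profiles()] drawn as a
#'   min/max band.
#' @return A ggplot object.
#' @export
plot_pairing_profile <- function(..., ribbon = NULL) {
  profiles <- list(...)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("set", seq_along(profiles))
  }
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    tibble::tibble(position = p$position, frequency = p$frequency, library = nm)
  })
  junctions <- stats::na.omit(c(attr(profiles[[1]], "junction5"),
                                attr(profiles[[1]], "junction3")))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$frequency,
                                         colour = .data$library))
  if (!is.null(ribbon)) {
    gg <- gg + ggplot2::geom_ribbon(
      data = ribbon,
      ggplot2::aes(.data$position, ymin = .data$min, ymax = .data$max),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  gg +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = junctions - 0.5, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position (0-based)", y = "pairing frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_pairing_profile
#' @param object a `pairing_profile`.
#' @method autoplot pairing_profile
#' @export
autoplot.pairing_profile <- function(object, ...) plot_pairing_profile(object, ...)

#' Plot abundance curves
#'
#' Read counts of the most abundant sequences, by descending rank, for one
#' or more libraries; biased libraries show a much steeper head.
#'
#' @param ... named count tables (tibbles with `sequence` / `count`).
#' @param top_m number of top sequences shown.
#' @return A ggplot object.
#' @export
plot_abundance_curve <- function(..., top_m = 100) {
  tables <- list(...)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("library", seq_along(tables))
  }
  df <- purrr::imap_dfr(tables, function(tab, nm) {
    dplyr::mutate(abundance_curve(tab, top_m), library = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$count,
                                   colour = .data$library)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "abundance rank", y = "reads", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot miRNA detection-threshold curves
#'
#' @param ... named tibbles with a `count` column (one row per miRNA).
#' @param thresholds count thresholds evaluated.
#' @return A ggplot object.
#' @export
plot_detection_curve <- function(..., thresholds = c(1, 2, 5, 10, 20, 50, 100)) {
  tables <- list(...)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("library", seq_along(tables))
  }
  df <- purrr::imap_dfr(tables, function(tab, nm) {
    dplyr::mutate(detection_curve(tab, thresholds), library = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$n_detected,
                                   colour = .data$library)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "count threshold", y = "miRNAs detected", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed versus expected Poisson multiplicity histogram
#'
#' @param object a [poisson_gof()] fit.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot poisson_gof
#' @export
autoplot.poisson_gof <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "series", values_to = "n_sequences")
  ggplot2::ggplot(df, ggplot2::aes(.data$count_bin, .data$n_sequences,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read count bin (pooled)", y = "distinct sequences",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
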