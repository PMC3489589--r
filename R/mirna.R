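#' Reads-per-million normalisation
#'
#' Scales raw counts to reads per million (RPM): `count / library_total *
#' 1e6`.  By default the denominator is the sum of the supplied counts
#' (reads assigned to known miRNAs); pass `library_total` to normalise by
#' total trimmed reads instead.  A `rank` column (1 = most abundant, ties
#' by first appearance) is added.
#'
#' @param data tibble with columns `name` and `count`.
#' @param library_total normalisation denominator; default `sum(count)`.
#' @return The input tibble with `rpm` and `rank` columns.
#' @export
rpm_normalize <- function(data, library_total = NULL) {
  stopifnot(is.data.frame(data), all(c("name", "count") %in% names(data)))
  if (is.null(library_total)) library_total <- sum(data$count)
  if (library_total <= 0) stop("library_total must be positive", call. = FALSE)
  if (library_total < sum(data$count)) {
    stop("library_total is smaller than the sum of counts", call. = FALSE)
  }
  data |>
    dplyr::mutate(rpm = .data$count / library_total * 1e6,
                  rank = rank(-.data$count, ties.method = "first"))
}

#' Number of miRNAs detected at increasing count thresholds
#'
#' @param data tibble with a `count` column (one row per miRNA).
#' @param thresholds positive count thresholds; a miRNA is detected at a
#'   threshold when `count >= threshold`.
#' @return A tibble `threshold` / `n_detected`, non-increasing in
#'   `threshold`.
#' @export
detection_curve <- function(data, thresholds = c(1, 2, 5, 10, 20, 50, 100)) {
  stopifnot(is.data.frame(data), "count" %in% names(data), all(thresholds > 0))
  tibble::tibble(
    threshold = thresholds,
    n_detected = vapply(thresholds, function(t) sum(data$count >= t), 1L)
  )
}

#' Fold-change concordance between two protocols
#'
#' Ligation bias is largely sequence specific, so the same miRNA suffers a
#' similar distortion in every sample; fold changes between conditions are
#' therefore far more protocol-robust than absolute levels.  This computes
#' per-miRNA `log2((wt + pseudocount) / (ko + pseudocount))` under each
#' protocol and their squared Pearson correlation.
#'
#' @param data tibble with columns `name`, `a_wt`, `a_ko`, `b_wt`, `b_ko`
#'   (normalised counts under protocols A and B, conditions WT and KO).
#' @param pseudocount added to numerator and denominator.
#' @return Object of class `fc_concordance` with `r_squared` and `pairs`
#'   (per-miRNA `log2fc_a`, `log2fc_b`); `tidy()`/`glance()` methods.
#' @export
fold_change_concordance <- function(data, pseudocount = 1) {
  need <- c("name", "a_wt", "a_ko", "b_wt", "b_ko")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  if (nrow(data) == 0) stop("no shared miRNAs between the protocols", call. = FALSE)
  pairs <- data |>
    dplyr::mutate(
      log2fc_a = log2((.data$a_wt + pseudocount) / (.data$a_ko + pseudocount)),
      log2fc_b = log2((.data$b_wt + pseudocount) / (.data$b_ko + pseudocount))
    )
  r2 <- stats::cor(pairs$log2fc_a, pairs$log2fc_b)^2
  structure(list(r_squared = r2, pairs = pairs), class = "fc_concordance")
}

#' @export
print.fc_concordance <- function(x, ...) {
  cat("Fold-change concordance over ", nrow(x$pairs), " miRNAs: R^2 = ",
      format(x$r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy fc_concordance
#' @export
tidy.fc_concordance <- function(x, ...) x$pairs

#' @method glance fc_concordance
#' @export
glance.fc_concordance <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_mirnas = nrow(x$pairs))
}

#' Detect arm switches between two protocols
#'
#' For each miRNA precursor the more abundant strand (5p or 3p) is
#' conventionally annotated as the mature miRNA.  When two library
#' protocols disagree about which strand dominates, the annotation is
#' protocol dependent — an "arm switch".  Replicate libraries are summed
#' within protocol; only precursors with either strand above
#' `rpm_threshold` RPM in either protocol are analysed.
#'
#' @param duplexes long tibble with columns `precursor`, `arm` (`"5p"` /
#'   `"3p"`), `protocol` (exactly two levels) and `count`; replicate rows
#'   are summed.
#' @param totals optional tibble `protocol` / `total` giving RPM
#'   denominators; default: per-protocol sum of the supplied counts.
#' @param rpm_threshold expression filter in reads per million.
#' @param pseudocount added to both strands for the log2 5p/3p ratio.
#' @return A tibble, one row per analysed precursor: summed counts per
#'   arm/protocol, `log2_ratio_*` (5p vs 3p), `dominant_*`, and `direction`
#'   (+1 = same dominant strand, -1 = arm switch, NA = tie / no call).
#' @export
detect_arm_switch <- function(duplexes, totals = NULL, rpm_threshold = 10,
                              pseudocount = 1) {
  need <- c("precursor", "arm", "protocol", "count")
  stopifnot(is.data.frame(duplexes), all(need %in% names(duplexes)))
  if (rpm_threshold < 0) stop("rpm_threshold must be non-negative", call. = FALSE)
  protocols <- sort(unique(duplexes$protocol))
  if (length(protocols) != 2) {
    stop("exactly two protocols are required (got ",
         length(protocols), ")", call. = FALSE)
  }
  if (!all(duplexes$arm %in% c("5p", "3p"))) {
    stop("arm must be '5p' or '3p'", call. = FALSE)
  }
  summed <- duplexes |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("precursor", "arm", "protocol"))
  if (is.null(totals)) {
    totals <- summed |>
      dplyr::summarise(total = sum(.data$count), .by = "protocol")
  }
  wide <- summed |>
    dplyr::left_join(totals, by = "protocol") |>
    dplyr::mutate(rpm = .data$count / .data$total * 1e6) |>
    tidyr::pivot_wider(id_cols = "precursor",
                       names_from = c("arm", "protocol"),
                       values_from = c("count", "rpm"), values_fill = 0)
  a <- protocols[1]; b <- protocols[2]
  col <- function(what, arm, proto) wide[[paste(what, arm, proto, sep = "_")]]
  res <- tibble::tibble(
    precursor = wide$precursor,
    count_5p_a = col("count", "5p", a), count_3p_a = col("count", "3p", a),
    count_5p_b = col("count", "5p", b), count_3p_b = col("count", "3p", b),
    max_rpm = pmax(col("rpm", "5p", a), col("rpm", "3p", a),
                   col("rpm", "5p", b), col("rpm", "3p", b))
  ) |>
    dplyr::filter(.data$max_rpm > rpm_threshold) |>
    dplyr::mutate(
      log2_ratio_a = log2((.data$count_5p_a + pseudocount) /
                            (.data$count_3p_a + pseudocount)),
      log2_ratio_b = log2((.data$count_5p_b + pseudocount) /
                            (.data$count_3p_b + pseudocount)),
      dominant_a = dplyr::case_when(
        .data$count_5p_a > .data$count_3p_a ~ "5p",
        .data$count_5p_a < .data$count_3p_a ~ "3p",
        TRUE ~ NA_character_
      ),
      dominant_b = dplyr::case_when(
        .data$count_5p_b > .data$count_3p_b ~ "5p",
        .data$count_5p_b < .data$count_3p_b ~ "3p",
        TRUE ~ NA_character_
      ),
      direction = dplyr::case_when(
        is.na(.data$dominant_a) | is.na(.data$dominant_b) ~ NA_real_,
        .data$dominant_a == .data$dominant_b ~ 1,
        TRUE ~ -1
      )
    )
  attr(res, "protocols") <- c(a = a, b = b)
  res
}

#' Filter new miRNA candidates
#'
#' Downstream filter applied to hairpin-discovery candidates: a candidate
#' is retained when its WT/KO fold change (pseudocount protected) strictly
#' exceeds `fc_min` — Dicer-dependent expression — and a star-strand read
#' has been observed for it.
#'
#' @param candidates tibble with columns `name`, `wt_count`, `ko_count`,
#'   `star_seen` (logical).
#' @param fc_min fold-change threshold (strict `>`), default 1.4.
#' @param pseudocount added to both counts.
#' @return The retained rows with a `fold_change` column.
#' @export
filter_new_candidates <- function(candidates, fc_min = 1.4, pseudocount = 1) {
  need <- c("name", "wt_count", "ko_count", "star_seen")
  stopifnot(is.data.frame(candidates), all(need %in% names(candidates)), fc_min > 0)
  candidates |>
    dplyr::mutate(fold_change = (.data$wt_count + pseudocount) /
                    (.data$ko_count + pseudocount)) |>
    dplyr::filter(.data$fold_change > fc_min, .data$star_seen)
}
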