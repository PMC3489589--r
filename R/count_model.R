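#' Expected Poisson multiplicity histogram for a degenerate library
#'
#' Sequencing a degenerate pool is a sampling process with a very large
#' sample and very low per-molecule frequencies, so under equimolarity the
#' number of times each of the `p` possible molecules is read follows a
#' Poisson distribution with rate `lambda = n / p`, where `n` is the total
#' number of reads.  This returns the expected number of distinct sequences
#' read exactly `k` times, for `k = 0, ..., max_count`, with all mass beyond
#' `max_count` pooled into the final bin so the expectations sum to `p`.
#'
#' @param n total number of reads (>= 0).
#' @param p number of possible molecules in the pool (e.g. `4^9` for N9).
#' @param max_count largest count bin; the last bin is `>= max_count`.
#' @return A tibble with columns `count` (0..max_count) and `expected`.
#' @export
poisson_expected_histogram <- function(n, p, max_count = 50) {
  stopifnot(length(n) == 1, length(p) == 1, n >= 0, max_count >= 1)
  if (p < 1) stop("p must be a positive number of possible molecules", call. = FALSE)
  lambda <- n / p
  k <- 0:(max_count - 1)
  expected <- p * stats::dpois(k, lambda)
  tail_mass <- p * stats::ppois(max_count - 1, lambda, lower.tail = FALSE)
  tibble::tibble(count = c(k, max_count), expected = c(expected, tail_mass))
}

#' Multiplicity histogram of an observed count table
#'
#' Tabulates how many distinct sequences were read exactly `k` times,
#' including the zero class (`p` minus the number of distinct sequences
#' observed).
#'
#' @param data a count table (tibble with `sequence` and `count`).
#' @param p number of possible molecules.
#' @return A tibble `count` / `n_sequences` covering every observed count
#'   value plus the zero class.
#' @export
multiplicity_histogram <- function(data, p) {
  stopifnot(is.data.frame(data), all(c("sequence", "count") %in% names(data)))
  obs <- data$count[data$count > 0]
  n_zero <- p - length(obs)
  if (n_zero < 0) stop("more distinct sequences than p possible molecules", call. = FALSE)
  tab <- table(obs)
  tibble::tibble(
    count = c(0, as.numeric(names(tab))),
    n_sequences = c(n_zero, as.numeric(tab))
  ) |> dplyr::arrange(.data$count)
}

#' Chi-squared goodness-of-fit test against the Poisson count model
#'
#' Tests whether the observed multiplicity histogram of a library is
#' consistent with the equimolar Poisson model (`lambda = n/p`).  Bins whose
#' expected value falls below `min_expected` are pooled from the tail
#' inward (standard Pearson chi-squared practice); the degrees of freedom
#' are the number of bins after pooling minus one.
#'
#' @param data a count table (tibble `sequence`/`count`), or a multiplicity
#'   histogram with columns `count`/`n_sequences` (the zero class included).
#' @param p number of possible molecules in the pool.
#' @param min_expected pooling threshold for expected bin counts.
#' @return An object of class `poisson_gof` with elements `chi2`, `dof`,
#'   `p_value`, `lambda`, `n`, `p` and `bins` (observed vs expected after
#'   pooling).  Use [generics::tidy()] / [generics::glance()] for tibbles.
#' @examples
#' set.seed(1)
#' lib <- count_table(sample(c("AAA", "CCC", "GGG", "UUU"), 300, replace = TRUE))
#' poisson_gof(lib, p = 64) # 4 abundant sequences in a 64-sequence space
#' @export
poisson_gof <- function(data, p, min_expected = 5) {
  stopifnot(is.data.frame(data))
  hist <- if (all(c("count", "n_sequences") %in% names(data))) {
    tibble::as_tibble(data)
  } else {
    multiplicity_histogram(data, p)
  }
  n <- sum(hist$count * hist$n_sequences)
  lambda <- n / p
  if (abs(sum(hist$n_sequences) - p) > 1e-6) {
    stop("histogram covers ", sum(hist$n_sequences),
         " sequences but p = ", p, "; include the zero class", call. = FALSE)
  }

  max_count <- max(hist$count)
  full <- tibble::tibble(count = 0:max_count) |>
    dplyr::left_join(hist, by = "count") |>
    dplyr::mutate(n_sequences = dplyr::coalesce(.data$n_sequences, 0))
  expected <- poisson_expected_histogram(n, p, max_count = max_count)$expected

  obs <- full$n_sequences
  exp <- expected
  # pool from the tail inward until every bin expects >= min_expected
  while (length(exp) > 1 && exp[length(exp)] < min_expected) {
    k <- length(exp)
    exp[k - 1] <- exp[k - 1] + exp[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    exp <- exp[-k]; obs <- obs[-k]
  }
  # the head (zero class) can also be vanishingly rare when lambda is large
  while (length(exp) > 1 && exp[1] < min_expected) {
    exp[2] <- exp[2] + exp[1]
    obs[2] <- obs[2] + obs[1]
    exp <- exp[-1]; obs <- obs[-1]
  }
  if (length(exp) < 2) {
    stop("fewer than 2 bins remain after pooling; the test is degenerate",
         call. = FALSE)
  }
  chi2 <- sum((obs - exp)^2 / exp)
  dof <- length(exp) - 1
  structure(
    list(chi2 = chi2, dof = dof,
         p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
         lambda = lambda, n = n, p = p,
         bins = tibble::tibble(observed = obs, expected = exp)),
    class = "poisson_gof"
  )
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat("Poisson goodness-of-fit (lambda = n/p = ", format(x$lambda, digits = 4),
      ")\n  X-squared = ", format(x$chi2, digits = 6), ", df = ", x$dof,
      ", p-value ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy poisson_gof
#' @export
tidy.poisson_gof <- function(x, ...) {
  dplyr::mutate(x$bins, count_bin = dplyr::row_number() - 1, .before = 1)
}

#' @method glance poisson_gof
#' @export
glance.poisson_gof <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, dof = x$dof, p_value = x$p_value,
                 lambda = x$lambda, n = x$n, p = x$p)
}

#' Fraction of the possible sequence space captured
#'
#' The proportion of all `p` possible insert sequences observed at least
#' once in a library.  In the N9 experiments the standard adapters captured
#' 42% of the `4^9` space while HD adapters captured 81%.
#'
#' @param data count table (tibble `sequence`/`count`).
#' @param p number of possible molecules; when `p = 4^k` every sequence in
#'   the table must have length `k`.
#' @return A single number in `[0, 1]`.
#' @export
capture_fraction <- function(data, p) {
  stopifnot(is.data.frame(data), all(c("sequence", "count") %in% names(data)))
  if (nrow(data) == 0) return(0)
  k <- round(log(p, base = 4))
  if (4^k == p && !all(nchar(data$sequence) == k)) {
    stop("sequence lengths are inconsistent with p = 4^", k, call. = FALSE)
  }
  sum(data$count >= 1) / p
}

#' Read counts of the most abundant sequences
#'
#' The abundance curve: counts of the `top_m` most abundant sequences in
#' descending order (ties broken alphabetically by sequence).  Biased
#' libraries show a steep curve; unbiased degenerate libraries are flat.
#'
#' @param data count table (tibble `sequence`/`count`).
#' @param top_m number of top sequences to return.
#' @return A tibble `rank` / `sequence` / `count`, at most `top_m` rows.
#' @export
abundance_curve <- function(data, top_m = 100) {
  stopifnot(is.data.frame(data), top_m >= 1)
  data |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    dplyr::slice_head(n = top_m) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select("rank", "sequence", "count")
}
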