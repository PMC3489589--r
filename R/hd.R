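#' Size of the degenerate-tag adapter space
#'
#' An HD adapter with a `tag_length`-nt fully degenerate tag is really a
#' pool of `4^tag_length` adapter variants per side, giving
#' `(4^tag_length)^2` possible 5'/3' tag pairs.  The standard 4N HD design
#' is a set of 256 adapters with 65,536 possible pairs.
#'
#' @param tag_length degenerate-tag length (>= 0).
#' @return A one-row tibble with `n_adapters` and `n_pairs`.
#' @export
enumerate_tag_space <- function(tag_length) {
  stopifnot(length(tag_length) == 1)
  if (is.na(tag_length) || tag_length < 0 || tag_length != floor(tag_length)) {
    stop("tag_length must be a non-negative integer", call. = FALSE)
  }
  n_adapters <- count_kmers(tag_length, 4)
  tibble::tibble(n_adapters = n_adapters, n_pairs = n_adapters^2)
}

#' All tag sequences of a given length
#'
#' @param tag_length tag length; `0` gives the single empty tag.
#' @return Character vector of all `4^tag_length` tags.
#' @export
all_tags <- function(tag_length) {
  if (tag_length == 0) return("")
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "U")), tag_length))
  apply(grid[rev(seq_len(tag_length))], 1, paste, collapse = "")
}

#' Structural diversity of one insert across tag combinations
#'
#' Folds the full adapter/insert construct under every supplied tag pair
#' and counts how many distinct secondary structures arise.  The degenerate
#' tags let the same insert adopt many different co-structures with the
#' adapters, which is the mechanism by which HD adapters average out
#' ligase structure preferences.  Structure identity is taken on the
#' insert-restricted dot-bracket (the biologically relevant portion); the
#' full-construct count is reported alongside.
#'
#' @param insert insert sequence.
#' @param adapters an [adapter_set()] with `tag_length > 0`.
#' @param tag_pairs optional data frame with columns `tag5`, `tag3`; by
#'   default the full tag space is enumerated, which is only allowed for
#'   `tag_length <= 2` (16 or 256 pairs) unless `allow_full = TRUE`.
#' @param allow_full override the combinatorial guard and enumerate all
#'   `4^(2 tag_length)` pairs.
#' @param engine,temperature passed to [fold_sequences()].
#' @return A list: `n_pairs_evaluated`, `n_distinct_insert`,
#'   `n_distinct_full`, and `census`, a tibble of insert-restricted
#'   structures with counts.
#' @export
structural_diversity <- function(insert, adapters, tag_pairs = NULL,
                                 allow_full = FALSE,
                                 engine = "nussinov", temperature = 22) {
  stopifnot(inherits(adapters, "adapter_set"))
  tl <- adapters$tag_length
  if (is.null(tag_pairs)) {
    if (tl > 2 && !allow_full) {
      stop("tag_length > 2 enumerates ", 4^(2 * tl), " pairs; pass tag_pairs= ",
           "or allow_full = TRUE", call. = FALSE)
    }
    tags <- all_tags(tl)
    tag_pairs <- tidyr::expand_grid(tag5 = tags, tag3 = tags)
  }
  built <- purrr::pmap(tag_pairs, function(tag5, tag3, ...) {
    build_construct(insert, adapters, mode = "full_construct",
                    tag5 = if (tl > 0) tag5, tag3 = if (tl > 0) tag3)
  })
  seqs <- vapply(built, `[[`, "", "sequence")
  folded <- fold_sequences(tibble::tibble(sequence = seqs),
                           engine = engine, temperature = temperature)
  ins_from <- built[[1]]$junction5 + 1L # 1-based substr bounds of the insert
  ins_to <- built[[1]]$junction3
  insert_db <- substr(folded$dotbracket, ins_from, ins_to)
  census <- tibble::tibble(structure = insert_db) |>
    dplyr::count(.data$structure, name = "count", sort = TRUE)
  list(
    n_pairs_evaluated = nrow(tag_pairs),
    n_distinct_insert = nrow(census),
    n_distinct_full = dplyr::n_distinct(folded$dotbracket),
    census = census
  )
}

#' Barcode-pair capture histogram
#'
#' For HD libraries, counts with how many distinct tag ("barcode") pairs
#' each insert was captured.  If ligation were tag-indifferent every insert
#' would be seen across many pairs; in practice most sequences are captured
#' by few pairs, showing that individual adapter variants have their own
#' preferences.
#'
#' @param tagged_reads data frame with columns `insert`, `tag5`, `tag3`
#'   (one row per read or per observed combination; duplicates of the same
#'   combination are counted once).
#' @param k_breaks thresholds for the capture summary.
#' @return A list: `histogram` (tibble `insert` / `n_pairs`) and `summary`
#'   (tibble `k` / `fraction` of inserts captured by fewer than `k` pairs).
#' @export
barcode_capture_histogram <- function(tagged_reads, k_breaks = c(2, 5, 10, 100)) {
  stopifnot(all(c("insert", "tag5", "tag3") %in% names(tagged_reads)))
  hist <- tagged_reads |>
    dplyr::distinct(.data$insert, .data$tag5, .data$tag3) |>
    dplyr::count(.data$insert, name = "n_pairs")
  summary <- tibble::tibble(
    k = k_breaks,
    fraction = vapply(k_breaks, function(k) mean(hist$n_pairs < k), 1.0)
  )
  list(histogram = hist, summary = summary)
}
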