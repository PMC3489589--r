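#' Normalise an oligonucleotide sequence to the RNA alphabet
#'
#' Uppercases, converts `T` to `U` and validates that only `A`, `C`, `G`,
#' `U` remain.  All internal sequence handling in the package is in the RNA
#' alphabet; DNA input is converted on the way in.
#'
#' @param x character vector of sequences.
#' @return The normalised character vector.
#' @export
oligo_normalize <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    offender <- gsub("[ACGU]", "", out[which(bad)[1]])
    stop("sequence contains characters outside the A/C/G/U alphabet: '",
         substr(offender, 1, 5), "'", call. = FALSE)
  }
  if (any(!nzchar(out))) stop("empty sequence", call. = FALSE)
  out
}

#' Define an adapter set
#'
#' An adapter set holds the invariant 5' and 3' adapter core sequences plus
#' the length of the fully degenerate tag at each ligation end.
#' `tag_length = 0` is a standard (Illumina-style) adapter pair;
#' `tag_length = 4` is the high-definition (HD) configuration, in which each
#' adapter is really a pool of `4^4 = 256` variants.
#'
#' @param adapter5,adapter3 adapter core sequences (RNA or DNA letters).
#' @param tag_length number of degenerate nucleotides at the ligation end of
#'   each adapter (0 = standard, 4 = HD).
#' @return An object of class `adapter_set`.
#' @examples
#' adapter_set("GUUCAGAGUUCUACAGUCCGACGAUC", "UCGUAUGCCGUCUUCUGCUUGU", tag_length = 4)
#' @export
adapter_set <- function(adapter5, adapter3, tag_length = 0) {
  stopifnot(length(tag_length) == 1, !is.na(tag_length), tag_length >= 0,
            tag_length == as.integer(tag_length))
  structure(
    list(adapter5 = oligo_normalize(adapter5),
         adapter3 = oligo_normalize(adapter3),
         tag_length = as.integer(tag_length)),
    class = "adapter_set"
  )
}

#' @export
print.adapter_set <- function(x, ...) {
  kind <- if (x$tag_length == 0) "standard" else paste0("HD (", x$tag_length, "N tags)")
  cat("<adapter_set> ", kind, "\n",
      "  5' adapter core: ", x$adapter5, "\n",
      "  3' adapter core: ", x$adapter3, "\n", sep = "")
  invisible(x)
}

#' Synthetic example adapter pair
#'
#' A small synthetic adapter pair used throughout the documentation, tests
#' and simulator defaults.  These are *not* any vendor's sequences; analyses
#' of real libraries should supply the adapters actually used.
#'
#' @param tag_length degenerate-tag length (0 = standard, 4 = HD).
#' @return An [adapter_set()].
#' @export
example_adapters <- function(tag_length = 0) {
  adapter_set("GUUCAGAGUUCUACAGUCCG", "UCGUAUGCCGUCUUCUGCUU", tag_length = tag_length)
}

#' Read sequences into a count table
#'
#' Reads small-RNA sequences from FASTA, FASTQ or a two-column TSV
#' (`sequence`, `count`, with a header) and aggregates identical sequences
#' into a count table.  `T` is normalised to `U`.  Records containing
#' ambiguous bases (`N`) are dropped with a warning; the number dropped is
#' recorded in the `n_dropped` attribute.
#'
#' @param path path to the input file.
#' @param format `"fasta"`, `"fastq"`, `"tsv"` or `"auto"` (guess from the
#'   file extension).
#' @return A tibble with columns `sequence` and `count`, sorted by
#'   decreasing count, with attributes `total_reads` (sum of counts) and
#'   `n_dropped`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , fasta = , fas = "fasta",
      fq = , fastq = "fastq",
      tsv = , txt = "tsv",
      stop("cannot guess format from extension '.", ext,
           "'; pass format= explicitly", call. = FALSE)
    )
  }
  if (format == "tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      sequence = readr::col_character(), count = readr::col_double()
    ), progress = FALSE)
    if (nrow(tab) == 0) stop("empty sequence table: ", path, call. = FALSE)
    if (any(tab$count < 0) || any(tab$count != floor(tab$count))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    seqs <- rep(tab$sequence, times = tab$count)
  } else {
    set <- Biostrings::readBStringSet(path, format = format)
    if (length(set) == 0) stop("no records in ", path, call. = FALSE)
    seqs <- as.character(set)
  }
  count_table(seqs)
}

#' Build a count table from a vector of sequences
#'
#' @param sequences character vector of (possibly repeated) sequences.
#' @return A tibble `sequence`/`count` as in [read_sequences()].
#' @export
count_table <- function(sequences) {
  has_n <- grepl("[nN]", sequences)
  n_dropped <- sum(has_n)
  if (n_dropped > 0) {
    warning(n_dropped, " record(s) containing ambiguous base 'N' dropped",
            call. = FALSE)
    sequences <- sequences[!has_n]
  }
  if (length(sequences) == 0) stop("no usable sequence records", call. = FALSE)
  sequences <- oligo_normalize(sequences)
  tab <- table(sequences)
  out <- tibble::tibble(sequence = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  attr(out, "total_reads") <- sum(out$count)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Trim adapters (and degenerate tags) off raw reads
#'
#' Each raw read is assumed to start at the insert (standard adapters) or at
#' the degenerate 5'-tag (HD adapters).  The 3'-adapter is located by an
#' exact match of the first `match_length` nucleotides of its core (no
#' mismatches); everything from the match onward is stripped, together with
#' the `tag_length` bases immediately preceding the match (the 3' tag) and
#' the `tag_length` bases at the start of the read (the 5' tag).
#'
#' @param reads character vector of raw reads, or a data frame with a
#'   `read` column.
#' @param adapters an [adapter_set()].
#' @param min_insert minimum insert length retained after trimming.
#' @param match_length number of exact 3'-adapter-prefix bases required.
#' @return A tibble with columns `read`, `insert` (NA when rejected) and
#'   `status` (`"ok"`, `"no_adapter"` or `"too_short"`).
#' @export
trim_reads <- function(reads, adapters, min_insert = 16, match_length = 8) {
  if (is.data.frame(reads)) {
    stopifnot("read" %in% names(reads))
    reads <- reads$read
  }
  stopifnot(inherits(adapters, "adapter_set"), match_length >= 1)
  reads <- oligo_normalize(reads)
  probe <- substr(adapters$adapter3, 1, match_length)
  if (nchar(probe) < match_length) {
    stop("adapter3 core is shorter than match_length", call. = FALSE)
  }
  tl <- adapters$tag_length
  hit <- as.integer(regexpr(probe, reads, fixed = TRUE)) # 1-based, -1 = none
  insert_start <- tl + 1L
  insert_end <- hit - 1L - tl
  status <- dplyr::case_when(
    hit < 0 ~ "no_adapter",
    insert_end - insert_start + 1L < min_insert ~ "too_short",
    TRUE ~ "ok"
  )
  insert <- ifelse(status == "ok", substr(reads, insert_start, insert_end), NA_character_)
  tibble::tibble(read = reads, insert = insert, status = status)
}

#' Number of possible k-mers
#'
#' Size of the sequence space of length-`k` oligonucleotides: for the
#' degenerate N9 pool this is `4^9 = 262144`, for N21 it is
#' `4^21` (about 4.4e12).
#'
#' @param k oligonucleotide length (>= 0).
#' @param alphabet_size alphabet size (4 for RNA).
#' @return `alphabet_size ^ k` as a double (exact for all practical `k`).
#' @export
count_kmers <- function(k, alphabet_size = 4) {
  stopifnot(length(k) == 1, length(alphabet_size) == 1, alphabet_size >= 1)
  if (is.na(k) || k < 0 || k != floor(k)) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  alphabet_size^k
}
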