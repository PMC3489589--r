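#' Assemble an insert/adapter construct for folding
#'
#' Concatenates the segments of a sequencing-ready molecule in ligation
#' order — 5' adapter core, 5' tag, insert, 3' tag, 3' adapter core — and
#' records the positions of the two ligation junctions.  Each junction is
#' indexed (0-based) at the first base of its downstream segment: for the 5'
#' ligation that is the first insert base, for the 3' ligation the first
#' base of the 3' tag (HD) or of the 3' adapter core (standard), i.e. the
#' position where ligation joins the insert to what follows.
#'
#' @param insert insert sequence.
#' @param adapters an [adapter_set()].
#' @param mode `"insert_only"`, `"insert_plus_3"` (insert + 3' side, the
#'   state after the first ligation) or `"full_construct"`.
#' @param tag5,tag3 concrete tag sequences; required exactly when
#'   `adapters$tag_length > 0`, with matching lengths.
#' @return A list with `sequence`, `junction5` (NA unless full_construct),
#'   `junction3` (NA for insert_only) and `segments`, a per-position label
#'   vector over `adapter5` / `tag5` / `insert` / `tag3` / `adapter3`.
#' @export
build_construct <- function(insert, adapters,
                            mode = c("insert_only", "insert_plus_3", "full_construct"),
                            tag5 = NULL, tag3 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(adapters, "adapter_set"))
  insert <- oligo_normalize(insert)
  tl <- adapters$tag_length
  need5 <- mode == "full_construct" && tl > 0
  need3 <- mode != "insert_only" && tl > 0
  if (need5 != !is.null(tag5) || need3 != !is.null(tag3)) {
    stop("tags must be supplied exactly when the adapter set is tagged and ",
         "the mode includes that side", call. = FALSE)
  }
  if (need5 && nchar(tag5) != tl) stop("tag5 length must equal tag_length", call. = FALSE)
  if (need3 && nchar(tag3) != tl) stop("tag3 length must equal tag_length", call. = FALSE)
  if (need5) tag5 <- oligo_normalize(tag5)
  if (need3) tag3 <- oligo_normalize(tag3)

  parts <- switch(mode,
    insert_only = list(insert = insert),
    insert_plus_3 = list(insert = insert, tag3 = if (need3) tag3,
                         adapter3 = adapters$adapter3),
    full_construct = list(adapter5 = adapters$adapter5,
                          tag5 = if (need5) tag5, insert = insert,
                          tag3 = if (need3) tag3, adapter3 = adapters$adapter3)
  )
  parts <- parts[!vapply(parts, is.null, TRUE)]
  lens <- vapply(parts, nchar, 1L)
  offsets <- cumsum(c(0L, lens))[seq_along(parts)]
  names(offsets) <- names(parts)
  insert_start <- offsets[["insert"]]
  junction5 <- if (mode == "full_construct") insert_start else NA_integer_
  junction3 <- if (mode == "insert_only") NA_integer_ else insert_start + nchar(insert)
  list(
    sequence = paste(unlist(parts), collapse = ""),
    junction5 = junction5,
    junction3 = junction3,
    segments = rep(names(parts), lens)
  )
}

#' Per-position base-pairing frequency profile
#'
#' Folds a set of equal-length constructs and reports, for every position,
#' the fraction of molecules whose MFE structure pairs that position.  This
#' is the junction-anchored profile used to read out RNA-ligase structure
#' preferences: T4 Rnl2 (3' ligation) favours base-paired nucleotides
#' upstream of its junction, T4 Rnl1 (5' ligation) favours single-stranded
#' junctions.
#'
#' @param constructs a data frame with a `sequence` column (all the same
#'   length), or a list of [build_construct()] results.
#' @param engine,temperature passed to [fold_sequences()].
#' @return A `pairing_profile`: a tibble with columns `position` (0-based),
#'   `frequency`, and `segment` when segment labels are available, plus
#'   attributes `n_molecules`, `junction5`, `junction3`.
#' @export
pairing_profile <- function(constructs, engine = "nussinov", temperature = 22) {
  j5 <- j3 <- NA_integer_
  segments <- NULL
  if (is.data.frame(constructs)) {
    seqs <- constructs$sequence
    if ("junction5" %in% names(constructs)) j5 <- constructs$junction5[1]
    if ("junction3" %in% names(constructs)) j3 <- constructs$junction3[1]
  } else {
    seqs <- vapply(constructs, `[[`, "", "sequence")
    j5 <- constructs[[1]]$junction5
    j3 <- constructs[[1]]$junction3
    segments <- constructs[[1]]$segments
  }
  if (length(seqs) == 0) stop("no molecules to profile", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("pairing profiles require equal-length constructs (fixed-length inserts)",
         call. = FALSE)
  }
  folded <- fold_sequences(tibble::tibble(sequence = seqs),
                           engine = engine, temperature = temperature)
  paired <- vapply(folded$dotbracket, .paired_positions, logical(lens[1]))
  freq <- rowMeans(matrix(paired, nrow = lens[1]))
  out <- tibble::tibble(position = seq_along(freq) - 1L, frequency = freq)
  if (!is.null(segments)) out$segment <- segments
  structure(out, n_molecules = length(seqs), junction5 = j5, junction3 = j3,
            class = c("pairing_profile", class(out)))
}

#' Merge replicate pairing profiles
#'
#' Averages two or more replicate profiles position-wise and records the
#' per-position minimum and maximum across replicates (the replicate bars
#' of a profile plot).
#'
#' @param ... two or more `pairing_profile` objects of equal length.
#' @return A tibble `position` / `frequency` (mean) / `min` / `max`.
#' @export
combine_profiles <- function(...) {
  profiles <- list(...)
  if (length(profiles) == 1 && is.list(profiles[[1]]) && !is.data.frame(profiles[[1]])) {
    profiles <- profiles[[1]]
  }
  stopifnot(length(profiles) >= 2)
  lens <- vapply(profiles, nrow, 1L)
  if (length(unique(lens)) != 1) stop("profiles have different lengths", call. = FALSE)
  mat <- vapply(profiles, function(p) p$frequency, numeric(lens[1]))
  tibble::tibble(
    position = profiles[[1]]$position,
    frequency = rowMeans(mat),
    min = apply(mat, 1, min),
    max = apply(mat, 1, max)
  )
}

#' Pairing frequency immediately adjacent to a ligation junction
#'
#' Reads off the profile value at the single base just upstream
#' (`junction - 1`) or just downstream (`junction`) of a ligation point.
#'
#' @param profile a [pairing_profile()].
#' @param junction 0-based junction position (first base of the downstream
#'   segment); defaults to the junction recorded in the profile.
#' @param side `"upstream"` or `"downstream"`.
#' @return The pairing frequency at that base.
#' @export
junction_pairing_fraction <- function(profile, junction = NULL,
                                      side = c("upstream", "downstream")) {
  side <- match.arg(side)
  if (is.null(junction)) {
    junction <- if (side == "upstream") attr(profile, "junction3") else attr(profile, "junction5")
    if (is.null(junction) || is.na(junction)) {
      stop("no junction recorded in the profile; pass junction=", call. = FALSE)
    }
  }
  pos <- if (side == "upstream") junction - 1 else junction
  if (pos < 0 || pos >= nrow(profile)) {
    stop("junction has no ", side, " base inside the profile", call. = FALSE)
  }
  profile$frequency[match(pos, profile$position)]
}

#' Squared correlation between two pairing profiles
#'
#' Squared Pearson correlation of two per-position frequency vectors; used
#' to ask which library's profile better matches a randomised control.
#'
#' @param a,b `pairing_profile` objects (or tibbles with `frequency`) of
#'   equal length.
#' @return R-squared in `[0, 1]`.
#' @export
profile_similarity <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  fa <- a$frequency; fb <- b$frequency
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    stop("profile has zero variance; correlation is undefined", call. = FALSE)
  }
  stats::cor(fa, fb)^2
}

#' Correlation between predicted structure stability and read abundance
#'
#' Folds each distinct sequence concatenated with the 3'-adapter core and
#' correlates the resulting MFE with log10(count + 1).  A ligation step that
#' favours stable co-structures makes more negative MFE go with higher
#' abundance, giving a large R-squared; an unbiased library gives R-squared
#' near zero.
#'
#' @param data count table (tibble `sequence`/`count`), equal-length inserts.
#' @param adapters an [adapter_set()]; only the 3'-adapter core is used
#'   (degenerate tags, if any, are not reconstructible from a count table).
#' @param engine,temperature passed to [fold_sequences()].
#' @return An object of class `mfe_abundance` with elements `r_squared` and
#'   `data` (per-sequence `mfe` and `log_count`); `tidy()`/`glance()`
#'   methods are provided.
#' @export
mfe_abundance_correlation <- function(data, adapters, engine = "nussinov",
                                      temperature = 22) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (stats::sd(data$count) == 0) {
    stop("all counts are equal; correlation is undefined", call. = FALSE)
  }
  plain <- adapter_set(adapters$adapter5, adapters$adapter3, tag_length = 0)
  seqs <- vapply(data$sequence, function(s) {
    build_construct(s, plain, mode = "insert_plus_3")$sequence
  }, "")
  folded <- fold_sequences(tibble::tibble(sequence = unname(seqs)),
                           engine = engine, temperature = temperature)
  df <- tibble::tibble(
    sequence = data$sequence,
    count = data$count,
    mfe = folded$mfe,
    log_count = log10(data$count + 1)
  )
  r2 <- if (stats::sd(df$mfe) == 0) 0 else stats::cor(df$mfe, df$log_count)^2
  structure(list(r_squared = r2, data = df), class = "mfe_abundance")
}

#' @export
print.mfe_abundance <- function(x, ...) {
  cat("MFE-abundance correlation over ", nrow(x$data),
      " distinct sequences: R^2 = ", format(x$r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy mfe_abundance
#' @export
tidy.mfe_abundance <- function(x, ...) x$data

#' @method glance mfe_abundance
#' @export
glance.mfe_abundance <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_sequences = nrow(x$data))
}
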