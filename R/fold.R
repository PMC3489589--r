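#' Predict a minimum-free-energy secondary structure
#'
#' Folds an RNA sequence into a single optimal secondary structure and
#' reports its minimum free energy (MFE).  Two engines are available:
#'
#' * `"nussinov"` (default, built in): a stacking-weighted Nussinov-style
#'   dynamic program.  Watson-Crick and G·U wobble pairs are allowed
#'   (scores GC = 3, AU = 2, GU = 1, +1 per stacked pair), the minimum
#'   hairpin loop is 3 nt, and the traceback is deterministic, so identical
#'   sequences always give identical structures.  The reported energy is the
#'   negated pair score in kcal/mol-like units; temperature only rescales
#'   the energy (structure choice is temperature independent).
#' * `"rnafold"`: delegates to ViennaRNA's `RNAfold` executable (full Turner
#'   energy model) and returns its MFE verbatim.  Requires `RNAfold` on the
#'   `PATH`.
#'
#' @param sequence RNA sequence (`T` is accepted and normalised to `U`).
#' @param temperature folding temperature in degrees Celsius.  The default,
#'   22, matches standard practice for ligation-bias structure analyses.
#' @param engine `"nussinov"` or `"rnafold"`.
#' @return An object of class `rna_structure`: a list with elements
#'   `sequence`, `dotbracket`, `mfe` (kcal/mol), `temperature` and `engine`.
#' @examples
#' fold("GGGAAAACCC")
#' @seealso [fold_sequences()] for the data-frame interface, [pair_table()].
#' @export
fold <- function(sequence, temperature = 22, engine = c("nussinov", "rnafold")) {
  engine <- match.arg(engine)
  seq <- oligo_normalize(sequence)
  res <- fold_sequences(tibble::tibble(sequence = seq),
                        temperature = temperature, engine = engine)
  structure(
    list(sequence = seq, dotbracket = res$dotbracket[1], mfe = res$mfe[1],
         temperature = temperature, engine = engine),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "  (", format(x$mfe, nsmall = 2), " kcal/mol, ",
      x$engine, " @ ", x$temperature, " °C)\n", sep = "")
  invisible(x)
}

#' Fold every sequence in a data frame
#'
#' Vectorised companion to [fold()]: takes a data frame with a `sequence`
#' column and returns it with `dotbracket` and `mfe` columns appended, one
#' MFE structure per row.
#'
#' @param data a data frame with a character `sequence` column.
#' @inheritParams fold
#' @return A tibble: `data` plus `dotbracket` and `mfe` columns.
#' @export
fold_sequences <- function(data, temperature = 22,
                           engine = c("nussinov", "rnafold")) {
  engine <- match.arg(engine)
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  seqs <- oligo_normalize(data$sequence)
  out <- tibble::as_tibble(data)
  out$sequence <- seqs
  if (nrow(out) == 0) {
    out$dotbracket <- character()
    out$mfe <- numeric()
    return(out)
  }
  if (engine == "nussinov") {
    # fold unique sequences once, then join back
    uniq <- unique(seqs)
    fit <- .fold_nussinov(uniq)
    scale <- (273.15 + 22) / (273.15 + temperature)
    mfe <- -as.numeric(fit$score) * scale
    i <- match(seqs, uniq)
    out$dotbracket <- fit$dotbracket[i]
    out$mfe <- mfe[i]
  } else {
    fit <- .fold_rnafold(unique(seqs), temperature)
    i <- match(seqs, fit$sequence)
    out$dotbracket <- fit$dotbracket[i]
    out$mfe <- fit$mfe[i]
  }
  out
}

# Bridge to the ViennaRNA RNAfold executable.
.fold_rnafold <- function(sequences, temperature) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("engine = \"rnafold\" requires the RNAfold executable on the PATH",
         call. = FALSE)
  }
  raw <- system2(exe, args = c("--noPS", "-T", format(temperature)),
                 input = sequences, stdout = TRUE)
  # output alternates: sequence line, then "structure ( energy)"
  seq_lines <- raw[seq(1, length(raw), by = 2)]
  str_lines <- raw[seq(2, length(raw), by = 2)]
  m <- regmatches(str_lines, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", str_lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("could not parse RNAfold output line: ", str_lines[which(bad)[1]])
  tibble::tibble(
    sequence = seq_lines,
    dotbracket = vapply(m, `[`, "", 2L),
    mfe = as.numeric(vapply(m, `[`, "", 3L))
  )
}

#' Base-pair partner table of a dot-bracket structure
#'
#' @param dotbracket a dot-bracket string over `(`, `)`, `.`.
#' @return An integer vector the length of the structure giving the 0-based
#'   partner of each position, `NA` for unpaired positions.  The mapping is
#'   symmetric: `pair_table(s)[pair_table(s)[i] + 1] == i - 1`.
#' @examples
#' pair_table("(...)")
#' @export
pair_table <- function(dotbracket) {
  stopifnot(is.character(dotbracket), length(dotbracket) == 1)
  chars <- strsplit(dotbracket, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("dot-bracket string may contain only '(', ')' and '.'", call. = FALSE)
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced brackets: unmatched ')' at position ", i - 1)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced brackets: unmatched '(' at position ", stack[1] - 1)
  }
  partner
}

# logical vector: is each position paired in this dot-bracket string?
.paired_positions <- function(dotbracket) {
  strsplit(dotbracket, "")[[1]] != "."
}
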