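#' Configuration for the ligation-bias library simulator
#'
#' Bundles and validates the parameters of the synthetic degenerate-pool
#' sequencing model.  The defaults emulate the N9 degenerate-pool
#' experiment: 9-nt inserts, the full `4^9` pool, one million reads.
#'
#' @param insert_length insert length in nt (9 for N9-style pools, 21 for
#'   N21-style pools).
#' @param pool_size number of distinct molecules in the pool
#'   (<= `4^insert_length`); the default is the full `4^9` space.
#' @param depth total number of reads sampled.
#' @param beta3 strength of the 3'-ligation (Rnl2-like) bias: molecules
#'   whose base upstream of the 3' junction is paired in the folded
#'   construct are favoured by `exp(2 * beta3)` relative to those where it
#'   is unpaired.  `0` = unbiased.
#' @param beta5 strength of the 5'-ligation (Rnl1-like) bias: molecules
#'   whose base downstream of the 5' junction is *unpaired* are favoured.
#' @param gamma optional overall structure-stability bias: weight factor
#'   `exp(-gamma * MFE)` so more stable (more negative MFE) constructs are
#'   favoured when `gamma > 0`.
#' @param tag_length degenerate-tag length of the simulated adapters.
#' @param tags_per_molecule for HD simulations, how many tag pairs are
#'   drawn per molecule.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param engine,temperature folding engine settings ([fold_sequences()]).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(insert_length = 9, pool_size = 4^9, depth = 1e6,
                              beta3 = 0, beta5 = 0, gamma = 0,
                              tag_length = 0, tags_per_molecule = 16,
                              seed = 1, engine = "nussinov", temperature = 22) {
  stopifnot(insert_length >= 1, pool_size >= 1, depth >= 1,
            beta3 >= 0, beta5 >= 0, gamma >= 0,
            tag_length >= 0, tags_per_molecule >= 1)
  if (pool_size > 4^insert_length) {
    stop("pool_size exceeds the 4^", insert_length, " possible sequences",
         call. = FALSE)
  }
  structure(
    list(insert_length = as.integer(insert_length), pool_size = pool_size,
         depth = depth, beta3 = beta3, beta5 = beta5, gamma = gamma,
         tag_length = as.integer(tag_length),
         tags_per_molecule = as.integer(tags_per_molecule),
         seed = as.integer(seed), engine = engine, temperature = temperature),
    class = "simulation_config"
  )
}

# i: 0-based indices (doubles allowed), L: length -> sequences
.index_to_seq <- function(i, L) {
  bases <- c("A", "C", "G", "U")
  out <- matrix("", nrow = length(i), ncol = L)
  rem <- i
  for (pos in L:1) {
    out[, pos] <- bases[rem %% 4 + 1]
    rem <- rem %/% 4
  }
  apply(out, 1, paste, collapse = "")
}

# Draw pool_size distinct uniform inserts of length L (uses the current RNG)
.draw_pool <- function(pool_size, L) {
  space <- 4^L
  if (pool_size >= 0.5 * space && L <= 10) {
    idx <- sample(seq_len(space) - 1, pool_size)
    return(.index_to_seq(idx, L))
  }
  seqs <- character(0)
  while (length(seqs) < pool_size) {
    m <- ceiling((pool_size - length(seqs)) * 1.2) + 10
    draw <- .index_to_seq(floor(stats::runif(m) * space), L)
    seqs <- unique(c(seqs, draw))
  }
  seqs[seq_len(pool_size)]
}

# Structure-dependent ligation weights for a set of full constructs.
# s3 = +1 if the base upstream of the 3' junction is paired, else -1
# (Rnl2 favours double-stranded context upstream of its junction);
# s5 = +1 if the base downstream of the 5' junction is unpaired, else -1
# (Rnl1 favours single-stranded junctions).
.ligation_weights <- function(constructs, cfg) {
  if (cfg$beta3 == 0 && cfg$beta5 == 0 && cfg$gamma == 0) {
    return(rep(1 / length(constructs), length(constructs)))
  }
  seqs <- vapply(constructs, `[[`, "", "sequence")
  folded <- fold_sequences(tibble::tibble(sequence = seqs),
                           engine = cfg$engine, temperature = cfg$temperature)
  j5 <- constructs[[1]]$junction5
  j3 <- constructs[[1]]$junction3
  paired <- lapply(folded$dotbracket, .paired_positions)
  s3 <- vapply(paired, function(p) if (p[j3]) 1 else -1, 1.0)       # j3-1, 0-based
  s5 <- vapply(paired, function(p) if (!p[j5 + 1]) 1 else -1, 1.0)  # j5, 0-based
  w <- exp(cfg$beta3 * s3 + cfg$beta5 * s5 - cfg$gamma * folded$mfe)
  w / sum(w)
}

#' Simulate a degenerate-pool sequencing library with ligation bias
#'
#' Implements the two-step ligation bias model: (1) `pool_size` distinct
#' inserts are drawn uniformly from the `4^insert_length` space; (2) each
#' molecule (and, for HD adapters, each sampled tag pair) is folded as the
#' full adapter construct and given the Boltzmann-like ligation weight
#' `exp(beta3 * s3 + beta5 * s5 - gamma * MFE)`, where `s3` rewards a
#' base-paired position upstream of the 3' junction and `s5` rewards an
#' unpaired position downstream of the 5' junction; (3) `depth` reads are
#' drawn from a multinomial over the normalised weights.  With all bias
#' parameters zero the sampling is exactly uniform-multinomial, so observed
#' counts follow the Poisson model tested by [poisson_gof()].
#'
#' @param cfg a [simulation_config()].
#' @param adapters an [adapter_set()]; its `tag_length` must match
#'   `cfg$tag_length`.  Default: [example_adapters()] at the configured tag
#'   length.
#' @param pool optional pre-drawn character vector of distinct inserts
#'   (used to share one pool between simulation arms).
#' @return A list of class `sim_library`: `counts` (tibble
#'   `sequence`/`count`, observed molecules only), `tagged` (tibble
#'   `insert`/`tag5`/`tag3`/`count`, HD only, else NULL), `truth` (tibble
#'   of all entities with normalised ligation `weight`), and `config`.
#' @export
simulate_library <- function(cfg, adapters = example_adapters(cfg$tag_length),
                             pool = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(adapters, "adapter_set"))
  if (adapters$tag_length != cfg$tag_length) {
    stop("adapters$tag_length must match cfg$tag_length", call. = FALSE)
  }
  set.seed(cfg$seed)
  if (is.null(pool)) pool <- .draw_pool(cfg$pool_size, cfg$insert_length)

  hd <- cfg$tag_length > 0
  if (hd) {
    tags <- all_tags(cfg$tag_length)
    k <- cfg$tags_per_molecule
    entities <- tibble::tibble(
      insert = rep(pool, each = k),
      tag5 = sample(tags, length(pool) * k, replace = TRUE),
      tag3 = sample(tags, length(pool) * k, replace = TRUE)
    ) |> dplyr::distinct()
    constructs <- purrr::pmap(entities, function(insert, tag5, tag3) {
      build_construct(insert, adapters, mode = "full_construct",
                      tag5 = tag5, tag3 = tag3)
    })
  } else {
    entities <- tibble::tibble(insert = pool)
    constructs <- lapply(pool, function(s) {
      build_construct(s, adapters, mode = "full_construct")
    })
  }

  weight <- .ligation_weights(constructs, cfg)
  reads <- as.integer(stats::rmultinom(1, size = cfg$depth, prob = weight))

  truth <- dplyr::mutate(entities, weight = weight)
  tagged <- NULL
  if (hd) {
    tagged <- entities |>
      dplyr::mutate(count = reads) |>
      dplyr::filter(.data$count > 0)
  }
  counts <- entities |>
    dplyr::mutate(count = reads) |>
    dplyr::summarise(count = sum(.data$count), .by = "insert") |>
    dplyr::filter(.data$count > 0) |>
    dplyr::rename(sequence = "insert") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  attr(counts, "total_reads") <- sum(counts$count)

  structure(list(counts = counts, tagged = tagged, truth = truth,
                 config = cfg, pool = pool),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library> ", length(x$pool), " molecules, ",
      sum(x$counts$count), " reads, beta3 = ", x$config$beta3,
      ", beta5 = ", x$config$beta5, ", gamma = ", x$config$gamma,
      if (x$config$tag_length > 0) paste0(", HD ", x$config$tag_length, "N tags"),
      "\n", sep = "")
  invisible(x)
}

#' Reconstruct raw reads for trimming tests
#'
#' Builds the sequenced-strand read for an insert: degenerate 5' tag,
#' insert, 3' tag, then the 3'-adapter core (read-through).  The read
#' starts at the insert for standard adapters and at the 5' tag for HD
#' adapters, matching the input contract of [trim_reads()].
#'
#' @param insert insert sequence(s).
#' @param adapters an [adapter_set()].
#' @param tag5,tag3 tag sequences (recycled); required when
#'   `adapters$tag_length > 0`.
#' @return Character vector of raw reads.
#' @export
make_read <- function(insert, adapters, tag5 = "", tag3 = "") {
  stopifnot(inherits(adapters, "adapter_set"))
  if (adapters$tag_length > 0 &&
      (any(nchar(tag5) != adapters$tag_length) ||
       any(nchar(tag3) != adapters$tag_length))) {
    stop("tag lengths must equal adapters$tag_length", call. = FALSE)
  }
  paste0(tag5, oligo_normalize(insert), tag3, adapters$adapter3)
}

#' Paired HD-versus-standard library simulation
#'
#' Simulates the same molecule pool through a standard-adapter arm and an
#' HD-adapter arm under the same bias parameters, and compares capture
#' fractions and abundance curves.  The HD arm spreads each molecule over
#' sampled tag pairs, so its effective ligation weight is averaged over tag
#' contexts — the mechanism by which degenerate tags flatten the bias.
#'
#' @param cfg a [simulation_config()]; `cfg$tag_length` is used for the HD
#'   arm (must be > 0), the standard arm uses `tag_length = 0`.
#' @param adapters_standard,adapters_hd adapter sets for the two arms;
#'   defaults share the same cores.
#' @param top_m length of the reported abundance curves.
#' @return A list of class `hd_comparison`: `standard` and `hd`
#'   (`sim_library` objects) and `comparison`, a tibble with one row per
#'   arm (`capture_fraction` over the shared pool, `top1_count`).
#' @export
simulate_hd_vs_standard <- function(cfg,
                                    adapters_standard = example_adapters(0),
                                    adapters_hd = example_adapters(cfg$tag_length),
                                    top_m = 100) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$tag_length < 1) stop("cfg$tag_length must be >= 1 for the HD arm",
                               call. = FALSE)
  set.seed(cfg$seed)
  pool <- .draw_pool(cfg$pool_size, cfg$insert_length)

  cfg_std <- cfg; cfg_std$tag_length <- 0L; cfg_std$seed <- cfg$seed + 1L
  cfg_hd <- cfg; cfg_hd$seed <- cfg$seed + 2L
  std <- simulate_library(cfg_std, adapters_standard, pool = pool)
  hd <- simulate_library(cfg_hd, adapters_hd, pool = pool)

  cap <- function(sim) nrow(sim$counts) / length(pool)
  comparison <- tibble::tibble(
    arm = c("standard", "hd"),
    capture_fraction = c(cap(std), cap(hd)),
    top1_count = c(abundance_curve(std$counts, 1)$count,
                   abundance_curve(hd$counts, 1)$count)
  )
  structure(list(standard = std, hd = hd, comparison = comparison),
            class = "hd_comparison")
}

#' Simulate two-protocol miRNA duplex count tables
#'
#' Generates 5p/3p strand counts for `n_precursors` miRNA precursors under
#' two protocols (two replicate libraries each), with a known subset whose
#' dominant strand flips between protocols.  Used as ground truth for
#' [detect_arm_switch()].
#'
#' @param n_precursors number of precursors (the reference analysis scale
#'   is 122 expressed duplex pairs).
#' @param arm_switch_fraction fraction of precursors simulated with a
#'   protocol-dependent dominant strand.
#' @param mean_expression mean per-duplex expression (reads per replicate).
#' @param dominance_log2 typical log2 dominance of the major strand.
#' @param seed integer seed.
#' @return A list: `duplexes` (long tibble `precursor` / `arm` /
#'   `protocol` / `library` / `count`) and `truth` (tibble `precursor` /
#'   `switched`).
#' @export
simulate_duplex_counts <- function(n_precursors = 122, arm_switch_fraction = 0.12,
                                   mean_expression = 200, dominance_log2 = 3,
                                   seed = 1) {
  stopifnot(arm_switch_fraction >= 0, arm_switch_fraction <= 1)
  set.seed(seed)
  n_switch <- round(n_precursors * arm_switch_fraction)
  switched <- c(rep(TRUE, n_switch), rep(FALSE, n_precursors - n_switch))
  switched <- sample(switched)
  precursor <- sprintf("mir-%03d", seq_len(n_precursors))

  expr <- stats::rlnorm(n_precursors, meanlog = log(mean_expression), sdlog = 0.8)
  delta <- sample(c(-1, 1), n_precursors, replace = TRUE) *
    (dominance_log2 + abs(stats::rnorm(n_precursors, 0, 1)))
  delta_b <- ifelse(switched, -delta, delta)

  rows <- purrr::pmap_dfr(
    list(precursor, expr, delta, delta_b),
    function(name, e, da, db) {
      mk <- function(proto, d) {
        mu5 <- e * 2^(d / 2); mu3 <- e * 2^(-d / 2)
        tibble::tibble(
          precursor = name,
          arm = rep(c("5p", "3p"), times = 2),
          protocol = proto,
          library = rep(c("rep1", "rep2"), each = 2),
          count = stats::rpois(4, c(mu5 / 2, mu3 / 2, mu5 / 2, mu3 / 2))
        )
      }
      dplyr::bind_rows(mk("A", da), mk("B", db))
    }
  )
  list(duplexes = rows, truth = tibble::tibble(precursor = precursor,
                                               switched = switched))
}

#' Write a count table to TSV
#'
#' @param data tibble with `sequence` and `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(data, path) {
  readr::write_tsv(dplyr::select(data, "sequence", "count"), path)
  invisible(path)
}

#' Write simulated raw reads as FASTA
#'
#' Expands a simulated library into per-read raw sequences (via
#' [make_read()]) and writes them as FASTA, for end-to-end trimming tests.
#'
#' @param sim a `sim_library` from [simulate_library()].
#' @param adapters the adapter set the library was simulated with.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(sim, adapters, path) {
  tab <- if (!is.null(sim$tagged)) sim$tagged else
    dplyr::mutate(dplyr::rename(sim$counts, insert = "sequence"),
                  tag5 = "", tag3 = "")
  reads <- rep(make_read(tab$insert, adapters, tab$tag5, tab$tag3),
               times = tab$count)
  set <- Biostrings::BStringSet(reads)
  names(set) <- sprintf("read_%06d", seq_along(set))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
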