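toy_adapters <- function(tag_length = 0) {
  adapter_set("CCAAGG", "GGUUCC", tag_length = tag_length)
}

test_that("constructs concatenate segments and index junctions correctly", {
  ad <- toy_adapters()
  ins <- build_construct("AAA", ad, mode = "insert_only")
  expect_equal(ins$sequence, "AAA")
  expect_true(is.na(ins$junction5) && is.na(ins$junction3))

  ad3 <- adapter_set("CC", "GGG", tag_length = 0)
  i3 <- build_construct("AAA", ad3, mode = "insert_plus_3")
  expect_equal(i3$sequence, "AAAGGG")
  expect_equal(i3$junction3, 3L)

  hd <- adapter_set("CC", "GG", tag_length = 2)
  full <- build_construct("AAA", hd, mode = "full_construct",
                          tag5 = "AU", tag3 = "GC")
  expect_equal(full$sequence, "CCAUAAAGCGG")
  expect_equal(full$junction5, 4L)
  expect_equal(full$junction3, 7L)
  expect_equal(full$segments[5:7], rep("insert", 3))
})

test_that("construct tag requirements are enforced", {
  hd <- adapter_set("CC", "GG", tag_length = 2)
  expect_error(build_construct("AAA", hd, mode = "full_construct"), "tags")
  expect_error(build_construct("AAA", hd, mode = "full_construct",
                               tag5 = "A", tag3 = "GC"), "length")
  std <- toy_adapters()
  expect_error(build_construct("AAA", std, mode = "full_construct",
                               tag5 = "AU", tag3 = "GC"), "tags")
})

test_that("pairing profiles are indicator averages", {
  # molecules that cannot pair anywhere -> all-zero profile
  p0 <- pairing_profile(tibble::tibble(sequence = c("AAAAAAAA", "AAACAAAA")))
  expect_true(all(p0$frequency == 0))
  # a single hairpin: 1 on the stem, 0 in the loop
  p1 <- pairing_profile(tibble::tibble(sequence = "GGGAAAACCC"))
  expect_equal(p1$frequency, c(1, 1, 1, 0, 0, 0, 0, 1, 1, 1))
  expect_equal(attr(p1, "n_molecules"), 1)
  # mixed lengths are rejected
  expect_error(pairing_profile(tibble::tibble(sequence = c("AAAA", "AAAAA"))),
               "equal-length")
})

test_that("profile of a union is the weighted average of the parts", {
  set.seed(21)
  a <- random_rna(12, 15); b <- random_rna(8, 15)
  pa <- pairing_profile(tibble::tibble(sequence = a))
  pb <- pairing_profile(tibble::tibble(sequence = b))
  pu <- pairing_profile(tibble::tibble(sequence = c(a, b)))
  expect_equal(pu$frequency,
               (12 * pa$frequency + 8 * pb$frequency) / 20, tolerance = 1e-12)
})

test_that("adding one molecule moves each frequency by at most 1/n", {
  set.seed(22)
  base <- random_rna(19, 12)
  p1 <- pairing_profile(tibble::tibble(sequence = base))
  p2 <- pairing_profile(tibble::tibble(sequence = c(base, random_rna(1, 12))))
  expect_true(all(abs(p2$frequency - p1$frequency * 19 / 20) <= 1 / 20 + 1e-12))
})

test_that("junction fractions read the base adjacent to the ligation point", {
  prof <- structure(tibble::tibble(position = 0:9, frequency = c(rep(0.2, 5), 0.53, rep(0.2, 4))),
                    junction5 = 2L, junction3 = 6L,
                    class = c("pairing_profile", "tbl_df", "tbl", "data.frame"))
  expect_equal(junction_pairing_fraction(prof, junction = 6, side = "downstream"), 0.2)
  expect_equal(junction_pairing_fraction(prof, junction = 6, side = "upstream"), 0.53)
  # defaults resolve against the junctions stored in the profile
  expect_equal(junction_pairing_fraction(prof, side = "upstream"), 0.53)
  expect_error(junction_pairing_fraction(prof, junction = 0, side = "upstream"), "edge|no ")
})

test_that("3'-ligation bias enriches pairing upstream of the junction", {
  ad <- example_adapters(0)
  upstream <- vapply(1:5, function(s) {
    biased <- simulate_library(simulation_config(insert_length = 15, pool_size = 150,
                                                 depth = 8e3, beta3 = 3, seed = s))
    tops <- abundance_curve(biased$counts, 60)$sequence
    pb <- pairing_profile(lapply(tops, build_construct, adapters = ad,
                                 mode = "full_construct"))
    set.seed(s + 900)
    ctrl <- pairing_profile(lapply(ligbias:::.draw_pool(150, 15), build_construct,
                                   adapters = ad, mode = "full_construct"))
    junction_pairing_fraction(pb, side = "upstream") -
      junction_pairing_fraction(ctrl, side = "upstream")
  }, 1.0)
  expect_true(all(upstream > 0))
})

test_that("profile similarity is a squared correlation", {
  set.seed(30)
  a <- pairing_profile(tibble::tibble(sequence = random_rna(10, 14)))
  expect_equal(profile_similarity(a, a), 1)
  flipped <- a
  flipped$frequency <- 1 - a$frequency
  expect_equal(profile_similarity(a, flipped), 1) # R^2 ignores sign
  flat <- a
  flat$frequency <- rep(0.5, nrow(a))
  expect_error(profile_similarity(a, flat), "zero variance")
  # independent random profiles have low R^2
  b <- pairing_profile(tibble::tibble(sequence = random_rna(10, 14)))
  expect_lt(profile_similarity(a, b), 0.9)
})

test_that("MFE-abundance correlation behaves at its extremes", {
  ad <- example_adapters(0)
  set.seed(40)
  seqs <- unique(random_rna(40, 12))
  folded <- fold_sequences(tibble::tibble(
    sequence = vapply(seqs, function(s) build_construct(s, ad, "insert_plus_3")$sequence, "")
  ))
  # counts as an exact monotone (linear in MFE) construction -> R^2 = 1
  counts <- round(1000 - 90 * folded$mfe)
  fit <- mfe_abundance_correlation(tibble::tibble(sequence = seqs, count = counts), ad)
  expect_gt(fit$r_squared, 0.99)
  expect_equal(nrow(tidy(fit)), length(seqs))
  # all-equal counts are degenerate
  expect_error(
    mfe_abundance_correlation(tibble::tibble(sequence = seqs, count = 5), ad),
    "equal"
  )
})

test_that("unbiased libraries show no MFE-abundance correlation", {
  ad <- example_adapters(0)
  r2 <- vapply(1:6, function(s) {
    sim <- simulate_library(simulation_config(insert_length = 21, pool_size = 150,
                                              depth = 1.5e4, seed = s))
    mfe_abundance_correlation(sim$counts, ad)$r_squared
  }, 1.0)
  expect_true(all(r2 < 0.05))
})

test_that("replicate profiles combine into mean with min/max envelope", {
  set.seed(50)
  p1 <- pairing_profile(tibble::tibble(sequence = random_rna(8, 12)))
  p2 <- pairing_profile(tibble::tibble(sequence = random_rna(8, 12)))
  comb <- combine_profiles(p1, p2)
  expect_equal(comb$frequency, (p1$frequency + p2$frequency) / 2)
  expect_true(all(comb$min <= comb$frequency & comb$frequency <= comb$max))
})
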