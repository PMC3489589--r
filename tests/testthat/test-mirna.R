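test_that("RPM normalisation is exact arithmetic", {
  tab <- tibble::tibble(name = c("miR-a", "miR-b"), count = c(150L, 0L))
  out <- rpm_normalize(tab, library_total = 1000)
  expect_equal(out$rpm, c(150000, 0))
  # self-normalised RPM sums to one million
  tab2 <- tibble::tibble(name = letters[1:5], count = c(10L, 20L, 5L, 40L, 25L))
  expect_equal(sum(rpm_normalize(tab2)$rpm), 1e6)
  expect_error(rpm_normalize(tab, library_total = 0), "positive")
  expect_error(rpm_normalize(tab2, library_total = 50), "smaller")
})

test_that("ranks are invariant to uniform depth scaling", {
  tab <- tibble::tibble(name = letters[1:4], count = c(10L, 40L, 20L, 5L))
  scaled <- dplyr::mutate(tab, count = count * 17L)
  expect_equal(rpm_normalize(tab)$rank, rpm_normalize(scaled)$rank)
})

test_that("detection curves count thresholded miRNAs and never increase", {
  tab <- tibble::tibble(name = c("a", "b", "c"), count = c(5L, 10L, 20L))
  out <- detection_curve(tab, thresholds = c(1, 10, 100))
  expect_equal(out$n_detected, c(3L, 2L, 0L))
  # non-increasing for arbitrary inputs
  set.seed(12)
  for (i in 1:5) {
    tab <- tibble::tibble(count = rpois(50, 10))
    curve <- detection_curve(tab, thresholds = sort(sample(1:40, 8)))
    expect_true(all(diff(curve$n_detected) <= 0))
  }
})

test_that("HD libraries detect at least as many molecules at every threshold", {
  cfg <- simulation_config(insert_length = 9, pool_size = 200, depth = 1e4,
                           beta3 = 3, beta5 = 3, tag_length = 2,
                           tags_per_molecule = 8, seed = 3)
  cmp <- simulate_hd_vs_standard(cfg)
  th <- c(1, 2, 5, 10, 20)
  d_std <- detection_curve(cmp$standard$counts, th)$n_detected
  d_hd <- detection_curve(cmp$hd$counts, th)$n_detected
  expect_true(all(d_hd >= d_std))
})

test_that("fold-change concordance is perfect for identical protocols", {
  tab <- tibble::tibble(name = letters[1:6],
                        a_wt = c(100, 50, 10, 0, 400, 3),
                        a_ko = c(10, 50, 40, 2, 100, 3))
  tab$b_wt <- tab$a_wt; tab$b_ko <- tab$a_ko
  fit <- fold_change_concordance(tab)
  expect_equal(fit$r_squared, 1)
  expect_equal(tidy(fit)$log2fc_a, tidy(fit)$log2fc_b)
})

test_that("pseudocounts keep fold changes finite with zero denominators", {
  tab <- tibble::tibble(name = "a", a_wt = 100, a_ko = 0, b_wt = 80, b_ko = 0)
  fit <- fold_change_concordance(tab, pseudocount = 1)
  expect_true(all(is.finite(tidy(fit)$log2fc_a)))
  expect_error(fold_change_concordance(tab[0, ]), "shared")
})

test_that("protocol-specific bias spares fold changes but distorts levels", {
  set.seed(77)
  n <- 60
  biology <- rlnorm(n, log(100), 1)     # protocol-independent expression
  effect <- 2^rnorm(n, 0, 1.2)          # WT/KO biology shared across protocols
  bias_a <- 2^rnorm(n, 0, 1.5)          # per-miRNA, protocol-specific distortion
  bias_b <- 2^rnorm(n, 0, 1.5)
  tab <- tibble::tibble(
    name = sprintf("m%02d", 1:n),
    a_wt = biology * effect * bias_a, a_ko = biology * bias_a,
    b_wt = biology * effect * bias_b, b_ko = biology * bias_b
  )
  fit <- fold_change_concordance(tab, pseudocount = 1)
  expect_gt(fit$r_squared, 0.5)
  # absolute levels, in contrast, agree poorly across protocols
  level_r2 <- cor(log2(tab$a_wt + 1), log2(tab$b_wt + 1))^2
  expect_lt(level_r2, fit$r_squared)
})

arm_duplexes <- function(c5a, c3a, c5b, c3b, name = "mir-1") {
  tidyr::expand_grid(precursor = name, arm = c("5p", "3p"), protocol = c("A", "B")) |>
    dplyr::mutate(count = dplyr::case_when(
      arm == "5p" & protocol == "A" ~ c5a, arm == "3p" & protocol == "A" ~ c3a,
      arm == "5p" & protocol == "B" ~ c5b, arm == "3p" & protocol == "B" ~ c3b
    ), library = "rep1")
}

test_that("arm switches are called when dominant strands disagree", {
  totals <- tibble::tibble(protocol = c("A", "B"), total = c(1e6, 1e6))
  switch <- detect_arm_switch(arm_duplexes(100, 10, 10, 100), totals = totals)
  expect_equal(switch$direction, -1)
  same <- detect_arm_switch(arm_duplexes(100, 10, 80, 12), totals = totals)
  expect_equal(same$direction, 1)
  tie <- detect_arm_switch(arm_duplexes(50, 50, 100, 10), totals = totals)
  expect_true(is.na(tie$direction)) # tie -> no call
})

test_that("low-expression duplexes are excluded from the arm-switch analysis", {
  totals <- tibble::tibble(protocol = c("A", "B"), total = c(1e6, 1e6))
  low <- detect_arm_switch(arm_duplexes(5, 3, 4, 2), totals = totals,
                           rpm_threshold = 10)
  expect_equal(nrow(low), 0)
  # > 10 RPM in either protocol is enough
  one_side <- detect_arm_switch(arm_duplexes(5, 3, 10000, 2), totals = totals)
  expect_equal(nrow(one_side), 1)
})

test_that("arm-switch calls are invariant to protocol relabelling", {
  sd <- simulate_duplex_counts(60, 0.15, seed = 8)
  a <- detect_arm_switch(sd$duplexes)
  flipped <- dplyr::mutate(sd$duplexes,
                           protocol = ifelse(protocol == "A", "B", "A"))
  b <- detect_arm_switch(flipped)
  merged <- dplyr::inner_join(a, b, by = "precursor", suffix = c("_ab", "_ba"))
  expect_equal(merged$direction_ab, merged$direction_ba)
  expect_equal(merged$dominant_a_ab, merged$dominant_b_ba)
})

test_that("replicates are summed within protocol before dominance calls", {
  dup <- dplyr::bind_rows(
    arm_duplexes(30, 40, 100, 10),                   # rep1: 3p dominant in A
    dplyr::mutate(arm_duplexes(40, 10, 100, 10), library = "rep2")
  ) # summed A: 5p 70 vs 3p 50 -> 5p dominant, as in B
  res <- detect_arm_switch(dup, totals = tibble::tibble(protocol = c("A", "B"),
                                                        total = c(1e6, 1e6)))
  expect_equal(res$count_5p_a, 70)
  expect_equal(res$direction, 1)
})

test_that("detect_arm_switch validates its inputs", {
  expect_error(detect_arm_switch(arm_duplexes(1, 2, 3, 4), rpm_threshold = -1),
               "non-negative")
  one_proto <- dplyr::filter(arm_duplexes(1, 2, 3, 4), protocol == "A")
  expect_error(detect_arm_switch(one_proto), "two protocols")
})

test_that("candidate filtering applies the strict fold-change and star rules", {
  cands <- tibble::tibble(
    name = c("kept", "boundary", "no_star", "strong"),
    wt_count = c(14, 13, 99, 100),
    ko_count = c(9, 9, 9, 9),
    star_seen = c(TRUE, TRUE, FALSE, TRUE)
  )
  out <- filter_new_candidates(cands, fc_min = 1.4)
  expect_setequal(out$name, c("kept", "strong"))
  # boundary: (13+1)/(9+1) = 1.4 exactly -> rejected under strict inequality
  expect_false("boundary" %in% out$name)
  expect_false("no_star" %in% out$name)
})
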