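test_that("perfect repeats are fully covered with the smallest tied period", {
  p <- detect_tandem_repeats(strrep("GA", 10), 1, 10)
  expect_equal(p$repeat_fraction, 1)
  expect_identical(p$regions$period, 2L)
  expect_identical(p$regions$consensus, "GA")
  q <- detect_tandem_repeats(strrep("GAGAGS", 5))
  expect_equal(q$repeat_fraction, 1)
  expect_identical(q$regions$consensus[1], "GAGAGS")
})

test_that("short sequences and repeat-free sequences yield empty profiles", {
  expect_equal(detect_tandem_repeats("G")$repeat_fraction, 0)
  expect_identical(nrow(detect_tandem_repeats("A", min_period = 1)$regions), 0L)
  expect_equal(detect_tandem_repeats("ARNDCQEGHILKMFPSTWYV")$repeat_fraction, 0)
})

test_that("detected coverage equals the exhaustive perfect-repeat oracle on small cases", {
  # spot panel here; the full <=12 sweep runs in the acceptance suite
  set.seed(1)
  cases <- c("AAGGAAGG", "AGAGAGA", "AAAAAAG", "GAGGAGGAG", "AGGAGGAA",
             replicate(40, random_aa(sample(4:12, 1), c("A", "G"))))
  for (s in cases) {
    det <- detect_tandem_repeats(s, 1, 60, min_copies = 2, max_divergence = 0)
    expect_equal(det$repeat_fraction * nchar(s), oracle_perfect_coverage(s),
                 info = s)
  }
})

test_that("random sequences stay mostly repeat-free under the null settings", {
  set.seed(99)
  fr <- replicate(30, detect_tandem_repeats(random_aa(1000), 1, 20,
                                            min_copies = 3,
                                            max_divergence = 0.1)$repeat_fraction)
  expect_gte(mean(fr < 0.10), 0.95)
})

test_that("raising max_divergence never decreases repeat coverage", {
  set.seed(12)
  for (i in 1:12) {
    s <- random_aa(250)
    if (i %% 3 == 0)
      s <- paste0(s, strrep("GAGAGS", 15), random_aa(60))
    f <- vapply(c(0, 0.1, 0.2, 0.3, 0.45), function(d)
      detect_tandem_repeats(s, max_divergence = d)$repeat_fraction, 1)
    expect_true(all(diff(f) >= -1e-12), info = paste(i))
  }
})

test_that("non-repetitive flanks are never absorbed into repeat regions", {
  set.seed(21)
  for (i in 1:25) {
    unit <- sample(c("GAGAGS", "SVSTSE", "CCQPTC"), 1)
    core <- strrep(unit, 15)
    pool <- setdiff(AA20_TEST, strsplit(unit, "")[[1]])
    half <- sample(length(pool))
    fl1 <- paste(sample(pool[half[1:8]], sample(4:8, 1)), collapse = "")
    fl2 <- paste(sample(pool[half[9:16]], sample(4:8, 1)), collapse = "")
    cov_core <- detect_tandem_repeats(core)$repeat_fraction * nchar(core)
    flanked <- paste0(fl1, core, fl2)
    cov_flank <- detect_tandem_repeats(flanked)$repeat_fraction * nchar(flanked)
    expect_lte(cov_flank, cov_core + 1e-9)
  }
})

test_that("profile invariants hold on mutated silk-like sequences", {
  g <- silk_grammars(0.05)
  set.seed(8)
  for (i in 1:6) {
    s <- generate_silk_protein(g[[sample(length(g), 1)]], 40,
                               termini = c(random_aa(30), random_aa(15)),
                               rng_seed = i)
    p <- detect_tandem_repeats(s)
    expect_gte(p$repeat_fraction, 0)
    expect_lte(p$repeat_fraction, 1)
    r <- p$regions
    if (nrow(r) > 1) {
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))  # disjoint, sorted
    }
    expect_true(all(r$start >= 0 & r$end <= p$length))
    expect_equal(sum(r$end - r$start) / p$length, p$repeat_fraction,
                 tolerance = 1e-9)
    expect_true(all(r$identity >= 0 & r$identity <= 1))
  }
})

test_that("repeat-fraction criterion is inclusive at the threshold", {
  expect_true(repeat_fraction_criterion(0.10, 0.10))
  expect_false(repeat_fraction_criterion(0, 0.10))
  expect_false(repeat_fraction_criterion(0.0999999, 0.10))
  p <- detect_tandem_repeats(strrep("GA", 10))
  expect_true(repeat_fraction_criterion(p, 0.10))
})

test_that("consensus is the column majority with earliest-copy tie-break", {
  # one mutated copy among 9 perfect leaves the consensus unchanged
  s <- paste0(strrep("GAGAGS", 4), "GTGAGS", strrep("GAGAGS", 5))
  p <- detect_tandem_repeats(s, max_divergence = 0.3)
  expect_identical(p$regions$consensus[1], "GAGAGS")
  # 50/50 column split: earliest copy wins (hand-built 2-copy case)
  reg <- list(start = 0L, end = 8L, period = 4L)
  expect_identical(consensus_motif(reg, "GASTGAVT"), "GAST")
})

test_that("motif classification follows the fibroin-style rules", {
  expect_identical(classify_motif("GAGAGS"), "silkworm-fibroin-like")
  expect_identical(classify_motif("GA"), "silkworm-fibroin-like")
  expect_identical(classify_motif("SASVSE"), "caddisworm-fibroin-like")
  expect_identical(classify_motif("SVSTSE"), "caddisworm-fibroin-like")
  expect_identical(classify_motif("GPP"), "collagen-like")
  expect_identical(classify_motif("GPPGPA"), "collagen-like")
  expect_identical(classify_motif("CCQPTC"), "KAP-like")
  expect_identical(classify_motif("LIVNMT"), "other")
  expect_error(classify_motif(""), "empty")
})
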