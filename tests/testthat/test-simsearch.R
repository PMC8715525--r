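test_that("self-alignment scores equal the diagonal substitution sums", {
  mat <- blosum62()
  for (s in c("GAGAGS", "MKTAYIAK", "WWWW")) {
    ch <- strsplit(s, "")[[1]]
    expect_equal(smith_waterman(s, s)$score,
                 sum(mat[cbind(ch, ch)]))
  }
  h <- smith_waterman("GAGAGS", "GAGAGS")
  expect_identical(c(h$q_start, h$q_end, h$s_start, h$s_end), c(0L, 6L, 0L, 6L))
  expect_identical(h$n_ident, 6L)
})

test_that("all-negative pairs and empty sequences give the no-hit sentinel", {
  h <- smith_waterman("WWWW", "GGGG")  # W-G = -2 under BLOSUM62
  expect_identical(h$score, 0)
  expect_identical(h$align_len, 0L)
  expect_identical(smith_waterman("", "GAGA")$score, 0)
})

test_that("alignment scores are symmetric under the symmetric matrix", {
  set.seed(5)
  for (i in 1:25) {
    a <- random_aa(sample(5:40, 1)); b <- random_aa(sample(5:40, 1))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("scores match path enumeration and an independent recursion on small pairs", {
  mat <- blosum62()
  set.seed(31)
  abc <- c("A", "G", "S")
  seqs3 <- unlist(lapply(1:3, function(L)
    apply(expand.grid(rep(list(abc), L)), 1, paste, collapse = "")))
  picks <- sample(length(seqs3)^2, 150)
  for (k in picks) {
    a <- seqs3[((k - 1) %% length(seqs3)) + 1]
    b <- seqs3[((k - 1) %/% length(seqs3)) + 1]
    expect_equal(smith_waterman(a, b)$score,
                 max(0, oracle_enum_local(a, b, mat)), info = paste(a, b))
  }
  for (i in 1:40) {
    a <- random_aa(sample(4:8, 1), abc); b <- random_aa(sample(4:8, 1), abc)
    expect_equal(smith_waterman(a, b)$score,
                 max(0, oracle_rec_local(a, b, mat)), info = paste(a, b))
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  expect_equal(evalue(100, 250, 1e5, K = 0.134, lambda = 0.3176),
               0.134 * 250 * 1e5 * exp(-0.3176 * 100))
  s <- seq(10, 300, by = 10)
  ev <- evalue(s, 200, 1e6)
  expect_true(all(diff(ev) < 0))              # strictly decreasing in score
  expect_equal(evalue(50, 100, 2e5), 2 * evalue(50, 100, 1e5))  # linear in n
  expect_error(evalue(10, 0, 100), "positive")
  expect_gt(bit_score(100), bit_score(50))
})

test_that("six-frame translation obeys the genetic code and strand symmetry", {
  fr <- six_frame_translate("ATGGCT")
  expect_identical(fr[["+1"]], "MA")
  expect_identical(six_frame_translate("TAATAG")[["+1"]], "**")
  expect_identical(six_frame_translate("ATGNNT")[["+1"]], "MX")
  set.seed(6)
  for (i in 1:10) {
    nt <- paste(sample(c("A", "C", "G", "T"), 3 * sample(5:30, 1), TRUE),
                collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    expect_identical(six_frame_translate(nt)[["-1"]],
                     six_frame_translate(rc)[["+1"]])
  }
})

test_that("novelty filter separates self-matches from unrelated queries", {
  set.seed(17)
  db <- setNames(replicate(30, random_aa(sample(80, 1) + 60)),
                 sprintf("known%02d", 1:30))
  expect_false(novelty_filter(db[[4]], db))      # identical to a db entry
  expect_error(novelty_filter("GAGAGS", character(0)), "empty")
  # random 200-mers against an unrelated db are almost always novel
  nov <- replicate(40, novelty_filter(random_aa(200), db))
  expect_gte(mean(nov), 0.99)
  # filter decision is invariant to database record order
  q <- db[[9]]
  expect_identical(novelty_filter(q, db), novelty_filter(q, rev(db)))
})

test_that("planted silks are novel against the decoy database", {
  st <- simulate_silk_study(tiny_config(seed = 4))
  kdb <- search_db(st$known_db)
  silk <- st$protein_info[role == "silk", protein_id]
  expect_true(all(vapply(st$proteins[silk], novelty_filter, logical(1),
                         known_db = kdb)))
  others <- st$protein_info[role != "silk", protein_id]
  expect_false(any(vapply(st$proteins[others[1:10]], novelty_filter,
                          logical(1), known_db = kdb)))
})

test_that("the k-mer prefilter does not change novelty decisions", {
  set.seed(23)
  db <- setNames(replicate(15, random_aa(150)), sprintf("d%02d", 1:15))
  queries <- c(db[[3]], random_aa(150), paste0(strrep("GAGAGS", 20),
                                               random_aa(40)))
  for (q in queries) {
    expect_identical(novelty_filter(q, db, prefilter_k = 5L),
                     novelty_filter(q, db, prefilter_k = 0L))
  }
})

test_that("conservation recovers a hand-planted matrix and the max-TPM rule", {
  set.seed(2)
  fams <- c(fx = paste0(random_aa(60), strrep("GAGAGS", 25)),
            fy = paste0(random_aa(60), strrep("SVSTSE", 25)))
  mk_decoy <- function() paste(sample(c("A", "C", "G", "T"), 900, TRUE),
                               collapse = "")
  asm <- list(
    spA = c(t1 = back_translate(substr(fams[["fx"]], 1, 170)), t2 = mk_decoy(),
            t3 = back_translate(substr(fams[["fx"]], 1, 170))),
    spB = c(t1 = mk_decoy(), t2 = back_translate(substr(fams[["fy"]], 1, 170))))
  tpms <- list(
    spA = data.table::data.table(transcript_id = c("t1", "t2", "t3"),
                                 tpm = c(5, 100, 50)),
    spB = data.table::data.table(transcript_id = c("t1", "t2"),
                                 tpm = c(7, 33)))
  cm <- conservation_matrix(fams, asm, tpms)
  expect_identical(nrow(cm), 4L)
  expect_identical(cm[family_id == "fx" & species_id == "spA", conserved], TRUE)
  expect_identical(cm[family_id == "fx" & species_id == "spB", conserved], FALSE)
  expect_identical(cm[family_id == "fy" & species_id == "spB", conserved], TRUE)
  # two qualifying transcripts with TPM 5 and 50: the maximum is reported
  expect_equal(cm[family_id == "fx" & species_id == "spA", expression_tpm], 50)
  expect_true(is.na(cm[family_id == "fx" & species_id == "spB",
                       expression_tpm]))
  # missing TPM flags the cell instead of zeroing it
  tpms2 <- tpms; tpms2$spA <- tpms2$spA[transcript_id != "t3"]
  cm2 <- conservation_matrix(fams, asm, tpms2)
  expect_true(cm2[family_id == "fx" & species_id == "spA", tpm_missing])
  expect_error(conservation_matrix(fams, asm, tpms["spA"]), "TPM")
})

test_that("conservation sensitivity is perfect at zero divergence and degrades monotonically", {
  cfg0 <- tiny_config(seed = 6, divergence = 0)
  st0 <- simulate_silk_study(cfg0)
  cm0 <- conservation_matrix(st0$families,
                             lapply(st0$transcriptomes, `[[`, "transcripts"),
                             lapply(st0$transcriptomes, `[[`, "tpm"))
  m0 <- merge(cm0, st0$truth$conservation, by = c("family_id", "species_id"))
  expect_identical(m0$conserved.x, m0$conserved.y)
  sens0 <- mean(m0[conserved.y == TRUE, conserved.x])
  expect_identical(sens0, 1)
  st4 <- simulate_silk_study(tiny_config(seed = 6, divergence = 0.4))
  cm4 <- conservation_matrix(st4$families,
                             lapply(st4$transcriptomes, `[[`, "transcripts"),
                             lapply(st4$transcriptomes, `[[`, "tpm"))
  m4 <- merge(cm4, st4$truth$conservation, by = c("family_id", "species_id"))
  sens4 <- mean(m4[conserved.y == TRUE, conserved.x])
  expect_lte(sens4, sens0)
})
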