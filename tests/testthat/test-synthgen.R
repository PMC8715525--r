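test_that("grammar sampling concatenates units with flanks and respects zero mutation", {
  g <- motif_grammar("toy", "GAGAGS", mutation_rate = 0)
  expect_identical(generate_silk_protein(g, 3, termini = c("M", ""), rng_seed = 1),
                   "MGAGAGSGAGAGSGAGAGS")
  g2 <- motif_grammar("toy", "GA", mutation_rate = 0)
  s <- generate_silk_protein(g2, 100, termini = c("MKT", "PQ"), rng_seed = 5)
  expect_identical(nchar(s), 5L + 200L)
})

test_that("silk generation is seed-deterministic and mutation separates seeds", {
  g <- motif_grammar("toy", "GAGAGS", mutation_rate = 0.05)
  expect_identical(generate_silk_protein(g, 50, rng_seed = 42),
                   generate_silk_protein(g, 50, rng_seed = 42))
  # Monte-Carlo: with per-residue mutation 0.05 over 300 residues, two seeds
  # almost surely differ (P[identical] ~ (1 - 2*0.05*0.95)^300, negligible)
  a <- generate_silk_protein(g, 50, rng_seed = 1)
  b <- generate_silk_protein(g, 50, rng_seed = 2)
  expect_false(identical(a, b))
})

test_that("grammar validation rejects degenerate configurations", {
  expect_error(motif_grammar("bad", character()), "core unit")
  expect_error(motif_grammar("bad", c("GA", "GS"), unit_weights = c(0.5, 0.6)),
               "sum to 1")
  expect_error(motif_grammar("bad", "GAGAX9"), "non-canonical")
  expect_error(motif_grammar("bad", "GAGAGS", mutation_rate = 1.2),
               "mutation_rate")
})

test_that("decoy proteome matches requested size, lengths and composition", {
  expect_length(generate_decoy_proteome(0), 0L)
  expect_error(generate_decoy_proteome(5, composition = rep(0, 20)),
               "degenerate")
  d <- generate_decoy_proteome(1000, length_range = c(100, 100), rng_seed = 3)
  expect_true(all(nchar(d) == 100))
  # uniform composition: per-residue frequency 0.05 within 3 binomial SEs
  ch <- unlist(strsplit(unname(d), ""))
  fr <- table(factor(ch, levels = AA20_TEST)) / length(ch)
  se <- sqrt(0.05 * 0.95 / length(ch))
  expect_true(all(abs(fr - 0.05) < 3 * se + 1e-12))
  expect_identical(d, generate_decoy_proteome(1000, length_range = c(100, 100),
                                              rng_seed = 3))
})

test_that("tryptic digestion follows the Keil rule", {
  expect_identical(in_silico_digest("AAKBBRCC", 0), c("AAK", "BBR", "CC"))
  expect_identical(in_silico_digest("AAKPBB", 0), "AAKPBB")
  expect_identical(in_silico_digest("", 2), character(0))
  # trailing K/R produces no empty peptide
  expect_identical(in_silico_digest("AAK", 0), "AAK")
})

test_that("missed-cleavage peptides equal the contiguous-fragment enumeration", {
  # oracle: all concatenations of <= mc+1 consecutive fully-cleaved fragments
  oracle <- function(seq, mc) {
    frags <- in_silico_digest(seq, 0)
    out <- character(0)
    for (i in seq_along(frags))
      for (j in i:min(i + mc, length(frags)))
        out <- c(out, paste(frags[i:j], collapse = ""))
    sort(out)
  }
  for (s in c("AKRK", "MAKRPKSTR", "KRKRKR", "AAAKAAARAAA")) {
    for (mc in 0:2) {
      expect_setequal(in_silico_digest(s, mc), oracle(s, mc))
    }
  }
})

test_that("peptide evidence has the planted noiseless limit and empirical CV", {
  prot <- c(p1 = "MAAAGTKLLSIERVVVTTTKQQQNDEK")
  ab <- c(p1 = 100)
  ev <- simulate_peptide_evidence(prot, ab, n_replicates = 3,
                                  detection_prob = 1, intensity_cv = 0,
                                  rng_seed = 1)
  expect_true(all(ev$feature_area == 100))
  npep <- length(observable_peptides(prot[[1]]))
  expect_identical(nrow(ev), npep * 3L)
  expect_identical(
    nrow(simulate_peptide_evidence(prot, ab, detection_prob = 0,
                                   rng_seed = 1)), 0L)
  expect_error(simulate_peptide_evidence(prot, ab, detection_prob = 1.5),
               "detection_prob")
  # log-normal noise: empirical per-peptide CV near the requested 0.3
  proteins <- setNames(rep(paste0(strrep("LSIAGTEV", 3), "K"), 40),
                       sprintf("q%02d", 1:40))
  ev2 <- simulate_peptide_evidence(proteins, setNames(rep(50, 40),
                                                      names(proteins)),
                                   n_replicates = 25, detection_prob = 1,
                                   intensity_cv = 0.3, rng_seed = 9)
  cvs <- ev2[, stats::sd(feature_area) / mean(feature_area),
             by = .(protein_id, peptide)]$V1
  expect_lt(abs(mean(cvs) - 0.3) / 0.3, 0.2)
})

test_that("back-translation round-trips through the standard genetic code", {
  aa <- "MGAGAGSKRWY"
  nt <- back_translate(aa)
  expect_identical(nchar(nt), 3L * nchar(aa))
  expect_identical(six_frame_translate(nt)[["+1"]], aa)
  expect_error(back_translate("MAX"), "non-canonical")
})

test_that("simulated transcriptomes plant orthologs per presence and normalise TPM", {
  fams <- c(famA = paste0(strrep("GAGAGS", 30), "MKTLLE"),
            famB = paste0(strrep("SVSTSE", 30), "MKTLLE"))
  pres <- rbind(famA = c(TRUE, FALSE), famB = c(TRUE, TRUE))
  tx <- simulate_transcriptomes(fams, pres, divergence = 0,
                                n_decoy_transcripts = 5, rng_seed = 2)
  expect_named(tx, c("sp1", "sp2"))
  expect_identical(sort(tx$sp1$planted$family_id), c("famA", "famB"))
  expect_identical(tx$sp2$planted$family_id, "famB")
  for (sp in tx) {
    expect_lt(abs(sum(sp$tpm$tpm) - 1e6), 1e-3)
    expect_identical(sp$tpm$id_rank, seq_along(sp$transcripts))
  }
  # divergence 0: a planted transcript translates back to the family prefix
  id <- tx$sp2$planted$transcript_id[1]
  fr <- six_frame_translate(tx$sp2$transcripts[[id]])
  expect_true(any(vapply(fr, function(x)
    identical(x, substr(fams[["famB"]], 1, nchar(x))), logical(1))))
  expect_warning(simulate_transcriptomes(fams, pres, divergence = 0.6,
                                         n_decoy_transcripts = 2,
                                         rng_seed = 1), "divergence")
})

test_that("study generation is byte-deterministic for a fixed config", {
  a <- simulate_silk_study(tiny_config(seed = 5))
  b <- simulate_silk_study(tiny_config(seed = 5))
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$peptides, b$peptides)
  expect_identical(lapply(a$transcriptomes, `[[`, "transcripts"),
                   lapply(b$transcriptomes, `[[`, "transcripts"))
  expect_false(identical(
    a$proteins, simulate_silk_study(tiny_config(seed = 6))$proteins))
})

test_that("study files round-trip through the plain-text exchange formats", {
  st <- simulate_silk_study(tiny_config(seed = 2))
  dir <- tempfile("study")
  on.exit(unlink(dir, recursive = TRUE))
  write_silk_study(st, dir)
  expect_identical(read_fasta(file.path(dir, "proteins.faa")), st$proteins)
  pep <- data.table::fread(file.path(dir, "peptides.tsv"))
  expect_identical(nrow(pep), nrow(st$peptides))
  tpm1 <- data.table::fread(file.path(dir, "tpm_sp1.tsv"))
  expect_lt(abs(sum(tpm1$tpm) - 1e6), 1e-3)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$config$seed, 2L)
})
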