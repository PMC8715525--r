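# The default synthetic silk study: six planted silk families (one
# GA/GAGAGS-type, three serine-rich paralogs sharing a conserved N-terminal
# flank, one GPX collagen-like, one cysteine-rich KAP-like), each with
# near-full-length isoforms, among hundreds of globular decoys; replicate
# peptide evidence; a known-protein database; and multi-species
# transcriptomes with planted orthologs. Plus the end-to-end screen driver.

#' Synthetic study configuration
#'
#' Bundles every tunable of [simulate_silk_study()] with the default study
#' conditions: 6 silk families (21 isoform transcripts) among 500 decoys,
#' 5 replicates at 0.9 detection probability and 0.3 intensity CV, and 8
#' species with 5% ortholog divergence.
#'
#' @param seed Master seed; all per-component seeds derive from it via
#'   [child_seed()].
#' @param n_decoys Number of decoy proteins (also the known database).
#' @param n_replicates Proteomic replicates (>= 2).
#' @param detection_prob Per-peptide, per-replicate detection probability.
#' @param intensity_cv Coefficient of variation of feature areas.
#' @param contaminant_count Flagged contaminant proteins added to the
#'   evidence and the known database.
#' @param n_species Number of synthetic species (>= 1).
#' @param divergence Ortholog per-site amino-acid substitution rate.
#' @param ortholog_presence Logical 6 x `n_species` matrix; default
#'   [default_presence()]. The three serine-rich paralogs share one
#'   presence pattern (their conserved flank and similar repeats make
#'   paralog-level presence unidentifiable by E-value search, so presence is
#'   planted at the class level).
#' @param mutation_rate Grammar unit mutation rate.
#' @param isoform_counts Integer 6-vector of isoforms per family (sums to
#'   the planted transcript count; default totals 21).
#' @param n_decoy_transcripts Decoy transcripts per species.
#' @param ortholog_repeat_aa Repeat residues retained in planted orthologs.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_decoys = 500L, n_replicates = 5L,
                         detection_prob = 0.9, intensity_cv = 0.3,
                         contaminant_count = 10L, n_species = 8L,
                         divergence = 0.05, ortholog_presence = NULL,
                         mutation_rate = 0.02,
                         isoform_counts = c(4L, 4L, 3L, 3L, 4L, 3L),
                         n_decoy_transcripts = 40L,
                         ortholog_repeat_aa = 60L) {
  stopifnot(n_decoys >= 0, n_replicates >= 2L, contaminant_count >= 0,
            n_species >= 1L, length(isoform_counts) == 6L,
            all(isoform_counts >= 1L))
  check_prob(detection_prob, "detection_prob")
  stopifnot(intensity_cv >= 0, divergence >= 0, divergence < 1)
  if (is.null(ortholog_presence))
    ortholog_presence <- default_presence(n_species)
  stopifnot(is.matrix(ortholog_presence), nrow(ortholog_presence) == 6L,
            ncol(ortholog_presence) == n_species)
  structure(
    list(seed = as.integer(seed), n_decoys = n_decoys,
         n_replicates = n_replicates, detection_prob = detection_prob,
         intensity_cv = intensity_cv, contaminant_count = contaminant_count,
         n_species = n_species, divergence = divergence,
         ortholog_presence = ortholog_presence,
         mutation_rate = mutation_rate, isoform_counts = isoform_counts,
         n_decoy_transcripts = n_decoy_transcripts,
         ortholog_repeat_aa = ortholog_repeat_aa),
    class = "synth_config")
}

#' Default ortholog presence/absence matrix
#'
#' Six families by `n_species`, echoing the conservation pattern typical of
#' tanaidacean-style silk screens: the collagen-like and KAP-like families
#' are conserved everywhere (including the outgroup-like last species,
#' marking them as probable mucus contaminants), the GA-rich family is
#' restricted to the tube-weaving species block, and the three serine-rich
#' paralogs share one class-level pattern that extends into a second
#' superfamily-like block.
#'
#' @param n_species Number of species (>= 1); patterns recycle sensibly for
#'   other counts, default 8.
#' @return Logical matrix with family rownames and `sp*` colnames.
#' @export
default_presence <- function(n_species = 8L) {
  base <- rbind(
    silkworm_like = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    caddis_a = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    caddis_b = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    caddis_c = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    collagen_like = rep(TRUE, 8),
    kap_like = rep(TRUE, 8))
  m <- base[, rep_len(seq_len(8L), n_species), drop = FALSE]
  colnames(m) <- sprintf("sp%d", seq_len(n_species))
  m
}

# A non-repetitive flank with K/R sprinkled every ~12 residues so tryptic
# digestion of the termini yields observable peptides.
random_flank <- function(len, rng_seed) {
  with_seed(rng_seed, {
    ch <- sample(setdiff(AA20, c("K", "R")), len, replace = TRUE)
    kr <- seq.int(6L, len, by = 12L)
    ch[kr] <- sample(c("K", "R"), length(kr), replace = TRUE)
    paste(ch, collapse = "")
  })
}

#' Simulate a complete synthetic silk study
#'
#' Generates the six planted silk families and their isoforms, decoy and
#' contaminant proteins, replicate peptide evidence, the known-protein
#' database (decoys + contaminants, so every non-silk protein fails the
#' novelty criterion while every silk is novel), per-species transcriptomes
#' with planted orthologs, and a ground-truth manifest.
#'
#' @param config A [synth_config()].
#' @return Object of class `silk_study`: list with `proteins` (named
#'   character vector: silk isoforms, decoys, contaminants), `protein_info`
#'   (`data.table`: id, family, class, role, planted abundance), `peptides`
#'   (feature-area table), `known_db`, `transcriptomes` (see
#'   [simulate_transcriptomes()]), `families` (full-length family proteins),
#'   `truth` (planted expectations), and `config`.
#' @export
simulate_silk_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  seed <- config$seed
  grams <- silk_grammars(config$mutation_rate)
  fam_ids <- rownames(config$ortholog_presence)
  classes <- vapply(grams, `[[`, "", "name")

  # family flanks: the serine-rich paralogs share one N-flank (2% diverged
  # copies); everyone else gets an unrelated flank
  shared_nflank <- random_flank(80L, child_seed(seed, "caddis_nflank"))
  nflanks <- c(
    random_flank(80L, child_seed(seed, "nflank_1")),
    vapply(1:3, function(i) {
      with_seed(child_seed(seed, paste0("caddis_flank_mut_", i)),
                paste(mutate_residues(seq_chars(shared_nflank), 0.02),
                      collapse = ""))
    }, ""),
    random_flank(80L, child_seed(seed, "nflank_5")),
    random_flank(80L, child_seed(seed, "nflank_6")))
  cflanks <- vapply(seq_len(6L), function(i) {
    random_flank(30L, child_seed(seed, paste0("cflank_", i)))
  }, "")
  n_units <- c(230L, 120L, 110L, 100L, 100L, 90L)

  families <- setNames(vapply(seq_len(6L), function(i) {
    generate_silk_protein(grams[[i]], n_units[i],
                          termini = c(nflanks[i], cflanks[i]),
                          rng_seed = child_seed(seed, paste0("family_", i)))
  }, ""), fam_ids)

  # isoforms: near-full-length C-terminal truncations with light substitution
  base_abund <- setNames(c(1000, 300, 200, 150, 80, 50), fam_ids)
  iso_seqs <- character(0); iso_info <- list()
  for (i in seq_len(6L)) {
    for (k in seq_len(config$isoform_counts[i])) {
      s_iso <- child_seed(seed, sprintf("iso_%d_%d", i, k))
      iso <- with_seed(s_iso, {
        fam <- families[[i]]
        keep <- if (k == 1L) nchar(fam)
                else floor(nchar(fam) * runif(1, 0.95, 1))
        paste(mutate_residues(seq_chars(substr(fam, 1L, keep)),
                              if (k == 1L) 0 else 0.003), collapse = "")
      })
      ab <- with_seed(s_iso + 1L,
                      base_abund[i] * if (k == 1L) 1 else runif(1, 0.3, 0.8))
      id <- sprintf("%s_iso%d", fam_ids[i], k)
      iso_seqs[id] <- iso
      iso_info[[id]] <- data.table(
        protein_id = id, family_id = fam_ids[i], class = classes[i],
        role = "silk", abundance = unname(ab))
    }
  }

  decoys <- generate_decoy_proteome(config$n_decoys,
                                    rng_seed = child_seed(seed, "decoys"))
  contams <- generate_decoy_proteome(config$contaminant_count,
                                     rng_seed = child_seed(seed, "contams"),
                                     prefix = "contam")
  dec_ab <- with_seed(child_seed(seed, "decoy_abund"),
                      setNames(rlnorm(length(decoys), log(5), 1),
                               names(decoys)))
  con_ab <- with_seed(child_seed(seed, "contam_abund"),
                      setNames(rlnorm(length(contams), log(30), 1),
                               names(contams)))

  proteins <- c(iso_seqs, decoys, contams)
  info <- rbindlist(c(iso_info, list(
    data.table(protein_id = names(decoys), family_id = NA_character_,
               class = NA_character_, role = "decoy",
               abundance = unname(dec_ab)),
    data.table(protein_id = names(contams), family_id = NA_character_,
               class = NA_character_, role = "contaminant",
               abundance = unname(con_ab)))))

  abundances <- setNames(info$abundance, info$protein_id)
  peptides <- simulate_peptide_evidence(
    proteins, abundances, n_replicates = config$n_replicates,
    detection_prob = config$detection_prob,
    intensity_cv = config$intensity_cv,
    rng_seed = child_seed(seed, "evidence"))

  txomes <- simulate_transcriptomes(
    families, config$ortholog_presence,
    species_ids = colnames(config$ortholog_presence),
    divergence = config$divergence,
    ortholog_repeat_aa = config$ortholog_repeat_aa,
    n_decoy_transcripts = config$n_decoy_transcripts,
    rng_seed = child_seed(seed, "txomes"))

  # truth: conservation is expected at the class level (paralogs sharing a
  # flank qualify against each other's orthologs by construction)
  class_of <- setNames(classes, fam_ids)
  truth_cons <- rbindlist(lapply(names(txomes), function(sp) {
    planted <- txomes[[sp]]$planted
    planted_class <- class_of[planted$family_id]
    tpm <- setNames(txomes[[sp]]$tpm$tpm, txomes[[sp]]$tpm$transcript_id)
    rbindlist(lapply(fam_ids, function(f) {
      qual <- planted$transcript_id[planted_class == class_of[f]]
      data.table(family_id = f, species_id = sp,
                 conserved = length(qual) > 0L,
                 expected_expression = if (length(qual)) max(tpm[qual])
                                       else NA_real_)
    }))
  }))

  structure(
    list(proteins = proteins, protein_info = info, peptides = peptides,
         known_db = c(decoys, contams), transcriptomes = txomes,
         families = families,
         truth = list(conservation = truth_cons,
                      most_abundant_family = fam_ids[which.max(base_abund)],
                      paralog_group = fam_ids[2:4],
                      n_families = 6L),
         config = config),
    class = "silk_study")
}

#' @export
print.silk_study <- function(x, ...) {
  cat(sprintf(paste0("<silk_study> %d proteins (%d silk isoforms in 6 ",
                     "families, %d decoys, %d contaminants), %d replicates, ",
                     "%d species\n"),
              length(x$proteins), sum(x$protein_info$role == "silk"),
              sum(x$protein_info$role == "decoy"),
              sum(x$protein_info$role == "contaminant"),
              x$config$n_replicates, x$config$n_species))
  invisible(x)
}

#' Run the full silk screen on a study
#'
#' Quantifies proteins (iBAQ + consistency), detects tandem repeats, applies
#' the novelty filter, evaluates the four-criterion screen, clusters
#' survivors into families, groups clusters by N-terminal homology, and
#' ranks survivors by abundance.
#'
#' @param study A `silk_study` (or a list with `proteins`, `peptides`,
#'   `known_db` of the same shape).
#' @param min_peptides,z_max,repeat_min Screen thresholds (defaults 2, 1,
#'   0.10).
#' @param evalue_max Novelty E-value cutoff (default 1e-15).
#' @param identity_min Family clustering identity threshold (default 0.90).
#' @param nterm_n,nterm_identity_min N-terminal grouping span and threshold.
#' @param repeat_args List of extra arguments for [detect_tandem_repeats()].
#' @return List of class `silk_screen_result`: `quants`, `repeat_fractions`,
#'   `novelty`, `verdicts`, `families`, `supergroups`, `ranked`,
#'   `parameters`.
#' @export
run_silk_screen <- function(study, min_peptides = 2L, z_max = 1.0,
                            repeat_min = 0.10, evalue_max = 1e-15,
                            identity_min = 0.90, nterm_n = 100L,
                            nterm_identity_min = 0.5, repeat_args = list()) {
  proteins <- study$proteins
  theo <- vapply(proteins, theoretical_peptide_count, 1L)
  quantified <- intersect(unique(study$peptides$protein_id),
                          names(theo)[theo >= 1L])
  quants <- normalize_and_consistency(
    compute_ibaq(study$peptides[protein_id %in% quantified],
                 theo[quantified]))
  rep_frac <- vapply(quants$protein_id, function(id) {
    do.call(detect_tandem_repeats,
            c(list(proteins[[id]], protein_id = id), repeat_args))$repeat_fraction
  }, 1.0)
  kdb <- search_db(study$known_db)
  nov <- vapply(quants$protein_id, function(id) {
    novelty_filter(proteins[[id]], kdb, evalue_max = evalue_max)
  }, logical(1))
  verdicts <- screen_candidates(quants, rep_frac, nov,
                                min_peptides = min_peptides, z_max = z_max,
                                repeat_min = repeat_min)
  survivors <- verdicts$protein_id[verdicts$passes]
  fams <- cluster_by_identity(proteins[survivors], identity_min = identity_min)
  groups <- if (nrow(fams)) {
    nterminal_homology_groups(fams, proteins, n_residues = nterm_n,
                              identity_min = nterm_identity_min)
  } else data.table()
  ranked <- rank_by_abundance(quants, verdicts)
  structure(
    list(quants = quants, repeat_fractions = rep_frac, novelty = nov,
         verdicts = verdicts, families = fams, supergroups = groups,
         ranked = ranked,
         parameters = list(min_peptides = min_peptides, z_max = z_max,
                           repeat_min = repeat_min, evalue_max = evalue_max,
                           identity_min = identity_min, nterm_n = nterm_n,
                           nterm_identity_min = nterm_identity_min)),
    class = "silk_screen_result")
}

#' @export
print.silk_screen_result <- function(x, ...) {
  v <- x$verdicts
  cat(sprintf(paste0("<silk_screen_result> %d quantified, %d pass all four ",
                     "criteria, %d families, %d super-groups\n"),
              nrow(v), sum(v$passes), nrow(x$families),
              if (length(x$supergroups)) nrow(x$supergroups) else 0L))
  cat("  failures:", sprintf("known_match %d,", sum(!v$novel)),
      sprintf("low_peptides %d,", sum(v$peptide_support <
                                        x$parameters$min_peptides)),
      sprintf("inconsistent %d,", sum(!v$consistent)),
      sprintf("low_repeat %d\n", sum(v$repeat_fraction <
                                       x$parameters$repeat_min)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the standard plain-text exchange formats: protein and known-database
#' FASTA, per-species transcript FASTA and TPM TSV, the peptide evidence TSV,
#' and a JSON ground-truth manifest.
#'
#' @param study A `silk_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_silk_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(study$proteins, file.path(dir, "proteins.faa"))
  write_fasta(study$known_db, file.path(dir, "known_db.faa"))
  fwrite(study$peptides, file.path(dir, "peptides.tsv"), sep = "\t")
  fwrite(study$protein_info, file.path(dir, "protein_info.tsv"), sep = "\t")
  for (sp in names(study$transcriptomes)) {
    tx <- study$transcriptomes[[sp]]
    write_fasta(tx$transcripts, file.path(dir, sprintf("%s.fna", sp)),
                type = "DNA")
    fwrite(tx$tpm, file.path(dir, sprintf("tpm_%s.tsv", sp)), sep = "\t")
  }
  manifest <- list(
    config = unclass(study$config)[setdiff(names(study$config),
                                           "ortholog_presence")],
    ortholog_presence = study$config$ortholog_presence,
    truth = list(
      conservation = study$truth$conservation,
      most_abundant_family = study$truth$most_abundant_family,
      paralog_group = study$truth$paralog_group,
      n_families = study$truth$n_families))
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting named character vectors.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta()`: named character vector.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}
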