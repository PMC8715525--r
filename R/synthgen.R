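# Synthetic-data generators: motif-grammar silk proteins, globular decoys,
# in-silico tryptic digestion, replicate peptide evidence, and per-species
# transcriptomes with planted orthologs.

#' Define a silk motif grammar
#'
#' A grammar is a weighted mixture of short amino-acid repeat units (cores)
#' and occasional linker units; a silk repeat region is built by sampling
#' units from the mixture and point-mutating each copy. The four default
#' grammars ([silk_grammars()]) emulate the motif classes seen in arthropod
#' silks: GA/GAGAGS silkworm-fibroin-type, serine-rich SXSX
#' caddisworm-fibroin-type, GPX collagen-type, and cysteine-rich
#' keratin-associated-protein-type.
#'
#' @param name Label for the grammar (used as the planted motif class).
#' @param core_units Character vector of repeat units (uppercase, 20-letter
#'   alphabet).
#' @param linker_units Optional character vector of linker units interspersed
#'   between core repeats.
#' @param unit_weights Sampling probabilities over
#'   `c(core_units, linker_units)`; must sum to 1. Defaults to uniform.
#' @param mutation_rate Per-residue substitution probability applied
#'   independently to every sampled unit copy, in `[0, 1]`.
#' @return An object of class `motif_grammar`.
#' @export
#' @examples
#' g <- motif_grammar("silkworm-like", "GAGAGS", mutation_rate = 0)
motif_grammar <- function(name, core_units, linker_units = character(),
                          unit_weights = NULL, mutation_rate = 0) {
  core_units <- as.character(core_units)
  linker_units <- as.character(linker_units)
  units <- c(core_units, linker_units)
  if (length(core_units) == 0L || any(!nzchar(units)))
    stop("grammar must have at least one nonempty core unit", call. = FALSE)
  bad <- setdiff(unique(unlist(strsplit(units, ""))), AA20)
  if (length(bad))
    stop("grammar units contain non-canonical residues: ",
         paste(bad, collapse = ","), call. = FALSE)
  if (is.null(unit_weights)) unit_weights <- rep(1 / length(units), length(units))
  if (length(unit_weights) != length(units))
    stop("`unit_weights` must cover core and linker units", call. = FALSE)
  if (abs(sum(unit_weights) - 1) > 1e-9)
    stop("`unit_weights` must sum to 1", call. = FALSE)
  check_prob(mutation_rate, "mutation_rate")
  structure(
    list(name = name, core_units = core_units, linker_units = linker_units,
         unit_weights = as.numeric(unit_weights),
         mutation_rate = mutation_rate),
    class = "motif_grammar")
}

#' @export
print.motif_grammar <- function(x, ...) {
  cat(sprintf("<motif_grammar> %s: %d core / %d linker units, mutation %.3f\n",
              x$name, length(x$core_units), length(x$linker_units),
              x$mutation_rate))
  invisible(x)
}

#' Default silk motif grammars
#'
#' Six grammars covering the four motif classes recurrent in structural
#' silk proteins: a glycine/alanine GAGAGS type with GPG-style and
#' `SGRVQQTYTSSF` linkers, three serine-rich SXSX variants sharing a class
#' but differing in their X residues, a GPX collagen-like type, and a
#' cysteine-rich KAP-like type. Linkers carry K/R so that tryptic digestion
#' of a repeat region yields observable peptides.
#'
#' @param mutation_rate Per-residue substitution rate applied to unit copies.
#' @return Named list of `motif_grammar` objects.
#' @export
silk_grammars <- function(mutation_rate = 0.02) {
  list(
    silkworm = motif_grammar(
      "silkworm-fibroin-like",
      core_units = c("GAGAGS", "GAGA", "GAGSGA"),
      linker_units = c("GPGGYG", "SGRVQQTYTSSF"),
      unit_weights = c(0.40, 0.25, 0.20, 0.10, 0.05),
      mutation_rate = mutation_rate),
    caddisworm_a = motif_grammar(
      "caddisworm-fibroin-like",
      core_units = c("SVSTSE", "SVSQSE", "SDSTSV"),
      linker_units = c("TDSKVESR"),
      unit_weights = c(0.35, 0.30, 0.22, 0.13),
      mutation_rate = mutation_rate),
    caddisworm_b = motif_grammar(
      "caddisworm-fibroin-like",
      core_units = c("SESTSD", "SQSTSY", "SESDSV"),
      linker_units = c("DSTKVQER"),
      unit_weights = c(0.35, 0.30, 0.22, 0.13),
      mutation_rate = mutation_rate),
    caddisworm_c = motif_grammar(
      "caddisworm-fibroin-like",
      core_units = c("SYSDST", "SVSESQ", "SDSQSE"),
      linker_units = c("ESTKVDQR"),
      unit_weights = c(0.35, 0.30, 0.22, 0.13),
      mutation_rate = mutation_rate),
    collagen = motif_grammar(
      "collagen-like",
      core_units = c("GPPGPA", "GPVGPQ", "GPAGPP"),
      linker_units = c("GPRGEK"),
      unit_weights = c(0.35, 0.28, 0.24, 0.13),
      mutation_rate = mutation_rate),
    kap = motif_grammar(
      "KAP-like",
      core_units = c("CCQPTC", "CCQSTC", "CCVPSC"),
      linker_units = c("CKTPCR"),
      unit_weights = c(0.35, 0.30, 0.22, 0.13),
      mutation_rate = mutation_rate)
  )
}

# Substitute each residue independently with probability `rate`, drawing the
# replacement uniformly from the other 19 canonical residues.
mutate_residues <- function(chars, rate) {
  if (rate <= 0 || length(chars) == 0L) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    repl <- vapply(chars[hit], function(a) sample(setdiff(AA20, a), 1L), "")
    chars[hit] <- repl
  }
  chars
}

#' Generate one silk-like protein from a motif grammar
#'
#' The sequence is `termini[1]` + `n_units` units sampled from the grammar
#' (each copy independently point-mutated at the grammar's mutation rate) +
#' `termini[2]`. Deterministic for a fixed `rng_seed`.
#'
#' @param grammar A [motif_grammar()].
#' @param n_units Number of repeat units to sample (>= 1).
#' @param termini Character vector of length 2: fixed non-repetitive N- and
#'   C-terminal flanks (either may be "").
#' @param rng_seed Integer seed.
#' @return A single character string (amino acids).
#' @export
#' @examples
#' g <- motif_grammar("toy", "GAGAGS", mutation_rate = 0)
#' generate_silk_protein(g, 3, termini = c("M", ""), rng_seed = 1)
generate_silk_protein <- function(grammar, n_units, termini = c("", ""),
                                  rng_seed = 1L) {
  if (!inherits(grammar, "motif_grammar"))
    stop("`grammar` must be a motif_grammar", call. = FALSE)
  stopifnot(length(n_units) == 1L, n_units >= 1, length(termini) == 2L)
  units <- c(grammar$core_units, grammar$linker_units)
  with_seed(rng_seed, {
    idx <- sample.int(length(units), n_units, replace = TRUE,
                      prob = grammar$unit_weights)
    copies <- vapply(idx, function(i) {
      paste(mutate_residues(seq_chars(units[i]), grammar$mutation_rate),
            collapse = "")
    }, "")
    paste0(termini[1], paste(copies, collapse = ""), termini[2])
  })
}

#' Generate a decoy proteome of globular-like random proteins
#'
#' Sequences are i.i.d. draws from a fixed residue composition with lengths
#' uniform in `length_range`; they serve as the negative class for
#' planted-recovery experiments and (optionally) as the known-protein
#' database for the novelty filter.
#'
#' @param n Number of sequences (>= 0).
#' @param length_range Integer pair, inclusive bounds for sequence length.
#' @param composition Numeric 20-vector of residue probabilities in the order
#'   of `AA20`, summing to 1. Default: uniform.
#' @param rng_seed Integer seed.
#' @param prefix Identifier prefix for names.
#' @return Named character vector of `n` amino-acid sequences.
#' @export
generate_decoy_proteome <- function(n, length_range = c(120L, 600L),
                                    composition = NULL, rng_seed = 1L,
                                    prefix = "decoy") {
  stopifnot(n >= 0, length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  if (is.null(composition)) composition <- rep(1 / 20, 20)
  if (length(composition) != 20L || any(composition < 0))
    stop("`composition` must be a non-negative 20-vector", call. = FALSE)
  if (sum(composition) <= 0)
    stop("degenerate composition: all weights zero", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("`composition` must sum to 1", call. = FALSE)
  if (n == 0L) return(setNames(character(0), character(0)))
  with_seed(rng_seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = composition), collapse = "")
    }, "")
    names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
    seqs
  })
}

#' Tryptic in-silico digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (the Keil
#' rule), and returns every peptide with at most `missed_cleavages` internal
#' uncleaved sites, ordered by start position then span.
#'
#' @param seq Amino-acid string.
#' @param missed_cleavages Maximum internal missed cleavage sites (>= 0).
#' @return Character vector of peptides (empty for an empty sequence).
#' @export
#' @examples
#' in_silico_digest("AAKBBRCC", 0)   # "AAK" "BBR" "CC"
#' in_silico_digest("AAKPBB", 0)     # no cleavage before P
in_silico_digest <- function(seq, missed_cleavages = 2L) {
  stopifnot(missed_cleavages >= 0)
  if (!nzchar(seq)) return(character(0))
  ch <- seq_chars(seq)
  L <- length(ch)
  sites <- which(ch %in% c("K", "R"))
  sites <- sites[sites < L & ch[sites + 1L] != "P"]
  bounds <- c(0L, sites, L)
  nfrag <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(i + missed_cleavages, nfrag)
    for (j in i:jmax) {
      out <- c(out, substr(seq, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  out
}

#' Count or list observable tryptic peptides
#'
#' Fully tryptic peptides (0 missed cleavages) within an observable length
#' band, the conventional denominator for iBAQ.
#'
#' @param seq Amino-acid string.
#' @param min_len,max_len Inclusive peptide length band (default 6-30).
#' @return `observable_peptides()`: character vector of distinct peptides;
#'   `theoretical_peptide_count()`: the number of distinct observable
#'   peptides (repeat regions duplicate peptides, which identification
#'   reports once).
#' @export
observable_peptides <- function(seq, min_len = 6L, max_len = 30L) {
  p <- in_silico_digest(seq, 0L)
  unique(p[nchar(p) >= min_len & nchar(p) <= max_len])
}

#' @rdname observable_peptides
#' @export
theoretical_peptide_count <- function(seq, min_len = 6L, max_len = 30L) {
  length(observable_peptides(seq, min_len, max_len))
}

#' Simulate replicate peptide-level feature areas
#'
#' Every observable peptide of every protein is detected in each replicate
#' with probability `detection_prob`; detected feature areas are log-normal
#' around the protein's planted abundance with coefficient of variation
#' `intensity_cv` (mean exactly the abundance, so the noiseless limit
#' `detection_prob = 1, intensity_cv = 0` reproduces the planted table).
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param abundances Named numeric vector of planted per-protein abundances
#'   (same names as `proteins`).
#' @param n_replicates Number of replicates (>= 2).
#' @param detection_prob Per-peptide, per-replicate detection probability.
#' @param intensity_cv Coefficient of variation of detected areas (>= 0).
#' @param rng_seed Integer seed.
#' @param min_len,max_len Observable peptide length band.
#' @return A `data.table` with columns `protein_id`, `peptide`,
#'   `replicate_id`, `feature_area`.
#' @export
simulate_peptide_evidence <- function(proteins, abundances, n_replicates = 5L,
                                      detection_prob = 0.9, intensity_cv = 0.3,
                                      rng_seed = 1L, min_len = 6L,
                                      max_len = 30L) {
  check_prob(detection_prob, "detection_prob")
  stopifnot(intensity_cv >= 0, n_replicates >= 2L,
            !is.null(names(proteins)), all(names(proteins) %in% names(abundances)))
  peps <- lapply(proteins, observable_peptides, min_len = min_len,
                 max_len = max_len)
  tab <- data.table(
    protein_id = rep(names(proteins), lengths(peps)),
    peptide = unlist(peps, use.names = FALSE))
  if (nrow(tab) == 0L || detection_prob == 0)
    return(data.table(protein_id = character(), peptide = character(),
                      replicate_id = character(), feature_area = numeric()))
  reps <- sprintf("r%d", seq_len(n_replicates))
  full <- tab[rep(seq_len(nrow(tab)), each = n_replicates)]
  full[, replicate_id := rep(reps, nrow(tab))]
  sdlog <- sqrt(log(1 + intensity_cv^2))
  with_seed(rng_seed, {
    keep <- runif(nrow(full)) < detection_prob
    full <- full[keep]
    base <- abundances[full$protein_id]
    noise <- if (sdlog > 0) rlnorm(nrow(full), -sdlog^2 / 2, sdlog) else 1
    full[, feature_area := as.numeric(base) * noise]
  })
  full[]
}

# Deterministic two-codon back-translation tables (standard genetic code).
# A single fixed codon per residue would make the reverse-complement frames
# of repetitive sequences perfectly periodic, which manufactures spurious
# translated-search homology between unrelated planted repeat classes (a
# GA-rich repeat's reverse frames become proline/alanine repeats, and so
# on). Two countermeasures, both deterministic:
#   * the synonymous codon for each residue is chosen by a positional hash,
#     so reverse frames are aperiodic mixtures rather than repeats;
#   * the second codon set avoids codons whose reverse complement encodes
#     cysteine (no ACA/GCA anywhere) and prefers codons whose reverse
#     complement is a stop (TCA, CTA), which breaks alignment chains in
#     reverse frames.
CODON1 <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
            E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
            M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
            Y = "TAT", V = "GTT")
CODON2 <- c(A = "GCG", R = "AGA", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
            E = "GAG", G = "GGA", H = "CAC", I = "ATC", L = "CTA", K = "AAG",
            M = "ATG", F = "TTC", P = "CCA", S = "TCA", T = "ACG", W = "TGG",
            Y = "TAC", V = "GTA")

#' Back-translate a protein with a deterministic codon table
#'
#' Chooses between two fixed synonymous codons per residue by a positional
#' hash: the forward round trip is exact and fully deterministic, while
#' reverse-complement frames of repetitive sequences stay aperiodic (see
#' source comments for why that matters to translated-search fixtures).
#'
#' @param seq Amino-acid string over the 20 canonical residues.
#' @return Nucleotide string of length `3 * nchar(seq)`.
#' @export
back_translate <- function(seq) {
  ch <- seq_chars(seq)
  pos <- seq_along(ch)
  h <- (pos * 1103515245 + 12345) %% 2147483648
  use2 <- (h %/% 65536) %% 2L == 1L
  codons <- ifelse(use2, CODON2[ch], CODON1[ch])
  if (anyNA(codons))
    stop("cannot back-translate non-canonical residues: ",
         paste(unique(ch[is.na(codons)]), collapse = ","), call. = FALSE)
  paste(codons, collapse = "")
}

#' Simulate per-species transcriptomes with planted silk orthologs
#'
#' For each species, planted orthologs of the silk families marked present in
#' `presence` are embedded among random decoy transcripts. An ortholog is the
#' N-terminal portion of the family protein (conserved flank plus
#' `ortholog_repeat_aa` residues of repeat, emulating repeat-collapsed
#' short-read assemblies), point-mutated at `divergence` and back-translated.
#' TPM is computed from simulated counts and sums to 1e6 per species.
#'
#' @param families Named character vector of family protein sequences.
#' @param presence Logical matrix, `length(families)` x `n_species`
#'   (rownames = family ids); `TRUE` plants an ortholog.
#' @param species_ids Character vector of species identifiers (defaults to
#'   `sp1..spN` from `ncol(presence)`).
#' @param divergence Per-site amino-acid substitution rate for orthologs, in
#'   `[0, 1)`; values >= 0.5 warn (conservation undetectable by design).
#' @param ortholog_repeat_aa Residues of repeat region retained in the
#'   planted transcript beyond the N-terminal flank span (default 60).
#' @param flank_aa N-terminal span treated as conserved flank (default 80).
#' @param n_decoy_transcripts Random decoy transcripts per species.
#' @param rng_seed Integer seed.
#' @return List with one element per species: `transcripts` (named character
#'   vector of nucleotide sequences), `tpm` (`data.table`: `transcript_id`,
#'   `tpm`, `id_rank`), `planted` (`data.table`: `transcript_id`,
#'   `family_id`).
#' @export
simulate_transcriptomes <- function(families, presence, species_ids = NULL,
                                    divergence = 0.05, ortholog_repeat_aa = 60L,
                                    flank_aa = 80L, n_decoy_transcripts = 40L,
                                    rng_seed = 1L) {
  stopifnot(is.matrix(presence), nrow(presence) == length(families))
  if (divergence >= 0.5)
    warning("divergence >= 0.5: planted conservation is undetectable by design")
  ns <- ncol(presence)
  if (is.null(species_ids)) species_ids <- sprintf("sp%d", seq_len(ns))
  if (is.null(rownames(presence))) rownames(presence) <- names(families)
  out <- vector("list", ns)
  names(out) <- species_ids
  for (j in seq_len(ns)) {
    sp <- species_ids[j]
    seed_sp <- child_seed(rng_seed, paste0("txome_", sp))
    out[[j]] <- with_seed(seed_sp, {
      dec_len <- sample(600:1500, n_decoy_transcripts, replace = TRUE)
      decoys <- vapply(dec_len, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, "")
      fam_here <- names(families)[presence[, j]]
      planted <- vapply(fam_here, function(f) {
        aa <- substr(families[[f]], 1L,
                     min(nchar(families[[f]]), flank_aa + ortholog_repeat_aa))
        aa <- paste(mutate_residues(seq_chars(aa), divergence), collapse = "")
        back_translate(aa)
      }, "")
      seqs <- c(decoys, planted)
      kind <- c(rep("decoy", length(decoys)), rep("planted", length(planted)))
      fam_of <- c(rep(NA_character_, length(decoys)), fam_here)
      ord <- sample.int(length(seqs))
      seqs <- seqs[ord]; kind <- kind[ord]; fam_of <- fam_of[ord]
      ids <- sprintf("%s_t%05d", sp, seq_along(seqs))
      names(seqs) <- ids
      counts <- ifelse(kind == "planted",
                       runif(length(seqs), 500, 5000),
                       rlnorm(length(seqs), log(20), 1))
      tpm <- compute_tpm(counts, nchar(seqs))
      list(transcripts = seqs,
           tpm = data.table(transcript_id = ids, tpm = tpm,
                            id_rank = seq_along(ids)),
           planted = data.table(transcript_id = ids[kind == "planted"],
                                family_id = fam_of[kind == "planted"]))
    })
  }
  out
}
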