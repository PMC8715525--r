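# Local-alignment similarity search with Karlin-Altschul E-values: the
# engine beneath the novelty filter (protein vs protein database) and the
# cross-species conservation screen (protein vs six-frame-translated
# transcripts). No low-complexity masking is applied anywhere: silk repeats
# are inherently low-complexity and masking would hide exactly the signal
# this screen is after.

.sw_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (including B/J/Z/X/`*` rows), as shipped
#' with Biostrings.
#'
#' @return Numeric matrix with residue row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.sw_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sw_env$blosum62 <- e$BLOSUM62
  }
  .sw_env$blosum62
}

# Encode residues as 1-based indices into the rows of `mat`; anything not in
# the matrix alphabet is mapped to X.
encode_seq <- function(seq, mat) {
  ch <- seq_chars(seq)
  idx <- match(ch, rownames(mat))
  idx[is.na(idx)] <- match("X", rownames(mat))
  idx
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full Smith-Waterman with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). The traceback is deterministic: the
#' highest-scoring cell wins, ties resolved by the smallest (row, column).
#' A best score of zero or less is the no-hit sentinel (score 0, empty
#' coordinates), as is any empty input sequence.
#'
#' @param query,subject Amino-acid strings.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11, 1).
#' @param traceback Compute coordinates and identity counts (default TRUE).
#' @return List of class `alignment_hit`: `score`, 0-based half-open
#'   `q_start`/`q_end`/`s_start`/`s_end`, `n_ident`, `align_len`.
#' @export
#' @examples
#' smith_waterman("GAGAGS", "GAGAGS")$score  # 30 under BLOSUM62
smith_waterman <- function(query, subject, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1, traceback = TRUE) {
  stopifnot(gap_open > 0, gap_extend > 0)
  hit <- sw_align_cpp(encode_seq(query, matrix), encode_seq(subject, matrix),
                      matrix, gap_open, gap_extend, traceback)
  structure(hit, class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("<alignment_hit> score %g, q[%d,%d) s[%d,%d), %d/%d identical\n",
              x$score, x$q_start, x$q_end, x$s_start, x$s_end,
              x$n_ident, x$align_len))
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in a search of a length-`m` query against
#' `n` database residues. Defaults are the conventional ungapped BLOSUM62
#' parameters.
#'
#' @param raw_score Alignment raw score.
#' @param m Query length (> 0).
#' @param n Database residue count (> 0).
#' @param K,lambda Karlin-Altschul parameters (> 0); defaults 0.134, 0.3176.
#' @return Non-negative E-value.
#' @export
evalue <- function(raw_score, m, n, K = 0.134, lambda = 0.3176) {
  if (any(m <= 0) || any(n <= 0))
    stop("query length and database size must be positive", call. = FALSE)
  stopifnot(K > 0, lambda > 0)
  K * m * n * exp(-lambda * raw_score)
}

#' Bit score from a raw score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue
#' @return Bit score.
#' @export
bit_score <- function(raw_score, K = 0.134, lambda = 0.3176) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Six-frame translation
#'
#' Translates frames +1..+3 of the sequence and +1..+3 of its reverse
#' complement (reported as -1..-3) under the standard genetic code. Stop
#' codons are emitted as `*`; codons containing N become `X`; trailing
#' partial codons are dropped.
#'
#' @param nt Nucleotide string over `A,C,G,T,N`.
#' @return Named character vector of 6 amino-acid strings
#'   (`"+1".."+3"`, `"-1".."-3"`).
#' @export
#' @examples
#' six_frame_translate("ATGGCT")[["+1"]]  # "MA"
six_frame_translate <- function(nt) {
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    L <- length(s) - off
    L <- L - (L %% 3L)
    if (L <= 0L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1L, off + L),
                                       if.fuzzy.codon = "X"))
  }
  out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# Vectorised six-frame translation of many transcripts at once (the scalar
# six_frame_translate has per-call overhead that dominates at database
# scale). Returns parallel vectors: translated frames, source transcript
# ids, and frame labels.
six_frame_set <- function(txs) {
  fwd <- Biostrings::DNAStringSet(txs)
  rev <- Biostrings::reverseComplement(fwd)
  frame_db <- character(0); frame_tx <- character(0); frame_id <- character(0)
  for (dir in c("+", "-")) {
    s <- if (dir == "+") fwd else rev
    for (off in 0:2) {
      w <- pmax(0L, (Biostrings::width(s) - off) %/% 3L * 3L)
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(s, start = off + 1L, width = w),
        if.fuzzy.codon = "X"))
      frame_db <- c(frame_db, unname(aa))
      frame_tx <- c(frame_tx, names(txs))
      frame_id <- c(frame_id, rep(sprintf("%s%d", dir, off + 1L), length(aa)))
    }
  }
  keep <- nchar(frame_db) > 0L
  list(db = frame_db[keep], tx = frame_tx[keep], frame = frame_id[keep])
}

# Split translated frames into stop-free segments (translated searches align
# within open reading frames; alignments never cross a stop codon). Keeps
# the transcript/frame bookkeeping of each segment.
split_at_stops <- function(fset) {
  segs <- strsplit(fset$db, "*", fixed = TRUE)
  n <- lengths(segs)
  out <- list(db = unlist(segs, use.names = FALSE),
              tx = rep(fset$tx, n), frame = rep(fset$frame, n))
  keep <- nchar(out$db) > 0L
  list(db = out$db[keep], tx = out$tx[keep], frame = out$frame[keep])
}

# Distinct k-mers of one sequence (character scalar).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# Build a k-mer -> subject-index map for a database of sequences.
kmer_index <- function(db, k) {
  km <- lapply(db, seq_kmers, k = k)
  data.table(kmer = unlist(km, use.names = FALSE),
             subject = rep(seq_along(db), lengths(km)))
}

# Subject indices sharing >= min_shared distinct k-mers with the query,
# ordered by shared-k-mer count (descending) so likely hits are aligned
# first.
prefilter_subjects <- function(query, index, k, min_shared = 1L) {
  qk <- seq_kmers(query, k)
  if (!length(qk)) return(integer(0))
  hits <- index[kmer %chin% qk, .N, by = subject]
  hits <- hits[N >= min_shared]
  setorder(hits, -N, subject)
  hits$subject
}

#' Precompile a protein database for repeated searches
#'
#' Precomputes residue encodings, the k-mer prefilter index, and the
#' database residue count, so that many queries (e.g. a whole proteome
#' through the novelty filter) can be searched without rebuilding them.
#'
#' @param db Named character vector of subject sequences.
#' @param prefilter_k k-mer length for the prefilter (0 disables).
#' @param matrix Substitution matrix used for encoding.
#' @return Object of class `search_db`, accepted by [protein_search()] and
#'   [novelty_filter()] in place of `db`.
#' @export
search_db <- function(db, prefilter_k = 5L, matrix = blosum62()) {
  stopifnot(length(db) > 0, !is.null(names(db)))
  structure(
    list(names = names(db), seqs = db,
         enc = lapply(db, encode_seq, mat = matrix),
         index = if (prefilter_k > 0L) kmer_index(db, prefilter_k) else NULL,
         k = prefilter_k, db_size = sum(nchar(db))),
    class = "search_db")
}

#' Search a protein query against a protein database
#'
#' Full Smith-Waterman against every candidate subject, with an exact k-mer
#' prefilter for speed (subjects sharing no k-mer with the query are skipped;
#' at the default `k = 5` this does not affect decisions at stringent
#' E-value cuts, and can be disabled with `prefilter_k = 0`).
#'
#' @param query Amino-acid string.
#' @param db Named character vector of subject sequences, or a prebuilt
#'   [search_db()] (preferred when searching many queries).
#' @param evalue_max Only hits with E-value below this are returned.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param K,lambda Karlin-Altschul parameters.
#' @param prefilter_k k-mer length for the prefilter (0 disables).
#' @param min_shared Minimum distinct shared k-mers for a subject to be
#'   aligned (default 1).
#' @param stop_at_first Stop after the first qualifying hit (used by the
#'   novelty filter, where any hit decides).
#' @param db_size Database residue count used for E-values; defaults to the
#'   total residues in `db` (pass explicitly when searching a pre-filtered
#'   slice of a larger database).
#' @return `data.table` of qualifying hits: `subject_id`, `raw_score`,
#'   `bit_score`, `evalue`, sorted by E-value then subject id.
#' @export
protein_search <- function(query, db, evalue_max = Inf, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1, K = 0.134,
                           lambda = 0.3176, prefilter_k = 5L,
                           min_shared = 1L, stop_at_first = FALSE,
                           db_size = NULL) {
  if (inherits(db, "search_db")) {
    dbo <- db
  } else {
    if (!length(db)) stop("empty database", call. = FALSE)
    dbo <- search_db(db, prefilter_k = prefilter_k, matrix = matrix)
  }
  if (is.null(db_size)) db_size <- dbo$db_size
  m <- nchar(query)
  empty <- data.table(subject_id = character(), raw_score = numeric(),
                      bit_score = numeric(), evalue = numeric())
  if (m == 0L) return(empty)
  cand <- if (!is.null(dbo$index)) {
    prefilter_subjects(query, dbo$index, dbo$k, min_shared)
  } else seq_along(dbo$seqs)
  if (!length(cand)) return(empty)
  qe <- encode_seq(query, matrix)
  out <- vector("list", length(cand))
  nhit <- 0L
  for (ci in cand) {
    sc <- sw_score_many_cpp(qe, dbo$enc[ci], matrix, gap_open, gap_extend)[1]
    if (sc <= 0) next
    ev <- evalue(sc, m, db_size, K = K, lambda = lambda)
    if (ev < evalue_max) {
      nhit <- nhit + 1L
      out[[nhit]] <- data.table(subject_id = dbo$names[ci], raw_score = sc,
                                bit_score = bit_score(sc, K, lambda),
                                evalue = ev)
      if (stop_at_first) break
    }
  }
  if (!nhit) return(empty)
  res <- rbindlist(out[seq_len(nhit)])
  setorder(res, evalue, subject_id)
  res[]
}

#' Novelty filter against a known-protein database
#'
#' `TRUE` (novel) iff no database subject aligns with an E-value below
#' `evalue_max`. No low-complexity masking is applied.
#'
#' @param query Amino-acid string.
#' @param known_db Nonempty named character vector of known proteins, or a
#'   prebuilt [search_db()].
#' @param evalue_max E-value cutoff (default 1e-15).
#' @param ... Passed to [protein_search()].
#' @return Logical: `TRUE` = novel.
#' @export
novelty_filter <- function(query, known_db, evalue_max = 1e-15, ...) {
  if (!inherits(known_db, "search_db") && !length(known_db))
    stop("novelty filter is meaningless against an empty database",
         call. = FALSE)
  hits <- protein_search(query, known_db, evalue_max = evalue_max,
                         stop_at_first = TRUE, ...)
  nrow(hits) == 0L
}

#' Cross-species conservation matrix by translated search
#'
#' For every (family, species) pair, the family representative protein is
#' searched against all six-frame translations of the species' transcripts
#' (TBlastN-style, complexity filtering off). Frames are split into
#' stop-free segments before alignment -- translated searches align within
#' open reading frames, never across a stop codon. A family is conserved in
#' a species iff its best hit has E-value below `evalue_max`; the reported
#' expression is the highest TPM among transcripts carrying a qualifying
#' hit. Best-hit ties are resolved by lower E-value, then higher bit score,
#' then lexicographic transcript id. A qualifying transcript missing from
#' the TPM table flags the cell rather than silently zeroing it.
#'
#' @param families Named character vector of family representative proteins.
#' @param assemblies Named list (per species) of named character vectors of
#'   nucleotide transcript sequences.
#' @param tpm_tables Named list (per species) of tables with `transcript_id`
#'   and `tpm` columns; every species in `assemblies` must appear.
#' @param evalue_max Conservation E-value cutoff (default 1e-15).
#' @param matrix,gap_open,gap_extend,K,lambda,prefilter_k,min_shared See
#'   [protein_search()]; the translated-search prefilter defaults to two
#'   shared 5-mers, far below what any alignment qualifying at stringent
#'   E-value cuts carries.
#' @return `data.table` with one row per family x species: `family_id`,
#'   `species_id`, `conserved`, `best_transcript`, `best_frame`,
#'   `best_evalue`, `best_bit_score`, `expression_tpm`, `tpm_missing`.
#' @export
conservation_matrix <- function(families, assemblies, tpm_tables,
                                evalue_max = 1e-15, matrix = blosum62(),
                                gap_open = 11, gap_extend = 1, K = 0.134,
                                lambda = 0.3176, prefilter_k = 5L,
                                min_shared = 2L) {
  stopifnot(length(families) > 0, length(assemblies) > 0)
  missing_tpm <- setdiff(names(assemblies), names(tpm_tables))
  if (length(missing_tpm))
    stop("species without TPM tables: ", paste(missing_tpm, collapse = ","),
         call. = FALSE)
  rows <- list()
  for (sp in names(assemblies)) {
    txs <- assemblies[[sp]]
    fset <- split_at_stops(six_frame_set(txs))
    frame_db <- fset$db; frame_tx <- fset$tx; frame_id <- fset$frame
    db_size <- sum(nchar(frame_db))
    enc <- lapply(frame_db, encode_seq, mat = matrix)
    idx <- if (prefilter_k > 0L) kmer_index(frame_db, prefilter_k) else NULL
    tpmtab <- as.data.table(tpm_tables[[sp]])
    for (f in names(families)) {
      q <- families[[f]]
      cand <- if (is.null(idx)) seq_along(frame_db)
              else prefilter_subjects(q, idx, prefilter_k, min_shared)
      best <- data.table(transcript = character(), frame = character(),
                         score = numeric(), ev = numeric(), bs = numeric())
      qual_tx <- character(0)
      if (length(cand)) {
        qe <- encode_seq(q, matrix)
        sc <- sw_score_many_cpp(qe, enc[cand], matrix, gap_open, gap_extend)
        ev <- evalue(sc, nchar(q), db_size, K = K, lambda = lambda)
        qual <- ev < evalue_max
        if (any(qual)) {
          best <- data.table(transcript = frame_tx[cand][qual],
                             frame = frame_id[cand][qual],
                             score = sc[qual], ev = ev[qual],
                             bs = bit_score(sc[qual], K, lambda))
          qual_tx <- unique(best$transcript)
        }
      }
      conserved <- nrow(best) > 0L
      if (conserved) {
        setorder(best, ev, -bs, transcript)
        expr <- tpmtab[transcript_id %in% qual_tx, tpm]
        missing <- sum(qual_tx %in% tpmtab$transcript_id) < length(qual_tx)
        rows[[length(rows) + 1L]] <- data.table(
          family_id = f, species_id = sp, conserved = TRUE,
          best_transcript = best$transcript[1], best_frame = best$frame[1],
          best_evalue = best$ev[1], best_bit_score = best$bs[1],
          expression_tpm = if (length(expr)) max(expr) else NA_real_,
          tpm_missing = missing)
      } else {
        rows[[length(rows) + 1L]] <- data.table(
          family_id = f, species_id = sp, conserved = FALSE,
          best_transcript = NA_character_, best_frame = NA_character_,
          best_evalue = NA_real_, best_bit_score = NA_real_,
          expression_tpm = NA_real_, tpm_missing = FALSE)
      }
    }
  }
  rbindlist(rows)
}
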