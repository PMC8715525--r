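# Peptide-to-protein quantification: iBAQ from feature areas, replicate
# consistency, TPM, and the assembly-level contamination filter.

#' Compute per-replicate iBAQ from peptide feature areas
#'
#' iBAQ for a protein in one replicate is the sum of that replicate's feature
#' areas for the protein divided by the protein's theoretical (observable,
#' fully tryptic) peptide count. Proteins with no features in a replicate get
#' 0 for that replicate; feature rows whose `protein_id` is missing from
#' `theoretical_peptides` are reported in a warning and skipped.
#'
#' @param features `data.table`/data.frame with columns `protein_id`,
#'   `peptide`, `replicate_id`, `feature_area` (areas >= 0).
#' @param theoretical_peptides Named integer vector of theoretical peptide
#'   counts per protein (all >= 1; see [theoretical_peptide_count()]).
#' @param replicate_ids Optional character vector fixing the replicate set
#'   and order; defaults to the sorted replicates present in `features`.
#' @return A `data.table` with one row per protein: `protein_id`,
#'   `peptide_count` (distinct peptides across replicates), and one `ibaq_*`
#'   column per replicate.
#' @export
compute_ibaq <- function(features, theoretical_peptides, replicate_ids = NULL) {
  features <- as.data.table(features)
  stopifnot(all(c("protein_id", "peptide", "replicate_id", "feature_area")
                %in% names(features)))
  if (any(features$feature_area < 0))
    stop("feature areas must be non-negative", call. = FALSE)
  if (any(theoretical_peptides < 1))
    stop("theoretical peptide counts must be >= 1", call. = FALSE)
  unknown <- setdiff(unique(features$protein_id), names(theoretical_peptides))
  if (length(unknown)) {
    warning(sprintf("%d protein id(s) missing a theoretical peptide count; %s",
                    length(unknown), "their feature rows were skipped"))
    features <- features[!protein_id %in% unknown]
  }
  if (is.null(replicate_ids))
    replicate_ids <- sort(unique(features$replicate_id))
  sums <- features[, .(total = sum(feature_area)),
                   by = .(protein_id, replicate_id)]
  wide <- dcast(sums, protein_id ~ factor(replicate_id, levels = replicate_ids),
                value.var = "total", fill = 0, drop = FALSE)
  setnames(wide, replicate_ids, paste0("ibaq_", replicate_ids))
  for (r in paste0("ibaq_", replicate_ids)) {
    wide[, (r) := get(r) / theoretical_peptides[protein_id]]
  }
  pc <- features[, .(peptide_count = uniqueN(peptide)), by = protein_id]
  out <- pc[wide, on = "protein_id"]
  setcolorder(out, c("protein_id", "peptide_count"))
  setorder(out, protein_id)
  out[]
}

#' Normalise iBAQ across replicates and compute the consistency statistic
#'
#' Each replicate's iBAQ column is divided by that replicate's total
#' (normalised intensity), making the statistic invariant to per-replicate
#' rescaling of raw areas. The consistency statistic is the coefficient of
#' variation of the normalised intensities across replicates
#' (`sd / mean`) -- the conventional reading of a "normalised standard
#' deviation". Proteins with zero mean get an `Inf` sentinel.
#'
#' @param quants Output of [compute_ibaq()] (>= 2 replicate columns).
#' @return `quants` with added columns `mean_norm_intensity` and
#'   `consistency_z`, and `norm_*` normalised-intensity columns.
#' @export
normalize_and_consistency <- function(quants) {
  quants <- as.data.table(quants)
  rep_cols <- grep("^ibaq_", names(quants), value = TRUE)
  if (length(rep_cols) < 2L)
    stop("consistency is undefined with fewer than 2 replicates", call. = FALSE)
  norm_cols <- sub("^ibaq_", "norm_", rep_cols)
  for (k in seq_along(rep_cols)) {
    tot <- sum(quants[[rep_cols[k]]])
    quants[, (norm_cols[k]) := if (tot > 0) get(rep_cols[k]) / tot else 0]
  }
  nm <- as.matrix(quants[, ..norm_cols])
  mu <- rowMeans(nm)
  sdev <- apply(nm, 1L, sd)
  quants[, mean_norm_intensity := mu]
  quants[, consistency_z := ifelse(mu > 0, sdev / mu, Inf)]
  quants[]
}

#' Assembly-level contamination filter
#'
#' Keeps transcript records with `tpm >= tpm_min` and `id_rank <=
#' max_id_rank` (assembler output order), preserving input order. The filter
#' is idempotent.
#'
#' @param transcripts `data.table`/data.frame with at least `tpm` and
#'   `id_rank` columns.
#' @param tpm_min Minimum TPM retained (default 1).
#' @param max_id_rank Maximum transcript ID rank retained (default 30000).
#' @return Filtered table, same columns, order preserved.
#' @export
filter_assembly <- function(transcripts, tpm_min = 1, max_id_rank = 30000L) {
  transcripts <- as.data.table(transcripts)
  stopifnot(all(c("tpm", "id_rank") %in% names(transcripts)))
  transcripts[tpm >= tpm_min & id_rank <= max_id_rank]
}

#' Transcripts-per-million from counts and lengths
#'
#' `tpm_i = (counts_i / lengths_i) / sum_j(counts_j / lengths_j) * 1e6`.
#'
#' @param counts Non-negative per-transcript counts.
#' @param lengths Positive per-transcript lengths.
#' @return Numeric vector summing to 1e6 (all zero, with a warning, when all
#'   counts are zero).
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0),
            all(counts >= 0))
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warning("all counts are zero; TPM undefined, returning zeros")
    return(rep(0, length(counts)))
  }
  rate / tot * 1e6
}
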