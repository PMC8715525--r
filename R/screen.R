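# The four-criterion silk screen and downstream family structure: verdicts,
# identity clustering, N-terminal homology super-groups, abundance ranking.

#' Apply the four-criterion silk screen
#'
#' A quantified protein passes iff it is (1) novel against the known-protein
#' database, (2) supported by at least `min_peptides` distinct peptides,
#' (3) consistently detected (`consistency_z < z_max`), and (4) at least
#' `repeat_min` repeat-covered. Every quantified protein receives a verdict
#' row -- nothing is silently dropped.
#'
#' @param quants Output of [normalize_and_consistency()].
#' @param repeat_fractions Named numeric vector of repeat-covered fractions
#'   (from [detect_tandem_repeats()]), covering every quantified protein.
#' @param novelty Named logical vector (`TRUE` = novel), covering every
#'   quantified protein.
#' @param min_peptides Minimum distinct peptide support (default 2).
#' @param z_max Consistency cutoff, exclusive (default 1).
#' @param repeat_min Repeat-fraction cutoff, inclusive (default 0.10).
#' @return `data.table` with one row per quantified protein: `protein_id`,
#'   `novel`, `peptide_support`, `consistent`, `repeat_fraction`, `passes`,
#'   `reasons` (comma-separated failed criteria, "" when passing).
#' @export
screen_candidates <- function(quants, repeat_fractions, novelty,
                              min_peptides = 2L, z_max = 1.0,
                              repeat_min = 0.10) {
  quants <- as.data.table(quants)
  ids <- quants$protein_id
  miss_rep <- setdiff(ids, names(repeat_fractions))
  if (length(miss_rep))
    stop("missing repeat profiles for: ",
         paste(head(miss_rep, 5), collapse = ","), call. = FALSE)
  miss_nov <- setdiff(ids, names(novelty))
  if (length(miss_nov))
    stop("missing novelty calls for: ",
         paste(head(miss_nov, 5), collapse = ","), call. = FALSE)
  v <- data.table(
    protein_id = ids,
    novel = unname(novelty[ids]),
    peptide_support = quants$peptide_count,
    consistent = quants$consistency_z < z_max,
    repeat_fraction = unname(repeat_fractions[ids]))
  v[, passes := novel & peptide_support >= min_peptides & consistent &
        repeat_fraction >= repeat_min]
  v[, reasons := apply(cbind(!novel,
                             peptide_support < min_peptides,
                             !consistent,
                             repeat_fraction < repeat_min), 1L, function(f) {
    paste(c("known_match", "low_peptide_support", "inconsistent",
            "low_repeat_content")[f], collapse = ",")
  })]
  v[]
}

# Union-find over n elements.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# Pairwise alignment identity: matches / alignment length. `mode = "global"`
# uses Needleman-Wunsch (end gaps count), `mode = "local"` Smith-Waterman.
pairwise_identity <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5,
    type = if (mode == "global") "global" else "local")
  alen <- nchar(as.character(Biostrings::pattern(aln)))
  if (alen == 0L) return(0)
  Biostrings::nmatch(aln) / alen
}

#' Cluster proteins into families by pairwise sequence identity
#'
#' Single-linkage components over pairwise alignment identity (matches
#' divided by alignment length) at `identity_min`. Cluster ids are assigned
#' by each cluster's smallest member id; the representative is the longest
#' member (ties: lexicographically smallest id).
#'
#' @param seqs Named character vector of protein sequences.
#' @param identity_min Identity threshold in (0, 1] (default 0.90).
#' @param mode `"global"` (default) or `"local"` alignment identity.
#' @return `data.table` with one row per cluster: `cluster_id`,
#'   `representative_id`, `n_members`, `member_ids` (list column).
#' @export
cluster_by_identity <- function(seqs, identity_min = 0.90,
                                mode = c("global", "local")) {
  mode <- match.arg(mode)
  stopifnot(identity_min > 0, identity_min <= 1, !is.null(names(seqs)))
  n <- length(seqs)
  if (n == 0L)
    return(data.table(cluster_id = character(), representative_id = character(),
                      n_members = integer(), member_ids = list()))
  ord <- order(names(seqs))
  seqs <- seqs[ord]
  parent <- uf_new(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (uf_find(parent, i) == uf_find(parent, j)) next
        if (pairwise_identity(seqs[[i]], seqs[[j]], mode) >= identity_min)
          parent <- uf_union(parent, i, j)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  groups <- split(names(seqs), names(seqs)[root])
  rows <- lapply(sort(names(groups)), function(g) {
    mem <- sort(groups[[g]])
    lens <- nchar(seqs[mem])
    rep_id <- mem[order(-lens, mem)][1]
    data.table(cluster_id = g, representative_id = rep_id,
               n_members = length(mem), member_ids = list(mem))
  })
  rbindlist(rows)
}

#' Group family clusters by conserved N-terminal homology
#'
#' Clusters whose representatives' first `n_residues` align at or above
#' `identity_min` are merged (single-linkage, hence transitive and
#' order-independent) into super-groups, capturing paralogous silk genes
#' that share a conserved N-terminal domain but divergent repeats.
#' Representatives shorter than `n_residues` are used at full length and
#' flagged.
#'
#' @param clusters Output of [cluster_by_identity()].
#' @param seqs Named character vector containing the representatives.
#' @param n_residues N-terminal span compared (default 100, >= 20).
#' @param identity_min Identity threshold for merging (default 0.5).
#' @param mode Alignment identity mode, as in [cluster_by_identity()].
#' @return `data.table` with one row per super-group: `group_id`,
#'   `cluster_ids` (list), `n_clusters`, `short_representatives` (list of
#'   flagged representative ids).
#' @export
nterminal_homology_groups <- function(clusters, seqs, n_residues = 100L,
                                      identity_min = 0.5,
                                      mode = c("global", "local")) {
  mode <- match.arg(mode)
  stopifnot(n_residues >= 20L)
  reps <- clusters$representative_id
  nterm <- substr(seqs[reps], 1L, n_residues)
  short <- reps[nchar(seqs[reps]) < n_residues]
  n <- length(reps)
  parent <- uf_new(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (uf_find(parent, i) == uf_find(parent, j)) next
        if (pairwise_identity(nterm[[i]], nterm[[j]], mode) >= identity_min)
          parent <- uf_union(parent, i, j)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  groups <- split(clusters$cluster_id, clusters$cluster_id[root])
  rows <- lapply(sort(names(groups)), function(g) {
    cl <- sort(groups[[g]])
    rp <- clusters$representative_id[match(cl, clusters$cluster_id)]
    data.table(group_id = g, cluster_ids = list(cl), n_clusters = length(cl),
               short_representatives = list(intersect(rp, short)))
  })
  rbindlist(rows)
}

#' Rank screen survivors by mean iBAQ abundance
#'
#' @param quants Output of [compute_ibaq()] (or downstream).
#' @param verdicts Output of [screen_candidates()].
#' @return `data.table` of survivors sorted by mean iBAQ descending (ties by
#'   protein id): `protein_id`, `mean_ibaq`, `rank`.
#' @export
rank_by_abundance <- function(quants, verdicts) {
  quants <- as.data.table(quants)
  rep_cols <- grep("^ibaq_", names(quants), value = TRUE)
  survivors <- verdicts$protein_id[verdicts$passes]
  q <- quants[protein_id %in% survivors]
  q[, mean_ibaq := rowMeans(as.matrix(.SD)), .SDcols = rep_cols]
  out <- q[, .(protein_id, mean_ibaq)]
  setorder(out, -mean_ibaq, protein_id)
  out[, rank := .I]
  out[]
}
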