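# Hydropathy characterisation: Kyte-Doolittle sliding-window profiles,
# GRAVY, and amino-acid composition.

#' Kyte-Doolittle hydropathy scale
#'
#' The standard per-residue hydropathy values (positive = hydrophobic,
#' range -4.5 to +4.5).
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
kd_scale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding unweighted mean of per-residue hydropathy over the N-terminal
#' `span_limit` residues. No partial windows are emitted at the ends, so the
#' profile has `span - window + 1` points centred at positions
#' `(window+1)/2 .. span-(window-1)/2` (1-based). Ambiguous residues
#' (`X`, `*`, anything off-scale) are excluded from window means with a
#' reduced denominator. A sequence shorter than the window yields a single
#' full-sequence mean, flagged via the `short` field.
#'
#' @param seq Amino-acid string.
#' @param window Odd window width >= 1 (default 9).
#' @param span_limit Residues analysed from the N-terminus (default 1000).
#' @param protein_id Optional identifier.
#' @return Object of class `hydropathy_profile`: list with `protein_id`,
#'   `window`, `span` (residues analysed), `positions`, `scores`, `gravy`,
#'   `short`.
#' @export
#' @examples
#' kyte_doolittle_profile(strrep("I", 20), window = 9)$scores[1]  # 4.5
kyte_doolittle_profile <- function(seq, window = 9L, span_limit = 1000L,
                                   protein_id = NA_character_) {
  stopifnot(window >= 1L, window %% 2L == 1L, span_limit >= 1L)
  window <- as.integer(window)
  scale <- kd_scale()
  ch <- seq_chars(seq)
  ch <- ch[seq_len(min(length(ch), span_limit))]
  span <- length(ch)
  vals <- unname(scale[ch])
  valid <- !is.na(vals)
  vals[!valid] <- 0
  if (span < window) {
    g <- if (any(valid)) sum(vals) / sum(valid) else NA_real_
    return(structure(
      list(protein_id = protein_id, window = window, span = span,
           positions = if (span > 0L) (span + 1L) %/% 2L else integer(0),
           scores = g, gravy = g, short = TRUE),
      class = "hydropathy_profile"))
  }
  csum <- c(0, cumsum(vals))
  cnum <- c(0, cumsum(as.numeric(valid)))
  starts <- seq_len(span - window + 1L)
  wsum <- csum[starts + window] - csum[starts]
  wnum <- cnum[starts + window] - cnum[starts]
  scores <- ifelse(wnum > 0, wsum / wnum, NA_real_)
  structure(
    list(protein_id = protein_id, window = window, span = span,
         positions = starts + (window - 1L) %/% 2L,
         scores = scores,
         gravy = if (sum(valid) > 0) sum(vals) / sum(valid) else NA_real_,
         short = FALSE),
    class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %s: window %d over %d aa, GRAVY %.3f%s\n",
              ifelse(is.na(x$protein_id), "(unnamed)", x$protein_id),
              x$window, x$span, x$gravy,
              if (x$short) " (shorter than window)" else ""))
  invisible(x)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle value over the analysed span; ambiguous residues are
#' excluded. Negative values indicate hydrophilicity.
#'
#' @param seq Nonempty amino-acid string.
#' @param span_limit Residues analysed from the N-terminus (default: all).
#' @return GRAVY value, or `NA` for an all-ambiguous sequence.
#' @export
gravy <- function(seq, span_limit = Inf) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  scale <- kd_scale()
  ch <- seq_chars(seq)
  ch <- ch[seq_len(min(length(ch), span_limit))]
  vals <- scale[ch]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Amino-acid composition
#'
#' Fractions over the 20 canonical residues (summing to 1); ambiguous
#' residues are counted separately.
#'
#' @param seq Nonempty amino-acid string.
#' @return List with `fractions` (named 20-vector summing to 1 over
#'   canonical residues) and `n_ambiguous`.
#' @export
#' @examples
#' aa_composition("GAGAGS")$fractions[c("G", "A", "S")]  # 0.5 0.333 0.167
aa_composition <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- seq_chars(seq)
  canon <- ch[ch %in% AA20]
  counts <- table(factor(canon, levels = AA20))
  n <- length(canon)
  list(fractions = setNames(if (n > 0) as.numeric(counts) / n
                            else rep(0, 20), AA20),
       n_ambiguous = length(ch) - n)
}
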