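# Imperfect tandem-repeat detection in protein sequences: seed-and-extend on
# the period-p self-match profile, greedy overlap resolution, consensus
# extraction and fibroin-style motif classification.

# Maximal runs of TRUE in a logical vector; returns data.frame(start, end)
# (1-based inclusive) or zero rows.
true_runs <- function(x) {
  if (!length(x)) return(data.frame(start = integer(), end = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Candidate regions for one period p. Seeds are maximal runs of consecutive
# self-matches (s[i] == s[i + p], run length >= min(p, 3)); each seed is
# extended outwards one unit copy at a time, accepting a copy only while its
# per-column divergence from the seed's consensus stays within
# `max_divergence` (plus a final partial copy of exactly matching columns).
# This anchors extension to the repeat unit, so non-repetitive flanking
# sequence is not absorbed on the back of a long region's mismatch budget.
period_candidates <- function(ch, p, max_divergence, min_copies) {
  L <- length(ch)
  if (L < 2L * p) return(NULL)
  m <- ch[seq_len(L - p)] == ch[seq.int(p + 1L, L)]
  if (max_divergence <= 0) {
    runs <- true_runs(m)
    if (!nrow(runs)) return(NULL)
    out <- data.frame(rstart = runs$start, rend = runs$end + p)
  } else {
    seed_len <- min(p, 3L)
    seeds <- true_runs(m)
    seeds <- seeds[seeds$end - seeds$start + 1L >= seed_len, , drop = FALSE]
    if (!nrow(seeds)) return(NULL)
    max_mm <- floor(max_divergence * p)
    ivs <- list()
    last_end <- 0L
    for (k in seq_len(nrow(seeds))) {
      if (seeds$start[k] <= last_end) next  # absorbed by a previous region
      a0 <- seeds$start[k]
      a <- a0; b <- seeds$end[k] + p  # region in sequence space [a, b]
      col_of <- function(pos) ((pos - a0) %% p) + 1L
      # consensus over the seed's aligned columns
      idx <- a:b
      cons <- vapply(seq_len(p), function(cc) {
        xs <- ch[idx[col_of(idx) == cc]]
        tb <- table(xs)
        top <- names(tb)[tb == max(tb)]
        if (length(top) > 1L) top <- xs[xs %in% top][1L]
        top
      }, "")
      # block-wise right extension, then a partial exactly-matching copy
      while (b + p <= L) {
        blk <- seq.int(b + 1L, b + p)
        if (sum(ch[blk] != cons[col_of(blk)]) > max_mm) break
        b <- b + p
      }
      while (b < L && ch[b + 1L] == cons[col_of(b + 1L)]) b <- b + 1L
      # and leftwards
      while (a - p >= 1L) {
        blk <- seq.int(a - p, a - 1L)
        if (sum(ch[blk] != cons[col_of(blk)]) > max_mm) break
        a <- a - p
      }
      while (a > 1L && ch[a - 1L] == cons[col_of(a - 1L)]) a <- a - 1L
      # trim residual boundary mismatches
      while (a < b && ch[a] != cons[col_of(a)]) a <- a + 1L
      while (b > a && ch[b] != cons[col_of(b)]) b <- b - 1L
      last_end <- max(last_end, b)
      ivs[[length(ivs) + 1L]] <- c(a, b)
    }
    if (!length(ivs)) return(NULL)
    ivs <- do.call(rbind, ivs)
    out <- data.frame(rstart = ivs[, 1], rend = ivs[, 2])
    out <- out[order(out$rstart), , drop = FALSE]
    # merge overlapping intervals of the same period
    if (nrow(out) > 1L) {
      keep <- list(out[1, ])
      for (k in 2:nrow(out)) {
        last <- keep[[length(keep)]]
        if (out$rstart[k] <= last$rend + 1L) {
          keep[[length(keep)]]$rend <- max(last$rend, out$rend[k])
        } else keep[[length(keep) + 1L]] <- out[k, ]
      }
      out <- do.call(rbind, keep)
    }
  }
  out$period <- p
  out$copies <- (out$rend - out$rstart + 1L) / p
  out[out$copies >= min_copies, , drop = FALSE]
}

# Column-majority consensus of a region (1-based inclusive coords, phase from
# rstart); ties resolved by the earliest copy's residue.
region_consensus <- function(ch, rstart, rend, p) {
  x <- ch[rstart:rend]
  col <- ((seq_along(x) - 1L) %% p) + 1L
  cons <- vapply(seq_len(p), function(cc) {
    xs <- x[col == cc]
    tb <- table(xs)
    top <- names(tb)[tb == max(tb)]
    if (length(top) > 1L) top <- xs[xs %in% top][1L]  # earliest copy wins
    top
  }, "")
  identity <- mean(x == cons[col])
  list(consensus = paste(cons, collapse = ""), identity = identity)
}

#' Detect imperfect tandem repeats in a protein sequence
#'
#' For every candidate period, exact self-match seeds at distance `p` are
#' extended while the mismatch fraction stays within `max_divergence`.
#' Overlapping calls across periods are resolved greedily: regions are taken
#' in order of residues covered (ties: smaller period, then smaller start),
#' and later regions are trimmed to the residues not yet covered, so the
#' reported disjoint regions tile exactly the union of all accepted calls.
#'
#' @param seq Amino-acid string.
#' @param min_period,max_period Period range searched (defaults 1-60).
#' @param min_copies Minimum (possibly fractional) unit copies per region
#'   (default 2).
#' @param max_divergence Maximum tolerated mismatch fraction in `[0, 0.5)`
#'   (default 0.3).
#' @param protein_id Optional identifier stored in the profile.
#' @return An object of class `repeat_profile`: list with `protein_id`,
#'   `length`, `regions` (a `data.frame` with 0-based half-open `start`,
#'   `end`, plus `period`, `copies`, `identity`, `consensus`), and
#'   `repeat_fraction`.
#' @export
#' @examples
#' detect_tandem_repeats(strrep("GA", 10))$repeat_fraction  # 1
detect_tandem_repeats <- function(seq, min_period = 1L, max_period = 60L,
                                  min_copies = 2, max_divergence = 0.3,
                                  protein_id = NA_character_) {
  stopifnot(min_period >= 1L, max_period >= min_period,
            max_divergence >= 0, max_divergence < 0.5, min_copies >= 1)
  ch <- seq_chars(seq)
  L <- length(ch)
  empty <- structure(
    list(protein_id = protein_id, length = L,
         regions = data.frame(start = integer(), end = integer(),
                              period = integer(), copies = numeric(),
                              identity = numeric(), consensus = character()),
         repeat_fraction = 0),
    class = "repeat_profile")
  if (L < 2L * min_period) return(empty)
  cands <- list()
  for (p in seq.int(min_period, min(max_period, L %/% 2L))) {
    cp <- period_candidates(ch, p, max_divergence, min_copies)
    if (!is.null(cp) && nrow(cp)) cands[[length(cands) + 1L]] <- cp
  }
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  cands$len <- cands$rend - cands$rstart + 1L
  cands <- cands[order(-cands$len, cands$period, cands$rstart), , drop = FALSE]
  covered <- logical(L)
  regions <- list()
  for (k in seq_len(nrow(cands))) {
    a <- cands$rstart[k]; b <- cands$rend[k]; p <- cands$period[k]
    free <- !covered[a:b]
    if (!any(free)) next
    # accept the free sub-intervals; fragments inherit the period (they are
    # continuations of the same repeat) with phase-adjusted consensus
    fr <- true_runs(free)
    for (q in seq_len(nrow(fr))) {
      fa <- a + fr$start[q] - 1L
      fb <- a + fr$end[q] - 1L
      cons <- region_consensus(ch, fa, fb, min(p, fb - fa + 1L))
      regions[[length(regions) + 1L]] <- data.frame(
        start = fa - 1L, end = fb, period = p,
        copies = (fb - fa + 1L) / p, identity = cons$identity,
        consensus = cons$consensus, stringsAsFactors = FALSE)
    }
    covered[a:b] <- TRUE
  }
  regions <- do.call(rbind, regions)
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(
    list(protein_id = protein_id, length = L, regions = regions,
         repeat_fraction = sum(covered) / L),
    class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat(sprintf("<repeat_profile> %s: length %d, %d region(s), fraction %.3f\n",
              ifelse(is.na(x$protein_id), "(unnamed)", x$protein_id),
              x$length, nrow(x$regions), x$repeat_fraction))
  invisible(x)
}

#' Repeat-content criterion
#'
#' `TRUE` iff the repeat-covered fraction is at least `threshold`
#' (inclusive, reading "at least 10 percent" at the default).
#'
#' @param profile A `repeat_profile` or a numeric repeat fraction.
#' @param threshold Fraction threshold in `[0, 1]` (default 0.10).
#' @return Logical.
#' @export
repeat_fraction_criterion <- function(profile, threshold = 0.10) {
  check_prob(threshold, "threshold")
  frac <- if (inherits(profile, "repeat_profile")) profile$repeat_fraction
          else as.numeric(profile)
  frac >= threshold
}

#' Consensus motif of a repeat region
#'
#' Column-wise majority residue over the aligned unit copies; ties are broken
#' by the earliest copy's residue.
#'
#' @param region One row of a `repeat_profile`'s `regions` table (or a list
#'   with 0-based half-open `start`, `end` and `period`).
#' @param seq The protein sequence the region was called on.
#' @return Consensus string of length `period`.
#' @export
consensus_motif <- function(region, seq) {
  ch <- seq_chars(seq)
  region_consensus(ch, region$start + 1L, region$end,
                   as.integer(region$period))$consensus
}

#' Classify a repeat consensus against fibroin-like motif classes
#'
#' Rule-based: glycine+alanine-dominated units with GA alternation are
#' silkworm-fibroin-like; serine-rich units with SX alternation are
#' caddisworm-fibroin-like; period-3 units with glycine at every first
#' position and a proline are collagen-like; cysteine-rich units are
#' KAP-like; anything else is "other".
#'
#' @param consensus Nonempty consensus unit string.
#' @param ga_min G+A fraction for the silkworm rule (default 0.6).
#' @param s_min Serine fraction for the caddisworm rule (default 0.3).
#' @param c_min Cysteine fraction for the KAP rule (default 0.2).
#' @return One of `"silkworm-fibroin-like"`, `"caddisworm-fibroin-like"`,
#'   `"collagen-like"`, `"KAP-like"`, `"other"`.
#' @export
#' @examples
#' classify_motif("GAGAGS")  # silkworm-fibroin-like
#' classify_motif("GPP")     # collagen-like
classify_motif <- function(consensus, ga_min = 0.6, s_min = 0.3, c_min = 0.2) {
  if (!nzchar(consensus)) stop("empty consensus", call. = FALSE)
  ch <- seq_chars(consensus)
  n <- length(ch)
  frac <- function(aa) mean(ch %in% aa)
  phase_all <- function(aa, step) {
    any(vapply(seq_len(min(step, n)), function(ph) {
      idx <- seq.int(ph, n, by = step)
      length(idx) > 0L && all(ch[idx] %in% aa)
    }, logical(1)))
  }
  if (frac(c("G", "A")) >= ga_min && grepl("GA|AG", consensus))
    return("silkworm-fibroin-like")
  s_alt <- any(vapply(1:min(2L, n), function(ph) {
    idx <- seq.int(ph, n, by = 2L)
    mean(ch[idx] == "S") >= 0.8
  }, logical(1)))
  if (frac("S") >= s_min && s_alt)
    return("caddisworm-fibroin-like")
  if (n >= 3L && phase_all("G", 3L) && frac("P") > 0)
    return("collagen-like")
  if (frac("C") >= c_min)
    return("KAP-like")
  "other"
}
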