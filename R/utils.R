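# Shared internals: alphabet, seeded evaluation, small validators.

# Canonical 20-letter amino-acid alphabet, in the conventional matrix order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a parent seed and a key
#'
#' One study-level seed fans out into per-component seeds through a fixed
#' congruential mix, so individual stages can be re-run in isolation and
#' still reproduce the full study byte for byte.
#'
#' @param seed Parent integer seed.
#' @param key Character label or integer distinguishing the component.
#' @return An integer in `[0, 2^31 - 20)`.
#' @export
#' @examples
#' child_seed(1, "proteome") == child_seed(1, "proteome")
child_seed <- function(seed, key) {
  if (is.character(key)) {
    v <- utf8ToInt(key)
    key <- sum(v * seq_along(v)) %% 2147483647
  }
  x <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + as.numeric(key) * 16807 + 11
  as.integer(x %% 2147483629)
}

# Validate that a probability-like scalar is in [0, 1].
check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1]", what), call. = FALSE)
  invisible(x)
}

# Split a sequence (character scalar) into a character vector of residues.
seq_chars <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("expected a single character string", call. = FALSE)
  strsplit(seq, "", fixed = TRUE)[[1]]
}
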