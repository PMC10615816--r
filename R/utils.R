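# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are deterministic
#' under their `seed` argument without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Stable small-integer hash of a string, used to derive per-study RNG
# sub-streams from one global seed. Kept below 2^31 - 1.
.str_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Derive a child seed from (seed, tag); tag may be string or integer.
.child_seed <- function(seed, tag) {
  t <- if (is.character(tag)) .str_hash(tag) else as.integer(tag) %% 2147483647L
  as.integer((as.numeric(seed) * 2654435761 + t) %% 2147483647)
}

# log(sum(exp(x))) along rows of a matrix, numerically stable.
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Chromosome number from a name like "chr08" / "chr8" / "LG08"; NA if none.
.chrom_number <- function(chrom) {
  n <- suppressWarnings(as.integer(sub("^[^0-9]*", "", chrom)))
  n
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
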