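# PAF (pairwise mapping format) parsing and deterministic best-hit choice.
#
# Only the 12 mandatory columns plus the tp:A (primary/secondary) tag are
# interpreted; all coordinates are 0-based half-open as in the format itself.

#' Parse PAF alignment records
#'
#' @param x path to a PAF file, or a character vector of PAF lines.
#' @return data.frame with one row per well-formed alignment: `query_name`,
#'   `query_len`, `query_start`, `query_end`, `strand`, `target_name`,
#'   `target_len`, `target_start`, `target_end`, `n_matches`, `aln_len`,
#'   `mapq`, `is_primary`. Malformed lines are reported in the `bad_lines`
#'   attribute (line number + reason) rather than silently skipped.
#' @export
parse_paf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 12L
  bad <- data.frame(line = which(!ok),
                    reason = rep("fewer than 12 columns", sum(!ok)),
                    stringsAsFactors = FALSE)
  parts <- parts[ok]
  col <- function(i) vapply(parts, `[[`, "", i)
  numcol <- function(i) suppressWarnings(as.numeric(col(i)))
  rec <- data.frame(
    query_name = col(1L), query_len = numcol(2L),
    query_start = numcol(3L), query_end = numcol(4L),
    strand = col(5L),
    target_name = col(6L), target_len = numcol(7L),
    target_start = numcol(8L), target_end = numcol(9L),
    n_matches = numcol(10L), aln_len = numcol(11L),
    mapq = numcol(12L),
    stringsAsFactors = FALSE
  )
  # tp:A tag; absent => primary by convention
  tags <- vapply(parts, function(p) {
    tp <- grep("^tp:A:", p[-seq_len(12L)], value = TRUE)
    if (length(tp)) substring(tp[1L], 6L, 6L) else "P"
  }, "")
  rec$is_primary <- tags == "P"

  line_no <- which(ok)
  invalid <- is.na(rec$query_len) | is.na(rec$query_start) | is.na(rec$query_end) |
    is.na(rec$target_len) | is.na(rec$target_start) | is.na(rec$target_end) |
    is.na(rec$n_matches) | is.na(rec$aln_len) | is.na(rec$mapq) |
    !(rec$strand %in% c("+", "-")) |
    rec$query_start < 0 | rec$query_start >= rec$query_end |
    rec$query_end > rec$query_len |
    rec$target_start < 0 | rec$target_start >= rec$target_end |
    rec$target_end > rec$target_len |
    rec$n_matches > rec$aln_len
  if (any(invalid)) {
    bad <- rbind(bad, data.frame(line = line_no[invalid],
                                 reason = "invalid coordinates or fields",
                                 stringsAsFactors = FALSE))
    rec <- rec[!invalid, , drop = FALSE]
  }
  bad <- bad[order(bad$line), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, bad_lines = bad, n_input_lines = n)
}

#' Deterministic best alignment among hits of one query
#'
#' Policy (fixed so that projection is reproducible): primary alignments are
#' preferred over secondary; among those, highest `mapq`; ties broken by
#' longest `aln_len`, then by lowest (`target_name`, `target_start`).
#'
#' @param hits data.frame of PAF records sharing one `query_name`.
#' @return a one-row data.frame, or `NULL` when `hits` is empty.
#' @export
select_best_hit <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  if (length(unique(hits$query_name)) > 1L) {
    stop("select_best_hit: hits span multiple query names")
  }
  ord <- order(!hits$is_primary,          # primaries first
               -hits$mapq,
               -hits$aln_len,
               hits$target_name,
               hits$target_start,
               method = "radix")
  hits[ord[1L], , drop = FALSE]
}

#' Write PAF lines
#' @param paf data.frame in the layout of [parse_paf()].
#' @param path output path.
#' @export
write_paf <- function(paf, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:%s",
                   paf$query_name, as.integer(paf$query_len),
                   as.integer(paf$query_start), as.integer(paf$query_end),
                   paf$strand, paf$target_name, as.integer(paf$target_len),
                   as.integer(paf$target_start), as.integer(paf$target_end),
                   as.integer(paf$n_matches), as.integer(paf$aln_len),
                   as.integer(paf$mapq), ifelse(paf$is_primary, "P", "S"))
  writeLines(lines, path)
  invisible(path)
}
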