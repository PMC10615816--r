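# Lifting QTL intervals to physical coordinates from flank alignments.
#
# Each QTL contributes two 1-kb flanking sequences named "<qtl_id>__L" and
# "<qtl_id>__R" (the sequences immediately outside the genetic mapping
# interval on the source assembly). After alignment to the target assembly,
# the projected interval is bounded by the flank edges that face the QTL:
# for a forward-strand placement the end of the left flank and the start of
# the right flank. Every QTL ends in exactly one status:
#
#   projected               both flanks placed concordantly
#   failed_flank_missing    no usable hit for one or both flanks
#   failed_cross_chrom      flanks placed on different chromosomes
#   failed_orientation      discordant strands, or an empty interval
#   excluded_quarter_filter projected but wider than 1/4 of its chromosome

PROJECTION_STATUSES <- c("projected", "failed_flank_missing",
                         "failed_cross_chrom", "failed_orientation",
                         "excluded_quarter_filter")

#' Project one QTL from its two flank alignment sets
#'
#' @param qtl_id the QTL identifier.
#' @param left_hits,right_hits PAF records (rows of [parse_paf()] output) for
#'   the "__L" and "__R" flank queries; may be empty.
#' @param chroms `chrom_table` of the target assembly.
#' @return one-row data.frame: qtl_id, chrom, start_bp, end_bp, status.
#' @export
project_interval <- function(qtl_id, left_hits, right_hits, chroms) {
  fail <- function(status) data.frame(
    qtl_id = qtl_id, chrom = NA_character_,
    start_bp = NA_real_, end_bp = NA_real_,
    status = status, stringsAsFactors = FALSE)
  L <- select_best_hit(left_hits)
  R <- select_best_hit(right_hits)
  if (is.null(L) || is.null(R)) return(fail("failed_flank_missing"))
  if (L$target_name != R$target_name) return(fail("failed_cross_chrom"))
  chrom <- L$target_name
  if (!chrom %in% names(chroms)) {
    stop("projected chromosome absent from chromosome table: ", chrom)
  }
  if (L$strand != R$strand) return(fail("failed_orientation"))
  # Inner edges after strand normalization: on "+" the QTL lies between the
  # left flank's end and the right flank's start; on "-" the whole layout is
  # mirrored, so the roles of the two flanks swap.
  if (L$strand == "+") {
    inner_left <- L$target_end
    inner_right <- R$target_start
  } else {
    inner_left <- R$target_end
    inner_right <- L$target_start
  }
  start <- min(inner_left, inner_right)
  end <- max(inner_left, inner_right)
  start <- max(0, start)
  end <- min(as.numeric(chroms[[chrom]]), end)
  if (!(start < end)) return(fail("failed_orientation"))
  data.frame(qtl_id = qtl_id, chrom = chrom,
             start_bp = start, end_bp = end,
             status = "projected", stringsAsFactors = FALSE)
}

#' Project every QTL in a table from a PAF alignment set
#'
#' Splits alignments by the `"<qtl_id>__L"` / `"<qtl_id>__R"` query-name
#' convention, picks the best hit per flank ([select_best_hit()]) and projects
#' each QTL ([project_interval()]). Projection is total: the output has one
#' row per input QTL and the statuses partition the input.
#'
#' @param qtls `qtl_table` (accepted records).
#' @param paf parsed alignments ([parse_paf()]).
#' @param chroms `chrom_table` of the target assembly.
#' @return data.frame with columns qtl_id, chrom, start_bp, end_bp, status,
#'   renamed_id (empty until [rename_qtls()]), plus the QTL's trait_code,
#'   trait_group, study_ref, lod, pve_percent carried through for reporting.
#' @export
project_qtls <- function(qtls, paf, chroms) {
  is_L <- endsWith(paf$query_name, "__L")
  is_R <- endsWith(paf$query_name, "__R")
  base <- sub("__[LR]$", "", paf$query_name)
  left_ix <- split(which(is_L), base[is_L])
  right_ix <- split(which(is_R), base[is_R])
  rows <- lapply(seq_len(nrow(qtls)), function(i) {
    id <- qtls$qtl_id[i]
    project_interval(id,
                     paf[left_ix[[id]] %||% integer(), , drop = FALSE],
                     paf[right_ix[[id]] %||% integer(), , drop = FALSE],
                     chroms)
  })
  out <- do.call(rbind, rows)
  out$renamed_id <- ""
  carry <- c("trait_code", "trait_group", "study_ref", "lod", "pve_percent")
  out[carry] <- qtls[match(out$qtl_id, qtls$qtl_id), carry]
  rownames(out) <- NULL
  out
}

#' Exclude projected QTLs wider than a quarter of their chromosome
#'
#' A projected interval strictly larger than `chrom_length / 4` is flagged
#' `excluded_quarter_filter`; an interval of exactly one quarter is retained
#' (strict reading of "larger than"). Coordinates are never changed, so the
#' filter is idempotent.
#'
#' @param projected output of [project_qtls()].
#' @param chroms `chrom_table`.
#' @return `projected` with updated `status`.
#' @export
quarter_filter <- function(projected, chroms) {
  sel <- projected$status %in% c("projected", "excluded_quarter_filter")
  len <- as.numeric(chroms[projected$chrom[sel]])
  wide <- (projected$end_bp[sel] - projected$start_bp[sel]) > len / 4
  projected$status[sel] <- ifelse(wide, "excluded_quarter_filter", "projected")
  projected
}

# Single-linkage connected components of intervals under intersection
# (half-open [start, end)). Returns an integer component id per row.
.interval_components <- function(start, end) {
  n <- length(start)
  comp <- integer(n)
  ord <- order(start, end, method = "radix")
  cur <- 0L
  cur_end <- -Inf
  for (i in ord) {
    if (start[i] < cur_end) {
      comp[i] <- cur
      cur_end <- max(cur_end, end[i])
    } else {
      cur <- cur + 1L
      comp[i] <- cur
      cur_end <- end[i]
    }
  }
  comp
}

#' Assign positional names to retained projected QTLs
#'
#' Within each (trait_code, chromosome), same-trait QTLs whose projected
#' intervals are connected under pairwise intersection (single linkage) form
#' one locus; loci are numbered `.1, .2, ...` by ascending start of the
#' locus, and every member of a locus shares the name
#' `<trait_code><chromosome number>.<rank>` (e.g. all seven studies mapping
#' one fruit-shape locus on chr08 become `FSI8.1`). The result is
#' deterministic and invariant to input row order.
#'
#' @param projected output of [project_qtls()] / [quarter_filter()].
#' @return `projected` with `renamed_id` filled for `status == "projected"`.
#' @export
rename_qtls <- function(projected) {
  projected$renamed_id <- ""
  sel <- which(projected$status == "projected")
  if (!length(sel)) return(projected)
  key <- paste(projected$trait_code[sel], projected$chrom[sel], sep = "\r")
  for (ix in split(sel, key)) {
    comp <- .interval_components(projected$start_bp[ix], projected$end_bp[ix])
    comp_start <- tapply(projected$start_bp[ix], comp, min)
    rank <- rank(comp_start, ties.method = "first")   # by ascending locus start
    chrom_no <- .chrom_number(projected$chrom[ix[1L]])
    chrom_tag <- if (is.na(chrom_no)) projected$chrom[ix[1L]] else chrom_no
    projected$renamed_id[ix] <- sprintf("%s%s.%d",
                                        projected$trait_code[ix],
                                        chrom_tag,
                                        rank[match(comp, names(comp_start))])
  }
  projected
}
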