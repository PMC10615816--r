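# Landscape summaries of the projected QTL set: per-chromosome counts and
# LOD/PVE means, hotspot clusters, same-trait overlap groups, and
# cross-trait co-localizations.

.retained <- function(projected) {
  projected[projected$status == "projected", , drop = FALSE]
}

#' Per-chromosome and global summary of retained QTLs
#'
#' Means of PVE and LOD are computed over non-missing values only; the
#' denominators are reported so that ragged literature tables do not hide
#' behind an average.
#'
#' @param projected projected QTLs (only `status == "projected"` rows are
#'   summarized).
#' @param chroms `chrom_table`; chromosomes with no QTLs appear with count 0
#'   and NA means.
#' @return list with `per_chromosome` (data.frame: chrom, n_qtl, mean_pve,
#'   n_pve, mean_lod, n_lod) and `global` (one-row data.frame, same layout).
#' @export
chromosome_summary <- function(projected, chroms) {
  rec <- .retained(projected)
  summarize <- function(sub) {
    data.frame(
      n_qtl = nrow(sub),
      mean_pve = if (any(!is.na(sub$pve_percent))) mean(sub$pve_percent, na.rm = TRUE) else NA_real_,
      n_pve = sum(!is.na(sub$pve_percent)),
      mean_lod = if (any(!is.na(sub$lod))) mean(sub$lod, na.rm = TRUE) else NA_real_,
      n_lod = sum(!is.na(sub$lod))
    )
  }
  per <- do.call(rbind, lapply(names(chroms), function(ch) {
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE),
          summarize(rec[rec$chrom == ch, , drop = FALSE]))
  }))
  rownames(per) <- NULL
  list(per_chromosome = per, global = summarize(rec))
}

#' Detect QTL hotspot clusters
#'
#' A cluster region is a window of at most `window_bp` (default 5 Mb)
#' harboring more than five QTLs (`min_count` = 6 by default), with QTL
#' positions taken as interval midpoints. Per chromosome the midpoints are
#' sorted and every maximal run of at least `min_count` midpoints with span
#' <= `window_bp` seeds a candidate region; overlapping candidates are merged
#' into one region trimmed to its member extremes.
#'
#' @param projected projected QTLs (retained rows used).
#' @param window_bp window span in bp.
#' @param min_count minimum number of QTLs in a window.
#' @return data.frame: chrom, window_start_bp, window_end_bp, n_members,
#'   member_ids (comma-joined), trait_codes (comma-joined unique, sorted);
#'   sorted by (chrom order of appearance, start).
#' @export
detect_clusters <- function(projected, window_bp = 5e6, min_count = 6L) {
  rec <- .retained(projected)
  out <- list()
  for (ch in unique(rec$chrom)) {
    sub <- rec[rec$chrom == ch, , drop = FALSE]
    mid <- (sub$start_bp + sub$end_bp) / 2
    ord <- order(mid, sub$qtl_id, method = "radix")
    sub <- sub[ord, , drop = FALSE]
    mid <- mid[ord]
    n <- length(mid)
    if (n < min_count) next
    # candidate windows: for each left anchor i, the maximal run within span
    runs <- list()
    for (i in seq_len(n)) {
      j <- max(which(mid - mid[i] <= window_bp))
      if (j - i + 1L >= min_count) runs[[length(runs) + 1L]] <- c(i, j)
    }
    if (!length(runs)) next
    # merge candidates that share members (overlapping index runs)
    merged <- list()
    cur <- runs[[1L]]
    for (r in runs[-1L]) {
      if (r[1L] <= cur[2L]) {
        cur[2L] <- max(cur[2L], r[2L])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- r
      }
    }
    merged[[length(merged) + 1L]] <- cur
    for (m in merged) {
      ix <- m[1L]:m[2L]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        window_start_bp = mid[m[1L]],
        window_end_bp = mid[m[2L]],
        n_members = length(ix),
        member_ids = paste(sub$qtl_id[ix], collapse = ","),
        trait_codes = paste(sort(unique(sub$trait_code[ix])), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), window_start_bp = numeric(),
                      window_end_bp = numeric(), n_members = integer(),
                      member_ids = character(), trait_codes = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$window_start_bp, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Group same-trait QTLs replicated across studies
#'
#' Within each (trait_code, chromosome), intervals connected under pairwise
#' intersection (single linkage, so a chain A-B-C is one group even when A
#' and C do not touch) form a locus; a locus is an "overlapped QTL" when its
#' members come from at least two distinct studies. The merged extent is the
#' union of member intervals.
#'
#' @param projected projected QTLs (retained rows used).
#' @return data.frame: group_id (positional name), trait_code, chrom,
#'   merged_start_bp, merged_end_bp, n_members, n_studies, member_ids.
#' @export
group_overlaps <- function(projected) {
  rec <- .retained(projected)
  out <- list()
  key <- paste(rec$trait_code, rec$chrom, sep = "\r")
  for (ix in split(seq_len(nrow(rec)), key)) {
    sub <- rec[ix, , drop = FALSE]
    comp <- .interval_components(sub$start_bp, sub$end_bp)
    for (cid in unique(comp)) {
      member <- sub[comp == cid, , drop = FALSE]
      n_studies <- length(unique(member$study_ref))
      if (n_studies < 2L) next
      member <- member[order(member$start_bp, member$qtl_id, method = "radix"), ]
      nm <- unique(member$renamed_id[member$renamed_id != ""])
      chrom_no <- .chrom_number(member$chrom[1L])
      out[[length(out) + 1L]] <- data.frame(
        group_id = if (length(nm) == 1L) nm else
          sprintf("%s%s.g", member$trait_code[1L],
                  if (is.na(chrom_no)) member$chrom[1L] else chrom_no),
        trait_code = member$trait_code[1L],
        chrom = member$chrom[1L],
        merged_start_bp = min(member$start_bp),
        merged_end_bp = max(member$end_bp),
        n_members = nrow(member),
        n_studies = n_studies,
        member_ids = paste(member$qtl_id, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(group_id = character(), trait_code = character(),
                      chrom = character(), merged_start_bp = numeric(),
                      merged_end_bp = numeric(), n_members = integer(),
                      n_studies = integer(), member_ids = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$merged_start_bp, res$trait_code,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect cross-trait co-localizations
#'
#' Per chromosome, a co-localization is a maximal set of retained intervals
#' that all contain a common point (for 1-D intervals these are exactly the
#' maximal cliques of the intersection graph) and that spans at least two
#' distinct trait codes. The reported locus is the common intersection, so
#' its length never exceeds the shortest member. Intersection semantics keep
#' the locus interpretable, unlike the union semantics of [group_overlaps()].
#'
#' @param projected projected QTLs (retained rows used).
#' @return data.frame: chrom, intersection_start_bp, intersection_end_bp,
#'   n_members, n_traits, trait_codes, member_ids.
#' @export
detect_colocalizations <- function(projected) {
  rec <- .retained(projected)
  out <- list()
  for (ch in unique(rec$chrom)) {
    sub <- rec[rec$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start_bp, sub$end_bp, sub$qtl_id, method = "radix"), ]
    n <- nrow(sub)
    if (n < 2L) next
    # Maximal cliques of an interval graph: for each interval e that ends
    # first in its clique, the clique is everything covering [max start, e).
    cliques <- list()
    for (i in seq_len(n)) {
      e <- sub$end_bp[i]
      memb <- which(sub$start_bp < e & sub$end_bp >= e)
      if (length(memb) < 2L) next
      cliques[[length(cliques) + 1L]] <- sort(memb)
    }
    cliques <- unique(cliques)
    if (!length(cliques)) next
    # drop cliques that are subsets of another
    keep <- rep(TRUE, length(cliques))
    for (a in seq_along(cliques)) {
      for (b in seq_along(cliques)) {
        if (a != b && keep[a] &&
            length(cliques[[a]]) <= length(cliques[[b]]) &&
            all(cliques[[a]] %in% cliques[[b]]) &&
            !(length(cliques[[a]]) == length(cliques[[b]]) && a < b)) {
          keep[a] <- FALSE
        }
      }
    }
    for (cl in cliques[keep]) {
      member <- sub[cl, , drop = FALSE]
      traits <- sort(unique(member$trait_code))
      if (length(traits) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        intersection_start_bp = max(member$start_bp),
        intersection_end_bp = min(member$end_bp),
        n_members = nrow(member),
        n_traits = length(traits),
        trait_codes = paste(traits, collapse = ","),
        member_ids = paste(member$qtl_id, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), intersection_start_bp = numeric(),
                      intersection_end_bp = numeric(), n_members = integer(),
                      n_traits = integer(), trait_codes = character(),
                      member_ids = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$intersection_start_bp, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
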