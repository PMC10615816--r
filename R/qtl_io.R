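# Tabular input/output: curated QTL metadata tables, chromosome-length
# tables (FASTA .fai-compatible) and projected-QTL BED/TSV artifacts.
#
# Internal coordinate convention: 0-based half-open everywhere (BED and PAF
# native). 1-based inclusive appears only in human-readable reports.

#' The seven recognized trait groups
#' @export
TRAIT_GROUPS <- c("fruit", "flower", "vegetative_organ", "seed",
                  "disease_resistance", "insect_resistance", "abiotic_stress")

#' The recognized mapping-population types
#' @export
POP_TYPES <- c("F2", "RIL", "DH", "BC", "other")

# Required columns of the curated QTL metadata table (tab-separated).
.QTL_REQUIRED_COLS <- c("qtl_id", "study_ref", "trait_code", "trait_group",
                        "linkage_group", "ci_start_cM", "ci_end_cM")
.QTL_OPTIONAL_COLS <- c("peak_cM", "lod", "pve_percent", "pop_type",
                        "pop_size", "parents", "source_genome")

#' Read and validate a curated QTL metadata table
#'
#' Reads a delimited table with one row per published QTL and validates each
#' row against the schema: unique `qtl_id`, a `trait_group` among the seven
#' recognized groups, an ordered genetic confidence interval
#' (`ci_start_cM <= ci_end_cM`, containing `peak_cM` when given), positive
#' LOD, PVE in (0, 100], and a positive population size. Optional fields
#' (`peak_cM`, `lod`, `pve_percent`, `pop_size`) may be empty; downstream
#' summaries skip missing values rather than imputing.
#'
#' Rows violating the schema are rejected, never silently dropped: the
#' returned table carries a `rejected` attribute with one row per rejected
#' input row (row number, qtl_id, reason) so that
#' `nrow(accepted) + nrow(rejected)` always equals the number of input rows.
#'
#' @param path path to the table.
#' @param sep field delimiter, tab by default.
#' @param col_map optional named character vector mapping schema names to the
#'   file's column names (e.g. `c(qtl_id = "QTL name")`), for ingesting
#'   externally curated layouts.
#' @return a `data.frame` of accepted records (class `qtl_table`), file order
#'   preserved, with attributes `rejected` (data.frame) and `group_counts`
#'   (named integer vector of trait-group counts).
#' @export
read_qtl_table <- function(path, sep = "\t", col_map = NULL) {
  if (!file.exists(path)) stop("QTL table not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      idx <- match(col_map[[schema_name]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- schema_name
    }
  }
  missing_cols <- setdiff(.QTL_REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    stop("QTL table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in .QTL_OPTIONAL_COLS) if (!col %in% names(raw)) raw[[col]] <- ""
  validate_qtl_table(raw)
}

#' Validate an in-memory QTL table against the schema
#'
#' @param raw data.frame with (at least) the required schema columns, all
#'   character or coercible.
#' @return same contract as [read_qtl_table()].
#' @export
validate_qtl_table <- function(raw) {
  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "" | is.na(x), NA, x)))
  peak <- num(raw$peak_cM); ci_lo <- num(raw$ci_start_cM); ci_hi <- num(raw$ci_end_cM)
  lod <- num(raw$lod); pve <- num(raw$pve_percent); pop_size <- num(raw$pop_size)

  reason <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }
  flag(is.na(raw$qtl_id) | raw$qtl_id == "", "missing qtl_id")
  flag(duplicated(raw$qtl_id) | duplicated(raw$qtl_id, fromLast = TRUE),
       "duplicate qtl_id")
  flag(!(raw$trait_group %in% TRAIT_GROUPS), "unknown trait_group")
  flag(is.na(ci_lo) | is.na(ci_hi), "non-numeric interval bound")
  flag(!is.na(ci_lo) & !is.na(ci_hi) & ci_lo > ci_hi, "interval reversed")
  flag(!is.na(ci_lo) & ci_lo < 0, "negative cM position")
  flag(!is.na(peak) & !is.na(ci_lo) & !is.na(ci_hi) &
         (peak < ci_lo | peak > ci_hi), "peak outside interval")
  flag((!is.na(raw$lod) & raw$lod != "" & is.na(lod)), "non-numeric LOD")
  flag(!is.na(lod) & lod <= 0, "non-positive LOD")
  flag((!is.na(raw$pve_percent) & raw$pve_percent != "" & is.na(pve)),
       "non-numeric PVE")
  flag(!is.na(pve) & (pve <= 0 | pve > 100), "PVE outside (0,100]")
  flag(!is.na(pop_size) & pop_size <= 0, "non-positive pop_size")
  pop_type <- ifelse(raw$pop_type %in% POP_TYPES, raw$pop_type, "other")

  ok <- reason == ""
  accepted <- data.frame(
    qtl_id = raw$qtl_id[ok],
    study_ref = raw$study_ref[ok],
    trait_code = raw$trait_code[ok],
    trait_group = raw$trait_group[ok],
    linkage_group = raw$linkage_group[ok],
    peak_cM = peak[ok],
    ci_start_cM = ci_lo[ok],
    ci_end_cM = ci_hi[ok],
    lod = lod[ok],
    pve_percent = pve[ok],
    pop_type = pop_type[ok],
    pop_size = pop_size[ok],
    parents = raw$parents[ok],
    source_genome = raw$source_genome[ok],
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(row = which(!ok),
                         qtl_id = raw$qtl_id[!ok],
                         reason = reason[!ok],
                         stringsAsFactors = FALSE)
  counts <- table(factor(accepted$trait_group, levels = TRAIT_GROUPS))
  structure(accepted,
            rejected = rejected,
            group_counts = stats::setNames(as.integer(counts), TRAIT_GROUPS),
            class = c("qtl_table", "data.frame"))
}

#' Write a QTL table in the package's tab-separated layout
#' @param qtls data.frame as returned by [read_qtl_table()].
#' @param path output path.
#' @export
write_qtl_table <- function(qtls, path) {
  out <- as.data.frame(qtls)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Accepts the two leading columns of a FASTA index (`samtools faidx` .fai):
#' chromosome name and length in bp. Order in the file is preserved.
#'
#' @param path path to a tab-separated file; extra .fai columns are ignored.
#' @return named numeric vector of lengths, ordered as in the file, with
#'   class `chrom_table`.
#' @export
read_chrom_table <- function(path) {
  if (!file.exists(path)) stop("chromosome table not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("chromosome table needs two columns (name, length)")
  chrom_table(stats::setNames(raw[[2L]], raw[[1L]]))
}

#' Construct / validate a chromosome-length table
#' @param lengths named vector, chromosome name -> length in bp.
#' @export
chrom_table <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "")) stop("chromosome names are required")
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1L])
  }
  len <- suppressWarnings(as.numeric(lengths))
  if (any(is.na(len)) || any(len <= 0) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(stats::setNames(len, nm), class = "chrom_table")
}

#' Write a chromosome table as a two-column .fai-style file
#' @param chroms a `chrom_table`.
#' @param path output path.
#' @export
write_chrom_table <- function(chroms, path) {
  writeLines(sprintf("%s\t%d", names(chroms), as.integer(chroms)), path)
  invisible(path)
}

#' Write projected QTLs as BED6
#'
#' Emits one BED line per record with `status` of `projected` or
#' `excluded_quarter_filter`: chrom, start, end (0-based half-open), name
#' (`renamed_id` when set, else `qtl_id`), score `round(10 * LOD)` (0 when
#' LOD is missing), strand ".". Lines are sorted by chromosome order in
#' `chroms`, then start. An empty input yields a file with only the header
#' comment.
#'
#' @param projected data.frame from [project_qtls()].
#' @param path output path.
#' @param chroms `chrom_table` fixing chromosome order; all chromosomes in
#'   `projected` must be present.
#' @export
write_projected_bed <- function(projected, path, chroms) {
  keep <- projected$status %in% c("projected", "excluded_quarter_filter")
  rec <- projected[keep, , drop = FALSE]
  unknown <- setdiff(unique(rec$chrom), names(chroms))
  if (length(unknown)) stop("unknown chromosome in BED output: ",
                            paste(unknown, collapse = ", "))
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (!nrow(rec)) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(match(rec$chrom, names(chroms)), rec$start_bp, rec$end_bp,
               rec$qtl_id, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  name <- ifelse(is.na(rec$renamed_id) | rec$renamed_id == "",
                 rec$qtl_id, rec$renamed_id)
  score <- ifelse(is.na(rec$lod), 0L, as.integer(round(10 * rec$lod)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   rec$chrom, as.integer(rec$start_bp), as.integer(rec$end_bp),
                   name, score)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED6 file written by [write_projected_bed()]
#' @param path BED path.
#' @return data.frame with chrom, start_bp, end_bp, name, score, strand.
#' @export
read_projected_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), name = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) stop("malformed BED6 line")
  data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start_bp = as.numeric(vapply(parts, `[[`, "", 2L)),
    end_bp = as.numeric(vapply(parts, `[[`, "", 3L)),
    name = vapply(parts, `[[`, "", 4L),
    score = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
}
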