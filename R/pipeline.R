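# One-shot composition of the stages: project -> atlas -> meta, with a
# config audit trail, per-stage counts and a Markdown report. The stage
# ledger is conserved: collected = projected + failed (all reasons), and
# projected = retained + excluded_quarter_filter.

#' Build a run configuration
#'
#' @param qtl_table,paf,fai input paths (curated QTL table, flank
#'   alignments, chromosome-length table).
#' @param outdir output directory.
#' @param flank_len flank length in bp (documentation of the upstream
#'   convention; projection itself reads it from the PAF records).
#' @param quarter_filter apply the quarter-chromosome exclusion.
#' @param cluster_window_bp,cluster_min_count hotspot rule (5 Mb, > 5 QTLs).
#' @param k_max,min_members,sd_min,seed meta-QTL parameters (see
#'   [run_metaqtl()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(qtl_table, paf, fai, outdir,
                       flank_len = 1000L, quarter_filter = TRUE,
                       cluster_window_bp = 5e6, cluster_min_count = 6L,
                       k_max = 5L, min_members = 2L, sd_min = 0.01,
                       seed = 17L) {
  stopifnot(cluster_window_bp > 0, cluster_min_count >= 1L,
            k_max >= 1L, min_members >= 1L, sd_min > 0)
  structure(list(qtl_table = qtl_table, paf = paf, fai = fai,
                 outdir = outdir, flank_len = as.integer(flank_len),
                 quarter_filter = isTRUE(quarter_filter),
                 cluster_window_bp = cluster_window_bp,
                 cluster_min_count = as.integer(cluster_min_count),
                 k_max = as.integer(k_max),
                 min_members = as.integer(min_members),
                 sd_min = sd_min, seed = as.integer(seed),
                 version = as.character(utils::packageVersion("melonmeta"))),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Run the full pipeline
#'
#' Validates inputs up front (no partial outputs on a bad path), then runs
#' projection, filtering, renaming, landscape summaries and meta-QTL
#' identification, writing every table to `outdir`:
#' `projected.tsv`, `projected.bed`, `summary.tsv`, `clusters.tsv`,
#' `overlaps.tsv`, `colocalizations.tsv`, `mqtl.tsv`, `members.tsv`,
#' `report.md`, `log.txt` and the effective `config.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory results and the `counts`
#'   stage ledger.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$qtl_table, config$paf, config$fai)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  qtls <- read_qtl_table(config$qtl_table)
  rej <- attr(qtls, "rejected")
  say("[ingest] accepted %d QTL record(s), rejected %d", nrow(qtls), nrow(rej))
  gc_counts <- attr(qtls, "group_counts")
  say("[ingest] trait groups: %s",
      paste(sprintf("%s=%d", names(gc_counts), gc_counts), collapse = ", "))
  chroms <- read_chrom_table(config$fai)
  paf <- parse_paf(config$paf)
  say("[paf] %d alignment(s) parsed, %d malformed line(s)",
      nrow(paf), nrow(attr(paf, "bad_lines")))

  projected <- project_qtls(qtls, paf, chroms)
  if (config$quarter_filter) projected <- quarter_filter(projected, chroms)
  projected <- rename_qtls(projected)
  status_tab <- table(factor(projected$status, levels = PROJECTION_STATUSES))
  say("[project] %s",
      paste(sprintf("%s=%d", names(status_tab), as.integer(status_tab)),
            collapse = ", "))
  counts <- list(
    collected = nrow(qtls),
    projected = sum(projected$status %in% c("projected",
                                            "excluded_quarter_filter")),
    retained = sum(projected$status == "projected"),
    excluded_quarter_filter = sum(projected$status == "excluded_quarter_filter"),
    failed = sum(startsWith(projected$status, "failed"))
  )
  stopifnot(counts$collected == counts$projected + counts$failed,
            counts$projected == counts$retained + counts$excluded_quarter_filter)

  summary <- chromosome_summary(projected, chroms)
  clusters <- detect_clusters(projected, window_bp = config$cluster_window_bp,
                              min_count = config$cluster_min_count)
  overlaps <- group_overlaps(projected)
  colocs <- detect_colocalizations(projected)
  say("[atlas] clusters=%d, overlap groups=%d, co-localizations=%d",
      nrow(clusters), nrow(overlaps), nrow(colocs))
  meta <- run_metaqtl(projected, chroms, qtls = qtls,
                      k_max = config$k_max, min_members = config$min_members,
                      sd_min = config$sd_min, seed = config$seed)
  say("[meta] %d meta-QTL(s) in %d group(s)", nrow(meta$mqtl),
      length(meta$models))
  counts$clusters <- nrow(clusters)
  counts$overlap_groups <- nrow(overlaps)
  counts$colocalizations <- nrow(colocs)
  counts$mqtls <- nrow(meta$mqtl)

  .write_tsv(projected, file.path(config$outdir, "projected.tsv"))
  write_projected_bed(projected, file.path(config$outdir, "projected.bed"),
                      chroms)
  .write_tsv(summary$per_chromosome, file.path(config$outdir, "summary.tsv"))
  .write_tsv(clusters, file.path(config$outdir, "clusters.tsv"))
  .write_tsv(overlaps, file.path(config$outdir, "overlaps.tsv"))
  .write_tsv(colocs, file.path(config$outdir, "colocalizations.tsv"))
  .write_tsv(meta$mqtl, file.path(config$outdir, "mqtl.tsv"))
  .write_tsv(meta$members, file.path(config$outdir, "members.tsv"))
  jsonlite::write_json(unclass(config),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(config$outdir, "log.txt"))
  writeLines(.run_report(counts, summary, meta),
             file.path(config$outdir, "report.md"))

  invisible(list(qtls = qtls, chroms = chroms, projected = projected,
                 summary = summary, clusters = clusters, overlaps = overlaps,
                 colocalizations = colocs, meta = meta, counts = counts,
                 log = log_lines))
}

# Markdown run report; every number restates a machine-readable TSV value.
.run_report <- function(counts, summary, meta) {
  g <- summary$global
  c(
    "# Meta-QTL integration run",
    "",
    "## Stage ledger",
    "",
    sprintf("- QTLs collected: %d", counts$collected),
    sprintf("- Projected onto the reference: %d (failed: %d)",
            counts$projected, counts$failed),
    sprintf("- Retained after quarter-chromosome filter: %d (excluded: %d)",
            counts$retained, counts$excluded_quarter_filter),
    sprintf("- Hotspot clusters: %d; same-trait overlap groups: %d; cross-trait co-localizations: %d",
            counts$clusters, counts$overlap_groups, counts$colocalizations),
    sprintf("- Meta-QTLs: %d", counts$mqtls),
    "",
    "## Retained QTL landscape",
    "",
    sprintf("- Mean PVE: %s%% (over %d records with PVE)",
            ifelse(is.na(g$mean_pve), "NA", sprintf("%.2f", g$mean_pve)),
            g$n_pve),
    sprintf("- Mean LOD: %s (over %d records with LOD)",
            ifelse(is.na(g$mean_lod), "NA", sprintf("%.2f", g$mean_lod)),
            g$n_lod),
    "",
    "## Meta-QTLs",
    "",
    if (nrow(meta$mqtl)) {
      sprintf("- %s: %d member(s), %.3f Mb, CI95 [%.3f, %.3f] Mb (K=%d)",
              meta$mqtl$mqtl_id, meta$mqtl$n_members,
              meta$mqtl$consensus_position_mb,
              meta$mqtl$ci95_start_mb, meta$mqtl$ci95_end_mb,
              meta$mqtl$model_K)
    } else "- none"
  )
}
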