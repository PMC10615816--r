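# Ground-truthed synthetic inputs for the whole pipeline: a toy genome
# (index only -- no bases), true meta-QTL loci, per-study QTL tables with
# the statistical structure the consensus model assumes, matching PAF flank
# placements, and recovery scoring against the truth.
#
# The generative model mirrors the analysis model: each study observes a
# true locus with probability detect_prob; the observed peak is the true
# position plus Gaussian noise; the confidence-interval width shrinks with
# population size and effect size (Darvasi-Soller-style CI = c / (N * PVE%)
# in cM, c = 530 by default); LOD follows the standard PVE identity
# LOD = -(N/2) * log10(1 - PVE). Genetic coordinates use one global
# cM <-> bp rate (default 1 cM = 250 kb).

# Twelve chromosome lengths in the 25-40 Mb range, totalling 379.2 Mb.
.DEFAULT_CHROM_MB <- c(40.0, 36.5, 35.0, 34.0, 33.0, 32.0,
                       31.0, 30.0, 29.0, 27.5, 26.2, 25.0)

#' Simulation configuration with field-realistic defaults
#'
#' @param chrom_lengths named vector of chromosome lengths in bp; default 12
#'   chromosomes of 25-40 Mb totalling 379.2 Mb.
#' @param loci data.frame (trait_code, chrom, n_loci): how many true loci to
#'   plant per trait x chromosome. Default: three fruit traits on two
#'   chromosomes, two loci each.
#' @param pve_range range of true per-locus effect sizes (fraction of
#'   variance explained).
#' @param min_sep_bp minimum separation between same-trait loci on one
#'   chromosome (identifiability control), default 8 Mb.
#' @param margin_bp keep loci this far from chromosome ends.
#' @param n_studies number of simulated mapping studies.
#' @param pop_size_range integer range of population sizes.
#' @param pop_types population types sampled per study.
#' @param detect_prob probability a study detects a given locus.
#' @param noise_mode `"ci"` (default): a study's positional error sd equals
#'   the sd implied by its own CI width -- the consensus model's generative
#'   assumption; `"fixed"`: one positional sd per study, drawn from
#'   `noise_sd_bp_range`; `"none"`: zero positional noise.
#' @param noise_sd_bp_range per-study positional sd range for
#'   `noise_mode = "fixed"`.
#' @param ci_mode `"darvasi"` (default): CI width in cM is
#'   `darvasi_c / (pop_size * pve_percent)`; `"uniform_sd"`: the implied
#'   positional sd is drawn uniformly from `sd_range_mb` and the CI width is
#'   `3.92 * sd`.
#' @param darvasi_c CI-width constant, default 530 (backcross-style
#'   approximation; a knob, not a biological claim).
#' @param sd_range_mb sd range for `ci_mode = "uniform_sd"`.
#' @param cm_to_bp global genetic-to-physical rate, bp per cM.
#' @param pve_jitter multiplicative half-width of the per-study PVE jitter.
#' @param flank_len flank length in bp used for PAF emission.
#' @param trait_group trait group recorded for all simulated traits.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = NULL,
                       loci = NULL,
                       pve_range = c(0.05, 0.30),
                       min_sep_bp = 8e6,
                       margin_bp = 2e6,
                       n_studies = 20L,
                       pop_size_range = c(60L, 250L),
                       pop_types = c("F2", "RIL", "DH", "BC"),
                       detect_prob = 0.8,
                       noise_mode = c("ci", "fixed", "none"),
                       noise_sd_bp_range = c(1e5, 5e5),
                       ci_mode = c("darvasi", "uniform_sd"),
                       darvasi_c = 530,
                       sd_range_mb = c(0.3, 1.5),
                       cm_to_bp = 250000,
                       pve_jitter = 0.15,
                       flank_len = 1000L,
                       trait_group = "fruit") {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(as.integer(.DEFAULT_CHROM_MB * 1e6),
                                     sprintf("chr%02d", seq_along(.DEFAULT_CHROM_MB)))
  }
  if (is.null(loci)) {
    loci <- expand.grid(trait_code = c("FSI", "FW", "TSS"),
                        chrom = c("chr01", "chr02"),
                        stringsAsFactors = FALSE)
    loci$n_loci <- 2L
  }
  stopifnot(all(loci$chrom %in% names(chrom_lengths)),
            all(loci$n_loci >= 1L),
            detect_prob >= 0, detect_prob <= 1,
            trait_group %in% TRAIT_GROUPS)
  structure(list(chrom_lengths = chrom_table(chrom_lengths),
                 loci = loci,
                 pve_range = pve_range,
                 min_sep_bp = min_sep_bp,
                 margin_bp = margin_bp,
                 n_studies = as.integer(n_studies),
                 pop_size_range = as.integer(pop_size_range),
                 pop_types = pop_types,
                 detect_prob = detect_prob,
                 noise_mode = match.arg(noise_mode),
                 noise_sd_bp_range = noise_sd_bp_range,
                 ci_mode = match.arg(ci_mode),
                 darvasi_c = darvasi_c,
                 sd_range_mb = sd_range_mb,
                 cm_to_bp = cm_to_bp,
                 pve_jitter = pve_jitter,
                 flank_len = as.integer(flank_len),
                 trait_group = trait_group),
            class = "sim_config")
}

#' Draw ground-truth loci and a study plan
#'
#' Loci are placed uniformly within `[margin, length - margin]` subject to a
#' minimum pairwise separation within each trait x chromosome (exact
#' uniform-with-gap sampling, so the draw is a single pass). The study plan
#' fixes each study's population type and size, detection probability and
#' positional-noise regime. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_truth`: `chrom_lengths`, `loci`
#'   (trait_code, chrom, locus_rank, position_bp, effect_pve), `study_plan`
#'   (study_ref, pop_type, pop_size, detect_prob, position_noise_sd_bp),
#'   `seed`, `config`.
#' @export
simulate_truth <- function(config = sim_config(), seed = 17L) {
  stopifnot(inherits(config, "sim_config"))
  loci <- with_seed(.child_seed(seed, "truth"), {
    rows <- lapply(seq_len(nrow(config$loci)), function(i) {
      trait <- config$loci$trait_code[i]
      chrom <- config$loci$chrom[i]
      n <- config$loci$n_loci[i]
      len <- as.numeric(config$chrom_lengths[[chrom]])
      avail <- len - 2 * config$margin_bp
      slack <- avail - (n - 1) * config$min_sep_bp
      if (slack < 0) {
        stop(sprintf("cannot place %d loci %g bp apart on %s (%g bp usable)",
                     n, config$min_sep_bp, chrom, avail))
      }
      pos <- config$margin_bp + sort(stats::runif(n, 0, slack)) +
        (seq_len(n) - 1L) * config$min_sep_bp
      data.frame(trait_code = trait, chrom = chrom,
                 locus_rank = seq_len(n),
                 position_bp = round(pos),
                 effect_pve = stats::runif(n, config$pve_range[1L],
                                           config$pve_range[2L]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  study_plan <- with_seed(.child_seed(seed, "studies"), {
    n <- config$n_studies
    # index-based draws avoid base::sample's scalar-x surprise
    sizes <- seq(config$pop_size_range[1L], config$pop_size_range[2L])
    data.frame(
      study_ref = sprintf("study%02d", seq_len(n)),
      pop_type = config$pop_types[sample.int(length(config$pop_types), n,
                                             replace = TRUE)],
      pop_size = sizes[sample.int(length(sizes), n, replace = TRUE)],
      detect_prob = config$detect_prob,
      position_noise_sd_bp = switch(config$noise_mode,
        ci = NA_real_,
        none = 0,
        fixed = stats::runif(n, config$noise_sd_bp_range[1L],
                             config$noise_sd_bp_range[2L])),
      stringsAsFactors = FALSE
    )
  })
  rownames(loci) <- NULL
  structure(list(chrom_lengths = config$chrom_lengths,
                 loci = loci, study_plan = study_plan,
                 seed = as.integer(seed), config = config),
            class = "synthetic_truth")
}

#' Simulate per-study QTL tables from the truth
#'
#' For each study x locus, with probability `detect_prob` one QTL record is
#' emitted: the observed peak is the true position plus Gaussian noise (see
#' `noise_mode` in [sim_config()]); the CI width is tied to population size
#' and effect size; LOD follows `-(N/2) * log10(1 - PVE)`. Genetic
#' coordinates are physical bp divided by the global `cm_to_bp` rate, so
#' flank placement can be reconstructed exactly. Per-study RNG sub-streams
#' are derived from (`truth$seed`, study_ref), so adding a study never
#' reshuffles the others.
#'
#' @param truth a [simulate_truth()] result.
#' @param seed optional override of `truth$seed`.
#' @return a validated `qtl_table` ([validate_qtl_table()]).
#' @export
simulate_studies <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  seed <- seed %||% truth$seed
  rows <- list()
  for (s in seq_len(nrow(truth$study_plan))) {
    st <- truth$study_plan[s, ]
    rows[[s]] <- with_seed(.child_seed(seed, st$study_ref), {
      out <- list()
      for (i in seq_len(nrow(truth$loci))) {
        lc <- truth$loci[i, ]
        if (stats::runif(1) > st$detect_prob) next
        len <- as.numeric(cfg$chrom_lengths[[lc$chrom]])
        pve_obs <- lc$effect_pve *
          stats::runif(1, 1 - cfg$pve_jitter, 1 + cfg$pve_jitter)
        pve_obs <- min(max(pve_obs, 0.005), 0.8)
        if (cfg$ci_mode == "darvasi") {
          width_cm <- cfg$darvasi_c / (st$pop_size * pve_obs * 100)
          width_bp <- width_cm * cfg$cm_to_bp
        } else {
          sd_mb <- stats::runif(1, cfg$sd_range_mb[1L], cfg$sd_range_mb[2L])
          width_bp <- 3.92 * sd_mb * 1e6
        }
        width_bp <- min(width_bp, len - 2 * cfg$flank_len - 2)
        noise_sd <- switch(cfg$noise_mode,
                           none = 0,
                           fixed = st$position_noise_sd_bp,
                           ci = width_bp / 3.92)
        peak_bp <- lc$position_bp +
          if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
        half <- max(1, round(width_bp / 2))
        start_bp <- round(peak_bp) - half
        end_bp <- round(peak_bp) + half
        # keep the interval (plus flanks) inside the chromosome
        if (start_bp < cfg$flank_len) {
          end_bp <- end_bp + (cfg$flank_len - start_bp)
          start_bp <- cfg$flank_len
        }
        if (end_bp > len - cfg$flank_len) {
          start_bp <- start_bp - (end_bp - (len - cfg$flank_len))
          end_bp <- len - cfg$flank_len
        }
        start_bp <- max(start_bp, cfg$flank_len)
        peak_rec <- min(max(round(peak_bp), start_bp), end_bp)
        pop_type <- if (st$pop_type %in% POP_TYPES) st$pop_type else "other"
        out[[length(out) + 1L]] <- data.frame(
          qtl_id = sprintf("%s_%s_%s_l%d", st$study_ref, lc$trait_code,
                           lc$chrom, lc$locus_rank),
          study_ref = st$study_ref,
          trait_code = lc$trait_code,
          trait_group = cfg$trait_group,
          linkage_group = sub("^chr", "LG", lc$chrom),
          peak_cM = peak_rec / cfg$cm_to_bp,
          ci_start_cM = start_bp / cfg$cm_to_bp,
          ci_end_cM = end_bp / cfg$cm_to_bp,
          lod = -(st$pop_size / 2) * log10(1 - pve_obs),
          pve_percent = pve_obs * 100,
          pop_type = pop_type,
          pop_size = st$pop_size,
          parents = "P1 x P2",
          source_genome = "synthetic_ref_v1",
          stringsAsFactors = FALSE
        )
      }
      if (length(out)) do.call(rbind, out) else NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  tab <- if (length(rows)) do.call(rbind, rows) else {
    empty <- data.frame(qtl_id = character(), study_ref = character(),
                        trait_code = character(), trait_group = character(),
                        linkage_group = character(), peak_cM = character(),
                        ci_start_cM = character(), ci_end_cM = character(),
                        lod = character(), pve_percent = character(),
                        pop_type = character(), pop_size = character(),
                        parents = character(), source_genome = character(),
                        stringsAsFactors = FALSE)
    empty
  }
  tab[] <- lapply(tab, as.character)
  validate_qtl_table(tab)
}

#' Emit PAF flank alignments matching a simulated QTL table
#'
#' Reconstructs each QTL's physical interval from its genetic coordinates
#' (exact, because the simulation used one global cM-to-bp rate) and writes
#' two primary PAF records per QTL, `"<qtl_id>__L"` and `"<qtl_id>__R"`,
#' mapq 60, placed immediately outside the interval. Corruption modes
#' exercise the projection failure paths.
#'
#' @param truth a [simulate_truth()] result.
#' @param qtls the matching `qtl_table` from [simulate_studies()].
#' @param flank_len flank length, default from the config.
#' @param drop_left,drop_right,cross_chrom character vectors of qtl_ids: omit
#'   the left / right flank record, or move the right flank to the next
#'   chromosome.
#' @return PAF data.frame ([parse_paf()] layout).
#' @export
emit_synthetic_paf <- function(truth, qtls, flank_len = NULL,
                               drop_left = character(),
                               drop_right = character(),
                               cross_chrom = character()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  flank_len <- flank_len %||% cfg$flank_len
  chroms <- truth$chrom_lengths
  chrom_names <- names(chroms)
  rows <- list()
  for (i in seq_len(nrow(qtls))) {
    id <- qtls$qtl_id[i]
    chrom <- sub("^LG", "chr", qtls$linkage_group[i])
    len <- as.numeric(chroms[[chrom]])
    start_bp <- round(qtls$ci_start_cM[i] * cfg$cm_to_bp)
    end_bp <- round(qtls$ci_end_cM[i] * cfg$cm_to_bp)
    if (start_bp - flank_len < 0 || end_bp + flank_len > len) {
      warning("interval too close to chromosome end, skipping flanks for ", id)
      next
    }
    mk <- function(suffix, tname, tlen, tstart) data.frame(
      query_name = paste0(id, suffix), query_len = flank_len,
      query_start = 0, query_end = flank_len, strand = "+",
      target_name = tname, target_len = tlen,
      target_start = tstart, target_end = tstart + flank_len,
      n_matches = flank_len, aln_len = flank_len, mapq = 60,
      is_primary = TRUE, stringsAsFactors = FALSE)
    if (!id %in% drop_left) {
      rows[[length(rows) + 1L]] <- mk("__L", chrom, len, start_bp - flank_len)
    }
    if (!id %in% drop_right) {
      if (id %in% cross_chrom) {
        other <- chrom_names[(match(chrom, chrom_names) %% length(chrom_names)) + 1L]
        rows[[length(rows) + 1L]] <-
          mk("__R", other, as.numeric(chroms[[other]]), flank_len)
      } else {
        rows[[length(rows) + 1L]] <- mk("__R", chrom, len, end_bp)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_name = character(), query_len = numeric(),
                      query_start = numeric(), query_end = numeric(),
                      strand = character(), target_name = character(),
                      target_len = numeric(), target_start = numeric(),
                      target_end = numeric(), n_matches = numeric(),
                      aln_len = numeric(), mapq = numeric(),
                      is_primary = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score recovered meta-QTLs against the planted truth
#'
#' Greedy 1-to-1 nearest matching between true loci and meta-QTLs of the
#' same trait x chromosome, within `match_cap_mb`. Reports per-group true
#' and found counts, the RMSE of matched positions, and the fraction of
#' matched true loci lying inside the meta-QTL's 95% interval.
#'
#' @param truth a [simulate_truth()] result.
#' @param mqtl the `mqtl` data.frame of a [run_metaqtl()] result.
#' @param match_cap_mb maximum match distance, default 2 Mb.
#' @return list of class `recovery_report`: `per_group` (trait_code, chrom,
#'   k_true, k_found), `matches`, `position_rmse_mb`, `ci_coverage`,
#'   `n_matched`, `n_true_unmatched`, `n_mqtl_unmatched`.
#' @export
score_recovery <- function(truth, mqtl, match_cap_mb = 2) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tl <- truth$loci
  tl$position_mb <- tl$position_bp / 1e6
  pairs <- list()
  for (i in seq_len(nrow(tl))) {
    cand <- which(mqtl$trait_code == tl$trait_code[i] &
                    mqtl$chrom == tl$chrom[i])
    for (j in cand) {
      d <- abs(mqtl$consensus_position_mb[j] - tl$position_mb[i])
      if (d <= match_cap_mb) {
        pairs[[length(pairs) + 1L]] <- c(i = i, j = j, d = d)
      }
    }
  }
  matched_true <- logical(nrow(tl))
  matched_mqtl <- logical(nrow(mqtl))
  matches <- list()
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, "d"], pm[, "i"], pm[, "j"]), , drop = FALSE]
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, "i"]; j <- pm[r, "j"]
      if (matched_true[i] || matched_mqtl[j]) next
      matched_true[i] <- TRUE
      matched_mqtl[j] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(
        trait_code = tl$trait_code[i], chrom = tl$chrom[i],
        true_position_mb = tl$position_mb[i],
        mqtl_id = mqtl$mqtl_id[j],
        mqtl_position_mb = mqtl$consensus_position_mb[j],
        error_mb = mqtl$consensus_position_mb[j] - tl$position_mb[i],
        in_ci95 = tl$position_mb[i] >= mqtl$ci95_start_mb[j] &
          tl$position_mb[i] <= mqtl$ci95_end_mb[j],
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(trait_code = character(), chrom = character(),
               true_position_mb = numeric(), mqtl_id = character(),
               mqtl_position_mb = numeric(), error_mb = numeric(),
               in_ci95 = logical(), stringsAsFactors = FALSE)
  key_true <- paste(tl$trait_code, tl$chrom)
  k_true <- table(key_true)
  key_found <- paste(mqtl$trait_code, mqtl$chrom)
  groups <- unique(c(names(k_true), unique(key_found)))
  per_group <- data.frame(
    trait_code = sub(" .*", "", groups),
    chrom = sub(".* ", "", groups),
    k_true = as.integer(k_true[groups]),
    k_found = as.integer(table(key_found)[groups]),
    stringsAsFactors = FALSE
  )
  per_group$k_true[is.na(per_group$k_true)] <- 0L
  per_group$k_found[is.na(per_group$k_found)] <- 0L
  structure(list(
    per_group = per_group,
    matches = matches,
    position_rmse_mb = if (nrow(matches)) sqrt(mean(matches$error_mb^2)) else NA_real_,
    ci_coverage = if (nrow(matches)) mean(matches$in_ci95) else 0,
    n_matched = nrow(matches),
    n_true_unmatched = sum(!matched_true),
    n_mqtl_unmatched = sum(!matched_mqtl)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %d matched, %d true unmatched, %d MQTL unmatched\n",
              x$n_matched, x$n_true_unmatched, x$n_mqtl_unmatched))
  cat(sprintf("  position RMSE: %.4f Mb; CI95 coverage: %.3f\n",
              x$position_rmse_mb, x$ci_coverage))
  invisible(x)
}

#' Write a full synthetic input set to a directory
#'
#' Emits `qtl_table.tsv`, `flanks.paf`, `genome.fai` and `truth.json`
#' (ground truth and study plan, for later [score_recovery()]).
#'
#' @param truth a [simulate_truth()] result.
#' @param dir output directory (created if needed).
#' @param seed optional override passed to [simulate_studies()].
#' @return invisibly, a list with the qtl table and paf.
#' @export
write_synthetic_run <- function(truth, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qtls <- simulate_studies(truth, seed = seed)
  paf <- emit_synthetic_paf(truth, qtls)
  write_qtl_table(qtls, file.path(dir, "qtl_table.tsv"))
  write_paf(paf, file.path(dir, "flanks.paf"))
  write_chrom_table(truth$chrom_lengths, file.path(dir, "genome.fai"))
  jsonlite::write_json(
    list(seed = truth$seed,
         chrom_lengths = as.list(unclass(truth$chrom_lengths)),
         loci = truth$loci,
         study_plan = truth$study_plan),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(qtls = qtls, paf = paf))
}
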