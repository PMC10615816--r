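# Meta-QTL identification: per trait x chromosome, reduce each retained
# projected QTL to a (position, sd) observation, select the number of true
# loci by AIC over known-variance Gaussian mixtures, assign members to loci
# by MAP, and report inverse-variance consensus positions and intervals.
#
# Analysis coordinate is projected physical Mb: all studies have been lifted
# onto the same assembly, so no consensus genetic map is needed.

#' Build Gaussian observations from projected QTLs
#'
#' Position (Mb): the interval midpoint, unless the source record carries a
#' genetic peak, in which case the peak is placed proportionally inside the
#' projected interval (`start + (peak - ci_start)/(ci_end - ci_start) *
#' width`). Standard deviation: the projected interval width treated as a
#' 95% confidence interval, `sd = width / 3.92` (see [ci_to_sd()]), floored
#' at `sd_min`. Records with a missing or zero physical width take the
#' median width of their trait x chromosome group and are flagged
#' (`width_imputed`).
#'
#' @param projected projected QTLs (retained rows used).
#' @param qtls the matching `qtl_table` (source of `peak_cM` bounds).
#' @param sd_min floor on sd in Mb, default 0.01.
#' @return data.frame: qtl_id, trait_code, chrom, position_mb, sd_mb,
#'   lod, pve_percent, width_imputed.
#' @export
build_observations <- function(projected, qtls = NULL, sd_min = 0.01) {
  rec <- projected[projected$status == "projected", , drop = FALSE]
  width <- (rec$end_bp - rec$start_bp) / 1e6
  pos <- (rec$start_bp + rec$end_bp) / 2 / 1e6
  if (!is.null(qtls)) {
    m <- match(rec$qtl_id, qtls$qtl_id)
    peak <- qtls$peak_cM[m]
    lo <- qtls$ci_start_cM[m]
    hi <- qtls$ci_end_cM[m]
    use <- !is.na(peak) & !is.na(lo) & !is.na(hi) & hi > lo
    frac <- (peak[use] - lo[use]) / (hi[use] - lo[use])
    pos[use] <- rec$start_bp[use] / 1e6 + frac * width[use]
  }
  # impute missing/zero widths from the trait x chromosome median
  imputed <- !is.finite(width) | width <= 0
  if (any(imputed)) {
    key <- paste(rec$trait_code, rec$chrom, sep = "\r")
    med <- tapply(width[!imputed], key[!imputed], stats::median)
    width[imputed] <- med[key[imputed]]
    width[!is.finite(width) | width <= 0] <- 3.92 * sd_min
  }
  data.frame(qtl_id = rec$qtl_id,
             trait_code = rec$trait_code,
             chrom = rec$chrom,
             position_mb = pos,
             sd_mb = ci_to_sd(width, sd_min = sd_min),
             lod = rec$lod,
             pve_percent = rec$pve_percent,
             width_imputed = imputed,
             stringsAsFactors = FALSE)
}

#' Identify meta-QTLs across all trait x chromosome groups
#'
#' For every (trait_code, chromosome) with at least `min_members`
#' observations: [select_K()] chooses the number of consensus loci by AIC,
#' members are MAP-assigned to loci, and each locus with at least one member
#' gets an inverse-variance [consensus()] position and 95% interval (clamped
#' to the chromosome). Meta-QTLs are named
#' `MQTL-<trait><chromosome number>.<rank>` with ranks by ascending
#' consensus position. Loci with a single member are kept but flagged
#' `singleton` (set `drop_singletons = TRUE` to drop them).
#'
#' @param projected projected QTLs ([project_qtls()] output, after
#'   [quarter_filter()]).
#' @param chroms `chrom_table`.
#' @param qtls optional matching `qtl_table` for peak placement.
#' @param k_max largest number of components per group, default 5.
#' @param min_members minimum observations per group, default 2 (a
#'   meta-analysis needs replication).
#' @param sd_min sd floor in Mb.
#' @param n_restarts,seed EM restart policy (see [fit_em()]).
#' @param drop_singletons drop consensus loci with a single member.
#' @return list of class `metaqtl_result`: `mqtl` (one row per meta-QTL:
#'   mqtl_id, trait_code, chrom, n_members, consensus_position_mb,
#'   consensus_sd_mb, ci95_start_mb, ci95_end_mb, ci95_width_mb, model_K,
#'   model_aic, singleton, member_ids), `members` (per-observation
#'   assignment), `models` (named list of AIC traces per group).
#' @export
run_metaqtl <- function(projected, chroms, qtls = NULL, k_max = 5L,
                        min_members = 2L, sd_min = 0.01, n_restarts = 10L,
                        seed = 17L, drop_singletons = FALSE) {
  obs <- build_observations(projected, qtls, sd_min = sd_min)
  mqtl_rows <- list()
  member_rows <- list()
  models <- list()
  key <- paste(obs$trait_code, obs$chrom, sep = "\r")
  for (k in sort(unique(key))) {
    grp <- obs[key == k, , drop = FALSE]
    if (nrow(grp) < min_members) next
    trait <- grp$trait_code[1L]
    chrom <- grp$chrom[1L]
    model <- select_K(grp$position_mb, grp$sd_mb, K_max = k_max,
                      n_restarts = n_restarts,
                      seed = .child_seed(seed, paste(trait, chrom)))
    assign <- map_assign(grp$position_mb, grp$sd_mb, model)
    models[[paste(trait, chrom, sep = "_")]] <- attr(model, "trace")
    comp_ids <- sort(unique(assign))
    cons <- lapply(comp_ids, function(c) {
      sel <- assign == c
      consensus(grp$position_mb[sel], grp$sd_mb[sel])
    })
    ord <- order(vapply(cons, `[[`, 0, "position"))
    chrom_no <- .chrom_number(chrom)
    chrom_tag <- if (is.na(chrom_no)) chrom else chrom_no
    chrom_len_mb <- as.numeric(chroms[[chrom]]) / 1e6
    for (r in seq_along(ord)) {
      c_id <- comp_ids[ord[r]]
      sel <- assign == c_id
      cs <- cons[[ord[r]]]
      member <- grp[sel, , drop = FALSE]
      mqtl_id <- sprintf("MQTL-%s%s.%d", trait, chrom_tag, r)
      mqtl_rows[[length(mqtl_rows) + 1L]] <- data.frame(
        mqtl_id = mqtl_id, trait_code = trait, chrom = chrom,
        n_members = nrow(member),
        consensus_position_mb = cs$position,
        consensus_sd_mb = cs$sd,
        ci95_start_mb = max(0, cs$ci95_start),
        ci95_end_mb = min(chrom_len_mb, cs$ci95_end),
        model_K = model$K,
        model_aic = model$aic,
        singleton = nrow(member) == 1L,
        member_ids = paste(member$qtl_id, collapse = ","),
        stringsAsFactors = FALSE
      )
      member_rows[[length(member_rows) + 1L]] <- data.frame(
        mqtl_id = mqtl_id, qtl_id = member$qtl_id,
        position_mb = member$position_mb, sd_mb = member$sd_mb,
        stringsAsFactors = FALSE
      )
    }
  }
  mqtl <- if (length(mqtl_rows)) do.call(rbind, mqtl_rows) else
    data.frame(mqtl_id = character(), trait_code = character(),
               chrom = character(), n_members = integer(),
               consensus_position_mb = numeric(), consensus_sd_mb = numeric(),
               ci95_start_mb = numeric(), ci95_end_mb = numeric(),
               model_K = integer(), model_aic = numeric(),
               singleton = logical(), member_ids = character(),
               stringsAsFactors = FALSE)
  if (drop_singletons) mqtl <- mqtl[!mqtl$singleton, , drop = FALSE]
  mqtl$ci95_width_mb <- mqtl$ci95_end_mb - mqtl$ci95_start_mb
  members <- if (length(member_rows)) do.call(rbind, member_rows) else
    data.frame(mqtl_id = character(), qtl_id = character(),
               position_mb = numeric(), sd_mb = numeric(),
               stringsAsFactors = FALSE)
  if (drop_singletons) members <- members[members$mqtl_id %in% mqtl$mqtl_id, ,
                                          drop = FALSE]
  rownames(mqtl) <- rownames(members) <- NULL
  structure(list(mqtl = mqtl, members = members, models = models,
                 observations = obs),
            class = "metaqtl_result")
}

#' @export
print.metaqtl_result <- function(x, ...) {
  cat(sprintf("metaqtl_result: %d meta-QTL(s) from %d observation(s) in %d group(s)\n",
              nrow(x$mqtl), nrow(x$observations), length(x$models)))
  if (nrow(x$mqtl)) {
    print(x$mqtl[, c("mqtl_id", "n_members", "consensus_position_mb",
                     "ci95_start_mb", "ci95_end_mb", "model_K")], ...)
  }
  invisible(x)
}
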