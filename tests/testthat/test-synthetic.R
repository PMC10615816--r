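test_that("truth simulation is deterministic and respects separation", {
  cfg <- sim_config()
  t1 <- simulate_truth(cfg, seed = 17)
  t2 <- simulate_truth(cfg, seed = 17)
  expect_identical(t1, t2)
  t3 <- simulate_truth(cfg, seed = 18)
  expect_false(identical(t1$loci$position_bp, t3$loci$position_bp))

  # all pairwise same-group distances >= 8 Mb (brute-force pairwise check)
  cfg3 <- sim_config(loci = data.frame(trait_code = "FSI", chrom = "chr01",
                                       n_loci = 3L))
  tr <- simulate_truth(cfg3, seed = 9)
  pos <- tr$loci$position_bp
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(abs(pos[i] - pos[j]), 8e6)
  }
  # positions stay inside the chromosome margins
  expect_true(all(pos >= cfg3$margin_bp))
  expect_true(all(pos <= tr$chrom_lengths[["chr01"]] - cfg3$margin_bp))

  # infeasible separation errors out
  bad <- sim_config(loci = data.frame(trait_code = "FSI", chrom = "chr12",
                                      n_loci = 4L), min_sep_bp = 2e7)
  expect_error(simulate_truth(bad, seed = 1), "cannot place")
})

test_that("study tables follow the stated CI-width and LOD identities", {
  cfg <- sim_config(loci = data.frame(trait_code = "FSI", chrom = "chr01",
                                      n_loci = 1L),
                    n_studies = 1L, pop_size_range = c(100L, 100L),
                    pve_range = c(0.05, 0.05), pve_jitter = 0,
                    detect_prob = 1, noise_mode = "none")
  qtls <- simulate_studies(simulate_truth(cfg, seed = 2))
  expect_equal(nrow(qtls), 1L)
  # CI width 530 / (100 * 5) = 1.06 cM (up to 1-bp rounding of the interval)
  expect_equal(qtls$ci_end_cM - qtls$ci_start_cM, 1.06,
               tolerance = 1e-5)
  # LOD = -(N/2) log10(1 - PVE)
  expect_equal(qtls$lod, -50 * log10(1 - 0.05))
  expect_equal(qtls$pve_percent, 5)

  # the worked identity at PVE = 24.2%
  cfg2 <- sim_config(loci = data.frame(trait_code = "FSI", chrom = "chr01",
                                       n_loci = 1L),
                     n_studies = 1L, pop_size_range = c(100L, 100L),
                     pve_range = c(0.242, 0.242), pve_jitter = 0,
                     detect_prob = 1, noise_mode = "none")
  q2 <- simulate_studies(simulate_truth(cfg2, seed = 2))
  expect_equal(q2$lod, -50 * log10(0.758), tolerance = 1e-6)
  expect_equal(round(q2$lod, 1), 6.0)

  # detection probability zero -> empty table
  cfg0 <- sim_config(detect_prob = 0)
  expect_equal(nrow(simulate_studies(simulate_truth(cfg0, seed = 2))), 0L)
})

test_that("simulated tables always pass their own schema validation", {
  for (seed in c(1, 7, 2026)) {
    tab <- simulate_studies(simulate_truth(sim_config(), seed = seed))
    expect_equal(nrow(attr(tab, "rejected")), 0L)
    expect_true(all(tab$ci_start_cM <= tab$peak_cM))
    expect_true(all(tab$peak_cM <= tab$ci_end_cM))
  }
})

test_that("PAF corruption modes hit exactly the intended failure paths", {
  truth <- simulate_truth(sim_config(n_studies = 5L), seed = 31)
  qtls <- simulate_studies(truth)
  ids <- qtls$qtl_id
  k <- 4L
  paf <- emit_synthetic_paf(truth, qtls,
                            drop_right = ids[1],
                            drop_left = ids[2],
                            cross_chrom = ids[3:(2 + k)])
  proj <- project_qtls(qtls, paf, truth$chrom_lengths)
  expect_equal(sum(proj$status == "failed_flank_missing"), 2L)
  expect_equal(sum(proj$status == "failed_cross_chrom"), k)
  expect_equal(sum(proj$status == "projected"), nrow(qtls) - 2L - k)
})

test_that("recovery scoring matches hand-computable cases", {
  truth <- simulate_truth(sim_config(loci = data.frame(
    trait_code = "FSI", chrom = "chr01", n_loci = 1L)), seed = 13)
  pos_mb <- truth$loci$position_bp / 1e6
  mk_mqtl <- function(position) data.frame(
    mqtl_id = "MQTL-FSI1.1", trait_code = "FSI", chrom = "chr01",
    n_members = 3L, consensus_position_mb = position,
    consensus_sd_mb = 0.2, ci95_start_mb = position - 0.392,
    ci95_end_mb = position + 0.392, model_K = 1L, model_aic = 0,
    singleton = FALSE, member_ids = "a,b,c", ci95_width_mb = 0.784,
    stringsAsFactors = FALSE)

  # exact recovery
  r0 <- score_recovery(truth, mk_mqtl(pos_mb))
  expect_equal(r0$position_rmse_mb, 0)
  expect_equal(r0$ci_coverage, 1.0)

  # displaced by 1 Mb: still matched (cap 2 Mb), RMSE 1, outside the CI
  r1 <- score_recovery(truth, mk_mqtl(pos_mb + 1))
  expect_equal(r1$position_rmse_mb, 1.0)
  expect_equal(r1$ci_coverage, 0)
  expect_equal(r1$n_matched, 1L)

  # displaced beyond the cap: unmatched on both sides
  r3 <- score_recovery(truth, mk_mqtl(pos_mb + 3))
  expect_equal(r3$n_matched, 0L)
  expect_equal(r3$n_true_unmatched, 1L)
  expect_equal(r3$n_mqtl_unmatched, 1L)
  expect_equal(r3$ci_coverage, 0)

  # no MQTLs at all
  rn <- score_recovery(truth, mk_mqtl(pos_mb)[0, ])
  expect_equal(rn$n_matched, 0L)
  expect_equal(rn$n_true_unmatched, 1L)
})

test_that("the full simulate-project-meta chain is seed-deterministic", {
  run_once <- function() {
    cfg <- sim_config(n_studies = 6L)
    truth <- simulate_truth(cfg, seed = 99)
    qtls <- simulate_studies(truth)
    paf <- emit_synthetic_paf(truth, qtls)
    proj <- rename_qtls(quarter_filter(
      project_qtls(qtls, paf, truth$chrom_lengths), truth$chrom_lengths))
    run_metaqtl(proj, truth$chrom_lengths, qtls = qtls, seed = 99)$mqtl
  }
  expect_identical(run_once(), run_once())
})
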