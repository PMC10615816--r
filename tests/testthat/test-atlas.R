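test_that("summary means skip missing values and report denominators", {
  chroms <- toy_chroms()
  proj <- proj_table(
    proj_row("a", "chrT", 0, 10, pve_percent = 10, lod = 4),
    proj_row("b", "chrT", 0, 10, pve_percent = 20, lod = 5),
    proj_row("c", "chrT", 0, 10)       # missing PVE and LOD
  )
  s <- chromosome_summary(proj, chroms)
  expect_equal(s$global$mean_pve, 15)
  expect_equal(s$global$n_pve, 2L)
  expect_equal(s$global$mean_lod, 4.5)
  expect_equal(s$global$n_lod, 2L)
  per <- s$per_chromosome
  # empty chromosomes appear with count 0 and NA means
  expect_equal(per$n_qtl[per$chrom == "chr01"], 0L)
  expect_true(is.na(per$mean_pve[per$chrom == "chr01"]))
  expect_equal(per$n_qtl[per$chrom == "chrT"], 3L)
})

test_that("cluster rule: six midpoints in a window qualify, five do not", {
  mk <- function(mids, ids) {
    do.call(rbind, lapply(seq_along(mids), function(i) {
      proj_row(ids[i], "chrT", mids[i] - 50, mids[i] + 50)
    }))
  }
  # 6 midpoints within 4.9 Mb -> one cluster of 6
  six <- mk(seq(1e6, 5.9e6, length.out = 6), sprintf("a%d", 1:6))
  cl <- detect_clusters(six)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 6L)
  # 5 midpoints within 1 Mb -> no cluster (strictly more than five)
  five <- mk(seq(1e6, 2e6, length.out = 5), sprintf("b%d", 1:5))
  expect_equal(nrow(detect_clusters(five)), 0L)
})

test_that("overlapping candidate windows merge; members match brute-force scan", {
  # 12 midpoints spanning 9 Mb: two overlapping 5-Mb windows of >= 6 each
  mids <- seq(1e6, 10e6, length.out = 12)
  proj <- do.call(rbind, lapply(seq_along(mids), function(i) {
    proj_row(sprintf("m%d", i), "chrT", mids[i] - 50, mids[i] + 50)
  }))
  cl <- detect_clusters(proj)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 12L)
  # oracle: brute-force scan over all 5-Mb windows
  expect_equal(sort(mids[mids >= cl$window_start_bp &
                           mids <= cl$window_end_bp]),
               brute_cluster_members(mids, 5e6, 6))

  # randomized agreement with the brute-force oracle
  set.seed(42)
  for (rep in 1:20) {
    m <- sort(round(runif(25, 0, 3e7)))
    p <- do.call(rbind, lapply(seq_along(m), function(i) {
      proj_row(sprintf("r%d", i), "chrT", m[i] - 10, m[i] + 10)
    }))
    got <- detect_clusters(p)
    got_members <- sort(unlist(lapply(seq_len(nrow(got)), function(i) {
      m[m >= got$window_start_bp[i] & m <= got$window_end_bp[i]]
    })))
    expect_equal(got_members, brute_cluster_members(m, 5e6, 6))
  }

  # degenerate completeness: min_count = 1 covers every QTL
  all_cl <- detect_clusters(proj, min_count = 1L)
  covered <- unlist(strsplit(all_cl$member_ids, ","))
  expect_setequal(covered, proj$qtl_id)
})

test_that("same-trait overlap groups use single linkage across studies", {
  # chain A-B-C from three studies: A and C do not touch but join via B
  chain <- proj_table(
    proj_row("A", "chrT", 0e6, 2e6, study_ref = "r1"),
    proj_row("B", "chrT", 1e6, 4e6, study_ref = "r2"),
    proj_row("C", "chrT", 3e6, 6e6, study_ref = "r3")
  )
  g <- group_overlaps(chain)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_members, 3L)
  expect_equal(g$n_studies, 3L)
  expect_equal(g$merged_start_bp, 0)
  expect_equal(g$merged_end_bp, 6e6)
  # oracle: brute-force connected components
  comp <- brute_components(chain$start_bp, chain$end_bp)
  expect_equal(length(unique(comp)), 1L)

  # two disjoint same-trait intervals -> no overlapped QTL
  disjoint <- proj_table(
    proj_row("A", "chrT", 0e6, 1e6, study_ref = "r1"),
    proj_row("B", "chrT", 5e6, 6e6, study_ref = "r2")
  )
  expect_equal(nrow(group_overlaps(disjoint)), 0L)

  # overlap within a single study is not an overlapped QTL
  same_study <- proj_table(
    proj_row("A", "chrT", 0e6, 2e6, study_ref = "r1"),
    proj_row("B", "chrT", 1e6, 3e6, study_ref = "r1")
  )
  expect_equal(nrow(group_overlaps(same_study)), 0L)
})

test_that("overlap grouping is permutation-invariant and respects extents", {
  set.seed(7)
  n <- 30
  proj <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- runif(1, 0, 3e7)
    proj_row(sprintf("q%d", i), "chrT", s, s + runif(1, 1e5, 5e6),
             trait_code = sample(c("FSI", "FW"), 1),
             study_ref = sprintf("r%d", sample(8, 1)))
  }))
  g1 <- group_overlaps(proj)
  g2 <- group_overlaps(proj[sample(n), ])
  expect_equal(g1, g2)
  # merged extent at least as long as the longest member
  for (i in seq_len(nrow(g1))) {
    ids <- strsplit(g1$member_ids[i], ",")[[1]]
    memb <- proj[proj$qtl_id %in% ids, ]
    expect_gte(g1$merged_end_bp[i] - g1$merged_start_bp[i],
               max(memb$end_bp - memb$start_bp))
    # no member appears twice in one group
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("co-localization uses common-intersection semantics", {
  # FW [10,20) and FSI [15,25) -> one group with intersection [15,20)
  two <- proj_table(
    proj_row("fw1", "chrT", 10e6, 20e6, trait_code = "FW"),
    proj_row("fsi1", "chrT", 15e6, 25e6, trait_code = "FSI")
  )
  g <- detect_colocalizations(two)
  expect_equal(nrow(g), 1L)
  expect_equal(g$intersection_start_bp, 15e6)
  expect_equal(g$intersection_end_bp, 20e6)

  # same-trait overlaps alone never co-localize
  same <- proj_table(
    proj_row("a", "chrT", 10e6, 20e6),
    proj_row("b", "chrT", 15e6, 25e6)
  )
  expect_equal(nrow(detect_colocalizations(same)), 0L)

  # chain of three traits where the ends do not meet -> two groups
  chain <- proj_table(
    proj_row("a", "chrT", 0e6, 10e6, trait_code = "FW"),
    proj_row("b", "chrT", 8e6, 20e6, trait_code = "FSI"),
    proj_row("c", "chrT", 18e6, 30e6, trait_code = "TSS")
  )
  g3 <- detect_colocalizations(chain)
  expect_equal(nrow(g3), 2L)
  expect_equal(g3$intersection_start_bp, c(8e6, 18e6))
  expect_equal(g3$intersection_end_bp, c(10e6, 20e6))
  # oracle: exhaustive subset enumeration
  oracle <- brute_coloc_groups(chain$start_bp, chain$end_bp, chain$trait_code)
  got <- lapply(strsplit(g3$member_ids, ","), function(ids)
    sort(match(ids, chain$qtl_id)))
  expect_setequal(lapply(oracle, sort), got)
})

test_that("co-localization groups match the subset oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    s <- runif(n, 0, 2e7)
    proj <- do.call(rbind, lapply(seq_len(n), function(i) {
      proj_row(sprintf("q%d", i), "chrT", s[i], s[i] + runif(1, 1e6, 8e6),
               trait_code = sample(c("FW", "FSI", "TSS"), 1))
    }))
    g <- detect_colocalizations(proj)
    got <- lapply(strsplit(g$member_ids, ","), function(ids)
      sort(match(ids, proj$qtl_id)))
    oracle <- brute_coloc_groups(proj$start_bp, proj$end_bp, proj$trait_code)
    expect_setequal(lapply(oracle, sort), got)
    # intersection never longer than the shortest member
    for (i in seq_len(nrow(g))) {
      memb <- proj[proj$qtl_id %in% strsplit(g$member_ids[i], ",")[[1]], ]
      expect_lte(g$intersection_end_bp[i] - g$intersection_start_bp[i],
                 min(memb$end_bp - memb$start_bp))
    }
  }
})
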