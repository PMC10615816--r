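test_that("a well-formed table ingests with correct group counts", {
  raw <- raw_qtl_rows(
    list(qtl_id = "q1", trait_group = "fruit"),
    list(qtl_id = "q2", trait_group = "fruit", trait_code = "FW"),
    list(qtl_id = "q3", trait_group = "seed", trait_code = "SW")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_qtl_table(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(nrow(attr(tab, "rejected")), 0L)
  gc <- attr(tab, "group_counts")
  expect_equal(gc[["fruit"]], 2L)
  expect_equal(gc[["seed"]], 1L)
  # group counts agree with an independent column count
  expect_equal(unname(gc[TRAIT_GROUPS]),
               as.integer(table(factor(raw$trait_group, TRAIT_GROUPS))))
})

test_that("invalid rows are rejected with reasons, never silently dropped", {
  raw <- raw_qtl_rows(
    list(qtl_id = "ok"),
    list(qtl_id = "rev", ci_start_cM = "12.0", ci_end_cM = "5.0"),
    list(qtl_id = "dup"), list(qtl_id = "dup"),
    list(qtl_id = "badgrp", trait_group = "mineral"),
    list(qtl_id = "badlod", lod = "not-a-number"),
    list(qtl_id = "badpve", pve_percent = "150"),
    list(qtl_id = "peakout", peak_cM = "99", ci_start_cM = "0", ci_end_cM = "10")
  )
  tab <- validate_qtl_table(raw)
  rej <- attr(tab, "rejected")
  expect_equal(nrow(tab) + nrow(rej), nrow(raw))
  expect_equal(tab$qtl_id, "ok")
  expect_setequal(rej$reason[rej$qtl_id == "rev"], "interval reversed")
  expect_equal(sum(rej$reason == "duplicate qtl_id"), 2L)
  expect_true("unknown trait_group" %in% rej$reason)
  expect_true("non-numeric LOD" %in% rej$reason)
  expect_true("PVE outside (0,100]" %in% rej$reason)
  expect_true("peak outside interval" %in% rej$reason)
})

test_that("a missing required column is a schema error naming the column", {
  raw <- raw_qtl_rows(list(qtl_id = "q1"))
  raw$trait_code <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_qtl_table(path), "trait_code")
})

test_that("column mapping ingests an external layout", {
  raw <- raw_qtl_rows(list(qtl_id = "q1"))
  names(raw)[names(raw) == "qtl_id"] <- "QTL name"
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_qtl_table(path, col_map = c(qtl_id = "QTL name"))
  expect_equal(tab$qtl_id, "q1")
})

test_that("write -> read is the identity on valid QTL tables", {
  cfg <- sim_config(n_studies = 4L)
  tab <- simulate_studies(simulate_truth(cfg, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_table(tab, path)
  back <- read_qtl_table(path)
  expect_equal(nrow(back), nrow(tab))
  for (col in names(tab)) {
    if (is.numeric(tab[[col]])) {
      expect_equal(back[[col]], tab[[col]], tolerance = 1e-12, info = col)
    } else {
      expect_equal(back[[col]], tab[[col]], info = col)
    }
  }
})

test_that("chromosome tables parse, validate and round-trip", {
  path <- withr::local_tempfile()
  writeLines("chrT\t40000000", path)
  expect_equal(unclass(read_chrom_table(path))[["chrT"]], 40000000)

  writeLines(c("chr01\t100", "chr01\t200"), path)
  expect_error(read_chrom_table(path), "duplicate")

  writeLines("chr01\t-5", path)
  expect_error(read_chrom_table(path), "positive")

  # a 12-chromosome toy genome sums to its stated total
  chroms <- sim_config()$chrom_lengths
  expect_equal(sum(chroms), 379200000)
  write_chrom_table(chroms, path)
  back <- read_chrom_table(path)
  expect_equal(unclass(back), unclass(chroms))
})

test_that("BED6 output follows the format rule and round-trips", {
  chroms <- toy_chroms()
  proj <- proj_table(
    proj_row("q1", "chrT", 100, 900, lod = 6.0)
  )
  proj$renamed_id <- "FSI1.1"
  path <- withr::local_tempfile(fileext = ".bed")
  write_projected_bed(proj, path, chroms)
  expect_equal(readLines(path)[2], "chrT\t100\t900\tFSI1.1\t60\t.")

  # empty input -> header-only file
  write_projected_bed(proj[0, ], path, chroms)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_true(startsWith(lines, "#"))

  # round-trip preserves coordinates exactly, sorted by (chrom order, start)
  proj2 <- proj_table(
    proj_row("b", "chr01", 5000, 9000),
    proj_row("a", "chrT", 200, 700, lod = 3.14),
    proj_row("c", "chrT", 100, 900)
  )
  write_projected_bed(proj2, path, chroms)
  back <- read_projected_bed(path)
  expect_equal(back$name, c("c", "a", "b"))
  expect_equal(back$start_bp, c(100, 200, 5000))
  expect_equal(back$end_bp, c(900, 700, 9000))
  expect_equal(back$score, c(0L, 31L, 0L))

  # unknown chromosome is an error
  proj3 <- proj_row("x", "chrUnknown", 1, 2)
  expect_error(write_projected_bed(proj3, path, chroms), "unknown chromosome")
})
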