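# In-code fixtures shared across test files. Everything is built
# programmatically; no binary data.

toy_chroms <- function() {
  melonmeta::chrom_table(c(chrT = 40000000, chr01 = 38000000, chr02 = 35000000))
}

# A minimal well-formed raw QTL table (character columns, as read from disk).
raw_qtl_rows <- function(...) {
  rows <- list(...)
  base <- list(qtl_id = "q1", study_ref = "ref1", trait_code = "FSI",
               trait_group = "fruit", linkage_group = "LG1",
               peak_cM = "", ci_start_cM = "0", ci_end_cM = "10",
               lod = "", pve_percent = "", pop_type = "F2", pop_size = "",
               parents = "", source_genome = "")
  do.call(rbind, lapply(rows, function(r) {
    row <- utils::modifyList(base, as.list(r))
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
}

# One PAF row in the parse_paf() layout.
paf_row <- function(query_name, target_name, target_start, target_end,
                    strand = "+", mapq = 60, is_primary = TRUE,
                    query_len = 1000, target_len = 40000000,
                    aln_len = NULL, n_matches = NULL) {
  aln_len <- if (is.null(aln_len)) target_end - target_start else aln_len
  n_matches <- if (is.null(n_matches)) aln_len else n_matches
  data.frame(query_name = query_name, query_len = query_len,
             query_start = 0, query_end = query_len, strand = strand,
             target_name = target_name, target_len = target_len,
             target_start = target_start, target_end = target_end,
             n_matches = n_matches, aln_len = aln_len, mapq = mapq,
             is_primary = is_primary, stringsAsFactors = FALSE)
}

# A projected-QTL data.frame row (post-projection layout).
proj_row <- function(qtl_id, chrom, start_bp, end_bp, trait_code = "FSI",
                     study_ref = "ref1", status = "projected",
                     lod = NA_real_, pve_percent = NA_real_) {
  data.frame(qtl_id = qtl_id, chrom = chrom, start_bp = start_bp,
             end_bp = end_bp, status = status, renamed_id = "",
             trait_code = trait_code, trait_group = "fruit",
             study_ref = study_ref, lod = lod, pve_percent = pve_percent,
             stringsAsFactors = FALSE)
}

proj_table <- function(...) do.call(rbind, list(...))
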