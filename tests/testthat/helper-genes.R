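# Shared builders for small synthetic gene models.

# A gene with `n_exons` 100 bp exons spaced 1 kb apart starting at `base`,
# one transcript per tpm value; transcript k uses exons k..n_exons so the
# first transcript always spans the gene.
make_gene <- function(gene_id = "G1", chrom = "chr1", base = 10000,
                      tpms = 100, n_exons = 5, disease_group = "RP",
                      modes = c("AD", "AR")) {
  exons <- data.frame(start = base + (seq_len(n_exons) - 1) * 1000,
                      end = base + (seq_len(n_exons) - 1) * 1000 + 99)
  txs <- lapply(seq_along(tpms), function(k) {
    transcript_model(sprintf("%s_T%d", gene_id, k), gene_id, "+",
                     exons[k:n_exons, , drop = FALSE], tpms[k])
  })
  gene_model(gene_id, paste0("SYM", gene_id), chrom, txs,
             disease_group = disease_group, inheritance_modes = modes)
}

# A gene whose two transcripts occupy disjoint exon sets: transcript 1
# (tpm1) uses the first exons, transcript 2 (tpm2) a private tail exon.
make_two_isoform_gene <- function(gene_id = "G1", chrom = "chr1",
                                  base = 10000, tpm_main = 100,
                                  tpm_minor = 1, modes = c("AD", "AR")) {
  main <- data.frame(start = base + c(0, 1000, 2000),
                     end = base + c(99, 1099, 2099))
  tail <- data.frame(start = base + 5000, end = base + 5099)
  gene_model(gene_id, paste0("SYM", gene_id), chrom,
             list(transcript_model(paste0(gene_id, "_T1"), gene_id, "+",
                                   main, tpm_main),
                  transcript_model(paste0(gene_id, "_T2"), gene_id, "+",
                                   tail, tpm_minor)),
             disease_group = "RP", inheritance_modes = modes)
}

# trio pedigree: unaffected parents, one affected child
make_trio <- function(fid = "FAM1", child_sex = "M", extra = NULL) {
  df <- data.frame(
    family_id = fid,
    id = paste0(fid, c("_F", "_M", "_C")),
    father = c(NA, NA, paste0(fid, "_F")),
    mother = c(NA, NA, paste0(fid, "_M")),
    sex = c("M", "F", child_sex),
    affected = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  pedigree(df)
}
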