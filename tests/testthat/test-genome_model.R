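test_that("overlap_bp handles identity, partial overlap and chrom mismatch", {
  a <- genomic_interval("chr1", 100, 199)
  expect_equal(overlap_bp(a, a), 100)
  expect_equal(overlap_bp(a, genomic_interval("chr1", 150, 249)), 50)
  expect_equal(overlap_bp(a, genomic_interval("chr2", 100, 199)), 0)
  expect_equal(overlap_bp(a, genomic_interval("chr1", 200, 300)), 0)
  expect_equal(overlap_bp(a, genomic_interval("chr1", 199, 300)), 1)
  expect_error(genomic_interval("chr1", 200, 100), "malformed")
})

test_that("overlap_bp is symmetric, bounded, and matches a counting oracle", {
  set.seed(11)
  for (i in 1:200) {
    s1 <- sample(1:500, 1); e1 <- s1 + sample(0:300, 1)
    s2 <- sample(1:500, 1); e2 <- s2 + sample(0:300, 1)
    a <- genomic_interval("chr1", s1, e1)
    b <- genomic_interval("chr1", s2, e2)
    oracle <- length(intersect(seq(s1, e1), seq(s2, e2)))
    expect_equal(overlap_bp(a, b), oracle)
    expect_equal(overlap_bp(a, b), overlap_bp(b, a))
    expect_lte(overlap_bp(a, b), min(interval_length(a), interval_length(b)))
  }
})

test_that("distance_to_nearest_exon matches brute-force scan and paper-style offsets", {
  g <- make_gene(base = 10000, tpms = c(50, 5), n_exons = 4)
  # brute force: min distance to any exon of any transcript, 0 if inside
  brute <- function(pos) {
    d <- Inf
    for (tx in g$transcripts) for (i in seq_len(nrow(tx$exons))) {
      s <- tx$exons$start[i]; e <- tx$exons$end[i]
      d <- min(d, if (pos >= s && pos <= e) 0 else min(abs(pos - s), abs(pos - e)))
    }
    d
  }
  span <- gene_span(g)
  set.seed(7)
  for (pos in sample(span$start:span$end, 300))
    expect_equal(distance_to_nearest_exon(pos, g), brute(pos), info = pos)
  expect_equal(distance_to_nearest_exon(10000, g), 0)     # exon start
  expect_equal(distance_to_nearest_exon(11099 + 11, g), 11)   # c.X-11 style
  expect_error(distance_to_nearest_exon(span$end + 1, g), "not intronic")

  # deep-intronic offset: 20231 bp downstream of a donor
  big <- gene_model("GBIG", "GBIG", "chr6",
                    list(transcript_model("T1", "GBIG", "+",
                                          data.frame(start = c(1000, 50000),
                                                     end = c(1100, 50100)), 10)))
  expect_equal(distance_to_nearest_exon(1100 + 20231, big), 20231)
})

test_that("spans_whole_gene is boundary-inclusive", {
  g <- make_gene(base = 10000, n_exons = 3)   # span 10000-12099
  expect_true(spans_whole_gene(genomic_interval("chr1", 10000, 12099), g))
  expect_true(spans_whole_gene(genomic_interval("chr1", 9000, 13000), g))
  expect_false(spans_whole_gene(genomic_interval("chr1", 10990, 11110), g))
  expect_false(spans_whole_gene(genomic_interval("chr1", 10001, 12099), g))
  expect_false(spans_whole_gene(genomic_interval("chr2", 10000, 12099), g))
})

test_that("parse_position accepts printed styles including the chrX- typo", {
  iv <- parse_position("chr20:25313454-25555587")
  expect_equal(c(iv$chrom, iv$start, iv$end),
               c("chr20", 25313454, 25555587))
  typo <- parse_position("chrX-18644599-18650206")
  expect_equal(c(typo$chrom, typo$start, typo$end),
               c("chrX", 18644599, 18650206))
  endash <- parse_position("chr4:633534–637421")
  expect_equal(endash$start, 633534)
  single <- parse_position("chr6:63964152")
  expect_equal(single$start, single$end)
  expect_error(parse_position("banana"), "cannot parse")
})

test_that("chrom normalization and BED converters round-trip", {
  expect_equal(normalize_chrom(c("1", "chrX", "chrx", "MT")),
               c("chr1", "chrX", "chrX", "chrM"))
  iv <- genomic_interval("chr1", 101, 200)
  bed <- interval_to_bed(iv)
  expect_equal(c(bed$start, bed$end), c(100, 200))
  back <- bed_to_interval(bed$chrom, bed$start, bed$end)
  expect_equal(c(back$start, back$end), c(iv$start, iv$end))
})

test_that("load_gene_models attaches TPMs, defaults missing ones, skips absent genes", {
  genes <- structure(list(
    A = make_gene("A", "chr1", 10000, tpms = c(30, 3)),
    B = make_gene("B", "chr2", 50000, tpms = 12),
    C = make_gene("C", "chr3", 90000, tpms = 7, disease_group = "CRD",
                  modes = "AD")),
    class = "gene_model_set")
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "g.gtf")
  write_gene_models_gtf(genes, gtf)
  write_panel_table(genes, file.path(dir, "panel.tsv"))
  # expression table missing transcript A_T2, plus a phantom panel gene
  expr <- data.frame(transcript_id = c("A_T1", "B_T1", "C_T1"),
                     tpm = c(30, 12, 7))
  write.table(expr, file.path(dir, "expr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  panel <- read.delim(file.path(dir, "panel.tsv"))
  panel <- rbind(panel, data.frame(symbol = "GHOST", gene_id = "Z",
                                   disease_group = "RP",
                                   inheritance_modes = "AR"))
  write.table(panel, file.path(dir, "panel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  expect_warning(
    expect_message(
      loaded <- load_gene_models(gtf, file.path(dir, "expr.tsv"),
                                 file.path(dir, "panel.tsv")),
      "absent from gene models"),
    "TPM set to 0")
  expect_equal(sort(names(loaded)), c("A", "B", "C"))
  expect_equal(attr(loaded, "skipped"), "Z")
  expect_equal(loaded$A$transcripts$A_T2$tpm, 0)
  expect_equal(loaded$A$transcripts$A_T1$tpm, 30)
  expect_equal(loaded$C$disease_group, "CRD")
  expect_equal(loaded$C$inheritance_modes, "AD")
  # structures survive the GTF round trip
  expect_equal(loaded$B$transcripts$B_T1$exons,
               genes$B$transcripts$B_T1$exons)
})

test_that("a generated 792-gene panel loads with 792 entries", {
  n <- 792
  genes <- lapply(seq_len(n), function(i)
    make_gene(sprintf("PG%03d", i), chrom = paste0("chr", 1 + i %% 22),
              base = 1e5 * i, tpms = 5, n_exons = 2))
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  class(genes) <- "gene_model_set"
  dir <- withr::local_tempdir()
  write_gene_models_gtf(genes, file.path(dir, "g.gtf"))
  write_expression_table(genes, file.path(dir, "expr.tsv"))
  write_panel_table(genes, file.path(dir, "panel.tsv"))
  loaded <- load_gene_models(file.path(dir, "g.gtf"),
                             file.path(dir, "expr.tsv"),
                             file.path(dir, "panel.tsv"))
  expect_length(loaded, 792)
})
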