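t0 <- threshold_config()

test_that("classify_snv matches an exhaustive rule-table oracle on a grid", {
  g <- make_gene(base = 100000, tpms = c(50, 5), n_exons = 4)
  # positions: inside exon, canonical (+1), non-canonical territory (+13),
  # deep intronic (+150 and +450)
  positions <- c(exonic = 100050, canonical = 100100, near = 100112,
                 deep1 = 100249, deep2 = 100549)
  grid <- expand.grid(
    term = c("stop_gained", "stop_lost", "frameshift_variant",
             "missense_variant", "intron_variant", "synonymous_variant"),
    pos_kind = names(positions),
    cadd = c(5, 25, NA), spliceai = c(0.1, 0.9, NA), eve = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  # oracle: an independent plain-R transcription of the category rules
  oracle <- function(term, dist, cadd, spliceai, eve) {
    gt <- function(x, c) !is.na(x) && x > c
    if (term == "stop_gained") return("stop_gain")
    if (term == "stop_lost") return("stop_loss")
    if (term == "frameshift_variant") return("frameshift")
    if (dist %in% c(1, 2))
      return(if (gt(spliceai, 0.5) || gt(cadd, 20)) "canonical_splice"
             else "not_pathogenic")
    if (term == "missense_variant")
      return(if (eve || gt(cadd, 20)) "missense_damaging" else "not_pathogenic")
    if (dist >= 100 && gt(spliceai, 0.5)) return("deep_intronic")
    if (dist >= 3 && dist < 100 && gt(spliceai, 0.5))
      return("non_canonical_splice")
    "not_pathogenic"
  }
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    pos <- positions[[row$pos_kind]]
    dist <- distance_to_nearest_exon(pos, g)
    # grid sanity: the intended territory is what the gene realizes
    expect_equal(dist, c(exonic = 0, canonical = 1, near = 13,
                         deep1 = 150, deep2 = 450)[[row$pos_kind]])
    got <- classify_snv(list(chrom = "chr1", pos = pos), g,
                        list(cadd = row$cadd, spliceai = row$spliceai,
                             eve_damaging = row$eve,
                             consequence_term = row$term), t0)
    expect_equal(got$category,
                 oracle(row$term, dist, row$cadd, row$spliceai, row$eve),
                 info = paste(unlist(row), collapse = "/"))
  }
})

test_that("classify_snv reproduces the published intronic worked examples", {
  big <- gene_model("EYSlike", "EYSlike", "chr6",
                    list(transcript_model("T1", "EYSlike", "+",
                                          data.frame(start = c(1000, 60000),
                                                     end = c(1100, 60100)), 10)))
  deep <- classify_snv(list(chrom = "chr6", pos = 1100 + 20231), big,
                       list(cadd = 3, spliceai = 0.9, eve_damaging = FALSE,
                            consequence_term = "intron_variant"), t0)
  expect_equal(deep$category, "deep_intronic")
  expect_equal(deep$evidence$distance, 20231)
  near <- classify_snv(list(chrom = "chr6", pos = 60000 - 13), big,
                       list(cadd = 3, spliceai = 0.8, eve_damaging = FALSE,
                            consequence_term = "intron_variant"), t0)
  expect_equal(near$category, "non_canonical_splice")
  expect_equal(near$evidence$distance, 13)
  # below both cutoffs
  dull <- classify_snv(list(chrom = "chr6", pos = 1050), big,
                       list(cadd = 19, spliceai = 0.1, eve_damaging = FALSE,
                            consequence_term = "missense_variant"), t0)
  expect_equal(dull$category, "not_pathogenic")
  # missing the only applicable score -> unscored
  unscored <- classify_snv(list(chrom = "chr6", pos = 1100 + 500), big,
                           list(cadd = NA, spliceai = NA,
                                eve_damaging = FALSE,
                                consequence_term = "intron_variant"), t0)
  expect_equal(unscored$category, "not_pathogenic")
  expect_equal(unscored$evidence$rule, "unscored")
})

test_that("classify_sv: DEL/DUP on exon overlap, INV must not span the gene", {
  g <- make_gene(base = 10000, n_exons = 3)   # span 10000-12099
  expect_equal(classify_sv(sv_record("DEL", "chr1", 10950, 11150), g)$category,
               "sv_del_dup_exonic")
  expect_equal(classify_sv(sv_record("DUP", "chr1", 10950, 11150), g)$category,
               "sv_del_dup_exonic")
  expect_equal(classify_sv(sv_record("DEL", "chr1", 10200, 10900), g)$category,
               "not_pathogenic")  # intronic SV
  expect_equal(classify_sv(sv_record("INV", "chr1", 10950, 11150), g)$category,
               "sv_inversion_exonic")
  expect_equal(classify_sv(sv_record("INV", "chr1", 9000, 13000), g)$category,
               "not_pathogenic")  # spans the whole gene
  # whole-gene DEL is still pathogenic
  expect_equal(classify_sv(sv_record("DEL", "chr1", 9000, 13000), g)$category,
               "sv_del_dup_exonic")
})

test_that("TDR reproduces the 0.43/361 TPM benign worked example", {
  g <- make_two_isoform_gene(tpm_main = 360.57, tpm_minor = 0.43)
  # SV hits only the minor isoform's private tail exon
  res <- transcript_disruption_ratio(sv_record("DEL", "chr1", 14990, 15120), g, t0)
  expect_equal(res$total_tpm_sum, 361)
  expect_equal(res$disrupted_tpm_sum, 0.43)
  expect_equal(res$ratio, 0.43 / 361, tolerance = 1e-12)
  expect_lt(res$ratio, 0.20)
  expect_equal(res$verdict, "exclude_benign")
  expect_equal(res$disrupted_transcript_ids, "G1_T2")
})

test_that("TDR extremes: no overlap -> 0/exclude, whole gene -> 1/retain, 0.20 retains", {
  g <- make_two_isoform_gene(tpm_main = 80, tpm_minor = 20)
  none <- transcript_disruption_ratio(sv_record("DEL", "chr1", 500, 900), g, t0)
  expect_equal(none$ratio, 0)
  expect_equal(none$verdict, "exclude_benign")
  span <- gene_span(g)
  whole <- transcript_disruption_ratio(
    sv_record("DEL", "chr1", span$start, span$end), g, t0)
  expect_equal(whole$ratio, 1)
  expect_equal(whole$verdict, "retain")
  # ratio exactly at the 20% threshold retains (exclusion is strictly below)
  boundary <- transcript_disruption_ratio(
    sv_record("DEL", "chr1", 14990, 15120), g, t0)
  expect_equal(boundary$ratio, 0.20)
  expect_equal(boundary$verdict, "retain")
  # unexpressed gene
  g0 <- make_two_isoform_gene(tpm_main = 0, tpm_minor = 0)
  expect_warning(z <- transcript_disruption_ratio(
    sv_record("DEL", "chr1", span$start, span$end), g0, t0), "unexpressed")
  expect_equal(z$ratio, 0)
  expect_equal(z$verdict, "exclude_benign")
})

test_that("inversion TDR rules: containment spares, internal breakpoint disrupts", {
  g <- make_two_isoform_gene(tpm_main = 90, tpm_minor = 10)
  # inversion containing the whole gene: nothing disrupted
  span <- gene_span(g)
  inv_all <- transcript_disruption_ratio(
    sv_record("INV", "chr1", span$start - 100, span$end + 100), g, t0)
  expect_equal(inv_all$ratio, 0)
  # inversion with one breakpoint inside the main transcript (no exon touch)
  inv_bp <- transcript_disruption_ratio(
    sv_record("INV", "chr1", 11500, 50000), g, t0)
  expect_true("G1_T1" %in% inv_bp$disrupted_transcript_ids)
  # the minor tail transcript (14990+) is fully contained -> spared
  expect_false("G1_T2" %in% inv_bp$disrupted_transcript_ids)
  expect_equal(inv_bp$ratio, 0.9)
})

test_that("TDR is monotone under SV containment; whole-gene deletions give 1", {
  set.seed(31)
  for (i in 1:60) {
    tpms <- runif(sample(1:3, 1), 0, 50)
    g <- make_gene("G", "chr1", base = 10000, tpms = tpms,
                   n_exons = sample(3:6, 1))
    span <- gene_span(g)
    s <- span$start + sample.int(span$end - span$start + 1, 1) - 1
    e <- s + sample.int(span$end - s + 1, 1) - 1
    small <- transcript_disruption_ratio(sv_record("DEL", "chr1", s, e), g, t0)
    big <- transcript_disruption_ratio(
      sv_record("DEL", "chr1", max(1, s - 500), e + 500), g, t0)
    expect_gte(big$ratio, small$ratio)
    expect_gte(small$ratio, 0); expect_lte(small$ratio, 1)
    if (sum(tpms) > 0) {
      whole <- transcript_disruption_ratio(
        sv_record("DEL", "chr1", span$start, span$end), g, t0)
      expect_equal(whole$ratio, 1)
    }
  }
})

test_that("sv_size_summary compares groups and rejects empty input", {
  path <- lapply(1:5, function(i) sv_record("DEL", "chr1", i * 1000, i * 1000 + 50000))
  bg <- lapply(1:5, function(i) sv_record("DEL", "chr1", i * 1000, i * 1000 + 999))
  res <- sv_size_summary(path, bg)
  expect_gt(res$pathogenic_median, res$comparison_median)
  expect_lt(res$p_value, 0.05)
  same <- sv_size_summary(path, path)
  # identical groups: rank-sum statistic sits at its null expectation
  expect_equal(same$statistic, length(path)^2 / 2)
  expect_equal(same$pathogenic_median, same$comparison_median)
  expect_error(sv_size_summary(path, list()), "non-empty")
})
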