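trio_ids <- function(fid = "FAM1") paste0(fid, c("_F", "_M", "_C"))

test_that("dominant check: de novo passes, unaffected carrier fails", {
  fam <- make_trio()
  ids <- trio_ids()
  denovo <- setNames(c("0/0", "0/0", "0/1"), ids)
  expect_true(check_dominant(denovo, fam)$pass)
  expect_equal(check_dominant(denovo, fam)$evidence, "full")
  carrier_father <- setNames(c("0/1", "0/0", "0/1"), ids)
  res <- check_dominant(carrier_father, fam)
  expect_false(res$pass)
  expect_equal(res$reason, "unaffected_carrier")
  # affected without the variant fails
  sibs <- data.frame(family_id = "FAM1", id = "FAM1_C2",
                     father = "FAM1_F", mother = "FAM1_M",
                     sex = "F", affected = TRUE)
  fam2 <- make_trio(extra = sibs)
  gt <- setNames(c("0/0", "0/0", "0/1", "0/0"), c(ids, "FAM1_C2"))
  expect_equal(check_dominant(gt, fam2)$reason, "affected_without_variant")
  # two affected sibs sharing the variant, absent in parents
  gt2 <- setNames(c("0/0", "0/0", "0/1", "0/1"), c(ids, "FAM1_C2"))
  expect_true(check_dominant(gt2, fam2)$pass)
  # no genotyped relatives -> sporadic evidence
  solo <- setNames("0/1", ids[3])
  res <- check_dominant(solo, fam)
  expect_true(res$pass)
  expect_equal(res$evidence, "sporadic")
})

test_that("recessive check: hom route", {
  fam <- make_trio()
  ids <- trio_ids()
  ok <- setNames(c("0/1", "0/1", "1/1"), ids)
  expect_true(check_recessive(ok, fam)$pass)
  het_child <- setNames(c("0/1", "0/1", "0/1"), ids)
  expect_equal(check_recessive(het_child, fam)$reason,
               "affected_not_homozygous")
  hom_father <- setNames(c("1/1", "0/1", "1/1"), ids)
  expect_equal(check_recessive(hom_father, fam)$reason,
               "unaffected_homozygous")
})

test_that("recessive check: compound het in trans passes, cis fails", {
  fam <- make_trio()
  ids <- trio_ids()
  a <- setNames(c("0/0", "0/1", "0/1"), ids)  # from mother
  b <- setNames(c("0/1", "0/0", "0/1"), ids)  # from father
  res <- check_recessive(list(a, b), fam)
  expect_true(res$pass)
  expect_equal(res$evidence, "full")
  # both variants on the father's haplotype: he carries both, unaffected
  a_cis <- setNames(c("0/1", "0/0", "0/1"), ids)
  res <- check_recessive(list(a_cis, b), fam)
  expect_false(res$pass)
  expect_equal(res$reason, "unaffected_carries_both")
  # no genotyped parents: pass but flagged phase-unresolved
  a1 <- setNames("0/1", ids[3]); b1 <- setNames("0/1", ids[3])
  res <- check_recessive(list(a1, b1), fam)
  expect_true(res$pass)
  expect_equal(res$evidence, "phase_unresolved")
  # affected must carry both alleles
  miss <- check_recessive(list(a, setNames(c("0/1", "0/0", "0/0"), ids)), fam)
  expect_equal(miss$reason, "affected_missing_allele")
})

test_that("X-linked check: hemizygous male with carrier mother passes", {
  fam <- make_trio(child_sex = "M")
  ids <- trio_ids()
  gt <- setNames(c("0", "0/1", "1"), ids)
  expect_true(check_xlinked(gt, fam, "chrX")$pass)
  # unaffected brother carrying it fails
  bro <- data.frame(family_id = "FAM1", id = "FAM1_C2", father = "FAM1_F",
                    mother = "FAM1_M", sex = "M", affected = FALSE)
  fam2 <- make_trio(child_sex = "M", extra = bro)
  gt2 <- setNames(c("0", "0/1", "1", "1"), c(ids, "FAM1_C2"))
  res <- check_xlinked(gt2, fam2, "chrX")
  expect_false(res$pass)
  expect_equal(res$reason, "unaffected_male_carrier")
  # homozygous unaffected mother is inconsistent with causality
  gt3 <- setNames(c("0", "1/1", "1"), ids)
  expect_equal(check_xlinked(gt3, fam, "chrX")$reason,
               "unaffected_female_homozygous")
  # affected female under the hemizygous model
  famF <- make_trio(child_sex = "F")
  gtF <- setNames(c("0", "0/1", "0/1"), ids)
  expect_equal(check_xlinked(gtF, famF, "chrX")$reason, "mode_inconsistent")
  # autosomal variant is a caller error
  expect_error(check_xlinked(gt, fam, "chr4"), "chrX")
})

test_that("diagnose_patient assembles compound-het SNV+SV diagnoses", {
  fam <- make_trio()
  ids <- trio_ids()
  genes <- structure(list(GA = make_gene("GA", "chr1", 10000, tpms = 100,
                                         modes = "AR")),
                     class = "gene_model_set")
  candidates <- data.frame(
    variant_id = c("v_snv", "v_sv"), gene_id = "GA",
    class = c("SNV", "SV"),
    category = c("stop_gain", "sv_del_dup_exonic"),
    chrom = "chr1", stringsAsFactors = FALSE)
  genotypes <- rbind(
    data.frame(variant_id = "v_snv", sample_id = ids,
               gt = c("0/0", "0/1", "0/1")),
    data.frame(variant_id = "v_sv", sample_id = ids,
               gt = c("0/1", "0/0", "0/1")))
  rep <- diagnose_patient(ids[3], candidates, genotypes, fam, genes)
  expect_s3_class(rep, "diagnosis_report")
  expect_equal(rep$mode, "AR_compound_het")
  expect_equal(rep$category, "SNV_plus_SV")
  expect_setequal(rep$variants$variant_id, c("v_snv", "v_sv"))
  expect_false(rep$ambiguous)
  # no candidates -> unresolved
  expect_null(diagnose_patient(ids[3], candidates[0, ], genotypes, fam, genes))
})

test_that("ties across genes are reported as ambiguous", {
  fam <- make_trio()
  ids <- trio_ids()
  genes <- structure(list(
    GA = make_gene("GA", "chr1", 10000, modes = "AD"),
    GB = make_gene("GB", "chr2", 10000, modes = "AD")),
    class = "gene_model_set")
  candidates <- data.frame(
    variant_id = c("va", "vb"), gene_id = c("GA", "GB"),
    class = "SV", category = "sv_del_dup_exonic",
    chrom = c("chr1", "chr2"), stringsAsFactors = FALSE)
  genotypes <- rbind(
    data.frame(variant_id = "va", sample_id = ids, gt = c("0/0", "0/0", "0/1")),
    data.frame(variant_id = "vb", sample_id = ids, gt = c("0/0", "0/0", "0/1")))
  rep <- diagnose_patient(ids[3], candidates, genotypes, fam, genes)
  expect_true(rep$ambiguous)
  expect_length(rep$alternative_genes, 1)
})

test_that("cohort_summary on reports: rate, categories, degenerate cases", {
  fake_report <- function(pid, cat, mode, sym) {
    structure(list(patient_id = pid, family_id = "F", gene_id = sym,
                   symbol = sym, disease_group = "RP", mode = mode,
                   variants = data.frame(), category = cat,
                   evidence = "full", ambiguous = FALSE,
                   alternative_genes = character(0)),
              class = "diagnosis_report")
  }
  reps <- list(fake_report("p1", "SV_only", "AD", "A"),
               fake_report("p2", "SNV_plus_SV", "AR_compound_het", "B"),
               fake_report("p3", "SV_only", "AR_hom", "A"))
  s <- cohort_summary(reps, cohort_size = 23)
  expect_equal(s$n_diagnosed, 3)
  expect_equal(s$diagnostic_rate_pct, 13)  # 3/23 = 13.04 -> 13
  expect_equal(unname(s$category_counts["SV_only"]), 2L)
  expect_equal(unname(s$gene_counts["A"]), 2L)
  empty <- cohort_summary(list(), cohort_size = 10)
  expect_equal(empty$n_diagnosed, 0)
  expect_equal(empty$diagnostic_rate_pct, 0)
  expect_error(cohort_summary(reps, cohort_size = 0), "cohort_size")
})

test_that("percentages round half up", {
  expect_equal(irddx:::round_half_up(13.5), 14)
  expect_equal(irddx:::round_half_up(12.54), 13)  # 34/271 style
  expect_equal(irddx:::round_half_up(12.4), 12)
})
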