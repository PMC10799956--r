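#' Genotype-level hard filter
#'
#' Applies the published genotype filters with strict comparators:
#' DP < dp_min or DP > dp_max; GQ < gq_min; heterozygous allele balance
#' AB < het_ab_low or AB > het_ab_high; hom-ref AB > homref_ab_max;
#' hom-alt (and hemizygous-alt) AB < homalt_ab_min. Boundary values pass
#' (DP = 10, GQ = 25, AB = 0.25 all pass with defaults). Missing DP/GQ
#' (or missing AB where the AB rule applies) fail with reason
#' "missing_metric". A failing genotype is set to missing downstream, the
#' site itself is kept.
#'
#' @param g a list with fields `gt` (genotype string; see [gt_class()]),
#'   `dp`, `gq`, `ab`
#' @param t a [threshold_config()]
#' @return list(pass = logical, reasons = character vector of failed checks)
#' @examples
#' filter_genotype(list(gt = "0/1", dp = 9, gq = 60, ab = 0.5),
#'                 threshold_config())
#' @export
filter_genotype <- function(g, t = threshold_config()) {
  t <- as_threshold_config(t)
  cls <- gt_class(g$gt)
  if (cls == "missing")
    return(list(pass = FALSE, reasons = "missing_genotype"))
  reasons <- character(0)
  dp <- g$dp; gq <- g$gq; ab <- g$ab
  if (is.null(dp) || is.na(dp) || is.null(gq) || is.na(gq))
    return(list(pass = FALSE, reasons = "missing_metric"))
  if (dp < t$dp_min || dp > t$dp_max) reasons <- c(reasons, "DP")
  if (gq < t$gq_min) reasons <- c(reasons, "GQ")
  ab_needed <- cls %in% c("het", "ref", "hom_alt", "hemi_alt")
  if (ab_needed && (is.null(ab) || is.na(ab))) {
    reasons <- c(reasons, "missing_metric")
  } else if (cls == "het") {
    if (ab < t$het_ab_low || ab > t$het_ab_high) reasons <- c(reasons, "AB")
  } else if (cls == "ref") {
    if (ab > t$homref_ab_max) reasons <- c(reasons, "AB")
  } else if (cls %in% c("hom_alt", "hemi_alt")) {
    if (ab < t$homalt_ab_min) reasons <- c(reasons, "AB")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Site-level hard filter
#'
#' Fails when any criterion trips: membership in a low-complexity region,
#' inbreeding coefficient < inbreeding_min, Hardy-Weinberg p-value <
#' hwe_min (strict), or a VQSR non-PASS flag. Reasons accumulate. A
#' missing LCR flag skips that check with a notice (LCR membership is an
#' optional BED-derived input).
#'
#' @param s a list with fields `in_lcr` (logical or NA),
#'   `inbreeding_coef`, `hwe_p`, `vqsr_pass`
#' @param t a [threshold_config()]
#' @return list(pass = logical, reasons = character)
#' @export
filter_site <- function(s, t = threshold_config()) {
  t <- as_threshold_config(t)
  reasons <- character(0)
  if (is.null(s$in_lcr) || is.na(s$in_lcr)) {
    # LCR annotation absent: check skipped
  } else if (isTRUE(s$in_lcr)) reasons <- c(reasons, "LCR")
  if (!is.null(s$inbreeding_coef) && !is.na(s$inbreeding_coef) &&
      s$inbreeding_coef < t$inbreeding_min)
    reasons <- c(reasons, "inbreeding")
  if (!is.null(s$hwe_p) && !is.na(s$hwe_p) && s$hwe_p < t$hwe_min)
    reasons <- c(reasons, "HWE")
  if (!is.null(s$vqsr_pass) && !is.na(s$vqsr_pass) && !isTRUE(s$vqsr_pass))
    reasons <- c(reasons, "VQSR")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Apply genotype- and site-level QC to a small-variant table
#'
#' SV records bypass these filters entirely; this operates on SNV/indel
#' tables only. Sites failing [filter_site()] are removed; genotypes
#' failing [filter_genotype()] are set to missing ("./.") but the site is
#' retained unless *all* its genotypes end up missing.
#'
#' @param variants data.frame with one row per site: `variant_id` plus the
#'   site-QC columns `in_lcr`, `inbreeding_coef`, `hwe_p`, `vqsr_pass`
#'   (absent columns are treated as NA, i.e. check skipped / pass)
#' @param genotypes long data.frame: `variant_id`, `sample_id`, `gt`,
#'   `dp`, `gq`, `ab`
#' @param t a [threshold_config()]
#' @return list with elements `variants` (surviving sites), `genotypes`
#'   (failing calls masked to "./."), and `report` (named counts per
#'   failure reason plus sites/genotypes removed)
#' @export
apply_qc <- function(variants, genotypes, t = threshold_config()) {
  t <- as_threshold_config(t)
  stopifnot(is.data.frame(variants), is.data.frame(genotypes))
  for (col in c("in_lcr", "inbreeding_coef", "hwe_p", "vqsr_pass"))
    if (!col %in% names(variants)) variants[[col]] <- NA

  site_reasons <- character(0)
  site_pass <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    res <- filter_site(as.list(variants[i, , drop = FALSE]), t)
    site_pass[i] <- res$pass
    site_reasons <- c(site_reasons, res$reasons)
  }
  kept_sites <- variants$variant_id[site_pass]
  gt <- genotypes[genotypes$variant_id %in% kept_sites, , drop = FALSE]

  geno_reasons <- character(0)
  already_missing <- gt_is_missing(gt$gt)
  n_masked <- 0L
  for (i in seq_len(nrow(gt))) {
    if (already_missing[i]) next
    res <- filter_genotype(list(gt = gt$gt[i], dp = gt$dp[i],
                                gq = gt$gq[i], ab = gt$ab[i]), t)
    if (!res$pass) {
      geno_reasons <- c(geno_reasons, res$reasons)
      gt$gt[i] <- "./."
      n_masked <- n_masked + 1L
    }
  }

  # drop sites where every genotype is now missing
  if (nrow(gt)) {
    all_missing <- tapply(gt_is_missing(gt$gt), gt$variant_id, all)
    dead <- names(all_missing)[all_missing]
  } else dead <- character(0)
  kept_sites <- setdiff(kept_sites, dead)
  out_variants <- variants[variants$variant_id %in% kept_sites, , drop = FALSE]
  out_gt <- gt[gt$variant_id %in% kept_sites, , drop = FALSE]
  rownames(out_variants) <- rownames(out_gt) <- NULL

  report <- list(
    sites_in = nrow(variants),
    sites_removed_site_qc = sum(!site_pass),
    sites_removed_all_missing = length(dead),
    sites_out = nrow(out_variants),
    genotypes_masked = n_masked,
    site_fail_reasons = as.list(table(site_reasons)),
    genotype_fail_reasons = as.list(table(geno_reasons))
  )
  list(variants = out_variants, genotypes = out_gt, report = report)
}
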