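#' Pipeline threshold configuration
#'
#' Every numeric cutoff used anywhere in the pipeline lives in this one
#' object. Defaults are the published hard filters of the analysis this
#' package implements; all comparisons downstream are *strict* in the
#' direction printed here (e.g. a genotype with DP exactly 10 passes,
#' an SV pair with reciprocal overlap exactly 0.8 does not match).
#'
#' @param dp_min minimum read depth for a genotype (fails when DP < dp_min)
#' @param dp_max maximum read depth (fails when DP > dp_max)
#' @param gq_min minimum genotype quality (fails when GQ < gq_min)
#' @param het_ab_low,het_ab_high allele-balance window for heterozygous
#'   calls; fails when AB < het_ab_low or AB > het_ab_high
#' @param homref_ab_max hom-ref fails when AB > homref_ab_max
#' @param homalt_ab_min hom-alt (and hemizygous-alt) fails when
#'   AB < homalt_ab_min
#' @param inbreeding_min site fails when inbreeding coefficient <
#'   inbreeding_min
#' @param hwe_min site fails when Hardy-Weinberg test p-value < hwe_min
#' @param af_max rarity cutoff: a variant is rare when its AF is strictly
#'   below af_max in *every* reference panel
#' @param sv_overlap_min SV consolidation/matching cutoff: two SVs match
#'   when their reciprocal overlap is strictly greater than sv_overlap_min
#' @param spliceai_min SpliceAI max delta score cutoff (strictly greater
#'   passes)
#' @param cadd_min scaled CADD cutoff (strictly greater passes)
#' @param deep_intron_bp intronic variants at a distance >= deep_intron_bp
#'   from the nearest exon are deep-intronic; closer (but outside the
#'   canonical +/-2 dinucleotide) they are non-canonical splice-site
#' @param tdr_min transcript disruption ratio below which an SV is
#'   excluded as benign (ratio exactly tdr_min retains)
#' @param benign_panel_min_samples minimum carrier count for a panel SV to
#'   enter the benign SV set
#' @param sv_overlap_denominator "longer" for reciprocal overlap relative
#'   to the longer interval (default, stricter), or "query" for
#'   query-relative overlap
#'
#' @return an object of class `threshold_config` (a named list)
#' @examples
#' t <- threshold_config()
#' t$af_max
#' @export
threshold_config <- function(dp_min = 10, dp_max = 400, gq_min = 25,
                             het_ab_low = 0.25, het_ab_high = 0.75,
                             homref_ab_max = 0.1, homalt_ab_min = 0.9,
                             inbreeding_min = -0.3, hwe_min = 1e-6,
                             af_max = 0.01, sv_overlap_min = 0.8,
                             spliceai_min = 0.5, cadd_min = 20,
                             deep_intron_bp = 100, tdr_min = 0.20,
                             benign_panel_min_samples = 2,
                             sv_overlap_denominator = c("longer", "query")) {
  sv_overlap_denominator <- match.arg(sv_overlap_denominator)
  t <- list(
    dp_min = dp_min, dp_max = dp_max, gq_min = gq_min,
    het_ab_low = het_ab_low, het_ab_high = het_ab_high,
    homref_ab_max = homref_ab_max, homalt_ab_min = homalt_ab_min,
    inbreeding_min = inbreeding_min, hwe_min = hwe_min,
    af_max = af_max, sv_overlap_min = sv_overlap_min,
    spliceai_min = spliceai_min, cadd_min = cadd_min,
    deep_intron_bp = deep_intron_bp, tdr_min = tdr_min,
    benign_panel_min_samples = benign_panel_min_samples,
    sv_overlap_denominator = sv_overlap_denominator
  )
  stopifnot(
    dp_min > 0, dp_max > dp_min, gq_min > 0,
    het_ab_low > 0, het_ab_high > het_ab_low, het_ab_high < 1,
    homref_ab_max > 0, homalt_ab_min > homref_ab_max,
    hwe_min > 0, af_max > 0, sv_overlap_min > 0, sv_overlap_min <= 1,
    spliceai_min > 0, cadd_min > 0, deep_intron_bp > 0,
    tdr_min > 0, tdr_min < 1, benign_panel_min_samples >= 1
  )
  structure(t, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_threshold_config <- function(t) {
  if (is.null(t)) return(threshold_config())
  if (!inherits(t, "threshold_config"))
    stop("`t` must be a threshold_config object")
  t
}
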