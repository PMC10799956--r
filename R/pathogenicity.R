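#' Likely-pathogenic categories
#' @return character vector of the recognized categories
#' @export
pathogenicity_categories <- function() {
  c("stop_gain", "stop_loss", "frameshift", "canonical_splice",
    "missense_damaging", "deep_intronic", "non_canonical_splice",
    "sv_del_dup_exonic", "sv_inversion_exonic", "not_pathogenic")
}

pathogenicity_call <- function(category, rule, ...) {
  stopifnot(category %in% pathogenicity_categories())
  structure(list(category = category,
                 evidence = c(list(rule = rule), list(...))),
            class = "pathogenicity_call")
}

#' @export
print.pathogenicity_call <- function(x, ...) {
  cat(sprintf("<pathogenicity_call> %s (rule: %s)\n",
              x$category, x$evidence$rule))
  invisible(x)
}

num_gt <- function(x, cutoff) !is.null(x) && !is.na(x) && x > cutoff

#' Classify an SNV/indel into a likely-pathogenic category
#'
#' Rule table (first match wins, exactly one category per variant/gene
#' pair):
#' \itemize{
#'   \item stop_gain / stop_loss / frameshift: assigned from the
#'     consequence term unconditionally;
#'   \item canonical splice (the +/-2 intronic dinucleotide, or a
#'     splice_donor/splice_acceptor consequence term): requires
#'     SpliceAI > 0.5 OR CADD > 20;
#'   \item missense: requires an EVE-damaging flag OR CADD > 20;
#'   \item intronic at distance >= 100 bp from the nearest exon with
#'     SpliceAI > 0.5: deep_intronic;
#'   \item intronic at distance 3-99 bp with SpliceAI > 0.5:
#'     non_canonical_splice;
#'   \item anything else: not_pathogenic (reason "unscored" when the only
#'     applicable rule lacked its score).
#' }
#' Exon distance uses the union of exons of all transcripts
#' ([distance_to_nearest_exon()]); LOFTEE/ClinVar annotations, when
#' present in `scores`, are carried through as evidence but never override
#' the rule table.
#'
#' @param variant list with `chrom` and `pos` (1-based); must lie within
#'   the gene span
#' @param gene a `gene_model`
#' @param scores list with `cadd`, `spliceai`, `eve_damaging`,
#'   `consequence_term` (VEP-style, e.g. "stop_gained",
#'   "missense_variant", "intron_variant")
#' @param t a [threshold_config()]
#' @return a `pathogenicity_call`
#' @export
classify_snv <- function(variant, gene, scores, t = threshold_config()) {
  t <- as_threshold_config(t)
  stopifnot(inherits(gene, "gene_model"))
  term <- scores$consequence_term
  if (is.null(term) || is.na(term)) term <- ""
  cadd <- scores$cadd; spliceai <- scores$spliceai
  eve <- isTRUE(scores$eve_damaging)

  if (grepl("stop_gained|stop_gain", term))
    return(pathogenicity_call("stop_gain", "consequence_term", term = term))
  if (grepl("stop_lost|stop_loss", term))
    return(pathogenicity_call("stop_loss", "consequence_term", term = term))
  if (grepl("frameshift", term))
    return(pathogenicity_call("frameshift", "consequence_term", term = term))

  dist <- tryCatch(distance_to_nearest_exon(variant$pos, gene),
                   error = function(e) NA_real_)
  canonical <- grepl("splice_acceptor|splice_donor", term) ||
    (!is.na(dist) && dist >= 1 && dist <= 2)
  if (canonical) {
    if (num_gt(spliceai, t$spliceai_min) || num_gt(cadd, t$cadd_min))
      return(pathogenicity_call("canonical_splice", "canonical_splice_scored",
                                distance = dist, spliceai = spliceai,
                                cadd = cadd))
    reason <- if ((is.null(spliceai) || is.na(spliceai)) &&
                  (is.null(cadd) || is.na(cadd))) "unscored" else "below_cutoffs"
    return(pathogenicity_call("not_pathogenic", reason, distance = dist))
  }
  if (grepl("missense", term)) {
    if (eve || num_gt(cadd, t$cadd_min))
      return(pathogenicity_call("missense_damaging", "missense_scored",
                                eve_damaging = eve, cadd = cadd))
    reason <- if (!isTRUE(scores$eve_damaging) &&
                  (is.null(cadd) || is.na(cadd))) "unscored" else "below_cutoffs"
    return(pathogenicity_call("not_pathogenic", reason))
  }
  intronic <- grepl("intron", term) || (!is.na(dist) && dist > 0)
  if (intronic && !is.na(dist) && dist > 0) {
    if (is.null(spliceai) || is.na(spliceai))
      return(pathogenicity_call("not_pathogenic", "unscored", distance = dist))
    if (dist >= t$deep_intron_bp && spliceai > t$spliceai_min)
      return(pathogenicity_call("deep_intronic", "deep_intronic_spliceai",
                                distance = dist, spliceai = spliceai))
    if (dist < t$deep_intron_bp && spliceai > t$spliceai_min)
      return(pathogenicity_call("non_canonical_splice",
                                "non_canonical_spliceai",
                                distance = dist, spliceai = spliceai))
    return(pathogenicity_call("not_pathogenic", "below_cutoffs",
                              distance = dist, spliceai = spliceai))
  }
  pathogenicity_call("not_pathogenic", "no_rule_applies", term = term,
                     distance = dist)
}

#' Classify a structural variant against a gene
#'
#' DEL/DUP are likely pathogenic on any exon overlap; INV on exon overlap
#' provided it does not span the whole gene (a whole-gene inversion leaves
#' every transcript intact).
#'
#' @param sv an [sv_record()]
#' @param gene a `gene_model`
#' @return a `pathogenicity_call` with category `sv_del_dup_exonic`,
#'   `sv_inversion_exonic` or `not_pathogenic`
#' @export
classify_sv <- function(sv, gene) {
  stopifnot(inherits(sv, "sv_record"), inherits(gene, "gene_model"))
  exon_ov <- 0
  for (tx in gene$transcripts) {
    for (i in seq_len(nrow(tx$exons))) {
      exon_ov <- max(exon_ov, overlap_bp(
        sv$interval,
        genomic_interval(gene$chrom, tx$exons$start[i], tx$exons$end[i])))
      if (exon_ov > 0) break
    }
    if (exon_ov > 0) break
  }
  if (sv$sv_type %in% c("DEL", "DUP")) {
    if (exon_ov > 0)
      return(pathogenicity_call("sv_del_dup_exonic", "exon_overlap",
                                sv_type = sv$sv_type))
    return(pathogenicity_call("not_pathogenic", "no_exon_overlap",
                              sv_type = sv$sv_type))
  }
  # INV
  if (exon_ov > 0 && !spans_whole_gene(sv$interval, gene))
    return(pathogenicity_call("sv_inversion_exonic", "exon_overlap_partial",
                              sv_type = "INV"))
  rule <- if (exon_ov > 0) "spans_whole_gene" else "no_exon_overlap"
  pathogenicity_call("not_pathogenic", rule, sv_type = "INV")
}

transcript_disrupted <- function(sv, tx, chrom) {
  span <- genomic_interval(chrom, min(tx$exons$start), max(tx$exons$end))
  exon_hit <- any(mapply(function(s, e) {
    overlap_bp(sv$interval, genomic_interval(chrom, s, e)) > 0
  }, tx$exons$start, tx$exons$end))
  if (sv$sv_type %in% c("DEL", "DUP")) return(exon_hit)
  # INV: an inversion containing the whole transcript leaves it intact;
  # otherwise it disrupts when it touches an exon or breaks inside the span
  contains <- sv$interval$chrom == chrom &&
    sv$interval$start <= span$start && sv$interval$end >= span$end
  if (contains) return(FALSE)
  bp_inside <- sv$interval$chrom == chrom &&
    ((sv$interval$start > span$start && sv$interval$start < span$end) ||
       (sv$interval$end > span$start && sv$interval$end < span$end))
  exon_hit || bp_inside
}

#' Retina transcript disruption ratio (TDR) of an SV
#'
#' The TPM-weighted fraction of a gene's retinal expression carried by
#' transcripts the SV disrupts: sum of disrupted-transcript TPMs over the
#' sum of all transcript TPMs. A DEL/DUP disrupts a transcript when it
#' overlaps any of its exons; an INV disrupts a transcript when it touches
#' an exon or has a breakpoint strictly inside the transcript span, unless
#' it contains the whole transcript. Verdict is `exclude_benign` iff the
#' ratio is strictly below `t$tdr_min` (default 20%; a ratio of exactly
#' 0.20 retains). An unexpressed gene (total TPM 0) yields ratio 0 and
#' `exclude_benign` with a warning.
#'
#' @param sv an [sv_record()]
#' @param gene a `gene_model` with TPMs attached
#' @param t a [threshold_config()]
#' @return an object of class `tdr_result`: gene_id,
#'   disrupted_transcript_ids, disrupted_tpm_sum, total_tpm_sum, ratio,
#'   verdict ("retain" or "exclude_benign")
#' @export
transcript_disruption_ratio <- function(sv, gene, t = threshold_config()) {
  t <- as_threshold_config(t)
  stopifnot(inherits(sv, "sv_record"), inherits(gene, "gene_model"))
  total <- gene_total_tpm(gene)
  disrupted <- vapply(gene$transcripts, transcript_disrupted, TRUE,
                      sv = sv, chrom = gene$chrom)
  dis_ids <- names(gene$transcripts)[disrupted]
  dis_tpm <- sum(vapply(gene$transcripts[disrupted], `[[`, 0, "tpm"))
  if (total > 0) {
    ratio <- dis_tpm / total
  } else {
    warning("unexpressed gene ", gene$gene_id, ": total TPM is 0")
    ratio <- 0
  }
  verdict <- if (ratio < t$tdr_min) "exclude_benign" else "retain"
  structure(list(gene_id = gene$gene_id,
                 disrupted_transcript_ids = dis_ids,
                 disrupted_tpm_sum = dis_tpm, total_tpm_sum = total,
                 ratio = ratio, verdict = verdict),
            class = "tdr_result")
}

#' @export
print.tdr_result <- function(x, ...) {
  cat(sprintf("<tdr_result> %s: %d transcript(s) disrupted, %.4g / %.4g TPM, ratio %.4g -> %s\n",
              x$gene_id, length(x$disrupted_transcript_ids),
              x$disrupted_tpm_sum, x$total_tpm_sum, x$ratio, x$verdict))
  invisible(x)
}

#' Size comparison of pathogenic vs comparison SVs
#'
#' Report-only (no filtering decision): per-group length quantiles and a
#' Wilcoxon rank-sum comparison of the two length distributions.
#'
#' @param pathogenic,comparison lists of [sv_record()] (or numeric length
#'   vectors)
#' @return list with per-group quantiles, medians and the rank-sum test
#' @export
sv_size_summary <- function(pathogenic, comparison) {
  lens <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(s) interval_length(s$interval), 0)
  }
  a <- lens(pathogenic); b <- lens(comparison)
  if (length(a) == 0 || length(b) == 0)
    stop("both SV groups must be non-empty")
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(pathogenic_quantiles = stats::quantile(a, qs),
       comparison_quantiles = stats::quantile(b, qs),
       pathogenic_median = stats::median(a),
       comparison_median = stats::median(b),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
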