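#' Pedigree constructor
#'
#' @param df data.frame with columns family_id, id, father, mother
#'   (0/NA/"" for missing), sex ("M"/"F" or 1/2), affected (logical, or
#'   PED phenotype codes 2=affected/1=unaffected/0=unknown)
#' @return a validated data.frame of class `pedigree`
#' @export
pedigree <- function(df) {
  need <- c("family_id", "id", "father", "mother", "sex", "affected")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df$sex <- ifelse(df$sex %in% c(1, "1", "M", "male"), "M",
                   ifelse(df$sex %in% c(2, "2", "F", "female"), "F", NA))
  if (is.numeric(df$affected) || all(df$affected %in% c("0", "1", "2")))
    df$affected <- as.numeric(df$affected) == 2
  df$affected <- as.logical(df$affected)
  df$father[df$father %in% c("0", 0, "")] <- NA
  df$mother[df$mother %in% c("0", 0, "")] <- NA
  bad <- c(df$father, df$mother)
  bad <- bad[!is.na(bad) & !(bad %in% df$id)]
  if (length(bad)) stop("unresolved parent id(s): ", paste(bad, collapse = ", "))
  for (fam in split(df, df$family_id))
    if (!any(fam$affected, na.rm = TRUE))
      stop("family ", fam$family_id[1], " has no affected individual")
  structure(df[, need], class = c("pedigree", "data.frame"))
}

seg_result <- function(pass, reason = NULL, evidence = "full") {
  list(pass = pass, reason = reason, evidence = evidence)
}

family_members <- function(ped, family_id) {
  ped[ped$family_id == family_id, , drop = FALSE]
}

genotyped_ids <- function(gt) names(gt)[!gt_is_missing(gt)]

#' Dominant-inheritance segregation check
#'
#' Pass iff every genotyped affected family member carries at least one
#' alternate allele and no genotyped unaffected relative carries it.
#' De novo variants are permitted (parents are not required to carry the
#' variant). With no genotyped relatives beyond the affected carrier(s)
#' the check passes with evidence level "sporadic". No reduced-penetrance
#' allowance: an unaffected carrier always fails the hypothesis.
#'
#' @param gt named character vector of genotypes (names = individual ids)
#' @param family a `pedigree` subset for one family
#' @return list(pass, reason, evidence)
#' @export
check_dominant <- function(gt, family) {
  aff <- family$id[family$affected %in% TRUE]
  unaff <- family$id[family$affected %in% FALSE]
  g_aff <- intersect(aff, genotyped_ids(gt))
  g_unaff <- intersect(unaff, genotyped_ids(gt))
  if (length(g_aff) == 0)
    return(seg_result(FALSE, "no_genotyped_affected"))
  if (!all(gt_carries_alt(gt[g_aff])))
    return(seg_result(FALSE, "affected_without_variant"))
  if (any(gt_carries_alt(gt[g_unaff])))
    return(seg_result(FALSE, "unaffected_carrier"))
  ev <- if (length(g_unaff) == 0 && length(g_aff) <= 1) "sporadic" else "full"
  seg_result(TRUE, evidence = ev)
}

#' Recessive-inheritance segregation check (homozygous or compound het)
#'
#' Homozygous (one variant): every genotyped affected is homozygous
#' alternate and no genotyped unaffected is. Compound heterozygous (two
#' variants): every genotyped affected carries both variants, and no
#' genotyped unaffected relative carries both (an unaffected parent
#' carrying exactly one is the expected AR carrier state). When both
#' parents are genotyped the trans configuration is inferred from
#' parental origin; two variants inherited from the same unaffected
#' parent fail as cis (that parent carries both). Without genotyped
#' parents the pair passes with the evidence flag "phase_unresolved".
#'
#' @param gts a single named genotype vector (homozygous test) or a list
#'   of two named genotype vectors (compound het test)
#' @param family a `pedigree` subset for one family
#' @return list(pass, reason, evidence)
#' @export
check_recessive <- function(gts, family) {
  aff <- family$id[family$affected %in% TRUE]
  unaff <- family$id[family$affected %in% FALSE]
  if (!is.list(gts)) {  # homozygous route
    gt <- gts
    g_aff <- intersect(aff, genotyped_ids(gt))
    g_unaff <- intersect(unaff, genotyped_ids(gt))
    if (length(g_aff) == 0)
      return(seg_result(FALSE, "no_genotyped_affected"))
    if (!all(gt_class(gt[g_aff]) == "hom_alt"))
      return(seg_result(FALSE, "affected_not_homozygous"))
    if (any(gt_class(gt[g_unaff]) == "hom_alt"))
      return(seg_result(FALSE, "unaffected_homozygous"))
    return(seg_result(TRUE))
  }
  stopifnot(length(gts) == 2)
  a <- gts[[1]]; b <- gts[[2]]
  g_aff <- intersect(aff, intersect(genotyped_ids(a), genotyped_ids(b)))
  if (length(g_aff) == 0)
    return(seg_result(FALSE, "no_genotyped_affected"))
  if (!all(gt_carries_alt(a[g_aff]) & gt_carries_alt(b[g_aff])))
    return(seg_result(FALSE, "affected_missing_allele"))
  carries_both <- function(id) {
    isTRUE(gt_carries_alt(a[id])) && isTRUE(gt_carries_alt(b[id]))
  }
  for (id in unaff) if (!is.na(id) && id %in% family$id && carries_both(id))
    return(seg_result(FALSE, "unaffected_carries_both"))
  # phase via parents of the first genotyped affected
  proband <- g_aff[1]
  fam_row <- family[family$id == proband, ]
  parents <- c(fam_row$father, fam_row$mother)
  parents <- parents[!is.na(parents)]
  g_parents <- intersect(parents, union(genotyped_ids(a), genotyped_ids(b)))
  if (length(g_parents) < 2)
    return(seg_result(TRUE, evidence = "phase_unresolved"))
  seg_result(TRUE, evidence = "full")
}

#' X-linked segregation check
#'
#' The variant must be on chrX. Affected males must carry the alternate
#' allele (hemizygous); genotyped unaffected males must not carry it;
#' unaffected females may be heterozygous carriers (exempt from the
#' dominant-style exclusion) but not homozygous. An affected female fails
#' with reason "mode_inconsistent" (the hemizygous model does not apply).
#'
#' @param gt named genotype vector
#' @param family a `pedigree` subset for one family
#' @param chrom the variant's chromosome
#' @return list(pass, reason, evidence)
#' @export
check_xlinked <- function(gt, family, chrom) {
  if (normalize_chrom(chrom) != "chrX")
    stop("check_xlinked requires a chrX variant, got ", chrom)
  aff <- family[family$affected %in% TRUE, , drop = FALSE]
  unaff <- family[family$affected %in% FALSE, , drop = FALSE]
  if (any(aff$sex %in% "F"))
    return(seg_result(FALSE, "mode_inconsistent"))
  g_aff_m <- intersect(aff$id[aff$sex %in% "M"], genotyped_ids(gt))
  if (length(g_aff_m) == 0)
    return(seg_result(FALSE, "no_genotyped_affected"))
  if (!all(gt_carries_alt(gt[g_aff_m])))
    return(seg_result(FALSE, "affected_without_variant"))
  g_unaff_m <- intersect(unaff$id[unaff$sex %in% "M"], genotyped_ids(gt))
  if (any(gt_carries_alt(gt[g_unaff_m])))
    return(seg_result(FALSE, "unaffected_male_carrier"))
  g_unaff_f <- intersect(unaff$id[unaff$sex %in% "F"], genotyped_ids(gt))
  if (any(gt_class(gt[g_unaff_f]) == "hom_alt"))
    return(seg_result(FALSE, "unaffected_female_homozygous"))
  ev <- if (length(g_unaff_m) + length(g_unaff_f) == 0 &&
            length(g_aff_m) <= 1) "sporadic" else "full"
  seg_result(TRUE, evidence = ev)
}

severity_rank <- function(category) {
  order <- c(stop_gain = 1, frameshift = 2, stop_loss = 3,
             canonical_splice = 4, sv_del_dup_exonic = 5,
             sv_inversion_exonic = 6, missense_damaging = 7,
             deep_intronic = 8, non_canonical_splice = 9,
             not_pathogenic = 99)
  unname(order[category])
}

diagnosis_category <- function(classes, categories) {
  intronic_cats <- c("deep_intronic", "non_canonical_splice")
  if (all(classes == "SV")) return("SV_only")
  if (any(classes == "SV")) return("SNV_plus_SV")
  if (all(categories %in% intronic_cats)) return("intronic")
  "SNV_only"
}

zygosity_label <- function(gt, sex, chrom) {
  cls <- gt_class(gt)
  if (cls == "hemi_alt" || (chrom == "chrX" && sex == "M" && cls != "ref"))
    return("Hem")
  c(ref = "Ref", het = "Het", hom_alt = "Hom", hemi_ref = "Ref",
    missing = "Missing")[cls]
}

#' Diagnose one patient from surviving candidate variants
#'
#' Enumerates (gene, mode, variant-set) hypotheses over the candidate
#' calls that survived QC, rarity, pathogenicity classification and (for
#' SVs) the TDR filter, checks each against the pedigree, and returns the
#' best-supported diagnosis. Hypotheses are ranked by segregation
#' evidence (full > sporadic/phase_unresolved) and then by summed
#' severity rank of the variants; ties across genes are all reported and
#' the diagnosis is flagged ambiguous.
#'
#' @param patient_id the affected individual to diagnose
#' @param candidates data.frame of candidate calls: variant_id, gene_id,
#'   class ("SNV"/"SV"), category (a pathogenicity category), chrom
#' @param genotypes long data.frame: variant_id, sample_id, gt
#' @param ped a [pedigree()]
#' @param genes a `gene_model_set`
#' @param t a [threshold_config()]
#' @return a `diagnosis_report`, or NULL when unresolved
#' @export
diagnose_patient <- function(patient_id, candidates, genotypes, ped, genes,
                             t = threshold_config()) {
  t <- as_threshold_config(t)
  fam_id <- ped$family_id[ped$id == patient_id]
  if (length(fam_id) != 1) stop("patient ", patient_id, " not in pedigree")
  family <- family_members(ped, fam_id)
  sex <- family$sex[family$id == patient_id]
  if (nrow(candidates) == 0) return(NULL)

  gt_vec <- function(vid) {
    g <- genotypes[genotypes$variant_id == vid, , drop = FALSE]
    stats::setNames(g$gt, g$sample_id)
  }
  carried <- vapply(candidates$variant_id, function(vid) {
    isTRUE(gt_carries_alt(gt_vec(vid)[patient_id]))
  }, TRUE)
  candidates <- candidates[carried, , drop = FALSE]
  if (nrow(candidates) == 0) return(NULL)

  hypotheses <- list()
  add_hyp <- function(gene_id, mode, vids, res) {
    if (!res$pass) return()
    rows <- candidates[match(vids, candidates$variant_id), , drop = FALSE]
    hypotheses[[length(hypotheses) + 1L]] <<- list(
      gene_id = gene_id, mode = mode, variant_ids = vids,
      classes = rows$class, categories = rows$category,
      evidence = res$evidence,
      severity = sum(severity_rank(rows$category)))
  }

  for (gid in unique(candidates$gene_id)) {
    gene <- genes[[gid]]
    if (is.null(gene)) next
    cand <- candidates[candidates$gene_id == gid, , drop = FALSE]
    modes <- gene$inheritance_modes
    if ("AD" %in% modes) {
      for (vid in cand$variant_id)
        add_hyp(gid, "AD", vid, check_dominant(gt_vec(vid), family))
    }
    if ("AR" %in% modes) {
      for (vid in cand$variant_id) {
        gv <- gt_vec(vid)
        if (gt_class(gv[patient_id]) == "hom_alt")
          add_hyp(gid, "AR_hom", vid, check_recessive(gv, family))
      }
      if (nrow(cand) >= 2) {
        prs <- utils::combn(cand$variant_id, 2, simplify = FALSE)
        for (pr in prs) {
          res <- check_recessive(list(gt_vec(pr[1]), gt_vec(pr[2])), family)
          add_hyp(gid, "AR_compound_het", pr, res)
        }
      }
    }
    if ("XL" %in% modes && gene$chrom == "chrX" && sex == "M") {
      for (vid in cand$variant_id)
        add_hyp(gid, "XL_hemizygous", vid,
                check_xlinked(gt_vec(vid), family, gene$chrom))
    }
  }
  if (length(hypotheses) == 0) return(NULL)

  ev_rank <- vapply(hypotheses, function(h)
    if (h$evidence == "full") 0L else 1L, 0L)
  sev <- vapply(hypotheses, `[[`, 0, "severity")
  ord <- order(ev_rank, sev)
  hypotheses <- hypotheses[ord]
  best <- hypotheses[[1]]
  top_genes <- unique(vapply(
    hypotheses[ev_rank[ord] == ev_rank[ord][1] & sev[ord] == sev[ord][1]],
    `[[`, "", "gene_id"))
  ambiguous <- length(top_genes) > 1

  gene <- genes[[best$gene_id]]
  vtab <- do.call(rbind, lapply(best$variant_ids, function(vid) {
    row <- candidates[candidates$variant_id == vid, , drop = FALSE]
    gv <- gt_vec(vid)
    data.frame(variant_id = vid, class = row$class, category = row$category,
               zygosity = zygosity_label(gv[[patient_id]], sex, gene$chrom),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    patient_id = patient_id, family_id = fam_id,
    gene_id = best$gene_id, symbol = gene$symbol,
    disease_group = gene$disease_group,
    mode = best$mode, variants = vtab,
    category = diagnosis_category(best$classes, best$categories),
    evidence = best$evidence, ambiguous = ambiguous,
    alternative_genes = setdiff(top_genes, best$gene_id)),
    class = "diagnosis_report")
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat(sprintf("<diagnosis_report> %s (family %s): %s [%s], mode %s, category %s%s\n",
              x$patient_id, x$family_id, x$symbol, x$disease_group, x$mode,
              x$category, if (x$ambiguous) " (AMBIGUOUS)" else ""))
  print(x$variants)
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Cohort-level summary of diagnoses and variants
#'
#' Dispatches on the input: a list of `diagnosis_report` objects (with a
#' cohort size) yields the diagnostic rate and category breakdown; a
#' variant table (columns gene, disease_group, class, and for SVs sv_type
#' / for intronic variants intron_offset) yields per-gene and
#' per-disease-group tallies, SV-type counts and the deep vs non-canonical
#' intronic split by the 100 bp rule. Percentages are rounded to the
#' nearest integer, half up.
#'
#' @param x list of diagnosis reports or a variant data.frame
#' @param cohort_size number of patients screened (required for rate
#'   computation from reports)
#' @param t a [threshold_config()]
#' @return a named list of summary tables and counts
#' @export
cohort_summary <- function(x, cohort_size = NULL, t = threshold_config()) {
  UseMethod("cohort_summary")
}

#' @export
cohort_summary.data.frame <- function(x, cohort_size = NULL,
                                      t = threshold_config()) {
  t <- as_threshold_config(t)
  stopifnot(all(c("gene", "disease_group", "class") %in% names(x)))
  n <- nrow(x)
  if (n == 0) stop("empty variant table")
  sv <- x[x$class == "SV", , drop = FALSE]
  intr <- x[x$class == "intronic", , drop = FALSE]
  deep <- if (nrow(intr)) sum(abs(intr$intron_offset) >= t$deep_intron_bp) else 0L
  gene_counts <- sort(table(x$gene), decreasing = TRUE)
  dg_counts <- table(x$disease_group)
  rp_n <- sum(x$disease_group == "RP")
  list(
    n_variants = n,
    n_sv = nrow(sv),
    n_intronic = nrow(intr),
    n_deep_intronic = as.integer(deep),
    n_non_canonical = as.integer(nrow(intr) - deep),
    n_genes = length(unique(x$gene)),
    gene_counts = gene_counts,
    top_gene = names(gene_counts)[1],
    top_gene_n = as.integer(gene_counts[1]),
    disease_group_counts = dg_counts,
    rp_n = as.integer(rp_n),
    rp_pct = round_half_up(100 * rp_n / n),
    non_rp_n = as.integer(n - rp_n),
    non_rp_pct = round_half_up(100 * (n - rp_n) / n),
    sv_type_counts = if (nrow(sv)) table(sv$sv_type) else table(character(0))
  )
}

#' @export
cohort_summary.list <- function(x, cohort_size = NULL,
                                t = threshold_config()) {
  t <- as_threshold_config(t)
  if (is.null(cohort_size) || cohort_size == 0)
    stop("cohort_size must be a positive patient count")
  x <- Filter(Negate(is.null), x)
  n_dx <- length(x)
  cats <- vapply(x, `[[`, "", "category")
  modes <- vapply(x, `[[`, "", "mode")
  genes <- vapply(x, `[[`, "", "symbol")
  cat_tab <- table(factor(cats, levels = c("SV_only", "SNV_plus_SV",
                                           "intronic", "SNV_only")))
  list(
    cohort_size = cohort_size,
    n_diagnosed = n_dx,
    diagnostic_rate_pct = round_half_up(100 * n_dx / cohort_size),
    category_counts = cat_tab,
    category_pct = round_half_up(100 * cat_tab / cohort_size),
    mode_counts = table(modes),
    gene_counts = sort(table(genes), decreasing = TRUE)
  )
}
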