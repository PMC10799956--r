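#' Map variants to candidate genes by position
#'
#' SNVs map to genes whose span contains the position; SVs to genes whose
#' span they overlap. A variant may map to several genes; each (variant,
#' gene) pair is classified independently downstream.
#' @keywords internal
map_to_genes <- function(chrom, start, end, genes) {
  hits <- character(0)
  for (g in genes) {
    span <- gene_span(g)
    if (span$chrom == chrom && start <= span$end && end >= span$start)
      hits <- c(hits, g$gene_id)
  }
  hits
}

#' Run the full prioritization pipeline on a cohort
#'
#' Stages, in order: (1) genotype/site QC on small variants (SVs bypass);
#' (2) dual-panel rarity — SNV/indel AF annotations and reciprocal-overlap
#' SV panel matching, both strictly below `t$af_max` in every panel;
#' (3) likely-pathogenic classification per (variant, gene) pair;
#' (4) transcript-disruption-ratio filtering of SVs (< `t$tdr_min`
#' excluded as benign); (5) per-family segregation and diagnosis. Every
#' variant receives a stage audit entry: the first stage that eliminated
#' it, "segregation" if it survived all filters but supported no passing
#' hypothesis, or "passed" if it backs a diagnosis.
#'
#' @param cohort an `ird_cohort` (from [simulate_cohort()] or assembled
#'   from files)
#' @param t a [threshold_config()]
#' @return list: `reports` (named list of `diagnosis_report` per diagnosed
#'   patient), `audit` (data.frame variant_id/stage), `qc_report`,
#'   `candidates` (surviving variant-gene pairs), `summary`
#'   (cohort-level, via [cohort_summary()])
#' @export
run_pipeline <- function(cohort, t = threshold_config()) {
  t <- as_threshold_config(t)
  stopifnot(inherits(cohort, "ird_cohort"))
  genes <- cohort$genes
  audit <- stats::setNames(
    rep(NA_character_, nrow(cohort$snv_variants) + nrow(cohort$sv_variants)),
    c(cohort$snv_variants$variant_id, cohort$sv_variants$variant_id))

  ## 1. QC (small variants only)
  qc <- apply_qc(cohort$snv_variants, cohort$snv_genotypes, t)
  snv <- qc$variants
  snv_gt <- qc$genotypes
  audit[setdiff(cohort$snv_variants$variant_id, snv$variant_id)] <- "qc"
  # sites alive but with no surviving carrier are dead ends from QC
  if (nrow(snv_gt)) {
    carriers <- tapply(gt_carries_alt(snv_gt$gt), snv_gt$variant_id, any)
    no_carrier <- names(carriers)[!carriers]
  } else no_carrier <- character(0)
  audit[no_carrier] <- "qc"
  snv <- snv[!snv$variant_id %in% no_carrier, , drop = FALSE]

  ## 2. rarity
  if (nrow(snv)) {
    rare <- vapply(seq_len(nrow(snv)), function(i)
      is_rare(c(snv$af_overall[i], snv$af_eas[i]), t), TRUE)
    audit[snv$variant_id[!rare]] <- "rarity"
    snv <- snv[rare, , drop = FALSE]
  }
  sv <- cohort$sv_variants
  if (nrow(sv)) {
    rare_sv <- vapply(seq_len(nrow(sv)), function(i) {
      rec <- sv_record(sv$svtype[i], sv$chrom[i], sv$start[i], sv$end[i])
      afs <- vapply(cohort$panels, function(p) sv_panel_af(rec, p, t), 0)
      is_rare(afs, t)
    }, TRUE)
    audit[sv$variant_id[!rare_sv]] <- "rarity"
    sv <- sv[rare_sv, , drop = FALSE]
  }

  ## 3. classification per (variant, gene)
  cand <- list()
  for (i in seq_len(nrow(snv))) {
    v <- snv[i, ]
    gids <- map_to_genes(v$chrom, v$pos, v$pos, genes)
    for (gid in gids) {
      call <- classify_snv(list(chrom = v$chrom, pos = v$pos), genes[[gid]],
                           list(cadd = v$cadd, spliceai = v$spliceai,
                                eve_damaging = v$eve_damaging,
                                consequence_term = v$consequence_term), t)
      if (call$category != "not_pathogenic")
        cand[[length(cand) + 1L]] <- data.frame(
          variant_id = v$variant_id, gene_id = gid, class = "SNV",
          category = call$category, chrom = v$chrom,
          stringsAsFactors = FALSE)
    }
  }
  sv_cand <- list()
  for (i in seq_len(nrow(sv))) {
    v <- sv[i, ]
    rec <- sv_record(v$svtype, v$chrom, v$start, v$end)
    gids <- map_to_genes(v$chrom, v$start, v$end, genes)
    for (gid in gids) {
      call <- classify_sv(rec, genes[[gid]])
      if (call$category != "not_pathogenic")
        sv_cand[[length(sv_cand) + 1L]] <- data.frame(
          variant_id = v$variant_id, gene_id = gid, class = "SV",
          category = call$category, chrom = v$chrom,
          stringsAsFactors = FALSE)
    }
  }
  classified <- unique(c(vapply(cand, `[[`, "", "variant_id"),
                         vapply(sv_cand, `[[`, "", "variant_id")))
  died <- setdiff(c(snv$variant_id, sv$variant_id), classified)
  audit[died] <- "classification"

  ## 4. TDR filter on SV candidates
  kept_sv <- list()
  for (h in sv_cand) {
    v <- sv[sv$variant_id == h$variant_id, ]
    rec <- sv_record(v$svtype, v$chrom, v$start, v$end)
    tdr <- transcript_disruption_ratio(rec, genes[[h$gene_id]], t)
    if (tdr$verdict == "retain") kept_sv[[length(kept_sv) + 1L]] <- h
  }
  tdr_dead <- setdiff(vapply(sv_cand, `[[`, "", "variant_id"),
                      vapply(kept_sv, `[[`, "", "variant_id"))
  audit[tdr_dead] <- "tdr"
  candidates <- do.call(rbind, c(cand, kept_sv))
  if (is.null(candidates))
    candidates <- data.frame(variant_id = character(0), gene_id = character(0),
                             class = character(0), category = character(0),
                             chrom = character(0))

  ## 5. segregation & diagnosis, per family
  geno_all <- rbind(
    snv_gt[, c("variant_id", "sample_id", "gt")],
    cohort$sv_genotypes[, c("variant_id", "sample_id", "gt")])
  ped <- cohort$pedigree
  reports <- list()
  used <- character(0)
  for (fid in unique(ped$family_id)) {
    fam <- family_members(ped, fid)
    fam_vids <- unique(geno_all$variant_id[geno_all$sample_id %in% fam$id])
    fam_cand <- candidates[candidates$variant_id %in% fam_vids, , drop = FALSE]
    if (nrow(fam_cand) == 0) next
    fam_gt <- geno_all[geno_all$variant_id %in% fam_cand$variant_id &
                         geno_all$sample_id %in% fam$id, , drop = FALSE]
    for (pid in fam$id[fam$affected %in% TRUE]) {
      rep <- diagnose_patient(pid, fam_cand, fam_gt, ped, genes, t)
      if (!is.null(rep)) {
        reports[[pid]] <- rep
        used <- c(used, rep$variants$variant_id)
      }
    }
  }
  audit[intersect(names(audit)[is.na(audit)],
                  candidates$variant_id)] <- "segregation"
  audit[unique(used)] <- "passed"
  audit[is.na(audit)] <- "classification"  # never reached a candidate gene

  n_patients <- sum(ped$affected, na.rm = TRUE)
  list(reports = reports,
       audit = data.frame(variant_id = names(audit), stage = unname(audit),
                          stringsAsFactors = FALSE),
       qc_report = qc$report,
       candidates = candidates,
       summary = cohort_summary(reports, cohort_size = n_patients, t = t))
}

#' Compare pipeline output with a simulated truth set
#'
#' @param result output of [run_pipeline()]
#' @param cohort the simulated `ird_cohort`
#' @return list: `recall` (fraction of truth records recovered with the
#'   correct gene and full causal variant set), `false_positive_genes`
#'   (diagnoses naming a gene not in the truth record for that patient),
#'   and a per-truth-record data.frame
#' @export
score_against_truth <- function(result, cohort) {
  truth <- cohort$truth
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    rep <- result$reports[[tr$patient_id]]
    want <- sort(strsplit(tr$variant_ids, ",")[[1]])
    got_gene <- if (is.null(rep)) NA_character_ else rep$gene_id
    got_vids <- if (is.null(rep)) character(0) else
      sort(rep$variants$variant_id)
    data.frame(family_id = tr$family_id, patient_id = tr$patient_id,
               expected_gene = tr$gene_id, got_gene = got_gene,
               recovered = identical(got_gene, tr$gene_id) &&
                 identical(got_vids, want),
               category_ok = !is.null(rep) &&
                 identical(rep$category, tr$expected_category),
               stringsAsFactors = FALSE)
  })
  per_record <- do.call(rbind, rows)
  fp <- vapply(result$reports, function(r) {
    tr <- truth[truth$patient_id == r$patient_id, ]
    nrow(tr) == 0 || !identical(r$gene_id, tr$gene_id)
  }, TRUE)
  list(recall = mean(per_record$recovered),
       category_accuracy = mean(per_record$category_ok),
       false_positive_genes = sum(fp),
       per_record = per_record)
}
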