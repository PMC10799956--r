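#' Simulation configuration
#'
#' Describes the synthetic cohort world: family structures, the
#' inheritance modes to plant (one causal configuration per family),
#' the background common-variant rate, and the reference-panel /
#' expression parameters. Defaults emulate the structure of a WGS IRD
#' cohort: trio/quad families, dual reference panels (a large European
#' and a smaller East Asian panel), highly expressed main transcripts
#' with a low-TPM minor isoform per gene.
#'
#' @param n_families number of families to simulate
#' @param family_structures named weights over c(trio=, quad=)
#' @param modes_to_plant named nonnegative weights over the seven planted
#'   modes: AD, AR_hom, AR_compound_het_SNV_SV, AR_compound_het_SV_SV,
#'   XL_hemizygous, intronic_AR, intronic_AD
#' @param background_variant_rate expected number of common background
#'   SNVs planted per family
#' @param panel_af_common range of panel AFs for common decoy SVs/SNVs
#'   (all >= 0.01 so they fail the rarity filter)
#' @param tpm_main,tpm_minor TPM ranges for main and minor transcripts
#'   (chosen so a minor-only disruption always falls below the 20% TDR
#'   cutoff and a main-transcript disruption always exceeds it)
#' @param seed RNG seed, recorded in the output manifest
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(
    n_families = 30,
    family_structures = c(trio = 0.6, quad = 0.4),
    modes_to_plant = c(AD = 1, AR_hom = 1, AR_compound_het_SNV_SV = 1,
                       AR_compound_het_SV_SV = 1, XL_hemizygous = 1,
                       intronic_AR = 1, intronic_AD = 1),
    background_variant_rate = 2,
    panel_af_common = c(0.02, 0.3),
    tpm_main = c(50, 200),
    tpm_minor = c(0.1, 2),
    seed = 1L) {
  stopifnot(n_families >= 1, all(modes_to_plant >= 0),
            sum(modes_to_plant) > 0, all(family_structures >= 0),
            panel_af_common[1] >= 0.01)
  modes <- c("AD", "AR_hom", "AR_compound_het_SNV_SV",
             "AR_compound_het_SV_SV", "XL_hemizygous", "intronic_AR",
             "intronic_AD")
  stopifnot(all(names(modes_to_plant) %in% modes))
  structure(list(n_families = n_families,
                 family_structures = family_structures,
                 modes_to_plant = modes_to_plant,
                 background_variant_rate = background_variant_rate,
                 panel_af_common = panel_af_common,
                 tpm_main = tpm_main, tpm_minor = tpm_minor,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Synthetic gene world: fixed coordinates, seeded TPMs. Each gene has a
# main transcript (8 exons of 200 bp every 5 kb) and a minor isoform
# (exons 2-8 plus a private tail exon) so that a tail-exon-only SV
# disrupts a sliver of expression (TDR << 20%) while any main-exon SV
# disrupts the bulk (TDR >> 20%).
synthetic_gene_table <- function() {
  data.frame(
    gene_id = paste0("G", sprintf("%02d", 1:10)),
    symbol = c("RPX1", "RPX2", "RPX3", "RPX4", "CRDX1", "USHX1", "XLX1",
               "STGDX1", "RSX1", "RPX5"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3", "chrX",
              "chr5", "chr4", "chr6"),
    base = c(1e6, 2e6, 1e6, 2e6, 1e6, 2e6, 1e6, 1e6, 1e6, 1e6),
    disease_group = c("RP", "RP", "RP", "RP", "CRD", "Usher",
                      "Choroideremia", "STGD", "Retinoschisis", "RP"),
    modes = c("AD", "AR", "AR", "AR", "AD", "AR", "XL", "AR", "AD", "AD"),
    stringsAsFactors = FALSE)
}

exon_grid <- function(base, n = 8, width = 200, spacing = 5000) {
  start <- base + (seq_len(n) - 1) * spacing
  data.frame(start = start, end = start + width - 1)
}

synthetic_genes <- function(cfg) {
  tab <- synthetic_gene_table()
  genes <- list()
  for (i in seq_len(nrow(tab))) {
    base <- tab$base[i]
    main_ex <- exon_grid(base)
    minor_ex <- rbind(main_ex[2:8, ],
                      data.frame(start = base + 40000, end = base + 40199))
    tpm_main <- stats::runif(1, cfg$tpm_main[1], cfg$tpm_main[2])
    tpm_minor <- stats::runif(1, cfg$tpm_minor[1], cfg$tpm_minor[2])
    gid <- tab$gene_id[i]
    genes[[gid]] <- gene_model(
      gid, tab$symbol[i], tab$chrom[i],
      list(transcript_model(paste0(gid, "_T1"), gid, "+", main_ex, tpm_main),
           transcript_model(paste0(gid, "_T2"), gid, "+", minor_ex, tpm_minor)),
      disease_group = tab$disease_group[i],
      inheritance_modes = strsplit(tab$modes[i], ",")[[1]])
  }
  structure(genes, class = "gene_model_set", skipped = character(0))
}

rand_base <- function(n = 1, exclude = NULL) {
  b <- c("A", "C", "G", "T")
  if (!is.null(exclude)) b <- setdiff(b, exclude)
  sample(b, n, replace = TRUE)
}

geno_metrics <- function(gt) {
  cls <- gt_class(gt)
  ab <- switch(cls,
               het = stats::runif(1, 0.40, 0.60),
               hom_alt = stats::runif(1, 0.95, 1.0),
               hemi_alt = stats::runif(1, 0.95, 1.0),
               ref = stats::runif(1, 0, 0.02),
               hemi_ref = stats::runif(1, 0, 0.02),
               NA_real_)
  list(dp = sample(20:60, 1), gq = sample(60:99, 1), ab = ab)
}

#' Simulate a synthetic IRD cohort with planted causal variants
#'
#' Deterministic given the config seed. Each family receives one planted
#' causal configuration (its inheritance mode drawn from
#' `modes_to_plant`; mode counts are allocated proportionally so every
#' positively weighted mode is represented when `n_families` allows) plus
#' decoy variants exercising the three rejection routes: common variants
#' (fail the dual-panel rarity filter), rare SVs disrupting only a
#' low-TPM transcript (fail the 20% TDR cutoff), and rare exonic SVs
#' carried by an unaffected parent (fail segregation), along with a
#' QC-failing genotype and an unscored-benign SNV. Planted causal
#' genotypes are Mendelian-consistent: compound-het alleles arrive one
#' per parental haplotype, each unaffected parent carrying exactly one;
#' unaffected relatives never carry the full causal genotype. Causal
#' variants are absent from both reference panels and always pass QC,
#' rarity, classification, and (for SVs) the TDR stage by construction.
#'
#' @param cfg a [simulation_config()]
#' @return an object of class `ird_cohort`: pedigree, gene models, SNV
#'   and SV variant/genotype tables, reference panels, truth set, decoy
#'   ledger and a manifest (seed, counts)
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- synthetic_genes(cfg)
  tab <- synthetic_gene_table()
  base_of <- stats::setNames(tab$base, tab$gene_id)
  chrom_of <- stats::setNames(tab$chrom, tab$gene_id)

  # proportional mode allocation (largest remainder), then shuffle
  w <- cfg$modes_to_plant[cfg$modes_to_plant > 0]
  quota <- cfg$n_families * w / sum(w)
  counts <- floor(quota)
  rem <- cfg$n_families - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  fam_modes <- sample(rep(names(counts), counts))

  ped_rows <- list(); snv_rows <- list(); snv_gt <- list()
  sv_rows <- list(); sv_gt <- list(); truth_rows <- list()
  decoy_rows <- list()
  mode_gene <- c(AD = "G01", AR_hom = "G02", AR_compound_het_SNV_SV = "G03",
                 AR_compound_het_SV_SV = "G04", XL_hemizygous = "G07",
                 intronic_AR = "G06", intronic_AD = "G05")

  add_snv <- function(fid, vid, gid, pos, consequence, cadd, spliceai, eve,
                      af1, af2, gts, metrics = NULL) {
    ref <- rand_base(1)
    snv_rows[[length(snv_rows) + 1L]] <<- data.frame(
      variant_id = vid, chrom = chrom_of[[gid]], pos = pos, ref = ref,
      alt = rand_base(1, exclude = ref), gene_hint = gid,
      cadd = cadd, spliceai = spliceai, eve_damaging = eve,
      consequence_term = consequence, af_overall = af1, af_eas = af2,
      in_lcr = FALSE, inbreeding_coef = 0, hwe_p = 0.5, vqsr_pass = TRUE,
      stringsAsFactors = FALSE)
    for (sid in names(gts)) {
      m <- if (!is.null(metrics) && sid %in% names(metrics))
        metrics[[sid]] else geno_metrics(gts[[sid]])
      snv_gt[[length(snv_gt) + 1L]] <<- data.frame(
        variant_id = vid, sample_id = sid, gt = gts[[sid]],
        dp = m$dp, gq = m$gq, ab = m$ab, stringsAsFactors = FALSE)
    }
  }
  add_sv <- function(vid, gid, start, end, svtype, gts) {
    sv_rows[[length(sv_rows) + 1L]] <<- data.frame(
      variant_id = vid, chrom = chrom_of[[gid]], start = start, end = end,
      svtype = svtype, gene_hint = gid, stringsAsFactors = FALSE)
    for (sid in names(gts))
      sv_gt[[length(sv_gt) + 1L]] <<- data.frame(
        variant_id = vid, sample_id = sid, gt = gts[[sid]],
        stringsAsFactors = FALSE)
  }

  for (f in seq_len(cfg$n_families)) {
    fid <- sprintf("FAM%03d", f)
    mode <- fam_modes[f]
    quad <- stats::runif(1) < cfg$family_structures["quad"] /
      sum(cfg$family_structures)
    father <- paste0(fid, "_F"); mother <- paste0(fid, "_M")
    proband <- paste0(fid, "_C1"); sib <- paste0(fid, "_C2")
    proband_sex <- sample(c("M", "F"), 1)
    if (mode == "XL_hemizygous" && proband_sex == "F") {
      message(fid, ": XL mode requires a male proband; resampling structure")
      proband_sex <- "M"
    }
    members <- c(father, mother, proband)
    sexes <- c("M", "F", proband_sex)
    if (quad) { members <- c(members, sib); sexes <- c(sexes, sample(c("M", "F"), 1)) }
    ped_rows[[f]] <- data.frame(
      family_id = fid, id = members,
      father = c(NA, NA, father, if (quad) father),
      mother = c(NA, NA, mother, if (quad) mother),
      sex = sexes, affected = c(FALSE, FALSE, TRUE, if (quad) FALSE),
      stringsAsFactors = FALSE)
    sib_sex <- if (quad) sexes[4] else NA

    gid <- mode_gene[[mode]]
    base <- base_of[[gid]]
    vnum <- 0L
    vid <- function() { vnum <<- vnum + 1L; sprintf("%s_V%02d", fid, vnum) }
    all_ref <- function(hemi_for = character(0)) {
      g <- stats::setNames(rep("0/0", length(members)), members)
      g[hemi_for] <- "0"
      g
    }

    truth_vids <- character(0)
    if (mode == "AD") {
      v <- vid(); truth_vids <- v
      gts <- all_ref(); gts[proband] <- "0/1"  # de novo
      add_sv(v, gid, base + 9500, base + 10699, "DEL", gts)
      category <- "SV_only"; dx_mode <- "AD"
    } else if (mode == "AR_hom") {
      v <- vid(); truth_vids <- v
      gts <- all_ref(); gts[father] <- gts[mother] <- "0/1"
      gts[proband] <- "1/1"
      if (quad) gts[sib] <- sample(c("0/0", "0/1"), 1)
      add_sv(v, gid, base + 9500, base + 10699, "DEL", gts)
      category <- "SV_only"; dx_mode <- "AR_hom"
    } else if (mode == "AR_compound_het_SNV_SV") {
      v1 <- vid(); v2 <- vid(); truth_vids <- c(v1, v2)
      gts1 <- all_ref(); gts1[mother] <- gts1[proband] <- "0/1"
      add_snv(fid, v1, gid, base + 20050, "stop_gained",
              cadd = stats::runif(1, 35, 45), spliceai = 0.01, eve = FALSE,
              af1 = 0, af2 = 0, gts = gts1)
      gts2 <- all_ref(); gts2[father] <- gts2[proband] <- "0/1"
      if (quad) { w <- sample(c("none", "v1", "v2"), 1)
        if (w == "v1") gts1[sib] <- "0/1" else if (w == "v2") gts2[sib] <- "0/1" }
      add_sv(v2, gid, base + 4700, base + 5400, "DEL", gts2)
      category <- "SNV_plus_SV"; dx_mode <- "AR_compound_het"
    } else if (mode == "AR_compound_het_SV_SV") {
      v1 <- vid(); v2 <- vid(); truth_vids <- c(v1, v2)
      gts1 <- all_ref(); gts1[mother] <- gts1[proband] <- "0/1"
      gts2 <- all_ref(); gts2[father] <- gts2[proband] <- "0/1"
      if (quad && stats::runif(1) < 0.5) gts1[sib] <- "0/1"
      add_sv(v1, gid, base + 4700, base + 5400, "DEL", gts1)
      add_sv(v2, gid, base + 24700, base + 25400, "DEL", gts2)
      category <- "SV_only"; dx_mode <- "AR_compound_het"
    } else if (mode == "XL_hemizygous") {
      v <- vid(); truth_vids <- v
      males <- members[sexes == "M"]
      gts <- all_ref(hemi_for = males)
      gts[mother] <- "0/1"  # carrier mother
      gts[proband] <- "1"
      if (quad && sib_sex == "F") gts[sib] <- sample(c("0/0", "0/1"), 1)
      add_sv(v, gid, base + 9500, base + 10699, "DEL", gts)
      category <- "SV_only"; dx_mode <- "XL_hemizygous"
    } else if (mode == "intronic_AR") {
      v <- vid(); truth_vids <- v
      gts <- all_ref(); gts[father] <- gts[mother] <- "0/1"
      gts[proband] <- "1/1"
      if (quad) gts[sib] <- sample(c("0/0", "0/1"), 1)
      off <- sample(150:2000, 1)  # deep intronic: >= 100 bp from exon 4
      add_snv(fid, v, gid, base + 15199 + off, "intron_variant",
              cadd = stats::runif(1, 2, 10),
              spliceai = stats::runif(1, 0.7, 0.99), eve = FALSE,
              af1 = 0, af2 = 0, gts = gts)
      category <- "intronic"; dx_mode <- "AR_hom"
    } else if (mode == "intronic_AD") {
      v <- vid(); truth_vids <- v
      gts <- all_ref(); gts[proband] <- "0/1"  # de novo
      off <- if (stats::runif(1) < 0.5) sample(150:2000, 1) else
        sample(5:50, 1)  # deep or non-canonical splice territory
      add_snv(fid, v, gid, base + 15199 + off, "intron_variant",
              cadd = stats::runif(1, 2, 10),
              spliceai = stats::runif(1, 0.7, 0.99), eve = FALSE,
              af1 = 0, af2 = 0, gts = gts)
      category <- "intronic"; dx_mode <- "AD"
    }
    truth_rows[[f]] <- data.frame(
      family_id = fid, patient_id = proband, gene_id = gid,
      variant_ids = paste(truth_vids, collapse = ","), mode = mode,
      dx_mode = dx_mode, expected_category = category,
      stringsAsFactors = FALSE)

    # --- decoys -----------------------------------------------------
    # (a) common SV in G08, matched by the reference panels -> rarity
    v <- vid()
    gts <- all_ref(); gts[proband] <- "0/1"
    add_sv(v, "G08", base_of[["G08"]] + 14800, base_of[["G08"]] + 15399,
           "DEL", gts)
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      family_id = fid, variant_id = v, kind = "common_sv",
      expected_fail_stage = "rarity", stringsAsFactors = FALSE)
    # (b) rare SV hitting only the low-TPM tail isoform of G09 -> TDR
    v <- vid()
    gts <- all_ref(); gts[proband] <- "0/1"
    add_sv(v, "G09", base_of[["G09"]] + 39800, base_of[["G09"]] + 40100,
           "DEL", gts)
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      family_id = fid, variant_id = v, kind = "low_tdr_sv",
      expected_fail_stage = "tdr", stringsAsFactors = FALSE)
    # (c) rare exonic SV shared with the unaffected father -> segregation
    v <- vid()
    gts <- all_ref(); gts[proband] <- gts[father] <- "0/1"
    add_sv(v, "G10", base_of[["G10"]] + 19800, base_of[["G10"]] + 20399,
           "DEL", gts)
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      family_id = fid, variant_id = v, kind = "unaffected_carrier_sv",
      expected_fail_stage = "segregation", stringsAsFactors = FALSE)
    # (d) common background SNVs -> rarity
    n_bg <- max(1L, stats::rpois(1, cfg$background_variant_rate))
    for (b in seq_len(n_bg)) {
      v <- vid()
      gts <- all_ref()
      for (sid in members) gts[sid] <- sample(c("0/0", "0/1"), 1)
      if (!any(gts == "0/1")) gts[proband] <- "0/1"
      add_snv(fid, v, "G08", base_of[["G08"]] + 30000 + sample(0:199, 1),
              "missense_variant", cadd = stats::runif(1, 15, 35),
              spliceai = 0.01, eve = FALSE,
              af1 = stats::runif(1, cfg$panel_af_common[1], cfg$panel_af_common[2]),
              af2 = stats::runif(1, cfg$panel_af_common[1], cfg$panel_af_common[2]),
              gts = gts)
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        family_id = fid, variant_id = v, kind = "common_snv",
        expected_fail_stage = "rarity", stringsAsFactors = FALSE)
    }
    # (e) rare nonsense with a failing genotype (DP = 5) -> QC mask
    v <- vid()
    gts <- all_ref(); gts[proband] <- "0/1"
    add_snv(fid, v, "G10", base_of[["G10"]] + 5050, "stop_gained",
            cadd = 40, spliceai = 0.01, eve = FALSE, af1 = 0, af2 = 0,
            gts = gts,
            metrics = stats::setNames(
              list(list(dp = 5, gq = 70, ab = 0.5)), proband))
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      family_id = fid, variant_id = v, kind = "low_dp_snv",
      expected_fail_stage = "qc", stringsAsFactors = FALSE)
    # (f) rare benign missense (below CADD/EVE cutoffs) -> classification
    v <- vid()
    gts <- all_ref(); gts[proband] <- "0/1"
    add_snv(fid, v, "G10", base_of[["G10"]] + 25100, "missense_variant",
            cadd = stats::runif(1, 2, 10), spliceai = 0.01, eve = FALSE,
            af1 = 0, af2 = 0, gts = gts)
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      family_id = fid, variant_id = v, kind = "benign_missense",
      expected_fail_stage = "classification", stringsAsFactors = FALSE)
  }

  # reference panels: the common G08 SV is present in both at AF >= 1%;
  # causal and rare-decoy SVs are absent; extra panel-only records
  # exercise benign-set construction
  g08 <- base_of[["G08"]]
  mk_panel <- function(panel_id, n, af_common) {
    an <- 2 * n
    svs <- data.frame(
      chrom = c(chrom_of[["G08"]], chrom_of[["G08"]], "chr7"),
      start = c(g08 + 14800, g08 + 24950, 5e6),
      end = c(g08 + 15399, g08 + 25249, 5.1e6),
      svtype = "DEL",
      ac = c(round(af_common * an), 1L, round(0.05 * an)),
      an = an,
      carrier_n = c(round(af_common * an), 1L, round(0.05 * an)),
      stringsAsFactors = FALSE)
    panel_summary(panel_id, n, svs)
  }
  panels <- list(EUR = mk_panel("EUR", 831, 0.05),
                 EAS = mk_panel("EAS", 196, 0.02))

  cohort <- structure(list(
    config = cfg,
    pedigree = pedigree(do.call(rbind, ped_rows)),
    genes = genes,
    snv_variants = do.call(rbind, snv_rows),
    snv_genotypes = do.call(rbind, snv_gt),
    sv_variants = do.call(rbind, sv_rows),
    sv_genotypes = do.call(rbind, sv_gt),
    panels = panels,
    truth = do.call(rbind, truth_rows),
    decoys = do.call(rbind, decoy_rows)),
    class = "ird_cohort")
  cohort$manifest <- list(
    seed = cfg$seed, n_families = cfg$n_families,
    n_individuals = nrow(cohort$pedigree),
    n_snv = nrow(cohort$snv_variants), n_sv = nrow(cohort$sv_variants),
    mode_counts = as.list(table(fam_modes)),
    panel_sizes = lapply(panels, `[[`, "n_samples"),
    config = unclass(cfg),
    hash = cohort_hash(cohort))
  cohort
}

#' Deterministic content hash of a cohort (manifest equality checks)
#' @param cohort an `ird_cohort`
#' @return md5 hex string of the serialized cohort payload
#' @export
cohort_hash <- function(cohort) {
  payload <- cohort[c("pedigree", "snv_variants", "snv_genotypes",
                      "sv_variants", "sv_genotypes", "truth", "decoys")]
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(payload, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @export
print.ird_cohort <- function(x, ...) {
  cat(sprintf("<ird_cohort> %d families / %d individuals, %d SNVs, %d SVs, seed %d\n",
              x$config$n_families, nrow(x$pedigree), nrow(x$snv_variants),
              nrow(x$sv_variants), x$config$seed))
  invisible(x)
}
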