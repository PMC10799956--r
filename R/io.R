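# File-format boundaries. Internal coordinates are 1-based inclusive;
# VCF POS is already 1-based, BED converters live in intervals.R. VCF
# writing is plain text (simple, fully specified headers); reading goes
# through VariantAnnotation so round-trips are checked by an independent
# parser.

#' Write a 6-column PED file
#' @param ped a [pedigree()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ped <- function(ped, path) {
  df <- data.frame(
    family_id = ped$family_id, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(ped$sex == "M", 1L, 2L),
    phenotype = ifelse(ped$affected, 2L, 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column PED file
#' @param path PED file path
#' @return a [pedigree()]
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("family_id", "id", "father",
                                        "mother", "sex", "affected"),
                          colClasses = "character")
  pedigree(df)
}

vcf_format_gt <- function(gt, dp, gq, ab) {
  fmt <- function(x, digits = NULL) {
    ifelse(is.na(x), ".",
           if (is.null(digits)) as.character(x) else
             formatC(x, digits = digits, format = "g"))
  }
  paste(gt, fmt(dp), fmt(gq), fmt(ab, 4), sep = ":")
}

#' Write small-variant records to a multi-sample VCF
#'
#' Site annotations (panel AFs, CADD, SpliceAI, EVE flag, consequence
#' term, site-QC metrics) are carried in INFO; genotypes as GT:DP:GQ:AB.
#'
#' @param variants SNV/indel table (variant_id, chrom, pos, ref, alt,
#'   plus annotation and site-QC columns)
#' @param genotypes long genotype table (variant_id, sample_id, gt, dp,
#'   gq, ab)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_snv_vcf <- function(variants, genotypes, path) {
  samples <- sort(unique(genotypes$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=irddx",
    "##INFO=<ID=AF_OVERALL,Number=1,Type=Float,Description=\"Panel AF, overall population\">",
    "##INFO=<ID=AF_EAS,Number=1,Type=Float,Description=\"Panel AF, East Asian population\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"Scaled CADD score\">",
    "##INFO=<ID=SPLICEAI,Number=1,Type=Float,Description=\"SpliceAI max delta score\">",
    "##INFO=<ID=EVE,Number=0,Type=Flag,Description=\"EVE damaging\">",
    "##INFO=<ID=CSQT,Number=1,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=LCR,Number=0,Type=Flag,Description=\"Low complexity region\">",
    "##INFO=<ID=IC,Number=1,Type=Float,Description=\"Inbreeding coefficient\">",
    "##INFO=<ID=HWE,Number=1,Type=Float,Description=\"Hardy-Weinberg p-value\">",
    "##FILTER=<ID=VQSRFail,Description=\"Failed VQSR\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance (alt fraction)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    num <- function(x) if (is.null(x) || is.na(x)) NULL else
      formatC(x, digits = 6, format = "g")
    info <- c(
      if (!is.null(v$af_overall)) paste0("AF_OVERALL=", num(v$af_overall)),
      if (!is.null(v$af_eas)) paste0("AF_EAS=", num(v$af_eas)),
      if (!is.na(v$cadd)) paste0("CADD=", num(v$cadd)),
      if (!is.na(v$spliceai)) paste0("SPLICEAI=", num(v$spliceai)),
      if (isTRUE(v$eve_damaging)) "EVE",
      if (!is.na(v$consequence_term)) paste0("CSQT=", v$consequence_term),
      if (isTRUE(v$in_lcr)) "LCR",
      if (!is.na(v$inbreeding_coef)) paste0("IC=", num(v$inbreeding_coef)),
      if (!is.na(v$hwe_p)) paste0("HWE=", num(v$hwe_p)))
    info <- paste(info, collapse = ";")
    if (!nzchar(info)) info <- "."
    filt <- if (isTRUE(v$vqsr_pass)) "PASS" else "VQSRFail"
    g <- genotypes[genotypes$variant_id == v$variant_id, , drop = FALSE]
    g <- g[match(samples, g$sample_id), , drop = FALSE]
    cells <- ifelse(is.na(g$gt), "./.:.:.:.",
                    vcf_format_gt(g$gt, g$dp, g$gq, g$ab))
    paste(c(v$chrom, format(v$pos, scientific = FALSE), v$variant_id,
            v$ref, v$alt, ".", filt, info, "GT:DP:GQ:AB", cells),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write SV records to a multi-sample VCF (symbolic ALT, SVTYPE/END INFO)
#' @param variants SV table (variant_id, chrom, start, end, svtype)
#' @param genotypes long genotype table (variant_id, sample_id, gt)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sv_vcf <- function(variants, genotypes, path) {
  samples <- sort(unique(genotypes$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=irddx",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end (1-based inclusive)\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  ord <- order(variants$chrom, variants$start)
  variants <- variants[ord, , drop = FALSE]
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g <- genotypes[genotypes$variant_id == v$variant_id, , drop = FALSE]
    g <- g[match(samples, g$sample_id), , drop = FALSE]
    cells <- ifelse(is.na(g$gt), "./.", g$gt)
    paste(c(v$chrom, format(v$start, scientific = FALSE), v$variant_id,
            "N", paste0("<", v$svtype, ">"), ".", "PASS",
            paste0("SVTYPE=", v$svtype, ";END=",
                   format(v$end, scientific = FALSE)),
            "GT", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

vcf_geno_long <- function(vcf, fields) {
  gt <- VariantAnnotation::geno(vcf)$GT
  vids <- rownames(gt)
  samples <- colnames(gt)
  out <- data.frame(
    variant_id = rep(vids, times = length(samples)),
    sample_id = rep(samples, each = length(vids)),
    gt = as.vector(gt), stringsAsFactors = FALSE)
  for (f in fields) {
    m <- VariantAnnotation::geno(vcf)[[f]]
    out[[tolower(f)]] <- if (is.null(m)) NA else as.vector(m)
  }
  out
}

info_col <- function(vcf, key, default = NA) {
  inf <- VariantAnnotation::info(vcf)
  if (!key %in% names(inf)) return(rep(default, nrow(inf)))
  v <- inf[[key]]
  if (is.logical(v)) return(v)
  v <- as.vector(v)
  ifelse(is.na(v), default, v)
}

#' Read a small-variant VCF written by [write_snv_vcf()]
#' @param path VCF path
#' @return list(variants, genotypes) matching the internal table layout
#' @export
read_snv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1], "")
  variants <- data.frame(
    variant_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF), alt = alt,
    af_overall = info_col(vcf, "AF_OVERALL", 0),
    af_eas = info_col(vcf, "AF_EAS", 0),
    cadd = info_col(vcf, "CADD"),
    spliceai = info_col(vcf, "SPLICEAI"),
    eve_damaging = info_col(vcf, "EVE", FALSE),
    consequence_term = info_col(vcf, "CSQT", NA_character_),
    in_lcr = info_col(vcf, "LCR", FALSE),
    inbreeding_coef = info_col(vcf, "IC"),
    hwe_p = info_col(vcf, "HWE"),
    vqsr_pass = !grepl("VQSRFail", rr$FILTER),
    stringsAsFactors = FALSE)
  genotypes <- vcf_geno_long(vcf, c("DP", "GQ", "AB"))
  rownames(variants) <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Read an SV VCF written by [write_sv_vcf()]
#' @param path VCF path
#' @return list(variants, genotypes)
#' @export
read_sv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    variant_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr),
    end = as.vector(info_col(vcf, "END")),
    svtype = as.vector(info_col(vcf, "SVTYPE", NA_character_)),
    stringsAsFactors = FALSE)
  genotypes <- vcf_geno_long(vcf, character(0))
  rownames(variants) <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits small-variant and SV VCFs, a PED file, a GTF of the synthetic
#' gene models, TSVs for the expression table, candidate panel, reference
#' panels and truth set, and a JSON manifest recording the seed and
#' configuration.
#'
#' @param cohort an `ird_cohort` from [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ird_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_ped(cohort$pedigree, p("cohort.ped"))
  write_snv_vcf(cohort$snv_variants, cohort$snv_genotypes, p("snv.vcf"))
  write_sv_vcf(cohort$sv_variants, cohort$sv_genotypes, p("sv.vcf"))
  write_gene_models_gtf(cohort$genes, p("genes.gtf"))
  write_expression_table(cohort$genes, p("expression.tsv"))
  write_panel_table(cohort$genes, p("panel.tsv"))
  for (pn in names(cohort$panels))
    utils::write.table(cohort$panels[[pn]]$svs, p(paste0("refpanel_", pn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$decoys, p("decoys.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(ped = p("cohort.ped"), snv = p("snv.vcf"), sv = p("sv.vcf"),
             gtf = p("genes.gtf"), expression = p("expression.tsv"),
             panel = p("panel.tsv"), truth = p("truth.tsv"),
             manifest = p("manifest.json"))
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Reassembles an `ird_cohort` from the on-disk standard formats (PED,
#' VCFs, GTF, TSVs, JSON manifest), suitable for [run_pipeline()].
#'
#' @param dir cohort directory
#' @return an `ird_cohort`
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  man <- jsonlite::fromJSON(p("manifest.json"))
  cfg <- do.call(simulation_config,
                 lapply(man$config, function(x) if (is.list(x)) unlist(x) else x))
  snv <- read_snv_vcf(p("snv.vcf"))
  sv <- read_sv_vcf(p("sv.vcf"))
  panels <- list()
  for (f in list.files(dir, pattern = "^refpanel_.*\\.tsv$")) {
    pid <- sub("^refpanel_(.*)\\.tsv$", "\\1", f)
    svs <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
    svs$af <- NULL  # recomputed from ac/an by panel_summary
    panels[[pid]] <- panel_summary(pid, man$panel_sizes[[pid]], svs)
  }
  read_if <- function(f) if (file.exists(p(f)))
    utils::read.delim(p(f), stringsAsFactors = FALSE) else NULL
  cohort <- structure(list(
    config = cfg,
    pedigree = read_ped(p("cohort.ped")),
    genes = load_gene_models(p("genes.gtf"), p("expression.tsv"),
                             p("panel.tsv")),
    snv_variants = snv$variants, snv_genotypes = snv$genotypes,
    sv_variants = sv$variants, sv_genotypes = sv$genotypes,
    panels = panels,
    truth = read_if("truth.tsv"),
    decoys = read_if("decoys.tsv"),
    manifest = man), class = "ird_cohort")
  cohort
}
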