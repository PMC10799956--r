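#' Transcript model
#'
#' @param transcript_id,gene_id identifiers
#' @param strand "+" or "-"
#' @param exons data.frame with columns start, end (1-based inclusive);
#'   exons must be non-overlapping and are stored sorted by start
#' @param tpm nonnegative retina expression level (TPM)
#' @return an object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, strand, exons, tpm = 0) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end))
    stop("malformed exon: start > end")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap within transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.na(tpm) || tpm < 0) stop("tpm must be >= 0")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 strand = strand, exons = exons, tpm = as.numeric(tpm)),
            class = "transcript_model")
}

#' Gene model
#'
#' A gene with its transcript structures, disease-group assignment and
#' permitted inheritance modes (from the candidate gene panel).
#'
#' @param gene_id,symbol identifiers
#' @param chrom chromosome (normalized to "chrN")
#' @param transcripts list of `transcript_model`
#' @param disease_group one of RP, CRD, STGD, Retinoschisis, Choroideremia,
#'   Usher, other
#' @param inheritance_modes subset of c("AD", "AR", "XL")
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, symbol, chrom, transcripts,
                       disease_group = "other",
                       inheritance_modes = c("AD", "AR")) {
  stopifnot(length(transcripts) >= 1,
            all(vapply(transcripts, inherits, TRUE, "transcript_model")))
  disease_group <- match.arg(disease_group, disease_groups())
  inheritance_modes <- match.arg(inheritance_modes, c("AD", "AR", "XL"),
                                 several.ok = TRUE)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, symbol = symbol,
                 chrom = normalize_chrom(chrom),
                 transcripts = transcripts,
                 disease_group = disease_group,
                 inheritance_modes = inheritance_modes),
            class = "gene_model")
}

#' Recognized disease groups
#' @return character vector of valid disease-group labels
#' @export
disease_groups <- function() {
  c("RP", "CRD", "STGD", "Retinoschisis", "Choroideremia", "Usher", "other")
}

#' Gene span: union of all transcript spans
#' @param gene a `gene_model`
#' @return a `genomic_interval` covering all transcripts
#' @export
gene_span <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  starts <- vapply(gene$transcripts, function(tx) min(tx$exons$start), 0)
  ends <- vapply(gene$transcripts, function(tx) max(tx$exons$end), 0)
  genomic_interval(gene$chrom, min(starts), max(ends))
}

#' Total retina expression of a gene (sum of transcript TPMs)
#' @param gene a `gene_model`
#' @return numeric TPM sum
#' @export
gene_total_tpm <- function(gene) {
  sum(vapply(gene$transcripts, `[[`, 0, "tpm"))
}

#' @export
print.gene_model <- function(x, ...) {
  span <- gene_span(x)
  cat(sprintf("<gene_model> %s (%s) %s:%s-%s | %s | %s | %d transcript(s), %.3g TPM\n",
              x$symbol, x$gene_id, span$chrom,
              format(span$start, scientific = FALSE),
              format(span$end, scientific = FALSE),
              x$disease_group, paste(x$inheritance_modes, collapse = "/"),
              length(x$transcripts), gene_total_tpm(x)))
  invisible(x)
}

#' Load gene models from GTF, expression table and candidate panel
#'
#' Reads a Gencode-dialect GTF (exon features with gene_id/transcript_id
#' attributes), a two-column expression TSV (transcript_id, tpm) and a
#' candidate-panel TSV (symbol, gene_id, disease_group, inheritance_modes
#' comma-separated). Only panel genes are loaded. Transcripts absent from
#' the expression table get TPM 0 with a warning; panel genes absent from
#' the gene models are recorded in the `skipped` attribute, not fatal.
#'
#' @param gene_model_file path to a GTF file
#' @param expression_table path to a TSV with columns transcript_id, tpm
#' @param panel_file path to a TSV with columns symbol, gene_id,
#'   disease_group, inheritance_modes
#' @return a named list of `gene_model` (class `gene_model_set`) with
#'   attribute `skipped` listing panel genes missing from the GTF
#' @export
load_gene_models <- function(gene_model_file, expression_table, panel_file) {
  panel <- utils::read.delim(panel_file, stringsAsFactors = FALSE)
  need <- c("symbol", "gene_id", "disease_group", "inheritance_modes")
  if (!all(need %in% names(panel)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  expr <- utils::read.delim(expression_table, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "tpm") %in% names(expr)))
    stop("expression table must have columns transcript_id, tpm")
  tpm <- stats::setNames(as.numeric(expr$tpm), expr$transcript_id)

  gtf <- rtracklayer::import(gene_model_file, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    stringsAsFactors = FALSE)

  missing_tpm <- character(0)
  genes <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(panel))) {
    gid <- panel$gene_id[i]
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    if (nrow(gdf) == 0) { skipped <- c(skipped, gid); next }
    txs <- lapply(split(gdf, gdf$transcript_id), function(t) {
      tid <- t$transcript_id[1]
      tv <- unname(tpm[tid])
      if (is.na(tv)) { missing_tpm <<- c(missing_tpm, tid); tv <- 0 }
      strand <- t$strand[1]
      if (!strand %in% c("+", "-")) strand <- "+"
      transcript_model(tid, gid, strand,
                       t[, c("start", "end"), drop = FALSE], tv)
    })
    modes <- strsplit(panel$inheritance_modes[i], ",")[[1]]
    genes[[gid]] <- gene_model(
      gid, panel$symbol[i], gdf$chrom[1], unname(txs),
      disease_group = panel$disease_group[i],
      inheritance_modes = trimws(modes))
  }
  if (length(missing_tpm))
    warning(length(missing_tpm),
            " transcript(s) absent from expression table; TPM set to 0: ",
            paste(utils::head(unique(missing_tpm), 5), collapse = ", "))
  if (length(skipped))
    message(length(skipped), " panel gene(s) absent from gene models (skipped)")
  structure(genes, class = "gene_model_set", skipped = skipped)
}

#' Write gene models to a Gencode-dialect GTF file
#' @param genes a `gene_model_set` or list of `gene_model`
#' @param path output GTF path
#' @return `path`, invisibly
#' @export
write_gene_models_gtf <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    for (tx in g$transcripts) {
      n <- nrow(tx$exons)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = tx$exons$start, end = tx$exons$end,
        strand = tx$strand, type = "exon", gene_id = g$gene_id,
        transcript_id = tx$transcript_id, gene_name = g$symbol,
        exon_number = seq_len(n), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$source <- "irddx"
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$gene_name <- df$gene_name
  gr$exon_number <- df$exon_number
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write the expression table (transcript_id, tpm) for a gene set
#' @param genes a `gene_model_set`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_expression_table <- function(genes, path) {
  rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(transcript_id = vapply(g$transcripts, `[[`, "", "transcript_id"),
               tpm = vapply(g$transcripts, `[[`, 0, "tpm"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the candidate-panel table for a gene set
#' @param genes a `gene_model_set`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_panel_table <- function(genes, path) {
  rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(symbol = g$symbol, gene_id = g$gene_id,
               disease_group = g$disease_group,
               inheritance_modes = paste(g$inheritance_modes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
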