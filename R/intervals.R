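#' Genomic interval (1-based, fully inclusive)
#'
#' All coordinates in this package are 1-based and inclusive at both ends,
#' matching the conventional printed style `chr20:25313454-25555587`
#' (length = end - start + 1). Converters at VCF/BED boundaries are
#' explicit ([bed_to_interval()], [interval_to_bed()]).
#'
#' @param chrom chromosome name; normalized to "chrN" form
#' @param start,end 1-based inclusive positions, start <= end
#' @return an object of class `genomic_interval`
#' @examples
#' genomic_interval("chr1", 100, 199)
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    stop("chrom must be a single nonempty string")
  if (is.na(start) || is.na(end)) stop("start/end must be numeric")
  if (start > end)
    stop(sprintf("malformed interval: start (%s) > end (%s)", start, end))
  if (start < 1) stop("positions are 1-based; start must be >= 1")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(interval_length(x), scientific = FALSE)))
  invisible(x)
}

#' Normalize chromosome names to "chrN" form
#'
#' `"1"` -> `"chr1"`, `"chrx"` -> `"chrX"`, `"MT"` -> `"chrM"`.
#' @param chrom character vector of chromosome names
#' @return normalized character vector
#' @export
normalize_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  bare <- sub("^[Cc][Hh][Rr]", "", chrom)
  bare <- ifelse(toupper(bare) %in% c("X", "Y"), toupper(bare), bare)
  bare <- ifelse(toupper(bare) %in% c("M", "MT"), "M", bare)
  ifelse(is.na(chrom) | !nzchar(bare), NA_character_, paste0("chr", bare))
}

#' Parse a printed genomic position or interval
#'
#' Accepts `"chr4:633534-637421"`, single positions `"chr6:63964152"`,
#' en-dash separators, and the lenient `"chrX-18644599-18650206"` style in
#' which the chromosome is followed by "-" instead of ":" (a typo pattern
#' observed in published tables).
#'
#' @param x a single position/interval string
#' @return a `genomic_interval` (start == end for single positions)
#' @export
parse_position <- function(x) {
  s <- gsub("–|—", "-", trimws(x))  # en/em dash -> hyphen
  m <- regmatches(s, regexec("^(chr[0-9XYM]+|[0-9XYM]+)[:-]([0-9,]+)(?:-([0-9,]+))?$",
                             s, ignore.case = TRUE))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse genomic position: '%s'", x))
  strip <- function(v) as.numeric(gsub(",", "", v))
  start <- strip(m[3])
  end <- if (is.na(m[4]) || !nzchar(m[4])) start else strip(m[4])
  genomic_interval(m[2], start, end)
}

#' Interval length in bp
#' @param x a `genomic_interval`
#' @return integer length (end - start + 1)
#' @export
interval_length <- function(x) x$end - x$start + 1

#' Overlap between two intervals, in base pairs
#'
#' Size of the intersection under 1-based inclusive coordinates;
#' 0 when the chromosomes differ. Symmetric in its arguments and bounded
#' by the shorter interval's length.
#'
#' @param a,b `genomic_interval` objects
#' @return nonnegative number of overlapping bases
#' @examples
#' overlap_bp(genomic_interval("chr1", 100, 199),
#'            genomic_interval("chr1", 150, 249))  # 50
#' @export
overlap_bp <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
}

#' Does an SV span an entire gene?
#'
#' TRUE iff the SV interval contains the full gene span (boundaries
#' inclusive) on the same chromosome. Used by the inversion pathogenicity
#' rule: an inversion that swallows a whole gene leaves its transcripts
#' intact and is not called exon-disrupting.
#'
#' @param sv a `genomic_interval`
#' @param gene a `gene_model`
#' @return logical
#' @export
spans_whole_gene <- function(sv, gene) {
  stopifnot(inherits(sv, "genomic_interval"), inherits(gene, "gene_model"))
  span <- gene_span(gene)
  sv$chrom == span$chrom && sv$start <= span$start && sv$end >= span$end
}

#' Distance from a position to the nearest exon of a gene
#'
#' Minimum, over the exons of *all* transcripts of the gene, of the
#' distance from `pos` to the nearest exon boundary; 0 when `pos` lies
#' inside any exon. The union over transcripts is the conservative choice
#' for the 100 bp deep-intronic rule. Strand never affects distances.
#'
#' @param pos 1-based position (must lie within the gene span)
#' @param gene a `gene_model`
#' @return nonnegative integer distance in bp
#' @export
distance_to_nearest_exon <- function(pos, gene) {
  stopifnot(inherits(gene, "gene_model"))
  span <- gene_span(gene)
  if (pos < span$start || pos > span$end)
    stop(sprintf("position %s is outside the span of gene %s (%s:%s-%s): not intronic for this gene",
                 pos, gene$gene_id, span$chrom, span$start, span$end))
  d <- Inf
  for (tx in gene$transcripts) {
    ex <- tx$exons
    inside <- pos >= ex$start & pos <= ex$end
    if (any(inside)) return(0)
    d <- min(d, min(pmax(ex$start - pos, pos - ex$end)))
  }
  if (!is.finite(d)) stop("gene has no exons")
  d
}

# VCF/BED converters: VCF POS is 1-based (same as internal), BED is
# 0-based half-open.

#' Convert a BED record (0-based half-open) to a genomic interval
#' @param chrom chromosome name
#' @param bed_start 0-based start
#' @param bed_end half-open end
#' @return a `genomic_interval`
#' @export
bed_to_interval <- function(chrom, bed_start, bed_end) {
  genomic_interval(chrom, bed_start + 1, bed_end)
}

#' Convert a genomic interval to BED coordinates (0-based half-open)
#' @param x a `genomic_interval`
#' @return list(chrom, start, end) in BED convention
#' @export
interval_to_bed <- function(x) {
  list(chrom = x$chrom, start = x$start - 1, end = x$end)
}
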