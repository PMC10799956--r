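#' Structural variant record
#'
#' @param sv_type one of "DEL", "DUP", "INV". Insertion and breakend
#'   records are rejected: size-based overlap matching and the transcript
#'   disruption rules below are defined for copy-number and inversion
#'   events only.
#' @param chrom,start,end interval in 1-based inclusive coordinates
#' @param id optional record id
#' @return an object of class `sv_record`
#' @export
sv_record <- function(sv_type, chrom, start, end, id = NULL) {
  sv_type <- toupper(sv_type)
  if (sv_type %in% c("INS", "BND", "TRA"))
    stop("SV type '", sv_type, "' is not supported: only DEL, DUP and INV ",
         "records are handled by interval-overlap matching")
  if (!sv_type %in% c("DEL", "DUP", "INV"))
    stop("unknown SV type: ", sv_type)
  structure(list(sv_type = sv_type,
                 interval = genomic_interval(chrom, start, end),
                 id = id),
            class = "sv_record")
}

#' Reciprocal overlap between two SV intervals
#'
#' overlap_bp / max(length(a), length(b)) under the default "longer"
#' denominator (the stricter convention); "query" uses the first
#' argument's length.
#'
#' @param a,b `sv_record` objects
#' @param denominator "longer" or "query"
#' @return overlap fraction in [0, 1]
#' @export
sv_reciprocal_overlap <- function(a, b, denominator = c("longer", "query")) {
  denominator <- match.arg(denominator)
  ov <- overlap_bp(a$interval, b$interval)
  den <- switch(denominator,
                longer = max(interval_length(a$interval),
                             interval_length(b$interval)),
                query = interval_length(a$interval))
  ov / den
}

#' Do two SV records match (consolidation rule)?
#'
#' TRUE iff same SV type, same chromosome, and overlap strictly greater
#' than `t$sv_overlap_min` (default 0.8) under the configured denominator.
#' With the default reciprocal ("longer") denominator the relation is
#' symmetric.
#'
#' @param query,candidate `sv_record` objects
#' @param t a [threshold_config()]
#' @return logical
#' @export
sv_match <- function(query, candidate, t = threshold_config()) {
  t <- as_threshold_config(t)
  if (query$sv_type != candidate$sv_type) return(FALSE)
  if (query$interval$chrom != candidate$interval$chrom) return(FALSE)
  sv_reciprocal_overlap(query, candidate, t$sv_overlap_denominator) >
    t$sv_overlap_min
}

#' Reference-panel summary for SV allele frequencies
#'
#' @param panel_id name of the panel (e.g. "EUR", "EAS")
#' @param n_samples number of individuals in the panel
#' @param svs data.frame with columns chrom, start, end, svtype and either
#'   `ac` + `an` (allele count / allele number) or `carrier_n` (number of
#'   carrier samples)
#' @return an object of class `panel_summary`
#' @export
panel_summary <- function(panel_id, n_samples, svs) {
  stopifnot(is.data.frame(svs),
            all(c("chrom", "start", "end", "svtype") %in% names(svs)))
  has_ac <- all(c("ac", "an") %in% names(svs))
  has_carrier <- "carrier_n" %in% names(svs)
  if (!has_ac && !has_carrier)
    stop("panel SVs need ac+an or carrier_n columns")
  if (has_carrier && any(svs$carrier_n > n_samples, na.rm = TRUE))
    stop("carrier count exceeds panel size")
  svs$chrom <- normalize_chrom(svs$chrom)
  svs$svtype <- toupper(svs$svtype)
  if (has_ac) {
    svs$af <- ifelse(svs$an > 0, svs$ac / svs$an, 0)
  } else {
    # carrier frequency stands in for allele frequency (caveat: upper
    # bound on AF when carriers may be het)
    message("panel '", panel_id,
            "' supplies carrier counts; using carrier frequency as AF")
    svs$af <- svs$carrier_n / n_samples
  }
  if (any(svs$af < 0 | svs$af > 1, na.rm = TRUE))
    stop("panel AFs must lie in [0, 1]")
  structure(list(panel_id = panel_id, n_samples = n_samples, svs = svs),
            class = "panel_summary")
}

#' Allele frequency of an SV in a reference panel
#'
#' Matches the query against every panel SV with [sv_match()] and returns
#' the AF of the best match (highest reciprocal overlap); 0 when nothing
#' matches.
#'
#' @param query an `sv_record`
#' @param panel a [panel_summary()]
#' @param t a [threshold_config()]
#' @return allele frequency in [0, 1]
#' @export
sv_panel_af <- function(query, panel, t = threshold_config()) {
  t <- as_threshold_config(t)
  stopifnot(inherits(panel, "panel_summary"))
  svs <- panel$svs
  svs <- svs[svs$chrom == query$interval$chrom &
               svs$svtype == query$sv_type, , drop = FALSE]
  if (nrow(svs) == 0) return(0)
  best_af <- 0; best_ov <- -1
  for (i in seq_len(nrow(svs))) {
    cand <- sv_record(svs$svtype[i], svs$chrom[i], svs$start[i], svs$end[i])
    if (!sv_match(query, cand, t)) next
    ov <- sv_reciprocal_overlap(query, cand, t$sv_overlap_denominator)
    if (ov > best_ov) { best_ov <- ov; best_af <- svs$af[i] }
  }
  best_af
}

#' Dual-population rarity filter
#'
#' A variant is rare iff its AF is strictly below `t$af_max` (default 1%)
#' in *every* configured panel. Monotone: lowering any AF never flips a
#' rare call to common.
#'
#' @param afs numeric vector of per-panel allele frequencies (one per
#'   panel; use 0 for "absent from panel")
#' @param t a [threshold_config()]
#' @return logical
#' @export
is_rare <- function(afs, t = threshold_config()) {
  t <- as_threshold_config(t)
  if (length(afs) == 0)
    stop("no reference panels configured: rarity is undefined")
  if (any(is.na(afs))) stop("panel AF is NA")
  all(afs < t$af_max)
}

#' Build the benign SV set from a reference panel
#'
#' Panel SVs that (i) overlap an exon of a candidate gene and (ii) are
#' carried by at least `t$benign_panel_min_samples` samples. The original
#' protocol's third criterion (manual IGV verification) is not
#' computable and is noted in the returned report attribute.
#'
#' @param panel a [panel_summary()] whose `svs` include a `carrier_n`
#'   column (or ac/an, in which case carriers are approximated by ac)
#' @param genes a `gene_model_set`
#' @param t a [threshold_config()]
#' @return data.frame of benign panel SVs with a `gene_id` column; the
#'   `note` attribute records the skipped manual-verification step
#' @export
build_benign_sv_set <- function(panel, genes, t = threshold_config()) {
  t <- as_threshold_config(t)
  svs <- panel$svs
  carriers <- if ("carrier_n" %in% names(svs)) svs$carrier_n else svs$ac
  keep <- list()
  for (i in seq_len(nrow(svs))) {
    if (is.na(carriers[i]) || carriers[i] < t$benign_panel_min_samples) next
    iv <- genomic_interval(svs$chrom[i], svs$start[i], svs$end[i])
    for (g in genes) {
      if (g$chrom != iv$chrom) next
      hit <- FALSE
      for (tx in g$transcripts) {
        ex <- tx$exons
        if (any(pmin(iv$end, ex$end) - pmax(iv$start, ex$start) >= 0)) {
          hit <- TRUE; break
        }
      }
      if (hit) {
        row <- svs[i, , drop = FALSE]
        row$gene_id <- g$gene_id
        keep[[length(keep) + 1L]] <- row
      }
    }
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    cbind(svs[0, , drop = FALSE], gene_id = character(0))
  rownames(out) <- NULL
  attr(out, "note") <-
    "manual IGV verification criterion not applied (not computable)"
  out
}
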