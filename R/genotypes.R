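# Genotype string helpers. Genotypes are VCF-style strings over a single
# alt allele: "0/0", "0/1", "1/1", hemizygous "1" or "0", missing "./."
# or ".". Multi-allelic sites are expected to be decomposed upstream.

#' Classify a genotype string
#' @param gt character vector of genotype strings
#' @return one of "ref", "het", "hom_alt", "hemi_ref", "hemi_alt",
#'   "missing" per element
#' @export
gt_class <- function(gt) {
  gt <- gsub("\\|", "/", as.character(gt))
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% "1/1"] <- "hom_alt"
  out[gt %in% "0"] <- "hemi_ref"
  out[gt %in% "1"] <- "hemi_alt"
  out
}

#' Number of alternate alleles carried by a genotype
#' @param gt character vector of genotype strings
#' @return integer vector (NA for missing genotypes)
#' @export
gt_alt_count <- function(gt) {
  cls <- gt_class(gt)
  unname(c(ref = 0L, het = 1L, hom_alt = 2L, hemi_ref = 0L, hemi_alt = 1L,
           missing = NA_integer_)[cls])
}

#' Is a genotype missing?
#' @param gt character vector of genotype strings
#' @return logical vector
#' @export
gt_is_missing <- function(gt) gt_class(gt) == "missing"

#' Does a genotype carry at least one alternate allele?
#' @param gt character vector of genotype strings
#' @return logical vector (FALSE for missing)
#' @export
gt_carries_alt <- function(gt) {
  n <- gt_alt_count(gt)
  !is.na(n) & n >= 1L
}
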