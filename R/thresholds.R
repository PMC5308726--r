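# Calling thresholds. Both threshold sets share the per-read filters
# (criteria i-iii) and a Fisher p-value cut (criterion vii); they differ in
# the depth/AF criteria (iv-vi). Bounds written >=/<= are inclusive; the
# Fisher cut is strict (< max_fisher_p), exactly as the criteria are printed.

validate_thresholds <- function(thr, probs) {
  for (f in names(thr)) {
    v <- thr[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_input("thresholds: `%s` must be a single finite number", f)
    if (v < 0) stop_input("thresholds: `%s` must be non-negative", f)
  }
  for (f in probs)
    if (thr[[f]] > 1) stop_input("thresholds: `%s` must lie in [0, 1]", f)
  thr
}

#' Thresholds for somatic calling in tumor versus normal tissue
#'
#' The seven genomic-DNA calling criteria: per-read mapping quality >= 25,
#' base quality >= 15, mismatched bases <= 5; tumor and normal filtered
#' depth >= 100; tumor VAF >= 0.05; normal VAF <= 0.05; Fisher exact
#' p < 0.05.
#'
#' @param min_mapping_quality,min_base_quality,max_mismatches per-read filters
#' @param min_depth minimum filtered depth required in tumor and in normal
#' @param min_tumor_vaf minimum variant allele frequency in tumor
#' @param max_normal_vaf maximum variant allele frequency in normal
#' @param max_fisher_p strict upper bound on the Fisher exact p-value
#' @return classed list of thresholds
#' @export
tumor_thresholds <- function(min_mapping_quality = 25,
                             min_base_quality = 15,
                             max_mismatches = 5,
                             min_depth = 100,
                             min_tumor_vaf = 0.05,
                             max_normal_vaf = 0.05,
                             max_fisher_p = 0.05) {
  thr <- list(
    min_mapping_quality = min_mapping_quality,
    min_base_quality = min_base_quality,
    max_mismatches = max_mismatches,
    min_depth = min_depth,
    min_tumor_vaf = min_tumor_vaf,
    max_normal_vaf = max_normal_vaf,
    max_fisher_p = max_fisher_p
  )
  thr <- validate_thresholds(thr,
    probs = c("min_tumor_vaf", "max_normal_vaf", "max_fisher_p"))
  structure(thr, class = c("tumor_thresholds", "calling_thresholds"))
}

#' Thresholds for tumor-informed mutation detection in plasma cfDNA
#'
#' The seven plasma criteria: the same per-read filters as tumor calling;
#' cfDNA filtered depth >= 100; cfDNA VAF >= 0.0005; supporting reads >= 2;
#' Fisher exact p < 0.05 against the matched normal-tissue pileup.
#'
#' @inheritParams tumor_thresholds
#' @param min_depth minimum filtered cfDNA depth
#' @param min_cfdna_vaf minimum cfDNA variant allele frequency (inclusive)
#' @param min_supporting_reads minimum variant-supporting read count
#' @return classed list of thresholds
#' @export
cfdna_thresholds <- function(min_mapping_quality = 25,
                             min_base_quality = 15,
                             max_mismatches = 5,
                             min_depth = 100,
                             min_cfdna_vaf = 0.0005,
                             min_supporting_reads = 2,
                             max_fisher_p = 0.05) {
  thr <- list(
    min_mapping_quality = min_mapping_quality,
    min_base_quality = min_base_quality,
    max_mismatches = max_mismatches,
    min_depth = min_depth,
    min_cfdna_vaf = min_cfdna_vaf,
    min_supporting_reads = min_supporting_reads,
    max_fisher_p = max_fisher_p
  )
  thr <- validate_thresholds(thr, probs = c("min_cfdna_vaf", "max_fisher_p"))
  structure(thr, class = c("cfdna_thresholds", "calling_thresholds"))
}
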