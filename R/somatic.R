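# Somatic SNV calling from paired tumor/normal read observations.
#
# A candidate passes when all seven criteria hold:
#   (i)   read mapping quality >= 25
#   (ii)  read base quality >= 15
#   (iii) read mismatched bases <= 5
#   (iv)  tumor AND normal filtered depth >= 100
#   (v)   tumor VAF >= 0.05
#   (vi)  normal VAF <= 0.05
#   (vii) one-sided Fisher exact p (alt excess in tumor vs normal) < 0.05
# Criteria i-iii act per read and define the filtered pileup; VAFs use the
# filtered depth. Reads with allele N are dropped before depth computation.

OBS_COLUMNS <- c("chrom", "pos", "ref", "allele", "base_quality",
                 "mapping_quality", "mismatch_count")

validate_observations <- function(obs) {
  miss <- setdiff(OBS_COLUMNS, names(obs))
  if (length(miss))
    stop_input("read observations: missing column(s) %s",
               paste(miss, collapse = ", "))
  bad <- !obs$allele %in% c(DNA_BASES, "N")
  if (any(bad))
    stop_input("read observations: invalid allele '%s'", obs$allele[which(bad)[1]])
  if (any(obs$mapping_quality < 0 | obs$base_quality < 0 | obs$mismatch_count < 0))
    stop_input("read observations: qualities and mismatch counts must be >= 0")
  obs
}

#' Construct a pileup column
#'
#' @param chrom,pos,ref site coordinates and reference base
#' @param counts named numeric vector of filtered read counts per allele
#'   (subset of A/C/G/T)
#' @return object of class `pileup_column` with fields `chrom`, `pos`,
#'   `ref`, `counts` (always length 4, named A/C/G/T) and `depth`
#' @export
pileup_column <- function(chrom, pos, ref, counts = c(A = 0, C = 0, G = 0, T = 0)) {
  full <- setNames(numeric(4), DNA_BASES)
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% DNA_BASES))
      stop_input("pileup_column: counts must be named with A/C/G/T")
    if (any(counts < 0)) stop_input("pileup_column: counts must be >= 0")
    full[names(counts)] <- counts
  }
  structure(list(chrom = chrom, pos = pos, ref = ref,
                 counts = full, depth = sum(full)),
            class = "pileup_column")
}

#' @export
print.pileup_column <- function(x, ...) {
  cat(sprintf("pileup %s:%s ref=%s depth=%d [%s]\n", x$chrom, x$pos, x$ref,
              as.integer(x$depth),
              paste(names(x$counts), as.integer(x$counts), sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Apply per-read filters and tabulate a pileup column
#'
#' Keeps reads with mapping quality, base quality and mismatch count within
#' the thresholds and a non-N allele, then counts reads per allele. All
#' observations must share one position.
#'
#' @param obs read-observation `data.frame` (see [read_observation_table()])
#' @param thresholds a [tumor_thresholds()] or [cfdna_thresholds()]
#' @return a [pileup_column()]
#' @examples
#' obs <- data.frame(chrom = "chr1", pos = 100, ref = "A",
#'                   allele = c("A", "A", "C"),
#'                   base_quality = c(30, 30, 14),
#'                   mapping_quality = 60, mismatch_count = 0)
#' filter_read_observations(obs)  # the C read fails base quality: depth 2
#' @export
filter_read_observations <- function(obs, thresholds = tumor_thresholds()) {
  obs <- validate_observations(obs)
  if (nrow(obs) == 0L)
    return(pileup_column(NA_character_, NA_integer_, NA_character_))
  key <- unique(obs[c("chrom", "pos")])
  if (nrow(key) > 1L)
    stop_input("filter_read_observations: observations span multiple positions (%s)",
               paste(paste0(key$chrom, ":", key$pos), collapse = ", "))
  keep <- obs$mapping_quality >= thresholds$min_mapping_quality &
    obs$base_quality >= thresholds$min_base_quality &
    obs$mismatch_count <= thresholds$max_mismatches &
    obs$allele != "N"
  kept <- obs$allele[keep]
  counts <- vapply(DNA_BASES, function(b) sum(kept == b), numeric(1))
  pileup_column(key$chrom[1], key$pos[1], obs$ref[1], counts)
}

#' Variant allele frequency from a pileup column
#'
#' @param column a [pileup_column()]
#' @param alt alt allele (must differ from the reference)
#' @return `counts[alt] / depth`; 0 when depth is 0
#' @export
vaf <- function(column, alt) {
  if (!inherits(column, "pileup_column"))
    stop_input("vaf: `column` must be a pileup_column")
  if (!alt %in% DNA_BASES) stop_input("vaf: `alt` must be one of A/C/G/T")
  if (!is.na(column$ref) && alt == column$ref)
    stop_input("vaf: alt allele equals the reference")
  if (column$depth == 0) return(0)
  unname(column$counts[alt] / column$depth)
}

#' One-sided Fisher exact test on a 2x2 count table
#'
#' Tests for alt-read excess in sample a versus sample b on the table with
#' rows (alt, ref) and columns (a, b). The one-sided p-value is the exact
#' upper hypergeometric tail `P(X >= alt_a)` with the observed margins. All
#' arguments are vectorised.
#'
#' @param alt_a,ref_a alt/ref read counts in sample a (e.g. tumor or plasma)
#' @param alt_b,ref_b alt/ref read counts in sample b (the comparator)
#' @param alternative `"greater"` (default, alt enrichment in a) or
#'   `"two.sided"` (delegated to [stats::fisher.test()])
#' @return p-value(s) in (0, 1]
#' @examples
#' fisher_exact_2x2(30, 70, 0, 200)
#' @export
fisher_exact_2x2 <- function(alt_a, ref_a, alt_b, ref_b,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(alt_a), length(ref_a), length(alt_b), length(ref_b))
  a <- rep_len(alt_a, n); b <- rep_len(ref_a, n)
  c_ <- rep_len(alt_b, n); d <- rep_len(ref_b, n)
  if (any(c(a, b, c_, d) < 0))
    stop_input("fisher_exact_2x2: counts must be >= 0")
  if (any(a + b + c_ + d == 0))
    stop_input("fisher_exact_2x2: at least one count must be positive")
  if (alternative == "greater") {
    phyper(a - 1, m = a + c_, n = b + d, k = a + b, lower.tail = FALSE)
  } else {
    vapply(seq_len(n), function(i)
      fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2L),
                  alternative = "two.sided")$p.value, numeric(1))
  }
}

# evaluate criteria iv-vii for one alt allele; returns a one-row data.frame
somatic_criteria <- function(tumor, normal, alt, thresholds, alternative) {
  t_alt <- unname(tumor$counts[alt]); t_ref <- unname(tumor$counts[tumor$ref])
  n_alt <- unname(normal$counts[alt]); n_ref <- unname(normal$counts[normal$ref])
  t_af <- if (tumor$depth > 0) t_alt / tumor$depth else 0
  n_af <- if (normal$depth > 0) n_alt / normal$depth else 0
  # 2x2 over alt and ref reads only; other non-ref alleles are excluded
  p <- if (t_alt + t_ref + n_alt + n_ref > 0)
    fisher_exact_2x2(t_alt, t_ref, n_alt, n_ref, alternative = alternative)
  else 1
  failed <- character(0)
  if (tumor$depth < thresholds$min_depth) failed <- c(failed, "tumor_depth")
  if (normal$depth < thresholds$min_depth) failed <- c(failed, "normal_depth")
  if (t_af < thresholds$min_tumor_vaf) failed <- c(failed, "tumor_vaf")
  if (n_af > thresholds$max_normal_vaf) failed <- c(failed, "normal_vaf")
  if (!(p < thresholds$max_fisher_p)) failed <- c(failed, "fisher_p")
  data.frame(
    chrom = tumor$chrom, pos = tumor$pos, ref = tumor$ref, alt = alt,
    tumor_alt = t_alt, tumor_depth = tumor$depth,
    normal_alt = n_alt, normal_depth = normal$depth,
    tumor_af = t_af, normal_af = n_af, fisher_p = p,
    pass = length(failed) == 0L,
    failed = paste(failed, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Call somatic variants at one site from tumor and normal pileups
#'
#' Evaluates every non-reference allele observed in the tumor pileup against
#' criteria iv-vii and records the outcome of each criterion. Per-read
#' criteria i-iii are assumed already applied by
#' [filter_read_observations()].
#'
#' @param tumor,normal [pileup_column()]s sharing position and reference
#' @param thresholds a [tumor_thresholds()]
#' @param alternative Fisher sidedness, see [fisher_exact_2x2()]
#' @return `data.frame` with one row per evaluated alt allele (zero rows if
#'   the tumor pileup carries no non-reference reads); columns include
#'   `tumor_af`, `normal_af`, `fisher_p`, `pass` and the semicolon-joined
#'   `failed` criteria among `tumor_depth`, `normal_depth`, `tumor_vaf`,
#'   `normal_vaf`, `fisher_p`
#' @export
call_somatic_site <- function(tumor, normal, thresholds = tumor_thresholds(),
                              alternative = "greater") {
  if (!inherits(tumor, "pileup_column") || !inherits(normal, "pileup_column"))
    stop_input("call_somatic_site: inputs must be pileup_column objects")
  if (!isTRUE(tumor$chrom == normal$chrom) || !isTRUE(tumor$pos == normal$pos))
    stop_input("call_somatic_site: tumor and normal pileups are at different positions")
  if (!isTRUE(tumor$ref == normal$ref))
    stop_input("call_somatic_site: tumor and normal disagree on the reference base")
  alts <- setdiff(DNA_BASES, tumor$ref)
  alts <- alts[tumor$counts[alts] > 0]
  out <- lapply(alts, somatic_criteria, tumor = tumor, normal = normal,
                thresholds = thresholds, alternative = alternative)
  if (!length(out))
    return(data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), tumor_alt = numeric(),
                      tumor_depth = numeric(), normal_alt = numeric(),
                      normal_depth = numeric(), tumor_af = numeric(),
                      normal_af = numeric(), fisher_p = numeric(),
                      pass = logical(), failed = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

split_by_site <- function(obs) {
  split(obs, paste(obs$chrom, obs$pos), drop = TRUE)
}

#' Call all somatic variants for one patient
#'
#' Runs per-read filtering and site-level calling at every position present
#' in the tumor observation table, annotates calls with the panel gene
#' containing the position, and returns the calls sorted by coordinate.
#'
#' @param tumor_obs,normal_obs read-observation tables for the tumor biopsy
#'   and matched normal tissue
#' @param panel panel `data.frame`; a call at a position outside every panel
#'   region raises a consistency error
#' @param thresholds a [tumor_thresholds()]
#' @param alternative Fisher sidedness
#' @param keep_failed also return non-passing candidates (default `FALSE`)
#' @return `data.frame` of calls (see [call_somatic_site()]) with a `gene`
#'   column
#' @export
call_patient <- function(tumor_obs, normal_obs, panel = default_panel(),
                         thresholds = tumor_thresholds(),
                         alternative = "greater", keep_failed = FALSE) {
  tumor_obs <- validate_observations(tumor_obs)
  normal_obs <- validate_observations(normal_obs)
  tumor_sites <- split_by_site(tumor_obs)
  normal_sites <- split_by_site(normal_obs)
  calls <- lapply(names(tumor_sites), function(k) {
    t_obs <- tumor_sites[[k]]
    t_col <- filter_read_observations(t_obs, thresholds)
    n_obs <- normal_sites[[k]]
    n_col <- if (is.null(n_obs))
      pileup_column(t_col$chrom, t_col$pos, t_col$ref)
    else filter_read_observations(n_obs, thresholds)
    call_somatic_site(t_col, n_col, thresholds, alternative)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- call_somatic_site(pileup_column("chr0", 1L, "A", c(A = 1)),
                             pileup_column("chr0", 1L, "A", c(A = 1)))
    out$gene <- character(0)
    return(out)
  }
  if (!keep_failed) calls <- calls[calls$pass, , drop = FALSE]
  if (nrow(calls)) {
    calls$gene <- panel_gene_at(panel, calls$chrom, calls$pos)
    if (anyNA(calls$gene))
      stop_input("call_patient: call at %s:%s lies outside every panel region",
                 calls$chrom[which(is.na(calls$gene))[1]],
                 calls$pos[which(is.na(calls$gene))[1]])
    calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  } else {
    calls$gene <- character(0)
  }
  rownames(calls) <- NULL
  calls
}
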