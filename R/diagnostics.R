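# Patient-level diagnostic accuracy of cfDNA against the tumor.
#
# The unit of analysis is the patient: for a given gene a patient is
# tumor-mutant when >= 1 tumor call falls in the gene, and cfDNA-positive
# when >= 1 concordant mutation falls in the gene. Per-gene 2x2 tables pool
# into a "Total" row by summing raw counts. Percent metrics are truncated
# (floored) at one decimal, the convention that reproduces printed values
# such as 66.6 for 2/3 and 89.1 for 33/37; rounding is available as an
# option.

#' Truncate a fraction to a one-decimal percent
#'
#' `floor(x * 1000) / 10` (with a 1e-9 guard against floating-point
#' representation just below an integer). Never rounds up.
#'
#' @param x fraction(s) in \[0, 1\]
#' @param mode `"truncate"` (default) or `"round"`
#' @return percent value(s) with one decimal
#' @examples
#' truncate_percent(2 / 3)    # 66.6
#' truncate_percent(33 / 37)  # 89.1
#' @export
truncate_percent <- function(x, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop_input("truncate_percent: `x` must lie in [0, 1]")
  if (mode == "truncate") floor(x * 1000 + 1e-9) / 10
  else round(x * 1000) / 10
}

trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

#' Tumor-mutant and cfDNA-positive status of one patient for one gene
#'
#' @param calls the patient's passing tumor calls (with a `gene` column)
#' @param concordant the patient's concordant mutations
#'   ([concordance_status()])
#' @param gene gene symbol; must belong to `panel`
#' @param panel panel `data.frame` used to validate `gene`
#' @return named logical vector `c(tumor_mutant =, cfdna_positive =)`
#' @export
patient_gene_status <- function(calls, concordant, gene,
                                panel = default_panel()) {
  if (!gene %in% panel$gene)
    stop_input("patient_gene_status: gene '%s' is not on the panel", gene)
  c(tumor_mutant = gene %in% calls$gene,
    cfdna_positive = gene %in% concordant$gene)
}

#' Patient-level contingency tables per gene, plus a pooled total
#'
#' @param statuses `data.frame` with one row per patient x gene:
#'   `patient`, `gene`, `tumor_mutant`, `cfdna_positive`
#' @param genes genes to tabulate (rows of the output, in this order)
#' @return `data.frame` with columns `gene`, `tp`, `fp`, `fn`, `tn`; the
#'   last row (`gene == "Total"`) sums the counts across `genes`
#' @export
build_contingency <- function(statuses, genes) {
  tab <- lapply(genes, function(g) {
    s <- statuses[statuses$gene == g, , drop = FALSE]
    data.frame(
      gene = g,
      tp = sum(s$tumor_mutant & s$cfdna_positive),
      fp = sum(!s$tumor_mutant & s$cfdna_positive),
      fn = sum(s$tumor_mutant & !s$cfdna_positive),
      tn = sum(!s$tumor_mutant & !s$cfdna_positive),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, tab)
  total <- data.frame(gene = "Total", tp = sum(tab$tp), fp = sum(tab$fp),
                      fn = sum(tab$fn), tn = sum(tab$tn),
                      stringsAsFactors = FALSE)
  rbind(tab, total)
}

#' Diagnostic metrics from patient-level contingency counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and accuracy `(tp+tn)/total`, each expressed as a
#' percent truncated at one decimal. A zero denominator yields `NA` for
#' that metric, never an error.
#'
#' @param tables `data.frame` with columns `tp`, `fp`, `fn`, `tn` (and
#'   optionally `gene`), e.g. from [build_contingency()]
#' @param mode percent mode, `"truncate"` (default) or `"round"`
#' @return the input with columns `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy` appended
#' @examples
#' diagnostic_metrics(data.frame(tp = 9, fp = 0, fn = 3, tn = 1))
#' @export
diagnostic_metrics <- function(tables, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  pct <- function(num, den)
    ifelse(den > 0, truncate_percent(ifelse(den > 0, num / den, 0), mode), NA_real_)
  tot <- tables$tp + tables$fp + tables$fn + tables$tn
  tables$sensitivity <- pct(tables$tp, tables$tp + tables$fn)
  tables$specificity <- pct(tables$tn, tables$tn + tables$fp)
  tables$ppv <- pct(tables$tp, tables$tp + tables$fp)
  tables$npv <- pct(tables$tn, tables$tn + tables$fn)
  tables$accuracy <- pct(tables$tp + tables$tn, tot)
  tables
}

#' Cohort-level mutation and concordance summary
#'
#' @param calls cohort-wide passing tumor calls with `patient` and `gene`
#' @param concordant cohort-wide concordant mutations with `patient` and
#'   `gene` (zero rows allowed)
#' @param patients character vector of all patient ids (so that patients
#'   without calls still count in denominators)
#' @param tumor_source optional named character vector mapping patient id to
#'   `"primary"` or `"recurrent"` (default: all primary)
#' @return list with `n_mutations`, `mean_mutations_per_patient` (truncated
#'   one decimal), `gene_frequency` (`data.frame` gene / n_patients /
#'   percent), `n_concordant_mutations`, `pct_concordant_mutations`,
#'   `n_primary_patients`, `n_concordant_primary_patients`,
#'   `pct_concordant_primary_patients`
#' @export
cohort_summary <- function(calls, concordant, patients,
                           tumor_source = NULL) {
  n_pat <- length(patients)
  if (is.null(tumor_source))
    tumor_source <- setNames(rep("primary", n_pat), patients)
  n_mut <- nrow(calls)
  mean_mut <- if (n_pat > 0) trunc1(n_mut / n_pat) else 0
  gene_freq <- if (n_mut > 0) {
    per_gene <- tapply(calls$patient, calls$gene,
                       function(p) length(unique(p)))
    data.frame(gene = names(per_gene),
               n_patients = as.integer(per_gene),
               percent = truncate_percent(as.integer(per_gene) / n_pat),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene = character(), n_patients = integer(),
               percent = numeric(), stringsAsFactors = FALSE)
  }
  gene_freq <- gene_freq[order(-gene_freq$n_patients, gene_freq$gene), ,
                         drop = FALSE]
  rownames(gene_freq) <- NULL
  n_conc <- nrow(concordant)
  primary <- patients[tumor_source[patients] == "primary"]
  conc_primary <- unique(concordant$patient[concordant$patient %in% primary])
  list(
    n_patients = n_pat,
    n_mutations = n_mut,
    mean_mutations_per_patient = mean_mut,
    gene_frequency = gene_freq,
    n_concordant_mutations = n_conc,
    pct_concordant_mutations = if (n_mut > 0)
      truncate_percent(n_conc / n_mut) else NA_real_,
    n_primary_patients = length(primary),
    n_concordant_primary_patients = length(conc_primary),
    pct_concordant_primary_patients = if (length(primary) > 0)
      truncate_percent(length(conc_primary) / length(primary)) else NA_real_
  )
}
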