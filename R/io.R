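# File formats.
#
# Read-observation TSV dialect: header
#   chrom  pos  ref  allele  base_quality  mapping_quality  mismatch_count
# one row per read per site, positions 1-based. Sample sheet and trajectory
# tables are plain TSVs with fixed headers. Somatic calls are emitted as
# VCF v4.2 plus a flat TSV mirror. Line numbers in parse errors count the
# header as line 1.

#' Read a read-observation table
#'
#' Validates the header, numeric columns and the 1-based position
#' convention; malformed rows are reported with their line number.
#'
#' @param path path to a TSV with columns `chrom`, `pos`, `ref`, `allele`,
#'   `base_quality`, `mapping_quality`, `mismatch_count`
#' @return typed `data.frame` of read observations
#' @export
read_observation_table <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(OBS_COLUMNS, names(raw))
  if (length(miss))
    stop_input("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  num_cols <- c("pos", "base_quality", "mapping_quality", "mismatch_count")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_input("%s: line %d: non-numeric value '%s' in column %s",
                 path, bad[1] + 1L, raw[[col]][bad[1]], col)
    raw[[col]] <- v
  }
  bad <- which(raw$pos < 1)
  if (length(bad))
    stop_input("%s: line %d: position %s is below 1 (positions are 1-based)",
               path, bad[1] + 1L, raw$pos[bad[1]])
  validate_observations(raw)
}

#' Write a read-observation table
#' @param obs read-observation `data.frame`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_observation_table <- function(obs, path) {
  write_tsv(validate_observations(obs)[OBS_COLUMNS], path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SAMPLE_TYPES <- c("tumor_primary", "tumor_recurrent", "normal", "plasma")

#' Read and validate a sample sheet
#'
#' Required columns: `patient`, `sample_id`, `sample_type` (one of
#' tumor_primary / tumor_recurrent / normal / plasma), `timepoint`, `month`,
#' `path`. Optional: `scc`, `p53_ab` (conventional serum biomarkers carried
#' as annotations only) and `imaging_recurrence_month`. Each patient needs
#' exactly one normal and at least one tumor sample; plasma rows need month
#' offsets.
#'
#' @param path path to the sample-sheet TSV
#' @param check_paths verify that each referenced observation table exists
#' @return validated `data.frame`
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("patient", "sample_id", "sample_type", "timepoint", "month", "path")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop_input("sample sheet: missing column(s) %s", paste(miss, collapse = ", "))
  bad <- !sheet$sample_type %in% SAMPLE_TYPES
  if (any(bad))
    stop_input("sample sheet: unknown sample_type '%s' (line %d)",
               sheet$sample_type[which(bad)[1]], which(bad)[1] + 1L)
  for (p in unique(sheet$patient)) {
    s <- sheet[sheet$patient == p, ]
    if (sum(s$sample_type == "normal") != 1L)
      stop_input("sample sheet: patient %s must have exactly one normal sample", p)
    if (!any(s$sample_type %in% c("tumor_primary", "tumor_recurrent")))
      stop_input("sample sheet: patient %s has no tumor sample", p)
    pl <- s[s$sample_type == "plasma", ]
    if (nrow(pl) && anyNA(suppressWarnings(as.numeric(pl$month))))
      stop_input("sample sheet: plasma rows of patient %s need month offsets", p)
  }
  if (check_paths) {
    missing_files <- !file.exists(file.path(dirname(path), sheet$path)) &
      !file.exists(sheet$path)
    if (any(missing_files))
      stop_input("sample sheet: observation table not found: %s",
                 sheet$path[which(missing_files)[1]])
  }
  sheet
}

#' Write somatic calls as VCF v4.2
#'
#' INFO keys: `TAF` (tumor AF), `NAF` (normal AF), `FP` (Fisher p), `GENE`.
#' FILTER holds `PASS` or the semicolon-joined failed criteria. Calls must
#' be sorted by (chrom, pos).
#'
#' @param calls calls `data.frame` from [call_patient()] /
#'   [call_somatic_site()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, path) {
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stop_input("write_vcf: calls must be sorted by (chrom, pos)")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=plasmatrack",
    "##INFO=<ID=TAF,Number=1,Type=Float,Description=\"Tumor variant allele frequency (filtered depth)\">",
    "##INFO=<ID=NAF,Number=1,Type=Float,Description=\"Normal variant allele frequency (filtered depth)\">",
    "##INFO=<ID=FP,Number=1,Type=Float,Description=\"Fisher exact test p-value, tumor vs normal\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene containing the site\">",
    "##FILTER=<ID=tumor_depth,Description=\"Tumor filtered depth below minimum\">",
    "##FILTER=<ID=normal_depth,Description=\"Normal filtered depth below minimum\">",
    "##FILTER=<ID=tumor_vaf,Description=\"Tumor VAF below minimum\">",
    "##FILTER=<ID=normal_vaf,Description=\"Normal VAF above maximum\">",
    "##FILTER=<ID=fisher_p,Description=\"Fisher exact p-value not below threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  records <- character(0)
  if (nrow(calls)) {
    gene <- if ("gene" %in% names(calls)) calls$gene else NA_character_
    info <- sprintf("TAF=%.6g;NAF=%.6g;FP=%.6g%s",
                    calls$tumor_af, calls$normal_af, calls$fisher_p,
                    ifelse(is.na(gene), "", paste0(";GENE=", gene)))
    filter <- ifelse(calls$pass, "PASS", calls$failed)
    records <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                       calls$chrom, as.integer(calls$pos), calls$ref,
                       calls$alt, filter, info)
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes one read-observation TSV per sample, the ground-truth table
#' (`ground_truth.tsv`), the panel BED (`panel.bed`) and a sample sheet
#' (`sample_sheet.tsv`) referencing every table, so a cohort can be fed back
#' through the file-based interface.
#'
#' @param cohort a `ctdna_cohort` from [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  write_panel_bed(cohort$panel, file.path(dir, "panel.bed"))
  rows <- list()
  for (p in names(cohort$samples)) {
    s <- cohort$samples[[p]]
    sc <- cohort$scenarios[[p]]
    t_path <- paste0(p, "_tumor.tsv")
    n_path <- paste0(p, "_normal.tsv")
    write_observation_table(s$tumor, file.path(dir, t_path))
    write_observation_table(s$normal, file.path(dir, n_path))
    imaging <- if (!is.null(sc)) sc$imaging_recurrence_month else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      patient = p, sample_id = c(paste0(p, "_tumor"), paste0(p, "_normal")),
      sample_type = c("tumor_primary", "normal"),
      timepoint = "", month = NA_real_, path = c(t_path, n_path),
      imaging_recurrence_month = imaging, stringsAsFactors = FALSE)
    if (!is.null(s$plasma)) {
      for (t in seq_along(s$plasma)) {
        lab <- names(s$plasma)[t]
        pl_path <- paste0(p, "_plasma_", lab, ".tsv")
        write_observation_table(s$plasma[[t]], file.path(dir, pl_path))
        rows[[length(rows) + 1L]] <- data.frame(
          patient = p, sample_id = paste0(p, "_plasma_", lab),
          sample_type = "plasma", timepoint = lab,
          month = sc$timepoints$month[t], path = pl_path,
          imaging_recurrence_month = imaging, stringsAsFactors = FALSE)
      }
    }
  }
  write_tsv(do.call(rbind, rows), file.path(dir, "sample_sheet.tsv"))
  invisible(dir)
}
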