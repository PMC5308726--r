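# Targeted gene panel: 53 genes recurrently mutated in esophageal squamous
# cell carcinoma. Coordinates are synthetic panel geometry (one compact
# region per gene), not genome-build positions; all downstream code only
# requires that regions be disjoint and 1-based inclusive.

#' Gene symbols of the default 53-gene panel
#'
#' Driver genes recurrently mutated in esophageal squamous cell carcinoma
#' (TP53, FAT3, MLL3, AJUBA, the NOTCH family, CREBBP, ...), padded with
#' pan-cancer drivers to 53 entries.
#'
#' @format character vector of length 53
#' @export
escc_panel_genes <- c(
  "TP53", "FAT3", "MLL3", "AJUBA", "NOTCH1", "NOTCH2", "NOTCH3", "CREBBP",
  "EP300", "PIK3CA", "NFE2L2", "CDKN2A", "ZNF750", "FBXW7", "KMT2D",
  "FAM135B", "RB1", "PTEN", "CCND1", "SOX2", "TET2", "FAT1", "FAT2", "FAT4",
  "KDM6A", "PTCH1", "EGFR", "ERBB2", "ERBB4", "SMAD4", "APC", "KRAS", "NRAS",
  "HRAS", "BRAF", "STK11", "CUL3", "KEAP1", "PBRM1", "ARID1A", "ARID2",
  "SMARCA4", "BRCA2", "ATM", "ATR", "CHEK2", "MTOR", "AKT1", "FGFR1",
  "FGFR2", "FGFR3", "NFKBIA", "PTPRD"
)

#' Construct the default targeted panel
#'
#' Builds a panel `data.frame` with one region per gene. Coordinates are
#' 1-based inclusive. The default geometry places genes on chr1-chr22 with
#' non-overlapping 500-bp regions.
#'
#' @param genes character vector of gene symbols (default: the 53-gene panel)
#' @param region_length width of each gene's captured region in bp
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`
#' @examples
#' panel <- default_panel()
#' nrow(panel)       # 53
#' panel_size(panel) # total targeted positions
#' @export
default_panel <- function(genes = escc_panel_genes, region_length = 500L) {
  n <- length(genes)
  if (n < 1L) stop_input("default_panel: `genes` must be non-empty")
  region_length <- as.integer(region_length)
  i <- seq_len(n)
  panel <- data.frame(
    gene  = genes,
    chrom = paste0("chr", ((i - 1L) %% 22L) + 1L),
    start = 100000L + (i - 1L) * 10000L,
    end   = 100000L + (i - 1L) * 10000L + region_length - 1L,
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
}

#' Validate a panel data.frame
#'
#' Checks column presence, `start <= end`, per-gene non-overlap of regions,
#' and a positive total position count.
#'
#' @param panel panel `data.frame` (gene, chrom, start, end)
#' @return the validated panel, invisibly unchanged
#' @export
validate_panel <- function(panel) {
  req <- c("gene", "chrom", "start", "end")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop_input("panel: missing column(s) %s", paste(miss, collapse = ", "))
  if (any(panel$start > panel$end))
    stop_input("panel: region with start > end (gene %s)",
               panel$gene[which(panel$start > panel$end)[1]])
  if (any(panel$start < 1L))
    stop_input("panel: coordinates are 1-based; start < 1 found")
  # regions must not overlap within a gene (on the same chromosome)
  by_gc <- split(panel, paste(panel$gene, panel$chrom))
  for (g in by_gc) {
    if (nrow(g) < 2L) next
    g <- g[order(g$start), ]
    if (any(g$start[-1L] <= g$end[-nrow(g)]))
      stop_input("panel: overlapping regions within gene %s", g$gene[1])
  }
  if (panel_size(panel) <= 0) stop_input("panel: no targeted positions")
  panel
}

#' Total number of targeted positions in a panel
#' @param panel panel `data.frame`
#' @return integer count of positions
#' @export
panel_size <- function(panel) sum(panel$end - panel$start + 1L)

#' Map genomic positions to panel genes
#'
#' @param panel panel `data.frame`
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @return character vector of gene symbols, `NA` where a position falls
#'   outside every panel region
#' @export
panel_gene_at <- function(panel, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    hit <- panel$chrom == chrom[i] & panel$start <= pos[i] & panel$end >= pos[i]
    if (any(hit)) panel$gene[which(hit)[1]] else NA_character_
  }, character(1))
}

#' Read a panel from a BED file
#'
#' BED is 0-based half-open; the returned panel uses the package's 1-based
#' inclusive convention. The conversion is delegated to `rtracklayer`.
#'
#' @param path path to a BED file whose name column carries the gene symbol
#' @return validated panel `data.frame`
#' @export
read_panel_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  panel <- data.frame(
    gene  = if (!is.null(gr$name)) as.character(gr$name)
            else paste0("region", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
}

#' Write a panel to a BED file
#' @param panel panel `data.frame` (1-based inclusive coordinates)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_panel_bed <- function(panel, path) {
  panel <- validate_panel(panel)
  gr <- GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(start = panel$start, end = panel$end),
    name = panel$gene
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
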