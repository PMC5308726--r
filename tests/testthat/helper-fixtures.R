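# shared builders and the independent Fisher oracle

make_obs <- function(n, allele, chrom = "chr1", pos = 100L, ref = "A",
                     mq = 60, bq = 30, mm = 0) {
  data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n),
             allele = rep_len(allele, n),
             base_quality = rep_len(bq, n),
             mapping_quality = rep_len(mq, n),
             mismatch_count = rep_len(mm, n),
             stringsAsFactors = FALSE)
}

col_of <- function(counts, ref = "A", chrom = "chr1", pos = 100L) {
  pileup_column(chrom, pos, ref, counts)
}

# brute-force one-sided Fisher p: enumerate every table with the observed
# margins from the hypergeometric counting formula (choose()), sum the
# probabilities of tables at least as alt-enriched in sample a
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  js <- a:min(r1, k)
  sum(exp(lchoose(r1, js) + lchoose(r2, k - js) - lchoose(N, k)))
}

# vectorised variant for large grids
oracle_fisher_grid <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  hi <- pmin(r1, k)
  len <- hi - a + 1L
  idx <- rep.int(seq_along(a), len)
  j <- sequence(len, from = a, by = 1L)
  lp <- lchoose(r1[idx], j) + lchoose(r2[idx], k[idx] - j) -
    lchoose(N[idx], k[idx])
  as.numeric(rowsum(exp(lp), idx))
}

# tiny deterministic cohort for io / pipeline smoke tests
tiny_config <- function(seed = 11, ...) {
  simulation_config(n_patients = 2,
                    mutations_per_patient = list(dist = "fixed", n = 2),
                    depth_tumor = 300, depth_normal = 300, depth_plasma = 300,
                    n_background_sites = 2, seed = seed, ...)
}
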