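# Toy-data builders shared across test files.

# Build a genotype_matrix from an n x m matrix (or list of columns) of
# two-character genotype strings ("AC", "AA", NA for missing).
make_gm <- function(calls, pos = NULL, chrom = "17", snp_id = NULL,
                    subjects = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(pos)) pos <- seq(44000000, by = 1000, length.out = m)
  if (is.null(snp_id)) snp_id <- sprintf("snp%03d", seq_len(m))
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(n))
  a1 <- substr(calls, 1, 1); dim(a1) <- dim(calls)
  a2 <- substr(calls, 2, 2); dim(a2) <- dim(calls)
  a1[is.na(calls)] <- NA; a2[is.na(calls)] <- NA
  genotype_matrix(subjects,
                  data.frame(snp_id = snp_id, chrom = chrom, pos = pos),
                  a1, a2)
}

# Genotype strings for n subjects at a biallelic SNP from integer codes.
codes_to_calls <- function(codes, a = "A", b = "C") {
  out <- c(paste0(a, a), paste0(a, b), paste0(b, b))[codes + 1]
  out[is.na(codes)] <- NA
  out
}

# Independent brute-force haplotype-frequency oracle: coarse grid over the
# (p_AB, p_Ab, p_aB) simplex followed by a local refinement, maximising the
# same multinomial genotype-class likelihood the EM maximises but by direct
# search (no EM steps involved).
grid_search_haplotypes <- function(counts, coarse = 0.005, fine = 5e-4) {
  ll <- function(pAB, pAb, paB) {
    pab_raw <- 1 - pAB - pAb - paB
    pab <- pmax(pab_raw, 0)
    term <- function(cnt, P) if (cnt > 0) cnt * log(P) else 0
    out <- term(counts[1, 1], pAB^2) +
      term(counts[1, 2], 2 * pAB * pAb) +
      term(counts[1, 3], pAb^2) +
      term(counts[2, 1], 2 * pAB * paB) +
      term(counts[2, 2], 2 * (pAB * pab + pAb * paB)) +
      term(counts[2, 3], 2 * pAb * pab) +
      term(counts[3, 1], paB^2) +
      term(counts[3, 2], 2 * paB * pab) +
      term(counts[3, 3], pab^2)
    out <- out + 0 * pab          # keep vector shape when all counts hit zero cells
    out[pab_raw < -1e-12] <- -Inf
    out[is.nan(out)] <- -Inf
    out
  }
  search <- function(lo, hi, step) {
    g <- expand.grid(pAB = seq(lo[1], hi[1], by = step),
                     pAb = seq(lo[2], hi[2], by = step),
                     paB = seq(lo[3], hi[3], by = step))
    g <- g[g$pAB + g$pAb + g$paB <= 1 + 1e-12, ]
    v <- ll(g$pAB, g$pAb, g$paB)
    best <- which.max(v)
    c(g$pAB[best], g$pAb[best], g$paB[best])
  }
  p <- search(c(0, 0, 0), c(1, 1, 1), coarse)
  lo <- pmax(p - 2 * coarse, 0); hi <- pmin(p + 2 * coarse, 1)
  p <- search(lo, hi, fine)
  c(p_AB = p[1], p_Ab = p[2], p_aB = p[3], p_ab = 1 - sum(p))
}

# Random small two-locus table with at least one copy of each allele.
random_two_locus_table <- function(n_max = 50) {
  repeat {
    p <- as.numeric(stats::rmultinom(1, 100, rep(1, 4))) / 100
    n <- sample(10:n_max, 1)
    tab <- simulate_ld_pair(n, p[1], p[2], p[3], p[4])
    nA <- 2 * sum(tab[1, ]) + sum(tab[2, ])
    nB <- 2 * sum(tab[, 1]) + sum(tab[, 2])
    if (nA > 0 && nA < 2 * n && nB > 0 && nB < 2 * n) return(tab)
  }
}
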