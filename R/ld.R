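## Two-locus linkage disequilibrium from unphased genotypes.
##
## Haplotype frequencies are estimated by EM over the 3 x 3 table of
## two-locus genotype classes (the double heterozygote being the only
## ambiguous class), then summarised as D, Lewontin's D', the squared
## allelic correlation r2, and a base-10 LOD score against linkage
## equilibrium with allele frequencies fixed at the observed margins.

#' Cross-tabulate two SNPs into a 3x3 genotype-class table
#'
#' @param g1,g2 integer genotype codes (0 = hom A, 1 = het, 2 = hom a) as
#'   from [geno_codes()]; pairs with a missing member are dropped.
#' @return 3x3 integer matrix, rows = locus 1 classes, cols = locus 2.
#' @export
two_locus_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb")))
  m
}

## multinomial log-likelihood of the 9 genotype classes given haplotype
## frequencies p = (pAB, pAb, paB, pab), under random union of gametes
genoclass_loglik <- function(p, counts) {
  pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pab <- p[4]
  P <- matrix(0, 3, 3)
  P[1, 1] <- pAB^2;        P[1, 2] <- 2 * pAB * pAb;              P[1, 3] <- pAb^2
  P[2, 1] <- 2 * pAB * paB; P[2, 2] <- 2 * (pAB * pab + pAb * paB); P[2, 3] <- 2 * pAb * pab
  P[3, 1] <- paB^2;        P[3, 2] <- 2 * paB * pab;              P[3, 3] <- pab^2
  sum(counts[counts > 0] * log(P[counts > 0]))
}

#' EM haplotype-frequency estimation for two unphased loci
#'
#' Maximises the multinomial likelihood of the nine genotype classes under
#' random union of gametes. Initialised at linkage equilibrium (product of
#' the observed allele frequencies); each E-step splits the double
#' heterozygotes between the cis (AB/ab) and trans (Ab/aB) phases in
#' proportion to the current frequency products. Boundary zero cells are
#' left at the boundary (no pseudocounts).
#'
#' @param counts 3x3 table from [two_locus_counts()].
#' @param tol convergence: maximum absolute frequency change (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return an `"ld_pair"` object: `p_AB`, `p_Ab`, `p_aB`, `p_ab`, allele
#'   frequencies, `em_iters`, `converged`, `loglik_trace`, plus the LD
#'   statistics filled in by [ld_stats()].
#' @export
em_haplotypes <- function(counts, tol = 1e-8, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty two-locus table")
  ## allele counts at each locus (A at locus 1, B at locus 2)
  nA <- 2 * sum(counts[1, ]) + sum(counts[2, ])
  nB <- 2 * sum(counts[, 1]) + sum(counts[, 2])
  pA <- nA / (2 * n); pB <- nB / (2 * n)
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ## fixed haplotype counts contributed by unambiguous classes
  base <- c(
    AB = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
    Ab = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    aB = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    ab = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  )
  ndh <- counts[2, 2]
  trace <- genoclass_loglik(p, counts)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    cis <- p[1] * p[4]
    trans <- p[2] * p[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    hap <- base + ndh * c(w, 1 - w, 1 - w, w)
    p_new <- hap / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    trace <- c(trace, genoclass_loglik(p, counts))
    if (delta < tol) { converged <- TRUE; break }
  }
  p <- unname(p)
  out <- list(p_AB = p[1], p_Ab = p[2], p_aB = p[3], p_ab = p[4],
              p_A = pA, p_B = pB, n = n, counts = counts,
              em_iters = it, converged = converged, loglik_trace = trace)
  class(out) <- "ld_pair"
  ld_stats(out)
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Fills in \eqn{D = p_{AB} - p_A p_B}; Lewontin's
#' \eqn{D' = D / D_{max}} with \eqn{D_{max} = \min(p_A p_b, p_a p_B)} when
#' \eqn{D > 0} and \eqn{\min(p_A p_B, p_a p_b)} otherwise;
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)}; and the base-10 LOD score comparing
#' the multinomial genotype-class likelihood at the estimated haplotype
#' frequencies with linkage equilibrium at the observed allele frequencies.
#'
#' @param ld an `"ld_pair"` from [em_haplotypes()].
#' @return the object with `D`, `D_prime`, `r2`, `lod` added.
#' @export
ld_stats <- function(ld) {
  pA <- ld$p_A; pB <- ld$p_B
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pA >= 1) stop("locus 1 is monomorphic; D' and r2 undefined")
  if (pB <= 0 || pB >= 1) stop("locus 2 is monomorphic; D' and r2 undefined")
  D <- ld$p_AB - pA * pB
  Dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  ld$D <- D
  ld$D_prime <- if (D == 0) 0 else D / Dmax
  ld$r2 <- D^2 / (pA * pa * pB * pb)
  p0 <- c(pA * pB, pA * pb, pa * pB, pa * pb)
  ll1 <- genoclass_loglik(c(ld$p_AB, ld$p_Ab, ld$p_aB, ld$p_ab), ld$counts)
  ll0 <- genoclass_loglik(p0, ld$counts)
  ld$lod <- max(0, (ll1 - ll0) / log(10))
  ld
}

#' @export
print.ld_pair <- function(x, ...) {
  cat("Two-locus LD (EM over", x$n, "subjects,",
      x$em_iters, "iterations)\n")
  cat(sprintf("  haplotype freqs: AB %.4f  Ab %.4f  aB %.4f  ab %.4f\n",
              x$p_AB, x$p_Ab, x$p_aB, x$p_ab))
  cat(sprintf("  D = %.4f  D' = %.4f  r2 = %.4f  LOD = %.2f\n",
              x$D, x$D_prime, x$r2, x$lod))
  if (!x$converged) cat("  WARNING: EM did not converge\n")
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts with
#' the expectation from the observed allele frequencies. Monomorphic input
#' has no testable departure and returns p = 1.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return list with `chisq`, `df`, `p`, `p_allele` (frequency of A).
#' @export
hwe_chi2 <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n <= 0) stop("no subjects")
  p <- (2 * nAA + nAa) / (2 * n)
  if (p <= 0 || p >= 1) {
    return(list(chisq = 0, df = 1, p = 1, p_allele = p))
  }
  q <- 1 - p
  expd <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
  list(chisq = chisq, df = 1,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE), p_allele = p)
}

#' Select surrogate SNPs for an untyped target within +/- 50 kb
#'
#' Candidates on the target's chromosome within the (closed) window are
#' screened for Hardy-Weinberg consistency, their LD with the target is
#' estimated by [em_haplotypes()], and qualifying candidates (LOD at least
#' `lod_min`) are ranked by LOD descending with ties broken by absolute
#' distance; the top `n_choose` are selected (possibly on the same side of
#' the target).
#'
#' @param gm a [genotype_matrix()] containing the target and candidates.
#' @param target_snp id of the target SNP.
#' @param window half-width in bp (default 50000, closed boundary).
#' @param lod_min critical LOD score (default 3.0).
#' @param hwe_alpha candidates with HWE p below this are excluded
#'   (default 0.05).
#' @param n_choose number of surrogates to select (default 2).
#' @return a `"surrogate_choice"`: `target_snp`, `chosen` (ids), and a
#'   candidate table with signed distance (negative = upstream of the
#'   target), `d_prime`, `r2`, `lod`, `hwe_p`, `qualifies`.
#' @export
select_surrogates <- function(gm, target_snp, window = 50000, lod_min = 3.0,
                              hwe_alpha = 0.05, n_choose = 2) {
  jt <- match(target_snp, gm$snps$snp_id)
  if (is.na(jt)) stop("target SNP ", target_snp, " not in genotype matrix")
  tpos <- gm$snps$pos[jt]; tchrom <- gm$snps$chrom[jt]
  cand <- which(gm$snps$chrom == tchrom &
                  abs(gm$snps$pos - tpos) <= window &
                  seq_len(nrow(gm$snps)) != jt)
  gt <- geno_codes(gm, jt)
  rows <- lapply(cand, function(j) {
    gc <- geno_codes(gm, j)
    tb <- tabulate(gc + 1L, 3L)
    hw <- hwe_chi2(tb[1], tb[2], tb[3])
    ld <- tryCatch(em_haplotypes(two_locus_counts(gt, gc)),
                   error = function(e) NULL)
    data.frame(snp_id = gm$snps$snp_id[j],
               distance = gm$snps$pos[j] - tpos,
               d_prime = if (is.null(ld)) NA_real_ else ld$D_prime,
               r2 = if (is.null(ld)) NA_real_ else ld$r2,
               lod = if (is.null(ld)) NA_real_ else ld$lod,
               hwe_p = hw$p)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(snp_id = character(), distance = integer(),
                      d_prime = numeric(), r2 = numeric(), lod = numeric(),
                      hwe_p = numeric())
  }
  tab$qualifies <- !is.na(tab$lod) & tab$lod >= lod_min & tab$hwe_p >= hwe_alpha
  q <- tab[tab$qualifies, , drop = FALSE]
  q <- q[order(-q$lod, abs(q$distance)), , drop = FALSE]
  chosen <- utils::head(q$snp_id, n_choose)
  if (length(chosen) == 0) {
    message("no surrogate qualifies for ", target_snp,
            " (window ", window, " bp, LOD >= ", lod_min, ")")
  }
  structure(list(target_snp = target_snp, chosen = chosen, candidates = tab),
            class = "surrogate_choice")
}

#' @export
print.surrogate_choice <- function(x, ...) {
  cat("Surrogate selection for", x$target_snp, "-",
      nrow(x$candidates), "candidate(s),",
      length(x$chosen), "chosen\n")
  if (length(x$chosen)) {
    sel <- x$candidates[match(x$chosen, x$candidates$snp_id), ]
    print(sel[, c("snp_id", "distance", "d_prime", "lod", "r2")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a surrogate-selection report
#'
#' TSV with one row per candidate: target, surrogate, distance (bp, negative
#' = upstream), D', LOD, r2, HWE p, chosen flag.
#'
#' @param choices a `"surrogate_choice"` or list of them.
#' @param path output path.
#' @export
write_surrogate_report <- function(choices, path) {
  if (inherits(choices, "surrogate_choice")) choices <- list(choices)
  rows <- do.call(rbind, lapply(choices, function(ch) {
    if (nrow(ch$candidates) == 0) return(NULL)
    cbind(target = ch$target_snp, ch$candidates,
          chosen = ch$candidates$snp_id %in% ch$chosen)
  }))
  utils::write.table(rows, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
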