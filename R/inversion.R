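## Inversion diplotype calling from unphased tag-SNP genotypes.
##
## The H1/H2 inversion suppresses recombination, so SNPs inside it behave as
## a single biallelic locus: subjects fall into three groups (homozygous for
## one haplotype, heterozygous, counter-homozygous) that many "indicator"
## SNPs trichotomise identically. The caller seeds the three groups from
## full-coverage SNPs, collects concordant indicator SNPs, and assigns every
## subject to the group whose consensus genotype vector it best matches.

#' Seed the three-group subject partition from full-coverage SNPs
#'
#' Among SNPs with no missing calls whose major homozygous and heterozygous
#' classes are both populated (the minor homozygous class may be empty in
#' small or low-frequency cohorts), finds the largest set inducing the
#' identical 3-way subject partition (up to allele relabelling) and returns
#' that partition. Group 1 is the larger
#' homozygous class (presumed H1_H1), group 2 the heterozygotes, group 3 the
#' minor homozygotes.
#'
#' @param gm a [genotype_matrix()].
#' @param min_group_frac genotype classes smaller than this fraction of
#'   subjects are not required to be non-empty when matching partitions
#'   (default 0.01); such subjects are resolved later by maximum similarity.
#' @param tol discordance tolerance used when scoring candidate partitions
#'   by their genome-wide indicator support (default 10).
#' @param min_coverage minimum SNP call rate eligible for seeding (default
#'   1, i.e. no missing data). When relaxed below 1 and no fully covered
#'   SNP exists, the single best-covered eligible SNP seeds the partition
#'   and its ungenotyped subjects are resolved by maximum similarity.
#' @return list with `groups` (list of three subject-ID vectors),
#'   `seed_snps` (ids), `seed_orientation` (per seed SNP, the allele carried
#'   by group 3, i.e. the H2-tagging allele).
#' @export
seed_partition <- function(gm, min_group_frac = 0.01, min_coverage = 1,
                           tol = 10) {
  codes <- geno_codes(gm)
  n <- nrow(codes)
  cov <- colMeans(!is.na(codes))
  full <- which(cov >= min_coverage)
  ## a seed SNP needs the major homozygous class and the heterozygous class;
  ## the minor homozygous class may be empty (rare-haplotype cohorts)
  full <- full[vapply(full, function(j) {
    tb <- tabulate(codes[, j] + 1L, 3L)
    max(tb[c(1, 3)]) >= 1 && tb[2] >= 1
  }, logical(1))]
  if (length(full) == 0) {
    stop("no SNP with coverage >= ", min_coverage,
         " and usable genotype classes; relax min_coverage or supply more SNPs")
  }
  if (any(cov[full] < 1)) {
    ## relaxed mode: seed from the single best-covered SNP
    j <- full[order(-cov[full], gm$snps$pos[full])][1]
    g <- codes[, j]
    if (sum(g == 2, na.rm = TRUE) > sum(g == 0, na.rm = TRUE)) g <- 2L - g
    groups <- list(gm$subjects[!is.na(g) & g == 0],
                   gm$subjects[!is.na(g) & g == 1],
                   gm$subjects[!is.na(g) & g == 2])
    h2 <- if (sum(codes[, j] == 2, na.rm = TRUE) >
                sum(codes[, j] == 0, na.rm = TRUE))
      gm$snps$allele_a[j] else gm$snps$allele_b[j]
    return(list(groups = groups, seed_snps = gm$snps$snp_id[j],
                seed_orientation = h2))
  }
  ## canonical orientation: larger homozygous class is code 0
  canon <- vapply(full, function(j) {
    g <- codes[, j]
    if (sum(g == 2) > sum(g == 0)) g <- 2L - g
    g
  }, integer(n))
  keys <- apply(canon, 2, paste, collapse = "")
  ## candidate partitions = distinct keys; score each by how many SNPs in
  ## the whole matrix behave as indicators for it (the inversion partition
  ## is the one "many SNPs" trichotomise identically); ties: larger seed
  ## set, then lower genomic position
  uk <- unique(keys)
  cand <- lapply(uk, function(k) {
    g <- canon[, match(k, keys)]
    part_k <- list(groups = list(gm$subjects[g == 0], gm$subjects[g == 1],
                                 gm$subjects[g == 2]))
    support <- nrow(find_indicators(gm, part_k, tol = tol))
    list(key = k, groups = part_k$groups, support = support,
         n_seed = sum(keys == k),
         min_pos = min(gm$snps$pos[full[keys == k]]))
  })
  ord <- order(-vapply(cand, `[[`, 0, "support"),
               -vapply(cand, `[[`, 0, "n_seed"),
               vapply(cand, `[[`, 0, "min_pos"))
  best <- cand[[ord[1]]]
  seed <- full[keys == best$key]
  groups <- best$groups
  orientation <- vapply(seed, function(j) {
    gg <- codes[, j]
    minor_code <- if (sum(gg == 2) > sum(gg == 0)) 0L else 2L
    if (minor_code == 2L) gm$snps$allele_b[j] else gm$snps$allele_a[j]
  }, "")
  list(groups = groups, seed_snps = gm$snps$snp_id[seed],
       seed_orientation = unname(orientation))
}

#' Collect indicator SNPs concordant with a 3-group partition
#'
#' A SNP qualifies as an indicator when, ignoring missing calls and allowing
#' at most `tol` discordant subjects in total, group 1 is homozygous for one
#' allele, group 2 heterozygous, and group 3 homozygous for the other
#' allele. The tolerated discordance absorbs rare genotyping errors and
#' post-divergence mutations. The H2-tagging allele of each indicator is the
#' group 3 homozygote allele.
#'
#' @param gm a [genotype_matrix()].
#' @param part partition from [seed_partition()].
#' @param tol maximum discordant subjects per SNP (default 10).
#' @return data frame `snp_id`, `h2_allele`, `n_discordant`, `call_rate`.
#' @export
find_indicators <- function(gm, part, tol = 10) {
  codes <- geno_codes(gm)
  i1 <- gm$subjects %in% part$groups[[1]]
  i2 <- gm$subjects %in% part$groups[[2]]
  i3 <- gm$subjects %in% part$groups[[3]]
  out <- lapply(seq_len(nrow(gm$snps)), function(j) {
    g <- codes[, j]
    ## majority homozygote code within group 1 fixes the orientation
    t1 <- tabulate(g[i1] + 1L, 3L)
    if (t1[1] == 0 && t1[3] == 0) return(NULL)
    hom1 <- if (t1[1] >= t1[3]) 0L else 2L
    hom3 <- 2L - hom1
    disc <- sum(g[i1] != hom1, na.rm = TRUE) +
      sum(g[i2] != 1L, na.rm = TRUE) +
      sum(g[i3] != hom3, na.rm = TRUE)
    ## group 2 must actually look heterozygous and group 3 counter-homozygous
    ok2 <- sum(i2 & !is.na(g)) == 0 ||
      sum(g[i2] == 1L, na.rm = TRUE) > sum(g[i2] != 1L, na.rm = TRUE)
    ok3 <- sum(i3 & !is.na(g)) == 0 ||
      sum(g[i3] == hom3, na.rm = TRUE) > sum(g[i3] != hom3, na.rm = TRUE)
    if (disc > tol || !ok2 || !ok3) return(NULL)
    h2 <- if (hom3 == 2L) gm$snps$allele_b[j] else gm$snps$allele_a[j]
    data.frame(snp_id = gm$snps$snp_id[j], h2_allele = h2,
               n_discordant = disc, call_rate = mean(!is.na(g)),
               hom1_code = hom1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(snp_id = character(), h2_allele = character(),
                                      n_discordant = integer(),
                                      call_rate = numeric(), hom1_code = integer())
  out
}

#' Assign every subject to an inversion diplotype by maximum similarity
#'
#' Each subject is scored against the three group-consensus genotype vectors
#' over the indicator SNPs (matching calls / non-missing comparisons) and
#' assigned to the best-scoring group; ties and subjects with no non-missing
#' indicator call are left `UNASSIGNED`. The larger homozygous group is
#' labelled `H1_H1`.
#'
#' @param gm a [genotype_matrix()].
#' @param indicators data frame from [find_indicators()].
#' @param part partition from [seed_partition()].
#' @return an `"inversion_call"` object: per-subject `label`, `mismatches`,
#'   `best_score`; `indicator_set`; `representative_snp`; `group_sizes`.
#' @export
assign_subjects <- function(gm, indicators, part) {
  if (nrow(indicators) == 0) stop("empty indicator set")
  jj <- match(indicators$snp_id, gm$snps$snp_id)
  codes <- geno_codes(gm)[, jj, drop = FALSE]
  ## consensus per group: group1 = hom1_code, group2 = het, group3 = counter
  cons <- rbind(indicators$hom1_code, 1L, 2L - indicators$hom1_code)
  score <- function(grow) {
    cmp <- sweep(codes, 2, grow, FUN = "==")
    matches <- rowSums(cmp, na.rm = TRUE)
    nonmiss <- rowSums(!is.na(codes))
    list(m = matches, n = nonmiss)
  }
  s1 <- score(cons[1, ]); s2 <- score(cons[2, ]); s3 <- score(cons[3, ])
  nonmiss <- s1$n
  frac <- cbind(s1$m, s2$m, s3$m) / ifelse(nonmiss == 0, NA, nonmiss)
  lab <- c("H1_H1", "H1_H2", "H2_H2")
  best <- apply(frac, 1, function(r) {
    if (all(is.na(r))) return(NA_integer_)
    w <- which(r == max(r))
    if (length(w) > 1) NA_integer_ else w
  })
  label <- ifelse(is.na(best), "UNASSIGNED", lab[best])
  mismatches <- ifelse(is.na(best), NA_integer_,
                       nonmiss - cbind(s1$m, s2$m, s3$m)[cbind(seq_along(best), best)])
  ## the larger assigned homozygous group carries the H1_H1 label
  if (sum(label == "H2_H2") > sum(label == "H1_H1")) {
    label[label == "H1_H1"] <- ".tmp"
    label[label == "H2_H2"] <- "H1_H1"
    label[label == ".tmp"] <- "H2_H2"
  }
  gs <- c(H1_H1 = sum(label == "H1_H1"), H1_H2 = sum(label == "H1_H2"),
          H2_H2 = sum(label == "H2_H2"), UNASSIGNED = sum(label == "UNASSIGNED"))
  structure(list(
    subjects = gm$subjects, label = unname(label),
    mismatches = unname(mismatches),
    best_score = unname(apply(frac, 1, max, na.rm = FALSE)),
    indicator_set = indicators,
    representative_snp = pick_representative(indicators, gm),
    group_sizes = gs, seed_snps = part$seed_snps
  ), class = "inversion_call")
}

#' @export
print.inversion_call <- function(x, ...) {
  n <- length(x$subjects)
  cat("Inversion diplotype call:", n, "subjects,",
      nrow(x$indicator_set), "indicator SNPs\n")
  gs <- x$group_sizes
  for (g in names(gs)) {
    cat(sprintf("  %-10s %6d (%.1f%%)\n", g, gs[[g]], 100 * gs[[g]] / n))
  }
  cat("Representative SNP:", x$representative_snp, "\n")
  cat(sprintf("Estimated H2 haplotype frequency: %.3f\n", h2_frequency(x)))
  invisible(x)
}

#' Pick the representative indicator SNP
#'
#' The indicator SNP with maximal call rate; ties broken by smallest genomic
#' position. One SNP suffices to represent the inversion in regression
#' because the indicators are in near-perfect linkage.
#'
#' @param indicators data frame from [find_indicators()].
#' @param gm a [genotype_matrix()].
#' @return the SNP id.
#' @export
pick_representative <- function(indicators, gm) {
  stopifnot(nrow(indicators) >= 1)
  pos <- gm$snps$pos[match(indicators$snp_id, gm$snps$snp_id)]
  ord <- order(-indicators$call_rate, pos)
  indicators$snp_id[ord[1]]
}

#' Estimated H2 haplotype frequency from called diplotypes
#'
#' \eqn{(2 n_{H2H2} + n_{H1H2}) / (2 n_{assigned})}.
#'
#' @param res an `"inversion_call"`.
#' @return proportion between 0 and 1.
#' @export
h2_frequency <- function(res) {
  gs <- res$group_sizes
  n_assigned <- gs[["H1_H1"]] + gs[["H1_H2"]] + gs[["H2_H2"]]
  if (n_assigned == 0) stop("no assigned subjects; H2 frequency undefined")
  (2 * gs[["H2_H2"]] + gs[["H1_H2"]]) / (2 * n_assigned)
}

#' Call inversion diplotypes end to end
#'
#' Runs [seed_partition()], [find_indicators()] and [assign_subjects()] in
#' one pass (no iterative refinement, for determinism).
#'
#' @param gm a [genotype_matrix()] restricted to the inversion region.
#' @param tol per-SNP discordance tolerance for indicator admission.
#' @param min_group_frac,min_coverage see [seed_partition()].
#' @return an `"inversion_call"`.
#' @export
call_inversion <- function(gm, tol = 10, min_group_frac = 0.01,
                           min_coverage = 1) {
  part <- seed_partition(gm, min_group_frac, min_coverage, tol = tol)
  ind <- find_indicators(gm, part, tol = tol)
  assign_subjects(gm, ind, part)
}

#' Write inversion-call results
#'
#' TSV of per-subject label, mismatch count and best similarity score, plus
#' a JSON sidecar with the indicator SNP ids, their H2-tagging alleles and
#' the representative SNP.
#'
#' @param res an `"inversion_call"`.
#' @param tsv_path,json_path output paths.
#' @export
write_inversion_call <- function(res, tsv_path, json_path = NULL) {
  d <- data.frame(subject_id = res$subjects, label = res$label,
                  mismatches = res$mismatches,
                  best_score = round(res$best_score, 4))
  utils::write.table(d, tsv_path, quote = FALSE, sep = "\t", row.names = FALSE)
  if (!is.null(json_path)) {
    js <- paste0(
      '{"representative_snp": "', res$representative_snp, '", ',
      '"indicator_snps": [',
      paste0('{"snp_id": "', res$indicator_set$snp_id,
             '", "h2_allele": "', res$indicator_set$h2_allele, '"}',
             collapse = ", "),
      "]}")
    writeLines(js, json_path)
  }
  invisible(tsv_path)
}
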