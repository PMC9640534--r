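## Descriptive tables, negative-control sampling and full-analysis
## orchestration.

#' Genotype-by-children-count cross-tabulation
#'
#' Counts of subjects at each children-count value per genotype class, with
#' derived pooled rows (`het+hom2`, `hom1+het`) and allele-dosage rows
#' (each homozygote contributes two copies of its allele, each heterozygote
#' one of each).
#'
#' @param genotype factor-like vector of genotype labels; `hom1` and `hom2`
#'   name the two homozygote classes and `het` the heterozygote, in the
#'   order `c(hom2, het, hom1)` to be displayed (e.g. CC, CT, TT).
#' @param nci non-negative integer children counts.
#' @param class_order optional explicit row order for the three classes;
#'   default: sorted so the rarer homozygote is first.
#' @return a `"nci_table"`: integer matrix, rows = classes plus derived
#'   rows, columns = children counts 0..max observed.
#' @export
crosstab_nci <- function(genotype, nci, class_order = NULL) {
  stopifnot(length(genotype) == length(nci), all(nci >= 0))
  g <- as.character(genotype)
  observed <- unique(g[!is.na(g)])
  if (any(nchar(observed) != 2)) {
    stop("genotype labels must be two-character allele pairs (e.g. CC, CT)")
  }
  alleles <- sort(unique(unlist(strsplit(observed, ""))))
  if (length(alleles) != 2) {
    stop("expected exactly two alleles across genotype labels, got ",
         paste(alleles, collapse = ", "))
  }
  ## normalise heterozygote spelling to sorted allele order
  het <- paste0(alleles[1], alleles[2])
  g[g %in% c(het, paste0(alleles[2], alleles[1]))] <- het
  homs <- paste0(alleles, alleles)
  if (is.null(class_order)) {
    sizes <- table(factor(g, levels = homs))
    homs <- homs[order(sizes, homs)]          # rarer homozygote first
    class_order <- c(homs[1], het, homs[2])
  }
  kmax <- max(nci)
  base <- t(vapply(class_order, function(cl) {
    tabulate(factor(nci[g == cl], levels = 0:kmax), kmax + 1)
  }, numeric(kmax + 1)))
  colnames(base) <- 0:kmax
  hom2 <- class_order[1]; hom1 <- class_order[3]
  a2 <- substr(hom2, 1, 1)                    # allele of the rarer homozygote
  a1 <- substr(hom1, 1, 1)
  out <- rbind(
    base,
    `het+hom1` = base[2, ] + base[3, ],
    `hom2+het` = base[1, ] + base[2, ],
    allele2 = 2 * base[1, ] + base[2, ],
    allele1 = 2 * base[3, ] + base[2, ]
  )
  rownames(out)[4:7] <- c(paste0(het, "+", hom1), paste0(hom2, "+", het),
                          paste0("allele_", a2), paste0("allele_", a1))
  structure(out, class = c("nci_table", "matrix"),
            classes = class_order, alleles = c(a2, a1))
}

#' Build the cross-tabulation from pre-counted genotype rows
#'
#' For published contingency counts (three genotype rows over children
#' counts 0..k) rather than per-subject vectors.
#'
#' @param counts integer matrix with three rows named by genotype (rarer
#'   homozygote, heterozygote, common homozygote, e.g. CC, CT, TT) and
#'   columns = children counts starting at 0.
#' @return a `"nci_table"` with the derived rows added.
#' @export
nci_table_from_counts <- function(counts) {
  stopifnot(nrow(counts) == 3)
  cls <- rownames(counts)
  is_het <- substr(cls, 1, 1) != substr(cls, 2, 2)
  stopifnot(sum(is_het) == 1, which(is_het) == 2)
  hom2 <- cls[1]; het <- cls[2]; hom1 <- cls[3]
  out <- rbind(
    counts,
    counts[2, ] + counts[3, ],
    counts[1, ] + counts[2, ],
    2 * counts[1, ] + counts[2, ],
    2 * counts[3, ] + counts[2, ]
  )
  rownames(out) <- c(cls, paste0(het, "+", hom1), paste0(hom2, "+", het),
                     paste0("allele_", substr(hom2, 1, 1)),
                     paste0("allele_", substr(hom1, 1, 1)))
  colnames(out) <- seq_len(ncol(counts)) - 1
  structure(out, class = c("nci_table", "matrix"),
            classes = cls, alleles = substr(c(hom2, hom1), 1, 1))
}

#' @export
print.nci_table <- function(x, ...) {
  cat("Children-count cross-tabulation (columns = NCI):\n")
  print(unclass(x))
  mn <- apply(x, 1, group_mean_nci)
  cat("\nTotals and means:\n")
  print(data.frame(total = rowSums(x), mean_nci = round(mn, 2)))
  invisible(x)
}

#' Mean children count of a count row
#'
#' \eqn{\sum_k k\, n_k / \sum_k n_k}; full precision (round only for
#' display).
#'
#' @param row named numeric vector of counts over children counts 0..k
#'   (names taken as the count values; unnamed rows assume 0..k).
#' @return the mean.
#' @export
group_mean_nci <- function(row) {
  tot <- sum(row)
  if (tot == 0) stop("empty count row; mean undefined")
  k <- if (is.null(names(row))) seq_along(row) - 1 else as.numeric(names(row))
  sum(k * row) / tot
}

#' Dominance and recessive descriptive contrasts
#'
#' `recessive` = mean(children | H2 homozygote) minus mean(children |
#' carrier-or-less, i.e. heterozygote + H1 homozygote); `dominant` =
#' mean(children | H2 homozygote or heterozygote) minus mean(children | H1
#' homozygote). Both are returned at full precision and in a display
#' variant where each group mean is first rounded to 3 decimals and then
#' subtracted (the arithmetic used when quoting rounded tables).
#'
#' @param tab a `"nci_table"` (row 1 = H2 homozygote, row 2 = heterozygote,
#'   row 3 = H1 homozygote, plus the derived rows).
#' @return list with `recessive`, `dominant`, `recessive_3dp`,
#'   `dominant_3dp` and the group means.
#' @export
dominance_contrasts <- function(tab) {
  stopifnot(inherits(tab, "nci_table"))
  if (any(rowSums(tab[1:3, ]) == 0)) stop("empty genotype class")
  m_hom2 <- group_mean_nci(tab[1, ])
  m_rest <- group_mean_nci(tab[2, ] + tab[3, ])
  m_carrier <- group_mean_nci(tab[1, ] + tab[2, ])
  m_hom1 <- group_mean_nci(tab[3, ])
  r3 <- function(x) round(x, 3)
  list(recessive = m_hom2 - m_rest,
       dominant = m_carrier - m_hom1,
       recessive_3dp = r3(m_hom2) - r3(m_rest),
       dominant_3dp = r3(m_carrier) - r3(m_hom1),
       means = c(hom2 = m_hom2, het_plus_hom1 = m_rest,
                 hom2_plus_het = m_carrier, hom1 = m_hom1))
}

#' H2 allele prevalence from a cross-tabulation
#'
#' Number of H2 alleles over total alleles, from the allele-dosage rows.
#'
#' @param tab a `"nci_table"`.
#' @return proportion.
#' @export
allele_prevalence <- function(tab) {
  al <- attr(tab, "alleles")
  n2 <- sum(tab[paste0("allele_", al[1]), ])
  n1 <- sum(tab[paste0("allele_", al[2]), ])
  n2 / (n1 + n2)
}

#' Published genotype-by-children-count reference table
#'
#' The genotype-by-NCI contingency counts for rs12373123, the SNP
#' representing the 17q21.31 inversion in the Polish cohort analysis
#' (male and female reports combined; CC is the H2-homozygote class).
#'
#' @return a `"nci_table"` built from the packaged counts.
#' @export
published_nci_counts <- function() {
  path <- system.file("extdata", "rs12373123_nci_counts.tsv",
                      package = "invfert", mustWork = TRUE)
  d <- utils::read.table(path, header = TRUE, row.names = 1, sep = "\t",
                         check.names = FALSE)
  nci_table_from_counts(as.matrix(d))
}

#' Sample negative-control SNPs
#'
#' Draws `n_target` SNP ids uniformly without replacement, then applies the
#' exclusions in order: SNPs on the excluded chromosomes or inside the
#' inversion region, then SNPs without all three genotype classes observed.
#'
#' @param gm a [genotype_matrix()] of candidate SNPs.
#' @param n_target number of ids drawn before exclusions (default 200).
#' @param excluded_chroms chromosomes never used as controls (default
#'   1, 5, 14, X, Y: chromosomes carrying candidate loci or sex linked).
#' @param region list `(chrom, start, end)` excluded as the inversion
#'   region; default 17:43488002-44857562 (the flanking-marker interval).
#' @param seed RNG seed for the draw.
#' @return character vector of surviving control SNP ids.
#' @export
sample_negative_controls <- function(gm, n_target = 200,
                                     excluded_chroms = c("1", "5", "14", "X", "Y"),
                                     region = list(chrom = "17",
                                                   start = 43488002,
                                                   end = 44857562),
                                     seed = 1) {
  set.seed(seed)
  ids <- sample(gm$snps$snp_id, min(n_target, nrow(gm$snps)))
  j <- match(ids, gm$snps$snp_id)
  in_region <- gm$snps$chrom[j] == region$chrom &
    gm$snps$pos[j] >= region$start & gm$snps$pos[j] <= region$end
  bad_chrom <- gm$snps$chrom[j] %in% excluded_chroms
  keep <- !(bad_chrom | in_region)
  ids <- ids[keep]; j <- j[keep]
  three <- vapply(j, function(jj) {
    tb <- tabulate(geno_codes(gm, jj) + 1L, 3L)
    all(tb >= 1)
  }, logical(1))
  out <- ids[three]
  if (length(out) < 1) stop("no control SNP survives the exclusions")
  out
}

#' Run the full association analysis
#'
#' Orchestrates: genotype/phenotype ingestion, SNP quality filters, the
#' age-range filter, region slicing, inversion diplotype calling,
#' representative-SNP selection, the descriptive cross-tabulation with
#' dominance/recessive contrasts, age-bin weights, the interaction model
#' with pruning, Wald term tests, the overdispersion check and Bonferroni
#' decisions; optionally surrogate selection and negative-control testing.
#' Subject and SNP counts are logged at every stage.
#'
#' @param genotypes a [genotype_matrix()], or `ped`/`map` paths via
#'   `ped_path`, `map_path`.
#' @param phenotypes phenotype data frame (or path via `phenotype_path`).
#' @param ped_path,map_path,phenotype_path optional file inputs.
#' @param region list `(chrom, start, end)` delimiting the inversion SNPs;
#'   default 17:43793582-44776837 (the inner marker interval).
#' @param tol indicator-SNP discordance tolerance.
#' @param min_call_rate,min_maf SNP filter thresholds.
#' @param min_age_female,min_age_male age-range bounds.
#' @param nonevent_threshold children-count recode threshold.
#' @param bonferroni_m number of tests in the Bonferroni family (default 7).
#' @param ld_targets optional SNP ids for surrogate selection.
#' @param control_snps optional number of negative-control SNPs to test.
#' @param seed seed for the control-SNP draw.
#' @return an `"analysis_report"` list: `log` (stage counts), `filter`,
#'   `inversion`, `representative_snp`, `table1`, `contrasts`,
#'   `h2_prevalence`, `fit` (final model or status), `terms`,
#'   `overdispersion`, `bonferroni`, `surrogates`, `controls`.
#' @export
run_full_analysis <- function(genotypes = NULL, phenotypes = NULL,
                              ped_path = NULL, map_path = NULL,
                              phenotype_path = NULL,
                              region = list(chrom = "17",
                                            start = 43793582,
                                            end = 44776837),
                              tol = 10, min_call_rate = 0.75, min_maf = 0.01,
                              min_age_female = 45, min_age_male = 55,
                              nonevent_threshold = 3, bonferroni_m = 7,
                              ld_targets = NULL, control_snps = NULL,
                              seed = 1) {
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- paste0(...)
    message("[", stage, "] ", log[[stage]])
  }
  if (is.null(genotypes)) {
    stopifnot(!is.null(ped_path), !is.null(map_path))
    genotypes <- read_ped_map(ped_path, map_path)$genotypes
  }
  if (is.null(phenotypes)) {
    stopifnot(!is.null(phenotype_path))
    phenotypes <- read_phenotypes(phenotype_path)
  }
  note("input", length(genotypes$subjects), " subjects, ",
       nrow(genotypes$snps), " SNPs, ", nrow(phenotypes), " phenotype rows")

  fl <- filter_snps(genotypes, min_call_rate, min_maf)
  gm <- fl$genotypes
  note("snp_filter", nrow(gm$snps), " SNPs kept of ", fl$report$n_input)

  ph <- filter_age_range(phenotypes, min_age_female, min_age_male)
  note("age_filter", nrow(ph), " subjects in age range of ", nrow(phenotypes))
  keep <- genotypes$subjects %in% ph$subject_id
  gm <- subset_subjects(gm, which(keep))
  ph <- ph[match(gm$subjects, ph$subject_id), , drop = FALSE]

  reg <- region_slice(gm, region$chrom, region$start, region$end)
  note("region", nrow(reg$snps), " SNPs in ", region$chrom, ":",
       region$start, "-", region$end)

  inv <- tryCatch(call_inversion(reg, tol = tol),
                  error = function(e) {
                    note("seed_relax",
                         "no full-coverage SNP; seeding from best-covered SNP")
                    call_inversion(reg, tol = tol, min_coverage = 0)
                  })
  note("inversion", paste(names(inv$group_sizes), inv$group_sizes,
                          sep = "=", collapse = " "))
  rep_snp <- inv$representative_snp

  ## genotype labels of the representative SNP, as allele pairs
  jr <- match(rep_snp, gm$snps$snp_id)
  lab <- paste0(gm$a1[, jr], gm$a2[, jr])
  lab[is.na(gm$a1[, jr])] <- NA
  ok <- !is.na(lab) & !is.na(ph$nci)
  tab1 <- crosstab_nci(lab[ok], ph$nci[ok])
  contr <- dominance_contrasts(tab1)
  prev <- allele_prevalence(tab1)
  note("descriptives", sum(ok), " subjects genotyped at ", rep_snp,
       "; H2 allele prevalence ", sprintf("%.1f%%", 100 * prev))

  w <- age_bin_weights(ph$age[ok])
  glab <- factor(lab[ok])
  ## reference level = the rarer (H2) homozygote class, so coefficients are
  ## printed for the heterozygote and the common homozygote
  ref <- attr(tab1, "classes")[1]
  glab <- stats::relevel(glab, ref = ref)
  fitres <- fit_snp_model(ph$nci[ok], glab, ph$age[ok], ph$sex[ok],
                          weights = w, threshold = nonevent_threshold)
  note("model", fitres$status)
  terms <- fitres$terms
  od <- if (fitres$status == "ok") overdispersion_check(fitres$fit) else NULL
  bonf <- if (!is.null(terms)) {
    b <- bonferroni(terms$p[terms$term == "snp"], m = bonferroni_m)
    cbind(term = "snp", b)
  } else NULL

  surrogates <- NULL
  if (!is.null(ld_targets)) {
    surrogates <- tryCatch({
      s <- lapply(ld_targets, function(t) select_surrogates(gm, t))
      names(s) <- ld_targets
      note("surrogates", length(ld_targets), " target(s) processed")
      s
    }, error = function(e) {
      note("surrogates", "stage failed: ", conditionMessage(e))
      NULL
    })
  }

  controls <- NULL
  if (!is.null(control_snps)) controls <- tryCatch({
    ids <- sample_negative_controls(gm, n_target = control_snps, seed = seed)
    controls <- lapply(ids, function(id) {
      jc <- match(id, gm$snps$snp_id)
      cl <- paste0(gm$a1[, jc], gm$a2[, jc])
      cl[is.na(gm$a1[, jc])] <- NA
      okc <- ok & !is.na(cl)
      f <- fit_snp_model(ph$nci[okc], factor(cl[okc]), ph$age[okc],
                         ph$sex[okc])
      p <- if (f$status == "ok") f$terms$p[f$terms$term == "snp"] else NA
      data.frame(snp_id = id, status = f$status, p_snp = p)
    })
    controls <- do.call(rbind, controls)
    note("controls", sum(controls$status == "ok"), " of ",
         nrow(controls), " control models formed")
    controls
  }, error = function(e) {
    note("controls", "stage failed: ", conditionMessage(e))
    NULL
  })

  structure(list(log = log, filter = fl$report, inversion = inv,
                 representative_snp = rep_snp, table1 = tab1,
                 contrasts = contr, h2_prevalence = prev,
                 fit = if (fitres$status == "ok") fitres$fit else NULL,
                 fit_status = fitres$status, terms = terms,
                 overdispersion = od, bonferroni = bonf,
                 surrogates = surrogates, controls = controls,
                 seed = seed),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Inversion-fertility analysis report\n")
  for (s in names(x$log)) cat(sprintf("  %-12s %s\n", s, x$log[[s]]))
  cat("\nRecessive contrast:",
      sprintf("%.4f", x$contrasts$recessive),
      " Dominant contrast:", sprintf("%.4f", x$contrasts$dominant), "\n")
  if (!is.null(x$terms)) {
    cat("\nCount-component Wald term tests:\n")
    print(x$terms, row.names = FALSE)
  }
  if (!is.null(x$bonferroni)) {
    cat("\nBonferroni (m adjusted):\n")
    print(x$bonferroni, row.names = FALSE)
  }
  invisible(x)
}
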