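## Genotype and phenotype input/output.
##
## A genotype matrix is stored as two n x m character matrices of allele
## calls (a1, a2), normalised so a1 <= a2 alphabetically, with NA for
## missing, plus a SNP table (snp_id, chrom, pos, allele_a, allele_b) and a
## subject-ID vector. Coordinates are 1-based GRCh37.

#' Construct a genotype matrix object
#'
#' @param subjects character vector of unique subject IDs.
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`, and
#'   optionally `allele_a`, `allele_b` (derived from the calls if absent).
#' @param a1,a2 character matrices (subjects x SNPs) of allele calls, NA for
#'   missing.
#' @return an object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(subjects, snps, a1, a2) {
  stopifnot(!anyDuplicated(subjects), !anyDuplicated(snps$snp_id),
            nrow(a1) == length(subjects), ncol(a1) == nrow(snps),
            identical(dim(a1), dim(a2)))
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  if (is.null(snps$allele_a) || is.null(snps$allele_b)) {
    al <- lapply(seq_len(nrow(snps)), function(j) {
      u <- sort(unique(c(a1[, j], a2[, j])))
      u[!is.na(u)]
    })
    snps$allele_a <- vapply(al, function(u) if (length(u) >= 1) u[1] else NA_character_, "")
    snps$allele_b <- vapply(al, function(u) if (length(u) >= 2) u[2] else NA_character_, "")
  }
  structure(list(subjects = as.character(subjects), snps = snps,
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$subjects), "subjects x",
      nrow(x$snps), "SNPs\n")
  cr <- mean(!is.na(x$a1))
  cat(sprintf("Overall call rate: %.1f%%\n", 100 * cr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$subjects), nrow(x$snps))

#' Per-subject genotype codes for one or all SNPs
#'
#' Code 0 = homozygous `allele_a`, 1 = heterozygous, 2 = homozygous
#' `allele_b`, NA = missing.
#'
#' @param gm a [genotype_matrix()].
#' @param j SNP index or id; NULL for the full integer matrix.
#' @return integer vector or matrix.
#' @export
geno_codes <- function(gm, j = NULL) {
  code_col <- function(jj) {
    aa <- gm$snps$allele_a[jj]; bb <- gm$snps$allele_b[jj]
    g <- rep(NA_integer_, length(gm$subjects))
    x1 <- gm$a1[, jj]; x2 <- gm$a2[, jj]
    ok <- !is.na(x1)
    g[ok & x1 == x2 & x1 == aa] <- 0L
    g[ok & x1 != x2] <- 1L
    if (!is.na(bb)) g[ok & x1 == x2 & x1 == bb] <- 2L
    g
  }
  if (!is.null(j)) {
    if (is.character(j)) j <- match(j, gm$snps$snp_id)
    return(code_col(j))
  }
  out <- vapply(seq_len(nrow(gm$snps)), code_col,
                integer(length(gm$subjects)))
  dimnames(out) <- list(gm$subjects, gm$snps$snp_id)
  out
}

#' Read PLINK text PED/MAP genotypes
#'
#' PED rows: family ID, individual ID, father, mother, sex, phenotype, then
#' two allele columns per MAP SNP ("0 0" = missing). MAP rows: chromosome,
#' SNP id, genetic distance, base-pair position. Allele order within a
#' genotype is normalised (unordered pair); subject order follows the file.
#'
#' @param ped_path,map_path file paths.
#' @return list with `genotypes` (a [genotype_matrix()]) and `ped_info`
#'   (data frame of the six leading PED columns).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop("PED row ", i, " has ", length(tok), " fields; expected ",
           6 + 2 * m, " for ", m, " MAP SNPs")
    }
    al <- tok[-(1:6)]
    bad <- !al %in% c("A", "C", "G", "T", "0")
    if (any(bad)) {
      stop("PED row ", i, ": non-ACGT0 allele symbol '", al[bad][1], "'")
    }
    x1 <- al[c(TRUE, FALSE)]
    x2 <- al[c(FALSE, TRUE)]
    miss <- x1 == "0" | x2 == "0"
    x1[miss] <- NA; x2[miss] <- NA
    a1[i, ] <- x1; a2[i, ] <- x2
    info[[i]] <- tok[1:6]
  }
  info <- if (n == 0) {
    data.frame(fid = character(), iid = character(), father = character(),
               mother = character(), sex = character(),
               phenotype = character())
  } else {
    stats::setNames(
      as.data.frame(do.call(rbind, info), stringsAsFactors = FALSE),
      c("fid", "iid", "father", "mother", "sex", "phenotype"))
  }
  snps <- map[, c("snp_id", "chrom", "pos")]
  gm <- genotype_matrix(info$iid, snps, a1, a2)
  list(genotypes = gm, ped_info = info)
}

#' Write PLINK text PED/MAP genotypes
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param ped_info optional data frame of the six leading PED columns; by
#'   default FID = IID = subject ID, parents 0, sex/phenotype 0/-9.
#' @export
write_ped_map <- function(gm, ped_path, map_path, ped_info = NULL) {
  map <- data.frame(chrom = gm$snps$chrom, snp_id = gm$snps$snp_id,
                    cm = 0, pos = gm$snps$pos)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- length(gm$subjects); m <- nrow(gm$snps)
  if (is.null(ped_info)) {
    ped_info <- data.frame(fid = gm$subjects, iid = gm$subjects,
                           father = rep(0, n), mother = rep(0, n),
                           sex = rep(0, n), phenotype = rep(-9, n))
  }
  a1 <- gm$a1; a2 <- gm$a2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  geno <- matrix("", n, 2 * m)
  geno[, c(TRUE, FALSE)] <- a1
  geno[, c(FALSE, TRUE)] <- a2
  rows <- cbind(as.matrix(ped_info), geno)
  lines <- if (n == 0) character(0) else apply(rows, 1, paste, collapse = " ")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read / write a phenotype table
#'
#' Tab-separated with header `subject_id, sex, age, nci, county`;
#' sex coded 1 = female, 2 = male; age in years; `nci` = number of children.
#'
#' @param path file path.
#' @param nci_cap sanity cap on children counts (default 20).
#' @return data frame.
#' @export
read_phenotypes <- function(path, nci_cap = 20) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("subject_id", "sex", "age", "nci")
  if (!all(req %in% names(ph))) {
    stop("phenotype file must have columns ", paste(req, collapse = ", "))
  }
  bad_sex <- !is.na(ph$sex) & !ph$sex %in% c(1, 2)
  if (any(bad_sex)) stop("sex must be coded 1 (female) or 2 (male)")
  if (any(ph$nci > nci_cap, na.rm = TRUE)) {
    stop("nci above sanity cap of ", nci_cap)
  }
  if (any(ph$age < 0, na.rm = TRUE)) stop("negative age")
  ph
}

#' @rdname read_phenotypes
#' @param ph phenotype data frame.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.table(ph, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' SNP quality filters
#'
#' Removes, in order: insertion/deletion records (non single-base alleles),
#' monomorphic SNPs (one allele type across all genotyped subjects), SNPs
#' genotyped in fewer than `min_call_rate` of subjects, and SNPs with minor
#' allele frequency (computed on non-missing alleles) not above `min_maf`.
#' Each excluded SNP is charged to the first rule it fails.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate call-rate threshold (default 0.75; "fewer than 75\%
#'   genotyped" is excluded).
#' @param min_maf MAF must be strictly greater than this (default 0.01).
#' @return list with `genotypes` (filtered) and `report` (a `filter_report`:
#'   `n_input`, exclusion counts per rule, `kept_ids`).
#' @export
filter_snps <- function(gm, min_call_rate = 0.75, min_maf = 0.01) {
  m <- nrow(gm$snps)
  if (m == 0 || length(gm$subjects) == 0) stop("empty genotype matrix")
  status <- rep("kept", m)
  for (j in seq_len(m)) {
    x1 <- gm$a1[, j]; x2 <- gm$a2[, j]
    obs <- !is.na(x1)
    alleles <- c(x1[obs], x2[obs])
    if (any(nchar(alleles) != 1) ||
        any(!c(gm$snps$allele_a[j], gm$snps$allele_b[j]) %in%
            c("A", "C", "G", "T", NA))) {
      status[j] <- "indel"
    } else if (length(unique(alleles)) <= 1) {
      status[j] <- "monomorphic"
    } else if (mean(obs) < min_call_rate) {
      status[j] <- "lowcall"
    } else {
      maf <- min(table(alleles)) / length(alleles)
      if (maf <= min_maf) status[j] <- "maf"
    }
  }
  keep <- status == "kept"
  report <- structure(list(
    n_input = m,
    n_excluded_indel = sum(status == "indel"),
    n_excluded_monomorphic = sum(status == "monomorphic"),
    n_excluded_lowcall = sum(status == "lowcall"),
    n_excluded_maf = sum(status == "maf"),
    kept_ids = gm$snps$snp_id[keep]
  ), class = "filter_report")
  list(genotypes = subset_snps(gm, which(keep)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report:", x$n_input, "input,",
      length(x$kept_ids), "kept\n")
  cat("  excluded: indel", x$n_excluded_indel,
      "| monomorphic", x$n_excluded_monomorphic,
      "| call rate", x$n_excluded_lowcall,
      "| MAF", x$n_excluded_maf, "\n")
  invisible(x)
}

subset_snps <- function(gm, j) {
  genotype_matrix(gm$subjects, gm$snps[j, , drop = FALSE],
                  gm$a1[, j, drop = FALSE], gm$a2[, j, drop = FALSE])
}

subset_subjects <- function(gm, i) {
  genotype_matrix(gm$subjects[i], gm$snps,
                  gm$a1[i, , drop = FALSE], gm$a2[i, , drop = FALSE])
}

#' Age-range subject filter
#'
#' Keeps women aged at least `min_age_female` and men aged at least
#' `min_age_male`, greatly reducing the chance of further children after the
#' survey. Subjects with missing sex or age are dropped with a warning.
#'
#' @param ph phenotype data frame (columns `sex`, `age`).
#' @param min_age_female,min_age_male inclusive lower bounds (defaults 45
#'   and 55 years).
#' @return the filtered phenotype data frame.
#' @export
filter_age_range <- function(ph, min_age_female = 45, min_age_male = 55) {
  if (nrow(ph) == 0) return(ph)
  miss <- is.na(ph$sex) | is.na(ph$age)
  if (any(miss)) {
    warning(sum(miss), " subject(s) dropped for missing sex or age")
    ph <- ph[!miss, , drop = FALSE]
  }
  keep <- (ph$sex == 1 & ph$age >= min_age_female) |
    (ph$sex == 2 & ph$age >= min_age_male)
  ph[keep, , drop = FALSE]
}

#' Slice a genomic region
#'
#' Closed 1-based interval: SNPs with `start_pos <= pos <= end_pos` on
#' `chrom`, in original order.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome label.
#' @param start_pos,end_pos interval bounds (bp).
#' @export
region_slice <- function(gm, chrom, start_pos, end_pos) {
  stopifnot(start_pos <= end_pos)
  j <- which(gm$snps$chrom == as.character(chrom) &
               gm$snps$pos >= start_pos & gm$snps$pos <= end_pos)
  subset_snps(gm, j)
}

#' Export concatenated diploid genotypes as FASTA
#'
#' One record per subject; the sequence is the subject's diploid bases over
#' all SNPs concatenated in chromosomal order (two characters per SNP,
#' missing rendered "NN"), for visual inspection of haplotype-group
#' structure in an alignment viewer.
#'
#' @param gm a [genotype_matrix()] (SNPs are sorted by position on output).
#' @param out_path output FASTA path.
#' @export
export_concat_fasta <- function(gm, out_path) {
  ord <- order(gm$snps$pos)
  a1 <- gm$a1[, ord, drop = FALSE]
  a2 <- gm$a2[, ord, drop = FALSE]
  a1[is.na(a1)] <- "N"; a2[is.na(a2)] <- "N"
  n <- length(gm$subjects); m <- ncol(a1)
  seqs <- vapply(seq_len(n), function(i) {
    x <- character(2 * m)
    x[c(TRUE, FALSE)] <- a1[i, ]
    x[c(FALSE, TRUE)] <- a2[i, ]
    paste(x, collapse = "")
  }, "")
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(paste0(">", gm$subjects, "\n", seqs), con)
  invisible(out_path)
}
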