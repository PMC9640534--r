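test_that("PED/MAP parsing normalises genotypes and flags malformed rows", {
  map <- c("17\trs1\t0\t44000100",
           "17\trs2\t0\t44000200",
           "17\trs3\t0\t44000300")
  ped <- c("f1 s1 0 0 1 -9 A A C T 0 0",
           "f2 s2 0 0 2 -9 A A T C A G")
  mp <- tempfile(fileext = ".map"); pp <- tempfile(fileext = ".ped")
  writeLines(map, mp); writeLines(ped, pp)
  r <- read_ped_map(pp, mp)
  gm <- r$genotypes
  expect_equal(gm$subjects, c("s1", "s2"))
  expect_equal(gm$snps$pos, c(44000100L, 44000200L, 44000300L))
  # "0 0" becomes missing; allele order within a genotype is irrelevant
  expect_true(is.na(gm$a1[1, 3]))
  expect_equal(paste0(gm$a1[1, 2], gm$a2[1, 2]), "CT")
  expect_equal(paste0(gm$a1[2, 2], gm$a2[2, 2]), "CT")
  expect_equal(geno_codes(gm, "rs2"), c(1L, 1L))

  writeLines(c("f1 s1 0 0 1 -9 A A C T"), pp)
  expect_error(read_ped_map(pp, mp), "row 1")
  writeLines(c("f1 s1 0 0 1 -9 A A C T X X"), pp)
  expect_error(read_ped_map(pp, mp), "non-ACGT0")
})

test_that("fixture write/read round-trip preserves genotype content", {
  cfg <- sim_config(n_subjects = 40, n_indicator_snps = 5, n_noise_snps = 3,
                    seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture(cfg, dir)
  coh <- simulate_cohort(cfg)
  rt <- read_ped_map(paths["ped"], paths["map"])$genotypes
  expect_equal(rt$subjects, coh$genotypes$subjects)
  expect_equal(rt$snps$pos, coh$genotypes$snps$pos)
  expect_equal(unname(rt$a1), unname(coh$genotypes$a1))
  expect_equal(unname(rt$a2), unname(coh$genotypes$a2))
  # write -> read -> write is byte-stable
  p2 <- file.path(dir, "again.ped"); m2 <- file.path(dir, "again.map")
  info <- data.frame(fid = rt$subjects, iid = rt$subjects, father = 0,
                     mother = 0, sex = coh$phenotypes$sex, phenotype = -9)
  write_ped_map(rt, p2, m2, info)
  expect_identical(readLines(p2), readLines(paths["ped"]))
  expect_identical(readLines(m2), readLines(paths["map"]))
})

test_that("SNP filters apply rules in order with exact thresholds", {
  n <- 100
  set.seed(1)
  good <- codes_to_calls(rbinom(n, 2, 0.4))
  lowcall <- good; lowcall[1:26] <- NA               # 74% call rate
  atcall <- good; atcall[1:25] <- NA                 # exactly 75%
  mono <- rep("AA", n)
  indel <- rep("AT", n); indel[1] <- "AT"            # placeholder column
  gm <- make_gm(cbind(good, lowcall, atcall, mono, indel))
  # make the last column a true indel by widening its alleles
  gm$snps$allele_a[5] <- "A"; gm$snps$allele_b[5] <- "AT"
  res <- filter_snps(gm)
  expect_equal(res$report$n_excluded_lowcall, 1)
  expect_equal(res$report$n_excluded_monomorphic, 1)
  expect_equal(res$report$n_excluded_indel, 1)
  expect_setequal(res$report$kept_ids, c("snp001", "snp003"))
  # counts ledger adds up
  rp <- res$report
  expect_equal(rp$n_input,
               length(rp$kept_ids) + rp$n_excluded_indel +
                 rp$n_excluded_monomorphic + rp$n_excluded_lowcall +
                 rp$n_excluded_maf)
  # filtering is idempotent
  res2 <- filter_snps(res$genotypes)
  expect_equal(res2$report$kept_ids, res$report$kept_ids)
  expect_equal(dim(res2$genotypes), dim(res$genotypes))
})

test_that("MAF boundary: 21 of 2000 minor alleles kept, 19 excluded", {
  n <- 1000
  kept21 <- codes_to_calls(c(rep(1, 21), rep(0, n - 21)))    # MAF 1.05%
  drop19 <- codes_to_calls(c(rep(1, 19), rep(0, n - 19)))    # MAF 0.95%
  gm <- make_gm(cbind(kept21, drop19))
  res <- filter_snps(gm)
  expect_equal(res$report$kept_ids, "snp001")
  expect_equal(res$report$n_excluded_maf, 1)
})

test_that("age-range filter keeps women >= 45 and men >= 55", {
  ph <- data.frame(subject_id = sprintf("s%d", 1:6),
                   sex = c(1, 1, 2, 2, 1, 2),
                   age = c(45, 44, 55, 54, NA, 80),
                   nci = 0)
  expect_warning(out <- filter_age_range(ph), "missing")
  expect_setequal(out$subject_id, c("s1", "s3", "s6"))
  empty <- ph[0, ]
  expect_equal(nrow(filter_age_range(empty)), 0)
})

test_that("region slice is a closed 1-based interval and splits cleanly", {
  pos <- c(43488001, 43488002, 43600000, 44000000, 44300000, 44500000,
           44700000, 44857562, 44857563, 45000000)
  calls <- matrix(rep(codes_to_calls(rep(1, 4)), 10), nrow = 4)
  gm <- make_gm(calls, pos = pos)
  r1 <- region_slice(gm, "17", 43488002, 44857562)
  expect_equal(r1$snps$pos[1], 43488002)
  expect_false(43488001 %in% r1$snps$pos)
  expect_false(44857563 %in% r1$snps$pos)
  expect_equal(nrow(r1$snps), 7)
  # enumeration: bounds spanning SNPs 3..7
  r2 <- region_slice(gm, "17", pos[3], pos[7])
  expect_equal(nrow(r2$snps), 5)
  # union over a split point equals the full slice
  split <- pos[5]
  left <- region_slice(gm, "17", pos[1], split)
  right <- region_slice(gm, "17", split + 1, pos[10])
  expect_equal(c(left$snps$snp_id, right$snps$snp_id), gm$snps$snp_id)
})

test_that("concatenated FASTA export renders diploid bases and missing as NN", {
  gm <- make_gm(rbind(c("AA", "CT"), c("AA", NA)))
  out <- tempfile(fileext = ".fasta")
  export_concat_fasta(gm, out)
  lines <- readLines(out)
  expect_equal(sum(startsWith(lines, ">")), 2)
  expect_equal(lines[2], "AACT")
  expect_equal(lines[4], "AANN")
})
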