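test_that("EM handles perfect coupling and exact equilibrium", {
  # only coupling double homozygotes: AB and ab haplotypes
  coupling <- matrix(0, 3, 3); coupling[1, 1] <- 30; coupling[3, 3] <- 70
  ld <- em_haplotypes(coupling)
  expect_equal(ld$p_AB, 0.3, tolerance = 1e-8)
  expect_equal(ld$p_ab, 0.7, tolerance = 1e-8)
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  # table exactly at independence: D = 0, LOD = 0, r2 = 0
  indep <- matrix(c(100, 200, 100, 200, 400, 200, 100, 200, 100), 3, 3)
  ld0 <- em_haplotypes(indep)
  expect_equal(ld0$D, 0, tolerance = 1e-10)
  expect_equal(ld0$lod, 0, tolerance = 1e-8)
  expect_equal(ld0$r2, 0, tolerance = 1e-10)
  # symmetric coupling at n = 100: D = 0.25, D' = r2 = 1
  sym <- matrix(0, 3, 3); sym[1, 1] <- 50; sym[3, 3] <- 50
  lds <- em_haplotypes(sym)
  expect_equal(lds$D, 0.25, tolerance = 1e-8)
  expect_equal(lds$D_prime, 1, tolerance = 1e-8)
  expect_equal(lds$r2, 1, tolerance = 1e-8)
})

test_that("EM frequencies match a brute-force grid-search oracle", {
  set.seed(11)
  for (i in 1:10) {
    tab <- random_two_locus_table(50)
    em <- em_haplotypes(tab)
    gs <- grid_search_haplotypes(tab)
    expect_lt(max(abs(c(em$p_AB, em$p_Ab, em$p_aB, em$p_ab) - gs)), 2e-3)
  }
})

test_that("EM log-likelihood is non-decreasing and identities hold", {
  set.seed(12)
  for (i in 1:10) {
    tab <- random_two_locus_table(50)
    ld <- em_haplotypes(tab)
    expect_true(all(diff(ld$loglik_trace) > -1e-9))
    pa <- 1 - ld$p_A; pb <- 1 - ld$p_B
    expect_equal(ld$r2, ld$D^2 / (ld$p_A * pa * ld$p_B * pb),
                 tolerance = 1e-12)
    expect_true(abs(ld$D_prime) <= 1 + 1e-9)
    expect_gte(ld$lod, 0)
    expect_equal(ld$p_AB + ld$p_Ab + ld$p_aB + ld$p_ab, 1, tolerance = 1e-9)
    # swapping allele labels at locus 1 negates D, preserves |D'|, r2, LOD
    sw <- em_haplotypes(tab[3:1, ])
    expect_equal(sw$D, -ld$D, tolerance = 1e-6)
    expect_equal(abs(sw$D_prime), abs(ld$D_prime), tolerance = 1e-6)
    expect_equal(sw$r2, ld$r2, tolerance = 1e-6)
    expect_equal(sw$lod, ld$lod, tolerance = 1e-6)
  }
})

test_that("monomorphic loci are rejected with a clear error", {
  mono <- matrix(0, 3, 3); mono[1, 1] <- 10; mono[1, 3] <- 10
  expect_error(em_haplotypes(mono), "monomorphic")
})

test_that("Hardy-Weinberg chi-square matches closed-form cases", {
  h <- hwe_chi2(25, 50, 25)
  expect_equal(h$chisq, 0); expect_equal(h$p, 1)
  h2 <- hwe_chi2(50, 0, 50)
  expect_equal(h2$chisq, 100)
  expect_lt(h2$p, 1e-20)
  h3 <- hwe_chi2(81, 18, 1)
  expect_equal(h3$p_allele, 0.9)
  expect_equal(h3$chisq, 0, tolerance = 1e-10)
  expect_equal(h3$p, 1)
  h4 <- hwe_chi2(100, 0, 0)   # monomorphic: no testable departure
  expect_equal(h4$p, 1)
})

test_that("r-squared recovery on simulated pairs with known truth", {
  # pA = pB = 0.5, D chosen for r2 = 0.5
  D <- sqrt(0.5 * 0.0625)
  tab <- simulate_ld_pair(10000, 0.25 + D, 0.25 - D, 0.25 - D, 0.25 + D,
                          seed = 5)
  ld <- em_haplotypes(tab)
  expect_lt(abs(ld$r2 - 0.5), 0.02)
})

test_that("surrogate selection ranks by LOD with distance tie-breaks", {
  set.seed(20)
  n <- 400
  target <- rbinom(n, 2, 0.4)
  strong <- target                          # near-perfect LD
  strong[sample(n, 5)] <- sample(0:2, 5, replace = TRUE)
  weak <- target; weak[sample(n, 200)] <- rbinom(200, 2, 0.4)
  hwe_bad <- c(rep(1, n))                   # all heterozygous: HWE violated
  unlinked <- rbinom(n, 2, 0.4)
  copy_near <- strong                       # identical genotypes, nearer
  calls <- cbind(codes_to_calls(target), codes_to_calls(strong),
                 codes_to_calls(weak), codes_to_calls(hwe_bad),
                 codes_to_calls(unlinked), codes_to_calls(copy_near))
  pos <- c(100000, 105000, 102000, 101000, 104000,
           100500)                          # copy at 500 bp, strong at 5000
  gm <- make_gm(calls, pos = pos)
  ch <- select_surrogates(gm, "snp001", window = 50000)
  # the two identical strong candidates tie on LOD; nearer first
  expect_equal(ch$chosen[1], "snp006")
  expect_equal(ch$chosen[2], "snp002")
  expect_false("snp004" %in% ch$candidates$snp_id[ch$candidates$qualifies])
  # closed window boundary: candidate at exactly +50000 in, +50001 out
  gm2 <- make_gm(cbind(codes_to_calls(target), codes_to_calls(strong),
                       codes_to_calls(strong)),
                 pos = c(100000, 150000, 150001))
  ch2 <- select_surrogates(gm2, "snp001", window = 50000)
  expect_true("snp002" %in% ch2$candidates$snp_id)
  expect_false("snp003" %in% ch2$candidates$snp_id)
  # signed distance: negative means upstream of the target
  ch3 <- select_surrogates(make_gm(cbind(codes_to_calls(target),
                                         codes_to_calls(strong)),
                                   pos = c(100000, 95000)), "snp001")
  expect_equal(ch3$candidates$distance, -5000)
})
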