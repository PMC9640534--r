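zinb_designs <- function(n = 300, seed = 21, theta = 2) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n), g = rbinom(n, 1, 0.4))
  mu <- exp(1 + 0.5 * d$x - 0.4 * d$g)
  pi_ <- plogis(-0.8 + 0.6 * d$g)
  d$y <- ifelse(runif(n) < pi_, 0L, rnbinom(n, mu = mu, size = theta))
  d
}

test_that("non-event recoding zeroes counts up to the threshold only", {
  expect_equal(recode_nonevents(c(0, 1, 2, 3)), c(0L, 0L, 0L, 0L))
  expect_equal(recode_nonevents(c(4, 13)), c(4L, 13L))
  expect_equal(recode_nonevents(c(1, 2, 5), threshold = 0), c(1L, 2L, 5L))
  expect_error(recode_nonevents(c(-1, 2)), "non-negative")
})

test_that("age-bin weights are inverse bin sizes scaled to the cohort size", {
  expect_equal(age_bin_weights(c(60, 60, 70)), c(0.75, 0.75, 1.5))
  expect_equal(age_bin_weights(rep(52, 8)), rep(1, 8))
  set.seed(2)
  ages <- sample(45:90, 137, replace = TRUE)
  expect_equal(sum(age_bin_weights(ages)), 137)
  expect_error(age_bin_weights(integer()), "empty")
})

test_that("log-likelihood matches distribution-function arithmetic exactly", {
  d <- zinb_designs()
  X <- model.matrix(~ x + g, d); Z <- X
  w <- runif(nrow(d), 0.5, 2)
  beta <- c(0.9, 0.4, -0.3); gamma <- c(-0.6, 0.2, 0.5); lt <- 0.4
  ll <- zinb_loglik(beta, gamma, lt, X, Z, d$y, w)
  mu <- exp(drop(X %*% beta)); pi_ <- plogis(drop(Z %*% gamma))
  f <- dnbinom(d$y, mu = mu, size = exp(lt))
  ref <- sum(w * log(ifelse(d$y == 0, pi_ + (1 - pi_) * f, (1 - pi_) * f)))
  expect_equal(ll, ref, tolerance = 1e-12)
})

test_that("likelihood limits: zero-inflation shutdown and the Poisson limit", {
  d <- zinb_designs(seed = 22)
  X <- model.matrix(~ x + g, d); Z <- X
  w <- rep(1, nrow(d))
  beta <- c(1, 0.5, -0.4)
  # gamma -> -Inf: reduces to the weighted negative-binomial log-likelihood
  ll <- zinb_loglik(beta, c(-50, 0, 0), 0.7, X, Z, d$y, w)
  nb <- sum(dnbinom(d$y, mu = exp(drop(X %*% beta)), size = exp(0.7),
                    log = TRUE))
  expect_equal(ll, nb, tolerance = 1e-8)
  # theta -> Inf: the count pmf approaches Poisson
  gamma <- c(-1, 0.3, 0)
  llp <- zinb_loglik(beta, gamma, log(1e8), X, Z, d$y, w)
  mu <- exp(drop(X %*% beta)); pi_ <- plogis(drop(Z %*% gamma))
  fp <- dpois(d$y, mu)
  refp <- sum(log(ifelse(d$y == 0, pi_ + (1 - pi_) * fp, (1 - pi_) * fp)))
  expect_equal(llp, refp, tolerance = 1e-6)
})

test_that("fitting with no zero component recovers weighted glm.nb estimates", {
  set.seed(9)
  n <- 500
  d <- data.frame(x = rnorm(n), g = rbinom(n, 1, 0.4))
  d$y <- rnbinom(n, mu = exp(1 + 0.5 * d$x - 0.4 * d$g), size = 2)
  w <- runif(n, 0.5, 2)
  f <- zinb(y ~ x + g | 0, data = d, weights = w)
  m <- suppressWarnings(MASS::glm.nb(y ~ x + g, data = d, weights = w))
  expect_lt(max(abs(coef(f, "count") - coef(m))), 1e-4)
  expect_equal(f$theta, m$theta, tolerance = 1e-3)
})

test_that("weight rescaling scales the log-likelihood, not the estimates", {
  d <- zinb_designs(seed = 23)
  w <- runif(nrow(d), 0.5, 2)
  f1 <- zinb(y ~ x + g, data = d, weights = w)
  w2 <- 2.5 * w
  f2 <- zinb(y ~ x + g, data = d, weights = w2)
  expect_equal(f2$loglik, 2.5 * f1$loglik, tolerance = 1e-6)
  expect_lt(max(abs(coef(f1, "full") - coef(f2, "full"))), 1e-4)
  # optimum dominates the starting values
  expect_gte(f1$loglik, f1$loglik_start)
})

test_that("Wald term tests equal z-squared for single-df terms and the
           explicit quadratic form for blocks", {
  d <- zinb_designs(seed = 24)
  d$g3 <- factor(sample(c("a", "b", "c"), nrow(d), replace = TRUE))
  f <- zinb(y ~ x + g3, data = d)
  tt <- wald_terms(f)
  # single-coefficient term: chisq = z^2 with the identical p
  zx <- f$zvals["count_x"]
  expect_equal(tt$chisq[tt$term == "x"], unname(zx^2), tolerance = 1e-10)
  expect_equal(tt$p[tt$term == "x"], unname(f$pvals["count_x"]),
               tolerance = 1e-12)
  # 2-df block equals b' V^-1 b by explicit inversion
  idx <- grep("count_g3", names(coef(f, "full")))
  b <- coef(f, "full")[idx]
  V <- f$vcov[idx, idx]
  expect_equal(tt$chisq[tt$term == "g3"], drop(t(b) %*% solve(V) %*% b),
               tolerance = 1e-10)
  expect_equal(tt$df[tt$term == "g3"], 2)
})

test_that("interaction pruning removes null interactions and keeps real ones", {
  set.seed(30)
  n <- 2500
  d <- data.frame(snp = factor(sample(c("ref", "alt"), n, TRUE)),
                  grp = rbinom(n, 1, 0.5))
  mu0 <- exp(1.2 - 0.3 * (d$snp == "alt"))
  pi_ <- plogis(-0.9)
  d$y <- ifelse(runif(n) < pi_, 0L, rnbinom(n, mu = mu0, size = 3))
  f_null <- suppressWarnings(prune_interactions(y ~ snp * grp, d))
  expect_true(attr(f_null, "pruned"))
  expect_false(any(grepl(":", names(coef(f_null, "count")))))
  # a strong planted interaction is retained
  mu1 <- exp(1.2 - 0.3 * (d$snp == "alt") + 1.0 * (d$snp == "alt") * d$grp)
  d$y <- ifelse(runif(n) < pi_, 0L, rnbinom(n, mu = mu1, size = 3))
  f_int <- suppressWarnings(prune_interactions(y ~ snp * grp, d))
  expect_false(attr(f_int, "pruned"))
  expect_true(any(grepl(":", names(coef(f_int, "count")))))
})

test_that("overdispersion check flags theta, not Poisson-like data", {
  set.seed(31)
  n <- 6000
  d <- data.frame(x = rnorm(n))
  mu <- exp(1.3 + 0.3 * d$x)
  pi_ <- plogis(-1)
  d$y <- ifelse(runif(n) < pi_, 0L, rnbinom(n, mu = mu, size = 0.5))
  f_od <- suppressWarnings(zinb(y ~ x, data = d))
  expect_true(overdispersion_check(f_od)$overdispersed)
  d$y <- ifelse(runif(n) < pi_, 0L, rpois(n, mu))
  f_p <- suppressWarnings(zinb(y ~ x, data = d))
  chk <- overdispersion_check(f_p)
  expect_false(chk$overdispersed)
})

test_that("degenerate genotype data reports model-not-formed", {
  n <- 200
  nci <- c(rep(0, 150), rep(5, 50))
  one_class <- rep("TT", n)
  res <- fit_snp_model(nci, one_class, age = rep(60, n), sex = rep(1, n))
  expect_equal(res$status, "model not formed")
  # two classes but events confined to one class
  two_class <- c(rep("TT", 150), rep("CT", 50))
  nci2 <- c(rep(0, 150), rep(5, 50))
  res2 <- fit_snp_model(nci2, two_class, age = rep(60, n), sex = rep(1, n))
  expect_equal(res2$status, "model not formed")
})

test_that("Bonferroni decisions use the family-size-adjusted threshold", {
  b <- bonferroni(c(0.004, 0.009), m = 7)
  expect_equal(b$significant, c(TRUE, FALSE))
  expect_equal(b$threshold, rep(0.05 / 7, 2))
  expect_true(bonferroni(0.049, m = 1)$significant)
})
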