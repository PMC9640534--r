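#' Recode small family sizes as non-events
#'
#' Counts of 0 to `threshold` children are set to zero so that the count
#' component of the zero-inflated model describes only larger-than-average
#' family sizes; counts above the threshold are kept as-is (no shift).
#'
#' @param nci non-negative integer vector of numbers of children.
#' @param threshold largest count treated as a non-event (default 3, the
#'   upper integer bound of the cohort mean).
#' @return integer vector with support \{0\} union \{threshold+1, ...\}.
#' @export
recode_nonevents <- function(nci, threshold = 3) {
  if (any(is.na(nci))) stop("missing values in nci")
  if (any(nci < 0)) stop("nci must be non-negative")
  if (any(nci != round(nci))) stop("nci must be integer counts")
  y <- as.integer(nci)
  y[y <= threshold] <- 0L
  y
}

#' Inverse age-bin frequency weights
#'
#' Each subject receives the inverse of the number of subjects sharing its
#' (integer-year) age bin, rescaled so the weights sum to the number of
#' subjects: \eqn{w_i = N / (B \, n_{b(i)})} with \eqn{B} distinct bins and
#' \eqn{n_{b(i)}} the size of subject \eqn{i}'s bin. This counteracts the
#' decline in enrolment with age.
#'
#' @param ages integer ages (bin = integer year).
#' @return numeric weights summing to `length(ages)`.
#' @export
age_bin_weights <- function(ages) {
  if (length(ages) == 0) stop("empty age vector")
  if (any(is.na(ages))) stop("missing ages")
  bin <- as.character(as.integer(ages))
  nb <- table(bin)
  raw <- 1 / as.numeric(nb[bin])
  raw * length(ages) / sum(raw)
}

#' Wald chi-square term tests (type II analysis of deviance analogue)
#'
#' For each term of the count component, tests the joint null that its
#' coefficient block is zero with \eqn{W = b' V_b^{-1} b}, df = block size,
#' against the upper chi-square tail. For a single-coefficient term this is
#' exactly the square of the coefficient's z value with the identical p.
#'
#' @param fit a [zinb()] fit.
#' @param component `"count"` (default; the genotype association test of the
#'   analysis) or `"zero"`.
#' @return data frame with columns `term`, `df`, `chisq`, `p`.
#' @export
wald_terms <- function(fit, component = c("count", "zero")) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "zinb"))
  asn <- fit$assign[[component]]
  labels <- attr(fit$terms[[component]], "term.labels")
  offset <- if (component == "count") 0 else length(fit$coefficients$count)
  out <- lapply(seq_along(labels), function(i) {
    idx <- offset + which(asn == i)
    b <- coef(fit, "full")[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    W <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    if (is.na(W)) {
      warning("singular covariance block for term ", labels[i])
    }
    data.frame(term = labels[i], df = length(idx), chisq = W,
               p = stats::pchisq(W, df = length(idx), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Drop jointly non-significant interactions
#'
#' Fits the full interaction model, and if every interaction coefficient in
#' both components has Wald \eqn{p \ge \alpha}, refits with main effects only
#' (main effects are kept regardless of their own significance). If any
#' interaction coefficient reaches \eqn{p < \alpha} the full model is kept.
#' When the full model cannot be formed the main-effects model is fitted
#' directly with a warning.
#'
#' @param formula full model formula, e.g. `y ~ snp * age * sex`.
#' @param data,weights,control passed to [zinb()].
#' @param alpha significance level for the interaction screen (default 0.05).
#' @return the selected `"zinb"` fit with attribute `"pruned"` (logical) and
#'   `"interaction_p"` (the interaction coefficient p-values examined).
#' @export
prune_interactions <- function(formula, data, weights = NULL, alpha = 0.05,
                               control = zinb_control()) {
  parts <- split_two_part_formula(formula)
  mains_rhs <- function(f) {
    tl <- attr(stats::terms(f, data = data), "term.labels")
    keep <- tl[!grepl(":", tl, fixed = TRUE)]
    stats::reformulate(keep, response = f[[2]], env = environment(formula))
  }
  f_mains <- mains_rhs(parts$count)
  if (!identical(deparse(parts$count[[3]]), deparse(parts$zero[[3]]))) {
    zc <- mains_rhs(parts$zero)
    f_mains <- stats::as.formula(
      call("~", f_mains[[2]], call("|", f_mains[[3]], zc[[3]])),
      env = environment(formula))
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else weights

  full <- tryCatch(suppressWarnings(
    zinb(formula, data, weights = w, control = control)),
    error = function(e) e)
  if (!inherits(full, "error") && !isTRUE(full$identifiable)) {
    full <- simpleError("interaction coefficients not identified (singular information)")
  }
  if (inherits(full, "error")) {
    warning("full interaction model not formed (", conditionMessage(full),
            "); falling back to main effects")
    out <- zinb(f_mains, data, weights = w, control = control)
    attr(out, "pruned") <- TRUE
    attr(out, "interaction_p") <- NULL
    return(out)
  }
  pv <- full$pvals
  inter <- grepl(":", names(pv), fixed = TRUE)
  ip <- pv[inter]
  if (length(ip) == 0 || any(ip < alpha, na.rm = TRUE)) {
    attr(full, "pruned") <- FALSE
    attr(full, "interaction_p") <- ip
    return(full)
  }
  out <- zinb(f_mains, data, weights = w, control = control)
  attr(out, "pruned") <- TRUE
  attr(out, "interaction_p") <- ip
  out
}

#' Overdispersion check via the log(theta) Wald test
#'
#' A non-significant \eqn{\log\theta} indicates the count component is not
#' overdispersed relative to Poisson (large \eqn{\theta}). When the
#' dispersion sits at the optimiser cap the test is meaningless and p is
#' reported as 1 with a boundary note.
#'
#' @param fit a [zinb()] fit.
#' @param alpha significance level (default 0.05).
#' @return list with `p`, `overdispersed`, `note`.
#' @export
overdispersion_check <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "zinb"))
  if (isTRUE(fit$theta_at_cap)) {
    return(list(p = 1, overdispersed = FALSE, note = "theta at boundary"))
  }
  p <- unname(fit$pvals["log_theta"])
  list(p = p, overdispersed = is.finite(p) && p < alpha, note = NULL)
}

#' Bonferroni significance decisions
#'
#' @param p p-values.
#' @param m number of tests in the correction family (default 7: one
#'   inversion-representative SNP plus six surrogate SNPs).
#' @param alpha family-wise level.
#' @return data frame with `p`, `threshold`, `significant` (p < alpha/m).
#' @export
bonferroni <- function(p, m = 7, alpha = 0.05) {
  stopifnot(m >= 1)
  data.frame(p = p, threshold = alpha / m, significant = p < alpha / m)
}

#' Fit the genotype association model for one SNP, tolerating failures
#'
#' Wraps [prune_interactions()] so that SNPs for which no valid model exists
#' (e.g. fewer than two genotype classes among events after recoding) are
#' reported with status `"model not formed"` instead of aborting a multi-SNP
#' run.
#'
#' @param nci raw children counts.
#' @param genotype factor of genotype labels; the reference level should be
#'   the H2-homozygote class so the reported effects are for the
#'   heterozygote and the H1 homozygote.
#' @param age,sex covariates.
#' @param weights per-subject weights; default [age_bin_weights()] on `age`.
#' @param threshold non-event recode threshold.
#' @param interactions start from the full `snp * age * sex` model and prune
#'   (default), or fit main effects directly.
#' @return list with `status` ("ok" or "model not formed"), `fit` (or NULL),
#'   `terms` (Wald term table, count component), `message`.
#' @export
fit_snp_model <- function(nci, genotype, age, sex, weights = NULL,
                          threshold = 3, interactions = TRUE) {
  d <- data.frame(y = recode_nonevents(nci, threshold),
                  snp = factor(genotype), age = as.numeric(age),
                  sex = as.numeric(sex))
  if (is.null(weights)) weights <- age_bin_weights(d$age)
  ok_classes <- length(unique(d$snp[!is.na(d$snp)])) >= 2
  events_per_class <- tapply(d$y > 0, d$snp, any)
  if (!ok_classes || sum(events_per_class, na.rm = TRUE) < 2) {
    return(list(status = "model not formed", fit = NULL, terms = NULL,
                message = "fewer than two genotype classes with events"))
  }
  f <- if (interactions) y ~ snp * age * sex else y ~ snp + age + sex
  fit <- tryCatch(
    prune_interactions(f, d, weights = weights),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(status = "model not formed", fit = NULL, terms = NULL,
                message = conditionMessage(fit)))
  }
  list(status = "ok", fit = fit, terms = wald_terms(fit), message = NULL)
}
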