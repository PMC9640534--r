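#' Zero-inflated negative-binomial regression by maximum likelihood
#'
#' Fits the mixture model in which a response count \eqn{y_i} is zero either
#' structurally, with probability \eqn{\pi_i = \mathrm{logit}^{-1}(z_i'\gamma)},
#' or as a draw from a negative-binomial distribution with mean
#' \eqn{\mu_i = \exp(x_i'\beta)} and dispersion \eqn{\theta}
#' (variance \eqn{\mu + \mu^2/\theta}):
#' \deqn{P(y_i = 0) = \pi_i + (1-\pi_i) f_{NB}(0;\mu_i,\theta), \quad
#'       P(y_i = k) = (1-\pi_i) f_{NB}(k;\mu_i,\theta), \; k > 0.}
#' Subject-level weights multiply the log-likelihood contributions.
#'
#' The two-part formula syntax of \code{pscl::zeroinfl} is supported:
#' \code{y ~ x1 + x2 | z1} uses \code{x1 + x2} in the count component and
#' \code{z1} in the zero component; a one-part formula uses the same
#' covariates in both components. In the fertility analysis the response is
#' the recoded number of children (see [recode_nonevents()]), the count
#' component carries the inversion genotype with the H2-homozygote class as
#' reference, and weights come from [age_bin_weights()].
#'
#' Optimisation is quasi-Newton (BFGS-class) on \eqn{(\beta, \gamma,
#' \log\theta)} with analytic gradient; \eqn{\log\theta} is box-constrained to
#' \code{[-log_theta_cap, log_theta_cap]} because near-Poisson data push
#' \eqn{\theta} towards infinity along an almost flat likelihood ridge.
#' Standard errors come from the inverse observed information (numerically
#' differentiated analytic gradient).
#'
#' @param formula model formula, optionally two-part (`count | zero`).
#' @param data a data frame containing the model variables.
#' @param weights optional non-negative per-subject weights; default 1.
#' @param subset,na.action as in [stats::lm()].
#' @param control a list from [zinb_control()].
#' @return An object of class `"zinb"` with components `coefficients` (list
#'   `count`, `zero`), `log_theta`, `theta`, `vcov`, `se`, `loglik`,
#'   `converged`, `n_iter`, `fitted_count`, `fitted_zero`, and the pieces
#'   needed by the methods (`terms`, design matrices, `y`, `weights`).
#' @seealso [wald_terms()], [prune_interactions()], [overdispersion_check()],
#'   [zinb_loglik()]
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(300))
#' mu <- exp(1 + 0.5 * d$x)
#' pi <- stats::plogis(-1)
#' y <- ifelse(stats::runif(300) < pi, 0L, stats::rnbinom(300, mu = mu, size = 2))
#' f <- zinb(y ~ x, data = d)
#' coef(f, model = "count")
#' @export
zinb <- function(formula, data, weights = NULL, subset = NULL,
                 na.action = stats::na.omit, control = zinb_control()) {
  cl <- match.call()
  parts <- split_two_part_formula(formula)
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  mf <- stats::model.frame(parts$full, data = data, na.action = na.action)
  y <- stats::model.response(mf)
  if (is.null(y)) stop("formula needs a response")
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be a non-negative integer count")
  }
  y <- as.integer(round(y))
  X <- stats::model.matrix(stats::terms(parts$count, data = data), mf)
  Z <- stats::model.matrix(stats::terms(parts$zero, data = data), mf)
  w <- if (is.null(weights)) rep(1, length(y)) else {
    ww <- eval(substitute(weights), data, parent.frame())
    if (length(ww) != nrow(data)) stop("weights length must match data")
    kept <- rownames(mf)
    ww[match(kept, rownames(data))]
  }
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be finite and non-negative")

  fit <- zinb_fit(X, Z, y, w, control)
  fit$call <- cl
  fit$formula <- formula
  fit$terms <- list(
    count = stats::terms(parts$count, data = data),
    zero  = stats::terms(parts$zero, data = data),
    full  = stats::terms(parts$full, data = data)
  )
  fit$assign <- list(count = attr(X, "assign"), zero = attr(Z, "assign"))
  fit$model <- mf
  fit$na.action <- attr(mf, "na.action")
  fit
}

#' Control parameters for [zinb()]
#'
#' @param maxit maximum quasi-Newton iterations.
#' @param reltol relative log-likelihood convergence tolerance.
#' @param grad_tol gradient max-norm defining the `converged` flag.
#' @param log_theta_cap bound on \eqn{|\log\theta|}; \eqn{\theta} at the upper
#'   cap means the fit sits on the Poisson boundary.
#' @param start optional named list with `count`, `zero`, `log_theta` start
#'   values; defaults are a weighted Poisson fit, a weighted logistic fit of
#'   the zero indicator, and \eqn{\log\theta = 0}.
#' @return a list of class `"zinb_control"`.
#' @export
zinb_control <- function(maxit = 500, reltol = 1e-10, grad_tol = 1e-6,
                         log_theta_cap = 20, start = NULL) {
  structure(list(maxit = maxit, reltol = reltol, grad_tol = grad_tol,
                 log_theta_cap = log_theta_cap, start = start),
            class = "zinb_control")
}

## split "y ~ a | b" into count and zero one-part formulas
split_two_part_formula <- function(formula) {
  rhs <- formula[[3]]
  lhs <- formula[[2]]
  if (is.call(rhs) && identical(rhs[[1]], as.name("|"))) {
    fc <- stats::as.formula(call("~", lhs, rhs[[2]]), env = environment(formula))
    fz <- stats::as.formula(call("~", lhs, rhs[[3]]), env = environment(formula))
    full <- stats::as.formula(call("~", lhs, call("+", rhs[[2]], rhs[[3]])),
                              env = environment(formula))
  } else {
    fc <- fz <- full <- formula
  }
  list(count = fc, zero = fz, full = full)
}

## ---- likelihood -----------------------------------------------------------

## lgamma(y + theta) - lgamma(theta) as an exact finite sum over the observed
## support: sum_{j=0}^{y-1} log(theta + j).  Avoids catastrophic cancellation
## of lgamma differences when theta is enormous (near-Poisson fits).
nb_lgamma_ratio <- function(y, theta) {
  out <- numeric(length(y))
  m <- max(y)
  if (m >= 1) {
    for (j in 0:(m - 1)) {
      idx <- y > j
      out[idx] <- out[idx] + log(theta + j)
    }
  }
  out
}

## digamma(y + theta) - digamma(theta) = sum_{j=0}^{y-1} 1/(theta + j)
nb_digamma_ratio <- function(y, theta) {
  out <- numeric(length(y))
  m <- max(y)
  if (m >= 1) {
    for (j in 0:(m - 1)) {
      idx <- y > j
      out[idx] <- out[idx] + 1 / (theta + j)
    }
  }
  out
}

## per-observation pieces shared by loglik and gradient
zinb_parts <- function(par, X, Z, y, kx) {
  kz <- ncol(Z)
  beta <- par[seq_len(kx)]
  gamma <- par[kx + seq_len(kz)]
  lt <- par[kx + kz + 1]
  theta <- exp(lt)
  eta <- drop(X %*% beta)
  ## an empty zero design means pi is structurally zero (plain weighted NB)
  zeta <- if (kz == 0) rep(-745, length(eta)) else drop(Z %*% gamma)
  mu <- exp(eta)
  ## log(theta/(theta+mu)) and log(mu/(theta+mu)) computed stably for both
  ## huge theta and huge mu
  log_t_tm <- -log1p(mu / theta)
  log_m_tm <- eta - lt + log_t_tm          # log(mu) - log(theta+mu)
  lf <- nb_lgamma_ratio(y, theta) - lgamma(y + 1) +
    theta * log_t_tm + y * log_m_tm        # log f_NB(y; mu, theta)
  lf0 <- theta * log_t_tm                  # log f_NB(0; mu, theta)
  logpi <- stats::plogis(zeta, log.p = TRUE)
  log1mpi <- stats::plogis(-zeta, log.p = TRUE)
  ## log(pi + (1-pi) f0) via log-sum-exp
  a <- logpi
  b <- log1mpi + lf0
  hi <- pmax(a, b)
  logdenom0 <- hi + log1p(exp(pmin(a, b) - hi))
  list(theta = theta, mu = mu, lf = lf, lf0 = lf0,
       logpi = logpi, log1mpi = log1mpi, logdenom0 = logdenom0)
}

#' Weighted zero-inflated negative-binomial log-likelihood
#'
#' Evaluates \eqn{\ell = \sum_i w_i \log[ 1\{y_i=0\}(\pi_i + (1-\pi_i)
#' f_{NB}(0;\mu_i,\theta)) + 1\{y_i>0\}(1-\pi_i) f_{NB}(y_i;\mu_i,\theta)]}
#' in log space, with the \eqn{\Gamma}-ratio in the negative-binomial pmf
#' expanded as an exact finite sum so that the near-Poisson regime
#' (\eqn{\theta \to \infty}) stays accurate.
#'
#' @param beta count-component coefficients (log link).
#' @param gamma zero-component coefficients (logit link).
#' @param log_theta log of the negative-binomial dispersion.
#' @param X,Z design matrices of count and zero components.
#' @param y non-negative integer response.
#' @param weights per-subject weights (default 1).
#' @return the scalar weighted log-likelihood.
#' @export
zinb_loglik <- function(beta, gamma, log_theta, X, Z, y,
                        weights = rep(1, length(y))) {
  p <- zinb_parts(c(beta, gamma, log_theta), X, Z, y, length(beta))
  ll_i <- ifelse(y == 0, p$logdenom0, p$log1mpi + p$lf)
  if (any(!is.finite(ll_i))) {
    stop("non-finite log-likelihood contribution at subject index ",
         which(!is.finite(ll_i))[1])
  }
  sum(weights * ll_i)
}

## negative loglik and analytic gradient on the packed parameter vector
zinb_negll <- function(par, X, Z, y, w, kx) {
  p <- zinb_parts(par, X, Z, y, kx)
  ll_i <- ifelse(y == 0, p$logdenom0, p$log1mpi + p$lf)
  v <- -sum(w * ll_i)
  if (!is.finite(v)) v <- .Machine$double.xmax / 2
  v
}

zinb_neggrad <- function(par, X, Z, y, w, kx) {
  kz <- ncol(Z)
  p <- zinb_parts(par, X, Z, y, kx)
  theta <- p$theta; mu <- p$mu
  z0 <- y == 0
  pi_ <- exp(p$logpi)
  log_t_tm <- -log1p(mu / theta)
  frac <- mu / (theta + mu)

  ## count part
  db <- numeric(length(y))
  db[!z0] <- y[!z0] - mu[!z0] * (theta + y[!z0]) / (theta + mu[!z0])
  r0 <- exp(p$log1mpi + p$lf0 - p$logdenom0)   # (1-pi) f0 / denom, in [0,1]
  db[z0] <- -r0[z0] * theta * frac[z0]
  gb <- drop(crossprod(X, w * db))

  ## zero part
  dg <- numeric(length(y))
  dg[!z0] <- -pi_[!z0]
  r1 <- exp(p$logpi - p$logdenom0)             # pi / denom
  one_m_f0 <- -expm1(p$lf0)
  dg[z0] <- r1[z0] * exp(p$log1mpi[z0]) * one_m_f0[z0]
  gg <- drop(crossprod(Z, w * dg))

  ## log(theta)
  dt <- numeric(length(y))
  dt[!z0] <- theta * (nb_digamma_ratio(y[!z0], theta) +
                        log_t_tm[!z0] + (mu[!z0] - y[!z0]) / (theta + mu[!z0]))
  dt[z0] <- r0[z0] * theta * (log_t_tm[z0] + frac[z0])
  gt <- sum(w * dt)

  -c(gb, gg, gt)
}

## core fitter on design matrices; used directly by the simulation studies
## to skip formula overhead
zinb_fit <- function(X, Z, y, w, control = zinb_control()) {
  kx <- ncol(X); kz <- ncol(Z)
  if (qr(X)$rank < kx) stop("count design matrix is singular")
  if (qr(Z)$rank < kz) stop("zero design matrix is singular")
  if (length(unique(y)) < 2) {
    stop("response has a single level after recoding: model not formed")
  }

  st <- control$start
  if (is.null(st)) {
    b0 <- suppressWarnings(
      stats::glm.fit(X, y, weights = w, family = stats::poisson())$coefficients)
    g0 <- if (kz == 0) numeric(0) else suppressWarnings(
      stats::glm.fit(Z, as.numeric(y == 0), weights = w,
                     family = stats::binomial())$coefficients)
    st <- list(count = b0, zero = g0, log_theta = 0)
  }
  par0 <- c(st$count, st$zero, st$log_theta)
  if (any(!is.finite(par0))) par0[!is.finite(par0)] <- 0
  cap <- control$log_theta_cap

  opt <- stats::optim(par0, fn = zinb_negll, gr = zinb_neggrad,
                      X = X, Z = Z, y = y, w = w, kx = kx,
                      method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  par <- opt$par
  ## near-Poisson fits drift up an almost flat log(theta) ridge; clamp at
  ## the cap and re-profile the remaining parameters there
  if (abs(par[kx + kz + 1]) > cap) {
    lt_fix <- sign(par[kx + kz + 1]) * cap
    opt2 <- stats::optim(par[seq_len(kx + kz)],
                         fn = function(q) zinb_negll(c(q, lt_fix), X, Z, y, w, kx),
                         gr = function(q) zinb_neggrad(c(q, lt_fix), X, Z, y, w, kx)[seq_len(kx + kz)],
                         method = "BFGS",
                         control = list(maxit = control$maxit,
                                        reltol = control$reltol))
    opt$par <- c(opt2$par, lt_fix)
    opt$value <- opt2$value
    opt$counts <- opt$counts + opt2$counts
    par <- opt$par
  }
  grad <- zinb_neggrad(par, X, Z, y, w, kx)
  at_cap <- abs(par[kx + kz + 1]) >= cap - 1e-8
  ## ignore the theta component of the gradient when pinned at the cap
  gnorm <- max(abs(grad[seq_len(kx + kz)]), if (at_cap) 0 else abs(grad[kx + kz + 1]))
  ll0 <- -zinb_negll(par0, X, Z, y, w, kx)
  ll <- -opt$value
  ## converged if the optimizer met its (tight) relative-change criterion or
  ## the score is numerically flat
  converged <- (opt$convergence == 0) || (gnorm < control$grad_tol)

  H <- stats::optimHess(par, fn = zinb_negll, gr = zinb_neggrad,
                        X = X, Z = Z, y = y, w = w, kx = kx)
  ## identifiability is judged on the coefficient block only: near-Poisson
  ## fits have an almost flat log(theta) direction (huge but legitimate SE),
  ## which must not be confused with a rank-deficient design
  Hbg <- H[seq_len(kx + kz), seq_len(kx + kz)]
  identifiable <- all(is.finite(H)) && rcond(Hbg) > 1e-12
  vc <- tryCatch(solve(H), error = function(e) {
    identifiable <<- FALSE
    pseudo_inverse(H)
  })
  if (!identifiable) {
    warning("observed information is singular; coefficients not all ",
            "identified and standard errors unreliable")
  }
  nm <- c(paste0("count_", colnames(X)),
          if (kz > 0) paste0("zero_", colnames(Z)), "log_theta")
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))
  se[diag(vc) <= 0] <- NA_real_
  est <- par
  names(est) <- nm
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))

  beta <- est[seq_len(kx)];   names(beta) <- colnames(X)
  gamma <- est[kx + seq_len(kz)]; names(gamma) <- colnames(Z)
  lt <- unname(est[kx + kz + 1])

  structure(list(
    coefficients = list(count = beta, zero = gamma),
    log_theta = lt, theta = exp(lt), theta_at_cap = at_cap,
    se = se, zvals = zval, pvals = pval, vcov = vc,
    identifiable = identifiable,
    loglik = ll, loglik_start = ll0, n_iter = opt$counts[["function"]],
    converged = converged, grad_norm = gnorm,
    df = kx + kz + 1, nobs = length(y),
    X = X, Z = Z, y = y, weights = w,
    fitted_count = exp(drop(X %*% beta)),
    fitted_zero = stats::plogis(drop(Z %*% gamma)),
    control = control
  ), class = "zinb")
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

## ---- methods --------------------------------------------------------------

#' @export
print.zinb <- function(x, ...) {
  cat("Zero-inflated negative-binomial regression\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat("\nCount coefficients (log link):\n")
  print(round(x$coefficients$count, 6))
  cat("\nZero-inflation coefficients (logit link):\n")
  print(round(x$coefficients$zero, 6))
  cat("\nTheta =", format(x$theta, digits = 6),
      if (x$theta_at_cap) "(at cap)" else "",
      "  Log-likelihood:", format(x$loglik, digits = 7),
      "on", x$df, "Df\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.zinb <- function(object, model = c("full", "count", "zero"), ...) {
  model <- match.arg(model)
  switch(model,
         count = object$coefficients$count,
         zero = object$coefficients$zero,
         full = c(stats::setNames(object$coefficients$count,
                                  paste0("count_", names(object$coefficients$count))),
                  stats::setNames(object$coefficients$zero,
                                  paste0("zero_", names(object$coefficients$zero))),
                  log_theta = object$log_theta))
}

#' @export
vcov.zinb <- function(object, ...) object$vcov

#' @export
logLik.zinb <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs, class = "logLik")
}

#' @export
nobs.zinb <- function(object, ...) object$nobs

#' @export
summary.zinb <- function(object, ...) {
  nm <- names(object$se)
  tab <- cbind(Estimate = coef(object, "full"), `Std. Error` = object$se,
               `z value` = object$zvals, `Pr(>|z|)` = object$pvals)
  rownames(tab) <- nm
  kx <- length(object$coefficients$count)
  kz <- length(object$coefficients$zero)
  out <- list(call = object$call,
              count = tab[seq_len(kx), , drop = FALSE],
              zero = tab[kx + seq_len(kz), , drop = FALSE],
              log_theta = tab[kx + kz + 1, , drop = FALSE],
              theta = object$theta, theta_at_cap = object$theta_at_cap,
              loglik = object$loglik, df = object$df,
              converged = object$converged, n_iter = object$n_iter)
  class(out) <- "summary.zinb"
  out
}

#' @export
print.summary.zinb <- function(x, ...) {
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n\n")
  cat("Count model coefficients (negbin with log link):\n")
  stats::printCoefmat(x$count, ...)
  cat("\nZero-inflation model coefficients (binomial with logit link):\n")
  stats::printCoefmat(x$zero, ...)
  cat("\nLog(theta):\n")
  stats::printCoefmat(x$log_theta, ...)
  cat("\nTheta =", format(x$theta, digits = 8),
      if (x$theta_at_cap) "(at cap; Poisson boundary)" else "", "\n")
  cat("Log-likelihood:", format(x$loglik, digits = 7), "on", x$df, "Df\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Predictions from a zero-inflated negative-binomial fit
#'
#' @param object a `"zinb"` fit.
#' @param newdata optional data frame; default is the fitting data.
#' @param type `"response"` for \eqn{(1-\pi)\mu}, `"count"` for \eqn{\mu},
#'   `"zero"` for \eqn{\pi}.
#' @param ... unused.
#' @export
predict.zinb <- function(object, newdata = NULL,
                         type = c("response", "count", "zero"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mu <- object$fitted_count
    pi_ <- object$fitted_zero
  } else {
    X <- stats::model.matrix(stats::delete.response(object$terms$count), newdata)
    Z <- stats::model.matrix(stats::delete.response(object$terms$zero), newdata)
    mu <- exp(drop(X %*% object$coefficients$count))
    pi_ <- stats::plogis(drop(Z %*% object$coefficients$zero))
  }
  switch(type, response = (1 - pi_) * mu, count = mu, zero = pi_)
}

#' @export
fitted.zinb <- function(object, ...) {
  (1 - object$fitted_zero) * object$fitted_count
}

#' Residuals of a zero-inflated negative-binomial fit
#'
#' Pearson residuals use the mixture variance
#' \eqn{(1-\pi)\mu(1 + \mu/\theta + \pi\mu)}.
#' @param object a `"zinb"` fit.
#' @param type `"pearson"` or `"response"`.
#' @param ... unused.
#' @export
residuals.zinb <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted_count; pi_ <- object$fitted_zero
  m <- (1 - pi_) * mu
  r <- object$y - m
  if (type == "response") return(r)
  v <- (1 - pi_) * mu * (1 + mu / object$theta + pi_ * mu)
  r / sqrt(v)
}

#' Simulate responses from a fitted zero-inflated negative-binomial model
#'
#' @param object a `"zinb"` fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.zinb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$nobs
  out <- as.data.frame(replicate(nsim, {
    structural <- stats::rbinom(n, 1, object$fitted_zero) == 1
    y <- stats::rnbinom(n, mu = object$fitted_count, size = object$theta)
    y[structural] <- 0L
    y
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
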