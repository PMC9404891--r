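# Exact null distribution of the Mann-Whitney U statistic (no ties): counts
# of subsets of ranks 1..(m+n) of size m achieving each U in 0..m*n, by the
# standard recurrence N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
# Memoised per (m, n); counts grow fast, so stored as doubles.
.mw_cache <- new.env(parent = emptyenv())

mw_exact_counts <- function(m, n) {
  key <- paste(m, n, sep = ",")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  # subset-sum DP: f[j+1, s+1] = number of j-subsets of the ranks seen so far
  # with rank sum s; U = ranksum - m(m+1)/2
  N <- m + n
  maxr <- sum((N - m + 1):N)
  f <- matrix(0, m + 1, maxr + 1)
  f[1, 1] <- 1
  for (k in seq_len(N)) {
    for (j in min(k, m):1) {
      f[j + 1, (k + 1):(maxr + 1)] <-
        f[j + 1, (k + 1):(maxr + 1)] + f[j, 1:(maxr + 1 - k)]
    }
  }
  counts <- f[m + 1, (m * (m + 1) / 2 + 1):(maxr + 1)]
  stopifnot(length(counts) == m * n + 1)
  .mw_cache[[key]] <- counts
  counts
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' `U` counts pairs (x, y) with x > y (ties counting one half); the rank-sum
#' form `W` equals `U` as reported by common statistical software. When `n1 *
#' n2 <= 400` and there are no ties, the two-sided p-value comes from the
#' exact permutation distribution of U; otherwise the normal approximation is
#' used with midrank tie correction and a 0.5 continuity correction.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (exact when feasible and tie-free), `"exact"`, or
#'   `"approx"`.
#' @return List (class `rank_test_result`): `U`, `W` (rank sum of `x`),
#'   `statistic` (the U/W form), `p_value`, `method`,
#'   `tie_correction_applied`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = (n1 * n2 <= 400) && !has_ties)
  if (use_exact && has_ties) {
    stop("exact mode requires tie-free data; use mode = 'approx'")
  }
  if (use_exact) {
    counts <- mw_exact_counts(n1, n2)
    total <- sum(counts)
    pl <- sum(counts[seq_len(u + 1)]) / total
    pg <- sum(counts[(u + 1):length(counts)]) / total
    p <- min(1, 2 * min(pl, pg))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
      p <- 2 * stats::pnorm(-abs(z))
      p <- min(1, p)
    }
    method <- "normal_approx"
  }
  structure(list(U = u, W = r1 - n1 * (n1 + 1) / 2, rank_sum = r1,
                 statistic = u, p_value = p, method = method,
                 tie_correction_applied = has_ties && method == "normal_approx",
                 n1 = n1, n2 = n2),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test: W = %g, p = %.4g (%s, n1 = %d, n2 = %d)\n",
              x$W, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Correlation of midranks, with the t-approximation on `n - 2` degrees of
#' freedom for the two-sided p-value.
#'
#' @param x,y numeric samples of equal length.
#' @return List (class `correlation_result`): `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: N = %d, r = %.3f, p = %.4g\n",
              x$n, x$rho, x$p_value))
  invisible(x)
}

# Negative log-likelihood and analytic gradient of the (zero-inflated)
# Poisson model. theta = (beta, [gamma]); log lambda = X beta + log(exposure);
# pi = plogis(gamma) is a shared structural-zero probability.
zip_nll <- function(theta, X, y, off, zip) {
  p <- ncol(X)
  eta <- as.numeric(X %*% theta[seq_len(p)]) + off
  lam <- exp(eta)
  if (zip) {
    gam <- theta[p + 1]
    pi0 <- stats::plogis(gam)
    z <- y == 0
    ll <- sum(log(pi0 + (1 - pi0) * exp(-lam[z]))) +
      sum(log(1 - pi0) + y[!z] * eta[!z] - lam[!z] - lgamma(y[!z] + 1))
  } else {
    ll <- sum(y * eta - lam - lgamma(y + 1))
  }
  -ll
}

zip_grad <- function(theta, X, y, off, zip) {
  p <- ncol(X)
  eta <- as.numeric(X %*% theta[seq_len(p)]) + off
  lam <- exp(eta)
  if (zip) {
    gam <- theta[p + 1]
    pi0 <- stats::plogis(gam)
    z <- y == 0
    denom <- pi0 + (1 - pi0) * exp(-lam)
    gb <- numeric(nrow(X))
    gb[z] <- -(1 - pi0) * exp(-lam[z]) * lam[z] / denom[z]
    gb[!z] <- y[!z] - lam[!z]
    gbeta <- as.numeric(crossprod(X, gb))
    dgam <- pi0 * (1 - pi0)
    ggam <- sum(dgam * (1 - exp(-lam[z])) / denom[z]) - sum(!z) * pi0
    -c(gbeta, ggam)
  } else {
    -as.numeric(crossprod(X, y - lam))
  }
}

#' Zero-inflated Poisson regression with Wald tests
#'
#' Maximum-likelihood fit of a Poisson or zero-inflated Poisson count model
#' with log link and log-exposure offset; the ZIP zero-inflation component is
#' a single structural-zero probability on the logit scale. Optimization is
#' BFGS with analytic gradient from a zero start for the count coefficients
#' (inflation started at the observed zero fraction), followed by safeguarded
#' Newton polishing until the gradient max-norm falls below `tol`. Wald
#' standard errors come from the inverse observed information; p-values are
#' two-sided normal.
#'
#' @param counts nonnegative integer response.
#' @param design data.frame or matrix of predictors (an intercept is added).
#' @param exposure positive per-observation exposure (offset on the log
#'   scale).
#' @param family `"zip"` or `"poisson"`.
#' @param tol gradient max-norm target.
#' @return Object of class `count_model_result`: list with `coefficients`
#'   (data.frame: term, estimate, se, z, p), `zero_inflation` (logit-scale
#'   estimate, SE and probability; NA for plain Poisson), `log_lik`,
#'   `ll_trace` (log-likelihood at start / after BFGS / after polishing),
#'   `gradient_norm`, `converged`, `family`, `n`.
#' @export
fit_zip <- function(counts, design, exposure = NULL,
                    family = c("zip", "poisson"), tol = 1e-8) {
  family <- match.arg(family)
  y <- as.numeric(counts)
  if (anyNA(y) || any(y < 0)) stop("counts must be nonnegative and complete")
  X <- stats::model.matrix(~ ., data = as.data.frame(design))
  if (anyNA(X)) stop("missing values in design")
  if (nrow(X) != length(y)) stop("design and counts lengths differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  if (is.null(exposure)) exposure <- rep(1, length(y))
  if (any(exposure <= 0)) stop("exposure must be strictly positive")
  off <- log(exposure)
  zip <- family == "zip"
  p <- ncol(X)
  z0 <- mean(y == 0)
  theta0 <- c(numeric(p),
              if (zip) stats::qlogis(min(max(z0, 0.02), 0.98)))
  ll0 <- -zip_nll(theta0, X, y, off, zip)
  opt <- stats::optim(theta0, zip_nll, zip_grad, X = X, y = y, off = off,
                      zip = zip, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-13))
  theta <- opt$par
  ll_bfgs <- -opt$value
  # Newton polishing with step halving: drives the gradient max-norm to tol
  # and yields the observed information for Wald SEs.
  H <- NULL
  ll_cur <- ll_bfgs
  for (it in 1:25) {
    g <- -zip_grad(theta, X, y, off, zip)
    if (max(abs(g)) < tol) break
    H <- stats::optimHess(theta, zip_nll, zip_grad, X = X, y = y,
                          off = off, zip = zip)
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    if (all(step == 0)) break
    alpha <- 1
    repeat {
      cand <- theta + alpha * step
      ll_new <- -zip_nll(cand, X, y, off, zip)
      if (is.finite(ll_new) && ll_new >= ll_cur - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { cand <- theta; ll_new <- ll_cur; break }
    }
    theta <- cand
    ll_cur <- ll_new
  }
  g_final <- -zip_grad(theta, X, y, off, zip)
  if (is.null(H) || max(abs(g_final)) >= tol) {
    H <- stats::optimHess(theta, zip_nll, zip_grad, X = X, y = y,
                          off = off, zip = zip)
  }
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(theta),
                                                      length(theta)))
  se <- sqrt(pmax(diag(vc), 0))
  est <- theta[seq_len(p)]
  se_b <- se[seq_len(p)]
  zstat <- est / se_b
  coefs <- data.frame(term = colnames(X), estimate = est, se = se_b,
                      z = zstat, p = 2 * stats::pnorm(-abs(zstat)),
                      stringsAsFactors = FALSE, row.names = NULL)
  zi <- if (zip) {
    list(logit = theta[p + 1], se = se[p + 1],
         prob = stats::plogis(theta[p + 1]))
  } else list(logit = NA_real_, se = NA_real_, prob = NA_real_)
  conv <- opt$convergence == 0 && max(abs(g_final)) < max(tol, 1e-6) * (1 + abs(ll_cur))
  structure(list(coefficients = coefs, zero_inflation = zi,
                 log_lik = ll_cur, ll_trace = c(ll0, ll_bfgs, ll_cur),
                 gradient_norm = max(abs(g_final)),
                 converged = conv, family = family, n = length(y)),
            class = "count_model_result")
}

#' @export
print.count_model_result <- function(x, ...) {
  cat(sprintf("%s count model (n = %d, logLik = %.2f%s)\n",
              toupper(x$family), x$n, x$log_lik,
              if (x$converged) "" else ", NOT converged"))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  if (x$family == "zip") {
    cat(sprintf("zero inflation: pi = %.3f (logit %.3f +/- %.3f)\n",
                x$zero_inflation$prob, x$zero_inflation$logit,
                x$zero_inflation$se))
  }
  invisible(x)
}
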