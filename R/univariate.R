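#' Eigendecomposition of the additive relationship matrix
#'
#' One-time spectral decomposition of `2 * phi` shared across all likelihood
#' evaluations: after rotating the data by the eigenvectors, the polygenic
#' covariance `2*Phi*Vg + I*Ve` is diagonal and every likelihood evaluation
#' is O(n). Pass the result to the fitting functions via `options$eig` when
#' fitting many traits or replicates on the same pedigree.
#'
#' @param phi kinship matrix over the analyzed individuals.
#' @return A list with eigenvalues `d` (of 2*phi), eigenvectors `U`, and the
#'   source matrix dimension.
#' @export
polygenic_eigen <- function(phi) {
  stopifnot(is.matrix(phi), nrow(phi) == ncol(phi))
  if (max(abs(phi - t(phi))) > 1e-10) stop("kinship matrix must be symmetric")
  eg <- eigen(2 * phi, symmetric = TRUE)
  list(d = eg$values, U = eg$vectors, n = nrow(phi))
}

check_design <- function(X, n) {
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design matrix has ", nrow(X), " rows, expected ", n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Exact log-likelihood of the univariate polygenic model
#'
#' Log-density of `y ~ Normal(X beta, 2*Phi*Vg + I*Ve)`, evaluated densely by
#' Cholesky factorization. This is the model SOLAR-style variance-components
#' heritability rests on: `Vg` scales the expected allele sharing `2*phi`
#' between relatives, `Ve` is the independent environmental residual.
#'
#' @param y trait vector.
#' @param X design matrix (including intercept).
#' @param phi kinship matrix over the same individuals.
#' @param vg,ve nonnegative variance components, not both zero.
#' @param beta fixed-effect coefficients, length `ncol(X)`.
#' @return Log-likelihood (scalar).
#' @export
loglik_univariate <- function(y, X, phi, vg, ve, beta) {
  n <- length(y)
  X <- check_design(X, n)
  stopifnot(nrow(phi) == n, length(beta) == ncol(X))
  if (vg < 0 || ve < 0) stop("variance components must be nonnegative")
  if (vg + ve <= 0) stop("singular covariance: Vg = Ve = 0")
  sigma <- 2 * phi * vg + diag(ve, n)
  r <- y - as.vector(X %*% beta)
  L <- tryCatch(chol(sigma), error = function(e)
    stop("covariance matrix not positive definite"))
  q <- sum(backsolve(L, r, transpose = TRUE)^2)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + q)
}

# Profile log-likelihood over h2 with beta (GLS) and Vp profiled
# analytically in the rotated basis. Returns loglik, beta, vp for given h2.
# reml = TRUE uses the restricted likelihood (Vp over n - p, plus the
# log-determinant of the GLS information).
profile_uni <- function(h2, yt, Xt, d, reml = FALSE) {
  n <- length(yt)
  p <- ncol(Xt)
  lam <- 1 + h2 * (d - 1)
  if (any(lam <= 1e-12)) return(list(ll = -Inf))
  w <- 1 / lam
  XtW <- Xt * w
  xtx <- crossprod(Xt, XtW)
  beta <- tryCatch(solve(xtx, crossprod(XtW, yt)),
                   error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  r <- yt - as.vector(Xt %*% beta)
  rss <- sum(r^2 * w)
  if (rss <= 0) return(list(ll = -Inf))
  if (reml) {
    vp <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + log(vp) + 1) + sum(log(lam)) +
                    determinant(xtx, logarithm = TRUE)$modulus[1])
  } else {
    vp <- rss / n
    ll <- -0.5 * (n * (log(2 * pi) + log(vp) + 1) + sum(log(lam)))
  }
  list(ll = ll, beta = as.vector(beta), vp = vp)
}

#' Fit the univariate polygenic model by maximum likelihood
#'
#' Estimates fixed effects and the variance components of
#' `y ~ Normal(X beta, 2*Phi*Vg + I*Ve)`. Beta is profiled by generalized
#' least squares and the total residual variance `Vp` analytically, leaving
#' a one-dimensional bounded search over `h2 = Vg / Vp` in `[0, 1]`, so the
#' nonnegativity boundary is handled exactly. The standard error of `h2`
#' comes from the delta method on the numerical Hessian of the profile
#' log-likelihood in `(h2, log Vp)` and is reported missing when the
#' estimate is pinned at a boundary.
#'
#' @param y trait vector (no missing values).
#' @param X design matrix including an intercept column; `NULL` for
#'   intercept-only.
#' @param phi kinship matrix over the same individuals (in order).
#' @param options list: `eig` (precomputed [polygenic_eigen()]), `reml`
#'   (logical, default FALSE = ML, the SOLAR-style default), `constrain_h2`
#'   (fix `h2`, e.g. 0 for the no-polygene null model).
#' @return An object of class `polygenic_fit`: `beta`, `vg`, `ve`, `vp`,
#'   `h2`, `h2_se`, `loglik`, `converged`, `boundary` (Vg pinned at 0),
#'   `fitted_fixed` (X beta in input order), `n`, `columns`.
#' @export
fit_univariate <- function(y, X = NULL, phi, options = list()) {
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals")
  if (anyNA(y)) stop("y contains missing values; subset first")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- check_design(X, n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  eig <- options$eig
  if (is.null(eig)) {
    stopifnot(nrow(phi) == n)
    if (max(abs(2 * phi - diag(n))) < 1e-10)
      stop("no related pairs: Vg and Ve are not separately identifiable")
    eig <- polygenic_eigen(phi)
  } else if (eig$n != n) stop("precomputed eigendecomposition size mismatch")
  if (max(eig$d) - min(eig$d) < 1e-10)
    stop("no related pairs: Vg and Ve are not separately identifiable")
  reml <- isTRUE(options$reml)
  yt <- as.vector(crossprod(eig$U, y))
  Xt <- crossprod(eig$U, X)

  if (!is.null(options$constrain_h2)) {
    h2 <- options$constrain_h2
    stopifnot(h2 >= 0, h2 <= 1)
    pr <- profile_uni(h2, yt, Xt, eig$d, reml)
    best <- list(h2 = h2, pr = pr)
  } else {
    f <- function(h) profile_uni(h, yt, Xt, eig$d, reml)$ll
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, f(0), f(1))
    h2 <- cand[which.max(lls)]
    best <- list(h2 = h2, pr = profile_uni(h2, yt, Xt, eig$d, reml))
  }
  pr <- best$pr
  if (!is.finite(pr$ll)) stop("likelihood not finite at the optimum")
  h2 <- best$h2
  vp <- pr$vp
  boundary <- h2 <= 1e-7
  upper <- h2 >= 1 - 1e-7
  h2_se <- NA_real_
  if (is.null(options$constrain_h2) && !boundary && !upper) {
    # curvature of the profile log-likelihood in h2 (vp, beta profiled out)
    st <- min(1e-4, h2 / 2, (1 - h2) / 2)
    f <- function(h) profile_uni(h, yt, Xt, eig$d, reml)$ll
    d2 <- (f(h2 + st) - 2 * pr$ll + f(h2 - st)) / st^2
    if (is.finite(d2) && d2 < 0) h2_se <- sqrt(-1 / d2)
  }
  beta <- stats::setNames(pr$beta, colnames(X))
  structure(list(
    beta = beta, vg = h2 * vp, ve = (1 - h2) * vp, vp = vp,
    h2 = h2, h2_se = h2_se, loglik = pr$ll,
    converged = TRUE, boundary = boundary, boundary_upper = upper,
    fitted_fixed = as.vector(X %*% pr$beta), n = n,
    columns = colnames(X), reml = reml,
    constrained = !is.null(options$constrain_h2)
  ), class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf(
    "<polygenic_fit> n=%d  h2=%.3f%s  Vp=%.4g  loglik=%.4f%s\n",
    x$n, x$h2,
    if (is.na(x$h2_se)) "" else sprintf(" (SE %.3f)", x$h2_se),
    x$vp, x$loglik,
    if (x$boundary) "  [Vg at boundary 0]" else ""))
  invisible(x)
}

# central-difference Hessian
numeric_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  step <- pmax(h, abs(x) * h)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k)
      ei[i] <- step[i]; ej[j] <- step[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * step[i] * step[j])
      }
    }
  }
  H
}

#' Likelihood-ratio test for heritability at the boundary
#'
#' Tests `Vg = 0` against `Vg > 0` by comparing the full fit with the
#' null fit (`h2` constrained to 0). Because the null pins a variance at its
#' boundary, the reference distribution is the 50:50 mixture of a point mass
#' at zero and chi-square with 1 df: `p = 0.5 * P(chi2_1 > stat)` for a
#' positive statistic and `p = 0.5` at zero. A pure chi-square reference is
#' available with `mixture = FALSE`.
#'
#' @param fit_full,fit_null [fit_univariate()] results on identical data;
#'   the null must have been fit with `constrain_h2 = 0`.
#' @param mixture use the boundary mixture reference (default TRUE).
#' @return List with `statistic` (2 * delta log-likelihood, clipped at 0)
#'   and `p_value`.
#' @export
lrt_heritability <- function(fit_full, fit_null, mixture = TRUE) {
  stopifnot(inherits(fit_full, "polygenic_fit"),
            inherits(fit_null, "polygenic_fit"))
  if (fit_full$n != fit_null$n ||
      !identical(fit_full$columns, fit_null$columns))
    stop("mismatched models: full and null differ in data or covariates")
  if (!fit_null$constrained || fit_null$h2 > 0)
    stop("null fit must constrain h2 to 0")
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  p <- if (mixture) {
    if (stat > 0) 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) else 0.5
  } else {
    stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p)
}

#' Screen covariates by likelihood-ratio tests
#'
#' Single-pass drop-one screening: the full polygenic model with all
#' candidate covariates is compared, for each candidate, against the model
#' dropping that candidate (chi-square, 1 df per column). Candidates with
#' p below the threshold are retained and the final model is refit on the
#' retained set. The liberal default threshold 0.1 avoids discarding
#' relevant covariates.
#'
#' @param y trait vector.
#' @param candidates data frame or matrix of candidate covariate columns.
#' @param phi kinship matrix.
#' @param threshold retention p-value threshold (default 0.1).
#' @param options passed to [fit_univariate()].
#' @return List: `table` (candidate, statistic, p_value, retained),
#'   `retained` (names), `fit` (final refit on retained covariates).
#' @export
screen_covariates <- function(y, candidates, phi, threshold = 0.1,
                              options = list()) {
  if (length(y) == 0) stop("empty trait vector")
  cand <- if (is.null(candidates)) NULL else as.matrix(candidates)
  n <- length(y)
  design <- function(cols) {
    cbind("(Intercept)" = rep(1, n),
          if (length(cols) > 0) cand[, cols, drop = FALSE])
  }
  if (is.null(cand) || ncol(cand) == 0) {
    fit <- fit_univariate(y, design(character(0)), phi, options)
    return(list(table = data.frame(covariate = character(0),
                                   statistic = numeric(0),
                                   p_value = numeric(0),
                                   retained = logical(0)),
                retained = character(0), fit = fit))
  }
  if (is.null(colnames(cand))) colnames(cand) <- paste0("x", seq_len(ncol(cand)))
  full <- fit_univariate(y, design(colnames(cand)), phi, options)
  rows <- lapply(colnames(cand), function(cn) {
    red <- fit_univariate(y, design(setdiff(colnames(cand), cn)), phi, options)
    stat <- max(0, 2 * (full$loglik - red$loglik))
    data.frame(covariate = cn, statistic = stat,
               p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$retained <- tab$p_value < threshold
  retained <- tab$covariate[tab$retained]
  final <- fit_univariate(y, design(retained), phi, options)
  list(table = tab, retained = retained, fit = final)
}

#' Proportion of trait variance explained by fitted covariates
#'
#' `Var(X beta-hat) / Var(y)` with the final-model coefficients; zero for an
#' intercept-only model. `y` is the trait on the scale the model was fit
#' (i.e. before residualization on the covariates).
#'
#' @param fit a [fit_univariate()] result.
#' @param y the trait vector the model was fit to.
#' @return Proportion in `[0, 1]` (clipped).
#' @export
proportion_variance_covariates <- function(fit, y) {
  stopifnot(inherits(fit, "polygenic_fit"))
  if (!fit$converged) stop("fit did not converge")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("zero-variance trait")
  if (length(fit$columns) <= 1 && all(fit$columns == "(Intercept)")) return(0)
  min(1, max(0, stats::var(fit$fitted_fixed) / vy))
}

#' Attribute variance to one risk factor by subtraction
#'
#' The share of variance attributed to a risk factor is the proportion of
#' variance due to all significant covariates of the extended model (basic
#' covariates plus the factor) minus that of the basic model, floored at
#' zero.
#'
#' @param prop_extended,prop_basic proportions in `[0, 1]`.
#' @return List: `delta` (floored difference) and `floored` (TRUE when the
#'   raw difference was negative).
#' @export
attribute_covariate_variance <- function(prop_extended, prop_basic) {
  stopifnot(prop_extended >= 0, prop_extended <= 1,
            prop_basic >= 0, prop_basic <= 1)
  raw <- prop_extended - prop_basic
  list(delta = max(0, raw), floored = raw < 0)
}
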