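#' Exact log-likelihood of the bivariate polygenic model
#'
#' Log-density of the stacked vector `(y1, y2)` under covariance
#' `2*Phi (x) G + I (x) E` with genetic covariance
#' `G = [[Vg1, rg*sqrt(Vg1*Vg2)], [., Vg2]]` and environmental covariance
#' `E = [[Ve1, re*sqrt(Ve1*Ve2)], [., Ve2]]`, evaluated densely (2n x 2n
#' Cholesky). Both traits share the design matrix but have their own
#' coefficients.
#'
#' @param y1,y2 trait vectors on the same individuals.
#' @param X design matrix (including intercept).
#' @param phi kinship matrix.
#' @param params list with `vg1`, `ve1`, `vg2`, `ve2`, `rg`, `re`, `beta1`,
#'   `beta2`.
#' @return Log-likelihood (scalar).
#' @export
loglik_bivariate <- function(y1, y2, X, phi, params) {
  n <- length(y1)
  stopifnot(length(y2) == n, nrow(phi) == n)
  X <- check_design(X, n)
  p <- params
  if (any(c(p$vg1, p$ve1, p$vg2, p$ve2) < 0))
    stop("variance components must be nonnegative")
  if (abs(p$rg) > 1 || abs(p$re) > 1)
    stop("correlations must lie in [-1, 1]: indefinite G or E")
  A <- 2 * phi
  cg <- p$rg * sqrt(p$vg1 * p$vg2)
  ce <- p$re * sqrt(p$ve1 * p$ve2)
  I <- diag(n)
  sigma <- rbind(
    cbind(A * p$vg1 + I * p$ve1, A * cg + I * ce),
    cbind(A * cg + I * ce, A * p$vg2 + I * p$ve2)
  )
  r <- c(y1 - as.vector(X %*% p$beta1), y2 - as.vector(X %*% p$beta2))
  L <- tryCatch(chol(sigma), error = function(e)
    stop("joint covariance not positive definite"))
  q <- sum(backsolve(L, r, transpose = TRUE)^2)
  -0.5 * (2 * n * log(2 * pi) + 2 * sum(log(diag(L))) + q)
}

# Fast bivariate log-likelihood in the rotated basis: per eigenvalue d_k of
# 2*Phi the 2x2 block is d_k*G + E; beta for both traits is profiled by GLS.
# theta = (h2_1, h2_2, vp1, vp2, rg, re) on the natural scale.
bivar_ll <- function(theta, y1t, y2t, Xt, d) {
  h1 <- theta[1]; h2 <- theta[2]
  vp1 <- theta[3]; vp2 <- theta[4]
  rg <- theta[5]; re <- theta[6]
  n <- length(y1t)
  vg1 <- h1 * vp1; ve1 <- (1 - h1) * vp1
  vg2 <- h2 * vp2; ve2 <- (1 - h2) * vp2
  cg <- rg * sqrt(vg1 * vg2)
  ce <- re * sqrt(ve1 * ve2)
  o11 <- d * vg1 + ve1
  o22 <- d * vg2 + ve2
  o12 <- d * cg + ce
  det_k <- o11 * o22 - o12^2
  if (any(det_k <= 0) || any(o11 <= 0) || any(o22 <= 0)) return(NULL)
  i11 <- o22 / det_k; i22 <- o11 / det_k; i12 <- -o12 / det_k
  # GLS for stacked (beta1, beta2)
  A11 <- crossprod(Xt, Xt * i11)
  A22 <- crossprod(Xt, Xt * i22)
  A12 <- crossprod(Xt, Xt * i12)
  b1 <- crossprod(Xt, i11 * y1t + i12 * y2t)
  b2 <- crossprod(Xt, i12 * y1t + i22 * y2t)
  Amat <- rbind(cbind(A11, A12), cbind(A12, A22))
  beta <- tryCatch(solve(Amat, rbind(b1, b2)), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  pp <- ncol(Xt)
  beta1 <- beta[seq_len(pp)]; beta2 <- beta[pp + seq_len(pp)]
  r1 <- y1t - as.vector(Xt %*% beta1)
  r2 <- y2t - as.vector(Xt %*% beta2)
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  ll <- -0.5 * (2 * n * log(2 * pi) + sum(log(det_k)) + quad)
  list(ll = ll, beta1 = beta1, beta2 = beta2)
}

#' Fit the bivariate polygenic model by maximum likelihood
#'
#' Joint ML estimation of the per-trait variance components and the genetic
#' (`rg`) and environmental (`re`) correlations between two traits,
#' partitioning their phenotypic correlation into a genetic and an
#' environmental component. Univariate fits initialize the search; the
#' likelihood is evaluated through the shared eigendecomposition of
#' `2 * Phi` (one 2x2 block per eigenvalue), and the box-constrained
#' optimizer works on `(h2_1, h2_2, log vp1, log vp2, rg, re)`. A fit pinned
#' at `|rg| = 1` (or `|re| = 1`) is flagged as a boundary solution and its
#' standard error reported missing.
#'
#' @param y1,y2 trait vectors on the same individuals.
#' @param X design matrix with intercept; `NULL` for intercept-only.
#' @param phi kinship matrix.
#' @param options list: `eig` (precomputed [polygenic_eigen()]), `fix`
#'   (named list pinning `rg` and/or `re`, e.g. `list(rg = 0)` for the
#'   no-genetic-correlation null).
#' @return Object of class `bivariate_fit`: per-trait `vg`, `ve`, `h2`;
#'   `rg`, `re`, `rg_se`, `re_se`; `loglik`; `rp_derived` (model-implied
#'   phenotypic correlation); boundary flags; coefficient matrix `beta`.
#' @export
fit_bivariate <- function(y1, y2, X = NULL, phi, options = list()) {
  n <- length(y1)
  stopifnot(length(y2) == n)
  if (anyNA(y1) || anyNA(y2)) stop("traits contain missing values")
  if (stats::var(y1) <= 0 || stats::var(y2) <= 0)
    stop("degenerate trait: zero variance")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- check_design(X, n)
  eig <- options$eig
  if (is.null(eig)) eig <- polygenic_eigen(phi)
  else if (eig$n != n) stop("precomputed eigendecomposition size mismatch")
  if (max(eig$d) - min(eig$d) < 1e-10)
    stop("no related pairs: variance components not identifiable")
  fix <- options$fix
  yt1 <- as.vector(crossprod(eig$U, y1))
  yt2 <- as.vector(crossprod(eig$U, y2))
  Xt <- crossprod(eig$U, X)

  u1 <- fit_univariate(y1, X, phi, options = list(eig = eig))
  u2 <- fit_univariate(y2, X, phi, options = list(eig = eig))
  r0 <- stats::cor(y1 - u1$fitted_fixed, y2 - u2$fitted_fixed)

  eps <- 1e-6
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  # optimize on (h1, h2, log vp1, log vp2, rg, re)
  obj <- function(par) {
    th <- c(clamp(par[1:2], eps, 1 - eps), exp(par[3:4]),
            clamp(par[5:6], -1 + eps, 1 - eps))
    if (!is.null(fix$rg)) th[5] <- fix$rg
    if (!is.null(fix$re)) th[6] <- fix$re
    res <- bivar_ll(th, yt1, yt2, Xt, eig$d)
    if (is.null(res) || !is.finite(res$ll)) 1e10 else -res$ll
  }
  h1s <- clamp(u1$h2, 0.05, 0.95)
  h2s <- clamp(u2$h2, 0.05, 0.95)
  rstart <- clamp(r0, -0.8, 0.8)
  starts <- list(
    c(h1s, h2s, log(u1$vp), log(u2$vp), rstart, rstart),
    c(h1s, h2s, log(u1$vp), log(u2$vp), 0, 0),
    c(h1s, h2s, log(u1$vp), log(u2$vp), clamp(2 * rstart, -0.9, 0.9), 0),
    c(0.5, 0.5, log(stats::var(y1)), log(stats::var(y2)), 0.5, -0.3)
  )
  lower <- c(eps, eps, -30, -30, -1 + eps, -1 + eps)
  upper <- c(1 - eps, 1 - eps, 30, 30, 1 - eps, 1 - eps)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    stop("bivariate fit did not converge from any start")
  # polish with Nelder-Mead
  o2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  if (o2$value < best$value) best <- o2

  par <- best$par
  th <- c(clamp(par[1:2], eps, 1 - eps), exp(par[3:4]),
          clamp(par[5:6], -1 + eps, 1 - eps))
  if (!is.null(fix$rg)) th[5] <- fix$rg
  if (!is.null(fix$re)) th[6] <- fix$re
  res <- bivar_ll(th, yt1, yt2, Xt, eig$d)
  h2_1 <- th[1]; h2_2 <- th[2]; vp1 <- th[3]; vp2 <- th[4]
  rg <- th[5]; re <- th[6]
  rg_boundary <- abs(rg) >= 1 - 10 * eps
  re_boundary <- abs(re) >= 1 - 10 * eps
  # standard errors from the observed information on the working scale
  rg_se <- re_se <- NA_real_
  free <- c(is.null(fix$rg) && !rg_boundary, is.null(fix$re) && !re_boundary)
  if (any(free)) {
    llfun <- function(p6) {
      t6 <- c(clamp(p6[1:2], eps, 1 - eps), exp(p6[3:4]),
              clamp(p6[5:6], -1 + eps, 1 - eps))
      if (!is.null(fix$rg)) t6[5] <- fix$rg
      if (!is.null(fix$re)) t6[6] <- fix$re
      r <- bivar_ll(t6, yt1, yt2, Xt, eig$d)
      if (is.null(r)) -Inf else r$ll
    }
    H <- tryCatch(numeric_hessian(llfun, par), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      V <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(V)) {
        if (free[1] && V[5, 5] > 0) rg_se <- sqrt(V[5, 5])
        if (free[2] && V[6, 6] > 0) re_se <- sqrt(V[6, 6])
      }
    }
  }
  rp <- derived_phenotypic_correlation(h2_1, h2_2, rg, re)
  structure(list(
    vg1 = h2_1 * vp1, ve1 = (1 - h2_1) * vp1, h2_1 = h2_1, vp1 = vp1,
    vg2 = h2_2 * vp2, ve2 = (1 - h2_2) * vp2, h2_2 = h2_2, vp2 = vp2,
    rg = rg, re = re, rg_se = rg_se, re_se = re_se,
    rg_boundary = rg_boundary, re_boundary = re_boundary,
    loglik = res$ll, rp_derived = rp,
    beta = cbind(trait1 = res$beta1, trait2 = res$beta2),
    columns = colnames(X), n = n, fixed = fix, converged = TRUE,
    data = list(y1 = y1, y2 = y2, X = X, eig = eig)
  ), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<bivariate_fit> n=%d  h2=(%.2f, %.2f)  rg=%.3f%s  re=%.3f%s",
           "  rp=%.3f  loglik=%.4f\n"),
    x$n, x$h2_1, x$h2_2,
    x$rg, if (x$rg_boundary) "*" else "",
    x$re, if (x$re_boundary) "*" else "",
    x$rp_derived, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for a genetic or environmental correlation
#'
#' Refits the bivariate model with `rg` (or `re`) pinned at zero and
#' compares likelihoods; the tested parameter is interior under the null, so
#' the reference is chi-square with 1 df. When the unconstrained estimate
#' sits at `|r| = 1`, the result carries a boundary note.
#'
#' @param fit_full an unconstrained [fit_bivariate()] result.
#' @param which `"rg"` or `"re"`.
#' @return List: `statistic`, `p_value`, `boundary_note`.
#' @export
lrt_correlation <- function(fit_full, which = c("rg", "re")) {
  which <- match.arg(which)
  stopifnot(inherits(fit_full, "bivariate_fit"))
  if (!is.null(fit_full$fixed[[which]]))
    stop("mismatched fits: '", which, "' was fixed in the full model")
  d <- fit_full$data
  fix <- stats::setNames(list(0), which)
  fit0 <- fit_bivariate(d$y1, d$y2, d$X, options = list(eig = d$eig, fix = fix))
  stat <- max(0, 2 * (fit_full$loglik - fit0$loglik))
  bound <- if (which == "rg") fit_full$rg_boundary else fit_full$re_boundary
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       boundary_note = bound)
}

#' Model-implied phenotypic correlation
#'
#' Decomposition of the phenotypic correlation of two traits into genetic
#' and environmental parts:
#' `rp = rg * sqrt(h2_1 * h2_2) + re * sqrt((1 - h2_1) * (1 - h2_2))`.
#'
#' @param h2_1,h2_2 heritabilities in `[0, 1]`.
#' @param rg,re correlations in `[-1, 1]`.
#' @return Phenotypic correlation.
#' @export
derived_phenotypic_correlation <- function(h2_1, h2_2, rg, re) {
  if (any(c(h2_1, h2_2) < 0 | c(h2_1, h2_2) > 1))
    stop("heritabilities must lie in [0, 1]")
  if (any(abs(c(rg, re)) > 1))
    stop("correlations must lie in [-1, 1]")
  rg * sqrt(h2_1 * h2_2) + re * sqrt((1 - h2_1) * (1 - h2_2))
}

#' Spearman rank correlation with t approximation
#'
#' Pearson correlation of average ranks; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (max(x) == min(x) || max(y) == min(y)) stop("constant input")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
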