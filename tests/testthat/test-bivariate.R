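biv_draw <- function(phi, vg1, ve1, vg2, ve2, rg, re) {
  # independent draw of a bivariate polygenic pair via the dense 2n x 2n
  # covariance (oracle-side construction, not the package's simulator)
  n <- nrow(phi)
  A <- 2 * phi
  I <- diag(n)
  cg <- rg * sqrt(vg1 * vg2); ce <- re * sqrt(ve1 * ve2)
  sigma <- rbind(cbind(A * vg1 + I * ve1, A * cg + I * ce),
                 cbind(A * cg + I * ce, A * vg2 + I * ve2))
  z <- as.vector(t(chol(sigma)) %*% stats::rnorm(2 * n))
  list(y1 = z[1:n], y2 = z[n + 1:n])
}

test_that("dense bivariate log-likelihood matches an independent MVN oracle", {
  ped <- pedigree(fid = rep("f", 3), id = c("d", "m", "c"),
                  father = c(NA, NA, "d"), mother = c(NA, NA, "m"))
  phi <- compute_kinship(ped)
  y1 <- c(0.4, -1.1, 0.7); y2 <- c(-0.2, 0.5, 1.3)
  X <- cbind(1, c(1, -1, 0))
  params <- list(vg1 = 0.5, ve1 = 0.5, vg2 = 0.8, ve2 = 0.3,
                 rg = 0.6, re = -0.2, beta1 = c(0.1, 0.3),
                 beta2 = c(-0.2, 0))
  ll <- loglik_bivariate(y1, y2, X, phi, params)
  A <- 2 * phi; I <- diag(3)
  cg <- params$rg * sqrt(params$vg1 * params$vg2)
  ce <- params$re * sqrt(params$ve1 * params$ve2)
  sigma <- rbind(cbind(A * params$vg1 + I * params$ve1, A * cg + I * ce),
                 cbind(A * cg + I * ce, A * params$vg2 + I * params$ve2))
  mu <- c(as.vector(X %*% params$beta1), as.vector(X %*% params$beta2))
  expect_equal(ll, dense_mvn_loglik(c(y1, y2), mu, sigma), tolerance = 1e-10)

  # zero correlations: block independence = sum of univariate likelihoods
  p0 <- utils::modifyList(params, list(rg = 0, re = 0))
  expect_equal(loglik_bivariate(y1, y2, X, phi, p0),
               loglik_univariate(y1, X, phi, p0$vg1, p0$ve1, p0$beta1) +
                 loglik_univariate(y2, X, phi, p0$vg2, p0$ve2, p0$beta2),
               tolerance = 1e-10)

  # trait-order symmetry
  swapped <- list(vg1 = params$vg2, ve1 = params$ve2, vg2 = params$vg1,
                  ve2 = params$ve1, rg = params$rg, re = params$re,
                  beta1 = params$beta2, beta2 = params$beta1)
  expect_equal(loglik_bivariate(y2, y1, X, phi, swapped), ll,
               tolerance = 1e-10)

  expect_error(loglik_bivariate(y1, y2, X, phi,
                                utils::modifyList(params, list(rg = 1.5))),
               "indefinite")
})

test_that("bivariate ML fit attains a grid-search oracle on a 6-person pedigree", {
  ped <- ped_two_families()
  phi <- compute_kinship(ped)
  set.seed(5)
  d <- biv_draw(phi, 0.6, 0.4, 0.6, 0.4, 0.7, 0.1)
  fit <- fit_bivariate(d$y1, d$y2, NULL, phi)
  X <- matrix(1, 6, 1)
  # oracle: coarse grid over (rg, re) at the fit's variance components --
  # the fit's likelihood must beat every grid point
  gmax <- grid_biv_loglik(d$y1, d$y2, X, phi,
                          fit$vg1, fit$ve1, fit$vg2, fit$ve2,
                          rg_grid = seq(-0.95, 0.95, by = 0.05),
                          re_grid = seq(-0.95, 0.95, by = 0.05))
  expect_gte(fit$loglik, gmax - 1e-5)

  # and the internal rotated likelihood equals the dense evaluation
  ll_dense <- loglik_bivariate(d$y1, d$y2, X, phi, list(
    vg1 = fit$vg1, ve1 = fit$ve1, vg2 = fit$vg2, ve2 = fit$ve2,
    rg = fit$rg, re = fit$re,
    beta1 = fit$beta[, 1], beta2 = fit$beta[, 2]))
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)
})

test_that("identical traits drive all correlations to the upper boundary", {
  ped <- replicate_pedigree(ped_nuclear(), 6)
  phi <- phi_phenotyped(ped)
  set.seed(9)
  y <- as.vector(t(chol(2 * phi * 0.5 + diag(0.5, nrow(phi)))) %*%
                   stats::rnorm(nrow(phi)))
  fit <- fit_bivariate(y, y + 1e-8 * stats::rnorm(length(y)), NULL, phi)
  expect_gt(fit$rg, 0.99)
  expect_gt(fit$re, 0.99)
  expect_gt(fit$rp_derived, 0.99)
  expect_true(fit$rg_boundary)
  expect_true(is.na(fit$rg_se))  # no SE at the boundary
})

test_that("correlation LRTs use chi-square(1) and flag fixed-parameter misuse", {
  ped <- replicate_pedigree(ped_nuclear(), 10)
  phi <- phi_phenotyped(ped)
  set.seed(23)
  d <- biv_draw(phi, 0.6, 0.4, 0.6, 0.4, 0.9, 0)
  fit <- fit_bivariate(d$y1, d$y2, NULL, phi)
  l_rg <- lrt_correlation(fit, "rg")
  expect_gte(l_rg$statistic, 0)
  expect_equal(l_rg$p_value,
               stats::pchisq(l_rg$statistic, 1, lower.tail = FALSE))
  # chi-square(1) quantile: stat = 3.841 -> p = 0.05
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)

  fit0 <- fit_bivariate(d$y1, d$y2, NULL, phi,
                        options = list(fix = list(rg = 0)))
  expect_equal(fit0$rg, 0)
  expect_error(lrt_correlation(fit0, "rg"), "fixed")
})

test_that("phenotypic correlation decomposition obeys its identity", {
  expect_equal(derived_phenotypic_correlation(0.4, 0.4, 1, 1), 1)
  expect_equal(derived_phenotypic_correlation(0.5, 0.5, 0, 0), 0)
  expect_equal(derived_phenotypic_correlation(0.5, 0.5, 0.8, 0.2), 0.5)
  expect_error(derived_phenotypic_correlation(1.2, 0.5, 0, 0), "\\[0, 1\\]")
  expect_error(derived_phenotypic_correlation(0.5, 0.5, 2, 0), "\\[-1, 1\\]")
})

test_that("spearman correlation matches rank-then-Pearson with t approximation", {
  x <- c(3.1, 5.2, 0.4, 9.9, 2.2, 7.3, 1.1, 8.8, 4.4, 6.6)
  y <- c(1.0, 2.5, 0.2, 9.1, 3.3, 5.5, 0.9, 7.7, 2.2, 8.4)
  sp <- spearman_correlation(x, y)
  rho_oracle <- stats::cor(rank(x), rank(y))
  expect_equal(sp$rho, rho_oracle, tolerance = 1e-12)
  t_oracle <- rho_oracle * sqrt(8 / (1 - rho_oracle^2))
  expect_equal(sp$p_value, 2 * stats::pt(-abs(t_oracle), 8),
               tolerance = 1e-12)
  # cross-check rho against the standard implementation
  expect_equal(sp$rho, unname(stats::cor(x, y, method = "spearman")),
               tolerance = 1e-12)

  expect_equal(spearman_correlation(1:5, c(2, 4, 5, 7, 10))$rho, 1)
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
})

test_that("bivariate marginals agree with univariate fits when correlations are small", {
  ped <- replicate_pedigree(build_fixture(), 3)
  phi <- phi_phenotyped(ped)
  eig <- polygenic_eigen(phi)
  set.seed(77)
  d <- biv_draw(phi, 0.6, 0.4, 0.3, 0.7, 0.1, 0.05)
  fb <- fit_bivariate(d$y1, d$y2, NULL, phi, options = list(eig = eig))
  f1 <- fit_univariate(d$y1, NULL, phi, options = list(eig = eig))
  f2 <- fit_univariate(d$y2, NULL, phi, options = list(eig = eig))
  expect_lt(abs(fb$h2_1 - f1$h2), 0.02)
  expect_lt(abs(fb$h2_2 - f2$h2), 0.02)
})
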