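test_that("dense univariate log-likelihood matches an independent MVN oracle", {
  ped <- pedigree(fid = rep("f", 3), id = c("d", "m", "c"),
                  father = c(NA, NA, "d"), mother = c(NA, NA, "m"))
  phi <- compute_kinship(ped)
  y <- c(1.2, -0.5, 0.3)
  X <- cbind(1, c(0.5, 1.5, -1))
  beta <- c(0.2, -0.1)
  vg <- 0.7; ve <- 0.4
  ll <- loglik_univariate(y, X, phi, vg, ve, beta)
  sigma <- 2 * phi * vg + diag(ve, 3)
  expect_equal(ll, dense_mvn_loglik(y, as.vector(X %*% beta), sigma),
               tolerance = 1e-10)

  # Vg = 0 reduces to independent normals
  ll0 <- loglik_univariate(y, X, phi, 0, ve, beta)
  expect_equal(ll0, sum(stats::dnorm(y, as.vector(X %*% beta),
                                     sqrt(ve), log = TRUE)),
               tolerance = 1e-10)

  # relabeling invariance
  pm <- c(3, 1, 2)
  expect_equal(
    loglik_univariate(y[pm], X[pm, ], phi[pm, pm], vg, ve, beta), ll,
    tolerance = 1e-10)

  expect_error(loglik_univariate(y, X, phi, 0, 0, beta), "singular")
  Xbad <- cbind(1, c(1, 2, 3), c(2, 4, 6))
  colnames(Xbad) <- c("int", "a", "twice_a")
  expect_error(loglik_univariate(y, Xbad, phi, vg, ve, c(0, 0, 0)),
               "twice_a")
})

test_that("ML fit attains the grid-search maximum on small pedigrees", {
  set.seed(31)
  for (ped in list(ped_two_families(), ped_nuclear(), ped_threegen())) {
    ids <- ped$id[ped$phenotyped]
    phi <- compute_kinship(ped)[ids, ids]
    n <- length(ids)
    y <- as.vector(t(chol(2 * phi * 0.6 + diag(0.4, n))) %*% stats::rnorm(n)) + 1
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    fit <- fit_univariate(y, X, phi)
    gmax <- grid_uni_loglik(y, X, phi,
                            h2_grid = seq(0, 0.999, by = 1e-3),
                            vp_grid = stats::var(y) * seq(0.2, 3, by = 0.005))
    expect_gte(fit$loglik, gmax - 1e-6)
    expect_lt(fit$loglik - gmax, 0.05)  # grid is fine enough to be close
  }
})

test_that("fit respects scale equivariance and boundary behavior", {
  ped <- replicate_pedigree(ped_nuclear(), 8)
  phi <- phi_phenotyped(ped)
  n <- nrow(phi)
  set.seed(11)
  y <- as.vector(t(chol(2 * phi * 0.5 + diag(0.5, n))) %*% stats::rnorm(n))
  f1 <- fit_univariate(y, NULL, phi)
  f2 <- fit_univariate(3 * y, NULL, phi)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-5)
  expect_equal(f2$vp, 9 * f1$vp, tolerance = 1e-4)
  # h2 invariant under affine transformation
  f3 <- fit_univariate(2 * y + 5, NULL, phi)
  expect_equal(f3$h2, f1$h2, tolerance = 1e-5)

  # independent data (Vg = 0 truth) on the 130-member cohort: estimates
  # small, boundary flag commonly set
  phic <- phi_phenotyped(build_fixture())
  eigc <- polygenic_eigen(phic)
  set.seed(21)
  hits <- vapply(1:20, function(i) {
    yy <- stats::rnorm(nrow(phic))
    ft <- fit_univariate(yy, NULL, phic, options = list(eig = eigc))
    c(ft$h2, ft$boundary)
  }, numeric(2))
  expect_lt(mean(hits[1, ]), 0.15)
  expect_gt(mean(hits[2, ]), 0.3)  # boundary flag commonly set

  # unrelated individuals: not identifiable
  solo <- pedigree(fid = letters[1:4], id = letters[1:4])
  expect_error(fit_univariate(stats::rnorm(4), NULL, compute_kinship(solo)),
               "identifiable")
})

test_that("heritability LRT uses the boundary chi-square mixture", {
  ped <- replicate_pedigree(ped_nuclear(), 5)
  phi <- phi_phenotyped(ped)
  set.seed(3)
  y <- as.vector(t(chol(2 * phi * 0.6 + diag(0.4, nrow(phi)))) %*%
                   stats::rnorm(nrow(phi)))
  full <- fit_univariate(y, NULL, phi)
  null <- fit_univariate(y, NULL, phi, options = list(constrain_h2 = 0))
  lrt <- lrt_heritability(full, null)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value,
               0.5 * stats::pchisq(lrt$statistic, 1, lower.tail = FALSE))

  # known quantile of the mixture: stat = 2.706 -> p = 0.05
  fake <- function(ll, constrained) {
    structure(list(loglik = ll, n = full$n, columns = full$columns,
                   constrained = constrained, h2 = 0),
              class = "polygenic_fit")
  }
  expect_equal(lrt_heritability(fake(1.353, FALSE), fake(0, TRUE))$p_value,
               0.05, tolerance = 1e-3)
  # zero (and numerically negative) statistics give the point-mass p = 0.5
  expect_equal(lrt_heritability(fake(0, FALSE), fake(1e-9, TRUE))$p_value, 0.5)
  expect_equal(lrt_heritability(fake(0, FALSE), fake(0, TRUE))$p_value, 0.5)

  # mismatched models are refused
  null2 <- fit_univariate(y, cbind(1, stats::rnorm(length(y))), phi,
                          options = list(constrain_h2 = 0))
  expect_error(lrt_heritability(full, null2), "mismatch")
})

test_that("covariate screening retains true effects and drops noise", {
  ped <- replicate_pedigree(build_fixture(), 2)
  phi <- phi_phenotyped(ped)
  eig <- polygenic_eigen(phi)
  n <- nrow(phi)
  set.seed(17)
  Lk <- t(chol(2 * phi * 0.5 + diag(0.5, n)))
  age <- stats::runif(n, 40, 85)
  retained_age <- logical(10)
  retained_noise <- logical(10)
  for (i in 1:10) {
    g <- as.vector(Lk %*% stats::rnorm(n)) * sqrt(0.9)
    beta_age <- sqrt(0.10 / stats::var(age))  # age at 10% of variance
    y <- g + beta_age * age
    noise <- stats::rnorm(n)
    scr <- screen_covariates(y, cbind(age = age, noise = noise), phi,
                             options = list(eig = eig))
    retained_age[i] <- "age" %in% scr$retained
    retained_noise[i] <- "noise" %in% scr$retained
  }
  expect_true(all(retained_age))          # power ~1 at n = 260
  expect_lt(mean(retained_noise), 0.5)    # threshold 0.1 null rate

  # empty candidate list -> intercept-only final model
  y <- stats::rnorm(n)
  scr0 <- screen_covariates(y, NULL, phi, options = list(eig = eig))
  expect_equal(scr0$retained, character(0))
  expect_equal(scr0$fit$columns, "(Intercept)")
  expect_error(screen_covariates(numeric(0), NULL, phi), "empty")
})

test_that("covariate variance proportion recovers an injected fraction", {
  ped <- replicate_pedigree(build_fixture(), 10)
  phi <- phi_phenotyped(ped)
  eig <- polygenic_eigen(phi)
  params <- trait_model_params(h2 = c(tr = 0.6), vp = c(tr = 1),
                               rg = matrix(1, 1, 1), re = matrix(1, 1, 1),
                               cov_fracs = c(age = 0.12))
  cov <- simulate_covariates(ped, seed = 8)
  Lk <- t(chol(2 * phi))
  props <- vapply(1:20, function(i) {
    tt <- simulate_traits(ped, cov, params, seed = 300 + i, sqrt_kin = Lk)
    X <- cbind("(Intercept)" = 1, age = tt$age)
    fit <- fit_univariate(tt$tr, X, phi, options = list(eig = eig))
    proportion_variance_covariates(fit, tt$tr)
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.12), 0.04)

  # intercept-only model explains nothing
  y <- stats::rnorm(nrow(phi))
  f0 <- fit_univariate(y, NULL, phi, options = list(eig = eig))
  expect_equal(proportion_variance_covariates(f0, y), 0)

  # orthogonal covariate contributes ~0
  x <- stats::rnorm(nrow(phi))
  fx <- fit_univariate(y, cbind(1, x = x), phi, options = list(eig = eig))
  expect_lt(proportion_variance_covariates(fx, y), 0.05)
})

test_that("covariate-variance attribution subtracts with a floor", {
  expect_equal(attribute_covariate_variance(0.15, 0.10)$delta, 0.05)
  expect_equal(attribute_covariate_variance(0.10, 0.10)$delta, 0)
  att <- attribute_covariate_variance(0.08, 0.10)
  expect_equal(att$delta, 0)
  expect_true(att$floored)
  expect_error(attribute_covariate_variance(1.2, 0.1))
})
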