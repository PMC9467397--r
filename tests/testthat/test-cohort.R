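test_that("fixture construction is a pure function of the config", {
  ped1 <- build_fixture()
  ped2 <- build_fixture()
  expect_identical(as.data.frame(ped1), as.data.frame(ped2))
  expect_equal(sum(ped1$phenotyped), 130)
  expect_equal(length(unique(ped1$fid)), 59)
  # family sizes: 47 two-member, 12 three-member (phenotyped)
  sizes <- table(table(ped1$fid[ped1$phenotyped]))
  expect_equal(unname(sizes[["2"]]), 47)
  expect_equal(unname(sizes[["3"]]), 12)

  empty <- build_fixture(cohort_config(family_templates = c(sib_pair = 0L)))
  expect_equal(nrow(empty), 0)

  expect_error(cohort_config(family_templates = c(nonsense = 3L)), "template")
})

test_that("replicate_pedigree makes disjoint namespaced copies", {
  ped <- ped_nuclear()
  expect_identical(replicate_pedigree(ped, 1), ped)
  expect_error(replicate_pedigree(ped, 0), ">= 1")

  ped10 <- replicate_pedigree(build_fixture(), 10)
  expect_equal(sum(ped10$phenotyped), 1300)
  cen <- pair_census(ped10)
  expect_equal(unname(cen["full-sibling"]), 550)

  # members of different copies are unrelated
  p2 <- replicate_pedigree(ped, 2)
  phi <- compute_kinship(p2)
  ids1 <- grep("^r1\\.", p2$id, value = TRUE)
  ids2 <- grep("^r2\\.", p2$id, value = TRUE)
  expect_true(all(phi[ids1, ids2] == 0))
})

test_that("simulated covariates honor prevalences, ranges and determinism", {
  ped <- build_fixture()
  cov <- simulate_covariates(ped, seed = 123)
  expect_equal(nrow(cov), 130)

  # same seed twice -> identical tables
  expect_identical(cov, simulate_covariates(ped, seed = 123))

  # exact binomial 99% interval around the configured prevalence
  ci <- stats::qbinom(c(0.005, 0.995), 130, 0.808)
  expect_gte(sum(cov$hypertension), ci[1])
  expect_lte(sum(cov$hypertension), ci[2])

  # ages in range, parents >= 18 years older than children
  expect_true(all(cov$age >= 38 & cov$age <= 85))
  pairs <- classify_relative_pairs(ped)
  pc <- pairs[pairs$label == "parent-child", ]
  age <- stats::setNames(cov$age, cov$id)
  gaps <- abs(age[pc$id1] - age[pc$id2])
  expect_true(all(gaps >= 18))

  # prevalence 0 -> all-zero column
  cfg0 <- cohort_config(covariates = utils::modifyList(
    cohort_config()$covariates, list(diabetes = 0)))
  cov0 <- simulate_covariates(ped, cfg0, seed = 5)
  expect_true(all(cov0$diabetes == 0))

  expect_error(
    cohort_config(covariates = utils::modifyList(
      cohort_config()$covariates, list(diabetes = 1.4))),
    "prevalence")
})

test_that("raw risk-factor measurements are consistent with binary statuses", {
  cov <- simulate_covariates(build_fixture(), seed = 99)
  expect_equal(
    as.integer(encode_hypertension(cov$htn_history, cov$systolic,
                                   cov$diastolic, cov$bp_meds)),
    cov$hypertension)
  expect_equal(
    as.integer(encode_diabetes(cov$dm_history, cov$antidiabetics,
                               cov$glucose)),
    cov$diabetes)
  expect_equal(
    as.integer(encode_hypercholesterolemia(cov$hc_history, cov$hc_treated,
                                           cov$total_chol, cov$ldl_chol)),
    cov$hypercholesterolemia)
})

test_that("simulated traits realize the constructed covariance", {
  # sibling-pair correlation: theory value 2*phi*h2
  ped <- replicate_pedigree(
    build_fixture(cohort_config(family_templates = c(sib_pair = 30L))), 1)
  for (h2t in c(0, 1)) {
    params <- trait_model_params(h2 = c(tr = h2t), vp = c(tr = 2),
                                 rg = matrix(1, 1, 1), re = matrix(1, 1, 1),
                                 cov_fracs = c(none = 0))
    cors <- vapply(1:500, function(i) {
      tt <- simulate_traits(ped, NULL, params, seed = i)
      y <- matrix(tt$tr, ncol = 2, byrow = TRUE)  # one row per sib pair
      stats::cor(y[, 1], y[, 2])
    }, numeric(1))
    theory <- 0.5 * h2t
    se <- stats::sd(cors) / sqrt(length(cors))
    expect_lt(abs(mean(cors) - theory), 3 * se + 1e-12)
  }
})

test_that("single individual draws Normal(0, vp) and seeds are reproducible", {
  solo <- pedigree(fid = "f", id = "only")
  params <- trait_model_params(h2 = c(tr = 0.4), vp = c(tr = 3),
                               rg = matrix(1, 1, 1), re = matrix(1, 1, 1),
                               cov_fracs = c(none = 0))
  ys <- vapply(1:2000, function(i)
    simulate_traits(solo, NULL, params, seed = i)$tr, numeric(1))
  expect_lt(abs(mean(ys)), 3 * stats::sd(ys) / sqrt(2000))
  expect_lt(abs(stats::var(ys) - 3), 3 * 3 * sqrt(2 / 1999))

  tt1 <- simulate_traits(build_fixture(), NULL, seed = 7)
  tt2 <- simulate_traits(build_fixture(), NULL, seed = 7)
  expect_identical(tt1, tt2)
})

test_that("invalid correlation structures are rejected with the block named", {
  expect_error(
    trait_model_params(h2 = c(a = .5, b = .5),
                       rg = matrix(c(1, 2, 2, 1), 2), re = diag(2)),
    "rg")
  expect_error(
    trait_model_params(h2 = c(a = .5, b = .5),
                       rg = diag(2), re = matrix(c(1, -3, -3, 1), 2)),
    "re")
})
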