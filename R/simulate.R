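#' Simulate covariates and risk factors for a cohort
#'
#' Draws per-individual covariates for the phenotyped members of a pedigree:
#' age (years, within the configured range, parents at least 18 years older
#' than their children), sex (taken from the pedigree where known, otherwise
#' drawn at the configured female fraction), BMI, APOE e4 carrier status,
#' ever-smoking, and the three vascular risk factors. For each binary risk
#' factor the raw measurements behind it (systolic/diastolic blood pressure,
#' fasting glucose, total and LDL cholesterol, medication/history flags) are
#' also emitted and are constructed to be consistent with the binary status
#' under the encoding rules of [encode_hypertension()], [encode_diabetes()]
#' and [encode_hypercholesterolemia()], so the encoders are testable against
#' ground truth.
#'
#' @param ped a [pedigree].
#' @param config a [cohort_config()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A data frame, one row per phenotyped individual: `id`, `fid`,
#'   `age`, `female`, `bmi`, `apoe4`, `smoking`, `hypertension`, `diabetes`,
#'   `hypercholesterolemia` plus the raw measurement columns.
#' @export
simulate_covariates <- function(ped, config = cohort_config(), seed = 1L) {
  stopifnot(is_pedigree(ped), inherits(config, "cohort_config"))
  if (nrow(ped) == 0) stop("pedigree is empty")
  cv <- config$covariates
  set.seed(as.integer(seed))
  members <- ped[ped$phenotyped, , drop = FALSE]
  n <- nrow(members)

  age <- simulate_ages(ped, cv$age_min, cv$age_max)[members$id]

  female <- ifelse(members$sex == "female", 1L,
            ifelse(members$sex == "male", 0L,
                   stats::rbinom(n, 1L, cv$female)))
  apoe4 <- stats::rbinom(n, 1L, cv$apoe4)
  smoking <- stats::rbinom(n, 1L, cv$smoking)
  bmi <- stats::rnorm(n, cv$bmi_mean, cv$bmi_sd)

  # hypertension: status first, then raw values consistent with it
  htn <- stats::rbinom(n, 1L, cv$hypertension) == 1L
  htn_history <- htn & stats::runif(n) < 0.7
  bp_meds <- htn & stats::runif(n) < 0.6
  need_bp <- htn & !htn_history & !bp_meds   # must exceed a threshold
  systolic <- ifelse(htn, stats::runif(n, 125, 185), stats::runif(n, 100, 138))
  systolic[need_bp] <- stats::runif(sum(need_bp), 142, 185)
  diastolic <- ifelse(htn, stats::runif(n, 70, 105), stats::runif(n, 60, 88))

  dm <- stats::rbinom(n, 1L, cv$diabetes) == 1L
  dm_history <- dm & stats::runif(n) < 0.8
  antidiabetics <- dm & stats::runif(n) < 0.6
  need_glu <- dm & !dm_history & !antidiabetics
  glucose <- ifelse(dm, stats::runif(n, 110, 210), stats::runif(n, 75, 124))
  glucose[need_glu] <- stats::runif(sum(need_glu), 128, 210)

  hc <- stats::rbinom(n, 1L, cv$hypercholesterolemia) == 1L
  hc_history <- hc & stats::runif(n) < 0.6
  hc_treated <- hc & stats::runif(n) < 0.5
  need_lip <- hc & !hc_history & !hc_treated
  total_chol <- ifelse(hc, stats::runif(n, 170, 290), stats::runif(n, 140, 198))
  ldl_chol <- ifelse(hc, stats::runif(n, 90, 190), stats::runif(n, 60, 128))
  total_chol[need_lip] <- stats::runif(sum(need_lip), 203, 290)

  data.frame(
    id = members$id, fid = members$fid,
    age = unname(age), female = female, bmi = bmi, apoe4 = apoe4,
    smoking = smoking,
    hypertension = as.integer(htn), diabetes = as.integer(dm),
    hypercholesterolemia = as.integer(hc),
    htn_history = htn_history, bp_meds = bp_meds,
    systolic = systolic, diastolic = diastolic,
    dm_history = dm_history, antidiabetics = antidiabetics,
    glucose = glucose,
    hc_history = hc_history, hc_treated = hc_treated,
    total_chol = total_chol, ldl_chol = ldl_chol,
    stringsAsFactors = FALSE
  )
}

# Family-correlated ages anchored on the phenotyped (study) generations.
# Each family's youngest phenotyped generation gets a base age: from a beta
# skewed towards the older end (median near 0.72 of the range, mimicking an
# elderly cohort) when the family's phenotyped members are a single
# generation, or a uniform draw low enough to fit a phenotyped parent above
# it otherwise. Older generations sit one fixed per-family gap (20.5-25 y)
# above the base per generation step, so phenotyped parent-child gaps are
# >= 18.5 y and every phenotyped age stays in [age_min, age_max].
# Unphenotyped placeholder founders follow the same ladder and are clipped
# to the range only as far as the 18-year gaps allow (their ages are never
# used downstream). Childless members get +-2 y of jitter so siblings
# differ.
simulate_ages <- function(ped, age_min, age_max) {
  n <- nrow(ped)
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- topological_order(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  span <- age_max - age_min
  # generation depth: founders 0, child = 1 + max(parent depth)
  depth <- rep(0L, n)
  for (i in ord) {
    d <- c(if (!is.na(fa[i])) depth[fa[i]], if (!is.na(mo[i])) depth[mo[i]])
    if (length(d) > 0) depth[i] <- 1L + max(d)
  }
  has_kids <- seq_len(n) %in% c(fa[!is.na(fa)], mo[!is.na(mo)])
  age <- rep(NA_real_, n)
  for (f in unique(ped$fid)) {
    fam <- which(ped$fid == f)
    ph <- fam[ped$phenotyped[fam]]
    if (length(ph) == 0) ph <- fam
    deepest <- max(depth[ph])
    multi_gen <- length(unique(depth[ph])) > 1
    base <- if (multi_gen) stats::runif(1, age_min + 2, age_max - 25)
            else age_min + span * stats::rbeta(1, 4.2, 1.8)
    gap <- stats::runif(1, 20.5, 25)
    age[fam] <- base + gap * (deepest - depth[fam])
  }
  jit <- stats::runif(n, -2, 2)
  age[!has_kids] <- age[!has_kids] + jit[!has_kids]
  # clip phenotyped members into range (jitter margin keeps gaps >= 18.5)
  keep <- ped$phenotyped
  age[keep] <- pmin(pmax(age[keep], age_min), age_max)
  stats::setNames(round(age, 1), ped$id)
}

#' Trait-model parameters for the 9-region simulator
#'
#' Ground-truth generative parameters for the nine regional R2* traits:
#' four basal-ganglia measures (composite, caudate, pallidum, putamen) and
#' five cortical measures (composite cortex, frontal, temporal, parietal,
#' occipital lobes). The default genetic-correlation matrix is block
#' compound-symmetric — 0.85 within the basal ganglia, 0.80 within the
#' cortex, 0 between blocks — mirroring a regime where the two systems are
#' driven by distinct gene sets; the environmental correlation defaults to
#' the identity. Default heritabilities are region-specific moderate-to-high
#' values; total variance defaults to 1 per trait. Covariate effects are
#' specified as signed fractions of total variance; the generator keeps
#' total variance at `vp` by shrinking the genetic and environmental
#' components proportionally, so the "proportion of variance due to
#' covariates" is a recoverable quantity.
#'
#' @param h2 named numeric vector of per-trait heritabilities in `[0, 1]`.
#' @param vp per-trait total variances (> 0).
#' @param rg genetic correlation matrix (unit diagonal, PSD).
#' @param re environmental correlation matrix (unit diagonal, PSD).
#' @param cov_fracs named numeric vector of signed variance fractions per
#'   covariate column; `abs()` is the fraction, the sign the direction.
#' @return A list of class `trait_model_params`.
#' @export
trait_model_params <- function(
    h2 = c(basal_ganglia = 0.75, caudate = 0.74, pallidum = 0.46,
           putamen = 0.82, total_cortex = 0.73, frontal = 0.65,
           temporal = 0.76, parietal = 0.65, occipital = 0.70),
    vp = stats::setNames(rep(1, length(h2)), names(h2)),
    rg = default_rg(names(h2)),
    re = diag(length(h2)),
    cov_fracs = c(age = 0.10, female = 0.02, bmi = 0.04, apoe4 = -0.03,
                  hypertension = 0.02, diabetes = 0.02,
                  hypercholesterolemia = 0.01, smoking = 0)) {
  stopifnot(all(h2 >= 0 & h2 <= 1), all(vp > 0),
            is.matrix(rg), is.matrix(re),
            nrow(rg) == length(h2), nrow(re) == length(h2))
  check_corr <- function(m, what) {
    if (any(abs(diag(m) - 1) > 1e-12))
      stop(what, " must have unit diagonal")
    if (any(abs(m - t(m)) > 1e-12)) stop(what, " must be symmetric")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(what, " is not positive semidefinite")
  }
  check_corr(rg, "rg"); check_corr(re, "re")
  if (sum(abs(cov_fracs)) >= 1)
    stop("covariate variance fractions must sum below 1")
  dimnames(rg) <- dimnames(re) <- list(names(h2), names(h2))
  structure(list(h2 = h2, vp = vp, rg = rg, re = re, cov_fracs = cov_fracs),
            class = "trait_model_params")
}

# block compound-symmetric genetic correlation: basal ganglia vs cortex
default_rg <- function(trait_names) {
  p <- length(trait_names)
  bg <- grepl("basal|caudate|pallidum|putamen", trait_names)
  rg <- matrix(0, p, p)
  rg[bg, bg] <- 0.85
  rg[!bg, !bg] <- 0.80
  diag(rg) <- 1
  rg
}

#' Simulate multi-trait phenotypes on a pedigree
#'
#' Draws the trait matrix from the generative mirror of the polygenic model:
#' the stacked traits are multivariate normal with cross-individual,
#' cross-trait covariance `2*Phi (x) G + I (x) E`, where
#' `G[s,t] = rg[s,t] * sqrt(Vg_s * Vg_t)` and
#' `E[s,t] = re[s,t] * sqrt(Ve_s * Ve_t)`. With covariate fractions `f_c`,
#' the components are `Vg_t = h2_t * vp_t * (1 - sum|f|)` and
#' `Ve_t = (1 - h2_t) * vp_t * (1 - sum|f|)`, and fixed effects
#' `beta_c = sign(f_c) * sqrt(|f_c| * vp_t / var(x_c))` are added, so total
#' variance stays near `vp_t` and each covariate contributes its configured
#' share.
#'
#' @param ped a [pedigree].
#' @param covars covariate table from [simulate_covariates()] (may be `NULL`
#'   for a pure polygenic draw over the phenotyped members).
#' @param params a [trait_model_params()].
#' @param seed integer seed.
#' @param sqrt_kin optional precomputed square root `L` (with `L L' = 2*Phi`
#'   over the phenotyped members, e.g. `t(chol(relationship_matrix(ped)))`);
#'   saves refactorizing the relationship matrix across many replicates.
#' @return `covars` with the trait columns appended (or a new data frame
#'   with `id` when `covars` is `NULL`).
#' @export
simulate_traits <- function(ped, covars = NULL, params = trait_model_params(),
                            seed = 1L, sqrt_kin = NULL) {
  stopifnot(is_pedigree(ped), inherits(params, "trait_model_params"))
  set.seed(as.integer(seed))
  ids <- if (is.null(covars)) ped$id[ped$phenotyped] else covars$id
  if (length(ids) == 0) stop("no phenotyped individuals")
  K <- if (is.null(sqrt_kin)) relationship_matrix(ped, ids) else NULL
  p <- length(params$h2)
  n <- length(ids)
  shrink <- 1 - sum(abs(params$cov_fracs))
  vg <- params$h2 * params$vp * shrink
  ve <- (1 - params$h2) * params$vp * shrink
  G <- params$rg * tcrossprod(sqrt(vg))
  E <- params$re * tcrossprod(sqrt(ve))
  chol_psd <- function(m, what) {
    # fast path for positive definite blocks, symmetric square root otherwise
    ch <- tryCatch(t(chol(m)), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    eg <- eigen(m, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
      stop("covariance block not positive semidefinite: ", what)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(m)) %*% t(eg$vectors)
  }
  Lk <- if (is.null(sqrt_kin)) chol_psd(K, "relationship matrix")
        else {
          stopifnot(nrow(sqrt_kin) == length(ids))
          sqrt_kin
        }
  Lg <- chol_psd(G, "genetic covariance G")
  Le <- chol_psd(E, "environmental covariance E")
  # vec(Lk Z Lg') has covariance G (x) K over (trait-major) stacking
  g <- Lk %*% matrix(stats::rnorm(n * p), n, p) %*% t(Lg)
  e <- matrix(stats::rnorm(n * p), n, p) %*% t(Le)
  y <- g + e
  colnames(y) <- names(params$h2)
  # fixed covariate effects as mean shifts
  if (!is.null(covars)) {
    for (cn in names(params$cov_fracs)) {
      f <- params$cov_fracs[[cn]]
      if (f == 0 || !cn %in% names(covars)) next
      x <- covars[[cn]]
      vx <- stats::var(x)
      if (!is.finite(vx) || vx <= 0) next
      beta <- sign(f) * sqrt(abs(f) * params$vp / vx)  # per-trait vector
      y <- y + outer(x - mean(x), beta)
    }
  }
  out <- if (is.null(covars)) data.frame(id = ids, stringsAsFactors = FALSE)
         else covars
  cbind(out, as.data.frame(y))
}
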