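#' Default analysis configuration
#'
#' Column names, covariate sets, screening threshold and FDR family
#' definitions used by the pipelines. The basic model carries age and sex;
#' extended models add one risk factor at a time. The five multiple-testing
#' families (univariate heritability, Spearman correlation, phenotypic,
#' genetic and environmental correlation) are corrected separately.
#'
#' @param traits trait column names (default: the 9 regional measures of the
#'   synthetic cohort).
#' @param basic_covariates covariates of the basic model.
#' @param risk_factors risk-factor columns for the extended models.
#' @param screening_threshold covariate retention threshold (default 0.1).
#' @param int_offset Blom offset of the inverse-normal transform.
#' @param verbose emit one log line per model fit.
#' @return A list of class `analysis_config`.
#' @export
default_config <- function(
    traits = c("basal_ganglia", "caudate", "pallidum", "putamen",
               "total_cortex", "frontal", "temporal", "parietal", "occipital"),
    basic_covariates = c("age", "female"),
    risk_factors = c("apoe4", "bmi", "hypertension", "diabetes",
                     "hypercholesterolemia", "smoking"),
    screening_threshold = 0.1,
    int_offset = 3 / 8,
    verbose = FALSE) {
  structure(list(traits = traits, basic_covariates = basic_covariates,
                 risk_factors = risk_factors,
                 screening_threshold = screening_threshold,
                 int_offset = int_offset, verbose = verbose),
            class = "analysis_config")
}

# resolve pedigree / phenotype arguments given either as paths or objects,
# check id consistency, and return aligned pieces shared by both pipelines
pipeline_inputs <- function(ped, pheno, config) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  stopifnot(is_pedigree(ped))
  if (is.character(pheno)) pheno <- utils::read.csv(pheno,
                                                    stringsAsFactors = FALSE)
  stopifnot(is.data.frame(pheno))
  ids_ped <- ped$id[ped$phenotyped]
  extra <- setdiff(pheno$id, ped$id)
  missing <- setdiff(ids_ped, pheno$id)
  if (length(extra) > 0 || length(missing) > 0)
    stop("id mismatch between pedigree and phenotype table; ",
         "not in pedigree: [", paste(extra, collapse = ", "),
         "]; phenotyped but absent from table: [",
         paste(missing, collapse = ", "), "]")
  miss_tr <- setdiff(config$traits, names(pheno))
  if (length(miss_tr) > 0)
    stop("missing trait column(s): ", paste(miss_tr, collapse = ", "))
  pheno <- pheno[match(ids_ped, pheno$id), , drop = FALSE]
  phi <- compute_kinship(ped)[ids_ped, ids_ped]
  list(ped = ped, pheno = pheno, phi = phi, eig = polygenic_eigen(phi))
}

log_fit <- function(config, what, fit) {
  if (!isTRUE(config$verbose)) return(invisible())
  message(sprintf("fit %-28s loglik=%.4f h2-ish=%s boundary=%s", what,
                  fit$loglik,
                  if (!is.null(fit$h2)) sprintf("%.3f", fit$h2)
                  else sprintf("rg=%.3f,re=%.3f", fit$rg, fit$re),
                  paste(c(fit$boundary, fit$rg_boundary), collapse = ",")))
}

#' Univariate heritability pipeline
#'
#' For every configured trait: rank-based inverse-normal transform, covariate
#' screening of the basic model (age, sex), maximum-likelihood polygenic fit,
#' boundary-mixture likelihood-ratio test of the heritability, FDR correction
#' across traits, proportion of variance due to the final covariates, and
#' per-risk-factor extended models whose covariate-variance increment over
#' the basic model attributes variance to that factor (with the direction of
#' its effect). Deterministic given inputs.
#'
#' @param ped a [pedigree] or path to a PED file.
#' @param pheno phenotype/covariate data frame or path to CSV; one row per
#'   phenotyped individual, with an `id` column.
#' @param config a [default_config()].
#' @return List: `heritability` (per-trait table: `h2`, `se`, `p`, `q`,
#'   `final_covariates`, `covariate_prop`), `attribution` (trait x factor
#'   table: `delta`, `direction`, `retained`), `fits` (named list of
#'   final basic-model fits).
#' @export
run_heritability_pipeline <- function(ped, pheno, config = default_config()) {
  inp <- pipeline_inputs(ped, pheno, config)
  pheno <- inp$pheno
  phi <- inp$phi
  opts <- list(eig = inp$eig)
  herit_rows <- list()
  attr_rows <- list()
  fits <- list()
  for (tr in config$traits) {
    y <- inverse_normal_transform(pheno[[tr]], offset = config$int_offset)
    cand_basic <- as.matrix(pheno[config$basic_covariates])
    scr <- screen_covariates(y, cand_basic, phi,
                             threshold = config$screening_threshold,
                             options = opts)
    fit <- scr$fit
    log_fit(config, paste0(tr, " [basic]"), fit)
    null <- fit_univariate(y, cbind("(Intercept)" = 1,
                                    cand_basic[, scr$retained, drop = FALSE]),
                           phi, options = c(opts, list(constrain_h2 = 0)))
    lrt <- lrt_heritability(fit, null)
    prop_basic <- proportion_variance_covariates(fit, y)
    herit_rows[[tr]] <- data.frame(
      trait = tr, h2 = fit$h2, se = fit$h2_se,
      p = lrt$p_value, boundary = fit$boundary,
      final_covariates = if (length(scr$retained) == 0) "-"
                         else paste(scr$retained, collapse = ","),
      covariate_prop = prop_basic, stringsAsFactors = FALSE
    )
    fits[[tr]] <- fit
    for (rf in config$risk_factors) {
      if (!rf %in% names(pheno))
        stop("missing risk-factor column: ", rf)
      cand_ext <- as.matrix(pheno[c(config$basic_covariates, rf)])
      scr_e <- screen_covariates(y, cand_ext, phi,
                                 threshold = config$screening_threshold,
                                 options = opts)
      log_fit(config, paste0(tr, " [+", rf, "]"), scr_e$fit)
      kept <- rf %in% scr_e$retained
      if (kept) {
        prop_ext <- proportion_variance_covariates(scr_e$fit, y)
        att <- attribute_covariate_variance(prop_ext, prop_basic)
        dir <- if (scr_e$fit$beta[[rf]] >= 0) "+" else "-"
        attr_rows[[paste(tr, rf)]] <- data.frame(
          trait = tr, factor = rf, retained = TRUE, delta = att$delta,
          floored = att$floored, direction = dir, stringsAsFactors = FALSE)
      } else {
        attr_rows[[paste(tr, rf)]] <- data.frame(
          trait = tr, factor = rf, retained = FALSE, delta = NA_real_,
          floored = NA, direction = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  herit <- do.call(rbind, herit_rows)
  herit$q <- bh_fdr(herit$p)
  rownames(herit) <- NULL
  attribution <- do.call(rbind, attr_rows)
  rownames(attribution) <- NULL
  list(heritability = herit, attribution = attribution, fits = fits)
}

#' Bivariate correlation pipeline
#'
#' Fits the bivariate polygenic model to every pair of configured traits
#' (inverse-normal transformed, age and sex as fixed covariates) and
#' assembles five separately FDR-corrected result families: univariate
#' heritability, Spearman correlation, model-derived phenotypic correlation,
#' genetic correlation and environmental correlation. The phenotypic
#' correlation p-value comes from the joint test of `rg = re = 0`
#' (chi-square, 2 df); `rg` and `re` are each tested by a 1-df
#' likelihood-ratio test.
#'
#' @inheritParams run_heritability_pipeline
#' @return List: `pairs` (long table, one row per trait pair), `families`
#'   (named list of per-family tables with `p` and `q`), `matrices` (named
#'   list of square matrices: `rg`, `rg_p`, `re`, `re_p`, `rp`, `rp_p`,
#'   `spearman_rho`, `spearman_p`), and `combined` (two-triangle character
#'   matrix, genetic correlation above, environmental below the diagonal).
#' @export
run_bivariate_pipeline <- function(ped, pheno, config = default_config()) {
  if (length(config$traits) < 2) stop("need at least 2 traits")
  inp <- pipeline_inputs(ped, pheno, config)
  pheno <- inp$pheno
  phi <- inp$phi
  opts <- list(eig = inp$eig)
  traits <- config$traits
  X <- cbind("(Intercept)" = 1, as.matrix(pheno[config$basic_covariates]))
  yint <- vapply(traits, function(tr)
    inverse_normal_transform(pheno[[tr]], offset = config$int_offset),
    numeric(nrow(pheno)))
  cmb <- utils::combn(traits, 2)
  rows <- list()
  for (k in seq_len(ncol(cmb))) {
    t1 <- cmb[1, k]; t2 <- cmb[2, k]
    fit <- fit_bivariate(yint[, t1], yint[, t2], X, phi, options = opts)
    log_fit(config, paste(t1, t2, sep = " x "), fit)
    l_rg <- lrt_correlation(fit, "rg")
    l_re <- lrt_correlation(fit, "re")
    fit00 <- fit_bivariate(yint[, t1], yint[, t2], X, phi,
                           options = c(opts, list(fix = list(rg = 0, re = 0))))
    stat_rp <- max(0, 2 * (fit$loglik - fit00$loglik))
    p_rp <- stats::pchisq(stat_rp, 2, lower.tail = FALSE)
    sp <- spearman_correlation(pheno[[t1]], pheno[[t2]])
    rows[[k]] <- data.frame(
      trait1 = t1, trait2 = t2,
      rg = fit$rg, rg_se = fit$rg_se, rg_p = l_rg$p_value,
      rg_boundary = fit$rg_boundary,
      re = fit$re, re_se = fit$re_se, re_p = l_re$p_value,
      re_boundary = fit$re_boundary,
      rp = fit$rp_derived, rp_p = p_rp,
      spearman_rho = sp$rho, spearman_p = sp$p_value,
      h2_1 = fit$h2_1, h2_2 = fit$h2_2, loglik = fit$loglik,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pair_label <- paste(pairs$trait1, pairs$trait2, sep = ":")
  families <- list(
    spearman = data.frame(pair = pair_label, estimate = pairs$spearman_rho,
                          p = pairs$spearman_p, q = bh_fdr(pairs$spearman_p)),
    phenotypic_corr = data.frame(pair = pair_label, estimate = pairs$rp,
                                 p = pairs$rp_p, q = bh_fdr(pairs$rp_p)),
    genetic_corr = data.frame(pair = pair_label, estimate = pairs$rg,
                              p = pairs$rg_p, q = bh_fdr(pairs$rg_p)),
    environmental_corr = data.frame(pair = pair_label, estimate = pairs$re,
                                    p = pairs$re_p, q = bh_fdr(pairs$re_p))
  )
  pairs$rg_q <- families$genetic_corr$q
  pairs$re_q <- families$environmental_corr$q
  pairs$rp_q <- families$phenotypic_corr$q
  pairs$spearman_q <- families$spearman$q

  sq <- function(col) {
    m <- matrix(NA_real_, length(traits), length(traits),
                dimnames = list(traits, traits))
    for (k in seq_len(nrow(pairs))) {
      m[pairs$trait1[k], pairs$trait2[k]] <- pairs[[col]][k]
      m[pairs$trait2[k], pairs$trait1[k]] <- pairs[[col]][k]
    }
    m
  }
  matrices <- list(rg = sq("rg"), rg_p = sq("rg_p"),
                   re = sq("re"), re_p = sq("re_p"),
                   rp = sq("rp"), rp_p = sq("rp_p"),
                   spearman_rho = sq("spearman_rho"),
                   spearman_p = sq("spearman_p"))
  combined <- matrix("", length(traits), length(traits),
                     dimnames = list(traits, traits))
  fmt <- function(est, se, p, bnd) {
    if (bnd) sprintf("%.2f^a (p=%.2g)", est, p)
    else sprintf("%.2f±%.2f (p=%.2g)", est, se, p)
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$trait1[k]; j <- pairs$trait2[k]
    combined[i, j] <- fmt(pairs$rg[k], pairs$rg_se[k], pairs$rg_q[k],
                          pairs$rg_boundary[k])
    combined[j, i] <- fmt(pairs$re[k], pairs$re_se[k], pairs$re_q[k],
                          pairs$re_boundary[k])
  }
  list(pairs = pairs, families = families, matrices = matrices,
       combined = combined)
}
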