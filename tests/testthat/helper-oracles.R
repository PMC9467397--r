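# Shared fixtures and independent oracles for the test suite.

# -- tiny pedigrees built in code ------------------------------------------

# father, mother, two full siblings
ped_nuclear <- function() {
  pedigree(
    fid = rep("f1", 4), id = c("dad", "mum", "s1", "s2"),
    father = c(NA, NA, "dad", "dad"), mother = c(NA, NA, "mum", "mum"),
    sex = c("male", "female", "unknown", "unknown"),
    phenotyped = c(TRUE, TRUE, TRUE, TRUE)
  )
}

# grandparents, two sibs, child of sib 1 (avuncular pair s2 - c1)
ped_threegen <- function() {
  pedigree(
    fid = rep("f1", 5), id = c("g1", "g2", "s1", "s2", "c1"),
    father = c(NA, NA, "g1", "g1", NA),
    mother = c(NA, NA, "g2", "g2", "s1"),
    sex = c("male", "female", "female", "unknown", "unknown"),
    phenotyped = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

# shared mother, two half siblings
ped_halfsib <- function() {
  pedigree(
    fid = rep("f1", 3), id = c("m", "h1", "h2"),
    father = c(NA, NA, NA), mother = c(NA, "m", "m"),
    sex = c("female", "unknown", "unknown"),
    phenotyped = c(FALSE, TRUE, TRUE)
  )
}

# two unrelated families of three (6 phenotyped) for small-fit oracles
ped_two_families <- function() {
  pedigree(
    fid = rep(c("fa", "fb"), each = 3),
    id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    father = c(NA, NA, "a1", NA, NA, "b1"),
    mother = c(NA, NA, "a2", NA, NA, "b2"),
    sex = rep(c("male", "female", "unknown"), 2),
    phenotyped = rep(TRUE, 6)
  )
}

# -- gene-dropping Monte-Carlo oracle for kinship ---------------------------
# Founders get unique allele labels; each child inherits one random allele
# per parent (an unknown parent contributes a fresh unique allele). The
# kinship estimate for (i, j) is the mean over the four allele comparisons
# of P(identical by descent), averaged over n_rep drops. Vectorized over
# replicates.
gene_drop_kinship <- function(ped, n_rep = 100000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  # topological order: parents before children
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  placed <- rep(FALSE, n); topo <- integer(0)
  while (length(topo) < n) {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    topo <- c(topo, which(ready)); placed[ready] <- TRUE
  }
  a1 <- a2 <- matrix(0L, n_rep, n)
  next_allele <- 0L
  fresh <- function() {
    next_allele <<- next_allele + 1L
    rep(next_allele, n_rep)
  }
  for (i in topo) {
    if (is.na(fa[i])) a1[, i] <- fresh()
    else {
      pick <- stats::runif(n_rep) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
    }
    if (is.na(mo[i])) a2[, i] <- fresh()
    else {
      pick <- stats::runif(n_rep) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
            (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    phi[i, j] <- phi[j, i] <- mean(ibd)
    se[i, j] <- se[j, i] <- stats::sd(ibd) / sqrt(n_rep)
  }
  list(phi = phi, se = se)
}

# -- dense multivariate-normal log-density oracle ---------------------------
# Independent of the package's chol/eigen paths: log-determinant via
# determinant(), quadratic form via solve().
dense_mvn_loglik <- function(y, mu, sigma) {
  n <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + sum(r * solve(sigma, r)))
}

# univariate grid-search oracle over (h2, vp): dense evaluation with beta
# fit by GLS at each grid point. For fixed h2 the correlation matrix
# C = h2*2*phi + (1-h2)*I is factored once and the exact dense
# log-likelihood -(n log 2 pi vp + logdet C + r' C^{-1} r / vp)/2 is
# evaluated at every vp grid value.
grid_uni_loglik <- function(y, X, phi, h2_grid, vp_grid) {
  best <- -Inf
  A <- 2 * phi
  n <- length(y)
  for (h2 in h2_grid) {
    C <- h2 * A + (1 - h2) * diag(n)
    Ci <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(Ci)) next
    xtsx <- t(X) %*% Ci %*% X
    beta <- tryCatch(solve(xtsx, t(X) %*% Ci %*% y), error = function(e) NULL)
    if (is.null(beta)) next
    r <- y - as.vector(X %*% beta)
    rss <- as.numeric(t(r) %*% Ci %*% r)
    ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
    ll <- -0.5 * (n * log(2 * pi) + n * log(vp_grid) + ld + rss / vp_grid)
    m <- max(ll)
    if (m > best) best <- m
  }
  best
}

# bivariate grid oracle over (rg, re) with the variance components held at
# supplied values; dense 2n x 2n evaluation, beta by GLS
grid_biv_loglik <- function(y1, y2, X, phi, vg1, ve1, vg2, ve2,
                            rg_grid, re_grid) {
  n <- length(y1)
  A <- 2 * phi
  I <- diag(n)
  best <- -Inf
  for (rg in rg_grid) for (re in re_grid) {
    cg <- rg * sqrt(vg1 * vg2); ce <- re * sqrt(ve1 * ve2)
    sigma <- rbind(cbind(A * vg1 + I * ve1, A * cg + I * ce),
                   cbind(A * cg + I * ce, A * vg2 + I * ve2))
    si <- tryCatch(solve(sigma), error = function(e) NULL)
    if (is.null(si)) next
    Xs <- rbind(cbind(X, X * 0), cbind(X * 0, X))
    xtsx <- t(Xs) %*% si %*% Xs
    beta <- tryCatch(solve(xtsx, t(Xs) %*% si %*% c(y1, y2)),
                     error = function(e) NULL)
    if (is.null(beta)) next
    ll <- dense_mvn_loglik(c(y1, y2), as.vector(Xs %*% beta), sigma)
    if (ll > best) best <- ll
  }
  best
}

# brute-force BH oracle: q_i = smallest level alpha at which the step-up
# rule (reject all p <= p_(k), k = max{ j : p_(j) <= j*alpha/m }) rejects p_i
bh_bruteforce <- function(p) {
  m <- length(p)
  ps <- sort(p)
  cand <- sort(unique(pmin(1, ps * m / seq_len(m))))
  vapply(p, function(pi) {
    for (a in cand) {
      k <- which(ps <= seq_len(m) * a / m)
      if (length(k) > 0 && pi <= ps[max(k)]) return(a)
    }
    1
  }, numeric(1))
}

# phenotyped kinship submatrix helper
phi_phenotyped <- function(ped) {
  ids <- ped$id[ped$phenotyped]
  compute_kinship(ped)[ids, ids]
}
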