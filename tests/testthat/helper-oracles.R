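# Independent oracles and small simulators used across the test files.
# Everything here is deliberately written from first principles (dense
# algebra, gene dropping, plain R Gibbs) so it never shares code with the
# implementation paths it checks.

# ---- bivariate phenotype simulator with known components ---------------------
# Direct simulation of y = mean + herd + batch + u + e for two traits from
# given 2x2 blocks; breeding values via the package generator (itself tested
# against closed-form covariances elsewhere).
sim_bivariate <- function(seed, G, C, Q, R, n_prog = 2000, n_sires = 100,
                          n_dams = 800, nh = 50, nb = 50) {
  set.seed(seed)
  sires <- sprintf("S%03d", seq_len(n_sires))
  dams <- sprintf("D%04d", seq_len(n_dams))
  prog <- sprintf("P%04d", seq_len(n_prog))
  ped <- pedigree_table(
    c(sires, dams, prog),
    c(rep(NA, n_sires + n_dams), sample(sires, n_prog, replace = TRUE)),
    c(rep(NA, n_sires + n_dams), sample(dams, n_prog, replace = TRUE)))
  dimnames(G) <- list(c("y1", "y2"), c("y1", "y2"))
  u <- simulate_breeding_values(ped, G, seed = seed + 1L)
  herd <- sample.int(nh, n_prog, replace = TRUE)
  batch <- sample.int(nb, n_prog, replace = TRUE)
  rmv <- function(n, S) {
    L <- chol(S + 1e-12 * diag(2))
    matrix(rnorm(2 * n), n, 2) %*% L
  }
  ch <- rmv(nh, C); qb <- rmv(nb, Q); ee <- rmv(n_prog, R)
  phen <- data.frame(animal = prog, herd = herd, batch = batch,
                     parity_class = 1L, age_class = 1L,
                     y1 = 10 + u[prog, 1] + ch[herd, 1] + qb[batch, 1] + ee[, 1],
                     y2 = 5 + u[prog, 2] + ch[herd, 2] + qb[batch, 2] + ee[, 2],
                     stringsAsFactors = FALSE)
  list(phen = phen, ped = ped)
}

# Study-condition blocks for the recovery checks: intra-herd h2 0.30 / 0.15,
# r_a = 0.9, herd and batch fractions 0.06 / 0.20 of unit phenotypic variance.
recovery_truth <- function() {
  a1 <- 0.30 * 0.74; e1 <- 0.74 - a1
  a2 <- 0.15 * 0.74; e2 <- 0.74 - a2
  list(G = matrix(c(a1, 0.9 * sqrt(a1 * a2), 0.9 * sqrt(a1 * a2), a2), 2),
       C = matrix(c(0.06, 0.03, 0.03, 0.06), 2),
       Q = matrix(c(0.20, 0.10, 0.10, 0.20), 2),
       R = matrix(c(e1, 0.5 * sqrt(e1 * e2), 0.5 * sqrt(e1 * e2), e2), 2))
}

# ---- gene-dropping kinship oracle -------------------------------------------
# Drops unique founder alleles down the pedigree nrep times; the additive
# relationship is twice the probability that random alleles from i and j are
# identical by descent. Returns the estimate and its Monte-Carlo SE per pair.
genedrop_relationship <- function(ped, nrep = 200000L, seed = 1L) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal)
  d <- match(ped$dam, ped$animal)
  set.seed(seed)
  a1 <- matrix(0L, n, nrep)
  a2 <- matrix(0L, n, nrep)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(s[i])) {
      a1[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(nrep) < 0.5
      a1[i, ] <- ifelse(pick, a1[s[i], ], a2[s[i], ])
    }
    if (is.na(d[i])) {
      a2[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(nrep) < 0.5
      a2[i, ] <- ifelse(pick, a1[d[i], ], a2[d[i], ])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  se <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
            (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
      if (i == j) k <- (1 + (a1[i, ] == a2[i, ])) / 2
      est[i, j] <- est[j, i] <- 2 * mean(k)
      se[i, j] <- se[j, i] <- 2 * stats::sd(k) / sqrt(nrep)
    }
  }
  list(A = est, se = se, ids = ped$animal)
}

# Random pedigree over g pseudo-generations with founders and within-table
# matings; used by the gene-dropping and inverse checks.
random_pedigree <- function(n, n_founders = 10, seed = 1L) {
  set.seed(seed)
  animal <- paste0("a", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    sire[i] <- animal[sample.int(i - 1L, 1)]
    repeat {
      dam[i] <- animal[sample.int(i - 1L, 1)]
      if (dam[i] != sire[i]) break
    }
  }
  pedigree_table(animal, sire, dam)
}

# ---- dense restricted-likelihood oracle -------------------------------------
# Explicit REML log-likelihood -(1/2)[(N-p) log 2pi + log|V| + log|X'V^-1 X|
# + y'Py] with V assembled densely; independent of the package's sparse
# mixed-model-equations path.
dense_reml_loglik <- function(y_list, X_list, A_obs, blocks,
                              herd = NULL, batch = NULL) {
  t <- length(y_list)
  n <- length(y_list[[1]])
  y <- unlist(y_list)
  X <- as.matrix(Matrix::bdiag(X_list))
  Zh <- if (!is.null(herd)) stats::model.matrix(~factor(herd) - 1) else NULL
  Zb <- if (!is.null(batch)) stats::model.matrix(~factor(batch) - 1) else NULL
  V <- kronecker(blocks$G, A_obs) + kronecker(blocks$R, diag(n))
  if (!is.null(blocks$C)) V <- V + kronecker(blocks$C, Zh %*% t(Zh))
  if (!is.null(blocks$Q)) V <- V + kronecker(blocks$Q, Zb %*% t(Zb))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  Pm <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(-0.5 * ((length(y) - ncol(X)) * log(2 * pi) +
                     determinant(V)$modulus + determinant(XtViX)$modulus +
                     t(y) %*% Pm %*% y))
}

# ---- plain-R BayesA Gibbs oracle --------------------------------------------
# The pi -> 0 limit of Bayes B: every effect always in the model with its own
# scaled-inv-chi2 variance. Written independently in R.
bayesa_gibbs_r <- function(X, y, niter, burnin, df_b, S_b, df_e, S_e, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  xx <- colSums(X^2)
  mu <- mean(y)
  beta <- numeric(p)
  s2j <- rep(S_b, p)
  e <- y - mu
  s2e <- stats::var(y) / 2
  bsum <- numeric(p); musum <- 0; ns <- 0
  for (it in seq_len(niter)) {
    mu_new <- mu + mean(e) + rnorm(1) * sqrt(s2e / n)
    e <- e - (mu_new - mu); mu <- mu_new
    for (j in seq_len(p)) {
      e <- e + X[, j] * beta[j]
      s2j[j] <- (df_b * S_b + beta[j]^2) / rchisq(1, df_b + 1)
      cj <- xx[j] + s2e / s2j[j]
      rhs <- sum(X[, j] * e)
      beta[j] <- rhs / cj + rnorm(1) * sqrt(s2e / cj)
      e <- e - X[, j] * beta[j]
    }
    s2e <- (df_e * S_e + sum(e^2)) / rchisq(1, df_e + n)
    if (it > burnin) {
      ns <- ns + 1; bsum <- bsum + beta; musum <- musum + mu
    }
  }
  list(mu = musum / ns, beta = bsum / ns)
}

# Small spectra matrix with a known linear signal, for calibration tests.
toy_spectra <- function(n, p, b, noise = 0.1, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("w", seq_len(p))))
  y <- drop(X %*% b) + rnorm(n, 0, noise)
  list(X = X, y = y)
}
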