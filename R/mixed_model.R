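#' Pedigree animal models with herd and slaughter-batch effects
#'
#' The observational model for one or two traits is
#' `y = X b + W1 c + W2 q + Z u + e`, with random herd effects
#' `c ~ N(0, C (x) I)`, slaughter-batch effects `q ~ N(0, Q (x) I)`,
#' additive-genetic animal effects `u ~ N(0, G (x) A)` (A the numerator
#' relationship matrix over the full pedigree) and residuals
#' `e ~ N(0, R (x) I)`. Variance components are estimated by REML: the exact
#' restricted log-likelihood is evaluated through the sparse mixed-model
#' equations and maximised by average-information (AI) quasi-Newton updates
#' with step-halving, which keeps the likelihood monotone non-decreasing
#' across iterations. The inverse AI matrix at convergence supplies the
#' asymptotic covariance of the estimates. Animals recorded for only one of
#' the two traits are handled by the missing-at-random REML formulation
#' (their residual block reduces to the observed trait's variance).
#'
#' @name mixed_model
NULL

fixed_rule_default <- function(trait) {
  if (grepl("^pH", trait)) "parity" else if (grepl("^L", trait)) "age" else "intercept"
}

#' Build the mixed-model design for one or two traits
#'
#' Applies the minimum-cell-size rule (herd and batch levels need at least 3
#' records; offending records are dropped iteratively and the count logged),
#' attaches the fixed effects per trait (dam-parity classes for pH,
#' slaughter-age classes for L*, intercept otherwise) and maps animals to the
#' sorted pedigree.
#'
#' @param phenotypes data.frame with columns `animal`, `herd`, `batch`,
#'   `parity_class`, `age_class` and one column per trait (NA = not
#'   recorded).
#' @param pedigree a `pedigree_table` containing every recorded animal.
#' @param traits character vector of 1 or 2 trait column names.
#' @param use_herd,use_batch include the corresponding random effect.
#' @param fixed_rule function mapping a trait name to `"parity"`, `"age"` or
#'   `"intercept"`.
#' @return object of class `mixed_model_spec`.
#' @export
build_design <- function(phenotypes, pedigree, traits,
                         use_herd = TRUE, use_batch = TRUE,
                         fixed_rule = fixed_rule_default) {
  stopifnot(length(traits) %in% c(1L, 2L))
  missing_tr <- setdiff(traits, colnames(phenotypes))
  if (length(missing_tr)) stop("trait column(s) not found: ",
                               paste(missing_tr, collapse = ", "))
  dat <- phenotypes[rowSums(!is.na(phenotypes[, traits, drop = FALSE])) > 0, ,
                    drop = FALSE]
  # minimum cell size of 3 records for herd and batch levels
  n0 <- nrow(dat)
  repeat {
    ok <- rep(TRUE, nrow(dat))
    if (use_herd) {
      th <- table(dat$herd)
      ok <- ok & dat$herd %in% names(th)[th >= 3]
    }
    if (use_batch) {
      tb <- table(dat$batch)
      ok <- ok & dat$batch %in% names(tb)[tb >= 3]
    }
    if (all(ok)) break
    dat <- dat[ok, , drop = FALSE]
    if (nrow(dat) == 0) stop("all records dropped by the minimum-cell-size rule")
  }
  n_dropped <- n0 - nrow(dat)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped by the minimum-cell-size rule (< 3 per level)")
  }
  ped <- sort_pedigree(pedigree)
  ai <- match(dat$animal, ped$animal)
  if (anyNA(ai)) {
    stop("animal(s) missing from the pedigree: ",
         paste(utils::head(dat$animal[is.na(ai)], 5), collapse = ", "))
  }
  herd <- if (use_herd) as.integer(factor(dat$herd)) else NULL
  batch <- if (use_batch) as.integer(factor(dat$batch)) else NULL
  X <- list(); y <- list(); obs <- list()
  for (i in seq_along(traits)) {
    tr <- traits[i]
    oi <- which(!is.na(dat[[tr]]))
    y[[i]] <- dat[[tr]][oi]
    obs[[i]] <- oi
    kind <- fixed_rule(tr)
    X[[i]] <- switch(kind,
      parity = stats::model.matrix(~factor(parity_class), dat[oi, , drop = FALSE]),
      age = stats::model.matrix(~factor(age_class), dat[oi, , drop = FALSE]),
      intercept = matrix(1, length(oi), 1, dimnames = list(NULL, "(Intercept)")))
    attr(X[[i]], "kind") <- kind
  }
  out <- list(traits = traits, data = dat, y = y, X = X, obs = obs,
              animal_idx = ai, herd = herd, batch = batch,
              n_herds = if (use_herd) max(herd) else 0L,
              n_batches = if (use_batch) max(batch) else 0L,
              pedigree = ped, n_dropped = n_dropped)
  class(out) <- "mixed_model_spec"
  out
}

# ---- internal REML machinery -------------------------------------------------

# Pack/unpack symmetric t x t blocks into a parameter vector (lower triangles).
vech <- function(M) M[lower.tri(M, diag = TRUE)]
unvech <- function(v, t) {
  M <- matrix(0, t, t)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

bend_psd <- function(M, floor_rel = 1e-8, scale = NULL) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  fl <- floor_rel * (if (is.null(scale)) max(abs(eg$values), 1e-12) else scale)
  if (min(eg$values) >= fl) return((M + t(M)) / 2)
  eg$vectors %*% (pmax(eg$values, fl) * t(eg$vectors))
}

# Build constant parts of the MME for a design + A-inverse.
reml_workspace <- function(spec, ainv, blocks) {
  t <- length(spec$traits)
  n_ped <- nrow(spec$pedigree)
  nh <- spec$n_herds; nb <- spec$n_batches
  n_obs <- lengths(spec$obs)
  N <- sum(n_obs)
  row_off <- cumsum(c(0, n_obs))[seq_len(t)]
  p_fix <- vapply(spec$X, ncol, 1L)
  fix_off <- cumsum(c(0, p_fix))[seq_len(t)]
  P <- sum(p_fix)
  use_h <- "C" %in% blocks; use_b <- "Q" %in% blocks
  col_h <- if (use_h) P else 0L
  col_b <- if (use_b) P + use_h * t * nh else 0L
  col_u <- P + use_h * t * nh + use_b * t * nb
  M <- col_u + t * n_ped
  ii <- jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(t)) {
    oi <- spec$obs[[i]]
    rows <- row_off[i] + seq_along(oi)
    Xi <- spec$X[[i]]
    ii <- c(ii, rep(rows, ncol(Xi)))
    jj <- c(jj, rep(fix_off[i] + seq_len(ncol(Xi)), each = length(oi)))
    xx <- c(xx, as.numeric(Xi))
    if (use_h) {
      ii <- c(ii, rows); jj <- c(jj, col_h + (i - 1L) * nh + spec$herd[oi])
      xx <- c(xx, rep(1, length(oi)))
    }
    if (use_b) {
      ii <- c(ii, rows); jj <- c(jj, col_b + (i - 1L) * nb + spec$batch[oi])
      xx <- c(xx, rep(1, length(oi)))
    }
    ii <- c(ii, rows); jj <- c(jj, col_u + (i - 1L) * n_ped + spec$animal_idx[oi])
    xx <- c(xx, rep(1, length(oi)))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, M))
  y <- unlist(spec$y, use.names = FALSE)
  # residual pattern bookkeeping
  if (t == 2L) {
    common <- intersect(spec$obs[[1]], spec$obs[[2]])
    r1 <- row_off[1] + match(common, spec$obs[[1]])
    r2 <- row_off[2] + match(common, spec$obs[[2]])
    only1 <- row_off[1] + which(!(spec$obs[[1]] %in% common))
    only2 <- row_off[2] + which(!(spec$obs[[2]] %in% common))
    rpat <- list(both = cbind(r1, r2), only = list(only1, only2))
  } else {
    rpat <- list(both = NULL, only = list(row_off[1] + seq_len(n_obs[1])))
  }
  list(t = t, N = N, M = M, P = P, W = W, y = y,
       n_ped = n_ped, nh = nh, nb = nb,
       use_h = use_h, use_b = use_b,
       col_h = col_h, col_b = col_b, col_u = col_u,
       row_off = row_off, rpat = rpat,
       Ainv = ainv$Ainv, log_det_A = ainv$log_det_A,
       Ainv_chol = Matrix::Cholesky(ainv$Ainv, LDL = FALSE),
       blocks = blocks)
}

# Sparse residual precision from the t x t residual block R.
build_rinv <- function(ws, R) {
  if (ws$t == 1L) {
    list(Rinv = Matrix::Diagonal(ws$N, 1 / R[1, 1]),
         ld = ws$N * log(R[1, 1]))
  } else {
    Ri <- solve(R)
    b <- ws$rpat$both
    ii <- jj <- integer(0); xx <- numeric(0)
    if (!is.null(b) && nrow(b)) {
      ii <- c(ii, b[, 1], b[, 2], b[, 1], b[, 2])
      jj <- c(jj, b[, 1], b[, 2], b[, 2], b[, 1])
      xx <- c(xx, rep(Ri[1, 1], nrow(b)), rep(Ri[2, 2], nrow(b)),
              rep(Ri[1, 2], 2 * nrow(b)))
    }
    for (i in 1:2) {
      oi <- ws$rpat$only[[i]]
      if (length(oi)) {
        ii <- c(ii, oi); jj <- c(jj, oi); xx <- c(xx, rep(1 / R[i, i], length(oi)))
      }
    }
    ld <- (if (is.null(b)) 0 else nrow(b) * determinant(R, logarithm = TRUE)$modulus[1]) +
      sum(lengths(ws$rpat$only) * log(diag(R)))
    list(Rinv = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ws$N, ws$N)),
         ld = ld)
  }
}

# Assemble the MME coefficient matrix for parameter blocks th = list(G,C,Q,R).
build_mme <- function(ws, th) {
  rin <- build_rinv(ws, th$R)
  WtRi <- Matrix::crossprod(ws$W, rin$Rinv)
  Cmat <- WtRi %*% ws$W
  t <- ws$t
  ld_rand <- 0
  prec <- list(Matrix::Matrix(0, ws$P, ws$P, sparse = TRUE))
  if (ws$use_h) {
    prec <- c(prec, list(Matrix::kronecker(solve(th$C), Matrix::Diagonal(ws$nh))))
    ld_rand <- ld_rand + ws$nh * determinant(th$C, logarithm = TRUE)$modulus[1]
  }
  if (ws$use_b) {
    prec <- c(prec, list(Matrix::kronecker(solve(th$Q), Matrix::Diagonal(ws$nb))))
    ld_rand <- ld_rand + ws$nb * determinant(th$Q, logarithm = TRUE)$modulus[1]
  }
  prec <- c(prec, list(Matrix::kronecker(solve(th$G), ws$Ainv)))
  ld_rand <- ld_rand + ws$n_ped * determinant(th$G, logarithm = TRUE)$modulus[1] +
    t * ws$log_det_A
  Cmat <- Cmat + Matrix::bdiag(prec)
  list(Cmat = Matrix::forceSymmetric(Cmat), Rinv = rin$Rinv, ld_R = rin$ld,
       ld_rand = ld_rand, WtRiy = as.numeric(WtRi %*% ws$y))
}

# Exact restricted log-likelihood (and, optionally, solver byproducts).
reml_loglik_ws <- function(ws, th, want_solve = FALSE) {
  ok <- all(vapply(th[ws$blocks], function(M) {
    min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values) > 0
  }, TRUE))
  if (!ok) return(if (want_solve) list(logL = -Inf) else -Inf)
  mme <- build_mme(ws, th)
  ch <- tryCatch(Matrix::Cholesky(mme$Cmat, LDL = FALSE, super = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) return(if (want_solve) list(logL = -Inf) else -Inf)
  ld_C <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus[1]
  sol <- as.numeric(Matrix::solve(ch, mme$WtRiy, system = "A"))
  yRy <- as.numeric(ws$y %*% (mme$Rinv %*% ws$y))
  yPy <- yRy - sum(sol * mme$WtRiy)
  logL <- -0.5 * ((ws$N - ws$P) * log(2 * pi) + mme$ld_R + mme$ld_rand +
                  ld_C + yPy)
  if (!want_solve) return(logL)
  list(logL = logL, chol = ch, Rinv = mme$Rinv, sol = sol, yPy = yPy)
}

#' Evaluate the restricted log-likelihood at given variance components
#'
#' Exposed so estimates can be checked against direct grid or oracle
#' computations of the same likelihood.
#'
#' @param spec a `mixed_model_spec`.
#' @param ainv a `relationship_inverse` for `spec$pedigree`.
#' @param theta named list of symmetric blocks among `G`, `C`, `Q`, `R`
#'   (t x t each); blocks present define the model.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(spec, ainv, theta) {
  blocks <- intersect(c("G", "C", "Q", "R"), names(theta))
  if (!all(c("G", "R") %in% blocks)) stop("theta needs at least G and R blocks")
  ws <- reml_workspace(spec, ainv, blocks)
  th <- lapply(theta, function(M) as.matrix(M))
  reml_loglik_ws(ws, th, want_solve = FALSE)
}

# parameter vector <-> block list
theta_pack <- function(th, blocks) unlist(lapply(th[blocks], vech))
theta_unpack <- function(v, blocks, t) {
  k <- t * (t + 1) / 2
  th <- list()
  for (i in seq_along(blocks)) th[[blocks[i]]] <- unvech(v[(i - 1) * k + 1:k], t)
  th
}

#' Estimate (co)variance components by AI-REML
#'
#' Maximises the restricted log-likelihood of the animal model over the
#' blocks `G` (additive), `C` (herd), `Q` (batch) and `R` (residual) using
#' average-information quasi-Newton steps on the sparse mixed-model
#' equations. The score is obtained by central differences of the exact
#' likelihood, the AI matrix exactly from working-vector solves; steps are
#' halved whenever they would decrease the likelihood, and interim blocks
#' are bent to the nearest positive-definite matrix. Convergence requires
#' `|delta logL| < tol_logL` together with a relative parameter change below
#' `tol_par` (or a stalled likelihood on two successive iterations).
#'
#' @param spec a `mixed_model_spec` from [build_design()].
#' @param ainv a `relationship_inverse` for `spec$pedigree`.
#' @param start optional named list of starting blocks; default assigns 40%
#'   of the phenotypic variance to the residual and 20% to each other block
#'   (remainder to the residual), zero covariances.
#' @param control list: `max_iter` (default 100), `tol_logL` (1e-8),
#'   `tol_par` (1e-6), `verbose`.
#' @return object of class `variance_components`: estimated blocks, `vcov`
#'   (inverse AI matrix, rows/columns named `G11, G21, G22, ...`), `logL`,
#'   `trace` (logL per iteration), `converged`, and design metadata.
#' @export
reml_animal <- function(spec, ainv, start = NULL,
                        control = list()) {
  ctl <- utils::modifyList(list(max_iter = 100L, tol_logL = 1e-8,
                                tol_par = 1e-6, verbose = FALSE), control)
  t <- length(spec$traits)
  blocks <- c("G", if (spec$n_herds > 0) "C", if (spec$n_batches > 0) "Q", "R")
  ws <- reml_workspace(spec, ainv, blocks)
  vp <- vapply(spec$y, stats::var, 1)
  scale_t <- sqrt(vp)
  scale_mat <- outer(scale_t, scale_t)
  if (is.null(start)) {
    n_other <- length(blocks) - 1L
    fr_other <- 0.2
    fr_res <- 1 - fr_other * n_other
    start <- list()
    for (b in blocks) {
      fr <- if (b == "R") fr_res else fr_other
      start[[b]] <- diag(fr * vp, t)
    }
  }
  th <- lapply(start, as.matrix)[blocks]
  k <- t * (t + 1) / 2
  npar <- length(blocks) * k
  # finite-difference scale per parameter
  pairs <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  h_scale <- rep(sqrt(vp[pairs[, 1]] * vp[pairs[, 2]]), length(blocks))
  floor_v <- 1e-8 * max(vp)

  bend_all <- function(th) {
    for (b in names(th)) th[[b]] <- bend_psd(th[[b]], 1e-8, scale = max(vp))
    th
  }
  th <- bend_all(th)
  cur <- reml_loglik_ws(ws, th, want_solve = TRUE)
  if (!is.finite(cur$logL)) stop("restricted likelihood not finite at start values")
  trace <- cur$logL
  converged <- FALSE
  stall <- 0L
  AI <- NULL
  for (iter in seq_len(ctl$max_iter)) {
    v0 <- theta_pack(th, blocks)
    # score by central differences of the exact logL
    score <- numeric(npar)
    for (m in seq_len(npar)) {
      h <- 1e-5 * h_scale[m]
      vp_ <- v0; vp_[m] <- vp_[m] + h
      vm_ <- v0; vm_[m] <- vm_[m] - h
      lp <- reml_loglik_ws(ws, theta_unpack(vp_, blocks, t))
      lm <- reml_loglik_ws(ws, theta_unpack(vm_, blocks, t))
      score[m] <- if (is.finite(lp) && is.finite(lm)) (lp - lm) / (2 * h)
        else if (is.finite(lp)) (lp - cur$logL) / h
        else if (is.finite(lm)) (cur$logL - lm) / h
        else 0
    }
    # AI matrix from working vectors
    Py <- as.numeric(cur$Rinv %*% (ws$y - as.numeric(ws$W %*% cur$sol)))
    Fm <- fvec_matrix(ws, spec, Py, blocks, pairs)
    WtRiF <- as.matrix(Matrix::crossprod(ws$W, cur$Rinv %*% Fm))
    solF <- as.matrix(Matrix::solve(cur$chol, WtRiF, system = "A"))
    PF <- as.matrix(cur$Rinv %*% (Fm - as.matrix(ws$W %*% solF)))
    AI <- 0.5 * crossprod(Fm, PF)
    AI <- (AI + t(AI)) / 2
    # damped Newton step with step halving
    lambda <- 1e-8 * max(diag(AI), 1)
    step <- tryCatch(solve(AI + lambda * diag(npar), score),
                     error = function(e) score / max(diag(AI), 1))
    improved <- FALSE
    fac <- 1
    for (half in 1:30) {
      v_new <- v0 + fac * step
      th_new <- bend_all(theta_unpack(v_new, blocks, t))
      for (b in names(th_new)) {
        diag(th_new[[b]]) <- pmax(diag(th_new[[b]]), floor_v)
      }
      new <- reml_loglik_ws(ws, th_new, want_solve = TRUE)
      if (is.finite(new$logL) && new$logL >= cur$logL - 1e-12) {
        improved <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!improved) {
      stall <- stall + 1L
      if (stall >= 2L) { converged <- TRUE; break }
      next
    }
    dl <- new$logL - cur$logL
    dpar <- max(abs(theta_pack(th_new, blocks) - v0) /
                  pmax(abs(v0), 0.01 * h_scale))
    th <- th_new
    cur <- new
    trace <- c(trace, cur$logL)
    if (ctl$verbose) {
      message(sprintf("iter %d logL %.6f dlogL %.2e dpar %.2e", iter, cur$logL, dl, dpar))
    }
    if (abs(dl) < ctl$tol_logL && dpar < ctl$tol_par) { converged <- TRUE; break }
    if (abs(dl) < ctl$tol_logL) stall <- stall + 1L else stall <- 0L
    if (stall >= 2L) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(class = c("reml_no_convergence", "error", "condition"),
                      list(message = paste0("REML did not converge in ",
                                            ctl$max_iter, " iterations"),
                           call = sys.call(),
                           last = th, trace = trace))
    stop(cond)
  }
  par_names <- as.vector(vapply(blocks, function(b)
    paste0(b, pairs[, 1], pairs[, 2]), character(k)))
  vcov <- tryCatch(solve(AI), error = function(e) pseudo_inverse(AI))
  dimnames(vcov) <- list(par_names, par_names)
  for (b in names(th)) dimnames(th[[b]]) <- list(spec$traits, spec$traits)
  out <- list(G = th$G, C = th$C, Q = th$Q, R = th$R,
              vcov = vcov, logL = cur$logL, trace = trace,
              converged = TRUE, traits = spec$traits,
              n_records = ws$N, n_dropped = spec$n_dropped,
              blocks = blocks)
  class(out) <- "variance_components"
  out
}

# Moore-Penrose fallback without importing MASS
pseudo_inverse <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Build the N x npar matrix of AI working vectors f_m = (dV/dtheta_m) Py.
fvec_matrix <- function(ws, spec, Py, blocks, pairs) {
  t <- ws$t
  k <- nrow(pairs)
  Fm <- matrix(0, ws$N, length(blocks) * k)
  rows_of <- function(i) ws$row_off[i] + seq_along(spec$obs[[i]])
  # gather Py by level for trait j, apply structure, scatter to trait i rows
  term <- function(b, i, j) {
    pj <- Py[rows_of(j)]
    f <- numeric(ws$N)
    if (b == "G") {
      idx <- spec$animal_idx[spec$obs[[j]]]
      w <- tabulate_sum(idx, pj, ws$n_ped)
      aw <- as.numeric(Matrix::solve(ws$Ainv_chol, w, system = "A"))
      f[rows_of(i)] <- aw[spec$animal_idx[spec$obs[[i]]]]
    } else if (b == "C") {
      w <- tabulate_sum(spec$herd[spec$obs[[j]]], pj, ws$nh)
      f[rows_of(i)] <- w[spec$herd[spec$obs[[i]]]]
    } else if (b == "Q") {
      w <- tabulate_sum(spec$batch[spec$obs[[j]]], pj, ws$nb)
      f[rows_of(i)] <- w[spec$batch[spec$obs[[i]]]]
    } else { # R: per-record identity on animals observed for both traits
      if (i == j) {
        f[rows_of(i)] <- pj
      } else if (!is.null(ws$rpat$both)) {
        ri <- ws$rpat$both[, i]; rj <- ws$rpat$both[, j]
        f[ri] <- Py[rj]
      }
    }
    f
  }
  col <- 0L
  for (b in blocks) {
    for (m in seq_len(k)) {
      col <- col + 1L
      kk <- pairs[m, 1]; ll <- pairs[m, 2]
      f <- term(b, kk, ll)
      if (kk != ll) f <- f + term(b, ll, kk)
      Fm[, col] <- f
    }
  }
  Fm
}

tabulate_sum <- function(idx, val, nlev) {
  as.numeric(unname(rowsum(c(val, numeric(nlev)), c(idx, seq_len(nlev)))))
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>", paste(x$traits, collapse = " x "),
      "| logL =", sprintf("%.4f", x$logL),
      "|", length(x$trace) - 1, "iterations\n")
  for (b in x$blocks) {
    cat(" ", b, ":\n")
    print(round(x[[b]], 6))
  }
  invisible(x)
}

#' Intra-herd heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`: the heritability within
#' contemporary-group strata, with herd and batch variance excluded from the
#' denominator. The SE follows by the first-order delta method from the
#' covariance of the two variance estimates.
#'
#' @param sigma2_a,sigma2_e additive-genetic and residual variance.
#' @param vcov optional 2x2 covariance matrix of `(sigma2_a, sigma2_e)`.
#' @return list with `h2` and `se` (NA without `vcov`).
#' @export
intraherd_heritability <- function(sigma2_a, sigma2_e, vcov = NULL) {
  if (sigma2_a < 0) stop("sigma2_a must be >= 0")
  tot <- sigma2_a + sigma2_e
  if (tot <= 0) stop("sigma2_a + sigma2_e must be > 0")
  h2 <- sigma2_a / tot
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c(sigma2_e, -sigma2_a) / tot^2
    se <- sqrt(drop(t(g) %*% vcov %*% g))
  }
  list(h2 = h2, se = se)
}

#' Genetic and residual correlations from bivariate components
#'
#' Computes `cov / sqrt(var1 * var2)` for the additive (`G`) and residual
#' (`R`) blocks, with delta-method SEs from the inverse-AI covariance.
#' Estimates beyond unit magnitude (possible at convergence on a bent
#' boundary) are clipped
#' and flagged.
#'
#' @param components a `variance_components` from a bivariate fit.
#' @return data.frame with rows `r_a`, `r_e`: estimate, SE, clipped flag.
#' @export
vc_correlations <- function(components) {
  stopifnot(length(components$traits) == 2L)
  one <- function(block, label) {
    B <- components[[block]]
    if (any(diag(B) <= 0)) stop("zero variance: ", label, " correlation undefined")
    r <- B[2, 1] / sqrt(B[1, 1] * B[2, 2])
    nm <- paste0(block, c("11", "21", "22"))
    se <- NA_real_
    if (!is.null(components$vcov) && all(nm %in% rownames(components$vcov))) {
      g <- c(-r / (2 * B[1, 1]), 1 / sqrt(B[1, 1] * B[2, 2]), -r / (2 * B[2, 2]))
      V <- components$vcov[nm, nm]
      se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
    }
    clipped <- abs(r) > 1
    data.frame(correlation = label, estimate = max(-1, min(1, r)), se = se,
               clipped = clipped, stringsAsFactors = FALSE)
  }
  rbind(one("G", "r_a"), one("R", "r_e"))
}

#' Per-trait genetic parameter summary of a bivariate fit
#'
#' Mirrors the reporting convention of the bundled reference tables:
#' phenotypic variance (sum of all components), ratios of each component to
#' the phenotypic variance, and intra-herd heritability with SE, for the
#' measured (first) and predicted (second) trait; plus `r_a`/`r_e` with SEs.
#' Traits flagged `scale100` report variances multiplied by 100.
#'
#' @param components a bivariate `variance_components`.
#' @param scale100 logical: report variances x100 (pH convention).
#' @return list with `variance_table` (one row per trait) and `correlations`.
#' @export
genetic_parameter_report <- function(components, scale100 = FALSE) {
  t <- length(components$traits)
  rows <- lapply(seq_len(t), function(i) {
    va <- components$G[i, i]
    vc <- if (!is.null(components$C)) components$C[i, i] else 0
    vq <- if (!is.null(components$Q)) components$Q[i, i] else 0
    ve <- components$R[i, i]
    vp <- va + vc + vq + ve
    nm <- paste0(c("G", "R"), i, i)
    V <- components$vcov[nm, nm]
    h <- intraherd_heritability(va, ve, V)
    data.frame(trait = components$traits[i],
               phen_var = vp * if (scale100) 100 else 1,
               f_additive = va / vp, f_batch = vq / vp, f_herd = vc / vp,
               f_residual = ve / vp,
               h2 = h$h2, h2_se = h$se, scale100 = scale100,
               stringsAsFactors = FALSE)
  })
  list(variance_table = do.call(rbind, rows),
       correlations = if (t == 2L) vc_correlations(components) else NULL)
}
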