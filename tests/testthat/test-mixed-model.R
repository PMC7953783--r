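# Animal-model design construction, the REML likelihood and estimates,
# heritability and correlation summaries.

test_that("design applies the minimum-cell-size rule and per-trait fixed effects", {
  ped <- pedigree_table(paste0("a", 1:10), rep(NA, 10), rep(NA, 10))
  phen <- data.frame(animal = paste0("a", 1:10),
                     herd = c(rep(1, 4), rep(2, 4), rep(3, 2)),
                     batch = rep(1:2, 5),
                     parity_class = rep(1:2, 5), age_class = rep(1:5, 2),
                     pH = rnorm(10), PL = rnorm(10), L = rnorm(10))
  expect_message(spec <- build_design(phen, ped, "PL", use_batch = FALSE),
                 "dropped")
  expect_equal(nrow(spec$data), 8)
  expect_equal(spec$n_dropped, 2)
  expect_equal(colnames(spec$X[[1]]), "(Intercept)")

  spec_ph <- build_design(phen, ped, "pH", use_herd = FALSE, use_batch = FALSE)
  expect_equal(attr(spec_ph$X[[1]], "kind"), "parity")
  expect_equal(ncol(spec_ph$X[[1]]), 2)  # 2 observed parity classes here

  full_par <- phen; full_par$parity_class <- rep(1:4, length.out = 10)
  spec_ph4 <- build_design(full_par, ped, "pH", use_herd = FALSE,
                           use_batch = FALSE)
  expect_equal(ncol(spec_ph4$X[[1]]), 4)  # intercept + 3 parity contrasts

  spec_L <- build_design(phen, ped, "L", use_herd = FALSE, use_batch = FALSE)
  expect_equal(attr(spec_L$X[[1]], "kind"), "age")
})

test_that("the sparse MME likelihood equals the dense REML formula", {
  set.seed(13)
  ped <- pedigree_table(c("A", "B", "C", "D", "E", "F", "G", "H"),
                        c(NA, NA, "A", "A", "A", "C", NA, "C"),
                        c(NA, NA, "B", "B", "B", "D", NA, "D"))
  A <- build_A(ped)$A
  phen <- data.frame(animal = ped$animal, herd = rep(1:2, 4),
                     batch = rep(1:2, each = 4), parity_class = 1L,
                     age_class = 1L, t1 = rnorm(8, 10, 2), t2 = rnorm(8, 5, 1))
  spec <- build_design(phen, ped, c("t1", "t2"))
  ainv <- build_A_inverse(ped)
  th <- list(G = matrix(c(2, 0.5, 0.5, 1), 2),
             C = matrix(c(0.5, 0.1, 0.1, 0.4), 2),
             Q = matrix(c(0.7, 0.2, 0.2, 0.6), 2),
             R = matrix(c(3, 0.3, 0.3, 2), 2))
  ll <- reml_loglik(spec, ainv, th)
  Ap <- A[phen$animal, phen$animal]
  ll_dense <- dense_reml_loglik(list(phen$t1, phen$t2),
                                list(matrix(1, 8, 1), matrix(1, 8, 1)),
                                Ap, th, herd = phen$herd, batch = phen$batch)
  expect_equal(ll, ll_dense, tolerance = 1e-8)
})

test_that("the REML estimate maximises the explicit likelihood over a grid", {
  set.seed(14)
  ped <- pedigree_table(c("A", "B", "C", "D", "E", "F", "G", "H"),
                        c(NA, NA, "A", "A", "A", "C", NA, "C"),
                        c(NA, NA, "B", "B", "B", "D", NA, "D"))
  A <- build_A(ped)$A
  phen <- data.frame(animal = ped$animal, herd = 1L, batch = 1L,
                     parity_class = 1L, age_class = 1L,
                     y = rnorm(8, 10, 2))
  spec <- build_design(phen, ped, "y", use_herd = FALSE, use_batch = FALSE)
  ainv <- build_A_inverse(ped)
  vc <- reml_animal(spec, ainv)
  Ap <- A[phen$animal, phen$animal]
  oracle <- function(a, e) dense_reml_loglik(list(phen$y),
                                             list(matrix(1, 8, 1)), Ap,
                                             list(G = matrix(a), R = matrix(e)))
  ll_hat <- oracle(vc$G[1, 1], vc$R[1, 1])
  grid <- expand.grid(a = seq(0.05, 8, length.out = 16),
                      e = seq(0.05, 8, length.out = 16))
  ll_grid <- mapply(oracle, grid$a, grid$e)
  expect_gte(ll_hat, max(ll_grid) - 1e-6)
})

test_that("balanced half-sib REML agrees with the ANOVA sire-component oracle", {
  set.seed(15)
  ns <- 40; npr <- 15
  sires <- sprintf("S%03d", 1:ns)
  prog <- sprintf("P%04d", 1:(ns * npr))
  ped <- pedigree_table(c(sires, prog),
                        c(rep(NA, ns), rep(sires, each = npr)),
                        rep(NA, ns + ns * npr))
  G <- matrix(4, dimnames = list("y", "y"))
  u <- simulate_breeding_values(ped, G, seed = 16)
  y <- 10 + u[prog, 1] + rnorm(length(prog), 0, sqrt(12))
  phen <- data.frame(animal = prog, herd = 1L, batch = 1L, parity_class = 1L,
                     age_class = 1L, y = y)
  spec <- build_design(phen, ped, "y", use_herd = FALSE, use_batch = FALSE)
  vc <- reml_animal(spec, build_A_inverse(ped))
  av <- stats::anova(stats::lm(y ~ factor(rep(sires, each = npr))))
  s2_sire <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / npr
  se_a <- sqrt(vc$vcov["G11", "G11"])
  expect_lt(abs(vc$G[1, 1] - 4 * s2_sire), 2 * se_a)
  expect_true(all(diff(vc$trace) > -1e-9))  # monotone likelihood path
})

test_that("null non-residual components are estimated near zero", {
  truth <- recovery_truth()
  d <- sim_bivariate(17, G = diag(1e-8, 2), C = diag(1e-8, 2),
                     Q = diag(1e-8, 2),
                     R = matrix(c(1, 0.5, 0.5, 1), 2),
                     n_prog = 600, n_sires = 40, n_dams = 300, nh = 15, nb = 15)
  spec <- build_design(d$phen, d$ped, c("y1", "y2"))
  vc <- reml_animal(spec, build_A_inverse(d$ped))
  idx <- list(c(1, 1), c(2, 1), c(2, 2))
  for (b in c("G", "C", "Q")) {
    for (ij in idx) {
      nm <- paste0(b, ij[1], ij[2])
      expect_lt(abs(vc[[b]][ij[1], ij[2]]), 2 * sqrt(vc$vcov[nm, nm]) + 1e-6)
    }
  }
})

test_that("intra-herd heritability reproduces the worked examples and edge cases", {
  expect_equal(intraherd_heritability(0.23, 0.54)$h2, 0.2987, tolerance = 1e-4)
  expect_equal(round(intraherd_heritability(0.23, 0.54)$h2, 2), 0.30)
  # the published 0.31 reflects unrounded components; the printed ratios give
  # 0.3019, inside the rounding tolerance
  expect_equal(intraherd_heritability(0.16, 0.37)$h2, 0.3019, tolerance = 1e-4)
  expect_lt(abs(intraherd_heritability(0.16, 0.37)$h2 - 0.31), 0.015)
  expect_equal(intraherd_heritability(0, 1)$h2, 0)
  expect_error(intraherd_heritability(0, 0), "> 0")
  h <- intraherd_heritability(2, 6, vcov = diag(c(0.04, 0.09)))
  expect_true(is.finite(h$se) && h$se > 0)
})

test_that("correlations from components follow the closed form", {
  vc <- list(G = matrix(c(1, 0.5, 0.5, 1), 2), R = matrix(c(2, 0, 0, 3), 2),
             traits = c("m", "p"), vcov = NULL)
  class(vc) <- "variance_components"
  co <- vc_correlations(vc)
  expect_equal(co$estimate[co$correlation == "r_a"], 0.5)
  expect_equal(co$estimate[co$correlation == "r_e"], 0)

  vc$G <- diag(2)
  expect_equal(vc_correlations(vc)$estimate[1], 0)
  vc$G <- matrix(c(0, 0, 0, 1), 2)
  expect_error(vc_correlations(vc), "zero variance")
})

test_that("a simulated genetic correlation is recovered within 2 SEs", {
  a <- 0.3; e <- 0.7
  G <- matrix(c(a, 0.8 * a, 0.8 * a, a), 2)
  d <- sim_bivariate(18, G = G, C = diag(0.05, 2), Q = diag(0.1, 2),
                     R = matrix(c(e, 0.3 * e, 0.3 * e, e), 2),
                     n_prog = 2000, n_sires = 100, n_dams = 800)
  spec <- build_design(d$phen, d$ped, c("y1", "y2"))
  vc <- reml_animal(spec, build_A_inverse(d$ped))
  co <- vc_correlations(vc)
  ra <- co[co$correlation == "r_a", ]
  expect_lt(abs(ra$estimate - 0.8), 2 * ra$se)
})
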