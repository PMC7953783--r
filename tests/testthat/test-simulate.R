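# Synthetic-data generator: pedigree structure, breeding values, phenotypes,
# spectra, and the serialisation round-trips.

micro_only <- list(micro = list(start = 905, stop = 1649, step = 6))

small_config <- function(...) {
  tc <- default_trait_catalog()
  sim_config(n_sires = 10, n_dams = 40, n_progeny = 120, n_herds = 6,
             n_batches = 8, traits = tc[tc$trait %in% c("L", "pH"), ],
             instruments = micro_only, seed = 42, ...)
}

test_that("simulated pedigree has the forced structure and is deterministic", {
  cfg <- sim_config(n_sires = 2, n_dams = 4, n_progeny = 8, seed = 1,
                    instruments = micro_only)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 14)
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 6)
  expect_identical(ped, simulate_pedigree(cfg))

  empty <- simulate_pedigree(sim_config(n_progeny = 0, instruments = micro_only))
  expect_s3_class(empty, "pedigree_table")
  expect_equal(nrow(empty), 0)

  big <- simulate_pedigree(sim_config(n_sires = 25, n_dams = 500,
                                      n_progeny = 2000, seed = 3,
                                      instruments = micro_only))
  per_sire <- tabulate(match(big$sire[!is.na(big$sire)],
                             big$animal[startsWith(big$animal, "S")]), 25)
  expect_equal(mean(per_sire), 2000 / 25)
})

test_that("breeding values have the configured genetic covariance structure", {
  n <- 5000
  founders <- pedigree_table(paste0("f", 1:n), rep(NA, n), rep(NA, n))
  G <- diag(2); dimnames(G) <- list(c("x", "y"), c("x", "y"))
  U <- simulate_breeding_values(founders, G, seed = 5)
  expect_lt(max(abs(stats::cov(U) - diag(2))), 4 / sqrt(n))

  U0 <- simulate_breeding_values(founders[1:50, ], matrix(0, 2, 2), seed = 5)
  expect_true(all(U0 == 0))

  # parent-offspring covariance = G/2
  ns <- 2500
  trio <- pedigree_table(c(paste0("s", 1:ns), paste0("d", 1:ns), paste0("o", 1:ns)),
                         c(rep(NA, 2 * ns), paste0("s", 1:ns)),
                         c(rep(NA, 2 * ns), paste0("d", 1:ns)))
  G1 <- matrix(2, 1, 1, dimnames = list("x", "x"))
  U1 <- simulate_breeding_values(trio, G1, seed = 6)
  cov_po <- stats::cov(U1[paste0("s", 1:ns), 1], U1[paste0("o", 1:ns), 1])
  expect_lt(abs(cov_po - 1), 3 * 2 / sqrt(ns))

  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_breeding_values(founders[1:10, ], bad, seed = 1),
               "eigenvalue")
})

test_that("phenotype variance decomposition follows the configured partition", {
  tc <- default_trait_catalog()
  cfg <- sim_config(n_sires = 40, n_dams = 600, n_progeny = 2000, n_herds = 25,
                    n_batches = 30, traits = tc[tc$trait == "L", ],
                    instruments = micro_only, seed = 8)
  ds <- simulate_dataset(cfg)
  v <- stats::var(ds$phenotypes$L)
  # fixed age-class effects add a little variance on top of 11.64
  expect_lt(abs(v - 11.64) / 11.64, 0.20)

  # realized herd-effect variance within 3 chi-square SEs of f_herd * V
  tr <- cfg$traits
  vh_target <- tr$f_herd * tr$phen_var
  vh <- stats::var(ds$truth$herd_effects$L) * (cfg$n_herds - 1) / cfg$n_herds
  se <- vh_target * sqrt(2 / (cfg$n_herds - 1))
  expect_lt(abs(vh - vh_target), 3 * se)

  # paternal half-sib phenotypic covariance ~ sigma2_a / 4 (no herd/batch)
  tr2 <- tr
  tr2$f_residual <- tr2$f_residual + tr2$f_herd + tr2$f_batch
  tr2$f_herd <- 0; tr2$f_batch <- 0
  cfg2 <- sim_config(n_sires = 25, n_dams = 2000, n_progeny = 6000,
                     n_herds = 4, n_batches = 4, traits = tr2,
                     instruments = micro_only, seed = 9)
  ped <- simulate_pedigree(cfg2)
  G <- nirherit:::latent_G(cfg2$traits)
  bv <- simulate_breeding_values(ped, G, seed = cfg2$seed)
  phn <- simulate_phenotypes(ped, bv, cfg2)
  prog <- phn$phenotypes
  prog$sire <- ped$sire[match(prog$animal, ped$animal)]
  pairs <- do.call(rbind, lapply(split(seq_len(nrow(prog)), prog$sire), function(i) {
    if (length(i) < 2) return(NULL)
    cbind(i[seq(1, length(i) - 1, by = 2)], i[seq(2, length(i), by = 2)])
  }))
  hs_cov <- stats::cov(prog$L[pairs[, 1]], prog$L[pairs[, 2]])
  sa2 <- tr2$f_additive * tr2$phen_var
  expect_lt(abs(hs_cov - sa2 / 4), 3 * tr2$phen_var / sqrt(nrow(pairs)))
})

test_that("latent trait equals the measured core when r_g = 1 and residual fully shared", {
  tc <- default_trait_catalog()
  tr <- tc[tc$trait == "pH", ]
  tr$r_g_latent <- 1; tr$shared_resid_frac <- 1
  cfg <- sim_config(n_sires = 10, n_dams = 50, n_progeny = 200, n_herds = 5,
                    n_batches = 6, traits = tr, instruments = micro_only, seed = 12)
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, nirherit:::latent_G(cfg$traits), cfg$seed)
  expect_equal(stats::cor(bv[, "pH"], bv[, "pH.latent"]), 1, tolerance = 1e-12)
  phn <- simulate_phenotypes(ped, bv, cfg)
  # measured minus mean and fixed-class effects equals the latent trait
  prog <- phn$phenotypes
  sdt <- sqrt(tr$phen_var)
  fx <- nirherit:::PARITY_COEF[prog$parity_class] * sdt
  expect_equal(unname(prog$pH - tr$mean - fx), unname(phn$latent[, "pH"]),
               tolerance = 1e-10)
})

test_that("degenerate variance partitions are honoured or rejected", {
  tc <- default_trait_catalog()
  tr <- tc[tc$trait == "L", ]
  tr[, c("f_additive", "f_batch", "f_herd", "f_residual")] <- c(0, 0, 0, 1)
  cfg <- sim_config(n_sires = 5, n_dams = 30, n_progeny = 600, n_herds = 5,
                    n_batches = 5, traits = tr, instruments = micro_only, seed = 3)
  ds <- simulate_dataset(cfg)
  herd_means <- tapply(ds$phenotypes$L, ds$phenotypes$herd, mean)
  expect_lt(stats::var(herd_means), tr$phen_var * 3 / min(table(ds$phenotypes$herd)))

  bad <- tc[tc$trait == "L", ]
  bad$f_additive <- 0.9
  expect_error(sim_config(traits = bad, instruments = micro_only),
               "sum to 1")
})

test_that("spectra honour replicates, noise and information settings", {
  tc <- default_trait_catalog()
  tr <- tc[tc$trait == "L", ]
  cfg <- sim_config(n_sires = 5, n_dams = 20, n_progeny = 60, n_herds = 4,
                    n_batches = 4, traits = tr, instruments = micro_only,
                    noise_sd_spectral = 0, outlier_rate = 0, seed = 2)
  ds <- simulate_dataset(cfg)
  ss <- ds$spectra$micro
  expect_equal(nrow(ss$absorbance), 60 * cfg$replicates_per_animal)
  one <- ss$absorbance[ss$meta$animal == ss$meta$animal[1], ]
  expect_lt(max(abs(sweep(one, 2, one[1, ]))), 1e-12)

  # zero information + zero noise: same-batch animals have identical spectra
  tr0 <- tr; tr0$spectral_info <- 0
  cfg0 <- sim_config(n_sires = 5, n_dams = 20, n_progeny = 60, n_herds = 4,
                     n_batches = 4, traits = tr0, instruments = micro_only,
                     noise_sd_spectral = 0, outlier_rate = 0, seed = 2)
  ds0 <- simulate_dataset(cfg0)
  b1 <- which(ds0$phenotypes$batch == 1)[1:2]
  s1 <- ds0$spectra$micro$absorbance[ds0$spectra$micro$meta$animal ==
                                       ds0$phenotypes$animal[b1[1]], ][1, ]
  s2 <- ds0$spectra$micro$absorbance[ds0$spectra$micro$meta$animal ==
                                       ds0$phenotypes$animal[b1[2]], ][1, ]
  expect_lt(max(abs(s1 - s2)), 1e-12)

  bad <- tr; bad$spectral_info <- 1.2
  expect_error(sim_config(traits = bad, instruments = micro_only),
               "spectral_info")
})

test_that("datasets are reproducible and structurally consistent", {
  cfg <- small_config()
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1, ds2)
  expect_true(all(ds1$phenotypes$animal %in% ds1$pedigree$animal))
  expect_true(all(table(ds1$phenotypes$herd) >= 3))
  expect_true(all(table(ds1$phenotypes$batch) >= 3))
  reps <- table(ds1$spectra$micro$meta$animal)
  expect_true(all(reps == cfg$replicates_per_animal))
})

test_that("config, phenotype and spectra files round-trip exactly", {
  cfg <- small_config()
  tf <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, tf)
  cfg2 <- read_sim_config(tf)
  expect_equal(cfg2$traits, cfg$traits, tolerance = 1e-12)
  expect_identical(cfg2$seed, cfg$seed)
  expect_identical(cfg2$instruments$micro$step, cfg$instruments$micro$step)

  ds <- simulate_dataset(cfg)
  pf <- tempfile(fileext = ".csv")
  write_phenotypes(ds$phenotypes, pf)
  ph2 <- read_phenotypes(pf)
  expect_identical(ph2$L, ds$phenotypes$L)
  expect_identical(ph2$animal, ds$phenotypes$animal)

  sf <- tempfile(fileext = ".csv")
  sub <- ds$spectra$micro
  keep <- sub$meta$animal %in% unique(sub$meta$animal)[1:5]
  sub2 <- spectra_set(sub$instrument, sub$wavelengths,
                      sub$absorbance[keep, ], sub$meta$animal[keep],
                      sub$meta$replicate[keep])
  write_spectra(sub2, sf)
  rt <- read_spectra(sf)
  expect_identical(rt$absorbance, sub2$absorbance)
  expect_identical(rt$wavelengths, sub2$wavelengths)
})
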