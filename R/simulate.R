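#' Synthetic pedigreed populations with NIR-visible latent traits
#'
#' The generator emulates the study design the package targets: ~200 A.I.
#' sires and ~1,300 dams producing ~1,300 phenotyped young bulls fattened in
#' ~100 herds and slaughtered in ~100 batches; nine meat-quality traits with
#' an additive/batch/herd/residual variance partition; and, for each animal,
#' replicated absorbance spectra on one or two instrument grids that carry a
#' tunable amount of information about a latent "day-1 muscle state" version
#' of each trait. The latent trait shares the herd and batch effects of the
#' measured trait, has its own additive component with a configurable genetic
#' correlation to the measured one, and shares a configurable fraction of the
#' residual; the rest of the measured residual is measurement-specific
#' (aging, transport, assay), which is what caps the attainable external
#' prediction accuracy.
#'
#' @name synthetic_data
NULL

#' Default trait parameter catalog
#'
#' One row per trait: population mean, phenotypic variance, variance-partition
#' fractions (additive, batch, herd, residual; renormalised to sum exactly
#' to 1), genetic correlation between measured and latent trait, target
#' spectral information (fraction of latent variance recoverable from one
#' averaged spectrum), fraction of the measured residual shared with the
#' latent state, and a `scale100` flag for traits reported on a x100 variance
#' scale (pH). Shipped as a YAML file (`inst/extdata/default_simulation.yaml`)
#' which this function reads, so the defaults live in a single editable place.
#'
#' @return data.frame with one row per trait.
#' @export
default_trait_catalog <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "default_simulation.yaml",
                                     package = "nirherit", mustWork = TRUE))
  tc <- do.call(rbind, lapply(cfg$traits, function(t) {
    as.data.frame(t, stringsAsFactors = FALSE)
  }))
  fr <- tc[, c("f_additive", "f_batch", "f_herd", "f_residual")]
  tc[, c("f_additive", "f_batch", "f_herd", "f_residual")] <- fr / rowSums(fr)
  tc
}

#' Simulation configuration
#'
#' @param n_sires,n_dams,n_progeny pedigree structure: founder sires and dams
#'   and number of phenotyped progeny.
#' @param n_herds,n_batches numbers of fattening-herd and slaughter-batch
#'   levels (each must end up with at least 3 animals).
#' @param traits trait catalog data.frame (see [default_trait_catalog()]);
#'   may be subset by row to simulate fewer traits.
#' @param instruments named list of wavelength grids, each
#'   `list(start, stop, step)` in nm.
#' @param replicates_per_animal spectra acquired per animal and instrument.
#' @param noise_sd_spectral white-noise SD per wavelength, absorbance units.
#' @param outlier_rate fraction of spectra corrupted into gross outliers
#'   (spike or offset) for QC testing.
#' @param seed integer; fully determines the generated dataset.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 204, n_dams = 1286, n_progeny = 1327,
                       n_herds = 98, n_batches = 106,
                       traits = default_trait_catalog(),
                       instruments = list(
                         vis = list(start = 350, stop = 1830, step = 1),
                         micro = list(start = 905, stop = 1649, step = 6)),
                       replicates_per_animal = 5,
                       noise_sd_spectral = 0.05,
                       outlier_rate = 0.01,
                       seed = 1L) {
  stopifnot(n_sires >= 1, n_dams >= 1, n_progeny >= 0)
  if (n_herds < 2 || n_batches < 2) stop("n_herds and n_batches must be >= 2")
  fr <- traits[, c("f_additive", "f_batch", "f_herd", "f_residual")]
  if (any(fr < 0)) stop("variance fractions must be >= 0")
  bad <- which(abs(rowSums(fr) - 1) > 1e-8)
  if (length(bad)) {
    stop("variance fractions must sum to 1; offending trait(s): ",
         paste(traits$trait[bad], collapse = ", "))
  }
  if (any(traits$spectral_info < 0 | traits$spectral_info > 1)) {
    stop("spectral_info must lie in [0, 1]")
  }
  if (any(abs(traits$r_g_latent) > 1)) stop("r_g_latent must lie in [-1, 1]")
  rownames(traits) <- NULL
  for (nm in names(instruments)) {
    g <- instruments[[nm]]
    if (g$step <= 0 || g$stop <= g$start) {
      stop("instrument '", nm, "': wavelength grid must be strictly increasing")
    }
  }
  out <- list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_progeny = as.integer(n_progeny),
              n_herds = as.integer(n_herds), n_batches = as.integer(n_batches),
              traits = traits, instruments = instruments,
              replicates_per_animal = as.integer(replicates_per_animal),
              noise_sd_spectral = noise_sd_spectral,
              outlier_rate = outlier_rate, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$traits <- lapply(seq_len(nrow(config$traits)),
                     function(i) as.list(config$traits[i, ]))
  names(x$traits) <- NULL
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  traits <- do.call(rbind, lapply(x$traits, as.data.frame))
  sim_config(n_sires = x$n_sires, n_dams = x$n_dams, n_progeny = x$n_progeny,
             n_herds = x$n_herds, n_batches = x$n_batches, traits = traits,
             instruments = x$instruments,
             replicates_per_animal = x$replicates_per_animal,
             noise_sd_spectral = x$noise_sd_spectral,
             outlier_rate = x$outlier_rate, seed = x$seed)
}

#' Simulate a two-generation pedigree
#'
#' Founder sires and dams (unknown parents), then progeny each assigned one
#' sire and one dam drawn uniformly with replacement. Founders are listed
#' before descendants. With `n_progeny = 0` an empty pedigree is returned.
#'
#' @param config a `sim_config` (its `seed` is used).
#' @return a `pedigree_table`.
#' @export
simulate_pedigree <- function(config) {
  if (config$n_progeny == 0L) {
    return(pedigree_table(character(0), character(0), character(0)))
  }
  set.seed(config$seed)
  sires <- sprintf("S%04d", seq_len(config$n_sires))
  dams <- sprintf("D%04d", seq_len(config$n_dams))
  prog <- sprintf("P%05d", seq_len(config$n_progeny))
  pedigree_table(
    animal = c(sires, dams, prog),
    sire = c(rep(NA, config$n_sires + config$n_dams),
             sample(sires, config$n_progeny, replace = TRUE)),
    dam = c(rep(NA, config$n_sires + config$n_dams),
            sample(dams, config$n_progeny, replace = TRUE)))
}

#' Simulate multivariate breeding values down a pedigree
#'
#' Founders are drawn from `N(0, G)`; a non-founder receives the parent
#' average plus a Mendelian-sampling deviation with covariance
#' `(0.5 - 0.25 (F_s + F_d)) G` (the usual adjustment when one parent is
#' unknown), with inbreeding coefficients `F` computed exactly from the
#' pedigree so the simulated covariance is `G (x) A`.
#'
#' @param pedigree a `pedigree_table`.
#' @param G symmetric positive semi-definite genetic covariance matrix
#'   (one row/column per trait).
#' @param seed integer seed.
#' @return numeric matrix, one row per animal (rownames = ids, sorted
#'   pedigree order), one column per trait of `G`.
#' @export
simulate_breeding_values <- function(pedigree, G, seed) {
  G <- as.matrix(G)
  if (!isSymmetric(G, tol = 1e-10)) stop("G must be symmetric")
  eg <- eigen(G, symmetric = TRUE)
  tolev <- -1e-8 * max(1, max(abs(eg$values)))
  if (min(eg$values) < tolev) {
    stop("G is not positive semi-definite (eigenvalue ",
         format(min(eg$values)), ")")
  }
  sqrtG <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  ib <- inbreeding(pedigree)
  ped <- ib$pedigree
  pi_ <- ped_indices(ped)
  n <- nrow(ped); t <- ncol(G)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * t), n, t) %*% sqrtG
  U <- matrix(0, n, t, dimnames = list(pi_$id, colnames(G)))
  Fv <- ib$F
  for (i in seq_len(n)) {
    s <- pi_$s[i]; d <- pi_$d[i]
    if (is.na(s) && is.na(d)) {
      U[i, ] <- Z[i, ]
    } else {
      pa <- 0.5 * ((if (is.na(s)) 0 else U[s, ]) + (if (is.na(d)) 0 else U[d, ]))
      msv <- if (!is.na(s) && !is.na(d)) {
        0.5 - 0.25 * (Fv[s] + Fv[d])
      } else {
        0.75 - 0.25 * (if (is.na(s)) Fv[d] else Fv[s])
      }
      U[i, ] <- pa + sqrt(msv) * Z[i, ]
    }
  }
  U
}

# Block-diagonal genetic covariance over (measured, latent) pairs per trait.
latent_G <- function(traits) {
  t_n <- nrow(traits)
  G <- matrix(0, 2 * t_n, 2 * t_n)
  nm <- character(2 * t_n)
  for (k in seq_len(t_n)) {
    va <- traits$f_additive[k] * traits$phen_var[k]
    r <- traits$r_g_latent[k]
    i <- 2 * k - 1
    G[i:(i + 1), i:(i + 1)] <- va * matrix(c(1, r, r, 1), 2)
    nm[i:(i + 1)] <- c(traits$trait[k], paste0(traits$trait[k], ".latent"))
  }
  dimnames(G) <- list(nm, nm)
  G
}

# Random allocation of progeny to levels, rejected until every level has >= 3.
allocate_levels <- function(n, k, label, max_tries = 1000) {
  if (n < 3 * k) stop("cannot give ", k, " ", label, " levels >= 3 animals with n = ", n)
  for (try in seq_len(max_tries)) {
    a <- sample.int(k, n, replace = TRUE)
    if (min(tabulate(a, k)) >= 3) return(a)
  }
  stop("failed to allocate ", label, " levels with minimum cell size 3")
}

# Fixed-effect class coefficients, expressed in trait-SD units.
PARITY_COEF <- c(0, -0.20, -0.35, -0.50)   # dam parity classes 1-4, acts on pH
AGE_COEF <- c(0, -0.15, -0.30, -0.45, -0.60) # slaughter-age classes 1-5, acts on L

#' Simulate phenotypes and latent surface traits
#'
#' Measured trait: `mean + fixed-class effect + herd + batch + u + e`, with
#' variance components `fraction x phenotypic variance` from the config.
#' The dam-parity effect (4 classes) enters pH and the slaughter-age effect
#' (5 classes) enters L*; other traits carry an intercept only. Latent
#' surface trait: `herd + batch + u_latent + e_shared`, i.e. the measured
#' trait stripped of its mean, fixed effects and measurement-specific
#' residual, with `u_latent` genetically correlated to `u` as configured.
#'
#' @param pedigree a `pedigree_table`.
#' @param bv breeding-value matrix from [simulate_breeding_values()] with
#'   columns `trait` and `trait.latent` per trait.
#' @param config a `sim_config`.
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @return list with `phenotypes` (data.frame: animal, herd, batch,
#'   parity_class, age_class, one column per trait), `latent` (matrix of
#'   latent surface traits) and `truth` (generating effect realisations).
#' @export
simulate_phenotypes <- function(pedigree, bv, config, seed = config$seed + 1L) {
  traits <- config$traits
  fr <- traits[, c("f_additive", "f_batch", "f_herd", "f_residual")]
  if (any(abs(rowSums(fr) - 1) > 1e-8)) stop("variance fractions must sum to 1")
  prog <- pedigree$animal[grepl("^P", pedigree$animal)]
  if (!length(prog)) prog <- pedigree$animal[!is.na(pedigree$sire) | !is.na(pedigree$dam)]
  n <- length(prog)
  set.seed(seed)
  herd <- allocate_levels(n, config$n_herds, "herd")
  batch <- allocate_levels(n, config$n_batches, "batch")
  parity <- sample.int(4, n, replace = TRUE, prob = c(0.30, 0.25, 0.35, 0.10))
  agecl <- sample.int(5, n, replace = TRUE, prob = c(0.15, 0.25, 0.25, 0.20, 0.15))
  ph <- data.frame(animal = prog, herd = herd, batch = batch,
                   parity_class = parity, age_class = agecl,
                   stringsAsFactors = FALSE)
  latent <- matrix(0, n, nrow(traits), dimnames = list(prog, traits$trait))
  truth <- list(herd_effects = list(), batch_effects = list())
  for (k in seq_len(nrow(traits))) {
    tr <- traits[k, ]
    V <- tr$phen_var
    sdt <- sqrt(V)
    c_h <- stats::rnorm(config$n_herds, 0, sqrt(tr$f_herd * V))
    q_b <- stats::rnorm(config$n_batches, 0, sqrt(tr$f_batch * V))
    v_sh <- tr$shared_resid_frac * tr$f_residual * V
    v_sp <- (1 - tr$shared_resid_frac) * tr$f_residual * V
    e_sh <- stats::rnorm(n, 0, sqrt(v_sh))
    e_sp <- stats::rnorm(n, 0, sqrt(v_sp))
    fx <- numeric(n)
    if (tr$trait == "pH") fx <- PARITY_COEF[parity] * sdt
    if (tr$trait == "L") fx <- AGE_COEF[agecl] * sdt
    u_m <- bv[prog, tr$trait]
    u_l <- bv[prog, paste0(tr$trait, ".latent")]
    ph[[tr$trait]] <- tr$mean + fx + c_h[herd] + q_b[batch] + u_m + e_sh + e_sp
    latent[, k] <- c_h[herd] + q_b[batch] + u_l + e_sh
    truth$herd_effects[[tr$trait]] <- c_h
    truth$batch_effects[[tr$trait]] <- q_b
  }
  list(phenotypes = ph, latent = latent, truth = truth)
}

# Smooth, mutually orthonormal loading curves spread across a grid, all
# orthogonal to the constant vector so batch-level offsets cannot leak into
# trait directions.
loading_curves <- function(wavelengths, n_traits) {
  p <- length(wavelengths)
  centers <- seq(min(wavelengths), max(wavelengths),
                 length.out = n_traits + 2)[-c(1, n_traits + 2)]
  width <- diff(range(wavelengths)) / (2.5 * n_traits)
  B <- sapply(centers, function(cc) exp(-0.5 * ((wavelengths - cc) / width)^2))
  Q <- qr.Q(qr(cbind(rep(1, p), B)))
  L <- Q[, -1, drop = FALSE]
  # fix sign so each curve peaks upward
  for (j in seq_len(ncol(L))) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  L
}

#' Simulate replicated absorbance spectra from latent surface traits
#'
#' Each spectrum is a fixed smooth baseline plus, per trait, an orthonormal
#' Gaussian-bump loading curve scaled by the animal's standardized latent
#' value, plus a batch-level flat offset and white noise; replicates differ
#' only in noise. The per-trait signal scale is calibrated in closed form
#' against the replicate-averaged noise level so that the population R^2 of
#' the best linear predictor of the latent trait from one averaged spectrum
#' equals the configured `spectral_info`. A configured fraction of spectra is
#' corrupted into gross outliers (narrow spike or flat offset) to exercise QC.
#'
#' @param latent latent-trait matrix from [simulate_phenotypes()] (rows =
#'   animals).
#' @param batch batch assignment per animal (integer vector).
#' @param config a `sim_config`.
#' @param instrument name of the instrument grid in `config$instruments`.
#' @param seed integer seed.
#' @return a `spectra_set`; the truth of which spectra were corrupted is in
#'   `meta$corrupted`.
#' @export
simulate_spectra <- function(latent, batch, config, instrument,
                             seed = config$seed + 2L) {
  info <- config$traits$spectral_info
  if (any(info < 0 | info > 1)) stop("spectral_info must lie in [0, 1]")
  info <- pmin(info, 0.999)
  g <- config$instruments[[instrument]]
  w <- seq(g$start, g$stop, by = g$step)
  p <- length(w)
  n <- nrow(latent)
  reps <- config$replicates_per_animal
  Z <- scale(latent)
  Z[is.nan(Z)] <- 0
  L <- loading_curves(w, ncol(latent))
  sigma_eff <- config$noise_sd_spectral / sqrt(reps)
  scl <- sigma_eff * sqrt(info / (1 - info))
  baseline <- 0.8 + 0.3 * sin(2 * pi * (w - min(w)) / diff(range(w))) +
    0.1 * cos(6 * pi * (w - min(w)) / diff(range(w)))
  set.seed(seed)
  shift <- stats::rnorm(max(batch), 0, 5 * config$noise_sd_spectral)
  signal <- matrix(baseline, n, p, byrow = TRUE) +
    Z %*% (t(L) * scl) +
    outer(shift[batch], rep(1 / sqrt(p), p))
  X <- signal[rep(seq_len(n), each = reps), , drop = FALSE] +
    matrix(stats::rnorm(n * reps * p, 0, config$noise_sd_spectral), n * reps, p)
  corrupted <- stats::runif(n * reps) < config$outlier_rate
  for (i in which(corrupted)) {
    if (stats::runif(1) < 0.5) {
      cc <- stats::runif(1, min(w), max(w))
      X[i, ] <- X[i, ] + 1.0 * exp(-0.5 * ((w - cc) / (2 * g$step))^2)
    } else {
      X[i, ] <- X[i, ] + 0.5
    }
  }
  ss <- spectra_set(instrument, w, X,
                    animal = rep(rownames(latent), each = reps),
                    replicate = rep(seq_len(reps), n))
  ss$meta$corrupted <- corrupted
  ss
}

#' Simulate a complete dataset
#'
#' Runs pedigree, breeding-value, phenotype and spectra simulation with
#' seeds derived from `config$seed`; the configuration fully determines the
#' output.
#'
#' @param config a `sim_config`.
#' @return list of class `simulated_dataset`: `pedigree`, `phenotypes`,
#'   `latent`, `spectra` (named list per instrument), `truth` (generating
#'   parameters and effect realisations) and `config`.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  G <- latent_G(config$traits)
  bv <- simulate_breeding_values(ped, G, seed = config$seed)
  phn <- simulate_phenotypes(ped, bv, config, seed = config$seed + 1L)
  spectra <- list()
  for (ins in names(config$instruments)) {
    spectra[[ins]] <- simulate_spectra(
      phn$latent, phn$phenotypes$batch, config, ins,
      seed = config$seed + 2L + match(ins, names(config$instruments)))
  }
  out <- list(pedigree = ped, phenotypes = phn$phenotypes, latent = phn$latent,
              breeding_values = bv,
              spectra = spectra,
              truth = c(phn$truth, list(G = G, traits = config$traits)),
              config = config)
  class(out) <- "simulated_dataset"
  out
}

#' Read / write the phenotype table as CSV
#'
#' Numeric values are written with 17 significant digits so round-trips are
#' bit-exact.
#'
#' @param phenotypes phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- phenotypes
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(animal = "character"))
}
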