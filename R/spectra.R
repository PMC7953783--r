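#' Spectra sets and chemometric pre-processing
#'
#' A `spectra_set` holds absorbance spectra for one instrument on a common
#' wavelength grid, one row per (animal, replicate) scan, together with QC
#' flags. Editing follows the fixed order flag -> average -> standardize:
#' Mahalanobis (GH) outlier screening, replicate averaging to one spectrum
#' per animal, then centring/standardizing of the covariate columns with
#' training-set parameters only.
#'
#' @name spectra
NULL

#' Construct a spectra set
#'
#' @param instrument instrument label, e.g. `"vis"` or `"micro"`.
#' @param wavelengths numeric vector (nm), strictly increasing.
#' @param absorbance numeric matrix, one row per spectrum, `length(wavelengths)`
#'   columns; no missing values.
#' @param animal,replicate id vectors, one entry per row of `absorbance`.
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(instrument, wavelengths, absorbance, animal, replicate) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must be strictly increasing")
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavelengths)) {
    stop("absorbance has ", ncol(absorbance), " columns but grid has ",
         length(wavelengths), " wavelengths")
  }
  if (anyNA(absorbance)) stop("missing absorbance values are not allowed")
  if (length(animal) != nrow(absorbance) || length(replicate) != nrow(absorbance)) {
    stop("animal/replicate length must match the number of spectra")
  }
  dimnames(absorbance) <- list(NULL, format_wavelength(wavelengths))
  out <- list(instrument = instrument,
              wavelengths = wavelengths,
              absorbance = absorbance,
              meta = data.frame(animal = as.character(animal),
                                replicate = as.integer(replicate),
                                stringsAsFactors = FALSE),
              qc = data.frame(distance = rep(NA_real_, nrow(absorbance)),
                              flag = rep(FALSE, nrow(absorbance))))
  class(out) <- "spectra_set"
  out
}

format_wavelength <- function(w) {
  ifelse(w == round(w), format(round(w), trim = TRUE, scientific = FALSE),
         format(w, trim = TRUE, scientific = FALSE))
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> instrument:", x$instrument,
      "|", nrow(x$absorbance), "spectra x", length(x$wavelengths), "wavelengths",
      sprintf("(%.0f-%.0f nm)", min(x$wavelengths), max(x$wavelengths)), "\n")
  cat("  animals:", length(unique(x$meta$animal)),
      "| flagged:", sum(x$qc$flag), "\n")
  invisible(x)
}

#' Flag outlier spectra by standardized Mahalanobis (GH) distance
#'
#' The Mahalanobis distance of each spectrum from the centroid is computed in
#' a principal-component subspace retaining 99% of the variance, capped at
#' `max_components` (the raw wavelength covariance is singular whenever
#' wavelengths outnumber spectra). The standardized distance `GH = D^2 / k`,
#' with `k` the number of retained components, is compared against
#' `threshold`; spectra with `GH > threshold` are flagged and excluded by all
#' downstream steps.
#'
#' @param spectra a `spectra_set` with at least 10 spectra.
#' @param threshold positive GH cutoff; conventional chemometric default 3.
#' @param variance_kept cumulative variance retained by the PCA subspace.
#' @param max_components cap on retained components.
#' @return the `spectra_set` with `qc$distance` and `qc$flag` filled in.
#' @export
flag_outliers_mahalanobis <- function(spectra, threshold = 3,
                                      variance_kept = 0.99, max_components = 20) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (threshold <= 0) stop("threshold must be > 0")
  X <- spectra$absorbance
  n <- nrow(X)
  if (n < 10) stop("need at least 10 spectra for outlier screening, got ", n)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(X), max_components))
  ev <- sv$d^2 / (n - 1)
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_kept)[1]
  if (is.na(k)) k <- length(ev)
  k_req <- k
  k <- min(k, max_components, n - 1L, ncol(X))
  if (k < k_req) {
    message("mahalanobis screening: retaining ", k, " components (",
            k_req, " needed for ", round(100 * variance_kept), "% variance)")
  }
  scores <- Xc %*% sv$v[, seq_len(k), drop = FALSE]
  d2 <- rowSums(sweep(scores^2, 2, pmax(ev[seq_len(k)], 1e-30), "/"))
  gh <- d2 / k
  spectra$qc$distance <- gh
  spectra$qc$flag <- is.finite(threshold) & gh > threshold
  attr(spectra$qc, "components") <- k
  spectra
}

#' Average unflagged replicate spectra to one spectrum per animal
#'
#' Arithmetic mean over the replicates that survived QC; animals whose
#' replicates were all flagged are dropped (a message records how many).
#'
#' @param spectra a `spectra_set` (typically after
#'   [flag_outliers_mahalanobis()]).
#' @return a `spectra_set` with one row per retained animal (`replicate = 1`).
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  keep <- !spectra$qc$flag
  animals <- unique(spectra$meta$animal)
  ok_anim <- unique(spectra$meta$animal[keep])
  dropped <- setdiff(animals, ok_anim)
  if (length(dropped)) {
    message(length(dropped), " animal(s) dropped: no unflagged replicate")
  }
  f <- factor(spectra$meta$animal[keep], levels = ok_anim)
  M <- rowsum(spectra$absorbance[keep, , drop = FALSE], f) /
    as.vector(table(f))
  out <- spectra_set(spectra$instrument, spectra$wavelengths, M,
                     animal = ok_anim, replicate = rep(1L, length(ok_anim)))
  attr(out, "dropped_animals") <- dropped
  out
}

#' Learn and apply per-wavelength centring/standardization
#'
#' `fit_standardization` learns per-wavelength means and standard deviations
#' from a training set; wavelengths with (numerically) zero variance are
#' recorded and dropped from the covariate set. `apply_standardization`
#' transforms any spectra set with the training parameters only, so held-out
#' data never leak into the scaling.
#'
#' @param training a `spectra_set` or numeric matrix with named columns.
#' @return `fit_standardization`: object of class `standardization_params`
#'   with `mean`, `sd`, `keep` (retained column names) and `dropped`.
#' @export
fit_standardization <- function(training) {
  X <- if (inherits(training, "spectra_set")) training$absorbance else as.matrix(training)
  if (nrow(X) == 0) stop("training set is empty")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  keep <- s > 1e-12
  if (!any(keep)) stop("all wavelength columns have zero variance")
  out <- list(mean = m[keep], sd = s[keep],
              keep = colnames(X)[keep], dropped = colnames(X)[!keep])
  class(out) <- "standardization_params"
  out
}

#' @rdname fit_standardization
#' @param params a `standardization_params`.
#' @param spectra a `spectra_set` or matrix to transform.
#' @return `apply_standardization`: numeric covariate matrix (rows = spectra,
#'   columns = retained wavelengths) with attribute `animal` when the input
#'   was a `spectra_set`.
#' @export
apply_standardization <- function(params, spectra) {
  stopifnot(inherits(params, "standardization_params"))
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  missing_cols <- setdiff(params$keep, colnames(X))
  if (length(missing_cols)) {
    stop("spectra lack wavelength column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  Z <- sweep(sweep(X[, params$keep, drop = FALSE], 2, params$mean), 2, params$sd, "/")
  if (inherits(spectra, "spectra_set")) attr(Z, "animal") <- spectra$meta$animal
  Z
}

#' Read / write spectra as a wide CSV
#'
#' Columns `animal_id, instrument, replicate` followed by one column per
#' wavelength named by its nm value. Values are written with 17 significant
#' digits so that write/read round-trips are bit-exact.
#'
#' @param spectra a `spectra_set`.
#' @param path file path.
#' @export
write_spectra <- function(spectra, path) {
  hdr <- c("animal_id", "instrument", "replicate",
           format_wavelength(spectra$wavelengths))
  body <- apply(spectra$absorbance, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  lines <- paste(spectra$meta$animal, spectra$instrument,
                 spectra$meta$replicate, body, sep = ",")
  writeLines(c(paste(hdr, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  wcols <- setdiff(colnames(x), c("animal_id", "instrument", "replicate"))
  spectra_set(instrument = x$instrument[1],
              wavelengths = as.numeric(wcols),
              absorbance = as.matrix(x[, wcols, drop = FALSE]),
              animal = x$animal_id, replicate = x$replicate)
}

#' Write the QC report (spectrum id, GH distance, flag) as CSV
#'
#' @param spectra a `spectra_set` after outlier screening.
#' @param path file path.
#' @export
write_qc_report <- function(spectra, path) {
  df <- data.frame(animal = spectra$meta$animal,
                   replicate = spectra$meta$replicate,
                   gh_distance = spectra$qc$distance,
                   flagged = spectra$qc$flag)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
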