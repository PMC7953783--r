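#' Bayes B chemometric calibration
#'
#' Regression of a trait on standardized spectral covariates under the Bayes B
#' mixture prior: each wavelength effect is exactly zero with probability
#' `pi`, otherwise drawn from a normal whose variance has a scaled inverse
#' chi-square prior (marginally a scaled-t effect). Fitting is by Gibbs
#' sampling; prediction uses posterior-mean effects. External validation is
#' leave-one-batch-out: all animals slaughtered on the same day are held out
#' together and predicted from a model (including the standardization) fitted
#' without them.
#'
#' @name calibration
NULL

#' Chain and prior settings for the Bayes B sampler
#'
#' Prior scales follow the usual expected-proportion-of-variance rule: with
#' `R2` the prior proportion of variance attributed to the spectra, the
#' effect-variance scale is `var(y) * R2 * (df_beta + 2) / (MSx * (1 - pi))`
#' with `MSx` the summed covariate variances, and the residual scale is
#' `var(y) * (1 - R2) * (df_e + 2)`.
#'
#' @param niter,burnin,thin Gibbs chain length, burn-in and thinning.
#' @param pi prior probability that a wavelength effect is exactly zero.
#' @param df_beta,df_e prior degrees of freedom for effect and residual
#'   variances.
#' @param R2 prior proportion of variance explained, used to set the scales.
#' @param seed integer seed fixing the chain.
#' @return list of class `bayesb_settings`.
#' @export
bayesb_settings <- function(niter = 12000, burnin = 2000, thin = 5,
                            pi = 0.95, df_beta = 5, df_e = 5, R2 = 0.5,
                            seed = 1L) {
  stopifnot(niter > burnin, thin >= 1, pi >= 0, pi < 1, R2 > 0, R2 < 1)
  out <- list(niter = as.integer(niter), burnin = as.integer(burnin),
              thin = as.integer(thin), pi = pi, df_beta = df_beta,
              df_e = df_e, R2 = R2, seed = as.integer(seed))
  class(out) <- "bayesb_settings"
  out
}

#' Fit a Bayes B regression
#'
#' @param X standardized covariate matrix (animals x wavelengths, named
#'   columns).
#' @param y trait vector, one value per row of `X`.
#' @param settings a [bayesb_settings()] object.
#' @return object of class `bayesb_model` with posterior-mean `intercept`,
#'   `effects` (posterior mean of `delta * beta` per wavelength),
#'   `inclusion_prob`, `sigma2e` and the settings used.
#' @export
fit_bayesb <- function(X, y, settings = bayesb_settings()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (anyNA(y) || any(!is.finite(y))) {
    stop("non-finite response at row(s): ",
         paste(utils::head(which(!is.finite(y)), 5), collapse = ", "))
  }
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite covariate at row ", bad[1, 1], ", column ",
         colnames(X)[bad[1, 2]])
  }
  vy <- stats::var(y)
  msx <- sum(apply(X, 2, stats::var)) * (nrow(X) - 1) / nrow(X)
  if (msx <= 0) msx <- 1
  S_b <- vy * settings$R2 * (settings$df_beta + 2) / (msx * (1 - settings$pi))
  S_e <- vy * (1 - settings$R2) * (settings$df_e + 2)
  set.seed(settings$seed)
  fit <- bayesb_gibbs_cpp(X, y, settings$niter, settings$burnin, settings$thin,
                          settings$pi, settings$df_beta, S_b,
                          settings$df_e, S_e)
  out <- list(intercept = fit$mu,
              effects = stats::setNames(fit$beta, colnames(X)),
              inclusion_prob = stats::setNames(fit$inclusion_prob, colnames(X)),
              pi = settings$pi,
              sigma2e = fit$sigma2e,
              n_samples = fit$n_samples,
              columns = colnames(X),
              settings = settings)
  class(out) <- "bayesb_model"
  out
}

#' @export
print.bayesb_model <- function(x, ...) {
  cat("<bayesb_model>", length(x$effects), "covariates | pi =", x$pi,
      "| mean inclusion", sprintf("%.3f", mean(x$inclusion_prob)),
      "| sigma2e", sprintf("%.4g", x$sigma2e), "\n")
  invisible(x)
}

#' Predict from a fitted Bayes B model
#'
#' `X_new` must be standardized with the model's training-set parameters and
#' carry the same wavelength columns (any order).
#'
#' @param object a `bayesb_model`.
#' @param X_new covariate matrix.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.bayesb_model <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  missing_cols <- setdiff(object$columns, colnames(X_new))
  extra <- setdiff(colnames(X_new), object$columns)
  if (length(missing_cols) || length(extra)) {
    stop("covariate mismatch; missing: ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         "; extra: ", paste(utils::head(extra, 5), collapse = ", "))
  }
  drop(object$intercept + X_new[, object$columns, drop = FALSE] %*% object$effects)
}

#' Leave-one-batch-out external validation
#'
#' For each slaughter batch, the per-wavelength standardization and the Bayes
#' B model are refitted on all animals outside the batch, and the batch is
#' predicted; predictions are accumulated over batches and the external R^2
#' is the squared Pearson correlation between accumulated predictions and
#' measurements. Each animal's prediction therefore comes from a model whose
#' training data exclude the animal's entire batch.
#'
#' @param spectra per-animal spectra: a `spectra_set` with one row per animal
#'   (see [average_replicates()]) or a raw absorbance matrix.
#' @param y measured trait values, one per animal.
#' @param batch batch labels, one per animal.
#' @param settings a [bayesb_settings()]; fold seeds are derived from
#'   `settings$seed`.
#' @return object of class `validation_result`: `predictions` (data.frame
#'   animal, batch, measured, predicted), `r2_ext`, `batch_sizes`.
#' @export
leave_one_batch_out <- function(spectra, y, batch, settings = bayesb_settings()) {
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  animal <- if (inherits(spectra, "spectra_set")) spectra$meta$animal else rownames(X)
  if (is.null(animal)) animal <- as.character(seq_len(nrow(X)))
  if (nrow(X) != length(y) || length(batch) != length(y)) {
    stop("spectra, y and batch must describe the same animals")
  }
  batch <- as.character(batch)
  ub <- unique(batch)
  if (length(ub) < 2) stop("external validation needs at least 2 batches")
  pred <- rep(NA_real_, length(y))
  for (b in seq_along(ub)) {
    test <- batch == ub[b]
    fold_settings <- settings
    fold_settings$seed <- settings$seed + b
    params <- fit_standardization(X[!test, , drop = FALSE])
    Xtr <- apply_standardization(params, X[!test, , drop = FALSE])
    Xte <- apply_standardization(params, X[test, , drop = FALSE])
    fit <- fit_bayesb(Xtr, y[!test], fold_settings)
    pred[test] <- predict(fit, Xte)
  }
  r2 <- if (stats::sd(pred) < 1e-12 || stats::sd(y) < 1e-12) 0
        else stats::cor(pred, y)^2
  out <- list(predictions = data.frame(animal = animal, batch = batch,
                                       measured = y, predicted = pred,
                                       stringsAsFactors = FALSE),
              r2_ext = r2,
              batch_sizes = table(batch))
  class(out) <- "validation_result"
  out
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>", nrow(x$predictions), "animals |",
      length(x$batch_sizes), "batches | R2_ext =", sprintf("%.3f", x$r2_ext), "\n")
  invisible(x)
}
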