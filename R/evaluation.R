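#' Derived comparisons and the reference-table verifier
#'
#' Tools for comparing measured traits with their spectral predictions at the
#' population level: proportional variance decreases, the regression of
#' external-validation R^2 on those decreases, correlation averages, and the
#' relative efficiency of indirect selection. The bundled reference tables
#' (descriptive statistics, variance components and measured-predicted
#' correlations from the source study) feed a verifier that recomputes every
#' aggregate these tables imply and checks it against the corresponding
#' printed summary value.
#'
#' @name evaluation
NULL

#' Load the bundled reference tables
#'
#' @return list of data.frames: `descriptives` (means, SDs and external R^2
#'   per trait and instrument), `variance_components` (phenotypic variance,
#'   component ratios, heritabilities), `correlations` (r_a, r_e with SEs).
#' @export
reference_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", "reference_tables", f, package = "nirherit",
                mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE)
  list(descriptives = rd("descriptives.csv"),
       variance_components = rd("variance_components.csv"),
       correlations = rd("correlations.csv"))
}

#' Proportional variance decrease of predictions
#'
#' `1 - var_predicted / var_measured`: the fraction of (phenotypic or
#' additive-genetic) variance lost when a trait is replaced by its spectral
#' prediction. Negative values mean the prediction is more variable.
#'
#' @param var_measured variance of the measured trait (> 0).
#' @param var_predicted variance of the prediction.
#' @return unitless fraction (<= 1).
#' @export
variance_decrease <- function(var_measured, var_predicted) {
  if (any(var_measured <= 0)) stop("var_measured must be > 0")
  1 - var_predicted / var_measured
}

#' R-squared of an ordinary least-squares line
#'
#' The squared Pearson correlation of x and y. A constant y is defined as
#' R^2 = 0 (flagged via attribute `degenerate`); a constant x is an error.
#'
#' @param x,y numeric vectors of equal length (>= 3 points).
#' @return scalar between 0 and 1.
#' @export
regression_r2 <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("need >= 3 paired points")
  }
  if (stats::sd(x) < 1e-12) stop("x is constant; regression undefined")
  if (stats::sd(y) < 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(x, y)^2
}

#' Mean genetic and residual correlations across traits
#'
#' @param correlations data.frame with columns `instrument`, `r_a`, `r_e`
#'   (as in [reference_tables()]`$correlations`), complete over traits.
#' @return data.frame of mean `r_a` and `r_e` per instrument plus an
#'   `overall` row.
#' @export
summarize_correlations <- function(correlations) {
  stopifnot(all(c("instrument", "r_a", "r_e") %in% colnames(correlations)))
  per <- do.call(rbind, lapply(split(correlations, correlations$instrument),
    function(d) data.frame(instrument = d$instrument[1],
                           mean_r_a = mean(d$r_a), mean_r_e = mean(d$r_e))))
  rownames(per) <- NULL
  rbind(per, data.frame(instrument = "overall",
                        mean_r_a = mean(correlations$r_a),
                        mean_r_e = mean(correlations$r_e)))
}

#' Relative efficiency of indirect selection
#'
#' Correlated response in the target trait from selecting on the indicator,
#' relative to direct selection at equal intensity:
#' `CR/R = r_a * h_indicator / h_target` (square roots of the
#' heritabilities).
#'
#' @param r_a genetic correlation between indicator and target.
#' @param h2_indicator,h2_target heritabilities in (0, 1].
#' @return unitless relative efficiency.
#' @export
selection_efficiency <- function(r_a, h2_indicator, h2_target) {
  if (any(h2_indicator <= 0 | h2_indicator > 1) ||
      any(h2_target <= 0 | h2_target > 1)) {
    stop("heritabilities must lie in (0, 1]")
  }
  r_a * sqrt(h2_indicator) / sqrt(h2_target)
}

#' Recompute and check every printed aggregate of the reference tables
#'
#' From the bundled tables the verifier recomputes: the OLS R^2 of external
#' R^2 on the proportional phenotypic-variance decrease across the nine
#' traits (per instrument); the mean proportional phenotypic-variance
#' decrease per instrument; the mean proportional additive-variance decrease
#' across traits and instruments; the mean SD reduction per instrument and
#' its maximum among the water-loss/tenderness traits (PL, CL, WBSF); the
#' mean genetic correlation across traits and instruments; and the intra-herd
#' heritability worked examples for L* and WBSF. Each value is compared with
#' the corresponding printed summary within a rounding tolerance (0.015
#' absolute on correlations and R^2, 1.5 percentage points on percentage
#' aggregates, half a printed unit on heritabilities).
#'
#' @param tables list from [reference_tables()] (or a modified copy).
#' @return data.frame ledger: check, computed, printed, tolerance, pass.
#' @export
verify_printed_aggregates <- function(tables = reference_tables()) {
  if (is.null(tables$descriptives) || nrow(tables$descriptives) == 0 ||
      is.null(tables$variance_components) || nrow(tables$variance_components) == 0 ||
      is.null(tables$correlations) || nrow(tables$correlations) == 0) {
    stop("reference tables are empty")
  }
  d <- tables$descriptives
  vc <- tables$variance_components
  co <- tables$correlations
  wide <- function(ins) vc[vc$instrument == ins, ][match(d$trait, vc$trait[vc$instrument == ins]), ]
  lab <- wide("lab"); vis <- wide("vis"); mic <- wide("micro")
  dvp_vis <- variance_decrease(lab$phen_var, vis$phen_var)
  dvp_mic <- variance_decrease(lab$phen_var, mic$phen_var)
  va <- function(w) w$f_additive * w$phen_var
  dva <- c(variance_decrease(va(lab), va(vis)), variance_decrease(va(lab), va(mic)))
  sdr_vis <- 1 - d$sd_vis / d$sd_lab
  sdr_mic <- 1 - d$sd_micro / d$sd_lab
  wet <- d$trait %in% c("PL", "CL", "WBSF")
  h2_L <- intraherd_heritability(lab$f_additive[d$trait == "L"],
                                 lab$f_residual[d$trait == "L"])$h2
  h2_W <- intraherd_heritability(lab$f_additive[d$trait == "WBSF"],
                                 lab$f_residual[d$trait == "WBSF"])$h2
  checks <- list(
    list("ols_r2_external_on_phenotypic_loss_vis",
         regression_r2(dvp_vis, d$r2ext_vis), 0.96, 0.015),
    list("ols_r2_external_on_phenotypic_loss_micro",
         regression_r2(dvp_mic, d$r2ext_micro), 0.98, 0.015),
    list("mean_phenotypic_variance_decrease_vis_pct",
         100 * mean(dvp_vis), 50, 1.5),
    list("mean_phenotypic_variance_decrease_micro_pct",
         100 * mean(dvp_mic), 60, 1.5),
    list("mean_additive_variance_decrease_pct",
         100 * mean(dva), 70, 1.5),
    list("mean_sd_reduction_vis_pct", 100 * mean(sdr_vis), 30, 1.5),
    list("mean_sd_reduction_micro_pct", 100 * mean(sdr_mic), 40, 1.5),
    list("max_sd_reduction_water_tenderness_pct",
         100 * max(sdr_vis[wet], sdr_mic[wet]), 78, 1.5),
    list("mean_genetic_correlation", mean(co$r_a), 0.81, 0.015),
    list("intraherd_h2_lab_lightness", h2_L, 0.30, 0.015),
    list("intraherd_h2_lab_shear_force", h2_W, 0.31, 0.015))
  out <- do.call(rbind, lapply(checks, function(ck) {
    data.frame(check = ck[[1]], computed = as.numeric(ck[[2]]),
               printed = ck[[3]], tolerance = ck[[4]],
               pass = abs(as.numeric(ck[[2]]) - ck[[3]]) <= ck[[4]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
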