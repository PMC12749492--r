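# Moles of trace gas in a headspace at a given mixing ratio (nmol).
headspace_nmol <- function(c_ppmv, volume_l, temperature_K, pressure_atm) {
  p_pa <- pressure_atm * foreland_constants$atm_Pa
  v_m3 <- volume_l / 1000
  n_total <- p_pa * v_m3 / (foreland_constants$R_J_per_mol_K * temperature_K)
  c_ppmv * 1e-6 * n_total * 1e9
}

# Log-linear and asymptotic first-order fits to a concentration series;
# returns per-model k, fitted values, AIC.
first_order_models <- function(times, conc, aicc = FALSE) {
  aic_fun <- if (aicc) gaussian_aicc else gaussian_aic
  out <- list()
  if (all(conc > 0)) {
    f <- stats::lm(log(conc) ~ times)
    k <- -unname(stats::coef(f)[2])
    fitted_c <- exp(stats::fitted(f))
    # suppress the "essentially perfect fit" notice: noiseless series are a
    # legitimate input here and their SE is genuinely ~0
    sm <- suppressWarnings(summary(f))
    out$first_order <- list(
      k = k, c0 = exp(unname(stats::coef(f)[1])), c_inf = 0,
      k_se = sm$coefficients[2, 2],
      residuals = conc - fitted_c, aic = aic_fun(conc - fitted_c, k = 3),
      r2 = sm$r.squared
    )
  }
  start <- list(c_inf = max(min(conc) * 0.5, 1e-9), c0 = max(conc),
                k = if (!is.null(out$first_order)) max(out$first_order$k, 1e-3) else 0.1)
  nl <- try(minpack.lm::nlsLM(
    conc ~ c_inf + (c0 - c_inf) * exp(-k * times),
    start = start, lower = c(c_inf = 0, c0 = 0, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (!inherits(nl, "try-error")) {
    co <- stats::coef(nl)
    res <- stats::residuals(nl)
    se <- tryCatch(summary(nl)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
    out$first_order_asymptote <- list(
      k = unname(co["k"]), c0 = unname(co["c0"]), c_inf = unname(co["c_inf"]),
      k_se = se, residuals = res, aic = aic_fun(res, k = 4),
      r2 = 1 - sum(res^2) / sum((conc - mean(conc))^2)
    )
  }
  if (!length(out)) stop("no first-order model could be fitted")
  out
}

#' Fit first-order trace-gas oxidation kinetics
#'
#' Fits both a simple first-order decay c(t) = c0 exp(-k t) (ordinary least
#' squares on log concentration) and an asymptotic variant
#' c(t) = c_inf + (c0 - c_inf) exp(-k t) (bounded nonlinear least squares,
#' c_inf >= 0), selecting between them by AIC. When a heat-killed control
#' series is supplied, the biotic rate constant is k_live - k_control,
#' floored at zero. The oxidation rate at the gas's atmospheric mixing ratio
#' is k_net times the headspace gas amount at that mixing ratio (ideal gas),
#' per gram of dry soil.
#'
#' @param times Sampling times (hours), strictly increasing, at least 4.
#' @param conc Headspace mixing ratios (ppmv).
#' @param control Optional list with elements `times`, `conc` for the
#'   heat-killed control series.
#' @param headspace_volume_l Headspace volume (litres).
#' @param soil_dry_g Soil dry mass (g). If only wet mass and a gravimetric
#'   moisture fraction are known, supply `soil_wet_g` and `moisture_fraction`
#'   instead.
#' @param soil_wet_g,moisture_fraction Alternative mass specification; dry
#'   mass = wet x (1 - moisture). If moisture is missing, wet mass is used
#'   with a warning.
#' @param c_atm_ppmv Atmospheric mixing ratio at which to express the rate.
#' @param temperature_K,pressure_atm Incubation conditions.
#' @param aicc Use small-sample corrected AIC.
#' @return Object of class `rate_fit`: `k_per_h`, `k_se`, `c_inf_ppmv`,
#'   `model`, `aic`, `r2`, `k_net_per_h`, `net_of_control`, `floored`,
#'   `rate_atm_nmol_per_gdw_h`.
#' @export
fit_first_order <- function(times, conc, control = NULL,
                            headspace_volume_l = 0.12, soil_dry_g = NULL,
                            soil_wet_g = NULL, moisture_fraction = NULL,
                            c_atm_ppmv = NULL,
                            temperature_K = 298.15, pressure_atm = 1,
                            aicc = FALSE) {
  if (length(times) < 4) stop("need at least 4 time points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("mixing ratios must be non-negative")
  if (is.null(soil_dry_g)) {
    if (is.null(soil_wet_g)) stop("supply soil_dry_g or soil_wet_g")
    if (is.null(moisture_fraction)) {
      warning("no moisture fraction supplied; using wet mass as dry mass")
      soil_dry_g <- soil_wet_g
    } else {
      soil_dry_g <- soil_wet_g * (1 - moisture_fraction)
    }
  }
  models <- first_order_models(times, conc, aicc)
  aics <- vapply(models, `[[`, numeric(1), "aic")
  sel <- names(which.min(aics))
  best <- models[[sel]]

  k_control <- 0
  if (!is.null(control)) {
    cm <- first_order_models(control$times, control$conc, aicc)
    csel <- names(which.min(vapply(cm, `[[`, numeric(1), "aic")))
    k_control <- cm[[csel]]$k
  }
  k_net <- best$k - k_control
  floored <- k_net < 0
  k_net <- max(k_net, 0)

  rate_atm <- NA_real_
  if (!is.null(c_atm_ppmv)) {
    n_atm <- headspace_nmol(c_atm_ppmv, headspace_volume_l, temperature_K,
                            pressure_atm)
    rate_atm <- k_net * n_atm / soil_dry_g
  }
  structure(list(k_per_h = best$k, k_se = best$k_se, c_inf_ppmv = best$c_inf,
                 model = sel, aic = unname(aics[sel]), r2 = best$r2,
                 k_net_per_h = k_net, net_of_control = !is.null(control),
                 floored = floored,
                 rate_atm_nmol_per_gdw_h = rate_atm,
                 soil_dry_g = soil_dry_g),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("first-order fit (%s): k = %.4g /h (se %.2g), r2 = %.3f\n",
              x$model, x$k_per_h, x$k_se, x$r2))
  if (x$net_of_control) {
    cat(sprintf("  net of heat-killed control: k_net = %.4g /h%s\n",
                x$k_net_per_h, if (x$floored) " (floored at 0)" else ""))
  }
  if (!is.na(x$rate_atm_nmol_per_gdw_h)) {
    cat(sprintf("  rate at atmospheric mixing ratio: %.4g nmol g_dw-1 h-1\n",
                x$rate_atm_nmol_per_gdw_h))
  }
  invisible(x)
}

#' Static-chamber soil-atmosphere gas flux
#'
#' Fits a linear model and a saturating exponential
#' c(t) = c_inf + (c0 - c_inf) exp(-lambda t) to the chamber headspace
#' series, selects by AIC, and converts the initial slope (at t = 0) to a
#' flux using the ideal-gas molar volume and the chamber's effective height
#' (volume / footprint area). Negative flux means uptake by the soil.
#'
#' @param times_min Sampling times (minutes), at least 5 points.
#' @param conc Mixing ratios (ppmv).
#' @param height_m Chamber effective height (m).
#' @param temperature_K,pressure_atm Field conditions.
#' @param aicc Use small-sample corrected AIC.
#' @return Object of class `flux_fit`: `flux_nmol_m2_s`,
#'   `initial_slope_ppmv_min`, `model`, `aic`, `r2`.
#' @export
fit_chamber_flux <- function(times_min, conc, height_m,
                             temperature_K = 298.15, pressure_atm = 1,
                             aicc = FALSE) {
  if (length(times_min) < 5) stop("need at least 5 chamber points")
  if (is.unsorted(times_min)) stop("times must be increasing")
  if (height_m <= 0) stop("chamber height must be positive")
  aic_fun <- if (aicc) gaussian_aicc else gaussian_aic
  lin <- stats::lm(conc ~ times_min)
  models <- list(linear = list(
    slope0 = unname(stats::coef(lin)[2]),
    aic = aic_fun(stats::residuals(lin), k = 3),
    r2 = suppressWarnings(summary(lin))$r.squared
  ))
  nl <- try(minpack.lm::nlsLM(
    conc ~ c_inf + (c0 - c_inf) * exp(-lambda * times_min),
    start = list(c_inf = conc[length(conc)], c0 = conc[1], lambda = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (!inherits(nl, "try-error") && stats::coef(nl)[["lambda"]] > 0) {
    co <- stats::coef(nl)
    res <- stats::residuals(nl)
    models$exponential <- list(
      slope0 = -co[["lambda"]] * (co[["c0"]] - co[["c_inf"]]),
      aic = aic_fun(res, k = 4),
      r2 = 1 - sum(res^2) / sum((conc - mean(conc))^2)
    )
  }
  aics <- vapply(models, `[[`, numeric(1), "aic")
  sel <- names(which.min(aics))
  slope0 <- models[[sel]]$slope0 # ppmv per minute
  mol_per_m3 <- pressure_atm * foreland_constants$atm_Pa /
    (foreland_constants$R_J_per_mol_K * temperature_K)
  flux <- (slope0 / 60) * 1e-6 * mol_per_m3 * height_m * 1e9
  structure(list(flux_nmol_m2_s = flux, initial_slope_ppmv_min = slope0,
                 model = sel, aic = unname(aics[sel]), r2 = models[[sel]]$r2),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("chamber flux (%s model): %.4g nmol m-2 s-1 (%s)\n",
              x$model, x$flux_nmol_m2_s,
              if (x$flux_nmol_m2_s < 0) "uptake" else "emission"))
  invisible(x)
}

#' Nutrient transformation rate with AIC model selection
#'
#' Fits linear (c = a + b t) and exponential (c = a exp(b t)) models to a
#' nutrient concentration time series and reports the initial rate (slope at
#' t = 0) of the AIC-selected model. Positive rates indicate accumulation,
#' negative rates uptake.
#'
#' @param times_days Sampling times (days), at least 4.
#' @param conc Concentrations (micromolar), non-negative.
#' @param aicc Use small-sample corrected AIC.
#' @return Object of class `nutrient_fit`: `rate_uM_day` (signed initial
#'   slope), `model`, `aic_linear`, `aic_exponential`, `delta_aic`,
#'   `indistinguishable` (delta AIC < 2).
#' @export
fit_nutrient_rate <- function(times_days, conc, aicc = FALSE) {
  if (length(times_days) < 4) stop("need at least 4 points")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  aic_fun <- if (aicc) gaussian_aicc else gaussian_aic
  lin <- stats::lm(conc ~ times_days)
  if (!all(is.finite(stats::coef(lin)))) stop("singular linear fit")
  out <- list(linear = list(
    rate = unname(stats::coef(lin)[2]),
    aic = aic_fun(stats::residuals(lin), k = 3)
  ))
  loglm <- NULL
  b0 <- -0.1
  if (all(conc > 0)) {
    loglm <- stats::lm(log(conc) ~ times_days)
    b0 <- unname(stats::coef(loglm)[2])
  }
  nl <- try(minpack.lm::nlsLM(conc ~ a * exp(b * times_days),
                              start = list(a = max(conc[1], 1e-6), b = b0),
                              control = minpack.lm::nls.lm.control(maxiter = 200)),
            silent = TRUE)
  if (!inherits(nl, "try-error")) {
    co <- stats::coef(nl)
    out$exponential <- list(
      rate = co[["a"]] * co[["b"]],
      aic = aic_fun(stats::residuals(nl), k = 3)
    )
  } else if (!is.null(loglm)) {
    # degenerate series (e.g. exactly constant) make the least-squares
    # gradient singular; the log-scale OLS fit is the exponential candidate
    a <- exp(unname(stats::coef(loglm)[1]))
    res <- conc - a * exp(b0 * times_days)
    out$exponential <- list(rate = a * b0, aic = aic_fun(res, k = 3))
  }
  aics <- vapply(out, `[[`, numeric(1), "aic")
  sel <- names(which.min(aics))
  delta <- if (length(aics) == 2) abs(diff(unname(aics))) else NA_real_
  structure(list(rate_uM_day = out[[sel]]$rate, model = sel,
                 aic_linear = unname(aics["linear"]),
                 aic_exponential = unname(aics["exponential"]),
                 delta_aic = delta,
                 indistinguishable = isTRUE(delta < 2)),
            class = "nutrient_fit")
}

#' @export
print.nutrient_fit <- function(x, ...) {
  cat(sprintf("nutrient rate (%s model): %+.4g uM day-1 (%s)%s\n",
              x$model, x$rate_uM_day,
              if (x$rate_uM_day >= 0) "accumulation" else "uptake",
              if (isTRUE(x$indistinguishable)) " [models indistinguishable, dAIC < 2]" else ""))
  invisible(x)
}

#' Absolute quantification from qPCR standard curves
#'
#' Builds the standard curve by ordinary least squares of mean Cp on log10
#' copy number, then inverts it for the unknowns:
#' copies = 10^((Cp - intercept) / slope), scaled by extraction/dilution
#' factors and divided by soil dry mass. Amplification efficiency is
#' (10^(-1/slope) - 1) x 100.
#'
#' @param standards data.frame with columns `copies` and `cp` (replicates
#'   allowed; averaged per dilution). Must span at least 3 decades with at
#'   least 4 dilutions.
#' @param unknowns data.frame with columns `sample` and `cp` (replicate rows
#'   averaged per sample).
#' @param soil_dry_g Dry soil mass per extraction (g); scalar or per sample.
#' @param scale_factor Combined elution/dilution factor applied to copies.
#' @return Object of class `qpcr_result`: `curve` (slope, intercept, r2,
#'   efficiency_pct) and `quant` data.frame (sample, cp, copies,
#'   copies_per_gdw, extrapolated).
#' @export
quantify_qpcr <- function(standards, unknowns, soil_dry_g = 1,
                          scale_factor = 1) {
  if (any(standards$copies <= 0)) stop("standard copies must be positive")
  agg <- stats::aggregate(cp ~ copies, data = standards, FUN = mean)
  if (nrow(agg) < 4) stop("need at least 4 standard dilutions")
  span <- log10(max(agg$copies) / min(agg$copies))
  if (span < 3) stop("standards must span at least 3 decades")
  fit <- stats::lm(cp ~ log10(copies), data = agg)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop("invalid standard curve: slope must be negative")
  curve <- list(slope = slope, intercept = intercept,
                r2 = summary(fit)$r.squared,
                efficiency_pct = (10^(-1 / slope) - 1) * 100)
  uq <- stats::aggregate(cp ~ sample, data = unknowns, FUN = mean)
  copies <- 10^((uq$cp - intercept) / slope) * scale_factor
  cp_range <- range(agg$cp)
  quant <- data.frame(
    sample = uq$sample, cp = uq$cp, copies = copies,
    copies_per_gdw = copies / soil_dry_g,
    extrapolated = uq$cp < cp_range[1] | uq$cp > cp_range[2],
    stringsAsFactors = FALSE
  )
  structure(list(curve = curve, quant = quant), class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, intercept %.2f, r2 %.4f, efficiency %.1f%%\n",
              x$curve$slope, x$curve$intercept, x$curve$r2,
              x$curve$efficiency_pct))
  print(x$quant, row.names = FALSE)
  invisible(x)
}
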