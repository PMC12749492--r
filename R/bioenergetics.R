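#' Trace-gas oxidation reaction registry
#'
#' Balanced aerobic oxidation reactions for the three atmospheric trace gases
#' with their standard Gibbs energies at 298.15 K (from standard formation
#' energies; water as liquid) and default gas-phase conditions. Stoichiometry
#' is stored as named coefficients, negative for reactants and positive for
#' products; gas-phase activities are partial pressures relative to
#' p0 = 1 atm, liquid water has activity 1.
#'
#' \itemize{
#'   \item h2:  H2 + 1/2 O2 -> H2O(l),        dG0 = -237.14 kJ/mol
#'   \item co:  CO + 1/2 O2 -> CO2,           dG0 = -257.22 kJ/mol
#'   \item ch4: CH4 + 2 O2 -> CO2 + 2 H2O(l), dG0 = -817.95 kJ/mol
#' }
#'
#' @param name One of "h2", "co", "ch4".
#' @return List of class `gas_species`: `name`, `stoichiometry` (named,
#'   gas-phase species only), `dG0_kJ_mol`, `c_atm_ppmv` (microcosm
#'   atmospheric mixing ratio), `default_conditions` (named partial
#'   pressures, atm).
#' @export
gas_species <- function(name = c("h2", "co", "ch4")) {
  name <- match.arg(name)
  reg <- list(
    h2 = list(
      stoichiometry = c(h2 = -1, o2 = -0.5),
      dG0_kJ_mol = -237.14, c_atm_ppmv = 0.5
    ),
    co = list(
      stoichiometry = c(co = -1, o2 = -0.5, co2 = 1),
      dG0_kJ_mol = -257.22, c_atm_ppmv = 0.6
    ),
    ch4 = list(
      stoichiometry = c(ch4 = -1, o2 = -2, co2 = 1),
      dG0_kJ_mol = -817.95, c_atm_ppmv = 1.8
    )
  )
  sp <- reg[[name]]
  cond <- c(o2 = 0.209, co2 = 420e-6)
  cond[name] <- sp$c_atm_ppmv * 1e-6
  structure(list(name = name, stoichiometry = sp$stoichiometry,
                 dG0_kJ_mol = sp$dG0_kJ_mol, c_atm_ppmv = sp$c_atm_ppmv,
                 default_conditions = cond),
            class = "gas_species")
}

#' Gibbs energy of a trace-gas oxidation under field conditions
#'
#' dG = dG0 + R T ln Q, with the reaction quotient Q built from gas-phase
#' activities (partial pressure over p0 = 1 atm) raised to their
#' stoichiometric coefficients. Liquid water is taken at activity 1 and so
#' never enters Q. dG0 is used as-is unless a reaction enthalpy is supplied,
#' in which case it is temperature-adjusted via the Gibbs-Helmholtz relation.
#'
#' @param species A `gas_species`.
#' @param conditions Named vector of partial pressures (atm) overriding the
#'   species defaults; all must be positive.
#' @param temperature_K Temperature (K).
#' @param dH0_kJ_mol Optional reaction enthalpy for temperature adjustment of
#'   dG0.
#' @return dG in kJ per mol of gas oxidised (attribute `dG0_adjusted` flags
#'   whether a temperature adjustment was applied).
#' @export
gibbs_energy <- function(species, conditions = NULL,
                         temperature_K = 298.15, dH0_kJ_mol = NULL) {
  cond <- species$default_conditions
  if (!is.null(conditions)) cond[names(conditions)] <- conditions
  st <- species$stoichiometry
  act <- cond[names(st)]
  if (any(is.na(act)) || any(act <= 0)) {
    stop("all gas-phase activities must be present and positive")
  }
  dG0 <- species$dG0_kJ_mol
  adjusted <- FALSE
  if (!is.null(dH0_kJ_mol) && temperature_K != foreland_constants$T0_K) {
    T0 <- foreland_constants$T0_K
    dG0 <- dH0_kJ_mol + (dG0 - dH0_kJ_mol) * temperature_K / T0
    adjusted <- TRUE
  }
  lnQ <- sum(st * log(act))
  dG <- dG0 + foreland_constants$R_J_per_mol_K / 1000 * temperature_K * lnQ
  attr(dG, "dG0_adjusted") <- adjusted
  dG
}

#' Power per cell from trace-gas oxidation
#'
#' Converts a bulk oxidation rate into metabolic power per putative oxidiser
#' cell: P = rate (mol per g dry weight per second) x |dG| (J/mol) divided by
#' the number of oxidiser cells per g dry weight (total cells from 16S qPCR
#' times the fraction of cells carrying the oxidation gene, capped at 1).
#' The result is classified against the empirical maintenance-power window
#' (1e-17 to 1e-12 W per cell).
#'
#' @param rate_nmol_per_gdw_h Oxidation rate at atmospheric mixing ratio.
#' @param dG_kJ_mol Gibbs energy of the oxidation under field conditions.
#' @param cells_per_gdw Total cells per g dry soil (16S rRNA gene copies).
#' @param oxidizer_fraction Fraction of cells carrying the oxidation gene
#'   (copies per organism, capped at 1).
#' @param gas,site Optional labels carried into the result.
#' @return Object of class `power_result`: `power_W_per_cell`,
#'   `n_oxidizer_cells_per_gdw`, `within_maintenance_window`,
#'   `above_window`, `below_window`, plus inputs.
#' @export
power_per_cell <- function(rate_nmol_per_gdw_h, dG_kJ_mol, cells_per_gdw,
                           oxidizer_fraction, gas = NA_character_,
                           site = NA_character_) {
  if (cells_per_gdw <= 0) stop("cells_per_gdw must be positive")
  if (oxidizer_fraction < 0 || oxidizer_fraction > 1) {
    stop("oxidizer_fraction must be in [0, 1] (cap copies-per-organism at 1)")
  }
  if (oxidizer_fraction == 0 && rate_nmol_per_gdw_h > 0) {
    stop("nonzero rate with zero oxidizer fraction: inconsistent inputs")
  }
  n_ox <- cells_per_gdw * oxidizer_fraction
  rate_mol_s <- rate_nmol_per_gdw_h * 1e-9 / 3600
  p <- if (rate_mol_s == 0) 0 else rate_mol_s * abs(dG_kJ_mol) * 1000 / n_ox
  win <- unname(foreland_constants$maintenance_W_per_cell)
  names(win) <- c("lower", "upper")
  win <- as.list(win)
  structure(list(gas = gas, site = site,
                 rate_mol_per_gdw_s = rate_mol_s, dG_kJ_mol = dG_kJ_mol,
                 n_oxidizer_cells_per_gdw = n_ox, power_W_per_cell = p,
                 within_maintenance_window = p >= win$lower & p <= win$upper,
                 above_window = p > win$upper, below_window = p < win$lower),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power per cell [%s %s]: %.3g W cell-1 (%s maintenance window 1e-17..1e-12 W)\n",
              x$gas, x$site, x$power_W_per_cell,
              if (x$within_maintenance_window) "within" else
                if (x$above_window) "above" else "below"))
  invisible(x)
}

#' Summarise power-per-cell results across gas-site combinations
#'
#' @param results List of `power_result` objects.
#' @return List: `mean_W`, `min_W`, `max_W`, `n`,
#'   `fraction_within_window`.
#' @export
summarize_power <- function(results) {
  if (!length(results)) stop("empty result list")
  p <- vapply(results, `[[`, numeric(1), "power_W_per_cell")
  w <- vapply(results, `[[`, logical(1), "within_maintenance_window")
  list(mean_W = mean(p), min_W = min(p), max_W = max(p), n = length(p),
       fraction_within_window = mean(w))
}
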