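#' Scholander-Irving heat-balance arithmetic
#'
#' Endotherms below the lower critical temperature `T_lc` of their thermal
#' neutral zone must elevate resting metabolism linearly with the body-ambient
#' temperature gradient.  The line through (`T_lc`, BMR) that extrapolates to
#' zero metabolism at the set-point body temperature `T_b` has slope
#' `-C`, the minimum thermal conductance.  These helpers implement that
#' geometry: conductance estimation, metabolic rate at the cold range
#' boundary (`MR_CRB`), metabolic expansibility (`ME_CRB = MR_CRB / BMR`),
#' and its inversion to a predicted lower thermal limit.
#'
#' All rates are in ml O2 h^-1, temperatures in degrees Celsius, and
#' conductance in ml O2 h^-1 degC^-1.  All functions are vectorised and
#' recycle arguments like base arithmetic.
#'
#' @name scholander_irving
NULL

#' Estimate minimum thermal conductance
#'
#' Conductance is the absolute slope of the line connecting basal metabolic
#' rate at the lower critical temperature to zero metabolism at body
#' temperature: `C = |(0 - BMR) / (T_b - T_lc)| = BMR / (T_b - T_lc)`.
#'
#' @param bmr Basal metabolic rate (ml O2 h^-1), strictly positive.
#' @param t_b Set-point body temperature (degC).
#' @param t_lc Lower critical temperature (degC); must be strictly below
#'   `t_b`.
#' @return Conductance in ml O2 h^-1 degC^-1, strictly positive.
#' @examples
#' estimate_conductance(bmr = 100, t_b = 37, t_lc = 27)  # 10
#' @export
estimate_conductance <- function(bmr, t_b, t_lc) {
  stopifnot(is.numeric(bmr), is.numeric(t_b), is.numeric(t_lc))
  if (any(bmr <= 0, na.rm = TRUE))
    stop("estimate_conductance(): 'bmr' must be > 0")
  if (any(t_b == t_lc, na.rm = TRUE))
    stop("estimate_conductance(): 't_b' equals 't_lc'; slope is undefined")
  if (any(t_lc > t_b, na.rm = TRUE))
    stop("estimate_conductance(): 't_lc' must be below 't_b'")
  bmr / (t_b - t_lc)
}

#' Resting metabolic rate at the cold range boundary
#'
#' `MR_CRB = (T_lc - T_min) * C + BMR` for boundary temperatures below the
#' lower critical temperature.  When `t_min >= t_lc` the species sits inside
#' its thermal neutral zone at the boundary; the function then returns `bmr`
#' and records the fact in the `"within_tnz"` attribute (such species are
#' excluded upstream rather than erroring, so batch runs never abort).
#'
#' @param t_min Coldest boundary temperature (degC).
#' @param t_lc Lower critical temperature (degC).
#' @param conductance Thermal conductance (ml O2 h^-1 degC^-1), > 0.
#' @param bmr Basal metabolic rate (ml O2 h^-1), > 0.
#' @return Numeric vector of MR_CRB with logical attribute `"within_tnz"`.
#' @examples
#' mr_at_cold_boundary(t_min = 7, t_lc = 27, conductance = 10, bmr = 100)
#' @export
mr_at_cold_boundary <- function(t_min, t_lc, conductance, bmr) {
  if (any(conductance <= 0, na.rm = TRUE))
    stop("mr_at_cold_boundary(): 'conductance' must be > 0")
  if (any(bmr <= 0, na.rm = TRUE))
    stop("mr_at_cold_boundary(): 'bmr' must be > 0")
  n <- max(length(t_min), length(t_lc), length(conductance), length(bmr))
  t_min <- rep_len(t_min, n); t_lc <- rep_len(t_lc, n)
  conductance <- rep_len(conductance, n); bmr <- rep_len(bmr, n)
  within <- t_min >= t_lc
  mr <- ifelse(within, bmr, (t_lc - t_min) * conductance + bmr)
  attr(mr, "within_tnz") <- within
  mr
}

#' Metabolic expansibility at the cold range boundary
#'
#' The factor by which boundary metabolism exceeds basal metabolism,
#' `ME_CRB = MR_CRB / BMR`.  With conductance derived via
#' [estimate_conductance()] this reduces to
#' `1 + (T_lc - T_min) / (T_b - T_lc)` and is independent of BMR.
#'
#' @param mr_crb Metabolic rate at the cold range boundary (ml O2 h^-1).
#' @param bmr Basal metabolic rate (ml O2 h^-1), > 0.
#' @return Dimensionless expansibility (>= 1 whenever `mr_crb >= bmr`).
#' @export
metabolic_expansibility <- function(mr_crb, bmr) {
  if (any(bmr <= 0, na.rm = TRUE))
    stop("metabolic_expansibility(): 'bmr' must be > 0")
  as.numeric(mr_crb) / bmr
}

#' Predicted lower thermal limit for a target expansibility
#'
#' Inverts the boundary model: the coldest temperature at which a species
#' can hold its observed expansibility is
#' `T_limit = T_lc - (ME - 1) * BMR / C`, which with derived conductance is
#' `T_lc - (ME - 1) * (T_b - T_lc)`.
#'
#' @param me_target Target metabolic expansibility, >= 1.
#' @param t_lc Lower critical temperature (degC).
#' @param bmr Basal metabolic rate (ml O2 h^-1).
#' @param conductance Thermal conductance (ml O2 h^-1 degC^-1), > 0.
#' @return Thermal limit in degC.
#' @examples
#' thermal_limit(me_target = 2.5, t_lc = 27, bmr = 100, conductance = 10)
#' @export
thermal_limit <- function(me_target, t_lc, bmr, conductance) {
  if (any(me_target < 1, na.rm = TRUE))
    stop("thermal_limit(): 'me_target' must be >= 1")
  if (any(conductance <= 0, na.rm = TRUE))
    stop("thermal_limit(): 'conductance' must be > 0")
  t_lc - (me_target - 1) * bmr / conductance
}

#' Ratio of boundary metabolism to summit metabolism
#'
#' `MR_CRB / M_sum` measures how much of the maximum cold-induced metabolic
#' capacity thermoregulation at the boundary would consume.  Values above 1
#' are permitted (and biologically interpretable as evasion of the coldest
#' conditions or summit rates measured in milder climates).
#'
#' @param mr_crb Metabolic rate at the cold range boundary (ml O2 h^-1).
#' @param m_sum Summit metabolism (ml O2 h^-1), > 0.
#' @return Dimensionless ratio.
#' @export
msum_ratio <- function(mr_crb, m_sum) {
  if (any(m_sum <= 0, na.rm = TRUE))
    stop("msum_ratio(): 'm_sum' must be > 0")
  mr_crb / m_sum
}

#' Convert metabolic rate from watts to ml O2 per hour
#'
#' Uses the lipid-metabolism equivalence of 179 ml O2 h^-1 per watt.
#'
#' @param x Rate in watts, >= 0.
#' @return Rate in ml O2 h^-1.
#' @export
watts_to_mlO2_per_h <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("watts_to_mlO2_per_h(): negative rate")
  179 * x
}

#' Metabolic expansibility at the warm range boundary
#'
#' Coarse warm-edge analogue of [metabolic_expansibility()]: for species
#' whose warm-boundary maximum temperature exceeds the upper critical
#' temperature, `ME_warm = ((T_max - T_uc) * C + BMR) / BMR`.  Species whose
#' boundary never exceeds `T_uc` (or lacking `T_uc` data) are flagged
#' not-applicable (`NA` with attribute `"applicable" = FALSE`) rather than
#' erroring; most endotherms never exceed their upper critical temperature
#' at the warm boundary.
#'
#' @param t_max Warmest boundary temperature (degC).
#' @param t_uc Upper critical temperature (degC); may be `NA`.
#' @param conductance Thermal conductance (ml O2 h^-1 degC^-1).
#' @param bmr Basal metabolic rate (ml O2 h^-1).
#' @return Numeric vector with attribute `"applicable"`.
#' @export
warm_expansibility <- function(t_max, t_uc, conductance, bmr) {
  n <- max(length(t_max), length(t_uc), length(conductance), length(bmr))
  t_max <- rep_len(t_max, n); t_uc <- rep_len(t_uc, n)
  conductance <- rep_len(conductance, n); bmr <- rep_len(bmr, n)
  applicable <- !is.na(t_uc) & t_max >= t_uc
  me <- ifelse(applicable, ((t_max - t_uc) * conductance + bmr) / bmr, NA_real_)
  attr(me, "applicable") <- applicable
  me
}

#' Validate a physiology table against its invariants
#'
#' Checks each row of a physiology table (see [read_physiology()] for the
#' schema) against the record invariants: positive BMR and mass,
#' `t_lc < t_b`, `t_lc < t_uc < t_b + 15` when `t_uc` is present,
#' `m_sum >= bmr` when present, positive conductance when present.
#'
#' @param phys Data frame with at least `species_id`, `bmr`, `mass_g`,
#'   `t_b`, `t_lc` columns.
#' @return Data frame of violations (`species_id`, `problem`); zero rows if
#'   clean.
#' @export
validate_physiology <- function(phys) {
  stopifnot(is.data.frame(phys))
  need <- c("species_id", "bmr", "mass_g", "t_b", "t_lc")
  miss <- setdiff(need, names(phys))
  if (length(miss))
    stop("validate_physiology(): missing columns: ", paste(miss, collapse = ", "))
  bad <- list()
  flag <- function(idx, why) {
    if (any(idx, na.rm = TRUE))
      bad[[length(bad) + 1L]] <<- data.frame(
        species_id = phys$species_id[which(idx)], problem = why,
        stringsAsFactors = FALSE)
  }
  flag(phys$bmr <= 0, "bmr_nonpositive")
  flag(phys$mass_g <= 0, "mass_nonpositive")
  flag(phys$t_lc >= phys$t_b, "tlc_not_below_tb")
  if ("t_uc" %in% names(phys))
    flag(!is.na(phys$t_uc) &
           (phys$t_uc <= phys$t_lc | phys$t_uc >= phys$t_b + 15),
         "tuc_out_of_bounds")
  if ("m_sum" %in% names(phys))
    flag(!is.na(phys$m_sum) & phys$m_sum < phys$bmr, "msum_below_bmr")
  if ("conductance" %in% names(phys))
    flag(!is.na(phys$conductance) & phys$conductance <= 0,
         "conductance_nonpositive")
  if (length(bad)) do.call(rbind, bad)
  else data.frame(species_id = character(), problem = character(),
                  stringsAsFactors = FALSE)
}
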