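# Published coefficient sets and microclimate summaries from the original
# field study of esparto transpiration under pine competition. These serve as
# generator defaults and as reference values for internal consistency checks;
# the site coding is baseline = dense (S = 0), composite = clear (S = 1).

#' Reference exponential power model coefficients
#'
#' The fitted coefficient sets of the combined exponential power model from
#' the original esparto field study, per period and leaf type, with their
#' log-scale residual standard error (SEE) and adjusted R-squared where
#' reported. Non-significant terms are `NA` (excluded). All senescent models
#' are intercept-only constants.
#'
#' @return Data frame with columns `period`, `leaf_type`, `beta0`, `beta0p`,
#'   `beta1`, `beta1p`, `beta2`, `beta2p`, `SEE`, `R2_adj`.
#' @seealso [esparto_site_models()], [esparto_microclimate()]
#' @export
esparto_coefficients <- function() {
  data.frame(
    period    = rep(c("summer", "autumn", "winter", "spring", "yearly"), each = 2),
    leaf_type = rep(c("green", "senescent"), times = 5),
    beta0  = c(-8.62, -3.91, -5.64, -3.97, -1.67, -3.96, -2.14, -3.52, -5.82, -3.92),
    beta0p = c( 5.03,    NA,  0.19,    NA,    NA,    NA,    NA,    NA,  1.04,    NA),
    beta1  = c(   NA,    NA,    NA,    NA, -0.048,   NA,    NA,    NA, -0.053,   NA),
    beta1p = c(   NA,    NA,    NA,    NA,    NA,    NA, 0.028,    NA,    NA,    NA),
    beta2  = c( 4.24,    NA,  1.26,    NA,    NA,    NA,    NA,    NA,  1.60,    NA),
    beta2p = c(-4.18,    NA,    NA,    NA,    NA,    NA,    NA,    NA, -0.25,    NA),
    SEE    = c( 1.04,    NA,  0.57,    NA,  0.39,    NA,  0.31,    NA,  0.90,    NA),
    R2_adj = c( 34.9,    NA,  48.5,    NA,  23.8,    NA,  23.6,    NA,  46.0,    NA)
  )
}

#' Reference coefficient set for one stratum as an `ep_coef`
#'
#' @param period One of `"summer"`, `"autumn"`, `"winter"`, `"spring"`,
#'   `"yearly"`.
#' @param leaf_type `"green"` or `"senescent"`.
#' @return An [ep_coef()] object with the non-significant terms excluded.
#' @export
esparto_coef <- function(period = "yearly", leaf_type = "green") {
  tab <- esparto_coefficients()
  row <- tab[tab$period == period & tab$leaf_type == leaf_type, ]
  if (nrow(row) != 1L)
    stop("unknown stratum: ", period, " / ", leaf_type, call. = FALSE)
  ep_coef(beta0 = row$beta0, beta0p = row$beta0p, beta1 = row$beta1,
          beta1p = row$beta1p, beta2 = row$beta2, beta2p = row$beta2p)
}

#' Reference per-site model lines and senescent constants
#'
#' The per-site regression lines published by the original study: for green
#' leaves the intercept, Sw slope and Sw exponent of each site's line, and
#' for senescent leaves the constant transpiration rate (mm h^-1).
#'
#' @return Data frame with columns `period`, `group` (one of `green-dense`,
#'   `green-clear`, `senescent`), `intercept`, `slope`, `exponent`,
#'   `constant_T`.
#' @export
esparto_site_models <- function() {
  data.frame(
    period = rep(c("summer", "autumn", "winter", "spring", "yearly"), each = 3),
    group  = rep(c("green-dense", "green-clear", "senescent"), times = 5),
    intercept = c(-8.62, -3.60, NA, -5.64, -5.45, NA, -1.67, -1.67, NA,
                  -2.14, -2.14, NA, -5.82, -4.78, NA),
    slope     = c(0, 0, NA, 0, 0, NA, -0.048, -0.048, NA,
                  0, 0.027, NA, -0.053, -0.053, NA),
    exponent  = c(4.24, 0.06, NA, 1.25, 1.25, NA, 0, 0, NA,
                  0, 0, NA, 1.60, 1.35, NA),
    constant_T = c(NA, NA, 0.0200, NA, NA, 0.0189, NA, NA, 0.0191,
                   NA, NA, 0.0296, NA, NA, 0.0198)
  )
}

#' Reference seasonal microclimate summaries
#'
#' Mean and dispersion of soil water content (Sw, %), soil temperature
#' (Ts, degrees C), photosynthetically active radiation (PAR,
#' umol m^-2 s^-1) and vapor pressure deficit (VPD, kPa) for each fitting
#' period of the original study. The dispersions are used by the synthetic
#' generator as per-observation standard deviations.
#'
#' @return Data frame with columns `period`, `Sw_mean`, `Sw_sd`, `Ts_mean`,
#'   `Ts_sd`, `PAR_mean`, `PAR_sd`, `VPD_mean`, `VPD_sd`.
#' @export
esparto_microclimate <- function() {
  data.frame(
    period   = c("summer", "autumn", "winter", "spring", "yearly"),
    Sw_mean  = c(3.4, 13.0, 16.3, 11.9, 11.8),
    Sw_sd    = c(0.4, 0.3, 0.4, 0.7, 6.5),
    Ts_mean  = c(32.9, 17.8, 11.0, 12.8, 18.9),
    Ts_sd    = c(0.5, 0.3, 0.5, 0.8, 9.5),
    PAR_mean = c(959, 576, 458, 198, 596),
    PAR_sd   = c(39, 24, 37, 64, 490),
    VPD_mean = c(5.2, 2.7, 1.6, 1.4, 2.8),
    VPD_sd   = c(2.9, 1.5, 0.6, 0.3, 2.1)
  )
}
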