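# Synthetic-study generator: reproduces the factorial sampling design
# (3 slots/day x 2 leaf types x 8 bushes x 14 days across 4 seasons), the
# seasonal soil/environmental microclimate, and transpiration generated from
# the exponential power model with multiplicative log-normal noise, so the
# whole pipeline runs without field data.

#' Configuration of a synthetic esparto transpiration study
#'
#' All defaults reproduce the original study's design: 8 bushes balanced
#' over 2 sites x 2 maturities, 14 sampling days split 4/4/3/3 over
#' summer/autumn/winter/spring, 3 daily measurement slots, 2 leaf types,
#' seasonal microclimate from [esparto_microclimate()] (dispersions used as
#' per-observation SDs), true model coefficients from
#' [esparto_coefficients()], and per-season log-scale noise SDs equal to the
#' published SEE values.
#'
#' @param seed Integer RNG seed.
#' @param n_bushes Number of bushes; must be divisible by 4.
#' @param days_per_season Named integer vector of sampling days per season.
#' @param slots_per_day Number of daily measurement slots (morning, midday,
#'   afternoon).
#' @param n_replicates Repeated chamber readings per slot (averaged).
#' @param microclimate Data frame in the layout of [esparto_microclimate()].
#' @param coefficients Data frame in the layout of [esparto_coefficients()].
#' @param noise_sd_log Named per-season log-scale noise SD for green leaves.
#' @param senescent_noise_sd Log-scale noise SD for senescent leaves.
#' @param replicate_noise_sd Log-scale SD of within-slot replicate noise.
#' @param bush_effect_sd Log-scale SD of the lognormal bush-level multiplier
#'   emulating the repeated-measures (random bush) structure.
#' @param ci_mean,ci_sd Mean and SD of the dense-site competition index.
#' @param sla Specific leaf area, cm^2 g^-1.
#' @param baseline_site Site coded S = 0 in the generating model.
#' @param site_offsets Named list, per season, of additive clear-minus-dense
#'   contrasts applied symmetrically to the microclimate means (VPD never
#'   receives one). The default puts the published summer pattern (clear
#'   site wetter, warmer soil, brighter) in place.
#' @param covariate_coupling Strength in [0, 1) of the shared day-level
#'   latent driver inducing the negative Sw-Ts cross-correlation.
#' @return Validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_bushes = 8L,
                             days_per_season = c(summer = 4L, autumn = 4L,
                                                 winter = 3L, spring = 3L),
                             slots_per_day = 3L,
                             n_replicates = 3L,
                             microclimate = esparto_microclimate(),
                             coefficients = esparto_coefficients(),
                             noise_sd_log = c(summer = 1.04, autumn = 0.57,
                                              winter = 0.39, spring = 0.31),
                             senescent_noise_sd = 0.30,
                             replicate_noise_sd = 0.05,
                             bush_effect_sd = 0.10,
                             ci_mean = 0.22, ci_sd = 0.03,
                             sla = 10.8,
                             baseline_site = "dense",
                             site_offsets = list(summer = c(Sw = 1.0,
                                                            Ts = 2.0,
                                                            PAR = 150)),
                             covariate_coupling = 0.5) {
  if (n_bushes %% 4L != 0L)
    stop("config error: `n_bushes` must be divisible by 4 (2 sites x 2 maturities)",
         call. = FALSE)
  seasons <- c("summer", "autumn", "winter", "spring")
  if (!setequal(names(days_per_season), seasons))
    stop("config error: `days_per_season` must name exactly the four seasons",
         call. = FALSE)
  if (any(days_per_season < 1L))
    stop("config error: at least one sampling day per season", call. = FALSE)
  bad <- setdiff(names(site_offsets), seasons)
  if (length(bad))
    stop("config error: unknown season label(s) in `site_offsets`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sd_cols <- grep("_sd$", names(microclimate), value = TRUE)
  stopifnot(all(as.matrix(microclimate[sd_cols]) >= 0, na.rm = TRUE),
            covariate_coupling >= 0, covariate_coupling < 1,
            senescent_noise_sd >= 0, all(noise_sd_log >= 0),
            replicate_noise_sd >= 0, bush_effect_sd >= 0)
  structure(list(seed = as.integer(seed), n_bushes = as.integer(n_bushes),
                 days_per_season = days_per_season[seasons],
                 slots_per_day = as.integer(slots_per_day),
                 n_replicates = as.integer(n_replicates),
                 microclimate = microclimate, coefficients = coefficients,
                 noise_sd_log = noise_sd_log,
                 senescent_noise_sd = senescent_noise_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 bush_effect_sd = bush_effect_sd,
                 ci_mean = ci_mean, ci_sd = ci_sd, sla = sla,
                 baseline_site = baseline_site, site_offsets = site_offsets,
                 covariate_coupling = covariate_coupling),
            class = "synthetic_config")
}

.slot_names <- c("morning", "midday", "afternoon")
# nominal first day of each season's sampling window
.season_start <- c(summer = "2020-08-01", autumn = "2020-11-01",
                   winter = "2021-01-15", spring = "2021-04-01")

#' Full factorial design frame of a synthetic study
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame with one row per (date, time_slot, bush_id,
#'   leaf_type) and a `season` column; exactly
#'   `slots x leaf types x bushes x days` rows under the defaults
#'   (3 x 2 x 8 x 14 = 672).
#' @export
gen_design <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  days <- do.call(rbind, lapply(names(cfg$days_per_season), function(se) {
    d <- cfg$days_per_season[[se]]
    data.frame(season = se,
               date = format(as.Date(.season_start[[se]]) + 7L * (seq_len(d) - 1L)))
  }))
  slots <- .slot_names[seq_len(cfg$slots_per_day)]
  bush_ids <- sprintf("B%02d", seq_len(cfg$n_bushes))
  grid <- expand.grid(leaf_type = c("green", "senescent"),
                      bush_id = bush_ids, time_slot = slots,
                      date = days$date, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$season <- days$season[match(grid$date, days$date)]
  grid[c("date", "season", "time_slot", "bush_id", "leaf_type")]
}

# truncated-normal draws by inverse-CDF
.rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate bush structures for a synthetic study
#'
#' Balanced site x maturity assignment (young Pb < 70 cm, mature
#' Pb > 130 cm). Dense-site bushes receive 2-4 competitor pines within the
#' 5 m sampling radius whose perimeter/distance quotients sum to a target
#' competition index drawn around `ci_mean`; clear-site bushes are isolated
#' (CI = 0).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `bushes` (one row per bush: site, maturity, Pb, height,
#'   root and dry-weight descriptors, CI) and `competitors` (long format:
#'   bush_id, tree_perimeter_m, distance_m).
#' @export
gen_bushes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  per_cell <- cfg$n_bushes %/% 4L
  grid <- expand.grid(maturity = c("young", "mature"),
                      site = c("clear", "dense"),
                      rep = seq_len(per_cell), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  young <- grid$maturity == "young"
  bushes <- data.frame(
    bush_id = sprintf("B%02d", seq_len(n)),
    site = grid$site, maturity = grid$maturity,
    Pb_cm = ifelse(young, stats::runif(n, 45, 68), stats::runif(n, 132, 210)),
    h_cm = ifelse(young, stats::rnorm(n, 60, 8), stats::rnorm(n, 95, 10)),
    root_depth_cm = ifelse(young, stats::rnorm(n, 14, 2), stats::rnorm(n, 19, 2)),
    root_length_cm = ifelse(young, stats::rnorm(n, 35, 6), stats::rnorm(n, 65, 8)),
    dw_green_g = ifelse(young, stats::rnorm(n, 150, 25), stats::rnorm(n, 400, 50)),
    dw_senescent_g = ifelse(young, stats::rnorm(n, 250, 40), stats::rnorm(n, 600, 70))
  )
  comp <- list()
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (bushes$site[i] != "dense") next
    target <- .rtruncnorm(1L, cfg$ci_mean, cfg$ci_sd, lower = 0.02)
    k <- sample(2:4, 1L)
    dist <- stats::runif(k, 1.5, 5)
    w <- stats::runif(k); w <- w / sum(w)
    per <- w * target * dist
    comp[[length(comp) + 1L]] <-
      data.frame(bush_id = bushes$bush_id[i], tree_perimeter_m = per,
                 distance_m = dist)
    ci[i] <- competition_index(per, dist)
  }
  bushes$CI <- ci
  competitors <- if (length(comp)) do.call(rbind, comp) else
    data.frame(bush_id = character(0), tree_perimeter_m = numeric(0),
               distance_m = numeric(0))
  rownames(competitors) <- NULL
  list(bushes = bushes, competitors = competitors)
}

#' Draw per-observation soil and environmental covariates for one season
#'
#' Truncated-normal draws around the seasonal means with the configured
#' per-observation SDs. Soil water and soil temperature are negatively
#' coupled through a shared latent driver (strength
#' `covariate_coupling`). Seasonal site offsets (if configured) are applied
#' as symmetric half-contrasts to the means of Sw, Ts and PAR; VPD never
#' receives a site offset.
#'
#' @param cfg A [synthetic_config()].
#' @param season Season name.
#' @param site `"clear"` or `"dense"` (vector allowed).
#' @param n Number of draws (defaults to `length(site)`).
#' @param latent Optional shared latent N(0,1) driver per draw (e.g. one
#'   value per sampling day); defaults to fresh draws.
#' @return Data frame with columns `Sw`, `Ts`, `PAR`, `VPD`.
#' @export
gen_microclimate <- function(cfg, season, site, n = length(site),
                             latent = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mc <- cfg$microclimate
  row <- mc[mc$period == season, ]
  if (nrow(row) != 1L) stop("unknown season: ", season, call. = FALSE)
  site <- rep_len(site, n)
  off <- cfg$site_offsets[[season]]
  half <- function(var) {
    if (is.null(off) || !var %in% names(off)) return(rep(0, n))
    ifelse(site == "clear", off[[var]] / 2, -off[[var]] / 2)
  }
  a <- cfg$covariate_coupling
  z <- if (is.null(latent)) stats::rnorm(n) else rep_len(latent, n)
  resid_sd <- sqrt(1 - a^2)
  sw_core <- a * z + resid_sd * stats::rnorm(n)
  ts_core <- -a * z + resid_sd * stats::rnorm(n)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  data.frame(
    Sw = clamp(row$Sw_mean + half("Sw") + row$Sw_sd * sw_core, 1e-3, 100),
    Ts = row$Ts_mean + half("Ts") + row$Ts_sd * ts_core,
    PAR = .rtruncnorm(n, row$PAR_mean, row$PAR_sd, lower = 0) + half("PAR"),
    VPD = .rtruncnorm(n, row$VPD_mean, row$VPD_sd, lower = 0)
  )
}

#' Generate transpiration for design rows with covariates
#'
#' Green leaves: `T = ep_evaluate(truth_season, Sw, S) * exp(N(0, sd))` with
#' the season's true coefficient set and log-scale noise SD. Senescent
#' leaves: the season's constant `exp(beta0)` times the same form of noise.
#' An optional per-bush lognormal multiplier emulates the repeated-measures
#' structure.
#'
#' @param cfg A [synthetic_config()].
#' @param rows Data frame with columns `season`, `site`, `leaf_type`, `Sw`,
#'   `bush_id`.
#' @param bush_effects Optional named log-scale bush effects (defaults to 0).
#' @return Numeric vector of transpiration rates, mm h^-1.
#' @export
gen_transpiration <- function(cfg, rows, bush_effects = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- nrow(rows)
  T_out <- numeric(n)
  S <- as.integer(rows$site != cfg$baseline_site)
  be <- if (is.null(bush_effects)) rep(0, n) else
    unname(bush_effects[rows$bush_id])
  for (se in unique(rows$season)) {
    g <- rows$season == se & rows$leaf_type == "green"
    if (any(g)) {
      truth <- .cfg_coef(cfg, se, "green")
      mu <- ep_evaluate(truth, rows$Sw[g], S[g])
      T_out[g] <- mu * exp(stats::rnorm(sum(g), 0, cfg$noise_sd_log[[se]]))
    }
    s <- rows$season == se & rows$leaf_type == "senescent"
    if (any(s)) {
      truth <- .cfg_coef(cfg, se, "senescent")
      T_out[s] <- exp(as.numeric(truth)[1]) *
        exp(stats::rnorm(sum(s), 0, cfg$senescent_noise_sd))
    }
  }
  T_out * exp(be)
}

.cfg_coef <- function(cfg, period, leaf_type) {
  tab <- cfg$coefficients
  row <- tab[tab$period == period & tab$leaf_type == leaf_type, ]
  if (nrow(row) != 1L)
    stop("no true coefficients configured for ", period, " / ", leaf_type,
         call. = FALSE)
  ep_coef(beta0 = row$beta0, beta0p = row$beta0p, beta1 = row$beta1,
          beta1p = row$beta1p, beta2 = row$beta2, beta2p = row$beta2p)
}

#' Simulate a complete synthetic study
#'
#' Generates bushes, the factorial design, day-level coupled soil
#' microclimate, per-slot environmental covariates, model-generated
#' transpiration, and the raw chamber records that reproduce it: each
#' observation is backed by `n_replicates` chamber readings whose computed
#' and averaged transpiration equals the observation's `T`. Running
#' [compute_observations()] on the emitted chamber/bush/soil tables
#' recovers `observations` up to floating-point round-trip error.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional directory: when given, writes `chamber.csv`,
#'   `bushes.csv`, `competitors.csv`, `soil.csv`, `observations.csv`.
#' @return List of data frames `bushes`, `competitors`, `soil`, `chamber`,
#'   `observations` (invisible when `dir` is given).
#' @export
simulate_study <- function(cfg = synthetic_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  bu <- gen_bushes(cfg)
  design <- gen_design(cfg)
  bush_eff <- stats::setNames(
    stats::rnorm(cfg$n_bushes, 0, cfg$bush_effect_sd), bu$bushes$bush_id)

  # soil microclimate: one record per (date, bush), shared day-level driver
  dates <- unique(design[c("date", "season")])
  day_latent <- stats::setNames(stats::rnorm(nrow(dates)), dates$date)
  soil <- do.call(rbind, lapply(seq_len(nrow(dates)), function(i) {
    b <- bu$bushes
    mc <- gen_microclimate(cfg, dates$season[i], b$site, n = nrow(b),
                           latent = day_latent[[dates$date[i]]])
    data.frame(date = dates$date[i], season = dates$season[i],
               bush_id = b$bush_id, Sw_pct = mc$Sw, Ts_C = mc$Ts)
  }))

  # per-(date, slot, bush) environmental covariates with a diurnal profile
  slot_par <- c(morning = 0.85, midday = 1.30, afternoon = 0.85)
  slot_vpd <- c(morning = 0.85, midday = 1.25, afternoon = 0.90)
  cells <- unique(design[c("date", "season", "time_slot", "bush_id")])
  env <- do.call(rbind, lapply(split(cells, cells$season), function(cc) {
    b_site <- bu$bushes$site[match(cc$bush_id, bu$bushes$bush_id)]
    mc <- gen_microclimate(cfg, cc$season[1], b_site, n = nrow(cc),
                           latent = day_latent[cc$date])
    cc$PAR <- pmax(mc$PAR * slot_par[cc$time_slot], 0)
    cc$VPD <- pmax(mc$VPD * slot_vpd[cc$time_slot], 0)
    cc
  }))

  obs <- merge(design, env,
               by = c("date", "season", "time_slot", "bush_id"))
  obs <- merge(obs, soil[c("date", "bush_id", "Sw_pct", "Ts_C")],
               by = c("date", "bush_id"))
  names(obs)[names(obs) == "Sw_pct"] <- "Sw"
  names(obs)[names(obs) == "Ts_C"] <- "Ts"
  obs$site <- bu$bushes$site[match(obs$bush_id, bu$bushes$bush_id)]
  obs$maturity <- bu$bushes$maturity[match(obs$bush_id, bu$bushes$bush_id)]
  obs$CI <- bu$bushes$CI[match(obs$bush_id, bu$bushes$bush_id)]
  obs <- obs[order(obs$date, obs$time_slot, obs$bush_id, obs$leaf_type), ]
  rownames(obs) <- NULL

  T_model <- gen_transpiration(cfg, obs, bush_effects = bush_eff)

  # chamber records: n_replicates readings per observation; the observation
  # T is the mean of the replicate-level computed rates
  nrep <- cfg$n_replicates
  n <- nrow(obs)
  rep_T <- matrix(T_model, n, nrep) *
    exp(matrix(stats::rnorm(n * nrep, 0, cfg$replicate_noise_sd), n, nrep))
  flow_F <- 500
  leaf_area <- stats::runif(n, 2, 4)
  Wr <- stats::runif(n, 8, 15)
  chamber <- do.call(rbind, lapply(seq_len(nrep), function(r) {
    Tm <- rep_T[, r] / 64.8576            # back to mol m^-2 s^-1
    A <- 100 * leaf_area * Tm / flow_F
    Ws <- (100 * A + Wr) / (1 + A)        # inverts the as-printed equation
    data.frame(date = obs$date, time_slot = obs$time_slot,
               bush_id = obs$bush_id, leaf_type = obs$leaf_type,
               replicate = r, flow_F = flow_F, W_sample = Ws,
               W_reference = Wr, leaf_area_cm2 = leaf_area,
               PAR = obs$PAR, VPD = obs$VPD)
  }))
  chamber <- chamber[order(chamber$date, chamber$time_slot, chamber$bush_id,
                           chamber$leaf_type, chamber$replicate), ]
  rownames(chamber) <- NULL

  obs$T <- rowMeans(rep_T)
  obs$flag_negative_T <- obs$T < 0
  obs <- obs[c("date", "season", "time_slot", "bush_id", "leaf_type", "T",
               "site", "maturity", "CI", "Sw", "Ts", "PAR", "VPD",
               "flag_negative_T")]

  out <- list(bushes = bu$bushes, competitors = bu$competitors,
              soil = soil, chamber = chamber, observations = obs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Parameter-recovery experiment for the fitting pipeline
#'
#' Repeatedly generates observations from a known coefficient set and
#' refits them with the full pipeline ([ep_fit()]), then summarises
#' per-coefficient median estimate, bias and RMSE, the fraction of
#' replicates whose stepwise-retained set equals the true support, and the
#' modal retained set.
#'
#' @param truth An [ep_coef()] (default: the yearly green reference set).
#' @param n_reps Number of replicates.
#' @param n_obs Observations per replicate (split evenly over the two
#'   sites).
#' @param noise_sd Log-scale noise SD.
#' @param sw_mean,sw_sd Mean and SD of the truncated-normal soil water
#'   distribution (%) the observations are drawn from.
#' @param alpha Stepwise retention level.
#' @param seed RNG seed.
#' @return List with `summary` (data frame: coefficient, truth, median,
#'   bias, rmse, prop_included), `support_recovery` (fraction of replicates
#'   retaining exactly the true support), `modal_support` (character vector
#'   of term names) and `estimates` (n_reps x 6 matrix).
#' @export
recovery_experiment <- function(truth = esparto_coef("yearly", "green"),
                                n_reps = 200L, n_obs = 2000L,
                                noise_sd = 0.3, sw_mean = 11.8, sw_sd = 6.5,
                                alpha = 0.05, seed = 1L) {
  set.seed(seed)
  true_b <- as.numeric(truth)
  true_support <- .ep_terms[attr(truth, "included")]
  est <- matrix(0, n_reps, 6L, dimnames = list(NULL, .ep_coef_names))
  supports <- character(n_reps)
  for (r in seq_len(n_reps)) {
    Sw <- .rtruncnorm(n_obs, sw_mean, sw_sd, lower = 0)
    site <- rep(c("dense", "clear"), length.out = n_obs)
    S <- as.integer(site != "dense")
    mu <- ep_evaluate(truth, Sw, S)
    obs <- data.frame(T = mu * exp(stats::rnorm(n_obs, 0, noise_sd)),
                      Sw = Sw, site = site)
    fit <- ep_fit(obs, baseline_site = "dense", alpha = alpha)
    est[r, ] <- as.numeric(fit$coefficients)
    supports[r] <- paste(sort(fit$retained), collapse = "+")
  }
  truth_key <- paste(sort(true_support), collapse = "+")
  summary <- data.frame(
    coefficient = .ep_coef_names, truth = true_b,
    median = apply(est, 2L, stats::median),
    bias = colMeans(est) - true_b,
    rmse = sqrt(colMeans(sweep(est, 2L, true_b)^2)),
    prop_included = colMeans(est != 0)
  )
  tab <- sort(table(supports), decreasing = TRUE)
  list(summary = summary,
       support_recovery = mean(supports == truth_key),
       modal_support = strsplit(names(tab)[1], "+", fixed = TRUE)[[1]],
       estimates = est)
}
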