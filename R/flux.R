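#' Molar transpiration from a chamber reading
#'
#' Computes the leaf-level water flux from the air flow, the water mole
#' fractions of the sample and reference air streams, and the projected leaf
#' area enclosed in the gas-exchange chamber.
#'
#' Two dialects of the chamber equation are supported.  The `"as-printed"`
#' dialect uses a denominator of `100 - Ws`; the `"instrument-manual"` dialect
#' uses `1000 - Ws`, the form consistent with mole fractions expressed in
#' mmol mol^-1 in the instrument documentation.  Both compute
#' `F * (Ws - Wr) / (100 * S * (D - Ws))` with `D` set by the dialect.  The
#' dialect used is recorded in the `"dialect"` attribute of the result.
#'
#' @param flow_F Air flow entering the chamber, umol air s^-1. Must be > 0.
#' @param W_sample Water mole fraction of the sample stream, mmol H2O mol^-1.
#' @param W_reference Water mole fraction of the reference stream,
#'   mmol H2O mol^-1.
#' @param leaf_area_S Projected leaf area in the chamber, cm^2. Must be > 0.
#' @param dialect `"as-printed"` (default) or `"instrument-manual"`.
#' @return Molar water flux, mol H2O m^-2 s^-1, with attribute `dialect`.
#'   The sign follows `W_sample - W_reference`; negative values indicate a
#'   drier sample stream than reference (e.g. sensor noise) and are flagged
#'   downstream rather than dropped here.
#' @seealso [to_mm_per_hour()], [compute_observations()]
#' @examples
#' molar_transpiration(500, 20, 10, 5)                        # 0.125
#' molar_transpiration(500, 20, 10, 5, "instrument-manual")   # ~0.0102
#' @export
molar_transpiration <- function(flow_F, W_sample, W_reference, leaf_area_S,
                                dialect = c("as-printed", "instrument-manual")) {
  dialect <- match.arg(dialect)
  if (any(!is.finite(flow_F)) || any(flow_F <= 0))
    stop("`flow_F` must be positive and finite", call. = FALSE)
  if (any(!is.finite(leaf_area_S)) || any(leaf_area_S <= 0))
    stop("`leaf_area_S` must be positive and finite", call. = FALSE)
  if (any(W_sample < 0) || any(W_reference < 0))
    stop("water mole fractions must be non-negative", call. = FALSE)
  D <- if (dialect == "as-printed") 100 else 1000
  denom <- D - W_sample
  if (any(denom <= 0))
    stop(sprintf("W_sample >= %d: denominator non-positive under the '%s' dialect",
                 D, dialect), call. = FALSE)
  E <- flow_F * (W_sample - W_reference) / (100 * leaf_area_S * denom)
  structure(E, dialect = dialect)
}

#' Convert a molar water flux to a transpiration rate in mm per hour
#'
#' Uses the molar mass of water (18.016 g mol^-1) and the equivalence
#' 1 L of water over 1 m^2 = 1 mm depth, so the conversion factor is
#' 18.016 / 1000 * 3600 = 64.8576.
#'
#' @param E Molar flux, mol H2O m^-2 s^-1.
#' @return Transpiration rate, mm h^-1. Linear in `E`.
#' @export
to_mm_per_hour <- function(E) {
  if (any(!is.finite(E))) stop("`E` must be finite", call. = FALSE)
  as.numeric(E) * 64.8576
}

#' Mean of repeated chamber readings within one hour slot
#'
#' Three repeated measures are taken for each hourly slot and their mean is
#' the analyzable transpiration datum.
#'
#' @param readings Numeric vector of transpiration rates (mm h^-1) for one
#'   slot; must be non-empty.
#' @return The arithmetic mean; a single reading is returned unchanged.
#' @export
replicate_mean <- function(readings) {
  if (length(readings) == 0L)
    stop("`readings` must contain at least one value", call. = FALSE)
  mean(as.numeric(readings))
}

#' Pine competition index for a bush
#'
#' For each competitor pine the quotient trunk perimeter / distance to the
#' focal bush is formed (both in metres); the index is the sum of these
#' quotients over all competitors within the sampling radius.  An isolated
#' bush (no competitors) has CI = 0.
#'
#' @param perimeters Competitor trunk perimeters, m.
#' @param distances Distances from each competitor to the bush, m; must be
#'   > 0 and the same length as `perimeters`.
#' @return Competition index, m m^-1.
#' @examples
#' competition_index(numeric(0), numeric(0))  # isolated bush: 0
#' competition_index(1.0, 5.0)                # 0.2
#' @export
competition_index <- function(perimeters, distances) {
  if (length(perimeters) != length(distances))
    stop("`perimeters` and `distances` must have equal length", call. = FALSE)
  if (length(perimeters) == 0L) return(0)
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("competitor distances must be positive", call. = FALSE)
  sum(perimeters / distances)
}

#' Scale leaf dry weight to total projected leaf area
#'
#' Total projected leaf area per leaf type is the leaf dry weight multiplied
#' by the specific leaf area (SLA).
#'
#' @param dry_weight Leaf dry weight, g; must be >= 0.
#' @param SLA Specific leaf area, cm^2 g^-1; must be > 0. The study-area
#'   value for esparto is 10.8 cm^2 g^-1.
#' @return Leaf area, cm^2.
#' @export
total_leaf_area <- function(dry_weight, SLA = 10.8) {
  if (any(dry_weight < 0)) stop("`dry_weight` must be >= 0", call. = FALSE)
  if (any(SLA <= 0)) stop("`SLA` must be > 0", call. = FALSE)
  dry_weight * SLA
}

#' Build analyzable observations from chamber, bush and soil tables
#'
#' Converts raw chamber readings to transpiration rates (mm h^-1), averages
#' the repeated readings within each (date, slot, bush, leaf type) cell,
#' joins bush structure (site, maturity, competition index) and the soil
#' microclimate record for the same date and bush, and returns one row per
#' observation.
#'
#' Rows whose computed transpiration is negative (sample stream drier than
#' reference) are retained and flagged in the `flag_negative_T` column; model
#' fitting excludes them because the log transform is undefined there.
#'
#' @param chamber Data frame with columns `date`, `time_slot`, `bush_id`,
#'   `leaf_type`, `flow_F`, `W_sample`, `W_reference`, `leaf_area_cm2`,
#'   `PAR`, `VPD`.
#' @param bushes Data frame with columns `bush_id`, `site`, `maturity` (and
#'   optionally further biometric columns).
#' @param competitors Data frame with columns `bush_id`, `tree_perimeter_m`,
#'   `distance_m`; bushes absent from it get CI = 0.
#' @param soil Data frame with columns `date`, `bush_id`, `Sw_pct`, `Ts_C`.
#' @param dialect Chamber-equation dialect, see [molar_transpiration()].
#' @return Data frame with one row per (date, time_slot, bush_id, leaf_type):
#'   columns `T`, `leaf_type`, `season` (if present in `soil` or `chamber`),
#'   `site`, `maturity`, `bush_id`, `CI`, `Sw`, `Ts`, `PAR`, `VPD`,
#'   `flag_negative_T`. The chamber-equation dialect and the number of
#'   negative-T rows are stored in attributes `dialect` and `n_negative`.
#' @export
compute_observations <- function(chamber, bushes, competitors = NULL, soil,
                                 dialect = c("as-printed", "instrument-manual")) {
  dialect <- match.arg(dialect)
  need <- c("date", "time_slot", "bush_id", "leaf_type", "flow_F",
            "W_sample", "W_reference", "leaf_area_cm2", "PAR", "VPD")
  miss <- setdiff(need, names(chamber))
  if (length(miss))
    stop("`chamber` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("bush_id", "site", "maturity"), names(bushes))
  if (length(miss))
    stop("`bushes` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("date", "bush_id", "Sw_pct", "Ts_C"), names(soil))
  if (length(miss))
    stop("`soil` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  E <- molar_transpiration(chamber$flow_F, chamber$W_sample,
                           chamber$W_reference, chamber$leaf_area_cm2,
                           dialect = dialect)
  chamber$T_mm_h <- to_mm_per_hour(E)

  key <- interaction(chamber$date, chamber$time_slot, chamber$bush_id,
                     chamber$leaf_type, drop = TRUE)
  agg <- aggregate(chamber[c("T_mm_h", "PAR", "VPD")], by = list(key = key),
                   FUN = mean)
  first <- chamber[!duplicated(key), c("date", "time_slot", "bush_id", "leaf_type")]
  first$key <- key[!duplicated(key)]
  obs <- merge(first, agg, by = "key")
  obs$key <- NULL
  names(obs)[names(obs) == "T_mm_h"] <- "T"

  ci <- vapply(bushes$bush_id, function(b) {
    if (is.null(competitors)) return(0)
    rows <- competitors[competitors$bush_id == b, , drop = FALSE]
    competition_index(rows$tree_perimeter_m, rows$distance_m)
  }, numeric(1))
  bush_info <- data.frame(bush_id = bushes$bush_id, site = bushes$site,
                          maturity = bushes$maturity, CI = ci)
  obs <- merge(obs, bush_info, by = "bush_id", all.x = TRUE)

  soil_cols <- intersect(c("date", "bush_id", "Sw_pct", "Ts_C", "season"),
                         names(soil))
  obs <- merge(obs, soil[soil_cols], by = c("date", "bush_id"), all.x = TRUE)
  names(obs)[names(obs) == "Sw_pct"] <- "Sw"
  names(obs)[names(obs) == "Ts_C"] <- "Ts"

  obs$flag_negative_T <- obs$T < 0
  obs <- obs[order(obs$date, obs$time_slot, obs$bush_id, obs$leaf_type), ]
  rownames(obs) <- NULL
  structure(obs, dialect = dialect, n_negative = sum(obs$flag_negative_T))
}
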