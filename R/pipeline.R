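# One-command orchestration: simulate -> flux -> correlate -> fit ->
# predict -> report, with a serialized manifest reconciling row counts at
# every stage boundary.

#' Read and validate a pipeline configuration file
#'
#' The JSON schema mirrors [synthetic_config()]: any of its arguments may be
#' given; unknown keys are a configuration error. `days_per_season` and
#' `noise_sd_log` are JSON objects keyed by season; `microclimate` and
#' `coefficients` are arrays of row objects in the layouts of
#' [esparto_microclimate()] and [esparto_coefficients()].
#'
#' @param path Path to a JSON configuration file.
#' @return A validated [synthetic_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path,
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path)
  allowed <- names(formals(synthetic_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in c("days_per_season", "noise_sd_log", "site_offsets"))
    if (!is.null(raw[[nm]]) && nm != "site_offsets")
      raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$site_offsets))
    raw$site_offsets <- lapply(raw$site_offsets, unlist)
  do.call(synthetic_config, raw)
}

.fit_strata <- function() {
  expand.grid(leaf_type = c("green", "senescent"),
              period = c("summer", "autumn", "winter", "spring", "yearly"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.ep_fit_row <- function(fit) {
  b <- as.numeric(fit$coefficients)
  inc <- attr(fit$coefficients, "included")
  vals <- ifelse(inc, b, NA_real_)
  data.frame(leaf_type = fit$leaf_type, period = fit$period,
             beta0 = vals[1], beta0p = vals[2], beta1 = vals[3],
             beta1p = vals[4], beta2 = vals[5], beta2p = vals[6],
             SEE = fit$SEE, R2_adj = fit$R2_adj, F_p = fit$F_p,
             n_used = fit$n_used, n_removed = nrow(fit$removed_points),
             n_excluded = fit$excluded_nonpositive, n_input = fit$n_input)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: study simulation (writing the raw CSV tables), the
#' chamber-flux stage ([compute_observations()] on those tables), seasonal
#' Spearman correlation screening, exponential power model fits for every
#' leaf type x period stratum, site-stratified prediction curves, a
#' human-readable report, and a run manifest with per-stage row counts and
#' file digests.
#'
#' @param config A [synthetic_config()], or the path to a JSON file for
#'   [read_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Chamber-equation dialect for the flux stage.
#' @return The manifest, invisibly. Side effects: writes `data/*.csv`,
#'   `observations.csv`, `correlations.csv`, `fits.csv`, `fits.json`,
#'   `curves.csv`, `report.md` and `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         dialect = "as-printed") {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data_dir <- file.path(out_dir, "data")
  counts <- list()

  # stage 1: simulate
  sim <- simulate_study(config, dir = data_dir)
  counts$simulate <- list(chamber_rows = nrow(sim$chamber),
                          design_rows = nrow(sim$observations))

  # stage 2: flux (from the serialized raw tables, as a field run would)
  chamber <- utils::read.csv(file.path(data_dir, "chamber.csv"))
  bushes <- utils::read.csv(file.path(data_dir, "bushes.csv"))
  competitors <- utils::read.csv(file.path(data_dir, "competitors.csv"))
  soil <- utils::read.csv(file.path(data_dir, "soil.csv"))
  obs <- compute_observations(chamber, bushes, competitors, soil,
                              dialect = dialect)
  utils::write.csv(obs, file.path(out_dir, "observations.csv"),
                   row.names = FALSE)
  counts$flux <- list(chamber_rows = nrow(chamber), obs_rows = nrow(obs),
                      negative_T = sum(obs$flag_negative_T))

  # stage 3: seasonal correlation screening (green leaves)
  seasons <- names(config$days_per_season)
  corr <- do.call(rbind, lapply(seasons, function(se)
    correlation_long(correlation_table(obs, season = se))))
  utils::write.csv(corr, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  counts$correlate <- list(tables = length(seasons), cells = nrow(corr))

  # stage 4: model fits per stratum
  strata <- .fit_strata()
  fits <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    fits[[i]] <- ep_fit(obs, leaf_type = strata$leaf_type[i],
                        period = strata$period[i],
                        baseline_site = config$baseline_site)
  }
  fit_tab <- do.call(rbind, lapply(fits, .ep_fit_row))
  utils::write.csv(fit_tab, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  fit_json <- lapply(fits, function(f) {
    list(leaf_type = f$leaf_type, period = f$period,
         baseline_site = f$baseline_site,
         coefficients = as.list(stats::setNames(as.numeric(f$coefficients),
                                                .ep_coef_names)),
         included = attr(f$coefficients, "included"),
         std_errors = as.list(f$std_errors), p_values = as.list(f$p_values),
         SEE = f$SEE, R2_adj = f$R2_adj, F_p = f$F_p, n_used = f$n_used,
         removed_points = f$removed_points,
         excluded_nonpositive = f$excluded_nonpositive,
         n_input = f$n_input, retained = f$retained, path = f$path)
  })
  jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts$fit <- list(strata = nrow(strata),
                     reconciled = all(fit_tab$n_used + fit_tab$n_removed +
                                        fit_tab$n_excluded == fit_tab$n_input))

  # stage 5: prediction curves for the green fits with soil-water terms
  curves <- do.call(rbind, lapply(fits, function(f) {
    if (!identical(f$leaf_type, "green")) return(NULL)
    if (!any(c("Sw", "S_Sw", "lnSw", "S_lnSw") %in% f$retained)) return(NULL)
    cv <- ep_predict(f)
    cv$leaf_type <- f$leaf_type; cv$period <- f$period
    cv
  }))
  if (!is.null(curves))
    utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
  counts$predict <- list(curve_rows = if (is.null(curves)) 0L else nrow(curves))

  # stage 6: report
  report_path <- render_report(fits, corr, file.path(out_dir, "report.md"))

  outputs <- c(file.path("data", c("bushes.csv", "competitors.csv",
                                   "soil.csv", "chamber.csv",
                                   "observations.csv")),
               "observations.csv", "correlations.csv", "fits.csv",
               "fits.json", if (!is.null(curves)) "curves.csv", "report.md")
  digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(digests) <- outputs
  cfg_txt <- jsonlite::toJSON(config[setdiff(names(config),
                                             c("microclimate", "coefficients"))],
                              auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile(); writeLines(cfg_txt, cfg_file)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   dialect = dialect, counts = counts, outputs = outputs,
                   digests = digests,
                   version = as.character(utils::packageVersion("espartoflux")))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# "T = e^(-5.82 - 0.053 Sw) Sw^1.60"-style model string for one site line
.model_string <- function(intercept, slope, exponent) {
  if (slope == 0 && exponent == 0)
    return(sprintf("T = %.4f", exp(intercept)))
  s <- sprintf("T = e^(%.3g", intercept)
  if (slope != 0) s <- sprintf("%s %s %.3g Sw", s,
                               if (slope < 0) "-" else "+", abs(slope))
  s <- paste0(s, ")")
  if (exponent != 0) s <- sprintf("%s Sw^%.3g", s, exponent)
  s
}

#' Render the markdown run report
#'
#' Writes per-stratum coefficient tables and the per-site model strings.
#' Intercept-only (senescent-type) fits render as constants; fits with no
#' retained site terms print one shared line for both sites.
#'
#' @param fits List of `ep_fit` objects.
#' @param corr Long-format correlation data frame (optional).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
render_report <- function(fits, corr = NULL, path) {
  ln <- c("# Esparto transpiration model run", "")
  for (f in fits) {
    ln <- c(ln, sprintf("## %s leaves, %s", f$leaf_type, f$period), "")
    ln <- c(ln,
            sprintf("n used = %d; removed (DFFITS) = %d; excluded (T or Sw <= 0) = %d",
                    f$n_used, nrow(f$removed_points), f$excluded_nonpositive),
            "")
    ln <- c(ln, "| term | estimate | std. error | p |",
            "|---|---|---|---|")
    for (tm in f$retained) {
      est <- as.numeric(f$coefficients)[match(tm, .ep_terms)]
      ln <- c(ln, sprintf("| %s | %.4g | %.3g | %.3g |", tm, est,
                          f$std_errors[[tm]], f$p_values[[tm]]))
    }
    ln <- c(ln, "",
            sprintf("SEE (log scale) = %.3f; adjusted R2 = %.1f%%; F p = %s",
                    f$SEE, f$R2_adj, format.pval(f$F_p, digits = 3)), "")
    cc <- composite_coefficients(f)
    base_line <- .model_string(cc["intercept", "baseline"],
                               cc["slope", "baseline"],
                               cc["exponent", "baseline"])
    comp_line <- .model_string(cc["intercept", "composite"],
                               cc["slope", "composite"],
                               cc["exponent", "composite"])
    other <- if (identical(f$baseline_site, "dense")) "clear" else "dense"
    if (identical(base_line, comp_line)) {
      ln <- c(ln, sprintf("Both sites: %s", base_line), "")
    } else {
      ln <- c(ln, sprintf("%s site (S = 0): %s", f$baseline_site, base_line),
              sprintf("%s site (S = 1): %s", other, comp_line), "")
    }
  }
  if (!is.null(corr)) {
    ln <- c(ln, "## Significant Spearman correlations (95%)", "")
    sig <- corr[corr$significant & !is.na(corr$significant), , drop = FALSE]
    if (nrow(sig)) {
      ln <- c(ln, "| season | pair | rho | p | n |", "|---|---|---|---|---|")
      for (i in seq_len(nrow(sig)))
        ln <- c(ln, sprintf("| %s | %s-%s | %.3f | %.3g | %d |",
                            sig$season[i], sig$var_a[i], sig$var_b[i],
                            sig$rho[i], sig$p[i], sig$n[i]))
    } else ln <- c(ln, "(none)")
    ln <- c(ln, "")
  }
  writeLines(ln, path)
  invisible(path)
}
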