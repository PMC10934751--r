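# Combined exponential power model of transpiration vs. soil water:
#   T = exp(b0 + b0'S + (b1 + b1'S) Sw) * Sw^(b2 + b2'S) * eps
# with site dummy S. Estimated by log-linearisation: the design columns are,
# in fixed order, [1, S, Sw, S*Sw, ln Sw, S*ln Sw].

.ep_terms <- c("(Intercept)", "S", "Sw", "S_Sw", "lnSw", "S_lnSw")
.ep_coef_names <- c("beta0", "beta0p", "beta1", "beta1p", "beta2", "beta2p")

#' Coefficient set of the exponential power transpiration model
#'
#' Holds the six model coefficients together with an inclusion mask. A
#' coefficient given as `NA` (the default for all but `beta0`) is excluded
#' from the model: it is stored as exactly 0 and marked not included.
#'
#' @param beta0 Log-scale intercept (always included).
#' @param beta0p Site increment to the intercept.
#' @param beta1 Log-scale linear slope on soil water content Sw (per %).
#' @param beta1p Site increment to the slope.
#' @param beta2 Exponent on Sw.
#' @param beta2p Site increment to the exponent.
#' @return An object of class `ep_coef`: a named numeric vector of length 6
#'   with a logical `included` attribute.
#' @examples
#' # yearly green-leaf coefficient set from the original study
#' ep_coef(beta0 = -5.82, beta0p = 1.04, beta1 = -0.053,
#'         beta2 = 1.60, beta2p = -0.25)
#' @export
ep_coef <- function(beta0, beta0p = NA, beta1 = NA, beta1p = NA,
                    beta2 = NA, beta2p = NA) {
  vals <- c(beta0 = beta0, beta0p = beta0p, beta1 = beta1,
            beta1p = beta1p, beta2 = beta2, beta2p = beta2p)
  if (is.na(vals[1])) stop("`beta0` is always included and must be given",
                           call. = FALSE)
  included <- !is.na(vals)
  vals[!included] <- 0
  structure(as.numeric(vals), names = .ep_coef_names,
            included = unname(included), class = "ep_coef")
}

#' @export
print.ep_coef <- function(x, ...) {
  inc <- attr(x, "included")
  shown <- ifelse(inc, formatC(unclass(x), digits = 4, format = "g"), "excl.")
  cat("Exponential power model coefficients (log-linear scale):\n")
  print(stats::setNames(shown, .ep_coef_names), quote = FALSE)
  invisible(x)
}

#' Evaluate the exponential power model
#'
#' Predicted transpiration `T = exp(b0 + b0'S + (b1 + b1'S) Sw) *
#' Sw^(b2 + b2'S)` at given soil water content and site dummy.
#'
#' @param coef An [ep_coef()] object (or numeric vector of length 6 in the
#'   same order).
#' @param Sw Soil water content, %. Must be > 0 unless the site-specific
#'   exponent is zero (excluded) or positive.
#' @param S Site dummy, 0 (baseline) or 1; recycled against `Sw`.
#' @return Predicted transpiration, mm h^-1.
#' @examples
#' cf <- ep_coef(beta0 = -5.82, beta0p = 1.04, beta1 = -0.053,
#'               beta2 = 1.60, beta2p = -0.25)
#' ep_evaluate(cf, Sw = 10, S = 0)  # ~0.0695 on the baseline (dense) line
#' @export
ep_evaluate <- function(coef, Sw, S = 0) {
  b <- as.numeric(coef)
  if (length(b) != 6L) stop("`coef` must hold six coefficients", call. = FALSE)
  n <- max(length(Sw), length(S))
  Sw <- rep_len(Sw, n); S <- rep_len(S, n)
  expo <- b[5] + b[6] * S
  if (any(Sw < 0) || any(Sw == 0 & expo < 0))
    stop("Sw must be > 0 where the exponent term is negative", call. = FALSE)
  lin <- b[1] + b[2] * S + (b[3] + b[4] * S) * Sw
  exp(lin) * Sw ^ expo
}

#' Log-linearise observations for the exponential power model
#'
#' Filters observations to one leaf type and period, drops rows where the
#' log transform is undefined (T <= 0 or Sw <= 0, counted), and builds the
#' response `ln T` with the fixed-order design matrix
#' `[1, S, Sw, S*Sw, ln Sw, S*ln Sw]`.
#'
#' @param obs Data frame with columns `T`, `Sw`, `site`, and (if filtering is
#'   requested) `leaf_type` and `season`.
#' @param leaf_type Optional filter, `"green"` or `"senescent"`.
#' @param period `"yearly"` (all rows) or one season name to filter on.
#' @param baseline_site Site coded S = 0. Defaults to `"dense"`, the coding
#'   under which the S = 1 composite line describes the clear site.
#' @param min_n Minimum usable rows (default 8, the number of design columns
#'   plus two).
#' @return List with `X` (design matrix), `y` (log response),
#'   `excluded_nonpositive` (dropped row count), `n_input` (stratum rows
#'   before exclusion), `rows` (row indices of `obs` kept) and
#'   `baseline_site`.
#' @export
ep_linearize <- function(obs, leaf_type = NULL, period = "yearly",
                         baseline_site = "dense", min_n = 8L) {
  dat <- obs
  if (!is.null(leaf_type)) {
    if (!"leaf_type" %in% names(dat))
      stop("`obs` has no `leaf_type` column to filter on", call. = FALSE)
    dat <- dat[dat$leaf_type == leaf_type, , drop = FALSE]
  }
  if (!identical(period, "yearly")) {
    if (!"season" %in% names(dat))
      stop("`obs` has no `season` column to filter on", call. = FALSE)
    dat <- dat[dat$season == period, , drop = FALSE]
  }
  if (!all(c("T", "Sw", "site") %in% names(dat)))
    stop("`obs` must contain columns T, Sw and site", call. = FALSE)
  n_input <- nrow(dat)
  usable <- is.finite(dat$T) & is.finite(dat$Sw) & dat$T > 0 & dat$Sw > 0
  excluded <- sum(!usable)
  dat <- dat[usable, , drop = FALSE]
  if (nrow(dat) < min_n)
    stop(sprintf("insufficient data: %d usable rows (< %d) in stratum",
                 nrow(dat), min_n), call. = FALSE)
  S <- as.integer(dat$site != baseline_site)
  lnSw <- log(dat$Sw)
  X <- cbind(1, S, dat$Sw, S * dat$Sw, lnSw, S * lnSw)
  colnames(X) <- .ep_terms
  list(X = X, y = log(dat$T), excluded_nonpositive = excluded,
       n_input = n_input, rows = which(usable), baseline_site = baseline_site)
}

# Shared degenerate-fit tolerance: below this residual SD the classical
# t statistics are 0/0; coefficients are then classed as zero/non-zero
# directly (|coef| < 1e-8 -> p = 1, otherwise p = 0).
.ep_sigma_tol <- 1e-10

#' Ordinary least squares on a linearised design
#'
#' Fits the log-scale regression by OLS and reports coefficient standard
#' errors, two-sided t p-values, the residual standard error (SEE), the
#' adjusted R-squared on a 0-100 scale, and the overall-regression F test
#' p-value.
#'
#' @param X Design matrix whose first column is the intercept.
#' @param y Response vector (`ln T`).
#' @return An object of class `ep_ols`: list with elements `coefficients`,
#'   `std_errors`, `p_values`, `cov` (coefficient covariance), `SEE`,
#'   `R2_adj` (percent), `F_p`, `n`, `df_residual`, `fitted`, `residuals`,
#'   and the underlying `lm` fit.
#' @details A rank-deficient design raises an error naming the collinear
#'   columns. On an exactly interpolating fit (residual SD below 1e-10) the
#'   t p-values are degenerate; a coefficient is then reported with p = 1
#'   when its magnitude is below 1e-8 and p = 0 otherwise.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than design columns", call. = FALSE)
  qr_X <- qr(X)
  if (qr_X$rank < p) {
    bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):p]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- as.data.frame(X)
  dat$.y <- y
  fm <- stats::lm(.y ~ 0 + ., data = dat)
  beta <- stats::coef(fm)
  names(beta) <- colnames(X)
  res <- stats::residuals(fm)
  rss <- sum(res^2)
  df <- n - p
  sigma <- sqrt(rss / df)
  # (X'X)^-1 from the fit's QR, undoing any column pivoting
  piv <- fm$qr$pivot
  XtX_inv_piv <- chol2inv(qr.R(fm$qr))
  XtX_inv <- matrix(0, p, p)
  XtX_inv[piv, piv] <- XtX_inv_piv
  covb <- sigma^2 * XtX_inv
  dimnames(covb) <- list(colnames(X), colnames(X))
  if (sigma < .ep_sigma_tol) {
    se <- rep(0, p)
    pv <- ifelse(abs(beta) < 1e-8, 1, 0)
    R2_adj <- 100
    F_p <- 0
  } else {
    se <- sqrt(diag(covb))
    tval <- beta / se
    pv <- 2 * stats::pt(-abs(tval), df)
    tss <- sum((y - mean(y))^2)
    R2 <- if (tss > 0) 1 - rss / tss else 0
    R2_adj <- 100 * max(0, 1 - (1 - R2) * (n - 1) / df)
    F_p <- if (p > 1L && tss > rss) {
      Fstat <- ((tss - rss) / (p - 1)) / (rss / df)
      stats::pf(Fstat, p - 1, df, lower.tail = FALSE)
    } else NA_real_
  }
  structure(list(coefficients = beta, std_errors = stats::setNames(se, colnames(X)),
                 p_values = stats::setNames(pv, colnames(X)), cov = covb,
                 SEE = sigma, R2_adj = R2_adj, F_p = F_p, n = n,
                 df_residual = df, fitted = stats::fitted(fm), residuals = res,
                 lm = fm, X = X, y = y),
            class = "ep_ols")
}

#' Backward (or forward) stepwise term selection at a fixed alpha
#'
#' Backward elimination starts from all six model terms and repeatedly drops
#' the non-intercept term with the largest p-value at or above `alpha`,
#' refitting after each drop, until every retained non-intercept term is
#' significant. The intercept is never dropped. When two candidate terms tie
#' on p-value, the later column in the fixed order [S, Sw, S*Sw, ln Sw,
#' S*ln Sw] is dropped first.
#'
#' @param X Full design matrix (intercept first column).
#' @param y Response vector.
#' @param alpha Significance level for retention (default 0.05).
#' @param direction `"backward"` (default) or `"forward"` (p-value guided
#'   forward inclusion, for sensitivity analysis).
#' @return List with `fit` (the final [fit_ols()] object on the retained
#'   columns), `retained` (column names) and `path` (data frame logging each
#'   elimination/inclusion step with the p-value that decided it).
#' @export
stepwise_select <- function(X, y, alpha = 0.05,
                            direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  X <- as.matrix(X)
  cols <- colnames(X)
  path <- data.frame(step = integer(0), action = character(0),
                     term = character(0), p = numeric(0))
  if (direction == "backward") {
    keep <- cols
    fit <- fit_ols(X[, keep, drop = FALSE], y)
    step_i <- 0L
    repeat {
      cand <- setdiff(keep, cols[1])
      if (!length(cand)) break
      pv <- fit$p_values[cand]
      worst <- max(pv)
      if (worst < alpha) break
      # ties: drop the later column in the fixed order first
      tied <- cand[pv >= worst - 1e-12]
      drop_term <- tied[which.max(match(tied, cols))]
      step_i <- step_i + 1L
      path <- rbind(path, data.frame(step = step_i, action = "drop",
                                     term = drop_term,
                                     p = unname(fit$p_values[drop_term])))
      keep <- setdiff(keep, drop_term)
      fit <- fit_ols(X[, keep, drop = FALSE], y)
    }
  } else {
    keep <- cols[1]
    fit <- fit_ols(X[, keep, drop = FALSE], y)
    step_i <- 0L
    repeat {
      cand <- setdiff(cols, keep)
      if (!length(cand)) break
      trial_p <- vapply(cand, function(tm) {
        f <- fit_ols(X[, c(keep, tm), drop = FALSE], y)
        unname(f$p_values[tm])
      }, numeric(1))
      best <- min(trial_p)
      if (best >= alpha) break
      tied <- cand[trial_p <= best + 1e-12]
      add_term <- tied[which.min(match(tied, cols))]
      step_i <- step_i + 1L
      path <- rbind(path, data.frame(step = step_i, action = "add",
                                     term = add_term,
                                     p = unname(trial_p[add_term])))
      keep <- cols[cols %in% c(keep, add_term)]
      fit <- fit_ols(X[, keep, drop = FALSE], y)
    }
  }
  list(fit = fit, retained = keep, path = path)
}

#' Flag and remove influential points by the DFFITS rule
#'
#' Computes DFFITS for every point of a completed OLS fit and removes the
#' points whose |DFFITS| exceeds `2 * sqrt(p / n)` (p = number of
#' coefficients, n = number of points). One removal pass is made.
#'
#' @param fit An `ep_ols` object from [fit_ols()].
#' @param threshold Numeric cut-off, or `NULL` (default) for
#'   `2 * sqrt(p / n)`.
#' @param min_n Minimum rows that must survive removal.
#' @return List with `removed` (data frame of row indices and their DFFITS),
#'   `keep` (logical vector), and `fit` refitted on the retained rows.
#' @details On an exactly interpolating fit (residual SD below 1e-10) DFFITS
#'   is undefined and no point is removed.
#' @export
remove_influential <- function(fit, threshold = NULL, min_n = 8L) {
  stopifnot(inherits(fit, "ep_ols"))
  n <- fit$n; p <- length(fit$coefficients)
  if (is.null(threshold)) threshold <- 2 * sqrt(p / n)
  if (fit$SEE < .ep_sigma_tol) {
    d <- rep(0, n)
  } else {
    d <- unname(stats::dffits(fit$lm))
    d[!is.finite(d)] <- Inf   # hat value 1: the point determines its own fit
  }
  out <- abs(d) > threshold
  removed <- data.frame(index = which(out), dffits = d[out])
  if (sum(!out) < min_n)
    stop("insufficient data: influential-point removal leaves fewer than ",
         min_n, " rows", call. = FALSE)
  refit <- if (any(out)) fit_ols(fit$X[!out, , drop = FALSE], fit$y[!out]) else fit
  list(removed = removed, keep = !out, fit = refit, threshold = threshold)
}

#' Fit the exponential power transpiration model for one stratum
#'
#' Runs the full estimation pipeline for one leaf type and period:
#' log-linearisation, a full-model OLS fit, one DFFITS influential-point
#' removal pass, and backward stepwise selection on the cleaned data.
#' For senescent leaves the selection typically collapses to the
#' intercept-only model, in which case `exp(beta0)` is the geometric mean of
#' the transpiration values used.
#'
#' @param obs Observation data frame (see [ep_linearize()]).
#' @param leaf_type `"green"` or `"senescent"` (or `NULL` to use all rows).
#' @param period `"yearly"` or a season name.
#' @param baseline_site Site coded S = 0 (default `"dense"`).
#' @param alpha Retention significance level (default 0.05).
#' @param influence_threshold DFFITS cut-off, `NULL` for `2*sqrt(p/n)`.
#' @param direction Stepwise direction, `"backward"` (default) or
#'   `"forward"`.
#' @return An object of class `ep_fit`: list with `coefficients` (an
#'   [ep_coef()] with excluded terms at 0), `std_errors`, `p_values`, `cov`
#'   (retained terms), `SEE`, `R2_adj`, `F_p`, `n_used`, `removed_points`,
#'   `excluded_nonpositive`, `n_input`, `retained`, `path`, plus the
#'   configuration used and the cleaned design (`X`, `y`) for later tests.
#' @export
ep_fit <- function(obs, leaf_type = NULL, period = "yearly",
                   baseline_site = "dense", alpha = 0.05,
                   influence_threshold = NULL,
                   direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  lin <- ep_linearize(obs, leaf_type = leaf_type, period = period,
                      baseline_site = baseline_site)
  full <- fit_ols(lin$X, lin$y)
  infl <- remove_influential(full, threshold = influence_threshold)
  Xc <- lin$X[infl$keep, , drop = FALSE]
  yc <- lin$y[infl$keep]
  sel <- stepwise_select(Xc, yc, alpha = alpha, direction = direction)
  fit <- sel$fit
  args <- stats::setNames(rep(list(NA), 6), .ep_coef_names)
  for (tm in sel$retained)
    args[[.ep_coef_names[match(tm, .ep_terms)]]] <- unname(fit$coefficients[tm])
  coefficients <- do.call(ep_coef, args)
  removed_points <- infl$removed
  removed_points$index <- lin$rows[removed_points$index]  # back to stratum rows
  structure(list(coefficients = coefficients,
                 std_errors = fit$std_errors, p_values = fit$p_values,
                 cov = fit$cov, SEE = fit$SEE, R2_adj = fit$R2_adj,
                 F_p = fit$F_p, n_used = fit$n,
                 removed_points = removed_points,
                 excluded_nonpositive = lin$excluded_nonpositive,
                 n_input = lin$n_input, retained = sel$retained,
                 path = sel$path, alpha = alpha,
                 baseline_site = baseline_site, leaf_type = leaf_type,
                 period = period, influence_threshold = infl$threshold,
                 direction = direction, X = Xc, y = yc),
            class = "ep_fit")
}

#' @export
print.ep_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential power transpiration model  [%s leaves, %s]\n",
              x$leaf_type %||% "all", x$period))
  cat(sprintf("  baseline site: %s (S = 0); n used = %d, removed = %d, excluded = %d\n",
              x$baseline_site, x$n_used, nrow(x$removed_points),
              x$excluded_nonpositive))
  tab <- data.frame(estimate = unname(sapply(x$retained, function(tm)
    unclass(x$coefficients)[match(tm, .ep_terms)])),
    std_error = unname(x$std_errors[x$retained]),
    p = unname(x$p_values[x$retained]), row.names = x$retained)
  print(round(tab, digits))
  cat(sprintf("  SEE = %.3f (log scale), adj. R2 = %.1f%%, F p = %s\n",
              x$SEE, x$R2_adj, format.pval(x$F_p, digits = 3)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficients of the S = 1 (composite) regression line
#'
#' Collapses the site-increment parameterisation to the coefficients of the
#' non-baseline site's own line: intercept `beta0 + beta0'`, slope
#' `beta1 + beta1'`, exponent `beta2 + beta2'`, using 0 for excluded terms.
#' Standard errors come from the coefficient covariance
#' (`var(a + b) = var(a) + var(b) + 2 cov(a, b)`) when a fitted model is
#' supplied.
#'
#' @param fit An `ep_fit` object, or an [ep_coef()] (then SEs are `NA`).
#' @return Data frame with rows `intercept`, `slope`, `exponent` and columns
#'   `baseline` (S = 0 line), `composite` (S = 1 line), `se_composite`.
#' @examples
#' cf <- ep_coef(beta0 = -5.82, beta0p = 1.04, beta1 = -0.053,
#'               beta2 = 1.60, beta2p = -0.25)
#' composite_coefficients(cf)  # clear-site line: -4.78, -0.053, 1.35
#' @export
composite_coefficients <- function(fit) {
  if (inherits(fit, "ep_coef")) {
    b <- as.numeric(fit)
    covb <- NULL
  } else if (inherits(fit, "ep_fit")) {
    b <- as.numeric(fit$coefficients)
    covb <- fit$cov
  } else stop("`fit` must be an ep_fit or ep_coef object", call. = FALSE)
  pairs <- list(intercept = c("(Intercept)", "S"),
                slope = c("Sw", "S_Sw"),
                exponent = c("lnSw", "S_lnSw"))
  base <- c(b[1], b[3], b[5])
  comp <- c(b[1] + b[2], b[3] + b[4], b[5] + b[6])
  se <- vapply(pairs, function(tm) {
    if (is.null(covb)) return(NA_real_)
    present <- intersect(tm, rownames(covb))
    if (!length(present)) return(0)
    sqrt(sum(covb[present, present]))
  }, numeric(1))
  data.frame(baseline = base, composite = comp, se_composite = unname(se),
             row.names = names(pairs))
}

#' Test the site (competition) effects of a fitted model
#'
#' Per-term two-sided t-tests for the site increments (S, S*Sw, S*ln Sw) in
#' the full six-term model on the cleaned data, plus a joint F-test
#' comparing the model with all three site terms against the model without
#' any of them.
#'
#' @param fit An `ep_fit` object.
#' @return List with `per_term` (data frame: term, estimate, p, retained)
#'   and `joint` (list: F, df, p).
#' @export
site_effect_test <- function(fit) {
  stopifnot(inherits(fit, "ep_fit"))
  X <- fit$X; y <- fit$y
  site_terms <- c("S", "S_Sw", "S_lnSw")
  full <- fit_ols(X, y)
  reduced <- fit_ols(X[, setdiff(colnames(X), site_terms), drop = FALSE], y)
  rss1 <- sum(full$residuals^2); rss0 <- sum(reduced$residuals^2)
  df1 <- full$df_residual
  Fstat <- ((rss0 - rss1) / length(site_terms)) / (rss1 / df1)
  joint_p <- stats::pf(Fstat, length(site_terms), df1, lower.tail = FALSE)
  per_term <- data.frame(term = site_terms,
                         estimate = unname(full$coefficients[site_terms]),
                         p = unname(full$p_values[site_terms]),
                         retained = site_terms %in% fit$retained)
  list(per_term = per_term,
       joint = list(F = Fstat, df = c(length(site_terms), df1), p = joint_p))
}

#' Site-stratified prediction curves over a soil water grid
#'
#' @param fit An `ep_fit` or `ep_coef` object.
#' @param Sw Grid of soil water content values (%), all > 0.
#' @param sites Named integer vector mapping site labels to the dummy values
#'   to predict for; the default gives the baseline (S = 0) and composite
#'   (S = 1) lines.
#' @return Data frame with columns `site`, `S`, `Sw`, `T_pred`.
#' @export
ep_predict <- function(fit, Sw = seq(0.5, 25, by = 0.5),
                       sites = NULL) {
  cf <- if (inherits(fit, "ep_fit")) fit$coefficients else fit
  if (is.null(sites)) {
    base <- if (inherits(fit, "ep_fit")) fit$baseline_site else "baseline"
    other <- if (identical(base, "dense")) "clear"
             else if (identical(base, "clear")) "dense" else "composite"
    sites <- stats::setNames(c(0L, 1L), c(base, other))
  }
  out <- do.call(rbind, lapply(seq_along(sites), function(i) {
    data.frame(site = names(sites)[i], S = unname(sites[i]), Sw = Sw,
               T_pred = ep_evaluate(cf, Sw, unname(sites[i])))
  }))
  rownames(out) <- NULL
  out
}
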