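# Spearman correlation screening between transpiration, competition and
# soil/environmental covariates, with 95% significance flags.

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (average ranks for ties), computed on
#' pairwise-complete cases. When either vector has zero rank variance the
#' correlation is undefined and `NA` is returned (a flag, not an error).
#'
#' @param x,y Numeric vectors of equal length, n >= 2 after removing
#'   incomplete pairs.
#' @return Correlation coefficient in [-1, 1], or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Significance of a Spearman coefficient at a given level
#'
#' Default test: the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on n - 2 degrees of freedom, two-sided. For n <= 8 an exact permutation
#' p-value (full enumeration of the n! rank permutations) is available.
#'
#' @param rho Spearman coefficient.
#' @param n Number of complete pairs; must be >= 4.
#' @param alpha Significance level (default 0.05).
#' @param exact Use the exact permutation null (only allowed for n <= 8).
#' @return List with `p` and `significant`. `|rho| = 1` is reported as
#'   significant with p at the smallest representable positive double.
#' @export
spearman_significance <- function(rho, n, alpha = 0.05, exact = FALSE) {
  if (n < 4L) stop("`n` must be at least 4", call. = FALSE)
  if (is.na(rho)) return(list(p = NA_real_, significant = FALSE))
  if (abs(rho) >= 1 - 1e-12)
    return(list(p = .Machine$double.xmin, significant = TRUE))
  if (exact) {
    if (n > 8L) stop("exact permutation p only supported for n <= 8",
                     call. = FALSE)
    p <- .spearman_perm_p(rho, n)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(p = p, significant = p < alpha)
}

# Exact permutation null for the Spearman coefficient of untied ranks:
# enumerate all n! permutations and count |rho_perm| >= |rho_obs|.
.spearman_perm_p <- function(rho, n) {
  perms <- .all_permutations(n)
  base <- seq_len(n)
  rhos <- apply(perms, 1L, function(pr) stats::cor(base, pr))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
  unname(out)
}

#' Seasonal Spearman correlation table
#'
#' All 15 unordered pairs among {CI, Sw, Ts, PAR, VPD, T} for one season's
#' green-leaf observations (or any requested stratum), computed on
#' pairwise-complete cases with 95% significance flags.
#'
#' @param obs Observation data frame with columns `CI`, `Sw`, `Ts`, `PAR`,
#'   `VPD`, `T`, plus `season`/`leaf_type` if filtering is requested.
#' @param season Season label to filter on, or `NULL` for all rows.
#' @param leaf_type Leaf type to filter on (default `"green"`), or `NULL`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `correlation_table`: list with `season`,
#'   `variables`, `rho` (symmetric matrix, `NA` diagonal), `p`,
#'   `significant` (logical matrix), and `n` (pairwise sample sizes).
#' @export
correlation_table <- function(obs, season = NULL, leaf_type = "green",
                              alpha = 0.05) {
  vars <- c("CI", "Sw", "Ts", "PAR", "VPD", "T")
  dat <- obs
  if (!is.null(leaf_type) && "leaf_type" %in% names(dat))
    dat <- dat[dat$leaf_type == leaf_type, , drop = FALSE]
  if (!is.null(season)) {
    if (!"season" %in% names(dat))
      stop("`obs` has no `season` column to filter on", call. = FALSE)
    dat <- dat[dat$season == season, , drop = FALSE]
  }
  miss <- setdiff(vars, names(dat))
  if (length(miss))
    stop("`obs` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(dat) == 0L)
    stop("insufficient data: empty stratum", call. = FALSE)
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  nmat <- matrix(0L, k, k, dimnames = list(vars, vars))
  sig <- matrix(FALSE, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- dat[[vars[i]]]; y <- dat[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    nij <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- nij
    if (nij < 2L) next
    r <- spearman_rho(x[ok], y[ok])
    rho[i, j] <- rho[j, i] <- r
    if (!is.na(r) && nij >= 4L) {
      s <- spearman_significance(r, nij, alpha = alpha)
      p[i, j] <- p[j, i] <- s$p
      sig[i, j] <- sig[j, i] <- s$significant
    }
  }
  structure(list(season = season %||% "all", variables = vars, rho = rho,
                 p = p, significant = sig, n = nmat, alpha = alpha),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat(sprintf("Spearman correlations (%s; * = p < %.2f)\n", x$season, x$alpha))
  m <- formatC(x$rho, digits = digits, format = "f")
  m[is.na(x$rho)] <- "."
  m[] <- paste0(m, ifelse(x$significant, "*", " "))
  print(as.data.frame(m), quote = FALSE)
  invisible(x)
}

#' Long-format view of a correlation table
#'
#' @param x A `correlation_table`.
#' @return Data frame with columns `season`, `var_a`, `var_b`, `rho`, `p`,
#'   `n`, `significant`; one row per unordered pair.
#' @export
correlation_long <- function(x) {
  stopifnot(inherits(x, "correlation_table"))
  vars <- x$variables
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  data.frame(season = x$season,
             var_a = vars[idx[, 1]], var_b = vars[idx[, 2]],
             rho = x$rho[idx], p = x$p[idx], n = x$n[idx],
             significant = x$significant[idx])
}

#' Grouped mean and standard error of transpiration
#'
#' @param obs Observation data frame with a `T` column.
#' @param by Character vector of grouping columns, e.g.
#'   `c("leaf_type", "season")`.
#' @return Data frame with one row per non-empty cell: the grouping columns,
#'   `mean`, `se` (SD / sqrt(n); 0 with a flag when n = 1) and `n`.
#' @export
group_summary <- function(obs, by = c("leaf_type", "season")) {
  miss <- setdiff(c(by, "T"), names(obs))
  if (length(miss))
    stop("`obs` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(obs[by], drop = TRUE, sep = "\r")
  cells <- split(obs$T, key)
  labels <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
  out <- data.frame(labels)
  names(out) <- by
  out$mean <- vapply(cells, mean, numeric(1))
  out$se <- vapply(cells, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0, numeric(1))
  out$n <- vapply(cells, length, integer(1))
  rownames(out) <- NULL
  out
}
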