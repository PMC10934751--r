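# Exponential power model: evaluation, linearisation, OLS, stepwise
# selection, influence diagnostics and the full per-stratum pipeline.

test_that("coefficient sets store excluded terms as exact zeros with a mask", {
  cf <- ep_coef(beta0 = -5.82, beta0p = 1.04, beta2 = 1.60)
  expect_length(attr(cf, "included"), 6L)
  expect_identical(attr(cf, "included"),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(as.numeric(cf)[c(3, 4, 6)], c(0, 0, 0))
  expect_error(ep_coef(beta0 = NA), "beta0")
})

test_that("model evaluation reproduces the published per-site arithmetic", {
  # senescent constant: exp(-3.91) prints as 0.0200 to 3 s.f.
  cf_sen <- ep_coef(beta0 = -3.91)
  expect_equal(signif(ep_evaluate(cf_sen, 7.3, 0), 3), 0.0200)
  expect_equal(ep_evaluate(cf_sen, 1, 1), ep_evaluate(cf_sen, 20, 0))
  # yearly green baseline (dense) line at Sw = 10
  cf <- esparto_coef("yearly", "green")
  expect_equal(ep_evaluate(cf, 10, 0), exp(-5.82 - 0.53) * 10^1.6)
  # Sw = 1 wipes out the power term for any coefficient set
  set.seed(2)
  for (i in 1:10) {
    b <- rnorm(6)
    cf_i <- ep_coef(b[1], b[2], b[3], b[4], b[5], b[6])
    for (S in 0:1)
      expect_equal(ep_evaluate(cf_i, 1, S),
                   exp(b[1] + b[2] * S + b[3] + b[4] * S))
  }
  expect_error(ep_evaluate(ep_coef(-1, beta2 = -0.5), 0, 0), "Sw")
  expect_error(ep_evaluate(cf, -1, 0), "Sw")
  # Sw = 0 with a positive exponent is the zero-transpiration limit
  expect_equal(ep_evaluate(cf, 0, 0), 0)
})

test_that("linearisation builds ln T against the fixed-order design", {
  obs <- data.frame(T = c(exp(-2), 0.1, 0, 0.2),
                    Sw = c(1, 10, 5, -1),
                    site = c("dense", "clear", "dense", "clear"))
  lin <- ep_linearize(obs, min_n = 2L)
  expect_identical(colnames(lin$X),
                   c("(Intercept)", "S", "Sw", "S_Sw", "lnSw", "S_lnSw"))
  expect_equal(lin$y, c(-2, log(0.1)))
  expect_equal(unname(lin$X[1, ]), c(1, 0, 1, 0, 0, 0))
  expect_equal(unname(lin$X[2, ]), c(1, 1, 10, 10, log(10), log(10)))
  # the T = 0 and Sw < 0 rows are excluded and counted
  expect_equal(lin$excluded_nonpositive, 2L)
  expect_equal(lin$n_input, 4L)
  # baseline coding flips S
  lin2 <- ep_linearize(obs, baseline_site = "clear", min_n = 2L)
  expect_equal(unname(lin2$X[, "S"]), c(1, 0))
  expect_error(ep_linearize(obs), "insufficient")
})

test_that("OLS matches the explicit normal-equations oracle on small data", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(8:12, 1)
    X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = runif(n), c = rexp(n))
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    ora <- ols_oracle(X, y)
    expect_equal(unname(fit$coefficients), unname(ora$coefficients),
                 tolerance = 1e-10)
    expect_equal(unname(fit$std_errors), unname(ora$se), tolerance = 1e-10)
    expect_equal(unname(fit$cov), unname(ora$cov), tolerance = 1e-10)
    expect_equal(fit$SEE, ora$sigma, tolerance = 1e-10)
  }
})

test_that("OLS handles interpolation and singularity explicitly", {
  X <- cbind(`(Intercept)` = 1, x = 1:10)
  y <- 2 + 3 * (1:10)
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit$R2_adj, 100)
  X2 <- cbind(X, dup = X[, "x"])
  expect_error(fit_ols(X2, rnorm(10)), "dup")
})

test_that("backward elimination keeps exactly the informative terms", {
  set.seed(100)
  # strong exponent-only signal
  obs <- make_model_obs(ep_coef(beta0 = -5, beta2 = 1.8), 400, 0.3)
  lin <- ep_linearize(obs)
  sel <- stepwise_select(lin$X, lin$y)
  expect_setequal(sel$retained, c("(Intercept)", "lnSw"))
  # every retained non-intercept term is significant
  expect_true(all(sel$fit$p_values[setdiff(sel$retained, "(Intercept)")] < 0.05))
  # one term per elimination step, path is consistent
  expect_equal(nrow(sel$path), 6L - length(sel$retained))
  expect_equal(sel$path$step, seq_len(nrow(sel$path)))

  # pure noise collapses to the intercept
  obs2 <- data.frame(T = 0.02 * exp(rnorm(300, 0, 0.3)),
                     Sw = runif(300, 1, 25),
                     site = rep(c("dense", "clear"), 150))
  lin2 <- ep_linearize(obs2)
  sel2 <- stepwise_select(lin2$X, lin2$y)
  expect_identical(sel2$retained, "(Intercept)")

  # all six terms with large effects are all retained
  obs3 <- make_model_obs(ep_coef(-6, 1.5, -0.15, 0.1, 2.0, -0.8), 2000, 0.2)
  lin3 <- ep_linearize(obs3)
  sel3 <- stepwise_select(lin3$X, lin3$y)
  expect_setequal(sel3$retained, colnames(lin3$X))
})

test_that("forward selection finds a strong single term", {
  set.seed(77)
  obs <- make_model_obs(ep_coef(beta0 = -5, beta2 = 1.8), 400, 0.3)
  lin <- ep_linearize(obs)
  sel <- stepwise_select(lin$X, lin$y, direction = "forward")
  expect_true("lnSw" %in% sel$retained)
  expect_true(all(sel$path$action == "add"))
})

test_that("DFFITS removal flags a planted outlier and spares clean data", {
  set.seed(303)
  obs <- make_model_obs(esparto_coef("yearly", "green"), 300, 0.3)
  lin <- ep_linearize(obs)
  fit <- fit_ols(lin$X, lin$y)
  clean <- remove_influential(fit)
  expect_lte(nrow(clean$removed) / fit$n, 0.05)
  # displace one response by 10 SEE
  y2 <- lin$y
  y2[57] <- y2[57] + 10 * fit$SEE
  fit2 <- fit_ols(lin$X, y2)
  d <- abs(stats::dffits(fit2$lm))
  expect_equal(unname(which.max(d)), 57L)
  infl <- remove_influential(fit2)
  expect_true(57L %in% infl$removed$index)
  # removal that would empty the data errors out
  tiny <- fit_ols(lin$X[1:9, ], lin$y[1:9])
  expect_error(remove_influential(tiny, threshold = 0), "insufficient")
})

test_that("noise-free data is recovered exactly with its exact support", {
  truths <- c(lapply(c("summer", "autumn", "winter", "spring", "yearly"),
                     esparto_coef, leaf_type = "green"),
              list(ep_coef(-4, 0.8, -0.1, beta2 = 1.2)))
  set.seed(9)
  for (truth in truths) {
    Sw <- runif(200, 1, 25)
    site <- rep(c("dense", "clear"), 100)
    obs <- data.frame(T = ep_evaluate(truth, Sw, as.integer(site != "dense")),
                      Sw = Sw, site = site)
    fit <- ep_fit(obs)
    expect_equal(as.numeric(fit$coefficients), as.numeric(truth),
                 tolerance = 1e-8)
    expect_identical(attr(fit$coefficients, "included"),
                     attr(truth, "included"))
    expect_equal(nrow(fit$removed_points), 0L)
  }
})

test_that("stratum bookkeeping reconciles and empty strata error", {
  set.seed(21)
  obs <- make_model_obs(esparto_coef("yearly", "green"), 300, 0.4)
  obs$T[c(3, 10)] <- 0                      # log-undefined rows
  obs$leaf_type <- "green"
  obs$season <- rep(c("summer", "autumn"), each = 150)
  fit <- ep_fit(obs, leaf_type = "green", period = "summer")
  expect_equal(fit$n_used + nrow(fit$removed_points) + fit$excluded_nonpositive,
               fit$n_input)
  expect_error(ep_fit(obs, leaf_type = "senescent", period = "summer"),
               "insufficient")
})

test_that("intercept-only fits return the geometric mean of transpiration", {
  set.seed(14)
  obs <- data.frame(T = 0.02 * exp(rnorm(200, 0, 0.3)),
                    Sw = runif(200, 1, 25),
                    site = rep(c("dense", "clear"), 100))
  fit <- ep_fit(obs)
  expect_identical(fit$retained, "(Intercept)")
  used <- setdiff(seq_len(fit$n_input), fit$removed_points$index)
  expect_equal(exp(as.numeric(fit$coefficients)[1]),
               exp(mean(log(obs$T[used]))))
  expect_equal(exp(as.numeric(fit$coefficients)[1]), 0.02, tolerance = 0.05)
})

test_that("composite coefficients collapse the site increments correctly", {
  # all increments excluded: composite equals baseline
  cc0 <- composite_coefficients(ep_coef(beta0 = -1.67, beta1 = -0.048))
  expect_equal(cc0$composite, cc0$baseline)
  # SEs propagate the covariance of the summed terms
  set.seed(31)
  obs <- make_model_obs(ep_coef(-6, 1.5, -0.15, 0.1, 2.0, -0.8), 1500, 0.2)
  fit <- ep_fit(obs)
  cc <- composite_coefficients(fit)
  v <- fit$cov
  expect_equal(cc["intercept", "se_composite"],
               sqrt(v["(Intercept)", "(Intercept)"] + v["S", "S"] +
                      2 * v["(Intercept)", "S"]))
  expect_equal(cc["exponent", "composite"],
               sum(as.numeric(fit$coefficients)[c(5, 6)]))
})

test_that("site effect tests have power and roughly nominal size", {
  set.seed(55)
  # power: a large intercept shift is detected
  obs <- make_model_obs(ep_coef(-5, 1.0, beta2 = 1.5), 800, 0.3)
  st <- site_effect_test(ep_fit(obs))
  expect_lt(st$joint$p, 0.05)
  expect_lt(st$per_term$p[st$per_term$term == "S"], 0.05)
  # size: with no site effects the joint test rejects near alpha
  rej <- vapply(1:150, function(i) {
    obs0 <- make_model_obs(ep_coef(-5, beta2 = 1.5), 150, 0.3)
    site_effect_test(ep_fit(obs0))$joint$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.15)
})

test_that("prediction curves cover both site lines over the grid", {
  cv <- ep_predict(esparto_coef("yearly", "green"), Sw = c(5, 10, 20))
  expect_equal(nrow(cv), 6L)
  expect_setequal(unique(cv$S), 0:1)
  expect_equal(cv$T_pred[cv$S == 0 & cv$Sw == 10],
               exp(-5.82 - 0.53) * 10^1.6)
})
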