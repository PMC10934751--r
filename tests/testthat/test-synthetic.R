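# Synthetic-study generator: design counts, bush structure, microclimate,
# model-generated transpiration and reproducibility.

test_that("the default design reproduces the factorial sampling layout", {
  d <- gen_design(synthetic_config())
  expect_equal(nrow(d), 3 * 2 * 8 * 14)           # 672
  expect_equal(sum(d$leaf_type == "green"), 336)
  expect_equal(length(unique(d$date)), 14L)
  expect_equal(as.integer(table(d$season)[c("summer", "autumn", "winter", "spring")]),
               c(4, 4, 3, 3) * 3 * 2 * 8)
  # counts follow the configuration exactly
  d2 <- gen_design(synthetic_config(n_bushes = 4L, slots_per_day = 1L,
                                    days_per_season = c(summer = 1L, autumn = 1L,
                                                        winter = 1L, spring = 1L)))
  expect_equal(nrow(d2), 1 * 2 * 4 * 4)
})

test_that("config validation rejects malformed designs", {
  expect_error(synthetic_config(n_bushes = 6L), "divisible by 4")
  expect_error(synthetic_config(days_per_season = c(summer = 4L)), "four seasons")
  expect_error(synthetic_config(site_offsets = list(monsoon = c(Sw = 1))),
               "monsoon")
})

test_that("bushes are balanced with maturity-consistent perimeters and CI", {
  set.seed(1)
  bu <- gen_bushes(synthetic_config())
  b <- bu$bushes
  expect_equal(nrow(b), 8L)
  expect_equal(unname(table(b$site, b$maturity)), matrix(2L, 2, 2))
  expect_true(all(b$Pb_cm[b$maturity == "young"] < 70))
  expect_true(all(b$Pb_cm[b$maturity == "mature"] > 130))
  expect_true(all(b$CI[b$site == "clear"] == 0))
  expect_true(all(b$CI[b$site == "dense"] > 0))
  # stored CI agrees with the index recomputed from the competitor lists
  for (i in which(b$site == "dense")) {
    rows <- bu$competitors[bu$competitors$bush_id == b$bush_id[i], ]
    expect_equal(b$CI[i], competition_index(rows$tree_perimeter_m,
                                            rows$distance_m))
    expect_true(all(rows$distance_m <= 5))
  }
})

test_that("dense-site CI centres on its configured mean across seeds", {
  cis <- unlist(lapply(1:300, function(s) {
    set.seed(s)
    bu <- gen_bushes(synthetic_config())
    bu$bushes$CI[bu$bushes$site == "dense"]
  }))
  expect_equal(mean(cis), 0.22, tolerance = 0.05 / 0.22)
})

test_that("microclimate draws centre on the seasonal means and stay in range", {
  cfg <- synthetic_config()
  set.seed(4)
  mc <- gen_microclimate(cfg, "summer", rep(c("clear", "dense"), 5000))
  expect_equal(mean(mc$Sw), 3.4, tolerance = 0.02)    # offsets cancel
  expect_equal(mean(mc$Ts), 32.9, tolerance = 0.02)
  expect_true(all(mc$Sw > 0))
  expect_true(all(mc$VPD >= 0))
  # the published summer site contrast: clear wetter, warmer soil, brighter
  clear <- rep(c(TRUE, FALSE), 5000)
  expect_gt(mean(mc$Sw[clear]), mean(mc$Sw[!clear]))
  expect_gt(mean(mc$Ts[clear]), mean(mc$Ts[!clear]))
  expect_gt(mean(mc$PAR[clear]), mean(mc$PAR[!clear]))
  # zero dispersion collapses every draw onto the mean
  mc0 <- cfg$microclimate
  mc0[grep("_sd$", names(mc0))] <- 0
  cfg0 <- synthetic_config(microclimate = mc0, site_offsets = list())
  d0 <- gen_microclimate(cfg0, "winter", rep("dense", 50))
  expect_true(all(d0$Sw == 16.3) && all(d0$Ts == 11.0) &&
                all(d0$PAR == 458) && all(d0$VPD == 1.6))
  # soil water and soil temperature are negatively coupled
  set.seed(5)
  mcy <- gen_microclimate(cfg, "yearly", rep("dense", 4000))
  expect_lt(cor(mcy$Sw, mcy$Ts), -0.1)
})

test_that("transpiration generation follows the model exactly at zero noise", {
  cfg <- synthetic_config(noise_sd_log = c(summer = 0, autumn = 0,
                                           winter = 0, spring = 0),
                          senescent_noise_sd = 0)
  rows <- data.frame(season = "summer", site = c("dense", "clear"),
                     leaf_type = "green", Sw = c(3, 5), bush_id = c("B1", "B2"))
  got <- gen_transpiration(cfg, rows)
  truth <- esparto_coef("summer", "green")
  expect_equal(got, ep_evaluate(truth, c(3, 5), c(0, 1)))
  rows$leaf_type <- "senescent"
  expect_equal(gen_transpiration(cfg, rows), rep(exp(-3.91), 2))
})

test_that("senescent draws have the published geometric mean", {
  set.seed(6)
  cfg <- synthetic_config()
  rows <- data.frame(season = "summer", site = "dense",
                     leaf_type = "senescent", Sw = 3, bush_id = "B1")
  rows <- rows[rep(1, 1e4), ]
  T_sen <- gen_transpiration(cfg, rows)
  expect_equal(exp(mean(log(T_sen))), 0.0200, tolerance = 0.01)
})

test_that("a full simulated study is reproducible bit for bit", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_study(synthetic_config(seed = 99), dir = d1)
  simulate_study(synthetic_config(seed = 99), dir = d2)
  for (f in c("bushes.csv", "competitors.csv", "soil.csv", "chamber.csv",
              "observations.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  sim3 <- simulate_study(synthetic_config(seed = 100))
  expect_false(identical(read.csv(file.path(d1, "observations.csv"))$T,
                         sim3$observations$T))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the flux stage reconstructs the simulated observations", {
  sim <- simulate_study(synthetic_config(seed = 17))
  obs <- compute_observations(sim$chamber, sim$bushes, sim$competitors,
                              sim$soil)
  expect_equal(nrow(obs), nrow(sim$observations))
  key <- function(d) paste(d$date, d$time_slot, d$bush_id, d$leaf_type)
  m <- match(key(sim$observations), key(obs))
  expect_equal(obs$T[m], sim$observations$T, tolerance = 1e-10)
  expect_equal(obs$Sw[m], sim$observations$Sw, tolerance = 1e-12)
  expect_equal(obs$CI[m], sim$observations$CI, tolerance = 1e-12)
})

test_that("refit quality degrades monotonically with generator noise", {
  set.seed(44)
  truth <- esparto_coef("yearly", "green")
  med_r2 <- vapply(c(0.1, 0.5, 1.0), function(sd_log) {
    r2 <- vapply(1:20, function(i) {
      obs <- make_model_obs(truth, 400, sd_log)
      ep_fit(obs)$R2_adj
    }, numeric(1))
    median(r2)
  }, numeric(1))
  expect_true(all(diff(med_r2) < 0))
})

test_that("the simulated summer reproduces the published sign pattern", {
  sim <- simulate_study(synthetic_config(seed = 33))
  ct <- correlation_table(sim$observations, season = "summer")
  expect_gt(ct$rho["Sw", "T"], 0)
  expect_lt(ct$rho["CI", "Sw"], 0)
})

test_that("a noise-free recovery replicate is exact", {
  r <- recovery_experiment(n_reps = 1L, n_obs = 400L, noise_sd = 0, seed = 3)
  expect_equal(max(abs(r$summary$bias)), 0, tolerance = 1e-8)
  expect_equal(r$support_recovery, 1)
})
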