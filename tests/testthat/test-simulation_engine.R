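# Coupled monthly simulation: accounting, discounting, ensembles,
# equilibrium curves, welfare reporting.

test_that("monthly biomass accounting is exact: end = start + growth/12 -
           fleet-expanded harvest", {
  obj <- default_objects()
  cfg <- small_scenario(noisy = TRUE, horizon_end = 2030, seed = 3)
  r <- run_single(cfg, obj$bio, obj$econ, seed = 99)
  tr <- r$trajectory
  # reconstruct the yearly growth increments from the trajectory
  set.seed(99)
  eps <- stats::rnorm(length(2014:2030), 0, obj$bio$sigma_s)
  x <- cfg$x0
  for (i in seq_len(nrow(tr))) {
    y <- (i - 1) %/% 12 + 1
    if ((i - 1) %% 12 == 0) {
      R <- intrinsic_rate(obj$bio,
                          cfg$seasonal$cui_winter[cfg$seasonal$year ==
                                                    2014 + y - 2],
                          cfg$seasonal$cui_fall[cfg$seasonal$year ==
                                                  2014 + y - 2])
      g_mon <- (logistic_growth(x, R, obj$bio$k) + eps[y]) / 12
    }
    x_end <- x + g_mon - obj$econ$fleet_multiplier * tr$harvest_kt[i]
    expect_equal(max(x_end, 0), tr$ssb_kt[i], tolerance = 1e-12)
    x <- x_end
    if (x < cfg$collapse_threshold_kt) break
  }
})

test_that("an unfished deterministic stock converges to carrying capacity
           and survives the whole horizon", {
  obj <- default_objects()
  econ <- obj$econ
  econ$a0 <- 1e-12          # demand so low the fishery never operates
  # a stable intrinsic rate: the annual-step logistic map converges to K
  # for 0 < R < 2 (the derived default rate ~3.8 is in the chaotic regime
  # of the annual map, see the divergence check below)
  bio <- bio_params(r = 1, k = obj$bio$k, sigma_s = 0)
  cfg <- small_scenario(horizon_end = 2079)
  r <- run_single(cfg, bio, econ, seed = 1)
  expect_false(r$collapsed)
  expect_equal(r$survival_years, 66)
  expect_lt(max(r$trajectory$harvest_kt), 1e-6)
  expect_equal(utils::tail(r$trajectory$ssb_kt, 1), bio$k,
               tolerance = 1e-3)
  # at carrying capacity the default stock is stationary without fishing
  bio_d <- obj$bio; bio_d$sigma_s <- 0
  cfg_k <- small_scenario(horizon_end = 2030)
  cfg_k$x0 <- bio_d$k
  rk <- run_single(cfg_k, bio_d, econ, seed = 1)
  expect_equal(max(abs(rk$trajectory$ssb_kt - bio_d$k)), 0,
               tolerance = 1e-6)
  # from the mean stock, the unfished annual-step map at the derived
  # default rate overshoots K and diverges: the chaotic regime is real
  rd <- run_single(small_scenario(horizon_end = 2030), bio_d, econ,
                   seed = 1)
  expect_gt(max(rd$trajectory$ssb_kt), bio_d$k)
})

test_that("a known interior steady state stays constant under sigma = 0", {
  # flat economics, constant climate: pick x* where annual removals equal
  # annual growth, then verify the trajectory stays at x*
  bio <- bio_params(r = 2, r_cw = 0, r_cf = 0, k = 300, sigma_s = 0)
  econ <- flat_econ(a0 = 30, eta0 = 2, c0 = 10, phi = 0.1, chi = 0)
  econ$fleet_multiplier <- 1
  clim <- toy_climate(2013:2020, sst = 0, cui = 0.3)
  seas <- seasonal_cui(clim)
  cfg0 <- scenario_config(clim, seas, "bau", x0 = 100, n_runs = 1,
                          base_year = 2014, horizon_end = 2020,
                          fuel_trend_monthly = 0,
                          density_trend_monthly = 0, seed = 1)
  # monthly equilibrium is state-independent (chi = 0, no trends): H_m
  w_f <- (1 - econ$subsidy_rate) * cfg0$fuel_base_price
  H_m <- solve_equilibrium(neutral_state(x = 100, w_f = w_f),
                           econ)$harvest_kt
  # annual growth R x (1 - x/K) = 12 H_m at the upper (stable) root
  disc <- sqrt(1 - 4 * 12 * H_m / (2 * 300))
  x_star <- 150 * (1 + disc)
  cfg <- scenario_config(clim, seas, "bau", x0 = x_star, n_runs = 1,
                         base_year = 2014, horizon_end = 2020,
                         fuel_trend_monthly = 0,
                         density_trend_monthly = 0, seed = 1)
  r <- run_single(cfg, bio, econ, seed = 1)
  expect_equal(max(abs(r$trajectory$ssb_kt - x_star)), 0,
               tolerance = 1e-6)
})

test_that("NPV of a constant monthly stream matches the geometric closed
           form and discounting is additive", {
  expect_equal(npv_monthly(rep(1, 12), 0.03),
               (1 - 1.03^-1) / (1 - 1.03^(-1 / 12)))
  expect_equal(npv_monthly(rep(1, 12), 0.03), 11.839, tolerance = 1e-4)
  set.seed(4)
  v <- stats::rnorm(60)
  split <- npv_monthly(v * (seq_along(v) <= 24), 0.03) +
    npv_monthly(v * (seq_along(v) > 24), 0.03)
  expect_equal(npv_monthly(v, 0.03), split, tolerance = 1e-12)
  # a run's reported NPVs equal the discounted trajectory streams
  obj <- default_objects()
  cfg <- small_scenario(horizon_end = 2025)
  r <- run_single(cfg, obj$bio, obj$econ, seed = 5)
  expect_equal(r$npv_fs, npv_monthly(r$trajectory$fs_fcfa, 0.03),
               tolerance = 1e-10)
  expect_equal(r$npv_cs, npv_monthly(r$trajectory$cs_fcfa, 0.03),
               tolerance = 1e-10)
})

test_that("survival is capped at the horizon and collapse is absorbing", {
  obj <- default_objects()
  cfg <- small_scenario(noisy = TRUE, horizon_end = 2079, seed = 8)
  for (s in c(101, 202, 303)) {
    r <- run_single(cfg, obj$bio, obj$econ, seed = s)
    expect_lte(r$survival_years, 66)
    expect_gte(r$survival_years, 0)
    if (r$collapsed) {
      i <- round(r$survival_years * 12)
      post <- r$trajectory[(i + 1):nrow(r$trajectory), ]
      expect_true(all(post$harvest_kt == 0))
      expect_true(all(post$fs_fcfa == 0 & post$cs_fcfa == 0))
    }
  }
})

test_that("ensembles are bit-for-bit reproducible from the master seed and
           degenerate to the single run when sigma = 0", {
  obj <- default_objects()
  cfg <- small_scenario(noisy = TRUE, n_runs = 6, horizon_end = 2040)
  e1 <- run_ensemble(cfg, obj$bio, obj$econ)
  e2 <- run_ensemble(cfg, obj$bio, obj$econ)
  expect_identical(e1$runs, e2$runs)
  expect_true(all(e1$mean_survival_years >= min(e1$runs$survival_years),
                  e1$mean_survival_years <= max(e1$runs$survival_years)))
  bio0 <- obj$bio; bio0$sigma_s <- 0
  e0 <- run_ensemble(cfg, bio0, obj$econ)
  expect_equal(length(unique(e0$runs$survival_years)), 1)
  expect_equal(length(unique(e0$runs$npv_total)), 1)
})

test_that("ensemble means at moderate size agree with a larger reference
           within Monte-Carlo error", {
  obj <- default_objects()
  cfg_s <- small_scenario(noisy = TRUE, n_runs = 60, horizon_end = 2045,
                          seed = 12)
  cfg_l <- small_scenario(noisy = TRUE, n_runs = 300, horizon_end = 2045,
                          seed = 12)
  es <- run_ensemble(cfg_s, obj$bio, obj$econ)
  el <- run_ensemble(cfg_l, obj$bio, obj$econ)
  se <- stats::sd(el$runs$survival_years) / sqrt(cfg_s$n_runs)
  expect_lt(abs(es$mean_survival_years - el$mean_survival_years), 4 * se)
})

test_that("equilibrium-biomass curve: unfished gives K, overwhelming
           pressure gives 0, and the root matches a fine grid scan", {
  obj <- default_objects()
  bio <- obj$bio; bio$sigma_s <- 0
  cfg <- small_scenario(horizon_end = 2030)
  e_none <- obj$econ; e_none$a0 <- 1e-12
  expect_equal(equilibrium_biomass_curve(2015, cfg, e_none, bio),
               bio$k, tolerance = 1e-3)
  e_huge <- obj$econ; e_huge$c0 <- obj$econ$c0 / 50
  expect_equal(equilibrium_biomass_curve(2015, cfg, e_huge, bio), 0)
  x_star <- equilibrium_biomass_curve(2016, cfg, obj$econ, bio)
  expect_gt(x_star, 0)
  # grid-scan oracle around the reported root
  pre <- sardsim:::precompute_monthly(cfg, obj$econ)
  sel <- which(pre$year == 2016)
  y <- (sel[1] - 1) %/% 12 + 1
  R <- intrinsic_rate(bio, pre$cui_w[y], pre$cui_f[y])
  f <- function(x) {
    h <- sum(vapply(sel, function(i)
      sardsim:::solve_eq_fast(pre$a[i], pre$eta[i],
                              pre$ct_num[i] / x^obj$econ$chi,
                              obj$econ$phi)[1], 0))
    logistic_growth(x, R, bio$k) - obj$econ$fleet_multiplier * h
  }
  grid <- seq(bio$k / 2000, bio$k, length.out = 2000)
  fv <- vapply(grid, f, 0)
  down <- which(fv[-2000] > 0 & fv[-1] <= 0)
  expect_gt(length(down), 0)
  expect_lt(abs(grid[max(down)] - x_star), bio$k / 1000)
})

test_that("welfare report converts surpluses to grain baskets as printed", {
  w <- welfare_report(8.77e9, 5.47e9)
  expect_equal(round(w$baskets_per_fisher), 946)
  expect_equal(w$baskets_per_capita, 5.47e9 / (2.4e6 * 1145))
  expect_equal(round(w$baskets_per_capita, 2), 1.99)
  expect_equal(w$total_fcfa, 14.24e9)
  expect_equal(welfare_report(0, 0)$baskets_per_fisher, 0)
})

test_that("decadal rents average undiscounted surplus and zero out extinct
           decades", {
  # constant stream: no change between decades
  traj <- data.frame(year = rep(2014:2043, each = 12),
                     fs_fcfa = 1e6, cs_fcfa = 5e5)
  dr <- decadal_rents(traj, list(c(2014, 2023), c(2024, 2033),
                                 c(2034, 2043)))
  expect_equal(attr(dr, "pct_change"), c(0, 0))
  expect_equal(dr$mean_annual_rent_fcfa, rep(12 * 1.5e6, 3))
  # collapse in 2030: the 2034-2043 decade is zero
  traj2 <- traj
  traj2$fs_fcfa[traj2$year >= 2030] <- 0
  traj2$cs_fcfa[traj2$year >= 2030] <- 0
  dr2 <- decadal_rents(traj2, list(c(2014, 2023), c(2034, 2043)))
  expect_equal(dr2$mean_annual_rent_fcfa[2], 0)
  expect_equal(attr(dr2, "pct_change"), -100)
  # hand-computed two-decade stream
  set.seed(9)
  traj3 <- data.frame(year = rep(2014:2033, each = 12),
                      fs_fcfa = stats::runif(240, 0, 2e6),
                      cs_fcfa = stats::runif(240, 0, 1e6))
  dr3 <- decadal_rents(traj3, list(c(2014, 2023), c(2024, 2033)))
  for (j in 1:2) {
    yrs <- if (j == 1) 2014:2023 else 2024:2033
    sel <- traj3$year %in% yrs
    expect_equal(dr3$mean_annual_rent_fcfa[j],
                 sum(traj3$fs_fcfa[sel] + traj3$cs_fcfa[sel]) / 10)
  }
})

test_that("melt-down accumulates recovered tax revenue, business-as-usual
           does not", {
  obj <- default_objects()
  rb <- run_single(small_scenario("bau", horizon_end = 2025),
                   obj$bio, obj$econ, seed = 31)
  rm_ <- run_single(small_scenario("melt_down", horizon_end = 2025),
                    obj$bio, obj$econ, seed = 31)
  expect_equal(rb$npv_tax_savings, 0)
  expect_gt(rm_$npv_tax_savings, 0)
})
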