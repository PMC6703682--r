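## Monthly coupled simulation of stock and market, 2014-2079 (or until
## collapse): single stochastic runs, reproducible ensembles, deterministic
## equilibrium-biomass curves, and welfare reporting.

#' Scenario configuration for the coupled simulation
#'
#' @param climate A `climate_series` of monthly SST covering at least
#'   `base_year`..`horizon_end`.
#' @param seasonal data.frame `year, cui_winter, cui_fall` covering at least
#'   `base_year - 1`..`horizon_end - 1` (growth in year y uses the indices
#'   of y-1).
#' @param policy `"bau"` or `"melt_down"`.
#' @param x0 Initial spawning stock biomass (kt) at the start of
#'   `base_year`.
#' @param n_runs Ensemble size (default 1000).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param base_year First simulated year (default 2014).
#' @param horizon_end Last simulated year (default 2079).
#' @param collapse_threshold_kt Stock level below which the fishery is
#'   considered collapsed (default 1 kt).
#' @param fuel_base_price World fuel price at t = 0 (FCFA/l).
#' @param fuel_trend_monthly Base monthly world fuel-price trend.
#' @param density_base Population density at t = 0 (persons/km^2).
#' @param density_trend_monthly Base monthly density trend.
#' @param seed Master RNG seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(climate, seasonal, policy = c("bau", "melt_down"),
                            x0 = 199.5, n_runs = 1000, discount_rate = 0.03,
                            base_year = 2014, horizon_end = 2079,
                            collapse_threshold_kt = 1,
                            fuel_base_price = 400,
                            fuel_trend_monthly = 0.002,
                            density_base = 150,
                            density_trend_monthly = 0.002,
                            seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(n_runs >= 1, discount_rate > 0, discount_rate < 1,
            horizon_end > base_year, x0 > 0, collapse_threshold_kt >= 0,
            fuel_base_price > 0, density_base >= 0)
  years <- base_year:horizon_end
  have <- unique(climate$year)
  if (!all(years %in% have))
    stop("climate series missing year(s): ",
         paste(setdiff(years, have), collapse = ", "))
  key <- paste(climate$year, climate$month)
  need <- as.vector(outer(years, 1:12, paste))
  if (!all(need %in% key))
    stop("climate series missing month(s): ",
         paste(utils::head(setdiff(need, key), 12), collapse = "; "))
  lag_years <- (base_year - 1):(horizon_end - 1)
  if (!all(lag_years %in% seasonal$year))
    stop("seasonal CUI table missing year(s): ",
         paste(setdiff(lag_years, seasonal$year), collapse = ", "))
  structure(list(climate = climate, seasonal = seasonal, policy = policy,
                 x0 = x0, n_runs = n_runs, discount_rate = discount_rate,
                 base_year = base_year, horizon_end = horizon_end,
                 collapse_threshold_kt = collapse_threshold_kt,
                 fuel_base_price = fuel_base_price,
                 fuel_trend_monthly = fuel_trend_monthly,
                 density_base = density_base,
                 density_trend_monthly = density_trend_monthly,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Precompute everything that does not depend on biomass or the shock draw:
# per-month unit-cost numerator, demand scale, elasticity, fuel prices and
# tax-saving rates. Returns a list of aligned vectors over the horizon.
precompute_monthly <- function(cfg, econ) {
  years <- cfg$base_year:cfg$horizon_end
  n <- length(years) * 12L
  t <- 0:(n - 1)
  m <- rep(1:12, length(years))
  yr <- rep(years, each = 12)
  key <- paste(cfg$climate$year, cfg$climate$month)
  sst <- cfg$climate$sst_c[match(paste(yr, m), key)]
  fp <- fuel_price_path(cfg$policy, t, cfg$fuel_base_price,
                        cfg$fuel_trend_monthly,
                        subsidy_rate = econ$subsidy_rate,
                        decay_years = econ$trend_decay_years)
  fp_bau <- fuel_price_path("bau", t, cfg$fuel_base_price,
                            cfg$fuel_trend_monthly,
                            subsidy_rate = econ$subsidy_rate,
                            decay_years = econ$trend_decay_years)
  density <- cfg$density_base *
    trend_level(cfg$density_trend_monthly, t, econ$trend_decay_years)
  eta <- demand_elasticity(econ, density)
  if (any(eta <= 1))
    stop("demand elasticity drops to eta <= 1 along the density path")
  a <- econ$a0 * trend_level(econ$g_a, t, econ$trend_decay_years)
  q <- catchability(t, m, sst, econ)
  ct_num <- econ$c0 * trend_level(econ$g_c, t, econ$trend_decay_years) *
    fp$paid^econ$alpha_f / q
  # removed-subsidy share converting fuel spend into exchequer savings
  sav_rate <- (econ$subsidy_rate - fp$subsidy) / (1 - fp$subsidy)
  disc <- (1 + cfg$discount_rate)^(-t / 12)
  seas <- cfg$seasonal[match(years - 1, cfg$seasonal$year), ]
  list(n = n, t = t, m = m, year = yr, sst = sst, a = a, eta = eta,
       ct_num = ct_num, sav_rate = sav_rate, disc = disc,
       cui_w = seas$cui_winter, cui_f = seas$cui_fall, years = years)
}


#' Run one stochastic simulation of the coupled fishery
#'
#' Each year draws one growth shock eps_y ~ N(0, sigma_s); annual net growth
#' is evaluated at the year-start stock with the seasonal upwelling indices
#' of the previous calendar year and spread over the 12 months (linear
#' interpolation of the annual growth, shock included). Each month the
#' open-access equilibrium is solved at the current stock and total
#' removals `fleet_multiplier * H` are subtracted. The run stops when the
#' stock falls below the collapse threshold; collapse is absorbing.
#' Surpluses are discounted monthly at `(1 + r)^(-t/12)`; under the
#' melt-down policy the recovered fuel-tax revenue is accumulated as an
#' additional welfare stream.
#'
#' @param cfg A `scenario_config`.
#' @param bio A `bio_params`.
#' @param econ An `econ_params`.
#' @param seed Integer seed for this run (defaults to `cfg$seed`).
#' @param keep_trajectory Keep the monthly trajectory data.frame?
#' @return Object of class `run_result`: `survival_years` (capped at the
#'   horizon), `collapsed`, `npv_fs`, `npv_cs`, `npv_tax_savings`,
#'   `npv_total` (FCFA), and optionally `trajectory`.
#' @export
run_single <- function(cfg, bio, econ, seed = cfg$seed,
                       keep_trajectory = TRUE) {
  pre <- precompute_monthly(cfg, econ)
  n_years <- length(pre$years)
  set.seed(seed)
  eps <- if (bio$sigma_s > 0) stats::rnorm(n_years, 0, bio$sigma_s)
         else numeric(n_years)
  x <- cfg$x0
  npv_fs <- npv_cs <- npv_tax <- 0
  collapsed <- FALSE
  months_survived <- pre$n
  traj <- if (keep_trajectory) {
    data.frame(year = pre$year, month = pre$m, ssb_kt = NA_real_,
               harvest_kt = 0, price_fcfa_kg = NA_real_, fs_fcfa = 0,
               cs_fcfa = 0, fuel_fcfa = 0)
  } else NULL
  g_mon <- 0
  for (i in seq_len(pre$n)) {
    if ((i - 1L) %% 12L == 0L) {
      y <- (i - 1L) %/% 12L + 1L
      R <- intrinsic_rate(bio, pre$cui_w[y], pre$cui_f[y])
      g_mon <- (logistic_growth(x, R, bio$k) + eps[y]) / 12
    }
    x <- x + g_mon
    H <- 0; price <- NA_real_; fs <- cs <- fuel <- 0
    if (x > 0) {
      ct <- pre$ct_num[i] / x^econ$chi
      hp <- solve_eq_fast(pre$a[i], pre$eta[i], ct, econ$phi)
      H <- hp[1]; price <- hp[2]
      fs <- ct * econ$phi * H^2 * 1e6
      cs <- price * H / (pre$eta[i] - 1) * 1e6
      fuel <- econ$alpha_f * ct * (H + econ$phi * H^2) * 1e6
      x <- x - econ$fleet_multiplier * H
    }
    npv_fs <- npv_fs + pre$disc[i] * fs
    npv_cs <- npv_cs + pre$disc[i] * cs
    npv_tax <- npv_tax + pre$disc[i] * pre$sav_rate[i] * fuel
    if (keep_trajectory) {
      traj$ssb_kt[i] <- max(x, 0)
      traj$harvest_kt[i] <- H
      traj$price_fcfa_kg[i] <- price
      traj$fs_fcfa[i] <- fs
      traj$cs_fcfa[i] <- cs
      traj$fuel_fcfa[i] <- fuel
    }
    if (x < cfg$collapse_threshold_kt) {
      collapsed <- TRUE
      months_survived <- i
      if (keep_trajectory && i < pre$n)
        traj$ssb_kt[(i + 1):pre$n] <- max(x, 0)
      break
    }
  }
  structure(list(
    survival_years = months_survived / 12,
    collapsed = collapsed,
    npv_fs = npv_fs, npv_cs = npv_cs, npv_tax_savings = npv_tax,
    npv_total = npv_fs + npv_cs + npv_tax,
    seed = seed, policy = cfg$policy,
    trajectory = traj), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Run (%s, seed %d): survived %.2f yr%s\n", x$policy, x$seed,
              x$survival_years, if (x$collapsed) " (collapsed)" else ""))
  cat(sprintf("  NPV: FS %.4g, CS %.4g, tax savings %.4g FCFA\n",
              x$npv_fs, x$npv_cs, x$npv_tax_savings))
  invisible(x)
}

#' Run a reproducible Monte-Carlo ensemble
#'
#' Per-run seeds are spawned deterministically from the master seed, so the
#' summary is a pure function of (config, seed) regardless of execution
#' order.
#'
#' @param cfg A `scenario_config` (`cfg$n_runs` runs, master seed
#'   `cfg$seed`).
#' @param bio,econ Parameter objects.
#' @param keep_trajectories Keep per-run monthly trajectories (memory-heavy
#'   for large ensembles)?
#' @return Object of class `ensemble_summary`: mean survival time, mean
#'   NPVs, the per-run table, and the survival-year distribution.
#' @export
run_ensemble <- function(cfg, bio, econ, keep_trajectories = FALSE) {
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, cfg$n_runs)
  runs <- lapply(seeds, function(s)
    run_single(cfg, bio, econ, seed = s,
               keep_trajectory = keep_trajectories))
  tab <- data.frame(
    run = seq_along(runs), seed = seeds,
    survival_years = vapply(runs, `[[`, 0, "survival_years"),
    collapsed = vapply(runs, `[[`, TRUE, "collapsed"),
    npv_fs = vapply(runs, `[[`, 0, "npv_fs"),
    npv_cs = vapply(runs, `[[`, 0, "npv_cs"),
    npv_tax_savings = vapply(runs, `[[`, 0, "npv_tax_savings"),
    npv_total = vapply(runs, `[[`, 0, "npv_total"))
  structure(list(
    policy = cfg$policy, n_runs = cfg$n_runs, seed = cfg$seed,
    mean_survival_years = mean(tab$survival_years),
    collapse_fraction = mean(tab$collapsed),
    mean_npv_fs = mean(tab$npv_fs), mean_npv_cs = mean(tab$npv_cs),
    mean_npv_tax_savings = mean(tab$npv_tax_savings),
    mean_npv_total = mean(tab$npv_total),
    runs = tab,
    trajectories = if (keep_trajectories)
      lapply(runs, `[[`, "trajectory") else NULL),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble (%s): %d runs, master seed %d\n", x$policy,
              x$n_runs, x$seed))
  cat(sprintf("  mean survival %.2f yr (%.0f%% of runs collapsed)\n",
              x$mean_survival_years, 100 * x$collapse_fraction))
  cat(sprintf("  mean NPV: total %.4g (FS %.4g, CS %.4g, tax %.4g) FCFA\n",
              x$mean_npv_total, x$mean_npv_fs, x$mean_npv_cs,
              x$mean_npv_tax_savings))
  invisible(x)
}

#' Deterministic equilibrium-biomass curve for one year
#'
#' For a fixed stock x the annualized harvest is the sum of the 12 monthly
#' open-access equilibria of `year` (times the fleet multiplier); annual
#' growth is the logistic curve at that year's (lagged) upwelling indices.
#' The dynamically stable positive equilibrium is the *rightmost*
#' down-crossing of growth minus harvest on (0, K]; if harvest exceeds
#' growth everywhere the only stable equilibrium is stock zero.
#'
#' @param year Calendar year to evaluate.
#' @param cfg A `scenario_config` supplying climate, fuel and density paths.
#' @param econ,bio Parameter objects.
#' @param n_grid Scan-grid size on (0, K] (default 400; roots are refined
#'   by bisection).
#' @return `x_star` in kt (0 if no positive stable equilibrium).
#' @export
equilibrium_biomass_curve <- function(year, cfg, econ, bio, n_grid = 400) {
  pre <- precompute_monthly(cfg, econ)
  sel <- which(pre$year == year)
  if (!length(sel)) stop("year ", year, " outside the configured horizon")
  y <- (sel[1] - 1L) %/% 12L + 1L
  R <- intrinsic_rate(bio, pre$cui_w[y], pre$cui_f[y])
  annual_harvest <- function(x) {
    h <- 0
    xc <- x^econ$chi
    for (i in sel) {
      h <- h + solve_eq_fast(pre$a[i], pre$eta[i], pre$ct_num[i] / xc,
                             econ$phi)[1]
    }
    econ$fleet_multiplier * h
  }
  f <- function(x) logistic_growth(x, R, bio$k) - annual_harvest(x)
  xs <- seq(bio$k / n_grid, bio$k, length.out = n_grid)
  fv <- vapply(xs, f, 0)
  down <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)
  if (!length(down)) return(0)
  i <- max(down)
  stats::uniroot(f, lower = xs[i], upper = xs[i + 1], tol = 1e-8)$root
}

#' Net present value of a monthly benefit stream
#'
#' Discounts a monthly stream at an annual rate: the value in month t
#' (t = 0 for the first month) is weighted by (1 + rate)^(-t/12). This is
#' the discounting used for all welfare streams in [run_single()], so a
#' run's reported NPVs equal `npv_monthly()` of its trajectory columns.
#'
#' @param values Monthly stream (first element is month 0).
#' @param annual_rate Annual discount rate (default 0.03).
#' @return The discounted sum.
#' @export
npv_monthly <- function(values, annual_rate = 0.03) {
  t <- seq_along(values) - 1
  sum(values * (1 + annual_rate)^(-t / 12))
}

#' Welfare report: grain-basket equivalents of the fishery's surpluses
#'
#' Converts fisher and consumer surplus into purchasing-power equivalents:
#' 5-kg baskets of local grains per fisher and per coastal inhabitant.
#'
#' @param fs_fcfa,cs_fcfa Annual fisher and consumer surplus (FCFA).
#' @param grain_basket_price Price of a 5-kg grain basket (FCFA),
#'   default 1145.
#' @param n_fishers Number of fishers (default 8100).
#' @param population Coastal population (default 2.4e6).
#' @return Named list with `baskets_per_fisher`, `baskets_per_capita`,
#'   `total_fcfa`.
#' @export
welfare_report <- function(fs_fcfa, cs_fcfa, grain_basket_price = 1145,
                           n_fishers = 8100, population = 2.4e6) {
  stopifnot(grain_basket_price > 0, n_fishers > 0, population > 0)
  list(baskets_per_fisher = fs_fcfa / (n_fishers * grain_basket_price),
       baskets_per_capita = cs_fcfa / (population * grain_basket_price),
       total_fcfa = fs_fcfa + cs_fcfa)
}

#' Undiscounted mean annual rents by decade
#'
#' Aggregates a run's monthly fisher + consumer surplus into mean annual
#' undiscounted rents per decade. Years after a collapse contribute zero,
#' so an extinct decade reports a mean of 0.
#'
#' @param trajectory Monthly trajectory data.frame from [run_single()]
#'   (columns `year`, `fs_fcfa`, `cs_fcfa`).
#' @param decades List of `c(first_year, last_year)` pairs.
#' @return data.frame `from, to, mean_annual_rent_fcfa`, plus attribute
#'   `pct_change` with percentage changes between consecutive decades.
#' @export
decadal_rents <- function(trajectory, decades) {
  out <- lapply(decades, function(d) {
    yrs <- d[1]:d[2]
    sel <- trajectory$year %in% yrs
    tot <- sum(trajectory$fs_fcfa[sel] + trajectory$cs_fcfa[sel])
    data.frame(from = d[1], to = d[2],
               mean_annual_rent_fcfa = tot / length(yrs))
  })
  res <- do.call(rbind, out)
  if (nrow(res) > 1) {
    prev <- res$mean_annual_rent_fcfa[-nrow(res)]
    nxt <- res$mean_annual_rent_fcfa[-1]
    attr(res, "pct_change") <- ifelse(prev == 0, NA_real_,
                                      100 * (nxt - prev) / prev)
  }
  res
}
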