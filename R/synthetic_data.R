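## Synthetic inputs: climate-projection archetypes (monthly SST + seasonal
## upwelling draws), fuel/density trend paths, and annual biology datasets
## for estimation-recovery studies. All generators are pure functions of
## (parameters, seed).

#' Climate-projection archetype
#'
#' Parameter bundle describing the statistical traits of a monthly SST
#' projection and the associated seasonal upwelling draws: a linear warming
#' trend, a seasonal cycle, AR(1) monthly noise, and independent yearly
#' Normal draws of the winter and fall coastal upwelling indices with a
#' slight negative trend.
#'
#' @param name Label.
#' @param sst_mean Mean SST (deg C) at the base year.
#' @param sst_trend Warming trend (deg C per decade).
#' @param seasonal_amplitude Amplitude of the SST seasonal cycle (deg C).
#' @param sst_noise_sd Innovation SD of the monthly AR(1) noise (deg C).
#' @param ar1_coeff AR(1) coefficient in [0, 1).
#' @param peak_month Calendar month of the SST seasonal maximum (default 9,
#'   late-summer peak typical of the region).
#' @param cui_winter_mean,cui_fall_mean Mean seasonal CUIs (m^3/s per m
#'   coastline).
#' @param cui_trend Linear trend of both seasonal CUI means per year
#'   (slightly negative by default).
#' @param cui_winter_sd,cui_fall_sd Inter-annual SDs of the seasonal draws.
#' @return Object of class `climate_archetype`.
#' @export
climate_archetype <- function(name = "custom",
                              sst_mean = 24, sst_trend = 0.35,
                              seasonal_amplitude = 3, sst_noise_sd = 0.4,
                              ar1_coeff = 0.5, peak_month = 9,
                              cui_winter_mean = mean(cui_observed_range("winter")),
                              cui_fall_mean = mean(cui_observed_range("fall")),
                              cui_trend = -2e-4,
                              cui_winter_sd = diff(cui_observed_range("winter")) / 4,
                              cui_fall_sd = diff(cui_observed_range("fall")) / 4) {
  stopifnot(sst_noise_sd >= 0, abs(ar1_coeff) < 1,
            cui_winter_sd >= 0, cui_fall_sd >= 0,
            peak_month %in% 1:12)
  structure(list(name = name, sst_mean = sst_mean, sst_trend = sst_trend,
                 seasonal_amplitude = seasonal_amplitude,
                 sst_noise_sd = sst_noise_sd, ar1_coeff = ar1_coeff,
                 peak_month = peak_month,
                 cui_winter_mean = cui_winter_mean,
                 cui_fall_mean = cui_fall_mean, cui_trend = cui_trend,
                 cui_winter_sd = cui_winter_sd, cui_fall_sd = cui_fall_sd),
            class = "climate_archetype")
}

#' The four shipped projection archetypes
#'
#' Two qualitative families are mirrored twice each: "high-trend /
#' high-variance" projections with a stronger warming trend, larger
#' seasonal-cycle amplitude and noisier inter-annual upwelling, and
#' "low-trend / low-variance" projections with milder warming, weaker
#' variability and slightly stronger mean upwelling. Absolute levels are
#' free calibration choices; only the qualitative ordering of the families
#' is meaningful.
#'
#' @return Named list of four `climate_archetype` objects.
#' @export
default_archetypes <- function() {
  hw <- function(name, jitter)
    climate_archetype(name = name, sst_mean = 24.2 + jitter,
                      sst_trend = 0.45, seasonal_amplitude = 3.4,
                      sst_noise_sd = 0.55, ar1_coeff = 0.6,
                      cui_winter_mean = 0.315, cui_fall_mean = 0.175,
                      cui_trend = -3e-4,
                      cui_winter_sd = 0.055, cui_fall_sd = 0.040)
  lw <- function(name, jitter)
    climate_archetype(name = name, sst_mean = 23.8 + jitter,
                      sst_trend = 0.28, seasonal_amplitude = 2.8,
                      sst_noise_sd = 0.35, ar1_coeff = 0.45,
                      cui_winter_mean = 0.345, cui_fall_mean = 0.195,
                      cui_trend = -1.5e-4,
                      cui_winter_sd = 0.030, cui_fall_sd = 0.022)
  list(high_var_a = hw("high_var_a", 0), high_var_b = hw("high_var_b", 0.15),
       low_var_a = lw("low_var_a", 0), low_var_b = lw("low_var_b", 0.1))
}

#' Generate a monthly climate series and seasonal CUI draws
#'
#' SST follows mean + trend + seasonal cosine + AR(1) noise; seasonal CUIs
#' are drawn independently per (year, season) from a Normal around a
#' linearly trending mean, truncated at zero.
#'
#' @param archetype A `climate_archetype`.
#' @param years Vector of calendar years (e.g. `2013:2079`).
#' @param seed RNG seed.
#' @param base_year Year at which trends are zero (default first of
#'   `years`).
#' @return List: `climate` (a `climate_series`, with `cui` filled by a
#'   smooth monthly interpolation of the seasonal draws for completeness)
#'   and `seasonal` (`year, cui_winter, cui_fall`).
#' @export
gen_climate <- function(archetype, years, seed = 1L,
                        base_year = min(years)) {
  stopifnot(length(years) >= 1)
  set.seed(seed)
  a <- archetype
  n <- length(years) * 12L
  yr <- rep(years, each = 12)
  mo <- rep(1:12, length(years))
  innov <- stats::rnorm(n, 0, a$sst_noise_sd)
  noise <- as.numeric(stats::filter(innov, a$ar1_coeff,
                                    method = "recursive"))
  sst <- a$sst_mean + a$sst_trend * (yr - base_year) / 10 +
    a$seasonal_amplitude * cos(2 * pi * (mo - a$peak_month) / 12) + noise
  cw <- pmax(0, stats::rnorm(length(years),
                             a$cui_winter_mean +
                               a$cui_trend * (years - base_year),
                             a$cui_winter_sd))
  cfall <- pmax(0, stats::rnorm(length(years),
                                a$cui_fall_mean +
                                  a$cui_trend * (years - base_year),
                                a$cui_fall_sd))
  seasonal <- data.frame(year = years, cui_winter = cw, cui_fall = cfall)
  # monthly cui: winter level in Jan-Mar, fall level in Oct-Dec, relaxed
  # toward zero upwelling mid-year (Jun-Sep), linear shoulders
  shape <- c(1, 1, 1, 2 / 3, 1 / 3, 0, 0, 0, 0, 1, 1, 1)
  level <- ifelse(mo >= 10, cfall[match(yr, years)],
                  cw[match(yr, years)])
  cui <- level * shape[mo]
  list(climate = climate_series(yr, mo, sst, cui), seasonal = seasonal)
}

#' Generate an annual biology dataset with known parameters
#'
#' Simulates the spawning stock forward under the logistic model with
#' N(0, sigma_s) annual shocks and seasonal CUI draws, recording everything
#' in the estimation schema. The accounting identity
#' growth = delta SSB + catch holds exactly by construction. The generating
#' truth is attached as attribute `truth` for recovery studies.
#'
#' Two catch rules are available. The default, `"escapement"`, is a
#' jittered constant-escapement rule: catch removes the surplus above a
#' log-normally jittered escapement target,
#' `catch_y = max(0, x_{y-1} + g_y - x_target exp(u_y))` with
#' `u_y ~ N(0, escapement_cv)`. It mimics effort tracking abundance, keeps
#' the highly productive stock on a bounded trajectory, and spreads the
#' observed stock sizes across the growth parabola — which is what makes
#' the carrying capacity identifiable. The `"proportional"` rule
#' (`catch_y = catch_fraction x_{y-1}`) is closer to constant-effort
#' harvesting but, at this stock's intrinsic rate, yields chaotic annual
#' dynamics that frequently hit the extinction floor, raising an error.
#'
#' @param bio A `bio_params` (the generating truth).
#' @param n_years Number of years (>= 6).
#' @param x0 Initial SSB (kt).
#' @param catch_rule `"escapement"` (default) or `"proportional"`.
#' @param x_target Escapement target (kt), default `bio$k / 2`.
#' @param escapement_cv SD of the log-normal escapement jitter (default
#'   0.3).
#' @param catch_fraction Harvest rate for the proportional rule.
#' @param archetype A `climate_archetype` supplying the CUI draws.
#' @param seed RNG seed.
#' @param floor_kt Extinction floor (kt): a year whose best achievable
#'   stock (zero catch) falls below this level aborts with an error
#'   suggesting a gentler catch rule.
#' @return data.frame in the estimation schema (see
#'   [annual_bio_records()]), with attribute `truth`.
#' @export
gen_bio_dataset <- function(bio, n_years = 30, x0 = 199.5,
                            catch_rule = c("escapement", "proportional"),
                            x_target = bio$k / 2, escapement_cv = 0.3,
                            catch_fraction = 0.5,
                            archetype = climate_archetype(), seed = 1L,
                            floor_kt = 5) {
  catch_rule <- match.arg(catch_rule)
  stopifnot(n_years >= 6, x0 > 0, catch_fraction >= 0, x_target > 0,
            escapement_cv >= 0)
  set.seed(seed)
  a <- archetype
  yrs <- seq_len(n_years + 1)
  cw <- pmax(0, stats::rnorm(n_years + 1, a$cui_winter_mean, a$cui_winter_sd))
  cfall <- pmax(0, stats::rnorm(n_years + 1, a$cui_fall_mean, a$cui_fall_sd))
  x <- numeric(n_years + 1); x[1] <- x0
  g <- ct <- numeric(n_years + 1)
  for (y in 2:(n_years + 1)) {
    R <- intrinsic_rate(bio, cw[y - 1], cfall[y - 1])
    # a shock that would extinguish the stock even with zero catch is
    # redrawn (the shock distribution is truncated at stock survival)
    for (try_i in 1:100) {
      eps <- if (bio$sigma_s > 0) stats::rnorm(1, 0, bio$sigma_s) else 0
      g[y] <- logistic_growth(x[y - 1], R, bio$k, eps)
      if (x[y - 1] + g[y] >= floor_kt) break
      if (try_i == 100)
        stop("synthetic trajectory went extinct in year ", y - 1,
             " even with zero catch; use a gentler catch rule or smaller ",
             "sigma_s")
    }
    ct[y] <- if (catch_rule == "escapement") {
      # capped below K: leaving more than 0.9 K in the water would push
      # the stock into the overcompensation region of the annual map
      esc <- min(0.9 * bio$k, x_target * exp(stats::rnorm(1, 0, escapement_cv)))
      max(0, x[y - 1] + g[y] - esc)
    } else {
      catch_fraction * x[y - 1]
    }
    xn <- x[y - 1] + g[y] - ct[y]
    if (xn < floor_kt) {
      if (catch_rule == "proportional")
        stop("synthetic trajectory went extinct in year ", y - 1,
             " under the proportional rule; use a gentler catch rule ",
             "(lower catch_fraction)")
      # escapement management never fishes the stock below the floor
      ct[y] <- x[y - 1] + g[y] - floor_kt
      xn <- floor_kt
    }
    x[y] <- xn
  }
  df <- data.frame(year = 2000L + yrs - 1L, ssb_kt = x,
                   catch_kt = ct,
                   cui_winter_lag1 = c(NA, cw[-length(cw)]),
                   cui_fall_lag1 = c(NA, cfall[-length(cfall)]))
  df$ssb_prev_kt <- c(NA, x[-length(x)])
  df$growth_kt <- df$ssb_kt - df$ssb_prev_kt + df$catch_kt
  attr(df, "truth") <- bio
  df
}

#' Deterministic trend path with linear slope decay
#'
#' Builds a monthly path base * trend_level(t): a linear ramp whose slope
#' declines linearly to zero over `decay_years` (the path is flat
#' afterwards). Optional multiplicative log-normal noise.
#'
#' @param base Starting level (> 0).
#' @param monthly_rate Base per-month trend rate.
#' @param years Path length in years.
#' @param decay_years Slope-decay horizon (default 20).
#' @param noise_sd SD of multiplicative log-normal noise (default 0, i.e.
#'   deterministic).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return data.frame `t, value` with `t` in months from 0.
#' @export
gen_trend_path <- function(base, monthly_rate, years, decay_years = 20,
                           noise_sd = 0, seed = 1L) {
  stopifnot(base > 0, years >= 1)
  t <- 0:(years * 12 - 1)
  v <- base * trend_level(monthly_rate, t, decay_years)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v * exp(stats::rnorm(length(t), -noise_sd^2 / 2, noise_sd))
  }
  data.frame(t = t, value = v)
}

#' Write a self-contained demo input bundle
#'
#' Generates the full input set for an end-to-end run — the four climate
#' archetypes as monthly CSV series plus seasonal CUI tables, fuel and
#' density trend paths, and the default biological/economic parameter
#' configuration — into a directory. Byte-identical for identical seeds.
#'
#' @param dir Target directory (must be empty or absent unless
#'   `force = TRUE`).
#' @param seed Master seed.
#' @param years Simulated period (default `2013:2079`).
#' @param force Overwrite a non-empty directory?
#' @return Invisibly, the directory path.
#' @export
demo_bundle <- function(dir, seed = 1L, years = 2013:2079, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("target directory ", dir, " is not empty; use force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arcs <- default_archetypes()
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(arcs))
  for (i in seq_along(arcs)) {
    g <- gen_climate(arcs[[i]], years, seed = sub_seeds[i],
                     base_year = 2014)
    write_climate_csv(g$climate,
                      file.path(dir, paste0("climate_", names(arcs)[i],
                                            ".csv")))
    utils::write.csv(g$seasonal,
                     file.path(dir, paste0("seasonal_cui_",
                                           names(arcs)[i], ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  cfg <- default_config()
  cfg$provenance <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 17)
  utils::write.csv(gen_trend_path(400, 0.002, length(years)),
                   file.path(dir, "fuel_world_price.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(gen_trend_path(150, 0.002, length(years)),
                   file.path(dir, "population_density.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
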