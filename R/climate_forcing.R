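## Wind stress, coastal upwelling index, seasonal aggregation and
## proportional bias correction of model climate series.

#' Bulk-formula wind stress from 10-m wind components
#'
#' Converts 10-m wind components into surface wind stress using the standard
#' bulk formula \eqn{\tau = \rho_a C_d |U| U}, so that the stress vector is
#' parallel to the wind and its magnitude is quadratic in wind speed.
#'
#' @param u10,v10 Eastward and northward 10-m wind components (m/s). Vectors
#'   are recycled to common length.
#' @param rho_air Air density (kg/m^3). Default 1.22.
#' @param drag_coeff Dimensionless drag coefficient. Default 1.3e-3.
#' @return A data.frame with columns `tau_x`, `tau_y` (N/m^2).
#' @examples
#' wind_stress(0, -5)           # pure northerly (equatorward) stress
#' wind_stress(3, 4)$tau_x      # direction (0.6, 0.8), |tau| = 0.03965
#' @export
wind_stress <- function(u10, v10, rho_air = 1.22, drag_coeff = 1.3e-3) {
  n <- max(length(u10), length(v10))
  u10 <- rep_len(u10, n); v10 <- rep_len(v10, n)
  bad <- !is.finite(u10) | !is.finite(v10)
  if (any(bad))
    stop("non-finite wind components at record(s): ",
         paste(which(bad), collapse = ", "))
  stopifnot(rho_air > 0, drag_coeff > 0)
  spd <- sqrt(u10^2 + v10^2)
  data.frame(tau_x = rho_air * drag_coeff * spd * u10,
             tau_y = rho_air * drag_coeff * spd * v10)
}

#' Coastal upwelling index from alongshore wind stress
#'
#' Offshore Ekman volume transport per metre of coastline (the Bakun index):
#' \eqn{CUI = \tau_{eq} / (\rho_{sw} f)} with Coriolis parameter
#' \eqn{f = 2\Omega\sin(\phi)}. On this west-facing coast equatorward
#' (southward) alongshore stress is upwelling-favourable, so the index is
#' positive when `tau_alongshore` points equatorward.
#'
#' @param tau_alongshore Equatorward alongshore wind stress (N/m^2); positive
#'   values are upwelling-favourable, negative values indicate downwelling.
#' @param latitude_deg Latitude in degrees; |latitude| must exceed 2 degrees
#'   so that f is bounded away from zero.
#' @param rho_sw Seawater density (kg/m^3). Default 1025.
#' @return CUI in m^3/s per metre of coastline.
#' @examples
#' ekman_cui(0.03965, 15)  # ~1.025 m^3/s per m coastline
#' @export
ekman_cui <- function(tau_alongshore, latitude_deg, rho_sw = 1025) {
  if (any(abs(latitude_deg) <= 2))
    stop("latitude within 2 degrees of the equator: Coriolis parameter ",
         "too close to zero for the Ekman transport formula")
  omega <- 7.2921e-5
  f <- 2 * omega * sin(latitude_deg * pi / 180)
  tau_alongshore / (rho_sw * abs(f))
}

#' Decompose a wind-stress vector into its equatorward alongshore component
#'
#' The coastline is treated as meridional (north-south, west-facing) by
#' default; `coast_angle_deg` rotates the decomposition counter-clockwise for
#' coastlines that deviate from north-south. The equatorward alongshore
#' component (positive toward the equator in the northern hemisphere) is the
#' upwelling-favourable direction entering [ekman_cui()].
#'
#' @param tau_x,tau_y Stress components (N/m^2).
#' @param coast_angle_deg Coastline rotation from meridional, degrees.
#' @return Equatorward alongshore stress (N/m^2).
#' @export
alongshore_stress <- function(tau_x, tau_y, coast_angle_deg = 0) {
  a <- coast_angle_deg * pi / 180
  # alongshore unit vector for a meridional coast is (0, -1) (equatorward);
  # rotate by the coast angle
  -(-sin(a) * tau_x + cos(a) * tau_y)
}

#' Assemble a monthly climate series
#'
#' Validates and orders a monthly series of sea-surface temperature and
#' coastal upwelling index values.
#'
#' @param year,month Integer vectors; `month` in 1..12.
#' @param sst_c Sea-surface temperature (deg C).
#' @param cui Coastal upwelling index (m^3/s per m coastline); may be
#'   negative (downwelling months).
#' @return A `climate_series` data.frame ordered by (year, month).
#' @export
climate_series <- function(year, month, sst_c, cui) {
  df <- data.frame(year = as.integer(year), month = as.integer(month),
                   sst_c = sst_c, cui = cui)
  if (any(df$month < 1 | df$month > 12)) stop("month outside 1..12")
  df <- df[order(df$year, df$month), , drop = FALSE]
  key <- df$year * 12L + df$month
  if (anyDuplicated(key)) stop("duplicated (year, month) in climate series")
  rownames(df) <- NULL
  class(df) <- c("climate_series", "data.frame")
  df
}

#' Read / write the CSV interchange format for climate series
#'
#' Expected header: `year,month,sst_c,cui` or `year,month,sst_c,u10,v10`;
#' in the latter case CUI is computed from wind stress via the bulk formula
#' and Ekman transport at `latitude_deg`.
#'
#' @param path CSV file path.
#' @param latitude_deg Latitude used when CUI must be derived from winds.
#' @param coast_angle_deg Coastline rotation, see [alongshore_stress()].
#' @return A `climate_series` data.frame.
#' @export
read_climate_csv <- function(path, latitude_deg = 15, coast_angle_deg = 0) {
  df <- utils::read.csv(path)
  need <- c("year", "month", "sst_c")
  if (!all(need %in% names(df)))
    stop("climate CSV must contain columns ", paste(need, collapse = ", "))
  if ("cui" %in% names(df)) {
    cui <- df$cui
  } else if (all(c("u10", "v10") %in% names(df))) {
    tau <- wind_stress(df$u10, df$v10)
    cui <- ekman_cui(alongshore_stress(tau$tau_x, tau$tau_y, coast_angle_deg),
                     latitude_deg)
  } else {
    stop("climate CSV needs either a 'cui' column or 'u10'/'v10' columns: ",
         path)
  }
  climate_series(df$year, df$month, df$sst_c, cui)
}

#' @rdname read_climate_csv
#' @param series A `climate_series`.
#' @export
write_climate_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("year", "month", "sst_c", "cui")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Seasonal upwelling indices for one calendar year
#'
#' Winter is the mean CUI over January-March and fall the mean over
#' October-December of the *same* calendar year. The one-year lag with which
#' these indices enter stock growth is applied downstream by indexing year
#' y-1, not here.
#'
#' @param series A `climate_series`.
#' @param year Calendar year(s); default all years fully covered.
#' @return data.frame `year, cui_winter, cui_fall`.
#' @export
seasonal_cui <- function(series, year = NULL) {
  if (is.null(year)) year <- sort(unique(series$year))
  out <- lapply(year, function(y) {
    season <- function(months) {
      sel <- series$year == y & series$month %in% months
      got <- sort(series$month[sel])
      if (!identical(got, as.integer(months))) {
        miss <- setdiff(months, got)
        stop("missing month(s) for year ", y, ": ",
             paste(miss, collapse = ", "))
      }
      mean(series$cui[sel])
    }
    data.frame(year = y, cui_winter = season(1:3), cui_fall = season(10:12))
  })
  do.call(rbind, out)
}

#' Proportional monthly bias factors between a model and a reference series
#'
#' For each calendar month m the factor is the slope of a regression through
#' the origin of the reference on the model values of that month,
#' \eqn{\hat\beta_m = \sum ref \cdot mod / \sum mod^2} — the proportional
#' ("scaling") flavour of offline bias correction. Non-positive model values
#' are excluded from the fit (a proportional correction is ill-defined across
#' sign changes); a month with no usable pairs gets factor 1 with a warning.
#'
#' @param model,reference `climate_series` objects with an overlapping period
#'   of at least 2 full years.
#' @param variable `"sst_c"` or `"cui"`.
#' @return Named list of class `bias_factors`: numeric `factors[12]`,
#'   the `variable`, and the overlap size.
#' @export
fit_bias_factors <- function(model, reference, variable = c("sst_c", "cui")) {
  variable <- match.arg(variable)
  key_m <- model$year * 12L + model$month
  key_r <- reference$year * 12L + reference$month
  common <- intersect(key_m, key_r)
  if (length(common) < 24)
    stop("model/reference overlap shorter than 2 full years (",
         length(common), " months)")
  mv <- model[[variable]][match(common, key_m)]
  rv <- reference[[variable]][match(common, key_r)]
  mo <- ((common - 1L) %% 12L) + 1L
  factors <- rep(1, 12)
  for (m in 1:12) {
    sel <- mo == m & mv > 0 & is.finite(mv) & is.finite(rv)
    if (!any(sel)) {
      warning("month ", m, ": no usable pairs for proportional fit; factor 1")
      next
    }
    factors[m] <- sum(rv[sel] * mv[sel]) / sum(mv[sel]^2)
  }
  structure(list(factors = factors, variable = variable,
                 n_overlap = length(common)),
            class = "bias_factors")
}

#' Apply monthly bias factors to a model climate series
#'
#' @param model A `climate_series`.
#' @param bias A `bias_factors` object from [fit_bias_factors()].
#' @return The corrected `climate_series`.
#' @export
apply_bias <- function(model, bias) {
  stopifnot(inherits(bias, "bias_factors"))
  if (any(bias$factors <= 0)) stop("bias factors must be positive")
  model[[bias$variable]] <- model[[bias$variable]] * bias$factors[model$month]
  model
}

#' @export
print.bias_factors <- function(x, ...) {
  cat("Proportional monthly bias factors for", x$variable,
      sprintf("(fit on %d overlapping months)\n", x$n_overlap))
  print(round(stats::setNames(x$factors, month.abb), 4))
  invisible(x)
}

# Observed seasonal CUI ranges (m^3/s per m coastline) used by plausibility
# validators and as defaults for the synthetic generators.
cui_observed_range <- function(season = c("winter", "fall")) {
  season <- match.arg(season)
  if (season == "winter") c(0.2509, 0.4103) else c(0.1243, 0.2418)
}
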