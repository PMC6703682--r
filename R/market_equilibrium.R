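## Monthly open-access market equilibrium: iso-elastic inverse demand with
## density-dependent elasticity, CRS Cobb-Douglas harvest technology with
## SST-dependent catchability, quadratic equilibrium cost, and the
## price = marginal-cost closure with fisher/consumer surplus accounting.
##
## Units: harvest and biomass kt; prices FCFA/kg; fuel FCFA/l; surpluses
## FCFA (kt x FCFA/kg x 1e6).

#' Economic parameters of the monthly market model
#'
#' @param a0 Demand scale (FCFA/kg at H = 1 kt, density D = 0 adjustment
#'   aside).
#' @param g_a Monthly linear demand trend (default 0.002 = 0.2 %/month).
#' @param eta0,eta_d Demand elasticity magnitude eta(D) = eta0 + eta_d * D
#'   (D in persons/km^2); eta(D) > 1 is required for finite consumer
#'   surplus.
#' @param alpha_kl,alpha_f Cobb-Douglas output elasticities of the
#'   capital-labour composite and fuel; must sum to 1 (constant returns).
#'   Defaults 0.815 / 0.185.
#' @param chi Biomass output elasticity (default 0.222).
#' @param q0 Catchability scale; the default `NULL` peak-normalizes the
#'   SST response, q0 = exp(b1^2/(4 b2)), so that the SST factor reaches 1
#'   at the optimum temperature.
#' @param g_q Monthly catchability trend (default 0.009 = 0.9 %/month).
#' @param month_dummies Positive multipliers d_1..d_12 encoding harvest
#'   seasonality (spring/winter high, late summer low).
#' @param b1,b2 Linear and quadratic SST coefficients in the exponential
#'   catchability term; b2 < 0 with peak at -b1/(2 b2) = 25.4 deg C by
#'   default.
#' @param c0 Cost scale; g_c monthly cost trend; phi quadratic cost
#'   curvature (>= 0).
#' @param subsidy_rate Proportionate fuel subsidy under business as usual
#'   (default 0.307).
#' @param fleet_multiplier Factor converting modelled purse-seine catches to
#'   total removals (other fleets), default 1.083.
#' @param trend_decay_years Years over which all monthly trends decay
#'   linearly to zero (default 20).
#' @return Object of class `econ_params`.
#' @export
econ_params <- function(a0, g_a = 0.002, eta0, eta_d = 0,
                        alpha_kl = 0.815, alpha_f = 0.185, chi = 0.222,
                        q0 = NULL, g_q = 0.009,
                        month_dummies = rep(1, 12),
                        b1 = NULL, b2 = NULL,
                        c0, g_c = 0.002, phi = 0,
                        subsidy_rate = 0.307, fleet_multiplier = 1.083,
                        trend_decay_years = 20) {
  if (is.null(b2)) b2 <- -1 / 16          # exp(-1) of peak at +/- 4 deg C
  if (is.null(b1)) b1 <- -2 * b2 * 25.4   # peak at 25.4 deg C
  if (is.null(q0)) q0 <- exp(b1^2 / (4 * b2))  # SST factor peaks at 1
  p <- list(a0 = a0, g_a = g_a, eta0 = eta0, eta_d = eta_d,
            alpha_kl = alpha_kl, alpha_f = alpha_f, chi = chi,
            q0 = q0, g_q = g_q, month_dummies = month_dummies,
            b1 = b1, b2 = b2, c0 = c0, g_c = g_c, phi = phi,
            subsidy_rate = subsidy_rate, fleet_multiplier = fleet_multiplier,
            trend_decay_years = trend_decay_years)
  problems <- validate_econ_params(p)
  if (length(problems)) stop(paste(problems, collapse = "\n  "))
  structure(p, class = "econ_params")
}

validate_econ_params <- function(p) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(abs(p$alpha_kl + p$alpha_f - 1) < 1e-12,
      sprintf("alpha_kl + alpha_f must equal 1 (constant returns), got %.6f",
              p$alpha_kl + p$alpha_f))
  chk(p$alpha_f > 0 && p$alpha_kl > 0, "output elasticities must be positive")
  chk(p$b2 < 0, "b2 must be negative (interior SST peak)")
  chk(p$eta0 > 1, sprintf(
    "eta0 must exceed 1 for finite consumer surplus, got %.4f", p$eta0))
  chk(p$eta_d >= 0, "eta_d must be non-negative")
  chk(p$a0 > 0, "a0 must be positive")
  chk(p$q0 > 0, "q0 must be positive")
  chk(p$c0 > 0, "c0 must be positive")
  chk(p$phi >= 0, "phi must be non-negative")
  chk(length(p$month_dummies) == 12 && all(p$month_dummies > 0),
      "month_dummies must be 12 positive multipliers")
  chk(p$chi >= 0, "chi must be non-negative")
  chk(p$subsidy_rate >= 0 && p$subsidy_rate < 1,
      "subsidy_rate must lie in [0, 1)")
  chk(p$fleet_multiplier >= 1, "fleet_multiplier must be >= 1")
  chk(p$trend_decay_years > 0, "trend_decay_years must be positive")
  problems
}

#' @export
print.econ_params <- function(x, ...) {
  cat("Monthly open-access market parameters:\n")
  cat(sprintf("  demand: a0 = %.4g, trend %.2f%%/mo, eta(D) = %.3f + %.4g D\n",
              x$a0, 100 * x$g_a, x$eta0, x$eta_d))
  cat(sprintf("  technology: alpha_kl/alpha_f = %.3f/%.3f, chi = %.3f\n",
              x$alpha_kl, x$alpha_f, x$chi))
  cat(sprintf("  catchability: q0 = %.4g, trend %.2f%%/mo, SST peak %.1f C\n",
              x$q0, 100 * x$g_q, -x$b1 / (2 * x$b2)))
  cat(sprintf("  cost: c0 = %.4g, trend %.2f%%/mo, phi = %.4g\n",
              x$c0, 100 * x$g_c, x$phi))
  cat(sprintf("  policy: subsidy %.1f%%, fleet multiplier %.3f, trends decay over %d yr\n",
              100 * x$subsidy_rate, x$fleet_multiplier, x$trend_decay_years))
  invisible(x)
}

#' Market state at one month
#'
#' @param t Months elapsed since the simulation base month (Jan 2014 = 0).
#' @param m Calendar month 1..12.
#' @param sst_c Sea-surface temperature (deg C).
#' @param x Spawning stock biomass (kt), > 0 for an operable fishery.
#' @param w_f Fuel price paid by fishers (FCFA/l), > 0.
#' @param density Population density (persons/km^2).
#' @return Object of class `market_state`.
#' @export
market_state <- function(t, m, sst_c, x, w_f, density) {
  stopifnot(t >= 0, m %in% 1:12, w_f > 0, x >= 0, density >= 0)
  structure(list(t = t, m = m, sst_c = sst_c, x = x, w_f = w_f,
                 density = density), class = "market_state")
}

#' Linearly decaying trend rate and its cumulative level
#'
#' All monthly trend rates (demand, catchability, cost, fuel, density)
#' decay linearly to zero over `decay_years`: the instantaneous rate at
#' month t is base * max(0, 1 - t/T) with T = 12 * decay_years. The
#' *level* factor applied to a price or productivity is the linear trend
#' "(1 + g t)" with the decaying slope accumulated month by month,
#' 1 + base * sum_(s=0)^(t-1) max(0, 1 - s/T)
#' = 1 + base * (t - t (t-1) / (2 T)) for t <= T and
#' 1 + base * (T + 1)/2 afterwards (the path is flat once the rate has
#' decayed away).
#'
#' @param base_monthly_rate Base per-month rate.
#' @param t Months elapsed (>= 0, integer-valued).
#' @param decay_years Years over which the rate reaches zero. Default 20.
#' @return `trend_decay()`: the effective instantaneous rate at month t;
#'   `trend_level()`: the cumulative trend factor.
#' @export
trend_decay <- function(base_monthly_rate, t, decay_years = 20) {
  stopifnot(all(t >= 0))
  base_monthly_rate * pmax(0, 1 - t / (12 * decay_years))
}

#' @rdname trend_decay
#' @export
trend_level <- function(base_monthly_rate, t, decay_years = 20) {
  stopifnot(all(t >= 0))
  T_ <- 12 * decay_years
  tc <- pmin(t, T_)
  cum <- tc - tc * (tc - 1) / (2 * T_)
  cum[t > T_] <- (T_ + 1) / 2
  1 + base_monthly_rate * cum
}

#' Demand elasticity magnitude at a population density
#' @inheritParams econ_params
#' @param p An `econ_params`.
#' @param density Persons/km^2.
#' @export
demand_elasticity <- function(p, density) p$eta0 + p$eta_d * density

#' Iso-elastic inverse demand
#'
#' p(H) = a0 * trend(t) * H^(-1/eta(D)): decreasing and convex in harvest,
#' with a positive linear time trend on the price level (0.2 %/month by
#' default) that decays over `trend_decay_years`.
#'
#' @param H Harvest (kt), > 0.
#' @param t Months elapsed since base month.
#' @param density Persons/km^2.
#' @param p An `econ_params`.
#' @return Price (FCFA/kg).
#' @export
inverse_demand <- function(H, t, density, p) {
  if (any(H <= 0)) stop("inverse demand requires H > 0 (choke behaviour is ",
                        "handled by the equilibrium solver)")
  eta <- demand_elasticity(p, density)
  p$a0 * trend_level(p$g_a, t, p$trend_decay_years) * H^(-1 / eta)
}

#' Composite catchability multiplier
#'
#' q = q0 * trend(t) * d_m * exp(b1 sst + b2 sst^2); the quadratic
#' exponential peaks at 25.4 deg C under the default coefficients,
#' reflecting the temperature-driven inshore availability of the stock.
#'
#' @param t Months elapsed; `m` calendar month 1..12; `sst_c` deg C.
#' @param m Calendar month.
#' @param sst_c SST (deg C).
#' @param p An `econ_params`.
#' @export
catchability <- function(t, m, sst_c, p) {
  p$q0 * trend_level(p$g_q, t, p$trend_decay_years) * p$month_dummies[m] *
    exp(p$b1 * sst_c + p$b2 * sst_c^2)
}

# scalar open-access equilibrium for demand scale a, elasticity eta, unit
# cost ct and cost curvature phi: root of a H^(-1/eta) = ct (1 + 2 phi H),
# bisected in log harvest for uniform relative precision. The root is
# bracketed by Hc = min(H0, H1), where H0 crosses the flat cost component
# and H1 the quadratic one; the full marginal cost lies between each
# component and its double, so H* is within a factor 2^eta below Hc.
# Returns c(H, price).
solve_eq_fast <- function(a, eta, ct, phi) {
  H0 <- (a / ct)^eta
  if (phi == 0) return(c(H0, ct))
  H1 <- (a / (2 * ct * phi))^(eta / (eta + 1))
  u_hi <- log(min(H0, H1))
  g <- function(u) a * exp(-u / eta) - ct * (1 + 2 * phi * exp(u))
  # the analytic bracket can be off by rounding at the endpoints: widen
  while (g(u_hi) > 0) u_hi <- u_hi + 1
  u_lo <- u_hi - 3
  for (i in 1:200) {
    if (g(u_lo) > 0) break
    u_lo <- u_lo - 3
  }
  u <- stats::uniroot(g, lower = u_lo, upper = u_hi, tol = 1e-13,
                      maxiter = 2000)$root
  H <- exp(u)
  c(H, a * exp(-u / eta))
}

# unit cost c-tilde: marginal cost at H -> 0. Fuel enters with exponent
# alpha_f (Shephard), catchability and biomass reduce cost multiplicatively.
unit_cost <- function(state, p) {
  if (state$x <= 0) stop("biomass is zero: fishery inoperable")
  q <- catchability(state$t, state$m, state$sst_c, p)
  p$c0 * trend_level(p$g_c, state$t, p$trend_decay_years) *
    state$w_f^p$alpha_f / (q * state$x^p$chi)
}

#' Marginal and total harvesting cost
#'
#' The reduced-form equilibrium cost function is quadratic in harvest:
#' C(H) = ctilde * (H + phi H^2) with
#' ctilde = c0 * trend(t) * w_f^alpha_f / (q * x^chi), so
#' MC(H) = ctilde * (1 + 2 phi H). The fuel-price elasticity of cost is
#' alpha_f and the biomass elasticity is -chi at every state.
#'
#' @param H Harvest (kt), >= 0.
#' @param state A `market_state`.
#' @param p An `econ_params`.
#' @return `marginal_cost()`: MC in FCFA/kg; `total_cost()`: C(H) in
#'   kt * FCFA/kg units (multiply by 1e6 for FCFA).
#' @export
marginal_cost <- function(H, state, p) {
  stopifnot(all(H >= 0))
  unit_cost(state, p) * (1 + 2 * p$phi * H)
}

#' @rdname marginal_cost
#' @export
total_cost <- function(H, state, p) {
  stopifnot(all(H >= 0))
  unit_cost(state, p) * (H + p$phi * H^2)
}

#' Fuel share of minimized Cobb-Douglas cost
#'
#' Solves the two-input cost minimization min w_kl*KL + w_f*F subject to
#' KL^alpha_kl * F^alpha_f = H for a constant-returns Cobb-Douglas
#' technology, and returns fuel expenditure as a share of total cost. By
#' Shephard's lemma the share equals alpha_f for all prices and output
#' levels.
#'
#' @param alpha_kl,alpha_f Output elasticities, must sum to 1.
#' @param w_kl,w_f Input prices, > 0.
#' @param H Output level, > 0.
#' @return Fuel cost share (dimensionless).
#' @export
cobb_douglas_cost_share <- function(alpha_kl, alpha_f, w_kl, w_f, H = 1) {
  if (abs(alpha_kl + alpha_f - 1) > 1e-12)
    stop("output elasticities must sum to 1 (constant returns to scale)")
  stopifnot(w_kl > 0, w_f > 0, H > 0, alpha_kl > 0, alpha_f > 0)
  # interior optimum: w_f F / (w_kl KL) = alpha_f / alpha_kl
  #  => KL = H (alpha_kl w_f / (alpha_f w_kl))^alpha_f,
  #     F  = H (alpha_f w_kl / (alpha_kl w_f))^alpha_kl
  kl <- H * (alpha_kl * w_f / (alpha_f * w_kl))^alpha_f
  f <- H * (alpha_f * w_kl / (alpha_kl * w_f))^alpha_kl
  (w_f * f) / (w_kl * kl + w_f * f)
}

#' Solve the monthly open-access equilibrium
#'
#' Finds the harvest H* at which the iso-elastic inverse demand equals the
#' marginal cost of the quadratic equilibrium cost function. Demand is
#' strictly decreasing with p -> Inf as H -> 0 and MC is non-decreasing, so
#' the crossing is unique and strictly positive whenever the stock is
#' fishable. Surpluses follow in closed form: FS = p H - C(H) =
#' ctilde * phi * H^2 (rents to inelastically supplied capital and labour)
#' and CS = p H / (eta - 1).
#'
#' @param state A `market_state`.
#' @param p An `econ_params`.
#' @return List of class `equilibrium_outcome`: `harvest_kt`,
#'   `price_fcfa_kg`, `fisher_surplus_fcfa`, `consumer_surplus_fcfa`,
#'   `fuel_expenditure_fcfa`, `eta`.
#' @export
solve_equilibrium <- function(state, p) {
  eta <- demand_elasticity(p, state$density)
  if (eta <= 1)
    stop("demand elasticity eta(D) = ", round(eta, 4),
         " must exceed 1 for finite consumer surplus")
  if (state$x <= 0) {
    out <- list(harvest_kt = 0, price_fcfa_kg = NA_real_,
                fisher_surplus_fcfa = 0, consumer_surplus_fcfa = 0,
                fuel_expenditure_fcfa = 0, eta = eta)
    class(out) <- "equilibrium_outcome"
    return(out)
  }
  ct <- unit_cost(state, p)
  a <- p$a0 * trend_level(p$g_a, state$t, p$trend_decay_years)
  hp <- solve_eq_fast(a, eta, ct, p$phi)
  H <- hp[1]
  price <- hp[2]
  fs <- ct * p$phi * H^2          # p H - C(H) with p = MC(H)
  cs <- price * H / (eta - 1)
  cost <- total_cost(H, state, p)
  out <- list(harvest_kt = H, price_fcfa_kg = price,
              fisher_surplus_fcfa = fs * 1e6,
              consumer_surplus_fcfa = cs * 1e6,
              fuel_expenditure_fcfa = p$alpha_f * cost * 1e6,
              eta = eta)
  class(out) <- "equilibrium_outcome"
  out
}

#' @export
print.equilibrium_outcome <- function(x, ...) {
  cat(sprintf(
    "Open-access equilibrium: H = %.3f kt at p = %.1f FCFA/kg\n",
    x$harvest_kt, x$price_fcfa_kg))
  cat(sprintf("  fisher surplus   %12.4g FCFA\n", x$fisher_surplus_fcfa))
  cat(sprintf("  consumer surplus %12.4g FCFA\n", x$consumer_surplus_fcfa))
  cat(sprintf("  fuel expenditure %12.4g FCFA\n", x$fuel_expenditure_fcfa))
  invisible(x)
}

#' Fuel price path under a policy scenario
#'
#' The unsubsidized world price follows a linear trend whose slope decays to
#' zero over the configured horizon. Under business as usual (BAU) fishers
#' pay (1 - 0.307) of the world price throughout. Under the "melt-down"
#' reform the tax exemption is phased out linearly from January 2015 until
#' it is fully abolished at the end of 2029, after which fishers pay the
#' world price.
#'
#' @param scenario `"bau"` or `"melt_down"`.
#' @param t Months since January 2014 (vectorized).
#' @param base_price World fuel price at t = 0 (FCFA/l).
#' @param monthly_rate Base monthly world-price trend.
#' @param subsidy_rate BAU subsidy rate (default 0.307).
#' @param decay_years Trend-decay horizon in years.
#' @param phase_out_start,phase_out_end Months (since Jan 2014) delimiting
#'   the linear subsidy phase-out: defaults 12 (Jan 2015) and 192
#'   (Dec 2029), i.e. 15 years.
#' @return List: `world` (unsubsidized price), `paid` (price fishers pay),
#'   `subsidy` (effective rate at t).
#' @export
fuel_price_path <- function(scenario = c("bau", "melt_down"), t,
                            base_price, monthly_rate = 0,
                            subsidy_rate = 0.307, decay_years = 20,
                            phase_out_start = 12, phase_out_end = 192) {
  scenario <- match.arg(scenario)
  stopifnot(all(t >= 0), base_price > 0)
  world <- base_price * trend_level(monthly_rate, t, decay_years)
  s <- if (scenario == "bau") {
    rep(subsidy_rate, length(t))
  } else {
    frac <- pmin(1, pmax(0, (t - phase_out_start) /
                              (phase_out_end - phase_out_start)))
    subsidy_rate * (1 - frac)
  }
  list(world = world, paid = (1 - s) * world, subsidy = s)
}

#' Calibrate the free economic parameters to a base-year outcome
#'
#' The demand/cost scale parameters (a0, c0, phi, eta0) are not published;
#' they are pinned so that the base-month equilibrium at a reference state
#' reproduces a target monthly harvest, price, and annual fisher and
#' consumer surplus. Given (H, p) the curvature follows from
#' FS: phi = FS / (H (p H - 2 FS)); the unit cost from p = ctilde(1+2 phi H);
#' eta from CS: eta = 1 + p H / CS; and a0 from the demand curve at (H, p).
#'
#' @param state Reference `market_state` (t = 0).
#' @param H_kt,price_fcfa_kg Target monthly equilibrium.
#' @param fs_annual_fcfa,cs_annual_fcfa Target annual surpluses (FCFA).
#' @param ... Remaining [econ_params()] arguments (trends, dummies, ...).
#' @return A calibrated `econ_params` with attribute
#'   `provenance = "calibrated"`.
#' @export
calibrate_econ_params <- function(state, H_kt, price_fcfa_kg,
                                  fs_annual_fcfa, cs_annual_fcfa, ...) {
  H <- H_kt; pr <- price_fcfa_kg
  fs_m <- fs_annual_fcfa / 12 / 1e6   # kt * FCFA/kg units
  cs_m <- cs_annual_fcfa / 12 / 1e6
  if (pr * H <= 2 * fs_m)
    stop("fisher-surplus target exceeds half of revenue: ",
         "quadratic-cost closure cannot reproduce it")
  phi <- fs_m / (H * (pr * H - 2 * fs_m))
  ct <- pr / (1 + 2 * phi * H)
  eta <- 1 + pr * H / cs_m
  dots <- list(...)
  eta_d <- if (!is.null(dots$eta_d)) dots$eta_d else 0
  dots$eta_d <- NULL
  eta0 <- eta - eta_d * state$density
  a0 <- pr * H^(1 / eta)   # t = 0: trend factor 1
  args <- c(list(a0 = a0, eta0 = eta0, eta_d = eta_d, c0 = 1, phi = phi),
            dots)
  p <- do.call(econ_params, args)
  # back out c0 so that unit_cost at the reference state equals ct
  p$c0 <- ct / (unit_cost(state, p) / p$c0)
  attr(p, "provenance") <- "calibrated"
  p
}
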