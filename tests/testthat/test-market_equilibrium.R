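# Demand, technology, cost, and the monthly open-access equilibrium.

test_that("inverse demand is iso-elastic with the configured monthly price
           trend", {
  p <- flat_econ(a0 = 100, eta0 = 2, g_a = 0.002)
  expect_equal(inverse_demand(4, 0, 0, p) / inverse_demand(1, 0, 0, p),
               0.5)
  expect_equal(inverse_demand(1, 1, 0, p) / inverse_demand(1, 0, 0, p),
               1.002)
  expect_error(inverse_demand(0, 0, 0, p), "H > 0")
  # convexity: positive second difference over an H grid
  set.seed(13)
  for (i in 1:10) {
    pp <- flat_econ(a0 = exp(stats::runif(1, 2, 6)),
                    eta0 = stats::runif(1, 1.2, 8))
    H <- sort(stats::runif(1, 1, 50) + c(0, 1, 2))
    d2 <- inverse_demand(H[3], 0, 0, pp) - 2 * inverse_demand(H[2], 0, 0, pp) +
      inverse_demand(H[1], 0, 0, pp)
    expect_gt(d2, 0)
  }
})

test_that("catchability peaks at 25.4 degrees, grows 0.9% in the first
           month, and is symmetric about the peak", {
  p <- econ_params(a0 = 100, eta0 = 2, c0 = 1)
  peak <- stats::optimize(function(s) catchability(0, 1, s, p),
                          c(15, 35), maximum = TRUE)$maximum
  expect_equal(peak, 25.4, tolerance = 1e-4)
  expect_equal(catchability(1, 3, 24, p) / catchability(0, 3, 24, p),
               1.009)
  for (d in c(0.5, 2, 4))
    expect_equal(catchability(0, 1, 25.4 + d, p),
                 catchability(0, 1, 25.4 - d, p))
})

test_that("marginal cost has fuel elasticity 0.185 and biomass elasticity
           -0.222 at any state", {
  p <- econ_params(a0 = 100, eta0 = 2, c0 = 3, phi = 0.05)
  st <- market_state(t = 7, m = 4, sst_c = 24, x = 150, w_f = 300,
                     density = 100)
  eps <- 1e-6
  up <- market_state(t = 7, m = 4, sst_c = 24, x = 150,
                     w_f = 300 * (1 + eps), density = 100)
  el_w <- log(marginal_cost(10, up, p) / marginal_cost(10, st, p)) /
    log(1 + eps)
  expect_equal(el_w, 0.185, tolerance = 1e-5)
  upx <- market_state(t = 7, m = 4, sst_c = 24, x = 150 * (1 + eps),
                      w_f = 300, density = 100)
  el_x <- log(marginal_cost(10, upx, p) / marginal_cost(10, st, p)) /
    log(1 + eps)
  expect_equal(el_x, -0.222, tolerance = 1e-5)
  # phi = 0: flat marginal cost; total cost is the integral of MC
  p0 <- flat_econ(phi = 0)
  expect_equal(marginal_cost(5, neutral_state(), p0),
               marginal_cost(50, neutral_state(), p0))
  pq <- flat_econ(phi = 0.1)
  H <- 7
  expect_equal(total_cost(H, neutral_state(), pq),
               stats::integrate(function(h)
                 marginal_cost(h, neutral_state(), pq), 0, H)$value,
               tolerance = 1e-8)
  expect_error(marginal_cost(1, neutral_state(x = 0), p0), "inoperable")
})

test_that("Cobb-Douglas fuel cost share equals the fuel output elasticity
           independent of prices, and matches a numeric minimizer", {
  expect_equal(cobb_douglas_cost_share(0.815, 0.185, 2, 3, 1), 0.185)
  expect_equal(cobb_douglas_cost_share(0.5, 0.5, 17, 0.3, 5), 0.5)
  set.seed(17)
  for (i in 1:5) {
    w_kl <- exp(stats::runif(1, -1, 3)); w_f <- exp(stats::runif(1, -1, 3))
    H <- exp(stats::runif(1, -1, 2))
    share <- cobb_douglas_cost_share(0.815, 0.185, w_kl, w_f, H)
    # brute-force: minimize cost over KL with F implied by the isoquant
    cost <- function(kl) w_kl * kl + w_f * (H / kl^0.815)^(1 / 0.185)
    kl_star <- stats::optimize(cost, c(1e-4, 1e4 * H),
                               tol = 1e-12)$minimum
    f_star <- (H / kl_star^0.815)^(1 / 0.185)
    expect_equal(share, w_f * f_star / cost(kl_star), tolerance = 1e-6)
  }
  expect_error(cobb_douglas_cost_share(0.815, 0.2, 1, 1, 1),
               "sum to 1")
})

test_that("flat-cost equilibrium matches the closed form", {
  p <- flat_econ(a0 = 100, eta0 = 2, c0 = 10, phi = 0)
  out <- solve_equilibrium(neutral_state(), p)
  expect_equal(out$harvest_kt, 100)
  expect_equal(out$price_fcfa_kg, 10)
  expect_equal(out$fisher_surplus_fcfa, 0)
  expect_equal(out$consumer_surplus_fcfa, 10 * 100 / (2 - 1) * 1e6)
})

test_that("equilibrium satisfies the surplus identities and comparative
           statics on random admissible states", {
  set.seed(19)
  for (i in 1:40) {
    d <- draw_admissible()
    out <- solve_equilibrium(d$state, d$econ)
    expect_gt(out$harvest_kt, 0)
    expect_gte(out$fisher_surplus_fcfa, 0)
    expect_gte(out$consumer_surplus_fcfa, 0)
    # CS * (eta - 1) = p H exactly
    expect_equal(out$consumer_surplus_fcfa * (out$eta - 1),
                 out$price_fcfa_kg * out$harvest_kt * 1e6,
                 tolerance = 1e-12)
    # fuel share of total cost is alpha_f to 1e-9
    tc <- total_cost(out$harvest_kt, d$state, d$econ) * 1e6
    expect_equal(out$fuel_expenditure_fcfa / tc, d$econ$alpha_f,
                 tolerance = 1e-9)
    # at H > 0 the price equals marginal cost
    expect_equal(out$price_fcfa_kg,
                 marginal_cost(out$harvest_kt, d$state, d$econ),
                 tolerance = 1e-6)
    # comparative statics, strict
    s <- d$state
    up_x <- market_state(s$t, s$m, s$sst_c, s$x * 1.2, s$w_f, s$density)
    expect_gt(solve_equilibrium(up_x, d$econ)$harvest_kt, out$harvest_kt)
    up_w <- market_state(s$t, s$m, s$sst_c, s$x, s$w_f * 2, s$density)
    out_w <- solve_equilibrium(up_w, d$econ)
    expect_lt(out_w$harvest_kt, out$harvest_kt)
    expect_gt(out_w$price_fcfa_kg, out$price_fcfa_kg)
    eq <- d$econ; eq$q0 <- eq$q0 * 1.5
    expect_gt(solve_equilibrium(s, eq)$harvest_kt, out$harvest_kt)
    ec <- d$econ; ec$c0 <- ec$c0 * 2
    expect_lt(solve_equilibrium(s, ec)$harvest_kt, out$harvest_kt)
  }
})

test_that("demand minus marginal cost changes sign exactly once on a log
           grid (equilibrium uniqueness)", {
  set.seed(23)
  for (i in 1:20) {
    d <- draw_admissible()
    a <- d$econ$a0 * trend_level(d$econ$g_a, d$state$t)
    eta <- demand_elasticity(d$econ, d$state$density)
    H <- exp(seq(log(1e-8), log(1e6), length.out = 4000))
    gap <- inverse_demand(H, d$state$t, d$state$density, d$econ) -
      marginal_cost(H, d$state, d$econ)
    expect_equal(sum(diff(sign(gap)) != 0), 1)
  }
})

test_that("rising population density makes demand more elastic and damps
           the price response to a biomass change", {
  p <- econ_params(a0 = 200, eta0 = 3, eta_d = 0.01, c0 = 5, phi = 0.05,
                   chi = 0.222)
  resp <- function(D) {
    s1 <- market_state(0, 1, 24, 150, 300, D)
    s2 <- market_state(0, 1, 24, 180, 300, D)
    o1 <- solve_equilibrium(s1, p); o2 <- solve_equilibrium(s2, p)
    abs(log(o2$price_fcfa_kg / o1$price_fcfa_kg) / log(180 / 150))
  }
  expect_lt(resp(300), resp(50))
})

test_that("fuel price scenarios: equal at the base month, linear phase-out,
           and the post-2030 price ratio", {
  expect_equal(fuel_price_path("bau", 0, 400)$paid,
               fuel_price_path("melt_down", 0, 400)$paid)
  # midpoint of the 2015-2029 phase-out: half the subsidy remains
  mid <- (12 + 192) / 2
  expect_equal(fuel_price_path("melt_down", mid, 400)$subsidy, 0.307 / 2)
  # after full abolition the melt-down price exceeds BAU by 1/(1-0.307)
  r <- fuel_price_path("melt_down", 200, 400, 0.001)$paid /
    fuel_price_path("bau", 200, 400, 0.001)$paid
  expect_equal(r, 1 / (1 - 0.307), tolerance = 1e-12)
  expect_equal(1 / (1 - 0.307), 1.4430, tolerance = 1e-4)
})

test_that("trend rates decay linearly to zero and the level equals the
           closed-form cumulative sum", {
  expect_equal(trend_decay(0.009, 0), 0.009)
  expect_equal(trend_decay(0.009, 240), 0)
  expect_equal(trend_decay(0.009, 120), 0.0045)
  # level = 1 + g * sum_{s<t} (1 - s/T): check against an explicit sum
  g <- 0.002; T_ <- 240
  for (t in c(1, 7, 120, 240, 241, 500)) {
    s <- 0:(t - 1)
    expect_equal(trend_level(g, t),
                 1 + g * sum(pmax(0, 1 - s / T_)))
  }
  expect_equal(trend_level(g, 240), trend_level(g, 241))
})

test_that("parameter validation rejects inadmissible economics", {
  expect_error(econ_params(a0 = 1, eta0 = 0.9, c0 = 1), "eta0")
  expect_error(econ_params(a0 = 1, eta0 = 2, c0 = 1, alpha_kl = 0.8,
                           alpha_f = 0.3), "alpha_kl")
  expect_error(econ_params(a0 = 1, eta0 = 2, c0 = 1, b2 = 0.1), "b2")
  expect_error(solve_equilibrium(neutral_state(),
                                 flat_econ(eta0 = 2, eta_d = 0)),
               NA)
  # an elasticity at or below 1 makes consumer surplus infinite
  p <- flat_econ(eta0 = 1.5)
  p$eta0 <- 0.9   # bypass the constructor to probe the solver's own guard
  expect_error(solve_equilibrium(neutral_state(), p), "finite")
})
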