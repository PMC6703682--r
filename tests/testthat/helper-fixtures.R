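# Shared fixtures built in code.

# A toy monthly climate series with known per-month values.
toy_climate <- function(years, sst = 24, cui = 0.3) {
  n <- length(years) * 12
  climate_series(rep(years, each = 12), rep(1:12, length(years)),
                 rep_len(sst, n), rep_len(cui, n))
}

# Economic parameters with every trend switched off and a flat SST response
# scale — convenient for closed-form checks.
flat_econ <- function(a0 = 100, eta0 = 2, c0 = 10, phi = 0, chi = 0,
                      g_a = 0, g_q = 0, g_c = 0, ...) {
  econ_params(a0 = a0, eta0 = eta0, c0 = c0, phi = phi, chi = chi,
              g_a = g_a, g_q = g_q, g_c = g_c, b1 = 0, b2 = -1e-9,
              q0 = 1, ...)
}

# A market state at the base month with neutral climate (sst 0 so the flat
# econ catchability factor is exactly 1).
neutral_state <- function(x = 1, w_f = 1, density = 0, t = 0, m = 1,
                          sst = 0) {
  market_state(t = t, m = m, sst_c = sst, x = x, w_f = w_f,
               density = density)
}

# Random admissible econ/state draws for property tests.
draw_admissible <- function() {
  econ <- econ_params(a0 = exp(stats::runif(1, 3, 6)),
                      eta0 = stats::runif(1, 1.5, 9),
                      eta_d = stats::runif(1, 0, 0.005),
                      c0 = exp(stats::runif(1, 1, 5)),
                      phi = stats::runif(1, 0, 0.2),
                      chi = 0.222)
  state <- market_state(t = sample(0:300, 1), m = sample(1:12, 1),
                        sst_c = stats::runif(1, 18, 30),
                        x = exp(stats::runif(1, log(5), log(400))),
                        w_f = exp(stats::runif(1, log(50), log(1500))),
                        density = stats::runif(1, 50, 400))
  list(econ = econ, state = state)
}

# Default simulation inputs at reduced ensemble size (deterministic climate
# unless noise is requested).
small_scenario <- function(policy = "bau", seed = 1, n_runs = 5,
                           noisy = FALSE, horizon_end = 2079) {
  arc <- default_archetypes()$low_var_a
  if (!noisy) {
    arc$sst_noise_sd <- 0; arc$cui_winter_sd <- 0; arc$cui_fall_sd <- 0
  }
  g <- gen_climate(arc, 2013:horizon_end, seed = seed, base_year = 2014)
  scenario_config(g$climate, g$seasonal, policy = policy, n_runs = n_runs,
                  horizon_end = horizon_end, seed = seed)
}

default_objects <- function() default_params()
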