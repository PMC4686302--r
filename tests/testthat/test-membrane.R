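## independent relaxation oracle: integrate dx/dt = a(1-x) - b x with a
## fine explicit scheme and extract the time constant from the decay
relax_tau <- function(ainf, tau, x0 = 0.9, t_end = 3 * tau) {
  dt <- tau / 2000
  x <- x0
  ts <- seq(dt, t_end, by = dt)
  xs <- numeric(length(ts))
  for (k in seq_along(ts)) {
    x <- x + dt * (ainf - x) / tau
    xs[k] <- x
  }
  fit <- stats::lm(log(abs(xs - ainf)) ~ ts)
  -1 / coef(fit)[2]
}

test_that("NaV rates: steady states, limits and relaxation", {
  v <- seq(-120, 80, by = 0.5)
  r <- nav_rates(v)
  for (nm in names(r)) expect_true(all(r[[nm]] >= 0))
  minf <- r$alpha_m / (r$alpha_m + r$beta_m)
  hinf <- r$alpha_h / (r$alpha_h + r$beta_h)
  expect_true(all(minf >= 0 & minf <= 1))
  expect_true(all(hinf >= 0 & hinf <= 1))
  ## hyperpolarized limits: m closed, h available
  expect_lt(minf[1], 1e-4)
  expect_gt(hinf[1], 0.999)
  ## m_inf = 0.5 where alpha_m = beta_m
  vhalf <- uniroot(function(x) {
    z <- nav_rates(x); z$alpha_m - z$beta_m
  }, c(-60, 20))$root
  z <- nav_rates(vhalf)
  expect_equal(z$alpha_m / (z$alpha_m + z$beta_m), 0.5, tolerance = 1e-6)
  ## removable singularities are filled continuously
  kd <- tj_kinetics()
  for (eps in c(-1e-9, 1e-9)) {
    za <- nav_rates(7.1 + kd$v_ref + eps)
    expect_equal(za$alpha_m, 0.55 * 4, tolerance = 1e-4)
  }
  ## voltage-clamp relaxation matches the analytic tau within 1%
  z <- nav_rates(vhalf)
  tau_m <- 1 / (z$alpha_m + z$beta_m)
  expect_equal(relax_tau(0.5, tau_m), tau_m, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("KDR gates: half-voltages, slopes, direction", {
  r <- kdr_rates(-32)
  expect_equal(r$n_inf, 0.5, tolerance = 1e-9)
  expect_equal(kdr_rates(-61)$l_inf, 0.5, tolerance = 1e-9)
  ## n activates, l inactivates with depolarization
  expect_gt(kdr_rates(-20)$n_inf, kdr_rates(-44)$n_inf)
  v <- seq(-120, 80, by = 1)
  rr <- kdr_rates(v)
  expect_true(all(diff(rr$n_inf) > 0))
  expect_true(all(diff(rr$l_inf) < 0))
  expect_true(all(rr$tau_n > 0) && all(rr$tau_l > 0))
  ## printed exponent slope: 0.1883/mV for the activation alpha
  expect_equal(5 * drgtj:::KDR_F_RT, 0.18826, tolerance = 1e-3)
})

test_that("KCNQ gate matches the printed two-state kinetics", {
  expect_equal(kcnq_rates(-35)$m_inf, 0.5)
  expect_equal(kcnq_rates(-35)$tau_m, 1000 / (3.3 * 2) / 3.54, tolerance = 1e-12)
  expect_equal(kcnq_rates(-35)$tau_m, 42.8, tolerance = 1e-3)
  expect_lt(kcnq_rates(-200)$m_inf, 1e-7)
  expect_gt(kcnq_rates(200)$m_inf, 1 - 1e-7)
  ## tau peaks at the half-activation voltage
  v <- seq(-100, 40, by = 1)
  tt <- kcnq_rates(v)$tau_m
  expect_equal(v[which.max(tt)], -35)
  ## current density at -30 mV for 0.2 mS/cm^2, per capacitance:
  ## within a factor 1.3 of 6 pA/pF
  i30 <- 0.2 * kcnq_rates(-30)$m_inf * (-30 - (-90))   # uA/cm^2 == pA/pF
  expect_lt(max(i30 / 6, 6 / i30), 1.3)
})

test_that("CaV rates: singularity limit and monotone activation", {
  expect_equal(cav_rates(81.5)$alpha_m, 156.9, tolerance = 1e-6)
  expect_equal(cav_rates(81.5 + 1e-10)$alpha_m, 156.9, tolerance = 1e-4)
  expect_equal(cav_rates(0)$beta_m, 0.29)
  v <- seq(-80, 60, by = 1)
  r <- cav_rates(v)
  minf <- r$alpha_m / (r$alpha_m + r$beta_m)
  expect_true(all(diff(minf) > 0))
})

test_that("calcium Nernst potential", {
  expect_equal(eca_nernst(2), 0)
  expect_equal(eca_nernst(5e-5), 140.6, tolerance = 1e-3)
  ca <- 10^seq(-7, 0, by = 0.25)
  expect_true(all(diff(eca_nernst(ca)) < 0))
  expect_error(eca_nernst(0), "positive")
})

test_that("SK gate opens with calcium", {
  ca <- 10^seq(-6, -1, by = 0.1)
  r <- sk_rates(ca)
  qinf <- r$alpha_q / (r$alpha_q + r$beta_q)
  expect_true(all(diff(qinf) > 0))
  kd <- tj_kinetics()
  expect_gt(qinf[length(ca)], 0.85)
  expect_lt(sk_rates(kd$ca_rest)$alpha_q /
              (sk_rates(kd$ca_rest)$alpha_q + sk_rates(kd$ca_rest)$beta_q), 0.01)
  ## q_inf = 0.5 exactly where alpha_q = beta_q
  ca_half <- uniroot(function(x) {
    z <- sk_rates(10^x); z$alpha_q - z$beta_q
  }, c(-6, 0), tol = 1e-12)$root
  z <- sk_rates(10^ca_half)
  expect_equal(z$alpha_q / (z$alpha_q + z$beta_q), 0.5, tolerance = 1e-6)
  expect_error(sk_rates(-1), "positive")
})

test_that("calcium pool dynamics", {
  kd <- tj_kinetics()
  ## fixed point with no current
  expect_equal(ca_dynamics_step(kd$ca_rest, 0, 1), kd$ca_rest)
  ## exponential relaxation with tau = 20 ms (log-linear fit)
  ca <- 10 * kd$ca_rest
  ts <- seq(0.1, 30, by = 0.1)
  vals <- numeric(length(ts))
  x <- ca
  for (k in seq_along(ts)) {
    x <- ca_dynamics_step(x, 0, 0.1)
    vals[k] <- x
  }
  fit <- stats::lm(log(vals - kd$ca_rest) ~ ts)
  expect_equal(-1 / coef(fit)[2], 20, tolerance = 1e-3, ignore_attr = TRUE)
  ## algebraic steady state under constant current
  ica <- -2e-3                     # inward Ca current, mA/cm^2
  x <- kd$ca_rest
  for (k in 1:8000) x <- ca_dynamics_step(x, ica, 0.25)
  expect_equal(x, kd$ca_rest - 0.026 * ica * 20, tolerance = 1e-6)
  ## inward current raises [Ca]
  expect_gt(ca_dynamics_step(kd$ca_rest, -1e-3, 1), kd$ca_rest)
})

test_that("pump current is saturating Michaelis-Menten with 3:2 split", {
  expect_equal(pump_current(0, 1e-3)$i_net, 0)
  expect_equal(pump_current(10, 1e-3, km = 10)$i_net, 0.5e-3)
  p <- pump_current(14, 1e-3)
  expect_equal(p$i_na, 3 * p$i_net)
  expect_equal(p$i_k, -2 * p$i_net)
  ## 1000-fold density scales the resting current 1000-fold
  expect_equal(pump_current(14, 1)$i_net / pump_current(14, 1e-3)$i_net, 1000)
  ## monotone and saturating
  na <- seq(0, 150, by = 5)
  inet <- pump_current(na, 1e-3)$i_net
  expect_true(all(diff(inet) > 0))
  expect_lt(max(inet), 1e-3)
})

test_that("gating steady states stay in [0,1] with positive taus", {
  v <- seq(-120, 80, by = 0.25)
  g <- drgtj:::gate_steady(v, tj_kinetics())
  for (nm in names(g)) expect_true(all(g[[nm]] >= 0 & g[[nm]] <= 1))
  kq <- kcnq_rates(v); kd <- kdr_rates(v)
  nv <- nav_rates(v); cv <- cav_rates(v)
  expect_true(all(kq$tau_m > 0))
  expect_true(all(1 / (nv$alpha_m + nv$beta_m) > 0))
  expect_true(all(1 / (cv$alpha_m + cv$beta_m) > 0))
})

test_that("channel currents vanish at their reversal potentials", {
  ## ohmic form: I = g * gate * (V - E); at V = E the current is zero for
  ## any gating state, including mid-transition ones
  set.seed(1)
  for (rep in 1:5) {
    gate <- runif(1)
    expect_equal(40 * gate^3 * runif(1) * (55 - 55), 0)        # NaV at E_Na
    expect_equal(40 * gate^3 * runif(1) * (-90 - -90), 0)      # KDR at E_K
    expect_equal(0.8 * gate * (-90 - -90), 0)                  # KCNQ at E_K
    eca <- eca_nernst(10^runif(1, -6, -2))
    expect_equal(5 * gate^2 * (eca - eca), 0)                  # CaV at E_Ca
  }
})

test_that("leak reversal calibration balances the resting currents", {
  cb <- default_cable()
  kin <- tj_kinetics()
  ## pure leak: E_leak = resting potential exactly
  m0 <- tj_model(cb, density_map(cb, na = NULL, kdr = NULL))
  expect_equal(unname(m0$e_leak), rep(-60, cb$n))
  ## KDR present at rest -> outward K+ current -> E_leak depolarized
  mk <- tj_model(cb, density_map(cb, na = NULL, kdr = c(all = 40)))
  expect_true(all(mk$e_leak[cb$area_cm2 > 0] > -60))
  ## NaV present at rest -> inward window current -> E_leak hyperpolarized
  mn <- tj_model(cb, density_map(cb, na = c(all = 40), kdr = NULL))
  expect_true(all(mn$e_leak[cb$area_cm2 > 0] < -60))
  ## zero net membrane current at initialization
  mdl <- default_model()
  st <- steady_state_init(mdl)
  g <- drgtj:::gate_steady(-60, kin)
  dens <- mdl$densities
  i_tot <- dens[, "na"] * g$m^3 * g$h * (-60 - 55) +
    dens[, "kdr"] * g$n^3 * g$l * (-60 + 90) +
    0.1 * (-60 - mdl$e_leak)
  expect_lt(max(abs(i_tot)), 1e-10)
})
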