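test_that("single passive compartment behaves as an RC circuit", {
  toys <- make_toy_models()
  cb <- toys$single$cable
  mdl <- tj_model(cb, density_map(cb, na = NULL, kdr = NULL))
  stim <- tj_stimulus("cable", cb$dist_um[1], amp_nA = 0.02,
                      width_ms = 80, onset_ms = 1)
  tr <- run_simulation(mdl, stim, duration = 81, dt = 0.01,
                       record = list(list("cable", cb$dist_um[1])),
                       record_dt = 0.01)
  v <- trace_v(tr)
  ## steady-state deflection: V = I * R_in
  r_in <- toys$single$r_in_MOhm
  expect_equal(max(v) + 60, 0.02 * r_in, tolerance = 1e-3)
  ## charging time constant = Rm*Cm = 10 ms exactly
  sel <- tr$time > 2 & tr$time < 30
  y <- log(1 - (v[sel] + 60) / (max(v) + 60))
  tau <- -1 / coef(stats::lm(y ~ tr$time[sel]))[2]
  expect_equal(unname(tau), toys$single$tau_ms, tolerance = 5e-3)
})

test_that("charge is conserved in passive mode", {
  toys <- make_toy_models()
  cb <- toys$single$cable
  mdl <- tj_model(cb, density_map(cb, na = NULL, kdr = NULL))
  tr <- run_simulation(mdl, tj_stimulus("cable", cb$dist_um[1], amp_nA = 0.02,
                                        width_ms = 20, onset_ms = 1),
                       duration = 30, dt = 0.005,
                       record = list(list("cable", cb$dist_um[1])),
                       record_dt = 0.005)
  v <- trace_v(tr)
  C <- cb$area_cm2[1]
  q_in <- 0.02e-3 * 20                        # nC -> uA*ms
  q_cap <- C * (v[length(v)] - v[1])
  q_leak <- sum(0.1 * cb$area_cm2[1] * (v - (-60))) * 0.005
  expect_equal(q_cap + q_leak, q_in, tolerance = 0.005)
})

test_that("active two-compartment model matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  toys <- make_toy_models()
  cb <- toys$two_comp$cable
  kin <- tj_kinetics()
  dm <- density_map(cb, na = c(all = 40), kdr = c(all = 40))
  mdl <- tj_model(cb, dm, kin)
  stim <- tj_stimulus("cable", cb$dist_um[1], amp_nA = 0.3,
                      width_ms = 1, onset_ms = 2)
  tr <- run_simulation(mdl, stim, duration = 20, dt = 0.002,
                       record = list(list("cable", cb$dist_um[1]),
                                     list("cable", cb$dist_um[2])),
                       record_dt = 0.01, method = "trapezoid")
  ## reference: scalar ODE system integrated by lsoda at tight tolerance
  area <- cb$area_cm2
  gax <- cb$g_axial[2]
  gna <- dm[, "na"] * area; gkdr <- dm[, "kdr"] * area
  gl <- 0.1 * area; el <- mdl$e_leak; cm <- area
  deriv <- function(t, y, p) {
    V <- y[1:2]; m <- y[3:4]; h <- y[5:6]; nn <- y[7:8]; ll <- y[9:10]
    nv <- nav_rates(V); kd <- kdr_rates(V)
    ina <- gna * m^3 * h * (V - 55)
    ik <- gkdr * nn^3 * ll * (V + 90)
    il <- gl * (V - el)
    iax <- c(gax * (V[2] - V[1]), gax * (V[1] - V[2]))
    istim <- c(if (t >= 2 && t <= 3) 0.3e-3 else 0, 0)
    taum <- 1 / (nv$alpha_m + nv$beta_m); minf <- nv$alpha_m * taum
    tauh <- 1 / (nv$alpha_h + nv$beta_h); hinf <- nv$alpha_h * tauh
    list(c((-(ina + ik + il) + iax + istim) / cm,
           (minf - m) / taum, (hinf - h) / tauh,
           (kd$n_inf - nn) / kd$tau_n, (kd$l_inf - ll) / kd$tau_l))
  }
  g <- drgtj:::gate_steady(-60, kin)
  y0 <- c(rep(-60, 2), rep(g$m, 2), rep(g$h, 2), rep(g$n, 2), rep(g$l, 2))
  ref <- deSolve::ode(y0, seq(0, 20, by = 0.01), deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  ## the toy spikes (peak > 0 mV); solver tracks the reference everywhere
  expect_gt(max(ref[, 2]), 0)
  err <- max(abs(tr$v[, 1] - ref[, 2]), abs(tr$v[, 2] - ref[, 3]))
  expect_lt(err, 0.1)
})

test_that("uniform passive cable follows the infinite-cable solution", {
  skip_if_not_installed("pracma")
  toys <- make_toy_models()
  cb <- toys$uniform$cable
  mdl <- tj_model(cb, density_map(cb, na = NULL, kdr = NULL))
  mid <- cb$dist_um[100]
  I <- 0.01
  tr <- run_simulation(mdl, tj_stimulus("cable", mid, amp_nA = I,
                                        width_ms = 500, onset_ms = 0),
                       duration = 8, dt = 0.005,
                       record = lapply(c(mid, cb$dist_um[120], cb$dist_um[140]),
                                       function(d) list("cable", d)),
                       record_dt = 0.1)
  lambda <- toys$uniform$lambda_um
  tau <- toys$uniform$tau_ms
  rinf <- (2 / pi) * sqrt(1e4 * 100) / (1e-4)^1.5 / 1e6
  v_inf <- function(x_um, t_ms) {
    X <- x_um / lambda; Tt <- t_ms / tau
    (I * rinf / 4) * (exp(-X) * pracma::erfc(X / (2 * sqrt(Tt)) - sqrt(Tt)) -
                        exp(X) * pracma::erfc(X / (2 * sqrt(Tt)) + sqrt(Tt)))
  }
  for (j in 1:3) {
    x <- abs(c(mid, cb$dist_um[120], cb$dist_um[140])[j] - mid)
    for (tt in c(2, 5, 8)) {
      vm <- unname(tr$v[which.min(abs(tr$time - tt)), j]) + 60
      expect_equal(vm, v_inf(x, tt), tolerance = 0.02)
    }
  }
})

test_that("a symmetric Y-junction carries identical spikes into both daughters", {
  toys <- make_toy_models()
  cb <- toys$y_junction$cable
  mdl <- tj_model(cb, density_map(cb, na = c(all = 40), kdr = c(all = 40)))
  d <- cb$dist_um[60]
  tr <- run_simulation(mdl, tj_stimulus("parent", cb$dist_um[5], amp_nA = 0.3),
                       duration = 15, dt = 0.01,
                       record = list(list("dauA", d), list("dauB", d)),
                       record_dt = 0.1)
  expect_gt(max(tr$v[, 1]), 0)                 # the spike traversed
  expect_lt(max(abs(tr$v[, 1] - tr$v[, 2])), 1e-9)
})

test_that("solution is invariant under compartment re-ordering", {
  cb <- default_cable()
  perm <- bfs_order(cb$parent)
  cb2 <- permute_cable(cb, perm)
  m1 <- tj_model(cb)
  m2 <- tj_model(cb2)
  ## distances chosen off the midpoints between compartment centers so
  ## both orderings resolve to the same physical compartments
  s <- tj_stimulus("peripheral", 4620, amp_nA = 0.4)
  rec <- list(list("junction", 0), list("central", 3010))
  a <- run_simulation(m1, s, duration = 25, dt = 0.025, record = rec)
  b <- run_simulation(m2, s, duration = 25, dt = 0.025, record = rec)
  expect_lt(max(abs(a$v - b$v)), 1e-7)
})

test_that("unstimulated model rests at -60 mV", {
  mdl <- default_model()
  tr <- run_simulation(mdl, NULL, duration = 500, dt = 0.025,
                       record = list(list("soma", 0), list("junction", 0),
                                     list("central", 5000)),
                       record_dt = 1)
  expect_lt(max(abs(tr$v + 60)), 0.5)
  ## quiescence from the steady-state init: < 0.1 mV over 100 ms
  expect_lt(max(abs(tr$v[tr$time <= 100, ] + 60)), 0.1)
})

test_that("resting state holds with SK, CaV and ion dynamics enabled", {
  cb <- default_cable()
  dm <- density_map(cb, ca = c(soma = 3), sk = c(soma = 1))
  mdl <- tj_model(cb, dm, ion_dynamics = TRUE, pump = TRUE)
  tr <- run_simulation(mdl, NULL, duration = 300, dt = 0.025,
                       record = list(list("soma", 0), list("central", 100)),
                       record_dt = 1, record_extra = TRUE)
  expect_lt(max(abs(tr$v + 60)), 0.5)
  ## ion pools in balance: E_Na/E_K pinned at +55/-90
  expect_lt(max(abs(tr$e_na - 55)), 0.25)
  expect_lt(max(abs(tr$e_k + 90)), 0.25)
})

test_that("halving dt changes the propagated spike by <1% of its amplitude", {
  mdl <- default_model()
  s <- tj_stimulus("peripheral", 4600, amp_nA = 0.4)
  rec <- list(list("junction", 0))
  a <- run_simulation(mdl, s, duration = 30, dt = 0.025, record = rec, record_dt = 0.05)
  b <- run_simulation(mdl, s, duration = 30, dt = 0.0125, record = rec, record_dt = 0.05)
  amp_a <- max(a$v) + 60
  amp_b <- max(b$v) + 60
  expect_lt(abs(amp_a - amp_b) / amp_b, 0.01)
  ## arrival-time shift below 2% of the conduction delay
  ta <- detect_spikes(a$time, a$v[, 1])$t_cross[1]
  tb <- detect_spikes(b$time, b$v[, 1])$t_cross[1]
  expect_lt(abs(ta - tb) / tb, 0.02)
})

test_that("spatial refinement leaves the solution unchanged", {
  cb2 <- discretize(build_geometry(stem_nseg = 200L, proximal_nseg = 200L,
                                   distal_nseg = 200L))
  m2 <- tj_model(cb2)
  s <- tj_stimulus("peripheral", 4600, amp_nA = 0.4)
  a <- run_simulation(default_model(), s, duration = 30, dt = 0.025,
                      record = list(list("junction", 0)), record_dt = 0.05)
  b <- run_simulation(m2, s, duration = 30, dt = 0.025,
                      record = list(list("junction", 0)), record_dt = 0.05)
  expect_lt(abs((max(a$v) - max(b$v)) / (max(b$v) + 60)), 0.01)
})

test_that("non-finite states are reported as numerical failures", {
  mdl <- default_model()
  bad <- steady_state_init(mdl)
  bad$v[1] <- NaN
  expect_error(run_simulation(mdl, NULL, duration = 1, dt = 0.025,
                              state = bad),
               "numerical failure")
})

test_that("simulation input validation", {
  mdl <- default_model()
  expect_error(run_simulation(mdl, NULL, duration = 10, dt = 0),
               "dt must be positive")
  expect_error(run_simulation(mdl, NULL, duration = 0.001, dt = 0.025),
               "duration")
  expect_error(tj_stimulus(amp_nA = Inf), "finite")
  expect_error(tj_stimulus(freq_Hz = -1), ">= 0")
  expect_error(tj_stimulus(n_pulses = 0), ">= 1")
})
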