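#' Mechanism density map
#'
#' Builds the per-compartment channel density matrix (mS/cm^2) from
#' region-level rules. Each argument is a named numeric vector mapping a
#' region to a density; later entries override earlier ones. Regions:
#' section names (\code{"soma"}, \code{"stem"}, \code{"peripheral_proximal"},
#' \code{"peripheral_distal"}, \code{"central_proximal"},
#' \code{"central_distal"}) plus the aliases \code{"all"}, \code{"axon"}
#' (the four axonal sections), \code{"proximal"} (both proximal axon
#' sections, i.e. the 100 um segments flanking the T-junction).
#'
#' The default is the exemplar active model: NaV and KDR at 40 mS/cm^2 in
#' every compartment with somatic NaV halved to 20 mS/cm^2.
#'
#' @param cable a \code{tj_cable}.
#' @param na,kdr,kcnq,ca,sk named region->density vectors (mS/cm^2).
#' @return numeric matrix n x 5 with columns na, kdr, kcnq, ca, sk.
#' @examples
#' cb <- discretize(build_geometry())
#' dm <- density_map(cb, kcnq = c(soma = 0.2, stem = 0.2, proximal = 0.2))
#' @export
density_map <- function(cable,
                        na = c(all = 40, soma = 20),
                        kdr = c(all = 40),
                        kcnq = NULL, ca = NULL, sk = NULL) {
  stopifnot(inherits(cable, "tj_cable"))
  axon_secs <- c("stem", "peripheral_proximal", "peripheral_distal",
                 "central_proximal", "central_distal")
  region_idx <- function(r) {
    switch(r,
      all = seq_len(cable$n),
      axon = which(cable$section %in% axon_secs),
      proximal = which(cable$section %in% c("peripheral_proximal", "central_proximal")),
      { i <- which(cable$section == r)
        if (!length(i)) stop("unknown region: ", r)
        i })
  }
  one <- function(rule) {
    d <- numeric(cable$n)
    if (is.null(rule)) return(d)
    if (is.null(names(rule)) || any(names(rule) == ""))
      stop("density specs must be named region = density vectors")
    if (any(!is.finite(rule)) || any(rule < 0)) stop("densities must be >= 0")
    for (r in names(rule)) d[region_idx(r)] <- rule[[r]]
    d
  }
  m <- cbind(na = one(na), kdr = one(kdr), kcnq = one(kcnq),
             ca = one(ca), sk = one(sk))
  m[cable$area_cm2 == 0, ] <- 0
  m
}

#' Assemble the full membrane model
#'
#' Combines a compartment graph, a mechanism density map and kinetics
#' parameters, calibrates the per-compartment leak reversal so that the
#' total membrane current is zero at the resting potential, and prepares
#' the resting state. Equilibrium potentials are fixed at E_Na = +55 mV
#' and E_K = -90 mV unless ion dynamics are enabled, in which case they
#' follow the Nernst equation for the evolving pools (intracellular
#' compartment volume; extracellular periaxonal shell).
#'
#' @param cable a \code{tj_cable}.
#' @param densities matrix from \code{density_map}.
#' @param kinetics a \code{tj_kinetics}.
#' @param ion_dynamics logical; track Na+/K+ pools and recompute E_Na/E_K.
#' @param pump logical; electrogenic Na+/K+ pump.
#' @param i_pump_max maximal net pump current density (mA/cm^2). The
#'   default is the density at which resting pump Na+ extrusion balances
#'   the resting NaV window influx of the exemplar model.
#' @param e_leak optional per-compartment leak reversal override (mV);
#'   when given, the automatic calibration is skipped, so the resting
#'   state need not be a fixed point (used to expose, e.g., the
#'   electrogenic shift of a raised pump density).
#' @return object of class \code{"tj_model"}.
#' @export
tj_model <- function(cable, densities = density_map(cable),
                     kinetics = tj_kinetics(),
                     ion_dynamics = FALSE, pump = FALSE,
                     i_pump_max = 1.3e-3, e_leak = NULL) {
  stopifnot(inherits(cable, "tj_cable"))
  if (!is.matrix(densities) || nrow(densities) != cable$n ||
      !all(c("na", "kdr", "kcnq", "ca", "sk") %in% colnames(densities)))
    stop("'densities' must be a density_map() matrix for this cable")
  kin <- if (inherits(kinetics, "tj_kinetics")) kinetics else do.call(tj_kinetics, kinetics)

  vrest <- kin$e_rest
  g <- gate_steady(vrest, kin)
  eca0 <- eca_nernst(kin$ca_rest, kin$ca_out)
  sk0 <- sk_rates(kin$ca_rest, kin$sk_div_a)
  q0 <- sk0$alpha_q / (sk0$alpha_q + sk0$beta_q)

  gleak_d <- 1000 / cable$passive$Rm   # mS/cm^2
  ip0 <- if (pump) i_pump_max * kin$na_i / (kin$na_i + kin$pump_km) else 0
  ## resting active current density, uA/cm^2 (outward positive)
  i_na_rest <- densities[, "na"] * g$m^3 * g$h * (vrest - kin$e_na)
  i_k_rest  <- (densities[, "kdr"] * g$n^3 * g$l + densities[, "kcnq"] * g$mq +
                densities[, "sk"] * q0^2) * (vrest - kin$e_k)
  i_ca_rest <- densities[, "ca"] * g$mc^2 * (vrest - eca0)
  i_rest <- i_na_rest + i_k_rest + i_ca_rest + 1e3 * ip0
  if (is.null(e_leak)) {
    e_leak <- vrest + i_rest / gleak_d
    if (any(!is.finite(e_leak)) || any(abs(e_leak) > 500))
      stop("configuration infeasible: leak reversal calibration out of range")
  } else {
    if (length(e_leak) == 1) e_leak <- rep(e_leak, cable$n)
    if (length(e_leak) != cable$n || any(!is.finite(e_leak)))
      stop("'e_leak' override must be finite, length 1 or n")
  }

  n <- cable$n
  area <- cable$area_cm2
  depth_um <- ifelse(cable$diameter_um > 0, cable$diameter_um / 4, 1)
  flux_coef <- 1e4 / 96485                     # mM/ms per mA/cm^2 per um depth
  state0 <- list(
    v = rep(vrest, n),
    m = rep(g$m, n), h = rep(g$h, n), n = rep(g$n, n), l = rep(g$l, n),
    mq = rep(g$mq, n), mc = rep(g$mc, n), q = rep(q0, n),
    ca = rep(kin$ca_rest, n),
    na_i = rep(kin$na_i, n), na_o = rep(kin$na_o, n),
    k_i = rep(kin$k_i, n), k_o = rep(kin$k_o, n)
  )

  sys <- list(
    parent = cable$parent, g_axial = cable$g_axial, area_cm2 = area,
    cm_uF = cable$passive$Cm * area,
    g_na = densities[, "na"] * area, g_kdr = densities[, "kdr"] * area,
    g_kcnq = densities[, "kcnq"] * area, g_ca = densities[, "ca"] * area,
    g_sk = densities[, "sk"] * area, g_leak = gleak_d * area,
    e_leak = e_leak,
    e_na = rep(kin$e_na, n), e_k = rep(kin$e_k, n),
    ca_rest = kin$ca_rest, ca_k = 0.026, ca_tau = 20,
    eca_coef = RT_2F_308, ca_out = kin$ca_out,
    pump_on = pump, ions_on = ion_dynamics,
    ipump_max = rep(if (pump) i_pump_max else 0, n),
    pump_km = kin$pump_km,
    flux_in = flux_coef / depth_um,
    flux_out = rep(flux_coef / kin$shell_um, n),
    base_flux_na = 1e-3 * i_na_rest + 3 * ip0,
    base_flux_k  = 1e-3 * i_k_rest - 2 * ip0,
    rt_f = RT_F_308
  )

  structure(list(cable = cable, densities = densities, kinetics = kin,
                 ion_dynamics = ion_dynamics, pump = pump,
                 i_pump_max = i_pump_max, e_leak = e_leak,
                 sys = sys, state0 = state0),
            class = "tj_model")
}

#' @export
print.tj_model <- function(x, ...) {
  on <- colnames(x$densities)[colSums(x$densities) > 0]
  cat(sprintf("T-junction membrane model: %d compartments; mechanisms: %s%s%s\n",
              x$cable$n,
              paste(c(on, "leak"), collapse = ", "),
              if (x$ion_dynamics) ", ion dynamics" else "",
              if (x$pump) sprintf(", pump (I_max = %g mA/cm^2)", x$i_pump_max) else ""))
  cat(sprintf("resting potential %g mV; E_leak range [%.2f, %.2f] mV\n",
              x$kinetics$e_rest, min(x$e_leak), max(x$e_leak)))
  invisible(x)
}

#' Resting-state initialization
#'
#' Returns the model state with every gate at its steady state for the
#' resting potential, [Ca]_i at rest, and ion pools at their configured
#' baselines. Because the leak reversal is calibrated compartment-wise,
#' this state carries zero net membrane current everywhere.
#'
#' @param model a \code{tj_model}.
#' @return named list of state vectors.
#' @export
steady_state_init <- function(model) {
  stopifnot(inherits(model, "tj_model"))
  model$state0
}

#' Stimulus protocol: train of current pulses
#'
#' @param branch,dist_um injection site (see \code{resolve_site}).
#' @param amp_nA pulse amplitude (nA).
#' @param width_ms pulse width (ms).
#' @param freq_Hz pulse rate (Hz); 0 for a single pulse.
#' @param n_pulses number of pulses.
#' @param onset_ms time of the first pulse (ms).
#' @return object of class \code{"tj_stimulus"}.
#' @export
tj_stimulus <- function(branch = "peripheral", dist_um = 4600,
                        amp_nA = 0.2, width_ms = 1,
                        freq_Hz = 0, n_pulses = 1, onset_ms = 1) {
  if (!is.finite(amp_nA)) stop("amplitude must be finite")
  if (freq_Hz < 0) stop("frequency must be >= 0")
  if (n_pulses < 1) stop("pulse count must be >= 1")
  if (width_ms <= 0) stop("pulse width must be positive")
  if (freq_Hz > 0 && 1000 / freq_Hz < width_ms)
    stop("inter-pulse interval shorter than pulse width")
  structure(list(branch = branch, dist_um = dist_um, amp_nA = amp_nA,
                 width_ms = width_ms, freq_Hz = freq_Hz,
                 n_pulses = as.integer(n_pulses), onset_ms = onset_ms),
            class = "tj_stimulus")
}

stim_matrix <- function(cable, stimuli) {
  if (is.null(stimuli)) return(matrix(0, 0, 6))
  if (inherits(stimuli, "tj_stimulus")) stimuli <- list(stimuli)
  do.call(rbind, lapply(stimuli, function(s) {
    stopifnot(inherits(s, "tj_stimulus"))
    comp <- resolve_site(cable, s$branch, s$dist_um)
    period <- if (s$freq_Hz > 0) 1000 / s$freq_Hz else 0
    c(comp, s$onset_ms, s$width_ms, period, s$n_pulses, s$amp_nA)
  }))
}

normalize_sites <- function(sites) {
  if (is.data.frame(sites)) {
    return(Map(function(b, d) list(branch = b, dist_um = d),
               as.character(sites$branch), sites$dist_um))
  }
  lapply(sites, function(s) {
    if (is.character(s)) {
      d <- if (length(s) > 1) as.numeric(s[2]) else 0
      list(branch = s[1], dist_um = d)
    } else {
      list(branch = as.character(s[[1]]), dist_um = as.numeric(s[[2]]))
    }
  })
}

#' Run a simulation
#'
#' Integrates the coupled voltage/gating/ion system on the compartment
#' tree with an implicit (unconditionally stable) backward-Euler solve of
#' the cable equation, staggered with exact-exponential gating updates.
#'
#' @param model a \code{tj_model}.
#' @param stimuli a \code{tj_stimulus} or list of them (NULL for none).
#' @param duration simulated time (ms).
#' @param dt time step (ms); default 0.01 ms (10 us).
#' @param record list of sites, each \code{list(branch, dist_um)}, or a
#'   data.frame with columns branch, dist_um.
#' @param record_dt sampling interval of the returned traces (ms).
#' @param record_extra also record [Ca]_i, E_Na, E_K and the Na+/K+
#'   membrane current densities at the recorded sites.
#' @param method \code{"euler"} (backward Euler, default) or
#'   \code{"trapezoid"} (second order; small dt only).
#' @param state optional initial state (default \code{steady_state_init}).
#' @return object of class \code{"tj_trace"}: \code{time} (ms), matrix
#'   \code{v} (mV, one column per site), per-compartment \code{vmax},
#'   the final \code{state}, and site/cable metadata.
#' @examples
#' \donttest{
#' mdl <- tj_model(discretize(build_geometry()))
#' tr <- run_simulation(mdl, tj_stimulus(), duration = 30, dt = 0.025,
#'                      record = list(list("soma", 0), list("central", 5000)))
#' }
#' @export
run_simulation <- function(model, stimuli = NULL, duration, dt = 0.01,
                           record = list(list(branch = "soma", dist_um = 0)),
                           record_dt = 0.025, record_extra = FALSE,
                           method = c("euler", "trapezoid"), state = NULL) {
  stopifnot(inherits(model, "tj_model"))
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must be >= dt")
  sites <- normalize_sites(record)
  comps <- vapply(sites, function(s) resolve_site(model$cable, s$branch, s$dist_um), 0L)
  labels <- vapply(sites, function(s) paste0(s$branch, "@", s$dist_um), "")

  sys <- model$sys
  sys$tables <- build_tables(model$kinetics, dt)
  sys$stimuli <- stim_matrix(model$cable, stimuli)
  ctrl <- list(dt = dt, nsteps = as.integer(round(duration / dt)),
               stride = max(1L, as.integer(round(record_dt / dt))),
               record = comps, trapezoid = (method == "trapezoid"),
               record_extra = record_extra)
  st <- if (is.null(state)) model$state0 else state
  out <- cpp_run(sys, st, ctrl)

  colnames(out$v) <- labels
  tr <- list(time = out$time, v = out$v, vmax = out$vmax,
             state = out$state, sites = labels, comps = comps,
             dt = dt, rest = model$kinetics$e_rest, cable = model$cable)
  if (record_extra) {
    for (nm in c("ca", "e_na", "e_k", "i_na", "i_k")) {
      colnames(out[[nm]]) <- labels
      tr[[nm]] <- out[[nm]]
    }
  }
  structure(tr, class = "tj_trace")
}

#' @export
print.tj_trace <- function(x, ...) {
  cat(sprintf("tj_trace: %.4g ms at %.3g ms sampling, %d site(s): %s\n",
              max(x$time), diff(x$time[1:2]), length(x$sites),
              paste(x$sites, collapse = ", ")))
  rng <- apply(x$v, 2, range)
  for (j in seq_along(x$sites))
    cat(sprintf("  %-18s V in [%.2f, %.2f] mV\n", x$sites[j], rng[1, j], rng[2, j]))
  invisible(x)
}

#' @export
plot.tj_trace <- function(x, sites = x$sites, ...) {
  sel <- match(sites, x$sites)
  matplot(x$time, x$v[, sel, drop = FALSE], type = "l", lty = 1,
          xlab = "time (ms)", ylab = "V (mV)", ...)
  legend("topright", legend = x$sites[sel], col = seq_along(sel), lty = 1, bty = "n")
  invisible(x)
}

#' Extract a trace column
#'
#' @param trace a \code{tj_trace}.
#' @param site site label (\code{"branch@dist"}) or index.
#' @return numeric vector of V (mV).
#' @export
trace_v <- function(trace, site = 1) {
  if (is.character(site)) site <- match(site, trace$sites)
  if (is.na(site)) stop("unknown site")
  trace$v[, site]
}
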