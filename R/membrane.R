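## Membrane mechanism kinetics.
##
## All rate functions take voltage in mV (or [Ca]_i in mM) and return
## 1/ms rates or (steady state, time constant) pairs. The model runs at a
## fixed 308 K; the Nernst coefficients below are RT/F and RT/2F at that
## temperature.

RT_F_308  <- 1000 * 8.314 * 308 / 96485     # 26.54 mV
RT_2F_308 <- RT_F_308 / 2                   # 13.27 mV
## exponent slope of the delayed-rectifier Borg-Graham alpha/beta terms:
## F/RT per mV at 308 K (printed as 9.648e4 / 2562.35)
KDR_F_RT  <- 9.648e4 / 2562.35 * 1e-3       # 0.03765 / mV

## ratio x/(exp(x/k)-1) with the removable singularity at x = 0 filled by
## its limit k (both the NaV and CaV alpha functions have this form)
expm1_ratio <- function(x, k) {
  out <- x / expm1(x / k)
  out[abs(x) < 1e-7] <- k
  out
}

#' Voltage-gated Na+ channel rate functions
#'
#' Traub-family m3h kinetics expressed relative to a reference potential:
#' rates are evaluated at v' = v - v_ref, where \code{v_ref} positions the
#' channel's voltage dependence (the model's value was chosen once so that
#' the resting potential, somatic spike amplitude, and peripheral
#' conduction velocity targets are met together; see the package vignette).
#'
#' @param v membrane potential (mV).
#' @param v_ref voltage reference (mV); default is the calibrated model value.
#' @return list with alpha_m, beta_m, alpha_h, beta_h (1/ms).
#' @export
nav_rates <- function(v, v_ref = tj_kinetics_defaults$v_ref) {
  vp <- v - v_ref
  list(
    alpha_m = 0.55 * expm1_ratio(7.1 - vp, 4),
    beta_m  = 0.48 * expm1_ratio(vp - 46.1, 5),
    alpha_h = 0.22 * exp((23 - vp) / 18),
    beta_h  = 6.92 / (1 + exp((46 - vp) / 5))
  )
}

#' Delayed-rectifier K+ channel gates
#'
#' Borg-Graham-form activation (n, half-voltage -32 mV) and slow
#' inactivation (l, half-voltage -61 mV). Steady state is
#' \code{1/(1 + alpha(v))} and the time constant is
#' \code{beta(v) / (a0 * (1 + alpha(v)))}, floored at \code{tau_min}
#' (the floor prevents the time constant collapsing at voltages far from
#' the half-voltage, as in standard implementations of this channel
#' family). The rate scales a0 are calibration constants.
#'
#' @param v membrane potential (mV).
#' @param a0_n,a0_l rate scales (1/ms).
#' @param tau_n_min,tau_l_min time-constant floors (ms).
#' @return list with n_inf, tau_n, l_inf, tau_l.
#' @export
kdr_rates <- function(v,
                      a0_n = tj_kinetics_defaults$a0_n,
                      a0_l = tj_kinetics_defaults$a0_l,
                      tau_n_min = tj_kinetics_defaults$tau_n_min,
                      tau_l_min = tj_kinetics_defaults$tau_l_min) {
  an <- exp(-5 * KDR_F_RT * (v + 32))
  bn <- exp(-2 * KDR_F_RT * (v + 32))
  al <- exp( 2 * KDR_F_RT * (v + 61))
  bl <- exp(-2 * KDR_F_RT * (v + 32))
  list(
    n_inf = 1 / (1 + an),
    tau_n = pmax(bn / (a0_n * (1 + an)), tau_n_min),
    l_inf = 1 / (1 + al),
    tau_l = pmax(bl / (a0_l * (1 + al)), tau_l_min)
  )
}

#' KCNQ (Kv7 / M-current) gate
#'
#' Two-state non-inactivating K+ channel: logistic activation with
#' half-voltage -35 mV and 10 mV slope; bell-shaped time constant peaking
#' at -35 mV (the /3.54 factor is the printed temperature adjustment).
#'
#' @param v membrane potential (mV).
#' @return list with m_inf and tau_m (ms).
#' @export
kcnq_rates <- function(v) {
  x <- v + 35
  list(
    m_inf = 1 / (1 + exp(-x / 10)),
    tau_m = (1000 / (3.3 * (exp(x / 20) + exp(-x / 20)))) / 3.54
  )
}

#' High-threshold Ca2+ channel rate functions
#'
#' The activation gate enters the current squared (m^2). The alpha
#' function's removable singularity at +81.5 mV takes its limit value.
#'
#' @param v membrane potential (mV).
#' @return list with alpha_m and beta_m (1/ms).
#' @export
cav_rates <- function(v) {
  list(
    alpha_m = 15.69 * expm1_ratio(81.5 - v, 10),
    beta_m  = 0.29 * exp(-v / 10.86)
  )
}

#' Calcium Nernst potential
#'
#' E_Ca = (RT/2F) ln([Ca]_o/[Ca]_i) at 308 K with 2 mM extracellular Ca2+.
#'
#' @param ca_i intracellular Ca2+ (mM).
#' @param ca_o extracellular Ca2+ (mM).
#' @return E_Ca in mV.
#' @export
eca_nernst <- function(ca_i, ca_o = 2) {
  if (any(ca_i <= 0)) stop("[Ca]_i must be positive")
  RT_2F_308 * log(ca_o / ca_i)
}

#' SK (Ca2+-activated K+) channel rate functions
#'
#' Calcium-dependent opening with the gate entering the current squared.
#' Rates are exponentials of 12*log10([Ca]_i in mM); \code{div_a} selects
#' the alpha divisor (4 as printed in the source equations; 4.5 in the
#' upstream channel family).
#'
#' @param ca_i intracellular Ca2+ (mM).
#' @param div_a alpha-rate divisor.
#' @return list with alpha_q and beta_q (1/ms).
#' @export
sk_rates <- function(ca_i, div_a = tj_kinetics_defaults$sk_div_a) {
  if (any(ca_i <= 0)) stop("[Ca]_i must be positive")
  x <- 12 * log10(ca_i)
  list(
    alpha_q = 0.00246 * exp((x + 28.48) / div_a),
    beta_q  = 0.006   * exp((x + 60.4) / 35)
  )
}

#' One step of intracellular Ca2+ dynamics
#'
#' d[Ca]/dt = -k * I_Ca - ([Ca]-[Ca]_rest)/tau, advanced by the exact
#' exponential update for constant I_Ca over the step. Inward (negative)
#' Ca2+ current raises [Ca]_i; with no current the pool relaxes to
#' [Ca]_rest with a 20 ms time constant.
#'
#' @param ca_i intracellular Ca2+ (mM).
#' @param i_ca Ca2+ current density (mA/cm^2, outward positive).
#' @param dt time step (ms).
#' @param ca_rest resting Ca2+ (mM).
#' @param tau removal time constant (ms).
#' @param k current-to-concentration factor (mM/ms per mA/cm^2).
#' @return updated [Ca]_i (mM), floored at 1e-9.
#' @export
ca_dynamics_step <- function(ca_i, i_ca, dt,
                             ca_rest = tj_kinetics_defaults$ca_rest,
                             tau = 20, k = 0.026) {
  if (dt <= 0) stop("dt must be positive")
  ca_inf <- ca_rest - k * i_ca * tau
  pmax(ca_inf + (ca_i - ca_inf) * exp(-dt / tau), 1e-9)
}

#' Electrogenic Na+/K+ pump current
#'
#' Michaelis-Menten dependence on intracellular Na+ with 3 Na+ out : 2 K+
#' in stoichiometry. The net (charge) current density is
#' I_max * [Na]_i/([Na]_i + K_m); the Na+ and K+ component fluxes are 3x
#' and -2x that value.
#'
#' @param na_i intracellular Na+ (mM).
#' @param i_pump_max maximal net pump current density (mA/cm^2).
#' @param km half-saturation Na+ concentration (mM).
#' @return list with i_net, i_na, i_k (mA/cm^2, outward positive).
#' @export
pump_current <- function(na_i, i_pump_max, km = 10) {
  if (any(na_i < 0)) stop("[Na]_i must be non-negative")
  inet <- i_pump_max * na_i / (na_i + km)
  list(i_net = inet, i_na = 3 * inet, i_k = -2 * inet)
}

## Calibrated kinetics constants (one-time calibration against the
## passive/active benchmarks; see vignette). Frozen package defaults.
tj_kinetics_defaults <- list(
  v_ref = -45.3,     # NaV voltage reference (mV)
  a0_n = 0.007,      # KDR activation rate scale (1/ms)
  a0_l = 1e-8,       # KDR inactivation rate scale (1/ms; l effectively static)
  tau_n_min = 0.5,   # ms
  tau_l_min = 10,    # ms
  sk_div_a = 4,
  ca_rest = 5e-5,    # mM (50 nM)
  ca_out = 2,        # mM
  e_na = 55, e_k = -90, e_rest = -60,
  pump_km = 10,      # mM
  na_i = 14, na_o = 111, k_i = 140, k_o = 4.7,  # mM, give E_Na=+55, E_K=-90
  shell_um = 0.1     # periaxonal shell thickness (um)
)

#' Kinetics and ion-model parameter set
#'
#' Collects the channel-kinetics calibration constants and ion-dynamics
#' parameters. Defaults are the package's calibrated values.
#'
#' @param ... overrides of any element of the default set (see
#'   \code{nav_rates}, \code{kdr_rates}, \code{sk_rates}).
#' @return list of class \code{"tj_kinetics"}.
#' @export
tj_kinetics <- function(...) {
  k <- tj_kinetics_defaults
  ov <- list(...)
  bad <- setdiff(names(ov), names(k))
  if (length(bad)) stop("unknown kinetics parameter(s): ", paste(bad, collapse = ", "))
  k[names(ov)] <- ov
  structure(k, class = "tj_kinetics")
}

## steady states at a voltage (used for initialization and E_leak)
gate_steady <- function(v, kin) {
  nv <- nav_rates(v, kin$v_ref)
  kd <- kdr_rates(v, kin$a0_n, kin$a0_l, kin$tau_n_min, kin$tau_l_min)
  kq <- kcnq_rates(v)
  cv <- cav_rates(v)
  list(
    m = nv$alpha_m / (nv$alpha_m + nv$beta_m),
    h = nv$alpha_h / (nv$alpha_h + nv$beta_h),
    n = kd$n_inf, l = kd$l_inf,
    mq = kq$m_inf,
    mc = cv$alpha_m / (cv$alpha_m + cv$beta_m)
  )
}

## Rate tables for the compiled integrator: steady state and exp(-dt/tau)
## on a fine grid, so the C++ core never re-states the kinetics.
build_tables <- function(kin, dt, vmin = -150, vmax = 100, dv = 0.025) {
  v <- seq(vmin, vmax, by = dv)
  tab <- function(xinf, tau) list(xmin = vmin, dx = dv, inf = xinf, ex = exp(-dt / tau))
  nv <- nav_rates(v, kin$v_ref)
  kd <- kdr_rates(v, kin$a0_n, kin$a0_l, kin$tau_n_min, kin$tau_l_min)
  kq <- kcnq_rates(v)
  cv <- cav_rates(v)
  ## SK over u = log10([Ca]_i), 1e-9 .. 1 mM
  u <- seq(-9, 0, by = 0.0025)
  sk <- sk_rates(10^u, kin$sk_div_a)
  list(
    nav_m  = tab(nv$alpha_m / (nv$alpha_m + nv$beta_m), 1 / (nv$alpha_m + nv$beta_m)),
    nav_h  = tab(nv$alpha_h / (nv$alpha_h + nv$beta_h), 1 / (nv$alpha_h + nv$beta_h)),
    kdr_n  = tab(kd$n_inf, kd$tau_n),
    kdr_l  = tab(kd$l_inf, kd$tau_l),
    kcnq_m = tab(kq$m_inf, kq$tau_m),
    cav_m  = tab(cv$alpha_m / (cv$alpha_m + cv$beta_m), 1 / (cv$alpha_m + cv$beta_m)),
    sk_q   = list(xmin = -9, dx = 0.0025,
                  inf = sk$alpha_q / (sk$alpha_q + sk$beta_q),
                  ex = exp(-dt * (sk$alpha_q + sk$beta_q)))
  )
}
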