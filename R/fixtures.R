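## Experiment presets and toy fixtures.
##
## Presets freeze the per-experiment configurations (geometry overrides,
## density maps, stimulus protocols, sweep grids) so experiments reference
## presets, not magic numbers. Toy models are tiny cables with independent
## analytic or brute-force references, used as numerical oracles.

preset_registry <- function() list(
  fig1_gr = list(
    description = "geometric ratios at the T-junction vs stem diameter",
    stem_diameters = seq(0.1, 2, by = 0.01),
    central_variants = c(0.4, 0.8)
  ),
  fig2_impedance = list(
    description = "input-impedance profile and junction-impedance maps (250 Hz)",
    freq_Hz = 250,
    profile_dists_um = seq(-100, 100, by = 5),
    central_variants = c(0.4, 0.8),
    stem_lengths = seq(50, 400, by = 25),
    stem_diameters = seq(0.8, 2, by = 0.2)
  ),
  fig3_amplitude = list(
    description = "early-mode amplitude profile for three axonal NaV densities",
    gna_axon = c(30, 40, 50),
    dists_um = seq(-100, 100, by = 10),
    stimulus = list(branch = "peripheral", dist_um = 4600,
                    amp_nA = 0.2, width_ms = 1)
  ),
  fig4_transfer = list(
    description = "soma-to-junction DC voltage transfer vs stem geometry",
    stem_lengths = seq(25, 300, by = 25),
    stem_diameters = c(0.8, 1, 1.2, 1.4, 1.6),
    soma_diameters = c(10, 25, 50)
  ),
  fig5_kcnq = list(
    description = "KCNQ density vs following frequency; ectopic spikes at 40 Hz",
    geometry = list(stem_length = 75),
    gkcnq = c(0, 0.2, 0.4, 0.8, 1.6),
    kcnq_regions = c("soma", "stem", "proximal"),
    amp_nA = 0.4,
    ectopic = list(gkcnq = 0.4, freq_Hz = 40, n_stimuli = 20,
                   sites_um = c(2600, 5100))
  ),
  fig6_soma_nav = list(
    description = "somatic NaV x KCNQ density; stem-length effects",
    geometry = list(stem_length = 75),
    gna_soma = c(20, 40),
    gkcnq = c(0.2, 0.4, 0.8),
    stem_lengths = seq(25, 250, by = 25)
  ),
  fig7_sk_soma = list(
    description = "somatic SK-mediated hyperpolarization and 10 Hz failure",
    gsk = seq(0.25, 2, by = 0.25),
    gca_soma = 3,
    sk_region = "soma",
    test_freq_Hz = 10,
    amp_nA = 0.4,
    gna_axon = c(40, 60)
  ),
  fig7_sk_axonal = list(
    description = "SK/CaV placed in the proximal axons instead of the soma",
    gsk = c(1, 2.5, 5, 7.5, 10),
    gca = 3,
    sk_region = "proximal",
    amp_nA = 0.4,
    test_freq_Hz = 10
  ),
  fig8_pump = list(
    description = "ion accumulation and electrogenic pump on a 100 Hz train",
    i_pump_low = 1.3e-6, i_pump_high = 1.3e-3,
    gsk = 0.2, gca_soma = 3,
    freq_Hz = 100, n_stimuli = 20
  )
)

#' Experiment presets
#'
#' Named, fully explicit configurations for each of the package's standard
#' experiments (geometric-ratio sweeps, impedance maps, amplitude
#' profiles, KCNQ/SK following-frequency sweeps, pump/ion experiments).
#'
#' @param name preset name; see \code{list_presets()}.
#' @return list of class \code{"tj_preset"} with all experiment parameters.
#' @export
make_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  structure(c(list(name = name), reg[[name]]), class = "tj_preset")
}

#' @rdname make_preset
#' @export
list_presets <- function() names(preset_registry())

## generic cable constructor for toy fixtures (same conventions as
## discretize: lateral cylinder areas, half-segment axial resistances)
toy_cable <- function(parent, diameter_um, length_um, passive = tj_passive(),
                      branch = "cable", dist_um = NULL) {
  n <- length(parent)
  stopifnot(length(diameter_um) == n, length(length_um) == n)
  half_r <- function(i) {
    if (length_um[i] == 0) return(0)
    passive$Ra * (length_um[i] * 1e-4 / 2) / (pi * (diameter_um[i] * 1e-4)^2 / 4) / 1000
  }
  hr <- vapply(seq_len(n), half_r, numeric(1))
  g_ax <- numeric(n)
  for (i in seq_len(n)) if (parent[i] > 0) g_ax[i] <- 1 / (hr[i] + hr[parent[i]])
  if (is.null(dist_um)) dist_um <- cumsum(length_um) - length_um / 2
  if (length(branch) == 1) branch <- rep(branch, n)
  structure(list(
    n = n, parent = as.integer(parent), g_axial = g_ax,
    area_cm2 = ifelse(length_um > 0, pi * diameter_um * 1e-4 * length_um * 1e-4, 0),
    section = branch, branch = branch, dist_um = dist_um,
    diameter_um = diameter_um, length_um = length_um,
    passive = passive, geometry = NULL
  ), class = "tj_cable")
}

#' Toy model fixtures with independent references
#'
#' Small cables used as numerical oracles for the solver:
#' \describe{
#'   \item{single}{one passive compartment; RC step response with
#'     tau = Rm*Cm = 10 ms exactly.}
#'   \item{two_comp}{two coupled compartments; reference is direct ODE
#'     integration of the two-state system.}
#'   \item{uniform}{a 2 mm uniform passive cable; interior step response
#'     follows the analytic infinite-cable solution before boundary
#'     effects arrive.}
#'   \item{y_junction}{a symmetric Y: identical daughters must carry
#'     identical spikes.}
#' }
#'
#' @return named list; each element holds a \code{cable} plus reference
#'   metadata (analytic constants, site indices).
#' @export
make_toy_models <- function() {
  p <- tj_passive()
  single <- list(
    cable = toy_cable(0L, 20, 20, p),
    tau_ms = p$Rm * p$Cm / 1000,         # 10 ms
    r_in_MOhm = p$Rm / (pi * 20e-4 * 20e-4) / 1e6
  )
  two <- list(
    cable = toy_cable(c(0L, 1L), c(10, 10), c(20, 20), p),
    note = "reference: direct integration of the coupled two-compartment ODEs"
  )
  nseg <- 200L
  uni <- list(
    cable = toy_cable(c(0L, seq_len(nseg - 1L)), rep(1, nseg),
                      rep(2000 / nseg, nseg), p),
    lambda_um = sqrt(p$Rm * 1e-4 / (4 * p$Ra)) * 1e4,  # DC space constant
    tau_ms = p$Rm * p$Cm / 1000
  )
  ## symmetric Y: 40-compartment parent (1.0 um), two 40-compartment
  ## daughters (0.6 um) from a zero-size branch node
  npar <- 40L; ndau <- 40L
  parent <- c(0L, seq_len(npar - 1L),              # parent chain 1..40
              npar,                                # node 41 (zero size)
              npar + 1L, npar + 1L + seq_len(ndau - 1L),  # daughter A 42..81
              npar + 1L, npar + 1L + ndau + seq_len(ndau - 1L)) # daughter B
  dia <- c(rep(1, npar), 0, rep(0.6, 2 * ndau))
  len <- c(rep(1000 / npar, npar), 0, rep(1000 / ndau, 2 * ndau))
  br <- c(rep("parent", npar), "node", rep("dauA", ndau), rep("dauB", ndau))
  dst <- c(seq_len(npar) * 25 - 12.5, 1000,
           1000 + seq_len(ndau) * 25 - 12.5, 1000 + seq_len(ndau) * 25 - 12.5)
  yj <- list(cable = toy_cable(parent, dia, len, p, branch = br, dist_um = dst))
  list(single = single, two_comp = two, uniform = uni, y_junction = yj)
}

#' Synthetic voltage trace with known spikes
#'
#' Builds a \code{tj_trace}-compatible object whose columns contain
#' triangular spike waveforms at specified times, for unit-testing the
#' spike and ectopic-event detectors against constructed ground truth.
#'
#' @param spike_times list of numeric vectors, one per site (ms), or a
#'   single vector for one site.
#' @param sites site labels (default \code{"cable@<k>"}).
#' @param duration_ms,dt_ms time base.
#' @param amplitude_mV spike peak above rest.
#' @param half_width_ms spike half-width.
#' @param rest resting potential (mV).
#' @return object of class \code{"tj_trace"}.
#' @export
make_synthetic_trace <- function(spike_times, sites = NULL,
                                 duration_ms = NULL, dt_ms = 0.1,
                                 amplitude_mV = 75, half_width_ms = 1,
                                 rest = -60) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  if (any(vapply(spike_times, is.unsorted, TRUE)))
    stop("spike times must be sorted")
  ns <- length(spike_times)
  if (is.null(sites)) sites <- paste0("cable@", seq_len(ns) * 1000)
  if (is.null(duration_ms))
    duration_ms <- max(c(10, unlist(spike_times) + 5))
  time <- seq(0, duration_ms, by = dt_ms)
  v <- matrix(rest, length(time), ns)
  w <- 2 * half_width_ms                    # triangle base half-length
  for (j in seq_len(ns)) for (ts in spike_times[[j]]) {
    shape <- pmax(0, 1 - abs(time - ts) / w)
    v[, j] <- pmax(v[, j], rest + amplitude_mV * shape)
  }
  colnames(v) <- sites
  structure(list(time = time, v = v, vmax = apply(v, 2, max),
                 state = NULL, sites = sites, comps = seq_len(ns),
                 dt = dt_ms, rest = rest, cable = NULL),
            class = "tj_trace")
}
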