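## Experiment layer: spike detection, conduction velocity, amplitude
## profiles, propagation reliability, following frequency, ectopic-spike
## classification, and parameter sweeps.

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings, at most one spike per refractory window.
#' Crossing times are linearly interpolated between samples; the spike
#' peak is the maximum V between the crossing and the return below
#' threshold. Amplitude is peak minus the resting potential.
#'
#' @param time time base (ms).
#' @param v voltage samples (mV).
#' @param threshold detection threshold (mV); default -10.
#' @param refractory minimum spike separation (ms); default 2.
#' @param rest resting potential used for amplitudes (mV).
#' @return data.frame with \code{t_cross}, \code{t_peak}, \code{peak_mV},
#'   \code{amplitude_mV}; zero rows if no spikes.
#' @export
detect_spikes <- function(time, v, threshold = -10, refractory = 2, rest = -60) {
  if (length(time) != length(v)) stop("time and v must have equal length")
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  out <- list()
  last <- -Inf
  for (i in up) {
    ## interpolated crossing time
    tc <- time[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (time[i + 1] - time[i])
    if (tc - last < refractory) next
    ## peak: maximum until v falls back below threshold (or trace ends)
    j <- i + 1
    while (j < length(v) && v[j] >= threshold) j <- j + 1
    seg <- i:(max(j, i + 1))
    k <- seg[which.max(v[seg])]
    out[[length(out) + 1]] <- c(tc, time[k], v[k])
    last <- tc
  }
  if (!length(out))
    return(data.frame(t_cross = numeric(0), t_peak = numeric(0),
                      peak_mV = numeric(0), amplitude_mV = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(t_cross = m[, 1], t_peak = m[, 2], peak_mV = m[, 3],
             amplitude_mV = m[, 3] - rest)
}

site_dist <- function(label) as.numeric(sub("^.*@", "", label))

#' Conduction velocity between two recorded sites
#'
#' CV = distance / spike-latency between the first spike detected at each
#' of two sites on one branch. Interpolated threshold-crossing times are
#' used for the latency.
#'
#' @param trace a \code{tj_trace} recorded at (at least) two sites on the
#'   same branch.
#' @param sites two site labels or column indices.
#' @param threshold spike threshold (mV).
#' @return conduction velocity in m/s.
#' @export
conduction_velocity <- function(trace, sites = c(1, 2), threshold = -10) {
  stopifnot(inherits(trace, "tj_trace"), length(sites) == 2)
  idx <- if (is.character(sites)) match(sites, trace$sites) else sites
  if (any(is.na(idx))) stop("unknown site(s)")
  br <- sub("@.*$", "", trace$sites[idx])
  if (br[1] != br[2])
    stop("sites must lie on the same branch (got ", br[1], ", ", br[2], ")")
  d <- abs(site_dist(trace$sites[idx]))
  if (abs(diff(d)) < 1) stop("sites must be at distinct distances")
  t12 <- vapply(idx, function(j) {
    sp <- detect_spikes(trace$time, trace$v[, j], threshold, rest = trace$rest)
    if (nrow(sp) == 0)
      stop("undefined conduction velocity: no spike at site ", trace$sites[j])
    sp$t_cross[1]
  }, numeric(1))
  if (abs(diff(t12)) < 1e-9) stop("zero latency between sites")
  abs(diff(d)) / abs(diff(t12)) * 1e-3   # um/ms -> m/s
}

#' Measure conduction velocity in the full model
#'
#' Evokes a single orthodromic spike (0.2 nA, 1 ms at 4.6 mm in the
#' peripheral axon) and measures CV between two distal sites on the
#' requested branch, away from the junction and cable ends.
#'
#' @param model a \code{tj_model}.
#' @param branch \code{"peripheral"} or \code{"central"}.
#' @param sites_um the two measurement distances from the junction (um).
#' @param dt time step (ms).
#' @return CV in m/s.
#' @export
measure_cv <- function(model, branch = c("peripheral", "central"),
                       sites_um = NULL, dt = 0.01) {
  branch <- match.arg(branch)
  if (is.null(sites_um))
    sites_um <- if (branch == "peripheral") c(3600, 1600) else c(2000, 4000)
  rec <- lapply(sites_um, function(d) list(branch = branch, dist_um = d))
  tr <- run_simulation(model, tj_stimulus("peripheral", 4600),
                       duration = 40, dt = dt, record = rec,
                       record_dt = dt)
  conduction_velocity(tr, c(1, 2))
}

first_peak_amplitude <- function(time, v, rest, min_rise = 0.5) {
  ## amplitude of the first local maximum after the trace has risen
  ## min_rise mV above rest (the early, orthodromically propagating mode;
  ## any later maximum belongs to the soma-reflected mode)
  n <- length(v)
  i <- which(v > rest + min_rise)
  if (!length(i)) return(0)
  i <- i[1]
  while (i < n && v[i + 1] >= v[i]) i <- i + 1
  v[i] - rest
}

#' Spatial profile of the early-mode spike amplitude
#'
#' Evokes a single orthodromic spike and reports, at sites spanning the
#' T-junction, the amplitude of the early (orthodromically propagating)
#' voltage peak - the first local maximum at each site; the later,
#' soma-reflected mode is excluded.
#'
#' @param model a \code{tj_model}.
#' @param dists_um signed distances from the junction (negative =
#'   peripheral side).
#' @param stimulus the evoking stimulus.
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @return data.frame with \code{distance_um}, \code{amplitude_mV}.
#' @export
amplitude_profile <- function(model, dists_um = seq(-100, 100, by = 10),
                              stimulus = tj_stimulus("peripheral", 4600),
                              duration = 40, dt = 0.025) {
  rec <- lapply(dists_um, function(d) {
    if (d == 0) list(branch = "junction", dist_um = 0)
    else if (d < 0) list(branch = "peripheral", dist_um = -d)
    else list(branch = "central", dist_um = d)
  })
  tr <- run_simulation(model, stimulus, duration = duration, dt = dt,
                       record = rec, record_dt = dt)
  amp <- vapply(seq_along(dists_um), function(j)
    first_peak_amplitude(tr$time, tr$v[, j], tr$rest), numeric(1))
  data.frame(distance_um = dists_um, amplitude_mV = amp)
}

#' Reliability of spike propagation through the T-junction
#'
#' Delivers a train of current pulses in the distal peripheral axon and
#' scores, for each stimulus, whether a spike reaches the distal central
#' axon. A stimulus counts as propagated when a central-site spike falls
#' inside a latency window around its expected arrival (the window is
#' anchored on the measured latency of the first propagated spike, and
#' spikes are consumed greedily so each can validate only one stimulus).
#' Following the convention that the first spike of a train always
#' propagates, stimuli from \code{score_from} onward are scored.
#'
#' @param model a \code{tj_model}.
#' @param freq_Hz stimulus frequency (Hz).
#' @param n_stimuli pulses in the train.
#' @param score_from first scored stimulus (default 2).
#' @param stim_branch,stim_dist_um injection site.
#' @param detect_branch,detect_dist_um detection site.
#' @param amp_nA,width_ms pulse shape; the default train amplitude
#'   (0.4 nA) is the calibrated suprathreshold value at which every pulse
#'   of a train generates a peripheral spike.
#' @param dt time step (ms).
#' @param threshold spike threshold (mV).
#' @return object of class \code{"tj_propagation"}: frequency, counts and
#'   \code{reliability} (percent).
#' @export
propagation_reliability <- function(model, freq_Hz, n_stimuli = 20,
                                    score_from = 2,
                                    stim_branch = "peripheral", stim_dist_um = 4600,
                                    detect_branch = "central", detect_dist_um = 5000,
                                    amp_nA = 0.4, width_ms = 1,
                                    dt = 0.025, threshold = -10) {
  if (n_stimuli < 1) stop("n_stimuli must be >= 1")
  if (freq_Hz <= 0) stop("stimulus frequency must be positive")
  onset <- 5
  isi <- 1000 / freq_Hz
  stim <- tj_stimulus(stim_branch, stim_dist_um, amp_nA, width_ms,
                      freq_Hz, n_stimuli, onset)
  duration <- onset + (n_stimuli - 1) * isi + 60
  tr <- run_simulation(model, stim, duration = duration, dt = dt,
                       record = list(list(detect_branch, detect_dist_um)),
                       record_dt = 0.1)
  sp <- detect_spikes(tr$time, tr$v[, 1], threshold, rest = tr$rest)
  stim_times <- onset + (seq_len(n_stimuli) - 1) * isi
  scored <- seq(score_from, n_stimuli)

  ok <- logical(n_stimuli)
  if (nrow(sp) > 0) {
    lat <- sp$t_cross[1] - stim_times[1]
    if (lat > 0 && lat < 60) {
      used <- logical(nrow(sp))
      for (k in seq_len(n_stimuli)) {
        w <- which(!used & sp$t_cross >= stim_times[k] + 0.5 * lat &
                     sp$t_cross <= stim_times[k] + 1.6 * lat + 5)
        if (length(w)) { ok[k] <- TRUE; used[w[1]] <- TRUE }
      }
    }
  }
  structure(list(freq_Hz = freq_Hz, n_stimuli = n_stimuli,
                 scored = scored, propagated = ok,
                 n_propagated = sum(ok[scored]),
                 reliability = 100 * sum(ok[scored]) / length(scored)),
            class = "tj_propagation")
}

#' @export
print.tj_propagation <- function(x, ...) {
  cat(sprintf("propagation at %g Hz: %d/%d scored stimuli -> %.1f%% reliability\n",
              x$freq_Hz, x$n_propagated, length(x$scored), x$reliability))
  invisible(x)
}

#' Following frequency
#'
#' The highest stimulation frequency at which 100% of peripherally evoked
#' spikes propagate into the distal central axon. A coarse frequency
#' ladder brackets the failure onset, then bisection refines it to 1 Hz
#' below 40 Hz and 2 Hz above; ties break toward the lower frequency.
#'
#' @param model a \code{tj_model}.
#' @param ladder initial coarse frequencies (Hz), increasing.
#' @param n_stimuli pulses per train.
#' @param ... passed to \code{propagation_reliability}.
#' @return list with \code{following_Hz}, \code{saturated} (TRUE if 100%
#'   at the ladder maximum), and the table of \code{evaluations}.
#' @export
following_frequency <- function(model, ladder = c(10, 20, 40, 70, 100, 130, 160),
                                n_stimuli = 20, ...) {
  evals <- data.frame(freq_Hz = numeric(0), reliability = numeric(0))
  rel <- function(f) {
    r <- propagation_reliability(model, f, n_stimuli, ...)$reliability
    evals <<- rbind(evals, data.frame(freq_Hz = f, reliability = r))
    r
  }
  ladder <- sort(unique(round(ladder)))
  lo <- NA; hi <- NA
  for (f in ladder) {
    if (rel(f) >= 100) lo <- f
    else { hi <- f; break }
  }
  if (is.na(hi))
    return(list(following_Hz = lo, saturated = TRUE, evaluations = evals))
  if (is.na(lo)) { # failure already at the lowest ladder frequency
    lo <- 1
    if (hi > lo && rel(lo) < 100)
      return(list(following_Hz = 0, saturated = FALSE, evaluations = evals))
  }
  repeat {
    tol <- if (hi <= 40) 1 else 2
    if (hi - lo <= tol) break
    mid <- floor((lo + hi) / 2)
    if (rel(mid) >= 100) lo <- mid else hi <- mid
  }
  list(following_Hz = lo, saturated = FALSE, evaluations = evals)
}

#' Classify orthodromic, antidromic (ectopic) and collided spikes
#'
#' Given spike trains recorded at two peripheral sites (a distal site near
#' the stimulus and a site more proximal to the T-junction), events are
#' paired across the sites within a travel-time window. An event at the
#' proximal site is \emph{antidromic} (ectopic, junction-born) when it
#' precedes its distal partner or has none; distal events with no
#' proximal partner are \emph{collisions} (the orthodromic spike vanished
#' between the sites).
#'
#' @param trace a \code{tj_trace} with the two peripheral sites recorded.
#' @param proximal_site,distal_site site labels or indices (proximal =
#'   closer to the junction).
#' @param threshold spike threshold (mV).
#' @param cv_min minimum plausible conduction velocity (m/s) used to set
#'   the pairing window.
#' @return list with data.frame \code{events} (time_ms, type at the
#'   proximal site) and \code{collision_times} (distal events that never
#'   arrived proximally).
#' @export
detect_ectopic_spikes <- function(trace, proximal_site = 1, distal_site = 2,
                                  threshold = -10, cv_min = 0.2) {
  stopifnot(inherits(trace, "tj_trace"))
  ip <- if (is.character(proximal_site)) match(proximal_site, trace$sites) else proximal_site
  id <- if (is.character(distal_site)) match(distal_site, trace$sites) else distal_site
  dp <- abs(site_dist(trace$sites[ip])); dd <- abs(site_dist(trace$sites[id]))
  if (dd <= dp) stop("distal_site must be farther from the junction than proximal_site")
  W <- (dd - dp) / (cv_min * 1000) + 1    # max travel time (ms) + margin
  tp <- detect_spikes(trace$time, trace$v[, ip], threshold, rest = trace$rest)$t_cross
  td <- detect_spikes(trace$time, trace$v[, id], threshold, rest = trace$rest)$t_cross

  used_d <- logical(length(td))
  type <- character(length(tp))
  for (i in seq_along(tp)) {
    cand <- which(!used_d & abs(td - tp[i]) <= W)
    if (!length(cand)) { type[i] <- "antidromic"; next }
    j <- cand[which.min(abs(td[cand] - tp[i]))]
    used_d[j] <- TRUE
    type[i] <- if (td[j] <= tp[i]) "orthodromic" else "antidromic"
  }
  list(events = data.frame(time_ms = tp, type = type),
       collision_times = td[!used_d])
}

#' Parameter sweep over model configurations
#'
#' Runs an independent deterministic simulation per grid point and
#' tabulates the outcome. Failed points are recorded with NA and the
#' error message, never dropped.
#'
#' @param grid data.frame; one row per configuration.
#' @param model_fn function(row) returning a \code{tj_model} for one row.
#' @param outcome_fn function(model, row) returning a single numeric
#'   outcome (e.g. a following frequency, a reliability, an amplitude).
#' @return the grid with added columns \code{outcome} and \code{error}.
#' @export
sweep_protocol <- function(grid, model_fn, outcome_fn) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  grid$outcome <- NA_real_
  grid$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(outcome_fn(model_fn(grid[i, , drop = FALSE]),
                               grid[i, , drop = FALSE]),
                    error = function(e) e)
    if (inherits(res, "error")) grid$error[i] <- conditionMessage(res)
    else grid$outcome[i] <- as.numeric(res)
  }
  grid
}

#' Ion-accumulation / electrogenic-pump experiment
#'
#' Runs a 100 Hz train of 20 peripherally evoked spikes with Na+/K+
#' concentration dynamics enabled, at a low and a high (1000x) maximal
#' pump current density, recording voltage, equilibrium potentials and
#' membrane currents near the junction, and scores propagation into the
#' distal central axon.
#'
#' @param cable a \code{tj_cable}.
#' @param densities density map (defaults to the NaV+KDR exemplar model).
#' @param kinetics a \code{tj_kinetics}.
#' @param i_pump_low,i_pump_high maximal net pump current densities
#'   (mA/cm^2); the high level is 1000x the low one. The leak reversal is
#'   calibrated on the pump-free model for both levels, so the raised
#'   pump expresses its electrogenic (hyperpolarizing) shift.
#' @param gsk somatic SK density (mS/cm^2) co-enabled with CaV and Ca
#'   dynamics when > 0.
#' @param freq_Hz,n_stimuli train parameters.
#' @param dt time step (ms).
#' @return list with one entry per pump level: the recorded
#'   \code{tj_trace} (with E_Na/E_K/currents) and the
#'   \code{tj_propagation} score.
#' @export
pump_ion_experiment <- function(cable, densities = NULL,
                                kinetics = tj_kinetics(),
                                i_pump_low = 1.3e-6, i_pump_high = 1.3e-3,
                                gsk = 0, freq_Hz = 100, n_stimuli = 20,
                                dt = 0.025) {
  if (is.null(densities)) {
    densities <- if (gsk > 0)
      density_map(cable, ca = c(soma = 3), sk = c(soma = gsk))
    else density_map(cable)
  }
  e_leak0 <- tj_model(cable, densities, kinetics)$e_leak
  run_level <- function(ipump) {
    mdl <- tj_model(cable, densities, kinetics,
                    ion_dynamics = TRUE, pump = TRUE, i_pump_max = ipump,
                    e_leak = e_leak0)
    onset <- 5
    stim <- tj_stimulus("peripheral", 4600, amp_nA = 0.4, freq_Hz = freq_Hz,
                        n_pulses = n_stimuli, onset_ms = onset)
    tr <- run_simulation(mdl, stim,
                         duration = onset + (n_stimuli - 1) * 1000 / freq_Hz + 60,
                         dt = dt,
                         record = list(list("central", 20), list("central", 5000)),
                         record_dt = 0.1, record_extra = TRUE)
    prop <- propagation_reliability(mdl, freq_Hz, n_stimuli, dt = dt)
    list(trace = tr, propagation = prop)
  }
  list(low = run_level(i_pump_low), high = run_level(i_pump_high))
}
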