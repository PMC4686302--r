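## Configuration parsing and result serialization.
##
## Configs are hierarchical YAML; unknown keys are rejected with the path
## to the offending key. CSV outputs embed units in column names and are
## written at full double precision so round-trips are exact.

config_defaults <- function() list(
  geometry = list(
    soma = list(length_um = 25, diameter_um = 25, nseg = 1),
    stem = list(length_um = 150, diameter_um = 1.4, nseg = 100),
    peripheral = list(diameter_um = 0.8),
    central = list(diameter_um = 0.4),
    proximal = list(length_um = 100, nseg = 100),
    distal = list(length_um = 5000, nseg = 100)
  ),
  passive = list(Rm = 10000, Ra = 100, Cm = 1),
  kinetics = unclass(tj_kinetics()),
  densities = list(na = list(all = 40, soma = 20), kdr = list(all = 40),
                   kcnq = NULL, ca = NULL, sk = NULL),
  ions = list(enabled = FALSE, pump = FALSE, i_pump_max = 1.3e-3),
  stimulus = list(branch = "peripheral", dist_um = 4600, amp_nA = 0.2,
                  width_ms = 1, freq_Hz = 0, n_pulses = 1, onset_ms = 1),
  simulation = list(dt_ms = 0.01, duration_ms = 40, record_dt_ms = 0.025,
                    record = list(list(branch = "soma", dist_um = 0)))
)

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  ## density maps take open region keys at any depth
  free <- startsWith(path, "config.densities")
  for (k in names(user)) {
    here <- paste0(path, ".", k)
    if (!k %in% names(defaults) && !free)
      stop("unknown configuration key: ", sub("^\\.", "", here))
    defaults[[k]] <- if (is.list(defaults[[k]]) || is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], here) else user[[k]]
  }
  defaults
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration, fills defaults (an empty file yields the
#' full default exemplar model) and rejects unknown keys.
#'
#' @param path file path, or NULL for pure defaults.
#' @return validated configuration list of class \code{"tj_config"}.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  cfg <- merge_config(config_defaults(), user, "config")
  dims <- c(unlist(lapply(cfg$geometry, function(s)
    s[names(s) %in% c("length_um", "diameter_um")])))
  if (any(dims <= 0)) stop("geometry dimensions must be positive")
  dens <- unlist(cfg$densities)
  if (length(dens) && any(dens < 0)) stop("densities must be >= 0")
  structure(cfg, class = "tj_config")
}

#' Build the model described by a configuration
#'
#' @param cfg a \code{tj_config}.
#' @return list with \code{cable}, \code{model}, \code{stimulus},
#'   \code{simulation} settings.
#' @export
build_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "tj_config"))
  g <- cfg$geometry
  geom <- build_geometry(
    soma_diameter = g$soma$diameter_um, soma_length = g$soma$length_um,
    stem_diameter = g$stem$diameter_um, stem_length = g$stem$length_um,
    peripheral_diameter = g$peripheral$diameter_um,
    central_diameter = g$central$diameter_um,
    proximal_length = g$proximal$length_um, distal_length = g$distal$length_um,
    soma_nseg = g$soma$nseg, stem_nseg = g$stem$nseg,
    proximal_nseg = g$proximal$nseg, distal_nseg = g$distal$nseg)
  cable <- discretize(geom, tj_passive(cfg$passive$Rm, cfg$passive$Ra, cfg$passive$Cm))
  dn <- lapply(cfg$densities, function(d) if (is.null(d)) NULL else unlist(d))
  dens <- density_map(cable, na = dn$na, kdr = dn$kdr, kcnq = dn$kcnq,
                      ca = dn$ca, sk = dn$sk)
  kin <- do.call(tj_kinetics, cfg$kinetics[names(cfg$kinetics) %in%
                                             names(tj_kinetics_defaults)])
  model <- tj_model(cable, dens, kin, ion_dynamics = cfg$ions$enabled,
                    pump = cfg$ions$pump, i_pump_max = cfg$ions$i_pump_max)
  stim <- do.call(tj_stimulus, cfg$stimulus)
  list(cable = cable, model = model, stimulus = stim,
       simulation = cfg$simulation)
}

full_precision_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a result to CSV with JSON metadata
#'
#' Traces are written in long format (time_ms, site, variable, value);
#' data.frame results (sweeps, profiles, maps) one row per point;
#' propagation results as a one-row table. A JSON sidecar records the
#' result class and package version. Numeric values are written at full
#' double precision; re-reading returns identical values.
#'
#' @param result a \code{tj_trace}, \code{tj_propagation} or data.frame.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  meta <- list(name = name, class = class(result)[1],
               package = "drgtj",
               version = as.character(utils::packageVersion("drgtj")))
  if (inherits(result, "tj_trace")) {
    vars <- c("v", intersect(c("ca", "e_na", "e_k", "i_na", "i_k"), names(result)))
    long <- do.call(rbind, lapply(vars, function(nm)
      do.call(rbind, lapply(seq_along(result$sites), function(j)
        data.frame(time_ms = result$time, site = result$sites[j],
                   variable = nm, value = result[[nm]][, j])))))
    full_precision_csv(long, csv)
    meta$sites <- result$sites
    meta$dt_ms <- result$dt
  } else if (inherits(result, "tj_propagation")) {
    full_precision_csv(data.frame(freq_Hz = result$freq_Hz,
                                  n_stimuli = result$n_stimuli,
                                  n_scored = length(result$scored),
                                  n_propagated = result$n_propagated,
                                  reliability_pct = result$reliability), csv)
  } else if (is.data.frame(result)) {
    full_precision_csv(result, csv)
  } else stop("unsupported result class: ", class(result)[1])
  js <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

#' Run record for provenance
#'
#' Writes a JSON run record: configuration snapshot, calibration constants
#' (NaV voltage reference, KDR rate scales, channel parameters), package
#' version and the output manifest. Re-running the recorded configuration
#' reproduces the outputs deterministically.
#'
#' @param cfg a \code{tj_config}.
#' @param outputs character vector of files produced.
#' @param path output path for the record.
#' @return invisibly, \code{path}.
#' @export
write_run_record <- function(cfg, outputs, path) {
  kin <- cfg$kinetics
  rec <- list(
    package = "drgtj",
    version = as.character(utils::packageVersion("drgtj")),
    calibration = kin[c("v_ref", "a0_n", "a0_l", "tau_n_min", "tau_l_min",
                        "sk_div_a")],
    channel_parameters = kin,
    config = unclass(cfg),
    outputs = outputs
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
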