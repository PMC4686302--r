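## Frequency-domain analysis of the passive compartment tree.
##
## The passive admittance matrix at angular frequency w is
## Y = G_leak + i w C + L (L the axial Laplacian). Input impedance at a
## node is the diagonal of Y^-1; voltage transfer follows from one column.
## The tree structure allows exact O(n) factorization (complex Hines
## elimination); a dense linear solve is kept as an independent
## cross-check (method = "dense").

passive_admittance <- function(cable, freq_Hz) {
  w <- 2 * pi * freq_Hz / 1000            # rad/ms
  gleak <- 1000 / cable$passive$Rm * cable$area_cm2   # mS
  cm <- cable$passive$Cm * cable$area_cm2             # uF
  gleak + 1i * w * cm                                  # mS (complex)
}

hines_factor <- function(parent, g_ax, ymem) {
  n <- length(parent)
  diag <- ymem
  for (i in 2:n) {
    diag[i] <- diag[i] + g_ax[i]
    diag[parent[i]] <- diag[parent[i]] + g_ax[i]
  }
  f <- complex(n)
  for (i in n:2) {
    f[i] <- -g_ax[i] / diag[i]
    diag[parent[i]] <- diag[parent[i]] + f[i] * g_ax[i]
  }
  list(parent = parent, g_ax = g_ax, diag = diag, f = f)
}

hines_solve <- function(fac, rhs) {
  n <- length(fac$diag)
  b <- as.complex(rhs)
  for (i in n:2) b[fac$parent[i]] <- b[fac$parent[i]] - fac$f[i] * b[i]
  x <- complex(n)
  x[1] <- b[1] / fac$diag[1]
  for (i in 2:n) x[i] <- (b[i] + fac$g_ax[i] * x[fac$parent[i]]) / fac$diag[i]
  x
}

dense_admittance <- function(cable, freq_Hz) {
  n <- cable$n
  Y <- matrix(0 + 0i, n, n)
  diag(Y) <- passive_admittance(cable, freq_Hz)
  for (i in 2:n) {
    p <- cable$parent[i]
    g <- cable$g_axial[i]
    Y[i, i] <- Y[i, i] + g
    Y[p, p] <- Y[p, p] + g
    Y[i, p] <- Y[i, p] - g
    Y[p, i] <- Y[p, i] - g
  }
  Y
}

#' Input impedance of the passive model
#'
#' Magnitude of the complex input impedance |Z_N| at a location, for a
#' sinusoidal current of the stated frequency (0 = DC), computed on the
#' purely passive cable (R_m, C_m, R_a only).
#'
#' @param cable a \code{tj_cable}.
#' @param branch,dist_um location (see \code{resolve_site}).
#' @param freq_Hz frequency (Hz); >= 0.
#' @param method \code{"tree"} (O(n) Hines elimination, default) or
#'   \code{"dense"} (full complex solve; cross-check).
#' @return |Z_N| in MOhm.
#' @examples
#' cb <- discretize(build_geometry())
#' input_impedance(cb, "junction", freq_Hz = 250)
#' @export
input_impedance <- function(cable, branch = "junction", dist_um = 0,
                            freq_Hz = 0, method = c("tree", "dense")) {
  stopifnot(inherits(cable, "tj_cable"))
  method <- match.arg(method)
  if (freq_Hz < 0) stop("frequency must be >= 0")
  k <- resolve_site(cable, branch, dist_um)
  rhs <- numeric(cable$n); rhs[k] <- 1            # 1 uA
  if (method == "tree") {
    fac <- hines_factor(cable$parent, cable$g_axial, passive_admittance(cable, freq_Hz))
    x <- hines_solve(fac, rhs)
  } else {
    x <- solve(dense_admittance(cable, freq_Hz), rhs)
  }
  Mod(x[k]) / 1000                                 # mV/uA = kOhm -> MOhm
}

#' Spatial input-impedance profile around the T-junction
#'
#' @param cable a \code{tj_cable}.
#' @param dists_um signed arc-distances (um): negative = peripheral side,
#'   positive = central side, 0 = junction node.
#' @param freq_Hz frequency (Hz).
#' @return data.frame with \code{distance_um}, \code{Z_MOhm}.
#' @export
impedance_profile <- function(cable, dists_um = seq(-100, 100, by = 5),
                              freq_Hz = 250) {
  stopifnot(inherits(cable, "tj_cable"))
  fac <- hines_factor(cable$parent, cable$g_axial, passive_admittance(cable, freq_Hz))
  z <- vapply(dists_um, function(d) {
    k <- if (d == 0) resolve_site(cable, "junction")
         else if (d < 0) resolve_site(cable, "peripheral", -d)
         else resolve_site(cable, "central", d)
    rhs <- numeric(cable$n); rhs[k] <- 1
    Mod(hines_solve(fac, rhs)[k]) / 1000
  }, numeric(1))
  data.frame(distance_um = dists_um, Z_MOhm = z)
}

#' T-junction impedance over stem/soma geometry grids
#'
#' Rebuilds the geometry at each grid point and evaluates |Z_N| at the
#' T-junction.
#'
#' @param stem_lengths stem lengths (um).
#' @param stem_diameters stem diameters (um); mutually exclusive with
#'   \code{soma_diameters} as the second grid axis.
#' @param soma_diameters soma diameters (um); when given,
#'   \code{stem_diameters} must be length 1.
#' @param freq_Hz frequency (Hz).
#' @param central_diameter central-axon diameter (um).
#' @param passive a \code{tj_passive}.
#' @return data.frame with one row per grid point and column \code{Z_MOhm}.
#' @export
junction_impedance_map <- function(stem_lengths = 150,
                                   stem_diameters = 1.4,
                                   soma_diameters = NULL,
                                   freq_Hz = 250,
                                   central_diameter = 0.4,
                                   passive = tj_passive()) {
  if (any(stem_lengths <= 0) || any(stem_diameters <= 0))
    stop("grids must be positive")
  somas <- if (is.null(soma_diameters)) 25 else soma_diameters
  grid <- expand.grid(stem_length_um = stem_lengths,
                      stem_diameter_um = stem_diameters,
                      soma_diameter_um = somas)
  grid$Z_MOhm <- vapply(seq_len(nrow(grid)), function(i) {
    g <- build_geometry(stem_length = grid$stem_length_um[i],
                        stem_diameter = grid$stem_diameter_um[i],
                        soma_diameter = grid$soma_diameter_um[i],
                        central_diameter = central_diameter)
    input_impedance(discretize(g, passive), "junction", freq_Hz = freq_Hz)
  }, numeric(1))
  grid
}

#' Steady-state soma-to-junction voltage transfer ratio
#'
#' DC voltage attenuation V_junction / V_soma of the passive model for a
#' steady potential originating at the soma (computed from a DC current
#' injected at the soma: the ratio of the two node voltages).
#'
#' @param cable a \code{tj_cable}.
#' @param method \code{"tree"} or \code{"dense"} (cross-check).
#' @return ratio in (0, 1].
#' @export
transfer_ratio <- function(cable, method = c("tree", "dense")) {
  stopifnot(inherits(cable, "tj_cable"))
  method <- match.arg(method)
  s <- resolve_site(cable, "soma")
  j <- resolve_site(cable, "junction")
  rhs <- numeric(cable$n); rhs[s] <- 1
  x <- if (method == "tree") {
    hines_solve(hines_factor(cable$parent, cable$g_axial,
                             passive_admittance(cable, 0)), rhs)
  } else {
    solve(dense_admittance(cable, 0), rhs)
  }
  Re(x[j]) / Re(x[s])
}

#' Voltage-transfer map over stem geometry
#'
#' @param stem_lengths stem lengths (um).
#' @param stem_diameters stem diameters (um).
#' @param soma_diameters soma diameters (um).
#' @param passive a \code{tj_passive}.
#' @return data.frame with the grid and column \code{ratio}.
#' @export
transfer_map <- function(stem_lengths = seq(25, 300, by = 25),
                         stem_diameters = 1.4, soma_diameters = 25,
                         passive = tj_passive()) {
  grid <- expand.grid(stem_length_um = stem_lengths,
                      stem_diameter_um = stem_diameters,
                      soma_diameter_um = soma_diameters)
  grid$ratio <- vapply(seq_len(nrow(grid)), function(i) {
    g <- build_geometry(stem_length = grid$stem_length_um[i],
                        stem_diameter = grid$stem_diameter_um[i],
                        soma_diameter = grid$soma_diameter_um[i])
    transfer_ratio(discretize(g, passive))
  }, numeric(1))
  grid
}
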