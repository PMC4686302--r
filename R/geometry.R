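#' Geometric ratio at an axonal branch point
#'
#' Computes the 3/2-power diameter ratio
#' \deqn{GR = (d_1^{3/2} + d_2^{3/2}) / d_p^{3/2}}
#' for a parent axon of diameter \code{parent} branching into two daughters.
#' GR = 1 corresponds to perfect impedance matching for semi-infinite
#' cables; GR > 1 implies a conductance load that filters propagating
#' action potentials.
#'
#' @param parent parent-axon diameter (um).
#' @param daughters numeric vector of two daughter diameters (um).
#' @return dimensionless geometric ratio.
#' @examples
#' geometric_ratio(0.8, c(1.4, 0.4))
#' @export
geometric_ratio <- function(parent, daughters) {
  if (!is.numeric(parent) || length(parent) != 1L || !is.finite(parent) || parent <= 0)
    stop("'parent' must be a single positive diameter (um)")
  if (!is.numeric(daughters) || length(daughters) != 2L ||
      any(!is.finite(daughters)) || any(daughters <= 0))
    stop("'daughters' must be two positive diameters (um)")
  sum(daughters^1.5) / parent^1.5
}

#' Geometric-ratio sweep over stem-axon diameter
#'
#' Evaluates the branch-point geometric ratio at the T-junction for spikes
#' arriving from one of the three branches, over a range of stem diameters.
#' The parent is the branch of origin and the daughters are the two
#' remaining branches:
#' \itemize{
#'   \item \code{"peripheral-origin"} orthodromic conduction (periphery to cord),
#'   \item \code{"central-origin"} antidromic conduction,
#'   \item \code{"stem-origin"} soma-generated spikes entering the junction.
#' }
#'
#' @param stem_diameters stem diameters to sweep (um).
#' @param direction one of \code{"stem-origin"}, \code{"peripheral-origin"},
#'   \code{"central-origin"}.
#' @param peripheral_diameter peripheral-axon diameter (um), default 0.8.
#' @param central_diameter central-axon diameter (um), default 0.4.
#' @return data.frame with columns \code{stem_diameter_um}, \code{direction},
#'   \code{GR}.
#' @export
gr_sweep <- function(stem_diameters,
                     direction = c("peripheral-origin", "central-origin", "stem-origin"),
                     peripheral_diameter = 0.8,
                     central_diameter = 0.4) {
  direction <- match.arg(direction)
  if (any(!is.finite(stem_diameters)) || any(stem_diameters <= 0))
    stop("stem diameters must be positive")
  gr <- vapply(stem_diameters, function(ds) {
    switch(direction,
      "peripheral-origin" = geometric_ratio(peripheral_diameter, c(ds, central_diameter)),
      "central-origin"    = geometric_ratio(central_diameter, c(ds, peripheral_diameter)),
      "stem-origin"       = geometric_ratio(ds, c(peripheral_diameter, central_diameter)))
  }, numeric(1))
  data.frame(stem_diameter_um = stem_diameters, direction = direction, GR = gr)
}

## default section dimensions (um); diameters and lengths as printed in the
## source morphology: 25 x 25 soma, 1.4 x 150 stem, 0.8 um peripheral and
## 0.4 um central axons with 100 um proximal segments and 5 mm distal
## extensions, 100 compartments per axonal section.
tj_defaults <- function() {
  list(
    soma_diameter = 25, soma_length = 25, soma_nseg = 1L,
    stem_diameter = 1.4, stem_length = 150, stem_nseg = 100L,
    peripheral_diameter = 0.8, central_diameter = 0.4,
    proximal_length = 100, proximal_nseg = 100L,
    distal_length = 5000, distal_nseg = 100L
  )
}

#' Construct the pseudo-unipolar neuron geometry
#'
#' Builds the section list and tree topology of the model: a cylindrical
#' soma joined by a stem axon to the T-junction, where the peripheral and
#' central axons meet. Each axonal branch has a finely subdivided 100 um
#' proximal segment at the junction and a 5 mm distal extension.
#'
#' @param soma_diameter,soma_length soma cylinder dimensions (um).
#' @param stem_diameter,stem_length stem axon dimensions (um).
#' @param peripheral_diameter,central_diameter axon diameters (um).
#' @param proximal_length,distal_length lengths of the proximal and distal
#'   axonal sections (um).
#' @param soma_nseg,stem_nseg,proximal_nseg,distal_nseg compartments per
#'   section.
#' @return an object of class \code{"tj_geometry"}: a list of
#'   \code{sections} (name, length_um, diameter_um, nseg) and the fixed
#'   tree \code{topology}.
#' @examples
#' g <- build_geometry()
#' print(g)
#' @export
build_geometry <- function(soma_diameter = 25, soma_length = 25,
                           stem_diameter = 1.4, stem_length = 150,
                           peripheral_diameter = 0.8, central_diameter = 0.4,
                           proximal_length = 100, distal_length = 5000,
                           soma_nseg = 1L, stem_nseg = 100L,
                           proximal_nseg = 100L, distal_nseg = 100L) {
  dims <- c(soma_diameter = soma_diameter, soma_length = soma_length,
            stem_diameter = stem_diameter, stem_length = stem_length,
            peripheral_diameter = peripheral_diameter,
            central_diameter = central_diameter,
            proximal_length = proximal_length, distal_length = distal_length)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all lengths and diameters must be positive: ",
         paste(names(dims)[!is.finite(dims) | dims <= 0], collapse = ", "))
  nsegs <- c(soma_nseg, stem_nseg, proximal_nseg, distal_nseg)
  if (any(nsegs < 1L)) stop("n_compartments must be >= 1 for every section")

  sec <- function(name, length, diameter, nseg)
    list(name = name, length_um = length, diameter_um = diameter,
         nseg = as.integer(nseg))
  sections <- list(
    sec("soma", soma_length, soma_diameter, soma_nseg),
    sec("stem", stem_length, stem_diameter, stem_nseg),
    sec("peripheral_proximal", proximal_length, peripheral_diameter, proximal_nseg),
    sec("peripheral_distal", distal_length, peripheral_diameter, distal_nseg),
    sec("central_proximal", proximal_length, central_diameter, proximal_nseg),
    sec("central_distal", distal_length, central_diameter, distal_nseg)
  )
  names(sections) <- vapply(sections, `[[`, "", "name")
  ## the junction node has degree 3: stem, peripheral_proximal, central_proximal
  topology <- list(
    c("soma", "stem"),
    c("stem", "junction"),
    c("junction", "peripheral_proximal"),
    c("peripheral_proximal", "peripheral_distal"),
    c("junction", "central_proximal"),
    c("central_proximal", "central_distal")
  )
  structure(list(sections = sections, topology = topology),
            class = "tj_geometry")
}

#' @export
print.tj_geometry <- function(x, ...) {
  cat("T-junction neuron geometry\n")
  s <- do.call(rbind, lapply(x$sections, function(z)
    data.frame(section = z$name, length_um = z$length_um,
               diameter_um = z$diameter_um, nseg = z$nseg)))
  rownames(s) <- NULL
  print(s, row.names = FALSE)
  invisible(x)
}

#' Passive membrane parameters
#'
#' @param Rm specific membrane resistivity (Ohm cm^2), default 10000.
#' @param Ra axial resistivity (Ohm cm), default 100.
#' @param Cm specific membrane capacitance (uF/cm^2), default 1.
#' @return list of class \code{"tj_passive"}.
#' @export
tj_passive <- function(Rm = 10000, Ra = 100, Cm = 1) {
  if (any(c(Rm, Ra, Cm) <= 0)) stop("passive parameters must be positive")
  structure(list(Rm = Rm, Ra = Ra, Cm = Cm), class = "tj_passive")
}

#' Discretize the geometry into a compartment graph
#'
#' Splits each section into \code{nseg} cylindrical compartments and builds
#' the tree of axial couplings. Compartment membrane area is the lateral
#' cylinder area pi*d*(L/nseg) with no end caps. Axial resistance between
#' adjacent compartment centers is the sum of the two half-segment
#' resistances Ra*(L/2)/(pi d^2/4). The T-junction is represented by an
#' explicit zero-area node coupled to the junction-facing ends of the stem
#' and the two proximal axon sections; its voltage is the quantity reported
#' "at the T-junction (0 um)". Signed arc-distance from the junction is
#' negative on the peripheral side and positive on the central side; soma
#' and stem compartments carry the (positive) path distance to the junction
#' with branch label "stem"/"soma".
#'
#' @param geometry a \code{tj_geometry}.
#' @param passive a \code{tj_passive}.
#' @return object of class \code{"tj_cable"} with per-compartment vectors:
#'   \code{parent} (0-based index of parent, -1 for root), \code{g_axial}
#'   (coupling to parent, mS), \code{area_cm2}, \code{section},
#'   \code{branch}, \code{dist_um} (signed arc-distance), \code{diameter_um},
#'   \code{length_um}, and the passive parameters.
#' @export
discretize <- function(geometry, passive = tj_passive()) {
  stopifnot(inherits(geometry, "tj_geometry"))
  stopifnot(inherits(passive, "tj_passive"))
  secs <- geometry$sections

  ## per-compartment accumulators
  section <- character(0); branch <- character(0)
  diam <- numeric(0); len <- numeric(0); dist <- numeric(0)

  add_section <- function(s, branchname, dist_at_junction_end, sign) {
    n <- s$nseg
    dl <- s$length_um / n
    ## compartments ordered from junction side outward
    centers <- dist_at_junction_end + (seq_len(n) - 0.5) * dl
    list(section = rep(s$name, n), branch = rep(branchname, n),
         diam = rep(s$diameter_um, n), len = rep(dl, n),
         dist = sign * centers)
  }

  parts <- list(
    junction = list(section = "junction", branch = "junction",
                    diam = 0, len = 0, dist = 0),
    stem = add_section(secs$stem, "stem", 0, +1),             # distance along stem path (unsigned +)
    soma = add_section(secs$soma, "soma", secs$stem$length_um, +1),
    pprox = add_section(secs$peripheral_proximal, "peripheral", 0, -1),
    pdist = add_section(secs$peripheral_distal, "peripheral",
                        secs$peripheral_proximal$length_um, -1),
    cprox = add_section(secs$central_proximal, "central", 0, +1),
    cdist = add_section(secs$central_distal, "central",
                        secs$central_proximal$length_um, +1)
  )
  for (p in parts) {
    section <- c(section, p$section); branch <- c(branch, p$branch)
    diam <- c(diam, p$diam); len <- c(len, p$len); dist <- c(dist, p$dist)
  }
  n <- length(section)
  idx <- seq_len(n)                      # 1-based compartment ids
  ## index bookkeeping: order is junction, stem(1..), soma(..), pprox, pdist, cprox, cdist
  off <- unname(cumsum(c(1L, vapply(parts[-1], function(p) length(p$section), 0L))))
  first <- c(junction = 1L, stem = off[1] + 1L, soma = off[2] + 1L,
             pprox = off[3] + 1L, pdist = off[4] + 1L,
             cprox = off[5] + 1L, cdist = off[6] + 1L)
  last <- c(first[-1] - 1L, n); names(last) <- names(first)

  ## half-segment axial resistance in kOhm (=> conductance in mS)
  ## R = Ra * (len/2) / (pi d^2/4), lengths um -> cm
  half_r <- function(i) {
    if (len[i] == 0) return(0)          # zero-size junction node
    a_cross <- pi * (diam[i] * 1e-4)^2 / 4
    passive$Ra * (len[i] * 1e-4 / 2) / a_cross / 1000
  }
  hr <- vapply(idx, half_r, numeric(1))

  parent <- integer(n); parent[] <- NA_integer_
  g_ax <- numeric(n)
  link <- function(child, par) {
    r <- hr[child] + hr[par]
    if (r <= 0) stop("degenerate axial resistance")
    list(parent = par, g = 1 / r)
  }
  parent[first["junction"]] <- 0L        # root, 0 => none
  g_ax[first["junction"]] <- 0

  chain <- function(ids, par0) {
    ## ids ordered junction-side first; par0 is the compartment each chain hangs from
    p <- par0
    for (i in ids) {
      lk <- link(i, p)
      parent[i] <<- lk$parent; g_ax[i] <<- lk$g
      p <- i
    }
    p
  }
  jn <- first[["junction"]]
  end_stem <- chain(first[["stem"]]:last[["stem"]], jn)
  chain(first[["soma"]]:last[["soma"]], end_stem)
  end_pp <- chain(first[["pprox"]]:last[["pprox"]], jn)
  chain(first[["pdist"]]:last[["pdist"]], end_pp)
  end_cp <- chain(first[["cprox"]]:last[["cprox"]], jn)
  chain(first[["cdist"]]:last[["cdist"]], end_cp)

  area <- ifelse(len > 0, pi * (diam * 1e-4) * (len * 1e-4), 0)  # cm^2

  structure(list(
    n = n,
    parent = parent,                  # 1-based, 0 for root (junction)
    g_axial = g_ax,                   # mS, coupling to parent
    area_cm2 = area,
    section = section,
    branch = branch,
    dist_um = dist,
    diameter_um = diam,
    length_um = len,
    passive = passive,
    geometry = geometry
  ), class = "tj_cable")
}

#' @export
print.tj_cable <- function(x, ...) {
  cat(sprintf("T-junction compartment graph: %d compartments, total area %.3g cm^2\n",
              x$n, sum(x$area_cm2)))
  cat(sprintf("passive: Rm = %g Ohm cm^2, Ra = %g Ohm cm, Cm = %g uF/cm^2\n",
              x$passive$Rm, x$passive$Ra, x$passive$Cm))
  invisible(x)
}

#' Resolve a recording/stimulation site to a compartment index
#'
#' Sites are addressed by branch and unsigned arc-distance from the
#' T-junction (um): branches \code{"peripheral"}, \code{"central"},
#' \code{"stem"}, \code{"soma"} (distance ignored for the soma; the soma
#' compartment nearest the stem is used), or \code{"junction"}.
#'
#' @param cable a \code{tj_cable}.
#' @param branch branch name.
#' @param dist_um unsigned distance from the junction along the branch (um).
#' @return integer compartment index.
#' @export
resolve_site <- function(cable, branch, dist_um = 0) {
  stopifnot(inherits(cable, "tj_cable"))
  if (branch == "junction") return(which(cable$branch == "junction")[1])
  sel <- which(cable$branch == branch)
  if (length(sel) == 0) stop("unknown branch: ", branch)
  if (branch == "soma") return(sel[which.min(abs(cable$dist_um[sel]))])
  d <- abs(cable$dist_um[sel])
  i <- sel[which.min(abs(d - dist_um))]
  if (abs(abs(cable$dist_um[i]) - dist_um) > max(2 * cable$length_um[i], 1))
    warning("nearest compartment is ", abs(cable$dist_um[i]), " um from junction, requested ", dist_um)
  i
}
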