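## shared fixtures, built once per test run
tj_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(tj_cache[[name]])) tj_cache[[name]] <- force(expr)
  tj_cache[[name]]
}

default_cable <- function() cached("cable", discretize(build_geometry()))
default_model <- function() cached("model", tj_model(default_cable()))
stem75_cable  <- function() cached("cable75", discretize(build_geometry(stem_length = 75)))
stem75_model  <- function() cached("model75", tj_model(stem75_cable()))

## reindex a cable with a different (valid) topological order of
## compartments; used to check solver invariance to index ordering
permute_cable <- function(cable, perm) {
  inv <- integer(cable$n)
  inv[perm] <- seq_len(cable$n)
  out <- cable
  for (f in c("g_axial", "area_cm2", "section", "branch", "dist_um",
              "diameter_um", "length_um"))
    out[[f]] <- cable[[f]][perm]
  p <- cable$parent[perm]
  newp <- integer(cable$n)
  newp[p > 0L] <- inv[p[p > 0L]]
  out$parent <- newp
  stopifnot(all(out$parent < seq_len(out$n)))
  out
}

## breadth-first topological order from the root
bfs_order <- function(parent) {
  n <- length(parent)
  children <- split(seq_len(n)[parent > 0], parent[parent > 0])
  ord <- integer(0)
  frontier <- which(parent == 0L)
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
  }
  ord
}
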