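# shared fixtures: the study acquisition scheme and small deterministic draws

dbsi_scheme <- function() build_grid_scheme(3, 1500)

# brute-force lattice enumeration oracle (independent of build_grid_scheme)
brute_lattice <- function(r) {
  pts <- list()
  for (qx in -r:r) for (qy in -r:r) for (qz in -r:r) {
    if (qx^2 + qy^2 + qz^2 <= r^2) pts[[length(pts) + 1]] <- c(qx, qy, qz)
  }
  do.call(rbind, pts)
}

fraction_vector <- function(v) {
  c(v$fiber_fraction, v$restricted_fraction, v$hindered_fraction,
    v$nonrestricted_fraction)
}
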