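# Independent brute-force Mann-Whitney oracle: U by direct pairwise
# comparison counts, exact two-tailed p by enumerating every assignment of
# the pooled values to the two groups.
brute_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  min(u, length(a) * length(b) - u)
}

brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- brute_u(a, b)
  combos <- utils::combn(length(pooled), n1)
  stat <- apply(combos, 2, function(idx) {
    brute_u(pooled[idx], pooled[-idx])
  })
  mean(stat <= obs + 1e-9)
}

# default symmetric control phantom reused across tests
default_phantom <- function(...) fovea_phenotype("control", ...)

# noise-free grid for a phenotype, centered at the true fovea
phantom_grid <- function(ph, eye = "OD", orientation = "horizontal",
                         n_ascans = 300) {
  cc <- make_boundary_profiles(ph, orientation = orientation, eye = eye,
                               n_ascans = n_ascans)
  prof <- thickness_profiles(cc)
  ctr <- cc$meta$center_col * cc$meta$um_per_ascan / 1000
  interpolate_grid(eccentricity_axis(prof, ctr, eye, orientation))
}
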