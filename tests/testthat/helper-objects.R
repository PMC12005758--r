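# shared fixtures, built in code

default_bundle <- function() {
  list(params = sim_params(), np = nanoparticle_spec(),
       magnet = magnet_spec(), well = well_geometry())
}

# a population at explicit positions, bypassing the sampler
make_pop <- function(positions, radii, np_counts = NULL) {
  positions <- matrix(positions, ncol = 3)
  pop <- list(n = nrow(positions), positions = positions,
              radii = rep_len(radii, nrow(positions)),
              np_counts = if (is.null(np_counts)) rep(0, nrow(positions))
              else rep_len(np_counts, nrow(positions)))
  class(pop) <- "mba_population"
  pop
}

# random, possibly overlapping cluster in a box above the floor (contact-rich)
random_cluster <- function(n, seed, spread = 6e-4, r_mean = 1e-4,
                           z0 = 8e-4) {
  set.seed(seed)
  make_pop(cbind(stats::runif(n, -spread, spread),
                 stats::runif(n, -spread, spread),
                 z0 + stats::runif(n, 0, spread)),
           radii = r_mean * exp(stats::rnorm(n, 0, 0.1)))
}

# O(n^2) brute-force contact oracle (spheres + analytic cylinder walls)
brute_contacts <- function(pop, well) {
  res <- list()
  n <- pop$n
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- pop$positions[i, ] - pop$positions[j, ]
      dist <- sqrt(sum(d^2))
      delta <- pop$radii[i] + pop$radii[j] - dist
      if (delta >= 0 && dist > 0)
        res[[length(res) + 1]] <- data.frame(i = i, j = j, delta = delta)
    }
    dfl <- pop$radii[i] - (pop$positions[i, 3] - well$floor_z)
    if (dfl >= 0)
      res[[length(res) + 1]] <- data.frame(i = i, j = 0L, delta = dfl)
    rho <- sqrt(sum(pop$positions[i, 1:2]^2))
    dlat <- pop$radii[i] - (well$radius - rho)
    if (dlat >= 0 && rho > 0)
      res[[length(res) + 1]] <- data.frame(i = i, j = 0L, delta = dlat)
  }
  if (!length(res))
    return(data.frame(i = integer(0), j = integer(0), delta = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$i, out$j, out$delta), ]
}
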