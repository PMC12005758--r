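test_that("area coverage handles empty, single-disk and overlapping cases", {
  R <- 2.5e-3
  empty <- make_pop(matrix(numeric(0), 0, 3), radii = numeric(0))
  expect_equal(area_coverage(empty, R), 0)
  # single disk fully inside the ROI
  one <- make_pop(c(2e-4, -1e-4, 1e-4), radii = 3e-4)
  expect_equal(area_coverage(one, R, px = 2e-6), (3e-4)^2 / R^2,
               tolerance = 1e-3)
  # two overlapping disks against a Monte-Carlo union-area oracle
  two <- make_pop(rbind(c(0, 0, 1e-4), c(1.5e-3, 0, 1e-4)),
                  radii = c(1.2e-3, 1e-3))
  set.seed(77)
  xs <- runif(1e6, -R, R); ys <- runif(1e6, -R, R)
  in_roi <- xs^2 + ys^2 <= R^2
  in_union <- (xs^2 + ys^2 <= (1.2e-3)^2) |
    ((xs - 1.5e-3)^2 + ys^2 <= (1e-3)^2)
  mc <- sum(in_union & in_roi) / sum(in_roi)
  expect_equal(area_coverage(two, R, px = 2e-6), mc, tolerance = 0.01)
})

test_that("assembly time inverts a known exponential approach", {
  tau <- 0.8
  t <- seq(0, 10, by = 0.002)
  series <- data.frame(time = t, coverage = 1 - exp(-t / tau))
  # threshold on the plateau value at t_end (~1): t* = tau ln 20 against
  # the closed-form inversion of the sampled plateau
  plateau <- series$coverage[nrow(series)]
  expect_equal(as.numeric(assembly_time(series, 0.95)),
               -tau * log(1 - 0.95 * plateau), tolerance = 1e-3)
  expect_equal(as.numeric(assembly_time(series, 0.95)), tau * log(20),
               tolerance = 0.01)
  # constant series is already converged
  const <- data.frame(time = 0:10, coverage = rep(0.4, 11))
  expect_equal(as.numeric(assembly_time(const)), 0)
  # exponential-fit variant recovers tau
  expect_equal(assembly_time(series, method = "exp_fit"), tau,
               tolerance = 1e-3)
  # still-rising series is flagged
  rising <- data.frame(time = 0:5, coverage = seq(0, 0.5, by = 0.1))
  expect_false(attr(assembly_time(rising), "reached"))
})

test_that("rate profile normalizes speed by radius and matches brute force", {
  # build a 2-snapshot trajectory with a uniform velocity field
  n <- 40
  set.seed(55)
  pos <- cbind(runif(n, -2e-3, 2e-3), runif(n, -2e-3, 2e-3), 1e-4)
  r <- rep(1e-4, n)
  v <- c(3e-4, 0, 0)
  snap <- function(t, pos) data.frame(
    time = t, id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
    r = r, vx = v[1], vy = v[2], vz = v[3], n_np = 0,
    fmx = 0, fmy = 0, fmz = 0, fgz = 0, fhx = 0, fhy = 0, fhz = 0)
  traj <- trajectory(rbind(snap(0, pos), snap(1, pos + rep(v, each = n))))
  rp <- rate_profile(traj, n_bins = 5)
  expect_equal(rp$rate[rp$count > 0],
               rep(sqrt(sum(v^2)) / 1e-4, sum(rp$count > 0)))
  # brute-force recomputation of bin means
  dist0 <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  rates <- rep(sqrt(sum(v^2)) / 1e-4, n)
  edges <- seq(0, max(dist0) * (1 + 1e-9), length.out = 6)
  bin <- findInterval(dist0, edges, rightmost.closed = TRUE)
  want <- tapply(rates, factor(bin, levels = 1:5), mean)
  expect_equal(rp$rate, as.numeric(want))
  # static trajectory: all rates zero
  traj0 <- trajectory(rbind(snap(0, pos), snap(1, pos)))
  rp0 <- rate_profile(traj0, n_bins = 5)
  expect_true(all(rp0$rate[rp0$count > 0] == 0))
})

test_that("body-force stress of a single spheroid matches hand arithmetic", {
  m <- magnet_spec(); np <- nanoparticle_spec(); p <- sim_params()
  r <- 1e-4
  pop <- make_pop(c(1.2e-3, 0, 3e-4), radii = r, np_counts = 5e9)
  sp <- stress_profiles(pop, m, np, p, n_bins = 1, component = "body")
  Fm <- magnetic_force(pop, m, np, p)[1, ]
  Fg <- gravity_buoyancy(pop, p)[1, ]
  expect_equal(sp$radial_stress, Fm[1] / (pi * r^2))
  expect_equal(sp$vertical_stress, (Fm[3] + Fg[3]) / (pi * r^2))
  expect_lt(sp$radial_stress, 0)   # compressive toward the axis
  expect_lt(sp$vertical_stress, 0) # and downward
  # no magnet, neutral buoyancy: identically zero
  p0 <- sim_params(rho_s = 1000, m_NPtot = 0)
  pop0 <- make_pop(c(1.2e-3, 0, 3e-4), radii = r, np_counts = 0)
  sp0 <- stress_profiles(pop0, m, np, p0, n_bins = 1, component = "body")
  expect_equal(sp0$radial_stress, 0)
  expect_equal(sp0$vertical_stress, 0)
})

test_that("transmitted stress of a floor-resting sphere matches the Hertz load", {
  p <- sim_params(rho_s = 1000)
  w <- well_geometry()
  r <- 1e-4; delta <- 2e-6
  pop <- make_pop(c(0, 1e-3, r - delta), radii = r)
  S <- particle_contact_stress(pop, p, w)
  estar <- 1 / (0.75 / p$E_spheroid + 0.75 / p$E_well)
  fz <- 4 / 3 * estar * sqrt(r * delta) * delta
  # branch (-r e_z) outer force (+fz e_z) over (4/3) pi r^3
  expect_equal(S[3, 3, 1], -r * fz / (4 / 3 * pi * r^3), tolerance = 1e-12)
  expect_equal(S[1, 1, 1], 0)
})

test_that("stress profiles are invariant under rotation about the magnet axis", {
  m <- magnet_spec(); np <- nanoparticle_spec(); p <- sim_params()
  w <- well_geometry()
  pop <- random_cluster(50, seed = 61, spread = 8e-4, z0 = 6e-5)
  pop$np_counts <- rep(4e9, 50)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- pop
  rot$positions <- pop$positions %*% t(Rz)
  for (comp in c("body", "transmitted")) {
    a <- stress_profiles(pop, m, np, p, n_bins = 6, r_max = 2e-3,
                         component = comp, well = w)
    b <- stress_profiles(rot, m, np, p, n_bins = 6, r_max = 2e-3,
                         component = comp, well = w)
    expect_equal(a$radial_stress, b$radial_stress, tolerance = 1e-8)
    expect_equal(a$vertical_stress, b$vertical_stress, tolerance = 1e-8)
    expect_equal(a$count, b$count)
  }
})

test_that("coverage is non-decreasing once a magnet-on run is underway", {
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  p <- sim_params(t_end = 2, seed = 71)
  res <- run_simulation(p, m, np, w, n = 100, kin_interval = 0.1)
  cov <- res$kinetics$coverage
  expect_true(all(diff(cov) > -1e-3))
})
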