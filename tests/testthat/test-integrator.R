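test_that("isolated spheroid reduces to pure Stokes mobility", {
  p <- sim_params(); m <- magnet_spec(); np <- nanoparticle_spec()
  w <- well_geometry()
  pop <- make_pop(c(0, 0, 2e-3), radii = 1e-4)
  fd <- force_decomposition(pop, m, np, p, w)
  sys <- assemble_system(pop, fd, params = p)
  expect_equal(as.matrix(sys$C), 6 * pi * p$eta_m * 1e-4 * diag(3))
  v <- solve_velocities(sys)
  expect_equal(v[1, ], sys$F / (6 * pi * p$eta_m * 1e-4))
})

test_that("assembled mobility matrix is symmetric positive definite", {
  p <- sim_params(); m <- magnet_spec(); np <- nanoparticle_spec()
  w <- well_geometry()
  for (seed in c(5, 6)) {
    pop <- random_cluster(80, seed, spread = 4e-4, z0 = 6e-5)
    fd <- force_decomposition(pop, m, np, p, w)
    sys <- assemble_system(pop, fd, params = p)
    Cd <- as.matrix(sys$C)
    expect_equal(max(abs(Cd - t(Cd))), 0)
    expect_true(all(eigen(Cd, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("off-diagonal pair blocks equal the negated damping block", {
  p <- sim_params(); m <- magnet_spec(); np <- nanoparticle_spec()
  w <- well_geometry(radius = 1, height = 1)
  pop <- make_pop(rbind(c(0, 0, 0.5), c(1.8e-4, 0, 0.5)), radii = 1e-4)
  fd <- force_decomposition(pop, m, np, p, w)
  sys <- assemble_system(pop, fd, params = p)
  B <- contact_damping_blocks(fd$contacts, p)[, , 1]
  Cd <- as.matrix(sys$C)
  expect_equal(Cd[1:3, 4:6], -B, tolerance = 1e-15)
  expect_equal(Cd[4:6, 1:3], -B, tolerance = 1e-15)
})

test_that("conjugate gradients matches a dense direct solve", {
  p <- sim_params(); m <- magnet_spec(); np <- nanoparticle_spec()
  w <- well_geometry()
  pop <- random_cluster(30, seed = 9, spread = 2.5e-4, z0 = 5e-5)
  pop$np_counts <- rep(1e9, 30)
  fd <- force_decomposition(pop, m, np, p, w)
  sys <- assemble_system(pop, fd, params = p)
  v_cg <- solve_velocities(sys, tol = 1e-12)
  v_dense <- matrix(solve(as.matrix(sys$C), sys$F), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(v_cg - v_dense)) / max(abs(v_dense)), 1e-8)
  # homogeneous system
  sys0 <- sys; sys0$F <- rep(0, length(sys$F))
  expect_true(all(solve_velocities(sys0) == 0))
})

test_that("a sedimenting spheroid moves at the Stokes terminal velocity", {
  p <- sim_params(m_NPtot = 0)
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  r <- 1e-4
  pop <- make_pop(c(0, 0, 2e-3), radii = r)
  st <- step_state(pop, p, m, np, w)
  v_terminal <- -2 * (p$rho_s - p$rho_m) * p$g * r^2 / (9 * p$eta_m)
  expect_equal(st$velocities[1, 3], v_terminal, tolerance = 1e-6)
  expect_equal(st$velocities[1, 1:2], c(0, 0))
  expect_equal(st$positions[1, 3], 2e-3 + p$dt * v_terminal,
               tolerance = 1e-12)
})

test_that("the explicit branch reproduces a manual force-solve-advance cycle", {
  p <- sim_params()  # lam = 0
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  pop <- random_cluster(20, seed = 12, spread = 2e-4, z0 = 6e-5)
  pop$np_counts <- rep(1e9, 20)
  fd <- force_decomposition(pop, m, np, p, w)
  v <- solve_velocities(assemble_system(pop, fd, params = p))
  st <- step_state(pop, p, m, np, w)
  expect_equal(st$positions, pop$positions + p$dt * v, tolerance = 1e-12)
})

test_that("the semi-implicit branch modifies the operator only when lam > 0", {
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  pop <- random_cluster(15, seed = 13, spread = 1.8e-4, z0 = 6e-5)
  st0 <- step_state(pop, sim_params(), m, np, w)
  st1 <- step_state(pop, sim_params(lam = 1), m, np, w)
  # overlapping cluster: stiffness blocks must change the solution
  expect_false(isTRUE(all.equal(st0$velocities, st1$velocities)))
  expect_true(all(is.finite(st1$velocities)))
  # the implicit operator damps the contact response, never amplifies it
  expect_lt(max(abs(st1$velocities)), 1.05 * max(abs(st0$velocities)))
})

test_that("production engine matches the R reference integrator", {
  p <- sim_params(t_end = 400 * 5e-5, I_out = 400 * 5e-5)
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  pop <- random_cluster(30, seed = 21, spread = 3e-4, z0 = 8e-5)
  pop$np_counts <- rep(1e9, 30)
  # disable the stability guard: the reference loop advances at fixed dt
  res <- run_simulation(p, m, np, w, pop = pop, kin_interval = 1,
                        substepping = FALSE)
  tab <- field_table(m, np, w, p)
  np_force <- function(x) field_table_np_force(tab, x)
  st <- pop
  for (k in seq_len(400)) st <- step_state(st, p, m, np, w,
                                           np_force = np_force)
  scale <- max(abs(st$positions - pop$positions))
  expect_lt(max(abs(res$final$positions - st$positions)) / scale, 1e-6)
})

test_that("without a magnet the population sediments onto the floor", {
  p <- sim_params(t_end = 1.5, I_out = 0.5, m_NPtot = 0)
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  set.seed(30)
  pop <- make_pop(cbind(runif(20, -2e-3, 2e-3), runif(20, -2e-3, 2e-3),
                        runif(20, 1.5e-4, 3.5e-4)),
                  radii = 1e-4)
  res <- run_simulation(p, m, np, w, pop = pop, kin_interval = 1)
  z <- res$final$positions[, 3]
  expect_true(all(z <= pop$radii + 5e-6))
  expect_true(all(z > 0))
})

test_that("halving the timestep changes final positions by under 1%", {
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  # 50-spheroid reference run carrying the per-spheroid nanoparticle load
  # of a full 1200-tissue well
  pop <- sample_population(50, 100e-6, 0.1, w, seed = 40)
  Ntot <- total_np_count(sim_params(), np)
  pop$np_counts <- rep(round(0.75 * Ntot / 1200), 50)
  p1 <- sim_params(t_end = 0.3, I_out = 0.3)
  p2 <- sim_params(t_end = 0.3, I_out = 0.3, dt = 2.5e-5)
  r1 <- run_simulation(p1, m, np, w, pop = pop, kin_interval = 1)
  r2 <- run_simulation(p2, m, np, w, pop = pop, kin_interval = 1)
  expect_lt(max(abs(r1$final$positions - r2$final$positions)) /
              mean(pop$radii), 0.01)
})

test_that("doubling the nanoparticle load accelerates assembly", {
  m <- magnet_spec(); np <- nanoparticle_spec(); w <- well_geometry()
  for (seed in c(101, 102)) {
    t30 <- local({
      p <- sim_params(t_end = 4, seed = seed, m_NPtot = 10e-9)
      assembly_time(run_simulation(p, m, np, w, n = 100,
                                   kin_interval = 0.05)$kinetics)
    })
    t60 <- local({
      p <- sim_params(t_end = 4, seed = seed, m_NPtot = 20e-9)
      assembly_time(run_simulation(p, m, np, w, n = 100,
                                   kin_interval = 0.05)$kinetics)
    })
    expect_lt(as.numeric(t60), as.numeric(t30))
  }
})
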