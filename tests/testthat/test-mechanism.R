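kB <- 1.380649e-23

test_that("channel gating follows the two-state Boltzmann form", {
  expect_equal(channel_open_probability(0), 0.5)
  expect_equal(channel_open_probability(kB * 298 * log(3), 298), 0.25,
               tolerance = 1e-12)
  expect_equal(channel_open_probability(1e-18), 0)     # +inf limit
  expect_equal(channel_open_probability(-1e-18), 1)    # -inf limit

  dG <- seq(-5, 5, by = 0.25) * kB * 298
  p <- channel_open_probability(dG, 298)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("the PB solver is exact for the homogeneous problem", {
  sys <- electrolyte_system(sigma = 0, rho_f = 0)
  sol <- solve_pb_radial(sys)
  expect_equal(max(abs(sol$psi)), 0)
})

test_that("small-charge PB solutions match the Debye-Huckel closed form", {
  sys <- electrolyte_system(sigma = 1e-6)  # e psi / kB T ~ 1e-4 at surface
  sol <- solve_pb_radial(sys, n_grid = 600)
  expect_lt(max(abs(sol$u)), 0.1)
  eps <- 8.8541878128e-12 * sys$eps_r
  kap <- sys$kappa
  dh <- sys$sigma * sys$a^2 / (eps * (1 + kap * sys$a)) *
    exp(-kap * (sol$r - sys$a)) / sol$r
  expect_lt(max(abs(sol$psi - dh)) / max(abs(dh)), 0.01)
})

test_that("the outer boundary is irrelevant once the layer is screened", {
  sys1 <- electrolyte_system(sigma = 1e-5)
  sys2 <- electrolyte_system(sigma = 1e-5,
                             R = sys1$a + 2 * (sys1$R - sys1$a))
  s1 <- solve_pb_radial(sys1, n_grid = 400)
  s2 <- solve_pb_radial(sys2, n_grid = 800)
  half <- s1$r <= sys1$a + (sys1$R - sys1$a) / 2
  psi2 <- approx(s2$r, s2$psi, xout = s1$r[half])$y
  expect_lt(max(abs(s1$psi[half] - psi2)) / max(abs(s1$psi)), 1e-3)
})

test_that("weak screening approaches the unscreened Coulomb profile", {
  # nearly unscreened electrolyte: kappa (R - a) << 1, so the analytic
  # limit on the finite domain is sigma a^2 / eps * (1/r - 1/R)
  sys <- electrolyte_system(a = 1e-6, R = 2e-6, sigma = 1e-6,
                            ions = data.frame(z = c(1, -1),
                                              c0 = c(1e-9, 1e-9)))
  expect_lt(sys$kappa * (sys$R - sys$a), 0.01)
  sol <- solve_pb_radial(sys, n_grid = 600)
  eps <- 8.8541878128e-12 * sys$eps_r
  coulomb <- sys$sigma * sys$a^2 / eps * (1 / sol$r - 1 / sys$R)
  expect_lt(max(abs(sol$psi - coulomb)) / max(abs(coulomb)), 0.01)
})

test_that("electrolyte systems must be bulk-electroneutral", {
  expect_error(
    electrolyte_system(ions = data.frame(z = c(1, -1), c0 = c(100, 80))),
    "electroneutral")
})

test_that("a leaky membrane relaxes exponentially to its reversal", {
  m <- membrane_model(Cm = 1, channels = data.frame(gbar = 0.3, E = -65),
                      I_ext = 0)
  tau <- m$Cm / sum(m$g)
  sim <- simulate_membrane(m, V0 = 0, duration = 10 * tau, dt = 0.001)
  closed <- -65 + (0 - -65) * exp(-sim$times / tau)
  expect_lt(max(abs(sim$V - closed)) / 65, 0.01)
})

test_that("multi-conductance steady state is the conductance-weighted mean", {
  ch <- data.frame(gbar = c(0.4, 0.1), E = c(-80, 20))
  m <- membrane_model(channels = ch, I_ext = 0)
  vstar <- sum(m$g * ch$E) / sum(m$g)
  expect_equal(membrane_steady_state(m), vstar)
  sim <- simulate_membrane(m, V0 = 0, duration = 200, dt = 0.01)
  expect_equal(sim$V[length(sim$V)], vstar, tolerance = 1e-6)

  # starting at the steady state, the trajectory stays there
  tau <- m$Cm / sum(m$g)
  hold <- simulate_membrane(m, V0 = vstar, duration = 10 * tau, dt = 0.01)
  expect_lt(max(abs(hold$V - vstar)), 1e-6)
})

test_that("a pure capacitor integrates current as a linear ramp", {
  m <- membrane_model(Cm = 2, channels = data.frame(gbar = 0, E = 0),
                      I_ext = 1.5)
  sim <- simulate_membrane(m, V0 = -10, duration = 100, dt = 0.1)
  expect_equal(sim$V, -10 + 1.5 / 2 * sim$times, tolerance = 1e-12)
})

test_that("the Hebbian rule is null at zero rate and bilinear in activities", {
  w0 <- matrix(c(0.1, -0.2, 0.3, 0), 2, 2)
  cs <- matrix(2, 2, 2)
  net0 <- plastic_network(w0, cs, x = c(1, 2), y = c(0.5, -1),
                          eta = function(cs) cs * 0)
  expect_identical(hebbian_step(net0, dt = 1)$weights, w0)

  # eta = 0.1, unit activities, 10 unit steps -> weight 1.0
  net <- plastic_network(matrix(0, 1, 1), matrix(1, 1, 1), 1, 1,
                         eta = function(cs) 0.1 * cs^0)
  for (i in 1:10) net <- hebbian_step(net, dt = 1)
  expect_equal(net$weights[1, 1], 1.0)

  netp <- plastic_network(w0, cs, x = c(1, 2), y = c(0.5, -1))
  netn <- plastic_network(w0, cs, x = -c(1, 2), y = c(0.5, -1))
  dp <- hebbian_step(netp, 0.5)$weights - w0
  dn <- hebbian_step(netn, 0.5)$weights - w0
  expect_equal(dn, -dp)
})

test_that("saturating eta makes weight growth monotone in CS concentration", {
  grow <- vapply(c(0.5, 1, 2, 5, 10), function(cs) {
    net <- plastic_network(matrix(0, 1, 1), matrix(cs, 1, 1), 1, 1)
    hebbian_step(net, dt = 1)$weights[1, 1]
  }, numeric(1))
  expect_true(all(diff(grow) > 0))
  # and bounded by eta0 * x * y * dt
  expect_true(all(grow < 0.1))
})
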