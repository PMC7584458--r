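test_that("initial condition is healthy-plus-seeds", {
  g <- cubic_lattice(30, 6, 3)
  p <- preset_params("primary_table1")

  s0 <- initial_condition(g, p, list())
  expect_true(all(s0$u == 0.75) && all(s0$v == 0.5))
  expect_true(all(s0$ut == 0) && all(s0$vt == 0) && all(s0$q == 0))

  s1 <- initial_condition(g, p, seed_spec("ut", 0.05,
                                          where = function(x, y, z) x <= 4))
  expect_identical(sum(s1$ut == 0.05), 5L * 6L * 3L)  # 90 seeded nodes
  expect_identical(sum(s1$ut == 0), 450L)

  s2 <- initial_condition(g, p, seed_spec("ut", 0,
                                          where = function(x, y, z) x <= 4))
  expect_identical(s2, s0)  # zero-amount seed is a no-op

  expect_error(initial_condition(g, p, seed_spec("ut", 0.05,
                                                 region = "amygdala")),
               "no nodes")

  # region seeding resolves by label substring, both hemispheres
  gc <- synthetic_connectome()
  s3 <- initial_condition(gc, p, seed_spec("vt", 0.01,
                                           region = "supramarginal"))
  expect_identical(sum(s3$vt > 0), 2L)
})

test_that("network RHS reduces to the homogeneous kinetics and damage law", {
  p <- preset_params("primary_table1")
  g <- cubic_lattice(4, 2, 2)
  n <- nrow(g$nodes)

  # homogeneous healthy state: all concentration derivatives vanish
  d0 <- network_rhs(g, p, damage_params(), initial_condition(g, p, list()))
  expect_lt(max(abs(c(d0$u, d0$ut, d0$v, d0$vt))), 1e-12)

  # any homogeneous state reproduces the homogeneous RHS at every node
  st <- structure(list(u = rep(0.3, n), ut = rep(0.2, n), v = rep(0.7, n),
                       vt = rep(0.1, n), q = rep(0, n)),
                  class = "state_vector")
  dn <- network_rhs(g, p, NULL, st)
  dh <- homogeneous_rhs(p, c(0.3, 0.2, 0.7, 0.1))
  for (k in 1:4) {
    expect_lt(max(abs(dn[[k]] - dh[k])), 1e-12)
  }

  # isolated node, hand-evaluated derivative
  g1 <- cubic_lattice(1, 1, 1)
  s <- structure(list(u = 0.75, ut = 0.05, v = 0.5, vt = 0, q = 0),
                 class = "state_vector")
  d1 <- network_rhs(g1, p, NULL, s)
  expect_equal(d1$u, -0.0375)          # -a2 u ut with production/clearance balanced
  expect_equal(d1$ut, (p$a2 * 0.75 - p$a1t) * 0.05)
  expect_equal(d1$vt, 0)

  # saturated damage stops evolving
  st$q <- rep(1, n)
  expect_equal(max(abs(network_rhs(g, p, damage_params(), st)$q)), 0)
})

test_that("uniform initial data reproduces the single-node trajectory", {
  p <- preset_params("primary_table1")
  times <- seq(0, 40, length.out = 21)
  init4 <- c(0.75, 0.05, 0.5, 0.02)
  ref <- homogeneous_simulate(p, init4, times, rtol = 1e-11, atol = 1e-13)
  for (rho in c(0.1, 1, 10)) {
    pl <- unclass(p)
    pl[c("rho_u", "rho_ut", "rho_v", "rho_vt")] <- rho
    pr <- do.call(kinetic_params, pl)
    g <- cubic_lattice(4, 3, 2)
    n <- nrow(g$nodes)
    st <- structure(list(u = rep(init4[1], n), ut = rep(init4[2], n),
                         v = rep(init4[3], n), vt = rep(init4[4], n),
                         q = rep(0, n)), class = "state_vector")
    tr <- simulate_network(g, pr, st, times, rtol = 1e-11, atol = 1e-13)
    for (f in c("u", "ut", "v", "vt")) {
      expect_lt(max(abs(tr[[f]] - ref[[f]][, 1])), 1e-8)
    }
  }
})

test_that("homogeneous perturbations relax to the stable stationary state", {
  # primary regime: epsilon off healthy converges to the fully toxic state
  p <- preset_params("fig22_primary")
  eq <- stationary_states(p)
  tr <- homogeneous_simulate(p, eq$states["s1", ] + c(0, 0.005, 0, 0.005),
                             times = c(0, seq(100, 400, by = 100)))
  term <- trajectory_state(tr)
  expect_equal(c(term$u, term$ut, term$v, term$vt),
               unname(eq$states["s4", ]), tolerance = 1e-6)

  # exactly at the healthy state: constant trajectory
  tr0 <- homogeneous_simulate(p, eq$states["s1", ], times = seq(0, 100, 25))
  expect_lt(max(abs(sweep(cbind(tr0$u, tr0$ut, tr0$v, tr0$vt), 2,
                          unname(eq$states["s1", ])))), 1e-9)

  # table-1 regime lands on (0.6, 0.25, v4, 0.45)
  p1 <- preset_params("primary_table1")
  eq1 <- stationary_states(p1)
  tr1 <- homogeneous_simulate(p1, eq1$states["s1", ] + 0.005,
                              times = c(0, 200, 400))
  t1 <- trajectory_state(tr1)
  expect_equal(c(t1$u, t1$ut, t1$v, t1$vt), unname(eq1$states["s4", ]),
               tolerance = 1e-6)
  expect_equal(t1$vt, 0.45, tolerance = 1e-6)
})

test_that("secondary tauopathy needs toxic amyloid to sustain toxic tau", {
  p <- preset_params("secondary_table1")
  g <- cubic_lattice(10, 2, 1)
  # tau-only seed decays back to the healthy state
  ic <- initial_condition(g, p, seed_spec("vt", 0.05,
                                          where = function(x, y, z) x <= 4))
  # toxic tau decays at rate b1t - b2 v1 = 0.025 here, so give it time
  tr <- simulate_network(g, p, ic, times = c(0, 300, 600, 900))
  term <- trajectory_state(tr)
  expect_lt(max(term$vt), 1e-8)
  expect_equal(term$v, rep(0.5, nrow(g$nodes)), tolerance = 1e-6)

  # adding an amyloid seed ignites the full tauopathy instead
  ic2 <- initial_condition(g, p, list(
    seed_spec("ut", 0.05, where = function(x, y, z) x <= 4),
    seed_spec("vt", 1e-11, nodes = seq_len(nrow(g$nodes)))))
  tr2 <- simulate_network(g, p, ic2, times = c(0, 150, 400, 800))
  expect_equal(max(trajectory_state(tr2)$vt), 7 / 12, tolerance = 1e-5)
})

test_that("damage is monotone, bounded, and saturates under persistent toxicity", {
  p <- preset_params("primary_table1")
  g <- cubic_lattice(6, 3, 1)
  dmg <- damage_params()  # k1..k4 baseline
  ic <- initial_condition(g, p, list(seed_spec("ut", 0.05, nodes = 1:3),
                                     seed_spec("vt", 0.05, nodes = 1:3)))
  tr <- simulate_network(g, p, ic, times = seq(0, 1500, length.out = 61),
                         damage = dmg)
  expect_true(all(diff(tr$q) >= -1e-9))
  expect_true(all(tr$q >= -1e-9 & tr$q <= 1 + 1e-9))
  expect_gt(min(trajectory_state(tr)$q), 0.99)  # q -> 1 everywhere

  # concentrations stay nonnegative throughout
  expect_gt(min(tr$u, tr$ut, tr$v, tr$vt), -1e-9)
})

test_that("first stored state is the initial condition and times increase", {
  p <- preset_params("primary_table1")
  g <- cubic_lattice(5, 1, 1)
  ic <- initial_condition(g, p, seed_spec("ut", 0.03, nodes = 1))
  tr <- simulate_network(g, p, ic, times = seq(0, 10, 2))
  expect_true(all(diff(tr$times) > 0))
  s0 <- trajectory_state(tr, 1)
  expect_equal(s0$ut, ic$ut)
  expect_equal(s0$u, ic$u)
  df <- as.data.frame(tr)
  expect_identical(nrow(df), length(tr$times) * nrow(g$nodes))
})
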