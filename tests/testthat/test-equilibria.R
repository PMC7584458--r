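test_that("stationary states match the published closed-form values", {
  p <- preset_params("primary_table1")
  eq <- stationary_states(p)
  expect_equal(unname(eq$states["s1", ]), c(0.75, 0, 0.5, 0))
  expect_equal(unname(eq$states["s2", ]), c(0.6, 0.25, 0.5, 0))
  expect_equal(unname(eq$states["s3", ]), c(0.75, 0, 0.4, 0.25))
  expect_equal(eq$states["s4", "vt"], 0.45)
  expect_true(all(eq$admissible))
  expect_equal(eq$mu, 0.75)

  s <- preset_params("secondary_table1")
  eqs <- stationary_states(s)
  expect_equal(unname(eqs$states["s4", ]),
               c(0.6, 0.25, 1.6 / (3 + 3), (5 * 3 - 1) / (4 * 3 + 12)),
               tolerance = 1e-12)
  expect_equal(eqs$states["s4", "vt"], 7 / 12)
  expect_false(eqs$admissible[["s3"]])
  expect_true(eqs$admissible[["s4"]])
})

test_that("coupling increments raise the fully toxic tau level as printed", {
  p3 <- kinetic_params(a0 = 0.75, a1 = 1, a2 = 1, a1t = 0.6,
                       b0 = 0.5, b1 = 1, b2 = 1, b1t = 0.4, b3 = 3)
  expect_equal(round(stationary_states(p3)$states["s4", "vt"], 3), 0.679)
  s5 <- kinetic_params(a0 = 0.75, a1 = 1, a2 = 1, a1t = 0.6,
                       b0 = 0.5, b1 = 1, b2 = 0.75, b1t = 0.4, b3 = 5)
  expect_equal(stationary_states(s5)$states["s4", "vt"], 0.75)
})

test_that("admissible states are fixed points of the kinetics to 1e-10", {
  for (name in c("primary_table1", "secondary_table1", "fig22_primary",
                 "fig23_secondary")) {
    p <- preset_params(name)
    eq <- stationary_states(p)
    for (s in rownames(eq$states)[eq$admissible]) {
      expect_lt(max(abs(homogeneous_rhs(p, eq$states[s, ]))), 1e-10)
    }
  }
  # and across random parameter draws
  set.seed(7)
  for (i in 1:200) {
    p <- rand_params()
    eq <- stationary_states(p)
    for (s in rownames(eq$states)[eq$admissible]) {
      expect_lt(max(abs(homogeneous_rhs(p, eq$states[s, ]))), 1e-10)
    }
  }
})

test_that("uncoupled unit-rate model sits on the transcritical boundary", {
  p <- kinetic_params(b3 = 0)  # all rates 1
  eq <- stationary_states(p)
  expect_equal(unname(eq$states["s1", ]), c(1, 0, 1, 0))
  # at the boundary the toxic states collapse onto the healthy state
  expect_equal(unname(eq$states["s2", ]), unname(eq$states["s1", ]))
  expect_equal(unname(eq$states["s3", ]), unname(eq$states["s1", ]))
  expect_false(eq$admissible[["s4"]])   # needs b3 > 0 and u1 > u2
  reg <- classify_regime(p)
  expect_setequal(reg$boundary, c("abeta", "tau"))
})

test_that("regime classification follows the balance-of-clearance inequalities", {
  expect_identical(classify_regime(preset_params("primary_table1"))$label,
                   "primary_tauopathy")
  expect_identical(classify_regime(preset_params("secondary_table1"))$label,
                   "secondary_tauopathy")
  expect_identical(classify_regime(preset_params("fig23_secondary"))$label,
                   "secondary_tauopathy")
  healthy <- kinetic_params(a0 = 0.5, a1 = 1, a2 = 1, a1t = 0.9,
                            b0 = 0.5, b1 = 1, b2 = 1, b1t = 0.9)
  expect_identical(classify_regime(healthy)$label, "healthy_stable")
  # amyloid inequality reversed, tau holds, but b3 too small to rescue state 4
  am <- kinetic_params(a0 = 0.75, a1 = 1, a2 = 1, a1t = 0.6,
                       b0 = 0.5, b1 = 1, b2 = 0.75, b1t = 0.4, b3 = 1e-8)
  expect_identical(classify_regime(am)$label, "amyloid_only")
  tau_only <- kinetic_params(a0 = 0.5, a1 = 1, a2 = 1, a1t = 0.9,
                             b0 = 0.5, b1 = 1, b2 = 1, b1t = 0.25)
  expect_identical(classify_regime(tau_only)$label, "tau_only_inadmissible_4")
})

test_that("jacobian matches central finite differences of the kinetics", {
  fd_jacobian <- function(p, state, h = 1e-6) {
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      e <- rep(0, 4); e[j] <- h
      J[, j] <- (homogeneous_rhs(p, state + e) - homogeneous_rhs(p, state - e)) / (2 * h)
    }
    J
  }
  set.seed(11)
  for (i in 1:25) {
    p <- rand_params()
    state <- stats::runif(4, 0, 2)
    expect_lt(max(abs(jacobian_matrix(p, state) - fd_jacobian(p, state))), 1e-6)
  }
  # analytic spot values
  p <- preset_params("primary_table1")
  healthy <- stationary_states(p)$states["s1", ]
  expect_equal(jacobian_matrix(p, healthy)["ut", "ut"], 0.15)  # a2 u1 - a1t
  expect_equal(unname(diag(jacobian_matrix(p, c(0, 0, 0, 0)))),
               c(-p$a1, -p$a1t, -p$b1, -p$b1t))
  # b3 = 0 decouples the families: tau rows lose their ut column entries
  p0 <- kinetic_params(b3 = 0)
  J0 <- jacobian_matrix(p0, c(0.3, 0.4, 0.5, 0.6))
  expect_identical(unname(J0[c("v", "vt"), "ut"]), c(0, 0))
})

test_that("closed-form eigenvalues agree with the numeric eigensolver", {
  p <- preset_params("primary_table1")
  healthy <- stationary_states(p)$states["s1", ]
  rep1 <- eigen_report(p, healthy)
  abeta_pair <- sort(Re(rep1$eigen_closed))[c(1, 4)]  # -1 and +0.15
  expect_equal(abeta_pair, c(-1, 0.15))
  expect_equal(rep1$B, 0.85)
  expect_equal(rep1$C, -0.15)
  # under primary parameters the healthy state has exactly two unstable modes
  expect_identical(sum(Re(rep1$eigen_closed) > 0), 2L)
  expect_false(rep1$stable)

  healthy_p <- kinetic_params(a0 = 0.5, a1 = 1, a2 = 1, a1t = 0.9,
                              b0 = 0.5, b1 = 1, b2 = 1, b1t = 0.9)
  eqh <- stationary_states(healthy_p)
  expect_true(eigen_report(healthy_p, eqh$states["s1", ])$stable)

  # property: closed vs numeric multisets across random draws and states
  set.seed(23)
  for (i in 1:1000) {
    p <- rand_params()
    state <- stats::runif(4, 0, 2)
    r <- eigen_report(p, state)
    expect_lt(max(Mod(r$eigen_closed - r$eigen_numeric)), 1e-8)
  }
})

test_that("tau pair reduces to the amyloid closed forms when decoupled", {
  set.seed(31)
  for (i in 1:20) {
    p <- rand_params()
    pl <- unclass(p)
    pl$b3 <- 0
    # mirrored parameters: tau family takes the amyloid rates
    mirror <- pl
    mirror[c("b0", "b1", "b2", "b1t")] <- pl[c("a0", "a1", "a2", "a1t")]
    pm <- do.call(kinetic_params, mirror)
    st <- stats::runif(4)
    st_m <- st[c(1, 2, 1, 2)]  # tau state mirrors the amyloid state
    r <- eigen_report(pm, st_m)
    expect_equal(sort(Re(r$eigen_closed))[c(1, 3)],
                 sort(Re(r$eigen_closed))[c(2, 4)], tolerance = 1e-10)
  }
})

test_that("tau gap is the direct state difference and vanishes with coupling", {
  p <- preset_params("primary_table1")
  expect_equal(tau_gap(p), 0.45 - 0.25, tolerance = 1e-12)
  eq <- stationary_states(p)
  expect_equal(tau_gap(p), eq$states["s4", "vt"] - eq$states["s3", "vt"],
               tolerance = 1e-12)

  expect_gt(tau_gap(preset_params("fig22_primary")), 0)

  # gap shrinks to zero with the coupling
  base <- unclass(p)
  gaps <- vapply(c(1e-2, 1e-4, 1e-6), function(b3) {
    base$b3 <- b3
    tau_gap(do.call(kinetic_params, base))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-6)

  expect_error(tau_gap(preset_params("secondary_table1")), "primary")
})

test_that("state 4 approaches the analytic limit as the amyloid excess closes", {
  # push a1t -> a2 a0/a1 so u2 -> u1; vt4 must approach b1 (v1 - v3) / b1t
  p <- preset_params("primary_table1")
  base <- unclass(p)
  lim <- p$b1 * (p$b0 / p$b1 - p$b1t / p$b2) / p$b1t
  base$a1t <- p$a2 * p$a0 / p$a1 - 1e-6
  eq <- stationary_states(do.call(kinetic_params, base))
  expect_equal(eq$states["s4", "vt"], lim, tolerance = 1e-4)

  # in the secondary regime the same limit is negative: sustained toxic tau
  # requires toxic amyloid
  s <- preset_params("secondary_table1")
  slim <- s$b1 * (s$b0 / s$b1 - s$b1t / s$b2) / s$b1t
  expect_lt(slim, 0)
  sbase <- unclass(s)
  sbase$a1t <- s$a2 * s$a0 / s$a1 - 1e-6
  seq4 <- stationary_states(do.call(kinetic_params, sbase))
  expect_equal(seq4$states["s4", "vt"], slim, tolerance = 1e-4)
  expect_false(seq4$admissible[["s4"]])
})

test_that("exact clearance-balance equality collapses toxic onto healthy states", {
  # amyloid family on the boundary: a1t/a2 == a0/a1 exactly
  p <- kinetic_params(a0 = 0.5, a1 = 1, a2 = 1.2, a1t = 0.6,
                      b0 = 0.5, b1 = 1, b2 = 1, b1t = 0.9)
  eq <- stationary_states(p)
  expect_lt(max(abs(eq$states["s2", ] - eq$states["s1", ])), 1e-12)
  expect_identical(classify_regime(p)$boundary, "abeta")
})
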