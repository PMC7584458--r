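#' Right-hand side of the homogeneous (well-mixed) kinetics
#'
#' Evaluates the spatially homogeneous reaction system for a state
#' `(u, ut, v, vt)` of healthy/toxic A-beta and healthy/toxic tau:
#' \deqn{\dot u = a_0 - a_1 u - a_2 u \tilde u}
#' \deqn{\dot{\tilde u} = -\tilde a_1 \tilde u + a_2 u \tilde u}
#' \deqn{\dot v = b_0 - b_1 v - b_2 v \tilde v - b_3 \tilde u v \tilde v}
#' \deqn{\dot{\tilde v} = -\tilde b_1 \tilde v + b_2 v \tilde v + b_3 \tilde u v \tilde v}
#'
#' This is the reaction part shared by the network and continuum models;
#' transport enters only through the graph Laplacian.
#'
#' @param p A [kinetic_params()] object.
#' @param state Numeric length-4 vector `(u, ut, v, vt)`.
#' @return Numeric length-4 derivative vector.
#' @export
homogeneous_rhs <- function(p, state) {
  u <- state[[1]]; ut <- state[[2]]; v <- state[[3]]; vt <- state[[4]]
  c(p$a0 - p$a1 * u - p$a2 * u * ut,
    -p$a1t * ut + p$a2 * u * ut,
    p$b0 - p$b1 * v - p$b2 * v * vt - p$b3 * ut * v * vt,
    -p$b1t * vt + p$b2 * v * vt + p$b3 * ut * v * vt)
}

#' Closed-form stationary states of the homogeneous system
#'
#' Computes the up-to-four stationary 4-tuples of the homogeneous kinetics:
#'
#' 1. healthy/healthy: `(a0/a1, 0, b0/b1, 0)` - always present;
#' 2. toxic A-beta / healthy tau: `u2 = a1t/a2`, `ut2 = a1(u1-u2)/a1t`;
#' 3. healthy A-beta / toxic tau: `v3 = b1t/b2`, `vt3 = b1(v1-v3)/b1t`;
#' 4. fully toxic: `(u2, ut2, v4, vt4)` with
#'    `v4 = a2 b2 u2 v3 / (a1 b3 (u1-u2) + a2 b2 u2)` and
#'    `vt4 = b1 a1t (v3-v4)(v1-v4) / (a1 b3 (u1-u2) v3 v4)`.
#'
#' A state is admissible when all components are real and non-negative;
#' state 2 requires `u1 >= u2`, state 3 requires `v1 >= v3`, and state 4
#' requires `u1 > u2` together with `(v3-v4)` and `(v1-v4)` of equal sign.
#' When `u1 = u2` exactly (so state 4 collapses onto an indeterminate 0/0
#' quotient), `vt4` is reported through its analytic limit
#' `b1 (v1 - v3) / b1t` and flagged degenerate.
#'
#' @param p A [kinetic_params()] object; must validate.
#' @return An object of class `equilibrium_set`: a list with `states` (4x4
#'   matrix, one stationary 4-tuple per row), `admissible` (logical 4),
#'   `mu` (the composite coupling scale `a0 b3 / b2`), `degenerate_state4`,
#'   and `regime` (see [classify_regime()]).
#' @export
#' @examples
#' eq <- stationary_states(preset_params("primary_table1"))
#' eq$states["s4", "vt"]  # 0.45
stationary_states <- function(p) {
  viol <- validate_params(p)
  if (length(viol) > 0L) stop("invalid parameters: ", paste(viol, collapse = "; "))
  u1 <- p$a0 / p$a1
  v1 <- p$b0 / p$b1
  u2 <- p$a1t / p$a2
  ut2 <- p$a1 * (u1 - u2) / p$a1t
  v3 <- p$b1t / p$b2
  vt3 <- p$b1 * (v1 - v3) / p$b1t

  s <- p$a1 * p$b3 * (u1 - u2)  # coupling pressure a1 b3 (u1 - u2)
  degenerate <- FALSE
  if (s + p$b2 * p$a1t == 0) {  # unreachable for valid params (b2 a1t > 0)
    v4 <- NA_real_; vt4 <- NA_real_
  } else {
    v4 <- p$b2 * p$a1t * v3 / (s + p$b2 * p$a1t)
    if (u1 == u2 || p$b3 == 0) {
      # 0/0 quotient: use the analytic limit u1 -> u2
      vt4 <- p$b1 * (v1 - v3) / p$b1t
      degenerate <- TRUE
    } else {
      vt4 <- p$b1 * p$a1t * (v3 - v4) * (v1 - v4) / (s * v3 * v4)
    }
  }

  states <- rbind(
    s1 = c(u1, 0, v1, 0),
    s2 = c(u2, ut2, v1, 0),
    s3 = c(u1, 0, v3, vt3),
    s4 = c(u2, ut2, v4, vt4))
  colnames(states) <- c("u", "ut", "v", "vt")

  admissible <- c(
    s1 = TRUE,
    s2 = u1 >= u2,
    s3 = v1 >= v3,
    s4 = is.finite(vt4) && p$b3 > 0 && u1 > u2 && vt4 >= 0 && v4 >= 0 &&
      ((v3 - v4) * (v1 - v4) >= 0))

  out <- structure(
    list(states = states, admissible = admissible,
         mu = p$a0 * p$b3 / p$b2,
         degenerate_state4 = degenerate,
         regime = classify_regime(p),
         params = p),
    class = "equilibrium_set")
  out
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("Stationary states (u, ut, v, vt):\n")
  m <- cbind(as.data.frame(round(x$states, 6)), admissible = x$admissible)
  print(m)
  cat(sprintf("regime: %s   mu = a0 b3 / b2 = %g\n", x$regime$label, x$mu))
  invisible(x)
}

#' Classify the kinetic regime from the balance-of-clearance inequalities
#'
#' The healthy state is stable if and only if both balance-of-clearance
#' inequalities hold: `a1t/a2 > a0/a1` and `b1t/b2 > b0/b1`. Their violation
#' pattern, together with the admissibility of the fully toxic state,
#' determines the disease phenomenology:
#'
#' * `healthy_stable`: both inequalities hold strictly;
#' * `primary_tauopathy`: both reversed - a self-sustaining toxic-tau state
#'   exists independently of A-beta;
#' * `secondary_tauopathy`: the A-beta inequality is reversed, the tau
#'   inequality holds (so the A-beta-free toxic-tau state is inadmissible)
#'   and the coupling `b3` is strong enough that the fully toxic state is
#'   admissible - toxic tau is slaved to toxic A-beta;
#' * `amyloid_only`: as above but the fully toxic state is inadmissible;
#' * `tau_only_inadmissible_4`: the remaining combination (A-beta inequality
#'   holds, tau reversed).
#'
#' Equalities within relative tolerance `tol` are reported through the
#' `boundary` field rather than silently assigned to a side; an exact
#' equality is the transcritical (moment-of-susceptibility) configuration.
#'
#' @param p A [kinetic_params()] object.
#' @param tol Relative tolerance for calling a clearance ratio equal to its
#'   production ratio.
#' @return An object of class `regime_label`: list with `label`, the two
#'   ratio pairs (`abeta_ratio` = a1t/a2 vs `abeta_threshold` = a0/a1 and
#'   the tau analogues), and `boundary` (character vector, possibly empty,
#'   naming families on the transcritical boundary).
#' @export
classify_regime <- function(p, tol = 1e-12) {
  viol <- validate_params(p)
  if (length(viol) > 0L) stop("invalid parameters: ", paste(viol, collapse = "; "))
  ra <- p$a1t / p$a2; ta <- p$a0 / p$a1
  rb <- p$b1t / p$b2; tb <- p$b0 / p$b1
  near <- function(x, y) abs(x - y) <= tol * max(abs(x), abs(y), 1)
  boundary <- character(0)
  if (near(ra, ta)) boundary <- c(boundary, "abeta")
  if (near(rb, tb)) boundary <- c(boundary, "tau")
  a_holds <- ra > ta
  b_holds <- rb > tb
  label <- if (a_holds && b_holds) {
    "healthy_stable"
  } else if (!a_holds && !b_holds) {
    "primary_tauopathy"
  } else if (!a_holds && b_holds) {
    # state-4 admissibility decides secondary vs amyloid-only; evaluate the
    # closed forms directly to avoid recursion through stationary_states()
    u1 <- p$a0 / p$a1; u2 <- p$a1t / p$a2
    v1 <- p$b0 / p$b1; v3 <- p$b1t / p$b2
    s <- p$a1 * p$b3 * (u1 - u2)
    v4 <- p$b2 * p$a1t * v3 / (s + p$b2 * p$a1t)
    vt4 <- if (u1 > u2 && p$b3 > 0) {
      p$b1 * p$a1t * (v3 - v4) * (v1 - v4) / (s * v3 * v4)
    } else {
      -Inf
    }
    if (is.finite(vt4) && vt4 >= 0 && (v3 - v4) * (v1 - v4) >= 0) {
      "secondary_tauopathy"
    } else {
      "amyloid_only"
    }
  } else {
    "tau_only_inadmissible_4"
  }
  structure(list(label = label,
                 abeta_ratio = ra, abeta_threshold = ta,
                 tau_ratio = rb, tau_threshold = tb,
                 boundary = boundary),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime: %s\n", x$label))
  cat(sprintf("  A-beta clearance balance: a1t/a2 = %g vs a0/a1 = %g\n",
              x$abeta_ratio, x$abeta_threshold))
  cat(sprintf("  tau    clearance balance: b1t/b2 = %g vs b0/b1 = %g\n",
              x$tau_ratio, x$tau_threshold))
  if (length(x$boundary) > 0L) {
    cat("  on transcritical boundary:", paste(x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Jacobian of the homogeneous kinetics at a state
#'
#' The linearization of the homogeneous system about `(u, ut, v, vt)`. The
#' A-beta block is upper-left and independent of tau (the coupling is
#' one-way), so the matrix is block lower-triangular.
#'
#' @param p A [kinetic_params()] object.
#' @param state Numeric length-4 state `(u, ut, v, vt)`.
#' @return A 4x4 numeric matrix.
#' @export
jacobian_matrix <- function(p, state) {
  u <- state[[1]]; ut <- state[[2]]; v <- state[[3]]; vt <- state[[4]]
  matrix(c(
    -(p$a2 * ut + p$a1),      -p$a2 * u,              0,                          0,
    p$a2 * ut,                 p$a2 * u - p$a1t,      0,                          0,
    0,  -p$b3 * v * vt,  -(p$b2 * vt + p$b1 + p$b3 * ut * vt),  -p$b2 * v - p$b3 * ut * v,
    0,   p$b3 * v * vt,    p$b2 * vt + p$b3 * ut * vt,           p$b2 * v - p$b1t + p$b3 * ut * v
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("u", "ut", "v", "vt"), c("u", "ut", "v", "vt")))
}

#' Closed-form and numeric eigenvalues of the linearized kinetics
#'
#' The one-way coupling makes the Jacobian block triangular, so the four
#' eigenvalues split into an A-beta pair and a tau pair, each the roots of a
#' quadratic: `lambda = -(B +/- sqrt(B^2 - 4C))/2` with
#' `B = a1 + a1t + a2 (ut - u)` and `C = a2 (a1t ut - a1 u) + a1 a1t` for
#' the A-beta pair, and the hatted analogues
#' `Bhat = b1 + b1t + b2 (vt - v) + b3 ut (vt - v)` and
#' `Chat = b2 (b1t vt - b1 v) + b1 b1t + b3 ut (b1t vt - b1 v)` for tau
#' (which reduce to the A-beta forms under `b3 = 0` or vanishing toxic
#' A-beta). Complex pairs (negative discriminant) are returned as complex
#' conjugates; stability is judged on real parts.
#'
#' @param p A [kinetic_params()] object.
#' @param state Numeric length-4 state, typically a row of
#'   [stationary_states()].
#' @return An object of class `stability_report`: list with `state`,
#'   `jacobian`, `eigen_closed` and `eigen_numeric` (complex 4-vectors,
#'   sorted by real then imaginary part), helper scalars `B`, `C`, `Bhat`,
#'   `Chat`, and `stable` (all real parts negative, closed forms).
#' @export
#' @examples
#' p <- preset_params("primary_table1")
#' eq <- stationary_states(p)
#' eigen_report(p, eq$states["s1", ])$eigen_closed  # contains +0.15: unstable
eigen_report <- function(p, state) {
  u <- state[[1]]; ut <- state[[2]]; v <- state[[3]]; vt <- state[[4]]
  quad_roots <- function(B, C) {
    disc <- as.complex(B^2 - 4 * C)
    c(-(B + sqrt(disc)) / 2, -(B - sqrt(disc)) / 2)
  }
  B <- p$a1 + p$a1t + p$a2 * (ut - u)
  C <- p$a2 * (p$a1t * ut - p$a1 * u) + p$a1t * p$a1
  Bhat <- (p$b1 + p$b1t + p$b2 * (vt - v)) + p$b3 * ut * (vt - v)
  Chat <- (p$b2 * (p$b1t * vt - p$b1 * v) + p$b1t * p$b1) +
    p$b3 * ut * (p$b1t * vt - p$b1 * v)
  closed <- c(quad_roots(B, C), quad_roots(Bhat, Chat))
  J <- jacobian_matrix(p, state)
  numeric_ev <- eigen(J, only.values = TRUE)$values
  sort_c <- function(z) z[order(Re(z), Im(z))]
  structure(
    list(state = state, jacobian = J,
         eigen_closed = sort_c(as.complex(closed)),
         eigen_numeric = sort_c(as.complex(numeric_ev)),
         B = B, C = C, Bhat = Bhat, Chat = Chat,
         stable = all(Re(closed) < 0)),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Eigenvalues of the linearized kinetics (closed form):\n")
  print(signif(x$eigen_closed, 6))
  cat(sprintf("stable: %s\n", x$stable))
  invisible(x)
}

#' Toxic-tau elevation due to toxic A-beta in primary tauopathy
#'
#' In the primary-tauopathy regime both the A-beta-free toxic-tau state
#' (component `vt3`) and the fully toxic state (component `vt4`) are
#' admissible, and the presence of toxic A-beta always raises the
#' asymptotic toxic-tau level. The gap has the closed form
#' \deqn{\tilde v_4 - \tilde v_3 =
#'   \frac{a_1 b_1 b_3 (u_1 - u_2)}{b_2 (a_1 b_3 (u_1 - u_2) + b_2 \tilde a_1)} > 0,}
#' proportional to the coupling `b3` and to the toxic A-beta excess
#' `u1 - u2`.
#'
#' @param p A [kinetic_params()] object in the primary-tauopathy regime.
#' @return The scalar gap `vt4 - vt3` (strictly positive).
#' @export
#' @examples
#' tau_gap(preset_params("primary_table1"))  # 0.45 - 0.25 = 0.20
tau_gap <- function(p) {
  regime <- classify_regime(p)
  if (regime$label != "primary_tauopathy") {
    stop("tau_gap requires the primary tauopathy regime (vt3 admissible); ",
         "current regime: ", regime$label)
  }
  u1 <- p$a0 / p$a1
  u2 <- p$a1t / p$a2
  s <- p$a1 * p$b3 * (u1 - u2)
  p$b1 * s / (p$b2 * (s + p$b2 * p$a1t))
}
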