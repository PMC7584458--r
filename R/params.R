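#' Kinetic parameter set for the coupled heterodimer model
#'
#' Bundles the nine reaction-rate constants and four per-species effective
#' diffusivities that define one regional kinetic regime of the coupled
#' amyloid-beta (A-beta) / tau heterodimer model. Each protein family has a
#' healthy and a toxic population; healthy protein is produced at a constant
#' rate, cleared at a first-order rate, and converted to the toxic form by
#' the toxic form itself. The two families are coupled through a single
#' term, `b3`, by which toxic A-beta catalyses the conversion of healthy tau
#' to toxic tau (toxic A-beta acts enzymatically and is not consumed).
#'
#' @param a0 Healthy A-beta production rate (1/time).
#' @param a1 Healthy A-beta clearance rate (1/time).
#' @param a2 A-beta healthy-to-toxic conversion rate (1/(conc time)).
#' @param a1t Toxic A-beta clearance rate (1/time).
#' @param b0 Healthy tau production rate (1/time).
#' @param b1 Healthy tau clearance rate (1/time).
#' @param b2 Tau healthy-to-toxic conversion rate (1/(conc time)).
#' @param b1t Toxic tau clearance rate (1/time).
#' @param b3 A-beta to tau coupling rate (1/(conc^2 time)); may be zero,
#'   which decouples the two families.
#' @param rho_u,rho_ut,rho_v,rho_vt Per-species effective diffusivities:
#'   dimensionless scale factors of the graph Laplacian (length^2/time in
#'   the continuum limit) for healthy A-beta, toxic A-beta, healthy tau and
#'   toxic tau respectively. Non-negative.
#'
#' @return An object of class `kinetic_params`: a named list of the 13
#'   numeric fields above.
#' @seealso [validate_params()], [preset_params()], [stationary_states()]
#' @export
#' @examples
#' p <- kinetic_params(a0 = 0.75, a1t = 0.6, b0 = 0.5, b1t = 0.4)
#' validate_params(p)
kinetic_params <- function(a0 = 1, a1 = 1, a2 = 1, a1t = 1,
                           b0 = 1, b1 = 1, b2 = 1, b1t = 1, b3 = 1,
                           rho_u = 1, rho_ut = 1, rho_v = 1, rho_vt = 1) {
  p <- list(a0 = a0, a1 = a1, a2 = a2, a1t = a1t,
            b0 = b0, b1 = b1, b2 = b2, b1t = b1t, b3 = b3,
            rho_u = rho_u, rho_ut = rho_ut, rho_v = rho_v, rho_vt = rho_vt)
  p <- lapply(p, as.numeric)
  class(p) <- "kinetic_params"
  viol <- validate_params(p)
  if (length(viol) > 0L) {
    stop("invalid kinetic parameters:\n  ", paste(viol, collapse = "\n  "))
  }
  p
}

.rate_fields <- c("a0", "a1", "a2", "a1t", "b0", "b1", "b2", "b1t")
.diff_fields <- c("rho_u", "rho_ut", "rho_v", "rho_vt")
.kp_fields <- c(.rate_fields, "b3", .diff_fields)

#' Validate a kinetic parameter set
#'
#' Checks the sign invariants of the model: every rate constant must be
#' strictly positive except the coupling `b3` (which may vanish, giving the
#' uncoupled two-family model) and the diffusivities, which must be
#' non-negative.
#'
#' @param p A [kinetic_params()] object or a named list with the same fields.
#' @return A character vector of violations, empty when the parameter set is
#'   valid. Each entry names the offending field and the rule it breaks.
#' @export
validate_params <- function(p) {
  viol <- character(0)
  for (f in .kp_fields) {
    x <- p[[f]]
    if (is.null(x) || length(x) != 1L || !is.finite(x)) {
      viol <- c(viol, sprintf("%s: must be a single finite number", f))
    }
  }
  if (length(viol) > 0L) return(viol)
  for (f in .rate_fields) {
    if (p[[f]] <= 0) viol <- c(viol, sprintf("%s: rate must be strictly positive", f))
  }
  if (p$b3 < 0) viol <- c(viol, "b3: coupling rate must be non-negative")
  for (f in .diff_fields) {
    if (p[[f]] < 0) viol <- c(viol, sprintf("%s: diffusivity must be non-negative", f))
  }
  viol
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (coupled heterodimer model)\n")
  cat(sprintf("  A-beta: a0=%g a1=%g a2=%g a1t=%g\n", x$a0, x$a1, x$a2, x$a1t))
  cat(sprintf("  tau:    b0=%g b1=%g b2=%g b1t=%g  coupling b3=%g\n",
              x$b0, x$b1, x$b2, x$b1t, x$b3))
  cat(sprintf("  diffusivities: rho_u=%g rho_ut=%g rho_v=%g rho_vt=%g\n",
              x$rho_u, x$rho_ut, x$rho_v, x$rho_vt))
  invisible(x)
}

#' Damage parameter set
#'
#' Rate constants of the first-order neuronal damage equation
#' `dq/dt = (k1*ut + k2*vt + k3*ut*vt + k4*A(q)) * (1 - q)`, where `q` in
#' \[0, 1\] is a coarse-grained per-node measure of neuronal dysfunction and
#' `A(q)` is the damage-adjacency-weighted neighbour sum carrying non-local
#' (transneuronal, deafferentation-type) degeneration.
#'
#' The default values are the baseline used for the illustrative damage
#' simulations: `k1 = 1e-4`, `k2 = 1e-2`, `k3 = 1e-1`, `k4 = 1e-3`; toxic
#' tau is taken as far more damaging than toxic A-beta, and joint toxicity
#' more damaging still.
#'
#' @param k1 Toxic A-beta damage rate (>= 0).
#' @param k2 Toxic tau damage rate (>= 0).
#' @param k3 Combined-toxicity damage rate (>= 0).
#' @param k4 Transneuronal (non-local) damage transmission rate (>= 0).
#' @return An object of class `damage_params`.
#' @export
damage_params <- function(k1 = 1e-4, k2 = 1e-2, k3 = 1e-1, k4 = 1e-3) {
  ks <- list(k1 = as.numeric(k1), k2 = as.numeric(k2),
             k3 = as.numeric(k3), k4 = as.numeric(k4))
  for (f in names(ks)) {
    if (length(ks[[f]]) != 1L || !is.finite(ks[[f]]) || ks[[f]] < 0) {
      stop(sprintf("%s: damage rate must be a single non-negative number", f))
    }
  }
  structure(ks, class = "damage_params")
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf("Damage parameters: k1=%g k2=%g k3=%g k4=%g\n",
              x$k1, x$k2, x$k3, x$k4))
  invisible(x)
}

#' Named kinetic parameter presets
#'
#' Literal transcriptions of the published parameter regimes:
#'
#' * `"primary_table1"`: the primary-tauopathy baseline (a0=0.75, a1=1,
#'   a2=1, a1t=0.6, b0=0.5, b1=1, b2=1, b1t=0.4, b3=1; all diffusivities 1).
#'   Both balance-of-clearance inequalities are violated, so a
#'   self-sustaining toxic-tau state exists independently of A-beta.
#' * `"secondary_table1"`: the same with b2=0.75 and b3=3 - the
#'   secondary-tauopathy baseline, in which toxic tau persists only in the
#'   presence of toxic A-beta.
#' * `"fig22_primary"`: unit rates with a1t=b1t=3/4, b3=1/2 and toxic
#'   diffusivities 0.01 (the 1D primary-tauopathy front experiment).
#' * `"fig23_secondary"`: unit rates with a1t=3/4, b1t=4/3, b3=3 and toxic
#'   diffusivities 0.01 (the 1D secondary-tauopathy front experiment).
#' * `"adni_mixed_table3"`: the mixed-modality synthetic regime used for the
#'   patient-data comparison, together with its regional overrides (per-region
#'   b3 changes in secondary-tauopathy regions and (b2, b3) changes placing
#'   five regions in primary tauopathy). Returned as a list with elements
#'   `base` (kinetic_params) and `map` (a [regional_map()]).
#'
#' The 1D front-experiment presets do not print diffusivities; the toxic
#' diffusivity 0.01 is the value under which the linearized speed formulas
#' reproduce every caption speed, and the healthy diffusivity is set equal
#' (it does not enter the speed formulas).
#'
#' @param name One of `"primary_table1"`, `"secondary_table1"`,
#'   `"fig22_primary"`, `"fig23_secondary"`, `"adni_mixed_table3"`.
#' @return A [kinetic_params()] object, or for `"adni_mixed_table3"` a list
#'   with elements `base` and `map`.
#' @export
#' @examples
#' preset_params("primary_table1")
preset_params <- function(name) {
  presets <- c("primary_table1", "secondary_table1", "fig22_primary",
               "fig23_secondary", "adni_mixed_table3")
  if (length(name) != 1L || !name %in% presets) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(presets, collapse = ", "))
  }
  switch(name,
    primary_table1 = kinetic_params(
      a0 = 0.75, a1 = 1, a2 = 1, a1t = 0.6,
      b0 = 0.5, b1 = 1, b2 = 1, b1t = 0.4, b3 = 1),
    secondary_table1 = kinetic_params(
      a0 = 0.75, a1 = 1, a2 = 1, a1t = 0.6,
      b0 = 0.5, b1 = 1, b2 = 0.75, b1t = 0.4, b3 = 3),
    fig22_primary = kinetic_params(
      a0 = 1, a1 = 1, a2 = 1, a1t = 3 / 4,
      b0 = 1, b1 = 1, b2 = 1, b1t = 3 / 4, b3 = 1 / 2,
      rho_u = 0.01, rho_ut = 0.01, rho_v = 0.01, rho_vt = 0.01),
    fig23_secondary = kinetic_params(
      a0 = 1, a1 = 1, a2 = 1, a1t = 3 / 4,
      b0 = 1, b1 = 1, b2 = 1, b1t = 4 / 3, b3 = 3,
      rho_u = 0.01, rho_ut = 0.01, rho_v = 0.01, rho_vt = 0.01),
    adni_mixed_table3 = {
      base <- kinetic_params(
        a0 = 1.035, a1 = 1.38, a2 = 1.38, a1t = 0.828,
        b0 = 0.69, b1 = 1.38, b2 = 1.035, b1t = 0.552, b3 = 4.14,
        rho_u = 1.38, rho_ut = 0.138, rho_v = 1.38, rho_vt = 0.014)
      list(base = base, map = regional_map(base, .adni_overrides()))
    })
}

# Regional b3 overrides for the secondary-tauopathy regions, and the (b2, b3)
# overrides that place five regions in primary tauopathy.
.adni_overrides <- function() {
  b3 <- c(
    "Pars opercularis" = 7.452, "Rostral middle frontal gyrus" = 6.707,
    "Superior frontal gyrus" = 7.452, "Caudal middle frontal gyrus" = 7.452,
    "Precentral gyrus" = 5.589, "Postcentral gyrus" = 3.726,
    "Lateral orbitofrontal cortex" = 6.486,
    "Medial orbitofrontal cortex" = 6.486,
    "Pars triangularis" = 5.520e-6, "Rostral anterior cingulate" = 6.210e-6,
    "Posterior cingulate cortex" = 3.45, "Inferior temporal cortex" = 13.11,
    "Middle temporal gyrus" = 11.04, "Superior temporal sulcus" = 8.97,
    "Superior temporal gyrus" = 8.28, "Superior parietal lobule" = 12.42,
    "Cuneus" = 13.8, "Pericalcarine cortex" = 13.8,
    "Inferior parietal lobule" = 11.73, "Lateral occipital sulcus" = 15.18,
    "Lingual gyrus" = 13.8, "Fusiform gyrus" = 7.59,
    "Parahippocampal gyrus" = 11.04, "Temporal pole" = 1.104e-5)
  primary <- list(
    "Entorhinal cortex" = list(b2 = 3.125, b3 = 1.104e-5),
    "Putamen" = list(b2 = 3.795, b3 = 3.795),
    "Pallidum" = list(b2 = 2.76, b3 = 2.76),
    "Precuneus" = list(b2 = 3.105, b3 = 3.105),
    "Locus coeruleus" = list(b2 = 1.38, b3 = 1.38))
  ov <- lapply(names(b3), function(r) list(region = r, values = list(b3 = unname(b3[[r]]))))
  ov <- c(ov, lapply(names(primary), function(r) list(region = r, values = primary[[r]])))
  ov
}

#' Regional parameter map
#'
#' Pairs a base kinetic parameter set with an ordered list of regional
#' overrides, each replacing a subset of the kinetic fields for the nodes
#' whose region label matches (or for an explicit node-index set).
#' Application order is last-write-wins.
#'
#' @param base A [kinetic_params()] object applied to every node by default.
#' @param overrides A list of overrides. Each element is a list with either
#'   `region` (a label matched case-insensitively as a substring of node
#'   region labels) or `nodes` (integer node indices), and `values`, a named
#'   list of kinetic fields replacing the base values.
#' @return An object of class `regional_map`.
#' @seealso [resolve_regional()]
#' @export
regional_map <- function(base, overrides = list()) {
  stopifnot(inherits(base, "kinetic_params"))
  for (ov in overrides) {
    if (is.null(ov$region) && is.null(ov$nodes)) {
      stop("each override needs a 'region' label or a 'nodes' index set")
    }
    bad <- setdiff(names(ov$values), .kp_fields)
    if (length(bad) > 0L) {
      stop("unknown kinetic field(s) in override: ", paste(bad, collapse = ", "))
    }
    merged <- utils::modifyList(unclass(base), lapply(ov$values, as.numeric))
    class(merged) <- "kinetic_params"
    viol <- validate_params(merged)
    if (length(viol) > 0L) {
      stop("override produces invalid parameters:\n  ",
           paste(viol, collapse = "\n  "))
    }
  }
  structure(list(base = base, overrides = overrides), class = "regional_map")
}

#' @export
print.regional_map <- function(x, ...) {
  cat(sprintf("Regional parameter map: %d override(s) on a common base\n",
              length(x$overrides)))
  invisible(x)
}

#' Resolve a regional map against a graph
#'
#' Expands a [regional_map()] to one kinetic parameter set per node of a
#' connectome graph. Nodes not matched by any override receive the base
#' values; overrides are applied in listed order (last write wins). Region
#' labels are matched case-insensitively as substrings of the node region
#' labels, so e.g. `"supramarginal"` selects both hemispheres.
#'
#' @param map A [regional_map()] (a plain [kinetic_params()] is accepted and
#'   treated as a map with no overrides).
#' @param graph A [connectome()] graph whose node labels cover the override
#'   targets.
#' @return An object of class `node_params`: a 13-column numeric matrix with
#'   one row per node, columns named by kinetic field.
#' @export
resolve_regional <- function(map, graph) {
  if (inherits(map, "kinetic_params")) map <- regional_map(map)
  stopifnot(inherits(map, "regional_map"), inherits(graph, "connectome"))
  n <- nrow(graph$nodes)
  base <- unlist(unclass(map$base)[.kp_fields])
  out <- matrix(rep(base, each = n), nrow = n,
                dimnames = list(NULL, .kp_fields))
  labels <- tolower(graph$nodes$label)
  for (ov in map$overrides) {
    if (!is.null(ov$nodes)) {
      idx <- as.integer(ov$nodes)
      if (any(idx < 1L | idx > n)) {
        stop("override node indices out of range 1..", n)
      }
    } else {
      idx <- which(grepl(tolower(ov$region), labels, fixed = TRUE))
      if (length(idx) == 0L) {
        stop("override region ", deparse(ov$region),
             " matches no node label of the graph")
      }
    }
    for (f in names(ov$values)) out[idx, f] <- as.numeric(ov$values[[f]])
  }
  structure(out, class = c("node_params", "matrix"))
}

# Coerce a kinetic_params / node_params / matrix to a per-node parameter
# matrix for a graph with n nodes.
as_node_params <- function(p, n) {
  if (inherits(p, "kinetic_params")) {
    base <- unlist(unclass(p)[.kp_fields])
    return(structure(matrix(rep(base, each = n), nrow = n,
                            dimnames = list(NULL, .kp_fields)),
                     class = c("node_params", "matrix")))
  }
  if (is.matrix(p)) {
    stopifnot(nrow(p) == n, all(.kp_fields %in% colnames(p)))
    return(structure(p[, .kp_fields, drop = FALSE],
                     class = c("node_params", "matrix")))
  }
  stop("expected kinetic_params or a per-node parameter matrix")
}

#' Write a parameter configuration file
#'
#' Serializes a kinetic parameter set (optionally with a damage parameter
#' set and regional overrides) to a flat YAML mapping. Field names are the
#' ASCII spellings used throughout the package (`a1t`/`b1t` for the toxic
#' clearance rates, `rho_*` for the per-species diffusivities). The decimal
#' values round-trip exactly through [read_params_file()].
#'
#' @param p A [kinetic_params()] object or the list returned by
#'   `preset_params("adni_mixed_table3")`.
#' @param path Output file path.
#' @param damage Optional [damage_params()] written under a `damage` key.
#' @return `path`, invisibly.
#' @export
write_params_file <- function(p, path, damage = NULL) {
  if (is.list(p) && !inherits(p, "kinetic_params") &&
      !is.null(p$base) && !is.null(p$map)) {
    p <- p$map
  }
  if (inherits(p, "regional_map")) {
    doc <- unclass(unclass(p$base))
    doc$overrides <- p$overrides
  } else {
    stopifnot(inherits(p, "kinetic_params"))
    doc <- unclass(p)
  }
  if (!is.null(damage)) doc$damage <- unclass(damage)
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read a parameter configuration file
#'
#' Inverse of [write_params_file()]. Unspecified kinetic fields take their
#' [kinetic_params()] defaults.
#'
#' @param path A YAML file with kinetic field names as top-level keys and
#'   optional `overrides` and `damage` entries.
#' @return A [kinetic_params()], a [regional_map()] when overrides are
#'   present, or a list with an additional `damage` element when damage
#'   rates are present.
#' @export
read_params_file <- function(path) {
  doc <- yaml::read_yaml(path)
  kp <- do.call(kinetic_params, doc[intersect(names(doc), .kp_fields)])
  out <- if (!is.null(doc$overrides)) regional_map(kp, doc$overrides) else kp
  if (!is.null(doc$damage)) {
    out <- list(params = out, damage = do.call(damage_params, doc$damage))
  }
  out
}
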