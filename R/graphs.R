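#' Connectome graph container
#'
#' An undirected weighted graph of brain regions (nodes) and white-matter
#' tracts (edges). Each edge carries the mean fiber number `n` and the mean
#' fiber length `l` from tractography; from these the package derives
#'
#' * the transport weights `W_ij = n_ij / l_ij^2` (the inverse-length-squared
#'   scaling of a consistent graph discretization of the diffusion operator),
#' * the weighted degree `D = diag(rowSums(W))` and graph Laplacian
#'   `L(rho) = rho (D - W)`, and
#' * the damage adjacency `A_ij = n_ij / l_ij` used by the non-local
#'   (transneuronal) term of the damage equation. Note `A_ij = W_ij l_ij`.
#'
#' @param nodes A data.frame with column `label` (region name) and optional
#'   numeric columns `x`, `y`, `z` (coordinates).
#' @param edges A data.frame with integer columns `from`, `to` (1-based node
#'   indices, `from != to`) and numeric columns `n` (fiber count > 0) and
#'   `l` (fiber length > 0). Edges are undirected; duplicate pairs are
#'   merged by summing `n` and averaging `l` (with a message).
#' @return An object of class `connectome`: list with `nodes`, `edges` and
#'   lazily built sparse matrices via [adjacency_weights()],
#'   [damage_adjacency()] and [graph_laplacian()].
#' @export
#' @examples
#' g <- cubic_lattice(2, 1, 1)
#' as.matrix(graph_laplacian(g, 1))  # [[1,-1],[-1,1]]
connectome <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot("label" %in% names(nodes),
            all(c("from", "to", "n", "l") %in% names(edges)))
  nV <- nrow(nodes)
  if (nrow(edges) > 0L) {
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    if (any(edges$from < 1L | edges$from > nV | edges$to < 1L | edges$to > nV)) {
      stop("edge endpoints out of node range 1..", nV)
    }
    if (any(!is.finite(edges$n) | edges$n <= 0) ||
        any(!is.finite(edges$l) | edges$l <= 0)) {
      stop("edge attributes n (fiber count) and l (fiber length) must be positive")
    }
    # canonical undirected orientation, then merge duplicates: sum n, mean l
    lo <- pmin(edges$from, edges$to)
    hi <- pmax(edges$from, edges$to)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
      message("merging ", sum(duplicated(key)),
              " duplicate edge(s): summing fiber counts, averaging lengths")
      n <- tapply(edges$n, key, sum)
      l <- tapply(edges$l, key, mean)
      uk <- names(n)
      ft <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
      edges <- data.frame(from = as.integer(ft[, 1]), to = as.integer(ft[, 2]),
                          n = as.numeric(n), l = as.numeric(l))
    } else {
      edges <- data.frame(from = lo, to = hi, n = edges$n, l = edges$l)
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "connectome")
  if (n_components(g) > 1L) {
    warning("graph is disconnected (", n_components(g), " components)")
  }
  g
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# sparse symmetric matrix from edge values
.edge_matrix <- function(g, values) {
  nV <- nrow(g$nodes)
  if (nrow(g$edges) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nV, nV)))
  }
  Matrix::sparseMatrix(i = c(g$edges$from, g$edges$to),
                       j = c(g$edges$to, g$edges$from),
                       x = rep(values, 2L), dims = c(nV, nV))
}

#' Transport weight matrix W = n / l^2
#'
#' @param g A [connectome()] graph.
#' @return A sparse symmetric matrix with zero diagonal.
#' @export
adjacency_weights <- function(g) {
  stopifnot(inherits(g, "connectome"))
  .edge_matrix(g, g$edges$n / g$edges$l^2)
}

#' Damage adjacency A = n / l
#'
#' Weighting of the non-local transneuronal damage term: deliberately `n/l`,
#' distinct from the transport weights `n/l^2` (`A_ij = W_ij * l_ij`).
#'
#' @param g A [connectome()] graph.
#' @return A sparse symmetric matrix with zero diagonal.
#' @export
damage_adjacency <- function(g) {
  stopifnot(inherits(g, "connectome"))
  .edge_matrix(g, g$edges$n / g$edges$l)
}

#' Weighted graph Laplacian L(rho) = rho (D - W)
#'
#' `W` are the transport weights `n/l^2` and `D` the diagonal weighted
#' degree matrix. `L` is symmetric positive semidefinite; constant vectors
#' lie in its kernel (one zero eigenvalue per connected component), so
#' diffusion `du/dt = -L u` conserves total mass and relaxes to the uniform
#' state on each component.
#'
#' @param g A [connectome()] graph.
#' @param rho Non-negative overall diffusivity scale.
#' @return A sparse symmetric matrix.
#' @export
graph_laplacian <- function(g, rho = 1) {
  stopifnot(rho >= 0)
  W <- adjacency_weights(g)
  rho * (Matrix::Diagonal(x = Matrix::rowSums(W)) - W)
}

# number of connected components (via igraph)
n_components <- function(g) {
  ig <- igraph::graph_from_data_frame(
    if (nrow(g$edges) > 0L) g$edges[, c("from", "to")] else
      data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g$nodes))))
  igraph::count_components(ig)
}

#' Synthetic cubic-lattice graph
#'
#' A three-dimensional regular lattice with 6-neighbour connectivity, unit
#' fiber count and fiber length equal to the lattice spacing, hence unit
#' transport weights for `spacing = 1`. Used as the synthetic test domain
#' (e.g. the 30 x 6 x 3 channel for front-propagation experiments). Node
#' labels encode the integer coordinates as `"x_y_z"` (0-based), and the
#' coordinate columns hold the positions in length units.
#'
#' @param nx,ny,nz Number of nodes per axis (>= 1).
#' @param spacing Lattice spacing (edge fiber length).
#' @return A [connectome()] graph with `nx*ny*nz` nodes.
#' @export
#' @examples
#' g <- cubic_lattice(30, 6, 3)
#' nrow(g$nodes); nrow(g$edges)  # 540, 1332
cubic_lattice <- function(nx, ny, nz = 1, spacing = 1) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, spacing > 0)
  coords <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1), iz = 0:(nz - 1))
  idx <- function(ix, iy, iz) 1L + ix + nx * (iy + ny * iz)
  nodes <- data.frame(
    label = paste(coords$ix, coords$iy, coords$iz, sep = "_"),
    x = coords$ix * spacing, y = coords$iy * spacing, z = coords$iz * spacing)
  ex <- coords$ix < nx - 1
  ey <- coords$iy < ny - 1
  ez <- coords$iz < nz - 1
  from <- c(idx(coords$ix[ex], coords$iy[ex], coords$iz[ex]),
            idx(coords$ix[ey], coords$iy[ey], coords$iz[ey]),
            idx(coords$ix[ez], coords$iy[ez], coords$iz[ez]))
  to <- c(idx(coords$ix[ex] + 1L, coords$iy[ex], coords$iz[ex]),
          idx(coords$ix[ey], coords$iy[ey] + 1L, coords$iz[ey]),
          idx(coords$ix[ez], coords$iy[ez], coords$iz[ez] + 1L))
  edges <- data.frame(from = from, to = to,
                      n = rep(1, length(from)),
                      l = rep(spacing, length(from)))
  connectome(nodes, edges)
}

#' Default GraphML edge-attribute name mapping
#'
#' Maps the package's edge fields to the attribute keys used in
#' braingraph.org-style connectome GraphML files. Override any entry when
#' loading files from other pipelines.
#'
#' @return Named list with entries `n` (fiber count key), `l` (fiber length
#'   key), and node attribute keys `label`, `x`, `y`, `z`.
#' @export
graphml_attr_map <- function() {
  list(n = "fiber_count_mean", l = "fiber_length_mean",
       label = "dn_name", x = "dn_position_x", y = "dn_position_y",
       z = "dn_position_z")
}

#' Load a connectome from GraphML
#'
#' Reads a GraphML file (e.g. a braingraph.org reference connectome) and
#' assembles a [connectome()] graph. Directed edges are symmetrized and
#' duplicate undirected pairs merged (summing fiber counts, averaging
#' lengths, with a message). Attribute keys are resolved through `attr_map`;
#' a label or coordinate key absent from the file degrades gracefully
#' (labels fall back to GraphML ids), but a missing fiber-count or
#' fiber-length key on the edges is an error naming the attribute.
#'
#' @param path GraphML file path.
#' @param attr_map Attribute name mapping, see [graphml_attr_map()]; partial
#'   lists are completed with the defaults.
#' @return A [connectome()] graph. GraphML node ids are preserved in
#'   `nodes$graphml_id`.
#' @export
load_graphml <- function(path, attr_map = graphml_attr_map()) {
  attr_map <- utils::modifyList(graphml_attr_map(), attr_map)
  ig <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr_names(ig)
  ea <- igraph::edge_attr_names(ig)
  has_edges <- igraph::ecount(ig) > 0L
  if (has_edges) {
    for (f in c("n", "l")) {
      if (!attr_map[[f]] %in% ea) {
        stop("edge attribute ", deparse(attr_map[[f]]), " (", f,
             ") not present in ", path,
             "; available: ", paste(ea, collapse = ", "))
      }
    }
  }
  nV <- igraph::vcount(ig)
  lab <- if (attr_map$label %in% va) {
    as.character(igraph::vertex_attr(ig, attr_map$label))
  } else if ("id" %in% va) {
    as.character(igraph::vertex_attr(ig, "id"))
  } else {
    as.character(seq_len(nV))
  }
  nodes <- data.frame(label = lab, stringsAsFactors = FALSE)
  for (f in c("x", "y", "z")) {
    if (attr_map[[f]] %in% va) {
      nodes[[f]] <- as.numeric(igraph::vertex_attr(ig, attr_map[[f]]))
    }
  }
  nodes$graphml_id <- if ("id" %in% va) {
    as.character(igraph::vertex_attr(ig, "id"))
  } else {
    as.character(seq_len(nV) - 1L)
  }
  edges <- if (has_edges) {
    el <- igraph::as_edgelist(ig, names = FALSE)
    data.frame(
      from = as.integer(el[, 1]), to = as.integer(el[, 2]),
      n = as.numeric(igraph::edge_attr(ig, attr_map$n)),
      l = as.numeric(igraph::edge_attr(ig, attr_map$l)))
  } else {
    data.frame(from = integer(0), to = integer(0),
               n = numeric(0), l = numeric(0))
  }
  bad <- which(!is.finite(edges$n) | !is.finite(edges$l))
  if (length(bad) > 0L) {
    stop("edge ", bad[1], " of ", path, " has a non-numeric '",
         attr_map$n, "' or '", attr_map$l, "' attribute")
  }
  connectome(nodes, edges)
}

#' Save a connectome to GraphML
#'
#' Writes standard GraphML with the attribute keys of [graphml_attr_map()]
#' (or a user mapping), re-loadable by [load_graphml()]. Unicode region
#' labels are preserved. An edgeless graph is valid and produces a warning.
#'
#' @param g A [connectome()] graph.
#' @param path Output file path.
#' @param attr_map Attribute name mapping as in [load_graphml()].
#' @return `path`, invisibly.
#' @export
save_graphml <- function(g, path, attr_map = graphml_attr_map()) {
  stopifnot(inherits(g, "connectome"))
  attr_map <- utils::modifyList(graphml_attr_map(), attr_map)
  if (nrow(g$edges) == 0L) warning("saving a graph with no edges")
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, attr_map$label, value = g$nodes$label)
  for (f in c("x", "y", "z")) {
    if (!is.null(g$nodes[[f]])) {
      ig <- igraph::set_vertex_attr(ig, attr_map[[f]], value = g$nodes[[f]])
    }
  }
  if (nrow(g$edges) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
    ig <- igraph::set_edge_attr(ig, attr_map$n, value = g$edges$n)
    ig <- igraph::set_edge_attr(ig, attr_map$l, value = g$edges$l)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Select lattice nodes by coordinate predicate
#'
#' Convenience selector for seeding: returns the indices of nodes whose
#' coordinates satisfy a predicate, e.g. `function(x, y, z) x <= 4`.
#'
#' @param g A [connectome()] graph with coordinate columns.
#' @param predicate Function of `(x, y, z)` returning a logical vector.
#' @return Integer node indices.
#' @export
nodes_where <- function(g, predicate) {
  stopifnot(inherits(g, "connectome"), !is.null(g$nodes$x))
  z <- if (is.null(g$nodes$z)) rep(0, nrow(g$nodes)) else g$nodes$z
  y <- if (is.null(g$nodes$y)) rep(0, nrow(g$nodes)) else g$nodes$y
  which(predicate(g$nodes$x, y, z))
}
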