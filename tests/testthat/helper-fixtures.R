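# Shared fixtures, all built in code.

# random strictly positive kinetic parameter draw (log-uniform rates)
rand_params <- function() {
  r <- function(lo = 0.1, hi = 3) exp(stats::runif(1, log(lo), log(hi)))
  kinetic_params(a0 = r(), a1 = r(), a2 = r(), a1t = r(),
                 b0 = r(), b1 = r(), b2 = r(), b1t = r(),
                 b3 = stats::runif(1, 0, 3),
                 rho_u = r(0.01, 1), rho_ut = r(0.01, 1),
                 rho_v = r(0.01, 1), rho_vt = r(0.01, 1))
}

# two disjoint triangles: a disconnected two-component fixture
two_component_graph <- function() {
  suppressWarnings(connectome(
    nodes = data.frame(label = paste0("n", 1:6)),
    edges = data.frame(from = c(1, 2, 3, 4, 5, 6),
                       to = c(2, 3, 1, 5, 6, 4),
                       n = c(2, 1, 1, 3, 1, 2),
                       l = c(1, 2, 1, 1.5, 1, 2))))
}

# small synthetic connectome with anatomical-style region labels and
# tractography-style edge attributes (fiber count, fiber length)
synthetic_connectome <- function(seed = 42) {
  set.seed(seed)
  labels <- c("Left supramarginal gyrus", "Right supramarginal gyrus",
              "Left entorhinal cortex", "Right entorhinal cortex",
              "Locus coeruleus", "Left cuneus", "Right cuneus",
              "Left precuneus", "Right precuneus", "Brain stem",
              "Left temporal pole", "Right temporal pole")
  n <- length(labels)
  # ring plus random chords keeps the graph connected
  ring <- data.frame(from = 1:n, to = c(2:n, 1))
  chords <- data.frame(from = sample(n, 8, replace = TRUE),
                       to = sample(n, 8, replace = TRUE))
  chords <- chords[chords$from != chords$to, ]
  edges <- rbind(ring, chords)
  edges$n <- sample(1:40, nrow(edges), replace = TRUE)
  edges$l <- stats::runif(nrow(edges), 10, 120)
  suppressMessages(connectome(
    nodes = data.frame(label = labels,
                       x = stats::rnorm(n), y = stats::rnorm(n),
                       z = stats::rnorm(n)),
    edges = edges))
}
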