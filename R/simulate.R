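# Benchmark generators: random geometric graphs on the unit square, static
# power-law graphs, planted perturbations (permuted or densified leading
# sub-network) with gold-standard differential node labels.

.node_labels <- function(n) sprintf("n%0*d", nchar(n), seq_len(n))

#' SimulationSpec: parameters of one benchmark instance
#'
#' @param kind One of \code{"rg_permuted"} (random geometric graph, first k
#'   node indices permuted), \code{"rg_denser"} (leading k-by-k block replaced
#'   by a denser random geometric graph) or \code{"pl_permuted"} (static
#'   power-law graph, first k indices permuted).
#' @param N Number of nodes.
#' @param d Random-geometric connection radius in (0, sqrt(2)); points closer
#'   than \code{d} on the unit square are joined.
#' @param k Size of the planted differential sub-network (the first k nodes in
#'   canonical label order).
#' @param d_prime Radius of the denser replacement block
#'   (\code{kind = "rg_denser"}); must exceed \code{d}.
#' @param E Number of edges of the power-law graph.
#' @param gamma Power-law degree exponent (> 1).
#' @param seed Integer seed; together with the spec it determines the
#'   instance bit-for-bit.
#' @return An object of class \code{SimulationSpec}.
#' @examples
#' simulationSpec("rg_permuted", N = 250, d = 0.15, k = 50, seed = 7)
#' @export
simulationSpec <- function(kind = c("rg_permuted", "rg_denser", "pl_permuted"),
                           N, d = NA_real_, k, d_prime = NA_real_,
                           E = NA_integer_, gamma = NA_real_, seed) {
  kind <- match.arg(kind)
  N <- as.integer(N); k <- as.integer(k); seed <- as.integer(seed)
  if (k >= N) stop("k must be smaller than N")
  if (kind %in% c("rg_permuted", "rg_denser")) {
    if (is.na(d) || d <= 0 || d >= sqrt(2)) stop("d must lie in (0, sqrt(2))")
  }
  if (kind == "rg_denser") {
    if (is.na(d_prime) || d_prime <= d)
      stop("d_prime must exceed d for a denser sub-network")
    if (d_prime >= sqrt(2)) stop("d_prime must be below sqrt(2)")
  }
  if (kind == "pl_permuted") {
    E <- as.integer(E)
    if (is.na(E) || E > N * (N - 1) / 2) stop("E must be at most N(N-1)/2")
    if (is.na(gamma) || gamma <= 1) stop("gamma must exceed 1")
  }
  structure(list(kind = kind, N = N, d = d, k = k, d_prime = d_prime,
                 E = E, gamma = gamma, seed = seed),
            class = "SimulationSpec")
}

#' @export
print.SimulationSpec <- function(x, ...) {
  flds <- vapply(names(x), function(f) {
    v <- x[[f]]
    if (is.na(v) && !is.character(v)) NA_character_
    else paste0(f, "=", format(v))
  }, "")
  cat("SimulationSpec(", paste(stats::na.omit(flds), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Random geometric graph on the unit square
#'
#' N points are sampled uniformly on [0,1]^2 and two nodes are joined iff
#' their Euclidean distance is strictly below \code{d}. Adjacency is binary.
#' Node labels are zero-padded so that the canonical (lexicographic) order
#' matches the generation order; "the first k nodes" always refers to this
#' order.
#'
#' @param n Number of nodes (>= 2).
#' @param d Connection radius in (0, sqrt(2)).
#' @param seed Integer seed (the global RNG state is left untouched).
#' @param labels Optional node labels.
#' @return A binary [LabeledGraph-class].
#' @examples
#' randomGeometric(100, 0.15, seed = 1)
#' @export
randomGeometric <- function(n, d, seed, labels = .node_labels(n)) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (!is.numeric(d) || d <= 0 || d >= sqrt(2))
    stop("d must lie in (0, sqrt(2))")
  pts <- withr::with_seed(seed, matrix(stats::runif(2L * n), ncol = 2L))
  adj <- .rg_adjacency(pts, d)
  dimnames(adj) <- list(labels, labels)
  LabeledGraph(adj)
}

.rg_adjacency <- function(pts, d) {
  dist2 <- as.matrix(stats::dist(pts))
  adj <- (dist2 < d) * 1
  diag(adj) <- 0
  adj
}

#' Permute the first k rows and columns of a graph
#'
#' Draws a uniform random permutation of the indices 1..k (in canonical
#' label order) and applies it simultaneously to rows and columns, so the
#' adjacency stays symmetric: edges among the last N-k nodes are untouched
#' while edges inside the leading block and those crossing the boundary are
#' rewired through the permutation. The whole-graph degree multiset is
#' preserved.
#'
#' @param g A [LabeledGraph-class].
#' @param k How many leading nodes to permute (2 <= k <= N).
#' @param seed Integer seed.
#' @return The perturbed [LabeledGraph-class] (same labels, same order).
#' @export
permuteFirstK <- function(g, k, seed) {
  stopifnot(is(g, "LabeledGraph"))
  n <- numNodes(g)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must lie in [2, N]")
  perm <- withr::with_seed(seed, sample.int(k))
  idx <- if (k == n) perm else c(perm, (k + 1L):n)
  m <- g@adjacency[idx, idx, drop = FALSE]
  dimnames(m) <- dimnames(g@adjacency)  # labels keep their positions
  LabeledGraph(m)
}

#' Replace the leading k-by-k block with a denser random geometric graph
#'
#' Generates a fresh random geometric graph on k nodes with radius
#' \code{d_prime} and overwrites the leading k-by-k block of the adjacency
#' with it. By default every entry outside the block is unchanged. With
#' \code{replace_incident = TRUE} the whole network formed by the first k
#' nodes -- their internal block \emph{and} their edges to the remaining
#' nodes -- is replaced by the fresh dense sub-network, so the planted nodes
#' keep only the new internal edges; this is the construction the
#' \code{rg_denser} benchmark uses (see [makeInstance()]).
#'
#' @param g A [LabeledGraph-class].
#' @param k Size of the block (2 <= k <= N).
#' @param d_prime Radius of the replacement graph, in (0, sqrt(2)).
#' @param seed Integer seed.
#' @param replace_incident Replace the crossing edges of the first k nodes
#'   as well (drop them), not just the internal block.
#' @return The perturbed [LabeledGraph-class].
#' @export
replaceDenseSubnetwork <- function(g, k, d_prime, seed,
                                   replace_incident = FALSE) {
  stopifnot(is(g, "LabeledGraph"))
  n <- numNodes(g)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must lie in [2, N]")
  if (!is.numeric(d_prime) || d_prime <= 0 || d_prime >= sqrt(2))
    stop("d_prime must lie in (0, sqrt(2))")
  pts <- withr::with_seed(seed, matrix(stats::runif(2L * k), ncol = 2L))
  block <- .rg_adjacency(pts, d_prime)
  m <- g@adjacency
  if (replace_incident) {
    m[seq_len(k), ] <- 0
    m[, seq_len(k)] <- 0
  }
  m[seq_len(k), seq_len(k)] <- block
  LabeledGraph(m, labels = rownames(g@adjacency))
}

#' Static power-law (scale-free) graph with a fixed edge count
#'
#' Static-model construction: node i carries weight
#' \eqn{w_i \propto i^{-1/(\gamma-1)}}; edge endpoints are drawn
#' independently with probability proportional to the weights, and
#' self-loops and duplicate edges are rejected until exactly E unique
#' undirected edges exist. The degree distribution tail follows a power law
#' with exponent gamma.
#'
#' @param n Number of nodes (>= 2).
#' @param e Number of edges (<= n(n-1)/2).
#' @param gamma Degree exponent (> 1); larger values give lighter tails.
#' @param seed Integer seed.
#' @return A binary [LabeledGraph-class].
#' @export
powerLaw <- function(n, e, gamma, seed) {
  n <- as.integer(n); e <- as.integer(e)
  if (n < 2L) stop("n must be at least 2")
  if (e < 1L || e > n * (n - 1) / 2) stop("e must lie in [1, n(n-1)/2]")
  if (!is.numeric(gamma) || gamma <= 1) stop("gamma must exceed 1")
  w <- seq_len(n)^(-1 / (gamma - 1))
  edges <- withr::with_seed(seed, {
    have <- integer(0)
    while (length(have) < e) {
      need <- e - length(have)
      draw <- max(2L * need, 100L)
      i <- sample.int(n, draw, replace = TRUE, prob = w)
      j <- sample.int(n, draw, replace = TRUE, prob = w)
      ok <- i != j
      lo <- pmin(i[ok], j[ok]); hi <- pmax(i[ok], j[ok])
      id <- (lo - 1) * n + hi  # unique id per unordered pair
      have <- unique(c(have, id))
    }
    have[seq_len(e)]
  })
  lo <- (edges - 1) %/% n + 1
  hi <- (edges - 1) %% n + 1
  labels <- .node_labels(n)
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  adj[cbind(lo, hi)] <- 1
  adj[cbind(hi, lo)] <- 1
  LabeledGraph(adj)
}

#' Build one benchmark instance with its gold standard
#'
#' Graph A is generated from the spec (random geometric or power-law); graph
#' B is derived by the spec's perturbation: for the permuted kinds a uniform
#' relabeling of the first k indices, for \code{rg_denser} the replacement of
#' the entire network formed by the first k nodes (internal and crossing
#' edges) by a fresh, denser random geometric graph, which leaves the planted
#' nodes clearly rewired rather than anchored by their unchanged crossing
#' edges. The gold standard is the first k node labels in canonical order.
#' The perturbation uses a seed deterministically derived from the spec seed
#' so the two draws do not share an RNG stream.
#'
#' @param spec A [simulationSpec()].
#' @return A list with elements \code{graph_a}, \code{graph_b} (aligned
#'   [LabeledGraph-class] objects) and \code{gold} (character vector of the
#'   planted differential node labels).
#' @examples
#' inst <- makeInstance(simulationSpec("rg_permuted", N = 250, d = 0.15,
#'                                     k = 50, seed = 7))
#' length(inst$gold)
#' @export
makeInstance <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  seed_b <- (spec$seed + 1000003L) %% .Machine$integer.max
  ga <- switch(spec$kind,
    rg_permuted = ,
    rg_denser = randomGeometric(spec$N, spec$d, spec$seed),
    pl_permuted = powerLaw(spec$N, spec$E, spec$gamma, spec$seed))
  gb <- switch(spec$kind,
    rg_permuted = ,
    pl_permuted = permuteFirstK(ga, spec$k, seed_b),
    rg_denser = replaceDenseSubnetwork(ga, spec$k, spec$d_prime, seed_b,
                                       replace_incident = TRUE))
  list(graph_a = ga, graph_b = gb,
       gold = nodeLabels(ga)[seq_len(spec$k)])
}
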