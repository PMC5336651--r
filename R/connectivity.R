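#' Cosine-similarity connectivity weights
#'
#' The weight between nodes i and j is the cosine of the angle between their
#' adjacency rows, \eqn{w_{ij} = \sum_l A_{il}A_{jl} / (\|A_{i.}\| \|A_{j.}\|)},
#' a one-step neighbourhood overlap that is cheap on sparse graphs. The sum
#' runs over all columns (the diagonal is zero and contributes nothing).
#' Rows of all zeros (isolated nodes) get weight 0 by convention, and the
#' diagonal is set to zero.
#'
#' @param g A [LabeledGraph-class] (binary or weighted).
#' @return A [ConnectivityMatrix-class].
#' @examples
#' g <- randomGeometric(50, 0.3, seed = 1)
#' cosineConnectivity(g)
#' @export
cosineConnectivity <- function(g) {
  stopifnot(is(g, "LabeledGraph"))
  m <- g@adjacency
  cross <- tcrossprod(m)
  nrm <- sqrt(diag(cross))
  denom <- outer(nrm, nrm)
  w <- ifelse(denom > 0, cross / denom, 0)
  diag(w) <- 0
  w[w > 1] <- 1  # guard against rounding just above 1
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(m)
  ConnectivityMatrix(w)
}

#' One-step topological-overlap connectivity weights
#'
#' For a binary graph, the weight between i and j counts their shared
#' neighbours (plus the direct edge) normalised by the smaller adjusted
#' degree:
#' \deqn{a_{ij} = \frac{\sum_{l \ne i,j} A_{il}A_{lj} + A_{ij}}
#'   {\min(\sum_{l \ne i} A_{il} - A_{ij},\; \sum_{l \ne j} A_{lj} - A_{ij}) + 1}.}
#' The diagonal is zero. Input must be 0/1; binarize weighted graphs first.
#'
#' @param g A binary [LabeledGraph-class].
#' @return A [ConnectivityMatrix-class].
#' @export
topologicalOverlap <- function(g) {
  stopifnot(is(g, "LabeledGraph"))
  m <- g@adjacency
  if (!all(m == 0 | m == 1))
    stop("topological overlap requires a binary adjacency; ",
         "binarize the graph first")
  shared <- m %*% m          # sum_l A_il A_lj; diagonal terms vanish as A_ii=0
  deg <- rowSums(m)
  # sum_{l != i,j} excludes l = j, i.e. subtracts A_ij * A_jj = 0; the matrix
  # product already omits nothing else because the diagonal of A is zero.
  num <- shared + m
  denom <- pmin(outer(deg, rep(1, length(deg))), outer(rep(1, length(deg)), deg)) - m + 1
  w <- num / denom
  diag(w) <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(m)
  ConnectivityMatrix(w)
}

#' Pooled correlation between cosine and topological-overlap weights
#'
#' Generates (or accepts) a collection of benchmark graphs, computes both
#' connectivity measures for each, pools the upper-triangle off-diagonal
#' entries across all graphs and returns the Pearson correlation between the
#' two pooled vectors.
#'
#' @param specs A list of [SimulationSpec] objects (or a single one) whose
#'   graph A is used; alternatively a list of [LabeledGraph-class] objects.
#' @return The pooled Pearson correlation (a single number).
#' @examples
#' specs <- lapply(1:5, function(s) simulationSpec("rg_permuted", N = 60,
#'   d = 0.15, k = 10, seed = s))
#' correlateMeasures(specs)
#' @export
correlateMeasures <- function(specs) {
  if (is(specs, "SimulationSpec") || is(specs, "LabeledGraph"))
    specs <- list(specs)
  graphs <- lapply(specs, function(s) {
    if (is(s, "LabeledGraph")) s else makeInstance(s)$graph_a
  })
  pooled <- lapply(graphs, function(g) {
    ut <- upper.tri(g@adjacency)
    list(cos = weightMatrix(cosineConnectivity(g))[ut],
         to = weightMatrix(topologicalOverlap(g))[ut])
  })
  x <- unlist(lapply(pooled, `[[`, "cos"), use.names = FALSE)
  y <- unlist(lapply(pooled, `[[`, "to"), use.names = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in pooled connectivity entries; correlation undefined")
  stats::cor(x, y)
}
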