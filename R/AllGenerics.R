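#' Accessors for ghdiff classes
#'
#' @param x A [LabeledGraph-class], [ConnectivityMatrix-class] or
#'   [DiffNetResult-class] object.
#' @return \code{nodeLabels} returns the ordered character vector of node
#'   identifiers; \code{adjacency} the adjacency matrix of a graph;
#'   \code{weightMatrix} the weight matrix of a connectivity object;
#'   \code{numNodes} the node count; \code{resultTable} and
#'   \code{removalTrace} the per-node table and removal trace of a
#'   differential analysis.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("removalTrace", function(x) standardGeneric("removalTrace"))

#' @rdname accessors
setMethod("nodeLabels", "LabeledGraph", function(x) rownames(x@adjacency))
#' @rdname accessors
setMethod("nodeLabels", "ConnectivityMatrix", function(x) rownames(x@weights))
#' @rdname accessors
setMethod("nodeLabels", "DiffNetResult", function(x) x@table$node)

#' @rdname accessors
setMethod("adjacency", "LabeledGraph", function(x) x@adjacency)
#' @rdname accessors
setMethod("weightMatrix", "ConnectivityMatrix", function(x) x@weights)

#' @rdname accessors
setMethod("numNodes", "LabeledGraph", function(x) nrow(x@adjacency))
#' @rdname accessors
setMethod("numNodes", "ConnectivityMatrix", function(x) nrow(x@weights))

#' @rdname accessors
setMethod("resultTable", "DiffNetResult", function(x) x@table)
#' @rdname accessors
setMethod("removalTrace", "DiffNetResult", function(x) x@trace)

setMethod("show", "LabeledGraph", function(object) {
  m <- object@adjacency
  n <- nrow(m)
  ne <- sum(m[upper.tri(m)] != 0)
  binary <- all(m %in% c(0, 1))
  cat(sprintf("LabeledGraph with %d nodes, %d %sedges\n", n, ne,
              if (binary) "" else "weighted "))
  if (n) cat("  labels:", paste(utils::head(rownames(m), 5), collapse = ", "),
             if (n > 5) "..." else "", "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  m <- object@weights
  cat(sprintf("ConnectivityMatrix on %d nodes (weights in [%.3f, %.3f])\n",
              nrow(m), min(m), max(m)))
})

setMethod("show", "GHDTest", function(object) {
  cat("GHD test for network independence\n")
  cat(sprintf("  nodes: %d\n  GHD = %.6g, null mean = %.6g, null sd = %.6g\n",
              object@nNodes, object@ghd, object@muPi, object@sigmaPi))
  cat(sprintf("  z = %.4g, p = %.4g (lower tail; small p => dependent)\n",
              object@z, object@pValue))
})

setMethod("show", "DiffNetResult", function(object) {
  tab <- object@table
  cat(sprintf("DiffNetResult (%s): %d nodes, %d called differential\n",
              object@method, nrow(tab), sum(tab$differential)))
  cat(sprintf("  theta = %g, alpha = %g; phase 1 removed %d, phase 2 removed %d, survivors %d\n",
              object@theta, object@alpha,
              sum(tab$phase == "1"), sum(tab$phase == "2"),
              sum(tab$phase == "survivor")))
})
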