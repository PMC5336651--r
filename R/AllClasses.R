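#' @import methods
NULL

.check_square_labeled <- function(m, what) {
  msgs <- character()
  if (!is.matrix(m) || !is.numeric(m))
    return(sprintf("%s must be a numeric matrix", what))
  if (nrow(m) != ncol(m))
    msgs <- c(msgs, sprintf("%s must be square", what))
  labs <- rownames(m)
  if (is.null(labs) || is.null(colnames(m)))
    msgs <- c(msgs, sprintf("%s must carry node labels as dimnames", what))
  else {
    if (!identical(labs, colnames(m)))
      msgs <- c(msgs, "row and column labels differ")
    if (anyDuplicated(labs))
      msgs <- c(msgs, "node labels must be unique")
  }
  if (anyNA(m))
    msgs <- c(msgs, sprintf("%s contains missing values", what))
  msgs
}

#' LabeledGraph: an undirected graph with ordered node labels
#'
#' Holds the raw input network: a symmetric, zero-diagonal adjacency matrix of
#' non-negative edge weights (0/1 for binary graphs) whose dimnames carry the
#' ordered node identifiers.
#'
#' @slot adjacency Square numeric matrix; symmetric, zero diagonal, entries
#'   >= 0, dimnames give the node labels.
#' @aliases LabeledGraph-class
#' @exportClass LabeledGraph
setClass("LabeledGraph", representation(adjacency = "matrix"))

setValidity("LabeledGraph", function(object) {
  m <- object@adjacency
  msgs <- .check_square_labeled(m, "adjacency")
  if (length(msgs)) return(msgs)
  if (!isSymmetric(unname(m), tol = 0))
    msgs <- c(msgs, "adjacency must be exactly symmetric")
  if (any(diag(m) != 0))
    msgs <- c(msgs, "adjacency diagonal must be exactly zero")
  if (any(m < 0))
    msgs <- c(msgs, "edge weights must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledGraph
#'
#' @param adjacency Symmetric numeric matrix with zero diagonal and
#'   non-negative entries.
#' @param labels Optional character vector of node labels; defaults to the
#'   matrix dimnames.
#' @return A [LabeledGraph-class] object.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1
#' LabeledGraph(m, labels = c("a", "b", "c"))
#' @export
LabeledGraph <- function(adjacency, labels = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (!is.null(labels))
    dimnames(adjacency) <- list(as.character(labels), as.character(labels))
  new("LabeledGraph", adjacency = adjacency)
}

#' ConnectivityMatrix: pairwise connectivity weights
#'
#' Symmetric matrix of pairwise edge weights in [0, 1] derived from a graph by
#' cosine similarity or one-step topological overlap; the object the GHD
#' statistic operates on.
#'
#' @slot weights Square numeric matrix; symmetric, zero diagonal, entries in
#'   [0, 1], dimnames give the node labels.
#' @aliases ConnectivityMatrix-class
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix", representation(weights = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  m <- object@weights
  msgs <- .check_square_labeled(m, "weights")
  if (length(msgs)) return(msgs)
  if (!isSymmetric(unname(m), tol = 0))
    msgs <- c(msgs, "weights must be exactly symmetric")
  if (any(diag(m) != 0))
    msgs <- c(msgs, "weight diagonal must be exactly zero")
  if (any(m < 0) || any(m > 1 + 1e-12))
    msgs <- c(msgs, "weights must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param weights Symmetric numeric matrix with zero diagonal and entries in
#'   [0, 1].
#' @param labels Optional character vector of node labels.
#' @return A [ConnectivityMatrix-class] object.
#' @export
ConnectivityMatrix <- function(weights, labels = rownames(weights)) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (!is.null(labels))
    dimnames(weights) <- list(as.character(labels), as.character(labels))
  new("ConnectivityMatrix", weights = weights)
}

#' GHDTest: one paired GHD comparison
#'
#' Result of testing two connectivity matrices for independence: the GHD
#' value, the closed-form permutation-null mean and standard deviation, the
#' standardized z-score and the lower-tail normal p-value. Small p-values
#' indicate the two networks share structure (dependence); large p-values are
#' consistent with independence.
#'
#' @slot ghd GHD between the mean-centered weights (>= 0).
#' @slot muPi Permutation-null mean of the statistic.
#' @slot sigmaPi Permutation-null standard deviation (>= 0).
#' @slot z Standardized statistic (ghd - muPi) / sigmaPi.
#' @slot pValue Lower-tail normal p-value in [0, 1].
#' @slot nNodes Number of nodes compared.
#' @aliases GHDTest-class
#' @exportClass GHDTest
setClass("GHDTest", representation(
  ghd = "numeric", muPi = "numeric", sigmaPi = "numeric",
  z = "numeric", pValue = "numeric", nNodes = "integer"))

setValidity("GHDTest", function(object) {
  msgs <- character()
  if (object@ghd < 0) msgs <- c(msgs, "ghd must be non-negative")
  if (object@sigmaPi < 0) msgs <- c(msgs, "sigmaPi must be non-negative")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' DiffNetResult: a differential sub-network analysis
#'
#' Per-node output of one of the detection algorithms, plus the step-by-step
#' trace of the sub-network statistics along the removal path.
#'
#' The node table has one row per node in removal order (survivors last, in
#' canonical label order) with columns \code{node}, \code{removal_order}
#' (1-based; survivors share the final rank), \code{phase} (\code{"1"},
#' \code{"2"} or \code{"survivor"}), \code{ghd}, \code{mu_pi},
#' \code{sigma_pi}, \code{z}, \code{p_value} (the statistics of the
#' sub-network remaining immediately after that node's removal; survivors
#' carry the terminal sub-network's), \code{p_adjusted}
#' (Benjamini-Hochberg) and \code{differential} (TRUE when
#' \code{p_adjusted > alpha}).
#'
#' @slot table data.frame as described above.
#' @slot trace data.frame with columns \code{remaining_n}, \code{ghd},
#'   \code{mu_pi}, \code{sigma_pi}, \code{z}, \code{p}; first row is the full
#'   network, then one row per removal.
#' @slot theta Phase-switch threshold on the sub-network p-value.
#' @slot alpha Significance cut-off used for the differential call.
#' @slot method One of "closed_form", "fast_approx", "dghd".
#' @aliases DiffNetResult-class
#' @exportClass DiffNetResult
setClass("DiffNetResult", representation(
  table = "data.frame", trace = "data.frame",
  theta = "numeric", alpha = "numeric", method = "character"))

setValidity("DiffNetResult", function(object) {
  msgs <- character()
  tab <- object@table
  need <- c("node", "removal_order", "phase", "ghd", "mu_pi", "sigma_pi",
            "z", "p_value", "p_adjusted", "differential")
  if (!all(need %in% names(tab)))
    msgs <- c(msgs, paste("table lacks columns:",
                          paste(setdiff(need, names(tab)), collapse = ", ")))
  else {
    if (anyDuplicated(tab$node))
      msgs <- c(msgs, "every node must appear exactly once")
    if (any(tab$p_adjusted + 1e-12 < tab$p_value, na.rm = TRUE))
      msgs <- c(msgs, "p_adjusted must be >= p_value")
    if (!all(tab$phase %in% c("1", "2", "survivor")))
      msgs <- c(msgs, "phase must be one of 1, 2, survivor")
  }
  tr <- object@trace
  if (nrow(tr) && (any(!is.finite(tr$p)) || any(tr$p < 0 | tr$p > 1)))
    msgs <- c(msgs, "trace p-values must be finite and in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
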