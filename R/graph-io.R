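#' Read a network from disk
#'
#' Two plain-text formats are supported. \code{edgelist}: TSV without header,
#' rows \code{nodeA<TAB>nodeB[<TAB>weight]}; a missing weight column means a
#' binary graph (weight 1), duplicate undirected edges collapse to one with
#' the last weight winning, and self-loops are dropped with a warning.
#' \code{adjacency}: dense CSV whose header row and first column both carry
#' the node labels; the matrix must be symmetric to within 1e-9.
#'
#' @param path Path to the file.
#' @param format Either \code{"edgelist"} or \code{"adjacency"}.
#' @return A [LabeledGraph-class]. Edge-list node order is sorted label order.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc"), f)
#' readGraph(f, "edgelist")
#' @export
readGraph <- function(path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edgelist") .read_edgelist(path) else .read_adjacency(path)
}

.read_edgelist <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty edge list: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: expected 2-3 tab-separated fields, got %d",
                 lineno[bad[1]], path, nf[bad[1]]))
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  w <- rep(1, length(from))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(fields[has_w], `[[`, "", 3L)
    wnum <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wnum))
      stop(sprintf("malformed row at line %d of %s: weight '%s' is not numeric",
                   lineno[has_w][which(is.na(wnum))[1]], path,
                   wtxt[which(is.na(wnum))[1]]))
    w[has_w] <- wnum
  }
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) in %s", sum(loops), path))
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
  }
  labels <- sort(unique(c(from, to)))
  n <- length(labels)
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- match(from, labels)
  j <- match(to, labels)
  # later rows overwrite earlier ones: last weight wins for duplicate edges
  for (e in seq_along(i)) {
    adj[i[e], j[e]] <- w[e]
    adj[j[e], i[e]] <- w[e]
  }
  LabeledGraph(adj)
}

.read_adjacency <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("adjacency CSV is not square: ", nrow(m), " rows, ", ncol(m),
         " value columns")
  if (anyNA(m)) stop("adjacency CSV contains non-numeric or missing entries")
  if (!identical(colnames(m), labels))
    stop("adjacency CSV header labels do not match first-column labels")
  dimnames(m) <- list(labels, labels)
  if (max(abs(m - t(m))) > 1e-9)
    stop("adjacency matrix is asymmetric beyond tolerance 1e-9")
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) {
    warning("non-zero diagonal entries set to zero (self-loops are dropped)")
    diag(m) <- 0
  }
  LabeledGraph(m)
}

#' Write a network to disk
#'
#' Inverse of [readGraph()]: \code{edgelist} writes one TSV row per undirected
#' edge (weight column included only for non-binary graphs), \code{adjacency}
#' writes the dense labeled CSV. Full double precision is retained so that a
#' write/read round trip reproduces the graph.
#'
#' @param graph A [LabeledGraph-class].
#' @param path Output path.
#' @param format Either \code{"edgelist"} or \code{"adjacency"}.
#' @return Invisibly, \code{path}.
#' @export
writeGraph <- function(graph, path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  stopifnot(is(graph, "LabeledGraph"))
  m <- graph@adjacency
  if (format == "edgelist") {
    idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    labs <- rownames(m)
    w <- m[idx]
    if (all(w == 1))
      lines <- paste(labs[idx[, 1L]], labs[idx[, 2L]], sep = "\t")
    else
      lines <- paste(labs[idx[, 1L]], labs[idx[, 2L]],
                     sprintf("%.17g", w), sep = "\t")
    writeLines(lines, path)
  } else {
    df <- data.frame(node = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Align two graphs onto one shared ordered node set
#'
#' The GHD framework compares networks defined on an identical node set.
#' \code{alignPair} checks that the label sets agree and reindexes both
#' graphs to the canonical (lexicographically sorted) label order, which all
#' downstream node indexing refers to.
#'
#' @param g1,g2 [LabeledGraph-class] objects with equal label sets.
#' @return A list with elements \code{g1} and \code{g2}, both reordered.
#' @export
alignPair <- function(g1, g2) {
  stopifnot(is(g1, "LabeledGraph"), is(g2, "LabeledGraph"))
  l1 <- nodeLabels(g1)
  l2 <- nodeLabels(g2)
  if (!setequal(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("graphs are not on the same node set; symmetric difference: {",
         paste(sort(diff), collapse = ", "), "}")
  }
  ord <- sort(l1)
  list(g1 = LabeledGraph(g1@adjacency[ord, ord, drop = FALSE]),
       g2 = LabeledGraph(g2@adjacency[ord, ord, drop = FALSE]))
}

#' Write a differential analysis result as TSV
#'
#' One row per node, in removal order with survivors last: columns
#' \code{node}, \code{removal_order}, \code{phase}, \code{ghd}, \code{mu_pi},
#' \code{sigma_pi}, \code{z}, \code{p_value}, \code{p_adjusted},
#' \code{differential} (0/1). Numeric fields keep full double precision.
#'
#' @param result A [DiffNetResult-class] with every node populated.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeResult <- function(result, path) {
  stopifnot(is(result, "DiffNetResult"))
  tab <- result@table
  if (!nrow(tab)) stop("empty result: nothing to write")
  out <- tab
  out$differential <- as.integer(out$differential)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [writeResult()]
#'
#' @param path Path to the TSV.
#' @return A data.frame with the same columns and types as the node table of
#'   a [DiffNetResult-class].
#' @export
readResult <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(node = "character"))
  df$differential <- as.logical(df$differential)
  df$phase <- as.character(df$phase)
  df
}
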