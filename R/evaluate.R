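# Evaluation against a planted gold standard: confusion counts, threshold
# metrics with Cohen's kappa, ROC/PR curves with AUCs, the multi-run
# benchmark harness and the theta-sensitivity profile.

#' Confusion counts of a differential call
#'
#' Standard 2x2 counts with the gold-standard nodes as positives.
#'
#' @param predicted Character vector of nodes called differential.
#' @param gold Character vector of truly differential nodes.
#' @param universe All node labels.
#' @return Named list with \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
confusionCounts <- function(predicted, gold, universe) {
  bad <- setdiff(c(predicted, gold), universe)
  if (length(bad))
    stop("nodes outside the universe: ", paste(bad, collapse = ", "))
  pred <- universe %in% predicted
  pos <- universe %in% gold
  list(tp = sum(pred & pos), fp = sum(pred & !pos),
       fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Threshold classification metrics
#'
#' Precision, recall (= TPR), accuracy, specificity and Cohen's kappa from a
#' 2x2 confusion table. Kappa is \eqn{(p_o - p_e)/(1 - p_e)} with observed
#' agreement \eqn{p_o} = accuracy and \eqn{p_e} the marginal chance
#' agreement. Ratios with zero denominators are reported as 0.
#'
#' @param counts List with \code{tp}, \code{fp}, \code{fn}, \code{tn} (see
#'   [confusionCounts()]).
#' @return Named list with the counts plus \code{precision}, \code{recall},
#'   \code{accuracy}, \code{specificity}, \code{kappa}.
#' @examples
#' classificationMetrics(list(tp = 90, fp = 10, fn = 10, tn = 890))
#' @export
classificationMetrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  n <- tp + fp + fn + tn
  if (n == 0) stop("all-zero confusion counts")
  rat <- function(num, den) if (den > 0) num / den else 0
  acc <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = rat(tp, tp + fp), recall = rat(tp, tp + fn),
       accuracy = acc, specificity = rat(tn, tn + fp), kappa = kappa)
}

#' ROC and precision-recall curves over a node ranking
#'
#' Sweeps all thresholds of a per-node score (higher = more differential).
#' \code{auc_roc} is the Mann-Whitney probability that a random gold node
#' outranks a random background node, with ties counted 1/2; \code{auc_pr}
#' integrates the PR step curve with precision held constant to the right of
#' each recall increment (no linear interpolation).
#'
#' @param score Named numeric vector of scores covering every node in
#'   \code{universe}.
#' @param gold Character vector of truly differential nodes (non-empty,
#'   proper subset of the universe).
#' @param universe All node labels.
#' @return List with \code{roc} (data.frame fpr/tpr), \code{pr} (data.frame
#'   recall/precision), \code{auc_roc}, \code{auc_pr}.
#' @export
rocPr <- function(score, gold, universe) {
  if (!all(universe %in% names(score)))
    stop("score must be defined for every node in the universe")
  if (length(gold) == 0 || length(gold) >= length(universe))
    stop("gold must be a non-empty proper subset of the universe")
  s <- score[universe]
  pos <- universe %in% gold
  np <- sum(pos); nn <- sum(!pos)

  r <- rank(s, ties.method = "average")
  auc_roc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)

  # step curves: process tied scores as one block, best scores first
  o <- order(-s)
  sv <- s[o]; pv <- pos[o]
  grp <- cumsum(!duplicated(sv))
  tp <- cumsum(pv); fp <- cumsum(!pv)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  prec <- tp / (tp + fp); rec <- tp / np
  d_rec <- diff(c(0, rec))
  auc_pr <- sum(d_rec * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = c(0, rec), precision = c(prec[1], prec)),
       auc_roc = auc_roc, auc_pr = auc_pr)
}

.eval_one <- function(result, gold, universe, alpha) {
  called <- callDifferential(result, alpha)
  m <- classificationMetrics(confusionCounts(called, gold, universe))
  cur <- rocPr(differentialScore(result), gold, universe)
  c(m[c("precision", "recall", "accuracy", "specificity", "kappa")],
    list(auc_roc = cur$auc_roc, auc_pr = cur$auc_pr,
         tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn))
}

.method_fun <- function(method, theta, alpha, min_size) {
  switch(method,
    closed_form = , cf = function(Wa, Wb)
      closedForm(Wa, Wb, theta = theta, alpha = alpha, min_size = min_size),
    fast_approx = , fa = function(Wa, Wb)
      fastApproximation(Wa, Wb, theta = theta, alpha = alpha,
                        min_size = min_size),
    dghd = function(Wa, Wb)
      dghdBaseline(Wa, Wb, alpha = alpha, min_size = min_size),
    stop("unknown method: ", method))
}

.canon_method <- function(m) {
  out <- c(cf = "closed_form", fa = "fast_approx", closed_form = "closed_form",
           fast_approx = "fast_approx", dghd = "dghd")[m]
  if (anyNA(out)) stop("unknown method: ", paste(m[is.na(out)], collapse = ", "))
  unname(out)
}

#' Multi-run simulation benchmark
#'
#' Repeats a benchmark \code{n_runs} times (run r uses seed
#' \code{base_seed + r}), runs each detection method on the cosine (or
#' topological-overlap) connectivity of the instance, and evaluates the
#' calls against the planted gold standard: threshold metrics at
#' \code{alpha}, AUCs from the adjusted-p node ranking.
#'
#' @param spec A [simulationSpec()]; its seed field is ignored in favour of
#'   the per-run seeds.
#' @param methods Character vector among \code{"closed_form"}/\code{"cf"},
#'   \code{"fast_approx"}/\code{"fa"}, \code{"dghd"}.
#' @param n_runs Number of runs (>= 2).
#' @param base_seed Integer; run r uses seed \code{base_seed + r}.
#' @param alpha Differential-call cut-off.
#' @param theta Phase-switch threshold for the two-phase methods.
#' @param weight Connectivity measure, \code{"cosine"} or \code{"to"}.
#' @param min_size Smallest sub-network considered.
#' @param file Optional path: the summary table is written there as CSV.
#' @return List with \code{runs} (per-run data.frame) and \code{summary}
#'   (mean and sd of every metric per method).
#' @examples
#' spec <- simulationSpec("rg_permuted", N = 100, d = 0.2, k = 20, seed = 1)
#' runBenchmark(spec, "cf", n_runs = 2, base_seed = 100)$summary
#' @export
runBenchmark <- function(spec, methods = c("closed_form", "dghd"),
                         n_runs = 20L, base_seed = 1L, alpha = 0.01,
                         theta = 1e-50, weight = c("cosine", "to"),
                         min_size = 4L, file = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"))
  weight <- match.arg(weight)
  if (n_runs < 2L) stop("n_runs must be at least 2")
  methods <- .canon_method(methods)
  conn <- if (weight == "cosine") cosineConnectivity else topologicalOverlap
  rows <- list()
  for (r in seq_len(n_runs)) {
    rspec <- spec
    rspec$seed <- as.integer(base_seed + r)
    inst <- makeInstance(rspec)
    Wa <- conn(inst$graph_a)
    Wb <- conn(inst$graph_b)
    universe <- nodeLabels(inst$graph_a)
    for (m in methods) {
      res <- .method_fun(m, theta, alpha, min_size)(Wa, Wb)
      ev <- .eval_one(res, inst$gold, universe, alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(run = r, seed = rspec$seed, method = m,
                   as.data.frame(ev), stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  metric_cols <- c("auc_roc", "auc_pr", "precision", "recall", "accuracy",
                   "specificity", "kappa")
  summ <- do.call(rbind, lapply(split(runs, runs$method), function(d) {
    out <- data.frame(method = d$method[1L])
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(d[[mc]])
      out[[paste0(mc, "_sd")]] <- stats::sd(d[[mc]])
    }
    out
  }))
  rownames(summ) <- NULL
  if (!is.null(file))
    utils::write.csv(summ, file, row.names = FALSE)
  list(runs = runs, summary = summ)
}

#' Sensitivity of the Closed-Form detection to theta
#'
#' For every theta on the grid, reruns the Closed-Form analysis on
#' freshly generated instances (run r uses seed \code{base_seed + r}) and
#' records the true-positive rate of the differential call at \code{alpha}.
#' Instances are generated once per run and reused across the grid.
#'
#' @param spec A [simulationSpec()].
#' @param theta_grid Numeric vector of thresholds in (0, 1).
#' @param n_runs Runs per theta.
#' @param base_seed Integer.
#' @param alpha Differential-call cut-off.
#' @param weight Connectivity measure.
#' @return data.frame with columns \code{theta}, \code{run}, \code{tpr}.
#' @export
thetaSensitivity <- function(spec, theta_grid, n_runs = 25L, base_seed = 1L,
                             alpha = 0.01, weight = c("cosine", "to")) {
  stopifnot(inherits(spec, "SimulationSpec"))
  weight <- match.arg(weight)
  if (any(theta_grid <= 0 | theta_grid >= 1))
    stop("theta grid values must lie in (0, 1)")
  conn <- if (weight == "cosine") cosineConnectivity else topologicalOverlap
  rows <- list()
  for (r in seq_len(n_runs)) {
    rspec <- spec
    rspec$seed <- as.integer(base_seed + r)
    inst <- makeInstance(rspec)
    Wa <- conn(inst$graph_a)
    Wb <- conn(inst$graph_b)
    universe <- nodeLabels(inst$graph_a)
    for (th in theta_grid) {
      res <- closedForm(Wa, Wb, theta = th, alpha = alpha)
      cm <- confusionCounts(callDifferential(res, alpha), inst$gold, universe)
      rows[[length(rows) + 1L]] <-
        data.frame(theta = th, run = r,
                   tpr = cm$tp / (cm$tp + cm$fn))
    }
  }
  do.call(rbind, rows)
}
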