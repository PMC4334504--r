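#' Discretization rule for continuous features
#'
#' The information-gain-ratio entropies are defined over discrete value
#' sets, so continuous features are binned first. The default is 10-bin
#' equal-frequency binning (bin edges at empirical quantiles), which is
#' robust to skewed feature distributions; equal-width binning is
#' available. Constant features collapse to a single bin.
#'
#' @param bins Number of bins (default 10).
#' @param strategy `"equal_frequency"` (default) or `"equal_width"`.
#' @return An object of class `discretization_rule`.
#' @export
discretization_rule <- function(bins = 10L, strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  stopifnot(bins >= 2L)
  structure(list(bins = as.integer(bins), strategy = strategy),
            class = "discretization_rule")
}

## Interior bin edges (strictly increasing, possibly empty) for one feature.
bin_edges <- function(values, rule) {
  if (rule$strategy == "equal_frequency") {
    qs <- stats::quantile(values, probs = seq_len(rule$bins - 1L) / rule$bins,
                          names = FALSE, type = 7)
    unique(qs)
  } else {
    lo <- min(values); hi <- max(values)
    if (lo == hi) return(numeric(0))
    seq(lo, hi, length.out = rule$bins + 1L)[-c(1L, rule$bins + 1L)]
  }
}

## Map values to integer bin ids using interior edges.
discretize <- function(values, edges) {
  if (length(edges) == 0L) return(rep(1L, length(values)))
  findInterval(values, edges, left.open = TRUE) + 1L
}

#' Information gain ratio of one feature
#'
#' `IGR = (H(C) - H(C|F)) / H(F)` with base-2 entropies: `H(C)` the class
#' entropy, `H(C|F)` the class entropy conditional on the discretized
#' feature value, and `H(F)` the feature's own entropy. A constant feature
#' (`H(F) = 0`) scores 0 by convention. The score lies in \[0, 1\].
#'
#' @param values Numeric feature values.
#' @param labels Binary labels (two classes present, else an error —
#'   ranking is meaningless when the class entropy is zero).
#' @param rule A [discretization_rule()].
#' @return IGR score in \[0, 1\].
#' @export
igr_score <- function(values, labels, rule = discretization_rule()) {
  labels <- as.character(labels)
  if (length(values) != length(labels)) stop("values and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; information gain ratio is undefined", call. = FALSE)
  }
  bins <- discretize(values, bin_edges(values, rule))
  igr_discrete(bins, labels)
}

## IGR on an already-discrete feature vector.
igr_discrete <- function(bins, labels) {
  n <- length(bins)
  h_c <- shannon(as.numeric(table(labels)) / n)
  p_v <- table(bins) / n
  h_f <- shannon(as.numeric(p_v))
  if (h_f == 0) return(0)
  h_c_given_f <- 0
  for (v in names(p_v)) {
    sub <- labels[bins == as.integer(v)]
    h_c_given_f <- h_c_given_f + as.numeric(p_v[v]) * shannon(as.numeric(table(sub)) / length(sub))
  }
  max(0, min(1, (h_c - h_c_given_f) / h_f))
}

#' Rank all features by information gain ratio
#'
#' Scores every column of a labeled feature matrix with [igr_score()] and
#' sorts descending. Ties keep the canonical column order (stable sort), so
#' the ranking is deterministic.
#'
#' @param fm A labeled [feature_matrix()].
#' @param rule A [discretization_rule()].
#' @return Data frame with columns `feature`, `igr`, in rank order.
#' @export
rank_features <- function(fm, rule = discretization_rule()) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled", call. = FALSE)
  labels <- as.character(fm$labels)
  scores <- apply(fm$x, 2L, igr_score, labels = labels, rule = rule)
  ord <- order(-scores)  # radix sort: stable, preserving column order on ties
  data.frame(feature = colnames(fm$x)[ord], igr = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Incremental feature selection
#'
#' Walks the IGR ranking from the top, evaluating the prefix of size k =
#' `step`, `2*step`, ..., d with a caller-supplied evaluator (typically
#' cross-validated training of the undersampling ensemble via
#' [cv_evaluator()]), and selects the smallest prefix whose balanced
#' accuracy is within `delta` of the best over all evaluated prefixes —
#' trading a tolerated 0.001-scale drop in balanced accuracy for a lower
#' dimension.
#'
#' @param fm A labeled [feature_matrix()].
#' @param ranking Ranking from [rank_features()].
#' @param evaluator Function(feature names) returning a named list/vector
#'   with components `sn`, `sp`, `acc`, `bacc`.
#' @param delta Tolerated drop from the maximal balanced accuracy
#'   (default 0.001).
#' @param step Prefix-size stride (default 1; larger strides coarsen the
#'   scan).
#' @return An object of class `ifs_trace`: list with `trace` (data frame of
#'   k, sn, sp, acc, bacc), `selected_k`, `selected_features`, `delta`.
#' @export
ifs_select <- function(fm, ranking, evaluator, delta = 0.001, step = 1L) {
  d <- nrow(ranking)
  ks <- unique(c(seq(step, d, by = step), d))
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    feats <- ranking$feature[seq_len(k)]
    m <- tryCatch(evaluator(feats), error = function(e) {
      stop(sprintf("IFS evaluator failed at prefix size %d: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[i]] <- data.frame(k = k, sn = m$sn, sp = m$sp, acc = m$acc, bacc = m$bacc)
  }
  trace <- do.call(rbind, rows)
  best <- max(trace$bacc)
  selected_k <- trace$k[which(trace$bacc >= best - delta)[1L]]
  structure(list(trace = trace, selected_k = selected_k,
                 selected_features = ranking$feature[seq_len(selected_k)],
                 delta = delta),
            class = "ifs_trace")
}

#' @export
print.ifs_trace <- function(x, ...) {
  cat(sprintf("<ifs_trace> %d prefixes evaluated; selected k = %d (BAcc %.4f, delta %.4g)\n",
              nrow(x$trace), x$selected_k,
              x$trace$bacc[match(x$selected_k, x$trace$k)], x$delta))
  invisible(x)
}

#' Cross-validation evaluator for incremental feature selection
#'
#' Builds the evaluator closure [ifs_select()] expects: for a candidate
#' feature subset it runs [stratified_cv()] on the given matrix and returns
#' the pooled metrics. The same seed is used for every prefix so traces are
#' reproducible and prefixes are compared on identical folds.
#'
#' @param fm A labeled [feature_matrix()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed.
#' @param rf_params Forest parameters, see [rf_params()].
#' @param ensemble Use the undersampling ensemble within each fold
#'   (default `TRUE`).
#' @return Function(features) -> list(sn, sp, acc, bacc).
#' @export
cv_evaluator <- function(fm, folds = 10L, seed = 1L, rf_params = NULL,
                         ensemble = TRUE) {
  force(fm); force(folds); force(seed); force(rf_params); force(ensemble)
  function(features) {
    m <- stratified_cv(fm, folds = folds, seed = seed, feature_subset = features,
                       rf_params = rf_params, ensemble = ensemble)
    list(sn = m$sn, sp = m$sp, acc = m$acc, bacc = m$bacc)
  }
}
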