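#' Random-forest parameters
#'
#' Defaults mirror the classic WEKA-era forest defaults: 10 trees,
#' unlimited depth, and `floor(log2(d)) + 1` candidate features per split
#' (applied at training time from the actual feature count d when `mtry`
#' is `NULL`).
#'
#' @param ntree Number of trees per forest member (default 10).
#' @param mtry Candidate features per split; `NULL` means
#'   `floor(log2(d)) + 1`.
#' @return An object of class `rf_params`.
#' @export
rf_params <- function(ntree = 10L, mtry = NULL) {
  stopifnot(ntree >= 1L)
  structure(list(ntree = as.integer(ntree), mtry = mtry), class = "rf_params")
}

default_rf_params <- function(p) if (is.null(p)) rf_params() else p

resolve_mtry <- function(params, d) {
  if (!is.null(params$mtry)) return(as.integer(params$mtry))
  max(1L, min(d, floor(log2(d)) + 1L))
}

#' Partition the majority class into undersampled training subsets
#'
#' Implements the undersampling scheme for imbalanced training: the
#' negatives are shuffled and split into `K = round(|neg| / |pos|)`
#' (minimum 1) near-equal groups (sizes differing by at most one), and each
#' group is paired with *all* positives to form one training subset. Every
#' negative appears in exactly one subset; with 410 positives and 4464
#' negatives this yields K = 11.
#'
#' @param pos_ids,neg_ids Sample ids of each class (non-empty).
#' @param seed Integer seed controlling the negative shuffle.
#' @return List of K character vectors of sample ids.
#' @export
make_undersampled_subsets <- function(pos_ids, neg_ids, seed = 1L) {
  if (length(pos_ids) == 0L || length(neg_ids) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  undersampled_subsets(pos_ids, neg_ids, seed,
                       max(1L, as.integer(round(length(neg_ids) / length(pos_ids)))))
}

## Shared partition core; `k` is forced to 1 by the single-forest baseline
## so that a one-member ensemble and a single forest are the same code path.
undersampled_subsets <- function(pos_ids, neg_ids, seed, k) {
  shuffled <- with_seed(seed, sample(neg_ids))
  base <- length(neg_ids) %/% k
  extra <- length(neg_ids) %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i) c(pos_ids, shuffled[starts[i]:stops[i]]))
}

## Train one forest on a row subset of a labeled matrix.
train_member <- function(fm, ids, features, seed, params) {
  x <- fm$x[ids, features, drop = FALSE]
  y <- droplevels(fm$labels[match(ids, rownames(fm$x))])
  if (nlevels(y) < 2L) stop("training subset contains a single class", call. = FALSE)
  y <- factor(as.character(y), levels = c("positive", "negative"))
  with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = params$ntree, mtry = resolve_mtry(params, ncol(x))
  ))
}

#' Train the undersampling random-forest ensemble
#'
#' Builds the K undersampled training subsets with
#' [make_undersampled_subsets()] and trains one random forest per subset on
#' the requested feature columns. With balanced input (K = 1) the ensemble
#' reduces exactly to a single forest.
#'
#' @param fm A labeled [feature_matrix()].
#' @param feature_subset Feature names to train on; default all columns.
#' @param seed Integer seed (negative partition and tree randomness).
#' @param rf_params A [rf_params()] or `NULL` for defaults.
#' @param k_members Override the member count derived from the class ratio
#'   (used by [single_forest()] to force a one-member, no-undersampling
#'   baseline; `NULL` applies the `round(|neg|/|pos|)` rule).
#' @return An object of class `ensemble_model`: list with `members`,
#'   `features`, `seed`, `tie_rule`, `rf_params`.
#' @export
train_ensemble <- function(fm, feature_subset = colnames(fm$x), seed = 1L,
                           rf_params = NULL, k_members = NULL) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled", call. = FALSE)
  missing <- setdiff(feature_subset, colnames(fm$x))
  if (length(missing) > 0L) {
    stop(sprintf("unknown feature '%s'", missing[1L]), call. = FALSE)
  }
  params <- default_rf_params(rf_params)
  ids <- rownames(fm$x)
  pos <- ids[fm$labels == "positive"]
  neg <- ids[fm$labels == "negative"]
  subsets <- if (is.null(k_members)) {
    make_undersampled_subsets(pos, neg, seed)
  } else {
    undersampled_subsets(pos, neg, seed, as.integer(k_members))
  }
  members <- lapply(seq_along(subsets), function(k) {
    train_member(fm, subsets[[k]], feature_subset, seed + k, params)
  })
  structure(list(members = members, features = feature_subset, seed = seed,
                 tie_rule = "positive", rf_params = unclass(params)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d forest member(s), %d features, seed %d\n",
              length(x$members), length(x$features), x$seed))
  invisible(x)
}

#' Majority-vote prediction
#'
#' Each ensemble member votes a class for every sample; the predicted label
#' is the class with the most votes. An even split (possible only for even
#' K) goes to the positive class — a documented convention that favors
#' minority-class recall; the reference configuration K = 11 cannot tie.
#'
#' @param model An `ensemble_model`.
#' @param fm A [feature_matrix()] whose columns include the model features.
#' @return Data frame with columns `id`, `label` (factor
#'   positive/negative), `votes_positive`, `votes_negative`.
#' @export
predict_vote <- function(model, fm) {
  missing <- setdiff(model$features, colnames(fm$x))
  if (length(missing) > 0L) {
    stop(sprintf("input is missing model feature '%s'", missing[1L]), call. = FALSE)
  }
  x <- fm$x[, model$features, drop = FALSE]
  votes <- vapply(model$members, function(m) {
    as.character(stats::predict(m, newdata = x))
  }, character(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  vp <- rowSums(votes == "positive")
  vn <- rowSums(votes == "negative")
  label <- ifelse(vp >= vn, "positive", "negative")  # ties -> positive
  data.frame(id = rownames(fm$x),
             label = factor(label, levels = c("positive", "negative")),
             votes_positive = vp, votes_negative = vn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `Sn = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)`,
#' accuracy `Acc = (TP + TN) / n` and balanced accuracy
#' `BAcc = (Sn + Sp) / 2` — the headline metric for imbalanced evaluation.
#' When the truth contains no positives (or no negatives) the affected
#' rates are reported as `NA`, an explicit undefined marker, never a
#' silent 0.
#'
#' @param truth,predicted Equal-length label vectors over
#'   \{"positive", "negative"\}.
#' @return An object of class `metrics_report`: list with `tp`, `tn`,
#'   `fp`, `fn`, `sn`, `sp`, `acc`, `bacc`.
#' @export
compute_metrics <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted labels differ in length", call. = FALSE)
  }
  tp <- sum(truth == "positive" & predicted == "positive")
  tn <- sum(truth == "negative" & predicted == "negative")
  fp <- sum(truth == "negative" & predicted == "positive")
  fn <- sum(truth == "positive" & predicted == "negative")
  sn <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  acc <- (tp + tn) / length(truth)
  bacc <- if (is.na(sn) || is.na(sp)) NA_real_ else (sn + sp) / 2
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sn = sn, sp = sp, acc = acc, bacc = bacc),
            class = "metrics_report")
}

#' @rdname compute_metrics
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  compute_metrics(
    truth = rep(c("positive", "negative"), c(tp + fn, tn + fp)),
    predicted = rep(c("positive", "negative", "negative", "positive"),
                    c(tp, fn, tn, fp))
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP %d FN %d TN %d FP %d | Sn %.3f Sp %.3f Acc %.3f BAcc %.3f\n",
              x$tp, x$fn, x$tn, x$fp, x$sn, x$sp, x$acc, x$bacc))
  invisible(x)
}

## Assign each id to one of `folds` near-equal folds, shuffled by the
## current RNG state.
fold_assignment <- function(ids, folds) {
  shuffled <- sample(ids)
  split(shuffled, rep_len(seq_len(folds), length(shuffled)))
}

#' Stratified k-fold cross-validation
#'
#' Positives and negatives are independently split into `folds` near-equal
#' parts; fold f tests on positive part f plus negative part f and trains
#' on the rest — via the undersampling ensemble by default, or a single
#' forest on the full (imbalanced) training rows with `ensemble = FALSE`.
#' Test predictions from all folds are pooled into one confusion matrix
#' before computing metrics.
#'
#' @param fm A labeled [feature_matrix()]; each class needs at least
#'   `folds` members.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (fold assignment and training randomness).
#' @param feature_subset Feature names to use; default all.
#' @param rf_params A [rf_params()] or `NULL`.
#' @param ensemble Train the undersampling ensemble in each fold
#'   (default `TRUE`); `FALSE` trains one forest per fold.
#' @return A `metrics_report` over the pooled predictions, with the
#'   per-fold trace in attribute `folds`.
#' @export
stratified_cv <- function(fm, folds = 10L, seed = 1L,
                          feature_subset = colnames(fm$x), rf_params = NULL,
                          ensemble = TRUE) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled", call. = FALSE)
  ids <- rownames(fm$x)
  pos <- ids[fm$labels == "positive"]
  neg <- ids[fm$labels == "negative"]
  if (length(pos) < folds || length(neg) < folds) {
    stop(sprintf("each class needs at least %d samples for %d-fold CV", folds, folds),
         call. = FALSE)
  }
  assign_folds <- with_seed(seed, list(pos = fold_assignment(pos, folds),
                                       neg = fold_assignment(neg, folds)))
  truth_all <- character(0)
  pred_all <- character(0)
  fold_trace <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_ids <- c(assign_folds$pos[[f]], assign_folds$neg[[f]])
    train_ids <- setdiff(ids, test_ids)
    train_fm <- feature_matrix(fm$x[train_ids, , drop = FALSE],
                               as.character(fm$labels[match(train_ids, ids)]))
    test_fm <- feature_matrix(fm$x[test_ids, , drop = FALSE])
    model <- if (ensemble) {
      train_ensemble(train_fm, feature_subset, seed = seed * 1000L + f,
                     rf_params = rf_params)
    } else {
      single_forest(train_fm, feature_subset, seed = seed * 1000L + f,
                    rf_params = rf_params)
    }
    pred <- predict_vote(model, test_fm)
    truth_f <- as.character(fm$labels[match(test_ids, ids)])
    truth_all <- c(truth_all, truth_f)
    pred_all <- c(pred_all, as.character(pred$label))
    fold_trace[[f]] <- compute_metrics(truth_f, as.character(pred$label))
  }
  out <- compute_metrics(truth_all, pred_all)
  attr(out, "folds") <- fold_trace
  out
}

#' Train a single forest (no undersampling) as a one-member ensemble
#'
#' Baseline against which the undersampling ensemble is compared: one
#' forest trained on all rows regardless of class balance.
#'
#' @inheritParams train_ensemble
#' @return An `ensemble_model` with one member.
#' @export
single_forest <- function(fm, feature_subset = colnames(fm$x), seed = 1L,
                          rf_params = NULL) {
  train_ensemble(fm, feature_subset, seed, rf_params, k_members = 1L)
}

#' Class-imbalance ratio sweep
#'
#' Reproduces the imbalance-pathology experiment: for each ratio r, build
#' `repeats` datasets holding all positives plus `r * n_pos` randomly drawn
#' negatives, evaluate each by stratified cross-validation with a *single*
#' forest (no undersampling — the sweep isolates the effect of imbalance),
#' and average the metrics over repeats. As r grows, specificity and
#' accuracy inflate while sensitivity collapses, which is why balanced
#' accuracy is the operative metric and why the undersampling ensemble
#' trains at an effective 1:1 ratio.
#'
#' @param fm A labeled [feature_matrix()] with at least
#'   `max(ratios) * n_pos` negatives.
#' @param ratios Negative:positive ratios to scan (default 1:10).
#' @param repeats Random redraws per ratio (default 10).
#' @param seed Integer seed.
#' @param folds CV folds per evaluation (default 10).
#' @param rf_params A [rf_params()] or `NULL`.
#' @return Data frame, one row per ratio: `ratio`, `sn`, `sp`, `acc`,
#'   `bacc` (means over repeats), plus `repeats`.
#' @export
ratio_sweep <- function(fm, ratios = 1:10, repeats = 10L, seed = 1L,
                        folds = 10L, rf_params = NULL) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled", call. = FALSE)
  ids <- rownames(fm$x)
  pos <- ids[fm$labels == "positive"]
  neg <- ids[fm$labels == "negative"]
  need <- max(ratios) * length(pos)
  if (length(neg) < need) {
    stop(sprintf("ratio sweep needs >= %d negatives (have %d)", need, length(neg)),
         call. = FALSE)
  }
  rows <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    reps <- matrix(NA_real_, nrow = repeats, ncol = 4L,
                   dimnames = list(NULL, c("sn", "sp", "acc", "bacc")))
    for (rep_i in seq_len(repeats)) {
      sub_seed <- seed + 97L * i + rep_i
      neg_draw <- with_seed(sub_seed, sample(neg, r * length(pos)))
      keep <- c(pos, neg_draw)
      sub <- feature_matrix(fm$x[keep, , drop = FALSE],
                            as.character(fm$labels[match(keep, ids)]))
      m <- stratified_cv(sub, folds = folds, seed = sub_seed,
                         rf_params = rf_params, ensemble = FALSE)
      reps[rep_i, ] <- c(m$sn, m$sp, m$acc, m$bacc)
    }
    rows[[i]] <- data.frame(ratio = r, t(colMeans(reps)), repeats = repeats)
  }
  do.call(rbind, rows)
}
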