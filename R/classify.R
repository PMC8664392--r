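#' Balanced random subsets of an unbalanced cohort
#'
#' Each subset contains every minority-class patient plus an equal-sized
#' random draw of majority-class patients (without replacement within a
#' subset). Majority patients are consumed in a shuffled cyclic order so the
#' union of the subsets covers the whole majority class. With balanced input
#' the single subset is the full cohort.
#'
#' @param labels Character vector "R"/"NR".
#' @param n_subsets Number of subsets; default ceiling(n_major/n_minor).
#' @param seed Integer seed.
#' @return List of integer index vectors (rows of the cohort).
#' @export
balance_subsets <- function(labels, n_subsets = NULL, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2L || any(tab < 2L)) {
    stop("labels must contain two classes with at least 2 patients each")
  }
  minor <- names(tab)[which.min(tab)]
  idx_min <- which(labels == minor)
  idx_maj <- which(labels != minor)
  n_min <- length(idx_min)
  if (is.null(n_subsets)) n_subsets <- ceiling(length(idx_maj) / n_min)
  set.seed(seed)
  shuffled <- sample(idx_maj)
  cyc <- rep(shuffled, length.out = n_subsets * n_min)
  lapply(seq_len(n_subsets), function(s) {
    take <- cyc[((s - 1L) * n_min + 1L):(s * n_min)]
    sort(c(idx_min, unique(take)))
  })
}

# deterministic k-nearest-neighbour score: fraction of the k nearest
# training points labelled positive; distance ties broken by row order
.knn_score <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1, function(p) {
    d <- sqrt(colSums((t(train_x) - p)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    mean(train_y[nn] == "R")
  })
}

# SVM-RBF decision score oriented so larger = more recurrence-like
.svm_score <- function(train_x, train_y, test_x, cost) {
  y <- factor(train_y, levels = c("R", "NR"))
  gam <- 1 / (ncol(train_x) * mean(apply(train_x, 2, stats::var)))
  fit <- e1071::svm(train_x, y, kernel = "radial", cost = cost,
                    gamma = gam, scale = FALSE)
  pr <- stats::predict(fit, test_x, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # decision value is positive for the first level of the column label
  if (grepl("^R/", colnames(attr(pr, "decision.values"))[1])) dv else -dv
}

.fold_standardize <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  s <- apply(train_x, 2, stats::sd)
  s[s == 0] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, s, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, s, "/"))
}

#' Rank-statistic AUC from continuous scores
#'
#' Mann-Whitney form with midranks, so ties contribute 1/2.
#' @param scores Numeric scores, larger = more positive.
#' @param y Labels, positive class "R".
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, y) {
  pos <- y == "R"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated classifier report
#'
#' For each patient the classifier is trained on all others (features
#' z-scored on the training fold only) and the held-out patient is scored.
#' Predictions use a score threshold of 1/2 (KNN vote fraction) or 0 (SVM
#' decision value). The report aggregates the confusion matrix with
#' recurrence as the positive class, sensitivity/specificity/accuracy in
#' percent, the rank-statistic AUC of the held-out scores, and the
#' per-patient predictions.
#'
#' @param features Feature data.frame or matrix.
#' @param labels Character vector "R"/"NR".
#' @param selected Character vector of feature columns to use (1-3).
#' @param kind "knn" or "svm".
#' @param config A `qus_config()` list (knn_k, svm_cost).
#' @return An object of class `classifier_report`.
#' @export
loocv_evaluate <- function(features, labels, selected, kind = "knn",
                           config = qus_config()) {
  if (length(selected) == 0L) stop("no features selected")
  X <- as.matrix(features[, selected, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.character(labels)
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr_y <- y[-i]
    if (length(unique(tr_y)) < 2L) stop("training fold has a single class")
    st <- .fold_standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    scores[i] <- if (kind == "knn") {
      .knn_score(st$train, tr_y, st$test, config$knn_k)
    } else {
      .svm_score(st$train, tr_y, st$test, config$svm_cost)
    }
  }
  thr <- if (kind == "knn") 0.5 else 0
  pred <- ifelse(scores >= thr, "R", "NR")
  tp <- sum(pred == "R" & y == "R"); fn <- sum(pred == "NR" & y == "R")
  tn <- sum(pred == "NR" & y == "NR"); fp <- sum(pred == "R" & y == "NR")
  structure(
    list(kind = kind, selected = selected,
         confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         accuracy = 100 * (tp + tn) / n,
         auc = auc_rank(scores, y),
         scores = scores, predicted = pred),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s classifier | features: %s\n", toupper(x$kind),
              paste(x$selected, collapse = " ")))
  cat(sprintf("sens %.0f%%  spec %.0f%%  acc %.0f%%  AUC %.2f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  invisible(x)
}

#' Greedy forward feature selection over balanced subsets
#'
#' At each round the feature whose addition maximizes the mean LOOCV
#' accuracy across the balanced subsets is added; selection stops at
#' `max_features` (default 3, to limit overfitting) or when no candidate
#' improves the criterion. Ties go to the earlier catalog column.
#'
#' @param features Feature data.frame (patient_id optional).
#' @param labels Character vector "R"/"NR".
#' @param kind "knn" or "svm".
#' @param config A `qus_config()` list.
#' @param pool Character vector of candidate feature names (default: all
#'   non-id columns).
#' @param seed Seed for the balanced subsets.
#' @return List: `selected`, `trace` (data.frame round/feature/criterion),
#'   `subsets`.
#' @export
forward_select <- function(features, labels, kind = "knn",
                           config = qus_config(), pool = NULL, seed = 1L) {
  labels <- as.character(labels)
  if (min(table(labels)) < 4L) stop("need at least 4 patients per class")
  cols <- setdiff(colnames(features), "patient_id")
  if (is.null(pool)) pool <- cols
  stopifnot(all(pool %in% cols))
  subsets <- balance_subsets(labels, config$n_subsets, seed = seed)

  crit <- function(sel) {
    mean(vapply(subsets, function(ss) {
      loocv_evaluate(features[ss, , drop = FALSE], labels[ss], sel,
                     kind, config)$accuracy
    }, numeric(1)))
  }
  selected <- character(0)
  best_val <- -Inf
  trace <- NULL
  for (round in seq_len(config$max_features)) {
    cand <- setdiff(pool, selected)
    vals <- vapply(cand, function(fc) crit(c(selected, fc)), numeric(1))
    i <- which.max(vals)
    if (vals[i] <= best_val) break
    best_val <- vals[i]
    selected <- c(selected, cand[i])
    trace <- rbind(trace, data.frame(round = round, feature = cand[i],
                                     criterion = vals[i],
                                     stringsAsFactors = FALSE))
  }
  list(selected = selected, trace = trace, subsets = subsets)
}

#' Feature pools for the classification protocol
#'
#' `qus_tex1`: spectral + first-pass texture (7 + 24); `all`: the full
#' 95-feature catalog.
#' @param pool "qus_tex1" or "all".
#' @return Character vector of feature names.
#' @export
feature_pool <- function(pool = c("all", "qus_tex1")) {
  pool <- match.arg(pool)
  catalog <- feature_catalog()
  tier <- attr(catalog, "tier")
  if (pool == "all") as.character(catalog)
  else as.character(catalog[tier %in% c("spectral", "tex1")])
}

#' Run the full classification protocol
#'
#' Both classifiers (KNN and SVM-RBF) on both feature pools (spectral +
#' first-pass texture, and all 95 features): forward selection of at most 3
#' features on balanced subsets, then one LOOCV report over the full cohort
#' with the selected features. Per-patient predicted groups are kept for
#' survival stratification.
#'
#' @param features Feature data.frame with the 95 catalog columns.
#' @param labels Character vector "R"/"NR".
#' @param config A `qus_config()` list.
#' @param kinds Classifiers to run.
#' @param pools Feature pools to run.
#' @param seed Seed for subset draws.
#' @return Named list of `classifier_report`s, names `<kind>_<pool>`.
#' @export
run_protocol <- function(features, labels, config = qus_config(),
                         kinds = c("knn", "svm"),
                         pools = c("qus_tex1", "all"), seed = 1L) {
  catalog <- feature_catalog()
  missing <- setdiff(catalog, colnames(features))
  if (length(missing) > 0L) {
    stop("feature matrix lacks catalog columns: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  reports <- list()
  for (k in kinds) {
    for (p in pools) {
      fs <- forward_select(features, labels, kind = k, config = config,
                           pool = feature_pool(p), seed = seed)
      rep_ <- loocv_evaluate(features, labels, fs$selected, k, config)
      rep_$pool <- p
      rep_$trace <- fs$trace
      reports[[paste(k, p, sep = "_")]] <- rep_
    }
  }
  reports
}
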