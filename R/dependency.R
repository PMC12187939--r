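#' Combine CRISPR and RNAi dependency scores
#'
#' Forms the predictive dependency vector as a weighted average of the
#' Chronos (CRISPR knockout) and Demeter (RNAi) fitness scores,
#' `combined = 0.8 * chronos + 0.2 * demeter` at the default weight.
#' Lines with a missing Demeter score fall back to the Chronos score
#' alone and are flagged.
#'
#' @param dependency Tibble with columns `cell_line`, `chronos` and
#'   (optionally) `demeter`.
#' @param chronos_weight Weight on the Chronos score (Demeter gets
#'   `1 - chronos_weight`).
#' @return Input tibble with `combined` and `demeter_fallback` columns.
#' @export
#' @examples
#' combine_dependency(tibble::tibble(cell_line = "L1", chronos = -1,
#'                                   demeter = -0.5))$combined  # -0.9
combine_dependency <- function(dependency, chronos_weight = 0.8) {
  stopifnot(all(c("cell_line", "chronos") %in% names(dependency)))
  if (nrow(dependency) == 0) stop("no cell lines to combine", call. = FALSE)
  demeter <- if ("demeter" %in% names(dependency)) dependency$demeter
             else rep(NA_real_, nrow(dependency))
  fallback <- is.na(demeter)
  combined <- ifelse(fallback, dependency$chronos,
                     chronos_weight * dependency$chronos +
                       (1 - chronos_weight) * demeter)
  dplyr::mutate(dependency, combined = combined, demeter_fallback = fallback)
}

#' Fit cross-validated dependency forests
#'
#' Trains one random-forest regression per fold on an 80:20 train:test
#' split of cell lines, mirroring the study design: `max_depth = 7`,
#' `min_samples_leaf = 2`, features per split = 0.5% of all features and
#' 10,000 trees at the published scale (pass smaller values for desk-scale
#' runs; the code path is identical). Each tree's out-of-bag R-squared is
#' recorded for prediction attenuation.
#'
#' @param features Tibble: `cell_line` column plus one numeric column per
#'   feature. Missing values are median-imputed per feature.
#' @param dependency Output of [combine_dependency()] (needs `cell_line`,
#'   `combined`).
#' @param n_folds Number of CV models (default 10).
#' @param train_frac Fraction of lines in each model's training split
#'   (default 0.8).
#' @param n_trees Trees per forest (study default 10,000).
#' @param max_depth Maximum tree depth (study default 7).
#' @param min_node Minimum terminal node size (study default 2).
#' @param max_features_frac Fraction of features tried per split (study
#'   default 0.005).
#' @param seed Seed governing splits and forests; per-fold substreams.
#' @return A `dependency_forest` object: per-fold ranger fits, per-tree
#'   OOB scores and attenuation weights, held-out predictions, and
#'   hyperparameters.
#' @export
fit_dependency_forests <- function(features, dependency, n_folds = 10,
                                   train_frac = 0.8,
                                   n_trees = 10000, max_depth = 7,
                                   min_node = 2, max_features_frac = 0.005,
                                   seed = 1L) {
  stopifnot("cell_line" %in% names(features))
  dep <- dplyr::inner_join(dependency, features["cell_line"], by = "cell_line")
  if (nrow(dep) < 2 * n_folds)
    stop("need at least ", 2 * n_folds, " cell lines", call. = FALSE)
  X <- as.matrix(features[match(dep$cell_line, features$cell_line),
                          setdiff(names(features), "cell_line")])
  storage.mode(X) <- "double"
  p <- ncol(X)
  mtry <- floor(max_features_frac * p)
  if (mtry < 1)
    stop("max_features_frac * n_features < 1; need at least ",
         ceiling(1 / max_features_frac), " features (or a larger fraction)",
         call. = FALSE)
  # median imputation with missingness indicators, so forests never see NA
  miss <- which(colSums(is.na(X)) > 0)
  if (length(miss) > 0) {
    ind <- matrix(0, nrow(X), length(miss),
                  dimnames = list(NULL, paste0(colnames(X)[miss], "_missing")))
    for (j in seq_along(miss)) {
      na <- is.na(X[, miss[j]])
      ind[na, j] <- 1
      X[na, miss[j]] <- stats::median(X[, miss[j]], na.rm = TRUE)
    }
    X <- cbind(X, ind)
  }
  y <- dep$combined
  n <- nrow(X)

  folds <- purrr::map(seq_len(n_folds), function(f) {
    fold_seed <- substream_seed(seed, paste0("fold_", f))
    set.seed(fold_seed)
    train <- sort(sample.int(n, round(train_frac * n)))
    test <- setdiff(seq_len(n), train)
    rf <- ranger::ranger(
      x = X[train, , drop = FALSE], y = y[train],
      num.trees = n_trees, mtry = min(mtry, ncol(X)),
      max.depth = max_depth, min.bucket = min_node,
      keep.inbag = TRUE, seed = fold_seed, num.threads = 1)
    pred_all <- stats::predict(rf, X[train, , drop = FALSE],
                               predict.all = TRUE,
                               num.threads = 1)$predictions
    inbag <- do.call(cbind, rf$inbag.counts)  # n_train x n_trees
    oob_r2 <- purrr::map_dbl(seq_len(n_trees), function(t) {
      oob <- inbag[, t] == 0
      if (sum(oob) < 2) return(0)
      yt <- y[train][oob]
      ss_tot <- sum((yt - mean(yt))^2)
      if (ss_tot == 0) return(0)
      1 - sum((yt - pred_all[oob, t])^2) / ss_tot
    })
    w <- attenuate_tree_weights(oob_r2)
    test_pred_all <- stats::predict(rf, X[test, , drop = FALSE],
                                    predict.all = TRUE,
                                    num.threads = 1)$predictions
    list(forest = rf, train = train, test = test, oob_r2 = oob_r2,
         tree_weights = w,
         all_oob_nonpositive = isTRUE(attr(w, "all_nonpositive")),
         test_pred = drop(test_pred_all %*% w))
  })

  predictions <- purrr::imap_dfr(folds, function(fd, f) {
    tibble::tibble(fold = as.integer(f), cell_line = dep$cell_line[fd$test],
                   y_true = y[fd$test], y_pred = fd$test_pred)
  })
  structure(list(folds = folds, predictions = predictions,
                 X = X, y = y, cell_line = dep$cell_line,
                 hyperparams = list(n_trees = n_trees, max_depth = max_depth,
                                    min_node = min_node, mtry = mtry,
                                    n_folds = n_folds, train_frac = train_frac,
                                    seed = seed)),
            class = "dependency_forest")
}

#' Attenuation weights from per-tree out-of-bag scores
#'
#' Tree predictions are down-weighted in proportion to out-of-bag
#' performance: `w_t = max(oob_t, 0) / sum(max(oob, 0))`. Negative OOB
#' R-squared values are clipped to zero so weights stay non-negative; if
#' every score is non-positive the weights fall back to uniform (flagged
#' via the `all_nonpositive` attribute).
#'
#' @param oob_scores Numeric vector of per-tree OOB R-squared values.
#' @return Non-negative weights summing to 1.
#' @export
#' @examples
#' attenuate_tree_weights(c(0.5, 0))   # c(1, 0)
#' attenuate_tree_weights(c(0.6, 0.2)) # c(0.75, 0.25)
attenuate_tree_weights <- function(oob_scores) {
  w <- pmax(oob_scores, 0)
  if (sum(w) == 0) {
    w <- rep(1 / length(oob_scores), length(oob_scores))
    attr(w, "all_nonpositive") <- TRUE
  } else {
    w <- w / sum(w)
  }
  w
}

#' Combine per-tree predictions with OOB attenuation
#'
#' @param pred_matrix Samples x trees matrix of per-tree predictions.
#' @param oob_scores Per-tree OOB R-squared values (one per column).
#' @return Attenuated predictions (length `nrow(pred_matrix)`).
#' @export
combine_tree_predictions <- function(pred_matrix, oob_scores) {
  pred_matrix <- rbind(pred_matrix)
  stopifnot(ncol(pred_matrix) == length(oob_scores))
  drop(pred_matrix %*% attenuate_tree_weights(oob_scores))
}

#' Predict dependency with the attenuated forest
#'
#' @param object A `dependency_forest`.
#' @param features Feature tibble (`cell_line` + feature columns). Columns
#'   absent from training (e.g. missingness indicators) are zero-filled.
#' @param fold Restrict to one CV model; default averages all folds.
#' @param ... Unused.
#' @return Tibble (`cell_line`, `y_pred`).
#' @export
predict.dependency_forest <- function(object, features, fold = NULL, ...) {
  Xn <- matrix(0, nrow(features), ncol(object$X),
               dimnames = list(NULL, colnames(object$X)))
  shared <- intersect(colnames(object$X), names(features))
  Xn[, shared] <- as.matrix(features[shared])
  folds <- if (is.null(fold)) object$folds else object$folds[fold]
  preds <- purrr::map(folds, function(fd) {
    pa <- stats::predict(fd$forest, Xn, predict.all = TRUE,
                         num.threads = 1)$predictions
    drop(rbind(pa) %*% fd$tree_weights)
  })
  tibble::tibble(cell_line = features$cell_line,
                 y_pred = Reduce(`+`, preds) / length(preds))
}

# Flatten one ranger tree (plus in-bag node covers) for the C++ explainer.
flatten_tree <- function(forest, t, X_train, inbag_counts) {
  ti <- ranger::treeInfo(forest, t)
  left <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
  right <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
  feature <- ifelse(is.na(ti$splitvarID), -1L, as.integer(ti$splitvarID))
  threshold <- ifelse(is.na(ti$splitval), 0, ti$splitval)
  value <- ifelse(is.na(ti$prediction), 0, ti$prediction)
  cover <- tree_node_cover(left, right, feature, threshold, X_train,
                           as.numeric(inbag_counts))
  list(left = left, right = right, feature = feature,
       threshold = threshold, value = value, cover = cover)
}

#' SHAP feature ranking across CV models
#'
#' Computes path-dependent TreeSHAP attributions of the attenuated forest
#' for every sample, takes mean absolute SHAP per feature within each CV
#' model, averages across the models, and ranks features by that
#' importance. The cumulative importance share supports the
#' "top SHAP (cumulative 15%)" signature rule.
#'
#' @param fit A `dependency_forest`.
#' @param features Optional feature tibble to explain; defaults to the
#'   training matrix.
#' @return A `shap_ranking` tibble: `feature`, `importance`, `rank`,
#'   `cumulative_share` (non-decreasing, reaching 1).
#' @export
shap_ranking <- function(fit, features = NULL) {
  stopifnot(inherits(fit, "dependency_forest"))
  X <- if (is.null(features)) fit$X else {
    Xn <- matrix(0, nrow(features), ncol(fit$X),
                 dimnames = list(NULL, colnames(fit$X)))
    shared <- intersect(colnames(fit$X), names(features))
    Xn[, shared] <- as.matrix(features[shared])
    Xn
  }
  per_model <- purrr::map(fit$folds, function(fd) {
    trees <- purrr::map(seq_len(fd$forest$num.trees), function(t) {
      flatten_tree(fd$forest, t, fit$X[fd$train, , drop = FALSE],
                   fd$forest$inbag.counts[[t]])
    })
    phi <- treeshap_values(trees, X, as.numeric(fd$tree_weights))
    colMeans(abs(phi))
  })
  importance <- Reduce(`+`, per_model) / length(per_model)
  ord <- order(-importance, colnames(fit$X))
  imp_sorted <- importance[ord]
  total <- sum(imp_sorted)
  out <- tibble::tibble(
    feature = colnames(fit$X)[ord],
    importance = imp_sorted,
    rank = seq_along(ord),
    cumulative_share = if (total > 0) cumsum(imp_sorted) / total
                       else seq_along(ord) / length(ord))
  class(out) <- c("shap_ranking", class(out))
  out
}

#' SHAP values of the attenuated forest
#'
#' Per-sample, per-feature attributions averaged over the CV models, with
#' the SHAP base value as an attribute; `rowSums(phi) + base` equals the
#' fold-averaged attenuated prediction.
#'
#' @inheritParams shap_ranking
#' @return Samples x features matrix with attribute `base`.
#' @export
shap_values <- function(fit, features = NULL) {
  stopifnot(inherits(fit, "dependency_forest"))
  X <- if (is.null(features)) fit$X else {
    Xn <- matrix(0, nrow(features), ncol(fit$X),
                 dimnames = list(NULL, colnames(fit$X)))
    shared <- intersect(colnames(fit$X), names(features))
    Xn[, shared] <- as.matrix(features[shared])
    Xn
  }
  phis <- purrr::map(fit$folds, function(fd) {
    trees <- purrr::map(seq_len(fd$forest$num.trees), function(t) {
      flatten_tree(fd$forest, t, fit$X[fd$train, , drop = FALSE],
                   fd$forest$inbag.counts[[t]])
    })
    list(phi = treeshap_values(trees, X, as.numeric(fd$tree_weights)),
         base = treeshap_base(trees, as.numeric(fd$tree_weights)))
  })
  phi <- Reduce(`+`, purrr::map(phis, "phi")) / length(phis)
  colnames(phi) <- colnames(fit$X)
  attr(phi, "base") <- mean(purrr::map_dbl(phis, "base"))
  phi
}

#' Top-SHAP membership by cumulative importance share
#'
#' The top set is the smallest rank prefix whose cumulative share of
#' total importance reaches `cumulative_share`; features tied (equal
#' importance) with the last included feature are all included.
#'
#' @param ranking A [shap_ranking()] tibble.
#' @param cumulative_share Share of total importance (default 0.15).
#' @return Logical vector along `ranking` rows.
#' @export
top_shap_features <- function(ranking, cumulative_share = 0.15) {
  k <- which(ranking$cumulative_share >= cumulative_share)[1]
  if (is.na(k)) k <- nrow(ranking)
  # ranking is sorted by descending importance, so boundary ties extend k
  k_tied <- max(which(ranking$importance == ranking$importance[k]))
  ranking$rank <= max(k, k_tied)
}

#' Select signature genes by the three-branch rule
#'
#' A candidate is selected iff it is in the top-SHAP set and satisfies
#' one of: literature count >= 7; literature count >= 5 with
#' shNRF2 6 h logFC < 0.25; or literature count >= 2 with logFC < 0.
#' Whether the top-SHAP requirement binds all three branches or only the
#' first is grammatically ambiguous in the source protocol; both
#' behaviors are available via `top_shap_scope`.
#'
#' @param candidates Tibble with `gene`, `in_top_shap`,
#'   `literature_count`, `shnrf2_logfc_6h`.
#' @param top_shap_scope `"all"` (default) applies the top-SHAP
#'   requirement to every branch; `"first_branch"` only to the first.
#' @return `candidates` with per-branch logical columns and `selected`.
#' @export
select_signature <- function(candidates, top_shap_scope = c("all", "first_branch")) {
  top_shap_scope <- match.arg(top_shap_scope)
  stopifnot(all(c("gene", "in_top_shap", "literature_count",
                  "shnrf2_logfc_6h") %in% names(candidates)))
  stopifnot(all(candidates$literature_count >= 0))
  b1 <- candidates$literature_count >= 7
  b2 <- candidates$literature_count >= 5 & candidates$shnrf2_logfc_6h < 0.25
  b3 <- candidates$literature_count >= 2 & candidates$shnrf2_logfc_6h < 0
  selected <- if (top_shap_scope == "all") {
    candidates$in_top_shap & (b1 | b2 | b3)
  } else {
    (candidates$in_top_shap & b1) | b2 | b3
  }
  dplyr::mutate(candidates, branch_literature = b1, branch_lit5_logfc = b2,
                branch_lit2_down = b3, selected = selected)
}

#' Held-out AUC and R-squared of dependency predictions
#'
#' Binarizes the true combined score at the dependency threshold
#' (`combined < -0.5` = dependent) and scores how well predictions rank
#' dependent below non-dependent lines: AUC equals the Wilcoxon rank-sum
#' statistic U / (n1 * n2), midranks for ties. R-squared is
#' `1 - SS_res / SS_tot` on the same held-out values.
#'
#' @param y_true True combined dependency scores.
#' @param y_pred Held-out predictions.
#' @param threshold Dependency cutoff (default -0.5).
#' @return One-row tibble: `auc`, `r2`, `n_dependent`, `n_independent`.
#' @export
dependency_auc <- function(y_true, y_pred, threshold = -0.5) {
  stopifnot(length(y_true) == length(y_pred))
  pos <- y_true < threshold
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0)
    stop("need cell lines on both sides of the dependency threshold",
         call. = FALSE)
  r <- rank(-y_pred)  # lower prediction = more dependent = higher rank score
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y_true - y_pred)^2) / ss_tot else NA_real_
  tibble::tibble(auc = auc, r2 = r2, n_dependent = n1, n_independent = n2)
}

#' @export
tidy.dependency_forest <- function(x, threshold = -0.5, ...) {
  x$predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::reframe(dependency_auc(.data$y_true, .data$y_pred,
                                  threshold = threshold))
}

#' @export
glance.dependency_forest <- function(x, threshold = -0.5, ...) {
  per_fold <- tidy.dependency_forest(x, threshold = threshold)
  tibble::tibble(n_folds = nrow(per_fold),
                 mean_r2 = mean(per_fold$r2),
                 mean_auc = mean(per_fold$auc),
                 n_trees = x$hyperparams$n_trees,
                 mtry = x$hyperparams$mtry)
}

#' @export
print.dependency_forest <- function(x, ...) {
  g <- glance.dependency_forest(x)
  cat("Cross-validated dependency forest\n")
  cat(sprintf("  %d folds x %d trees (mtry %d, max depth %d)\n",
              g$n_folds, g$n_trees, g$mtry, x$hyperparams$max_depth))
  cat(sprintf("  held-out R^2 = %.3f, mean AUC = %.3f\n", g$mean_r2, g$mean_auc))
  invisible(x)
}
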