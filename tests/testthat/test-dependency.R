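# shared small fixture: quick forest on planted data
small_fit <- local({
  spec <- synthetic_spec(n_cell_lines = 80, n_features = 40, n_informative = 4,
                         noise_sd = 0.5, seed = 21)
  dd <- simulate_dependency_dataset(spec)
  dep <- combine_dependency(dd$dependency)
  list(data = dd, dep = dep,
       fit = fit_dependency_forests(dd$features, dep, n_folds = 3,
                                    n_trees = 40, max_features_frac = 0.25,
                                    seed = 21))
})

test_that("dependency combination applies the 80:20 weighting", {
  d <- tibble::tibble(cell_line = c("a", "b", "c"),
                      chronos = c(-1, 0, -2),
                      demeter = c(-0.5, 0, NA))
  out <- combine_dependency(d)
  expect_equal(out$combined, c(-0.9, 0, -2))
  expect_equal(out$demeter_fallback, c(FALSE, FALSE, TRUE))
  expect_error(combine_dependency(d[0, ]), "no cell lines")
})

test_that("attenuation weights clip negative OOB scores and normalize", {
  expect_equal(attenuate_tree_weights(c(0.5, 0)), c(1, 0))
  expect_equal(attenuate_tree_weights(c(0.6, 0.2)), c(0.75, 0.25))
  w <- attenuate_tree_weights(c(-0.3, -0.1))
  expect_equal(as.numeric(w), c(0.5, 0.5))
  expect_true(attr(w, "all_nonpositive"))
  expect_equal(sum(attenuate_tree_weights(stats::runif(20, -1, 1))), 1)
})

test_that("attenuated prediction combines trees by OOB weight", {
  pred <- matrix(c(1, 3), nrow = 1)
  expect_equal(combine_tree_predictions(pred, c(0.5, 0.0)), 1.0)
  expect_equal(combine_tree_predictions(pred, c(0.6, 0.2)), 1.5)
  # equal scores reduce to the plain forest mean
  expect_equal(combine_tree_predictions(pred, c(0.4, 0.4)), 2.0)
})

test_that("zero-weight trees never influence attenuated predictions", {
  set.seed(1)
  pred <- matrix(stats::rnorm(30), nrow = 5)
  oob <- c(0.5, -0.2, 0.3, 0, 0.1, -0.9)
  keep <- attenuate_tree_weights(oob) > 0
  expect_equal(combine_tree_predictions(pred, oob),
               combine_tree_predictions(pred[, keep, drop = FALSE], oob[keep]))
})

test_that("TreeSHAP matches the exhaustive Shapley oracle on small trees", {
  set.seed(9)
  ts <- nrf2regulome:::treeshap_values
  for (rep in 1:6) {
    n <- 40; p <- 4
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- paste0("x", 1:p)
    y <- X[, 1] * 2 + X[, 2] * X[, 3] + stats::rnorm(n, 0, 0.3)
    rf <- ranger::ranger(x = data.frame(X), y = y, num.trees = 2,
                         max.depth = 3, min.bucket = 2, mtry = p,
                         keep.inbag = TRUE, seed = rep, num.threads = 1)
    for (t in 1:2) {
      tr <- nrf2regulome:::flatten_tree(rf, t, X, rf$inbag.counts[[t]])
      phi <- ts(list(tr), X, 1.0)
      for (i in c(1, 20, 40)) {
        expect_equal(phi[i, ], shapley_tree_oracle(tr, X[i, ], p),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("SHAP attributions are additive to the attenuated prediction", {
  fit <- small_fit$fit
  phi <- shap_values(fit)
  pred <- predict(fit, small_fit$data$features)$y_pred
  expect_lt(max(abs(rowSums(phi) + attr(phi, "base") - pred)), 1e-9)
})

test_that("constant features get exactly zero SHAP importance", {
  dd <- small_fit$data
  feats <- dplyr::mutate(dd$features, flat_feature = 1.0)
  fit <- fit_dependency_forests(feats, small_fit$dep, n_folds = 2,
                                n_trees = 30, max_features_frac = 0.25,
                                seed = 3)
  rk <- shap_ranking(fit)
  expect_equal(rk$importance[rk$feature == "flat_feature"], 0)
  expect_true(all(diff(rk$cumulative_share) >= -1e-12))
  expect_equal(rk$cumulative_share[nrow(rk)], 1)
})

test_that("identical refits are bit-identical (seed contract)", {
  dd <- small_fit$data
  f1 <- fit_dependency_forests(dd$features, small_fit$dep, n_folds = 2,
                               n_trees = 25, max_features_frac = 0.25, seed = 5)
  f2 <- fit_dependency_forests(dd$features, small_fit$dep, n_folds = 2,
                               n_trees = 25, max_features_frac = 0.25, seed = 5)
  expect_identical(f1$predictions, f2$predictions)
})

test_that("too-small feature fractions are rejected with guidance", {
  dd <- small_fit$data
  expect_error(fit_dependency_forests(dd$features, small_fit$dep,
                                      max_features_frac = 0.001, seed = 1),
               "at least")
})

test_that("noise-free single-feature dependency is recovered almost perfectly", {
  spec <- synthetic_spec(n_cell_lines = 200, n_features = 50,
                         n_informative = 1, noise_sd = 0, seed = 7)
  dd <- simulate_dependency_dataset(spec)
  dep <- combine_dependency(dd$dependency)
  fit <- fit_dependency_forests(dd$features, dep, n_trees = 200,
                                max_features_frac = 1.0, seed = 7)
  expect_gt(glance(fit)$mean_r2, 0.95)
})

test_that("signature selection reproduces the three-branch rule", {
  cand <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
    in_top_shap = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    literature_count = c(7, 5, 5, 2, 2, 1, 9),
    shnrf2_logfc_6h = c(1.0, 0.20, 0.30, -0.1, 0.1, -2, -2))
  out <- select_signature(cand)
  expect_equal(out$selected,
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # order invariance
  perm <- sample(nrow(cand))
  out2 <- select_signature(cand[perm, ])
  expect_equal(out2$selected[order(perm)], out$selected)
  # relaxed scope keeps branch-1 gated on SHAP but frees branches 2-3
  out3 <- select_signature(cand, top_shap_scope = "first_branch")
  expect_equal(out3$selected,
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("growing the cumulative-share window never drops selected genes", {
  rk <- shap_ranking(small_fit$fit)
  prev <- top_shap_features(rk, 0.05)
  for (cs in c(0.10, 0.15, 0.3, 0.6, 1.0)) {
    cur <- top_shap_features(rk, cs)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("dependency AUC equals the pairwise-comparison oracle", {
  expect_equal(dependency_auc(c(-2, -1, 0, 1), c(-2, -1, 0, 1))$auc, 1)
  set.seed(13)
  for (rep in 1:5) {
    y <- stats::rnorm(40, -0.5, 1)
    p <- round(stats::rnorm(40, -0.5, 1), 1)  # rounding forces ties
    expect_equal(dependency_auc(y, p)$auc, pairwise_auc(y, p))
  }
  expect_error(dependency_auc(c(-2, -1), c(0, 0)), "both sides")
})

test_that("tidy and glance summarise per-fold and overall metrics", {
  td <- tidy(small_fit$fit)
  expect_equal(nrow(td), 3)
  expect_true(all(c("fold", "auc", "r2") %in% names(td)))
  gl <- glance(small_fit$fit)
  expect_equal(gl$mean_r2, mean(td$r2))
  expect_equal(gl$mean_auc, mean(td$auc))
})
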