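test_that("metrics match the confusion-count formulas", {
  truth <- c(rep("pos", 15), rep("neg", 12))
  pred <- c(rep("pos", 10), rep("neg", 5), rep("pos", 2), rep("neg", 10))
  m <- classification_metrics(truth, pred, positive = "pos")
  expect_equal(unname(m["precision"]), 10 / 12, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 10 / 15, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 2 * (10 / 12) * (10 / 15) /
                 (10 / 12 + 10 / 15), tolerance = 1e-12)
  expect_equal(round(unname(m["precision"]), 3), 0.833)
  expect_equal(round(unname(m["recall"]), 3), 0.667)
  expect_equal(round(unname(m["f1"]), 3), 0.741)
})

test_that("F1 is the harmonic-mean identity on random confusions", {
  set.seed(21)
  for (rep in 1:25) {
    truth <- sample(c("a", "b"), 40, replace = TRUE)
    pred <- sample(c("a", "b"), 40, replace = TRUE)
    if (!all(c("a", "b") %in% truth)) next
    m <- classification_metrics(truth, pred, positive = "b")
    if (!is.na(m["precision"]) && !is.na(m["recall"]) &&
        m["precision"] + m["recall"] > 0) {
      expect_equal(unname(m["f1"]),
                   unname(2 * m["precision"] * m["recall"] /
                            (m["precision"] + m["recall"])),
                   tolerance = 1e-12)
    }
    expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  }
})

test_that("AUC matches brute-force pairwise comparison and label-swap", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    truth <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n)
    auc_b <- classification_metrics(truth, truth, scores, positive = "b")["auc"]
    expect_equal(unname(auc_b), brute_auc(scores, truth, "b"),
                 tolerance = 1e-12)
    # same scores viewed from the other class: AUC(a) = 1 - AUC(b)
    auc_a <- classification_metrics(truth, truth, scores, positive = "a")["auc"]
    expect_equal(unname(auc_a), 1 - unname(auc_b), tolerance = 1e-12)
  }
})

test_that("UMAP embedding is seeded-deterministic with the right shape", {
  set.seed(23)
  x <- matrix(rnorm(100 * 25), 100, 25)
  e1 <- embed_umap(x, n_neighbors = 10, n_components = 2, seed = 5)
  e2 <- embed_umap(x, n_neighbors = 10, n_components = 2, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(100L, 2L))
  e3 <- embed_umap(x, n_neighbors = 10, n_components = 3, seed = 5)
  expect_equal(ncol(e3), 3L)
  expect_error(embed_umap(x, n_neighbors = 100), "must be <")
})

test_that("a separable feature yields perfect metrics in every replicate", {
  x <- matrix(c(rnorm(40, -5), rnorm(40, 5)), ncol = 1)
  y <- rep(c("30", "34"), each = 40)
  ev <- evaluate_classifier(x, y, seed = 3)
  expect_s3_class(ev, "bee_class_eval")
  expect_equal(ev$positive, "34")
  expect_true(all(ev$replicates[, c("precision", "recall", "f1", "auc")] == 1))
  expect_equal(ev$summary$sd, rep(0, 4))
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(24)
  x <- matrix(rnorm(200 * 10), 200, 10)
  y <- sample(rep(c("30", "34"), each = 100))
  ev <- evaluate_classifier(x, y, seed = 6)
  auc <- ev$summary$mean[ev$summary$metric == "auc"]
  expect_gt(auc, 0.35); expect_lt(auc, 0.65)
})

test_that("fixed_split reuses one split, giving zero SD across replicates", {
  set.seed(25)
  x <- matrix(rnorm(80 * 5), 80, 5)
  y <- rep(c("30", "34"), 40)
  ev <- evaluate_classifier(x, y, seed = 4, fixed_split = TRUE)
  expect_equal(ev$summary$sd, rep(0, 4))
})

test_that("evaluate_classifier enforces its contract", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(evaluate_classifier(x, rep("a", 10)), "two classes")
  expect_error(evaluate_classifier(x, rep(c("a", "b"), 5),
                                   train_fraction = 1), "train_fraction")
  expect_error(evaluate_classifier(x, rep(c("a", "b"), 5), positive = "c"),
               "not present")
})

test_that("sweep covers the grid and one cell equals the direct composition", {
  set.seed(26)
  x <- matrix(rnorm(60 * 15), 60, 15)
  y <- rep(c("30", "34"), each = 30)
  sw <- sweep_umap_svm(x, y, neighbors_grid = c(5, 10), dims_grid = 2:3,
                       n_replicates = 3, seed = 9)
  expect_equal(nrow(sw), 4)
  expect_setequal(names(sw)[1:2], c("n_neighbors", "n_components"))

  one <- sweep_umap_svm(x, y, neighbors_grid = 10, dims_grid = 2,
                        n_replicates = 3, seed = 9)
  emb <- embed_umap(x, 10, 2, seed = beecolor:::sub_seed(9, "umap-10-2"))
  ev <- evaluate_classifier(emb, y, n_replicates = 3, seed = 9)
  expect_equal(one$f1_mean, ev$summary$mean[ev$summary$metric == "f1"],
               tolerance = 1e-12)
  expect_equal(one$auc_sd, ev$summary$sd[ev$summary$metric == "auc"],
               tolerance = 1e-12)
  expect_error(sweep_umap_svm(x, y, neighbors_grid = integer(0)),
               "non-empty")

  srt <- sweep_umap_svm(x, y, neighbors_grid = c(5, 10), dims_grid = 2:3,
                        n_replicates = 3, seed = 9, sort_by_f1 = TRUE)
  expect_true(!is.unsorted(rev(srt$f1_mean)))
})

test_that("classify_temperature runs per colony and preprocessing", {
  gp <- generate_profiles(group_design(n_per_group = 20,
                                       origin_effect = 0.02,
                                       temperature_effect = 0.03),
                          L = 60, seed = 31)
  m <- classify_temperature(gp$profiles, gp$meta, umap_neighbors = 10,
                            umap_dims = 2, n_replicates = 3, seed = 8)
  expect_equal(nrow(m), 4)
  expect_setequal(paste(m$colony, m$preprocessing),
                  c("gray raw", "gray umap", "yellow raw", "yellow umap"))
  expect_true(all(m$positive == "34"))
  expect_true(all(m$f1_mean >= 0 & m$f1_mean <= 1, na.rm = TRUE))

  # leakage-free variant runs and keeps the schema
  m2 <- classify_temperature(gp$profiles, gp$meta, umap_neighbors = 10,
                             umap_dims = 2, umap_fit = "train",
                             n_replicates = 2, seed = 8,
                             preprocess = "umap")
  expect_equal(nrow(m2), 2)
})
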