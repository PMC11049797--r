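# Seed substreams: every stochastic stage draws its own seed from the master
# seed plus a tag, so stages are reproducible independently of call order.
sub_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' UMAP embedding of coloration profiles
#'
#' Reduces profile vectors to a low-dimensional embedding with UMAP
#' (Euclidean metric, min_dist 0.1 unless overridden). With a fixed seed the
#' embedding is bit-reproducible; row order is preserved.
#'
#' @param profiles Numeric matrix, one profile per row.
#' @param n_neighbors Number of neighbors (default 75, chosen to capture
#'   global structure at 100 specimens per colony). Must be < nrow(profiles).
#' @param n_components Embedding dimension (default 2).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param min_dist,metric Passed to [uwot::umap()].
#' @return Numeric matrix `nrow(profiles) x n_components`, rownames kept.
#' @export
embed_umap <- function(profiles, n_neighbors = 75L, n_components = 2L,
                       seed = NULL, min_dist = 0.1, metric = "euclidean") {
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles)
  if (n_neighbors >= n) {
    stop("n_neighbors (", n_neighbors, ") must be < number of samples (",
         n, ")", call. = FALSE)
  }
  if (n_neighbors < 2L || n_components < 2L) {
    stop("n_neighbors and n_components must be >= 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  emb <- uwot::umap(profiles, n_neighbors = n_neighbors,
                    n_components = n_components, min_dist = min_dist,
                    metric = metric, n_threads = 1, n_sgd_threads = 0)
  rownames(emb) <- rownames(profiles)
  emb
}

#' Classification metrics from predictions and scores
#'
#' Precision, recall and F1 for the positive class from the confusion counts,
#' plus AUC from continuous decision scores (higher score = more positive).
#'
#' @param truth Factor/character vector of true labels.
#' @param pred Predicted labels.
#' @param scores Numeric decision scores oriented toward `positive`.
#' @param positive The positive class label.
#' @return Named numeric vector `precision, recall, f1, auc` (AUC is `NA`
#'   when `scores` is `NULL`).
#' @export
classification_metrics <- function(truth, pred, scores = NULL, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    lev <- c(setdiff(unique(truth), positive)[1], positive)
    roc <- pROC::roc(response = factor(truth, levels = lev),
                     predictor = as.numeric(scores),
                     levels = lev, direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  }
  c(precision = precision, recall = recall, f1 = f1, auc = auc)
}

# Stratified train/test split; returns train indices. Guarantees both classes
# in train and test (errors if a class is too small for that).
stratified_split <- function(labels, train_fraction) {
  idx_by_class <- split(seq_along(labels), labels)
  train <- integer(0)
  for (idx in idx_by_class) {
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    if (length(idx) < 2L) {
      stop("each class needs >= 2 samples for a stratified split",
           call. = FALSE)
    }
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Repeated train/test evaluation of a linear SVM
#'
#' The classifier-evaluation harness: per replicate, a stratified random
#' 75/25 train/test split, a linear-kernel SVM fit on the training set, and
#' precision / recall / F1 / AUC on the test set, with AUC computed from the
#' SVM decision values. Metrics are summarized as mean and SD over
#' replicates.
#'
#' @param features Numeric matrix (samples x features): raw profiles or a
#'   UMAP embedding.
#' @param labels Two-class factor/character vector, one per row.
#' @param train_fraction Fraction used for training (default 0.75).
#' @param n_replicates Number of repeated splits (default 10).
#' @param seed Integer master seed; each replicate uses its own substream.
#' @param positive Positive class for precision/recall; default the
#'   lexicographically larger label (e.g. "34" of 30/34), stated in output.
#' @param cost SVM regularization constant (default 1, the e1071 default).
#' @param fixed_split Reuse the first split in all replicates (emulates
#'   evaluation protocols whose replicates share one split).
#' @param preprocess_fn Optional `function(train_x, test_x)` returning
#'   `list(train=, test=)`, applied per replicate (e.g. leakage-free UMAP fit
#'   on the training set only).
#' @return A `bee_class_eval`: list with `replicates` (data.frame, one row
#'   per replicate), `summary` (mean/sd per metric), `positive`, `n`.
#' @export
evaluate_classifier <- function(features, labels, train_fraction = 0.75,
                                n_replicates = 10L, seed = 1L,
                                positive = NULL, cost = 1,
                                fixed_split = FALSE, preprocess_fn = NULL) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) {
    stop("labels must have exactly two classes", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (is.null(positive)) positive <- max(levels(labels))
  positive <- as.character(positive)
  if (!positive %in% levels(labels)) {
    stop("positive label '", positive, "' not present", call. = FALSE)
  }

  rows <- vector("list", n_replicates)
  split0 <- NULL
  for (r in seq_len(n_replicates)) {
    set.seed(sub_seed(seed, paste0("split", if (fixed_split) 1L else r)))
    if (fixed_split && !is.null(split0)) {
      train <- split0
    } else {
      train <- stratified_split(labels, train_fraction)
      if (fixed_split) split0 <- train
    }
    test <- setdiff(seq_along(labels), train)
    x_tr <- features[train, , drop = FALSE]
    x_te <- features[test, , drop = FALSE]
    if (!is.null(preprocess_fn)) {
      px <- preprocess_fn(x_tr, x_te)
      x_tr <- px$train; x_te <- px$test
    }
    fit <- e1071::svm(x = x_tr, y = droplevels(labels[train]),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, x_te, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 names the decision column "A/B": positive sign favors class A.
    favored <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    scores <- if (identical(favored, positive)) dv[, 1] else -dv[, 1]
    rows[[r]] <- c(replicate = r,
                   classification_metrics(labels[test], pred, scores, positive))
  }
  reps <- as.data.frame(do.call(rbind, rows))
  summ <- data.frame(
    metric = c("precision", "recall", "f1", "auc"),
    mean = vapply(reps[c("precision", "recall", "f1", "auc")],
                  mean, numeric(1), na.rm = TRUE),
    sd = vapply(reps[c("precision", "recall", "f1", "auc")],
                stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL
  )
  structure(list(replicates = reps, summary = summ, positive = positive,
                 n = length(labels)),
            class = "bee_class_eval")
}

#' @export
print.bee_class_eval <- function(x, ...) {
  cat(sprintf("Linear SVM evaluation (%d replicates, n = %d, positive = '%s')\n",
              nrow(x$replicates), x$n, x$positive))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Sweep UMAP parameters for SVM classification
#'
#' Runs [embed_umap()] + [evaluate_classifier()] over a grid of
#' `n_neighbors` x `n_components` values. Defaults cover neighbors
#' 5/10/20/50/75/99 and dimensions 2-10 (54 cells). UMAP is fit on the full
#' dataset before splitting (transductive preprocessing); see
#' `preprocess_fn` of [evaluate_classifier()] for the leakage-free variant.
#'
#' @param profiles Numeric matrix of profiles (samples x length).
#' @param labels Two-class labels.
#' @param neighbors_grid,dims_grid Integer grids to sweep.
#' @param sort_by_f1 Sort the result by mean F1, descending.
#' @inheritParams evaluate_classifier
#' @return data.frame with one row per grid cell: `n_neighbors`,
#'   `n_components`, and `<metric>_mean` / `<metric>_sd` columns.
#' @export
sweep_umap_svm <- function(profiles, labels,
                           neighbors_grid = c(5L, 10L, 20L, 50L, 75L, 99L),
                           dims_grid = 2:10,
                           train_fraction = 0.75, n_replicates = 10L,
                           seed = 1L, positive = NULL, cost = 1,
                           fixed_split = FALSE, sort_by_f1 = FALSE) {
  if (!length(neighbors_grid) || !length(dims_grid)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(n_neighbors = as.integer(neighbors_grid),
                      n_components = as.integer(dims_grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nb <- grid$n_neighbors[i]; nc <- grid$n_components[i]
    emb <- embed_umap(profiles, n_neighbors = nb, n_components = nc,
                      seed = sub_seed(seed, sprintf("umap-%d-%d", nb, nc)))
    ev <- evaluate_classifier(emb, labels, train_fraction = train_fraction,
                              n_replicates = n_replicates, seed = seed,
                              positive = positive, cost = cost,
                              fixed_split = fixed_split)
    s <- ev$summary
    row <- data.frame(n_neighbors = nb, n_components = nc)
    for (j in seq_len(nrow(s))) {
      row[[paste0(s$metric[j], "_mean")]] <- s$mean[j]
      row[[paste0(s$metric[j], "_sd")]] <- s$sd[j]
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  if (sort_by_f1) res <- res[order(-res$f1_mean), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Temperature classification per colony of origin
#'
#' Reproduces the evaluation-table layout: the incubation-temperature
#' classifier is trained and tested separately for each colony of origin, on
#' raw profile vectors and/or on UMAP-preprocessed vectors, giving one row
#' per colony x preprocessing combination.
#'
#' @param profiles Profile matrix, rownames = specimen ids.
#' @param meta data.frame with `specimen_id`, `colony`, `temperature`.
#' @param preprocess Character subset of `c("raw", "umap")`.
#' @param umap_neighbors,umap_dims UMAP parameters for the "umap" rows.
#' @param umap_fit `"all"` (transductive: UMAP fit once on the colony's full
#'   dataset before splitting, the default) or `"train"` (leakage-free: fit
#'   on each training split and project the test split).
#' @inheritParams evaluate_classifier
#' @return data.frame with columns `colony`, `preprocessing`, `positive`,
#'   and `<metric>_mean` / `<metric>_sd` for precision, recall, f1, auc.
#' @export
classify_temperature <- function(profiles, meta,
                                 preprocess = c("raw", "umap"),
                                 umap_neighbors = 75L, umap_dims = 2L,
                                 umap_fit = c("all", "train"),
                                 train_fraction = 0.75, n_replicates = 10L,
                                 seed = 1L, positive = "34", cost = 1,
                                 fixed_split = FALSE) {
  preprocess <- match.arg(preprocess, c("raw", "umap"), several.ok = TRUE)
  umap_fit <- match.arg(umap_fit)
  meta <- meta[match(rownames(profiles), meta$specimen_id), ]
  if (anyNA(meta$specimen_id)) {
    stop("metadata missing for some specimens", call. = FALSE)
  }
  out <- list()
  for (col in sort(unique(meta$colony))) {
    sel <- meta$colony == col
    x <- profiles[sel, , drop = FALSE]
    y <- as.character(meta$temperature[sel])
    for (pp in preprocess) {
      if (pp == "raw") {
        ev <- evaluate_classifier(x, y, train_fraction, n_replicates,
                                  seed = sub_seed(seed, paste0(col, "-raw")),
                                  positive = positive, cost = cost,
                                  fixed_split = fixed_split)
      } else if (umap_fit == "all") {
        emb <- embed_umap(x, umap_neighbors, umap_dims,
                          seed = sub_seed(seed, paste0(col, "-umap")))
        ev <- evaluate_classifier(emb, y, train_fraction, n_replicates,
                                  seed = sub_seed(seed, paste0(col, "-umap")),
                                  positive = positive, cost = cost,
                                  fixed_split = fixed_split)
      } else {
        useed <- sub_seed(seed, paste0(col, "-umap-train"))
        pre <- function(tr, te) {
          set.seed(useed)
          fit <- uwot::umap(tr, n_neighbors = min(umap_neighbors, nrow(tr) - 1L),
                            n_components = umap_dims, min_dist = 0.1,
                            n_threads = 1, n_sgd_threads = 0, ret_model = TRUE)
          list(train = fit$embedding,
               test = uwot::umap_transform(te, fit, n_threads = 1))
        }
        ev <- evaluate_classifier(x, y, train_fraction, n_replicates,
                                  seed = useed, positive = positive,
                                  cost = cost, fixed_split = fixed_split,
                                  preprocess_fn = pre)
      }
      s <- ev$summary
      row <- data.frame(colony = col, preprocessing = pp,
                        positive = ev$positive, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(s))) {
        row[[paste0(s$metric[j], "_mean")]] <- s$mean[j]
        row[[paste0(s$metric[j], "_sd")]] <- s$sd[j]
      }
      out[[paste(col, pp)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
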