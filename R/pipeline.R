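#' Run the full coloration-analysis pipeline
#'
#' End-to-end driver: extract fixed-length profiles from every image,
#' compute coloration indices, tabulate group summaries, evaluate the
#' temperature classifier per colony (raw and UMAP-preprocessed profiles),
#' and run the inferential chain. Every stage's output is written to
#' `out_dir`; re-running with the same inputs and seed reproduces the outputs
#' byte for byte.
#'
#' @param image_dir Directory of specimen images (PNG/TIFF/JPEG).
#' @param roi_csv Path to the ROI table (`image_id,x0,y0,x1,y1`), or `NULL`
#'   for full-frame ROIs.
#' @param meta_csv Path to the metadata CSV
#'   (`specimen_id,colony,temperature`).
#' @param out_dir Output directory (created if needed).
#' @param target_length Profile length L (default 1998).
#' @param sat_threshold Saturation cutoff (default 0.95).
#' @param umap_neighbors,umap_dims UMAP parameters for classification.
#' @param train_fraction,n_replicates Classifier evaluation protocol.
#' @param alpha Significance level for the inference chain.
#' @param seed Master seed; all stage randomness derives from it.
#' @param sweep Also run the UMAP parameter sweep per colony (default FALSE).
#' @param sweep_neighbors,sweep_dims Sweep grids (defaults: 5/10/20/50/75/99
#'   neighbors, 2-10 dimensions).
#' @param max_masked_fraction Specimen rejection threshold for fully masked
#'   columns.
#' @return Invisibly, a list of the computed objects (`profiles`, `indices`,
#'   `group_summary`, `metrics`, `inference`, and `sweep` if requested).
#' @export
run_pipeline <- function(image_dir, roi_csv = NULL, meta_csv, out_dir,
                         target_length = 1998L, sat_threshold = 0.95,
                         umap_neighbors = 75L, umap_dims = 2L,
                         train_fraction = 0.75, n_replicates = 10L,
                         alpha = 0.05, seed = 1L, sweep = FALSE,
                         sweep_neighbors = c(5L, 10L, 20L, 50L, 75L, 99L),
                         sweep_dims = 2:10, max_masked_fraction = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  meta <- stage("meta", {
    m <- utils::read.csv(meta_csv, stringsAsFactors = FALSE,
                         colClasses = "character")
    need <- c("specimen_id", "colony", "temperature")
    if (!all(need %in% names(m))) {
      stop("metadata must have columns ", paste(need, collapse = ", "))
    }
    m
  })
  rois <- if (!is.null(roi_csv)) stage("rois", read_roi_table(roi_csv))
          else NULL
  profiles <- stage("extract",
    extract_profiles(image_dir, rois, L = target_length,
                     sat_threshold = sat_threshold,
                     max_masked_fraction = max_masked_fraction))
  missing_meta <- setdiff(rownames(profiles), meta$specimen_id)
  if (length(missing_meta)) {
    stop("pipeline stage 'meta' failed: no metadata for specimen(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  write_profiles(profiles, file.path(out_dir, "profiles.csv"))

  indices <- stage("index", coloration_indices(profiles))
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)

  group_summary <- stage("summarize", summarize_groups(indices, meta))
  utils::write.csv(group_summary, file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)

  metrics <- stage("classify",
    classify_temperature(profiles, meta, preprocess = c("raw", "umap"),
                         umap_neighbors = umap_neighbors,
                         umap_dims = umap_dims,
                         train_fraction = train_fraction,
                         n_replicates = n_replicates,
                         seed = sub_seed(seed, "classify")))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  sweep_res <- NULL
  if (sweep) {
    sweep_res <- stage("sweep", {
      meta_o <- meta[match(rownames(profiles), meta$specimen_id), ]
      res <- lapply(sort(unique(meta_o$colony)), function(col) {
        sel <- meta_o$colony == col
        sw <- sweep_umap_svm(profiles[sel, , drop = FALSE],
                             meta_o$temperature[sel],
                             neighbors_grid = sweep_neighbors,
                             dims_grid = sweep_dims,
                             train_fraction = train_fraction,
                             n_replicates = n_replicates,
                             seed = sub_seed(seed, paste0("sweep-", col)))
        cbind(colony = col, sw)
      })
      do.call(rbind, res)
    })
    utils::write.csv(sweep_res, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }

  inference <- stage("stats", run_inference(indices, meta, alpha = alpha))
  report <- list(
    n = inference$n,
    assumptions = list(
      shapiro_residuals_p = inference$assumptions$shapiro_residuals_p,
      shapiro_group_p = as.list(inference$assumptions$shapiro_group_p),
      max_variance_ratio = inference$assumptions$max_variance_ratio,
      variance_p = inference$assumptions$variance_p),
    transform = list(type = inference$transform, lambda = inference$lambda),
    anova = inference$anova,
    tukey = inference$tukey)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  config <- list(target_length = target_length,
                 sat_threshold = sat_threshold,
                 umap_neighbors = umap_neighbors, umap_dims = umap_dims,
                 train_fraction = train_fraction,
                 n_replicates = n_replicates, alpha = alpha, seed = seed,
                 sweep = sweep, max_masked_fraction = max_masked_fraction)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(profiles = profiles, indices = indices,
                 group_summary = group_summary, metrics = metrics,
                 sweep = sweep_res, inference = inference))
}

#' Plot coloration profiles
#'
#' Overlays profile vectors (gray value vs position along the abdomen),
#' optionally colored by group.
#'
#' @param profiles Profile matrix, one row per specimen.
#' @param group Optional factor of group labels, one per row.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `NULL`.
#' @export
plot_profiles <- function(profiles, group = NULL, ...) {
  stopifnot(is.matrix(profiles))
  cols <- if (is.null(group)) grDevices::adjustcolor("gray30", 0.4) else {
    group <- factor(group)
    grDevices::adjustcolor(as.integer(group) + 1L, 0.4)
  }
  graphics::matplot(t(profiles), type = "l", lty = 1, col = cols,
                    xlab = "position along abdomen (px)",
                    ylab = "median gray value", ...)
  if (!is.null(group)) {
    graphics::legend("topright", legend = levels(group),
                     col = seq_len(nlevels(group)) + 1L, lty = 1, bty = "n")
  }
  invisible(NULL)
}
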