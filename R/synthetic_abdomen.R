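#' Parameters for the synthetic abdomen generator
#'
#' Describes an idealized stereo-microscope ROI of a worker-bee half-abdomen:
#' dark cuticle at `base_gray`, `n_tergites` segments along the long (x)
#' axis separated by darkened seams, optional brighter "yellow" marks on the
#' anterior part of the first tergites, a sprinkling of saturated specular
#' highlights, and Gaussian pixel noise. Synthetic images are gray
#' (R = G = B): the analysis averages the channels anyway, so yellow marks
#' are modeled purely as brightness.
#'
#' @param width,height ROI size in pixels (defaults 1600 x 240).
#' @param base_gray Cuticle brightness in `[0,1]` (default 0.22, placing
#'   full-length coloration indices near 440).
#' @param n_tergites Number of tergite segments along x (default 5).
#' @param seam_darkening Brightness drop at segment seams (default 0.08).
#' @param seam_fraction Fraction of each segment's columns occupied by the
#'   seam at its posterior edge (default 0.08).
#' @param yellow_amplitude Brightness increase of yellow marks (default 0).
#' @param yellow_band_fraction Anterior fraction of a marked tergite covered
#'   by the mark (default 0.3); marks sit on tergites 1-3.
#' @param highlight_fraction Fraction of pixels saturated to 1.0 (default 0).
#' @param noise_sd SD of Gaussian pixel noise, clipped to `[0,1]`
#'   (default 0.05).
#' @param bit_depth 8 or 16 (default 8).
#' @return A `synth_params` list.
#' @export
synth_params <- function(width = 1600L, height = 240L, base_gray = 0.22,
                         n_tergites = 5L, seam_darkening = 0.08,
                         seam_fraction = 0.08, yellow_amplitude = 0,
                         yellow_band_fraction = 0.3, highlight_fraction = 0,
                         noise_sd = 0.05, bit_depth = 8L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            base_gray = base_gray, n_tergites = as.integer(n_tergites),
            seam_darkening = seam_darkening, seam_fraction = seam_fraction,
            yellow_amplitude = yellow_amplitude,
            yellow_band_fraction = yellow_band_fraction,
            highlight_fraction = highlight_fraction, noise_sd = noise_sd,
            bit_depth = as.integer(bit_depth))
  if (p$width < p$n_tergites || p$height < 1L) {
    stop("image too small for the requested tergite count", call. = FALSE)
  }
  if (p$base_gray + p$yellow_amplitude > 0.95) {
    stop("base_gray + yellow_amplitude must be <= 0.95 (marks would be ",
         "masked as saturated)", call. = FALSE)
  }
  fr <- c(p$seam_fraction, p$yellow_band_fraction, p$highlight_fraction)
  if (any(fr < 0 | fr > 1) || p$noise_sd < 0 || p$yellow_amplitude < 0) {
    stop("fractions must be in [0,1]; amplitudes and noise_sd >= 0",
         call. = FALSE)
  }
  if (!p$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16",
                                         call. = FALSE)
  structure(p, class = "synth_params")
}

# Noise-free column template: base gray with darkened seams and, optionally,
# brightened anterior bands on tergites 1..3. `extra` is an additive global
# brightness (temperature effect + per-specimen variation).
template_columns <- function(width, params, band_amplitude = NULL,
                             extra = 0) {
  if (is.null(band_amplitude)) band_amplitude <- params$yellow_amplitude
  tmpl <- rep(params$base_gray + extra, width)
  bounds <- round(seq(0, width, length.out = params$n_tergites + 1))
  marked <- seq_len(min(3L, params$n_tergites))
  for (s in seq_len(params$n_tergites)) {
    lo <- bounds[s] + 1L; hi <- bounds[s + 1]
    seg_w <- hi - lo + 1L
    if (band_amplitude > 0 && s %in% marked) {
      n_band <- round(params$yellow_band_fraction * seg_w)
      if (n_band > 0) {
        tmpl[lo:(lo + n_band - 1L)] <- tmpl[lo:(lo + n_band - 1L)] +
          band_amplitude
      }
    }
    n_seam <- round(params$seam_fraction * seg_w)
    if (n_seam > 0) {
      tmpl[(hi - n_seam + 1L):hi] <- tmpl[(hi - n_seam + 1L):hi] -
        params$seam_darkening
    }
  }
  pmin(pmax(tmpl, 0), 1)
}

# Fraction of columns carrying a yellow mark under `params` (used to convert
# a mean-gray group effect into a band amplitude).
band_coverage <- function(params) {
  params$yellow_band_fraction * min(3L, params$n_tergites) / params$n_tergites
}

#' Generate one synthetic abdomen ROI image
#'
#' Rasterizes the column template of [synth_params()] into an RGB
#' `bee_image`: per-pixel Gaussian noise, a `highlight_fraction` of pixels
#' saturated to 1.0, values clipped to `[0,1]` and quantized to the bit
#' depth. The ground-truth profile is the noise-free, highlight-free column
#' value after quantization — exactly what a perfect extraction would
#' recover.
#'
#' @param params A `synth_params`.
#' @param image_id Identifier for the generated image.
#' @param seed Optional integer seed.
#' @param extra Additive brightness offset applied to the whole template
#'   (group effects, specimen-level variation).
#' @param band_amplitude Overrides `params$yellow_amplitude` when not `NULL`.
#' @return List with `image` (a `bee_image`) and `truth` (numeric vector of
#'   length `width`).
#' @export
generate_abdomen_image <- function(params = synth_params(),
                                   image_id = "synthetic", seed = NULL,
                                   extra = 0, band_amplitude = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (!is.null(seed)) set.seed(seed)
  maxval <- 2^params$bit_depth - 1
  tmpl <- template_columns(params$width, params, band_amplitude, extra)
  truth <- round(tmpl * maxval) / maxval
  m <- matrix(rep(tmpl, each = params$height),
              nrow = params$height, ncol = params$width)
  if (params$noise_sd > 0) {
    m <- m + stats::rnorm(length(m), sd = params$noise_sd)
  }
  if (params$highlight_fraction > 0) {
    n_hl <- round(params$highlight_fraction * length(m))
    if (n_hl > 0) m[sample.int(length(m), n_hl)] <- 1
  }
  m <- pmin(pmax(m, 0), 1)
  q <- as.integer(round(m * maxval))
  pixels <- array(q, dim = c(params$height, params$width, 3L))
  list(image = new_bee_image(pixels, params$bit_depth, image_id),
       truth = truth)
}

#' Describe the four-group experimental design
#'
#' The study design: two colonies of origin ("gray" and "yellow", the latter
#' carrying brighter marks on the anterior tergites) crossed with two brood
#' incubation temperatures (30 and 34 deg C), `n_per_group` specimens each.
#'
#' @param n_per_group Specimens per group (default 50, i.e. 200 total).
#' @param origin_effect Mean-gray increase of the yellow colony, achieved by
#'   brightening its tergite marks (default 0.006; about +12 index units at
#'   profile length 1998).
#' @param temperature_effect Global mean-gray increase at 34 deg C
#'   (default 0.002).
#' @param specimen_sd SD of the per-specimen global brightness offset
#'   (biological + imaging variation between bees; default 0.0105, giving a
#'   within-group index SD near 21 at length 1998).
#' @return A `group_design` list.
#' @export
group_design <- function(n_per_group = 50L, origin_effect = 0.006,
                         temperature_effect = 0.002, specimen_sd = 0.0105) {
  structure(list(n_per_group = as.integer(n_per_group),
                 origin_effect = origin_effect,
                 temperature_effect = temperature_effect,
                 specimen_sd = specimen_sd),
            class = "group_design")
}

design_meta <- function(design) {
  groups <- expand.grid(temperature = c("30", "34"),
                        colony = c("gray", "yellow"),
                        stringsAsFactors = FALSE)
  meta <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    data.frame(
      specimen_id = sprintf("bee_%s%s_%03d", groups$temperature[g],
                            groups$colony[g], seq_len(design$n_per_group)),
      colony = groups$colony[g], temperature = groups$temperature[g],
      stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  meta
}

# Per-specimen template modifiers: the yellow colony's mark amplitude is the
# design's mean-gray effect divided by the mark coverage, so the effect is
# expressed on the same mean-gray scale as the temperature effect.
specimen_effects <- function(meta, design, params) {
  if (design$origin_effect != 0 && band_coverage(params) == 0) {
    stop("origin_effect requires a non-zero yellow_band_fraction",
         call. = FALSE)
  }
  amp <- ifelse(meta$colony == "yellow",
                params$yellow_amplitude +
                  design$origin_effect / band_coverage(params),
                params$yellow_amplitude)
  extra <- ifelse(meta$temperature == "34", design$temperature_effect, 0) +
    stats::rnorm(nrow(meta), sd = design$specimen_sd)
  list(band_amplitude = amp, extra = extra)
}

#' Generate a full synthetic image dataset
#'
#' Simulates the study: `4 * n_per_group` abdomen images with known group
#' effects, random abdomen widths (uniform on `[0.75 L, L]` columns so that
#' length equalization is exercised), full-frame ROIs, metadata, and
#' ground-truth coloration indices (trapezoidal area of the equalized
#' noise-free profile).
#'
#' @param design A `group_design`.
#' @param params A `synth_params`; its `width` is the maximum abdomen length
#'   `L`.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, images are written there as PNGs (with
#'   `rois.csv`, `meta.csv`, `truth.csv`) and not kept in memory.
#' @return List with `meta` (data.frame), `truth` (data.frame of ground-truth
#'   indices), `rois` (named list), and either `images` (named list of
#'   `bee_image`) or `paths` (written files).
#' @export
generate_dataset <- function(design = group_design(),
                             params = synth_params(), seed = 1L,
                             out_dir = NULL) {
  stopifnot(inherits(design, "group_design"), inherits(params, "synth_params"))
  set.seed(sub_seed(seed, "dataset"))
  meta <- design_meta(design)
  n <- nrow(meta)
  eff <- specimen_effects(meta, design, params)
  widths <- as.integer(round(stats::runif(n, 0.75 * params$width,
                                          params$width)))
  L <- params$width
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  images <- if (write_out) NULL else vector("list", n)
  paths <- character(n)
  truth_index <- numeric(n)
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- params
    pi$width <- widths[i]
    gen <- generate_abdomen_image(pi, image_id = meta$specimen_id[i],
                                  extra = eff$extra[i],
                                  band_amplitude = eff$band_amplitude[i])
    truth_index[i] <- coloration_index(suppressWarnings(
      equalize_length(gen$truth, L)))
    rois[[i]] <- roi_rect(meta$specimen_id[i], 0L, 0L, widths[i],
                          params$height)
    if (write_out) {
      paths[i] <- file.path(out_dir, paste0(meta$specimen_id[i], ".png"))
      write_image(gen$image, paths[i])
    } else {
      images[[i]] <- gen$image
    }
  }
  names(rois) <- meta$specimen_id
  truth <- data.frame(specimen_id = meta$specimen_id, index = truth_index,
                      stringsAsFactors = FALSE)
  if (write_out) {
    roi_df <- data.frame(image_id = meta$specimen_id,
                         x0 = 0L, y0 = 0L, x1 = widths,
                         y1 = params$height)
    utils::write.csv(roi_df, file.path(out_dir, "rois.csv"),
                     row.names = FALSE)
    utils::write.csv(meta, file.path(out_dir, "meta.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    list(meta = meta, truth = truth, rois = rois, paths = paths,
         dir = out_dir)
  } else {
    names(images) <- meta$specimen_id
    list(meta = meta, truth = truth, rois = rois, images = images)
  }
}

#' Generate synthetic coloration profiles directly
#'
#' Fast path for simulation studies: the same group structure as
#' [generate_dataset()] without rasterizing images. Each specimen's profile
#' is its noise-free column template at a random width (uniform on
#' `[0.75 L, L]`), plus a per-specimen brightness offset and per-column
#' noise emulating the sampling error of column medians, then equalized to
#' length `L`.
#'
#' @param design A `group_design`.
#' @param L Target profile length (default 1998).
#' @param params A `synth_params` (its `width` is ignored; `L` rules).
#' @param profile_noise_sd Per-column noise SD (default 0.004, matching the
#'   column-median sampling error of the default image parameters).
#' @param seed Integer seed.
#' @return List with `profiles` (matrix `4*n_per_group x L`) and `meta`.
#' @export
generate_profiles <- function(design = group_design(), L = 1998L,
                              params = synth_params(),
                              profile_noise_sd = 0.004, seed = 1L) {
  set.seed(sub_seed(seed, "profiles"))
  meta <- design_meta(design)
  n <- nrow(meta)
  eff <- specimen_effects(meta, design, params)
  widths <- as.integer(round(stats::runif(n, 0.75 * L, L)))
  profiles <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    pi <- params
    pi$width <- widths[i]
    v <- template_columns(widths[i], pi,
                          band_amplitude = eff$band_amplitude[i],
                          extra = eff$extra[i])
    if (profile_noise_sd > 0) {
      v <- v + stats::rnorm(widths[i], sd = profile_noise_sd)
    }
    v <- pmin(pmax(v, 1e-6), 0.95)
    profiles[i, ] <- equalize_length(v, L)
  }
  rownames(profiles) <- meta$specimen_id
  list(profiles = profiles, meta = meta)
}
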