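#' Coloration index of a profile
#'
#' The single-value summary of abdominal coloration: the area under the
#' coloration profile, with gray value on the y axis and position along the
#' abdomen on the x axis. Positions are vector indices with unit spacing, so
#' a constant profile `c` of length `L` has index `c * (L - 1)` and typical
#' full-length profiles (L = 1998, mean gray around 0.22) land near 450.
#' Higher index means a lighter abdomen.
#'
#' @param p A `fixed_profile` or complete numeric vector, length >= 2.
#' @return The trapezoidal area (scalar).
#' @export
coloration_index <- function(p) {
  v <- as.numeric(p)
  if (length(v) < 2L) stop("profile must have length >= 2", call. = FALSE)
  if (anyNA(v)) stop("profile contains missing values", call. = FALSE)
  pracma::trapz(seq_along(v) - 1, v)
}

#' Coloration indices for a profile matrix
#'
#' @param profiles Numeric matrix, one profile per row (rownames = ids).
#' @return A data.frame with columns `specimen_id` and `index`.
#' @export
coloration_indices <- function(profiles) {
  stopifnot(is.matrix(profiles))
  data.frame(
    specimen_id = if (!is.null(rownames(profiles))) rownames(profiles)
                  else as.character(seq_len(nrow(profiles))),
    index = apply(profiles, 1, coloration_index),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Group summary table of coloration indices
#'
#' One row per colony x temperature group with N, mean, SD (n-1 denominator),
#' min, max and SE = SD / sqrt(N).
#'
#' @param indices data.frame with `specimen_id` and `index` columns.
#' @param meta data.frame with `specimen_id`, `colony` (gray/yellow) and
#'   `temperature` (30/34) columns; every specimen in `indices` must appear.
#' @return data.frame with columns `group, n, mean, sd, min, max, se`,
#'   one row per occupied group.
#' @export
summarize_groups <- function(indices, meta) {
  stopifnot(all(c("specimen_id", "index") %in% names(indices)),
            all(c("specimen_id", "colony", "temperature") %in% names(meta)))
  missing_meta <- setdiff(indices$specimen_id, meta$specimen_id)
  if (length(missing_meta)) {
    stop("no metadata for specimen(s): ",
         paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  d <- merge(indices, meta, by = "specimen_id")
  d$group <- paste0(d$temperature, d$colony)
  groups <- split(d$index, d$group)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = stats::sd(x), min = min(x), max = max(x),
               se = stats::sd(x) / sqrt(length(x)),
               stringsAsFactors = FALSE)
  }))
  out[order(out$group), , drop = FALSE]
}
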