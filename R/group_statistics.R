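#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk tests of the pooled two-way-model residuals and of each group,
#' plus variance-homogeneity checks across the four colony x temperature
#' groups: pairwise F-ratio tests (the largest variance ratio is reported)
#' or, alternatively, Levene's test.
#'
#' @param values Numeric vector of coloration indices.
#' @param colony,temperature Factors (or coercible), one entry per value.
#' @param variance_test `"pairwise_f"` (default) or `"levene"`.
#' @return List with `shapiro_residuals_p`, `shapiro_group_p` (named vector),
#'   `variance` (data.frame of pairwise F tests, or the Levene table),
#'   `max_variance_ratio`, and `variance_p` (minimum pairwise p, or Levene p).
#' @export
check_assumptions <- function(values, colony, temperature,
                              variance_test = c("pairwise_f", "levene")) {
  variance_test <- match.arg(variance_test)
  colony <- factor(colony); temperature <- factor(temperature)
  group <- interaction(temperature, colony, sep = "", lex.order = FALSE)
  ns <- table(group)
  if (any(ns < 3L)) {
    stop("each group needs n >= 3 for the normality check", call. = FALSE)
  }
  fit <- stats::lm(values ~ colony * temperature)
  shapiro_res <- stats::shapiro.test(stats::residuals(fit))$p.value
  shapiro_grp <- vapply(split(values, group),
                        function(x) stats::shapiro.test(x)$p.value,
                        numeric(1))
  vars <- vapply(split(values, group), stats::var, numeric(1))
  max_ratio <- max(vars) / min(vars)
  if (variance_test == "pairwise_f") {
    gs <- names(vars)
    pairs <- utils::combn(gs, 2)
    vt <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ft <- stats::var.test(values[group == a], values[group == b])
      data.frame(group1 = a, group2 = b,
                 ratio = unname(ft$estimate), p = ft$p.value,
                 stringsAsFactors = FALSE)
    }))
    var_p <- min(vt$p)
  } else {
    lv <- car::leveneTest(values ~ group)
    vt <- as.data.frame(lv)
    var_p <- lv[["Pr(>F)"]][1]
  }
  list(shapiro_residuals_p = shapiro_res, shapiro_group_p = shapiro_grp,
       variance = vt, max_variance_ratio = max_ratio, variance_p = var_p)
}

#' Box-Cox power transform
#'
#' Chooses the power-transform parameter lambda by profile maximum likelihood
#' (on a grid, refined around the optimum) and applies
#' `(x^lambda - 1) / lambda` (natural log at lambda = 0). The transform is
#' monotone increasing in the original values, so it changes the scale of the
#' index without reordering specimens.
#'
#' @param values Strictly positive numeric vector.
#' @param lambda Optional fixed lambda; `NULL` (default) estimates it.
#' @param lambda_grid Search grid when estimating (default `seq(-2, 2, 0.01)`).
#' @return List of class `bee_boxcox`: `lambda`, `transformed`,
#'   `log_likelihood`.
#' @export
boxcox_transform <- function(values, lambda = NULL,
                             lambda_grid = seq(-2, 2, by = 0.01)) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox requires strictly positive values", call. = FALSE)
  }
  if (is.null(lambda)) {
    bc <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
    ll <- max(bc$y)
  } else {
    bc <- MASS::boxcox(values ~ 1, lambda = lambda, plotit = FALSE)
    ll <- bc$y[1]
  }
  transformed <- if (abs(lambda) < 1e-12) log(values)
                 else (values^lambda - 1) / lambda
  structure(list(lambda = lambda, transformed = transformed,
                 log_likelihood = ll),
            class = "bee_boxcox")
}

#' @export
print.bee_boxcox <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.3f (profile logLik %.2f)\n",
              x$lambda, x$log_likelihood))
  invisible(x)
}

#' Two-way factorial ANOVA with interaction
#'
#' Fits `values ~ colony * temperature` and tests the two main effects and
#' their interaction with Type II sums of squares (invariant to factor order;
#' identical to Type I under a balanced design).
#'
#' @param values Numeric response (coloration indices, possibly transformed).
#' @param colony,temperature Factors, 2 x 2 factorial with every cell n >= 2.
#' @return data.frame with one row per term (`colony`, `temperature`,
#'   `colony:temperature`, `Residuals`) and columns `sum_sq, df, f, p`.
#' @export
two_way_anova <- function(values, colony, temperature) {
  colony <- factor(colony); temperature <- factor(temperature)
  if (nlevels(colony) != 2L || nlevels(temperature) != 2L) {
    stop("two_way_anova needs a 2 x 2 factorial (both factors with 2 levels)",
         call. = FALSE)
  }
  cells <- table(colony, temperature)
  if (any(cells < 2L)) {
    stop("every colony x temperature cell needs n >= 2", call. = FALSE)
  }
  fit <- stats::lm(values ~ colony * temperature)
  a2 <- car::Anova(fit, type = 2)
  data.frame(term = rownames(a2),
             sum_sq = a2[["Sum Sq"]],
             df = a2[["Df"]],
             f = a2[["F value"]],
             p = a2[["Pr(>F)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise contrasts between the experimental groups with
#' studentized-range adjusted p-values (6 contrasts for 4 groups).
#'
#' @param values Numeric response.
#' @param group Factor of group labels (e.g. "30gray" ... "34yellow").
#' @return data.frame with columns `pair, estimate, lwr, upr, p_adj`.
#' @export
tukey_hsd <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stop("Tukey HSD needs >= 2 groups with n >= 2 each", call. = FALSE)
  }
  fit <- stats::aov(values ~ group)
  tk <- stats::TukeyHSD(fit)$group
  data.frame(pair = rownames(tk), estimate = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full inferential chain on coloration indices
#'
#' Runs the assumption checks, conditionally Box-Cox transforms the indices
#' when the Shapiro-Wilk test of the two-way-model residuals rejects
#' normality at `alpha`, then fits the two-way ANOVA (colony, temperature and
#' their interaction) and the Tukey HSD post-hoc comparisons on the same
#' (possibly transformed) scale.
#'
#' @param indices data.frame with `specimen_id` and `index`.
#' @param meta data.frame with `specimen_id`, `colony`, `temperature`.
#' @param alpha Significance level gating the transform (default 0.05).
#' @param force_transform `NULL` (decide from the Shapiro test), `TRUE`, or
#'   `FALSE`.
#' @return A `bee_inference` object: list with `assumptions`, `transform`
#'   (`"none"` or `"boxcox"`), `lambda`, `anova` (term table), `tukey`
#'   (pairwise table), `alpha`, `n`.
#' @export
run_inference <- function(indices, meta, alpha = 0.05,
                          force_transform = NULL) {
  stopifnot(all(c("specimen_id", "index") %in% names(indices)))
  missing_meta <- setdiff(indices$specimen_id, meta$specimen_id)
  if (length(missing_meta)) {
    stop("no metadata for specimen(s): ",
         paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  d <- merge(indices, meta, by = "specimen_id")
  d$colony <- factor(d$colony)
  d$temperature <- factor(d$temperature)
  d$group <- factor(paste0(d$temperature, d$colony))

  assum <- check_assumptions(d$index, d$colony, d$temperature)
  do_transform <- if (is.null(force_transform)) {
    assum$shapiro_residuals_p < alpha
  } else isTRUE(force_transform)

  lambda <- NULL
  y <- d$index
  if (do_transform) {
    bc <- boxcox_transform(d$index)
    y <- bc$transformed
    lambda <- bc$lambda
  }
  an <- two_way_anova(y, d$colony, d$temperature)
  tk <- tukey_hsd(y, d$group)
  structure(list(assumptions = assum,
                 transform = if (do_transform) "boxcox" else "none",
                 lambda = lambda, anova = an, tukey = tk,
                 alpha = alpha, n = nrow(d)),
            class = "bee_inference")
}

#' @export
print.bee_inference <- function(x, digits = 4, ...) {
  cat(sprintf("Coloration-index inference (n = %d)\n", x$n))
  cat(sprintf("  residual normality: Shapiro p = %.3g -> transform: %s%s\n",
              x$assumptions$shapiro_residuals_p, x$transform,
              if (!is.null(x$lambda)) sprintf(" (lambda = %.3f)", x$lambda)
              else ""))
  cat("  ANOVA (Type II):\n")
  an <- x$anova[x$anova$term != "Residuals", ]
  for (i in seq_len(nrow(an))) {
    cat(sprintf("    %-22s F(%d) = %8.3f, p = %.3g\n",
                an$term[i], an$df[i], an$f[i], an$p[i]))
  }
  cat("  Tukey HSD:\n")
  for (i in seq_len(nrow(x$tukey))) {
    cat(sprintf("    %-18s diff = %8.3f, adj p = %.3g\n",
                x$tukey$pair[i], x$tukey$estimate[i], x$tukey$p_adj[i]))
  }
  invisible(x)
}
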