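test_that("Box-Cox transform obeys its closed forms and finds log for lognormal", {
  x <- c(0.5, 1, 2, 5, 10)
  expect_equal(boxcox_transform(x, lambda = 1)$transformed, x - 1)
  expect_equal(boxcox_transform(x, lambda = 0)$transformed, log(x))
  expect_error(boxcox_transform(c(1, 0, 2)), "strictly positive")
  expect_error(boxcox_transform(c(1, -3)), "strictly positive")

  set.seed(41)
  y <- exp(rnorm(500, mean = 1, sd = 0.6))
  bc <- boxcox_transform(y)
  expect_gte(bc$lambda, -0.3); expect_lte(bc$lambda, 0.3)
  # monotone increasing in the original values
  expect_true(all(diff(bc$transformed[order(y)]) >= 0))
})

test_that("two-way ANOVA: Type II equals Type I under balance", {
  set.seed(42)
  colony <- rep(c("gray", "yellow"), each = 40)
  temperature <- rep(rep(c("30", "34"), each = 20), 2)
  y <- rnorm(80) + (colony == "yellow") * 0.8
  res <- two_way_anova(y, colony, temperature)
  expect_setequal(res$term, c("colony", "temperature",
                              "colony:temperature", "Residuals"))
  expect_equal(res$df[res$term == "Residuals"], 80 - 4)

  a1 <- stats::anova(stats::lm(y ~ factor(colony) * factor(temperature)))
  expect_equal(res$f[match(c("colony", "temperature", "colony:temperature"),
                           res$term)],
               a1[["F value"]][1:3], tolerance = 1e-10)
  expect_equal(res$p[match(c("colony", "temperature", "colony:temperature"),
                           res$term)],
               a1[["Pr(>F)"]][1:3], tolerance = 1e-10)

  expect_error(two_way_anova(y[1:3], colony[1:3], temperature[1:3]),
               "2 x 2 factorial")
  small <- data.frame(col = c("g", "g", "g", "y", "y", "y"),
                      temp = c("30", "34", "34", "30", "30", "34"))
  expect_error(two_way_anova(rnorm(6), small$col, small$temp), "n >= 2")
})

test_that("assumption checks report Shapiro and variance-homogeneity results", {
  set.seed(43)
  colony <- rep(c("gray", "yellow"), each = 40)
  temperature <- rep(rep(c("30", "34"), each = 20), 2)
  y <- rnorm(80, mean = 100, sd = 5)
  a <- check_assumptions(y, colony, temperature)
  expect_true(a$shapiro_residuals_p > 0 && a$shapiro_residuals_p <= 1)
  expect_length(a$shapiro_group_p, 4)
  expect_equal(nrow(a$variance), 6)  # pairwise F tests over 4 groups
  expect_gte(a$max_variance_ratio, 1)

  # identical samples in every group: all variance ratios exactly 1
  y_id <- rep(c(1, 2, 3, 4, 5), 16)
  a_id <- check_assumptions(y_id, colony, temperature)
  expect_equal(a_id$max_variance_ratio, 1)
  expect_true(all(abs(a_id$variance$ratio - 1) < 1e-12))

  # strongly non-normal data is flagged
  y_exp <- rexp(80, rate = 2)
  a_exp <- check_assumptions(y_exp, colony, temperature)
  expect_lt(a_exp$shapiro_residuals_p, 0.05)

  lev <- check_assumptions(y, colony, temperature,
                           variance_test = "levene")
  expect_true(lev$variance_p > 0 && lev$variance_p <= 1)
})

test_that("Tukey HSD produces all pairwise contrasts with adjusted p-values", {
  set.seed(44)
  group <- rep(c("30gray", "30yellow", "34gray", "34yellow"), each = 50)
  y <- rnorm(200) + (group %in% c("30yellow", "34yellow")) * 5
  tk <- tukey_hsd(y, group)
  expect_equal(nrow(tk), choose(4, 2))
  expect_lt(tk$p_adj[tk$pair == "30yellow-30gray"], 0.001)

  # adjusted p >= unadjusted pairwise t-test p for every contrast
  for (i in seq_len(nrow(tk))) {
    gs <- strsplit(tk$pair[i], "-", fixed = TRUE)[[1]]
    praw <- stats::t.test(y[group == gs[1]], y[group == gs[2]],
                          var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[i] + 1e-12, praw)
  }
  expect_error(tukey_hsd(y[1:2], group[1:2]), ">= 2 groups")
})

test_that("run_inference transforms conditionally and reports the full chain", {
  set.seed(45)
  meta <- data.frame(
    specimen_id = sprintf("s%03d", 1:200),
    colony = rep(c("gray", "yellow"), each = 100),
    temperature = rep(rep(c("30", "34"), each = 50), 2))

  idx_norm <- data.frame(specimen_id = meta$specimen_id,
                         index = rnorm(200, 450, 20))
  inf <- run_inference(idx_norm, meta)
  expect_s3_class(inf, "bee_inference")
  expect_equal(inf$transform, "none")
  expect_null(inf$lambda)
  expect_setequal(inf$anova$term,
                  c("colony", "temperature", "colony:temperature",
                    "Residuals"))
  expect_equal(nrow(inf$tukey), 6)
  expect_true(all(inf$anova$p[!is.na(inf$anova$p)] >= 0 &
                    inf$anova$p[!is.na(inf$anova$p)] <= 1))

  idx_skew <- data.frame(specimen_id = meta$specimen_id,
                         index = exp(rnorm(200, 6, 0.8)))
  inf_sk <- run_inference(idx_skew, meta)
  expect_equal(inf_sk$transform, "boxcox")
  expect_true(is.finite(inf_sk$lambda))

  expect_error(run_inference(rbind(idx_norm,
                                   data.frame(specimen_id = "zz", index = 1)),
                             meta), "no metadata.*zz")
  expect_output(print(inf), "transform: none")
})

test_that("a strong colony effect is detected while a null temperature is not", {
  set.seed(46)
  hits_col <- hits_temp <- 0L
  for (rep in 1:40) {
    gp <- generate_profiles(group_design(n_per_group = 25,
                                         origin_effect = 0.012,
                                         temperature_effect = 0),
                            L = 150, seed = 1000 + rep)
    inf <- run_inference(coloration_indices(gp$profiles), gp$meta)
    hits_col <- hits_col + (inf$anova$p[inf$anova$term == "colony"] < 0.05)
    hits_temp <- hits_temp +
      (inf$anova$p[inf$anova$term == "temperature"] < 0.05)
  }
  expect_gte(hits_col, 36)   # ~1.1 SD effect, n = 50/colony arm
  expect_lte(hits_temp, 8)   # null term stays near nominal alpha
})
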