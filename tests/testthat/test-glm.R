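test_that("design matrices have the specified shape and contrasts", {
  rec <- fake_records(6)
  d <- build_design(rec, "group_compare")
  expect_equal(dim(d$X), c(12, 6))  # 2 indicators + 4 covariates
  expect_named(d$contrasts, "HC-AD")
  expect_equal(sum(d$contrasts[[1]] != 0), 2)

  da <- build_design(rec, "ageing")
  expect_equal(colnames(da$X), c("intercept", "age", "sex", "scanner"))
  expect_equal(da$effect_cols, "age")

  db <- build_design(fake_records(5), "beta_ageing_by_group")
  expect_true(all(c("age_HC", "age_AD") %in% colnames(db$X)))
  expect_named(db$contrasts, "age_HC-age_AD")
})

test_that("swapping group labels negates the cope", {
  rec <- fake_records(6)
  set.seed(30)
  y <- rnorm(12) + 0.8 * (rec$group == "AD")
  d <- build_design(rec, "group_compare")
  f1 <- fit_glm(y, d$X, d$contrasts[[1]])
  rec2 <- rec
  rec2$group <- ifelse(rec$group == "HC", "AD", "HC")
  d2 <- build_design(rec2, "group_compare")
  # the same HC-AD contrast applied to swapped labels flips the cope sign
  w <- as.numeric(colnames(d2$X) == "group_HC") -
    as.numeric(colnames(d2$X) == "group_AD")
  f2 <- fit_glm(y, d2$X, w)
  expect_equal(f2$cope, -f1$cope, tolerance = 1e-10)
})

test_that("a single-scanner cohort drops the constant column with a warning", {
  rec <- fake_records(5, scanners = "A")
  expect_warning(d <- build_design(rec, "group_compare"), "scanner")
  expect_false("scanner" %in% colnames(d$X))
})

test_that("the group contrast reduces to the pooled two-sample t-test", {
  set.seed(31)
  rec <- fake_records(10)
  y <- rnorm(20) + 1 * (rec$group == "AD")
  X <- cbind(group_HC = as.numeric(rec$group == "HC"),
             group_AD = as.numeric(rec$group == "AD"))
  f <- fit_glm(y, X, c(1, -1))
  tt <- t.test(y[rec$group == "HC"], y[rec$group == "AD"], var.equal = TRUE)
  expect_equal(f$cope, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  expect_equal(f$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(f$df, 18)
})

test_that("the age cope recovers a known simulated slope", {
  set.seed(32)
  hits <- vapply(1:100, function(i) {
    rec <- fake_records(200, groups = "HC", seed = 1000 + i)
    y <- 0.3 * rec$age + rnorm(200)
    d <- build_design(rec, "ageing")
    f <- fit_glm(y, d$X, d$contrasts$age)
    abs(f$cope - 0.3) <= 2 * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.90)  # nominal 95 % coverage
})

test_that("duplicating every subject leaves the cope unchanged", {
  set.seed(33)
  rec <- fake_records(6)
  y <- rnorm(12)
  d <- build_design(rec, "group_compare")
  f1 <- fit_glm(y, d$X, d$contrasts[[1]])
  f2 <- fit_glm(rep(y, 2), rbind(d$X, d$X), d$contrasts[[1]])
  expect_equal(f2$cope, f1$cope, tolerance = 1e-10)
})

test_that("an effect exceeding every null maximum attains the minimal p-value", {
  set.seed(34)
  rec <- fake_records(15)
  d <- build_design(rec, "group_compare")
  Y <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, paste0("cell", 1:5)))
  Y[, 3] <- Y[, 3] + 10 * (rec$group == "AD")
  res <- maxt_permutation(Y, d, n_perm = 500, seed = 1)
  expect_equal(min(res$p_fwe), 1 / 501, tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(td$cell[which.min(td$p_fwe)], "cell3")
  expect_lt(td$cope[td$cell == "cell3"], 0)  # HC-AD of an AD increase
})

test_that("max-t correction dominates the single-cell permutation p-value", {
  set.seed(35)
  rec <- fake_records(12)
  d <- build_design(rec, "group_compare")
  Y <- matrix(rnorm(24 * 6), 24, 6,
              dimnames = list(NULL, paste0("cell", 1:6)))
  Y[, 1] <- Y[, 1] + 1.2 * (rec$group == "AD")
  res_all <- maxt_permutation(Y, d, n_perm = 300, seed = 2)
  for (j in 1:6) {
    res_j <- maxt_permutation(Y[, j, drop = FALSE], d, n_perm = 300, seed = 2)
    expect_gte(res_all$p_fwe[1, j] + 1e-12, res_j$p_fwe[1, 1])
  }
})

test_that("statistics are invariant under a joint row permutation of data and design", {
  set.seed(36)
  rec <- fake_records(10)
  d <- build_design(rec, "group_compare")
  Y <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("c", 1:4)))
  perm <- sample(20)
  r1 <- maxt_permutation(Y, d, n_perm = 200, seed = 3)
  d2 <- d; d2$X <- d$X[perm, ]
  r2 <- maxt_permutation(Y[perm, ], d2, n_perm = 200, seed = 3)
  expect_equal(r2$t, r1$t, tolerance = 1e-10)
  expect_equal(r2$cope, r1$cope, tolerance = 1e-10)
})

test_that("corrected p-values stabilise across permutation seeds", {
  set.seed(37)
  rec <- fake_records(20)
  d <- build_design(rec, "group_compare")
  Y <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("c", 1:8)))
  Y[, 2] <- Y[, 2] + 0.9 * (rec$group == "AD")
  r1 <- maxt_permutation(Y, d, n_perm = 5000, seed = 101)
  r2 <- maxt_permutation(Y, d, n_perm = 5000, seed = 202)
  expect_lt(max(abs(r1$p_fwe - r2$p_fwe)), 0.01)
})

test_that("tiny cohorts warn about exhausted permutations", {
  set.seed(39)
  X <- cbind(group_HC = rep(c(1, 0), each = 2),
             group_AD = rep(c(0, 1), each = 2))
  d <- list(X = X, contrasts = list(`HC-AD` = c(1, -1)),
            effect_cols = colnames(X))
  Y <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(maxt_permutation(Y, d, n_perm = 100, seed = 1),
                 "replacement")
})

test_that("degrees of freedom: operative rank-based value and report formula", {
  rec <- fake_records(10)
  d <- build_design(rec, "ageing")
  rep1 <- residual_df_report(20, d$X, 1)
  expect_equal(rep1$df_operative, 20 - 4)

  X1 <- matrix(1, 20, 1)
  expect_equal(residual_df_report(20, X1, 0)$df_operative, 19)

  # a rank-8 design over 191 subjects leaves 183 operative df
  set.seed(38)
  X8 <- cbind(1, matrix(rnorm(191 * 7), 191, 7))
  expect_equal(residual_df_report(191, X8, 1)$df_operative, 183)

  # formula echo: n - (n_comparisons + n_regressors - 1 + 1)
  expect_equal(residual_df_report(100, X8, 3)$df_formula, 100 - (3 + 8))
})

test_that("sex-balance chi-squared matches the classical Pearson statistic", {
  # proportional table -> 0
  prop <- cbind(male = c(10, 20), female = c(30, 60))
  expect_equal(chi_squared_sex_balance(prop)$statistic, 0, tolerance = 1e-12)

  sq <- chi_squared_sex_balance(cbind(c(10, 10), c(10, 10)))
  expect_equal(sq$statistic, 0)
  expect_equal(sq$df, 1)

  expect_error(chi_squared_sex_balance(cbind(c(0, 0), c(5, 5))),
               "zero-margin")
})
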