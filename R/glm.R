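#' Build a design matrix and contrasts for a cohort analysis
#'
#' Three standard designs over the subject covariate table:
#'
#' * `"ageing"`: intercept, age, plus centred sex and scanner nuisance
#'   columns; the contrast picks out the age slope.
#' * `"group_compare"`: one indicator column per group (no separate
#'   intercept) plus centred age, sex, scanner and grey-matter-volume
#'   nuisance columns; one pairwise `+1/-1` contrast per group pair.
#' * `"beta_ageing_by_group"`: per-group indicators plus per-group age-slope
#'   columns (centred age times group indicator); contrasts are pairwise
#'   differences of the age slopes, testing divergent ageing trajectories.
#'
#' Continuous and indicator nuisance covariates are mean-centred so group
#' indicators retain their group-mean interpretation.  A covariate that is
#' constant across the cohort (e.g. a single-scanner study) is dropped with a
#' warning rather than producing a rank-deficient design.
#'
#' @param records Covariate tibble with columns `subject_id`, `group`, `age`,
#'   `sex` (`"M"`/`"F"`), `scanner`, `gm_volume`.
#' @param analysis One of `"ageing"`, `"group_compare"`,
#'   `"beta_ageing_by_group"`.
#' @return List with `X` (design matrix, named columns), `contrasts` (named
#'   list of weight vectors) and `effect_cols` (columns permuted under the
#'   null by [maxt_permutation()]).
#' @export
build_design <- function(records,
                         analysis = c("ageing", "group_compare",
                                      "beta_ageing_by_group")) {
  analysis <- match.arg(analysis)
  if (anyNA(records[c("group", "age", "sex", "scanner", "gm_volume")])) {
    stop("missing covariates in records", call. = FALSE)
  }
  n <- nrow(records)
  centred <- function(x) x - mean(x)
  sex_c <- centred(as.numeric(records$sex == "M"))
  scan_c <- centred(as.numeric(records$scanner == sort(unique(records$scanner))[1]))
  age_c <- centred(records$age)
  gm_c <- centred(records$gm_volume)

  drop_constant <- function(X) {
    const <- apply(X, 2, function(col) stats::sd(col) == 0)
    # an all-ones intercept or group indicator block is legitimate
    const[colnames(X) %in% c("intercept", paste0("group_", unique(records$group)))] <- FALSE
    if (any(const)) {
      warning("dropping constant covariate column(s): ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
    X
  }

  if (analysis == "ageing") {
    X <- cbind(intercept = 1, age = records$age, sex = sex_c, scanner = scan_c)
    X <- drop_constant(X)
    contrasts <- list(age = as.numeric(colnames(X) == "age"))
    effect_cols <- "age"
  } else {
    groups <- unique(records$group)
    if (length(groups) < 2) stop("group designs need >= 2 groups", call. = FALSE)
    if (any(table(records$group) < 2)) {
      stop("each group needs >= 2 subjects", call. = FALSE)
    }
    ind <- sapply(groups, function(g) as.numeric(records$group == g))
    colnames(ind) <- paste0("group_", groups)
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    if (analysis == "group_compare") {
      X <- cbind(ind, age = age_c, sex = sex_c, scanner = scan_c,
                 gm_volume = gm_c)
      X <- drop_constant(X)
      contrasts <- lapply(pairs, function(pr) {
        w <- numeric(ncol(X))
        w[colnames(X) == paste0("group_", pr[1])] <- 1
        w[colnames(X) == paste0("group_", pr[2])] <- -1
        w
      })
      names(contrasts) <- vapply(pairs, paste, "", collapse = "-")
      effect_cols <- colnames(ind)
    } else {
      slope <- ind * age_c
      colnames(slope) <- paste0("age_", groups)
      X <- cbind(ind, slope)
      X <- drop_constant(X)
      contrasts <- lapply(pairs, function(pr) {
        w <- numeric(ncol(X))
        w[colnames(X) == paste0("age_", pr[1])] <- 1
        w[colnames(X) == paste0("age_", pr[2])] <- -1
        w
      })
      names(contrasts) <- vapply(pairs, function(pr)
        paste0("age_", pr[1], "-age_", pr[2]), "")
      effect_cols <- colnames(slope)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  }
  list(X = X, contrasts = contrasts, effect_cols = effect_cols)
}

#' Fit one metric with OLS and evaluate a contrast
#'
#' Ordinary least squares of a metric vector on the design, returning the
#' contrast of parameter estimates (cope), its standard error, the
#' t-statistic and the residual degrees of freedom `n - rank(X)`.
#'
#' @param y Metric vector over subjects.
#' @param X Design matrix (rows aligned with `y`).
#' @param contrast Weight vector over design columns.
#' @return Tibble `cope`, `se`, `t`, `df`.
#' @examples
#' X <- cbind(g1 = rep(1:0, each = 5), g2 = rep(0:1, each = 5))
#' fit_glm(rnorm(10), X, c(1, -1))
#' @export
fit_glm <- function(y, X, contrast) {
  stopifnot(length(y) == nrow(X), length(contrast) == ncol(X),
            any(contrast != 0))
  qrX <- qr(X)
  df <- nrow(X) - qrX$rank
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / df
  if (s2 == 0) stop("zero residual variance", call. = FALSE)
  cvc <- drop(t(contrast) %*% chol2inv(qr.R(qrX)) %*% contrast)
  cope <- drop(contrast %*% beta)
  se <- sqrt(s2 * cvc)
  tibble::tibble(cope = cope, se = se, t = cope / se, df = df)
}

# t-statistics for all outcome columns and all contrasts at once.
# Y: n x m matrix; returns list(t = m x n_contrast matrix, cope, se, df).
glm_tstats <- function(Y, X, contrasts) {
  qrX <- qr(X)
  df <- nrow(X) - qrX$rank
  beta <- qr.coef(qrX, Y)                      # k x m
  res <- Y - X %*% beta
  s2 <- colSums(res^2) / df                    # m
  XtXinv <- chol2inv(qr.R(qrX))
  C <- do.call(rbind, contrasts)               # n_contrast x k
  cope <- C %*% beta                           # n_contrast x m
  cvc <- rowSums((C %*% XtXinv) * C)           # n_contrast
  se <- sqrt(outer(cvc, s2))                   # n_contrast x m
  list(t = cope / se, cope = cope, se = se, df = df)
}

#' Max-t permutation GLM over a metric table
#'
#' Mass-univariate OLS over every metric cell (parcel x metric/band) with
#' family-wise error control by the maximum-statistic method: for each of
#' `n_perm` permutations the rows of the effect regressors (group indicators
#' for group contrasts, age for ageing contrasts) are permuted with nuisance
#' columns fixed, t-statistics are recomputed for every cell, and the maximum
#' `|t|` across all cells and contrasts forms the null distribution.  The
#' two-tailed FWE-corrected p-value for a cell is
#' `(1 + #permutation maxima >= |t_observed|) / (n_perm + 1)`.
#'
#' @param Y Subjects x cells numeric matrix (named columns).
#' @param design A list from [build_design()], or a list with `X`,
#'   `contrasts`, `effect_cols`.
#' @param n_perm Number of permutations (default 5000, minimum 100).
#' @param seed Integer seed for the permutation stream.
#' @return A `maxt_glm` object; see [tidy.maxt_glm()].
#' @export
maxt_permutation <- function(Y, design, n_perm = 5000, seed = 1) {
  stopifnot(is.matrix(Y), nrow(Y) == nrow(design$X), n_perm >= 100)
  X <- design$X
  n <- nrow(X)
  if (factorial(min(n, 170)) < n_perm) {
    warning("fewer distinct permutations than n_perm; sampling with ",
            "replacement")
  }
  obs <- glm_tstats(Y, X, design$contrasts)
  eff <- which(colnames(X) %in% design$effect_cols)
  if (length(eff) == 0) stop("effect columns not found in design", call. = FALSE)
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    Xp <- X
    Xp[, eff] <- X[sample(n), eff]
    max(abs(glm_tstats(Y, Xp, design$contrasts)$t))
  }, numeric(1))
  p <- matrix(0, nrow(obs$t), ncol(obs$t))
  for (i in seq_len(length(obs$t))) {
    p[i] <- (1 + sum(null_max >= abs(obs$t[i]))) / (n_perm + 1)
  }
  structure(
    list(cells = colnames(Y), contrasts = names(design$contrasts),
         cope = obs$cope, se = obs$se, t = obs$t, p_fwe = p, df = obs$df,
         null_max = null_max, n_perm = n_perm, seed = seed),
    class = "maxt_glm"
  )
}

#' Tidy max-t GLM results
#'
#' @param x A `maxt_glm`.
#' @param ... Unused.
#' @return Tibble with one row per (cell, contrast): `cell`, `contrast`,
#'   `cope`, `se`, `t`, `df`, `p_fwe`.
#' @export
tidy.maxt_glm <- function(x, ...) {
  tidyr::expand_grid(contrast = x$contrasts, cell = x$cells) |>
    dplyr::mutate(cope = as.vector(t(x$cope)), se = as.vector(t(x$se)),
                  t = as.vector(t(x$t)), df = x$df,
                  p_fwe = as.vector(t(x$p_fwe)))
}

#' One-row summary of a max-t GLM
#'
#' @param x A `maxt_glm`.
#' @param ... Unused.
#' @return Tibble: cells, contrasts, permutations, residual df, number of
#'   FWE-significant cells at 0.05, and the null 95th percentile of max |t|.
#' @export
glance.maxt_glm <- function(x, ...) {
  tibble::tibble(n_cells = length(x$cells),
                 n_contrasts = length(x$contrasts),
                 n_perm = x$n_perm, df = x$df,
                 n_significant = sum(x$p_fwe < 0.05),
                 null_q95 = unname(stats::quantile(x$null_max, 0.95)))
}

#' @export
print.maxt_glm <- function(x, ...) {
  cat("<maxt_glm> ", length(x$cells), " cells x ", length(x$contrasts),
      " contrast(s), ", x$n_perm, " permutations, df = ", x$df, "; ",
      sum(x$p_fwe < 0.05), " cell(s) FWE-significant at 0.05\n", sep = "")
  invisible(x)
}

#' Residual degrees of freedom, operative and as-reported
#'
#' Inference uses the operative residual degrees of freedom
#' `n - rank(X)`.  Published MEG reports sometimes state a bookkeeping
#' formula, `n - (n_comparisons + n_regressors - 1 + 1)`; that value is
#' echoed alongside for report parity.
#'
#' @param n_subjects Number of subjects.
#' @param X Design matrix.
#' @param n_comparisons Number of group comparisons in the report formula.
#' @return Tibble `df_operative`, `df_formula`.
#' @export
residual_df_report <- function(n_subjects, X, n_comparisons = 1) {
  stopifnot(n_subjects > 0, n_comparisons >= 0)
  n_regressors <- ncol(X)
  tibble::tibble(
    df_operative = n_subjects - qr(X)$rank,
    df_formula = n_subjects - (n_comparisons + n_regressors - 1 + 1)
  )
}

#' Chi-squared test of sex balance across groups
#'
#' Pearson chi-squared (no continuity correction) on a groups x sex count
#' table, the standard demographic balance check.
#'
#' @param counts Matrix or data frame: rows = groups, columns = male/female
#'   counts.  All row and column margins must be positive.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @examples
#' chi_squared_sex_balance(cbind(male = c(14, 15), female = c(15, 10)))
#' @export
chi_squared_sex_balance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero-margin row or column in the count table", call. = FALSE)
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}
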