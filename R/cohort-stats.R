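## Cohort-level statistics: bivariate OLS fits of density against
## demography and stress, Welch two-group comparisons with pairwise
## Bonferroni-corrected extensions, and percentage-difference summaries.

#' Validate a cohort table
#'
#' Checks the contract of a per-subject cohort table: unique ids, ages in
#' [20, 100], positive densities, gender/race levels.
#'
#' @param table data.frame with columns id, age, gender, race, bmi,
#'   weight_lbs, height_ft, height_m, density (others optional).
#' @return invisibly, `table`.
#' @export
validateCohort <- function(table) {
  need <- c("id", "age", "gender", "race", "bmi", "weight_lbs",
            "height_ft", "height_m", "density")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(table$id)) stop("duplicate subject ids", call. = FALSE)
  if (any(table$age < 20 | table$age > 100))
    stop("ages must lie within [20, 100]", call. = FALSE)
  if (any(table$density <= 0)) stop("densities must be > 0", call. = FALSE)
  if (!all(table$gender %in% c("female", "male")))
    stop("gender must be 'female' or 'male'", call. = FALSE)
  if (!all(table$race %in% c("Caucasian", "Black", "Asian", "Mixed")))
    stop("unknown race level", call. = FALSE)
  invisible(table)
}

#' Simple bivariate OLS fit
#'
#' Ordinary least squares of `y` on `x` via the closed-form normal
#' equations, with standard errors and R-squared.
#'
#' @param table data.frame.
#' @param x,y column names of the covariate and response.
#' @return a [BivariateFit-class].
#' @examples
#' d <- data.frame(a = 1:3, b = 2 * (1:3) + 1)
#' bivariateFit(d, "a", "b")  # slope 2, intercept 1, R^2 = 1
#' @export
bivariateFit <- function(table, x, y) {
  if (!x %in% names(table)) stop("unknown covariate: ", x, call. = FALSE)
  if (!y %in% names(table)) stop("unknown response: ", y, call. = FALSE)
  xv <- table[[x]]; yv <- table[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("need >= 3 finite observations", call. = FALSE)
  sxx <- sum((xv - mean(xv))^2)
  if (sxx == 0) stop("degenerate regressor: '", x, "' is constant",
                     call. = FALSE)
  sxy <- sum((xv - mean(xv)) * (yv - mean(yv)))
  slope <- sxy / sxx
  intercept <- mean(yv) - slope * mean(xv)
  resid <- yv - intercept - slope * xv
  syy <- sum((yv - mean(yv))^2)
  r2 <- if (syy == 0) 0 else 1 - sum(resid^2) / syy
  sigma2 <- sum(resid^2) / (n - 2)
  seSlope <- sqrt(sigma2 / sxx)
  seIntercept <- sqrt(sigma2 * (1 / n + mean(xv)^2 / sxx))
  new("BivariateFit", slope = slope, intercept = intercept,
      rSquared = max(0, min(1, r2)),
      se = c(slope = seSlope, intercept = seIntercept),
      n = as.integer(n), xName = x, yName = y)
}

#' Welch two-sample comparison of a value between two groups
#'
#' Welch's unequal-variance t test, with group means and SDs.
#'
#' @param table data.frame.
#' @param groupKey grouping column with exactly two levels present.
#' @param value numeric column to compare.
#' @return list(t, df, pValue, means, sds, ns).
#' @export
twoSampleT <- function(table, groupKey, value) {
  if (!groupKey %in% names(table))
    stop("unknown group key: ", groupKey, call. = FALSE)
  if (!value %in% names(table))
    stop("unknown value column: ", value, call. = FALSE)
  sp <- split(table[[value]], table[[groupKey]], drop = TRUE)
  if (length(sp) != 2L)
    stop("need exactly two groups, got ", length(sp), call. = FALSE)
  if (any(lengths(sp) < 2L))
    stop("both groups need n >= 2", call. = FALSE)
  tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value,
       means = vapply(sp, mean, numeric(1)),
       sds = vapply(sp, stats::sd, numeric(1)),
       ns = lengths(sp))
}

#' Pairwise Welch comparisons with Bonferroni correction
#'
#' All pairwise Welch t tests between the levels of a grouping column, with
#' Bonferroni-adjusted p values.
#'
#' @param table data.frame.
#' @param groupKey grouping column.
#' @param value numeric column.
#' @return data.frame(groupA, groupB, meanA, meanB, t, df, p, pAdjusted).
#' @export
pairwiseGroupTests <- function(table, groupKey, value) {
  sp <- split(table[[value]], table[[groupKey]], drop = TRUE)
  sp <- sp[lengths(sp) >= 2L]
  lv <- names(sp)
  if (length(lv) < 2L) stop("need >= 2 groups with n >= 2", call. = FALSE)
  pairs <- utils::combn(lv, 2)
  rows <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(sp[[pr[1]]], sp[[pr[2]]], var.equal = FALSE)
    data.frame(groupA = pr[1], groupB = pr[2],
               meanA = mean(sp[[pr[1]]]), meanB = mean(sp[[pr[2]]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Percentage difference between two group means
#'
#' 100 * (meanA - meanB) / meanB: how much higher A is than B, relative to
#' B. The companion convention relative to A is returned alongside, since
#' summary rhetoric often mixes the two.
#'
#' @param meanA,meanB positive group means.
#' @return list(relB, relA): 100(a-b)/b and 100(a-b)/a.
#' @examples
#' percentDifference(0.9693199, 0.6653613)$relB  # ~45.68
#' @export
percentDifference <- function(meanA, meanB) {
  if (meanB <= 0) stop("meanB must be > 0", call. = FALSE)
  if (meanA <= 0) stop("meanA must be > 0", call. = FALSE)
  list(relB = 100 * (meanA - meanB) / meanB,
       relA = 100 * (meanA - meanB) / meanA)
}
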