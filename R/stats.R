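## Cohort statistics on per-sample private-variant counts:
## two-group Mann-Whitney rank-sum, three-group Kruskal-Wallis, and
## univariate least-squares regression of variant count on donor age
## with adjusted R-squared. No multiple-testing correction is applied,
## and all tests are two-sided; significance level 0.05.

#' Mann-Whitney rank-sum test
#'
#' Exact null distribution when the combined sample size is at most 20
#' and there are no ties; tie-corrected normal approximation (with
#' continuity correction) otherwise. Backed by
#' \code{stats::wilcox.test}; the reported U is the Mann-Whitney
#' statistic of the first group.
#'
#' @param a,b Numeric vectors (e.g. variant counts per sample).
#' @param exact_max Combined size up to which the exact method is used
#'   (default 20).
#' @return A list: \code{U}, \code{p} (two-sided), \code{method}
#'   (\code{"exact"} or \code{"normal_approx"}), \code{n}.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))   # U = 0, p = 0.1
#' @export
rank_sum_test <- function(a, b, exact_max = 20L) {
  if (!length(a) || !length(b))
    stop("rank_sum_test() needs non-empty groups", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n = c(length(a), length(b)))
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1
#' degrees of freedom (backed by \code{stats::kruskal.test}).
#'
#' @param groups A list of three or more numeric vectors.
#' @return A list: \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("kruskal_wallis() needs at least three groups", call. = FALSE)
  if (any(!lengths(groups)))
    stop("kruskal_wallis() needs non-empty groups", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Univariate linear fit with adjusted R-squared
#'
#' Ordinary least squares of \code{y} on \code{x}; the adjusted
#' R-squared uses the univariate formula
#' \code{1 - (1 - R2) (n - 1) / (n - 2)}; the slope p-value is the
#' two-sided t-test.
#'
#' @param x Predictor (e.g. donor age, years).
#' @param y Response (e.g. variant count).
#' @return A list: \code{slope}, \code{intercept}, \code{r2},
#'   \code{adjusted_r2}, \code{p_slope}, \code{n}.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("linear_fit() needs n >= 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate design: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  n <- length(x)
  r2 <- sm$r.squared
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = r2,
       adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
       p_slope = sm$coefficients[2L, 4L],
       n = n)
}

#' Dichotomize donor age
#'
#' @param age Ages in years.
#' @param cutoff Old-group threshold (default 50: donors at or above 50
#'   are "old").
#' @return Factor with levels \code{young}, \code{old}.
#' @export
age_group <- function(age, cutoff = 50) {
  factor(ifelse(age >= cutoff, "old", "young"), levels = c("young", "old"))
}

#' Count PASS private variants per sample
#'
#' @param call_sets Named list of private \code{mito_calls}.
#' @param manifest A validated lineage manifest; counts are joined to
#'   its covariates by sample name.
#' @return A data.frame: one row per sample with \code{n_variants} and
#'   the manifest covariates.
#' @export
count_private_variants <- function(call_sets, manifest) {
  counts <- vapply(call_sets, function(x) sum(x$pass), integer(1L))
  i <- match(names(call_sets), manifest$sample_id)
  if (anyNA(i))
    stop("samples missing from manifest: ",
         paste(names(call_sets)[is.na(i)], collapse = ", "), call. = FALSE)
  data.frame(sample_id = names(call_sets), n_variants = unname(counts),
             manifest[i, c("line_id", "stage", "group", "donor_age",
                           "reprogramming_method", "haplogroup")],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-wise cohort statistics report
#'
#' For each lineage stage: Mann-Whitney young-vs-old comparison of
#' variant counts, Kruskal-Wallis across the control / mitochondrial /
#' nuclear groups, and the age regression with adjusted R-squared.
#'
#' @param counts Output of \code{\link{count_private_variants}}.
#' @param age_cutoff Old-group age threshold (default 50).
#' @return A data.frame with one row per stage x test.
#' @export
stats_report <- function(counts, age_cutoff = 50) {
  rows <- list()
  for (st in intersect(c("fibroblast", "iPSC", "NPC"), counts$stage)) {
    x <- counts[counts$stage == st, , drop = FALSE]
    ag <- age_group(x$donor_age, age_cutoff)
    if (all(c("young", "old") %in% ag)) {
      mw <- rank_sum_test(x$n_variants[ag == "young"],
                          x$n_variants[ag == "old"])
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, test = "age_rank_sum", statistic = mw$U, p = mw$p,
        detail = mw$method, stringsAsFactors = FALSE)
    }
    grps <- split(x$n_variants, x$group)
    if (length(grps) >= 3L) {
      kw <- kruskal_wallis(grps)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, test = "group_kruskal_wallis", statistic = kw$H,
        p = kw$p, detail = paste0("df=", kw$df), stringsAsFactors = FALSE)
    }
    if (length(unique(x$donor_age)) > 1L && nrow(x) >= 3L) {
      lf <- linear_fit(x$donor_age, x$n_variants)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, test = "age_regression", statistic = lf$adjusted_r2,
        p = lf$p_slope,
        detail = sprintf("slope=%.4g;r2=%.4g", lf$slope, lf$r2),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(stage = character(0), test = character(0),
                      statistic = numeric(0), p = numeric(0),
                      detail = character(0)))
  do.call(rbind, rows)
}
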