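#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Used for binary basic
#' covariates such as sex.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `statistic` (t), `df`, `p_value`.
#' @export
#' @examples
#' welch_t_test(1:5, 2:6)  # t = -1, df = 8, p ~ 0.347
welch_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    icp_stop("welch_t_test needs n >= 2 in each group", "test_error")
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, df = na + nb - 2, p_value = 1))
    icp_stop("welch_t_test: both groups constant with different means",
             "test_error")
  }
  se2 <- va / na + vb / nb
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df))
}

#' Pearson correlation test
#'
#' Pearson correlation r with the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` and a two-sided p-value. Used for
#' continuous basic covariates (age, weight, height, BMI). A Spearman
#' variant (ranks, then the same statistic) is available.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param method "pearson" (default) or "spearman".
#' @return list with `estimate` (r), `statistic` (t), `df`, `p_value`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) icp_stop("x and y must have equal length", "test_error")
  if (n < 3L) icp_stop("correlation_test needs n >= 3", "test_error")
  if (var(x) == 0) icp_stop("correlation_test: x is constant", "test_error")
  if (var(y) == 0) icp_stop("correlation_test: y is constant", "test_error")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  df <- n - 2
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  list(estimate = r, statistic = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df))
}

#' Association table of fitted parameters vs basic covariates
#'
#' For every combination of basic covariate x monitored variable x
#' parameter (mu, sigma) x state, tests whether the per-patient fitted
#' parameter is associated with the covariate across patients: a Welch
#' t-test between groups for the binary covariate (sex), a correlation
#' test for the continuous ones (age, weight, height, BMI). Cells that
#' cannot be tested (constant parameter, group too small) are marked
#' `untestable` with `p_value = NA` rather than dropped.
#'
#' @param records parameter records: data frame with patient_id,
#'   variable, state, mu_hat, sigma_hat (from [extract_parameters()] /
#'   [fit_cohort()]).
#' @param profiles basic profiles data frame (patient_id, sex, age,
#'   weight, height, bmi).
#' @param alpha significance reporting threshold (default 0.01).
#' @param basic_vars covariates to test.
#' @param method correlation method for continuous covariates.
#' @return data frame basic_var, monitored_var, parameter, state,
#'   statistic, p_value, test_kind, significant; class
#'   `association_table`.
#' @export
build_association_table <- function(records, profiles, alpha = 0.01,
                                    basic_vars = c("sex", "age", "weight",
                                                   "height", "bmi"),
                                    method = "pearson") {
  idx <- match(records$patient_id, profiles$patient_id)
  if (anyNA(idx))
    icp_stop("records reference patients missing from profiles",
             "integrity_error")
  vars <- unique(records$variable)
  states <- sort(unique(records$state))
  out <- list()
  for (bv in basic_vars) {
    covariate <- profiles[[bv]][idx]
    binary <- length(unique(profiles[[bv]])) == 2L
    for (mv in vars) for (par in c("mu", "sigma")) for (s in states) {
      sel <- records$variable == mv & records$state == s
      y <- records[[paste0(par, "_hat")]][sel]
      x <- covariate[sel]
      cell <- tryCatch({
        if (length(y) < 2L || var(y) == 0)
          icp_stop("degenerate cell: constant parameter", "test_error")
        if (binary) {
          groups <- split(y, x)
          if (length(groups) != 2L)
            icp_stop("single group", "test_error")
          tst <- welch_t_test(groups[[1]], groups[[2]])
          list(statistic = tst$statistic, p = tst$p_value,
               kind = "welch_t")
        } else {
          tst <- correlation_test(x, y, method = method)
          list(statistic = tst$statistic, p = tst$p_value,
               kind = paste0(method, "_cor"))
        }
      }, test_error = function(e) list(statistic = NA_real_, p = NA_real_,
                                       kind = "untestable"))
      out[[length(out) + 1L]] <- data.frame(
        basic_var = bv, monitored_var = mv, parameter = par, state = s,
        statistic = cell$statistic, p_value = cell$p,
        test_kind = cell$kind,
        significant = !is.na(cell$p) & cell$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  class(res) <- c("association_table", class(res))
  res
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %d cells, alpha = %g: %d significant, %d untestable\n",
              nrow(x), attr(x, "alpha"), sum(x$significant),
              sum(x$test_kind == "untestable")))
  NextMethod()
}
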