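#' Symmetric quantile forecast interval from leaf responses
#'
#' Maps a nominal level c to the symmetric quantile levels
#' ((1 - c)/2, 1 - (1 - c)/2) — an 80% interval uses the 0.1 and 0.9
#' quantiles — and returns the empirical quantiles of the leaf's
#' responses at those levels (linear-interpolation quantile definition,
#' R type 7). `c = 1` gives the leaf (min, max).
#'
#' @param responses numeric responses in the terminal node (non-empty).
#' @param level nominal level c in (0, 1].
#' @return list with `lower`, `upper`, `level`, `probs` (the two
#'   quantile levels); class `forecast_interval`.
#' @export
#' @examples
#' leaf_interval(rnorm(100), 0.8)$probs  # 0.1 0.9
leaf_interval <- function(responses, level) {
  if (!length(responses)) icp_stop("empty leaf", "forecast_error")
  if (!(level > 0 && level <= 1))
    icp_stop("level must be in (0, 1]", "forecast_error")
  # rounding kills float drift: (1 - 0.8)/2 must be exactly 0.1
  probs <- round(c((1 - level) / 2, 1 - (1 - level) / 2), 12)
  q <- quantile(responses, probs, names = FALSE, type = 7)
  structure(list(lower = q[1], upper = q[2], level = level, probs = probs),
            class = "forecast_interval")
}

#' Relative interval width
#'
#' The interval width divided by the 0.95 - 0.05 quantile span of the
#' reference responses (the full training-set response column for that
#' monitored variable x parameter x state), which removes the influence
#' of the variable's units. Undefined (NA, with a warning) when the
#' reference spread is zero.
#'
#' @param interval a `forecast_interval` (or list with lower/upper).
#' @param reference numeric reference responses.
#' @return relative width >= 0, or NA when undefined.
#' @export
relative_width <- function(interval, reference) {
  span <- diff(quantile(reference, c(0.05, 0.95), names = FALSE, type = 7))
  if (span == 0) {
    warning("relative_width undefined: zero reference spread")
    return(NA_real_)
  }
  (interval$upper - interval$lower) / span
}

# one interval per leaf from the training responses
tree_intervals <- function(tree, level) {
  ids <- leaf_ids(tree)
  setNames(lapply(ids, function(id) {
    leaf_interval(tree$responses[tree$nodes[[id]]$members], level)
  }), as.character(ids))
}

#' Held-out coverage and width of leaf intervals
#'
#' Routes each evaluation observation to its terminal node and counts it
#' covered iff `lower <= y <= upper` for that leaf's interval. Coverage
#' is the exact fraction covered; the relative width is averaged over
#' leaves weighted by evaluation counts, with the training-set responses
#' as the unit reference.
#'
#' @param tree a `cond_tree` grown on training data.
#' @param eval_predictors data frame of held-out predictor rows.
#' @param eval_responses held-out responses, aligned with
#'   `eval_predictors`.
#' @param level nominal interval level.
#' @return list with `level`, `coverage`, `relative_width`, `n_eval`.
#' @export
interval_coverage <- function(tree, eval_predictors, eval_responses, level) {
  if (nrow(eval_predictors) != length(eval_responses))
    icp_stop("evaluation predictors/responses length mismatch",
             "forecast_error")
  intervals <- tree_intervals(tree, level)
  leaf <- route_all(tree, eval_predictors)
  inside <- logical(length(eval_responses))
  for (i in seq_along(eval_responses)) {
    iv <- intervals[[as.character(leaf[i])]]
    inside[i] <- eval_responses[i] >= iv$lower & eval_responses[i] <= iv$upper
  }
  widths <- vapply(intervals, relative_width, numeric(1),
                   reference = tree$responses)
  counts <- table(factor(as.character(leaf), levels = names(intervals)))
  w <- as.numeric(counts)
  ok <- !is.na(widths) & w > 0
  avg_width <- if (any(ok)) sum(widths[ok] * w[ok]) / sum(w[ok]) else NA_real_
  list(level = level,
       coverage = sum(inside) / length(inside),
       relative_width = avg_width,
       n_eval = length(inside))
}

# wide response table: one row per patient, one column per
# (variable, parameter, state), joined with the profile covariates
records_to_responses <- function(records, profiles,
                                 parameters = c("mu", "sigma")) {
  ids <- unique(records$patient_id)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (v in unique(records$variable)) {
    for (s in sort(unique(records$state))) {
      sel <- records$variable == v & records$state == s
      sub <- records[sel, , drop = FALSE]
      m <- match(ids, sub$patient_id)
      for (par in parameters) {
        out[[sprintf("%s:%s:%d", v, par, s)]] <-
          sub[[paste0(par, "_hat")]][m]
      }
    }
  }
  m <- match(ids, profiles$patient_id)
  for (bv in c("sex", "age", "weight", "height", "bmi")) {
    out[[bv]] <- profiles[[bv]][m]
  }
  out
}

#' Coverage / relative-width tradeoff curve
#'
#' For each response column (monitored variable x parameter x state) a
#' conditional inference tree is grown on a seeded patient-level
#' training split; leaf quantile intervals at each nominal level are
#' evaluated on the held-out patients, giving per-response and averaged
#' coverage and relative width per level. Coverage increases with the
#' nominal level while the width grows faster at high levels, which is
#' the tradeoff the curve exposes.
#'
#' @param records parameter records (patient_id, variable, state,
#'   mu_hat, sigma_hat).
#' @param profiles basic profiles (the tree predictors).
#' @param levels nominal levels, at least two.
#' @param parameters which parameters to forecast ("mu", "sigma").
#' @param alpha,max_depth,min_leaf tree settings (defaults 0.1, 5, 20).
#' @param train_frac training fraction of the patient-level split.
#' @param split_seed seed of the train/test split.
#' @param method correlation method for tree selection.
#' @return data frame response, level, coverage, relative_width,
#'   n_eval; the per-level averages across responses are in the
#'   `averages` attribute.
#' @export
coverage_width_curve <- function(records, profiles, levels = c(0.5, 0.8, 0.95),
                                 parameters = c("mu", "sigma"),
                                 alpha = 0.1, max_depth = 5L, min_leaf = 20L,
                                 train_frac = 0.7, split_seed = 1L,
                                 method = "pearson") {
  if (length(levels) < 1L)
    icp_stop("need at least one level", "forecast_error")
  wide <- records_to_responses(records, profiles, parameters)
  resp_cols <- grep(":", names(wide), value = TRUE, fixed = TRUE)
  pred_cols <- c("sex", "age", "weight", "height", "bmi")
  n <- nrow(wide)
  set.seed(split_seed)
  train <- sample.int(n) <= round(train_frac * n)
  if (sum(train) < 2L * min_leaf || sum(!train) < 1L)
    icp_stop(sprintf(
      "split too small for the tree: %d training patients but min_leaf = %d requires >= %d",
      sum(train), min_leaf, 2L * min_leaf), "forecast_error")
  out <- list()
  for (rc in resp_cols) {
    y <- wide[[rc]]
    keep <- !is.na(y)
    tr <- train & keep; te <- !train & keep
    tree <- grow_tree(y[tr], wide[tr, pred_cols, drop = FALSE],
                      alpha = alpha, max_depth = max_depth,
                      min_leaf = min_leaf, method = method)
    for (lv in levels) {
      met <- interval_coverage(tree, wide[te, pred_cols, drop = FALSE],
                               y[te], lv)
      out[[length(out) + 1L]] <- data.frame(
        response = rc, level = lv, coverage = met$coverage,
        relative_width = met$relative_width, n_eval = met$n_eval,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  avg <- do.call(rbind, lapply(split(res, res$level), function(d) {
    data.frame(level = d$level[1],
               coverage = mean(d$coverage),
               relative_width = mean(d$relative_width, na.rm = TRUE),
               n_eval = sum(d$n_eval))
  }))
  rownames(avg) <- NULL
  attr(res, "averages") <- avg[order(avg$level), , drop = FALSE]
  res
}
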