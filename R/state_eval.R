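#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computes the AUC as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive is scored higher,
#' with ties credited 0.5. This equals the area under the ROC curve over
#' all thresholds; 0.5 is chance, 1.0 a perfect ranking.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or a two-level factor with
#'   the positive class as the higher level / TRUE / 1).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  if (length(scores) != length(pos))
    icp_stop("scores and labels must have equal length", "eval_error")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    icp_stop("AUC undefined: labels contain a single class", "eval_error")
  r <- rank(scores)                       # average ranks credit ties 0.5
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (identical(u, c("failure", "safe")) || all(u %in% c("failure", "safe")))
      return(labels == "failure")
    if (length(u) > 2L)
      icp_stop("labels must be binary", "eval_error")
    return(labels == u[length(u)])
  }
  if (!all(labels %in% c(0, 1)))
    icp_stop("numeric labels must be 0/1", "eval_error")
  labels == 1
}

#' Per-patient AUC of decoded states against rule labels
#'
#' Scores each time point with the posterior probability of the
#' failure-aligned state (state 1 after [align_states()]) and computes a
#' Mann-Whitney AUC against the rule-based labels, one result per
#' patient whose labels contain both classes. Single-class patients are
#' excluded from the AUC measurement.
#'
#' @param fits named list of aligned `hmm_fit` objects (names =
#'   patient_id).
#' @param labels data frame patient_id, time, label as produced by
#'   [label_states()].
#' @return data frame patient_id, auc, n_pos, n_neg (one row per
#'   multi-state patient), with a `summary` attribute holding the mean,
#'   median and histogram counts over 10 equal AUC bins.
#' @export
evaluate_cohort_auc <- function(fits, labels) {
  if (is.null(names(fits)) || any(names(fits) == ""))
    icp_stop("fits must be a named list keyed by patient_id", "eval_error")
  out <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    if (!isTRUE(fit$aligned))
      icp_stop("fits must be failure-aligned: call align_states() first",
               "eval_error")
    pid <- names(fits)[i]
    lab <- labels[labels$patient_id == pid, , drop = FALSE]
    lab <- lab[order(lab$time), , drop = FALSE]
    if (nrow(lab) != nrow(fit$posteriors))
      icp_stop(paste("labels do not cover fitted time points for", pid),
               "eval_error")
    y <- lab$label == "failure"
    if (all(y) || !any(y)) next          # single-class: excluded
    score <- fit$posteriors[, 1L]        # failure-aligned state posterior
    out[[i]] <- data.frame(patient_id = pid,
                           auc = auc(score, y),
                           n_pos = sum(y), n_neg = sum(!y),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(patient_id = character(), auc = numeric(),
                      n_pos = integer(), n_neg = integer())
  breaks <- seq(0, 1, by = 0.1)
  attr(res, "summary") <- list(
    n = nrow(res),
    mean = if (nrow(res)) mean(res$auc) else NA_real_,
    median = if (nrow(res)) median(res$auc) else NA_real_,
    hist = data.frame(bin_lower = breaks[-11], bin_upper = breaks[-1],
                      count = if (nrow(res))
                        as.integer(table(cut(res$auc, breaks,
                                             include.lowest = TRUE)))
                      else integer(10)))
  res
}
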