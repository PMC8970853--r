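#' Conditional inference tree for parameter responses
#'
#' Recursive binary partitioning in a conditional inference style: at
#' each node the predictor most associated with the response is chosen
#' by association-test p-value (Welch t-test for binary predictors,
#' correlation test for continuous ones), Bonferroni-adjusted across the
#' predictors tested at that node; splitting stops when the adjusted
#' p-value exceeds `alpha`, at `max_depth`, or when no cutpoint leaves
#' both children with at least `min_leaf` members. Continuous cutpoints
#' are the midpoints of adjacent sorted distinct values, chosen to
#' maximise the absolute Welch t statistic between the two children;
#' binary predictors split by category. Routing sends values `<=`
#' threshold to the left child.
#'
#' @param responses numeric response vector (e.g. a fitted `mu_hat`
#'   column across patients).
#' @param predictors data frame of numeric predictors (binary ones coded
#'   with two distinct values), one row per response.
#' @param alpha selection significance threshold (default 0.1).
#' @param max_depth maximum tree depth; the root has depth 0.
#' @param min_leaf minimum member count per leaf (default 20, so leaf
#'   quantiles at the 0.05/0.95 level are estimable).
#' @param method correlation method for continuous predictors.
#' @return an object of class `cond_tree`: a flat list of nodes plus the
#'   training responses.
#' @export
grow_tree <- function(responses, predictors, alpha = 0.1, max_depth = 5L,
                      min_leaf = 20L, method = "pearson") {
  if (!length(responses)) icp_stop("empty response vector", "tree_error")
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(responses))
    icp_stop("predictors and responses must have equal length", "tree_error")
  env <- new.env()
  env$nodes <- list()
  build_node(env, responses, predictors, idx = seq_along(responses),
             depth = 0L, alpha = alpha, max_depth = max_depth,
             min_leaf = min_leaf, method = method)
  structure(list(nodes = env$nodes, responses = responses,
                 predictor_names = names(predictors),
                 alpha = alpha, max_depth = max_depth, min_leaf = min_leaf),
            class = "cond_tree")
}

build_node <- function(env, responses, predictors, idx, depth, alpha,
                       max_depth, min_leaf, method) {
  id <- length(env$nodes) + 1L
  node <- list(node_id = id, depth = depth, n = length(idx), kind = "leaf",
               split_variable = NA_character_, split_point = NA_real_,
               p_adjusted = NA_real_, left = NA_integer_, right = NA_integer_,
               members = idx)
  env$nodes[[id]] <- node
  y <- responses[idx]

  can_split <- depth < max_depth && length(idx) >= 2L * min_leaf &&
    var(y) > 0
  if (can_split) {
    sel <- split_variable_selection(y, predictors[idx, , drop = FALSE],
                                    alpha = alpha, method = method)
    if (!sel$stop) {
      thr <- split_point_search(y, predictors[idx, , drop = FALSE][[sel$variable]],
                                min_leaf = min_leaf)
      if (!is.na(thr)) {
        node$kind <- "internal"
        node$split_variable <- sel$variable
        node$split_point <- thr
        node$p_adjusted <- sel$p_adjusted
        go_left <- predictors[idx, sel$variable] <= thr
        env$nodes[[id]] <- node
        left_id <- build_node(env, responses, predictors, idx[go_left],
                              depth + 1L, alpha, max_depth, min_leaf, method)
        right_id <- build_node(env, responses, predictors, idx[!go_left],
                               depth + 1L, alpha, max_depth, min_leaf, method)
        node$left <- left_id; node$right <- right_id
        env$nodes[[id]] <- node
        return(id)
      }
    } else {
      node$p_adjusted <- sel$p_adjusted
      env$nodes[[id]] <- node
    }
  }
  id
}

#' Select the splitting variable by minimum adjusted p-value
#'
#' Tests each predictor against the response (Welch t-test if the
#' predictor takes exactly two distinct values in the node, correlation
#' test otherwise), Bonferroni-multiplies the minimum p-value by the
#' number of testable predictors (capped at 1), and stops when the
#' adjusted p exceeds `alpha`. Ties are broken to the first predictor in
#' declaration order.
#'
#' An optional seeded Monte-Carlo permutation p-value (`p_method =
#' "permutation"`) replaces the asymptotic p per predictor with
#' `(1 + #permuted |statistic| >= observed) / (n_perm + 1)` under
#' response permutation, as a fidelity check on the asymptotic route.
#'
#' @param responses response values in the node.
#' @param predictors predictor data frame restricted to the node.
#' @param alpha selection threshold.
#' @param method correlation method.
#' @param p_method "asymptotic" (default) or "permutation".
#' @param n_perm number of Monte-Carlo permutations.
#' @param perm_seed seed of the permutation draw.
#' @return list with `stop` (logical), `variable`, `p_adjusted`.
#' @export
split_variable_selection <- function(responses, predictors, alpha = 0.1,
                                     method = "pearson",
                                     p_method = c("asymptotic",
                                                  "permutation"),
                                     n_perm = 9999L, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  stat_fun <- function(x, y) {
    u <- unique(x)
    if (length(u) < 2L) return(NA_real_)
    if (length(u) == 2L) {
      g <- split(y, x)
      abs(welch_t_test(g[[1]], g[[2]])$statistic)
    } else {
      abs(correlation_test(x, y, method = method)$statistic)
    }
  }
  pvals <- rep(NA_real_, ncol(predictors))
  for (j in seq_len(ncol(predictors))) {
    x <- predictors[[j]]
    u <- unique(x)
    pvals[j] <- tryCatch({
      if (length(u) < 2L) NA_real_
      else if (p_method == "permutation") {
        obs <- stat_fun(x, responses)
        set.seed(perm_seed + j)
        exceed <- sum(replicate(n_perm, {
          s <- tryCatch(stat_fun(x, sample(responses)),
                        test_error = function(e) NA_real_)
          !is.na(s) && s >= obs
        }))
        (1 + exceed) / (n_perm + 1)
      } else if (length(u) == 2L) {
        g <- split(responses, x)
        welch_t_test(g[[1]], g[[2]])$p_value
      } else {
        correlation_test(x, responses, method = method)$p_value
      }
    }, test_error = function(e) NA_real_)
  }
  testable <- which(!is.na(pvals))
  if (!length(testable))
    return(list(stop = TRUE, variable = NA_character_,
                p_adjusted = NA_real_))
  j_best <- testable[which.min(pvals[testable])]   # first wins ties
  p_adj <- min(1, pvals[j_best] * length(testable))
  list(stop = p_adj > alpha, variable = names(predictors)[j_best],
       p_adjusted = p_adj)
}

#' Search the best cutpoint for a selected predictor
#'
#' Candidate thresholds are the midpoints of adjacent sorted distinct
#' predictor values; the one maximising the absolute standardised
#' two-sample mean difference (Welch t statistic) between the `<=` and
#' `>` groups is returned, subject to both children having at least
#' `min_leaf` members. Binary predictors split at the category midpoint.
#'
#' @param responses response values in the node.
#' @param predictor predictor values in the node.
#' @param min_leaf minimum child size.
#' @return the threshold, or `NA` when no admissible cutpoint exists.
#' @export
split_point_search <- function(responses, predictor, min_leaf = 20L) {
  u <- sort(unique(predictor))
  if (length(u) < 2L) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  best_thr <- NA_real_; best_stat <- -Inf
  for (thr in cand) {
    left <- predictor <= thr
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    stat <- tryCatch(abs(welch_t_test(responses[left],
                                      responses[!left])$statistic),
                     test_error = function(e) NA_real_)
    if (!is.na(stat) && stat > best_stat) {
      best_stat <- stat
      best_thr <- thr
    }
  }
  best_thr
}

#' Route a profile to its terminal node
#'
#' Walks the tree from the root: at each internal node the profile goes
#' left iff its split-variable value is `<=` the threshold (boundary
#' values go left). Every valid profile reaches exactly one leaf.
#'
#' @param tree a `cond_tree`.
#' @param profile a one-row data frame, list, or named vector holding
#'   all split variables.
#' @return the leaf `node_id`.
#' @export
route <- function(tree, profile) {
  node <- tree$nodes[[1L]]
  while (node$kind == "internal") {
    v <- profile[[node$split_variable]]
    if (is.null(v) || is.na(v))
      icp_stop(paste("profile missing split variable:", node$split_variable),
               "tree_error")
    node <- tree$nodes[[if (v <= node$split_point) node$left else node$right]]
  }
  node$node_id
}

# vectorised routing of a predictor data frame
route_all <- function(tree, predictors) {
  vapply(seq_len(nrow(predictors)),
         function(i) route(tree, predictors[i, , drop = FALSE]), integer(1))
}

#' @export
print.cond_tree <- function(x, ...) {
  leaves <- vapply(x$nodes, function(n) n$kind == "leaf", logical(1))
  cat(sprintf("<cond_tree> %d nodes (%d leaves), depth %d, n = %d\n",
              length(x$nodes), sum(leaves),
              max(vapply(x$nodes, `[[`, integer(1), "depth")),
              x$nodes[[1]]$n))
  invisible(x)
}

tree_depth <- function(tree) {
  max(vapply(tree$nodes, `[[`, integer(1), "depth"))
}

leaf_ids <- function(tree) {
  ids <- vapply(tree$nodes, `[[`, integer(1), "node_id")
  ids[vapply(tree$nodes, function(n) n$kind == "leaf", logical(1))]
}

#' Serialise a tree to JSON
#'
#' Writes the node list (ids, splits, adjusted p-values, and per-leaf
#' response summaries: n, mean, and 0.05/0.25/0.5/0.75/0.95 quantiles)
#' as a JSON document.
#'
#' @param tree a `cond_tree`.
#' @param path output file; when `NULL`, the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(n) {
    out <- n[c("node_id", "depth", "n", "kind", "split_variable",
               "split_point", "p_adjusted", "left", "right")]
    if (n$kind == "leaf") {
      y <- tree$responses[n$members]
      out$response_summary <- list(
        n = length(y), mean = mean(y),
        quantiles = as.list(quantile(y, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                     names = TRUE)))
    }
    out
  })
  doc <- list(model = "cond_tree",
              alpha = tree$alpha, max_depth = tree$max_depth,
              min_leaf = tree$min_leaf,
              predictor_names = tree$predictor_names, nodes = nodes)
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                            na = "null", pretty = TRUE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
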