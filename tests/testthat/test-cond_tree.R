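make_predictors <- function(n, seed = 1) {
  set.seed(seed)
  d <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 18, 95),
                  weight = rnorm(n, 78, 12), height = rnorm(n, 1.7, 0.1))
  d$bmi <- d$weight / d$height^2
  d
}

test_that("a strongly correlated predictor is selected with a tiny p", {
  set.seed(5)
  x <- rnorm(200)
  pred <- data.frame(noise = rnorm(200), signal = x)
  y <- 0.9 * x + rnorm(200, 0, sqrt(1 - 0.81))   # cor ~ 0.9
  sel <- split_variable_selection(y, pred, alpha = 0.1)
  expect_false(sel$stop)
  expect_identical(sel$variable, "signal")
  expect_lt(sel$p_adjusted, 1e-10)               # Fisher-z power oracle
})

test_that("permutation p-values agree with the asymptotic route", {
  set.seed(14)
  x <- rnorm(80)
  y <- 0.4 * x + rnorm(80)
  pred <- data.frame(x = x)
  asym <- split_variable_selection(y, pred, alpha = 1)
  perm <- split_variable_selection(y, pred, alpha = 1,
                                   p_method = "permutation",
                                   n_perm = 1999, perm_seed = 3)
  # Monte-Carlo SE of the permutation p at this n is ~ sqrt(p(1-p)/2000)
  expect_lt(abs(asym$p_adjusted - perm$p_adjusted),
            3 * sqrt(0.05 / 2000) + 0.01)
})

test_that("identical predictors tie to the first in declaration order", {
  set.seed(6)
  x <- rnorm(100)
  y <- x + rnorm(100, 0, 0.5)
  sel <- split_variable_selection(y, data.frame(first = x, second = x),
                                  alpha = 0.1)
  expect_identical(sel$variable, "first")
})

test_that("pure-noise selection stops about 1 - alpha of the time", {
  set.seed(7)
  stops <- replicate(400, {
    split_variable_selection(rnorm(60), data.frame(x = rnorm(60)),
                             alpha = 0.1)$stop
  })
  # null-uniform p oracle: stop rate ~ 0.9, 3 binomial SEs of 400 reps
  expect_lt(abs(mean(stops) - 0.9), 3 * sqrt(0.09 / 400))
})

test_that("all-constant predictors stop the node", {
  sel <- split_variable_selection(rnorm(50), data.frame(a = rep(1, 50)),
                                  alpha = 0.1)
  expect_true(sel$stop)
})

test_that("the cutpoint search finds a step and respects min_leaf", {
  set.seed(8)
  x <- runif(200, 0, 100)
  y <- ifelse(x <= 50, 0, 5) + rnorm(200, 0, 0.5)
  thr <- split_point_search(y, x, min_leaf = 20)
  # exhaustive-cutpoint oracle: the step at 50 wins within one midpoint gap
  xs <- sort(x)
  gap <- max(diff(xs[xs > 40 & xs < 60]))
  expect_lt(abs(thr - 50), gap + 1e-9)
  # binary predictors split at the category midpoint
  b <- rbinom(200, 1, 0.5)
  yb <- b * 3 + rnorm(200)
  expect_identical(split_point_search(yb, b, min_leaf = 20), 0.5)
  # no admissible cutpoint
  expect_true(is.na(split_point_search(rnorm(10), runif(10), min_leaf = 20)))
})

test_that("trees respect max depth and split only on the informative variable", {
  pred <- make_predictors(300, seed = 9)
  y <- 1 + 4 * pred$sex + rnorm(300, 0, 0.5)
  tree <- grow_tree(y, pred, alpha = 0.1, max_depth = 5, min_leaf = 20)
  root <- tree$nodes[[1]]
  expect_identical(root$split_variable, "sex")
  expect_identical(root$split_point, 0.5)
  expect_identical(tree$nodes[[root$left]]$kind, "leaf")
  expect_identical(tree$nodes[[root$right]]$kind, "leaf")
  # depth never exceeds the cap even with strong signal everywhere
  y2 <- pred$age + 10 * pred$sex + pred$weight + rnorm(300, 0, 0.01)
  deep <- grow_tree(y2, pred, alpha = 0.5, max_depth = 5, min_leaf = 20)
  expect_lte(max(vapply(deep$nodes, `[[`, integer(1), "depth")), 5L)
  expect_error(grow_tree(numeric(0), pred), class = "tree_error")
})

test_that("on null data the root splits at about the alpha rate", {
  set.seed(10)
  splits <- replicate(250, {
    tree <- grow_tree(rnorm(120), data.frame(x = runif(120)),
                      alpha = 0.1, max_depth = 5, min_leaf = 20)
    tree$nodes[[1]]$kind == "internal"
  })
  expect_lt(abs(mean(splits) - 0.1), 3 * sqrt(0.09 / 250) + 0.02)
})

test_that("lowering alpha never deepens the tree", {
  for (seed in 1:5) {
    pred <- make_predictors(250, seed = seed)
    set.seed(seed + 100)
    y <- 0.4 * pred$sex + 0.01 * pred$age + rnorm(250)
    depths <- vapply(c(0.001, 0.05, 0.1, 0.5), function(a) {
      max(vapply(grow_tree(y, pred, alpha = a)$nodes, `[[`, integer(1),
                 "depth"))
    }, integer(1))
    expect_true(all(diff(depths) >= 0))
  }
})

test_that("leaves partition the training set and routing reproduces it", {
  pred <- make_predictors(400, seed = 11)
  set.seed(11)
  y <- 2 * pred$sex + 0.05 * pred$age + rnorm(400)
  tree <- grow_tree(y, pred, alpha = 0.1)
  leaves <- Filter(function(n) n$kind == "leaf", tree$nodes)
  members <- sort(unlist(lapply(leaves, `[[`, "members")))
  expect_identical(members, seq_len(400))          # disjoint + exhaustive
  # internal nodes: children partition the parent exactly
  for (n in tree$nodes) {
    if (n$kind == "internal") {
      kids <- sort(c(tree$nodes[[n$left]]$members,
                     tree$nodes[[n$right]]$members))
      expect_identical(kids, sort(n$members))
    }
  }
  # routing every training row reproduces the leaf membership
  routed <- vapply(seq_len(400),
                   function(i) route(tree, pred[i, ]), integer(1))
  for (lf in leaves) {
    expect_setequal(which(routed == lf$node_id), lf$members)
  }
})

test_that("routing conventions: depth-0 tree, boundary goes left, errors", {
  tree0 <- grow_tree(rnorm(50), data.frame(x = rnorm(50)), alpha = 1e-9)
  expect_identical(route(tree0, list(x = 3)), 1L)
  pred <- data.frame(x = c(rep(0, 40), rep(10, 40)))
  y <- c(rnorm(40), rnorm(40, 20))
  tree <- grow_tree(y, pred, alpha = 0.5, min_leaf = 20)
  thr <- tree$nodes[[1]]$split_point
  expect_identical(route(tree, list(x = thr)), tree$nodes[[1]]$left)
  expect_error(route(tree, list(z = 1)), "missing", class = "tree_error")
})

test_that("trees serialise to JSON with leaf summaries", {
  pred <- make_predictors(120, seed = 12)
  set.seed(12)
  y <- 3 * pred$sex + rnorm(120)
  tree <- grow_tree(y, pred)
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  doc <- jsonlite::read_json(path)
  expect_identical(length(doc$nodes), length(tree$nodes))
  leaf <- Filter(function(n) n$kind == "leaf", doc$nodes)[[1]]
  expect_true(all(c("n", "mean", "quantiles") %in%
                    names(leaf$response_summary)))
})
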