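#' @title Built-in classifiers
#'
#' @description No SVM or tree-ensemble package ships with the analysis
#'   environment, so the three classifiers are implemented here: a linear
#'   soft-margin SVM trained by dual coordinate descent (the LIBLINEAR
#'   L2-regularized L1-loss algorithm), a small exact CART regression-tree
#'   learner, and on top of it bagged trees (random forest) and
#'   logistic-loss gradient boosting. Each learner exposes `fit`, `predict`
#'   and a per-feature `importance` used by recursive feature elimination:
#'   |w| for the SVM, total split impurity reduction for the tree ensembles.
#' @name learners
NULL

#' Fit a linear soft-margin SVM by dual coordinate descent
#'
#' Hinge loss, L2 regularization, cost parameter C = 1 by default; labels
#' are coerced to -1/+1. Deterministic given the seed (coordinate order is
#' shuffled per epoch). Features should be standardized by the caller.
#'
#' @param X n x p numeric matrix
#' @param y labels (0/1 or -1/+1)
#' @param C cost parameter
#' @param max_epochs coordinate-descent epochs
#' @param tol stop when the largest projected-gradient step falls below this
#' @param seed integer seed for coordinate shuffling
#' @return object of class `svm_linear`: `w`, `b`
#' @export
svm_linear_fit <- function(X, y, C = 1, max_epochs = 200L, tol = 1e-4,
                           seed = 1L) {
  X <- as.matrix(X)
  yy <- ifelse(y > 0, 1, -1)
  n <- nrow(X)
  Xb <- cbind(X, 1)              # bias folded into the weight vector
  qii <- rowSums(Xb^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xb))
  with_seed(seed, {
    for (ep in seq_len(max_epochs)) {
      idx <- sample.int(n)
      max_step <- 0
      for (i in idx) {
        gi <- yy[i] * sum(w * Xb[i, ]) - 1
        pg <- if (alpha[i] == 0) min(gi, 0)
              else if (alpha[i] == C) max(gi, 0) else gi
        if (abs(pg) > 1e-12) {
          old <- alpha[i]
          alpha[i] <- min(max(alpha[i] - gi / qii[i], 0), C)
          d <- alpha[i] - old
          if (d != 0) w <- w + d * yy[i] * Xb[i, ]
          max_step <- max(max_step, abs(d))
        }
      }
      if (max_step < tol) break
    }
  })
  structure(list(w = w[-length(w)], b = w[length(w)]), class = "svm_linear")
}

#' @rdname svm_linear_fit
#' @param object fitted `svm_linear`
#' @param newdata matrix of predictors
#' @return predicted labels in {0, 1}
#' @export
svm_linear_predict <- function(object, newdata) {
  s <- as.matrix(newdata) %*% object$w + object$b
  as.integer(s > 0)
}

# ---- CART regression trees (exact greedy splits, squared loss) -----------

best_split <- function(x, g) {
  ord <- order(x)
  xs <- x[ord]
  gs <- g[ord]
  n <- length(gs)
  cs <- cumsum(gs)
  cs2 <- cumsum(gs^2)
  tot <- cs[n]
  nl <- seq_len(n - 1)
  # candidate split after position i (only where x strictly increases)
  valid <- xs[nl] < xs[nl + 1]
  if (!any(valid)) return(NULL)
  sseL <- cs2[nl] - cs[nl]^2 / nl
  nr <- n - nl
  sseR <- (cs2[n] - cs2[nl]) - (tot - cs[nl])^2 / nr
  sse0 <- cs2[n] - tot^2 / n
  gain <- sse0 - (sseL + sseR)
  gain[!valid] <- -Inf
  i <- which.max(gain)
  if (!is.finite(gain[i]) || gain[i] <= 1e-12) return(NULL)
  list(threshold = (xs[i] + xs[i + 1]) / 2, gain = gain[i])
}

grow_tree <- function(X, g, depth, max_depth, min_node, mtry, nodes,
                      rows) {
  node <- list(value = mean(g[rows]), feature = NA_integer_,
               threshold = NA_real_, gain = 0, left = NA_integer_,
               right = NA_integer_)
  id <- length(nodes) + 1L
  nodes[[id]] <- node
  if (depth >= max_depth || length(rows) < 2 * min_node) return(nodes)
  feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
  best <- NULL
  for (f in feats) {
    sp <- best_split(X[rows, f], g[rows])
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- sp
      best$feature <- f
    }
  }
  if (is.null(best)) return(nodes)
  go_left <- X[rows, best$feature] <= best$threshold
  if (sum(go_left) < min_node || sum(!go_left) < min_node) return(nodes)
  nodes[[id]]$feature <- best$feature
  nodes[[id]]$threshold <- best$threshold
  nodes[[id]]$gain <- best$gain
  nodes[[id]]$left <- length(nodes) + 1L
  nodes <- grow_tree(X, g, depth + 1L, max_depth, min_node, mtry, nodes,
                     rows[go_left])
  nodes[[id]]$right <- length(nodes) + 1L
  nodes <- grow_tree(X, g, depth + 1L, max_depth, min_node, mtry, nodes,
                     rows[!go_left])
  nodes
}

fit_cart <- function(X, g, max_depth = 2L, min_node = 5L, mtry = ncol(X)) {
  nodes <- grow_tree(as.matrix(X), g, 0L, max_depth, min_node, mtry,
                     list(), seq_along(g))
  structure(list(nodes = nodes, p = ncol(X)), class = "cart_tree")
}

predict_cart <- function(tree, X) {
  X <- as.matrix(X)
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (is.na(nd$feature)) return(nd$value)
      id <- if (X[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }, 0)
}

cart_importance <- function(tree) {
  imp <- numeric(tree$p)
  for (nd in tree$nodes) {
    if (!is.na(nd$feature)) imp[nd$feature] <- imp[nd$feature] + nd$gain
  }
  imp
}

#' Random forest: bagged CART trees with feature subsampling
#'
#' Regression trees on +/-1 labels; prediction by the sign of the ensemble
#' mean. Importance is the impurity reduction summed over all trees.
#'
#' @param X n x p matrix
#' @param y labels (0/1)
#' @param n_trees ensemble size (default 100)
#' @param max_depth per-tree depth (default 4)
#' @param mtry features tried per split (default sqrt(p))
#' @param seed integer seed
#' @return object of class `random_forest`
#' @export
random_forest_fit <- function(X, y, n_trees = 100L, max_depth = 4L,
                              mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  yy <- ifelse(y > 0, 1, -1)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      rows <- sample.int(n, n, replace = TRUE)
      fit_cart(X[rows, , drop = FALSE], yy[rows], max_depth = max_depth,
               min_node = 2L, mtry = mtry)
    })
  })
  structure(list(trees = trees, p = ncol(X)), class = "random_forest")
}

#' @rdname random_forest_fit
#' @param object fitted forest
#' @param newdata matrix of predictors
#' @return predicted labels in {0, 1}
#' @export
random_forest_predict <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  pred <- rowMeans(vapply(object$trees,
                          function(tr) predict_cart(tr, newdata),
                          numeric(nrow(newdata))))
  as.integer(pred > 0)
}

#' Gradient boosting with logistic loss and shallow CART trees
#'
#' Standard gradient boosting machine: depth-2 regression trees fit to the
#' negative gradient of the binomial deviance, shrinkage 0.1, subsample 1.
#'
#' @param X n x p matrix
#' @param y labels (0/1)
#' @param n_trees boosting rounds (default 100)
#' @param learning_rate shrinkage (default 0.1)
#' @param max_depth per-tree depth (default 2)
#' @param seed integer seed (tree growth is deterministic at full mtry; the
#'   seed only matters if `mtry` is set)
#' @param mtry features tried per split (default all)
#' @return object of class `gradient_boosting`
#' @export
gradient_boosting_fit <- function(X, y, n_trees = 100L, learning_rate = 0.1,
                                  max_depth = 2L, seed = 1L, mtry = NULL) {
  X <- as.matrix(X)
  y01 <- as.integer(y > 0)
  if (is.null(mtry)) mtry <- ncol(X)
  p0 <- mean(y01)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, nrow(X))
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (b in seq_len(n_trees)) {
      prob <- 1 / (1 + exp(-f))
      grad <- y01 - prob                      # negative gradient
      tr <- fit_cart(X, grad, max_depth = max_depth, min_node = 5L,
                     mtry = mtry)
      f <- f + learning_rate * predict_cart(tr, X)
      trees[[b]] <- tr
    }
  })
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 p = ncol(X)), class = "gradient_boosting")
}

#' @rdname gradient_boosting_fit
#' @param object fitted booster
#' @param newdata matrix of predictors
#' @return predicted labels in {0, 1}
#' @export
gradient_boosting_predict <- function(object, newdata) {
  f <- rep(object$f0, nrow(as.matrix(newdata)))
  for (tr in object$trees) f <- f + object$learning_rate *
      predict_cart(tr, newdata)
  as.integer(f > 0)
}

#' Uniform interface over the three classifiers
#'
#' @param model one of "svm", "rf", "gb"
#' @param X,y training data
#' @param seed integer seed
#' @param ... passed to the underlying fit
#' @return list: `fit`, `predict(newdata)`, `importance` (per-feature)
#' @export
fit_classifier <- function(model = c("svm", "rf", "gb"), X, y, seed = 1L,
                           ...) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (model == "svm") {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    f <- svm_linear_fit(Xs, y, seed = seed, ...)
    list(fit = f,
         predict = function(newdata) {
           Xn <- sweep(sweep(as.matrix(newdata), 2, ctr), 2, scl, "/")
           svm_linear_predict(f, Xn)
         },
         importance = abs(f$w))
  } else if (model == "rf") {
    f <- random_forest_fit(X, y, seed = seed, ...)
    imp <- Reduce(`+`, lapply(f$trees, cart_importance))
    list(fit = f,
         predict = function(newdata) random_forest_predict(f, newdata),
         importance = imp)
  } else {
    f <- gradient_boosting_fit(X, y, seed = seed, ...)
    imp <- Reduce(`+`, lapply(f$trees, cart_importance))
    list(fit = f,
         predict = function(newdata) gradient_boosting_predict(f, newdata),
         importance = imp)
  }
}
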