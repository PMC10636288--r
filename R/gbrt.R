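# Least-squares gradient-boosted regression trees: the surrogate that
# maps encoded architectures to fitness. Deterministic (no row/column
# subsampling), depth-limited, with gain (squared-error-reduction)
# feature importances — the same quantities a boosted-tree library
# exposes, sized for the tiny n (tens to hundreds of records) this
# search produces.

# Internal: fit one regression tree to (x, y) by recursive best-split
# on SSE gain. Returns flat node vectors plus per-feature gain.
fit_tree <- function(x, y, max_depth, min_obs) {
  nf <- ncol(x)
  feature <- integer(0L); threshold <- numeric(0L)
  left <- integer(0L); right <- integer(0L); value <- numeric(0L)
  gain_by_feature <- numeric(nf)

  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    value[length(value) + 1L] <<- NA_real_
    length(feature)
  }

  best_split <- function(rows) {
    yy <- y[rows]
    n <- length(rows)
    sse_tot <- sum(yy^2) - sum(yy)^2 / n
    cand <- vector("list", nf)
    gains <- rep(-Inf, nf)
    for (j in seq_len(nf)) {
      xx <- x[rows, j]
      o <- order(xx, method = "radix")
      xs <- xx[o]; ys <- yy[o]
      cs <- cumsum(ys); cs2 <- cumsum(ys^2)
      k <- seq_len(n - 1L)
      valid <- xs[k] < xs[k + 1L] & k >= min_obs & (n - k) >= min_obs
      if (!any(valid)) next
      sse_l <- cs2[k] - cs[k]^2 / k
      sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
      gain <- sse_tot - (sse_l + sse_r)
      gain[!valid] <- -Inf
      b <- which.max(gain)
      gains[j] <- gain[b]
      cand[[j]] <- list(gain = gain[b], feature = j,
                        threshold = (xs[b] + xs[b + 1L]) / 2,
                        left_rows = rows[o[seq_len(b)]],
                        right_rows = rows[o[(b + 1L):n]])
    }
    top <- max(gains)
    if (!is.finite(top) || top <= 1e-12) return(NULL)
    # exact gain ties (e.g. anti-correlated one-hot siblings produce the
    # same partition) are broken at random so importance spreads evenly
    tied <- which(gains >= top - 1e-12 * max(1, abs(top)))
    cand[[if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]]]
  }

  grow <- function(rows, depth) {
    id <- new_node()
    sp <- if (depth < max_depth && length(rows) >= 2L * min_obs)
      best_split(rows) else NULL
    if (is.null(sp)) {
      value[id] <<- mean(y[rows])
    } else {
      feature[id] <<- sp$feature
      threshold[id] <<- sp$threshold
      gain_by_feature[sp$feature] <<- gain_by_feature[sp$feature] + sp$gain
      left[id] <<- grow(sp$left_rows, depth + 1L)
      right[id] <<- grow(sp$right_rows, depth + 1L)
    }
    id
  }

  grow(seq_len(nrow(x)), 0L)
  list(feature = feature, threshold = threshold, left = left, right = right,
       value = value, gain = gain_by_feature)
}

# Internal: vectorized prediction for one tree
predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  recurse <- function(id, rows) {
    if (is.na(tree$feature[id])) {
      out[rows] <<- tree$value[id]
    } else {
      go_left <- x[rows, tree$feature[id]] <= tree$threshold[id]
      if (any(go_left)) recurse(tree$left[id], rows[go_left])
      if (any(!go_left)) recurse(tree$right[id], rows[!go_left])
    }
  }
  if (nrow(x) > 0L) recurse(1L, seq_len(nrow(x)))
  out
}

#' Fit a gradient-boosted regression-tree ensemble
#'
#' Standard least-squares boosting: start from the mean, then repeatedly
#' fit a depth-limited regression tree to the residuals and add it with
#' shrinkage `learning_rate`. Fitting is deterministic — there is no
#' row/column subsampling, so `seed` only labels the model. Boosting
#' stops early once the residual sum of squares is negligible.
#'
#' @param x Numeric feature matrix.
#' @param y Numeric response.
#' @param n_trees Maximum number of trees (default 1000).
#' @param learning_rate Shrinkage (default 0.1).
#' @param max_depth Tree depth limit (default 3).
#' @param min_obs Minimum observations per child (default 2).
#' @param seed Integer seed for split tie-breaking; the fit is
#'   deterministic given it (no row/column subsampling).
#' @return A `gbrt_model`: trees, intercept, shrinkage, per-feature gain
#'   `importance` (named by column), `r_squared` on the training data,
#'   and `n_trees_used`.
#' @export
gbrt_fit <- function(x, y, n_trees = 1000L, learning_rate = 0.1,
                     max_depth = 3L, min_obs = 2L, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  set.seed(as.integer(seed))
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  sst <- sum((y - f0)^2)
  trees <- list()
  gain <- numeric(ncol(x))
  for (t in seq_len(n_trees)) {
    resid <- y - pred
    if (sum(resid^2) <= max(1e-12 * max(sst, 1), 1e-300)) break
    tree <- fit_tree(x, resid, max_depth = max_depth, min_obs = min_obs)
    if (all(is.na(tree$feature))) break # no further splittable structure
    trees[[length(trees) + 1L]] <- tree
    gain <- gain + tree$gain
    pred <- pred + learning_rate * predict_tree(tree, x)
  }
  sse <- sum((y - pred)^2)
  structure(list(trees = trees, f0 = f0, learning_rate = learning_rate,
                 importance = stats::setNames(gain, colnames(x)),
                 r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
                 n_trees_used = length(trees), seed = seed),
            class = "gbrt_model")
}

#' Predict from a boosted-tree ensemble
#' @param object A `gbrt_model`.
#' @param x Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.gbrt_model <- function(object, x, ...) {
  x <- as.matrix(x)
  pred <- rep(object$f0, nrow(x))
  for (tree in object$trees)
    pred <- pred + object$learning_rate * predict_tree(tree, x)
  pred
}
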