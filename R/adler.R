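# The feed-forward classifier realized from an individual: k hidden
# blocks, each dense -> (batch norm) -> activation -> dropout, then a
# dense softmax head; trained by minimizing L1/L2-penalized mean
# cross-entropy with early stopping on validation accuracy.

BN_EPS <- 1e-5
PROB_CLIP <- 1e-12

# Internal activation functions and their derivatives (in terms of the
# activation output, which is all backprop needs for these three).
act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     dfda = function(a) (a > 0) * 1),
         tanh = list(f = base::tanh,
                     dfda = function(a) 1 - a^2),
         sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                        dfda = function(a) a * (1 - a)),
         stop("unknown activation: ", name))
}

#' Build an untrained network from an individual
#'
#' Realizes the architecture: `k` hidden blocks (dense layer computing
#' `W x - theta`, optional batch normalization, activation, dropout)
#' followed by a dense softmax layer of width `n_classes`. Weights use
#' Glorot-uniform initialization, deterministic given `seed`.
#'
#' @param ind An `adler_individual` (depth >= 1).
#' @param n_inputs Number of input features (>= 1).
#' @param n_classes Number of output classes (>= 1).
#' @param seed Integer seed for weight initialization.
#' @return An `adler_network` list (untrained parameters + architecture).
#' @export
build_network <- function(ind, n_inputs, n_classes, seed = 1L) {
  stopifnot(inherits(ind, "adler_individual"))
  if (n_inputs < 1L || n_classes < 1L) stop("n_inputs and n_classes must be >= 1")
  if (length(ind$layers) < 1L) stop("network needs at least one hidden layer")
  for (h in ind$layers) act_fun(h$activation) # validate names up front
  set.seed(as.integer(seed))
  glorot <- function(d_in, d_out) {
    lim <- sqrt(6 / (d_in + d_out))
    matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
  }
  d_prev <- n_inputs
  layers <- vector("list", length(ind$layers))
  for (l in seq_along(ind$layers)) {
    h <- ind$layers[[l]]
    layers[[l]] <- list(
      W = glorot(d_prev, h$width), theta = numeric(h$width),
      activation = h$activation, dropout = h$dropout,
      batchnorm = h$batchnorm, l1 = h$l1, l2 = h$l2,
      gamma = if (h$batchnorm) rep(1, h$width),
      beta = if (h$batchnorm) numeric(h$width),
      run_mean = if (h$batchnorm) numeric(h$width),
      run_var = if (h$batchnorm) rep(1, h$width))
    d_prev <- h$width
  }
  structure(list(individual = ind, layers = layers,
                 W_out = glorot(d_prev, n_classes),
                 theta_out = numeric(n_classes),
                 n_inputs = n_inputs, n_classes = n_classes, seed = seed),
            class = "adler_network")
}

#' Dropout layer forward pass
#'
#' Training mode keeps each unit with probability `1 - rho` (Bernoulli
#' mask) and rescales survivors by `1/(1 - rho)` ("inverted" dropout) so
#' the expected activation is preserved; inference mode is the identity.
#'
#' @param x Numeric vector or matrix of activations.
#' @param rho Drop probability in `[0, 1)`.
#' @param training Logical; masking happens only when `TRUE`.
#' @param seed Optional integer seed for the mask.
#' @return Activations of the same shape.
#' @export
dropout_forward <- function(x, rho, training = TRUE, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (!training || rho == 0) return(x)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mask <- stats::runif(length(x)) >= rho
  x * mask / (1 - rho)
}

#' Batch-normalization forward pass
#'
#' Training mode standardizes each feature by the batch mean and
#' (biased) batch variance with an `eps` guard, then applies the affine
#' transform `gamma * xhat + beta`; inference mode uses the supplied
#' running statistics.
#'
#' @param x Numeric matrix (batch x features).
#' @param gamma,beta Per-feature affine parameters.
#' @param eps Variance guard (default `1e-5`).
#' @param training Logical; training requires batch size >= 2.
#' @param running Optional list with `mean` and `var` used at inference.
#' @return Matrix of normalized activations.
#' @export
batchnorm_forward <- function(x, gamma, beta, eps = BN_EPS, training = TRUE,
                              running = NULL) {
  x <- as.matrix(x)
  if (training) {
    if (nrow(x) < 2L) stop("batch normalization needs batch size >= 2 in training")
    mu <- matrixStats::colMeans2(x)
    v <- matrixStats::colMeans2(sweep(x, 2L, mu)^2)
  } else {
    if (is.null(running)) stop("inference mode requires running statistics")
    mu <- running$mean; v <- running$var
  }
  xhat <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + eps), "/")
  sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
}

# Internal: numerically stable row-wise softmax
softmax_rows <- function(z) {
  z <- z - matrixStats::rowMaxs(z)
  ez <- exp(z)
  ez / matrixStats::rowSums2(ez)
}

#' Penalized cross-entropy loss
#'
#' Mean negative log-likelihood `-(1/n) sum_i sum_t y[i,t] log(p[i,t])`
#' plus the per-layer penalties `sum_l l1[l] * ||W_l||_1 + l2[l] *
#' ||W_l||_F^2`. Probabilities at a true class are clipped at `1e-12`
#' (with a warning) before the log.
#'
#' @param probs Matrix of predicted class probabilities (rows sum to 1).
#' @param y One-hot label matrix of the same shape.
#' @param weights List of weight matrices entering the penalty.
#' @param l1,l2 Non-negative coefficient vectors, one per weight matrix
#'   (recycled if scalar).
#' @return Scalar loss.
#' @export
compute_loss <- function(probs, y, weights = list(), l1 = 0, l2 = 0) {
  probs <- as.matrix(probs); y <- as.matrix(y)
  stopifnot(all(dim(probs) == dim(y)))
  if (any(l1 < 0) || any(l2 < 0)) stop("penalty coefficients must be >= 0")
  p_true <- probs[y > 0]
  if (any(p_true < PROB_CLIP)) {
    warning("probability at a true class below 1e-12; clipped")
    p_true <- pmax(p_true, PROB_CLIP)
  }
  nll <- -sum(y[y > 0] * log(p_true)) / nrow(probs)
  l1 <- rep_len(l1, length(weights)); l2 <- rep_len(l2, length(weights))
  pen <- 0
  for (i in seq_along(weights))
    pen <- pen + l1[i] * sum(abs(weights[[i]])) + l2[i] * sum(weights[[i]]^2)
  nll + pen
}

# Internal: full forward pass. Returns probs and per-layer caches when
# training (needed by backprop); updates running BN stats in place via
# the returned net.
forward_pass <- function(net, x, training = FALSE, bn_momentum = 0.1) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    z <- a %*% ly$W
    z <- sweep(z, 2L, ly$theta)
    if (ly$batchnorm) {
      if (training) {
        mu <- matrixStats::colMeans2(z)
        v <- matrixStats::colMeans2(sweep(z, 2L, mu)^2)
        net$layers[[l]]$run_mean <- (1 - bn_momentum) * ly$run_mean +
          bn_momentum * mu
        net$layers[[l]]$run_var <- (1 - bn_momentum) * ly$run_var +
          bn_momentum * v
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      inv_sd <- 1 / sqrt(v + BN_EPS)
      zhat <- sweep(sweep(z, 2L, mu), 2L, inv_sd, "*")
      zb <- sweep(sweep(zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    } else {
      zhat <- NULL; inv_sd <- NULL; mu <- NULL; zb <- z
    }
    act <- act_fun(ly$activation)
    a_out <- act$f(zb)
    if (training && ly$dropout > 0) {
      mask <- matrix(stats::runif(length(a_out)) >= ly$dropout,
                     nrow(a_out), ncol(a_out))
      a_drop <- a_out * mask / (1 - ly$dropout)
    } else {
      mask <- NULL; a_drop <- a_out
    }
    caches[[l]] <- list(input = a, z = z, zhat = zhat, inv_sd = inv_sd,
                        a_out = a_out, mask = mask)
    a <- a_drop
  }
  logits <- sweep(a %*% net$W_out, 2L, net$theta_out)
  list(probs = softmax_rows(logits), head_input = a, caches = caches,
       net = net)
}

# Internal: backprop of the penalized mean cross-entropy. Returns a
# named list of gradients matching parameter names.
backward_pass <- function(net, fwd, y) {
  m <- nrow(y)
  grads <- list()
  dlogits <- (fwd$probs - y) / m
  grads$W_out <- crossprod(fwd$head_input, dlogits)
  grads$theta_out <- -matrixStats::colSums2(dlogits)
  # output matrix carries the last hidden layer's penalty pair
  kk <- length(net$layers)
  grads$W_out <- grads$W_out + net$layers[[kk]]$l1 * sign(net$W_out) +
    2 * net$layers[[kk]]$l2 * net$W_out
  da <- tcrossprod(dlogits, net$W_out)
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]; ch <- fwd$caches[[l]]
    if (!is.null(ch$mask)) da <- da * ch$mask / (1 - ly$dropout)
    act <- act_fun(ly$activation)
    dzb <- da * act$dfda(ch$a_out)
    if (ly$batchnorm) {
      grads[[paste0("gamma_", l)]] <- matrixStats::colSums2(dzb * ch$zhat)
      grads[[paste0("beta_", l)]] <- matrixStats::colSums2(dzb)
      dxhat <- sweep(dzb, 2L, ly$gamma, "*")
      # standard BN backward in terms of xhat and 1/sd
      sum_dxhat <- matrixStats::colSums2(dxhat)
      sum_dxhat_xhat <- matrixStats::colSums2(dxhat * ch$zhat)
      dz <- sweep(dxhat, 2L, sum_dxhat / nrow(dzb))
      dz <- dz - sweep(ch$zhat, 2L, sum_dxhat_xhat / nrow(dzb), "*")
      dz <- sweep(dz, 2L, ch$inv_sd, "*")
    } else {
      dz <- dzb
    }
    gW <- crossprod(ch$input, dz) + ly$l1 * sign(ly$W) + 2 * ly$l2 * ly$W
    grads[[paste0("W_", l)]] <- gW
    grads[[paste0("theta_", l)]] <- -matrixStats::colSums2(dz)
    da <- tcrossprod(dz, ly$W)
  }
  grads
}

# Internal parameter plumbing: get/set the trainable tensors by name
get_params <- function(net) {
  p <- list(W_out = net$W_out, theta_out = net$theta_out)
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    p[[paste0("W_", l)]] <- ly$W
    p[[paste0("theta_", l)]] <- ly$theta
    if (ly$batchnorm) {
      p[[paste0("gamma_", l)]] <- ly$gamma
      p[[paste0("beta_", l)]] <- ly$beta
    }
  }
  p
}

set_params <- function(net, p) {
  net$W_out <- p$W_out; net$theta_out <- p$theta_out
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- p[[paste0("W_", l)]]
    net$layers[[l]]$theta <- p[[paste0("theta_", l)]]
    if (net$layers[[l]]$batchnorm) {
      net$layers[[l]]$gamma <- p[[paste0("gamma_", l)]]
      net$layers[[l]]$beta <- p[[paste0("beta_", l)]]
    }
  }
  net
}

# Internal: one optimizer step. state persists across calls.
optim_step <- function(params, grads, state, optimizer, lr) {
  if (is.null(state$t)) state$t <- 0L
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (optimizer == "sgd") { # momentum SGD (mu = 0.9)
      v <- state$v[[nm]] %||% (g * 0)
      v <- 0.9 * v - lr * g
      state$v[[nm]] <- v
      params[[nm]] <- params[[nm]] + v
    } else if (optimizer == "rmsprop") {
      s <- state$s[[nm]] %||% (g * 0)
      s <- 0.9 * s + 0.1 * g^2
      state$s[[nm]] <- s
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(s) + 1e-8)
    } else if (optimizer == "adam") {
      m <- state$m[[nm]] %||% (g * 0)
      v <- state$v[[nm]] %||% (g * 0)
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g^2
      state$m[[nm]] <- m; state$v[[nm]] <- v
      mhat <- m / (1 - 0.9^state$t)
      vhat <- v / (1 - 0.999^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    } else stop("unknown optimizer: ", optimizer)
  }
  list(params = params, state = state)
}

# Internal: overall accuracy of argmax predictions
accuracy_of <- function(probs, y_idx) {
  mean(max.col(probs, ties.method = "first") == y_idx)
}

#' Train a network on numeric matrices
#'
#' Minimizes the penalized cross-entropy with the individual's optimizer
#' and learning rate for at most `epochs` epochs (mini-batches of
#' `batch_size`), stopping early once validation accuracy has not
#' improved for more than `patience` consecutive epochs, and returning
#' the weights of the best validation epoch. A non-finite training loss
#' aborts training (`aborted = TRUE`; callers score such fits 0).
#'
#' @param net An [build_network()] result.
#' @param x_train,x_val Numeric matrices (already standardized).
#' @param y_train,y_val Integer class indices in `1..n_classes`.
#' @param patience Early-stopping patience in epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed for batch shuffling and dropout masks.
#' @return The trained `adler_network` with `history` (per-epoch
#'   train/validation loss and accuracy), `best_epoch`, and `aborted`.
#' @export
train_network <- function(net, x_train, y_train, x_val, y_val,
                          patience = 50L, batch_size = 32L, seed = 1L) {
  stopifnot(inherits(net, "adler_network"))
  if (length(y_val) == 0L) stop("validation split must be non-empty")
  if (patience < 0L) stop("patience must be >= 0")
  ind <- net$individual
  n <- nrow(x_train)
  y_onehot <- diag(net$n_classes)[y_train, , drop = FALSE]
  set.seed(as.integer(seed))
  state <- list()
  hist <- data.frame(epoch = integer(0L), train_loss = numeric(0L),
                     train_acc = numeric(0L), val_loss = numeric(0L),
                     val_acc = numeric(0L))
  best <- list(acc = -Inf, epoch = 0L, params = get_params(net),
               layers = net$layers)
  wait <- 0L
  aborted <- FALSE
  eff_bs <- min(batch_size, n)
  for (epoch in seq_len(ind$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = eff_bs)) {
      idx <- ord[start:min(start + eff_bs - 1L, n)]
      if (length(idx) < 2L && any(vapply(net$layers, `[[`, TRUE, "batchnorm")))
        next # BN needs batch size >= 2; drop trailing singleton batch
      fwd <- forward_pass(net, x_train[idx, , drop = FALSE], training = TRUE)
      net <- fwd$net # running BN stats advanced
      batch_loss <- compute_loss(fwd$probs,
                                 y_onehot[idx, , drop = FALSE],
                                 weights = list(), l1 = 0, l2 = 0)
      if (!is.finite(batch_loss)) { aborted <- TRUE; break }
      grads <- backward_pass(net, fwd, y_onehot[idx, , drop = FALSE])
      if (!all(vapply(grads, function(g) all(is.finite(g)), TRUE))) {
        aborted <- TRUE; break
      }
      stepped <- optim_step(get_params(net), grads, state, ind$optimizer,
                            ind$lr)
      state <- stepped$state
      net <- set_params(net, stepped$params)
      epoch_loss <- epoch_loss + batch_loss * length(idx)
      nb <- nb + length(idx)
    }
    if (aborted) break
    tr <- forward_pass(net, x_train, training = FALSE)
    vl <- forward_pass(net, x_val, training = FALSE)
    y_val_onehot <- diag(net$n_classes)[y_val, , drop = FALSE]
    val_acc <- accuracy_of(vl$probs, y_val)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = epoch_loss / max(nb, 1L),
      train_acc = accuracy_of(tr$probs, y_train),
      val_loss = suppressWarnings(compute_loss(vl$probs, y_val_onehot)),
      val_acc = val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, params = get_params(net),
                   layers = net$layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > patience) break
    }
  }
  if (best$epoch > 0L) {
    net$layers <- best$layers # restores BN running stats of the best epoch
    net <- set_params(net, best$params)
  }
  net$history <- hist
  net$best_epoch <- best$epoch
  net$best_val_acc <- if (is.finite(best$acc)) best$acc else 0
  net$aborted <- aborted
  net
}

#' Fit a classifier to an expression matrix
#'
#' High-level training wrapper: aligns labels, per-gene standardizes the
#' training expression (mean/sd of the training split only; recorded in
#' the model for prediction), builds the network from the individual and
#' trains it with early stopping against the supplied validation split
#' (or a stratified 20% carve-out when none is given).
#'
#' @param expr Training [expression_matrix()].
#' @param labels A [label_table()] covering (at least) the training
#'   samples.
#' @param ind An `adler_individual`.
#' @param val_expr,val_labels Optional explicit validation split.
#' @param patience Early-stopping patience (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed (initialization, carve-out, shuffling).
#' @return An `adler_model`: the trained network plus `gene_ids`,
#'   `class_names`, standardization vectors and training history.
#' @export
fit_adler <- function(expr, labels, ind, val_expr = NULL, val_labels = NULL,
                      patience = 50L, batch_size = 32L, seed = 1L) {
  cls <- class_names(labels)
  y_all <- align_labels(expr, labels)
  x_all <- unclass(expr)
  if (is.null(val_expr)) { # stratified 20% carve-out for early stopping
    folds <- stratified_folds(y_all, k = 5L, seed = derive_seed(seed, "val"))
    val_idx <- folds == 1L
    x_val <- x_all[val_idx, , drop = FALSE]
    y_val <- y_all[val_idx]
    x_tr <- x_all[!val_idx, , drop = FALSE]
    y_tr <- y_all[!val_idx]
  } else {
    x_tr <- x_all; y_tr <- y_all
    x_val <- unclass(val_expr)[, colnames(expr), drop = FALSE]
    y_val <- align_labels(val_expr, val_labels %||% labels)
  }
  mu <- matrixStats::colMeans2(x_tr)
  sd_ <- matrixStats::colSds(x_tr)
  sd_[sd_ < 1e-8] <- 1 # constant genes carry no signal; avoid 0-division
  standardize <- function(x) sweep(sweep(x, 2L, mu), 2L, sd_, "/")
  net <- build_network(ind, n_inputs = ncol(x_tr), n_classes = length(cls),
                       seed = derive_seed(seed, "init"))
  net <- train_network(net, standardize(x_tr), match(y_tr, cls),
                       standardize(x_val), match(y_val, cls),
                       patience = patience, batch_size = batch_size,
                       seed = derive_seed(seed, "train"))
  structure(list(net = net, individual = ind, gene_ids = colnames(expr),
                 class_names = cls, center = mu, scale = sd_,
                 history = net$history, best_epoch = net$best_epoch,
                 val_accuracy = net$best_val_acc, aborted = net$aborted,
                 seed = seed),
            class = "adler_model")
}

#' Predict subtype probabilities for new samples
#'
#' Aligns the input genes to the training gene set by identifier
#' (column order is irrelevant; missing genes are an error listing
#' them), applies the stored standardization, and runs the network in
#' inference mode.
#'
#' @param object An `adler_model` from [fit_adler()].
#' @param expr An [expression_matrix()] containing the training genes.
#' @param ... Unused.
#' @return List with `prob` (samples x classes matrix, rows sum to 1)
#'   and `label` (argmax class, lowest class index on exact ties).
#' @export
predict.adler_model <- function(object, expr, ...) {
  miss <- setdiff(object$gene_ids, colnames(expr))
  if (length(miss) > 0L)
    stop("genes missing from input: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(", ... (%d total)", length(miss)))
  x <- unclass(expr)[, object$gene_ids, drop = FALSE]
  x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  probs <- forward_pass(object$net, x, training = FALSE)$probs
  colnames(probs) <- object$class_names
  rownames(probs) <- rownames(expr)
  list(prob = probs,
       label = object$class_names[max.col(probs, ties.method = "first")])
}

#' @export
print.adler_model <- function(x, ...) {
  cat("<adler_model> ", length(x$gene_ids), " genes -> ",
      length(x$class_names), " classes; best epoch ", x$best_epoch,
      " (val acc ", sprintf("%.3f", x$val_accuracy), ")",
      if (isTRUE(x$aborted)) " [ABORTED]", "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to a directory
#'
#' Plain-text persistence: `architecture.json` (decoded individual,
#' class names, gene ids, standardization vectors, history) plus one TSV
#' per weight tensor.
#'
#' @param model An `adler_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_adler_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- get_params(model$net)
  bn <- stats::setNames(lapply(model$net$layers, function(ly) {
    if (ly$batchnorm) list(run_mean = as.numeric(ly$run_mean),
                           run_var = as.numeric(ly$run_var))
  }), paste0("layer", seq_along(model$net$layers)))
  meta <- list(individual = unclass(model$individual),
               gene_ids = model$gene_ids, class_names = model$class_names,
               center = model$center, scale = model$scale,
               best_epoch = model$best_epoch,
               val_accuracy = model$val_accuracy, seed = model$seed,
               aborted = model$aborted, bn_running = bn,
               param_names = names(params))
  jsonlite::write_json(meta, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(params)) {
    m <- as.matrix(params[[nm]])
    writeLines(apply(matrix(sprintf("%.17g", m), nrow(m)), 1L, paste,
                     collapse = "\t"),
               file.path(dir, paste0(nm, ".tsv")), useBytes = TRUE)
  }
  invisible(dir)
}

#' Load a model saved by [save_adler_model()]
#' @param dir Directory written by [save_adler_model()].
#' @return An `adler_model`.
#' @export
load_adler_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  lay_df <- meta$individual$layers # data.frame after simplification
  ind <- individual(meta$individual$epochs, meta$individual$optimizer,
                    meta$individual$lr,
                    lapply(seq_len(nrow(lay_df)),
                           function(i) as.list(lay_df[i, ])))
  net <- build_network(ind, n_inputs = length(meta$gene_ids),
                       n_classes = length(meta$class_names), seed = 1L)
  params <- list()
  for (nm in meta$param_names) {
    m <- as.matrix(data.table::fread(file.path(dir, paste0(nm, ".tsv")),
                                     header = FALSE))
    params[[nm]] <- if (grepl("^(theta|gamma|beta)", nm)) as.numeric(m)
                    else unname(m)
  }
  net <- set_params(net, params)
  for (l in seq_along(net$layers)) {
    if (net$layers[[l]]$batchnorm) {
      bn <- meta$bn_running[[paste0("layer", l)]]
      net$layers[[l]]$run_mean <- as.numeric(bn$run_mean)
      net$layers[[l]]$run_var <- as.numeric(bn$run_var)
    }
  }
  structure(list(net = net, individual = ind, gene_ids = meta$gene_ids,
                 class_names = meta$class_names, center = meta$center,
                 scale = meta$scale, history = NULL,
                 best_epoch = meta$best_epoch,
                 val_accuracy = meta$val_accuracy,
                 aborted = isTRUE(meta$aborted), seed = meta$seed),
            class = "adler_model")
}
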