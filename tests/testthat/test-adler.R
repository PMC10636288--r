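# The feed-forward classifier: layer primitives, loss, gradients,
# training behaviour, prediction contracts.

test_that("build_network realizes the reference topology deterministically", {
  ind <- adler1_individual()
  net <- build_network(ind, n_inputs = 40L, n_classes = 4L, seed = 2L)
  expect_identical(dim(net$layers[[1L]]$W), c(40L, 500L))
  expect_identical(dim(net$layers[[2L]]$W), c(500L, 30L))
  expect_identical(net$layers[[1L]]$activation, "tanh")
  expect_identical(dim(net$W_out), c(30L, 4L))
  net2 <- build_network(ind, 40L, 4L, seed = 2L)
  expect_identical(net$layers[[1L]]$W, net2$layers[[1L]]$W) # same seed
  net3 <- build_network(ind, 40L, 4L, seed = 3L)
  expect_false(identical(net$layers[[1L]]$W, net3$layers[[1L]]$W))
  bad <- ind; bad$layers[[1L]]$activation <- "selu"
  expect_error(build_network(bad, 40L, 4L), "unknown activation")
})

test_that("dropout: identity cases and Monte-Carlo keep fraction", {
  x <- rep(1, 1e5)
  expect_identical(dropout_forward(x, 0, training = TRUE), x)
  expect_identical(dropout_forward(x, 0.7, training = FALSE), x)
  y <- dropout_forward(x, 0.5, training = TRUE, seed = 42L)
  keep <- mean(y > 0)
  expect_lt(abs(keep - 0.5), 0.02)
  expect_lt(abs(mean(y) - 1), 0.02)  # inverted scaling preserves E[x]
  expect_error(dropout_forward(x, 1), "rho")
})

test_that("batch normalization standardizes and respects the affine map", {
  set.seed(8)
  x <- matrix(rnorm(200 * 3, mean = 5, sd = 2), 200, 3)
  out <- batchnorm_forward(x, gamma = rep(1, 3), beta = rep(0, 3))
  expect_equal(colMeans(out), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(out, 2, var), rep(1, 3), tolerance = 1e-2)
  out2 <- batchnorm_forward(x, gamma = rep(2, 3), beta = rep(3, 3))
  expect_equal(colMeans(out2), rep(3, 3), tolerance = 1e-10)
  expect_equal(apply(out2, 2, sd), rep(2, 3), tolerance = 2e-2)
  # constant feature: eps guard keeps output at beta
  xc <- matrix(7, 10, 1)
  expect_equal(as.numeric(batchnorm_forward(xc, 1, 0.5)), rep(0.5, 10),
               tolerance = 1e-8)
  expect_error(batchnorm_forward(matrix(1, 1, 2), c(1, 1), c(0, 0)),
               "batch size")
})

test_that("loss: closed forms and penalty arithmetic", {
  perfect <- diag(2)[c(1, 2, 1), ]
  expect_equal(compute_loss(perfect, perfect), 0)
  unif <- matrix(0.5, 3, 2)
  expect_equal(compute_loss(unif, perfect), log(2), tolerance = 1e-12)
  w <- list(matrix(c(0.2, -0.3), 1, 2)) # |W| sums to 0.5
  expect_equal(compute_loss(unif, perfect, weights = w, l1 = 1, l2 = 0),
               log(2) + 0.5, tolerance = 1e-12)
  expect_equal(compute_loss(unif, perfect, weights = w, l1 = 0, l2 = 2),
               log(2) + 2 * (0.04 + 0.09), tolerance = 1e-12)
  expect_warning(compute_loss(matrix(c(1, 0, 0, 1), 2, 2), diag(2)[2:1, ]),
                 "clipped")
})

test_that("backprop matches finite-difference gradients", {
  # small net exercising BN + dropout-free path with penalties
  ind <- individual(10L, "sgd", 1e-2,
                    list(list(width = 5L, activation = "tanh", dropout = 0,
                              batchnorm = TRUE, l1 = 1e-3, l2 = 1e-3),
                         list(width = 4L, activation = "sigmoid", dropout = 0,
                               batchnorm = FALSE, l1 = 0, l2 = 1e-3)))
  net <- build_network(ind, n_inputs = 6L, n_classes = 3L, seed = 7L)
  set.seed(99)
  x <- matrix(rnorm(12 * 6), 12, 6)
  y <- diag(3)[sample(1:3, 12, TRUE), ]
  loss_at <- function(net) {
    fwd <- dnasearch:::forward_pass(net, x, training = TRUE)
    # penalties as backprop applies them: per-layer + output with last pair
    compute_loss(fwd$probs, y,
                 weights = list(net$layers[[1]]$W, net$layers[[2]]$W,
                                net$W_out),
                 l1 = c(1e-3, 0, 0), l2 = c(1e-3, 1e-3, 1e-3))
  }
  fwd <- dnasearch:::forward_pass(net, x, training = TRUE)
  grads <- dnasearch:::backward_pass(net, fwd, y)
  params <- dnasearch:::get_params(net)
  eps <- 1e-6
  for (nm in c("W_1", "theta_1", "gamma_1", "beta_1", "W_2", "W_out",
               "theta_out")) {
    g <- grads[[nm]]
    idx <- seq_len(min(4L, length(g)))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(dnasearch:::set_params(net, up)) -
                loss_at(dnasearch:::set_params(net, dn))) / (2 * eps)
      expect_equal(unname(g[i]), num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("training learns separable data and is deterministic", {
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 2L, n_per_class = 40L, n_genes = 30L,
                   n_informative_per_class = 5L, effect_size = 4.0,
                   seed = 17L))
  ind <- individual(100L, "adam", 1e-3,
                    list(list(width = 16L, activation = "relu", dropout = 0,
                              batchnorm = FALSE, l1 = 0, l2 = 0)))
  m <- fit_adler(ds$expression, ds$labels, ind, seed = 5L)
  pr <- predict(m, ds$expression)
  expect_gte(mean(pr$label == ds$labels$label), 0.95)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
  m2 <- fit_adler(ds$expression, ds$labels, ind, seed = 5L)
  expect_identical(m$history, m2$history)     # bitwise-deterministic
  expect_identical(m$net$W_out, m2$net$W_out)
})

test_that("early stopping honours patience, including the 0 boundary", {
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 2L, n_per_class = 20L, n_genes = 20L,
                   n_informative_per_class = 3L, effect_size = 2.0,
                   seed = 23L))
  ind <- individual(400L, "sgd", 1e-4,
                    list(list(width = 8L, activation = "tanh", dropout = 0,
                              batchnorm = FALSE, l1 = 0, l2 = 0)))
  m0 <- fit_adler(ds$expression, ds$labels, ind, patience = 0L, seed = 1L)
  # patience 0: the run ends at the first epoch with no improvement
  h <- m0$history
  expect_lt(nrow(h), 400L)
  # every epoch but the last must have improved on the running best
  if (nrow(h) > 2L) {
    run_best <- cummax(h$val_acc)
    expect_true(all(h$val_acc[2:(nrow(h) - 1L)] >
                      run_best[1:(nrow(h) - 2L)]))
  }
  expect_lte(h$val_acc[nrow(h)], max(h$val_acc[-nrow(h)]))
  m50 <- fit_adler(ds$expression, ds$labels, ind, patience = 50L, seed = 1L)
  expect_gte(nrow(m50$history), nrow(m0$history))
})

test_that("regularization pushes weights down and predictions to the prior", {
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 2L, n_per_class = 30L, n_genes = 20L,
                   n_informative_per_class = 4L, effect_size = 3.0,
                   seed = 29L))
  mk <- function(l2) individual(60L, "adam", 1e-2,
    list(list(width = 8L, activation = "tanh", dropout = 0,
              batchnorm = FALSE, l1 = 0, l2 = l2)))
  m_free <- fit_adler(ds$expression, ds$labels, mk(0), seed = 3L)
  m_reg <- fit_adler(ds$expression, ds$labels, mk(10), seed = 3L)
  norm_free <- sum(m_free$net$layers[[1L]]$W^2)
  norm_reg <- sum(m_reg$net$layers[[1L]]$W^2)
  expect_lt(norm_reg, norm_free / 10)
  pr <- predict(m_reg, ds$expression)
  # crushed weights -> probabilities near the uniform class prior
  expect_true(all(abs(pr$prob - 0.5) < 0.2))
})

test_that("prediction aligns genes by id and breaks ties at the lowest index", {
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 2L, n_per_class = 20L, n_genes = 15L,
                   n_informative_per_class = 3L, effect_size = 3.0,
                   seed = 37L))
  ind <- individual(30L, "adam", 1e-2,
                    list(list(width = 8L, activation = "relu", dropout = 0,
                              batchnorm = FALSE, l1 = 0, l2 = 0)))
  m <- fit_adler(ds$expression, ds$labels, ind, seed = 2L)
  x <- unclass(ds$expression)
  shuffled <- expression_matrix(x[, rev(colnames(x)), drop = FALSE])
  expect_identical(predict(m, shuffled)$prob, predict(m, ds$expression)$prob)
  one <- expression_matrix(x[1L, , drop = FALSE])
  expect_identical(nrow(predict(m, one)$prob), 1L)
  expect_error(predict(m, expression_matrix(x[, 1:5, drop = FALSE])),
               "missing")
  # exact tie: zeroed output weights give uniform probabilities
  m_tie <- m
  m_tie$net$W_out[] <- 0
  m_tie$net$theta_out[] <- 0
  pr <- predict(m_tie, ds$expression)
  expect_true(all(pr$prob == 0.5))
  expect_true(all(pr$label == m$class_names[1L]))
})

test_that("model save/load round-trips predictions exactly", {
  ds <- generate_classification_dataset(
    synthetic_spec(n_classes = 3L, n_per_class = 15L, n_genes = 20L,
                   n_informative_per_class = 3L, effect_size = 2.5,
                   seed = 41L))
  ind <- individual(30L, "rmsprop", 1e-3,
                    list(list(width = 8L, activation = "tanh", dropout = 0.2,
                              batchnorm = TRUE, l1 = 0, l2 = 1e-5)))
  m <- fit_adler(ds$expression, ds$labels, ind, seed = 9L)
  dir <- withr::local_tempdir()
  save_adler_model(m, dir)
  m2 <- load_adler_model(dir)
  expect_equal(predict(m2, ds$expression)$prob,
               predict(m, ds$expression)$prob, tolerance = 1e-12)
  expect_identical(m2$class_names, m$class_names)
})
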