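# Shared fixtures, all built in code at test time.

# Tiny 64-configuration pool: six binary decision slots, everything else
# a singleton; max depth 1. Small enough for exhaustive enumeration.
tiny_pool <- function() {
  hyperparameter_pool(
    epochs = c(10L, 20L), optimizer = c("sgd", "adam"), lr = c(1e-2, 1e-3),
    depth = 1L, width = c(8L, 16L), activation = c("relu", "tanh"),
    dropout = c(0, 0.2), batchnorm = FALSE, l1 = 0, l2 = 0)
}

# Deterministic separable fitness on the tiny pool: 0.4 + 0.1 per slot
# set to its "good" value; unique optimum at 1.0.
mock_fitness <- function(ind) {
  s <- (ind$epochs == 20L) + (ind$optimizer == "adam") + (ind$lr == 1e-3) +
    (ind$layers[[1L]]$width == 16L) +
    (ind$layers[[1L]]$activation == "tanh") +
    (ind$layers[[1L]]$dropout == 0.2)
  0.4 + 0.1 * s
}

# Reduced pool for desk-scale end-to-end search runs.
desk_pool <- function() {
  hyperparameter_pool(
    epochs = c(30L, 60L), optimizer = c("adam", "sgd"), lr = c(1e-2, 1e-3),
    depth = c(1L, 2L), width = c(16L, 32L), activation = c("relu", "tanh"),
    dropout = c(0, 0.2), batchnorm = c(TRUE, FALSE), l1 = 0,
    l2 = c(0, 1e-4))
}

# Small expression matrix with explicit values for hand arithmetic.
toy_expression <- function() {
  expression_matrix(
    matrix(c(5, 5, 3, 3,    # gene A: 5 in group, 3 out -> lfc 2
             1, 1, 1, 1,    # gene B: constant
             2, 4, 3, 5),   # gene C: mixed
           nrow = 4, ncol = 3,
           dimnames = list(paste0("s", 1:4), c("gA", "gB", "gC"))))
}

# The two-hidden-layer (500, 30) tanh reference architecture.
adler1_individual <- function(pool = default_pool()) {
  individual(100L, "adam", 1e-3,
             list(list(width = 500L, activation = "tanh", dropout = 0,
                       batchnorm = FALSE, l1 = 0, l2 = 0),
                  list(width = 30L, activation = "tanh", dropout = 0,
                       batchnorm = FALSE, l1 = 0, l2 = 0)),
             pool = pool)
}

# Uniform random-search baseline: best of `budget` uniform draws.
random_search_best <- function(pool, fitness_fn, budget, seed) {
  set.seed(seed)
  best <- -Inf
  for (i in seq_len(budget)) {
    f <- fitness_fn(random_individual(pool))
    if (f > best) best <- f
  }
  best
}
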