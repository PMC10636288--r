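#' Construct a hyperparameter pool
#'
#' The pool fixes the discrete candidate values for every architecture
#' decision: training epochs `e`, optimizer, learning rate, network
#' depth, and per hidden layer the width, activation, dropout rate,
#' batch-normalization flag, and L1/L2 penalty coefficients. Per-layer
#' pools are shared across layers.
#'
#' @param epochs Positive integer epoch choices.
#' @param optimizer Optimizer names among `"sgd"`, `"adam"`, `"rmsprop"`.
#' @param lr Positive learning-rate choices.
#' @param depth Positive integer depth (hidden layer count) choices.
#' @param width Positive integer layer-width choices.
#' @param activation Activation names among `"relu"`, `"tanh"`,
#'   `"sigmoid"`.
#' @param dropout Dropout rates in `[0, 1)`.
#' @param batchnorm Logical batch-norm on/off choices.
#' @param l1,l2 Non-negative penalty coefficient choices.
#' @return A `hyperparameter_pool` list.
#' @export
hyperparameter_pool <- function(epochs = c(50L, 100L, 200L, 400L),
                                optimizer = c("sgd", "adam", "rmsprop"),
                                lr = c(1e-2, 1e-3, 1e-4),
                                depth = c(1L, 2L, 3L),
                                width = c(30L, 100L, 500L, 1000L),
                                activation = c("relu", "tanh", "sigmoid"),
                                dropout = c(0.0, 0.2, 0.5),
                                batchnorm = c(TRUE, FALSE),
                                l1 = c(0, 1e-5, 1e-3),
                                l2 = c(0, 1e-5, 1e-3)) {
  pool <- list(epochs = as.integer(epochs), optimizer = as.character(optimizer),
               lr = as.numeric(lr), depth = as.integer(depth),
               width = as.integer(width), activation = as.character(activation),
               dropout = as.numeric(dropout), batchnorm = as.logical(batchnorm),
               l1 = as.numeric(l1), l2 = as.numeric(l2))
  for (nm in names(pool)) {
    if (length(pool[[nm]]) == 0L) stop("empty choice list: ", nm)
    if (anyDuplicated(pool[[nm]])) stop("duplicate choices in: ", nm)
  }
  if (any(pool$epochs < 1L)) stop("epochs must be positive")
  if (any(pool$lr <= 0)) stop("learning rates must be positive")
  if (any(pool$depth < 1L)) stop("depth must be >= 1")
  if (any(pool$width < 1L)) stop("widths must be positive integers")
  if (!all(pool$optimizer %in% c("sgd", "adam", "rmsprop")))
    stop("unknown optimizer name")
  if (!all(pool$activation %in% c("relu", "tanh", "sigmoid")))
    stop("unknown activation name")
  if (any(pool$dropout < 0 | pool$dropout >= 1))
    stop("dropout rates must lie in [0, 1)")
  if (any(pool$l1 < 0) || any(pool$l2 < 0))
    stop("penalty coefficients must be >= 0")
  class(pool) <- "hyperparameter_pool"
  pool
}

#' Default hyperparameter pool
#'
#' The documented defaults span a two-hidden-layer (500, 30) tanh
#' baseline so the reference architecture is reachable; every list is
#' config-overridable.
#'
#' @return A [hyperparameter_pool()].
#' @export
default_pool <- function() hyperparameter_pool()

#' Total number of distinct configurations in a pool
#'
#' Closed form: prefix choices (epochs x optimizer x lr) times
#' `sum over k in depth of (per-layer block size)^k`, where the block
#' size is the product of the per-layer choice counts.
#'
#' @param pool A [hyperparameter_pool()].
#' @return A double (counts overflow integer range quickly).
#' @export
count_configurations <- function(pool) {
  block <- prod(lengths(pool[c("width", "activation", "dropout",
                               "batchnorm", "l1", "l2")]))
  prod(lengths(pool[c("epochs", "optimizer", "lr")])) *
    sum(block^pool$depth)
}

# Internal: ordered decision slots of the layered graph. Each slot is a
# list(name, field, layer, values, type). Slot order: e -> optimizer ->
# lr -> depth -> per-layer (width, activation, dropout, batchnorm, l1,
# l2) for layers 1..max(depth). Depth precedes the layer slots so a walk
# knows where to stop.
pool_slots <- function(pool) {
  per_layer <- c("width", "activation", "dropout", "batchnorm", "l1", "l2")
  cat_fields <- c("optimizer", "depth", "activation", "batchnorm")
  slots <- list(
    list(name = "epochs", field = "epochs", layer = 0L),
    list(name = "optimizer", field = "optimizer", layer = 0L),
    list(name = "lr", field = "lr", layer = 0L),
    list(name = "depth", field = "depth", layer = 0L))
  for (l in seq_len(max(pool$depth))) {
    for (f in per_layer) {
      slots[[length(slots) + 1L]] <-
        list(name = paste0(f, "_L", l), field = f, layer = l)
    }
  }
  lapply(slots, function(s) {
    s$values <- pool[[s$field]]
    s$type <- if (s$field %in% cat_fields) "categorical" else "numeric"
    s
  })
}

# Internal: encoding layout. Categorical slots contribute a one-hot
# block (one column per candidate value); numeric slots one raw column.
# Returns a list of per-slot column index vectors plus total length.
encoding_layout <- function(pool) {
  slots <- pool_slots(pool)
  cols <- list(); names_out <- character(0L); at <- 0L
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    w <- if (s$type == "categorical") length(s$values) else 1L
    cols[[i]] <- at + seq_len(w)
    names_out <- c(names_out,
                   if (s$type == "categorical")
                     paste0(s$name, "=", s$values) else s$name)
    at <- at + w
  }
  list(slots = slots, columns = cols, length = at, names = names_out)
}

#' Construct a candidate architecture (an individual)
#'
#' @param epochs,optimizer,lr Scalar training hyperparameters, each
#'   drawn from the pool.
#' @param layers List of per-layer specs; each a list with fields
#'   `width`, `activation`, `dropout`, `batchnorm`, `l1`, `l2`.
#' @param pool Optional [hyperparameter_pool()]; when given, every field
#'   is validated against it.
#' @return An `adler_individual` list.
#' @export
individual <- function(epochs, optimizer, lr, layers, pool = NULL) {
  ind <- list(epochs = as.integer(epochs), optimizer = as.character(optimizer),
              lr = as.numeric(lr),
              layers = lapply(layers, function(h)
                list(width = as.integer(h$width),
                     activation = as.character(h$activation),
                     dropout = as.numeric(h$dropout),
                     batchnorm = as.logical(h$batchnorm),
                     l1 = as.numeric(h$l1), l2 = as.numeric(h$l2))))
  class(ind) <- "adler_individual"
  if (!is.null(pool)) validate_individual(ind, pool)
  ind
}

# Internal: check every field of an individual against its pool
validate_individual <- function(ind, pool) {
  chk <- function(v, choices, what) {
    if (!v %in% choices) stop("value ", v, " not in pool for ", what)
  }
  chk(ind$epochs, pool$epochs, "epochs")
  chk(ind$optimizer, pool$optimizer, "optimizer")
  chk(ind$lr, pool$lr, "lr")
  k <- length(ind$layers)
  chk(k, pool$depth, "depth")
  for (l in seq_len(k)) {
    h <- ind$layers[[l]]
    chk(h$width, pool$width, paste0("width of layer ", l))
    chk(h$activation, pool$activation, paste0("activation of layer ", l))
    chk(h$dropout, pool$dropout, paste0("dropout of layer ", l))
    chk(h$batchnorm, pool$batchnorm, paste0("batchnorm of layer ", l))
    chk(h$l1, pool$l1, paste0("l1 of layer ", l))
    chk(h$l2, pool$l2, paste0("l2 of layer ", l))
  }
  invisible(TRUE)
}

#' @export
print.adler_individual <- function(x, ...) {
  lay <- vapply(x$layers, function(h)
    sprintf("%d/%s(do=%g,bn=%s,l1=%g,l2=%g)", h$width, h$activation,
            h$dropout, if (h$batchnorm) "on" else "off", h$l1, h$l2),
    character(1L))
  cat("<individual> epochs=", x$epochs, " opt=", x$optimizer, " lr=", x$lr,
      " layers: ", paste(lay, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Hybrid one-hot/numeric encoding of an individual
#'
#' Fixed-length numeric vector whose layout depends only on the pool:
#' categorical decisions (optimizer, depth, per-layer activation and
#' batch-norm flag) become one-hot blocks; numeric decisions (epochs,
#' learning rate, width, dropout, L1, L2) stay raw. Layer blocks beyond
#' the individual's depth are zero-filled, so the length is constant.
#'
#' @param ind An `adler_individual`.
#' @param pool The governing [hyperparameter_pool()].
#' @return Named numeric vector of length `encoding_length(pool)`.
#' @export
encode_individual <- function(ind, pool) {
  validate_individual(ind, pool)
  lay <- encoding_layout(pool)
  v <- numeric(lay$length)
  k <- length(ind$layers)
  for (i in seq_along(lay$slots)) {
    s <- lay$slots[[i]]
    if (s$layer > k) next # unused layer slots stay zero
    val <- if (s$layer == 0L) {
      if (s$field == "depth") k else ind[[s$field]]
    } else ind$layers[[s$layer]][[s$field]]
    if (s$type == "categorical") {
      v[lay$columns[[i]][match(val, s$values)]] <- 1
    } else {
      v[lay$columns[[i]]] <- as.numeric(val)
    }
  }
  stats::setNames(v, lay$names)
}

#' Encoding vector length for a pool
#' @param pool A [hyperparameter_pool()].
#' @return Integer length of [encode_individual()] output.
#' @export
encoding_length <- function(pool) encoding_layout(pool)$length

#' Decode an encoded vector back to an individual
#'
#' Exact inverse of [encode_individual()]: `decode(encode(p)) == p` for
#' every valid individual. Malformed one-hot blocks (not exactly one 1
#' among the active slots) or numeric entries outside the pool are
#' decoding errors.
#'
#' @param v Numeric vector produced by [encode_individual()].
#' @param pool The governing [hyperparameter_pool()].
#' @return An `adler_individual`.
#' @export
decode_individual <- function(v, pool) {
  lay <- encoding_layout(pool)
  if (length(v) != lay$length)
    stop("encoded vector has length ", length(v), ", expected ", lay$length)
  slot_value <- function(i) {
    s <- lay$slots[[i]]; block <- v[lay$columns[[i]]]
    if (s$type == "categorical") {
      on <- which(block == 1)
      if (length(on) != 1L || !all(block %in% c(0, 1)))
        stop("malformed one-hot block for slot ", s$name)
      s$values[on]
    } else {
      j <- match(block, s$values)
      if (is.na(j)) stop("value ", block, " not in pool for slot ", s$name)
      s$values[j]
    }
  }
  k <- as.integer(slot_value(4L))
  layers <- vector("list", k)
  for (i in seq_along(lay$slots)) {
    s <- lay$slots[[i]]
    if (s$layer == 0L || s$layer > k) {
      if (s$layer > k && any(v[lay$columns[[i]]] != 0))
        stop("non-zero entries in unused layer slot ", s$name)
      next
    }
    if (is.null(layers[[s$layer]])) layers[[s$layer]] <- list()
    layers[[s$layer]][[s$field]] <- slot_value(i)
  }
  individual(epochs = slot_value(1L), optimizer = slot_value(2L),
             lr = slot_value(3L), layers = layers, pool = pool)
}

#' Draw a uniformly random individual from a pool
#'
#' Uniform over decision slots (depth first, then each active slot
#' independently) — the random-search baseline sampler.
#'
#' @param pool A [hyperparameter_pool()].
#' @return An `adler_individual`.
#' @export
random_individual <- function(pool) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  k <- pick(pool$depth)
  layers <- lapply(seq_len(k), function(l)
    list(width = pick(pool$width), activation = pick(pool$activation),
         dropout = pick(pool$dropout), batchnorm = pick(pool$batchnorm),
         l1 = pick(pool$l1), l2 = pick(pool$l2)))
  individual(pick(pool$epochs), pick(pool$optimizer), pick(pool$lr), layers,
             pool = pool)
}

#' Build the layered pheromone graph over a pool
#'
#' A layered DAG with one node per candidate value per decision slot and
#' a single source; consecutive slots are fully connected. A walk
#' chooses one node per slot in order (epochs, optimizer, learning rate,
#' depth, then the per-layer slots) and terminates after the last slot
#' of layer `k`, where `k` is the value chosen at the depth slot — so
#' every complete walk decodes to exactly one valid individual. Each
#' edge carries a pheromone value `xi` (initialized to `xi0`) and a
#' heuristic value `eta` (initialized to 1; later overwritten from the
#' surrogate importances).
#'
#' @param pool A [hyperparameter_pool()].
#' @param xi0 Initial pheromone (> 0).
#' @return A `search_graph` list with elements `slots`, `xi`, `eta`
#'   (lists of edge matrices, entry `i` holding edges into slot `i` from
#'   slot `i - 1`, or from the source for `i = 1`), `pool`, `xi0`.
#' @export
build_search_graph <- function(pool, xi0 = 1.0) {
  if (xi0 <= 0) stop("xi0 must be > 0")
  slots <- pool_slots(pool)
  xi <- vector("list", length(slots))
  eta <- vector("list", length(slots))
  prev <- 1L # single source node
  for (i in seq_along(slots)) {
    nv <- length(slots[[i]]$values)
    xi[[i]] <- matrix(xi0, nrow = prev, ncol = nv)
    eta[[i]] <- matrix(1, nrow = prev, ncol = nv)
    prev <- nv
  }
  structure(list(slots = slots, xi = xi, eta = eta, pool = pool, xi0 = xi0),
            class = "search_graph")
}

# Internal: number of decision slots a walk visits for depth k
active_slot_count <- function(graph, k) 4L + 6L * k

# Internal: convert a walk (integer value indices per visited slot) to
# an individual
walk_to_individual <- function(graph, walk) {
  slots <- graph$slots
  val <- function(i) slots[[i]]$values[[walk[i]]]
  k <- as.integer(val(4L))
  layers <- lapply(seq_len(k), function(l) {
    base <- 4L + 6L * (l - 1L)
    list(width = val(base + 1L), activation = val(base + 2L),
         dropout = val(base + 3L), batchnorm = val(base + 4L),
         l1 = val(base + 5L), l2 = val(base + 6L))
  })
  individual(val(1L), val(2L), val(3L), layers, pool = graph$pool)
}

#' Enumerate every complete path of a search graph
#'
#' Exhaustive enumeration of source-to-sink walks; practical only for
#' tiny pools (used by the bijection and brute-force oracles).
#'
#' @param graph A [build_search_graph()] result.
#' @param max_paths Safety cap on the enumeration size.
#' @return List of integer walk vectors (value index per visited slot).
#' @export
enumerate_paths <- function(graph, max_paths = 1e5) {
  if (count_configurations(graph$pool) > max_paths)
    stop("pool too large to enumerate (", count_configurations(graph$pool),
         " paths)")
  out <- list()
  recurse <- function(walk) {
    i <- length(walk) + 1L
    k <- if (i > 4L) as.integer(graph$slots[[4L]]$values[[walk[4L]]]) else NA
    if (i > 4L && i > active_slot_count(graph, k)) {
      out[[length(out) + 1L]] <<- walk
      return(invisible())
    }
    for (s in seq_along(graph$slots[[i]]$values)) recurse(c(walk, s))
  }
  recurse(integer(0L))
  out
}
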