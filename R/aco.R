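# Ant-colony architecture search: pheromone-guided walks over the
# layered hyperparameter graph, fitness = cross-validated accuracy of
# the realized classifier, heuristic information refreshed each
# iteration from a boosted-tree surrogate's feature importances, local
# (per-step evaporation toward xi0) and global-best pheromone deposits.

#' Ant-colony search configuration
#'
#' @param population_size Ants per iteration (default 10; >= 2).
#' @param iterations Search iterations (default 10).
#' @param alpha_bar Pheromone exponent in the transition rule.
#' @param beta_bar Heuristic exponent in the transition rule.
#' @param phi Global pheromone decay, in (0, 1].
#' @param psi Local pheromone decay, in (0, 1].
#' @param xi0 Initial pheromone (> 0); also the local-update target.
#'   Must sit below the typical global deposit `eta * f` (importance
#'   mass times fitness, usually 0.03-0.3) for reinforcement to raise
#'   best-path pheromone above untouched edges; hence the small
#'   default.
#' @param trees Surrogate tree count (default 1000).
#' @param deposit `"eta_times_f"` (the printed global rule, default) or
#'   `"f_only"` (conventional ACS deposit) — sensitivity switch.
#' @param cv_folds Stratified folds per fitness evaluation (default 5).
#' @param patience Early-stopping patience for each training (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer master seed.
#' @return An `aco_config` list.
#' @export
aco_config <- function(population_size = 10L, iterations = 10L,
                       alpha_bar = 1, beta_bar = 1, phi = 0.1, psi = 0.1,
                       xi0 = 0.01, trees = 1000L, deposit = "eta_times_f",
                       cv_folds = 5L, patience = 50L, batch_size = 32L,
                       seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              iterations = as.integer(iterations),
              alpha_bar = as.numeric(alpha_bar),
              beta_bar = as.numeric(beta_bar),
              phi = as.numeric(phi), psi = as.numeric(psi),
              xi0 = as.numeric(xi0), trees = as.integer(trees),
              deposit = match.arg(deposit, c("eta_times_f", "f_only")),
              cv_folds = as.integer(cv_folds),
              patience = as.integer(patience),
              batch_size = as.integer(batch_size), seed = as.integer(seed))
  if (cfg$population_size < 2L) stop("population_size must be >= 2")
  if (cfg$iterations < 1L) stop("iterations must be >= 1")
  if (cfg$phi <= 0 || cfg$phi > 1) stop("phi must lie in (0, 1]")
  if (cfg$psi <= 0 || cfg$psi > 1) stop("psi must lie in (0, 1]")
  if (cfg$alpha_bar < 0 || cfg$beta_bar < 0)
    stop("alpha_bar and beta_bar must be >= 0")
  if (cfg$xi0 <= 0) stop("xi0 must be > 0")
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2")
  class(cfg) <- "aco_config"
  cfg
}

#' Transition distribution out of a graph node
#'
#' The probability of stepping to candidate value `s` of the next slot
#' is `xi^alpha_bar * eta^beta_bar`, normalized over the feasible
#' candidates. If every feasible weight is zero the distribution falls
#' back to uniform with a warning.
#'
#' @param graph A [build_search_graph()] result.
#' @param slot Index of the destination slot.
#' @param from Index of the current node's value in the previous slot
#'   (1 for the source when `slot == 1`).
#' @param alpha_bar,beta_bar Non-negative exponents.
#' @param feasible Optional logical mask over the destination values.
#' @return Numeric probability vector over the destination slot's
#'   values (zero outside `feasible`), summing to 1.
#' @export
transition_probabilities <- function(graph, slot, from, alpha_bar = 1,
                                     beta_bar = 1, feasible = NULL) {
  xi <- graph$xi[[slot]][from, ]
  eta <- graph$eta[[slot]][from, ]
  w <- xi^alpha_bar * eta^beta_bar
  if (is.null(feasible)) feasible <- rep(TRUE, length(w))
  if (!any(feasible)) stop("no feasible candidate values")
  w[!feasible] <- 0
  if (sum(w) == 0 || !all(is.finite(w))) {
    warning("all feasible transition weights are zero; uniform fallback")
    w <- as.numeric(feasible)
  }
  w / sum(w)
}

#' Local pheromone update on one edge
#'
#' Per-step evaporation toward the initial level: `xi <- (1 - psi) * xi
#' + psi * xi0`. Applied to an edge as soon as an ant traverses it,
#' lowering the pull of recently chosen values so the colony diversifies
#' within an iteration. `xi = xi0` is the fixed point.
#'
#' @param graph A `search_graph`.
#' @param edge Integer triple `c(slot, from, to)`.
#' @param psi Local decay in (0, 1].
#' @param xi0 Deposit target; defaults to the graph's initial pheromone.
#' @return The updated graph.
#' @export
local_pheromone_update <- function(graph, edge, psi, xi0 = graph$xi0) {
  graph$xi[[edge[1L]]][edge[2L], edge[3L]] <-
    (1 - psi) * graph$xi[[edge[1L]]][edge[2L], edge[3L]] + psi * xi0
  graph
}

#' Global pheromone update along the best path
#'
#' Only the globally best configuration deposits: every edge on its
#' path is moved toward `eta(edge) * f` (or plain `f` under the
#' `f_only` deposit variant) by factor `phi`; all other edges are
#' untouched. Executed once per iteration, after all evaluations.
#'
#' @param graph A `search_graph`.
#' @param best A fitness record (needs `$walk` and `$f`).
#' @param phi Global decay in (0, 1].
#' @param deposit `"eta_times_f"` (default) or `"f_only"`.
#' @return The updated graph.
#' @export
global_pheromone_update <- function(graph, best, phi,
                                    deposit = "eta_times_f") {
  walk <- best$walk
  from <- 1L
  for (i in seq_along(walk)) {
    delta <- if (deposit == "eta_times_f")
      graph$eta[[i]][from, walk[i]] * best$f else best$f
    graph$xi[[i]][from, walk[i]] <-
      (1 - phi) * graph$xi[[i]][from, walk[i]] + phi * delta
    from <- walk[i]
  }
  graph
}

#' Refresh heuristic information from surrogate importances
#'
#' Every edge into a slot value gets `eta = nu * phi_mass`, where
#' `phi_mass` is the normalized importance of the destination value's
#' encoding column (its one-hot column for categorical slots, the
#' slot's single numeric column otherwise), floored at `1e-6` so no
#' edge becomes unreachable.
#'
#' @param graph A `search_graph`.
#' @param nu Surrogate fit quality in (0, 1].
#' @param phi_importance Normalized importance vector named by encoding
#'   column (as produced by [fit_surrogate_and_weights()]).
#' @return The updated graph.
#' @export
update_heuristic <- function(graph, nu, phi_importance) {
  lay <- encoding_layout(graph$pool)
  for (i in seq_along(graph$slots)) {
    s <- lay$slots[[i]]
    cols <- lay$names[lay$columns[[i]]]
    mass <- if (s$type == "categorical") phi_importance[cols]
            else rep(phi_importance[cols], length(s$values))
    eta_row <- pmax(nu * as.numeric(mass), 1e-6)
    graph$eta[[i]] <- matrix(eta_row, nrow = nrow(graph$eta[[i]]),
                             ncol = length(eta_row), byrow = TRUE)
  }
  graph
}

#' Construct one candidate by a pheromone-guided walk
#'
#' Samples a source-to-sink walk, one slot at a time, from the
#' transition distribution; the depth chosen at the fourth slot decides
#' after which layer the walk exits. By default each traversed edge
#' immediately receives the local pheromone update (set `update_local =
#' FALSE` for sampling diagnostics that must not perturb the graph).
#'
#' @param graph A `search_graph`.
#' @param config An [aco_config()] (exponents and psi are read from it).
#' @param update_local Apply [local_pheromone_update()] per step?
#' @return List with `individual`, `walk` (value index per visited
#'   slot) and the (possibly updated) `graph`.
#' @export
construct_individual <- function(graph, config = aco_config(),
                                 update_local = TRUE) {
  walk <- integer(0L)
  from <- 1L
  n_slots <- length(graph$slots)
  i <- 1L
  k <- NA_integer_
  while (i <= n_slots) {
    pr <- transition_probabilities(graph, i, from, config$alpha_bar,
                                   config$beta_bar)
    choice <- sample.int(length(pr), 1L, prob = pr)
    walk[i] <- choice
    if (update_local)
      graph <- local_pheromone_update(graph, c(i, from, choice), config$psi)
    from <- choice
    if (i == 4L) k <- as.integer(graph$slots[[4L]]$values[[choice]])
    if (!is.na(k) && i >= active_slot_count(graph, k)) break
    i <- i + 1L
  }
  list(individual = walk_to_individual(graph, walk), walk = walk,
       graph = graph)
}

# Internal: cache key of an individual under a pool
encoding_key <- function(ind, pool) {
  paste(format(encode_individual(ind, pool), digits = 15L), collapse = ",")
}

#' Evaluate a population by cross-validated training
#'
#' Fitness of an individual is the mean stratified k-fold validation
#' accuracy of the classifier it encodes: per fold, the network trains
#' on the remaining folds (per-gene standardization re-fit on them) and
#' is scored on the held-out fold at its best early-stopping epoch. A
#' fold whose training aborts (non-finite loss) scores 0 and flags the
#' record. Duplicate individuals share one evaluation through `cache`.
#'
#' @param population List of `adler_individual`s.
#' @param expr (DEG-filtered) [expression_matrix()].
#' @param labels A [label_table()].
#' @param pool The governing pool (for the cache key / encoding).
#' @param cv_folds Number of stratified folds.
#' @param seed Integer seed (fold assignment + per-individual training).
#' @param patience,batch_size Training controls.
#' @param cache Optional environment carrying evaluations across calls.
#' @return List of fitness records: `individual`, `encoded`, `f`,
#'   `fold_acc`, `aborted`.
#' @export
evaluate_population <- function(population, expr, labels, pool,
                                cv_folds = 5L, seed = 1L, patience = 50L,
                                batch_size = 32L, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  keys <- vapply(population, encoding_key, character(1L), pool = pool)
  folds <- NULL; y <- NULL; x <- NULL
  lapply(seq_along(population), function(idx) {
    ind <- population[[idx]]
    key <- keys[[idx]]
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (is.null(folds)) { # data prep deferred until a miss needs it
      y <<- align_labels(expr, labels)
      folds <<- stratified_folds(y, cv_folds,
                                 seed = derive_seed(seed, "folds"))
      x <<- unclass(expr)
    }
    fold_acc <- numeric(cv_folds)
    aborted <- FALSE
    for (fd in seq_len(cv_folds)) {
      tr <- folds != fd
      expr_tr <- expression_matrix(x[tr, , drop = FALSE])
      expr_va <- expression_matrix(x[!tr, , drop = FALSE])
      fit <- fit_adler(expr_tr, labels, ind,
                       val_expr = expr_va, val_labels = labels,
                       patience = patience, batch_size = batch_size,
                       seed = derive_seed(seed, paste0("fit", key, fd)))
      if (fit$aborted) { aborted <- TRUE; fold_acc[fd] <- 0 }
      else fold_acc[fd] <- fit$val_accuracy
    }
    rec <- list(individual = ind, encoded = encode_individual(ind, pool),
                f = mean(fold_acc), fold_acc = fold_acc, aborted = aborted)
    cache[[key]] <- rec
    rec
  })
}

#' Fit the surrogate and derive heuristic weights
#'
#' Trains the boosted-tree regressor on all (encoded architecture ->
#' fitness) records collected so far, returning its fit quality `nu`
#' (training R-squared clipped to `[0.01, 1]`) and the per-encoding-
#' column importance `phi` normalized to sum 1. With fewer than two
#' distinct fitness values the surrogate is skipped (`nu = 0.01`,
#' uniform `phi`).
#'
#' @param records List of fitness records (need `$encoded` and `$f`).
#' @param trees Number of boosting trees (default 1000).
#' @param seed Passed to [gbrt_fit()] (provenance; fit deterministic).
#' @return List with `nu`, `phi` (named numeric), and `model` (the
#'   `gbrt_model`, or NULL on the fallback branch).
#' @export
fit_surrogate_and_weights <- function(records, trees = 1000L, seed = 1L) {
  E <- do.call(rbind, lapply(records, `[[`, "encoded"))
  f <- vapply(records, `[[`, numeric(1L), "f")
  uniform <- stats::setNames(rep(1 / ncol(E), ncol(E)), colnames(E))
  if (length(unique(f)) < 2L)
    return(list(nu = 0.01, phi = uniform, model = NULL))
  model <- gbrt_fit(E, f, n_trees = trees, seed = seed)
  imp <- model$importance
  phi <- if (sum(imp) > 0) imp / sum(imp) else uniform
  nu <- model$r_squared
  nu <- if (is.na(nu)) 0.01 else min(max(nu, 0.01), 1)
  list(nu = nu, phi = phi, model = model)
}

#' Run the full architecture search
#'
#' Iterates construct -> evaluate -> fit surrogate -> refresh heuristic
#' -> global pheromone update for `config$iterations` iterations with
#' `config$population_size` ants each. The heuristic is uniform (eta =
#' 1) in iteration 1, before any surrogate exists. Fitness defaults to
#' cross-validated training of the encoded classifier; `fitness_fn`
#' (signature `function(individual) -> numeric in [0, 1]`) replaces it
#' for mock landscapes and tests. Fully reproducible given
#' `config$seed`.
#'
#' @param expr (DEG-filtered) [expression_matrix()]; may be NULL when
#'   `fitness_fn` is supplied.
#' @param labels A [label_table()]; may be NULL with `fitness_fn`.
#' @param pool A [hyperparameter_pool()].
#' @param config An [aco_config()].
#' @param fitness_fn Optional deterministic fitness override.
#' @param verbose Log per-iteration progress?
#' @return A `dnas_search_result`: `best_individual`, `best_fitness`,
#'   `best_record`, `trace` (iteration, best_f, mean_f, nu,
#'   evaluations), `records`, final `graph`, `config`, `seed`.
#' @export
run_search <- function(expr, labels, pool, config = aco_config(),
                       fitness_fn = NULL, verbose = FALSE) {
  graph <- build_search_graph(pool, xi0 = config$xi0)
  cache <- new.env(parent = emptyenv())
  records <- list()
  best <- NULL
  trace <- data.frame(iteration = integer(0L), best_f = numeric(0L),
                      mean_f = numeric(0L), nu = numeric(0L),
                      evaluations = integer(0L))
  n_evals <- 0L
  for (it in seq_len(config$iterations)) {
    set.seed(derive_seed(config$seed, paste0("walk", it)))
    walks <- vector("list", config$population_size)
    pop <- vector("list", config$population_size)
    for (a in seq_len(config$population_size)) {
      cons <- construct_individual(graph, config)
      graph <- cons$graph
      pop[[a]] <- cons$individual
      walks[[a]] <- cons$walk
    }
    if (is.null(fitness_fn)) {
      recs <- evaluate_population(pop, expr, labels, pool,
                                  cv_folds = config$cv_folds,
                                  seed = derive_seed(config$seed,
                                                     paste0("eval", it)),
                                  patience = config$patience,
                                  batch_size = config$batch_size,
                                  cache = cache)
    } else {
      recs <- lapply(pop, function(ind) {
        key <- encoding_key(ind, pool)
        if (is.null(cache[[key]])) {
          f <- fitness_fn(ind)
          stopifnot(is.finite(f))
          cache[[key]] <- list(individual = ind,
                               encoded = encode_individual(ind, pool),
                               f = f, fold_acc = f, aborted = FALSE)
        }
        cache[[key]]
      })
    }
    n_evals <- n_evals + length(recs)
    for (a in seq_along(recs)) {
      recs[[a]]$walk <- walks[[a]]
      recs[[a]]$iteration <- it
      if (is.null(best) || recs[[a]]$f > best$f) best <- recs[[a]]
    }
    records <- c(records, recs)
    sur <- if (length(records) >= config$population_size)
      fit_surrogate_and_weights(records, trees = config$trees,
                                seed = derive_seed(config$seed, "surrogate"))
    else list(nu = NA_real_, phi = NULL)
    if (!is.null(sur$phi)) graph <- update_heuristic(graph, sur$nu, sur$phi)
    graph <- global_pheromone_update(graph, best, config$phi, config$deposit)
    trace <- rbind(trace, data.frame(
      iteration = it, best_f = best$f,
      mean_f = mean(vapply(recs, `[[`, numeric(1L), "f")),
      nu = sur$nu, evaluations = n_evals))
    if (verbose)
      log_msg(sprintf("iteration %d/%d: best f = %.4f, mean f = %.4f",
                      it, config$iterations, best$f, trace$mean_f[it]))
  }
  structure(list(best_individual = best$individual, best_fitness = best$f,
                 best_record = best, trace = trace, records = records,
                 graph = graph, config = config, seed = config$seed),
            class = "dnas_search_result")
}

#' @export
print.dnas_search_result <- function(x, ...) {
  cat("<dnas_search_result> ", nrow(x$trace), " iterations, ",
      utils::tail(x$trace$evaluations, 1L), " evaluations; best fitness ",
      sprintf("%.4f", x$best_fitness), "\n", sep = "")
  print(x$best_individual)
  invisible(x)
}
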