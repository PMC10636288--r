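#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict rnorm runif var sd pt pnorm p.adjust setNames
#' @importFrom utils modifyList packageVersion
NULL

# Internal: emit a timestamped log line to stderr (and optionally a file).
# Kept deliberately minimal; every CLI subcommand routes through this.
log_msg <- function(..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  paste0(..., collapse = ""))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

#' Derive a component seed from a global seed
#'
#' One global `--seed` fans out to per-component seeds so that each stage
#' (simulation, fold assignment, weight initialization, graph walks, ...)
#' is individually reproducible. The derivation is a small deterministic
#' hash of the component tag folded into the global seed, kept below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param seed Integer global seed.
#' @param tag Character scalar naming the component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629)
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` cross-validation folds, stratified by class so
#' every fold sees approximately the class proportions of the whole data.
#' `k == n` is leave-one-out and bypasses stratification (singleton folds).
#'
#' @param labels Character or factor vector of class labels.
#' @param k Number of folds, `2 <= k <= length(labels)`.
#' @param seed Integer seed controlling the (deterministic) shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  rng <- local({ set.seed(as.integer(seed)); sample.int(n) })
  if (k == n) { # leave-one-out: singleton folds, stratification vacuous
    folds <- integer(n); folds[rng] <- seq_len(n); return(folds)
  }
  small <- names(which(table(labels) < k))
  if (length(small) > 0L) {
    stop("class(es) ", paste(small, collapse = ", "), " have fewer than k = ",
         k, " samples; use a smaller k")
  }
  folds <- integer(n)
  offset <- 0L
  for (cl in unique(labels[rng])) {
    idx <- rng[labels[rng] == cl]
    folds[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
    offset <- offset + length(idx) # stagger so small classes spread evenly
  }
  folds
}

# Internal: %||% default operator
`%||%` <- function(a, b) if (is.null(a)) b else a
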