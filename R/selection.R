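#' Iterative bagging screen for informative variants
#'
#' First phase of the variable-selection strategy. The forest is run in
#' bagging mode (`mtry` equal to the number of current variables), so every
#' tree sees all variables and only the subjects differ between trees. Any
#' variable with importance exactly zero was never chosen as a split
#' variable by any tree and is eliminated; the procedure repeats on the
#' survivors until every remaining variable has positive importance. This
#' removes variables that carry no information beyond what their neighbours
#' in linkage disequilibrium already provide, while retaining the ones the
#' trees actually use. Survivors are returned ranked by descending
#' importance from the final iteration.
#'
#' @inheritParams kin_forest
#' @param ntree trees per screening iteration.
#' @return An object of class `"bagging_screen"`: list with `variables`
#'   (ranked character vector; empty, with a warning, when nothing is
#'   informative), `importance` (final-iteration \eqn{\eta} of the
#'   survivors), `sizes` (variable-set size per iteration, non-increasing)
#'   and `oob_errors` (\eqn{\Lambda} per iteration).
#' @examples
#' set.seed(1)
#' G <- matrix(sample(0:2, 20 * 40, replace = TRUE), 20,
#'             dimnames = list(NULL, paste0("snp", 1:40)))
#' y <- rep(1:0, each = 10)
#' G[, 7] <- y * 2
#' bagging_screen(G, y, ntree = 200, seed = 11)
#' @seealso [backward_select()] for the second phase.
#' @export
bagging_screen <- function(x, y = NULL, ntree = 500, min_node = 2,
                           inbag_per_class = NULL, seed = NULL) {
  if (inherits(x, "matched_sample")) {
    y <- x$status
    x <- x$genotypes
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  current <- colnames(x)
  sizes <- integer(0)
  oob <- numeric(0)
  iter_seeds <- spawn_seeds(seed, ncol(x) + 1L)
  it <- 0L
  imp <- numeric(0)
  repeat {
    it <- it + 1L
    sizes <- c(sizes, length(current))
    fit <- kin_forest(x[, current, drop = FALSE], y, ntree = ntree,
                      mtry = length(current), min_node = min_node,
                      inbag_per_class = inbag_per_class,
                      seed = iter_seeds[it], keep_trees = FALSE)
    oob <- c(oob, fit$oob_error)
    imp <- fit$importance
    survivors <- names(imp)[imp > 0]
    if (length(survivors) == 0L) {
      warning("no informative variables: all importances are zero")
      current <- character(0)
      imp <- numeric(0)
      break
    }
    if (length(survivors) == length(current)) {
      current <- survivors
      break
    }
    current <- survivors
  }
  ord <- order(-imp[current], match(current, colnames(x)))
  out <- list(variables = current[ord],
              importance = imp[current][ord],
              sizes = sizes,
              oob_errors = oob,
              seed = seed)
  class(out) <- "bagging_screen"
  out
}

#' @export
print.bagging_screen <- function(x, ...) {
  cat("Bagging screen:", length(x$sizes), "iteration(s), variable sets of size",
      paste(x$sizes, collapse = " -> "), "\n")
  if (length(x$variables)) {
    cat("Top survivors:",
        paste(utils::head(x$variables, 10), collapse = ", "), "\n")
  } else cat("No informative variables survived.\n")
  invisible(x)
}

#' Backward selection of the final variant set
#'
#' Second phase of the selection strategy: starting from the screened,
#' importance-ranked list, forests are refitted on the top \eqn{k}
#' variables for \eqn{k} decreasing from the full list to 1, with
#' \eqn{mtry = \lfloor\sqrt{k}\rfloor} (the usual random-forest rule, which
#' decorrelates trees after the bagging phase). The out-of-bag error
#' \eqn{\Lambda_k} is recorded at each step; stepping stops once
#' \eqn{\Lambda_k} has exceeded the best error seen by more than the
#' stopping tolerance (one out-of-bag subject's worth of error,
#' `1/oob size`) for `patience` consecutive steps, because the out-of-bag
#' estimate of "starts to increase" is noisy. The final set is the smallest
#' \eqn{k} attaining the minimum recorded \eqn{\Lambda}: the smallest model
#' with the lowest prediction error.
#'
#' @inheritParams kin_forest
#' @param ranked character vector of variable names in descending
#'   importance order, or a [bagging_screen()] result.
#' @param ntree trees per refit.
#' @param patience consecutive worsening steps tolerated before stopping.
#' @return An object of class `"selection_trace"`: list with `steps` (data
#'   frame `k`, `oob_error` in the order visited), `final_k`, `final_set`
#'   and `seed`.
#' @export
backward_select <- function(x, y = NULL, ranked, ntree = 500, min_node = 2,
                            inbag_per_class = NULL, seed = NULL,
                            patience = 3L) {
  if (inherits(x, "matched_sample")) {
    y <- x$status
    x <- x$genotypes
  }
  if (inherits(ranked, "bagging_screen")) ranked <- ranked$variables
  ranked <- as.character(ranked)
  if (length(ranked) == 0L) stop("ranked variable list must be non-empty")
  x <- as.matrix(x)
  if (!all(ranked %in% colnames(x)))
    stop("ranked list contains unknown variable names")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  K <- length(ranked)
  step_seeds <- spawn_seeds(seed, K)
  ks <- integer(0)
  lams <- numeric(0)
  best <- Inf
  worse <- 0L
  tol <- NULL
  for (k in K:1) {
    fit <- kin_forest(x[, ranked[seq_len(k)], drop = FALSE], y,
                      ntree = ntree, mtry = max(1L, floor(sqrt(k))),
                      min_node = min_node,
                      inbag_per_class = inbag_per_class,
                      seed = step_seeds[K - k + 1L], keep_trees = FALSE)
    if (is.null(tol)) {
      n_oob <- length(fit$y) - 2L * fit$config$inbag_per_class
      tol <- 1 / max(1L, n_oob)
    }
    ks <- c(ks, k)
    lams <- c(lams, fit$oob_error)
    if (fit$oob_error < best) best <- fit$oob_error
    worse <- if (fit$oob_error > best + tol) worse + 1L else 0L
    if (worse >= patience) break
  }
  lam_min <- min(lams)
  final_k <- min(ks[lams == lam_min])
  out <- list(steps = data.frame(k = ks, oob_error = lams),
              final_k = final_k,
              final_set = ranked[seq_len(final_k)],
              seed = seed)
  class(out) <- "selection_trace"
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Backward selection over", nrow(x$steps), "step(s)\n")
  cat("Minimum OOB error", format(min(x$steps$oob_error), digits = 4),
      "attained with the", x$final_k, "top variable(s):\n  ",
      paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.selection_trace <- function(x, ...) {
  ord <- order(x$steps$k)
  graphics::plot(x$steps$k[ord], x$steps$oob_error[ord], type = "b",
                 xlab = "number of top-ranked variables k",
                 ylab = "out-of-bag error", pch = 19, ...)
  graphics::abline(v = x$final_k, lty = 2)
  invisible(x)
}

#' Write a selection trace as TSV
#'
#' Columns `k`, `oob_error` (the error-versus-model-size curve).
#'
#' @param trace a `"selection_trace"` object.
#' @param path file path.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.table(trace$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
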