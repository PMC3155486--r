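#' Fit a deviance-split random forest on a matched case-control sample
#'
#' The prediction model is an ensemble of \eqn{M} classification trees over
#' categorical predictors (SNP genotypes with 2-3 levels, plus optional
#' categorical covariates). Each tree is grown on a stratified in-bag
#' subsample (`inbag_per_class` subjects per class, drawn without
#' replacement; the default is half of each class, so the in-bag and
#' out-of-bag halves are both balanced) and on a per-tree random subset of
#' `mtry` predictors. Splits are binary partitions of a variable's levels
#' chosen to maximally decrease the Bernoulli deviance (binary
#' cross-entropy); nodes are split while they hold at least `min_node`
#' subjects and are impure. The model prediction is the mean vote of the
#' trees, and the ensemble error \eqn{\Lambda} is the fraction of subjects
#' misclassified by the majority vote of the trees for which they were
#' out-of-bag, so it is never computed on training points.
#'
#' The importance \eqn{\eta_j} of variable \eqn{j} is the total deviance
#' decrease induced by splits on \eqn{j} across all trees (unnormalised);
#' \eqn{\eta_j = 0} exactly when \eqn{j} is never a split variable, which is
#' what the bagging screening phase ([bagging_screen()]) exploits.
#'
#' With `mtry` equal to the number of predictors the procedure runs in
#' *bagging mode*: trees differ only by their in-bag subjects.
#'
#' @param x a [matched_sample()] object, or a matrix/data frame of
#'   categorical predictors (values `0/1/2`, factors or character; `NA`
#'   allowed) with subjects in rows.
#' @param y binary response (0/1, logical, or two-level factor); ignored
#'   when `x` is a matched sample (its status vector is used).
#' @param ntree number of trees \eqn{M}.
#' @param mtry per-tree number of candidate variables; default
#'   \eqn{\lfloor\sqrt{P}\rfloor} (at least 1).
#' @param min_node minimum node size still eligible for splitting.
#' @param inbag_per_class in-bag subjects per class; default
#'   \eqn{\lfloor I/2 \rfloor} for the smaller class size \eqn{I}.
#' @param seed integer master seed; each tree consumes its own derived
#'   substream, so results are independent of evaluation order. When `NULL`
#'   a seed is drawn from the session RNG and recorded.
#' @param keep_trees keep the tree structures (needed by [predict()] on new
#'   data); switch off in screening loops to save memory.
#' @param keep_inbag keep the ntree x n in-bag indicator matrix (used by
#'   the out-of-bag bookkeeping audit).
#' @return An object of class `"kin_forest"`: list with `importance` (named
#'   vector \eqn{\eta}), `oob_error` (\eqn{\Lambda}), `oob_votes`
#'   (per-subject out-of-bag vote fraction), `oob_n`, `config`, `seed`,
#'   `levels` (per-variable category dictionaries), `y`, and (optionally)
#'   `trees` and `inbag`.
#' @examples
#' set.seed(1)
#' G <- matrix(sample(0:2, 20 * 30, replace = TRUE), 20,
#'             dimnames = list(paste0("s", 1:20), paste0("snp", 1:30)))
#' y <- rep(1:0, each = 10)
#' G[, 1] <- y * 2           # a perfectly separating variant
#' fit <- kin_forest(G, y, ntree = 100, mtry = 30, seed = 7)
#' fit
#' names(which.max(importance(fit)))
#' @seealso [bagging_screen()], [backward_select()], [classify()].
#' @export
kin_forest <- function(x, y = NULL, ntree = 1000, mtry = NULL, min_node = 2,
                       inbag_per_class = NULL, seed = NULL,
                       keep_trees = TRUE, keep_inbag = FALSE) {
  if (inherits(x, "matched_sample")) {
    y <- x$status
    x <- x$genotypes
  }
  if (is.null(y)) stop("a response is required")
  y <- encode_response(y)
  enc <- encode_predictors(x)
  n <- nrow(enc$X)
  P <- ncol(enc$X)
  if (length(y) != n) stop("response length does not match predictor rows")
  if (n < 4) stop("at least 4 subjects are required")
  n1 <- sum(y == 1L)
  n0 <- n - n1
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 subjects")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(P)))
  mtry <- as.integer(mtry)
  if (mtry < 1 || mtry > P) stop("mtry must be in [1, P]")
  if (is.null(inbag_per_class)) inbag_per_class <- max(1L, min(n0, n1) %/% 2L)
  inbag_per_class <- as.integer(inbag_per_class)
  if (inbag_per_class >= min(n0, n1))
    stop("configuration error: in-bag size leaves a class empty out-of-bag")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)

  res <- cpp_grow_forest(enc$X, y, enc$nlev, as.integer(ntree), mtry,
                         as.integer(min_node), inbag_per_class,
                         as.double(seed), keep_trees, keep_inbag)

  subj <- rownames(enc$X) %||% paste0("s", seq_len(n))
  imp <- res$importance
  names(imp) <- colnames(enc$X)
  votes <- res$oob_votes
  names(votes) <- subj
  out <- list(importance = imp,
              oob_error = res$oob_error,
              oob_votes = votes,
              oob_n = res$oob_n,
              config = list(ntree = as.integer(ntree), mtry = mtry,
                            min_node = as.integer(min_node),
                            inbag_per_class = inbag_per_class),
              seed = seed,
              levels = enc$levels,
              y = y,
              call = match.call())
  if (keep_trees) out$trees <- res$trees
  if (keep_inbag) out$inbag <- res$inbag
  class(out) <- "kin_forest"
  out
}

# response to integer 0/1
encode_response <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("factor response must have exactly 2 levels")
    return(as.integer(y) - 1L)
  }
  if (is.logical(y)) return(as.integer(y))
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% 0:1))
    stop("response must be binary 0/1")
  y
}

# columns to 0-based integer codes with per-variable level dictionaries
encode_predictors <- function(x, dict = NULL) {
  if (is.data.frame(x)) x <- as.matrix(as.data.frame(lapply(x, as.character),
                                                     stringsAsFactors = FALSE,
                                                     check.names = FALSE,
                                                     row.names = rownames(x)))
  if (!is.matrix(x)) stop("predictors must be a matrix or data frame")
  P <- ncol(x)
  if (P < 1) stop("at least one predictor is required")
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(P))
  xc <- matrix(as.character(x), nrow(x), P, dimnames = dimnames(x))
  X <- matrix(NA_integer_, nrow(x), P, dimnames = dimnames(x))
  levels <- vector("list", P)
  names(levels) <- colnames(x)
  for (j in seq_len(P)) {
    lv <- if (is.null(dict)) sort(unique(xc[, j][!is.na(xc[, j])]))
          else dict[[colnames(x)[j]]]
    if (is.null(lv)) stop("no level dictionary for variable ", colnames(x)[j])
    if (length(lv) > 8)
      stop("variable ", colnames(x)[j], " has more than 8 categories")
    code <- match(xc[, j], lv) - 1L  # unseen -> NA
    X[, j] <- code
    levels[[j]] <- lv
  }
  nlev <- vapply(levels, function(l) max(1L, length(l)), integer(1))
  list(X = X, levels = levels, nlev = as.integer(nlev))
}

#' @export
print.kin_forest <- function(x, ...) {
  cat("Deviance-split random forest (", x$config$ntree, " trees, mtry = ",
      x$config$mtry, ")\n", sep = "")
  cat("  subjects: ", length(x$y), " (", sum(x$y == 1), " cases), ",
      "predictors: ", length(x$importance), "\n", sep = "")
  cat("  out-of-bag error Lambda: ", format(x$oob_error, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.kin_forest <- function(object, n_top = 10L, ...) {
  imp <- sort(object$importance, decreasing = TRUE)
  out <- list(config = object$config,
              oob_error = object$oob_error,
              n_used = sum(object$importance > 0),
              n_variables = length(object$importance),
              top = imp[seq_len(min(n_top, length(imp)))])
  class(out) <- "summary.kin_forest"
  out
}

#' @export
print.summary.kin_forest <- function(x, ...) {
  cat("Forest of", x$config$ntree, "trees; OOB error",
      format(x$oob_error, digits = 4), "\n")
  cat(x$n_used, "of", x$n_variables,
      "variables ever used as split variables\n")
  cat("Top importance (total Bernoulli deviance decrease):\n")
  print(round(x$top, 3))
  invisible(x)
}

#' @export
plot.kin_forest <- function(x, n_top = 20L, ...) {
  imp <- sort(x$importance, decreasing = TRUE)
  imp <- imp[seq_len(min(n_top, length(imp)))]
  graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                    xlab = "importance (deviance decrease)",
                    main = "Variable importance", ...)
  invisible(x)
}

#' Predicted disease probability
#'
#' Mean vote of the trees for class 1. For the training sample itself
#' (omit `newdata`), out-of-bag vote fractions are returned, so the
#' estimate is not contaminated by in-bag memorisation. Prediction-time
#' category levels never seen in training are routed like missing values:
#' down the more populous child of each split.
#'
#' @param object a [kin_forest()] fit (with `keep_trees = TRUE` for new
#'   data).
#' @param newdata matrix/data frame of predictors with the training columns.
#' @param type `"prob"` for vote fractions, `"class"` for Bayes-rule calls.
#' @param threshold classification threshold passed to [classify()].
#' @param ... unused.
#' @return Numeric vector of probabilities, or integer 0/1 vector.
#' @export
predict.kin_forest <- function(object, newdata = NULL,
                               type = c("prob", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    pr <- object$oob_votes
  } else {
    if (is.null(object$trees))
      stop("forest was fitted with keep_trees = FALSE")
    nd <- newdata
    if (!is.null(colnames(nd))) {
      miss <- setdiff(names(object$levels), colnames(nd))
      if (length(miss))
        stop("newdata lacks variable(s): ", paste(miss, collapse = ", "))
      nd <- nd[, names(object$levels), drop = FALSE]
    }
    enc <- encode_predictors(nd, dict = object$levels)
    pr <- cpp_predict_forest(object$trees, enc$X)
    names(pr) <- rownames(enc$X)
  }
  if (type == "class") classify(pr, threshold) else pr
}

#' Bayes-rule classification of vote fractions
#'
#' Calls class 1 when the predicted probability strictly exceeds the
#' threshold; 0.5 is the Bayes rule under equal priors, and the threshold
#' can be moved to reflect the disease prevalence. Exact ties go to class 0.
#'
#' @param prob numeric probabilities in `[0, 1]`.
#' @param threshold scalar in (0, 1).
#' @return Integer vector of 0/1 calls.
#' @export
classify <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  if (any(is.na(prob)) || any(prob < 0) || any(prob > 1))
    stop("probabilities must lie in [0, 1]")
  as.integer(prob > threshold)
}

#' Variable importance
#'
#' @param x a fitted object.
#' @param ... passed to methods.
#' @return For `kin_forest`: named vector of total deviance decreases
#'   \eqn{\eta} (use `sorted = TRUE` for descending order).
#' @export
importance <- function(x, ...) UseMethod("importance")

#' @rdname importance
#' @param sorted return in descending order.
#' @export
importance.kin_forest <- function(x, sorted = FALSE, ...) {
  if (sorted) sort(x$importance, decreasing = TRUE) else x$importance
}

#' Save / load a fitted forest
#'
#' Serialises the complete fit — tree structures, configuration, level
#' dictionaries and seed — to a portable RDS archive so the model can be
#' reused for prediction in a later session.
#'
#' @param fit a [kin_forest()] object fitted with `keep_trees = TRUE`.
#' @param path archive path.
#' @return `load_forest()` returns the restored `"kin_forest"` object.
#' @export
save_forest <- function(fit, path) {
  stopifnot(inherits(fit, "kin_forest"))
  if (is.null(fit$trees))
    stop("forest was fitted with keep_trees = FALSE; nothing to serialise")
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "kin_forest")) stop("not a serialised forest: ", path)
  fit
}
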