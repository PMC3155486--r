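#' Two-sided Fisher exact test on a status-by-genotype table
#'
#' Exact test of independence between binary disease status and a
#' categorical genotype (2 or 3 levels), under the fixed-margins
#' (multivariate hypergeometric) null. The two-sided p-value follows the
#' point-probability rule: the sum of the probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table. A table with a zero row or column margin carries no
#' information about association; its p-value is defined as 1, with a
#' warning.
#'
#' @param table 2 x g integer matrix, g in 2..3 (rows: status 0/1, columns:
#'   genotype levels), non-negative counts, positive grand total.
#' @return A p-value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))          # 1
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))        # ~1.08e-5
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2 || !(ncol(tab) %in% 2:3))
    stop("table must be 2 x 2 or 2 x 3")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (sum(tab) == 0) stop("table has zero grand total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero row/column margin: no information, p set to 1")
    return(1)
  }
  min(1, stats::fisher.test(tab)$p.value)
}

#' Single-point Fisher exact genome scan
#'
#' Tests every variant of a matched sample for independence from disease
#' status with [fisher_exact()] and attaches the three multiplicity
#' adjustments used as ranking comparators: Benjamini-Hochberg step-up
#' ([bh_adjust()]), Storey q-values ([storey_qvalues()]) and Efron-style
#' local false discovery rates ([local_fdr()]). Missing genotypes are
#' dropped per variant (complete-case per test). Variants that are
#' monomorphic among the tested subjects carry no information; they get
#' p = 1 and are flagged.
#'
#' @param sample a [matched_sample()] object (both classes present).
#' @param allelic if `TRUE` and genotypes are dose-coded 0/1/2, each variant
#'   is collapsed to a 2 x 2 allele-count table; default is the genotypic
#'   2 x g table over the observed levels.
#' @return An object of class `"scan_result"`: data frame with columns
#'   `variant`, `p`, `bh`, `q`, `lfdr`, `rank` (ascending p, ties broken by
#'   variant order) and `flagged` (monomorphic / zero-margin variants).
#' @examples
#' \donttest{
#' ped <- simulate_pedigree(n_founders = 12, n_generations = 4, seed = 1)
#' G <- gene_drop_genotypes(ped, maf = rep(0.3, 50), seed = 2)
#' st <- assign_disease(G, disease_model(1:5, rep(2L, 5)), n_cases = 10,
#'                      seed = 3)
#' cases <- names(st)[st == 1]
#' K <- kinship_matrix(ped, cases, setdiff(names(st), cases))
#' s <- matched_sample(hungarian_select(K), G)
#' head(as.data.frame(genome_scan(s)))
#' }
#' @export
genome_scan <- function(sample, allelic = FALSE) {
  stopifnot(inherits(sample, "matched_sample"))
  G <- sample$genotypes
  P <- ncol(G)
  if (P < 1) stop("empty result: the sample has no variants")
  y <- sample$status
  if (length(unique(y)) < 2) stop("both classes must be present")
  p <- numeric(P)
  flagged <- logical(P)
  for (j in seq_len(P)) {
    x <- G[, j]
    keep <- !is.na(x)
    xs <- x[keep]
    ys <- y[keep]
    lev <- unique(xs)
    if (length(xs) == 0 || length(lev) < 2 || length(unique(ys)) < 2) {
      p[j] <- 1
      flagged[j] <- TRUE
      next
    }
    tab <- if (allelic) allele_table(xs, ys) else table(ys, xs)
    if (is.null(tab)) {
      p[j] <- 1
      flagged[j] <- TRUE
      next
    }
    p[j] <- min(1, stats::fisher.test(tab)$p.value)
  }
  variant <- colnames(G) %||% paste0("v", seq_len(P))
  out <- data.frame(variant = variant, p = p,
                    bh = bh_adjust(p),
                    q = if (P >= 2) suppressWarnings(storey_qvalues(p)) else p,
                    lfdr = suppressWarnings(local_fdr(p)),
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  out$rank <- rank_by_p(p)
  class(out) <- c("scan_result", "data.frame")
  out
}

# 2x2 allele-count table from dose-coded genotypes; NULL if monomorphic
allele_table <- function(x, y) {
  x <- suppressWarnings(as.numeric(x))
  if (anyNA(x) || any(!x %in% 0:2))
    stop("allelic mode requires 0/1/2 dose-coded genotypes")
  a1 <- c(sum(x[y == 0]), sum(x[y == 1]))
  a0 <- c(2 * sum(y == 0), 2 * sum(y == 1)) - a1
  tab <- cbind(a0, a1)
  if (any(colSums(tab) == 0)) return(NULL)
  tab
}

# ascending p, ties broken by input order
rank_by_p <- function(p) {
  ord <- order(p, seq_along(p))
  r <- integer(length(p))
  r[ord] <- seq_along(p)
  r
}

#' @export
print.scan_result <- function(x, n = 10L, ...) {
  cat("Single-point scan over", nrow(x), "variants\n")
  cat("  p < 0.05:", sum(x$p < 0.05), "  flagged:", sum(x$flagged), "\n")
  cat("Top", min(n, nrow(x)), "variants by p-value:\n")
  top <- x[order(x$rank), , drop = FALSE][seq_len(min(n, nrow(x))), ]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Empirical CDF of scan p-values on a fine grid
#'
#' The proportion of all p-values at or below each threshold of a regular
#' grid inside `(0, grid_max]`. Comparing this curve between the
#' kinship-matched design and random designs shows how much spurious
#' association signal the matched design removes: fewer small p-values
#' under the matched design at equal power indicates reduced stratification
#' noise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param grid_max upper end of the threshold grid (default 0.01).
#' @param n_grid number of thresholds.
#' @return Data frame with columns `threshold` and `proportion`.
#' @export
pvalue_ecdf <- function(p, grid_max = 0.01, n_grid = 100L) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (grid_max <= 0 || grid_max > 1) stop("grid_max must be in (0, 1]")
  grid <- seq(grid_max / n_grid, grid_max, length.out = n_grid)
  data.frame(threshold = grid,
             proportion = vapply(grid, function(t) mean(p <= t), numeric(1)))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH adjustment: ordered p-values are multiplied by \eqn{P/i} and
#' monotonised from the largest down (`stats::p.adjust(method = "BH")`).
#' Ranking variants by the adjusted values is identical to ranking by the
#' raw p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`, entrywise at least `p`.
#' @export
bh_adjust <- function(p) {
  check_pvec(p)
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' Positive-FDR q-values: \eqn{\hat\pi_0} (the null proportion) is estimated
#' on a lambda grid with spline smoothing when at least 100 p-values are
#' available; for shorter vectors the adaptive estimate is unstable (exact
#' test p-values concentrate on 0 and 1 at small sample sizes), so a fixed
#' \eqn{\lambda = 0.5} is used. Then
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 P p_{(j)} / j}, capped at 1.
#' With \eqn{\hat\pi_0 = 1} the result equals [bh_adjust()] exactly.
#'
#' @param p numeric vector of at least 2 p-values.
#' @param pi0 optionally force the null-proportion estimate (e.g. 1).
#' @return q-values in `[0, 1]`, monotone in p.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  check_pvec(p)
  m <- length(p)
  if (m < 2) stop("at least 2 p-values are required")
  if (length(unique(p)) == 1L) {
    warning("all p-values identical; q = pi0 * p * P / rank is degenerate")
  }
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  for (k in seq_len(m)) {
    i <- ord[k]
    rank_i <- m - k + 1L
    # association order matches the BH step-up product, so pi0 = 1
    # collapses to it exactly, bit for bit
    running <- min(running, pi0 * ((m / rank_i) * p[i]))
    q[i] <- min(1, running)
  }
  q
}

estimate_pi0 <- function(p) {
  m <- length(p)
  if (m < 100) {
    lambda <- 0.5
    pi0 <- mean(p > lambda) / (1 - lambda)
    return(min(1, max(pi0, 1 / m)))
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(1, max(pi0, 1 / m))
}

#' Local false discovery rate
#'
#' Efron-style empirical-Bayes local fdr on the probit scale:
#' \eqn{z = \Phi^{-1}(1 - p)}, \eqn{lfdr(z) = \hat\pi_0 f_0(z) / \hat f(z)}
#' with \eqn{f_0} the theoretical standard normal null (the small-sample
#' default) and \eqn{\hat f} a Gaussian kernel density estimate of the
#' observed z, clipped to `[0, 1]`. The estimate is then monotonised along
#' increasing p (running maximum), so that ranking variants by lfdr always
#' agrees with ranking by raw p. p-values of exactly 0 or 1 are clipped to
#' the machine-representable open interval with a warning.
#'
#' @param p numeric vector of p-values; intended for 50 or more tests
#'   (density estimation is unreliable below that).
#' @return lfdr values in `[0, 1]`.
#' @export
local_fdr <- function(p) {
  check_pvec(p)
  m <- length(p)
  if (length(unique(p)) == 1L) {
    warning("constant p-value vector: no signal, lfdr set to 1")
    return(rep(1, m))
  }
  eps <- 1e-12
  if (any(p <= 0) || any(p >= 1)) {
    warning("p-values of exactly 0/1 clipped to the open interval")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  z <- stats::qnorm(1 - p)
  pi0 <- estimate_pi0(p)
  bw <- stats::bw.nrd0(z)
  dens <- stats::density(z, bw = bw, n = 512,
                         from = min(z) - 3 * bw, to = max(z) + 3 * bw)
  fhat <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  fhat <- pmax(fhat, 1e-10)
  lfdr <- pmin(1, pi0 * stats::dnorm(z) / fhat)
  # monotonise along increasing p: preserves the raw-p ranking exactly
  ord <- order(p, seq_along(p))
  lfdr[ord] <- cummax(lfdr[ord])
  lfdr
}

check_pvec <- function(p) {
  if (!is.numeric(p) || length(p) == 0)
    stop("p must be a non-empty numeric vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  invisible(TRUE)
}

#' Write a scan result as TSV
#'
#' Columns `variant`, `p`, `bh`, `q`, `lfdr`, `rank`, `flagged`.
#'
#' @param scan a `"scan_result"` object.
#' @param path file path.
#' @export
write_scan_result <- function(scan, path) {
  utils::write.table(as.data.frame(scan)[, c("variant", "p", "bh", "q",
                                             "lfdr", "rank", "flagged")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
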