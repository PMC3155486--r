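#' Area under the ROC curve of a variant ranking
#'
#' Every compared method produces an ordering of all \eqn{P} variants by
#' association evidence; taking each of the \eqn{P} ranks as a cut point
#' gives a ROC curve (true positive rate = fraction of causal variants above
#' the cut; false positive rate = fraction of non-causal ones), whose
#' trapezoidal area equals the Mann-Whitney statistic with half credit for
#' ties. An AUC of 1 means all causal variants are ranked first, 0.5 is the
#' level of a random ordering.
#'
#' @param ranking character vector: a permutation of all variant ids,
#'   most-associated first.
#' @param causal non-empty subset of the ids: the true causal variants.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c("a", "b", "c", "d"), causal = c("a", "b"))  # 1
#' @export
roc_auc <- function(ranking, causal) {
  ranking <- as.character(ranking)
  causal <- as.character(causal)
  if (length(causal) == 0) stop("causal set must be non-empty")
  if (anyDuplicated(ranking)) stop("ranking must not contain duplicates")
  if (!all(causal %in% ranking)) stop("causal ids must all appear in ranking")
  if (length(causal) == length(ranking))
    stop("at least one non-causal variant is required")
  score <- rev(seq_along(ranking))  # higher = more associated
  auc_from_scores(score, ranking %in% causal)
}

# Mann-Whitney AUC from raw scores (higher = more associated),
# half credit for tied scores via midranks.
auc_from_scores <- function(score, is_causal) {
  p <- sum(is_causal)
  q <- sum(!is_causal)
  r <- rank(score, ties.method = "average")
  (sum(r[is_causal]) - p * (p + 1) / 2) / (p * q)
}

#' Run one simulation replicate
#'
#' One draw of the method-comparison experiment: disease status is assigned
#' from the cohort genotypes through the configuration-count model; the
#' controls are selected either by the Hungarian method on the pedigree
#' kinship matrix or at random; each requested method then ranks all
#' variants on the resulting balanced 2I-subject sample and is scored by
#' ROC AUC against the true causal set.
#'
#' Methods: `"rf"` ranks by forest importance from a bagging-mode fit
#' ([kin_forest()] with `mtry = P`); `"fisher_bh"`, `"qvalue"` and
#' `"lfdr"` rank by the Fisher exact scan with the respective adjustment
#' ([genome_scan()]). Tied scores receive half credit in the AUC.
#'
#' @param cohort a cohort as built by [simulate_cohort()] (or any list with
#'   elements `ids`, `genotypes`, `kinship`).
#' @param model a [disease_model()].
#' @param design `"hungarian"` or `"random"`.
#' @param methods subset of `c("rf", "fisher_bh", "qvalue", "lfdr")`.
#' @param n_cases cases per replicate (default 10).
#' @param ntree trees for the forest ranking.
#' @param seed integer seed (drives status assignment, the random design
#'   and the forest).
#' @return Data frame with one row per method: `design`, `method`, `auc`,
#'   `causal_recovered_at_p` (causal variants among the top \eqn{p} ranks).
#' @export
run_replicate <- function(cohort, model, design = c("hungarian", "random"),
                          methods = c("rf", "fisher_bh", "qvalue", "lfdr"),
                          n_cases = 10L, ntree = 200L, seed = NULL) {
  design <- match.arg(design)
  methods <- match.arg(methods, several.ok = TRUE)
  G <- cohort$genotypes
  ids <- cohort$ids %||% rownames(G)
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max, 1), 3L)

  status <- assign_disease(G, model, n_cases = n_cases, seed = seeds[1])
  cases <- ids[status == 1L]
  pool <- ids[status == 0L]
  if (length(pool) < n_cases)
    stop("fewer than ", n_cases, " available controls")
  K <- cohort$kinship[cases, pool, drop = FALSE]
  asn <- if (design == "hungarian") hungarian_select(K)
         else random_select(cases, pool, seed = seeds[2], kinship = K)
  sample2I <- matched_sample(asn, G)

  P <- ncol(G)
  p <- length(model$causal_indices)
  is_causal <- seq_len(P) %in% model$causal_indices
  scan <- NULL
  res <- lapply(methods, function(m) {
    score <- switch(m,
      rf = {
        fit <- kin_forest(sample2I, ntree = ntree, mtry = P,
                          seed = seeds[3], keep_trees = FALSE)
        fit$importance
      },
      fisher_bh = ,
      qvalue = ,
      lfdr = {
        if (is.null(scan)) scan <<- genome_scan(sample2I)
        -switch(m, fisher_bh = scan$bh, qvalue = scan$q, lfdr = scan$lfdr)
      })
    rec <- sum(rank(-score, ties.method = "min")[is_causal] <= p)
    data.frame(design = design, method = m,
               auc = auc_from_scores(score, is_causal),
               causal_recovered_at_p = rec,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_cases") <- sum(sample2I$status == 1L)
  attr(out, "sample_size") <- length(sample2I$subject_id)
  attr(out, "total_kinship") <- asn$total_kinship
  out
}

#' Simulate a study cohort
#'
#' Builds the fixed backdrop of a simulation study: a consanguineous
#' pedigree, gene-dropped genotypes for every member, and the full kinship
#' matrix (cached once; every replicate reuses it).
#'
#' @inheritParams simulate_pedigree
#' @param n_snps number of loci P (study default 1000).
#' @param maf_range allele frequencies are drawn uniformly in this range.
#' @param ld_block_size,ld_r passed to [gene_drop_genotypes()].
#' @param seed integer seed.
#' @return An object of class `"sim_cohort"`: list with `ped`, `ids`,
#'   `genotypes`, `kinship`.
#' @export
simulate_cohort <- function(n_founders = 25, n_generations = 4,
                            mean_offspring = 3, p_within = 0.85,
                            n_snps = 1000L, maf_range = c(0.1, 0.5),
                            ld_block_size = 1, ld_r = 0.8, seed = NULL) {
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max, 1), 3L)
  ped <- simulate_pedigree(n_founders, n_generations, mean_offspring,
                           p_within, seed = seeds[1])
  maf <- with_seed(seeds[2],
                   stats::runif(n_snps, maf_range[1], maf_range[2]))
  G <- gene_drop_genotypes(ped, maf, ld_block_size, ld_r, seed = seeds[3])
  out <- list(ped = ped, ids = ped$id, genotypes = G,
              kinship = kinship_all(ped))
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$ids), "subjects,",
      ncol(x$genotypes), "SNPs\n")
  cat("  mean off-diagonal kinship:",
      format(mean(x$kinship[upper.tri(x$kinship)]), digits = 3), "\n")
  invisible(x)
}

#' Run the ROC/AUC method-comparison study
#'
#' The full simulation experiment: a cohort is simulated once; in each of
#' `n_replicates` replicates, `n_subjects` members are drawn from it, a
#' fresh causal set and risk configuration are drawn, disease status is
#' assigned, and every method is scored under each requested design. The
#' distribution of AUCs per method and design is the study's result
#' (box-plot material); the headline comparison is the kinship-matched
#' (Hungarian) versus random control selection.
#'
#' @param n_replicates number of replicates R (study default 1000; reduced
#'   runs use 100).
#' @param cohort optionally a prebuilt [simulate_cohort()]; otherwise one
#'   is simulated with `...` forwarded.
#' @param n_subjects subjects drawn per replicate (N, default 50).
#' @param n_causal causal variants p per replicate (default 5).
#' @param n_cases cases I per replicate (default 10).
#' @param designs subset of `c("hungarian", "random")`.
#' @param methods passed to [run_replicate()].
#' @param ntree forest size per replicate.
#' @param slope,intercept disease-model link parameters.
#' @param seed master seed; everything downstream is derived from it.
#' @param ... forwarded to [simulate_cohort()] when `cohort` is `NULL`.
#' @return An object of class `"sim_study"`: list with `results` (one row
#'   per replicate x design x method) and `summary` (mean and quartiles of
#'   AUC per method x design).
#' @examples
#' \donttest{
#' st <- run_study(n_replicates = 5, n_snps = 50, ntree = 50, seed = 1)
#' st$summary
#' }
#' @export
run_study <- function(n_replicates = 1000L, cohort = NULL, n_subjects = 50L,
                      n_causal = 5L, n_cases = 10L,
                      designs = c("hungarian", "random"),
                      methods = c("rf", "fisher_bh", "qvalue", "lfdr"),
                      ntree = 200L, slope = 1, intercept = 0, seed = NULL,
                      ...) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  designs <- match.arg(designs, several.ok = TRUE)
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                       2L + 2L * n_replicates)
  if (is.null(cohort))
    cohort <- simulate_cohort(..., seed = seeds[1])
  N_all <- length(cohort$ids)
  if (n_subjects > N_all)
    stop("cohort smaller than n_subjects; enlarge the pedigree")
  P <- ncol(cohort$genotypes)
  rows <- vector("list", n_replicates * length(designs))
  ri <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- seeds[2L + 2L * r - 1L]
    sub <- with_seed(rep_seed, {
      model <- draw_disease_model(P, n_causal, slope = slope,
                                  intercept = intercept)
      ids <- sample(cohort$ids, n_subjects)
      list(model = model, ids = ids)
    })
    sub_cohort <- list(
      ids = sub$ids,
      genotypes = cohort$genotypes[sub$ids, , drop = FALSE],
      kinship = cohort$kinship[sub$ids, sub$ids, drop = FALSE])
    for (d in designs) {
      ri <- ri + 1L
      out <- run_replicate(sub_cohort, sub$model, design = d,
                           methods = methods, n_cases = n_cases,
                           ntree = ntree, seed = seeds[2L + 2L * r])
      out$replicate <- r
      rows[[ri]] <- out
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(auc ~ design + method, data = results,
                              FUN = function(a) {
                                c(mean = mean(a),
                                  q25 = unname(stats::quantile(a, 0.25)),
                                  median = stats::median(a),
                                  q75 = unname(stats::quantile(a, 0.75)))
                              })
  summary <- cbind(summary[c("design", "method")],
                   as.data.frame(summary$auc))
  out <- list(results = results, summary = summary,
              n_replicates = n_replicates, seed = seed)
  class(out) <- "sim_study"
  out
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulation study:", x$n_replicates, "replicates\n")
  cat("AUC by design and method:\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sim_study <- function(x, ...) {
  f <- interaction(x$results$method, x$results$design)
  graphics::boxplot(x$results$auc ~ f, las = 2, ylab = "AUC",
                    xlab = "", main = "Ranking performance by design", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
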