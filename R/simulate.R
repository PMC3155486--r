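#' Simulate a multi-generation consanguineous pedigree
#'
#' Generates a random pedigree emulating a small genetic isolate with high
#' endogamy: generation 0 consists of unrelated founders; in each later
#' generation, members of the previous generation are paired at random into
#' male-female couples (full siblings and parent-offspring pairings are
#' excluded), and each prospective parent mates within the pedigree with
#' probability `p_within`, otherwise with a fresh immigrant founder. Each
#' couple has a Poisson(`mean_offspring`) number of children. Repeated
#' within-pedigree mating across generations produces cousin marriages and
#' hence inbreeding, which is what the kinship-matched design exploits;
#' lowering `p_within` yields an outbred population.
#'
#' @param n_founders founders in generation 0 (at least 2; sexes balanced).
#' @param n_generations total number of generations including the founders.
#' @param mean_offspring mean children per couple.
#' @param p_within probability that a spouse is drawn from inside the
#'   pedigree rather than being an immigrant founder (default 0.85, a high
#'   endogamy level typical of the isolates this design targets).
#' @param seed integer seed; the pedigree is reproducible given the seed.
#' @return A [pedigree()] object; ids are `G<generation>_<index>` with
#'   immigrant founders labelled `I<generation>_<index>`.
#' @examples
#' ped <- simulate_pedigree(n_founders = 10, n_generations = 4, seed = 1)
#' summary(ped)
#' @export
simulate_pedigree <- function(n_founders = 20, n_generations = 4,
                              mean_offspring = 3, p_within = 0.85,
                              seed = NULL) {
  if (n_founders < 2) stop("n_founders must be at least 2")
  if (n_generations < 1) stop("n_generations must be at least 1")
  with_seed(seed, {
    id <- paste0("G0_", seq_len(n_founders))
    father <- rep(NA_character_, n_founders)
    mother <- rep(NA_character_, n_founders)
    sex <- rep(c("male", "female"), length.out = n_founders)
    gen_ids <- id
    gen_sex <- sex
    gen_fa <- father
    gen_mo <- mother
    for (g in seq_len(n_generations - 1L)) {
      # every member of the previous generation seeks one spouse: within the
      # pedigree with probability p_within (full sibs excluded), otherwise
      # an immigrant founder marries in
      members <- gen_ids[sample.int(length(gen_ids))]
      unpaired <- members
      sibkey <- ifelse(is.na(gen_fa), paste0("founder:", gen_ids),
                       paste(gen_fa, gen_mo))[match(members, gen_ids)]
      names(sibkey) <- members
      msex <- gen_sex[match(members, gen_ids)]
      names(msex) <- members
      child_id <- child_fa <- child_mo <- child_sex <- character(0)
      n_imm <- 0L
      ci <- 0L
      while (length(unpaired)) {
        a <- unpaired[1]
        unpaired <- unpaired[-1]
        want <- if (msex[[a]] == "male") "female" else "male"
        cands <- unpaired[msex[unpaired] == want &
                            sibkey[unpaired] != sibkey[[a]]]
        if (length(cands) && stats::runif(1) < p_within) {
          b <- cands[1]
          unpaired <- setdiff(unpaired, b)
        } else {
          n_imm <- n_imm + 1L
          b <- paste0("I", g, "_", n_imm)
          id <- c(id, b)
          father <- c(father, NA_character_)
          mother <- c(mother, NA_character_)
          sex <- c(sex, want)
          msex[b] <- want
        }
        m <- if (msex[[a]] == "male") a else b
        f <- if (msex[[a]] == "male") b else a
        n_child <- stats::rpois(1, mean_offspring)
        for (cc in seq_len(n_child)) {
          ci <- ci + 1L
          child_id <- c(child_id, paste0("G", g, "_", ci))
          child_fa <- c(child_fa, m)
          child_mo <- c(child_mo, f)
          child_sex <- c(child_sex,
                         if (stats::runif(1) < 0.5) "male" else "female")
        }
      }
      if (length(child_id) == 0L)
        stop("generation ", g, " is empty; increase n_founders or ",
             "mean_offspring")
      id <- c(id, child_id)
      father <- c(father, child_fa)
      mother <- c(mother, child_mo)
      sex <- c(sex, child_sex)
      gen_ids <- child_id
      gen_fa <- child_fa
      gen_mo <- child_mo
      gen_sex <- child_sex
    }
    pedigree(id, father, mother, sex)
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Simulates SNP genotypes consistent with the pedigree's relatedness by
#' Mendelian gene dropping. Founder haplotypes are drawn per locus from the
#' supplied minor-allele frequencies; within an optional LD block, loci copy
#' a shared latent allele (frequency of the block's first locus) with
#' probability `ld_r`, creating the clumpy dependence typical of dense SNP
#' panels. Each meiosis transmits one parental haplotype per block, with
#' free recombination between blocks and none within, so the genotype
#' correlation structure matches the pedigree kinship used by the matching
#' step.
#'
#' @param ped a [pedigree()] object.
#' @param maf numeric vector of allele frequencies in `(0, 0.5]`, one per
#'   locus (its length sets P).
#' @param ld_block_size loci per LD block (1 = independent loci).
#' @param ld_r within-block probability of copying the block's latent
#'   allele.
#' @param seed integer seed.
#' @return Integer matrix of 0/1/2 allele counts, subjects in rows (row
#'   names = pedigree ids), loci in columns (`snp1..snpP`).
#' @export
gene_drop_genotypes <- function(ped, maf, ld_block_size = 1, ld_r = 0.8,
                                seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  maf <- as.numeric(maf)
  if (length(maf) == 0 || any(is.na(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("maf entries must lie in (0, 0.5]")
  P <- length(maf)
  n <- length(ped$id)
  block <- rep(seq_len(ceiling(P / ld_block_size)),
               each = ld_block_size)[seq_len(P)]
  n_blocks <- max(block)
  block_first <- match(seq_len(n_blocks), block)
  with_seed(seed, {
    idx <- seq_len(n)
    names(idx) <- ped$id
    H1 <- matrix(0L, n, P)
    H2 <- matrix(0L, n, P)
    draw_founder_hap <- function() {
      if (ld_block_size == 1L) return(stats::rbinom(P, 1L, maf))
      z <- stats::rbinom(n_blocks, 1L, maf[block_first])
      copy <- stats::rbinom(P, 1L, ld_r) == 1L
      h <- stats::rbinom(P, 1L, maf)
      h[copy] <- z[block[copy]]
      h
    }
    meiosis <- function(h1, h2) {
      pick <- stats::rbinom(n_blocks, 1L, 0.5)[block] == 1L
      out <- h2
      out[pick] <- h1[pick]
      out
    }
    for (i in ped$order) {
      if (is.na(ped$father[i])) {
        H1[i, ] <- draw_founder_hap()
        H2[i, ] <- draw_founder_hap()
      } else {
        f <- idx[[ped$father[i]]]
        m <- idx[[ped$mother[i]]]
        H1[i, ] <- meiosis(H1[f, ], H2[f, ])
        H2[i, ] <- meiosis(H1[m, ], H2[m, ])
      }
    }
    G <- H1 + H2
    dimnames(G) <- list(ped$id, paste0("snp", seq_len(P)))
    G
  })
}

#' Configuration-count disease model
#'
#' The disease model of the simulation framework: a small set of causal
#' variants, one "risk configuration" (a specific genotype level) per
#' causal variant, and a logistic link on the number of matches. For a
#' subject with match count \eqn{c},
#' \deqn{\Pr(Y = 1 \mid x) = \mathrm{logit}^{-1}(\alpha + \beta c)}
#' with defaults \eqn{\alpha = 0}, \eqn{\beta = 1} (the inverse logit of
#' the raw count), so probabilities increase strictly with \eqn{c}.
#'
#' @param causal_indices distinct column indices of the causal variants
#'   (default count in the simulation study: 5).
#' @param configuration one genotype level (0/1/2) per causal variant.
#' @param slope,intercept link parameters; `slope` must be non-negative
#'   (probabilities strictly increase with the count when `slope > 0`;
#'   `slope = 0` is the no-effect null).
#' @return An object of class `"disease_model"`.
#' @export
disease_model <- function(causal_indices, configuration, slope = 1,
                          intercept = 0) {
  causal_indices <- as.integer(causal_indices)
  if (anyDuplicated(causal_indices)) stop("causal indices must be distinct")
  if (length(configuration) != length(causal_indices))
    stop("one configuration level per causal variant is required")
  if (slope < 0)
    stop("slope must be non-negative (0 gives the no-effect null model)")
  out <- list(causal_indices = causal_indices,
              configuration = as.integer(configuration),
              slope = slope, intercept = intercept)
  class(out) <- "disease_model"
  out
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Configuration-count disease model:", length(x$causal_indices),
      "causal variants\n")
  cat("  indices:      ", paste(x$causal_indices, collapse = ", "), "\n")
  cat("  configuration:", paste(x$configuration, collapse = ", "), "\n")
  cat("  link: inverse-logit(", x$intercept, " + ", x$slope,
      " * match count )\n", sep = "")
  invisible(x)
}

# random configuration over p causal variants, redrawn per replicate
draw_disease_model <- function(P, p = 5L, levels = 0:2, slope = 1,
                               intercept = 0) {
  if (p > P) stop("more causal variants than variants available")
  disease_model(sample.int(P, p), sample(levels, p, replace = TRUE),
                slope = slope, intercept = intercept)
}

#' Assign disease status from genotypes
#'
#' Computes each subject's match count \eqn{c_n} (number of causal variants
#' whose genotype equals the model's configuration level), converts it to
#' \eqn{\Pr(Y_n = 1)} through the model link, and assigns case status to
#' the `n_cases` subjects with the highest probability, breaking ties by a
#' seeded uniform draw. Exactly `n_cases` cases result, always — the
#' construction used throughout the simulation study (default 10 cases out
#' of 50 subjects).
#'
#' @param G genotype matrix (subjects x variants, 0/1/2).
#' @param model a [disease_model()].
#' @param n_cases number of cases to assign (must be < number of subjects).
#' @param seed integer seed (tie-breaking).
#' @return Integer 0/1 vector named by the subjects, with attribute
#'   `"prob"` carrying the model probabilities.
#' @export
assign_disease <- function(G, model, n_cases = 10L, seed = NULL) {
  stopifnot(inherits(model, "disease_model"))
  G <- as.matrix(G)
  N <- nrow(G)
  if (n_cases >= N) stop("n_cases must be smaller than the cohort size")
  if (max(model$causal_indices) > ncol(G))
    stop("causal index exceeds the number of variants")
  cc <- rep(0L, N)
  for (k in seq_along(model$causal_indices)) {
    cc <- cc + as.integer(G[, model$causal_indices[k]] ==
                            model$configuration[k])
  }
  pr <- stats::plogis(model$intercept + model$slope * cc)
  status <- integer(N)
  ord <- with_seed(seed, order(-pr, stats::runif(N)))
  status[ord[seq_len(n_cases)]] <- 1L
  names(status) <- rownames(G)
  attr(status, "prob") <- pr
  status
}

#' Monte-Carlo gene-dropping kinship estimate
#'
#' Estimates the kinship coefficient of a pair directly from its defining
#' experiment: founder alleles are given unique labels, alleles are dropped
#' through every meiosis, and the estimate is the observed probability that
#' one allele sampled from each individual is identical by descent. Serves
#' as the independent oracle for the recursive computation in
#' [kinship_pair()] (the two agree within Monte-Carlo error).
#'
#' @param ped a [pedigree()] object.
#' @param i,j individual ids (i = j gives the self-kinship
#'   \eqn{(1 + F_i)/2}).
#' @param n_drops number of gene drops (at least 1e4).
#' @param seed integer seed.
#' @return List with `estimate` and `se` (binomial-type standard error).
#' @export
mc_kinship_oracle <- function(ped, i, j, n_drops = 1e6, seed = 1) {
  res <- mc_kinship_pairs(ped, cbind(i, j), n_drops = n_drops, seed = seed)
  list(estimate = res$estimate[1], se = res$se[1])
}

#' @rdname mc_kinship_oracle
#' @param pairs two-column matrix of id pairs (all estimated from the same
#'   shared set of drops).
#' @export
mc_kinship_pairs <- function(ped, pairs, n_drops = 1e6, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  if (n_drops < 1e4) stop("n_drops must be at least 1e4")
  pairs <- matrix(as.character(pairs), ncol = 2)
  i1 <- ped_index(ped, pairs[, 1])
  i2 <- ped_index(ped, pairs[, 2])
  # reindex into topological order for the C++ dropper
  pos <- integer(length(ped$id))
  pos[ped$order] <- seq_along(ped$order)
  idx <- seq_along(ped$id)
  names(idx) <- ped$id
  fa <- rep(-1L, length(ped$id))
  mo <- rep(-1L, length(ped$id))
  known <- !is.na(ped$father)
  fa[known] <- pos[idx[ped$father[known]]] - 1L
  mo[known] <- pos[idx[ped$mother[known]]] - 1L
  fa_t <- fa[ped$order]
  mo_t <- mo[ped$order]
  p_t <- cbind(pos[i1] - 1L, pos[i2] - 1L)
  res <- cpp_mc_kinship(fa_t, mo_t, p_t, as.integer(n_drops),
                        as.double(seed))
  data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
             estimate = res$estimate, se = res$se,
             stringsAsFactors = FALSE)
}
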