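#' Select the jointly most-related controls (Hungarian method)
#'
#' Given the case-by-control kinship matrix \eqn{K'}, finds the one-to-one
#' matching of all \eqn{I} cases to \eqn{I} distinct controls that maximises
#' the total matched kinship, i.e. the sub-matrix \eqn{K_{I \times I}} of
#' \eqn{K'} with maximal trace over all injections of cases into controls.
#' This is a linear assignment problem, solved exactly with the Hungarian
#' method (`clue::solve_LSAP`), which handles the rectangular \eqn{I < J}
#' case natively. The resulting balanced design concentrates case/control
#' pairs inside close kin, reducing the genetic variability exogenous to the
#' disease before any association testing is done.
#'
#' @param K numeric kinship matrix, cases in rows, controls in columns,
#'   finite non-negative entries; dimnames used as subject labels when
#'   present.
#' @return An object of class `"assignment"`: list with `pairs` (data frame
#'   with `case_index`, `control_index`, `case_id`, `control_id`,
#'   `kinship`), `total_kinship` and `design` (`"hungarian"`).
#' @examples
#' K <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("u1", "u2")))
#' hungarian_select(K)
#' @seealso [random_select()] for the unmatched comparator,
#'   [matched_sample()] to assemble the design into an analysable sample.
#' @export
hungarian_select <- function(K) {
  K <- as_kinship_input(K)
  I <- nrow(K)
  J <- ncol(K)
  if (I > J) {
    stop("infeasible design: fewer potential controls (", J,
         ") than cases (", I, ")")
  }
  sel <- as.integer(clue::solve_LSAP(K, maximum = TRUE))
  new_assignment(K, sel, "hungarian")
}

#' Select controls at random (comparator design)
#'
#' Samples `length(case_ids)` distinct controls uniformly without
#' replacement from the pool and pairs them to the cases in order. This is
#' the usual design for observational studies of outbred populations and
#' serves as the comparator against the kinship-matched design.
#'
#' @param case_ids character vector of case labels.
#' @param control_pool character vector of available control labels.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param kinship optional kinship matrix (cases x pool, dimnames matching
#'   the ids) used to report the total matched kinship of the random draw.
#' @return An `"assignment"` object (see [hungarian_select()]); its
#'   `total_kinship` is `NA` when `kinship` is not supplied.
#' @export
random_select <- function(case_ids, control_pool, seed = NULL,
                          kinship = NULL) {
  case_ids <- as.character(case_ids)
  control_pool <- as.character(control_pool)
  I <- length(case_ids)
  if (length(control_pool) < I) {
    stop("infeasible design: fewer potential controls (",
         length(control_pool), ") than cases (", I, ")")
  }
  sel_ids <- with_seed(seed, sample(control_pool, I, replace = FALSE))
  if (is.null(kinship)) {
    K <- matrix(NA_real_, I, I,
                dimnames = list(case_ids, sel_ids))
    sel <- seq_len(I)
    out <- new_assignment(K, sel, "random")
    out$pairs$control_index <- match(sel_ids, control_pool)
    return(out)
  }
  K <- as_kinship_input(kinship)
  if (!identical(rownames(K), case_ids))
    K <- K[case_ids, , drop = FALSE]
  sel <- match(sel_ids, colnames(K))
  if (anyNA(sel)) stop("kinship matrix columns do not cover the pool")
  new_assignment(K, sel, "random")
}

as_kinship_input <- function(K) {
  K <- as.matrix(K)
  storage.mode(K) <- "double"
  if (!all(is.finite(K))) stop("kinship matrix entries must be finite")
  if (is.null(rownames(K))) rownames(K) <- paste0("case", seq_len(nrow(K)))
  if (is.null(colnames(K))) colnames(K) <- paste0("ctrl", seq_len(ncol(K)))
  K
}

new_assignment <- function(K, sel, design) {
  I <- nrow(K)
  stopifnot(length(sel) == I, !anyDuplicated(sel))
  kin <- K[cbind(seq_len(I), sel)]
  out <- list(
    pairs = data.frame(case_index = seq_len(I),
                       control_index = sel,
                       case_id = rownames(K),
                       control_id = colnames(K)[sel],
                       kinship = kin,
                       stringsAsFactors = FALSE),
    total_kinship = sum(kin),
    design = design)
  class(out) <- "assignment"
  out
}

#' @export
print.assignment <- function(x, ...) {
  cat("Control assignment (", x$design, " design): ",
      nrow(x$pairs), " case-control pairs\n", sep = "")
  if (!is.na(x$total_kinship))
    cat("Total matched kinship:", format(x$total_kinship), "\n")
  invisible(x)
}

#' Assemble a balanced matched case-control sample
#'
#' Combines an [hungarian_select()] / [random_select()] assignment with the
#' genotype matrix into the balanced sample of \eqn{2I} subjects (all cases,
#' status 1, followed by their selected controls, status 0) on which the
#' forest and the single-point scans are run.
#'
#' @param assignment an `"assignment"` object.
#' @param genotypes matrix or data frame of categorical predictors with row
#'   names covering every selected subject (values `0/1/2`, factor levels or
#'   `NA`).
#' @param covariates optional additional categorical columns, same row-name
#'   convention; appended to the predictor matrix.
#' @return An object of class `"matched_sample"`: list with `subject_id`
#'   (length \eqn{2I}), `status` (integer, \eqn{I} ones then \eqn{I} zeros),
#'   `genotypes` (\eqn{2I \times P}), `matched_case` (`NA` for cases, the
#'   paired case id for controls) and `design`.
#' @export
matched_sample <- function(assignment, genotypes, covariates = NULL) {
  stopifnot(inherits(assignment, "assignment"))
  p <- assignment$pairs
  if (anyDuplicated(p$control_id))
    stop("invalid assignment: duplicated control")
  overlap <- intersect(p$case_id, p$control_id)
  if (length(overlap))
    stop("subject selected as both case and control: ",
         paste(overlap, collapse = ", "))
  ids <- c(p$case_id, p$control_id)
  G <- as.matrix(genotypes)
  if (is.null(rownames(G))) stop("genotypes must carry subject row names")
  missing_rows <- setdiff(ids, rownames(G))
  if (length(missing_rows)) {
    stop("no genotype row for subject(s): ",
         paste(missing_rows, collapse = ", "))
  }
  G <- G[ids, , drop = FALSE]
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    missing_rows <- setdiff(ids, rownames(C))
    if (length(missing_rows))
      stop("no covariate row for subject(s): ",
           paste(missing_rows, collapse = ", "))
    G <- cbind(G, C[ids, , drop = FALSE])
  }
  out <- list(subject_id = ids,
              status = rep(1:0, each = nrow(p)),
              genotypes = G,
              matched_case = c(rep(NA_character_, nrow(p)), p$case_id),
              design = assignment$design)
  class(out) <- "matched_sample"
  out
}

#' @export
print.matched_sample <- function(x, ...) {
  I <- sum(x$status == 1)
  cat("Matched sample (", x$design, " design): ", length(x$subject_id),
      " subjects (", I, " cases / ", sum(x$status == 0), " controls), ",
      ncol(x$genotypes), " predictors\n", sep = "")
  invisible(x)
}

#' Write / read a matched sample table
#'
#' TSV with columns `subject_id`, `status`, `matched_case_id`, `design_tag`.
#'
#' @param sample a `"matched_sample"` object.
#' @param path file path.
#' @return `read_matched_sample()` returns a data frame (genotypes are not
#'   stored in this table; re-attach them with [matched_sample_from_table()]).
#' @export
write_matched_sample <- function(sample, path) {
  stopifnot(inherits(sample, "matched_sample"))
  df <- data.frame(subject_id = sample$subject_id,
                   status = sample$status,
                   matched_case_id = ifelse(is.na(sample$matched_case), "-",
                                            sample$matched_case),
                   design_tag = sample$design,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matched_sample
#' @export
read_matched_sample <- function(path) {
  utils::read.delim(path, comment.char = "#",
                    colClasses = c(subject_id = "character",
                                   matched_case_id = "character"))
}

#' Rebuild a matched sample from its table and a genotype matrix
#'
#' @param table data frame as returned by [read_matched_sample()].
#' @param genotypes genotype matrix with subject row names.
#' @return A `"matched_sample"` object.
#' @export
matched_sample_from_table <- function(table, genotypes) {
  ids <- table$subject_id
  G <- as.matrix(genotypes)
  missing_rows <- setdiff(ids, rownames(G))
  if (length(missing_rows))
    stop("no genotype row for subject(s): ",
         paste(missing_rows, collapse = ", "))
  mc <- table$matched_case_id
  mc[mc == "-"] <- NA_character_
  out <- list(subject_id = ids,
              status = as.integer(table$status),
              genotypes = G[ids, , drop = FALSE],
              matched_case = mc,
              design = as.character(table$design_tag[1]))
  class(out) <- "matched_sample"
  out
}
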