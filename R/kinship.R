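#' Kinship coefficients from a pedigree
#'
#' The kinship coefficient \eqn{k_{ij}} is the probability that two alleles,
#' one sampled at random from individual \eqn{i} and one from \eqn{j}, are
#' identical by descent through the pedigree. It is computed by the classical
#' recursion, processing individuals founders-first: for a founder,
#' \eqn{k(i,i) = 1/2} and kinship with any earlier individual is 0; for a
#' non-founder \eqn{j} with parents \eqn{f, m},
#' \deqn{k(j,j) = \tfrac12 (1 + k(f, m)), \qquad
#'       k(i,j) = \tfrac12 (k(i,f) + k(i,m))}
#' where \eqn{i} precedes \eqn{j} in topological order. Founders are assumed
#' mutually unrelated and non-inbred. The full matrix is memoised on the
#' pedigree object, so repeated pair queries are O(1) after the first.
#'
#' Typical values: parent-offspring 1/4, full siblings 1/4, unrelated 0,
#' self-kinship of a non-inbred individual 1/2. The inbreeding coefficient of
#' an individual equals the kinship of its parents, i.e. \eqn{2 k(i,i) - 1}.
#'
#' @param ped a [pedigree()] object.
#' @param i,j individual ids.
#' @return `kinship_pair()`: a single coefficient in `[0, 1)`.
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' kinship_pair(ped, "A", "C")  # parent-offspring: 0.25
#' kinship_pair(ped, "A", "B")  # unrelated founders: 0
#' @seealso [kinship_matrix()], [mc_kinship_oracle()] for the gene-dropping
#'   Monte-Carlo estimate of the same quantity.
#' @export
kinship_pair <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  ii <- ped_index(ped, c(i, j))
  phi <- kinship_all(ped)
  phi[ii[1], ii[2]]
}

#' Full kinship matrix of a pedigree
#'
#' Computes (and caches) the complete symmetric matrix of pairwise kinship
#' coefficients, including self-kinship on the diagonal.
#'
#' @param ped a [pedigree()] object.
#' @return Numeric matrix with row/column names equal to the individual ids.
#' @export
kinship_all <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  cached <- ped$.cache$phi
  if (!is.null(cached)) return(cached)
  n <- length(ped$id)
  idx <- seq_len(n)
  names(idx) <- ped$id
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- integer(n) # position in topological order
  pos[ped$order] <- seq_len(n)
  for (t in seq_len(n)) {
    i <- ped$order[t]
    if (is.na(ped$father[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- idx[[ped$father[i]]]
      m <- idx[[ped$mother[i]]]
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      if (t > 1L) {
        earlier <- ped$order[seq_len(t - 1L)]
        v <- 0.5 * (phi[earlier, f] + phi[earlier, m])
        phi[earlier, i] <- v
        phi[i, earlier] <- v
      }
    }
  }
  ped$.cache$phi <- phi
  phi
}

#' Case-by-control kinship matrix
#'
#' Builds the matrix \eqn{K'} whose entry \eqn{(i, j)} is the kinship
#' coefficient between case \eqn{i} and potential control \eqn{j}. This is
#' the input to the assignment problem solved by [hungarian_select()].
#'
#' @param ped a [pedigree()] object.
#' @param case_ids,control_ids disjoint sets of individual ids present in
#'   the pedigree.
#' @return Numeric matrix (cases in rows, controls in columns, dimnames set)
#'   with entries in `[0, 1)`.
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' kinship_matrix(ped, "C", c("A", "B"))
#' @export
kinship_matrix <- function(ped, case_ids, control_ids) {
  stopifnot(inherits(ped, "pedigree"))
  case_ids <- as.character(case_ids)
  control_ids <- as.character(control_ids)
  if (length(case_ids) == 0L || length(control_ids) == 0L)
    stop("case and control id sets must be non-empty")
  if (anyDuplicated(case_ids) || anyDuplicated(control_ids))
    stop("case and control ids must be unique")
  overlap <- intersect(case_ids, control_ids)
  if (length(overlap)) {
    stop("case and control sets overlap: ",
         paste(overlap, collapse = ", "))
  }
  ri <- ped_index(ped, case_ids, "case")
  ci <- ped_index(ped, control_ids, "control")
  phi <- kinship_all(ped)
  K <- phi[ri, ci, drop = FALSE]
  dimnames(K) <- list(case_ids, control_ids)
  K
}

#' Write / read a kinship matrix as TSV
#'
#' Plain tab-separated text: header row of control ids, first column of case
#' ids, full floating-point precision, so that write-then-read round-trips
#' exactly.
#'
#' @param K numeric kinship matrix with dimnames (cases x controls).
#' @param path file path.
#' @return `read_kinship()` returns the matrix; `write_kinship()` returns
#'   `path` invisibly.
#' @export
write_kinship <- function(K, path) {
  stopifnot(is.matrix(K), !is.null(rownames(K)), !is.null(colnames(K)))
  header <- paste(c("case_id", colnames(K)), collapse = "\t")
  body <- vapply(seq_len(nrow(K)), function(i) {
    paste(c(rownames(K)[i], sprintf("%.17g", K[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          colClasses = c("character"))
  K <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(K) <- "double"
  rownames(K) <- df[[1]]
  K
}
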