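#' Build a validated pedigree
#'
#' A pedigree is the directed acyclic parent structure over a set of
#' individuals; it is the sole source of relatedness information used by the
#' kinship computations and, through them, by the matched case-control
#' design. Founders are individuals with no recorded parents and are assumed
#' mutually unrelated and non-inbred.
#'
#' Validation enforces: unique ids, parents either both missing or both
#' present and known, no self-parentage, no selfing (the same individual as
#' both father and mother), and acyclicity. A topological order
#' (founders first) is computed and cached; all downstream recursions use it.
#'
#' @param id character vector of unique individual labels.
#' @param father,mother character vectors of parent labels; `NA`, `""` or
#'   `"0"` mean "missing" (founder).
#' @param sex optional vector coded `"male"`/`"female"`/`"unknown"` or
#'   PLINK-style `1`/`2`/`0`. Sex is carried along (the synthetic pedigree
#'   generator uses it for mating) but never enters any kinship computation.
#' @return An object of class `"pedigree"`: a list with elements `id`,
#'   `father`, `mother`, `sex` (aligned vectors, `NA` for missing parents)
#'   and `order` (topological permutation of indices, parents before
#'   children).
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' founders(ped)
#' @seealso [read_pedigree()] for the PLINK-FAM file reader,
#'   [kinship_pair()] and [kinship_matrix()].
#' @export
pedigree <- function(id, father, mother, sex = NULL) {
  id <- as.character(id)
  father <- normalize_parent(father)
  mother <- normalize_parent(mother)
  n <- length(id)
  if (n == 0L) stop("pedigree must contain at least one individual")
  if (length(father) != n || length(mother) != n)
    stop("id, father and mother must have the same length")
  if (anyNA(id) || any(id == "")) stop("individual ids must be non-missing")
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }

  sex <- normalize_sex(sex, n)

  half <- xor(is.na(father), is.na(mother))
  if (any(half)) {
    stop("single known parent for individual(s): ",
         paste(id[half], collapse = ", "),
         " (both parents must be recorded or both missing)")
  }
  self <- !is.na(father) & (father == id | mother == id)
  if (any(self)) {
    stop("self-parentage for individual(s): ",
         paste(id[self], collapse = ", "))
  }
  selfing <- !is.na(father) & father == mother
  if (any(selfing)) {
    stop("father and mother are the same individual for: ",
         paste(id[selfing], collapse = ", "))
  }
  known <- c(father, mother)
  bad <- !is.na(known) & !(known %in% id)
  if (any(bad)) {
    stop("unknown parent id(s): ",
         paste(unique(known[bad]), collapse = ", "))
  }

  ord <- topological_order(id, father, mother)

  ped <- list(id = id, father = father, mother = mother, sex = sex,
              order = ord)
  ped$.cache <- new.env(parent = emptyenv())
  class(ped) <- "pedigree"
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "" | x == "-")] <- NA_character_
  x
}

normalize_sex <- function(sex, n) {
  if (is.null(sex)) return(rep("unknown", n))
  if (length(sex) != n) stop("sex must have one entry per individual")
  if (is.numeric(sex)) {
    out <- c("0" = "unknown", "1" = "male", "2" = "female")[as.character(sex)]
    out[is.na(out)] <- "unknown"
    return(unname(out))
  }
  sex <- as.character(sex)
  sex[is.na(sex) | !(sex %in% c("male", "female"))] <- "unknown"
  sex
}

# Kahn's algorithm; fails with the name of one individual on a cycle.
topological_order <- function(id, father, mother) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  fa <- ifelse(is.na(father), 0L, idx[father])
  mo <- ifelse(is.na(mother), 0L, idx[mother])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(fa[i], mo[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- idx[indeg == 0L]
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    on_cycle <- setdiff(idx, ord)
    stop("pedigree contains a cycle involving individual: ",
         id[on_cycle[1]])
  }
  unname(ord)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$father))
  cat("Pedigree:", length(x$id), "individuals (", nf, "founders,",
      length(x$id) - nf, "non-founders )\n")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  nf <- sum(is.na(object$father))
  depth <- pedigree_depth(object)
  out <- list(n = length(object$id), founders = nf,
              non_founders = length(object$id) - nf,
              generations = max(depth) + 1L)
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat("Pedigree with", x$n, "individuals\n")
  cat("  founders:      ", x$founders, "\n")
  cat("  non-founders:  ", x$non_founders, "\n")
  cat("  generations:   ", x$generations, "\n")
  invisible(x)
}

# generation depth: founders 0, child = 1 + max(parents)
pedigree_depth <- function(ped) {
  idx <- seq_along(ped$id)
  names(idx) <- ped$id
  depth <- integer(length(idx))
  for (i in ped$order) {
    if (!is.na(ped$father[i])) {
      depth[i] <- 1L + max(depth[idx[ped$father[i]]],
                           depth[idx[ped$mother[i]]])
    }
  }
  depth
}

#' Founder labels of a pedigree
#'
#' @param ped a [pedigree()] object.
#' @return Character vector of ids with no recorded parents.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[is.na(ped$father)]
}

ped_index <- function(ped, ids, what = "individual") {
  i <- match(ids, ped$id)
  if (anyNA(i)) {
    stop("unknown ", what, " id(s): ",
         paste(ids[is.na(i)], collapse = ", "))
  }
  i
}
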