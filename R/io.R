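#' Read a pedigree from a PLINK-FAM-compatible file
#'
#' Whitespace-delimited text with columns `family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex` and (optionally) `phenotype`; `0` means
#' "missing parent" and sex is coded 1 = male, 2 = female, 0 = unknown.
#' The family id is ignored for kinship (the whole file is one genealogy);
#' the phenotype column, when present, is attached as attribute
#' `"phenotype"` (named by individual).
#'
#' @param path file path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("pedigree file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(5L, 6L)))
  if (length(bad)) {
    stop("malformed pedigree line ", bad[1], " (", nf[bad[1]],
         " columns; expected 5 or 6): ", lines[bad[1]])
  }
  m <- do.call(rbind, fields)
  ped <- pedigree(id = m[, 2], father = m[, 3], mother = m[, 4],
                  sex = suppressWarnings(as.numeric(m[, 5])))
  if (ncol(m) == 6L) {
    phen <- m[, 6]
    names(phen) <- m[, 2]
    attr(ped, "phenotype") <- phen
  }
  ped
}

#' Write a pedigree as a PLINK-FAM file
#'
#' @param ped a [pedigree()] object.
#' @param path file path.
#' @param family_id constant family label for column 1.
#' @export
write_pedigree <- function(ped, path, family_id = "FAM1") {
  stopifnot(inherits(ped, "pedigree"))
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  phen <- attr(ped, "phenotype")
  phen <- if (is.null(phen)) rep("-9", length(ped$id)) else phen[ped$id]
  lines <- paste(family_id, ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 sex_code, phen)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype matrix
#'
#' TSV with a header line (first column = subject id, remaining columns =
#' variant ids) and one row per subject; values 0/1/2, declared category
#' labels, or `NA` for missing. When every value is a 0/1/2 dose the matrix
#' is returned as integer.
#'
#' @param path file path.
#' @param ped optionally a [pedigree()]; when supplied, every subject must
#'   be present in it (reconciliation error otherwise).
#' @return Matrix with subject row names and variant column names.
#' @export
read_genotypes <- function(path, ped = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("genotype file needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop("ragged genotype file: line ", bad, " has ", nf[bad],
         " columns, header has ", nf[1])
  }
  header <- fields[[1]]
  body <- do.call(rbind, fields[-1])
  subjects <- body[, 1]
  if (anyDuplicated(subjects))
    stop("duplicate subject id(s) in genotype file")
  G <- body[, -1, drop = FALSE]
  G[G %in% c("NA", "")] <- NA
  dimnames(G) <- list(subjects, header[-1])
  vals <- unique(G[!is.na(G)])
  if (all(vals %in% c("0", "1", "2"))) {
    Gi <- matrix(as.integer(G), nrow(G), dimnames = dimnames(G))
    G <- Gi
  }
  if (!is.null(ped)) {
    unknown <- setdiff(subjects, ped$id)
    if (length(unknown)) {
      stop("genotyped subject(s) absent from the pedigree: ",
           paste(unknown, collapse = ", "))
    }
  }
  G
}

#' Write a genotype matrix as TSV
#'
#' @param G matrix with subject row names and variant column names.
#' @param path file path.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(is.matrix(G), !is.null(rownames(G)))
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  header <- paste(c("subject", colnames(G)), collapse = "\t")
  vals <- matrix(as.character(G), nrow(G))
  vals[is.na(vals)] <- "NA"
  body <- vapply(seq_len(nrow(G)), function(i) {
    paste(c(rownames(G)[i], vals[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Run the full design-then-model pipeline
#'
#' Composes the workflow end to end: pedigree kinship, control selection
#' (Hungarian by default), then the single-point Fisher scan and/or the
#' forest screening and backward selection, writing each artifact as TSV
#' into `out_dir` (`kinship.tsv`, `sample.tsv`, `scan.tsv`, `screen.tsv`,
#' `trace.tsv`). Every output starts with comment header lines recording
#' the package version and the seed, so a rerun with the same inputs and
#' seed reproduces the tables byte for byte below the header.
#'
#' @param ped_file PLINK-FAM pedigree file.
#' @param geno_file genotype TSV (see [read_genotypes()]).
#' @param case_ids character vector of case ids, or a file with one id per
#'   line.
#' @param out_dir output directory (created if needed).
#' @param design `"hungarian"` or `"random"`.
#' @param do_scan,do_select which analysis stages to run.
#' @param ntree forest size for the selection stage.
#' @param seed master seed.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(ped_file, geno_file, case_ids, out_dir,
                         design = c("hungarian", "random"),
                         do_scan = TRUE, do_select = TRUE, ntree = 500L,
                         seed = 1L, verbose = FALSE) {
  design <- match.arg(design)
  say <- function(...) if (verbose) message("[kinforest] ", ...)
  if (!file.exists(geno_file))
    stop("stage io: genotype file not found: ", geno_file)
  ped <- read_pedigree(ped_file)
  G <- read_genotypes(geno_file, ped = ped)
  if (length(case_ids) == 1 && file.exists(case_ids))
    case_ids <- readLines(case_ids)
  case_ids <- trimws(case_ids[nzchar(trimws(case_ids))])
  pool <- setdiff(rownames(G), case_ids)
  if (!all(case_ids %in% rownames(G)))
    stop("stage design: case id(s) without genotypes: ",
         paste(setdiff(case_ids, rownames(G)), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(seed, 3L)

  say("kinship: ", length(case_ids), " cases x ", length(pool), " controls")
  K <- kinship_matrix(ped, case_ids, pool)
  write_with_header(function(p) write_kinship(K, p),
                    file.path(out_dir, "kinship.tsv"), seed)

  say("match: ", design, " design")
  asn <- if (design == "hungarian") hungarian_select(K)
         else random_select(case_ids, pool, seed = seeds[1], kinship = K)
  smp <- matched_sample(asn, G)
  write_with_header(function(p) write_matched_sample(smp, p),
                    file.path(out_dir, "sample.tsv"), seed)

  results <- list(kinship = K, assignment = asn, sample = smp)
  if (do_scan) {
    say("scan: ", ncol(G), " variants")
    scan <- genome_scan(smp)
    write_with_header(function(p) write_scan_result(scan, p),
                      file.path(out_dir, "scan.tsv"), seed)
    results$scan <- scan
  }
  if (do_select) {
    say("rf-select: bagging screen over ", ncol(G), " variants")
    scr <- bagging_screen(smp, ntree = ntree, seed = seeds[2])
    utils::write.table(
      data.frame(iteration = seq_along(scr$sizes), k = scr$sizes,
                 oob_error = scr$oob_errors),
      file.path(out_dir, "screen.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$screen <- scr
    if (length(scr$variables)) {
      say("rf-select: backward selection over ", length(scr$variables),
          " survivors")
      trace <- backward_select(smp, ranked = scr, ntree = ntree,
                               seed = seeds[3])
      write_with_header(function(p) write_selection_trace(trace, p),
                        file.path(out_dir, "trace.tsv"), seed)
      results$trace <- trace
    }
  }
  say("done")
  invisible(results)
}

# prepend "# kinforest <version> seed=<seed>" comment lines to an artifact
write_with_header <- function(writer, path, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writer(tmp)
  header <- paste0("# kinforest ",
                   as.character(utils::packageVersion("kinforest")),
                   " seed=", seed)
  writeLines(c(header, readLines(tmp)), path)
  invisible(path)
}

#' Read a TSV artifact written by [run_pipeline()]
#'
#' Skips the `#` comment header.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_artifact <- function(path) {
  utils::read.delim(path, comment.char = "#")
}
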