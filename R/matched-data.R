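#' Matched case-control dataset with block-structured covariates
#'
#' Bundles a numeric covariate matrix, a stratum (matched-set) label per
#' observation, a binary case indicator and the block structure of the
#' covariate columns into a validated object used by every fitting,
#' tuning and selection function in the package.
#'
#' A valid dataset satisfies 1:k matching: every stratum contains exactly one
#' case (`y == 1`) and at least one control (`y == 0`). Covariate columns are
#' ordered and blocks are contiguous column ranges; `block_sizes` must sum to
#' `ncol(X)`. Stratum labels may be arbitrary atomic values (strings, factors,
#' integers); they are mapped internally to dense integer ids. Missing values
#' are rejected: rows with `NA` covariates must be removed (or their whole
#' stratum, to preserve matching) before construction.
#'
#' @param X numeric matrix (observations x covariates), no missing values.
#' @param stratum vector of matched-set labels, one per row of `X`.
#' @param y binary case indicator per row, coded exactly 0/1.
#' @param block_sizes positive integers giving the number of columns in each
#'   contiguous covariate block; must sum to `ncol(X)`.
#' @param block_names optional character labels for the blocks.
#'
#' @return An object of class `matched_data`: a list with elements `X`
#'   (rows sorted by stratum), `stratum` (dense integer ids), `y`,
#'   `block_sizes`, `block` (block id per column), `n_strata`, and
#'   `stratum_labels` (original labels in id order).
#' @export
#' @examples
#' X <- matrix(rnorm(12), 4, 3)
#' d <- matched_data(X, stratum = c(1, 1, 2, 2), y = c(1, 0, 0, 1),
#'                   block_sizes = c(2, 1))
#' d$n_strata
matched_data <- function(X, stratum, y, block_sizes, block_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0)
    stop("incomplete row: covariate matrix has missing values in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", call. = FALSE)
  }
  n <- nrow(X)
  if (length(stratum) != n || length(y) != n)
    stop("stratum and y must have one entry per row of X", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("invalid response: case indicator must be coded exactly 0/1",
         call. = FALSE)
  y <- as.integer(y)

  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 1L || any(block_sizes < 1L))
    stop("invalid block spec: block sizes must be positive integers",
         call. = FALSE)
  if (sum(block_sizes) != ncol(X))
    stop("invalid block spec: block sizes sum to ", sum(block_sizes),
         " but X has ", ncol(X), " columns", call. = FALSE)
  if (is.null(block_names)) block_names <- paste0("block", seq_along(block_sizes))

  f <- factor(stratum, levels = unique(stratum))
  sid <- as.integer(f)
  cases_per <- tapply(y, sid, sum)
  sizes <- tabulate(sid)
  bad <- which(cases_per != 1L)
  if (length(bad) > 0L)
    stop("invalid matching: stratum ", paste(levels(f)[bad[1:min(5, length(bad))]],
         collapse = ", "), " must contain exactly one case", call. = FALSE)
  if (any(sizes < 2L))
    stop("invalid matching: stratum ",
         levels(f)[which(sizes < 2L)[1L]], " has no control", call. = FALSE)

  ord <- order(sid)
  out <- list(
    X = X[ord, , drop = FALSE],
    stratum = sid[ord],
    y = y[ord],
    block_sizes = block_sizes,
    block_names = block_names,
    block = rep(seq_along(block_sizes), block_sizes),
    n_strata = nlevels(f),
    stratum_labels = levels(f)
  )
  if (is.null(colnames(out$X)))
    colnames(out$X) <- paste0("V", seq_len(ncol(out$X)))
  class(out) <- "matched_data"
  out
}

#' @export
print.matched_data <- function(x, ...) {
  cat("Matched case-control dataset:", x$n_strata, "strata,",
      nrow(x$X), "observations,", ncol(x$X), "covariates in",
      length(x$block_sizes), "block(s) [",
      paste(x$block_sizes, collapse = ", "), "]\n")
  invisible(x)
}

# 0-based stratum start offsets (with sentinel) for the C++ routines;
# rows of d$X are already sorted by stratum.
stratum_starts <- function(d) {
  c(0L, cumsum(tabulate(d$stratum, nbins = d$n_strata)))
}

#' Restrict a matched dataset to a subset of strata or covariate columns
#'
#' @param d a [matched_data] object.
#' @param strata integer vector of stratum ids to keep (default: all).
#' @param columns integer vector of covariate column indices to keep; must be
#'   compatible with a contiguous-block structure, which is recomputed.
#' @return a [matched_data] object.
#' @export
subset_strata <- function(d, strata = NULL, columns = NULL) {
  keep <- if (is.null(strata)) rep(TRUE, nrow(d$X)) else d$stratum %in% strata
  X <- d$X[keep, , drop = FALSE]
  blk <- d$block
  if (!is.null(columns)) {
    columns <- sort(unique(as.integer(columns)))
    X <- X[, columns, drop = FALSE]
    blk <- d$block[columns]
  }
  bs <- as.integer(table(factor(blk, levels = unique(blk))))
  matched_data(X, d$stratum[keep], d$y[keep], bs,
               block_names = d$block_names[unique(blk)])
}

#' Case-minus-control differences for 1:1 matched data
#'
#' Reduces a 1:1 matched dataset to the standard pair-difference form: one row
#' per stratum equal to the case's covariate vector minus its control's. The
#' conditional likelihood of a 1:1 design equals an intercept-free logistic
#' likelihood on these differences with response identically 1, which this
#' package uses as an independent oracle in its tests.
#'
#' @param d a [matched_data] object with exactly 2 members per stratum.
#' @return numeric matrix (`n_strata` x p) of within-pair differences.
#' @export
pair_differences <- function(d) {
  sizes <- tabulate(d$stratum, nbins = d$n_strata)
  if (any(sizes != 2L))
    stop("not 1:1 matched: stratum ",
         d$stratum_labels[which(sizes != 2L)[1L]], " has ",
         sizes[which(sizes != 2L)[1L]], " members", call. = FALSE)
  Xc <- d$X[d$y == 1L, , drop = FALSE]
  X0 <- d$X[d$y == 0L, , drop = FALSE]
  ord1 <- order(d$stratum[d$y == 1L])
  ord0 <- order(d$stratum[d$y == 0L])
  Xc[ord1, , drop = FALSE] - X0[ord0, , drop = FALSE]
}

#' Read a matched dataset from a delimited file plus a block-structure config
#'
#' The data file is a CSV or TSV with a header row containing the stratum
#' column, the case column and the covariate columns (all remaining columns,
#' in file order). The config file (YAML or JSON, by extension) supplies
#' `blocks` (ordered block sizes) and may supply `stratum_column` and
#' `case_column` (which the function arguments override).
#'
#' @param file path to a delimited text file with header.
#' @param config path to a YAML (`.yml`/`.yaml`) or JSON config file.
#' @param stratum_column,case_column column names; default taken from config.
#' @param sep field separator; guessed from the file extension if `NULL`
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return a validated [matched_data] object.
#' @export
#' @examples
#' d <- read_matched_data(
#'   system.file("extdata", "example_pairs.csv", package = "clrnet"),
#'   system.file("extdata", "example_blocks.yaml", package = "clrnet"))
#' d
read_matched_data <- function(file, config, stratum_column = NULL,
                              case_column = NULL, sep = NULL) {
  cfg <- read_block_config(config)
  if (is.null(stratum_column)) stratum_column <- cfg$stratum_column
  if (is.null(case_column)) case_column <- cfg$case_column
  if (is.null(stratum_column) || is.null(case_column))
    stop("stratum_column and case_column must be given in the config or as arguments",
         call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (cc in c(stratum_column, case_column))
    if (!cc %in% names(tab))
      stop("column '", cc, "' not found in ", file, call. = FALSE)
  covars <- setdiff(names(tab), c(stratum_column, case_column))
  X <- as.matrix(tab[, covars, drop = FALSE])
  matched_data(X, tab[[stratum_column]], tab[[case_column]],
               cfg$blocks, block_names = cfg$block_names)
}

read_block_config <- function(config) {
  cfg <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(cfg$blocks))
    stop("invalid block spec: config must contain a 'blocks' entry", call. = FALSE)
  cfg$blocks <- as.integer(unlist(cfg$blocks))
  cfg
}

#' Write a matched dataset back to CSV (plus optional YAML block config)
#'
#' @param d a [matched_data] object.
#' @param file output CSV path.
#' @param config_out optional path for a YAML config describing the blocks.
#' @return `file`, invisibly.
#' @export
write_matched_data <- function(d, file, config_out = NULL) {
  tab <- data.frame(stratum = d$stratum_labels[d$stratum], case = d$y,
                    d$X, check.names = FALSE)
  utils::write.table(tab, file, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(config_out)) {
    yaml::write_yaml(list(blocks = as.integer(d$block_sizes),
                          stratum_column = "stratum",
                          case_column = "case"), config_out)
  }
  invisible(file)
}
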