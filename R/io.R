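#' Read rectangular unit-level data from a delimited text file
#'
#' Reads a header CSV (or other delimiter) with one row per unit and splits
#' it into the pieces the estimation functions expect: a covariate matrix,
#' a treatment vector, and optional outcome and offset vectors.
#'
#' @param path file path.
#' @param treatment name of the treatment column.
#' @param outcome,offset optional column names.
#' @param covariates character vector of covariate columns; default: every
#'   remaining column.
#' @param sep field delimiter (default `","`).
#' @return A list with components `x` (covariate matrix), `t`, `y`
#'   (or `NULL`), `offset` (or `NULL`), `n`.
#' @export
read_units <- function(path, treatment = "T", outcome = NULL, offset = NULL,
                       covariates = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  for (col in c(treatment, outcome, offset)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c(treatment, outcome, offset))
  }
  list(x = as.matrix(df[covariates]),
       t = df[[treatment]],
       y = if (is.null(outcome)) NULL else df[[outcome]],
       offset = if (is.null(offset)) NULL else df[[offset]],
       n = nrow(df))
}

#' Read a long-format panel from a delimited text file
#'
#' @inheritParams read_units
#' @param id,interval column names of the unit id and interval index.
#' @return A `data.frame` suitable for [pool_longitudinal()].
#' @export
read_panel <- function(path, id = "id", interval = "interval",
                       treatment = "treatment", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  for (col in c(id, interval, treatment)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  df
}
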