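#' Build the covariate-association-eliminating constraint system
#'
#' Constructs the linear system `A %*% W = b` whose rows are the weighted
#' score equations of the chosen propensity function model, evaluated at
#' parameter values indicating no covariate--treatment association: the
#' baseline (intercept) parameters fixed at the marginal maximum-likelihood
#' fit and every covariate (dependence) coefficient fixed at zero.  Weights
#' satisfying the system make the covariates unassociated with treatment, as
#' characterized by that model, in the weighted data, while preserving the
#' observed marginal treatment distribution.  A final row `sum(W) = n`
#' equates the sizes of the weighted and observed pseudo-populations.
#'
#' @param t treatment vector (length `n`).
#' @param x design matrix from [design_matrix()] (or a covariate matrix /
#'   `NULL`, which is passed through `design_matrix`); `n` rows.
#' @param family a [treatment_family()] (or family name).
#' @param marginal a [fit_marginal()] result for `t` and `family`; fitted on
#'   the fly when `NULL`.
#' @param projection_override optional scalar replacing the fitted marginal
#'   treatment probability in the projection function, for binary treatments
#'   or the binary component of a semicontinuous treatment (e.g. `1/2`,
#'   which reproduces classical covariate-balancing conditions equating
#'   weighted group totals).  The projection function must not depend on
#'   covariates, but is otherwise a free choice affecting efficiency only.
#'
#' @return An object of class `"caew_conditions"`: a list with the
#'   constraint matrix `A` (one column per unit), targets `b`, `row_labels`,
#'   the `projection` (marginal fit plus any override), `family`, the
#'   retained `design` matrix, and `n_units`.
#'
#' @details Rows that are identically zero across units (e.g. a constant
#'   covariate interacting with a degenerate indicator) are dropped with a
#'   warning; linearly dependent rows are dropped by a rank-revealing check
#'   at tolerance `1e-10` (reported via `message`).  Score rows are stored
#'   un-normalized, exactly as the per-unit score contributions; rescaling a
#'   row does not change the feasible set.
#' @examples
#' t <- c(1, 0, 1, 0)
#' x <- design_matrix(cbind(z = c(1, 1, -1, -1)))
#' cs <- build_conditions(t, x, "binary")
#' cs$A %*% rep(1, 4)  # already balanced: every target met at W = 1
#' @export
build_conditions <- function(t, x, family, marginal = NULL,
                             projection_override = NULL) {
  family <- as_family(family)
  n <- length(t)
  x <- as_design(x, n)
  if (is.null(marginal)) marginal <- fit_marginal(t, family)
  if (!inherits(marginal, "caew_marginal")) {
    stop("'marginal' must be a caew_marginal object", call. = FALSE)
  }
  if (marginal$family$name != family$name) {
    stop("marginal fit is for family '", marginal$family$name,
         "' but conditions requested for '", family$name, "'", call. = FALSE)
  }
  if (!is.null(projection_override) &&
      !family$name %in% c("binary", "semicontinuous")) {
    stop("'projection_override' applies only to the binary component ",
         "(binary or semicontinuous families)", call. = FALSE)
  }

  blk <- condition_rows(t, x, family, marginal, projection_override)
  finish_conditions(blk$A, blk$labels, x, family, marginal,
                    projection_override)
}

## family-specific per-unit score rows (the Eq.-(2) block, without the sum
## row); returns list(A = K x n matrix, labels)
condition_rows <- function(t, x, family, marginal, projection_override) {
  cols <- colnames(x)
  rows <- list()
  labels <- character(0)
  add <- function(v, lab) {
    rows[[length(rows) + 1L]] <<- v
    labels[length(labels) + 1L] <<- lab
  }

  binary_rows <- function(ind, prefix) {
    pi0 <- if (!is.null(projection_override)) projection_override else
      marginal$pi0
    if (pi0 <= 0 || pi0 >= 1) {
      stop("projection probability must lie strictly in (0,1)", call. = FALSE)
    }
    resid <- ind - pi0
    for (j in seq_along(cols)) add(x[, j] * resid, paste0(prefix, cols[j]))
  }
  normal_rows <- function(value, member, mu0, s2) {
    ## 'member' masks units outside the continuous component (contribution 0)
    r <- ifelse(member, value - mu0, 0)
    for (j in seq_along(cols)) add(x[, j] * r / s2, paste0("mean:", cols[j]))
    vscore <- ifelse(member, -1 + r^2 / s2, 0)
    if (identical(family$structure, "B")) {
      add(vscore, "var:(Intercept)")
    } else {
      for (j in seq_along(cols)) add(x[, j] * vscore, paste0("var:", cols[j]))
    }
  }

  switch(family$name,
    binary = binary_rows(t, "binary:"),
    categorical = {
      lev <- names(marginal$probs)
      f <- factor(t, levels = lev)
      if (anyNA(f)) stop("treatment has categories absent from the marginal fit",
                         call. = FALSE)
      for (k in seq_along(lev)[-1L]) {
        resid <- (f == lev[k]) - marginal$probs[k]
        for (j in seq_along(cols)) {
          add(x[, j] * resid, paste0("cat[", lev[k], "]:", cols[j]))
        }
      }
    },
    normal = normal_rows(t, rep(TRUE, length(t)), marginal$mu0,
                         marginal$sigma0_sq),
    poisson = {
      resid <- t - marginal$lambda0
      for (j in seq_along(cols)) add(x[, j] * resid, paste0("poisson:", cols[j]))
    },
    semicontinuous = {
      member <- two_part_member(t)
      binary_rows(as.numeric(member), "binary:")
      gt <- rep(0, length(t))
      gt[member] <- g_fun(family$g)(t[member])
      normal_rows(gt, member, marginal$mu0, marginal$sigma0_sq)
    },
    stop("unsupported family: ", family$name, call. = FALSE)
  )
  list(A = do.call(rbind, rows), labels = labels)
}

## drop zero and linearly dependent rows, append the sum row, assemble object
finish_conditions <- function(A, labels, x, family, marginal,
                              projection_override, blk_b = NULL,
                              extra_A = NULL, extra_b = NULL,
                              extra_labels = NULL) {
  n <- ncol(A)
  if (is.null(blk_b)) blk_b <- rep(0, nrow(A))
  scale <- max(abs(A), 1)
  nonzero <- apply(abs(A), 1L, max) > 1e-12 * scale
  if (any(!nonzero)) {
    warning("dropping identically-zero constraint row(s): ",
            paste(labels[!nonzero], collapse = ", "), call. = FALSE)
    A <- A[nonzero, , drop = FALSE]
    labels <- labels[nonzero]
    blk_b <- blk_b[nonzero]
  }
  if (nrow(A) == 0L) {
    stop("unidentifiable conditions: every score row is degenerate",
         call. = FALSE)
  }

  b <- blk_b
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    b <- c(b, extra_b)
    labels <- c(labels, extra_labels)
  }
  sum_row <- rep(1, n)

  ## rank-revealing deduplication (sum row always retained, checked first)
  keep <- dedup_rows(rbind(sum_row, A), tol = 1e-10)
  if (!keep[1L]) stop("sum-to-n row unexpectedly degenerate", call. = FALSE)
  keep_blk <- keep[-1L]
  if (any(!keep_blk)) {
    message("dropping ", sum(!keep_blk),
            " linearly dependent constraint row(s) at tolerance 1e-10: ",
            paste(labels[!keep_blk], collapse = ", "))
    A <- A[keep_blk, , drop = FALSE]
    b <- b[keep_blk]
    labels <- labels[keep_blk]
  }
  if (nrow(A) == 0L) {
    stop("unidentifiable conditions: every score row is degenerate",
         call. = FALSE)
  }

  out <- list(A = rbind(A, sum = sum_row),
              b = c(b, n),
              row_labels = c(labels, "sum"),
              projection = marginal,
              projection_override = projection_override,
              family = family,
              design = x,
              n_units = n)
  class(out) <- "caew_conditions"
  out
}

## greedy full-row-rank subset in row order; rows pre-scaled to unit norm so
## the tolerance is scale-free
dedup_rows <- function(M, tol = 1e-10) {
  norms <- pmax(sqrt(rowSums(M^2)), 1e-300)
  Ms <- M / norms
  keep <- logical(nrow(M))
  basis <- NULL
  r <- 0L
  for (k in seq_len(nrow(M))) {
    cand <- rbind(basis, Ms[k, ])
    d <- svd(cand, nu = 0, nv = 0)$d
    if (sum(d > tol * d[1L]) > r) {
      keep[k] <- TRUE
      basis <- cand
      r <- r + 1L
    }
  }
  keep
}

#' @export
print.caew_conditions <- function(x, ...) {
  cat("CAEW constraint system: ", nrow(x$A), " rows x ", x$n_units,
      " units (family: ", x$family$name, ")\n", sep = "")
  cat("rows:", paste(x$row_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Pool per-interval score rows for a longitudinal panel
#'
#' For a time-varying treatment observed over (possibly unbalanced)
#' follow-up intervals, the weight constraints sum the per-unit-interval
#' score contributions over all units and intervals jointly, with one
#' decision variable per unit-interval.  The marginal (projection) model is
#' fitted to the pooled treatment values.  With a single interval per unit
#' the system reduces exactly to the cross-sectional one.
#'
#' @param panel a long-format `data.frame`, one row per unit-interval, or a
#'   list of per-interval data frames with identical columns.
#' @param family,marginal,projection_override as in [build_conditions()].
#' @param id,interval,treatment names of the unit-id, interval-index and
#'   treatment columns.
#' @param covariates character vector of covariate columns forming
#'   \eqn{\tilde X_{ij}}; default: every other column.
#'
#' @return A `"caew_conditions"` object over the `sum(m_i)` unit-intervals
#'   (the sum row targets the total number of unit-intervals); rows of the
#'   panel are carried in attribute `"panel_index"`.
#' @export
pool_longitudinal <- function(panel, family, marginal = NULL,
                              projection_override = NULL,
                              id = "id", interval = "interval",
                              treatment = "treatment", covariates = NULL) {
  if (is.list(panel) && !is.data.frame(panel)) {
    nms <- lapply(panel, names)
    if (length(panel) == 0L) stop("empty panel", call. = FALSE)
    if (!all(vapply(nms, identical, logical(1), nms[[1L]]))) {
      stop("inconsistent covariate columns across intervals", call. = FALSE)
    }
    panel <- do.call(rbind, panel)
  }
  if (!is.data.frame(panel) || nrow(panel) == 0L) {
    stop("empty panel", call. = FALSE)
  }
  needed <- c(id, interval, treatment)
  if (!all(needed %in% names(panel))) {
    stop("panel must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(covariates)) covariates <- setdiff(names(panel), needed)
  t <- panel[[treatment]]
  x <- if (length(covariates)) {
    design_matrix(as.matrix(panel[covariates]))
  } else {
    design_matrix(NULL, n = nrow(panel))
  }
  family <- as_family(family)
  if (is.null(marginal)) marginal <- fit_marginal(t, family)
  out <- build_conditions(t, x, family, marginal, projection_override)
  attr(out, "panel_index") <- panel[, c(id, interval)]
  out
}

#' Append target-population covariate-mean conditions
#'
#' Supplements the constraint system with rows forcing the weighted
#' covariate means to equal the covariate means `c` of a target population
#' (\eqn{\sum_i W_i \tilde X_i / n = c}), so that the weighted estimate
#' addresses that population rather than the sampled one.  Targets far
#' outside the convex hull of the observed covariates make the system
#' infeasible.
#'
#' @param system a `"caew_conditions"` object.
#' @param target_means numeric vector of target means, one per non-intercept
#'   column of the design matrix (matched by name if named).
#' @return The augmented `"caew_conditions"` object.
#' @export
append_target_population <- function(system, target_means) {
  stopifnot(inherits(system, "caew_conditions"))
  x <- system$design
  covs <- setdiff(colnames(x), "(Intercept)")
  if (length(target_means) != length(covs)) {
    stop("'target_means' must have length ", length(covs),
         " (one per non-intercept covariate)", call. = FALSE)
  }
  if (!is.null(names(target_means))) {
    if (!setequal(names(target_means), covs)) {
      stop("names of 'target_means' do not match covariate columns",
           call. = FALSE)
    }
    target_means <- target_means[covs]
  }
  n <- system$n_units
  K <- nrow(system$A)
  blk_A <- system$A[-K, , drop = FALSE]
  blk_b <- system$b[-K]
  extra_A <- t(x[, covs, drop = FALSE])
  extra_b <- n * as.numeric(target_means)
  finish_conditions(blk_A, system$row_labels[-K], x, system$family,
                    system$projection, system$projection_override,
                    blk_b = blk_b,
                    extra_A = extra_A, extra_b = extra_b,
                    extra_labels = paste0("target:", covs))
}

#' Write a constraint system to delimited text plus a JSON sidecar
#'
#' @param system a `"caew_conditions"` object.
#' @param matrix_path path for the tab-delimited constraint matrix, one row
#'   per constraint with the target in the final column.
#' @param json_path path for the JSON sidecar (row labels, family, projection
#'   parameters).
#' @return `invisible(system)`.
#' @export
write_conditions <- function(system, matrix_path, json_path) {
  stopifnot(inherits(system, "caew_conditions"))
  utils::write.table(cbind(system$A, target = system$b), matrix_path,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  side <- list(row_labels = system$row_labels,
               family = system$family$name,
               structure = system$family$structure,
               g = system$family$g,
               n_units = system$n_units,
               projection = jsonlite::fromJSON(marginal_to_json(system$projection)))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              na = "null"), json_path)
  invisible(system)
}
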