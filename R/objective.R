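# Restraint objective and its analytic gradient with respect to the free
# cell parameters.
#
# Primary ("squared") form:    total = sum_R (1/sigma_R^2) (d_R^2 - Delta_R^2)^2
# Least-squares form:          total = sum_R (1/sigma_R^2) (d_R - Delta_R)^2
# with d_R^2 = dx' G(cell) dx for the fractional difference dx of the
# restrained pair. Both forms share their minimum along any one-parameter
# family for a single restraint; the squared form avoids the modulus and has
# simpler derivatives. The hill-climb fitting criterion is the weighted mean
# absolute deviation sum w_R |d_R - Delta_R| / sum w_R with w_R = 1/sigma_R.

.restraint_dx <- function(structure) {
  r <- structure$restraints
  a <- structure$atoms
  cbind(a$x[r$atom1] - a$x[r$atom2],
        a$y[r$atom1] - a$y[r$atom2],
        a$z[r$atom1] - a$z[r$atom2])
}

# fast path for optimizer inner loops: totals only, no report table
.residual_quick <- function(structure, cell, form = "squared") {
  r <- structure$restraints
  G <- metric_tensor(cell)
  dx <- .restraint_dx(structure)
  d2 <- rowSums((dx %*% G) * dx)
  d <- sqrt(d2)
  total <- if (form == "squared") sum((d2 - r$target^2)^2 / r$sigma^2)
           else sum((d - r$target)^2 / r$sigma^2)
  w <- 1 / r$sigma
  list(total = total, wmad = sum(w * abs(d - r$target)) / sum(w))
}

#' Restraint residual of a structure under a trial cell
#'
#' Recomputes every restrained inter-atomic distance from the structure's
#' fixed fractional coordinates under `cell` and scores the discrepancy
#' against the restraint targets.
#'
#' @param structure A `"shelx_structure"` with at least one restraint.
#' @param cell Trial [unit_cell()]; defaults to the structure's own cell.
#' @param form Objective form: `"squared"` (default) uses
#'   \eqn{\sum \sigma^{-2} (d^2-\Delta^2)^2}; `"least_squares"` uses
#'   \eqn{\sum \sigma^{-2} (d-\Delta)^2}.
#' @return A list of class `"cell_objective"`: `total` (dimensionless
#'   weighted residual), `weighted_mean_abs_dev` (angstroms; weights
#'   \eqn{1/\sigma}), and `per_restraint`, a data frame with the current
#'   distance `d`, signed deviation `d - target` in angstroms, and each
#'   restraint's weighted `contribution` to `total`.
#' @export
cell_residual <- function(structure, cell = structure$cell,
                          form = c("squared", "least_squares")) {
  form <- match.arg(form)
  stopifnot(inherits(structure, "shelx_structure"))
  r <- structure$restraints
  if (nrow(r) == 0)
    stop("nothing to optimize: the structure carries no DFIX/DANG restraints")
  validate_cell(cell)
  G <- metric_tensor(cell)
  dx <- .restraint_dx(structure)
  d2 <- rowSums((dx %*% G) * dx)
  d <- sqrt(d2)
  contrib <- if (form == "squared") (d2 - r$target^2)^2 / r$sigma^2
             else (d - r$target)^2 / r$sigma^2
  w <- 1 / r$sigma
  out <- list(
    total = sum(contrib),
    weighted_mean_abs_dev = sum(w * abs(d - r$target)) / sum(w),
    form = form,
    per_restraint = data.frame(
      restraint = seq_len(nrow(r)),
      atom1 = structure$atoms$name[r$atom1],
      atom2 = structure$atoms$name[r$atom2],
      kind = r$kind, target = r$target, sigma = r$sigma,
      d = d, deviation = d - r$target, contribution = contrib,
      stringsAsFactors = FALSE))
  class(out) <- "cell_objective"
  out
}

#' @export
print.cell_objective <- function(x, ...) {
  cat(sprintf("restraint objective (%s form): total = %.6g, weighted mean |dev| = %.5f A over %d restraints\n",
              x$form, x$total, x$weighted_mean_abs_dev, nrow(x$per_restraint)))
  invisible(x)
}

#' Analytic gradient of the restraint residual over free cell parameters
#'
#' Chain rule through the metric tensor:
#' \eqn{\partial d^2/\partial\tau = \Delta x^\top (\partial G/\partial\tau)
#' \Delta x}, composed with the crystal system's constraint map — tied
#' parameters accumulate their partials, fixed parameters are absent. Angle
#' components are per degree, matching the external free-vector units.
#'
#' @inheritParams cell_residual
#' @param system A [crystal_system()] (or its name).
#' @return Named numeric vector of length `system$free_parameter_count`.
#' @export
cell_gradient <- function(structure, cell = structure$cell, system = "triclinic",
                          form = c("squared", "least_squares")) {
  form <- match.arg(form)
  system <- crystal_system(system)
  r <- structure$restraints
  if (nrow(r) == 0)
    stop("nothing to optimize: the structure carries no DFIX/DANG restraints")
  validate_cell(cell)
  G <- metric_tensor(cell)
  dG <- metric_tensor_grad(cell)
  dx <- .restraint_dx(structure)
  d2 <- rowSums((dx %*% G) * dx)
  # d(total)/d(d2) per restraint
  dtot_dd2 <- if (form == "squared") 2 * (d2 - r$target^2) / r$sigma^2
              else (1 - r$target / sqrt(d2)) / r$sigma^2
  raw <- vapply(names(dG), function(p) {
    dd2 <- rowSums((dx %*% dG[[p]]) * dx)
    sum(dtot_dd2 * dd2)
  }, numeric(1))
  # fold the full six-parameter gradient onto the system's free variables
  g <- stats::setNames(raw[system$free], system$free)
  for (tied in names(system$ties)) {
    anchor <- system$ties[[tied]]
    if (anchor %in% names(g)) g[[anchor]] <- g[[anchor]] + raw[[tied]]
  }
  g
}

#' Per-restraint deviation report
#'
#' Signed geometry deviations `d - target` in angstroms for every
#' restraint, as a plain data frame; optionally written as a
#' tab-delimited table.
#'
#' @inheritParams cell_residual
#' @param path Optional output path for a tab-separated file.
#' @return The per-restraint data frame, invisibly when `path` is given.
#' @export
deviation_report <- function(structure, cell = structure$cell,
                             form = c("squared", "least_squares"),
                             path = NULL) {
  tab <- cell_residual(structure, cell, form)$per_restraint
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
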