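#' Fit unit-cell parameters to geometric distance restraints
#'
#' The main entry point. Reads (or takes) a SHELX structure model carrying
#' DFIX/DANG distance restraints and refines the unit-cell parameters —
#' under the declared crystal system's lattice constraints — so that the
#' inter-atomic distances recomputed from the fixed fractional coordinates
#' best match the restraint targets. Electron-diffraction models are the
#' motivating case: their short wavelength couples the cell strongly with
#' the detector distance, so cells are often systematically off while the
#' fractional model is good.
#'
#' With `iterate = TRUE` the cell optimization alternates with a
#' coordinate-refinement step (by default the internal restraint-only
#' regularizer; an external refiner command can be supplied), capped at
#' `max_iter` alternations.
#'
#' @param input A `"shelx_structure"` (from [read_res()]/[parse_res()]) or a
#'   path to a RES/INS file.
#' @param system Crystal system name (default `"triclinic"`, i.e. all six
#'   parameters free — the P1 relaxation). The starting cell must satisfy
#'   the system's constraints exactly.
#' @param driver `"bfgs"` (gradient-based, default) or `"hillclimb"`.
#' @param form Objective form, see [cell_residual()].
#' @param iterate Alternate with coordinate refinement?
#' @param refiner Coordinate-refinement hook used when `iterate = TRUE`;
#'   see [iterate_cell()]. Default `"internal"`.
#' @param max_iter Alternation cap (default 25).
#' @param ... Further arguments to the driver ([optimize_cell_bfgs()] /
#'   [optimize_cell_hillclimb()]).
#' @return An object of class `"cellfit"` with components `cell` (optimized
#'   [unit_cell()]), `start_cell`, `system`, `structure` (final model),
#'   `trace` (`"cell_trace"`), `converged`, `termination_reason`, and the
#'   initial/final objective summaries. Methods: [print.cellfit()],
#'   [summary.cellfit()], [coef.cellfit()], [residuals.cellfit()],
#'   [fitted.cellfit()], [predict.cellfit()], [plot.cellfit()].
#' @examples
#' fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30),
#'                        molecule = "tetrahedral", seed = 7)
#' fit <- cellfit(fx$structure, system = "orthorhombic")
#' coef(fit)          # close to the generating 10, 20, 30 cell
#' summary(fit)
#' @export
cellfit <- function(input, system = "triclinic",
                    driver = c("bfgs", "hillclimb"),
                    form = c("squared", "least_squares"),
                    iterate = FALSE, refiner = "internal",
                    max_iter = 25L, ...) {
  driver <- match.arg(driver)
  form <- match.arg(form)
  system <- crystal_system(system)
  structure <- if (is.character(input)) read_res(input) else input
  if (!inherits(structure, "shelx_structure"))
    stop("input must be a shelx_structure or a path to a RES/INS file")
  if (nrow(structure$restraints) == 0)
    stop("nothing to optimize: the structure carries no DFIX/DANG restraints")

  start_cell <- structure$cell
  obj0 <- cell_residual(structure, form = form)

  if (iterate) {
    res <- iterate_cell(structure, system, driver = driver,
                        refiner = refiner, max_iter = max_iter,
                        form = form, ...)
    final_structure <- res$structure
    trace <- res$trace
  } else {
    res <- if (driver == "bfgs")
      optimize_cell_bfgs(structure, system, form = form, ...)
    else
      optimize_cell_hillclimb(structure, system, form = form, ...)
    final_structure <- set_cell(structure, res$cell)
    trace <- res$trace
  }

  obj1 <- cell_residual(final_structure, form = form)
  out <- list(cell = final_structure$cell, start_cell = start_cell,
              system = system, driver = driver, form = form,
              structure = final_structure, trace = trace,
              converged = trace$converged,
              termination_reason = trace$termination_reason,
              objective_start = obj0, objective_final = obj1)
  class(out) <- "cellfit"
  out
}

#' @export
print.cellfit <- function(x, digits = 4, ...) {
  cat(sprintf("cell optimization against %d distance restraints (%s system, %s driver)\n",
              nrow(x$structure$restraints), x$system$name, x$driver))
  cat("start:     "); print(x$start_cell, digits = digits)
  cat("optimized: "); print(x$cell, digits = digits)
  cat(sprintf("objective %.6g -> %.6g; weighted mean |dev| %.5f -> %.5f A; %s\n",
              x$objective_start$total, x$objective_final$total,
              x$objective_start$weighted_mean_abs_dev,
              x$objective_final$weighted_mean_abs_dev,
              if (x$converged) "converged" else
                paste0("NOT converged (", x$termination_reason, ")")))
  invisible(x)
}

#' Summarize a cell fit
#'
#' @param object A `"cellfit"`.
#' @param ... Unused.
#' @return A list of class `"summary.cellfit"` with the cell before/after,
#'   parameter shifts, and deviation statistics of the restraints.
#' @export
summary.cellfit <- function(object, ...) {
  dev <- object$objective_final$per_restraint$deviation
  shifts <- unclass(object$cell) - unclass(object$start_cell)
  out <- list(fit = object,
              shifts = shifts,
              dev_stats = c(mean_abs = mean(abs(dev)),
                            rms = sqrt(mean(dev^2)),
                            max_abs = max(abs(dev))),
              worst = utils::head(
                object$objective_final$per_restraint[
                  order(-abs(dev)), , drop = FALSE], 5))
  class(out) <- "summary.cellfit"
  out
}

#' @export
print.summary.cellfit <- function(x, ...) {
  print(x$fit)
  cat("\nparameter shifts:\n")
  print(round(x$shifts, 5))
  cat(sprintf("\nrestraint deviations (A): mean |dev| %.5f, rms %.5f, max |dev| %.5f\n",
              x$dev_stats[["mean_abs"]], x$dev_stats[["rms"]],
              x$dev_stats[["max_abs"]]))
  cat("\nworst restraints:\n")
  print(x$worst, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cellfit <- function(object, ...) {
  stats::setNames(as.numeric(object$cell),
                  c("a", "b", "c", "alpha", "beta", "gamma"))
}

#' Signed restraint residuals of a cell fit
#'
#' @param object A `"cellfit"`.
#' @param ... Unused.
#' @return Numeric vector of signed deviations `d - target` (angstroms),
#'   one per restraint, under the optimized cell.
#' @export
residuals.cellfit <- function(object, ...) {
  object$objective_final$per_restraint$deviation
}

#' @export
fitted.cellfit <- function(object, ...) {
  object$objective_final$per_restraint$d
}

#' Predict inter-atomic distances under the optimized cell
#'
#' @param object A `"cellfit"`.
#' @param pairs Two-column matrix (or data frame) of atom names or indices;
#'   defaults to the restrained pairs.
#' @param ... Unused.
#' @return Numeric vector of distances in angstroms.
#' @export
predict.cellfit <- function(object, pairs = NULL, ...) {
  s <- object$structure
  if (is.null(pairs))
    pairs <- cbind(s$restraints$atom1, s$restraints$atom2)
  pairs <- as.matrix(pairs)
  to_idx <- function(v) {
    if (is.numeric(v)) return(as.integer(v))
    i <- match(toupper(v), s$atoms$name)
    if (anyNA(i)) stop(sprintf("unknown atom name: %s",
                               paste(v[is.na(i)], collapse = ", ")))
    i
  }
  i1 <- to_idx(pairs[, 1]); i2 <- to_idx(pairs[, 2])
  vapply(seq_along(i1), function(k)
    frac_distance(object$cell,
                  c(s$atoms$x[i1[k]], s$atoms$y[i1[k]], s$atoms$z[i1[k]]),
                  c(s$atoms$x[i2[k]], s$atoms$y[i2[k]], s$atoms$z[i2[k]])),
    numeric(1))
}

#' Plot the optimization trace of a cell fit
#'
#' Convergence diagnostics: cell lengths, cell angles (when free), and the
#' objective on a log scale, against the recorded optimization steps.
#'
#' @param x A `"cellfit"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.cellfit <- function(x, ...) {
  tr <- x$trace$iterations
  op <- graphics::par(mfrow = c(1 + any(c("alpha", "beta", "gamma") %in%
                                          x$system$free), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tr$iteration, tr[, c("a", "b", "c")], type = "l", lty = 1,
                    xlab = "step", ylab = "length (A)", main = "cell lengths", ...)
  graphics::legend("topright", legend = c("a", "b", "c"), col = 1:3, lty = 1,
                   bty = "n")
  pos <- tr$objective > 0
  graphics::plot(tr$iteration[pos], tr$objective[pos], type = "b", log = "y",
                 xlab = "step", ylab = "objective", main = "restraint residual")
  if (any(c("alpha", "beta", "gamma") %in% x$system$free)) {
    graphics::matplot(tr$iteration, tr[, c("alpha", "beta", "gamma")],
                      type = "l", lty = 1, xlab = "step", ylab = "angle (deg)",
                      main = "cell angles")
    graphics::legend("topright", legend = c("alpha", "beta", "gamma"),
                     col = 1:3, lty = 1, bty = "n")
    graphics::plot(tr$iteration, tr$mean_abs_dev, type = "b", xlab = "step",
                   ylab = "weighted mean |dev| (A)", main = "fit criterion")
  }
  invisible(x)
}
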