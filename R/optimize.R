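# Minimization drivers over the free cell parameters, and the iterative
# alternation between cell optimization and coordinate refinement.

.trace_row <- function(iteration, cell, total, wmad, step = "", score = NA_real_) {
  data.frame(iteration = iteration,
             a = cell[["a"]], b = cell[["b"]], c = cell[["c"]],
             alpha = cell[["alpha"]], beta = cell[["beta"]], gamma = cell[["gamma"]],
             objective = total, mean_abs_dev = wmad,
             step = step, refiner_score = score,
             stringsAsFactors = FALSE)
}

.new_trace <- function(rows, converged, reason) {
  structure(list(iterations = rows, converged = converged,
                 termination_reason = reason),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  n <- nrow(x$iterations)
  cat(sprintf("optimization trace: %d recorded step%s, %s (%s)\n",
              n, if (n == 1) "" else "s",
              if (x$converged) "converged" else "not converged",
              x$termination_reason))
  if (n > 0) {
    cat(sprintf("  objective %.6g -> %.6g, weighted mean |dev| %.5f -> %.5f A\n",
                x$iterations$objective[1], x$iterations$objective[n],
                x$iterations$mean_abs_dev[1], x$iterations$mean_abs_dev[n]))
  }
  invisible(x)
}

#' Write a per-iteration CSV log from a trace
#'
#' Machine-readable convergence log: one row per recorded step with the six
#' cell parameters, objective, weighted mean absolute deviation and any
#' external refiner score.
#'
#' @param trace A `"cell_trace"`.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cell_trace"))
  utils::write.csv(trace$iterations, path, row.names = FALSE, quote = FALSE)
  invisible(trace$iterations)
}

# objective closure over the free vector; invalid trial cells score a large
# finite penalty so line searches back off rather than crash
.make_objective <- function(structure, system, form) {
  function(free) {
    cell <- tryCatch(cs_constrain(system, free), error = function(e) NULL)
    if (is.null(cell)) return(1e30)
    .residual_quick(structure, cell, form)$total
  }
}

.grad_norm <- function(g) sqrt(sum(g^2))

#' Optimize the unit cell with BFGS
#'
#' Gradient-based minimization of the restraint residual over the crystal
#' system's free parameters, using the BFGS quasi-Newton method
#' ([stats::optim()]) with the package's analytic gradient, followed by a
#' damped Newton polish until the gradient norm falls below `grad_tol`.
#' Only a local minimum is guaranteed.
#'
#' @param structure A `"shelx_structure"` with at least one restraint; its
#'   stored cell is the starting point and must conform to `system`.
#' @param system A [crystal_system()] or its name.
#' @param step Initial parameter scale passed to the line search
#'   (`parscale`); the default 0.01 is safe for cells in the usual 5-50
#'   angstrom range.
#' @param grad_tol Gradient-norm convergence tolerance (default `1e-6`).
#' @param form Objective form, see [cell_residual()].
#' @param max_iter Iteration cap for the BFGS stage.
#' @return List with `cell` (the optimized [unit_cell()]) and `trace`
#'   (a `"cell_trace"`; the accepted, monotonically improving evaluations).
#'   Optimizer failure is surfaced via `trace$termination_reason` together
#'   with the best cell seen, never as an error.
#' @export
optimize_cell_bfgs <- function(structure, system, step = 0.01,
                               grad_tol = 1e-6,
                               form = c("squared", "least_squares"),
                               max_iter = 500L) {
  form <- match.arg(form)
  system <- crystal_system(system)
  free0 <- cs_free_vector(system, structure$cell)   # errors if non-conforming
  fn <- .make_objective(structure, system, form)
  gr <- function(free) {
    cell <- tryCatch(cs_constrain(system, free), error = function(e) NULL)
    if (is.null(cell)) return(rep(0, length(free)))
    cell_gradient(structure, cell, system, form)
  }

  log_env <- new.env(parent = emptyenv())
  log_env$free <- list(); log_env$val <- numeric(0)
  fn_logged <- function(free) {
    v <- fn(free)
    log_env$free[[length(log_env$free) + 1L]] <- free
    log_env$val <- c(log_env$val, v)
    v
  }

  res <- stats::optim(free0, fn_logged, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-15,
                                     parscale = rep(step / 0.01, length(free0))))
  best <- res$par
  # damped Newton polish: optim has no gradient-norm stop of its own
  for (k in seq_len(60L)) {
    g <- gr(best)
    if (.grad_norm(g) < grad_tol) break
    H <- .fd_jacobian(gr, best)
    H <- (H + t(H)) / 2
    dirn <- tryCatch(-solve(H, g), error = function(e) -g)
    if (!all(is.finite(dirn)) || sum(dirn * g) > 0) dirn <- -g
    f0 <- fn(best); t_step <- 1
    repeat {
      cand <- best + t_step * dirn
      if (fn(cand) < f0 + 1e-12) { best <- cand; break }
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    if (t_step < 1e-14) break
  }

  gfin <- .grad_norm(gr(best))
  reason <- if (gfin < grad_tol) "gradient_tolerance"
            else if (res$convergence == 1) "max_iterations"
            else "step_exhausted"
  cell <- cs_constrain(system, best)

  # accepted (monotone) subsequence of the logged evaluations, plus the
  # polished endpoint
  rows <- .trace_row(0L, cs_constrain(system, free0), fn(free0),
                     cell_residual(structure, cs_constrain(system, free0), form)$weighted_mean_abs_dev,
                     step = "start")
  bestv <- rows$objective[1]; it <- 0L
  for (i in seq_along(log_env$val)) {
    if (log_env$val[i] < bestv) {
      bestv <- log_env$val[i]
      it <- it + 1L
      ci <- tryCatch(cs_constrain(system, log_env$free[[i]]), error = function(e) NULL)
      if (!is.null(ci))
        rows <- rbind(rows, .trace_row(it, ci, log_env$val[i],
                                       cell_residual(structure, ci, form)$weighted_mean_abs_dev,
                                       step = "bfgs"))
    }
  }
  ores <- cell_residual(structure, cell, form)
  if (ores$total <= bestv + 1e-30)
    rows <- rbind(rows, .trace_row(it + 1L, cell, ores$total,
                                   ores$weighted_mean_abs_dev, step = "polish"))
  list(cell = cell,
       trace = .new_trace(rows, gfin < grad_tol, reason))
}

# central finite-difference Jacobian of a vector-valued function
.fd_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    hp <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hp
    xm <- x; xm[i] <- x[i] - hp
    J[, i] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}

#' Optimize the unit cell by multi-level hill climbing
#'
#' Systematically modifies each free cell parameter by plus/minus the
#' current step (initially 0.1 angstroms for lengths and 0.1 degrees for
#' angles), scores each trial cell by the weighted mean absolute deviation
#' from the restraints, and keeps only the single modification with the
#' largest improvement per round. When a full round over all free
#' parameters yields no improvement, the step size is halved; the process
#' aborts after `abort_cycles` consecutive improvement-free cycles.
#' Tie-breaks are deterministic: parameter order a, b, c, alpha, beta,
#' gamma, and `+` before `-`.
#'
#' @inheritParams optimize_cell_bfgs
#' @param initial_step Starting modification step (0.1 angstroms / degrees).
#' @param abort_cycles Consecutive improvement-free rounds (halvings
#'   included) before termination; default 10.
#' @param criterion Fitting criterion scored when comparing trial cells:
#'   `"wmad"` (weighted mean absolute deviation, the default) or
#'   `"objective"` (the squared-form total; lets the two drivers share a
#'   common criterion).
#' @param max_rounds Safety cap on proposal rounds. Single-parameter
#'   coordinate descent can crawl along narrow diagonal valleys of the
#'   criterion; when the cap is hit the best cell so far is returned with
#'   `termination_reason = "step_exhausted"`.
#' @return List with `cell` and `trace`, as for [optimize_cell_bfgs()];
#'   the trace records every accepted modification.
#' @export
optimize_cell_hillclimb <- function(structure, system, initial_step = 0.1,
                                    abort_cycles = 10L,
                                    form = c("squared", "least_squares"),
                                    criterion = c("wmad", "objective"),
                                    max_rounds = 20000L) {
  form <- match.arg(form)
  criterion <- match.arg(criterion)
  system <- crystal_system(system)
  free <- cs_free_vector(system, structure$cell)
  score_of <- function(free) {
    cell <- tryCatch(cs_constrain(system, free), error = function(e) NULL)
    if (is.null(cell)) return(Inf)
    o <- .residual_quick(structure, cell, form)
    if (criterion == "wmad") o$wmad else o$total
  }
  cur <- score_of(free)
  cell0 <- cs_constrain(system, free)
  o0 <- cell_residual(structure, cell0, form)
  rows <- .trace_row(0L, cell0, o0$total, o0$weighted_mean_abs_dev, step = "start")

  step <- initial_step
  no_improve <- 0L
  it <- 0L
  rounds <- 0L
  while (no_improve < abort_cycles && rounds < max_rounds) {
    rounds <- rounds + 1L
    # strict improvement, with a relative epsilon so floating-point
    # near-ties (e.g. symmetric overshoot) never count as improvements
    eps <- 1e-9 * max(abs(cur), 1e-12)
    cand_i <- integer(0); cand_s <- numeric(0); cand_sc <- numeric(0)
    for (i in seq_along(free)) {
      for (s in c(step, -step)) {       # "+" before "-", a before b ...
        cand <- free; cand[i] <- cand[i] + s
        sc <- score_of(cand)
        if (sc < cur - eps) {
          cand_i <- c(cand_i, i); cand_s <- c(cand_s, s)
          cand_sc <- c(cand_sc, sc)
        }
      }
    }
    best_i <- 0L; best_s <- NA_real_; best_score <- cur; best_lab <- ""
    if (length(cand_i) > 0) {
      # largest improvement wins; improvements within eps are tied and the
      # first candidate in parameter order takes precedence
      k <- which(cand_sc <= min(cand_sc) + eps)[1]
      best_i <- cand_i[k]; best_s <- cand_s[k]; best_score <- cand_sc[k]
      best_lab <- sprintf("%s%+g", system$free[best_i], best_s)
    }
    if (best_i > 0L) {
      free[best_i] <- free[best_i] + best_s
      cur <- best_score
      no_improve <- 0L
      it <- it + 1L
      cell_i <- cs_constrain(system, free)
      oi <- cell_residual(structure, cell_i, form)
      rows <- rbind(rows, .trace_row(it, cell_i, oi$total,
                                     oi$weighted_mean_abs_dev, step = best_lab))
    } else {
      step <- step / 2
      no_improve <- no_improve + 1L
    }
  }
  finished <- no_improve >= abort_cycles
  list(cell = cs_constrain(system, free),
       trace = .new_trace(rows, finished,
                          if (finished) "no_improvement" else "step_exhausted"))
}

#' Regularize atomic coordinates against the restraints
#'
#' Minimizes the restraint residual over the fractional coordinates of the
#' restrained atoms with the cell held fixed — a restraint-only coordinate
#' refinement used as the internal fallback for the alternating iteration
#' (an external refiner fitting diffraction data can be plugged in
#' instead). Atoms appearing in no restraint are untouched. Since the
#' objective is invariant under rigid translation, the net translation is
#' removed afterwards: the centroid of the restrained atoms is preserved.
#'
#' @inheritParams cell_residual
#' @return The structure with updated fractional coordinates.
#' @export
regularize_coordinates <- function(structure, cell = structure$cell,
                                   form = c("squared", "least_squares")) {
  form <- match.arg(form)
  r <- structure$restraints
  if (nrow(r) == 0)
    stop("nothing to optimize: the structure carries no DFIX/DANG restraints")
  validate_cell(cell)
  G <- metric_tensor(cell)
  idx <- sort(unique(c(r$atom1, r$atom2)))
  pos <- match(seq_len(nrow(structure$atoms)), idx)   # atom -> free slot

  pack <- function(at) as.numeric(t(as.matrix(at[idx, c("x", "y", "z")])))
  x0 <- pack(structure$atoms)
  coords_of <- function(p) matrix(p, ncol = 3, byrow = TRUE)

  fn <- function(p) {
    xyz <- coords_of(p)
    dx <- xyz[pos[r$atom1], , drop = FALSE] - xyz[pos[r$atom2], , drop = FALSE]
    d2 <- rowSums((dx %*% G) * dx)
    if (form == "squared") sum((d2 - r$target^2)^2 / r$sigma^2)
    else sum((sqrt(d2) - r$target)^2 / r$sigma^2)
  }
  gr <- function(p) {
    xyz <- coords_of(p)
    dx <- xyz[pos[r$atom1], , drop = FALSE] - xyz[pos[r$atom2], , drop = FALSE]
    Gdx <- dx %*% G
    d2 <- rowSums(Gdx * dx)
    coef <- if (form == "squared") 2 * (d2 - r$target^2) / r$sigma^2
            else (1 - r$target / sqrt(d2)) / r$sigma^2
    g <- matrix(0, nrow = length(idx), ncol = 3)
    contrib <- 2 * coef * Gdx
    for (k in seq_len(nrow(r))) {
      i1 <- pos[r$atom1[k]]; i2 <- pos[r$atom2[k]]
      g[i1, ] <- g[i1, ] + contrib[k, ]
      g[i2, ] <- g[i2, ] - contrib[k, ]
    }
    as.numeric(t(g))
  }

  res <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-15))
  xyz <- coords_of(res$par)
  # gauge fix: restore the centroid of the restrained atoms
  shift <- colMeans(coords_of(x0)) - colMeans(xyz)
  xyz <- sweep(xyz, 2, shift, "+")
  structure$atoms$x[idx] <- xyz[, 1]
  structure$atoms$y[idx] <- xyz[, 2]
  structure$atoms$z[idx] <- xyz[, 3]
  structure
}

#' Alternate cell optimization and coordinate refinement
#'
#' Step (1) optimizes the unit-cell parameters at fixed fractional
#' coordinates; step (2) refines the coordinates at the fixed new cell.
#' The alternation stops when the cell change between successive
#' iterations falls below tolerance (`1e-4` angstroms on lengths, `1e-3`
#' degrees on angles) or after `max_iter` iterations (default 25).
#'
#' @inheritParams optimize_cell_bfgs
#' @param driver `"bfgs"` or `"hillclimb"`.
#' @param refiner Coordinate-refinement hook for step (2):
#'   `NULL` (single-shot cell optimization, no alternation),
#'   `"internal"` (the restraint-only [regularize_coordinates()]),
#'   a function `function(structure, cell) -> structure`, or an external
#'   command template containing `{in}` and `{out}` placeholders — the
#'   current model is written as a RES file to `{in}`, the command run, and
#'   `{out}` re-parsed; a nonzero exit or missing/unparseable output stops
#'   the iteration with a partial trace (reported, not swallowed). An
#'   external refiner may append `REM CELLFIT_SCORE <x>` to its output to
#'   report a score that is logged per iteration.
#' @param max_iter Iteration cap for the alternation (default 25).
#' @param tol_len,tol_ang Cell-change convergence tolerances.
#' @param ... Passed on to the driver.
#' @return List with `structure` (final model), `cell` and `trace`; the
#'   trace holds one record per alternation iteration.
#' @export
iterate_cell <- function(structure, system, driver = c("bfgs", "hillclimb"),
                         refiner = NULL, max_iter = 25L,
                         tol_len = 1e-4, tol_ang = 1e-3,
                         form = c("squared", "least_squares"), ...) {
  driver <- match.arg(driver)
  form <- match.arg(form)
  system <- crystal_system(system)
  drive <- function(s) {
    if (driver == "bfgs") optimize_cell_bfgs(s, system, form = form, ...)
    else optimize_cell_hillclimb(s, system, form = form, ...)
  }
  rows <- NULL
  converged <- FALSE
  reason <- "max_iterations"
  prev_cell <- structure$cell

  for (it in seq_len(max_iter)) {
    step1 <- drive(structure)
    structure <- set_cell(structure, step1$cell)
    score <- NA_real_
    if (!is.null(refiner)) {
      ref <- tryCatch(.apply_refiner(structure, refiner, form),
                      error = function(e) e)
      if (inherits(ref, "error")) {
        o <- cell_residual(structure, form = form)
        rows <- rbind(rows, .trace_row(it, structure$cell, o$total,
                                       o$weighted_mean_abs_dev, step = driver))
        warning(sprintf("iteration %d: coordinate refiner failed: %s",
                        it, conditionMessage(ref)))
        return(list(structure = structure, cell = structure$cell,
                    trace = .new_trace(rows, FALSE, "refiner_error")))
      }
      structure <- ref$structure
      score <- ref$score
    }
    o <- cell_residual(structure, form = form)
    rows <- rbind(rows, .trace_row(it, structure$cell, o$total,
                                   o$weighted_mean_abs_dev,
                                   step = driver, score = score))
    if (is.null(refiner)) { converged <- step1$trace$converged
                            reason <- step1$trace$termination_reason
                            break }
    dlen <- max(abs(unlist(structure$cell[c("a", "b", "c")]) -
                      unlist(prev_cell[c("a", "b", "c")])))
    dang <- max(abs(unlist(structure$cell[c("alpha", "beta", "gamma")]) -
                      unlist(prev_cell[c("alpha", "beta", "gamma")])))
    if (it > 1 && dlen < tol_len && dang < tol_ang) {
      converged <- TRUE
      reason <- "cell_tolerance"
      break
    }
    prev_cell <- structure$cell
  }
  list(structure = structure, cell = structure$cell,
       trace = .new_trace(rows, converged, reason))
}

.apply_refiner <- function(structure, refiner, form) {
  if (is.function(refiner))
    return(list(structure = refiner(structure, structure$cell), score = NA_real_))
  if (identical(refiner, "internal"))
    return(list(structure = regularize_coordinates(structure, form = form),
                score = NA_real_))
  if (is.character(refiner) && length(refiner) == 1L) {
    fin <- tempfile(fileext = ".res"); fout <- tempfile(fileext = ".res")
    write_res(structure, new_cell = structure$cell, path = fin)
    cmd <- gsub("{in}", fin, gsub("{out}", fout, refiner, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop(sprintf("external refiner exited with status %d", status))
    if (!file.exists(fout)) stop("external refiner produced no output file")
    txt <- readLines(fout, warn = FALSE)
    refined <- parse_res(txt)
    score <- NA_real_
    m <- grep("^REM CELLFIT_SCORE ", txt, value = TRUE)
    if (length(m) > 0)
      score <- suppressWarnings(as.numeric(sub("^REM CELLFIT_SCORE ", "", m[1])))
    return(list(structure = refined, score = score))
  }
  stop("refiner must be NULL, \"internal\", a function, or a command template")
}
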