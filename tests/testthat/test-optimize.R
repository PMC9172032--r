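test_that("BFGS solves the cubic scaling family in closed form", {
  # single restraint between (0,0,0) and (t,0,0): minimum at a = Delta/t
  for (a0 in c(3, 7, 12, 40)) {
    s <- single_restraint_res(a = a0, t = 0.2, target = 1.5)
    fit <- optimize_cell_bfgs(s, "cubic")
    expect_equal(fit$cell[["a"]], 1.5 / 0.2, tolerance = 1e-8)
    expect_true(fit$trace$converged)
    expect_identical(fit$trace$termination_reason, "gradient_tolerance")
  }
})

test_that("starting at the optimum is a fixed point for both drivers", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 4, cell_perturbation = 0)
  fb <- optimize_cell_bfgs(fx$structure, "orthorhombic")
  expect_equal(unclass(fb$cell), unclass(fx$true_cell), tolerance = 1e-10)
  fh <- optimize_cell_hillclimb(fx$structure, "orthorhombic")
  # zero accepted modifications: the trace holds only the start record
  expect_equal(nrow(fh$trace$iterations), 1)
  expect_identical(unclass(fh$cell), unclass(fx$true_cell))
  expect_identical(fh$trace$termination_reason, "no_improvement")
})

test_that("BFGS recovers a 5%-perturbed orthorhombic cell to 1e-3 A", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 17, cell_perturbation = 0.05)
  fit <- optimize_cell_bfgs(fx$structure, "orthorhombic")
  expect_lt(max(abs(unclass(fit$cell)[1:3] - c(10, 20, 30))), 1e-3)
})

test_that("a non-conforming starting cell is rejected", {
  s <- single_restraint_res(a = 7)
  s$cell <- unit_cell(7, 7.1, 7)
  expect_error(optimize_cell_bfgs(s, "cubic"), "conform|differs")
  expect_error(optimize_cell_hillclimb(s, "cubic"), "conform|differs")
})

test_that("hill climbing follows the documented step schedule", {
  # one free parameter offset by exactly -0.35: three +0.1 steps are
  # accepted, a fourth overshoots symmetrically (no strict improvement),
  # the step halves and +0.05 lands exactly on the optimum
  s <- single_restraint_res(a = 7.5 - 0.35, t = 0.2, target = 1.5)
  fit <- optimize_cell_hillclimb(s, "cubic")
  steps <- fit$trace$iterations$step[-1]
  expect_identical(steps[1:3], rep("a+0.1", 3))
  expect_identical(steps[4], "a+0.05")
  expect_equal(fit$cell[["a"]], 7.5, tolerance = 1e-12)
  # accepted criterion values decrease strictly
  expect_true(all(diff(fit$trace$iterations$mean_abs_dev) < 0))
})

test_that("hill climbing keeps only the single best improvement per round", {
  # the b restraint has twice the fractional span, so a step on b improves
  # the criterion twice as much as a step on a; b must be accepted first
  s <- parse_res(c("TITL two-parameter", "CELL 0 10.1 20.3 7 90 90 90", "SFAC C",
                   "DFIX 1.0 0.02 C1 C2", "DFIX 4.0 0.02 C1 C3",
                   "C1 1 0 0 0", "C2 1 0.1 0 0", "C3 1 0 0.2 0", "END"))
  fit <- optimize_cell_hillclimb(s, "orthorhombic")
  expect_identical(fit$trace$iterations$step[2], "b-0.1")
  expect_equal(fit$cell[["a"]], 10, tolerance = 1e-6)
  expect_equal(fit$cell[["b"]], 20, tolerance = 1e-6)
})

test_that("drivers agree when scoring a common criterion", {
  # the hill climb's own criterion (weighted mean |dev|) has kinks where
  # single-parameter moves stall; forcing the smooth squared criterion puts
  # both drivers on the same objective and they must find the same minimum
  for (s in all_systems) {
    fx <- generate_fixture(s, true_cell_for(s), "tetrahedral",
                           seed = 23 + match(s, all_systems))
    fb <- optimize_cell_bfgs(fx$structure, s)$cell
    fh <- optimize_cell_hillclimb(fx$structure, s, criterion = "objective")$cell
    expect_lt(max(abs(unclass(fb)[1:3] - unclass(fh)[1:3])), 5e-3)
    expect_lt(max(abs(unclass(fb)[4:6] - unclass(fh)[4:6])), 5e-2)
  }
})

test_that("optimized cells satisfy the lattice constraints bitwise", {
  for (s in c("monoclinic", "orthorhombic", "hexagonal", "tetragonal", "cubic")) {
    sys <- crystal_system(s)
    fx <- generate_fixture(s, true_cell_for(s), "tetrahedral",
                           seed = 31 + match(s, all_systems))
    for (cl in list(optimize_cell_bfgs(fx$structure, s)$cell,
                    optimize_cell_hillclimb(fx$structure, s)$cell)) {
      for (p in names(sys$fixed)) expect_identical(cl[[p]], sys$fixed[[p]])
      for (tied in names(sys$ties))
        expect_identical(cl[[tied]], cl[[sys$ties[[tied]]]])
    }
  }
})

test_that("P1 relaxation of a true orthorhombic fixture recovers 90-degree angles", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 41)
  fit <- optimize_cell_bfgs(fx$structure, "triclinic")
  expect_lt(max(abs(unclass(fit$cell)[4:6] - 90)), 0.05)
  expect_lt(max(abs(unclass(fit$cell)[1:3] - c(10, 20, 30))), 1e-3)
})

test_that("a planar molecule leaves the out-of-plane axis unrecovered", {
  # hexagon in the a-b plane: no restraint spans c, so its gradient
  # component is identically zero and c stays at the (wrong) start value
  fx <- generate_fixture("orthorhombic", unit_cell(10, 12, 15),
                         "hexagon_planar", seed = 3)
  expect_identical(unname(fx$manifest$observable), c(TRUE, TRUE, FALSE))
  g <- cell_gradient(fx$structure, fx$structure$cell, "orthorhombic")
  expect_lt(abs(g[["c"]]), 1e-10)
  fit <- optimize_cell_bfgs(fx$structure, "orthorhombic")
  expect_lt(max(abs(unclass(fit$cell)[1:2] - c(10, 12))), 1e-3)
  expect_equal(fit$cell[["c"]], fx$structure$cell[["c"]], tolerance = 1e-8)
})

test_that("the trace never ends above its starting objective", {
  for (driver in c("bfgs", "hillclimb")) {
    fx <- generate_fixture("triclinic", true_cell_for("triclinic"),
                           "tetrahedral", seed = 57,
                           restraint_noise_sd = 0.02)
    f <- if (driver == "bfgs") optimize_cell_bfgs(fx$structure, "triclinic")
         else optimize_cell_hillclimb(fx$structure, "triclinic")
    it <- f$trace$iterations
    expect_lte(it$objective[nrow(it)], it$objective[1])
  }
})

test_that("coordinate regularization restores a displaced atom's geometry", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 2, cell_perturbation = 0)
  s <- fx$structure
  true_xyz <- cart_coords(s)
  # displace one atom by 0.05 A Cartesian along x
  d <- solve(orthogonalization_matrix(s$cell)) %*% c(0.05, 0, 0)
  s$atoms$x[2] <- s$atoms$x[2] + d[1]
  r <- regularize_coordinates(s)
  # restraint geometry is restored (distances only fix shape up to rigid
  # motion, so compare after optimal superposition)
  expect_lt(kabsch_max_err(true_xyz, cart_coords(r)), 1e-4)
  # the centroid gauge is preserved
  expect_equal(colMeans(as.matrix(r$atoms[, c("x", "y", "z")])),
               colMeans(as.matrix(s$atoms[, c("x", "y", "z")])),
               tolerance = 1e-10)
  # already-satisfied coordinates stay put
  r0 <- regularize_coordinates(fx$structure)
  expect_equal(as.matrix(r0$atoms[, c("x", "y", "z")]),
               as.matrix(fx$structure$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9)
})

test_that("unrestrained atoms are untouched by regularization", {
  txt <- c("TITL with solvent", "CELL 0 10 10 10 90 90 90", "SFAC C O",
           "DFIX 1.6 0.02 C1 C2",
           "C1 1 0.0 0.0 0.0", "C2 1 0.15 0.0 0.0",
           "O1 2 0.71234567 0.81234567 0.91234567",
           "END")
  s <- parse_res(txt)
  r <- regularize_coordinates(s)
  expect_identical(r$atoms$x[3], s$atoms$x[3])
  expect_identical(r$atoms$y[3], s$atoms$y[3])
  expect_identical(r$atoms$z[3], s$atoms$z[3])
  expect_equal(cell_residual(r)$per_restraint$d, 1.6, tolerance = 1e-6)
})

test_that("iteration without a refiner equals a single driver run", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 19)
  single <- optimize_cell_bfgs(fx$structure, "orthorhombic")
  it <- iterate_cell(fx$structure, "orthorhombic", refiner = NULL)
  expect_equal(unclass(it$cell), unclass(single$cell), tolerance = 1e-12)
  expect_equal(nrow(it$trace$iterations), 1)
})

test_that("alternation with the internal regularizer recovers cell and coordinates", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 29, cell_perturbation = 0.05)
  it <- iterate_cell(fx$structure, "orthorhombic", refiner = "internal")
  expect_true(it$trace$converged)
  expect_lt(nrow(it$trace$iterations), 25)
  expect_lt(max(abs(unclass(it$cell)[1:3] - c(10, 20, 30))), 1e-3)
  expect_lt(cell_residual(it$structure)$weighted_mean_abs_dev, 1e-4)
})

test_that("an adversarial refiner hook hits the 25-iteration cap", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 37)
  kick <- local({
    k <- 0
    function(structure, cell) {
      k <<- k + 1
      set.seed(7000 + k)
      n <- nrow(structure$atoms)
      structure$atoms$x <- structure$atoms$x + rnorm(n, sd = 2e-3)
      structure$atoms$y <- structure$atoms$y + rnorm(n, sd = 2e-3)
      structure
    }
  })
  it <- iterate_cell(fx$structure, "orthorhombic", refiner = kick)
  expect_identical(it$trace$termination_reason, "max_iterations")
  expect_equal(nrow(it$trace$iterations), 25)
  # each cell half-step minimizes at fixed coordinates, so the objective
  # right after it never exceeds the pre-step value; spot-check the final
  # model is no worse than the start under its own coordinates
  expect_false(it$trace$converged)
})

test_that("a failing external refiner stops with a partial trace, not a crash", {
  fx <- generate_fixture("orthorhombic", unit_cell(10, 20, 30), "tetrahedral",
                         seed = 43)
  expect_warning(
    it <- iterate_cell(fx$structure, "orthorhombic", refiner = "false # {in} {out}"),
    "refiner failed")
  expect_identical(it$trace$termination_reason, "refiner_error")
  expect_equal(nrow(it$trace$iterations), 1)
  expect_false(it$trace$converged)
})

test_that("cell half-steps never increase the objective at fixed coordinates", {
  fx <- generate_fixture("triclinic", true_cell_for("triclinic"), "tetrahedral",
                         seed = 61, restraint_noise_sd = 0.02)
  s <- fx$structure
  for (k in 1:3) {
    before <- cell_residual(s)$total
    step <- optimize_cell_bfgs(s, "triclinic")
    after <- cell_residual(s, step$cell)$total
    expect_lte(after, before + 1e-12)
    s <- regularize_coordinates(cellfit:::set_cell(s, step$cell))
  }
})
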