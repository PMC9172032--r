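# shared oracles and generators; everything here is independent of the
# analytic code paths it checks

# central finite differences of the objective over the free parameters
fd_gradient <- function(structure, cell, system, form = "squared", h = 1e-6) {
  system <- crystal_system(system)
  free <- cs_free_vector(system, cell)
  vapply(seq_along(free), function(i) {
    hi <- h * max(1, abs(free[i]))
    fp <- free; fp[i] <- free[i] + hi
    fm <- free; fm[i] <- free[i] - hi
    (cell_residual(structure, cs_constrain(system, fp), form)$total -
       cell_residual(structure, cs_constrain(system, fm), form)$total) / (2 * hi)
  }, numeric(1))
}

# max per-atom displacement after optimal rigid superposition (Kabsch)
kabsch_max_err <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(t(Yc) %*% Xc)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  max(sqrt(rowSums((Xc - Yc %*% R)^2)))
}

cart_coords <- function(structure, cell = structure$cell) {
  M <- orthogonalization_matrix(cell)
  t(M %*% t(as.matrix(structure$atoms[, c("x", "y", "z")])))
}

# random cell conforming to the given system, in realistic ranges
random_conforming_cell <- function(system) {
  system <- crystal_system(system)
  free <- vapply(system$free, function(p) {
    if (p %in% c("a", "b", "c")) runif(1, 6, 25)
    else runif(1, 80, 100)             # keeps the metric positive definite
  }, numeric(1))
  cs_constrain(system, free)
}

# one-restraint structure: two atoms along [100] in a cubic-style cell
single_restraint_res <- function(a = 7, t = 0.2, target = 1.5, sigma = 0.02) {
  parse_res(c("TITL single restraint",
              sprintf("CELL 0.0251 %g %g %g 90 90 90", a, a, a),
              "SFAC C",
              sprintf("DFIX %g %g C1 C2", target, sigma),
              "C1 1 0.0 0.0 0.0 11.0 0.05",
              sprintf("C2 1 %g 0.0 0.0 11.0 0.05", t),
              "END"))
}

all_systems <- c("triclinic", "monoclinic", "orthorhombic",
                 "hexagonal", "tetragonal", "cubic")

# a conforming true cell per system, used by recovery tests
true_cell_for <- function(system) {
  switch(system,
         triclinic    = unit_cell(9, 11, 13, 85, 95, 100),
         monoclinic   = unit_cell(9, 11, 13, 90, 102, 90),
         orthorhombic = unit_cell(10, 20, 30),
         hexagonal    = unit_cell(8, 8, 12, 90, 90, 120),
         tetragonal   = unit_cell(8, 8, 12),
         cubic        = unit_cell(9, 9, 9))
}
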