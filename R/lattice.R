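#' Construct a unit cell
#'
#' A unit cell is described by three axis lengths \eqn{a, b, c} (in angstroms)
#' and three inter-axial angles \eqn{\alpha, \beta, \gamma} (in degrees).
#' Angles are degrees at every external interface; conversion to radians
#' happens exactly once, inside the metric-tensor computation.
#'
#' @param a,b,c Axis lengths in angstroms; must be strictly positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees; each strictly
#'   between 0 and 180, and jointly such that the metric tensor is positive
#'   definite (equivalently, the cell volume is real and positive).
#' @return An object of class `"unit_cell"`: a named numeric vector of the
#'   six parameters.
#' @examples
#' unit_cell(10, 20, 30)
#' unit_cell(12.136, 13.173, 33.346, 83.130, 84.435, 77.633)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            gamma = as.numeric(gamma))
  validate_cell(cell)
  class(cell) <- "unit_cell"
  cell
}

validate_cell <- function(cell) {
  nm <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (length(cell) != 6L || !all(nm %in% names(cell)))
    stop("a unit cell needs the six named parameters a, b, c, alpha, beta, gamma")
  for (p in c("a", "b", "c")) {
    v <- cell[[p]]
    if (!is.finite(v) || v <= 0)
      stop(sprintf("invalid unit cell: length '%s' = %g must be finite and > 0", p, v))
  }
  for (p in c("alpha", "beta", "gamma")) {
    v <- cell[[p]]
    if (!is.finite(v) || v <= 0 || v >= 180)
      stop(sprintf("invalid unit cell: angle '%s' = %g must lie strictly in (0, 180) degrees", p, v))
  }
  # positive cell volume <=> the metric tensor is positive definite
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  vol2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol2 <= 0)
    stop("invalid unit cell: the angle combination gives non-positive cell volume (alpha/beta/gamma incompatible)")
  invisible(cell)
}

#' @export
print.unit_cell <- function(x, digits = 4, ...) {
  cat(sprintf("unit cell: a=%.*f b=%.*f c=%.*f  alpha=%.*f beta=%.*f gamma=%.*f  V=%.*f A^3\n",
              digits, x[["a"]], digits, x[["b"]], digits, x[["c"]],
              digits, x[["alpha"]], digits, x[["beta"]], digits, x[["gamma"]],
              digits, cell_volume(x)))
  invisible(x)
}

#' Metric tensor of a unit cell
#'
#' The real-space metric tensor \eqn{G} turns fractional coordinate
#' differences into squared Cartesian distances:
#' \eqn{d^2 = \Delta x^\top G \Delta x}. Its entries are
#' \eqn{G_{11}=a^2}, \eqn{G_{22}=b^2}, \eqn{G_{33}=c^2},
#' \eqn{G_{12}=ab\cos\gamma}, \eqn{G_{13}=ac\cos\beta},
#' \eqn{G_{23}=bc\cos\alpha}.
#'
#' @param cell A [unit_cell()].
#' @return A symmetric 3x3 numeric matrix in square angstroms.
#' @export
metric_tensor <- function(cell) {
  validate_cell(cell)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc),
         nrow = 3, byrow = TRUE)
}

#' Unit-cell volume
#'
#' Closed-form volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'   + 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic angstroms.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  cell[["a"]] * cell[["b"]] * cell[["c"]] *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Orthogonalization matrix
#'
#' Matrix \eqn{M} mapping fractional to Cartesian coordinates
#' (\eqn{X = M x}), in the standard crystallographic convention: the
#' \eqn{a} axis lies along the first Cartesian axis and \eqn{b} lies in the
#' first coordinate plane. The metric tensor equals \eqn{M^\top M}, which
#' makes all distance computations independent of this convention; it only
#' matters for exported Cartesian coordinates.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 numeric matrix (angstroms).
#' @export
orthogonalization_matrix <- function(cell) {
  validate_cell(cell)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]] * pi / 180
  be <- cell[["beta"]] * pi / 180
  ga <- cell[["gamma"]] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0,           cc * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Distance between two fractional positions
#'
#' Computes \eqn{\sqrt{\Delta x^\top G \Delta x}} for
#' \eqn{\Delta x = x_1 - x_2}. Coordinates are used literally as given —
#' no minimum-image/periodic wrapping — matching SHELX semantics where
#' restrained atom pairs are listed explicitly within the model.
#'
#' @param cell A [unit_cell()].
#' @param frac1,frac2 Fractional coordinate 3-vectors.
#' @return Distance in angstroms.
#' @export
frac_distance <- function(cell, frac1, frac2) {
  G <- metric_tensor(cell)
  dx <- as.numeric(frac1) - as.numeric(frac2)
  sqrt(drop(dx %*% G %*% dx))
}

## ---- crystal systems -------------------------------------------------------

# free parameters per system; tied groups share one free variable, fixed
# angles are written bit-for-bit as 90 or 120
.cs_table <- list(
  triclinic    = list(free = c("a", "b", "c", "alpha", "beta", "gamma"),
                      ties = list(), fixed = c()),
  monoclinic   = list(free = c("a", "b", "c", "beta"),
                      ties = list(), fixed = c(alpha = 90, gamma = 90)),
  orthorhombic = list(free = c("a", "b", "c"),
                      ties = list(), fixed = c(alpha = 90, beta = 90, gamma = 90)),
  hexagonal    = list(free = c("a", "c"),
                      ties = list(b = "a"),
                      fixed = c(alpha = 90, beta = 90, gamma = 120)),
  tetragonal   = list(free = c("a", "c"),
                      ties = list(b = "a"),
                      fixed = c(alpha = 90, beta = 90, gamma = 90)),
  cubic        = list(free = c("a"),
                      ties = list(b = "a", c = "a"),
                      fixed = c(alpha = 90, beta = 90, gamma = 90))
)

#' Declare a crystal system
#'
#' A crystal system fixes some cell angles (at exactly 90 or 120 degrees)
#' and ties some lengths equal, leaving a reduced set of free optimization
#' variables:
#' triclinic 6 (a, b, c, alpha, beta, gamma); monoclinic 4 (a, b, c, beta;
#' unique axis b); orthorhombic 3 (a, b, c); hexagonal 2 (a, c; a = b,
#' gamma = 120); tetragonal 2 (a, c; a = b); cubic 1 (a).
#' Rhombohedral/trigonal lattices are handled in the hexagonal setting.
#'
#' @param name One of `"triclinic"`, `"monoclinic"`, `"orthorhombic"`,
#'   `"hexagonal"`, `"tetragonal"`, `"cubic"` (partial matching allowed).
#' @return An object of class `"crystal_system"` with elements `name`,
#'   `free` (free parameter names), `ties`, `fixed` and
#'   `free_parameter_count`.
#' @examples
#' crystal_system("hexagonal")$free_parameter_count  # 2
#' @export
crystal_system <- function(name = c("triclinic", "monoclinic", "orthorhombic",
                                    "hexagonal", "tetragonal", "cubic")) {
  if (inherits(name, "crystal_system")) return(name)
  name <- match.arg(name)
  sys <- .cs_table[[name]]
  structure(list(name = name, free = sys$free, ties = sys$ties,
                 fixed = sys$fixed,
                 free_parameter_count = length(sys$free)),
            class = "crystal_system")
}

#' @export
print.crystal_system <- function(x, ...) {
  cat(sprintf("crystal system: %s (%d free parameter%s: %s)\n", x$name,
              x$free_parameter_count,
              if (x$free_parameter_count == 1) "" else "s",
              paste(x$free, collapse = ", ")))
  invisible(x)
}

#' Build a full cell from a free-parameter vector
#'
#' Expands the system's free variables into all six cell parameters:
#' tied lengths are copied, fixed angles are written exactly
#' (bit-for-bit 90/120).
#'
#' @param system A [crystal_system()] (or its name).
#' @param free Numeric vector of length `free_parameter_count`, ordered as
#'   in `system$free` (lengths in angstroms, angles in degrees).
#' @return A [unit_cell()] satisfying the system's constraints exactly.
#' @export
cs_constrain <- function(system, free) {
  system <- crystal_system(system)
  if (length(free) != system$free_parameter_count)
    stop(sprintf("free vector has length %d; %s needs %d",
                 length(free), system$name, system$free_parameter_count))
  p <- c(a = NA_real_, b = NA_real_, c = NA_real_,
         alpha = 90, beta = 90, gamma = 90)
  p[system$free] <- as.numeric(free)
  for (tied in names(system$ties)) p[[tied]] <- p[[system$ties[[tied]]]]
  p[names(system$fixed)] <- system$fixed
  unit_cell(p[["a"]], p[["b"]], p[["c"]], p[["alpha"]], p[["beta"]], p[["gamma"]])
}

#' Extract the free-parameter vector from a conforming cell
#'
#' Inverse of [cs_constrain()]. The cell must already satisfy the declared
#' system's constraints: fixed angles exactly 90/120 and tied lengths exactly
#' equal. A cell that violates them is rejected — fix the cell or relax the
#' system to triclinic.
#'
#' @param system A [crystal_system()] (or its name).
#' @param cell A conforming [unit_cell()].
#' @return Named numeric vector of the system's free parameters.
#' @export
cs_free_vector <- function(system, cell) {
  system <- crystal_system(system)
  validate_cell(cell)
  for (p in names(system$fixed))
    if (cell[[p]] != system$fixed[[p]])
      stop(sprintf("cell does not conform to %s: %s = %.6g, expected exactly %g (relax to triclinic to refine it)",
                   system$name, p, cell[[p]], system$fixed[[p]]))
  for (tied in names(system$ties))
    if (cell[[tied]] != cell[[system$ties[[tied]]]])
      stop(sprintf("cell does not conform to %s: %s = %.6g differs from %s = %.6g",
                   system$name, tied, cell[[tied]],
                   system$ties[[tied]], cell[[system$ties[[tied]]]]))
  stats::setNames(as.numeric(cell[system$free]), system$free)
}

# partial derivatives dG/dtau for the six raw parameters; angles in degrees
# (the pi/180 Jacobian factor is folded in here, once)
metric_tensor_grad <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]] * pi / 180
  be <- cell[["beta"]] * pi / 180
  ga <- cell[["gamma"]] * pi / 180
  d2r <- pi / 180
  sym <- function(m12, m13, m23, d11 = 0, d22 = 0, d33 = 0)
    matrix(c(d11, m12, m13, m12, d22, m23, m13, m23, d33), nrow = 3)
  list(
    a     = sym(b * cos(ga), cc * cos(be), 0, d11 = 2 * a),
    b     = sym(a * cos(ga), 0, cc * cos(al), d22 = 2 * b),
    c     = sym(0, a * cos(be), b * cos(al), d33 = 2 * cc),
    alpha = sym(0, 0, -b * cc * sin(al) * d2r),
    beta  = sym(0, -a * cc * sin(be) * d2r, 0),
    gamma = sym(-a * b * sin(ga) * d2r, 0, 0)
  )
}
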