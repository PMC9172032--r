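# Synthetic fixture generator: structures with a known true cell, a molecule
# of known geometry, restraints equal to (optionally noised) true distances,
# and a perturbed starting cell. Every test and demo gets its ground truth
# from here.

# template molecules, Cartesian coordinates in angstroms
.molecule_coords <- function(molecule, n_chain = 6L,
                             bond = 1.54, ring_bond = 1.39) {
  switch(molecule,
    hexagon_planar = {
      # regular 6-ring in the x-y plane; circumradius equals the bond length
      ang <- (0:5) * pi / 3
      cbind(x = ring_bond * cos(ang), y = ring_bond * sin(ang), z = 0,
            deparse.level = 0)
    },
    tetrahedral = {
      # methane-like: central atom plus four substituents on tetrahedron
      # vertices at the bond distance
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      rbind(c(0, 0, 0), bond * v)
    },
    chain = {
      # zigzag in the x-z plane with tetrahedral backbone angle
      half <- (109.47 / 2) * pi / 180
      i <- seq_len(n_chain) - 1
      cbind(x = i * bond * sin(half), y = 0,
            z = (i %% 2) * bond * cos(half), deparse.level = 0)
    },
    stop(sprintf("unknown molecule template '%s'", molecule))
  )
}

# distance-based bonding; symmetric cutoff table per element pair
.default_cutoffs <- c("C-C" = 1.80, "C-N" = 1.75, "C-O" = 1.70, "N-O" = 1.65,
                      "N-N" = 1.70, "O-O" = 1.60, "C-H" = 1.25, "N-H" = 1.20,
                      "O-H" = 1.15, "H-H" = 0.0)

.pair_cutoff <- function(e1, e2, cutoffs) {
  k1 <- paste(e1, e2, sep = "-"); k2 <- paste(e2, e1, sep = "-")
  if (k1 %in% names(cutoffs)) cutoffs[[k1]]
  else if (k2 %in% names(cutoffs)) cutoffs[[k2]]
  else 1.8
}

#' Derive distance restraints from a molecular geometry
#'
#' Emulates a restraint dictionary generator on ideal coordinates: every
#' bonded pair (within the element-pair distance cutoff) yields a 1,2
#' (DFIX-type) restraint and every pair of atoms sharing a bonded neighbour
#' but not bonded to each other yields a 1,3 (DANG-type) restraint, with
#' targets equal to the current distances and the SHELX default sigmas
#' (0.02 and 0.04 angstroms).
#'
#' @param xyz Numeric matrix (n x 3) of Cartesian coordinates in angstroms.
#' @param elements Character vector of element labels (C/N/O/H-like).
#' @param cutoffs Named numeric vector of per-element-pair bonding cutoffs
#'   in angstroms (`"C-C"`, `"C-H"`, ...); unknown pairs fall back to 1.8.
#' @return Data frame with columns `kind`, `i`, `j` (atom indices),
#'   `target`, `sigma`; attribute `connected` is `FALSE` (with a warning)
#'   when the bond graph is disconnected.
#' @export
restraints_from_geometry <- function(xyz, elements = rep("C", nrow(xyz)),
                                     cutoffs = .default_cutoffs) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2) stop("need at least two atoms to derive restraints")
  dmat <- as.matrix(stats::dist(xyz))
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (dmat[i, j] <= .pair_cutoff(elements[i], elements[j], cutoffs) &&
        dmat[i, j] > 1e-6)
      bonded[i, j] <- bonded[j, i] <- TRUE
  }
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j])
      rows[[length(rows) + 1L]] <- data.frame(kind = "bond_12", i = i, j = j,
                                              target = dmat[i, j], sigma = 0.02)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!bonded[i, j] && any(bonded[i, ] & bonded[j, ]))
      rows[[length(rows) + 1L]] <- data.frame(kind = "angle_13", i = i, j = j,
                                              target = dmat[i, j], sigma = 0.04)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), i = integer(0), j = integer(0),
                      target = numeric(0), sigma = numeric(0))
  # connectivity check (simple BFS over the bond graph)
  seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(bonded[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  connected <- all(seen)
  if (!connected)
    warning("atom set is disconnected under the bonding cutoffs; restraints cover connected parts only")
  attr(out, "connected") <- connected
  out
}

# run code under a private, seeded RNG stream without disturbing the caller's
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic SHELX fixture with known ground truth
#'
#' Places a template molecule in a known true cell, derives 1,2 and 1,3
#' distance restraints whose targets equal the true distances (optionally
#' with Gaussian noise), then perturbs the cell multiplicatively on the
#' crystal system's free parameters. With all noise and perturbation zero
#' the emitted structure has restraint residual exactly zero at the true
#' cell. Identical seed and arguments give a byte-identical fixture.
#'
#' @param system A [crystal_system()] or its name.
#' @param true_cell The generating [unit_cell()]; must conform to `system`.
#' @param molecule `"hexagon_planar"` (6-ring in the a-b plane),
#'   `"tetrahedral"` (methane-like 3D), or `"chain"` (zigzag).
#' @param n_chain Chain length for `molecule = "chain"`.
#' @param cell_perturbation Fractional amplitude applied multiplicatively to
#'   each free parameter (sign drawn at random per parameter); 0.05 = 5%.
#' @param restraint_noise_sd Gaussian noise (angstroms) added to restraint
#'   targets.
#' @param coordinate_noise_sd Gaussian noise (angstroms, Cartesian) added to
#'   atom positions before restraint targets are measured.
#' @param seed Integer seed; the only source of randomness in the package.
#' @return List with `structure` (a `"shelx_structure"` carrying the
#'   perturbed cell), `true_cell`, `res_text` (the emitted RES lines) and
#'   `manifest` (true and perturbed cells, seed, noise levels, and
#'   per-parameter observability flags — a free length is flagged
#'   unobservable when no restraint has a coordinate difference along that
#'   axis, the flat-molecule degeneracy).
#' @export
generate_fixture <- function(system, true_cell,
                             molecule = c("tetrahedral", "hexagon_planar", "chain"),
                             n_chain = 6L,
                             cell_perturbation = 0.05,
                             restraint_noise_sd = 0,
                             coordinate_noise_sd = 0,
                             seed = 1L) {
  molecule <- match.arg(molecule)
  system <- crystal_system(system)
  validate_cell(true_cell)
  free_true <- cs_free_vector(system, true_cell)  # must conform

  .with_seed(seed, {
    xyz <- .molecule_coords(molecule, n_chain = n_chain)
    if (nrow(xyz) < 2) stop("molecule must have at least 2 atoms")
    if (coordinate_noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = coordinate_noise_sd),
                          ncol = 3)
    rs <- restraints_from_geometry(xyz)

    # fractional coordinates under the TRUE cell, molecule centred in the box
    M <- orthogonalization_matrix(true_cell)
    frac <- t(solve(M) %*% t(xyz))
    frac <- sweep(frac, 2, 0.5 - colMeans(frac), "+")
    # quantize to the precision written into the RES text, then measure the
    # restraint targets from the quantized coordinates under the true cell:
    # the zero-noise fixture is then satisfied exactly (to the last bit) at
    # the true cell even after a text round trip
    frac <- round(frac, 8)
    rs$target <- vapply(seq_len(nrow(rs)), function(k)
      frac_distance(true_cell, frac[rs$i[k], ], frac[rs$j[k], ]), numeric(1))
    if (restraint_noise_sd > 0)
      rs$target <- rs$target + stats::rnorm(nrow(rs), sd = restraint_noise_sd)
    if (any(rs$target <= 0)) stop("restraint noise produced a non-positive target")

    # multiplicative perturbation on free parameters only; random sign,
    # full amplitude, so "5%" means exactly +/-5% per parameter
    signs <- sample(c(-1, 1), length(free_true), replace = TRUE)
    free_pert <- free_true * (1 + signs * cell_perturbation)
    perturbed <- cs_constrain(system, free_pert)   # errors if invalid

    # observability: a free length is informed only if some restrained pair
    # differs along its axis (in the true-cell fractional frame)
    axis_of <- c(a = 1L, b = 2L, c = 3L)
    span <- vapply(1:3, function(k)
      any(abs(frac[rs$i, k] - frac[rs$j, k]) > 1e-9), logical(1))
    observable <- vapply(system$free, function(p) {
      if (p %in% names(axis_of)) span[axis_of[[p]]] else TRUE
    }, logical(1))

    res_text <- c(
      "TITL synthetic fixture (generated; known ground truth)",
      .format_cell_line(0.0251, perturbed),
      sprintf("ZERR 1 %s", paste(rep("0.001", 6), collapse = " ")),
      "LATT -1",
      "SFAC C",
      sprintf("UNIT %d", nrow(xyz)),
      vapply(seq_len(nrow(rs)), function(k) {
        # 17 significant digits: the printed target parses back to the
        # identical double, keeping zero-noise fixtures exact
        sprintf("%s %.17g %.3f C%d C%d",
                if (rs$kind[k] == "bond_12") "DFIX" else "DANG",
                rs$target[k], rs$sigma[k], rs$i[k], rs$j[k])
      }, character(1)),
      "FVAR 1.0",
      vapply(seq_len(nrow(xyz)), function(k) {
        sprintf("C%-3d 1 %11.8f %11.8f %11.8f 11.0 0.05",
                k, frac[k, 1], frac[k, 2], frac[k, 3])
      }, character(1)),
      "END")

    structure_obj <- parse_res(res_text)
    manifest <- list(
      system = system$name, molecule = molecule, seed = seed,
      true_cell = true_cell, perturbed_cell = perturbed,
      cell_perturbation = cell_perturbation,
      restraint_noise_sd = restraint_noise_sd,
      coordinate_noise_sd = coordinate_noise_sd,
      n_atoms = nrow(xyz), n_restraints = nrow(rs),
      observable = observable,
      connected = isTRUE(attr(rs, "connected")))
    list(structure = structure_obj, true_cell = true_cell,
         res_text = res_text, manifest = manifest)
  })
}

#' Write a fixture manifest as plain text
#'
#' Records the ground truth of a generated fixture (true and perturbed
#' cells, seed, noise levels, observability flags) in a key-value text
#' format.
#'
#' @param manifest The `manifest` element returned by [generate_fixture()].
#' @param path Output file path.
#' @return The lines written, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  fmt_cell <- function(cell) paste(sprintf("%.6f", unclass(cell)), collapse = " ")
  lines <- c(
    sprintf("system\t%s", manifest$system),
    sprintf("molecule\t%s", manifest$molecule),
    sprintf("seed\t%d", manifest$seed),
    sprintf("true_cell\t%s", fmt_cell(manifest$true_cell)),
    sprintf("perturbed_cell\t%s", fmt_cell(manifest$perturbed_cell)),
    sprintf("cell_perturbation\t%g", manifest$cell_perturbation),
    sprintf("restraint_noise_sd\t%g", manifest$restraint_noise_sd),
    sprintf("coordinate_noise_sd\t%g", manifest$coordinate_noise_sd),
    sprintf("n_atoms\t%d", manifest$n_atoms),
    sprintf("n_restraints\t%d", manifest$n_restraints),
    sprintf("observable\t%s",
            paste(sprintf("%s=%s", names(manifest$observable),
                          ifelse(manifest$observable, "yes", "no")),
                  collapse = " ")),
    sprintf("connected\t%s", if (manifest$connected) "yes" else "no"))
  writeLines(lines, path)
  invisible(lines)
}
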