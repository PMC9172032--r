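# SHELX RES/INS reader and writer.
#
# Instructions are matched on their first four characters, case-insensitive,
# per SHELX convention. Continuation lines (trailing "=") are joined before
# tokenizing. Instructions the optimizer does not need are preserved verbatim
# so that writing reproduces the input.

# commands recognised as instructions (so they are never mistaken for atom
# records); everything here except the handled subset passes through verbatim
.shelx_commands <- c(
  "TITL", "CELL", "ZERR", "LATT", "SYMM", "SFAC", "DISP", "UNIT", "LAUE",
  "REM",  "MORE", "TIME", "END",  "HKLF", "OMIT", "SHEL", "BASF", "TWIN",
  "EXTI", "SWAT", "HOPE", "MERG", "SPEC", "RESI", "MOVE", "ANIS", "AFIX",
  "HFIX", "FRAG", "FEND", "EXYZ", "EADP", "EQIV", "CONN", "PART", "BIND",
  "FREE", "DFIX", "DANG", "BUMP", "SAME", "SADI", "CHIV", "FLAT", "DELU",
  "SIMU", "DEFS", "ISOR", "NCSY", "SUMP", "L.S.", "CGLS", "BLOC", "DAMP",
  "STIR", "WGHT", "FVAR", "BOND", "CONF", "MPLA", "RTAB", "HTAB", "LIST",
  "ACTA", "SIZE", "TEMP", "WPDB", "FMAP", "GRID", "PLAN", "MOLE", "ABIN",
  "ANSC", "ANSR", "NEUT", "PRIG", "XNPD", "TANG"
)

.is_num <- function(s) grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)

# SHELX fixed-parameter convention: a coordinate v with 5 <= |v| < 15 is
# fixed at v - 10; FVAR references (|v| >= 15, multiplier m >= 2) are not
# interpreted and raise an error
.decode_coord <- function(v, line_no) {
  if (abs(v) >= 15)
    stop(sprintf("line %d: coordinate %g uses an FVAR free-variable reference (|10m+p|, m >= 2), which is not supported",
                 line_no, v))
  if (abs(v) >= 5) list(value = v - 10, fixed = TRUE)
  else list(value = v, fixed = FALSE)
}

# split an atom reference "NAME" or "NAME_resi"; "$n" symmetry references
# are out of scope and rejected explicitly
.split_atom_ref <- function(ref, line_no) {
  if (grepl("\\$", ref))
    stop(sprintf("line %d: symmetry-equivalent atom reference '%s' ($n/EQIV) is not supported", line_no, ref))
  m <- regmatches(ref, regexec("^(.*)_([0-9]+)$", ref))[[1]]
  if (length(m) == 3) list(name = toupper(m[2]), resi = as.integer(m[3]))
  else list(name = toupper(ref), resi = NA_integer_)
}

#' Parse a SHELX RES/INS instruction stream
#'
#' Reads the subset of SHELX needed for restraint-based cell optimization:
#' `CELL` (wavelength plus six cell parameters), `SFAC` (element list),
#' `RESI` (residue scope for subsequent atoms and restraint references),
#' `DFIX`/`DANG` distance restraints (with optional sigma and one or more
#' atom pairs, each pair becoming one restraint sharing target and sigma),
#' atom records, and the `+filename` include syntax by which restraints can
#' be stored in separate files. All other instructions are preserved
#' verbatim for round-trip writing.
#'
#' Restraint atom references without a `_n` residue qualifier resolve within
#' the residue scope current at the restraint's line first, then globally.
#'
#' @param text Character scalar (the file content) or character vector of
#'   lines.
#' @param include_resolver Function mapping an include name (the part after
#'   `+`) to further text, or `NULL` (then any `+filename` line is an
#'   error). [read_res()] supplies a resolver reading files relative to the
#'   input.
#' @return An object of class `"shelx_structure"`: a list with `cell`
#'   ([unit_cell()]), `wavelength`, `sfac` (element labels), `atoms`
#'   (data frame: `name`, `resi`, `sfac`, `x`, `y`, `z`, coordinate fixed
#'   flags, trailing fields and the raw line), `restraints` (data frame:
#'   `kind` `"bond_12"`/`"angle_13"`, `target`, `sigma`, resolved atom
#'   indices `atom1`/`atom2`) and the preserved line records.
#' @seealso [read_res()], [write_res()]
#' @export
parse_res <- function(text, include_resolver = NULL) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  # join continuation lines: trailing "=" (possibly followed by blanks)
  joined <- character(0)
  buf <- NULL
  for (ln in text) {
    if (!is.null(buf)) ln <- paste(buf, ln)
    if (grepl("=\\s*$", ln) && !grepl("^\\s*(TITL|REM)", ln, ignore.case = TRUE)) {
      buf <- sub("=\\s*$", "", ln)
    } else {
      joined <- c(joined, ln)
      buf <- NULL
    }
  }
  if (!is.null(buf)) joined <- c(joined, buf)

  st <- new.env(parent = emptyenv())
  st$lines <- list()          # records: list(kind, text, atom = NA)
  st$cell <- NULL; st$wavelength <- NA_real_
  st$sfac <- character(0)
  st$atoms <- list()
  st$pending <- list()        # unresolved restraint records
  st$resi <- NA_integer_
  st$ended <- FALSE

  parse_lines <- function(lines, from_include, resolver) {
    for (i in seq_along(lines)) {
      ln <- lines[[i]]
      .parse_line(st, ln, i, from_include, resolver)
    }
  }
  .parse_line <- function(st, ln, line_no, from_include, resolver) {
    rec <- function(kind) {
      if (!from_include)
        st$lines[[length(st$lines) + 1L]] <- list(kind = kind, text = ln,
                                                  atom = NA_integer_)
    }
    trimmed <- trimws(ln)
    if (identical(trimmed, "")) { rec("other"); return(invisible()) }
    if (startsWith(trimmed, "+")) {
      nm <- sub("^\\+", "", trimmed)
      if (is.null(resolver))
        stop(sprintf("line %d: cannot resolve include '+%s' (no include resolver given)", line_no, nm))
      inc <- resolver(nm)
      if (is.null(inc))
        stop(sprintf("line %d: include '+%s' could not be resolved", line_no, nm))
      rec("other")
      if (length(inc) == 1L && grepl("\n", inc))
        inc <- strsplit(inc, "\n", fixed = TRUE)[[1]]
      for (j in seq_along(inc)) .parse_line(st, inc[[j]], j, TRUE, resolver)
      return(invisible())
    }
    toks <- strsplit(trimmed, "\\s+")[[1]]
    key <- toupper(substr(toks[1], 1, 4))
    known <- key %in% .shelx_commands

    if (known && key == "CELL") {
      nums <- suppressWarnings(as.numeric(toks[-1]))
      if (length(nums) < 7 || anyNA(nums[1:7]))
        stop(sprintf("line %d: CELL needs wavelength and six cell parameters", line_no))
      st$wavelength <- nums[1]
      st$cell <- unit_cell(nums[2], nums[3], nums[4], nums[5], nums[6], nums[7])
      rec("cell")
      return(invisible())
    }
    if (known && key == "SFAC") {
      args <- toks[-1]
      if (length(args) >= 2 && any(.is_num(args[-1]))) {
        st$sfac <- c(st$sfac, args[1])          # full scattering-factor form
      } else {
        st$sfac <- c(st$sfac, args)
      }
      rec("other")
      return(invisible())
    }
    if (known && key == "RESI") {
      args <- toks[-1]
      num <- suppressWarnings(as.integer(args[.is_num(args)][1]))
      st$resi <- if (is.na(num) || num == 0L) NA_integer_ else num
      rec("other")
      return(invisible())
    }
    if (known && (key == "DFIX" || key == "DANG")) {
      args <- toks[-1]
      if (length(args) < 3 || !.is_num(args[1]))
        stop(sprintf("line %d: %s needs a target distance and at least one atom pair", line_no, key))
      target <- as.numeric(args[1]); args <- args[-1]
      if (.is_num(args[1])) { sigma <- as.numeric(args[1]); args <- args[-1] }
      else sigma <- if (key == "DFIX") 0.02 else 0.04
      if (length(args) < 2 || length(args) %% 2 != 0)
        stop(sprintf("line %d: %s atom list must contain complete pairs", line_no, key))
      for (k in seq(1, length(args), by = 2)) {
        r1 <- .split_atom_ref(args[k], line_no)
        r2 <- .split_atom_ref(args[k + 1], line_no)
        st$pending[[length(st$pending) + 1L]] <- list(
          kind = if (key == "DFIX") "bond_12" else "angle_13",
          target = target, sigma = sigma,
          name1 = r1$name, resi1 = r1$resi,
          name2 = r2$name, resi2 = r2$resi,
          scope = st$resi, line = line_no)
      }
      rec("other")
      return(invisible())
    }
    if (known && (key == "HKLF" || key == "END")) {
      st$ended <- TRUE
      rec("other")
      return(invisible())
    }
    if (!known && !st$ended && length(toks) >= 5 && all(.is_num(toks[2:5]))) {
      # atom record: name sfac x y z [sof U...]
      xyz_raw <- as.numeric(toks[3:5])
      dec <- lapply(xyz_raw, .decode_coord, line_no = line_no)
      idx <- length(st$atoms) + 1L
      st$atoms[[idx]] <- list(
        name = toupper(toks[1]), resi = st$resi,
        sfac = as.integer(as.numeric(toks[2])),
        x = dec[[1]]$value, y = dec[[2]]$value, z = dec[[3]]$value,
        fx = dec[[1]]$fixed, fy = dec[[2]]$fixed, fz = dec[[3]]$fixed,
        rest = if (length(toks) > 5) paste(toks[6:length(toks)], collapse = " ") else "",
        raw = ln,
        x0 = dec[[1]]$value, y0 = dec[[2]]$value, z0 = dec[[3]]$value)
      if (!from_include)
        st$lines[[length(st$lines) + 1L]] <- list(kind = "atom", text = ln, atom = idx)
      return(invisible())
    }
    if (!known && !st$ended && length(toks) >= 4 && all(.is_num(toks[2:4])) &&
        as.numeric(toks[2]) == round(as.numeric(toks[2]))) {
      # looks like an atom record but its coordinate fields do not parse
      bad <- if (length(toks) == 4) "is missing a coordinate"
             else sprintf("has a non-numeric coordinate field '%s'", toks[5])
      stop(sprintf("line %d: atom record '%s' %s", line_no, toks[1], bad))
    }
    rec("other")
    invisible()
  }

  parse_lines(joined, FALSE, include_resolver)

  if (is.null(st$cell))
    stop("no CELL instruction found: cannot build a structure without a unit cell")

  atoms <- do.call(rbind, lapply(st$atoms, function(a)
    data.frame(name = a$name, resi = a$resi, sfac = a$sfac,
               x = a$x, y = a$y, z = a$z,
               fx = a$fx, fy = a$fy, fz = a$fz,
               rest = a$rest, raw = a$raw,
               x0 = a$x0, y0 = a$y0, z0 = a$z0,
               stringsAsFactors = FALSE)))
  if (is.null(atoms))
    atoms <- data.frame(name = character(0), resi = integer(0),
                        sfac = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), fx = logical(0), fy = logical(0),
                        fz = logical(0), rest = character(0),
                        raw = character(0), x0 = numeric(0), y0 = numeric(0),
                        z0 = numeric(0), stringsAsFactors = FALSE)
  key <- paste(atoms$resi, atoms$name)
  if (anyDuplicated(key))
    stop(sprintf("duplicate atom name within a residue: %s",
                 paste(unique(atoms$name[duplicated(key)]), collapse = ", ")))

  resolve <- function(name, resi, scope, line) {
    if (!is.na(resi)) {
      hit <- which(atoms$name == name & !is.na(atoms$resi) & atoms$resi == resi)
    } else {
      hit <- integer(0)
      if (!is.na(scope))
        hit <- which(atoms$name == name & !is.na(atoms$resi) & atoms$resi == scope)
      if (length(hit) == 0) hit <- which(atoms$name == name)
    }
    if (length(hit) == 0)
      stop(sprintf("line %d: restraint references unknown atom '%s'%s",
                   line, name, if (!is.na(resi)) sprintf(" in residue %d", resi) else ""))
    if (length(hit) > 1)
      stop(sprintf("line %d: restraint reference '%s' is ambiguous across residues (add a _resi qualifier)",
                   line, name))
    hit
  }
  restraints <- do.call(rbind, lapply(st$pending, function(r)
    data.frame(kind = r$kind, target = r$target, sigma = r$sigma,
               atom1 = resolve(r$name1, r$resi1, r$scope, r$line),
               atom2 = resolve(r$name2, r$resi2, r$scope, r$line),
               line = r$line, stringsAsFactors = FALSE)))
  if (is.null(restraints))
    restraints <- data.frame(kind = character(0), target = numeric(0),
                             sigma = numeric(0), atom1 = integer(0),
                             atom2 = integer(0), line = integer(0),
                             stringsAsFactors = FALSE)
  if (nrow(restraints) > 0 &&
      (any(restraints$target <= 0) || any(restraints$sigma <= 0)))
    stop("restraint targets and sigmas must be > 0")

  structure(list(cell = st$cell, wavelength = st$wavelength, sfac = st$sfac,
                 atoms = atoms, restraints = restraints, lines = st$lines),
            class = "shelx_structure")
}

#' Read a SHELX RES/INS file
#'
#' Wrapper around [parse_res()] whose include resolver reads `+filename`
#' includes relative to the directory of `path`.
#'
#' @param path Path to a `.res`/`.ins` file.
#' @return A `"shelx_structure"`; see [parse_res()].
#' @export
read_res <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dir <- dirname(path)
  resolver <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    readLines(p, warn = FALSE)
  }
  parse_res(readLines(path, warn = FALSE), include_resolver = resolver)
}

.format_atom_line <- function(a) {
  enc <- function(v, fixed) if (fixed) v + 10 else v
  sprintf("%-4s %3d %11.6f %11.6f %11.6f%s",
          a$name, a$sfac,
          enc(a$x, a$fx), enc(a$y, a$fy), enc(a$z, a$fz),
          if (nzchar(a$rest)) paste0(" ", a$rest) else "")
}

.format_cell_line <- function(wavelength, cell) {
  sprintf("CELL %.5f %10.5f %10.5f %10.5f %9.4f %9.4f %9.4f",
          wavelength, cell[["a"]], cell[["b"]], cell[["c"]],
          cell[["alpha"]], cell[["beta"]], cell[["gamma"]])
}

#' Write a structure back to SHELX format
#'
#' Emits an instruction stream identical to the parsed input except for the
#' `CELL` line when `new_cell` is given (a provenance comment is added after
#' it), and except for atom records whose coordinates were modified since
#' parsing (these are reformatted; untouched atom lines are emitted
#' byte-identically). Cell lengths are written with 5 decimals and angles
#' with 4, enough for exact round-trip at SHELX precision.
#'
#' @param structure A `"shelx_structure"`.
#' @param new_cell Optional replacement [unit_cell()].
#' @param path Optional file path; when given the text is also written there.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_res <- function(structure, new_cell = NULL, path = NULL) {
  stopifnot(inherits(structure, "shelx_structure"))
  cell <- if (is.null(new_cell)) structure$cell else { validate_cell(new_cell); new_cell }
  out <- character(0)
  for (rec in structure$lines) {
    if (rec$kind == "cell") {
      if (is.null(new_cell)) {
        out <- c(out, rec$text)
      } else {
        out <- c(out, .format_cell_line(structure$wavelength, cell),
                 "REM cell parameters replaced by restraint-based optimization")
      }
    } else if (rec$kind == "atom") {
      a <- structure$atoms[rec$atom, ]
      moved <- (a$x != a$x0) || (a$y != a$y0) || (a$z != a$z0)
      out <- c(out, if (moved) .format_atom_line(a) else rec$text)
    } else {
      out <- c(out, rec$text)
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Export atoms as a minimal PDB coordinate file
#'
#' Writes `ATOM` records with Cartesian coordinates obtained from the
#' structure's cell via the standard orthogonalization convention, plus a
#' `CRYST1` record. Useful for feeding external restraint generators.
#'
#' @param structure A `"shelx_structure"`.
#' @param path Output file path.
#' @return The lines written, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "shelx_structure"))
  M <- orthogonalization_matrix(structure$cell)
  cell <- structure$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cell[["a"]], cell[["b"]], cell[["c"]],
                   cell[["alpha"]], cell[["beta"]], cell[["gamma"]])
  for (i in seq_len(nrow(structure$atoms))) {
    a <- structure$atoms[i, ]
    xyz <- drop(M %*% c(a$x, a$y, a$z))
    el <- if (a$sfac >= 1 && a$sfac <= length(structure$sfac))
      structure$sfac[a$sfac] else "C"
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s MOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, substr(a$name, 1, 4), ifelse(is.na(a$resi), 1L, a$resi),
      xyz[1], xyz[2], xyz[3], toupper(el)))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(lines)
}

#' @export
print.shelx_structure <- function(x, ...) {
  cat(sprintf("SHELX structure: %d atoms, %d restraints (%d bond 1,2 / %d angle 1,3)\n",
              nrow(x$atoms), nrow(x$restraints),
              sum(x$restraints$kind == "bond_12"),
              sum(x$restraints$kind == "angle_13")))
  print(x$cell)
  invisible(x)
}

# replace the stored cell (validated); coordinates untouched
set_cell <- function(structure, cell) {
  validate_cell(cell)
  structure$cell <- cell
  structure
}
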