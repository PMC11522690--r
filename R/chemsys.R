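# Chemistry data model: molecules, canonical pair indexing, XYZ and
# dataset-record I/O.
#
# Conventions used throughout the package:
#   * atom indices are 1-based (idiomatic R),
#   * unordered pairs are stored with i < j in row-major upper-triangle
#     order, i.e. (1,2), (1,3), ..., (1,M), (2,3), ...,
#   * coordinates are in Angstrom, electron-count properties in electrons
#     ("e"), energies in atomic units ("au").

#' Element symbols for Z = 1..94
#'
#' @format Character vector; position Z holds the conventional symbol.
#' @keywords internal
#' @noRd
.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu"
)

#' Convert atomic numbers to element symbols
#'
#' @param Z integer vector of atomic numbers (1..94).
#' @return character vector of element symbols.
#' @export
element_symbol <- function(Z) {
  Z <- as.integer(Z)
  if (any(is.na(Z)) || any(Z < 1L) || any(Z > length(.ELEMENT_SYMBOLS))) {
    stop("atomic numbers must be integers in [1, ", length(.ELEMENT_SYMBOLS), "]")
  }
  .ELEMENT_SYMBOLS[Z]
}

#' Convert element symbols to atomic numbers (case-insensitive)
#'
#' @param symbols character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
element_number <- function(symbols) {
  idx <- match(toupper(symbols), toupper(.ELEMENT_SYMBOLS))
  if (any(is.na(idx))) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  as.integer(idx)
}

#' Construct a molecule
#'
#' A molecule is the sole physical input of the package: atomic numbers
#' `Z` and Cartesian coordinates `R` (Angstrom), plus an opaque id label.
#'
#' @param Z integer vector of atomic numbers (all >= 1).
#' @param R numeric M x 3 matrix of Cartesian coordinates in Angstrom.
#' @param id character label (opaque; defaults to "mol").
#' @return an object of class `molecule` with fields `Z`, `R`, `id`.
#' @examples
#' water <- molecule(c(8, 1, 1),
#'                   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(water)
#' @export
molecule <- function(Z, R, id = "mol") {
  Z <- as.integer(Z)
  R <- as.matrix(R)
  storage.mode(R) <- "double"
  if (length(Z) < 1L) stop("a molecule must contain at least one atom")
  if (any(is.na(Z)) || any(Z < 1L)) stop("atomic numbers must be integers >= 1")
  if (ncol(R) != 3L || nrow(R) != length(Z)) {
    stop("R must be a ", length(Z), " x 3 coordinate matrix")
  }
  if (!all(is.finite(R))) stop("coordinates must be finite")
  structure(list(Z = Z, R = R, id = as.character(id)[1]), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule '", x$id, "': ", length(x$Z), " atoms [",
      paste(element_symbol(x$Z), collapse = " "), "]>\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer atom count M.
#' @export
n_atoms <- function(mol) length(mol$Z)

#' Enumerate the canonical unordered atom pairs of an M-atom system
#'
#' All M(M-1)/2 non-equivalent pairs (diagonal excluded), in row-major
#' upper-triangle order. The `flat` column is the 1-based position of the
#' pair in this canonical enumeration; every two-body property array in
#' the package is aligned with it.
#'
#' @param M integer atom count (>= 1).
#' @return data.frame with integer columns `i`, `j` (i < j) and `flat`.
#' @examples
#' enumerate_pairs(3)  # (1,2), (1,3), (2,3)
#' @export
enumerate_pairs <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("atom count M must be an integer >= 1")
  if (M == 1L) {
    return(data.frame(i = integer(0), j = integer(0), flat = integer(0)))
  }
  i <- rep.int(seq_len(M - 1L), times = (M - 1L):1L)
  j <- unlist(lapply(seq_len(M - 1L), function(a) (a + 1L):M), use.names = FALSE)
  data.frame(i = i, j = as.integer(j), flat = seq_along(i))
}

#' Number of unordered pairs for M atoms
#' @param M atom count.
#' @return M(M-1)/2.
#' @export
n_pairs <- function(M) as.integer(M * (M - 1) / 2)

#' Flat index of pair (i, j) in the canonical enumeration
#'
#' @param i,j 1-based atom indices, i != j (order irrelevant).
#' @param M atom count.
#' @return 1-based flat index; vectorized over i, j.
#' @export
pair_flat_index <- function(i, j, M) {
  if (any(i == j)) stop("pair indices must be distinct (i != j)")
  a <- pmin(i, j); b <- pmax(i, j)
  if (any(a < 1L) || any(b > M)) stop("pair indices out of range for M = ", M)
  as.integer((a - 1) * M - a * (a - 1) / 2 + (b - a))
}

#' Recover (i, j) from a flat pair index
#'
#' @param flat 1-based flat index (vectorized).
#' @param M atom count.
#' @return data.frame with columns `i`, `j` (i < j).
#' @export
pair_unflatten <- function(flat, M) {
  if (any(flat < 1L) || any(flat > n_pairs(M))) {
    stop("flat pair index out of range for M = ", M)
  }
  # invert the row-major triangular enumeration
  i <- integer(length(flat)); j <- integer(length(flat))
  for (k in seq_along(flat)) {
    f <- flat[k]
    a <- 1L
    while (f > M - a) {
      f <- f - (M - a)
      a <- a + 1L
    }
    i[k] <- a
    j[k] <- a + f
  }
  data.frame(i = i, j = j)
}

#' Euclidean distance between two atoms of a molecule
#'
#' Symmetric and invariant under rigid rotations and translations.
#'
#' @param mol a `molecule`.
#' @param i,j distinct 1-based atom indices.
#' @return distance in Angstrom.
#' @export
interatomic_distance <- function(mol, i, j) {
  M <- n_atoms(mol)
  if (i < 1L || j < 1L || i > M || j > M) stop("atom index out of range")
  if (i == j) stop("interatomic distance requires two distinct atoms (i != j)")
  sqrt(sum((mol$R[i, ] - mol$R[j, ])^2))
}

#' All-pair distance vector in canonical order
#' @param mol a `molecule`.
#' @return numeric vector of length M(M-1)/2 aligned with [enumerate_pairs()].
#' @export
pair_distances <- function(mol) {
  as.numeric(stats::dist(mol$R))  # dist() uses the same upper-triangle order
}

# ---------------------------------------------------------------------------
# XYZ I/O

#' Read a (multi-structure) XYZ file
#'
#' Standard dialect: atom-count line, comment line, then one
#' `Symbol x y z` line per atom; frames concatenated.
#'
#' @param path file path.
#' @return list of `molecule` objects; the comment line is used as `id`
#'   when non-empty, else `frame<k>`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  mols <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    M <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(M) || M < 1L) {
      stop("XYZ parse error at line ", ln, ": expected a positive atom count")
    }
    if (ln + 1L + M > length(lines)) {
      stop("XYZ parse error at line ", ln, ": frame truncated (", M,
           " atoms declared)")
    }
    comment <- trimws(lines[ln + 1L])
    body <- lines[(ln + 2L):(ln + 1L + M)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    nt <- lengths(toks)
    if (any(nt < 4L)) {
      bad <- which(nt < 4L)[1]
      stop("XYZ parse error at line ", ln + 1L + bad,
           ": expected 'Symbol x y z'")
    }
    sym <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      v
    }, numeric(3)))
    if (any(!is.finite(xyz))) {
      bad <- which(!stats::complete.cases(xyz))[1]
      stop("XYZ parse error at line ", ln + 1L + bad,
           ": non-numeric coordinate")
    }
    Z <- tryCatch(element_number(sym), error = function(e) {
      stop("XYZ parse error in frame starting at line ", ln, ": ",
           conditionMessage(e), call. = FALSE)
    })
    id <- if (nzchar(comment)) comment else paste0("frame", length(mols) + 1L)
    mols[[length(mols) + 1L]] <- molecule(Z, xyz, id = id)
    ln <- ln + 2L + M
  }
  mols
}

#' Write molecules to a (multi-structure) XYZ file
#'
#' @param molecules a `molecule` or list of molecules.
#' @param path output path.
#' @param digits coordinate precision (default 10, enough for a lossless
#'   1e-6 Angstrom round trip).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(molecules, path, digits = 10) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in molecules) {
    writeLines(as.character(n_atoms(mol)), con)
    writeLines(mol$id, con)
    writeLines(sprintf(paste0("%-2s %.", digits, "f %.", digits, "f %.", digits, "f"),
                       element_symbol(mol$Z), mol$R[, 1], mol$R[, 2], mol$R[, 3]),
               con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Labeled dataset records

#' Construct a labeled local-property record
#'
#' Bundles a molecule with named one-body (per-atom) and two-body
#' (per-pair, canonical order) property arrays and their unit tags.
#'
#' @param mol a `molecule`.
#' @param props_1p named list of length-M numeric vectors (e.g. `Q`,
#'   `lambda`, `N_A`, `E_intra`).
#' @param props_2p named list of length-M(M-1)/2 numeric vectors (e.g.
#'   `delta`, `E_inter`), aligned with [enumerate_pairs()].
#' @param units named character vector mapping property names to `"e"`
#'   (electrons) or `"au"` (atomic units).
#' @param extras named list of per-molecule scalars (e.g. the exact total
#'   energy `E_total` stored by the surrogate generator).
#' @return object of class `local_record`.
#' @export
local_record <- function(mol, props_1p = list(), props_2p = list(),
                         units = character(), extras = list()) {
  stopifnot(inherits(mol, "molecule"))
  M <- n_atoms(mol)
  P <- n_pairs(M)
  for (nm in names(props_1p)) {
    v <- as.numeric(props_1p[[nm]])
    if (length(v) != M) {
      stop("record '", mol$id, "': 1P property '", nm, "' has length ",
           length(v), ", expected M = ", M)
    }
    if (any(!is.finite(v))) stop("record '", mol$id, "': non-finite values in '", nm, "'")
    props_1p[[nm]] <- v
  }
  for (nm in names(props_2p)) {
    v <- as.numeric(props_2p[[nm]])
    if (length(v) != P) {
      stop("record '", mol$id, "': 2P property '", nm, "' has length ",
           length(v), ", expected M(M-1)/2 = ", P)
    }
    if (any(!is.finite(v))) stop("record '", mol$id, "': non-finite values in '", nm, "'")
    props_2p[[nm]] <- v
  }
  structure(list(molecule = mol, props_1p = props_1p, props_2p = props_2p,
                 units = units, extras = extras),
            class = "local_record")
}

#' @export
print.local_record <- function(x, ...) {
  cat("<local_record '", x$molecule$id, "': M=", n_atoms(x$molecule),
      "; 1P: ", paste(names(x$props_1p), collapse = ","),
      "; 2P: ", paste(names(x$props_2p), collapse = ","), ">\n", sep = "")
  invisible(x)
}

#' Write labeled records as newline-delimited JSON
#'
#' One record per line with fields `id`, `Z`, `R` (M x 3, Angstrom),
#' `props_1p`, `props_2p` (canonical pair order) and `units`. The format
#' is plain text, diffable and streamable.
#'
#' @param records list of `local_record` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  if (inherits(records, "local_record")) records <- list(records)
  lines <- vapply(records, function(rec) {
    obj <- list(
      id = rec$molecule$id,
      Z = rec$molecule$Z,
      R = rec$molecule$R,
      props_1p = rec$props_1p,
      props_2p = rec$props_2p,
      units = as.list(rec$units),
      extras = rec$extras
    )
    as.character(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                                  matrix = "rowmajor"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a newline-delimited dataset written by [write_dataset()]
#'
#' @param path file path.
#' @return list of `local_record` objects.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(k) {
    obj <- jsonlite::fromJSON(lines[k], simplifyVector = TRUE)
    Rmat <- obj$R
    if (!is.matrix(Rmat)) Rmat <- matrix(Rmat, ncol = 3, byrow = TRUE)
    mol <- molecule(obj$Z, Rmat,
                    id = if (is.null(obj$id)) paste0("rec", k) else obj$id)
    units <- unlist(obj$units)
    if (is.null(units)) units <- character()
    tryCatch(
      local_record(mol,
                   props_1p = as.list(obj$props_1p),
                   props_2p = as.list(obj$props_2p),
                   units = units,
                   extras = if (is.null(obj$extras)) list() else as.list(obj$extras)),
      error = function(e) {
        stop("dataset schema error in record ", k, " ('", mol$id, "'): ",
             conditionMessage(e), call. = FALSE)
      }
    )
  })
}
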