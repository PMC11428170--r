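#' Bead sequence for the BLN model
#'
#' A BLN bead protein is defined by a hydrophobicity label per bead --
#' Hydrophobic (`"B"`), Hydrophilic (`"L"`) or Neutral (`"N"`) -- and a
#' secondary-structure class per backbone dihedral -- Helix (`"H"`),
#' Extended strand (`"E"`) or Turn/coil (`"T"`). A chain of `n` beads has
#' `n - 3` dihedrals.
#'
#' @param labels character vector of bead labels in `{"B","L","N"}`.
#' @param dihedral_classes character vector of length `length(labels) - 3`
#'   with entries in `{"H","E","T"}`. May be `NULL` for chains shorter than 4
#'   beads.
#' @return An object of class `bead_sequence`.
#' @examples
#' bead_sequence(c("B", "B", "L", "N"), "T")
#' @export
bead_sequence <- function(labels, dihedral_classes = NULL) {
  labels <- toupper(as.character(labels))
  if (length(labels) == 1L && nchar(labels) > 1L)
    labels <- strsplit(labels, "")[[1]]
  if (!all(labels %in% c("B", "L", "N")))
    stop("bead labels must be 'B', 'L' or 'N'")
  n <- length(labels)
  if (is.null(dihedral_classes)) {
    if (n >= 4L) stop("dihedral_classes required for chains of >= 4 beads")
    dihedral_classes <- character(0)
  } else {
    dihedral_classes <- toupper(as.character(dihedral_classes))
    if (length(dihedral_classes) == 1L && nchar(dihedral_classes) > 1L)
      dihedral_classes <- strsplit(dihedral_classes, "")[[1]]
  }
  if (!all(dihedral_classes %in% c("H", "E", "T")))
    stop("dihedral classes must be 'H', 'E' or 'T'")
  if (n >= 4L && length(dihedral_classes) != n - 3L)
    stop("need exactly n - 3 dihedral classes, got ", length(dihedral_classes))
  structure(list(labels = labels, dihedral_classes = dihedral_classes),
            class = "bead_sequence")
}

#' @export
print.bead_sequence <- function(x, ...) {
  cat("BLN bead sequence (", length(x$labels), " beads)\n", sep = "")
  cat("  beads:     ", paste(x$labels, collapse = ""), "\n", sep = "")
  cat("  dihedrals: ", paste(x$dihedral_classes, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
length.bead_sequence <- function(x) length(x$labels)

# integer codes used by the compiled kernels
bead_codes <- function(seq) match(seq$labels, c("B", "L", "N")) - 1L
dihedral_codes <- function(seq) match(seq$dihedral_classes, c("H", "E", "T")) - 1L

#' BLN force-field parameters
#'
#' Parameter set for the BLN potential, in reduced units (energies in
#' \eqn{\epsilon}, distances in Angstrom). The bond term uses the full
#' prefactor convention `k_b * (r - sigma)^2` (no 1/2 factor); the angle term
#' is `(k_theta/2) * (theta - theta0)^2`. Dihedral coefficients `(A, B, C)`
#' multiply `(1 + cos phi)`, `(1 + cos 3 phi)` and `(1 + sin phi)` and are
#' set per secondary-structure class; nonbonded pairs separated by at least
#' three bonds interact through `4 eps S1 [(sigma/r)^12 - S2 (sigma/r)^6]`
#' with `(S1, S2)` determined by the bead-class pair.
#'
#' Default pair scalings: (B,B) attract with `(1, 1)`; L with B or L is
#' repulsive-only with `(2/3, -1)`; any pair involving N is purely
#' excluded-volume with `(1, 0)`. Default dihedral coefficients per class
#' (helix, extended, turn) follow the Honeycutt-Thirumalai/Head-Gordon
#' lineage of the model and are freely overridable: the native-structure
#' parameterization of any specific published bead protein can be dropped in
#' via the arguments or a key-value override file (see
#' [read_parameter_overrides()]).
#'
#' @param k_b bond force constant (\eqn{\epsilon} A^-2).
#' @param sigma equilibrium bond length and Lennard-Jones length (A).
#' @param k_theta angle force constant (\eqn{\epsilon} rad^-2).
#' @param theta0 equilibrium bond angle (rad).
#' @param epsilon energy unit (1 in reduced units).
#' @param dihedral_table 3x3 numeric matrix, rows `H`, `E`, `T`, columns
#'   `A`, `B`, `C`.
#' @param S1,S2 3x3 symmetric matrices of pair scalings, rows/columns
#'   `B`, `L`, `N`.
#' @return An object of class `bln_parameters`.
#' @export
bln_parameters <- function(k_b = 115.6, sigma = 3.8, k_theta = 10,
                           theta0 = 1.8326, epsilon = 1,
                           dihedral_table = NULL, S1 = NULL, S2 = NULL) {
  if (is.null(dihedral_table)) {
    dihedral_table <- rbind(H = c(A = 0.0, B = 0.2, C = 0.2),
                            E = c(A = 0.9, B = 1.2, C = 0.0),
                            T = c(A = 0.0, B = 0.2, C = 0.0))
  }
  if (is.null(S1)) {
    S1 <- matrix(c(1, 2/3, 1,
                   2/3, 2/3, 1,
                   1, 1, 1), 3, 3, byrow = TRUE,
                 dimnames = list(c("B", "L", "N"), c("B", "L", "N")))
  }
  if (is.null(S2)) {
    S2 <- matrix(c(1, -1, 0,
                   -1, -1, 0,
                   0, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("B", "L", "N"), c("B", "L", "N")))
  }
  stopifnot(identical(dim(dihedral_table), c(3L, 3L)),
            identical(dim(S1), c(3L, 3L)), identical(dim(S2), c(3L, 3L)))
  if (!isTRUE(all.equal(S1, t(S1))) || !isTRUE(all.equal(S2, t(S2))))
    stop("pair tables S1/S2 must be symmetric under bead-pair exchange")
  structure(list(k_b = k_b, sigma = sigma, k_theta = k_theta,
                 theta0 = theta0, epsilon = epsilon,
                 dihedral_table = unname(dihedral_table),
                 S1 = unname(S1), S2 = unname(S2)),
            class = "bln_parameters")
}

#' @export
print.bln_parameters <- function(x, ...) {
  cat("BLN parameters: k_b =", x$k_b, " sigma =", x$sigma,
      " k_theta =", x$k_theta, " theta0 =", x$theta0, "\n")
  invisible(x)
}

#' Read BLN parameter overrides from a key-value file
#'
#' Lines of the form `key = value`; `#` starts a comment. Scalar keys are
#' `k_b`, `sigma`, `k_theta`, `theta0`, `epsilon`. Dihedral coefficients use
#' keys like `dihedral.H.A`; pair scalings use keys like `pair.BL.S2`
#' (applied symmetrically).
#'
#' @param file path to the override file.
#' @param base parameter set to start from.
#' @return A `bln_parameters` object with the overrides applied.
#' @export
read_parameter_overrides <- function(file, base = bln_parameters()) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cls <- c(H = 1L, E = 2L, T = 3L)
  bd <- c(B = 1L, L = 2L, N = 3L)
  col <- c(A = 1L, B = 2L, C = 3L)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed override line: ", ln)
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric value in override line: ", ln)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (!key %in% c("k_b", "sigma", "k_theta", "theta0", "epsilon"))
        stop("unknown parameter key: ", key)
      base[[key]] <- val
    } else if (parts[1] == "dihedral" && length(parts) == 3L) {
      base$dihedral_table[cls[[parts[2]]], col[[parts[3]]]] <- val
    } else if (parts[1] == "pair" && length(parts) == 3L) {
      ij <- strsplit(parts[2], "")[[1]]
      tab <- parts[3]
      if (!tab %in% c("S1", "S2")) stop("unknown pair table: ", tab)
      base[[tab]][bd[[ij[1]]], bd[[ij[2]]]] <- val
      base[[tab]][bd[[ij[2]]], bd[[ij[1]]]] <- val
    } else stop("unknown parameter key: ", key)
  }
  base
}

# validate a conformation against a sequence; returns the coords matrix
as_conformation <- function(conf, n = NULL) {
  conf <- as.matrix(conf)
  if (ncol(conf) != 3L) stop("a conformation must be an N x 3 matrix")
  if (!all(is.finite(conf))) stop("conformation has non-finite coordinates")
  if (!is.null(n) && nrow(conf) != n)
    stop("conformation has ", nrow(conf), " beads; expected ", n)
  storage.mode(conf) <- "double"
  unname(conf)
}
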