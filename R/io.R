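#' Read and write bead sequence files
#'
#' Plain-text format: line one holds the bead labels (`B`/`L`/`N`, one
#' character per bead), line two the dihedral classes (`H`/`E`/`T`, one per
#' dihedral, length N - 3).
#'
#' @param file path.
#' @param seq a [bead_sequence()].
#' @return `read_bead_sequence` returns a [bead_sequence()].
#' @export
read_bead_sequence <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("sequence file needs two non-empty lines")
  bead_sequence(lines[1], lines[2])
}

#' @rdname read_bead_sequence
#' @export
write_bead_sequence <- function(seq, file) {
  writeLines(c(paste(seq$labels, collapse = ""),
               paste(seq$dihedral_classes, collapse = "")), file)
  invisible(file)
}

#' Write and read conformations in XYZ format
#'
#' Standard multi-frame XYZ: atom count, comment line, then one
#' `element x y z` row per bead. The element column carries the bead class
#' letter when a sequence is supplied (`X` otherwise).
#'
#' @param conf N x 3 matrix, or a list of them for a multi-frame file.
#' @param file path.
#' @param seq optional [bead_sequence()] supplying element letters.
#' @param comment comment line text (recycled across frames).
#' @return `read_xyz` returns a list of N x 3 matrices with the element
#'   letters in `attr(, "elements")`.
#' @export
write_xyz <- function(conf, file, seq = NULL, comment = "gdsfold") {
  frames <- if (is.list(conf)) conf else list(conf)
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in frames) {
    fr <- as_conformation(fr)
    el <- if (is.null(seq)) rep("X", nrow(fr)) else seq$labels
    writeLines(as.character(nrow(fr)), con)
    writeLines(comment, con)
    writeLines(sprintf("%s %.8f %.8f %.8f", el, fr[, 1], fr[, 2],
                       fr[, 3]), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file, warn = FALSE)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    el <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    elements <- el
    i <- i + 2L + n
  }
  attr(frames, "elements") <- elements
  frames
}

# bead class <-> residue name mapping for CA-only bead PDB files
.bead_resname <- c(B = "ALA", L = "SER", N = "GLY")

#' Write and read CA-only bead PDB files
#'
#' One CA atom per bead; the residue name encodes the bead class
#' (B -> ALA, L -> SER, N -> GLY), making the mapping reversible.
#'
#' @param conf N x 3 matrix.
#' @param seq a [bead_sequence()].
#' @param file path.
#' @return `read_bead_pdb` returns a list with `coords` and `labels`.
#' @export
write_bead_pdb <- function(conf, seq, file) {
  conf <- as_conformation(conf, length(seq))
  res <- .bead_resname[seq$labels]
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(conf)), res, seq_len(nrow(conf)),
    conf[, 1], conf[, 2], conf[, 3])
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname write_bead_pdb
#' @export
read_bead_pdb <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM")]
  res <- trimws(substr(lines, 18, 20))
  inv <- setNames(names(.bead_resname), .bead_resname)
  coords <- cbind(as.numeric(substr(lines, 31, 38)),
                  as.numeric(substr(lines, 39, 46)),
                  as.numeric(substr(lines, 47, 54)))
  list(coords = coords, labels = unname(inv[res]))
}

#' Write a path ensemble to a run directory
#'
#' One subdirectory per path holding the contact maps (edge-list TSV), any
#' reconstructed conformations (multi-frame XYZ) and a plain-text metadata
#' record (seed, final objective, objective trace).
#'
#' @param ensemble result of [generate_ensemble()].
#' @param dir output directory (created if needed).
#' @param seq optional [bead_sequence()] for XYZ element letters.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir, seq = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_along(ensemble)) {
    path <- ensemble[[p]]
    pd <- file.path(dir, sprintf("path_%04d", p))
    dir.create(pd, showWarnings = FALSE)
    for (m in seq_along(path$sequence$maps)) {
      write_contact_map(path$sequence$maps[[m]],
                        file.path(pd, sprintf("map_%02d.tsv", m - 1L)))
    }
    confs <- path$sequence$conformations
    if (!is.null(confs) && !any(vapply(confs, is.null, logical(1)))) {
      write_xyz(confs, file.path(pd, "conformations.xyz"), seq = seq)
    }
    meta <- c(sprintf("seed %d", path$seed),
              sprintf("objective %.10g", path$objective),
              paste("trace", paste(format(path$trace, digits = 8),
                                   collapse = " ")))
    writeLines(meta, file.path(pd, "metadata.txt"))
  }
  invisible(dir)
}
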