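#' Contact map of a conformation
#'
#' `G[i, j] = 1` iff beads i and j are strictly closer than the cutoff
#' `r_c` (ties at exactly `r_c` are non-contacts), `i != j`. The result is a
#' symmetric 0/1 integer matrix with zero diagonal.
#'
#' @param conf N x 3 coordinate matrix.
#' @param r_c contact cutoff distance (A), default 8.
#' @return N x N integer contact map.
#' @export
map_from_conformation <- function(conf, r_c = 8) {
  conf <- as_conformation(conf)
  d <- as.matrix(dist(conf))
  G <- (d < r_c) * 1L
  diag(G) <- 0L
  storage.mode(G) <- "integer"
  unname(G)
}

check_map <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("contact map must be square")
  if (!all(G %in% c(0L, 1L))) stop("contact map entries must be 0/1")
  if (any(diag(G) != 0L)) stop("contact map diagonal must be zero")
  if (!identical(unname(G == t(G)), matrix(TRUE, nrow(G), ncol(G))) &&
      any(G != t(G)))
    stop("contact map must be symmetric")
  storage.mode(G) <- "integer"
  unname(G)
}

#' Hamming distance between contact maps
#'
#' Number of unordered bead pairs `i < j` at which the two maps differ; one
#' bit flip changes the distance by one.
#'
#' @param A,B contact maps of equal size.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(A, B) {
  A <- check_map(A); B <- check_map(B)
  if (nrow(A) != nrow(B)) stop("contact maps differ in size")
  sum(abs(A - B)) %/% 2L
}

#' All-pairs shortest contact hops
#'
#' Unweighted shortest-path lengths on the contact graph of a map. Pairs in
#' different connected components are assigned the cap value `N` (finite,
#' larger than any achievable connected distance; bead chains whose bonded
#' neighbours are within the contact cutoff are always connected).
#'
#' @param G a contact map.
#' @return N x N integer hop matrix.
#' @export
shortest_hop_matrix <- function(G) {
  G <- check_map(G)
  .hop_matrix_cpp(G, nrow(G))
}

# SCH from precomputed hop matrices (hot path of the SA search)
sch_from_hops <- function(SA, SB) .sch_from_hops_cpp(SA, SB)

#' Shortest-contact-hop (SCH) distance between contact maps
#'
#' Contact-map metric built from all-pairs shortest-hop matrices
#' \eqn{S^A, S^B}:
#' \deqn{f_{SCH}(A,B) = \frac{2}{N(N-1)} \sum_{i<j}
#'   \frac{|S^A_{ij} - S^B_{ij}|}{\max(S^A_{ij}, S^B_{ij})}}
#' The per-pair relative difference down-weights differences at large hop
#' counts (long real-space distances), each summand lies in `[0, 1)`, and
#' the function is a true metric (satisfies the triangle inequality).
#'
#' @param A,B contact maps of equal size (N >= 2).
#' @param hops_A,hops_B optional precomputed hop matrices.
#' @return A number in `[0, 1)`; zero iff the hop matrices agree.
#' @export
sch_distance <- function(A, B, hops_A = NULL, hops_B = NULL) {
  A <- check_map(A); B <- check_map(B)
  if (nrow(A) != nrow(B)) stop("contact maps differ in size")
  if (nrow(A) < 2) stop("SCH distance needs at least 2 beads")
  if (is.null(hops_A)) hops_A <- shortest_hop_matrix(A)
  if (is.null(hops_B)) hops_B <- shortest_hop_matrix(B)
  sch_from_hops(hops_A, hops_B)
}

#' Mutable contact-map pairs
#'
#' Bead pairs eligible for bit-flip moves: separated by at least `min_sep`
#' peptide bonds (default 3, so bonded and next-nearest pairs are immutable).
#'
#' @param n number of beads.
#' @param min_sep minimum sequence separation.
#' @return Two-column integer matrix of pairs (1-based, i < j).
#' @export
mutable_pairs <- function(n, min_sep = 3L) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= min_sep, , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Toggle contact-map entries
#'
#' Applies a list of bit flips symmetrically. Applying the same flips twice
#' returns the original map (involution). Flips on immutable pairs
#' (separation below `min_sep`) are rejected with an error.
#'
#' @param G a contact map.
#' @param flips two-column matrix of bead pairs (1-based indices).
#' @param min_sep minimum sequence separation for a mutable pair.
#' @return The edited contact map.
#' @export
apply_bit_flips <- function(G, flips, min_sep = 3L) {
  G <- check_map(G)
  if (is.null(flips) || NROW(flips) == 0L) return(G)
  flips <- matrix(as.integer(flips), ncol = 2L)
  if (any(abs(flips[, 1] - flips[, 2]) < min_sep))
    stop("bit flip on an immutable pair (separation < ", min_sep, ")")
  if (any(flips < 1L) || any(flips > nrow(G)))
    stop("flip indices out of range")
  for (r in seq_len(nrow(flips))) {
    i <- flips[r, 1]; j <- flips[r, 2]
    G[i, j] <- 1L - G[i, j]
    G[j, i] <- G[i, j]
  }
  G
}

#' Write / read a contact map
#'
#' Two plain-text dialects: `"dense"` is a whitespace-separated 0/1 matrix;
#' `"edges"` is a sparse TSV edge list with columns `i`, `j` (0-based
#' indices, i < j) preceded by a `# n <N>` header recording the map size.
#'
#' @param G a contact map.
#' @param file path.
#' @param format `"edges"` or `"dense"`.
#' @return `read_contact_map` returns the contact map;
#'   `write_contact_map` returns `file` invisibly.
#' @export
write_contact_map <- function(G, file, format = c("edges", "dense")) {
  G <- check_map(G)
  format <- match.arg(format)
  if (format == "dense") {
    write.table(G, file, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste("# n", nrow(G)), con)
    writeLines("i\tj", con)
    idx <- which(upper.tri(G) & G == 1L, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      writeLines(paste(idx[, 1] - 1L, idx[, 2] - 1L, sep = "\t"), con)
    }
  }
  invisible(file)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(file, format = c("auto", "edges", "dense")) {
  format <- match.arg(format)
  first <- readLines(file, n = 1L)
  if (format == "auto")
    format <- if (startsWith(first, "# n")) "edges" else "dense"
  if (format == "dense") {
    G <- as.matrix(read.table(file))
    return(check_map(G))
  }
  n <- as.integer(strsplit(trimws(first), "\\s+")[[1]][3])
  tab <- read.table(file, skip = 1L, header = TRUE, sep = "\t")
  G <- matrix(0L, n, n)
  if (nrow(tab) > 0) {
    i <- tab$i + 1L; j <- tab$j + 1L
    G[cbind(i, j)] <- 1L
    G[cbind(j, i)] <- 1L
  }
  check_map(G)
}
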