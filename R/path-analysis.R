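#' Degree-of-formation order parameter
#'
#' Fraction of a set of native bead pairs whose current distance lies
#' within a tolerance of its value in the folded structure:
#' \deqn{\chi = \frac{1}{|pairs|} \sum_{(i,j)}
#'   H(\mathrm{tol}_{ij} - |r_{ij} - r_{ij}^{folded}|)}
#' with `H` the Heaviside step (`H(0) = 0`). The tolerance of 0.2 is
#' interpreted in units of the bond length by default (`"sigma"`, i.e.
#' 0.76 A); absolute-Angstrom and relative-to-native interpretations are
#' available.
#'
#' @param conf conformation to evaluate.
#' @param folded_conf reference folded conformation.
#' @param pair_set two-column matrix of bead pairs (1-based).
#' @param tolerance numeric tolerance, default 0.2.
#' @param tolerance_mode `"sigma"` (tolerance * sigma Angstrom),
#'   `"absolute"` (tolerance in Angstrom) or `"relative"`
#'   (tolerance * native distance).
#' @param sigma bond length used by the `"sigma"` mode.
#' @return \eqn{\chi \in [0, 1]}.
#' @export
chi_order_parameter <- function(conf, folded_conf, pair_set,
                                tolerance = 0.2,
                                tolerance_mode = c("sigma", "absolute",
                                                   "relative"),
                                sigma = 3.8) {
  tolerance_mode <- match.arg(tolerance_mode)
  pair_set <- matrix(as.integer(pair_set), ncol = 2L)
  if (nrow(pair_set) == 0L) stop("empty pair set")
  conf <- as_conformation(conf)
  folded_conf <- as_conformation(folded_conf, nrow(conf))
  pd <- function(m, p) sqrt(rowSums((m[p[, 1], , drop = FALSE] -
                                     m[p[, 2], , drop = FALSE])^2))
  r <- pd(conf, pair_set)
  r0 <- pd(folded_conf, pair_set)
  tol <- switch(tolerance_mode,
                sigma = rep(tolerance * sigma, length(r0)),
                absolute = rep(tolerance, length(r0)),
                relative = tolerance * r0)
  mean(abs(r - r0) < tol)
}

#' Native-contact pair sets for declared hairpin ranges
#'
#' Pairs in contact in the folded structure (separation >= `min_sep`) with
#' both beads inside the declared residue range.
#'
#' @param folded_conf folded conformation.
#' @param range integer vector of residue indices (e.g. `1:18`).
#' @param r_c contact cutoff (A).
#' @param min_sep minimum sequence separation.
#' @return Two-column pair matrix.
#' @export
native_pair_set <- function(folded_conf, range, r_c = 8, min_sep = 3L) {
  G <- map_from_conformation(folded_conf, r_c)
  idx <- which(upper.tri(G) & G == 1L, arr.ind = TRUE)
  keep <- idx[, 2] - idx[, 1] >= min_sep &
    idx[, 1] %in% range & idx[, 2] %in% range
  out <- idx[keep, , drop = FALSE]
  colnames(out) <- c("i", "j")
  out
}

#' Two-hairpin order-parameter track of a path
#'
#' Evaluates \eqn{(\chi_{\beta 1}, \chi_{\beta 2})} at every conformation of
#' a path, producing the track used for Frechet comparison and clustering.
#'
#' @param conformations ordered list of conformations (e.g. the five
#'   sequence structures, or all NEB images for a denser track).
#' @param folded_conf folded reference.
#' @param pairs1,pairs2 pair sets of the two hairpins (see
#'   [native_pair_set()]).
#' @param ... passed to [chi_order_parameter()].
#' @return Matrix with columns `chi1`, `chi2`, one row per conformation.
#' @export
chi_track <- function(conformations, folded_conf, pairs1, pairs2, ...) {
  out <- t(vapply(conformations, function(cf)
    c(chi_order_parameter(cf, folded_conf, pairs1, ...),
      chi_order_parameter(cf, folded_conf, pairs2, ...)),
    numeric(2)))
  colnames(out) <- c("chi1", "chi2")
  out
}

#' Discrete Frechet distance between two tracks
#'
#' Dynamic-programming discrete Frechet distance with the Euclidean point
#' metric: the smallest over all monotone couplings of the largest coupled
#' point distance. Respects time order but not step size.
#'
#' @param trackA,trackB matrices with one point per row (equal column
#'   count), or numeric vectors treated as 1-D tracks.
#' @return Non-negative distance.
#' @export
discrete_frechet <- function(trackA, trackB) {
  A <- if (is.matrix(trackA)) trackA else matrix(trackA, ncol = 1L)
  B <- if (is.matrix(trackB)) trackB else matrix(trackB, ncol = 1L)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty track")
  n <- nrow(A); m <- nrow(B)
  D <- matrix(0, n, m)
  for (j in seq_len(m)) {
    diffs <- sweep(A, 2L, B[j, ], "-")
    D[, j] <- sqrt(rowSums(diffs^2))
  }
  ca <- matrix(Inf, n, m)
  ca[1, 1] <- D[1, 1]
  for (i in 2:max(n, 2L)) if (n >= 2) ca[i, 1] <- max(ca[i - 1, 1], D[i, 1])
  for (j in 2:max(m, 2L)) if (m >= 2) ca[1, j] <- max(ca[1, j - 1], D[1, j])
  if (n >= 2 && m >= 2) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                        D[i, j])
      }
    }
  }
  ca[n, m]
}

#' Pairwise Frechet distance matrix of an ensemble of tracks
#'
#' @param tracks list of track matrices.
#' @return Symmetric non-negative matrix with zero diagonal; class
#'   `path_distance_matrix`.
#' @export
frechet_matrix <- function(tracks) {
  k <- length(tracks)
  D <- matrix(0, k, k)
  if (k >= 2) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        D[i, j] <- D[j, i] <- discrete_frechet(tracks[[i]], tracks[[j]])
      }
    }
  }
  structure(D, class = c("path_distance_matrix", "matrix"))
}

#' Select the lowest floored-energy paths
#'
#' @param paths list of [refine_path()] results (or any lists with a
#'   `floored_energy` element).
#' @param n number of paths to keep; if more than available, all are
#'   returned with a warning.
#' @return The selected subset, ordered by floored energy with stable
#'   tie-break by position.
#' @export
select_low_energy_paths <- function(paths, n = 100) {
  if (n <= 0) return(paths[integer(0)])
  fe <- vapply(paths, function(p) p$floored_energy, numeric(1))
  if (n > length(paths)) {
    warning("requested ", n, " paths but only ", length(paths),
            " available; returning all")
    n <- length(paths)
  }
  ord <- order(fe, seq_along(fe))
  paths[ord[seq_len(n)]]
}

#' Cluster folding paths on a precomputed distance matrix
#'
#' Hierarchical density-based clustering (HDBSCAN) on the pairwise path
#' distance matrix: single-linkage on mutual-reachability distances,
#' condensed-tree construction with the given minimum cluster size, and
#' excess-of-mass cluster selection. Points in no selected cluster are
#' noise (label -1). Deterministic for fixed inputs; with fewer paths than
#' `min_cluster_size` everything is noise.
#'
#' @param D symmetric distance matrix (e.g. from [frechet_matrix()]).
#' @param min_cluster_size smallest cluster size, default 5.
#' @param min_samples neighbourhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @return Integer vector of cluster labels (`1, 2, ...`; `-1` = noise).
#' @export
cluster_paths <- function(D, min_cluster_size = 5, min_samples = NULL) {
  D <- unclass(as.matrix(D))
  hdbscan_labels(D, min_cluster_size,
                 if (is.null(min_samples)) min_cluster_size else min_samples)
}

#' Prune a track to its folding transition segment
#'
#' Returns the contiguous segment from the last frame in the unfolded
#' regime (both \eqn{\chi} below `lower`) to the first subsequent frame in
#' the folded regime (both \eqn{\chi} above `upper`). If a regime is never
#' visited an empty segment is returned with a warning.
#'
#' @param track matrix of `(chi1, chi2)` rows.
#' @param lower,upper regime thresholds (defaults 0.4 and 0.8).
#' @return The pruned track segment (possibly 0 rows).
#' @export
prune_transition_segment <- function(track, lower = 0.4, upper = 0.8) {
  track <- as.matrix(track)
  folded <- which(track[, 1] > upper & track[, 2] > upper)
  if (length(folded) == 0L) {
    warning("track never reaches the folded regime")
    return(track[integer(0), , drop = FALSE])
  }
  unfolded <- which(track[, 1] < lower & track[, 2] < lower)
  u <- min(folded)
  unfolded <- unfolded[unfolded <= u]
  if (length(unfolded) == 0L) {
    warning("track never visits the unfolded regime before folding")
    return(track[integer(0), , drop = FALSE])
  }
  s <- max(unfolded)
  track[s:u, , drop = FALSE]
}

#' Gridded occupancy of order-parameter space
#'
#' 2-D histogram of `(chi1, chi2)` occupancy over a set of track segments,
#' written as tabular text for plotting.
#'
#' @param tracks list of track matrices.
#' @param breaks number of grid cells per axis on `[0, 1]`.
#' @return Data frame with columns `chi1`, `chi2`, `count`.
#' @export
chi_occupancy_grid <- function(tracks, breaks = 25) {
  pts <- do.call(rbind, tracks)
  edges <- seq(0, 1, length.out = breaks + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  b1 <- pmin(pmax(findInterval(pts[, 1], edges, all.inside = TRUE), 1),
             breaks)
  b2 <- pmin(pmax(findInterval(pts[, 2], edges, all.inside = TRUE), 1),
             breaks)
  counts <- table(factor(b1, levels = 1:breaks),
                  factor(b2, levels = 1:breaks))
  data.frame(chi1 = rep(mids, times = breaks),
             chi2 = rep(mids, each = breaks),
             count = as.vector(counts))
}

#' TM-score of two equal-length bead chains
#'
#' Template-modeling score
#' \deqn{TM = \max \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0(L))^2}},
#' \eqn{d_0(L) = 1.24 (L - 15)^{1/3} - 1.8}, maximized over superpositions
#' by iterative least-squares (Kabsch) fitting on the subset of residues
#' currently within a distance cutoff, as in the standard TM-score
#' heuristic. No alignment search is performed: residue i of `confA`
#' corresponds to residue i of `confB`. For chains of 15 or fewer residues
#' (or whenever the formula goes below it) `d0` is clamped to 0.5 with a
#' warning.
#'
#' @param confA,confB conformations of equal length.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(confA, confB) {
  A <- as_conformation(confA)
  B <- as_conformation(confB, nrow(A))
  L <- nrow(A)
  d0 <- 1.24 * (L - 15)^(1/3) - 1.8
  if (L <= 15 || !is.finite(d0) || d0 < 0.5) {
    warning("chain too short for the d0 formula; clamping d0 to 0.5")
    d0 <- 0.5
  }
  score_from <- function(sub) {
    fit <- kabsch_fit(A[sub, , drop = FALSE], B[sub, , drop = FALSE])
    Bfit <- sweep(B, 2L, fit$center_b) %*% fit$rotation
    Bfit <- sweep(Bfit, 2L, fit$center_a, "+")
    d <- sqrt(rowSums((A - Bfit)^2))
    list(score = mean(1 / (1 + (d / d0)^2)), d = d)
  }
  best <- -Inf
  # several cutoff ladders, as in the reference heuristic
  for (init_len in unique(pmax(4L, c(L, L %/% 2, L %/% 4)))) {
    sub <- seq_len(init_len)
    prev <- integer(0)
    for (it in 1:30) {
      res <- score_from(sub)
      best <- max(best, res$score)
      cutoff <- max(d0, 4.5)
      nsub <- which(res$d < cutoff)
      while (length(nsub) < 4L && cutoff < 50) {
        cutoff <- cutoff + 0.5
        nsub <- which(res$d < cutoff)
      }
      if (length(nsub) < 4L || identical(nsub, prev)) break
      prev <- sub
      sub <- nsub
    }
  }
  best
}

# least-squares superposition of b onto a (equal-row matrices)
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, center_a = ca, center_b = cb)
}

#' Compare contact-map metrics against the TM-score on synthetic pairs
#'
#' Generates structure pairs by perturbing local minima of a BLN system
#' with short MD bursts of varying temperature and duration (followed by
#' minimization), then measures the Spearman rank correlation of the SCH
#' and Hamming contact-map distances against the real-space TM-score. A
#' contact-map metric that tracks real-space similarity should correlate
#' (negatively) with TM; the SCH metric is expected to correlate more
#' strongly than Hamming.
#'
#' @param minima_db list of local-minimum conformations.
#' @param seq,params the BLN system.
#' @param n_pairs number of structure pairs.
#' @param seed integer seed.
#' @param temperatures MD burst temperatures sampled per pair.
#' @param durations MD burst durations (tu) sampled per pair.
#' @return A list with `table` (per-pair metrics) and `spearman`
#'   (named correlations of SCH and Hamming vs TM).
#' @export
validate_sch_metric <- function(minima_db, seq, params = bln_parameters(),
                                n_pairs = 200, seed = NULL,
                                temperatures = c(0.2, 0.5, 1, 1.5),
                                durations = c(1, 3, 10)) {
  if (!is.null(seed)) set.seed(seed)
  confs <- lapply(minima_db, function(m)
    if (is.list(m)) m$conformation else m)
  efn <- bln_energy_fn(seq, params)
  gfn <- bln_gradient_fn(seq, params)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    start <- confs[[sample.int(length(confs), 1L)]]
    temp <- sample(temperatures, 1L)
    dur <- sample(durations, 1L)
    traj <- run_md_nvt(start, seq, params,
                       md_config(temperature = temp, duration = dur,
                                 stride = .Machine$integer.max))
    pert <- minimize_geometry(traj$coords, efn, gfn, tol = 1e-4,
                              max_iter = 2e4)$conformation
    GA <- map_from_conformation(start)
    GB <- map_from_conformation(pert)
    rows[[i]] <- data.frame(
      pair = i, temperature = temp, duration = dur,
      sch = sch_distance(GA, GB),
      hamming = hamming_distance(GA, GB),
      tm = tm_score(start, pert))
  }
  tab <- do.call(rbind, rows)
  sp <- c(sch = cor(tab$sch, tab$tm, method = "spearman"),
          hamming = cor(tab$hamming, tab$tm, method = "spearman"))
  list(table = tab, spearman = sp)
}
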