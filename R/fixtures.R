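#' Extended chain conformation
#'
#' Nearly collinear chain with exact bond lengths and a tiny deterministic
#' transverse dither (a slow precessing curvature) so that no bond angle is
#' exactly straight and every dihedral is defined -- the gradient of the
#' BLN potential is then finite everywhere. Contacts of the output are
#' exactly the pairs within two bonds.
#'
#' @param n number of beads (>= 2).
#' @param bond_length bond length (A).
#' @param dither transverse dither amplitude (dimensionless direction
#'   component).
#' @return N x 3 coordinate matrix.
#' @export
extended_chain <- function(n, bond_length = 3.8, dither = 0.02) {
  stopifnot(n >= 2)
  coords <- matrix(0, n, 3)
  for (i in 2:n) {
    ang <- 2.399963 * (i - 2)  # golden-angle precession of the dither
    dir <- c(1, dither * cos(ang), dither * sin(ang))
    dir <- dir / sqrt(sum(dir^2))
    coords[i, ] <- coords[i - 1, ] + bond_length * dir
  }
  coords
}

#' Toy bead-protein specification
#'
#' Declarative segment list mapping to bead labels and dihedral classes.
#' Each segment is a list with `type` (`"strand"`, `"turn"`, `"helix"` or
#' `"loop"`) and `length`. Strands are hydrophobic (`B`) with extended
#' (`E`) dihedrals; turns/loops are neutral (`N`) with turn (`T`)
#' dihedrals; helices carry a sparse amphipathic hydrophobic stripe
#' (pattern `LLBLLLLB`) with helical (`H`) dihedrals, so the helix packs
#' against the hairpins without driving a global hydrophobic collapse.
#'
#' @param segments list of segment descriptors.
#' @param seed integer seed (reserved for randomized motifs; the default
#'   mapping is deterministic).
#' @return An object of class `toy_protein_spec`.
#' @export
toy_protein_spec <- function(segments, seed = 1L) {
  stopifnot(length(segments) >= 1L)
  for (s in segments) {
    stopifnot(is.list(s), s$type %in% c("strand", "turn", "helix", "loop"),
              s$length >= 1)
  }
  structure(list(segments = segments, seed = as.integer(seed)),
            class = "toy_protein_spec")
}

#' Two-hairpin + helix toy protein
#'
#' The canonical synthetic test protein: a 56-bead chain whose architecture
#' mirrors a small alpha/beta domain -- an N-terminal beta-hairpin, a
#' central alpha-helix, and a C-terminal beta-hairpin. Returns the bead
#' sequence and the two declared hairpin residue ranges used by the
#' order-parameter analysis. An externally supplied bead sequence file (see
#' [read_bead_sequence()]) can replace it for reproduction work on a
#' specific published system.
#'
#' @param spec a [toy_protein_spec()]; the default builds the 56-bead
#'   two-hairpin + helix motif.
#' @return A list with `seq` (a [bead_sequence()]), `hairpins` (list of two
#'   residue-index ranges) and `spec`.
#' @export
make_toy_protein <- function(spec = NULL) {
  if (is.null(spec)) {
    spec <- toy_protein_spec(list(
      list(type = "strand", length = 8),
      list(type = "turn", length = 2),
      list(type = "strand", length = 8),
      list(type = "loop", length = 3),
      list(type = "helix", length = 14),
      list(type = "loop", length = 3),
      list(type = "strand", length = 8),
      list(type = "turn", length = 2),
      list(type = "strand", length = 8)))
  }
  labels <- character(0)
  classes <- character(0)
  bounds <- list()
  pos <- 0L
  helix_pat <- c("L", "L", "B", "L", "L", "L", "L", "B")
  for (s in spec$segments) {
    len <- s$length
    seg_labels <- switch(s$type,
      strand = rep("B", len),
      turn = rep("N", len),
      loop = rep("N", len),
      helix = rep(helix_pat, length.out = len))
    seg_class <- switch(s$type, strand = "E", turn = "T", loop = "T",
                        helix = "H")
    labels <- c(labels, seg_labels)
    classes <- c(classes, rep(seg_class, len))
    bounds[[length(bounds) + 1L]] <-
      list(type = s$type, range = (pos + 1L):(pos + len))
    pos <- pos + len
  }
  n <- length(labels)
  # one dihedral class per dihedral (beads i..i+3): use the class of bead i+1
  dihedral_classes <- classes[2:(n - 2L)]
  bseq <- bead_sequence(labels, dihedral_classes)
  # hairpins: contiguous strand-turn-strand blocks
  hairpins <- list()
  i <- 1L
  while (i + 2L <= length(bounds)) {
    if (bounds[[i]]$type == "strand" &&
        bounds[[i + 1L]]$type == "turn" &&
        bounds[[i + 2L]]$type == "strand") {
      hairpins[[length(hairpins) + 1L]] <-
        range(c(bounds[[i]]$range, bounds[[i + 2L]]$range))
      hairpins[[length(hairpins)]] <-
        hairpins[[length(hairpins)]][1]:hairpins[[length(hairpins)]][2]
      i <- i + 3L
    } else i <- i + 1L
  }
  list(seq = bseq, hairpins = hairpins, spec = spec)
}

#' Idealized native structure of the toy protein
#'
#' Constructs target coordinates for the two-hairpin + helix motif from
#' idealized secondary-structure geometry -- antiparallel strand pairs
#' (3.63 A rise, 0.55 A zigzag, 5 A sheet separation), an ideal helix
#' (1.5 A rise per residue, radius chosen for the 3.8 A bond length) --
#' with the three blocks stacked far enough apart that the two hairpins
#' share no contacts, then relaxes the construct to the nearest local
#' minimum of the BLN potential. This mirrors how such bead proteins are
#' designed: the dihedral classes of the sequence are assigned from a
#' target native structure, and that target (not whatever deeper collapsed
#' minimum the landscape may hold) defines the folded state. Deterministic.
#'
#' @param toy a [make_toy_protein()] result (the default 56-bead motif).
#' @param params a [bln_parameters()] set.
#' @return A list with `conformation` (the relaxed native) and `energy`.
#' @export
toy_native_structure <- function(toy = make_toy_protein(),
                                 params = bln_parameters()) {
  segs <- toy$spec$segments
  types <- vapply(segs, `[[`, character(1), "type")
  lens <- vapply(segs, function(s) as.integer(s$length), integer(1))
  stopifnot(identical(types, c("strand", "turn", "strand", "loop", "helix",
                               "loop", "strand", "turn", "strand")))
  rise_s <- 3.63; zig <- 0.55; sheet_gap <- 5
  strand <- function(n, x0, y, dirx) {
    cbind(x0 + dirx * rise_s * (0:(n - 1)), y,
          zig * (-1)^(0:(n - 1)))
  }
  bridge <- function(n, from, to) {
    # evenly spaced beads between two anchor points, bowed slightly out
    f <- seq_len(n) / (n + 1)
    out <- (1 - f) %o% from + f %o% to
    out[, 3] <- out[, 3] + 1.5 * sin(pi * f)
    out
  }
  helix <- function(n, x0, yc, zc) {
    rise <- 1.5; dphi <- 100 * pi / 180
    rad <- sqrt(3.8^2 - rise^2) / (2 * sin(dphi / 2))
    cbind(x0 + rise * (0:(n - 1)), yc + rad * cos(dphi * (0:(n - 1))),
          zc + rad * sin(dphi * (0:(n - 1))))
  }
  hairpin <- function(n1, nt, n2, x0, y0, dirx) {
    s1 <- strand(n1, x0, y0, dirx)
    xe <- s1[n1, 1]
    s2 <- strand(n2, xe, y0 + sheet_gap, -dirx)
    tn <- bridge(nt, s1[n1, ] + c(dirx * 2, 0, 0),
                 s2[1, ] + c(dirx * 2, 0, 0))
    rbind(s1, tn, s2)
  }
  # linear arrangement along x: hairpin1 | helix | hairpin2, so the two
  # hairpins are far apart and share no contacts (structural independence
  # of the two order parameters)
  len1 <- rise_s * (lens[1] - 1)
  h1 <- hairpin(lens[1], lens[2], lens[3], len1, 0, -1)
  hx <- helix(lens[5], len1 + 3, 2.5, 0)
  l1 <- bridge(lens[4], h1[nrow(h1), ], hx[1, ])
  h2 <- hairpin(lens[7], lens[8], lens[9], hx[nrow(hx), 1] + 3, 0, 1)
  l2 <- bridge(lens[6], hx[nrow(hx), ], h2[1, ])
  coords <- rbind(h1, l1, hx, l2, h2)
  res <- minimize_geometry(coords, bln_energy_fn(toy$seq, params),
                           bln_gradient_fn(toy$seq, params))
  list(conformation = res$conformation, energy = res$energy)
}

#' Build a database of local minima by annealing with restarts
#'
#' Repeated [anneal_to_minimum()] runs, each re-seeded from the current
#' best structure, until the best-known energy has not improved for
#' `stop_after` consecutive restarts (or `n_restarts` is exhausted).
#' Minima are deduplicated by energy (within `energy_tol`) and RMSD after
#' least-squares superposition (within `rmsd_tol`), and returned sorted by
#' energy.
#'
#' @param seq,params the BLN system.
#' @param n_restarts restart budget.
#' @param stop_after restarts without improvement before stopping.
#' @param seed integer seed.
#' @param start starting conformation; default extended chain.
#' @param energy_tol,rmsd_tol deduplication thresholds.
#' @param ... passed to [anneal_to_minimum()].
#' @return A list of `(conformation, energy)` records, lowest energy first.
#' @export
build_minima_database <- function(seq, params = bln_parameters(),
                                  n_restarts = 100, stop_after = 20,
                                  seed = NULL, start = NULL,
                                  energy_tol = 1e-6, rmsd_tol = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- extended_chain(length(seq))
  db <- list()
  best_e <- Inf
  best_conf <- start
  unimproved <- 0L
  for (r in seq_len(n_restarts)) {
    res <- tryCatch(
      anneal_to_minimum(best_conf, seq, params, seed = NULL, ...),
      error = function(e) e)
    if (inherits(res, "error") || isTRUE(res$failed)) next
    dup <- FALSE
    for (m in db) {
      if (abs(m$energy - res$energy) < energy_tol &&
          superposed_rmsd(m$conformation, res$conformation) < rmsd_tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) db[[length(db) + 1L]] <-
        list(conformation = res$conformation, energy = res$energy)
    if (res$energy < best_e - energy_tol) {
      best_e <- res$energy
      best_conf <- res$conformation
      unimproved <- 0L
    } else {
      unimproved <- unimproved + 1L
      if (unimproved >= stop_after) break
    }
  }
  db[order(vapply(db, function(m) m$energy, numeric(1)))]
}

#' RMSD after least-squares superposition
#'
#' @param a,b equal-size N x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(a, b) {
  a <- as_conformation(a); b <- as_conformation(b, nrow(a))
  fit <- kabsch_fit(a, b)
  bfit <- sweep(sweep(b, 2L, fit$center_b) %*% fit$rotation, 2L,
                fit$center_a, "+")
  sqrt(mean(rowSums((a - bfit)^2)))
}

#' Bit-flip-perturbed reconstruction targets
#'
#' Each target pairs a random database minimum (the reconstruction start)
#' with its own contact map perturbed by `n_flips` random mutable-pair bit
#' flips -- a mixture of physical and nonphysical target maps.
#'
#' @param db minima database (list of `(conformation, energy)` records or
#'   plain conformations).
#' @param n_flips flips per target.
#' @param n_targets number of targets.
#' @param seed integer seed.
#' @param r_c contact cutoff.
#' @return List of `list(start, target)` records.
#' @export
perturb_targets_bitflip <- function(db, n_flips = 5, n_targets = 100,
                                    seed = NULL, r_c = 8) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(db) > 0)
  confs <- lapply(db, function(m) if (is.list(m)) m$conformation else m)
  lapply(seq_len(n_targets), function(i) {
    start <- confs[[sample.int(length(confs), 1L)]]
    G0 <- map_from_conformation(start, r_c)
    target <- G0
    if (n_flips > 0) {
      pairs <- mutable_pairs(nrow(start))
      flips <- pairs[sample.int(nrow(pairs), n_flips), , drop = FALSE]
      target <- apply_bit_flips(G0, flips)
    }
    list(start = start, target = target)
  })
}

#' Physically realizable reconstruction targets from high-T dynamics
#'
#' Each target pairs a random database minimum with the contact map of a
#' structure obtained by a short high-temperature MD burst followed by
#' minimization -- by construction the map of a physical local minimum.
#'
#' @inheritParams perturb_targets_bitflip
#' @param seq,params the BLN system.
#' @param temperature MD burst temperature (\eqn{\epsilon}).
#' @param duration MD burst length (tu).
#' @return List of `list(start, target)` records.
#' @export
perturb_targets_md <- function(db, seq, params = bln_parameters(),
                               temperature = 1.0, duration = 10,
                               n_targets = 100, seed = NULL, r_c = 8) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(db) > 0)
  confs <- lapply(db, function(m) if (is.list(m)) m$conformation else m)
  efn <- bln_energy_fn(seq, params)
  gfn <- bln_gradient_fn(seq, params)
  lapply(seq_len(n_targets), function(i) {
    start <- confs[[sample.int(length(confs), 1L)]]
    traj <- run_md_nvt(start, seq, params,
                       md_config(temperature = temperature,
                                 duration = duration,
                                 stride = .Machine$integer.max))
    minres <- minimize_geometry(traj$coords, efn, gfn, tol = 1e-6,
                                max_iter = 5e4)
    list(start = start,
         target = map_from_conformation(minres$conformation, r_c))
  })
}
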