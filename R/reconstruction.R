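#' Graph-restraining-potential configurations
#'
#' `grp_new_config()` parameterizes the one-sided harmonic GRP: a single
#' force constant `k` drives contact pairs below `r_con`, non-contact pairs
#' above `r_con`, and every nonbonded pair above the steric floor
#' `r_steric`; each term acts only when its constraint is violated, so the
#' potential is zero exactly when the conformation satisfies the map.
#' `grp_old_config()` parameterizes the legacy GRP kept as a baseline:
#' harmonic contact wells `kappa1 (r - r_con)^2` plus a bounded logistic
#' repulsion `kappa2 * sigmoid((r_max^2 - r^2)/gamma)` for non-contacts.
#'
#' @param k harmonic force constant (\eqn{\epsilon} A^-2).
#' @param r_con contact threshold distance (A).
#' @param r_steric steric floor (A).
#' @param margin enforcement margin (A): contacts are pulled below
#'   `r_con - margin` and non-contacts pushed above `r_con + margin`, so a
#'   subsequent relaxation under the physical potential alone does not let
#'   marginal pairs drift back across the cutoff. Zero gives the plain
#'   one-sided form; the reconstruction routines default to 0.25 A.
#' @return A config list with class `grp_new_config` / `grp_old_config`.
#' @export
grp_new_config <- function(k = 100, r_con = 8, r_steric = 2, margin = 0) {
  stopifnot(k > 0, r_steric < r_con, margin >= 0, margin < r_con)
  structure(list(k = k, r_con = r_con, r_steric = r_steric,
                 margin = margin),
            class = "grp_new_config")
}

#' @rdname grp_new_config
#' @param kappa1 contact well force constant (\eqn{\epsilon} A^-2).
#' @param kappa2 repulsion height (\eqn{\epsilon}).
#' @param gamma logistic width (A^2).
#' @param r_min,r_max lower/upper close-contact thresholds (A); the contact
#'   target distance is their midpoint.
#' @export
grp_old_config <- function(kappa1 = 1, kappa2 = 6, gamma = 6,
                           r_min = 2, r_max = 8) {
  stopifnot(r_min < r_max)
  structure(list(kappa1 = kappa1, kappa2 = kappa2, gamma = gamma,
                 r_min = r_min, r_max = r_max,
                 r_con = (r_min + r_max) / 2),
            class = "grp_old_config")
}

#' One-sided harmonic graph-restraining potential
#'
#' @param conf N x 3 coordinate matrix.
#' @param G target contact map.
#' @param cfg a [grp_new_config()].
#' @return Energy in \eqn{\epsilon} (`grp_new_energy`) or the N x 3
#'   gradient (`grp_new_gradient`).
#' @export
grp_new_energy <- function(conf, G, cfg = grp_new_config()) {
  conf <- as_conformation(conf, nrow(G))
  .grp_new_cpp(conf, check_map(G), cfg$k, cfg$r_con, cfg$r_steric,
               FALSE, cfg$margin)$energy
}

#' @rdname grp_new_energy
#' @export
grp_new_gradient <- function(conf, G, cfg = grp_new_config()) {
  conf <- as_conformation(conf, nrow(G))
  .grp_new_cpp(conf, check_map(G), cfg$k, cfg$r_con, cfg$r_steric,
               TRUE, cfg$margin)$gradient
}

#' Legacy logistic graph-restraining potential
#'
#' @param conf N x 3 coordinate matrix.
#' @param G target contact map.
#' @param cfg a [grp_old_config()].
#' @return Energy in \eqn{\epsilon} or the N x 3 gradient.
#' @export
grp_old_energy <- function(conf, G, cfg = grp_old_config()) {
  conf <- as_conformation(conf, nrow(G))
  .grp_old_cpp(conf, check_map(G), cfg$kappa1, cfg$kappa2, cfg$gamma,
               cfg$r_con, cfg$r_max, FALSE)$energy
}

#' @rdname grp_old_energy
#' @export
grp_old_gradient <- function(conf, G, cfg = grp_old_config()) {
  conf <- as_conformation(conf, nrow(G))
  .grp_old_cpp(conf, check_map(G), cfg$kappa1, cfg$kappa2, cfg$gamma,
               cfg$r_con, cfg$r_max, TRUE)$gradient
}

grp_energy_fn <- function(G, grp) {
  G <- check_map(G)
  if (inherits(grp, "grp_new_config")) {
    function(conf) .grp_new_cpp(conf, G, grp$k, grp$r_con, grp$r_steric,
                                FALSE, grp$margin)$energy
  } else {
    function(conf) .grp_old_cpp(conf, G, grp$kappa1, grp$kappa2, grp$gamma,
                                grp$r_con, grp$r_max, FALSE)$energy
  }
}

grp_gradient_fn <- function(G, grp) {
  G <- check_map(G)
  if (inherits(grp, "grp_new_config")) {
    function(conf) .grp_new_cpp(conf, G, grp$k, grp$r_con, grp$r_steric,
                                TRUE, grp$margin)$gradient
  } else {
    function(conf) .grp_old_cpp(conf, G, grp$kappa1, grp$kappa2, grp$gamma,
                                grp$r_con, grp$r_max, TRUE)$gradient
  }
}

reconstruction_result <- function(conformation, target, r_c, failed,
                                  diagnostics) {
  if (failed || is.null(conformation) || !all(is.finite(conformation))) {
    return(structure(list(conformation = conformation, achieved_map = NULL,
                          sch_to_target = NA_real_, failed = TRUE,
                          diagnostics = diagnostics),
                     class = "reconstruction_result"))
  }
  amap <- map_from_conformation(conformation, r_c)
  structure(list(conformation = conformation, achieved_map = amap,
                 sch_to_target = sch_distance(amap, target),
                 failed = FALSE, diagnostics = diagnostics),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat("reconstruction:", if (x$failed) "FAILED" else "ok",
      " SCH to target =", format(x$sch_to_target, digits = 4),
      "\n  ", x$diagnostics, "\n")
  invisible(x)
}

# failure definition shared by both reconstruction routes
recon_failed <- function(conf, energy, min_dist_floor = 0.5) {
  if (is.null(conf) || !all(is.finite(conf))) return("non-finite coordinates")
  if (!is.finite(energy)) return("non-finite energy")
  if (.min_pair_dist_cpp(conf, 1L) < min_dist_floor)
    return(sprintf("pair distance below %.2f A in output", min_dist_floor))
  NULL
}

# physical potential guarded by the map-independent steric floor (zero for
# any structure without sub-2-A overlaps; keeps the free relaxation out of
# the angle-collapse channel between next-nearest beads)
physical_energy_fn <- function(seq, params, grp) {
  vfn <- bln_energy_fn(seq, params)
  k <- if (!is.null(grp$k)) grp$k else 100
  rs <- if (!is.null(grp$r_steric)) grp$r_steric else 2
  function(conf) vfn(conf) + .steric_floor_cpp(conf, k, rs, FALSE)$energy
}

physical_gradient_fn <- function(seq, params, grp) {
  vgr <- bln_gradient_fn(seq, params)
  k <- if (!is.null(grp$k)) grp$k else 100
  rs <- if (!is.null(grp$r_steric)) grp$r_steric else 2
  function(conf) vgr(conf) + .steric_floor_cpp(conf, k, rs, TRUE)$gradient
}

#' Back-map a contact map by restrained minimization
#'
#' Minimizes the mixed surface `V(r) + W(r, G)` -- physical BLN potential
#' plus graph-restraining potential -- from a starting geometry (typically
#' the previous folding intermediate), then minimizes `V` alone so the
#' result is a physical structure. When `kicks > 0` and the achieved map
#' still differs from the target, the route restarts up to that many times
#' from a crankshaft Monte Carlo walk on the restraint potential (a
#' stochastic kick along the map-feasible manifold), keeping the best
#' result; this recovers exactly realizable maps whose basin the direct
#' projection misses. Failures (non-finite values, optimizer abort, or any
#' pair distance below 0.5 A in the output) are captured in the result,
#' not raised.
#'
#' @param conf0 starting N x 3 conformation.
#' @param G target contact map.
#' @param seq a [bead_sequence()].
#' @param params a [bln_parameters()] set.
#' @param grp a [grp_new_config()] or [grp_old_config()].
#' @param tol,max_iter passed to [minimize_geometry()].
#' @param kicks number of crankshaft-restart rounds (0 = single shot).
#' @param kick_steps,kick_T MC steps and starting temperature per kick.
#' @param retries jittered restarts after a numerical failure: the whole
#'   route is retried from the start geometry plus small Gaussian noise
#'   (0.05 A), which breaks the rare symmetric jams in which two beads two
#'   positions apart collapse onto each other; a failure is reported only
#'   if every retry fails.
#' @return A `reconstruction_result`: `conformation`, `achieved_map`,
#'   `sch_to_target`, `failed`, `diagnostics`.
#' @export
reconstruct_minimize <- function(conf0, G, seq, params = bln_parameters(),
                                 grp = grp_new_config(margin = 0.25),
                                 tol = 1e-6, max_iter = 5e4, kicks = 0,
                                 kick_steps = 5000, kick_T = 0.5,
                                 retries = 2) {
  G <- check_map(G)
  conf0 <- as_conformation(conf0, nrow(G))
  best <- recon_minimize_once(conf0, G, seq, params, grp, tol, max_iter)
  attempt <- 0
  while (best$failed && attempt < retries) {
    attempt <- attempt + 1
    jit <- conf0 + matrix(rnorm(length(conf0), sd = 0.05), nrow(conf0), 3)
    best <- recon_minimize_once(jit, G, seq, params, grp, tol, max_iter)
  }
  if (kicks > 0 && inherits(grp, "grp_new_config")) {
    x <- if (best$failed) conf0 else best$conformation
    for (r in seq_len(kicks)) {
      if (!best$failed && best$sch_to_target == 0) break
      mc <- .crankshaft_cpp(x, G, grp$k, grp$r_con, grp$r_steric,
                            as.integer(kick_steps), kick_T, 0.01,
                            grp$margin)
      res <- recon_minimize_once(mc$coords, G, seq, params, grp, tol,
                                 max_iter)
      if (!res$failed &&
          (best$failed || res$sch_to_target < best$sch_to_target)) {
        best <- res
      }
      if (!res$failed) x <- res$conformation
    }
  }
  best
}

recon_minimize_once <- function(conf0, G, seq, params, grp, tol, max_iter) {
  r_c <- if (!is.null(grp$r_con)) grp$r_con else 8
  vfn <- bln_energy_fn(seq, params)
  vgr <- bln_gradient_fn(seq, params)
  wfn <- grp_energy_fn(G, grp)
  wgr <- grp_gradient_fn(G, grp)
  tot_fn <- function(conf) vfn(conf) + wfn(conf)
  tot_gr <- function(conf) vgr(conf) + wgr(conf)
  stage1 <- minimize_geometry(conf0, tot_fn, tot_gr, tol = tol,
                              max_iter = max_iter)
  if (stage1$failed) {
    return(reconstruction_result(stage1$conformation, G, r_c, TRUE,
                                 paste("restrained stage:",
                                       stage1$diagnostics)))
  }
  sfn <- physical_energy_fn(seq, params, grp)
  sgr <- physical_gradient_fn(seq, params, grp)
  stage2 <- minimize_geometry(stage1$conformation, sfn, sgr, tol = tol,
                              max_iter = max_iter)
  if (stage2$failed) {
    return(reconstruction_result(stage2$conformation, G, r_c, TRUE,
                                 paste("physical stage:",
                                       stage2$diagnostics)))
  }
  bad <- recon_failed(stage2$conformation, stage2$energy)
  reconstruction_result(stage2$conformation, G, r_c, !is.null(bad),
                        if (is.null(bad)) "ok" else bad)
}

#' Back-map a contact map by crankshaft Monte Carlo
#'
#' Metropolis Monte Carlo on the graph-restraining potential using
#' off-lattice crankshaft moves: a randomly chosen interior bead is rotated
#' by a uniform angle in `[-pi, pi]` about the axis through its two chain
#' neighbours (an isometry for the distances to both neighbours); terminal
#' beads pivot about the terminal bond axis. Proposals placing any nonbonded
#' pair below the steric floor are rejected outright. The temperature decays
#' geometrically from `T0` to `T1`; a final minimization under the physical
#' BLN potential yields the returned structure.
#'
#' @inheritParams reconstruct_minimize
#' @param grp a [grp_new_config()].
#' @param n_steps number of MC steps.
#' @param T0,T1 initial and final MC temperatures (objective units).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param retries jittered restarts after a numerical failure (see
#'   [reconstruct_minimize()]).
#' @return A `reconstruction_result`.
#' @export
reconstruct_crankshaft <- function(conf0, G, seq, params = bln_parameters(),
                                   grp = grp_new_config(margin = 0.25),
                                   n_steps = 1e5,
                                   T0 = 1.0, T1 = 0.01, seed = NULL,
                                   tol = 1e-6, max_iter = 5e4,
                                   retries = 2) {
  G <- check_map(G)
  conf0 <- as_conformation(conf0, nrow(G))
  if (!is.null(seed)) set.seed(seed)
  res <- recon_crankshaft_once(conf0, G, seq, params, grp, n_steps, T0, T1,
                               tol, max_iter)
  attempt <- 0
  while (res$failed && attempt < retries) {
    attempt <- attempt + 1
    jit <- conf0 + matrix(rnorm(length(conf0), sd = 0.05), nrow(conf0), 3)
    res <- recon_crankshaft_once(jit, G, seq, params, grp, n_steps, T0, T1,
                                 tol, max_iter)
  }
  res
}

recon_crankshaft_once <- function(conf0, G, seq, params, grp, n_steps, T0,
                                  T1, tol, max_iter) {
  mc <- .crankshaft_cpp(conf0, G, grp$k, grp$r_con, grp$r_steric,
                        as.integer(n_steps), T0, T1, grp$margin)
  stage2 <- minimize_geometry(mc$coords, physical_energy_fn(seq, params, grp),
                              physical_gradient_fn(seq, params, grp),
                              tol = tol, max_iter = max_iter)
  if (stage2$failed) {
    return(reconstruction_result(stage2$conformation, G, grp$r_con, TRUE,
                                 paste("physical stage:",
                                       stage2$diagnostics)))
  }
  bad <- recon_failed(stage2$conformation, stage2$energy)
  reconstruction_result(stage2$conformation, G, grp$r_con, !is.null(bad),
                        if (is.null(bad))
                          sprintf("ok (%d/%d MC moves accepted)",
                                  mc$accepted, mc$n_steps) else bad)
}

#' Benchmark reconstruction methods on bit-flip-perturbed targets
#'
#' For each trial a random structure is drawn from a database of local
#' minima, its contact map is perturbed by `n_flips` random mutable-pair bit
#' flips, and the perturbed map is reconstructed from the unperturbed
#' structure with the chosen method. Reports the percentage of numerical
#' failures and the mean SCH distance between the achieved and target maps
#' (the two columns of the reconstruction benchmark table), plus the
#' per-trial records.
#'
#' @param minima_db list of conformations (or of lists with a
#'   `conformation` element), e.g. from [build_minima_database()].
#' @param seq,params the BLN system.
#' @param n_trials number of trials.
#' @param n_flips random bit flips per target.
#' @param method `"new_grp"`, `"crankshaft"` or `"old_grp"`.
#' @param seed integer seed.
#' @param targets optional precomputed list of `(start, target)` pairs, e.g.
#'   from [perturb_targets_bitflip()] or [perturb_targets_md()]; overrides
#'   `n_trials`/`n_flips`.
#' @param ... further arguments to the reconstruction routine.
#' @return An object of class `reconstruction_benchmark`: list with
#'   `summary` (data.frame: method, pct_failures, mean_sch) and `trials`
#'   (one row per trial).
#' @export
benchmark_reconstruction <- function(minima_db, seq,
                                     params = bln_parameters(),
                                     n_trials = 500, n_flips = 5,
                                     method = c("new_grp", "crankshaft",
                                                "old_grp"),
                                     seed = NULL, targets = NULL, ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  confs <- lapply(minima_db, function(m)
    if (is.list(m)) m$conformation else m)
  if (is.null(targets)) {
    if (length(confs) == 0L && n_trials > 0)
      stop("empty minima database")
    targets <- lapply(seq_len(n_trials), function(i) {
      start <- confs[[sample.int(length(confs), 1L)]]
      G0 <- map_from_conformation(start)
      pairs <- mutable_pairs(nrow(start))
      flips <- pairs[sample.int(nrow(pairs), n_flips), , drop = FALSE]
      list(start = start, target = apply_bit_flips(G0, flips))
    })
  }
  n_trials <- length(targets)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tg <- targets[[i]]
    res <- switch(method,
      new_grp = reconstruct_minimize(tg$start, tg$target, seq, params,
                                     ...),
      old_grp = reconstruct_minimize(tg$start, tg$target, seq, params,
                                     grp = grp_old_config(), ...),
      crankshaft = reconstruct_crankshaft(tg$start, tg$target, seq,
                                          params, ...))
    rows[[i]] <- data.frame(trial = i, method = method,
                            failed = res$failed,
                            sch_to_target = res$sch_to_target)
  }
  trials <- if (n_trials > 0) do.call(rbind, rows) else
    data.frame(trial = integer(0), method = character(0),
               failed = logical(0), sch_to_target = numeric(0))
  summary <- data.frame(
    method = method,
    pct_failures = if (n_trials > 0) 100 * mean(trials$failed) else NA_real_,
    mean_sch = if (n_trials > 0)
      mean(trials$sch_to_target[!trials$failed]) else NA_real_)
  structure(list(summary = summary, trials = trials),
            class = "reconstruction_benchmark")
}

#' @export
print.reconstruction_benchmark <- function(x, ...) {
  cat("Reconstruction benchmark (", nrow(x$trials), " trials)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report to a tabular text file
#'
#' @param x a `reconstruction_benchmark`.
#' @param file output path; per-trial rows, then a summary block.
#' @export
write_benchmark_report <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# per-trial records", con)
  write.table(x$trials, con, row.names = FALSE, sep = "\t", quote = FALSE)
  writeLines("# summary", con)
  write.table(x$summary, con, row.names = FALSE, sep = "\t", quote = FALSE)
  invisible(file)
}
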