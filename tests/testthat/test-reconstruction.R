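test_that("one-sided GRP evaluates its defining cases", {
  # single contact pair at 10 A: (100/2) * (10 - 8)^2
  conf <- rbind(c(0, 0, 0), c(3.3, 0, 0), c(6.6, 0, 0), c(10, 0, 0))
  G <- matrix(0L, 4, 4); G[1, 4] <- G[4, 1] <- 1L
  expect_equal(grp_new_energy(conf, G), 200)
  # satisfied constraints give exactly zero
  conf2 <- rbind(c(0, 0, 0), c(3.3, 0, 0), c(6.6, 0, 0), c(7, 2, 0))
  expect_equal(grp_new_energy(conf2, G), 0)
  # steric floor: contact pair at 1.5 A adds (100/2) * 0.5^2
  # (bead 4 placed so no other steric term engages)
  conf3 <- rbind(c(0, 0, 0), c(3.3, 0, 0), c(6.6, 0, 0), c(-1.5, 0, 0))
  expect_equal(grp_new_energy(conf3, G), 12.5)
})

test_that("one-sided GRP is C1 across its hinge points", {
  G <- matrix(0L, 4, 4); G[1, 4] <- G[4, 1] <- 1L
  cfg <- grp_new_config()
  place <- function(r) rbind(c(0, 0, 0), c(3.3, 1, 0), c(6.6, -1, 0),
                             c(r, 0, 0))
  for (r0 in c(cfg$r_con, cfg$r_steric)) {
    h <- 1e-5
    d_left <- (grp_new_energy(place(r0), G) -
               grp_new_energy(place(r0 - h), G)) / h
    d_right <- (grp_new_energy(place(r0 + h), G) -
                grp_new_energy(place(r0), G)) / h
    expect_lt(abs(d_left - d_right), 1e-2)
  }
  # gradient matches finite differences
  set.seed(70)
  conf <- matrix(rnorm(15, sd = 4), 5, 3)
  G5 <- random_contact_map(5, 0.5)
  g <- grp_new_gradient(conf, G5)
  for (i in 1:5) for (k in 1:3) {
    cp <- conf; cp[i, k] <- cp[i, k] + 1e-6
    cm <- conf; cm[i, k] <- cm[i, k] - 1e-6
    fd <- (grp_new_energy(cp, G5) - grp_new_energy(cm, G5)) / 2e-6
    expect_equal(g[i, k], fd, tolerance = 1e-4)
  }
})

test_that("GRP vanishes exactly when the conformation realizes the map", {
  set.seed(71)
  for (rep in 1:10) {
    conf <- extended_chain(9) + matrix(rnorm(27, sd = 1.5), 9, 3)
    G <- map_from_conformation(conf)
    expect_equal(grp_new_energy(conf, G), 0)
    # flipping any mutable pair makes it positive
    pairs <- mutable_pairs(9)
    fl <- pairs[sample(nrow(pairs), 1), , drop = FALSE]
    expect_gt(grp_new_energy(conf, apply_bit_flips(G, fl)), 0)
  }
})

test_that("legacy GRP matches its closed-form spot values", {
  cfg <- grp_old_config()  # r_con = 5, r_max = 8
  mk <- function(r) rbind(c(0, 0, 0), c(3.3, 1, 0), c(6.6, -1, 0),
                          c(r, 0, 0))
  G <- matrix(0L, 4, 4); G[1, 4] <- G[4, 1] <- 1L
  expect_equal(grp_old_energy(mk(cfg$r_con), G), 0)
  Gnone <- matrix(0L, 4, 4)
  # logistic midpoint at r = r_max: kappa2 * sigma(0) = 3
  e_mid <- grp_old_energy(mk(cfg$r_max), Gnone)
  e_mid_base <- grp_old_energy(mk(100), Gnone)  # far tail ~ 0
  expect_equal(e_mid - e_mid_base, 3, tolerance = 1e-3)
  expect_lt(e_mid_base, 1e-6)
})

test_that("restrained minimization honours fixed points and impossible targets", {
  fx <- fix_small10()
  conf0 <- fx$min$conformation
  G <- map_from_conformation(conf0)
  res <- reconstruct_minimize(conf0, G, fx$seq)
  expect_false(res$failed)
  expect_equal(res$sch_to_target, 0)
  expect_lt(superposed_rmsd(res$conformation, conf0), 0.05)
  # an all-pairs-contact target on a long chain cannot be embedded:
  # reconstruction completes (not failed) but cannot reach the map
  fx56 <- fix_toy56()
  n <- 56
  Gfull <- matrix(1L, n, n); diag(Gfull) <- 0L
  res2 <- reconstruct_minimize(fx56$db[[1]]$conformation, Gfull, fx56$seq,
                               tol = 1e-4, max_iter = 5000)
  expect_false(res2$failed)
  expect_gt(res2$sch_to_target, 0)
})

test_that("crankshaft moves preserve bond lengths and respect the target", {
  fx <- fix_small10()
  conf0 <- fx$min$conformation
  G <- map_from_conformation(conf0)
  set.seed(72)
  # near-zero temperature: only restraint-non-increasing moves accepted
  mc <- gdsfold:::.crankshaft_cpp(conf0, G, 100, 8, 2, 2000, 1e-9, 1e-12)
  bonds0 <- sqrt(rowSums(diff(conf0)^2))
  bonds1 <- sqrt(rowSums(diff(mc$coords)^2))
  expect_equal(bonds1, bonds0, tolerance = 1e-9)
  # target = current map: the restraint energy stays zero and the map of
  # the walked structure still matches
  expect_equal(grp_new_energy(mc$coords, G), 0)
  expect_identical(map_from_conformation(mc$coords), G)
  # full reconstruction from the map succeeds
  # the hot-start MC wanders before cooling; the recovered structure must
  # stay within a single conformational step (SCH ~ 0.15) of the target
  res <- reconstruct_crankshaft(conf0, G, fx$seq, n_steps = 3e4, seed = 73)
  expect_false(res$failed)
  expect_lt(res$sch_to_target, 0.15)
})

test_that("benchmark aggregates per-trial records and handles n = 0", {
  fx <- fix_small10()
  db <- list(list(conformation = fx$min$conformation,
                  energy = fx$min$energy))
  bm <- benchmark_reconstruction(db, fx$seq, n_trials = 6, n_flips = 2,
                                 method = "new_grp", seed = 74,
                                 tol = 1e-4, max_iter = 4000)
  expect_equal(nrow(bm$trials), 6)
  expect_equal(bm$summary$pct_failures, 100 * mean(bm$trials$failed))
  expect_true(all(bm$trials$sch_to_target[!bm$trials$failed] >= 0))
  bm0 <- benchmark_reconstruction(db, fx$seq, n_trials = 0,
                                  method = "new_grp")
  expect_equal(nrow(bm0$trials), 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_report(bm, f)
  expect_true(any(grepl("pct_failures", readLines(f))))
})
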