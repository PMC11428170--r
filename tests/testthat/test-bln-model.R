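test_that("energy vanishes at equilibrium geometries", {
  s2 <- bead_sequence(c("B", "B"))
  expect_equal(bln_energy(rbind(c(0, 0, 0), c(3.8, 0, 0)), s2), 0)

  # two 3.8 A bonds at exactly the equilibrium angle
  s3 <- bead_sequence(c("B", "L", "N"))
  th <- 1.8326
  c3 <- rbind(c(0, 0, 0), c(3.8, 0, 0),
              c(3.8, 0, 0) + 3.8 * c(cos(pi - th), sin(pi - th), 0))
  expect_equal(bln_energy(c3, s3), 0, tolerance = 1e-12)
})

test_that("energy matches an independent per-term summation oracle", {
  set.seed(10)
  s10 <- bead_sequence(strsplit("BLNBBLNBLB", "")[[1]],
                       strsplit("HETHETH", "")[[1]])
  for (rep in 1:5) {
    conf <- extended_chain(10) + matrix(rnorm(30, sd = 0.4), 10, 3)
    e <- bln_energy(conf, s10)
    expect_equal(e, oracle_bln_energy(conf, s10), tolerance = 1e-10)
  }
})

test_that("coincident nonbonded beads give a non-finite energy", {
  s5 <- bead_sequence(c("B", "B", "B", "B", "B"), c("T", "T"))
  conf <- extended_chain(5)
  conf[5, ] <- conf[1, ]  # beads 1 and 5 coincide (nonbonded pair)
  expect_true(is.infinite(bln_energy(conf, s5)))
  expect_true(all(is.na(bln_gradient(conf, s5))))
})

test_that("forces match central finite differences and sum to zero", {
  set.seed(11)
  s10 <- bead_sequence(strsplit("BBLLNNBLNB", "")[[1]],
                       strsplit("EEHHTTE", "")[[1]])
  conf <- extended_chain(10) + matrix(rnorm(30, sd = 0.3), 10, 3)
  f <- bln_gradient(conf, s10)
  h <- 1e-6
  fd <- matrix(0, 10, 3)
  for (i in 1:10) {
    for (k in 1:3) {
      cp <- conf; cp[i, k] <- cp[i, k] + h
      cm <- conf; cm[i, k] <- cm[i, k] - h
      fd[i, k] <- -(bln_energy(cp, s10) - bln_energy(cm, s10)) / (2 * h)
    }
  }
  expect_lt(max(abs(f - fd)), 1e-5)
  # translation invariance: total force is the zero vector
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
  # equilibrium dimer has zero force
  s2 <- bead_sequence(c("L", "L"))
  expect_equal(bln_gradient(rbind(c(0, 0, 0), c(3.8, 0, 0)), s2),
               matrix(0, 2, 3), tolerance = 1e-12)
})

test_that("energy is invariant under rigid rotation and translation", {
  set.seed(12)
  s8 <- bead_sequence(rep("B", 8), rep("T", 5))
  for (rep in 1:5) {
    conf <- extended_chain(8) + matrix(rnorm(24, sd = 0.3), 8, 3)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- sweep(conf %*% R, 2, rnorm(3), "+")
    expect_equal(bln_energy(conf, s8), bln_energy(moved, s8),
                 tolerance = 1e-9)
  }
})

test_that("minimization converges, never increases energy, honours fixed points", {
  s2 <- bead_sequence(c("B", "B"))
  efn <- bln_energy_fn(s2); gfn <- bln_gradient_fn(s2)
  # stretched dimer relaxes to the 3.8 A bond length
  res <- minimize_geometry(rbind(c(0, 0, 0), c(5, 0, 0)), efn, gfn)
  expect_true(res$converged)
  expect_equal(as.numeric(dist(res$conformation)), 3.8, tolerance = 1e-6)
  # an exact minimum is a fixed point
  res2 <- minimize_geometry(res$conformation, efn, gfn)
  expect_true(res2$converged)
  expect_equal(res2$energy, res$energy, tolerance = 1e-12)
  expect_lte(res2$energy, res$energy)
})

test_that("a perturbed minimum relaxes back to the stored minimum energy", {
  fx <- fix_small10()
  set.seed(13)
  pert <- fx$min$conformation + matrix(rnorm(30, sd = 0.1), 10, 3)
  res <- minimize_geometry(pert, bln_energy_fn(fx$seq),
                           bln_gradient_fn(fx$seq))
  expect_false(res$failed)
  expect_lt(abs(res$energy - fx$min$energy), 1e-6)
})

test_that("NVE dynamics conserves energy and MD is deterministic", {
  s8 <- bead_sequence(rep("B", 8), rep("T", 5))
  md <- md_config(dt = 5e-4, temperature = 0.5, collision_rate = 0,
                  duration = 0.5, seed = 21, stride = 10)
  tr <- run_md_nvt(extended_chain(8), s8, md = md)
  etot <- tr$potential + tr$kinetic
  expect_lt((max(etot) - min(etot)) / 8, 1e-4)
  # determinism under a fixed seed (thermostatted run)
  md2 <- md_config(dt = 1e-3, temperature = 0.5, collision_rate = 1e-2,
                   duration = 1, seed = 22, stride = 100)
  a <- run_md_nvt(extended_chain(8), s8, md = md2)
  b <- run_md_nvt(extended_chain(8), s8, md = md2)
  expect_identical(a$coords, b$coords)
})

test_that("thermostatted dynamics samples the equipartition kinetic energy", {
  s10 <- bead_sequence(strsplit("BLNBBLNBLB", "")[[1]],
                       strsplit("HETHETH", "")[[1]])
  temp <- 0.5
  tr <- run_md_nvt(extended_chain(10), s10,
                   md = md_config(dt = 1e-3, temperature = temp,
                                  collision_rate = 1e-2, duration = 40,
                                  seed = 23, stride = 100))
  # discard the first quarter as equilibration
  ke <- tr$kinetic[-seq_len(length(tr$kinetic) %/% 4)] / 10
  expect_equal(mean(ke), 1.5 * temp, tolerance = 0.05)
})

test_that("annealing finds the brute-force global minimum of a 4-bead chain", {
  s4 <- bead_sequence(rep("B", 4), "T")
  efn <- bln_energy_fn(s4); gfn <- bln_gradient_fn(s4)
  # dense random-restart reference
  set.seed(31)
  best_ref <- Inf
  for (i in 1:400) {
    start <- extended_chain(4) + matrix(rnorm(12, sd = 1.2), 4, 3)
    r <- minimize_geometry(start, efn, gfn, tol = 1e-6, max_iter = 2e4)
    if (!r$failed && r$energy < best_ref) best_ref <- r$energy
  }
  best_sa <- Inf
  for (sd in 1:12) {
    a <- anneal_to_minimum(extended_chain(4), s4, start_T = 2,
                           n_halvings = 6, stage_duration = 2, seed = sd)
    best_sa <- min(best_sa, a$energy)
    expect_lte(a$energy, bln_energy(extended_chain(4), s4))
  }
  expect_lt(abs(best_sa - best_ref), 1e-6)
  # determinism
  a1 <- anneal_to_minimum(extended_chain(4), s4, start_T = 2,
                          n_halvings = 4, stage_duration = 1, seed = 7)
  a2 <- anneal_to_minimum(extended_chain(4), s4, start_T = 2,
                          n_halvings = 4, stage_duration = 1, seed = 7)
  expect_identical(a1$conformation, a2$conformation)
})

test_that("compact minima beat the extended chain for a sticky homopolymer", {
  s8 <- bead_sequence(rep("B", 8), rep("T", 5))
  a <- anneal_to_minimum(extended_chain(8), s8, start_T = 2,
                         n_halvings = 6, stage_duration = 2, seed = 41)
  e_ext <- bln_energy(extended_chain(8), s8)
  expect_lt(a$energy, e_ext)
  # and the minimum is compact: radius of gyration shrinks
  rg <- function(x) sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  expect_lt(rg(a$conformation), rg(extended_chain(8)))
})

test_that("parameter overrides parse and apply", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("k_b = 100", "dihedral.E.A = 0.5", "pair.BL.S2 = 0  # off"),
             f)
  p <- read_parameter_overrides(f)
  expect_equal(p$k_b, 100)
  expect_equal(p$dihedral_table[2, 1], 0.5)
  expect_equal(p$S2[1, 2], 0)
  expect_equal(p$S2[2, 1], 0)
  expect_error(read_parameter_overrides(
    withr::local_tempfile(lines = "nope = 1", fileext = ".cfg")),
    "unknown parameter")
})
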