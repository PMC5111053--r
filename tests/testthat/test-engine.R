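test_that("move proposals are uniform over monomers and directions", {
  pm <- propose_moves(6e4, n = 5, mode = "bulk3d", seed = 99)
  # direction frequencies within 5 sigma of 1/6
  dir_id <- paste(pm$dx, pm$dy, pm$dz)
  p <- 1 / 6
  tol <- 5 * sqrt(p * (1 - p) / nrow(pm))
  expect_true(all(abs(table(dir_id) / nrow(pm) - p) < tol))
  expect_true(all(abs(table(pm$monomer) / nrow(pm) - 1 / 5) <
                  5 * sqrt(0.2 * 0.8 / nrow(pm))))
  # single monomer: index always 1
  expect_true(all(propose_moves(1000, n = 1, mode = "bulk3d")$monomer == 1))
  # in-plane proposals never leave the plane
  pm2 <- propose_moves(5000, n = 4, mode = "plane2d", seed = 7)
  expect_true(all(pm2$dz == 0))
  expect_equal(sort(unique(paste(pm2$dx, pm2$dy))),
               sort(c("1 0", "-1 0", "0 1", "0 -1")))
})

test_that("Metropolis acceptance has the exact exponential rate", {
  set.seed(11)
  expect_true(all(metropolis_accept(rep(0, 1000))))
  expect_true(all(metropolis_accept(rep(-2, 1000))))
  n <- 2e5
  rate <- mean(metropolis_accept(rep(1, n)))
  expect_lt(abs(rate - exp(-1)), 5 * sqrt(exp(-1) * (1 - exp(-1)) / n))
})

test_that("chain invariants hold along randomized trajectories in all modes", {
  # check_every = 1 recounts contacts and re-verifies self-avoidance,
  # bond lengths and non-crossing after every MCS; any violation errors out
  for (mode in c("bulk3d", "slab", "plane2d")) {
    r <- run_polymer(16, mode, e_pp = 0.7, e_ps = if (mode == "slab") 1.2 else 0,
                     seed = 31, check_every = 1,
                     protocol = quick_protocol(16, mode, production_mcs = 300))
    expect_equal(r$n_pp_final, r$n_pp_recount)
    expect_equal(r$n_ps_final, r$n_ps_recount)
    # recorded bond vectors of the final state are valid
    expect_true(all(bond_is_valid(diff(r$final_positions), mode = mode)))
  }
})

test_that("incremental bookkeeping matches recounts from arbitrary states", {
  # start from exact-sampled tiny-chain states and run with per-MCS audits
  ens <- enumerate_chains(4, "bulk3d")
  for (s in 1:3) {
    p0 <- sample_config(ens, seed = s) + matrix(rep(c(10L, 10L, 10L),
                                                    each = 4), 4)
    r <- run_mcs(p0, 200, "bulk3d", e_pp = 1,
                 box = box_spec("bulk3d", n = 4, l_x = 20),
                 seed = s, check_every = 1)
    expect_equal(r$n_pp_final, r$n_pp_recount)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  a <- run_polymer(12, "slab", e_ps = 1, seed = 555,
                   protocol = quick_protocol(12, "slab"))
  b <- run_polymer(12, "slab", e_ps = 1, seed = 555,
                   protocol = quick_protocol(12, "slab"))
  expect_identical(a$com, b$com)
  expect_identical(a$end_to_end, b$end_to_end)
  expect_identical(a$final_positions, b$final_positions)
  c <- run_polymer(12, "slab", e_ps = 1, seed = 556,
                   protocol = quick_protocol(12, "slab"))
  expect_false(identical(a$final_positions, c$final_positions))
})

test_that("the adsorption protocol ends with the chain at the surface", {
  r <- run_polymer(16, "slab", e_ps = 2, seed = 20,
                   protocol = quick_protocol(16, "slab", production_mcs = 2000))
  expect_true(is.finite(r$adsorption_wait_mcs))
  expect_gte(r$adsorption_wait_mcs, 0)
  # at E_PS = 2 the chain stays adsorbed essentially always
  expect_lt(r$desorbed_fraction, 0.05)
  expect_gt(mean(r$n_ps), 1)
  # a tiny adsorption cap triggers the failure signal
  expect_error(
    run_polymer(16, "slab", e_ps = 1, seed = 20,
                box = box_spec("slab", n = 16, l_z = 40),
                protocol = run_protocol(16, "slab", production_mcs = 100,
                                        adsorb_cap_mcs = 1)),
    "adsorb")
})

test_that("slab geometry is respected: z >= 1 always, wall contacts at z = 1", {
  r <- run_polymer(10, "slab", e_ps = 2.5, seed = 8, record_positions = TRUE,
                   protocol = quick_protocol(10, "slab", production_mcs = 500,
                                             sample_interval = 1))
  expect_gte(min(r$positions[, , 3]), 1)
  nps_direct <- apply(r$positions[, , 3, drop = FALSE] == 1, 1, sum)
  expect_equal(as.integer(nps_direct), as.integer(r$n_ps))
})

test_that("a free monomer diffuses with unit-step statistics", {
  # every attempt is accepted: msd_xyz(t) = t, so D_xy = (2/3 t)/(4 t) = 1/6
  r <- run_polymer(1, "bulk3d", seed = 17,
                   protocol = run_protocol(1, "bulk3d", equilibration_mcs = 0,
                                           production_mcs = 4e4,
                                           sample_interval = 1))
  expect_equal(r$acceptance_rate, 1.0)
  m <- msd_com(r, "xyz", lags = c(1, 2, 4, 8, 16))
  expect_equal(m$msd, c(1, 2, 4, 8, 16), tolerance = 0.1)
})

test_that("N = 2 sampling matches the exact dimer ensemble regardless of E_PP", {
  # all 26 bond vectors equally likely (n_PP = 0 identically for a dimer)
  counts <- NULL
  for (epp in c(0, 2)) {
    r <- run_polymer(2, "bulk3d", e_pp = epp, seed = 23,
                     box = box_spec("bulk3d", n = 2, l_x = 8),
                     protocol = run_protocol(2, "bulk3d",
                                             equilibration_mcs = 500,
                                             production_mcs = 6e4,
                                             sample_interval = 10))
    expect_true(all(r$n_pp == 0L))
    r2 <- rowSums(r$end_to_end^2)
    expect_lt(abs(mean(r2) - 27 / 13), 4 * sd(r2) / sqrt(length(r2) / 4))
    if (epp == 0) {
      key <- apply(r$end_to_end, 1, paste, collapse = ",")
      counts <- table(key)
      expect_equal(length(counts), 26)
      gof <- suppressWarnings(stats::chisq.test(as.vector(counts)))
      expect_gt(gof$p.value, 0.01)
    }
  }
})

test_that("slab equilibrium of a trimer matches exact enumeration", {
  # identical finite box for sampler and oracle: L_z = z_max + 1
  z_max <- 4
  params <- energy_params(e_pp = 0.8, e_ps = 1)
  ens <- enumerate_chains(3, "slab", params, z_max = z_max)
  box <- box_spec("slab", n = 3, l_x = 10, l_z = z_max + 1)
  reps <- sapply(1:6, function(s) {
    r <- run_polymer(3, "slab", e_pp = params$e_pp, e_ps = params$e_ps,
                     box = box, seed = 700 + s, adsorb = FALSE,
                     protocol = run_protocol(3, "slab",
                                             equilibration_mcs = 2000,
                                             production_mcs = 4e4,
                                             sample_interval = 4))
    c(nps = mean(r$n_ps), npp = mean(r$n_pp),
      r2 = mean(rowSums(r$end_to_end^2)))
  })
  for (ob in c("nps", "npp", "r2")) {
    col <- c(nps = "n_ps", npp = "n_pp", r2 = "r_sq")[[ob]]
    se <- sd(reps[ob, ]) / sqrt(ncol(reps))
    expect_lt(abs(mean(reps[ob, ]) - exact_average(ens, col)),
              4 * se + 1e-3)
  }
})

test_that("bulk trimer configuration frequencies follow the Boltzmann law", {
  params <- energy_params(e_pp = 1)
  ens <- enumerate_chains(3, "bulk3d", params)
  probs <- ensemble_probabilities(ens)
  r <- run_polymer(3, "bulk3d", e_pp = params$e_pp, seed = 41,
                   box = box_spec("bulk3d", n = 3, l_x = 8),
                   protocol = run_protocol(3, "bulk3d",
                                           equilibration_mcs = 1000,
                                           production_mcs = 1.3e5,
                                           sample_interval = 10),
                   record_positions = TRUE)
  keys <- apply(r$positions, 1, function(p) config_key(p, "bulk3d"))
  obs <- table(factor(keys, levels = probs$key))
  expect_equal(sum(obs), length(keys))  # every sampled state is enumerated
  gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = probs$prob))
  expect_gt(gof$p.value, 0.01)
})

test_that("move admissibility rules match the spec examples", {
  # stretching an end bond to squared length 4 is refused
  rod <- cbind(0:3, 0L, 5L)
  expect_false(move_is_allowed(rod, 1, c(-1, 0, 0), mode = "bulk3d"))
  # an end monomer stepping sideways to a free site (bond becomes sqrt 2)
  expect_true(move_is_allowed(rod, 1, c(0, 1, 0), mode = "bulk3d"))
  # stepping onto an occupied site
  expect_false(move_is_allowed(rod, 1, c(1, 0, 0), mode = "bulk3d"))
  # slab: moving from z = 1 into the wall
  pos <- rbind(c(0, 0, 1), c(1, 0, 1))
  expect_false(move_is_allowed(pos, 1, c(0, 0, -1), mode = "slab"))
  expect_true(move_is_allowed(pos, 1, c(0, 0, 1), mode = "slab"))
  # a move whose displaced bond would cross another bond is refused:
  # dropping monomer 3 to z = 0 would put bond 3-4 at (1,0,0)-(0,1,0),
  # crossing the non-adjacent diagonal bond 1-2 at (0.5, 0.5, 0)
  zig <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_false(move_is_allowed(zig, 3, c(0, 0, -1), mode = "bulk3d"))
  # property: an allowed move always yields a configuration that satisfies
  # every chain invariant (checked with the independent R-side rules), and
  # any move onto an occupied site is always refused
  chain_valid <- function(p) {
    if (anyDuplicated(as.data.frame(p)) > 0) return(FALSE)
    if (!all(bond_is_valid(diff(p), mode = "bulk3d"))) return(FALSE)
    nb <- nrow(p) - 1
    for (a in seq_len(nb)) for (b in seq_len(nb)) {
      if (b > a + 1 &&
          polylat:::.seg_intersect_ref(p[a, ], p[a + 1, ],
                                       p[b, ], p[b + 1, ])) return(FALSE)
    }
    TRUE
  }
  ens <- enumerate_chains(4, "bulk3d")
  box <- box_spec("bulk3d", n = 4, l_x = 20)
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  n_allowed <- 0
  for (s in 1:12) {
    p0 <- sample_config(ens, seed = 100 + s) + 10L
    for (m in 1:4) for (d in 1:6) {
      p1 <- p0; p1[m, ] <- p1[m, ] + dirs[d, ]
      ok <- move_is_allowed(p0, m, dirs[d, ], mode = "bulk3d", box = box)
      if (ok) {
        n_allowed <- n_allowed + 1
        expect_true(chain_valid(p1))
      } else if (chain_valid(p1)) {
        fail(sprintf("seed %d monomer %d dir %d: refused but valid", s, m, d))
      }
    }
  }
  expect_gt(n_allowed, 0)
})

test_that("recorded energies equal from-scratch energies of the frames", {
  params <- energy_params(e_pp = 0.7, e_ps = 1.3)
  r <- run_polymer(12, "slab", e_pp = params$e_pp, e_ps = params$e_ps,
                   seed = 77, record_positions = TRUE,
                   protocol = quick_protocol(12, "slab", production_mcs = 400,
                                             sample_interval = 2))
  box <- r$config$box
  for (f in seq(1, length(r$times), by = 20)) {
    expect_equal(r$energy[f],
                 total_energy(r$positions[f, , ], params, "slab", box))
  }
})

test_that("acceptance ratios of forward and reverse moves obey detailed balance", {
  # proposal symmetry makes p_acc(dE)/p_acc(-dE) = exp(-dE) for every dE
  set.seed(99)
  n <- 2e5
  for (de in c(0.5, 1.5)) {
    fwd <- mean(metropolis_accept(rep(de, n)))
    rev <- mean(metropolis_accept(rep(-de, n)))
    se <- sqrt(exp(-de) * (1 - exp(-de)) / n)
    expect_lt(abs(fwd / rev - exp(-de)), 6 * se)
  }
})

test_that("with all couplings zero, rejections are purely geometric", {
  # the engine's acceptance rate must match the fraction of geometrically
  # admissible proposals over equilibrium states, measured independently
  # with move_is_allowed on recorded frames
  box <- box_spec("bulk3d", n = 8, l_x = 32)
  r <- run_polymer(8, "bulk3d", seed = 63, box = box, record_positions = TRUE,
                   protocol = run_protocol(8, "bulk3d",
                                           equilibration_mcs = 1000,
                                           production_mcs = 4000,
                                           sample_interval = 2))
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  set.seed(5)
  frames <- sample(dim(r$positions)[1], 300, replace = TRUE)
  geo <- mean(vapply(frames, function(f) {
    move_is_allowed(r$positions[f, , ], sample(8, 1),
                    dirs[sample(6, 1), ], mode = "bulk3d", box = box)
  }, logical(1)))
  se <- sqrt(geo * (1 - geo) / 300)
  expect_lt(abs(r$acceptance_rate - geo), 4 * se + 0.01)
})
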