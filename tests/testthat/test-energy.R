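# Residue-pair interaction energies and the distance-dependent dielectric.

test_that("the dielectric rises sigmoidally from ~1.35 to the bulk-water limit", {
  m <- dielectric_model()
  # Closed-form value at contact, computed independently of dielectric_eps.
  eps_contact <- m$a + (m$eps0 - m$a) / (1 + m$k)
  expect_equal(dielectric_eps(0), eps_contact, tolerance = 1e-12)
  expect_equal(eps_contact, 1.3466, tolerance = 1e-4)
  expect_equal(dielectric_eps(1e6), 78.4, tolerance = 1e-6)
  r <- seq(0, 100, by = 0.5)
  eps <- dielectric_eps(r)
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps > eps_contact - 1e-12 & eps < 78.4 + 1e-12))
  expect_lt(dielectric_eps(5), dielectric_eps(10))
  expect_lt(dielectric_eps(10), dielectric_eps(20))
  expect_error(dielectric_eps(-1), class = "quantavax_domain_error")
})

test_that("screened Coulomb pair energies have the right sign, decay and scale", {
  expect_equal(pair_electrostatic(0, 0, 5), 0)
  e5 <- pair_electrostatic(1, -1, 5)
  expect_equal(e5, 332.0637 * (-1) / (dielectric_eps(5) * 5), tolerance = 1e-12)
  expect_equal(pair_electrostatic(-1, -1, 5), -e5)
  mags <- abs(pair_electrostatic(1, -1, c(2, 5, 10, 30)))
  expect_true(all(diff(mags) < 0))
  expect_error(pair_electrostatic(1, 1, 0), class = "quantavax_singularity_error")
})

test_that("the 12-6 potential has its zero and minimum where calculus says", {
  A <- 5e4; B <- 120
  r_zero <- (A / B)^(1 / 6)
  expect_equal(pair_vdw(A, B, r_zero), 0, tolerance = 1e-9)
  r_min <- (2 * A / B)^(1 / 6)
  expect_equal(pair_vdw(A, B, r_min), -B^2 / (4 * A), tolerance = 1e-12)
  expect_gt(pair_vdw(A, B, r_min * 0.99), pair_vdw(A, B, r_min))
  expect_gt(pair_vdw(A, B, r_min * 1.01), pair_vdw(A, B, r_min))
  expect_equal(pair_vdw(0, 0, 3), 0)
  expect_error(pair_vdw(A, B, 0), class = "quantavax_singularity_error")
})

test_that("per-atom LJ parameters combine to a pair minimum at Rmin_ij", {
  lj <- list(rmin_half = 1.9080, epsilon = 0.1094)
  pair <- lj_pair_from_atoms(lj, lj)
  rmin <- 2 * 1.9080
  expect_equal(pair$Aij, 0.1094 * rmin^12, tolerance = 1e-12)
  expect_equal(pair$Bij, 2 * 0.1094 * rmin^6, tolerance = 1e-12)
  expect_equal(pair_vdw(pair$Aij, pair$Bij, rmin), -0.1094, tolerance = 1e-9)
  opt <- stats::optimize(function(r) pair_vdw(pair$Aij, pair$Bij, r),
                         interval = c(2, 8))
  expect_equal(opt$minimum, rmin, tolerance = 1e-4)
  zero <- lj_pair_from_atoms(list(rmin_half = 1, epsilon = 0), lj)
  expect_equal(c(zero$Aij, zero$Bij), c(0, 0))
  expect_error(lj_pair_from_atoms(list(rmin_half = -1, epsilon = 0.1), lj),
               class = "quantavax_parameter_error")
})

test_that("residue-pair matrices equal the brute-force atom-pair double loop", {
  cx <- gen_complex(n_res = 10, atoms_per_res = 3, patch1 = c(2, 4),
                    patch2 = c(6, 8), n_snapshots = 3, jitter_sd = 0.2,
                    seed = 101)
  for (frame in cx$traj) {
    m <- residue_pair_matrix(frame, cx$atoms)
    expect_equal(sum(m$e_total), brute_force_total_energy(frame, cx$atoms),
                 tolerance = 1e-6)
    expect_equal(m$e_total, m$e_el + m$e_vdw, tolerance = 1e-9)
  }
})

test_that("only inter-chain pairs contribute and geometry is translation-invariant", {
  atoms <- atom_sites(c("a1", "b1"), c("A", "B"), c(1, 1), c(0, 0),
                      rmin_half = c(1, 1), epsilon = c(0, 0))
  m <- residue_pair_matrix(rbind(c(0, 0, 0), c(4, 0, 0)), atoms)
  expect_equal(dim(m$e_total), c(1, 1))
  expect_equal(m$e_total[1, 1], 0)

  cx <- gen_complex(n_res = 6, patch1 = c(2, 3), patch2 = c(4, 5),
                    seed = 5, n_snapshots = 1, jitter_sd = 0)
  m1 <- residue_pair_matrix(cx$traj[[1]], cx$atoms)
  shifted <- cx$traj[[1]] + matrix(rep(c(11, -3, 7), each = nrow(cx$traj[[1]])),
                                   ncol = 3)
  m2 <- residue_pair_matrix(shifted, cx$atoms)
  expect_equal(m1$e_total, m2$e_total, tolerance = 1e-9)

  one_chain <- atom_sites("x", "A", 1, 0, 1, 0)
  expect_error(residue_pair_matrix(matrix(0, 1, 3), one_chain),
               class = "quantavax_chain_error")
})

test_that("trajectory averaging is an elementwise mean over snapshots", {
  cx <- gen_complex(n_res = 8, patch1 = c(2, 4), patch2 = c(5, 7),
                    n_snapshots = 2, jitter_sd = 0.3, seed = 9)
  avg <- average_over_trajectory(cx$traj, cx$atoms)
  expect_equal(avg$n_snapshots, 2)
  per_frame <- lapply(cx$traj, residue_pair_matrix, atoms = cx$atoms)
  expect_equal(avg$e_total,
               (per_frame[[1]]$e_total + per_frame[[2]]$e_total) / 2,
               tolerance = 1e-12)
  one <- average_over_trajectory(cx$traj[1], cx$atoms)
  expect_equal(one$e_total, per_frame[[1]]$e_total)
  dup <- average_over_trajectory(c(cx$traj, cx$traj), cx$atoms)
  expect_equal(dup$e_total, avg$e_total, tolerance = 1e-12)
  expect_error(average_over_trajectory(list(cx$traj[[1]], cx$traj[[1]][-1, ]), cx$atoms),
               class = "quantavax_trajectory_error")
  expect_error(average_over_trajectory(list(), cx$atoms),
               class = "quantavax_trajectory_error")
})

test_that("a planted opposite-charge contact patch is recovered exactly", {
  cx <- gen_complex(n_res = 20, patch1 = c(5, 9), patch2 = c(10, 14),
                    separation = 4, background_separation = 30,
                    n_snapshots = 5, jitter_sd = 0.1, seed = 42)
  energy <- average_over_trajectory(cx$traj, cx$atoms)
  regions <- find_interaction_regions(energy, z_threshold = 1, merge_gap = 2)
  a <- regions[regions$chain == "A", ]
  b <- regions[regions$chain == "B", ]
  expect_equal(nrow(a), 1)
  expect_equal(c(a$start, a$end), c(5, 9))
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(10, 14))
  expect_true(all(regions$mean_energy < 0))
})

test_that("region extraction handles flat and multi-patch score landscapes", {
  flat <- structure(list(chains = c("A", "B"),
                         e_total = matrix(0, 4, 4,
                                          dimnames = list(1:4, 1:4))),
                    class = "residue_pair_energy")
  expect_warning(r <- find_interaction_regions(flat), "zero-variance")
  expect_equal(nrow(r), 0)

  # Two favourable patches on chain A separated by more than merge_gap.
  e <- matrix(0, 12, 4, dimnames = list(1:12, 1:4))
  e[2:3, 1] <- -50
  e[9:10, 1] <- -50
  two <- structure(list(chains = c("A", "B"), e_total = e),
                   class = "residue_pair_energy")
  r2 <- find_interaction_regions(two, z_threshold = 1, merge_gap = 2)
  a2 <- r2[r2$chain == "A", ]
  expect_equal(nrow(a2), 2)
  expect_equal(sort(a2$start), c(2, 9))
  expect_equal(sort(a2$end), c(3, 10))
})
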