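# pair potentials: contracts and finite-difference gradient oracles

test_that("excluded volume is purely repulsive with contact at a", {
  ff <- ff_default
  far <- excluded_volume(c(1.5, 0, 0), ff)
  expect_identical(far$energy, 0)
  expect_identical(far$force_on_i, c(0, 0, 0))
  at_contact <- excluded_volume(c(1, 0, 0), ff)
  expect_equal(at_contact$energy, 0, tolerance = 1e-12)
  # approach continuity at r = a
  eps <- excluded_volume(c(1 - 1e-8, 0, 0), ff)
  expect_lt(eps$energy, 1e-6)
  inside <- excluded_volume(c(0.9, 0, 0), ff)
  expect_gt(inside$energy, 0)
  expect_gt(inside$force_on_i[1], 0) # along +r_ij, pushing i away from j
  expect_error(excluded_volume(c(0, 0, 0), ff), "overlapping")
})

test_that("bond and crosslink are harmonic with the documented closed forms", {
  ff <- ff_params(k_bond = 100, k_crosslink = 50, d0 = 1.5)
  expect_equal(bond(c(1, 0, 0), ff)$energy, 0)
  expect_equal(bond(c(1, 0, 0), ff)$force_on_i, c(0, 0, 0))
  expect_equal(bond(c(1.1, 0, 0), ff)$energy, 0.5, tolerance = 1e-12)
  expect_equal(crosslink(c(1.5, 0, 0), ff)$energy, 0)
  expect_equal(crosslink(c(1.7, 0, 0), ff)$energy, 1.0, tolerance = 1e-12)
})

test_that("pair forces obey Newton's third law and match finite differences", {
  ff <- ff_default
  withr::with_seed(11, {
    for (rep in 1:20) {
      r <- runif(1, 0.7, 1.4) * rand_unit()
      for (kind in c("ev", "bond", "crosslink")) {
        fn <- switch(kind, ev = excluded_volume, bond = bond, crosslink = crosslink)
        res <- fn(r, ff)
        expect_equal(res$force_on_j, -res$force_on_i)
        expect_equal(res$torque_on_i, c(0, 0, 0))
        fd <- fd_grad(function(x) fn(x, ff)$energy, r)
        expect_equal(res$force_on_i, -fd, tolerance = 1e-5)
      }
    }
  })
})

test_that("bending vanishes for straight triples and matches finite differences", {
  ff <- ff_default
  straight <- bending(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), ff)
  expect_equal(straight$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(c(straight$force_prev, straight$force_mid,
                         straight$force_next))), 0, tolerance = 1e-10)
  right <- bending(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), ff)
  mirror <- bending(c(0, 0, 0), c(1, 0, 0), c(1, -1, 0), ff)
  expect_gt(right$energy, 0)
  expect_equal(right$energy, mirror$energy)
  expect_error(bending(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), ff), "degenerate")
  withr::with_seed(12, {
    for (rep in 1:10) {
      r1 <- rnorm(3); r2 <- r1 + rand_unit(); r3 <- r2 + rand_unit()
      res <- bending(r1, r2, r3, ff)
      # forces on the triple sum to zero
      expect_equal(res$force_prev + res$force_mid + res$force_next,
                   c(0, 0, 0), tolerance = 1e-10)
      fd <- fd_grad(function(x) bending(x, r2, r3, ff)$energy, r1)
      expect_equal(res$force_prev, -fd, tolerance = 1e-5)
      fd2 <- fd_grad(function(x) bending(r1, x, r3, ff)$energy, r2)
      expect_equal(res$force_mid, -fd2, tolerance = 1e-5)
    }
  })
})

test_that("polarization alignment is minimized at theta0 and has exact gradients", {
  ff <- ff_params(theta0_deg = 90)
  bonds <- rbind(c(1, 0, 0), c(1, 0, 0))
  perp <- polarization_alignment(c(0, 0, 1), bonds, ff)
  expect_equal(perp$energy, 0, tolerance = 1e-12)
  expect_equal(perp$torque, c(0, 0, 0))
  para <- polarization_alignment(c(1, 0, 0), bonds, ff)
  expect_gt(para$energy, perp$energy)
  # parallel orientation is the symmetry extremum among sampled orientations
  withr::with_seed(13, {
    es <- replicate(50, polarization_alignment(rand_unit(), bonds, ff)$energy)
    expect_gte(para$energy, max(es) - 1e-9)
  })
  expect_error(polarization_alignment(c(0, 0, 1), rbind(c(0, 0, 0)), ff),
               "zero-length")
  # rotational finite differences
  withr::with_seed(14, {
    for (rep in 1:10) {
      p <- rand_unit()
      bv <- rbind(rand_unit(), rand_unit())
      res <- polarization_alignment(p, bv, ff)
      for (k in 1:3) {
        ax <- numeric(3); ax[k] <- 1
        h <- 1e-6
        fd <- (polarization_alignment(rot_about(p, ax, h), bv, ff)$energy -
                 polarization_alignment(rot_about(p, ax, -h), bv, ff)$energy) / (2 * h)
        expect_equal(res$torque[k], -fd, tolerance = 1e-5)
      }
      # gradient w.r.t. the bond vector
      fd <- fd_grad(function(x) polarization_alignment(p, rbind(x, bv[2, ]), ff)$energy,
                    bv[1, ])
      expect_equal(as.numeric(res$dUdbond[1, ]), fd, tolerance = 1e-5)
    }
  })
})

test_that("helical coupling is minimized at the pitch angle and reduces to the non-helical variant", {
  ff <- ff_params(psi_nn_parA_deg = 60)
  p1 <- c(0, 1, 0)
  p2 <- rot_about(p1, c(1, 0, 0), pi / 3)
  at_min <- helical_coupling(p1, p2, "nn", ff)
  expect_equal(at_min$energy, 0, tolerance = 1e-12)
  expect_equal(at_min$torque_i, c(0, 0, 0), tolerance = 1e-9)
  ff0 <- ff_params(psi_nn_parA_deg = 0, psi_nnn_parA_deg = 0)
  expect_equal(helical_coupling(p1, p1, "nn", ff0)$energy, 0)
  withr::with_seed(15, {
    for (rep in 1:10) {
      pa <- rand_unit(); pb <- rand_unit()
      res <- helical_coupling(pa, pb, "nn", ff)
      for (k in 1:3) {
        ax <- numeric(3); ax[k] <- 1
        h <- 1e-6
        fd <- (helical_coupling(rot_about(pa, ax, h), pb, "nn", ff)$energy -
                 helical_coupling(rot_about(pa, ax, -h), pb, "nn", ff)$energy) / (2 * h)
        expect_equal(res$torque_i[k], -fd, tolerance = 1e-5)
      }
    }
  })
})

test_that("binding attains exactly -eps_b at the optimal geometry and vanishes at the cutoff", {
  ff <- ff_params(eps_b = 10, r_b = 1, range_b = 1.5)
  opt <- binding(c(1, 0, 0), c(1, 0, 0), c(-1, 0, 0), ff)
  expect_equal(opt$energy, -10, tolerance = 1e-12)
  beyond <- binding(c(1.6, 0, 0), c(1, 0, 0), c(-1, 0, 0), ff)
  expect_identical(beyond$energy, 0)
  expect_identical(beyond$force_on_i, c(0, 0, 0))
  expect_identical(beyond$torque_on_i, c(0, 0, 0))
  # the no-ParB-polarization variants drop the ParB orientation factor
  ffv <- ff_params(binding_form = "SIDE_NO_PARB_POLAR")
  e1 <- binding(c(1.1, 0.1, 0), c(1, 0, 0), c(0, 1, 0), ffv)$energy
  e2 <- binding(c(1.1, 0.1, 0), c(1, 0, 0), c(0, 0, 1), ffv)$energy
  expect_equal(e1, e2)
  expect_equal(max(abs(binding(c(1.1, 0.1, 0), c(1, 0, 0), c(0, 1, 0), ffv)$torque_on_j)), 0)
})

test_that("binding energy is bounded below by -eps_b over random geometries", {
  ff <- ff_default
  emin <- parabd:::binding_min_scan_cpp(2e5, 16, ff)
  expect_gte(emin, -ff$eps_b)
  expect_lt(emin, -0.5 * ff$eps_b) # the sample does reach deep binding
})

test_that("binding force and torques match finite differences at random geometries", {
  withr::with_seed(17, {
    for (form in c("ORIENTED", "SIDE_NO_PARB_POLAR")) {
      ff <- ff_params(binding_form = form)
      for (rep in 1:15) {
        r <- runif(1, 0.6, 1.45) * rand_unit()
        p1 <- rand_unit(); p2 <- rand_unit()
        res <- binding(r, p1, p2, ff)
        fd <- fd_grad(function(x) binding(x, p1, p2, ff)$energy, r)
        expect_equal(res$force_on_j, -fd, tolerance = 1e-5)
        expect_equal(res$force_on_i, fd, tolerance = 1e-5)
        for (k in 1:3) {
          ax <- numeric(3); ax[k] <- 1
          h <- 1e-6
          fdt <- (binding(r, rot_about(p1, ax, h), p2, ff)$energy -
                    binding(r, rot_about(p1, ax, -h), p2, ff)$energy) / (2 * h)
          expect_equal(res$torque_on_i[k], -fdt, tolerance = 1e-5)
          fdt2 <- (binding(r, p1, rot_about(p2, ax, h), ff)$energy -
                     binding(r, p1, rot_about(p2, ax, -h), ff)$energy) / (2 * h)
          expect_equal(res$torque_on_j[k], -fdt2, tolerance = 1e-5)
        }
      }
    }
  })
})

test_that("total_forces aggregates exactly: free subunit, rest dimer, brute-force oracle", {
  ff <- ff_default
  free <- pb_state(pos = matrix(0, 1, 3), pol = matrix(c(1, 0, 0), 1, 3),
                   species = "PARA", nucleotide = "ATP", alpha = 1,
                   anchored = FALSE, chains = list(), chain_anchored = logical(0),
                   crosslinks = matrix(integer(0), 0, 2), n_para0 = 1)
  tf <- total_forces(free, ff)
  expect_equal(max(abs(tf$forces)), 0)
  expect_equal(max(abs(tf$torques)), 0)

  dimer <- pb_state(pos = rbind(c(0, 0, 0), c(1, 0, 0)),
                    pol = rbind(c(0, 0, 1), c(0, 0, 1)),
                    species = rep("PARA", 2), nucleotide = rep("ATP", 2),
                    alpha = c(1, 1), anchored = c(FALSE, FALSE),
                    chains = list(1:2), chain_anchored = FALSE,
                    crosslinks = matrix(integer(0), 0, 2))
  ffq <- ff_params(k_align = 0, k_helix_nn = 0, k_helix_nnn = 0, eps_b = 0)
  tfd <- total_forces(dimer, ffq)
  expect_equal(max(abs(tfd$forces)), 0, tolerance = 1e-12)

  st <- make_tiny_state(n_fil = 2, len = 5, n_parb = 10, n_bind = 6)
  with_nl <- total_forces(st, ff)
  brute <- total_forces(st, ff, use_neighbor_list = FALSE)
  expect_identical(with_nl$forces, brute$forces)
  expect_identical(with_nl$energy, brute$energy)
  # internal forces sum to zero
  expect_equal(colSums(with_nl$forces), c(0, 0, 0), tolerance = 1e-10)
})

test_that("total_forces is the exact gradient of the total energy", {
  st <- make_tiny_state(n_fil = 2, len = 4, n_parb = 6, n_bind = 4, seed = 21)
  ff <- ff_default
  tf <- total_forces(st, ff, use_neighbor_list = FALSE)
  E <- function(s) total_forces(s, ff, use_neighbor_list = FALSE)$energy
  h <- 1e-6
  withr::with_seed(22, ids <- sample(nrow(st$pos), 5))
  for (i in ids) for (k in 1:3) {
    sp <- st; sp$pos[i, k] <- sp$pos[i, k] + h
    sm <- st; sm$pos[i, k] <- sm$pos[i, k] - h
    expect_equal(tf$forces[i, k], -(E(sp) - E(sm)) / (2 * h), tolerance = 1e-5)
  }
  for (i in ids) for (k in 1:3) {
    ax <- numeric(3); ax[k] <- 1
    sp <- st; sp$pol[i, ] <- rot_about(st$pol[i, ], ax, h)
    sm <- st; sm$pol[i, ] <- rot_about(st$pol[i, ], ax, -h)
    expect_equal(tf$torques[i, k], -(E(sp) - E(sm)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("total_forces flags non-finite coordinates with the subunit id", {
  st <- make_tiny_state()
  st$pos[3, 1] <- NaN
  expect_error(total_forces(st, ff_default), "subunit 3")
})
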