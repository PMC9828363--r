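simple_case <- function(n = 12, seed = 1, site = c(0, 0, 0)) {
  pos <- fixture_random_positions(n, site = site, seed = seed)
  struct <- fixture_positions_structure(pos)
  tensor <- random_tensor(seed + 100)
  ds <- fixture_dataset_from_positions(tensor, site, pos)
  list(struct = struct, tensor = tensor, ds = ds, pos = pos, site = site)
}

test_that("inside the flat bottom the PCS energy and all gradients vanish", {
  cs <- simple_case()
  restr <- pcs_restraint_set(cs$ds, cs$tensor, cs$site, tolerance = 0.05)
  out <- pcs_energy_grad(cs$struct, restr)   # calc == obs exactly
  expect_identical(out$energy, 0)
  expect_true(all(out$grad_atoms == 0))
  expect_true(all(out$grad_site == 0))
})

test_that("analytic PCS gradients match central finite differences", {
  h <- 1e-5
  worst <- 0
  for (seed in 1:50) {
    cs <- simple_case(n = 6, seed = seed)
    obs_shift <- withr::with_seed(seed, rnorm(6, 0, 0.3))
    ds <- cs$ds
    ds$pcs <- ds$pcs + obs_shift   # push out of the flat bottom
    restr <- pcs_restraint_set(ds, cs$tensor, cs$site,
                               force_constant = 2, tolerance = 0.02)
    out <- pcs_energy_grad(cs$struct, restr)
    energy_at <- function(struct, site) {
      r <- restr
      r$site <- site
      pcs_energy_grad(struct, r)$energy
    }
    # nuclear coordinates
    num <- matrix(0, nrow(cs$pos), 3)
    cols <- c("x", "y", "z")
    for (i in seq_len(nrow(cs$pos))) for (k in 1:3) {
      sp <- cs$struct; sm <- cs$struct
      sp[i, cols[k]] <- sp[i, cols[k]] + h
      sm[i, cols[k]] <- sm[i, cols[k]] - h
      num[i, k] <- (energy_at(sp, cs$site) - energy_at(sm, cs$site)) / (2 * h)
    }
    num_site <- vapply(1:3, function(k) {
      d <- c(0, 0, 0); d[k] <- h
      (energy_at(cs$struct, cs$site + d) - energy_at(cs$struct, cs$site - d)) / (2 * h)
    }, 0)
    scale <- max(abs(num), abs(num_site), 1e-8)
    worst <- max(worst,
                 max(abs(out$grad_atoms - num)) / scale,
                 max(abs(out$grad_site - num_site)) / scale)
  }
  expect_lt(worst, 1e-6)
})

test_that("multi-dataset energy equals the sum of single-dataset energies", {
  cs1 <- simple_case(seed = 3)
  cs2 <- simple_case(seed = 4)
  ds1 <- cs1$ds; ds1$pcs <- ds1$pcs + 0.2
  ds2 <- cs2$ds; ds2$pcs <- ds2$pcs - 0.15
  both <- pcs_restraint_set(list(ds1, ds2), list(cs1$tensor, cs2$tensor),
                            cs1$site, tolerance = 0.03)
  only1 <- pcs_restraint_set(ds1, cs1$tensor, cs1$site, tolerance = 0.03)
  only2 <- pcs_restraint_set(ds2, cs2$tensor, cs1$site, tolerance = 0.03)
  e_both <- pcs_energy_grad(cs1$struct, both)$energy
  e_sum <- pcs_energy_grad(cs1$struct, only1)$energy +
    pcs_energy_grad(cs1$struct, only2)$energy
  expect_equal(e_both, e_sum, tolerance = 1e-12)
})

test_that("restraints on absent atoms raise a mapping error listing keys", {
  cs <- simple_case()
  ds <- cs$ds
  ds$residue_number[2] <- 777L
  restr <- pcs_restraint_set(ds, cs$tensor, cs$site)
  expect_error(pcs_energy_grad(cs$struct, restr), "777",
               class = "parashift_restraint_mapping_error")
})

test_that("refinement started at a planted minimum does not move", {
  helix <- fixture_helix(5)
  geom <- geometry_template(helix)
  ds <- fixture_exact_datasets(helix, c(4, 4, -5))
  restr <- pcs_restraint_set(ds, default_tensors(), c(4, 4, -5))
  out <- refine_structure(helix, geom, restr, max_steps = 50)
  disp <- sqrt(rowSums((as.matrix(out[, c("x", "y", "z")]) -
                          as.matrix(helix[, c("x", "y", "z")]))^2))
  expect_lt(max(disp), 1e-6)
  trace <- attr(out, "energy_trace")
  expect_true(all(diff(trace) <= 0))
})

test_that("refining a perturbed structure against noiseless PCS lowers Q", {
  helix <- fixture_helix(6)
  site <- c(4, 3, 10)
  ds <- fixture_exact_datasets(helix, site)
  geom <- geometry_template(helix, force_constant = 1)
  restr <- pcs_restraint_set(ds, default_tensors(), site,
                             force_constant = 50, tolerance = 0)
  start <- helix
  jitter <- withr::with_seed(8, matrix(rnorm(3 * nrow(helix), 0, 0.5), ncol = 3))
  start[, c("x", "y", "z")] <- start[, c("x", "y", "z")] + as.data.frame(jitter)
  q_of <- function(s) {
    fit_tensor_fixed_position(ds$Tm, s, site)$q_factor
  }
  out <- refine_structure(start, geom, restr, max_steps = 400,
                          refine_site = FALSE)
  expect_lt(q_of(out), q_of(start))
  expect_true(all(diff(attr(out, "energy_trace")) <= 0))
})

test_that("iterating tensors and structure from the truth converges in one round", {
  helix <- fixture_helix(6)
  site <- c(3, 2, 8)
  ds <- fixture_exact_datasets(helix, site)
  geom <- geometry_template(helix)
  out <- suppressMessages(iterate_tensor_structure(
    helix, ds, geom, max_rounds = 5, grid_spacing = 3,
    check_consistency = FALSE))
  expect_true(out$converged)
  expect_equal(max(out$rounds$round), 1)
  truth <- default_tensors()
  for (nm in names(truth)) {
    i <- which(vapply(out$fit$fits, function(f) f$metal_label, "") == nm)
    rel <- max(abs(out$fit$fits[[i]]$tensor$M - truth[[nm]]$M)) /
      max(abs(truth[[nm]]$M))
    expect_lt(rel, 1e-4)
  }
})

test_that("max_rounds = 0 returns the initial fit flagged unconverged", {
  helix <- fixture_helix(5)
  ds <- fixture_exact_datasets(helix, c(4, 4, -5))
  geom <- geometry_template(helix)
  out <- iterate_tensor_structure(helix, ds, geom, max_rounds = 0,
                                  grid_spacing = 3, check_consistency = FALSE)
  expect_false(out$converged)
  expect_equal(nrow(out$rounds), 0)
  expect_s3_class(out$fit, "pcs_joint_fit")
})

test_that("identical models give zero RMSD; rigid motion is invisible", {
  helix <- fixture_helix(4)
  two <- dplyr::bind_rows(helix, dplyr::mutate(helix, model = 2L))
  bs <- bundle_stats(as_structure(two))
  expect_lt(bs$pairwise_rmsd_mean, 1e-10)
  moved <- helix
  R <- rot_zyz(25, 40, 65)
  pos <- as.matrix(helix[, c("x", "y", "z")]) %*% t(R)
  moved[, c("x", "y", "z")] <- as.data.frame(sweep(pos, 2, c(3, -2, 7), "+"))
  moved$model <- 2L
  bs2 <- bundle_stats(as_structure(dplyr::bind_rows(helix, moved)))
  expect_lt(bs2$pairwise_rmsd_mean, 1e-6)
})

test_that("bundle stats are invariant under a global rigid motion of the ensemble", {
  helix <- fixture_helix(4)
  m2 <- helix
  jit <- withr::with_seed(5, matrix(rnorm(3 * nrow(helix), 0, 0.4), ncol = 3))
  m2[, c("x", "y", "z")] <- m2[, c("x", "y", "z")] + as.data.frame(jit)
  m2$model <- 2L
  ens <- as_structure(dplyr::bind_rows(helix, m2))
  bs <- bundle_stats(ens)
  R <- rot_zyz(-15, 72, 31)
  pos <- as.matrix(ens[, c("x", "y", "z")]) %*% t(R)
  ens2 <- ens
  ens2[, c("x", "y", "z")] <- as.data.frame(sweep(pos, 2, c(10, 0, -4), "+"))
  bs2 <- bundle_stats(as_structure(ens2))
  expect_equal(bs$pairwise_rmsd_mean, bs2$pairwise_rmsd_mean, tolerance = 1e-9)
})

test_that("moving one atom by d gives RMSD d/sqrt(N) under exact side-superposition", {
  helix <- fixture_helix(4)
  n <- nrow(helix)
  d <- 1.7
  m2 <- helix
  m2$z[1] <- m2$z[1] + d
  m2$model <- 2L
  ens <- as_structure(dplyr::bind_rows(helix, m2))
  moved_key <- paste(helix$residue_number[1], helix$atom_name[1])
  bs <- bundle_stats(
    ens,
    selection = function(s) rep(TRUE, nrow(s)),
    superpose = function(s) paste(s$residue_number, s$atom_name) != moved_key)
  expect_equal(bs$pairwise_rmsd_mean, d / sqrt(n), tolerance = 1e-9)
})

test_that("metal spread reflects the metal scatter after superposition", {
  helix <- fixture_helix(4)
  with_metal <- function(m, metal_xyz) {
    dplyr::bind_rows(helix,
                     tibble::tibble(model = 1L, residue_number = 999L,
                                    residue_name = "LN", atom_name = "LN",
                                    x = metal_xyz[1], y = metal_xyz[2],
                                    z = metal_xyz[3])) |>
      dplyr::mutate(model = m)
  }
  ens <- as_structure(dplyr::bind_rows(with_metal(1L, c(4, 4, 0)),
                                       with_metal(2L, c(4, 4, 1))))
  bs <- bundle_stats(ens, metal_atom_name = "LN")
  expect_equal(bs$metal_spread_rmsd, 0.5, tolerance = 1e-9)
})

test_that("tiny selections are rejected for superposition", {
  helix <- fixture_helix(3)
  two <- as_structure(dplyr::bind_rows(helix, dplyr::mutate(helix, model = 2L)))
  expect_error(bundle_stats(two, selection = function(s) seq_len(nrow(s)) <= 2),
               class = "parashift_superposition_error")
})

test_that("interhelical angle of a straight duplex split in half is ~0", {
  helix <- fixture_helix(12)
  pr <- attr(helix, "pairing")
  expect_lt(interhelical_angle(helix, pr[1:6, ], pr[7:12, ]), 1)
})

test_that("a junction built at 113 degrees measures 113 within a degree", {
  j <- fixture_junction(113)
  prs <- attr(j, "helix_pairings")
  expect_equal(interhelical_angle(j, prs[[1]], prs[[2]]), 113, tolerance = 1)
})

test_that("helices with fewer than 3 base pairs are a geometry error", {
  j <- fixture_junction(90)
  prs <- attr(j, "helix_pairings")
  expect_error(interhelical_angle(j, prs[[1]], prs[[2]][1:2, ]),
               class = "parashift_geometry_error")
})
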