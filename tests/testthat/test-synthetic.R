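test_that("helix geometry: rise between base-pair midpoints and atom counts", {
  h <- make_helix(10)
  pr <- attr(h, "pairing")
  mids <- t(apply(as.matrix(pr), 1, function(p) {
    a <- as.numeric(h[h$residue_number == p[1] & h$atom_name == "C1'",
                      c("x", "y", "z")])
    b <- as.numeric(h[h$residue_number == p[2] & h$atom_name == "C1'",
                      c("x", "y", "z")])
    (a + b) / 2
  }))
  seps <- sqrt(rowSums(diff(mids)^2))
  expect_true(all(abs(seps - 3.38) < 0.01))
  expect_equal(nrow(h), 10 * 2 * 6)   # n_bp x 2 strands x atoms per nucleotide
  expect_error(make_helix(0), "n_bp")
})

test_that("one helical step (twist + rise) maps base pair i onto i+1", {
  h <- make_helix(6)
  R <- rot_zyz(36, 0, 0)
  for (i in 1:5) {
    bp_i <- h[h$residue_number %in% c(i, 13 - i), ]
    bp_next <- h[h$residue_number %in% c(i + 1, 12 - i), ]
    mapped <- sweep(as.matrix(bp_i[, c("x", "y", "z")]) %*% t(R),
                    2, c(0, 0, 3.38), "+")
    # same atom order by construction within each strand/residue
    target <- as.matrix(bp_next[, c("x", "y", "z")])
    expect_lt(max(abs(mapped - target)), 1e-6)
  }
})

test_that("junction records the requested inter-axis angles as ground truth", {
  j <- fixture_junction(90)
  expect_equal(attr(j, "truth_angles")[1, 2], 90, tolerance = 1e-9)
  prs <- attr(j, "helix_pairings")
  expect_equal(interhelical_angle(j, prs[[1]], prs[[2]]), 90, tolerance = 1)
  j113 <- fixture_junction(113)
  expect_equal(attr(j113, "truth_angles")[1, 2], 113, tolerance = 1e-9)
})

test_that("overlapping helices raise a clash error", {
  # second helix placed exactly on top of the first
  expect_error(
    make_junction(list(list(n_bp = 6),
                       list(n_bp = 6, direction = c(0, 0, 1), gap = -18.9))),
    class = "parashift_clash_error")
})

test_that("noiseless uncensored planting equals the exact forward model", {
  h <- fixture_helix(6)
  site <- c(4, 4, 8)
  ds <- plant_pcs(h, site, noise_sigma = 0, blind_radius = 0,
                  missing_fraction = 0, seed = 1)
  protons <- h[startsWith(h$atom_name, "H"), ]
  expect_equal(nrow(ds$Tm), nrow(protons))
  tm <- default_tensors()$Tm
  exact <- pcs_forward(tm, site, as.matrix(protons[, c("x", "y", "z")]))
  expect_equal(ds$Tm$pcs, exact, tolerance = 1e-12)
})

test_that("the blind zone equals a brute-force distance filter", {
  h <- fixture_helix(8)
  site <- c(2, 3, 10)
  ds <- plant_pcs(h, site, noise_sigma = 0, blind_radius = 7,
                  missing_fraction = 0, seed = 2)
  protons <- h[startsWith(h$atom_name, "H"), ]
  d <- sqrt(rowSums(sweep(as.matrix(protons[, c("x", "y", "z")]), 2, site)^2))
  kept <- protons[d >= 7, ]
  expect_equal(nrow(ds$Eu), nrow(kept))
  expect_setequal(paste(ds$Eu$residue_number, ds$Eu$atom_name),
                  paste(kept$residue_number, kept$atom_name))
})

test_that("planting is deterministic in the seed and censoring thins datasets", {
  h <- fixture_helix(6)
  a <- plant_pcs(h, c(4, 4, 8), noise_sigma = 0.02, missing_fraction = 0.3,
                 seed = 42)
  b <- plant_pcs(h, c(4, 4, 8), noise_sigma = 0.02, missing_fraction = 0.3,
                 seed = 42)
  expect_identical(a, b)
  full <- plant_pcs(h, c(4, 4, 8), noise_sigma = 0, blind_radius = 0,
                    missing_fraction = 0, seed = 1)
  expect_lt(nrow(a$Tm), nrow(full$Tm))
  expect_error(plant_pcs(h, c(4, 4, 8), blind_radius = 1e4),
               class = "parashift_empty_dataset_error")
})

test_that("solvent perturbation with identity parameters is the identity", {
  t <- default_tensors()$Yb
  same <- perturb_tensor_solvent(t, scale = 1, rotation = 0)
  expect_lt(max(abs(t$M - same$M)), 1e-14)
})

test_that("noiseless censored data still give exact recovery (no censoring bias)", {
  h <- fixture_helix(8)
  site <- c(2, 3, 10)
  ds <- plant_pcs(h, site, noise_sigma = 0, blind_radius = 7,
                  missing_fraction = 0.2, seed = 3)
  expect_true(all(vapply(ds, nrow, 0L) >= 5))
  jf <- fit_position_and_tensors(ds, h, grid_spacing = 3,
                                 check_consistency = FALSE)
  expect_lt(sqrt(sum((jf$site - site)^2)), 0.01)
  truth <- default_tensors()
  for (nm in names(truth)) {
    i <- which(vapply(jf$fits, function(f) f$metal_label, "") == nm)
    expect_lt(max(abs(jf$fits[[i]]$tensor$M - truth[[nm]]$M)) /
                max(abs(truth[[nm]]$M)), 1e-6)
  }
})

test_that("noisy end-to-end closure: site within 0.3 A, axiality within 5 %", {
  h <- fixture_junction(113, n_bp = 6)
  site <- c(3, 2, 22)
  truth_ax <- tensor_convert(default_tensors()$Tm, "paf")$dchi_ax
  res <- purrr::map_dfr(1:20, function(s) {
    ds <- plant_pcs(h, site, noise_sigma = 0.02, blind_radius = 7,
                    missing_fraction = 0.1, seed = s)
    jf <- fit_position_and_tensors(ds, h, box = rbind(site - 8, site + 8),
                                   grid_spacing = 4, check_consistency = FALSE)
    i <- which(vapply(jf$fits, function(f) f$metal_label, "") == "Tm")
    tibble::tibble(site_err = sqrt(sum((jf$site - site)^2)),
                   ax_rel = abs(tensor_convert(jf$fits[[i]]$tensor, "paf")$dchi_ax -
                                  truth_ax) / abs(truth_ax))
  })
  expect_lt(median(res$site_err), 0.3)
  expect_lt(median(res$ax_rel), 0.05)
})

test_that("titration generator closes the loop with the Kd fitter", {
  pts <- make_titration(300e-9, 10e-6, seq(0, 40e-6, length.out = 12),
                        s_free = 0.2, s_bound = 1.1)
  fit <- fit_kd_titration(pts, ligand_total = 10e-6)
  expect_equal(fit$kd, 300e-9, tolerance = 1e-6)
  expect_equal(fit$s_free, 0.2, tolerance = 1e-6)
  # endpoint: no metal, free signal exactly
  expect_equal(pts$signal[pts$metal_total == 0], 0.2)
  # determinism
  a <- make_titration(1e-6, 5e-6, c(0, 2e-6, 6e-6, 2e-5), noise_sd = 0.05, seed = 9)
  b <- make_titration(1e-6, 5e-6, c(0, 2e-6, 6e-6, 2e-5), noise_sd = 0.05, seed = 9)
  expect_identical(a, b)
})
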