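test_that("Q-factor matches hand arithmetic and its edge cases", {
  expect_equal(q_factor(c(1, 2, -3), c(1, 2, -3)), 0)
  expect_equal(q_factor(c(1, -1), c(0.9, -0.9)), 0.1, tolerance = 1e-12)
  expect_equal(q_factor(c(0.4, -0.7, 1.1), c(0, 0, 0)), 1)
  # scale consistency
  obs <- c(0.3, -0.8, 1.2); calc <- c(0.25, -0.7, 1.3)
  for (c_ in c(2, -5, 0.01)) {
    expect_equal(q_factor(c_ * obs, c_ * calc), q_factor(obs, calc),
                 tolerance = 1e-12)
  }
  expect_error(q_factor(c(0, 0), c(1, 2)), class = "parashift_undefined_q_error")
  expect_error(q_factor(1:3, 1:2), "equal")
})

test_that("noiseless linear fit recovers the planted tensor exactly", {
  site <- c(1, -2, 0.5)
  pos <- fixture_random_positions(20, site = site, seed = 21)
  truth <- random_tensor(5)
  ds <- fixture_dataset_from_positions(truth, site, pos)
  fit <- fit_tensor_fixed_position(ds, fixture_positions_structure(pos), site)
  expect_lt(max(abs(fit$tensor$M - truth$M)), 1e-10)
  expect_lt(fit$q_factor, 1e-10)
  expect_equal(fit$n_obs, 20)
})

test_that("five general-position atoms reproduce the pseudo-inverse oracle", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(5, seed = 31)
  truth <- random_tensor(7)
  ds <- fixture_dataset_from_positions(truth, site, pos)
  # independent oracle: columns of the design built by evaluating the
  # PAF-route forward model on unit component tensors, then a direct solve
  unit <- list(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0),
               c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1))
  A <- vapply(unit, function(u) {
    pcs_forward(dchi_components(u[1], u[2], u[3], u[4], u[5]), site, pos,
                method = "paf")
  }, numeric(5))
  beta <- solve(A, ds$pcs)
  fit <- fit_tensor_fixed_position(ds, fixture_positions_structure(pos), site)
  got <- tensor_convert(fit$tensor, "components")
  expect_equal(unname(unlist(got)), unname(beta), tolerance = 1e-8)
})

test_that("collinear atoms raise a degenerate-geometry error", {
  site <- c(0, 0, 0)
  pos <- cbind(seq(2, 20, length.out = 10), 0, 0)  # one line through the site
  truth <- random_tensor(1)
  ds <- fixture_dataset_from_positions(truth, site, pos)
  expect_error(fit_tensor_fixed_position(ds, fixture_positions_structure(pos), site),
               "null space", class = "parashift_degenerate_geometry_error")
})

test_that("entries without structure atoms are skipped with a log message", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(10, seed = 2)
  truth <- random_tensor(2)
  ds <- fixture_dataset_from_positions(truth, site, pos)
  ds$residue_number[1] <- 999L
  expect_message(
    fit <- fit_tensor_fixed_position(ds, fixture_positions_structure(pos), site),
    "skipping")
  expect_equal(fit$n_obs, 9)
})

test_that("joint fit recovers four planted tensors and their shared site", {
  helix <- fixture_helix()
  site <- c(4, 4, -5)
  datasets <- fixture_exact_datasets(helix, site)
  jf <- fit_position_and_tensors(datasets, helix, grid_spacing = 3)
  expect_lt(sqrt(sum((jf$site - site)^2)), 0.01)
  truth <- default_tensors()
  for (nm in names(truth)) {
    i <- which(vapply(jf$fits, function(f) f$metal_label, "") == nm)
    rel <- max(abs(jf$fits[[i]]$tensor$M - truth[[nm]]$M)) / max(abs(truth[[nm]]$M))
    expect_lt(rel, 1e-6)
    expect_lt(jf$fits[[i]]$q_factor, 1e-8)
  }
})

test_that("single-dataset joint fit agrees with the fixed-position fit at its site", {
  helix <- fixture_helix(6)
  site <- c(3, 2, 8)
  ds <- fixture_exact_datasets(helix, site)[[1]]
  jf <- fit_position_and_tensors(ds, helix, grid_spacing = 3)
  expect_lt(sqrt(sum((jf$site - site)^2)), 0.05)
  ff <- fit_tensor_fixed_position(ds, helix, jf$site)
  expect_lt(max(abs(jf$fits[[1]]$tensor$M - ff$tensor$M)), 1e-10)
  expect_equal(jf$fits[[1]]$q_factor, ff$q_factor, tolerance = 1e-10)
})

test_that("datasets planted at different sites trigger the inconsistency warning", {
  helix <- fixture_helix()
  t1 <- dchi_paf(2.5, -0.8, 20, 40, 10)
  t2 <- dchi_paf(-3.1, 1.1, 70, 30, -50)
  d1 <- plant_pcs(helix, c(4, 4, -5), list(A = t1), noise_sigma = 0,
                  blind_radius = 0, missing_fraction = 0, seed = 1)[[1]]
  d2 <- plant_pcs(helix, c(4, 4, 0), list(B = t2), noise_sigma = 0,
                  blind_radius = 0, missing_fraction = 0, seed = 1)[[1]]
  ws <- testthat::capture_warnings(
    jf <- fit_position_and_tensors(list(d1, d2), helix, grid_spacing = 3))
  expect_true(any(grepl("share a metal site", ws)))
  # joint Q markedly exceeds what each dataset achieves on its own site
  sep1 <- fit_position_and_tensors(d1, helix, grid_spacing = 3,
                                   check_consistency = FALSE)
  expect_gt(min(vapply(jf$fits, function(f) f$q_factor, 0)) /
              max(sep1$fits[[1]]$q_factor, 1e-12), 2)
})

test_that("flat PCS surfaces are reported as non-identifiable", {
  pos <- fixture_random_positions(8, seed = 3)
  ds <- pcs_dataset(tibble::tibble(residue_number = 1:8, atom_name = "H8",
                                   pcs = 0, sigma = 0.01))
  # all-zero observations: every candidate site fits exactly, surface flat
  expect_error(
    fit_position_and_tensors(ds, fixture_positions_structure(pos),
                             box = rbind(c(-5, -5, -5), c(5, 5, 5)),
                             grid_spacing = 5),
    class = "parashift_non_identifiable_error")
})

test_that("leave-one-out on noiseless data predicts held-out entries exactly", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(15, seed = 12)
  truth <- random_tensor(4)
  ds <- fixture_dataset_from_positions(truth, site, pos)
  cv <- cross_validate(ds, fixture_positions_structure(pos), site, scheme = "loo")
  expect_lt(cv$q_free, 1e-8)
  expect_lt(cv$q_work, 1e-10)
})

test_that("with noise, Q_free >= Q_work in nearly all replicates", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(40, seed = 13)
  struct <- fixture_positions_structure(pos)
  truth <- random_tensor(9)
  exact <- pcs_forward(truth, site, pos)
  worse <- withr::with_seed(99, vapply(1:100, function(r) {
    ds <- pcs_dataset(tibble::tibble(residue_number = 1:40, atom_name = "H8",
                                     pcs = exact + rnorm(40, 0, 0.02),
                                     sigma = 0.02))
    cv <- cross_validate(ds, struct, site, scheme = "loo")
    cv$q_free >= cv$q_work
  }, TRUE))
  expect_gte(sum(worse), 95)
})

test_that("a nucleus holdout with no matching entries is a fold-size error", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(10, seed = 14)
  ds <- fixture_dataset_from_positions(random_tensor(1), site, pos)
  expect_error(
    cross_validate(ds, fixture_positions_structure(pos), site,
                   holdout_nucleus = "^P"),
    class = "parashift_fold_size_error")
})

test_that("31P-style holdout keeps phosphorus out of training", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(14, seed = 15)
  struct <- fixture_positions_structure(pos)
  struct$atom_name[11:14] <- "P"
  truth <- random_tensor(6)
  ds <- pcs_dataset(tibble::tibble(
    residue_number = 1:14,
    atom_name = struct$atom_name,
    pcs = pcs_forward(truth, site, pos), sigma = 0.01))
  cv <- cross_validate(ds, struct, site, holdout_nucleus = "^P")
  expect_equal(nrow(cv$predictions), 4)
  expect_true(all(cv$predictions$atom_name == "P"))
  expect_lt(cv$q_free, 1e-8)   # noiseless: the exact model extrapolates
})

test_that("bootstrap uncertainties are deterministic and scale with sigma", {
  helix <- fixture_helix(6)
  site <- c(3, 2, 8)
  ds <- fixture_exact_datasets(helix, site)[c("Tm", "Eu")]
  jf <- fit_position_and_tensors(ds, helix, grid_spacing = 3,
                                 check_consistency = FALSE)
  u1 <- mc_uncertainty(jf, ds, helix, sigma = 0.01, n_replicates = 60, seed = 5)
  u1b <- mc_uncertainty(jf, ds, helix, sigma = 0.01, n_replicates = 60, seed = 5)
  expect_identical(u1, u1b)
  u2 <- mc_uncertainty(jf, ds, helix, sigma = 0.02, n_replicates = 60, seed = 5)
  ax1 <- u1$sd[u1$dataset == "Tm" & u1$parameter == "dchi_ax"]
  ax2 <- u2$sd[u2$dataset == "Tm" & u2$parameter == "dchi_ax"]
  expect_equal(ax2 / ax1, 2, tolerance = 0.2)
  expect_error(mc_uncertainty(jf, ds, helix, sigma = 0), "> 0")
  expect_error(mc_uncertainty(jf, ds, helix, sigma = 0.01, n_replicates = 10),
               ">= 50")
})

test_that("the fixed-site estimator is unbiased over noise replicates", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(25, seed = 16)
  struct <- fixture_positions_structure(pos)
  truth <- dchi_paf(1.42, -0.55, 30, 60, 20)
  truth_ax <- tensor_convert(truth, "paf")$dchi_ax
  exact <- pcs_forward(truth, site, pos)
  est <- withr::with_seed(7, vapply(1:200, function(r) {
    ds <- pcs_dataset(tibble::tibble(residue_number = 1:25, atom_name = "H8",
                                     pcs = exact + rnorm(25, 0, 0.02),
                                     sigma = 0.02))
    f <- fit_tensor_fixed_position(ds, struct, site)
    p <- tensor_convert(f$tensor, "paf")
    sign(p$dchi_ax) * p$dchi_ax
  }, 0))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - abs(truth_ax)), 3 * se)
})

test_that("Q grows with the injected noise level", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(30, seed = 17)
  struct <- fixture_positions_structure(pos)
  truth <- random_tensor(3)
  exact <- pcs_forward(truth, site, pos)
  mean_q <- vapply(c(0.005, 0.02, 0.08), function(s) {
    qs <- withr::with_seed(11, vapply(1:20, function(r) {
      ds <- pcs_dataset(tibble::tibble(residue_number = 1:30, atom_name = "H8",
                                       pcs = exact + rnorm(30, 0, s),
                                       sigma = s))
      fit_tensor_fixed_position(ds, struct, site)$q_factor
    }, 0))
    mean(qs)
  }, 0)
  expect_true(all(diff(mean_q) > 0))
})

test_that("diastereotopic swaps are found and undone", {
  site <- c(0, 0, 0)
  pos <- fixture_random_positions(12, seed = 18)
  struct <- as_structure(tibble::tibble(
    residue_number = rep(1:6, each = 2),
    residue_name = "DG",
    atom_name = rep(c("H5'", "H5''"), 6),
    x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  truth <- random_tensor(8)
  exact <- pcs_forward(truth, site, pos)
  d <- tibble::tibble(residue_number = struct$residue_number,
                      atom_name = struct$atom_name,
                      pcs = exact, sigma = 0.01)
  # swap the observed pair of residues 2 and 5 (mis-assignment)
  for (res in c(2, 5)) {
    i <- which(d$residue_number == res)
    d$pcs[i] <- rev(d$pcs[i])
  }
  ds <- pcs_dataset(d)
  fixed <- resolve_diastereotopic(ds, struct, site, truth)
  expect_setequal(attr(fixed, "swapped"),
                  c("2:H5'/H5''", "5:H5'/H5''"))
  f <- fit_tensor_fixed_position(fixed, struct, site)
  expect_lt(f$q_factor, 1e-10)
})
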