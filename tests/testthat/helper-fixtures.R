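# Shared fixtures, all built in code.

# A 10-bp duplex with all template atoms.
fixture_helix <- function(n_bp = 10) make_helix(n_bp)

# Two-helix junction at a given inter-axis angle (degrees).
fixture_junction <- function(angle = 113, n_bp = 8, gap = 8) {
  a <- angle * pi / 180
  make_junction(list(
    list(n_bp = n_bp),
    list(n_bp = n_bp, direction = c(sin(a), 0, cos(a)), gap = gap)))
}

# Noiseless, uncensored PCS from the reference tensors.
fixture_exact_datasets <- function(structure, site) {
  plant_pcs(structure, site, noise_sigma = 0, blind_radius = 0,
            missing_fraction = 0, seed = 1)
}

# Random general-position atoms around (but not too near) a site.
fixture_random_positions <- function(n, site = c(0, 0, 0), seed = 1,
                                     r_min = 6, r_max = 20) {
  withr::with_seed(seed, {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(n, r_min, r_max)
    sweep(u * r, 2, site, "+")
  })
}

# Structure tibble wrapping a coordinate matrix of proton-like atoms.
fixture_positions_structure <- function(pos) {
  as_structure(tibble::tibble(
    residue_number = seq_len(nrow(pos)),
    residue_name = "DG",
    atom_name = "H8",
    x = pos[, 1], y = pos[, 2], z = pos[, 3]))
}

# Dataset with exact forward PCS at the given positions.
fixture_dataset_from_positions <- function(tensor, site, pos, sigma = 0.01) {
  pcs_dataset(tibble::tibble(
    residue_number = seq_len(nrow(pos)),
    atom_name = "H8",
    pcs = pcs_forward(tensor, site, pos),
    sigma = sigma))
}

random_tensor <- function(seed) {
  withr::with_seed(seed, {
    v <- rnorm(5)
    dchi_components(v[1], v[2], v[3], v[4], v[5])
  })
}

expect_no_condition_quietly <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}
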