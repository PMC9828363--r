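# Reduced-atom nucleotide template, local base-pair frame (Angstrom).
# The C1' sits on the frame's y axis so that paired C1' midpoints fall
# exactly on the helix axis; PCS depends only on positions, so a reduced
# atom set is sufficient for synthetic ground-truth work.
NT_TEMPLATE <- tibble::tribble(
  ~atom_name, ~px,  ~py,  ~pz,
  "P",         3.0,  8.0,  2.2,
  "C1'",       0.0,  5.9,  0.0,
  "N1",        0.8,  3.5,  0.2,
  "H1'",       1.2,  6.5,  0.8,
  "H8",        2.2,  4.5,  0.5,
  "H2'",       2.8,  7.0,  1.4
)

#' Build an idealised reduced-atom DNA duplex
#'
#' Places a reduced atom set per nucleotide (P, C1', a base-nitrogen proxy
#' and three proton sites) by helical symmetry: base pair `i` is base pair
#' `i-1` rotated by `twist` degrees about the z axis and translated by
#' `rise` Angstrom along it. The second strand is the C2 dyad image of the
#' first, so residue `i` (strand 1, residues `1..n_bp`) pairs residue
#' `2*n_bp + 1 - i` (strand 2) and paired C1' midpoints lie exactly on the
#' axis, `rise` apart.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param rise Helical rise, Angstrom (default 3.38).
#' @param twist Helical twist, degrees (default 36).
#' @param atoms Atom-name subset of the template (default: all 6).
#' @param start_residue First residue number of strand 1.
#' @return A structure tibble with attributes `pairing` (tibble `res1`,
#'   `res2`, one row per bp, axis order) and `axis` (unit 3-vector, z).
#' @export
make_helix <- function(n_bp, rise = 3.38, twist = 36.0,
                       atoms = NT_TEMPLATE$atom_name, start_residue = 1L) {
  if (n_bp < 1) abort("n_bp must be >= 1")
  if (rise <= 0 || twist <= 0) abort("rise and twist must be > 0")
  tmpl <- NT_TEMPLATE[NT_TEMPLATE$atom_name %in% atoms, ]
  if (!nrow(tmpl)) abort("no template atoms selected")
  names_bp <- rep_len(c("DA", "DG"), n_bp)
  comp <- c(DA = "DT", DG = "DC")
  rows <- purrr::map_dfr(seq_len(n_bp), function(i) {
    Rz <- rot_axis((i - 1) * twist, "z")
    shift <- c(0, 0, (i - 1) * rise)
    local1 <- as.matrix(tmpl[, c("px", "py", "pz")])
    local2 <- local1 %*% diag(c(1, -1, -1))     # C2 dyad about the bp x axis
    g1 <- sweep(local1 %*% t(Rz), 2, shift, "+")
    g2 <- sweep(local2 %*% t(Rz), 2, shift, "+")
    dplyr::bind_rows(
      tibble(residue_number = start_residue + i - 1L,
             residue_name = names_bp[i], atom_name = tmpl$atom_name,
             x = g1[, 1], y = g1[, 2], z = g1[, 3]),
      tibble(residue_number = start_residue + 2L * n_bp - i,
             residue_name = comp[[names_bp[i]]], atom_name = tmpl$atom_name,
             x = g2[, 1], y = g2[, 2], z = g2[, 3]))
  })
  out <- as_structure(dplyr::arrange(rows, .data$residue_number))
  attr(out, "pairing") <- tibble(res1 = start_residue + seq_len(n_bp) - 1L,
                                 res2 = start_residue + 2L * n_bp - seq_len(n_bp))
  attr(out, "axis") <- c(0, 0, 1)
  out
}

#' Assemble a multi-helix junction with known interhelical angles
#'
#' Builds each helix with [make_helix()], rotates it so its axis points
#' along the requested direction, and places it beyond the end of the
#' previous helix with a linker gap. Residue numbering is contiguous across
#' helices. The requested axis directions are recorded as ground truth.
#'
#' @param helices List of per-helix specs: each a list with `n_bp` and
#'   optionally `rise`, `twist`, `direction` (3-vector; default the z axis
#'   for the first helix), `gap` (Angstrom along the new direction,
#'   default 2).
#' @param min_separation Clash threshold, Angstrom: any pair of atoms from
#'   different helices closer than this raises a clash error.
#' @return A structure tibble with attributes `helix_pairings` (list of
#'   base-pair tables for [interhelical_angle()]), `helix_residues` (list
#'   of residue-number vectors, for [geometry_template()] groups),
#'   `truth_angles` (matrix of pairwise inter-axis angles, degrees) and
#'   `axes` (list of unit vectors).
#' @export
make_junction <- function(helices, min_separation = 1) {
  stopifnot(length(helices) >= 1)
  placed <- list()
  pairings <- list()
  residues <- list()
  axes <- list()
  next_res <- 1L
  anchor <- c(0, 0, 0)
  for (h in seq_along(helices)) {
    spec <- helices[[h]]
    dir <- spec$direction %||% c(0, 0, 1)
    dir <- dir / sqrt(sum(dir^2))
    gap <- spec$gap %||% 2
    hx <- make_helix(spec$n_bp, rise = spec$rise %||% 3.38,
                     twist = spec$twist %||% 36.0, start_residue = next_res)
    R <- rot_between(c(0, 0, 1), dir)
    pos <- as.matrix(hx[, c("x", "y", "z")]) %*% t(R)
    origin <- anchor + if (h == 1) c(0, 0, 0) else gap * dir
    pos <- sweep(pos, 2, origin, "+")
    hx$x <- pos[, 1]; hx$y <- pos[, 2]; hx$z <- pos[, 3]
    placed[[h]] <- hx
    pairings[[h]] <- attr(hx, "pairing")
    residues[[h]] <- sort(unique(hx$residue_number))
    axes[[h]] <- dir
    # helix axis runs from bp 1 to bp n: advance the anchor to its far end
    anchor <- origin + dir * ((spec$n_bp - 1) * (spec$rise %||% 3.38) + gap)
    next_res <- next_res + 2L * spec$n_bp
  }
  out <- dplyr::bind_rows(placed)
  if (length(placed) > 1) {
    for (a in seq_along(placed)) {
      for (b in seq_along(placed)) {
        if (b <= a) next
        pa <- as.matrix(placed[[a]][, c("x", "y", "z")])
        pb <- as.matrix(placed[[b]][, c("x", "y", "z")])
        d2min <- min(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))
        if (d2min < min_separation^2) {
          abort(sprintf("helices %d and %d clash (closest approach %.2f A)",
                        a, b, sqrt(max(0, d2min))),
                class = "parashift_clash_error")
        }
      }
    }
  }
  out <- as_structure(out)
  nh <- length(axes)
  truth <- matrix(0, nh, nh)
  for (a in seq_len(nh)) for (b in seq_len(nh)) {
    truth[a, b] <- rad2deg(acos(max(-1, min(1, sum(axes[[a]] * axes[[b]])))))
  }
  attr(out, "helix_pairings") <- pairings
  attr(out, "helix_residues") <- residues
  attr(out, "truth_angles") <- truth
  attr(out, "axes") <- axes
  out
}

#' Reference set of planted delta-chi tensors
#'
#' Four tensors with mixed signs and magnitudes spanning the range typical
#' of lanthanides in a nucleic-acid binding site (axialities between -4 and
#' +1.5 in 1e-32 m^3), each with a distinct principal-axis orientation, so
#' that every emulated metal produces a very different PCS pattern.
#'
#' @return Named list of [dchi_tensor] objects (Ce, Eu, Tm, Yb).
#' @export
default_tensors <- function() {
  list(Ce = dchi_paf(0.96, -0.61, alpha = 10, beta = 25, gamma = 40),
       Eu = dchi_paf(1.42, -0.55, alpha = 120, beta = 70, gamma = -30),
       Tm = dchi_paf(-3.88, 1.62, alpha = -60, beta = 45, gamma = 15),
       Yb = dchi_paf(-2.77, 1.29, alpha = 75, beta = 110, gamma = 80))
}

#' Plant synthetic PCS datasets on a structure
#'
#' For every proton-like atom (name starting with `H`) the exact forward
#' PCS is computed, Gaussian noise of `noise_sigma` ppm is added, atoms
#' closer than `blind_radius` to the metal are removed (the PRE blind zone,
#' where broadening quenches the peaks), and a further random fraction
#' `missing_fraction` is dropped (emulating unassignable resonances). Fully
#' reproducible from `seed`.
#'
#' @param structure Structure tibble (first model used).
#' @param site Metal position, 3-vector.
#' @param tensors List of [dchi_tensor] (default [default_tensors()]).
#' @param noise_sigma Gaussian shift noise, ppm (default 0.02).
#' @param blind_radius PRE blind-zone radius, Angstrom (default 7).
#' @param missing_fraction Random missing-peak probability (default 0.1).
#' @param seed RNG seed.
#' @return Named list of [pcs_dataset()] (one per tensor).
#' @export
plant_pcs <- function(structure, site, tensors = default_tensors(),
                      noise_sigma = 0.02, blind_radius = 7,
                      missing_fraction = 0.1, seed = 1L) {
  if (noise_sigma < 0 || blind_radius < 0) abort("noise_sigma and blind_radius must be >= 0")
  if (missing_fraction < 0 || missing_fraction >= 1) abort("missing_fraction must be in [0, 1)")
  s <- structure[structure$model == structure$model[1], ]
  protons <- s[startsWith(s$atom_name, "H"), ]
  if (!nrow(protons)) abort("structure has no proton-like atoms")
  pos <- as.matrix(protons[, c("x", "y", "z")])
  dist <- sqrt(rowSums(sweep(pos, 2, as.numeric(site))^2))
  visible <- dist >= max(blind_radius, PCS_GUARD_RADIUS)
  if (!any(visible)) abort("blind zone removes every proton",
                           class = "parashift_empty_dataset_error")
  labels <- names(tensors) %||% paste0("metal", seq_along(tensors))
  withr::with_seed(seed, {
    purrr::imap(setNames(tensors, labels), function(tensor, label) {
      keep <- visible & (runif(nrow(protons)) >= missing_fraction)
      if (!any(keep)) abort("censoring removed every observation",
                            class = "parashift_empty_dataset_error")
      p <- protons[keep, ]
      exact <- pcs_forward(tensor, site, pos[keep, , drop = FALSE])
      pcs_dataset(tibble(residue_number = p$residue_number,
                         atom_name = p$atom_name,
                         pcs = exact + rnorm(sum(keep), 0, noise_sigma),
                         sigma = max(noise_sigma, 1e-4)),
                  metal_label = label)
    })
  })
}

#' Simulate a 1:1 titration table
#'
#' Generates `signal = s_free + (s_bound - s_free) * f_bound(ligand)` from
#' the closed-form 1:1 binding model plus Gaussian noise.
#'
#' @param kd Dissociation constant, molar.
#' @param ligand_total Ligand (oligonucleotide) concentration, molar.
#' @param metal_points Numeric vector of total metal concentrations, molar.
#' @param s_free,s_bound Signal end points.
#' @param noise_sd Absolute Gaussian noise on the signal.
#' @param seed RNG seed.
#' @return Tibble with `metal_total` and `signal`.
#' @export
make_titration <- function(kd, ligand_total, metal_points,
                           s_free = 0, s_bound = 1, noise_sd = 0, seed = 1L) {
  fb <- vapply(metal_points, function(m) {
    bound_fraction_ligand(ligand_total, m, kd)
  }, 0)
  signal <- s_free + (s_bound - s_free) * fb
  if (noise_sd > 0) {
    signal <- withr::with_seed(seed, signal + rnorm(length(signal), 0, noise_sd))
  }
  tibble(metal_total = metal_points, signal = signal)
}
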