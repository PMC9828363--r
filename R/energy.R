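#' PCS restraint set for refinement
#'
#' Bundles one or more PCS datasets with their (fixed) tensors, the shared
#' metal site, a force constant and a flat-bottom tolerance into the
#' restraint object consumed by [pcs_energy_grad()] and
#' [refine_structure()]. Multiple datasets (samples) contribute additively.
#'
#' @param datasets A [pcs_dataset()] or list of them.
#' @param tensors A [dchi_tensor] or list, one per dataset.
#' @param site Metal position, Angstrom 3-vector.
#' @param force_constant Energy per ppm^2 (default 1).
#' @param tolerance Flat-bottom half-width, ppm (default 0.05): deviations
#'   smaller than this cost nothing.
#' @return A `pcs_restraint_set`.
#' @export
pcs_restraint_set <- function(datasets, tensors, site,
                              force_constant = 1, tolerance = 0.05) {
  if (inherits(datasets, "pcs_dataset")) datasets <- list(datasets)
  if (is_dchi_tensor(tensors)) tensors <- list(tensors)
  if (length(datasets) != length(tensors)) {
    abort("need exactly one tensor per dataset")
  }
  if (tolerance < 0) abort("tolerance must be >= 0")
  structure(list(datasets = datasets, tensors = tensors,
                 site = as.numeric(site),
                 force_constant = force_constant, tolerance = tolerance),
            class = "pcs_restraint_set")
}

#' PCS pseudo-energy and analytic gradients
#'
#' Flat-bottom harmonic restraint energy over all datasets,
#' `E = sum_d sum_i k * max(0, |calc_i - obs_i| - tol)^2`, with analytic
#' gradients with respect to every restrained nuclear coordinate and the
#' three metal-site coordinates (chain rule through the forward model).
#' The total energy is exactly the sum of single-dataset energies.
#'
#' @param structure Structure tibble (single model).
#' @param restraints A [pcs_restraint_set()].
#' @return List with `energy` (scalar), `grad_atoms` (n_atoms x 3 matrix,
#'   zero rows for unrestrained atoms, ordered as the structure rows) and
#'   `grad_site` (length-3).
#' @export
pcs_energy_grad <- function(structure, restraints) {
  s <- structure[structure$model == structure$model[1], ]
  pos_all <- as.matrix(s[, c("x", "y", "z")])
  key <- paste(s$residue_number, s$atom_name)
  energy <- 0
  grad_atoms <- matrix(0, nrow(s), 3)
  grad_site <- c(0, 0, 0)
  k <- restraints$force_constant
  tol <- restraints$tolerance
  for (j in seq_along(restraints$datasets)) {
    d <- restraints$datasets[[j]]
    idx <- match(paste(d$residue_number, d$atom_name), key)
    if (anyNA(idx)) {
      bad <- paste(d$residue_number, d$atom_name)[is.na(idx)]
      abort(paste0("restrained atom(s) absent from the structure: ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            class = "parashift_restraint_mapping_error")
    }
    pos <- pos_all[idx, , drop = FALSE]
    tensor <- restraints$tensors[[j]]
    calc <- pcs_forward(tensor, restraints$site, pos)
    dev <- calc - d$pcs
    excess <- pmax(0, abs(dev) - tol)
    energy <- energy + k * sum(excess^2)
    dEdcalc <- 2 * k * excess * sign(dev)
    active <- dEdcalc != 0
    if (any(active)) {
      g <- pcs_forward_grad(tensor, restraints$site, pos[active, , drop = FALSE])
      contrib <- g * dEdcalc[active]
      for (col in 1:3) {
        grad_atoms[, col] <- grad_atoms[, col] +
          as.vector(tapply(contrib[, col], factor(idx[active], levels = seq_len(nrow(s))),
                           sum, default = 0))
      }
      grad_site <- grad_site - colSums(contrib)
    }
  }
  list(energy = energy, grad_atoms = grad_atoms, grad_site = grad_site)
}

#' Harmonic geometry template from a reference structure
#'
#' Extracts harmonic distance terms (bond/stacking/base-pair surrogates)
#' from a reference structure: every atom pair within `cutoff` that belongs
#' to the same `group` (e.g. the same helix), plus sequence-adjacent pairs
#' within `linker_cutoff` regardless of group to preserve chain
#' connectivity. The targets are the reference distances, so the reference
#' is an exact minimum of the template energy. This deliberately local
#' template mirrors the short-range character of NOE-type restraints: it
#' keeps each helix rigid while leaving the mutual orientation of the
#' helices essentially free.
#'
#' @param reference Structure tibble (single model used).
#' @param groups Optional list of residue-number vectors defining rigid
#'   groups (default: one group with all residues).
#' @param cutoff Within-group pair distance cutoff, Angstrom.
#' @param linker_cutoff Cross-group cutoff for |residue difference| <= 1.
#' @param force_constant Energy per Angstrom^2.
#' @return A `geometry_template` tibble: atom-pair indices and keys,
#'   `target` distance, `k`.
#' @export
geometry_template <- function(reference, groups = NULL, cutoff = 6,
                              linker_cutoff = 8, force_constant = 5) {
  s <- reference[reference$model == reference$model[1], ]
  pos <- as.matrix(s[, c("x", "y", "z")])
  n <- nrow(s)
  grp <- rep(1L, n)
  if (!is.null(groups)) {
    grp <- rep(NA_integer_, n)
    for (g in seq_along(groups)) grp[s$residue_number %in% groups[[g]]] <- g
  }
  D <- as.matrix(stats::dist(pos))
  same <- outer(grp, grp, `==`)
  same[is.na(same)] <- FALSE
  adj <- abs(outer(s$residue_number, s$residue_number, `-`)) <= 1
  keep <- upper.tri(D) & ((same & D <= cutoff) | (adj & D <= linker_cutoff))
  ij <- which(keep, arr.ind = TRUE)
  if (!nrow(ij)) abort("geometry template is empty: no pairs within cutoff")
  out <- tibble(i = ij[, 1], j = ij[, 2],
                res_i = s$residue_number[ij[, 1]], atom_i = s$atom_name[ij[, 1]],
                res_j = s$residue_number[ij[, 2]], atom_j = s$atom_name[ij[, 2]],
                target = D[keep], k = force_constant)
  if (any(out$target <= 0)) abort("geometry template targets must be > 0")
  class(out) <- c("geometry_template", class(out))
  out
}

# Harmonic template energy and gradient for a coordinate matrix.
geometry_energy_grad <- function(pos, template) {
  d_vec <- pos[template$j, , drop = FALSE] - pos[template$i, , drop = FALSE]
  d <- sqrt(rowSums(d_vec^2))
  dev <- d - template$target
  energy <- sum(template$k * dev^2)
  f <- 2 * template$k * dev / pmax(d, 1e-12)
  gi <- -f * d_vec
  grad <- matrix(0, nrow(pos), 3)
  for (col in 1:3) {
    grad[, col] <- as.vector(tapply(gi[, col], factor(template$i, levels = seq_len(nrow(pos))), sum, default = 0)) -
      as.vector(tapply(gi[, col], factor(template$j, levels = seq_len(nrow(pos))), sum, default = 0))
  }
  list(energy = energy, grad = grad)
}
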