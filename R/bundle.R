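#' Ensemble bundle statistics
#'
#' All-pairs best-fit superposition (least-squares, via \pkg{bio3d}) of the
#' selected atoms across the models of an ensemble, reporting the mean
#' pairwise RMSD, the full pair table, and — when a metal atom name is
#' given — the metal spread: the RMSD of the metal coordinates about their
#' mean after superposing every model on the selection of the first.
#'
#' @param ensemble Multi-model structure tibble (>= 2 models).
#' @param selection Optional predicate on atom rows, as a one-sided formula
#'   or function taking the tibble and returning a logical vector; default
#'   selects every atom except the metal.
#' @param metal_atom_name Atom name of the metal (e.g. `"LN"`), or `NULL`.
#' @param superpose Optional separate predicate selecting the atoms used to
#'   fit the superposition; RMSDs are still computed over `selection`.
#'   Defaults to `selection` itself.
#' @return A `bundle_stats` list: `pairwise_rmsd_mean`, `pairwise` tibble
#'   (model_i, model_j, rmsd), `metal_spread_rmsd` (or `NA`), `selection_n`.
#' @export
bundle_stats <- function(ensemble, selection = NULL, metal_atom_name = NULL,
                         superpose = NULL) {
  ensemble <- as_structure(ensemble)
  models <- unique(ensemble$model)
  if (length(models) < 2) abort("need an ensemble of >= 2 models")
  s1 <- ensemble[ensemble$model == models[1], ]
  sel <- if (is.null(selection)) {
    if (is.null(metal_atom_name)) rep(TRUE, nrow(s1)) else s1$atom_name != metal_atom_name
  } else if (is.function(selection)) {
    selection(s1)
  } else {
    abort("selection must be NULL or a function(structure_rows) -> logical")
  }
  sup <- if (is.null(superpose)) sel else superpose(s1)
  if (sum(sup) < 3) abort("selection must contain >= 3 atoms for superposition",
                          class = "parashift_superposition_error")
  coords <- lapply(models, function(m) structure_coords(ensemble, m))
  sel_idx <- which(sel)
  xyz_inds <- bio3d::atom2xyz(which(sup))
  pairs <- utils::combn(seq_along(models), 2)
  pair_tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    fitted <- suppressWarnings(bio3d::fit.xyz(
      fixed = as.vector(t(coords[[i]])), mobile = as.vector(t(coords[[j]])),
      fixed.inds = xyz_inds, mobile.inds = xyz_inds))
    B <- matrix(fitted, ncol = 3, byrow = TRUE)
    rmsd <- sqrt(mean(rowSums((B[sel_idx, , drop = FALSE] -
                                 coords[[i]][sel_idx, , drop = FALSE])^2)))
    tibble(model_i = models[i], model_j = models[j], rmsd = rmsd)
  })
  metal_spread <- NA_real_
  if (!is.null(metal_atom_name)) {
    mi <- which(s1$atom_name == metal_atom_name)
    if (!length(mi)) abort(paste0("no atom named ", metal_atom_name, " in the ensemble"))
    metal_pos <- t(vapply(seq_along(models), function(j) {
      if (j == 1) return(coords[[1]][mi[1], ])
      fitted <- suppressWarnings(bio3d::fit.xyz(
        fixed = as.vector(t(coords[[1]])), mobile = as.vector(t(coords[[j]])),
        fixed.inds = xyz_inds, mobile.inds = xyz_inds))
      matrix(fitted, ncol = 3, byrow = TRUE)[mi[1], ]
    }, numeric(3)))
    metal_spread <- sqrt(mean(rowSums(sweep(metal_pos, 2, colMeans(metal_pos))^2)))
  }
  structure(list(pairwise_rmsd_mean = mean(pair_tbl$rmsd),
                 pairwise = pair_tbl,
                 metal_spread_rmsd = metal_spread,
                 selection_n = sum(sel)),
            class = "bundle_stats")
}

#' @export
print.bundle_stats <- function(x, ...) {
  cat(sprintf("<bundle_stats> %d-atom selection\n", x$selection_n))
  cat(sprintf("  mean pairwise RMSD: %.3f A over %d pairs\n",
              x$pairwise_rmsd_mean, nrow(x$pairwise)))
  if (is.finite(x$metal_spread_rmsd)) {
    cat(sprintf("  metal spread RMSD:  %.3f A\n", x$metal_spread_rmsd))
  }
  invisible(x)
}

#' Interhelical angle from base-pair C1' midpoints
#'
#' The axis of each helix is the first principal axis of the series of
#' C1'-C1' midpoints of its consecutive base pairs, oriented along the
#' base-pair order of the first strand (5' to 3'). Returns the angle
#' between the two axis vectors, in degrees within [0, 180].
#'
#' @param structure Structure tibble (first model used).
#' @param helix_a,helix_b Two-column data frames (or matrices) of paired
#'   residue numbers, one row per base pair, >= 3 rows, ordered along the
#'   first strand.
#' @return Angle in degrees.
#' @export
interhelical_angle <- function(structure, helix_a, helix_b) {
  a <- helix_axis(structure, helix_a)
  b <- helix_axis(structure, helix_b)
  rad2deg(acos(max(-1, min(1, sum(a * b)))))
}

helix_axis <- function(structure, pairing) {
  pairing <- as.matrix(pairing)
  if (nrow(pairing) < 3) {
    abort("helix must have >= 3 base pairs", class = "parashift_geometry_error")
  }
  s <- structure[structure$model == structure$model[1], ]
  mid <- t(apply(pairing, 1, function(pr) {
    p1 <- s[s$residue_number == pr[1] & s$atom_name == "C1'", c("x", "y", "z")]
    p2 <- s[s$residue_number == pr[2] & s$atom_name == "C1'", c("x", "y", "z")]
    if (nrow(p1) != 1 || nrow(p2) != 1) {
      abort(sprintf("missing C1' atom for base pair %d:%d", pr[1], pr[2]),
            class = "parashift_geometry_error")
    }
    (as.numeric(p1) + as.numeric(p2)) / 2
  }))
  pc <- stats::prcomp(mid, center = TRUE)
  axis <- pc$rotation[, 1]
  direction <- mid[nrow(mid), ] - mid[1, ]
  if (sum(axis * direction) < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}
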