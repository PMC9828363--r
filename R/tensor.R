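#' Magnetic susceptibility anisotropy (delta-chi) tensors
#'
#' A `dchi_tensor` is a traceless symmetric rank-2 tensor describing the
#' anisotropy of the magnetic susceptibility of a paramagnetic centre, in
#' units of 1e-32 m^3 throughout the package. Two equivalent
#' parameterisations are supported:
#'
#' * **components** — the 5 independent Cartesian entries
#'   `(chi_xx, chi_yy, chi_xy, chi_xz, chi_yz)` with
#'   `chi_zz = -chi_xx - chi_yy`;
#' * **paf** — axial and rhombic anisotropies `dchi_ax`, `dchi_rh` plus ZYZ
#'   Euler angles (degrees) orienting the principal axis frame (PAF), where
#'   `dchi_ax = chi_zz - (chi_xx + chi_yy)/2` and `dchi_rh = chi_xx - chi_yy`
#'   in the principal frame.
#'
#' @param chi_xx,chi_yy,chi_xy,chi_xz,chi_yz Cartesian tensor components
#'   (1e-32 m^3).
#' @param dchi_ax,dchi_rh Axial and rhombic anisotropy (1e-32 m^3).
#' @param alpha,beta,gamma ZYZ Euler angles of the PAF, degrees.
#' @return An object of class `dchi_tensor` wrapping the full 3x3 matrix.
#' @examples
#' t1 <- dchi_paf(dchi_ax = -3.88, dchi_rh = 1.62, alpha = 30, beta = 60)
#' tensor_convert(t1, "components")
#' @name dchi_tensor
NULL

new_dchi_tensor <- function(M, degenerate = FALSE) {
  structure(list(M = M, degenerate = degenerate), class = "dchi_tensor")
}

#' @rdname dchi_tensor
#' @export
dchi_components <- function(chi_xx, chi_yy, chi_xy, chi_xz, chi_yz) {
  vals <- c(chi_xx, chi_yy, chi_xy, chi_xz, chi_yz)
  if (!all(is.finite(vals))) abort("tensor components must be finite")
  M <- matrix(c(chi_xx, chi_xy, chi_xz,
                chi_xy, chi_yy, chi_yz,
                chi_xz, chi_yz, -chi_xx - chi_yy), 3, 3, byrow = TRUE)
  new_dchi_tensor(M)
}

#' @rdname dchi_tensor
#' @export
dchi_paf <- function(dchi_ax, dchi_rh = 0, alpha = 0, beta = 0, gamma = 0) {
  if (!all(is.finite(c(dchi_ax, dchi_rh, alpha, beta, gamma)))) {
    abort("tensor parameters must be finite")
  }
  # Traceless eigenvalues consistent with the ax/rh definitions
  lam <- c(-dchi_ax / 3 + dchi_rh / 2,
           -dchi_ax / 3 - dchi_rh / 2,
           2 * dchi_ax / 3)
  R <- rot_zyz(alpha, beta, gamma)
  M <- R %*% diag(lam) %*% t(R)
  M <- (M + t(M)) / 2
  new_dchi_tensor(M, degenerate = isTRUE(all.equal(lam[1], lam[2])) && dchi_ax == 0)
}

#' @export
is_dchi_tensor <- function(x) inherits(x, "dchi_tensor")

#' Convert a delta-chi tensor between representations
#'
#' Eigen-decomposition based conversion between the 5-component Cartesian
#' form and the principal-axis-frame (axial/rhombic + Euler angles) form.
#' In the principal frame the eigenvalues are assigned to axes so that
#' `|chi_zz| >= |chi_yy| >= |chi_xx|`; the sign of `dchi_rh` is reported as
#' obtained (no rhombicity clamp). Degenerate eigenvalues leave the
#' orientation undetermined: a canonical frame is returned and the
#' `degenerate` flag is set.
#'
#' @param tensor A [dchi_tensor].
#' @param target `"components"` or `"paf"`.
#' @return A named list. For `"components"`: entries `chi_xx, chi_yy,
#'   chi_xy, chi_xz, chi_yz`. For `"paf"`: `dchi_ax`, `dchi_rh`, `alpha`,
#'   `beta`, `gamma` (degrees) and logical `degenerate`.
#' @export
tensor_convert <- function(tensor, target = c("paf", "components")) {
  stopifnot(is_dchi_tensor(tensor))
  target <- match.arg(target)
  M <- tensor$M
  if (target == "components") {
    return(list(chi_xx = M[1, 1], chi_yy = M[2, 2],
                chi_xy = M[1, 2], chi_xz = M[1, 3], chi_yz = M[2, 3]))
  }
  ev <- eigen(M, symmetric = TRUE)
  ord <- order(abs(ev$values))          # |xx| <= |yy| <= |zz|
  lam <- ev$values[ord]
  V <- ev$vectors[, ord, drop = FALSE]
  if (det(V) < 0) V[, 1] <- -V[, 1]
  gaps <- abs(diff(sort(ev$values)))
  scale_ref <- max(abs(ev$values), 1e-300)
  degenerate <- any(gaps < 1e-9 * scale_ref) || all(abs(ev$values) < 1e-15)
  ang <- if (degenerate && all(abs(ev$values) < 1e-15)) {
    c(alpha = 0, beta = 0, gamma = 0)
  } else {
    euler_zyz(V)
  }
  list(dchi_ax = lam[3] - (lam[1] + lam[2]) / 2,
       dchi_rh = lam[1] - lam[2],
       alpha = unname(ang[1]), beta = unname(ang[2]), gamma = unname(ang[3]),
       degenerate = degenerate)
}

#' @export
print.dchi_tensor <- function(x, ...) {
  p <- tensor_convert(x, "paf")
  cat("<dchi_tensor>  (units 1e-32 m^3)\n")
  cat(sprintf("  dchi_ax = %+.4f   dchi_rh = %+.4f%s\n", p$dchi_ax, p$dchi_rh,
              if (p$degenerate) "   [orientation undetermined]" else ""))
  cat(sprintf("  PAF Euler ZYZ (deg): alpha = %.2f, beta = %.2f, gamma = %.2f\n",
              p$alpha, p$beta, p$gamma))
  invisible(x)
}

#' Scale and reorient a tensor (solvent-change emulation)
#'
#' Multiplies all eigenvalues by `scale` and rotates the principal axis
#' frame by `rotation` degrees about `axis` (laboratory frame). Used to
#' emulate the change of a lanthanide's delta-chi tensor between H2O and
#' D2O solvation.
#'
#' @param tensor A [dchi_tensor].
#' @param scale Positive multiplicative factor on the eigenvalues.
#' @param rotation Rotation angle in degrees.
#' @param axis Unit 3-vector (laboratory frame) or `"x"`, `"y"`, `"z"`.
#' @return A new [dchi_tensor].
#' @export
perturb_tensor_solvent <- function(tensor, scale = 1, rotation = 0, axis = "z") {
  stopifnot(is_dchi_tensor(tensor))
  if (!is.numeric(scale) || scale <= 0) abort("`scale` must be > 0")
  R <- if (is.character(axis)) {
    rot_axis(rotation, axis)
  } else {
    a <- axis / sqrt(sum(axis^2))
    # Rodrigues' formula
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
    th <- deg2rad(rotation)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  M <- R %*% (scale * tensor$M) %*% t(R)
  new_dchi_tensor((M + t(M)) / 2, degenerate = tensor$degenerate)
}

#' Serialise / parse a tensor as a key-value text block
#'
#' Writes both representations with units stated, in a plain-text block that
#' round-trips through [parse_tensor_block()]. Used in results files.
#'
#' @param tensor A [dchi_tensor].
#' @param label Optional label line.
#' @return Character vector of lines (`format_tensor_block`), or a
#'   [dchi_tensor] (`parse_tensor_block`).
#' @export
format_tensor_block <- function(tensor, label = NULL) {
  cmp <- tensor_convert(tensor, "components")
  paf <- tensor_convert(tensor, "paf")
  c(if (!is.null(label)) paste0("tensor_label: ", label),
    "units: 1e-32 m^3; angles deg (ZYZ)",
    sprintf("chi_xx: %.10g", cmp$chi_xx),
    sprintf("chi_yy: %.10g", cmp$chi_yy),
    sprintf("chi_xy: %.10g", cmp$chi_xy),
    sprintf("chi_xz: %.10g", cmp$chi_xz),
    sprintf("chi_yz: %.10g", cmp$chi_yz),
    sprintf("dchi_ax: %.10g", paf$dchi_ax),
    sprintf("dchi_rh: %.10g", paf$dchi_rh),
    sprintf("alpha: %.6g", paf$alpha),
    sprintf("beta: %.6g", paf$beta),
    sprintf("gamma: %.6g", paf$gamma))
}

#' @rdname format_tensor_block
#' @param lines Character vector as produced by `format_tensor_block`.
#' @export
parse_tensor_block <- function(lines) {
  kv <- lines[grepl("^chi_[a-z]{2}:", lines)]
  vals <- setNames(
    as.numeric(sub("^[a-z_]+: *", "", kv)),
    sub(":.*$", "", kv)
  )
  dchi_components(vals[["chi_xx"]], vals[["chi_yy"]],
                  vals[["chi_xy"]], vals[["chi_xz"]], vals[["chi_yz"]])
}
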