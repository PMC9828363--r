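#' Write a back-calculated PCS field as an OpenDX scalar grid
#'
#' Evaluates the forward PCS model on a regular lattice and writes it in
#' OpenDX scalar-grid format, readable by common molecular viewers for
#' isosurface display (e.g. the +0.2 / -0.2 ppm lobes of a tensor around
#' its metal site). Lattice points closer than the singularity guard radius
#' to the site are clamped to the value at the guard radius along the same
#' direction, with a warning.
#'
#' @param tensor A [dchi_tensor].
#' @param site Metal position, Angstrom 3-vector.
#' @param origin Lattice origin (corner), Angstrom 3-vector.
#' @param spacing Positive lattice spacing(s), length 1 or 3, Angstrom.
#' @param counts Integer lattice point counts per axis, each >= 2.
#' @param path Output file.
#' @return The lattice values, invisibly (array `counts[1] x counts[2] x
#'   counts[3]`, ppm).
#' @export
write_grid <- function(tensor, site, origin, spacing, counts, path) {
  stopifnot(is_dchi_tensor(tensor))
  spacing <- rep_len(as.numeric(spacing), 3)
  counts <- as.integer(rep_len(counts, 3))
  if (any(spacing <= 0)) abort("spacing must be > 0")
  if (any(counts < 2)) abort("counts must be >= 2 on every axis")
  site <- as.numeric(site)
  ax <- lapply(1:3, function(i) origin[i] + spacing[i] * (seq_len(counts[i]) - 1))
  # OpenDX convention: z varies fastest
  pts <- as.matrix(expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]]))[, c("x", "y", "z")]
  v <- sweep(pts, 2, site)
  r <- sqrt(rowSums(v^2))
  near <- r < PCS_GUARD_RADIUS
  if (any(near)) {
    warn(sprintf("%d lattice point(s) within %.2f Angstrom of the site: values clamped to the guard radius", sum(near), PCS_GUARD_RADIUS))
    dir <- v[near, , drop = FALSE]
    zero <- rowSums(dir^2) == 0
    dir[zero, ] <- matrix(rep(c(0, 0, 1), sum(zero)), ncol = 3, byrow = TRUE)
    dir <- dir / sqrt(rowSums(dir^2))
    pts[near, ] <- sweep(dir * PCS_GUARD_RADIUS, 2, site, "+")
  }
  vals <- pcs_forward(tensor, site, pts)
  n <- prod(counts)
  header <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", counts[1], counts[2], counts[3]),
    sprintf("origin %.6f %.6f %.6f", origin[1], origin[2], origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", spacing[1]),
    sprintf("delta 0.000000 %.6f 0.000000", spacing[2]),
    sprintf("delta 0.000000 0.000000 %.6f", spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", counts[1], counts[2], counts[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  rows <- split(vals, ceiling(seq_along(vals) / 3))
  body <- vapply(rows, function(r) paste(sprintf("%.10e", r), collapse = " "), "")
  footer <- c('attribute "dep" string "positions"',
              'object "pcs (ppm)" class field',
              'component "positions" value 1',
              'component "connections" value 2',
              'component "data" value 3')
  writeLines(c(header, body, footer), path)
  invisible(array(vals, dim = rev(counts))) # z fastest -> dim (nz, ny, nx) reversed
}
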