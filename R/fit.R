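#' Q-factor of observed vs back-calculated paramagnetic data
#'
#' `Q = sqrt( sum(obs - calc)^2 / sum(obs^2) )`; the weighted variant
#' replaces each square by `w * square`. No mean-centering is applied —
#' the normalisation used by the standard multi-tensor fitting tools.
#'
#' @param observed,calculated Numeric vectors of equal length.
#' @param weights Optional non-negative weights.
#' @return A non-negative scalar.
#' @examples
#' q_factor(c(1, -1), c(0.9, -0.9)) # 0.1
#' @export
q_factor <- function(observed, calculated, weights = NULL) {
  if (length(observed) != length(calculated) || !length(observed)) {
    abort("observed and calculated must have equal positive length")
  }
  w <- weights %||% rep(1, length(observed))
  denom <- sum(w * observed^2)
  if (denom == 0) abort("Q-factor undefined: all observed values are zero",
                        class = "parashift_undefined_q_error")
  sqrt(sum(w * (observed - calculated)^2) / denom)
}

# Match PCS entries to structure atoms. Returns list(data, positions);
# entries whose atoms are absent from the structure are skipped with a log
# line (PRE-missing observations are information-free).
match_dataset_atoms <- function(dataset, structure, model = NULL) {
  m <- model %||% structure$model[1]
  s <- structure[structure$model == m, ]
  idx <- match(paste(dataset$residue_number, dataset$atom_name),
               paste(s$residue_number, s$atom_name))
  drop <- is.na(idx)
  if (any(drop)) {
    inform(sprintf("skipping %d PCS entr%s without a matching structure atom",
                   sum(drop), if (sum(drop) == 1) "y" else "ies"))
  }
  d <- dataset[!drop, , drop = FALSE]
  list(data = d,
       positions = as.matrix(s[idx[!drop], c("x", "y", "z")]))
}

fit_weights <- function(data, weights = c("uniform", "inverse_variance")) {
  weights <- match.arg(weights)
  if (weights == "uniform") rep(1, nrow(data)) else 1 / data$sigma^2
}

#' Fit a delta-chi tensor at a fixed metal position
#'
#' Weighted linear least squares over the 5 independent Cartesian tensor
#' components, using the design matrix of the forward model's Cartesian
#' form. The problem is linear, so the solve is exact.
#'
#' @param dataset A [pcs_dataset()].
#' @param structure A structure tibble; entries whose atoms are missing are
#'   skipped with a log line.
#' @param site Metal position, Angstrom 3-vector.
#' @param weights `"uniform"` (default) or `"inverse_variance"`.
#' @param model Which structure model to fit against (default: first).
#' @return A `pcs_fit` object: fitted tensor, site, per-entry data with
#'   `calc` and `residual` columns, `q_factor` and `n_obs`.
#' @export
fit_tensor_fixed_position <- function(dataset, structure, site,
                                      weights = c("uniform", "inverse_variance"),
                                      model = NULL) {
  weights <- match.arg(weights)
  m <- match_dataset_atoms(dataset, structure, model)
  if (nrow(m$data) < 5) {
    abort(sprintf("need >= 5 matched PCS entries to determine a tensor (got %d)",
                  nrow(m$data)))
  }
  w <- fit_weights(m$data, weights)
  A <- pcs_design_matrix(site, m$positions)
  sw <- sqrt(w)
  qrA <- qr(A * sw)
  if (qrA$rank < 5) {
    abort(sprintf("degenerate geometry: design matrix rank %d < 5 (null space dimension %d); the atoms do not determine a tensor", qrA$rank, 5 - qrA$rank),
          class = "parashift_degenerate_geometry_error")
  }
  beta <- qr.coef(qrA, m$data$pcs * sw)
  tensor <- dchi_components(beta[1], beta[2], beta[3], beta[4], beta[5])
  calc <- drop(A %*% beta)
  data <- m$data
  data$calc <- calc
  data$residual <- data$pcs - calc
  res <- list(tensor = tensor, site = as.numeric(site), data = data,
              q_factor = q_factor(data$pcs, calc, if (weights == "uniform") NULL else w),
              n_obs = nrow(data), weights = weights,
              metal_label = attr(dataset, "metal_label") %||% "metal")
  class(res) <- "pcs_fit"
  res
}

#' @export
print.pcs_fit <- function(x, ...) {
  p <- tensor_convert(x$tensor, "paf")
  cat(sprintf("<pcs_fit> %s: n_obs = %d, Q = %.4f\n", x$metal_label, x$n_obs, x$q_factor))
  cat(sprintf("  dchi_ax = %+.3f, dchi_rh = %+.3f (1e-32 m^3)\n", p$dchi_ax, p$dchi_rh))
  cat(sprintf("  site = (%.2f, %.2f, %.2f) A\n", x$site[1], x$site[2], x$site[3]))
  invisible(x)
}

#' Resolve diastereotopic assignment ambiguity
#'
#' For prochiral proton pairs (H5'/H5'', H2'/H2'') whose two observed PCS
#' cannot be stereo-assigned, assigns each pair's two observed values to
#' the two atoms in the permutation minimising that pair's residual sum
#' against the current tensor and site (standard ambiguous-restraint
#' treatment). Swapped keys are recorded in the `swapped` attribute.
#'
#' @param dataset A [pcs_dataset()].
#' @param structure Structure tibble.
#' @param site Metal position.
#' @param tensor Current [dchi_tensor].
#' @param pairs List of length-2 atom-name vectors treated as ambiguous.
#' @return The dataset with possibly-permuted `pcs` values.
#' @export
resolve_diastereotopic <- function(dataset, structure, site, tensor,
                                   pairs = list(c("H5'", "H5''"),
                                                c("H2'", "H2''"))) {
  m <- match_dataset_atoms(dataset, structure)
  d <- m$data
  calc <- pcs_forward(tensor, site, m$positions)
  swapped <- character()
  for (res in unique(d$residue_number)) {
    for (pr in pairs) {
      i <- which(d$residue_number == res & d$atom_name == pr[1])
      j <- which(d$residue_number == res & d$atom_name == pr[2])
      if (length(i) != 1 || length(j) != 1) next
      keep <- (d$pcs[i] - calc[i])^2 + (d$pcs[j] - calc[j])^2
      swap <- (d$pcs[j] - calc[i])^2 + (d$pcs[i] - calc[j])^2
      if (swap < keep) {
        tmp <- d$pcs[i]; d$pcs[i] <- d$pcs[j]; d$pcs[j] <- tmp
        swapped <- c(swapped, paste0(res, ":", pr[1], "/", pr[2]))
      }
    }
  }
  out <- pcs_dataset(d[, c("residue_number", "atom_name", "pcs", "sigma")],
                     metal_label = attr(dataset, "metal_label") %||% "metal",
                     solvent = attr(dataset, "solvent") %||% "D2O")
  attr(out, "swapped") <- swapped
  out
}

# Objective for a candidate site: per-dataset exact linear solve, summed
# weighted squared residuals. Entries within `leverage_radius` of the
# candidate site are down-weighted by `leverage_factor` (near-singular
# leverage guard: the closest nuclei are most affected by unmodelled
# contact shifts and local dynamics).
joint_objective <- function(site, matched, weight_list,
                            leverage_radius = 5, leverage_factor = 0.1) {
  total <- 0
  for (k in seq_along(matched)) {
    pos <- matched[[k]]$positions
    obs <- matched[[k]]$data$pcs
    v <- sweep(pos, 2, site)
    r2 <- rowSums(v^2)
    if (any(r2 < PCS_GUARD_RADIUS^2)) return(Inf)
    w <- weight_list[[k]]
    w <- ifelse(r2 < leverage_radius^2, w * leverage_factor, w)
    A <- pcs_design_matrix(site, pos)
    sw <- sqrt(w)
    fit <- tryCatch(qr.coef(qr(A * sw), obs * sw), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) return(Inf)
    total <- total + sum(w * (obs - drop(A %*% fit))^2)
  }
  total
}

#' Joint fit of the shared metal position and per-dataset tensors
#'
#' Nested optimisation: the three site coordinates are searched over a
#' coarse grid covering `box` (the PCS objective has narrow r^-3 basins, so
#' a grid-first strategy avoids local minima), then refined from the best
#' node by a derivative-free Nelder-Mead simplex; for each candidate site
#' the five tensor components of every dataset are solved exactly by
#' weighted linear least squares. The objective is the sum over datasets of
#' weighted squared residuals.
#'
#' @param datasets A [pcs_dataset()] or list of them (one per metal).
#' @param structure Structure tibble.
#' @param box Optional 2x3 matrix `rbind(lower, upper)` of the search box
#'   (Angstrom). Default: structure bounding box inflated by 10 Angstrom.
#' @param grid_spacing Coarse-grid spacing, Angstrom (default 2).
#' @param coord_tol Site convergence tolerance of the local stage, Angstrom.
#' @param weights `"uniform"` or `"inverse_variance"`.
#' @param check_consistency Compare the joint Q of each dataset against its
#'   own separately-fitted site and warn when the joint fit is markedly
#'   worse (ratio > 2), which indicates the datasets do not share a site.
#' @param diastereotopic Optional list of length-2 atom-name vectors (see
#'   [resolve_diastereotopic()]): after each search pass the ambiguous
#'   pairs are re-assigned to minimise their residuals and the local stage
#'   is repeated, until the assignment is stable.
#' @param model Structure model to fit against.
#' @return A `pcs_joint_fit`: shared `site`, list `fits` of per-dataset
#'   [fit_tensor_fixed_position()] results, total `objective`.
#' @export
fit_position_and_tensors <- function(datasets, structure, box = NULL,
                                     grid_spacing = 2, coord_tol = 1e-4,
                                     weights = c("uniform", "inverse_variance"),
                                     check_consistency = TRUE,
                                     diastereotopic = NULL, model = NULL) {
  weights <- match.arg(weights)
  if (inherits(datasets, "pcs_dataset")) datasets <- list(datasets)
  if (!length(datasets)) abort("need at least one PCS dataset")
  matched <- lapply(datasets, match_dataset_atoms, structure = structure, model = model)
  for (m in matched) {
    if (nrow(m$data) < 5) abort("every dataset needs >= 5 matched entries")
  }
  weight_list <- lapply(matched, function(m) fit_weights(m$data, weights))
  coords <- structure_coords(structure, model)
  if (is.null(box)) {
    box <- rbind(apply(coords, 2, min) - 10, apply(coords, 2, max) + 10)
  }
  grid_axes <- lapply(1:3, function(i) {
    n <- max(2, ceiling((box[2, i] - box[1, i]) / grid_spacing) + 1)
    seq(box[1, i], box[2, i], length.out = n)
  })
  nodes <- as.matrix(expand.grid(grid_axes[[1]], grid_axes[[2]], grid_axes[[3]]))
  vals <- apply(nodes, 1, joint_objective, matched = matched, weight_list = weight_list)
  finite <- is.finite(vals)
  if (!any(finite)) {
    abort("no admissible site in the search box", class = "parashift_search_error")
  }
  v_f <- vals[finite]
  if (max(v_f) - min(v_f) <= 1e-12 * max(abs(v_f), 1e-300) && length(v_f) > 1) {
    abort("objective surface is flat across the search box: metal position is not identifiable",
          class = "parashift_non_identifiable_error")
  }
  start <- nodes[which.min(vals), ]
  opt <- optim(start, joint_objective, matched = matched, weight_list = weight_list,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  # polish until the simplex collapses below the coordinate tolerance
  for (i in 1:5) {
    opt2 <- optim(opt$par, joint_objective, matched = matched, weight_list = weight_list,
                  method = "Nelder-Mead",
                  control = list(reltol = 1e-15, maxit = 2000))
    if (sqrt(sum((opt2$par - opt$par)^2)) < coord_tol) {
      opt <- opt2
      break
    }
    opt <- opt2
  }
  site <- opt$par
  fits <- purrr::map(datasets, fit_tensor_fixed_position, structure = structure,
                     site = site, weights = weights, model = model)
  if (!is.null(diastereotopic)) {
    for (pass in 1:5) {
      reassigned <- purrr::map2(datasets, fits, function(d, f) {
        resolve_diastereotopic(d, structure, site, f$tensor,
                               pairs = diastereotopic)
      })
      n_swaps <- sum(lengths(purrr::map(reassigned, attr, "swapped")))
      datasets <- reassigned
      matched <- lapply(datasets, match_dataset_atoms, structure = structure,
                        model = model)
      opt <- optim(site, joint_objective, matched = matched,
                   weight_list = weight_list, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 2000))
      site <- opt$par
      fits <- purrr::map(datasets, fit_tensor_fixed_position,
                         structure = structure, site = site,
                         weights = weights, model = model)
      if (n_swaps == 0) break
    }
    swapped <- purrr::map(datasets, attr, "swapped")
    for (i in seq_along(fits)) fits[[i]]$swapped <- swapped[[i]]
  }
  if (check_consistency && length(datasets) > 1) {
    for (k in seq_along(datasets)) {
      sep <- optim(site, joint_objective, matched = matched[k],
                   weight_list = weight_list[k], method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 1000))
      sep_fit <- fit_tensor_fixed_position(datasets[[k]], structure, sep$par,
                                           weights = weights, model = model)
      if (sep_fit$q_factor > 0 && fits[[k]]$q_factor / sep_fit$q_factor > 2) {
        warn(sprintf("dataset %d (%s): joint-site Q (%.3f) exceeds its separate-site Q (%.3f) more than 2-fold; the datasets may not share a metal site",
                     k, fits[[k]]$metal_label, fits[[k]]$q_factor, sep_fit$q_factor))
      }
    }
  }
  res <- list(site = site, fits = fits, objective = opt$value,
              weights = weights, box = box)
  class(res) <- "pcs_joint_fit"
  res
}

#' @export
print.pcs_joint_fit <- function(x, ...) {
  cat(sprintf("<pcs_joint_fit> shared site = (%.2f, %.2f, %.2f) A, objective = %.4g\n",
              x$site[1], x$site[2], x$site[3], x$objective))
  for (f in x$fits) {
    p <- tensor_convert(f$tensor, "paf")
    cat(sprintf("  %-4s dchi_ax = %+.3f dchi_rh = %+.3f  Q = %.4f  n = %d\n",
                f$metal_label, p$dchi_ax, p$dchi_rh, f$q_factor, f$n_obs))
  }
  invisible(x)
}

#' Cross-validate a PCS fit
#'
#' Refits the tensor on training folds and evaluates the Q-factor on the
#' held-out entries only (`Q_free`), alongside the full-fit `Q_work`. With
#' `holdout_nucleus` set (a regular expression on atom names, e.g. `"^P"`
#' for 31P), the matching nuclei are never part of training — the
#' phosphorus cross-validation protocol.
#'
#' @param dataset A [pcs_dataset()].
#' @param structure Structure tibble.
#' @param site Fixed metal position.
#' @param scheme `"loo"` (leave-one-out) or `"k_fold"`.
#' @param k Number of folds for `"k_fold"`.
#' @param holdout_nucleus Optional regex; matching atoms form the held-out
#'   set and the scheme argument is ignored.
#' @param weights Weighting scheme passed to the tensor fit.
#' @param seed Fold-assignment seed for `"k_fold"`.
#' @return List with `q_work`, `q_free`, and the per-entry prediction table.
#' @export
cross_validate <- function(dataset, structure, site,
                           scheme = c("loo", "k_fold"), k = 5,
                           holdout_nucleus = NULL,
                           weights = c("uniform", "inverse_variance"),
                           seed = 1L) {
  scheme <- match.arg(scheme)
  weights <- match.arg(weights)
  m <- match_dataset_atoms(dataset, structure)
  n <- nrow(m$data)
  full <- fit_tensor_fixed_position(dataset, structure, site, weights = weights)
  if (!is.null(holdout_nucleus)) {
    test_idx <- list(which(grepl(holdout_nucleus, m$data$atom_name)))
    if (!length(test_idx[[1]])) {
      abort(sprintf("holdout filter '%s' matches no entries", holdout_nucleus),
            class = "parashift_fold_size_error")
    }
  } else if (scheme == "loo") {
    test_idx <- as.list(seq_len(n))
  } else {
    fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    test_idx <- split(seq_len(n), fold)
  }
  preds <- numeric(n)
  tested <- logical(n)
  for (ti in test_idx) {
    if (n - length(ti) < 5) {
      abort(sprintf("fold leaves only %d training observations (need >= 5)", n - length(ti)),
            class = "parashift_fold_size_error")
    }
    train <- pcs_dataset(m$data[-ti, c("residue_number", "atom_name", "pcs", "sigma")],
                         metal_label = attr(dataset, "metal_label") %||% "metal")
    f <- fit_tensor_fixed_position(train, structure, site, weights = weights)
    preds[ti] <- pcs_forward(f$tensor, site, m$positions[ti, , drop = FALSE])
    tested[ti] <- TRUE
  }
  q_free <- q_factor(m$data$pcs[tested], preds[tested])
  list(q_work = full$q_factor, q_free = q_free,
       predictions = tibble(residue_number = m$data$residue_number[tested],
                            atom_name = m$data$atom_name[tested],
                            pcs = m$data$pcs[tested],
                            pcs_pred = preds[tested]))
}

#' Parametric-bootstrap uncertainty of a joint fit
#'
#' Resamples each dataset's PCS about the fitted values with Gaussian noise
#' of standard deviation `sigma`, refits site and tensors (locally, warm
#' started from the fit), and reports standard deviations of `dchi_ax`,
#' `dchi_rh`, the Euler angles and the site coordinates.
#'
#' @param fit A `pcs_joint_fit`.
#' @param datasets The datasets the fit was computed from.
#' @param structure Structure tibble.
#' @param sigma Noise level, ppm (> 0).
#' @param n_replicates Number of bootstrap replicates (>= 50).
#' @param seed RNG seed.
#' @return A tibble with one row per (dataset, parameter) plus the site
#'   coordinates, column `sd`.
#' @export
mc_uncertainty <- function(fit, datasets, structure, sigma,
                           n_replicates = 100, seed = 1L) {
  if (!is.numeric(sigma) || sigma <= 0) abort("sigma must be > 0")
  if (n_replicates < 50) abort("need n_replicates >= 50")
  if (inherits(datasets, "pcs_dataset")) datasets <- list(datasets)
  matched <- lapply(datasets, match_dataset_atoms, structure = structure)
  weight_list <- lapply(matched, function(m) fit_weights(m$data, fit$weights))
  reps <- withr::with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(r) {
      noisy <- purrr::map2(datasets, fit$fits, function(d, f) {
        m <- match_dataset_atoms(d, structure)
        d2 <- m$data
        d2$pcs <- pcs_forward(f$tensor, fit$site, m$positions) + rnorm(nrow(d2), 0, sigma)
        pcs_dataset(d2[, c("residue_number", "atom_name", "pcs", "sigma")],
                    metal_label = f$metal_label)
      })
      matched_r <- lapply(noisy, match_dataset_atoms, structure = structure)
      opt <- optim(fit$site, joint_objective, matched = matched_r,
                   weight_list = weight_list, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 1000))
      params <- purrr::imap_dfr(noisy, function(d, i) {
        f <- fit_tensor_fixed_position(d, structure, opt$par, weights = fit$weights)
        p <- tensor_convert(f$tensor, "paf")
        tibble(dataset = f$metal_label,
               parameter = c("dchi_ax", "dchi_rh", "alpha", "beta", "gamma"),
               value = c(p$dchi_ax, p$dchi_rh, p$alpha, p$beta, p$gamma))
      })
      dplyr::bind_rows(params,
                       tibble(dataset = "site",
                              parameter = c("x", "y", "z"),
                              value = opt$par))
    })
  })
  dplyr::bind_rows(reps, .id = "replicate") |>
    dplyr::group_by(.data$dataset, .data$parameter) |>
    dplyr::summarise(sd = sd(.data$value), .groups = "drop")
}

#' @export
tidy.pcs_fit <- function(x, ...) {
  p <- tensor_convert(x$tensor, "paf")
  tibble(term = c("dchi_ax", "dchi_rh", "alpha", "beta", "gamma",
                  "site_x", "site_y", "site_z"),
         estimate = c(p$dchi_ax, p$dchi_rh, p$alpha, p$beta, p$gamma, x$site))
}

#' @export
glance.pcs_fit <- function(x, ...) {
  tibble(metal_label = x$metal_label, q_factor = x$q_factor, n_obs = x$n_obs,
         weights = x$weights)
}

#' @export
tidy.pcs_joint_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::mutate(tidy(f), metal_label = f$metal_label, .before = 1)
  })
}

#' @export
glance.pcs_joint_fit <- function(x, ...) {
  tibble(n_datasets = length(x$fits), objective = x$objective,
         site_x = x$site[1], site_y = x$site[2], site_z = x$site[3],
         q_mean = mean(purrr::map_dbl(x$fits, "q_factor")))
}

#' Observed vs back-calculated PCS plot
#'
#' @param object A `pcs_fit` or `pcs_joint_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcs_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$pcs, y = .data$calc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed PCS (ppm)", y = "back-calculated PCS (ppm)",
                  title = sprintf("%s: Q = %.3f (n = %d)",
                                  object$metal_label, object$q_factor, object$n_obs)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pcs_fit
#' @export
autoplot.pcs_joint_fit <- function(object, ...) {
  df <- purrr::map_dfr(object$fits, function(f) {
    dplyr::mutate(f$data, metal_label = f$metal_label)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcs, y = .data$calc,
                                   colour = .data$metal_label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed PCS (ppm)", y = "back-calculated PCS (ppm)",
                  colour = "metal") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
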