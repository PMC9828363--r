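#' Gradient minimisation of geometry + PCS energy
#'
#' Minimises the sum of the harmonic geometry-template energy and the PCS
#' pseudo-energy with the analytic gradients of both terms (quasi-Newton
#' L-BFGS steps, run in short chunks whose accepted energies form a
#' monotone non-increasing trace). The metal site is a free variable
#' coupled to the structure only through the PCS terms. This is a
#' deliberately simple geometry-template minimiser that stands in for a
#' full molecular-dynamics engine at method-verification scale.
#'
#' @param start Structure tibble (single model).
#' @param geometry A [geometry_template()] built on the same atom set.
#' @param restraints Optional [pcs_restraint_set()].
#' @param max_steps Maximum total quasi-Newton iterations.
#' @param chunk Iterations per chunk (one trace entry per chunk).
#' @param tol Stop when the energy decrease over a chunk falls below this.
#' @param refine_site Optimise the metal site alongside the coordinates.
#' @return The minimised structure, with attributes `energy_trace`
#'   (monotone non-increasing accepted energies), `site` (final site) and
#'   `converged`.
#' @export
refine_structure <- function(start, geometry, restraints = NULL,
                             max_steps = 200, chunk = 25, tol = 1e-8,
                             refine_site = TRUE) {
  s <- start[start$model == start$model[1], ]
  pos <- as.matrix(s[, c("x", "y", "z")])
  n <- nrow(pos)
  with_site <- !is.null(restraints) && refine_site
  site <- if (!is.null(restraints)) restraints$site else NULL

  unpack <- function(par) {
    list(pos = matrix(par[seq_len(3 * n)], ncol = 3),
         site = if (with_site) par[3 * n + 1:3] else site)
  }
  eval_energy <- function(par) {
    st <- unpack(par)
    ge <- geometry_energy_grad(st$pos, geometry)
    e <- ge$energy
    g_atoms <- ge$grad
    g_site <- NULL
    if (!is.null(restraints)) {
      r <- restraints
      r$site <- st$site
      s$x <- st$pos[, 1]; s$y <- st$pos[, 2]; s$z <- st$pos[, 3]
      pe <- pcs_energy_grad(s, r)
      e <- e + pe$energy
      g_atoms <- g_atoms + pe$grad_atoms
      g_site <- pe$grad_site
    }
    list(energy = e, grad = c(as.vector(g_atoms), if (with_site) g_site))
  }

  par <- c(as.vector(pos), if (with_site) site)
  cur <- eval_energy(par)
  if (!is.finite(cur$energy)) {
    abort("energy not finite at the starting structure",
          class = "parashift_step_failure")
  }
  trace <- cur$energy
  done <- 0
  while (done < max_steps) {
    it <- min(chunk, max_steps - done)
    opt <- tryCatch(
      optim(par, fn = function(p) eval_energy(p)$energy,
            gr = function(p) eval_energy(p)$grad,
            method = "L-BFGS-B",
            control = list(maxit = it, factr = 10)),
      error = function(e) {
        abort(paste0("minimisation step failed: ", conditionMessage(e)),
              class = "parashift_step_failure")
      })
    if (is.nan(opt$value)) {
      abort("energy diverged (NaN) during minimisation",
            class = "parashift_step_failure")
    }
    d_e <- trace[length(trace)] - opt$value
    if (d_e < 0) break          # reject a non-decreasing chunk
    par <- opt$par
    trace <- c(trace, opt$value)
    done <- done + it
    if (d_e < tol) break
  }
  st <- unpack(par)
  out <- s
  out$x <- st$pos[, 1]; out$y <- st$pos[, 2]; out$z <- st$pos[, 3]
  attr(out, "energy_trace") <- trace
  attr(out, "site") <- st$site
  attr(out, "converged") <- done < max_steps
  out
}

#' Iterative tensor / structure refinement
#'
#' Alternates (a) a joint fit of the shared metal position and per-dataset
#' tensors on the current coordinates with (b) restrained minimisation of
#' the structure holding the tensors fixed, until between consecutive
#' rounds the relative change of `dchi_ax` and `dchi_rh` is below 1 %, the
#' principal-axis-frame rotation is below 2 degrees, the site moves less
#' than 0.1 Angstrom and the structure RMSD is below 0.05 Angstrom — or
#' `max_rounds` is reached. An objective increasing over three consecutive
#' rounds aborts with a non-convergence error carrying the trace.
#'
#' @param start Structure tibble.
#' @param datasets List of [pcs_dataset()] (one per metal).
#' @param geometry A [geometry_template()].
#' @param max_rounds Maximum rounds (0 returns the initial fit only,
#'   flagged unconverged).
#' @param tol_tensor Relative tensor-magnitude convergence threshold.
#' @param tol_rotation PAF rotation threshold, degrees.
#' @param tol_site Site displacement threshold, Angstrom.
#' @param tol_rmsd Structure RMSD threshold, Angstrom.
#' @param force_constant,tolerance_ppm PCS restraint parameters.
#' @param refine_steps Descent steps per round.
#' @param ... Passed to [fit_position_and_tensors()] (e.g. `box`,
#'   `grid_spacing`).
#' @return List: `structure` (final), `fit` (final joint fit), `rounds`
#'   (per-round log tibble), `converged`, `tensors_by_round`.
#' @export
iterate_tensor_structure <- function(start, datasets, geometry,
                                     max_rounds = 10,
                                     tol_tensor = 0.01, tol_rotation = 2,
                                     tol_site = 0.1, tol_rmsd = 0.05,
                                     force_constant = 1, tolerance_ppm = 0.05,
                                     refine_steps = 150, ...) {
  fit <- fit_position_and_tensors(datasets, start, ...)
  log_rows <- list()
  tensors_by_round <- list(purrr::map(fit$fits, "tensor"))
  if (max_rounds < 1) {
    return(list(structure = start, fit = fit, rounds = tibble(),
                converged = FALSE, tensors_by_round = tensors_by_round))
  }
  current <- start
  prev_fit <- fit
  obj_trace <- fit$objective
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    restr <- pcs_restraint_set(datasets, purrr::map(prev_fit$fits, "tensor"),
                               prev_fit$site,
                               force_constant = force_constant,
                               tolerance = tolerance_ppm)
    refined <- refine_structure(current, geometry, restr,
                                max_steps = refine_steps)
    new_fit <- fit_position_and_tensors(
      datasets, refined,
      box = rbind(prev_fit$site - 3, prev_fit$site + 3),
      grid_spacing = 1.5, check_consistency = FALSE)
    rmsd <- sqrt(mean(rowSums((as.matrix(refined[, c("x", "y", "z")]) -
                                 as.matrix(current[, c("x", "y", "z")]))^2)))
    site_shift <- sqrt(sum((new_fit$site - prev_fit$site)^2))
    deltas <- purrr::map2_dfr(new_fit$fits, prev_fit$fits, function(a, b) {
      pa <- tensor_convert(a$tensor, "paf")
      pb <- tensor_convert(b$tensor, "paf")
      Ra <- rot_zyz(pa$alpha, pa$beta, pa$gamma)
      Rb <- rot_zyz(pb$alpha, pb$beta, pb$gamma)
      # PAF axes are sign-ambiguous; take the smallest equivalent rotation
      rot <- min(vapply(list(diag(3),
                             diag(c(-1, -1, 1)),
                             diag(c(1, -1, -1)),
                             diag(c(-1, 1, -1))), function(S) {
        rotation_angle_deg(t(Ra) %*% Rb %*% S)
      }, 0))
      tibble(metal_label = a$metal_label,
             rel_ax = abs(pa$dchi_ax - pb$dchi_ax) / max(abs(pb$dchi_ax), 1e-12),
             rel_rh = abs(pa$dchi_rh - pb$dchi_rh) / max(abs(pb$dchi_rh), 1e-12),
             paf_rotation = rot,
             q = a$q_factor)
    })
    log_rows[[round]] <- dplyr::mutate(deltas, round = round,
                                       site_shift = site_shift,
                                       structure_rmsd = rmsd,
                                       objective = new_fit$objective)
    tensors_by_round[[round + 1]] <- purrr::map(new_fit$fits, "tensor")
    obj_trace <- c(obj_trace, new_fit$objective)
    n_obj <- length(obj_trace)
    if (n_obj >= 4 && all(diff(utils::tail(obj_trace, 4)) > 0)) {
      abort(paste0("objective increased over three consecutive rounds; trace: ",
                   paste(sprintf("%.4g", obj_trace), collapse = " -> ")),
            class = "parashift_non_convergence_error")
    }
    current <- refined
    if (max(deltas$rel_ax) < tol_tensor && max(deltas$rel_rh) < tol_tensor &&
        max(deltas$paf_rotation) < tol_rotation && site_shift < tol_site &&
        rmsd < tol_rmsd) {
      prev_fit <- new_fit
      converged <- TRUE
      break
    }
    prev_fit <- new_fit
  }
  list(structure = current, fit = prev_fit,
       rounds = dplyr::bind_rows(log_rows),
       converged = converged,
       tensors_by_round = tensors_by_round)
}
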