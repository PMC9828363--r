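EXCHANGEABLE_PROTONS <- c("H1", "H3", "H21", "H22", "H41", "H42", "H61", "H62")

#' Assigned chemical-shift tables
#'
#' A shift table is a tibble with columns `residue_number`, `residue_name`,
#' `atom_name`, `shift` (ppm) and optionally `sigma` (ppm), carrying
#' `sample_label` and `solvent` (`"H2O"` or `"D2O"`) as attributes.
#'
#' @param df Data frame of records.
#' @param sample_label Sample identifier, e.g. `"Lu"` or `"Tm"`.
#' @param solvent `"H2O"` or `"D2O"`.
#' @return A validated shift-table tibble.
#' @export
shift_table <- function(df, sample_label = "sample", solvent = c("D2O", "H2O")) {
  solvent <- match.arg(solvent)
  df <- as_tibble(df)
  need <- c("residue_number", "residue_name", "atom_name", "shift")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("shift table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df$residue_number <- as.integer(df$residue_number)
  df$shift <- as.numeric(df$shift)
  if (any(!is.finite(df$shift))) abort("non-numeric or non-finite shift value")
  dup <- df |>
    dplyr::count(.data$residue_number, .data$atom_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (residue, atom) key(s): ",
                 paste(paste0(dup$residue_number, ":", dup$atom_name), collapse = ", ")),
          class = "parashift_duplicate_key_error")
  }
  attr(df, "sample_label") <- sample_label
  attr(df, "solvent") <- solvent
  df
}

#' Read an assigned chemical-shift table
#'
#' Accepts either a tab-separated table (header row with columns
#' `residue_number`, `residue_name`, `atom_name`, `shift` and optional
#' `sigma`) or an NMR-STAR v3 file, from which the `_Atom_chem_shift` loop
#' is extracted.
#'
#' @param path File path.
#' @param format `"tsv"`, `"nmrstar"` or `"auto"` (NMR-STAR is detected by a
#'   `save_`/`loop_` header or a `.str` extension).
#' @param sample_label,solvent Metadata attached to the table.
#' @return A shift-table tibble (see [shift_table()]).
#' @export
read_shift_table <- function(path, format = c("auto", "tsv", "nmrstar"),
                             sample_label = NULL, solvent = c("D2O", "H2O")) {
  format <- match.arg(format)
  solvent <- match.arg(solvent)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    head_lines <- readLines(path, n = 50, warn = FALSE)
    is_star <- grepl("\\.str$", path, ignore.case = TRUE) ||
      any(grepl("^\\s*(save_|loop_|data_)", head_lines)) &&
      any(grepl("_Atom_chem_shift", head_lines)) ||
      any(grepl("_Atom_chem_shift", readLines(path, warn = FALSE)))
    format <- if (is_star) "nmrstar" else "tsv"
  }
  label <- sample_label %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!"shift" %in% names(df) || any(is.na(suppressWarnings(as.numeric(df$shift))))) {
      abort("TSV shift table: missing or non-numeric `shift` column")
    }
    shift_table(df, sample_label = label, solvent = solvent)
  } else {
    read_shift_table_nmrstar(path, sample_label = label, solvent = solvent)
  }
}

# Minimal NMR-STAR v3 reader restricted to the assigned chemical shift loop
# (tags _Atom_chem_shift.*); no installed R package parses NMR-STAR.
read_shift_table_nmrstar <- function(path, sample_label, solvent) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    rows <- list()
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (tl %in% c("stop_", "save_") || startsWith(tl, "loop_")) break
      if (tl != "" && !startsWith(tl, "#")) {
        rows[[length(rows) + 1L]] <- strsplit(tl, "[[:space:]]+")[[1]]
      }
      i <- i + 1L
    }
    if (!length(rows)) abort("NMR-STAR chemical-shift loop has no data rows")
    if (any(lengths(rows) != length(tags))) {
      abort("NMR-STAR parse failure: row width does not match tag count")
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- tags
    pick <- function(...) {
      for (nm in c(...)) {
        full <- paste0("_Atom_chem_shift.", nm)
        if (full %in% tags) return(tab[, full])
      }
      NULL
    }
    seq_id <- pick("Seq_ID", "Comp_index_ID", "Auth_seq_ID")
    comp <- pick("Comp_ID", "Auth_comp_ID")
    atom <- pick("Atom_ID", "Auth_atom_ID")
    val <- pick("Val")
    err <- pick("Val_err")
    if (is.null(seq_id) || is.null(atom) || is.null(val)) {
      abort("NMR-STAR chemical-shift loop lacks Seq_ID/Atom_ID/Val tags")
    }
    df <- tibble(residue_number = as.integer(seq_id),
                 residue_name = if (is.null(comp)) NA_character_ else comp,
                 atom_name = atom,
                 shift = as.numeric(val))
    if (!is.null(err)) {
      sig <- suppressWarnings(as.numeric(err))
      if (any(is.finite(sig))) df$sigma <- sig
    }
    if (any(!is.finite(df$shift))) abort("non-numeric shift value in NMR-STAR loop")
    return(shift_table(df, sample_label = sample_label, solvent = solvent))
  }
  abort("no _Atom_chem_shift loop found in NMR-STAR file")
}

#' @rdname read_shift_table
#' @param table A shift table to write.
#' @export
write_shift_table <- function(table, path) {
  cols <- intersect(c("residue_number", "residue_name", "atom_name", "shift", "sigma"),
                    names(table))
  readr::write_tsv(table[, cols], path, progress = FALSE)
  invisible(path)
}

#' Build a PCS dataset from paramagnetic and diamagnetic shift tables
#'
#' The pseudocontact shift of each nucleus is the chemical-shift difference
#' between the paramagnetic sample and the diamagnetic reference,
#' `pcs = shift_para - shift_dia`, computed for every `(residue_number,
#' atom_name)` key present in **both** tables. Keys present in only one
#' table are dropped and logged: their absence carries no information (peaks
#' near the metal are broadened beyond detection by PRE) and is never
#' penalised. Residue names are not part of the matching key; a mismatched
#' residue name at a matched key triggers a warning.
#'
#' @param para,dia Shift tables ([shift_table()]), paramagnetic sample and
#'   diamagnetic reference.
#' @param default_sigma Uncertainty (ppm) assigned where neither table
#'   carries a `sigma` column.
#' @param exclude_exchangeable Drop imino/amino protons
#'   (`r paste(EXCHANGEABLE_PROTONS, collapse = ", ")`), appropriate for
#'   D2O datasets.
#' @param allow_solvent_mismatch Permit pairing tables with different
#'   solvent tags (the tensor differs between H2O and D2O, so this is
#'   loudly warned about).
#' @return A `pcs_dataset` tibble with columns `residue_number`,
#'   `atom_name`, `pcs` (ppm), `sigma` (ppm); attributes `metal_label`
#'   (from `para`) and `solvent`.
#' @export
compute_pcs_dataset <- function(para, dia, default_sigma = 0.01,
                                exclude_exchangeable = FALSE,
                                allow_solvent_mismatch = FALSE) {
  if (!nrow(para) || !nrow(dia)) abort("shift tables must be non-empty")
  sol_p <- attr(para, "solvent") %||% "D2O"
  sol_d <- attr(dia, "solvent") %||% "D2O"
  if (!identical(sol_p, sol_d)) {
    if (!allow_solvent_mismatch) {
      abort(paste0("solvent mismatch (", sol_p, " vs ", sol_d, "); the delta-chi ",
                   "tensor differs between H2O and D2O. Set ",
                   "`allow_solvent_mismatch = TRUE` to pair them anyway."))
    }
    warn(paste0("pairing shift tables measured in different solvents (", sol_p,
                " vs ", sol_d, "): tensors differ between H2O and D2O; ",
                "interpret the resulting PCS with care"))
  }
  j <- dplyr::inner_join(
    dplyr::select(para, "residue_number", "atom_name",
                  para_name = "residue_name", shift_para = "shift",
                  dplyr::any_of(c(sigma_para = "sigma"))),
    dplyr::select(dia, "residue_number", "atom_name",
                  dia_name = "residue_name", shift_dia = "shift",
                  dplyr::any_of(c(sigma_dia = "sigma"))),
    by = c("residue_number", "atom_name"))
  if (!nrow(j)) abort("no shared (residue, atom) keys between the two tables",
                      class = "parashift_empty_dataset_error")
  n_drop <- nrow(para) + nrow(dia) - 2 * nrow(j)
  if (n_drop > 0) {
    inform(sprintf("compute_pcs_dataset: %d record(s) present in only one table were dropped (missing peaks carry no information)", n_drop))
  }
  mism <- j$para_name != j$dia_name
  if (any(mism)) {
    warn(paste0("residue_name differs at matched key(s): ",
                paste(utils::head(paste0(j$residue_number[mism], ":",
                                         j$atom_name[mism]), 5), collapse = ", ")))
  }
  sig <- rep(default_sigma, nrow(j))
  if (all(c("sigma_para", "sigma_dia") %in% names(j))) {
    both <- is.finite(j$sigma_para) & is.finite(j$sigma_dia)
    sig[both] <- sqrt(j$sigma_para[both]^2 + j$sigma_dia[both]^2)
  } else if ("sigma_para" %in% names(j)) {
    ok <- is.finite(j$sigma_para)
    sig[ok] <- j$sigma_para[ok]
  }
  out <- tibble(residue_number = j$residue_number,
                atom_name = j$atom_name,
                pcs = j$shift_para - j$shift_dia,
                sigma = sig)
  if (exclude_exchangeable) {
    out <- out[!out$atom_name %in% EXCHANGEABLE_PROTONS, ]
  }
  if (!nrow(out)) abort("PCS dataset is empty after filtering",
                        class = "parashift_empty_dataset_error")
  if (any(out$sigma <= 0)) abort("sigma must be > 0")
  pcs_dataset(out,
              metal_label = attr(para, "sample_label") %||% "para",
              solvent = sol_p)
}

#' @rdname compute_pcs_dataset
#' @param df Data frame with `residue_number`, `atom_name`, `pcs`, `sigma`.
#' @param metal_label Metal identifier (e.g. `"Tm"`).
#' @param solvent Solvent tag.
#' @export
pcs_dataset <- function(df, metal_label = "metal", solvent = "D2O") {
  df <- as_tibble(df)[, c("residue_number", "atom_name", "pcs", "sigma")]
  if (any(df$sigma <= 0)) abort("sigma must be > 0")
  if (any(!is.finite(df$pcs))) abort("pcs values must be finite")
  attr(df, "metal_label") <- metal_label
  attr(df, "solvent") <- solvent
  class(df) <- c("pcs_dataset", class(df))
  df
}

NOE_CLASS_BOUNDS <- list(strong = c(1.8, 3.0),
                         medium = c(2.0, 4.0),
                         weak   = c(2.2, 5.0))

#' Calibrate NOESY volumes into classed distance restraints
#'
#' Cross-peak volumes are classed against a reference volume from fixed
#' distances (H5-H6 in cytidines, H2'-H2'' in deoxyriboses): strong when
#' `V >= 0.5 * V_ref`, medium when `0.1 * V_ref <= V < 0.5 * V_ref`, weak
#' otherwise (r^-6 bracketing about the ~2.4 Angstrom reference distance).
#' Classes carry the bounds strong 1.8-3.0, medium 2.0-4.0 and weak
#' 2.2-5.0 Angstrom.
#'
#' @param volumes Data frame with atom-pair key columns (everything except
#'   `volume`) and a positive `volume` column.
#' @param reference_volume Positive reference volume.
#' @return The input with `class`, `lower_bound`, `upper_bound` appended.
#' @export
noe_calibrate <- function(volumes, reference_volume) {
  volumes <- as_tibble(volumes)
  if (!"volume" %in% names(volumes)) abort("`volumes` needs a `volume` column")
  if (any(volumes$volume <= 0) || reference_volume <= 0) {
    abort("volumes and reference_volume must be > 0")
  }
  ratio <- volumes$volume / reference_volume
  cls <- dplyr::case_when(ratio >= 0.5 ~ "strong",
                          ratio >= 0.1 ~ "medium",
                          TRUE ~ "weak")
  bounds <- do.call(rbind, NOE_CLASS_BOUNDS[cls])
  volumes$class <- cls
  volumes$lower_bound <- unname(bounds[, 1])
  volumes$upper_bound <- unname(bounds[, 2])
  volumes
}
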