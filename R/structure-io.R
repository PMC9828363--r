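#' Atomic structures as tibbles
#'
#' Throughout the package a structure (or multi-model ensemble) is a tibble
#' with columns `model` (integer), `residue_number`, `residue_name`,
#' `atom_name`, `x`, `y`, `z` (Angstrom). All models of an ensemble share
#' the same atom keys `(residue_number, atom_name)` in the same order.
#'
#' @param df A data frame with at least `residue_number`, `residue_name`,
#'   `atom_name`, `x`, `y`, `z`; a `model` column is added (= 1) if absent.
#' @return A validated structure tibble.
#' @export
as_structure <- function(df) {
  df <- as_tibble(df)
  if (!"model" %in% names(df)) df$model <- 1L
  need <- c("model", "residue_number", "residue_name", "atom_name", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("structure is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df[, c(need, setdiff(names(df), need))]
  df$model <- as.integer(df$model)
  df$residue_number <- as.integer(df$residue_number)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("structure coordinates must be finite")
  }
  dup <- df |>
    dplyr::count(.data$model, .data$residue_number, .data$atom_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate atom key(s) within a model: ",
                 paste(utils::head(paste0(dup$residue_number, ":", dup$atom_name), 5),
                       collapse = ", ")))
  }
  check_shared_topology(df)
  df
}

check_shared_topology <- function(df) {
  keys <- split(paste(df$residue_number, df$atom_name), df$model)
  if (length(keys) <= 1) return(invisible(TRUE))
  ref <- keys[[1]]
  for (m in names(keys)[-1]) {
    if (!identical(sort(keys[[m]]), sort(ref))) {
      bad <- c(setdiff(ref, keys[[m]]), setdiff(keys[[m]], ref))
      abort(paste0("models do not share a common atom set; offending atom(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            class = "parashift_topology_error")
    }
  }
  invisible(TRUE)
}

# n x 3 coordinate matrix of one model (default: first), rows in table order.
structure_coords <- function(structure, model = NULL) {
  m <- model %||% structure$model[1]
  s <- structure[structure$model == m, ]
  as.matrix(s[, c("x", "y", "z")])
}

#' Read a structure (PDB or mmCIF, possibly multi-model)
#'
#' PDB files are parsed with \pkg{bio3d}; mmCIF files through the package's
#' `atom_site` loop reader. Models with differing atom sets raise a topology
#' error naming the offending atoms.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return A structure tibble (one block of rows per model).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse failure: ", conditionMessage(e)))
  )
  n_models <- nrow(pdb$xyz)
  atom <- pdb$atom
  check_pdb_model_topology(path)
  purrr::map_dfr(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    tibble(model = m,
           residue_number = as.integer(atom$resno),
           residue_name = trimws(atom$resid),
           atom_name = trimws(atom$elety),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }) |> as_structure()
}

# bio3d recycles the model-1 atom table across models, so a per-model key
# scan of the raw file is needed to detect topology mismatches honestly.
check_pdb_model_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_idx <- 0L
  keys <- list()
  cur <- character()
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      model_idx <- model_idx + 1L
      cur <- character()
    } else if (startsWith(rec, "ENDMDL")) {
      keys[[length(keys) + 1L]] <- cur
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      cur <- c(cur, paste(trimws(substr(ln, 23, 26)), trimws(substr(ln, 13, 16))))
    }
  }
  if (length(keys) > 1) {
    ref <- keys[[1]]
    for (i in seq_along(keys)[-1]) {
      if (!identical(sort(keys[[i]]), sort(ref))) {
        bad <- c(setdiff(ref, keys[[i]]), setdiff(keys[[i]], ref))
        abort(paste0("PDB models differ in atom content; offending atom(s): ",
                     paste(utils::head(bad, 5), collapse = ", ")),
              class = "parashift_topology_error")
      }
    }
  }
  invisible(TRUE)
}

read_structure_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(tags, "_atom_site."))) next
    rows <- list()
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (tl == "" || startsWith(tl, "_") || startsWith(tl, "loop_") ||
          startsWith(tl, "#") || startsWith(tl, "data_")) break
      rows[[length(rows) + 1L]] <- strsplit(tl, "[[:space:]]+")[[1]]
      i <- i + 1L
    }
    if (!length(rows)) abort("mmCIF atom_site loop has no data rows")
    if (any(lengths(rows) != length(tags))) {
      abort("mmCIF parse failure: atom_site row width does not match tag count")
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- tags
    get <- function(name, alt = NULL) {
      for (nm in c(name, alt)) {
        full <- paste0("_atom_site.", nm)
        if (full %in% tags) return(tab[, full])
      }
      abort(paste0("mmCIF atom_site loop lacks tag _atom_site.", name))
    }
    model <- if ("_atom_site.pdbx_PDB_model_num" %in% tags) {
      as.integer(tab[, "_atom_site.pdbx_PDB_model_num"])
    } else rep(1L, nrow(tab))
    out <- tibble(
      model = model,
      residue_number = as.integer(get("label_seq_id", "auth_seq_id")),
      residue_name = get("label_comp_id", "auth_comp_id"),
      atom_name = gsub('"', "", get("label_atom_id", "auth_atom_id")),
      x = as.numeric(get("Cartn_x")),
      y = as.numeric(get("Cartn_y")),
      z = as.numeric(get("Cartn_z")))
    if (any(!is.finite(out$x))) abort("mmCIF parse failure: non-numeric coordinates")
    return(as_structure(out))
  }
  abort("mmCIF parse failure: no atom_site loop found")
}

#' Write a structure (PDB or mmCIF, multi-model)
#'
#' @param structure A structure tibble (see [as_structure()]).
#' @param path Output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  structure <- as_structure(structure)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  models <- unique(structure$model)
  if (format == "pdb") {
    s1 <- structure[structure$model == models[1], ]
    xyz <- do.call(rbind, lapply(models, function(m) {
      as.vector(t(structure_coords(structure, m)))
    }))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = s1$residue_number,
                     resid = s1$residue_name,
                     elety = s1$atom_name,
                     chain = rep("A", nrow(s1)))
  } else {
    hdr <- c("data_parashift", "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.label_atom_id", "_atom_site.label_comp_id",
             "_atom_site.label_seq_id", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.pdbx_PDB_model_num")
    body <- sprintf("ATOM %d %s %s %d %.3f %.3f %.3f %d",
                    seq_len(nrow(structure)),
                    ifelse(grepl("'", structure$atom_name),
                           paste0('"', structure$atom_name, '"'),
                           structure$atom_name),
                    structure$residue_name, structure$residue_number,
                    structure$x, structure$y, structure$z, structure$model)
    writeLines(c(hdr, body, "#"), path)
  }
  invisible(path)
}
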