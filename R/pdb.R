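#' Read a (multi-model) PDB file into a coordinate tibble
#'
#' Parses ATOM/HETATM records (via bio3d) from a single- or
#' multi-model PDB file into one tidy tibble with a `model` column.
#' Every model must share one atom roster (same atoms, same order); a
#' mismatch is a hard error naming the first offending atom. Only
#' altloc `''`/`A` is kept; hydrogens are kept when present.
#'
#' @param path Path to a PDB file.
#' @return A tibble with columns `model`, `chain`, `residue_number`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z`.
#' @export
read_models <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  check_roster(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, ]
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- ifelse(is.na(elem) | elem == "", guess_element(at$elety), elem)
  n_models <- nrow(pdb$xyz)
  xyz_idx <- bio3d::atom2xyz(which(keep))
  map(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, xyz_idx], ncol = 3, byrow = TRUE)
    tibble(model = m,
           chain = ifelse(is.na(at$chain), "A", at$chain),
           residue_number = at$resno,
           residue_name = at$resid,
           atom_name = at$elety,
           element = toupper(trimws(elem)),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }) |> list_rbind()
}

# scan raw records so a roster mismatch can name the first offending
# atom (the multi-model reader only reports a dimension failure)
check_roster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (!any(model_starts)) return(invisible(TRUE))
  model_id <- cumsum(model_starts)
  keys <- split(
    paste(trimws(substr(lines[is_atom], 13, 16)),
          trimws(substr(lines[is_atom], 18, 20)),
          trimws(substr(lines[is_atom], 22, 22)),
          trimws(substr(lines[is_atom], 23, 26))),
    model_id[is_atom])
  keys <- keys[names(keys) != "0"]
  if (length(keys) < 2L) return(invisible(TRUE))
  ref <- keys[[1]]
  for (m in seq_along(keys)[-1]) {
    k <- keys[[m]]
    if (length(k) != length(ref)) {
      n <- min(length(k), length(ref))
      diff <- which(k[seq_len(n)] != ref[seq_len(n)])
      at <- if (length(diff)) k[diff[1]] else
        if (length(k) > n) k[n + 1] else ref[n + 1]
      abort(sprintf(
        "atom roster mismatch in model %d (%d vs %d atoms); first offending atom: %s",
        m, length(k), length(ref), at))
    }
    diff <- which(k != ref)
    if (length(diff)) {
      abort(sprintf(
        "atom roster mismatch in model %d at atom %d: '%s' vs '%s'",
        m, diff[1], k[diff[1]], ref[diff[1]]))
    }
  }
  invisible(TRUE)
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  first <- substr(nm, 1, 1)
  ifelse(first == "" & grepl("^[0-9]*H", trimws(atom_name)), "H", first)
}

#' Write a coordinate tibble to a (multi-model) PDB file
#'
#' @param coords Coordinate tibble as from [read_models()] (the
#'   `model` column may be absent for a single model).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_models <- function(coords, path) {
  if (!"model" %in% names(coords)) coords$model <- 1L
  models <- split(coords, coords$model)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    tb <- models[[m]]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(tb)), format_atom_name(tb$atom_name),
      tb$residue_name, tb$chain, tb$residue_number,
      tb$x, tb$y, tb$z, 1, 0, tb$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# PDB column convention: 1-3 character names start in column 14,
# 4-character names in column 13
format_atom_name <- function(nm) {
  ifelse(nchar(nm) >= 4, substr(nm, 1, 4), paste0(" ", sprintf("%-3s", nm)))
}

# resolve a selection argument into a logical vector over atoms:
# NULL = everything, character = atom names, function = predicate
resolve_selection <- function(coords, selection) {
  if (is.null(selection)) return(rep(TRUE, nrow(coords)))
  if (is.character(selection)) return(coords$atom_name %in% selection)
  if (is.function(selection)) return(selection(coords))
  if (is.logical(selection)) return(selection)
  abort("selection must be NULL, atom names, a predicate or logical")
}

#' Backbone atom selection (N, CA, C)
#'
#' The backbone convention used throughout: amide nitrogen, alpha
#' carbon and carbonyl carbon (the carbonyl oxygen is excluded).
#' @return A character vector of atom names, usable as a `selection`.
#' @export
sel_backbone <- function() c("N", "CA", "C")

coords_matrix <- function(coords) {
  as.matrix(coords[, c("x", "y", "z")])
}

split_models <- function(coords) {
  if (!"model" %in% names(coords)) return(list(coords))
  split(coords, coords$model)
}
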