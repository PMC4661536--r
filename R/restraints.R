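#' Classify NOE distance restraints by residue separation
#'
#' Standard sequence-separation classes used in NMR structure
#' statistics: intraresidual (|i-j| = 0), sequential (|i-j| = 1),
#' medium-range (1 < |i-j| < 5) and long-range (|i-j| > 4).
#' Percentages are rounded half-up to 2 decimals to match the usual
#' table formatting; `per_residue` is total/n_residues rounded the
#' same way.
#'
#' @param restraints Tibble with integer columns `residue_i`,
#'   `residue_j` (other columns such as atom names and upper bounds
#'   are ignored here).
#' @param n_residues Number of residues in the construct.
#' @return Tibble with one row per class (`class`, `count`,
#'   `percent`) plus attributes `total` and `per_residue`.
#' @export
classify_restraints <- function(restraints, n_residues) {
  stopifnot(n_residues > 0)
  if (nrow(restraints) == 0L) abort("empty restraint list")
  sep <- abs(restraints$residue_i - restraints$residue_j)
  cls <- dplyr::case_when(
    sep == 0 ~ "intraresidual",
    sep == 1 ~ "sequential",
    sep < 5 ~ "medium",
    .default = "long"
  )
  levels <- c("intraresidual", "sequential", "medium", "long")
  counts <- map_int(levels, function(l) sum(cls == l))
  total <- length(sep)
  out <- tibble(class = levels, count = counts,
                percent = round_half_up(100 * counts / total, 2))
  structure(out, total = total,
            per_residue = round_half_up(total / n_residues, 2))
}

#' Read an NOE restraint list from TSV
#'
#' Columns: `residue_i`, `atom_i`, `residue_j`, `atom_j`,
#' `upper_bound` (Angstrom).
#' @param path File path.
#' @return Tibble of restraints.
#' @export
read_restraints <- function(path) {
  df <- as_tibble(utils::read.delim(path, comment.char = "#"))
  need <- c("residue_i", "residue_j")
  if (!all(need %in% names(df))) {
    abort("restraint file needs residue_i and residue_j columns")
  }
  if ("upper_bound" %in% names(df) && any(df$upper_bound <= 0)) {
    abort("upper bounds must be positive")
  }
  df
}

#' Generate ambiguous interaction restraints (AIRs) from a CSP profile
#'
#' Implements the standard data-driven docking recipe: "active"
#' residues are those whose combined CSP exceeds the mean by more than
#' one standard deviation (classes `significant`/`strong`); "passive"
#' residues are solvent-exposed neighbours — relative SASA above
#' `sasa_cut` with a heavy atom within `vicinity` of any active
#' residue — that are not themselves active. The emitted restraint
#' text uses the ambiguous-distance dialect
#' (`assign (resid ... and segid A) (resid ... and segid B) d dm dp`)
#' with an effective distance of `dist` Angstrom (bounds `dist - dist`
#' to `dist + 0`, i.e. 0 to `dist`).
#'
#' The explicit passive rule is an approximation of docking servers'
#' automatic surface definition and is exposed via its two thresholds.
#'
#' @param profile A classified `csp_profile`.
#' @param model Coordinate tibble (see [read_models()]) covering the
#'   profile residues; used for SASA and vicinity.
#' @param ligand_active Residue numbers of the partner (segid B)
#'   defined active.
#' @param sasa_cut Relative-SASA threshold for passive residues
#'   (default 0.5, i.e. >50% exposed).
#' @param vicinity Heavy-atom distance (Angstrom) defining "near an
#'   active residue"; default 6.5.
#' @param dist Effective AIR distance (Angstrom); default 2.0.
#' @return An `air_spec` list: `active`, `passive`, `partner_active`,
#'   `distance_bound`, and `text` (the restraint file contents).
#' @export
generate_airs <- function(profile, model, ligand_active,
                          sasa_cut = 0.5, vicinity = 6.5, dist = 2.0) {
  active <- sort(profile$residue_number[profile$class %in%
                                          c("significant", "strong")])
  if (length(active) == 0L) abort("no significant CSPs: no active residues")
  rel <- relative_sasa(model)
  exposed <- rel$residue_number[!is.na(rel$rel_sasa) &
                                  rel$rel_sasa > sasa_cut]
  heavy <- model[model$element != "H", ]
  act_xyz <- as.matrix(heavy[heavy$residue_number %in% active,
                             c("x", "y", "z")])
  near_active <- map_lgl(sort(unique(model$residue_number)), function(r) {
    if (r %in% active) return(FALSE)
    xyz <- as.matrix(heavy[heavy$residue_number == r, c("x", "y", "z")])
    if (nrow(xyz) == 0L || nrow(act_xyz) == 0L) return(FALSE)
    min(pair_dists(xyz, act_xyz)) <= vicinity
  })
  candidates <- sort(unique(model$residue_number))[near_active]
  passive <- sort(intersect(candidates, exposed))
  passive <- setdiff(passive, active)
  lines <- c(
    "! ambiguous interaction restraints derived from CSP mapping",
    sprintf("! active (segid A): %s", paste(active, collapse = " ")),
    sprintf("! passive (segid A): %s", paste(passive, collapse = " ")),
    map_chr(active, function(r) {
      sprintf(paste0("assign (resid %d and segid A) ",
                     "((resid %s and segid B)) %.1f %.1f 0.0"),
              r, paste(ligand_active, collapse = " or resid "),
              dist, dist)
    }),
    map_chr(sort(ligand_active), function(r) {
      sel <- paste(c(active, passive), collapse = " or resid ")
      sprintf(paste0("assign (resid %d and segid B) ",
                     "((resid %s and segid A)) %.1f %.1f 0.0"),
              r, sel, dist, dist)
    })
  )
  structure(list(active = active, passive = passive,
                 partner_active = sort(ligand_active),
                 distance_bound = dist,
                 text = paste(lines, collapse = "\n")),
            class = "air_spec")
}

#' @export
print.air_spec <- function(x, ...) {
  cat(sprintf("AIR spec: %d active, %d passive, %d partner-active; d = %.1f A\n",
              length(x$active), length(x$passive),
              length(x$partner_active), x$distance_bound))
  invisible(x)
}

#' Write an AIR spec to a restraint file
#' @param spec An `air_spec` from [generate_airs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_airs <- function(spec, path) {
  writeLines(spec$text, path)
  invisible(path)
}

# all pairwise Euclidean distances between rows of two xyz matrices
pair_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}
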