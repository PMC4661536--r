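#' @name sasa-constants
#' @title Radii and reference areas used by the surface-area routines
#' @description
#' Van der Waals radii (Angstrom): C 1.70, N 1.55, O 1.52, P 1.80,
#' S 1.80, H 1.20. Hydrogens are included when present; united-atom
#' radii are not used. Per-residue maximum accessible surface areas
#' for relative SASA are the theoretical values of Tien et al. (2013)
#' PLoS ONE 8:e80635.
#' @keywords internal
NULL

vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

# Tien et al. 2013, theoretical maximum ASA (A^2)
max_asa_tien2013 <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# deterministic Fibonacci lattice on the unit sphere: SASA results are
# exactly reproducible for a given n_points (no RNG involved)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)        # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- phi * (seq_len(n) - 1)
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

atom_radii <- function(coords) {
  r <- unname(vdw_radii[coords$element])
  if (anyNA(r)) {
    bad <- unique(coords$element[is.na(r)])
    abort(sprintf("no van der Waals radius for element(s): %s (atoms: %s)",
                  paste(bad, collapse = ", "),
                  paste(head(coords$atom_name[is.na(r)], 5), collapse = ", ")))
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over every atom using a deterministic
#' Fibonacci point lattice: each atom's accessible area is the
#' unoccluded fraction of `n_points` test points on its solvent sphere
#' (radius vdW + probe) times the sphere area. Deterministic given
#' `n_points`.
#'
#' @param model Single-model coordinate tibble with an `element`
#'   column covered by the shipped radius table (C/N/O/P/S/H).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (>= 100; default 960).
#' @return Per-atom tibble (`chain`, `residue_number`, `residue_name`,
#'   `atom_name`, `element`, `area` in Angstrom^2). Aggregate with
#'   [residue_sasa()].
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L) {
  if (n_points < 100L) abort("n_points must be >= 100")
  if ("model" %in% names(model) && length(unique(model$model)) > 1L) {
    abort("sasa() expects a single model; filter or split first")
  }
  r <- atom_radii(model) + probe
  xyz <- coords_matrix(model)
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  d <- pair_dists(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    sphere <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dx <- sphere[, 1] - xyz[j, 1]
      dy <- sphere[, 2] - xyz[j, 2]
      dz <- sphere[, 3] - xyz[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz > r[j]^2)
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  out <- model |>
    select(dplyr::any_of(c("chain", "residue_number", "residue_name",
                           "atom_name", "element")))
  out$area <- area
  out
}

#' Aggregate atomic SASA per residue
#' @param atom_sasa Output of [sasa()].
#' @return Tibble `chain`, `residue_number`, `residue_name`, `area`.
#' @export
residue_sasa <- function(atom_sasa) {
  atom_sasa |>
    group_by(.data$chain, .data$residue_number, .data$residue_name) |>
    summarise(area = sum(.data$area), .groups = "drop")
}

#' Buried surface area across an interface
#'
#' Per-residue BSA = SASA of the residue in its isolated component
#' minus its SASA in the complex; the total interface area is half
#' the sum of the per-residue BSAs over both components (the two
#' sides each "lose" one face of the same interface).
#'
#' @param complex_model Single-model coordinate tibble of the complex.
#' @param group_a,group_b Disjoint atom groups covering the two
#'   components: atom-name vectors, predicates or logical vectors
#'   (see [superpose()] selections); commonly
#'   `function(tb) tb$chain == "A"`.
#' @param probe,n_points As in [sasa()].
#' @return A list: `residues` tibble (`component`, `chain`,
#'   `residue_number`, `residue_name`, `bsa`) sorted by decreasing
#'   BSA, and `total_interface_area` (Angstrom^2).
#' @export
buried_surface_area <- function(complex_model, group_a, group_b,
                                probe = 1.4, n_points = 960L) {
  in_a <- resolve_selection(complex_model, group_a)
  in_b <- resolve_selection(complex_model, group_b)
  if (any(in_a & in_b)) abort("partition groups overlap")
  if (!any(in_a) || !any(in_b)) abort("both groups must be non-empty")
  keep <- in_a | in_b
  part <- complex_model[keep, ]
  in_a <- in_a[keep]
  complex_sasa <- residue_sasa(sasa(part, probe, n_points)) |>
    rename(area_complex = "area")
  comp <- function(sel, label) {
    residue_sasa(sasa(part[sel, ], probe, n_points)) |>
      mutate(component = label)
  }
  alone <- bind_rows(comp(in_a, "A"), comp(!in_a, "B"))
  res <- alone |>
    left_join(complex_sasa, by = c("chain", "residue_number",
                                   "residue_name")) |>
    mutate(bsa = .data$area - .data$area_complex) |>
    select("component", "chain", "residue_number", "residue_name",
           "bsa") |>
    arrange(dplyr::desc(.data$bsa))
  list(residues = res, total_interface_area = sum(res$bsa) / 2)
}

#' Relative (fractional) solvent accessibility per residue
#'
#' Residue SASA divided by its theoretical maximum accessible area
#' (Tien et al. 2013). Values can exceed 1 for distorted or terminal
#' residues and are not clipped. Residues with no reference value
#' (non-standard names, nucleotides) get `NA` with a warning.
#'
#' @param model Single-model protein coordinate tibble.
#' @param probe,n_points As in [sasa()].
#' @return Tibble `chain`, `residue_number`, `residue_name`, `area`,
#'   `rel_sasa`.
#' @export
relative_sasa <- function(model, probe = 1.4, n_points = 960L) {
  res <- residue_sasa(sasa(model, probe, n_points))
  ref <- unname(max_asa_tien2013[res$residue_name])
  if (anyNA(ref)) {
    warn(sprintf("no reference max ASA for residue type(s): %s",
                 paste(unique(res$residue_name[is.na(ref)]), collapse = ", ")))
  }
  res$rel_sasa <- res$area / ref
  res
}
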