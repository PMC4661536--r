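# Planar ring systems and stacking-relevant groups, by residue type.
# Purine bases are treated as one fused ring system; centers are
# unweighted centers of geometry of the defining atoms.
ring_defs <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  A = list(ring = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")),
  G = list(ring = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")),
  C = list(ring = c("N1", "C2", "N3", "C4", "C5", "C6")),
  U = list(ring = c("N1", "C2", "N3", "C4", "C5", "C6"))
)

phosphate_atoms <- c("P", "O1P", "O2P", "OP1", "OP2")
ribose_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")

# collect stacking groups (rings, phosphates, riboses, lone aliphatic
# CH carbons) for the atoms selected by `sel`
stack_groups <- function(model, sel) {
  sub <- model[sel, ]
  out <- list()
  for (r in unique(paste(sub$chain, sub$residue_number))) {
    rows <- sub[paste(sub$chain, sub$residue_number) == r, ]
    rn <- rows$residue_name[1]
    label <- paste(rows$chain[1], rows$residue_number[1], rn, sep = ":")
    ring_atoms_used <- character()
    defs <- ring_defs[[rn]]
    if (!is.null(defs)) {
      for (nm in names(defs)) {
        atoms <- rows[rows$atom_name %in% defs[[nm]], ]
        if (nrow(atoms) >= 4L) {
          out[[length(out) + 1L]] <- list(
            id = paste(label, nm, sep = ":"), kind = "ring",
            xyz = coords_matrix(atoms))
          ring_atoms_used <- c(ring_atoms_used, defs[[nm]])
        }
      }
    }
    ph <- rows[rows$atom_name %in% phosphate_atoms, ]
    if (nrow(ph) >= 2L) {
      out[[length(out) + 1L]] <- list(
        id = paste(label, "phosphate", sep = ":"), kind = "anion",
        xyz = coords_matrix(ph))
    }
    rb <- rows[rows$atom_name %in% ribose_atoms, ]
    if (nrow(rb) >= 4L) {
      out[[length(out) + 1L]] <- list(
        id = paste(label, "ribose", sep = ":"), kind = "ch",
        xyz = coords_matrix(rb))
    }
    # lone aliphatic carbons (outside rings / ribose / phosphate)
    ali <- rows[rows$element == "C" &
                  !rows$atom_name %in% c(ring_atoms_used, ribose_atoms,
                                         phosphate_atoms, "C"), ]
    for (i in seq_len(nrow(ali))) {
      out[[length(out) + 1L]] <- list(
        id = paste(label, ali$atom_name[i], sep = ":"), kind = "ch",
        xyz = coords_matrix(ali[i, , drop = FALSE]))
    }
  }
  out
}

centroid <- function(xyz) colMeans(xyz)

plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  svd(c0)$v[, 3]
}

#' Detect stacking interactions across an interface
#'
#' Geometric detection of pi-pi, CH-pi and anion-pi contacts between
#' two atom groups, using unweighted centers of geometry throughout.
#' A pi-pi contact requires two ring systems with centroids within
#' `d_pipi`; it is classified by the interplanar angle (best-fit
#' plane normals, folded to 0-90 degrees): at most 30 degrees is the
#' parallel family — split into `pi_pi_parallel` and
#' `pi_pi_displaced` at a lateral centroid offset of 1.0 Angstrom —
#' and 60 degrees or more is `pi_pi_tshaped`; intermediate
#' inclinations are not reported. The lateral offset is the component
#' of the centroid-centroid vector in the mean ring plane. A CH-pi
#' contact pairs an aliphatic carbon group (a ribose ring or a single
#' side-chain carbon) with an aromatic ring within `d_chpi`; an
#' anion-pi contact pairs a phosphate group with a ring within
#' `d_anpi`.
#'
#' @param model Single-model coordinate tibble.
#' @param group_a,group_b Interface partition.
#' @param d_pipi,d_chpi,d_anpi Centroid distance cutoffs (Angstrom;
#'   defaults 5.5, 4.5, 5.0).
#' @param offset_parallel Lateral offset separating face-to-face from
#'   displaced stacks (default 1.0 Angstrom).
#' @return Tibble `group_a`, `group_b`, `kind`, `centroid_distance`,
#'   `interplanar_angle`, `lateral_offset` (angle and offset `NA`
#'   for CH-pi and anion-pi).
#' @export
detect_stacking <- function(model, group_a, group_b, d_pipi = 5.5,
                            d_chpi = 4.5, d_anpi = 5.0,
                            offset_parallel = 1.0) {
  in_a <- resolve_selection(model, group_a)
  in_b <- resolve_selection(model, group_b)
  if (any(in_a & in_b)) abort("partition groups overlap")
  ga <- stack_groups(model, in_a)
  gb <- stack_groups(model, in_b)
  res <- list()
  for (a in ga) {
    for (b in gb) {
      ca <- centroid(a$xyz); cb <- centroid(b$xyz)
      dist <- sqrt(sum((ca - cb)^2))
      if (a$kind == "ring" && b$kind == "ring") {
        if (dist > d_pipi) next
        na_ <- plane_normal(a$xyz); nb_ <- plane_normal(b$xyz)
        if (sum(na_ * nb_) < 0) nb_ <- -nb_
        ang <- angle_deg(na_, c(0, 0, 0), nb_)
        ang <- min(ang, 180 - ang)
        nm <- na_ + nb_; nm <- nm / sqrt(sum(nm^2))
        v <- cb - ca
        offset <- sqrt(sum((v - sum(v * nm) * nm)^2))
        kind <- if (ang <= 30) {
          if (offset > offset_parallel) "pi_pi_displaced" else "pi_pi_parallel"
        } else if (ang >= 60) "pi_pi_tshaped" else NA_character_
        if (is.na(kind)) next
        res[[length(res) + 1L]] <- tibble(
          group_a = a$id, group_b = b$id, kind = kind,
          centroid_distance = dist, interplanar_angle = ang,
          lateral_offset = offset)
      } else if (xor(a$kind == "ring", b$kind == "ring")) {
        other <- if (a$kind == "ring") b else a
        cutoff <- switch(other$kind, ch = d_chpi, anion = d_anpi)
        if (dist > cutoff) next
        res[[length(res) + 1L]] <- tibble(
          group_a = a$id, group_b = b$id,
          kind = if (other$kind == "ch") "ch_pi" else "anion_pi",
          centroid_distance = dist, interplanar_angle = NA_real_,
          lateral_offset = NA_real_)
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble(group_a = character(), group_b = character(),
                  kind = character(), centroid_distance = double(),
                  interplanar_angle = double(), lateral_offset = double()))
  }
  list_rbind(res)
}
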