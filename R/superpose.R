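#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD between
#' selected atoms of a mobile and a reference coordinate set, via SVD
#' of the 3x3 cross-covariance matrix with the usual reflection
#' correction. Atoms are paired by (chain, residue number, atom name).
#'
#' @param mobile,reference Single-model coordinate tibbles.
#' @param selection Atoms to superpose on: `NULL` (all), a character
#'   vector of atom names, or a predicate function. See
#'   [sel_backbone()].
#' @return A `superposition` list: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (Angstrom, over the selection) and `n_atoms`.
#'   Apply with [apply_superposition()].
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  ms <- mobile[resolve_selection(mobile, selection), ]
  rs <- reference[resolve_selection(reference, selection), ]
  key <- function(tb) paste(tb$chain, tb$residue_number, tb$atom_name)
  common <- intersect(key(ms), key(rs))
  if (length(common) < 3L) abort("need >= 3 paired atoms to superpose")
  p <- coords_matrix(ms[match(common, key(ms)), ])
  q <- coords_matrix(rs[match(common, key(rs)), ])
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2, pc); q0 <- sweep(q, 2, qc)
  sv_p <- svd(p0)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1)) {
    abort("selected atoms are collinear; superposition is degenerate")
  }
  h <- crossprod(p0, q0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- p0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q0)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(qc - pc %*% t(rot)),
                 rmsd = rmsd, n_atoms = length(common)),
            class = "superposition")
}

#' Apply a superposition transform to a coordinate tibble
#'
#' @param coords Coordinate tibble.
#' @param sp A `superposition` from [superpose()].
#' @return The transformed tibble.
#' @export
apply_superposition <- function(coords, sp) {
  xyz <- coords_matrix(coords) %*% t(sp$rotation)
  xyz <- sweep(xyz, 2, sp$translation, "+")
  coords$x <- xyz[, 1]; coords$y <- xyz[, 2]; coords$z <- xyz[, 3]
  coords
}

rmsd_between <- function(a, b, selection = NULL) {
  superpose(a, b, selection)$rmsd
}

#' Ensemble RMSD statistics
#'
#' Mean and SD of superposed RMSDs across a multi-model ensemble,
#' either over all model pairs (`pairwise_mean`, the default) or to
#' the iteratively computed mean structure (`to_mean_structure`).
#' Which convention a published number uses is often unstated, so
#' both are exposed and the mode is recorded in the output.
#'
#' @param ensemble Coordinate tibble with a `model` column (>= 2
#'   models).
#' @param selection Atom selection (see [superpose()]).
#' @param mode `"pairwise_mean"` or `"to_mean_structure"`.
#' @return A tibble: `mode`, `mean`, `sd`, `n_models`, `n_atoms`.
#' @export
ensemble_rmsd <- function(ensemble, selection = NULL,
                          mode = c("pairwise_mean", "to_mean_structure")) {
  mode <- match.arg(mode)
  models <- split_models(ensemble)
  if (length(models) < 2L) abort("need >= 2 models")
  if (!any(resolve_selection(models[[1]], selection))) {
    abort("empty atom selection")
  }
  if (mode == "pairwise_mean") {
    pairs <- utils::combn(length(models), 2)
    vals <- map_dbl(seq_len(ncol(pairs)), function(i) {
      rmsd_between(models[[pairs[1, i]]], models[[pairs[2, i]]], selection)
    })
  } else {
    aligned <- align_to_mean(models, selection)
    mean_xyz <- mean_coords(aligned)
    vals <- map_dbl(aligned, function(m) {
      sel <- resolve_selection(m, selection)
      sqrt(mean(rowSums((coords_matrix(m)[sel, , drop = FALSE] -
                           mean_xyz[sel, , drop = FALSE])^2)))
    })
  }
  tibble(mode = mode, mean = mean(vals),
         sd = if (length(vals) > 1L) sd(vals) else 0,
         n_models = length(models),
         n_atoms = sum(resolve_selection(models[[1]], selection)))
}

# superpose all models onto their evolving mean structure until the
# mean stabilises (or 10 rounds)
align_to_mean <- function(models, selection = NULL, max_iter = 10L) {
  aligned <- map(models, function(m) {
    apply_superposition(m, superpose(m, models[[1]], selection))
  })
  for (it in seq_len(max_iter)) {
    mx <- mean_coords(aligned)
    ref <- aligned[[1]]
    ref$x <- mx[, 1]; ref$y <- mx[, 2]; ref$z <- mx[, 3]
    new <- map(aligned, function(m) {
      apply_superposition(m, superpose(m, ref, selection))
    })
    shift <- max(abs(mean_coords(new) - mx))
    aligned <- new
    if (shift < 1e-8) break
  }
  aligned
}

mean_coords <- function(models) {
  Reduce(`+`, map(models, coords_matrix)) / length(models)
}

#' Detect the ordered residue range of an ensemble
#'
#' Iterative procedure: superpose all models globally on the backbone
#' of the currently retained residues, compute each residue's mean
#' positional spread about the ensemble-mean coordinates, drop
#' residues whose spread exceeds `cutoff`, and repeat until the
#' retained set is stable (or `max_iter` rounds). Returns the maximal
#' contiguous residue ranges that survive — the "ordered core" used
#' for quoting converged-ensemble RMSDs.
#'
#' @param ensemble Multi-model coordinate tibble.
#' @param cutoff Spread cutoff in Angstrom (default 1.5).
#' @param selection Atom selection used for fitting and spread
#'   (default backbone N, CA, C).
#' @param max_iter Iteration cap (default 20).
#' @return A tibble of ranges (`start`, `end`) plus a `spread`
#'   attribute with the final per-residue spread profile.
#' @export
find_ordered_range <- function(ensemble, cutoff = 1.5,
                               selection = sel_backbone(),
                               max_iter = 20L) {
  models <- split_models(ensemble)
  if (length(models) < 2L) abort("need >= 2 models")
  residues <- unique(models[[1]]$residue_number)
  retained <- residues
  spread_tbl <- NULL
  for (it in seq_len(max_iter)) {
    fit_sel <- function(tb) {
      resolve_selection(tb, selection) & tb$residue_number %in% retained
    }
    aligned <- align_to_mean(models, fit_sel)
    mx <- mean_coords(aligned)
    sel <- resolve_selection(aligned[[1]], selection)
    dev2 <- Reduce(`+`, map(aligned, function(m) {
      rowSums((coords_matrix(m) - mx)^2)
    })) / length(aligned)
    spread_tbl <- tibble(residue_number = aligned[[1]]$residue_number[sel],
                         dev2 = dev2[sel]) |>
      group_by(.data$residue_number) |>
      summarise(spread = sqrt(mean(.data$dev2)), .groups = "drop")
    new_retained <- spread_tbl$residue_number[spread_tbl$spread <= cutoff]
    if (length(new_retained) == 0L) {
      abort("all residues exceed the spread cutoff; try a larger cutoff")
    }
    if (setequal(new_retained, retained)) break
    retained <- new_retained
  }
  runs <- contiguous_ranges(sort(retained))
  structure(runs, spread = spread_tbl)
}

contiguous_ranges <- function(x) {
  if (length(x) == 0L) return(tibble(start = integer(), end = integer()))
  brk <- c(FALSE, diff(x) != 1L)
  grp <- cumsum(brk)
  tibble(residue = x, grp = grp) |>
    group_by(.data$grp) |>
    summarise(start = min(.data$residue), end = max(.data$residue),
              .groups = "drop") |>
    select("start", "end")
}

#' Per-residue root-mean-square fluctuation
#'
#' For a trajectory whose frames are already superposed on a common
#' reference selection, computes for each atom the RMS deviation from
#' its time-mean position, then averages over the selected atoms of
#' each residue.
#'
#' @param traj Multi-model coordinate tibble (model order = time).
#' @param selection Atom selection (default backbone N, CA, C).
#' @return A tibble `residue_number`, `rmsf` (Angstrom).
#' @export
per_residue_rmsf <- function(traj, selection = sel_backbone()) {
  frames <- split_models(traj)
  if (length(frames) < 2L) abort("need >= 2 frames")
  mx <- mean_coords(frames)
  dev2 <- Reduce(`+`, map(frames, function(f) {
    rowSums((coords_matrix(f) - mx)^2)
  })) / length(frames)
  sel <- resolve_selection(frames[[1]], selection)
  tibble(residue_number = frames[[1]]$residue_number[sel],
         atom_rmsf = sqrt(dev2[sel])) |>
    group_by(.data$residue_number) |>
    summarise(rmsf = mean(.data$atom_rmsf), .groups = "drop")
}

#' Plot a per-residue RMSF profile
#' @param profile Output of [per_residue_rmsf()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$residue_number, .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
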