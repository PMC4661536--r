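#' Generate a free/bound shift-table pair with planted hotspots
#'
#' Emulates an HSQC titration endpoint: free-state amide shifts drawn
#' from plausible ranges (1H 7.5-9.5 ppm, 15N 105-130 ppm — value
#' placeholders, not predictions), and a bound state equal to the
#' free state plus a planted perturbation on the hotspot residues
#' plus Gaussian noise everywhere. The planted residue set is
#' returned as ground truth; every output is bit-reproducible from
#' `seed`.
#'
#' Defaults mirror a ~100-residue RRM construct with two contact
#' clusters and effect sizes well above the noise floor.
#'
#' @param seed Integer seed.
#' @param n_residues Number of residues.
#' @param first_residue Residue number of the first residue.
#' @param hotspots List of `c(start, end)` residue ranges to perturb;
#'   overlapping ranges are merged with a warning.
#' @param effect_h,effect_n Planted shift change (ppm) on hotspot
#'   residues for 1H and 15N.
#' @param noise_sd_h,noise_sd_n Gaussian noise SD (ppm) applied to
#'   every bound-state shift.
#' @return List `free`, `bound` (shift tables) and `truth` (sorted
#'   hotspot residue numbers).
#' @export
make_shift_pair <- function(seed = 1L, n_residues = 97L,
                            first_residue = 231L,
                            hotspots = list(c(262L, 267L), c(270L, 275L)),
                            effect_h = 0.2, effect_n = 1.0,
                            noise_sd_h = 0.01, noise_sd_n = 0.05) {
  residues <- first_residue + seq_len(n_residues) - 1L
  rngs <- map(hotspots, function(h) seq(h[[1]], h[[2]]))
  if (length(rngs) > 1L) {
    overlap <- any(duplicated(unlist(rngs)))
    if (overlap) warn("overlapping hotspot ranges merged")
  }
  hot <- sort(unique(unlist(rngs)))
  if (!all(hot %in% residues)) abort("hotspot ranges outside residue range")
  set.seed(seed)
  h_free <- runif(n_residues, 7.5, 9.5)
  n_free <- runif(n_residues, 105, 130)
  is_hot <- residues %in% hot
  h_bound <- h_free + effect_h * is_hot + rnorm(n_residues, 0, noise_sd_h)
  n_bound <- n_free + effect_n * is_hot + rnorm(n_residues, 0, noise_sd_n)
  mk <- function(h, nn) {
    tibble(residue_number = rep(residues, 2),
           residue_type = "ALA",
           atom_name = rep(c("H", "N"), each = n_residues),
           shift = c(h, nn)) |>
      arrange(.data$residue_number, .data$atom_name)
  }
  list(free = mk(h_free, n_free), bound = mk(h_bound, n_bound),
       truth = hot)
}

# idealised extended backbone trace (N, CA, C) for residue i of a
# synthetic chain; planar but non-collinear so superposition is
# well-posed
ideal_backbone <- function(residues, chain = "A") {
  map(residues, function(i) {
    tibble(chain = chain, residue_number = i, residue_name = "ALA",
           atom_name = c("N", "CA", "C"), element = c("N", "C", "C"),
           x = 3.8 * i + c(-1.2, 0, 1.2),
           y = c(0.8, 0, 0.8),
           z = 0)
  }) |> list_rbind()
}

#' Generate a synthetic multi-model ensemble with a rigid core
#'
#' Builds an idealised backbone trace and perturbs each model's atoms
#' with per-residue displacements whose SD follows a step profile: a
#' small `sigma_core` inside `core_range` and a larger `sigma_tail`
#' outside, emulating an ordered domain with disordered tails.
#' `jitter = "gaussian"` draws i.i.d. normal displacements;
#' `jitter = "deterministic"` displaces each atom by exactly its
#' sigma along +x/-x in alternating models, making the per-residue
#' RMSF equal the sigma profile exactly.
#'
#' @param seed Integer seed.
#' @param n_models Number of models (>= 2).
#' @param n_residues Chain length.
#' @param core_range `c(start, end)` residues of the rigid core.
#' @param sigma_core,sigma_tail Displacement SD (Angstrom).
#' @param jitter `"gaussian"` or `"deterministic"`.
#' @return List `ensemble` (coordinate tibble with `model` column)
#'   and `truth` (tibble `residue_number`, `sigma`).
#' @export
make_ensemble <- function(seed = 1L, n_models = 20L, n_residues = 60L,
                          core_range = c(11L, 50L), sigma_core = 0.1,
                          sigma_tail = 2.0,
                          jitter = c("gaussian", "deterministic")) {
  jitter <- match.arg(jitter)
  stopifnot(n_models >= 2, sigma_core >= 0, sigma_tail >= 0)
  residues <- seq_len(n_residues)
  base <- ideal_backbone(residues)
  sigma <- ifelse(residues >= core_range[[1]] & residues <= core_range[[2]],
                  sigma_core, sigma_tail)
  sig_atom <- sigma[match(base$residue_number, residues)]
  set.seed(seed)
  ens <- map(seq_len(n_models), function(m) {
    tb <- base
    if (jitter == "gaussian") {
      tb$x <- tb$x + rnorm(nrow(tb), 0, sig_atom)
      tb$y <- tb$y + rnorm(nrow(tb), 0, sig_atom)
      tb$z <- tb$z + rnorm(nrow(tb), 0, sig_atom)
    } else {
      tb$x <- tb$x + sig_atom * if (m %% 2 == 0) 1 else -1
    }
    tb$model <- m
    tb[, c("model", setdiff(names(tb), "model"))]
  }) |> list_rbind()
  list(ensemble = ens,
       truth = tibble(residue_number = residues, sigma = sigma))
}

#' Generate a trajectory with hydrogen bonds of prescribed occupancy
#'
#' Builds an interface toy — one lysine N-zeta donor (chain A) facing
#' one uridine phosphate-oxygen acceptor (chain B) per requested
#' bond, each pair well separated from the others — and toggles each
#' pair between bonded (donor-acceptor 2.9 Angstrom, D-H...A 180
#' degrees) and broken (6 Angstrom) geometry frame by frame. Each
#' bond is present in exactly `round(occupancy * n_frames)` frames
#' (schedule drawn once from `seed`), unless explicit logical
#' `schedules` are given.
#'
#' @param occupancies Per-bond target occupancies in `[0, 1]`.
#' @param n_frames Number of frames (>= 2).
#' @param schedules Optional list of logical vectors (length
#'   `n_frames`) overriding the drawn schedules.
#' @param seed Integer seed.
#' @return List `traj` (coordinate tibble with `model` column),
#'   `truth` (list of logical schedules), `group_a`/`group_b`
#'   (partition predicates for the analysis functions).
#' @export
make_hbond_trajectory <- function(occupancies = c(1, 0.6),
                                  n_frames = 10L, schedules = NULL,
                                  seed = 1L) {
  stopifnot(all(occupancies >= 0), all(occupancies <= 1), n_frames >= 2)
  n_bonds <- length(occupancies)
  set.seed(seed)
  if (is.null(schedules)) {
    schedules <- map(occupancies, function(o) {
      k <- round(o * n_frames)
      on <- rep(FALSE, n_frames)
      on[sample.int(n_frames, k)] <- TRUE
      on
    })
  }
  stopifnot(length(schedules) == n_bonds,
            all(map_int(schedules, length) == n_frames))
  frames <- map(seq_len(n_frames), function(f) {
    map(seq_len(n_bonds), function(b) {
      y <- 50 * b
      d <- if (schedules[[b]][f]) 2.9 else 6.0
      bind_rows(
        tibble(chain = "A", residue_number = b, residue_name = "LYS",
               atom_name = c("NZ", "HZ1"), element = c("N", "H"),
               x = c(0, 1.0), y = y, z = 0),
        tibble(chain = "B", residue_number = b, residue_name = "U",
               atom_name = "O1P", element = "O", x = d, y = y, z = 0))
    }) |> list_rbind() |> mutate(model = f)
  }) |> list_rbind()
  list(traj = frames[, c("model", setdiff(names(frames), "model"))],
       truth = schedules,
       group_a = function(tb) tb$chain == "A",
       group_b = function(tb) tb$chain == "B")
}

regular_polygon <- function(n, radius) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(th), radius * sin(th), 0)
}

rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
         byrow = TRUE)
}

#' Build an idealised stacking fixture with exact geometry
#'
#' Places a tyrosine-like regular hexagon ring (chain A, residue 274)
#' and a partner group (chain B, residue 12) at an exact centroid
#' distance, interplanar angle and lateral offset, so that
#' [detect_stacking()] must report those values back. For `pi_pi` the
#' partner is a cytosine-like hexagon and the two rings are tilted by
#' half the angle each about the offset axis, which makes the
#' detector's mean-plane offset computation exact. For `ch_pi` the
#' partner is a ribose-like pentagon; for `anion_pi` a phosphate
#' group whose centroid sits at the requested distance. Rings are
#' idealised regular polygons (1.39 Angstrom bond length), not
#' residue templates, so centroids are closed-form.
#'
#' @param kind `"pi_pi"`, `"ch_pi"` or `"anion_pi"`.
#' @param distance Centroid-centroid distance (Angstrom).
#' @param angle Interplanar angle in degrees (pi_pi only).
#' @param offset Lateral centroid offset (Angstrom, pi_pi only; must
#'   not exceed `distance`).
#' @return A single-model coordinate tibble; partition with chain A
#'   vs chain B.
#' @export
make_stack_fixture <- function(kind = c("pi_pi", "ch_pi", "anion_pi"),
                               distance = 3.4, angle = 0, offset = 0) {
  kind <- match.arg(kind)
  stopifnot(distance > 0, offset >= 0, offset <= distance)
  hex <- regular_polygon(6, 1.39)
  ring_a_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  mk <- function(xyz, chain, resno, resname, atoms, elements) {
    tibble(chain = chain, residue_number = resno, residue_name = resname,
           atom_name = atoms, element = elements,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  if (kind == "pi_pi") {
    a_xyz <- hex %*% t(rot_x(-angle / 2))
    rise <- sqrt(distance^2 - offset^2)
    b_xyz <- sweep(hex %*% t(rot_x(angle / 2)), 2, c(offset, 0, rise), "+")
    b <- mk(b_xyz, "B", 12L, "C",
            c("N1", "C2", "N3", "C4", "C5", "C6"),
            c("N", "C", "N", "C", "C", "C"))
  } else if (kind == "ch_pi") {
    a_xyz <- hex
    pent <- sweep(regular_polygon(5, 1.2), 2, c(0, 0, distance), "+")
    b <- mk(pent, "B", 12L, "C",
            c("C1'", "C2'", "C3'", "C4'", "O4'"),
            c("C", "C", "C", "C", "O"))
  } else {
    a_xyz <- hex
    ph <- rbind(c(0, 0, distance + 0.5),
                c(1.2, 0, distance - 0.25),
                c(-1.2, 0, distance - 0.25))
    b <- mk(ph, "B", 12L, "C", c("P", "O1P", "O2P"), c("P", "O", "O"))
  }
  a <- mk(a_xyz, "A", 274L, "TYR", ring_a_names, rep("C", 6))
  bind_rows(a, b)
}
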