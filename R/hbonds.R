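the_template_cache <- new.env(parent = emptyenv())

#' Hydrogen-bond donor/acceptor templates
#'
#' Per-residue donor and acceptor atom definitions for the 20 amino
#' acids and the 4 ribonucleotides (including the phosphate O1P/O2P
#' [OP1/OP2], ribose O2'/O3'/O4'/O5' and base N/O atoms), shipped as
#' a plain-text table under `extdata`. Donors list their covalent
#' hydrogen names so that an angle criterion can be applied when
#' hydrogens are present in the model.
#'
#' @return Tibble `residue_name`, `atom_name`, `role`
#'   (`donor`/`acceptor`/`both`), `hydrogens` (comma-separated).
#' @export
hbond_templates <- function() {
  if (is.null(the_template_cache$tbl)) {
    path <- system.file("extdata", "hbond_templates.tsv",
                        package = "rrmbind", mustWork = TRUE)
    the_template_cache$tbl <- as_tibble(
      utils::read.delim(path, na.strings = NULL,
                        colClasses = "character"))
  }
  the_template_cache$tbl
}

atom_id <- function(tb) {
  paste(tb$chain, tb$residue_number, tb$residue_name, tb$atom_name,
        sep = ":")
}

#' Detect hydrogen bonds across an interface
#'
#' Geometric criteria: a donor-acceptor pair is a hydrogen bond when
#' the donor-acceptor distance is at most `d_max` and — if the donor's
#' hydrogen(s) are present in the model — the D-H...A angle of at
#' least one hydrogen is `theta_min` or more (the best hydrogen is
#' reported). Without hydrogens the criterion is distance-only, as is
#' common for heavy-atom-only models. Only bonds crossing the
#' partition (donor in one group, acceptor in the other) are
#' reported. Donor/acceptor typing comes from [hbond_templates()];
#' atoms of residue types absent from the templates are skipped with
#' a warning.
#'
#' @param model Single-model coordinate tibble.
#' @param group_a,group_b Disjoint atom groups (predicates, atom-name
#'   vectors or logical vectors).
#' @param d_max Donor-acceptor distance cutoff (Angstrom, default
#'   3.5).
#' @param theta_min D-H...A angle cutoff (degrees, default 120).
#' @return Tibble with `donor`, `hydrogen`, `acceptor` (atom ids
#'   `chain:residue:resname:atom`), `distance_da` and `angle_dha`
#'   (`NA` when no hydrogen present).
#' @export
detect_hbonds <- function(model, group_a, group_b,
                          d_max = 3.5, theta_min = 120) {
  in_a <- resolve_selection(model, group_a)
  in_b <- resolve_selection(model, group_b)
  if (any(in_a & in_b)) abort("partition groups overlap")
  tpl <- hbond_templates()
  known <- unique(tpl$residue_name)
  unknown <- setdiff(unique(model$residue_name), known)
  if (length(unknown)) {
    warn(sprintf("no donor/acceptor template for residue type(s): %s; atoms skipped",
                 paste(unknown, collapse = ", ")))
  }
  model$.row <- seq_len(nrow(model))
  typed <- model |>
    inner_join(tpl, by = c("residue_name", "atom_name"),
               relationship = "many-to-many")
  donors <- typed[typed$role %in% c("donor", "both"), ]
  acceptors <- typed[typed$role %in% c("acceptor", "both"), ]
  one_way <- function(dn, ac) {
    if (nrow(dn) == 0L || nrow(ac) == 0L) return(NULL)
    dmat <- pair_dists(coords_matrix(dn), coords_matrix(ac))
    hits <- which(dmat <= d_max, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(NULL)
    map(seq_len(nrow(hits)), function(k) {
      d <- dn[hits[k, 1], ]; a <- ac[hits[k, 2], ]
      hyds <- strsplit(d$hydrogens %||% "", ",")[[1]]
      hyds <- hyds[nzchar(hyds)]
      hrows <- model[model$chain == d$chain &
                       model$residue_number == d$residue_number &
                       model$atom_name %in% hyds, ]
      ang <- NA_real_; hname <- NA_character_
      if (nrow(hrows) > 0L) {
        angles <- map_dbl(seq_len(nrow(hrows)), function(hi) {
          angle_deg(c(d$x, d$y, d$z),
                    c(hrows$x[hi], hrows$y[hi], hrows$z[hi]),
                    c(a$x, a$y, a$z))
        })
        best <- which.max(angles)
        ang <- angles[best]; hname <- atom_id(hrows[best, ])
        if (ang < theta_min) return(NULL)
      }
      tibble(donor = atom_id(d), hydrogen = hname, acceptor = atom_id(a),
             distance_da = dmat[hits[k, 1], hits[k, 2]], angle_dha = ang)
    }) |> list_rbind()
  }
  res <- bind_rows(
    one_way(donors[in_a[donors$.row], ], acceptors[in_b[acceptors$.row], ]),
    one_way(donors[in_b[donors$.row], ], acceptors[in_a[acceptors$.row], ]))
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(donor = character(), hydrogen = character(),
                  acceptor = character(), distance_da = double(),
                  angle_dha = double()))
  }
  arrange(res, .data$donor, .data$acceptor)
}

# angle at vertex `h` between points d-h-a, in degrees
angle_deg <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Runs [detect_hbonds()] on every frame and tabulates, per candidate
#' bond (keyed by donor and acceptor atom), the fraction of frames in
#' which it is present, plus the mean number of interface bonds per
#' frame within consecutive frame intervals — the quantity behind
#' "n redundant bonds were always maintained" statements.
#'
#' @param traj Multi-model coordinate tibble (frames in time order).
#' @param group_a,group_b Interface partition, as in
#'   [detect_hbonds()].
#' @param d_max,theta_min Criteria passed to [detect_hbonds()].
#' @param interval_frames Frames per interval for the per-interval
#'   counts (default: all frames in one interval).
#' @return A list: `occupancy` (tibble `donor`, `acceptor`,
#'   `n_frames_present`, `occupancy`), `intervals` (tibble
#'   `interval`, `first_frame`, `last_frame`, `mean_bonds`,
#'   `min_bonds`), `n_frames`.
#' @export
hbond_occupancy <- function(traj, group_a, group_b, d_max = 3.5,
                            theta_min = 120, interval_frames = NULL) {
  frames <- split_models(traj)
  if (length(frames) < 2L) abort("need >= 2 frames")
  per_frame <- map(frames, function(f) {
    suppressWarnings(detect_hbonds(f, group_a, group_b, d_max, theta_min))
  })
  n <- length(frames)
  all_bonds <- bind_rows(imap(per_frame, function(b, i) {
    if (nrow(b) == 0L) return(NULL)
    b$frame <- as.integer(i)
    b
  }))
  occ <- if (nrow(all_bonds) == 0L) {
    tibble(donor = character(), acceptor = character(),
           n_frames_present = integer(), occupancy = double())
  } else {
    all_bonds |>
      group_by(.data$donor, .data$acceptor) |>
      summarise(n_frames_present = dplyr::n_distinct(.data$frame),
                .groups = "drop") |>
      mutate(occupancy = .data$n_frames_present / n)
  }
  iv <- interval_frames %||% n
  counts <- map_int(seq_len(n), function(i) {
    if (nrow(all_bonds) == 0L) 0L else sum(all_bonds$frame == i)
  })
  grp <- ceiling(seq_len(n) / iv)
  intervals <- tibble(frame = seq_len(n), grp = grp, count = counts) |>
    group_by(.data$grp) |>
    summarise(first_frame = min(.data$frame),
              last_frame = max(.data$frame),
              mean_bonds = mean(.data$count),
              min_bonds = min(.data$count), .groups = "drop") |>
    rename(interval = "grp")
  list(occupancy = occ, intervals = intervals, n_frames = n)
}

#' Interface residues by buried surface area
#'
#' Residues whose buried surface area upon complex formation exceeds
#' a threshold, sorted by decreasing BSA.
#'
#' @inheritParams buried_surface_area
#' @param bsa_threshold Minimum BSA (Angstrom^2, default 0).
#' @return Tibble `component`, `chain`, `residue_number`,
#'   `residue_name`, `bsa`.
#' @export
interface_residues <- function(complex_model, group_a, group_b,
                               bsa_threshold = 0, probe = 1.4,
                               n_points = 960L) {
  bsa <- buried_surface_area(complex_model, group_a, group_b,
                             probe, n_points)
  filter(bsa$residues, .data$bsa > bsa_threshold)
}
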