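#' Read a chemical-shift table
#'
#' Reads per-residue, per-atom chemical shifts for one state (free or
#' bound) from either a tab-separated file or a minimal NMR-STAR v3
#' `Atom_chem_shift` loop.
#'
#' The TSV dialect requires a header line with columns
#' `residue_number`, `residue_type`, `atom_name`, `shift`; lines
#' starting with `#` are comments. The NMR-STAR reader covers only the
#' `_Atom_chem_shift` loop (tags `Comp_index_ID`, `Comp_ID`, `Atom_ID`,
#' `Val`), the subset needed to ingest deposited backbone assignments.
#'
#' @param path Path to the shift file.
#' @param format `"tsv"` (default) or `"nmrstar"`.
#' @param state_label,construct_label Optional labels stored as
#'   attributes on the returned table.
#'
#' @return A tibble with columns `residue_number` (integer),
#'   `residue_type`, `atom_name`, `shift` (ppm), one row per
#'   (residue, atom). Duplicate (residue, atom) keys are a hard error.
#' @export
read_shift_table <- function(path, format = c("tsv", "nmrstar"),
                             state_label = NULL, construct_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("shift file not found: ", path))
  tbl <- switch(format,
    tsv = read_shift_tsv(path),
    nmrstar = read_shift_nmrstar(path)
  )
  if (nrow(tbl) == 0L) abort(paste0("empty shift table: ", path))
  dup <- tbl |>
    dplyr::count(.data$residue_number, .data$atom_name) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf(
      "duplicate (residue, atom) key(s) in %s: %s", path,
      paste(sprintf("(%d, %s)", dup$residue_number, dup$atom_name),
            collapse = ", ")
    ))
  }
  attr(tbl, "state_label") <- state_label
  attr(tbl, "construct_label") <- construct_label
  tbl
}

read_shift_tsv <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) < 1L) abort(paste0("empty shift table: ", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("residue_number", "residue_type", "atom_name", "shift")
  idx <- match(need, trimws(header))
  if (anyNA(idx)) {
    abort(sprintf("missing column(s) in %s: %s", path,
                  paste(need[is.na(idx)], collapse = ", ")))
  }
  body <- lines[-1]
  body_lineno <- lineno[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_one <- function(f) {
    if (length(f) < max(idx)) return(NULL)
    resno <- suppressWarnings(as.integer(f[[idx[1]]]))
    val <- suppressWarnings(as.numeric(f[[idx[4]]]))
    if (is.na(resno) || !is.finite(val)) return(NULL)
    tibble(residue_number = resno,
           residue_type = trimws(f[[idx[2]]]),
           atom_name = trimws(f[[idx[3]]]),
           shift = val)
  }
  rows <- map(fields, parse_one)
  bad <- map_lgl(rows, is.null)
  if (any(bad)) {
    warn(sprintf("%s: skipped unparseable line(s) %s", path,
                 paste(body_lineno[bad], collapse = ", ")))
  }
  list_rbind(rows[!bad])
}

# Minimal NMR-STAR v3 reader: only the Atom_chem_shift loop, which is
# all that backbone CSP analysis needs from a BMRB deposition.
read_shift_nmrstar <- function(path) {
  raw <- trimws(readLines(path, warn = FALSE))
  tags <- character()
  data_rows <- list()
  in_loop <- FALSE
  collecting <- FALSE
  for (ln in raw) {
    if (ln == "loop_") {
      in_loop <- TRUE; collecting <- FALSE; tags <- character()
      next
    }
    if (!in_loop) next
    if (grepl("^_", ln)) {
      tags <- c(tags, ln)
      next
    }
    if (ln == "stop_") {
      in_loop <- FALSE; collecting <- FALSE
      next
    }
    if (length(tags) > 0L && !any(grepl("^_Atom_chem_shift\\.", tags))) {
      in_loop <- FALSE   # some other loop; skip its data
      next
    }
    if (ln == "" || grepl("^#", ln)) next
    collecting <- TRUE
    data_rows[[length(data_rows) + 1L]] <- strsplit(ln, "\\s+")[[1]]
    attr(data_rows, "tags") <- tags
  }
  if (length(data_rows) == 0L) {
    abort(paste0("no _Atom_chem_shift loop found in ", path))
  }
  tags <- attr(data_rows, "tags")
  want <- paste0("_Atom_chem_shift.",
                 c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val"))
  idx <- match(want, tags)
  if (anyNA(idx)) {
    abort(sprintf("missing NMR-STAR tag(s) in %s: %s", path,
                  paste(want[is.na(idx)], collapse = ", ")))
  }
  map(data_rows, function(f) {
    tibble(residue_number = as.integer(f[[idx[1]]]),
           residue_type = f[[idx[2]]],
           atom_name = f[[idx[3]]],
           shift = as.numeric(f[[idx[4]]]))
  }) |> list_rbind()
}

#' Compute combined amide chemical shift perturbations
#'
#' For every residue observed (both amide proton and nitrogen) in both
#' the free and bound shift tables, computes the combined perturbation
#'
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 +
#'       (\alpha\,\Delta\delta_N)^2}}
#'
#' where \eqn{\alpha} down-weights the nitrogen shift change to the
#' proton ppm scale. The default \eqn{\alpha = 0.14} is the standard
#' weighting for backbone amides; it is exposed because conventions in
#' the literature vary (0.10-0.20).
#'
#' Residues present in only one state (or missing one of the two
#' atoms) are classed `unobserved` and excluded from the profile mean
#' and standard deviation. The SD is the population SD (denominator
#' `n`), matching how significance tiers are conventionally drawn on
#' CSP histograms.
#'
#' @param free,bound Shift tables as returned by [read_shift_table()].
#' @param n_weight Nitrogen weighting \eqn{\alpha > 0}; default 0.14.
#' @param h_atom,n_atom Atom names of the amide proton and nitrogen.
#'
#' @return A `csp_profile` tibble with columns `residue_number`,
#'   `delta_h`, `delta_n`, `delta_combined` (all ppm) and `class`
#'   (`"none"` until [classify_csp()] is applied, or `"unobserved"`),
#'   with attributes `mean_csp`, `sd_csp`, `n_weight`.
#' @seealso [classify_csp()], [hotspot_clusters()], [make_shift_pair()]
#' @export
compute_csp <- function(free, bound, n_weight = 0.14,
                        h_atom = "H", n_atom = "N") {
  stopifnot(is.numeric(n_weight), n_weight > 0)
  wide <- function(tbl, suffix) {
    tbl |>
      filter(.data$atom_name %in% c(h_atom, n_atom)) |>
      mutate(atom_name = ifelse(.data$atom_name == h_atom, "h", "n")) |>
      select("residue_number", "atom_name", "shift") |>
      tidyr::pivot_wider(names_from = "atom_name", values_from = "shift",
                         names_prefix = paste0(suffix, "_"))
  }
  f <- wide(free, "free")
  b <- wide(bound, "bound")
  all_res <- sort(union(f$residue_number, b$residue_number))
  if (length(all_res) == 0L) abort("no amide H/N entries in the tables")
  prof <- tibble(residue_number = all_res) |>
    left_join(f, by = "residue_number") |>
    left_join(b, by = "residue_number")
  for (col in c("free_h", "free_n", "bound_h", "bound_n")) {
    if (!col %in% names(prof)) prof[[col]] <- NA_real_
  }
  prof <- prof |>
    mutate(
      observed = complete.cases(.data$free_h, .data$free_n,
                                .data$bound_h, .data$bound_n),
      delta_h = ifelse(.data$observed, .data$bound_h - .data$free_h, NA_real_),
      delta_n = ifelse(.data$observed, .data$bound_n - .data$free_n, NA_real_),
      delta_combined = sqrt(.data$delta_h^2 + (n_weight * .data$delta_n)^2),
      class = ifelse(.data$observed, "none", "unobserved")
    ) |>
    select("residue_number", "delta_h", "delta_n", "delta_combined", "class")
  if (!any(prof$class != "unobserved")) {
    abort("no residue observed in both free and bound tables")
  }
  obs <- prof$delta_combined[prof$class != "unobserved"]
  structure(prof,
            class = c("csp_profile", class(prof)),
            mean_csp = mean(obs),
            sd_csp = sqrt(mean((obs - mean(obs))^2)),  # population SD
            n_weight = n_weight)
}

#' Classify CSPs into significance tiers
#'
#' Marks a residue `significant` when its combined CSP strictly exceeds
#' the profile mean plus one (population) standard deviation, and
#' `strong` when it exceeds the mean plus two standard deviations; the
#' strong set is therefore a subset of the significant set. On
#' degenerate profiles (a single observed residue, or zero variance)
#' the SD is 0 and the strict inequality classifies nothing, which
#' avoids false positives.
#'
#' @param profile A `csp_profile` from [compute_csp()].
#' @return The profile with `class` filled in
#'   (`none`/`significant`/`strong`/`unobserved`). Idempotent.
#' @export
classify_csp <- function(profile) {
  m <- attr(profile, "mean_csp")
  s <- attr(profile, "sd_csp")
  if (is.null(m) || is.null(s)) abort("profile lacks mean/SD; use compute_csp()")
  if (!is.finite(s)) s <- 0
  old <- profile$class
  profile$class <- dplyr::case_when(
    old == "unobserved" ~ "unobserved",
    profile$delta_combined > m + 2 * s ~ "strong",
    profile$delta_combined > m + s ~ "significant",
    .default = "none"
  )
  profile
}

#' Find clusters of perturbed residues
#'
#' Maximal runs of consecutive significant/strong residues. A single
#' intervening unobserved residue (e.g. a proline, which has no amide
#' proton) does not break a run — otherwise proline gaps would split
#' biologically contiguous binding patches — but a sub-threshold
#' (`none`) residue does.
#'
#' @param profile A classified `csp_profile`.
#' @param min_run Minimum run length (residue span) to report.
#' @return A tibble with `start`, `end` (residue numbers) and
#'   `n_significant` per cluster.
#' @export
hotspot_clusters <- function(profile, min_run = 2L) {
  sig <- sort(profile$residue_number[profile$class %in%
                                       c("significant", "strong")])
  if (length(sig) == 0L) {
    return(tibble(start = integer(), end = integer(),
                  n_significant = integer()))
  }
  status <- setNames(profile$class, profile$residue_number)
  gap_ok <- function(a, b) {
    g <- b - a
    if (g == 1L) return(TRUE)
    if (g != 2L) return(FALSE)
    mid <- as.character(a + 1L)
    # residues absent from the table altogether were never assigned
    !(mid %in% names(status)) || status[[mid]] == "unobserved"
  }
  brk <- c(FALSE, !map2_lgl(sig[-length(sig)], sig[-1], gap_ok))
  grp <- cumsum(brk)
  tibble(residue_number = sig, grp = grp) |>
    group_by(.data$grp) |>
    summarise(start = min(.data$residue_number),
              end = max(.data$residue_number),
              n_significant = n(), .groups = "drop") |>
    filter(.data$end - .data$start + 1L >= min_run) |>
    select("start", "end", "n_significant")
}

#' Write a CSP profile to TSV
#'
#' Columns: residue, delta_h, delta_n, delta_combined, class.
#' @param profile A `csp_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csp <- function(profile, path) {
  out <- profile |>
    rename(residue = "residue_number")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.csp_profile <- function(x, ...) {
  m <- attr(x, "mean_csp"); s <- attr(x, "sd_csp")
  cat(sprintf(
    "CSP profile: %d residues (%d observed), mean %.4f ppm, SD %.4f ppm\n",
    nrow(x), sum(x$class != "unobserved"), m, s))
  NextMethod()
}

#' Plot a CSP profile
#'
#' Per-residue combined CSP bars with the mean, mean + 1 SD and
#' mean + 2 SD significance lines.
#' @param object A `csp_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csp_profile <- function(object, ...) {
  m <- attr(object, "mean_csp"); s <- attr(object, "sd_csp")
  df <- as_tibble(object) |> filter(.data$class != "unobserved")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_number,
                                   y = .data$delta_combined,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = m, linetype = "solid",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = m + s, linetype = "dotted",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = m + 2 * s, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "residue", y = "combined CSP (ppm)") +
    ggplot2::theme_minimal()
}
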