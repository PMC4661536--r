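#' Fold the terminal stem of a short RNA hairpin
#'
#' Pairs position k with L+1-k from the two ends inward for as long as
#' the bases are Watson-Crick complementary (optionally also G-U
#' wobble) and at least 3 unpaired nucleotides remain for the loop,
#' stopping at the first non-pairing position. This is the
#' construction used to build hairpin models of short synthetic RNAs
#' (a single contiguous terminal stem; no bulges, internal loops or
#' free-energy optimisation — general secondary-structure prediction
#' is deliberately out of scope).
#'
#' Positions are 1-based throughout.
#'
#' @param seq RNA sequence string over A/C/G/U (case-insensitive; T is
#'   accepted and read as U).
#' @param allow_gu Also accept G-U wobble pairs; default FALSE.
#' @return A `stem_loop` list with `pairs` (tibble `i`, `j`,
#'   `base_i`, `base_j`), `loop_range` (c(start, end)), `n_pairs`,
#'   `loop_length`, `dot_bracket`, `seq`. If no terminal pair forms,
#'   `pairs` is empty and the whole sequence is the loop (flagged via
#'   `n_pairs = 0`).
#' @export
fold_terminal_stem <- function(seq, allow_gu = FALSE) {
  bases <- parse_rna(seq)
  len <- length(bases)
  if (len < 7L) abort("sequence shorter than minimal hairpin (2 bp + 3 nt)")
  ok_pair <- function(a, b) {
    wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G")
    if (allow_gu) wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
    wc
  }
  pairs <- list()
  k <- 1L
  while ((len + 1L - 2L * k) - 1L >= 3L && ok_pair(bases[k], bases[len + 1L - k])) {
    pairs[[k]] <- tibble(i = k, j = len + 1L - k,
                         base_i = bases[k], base_j = bases[len + 1L - k])
    k <- k + 1L
  }
  pairs <- if (length(pairs)) list_rbind(pairs) else
    tibble(i = integer(), j = integer(),
           base_i = character(), base_j = character())
  n_pairs <- nrow(pairs)
  loop_range <- c(n_pairs + 1L, len - n_pairs)
  ss <- structure(list(pairs = pairs, loop_range = loop_range,
                       n_pairs = n_pairs,
                       loop_length = loop_range[2] - loop_range[1] + 1L,
                       seq = paste(bases, collapse = "")),
                  class = "stem_loop")
  ss$dot_bracket <- to_dot_bracket(ss, len)
  ss
}

parse_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  bases <- strsplit(toupper(gsub("\\s", "", seq)), "")[[1]]
  bases[bases == "T"] <- "U"
  bad <- setdiff(unique(bases), c("A", "C", "G", "U"))
  if (length(bad)) abort(paste0("non-RNA characters: ",
                                paste(bad, collapse = ", ")))
  bases
}

#' Predict the number of observable imino proton resonances
#'
#' Each A-U pair protects one uracil H3, each G-C pair one guanine H1,
#' and each G-U wobble protects both (two resonances). Iminos are only
#' observable when protected in a base pair, so this count is directly
#' comparable with the number of resolved imino resonances in a 1D 1H
#' spectrum of the folded hairpin (typically 10-15 ppm).
#'
#' @param ss A `stem_loop` from [fold_terminal_stem()].
#' @return Integer count of expected imino resonances.
#' @export
expected_imino_count <- function(ss) {
  p <- ss$pairs
  if (nrow(p) == 0L) return(0L)
  key <- paste0(pmin(p$base_i, p$base_j), pmax(p$base_i, p$base_j))
  counts <- dplyr::case_when(
    key == "AU" ~ 1L,
    key == "CG" ~ 1L,
    key == "GU" ~ 2L,
    .default = NA_integer_
  )
  if (anyNA(counts)) {
    abort(paste0("non-complementary pair(s): ",
                 paste(unique(key[is.na(counts)]), collapse = ", ")))
  }
  sum(counts)
}

#' Dot-bracket string for a stem-loop
#'
#' @param ss A `stem_loop` (or any list with a `pairs` tibble of
#'   columns `i`, `j`).
#' @param length Sequence length.
#' @return A dot-bracket string: `(` at 5' partners, `)` at 3'
#'   partners, `.` elsewhere. Crossing pairs are rejected.
#' @export
to_dot_bracket <- function(ss, length) {
  p <- ss$pairs
  out <- rep(".", length)
  if (nrow(p) > 0L) {
    if (any(p$i >= p$j) || any(p$i < 1L) || any(p$j > length)) {
      abort("pair positions out of range")
    }
    # nested, non-crossing check
    ord <- order(p$i)
    pi_ <- p$i[ord]; pj <- p$j[ord]
    for (a in seq_len(nrow(p) - 1L)) {
      for (b in seq((a + 1L), nrow(p))) {
        crossing <- pi_[a] < pi_[b] && pi_[b] < pj[a] && pj[a] < pj[b]
        if (crossing) abort("crossing pairs are not representable")
      }
    }
    out[p$i] <- "("
    out[p$j] <- ")"
  }
  paste(out, collapse = "")
}

#' @export
print.stem_loop <- function(x, ...) {
  cat(sprintf("stem-loop: %d bp stem, %d nt loop (%d-%d)\n%s\n%s\n",
              x$n_pairs, x$loop_length, x$loop_range[1], x$loop_range[2],
              x$seq, x$dot_bracket))
  invisible(x)
}
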