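write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("TSV shift tables are read, with duplicates and bad lines caught", {
  path <- write_tsv_fixture(c(
    "residue_number\tresidue_type\tatom_name\tshift",
    "# a comment",
    "1\tALA\tH\t8.2",
    "1\tALA\tN\t120.1",
    "2\tGLY\tH\t7.9"))
  tbl <- read_shift_table(path)
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$shift, c(8.2, 120.1, 7.9))

  dup <- write_tsv_fixture(c(
    "residue_number\tresidue_type\tatom_name\tshift",
    "1\tALA\tH\t8.2", "1\tALA\tH\t8.3"))
  expect_error(read_shift_table(dup), "duplicate.*\\(1, H\\)")

  bad <- write_tsv_fixture(c(
    "residue_number\tresidue_type\tatom_name\tshift",
    "1\tALA\tH\t8.2", "oops\tALA\tH\tnot_a_number", "2\tALA\tH\t7.7"))
  expect_warning(tbl2 <- read_shift_table(bad), "line\\(s\\) 3")
  expect_equal(nrow(tbl2), 2L)

  empty <- write_tsv_fixture("residue_number\tresidue_type\tatom_name\tshift")
  expect_error(read_shift_table(empty), "empty")
})

test_that("the NMR-STAR subset reader matches a hand parse of the fixture", {
  path <- write_tsv_fixture(c(
    "data_test", "save_assigned_chemical_shifts", "loop_",
    "_Atom_chem_shift.ID",
    "_Atom_chem_shift.Comp_index_ID",
    "_Atom_chem_shift.Comp_ID",
    "_Atom_chem_shift.Atom_ID",
    "_Atom_chem_shift.Val",
    "1 231 SER H 8.431",
    "2 231 SER N 118.20",
    "3 232 GLY H 8.105",
    "4 232 GLY N 109.77",
    "5 233 ASN H 8.512",
    "stop_", "save_"))
  tbl <- read_shift_table(path, format = "nmrstar")
  # hand-parsed expectation, frozen from the fixture text above
  expect_equal(nrow(tbl), 5L)
  expect_equal(tbl$residue_number, c(231L, 231L, 232L, 232L, 233L))
  expect_equal(tbl$residue_type, c("SER", "SER", "GLY", "GLY", "ASN"))
  expect_equal(tbl$atom_name, c("H", "N", "H", "N", "H"))
  expect_equal(tbl$shift, c(8.431, 118.20, 8.105, 109.77, 8.512))
})

make_tables <- function(df) {
  # df: residue, h_free, n_free, h_bound, n_bound (NA = missing)
  mk <- function(h, n) {
    tibble::tibble(residue_number = rep(df$residue, 2),
                   residue_type = "ALA",
                   atom_name = rep(c("H", "N"), each = nrow(df)),
                   shift = c(h, n)) |>
      dplyr::filter(is.finite(.data$shift))
  }
  list(free = mk(df$h_free, df$n_free), bound = mk(df$h_bound, df$n_bound))
}

test_that("combined CSP follows the weighted root-sum-square formula", {
  df <- tibble::tibble(residue = 1:2,
                       h_free = c(8.0, 8.5), n_free = c(120, 115),
                       h_bound = c(8.1, 8.5), n_bound = c(120.5, 115))
  tb <- make_tables(df)
  prof <- compute_csp(tb$free, tb$bound, n_weight = 0.14)
  expect_equal(prof$delta_combined[1], sqrt(0.1^2 + (0.14 * 0.5)^2),
               tolerance = 1e-10)
  expect_equal(prof$delta_combined[1], 0.1220656, tolerance = 1e-6)
  expect_equal(prof$delta_combined[2], 0)

  # identity: free == bound
  prof0 <- compute_csp(tb$free, tb$free)
  expect_true(all(prof0$delta_combined == 0))
  expect_equal(attr(prof0, "mean_csp"), 0)
  expect_equal(attr(prof0, "sd_csp"), 0)

  # swapping free and bound leaves the combined CSP unchanged
  swapped <- compute_csp(tb$bound, tb$free)
  expect_equal(swapped$delta_combined, prof$delta_combined)

  # with no proton change the combined CSP is linear in n_weight
  df2 <- tibble::tibble(residue = 1, h_free = 8, n_free = 120,
                        h_bound = 8, n_bound = 121)
  tb2 <- make_tables(df2)
  c1 <- compute_csp(tb2$free, tb2$bound, n_weight = 0.14)$delta_combined
  c3 <- compute_csp(tb2$free, tb2$bound, n_weight = 0.42)$delta_combined
  expect_equal(c3, 3 * c1)
})

test_that("residues missing from one state become unobserved", {
  free <- make_tables(tibble::tibble(
    residue = 1:3, h_free = c(8, 8.2, 8.4), n_free = c(120, 121, 122),
    h_bound = NA, n_bound = NA))$free
  bound <- make_tables(tibble::tibble(
    residue = 1:2, h_free = c(8.1, 8.2), n_free = c(120, 121),
    h_bound = NA, n_bound = NA))$free
  prof <- compute_csp(free, bound)
  expect_equal(prof$class[prof$residue_number == 3], "unobserved")
  expect_true(is.na(prof$delta_combined[prof$residue_number == 3]))
  # excluded from the statistics
  obs <- prof$delta_combined[prof$class != "unobserved"]
  expect_equal(attr(prof, "mean_csp"), mean(obs))
  expect_error(compute_csp(free, dplyr::mutate(free, residue_number =
                                                 residue_number + 100)),
               "no residue observed")
})

test_that("significance tiers use mean + 1 SD / + 2 SD with population SD", {
  # nine residues at 0.010 ppm and one at 0.500 ppm: mean 0.059,
  # population SD 0.147, so only the 0.500 residue clears mean + 2 SD
  deltas <- c(rep(0.010, 9), 0.500)
  df <- tibble::tibble(residue = 1:10, h_free = 8, n_free = 120,
                       h_bound = 8 + deltas, n_bound = 120)
  tb <- make_tables(df)
  prof <- classify_csp(compute_csp(tb$free, tb$bound))
  expect_equal(attr(prof, "mean_csp"), 0.059, tolerance = 1e-12)
  expect_equal(attr(prof, "sd_csp"), 0.147, tolerance = 1e-3)
  expect_equal(prof$class[10], "strong")
  expect_true(all(prof$class[1:9] == "none"))

  # all residues equal: SD 0 and the strict inequality excludes all
  df_eq <- tibble::tibble(residue = 1:5, h_free = 8, n_free = 120,
                          h_bound = 8.3, n_bound = 120)
  tb_eq <- make_tables(df_eq)
  prof_eq <- classify_csp(compute_csp(tb_eq$free, tb_eq$bound))
  expect_true(all(prof_eq$class == "none"))

  # single-residue profile: nothing significant
  df_1 <- tibble::tibble(residue = 1, h_free = 8, n_free = 120,
                         h_bound = 9, n_bound = 125)
  tb_1 <- make_tables(df_1)
  expect_true(all(classify_csp(compute_csp(tb_1$free, tb_1$bound))$class
                  == "none"))
})

test_that("classification is idempotent and strong implies significant", {
  for (seed in 1:20) {
    sp <- make_shift_pair(seed = seed, noise_sd_h = 0.03, noise_sd_n = 0.15)
    prof <- classify_csp(compute_csp(sp$free, sp$bound))
    expect_identical(classify_csp(prof)$class, prof$class)
    m <- attr(prof, "mean_csp"); s <- attr(prof, "sd_csp")
    strong <- prof$residue_number[prof$class == "strong"]
    sig_or_strong <- prof$residue_number[prof$class %in%
                                           c("significant", "strong")]
    expect_true(all(strong %in% sig_or_strong))
    expect_true(all(prof$delta_combined[match(strong, prof$residue_number)]
                    > m + s))
  }
})

test_that("hotspot clusters bridge single unobserved gaps only", {
  prof <- tibble::tibble(
    residue_number = c(262:267, 270:275, 280, 282, 285),
    delta_h = 0, delta_n = 0, delta_combined = 0.5,
    class = "significant")
  # residues 268, 269 absent entirely: the 2-residue gap splits runs;
  # 280-282 bridges the single absent residue 281, 285 is too far
  expect_equal(hotspot_clusters(prof, min_run = 3),
               tibble::tibble(start = c(262L, 270L, 280L),
                              end = c(267L, 275L, 282L),
                              n_significant = c(6L, 6L, 2L)))
  # a single unobserved residue inside a run does not break it
  prof2 <- tibble::tibble(
    residue_number = 262:267, delta_h = 0, delta_n = 0,
    delta_combined = c(0.5, 0.5, NA, 0.5, 0.5, 0.5),
    class = c("significant", "significant", "unobserved",
              "significant", "strong", "significant"))
  expect_equal(hotspot_clusters(prof2, min_run = 3)$start, 262L)
  expect_equal(hotspot_clusters(prof2, min_run = 3)$end, 267L)
  # but a sub-threshold residue does
  prof3 <- prof2
  prof3$class[3] <- "none"
  expect_equal(nrow(hotspot_clusters(prof3, min_run = 3)), 1L)
  expect_equal(hotspot_clusters(prof3, min_run = 3)$start, 265L)
  # no significant residues -> empty
  prof4 <- dplyr::mutate(prof, class = "none")
  expect_equal(nrow(hotspot_clusters(prof4)), 0L)
})

test_that("CSP profiles round-trip through the TSV writer", {
  sp <- make_shift_pair(seed = 9)
  prof <- classify_csp(compute_csp(sp$free, sp$bound))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_csp(prof, path)
  back <- utils::read.delim(path)
  expect_equal(back$residue, prof$residue_number)
  expect_equal(back$delta_combined, prof$delta_combined, tolerance = 1e-12)
  expect_equal(back$class, prof$class)
})
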