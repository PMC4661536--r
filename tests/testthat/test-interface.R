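in_chain <- function(ch) function(tb) tb$chain == ch

test_that("ideal and out-of-range hydrogen-bond geometries are judged correctly", {
  # linear N-H...O at 2.9 A donor-acceptor distance
  model <- tibble::tibble(
    chain = c("A", "A", "B"),
    residue_number = c(1L, 1L, 2L),
    residue_name = c("LYS", "LYS", "U"),
    atom_name = c("NZ", "HZ1", "O1P"),
    element = c("N", "H", "O"),
    x = c(0, 1.0, 2.9), y = 0, z = 0)
  hb <- detect_hbonds(model, in_chain("A"), in_chain("B"))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance_da, 2.9)
  expect_equal(hb$angle_dha, 180, tolerance = 1e-9)

  # too far
  far <- model; far$x[3] <- 5.0
  expect_equal(nrow(detect_hbonds(far, in_chain("A"), in_chain("B"))), 0L)

  # bad angle: hydrogen pointing away
  bent <- model; bent$x[2] <- -1.0
  expect_equal(nrow(detect_hbonds(bent, in_chain("A"), in_chain("B"))), 0L)

  # without the hydrogen the criterion is distance-only
  noh <- model[-2, ]
  hb2 <- detect_hbonds(noh, in_chain("A"), in_chain("B"))
  expect_equal(nrow(hb2), 1L)
  expect_true(is.na(hb2$angle_dha))

  # unknown residue types are skipped with a warning
  odd <- model
  odd$residue_name[3] <- "XXX"
  expect_warning(r <- detect_hbonds(odd, in_chain("A"), in_chain("B")),
                 "XXX")
  expect_equal(nrow(r), 0L)
})

test_that("detection equals brute-force pair enumeration on random toys", {
  for (seed in 1:100) {
    toy <- random_hbond_toy(seed)
    in_a <- toy$chain == "A"
    in_b <- toy$chain == "B"
    got <- detect_hbonds(toy, in_a, in_b)
    got_keys <- sort(unique(paste(got$donor, got$acceptor, sep = "->")))
    expect_identical(got_keys, brute_hbonds(toy, in_a, in_b))
  }
})

test_that("hydrogen-bond detection is invariant under rigid transforms", {
  toy <- random_hbond_toy(7)
  base <- detect_hbonds(toy, in_chain("A"), in_chain("B"))
  moved <- rigid_transform_coords(toy, random_rotation(2), c(5, 6, -7))
  got <- detect_hbonds(moved, in_chain("A"), in_chain("B"))
  expect_equal(got$donor, base$donor)
  expect_equal(got$distance_da, base$distance_da, tolerance = 1e-9)
})

test_that("occupancy is exactly k/n and redundancy is visible per interval", {
  ht <- make_hbond_trajectory(c(1, 0.6), n_frames = 10, seed = 2)
  occ <- hbond_occupancy(ht$traj, ht$group_a, ht$group_b)
  expect_equal(sort(occ$occupancy$occupancy), c(0.6, 1.0))
  expect_equal(occ$n_frames, 10L)

  # a static frame repeated: every detected bond has occupancy 1
  static <- make_hbond_trajectory(c(1, 1, 1), n_frames = 5, seed = 1)
  occ1 <- hbond_occupancy(static$traj, static$group_a, static$group_b)
  expect_true(all(occ1$occupancy$occupancy == 1))

  # two anti-correlated bonds (never both absent): per-frame total
  # count never drops below 1 in any interval
  sched <- list(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  anti <- make_hbond_trajectory(c(0.5, 0.5), n_frames = 6,
                                schedules = sched)
  occ2 <- hbond_occupancy(anti$traj, anti$group_a, anti$group_b,
                          interval_frames = 2)
  expect_true(all(occ2$intervals$min_bonds >= 1))
  expect_equal(nrow(occ2$intervals), 3L)
})

test_that("stacking fixtures round-trip their construction geometry", {
  a <- in_chain("A"); b <- in_chain("B")
  # face-to-face stack
  s1 <- detect_stacking(make_stack_fixture("pi_pi", 3.4, 0, 0), a, b)
  expect_equal(s1$kind, "pi_pi_parallel")
  expect_equal(s1$centroid_distance, 3.4, tolerance = 1e-6)
  expect_equal(s1$interplanar_angle, 0, tolerance = 1e-6)
  expect_equal(s1$lateral_offset, 0, tolerance = 1e-6)

  # displaced stack with a 1.5 A slide
  d2 <- sqrt(3.4^2 + 1.5^2)
  s2 <- detect_stacking(make_stack_fixture("pi_pi", d2, 0, 1.5), a, b)
  expect_equal(s2$kind, "pi_pi_displaced")
  expect_equal(s2$lateral_offset, 1.5, tolerance = 1e-6)

  # a realistic displaced-parallel geometry (3.3 A, 5.3 degrees)
  s3 <- detect_stacking(make_stack_fixture("pi_pi", 3.3, 5.3, 1.2), a, b)
  expect_equal(s3$kind, "pi_pi_displaced")
  expect_equal(s3$centroid_distance, 3.3, tolerance = 1e-6)
  expect_equal(s3$interplanar_angle, 5.3, tolerance = 1e-6)
  expect_equal(s3$lateral_offset, 1.2, tolerance = 1e-6)

  # perpendicular rings at 5.0 A are T-shaped
  s4 <- detect_stacking(make_stack_fixture("pi_pi", 5.0, 90, 0), a, b)
  expect_equal(s4$kind, "pi_pi_tshaped")
  expect_equal(s4$interplanar_angle, 90, tolerance = 1e-6)

  # anion-pi (phosphate at 4.1 A) and CH-pi (ribose at 3.9 A)
  s5 <- detect_stacking(make_stack_fixture("anion_pi", 4.1), a, b)
  expect_equal(s5$kind, "anion_pi")
  expect_equal(s5$centroid_distance, 4.1, tolerance = 1e-6)
  s6 <- detect_stacking(make_stack_fixture("ch_pi", 3.9), a, b)
  expect_equal(s6$kind, "ch_pi")
  expect_equal(s6$centroid_distance, 3.9, tolerance = 1e-6)

  # beyond the cutoffs nothing is reported
  expect_equal(nrow(detect_stacking(make_stack_fixture("pi_pi", 6.5),
                                    a, b)), 0L)

  # rigid-transform invariance of the reported geometry
  fx <- make_stack_fixture("pi_pi", 3.3, 5.3, 1.2)
  moved <- rigid_transform_coords(fx, random_rotation(5), c(-3, 9, 1))
  sm <- detect_stacking(moved, a, b)
  expect_equal(sm$centroid_distance, 3.3, tolerance = 1e-6)
  expect_equal(sm$interplanar_angle, 5.3, tolerance = 1e-6)
  expect_equal(sm$lateral_offset, 1.2, tolerance = 1e-6)
})

test_that("interface residues are ranked by BSA with a monotone threshold", {
  set.seed(4)
  mk <- function(chain, off) tibble::tibble(
    chain = chain, residue_number = rep(1:3, each = 2),
    residue_name = "ALA", atom_name = rep(c("CA", "CB"), 3),
    element = "C",
    x = off + runif(6, 0, 4), y = runif(6, 0, 4), z = runif(6, 0, 4))
  cm <- dplyr::bind_rows(mk("A", 0), mk("B", 3.5))
  all_res <- interface_residues(cm, in_chain("A"), in_chain("B"), 0)
  some <- interface_residues(cm, in_chain("A"), in_chain("B"), 30)
  expect_true(all(paste(some$chain, some$residue_number) %in%
                    paste(all_res$chain, all_res$residue_number)))
  expect_true(!is.unsorted(rev(all_res$bsa)))
  far <- cm
  far$x[far$chain == "B"] <- far$x[far$chain == "B"] + 100
  expect_equal(nrow(interface_residues(far, in_chain("A"), in_chain("B"),
                                       1e-6)), 0L)
})
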