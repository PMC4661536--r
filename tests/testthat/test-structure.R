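toy_coords <- function(xyz, atom_names = NULL, elements = "C") {
  n <- nrow(xyz)
  if (is.null(atom_names)) atom_names <- rep("CA", n)
  tibble::tibble(chain = "A", residue_number = seq_len(n),
                 residue_name = "ALA",
                 atom_name = atom_names,
                 element = elements,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("multi-model PDB files round-trip and roster errors are named", {
  g <- make_ensemble(seed = 3, n_models = 4, n_residues = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_models(g$ensemble, path)
  back <- read_models(path)
  expect_equal(length(unique(back$model)), 4L)
  expect_equal(back$atom_name, g$ensemble$atom_name)
  expect_equal(back$x, g$ensemble$x, tolerance = 1e-3)

  single <- g$ensemble[g$ensemble$model == 1, ]
  path1 <- withr::local_tempfile(fileext = ".pdb")
  write_models(dplyr::select(single, -"model"), path1)
  expect_equal(unique(read_models(path1)$model), 1L)

  # drop one atom from model 2: the error names the first offending atom
  lines <- readLines(path)
  drop <- which(grepl("^ATOM", lines) &
                  cumsum(grepl("^MODEL", lines)) == 2)[5]
  path_bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-drop], path_bad)
  expect_error(read_models(path_bad), "roster mismatch in model 2")
})

test_that("Kabsch superposition is exact on rigid transforms", {
  set.seed(42)
  xyz <- matrix(rnorm(30), ncol = 3)
  ref <- toy_coords(xyz)
  # identity
  sp <- superpose(ref, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  mob <- ref; mob$x <- mob$x + 5
  expect_equal(superpose(mob, ref)$rmsd, 0, tolerance = 1e-10)
  # arbitrary rigid transform
  rot <- random_rotation(7)
  mob2 <- rigid_transform_coords(ref, rot, c(3, -2, 8))
  sp2 <- superpose(mob2, ref)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-9)
  # applying the returned transform reproduces the reported RMSD
  moved <- apply_superposition(mob2, sp2)
  expect_equal(sqrt(mean((as.matrix(moved[, c("x", "y", "z")]) -
                            as.matrix(ref[, c("x", "y", "z")]))^2) * 3),
               sp2$rmsd, tolerance = 1e-9)
  # degenerate selections are rejected
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), ">= 3")
  line <- toy_coords(cbind(1:4, 0, 0))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition RMSD matches an exhaustive rotation-grid search", {
  for (seed in 1:4) {
    set.seed(seed)
    p <- matrix(rnorm(12, sd = 2), ncol = 3)
    q <- matrix(rnorm(12, sd = 2), ncol = 3)
    kabsch <- superpose(toy_coords(p), toy_coords(q))$rmsd
    grid <- grid_min_rmsd(p, q)
    expect_lt(abs(kabsch - grid), 0.01)
    expect_lte(kabsch, grid + 1e-12)  # Kabsch is the global minimum
  }
})

test_that("superposed RMSD agrees with the bio3d reference implementation", {
  set.seed(10)
  p <- matrix(rnorm(60, sd = 3), ncol = 3)
  q <- p + matrix(rnorm(60, sd = 0.5), ncol = 3)
  ours <- superpose(toy_coords(p), toy_coords(q))$rmsd
  theirs <- bio3d::rmsd(as.vector(t(q)), as.vector(t(p)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("ensemble RMSD modes behave on degenerate and jittered ensembles", {
  g0 <- make_ensemble(seed = 1, n_models = 4, sigma_core = 0,
                      sigma_tail = 0)
  expect_equal(ensemble_rmsd(g0$ensemble)$mean, 0, tolerance = 1e-9)
  expect_equal(ensemble_rmsd(g0$ensemble,
                             mode = "to_mean_structure")$mean, 0,
               tolerance = 1e-9)
  # translated copies still give zero
  shifted <- g0$ensemble
  shifted$x <- shifted$x + 3 * shifted$model
  expect_equal(ensemble_rmsd(shifted)$mean, 0, tolerance = 1e-9)

  # pairwise mean equals a brute-force loop over all model pairs
  g <- make_ensemble(seed = 5, n_models = 5, sigma_core = 0.3,
                     sigma_tail = 0.3)
  models <- split(g$ensemble, g$ensemble$model)
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    vals <- c(vals, superpose(models[[i]], models[[j]])$rmsd)
  }
  expect_equal(ensemble_rmsd(g$ensemble)$mean, mean(vals),
               tolerance = 1e-9)
  expect_error(ensemble_rmsd(models[[1]]), ">= 2")
  expect_error(ensemble_rmsd(g$ensemble, selection = "XX"), "empty")
})

test_that("RMSD statistics are invariant under rigid transforms", {
  g <- make_ensemble(seed = 8, n_models = 4, sigma_core = 0.2,
                     sigma_tail = 1)
  base <- ensemble_rmsd(g$ensemble)$mean
  rot <- random_rotation(3)
  moved <- rigid_transform_coords(g$ensemble, rot, c(10, -4, 2))
  expect_equal(ensemble_rmsd(moved)$mean, base, tolerance = 1e-9)
  rmsf0 <- per_residue_rmsf(g$ensemble)
  # a common transform of every frame leaves RMSF unchanged
  expect_equal(per_residue_rmsf(rigid_transform_coords(g$ensemble, rot,
                                                       c(1, 2, 3)))$rmsf,
               rmsf0$rmsf, tolerance = 1e-9)
})

test_that("ordered-range detection recovers planted rigid cores", {
  # fully rigid ensemble: the whole chain is returned
  g0 <- make_ensemble(seed = 2, n_models = 5, sigma_core = 0,
                      sigma_tail = 0)
  r0 <- find_ordered_range(g0$ensemble, cutoff = 1)
  expect_equal(r0$start, 1L)
  expect_equal(r0$end, 60L)

  # residues 51-60 given 10 A jitter: range 1-50 at cutoff 2
  g1 <- make_ensemble(seed = 4, n_models = 10, n_residues = 60,
                      core_range = c(1, 50), sigma_core = 0.05,
                      sigma_tail = 10)
  r1 <- find_ordered_range(g1$ensemble, cutoff = 2)
  expect_equal(r1$start, 1L)
  expect_equal(r1$end, 50L)

  # a flexible loop splits the chain into two ranges
  g2 <- make_ensemble(seed = 6, n_models = 10, n_residues = 60,
                      core_range = c(20, 23), sigma_core = 10,
                      sigma_tail = 0.05)  # "core" range made mobile
  r2 <- find_ordered_range(g2$ensemble, cutoff = 2)
  expect_equal(r2$start, c(1L, 24L))
  expect_equal(r2$end, c(19L, 60L))

  expect_error(find_ordered_range(g1$ensemble, cutoff = 1e-6),
               "larger cutoff")
})

test_that("RMSF matches closed forms and planted mobility profiles", {
  g0 <- make_ensemble(seed = 1, n_models = 6, sigma_core = 0,
                      sigma_tail = 0)
  expect_lt(max(per_residue_rmsf(g0$ensemble)$rmsf), 1e-12)

  # one atom oscillating +/- d about its mean has RMSF exactly d
  base <- toy_coords(matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0), ncol = 3,
                            byrow = TRUE), atom_names = c("N", "CA", "C"))
  base$residue_number <- 1L
  d <- 0.7
  traj <- dplyr::bind_rows(
    dplyr::mutate(base, model = 1L, x = x + c(d, 0, 0)),
    dplyr::mutate(base, model = 2L, x = x - c(d, 0, 0)),
    dplyr::mutate(base, model = 3L, x = x + c(d, 0, 0)),
    dplyr::mutate(base, model = 4L, x = x - c(d, 0, 0)))
  r <- per_residue_rmsf(traj, selection = "N")
  expect_equal(r$rmsf, d, tolerance = 1e-12)

  # deterministic ensemble: RMSF equals the planted sigma profile,
  # so the planted mobile segment attains the profile maximum
  gd <- make_ensemble(seed = 2, n_models = 6, jitter = "deterministic",
                      sigma_core = 0.1, sigma_tail = 2)
  rd <- per_residue_rmsf(gd$ensemble)
  expect_equal(rd$rmsf, gd$truth$sigma, tolerance = 1e-10)
  # monotone match with the planted profile (round away float fuzz
  # so ties rank identically)
  expect_equal(cor(round(rd$rmsf, 8), gd$truth$sigma,
                   method = "spearman"), 1)
})
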