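# Independent oracles used to cross-check the package implementations.
# These are deliberately written with different algorithms than the
# package code paths they test.

# One-site isotherm via free-ligand mass balance solved numerically
# (the package solves the bound-fraction quadratic in closed form).
wiseman_oracle <- function(n, ka, dh, scheme) {
  v0 <- scheme$cell_volume_ul
  dv <- scheme$injection_volumes_ul
  m <- scheme$cell_conc_um * 1e-6
  xs <- scheme$syringe_conc_um * 1e-6
  xt <- 0
  q <- numeric(length(dv))
  for (i in seq_along(dv)) {
    f <- 1 - dv[i] / v0
    m <- m * f
    xt <- xt * f + xs * dv[i] / v0
    sites <- n * m
    bal <- function(x) x + sites * ka * x / (1 + ka * x) - xt
    x_free <- if (xt == 0) 0 else uniroot(bal, c(0, xt), tol = 1e-18)$root
    complex_conc <- sites * ka * x_free / (1 + ka * x_free)
    q[i] <- complex_conc * (v0 * 1e-6) * dh
  }
  dq <- numeric(length(q))
  q_prev <- 0
  for (i in seq_along(q)) {
    dq[i] <- q[i] - q_prev + (dv[i] / v0) * (q[i] + q_prev) / 2
    q_prev <- q[i]
  }
  dq / (xs * dv * 1e-6)
}

# Exhaustive rotation-grid RMSD search (coarse global grid refined by
# a 1-degree local grid), independent of the SVD solution.
grid_min_rmsd <- function(p, q, coarse = 5, fine = 1) {
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  g <- crossprod(q0, p0)  # rmsd^2 = (Sp + Sq - 2 sum(G * R)) / n
  sp <- sum(p0^2); sq <- sum(q0^2); n <- nrow(p)
  eval_grid <- function(a, b, c) {
    gr <- expand.grid(a = a, b = b, c = c)
    ca <- cos(gr$a); sa <- sin(gr$a)
    cb <- cos(gr$b); sb <- sin(gr$b)
    cc <- cos(gr$c); sc <- sin(gr$c)
    tr <- g[1, 1] * (ca * cb * cc - sa * sc) +
      g[1, 2] * (-ca * cb * sc - sa * cc) +
      g[1, 3] * (ca * sb) +
      g[2, 1] * (sa * cb * cc + ca * sc) +
      g[2, 2] * (-sa * cb * sc + ca * cc) +
      g[2, 3] * (sa * sb) +
      g[3, 1] * (-sb * cc) +
      g[3, 2] * (sb * sc) +
      g[3, 3] * cb
    list(gr = gr, rmsd = sqrt(pmax(0, (sp + sq - 2 * tr) / n)))
  }
  d2r <- pi / 180
  step1 <- eval_grid(seq(0, 360 - coarse, by = coarse) * d2r,
                     seq(0, 180, by = coarse) * d2r,
                     seq(0, 360 - coarse, by = coarse) * d2r)
  best <- step1$gr[which.min(step1$rmsd), ]
  rng <- function(x0) x0 + seq(-coarse, coarse, by = fine) * d2r
  step2 <- eval_grid(rng(best$a), rng(best$b), rng(best$c))
  min(step2$rmsd)
}

# Brute-force cross-partition hydrogen-bond enumeration with plain
# nested loops over template-typed atoms (distance-only criteria).
brute_hbonds <- function(model, in_a, in_b, d_max = 3.5) {
  tpl <- hbond_templates()
  found <- character()
  for (i in seq_len(nrow(model))) {
    for (j in seq_len(nrow(model))) {
      if (!((in_a[i] && in_b[j]) || (in_b[i] && in_a[j]))) next
      di <- tpl[tpl$residue_name == model$residue_name[i] &
                  tpl$atom_name == model$atom_name[i] &
                  tpl$role %in% c("donor", "both"), ]
      aj <- tpl[tpl$residue_name == model$residue_name[j] &
                  tpl$atom_name == model$atom_name[j] &
                  tpl$role %in% c("acceptor", "both"), ]
      if (nrow(di) == 0 || nrow(aj) == 0) next
      d <- sqrt((model$x[i] - model$x[j])^2 +
                  (model$y[i] - model$y[j])^2 +
                  (model$z[i] - model$z[j])^2)
      if (d <= d_max) {
        found <- c(found, paste(
          paste(model$chain[i], model$residue_number[i],
                model$residue_name[i], model$atom_name[i], sep = ":"),
          paste(model$chain[j], model$residue_number[j],
                model$residue_name[j], model$atom_name[j], sep = ":"),
          sep = "->"))
      }
    }
  }
  sort(unique(found))
}

# random heavy-atom interface toy: donors/acceptors on two chains
random_hbond_toy <- function(seed, n_per_chain = 25L, box = 12) {
  set.seed(seed)
  catalog_a <- list(c("LYS", "NZ", "N"), c("SER", "OG", "O"),
                    c("THR", "OG1", "O"), c("ALA", "O", "O"),
                    c("ALA", "N", "N"))
  catalog_b <- list(c("U", "O1P", "O"), c("U", "N3", "N"),
                    c("A", "N1", "N"), c("G", "O6", "O"),
                    c("C", "O2", "O"))
  mk <- function(chain, catalog) {
    picks <- sample(length(catalog), n_per_chain, replace = TRUE)
    purrr::map2(seq_len(n_per_chain), picks, function(i, k) {
      tibble::tibble(chain = chain, residue_number = i,
                     residue_name = catalog[[k]][1],
                     atom_name = catalog[[k]][2],
                     element = catalog[[k]][3],
                     x = runif(1, 0, box), y = runif(1, 0, box),
                     z = runif(1, 0, box))
    }) |> purrr::list_rbind()
  }
  dplyr::bind_rows(mk("A", catalog_a), mk("B", catalog_b))
}

# sphere-surface SASA by latitude-longitude quadrature (different
# point set and weighting than the package's Fibonacci lattice)
sasa_latlon_oracle <- function(xyz, radii, probe, n_theta = 1000L,
                               n_lon = 1000L) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_lon) - 0.5) * 2 * pi / n_lon
  gr <- expand.grid(theta = theta, phi = phi)
  w <- sin(gr$theta)
  pts <- cbind(sin(gr$theta) * cos(gr$phi),
               sin(gr$theta) * sin(gr$phi),
               cos(gr$theta))
  r <- radii + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    sph <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(sph))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (sph[, 1] - xyz[j, 1])^2 + (sph[, 2] - xyz[j, 2])^2 +
        (sph[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
    }
    4 * pi * r[i]^2 * sum(w * exposed) / sum(w)
  }, numeric(1))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

rigid_transform_coords <- function(coords, rot, shift) {
  xyz <- as.matrix(coords[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  coords$x <- xyz[, 1]; coords$y <- xyz[, 2]; coords$z <- xyz[, 3]
  coords
}
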