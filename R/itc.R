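#' Define an ITC titration scheme
#'
#' Describes the experiment geometry: macromolecule in the cell,
#' titrant in the syringe, and a schedule of injection volumes. The
#' default mirrors a typical small-cell calorimeter run: 200 uL cell,
#' 100 uM macromolecule, 1 mM titrant, twenty 2 uL injections at 298 K.
#'
#' @param cell_volume_ul Active cell volume (uL).
#' @param cell_conc_um Initial macromolecule concentration in the cell
#'   (uM).
#' @param syringe_conc_um Titrant concentration in the syringe (uM).
#' @param injection_volumes_ul Vector of injection volumes (uL).
#' @param spacing_s Injection spacing in seconds (metadata only).
#' @param temperature_k Temperature (K).
#' @return An `itc_scheme` list.
#' @export
itc_scheme <- function(cell_volume_ul = 200, cell_conc_um = 100,
                       syringe_conc_um = 1000,
                       injection_volumes_ul = rep(2, 20),
                       spacing_s = 150, temperature_k = 298) {
  stopifnot(cell_volume_ul > 0, cell_conc_um > 0, syringe_conc_um > 0,
            all(injection_volumes_ul > 0), temperature_k > 0)
  structure(list(cell_volume_ul = cell_volume_ul,
                 cell_conc_um = cell_conc_um,
                 syringe_conc_um = syringe_conc_um,
                 injection_volumes_ul = injection_volumes_ul,
                 spacing_s = spacing_s,
                 temperature_k = temperature_k),
            class = "itc_scheme")
}

# Post-injection total concentrations (mol/L) in the cell under the
# per-injection displacement-dilution factor (1 - dV_i/V0): each
# injection expels a fully mixed volume dV_i, so existing contents are
# scaled by that factor and the injected titrant adds X_syr * dV_i/V0.
# Used identically by the simulator and by both fitters.
itc_concentrations <- function(scheme) {
  v0 <- scheme$cell_volume_ul
  dv <- scheme$injection_volumes_ul
  m <- x <- numeric(length(dv))
  m_prev <- scheme$cell_conc_um * 1e-6
  x_prev <- 0
  xs <- scheme$syringe_conc_um * 1e-6
  for (i in seq_along(dv)) {
    f <- 1 - dv[i] / v0
    m[i] <- m_prev * f
    x[i] <- x_prev * f + xs * dv[i] / v0
    m_prev <- m[i]
    x_prev <- x[i]
  }
  tibble(injection = seq_along(dv), volume_ul = dv,
         m_total = m, x_total = x, molar_ratio = x / m)
}

# Single-site (Wiseman) cumulative heat content and per-injection heats
# normalised per mole of injectant (kcal/mol). theta solves the
# mass-action quadratic at each post-injection composition.
one_site_heats <- function(n, ka, dh, scheme) {
  cc <- itc_concentrations(scheme)
  v0_l <- scheme$cell_volume_ul * 1e-6
  ratio <- cc$x_total / (n * cc$m_total)
  r <- 1 / (ka * n * cc$m_total)
  b <- 1 + ratio + r
  theta <- (b - sqrt(b^2 - 4 * ratio)) / 2
  q <- n * theta * cc$m_total * v0_l * dh   # kcal
  dq <- numeric(length(q))
  q_prev <- 0
  for (i in seq_along(q)) {
    dq[i] <- q[i] - q_prev +
      (cc$volume_ul[i] / scheme$cell_volume_ul) * (q[i] + q_prev) / 2
    q_prev <- q[i]
  }
  moles_injected <- scheme$syringe_conc_um * 1e-6 * cc$volume_ul * 1e-6
  cc$heat <- dq / moles_injected
  cc
}

#' Simulate a single-site ITC isotherm
#'
#' Forward-simulates per-injection heats under the single-site Wiseman
#' binding model with displacement dilution, optionally adding
#' independent Gaussian noise to each normalised heat. Deterministic
#' given `seed`.
#'
#' @param n Stoichiometry (sites per macromolecule).
#' @param dh Binding enthalpy (kcal/mol).
#' @param kd_um Dissociation constant (uM); alternatively give `ka`.
#' @param ka Association constant (1/M); overrides `kd_um` if given.
#' @param scheme An [itc_scheme()].
#' @param noise_sd Gaussian noise SD on each heat (kcal/mol
#'   injectant).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return An `itc_isotherm` tibble: `injection`, `volume_ul`,
#'   `molar_ratio`, `heat` (kcal per mole of injectant), with the
#'   scheme and true parameters stored as attributes.
#' @export
simulate_one_site <- function(n, dh, kd_um = NULL, ka = NULL,
                              scheme = itc_scheme(), noise_sd = 0,
                              seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (is.null(ka)) {
    if (is.null(kd_um)) abort("give kd_um or ka")
    ka <- 1e6 / kd_um
  }
  stopifnot(ka > 0, n > 0)
  cc <- one_site_heats(n, ka, dh, scheme)
  heat <- cc$heat
  if (noise_sd > 0) {
    set.seed(seed)
    heat <- heat + rnorm(length(heat), 0, noise_sd)
  }
  iso <- tibble(injection = cc$injection, volume_ul = cc$volume_ul,
                molar_ratio = cc$molar_ratio, heat = heat)
  structure(iso, class = c("itc_isotherm", class(iso)),
            scheme = scheme,
            truth = list(n = n, ka = ka, dh = dh))
}

#' Subtract a heat-of-dilution control
#'
#' Pointwise subtraction of a titrant-into-buffer control titration
#' from a sample titration; molar ratios are taken from the sample.
#'
#' @param sample,control `itc_isotherm` tibbles with equal injection
#'   counts.
#' @return The corrected isotherm.
#' @export
subtract_dilution <- function(sample, control) {
  if (nrow(sample) != nrow(control)) {
    abort(sprintf("injection count mismatch: %d vs %d",
                  nrow(sample), nrow(control)))
  }
  sample$heat <- sample$heat - control$heat
  sample
}

r_gas_cal <- 1.9872  # cal / (mol K)

derive_thermo <- function(n, ka, dh, temperature_k) {
  kd_um <- 1e6 / ka
  dg <- -r_gas_cal * 1e-3 * temperature_k * log(ka)  # kcal/mol
  ds <- 1000 * (dh - dg) / temperature_k             # cal/(mol K)
  list(kd_um = kd_um, dg = dg, ds = ds)
}

auto_init_one_site <- function(isotherm, scheme) {
  h <- isotherm$heat
  mr <- isotherm$molar_ratio
  dh0 <- mean(head(h, 2))
  if (!is.finite(dh0) || dh0 == 0) dh0 <- h[which.max(abs(h))]
  # stoichiometry from the inflection: molar ratio where the heat
  # drops through half its initial plateau
  half <- dh0 / 2
  below <- which(abs(h) <= abs(half))
  n0 <- if (length(below)) mr[below[1]] else mr[ceiling(length(mr) / 2)]
  n0 <- min(max(n0, 0.1), 5)
  m0 <- scheme$cell_conc_um * 1e-6
  # coarse grid on log10(Ka), refined by the optimiser
  grid <- 10^seq(2, 9, by = 0.5)
  sse <- map_dbl(grid, function(ka) {
    pred <- one_site_heats(n0, ka, dh0, scheme)$heat
    sum((pred - h)^2)
  })
  list(n = n0, log_ka = log(grid[which.min(sse)]), dh = dh0)
}

#' Fit the single-site binding model to an ITC isotherm
#'
#' Weighted least squares of the noise-free Wiseman forward model
#' against the observed per-injection heats, via Levenberg-Marquardt.
#' Ka is fitted on the log scale. Derived quantities use
#' Kd = 1e6/Ka (uM), dG = -RT ln Ka and dS = 1000 (dH - dG)/T with
#' R = 1.9872 cal/(mol K).
#'
#' A Wiseman c-value (N * M0 * Ka) below 1 triggers a warning that the
#' stoichiometry is poorly determined. Non-convergence is flagged in
#' the result rather than raising an error.
#'
#' @param isotherm An `itc_isotherm` (simulated or read from file).
#' @param scheme The [itc_scheme()]; defaults to the one attached to
#'   the isotherm.
#' @param init Optional list with `n`, `ka` (or `log_ka`), `dh`;
#'   otherwise initial values are derived from the isotherm shape.
#' @param weights Optional per-point SDs (kcal/mol); uniform weights by
#'   default.
#' @param discard_first Drop the first injection before fitting (small
#'   first-injection anomalies are common in practice); default FALSE.
#' @return An `itc_fit` object; see [tidy.itc_fit()] and
#'   [glance.itc_fit()].
#' @export
fit_one_site <- function(isotherm, scheme = NULL, init = NULL,
                         weights = NULL, discard_first = FALSE) {
  scheme <- scheme %||% attr(isotherm, "scheme")
  if (is.null(scheme)) abort("no titration scheme supplied")
  keep <- seq_len(nrow(isotherm))
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 6L) abort("need at least 6 informative injections")
  h <- isotherm$heat[keep]
  w <- if (is.null(weights)) rep(1, length(h)) else 1 / weights[keep]^2
  if (is.null(init)) {
    init <- auto_init_one_site(isotherm[keep, ], scheme)
  } else if (is.null(init$log_ka)) {
    init$log_ka <- log(init$ka)
  }
  model_fn <- function(n, log_ka, dh) {
    one_site_heats(n, exp(log_ka), dh, scheme)$heat[keep]
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      h ~ model_fn(n, log_ka, dh),
      start = list(n = init$n, log_ka = init$log_ka, dh = init$dh),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, message = conditionMessage(fit),
                          isotherm = isotherm, scheme = scheme,
                          model = "one_site"),
                     class = "itc_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  names(se) <- names(est)
  n_hat <- est[["n"]]; ka_hat <- exp(est[["log_ka"]]); dh_hat <- est[["dh"]]
  der <- derive_thermo(n_hat, ka_hat, dh_hat, scheme$temperature_k)
  ka_se <- ka_hat * se[["log_ka"]]          # delta method
  kd_se <- (1e6 / ka_hat) * se[["log_ka"]]
  c_value <- n_hat * scheme$cell_conc_um * 1e-6 * ka_hat
  if (is.finite(c_value) && c_value < 1) {
    warn(sprintf("c-value %.3g < 1: stoichiometry poorly determined",
                 c_value))
  }
  params <- tibble(
    term = c("n", "ka", "dh", "kd_um", "dg", "ds"),
    estimate = c(n_hat, ka_hat, dh_hat, der$kd_um, der$dg, der$ds),
    std.error = c(se[["n"]], ka_se, se[["dh"]], kd_se, NA_real_, NA_real_))
  structure(list(params = params, converged = fit$convInfo$isConv,
                 rss = sum(w * residuals(fit)^2),
                 sigma = sqrt(sum(residuals(fit)^2) /
                                max(1, length(h) - 3)),
                 c_value = c_value,
                 fitted = one_site_heats(n_hat, ka_hat, dh_hat, scheme)$heat,
                 isotherm = isotherm, scheme = scheme, keep = keep,
                 model = "one_site", fit = fit),
            class = "itc_fit")
}

# Sequential-sites partition function Z = 1 + sum_j beta_j x^j with
# stepwise constants K1..Kk (beta_j = K1...Kj); free titrant x solved
# from mass balance per injection, heat content from the
# enthalpy-weighted site populations.
sequential_heats <- function(ks, dhs, scheme) {
  k <- length(ks)
  beta <- cumprod(ks)
  cum_dh <- cumsum(dhs)
  cc <- itc_concentrations(scheme)
  v0_l <- scheme$cell_volume_ul * 1e-6
  q <- numeric(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    m <- cc$m_total[i]; xt <- cc$x_total[i]
    bal <- function(x) {
      zj <- beta * x^seq_len(k)
      x + m * sum(seq_len(k) * zj) / (1 + sum(zj)) - xt
    }
    x_free <- if (xt == 0) 0 else
      uniroot(bal, c(0, xt), tol = max(1e-16, xt * 1e-13))$root
    zj <- beta * x_free^seq_len(k)
    q[i] <- v0_l * m * sum(cum_dh * zj) / (1 + sum(zj))
  }
  dq <- numeric(length(q))
  q_prev <- 0
  for (i in seq_along(q)) {
    dq[i] <- q[i] - q_prev +
      (cc$volume_ul[i] / scheme$cell_volume_ul) * (q[i] + q_prev) / 2
    q_prev <- q[i]
  }
  moles_injected <- scheme$syringe_conc_um * 1e-6 * cc$volume_ul * 1e-6
  cc$heat <- dq / moles_injected
  cc
}

#' Simulate a sequential-sites ITC isotherm
#'
#' Forward model with stepwise association constants `ks` (1/M) and
#' per-step enthalpies `dhs` (kcal/mol); otherwise as
#' [simulate_one_site()].
#'
#' @param ks,dhs Numeric vectors of equal length k (sites in stepwise
#'   order).
#' @inheritParams simulate_one_site
#' @return An `itc_isotherm` tibble.
#' @export
simulate_sequential <- function(ks, dhs, scheme = itc_scheme(),
                                noise_sd = 0, seed = 1L) {
  stopifnot(length(ks) == length(dhs), all(ks > 0), noise_sd >= 0)
  cc <- sequential_heats(ks, dhs, scheme)
  heat <- cc$heat
  if (noise_sd > 0) {
    set.seed(seed)
    heat <- heat + rnorm(length(heat), 0, noise_sd)
  }
  iso <- tibble(injection = cc$injection, volume_ul = cc$volume_ul,
                molar_ratio = cc$molar_ratio, heat = heat)
  structure(iso, class = c("itc_isotherm", class(iso)),
            scheme = scheme, truth = list(ks = ks, dhs = dhs))
}

#' Fit the sequential-sites binding model
#'
#' Least-squares fit of the k-site sequential (stepwise) binding
#' model. Because the objective is multi-modal, the fit is
#' multi-started from `n_starts` dispersed initial values (plus any
#' user-supplied `init`) and the best final fit is returned. With
#' `k = 1` the model coincides with the single-site model at N = 1.
#' Under-determined fits are flagged by their standard-error
#' magnitudes rather than an error.
#'
#' @param isotherm An `itc_isotherm`.
#' @param scheme The [itc_scheme()]; defaults to the attached one.
#' @param k Number of sequential sites (1-3).
#' @param init Optional list with `ks` and `dhs` starting values.
#' @param n_starts Number of random multi-starts.
#' @param seed Seed for the multi-start draw.
#' @return An `itc_fit` object with terms `ka_1..k`, `dh_1..k` plus
#'   per-site `kd_um_i`.
#' @export
fit_sequential <- function(isotherm, scheme = NULL, k = 2L, init = NULL,
                           n_starts = 12L, seed = 1L) {
  scheme <- scheme %||% attr(isotherm, "scheme")
  if (is.null(scheme)) abort("no titration scheme supplied")
  if (!k %in% 1:3) abort("k must be 1, 2 or 3")
  h <- isotherm$heat
  if (length(h) < 2 * k + 2) abort("too few injections for this k")
  m0 <- scheme$cell_conc_um * 1e-6
  model_fn <- function(par) {
    ks <- exp(par[seq_len(k)])
    dhs <- par[k + seq_len(k)]
    sequential_heats(ks, dhs, scheme)$heat
  }
  obj <- function(par) {
    pred <- tryCatch(model_fn(par), error = function(e) rep(NA_real_, length(h)))
    res <- pred - h
    if (anyNA(res)) rep(1e6, length(h)) else res
  }
  set.seed(seed)
  dh_scale <- max(abs(h))
  starts <- map(seq_len(n_starts), function(i) {
    c(log(10^runif(k, 3, 7)), runif(k, -2 * dh_scale, 2 * dh_scale))
  })
  if (!is.null(init)) starts <- c(list(c(log(init$ks), init$dhs)), starts)
  fits <- map(starts, function(p0) {
    tryCatch(minpack.lm::nls.lm(
      par = p0, fn = obj,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
  })
  fits <- fits[!map_lgl(fits, is.null)]
  if (length(fits) == 0L) {
    return(structure(list(converged = FALSE, model = "sequential",
                          isotherm = isotherm, scheme = scheme),
                     class = "itc_fit"))
  }
  best <- fits[[which.min(map_dbl(fits, function(f) sum(f$fvec^2)))]]
  par <- best$par
  ks_hat <- exp(par[seq_len(k)])
  dhs_hat <- par[k + seq_len(k)]
  se <- tryCatch({
    cv <- solve(best$hessian) * sum(best$fvec^2) /
      max(1, length(h) - 2 * k)
    sqrt(abs(diag(cv)))
  }, error = function(e) rep(NA_real_, 2 * k))
  params <- tibble(
    term = c(paste0("ka_", seq_len(k)), paste0("dh_", seq_len(k)),
             paste0("kd_um_", seq_len(k))),
    estimate = c(ks_hat, dhs_hat, 1e6 / ks_hat),
    std.error = c(ks_hat * se[seq_len(k)], se[k + seq_len(k)],
                  (1e6 / ks_hat) * se[seq_len(k)]))
  structure(list(params = params, converged = best$info %in% 1:4,
                 rss = sum(best$fvec^2),
                 sigma = sqrt(sum(best$fvec^2) / max(1, length(h) - 2 * k)),
                 fitted = model_fn(par), isotherm = isotherm,
                 scheme = scheme, k = k, model = "sequential"),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("ITC %s fit (%s)\n", x$model,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Tidy an ITC fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`), including derived quantities (Kd in uM, dG in
#'   kcal/mol, dS in cal/(mol K) for the one-site model).
#' @export
tidy.itc_fit <- function(x, ...) {
  x$params %||% tibble(term = character(), estimate = double(),
                       std.error = double())
}

#' One-row summary of an ITC fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `converged`, `rss`, `sigma`,
#'   `c_value`, `n_injections`.
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(model = x$model, converged = isTRUE(x$converged),
         rss = x$rss %||% NA_real_, sigma = x$sigma %||% NA_real_,
         c_value = x$c_value %||% NA_real_,
         n_injections = nrow(x$isotherm))
}

#' Plot an ITC isotherm and fit
#'
#' Observed normalised heats against molar ratio, with the fitted
#' curve overlaid when available.
#' @param object An `itc_fit` or `itc_isotherm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itc_fit <- function(object, ...) {
  df <- tibble(molar_ratio = object$isotherm$molar_ratio,
               heat = object$isotherm$heat)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$molar_ratio, .data$heat)) +
    ggplot2::geom_point(shape = 15) +
    ggplot2::labs(x = "molar ratio", y = "kcal per mole of injectant") +
    ggplot2::theme_minimal()
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(
      data = tibble(molar_ratio = object$isotherm$molar_ratio,
                    heat = object$fitted),
      colour = "red")
  }
  p
}

#' @rdname autoplot.itc_fit
#' @export
autoplot.itc_isotherm <- function(object, ...) {
  ggplot2::ggplot(tibble(molar_ratio = object$molar_ratio,
                         heat = object$heat),
                  ggplot2::aes(.data$molar_ratio, .data$heat)) +
    ggplot2::geom_point(shape = 15) +
    ggplot2::labs(x = "molar ratio", y = "kcal per mole of injectant") +
    ggplot2::theme_minimal()
}

#' Read / write isotherms as TSV
#'
#' Columns: `injection`, `volume_ul`, `molar_ratio`, `heat` (kcal per
#' mole of injectant).
#' @param path File path.
#' @param isotherm An `itc_isotherm` tibble.
#' @return `read_isotherm()` returns an `itc_isotherm` tibble;
#'   `write_isotherm()` returns `path` invisibly.
#' @export
read_isotherm <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("injection", "volume_ul", "molar_ratio", "heat")
  if (!all(need %in% names(df))) {
    abort(paste0("isotherm file must have columns: ",
                 paste(need, collapse = ", ")))
  }
  iso <- as_tibble(df[need])
  structure(iso, class = c("itc_isotherm", class(iso)))
}

#' @rdname read_isotherm
#' @export
write_isotherm <- function(isotherm, path) {
  utils::write.table(as.data.frame(isotherm)[
    c("injection", "volume_ul", "molar_ratio", "heat")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
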