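#' ITC binding parameters for the single-site-class model
#'
#' Parameters of the n-identical-independent-sites (Wiseman) isotherm. The
#' defaults mirror a standard protein-in-cell / peptide-in-syringe setup:
#' 100 uM macromolecule in a 0.2-mL cell titrated with 1200 uM ligand over
#' 19 x 2 uL injections.
#'
#' @param kd Per-site dissociation constant, uM.
#' @param dh Enthalpy per mole of sites, kcal/mol.
#' @param n Binding sites per macromolecule.
#' @param cell_conc Macromolecule concentration in the cell, uM.
#' @param syringe_conc Titrant concentration, uM.
#' @param v0 Cell volume, mL.
#' @return List of class `binding_params`; includes the Wiseman c-value
#'   `c = n * cell_conc / kd`, the main determinant of curve fittability.
#' @export
binding_params <- function(kd, dh = -10, n = 1,
                           cell_conc = 100, syringe_conc = 1200,
                           v0 = 0.2) {
  stopifnot(kd > 0, n > 0, cell_conc > 0, syringe_conc > 0, v0 > 0)
  structure(list(kd = kd, dh = dh, n = n, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, v0 = v0,
                 c_value = n * cell_conc / kd),
            class = "binding_params")
}

#' Default injection schedule
#'
#' @param n_injections Number of injections (default 19).
#' @param volume_uL Volume per injection, uL (default 2).
#' @return Numeric vector of injection volumes in uL.
#' @export
injection_schedule <- function(n_injections = 19L, volume_uL = 2) {
  rep(volume_uL, n_injections)
}

# Core forward model. Perfusion (overflow) dilution convention as used by
# MicroCal/Origin: after cumulative injected volume DV (uL) into a cell of
# volume V0 (uL),
#   [M]_i = M0 (1 - DV/2V0) / (1 + DV/2V0)
#   [X]_i = X0 (DV/V0)     / (1 + DV/2V0)
# Bound-site concentration from the binding quadratic with S = n[M]:
#   C = ((S + X + Kd) - sqrt((S + X + Kd)^2 - 4 S X)) / 2
# Cell heat content Q_i = C_i V0 dH; measured injection heat corrects for
# the half-injection of pre-equilibrated solution displaced into the
# overflow: dQ_i = Q_i - Q_{i-1} + (dV_i/V0) (Q_i + Q_{i-1}) / 2.
# Units: uM x mL = nmol; nmol x kcal/mol = ucal.
wiseman_heats <- function(kd, dh, n, cell_conc, syringe_conc, v0_mL,
                          injections_uL) {
  v0 <- v0_mL * 1000            # uL
  dv <- cumsum(injections_uL)
  mt <- cell_conc * (1 - dv / (2 * v0)) / (1 + dv / (2 * v0))
  xt <- syringe_conc * (dv / v0) / (1 + dv / (2 * v0))
  s <- n * mt
  b <- s + xt + kd
  cplx <- (b - sqrt(pmax(b^2 - 4 * s * xt, 0))) / 2
  q <- cplx * v0_mL * dh        # ucal
  qprev <- c(0, q[-length(q)])
  dq <- q - qprev + (injections_uL / v0) * (q + qprev) / 2
  list(heats = dq, molar_ratio = xt / mt, q_cell = q,
       mt = mt, xt = xt)
}

#' Predict per-injection ITC heats
#'
#' Forward model: the single-site-class isotherm with perfusion dilution
#' correction (see source for the documented formulas). Heats approach zero
#' as the sites saturate, and the summed heat over a saturating schedule
#' approaches `n * cell_conc * v0 * dh`.
#'
#' @param params A [binding_params()] object.
#' @param injections Injection volumes in uL (default
#'   [injection_schedule()]).
#' @return Object of class `isotherm`: `volume_uL`, `heat_ucal`,
#'   `molar_ratio` per injection, plus the c-value and a saturation flag
#'   (TRUE when the schedule fails to reach twice the stoichiometric
#'   equivalence point).
#' @export
predict_heats <- function(params, injections = injection_schedule()) {
  stopifnot(inherits(params, "binding_params"), all(injections > 0))
  w <- wiseman_heats(params$kd, params$dh, params$n, params$cell_conc,
                     params$syringe_conc, params$v0, injections)
  under_saturated <- max(w$molar_ratio) < 2 * params$n
  if (under_saturated) {
    warning("schedule reaches molar ratio ",
            sprintf("%.2f", max(w$molar_ratio)),
            " < 2N; titration may not saturate", call. = FALSE)
  }
  structure(list(volume_uL = injections, heat_ucal = w$heats,
                 molar_ratio = w$molar_ratio, c_value = params$c_value,
                 under_saturated = under_saturated),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("isotherm: %d injections, molar ratio up to %.2f%s\n",
              length(x$heat_ucal), max(x$molar_ratio),
              if (isTRUE(x$under_saturated)) " (under-saturated)" else ""))
  invisible(x)
}

#' Simulate a noisy ITC isotherm
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `noise_sd * max(abs(heat))` to the forward-model heats.
#'
#' @inheritParams predict_heats
#' @param noise_sd Noise level as a fraction of the largest absolute heat.
#' @param seed Integer seed.
#' @return An `isotherm` with a `truth` attribute recording the generating
#'   parameters (ground truth is always emitted alongside synthetic data).
#' @export
simulate_isotherm <- function(params, injections = injection_schedule(),
                              noise_sd = 0.01, seed = 1L) {
  iso <- suppressWarnings(predict_heats(params, injections))
  if (noise_sd > 0) {
    sd_abs <- noise_sd * max(abs(iso$heat_ucal))
    iso$heat_ucal <- with_seed(split_seed(seed, "itc"), {
      iso$heat_ucal + rnorm(length(iso$heat_ucal), 0, sd_abs)
    })
  }
  if (iso$under_saturated) {
    warning("titration does not reach 2x saturation", call. = FALSE)
  }
  attr(iso, "truth") <- unclass(params)
  iso
}

#' Write / read an isotherm as CSV
#'
#' Columns: `injection_index`, `volume_uL`, `heat_ucal`.
#'
#' @param iso An `isotherm`.
#' @param path File path.
#' @export
write_isotherm <- function(iso, path) {
  df <- data.frame(injection_index = seq_along(iso$heat_ucal),
                   volume_uL = iso$volume_uL, heat_ucal = iso$heat_ucal)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_isotherm
#' @return `read_isotherm`: an `isotherm` (molar ratios absent until
#'   concentrations are known at fit time).
#' @export
read_isotherm <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  structure(list(volume_uL = df$volume_uL, heat_ucal = df$heat_ucal,
                 molar_ratio = NULL, c_value = NA,
                 under_saturated = NA),
            class = "isotherm")
}

#' Fit the single-site-class isotherm by nonlinear least squares
#'
#' Minimizes squared residuals in heat-per-mole-of-injectant units
#' (kcal/mol, the Wiseman convention) over (Kd, dH, N), parameterized as
#' (log Kd, dH, log N), from a deterministic multi-start grid refined with
#' BFGS and Nelder-Mead polishing. Approximate standard errors come from
#' the numerical Hessian of the residual sum of squares.
#'
#' @param iso An `isotherm` (observed heats).
#' @param cell_conc,syringe_conc,v0 Cell/syringe concentrations (uM) and
#'   cell volume (mL) of the experiment.
#' @return List of class `itc_fit`: `kd`, `dh`, `n`, standard errors,
#'   `c_value`, `residuals` (ucal), `converged`, and `flags` (c-value
#'   outside \[1, 1000\], under-saturation).
#' @export
fit_isotherm <- function(iso, cell_conc = 100, syringe_conc = 1200,
                         v0 = 0.2) {
  heats <- iso$heat_ucal
  vols <- iso$volume_uL
  if (length(heats) < 8) {
    stop("need at least 8 injections to fit", call. = FALSE)
  }
  if (max(abs(heats)) < 1e-12) {
    stop("no binding detected: all heats are zero", call. = FALSE)
  }
  inj_nmol <- syringe_conc * vols / 1000        # uM * uL / 1000 = nmol
  obs_ndh <- heats / inj_nmol                   # kcal per mole injectant

  objective <- function(par) {
    kd <- exp(par[1]); dh <- par[2]; n <- exp(par[3])
    pred <- wiseman_heats(kd, dh, n, cell_conc, syringe_conc, v0,
                          vols)$heats
    sum((pred / inj_nmol - obs_ndh)^2)
  }

  total_q <- sum(heats)
  dh0 <- total_q / (cell_conc * v0)             # assume N ~ 1 at start
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -10
  starts <- expand.grid(kd = c(0.1, 1, 10, 100),
                        n = c(0.5, 1, 2, 3, 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts$kd[i]), dh0 / starts$n[i], log(starts$n[i]))
    f0 <- suppressWarnings(objective(p0))
    if (!is.finite(f0)) next
    fit <- suppressWarnings(tryCatch(
      optim(p0, objective, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL))
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("fit did not converge from any start", call. = FALSE)
  }
  # polish with Nelder-Mead then BFGS until no further improvement
  for (k in 1:3) {
    nm <- suppressWarnings(optim(best$par, objective, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-15)))
    if (nm$value < best$value) best <- nm
    bf <- suppressWarnings(tryCatch(
      optim(best$par, objective, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-15)),
      error = function(e) NULL))
    if (!is.null(bf) && bf$value < best$value) best <- bf
  }

  kd <- exp(best$par[1]); dh <- best$par[2]; n <- exp(best$par[3])
  pred <- wiseman_heats(kd, dh, n, cell_conc, syringe_conc, v0, vols)$heats
  m <- length(heats); p <- 3L
  sigma2 <- best$value / max(m - p, 1)
  se <- rep(NA_real_, 3)
  H <- tryCatch(numeric_hessian(objective, best$par), error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
      se_par <- sqrt(diag(cv))
      # delta method for the log-parameterized Kd and N
      se <- c(kd * se_par[1], se_par[2], n * se_par[3])
    }
  }
  c_value <- n * cell_conc / kd
  flags <- character()
  if (c_value < 1 || c_value > 1000) {
    flags <- c(flags, sprintf("c-value %.3g outside [1, 1000]", c_value))
  }
  if (isTRUE(iso$under_saturated)) flags <- c(flags, "under-saturated")
  structure(list(kd = kd, dh = dh, n = n,
                 kd_se = se[1], dh_se = se[2], n_se = se[3],
                 c_value = c_value, rss = best$value,
                 residuals = heats - pred, converged = TRUE,
                 flags = flags),
            class = "itc_fit")
}

numeric_hessian <- function(f, x, eps = 1e-5) {
  p <- length(x)
  H <- matrix(0, p, p)
  h <- pmax(abs(x), 1) * eps
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- rep(0, p); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) -
           f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("itc_fit: Kd = %.3g uM, dH = %.3g kcal/mol, N = %.3g (c = %.3g)\n",
              x$kd, x$dh, x$n, x$c_value))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Compare binding affinities against a reference state
#'
#' Reports `Kd_j / Kd_ref` for each labeled fit, with the uncertainty
#' propagated from the fits' Kd standard errors (first-order).
#'
#' @param fits Named list of `itc_fit` objects (length >= 2).
#' @param reference Name of the reference fit.
#' @return Data frame: `label`, `kd`, `ratio_vs_ref`, `ratio_se`,
#'   `ratio_1dp` (ratio rounded to one decimal, "1.2-fold" style).
#' @export
compare_affinities <- function(fits, reference) {
  stopifnot(length(fits) >= 2)
  if (!(reference %in% names(fits))) {
    stop("reference state '", reference, "' not among fits", call. = FALSE)
  }
  ref <- fits[[reference]]
  out <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    ratio <- f$kd / ref$kd
    rel <- sqrt((f$kd_se / f$kd)^2 + (ref$kd_se / ref$kd)^2)
    data.frame(label = nm, kd = f$kd, ratio_vs_ref = ratio,
               ratio_se = if (is.finite(rel)) ratio * rel else NA_real_,
               ratio_1dp = round(ratio, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
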