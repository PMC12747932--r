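# Gas constant in kcal / (mol K); standard state 1 M.
R_KCAL <- 1.9872e-3

#' Titration setup
#'
#' Cell/syringe geometry and concentrations of a single-cell ITC run.
#' Defaults mirror a typical small-volume instrument run for a
#' peptide-into-protein titration: 200 uL cell, 0.05 mM macromolecule,
#' 1 mM peptide in the syringe, one small 1 uL priming shot followed by
#' 19 x 2 uL injections, 20 C. The first injection is flagged for discard,
#' standard practice for the diluted priming shot.
#'
#' @param cell_volume Active cell volume, L.
#' @param cell_conc Macromolecule concentration in the cell, mol/L.
#' @param syringe_conc Titrant concentration in the syringe, mol/L.
#' @param injection_volumes Per-injection volumes, L.
#' @param temperature Kelvin (default 293.15, i.e. 20 C).
#' @param discard_first Flag the first injection as discarded.
#' @return A list of class `titration_setup`.
#' @export
titration_setup <- function(cell_volume = 200e-6,
                            cell_conc = 0.05e-3,
                            syringe_conc = 1e-3,
                            injection_volumes = c(1e-6, rep(2e-6, 19)),
                            temperature = 293.15,
                            discard_first = TRUE) {
  vals <- c(cell_volume, cell_conc, syringe_conc, injection_volumes,
            temperature)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all titration setup quantities must be positive and finite")
  }
  out <- list(cell_volume = cell_volume, cell_conc = cell_conc,
              syringe_conc = syringe_conc,
              injection_volumes = injection_volumes,
              temperature = temperature, discard_first = discard_first)
  class(out) <- "titration_setup"
  out
}

#' Bound complex concentration of the single-site model
#'
#' Closed-form root of the 1:1 binding quadratic in total concentrations:
#' `[ML] = ((N Mt + Lt + KD) - sqrt((N Mt + Lt + KD)^2 - 4 N Mt Lt)) / 2`,
#' clamped into `[0, min(N Mt, Lt)]`. Vectorised over `Mt`/`Lt`.
#'
#' @param Mt Total macromolecule concentration, mol/L.
#' @param Lt Total titrant concentration, mol/L.
#' @param N Stoichiometry.
#' @param K_D Dissociation constant, mol/L.
#' @return Bound concentration, mol/L.
#' @export
bound_concentration <- function(Mt, Lt, N, K_D) {
  if (any(c(Mt, Lt, N, K_D) < 0)) stop("inputs must be non-negative")
  b <- N * Mt + Lt + K_D
  disc <- b^2 - 4 * N * Mt * Lt
  if (any(disc < 0)) {
    warning("negative discriminant clamped to 0")
    disc <- pmax(disc, 0)
  }
  ml <- (b - sqrt(disc)) / 2
  pmin(pmax(ml, 0), pmin(N * Mt, Lt))
}

# Cell concentrations after a cumulative injected volume dv (perfusion
# displacement factors of the standard instrument model).
cell_concentrations <- function(setup, cumulative_volume) {
  v0 <- setup$cell_volume
  f <- cumulative_volume / v0
  Mt <- setup$cell_conc * (1 - f / 2) / (1 + f / 2)
  Lt <- setup$syringe_conc * f / (1 + f / 2)
  list(Mt = Mt, Lt = Lt)
}

#' Simulate a single-site ITC thermogram
#'
#' Forward model: after injection i the cumulative heat content is
#' `Q_i = dH * V0 * [ML]_i`; the differential injection heat with the
#' standard displaced-volume correction is
#' `q_i = Q_i - Q_{i-1} + (v_i / V0) * (Q_i + Q_{i-1}) / 2`.
#' Optional additive Gaussian noise (sd in ucal) is reproducible under
#' `seed`; the global RNG state is left untouched.
#'
#' @param setup A [titration_setup].
#' @param N Stoichiometry.
#' @param K_D Dissociation constant, mol/L.
#' @param dH Binding enthalpy, kcal/mol.
#' @param noise_sd Gaussian noise sd on injection heats, ucal (0 = none).
#' @param seed Optional integer seed for the noise.
#' @return A data.frame of class `thermogram` with per-injection columns
#'   `injection`, `volume` (L), `Mt`, `Lt` (mol/L), `molar_ratio`,
#'   `q_ucal` (heat, microcalories) and `ndh` (normalised heat, kcal per
#'   mol of injectant); the setup and true parameters are attached as
#'   attributes.
#' @export
simulate_thermogram <- function(setup, N, K_D, dH, noise_sd = 0,
                                seed = NULL) {
  stopifnot(inherits(setup, "titration_setup"))
  v <- setup$injection_volumes
  cum_v <- cumsum(v)
  conc <- cell_concentrations(setup, cum_v)
  ml <- bound_concentration(conc$Mt, conc$Lt, N, K_D)
  Q <- dH * setup$cell_volume * ml            # kcal
  Q_prev <- c(0, Q[-length(Q)])
  q_kcal <- Q - Q_prev + (v / setup$cell_volume) * (Q + Q_prev) / 2
  q_ucal <- q_kcal * 1e9
  if (noise_sd > 0) {
    q_ucal <- q_ucal + with_seed(seed, stats::rnorm(length(q_ucal), 0,
                                                    noise_sd))
  }
  ndh <- (q_ucal * 1e-9) / (v * setup$syringe_conc)  # kcal/mol injectant
  out <- data.frame(injection = seq_along(v), volume = v,
                    Mt = conc$Mt, Lt = conc$Lt,
                    molar_ratio = conc$Lt / conc$Mt,
                    q_ucal = q_ucal, ndh = ndh)
  attr(out, "setup") <- setup
  attr(out, "true_params") <- c(N = N, K_D = K_D, dH = dH,
                                noise_sd = noise_sd)
  class(out) <- c("thermogram", "data.frame")
  out
}

#' Write / read a thermogram as TSV
#'
#' Two-column tabular interchange (injection heat keyed by molar ratio),
#' with the setup serialised in `#`-prefixed header comments so that a
#' written file round-trips into a fittable thermogram.
#'
#' @param tg A `thermogram`.
#' @param path File path.
#' @return `path` invisibly / the parsed `thermogram`.
#' @export
write_thermogram <- function(tg, path) {
  setup <- attr(tg, "setup")
  hdr <- c(
    sprintf("# cell_volume=%.8g", setup$cell_volume),
    sprintf("# cell_conc=%.8g", setup$cell_conc),
    sprintf("# syringe_conc=%.8g", setup$syringe_conc),
    sprintf("# temperature=%.4f", setup$temperature),
    sprintf("# discard_first=%s", setup$discard_first),
    sprintf("# injection_volumes=%s",
            paste(sprintf("%.8g", setup$injection_volumes), collapse = ",")),
    "molar_ratio\tq_ucal"
  )
  body <- sprintf("%.8f\t%.8f", tg$molar_ratio, tg$q_ucal)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit) == 0) stop("thermogram file lacks header key: ", key)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  setup <- titration_setup(
    cell_volume = as.numeric(get("cell_volume")),
    cell_conc = as.numeric(get("cell_conc")),
    syringe_conc = as.numeric(get("syringe_conc")),
    injection_volumes = as.numeric(strsplit(get("injection_volumes"),
                                            ",")[[1]]),
    temperature = as.numeric(get("temperature")),
    discard_first = as.logical(get("discard_first"))
  )
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  v <- setup$injection_volumes
  if (nrow(tab) != length(v)) {
    stop("injection count does not match header injection_volumes")
  }
  conc <- cell_concentrations(setup, cumsum(v))
  out <- data.frame(injection = seq_along(v), volume = v,
                    Mt = conc$Mt, Lt = conc$Lt,
                    molar_ratio = tab$molar_ratio,
                    q_ucal = tab$q_ucal,
                    ndh = (tab$q_ucal * 1e-9) / (v * setup$syringe_conc))
  attr(out, "setup") <- setup
  class(out) <- c("thermogram", "data.frame")
  out
}

#' Thermodynamic decomposition of a binding constant
#'
#' `dG = R T ln(K_D)` (standard state 1 M, R = 1.9872e-3 kcal/(mol K)),
#' `-TdS = dG - dH`. Vectorised.
#'
#' @param K_D Dissociation constant, mol/L (> 0).
#' @param dH Binding enthalpy, kcal/mol.
#' @param temperature Kelvin (default 293.15).
#' @return data.frame with columns `dG` and `minus_TdS` (kcal/mol).
#' @export
itc_decompose <- function(K_D, dH, temperature = 293.15) {
  if (any(!is.finite(K_D)) || any(K_D <= 0)) {
    stop("K_D must be positive")
  }
  dG <- R_KCAL * temperature * log(K_D)
  data.frame(dG = dG, minus_TdS = dG - dH)
}

#' Affinity fold change
#'
#' Ratio of dissociation constants, variant over reference (> 1 means the
#' variant binds more weakly).
#'
#' @param K_D_variant,K_D_reference Dissociation constants (same units).
#' @return The ratio.
#' @export
fold_change <- function(K_D_variant, K_D_reference) {
  if (any(c(K_D_variant, K_D_reference) <= 0)) stop("K_D must be positive")
  K_D_variant / K_D_reference
}

model_heats_ucal <- function(setup, N, K_D, dH) {
  v <- setup$injection_volumes
  conc <- cell_concentrations(setup, cumsum(v))
  ml <- bound_concentration(conc$Mt, conc$Lt, N, K_D)
  Q <- dH * setup$cell_volume * ml
  Q_prev <- c(0, Q[-length(Q)])
  (Q - Q_prev + (v / setup$cell_volume) * (Q + Q_prev) / 2) * 1e9
}

#' Fit the single-site model to a thermogram
#'
#' Least-squares fit of (N, K_D, dH) minimising the sum of squared
#' differences between observed and modelled injection heats, via
#' Levenberg-Marquardt (minpack.lm). The association constant is
#' parameterised as log(K_A) internally for conditioning. Initialisation
#' (`init_policy = "midpoint"`): N from the molar ratio at the midpoint of
#' the cumulative heat, dH from the early-injection normalised heat, and a
#' small ladder of c-value starting points for K_A with the best
#' sum-of-squares retained. The first injection is discarded when the
#' setup flags it. Parameter uncertainties come from the covariance of the
#' least-squares Jacobian. Non-convergence is flagged, never silently
#' returned; a fit with c-value below 1 or K_D beyond the titrated range
#' is flagged unreliable.
#'
#' @param tg A `thermogram` (simulated or read from TSV).
#' @param setup A [titration_setup]; defaults to the one attached to `tg`.
#' @param init_policy Initialisation policy (only `"midpoint"` defined).
#' @return A list of class `itc_fit`: `N`, `K_D` (mol/L), `dH` (kcal/mol),
#'   `dG`, `minus_TdS`, `se` (named vector), `converged`, `reliable`,
#'   `c_value`, `ssr`, `n_used`.
#' @export
fit_single_site <- function(tg, setup = attr(tg, "setup"),
                            init_policy = "midpoint") {
  init_policy <- match.arg(init_policy, "midpoint")
  if (is.null(setup)) stop("no titration setup attached or supplied")
  use <- seq_len(nrow(tg))
  if (isTRUE(setup$discard_first)) use <- use[-1]
  if (length(use) < 6) stop("need at least 6 usable injections")
  q_obs <- tg$q_ucal[use]
  if (max(abs(q_obs)) < 1e-9) stop("degenerate thermogram: all heats zero")
  v <- setup$injection_volumes
  # midpoint initialisation
  cum_heat <- cumsum(abs(q_obs))
  mid_idx <- use[which.min(abs(cum_heat - max(cum_heat) / 2))]
  ratio <- tg$molar_ratio
  n0 <- max(ratio[mid_idx], 0.2)
  dh0 <- mean((q_obs[1:2] * 1e-9) / (v[use[1:2]] * setup$syringe_conc))
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  resid_fn <- function(par) {
    q_mod <- model_heats_ucal(setup, par[1], exp(-par[2]), par[3])[use]
    q_obs - q_mod
  }
  best <- NULL
  for (c0 in c(1, 10, 100, 1000)) {
    ka0 <- c0 / (n0 * setup$cell_conc)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(N = n0, lnKa = log(ka0), dH = dh0),
        fn = resid_fn,
        lower = c(0.05, log(1), -1e4),
        upper = c(10, log(1e15), 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr_) {
      fit$ssr_ <- ssr
      best <- fit
    }
  }
  if (is.null(best)) stop("single-site fit failed from all starting points")
  par <- best$par
  N <- par[["N"]]; K_D <- exp(-par[["lnKa"]]); dH <- par[["dH"]]
  converged <- best$info %in% 1:3
  dof <- length(use) - 3L
  se <- rep(NA_real_, 3)
  cov <- tryCatch(solve(best$hessian) * best$ssr_ / max(dof, 1L),
                  error = function(e) NULL)
  if (!is.null(cov)) {
    se <- sqrt(pmax(diag(cov), 0))
    # delta method: sd(K_D) = K_D * sd(lnKa)
    se <- c(N = se[1], K_D = K_D * se[2], dH = se[3])
  } else {
    se <- c(N = NA_real_, K_D = NA_real_, dH = NA_real_)
  }
  c_value <- N * setup$cell_conc / K_D
  max_lt <- max(tg$Lt)
  reliable <- converged && c_value >= 1 && K_D <= 10 * max_lt
  dec <- itc_decompose(K_D, dH, setup$temperature)
  out <- list(N = N, K_D = K_D, dH = dH, dG = dec$dG,
              minus_TdS = dec$minus_TdS, se = se, converged = converged,
              reliable = reliable, c_value = c_value, ssr = best$ssr_,
              n_used = length(use), temperature = setup$temperature)
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("<itc_fit> single-site model\n")
  cat(sprintf("  N = %.3f, K_D = %.4g M, dH = %.2f kcal/mol\n",
              x$N, x$K_D, x$dH))
  cat(sprintf("  dG = %.2f, -TdS = %.2f kcal/mol at %.2f K\n",
              x$dG, x$minus_TdS, x$temperature))
  cat(sprintf("  c = %.1f, converged: %s, reliable: %s\n",
              x$c_value, x$converged, x$reliable))
  invisible(x)
}

#' Published WDR5 / WIN-motif peptide ITC table
#'
#' The printed single-site ITC results for WDR5 titrated with the
#' kinesin-13 WIN-motif peptide and its variants (wild-type 114-122,
#' R117A, truncated 114-120, S121G, S121A, and the WDR5 Y191F protein
#' variant) at 20 C: dH and -TdS (kcal/mol), stoichiometry N, and K_D
#' (uM, mean +/- SD across duplicates). The R117A row records
#' non-detectable binding. Shipped as a plain-text table in
#' `inst/extdata/wdr5_itc_table.csv`.
#'
#' @return A data.frame, one row per titration.
#' @export
wdr5_itc_table <- function() {
  path <- system.file("extdata", "wdr5_itc_table.csv", package = "wins7",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Internal-consistency check of a published ITC table
#'
#' Recomputes `-TdS` from the printed K_D and dH of every detectable row
#' via [itc_decompose()] and reports the deviation from the printed
#' `-TdS`; also recomputes affinity fold changes of each variant against
#' the wild-type row. Printed fold changes in the source table differ from
#' the ratios of the printed K_D values, so the computed ratios are
#' reported and the discrepancy is left visible rather than reconciled.
#'
#' @param table A data.frame as from [wdr5_itc_table()].
#' @param temperature Kelvin.
#' @return `table` with extra columns `minus_TdS_computed`,
#'   `minus_TdS_dev`, `fold_change_vs_wt`.
#' @export
itc_consistency_check <- function(table = wdr5_itc_table(),
                                  temperature = 293.15) {
  ok <- table$detectable
  dec <- itc_decompose(table$KD_uM[ok] * 1e-6, table$dH_kcal_mol[ok],
                       temperature)
  table$minus_TdS_computed <- NA_real_
  table$minus_TdS_computed[ok] <- dec$minus_TdS
  table$minus_TdS_dev <- table$minus_TdS_computed - table$minus_TdS_kcal_mol
  wt <- which(ok & table$peptide == "Kif2A_114-122" &
                table$protein == "WDR5")[1]
  table$fold_change_vs_wt <- NA_real_
  table$fold_change_vs_wt[ok] <- fold_change(table$KD_uM[ok],
                                             table$KD_uM[wt])
  table
}
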