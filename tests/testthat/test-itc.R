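test_that("bound concentration solves the binding quadratic", {
  expect_equal(bound_concentration(1, 0, 1, 1), 0)
  # saturation limit: K_D -> 0 with excess ligand gives N*Mt
  expect_equal(bound_concentration(1e-4, 1e-3, 0.9, 1e-15), 0.9e-4,
               tolerance = 1e-6)
  # symbolic oracle: Mt = Lt = K_D = 1, N = 1 -> (3 - sqrt(5)) / 2
  expect_equal(bound_concentration(1, 1, 1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  expect_true(all(bound_concentration(1e-4, c(0, 1e-5, 1e-3), 1, 1e-6) <=
                    pmin(1e-4, c(0, 1e-5, 1e-3))))
  expect_error(bound_concentration(-1, 1, 1, 1), "non-negative")
})

test_that("the simulated thermogram behaves like a titration", {
  setup <- titration_setup()
  expect_equal(sum(abs(simulate_thermogram(setup, 0.91, 0.78e-6, 0)$q_ucal)),
               0)
  tg <- simulate_thermogram(setup, 0.91, 0.78e-6, -15.7)
  expect_equal(nrow(tg), 20L)
  expect_true(all(tg$q_ucal < 0))        # exothermic throughout
  # inflection (steepest change in normalised heat) near molar ratio = N
  drop_idx <- which.max(abs(diff(tg$ndh[-1]))) + 1L
  expect_equal(tg$molar_ratio[drop_idx], 0.91, tolerance = 0.15)
  # determinism under seed, and the global RNG stream is untouched
  t1 <- simulate_thermogram(setup, 0.91, 0.78e-6, -15.7, 0.5, seed = 7)
  t2 <- simulate_thermogram(setup, 0.91, 0.78e-6, -15.7, 0.5, seed = 7)
  expect_identical(t1$q_ucal, t2$q_ucal)
  set.seed(123); before <- stats::rnorm(1)
  set.seed(123)
  invisible(simulate_thermogram(setup, 0.91, 0.78e-6, -15.7, 0.5, seed = 9))
  expect_identical(stats::rnorm(1), before)
})

test_that("larger K_D lowers the heat signal at fixed enthalpy", {
  setup <- titration_setup()
  q_tight <- simulate_thermogram(setup, 1, 0.5e-6, -15)$q_ucal
  q_weak <- simulate_thermogram(setup, 1, 5e-6, -15)$q_ucal
  expect_lt(sum(abs(q_weak)), sum(abs(q_tight)))
})

test_that("thermograms round-trip through the TSV dialect", {
  setup <- titration_setup()
  tg <- simulate_thermogram(setup, 1.1, 2e-6, -12, 0.4, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_thermogram(tg, path)
  back <- read_thermogram(path)
  expect_equal(back$q_ucal, tg$q_ucal, tolerance = 1e-6)
  expect_equal(attr(back, "setup")$cell_conc, setup$cell_conc)
  # identical file bytes under the same seed
  p2 <- withr::local_tempfile(fileext = ".tsv")
  make_thermogram(p2, setup, 1.1, 2e-6, -12, noise_sd = 0.4, seed = 5)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  make_thermogram(p3, setup, 1.1, 2e-6, -12, noise_sd = 0.4, seed = 5)
  expect_identical(readLines(p2), readLines(p3))
})

test_that("noise-free simulate -> fit round trip recovers the parameters", {
  setup <- titration_setup()
  for (truth in list(c(0.91, 0.78e-6, -15.7),
                     c(1.19, 6.71e-6, -9.2),
                     c(0.94, 3.72e-6, -10.6))) {
    tg <- simulate_thermogram(setup, truth[1], truth[2], truth[3])
    fit <- fit_single_site(tg)
    expect_true(fit$converged)
    expect_true(fit$reliable)
    expect_equal(fit$N, truth[1], tolerance = 1e-3)
    expect_equal(fit$K_D, truth[2], tolerance = 1e-3)
    expect_equal(fit$dH, truth[3], tolerance = 1e-3)
    # thermodynamic identity holds exactly
    expect_equal(fit$dG, fit$dH + fit$minus_TdS, tolerance = 1e-9)
  }
})

test_that("distinct affinities separate cleanly after refitting", {
  setup <- titration_setup()
  fit_wt <- fit_single_site(simulate_thermogram(setup, 0.91, 0.78e-6, -15.7))
  fit_mut <- fit_single_site(simulate_thermogram(setup, 0.94, 3.72e-6, -10.6))
  expect_equal(fold_change(fit_mut$K_D, fit_wt$K_D), 3.72 / 0.78,
               tolerance = 0.01)
})

test_that("degenerate thermograms are refused or flagged, never returned silently", {
  setup <- titration_setup()
  flat <- simulate_thermogram(setup, 0.91, 0.78e-6, 0)
  expect_error(fit_single_site(flat), "degenerate")
  # too few usable injections
  short <- titration_setup(injection_volumes = c(1e-6, rep(2e-6, 4)))
  expect_error(fit_single_site(simulate_thermogram(short, 1, 1e-6, -10)),
               "at least 6")
  # pure-noise thermogram must not come back as a reliable fit
  noise_only <- simulate_thermogram(setup, 0.91, 0.78e-6, -1e-6,
                                    noise_sd = 5, seed = 2)
  res <- tryCatch(fit_single_site(noise_only), error = function(e) e)
  if (!inherits(res, "error")) expect_false(res$reliable)
})

test_that("decomposition reproduces the published entropy terms", {
  d1 <- itc_decompose(0.78e-6, -15.7)
  expect_equal(d1$minus_TdS, 7.51, tolerance = 0.01)
  d2 <- itc_decompose(6.71e-6, -9.2)
  expect_equal(d2$minus_TdS, 2.26, tolerance = 0.01)
  # dH equal to dG leaves no entropic term
  dg <- itc_decompose(1e-6, 0)$dG
  expect_equal(itc_decompose(1e-6, dg)$minus_TdS, 0, tolerance = 1e-12)
  expect_error(itc_decompose(0, -10), "positive")
  expect_error(itc_decompose(-1e-6, -10), "positive")
})

test_that("fold changes are plain K_D ratios", {
  expect_equal(fold_change(1e-6, 1e-6), 1)
  expect_equal(fold_change(3.72, 0.78), 4.769, tolerance = 1e-3)
  expect_equal(fold_change(323e-6, 4.94e-9), 6.54e4, tolerance = 0.01)
  expect_error(fold_change(0, 1), "positive")
})

test_that("every detectable published row is internally consistent", {
  tab <- itc_consistency_check()
  expect_equal(sum(tab$detectable), 5L)
  expect_true(all(abs(tab$minus_TdS_dev[tab$detectable]) < 0.1))
  expect_equal(tab$fold_change_vs_wt[tab$peptide == "Kif2A_114-122_S121G"],
               3.72 / 0.78, tolerance = 1e-9)
  expect_equal(tab$fold_change_vs_wt[tab$peptide == "Kif2A_114-120"],
               6.71 / 0.78, tolerance = 1e-9)
})
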