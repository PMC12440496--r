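test_that("Bonferroni adjustment clamps at 1 and matches p.adjust", {
  expect_equal(bonferroni(0.0005, m = 91), 0.0455)
  expect_equal(bonferroni(0.5, m = 91), 1)
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  expect_warning(bonferroni(c(0.2, 0.7), m = 1), "family size")
  p <- c(0.001, 0.02, 0.3)
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
})

test_that("triple concordance and leave-one-out gates behave as specified", {
  fit <- function(beta, se = 0.05) mrmediation:::new_mr_fit("ivw_fixed", 10L, beta, se)
  loo_ok <- tibble::tibble(beta = c(0.2, 0.25, 0.3), pval = c(0.01, 0.02, 0.001))
  g <- triple_concordance(list(ivw = fit(0.2), weighted_median = fit(0.25),
                               presso_corrected = fit(0.22)), loo_ok)
  expect_true(g$concordant)
  expect_true(g$loo_stable)

  g2 <- triple_concordance(list(ivw = fit(0.2), weighted_median = fit(-0.05),
                                presso_corrected = fit(0.22)), loo_ok)
  expect_false(g2$concordant)

  loo_flip <- loo_ok
  loo_flip$beta[2] <- -0.01
  g3 <- triple_concordance(list(ivw = fit(0.2), weighted_median = fit(0.25),
                                presso_corrected = fit(0.22)), loo_flip)
  expect_false(g3$loo_stable)

  # strict mode also demands retained significance
  loo_ns <- loo_ok
  loo_ns$pval[3] <- 0.2
  g4 <- triple_concordance(list(ivw = fit(0.2), weighted_median = fit(0.25),
                                presso_corrected = fit(0.22)), loo_ns,
                          strict = TRUE)
  expect_false(g4$loo_stable)

  expect_error(
    triple_concordance(list(ivw = fit(0.2), weighted_median = NULL,
                            presso_corrected = fit(0.22)), loo_ok),
    class = "mrmediation_incomplete_evidence_error"
  )
})

test_that("config validation demands a seed and sane thresholds", {
  expect_error(screen_config(), class = "mrmediation_config_error")
  expect_error(screen_config(iv_pval = 0, seed = 1))
  cfg <- screen_config(seed = 1)
  expect_equal(cfg$iv_pval, 1e-5)
  expect_equal(cfg$clump_r2, 0.001)
  expect_equal(cfg$clump_kb, 1000)
  expect_equal(cfg$f_min, 10)
})

test_that("YAML round trip preserves thresholds and data paths", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("iv_pval: 1.0e-4", "screen_alpha: 0.01", "seed: 77",
               "outcome: outcome.tsv"), f)
  cfg <- read_screen_config(f)
  expect_equal(cfg$iv_pval, 1e-4)
  expect_equal(cfg$screen_alpha, 0.01)
  expect_equal(cfg$seed, 77)
  expect_equal(attr(cfg, "paths")$outcome, "outcome.tsv")
})

toy <- simulate_toy_screen(seed = 20250912)
cfg_toy <- screen_config(seed = 20250912, presso_nsim = 400, n_boot = 400)

test_that("the forward screen recovers the designed causal structure", {
  scr <- mr_screen(toy$exposures, toy$outcome, cfg_toy)
  expect_equal(nrow(scr), 2)
  expect_true(scr$passes[scr$exposure_id == "x1"])
  expect_false(scr$passes[scr$exposure_id == "x2"])
  expect_true(all(scr$n_snp >= 3))
  # duplicated ids are a configuration error
  expect_error(
    mr_screen(list(x1 = toy$exposures$x1, x1 = toy$exposures$x1),
              toy$outcome, cfg_toy),
    class = "mrmediation_config_error"
  )
})

test_that("an exposure with no surviving instruments is recorded, not fatal", {
  weak <- toy$exposures$x1
  weak$pval <- rep(0.5, nrow(weak))  # nothing passes selection
  weak <- sumstats(weak, trait_id = "weak")
  scr <- mr_screen(list(weak = weak), toy$outcome, cfg_toy)
  expect_equal(scr$status, "no_instruments")
  expect_false(scr$passes)
  expect_equal(scr$n_snp, 0L)
})

test_that("tightening screen_alpha never enlarges the pass set", {
  scr_05 <- mr_screen(toy$mediators, toy$outcome, cfg_toy)
  cfg_tight <- screen_config(seed = 20250912, presso_nsim = 400, n_boot = 400,
                             screen_alpha = 0.001)
  scr_001 <- mr_screen(toy$mediators, toy$outcome, cfg_tight)
  expect_true(all(scr_001$exposure_id[scr_001$passes] %in%
                    scr_05$exposure_id[scr_05$passes]))
})

test_that("the pipeline is deterministic and its manifest counts conserve", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res1 <- run_pipeline(toy$exposures, toy$mediators, toy$outcome, cfg_toy, dir1)
  res2 <- run_pipeline(toy$exposures, toy$mediators, toy$outcome, cfg_toy, dir2)
  files <- sort(list.files(dir1))
  expect_equal(sort(list.files(dir2)), files)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = paste("file", f))
  }
  # gate bookkeeping: candidates = passed + failed + no-instruments
  for (gate in res1$manifest$gates[c("forward", "reverse", "mediators",
                                     "exposure_mediator")]) {
    expect_equal(gate$candidates, gate$passed + gate$failed + gate$no_instruments)
  }
  # designed causal traits pass their screens
  expect_true(res1$forward$passes[res1$forward$exposure_id == "x1"])
  expect_false(res1$forward$passes[res1$forward$exposure_id == "x2"])
  med_pass <- res1$mediators$exposure_id[res1$mediators$passes]
  expect_true(all(c("m1", "m2") %in% med_pass))
  # the designed mediated pair is reported
  expect_true(!is.null(res1$mediation))
  expect_true(any(res1$mediation$exposure_id == "x1" &
                    res1$mediation$mediator_id == "m1"))
  # reverse screen found instruments and no reverse effect on x1
  expect_equal(res1$manifest$gates$reverse$candidates, 1)
  expect_equal(res1$manifest$gates$reverse$passed, 0)
})

test_that("reverse and mediator screens share the forward machinery", {
  rev <- reverse_screen(toy$outcome, toy$exposures["x1"], cfg_toy)
  expect_equal(rev$exposure_id, "outcome")
  expect_equal(rev$outcome_id, "x1")
  expect_gt(rev$n_snp, 3)
  empty <- reverse_screen(toy$outcome, list(), cfg_toy)
  expect_true(is.null(empty) || nrow(empty) == 0)
})
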