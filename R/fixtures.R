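#' Published worked-example summary estimates
#'
#' Bundled point estimates from a published two-sample MR mediation study
#' of circulating inflammatory proteins, plasma metabolites and ulcerative
#' colitis (UC), as printed: reverse-direction UC-on-protein fits
#' (`reverse_uc`), the 21 metabolite-on-UC fits (`metabolites_uc`), the
#' five exposure-to-mediator stage-one fits (`stage1`), the matching five
#' mediator-to-UC stage-two fits (`stage2`), the two total exposure-on-UC
#' effects (`totals`, betas recovered as `log(OR)`), and the published
#' mediation decompositions (`mediation_reported`). Used as worked-example
#' inputs for [mediate()], [proportion_summary()] and [to_odds_ratio()];
#' betas printed only as bounds (e.g. "<0.001") are stored as `NA`.
#'
#' @return A named list of tibbles.
#' @export
worked_example_tables <- function() {
  reverse_uc <- tibble(
    exposure = "UC",
    outcome = c("CCL11", "CCL4", "Flt3L", "IL10RB", "CCL8", "PD-L1"),
    method = "ivw", nsnp = 42L,
    beta = c(-0.007, 0.031, -0.016, 0.040, NA, -0.010),
    se = c(0.013, 0.054, 0.015, 0.044, 0.016, 0.013),
    pval = c(0.62, 0.567, 0.307, 0.362, 0.99, 0.453),
    or = c(0.993, 1.032, 0.985, 1.041, 1.000, 0.990),
    or_ci_low = c(0.968, 0.927, 0.955, 0.955, 0.969, 0.964),
    or_ci_high = c(1.020, 1.147, 1.014, 1.135, 1.032, 1.016)
  )
  metabolites_uc <- tibble(
    exposure = c(
      "Stearoylcarnitine", "1-Arachidonoyl-GPC (20:4n6)",
      "3-Methoxycatechol sulfate (2)", "Nonanoylcarnitine (C9)",
      "1-Stearoyl-2-linoleoyl-GPC (18:0/18:2)",
      "1-Palmitoyl-2-docosahexaenoyl-GPC (16:0/22:6)",
      "1-Stearoyl-2-docosahexaenoyl-GPC (18:0/22:6)",
      "1-(1-Enyl-stearoyl)-2-arachidonoyl-GPE (p-18:0/20:4)",
      "1-Oleoyl-2-linoleoyl-GPE (18:1/18:2)", "Arachidonoylcholine",
      "Tetradecadienoate (14:2)", "X-11308", "X-15461", "X-17351",
      "X-19438", "X-24494", "2'-O-methylcytidine",
      "Arachidonate to oleate to vaccenate ratio",
      "Oleoyl-linoleoyl-glycerol to linoleoyl-arachidonoyl-glycerol ratio",
      "Phosphate to threonine ratio", "Cholesterol to cortisol ratio"
    ),
    outcome = "UC", method = "ivw",
    nsnp = c(20L, 27L, 22L, 20L, 20L, 23L, 27L, 24L, 33L, 19L, 15L, 29L,
             24L, 17L, 24L, 19L, 19L, 19L, 25L, 33L, 17L),
    beta = c(-0.193, -0.109, 0.132, 0.114, 0.232, -0.153, -0.117, -0.154,
             0.099, -0.149, -0.211, -0.106, 0.147, 0.147, 0.182, -0.153,
             0.072, -0.121, 0.103, -0.111, -0.170),
    se = c(0.069, 0.037, 0.050, 0.038, 0.061, 0.053, 0.044, 0.050, 0.029,
           0.057, 0.068, 0.039, 0.053, 0.057, 0.048, 0.048, 0.026, 0.044,
           0.028, 0.043, 0.064),
    or = c(0.824, 0.897, 1.141, 1.120, 1.262, 0.858, 0.890, 0.857, 1.104,
           0.861, 0.810, 0.900, 1.159, 1.159, 1.199, 0.858, 1.075, 0.886,
           1.108, 0.895, 0.844),
    or_ci_low = c(0.719, 0.835, 1.034, 1.039, 1.119, 0.774, 0.817, 0.778,
                  1.043, 0.771, 0.709, 0.833, 1.045, 1.036, 1.092, 0.781,
                  1.021, 0.813, 1.049, 0.823, 0.745),
    or_ci_high = c(0.944, 0.964, 1.259, 1.207, 1.423, 0.951, 0.970, 0.945,
                   1.169, 0.962, 0.925, 0.971, 1.285, 1.296, 1.317, 0.943,
                   1.131, 0.966, 1.171, 0.973, 0.956)
  )
  stage1 <- tibble(
    exposure = c("CCL4", "CCL4", "IL10RB", "IL10RB", "IL10RB"),
    mediator = c("1-(1-Enyl-stearoyl)-2-arachidonoyl-GPE (p-18:0/20:4)",
                 "X-24494", "1-Arachidonoyl-GPC (20:4n6)",
                 "2'-O-methylcytidine", "Tetradecadienoate (14:2)"),
    nsnp = c(30L, 30L, 20L, 20L, 20L),
    beta1 = c(-0.065, 0.065, 0.059, 0.062, 0.075),
    se1 = c(0.028, 0.030, 0.025, 0.026, 0.026),
    pval = c(0.020, 0.033, 0.019, 0.016, 0.003),
    or = c(0.937, 1.067, 1.061, 1.063, 1.078)
  )
  stage2 <- tibble(
    mediator = c("1-Arachidonoyl-GPC (20:4n6)",
                 "1-(1-Enyl-stearoyl)-2-arachidonoyl-GPE (p-18:0/20:4)",
                 "Tetradecadienoate (14:2)", "X-24494",
                 "2'-O-methylcytidine"),
    outcome = "UC",
    nsnp = c(27L, 24L, 15L, 19L, 19L),
    beta2 = c(-0.109, -0.154, -0.211, -0.153, 0.072),
    se2 = c(0.037, 0.050, 0.068, 0.048, 0.026),
    pval = c(0.0030, 0.0020, 0.0019, 0.0015, 0.0062),
    or = c(0.897, 0.857, 0.810, 0.858, 1.075)
  )
  totals <- tibble(
    exposure = c("CCL4", "IL10RB"),
    outcome = "UC",
    or_total = c(1.12, 1.15),
    beta_total = log(c(1.12, 1.15)),
    pval = c(0.008, 0.011)
  )
  mediation_reported <- tibble(
    exposure = c("CCL4", "CCL4", "IL10RB", "IL10RB", "IL10RB"),
    mediator = c("1-(1-Enyl-stearoyl)-2-arachidonoyl-GPE (p-18:0/20:4)",
                 "X-24494", "1-Arachidonoyl-GPC (20:4n6)",
                 "Tetradecadienoate (14:2)", "2'-O-methylcytidine"),
    outcome = "UC",
    mediated_effect = c(0.010, -0.010, -0.006, -0.016, 0.004),
    effect_ci_low = c(-0.001, -0.021, -0.013, -0.031, -0.001),
    effect_ci_high = c(0.021, 0.001, 0.000, -0.001, 0.009),
    mediated_proportion_pct = c(8.6, -8.6, -4.7, -11.7, 3.3)
  )
  list(reverse_uc = reverse_uc, metabolites_uc = metabolites_uc,
       stage1 = stage1, stage2 = stage2, totals = totals,
       mediation_reported = mediation_reported)
}

#' Worked-example mediation decompositions
#'
#' Feeds the printed stage-one and stage-two coefficients from
#' [worked_example_tables()] through [mediate()], using the published total
#' effects (`log(OR)`, standard errors not printed and therefore `NA`).
#'
#' @return A `mediation_result` tibble with five rows, matched by
#'   (exposure, mediator).
#' @export
worked_example_mediation <- function() {
  tabs <- worked_example_tables()
  s1 <- tabs$stage1
  rows <- map(seq_len(nrow(s1)), function(i) {
    s2 <- tabs$stage2[match(s1$mediator[i], tabs$stage2$mediator), ]
    tot <- tabs$totals[match(s1$exposure[i], tabs$totals$exposure), ]
    mediate(
      list(beta = s1$beta1[i], se = s1$se1[i]),
      list(beta = s2$beta2, se = s2$se2),
      list(beta = tot$beta_total, se = NA_real_),
      exposure = s1$exposure[i], mediator = s1$mediator[i], outcome = "UC"
    )
  })
  list_rbind(rows)
}

#' Outlier demonstration instrument set
#'
#' Deterministic 29-valid + 1-displaced instrument set: outcome effects sit
#' on a Wald ratio of `theta` plus noise at the outcome standard error,
#' except one variant whose outcome beta is displaced by `shift_se`
#' standard errors - a designed pleiotropic outlier for [mr_presso()].
#'
#' @param seed RNG seed; default 20250912.
#' @param k Number of instruments; default 30.
#' @param theta True causal ratio; default 0.2.
#' @param shift_se Displacement of the last variant's outcome effect in
#'   outcome-SE units; default 10.
#' @return A `harmonized` tibble.
#' @export
simulate_outlier_demo <- function(seed = 20250912, k = 30, theta = 0.2,
                                  shift_se = 10) {
  with_seed(seed, {
    be <- runif(k, 0.03, 0.10)
    see <- be / runif(k, 8, 15)
    seo <- runif(k, 0.008, 0.02)
    bo <- theta * be + rnorm(k, 0, seo)
    bo[k] <- theta * be[k] + shift_se * seo[k]
    harmonized_set(
      variant_id = paste0("rs", seq_len(k)),
      beta_exp = be, se_exp = see, beta_out = bo, se_out = seo,
      n_exp = 50000L, n_out = 50000L,
      exposure_id = "exposure", outcome_id = "outcome"
    )
  })
}

#' Toy screening panel with designed pass/fail structure
#'
#' Small deterministic multi-trait panel: exposure `x1` is causal on the
#' outcome (partly through mediator `m1`), `x2` is null; mediators `m1`
#' and `m2` are causal on the outcome, `m3`-`m6` are null; the outcome has
#' 12 strong variants of its own so a reverse screen has instruments. All
#' traits share one variant panel so every pairwise harmonization overlaps.
#'
#' @param seed RNG seed; default 20250912.
#' @param n Per-trait GWAS sample size; default 20,000.
#' @return A list with `exposures`, `mediators`, `outcome` and the
#'   `design` (which traits were built causal).
#' @export
simulate_toy_screen <- function(seed = 20250912, n = 20000) {
  k_per <- 12L
  n_expo <- 2L
  n_med <- 6L
  k_out <- 12L
  k <- k_per * (n_expo + n_med) + k_out
  with_seed(seed, {
    maf <- runif(k, 0.1, 0.5)
    vg <- 2 * maf * (1 - maf)
    r2 <- runif(k, 0.002, 0.004)
    per_allele <- sqrt(r2 / vg)
    blocks <- split(seq_len(k), rep(seq_len(n_expo + n_med + 1),
                                    times = c(rep(k_per, n_expo + n_med), k_out)))
    gamma <- matrix(0, k, n_expo + n_med)
    for (j in seq_len(n_expo + n_med)) gamma[blocks[[j]], j] <- per_allele[blocks[[j]]]
    delta_y <- rep(0, k)
    delta_y[blocks[[n_expo + n_med + 1]]] <- per_allele[blocks[[n_expo + n_med + 1]]] * 3

    b_xm1 <- 0.4     # x1 -> m1
    theta_x1 <- 0.5  # x1 -> outcome, direct
    theta_m <- c(-0.4, 0.45, 0, 0, 0, 0)  # mediators -> outcome

    map <- snp_map(k, chrom_size = 6L)
    make_latents <- function(nn) {
      G <- draw_genotypes(nn, maf)
      Gc <- sweep(G, 2, 2 * maf)
      x <- Gc %*% gamma[, 1:n_expo] +
        matrix(rnorm(nn * n_expo, sd = sqrt(1 - 0.036)), nn, n_expo)
      m <- Gc %*% gamma[, n_expo + seq_len(n_med)] +
        matrix(rnorm(nn * n_med, sd = sqrt(1 - 0.04 - b_xm1^2)), nn, n_med)
      m[, 1] <- m[, 1] + b_xm1 * x[, 1]
      liab <- theta_x1 * x[, 1] + m %*% theta_m + as.vector(Gc %*% delta_y)
      list(G = G, x = x, m = m, liab = as.vector(liab))
    }

    tables <- list()
    for (j in 1:n_expo) {
      s <- make_latents(n)
      tables[[paste0("x", j)]] <- assemble_table(
        map, summary_stats(s$G, s$x[, j], "continuous"),
        paste0("x", j), "continuous")
    }
    for (j in 1:n_med) {
      s <- make_latents(n)
      tables[[paste0("m", j)]] <- assemble_table(
        map, summary_stats(s$G, s$m[, j], "continuous"),
        paste0("m", j), "continuous")
    }
    s <- make_latents(n)
    y <- binarize(s$liab, 0.5)
    outcome <- assemble_table(map, summary_stats(s$G, y, "binary"),
                              "outcome", "binary")
    list(
      exposures = tables[paste0("x", 1:n_expo)],
      mediators = tables[paste0("m", 1:n_med)],
      outcome = outcome,
      design = list(
        causal_exposures = "x1", causal_mediators = c("m1", "m2"),
        mediated_pair = c("x1", "m1"),
        theta_x1 = theta_x1, b_xm1 = b_xm1, theta_m = theta_m
      )
    )
  })
}

#' Write a named test fixture bundle
#'
#' Deterministic small bundles backing examples and tests:
#' `"tables_worked_examples"` (the published worked-example estimates as
#' TSV), `"toy_screen"` (a 2-exposure x 6-mediator x 1-outcome synthetic
#' panel with designed pass/fail structure, written as per-trait sumstats
#' TSVs plus a design manifest) and `"outlier_demo"` (29 concordant
#' instruments plus one displaced by 10 outcome standard errors).
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the synthetic bundles; default 20250912.
#' @return The paths written, invisibly.
#' @export
make_fixture <- function(name = c("tables_worked_examples", "toy_screen",
                                  "outlier_demo"),
                         dir, seed = 20250912) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(tbl, file) {
    p <- file.path(dir, file)
    readr::write_tsv(tbl, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  if (name == "tables_worked_examples") {
    tabs <- worked_example_tables()
    for (nm in names(tabs)) put(tabs[[nm]], paste0(nm, ".tsv"))
  } else if (name == "toy_screen") {
    toy <- simulate_toy_screen(seed = seed)
    for (nm in names(toy$exposures)) {
      p <- file.path(dir, paste0("exposure_", nm, ".tsv"))
      write_sumstats(toy$exposures[[nm]], p)
      paths <- c(paths, p)
    }
    for (nm in names(toy$mediators)) {
      p <- file.path(dir, paste0("mediator_", nm, ".tsv"))
      write_sumstats(toy$mediators[[nm]], p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, "outcome.tsv")
    write_sumstats(toy$outcome, p)
    paths <- c(paths, p)
    jsonlite::write_json(toy$design, file.path(dir, "design.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, file.path(dir, "design.json"))
  } else {
    h <- simulate_outlier_demo(seed = seed)
    put(as_tibble(h), "outlier_demo.tsv")
  }
  invisible(paths)
}
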