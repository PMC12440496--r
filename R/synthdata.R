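#' Ground-truth parameters for the synthetic GWAS generator
#'
#' Fixes every structural parameter of the additive-genetic simulation:
#' per-variant allele frequencies and exposure effects, the causal chain
#' exposure -> mediator -> outcome, horizontal pleiotropy, reverse-causal
#' instruments, and per-trait sample sizes. Allele frequencies and
#' per-variant variance shares are drawn once here (from `seed`), so a
#' `sim_truth` object fully determines every downstream dataset.
#'
#' Effect-size conventions: exposure and mediator are standardized
#' (variance about 1), so `gamma` is in SD units per allele; outcome
#' effects (`theta_my`, `theta_xy_direct`, pleiotropy) are log-odds per SD
#' for a binary outcome and SD units for a continuous one.
#'
#' @param n_snp Number of exposure-associated variants; default 30.
#' @param n_snp_med Number of mediator-specific variants (used by
#'   [simulate_mediation()]); default `n_snp`.
#' @param r2_range Range of per-variant exposure variance explained; each
#'   variant's share is drawn uniformly from it. Default `c(5e-4, 2e-3)`,
#'   i.e. per-variant F of roughly 25-100 at n = 50,000.
#' @param maf_range Allele-frequency range for the minor allele; default
#'   `c(0.05, 0.5)`.
#' @param theta_xm Causal effect of exposure on mediator (SD per SD);
#'   default 0.3.
#' @param theta_my Causal effect of mediator on outcome (log-odds per SD);
#'   default 0.4.
#' @param theta_xy_direct Direct exposure-outcome effect; default 0.08.
#'   The pairwise generator uses the implied total effect
#'   `theta_xy_direct + theta_xm * theta_my` (0.2 under the defaults).
#' @param pleio_prop Proportion of exposure variants with a direct
#'   (InSIDE-violating when `pleio_mean != 0`) outcome effect; default 0.
#' @param pleio_mean,pleio_sd Normal distribution of those pleiotropic
#'   effects; defaults 0.
#' @param reverse_prop Proportion of variants that act on the outcome first
#'   and reach the exposure only through it; default 0.
#' @param reverse_kappa Outcome-to-exposure path coefficient for
#'   reverse-causal variants; default 0.3.
#' @param reverse_r2_range Per-variant outcome variance explained by
#'   reverse-causal variants; default `c(1e-3, 3e-3)` (outcome GWAS hits
#'   are typically stronger than relaxed-threshold exposure instruments).
#' @param n_exp,n_med,n_out Per-trait GWAS sample sizes (non-overlapping
#'   samples); defaults 50,000.
#' @param outcome_prevalence Case fraction of the binary outcome sample;
#'   default 0.5 (a balanced case-control design).
#' @param outcome_type `"binary"` (logistic-liability threshold, effects on
#'   the log-odds scale) or `"continuous"`.
#' @param ld Optional `list(block_size =, rho =)` activating block-wise
#'   AR(1) genotype correlation; the generators then also return the
#'   empirical LD matrix of the exposure sample.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(n_snp = 30, n_snp_med = n_snp,
                      r2_range = c(5e-4, 2e-3), maf_range = c(0.05, 0.5),
                      theta_xm = 0.3, theta_my = 0.4, theta_xy_direct = 0.08,
                      pleio_prop = 0, pleio_mean = 0, pleio_sd = 0,
                      reverse_prop = 0, reverse_kappa = 0.3,
                      reverse_r2_range = c(1e-3, 3e-3),
                      n_exp = 50000, n_med = 50000, n_out = 50000,
                      outcome_prevalence = 0.5,
                      outcome_type = c("binary", "continuous"),
                      ld = NULL, seed) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) abort("sim_truth requires an explicit seed",
                           class = "mrmediation_validation_error")
  stopifnot(
    n_snp >= 1, n_snp_med >= 0,
    pleio_prop >= 0, pleio_prop <= 1,
    reverse_prop >= 0, reverse_prop < 1,
    n_exp >= 100, n_med >= 100, n_out >= 100,
    outcome_prevalence > 0, outcome_prevalence < 1,
    maf_range[1] > 0, maf_range[2] <= 0.5
  )
  n_rev <- round(reverse_prop * n_snp)
  n_valid <- n_snp - n_rev
  truth <- with_seed(seed, {
    maf <- runif(n_snp, maf_range[1], maf_range[2])
    r2 <- runif(n_snp, r2_range[1], r2_range[2])
    gamma <- sqrt(r2 / (2 * maf * (1 - maf)))
    delta <- rep(0, n_snp)
    if (n_rev > 0) {
      gamma[(n_valid + 1):n_snp] <- 0
      rev_r2 <- runif(n_rev, reverse_r2_range[1], reverse_r2_range[2])
      vg <- 2 * maf[(n_valid + 1):n_snp] * (1 - maf[(n_valid + 1):n_snp])
      delta[(n_valid + 1):n_snp] <- sqrt(rev_r2 / vg)
    }
    alpha <- rep(0, n_snp)
    n_pleio <- round(pleio_prop * n_valid)
    if (n_pleio > 0) {
      idx <- sample.int(n_valid, n_pleio)
      alpha[idx] <- rnorm(n_pleio, pleio_mean, pleio_sd)
    }
    maf_med <- if (n_snp_med > 0) runif(n_snp_med, maf_range[1], maf_range[2]) else numeric(0)
    r2_med <- if (n_snp_med > 0) runif(n_snp_med, r2_range[1], r2_range[2]) else numeric(0)
    gamma_med <- if (n_snp_med > 0) sqrt(r2_med / (2 * maf_med * (1 - maf_med))) else numeric(0)
    list(maf = maf, gamma = gamma, alpha = alpha, delta = delta,
         maf_med = maf_med, gamma_med = gamma_med)
  })
  structure(
    c(truth, list(
      n_snp = as.integer(n_snp), n_snp_med = as.integer(n_snp_med),
      theta_xm = theta_xm, theta_my = theta_my,
      theta_xy_direct = theta_xy_direct,
      theta_xy_total = theta_xy_direct + theta_xm * theta_my,
      pleio_prop = pleio_prop, pleio_mean = pleio_mean, pleio_sd = pleio_sd,
      reverse_prop = reverse_prop, reverse_kappa = reverse_kappa,
      n_exp = as.integer(n_exp), n_med = as.integer(n_med),
      n_out = as.integer(n_out),
      outcome_prevalence = outcome_prevalence, outcome_type = outcome_type,
      ld = ld, seed = seed
    )),
    class = "sim_truth"
  )
}

# Genotype matrix in Hardy-Weinberg equilibrium; with truth$ld set, allele
# draws follow block-wise AR(1) latent Gaussians, giving within-block LD.
draw_genotypes <- function(n, maf, ld = NULL) {
  k <- length(maf)
  if (is.null(ld)) {
    return(matrix(rbinom(n * k, 2L, rep(maf, each = n)), nrow = n, ncol = k))
  }
  thr <- qnorm(maf)
  allele <- function() {
    Z <- matrix(rnorm(n * k), n, k)
    start <- seq(1, k, by = ld$block_size)
    for (j in seq_len(k)[-start[1]]) {
      if (!(j %in% start)) {
        Z[, j] <- ld$rho * Z[, j - 1] + sqrt(1 - ld$rho^2) * Z[, j]
      }
    }
    sweep(Z, 2, thr, `<`) * 1L
  }
  allele() + allele()
}

# Per-variant association summary statistics. Continuous traits: simple
# linear regression per column. Binary traits: logistic score test, which
# gives per-allele log-odds effects beta = U/V, se = 1/sqrt(V) with
# U = sum(g (y - ybar)), V = ybar (1 - ybar) sum((g - gbar)^2).
summary_stats <- function(G, y, type = c("continuous", "binary")) {
  type <- match.arg(type)
  n <- nrow(G)
  gbar <- colMeans(G)
  sgg <- colSums(G^2) - n * gbar^2
  yc <- y - mean(y)
  sgy <- as.vector(crossprod(G, yc))
  if (type == "continuous") {
    beta <- sgy / sgg
    syy <- sum(yc^2)
    sigma2 <- pmax(syy - beta * sgy, 0) / (n - 2)
    se <- sqrt(sigma2 / sgg)
    pval <- pmax(2 * pt(-abs(beta / se), df = n - 2), .Machine$double.xmin)
  } else {
    ybar <- mean(y)
    v <- ybar * (1 - ybar) * sgg
    beta <- sgy / v
    se <- 1 / sqrt(v)
    pval <- two_sided_p(beta / se)
  }
  tibble(eaf = gbar / 2, beta = beta, se = se, pval = pval, n = n)
}

snp_map <- function(k, prefix = "rs", chrom_size = 10L, spacing = 500000L) {
  tibble(
    variant_id = paste0(prefix, seq_len(k)),
    chrom = as.character(((seq_len(k) - 1L) %/% chrom_size) + 1L),
    pos = 1000000L + ((seq_len(k) - 1L) %% chrom_size) * spacing,
    effect_allele = "A",
    other_allele = "G"
  )
}

assemble_table <- function(map, stats, trait_id, trait_type) {
  sumstats(dplyr::bind_cols(map, stats), trait_id = trait_id, trait_type = trait_type)
}

# Binary outcome from a logistic liability: latent = linear predictor +
# standard logistic noise, thresholded at the empirical (1 - prevalence)
# quantile. Marginal per-variant effects are then on the log-odds scale, so
# the generator's theta parameters are recovered (up to the usual slight
# non-collapsibility attenuation) by logistic score statistics.
binarize <- function(linpred, prevalence) {
  liab <- linpred + rlogis(length(linpred))
  as.numeric(liab > quantile(liab, 1 - prevalence))
}

#' Simulate a two-sample exposure/outcome GWAS pair with known causal effect
#'
#' Draws genotypes in two non-overlapping samples. The exposure is
#' `X = sum(gamma_j g_j) + noise`, standardized. The outcome adds the
#' causal term `theta_xy_total * X`, any pleiotropic direct variant
#' effects, and, for binary outcomes, standard-logistic liability noise
#' thresholded at the prevalence quantile. When `reverse_prop > 0`, the
#' reverse-causal variants act on the outcome's genetic component first and
#' reach the exposure only through the outcome-to-exposure path
#' `reverse_kappa`.
#'
#' @param truth A [sim_truth()] object.
#' @return A list with elements `exposure` and `outcome` (`sumstats`
#'   tables), `truth`, and `ld` (an [ld_matrix()], only when `truth$ld` is
#'   set: the empirical r^2 of the exposure-sample genotypes).
#' @export
simulate_pair <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(truth$seed + 1, {
    k <- truth$n_snp
    map <- snp_map(k)
    rev_idx <- truth$delta != 0
    kappa <- truth$reverse_kappa
    var_y0 <- 1
    var_x_explained <- sum(truth$gamma^2 * 2 * truth$maf * (1 - truth$maf)) +
      (if (any(rev_idx)) kappa^2 * var_y0 else 0)
    sd_eps_x <- sqrt(max(1 - var_x_explained, 0.1))

    make_sample <- function(n) {
      # mean shifts are irrelevant downstream (regressions are centered and
      # the liability threshold is a quantile), so genotypes stay uncentered
      G <- draw_genotypes(n, truth$maf, truth$ld)
      y0 <- if (any(rev_idx)) {
        gen <- as.vector(G[, rev_idx, drop = FALSE] %*% truth$delta[rev_idx])
        gen + rnorm(n, sd = sqrt(max(var_y0 - var(gen), 0.05)))
      } else {
        rep(0, n)
      }
      x <- as.vector(G %*% truth$gamma) +
        (if (any(rev_idx)) kappa * y0 else 0) +
        rnorm(n, sd = sd_eps_x)
      list(G = G, x = x, y0 = y0)
    }

    s1 <- make_sample(truth$n_exp)
    exposure <- assemble_table(map, summary_stats(s1$G, s1$x, "continuous"),
                               "exposure", "continuous")
    ld_out <- if (!is.null(truth$ld)) ld_matrix({
      r2 <- suppressWarnings(stats::cor(s1$G))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 1
      r2 <- (r2 + t(r2)) / 2
      dimnames(r2) <- list(map$variant_id, map$variant_id)
      r2
    }) else NULL

    s2 <- make_sample(truth$n_out)
    linpred <- truth$theta_xy_total * s2$x + s2$y0 +
      as.vector(s2$G %*% truth$alpha)
    if (truth$outcome_type == "binary") {
      y <- binarize(linpred, truth$outcome_prevalence)
      outcome <- assemble_table(map, summary_stats(s2$G, y, "binary"),
                                "outcome", "binary")
    } else {
      y <- linpred + rnorm(truth$n_out)
      outcome <- assemble_table(map, summary_stats(s2$G, y, "continuous"),
                                "outcome", "continuous")
    }
    list(exposure = exposure, outcome = outcome, truth = truth, ld = ld_out)
  })
}

#' Simulate exposure/mediator/outcome GWAS triplets with known mediation
#'
#' Three non-overlapping samples over a shared panel of
#' `n_snp + n_snp_med` variants: the first block instruments the exposure,
#' the second block the mediator. In every sample the latent chain is
#' rebuilt (`X` from its variants; `M = theta_xm X + mediator genetics +
#' noise`; outcome liability `theta_my M + theta_xy_direct X`), and each
#' sample contributes the summary statistics of its own trait. The true
#' total effect is `theta_xy_direct + theta_xm theta_my`; the true
#' proportion mediated is `theta_xm theta_my / total`.
#'
#' @param truth A [sim_truth()] object with `n_snp_med > 0`.
#' @return A list with `exposure`, `mediator`, `outcome` (`sumstats`
#'   tables over the shared variant panel) and `truth`.
#' @export
simulate_mediation <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"), truth$n_snp_med > 0)
  with_seed(truth$seed + 2, {
    maf_all <- c(truth$maf, truth$maf_med)
    k <- length(maf_all)
    map <- snp_map(k)
    gx <- c(truth$gamma, rep(0, truth$n_snp_med))
    gm <- c(rep(0, truth$n_snp), truth$gamma_med)
    var_gx <- sum(gx^2 * 2 * maf_all * (1 - maf_all))
    var_gm <- sum(gm^2 * 2 * maf_all * (1 - maf_all))
    sd_eps_x <- sqrt(max(1 - var_gx, 0.1))
    sd_eps_m <- sqrt(max(1 - truth$theta_xm^2 - var_gm, 0.1))

    make_latents <- function(n) {
      G <- draw_genotypes(n, maf_all, truth$ld)
      x <- as.vector(G %*% gx) + rnorm(n, sd = sd_eps_x)
      m <- truth$theta_xm * x + as.vector(G %*% gm) + rnorm(n, sd = sd_eps_m)
      list(G = G, x = x, m = m)
    }

    sx <- make_latents(truth$n_exp)
    exposure <- assemble_table(map, summary_stats(sx$G, sx$x, "continuous"),
                               "exposure", "continuous")
    sm <- make_latents(truth$n_med)
    mediator <- assemble_table(map, summary_stats(sm$G, sm$m, "continuous"),
                               "mediator", "continuous")
    sy <- make_latents(truth$n_out)
    linpred <- truth$theta_my * sy$m + truth$theta_xy_direct * sy$x
    if (truth$outcome_type == "binary") {
      y <- binarize(linpred, truth$outcome_prevalence)
      outcome <- assemble_table(map, summary_stats(sy$G, y, "binary"),
                                "outcome", "binary")
    } else {
      y <- linpred + rnorm(truth$n_out)
      outcome <- assemble_table(map, summary_stats(sy$G, y, "continuous"),
                                "outcome", "continuous")
    }
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth)
  })
}
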