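load_tables <- function(x, trait_type = "continuous") {
  if (inherits(x, "sumstats")) return(setNames(list(x), trait_id(x)))
  if (is.character(x)) {
    tabs <- map(x, read_sumstats, trait_type = trait_type)
    return(setNames(tabs, vapply(tabs, trait_id, character(1))))
  }
  if (is.list(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      names(x) <- vapply(x, trait_id, character(1))
    }
    return(x)
  }
  abort("expected sumstats object(s) or file path(s)",
        class = "mrmediation_config_error")
}

screen_report <- function(screen) {
  select(screen, -any_of("fits"))
}

wald_ratio_report <- function(screen) {
  rows <- map(seq_len(nrow(screen)), function(i) {
    fits <- screen$fits[[i]]
    if (is.null(fits)) return(NULL)
    h <- fits$h
    wr <- mr_wald_ratios(h)
    tibble(
      exposure = screen$exposure_id[i], outcome = screen$outcome_id[i],
      variant_id = h$variant_id,
      beta_exp = h$beta_exp, se_exp = h$se_exp,
      beta_out = h$beta_out, se_out = h$se_out,
      ratio = wr$ratio, se_ratio = wr$se_ratio
    )
  })
  list_rbind(rows)
}

#' Run the full screening and mediation pipeline
#'
#' Orchestrates the study cascade: forward screen of every exposure on the
#' outcome; reverse screen (outcome instruments against each
#' forward-passing exposure); mediator screen; exposure-to-mediator MR for
#' every (passing exposure, passing mediator) pair; and mediation
#' decomposition for pairs whose exposure-mediator IVW estimate is
#' significant at `screen_alpha`. All stage reports are written as TSV,
#' with variant-level Wald-ratio tables for external scatter/forest
#' plotting, plus a JSON manifest recording the seed, thresholds and gate
#' counts. The run is deterministic given the configuration seed: a rerun
#' produces byte-identical files.
#'
#' @param exposures,mediators Named lists of `sumstats` tables, or
#'   character vectors of TSV paths.
#' @param outcome A `sumstats` table or TSV path (read as a binary trait
#'   when a path is given).
#' @param cfg A [screen_config()].
#' @param out_dir Output directory (created if needed).
#' @param ld Optional [ld_matrix()] or square-TSV path.
#' @param exclude Optional variant-id exclusion list (character vector or
#'   one-id-per-line file path).
#' @return Invisibly, a list with the stage tibbles (`forward`, `reverse`,
#'   `mediators`, `exposure_mediator`, `mediation`) and the `manifest`.
#' @export
run_pipeline <- function(exposures, mediators, outcome, cfg, out_dir,
                         ld = NULL, exclude = character()) {
  stopifnot(inherits(cfg, "screen_config"))
  if (missing(outcome) || is.null(outcome)) {
    abort("an outcome table or path is required", class = "mrmediation_config_error")
  }
  exposures <- load_tables(exposures)
  mediators <- if (is.null(mediators)) list() else load_tables(mediators)
  if (is.character(outcome)) outcome <- read_sumstats(outcome, trait_type = "binary")
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  if (length(exclude) == 1 && file.exists(exclude)) exclude <- read_exclusion_list(exclude)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  forward <- mr_screen(exposures, outcome, cfg, ld = ld, exclude = exclude)
  passing_exp <- forward$exposure_id[forward$passes]

  reverse <- if (length(passing_exp) > 0) {
    reverse_screen(outcome, exposures[passing_exp], cfg, ld = ld, exclude = exclude)
  } else {
    NULL
  }

  med_screen <- if (length(mediators) > 0) {
    mediator_screen(mediators, outcome, cfg, ld = ld, exclude = exclude)
  } else {
    NULL
  }
  passing_med <- if (is.null(med_screen)) character(0) else {
    med_screen$exposure_id[med_screen$passes]
  }

  xm_rows <- list()
  mediation_rows <- list()
  for (ex in passing_exp) {
    for (me in passing_med) {
      xm <- mr_screen(exposures[ex], mediators[[me]], cfg, ld = ld,
                      exclude = exclude)
      xm_rows[[paste(ex, me, sep = "|")]] <- xm
      if (is.na(xm$pval_ivw[1]) || xm$pval_ivw[1] >= cfg$screen_alpha) next
      fit_xm <- xm$fits[[1]]$ivw
      fit_my <- med_screen$fits[[match(me, med_screen$exposure_id)]]$ivw
      fit_xy <- forward$fits[[match(ex, forward$exposure_id)]]$ivw
      mediation_rows[[paste(ex, me, sep = "|")]] <-
        mediate(fit_xm, fit_my, fit_xy,
                exposure = ex, mediator = me, outcome = trait_id(outcome))
    }
  }
  xm_tbl <- if (length(xm_rows) > 0) list_rbind(unname(xm_rows)) else NULL
  mediation_tbl <- if (length(mediation_rows) > 0) {
    list_rbind(unname(mediation_rows))
  } else {
    NULL
  }

  write_stage <- function(tbl, file) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_tsv(tbl, file.path(out_dir, file), progress = FALSE)
    }
  }
  write_stage(screen_report(forward), "forward_screen.tsv")
  write_stage(wald_ratio_report(forward), "forward_wald_ratios.tsv")
  if (!is.null(reverse)) {
    write_stage(screen_report(reverse), "reverse_screen.tsv")
  }
  if (!is.null(med_screen)) {
    write_stage(screen_report(med_screen), "mediator_screen.tsv")
    write_stage(wald_ratio_report(med_screen), "mediator_wald_ratios.tsv")
  }
  if (!is.null(xm_tbl)) write_stage(screen_report(xm_tbl), "exposure_mediator.tsv")
  if (!is.null(mediation_tbl)) {
    write_stage(mediation_tbl, "mediation.tsv")
    write_stage(proportion_summary(mediation_tbl), "mediation_summary.tsv")
  }

  count_gate <- function(screen) {
    if (is.null(screen)) return(list(candidates = 0L, passed = 0L,
                                     failed = 0L, no_instruments = 0L))
    list(
      candidates = nrow(screen),
      passed = sum(screen$passes),
      failed = sum(!screen$passes & screen$status == "screened"),
      no_instruments = sum(screen$status %in%
                             c("no_instruments", "insufficient_instruments"))
    )
  }
  manifest <- list(
    package = "mrmediation",
    version = as.character(utils::packageVersion("mrmediation")),
    seed = cfg$seed,
    thresholds = cfg[c("iv_pval", "clump_r2", "clump_kb", "f_min",
                       "steiger_alpha", "screen_alpha", "presso_nsim",
                       "n_boot")],
    outcome = trait_id(outcome),
    gates = list(
      forward = count_gate(forward),
      reverse = count_gate(reverse),
      mediators = count_gate(med_screen),
      exposure_mediator = count_gate(xm_tbl),
      mediation = list(candidates = if (is.null(xm_tbl)) 0L else
                         sum(!is.na(xm_tbl$pval_ivw) &
                               xm_tbl$pval_ivw < cfg$screen_alpha),
                       reported = if (is.null(mediation_tbl)) 0L else nrow(mediation_tbl))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(forward = forward, reverse = reverse, mediators = med_screen,
                 exposure_mediator = xm_tbl, mediation = mediation_tbl,
                 manifest = manifest))
}
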