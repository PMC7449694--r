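.defaultThresholds <- function() list(p = 5e-8, r2 = 0.05, f = 10,
                                      alpha = 0.05)

`%||%` <- function(a, b) if (is.null(a)) b else a

.bindRows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Validate a study configuration
#'
#' A configuration is a named list (or a YAML file holding one) with:
#' \itemize{
#'   \item `scenario`: a preset name from [scenarioPresets()] or a list with
#'     `preset` plus overrides — the run then simulates its own cohorts; or
#'   \item `files`: per-sex paths to summary-statistics files
#'     (`files$male$ldl`, `files$male$testosterone`, `files$male$ihd`, the
#'     same for `female`) and optional per-sex LD matrix paths under
#'     `files$ld`;
#'   \item `thresholds`: `p` (genome-wide significance, default 5e-8), `r2`
#'     (independence, default 0.05), `f` (instrument strength, default 10),
#'     `alpha` (significance level, default 0.05);
#'   \item `seed`: integer controlling every random element of the run;
#'   \item `nBoot`: weighted-median bootstrap draws (default 2000);
#'   \item `gateOnExposureOutcomeP`: if TRUE, skip the multivariable stage
#'     for a sex when the drug-to-testosterone p-value is above `alpha`
#'     (default FALSE: the gate verdict is reported, never enforced).
#' }
#'
#' @param config list or YAML path.
#' @return the normalized configuration list.
#' @export
validateStudyConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  th <- .defaultThresholds()
  th[names(config$thresholds)] <- config$thresholds
  config$thresholds <- th
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha must lie in (0,1)")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$nBoot)) config$nBoot <- 2000L
  if (is.null(config$gateOnExposureOutcomeP))
    config$gateOnExposureOutcomeP <- FALSE
  if (is.null(config$scenario) && is.null(config$files))
    stop("config needs either a 'scenario' or a 'files' block")
  if (!is.null(config$files)) {
    paths <- unlist(config$files)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("referenced file(s) do not exist: ",
           paste(missing, collapse = ", "))
  }
  config
}

.loadStudyInputs <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    scenario <- if (is.character(sc)) {
      scenarioPresets(sc, seed = config$seed)
    } else {
      ov <- sc[setdiff(names(sc), "preset")]
      if (is.null(ov$seed)) ov$seed <- config$seed
      do.call(scenarioPresets, c(list(name = sc$preset), ov))
    }
    cohorts <- simulateCohort(scenario)
    out <- list(scenario = scenario)
    for (sex in c("male", "female")) {
      co <- cohorts[[sex]]
      out[[sex]] <- list(
        ldl = computeSumstats(co, "ldl"),
        testosterone = computeSumstats(co, "testosterone"),
        ihd = computeSumstats(co, "ihd"),
        ld = realizedLDMatrix(co),
        caseFraction = mean(co@phenotypes$ihd))
    }
    out
  } else {
    out <- list()
    for (sex in c("male", "female")) {
      fs <- config$files[[sex]]
      out[[sex]] <- list(
        ldl = readSumstats(fs$ldl, trait = "ldl", sex = sex),
        testosterone = readSumstats(fs$testosterone, trait = "testosterone",
                                    sex = sex),
        ihd = readSumstats(fs$ihd, trait = "ihd", sex = sex,
                           scale = "logodds"),
        ld = if (!is.null(config$files$ld[[sex]]))
          readLDMatrix(config$files$ld[[sex]]) else NULL,
        caseFraction = NA_real_)
    }
    out
  }
}

.estRow <- function(sex, exposure, outcome, instrumented, est) {
  data.frame(sex = sex, exposure = exposure, outcome = outcome,
             instrumented_by = instrumented, n_snps = est@nSnps,
             method = est@method, beta = est@beta,
             or = if (est@scale == "logodds") exp(est@beta) else NA_real_,
             ci_low = est@ciLow, ci_high = est@ciHigh, p = est@p,
             egger_intercept_p = est@eggerInterceptP,
             stringsAsFactors = FALSE)
}

.significantOnly <- function(stats, pThreshold, what) {
  stats@records <- stats@records[!is.na(stats@records$p) &
                                   stats@records$p < pThreshold, ,
                                 drop = FALSE]
  if (nrow(stats@records) == 0L)
    stop("no genome-wide significant ", what, " SNPs")
  stats
}

#' Run the full sex-specific drug-target MR study
#'
#' Per sex: screens instruments (genome-wide significance, F >= threshold,
#' LD pruning at the configured r squared), estimates the drug-mimicking
#' exposure's effects on testosterone and disease (lead-SNP main analysis;
#' correlated-SNP GLS sensitivity analysis), estimates testosterone's effect
#' on disease with IVW plus weighted-median and MR-Egger sensitivity (only
#' when the instruments are uncorrelated and J >= 3), checks
#' testosterone-disease directionality by Steiger filtering, fits the
#' multivariable model pooling the drug and testosterone instruments
#' (IVW and MVMR-Egger, conditional F, instrument-validity Q), and finally
#' computes cross-sex contrasts: fixed-effect meta-analysis of the
#' multivariable Egger drug estimates, sex-difference z-tests for
#' testosterone (univariable and multivariable), and mediation by
#' attenuation. Any stage error is recorded in the run log and its
#' dependents skipped; independent branches continue. An exposure whose
#' entire instrument set is dropped is reported as such rather than
#' vanishing silently.
#'
#' @param config configuration list or YAML path (see
#'   [validateStudyConfig()]).
#' @param outDir output directory; when non-NULL, writes `estimates.tsv`,
#'   `mvmr.tsv`, `diagnostics.tsv`, `contrasts.tsv`, `selection_log.tsv`,
#'   `run_log.txt` and `run_manifest.yaml`. Reruns with the same config are
#'   byte-identical.
#' @return invisible list with elements `estimates`, `mvmr`, `diagnostics`,
#'   `contrasts`, `selectionLog` (data.frames), `objects` (the fitted S4
#'   objects) and `log` (character).
#' @export
runStudy <- function(config, outDir = NULL) {
  config <- validateStudyConfig(config)
  th <- config$thresholds
  state <- new.env(parent = emptyenv())
  state$log <- character(0)
  state$estimates <- list(); state$mvmr <- list(); state$diags <- list()
  state$contrasts <- list(); state$selLog <- list(); state$objects <- list()
  note <- function(...) state$log <- c(state$log, sprintf(...))
  note("run seed %d; thresholds p<%.3g r2<%.3g F>=%g alpha=%.3g",
       config$seed, th$p, th$r2, th$f, th$alpha)

  inputs <- .loadStudyInputs(config)

  tryStage <- function(label, fun) {
    tryCatch(fun(), error = function(e) {
      call <- conditionCall(e)
      note("stage '%s' failed: %s%s (dependents skipped)", label,
           conditionMessage(e),
           if (is.null(call)) "" else
             sprintf(" [in %s]", deparse1(call, collapse = " ")))
      NULL
    })
  }

  for (sex in c("male", "female")) {
    dat <- inputs[[sex]]
    nTotal <- stats::median(dat$ldl@records$n, na.rm = TRUE)

    sel <- tryStage(paste0(sex, "/drug_instruments"), function() {
      sig <- .significantOnly(dat$ldl, th$p, "exposure")
      ff <- filterByF(sig, th$f)
      if (nrow(ff$stats@records) == 0L)
        stop("entire instrument set dropped at F < ", th$f)
      pruned <- ldPrune(ff$stats, dat$ld, r2Threshold = th$r2)
      state$selLog[[paste0(sex, "_drug")]] <-
        cbind(sex = sex, trait = "ldl", rbind(ff$log, pruned@log))
      lead <- selectLead(ff$stats)
      note("%s: drug instruments — %d significant, lead %s, %d independent",
           sex, nrow(ff$stats@records), lead, length(pruned@snps))
      list(all = ff$stats, independent = pruned, lead = lead)
    })

    tSel <- tryStage(paste0(sex, "/testosterone_instruments"), function() {
      sig <- .significantOnly(dat$testosterone, th$p, "testosterone")
      # keep the instrument lists disjoint, as with published per-trait
      # instruments: variants significant for the drug biomarker belong to
      # the drug-locus set, not the testosterone set
      drugSig <- dat$ldl@records$snp[!is.na(dat$ldl@records$p) &
                                       dat$ldl@records$p < th$p]
      shared <- intersect(sig@records$snp, drugSig)
      if (length(shared)) {
        state$selLog[[paste0(sex, "_testo_excl")]] <- data.frame(
          sex = sex, trait = "testosterone", snp = shared,
          action = "excluded_drug_locus",
          detail = "significant for the drug biomarker",
          stringsAsFactors = FALSE)
        sig@records <- sig@records[!sig@records$snp %in% shared, ,
                                   drop = FALSE]
        if (nrow(sig@records) == 0L)
          stop("all testosterone SNPs belong to the drug locus")
      }
      ff <- filterByF(sig, th$f)
      if (nrow(ff$stats@records) == 0L)
        stop("entire instrument set dropped at F < ", th$f)
      pruned <- ldPrune(ff$stats, dat$ld, r2Threshold = th$r2)
      state$selLog[[paste0(sex, "_testo")]] <-
        cbind(sex = sex, trait = "testosterone", rbind(ff$log, pruned@log))
      note("%s: testosterone instruments — %d independent (mean F %.1f)",
           sex, length(pruned@snps),
           meanF(subsetSnps(ff$stats, pruned@snps)))
      list(stats = ff$stats, independent = pruned)
    })

    # drug-mimicking exposure on testosterone and on disease
    if (!is.null(sel)) {
      for (outcome in c("testosterone", "ihd")) {
        lab <- sprintf("%s/drug->%s", sex, outcome)
        tryStage(lab, function() {
          hLead <- harmonize(subsetSnps(dat$ldl, sel$lead),
                             subsetSnps(dat[[outcome]], sel$lead))
          est <- mrIVW(hLead)
          state$estimates[[paste0(lab, "/lead")]] <-
            .estRow(sex, "drug_mimic", outcome, "1 lead SNP", est)
          state$objects[[paste0(lab, "/lead")]] <- est
        })
        tryStage(paste0(lab, "/correlated"), function() {
          allSnps <- sel$all@records$snp
          if (length(allSnps) < 2) return(NULL)
          hAll <- harmonize(sel$all, subsetSnps(dat[[outcome]], allSnps))
          hAll <- alignLD(hAll, dat$ld)
          est <- mrIVWCorrelated(hAll, ridge = 1e-6)
          state$estimates[[paste0(lab, "/correlated")]] <-
            .estRow(sex, "drug_mimic", outcome,
                    sprintf("%d correlated SNPs", est@nSnps), est)
          state$objects[[paste0(lab, "/correlated")]] <- est
        })
      }
      gRow <- state$estimates[[sprintf("%s/drug->testosterone/lead", sex)]]
      if (!is.null(gRow)) {
        investigate <- gRow$p < th$alpha
        state$diags[[paste0(sex, "_gate")]] <- data.frame(
          sex = sex, metric = "drug_testosterone_gate", value = gRow$p,
          detail = sprintf("investigate_further=%s (alpha %.3g)",
                           investigate, th$alpha), stringsAsFactors = FALSE)
        note("%s: gate drug->testosterone p=%.3g, investigate_further=%s",
             sex, gRow$p, investigate)
      }
    }

    # testosterone on disease with sensitivity estimators and Steiger check
    if (!is.null(tSel)) {
      tryStage(paste0(sex, "/testosterone->ihd"), function() {
        tStats <- subsetSnps(tSel$stats, tSel$independent@snps)
        h <- harmonize(tStats, subsetSnps(dat$ihd, tSel$independent@snps))
        est <- mrIVW(h)
        state$estimates[[sprintf("%s/testo_ivw", sex)]] <-
          .estRow(sex, "testosterone", "ihd",
                  sprintf("%d independent SNPs", est@nSnps), est)
        state$objects[[sprintf("%s/testo_ivw", sex)]] <- est
        if (length(h@snps) >= 3) {
          wm <- mrWeightedMedian(h, nBoot = config$nBoot,
                                 seed = config$seed + 1000L)
          state$estimates[[sprintf("%s/testo_wm", sex)]] <-
            .estRow(sex, "testosterone", "ihd",
                    sprintf("%d independent SNPs", wm@nSnps), wm)
          eg <- mrEgger(h)
          state$estimates[[sprintf("%s/testo_egger", sex)]] <-
            .estRow(sex, "testosterone", "ihd",
                    sprintf("%d independent SNPs", eg@nSnps), eg)
          state$objects[[sprintf("%s/testo_egger", sex)]] <- eg
        }
        st <- steigerFilter(h, nExposure = nTotal, nOutcome = nTotal,
                            caseFraction = dat$caseFraction)
        state$objects[[sprintf("%s/steiger", sex)]] <- st
        state$diags[[paste0(sex, "_steiger")]] <- data.frame(
          sex = sex, metric = "steiger_direction", value = NA_real_,
          detail = sprintf("%s (sum r2 exposure %.4g vs outcome %.4g)",
                           st@direction, sum(st@r2Exposure),
                           sum(st@r2Outcome)), stringsAsFactors = FALSE)
        state$diags[[paste0(sex, "_meanF")]] <- data.frame(
          sex = sex, metric = "testosterone_mean_F", value = meanF(h),
          detail = sprintf("%d SNPs", length(h@snps)),
          stringsAsFactors = FALSE)
      })
    }

    # multivariable model pooling the drug and testosterone instruments
    gRow <- state$estimates[[sprintf("%s/drug->testosterone/lead", sex)]]
    gateBlocks <- config$gateOnExposureOutcomeP && !is.null(gRow) &&
      gRow$p >= th$alpha
    if (gateBlocks)
      note("%s: multivariable stage gated off (drug->testosterone p >= alpha)",
           sex)
    if (!is.null(sel) && !is.null(tSel) && !gateBlocks) {
      tryStage(paste0(sex, "/mvmr"), function() {
        pooled <- unique(c(sel$lead, tSel$independent@snps))
        hMV <- harmonize(subsetSnps(dat$ldl, pooled),
                         subsetSnps(dat$ihd, pooled),
                         exposure2 = subsetSnps(dat$testosterone, pooled))
        ivw <- mvmrIVW(hMV)
        egg <- mvmrEgger(hMV)
        state$objects[[sprintf("%s/mvmr_ivw", sex)]] <- ivw
        state$objects[[sprintf("%s/mvmr_egger", sex)]] <- egg
        for (fit in list(ivw, egg)) {
          e <- fit@estimates
          state$mvmr[[paste0(sex, fit@method)]] <- data.frame(
            sex = sex, exposure = c("drug_mimic", "testosterone"),
            instrumented_by = sprintf("%d pooled SNPs", fit@J),
            adjusted_for = c("testosterone", "drug_mimic"),
            method = fit@method, beta = e$beta, or = exp(e$beta),
            ci_low = e$ciLow, ci_high = e$ciHigh, p = e$p,
            egger_intercept_p = fit@eggerInterceptP,
            stringsAsFactors = FALSE)
        }
        qv <- heterogeneityQ(ivw)
        eggerPrimary <- qv[["p"]] < th$alpha &&
          !is.na(egg@eggerInterceptP) && egg@eggerInterceptP < th$alpha
        state$diags[[paste0(sex, "_mvmrQ")]] <- data.frame(
          sex = sex, metric = "mvmr_Q_validity", value = qv[["Q"]],
          detail = sprintf("df %g, p %.3g; egger_primary=%s", qv[["df"]],
                           qv[["p"]], eggerPrimary),
          stringsAsFactors = FALSE)
        cf <- ivw@conditionalF
        state$diags[[paste0(sex, "_condF")]] <- data.frame(
          sex = sex, metric = sprintf("conditional_F_%s", names(cf)),
          value = unname(cf), detail = sprintf("J %d", ivw@J),
          stringsAsFactors = FALSE)
        note("%s: MVMR J=%d, Q=%.2f (p %.3g), conditional F %s", sex,
             ivw@J, qv[["Q"]], qv[["p"]],
             paste(sprintf("%.2f", cf), collapse = "/"))
      })
    }
  }

  # cross-sex contrasts
  obj <- state$objects
  tryStage("contrasts/meta_mvmr_egger_drug", function() {
    em <- obj[["male/mvmr_egger"]]; ew <- obj[["female/mvmr_egger"]]
    if (is.null(em) || is.null(ew)) stop("multivariable Egger missing")
    asMR <- function(fit) mrEstimate("mvmr_egger",
      fit@estimates$beta[1L], fit@estimates$se[1L], fit@J,
      scale = fit@scale)
    pooled <- fixedEffectMeta(list(asMR(em), asMR(ew)))
    state$objects[["meta_mvmr_egger_drug"]] <- pooled
    state$contrasts[["meta"]] <- data.frame(
      label = "drug_mimic on ihd, MVMR-Egger, sexes pooled",
      beta_m = em@estimates$beta[1L], beta_w = ew@estimates$beta[1L],
      z = NA_real_, p = pooled@p, pooled_beta = pooled@beta,
      pooled_or = exp(pooled@beta), pooled_ci_low = exp(pooled@ciLow),
      pooled_ci_high = exp(pooled@ciHigh), attenuation = NA_real_,
      stringsAsFactors = FALSE)
  })
  tryStage("contrasts/testosterone_z", function() {
    pick <- function(o) if (is(o, "MVMRResult"))
      mrEstimate("mvmr_ivw", o@estimates$beta[2L], o@estimates$se[2L],
                 o@J, scale = o@scale) else o
    for (layer in c("uni", "multi")) {
      em <- if (layer == "uni") obj[["male/testo_ivw"]]
            else obj[["male/mvmr_ivw"]]
      ew <- if (layer == "uni") obj[["female/testo_ivw"]]
            else obj[["female/mvmr_ivw"]]
      if (is.null(em) || is.null(ew)) next
      zt <- sexDifferenceZ(pick(em), pick(ew))
      state$contrasts[[paste0("z_", layer)]] <- data.frame(
        label = sprintf("testosterone on ihd, %svariable, men vs women",
                        layer),
        beta_m = pick(em)@beta, beta_w = pick(ew)@beta, z = zt[["z"]],
        p = zt[["p"]], pooled_beta = NA_real_, pooled_or = NA_real_,
        pooled_ci_low = NA_real_, pooled_ci_high = NA_real_,
        attenuation = NA_real_, stringsAsFactors = FALSE)
    }
  })
  tryStage("contrasts/attenuation", function() {
    for (sex in c("male", "female")) {
      uni <- obj[[sprintf("%s/drug->ihd/lead", sex)]]
      mv <- obj[[sprintf("%s/mvmr_ivw", sex)]]
      if (is.null(uni) || is.null(mv)) next
      multi <- mrEstimate("mvmr_ivw", mv@estimates$beta[1L],
                          mv@estimates$se[1L], mv@J, scale = mv@scale)
      at <- mediationAttenuation(uni, multi,
        label = sprintf("%s drug_mimic on ihd: univariable vs multivariable",
                        sex))
      state$objects[[sprintf("%s/attenuation", sex)]] <- at
      state$contrasts[[paste0("att_", sex)]] <- data.frame(
        label = at@label, beta_m = NA_real_, beta_w = NA_real_,
        z = NA_real_, p = NA_real_, pooled_beta = NA_real_,
        pooled_or = NA_real_, pooled_ci_low = NA_real_,
        pooled_ci_high = NA_real_,
        attenuation = at@attenuation[["proportion_attenuated"]],
        stringsAsFactors = FALSE)
    }
  })

  result <- list(
    estimates = .bindRows(state$estimates),
    mvmr = .bindRows(state$mvmr),
    diagnostics = .bindRows(state$diags),
    contrasts = .bindRows(state$contrasts),
    selectionLog = .bindRows(state$selLog),
    objects = state$objects, log = state$log, config = config)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, file) {
      if (is.null(df)) df <- data.frame(note = "no rows produced")
      utils::write.table(df, file.path(outDir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wr(result$estimates, "estimates.tsv")
    wr(result$mvmr, "mvmr.tsv")
    wr(result$diagnostics, "diagnostics.tsv")
    wr(result$contrasts, "contrasts.tsv")
    wr(result$selectionLog, "selection_log.tsv")
    writeLines(result$log, file.path(outDir, "run_log.txt"))
    yaml::write_yaml(list(
      package = "drugTargetMR",
      version = as.character(utils::packageVersion("drugTargetMR")),
      seed = config$seed, thresholds = th,
      scenario = if (is.character(config$scenario)) config$scenario
                 else config$scenario$preset %||% "custom",
      nBoot = config$nBoot), file.path(outDir, "run_manifest.yaml"))
  }
  invisible(result)
}
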