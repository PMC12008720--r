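#' Preprocess one recording to subject-level wPLI adjacency
#'
#' The fixed conditioning order: (optional) down-sample to `analysis_fs`,
#' average re-reference, broadband zero-phase band-pass, 60 s discard +
#' 20 s epoching, Welch cross-spectra, per-epoch band wPLI, epoch average.
#' Permuting the average reference with the (linear) filter leaves the
#' output unchanged; the order above is the one logged. The artifact-removal
#' hook (`artifact_fun`) is a no-op by default: synthetic recordings are
#' artifact-free, and ICA cleaning of real data happens upstream.
#'
#' @param rec A [recording()].
#' @param band Analysis band in Hz (default alpha `c(8, 13)`).
#' @param analysis_fs Rate to down-sample to when `rec$fs` is higher
#'   (default 256 Hz).
#' @param broadband Broadband filter edges (default `c(0.5, 40)`).
#' @param discard_s,epoch_s Epoching contract (defaults 60 / 20 s).
#' @param window_s,overlap_frac Welch parameters (defaults 0.5 s / 0.5).
#' @param artifact_fun Optional `function(recording) recording` hook applied
#'   after re-referencing.
#' @return A subject-level `connectivity_matrix` (epoch-averaged).
#' @export
recording_to_adjacency <- function(rec, band = c(8, 13), analysis_fs = 256,
                                   broadband = c(0.5, 40),
                                   discard_s = 60, epoch_s = 20,
                                   window_s = 0.5, overlap_frac = 0.5,
                                   artifact_fun = NULL) {
  if (rec$fs > analysis_fs) rec <- resample_recording(rec, analysis_fs)
  rec <- rereference_average(rec)
  if (!is.null(artifact_fun)) rec <- artifact_fun(rec)
  rec <- bandpass(rec, broadband[1], broadband[2])
  ep <- epoch_recording(rec, discard_s = discard_s, epoch_s = epoch_s)
  cs <- cross_spectra(ep, window_s = window_s, overlap_frac = overlap_frac,
                      fmax = broadband[2] + 2)
  subject_adjacency(wpli_band(cs, band))
}

#' Graph-metric feature table for a simulated cohort
#'
#' Streams through the cohort subject by subject (recordings are regenerated
#' from the ground-truth seeds when they were not kept), computes the
#' subject adjacency per condition and band, and the global graph measures
#' on the full montage and each requested electrode subset.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param bands Named list of bands (default alpha; add
#'   `theta = c(4, 8)` for the exploratory run).
#' @param subsets Electrode subset sizes to add (default none; e.g.
#'   `c(64, 32, 24)`); ignored for montages smaller than the subset.
#' @param ... Passed to [recording_to_adjacency()].
#' @return Tidy `data.frame`: subject_id, condition, band, electrode_set,
#'   C, L, n_unreachable.
#' @export
cohort_graph_features <- function(cohort, bands = list(alpha = c(8, 13)),
                                  subsets = integer(0), ...) {
  cfg <- cohort$config
  full_labels <- channel_labels_for(cfg$n_channels)
  sub_defs <- list()
  for (s in subsets) {
    sl <- montage_labels(s)
    if (all(sl %in% full_labels)) {
      sub_defs[[as.character(s)]] <-
        electrode_subset(s, montage = full_labels)
    }
  }
  out <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    for (cond in cfg$conditions) {
      rec <- if (!is.null(cohort$recordings)) {
        cohort$recordings[[sid]][[cond]]
      } else {
        seed_col <- paste0("eeg_seed_", cond)
        simulate_subject_eeg(cfg, cohort$ground_truth$severity[i],
                             cohort$ground_truth[[seed_col]][i],
                             condition = cond, subject_id = sid)
      }
      for (bn in names(bands)) {
        adj <- recording_to_adjacency(rec, band = bands[[bn]], ...)
        gm <- graph_metrics(adj, electrode_set = as.character(cfg$n_channels))
        gm$band <- bn
        out[[length(out) + 1L]] <- gm
        for (sd_ in sub_defs) {
          sm <- subset_metrics(adj, sd_)
          sm$band <- bn
          out[[length(out) + 1L]] <- sm
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Assemble the per-subject analysis table
#'
#' Joins the subject table (demographics, amyloid, per-region tau) with the
#' primary graph metrics (given band/condition/electrode set) and computes
#' the composite VOI columns (`dvr_early_metaVOI`, `dvr_neocortical`,
#' aggregated `tau_hippocampus`, `tau_parahippocampus`).
#'
#' @param subjects Subject table from [simulate_cohort()] (or read from
#'   `cohort.tsv`).
#' @param features Graph feature table from [cohort_graph_features()].
#' @param band,condition,electrode_set Which feature stratum becomes the
#'   `C`/`L` columns.
#' @param voxel_counts Named voxel counts per region (default
#'   [default_voxel_counts()]).
#' @return One row per subject with `C` and `L` columns attached.
#' @export
build_feature_table <- function(subjects, features, band = "alpha",
                                condition = "eyes_closed",
                                electrode_set = NULL,
                                voxel_counts = default_voxel_counts()) {
  f <- features[features$band == band & features$condition == condition, ]
  if (!is.null(electrode_set)) {
    f <- f[f$electrode_set == as.character(electrode_set), ]
  } else {
    biggest <- max(as.integer(f$electrode_set))
    f <- f[f$electrode_set == as.character(biggest), ]
  }
  tab <- merge(subjects, f[, c("subject_id", "C", "L")], by = "subject_id",
               sort = FALSE)
  region_cols <- grep("^tau_", names(tab), value = TRUE)
  regions <- sub("^tau_", "", region_cols)
  voi_cols <- function(voi) {
    idx <- match(voi$members, regions)
    if (anyNA(idx)) return(rep(NA_real_, nrow(tab)))
    v <- voxel_counts[voi$members]
    as.numeric(as.matrix(tab[, region_cols[idx], drop = FALSE]) %*% v / sum(v))
  }
  tab$dvr_early_metaVOI <- voi_cols(voi_definition("early_metaVOI"))
  tab$dvr_neocortical <- voi_cols(voi_definition("neocortical_VOI"))
  tab$tau_hippocampus <- voi_cols(voi_definition("hippocampus"))
  tab$tau_parahippocampus <- voi_cols(voi_definition("parahippocampus"))
  tab
}

stage_try <- function(log, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    structure(list(stage = name, reason = conditionMessage(e)),
              class = "stage_skip")
  })
  if (inherits(res, "stage_skip")) {
    log$skipped[[name]] <- res$reason
    log$value <- NULL
  } else {
    log$value <- res
  }
  log
}

#' Run the full statistical battery on an assembled feature table
#'
#' Reproduces the study's analysis structure on one feature table:
#' \itemize{
#'   \item whole-group regressions of C and L on early-metaVOI tau + age +
#'     sex + APOE;
#'   \item gatekept per-subgroup Spearman and partial (age, sex)
#'     correlations and per-region analyses -- these run only when the primary regression's tau term is
#'     significant (gatekeeping, so no multiplicity correction inside);
#'   \item Kruskal-Wallis + Dunn group comparisons of C and L;
#'   \item amyloid-Centiloid regression (CL + age + sex) restricted to the
#'     cognitively unimpaired;
#'   \item tau-positivity split (mean + 1 SD of the CU- reference) with
#'     normality-gated two-group comparisons;
#'   \item neuropsych factor analysis, Thurstone scores, and their partial
#'     (age, sex, education) correlations with tau and the graph measures;
#'   \item neocortical-VOI regressions;
#'   \item when the full feature table is supplied (`features` +
#'     `subjects`), exploratory reruns of the primary regressions for every
#'     other stratum present -- theta band, eyes-open condition,
#'     reduced electrode sets (`strata` in the output).
#' }
#' Stages whose inputs are missing or degenerate are skipped with a logged
#' reason instead of failing the run.
#'
#' @param table Feature table from [build_feature_table()].
#' @param features,subjects Optional: the full tidy feature table from
#'   [cohort_graph_features()] plus the subject table, enabling the
#'   stratified exploratory reruns.
#' @param alpha Significance level used by the gatekeeping rule
#'   (default 0.05).
#' @param region_vars Tau columns for the gatekept per-region stage.
#' @param dunn_adjust Adjustment for Dunn pairs (default `"holm"`).
#' @param region_adjust Adjustment across the per-region correlation family
#'   (default `"BH"`, i.e. FDR).
#' @return List of result tables plus `log` (skipped stages, gate status,
#'   n).
#' @export
run_full_analysis <- function(table, alpha = 0.05,
                              region_vars = c("tau_entorhinal",
                                              "tau_perirhinal",
                                              "tau_hippocampus",
                                              "tau_parahippocampus",
                                              "tau_fusiform"),
                              dunn_adjust = "holm",
                              region_adjust = "BH",
                              features = NULL, subjects = NULL) {
  out <- list()
  log <- list(skipped = list(), n = nrow(table))
  groups <- table$group

  ## (a) primary whole-group regressions
  primary <- list()
  for (oc in c("C", "L")) {
    log <- stage_try(log, paste0("primary_", oc),
                     fit_primary_regression(table, oc, "dvr_early_metaVOI"))
    primary[[oc]] <- log$value
  }
  out$primary <- primary
  tau_sig <- vapply(primary, function(r) {
    if (is.null(r)) FALSE else
      regression_term(r, "dvr_early_metaVOI")$p < alpha
  }, TRUE)
  log$gate_open <- any(tau_sig)

  ## (b) gatekept subgroup correlations
  if (log$gate_open) {
    rows <- list()
    for (g in unique(groups)) {
      sub <- table[groups == g, ]
      for (oc in c("C", "L")) {
        plain <- tryCatch(
          spearman_partial(sub$dvr_early_metaVOI, sub[[oc]]),
          error = function(e) NULL)
        part <- tryCatch(
          spearman_partial(sub$dvr_early_metaVOI, sub[[oc]],
                           covariates = sub[, c("age", "sex")]),
          error = function(e) NULL)
        if (is.null(plain)) next
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, outcome = oc, rho = plain$rho,
          ci_lo = plain$ci[1], ci_hi = plain$ci[2], p = plain$p,
          rho_partial = if (is.null(part)) NA else part$rho,
          p_partial = if (is.null(part)) NA else part$p,
          n = plain$n, stringsAsFactors = FALSE)
      }
    }
    out$subgroup_corr <- do.call(rbind, rows)
  } else {
    log$skipped[["subgroup_corr"]] <-
      "gate closed: primary tau term not significant"
  }

  ## (c) group comparisons of the graph measures
  group_tests <- list()
  for (oc in c("C", "L")) {
    log <- stage_try(log, paste0("kruskal_", oc),
                     kruskal_dunn(table[[oc]], groups, adjust = dunn_adjust))
    group_tests[[oc]] <- log$value
  }
  out$group_tests <- group_tests

  ## (d) amyloid regression in the cognitively unimpaired
  cu <- table[groups %in% c("CU-", "CU+"), ]
  amyloid <- list()
  for (oc in c("C", "L")) {
    log <- stage_try(log, paste0("amyloid_", oc),
                     fit_primary_regression(cu, oc, "cl_amyloid",
                                            covariates = c("age", "sex")))
    amyloid[[oc]] <- log$value
  }
  out$amyloid <- amyloid

  ## gatekept per-region analyses
  if (log$gate_open) {
    reg_rows <- list(); corr_rows <- list()
    for (rv in intersect(region_vars, names(table))) {
      for (oc in c("C", "L")) {
        fit <- tryCatch(fit_primary_regression(table, oc, rv),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          tt <- regression_term(fit, rv)
          reg_rows[[length(reg_rows) + 1L]] <- data.frame(
            region = rv, outcome = oc, beta_tau = tt$beta, p_tau = tt$p,
            overall_p = fit$overall_p, n = fit$n, stringsAsFactors = FALSE)
        }
        cup <- table[groups == "CU+", ]
        part <- tryCatch(
          spearman_partial(cup[[rv]], cup[[oc]],
                           covariates = cup[, c("age", "sex")]),
          error = function(e) NULL)
        plain <- tryCatch(spearman_partial(cup[[rv]], cup[[oc]]),
                          error = function(e) NULL)
        if (!is.null(plain)) {
          corr_rows[[length(corr_rows) + 1L]] <- data.frame(
            region = rv, outcome = oc, rho = plain$rho, p = plain$p,
            rho_partial = if (is.null(part)) NA else part$rho,
            p_partial = if (is.null(part)) NA else part$p,
            n = plain$n, stringsAsFactors = FALSE)
        }
      }
    }
    out$region_regressions <- do.call(rbind, reg_rows)
    rc <- do.call(rbind, corr_rows)
    if (!is.null(rc)) {
      rc$p_adj <- NA_real_
      for (oc in unique(rc$outcome)) {
        sel <- rc$outcome == oc
        rc$p_adj[sel] <- fdr_adjust(rc$p[sel])
      }
    }
    out$region_corr_cu_pos <- rc
  } else {
    log$skipped[["region_analyses"]] <-
      "gate closed: primary tau term not significant"
  }

  ## tau-positivity split
  cu_neg <- table[groups == "CU-", ]
  tau_split <- list()
  for (voi in c("dvr_early_metaVOI", "dvr_neocortical")) {
    log <- stage_try(log, paste0("tau_split_", voi), {
      thr <- tau_positivity_threshold(cu_neg[[voi]])
      status <- classify_tau(table[[voi]], thr)
      comp <- lapply(stats::setNames(c("C", "L"), c("C", "L")),
                     function(oc) two_group_compare(table[[oc]], status))
      list(threshold = as.numeric(thr), threshold_n = attr(thr, "n"),
           n_positive = sum(status == "positive"),
           n_negative = sum(status == "negative"),
           compare = comp)
    })
    tau_split[[voi]] <- log$value
  }
  out$tau_split <- tau_split

  ## neuropsych factor pipeline
  np_cols <- rownames(default_factor_loadings())
  if (all(np_cols %in% names(table))) {
    log <- stage_try(log, "factor_model", {
      fm <- factor_analysis(table[, np_cols], n_factors = 2)
      sc <- thurstone_scores(fm, table[, np_cols])
      corr <- list()
      covs <- table[, c("age", "sex", "education")]
      for (fx in colnames(sc)) {
        for (v in c("dvr_early_metaVOI", "C", "L")) {
          corr[[paste(fx, v, sep = "_vs_")]] <- tryCatch(
            spearman_partial(sc[, fx], table[[v]], covariates = covs),
            error = function(e) NULL)
        }
      }
      list(model = fm, scores = sc, correlations = corr)
    })
    out$factor <- log$value
  } else {
    log$skipped[["factor_model"]] <- "neuropsych test columns missing"
  }

  ## neocortical VOI regressions
  neo <- list()
  for (oc in c("C", "L")) {
    log <- stage_try(log, paste0("neocortical_", oc),
                     fit_primary_regression(table, oc, "dvr_neocortical"))
    neo[[oc]] <- log$value
  }
  out$neocortical <- neo

  ## exploratory stratum reruns (theta band, eyes-open, electrode subsets)
  if (!is.null(features) && !is.null(subjects)) {
    strata <- unique(features[, c("band", "condition", "electrode_set")])
    rows <- list()
    for (r in seq_len(nrow(strata))) {
      st <- strata[r, ]
      tab_s <- tryCatch(
        build_feature_table(subjects, features, band = st$band,
                            condition = st$condition,
                            electrode_set = st$electrode_set),
        error = function(e) NULL)
      if (is.null(tab_s)) next
      for (oc in c("C", "L")) {
        fit <- tryCatch(
          fit_primary_regression(tab_s, oc, "dvr_early_metaVOI"),
          error = function(e) NULL)
        if (is.null(fit)) next
        tt <- regression_term(fit, "dvr_early_metaVOI")
        rows[[length(rows) + 1L]] <- data.frame(
          band = st$band, condition = st$condition,
          electrode_set = st$electrode_set, outcome = oc,
          beta_tau = tt$beta, p_tau = tt$p, overall_p = fit$overall_p,
          n = fit$n, stringsAsFactors = FALSE)
      }
    }
    out$strata <- do.call(rbind, rows)
  }

  log$value <- NULL
  out$log <- log
  out
}

#' Write the analysis bundle as one TSV per result table
#'
#' @param results Result of [run_full_analysis()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis_tsv <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    if (!is.null(df) && nrow(df) > 0) {
      utils::write.table(df, file.path(dir, file), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  reg_df <- function(lst) {
    do.call(rbind, lapply(names(lst), function(oc) {
      r <- lst[[oc]]
      if (is.null(r)) return(NULL)
      cbind(outcome = oc, r$coefficients,
            overall_p = r$overall_p, n = r$n)
    }))
  }
  wt(reg_df(results$primary), "table3_regression.tsv")
  wt(results$subgroup_corr, "table4_subgroup_corr.tsv")
  kw <- results$group_tests
  if (!is.null(kw)) {
    kw_df <- do.call(rbind, lapply(names(kw), function(oc) {
      if (is.null(kw[[oc]])) return(NULL)
      data.frame(outcome = oc, H = kw[[oc]]$H, df = kw[[oc]]$df,
                 p = kw[[oc]]$p)
    }))
    wt(kw_df, "table5_group_metrics.tsv")
    dunn <- do.call(rbind, lapply(names(kw), function(oc) {
      if (is.null(kw[[oc]])) return(NULL)
      cbind(outcome = oc, kw[[oc]]$pairs)
    }))
    wt(dunn, "table5_dunn_pairs.tsv")
  }
  wt(results$region_regressions, "table6_region_regressions.tsv")
  wt(results$region_corr_cu_pos, "table6_region_corr.tsv")
  wt(reg_df(results$amyloid), "amyloid_regression.tsv")
  wt(reg_df(results$neocortical), "neocortical_regression.tsv")
  wt(results$strata, "exploratory_strata.tsv")
  skips <- results$log$skipped
  manifest <- list(n = results$log$n, gate_open = results$log$gate_open,
                   skipped = if (length(skips)) skips else NULL)
  yaml::write_yaml(manifest, file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}
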