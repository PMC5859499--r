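# End-to-end orchestration of the two-phase workflow:
# profile -> design -> predict -> measure/compare -> variance decomposition
# -> Bayesian bias assessment.

#' Run the full reference-sample design and assessment pipeline
#'
#' Simulates (or accepts) the profiling and mixture phases, searches the
#' design grid, predicts the mixture pair in silico, computes dCq/ddCq
#' summaries, decomposes variance, and fits the Bayesian mixed-effects
#' model per target analyte with marginal-likelihood scenario comparison.
#'
#' @param config a [simulation_config()] (also supplies the mixture
#'   designs).
#' @param seed integer seed controlling all randomness.
#' @param profiling,rna_mix,cell_mix optional well-level Cq tables; when
#'   `NULL` they are simulated from `config` and `seed`.
#' @param control_analyte control assay for ddCq (default `"MIR-16"`).
#' @param variant Bayesian model variant(s) to fit (default 1).
#' @param mcmc list overriding the MCMC schedule
#'   (`n_chains`, `n_iter`, `burn_in`, `thin`).
#' @param design_grid per-component weights for the design search grid.
#' @param out_dir if non-`NULL`, writes tables (CSV), a machine-readable
#'   `summary.json` stamped with seed and config hash, and plots (PDF).
#' @return (invisibly when writing) list with elements `profiles`,
#'   `insilico`, `rna_mix`, `cell_mix` (collapsed tables), `design_ranking`,
#'   `dcq` (per-replicate and summaries), `anova`, `bayes` (per analyte:
#'   curves and scenario comparison), `truth`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = simulation_config(), seed = 1,
                         profiling = NULL, rna_mix = NULL, cell_mix = NULL,
                         control_analyte = "MIR-16", variant = 1,
                         mcmc = list(), design_grid = c(1, 3),
                         out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  mc <- utils::modifyList(list(n_chains = 2, n_iter = 2500, burn_in = 500,
                               thin = 1), mcmc)
  if (is.null(profiling)) profiling <- simulate_profiling_phase(config, seed)
  if (is.null(rna_mix)) {
    rna_mix <- simulate_mixture_phase(config, "rna_mixture", seed + 1000L)
  }
  if (is.null(cell_mix)) {
    cell_mix <- simulate_mixture_phase(config, "cell_mixture", seed + 2000L)
  }
  profiles <- collapse_wells(profiling)
  rna_c <- collapse_wells(rna_mix)
  cell_c <- collapse_wells(cell_mix)
  targets <- setdiff(unique(profiles$analyte), toupper(control_analyte))

  # --- design search over the grid ------------------------------------
  prof_targets <- profiles[profiles$analyte %in% targets, , drop = FALSE]
  pairs <- enumerate_designs(colnames(config$cell_means), design_grid)
  candidates <- lapply(pairs, score_design_pair, profiles = prof_targets)
  ranking <- rank_designs(candidates)

  # --- in-silico prediction of the configured pair --------------------
  insilico <- predict_pair_profiles(prof_targets, config$designs)

  # --- dCq / ddCq ------------------------------------------------------
  dcq_insilico <- delta_cq(insilico, pairing = "plate")
  dcq_rna <- delta_cq(rna_c[rna_c$analyte %in% targets, ])
  dcq_cell <- delta_cq(cell_c[cell_c$analyte %in% targets, ])
  ddcq_rna <- delta_delta_cq(rna_c, control = control_analyte)
  dcq <- list(
    insilico = dcq_insilico, rna = dcq_rna, cell = dcq_cell,
    ddcq_rna = ddcq_rna,
    rna_by_isolation = summarize_dcq(dcq_rna, "by_isolation"),
    cell_by_plate = summarize_dcq(dcq_cell, "by_plate"))

  # --- variance decomposition -----------------------------------------
  anova_profiling <- factorial_anova(
    profiles, c("analyte", "sample", "isolation_lab", "isolation_rep",
                "pcr_lab"), "cq")
  anova_rna <- factorial_anova(
    rna_c, c("analyte", "sample", "isolation_rep", "pcr_lab"), "cq")
  anova_rna_dcq <- factorial_anova(
    dcq_rna, c("analyte", "isolation_rep", "pcr_lab"), "dcq")

  # --- Bayesian bias assessment ---------------------------------------
  combined <- rbind(insilico, rna_c, cell_c)
  scen <- scenario_table()
  bayes <- lapply(stats::setNames(targets, targets), function(an) {
    fit <- fit_mixed_model(combined, an, variant = variant[1L],
                           seed = seed + 1L, n_chains = mc$n_chains,
                           n_iter = mc$n_iter, burn_in = mc$burn_in,
                           thin = mc$thin)
    curves <- list()
    for (k in seq_len(nrow(scen))) {
      s <- scen[k, ]
      src <- if (s$source == "PURE_CELL_LINE") "IN_SILICO_MIXTURE" else
        s$source
      w <- try(dcq_weights(fit, source = src,
                           isolation_lab = s$isolation_lab,
                           pcr_lab = s$pcr_lab), silent = TRUE)
      if (inherits(w, "try-error")) next
      lab <- paste0("scenario", s$scenario_id)
      curves[[lab]] <- marginal_likelihood_curve(fit, w, label = lab)
    }
    list(fit_diagnostics = fit$diagnostics, curves = curves,
         comparison = compare_scenarios(curves))
  })

  result <- list(profiles = profiles, insilico = insilico, rna_mix = rna_c,
                 cell_mix = cell_c, design_ranking = ranking, dcq = dcq,
                 anova = list(profiling = anova_profiling, rna = anova_rna,
                              rna_dcq = anova_rna_dcq),
                 bayes = bayes, truth = simulation_truth(config),
                 seed = seed, config_hash = .config_hash(config))
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = result$seed, config_hash = result$config_hash)
  write_cq_table(result$profiles, file.path(out_dir, "profiles.csv"))
  write_cq_table(result$insilico, file.path(out_dir, "insilico.csv"))
  utils::write.csv(result$dcq$rna_by_isolation,
                   file.path(out_dir, "dcq_rna_by_isolation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$dcq$cell_by_plate,
                   file.path(out_dir, "dcq_cell_by_plate.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$anova$profiling),
                   file.path(out_dir, "anova_profiling.csv"),
                   row.names = FALSE)
  peaks <- lapply(result$bayes, function(b) {
    lapply(b$curves, function(cv) cv$peak)
  })
  summary <- c(stamp, list(
    n_feasible_designs = length(result$design_ranking),
    top_design = if (length(result$design_ranking) > 0L) {
      cand <- result$design_ranking[[1L]]
      list(mix1 = cand$pair[[1L]]$fractions,
           mix2 = cand$pair[[2L]]$fractions, score = cand$score)
    },
    dcq_peaks = peaks,
    true_dcq = result$truth))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (length(result$design_ranking) > 0L) {
    print(plot_bland_altman(result$design_ranking[[1L]]$points))
  }
  print(plot_variance_table(filter_report(result$anova$profiling)))
  for (an in names(result$bayes)) {
    print(plot_likelihood_curves(result$bayes[[an]]$curves,
                                 title = paste("Average dCq,", an)))
  }
  invisible(out_dir)
}

#' Bland-Altman plot of a design's per-analyte geometry
#'
#' Mean Cq on the x axis (reversed: right = more abundant) against dCq on
#' the y axis (reversed: down = more abundant in Mix1).
#'
#' @param points data.frame from [bland_altman()] (or a
#'   `design_candidate$points`).
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(points) {
  ggplot2::ggplot(points,
                  ggplot2::aes(x = .data$mean_cq, y = .data$delta_cq,
                               label = .data$analyte)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "mean Cq (Mix1, Mix2)", y = "dCq (Mix1 - Mix2)") +
    ggplot2::theme_bw()
}

#' Bar chart of a variance table (log scale)
#'
#' @param table a `variance_table`.
#' @return a ggplot object.
#' @export
plot_variance_table <- function(table) {
  df <- as.data.frame(table)
  df <- df[!is.na(df$ms), , drop = FALSE]
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$ms)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean square (Cq^2)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Overlayed marginal-likelihood curves
#'
#' @param curves list of `likelihood_curve` objects.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_likelihood_curves <- function(curves, title = NULL) {
  labels <- names(curves)
  if (is.null(labels)) labels <- vapply(curves, `[[`, character(1), "label")
  df <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(curve = labels[i], x = curves[[i]]$grid,
               likelihood = curves[[i]]$likelihood,
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$likelihood,
                                   colour = .data$curve)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "average dCq (cycles)", y = "marginal likelihood",
                  title = title) +
    ggplot2::theme_bw()
}
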