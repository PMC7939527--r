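#' Pipeline configuration
#'
#' Collects every stage threshold under the defaults used throughout the
#' package (the values carried by each stage's own signature), plus the
#' seed and age cutoff. Configs round-trip losslessly through YAML when
#' the `yaml` package is available.
#'
#' @param q_threshold FDR threshold for DMP and DEG calls.
#' @param delta_threshold Minimum |Delta beta| for DMP calls.
#' @param stringent Named list of stringent-filter thresholds (see
#'   [apply_stringent_filters()]).
#' @param dmr_max_gap,dmr_min_probes,dmr_min_delta DMR rule parameters.
#' @param hmc_score_threshold,hmc_min_samples,hmc_density_quantile 5hmC
#'   call parameters.
#' @param methylated_threshold State-assignment beta cutoff.
#' @param rho_threshold Dyad selection threshold on |Spearman rho|.
#' @param enrichment_correction `"bonferroni"` or `"bh"`.
#' @param age_cutoff AYA/MOA age cutoff in years.
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(q_threshold = 0.05,
                            delta_threshold = 0.2,
                            stringent = list(delta_min = 0.20, frac_min = 0.70,
                                             n_sd = 2, ntl_max_hyper = 0.25,
                                             ntl_min_hypo = 0.25, sd_floor = 0.01),
                            dmr_max_gap = 250, dmr_min_probes = 2,
                            dmr_min_delta = 0.2,
                            hmc_score_threshold = 0.3, hmc_min_samples = 3,
                            hmc_density_quantile = 0.75,
                            methylated_threshold = 0.3,
                            rho_threshold = 0.5,
                            enrichment_correction = "bonferroni",
                            age_cutoff = 44,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full integrative pipeline on a dataset
#'
#' Chains cohort summary, DMP testing/calling/stringent filtering, DMR
#' calling, 5hmC scoring and transition classification, paired
#' differential expression, and gene-level integration with enrichment,
#' and returns one report object. Inputs are either a [simulate_dataset()]
#' result or a list with the same elements read from disk
#' (`manifest`, `sheet`, `beta_bs`, `beta_oxbs`, `expression`,
#' `genesets`; per-tissue beta submatrices are derived from the sheet if
#' absent).
#'
#' @param data Dataset list (see above).
#' @param config A [pipeline_config()].
#' @param exclusion Optional age-related probe exclusion list (ids or
#'   file path).
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `dmp_tests`, `dmps`, `dmrs`, `hmc_hcc`, `hmc_ntl`, `transitions`,
#'   `hmc_context`, `degs`, `dyads`, `enrichment`, `overlaps` and a flat
#'   `report` list of headline counts.
#' @export
run_pipeline <- function(data, config = pipeline_config(), exclusion = character(0)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sheet <- data$sheet
  hcc_ids <- sheet$sample_id[sheet$tissue == "HCC"]
  ntl_ids <- sheet$sample_id[sheet$tissue == "NTL"]
  pick <- function(m, ids) m[, intersect(colnames(m), ids), drop = FALSE]
  beta_bs_hcc <- data$beta_bs_hcc %||% pick(data$beta_bs, hcc_ids)
  beta_bs_ntl <- data$beta_bs_ntl %||% pick(data$beta_bs, ntl_ids)
  beta_ox_hcc <- data$beta_oxbs_hcc %||% pick(data$beta_oxbs, hcc_ids)
  beta_ox_ntl <- data$beta_oxbs_ntl %||% pick(data$beta_oxbs, ntl_ids)

  cohort <- stage("cohort", summarize_cohort(sheet, cutoff = config$age_cutoff))

  dmp_tests <- stage("dmp", test_dmps(beta_bs_hcc, beta_bs_ntl, sheet))
  dmps <- call_dmps(dmp_tests, config$q_threshold, config$delta_threshold)
  dmps <- do.call(apply_stringent_filters,
                  c(list(dmps, beta_bs_hcc, beta_bs_ntl), config$stringent))
  dmps <- exclude_age_related(dmps, exclusion, data$manifest)

  sig <- dmps[!dmps$age_excluded, , drop = FALSE]
  dmrs <- stage("dmr", call_dmrs(dmps_with_positions(sig, data$manifest),
                                 max_gap = config$dmr_max_gap,
                                 min_probes = config$dmr_min_probes,
                                 min_delta = config$dmr_min_delta))

  hmc <- stage("hydroxy", {
    scores_hcc <- compute_scores(beta_bs_hcc, beta_ox_hcc)
    scores_ntl <- compute_scores(beta_bs_ntl, beta_ox_ntl)
    calls_hcc <- call_5hmc(scores_hcc, config$hmc_score_threshold,
                           config$hmc_min_samples, config$hmc_density_quantile)
    calls_ntl <- call_5hmc(scores_ntl, config$hmc_score_threshold,
                           config$hmc_min_samples, config$hmc_density_quantile)
    st_hcc <- assign_state(calls_hcc, beta_ox_hcc, config$methylated_threshold)
    st_ntl <- assign_state(calls_ntl, beta_ox_ntl, config$methylated_threshold)
    list(calls_hcc = calls_hcc, calls_ntl = calls_ntl,
         scores = cbind(scores_hcc, scores_ntl),
         transitions = classify_transitions(st_ntl, st_hcc),
         context = summarize_hydroxy_context(calls_hcc, calls_ntl, data$manifest))
  })

  degs <- stage("dge", test_dge(data$expression, sheet, config$q_threshold))

  dyads <- stage("integrate", {
    d <- merge_layers(degs, dmps, hmc$transitions, data$manifest,
                      data$expression, data$beta_bs, scores = hmc$scores)
    select_dyads(d, config$rho_threshold)
  })
  sel_genes <- unique(dyads$gene_symbol[dyads$selected])
  enrichment <- if (!is.null(data$genesets)) {
    enrich(sel_genes, rownames(data$expression), data$genesets,
           correction = config$enrichment_correction)
  } else NULL
  overlaps <- summary_report(degs, dmps, hmc$transitions, data$manifest)

  report <- list(
    seed = config$seed,
    n_pairs = length(hcc_ids),
    n_probes = nrow(data$beta_bs),
    n_genes = nrow(data$expression),
    n_dmps = nrow(dmps),
    n_stringent_dmps = sum(dmps$passes_stringent & !dmps$age_excluded),
    hyper_dmp_fraction = if (nrow(dmps) > 0) mean(dmps$direction == "hyper") else NA_real_,
    n_dmrs = nrow(dmrs),
    transition_counts = as.list(hmc$transitions$counts),
    n_degs = sum(degs$deg),
    n_dyads = nrow(dyads),
    n_selected_dyads = sum(dyads$selected),
    prc2_enrichment_p = if (!is.null(enrichment) && "PRC2_TARGETS" %in% enrichment$gene_set)
      enrichment$p[enrichment$gene_set == "PRC2_TARGETS"] else NA_real_
  )

  out <- list(cohort = cohort, dmp_tests = dmp_tests, dmps = dmps, dmrs = dmrs,
              hmc_hcc = hmc$calls_hcc, hmc_ntl = hmc$calls_ntl,
              transitions = hmc$transitions, hmc_context = hmc$context,
              degs = degs, dyads = dyads, enrichment = enrichment,
              overlaps = overlaps, report = report)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("Integrative pipeline: %d pairs, %d probes, %d genes\n",
              r$n_pairs, r$n_probes, r$n_genes))
  cat(sprintf("  DMPs: %d called, %d pass stringent filters (%.1f%% hyper)\n",
              r$n_dmps, r$n_stringent_dmps, 100 * r$hyper_dmp_fraction))
  cat(sprintf("  DMRs: %d; transitions I/II/III/IV: %s\n", r$n_dmrs,
              paste(unlist(r$transition_counts), collapse = "/")))
  cat(sprintf("  DEGs: %d; dyads: %d (%d selected at |rho| > threshold)\n",
              r$n_degs, r$n_dyads, r$n_selected_dyads))
  if (!is.na(r$prc2_enrichment_p)) {
    cat(sprintf("  PRC2-target enrichment p = %.3g\n", r$prc2_enrichment_p))
  }
  invisible(x)
}

#' Write the pipeline run report as JSON
#'
#' @param result A [run_pipeline()] result.
#' @param path Output path.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
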