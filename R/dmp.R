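#' Logit (M-value) transform of beta values
#'
#' `M = log2((beta + epsilon) / (1 - beta + epsilon))`. The epsilon offset
#' keeps the transform finite at the boundaries; differential testing is
#' done on M-values (variance stabilization) while effect sizes are
#' reported on the beta scale.
#'
#' @param beta Numeric vector/matrix of beta values in [0, 1].
#' @param epsilon Boundary offset (default 1e-3).
#' @return M-values, same shape as `beta`.
#' @examples
#' beta_to_m(0.5)           # 0
#' beta_to_m(0.8, epsilon = 0) # 2
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  log2((beta + epsilon) / (1 - beta + epsilon))
}

# order the columns of both matrices so column j is the same pair
align_pairs <- function(beta_hcc, beta_ntl, sheet) {
  hcc <- sheet[sheet$tissue == "HCC", c("sample_id", "pair_id")]
  ntl <- sheet[sheet$tissue == "NTL", c("sample_id", "pair_id")]
  m <- merge(hcc, ntl, by = "pair_id", suffixes = c("_hcc", "_ntl"))
  missing <- setdiff(c(m$sample_id_hcc, m$sample_id_ntl),
                     c(colnames(beta_hcc), colnames(beta_ntl)))
  if (length(missing) > 0) {
    stop(sprintf("samples in sheet absent from matrices: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  list(hcc = beta_hcc[, m$sample_id_hcc, drop = FALSE],
       ntl = beta_ntl[, m$sample_id_ntl, drop = FALSE])
}

#' Paired moderated test for differential methylation
#'
#' Transforms both beta matrices to M-values, forms within-pair
#' differences (tumor minus normal), applies the empirical-Bayes moderated
#' paired t-test ([moderated_paired_t()]), and adjusts p-values across all
#' probes by Benjamini-Hochberg.
#'
#' @param beta_hcc,beta_ntl Probes x samples beta matrices for tumor and
#'   matched normal tissue; shared probe rows.
#' @param sheet Sample sheet defining the pairing (columns `sample_id`,
#'   `pair_id`, `tissue`).
#' @param epsilon Offset for [beta_to_m()].
#' @return `data.frame` with columns `probe_id`, `delta_beta` (mean beta
#'   difference, beta scale), `statistic`, `p`, `q`.
#' @export
test_dmps <- function(beta_hcc, beta_ntl, sheet, epsilon = 1e-3) {
  assert_beta_matrix(beta_hcc)
  assert_beta_matrix(beta_ntl)
  if (!identical(rownames(beta_hcc), rownames(beta_ntl))) {
    stop("matrices must share probe rows", call. = FALSE)
  }
  al <- align_pairs(beta_hcc, beta_ntl, sheet)
  if (ncol(al$hcc) < 3) stop("at least 3 pairs are required", call. = FALSE)
  fit <- moderated_paired_t(beta_to_m(al$hcc, epsilon), beta_to_m(al$ntl, epsilon))
  data.frame(
    probe_id = rownames(beta_hcc),
    delta_beta = rowMeans(al$hcc) - rowMeans(al$ntl),
    statistic = fit$statistic,
    p = fit$p,
    q = stats::p.adjust(fit$p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Call differentially methylated positions
#'
#' A probe is a DMP iff `q < q_threshold` and `|delta_beta| >=
#' delta_threshold`; direction is the sign of the mean beta difference.
#'
#' @param tests Output of [test_dmps()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param delta_threshold Minimum |Delta beta| (default 0.2).
#' @return `data.frame` of class `dmp_calls`: the DMP rows of `tests` plus
#'   `direction` (`hyper`/`hypo`). Attribute `n_tested` records the testing
#'   universe size.
#' @export
call_dmps <- function(tests, q_threshold = 0.05, delta_threshold = 0.2) {
  keep <- tests$q < q_threshold & abs(tests$delta_beta) >= delta_threshold
  out <- tests[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta_beta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(tests)
  class(out) <- c("dmp_calls", "data.frame")
  out
}

#' Apply the stringent biological-relevance filters
#'
#' Three per-probe criteria, evaluated on the beta scale:
#' \describe{
#'   \item{c1}{`|mean beta_HCC - mean beta_NTL| >= delta_min` (default 0.20).}
#'   \item{c2}{more than `frac_min` (default 70%) of tumor samples have beta
#'     above the normal mean + 2 SD at that probe (hypermethylated
#'     direction), or below the normal mean - 2 SD (hypomethylated).}
#'   \item{c3}{mean normal beta at the probe is at most `ntl_max_hyper`
#'     (default 0.25) for hypermethylated probes, or at least
#'     `ntl_min_hypo` (default 0.25) for hypomethylated probes.}
#' }
#' A probe passes iff all three hold. When the normal-tissue SD is zero it
#' is floored at `sd_floor` so c2 stays defined.
#'
#' @param dmps [call_dmps()] output.
#' @param beta_hcc,beta_ntl Full beta matrices (all tumor / all normal
#'   samples; c2 uses the distribution over all normal samples).
#' @param delta_min,frac_min,n_sd,ntl_max_hyper,ntl_min_hypo,sd_floor
#'   Filter thresholds, exposed for sensitivity analysis.
#' @return `dmps` with added logical columns `c1`, `c2`, `c3`,
#'   `passes_stringent`.
#' @export
apply_stringent_filters <- function(dmps, beta_hcc, beta_ntl,
                                    delta_min = 0.20, frac_min = 0.70,
                                    n_sd = 2,
                                    ntl_max_hyper = 0.25, ntl_min_hypo = 0.25,
                                    sd_floor = 0.01) {
  if (nrow(dmps) == 0) {
    dmps$c1 <- dmps$c2 <- dmps$c3 <- dmps$passes_stringent <- logical(0)
    return(dmps)
  }
  idx <- match(dmps$probe_id, rownames(beta_hcc))
  if (anyNA(idx)) stop("DMP probes missing from beta matrices", call. = FALSE)
  hcc <- beta_hcc[idx, , drop = FALSE]
  ntl <- beta_ntl[idx, , drop = FALSE]
  ntl_mean <- rowMeans(ntl)
  ntl_sd <- pmax(apply(ntl, 1, stats::sd), sd_floor)
  hyper <- dmps$direction == "hyper"

  dmps$c1 <- abs(rowMeans(hcc) - ntl_mean) >= delta_min
  upper <- ntl_mean + n_sd * ntl_sd
  lower <- ntl_mean - n_sd * ntl_sd
  frac_above <- rowMeans(hcc > upper)
  frac_below <- rowMeans(hcc < lower)
  dmps$c2 <- ifelse(hyper, frac_above > frac_min, frac_below > frac_min)
  dmps$c3 <- ifelse(hyper, ntl_mean <= ntl_max_hyper, ntl_mean >= ntl_min_hypo)
  dmps$passes_stringent <- dmps$c1 & dmps$c2 & dmps$c3
  dmps
}

#' Flag and drop age-related probes
#'
#' Marks DMPs present in a user-supplied exclusion list (e.g. probes known
#' to drift with age) and removes them from downstream summaries. Unknown
#' ids trigger a warning and are ignored.
#'
#' @param dmps [call_dmps()] (optionally filtered) output.
#' @param exclusion Character vector of probe ids, or a path to a text file
#'   with one probe id per line.
#' @param manifest Optional manifest used to warn about unknown ids.
#' @return `dmps` with a logical `age_excluded` column; excluded rows are
#'   retained in the table but flagged.
#' @export
exclude_age_related <- function(dmps, exclusion = character(0), manifest = NULL) {
  if (length(exclusion) == 1 && file.exists(exclusion)) {
    exclusion <- readLines(exclusion, warn = FALSE)
    exclusion <- trimws(exclusion[nzchar(trimws(exclusion))])
  }
  if (!is.null(manifest)) {
    unknown <- setdiff(exclusion, manifest$probe_id)
    if (length(unknown) > 0) {
      warning(sprintf("%d exclusion probe id(s) not in manifest; ignored",
                      length(unknown)))
      exclusion <- setdiff(exclusion, unknown)
    }
  }
  dmps$age_excluded <- dmps$probe_id %in% exclusion
  dmps
}

#' Genomic-context summary of DMP calls
#'
#' Cross-tabulates DMPs (after age exclusion) by direction, CpG-island
#' relation and gene-feature region, and reports the hypermethylated
#' fraction.
#'
#' @param dmps DMP table with `direction` (and optionally `age_excluded`,
#'   `passes_stringent`).
#' @param manifest Probe manifest covering all DMP probes.
#' @param stringent_only If TRUE (default when the column exists), restrict
#'   to probes passing the stringent filters.
#' @return List of class `dmp_context`: `n`, `hyper_fraction`,
#'   `by_island` and `by_feature` (direction x category count tables),
#'   `table` (full cross-tab).
#' @export
summarize_context <- function(dmps, manifest,
                              stringent_only = "passes_stringent" %in% names(dmps)) {
  if ("age_excluded" %in% names(dmps)) dmps <- dmps[!dmps$age_excluded, , drop = FALSE]
  if (stringent_only && "passes_stringent" %in% names(dmps)) {
    dmps <- dmps[dmps$passes_stringent, , drop = FALSE]
  }
  idx <- match(dmps$probe_id, manifest$probe_id)
  if (anyNA(idx)) {
    stop(sprintf("probe(s) missing from manifest: %s",
                 paste(dmps$probe_id[is.na(idx)][1], collapse = ", ")),
         call. = FALSE)
  }
  dir <- factor(dmps$direction, levels = c("hyper", "hypo"))
  isl <- factor(manifest$island_relation[idx], levels = .island_levels)
  fea <- factor(manifest$feature[idx], levels = .feature_levels)
  out <- list(
    n = nrow(dmps),
    hyper_fraction = if (nrow(dmps) > 0) mean(dir == "hyper") else NA_real_,
    by_island = table(direction = dir, island = isl),
    by_feature = table(direction = dir, feature = fea),
    table = table(direction = dir, island = isl, feature = fea)
  )
  class(out) <- "dmp_context"
  out
}

#' @export
print.dmp_context <- function(x, ...) {
  cat(sprintf("%d DMPs (%.1f%% hypermethylated)\n", x$n, 100 * x$hyper_fraction))
  print(x$by_island)
  invisible(x)
}
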