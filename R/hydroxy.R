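#' Per-sample 5hmC scores from paired BS/oxBS beta values
#'
#' Bisulfite arrays read 5mC + 5hmC jointly while oxidative-bisulfite
#' arrays read 5mC only, so their per-sample beta difference estimates the
#' 5hmC fraction: `score = beta_BS - beta_oxBS`. Negative scores (noise)
#' are retained for QC but never produce calls.
#'
#' @param beta_bs,beta_oxbs Probes x samples beta matrices from the
#'   bisulfite and oxidative-bisulfite treatments of the same samples;
#'   identical dimnames required.
#' @return Probes x samples matrix of 5hmC scores in [-1, 1].
#' @examples
#' compute_scores(matrix(0.7), matrix(0.3)) # 0.4
#' @export
compute_scores <- function(beta_bs, beta_oxbs) {
  assert_beta_matrix(beta_bs)
  assert_beta_matrix(beta_oxbs)
  if (!identical(dim(beta_bs), dim(beta_oxbs)) ||
      !identical(dimnames(beta_bs), dimnames(beta_oxbs))) {
    stop("BS and oxBS matrices must share probes and samples", call. = FALSE)
  }
  beta_bs - beta_oxbs
}

#' Call hydroxymethylated probes in one tissue
#'
#' Two-stage rule, applied independently per tissue: a probe is a
#' *candidate* if its 5hmC score is at least `score_threshold` in at least
#' `min_samples` samples; it is a *definite* call if its mean score over
#' the tissue's samples lies at or above the `(1 - density_quantile)`
#' quantile of the candidate mean-score distribution (the default keeps
#' the upper 75% of candidates).
#'
#' @param scores Probes x samples score matrix for one tissue
#'   ([compute_scores()] subset to that tissue's samples).
#' @param score_threshold Minimum per-sample score (default 0.3).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 3).
#' @param density_quantile Fraction of candidates retained by the
#'   mean-score filter (default 0.75); 1 disables the filter.
#' @return `data.frame` of class `hmc_calls`: `probe_id`, `n_above`,
#'   `mean_score`, `candidate`, `definite`.
#' @export
call_5hmc <- function(scores, score_threshold = 0.3, min_samples = 3,
                      density_quantile = 0.75) {
  if (ncol(scores) < min_samples) {
    stop(sprintf("need at least %d samples, have %d", min_samples, ncol(scores)),
         call. = FALSE)
  }
  n_above <- rowSums(scores >= score_threshold)
  mean_score <- rowMeans(scores)
  candidate <- n_above >= min_samples
  definite <- rep(FALSE, nrow(scores))
  if (any(candidate)) {
    cut <- stats::quantile(mean_score[candidate], probs = 1 - density_quantile,
                           type = 7, names = FALSE)
    definite <- candidate & mean_score >= cut
  }
  out <- data.frame(probe_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
                    n_above = n_above, mean_score = mean_score,
                    candidate = candidate, definite = definite,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hmc_calls", "data.frame")
  out
}

#' Assign a per-probe methylation state in one tissue
#'
#' Precedence: a probe called 5hmC (definite) in the tissue is `fivehmC`;
#' otherwise it is `fivemC` when its mean oxBS beta (pure 5mC readout) is
#' at least `methylated_threshold`, else `non5mC`. The numeric threshold
#' for "methylated" is a package convention (default 0.3), exposed because
#' the state vocabulary has no canonical cutoff.
#'
#' @param calls [call_5hmc()] result for the tissue.
#' @param beta_oxbs Probes x samples oxBS beta matrix for the tissue.
#' @param methylated_threshold Mean-beta cutoff separating `fivemC` from
#'   `non5mC` (default 0.3).
#' @return Named character vector probe -> state in
#'   `c("non5mC", "fivemC", "fivehmC")`.
#' @export
assign_state <- function(calls, beta_oxbs, methylated_threshold = 0.3) {
  mean_ox <- rowMeans(beta_oxbs)[calls$probe_id]
  state <- ifelse(calls$definite, "fivehmC",
                  ifelse(mean_ox >= methylated_threshold, "fivemC", "non5mC"))
  stats::setNames(state, calls$probe_id)
}

#' Classify per-CpG methylation-state transitions between tissues
#'
#' Four categories of normal-to-tumor state change:
#' I `non5mC -> fivehmC` (de novo hydroxymethylation), II `fivemC ->
#' fivehmC`, III `fivehmC -> non5mC`, IV `fivehmC -> fivemC`; every other
#' combination is `none`.
#'
#' @param states_ntl,states_hcc Named state vectors from [assign_state()]
#'   over the same probes.
#' @return List of class `hmc_transitions`: `records` (`probe_id`,
#'   `ntl_state`, `hcc_state`, `category`) and `counts` (named I-IV).
#' @export
classify_transitions <- function(states_ntl, states_hcc) {
  probes <- names(states_ntl)
  if (!identical(sort(probes), sort(names(states_hcc)))) {
    stop("state vectors must cover the same probes", call. = FALSE)
  }
  hcc <- states_hcc[probes]
  category <- rep("none", length(probes))
  category[states_ntl == "non5mC" & hcc == "fivehmC"] <- "I"
  category[states_ntl == "fivemC" & hcc == "fivehmC"] <- "II"
  category[states_ntl == "fivehmC" & hcc == "non5mC"] <- "III"
  category[states_ntl == "fivehmC" & hcc == "fivemC"] <- "IV"
  records <- data.frame(probe_id = probes, ntl_state = unname(states_ntl),
                        hcc_state = unname(hcc), category = category,
                        stringsAsFactors = FALSE, row.names = NULL)
  counts <- vapply(.transition_levels, function(k) sum(category == k), integer(1))
  out <- list(records = records, counts = counts)
  class(out) <- "hmc_transitions"
  out
}

#' @export
print.hmc_transitions <- function(x, ...) {
  cat("Methylation-state transitions (NTL -> HCC):\n")
  lab <- c(I = "non-5mC -> 5hmC", II = "5mC -> 5hmC",
           III = "5hmC -> non-5mC", IV = "5hmC -> 5mC")
  for (k in names(x$counts)) {
    cat(sprintf("  %-4s %-17s %d\n", k, lab[k], x$counts[k]))
  }
  invisible(x)
}

#' Gain/loss summary of 5hmC calls by genomic context
#'
#' Compares definite 5hmC calls between tumor and normal tissue: probes
#' called in tumor only are gains, in normal only losses. Counts are
#' binned by island relation and gene feature.
#'
#' @param calls_hcc,calls_ntl [call_5hmc()] results per tissue.
#' @param manifest Probe manifest covering all called probes.
#' @return List of class `hmc_context` with `gain`, `loss`, `shared`
#'   (probe id vectors) and count tables `gain_by_island`,
#'   `loss_by_island`, `gain_by_feature`, `loss_by_feature`.
#' @export
summarize_hydroxy_context <- function(calls_hcc, calls_ntl, manifest) {
  in_hcc <- calls_hcc$probe_id[calls_hcc$definite]
  in_ntl <- calls_ntl$probe_id[calls_ntl$definite]
  called <- union(in_hcc, in_ntl)
  missing <- setdiff(called, manifest$probe_id)
  if (length(missing) > 0) {
    stop(sprintf("called probe(s) missing from manifest: %s", missing[1]),
         call. = FALSE)
  }
  gain <- setdiff(in_hcc, in_ntl)
  loss <- setdiff(in_ntl, in_hcc)
  shared <- intersect(in_hcc, in_ntl)
  bin <- function(ids, col) {
    idx <- match(ids, manifest$probe_id)
    lev <- if (col == "island_relation") .island_levels else .feature_levels
    table(factor(manifest[[col]][idx], levels = lev))
  }
  out <- list(gain = gain, loss = loss, shared = shared,
              gain_by_island = bin(gain, "island_relation"),
              loss_by_island = bin(loss, "island_relation"),
              gain_by_feature = bin(gain, "feature"),
              loss_by_feature = bin(loss, "feature"))
  class(out) <- "hmc_context"
  out
}
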