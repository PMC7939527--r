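#' Average-rank Spearman correlation with t-approximation p-value
#'
#' Spearman's rho computed as the Pearson correlation of average ranks
#' (ties get mean rank), with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom.
#'
#' @param x,y Equal-length numeric vectors, length >= 4.
#' @return List with `rho` and `p`; both `NA` (flagged via attribute
#'   `constant = TRUE`) when either vector is constant.
#' @examples
#' spearman_rho(1:4, 4:1)$rho # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(rho = NA_real_, p = NA_real_)
    attr(out, "constant") <- TRUE
    return(out)
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Merge expression, methylation and 5hmC layers at gene level
#'
#' Forms one dyad per (DEG gene x matching probe) where the probe is
#' either a passing DMP (layer `dmp`) or a category-I transition — de novo
#' hydroxymethylation, `non5mC -> fivehmC` (layer `de_novo_5hmC`). Gene
#' matching goes through the manifest's gene symbols. DEG genes with no
#' matching probe are dropped and counted. For each dyad the Spearman
#' correlation between the gene's expression and the probe's BS beta
#' values (layer `dmp`) or 5hmC scores (layer `de_novo_5hmC`) is computed
#' across the requested samples.
#'
#' @param degs [test_dge()] output; only rows with `deg == TRUE` are used.
#' @param dmps DMP table; rows with `passes_stringent == TRUE` (or all
#'   rows if the column is absent) define the `dmp` layer. Excluded
#'   (`age_excluded`) probes are skipped.
#' @param transitions [classify_transitions()] output (or its `records`).
#' @param manifest Probe manifest mapping probes to gene symbols.
#' @param expression Genes x samples log2 expression matrix.
#' @param beta_bs Probes x samples BS beta matrix.
#' @param scores Optional probes x samples 5hmC score matrix (required for
#'   the `de_novo_5hmC` layer correlations; defaults to `beta_bs` rows
#'   when absent).
#' @param samples Character vector of sample ids to correlate over;
#'   default all columns shared by `expression` and `beta_bs` (tissues
#'   pooled, which maximizes dynamic range; pass one tissue's samples for
#'   per-tissue mode).
#' @return `data.frame` of class `integration_dyads`: `gene_symbol`,
#'   `probe_id`, `layer`, `deg_direction`, `dmp_direction` (NA for 5hmC
#'   layer), `rho`, `rho_p`. Attribute `n_dropped` counts DEG genes
#'   without probes.
#' @export
merge_layers <- function(degs, dmps, transitions, manifest, expression,
                         beta_bs, scores = NULL, samples = NULL) {
  if (anyDuplicated(rownames(expression))) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  if (inherits(transitions, "hmc_transitions")) transitions <- transitions$records
  if (is.null(samples)) {
    samples <- intersect(colnames(expression), colnames(beta_bs))
  }
  deg_tab <- degs[degs$deg, , drop = FALSE]

  if ("age_excluded" %in% names(dmps)) dmps <- dmps[!dmps$age_excluded, , drop = FALSE]
  if ("passes_stringent" %in% names(dmps)) {
    dmps <- dmps[dmps$passes_stringent, , drop = FALSE]
  }
  cat1 <- transitions$probe_id[transitions$category == "I"]

  gene_of <- stats::setNames(manifest$gene_symbol, manifest$probe_id)
  dir_of <- stats::setNames(dmps$direction, dmps$probe_id)

  rows <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(deg_tab))) {
    g <- deg_tab$gene_symbol[i]
    gene_probes <- manifest$probe_id[manifest$gene_symbol == g]
    p_dmp <- intersect(gene_probes, dmps$probe_id)
    p_hmc <- intersect(gene_probes, cat1)
    if (length(p_dmp) + length(p_hmc) == 0) {
      n_dropped <- n_dropped + 1L
      next
    }
    mk <- function(pids, layer) {
      if (length(pids) == 0) return(NULL)
      data.frame(gene_symbol = g, probe_id = pids, layer = layer,
                 deg_direction = deg_tab$direction[i],
                 dmp_direction = if (layer == "dmp") unname(dir_of[pids]) else NA_character_,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(mk(p_dmp, "dmp"), mk(p_hmc, "de_novo_5hmC"))
  }
  dyads <- do.call(rbind, rows)
  if (is.null(dyads)) {
    dyads <- data.frame(gene_symbol = character(0), probe_id = character(0),
                        layer = character(0), deg_direction = character(0),
                        dmp_direction = character(0), stringsAsFactors = FALSE)
  }

  dyads$rho <- rep(NA_real_, nrow(dyads))
  dyads$rho_p <- rep(NA_real_, nrow(dyads))
  for (i in seq_len(nrow(dyads))) {
    meth <- if (dyads$layer[i] == "de_novo_5hmC" && !is.null(scores)) {
      scores[dyads$probe_id[i], samples]
    } else {
      beta_bs[dyads$probe_id[i], samples]
    }
    sp <- spearman_rho(expression[dyads$gene_symbol[i], samples], meth)
    dyads$rho[i] <- sp$rho
    dyads$rho_p[i] <- sp$p
  }
  if (n_dropped > 0) log_msg("merge_layers: %d DEG gene(s) had no matching probe", n_dropped)
  attr(dyads, "n_dropped") <- n_dropped
  rownames(dyads) <- NULL
  class(dyads) <- c("integration_dyads", "data.frame")
  dyads
}

#' Select highly correlated dyads and label concordance
#'
#' A dyad is selected iff `|rho| > rho_threshold` (strict). Concordance
#' combines the DMP direction with the DEG direction (`hyper_down`,
#' `hyper_up`, `hypo_down`, `hypo_up`; `na` for the 5hmC layer). The
#' fraction of selected dmp-layer genes that are concomitantly
#' hypermethylated and down-regulated is reported as an attribute
#' `hyper_down_fraction`.
#'
#' @param dyads [merge_layers()] output.
#' @param rho_threshold Selection threshold on |rho| (default 0.5).
#' @return `dyads` with added `selected` (logical) and `concordance`.
#' @export
select_dyads <- function(dyads, rho_threshold = 0.5) {
  dyads$selected <- !is.na(dyads$rho) & abs(dyads$rho) > rho_threshold
  dyads$concordance <- ifelse(
    is.na(dyads$dmp_direction), "na",
    paste(dyads$dmp_direction, dyads$deg_direction, sep = "_")
  )
  sel_genes <- unique(dyads$gene_symbol[dyads$selected & dyads$layer == "dmp"])
  hd_genes <- unique(dyads$gene_symbol[dyads$selected & dyads$concordance == "hyper_down"])
  attr(dyads, "hyper_down_fraction") <-
    if (length(sel_genes) > 0) length(hd_genes) / length(sel_genes) else NA_real_
  dyads
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a selected gene
#' list and each gene set, within a fixed universe:
#' `P(X >= k)` for `X ~ Hypergeom(set size, universe - set size, list
#' size)`. Gene sets are intersected with the universe first. Adjustment
#' across sets by Bonferroni (default) or Benjamini-Hochberg.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @param gene_sets Named list of character vectors (e.g. read by
#'   [read_gmt()]).
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @return `data.frame` of class `enrichment_results`: `gene_set`,
#'   `overlap`, `set_size`, `list_size`, `universe_size`, `p`, `p_adj`.
#' @examples
#' enrich(letters[1:5], letters[1:10], list(S = letters[1:5]))$p # 1/252
#' @export
enrich <- function(selected, universe, gene_sets, correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  selected <- intersect(unique(selected), universe)
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(selected, set))
    # P(X >= k), upper tail including the observed overlap
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(selected), lower.tail = FALSE)
    data.frame(gene_set = nm, overlap = k, set_size = length(set),
               list_size = length(selected), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = if (correction == "bh") "BH" else "bonferroni")
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Layer-overlap counts for circular-plot style visualization
#'
#' Counts genes in each of the three layers — down-regulated DEGs, genes
#' with (passing) DMP probes, genes with de novo 5hmC (category I)
#' probes — and every pairwise and triple overlap.
#'
#' @param degs [test_dge()] output.
#' @param dmps DMP table (stringent/passing rows used when flagged).
#' @param transitions [classify_transitions()] output (or its `records`).
#' @param manifest Probe manifest.
#' @return List of class `integration_summary` with per-layer gene
#'   vectors and `counts` (named: deg_down, dmp, de_novo_5hmC, the three
#'   pairwise overlaps, and triple).
#' @export
summary_report <- function(degs, dmps, transitions, manifest) {
  if (inherits(transitions, "hmc_transitions")) transitions <- transitions$records
  if ("age_excluded" %in% names(dmps)) dmps <- dmps[!dmps$age_excluded, , drop = FALSE]
  if ("passes_stringent" %in% names(dmps)) {
    dmps <- dmps[dmps$passes_stringent, , drop = FALSE]
  }
  gene_of <- stats::setNames(manifest$gene_symbol, manifest$probe_id)
  g_deg <- unique(degs$gene_symbol[degs$deg & degs$direction == "down"])
  g_dmp <- setdiff(unique(gene_of[dmps$probe_id]), "")
  g_hmc <- setdiff(unique(gene_of[transitions$probe_id[transitions$category == "I"]]), "")
  g_dmp <- g_dmp[!is.na(g_dmp)]
  g_hmc <- g_hmc[!is.na(g_hmc)]
  counts <- c(
    deg_down = length(g_deg), dmp = length(g_dmp), de_novo_5hmC = length(g_hmc),
    deg_dmp = length(intersect(g_deg, g_dmp)),
    deg_hmc = length(intersect(g_deg, g_hmc)),
    dmp_hmc = length(intersect(g_dmp, g_hmc)),
    triple = length(Reduce(intersect, list(g_deg, g_dmp, g_hmc)))
  )
  out <- list(deg_down = g_deg, dmp = g_dmp, de_novo_5hmC = g_hmc, counts = counts)
  class(out) <- "integration_summary"
  out
}

#' @export
print.integration_summary <- function(x, ...) {
  cat("Layer overlap (genes):\n")
  print(x$counts)
  invisible(x)
}
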