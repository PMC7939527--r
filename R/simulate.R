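#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' study conditions the package targets: 70 tumor/normal (HCC/NTL) pairs with
#' a bimodal age structure (just over half of patients aged 44 or younger),
#' hypermethylation carrying 99% of planted differentially methylated
#' positions (DMPs), a Delta-beta effect of 0.3, a 5hmC probe fraction of 5%
#' with a transition mix proportional to the four observed category counts
#' 1954/293/1919/1081, and strong (|rho| = 0.9) expression-methylation
#' coupling on planted dyads. Array sizes default to a desk-scale 2,000
#' probes over 400 genes.
#'
#' @param n_pairs Number of HCC/NTL pairs.
#' @param aya_fraction Expected fraction of pairs aged <= 44 ("AYA").
#' @param n_probes,n_genes Array dimensions.
#' @param dmp_fraction Fraction of probes planted as DMPs.
#' @param hyper_fraction_among_dmps Fraction of planted DMPs that are
#'   hypermethylated in tumor.
#' @param delta_beta_effect Planted |Delta beta| at DMP probes.
#' @param hmc_fraction Fraction of probes planted with a 5hmC effect.
#' @param transition_mix Length-4 proportions over transition categories
#'   I (non-5mC to 5hmC), II (5mC to 5hmC), III (5hmC to non-5mC),
#'   IV (5hmC to 5mC); must sum to 1.
#' @param hmc_level Planted 5hmC fraction at carrying probes.
#' @param deg_fraction Fraction of genes planted as differentially expressed.
#' @param log_fc_effect Planted |log2 fold change| for DEGs.
#' @param corr_dyad_fraction Fraction of genes planted as correlated
#'   expression-methylation dyads.
#' @param rho_effect Target |Spearman rho| of planted dyads.
#' @param beta_dispersion Precision of the beta-distributed measurement
#'   noise (higher = less noise).
#' @param expr_sd Standard deviation of expression noise (log2 scale).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pairs = 70,
                       aya_fraction = 36 / 70,
                       n_probes = 2000,
                       n_genes = 400,
                       dmp_fraction = 0.05,
                       hyper_fraction_among_dmps = 0.99,
                       delta_beta_effect = 0.3,
                       hmc_fraction = 0.05,
                       transition_mix = c(1954, 293, 1919, 1081) / 5247,
                       hmc_level = 0.4,
                       deg_fraction = 0.1,
                       log_fc_effect = 1.5,
                       corr_dyad_fraction = 0.05,
                       rho_effect = 0.9,
                       beta_dispersion = 100,
                       expr_sd = 1,
                       seed = 1L) {
  cfg <- list(
    n_pairs = n_pairs, aya_fraction = aya_fraction,
    n_probes = n_probes, n_genes = n_genes,
    dmp_fraction = dmp_fraction,
    hyper_fraction_among_dmps = hyper_fraction_among_dmps,
    delta_beta_effect = delta_beta_effect,
    hmc_fraction = hmc_fraction,
    transition_mix = transition_mix, hmc_level = hmc_level,
    deg_fraction = deg_fraction, log_fc_effect = log_fc_effect,
    corr_dyad_fraction = corr_dyad_fraction, rho_effect = rho_effect,
    beta_dispersion = beta_dispersion, expr_sd = expr_sd,
    seed = as.integer(seed)
  )
  for (nm in c("n_pairs", "n_probes", "n_genes")) {
    if (cfg[[nm]] < 1) stop(sprintf("`%s` must be a positive count", nm), call. = FALSE)
  }
  props <- c("aya_fraction", "dmp_fraction", "hyper_fraction_among_dmps",
             "hmc_fraction", "deg_fraction", "corr_dyad_fraction")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (length(cfg$transition_mix) != 4 || any(cfg$transition_mix < 0) ||
      abs(sum(cfg$transition_mix) - 1) > 1e-8) {
    stop("`transition_mix` must be 4 nonnegative proportions summing to 1", call. = FALSE)
  }
  if (cfg$beta_dispersion <= 0) stop("`beta_dispersion` must be positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d pairs (AYA fraction %.2f), %d probes, %d genes, seed %d\n",
              x$n_pairs, x$aya_fraction, x$n_probes, x$n_genes, x$seed))
  cat(sprintf("  DMP: %.1f%% of probes, %.0f%% hyper, |Delta beta| = %.2f\n",
              100 * x$dmp_fraction, 100 * x$hyper_fraction_among_dmps,
              x$delta_beta_effect))
  cat(sprintf("  5hmC: %.1f%% of probes at level %.2f, mix %s\n",
              100 * x$hmc_fraction, x$hmc_level,
              paste(sprintf("%.2f", x$transition_mix), collapse = "/")))
  cat(sprintf("  DEG: %.1f%% of genes at |log2FC| = %.2f; dyads %.1f%% at |rho| = %.2f\n",
              100 * x$deg_fraction, x$log_fc_effect,
              100 * x$corr_dyad_fraction, x$rho_effect))
  invisible(x)
}

# island-relation and gene-feature frequencies loosely shaped on Infinium
# 450K annotation; exact values are generator conventions, not data claims
.island_levels <- c("island", "shore", "shelf", "open_sea")
.island_probs <- c(0.31, 0.23, 0.10, 0.36)
.feature_levels <- c("TSS200", "TSS1500", "UTR5", "body", "UTR3", "intergenic")
.transition_levels <- c("I", "II", "III", "IV")

#' Generate a synthetic probe manifest
#'
#' Lays `n_probes` CpG probes along a small set of chromosomes, assigns each
#' an island relation (island/shore/shelf/open sea), a gene-feature region
#' and a gene symbol. Island probes are preferentially annotated to promoter
#' windows (TSS200/TSS1500) and open-sea probes to gene bodies, mirroring
#' the usual array annotation structure. Consecutive probes within a gene
#' are placed 20-2000 bp apart so that neighboring-CpG region calling has
#' realistic gap structure.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `probe_manifest` with columns `probe_id`,
#'   `chrom`, `pos`, `island_relation`, `gene_symbol`, `feature`, sorted by
#'   (chrom, pos).
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_probes < 10) stop("`n_probes` must be at least 10", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_probes
  g <- config$n_genes

  # genes get contiguous probe blocks; ~10% of probes are intergenic
  gene_names <- sprintf("GENE%04d", seq_len(g))
  gene_of <- sample(c(gene_names, NA), n,
                    replace = TRUE,
                    prob = c(rep(0.9 / g, g), 0.1))
  # guarantee every gene owns at least one probe where possible
  missing_genes <- setdiff(gene_names, gene_of)
  if (length(missing_genes) > 0 && length(missing_genes) <= n) {
    slots <- sample(seq_len(n), length(missing_genes))
    gene_of[slots] <- missing_genes
  }

  island <- sample(.island_levels, n, replace = TRUE, prob = .island_probs)
  feature <- character(n)
  for (i in seq_len(n)) {
    feature[i] <- if (is.na(gene_of[i])) "intergenic" else if (island[i] == "island") {
      sample(c("TSS200", "TSS1500", "UTR5", "body"), 1,
             prob = c(0.35, 0.30, 0.15, 0.20))
    } else {
      sample(c("TSS200", "TSS1500", "UTR5", "body", "UTR3"), 1,
             prob = c(0.05, 0.10, 0.10, 0.60, 0.15))
    }
  }

  n_chrom <- max(1L, min(5L, n %/% 10L))
  chrom <- sort(sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE))
  pos <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- sample(c(20:200, seq(250, 2000, by = 50)), length(idx), replace = TRUE)
    pos[idx] <- cumsum(gaps) + 10000L
  }

  man <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(pos),
    island_relation = island,
    gene_symbol = ifelse(is.na(gene_of), "", gene_of),
    feature = feature,
    stringsAsFactors = FALSE
  )
  man <- man[order(man$chrom, man$pos), , drop = FALSE]
  rownames(man) <- NULL
  class(man) <- c("probe_manifest", "data.frame")
  man
}

#' Generate a synthetic paired cohort
#'
#' Draws `n_pairs` tumor/normal pairs with a bimodal age distribution: a
#' young mode Normal(27, 9^2) and an old mode Normal(67, 11.3^2), truncated
#' to [13, 94], mixed with weight `aya_fraction` on the young mode. Sex, HBV
#' status, cirrhosis, AFP and tumor size are drawn with age-stratum-specific
#' rates patterned on the target cohort (HBV ~92%/80% young/old, cirrhosis
#' absent in the young stratum).
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `sample_sheet`, two rows (HCC + NTL) per
#'   pair, columns `sample_id`, `pair_id`, `tissue`, `age`, `sex`,
#'   `hbv_positive`, `cirrhosis`, `afp`, `tumor_size`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_pairs < 2) stop("`n_pairs` must be at least 2", call. = FALSE)
  set.seed(config$seed + 1L)
  np <- config$n_pairs

  young <- stats::runif(np) < config$aya_fraction
  draw_trunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  age <- numeric(np)
  if (any(young)) age[young] <- draw_trunc(sum(young), 27, 9, 13, 44)
  if (any(!young)) age[!young] <- draw_trunc(sum(!young), 67, 11.3, 45, 94)
  age <- as.integer(round(age))
  # rounding must not cross the stratum boundary
  age[young & age > 44] <- 44L
  age[!young & age < 45] <- 45L

  sex <- sample(c("F", "M"), np, replace = TRUE, prob = c(0.31, 0.69))
  hbv <- stats::runif(np) < ifelse(young, 0.92, 0.80)
  cirr <- stats::runif(np) < ifelse(young, 0.0, 0.115)
  tumor_size <- pmin(pmax(stats::rnorm(np, 14.4, 7.5), 5), 30)
  afp <- exp(stats::rnorm(np, log(5e4), 1.5)) # heavy-tailed, like serum AFP

  pair_id <- sprintf("P%03d", seq_len(np))
  sheet <- data.frame(
    sample_id = c(paste0(pair_id, "_HCC"), paste0(pair_id, "_NTL")),
    pair_id = rep(pair_id, 2),
    tissue = rep(c("HCC", "NTL"), each = np),
    age = rep(age, 2),
    sex = rep(sex, 2),
    hbv_positive = rep(hbv, 2),
    cirrhosis = rep(cirr, 2),
    afp = rep(round(afp, 1), 2),
    tumor_size = rep(round(tumor_size, 1), 2),
    stringsAsFactors = FALSE
  )
  sheet <- sheet[order(sheet$pair_id, sheet$tissue), , drop = FALSE]
  rownames(sheet) <- NULL
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

# mean/precision parameterization of the beta distribution; means are first
# pulled into the open interval so shapes stay positive
rbeta_mp <- function(n, mean, precision) {
  m <- clamp(mean, 1e-3, 1 - 1e-3)
  stats::rbeta(n, shape1 = m * precision, shape2 = (1 - m) * precision)
}

#' Simulate paired BS/oxBS methylomes with planted effects
#'
#' Draws a true 5mC level per probe and tissue (low at CpG islands, high at
#' open sea), plants DMPs by shifting tumor 5mC by `delta_beta_effect`
#' (hypermethylation placed at island/promoter probes with probability 0.8,
#' hypomethylation at open-sea/body probes with probability 0.8), plants
#' 5hmC carriers according to `transition_mix`, then observes
#' `beta_BS = clamp(5mC + 5hmC) + noise` and `beta_oxBS = clamp(5mC) +
#' noise` with beta-distributed noise of precision `beta_dispersion`.
#' DMP and 5hmC plants are placed on disjoint probe sets so the truth table
#' attributes every effect unambiguously.
#'
#' @param manifest A [generate_manifest()] result.
#' @param sheet A [generate_cohort()] result.
#' @param config A [sim_config()].
#' @return A list of class `sim_methylome`: `beta_bs`, `beta_oxbs` (probes x
#'   all samples), per-tissue submatrices `beta_bs_hcc`, `beta_bs_ntl`,
#'   `beta_oxbs_hcc`, `beta_oxbs_ntl`, and `truth` (see
#'   [simulate_dataset()]).
#' @export
simulate_methylome <- function(manifest, sheet, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(sheet$sample_id == make.unique(sheet$sample_id))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  n <- nrow(manifest)
  probes <- manifest$probe_id
  hcc_ids <- sheet$sample_id[sheet$tissue == "HCC"]
  ntl_ids <- sheet$sample_id[sheet$tissue == "NTL"]
  np <- length(hcc_ids)

  # baseline 5mC by island relation: islands largely unmethylated,
  # open sea largely methylated
  base_mean <- c(island = 0.12, shore = 0.35, shelf = 0.55, open_sea = 0.72)
  base <- base_mean[manifest$island_relation]
  # promoter CpGs are largely unmethylated in normal tissue regardless of
  # island context
  base[manifest$feature %in% c("TSS200", "TSS1500")] <- 0.15
  mu_ntl <- rbeta_mp(n, base, 30)
  mu_hcc <- mu_ntl

  # ---- plant DMPs ------------------------------------------------------
  n_dmp <- round(config$dmp_fraction * n)
  dmp_idx <- integer(0)
  dmp_dir <- character(0)
  if (n_dmp > 0 && config$delta_beta_effect > 0) {
    n_hyper <- round(config$hyper_fraction_among_dmps * n_dmp)
    promoter_like <- manifest$island_relation == "island" |
      manifest$feature %in% c("TSS200", "TSS1500")
    body_like <- manifest$island_relation == "open_sea" | manifest$feature == "body"
    w_hyper <- ifelse(promoter_like, 0.8, 0.2)
    w_hypo <- ifelse(body_like, 0.8, 0.2)
    # only plant where the shift has headroom, so the planted magnitude is
    # the realized magnitude (truth stays consistent with the observable)
    w_hyper[mu_ntl > 0.98 - config$delta_beta_effect] <- 0
    w_hypo[mu_ntl < 0.02 + config$delta_beta_effect] <- 0
    n_hyper <- min(n_hyper, sum(w_hyper > 0))
    hyper_idx <- sample(seq_len(n), n_hyper, prob = w_hyper)
    rest <- setdiff(seq_len(n), hyper_idx)
    n_hypo <- min(n_dmp - n_hyper, sum(w_hypo[rest] > 0))
    hypo_idx <- sample(rest, n_hypo, prob = w_hypo[rest])
    shifted_up <- mu_ntl[hyper_idx] + config$delta_beta_effect
    shifted_dn <- mu_ntl[hypo_idx] - config$delta_beta_effect
    if (any(shifted_up > 0.98) || any(shifted_dn < 0.02)) {
      warning("planted Delta beta pushed some means outside (0,1); clamped")
    }
    mu_hcc[hyper_idx] <- clamp(shifted_up, 0.02, 0.98)
    mu_hcc[hypo_idx] <- clamp(shifted_dn, 0.02, 0.98)
    dmp_idx <- c(hyper_idx, hypo_idx)
    dmp_dir <- c(rep("hyper", length(hyper_idx)), rep("hypo", length(hypo_idx)))
  }

  # ---- plant 5hmC carriers (disjoint from DMP probes) ------------------
  h_ntl <- numeric(n)
  h_hcc <- numeric(n)
  hmc_idx <- integer(0)
  hmc_cat <- character(0)
  n_hmc <- round(config$hmc_fraction * n)
  free <- setdiff(seq_len(n), dmp_idx)
  if (n_hmc > 0 && length(free) >= n_hmc) {
    hmc_idx <- sample(free, n_hmc)
    hmc_cat <- sample(.transition_levels, n_hmc, replace = TRUE,
                      prob = config$transition_mix)
    h <- config$hmc_level
    for (k in seq_along(hmc_idx)) {
      i <- hmc_idx[k]
      switch(hmc_cat[k],
        I = { # unmethylated normal -> hydroxymethylated tumor
          mu_ntl[i] <- mu_hcc[i] <- 0.10
          h_hcc[i] <- h
        },
        II = { # methylated normal -> hydroxymethylated tumor
          mu_ntl[i] <- 0.60
          mu_hcc[i] <- 0.10
          h_hcc[i] <- h
        },
        III = { # hydroxymethylated normal -> unmethylated tumor
          mu_ntl[i] <- mu_hcc[i] <- 0.10
          h_ntl[i] <- h
        },
        IV = { # hydroxymethylated normal -> methylated tumor
          mu_ntl[i] <- 0.10
          mu_hcc[i] <- 0.60
          h_ntl[i] <- h
        }
      )
    }
  }

  draw_matrix <- function(mu5mc, h5hmc, ids) {
    bs <- matrix(0, n, length(ids), dimnames = list(probes, ids))
    ox <- bs
    mean_bs <- clamp(mu5mc + h5hmc, 0.02, 0.98)
    for (j in seq_along(ids)) {
      bs[, j] <- rbeta_mp(n, mean_bs, config$beta_dispersion)
      ox[, j] <- rbeta_mp(n, mu5mc, config$beta_dispersion)
    }
    list(bs = bs, ox = ox)
  }
  hcc <- draw_matrix(mu_hcc, h_hcc, hcc_ids)
  ntl <- draw_matrix(mu_ntl, h_ntl, ntl_ids)

  truth <- list(
    dmp_probes = data.frame(
      probe_id = probes[dmp_idx], direction = dmp_dir,
      stringsAsFactors = FALSE
    ),
    hmc_transitions = data.frame(
      probe_id = probes[hmc_idx], category = hmc_cat,
      stringsAsFactors = FALSE
    ),
    true_5mc_ntl = stats::setNames(mu_ntl, probes),
    true_5mc_hcc = stats::setNames(mu_hcc, probes),
    true_5hmc_ntl = stats::setNames(h_ntl, probes),
    true_5hmc_hcc = stats::setNames(h_hcc, probes)
  )

  out <- list(
    beta_bs = cbind(hcc$bs, ntl$bs),
    beta_oxbs = cbind(hcc$ox, ntl$ox),
    beta_bs_hcc = hcc$bs, beta_bs_ntl = ntl$bs,
    beta_oxbs_hcc = hcc$ox, beta_oxbs_ntl = ntl$ox,
    truth = truth
  )
  class(out) <- "sim_methylome"
  out
}

#' Simulate expression coupled to the planted methylome
#'
#' Generates a log2-scale genes-x-samples expression matrix with Gaussian
#' noise. Planted DEGs receive a +/- `log_fc_effect` shift in tumor.
#' Correlated dyads are planted on genes that own a planted hyper-DMP probe:
#' the gene's expression is generated through a Gaussian copula on the ranks
#' of that probe's BS beta values across all samples, so the population
#' Spearman correlation is `-rho_effect` (methylation up, expression down).
#' Dyad genes are also recorded as down-regulated DEGs in the truth table,
#' since the methylation group shift propagates through the coupling.
#'
#' @param manifest,sheet,config As in [simulate_methylome()].
#' @param methylome A [simulate_methylome()] result on the same
#'   manifest/sheet; its truth table is extended in place.
#' @return List with `expression` (genes x samples, log2 scale) and the
#'   extended `truth` (adds `deg_genes` and `corr_dyads`).
#' @export
simulate_expression <- function(manifest, sheet, methylome, config) {
  stopifnot(inherits(config, "sim_config"), inherits(methylome, "sim_methylome"))
  set.seed(config$seed + 3L)
  genes <- sort(unique(manifest$gene_symbol[manifest$gene_symbol != ""]))
  ids <- sheet$sample_id
  is_hcc <- sheet$tissue == "HCC"
  ng <- length(genes)
  ns <- length(ids)

  mu_g <- stats::rnorm(ng, 8, 2)
  expr <- matrix(stats::rnorm(ng * ns, 0, config$expr_sd), ng, ns,
                 dimnames = list(genes, ids)) + mu_g

  # ---- dyad genes: copula-coupled to a planted hyper-DMP probe ---------
  truth <- methylome$truth
  dyads <- data.frame(gene_symbol = character(0), probe_id = character(0),
                      sign = integer(0), stringsAsFactors = FALSE)
  n_dyad <- round(config$corr_dyad_fraction * ng)
  hyper_probes <- truth$dmp_probes$probe_id[truth$dmp_probes$direction == "hyper"]
  probe_gene <- stats::setNames(manifest$gene_symbol, manifest$probe_id)
  # dyads emulate promoter-island hypermethylation silencing: couple genes
  # to island/promoter hyper-probes (unmethylated in normal tissue), the
  # Polycomb-target pattern the integration layer is meant to find
  idx_h <- match(hyper_probes, manifest$probe_id)
  promoterish <- manifest$island_relation[idx_h] == "island" |
    manifest$feature[idx_h] %in% c("TSS200", "TSS1500")
  cand <- hyper_probes[promoterish & probe_gene[hyper_probes] != ""]
  if (length(cand) == 0) cand <- hyper_probes[probe_gene[hyper_probes] != ""]
  cand_genes <- unique(probe_gene[cand])
  if (n_dyad > 0 && length(cand_genes) > 0) {
    dyad_genes <- sample(cand_genes, min(n_dyad, length(cand_genes)))
    dyad_probe <- vapply(dyad_genes, function(g) {
      sample(rep(cand[probe_gene[cand] == g], 2), 1) # rep() guards length-1
    }, character(1))
    r <- 2 * sin(pi * config$rho_effect / 6) # Spearman -> Pearson (copula)
    for (k in seq_along(dyad_genes)) {
      b <- methylome$beta_bs[dyad_probe[k], ids]
      z_b <- stats::qnorm((rank(b) - 0.5) / ns)
      z_e <- -(r * z_b) + sqrt(1 - r^2) * stats::rnorm(ns)
      expr[dyad_genes[k], ] <- mu_g[match(dyad_genes[k], genes)] +
        1.5 * config$expr_sd * z_e
    }
    dyads <- data.frame(gene_symbol = dyad_genes, probe_id = dyad_probe,
                        sign = -1L, stringsAsFactors = FALSE)
  }

  # ---- plain DEGs on the remaining genes -------------------------------
  n_deg <- round(config$deg_fraction * ng)
  free <- setdiff(genes, dyads$gene_symbol)
  deg <- data.frame(gene_symbol = character(0), direction = character(0),
                    stringsAsFactors = FALSE)
  if (n_deg > 0 && config$log_fc_effect != 0 && length(free) > 0) {
    deg_genes <- sample(free, min(n_deg, length(free)))
    deg_dir <- sample(c("up", "down"), length(deg_genes), replace = TRUE)
    shift <- ifelse(deg_dir == "up", config$log_fc_effect, -config$log_fc_effect)
    expr[deg_genes, is_hcc] <- expr[deg_genes, is_hcc] + shift
    deg <- data.frame(gene_symbol = deg_genes, direction = deg_dir,
                      stringsAsFactors = FALSE)
  }
  if (nrow(dyads) > 0) {
    deg <- rbind(deg, data.frame(gene_symbol = dyads$gene_symbol,
                                 direction = "down", stringsAsFactors = FALSE))
  }

  truth$deg_genes <- deg
  truth$corr_dyads <- dyads
  list(expression = expr, truth = truth)
}

#' Generate gene sets with a planted target set
#'
#' Builds a small GMT-style gene-set collection over the simulated gene
#' universe. The first set, `PRC2_TARGETS`, is seeded with all planted
#' correlated-dyad genes plus random fill, emulating a Polycomb-target set
#' that the integration layer should recover as enriched; the remaining
#' sets are random draws.
#'
#' @param truth Truth table from [simulate_expression()].
#' @param genes Character vector: the gene universe.
#' @param n_sets Number of decoy sets.
#' @param set_size Size of each set.
#' @param seed Integer seed.
#' @return Named list of character vectors (class `gene_sets`).
#' @export
generate_genesets <- function(truth, genes, n_sets = 5, set_size = 40, seed = 1L) {
  set.seed(seed + 4L)
  set_size <- min(set_size, length(genes))
  planted <- unique(truth$corr_dyads$gene_symbol)
  fill <- sample(setdiff(genes, planted),
                 max(0, set_size - length(planted)))
  sets <- list(PRC2_TARGETS = sort(unique(c(planted, fill))))
  for (k in seq_len(n_sets)) {
    sets[[sprintf("RANDOM_SET_%02d", k)]] <- sort(sample(genes, set_size))
  }
  class(sets) <- c("gene_sets", "list")
  sets
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generate_manifest()], [generate_cohort()],
#' [simulate_methylome()], [simulate_expression()] and
#' [generate_genesets()] under one seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `config`, `manifest`,
#'   `sheet`, `beta_bs`, `beta_oxbs`, per-tissue beta submatrices,
#'   `expression`, `genesets` and `truth`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_pairs = 6, n_probes = 50,
#'                                    n_genes = 10, seed = 42))
#' dim(sim$beta_bs)
#' @export
simulate_dataset <- function(config = sim_config()) {
  manifest <- generate_manifest(config)
  sheet <- generate_cohort(config)
  meth <- simulate_methylome(manifest, sheet, config)
  ex <- simulate_expression(manifest, sheet, meth, config)
  genes <- rownames(ex$expression)
  gs <- generate_genesets(ex$truth, genes, seed = config$seed)
  out <- list(
    config = config, manifest = manifest, sheet = sheet,
    beta_bs = meth$beta_bs, beta_oxbs = meth$beta_oxbs,
    beta_bs_hcc = meth$beta_bs_hcc, beta_bs_ntl = meth$beta_bs_ntl,
    beta_oxbs_hcc = meth$beta_oxbs_hcc, beta_oxbs_ntl = meth$beta_oxbs_ntl,
    expression = ex$expression, genesets = gs, truth = ex$truth
  )
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated paired study: %d pairs, %d probes, %d genes (seed %d)\n",
    x$config$n_pairs, nrow(x$manifest), nrow(x$expression), x$config$seed))
  cat(sprintf("  planted: %d DMPs, %d 5hmC carriers, %d DEGs, %d dyads\n",
              nrow(x$truth$dmp_probes), nrow(x$truth$hmc_transitions),
              nrow(x$truth$deg_genes), nrow(x$truth$corr_dyads)))
  invisible(x)
}
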