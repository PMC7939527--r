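test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_probes = 0), "n_probes")
  expect_error(sim_config(aya_fraction = 1.2), "aya_fraction")
  expect_error(sim_config(transition_mix = c(0.5, 0.5, 0.5, 0.5)), "transition_mix")
  expect_error(sim_config(beta_dispersion = -1), "beta_dispersion")
})

test_that("manifest has the configured shape and is deterministic", {
  cfg <- sim_config(n_probes = 100, n_genes = 20, seed = 1)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man), 100)
  expect_false(anyDuplicated(man$probe_id) > 0)
  genes <- unique(man$gene_symbol[man$gene_symbol != ""])
  expect_length(genes, 20)
  expect_true(all(man$pos >= 1))
  expect_false(is.unsorted(order(man$chrom, man$pos)))

  man2 <- generate_manifest(sim_config(n_probes = 100, n_genes = 20, seed = 1))
  expect_identical(man, man2)
  expect_error(generate_manifest(sim_config(n_probes = 5)), "at least 10")
})

test_that("cohort generation respects pairing, the AYA boundary, and its rate", {
  sheet <- generate_cohort(sim_config(n_pairs = 10, aya_fraction = 0.5, seed = 7))
  expect_equal(nrow(sheet), 20)
  tab <- table(sheet$pair_id, sheet$tissue)
  expect_true(all(tab == 1))
  # both members of a pair share the age
  ages <- tapply(sheet$age, sheet$pair_id, function(a) length(unique(a)))
  expect_true(all(ages == 1))

  all_young <- generate_cohort(sim_config(n_pairs = 10, aya_fraction = 1, seed = 2))
  expect_true(all(all_young$age <= 44))
  expect_true(all(all_young$age >= 13))

  # binomial bound: at n = 500 the observed AYA fraction sits within +/- 0.05
  big <- generate_cohort(sim_config(n_pairs = 500, aya_fraction = 0.5, seed = 11))
  pts <- big[!duplicated(big$pair_id), ]
  expect_lt(abs(mean(pts$age <= 44) - 0.5), 0.05)
})

test_that("null methylome simulation plants nothing and shows no signal", {
  cfg <- sim_config(n_pairs = 5, n_probes = 50, n_genes = 10,
                    delta_beta_effect = 0, hmc_fraction = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$dmp_probes), 0)
  expect_equal(nrow(sim$truth$hmc_transitions), 0)
  delta <- rowMeans(sim$beta_bs_hcc) - rowMeans(sim$beta_bs_ntl)
  expect_lt(mean(abs(delta)), 0.05)
})

test_that("BS/oxBS additivity holds in the near-noise-free limit", {
  cfg <- sim_config(n_pairs = 4, n_probes = 200, n_genes = 20,
                    hmc_fraction = 0.3, dmp_fraction = 0,
                    beta_dispersion = 1e7, seed = 5)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$hmc_transitions
  cat1 <- tr$probe_id[tr$category == "I"]
  expect_gt(length(cat1), 0)
  # category I: tumor reads 5mC 0.1 + 5hmC 0.4 in BS, 0.1 in oxBS
  expect_equal(unname(rowMeans(sim$beta_bs_hcc[cat1, , drop = FALSE])),
               rep(0.5, length(cat1)), tolerance = 0.01)
  expect_equal(unname(rowMeans(sim$beta_oxbs_hcc[cat1, , drop = FALSE])),
               rep(0.1, length(cat1)), tolerance = 0.01)
  score <- sim$beta_bs_hcc[cat1, ] - sim$beta_oxbs_hcc[cat1, ]
  expect_equal(unname(rowMeans(score)), rep(0.4, length(cat1)), tolerance = 0.01)
  # all beta values stay inside the unit interval
  expect_true(all(sim$beta_bs >= 0 & sim$beta_bs <= 1))
  expect_true(all(sim$beta_oxbs >= 0 & sim$beta_oxbs <= 1))
})

test_that("planted DMP directions follow the configured hyper fraction", {
  cfg <- sim_config(n_pairs = 4, n_probes = 2000, n_genes = 100,
                    dmp_fraction = 0.1, hyper_fraction_among_dmps = 0.99,
                    hmc_fraction = 0, seed = 9)
  sim <- suppressWarnings(simulate_dataset(cfg))
  dirs <- sim$truth$dmp_probes$direction
  expect_equal(mean(dirs == "hyper"), 0.99, tolerance = 0.005)
  # hyper plants favor island/promoter context
  man <- sim$manifest
  idx <- match(sim$truth$dmp_probes$probe_id[dirs == "hyper"], man$probe_id)
  promoter_like <- man$island_relation[idx] == "island" |
    man$feature[idx] %in% c("TSS200", "TSS1500")
  expect_gt(mean(promoter_like), 0.6)
})

test_that("null expression has no paired fold change; dyads hit target rho", {
  cfg <- sim_config(n_pairs = 10, n_probes = 60, n_genes = 15,
                    deg_fraction = 0, corr_dyad_fraction = 0,
                    dmp_fraction = 0, hmc_fraction = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$deg_genes), 0)
  hcc <- sim$sheet$sample_id[sim$sheet$tissue == "HCC"]
  ntl <- sim$sheet$sample_id[sim$sheet$tissue == "NTL"]
  lfc <- rowMeans(sim$expression[, hcc]) - rowMeans(sim$expression[, ntl])
  expect_lt(max(abs(lfc)), 1)

  # empirical check of the rank-copula coupling at n_pairs = 200
  cfg2 <- sim_config(n_pairs = 200, n_probes = 300, n_genes = 30,
                     dmp_fraction = 0.2, hyper_fraction_among_dmps = 1,
                     corr_dyad_fraction = 0.2, rho_effect = 0.9,
                     hmc_fraction = 0, seed = 17)
  sim2 <- simulate_dataset(cfg2)
  dy <- sim2$truth$corr_dyads
  expect_gt(nrow(dy), 3)
  rhos <- vapply(seq_len(nrow(dy)), function(i) {
    cor(sim2$expression[dy$gene_symbol[i], ],
        sim2$beta_bs[dy$probe_id[i], colnames(sim2$expression)],
        method = "spearman")
  }, numeric(1))
  expect_true(all(abs(rhos - (-0.9)) < 0.1))
})

test_that("identical configs reproduce bit-identical datasets", {
  cfg <- sim_config(n_pairs = 5, n_probes = 80, n_genes = 12, seed = 21)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$beta_bs, s2$beta_bs)
  expect_identical(s1$beta_oxbs, s2$beta_oxbs)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)
})

test_that("truth table is exhaustive: zeroed effects plant nothing", {
  cfg <- sim_config(n_pairs = 4, n_probes = 100, n_genes = 10,
                    dmp_fraction = 0, hmc_fraction = 0, deg_fraction = 0,
                    corr_dyad_fraction = 0, seed = 23)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$dmp_probes), 0)
  expect_equal(nrow(sim$truth$hmc_transitions), 0)
  expect_equal(nrow(sim$truth$deg_genes), 0)
  expect_equal(nrow(sim$truth$corr_dyads), 0)
  expect_true(all(sim$truth$true_5hmc_hcc == 0))
  expect_true(all(sim$truth$true_5hmc_ntl == 0))
})
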