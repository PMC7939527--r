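test_that("M-value transform is symmetric, exact and monotone", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8, epsilon = 0), 2)
  grid <- seq(0, 1, by = 0.01)
  m <- beta_to_m(grid)
  expect_true(all(diff(m) > 0))
  expect_true(all(is.finite(m)))
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(99)
  for (n in c(1, 7, 50, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
})

test_that("DMP calling enforces both thresholds and assigns direction", {
  tests <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    delta_beta = c(0.19, 0.25, -0.25, 0.5),
    statistic = 5, p = c(0.001, 0.001, 0.001, 0.5),
    q = c(0.001, 0.01, 0.01, 0.6), stringsAsFactors = FALSE
  )
  dmps <- call_dmps(tests)
  expect_equal(dmps$probe_id, c("b", "c")) # a fails delta, d fails q
  expect_equal(dmps$direction, c("hyper", "hypo"))
})

test_that("identical matrices yield no DMPs", {
  b <- make_beta(runif(20, 0.2, 0.8), 6, "S")
  sheet <- make_sheet(3)
  colnames(b) <- sheet$sample_id[order(sheet$tissue)] # 3 HCC then 3 NTL
  hcc <- b[, 1:3]; ntl <- b[, 4:6]
  res <- test_dmps(hcc, ntl, sheet)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
  expect_equal(nrow(call_dmps(res)), 0)
})

test_that("stringent filters reproduce the worked 10-pair probe", {
  ntl <- matrix(rep(c(0.15, 0.25), 5), nrow = 1,
                dimnames = list("cg1", sprintf("N%02d", 1:10)))
  hcc <- matrix(c(rep(0.60, 8), rep(0.25, 2)), nrow = 1,
                dimnames = list("cg1", sprintf("H%02d", 1:10)))
  dmp <- data.frame(probe_id = "cg1", delta_beta = 0.33, statistic = 5,
                    p = 1e-5, q = 1e-4, direction = "hyper",
                    stringsAsFactors = FALSE)
  out <- apply_stringent_filters(dmp, hcc, ntl)
  expect_equal(mean(ntl), 0.20)
  expect_equal(sd(ntl), 0.0527, tolerance = 1e-3)
  expect_equal(rowMeans(hcc) - rowMeans(ntl), c(cg1 = 0.33))
  expect_true(out$c1); expect_true(out$c2); expect_true(out$c3)
  expect_true(out$passes_stringent)

  # each perturbation fails exactly its own criterion
  hcc_c1 <- matrix(c(rep(0.35, 8), rep(0.25, 2)), nrow = 1,
                   dimnames = dimnames(hcc))
  o1 <- apply_stringent_filters(dmp, hcc_c1, ntl)
  expect_equal(c(o1$c1, o1$c2, o1$c3), c(FALSE, TRUE, TRUE))

  hcc_c2 <- matrix(c(rep(0.60, 6), rep(0.25, 4)), nrow = 1,
                   dimnames = dimnames(hcc))
  o2 <- apply_stringent_filters(dmp, hcc_c2, ntl)
  expect_equal(c(o2$c1, o2$c2, o2$c3), c(TRUE, FALSE, TRUE))

  ntl_c3 <- ntl + 0.20 # mean 0.40, same SD
  hcc_c3 <- matrix(c(rep(0.80, 8), rep(0.45, 2)), nrow = 1,
                   dimnames = dimnames(hcc))
  o3 <- apply_stringent_filters(dmp, hcc_c3, ntl_c3)
  expect_equal(c(o3$c1, o3$c2, o3$c3), c(TRUE, TRUE, FALSE))
})

test_that("stringent pass is monotone in tumor beta for hyper probes", {
  set.seed(4)
  ntl <- matrix(runif(10, 0.05, 0.20), nrow = 1,
                dimnames = list("cg1", sprintf("N%02d", 1:10)))
  hcc <- matrix(runif(10, 0.55, 0.75), nrow = 1,
                dimnames = list("cg1", sprintf("H%02d", 1:10)))
  dmp <- data.frame(probe_id = "cg1", delta_beta = 0.5, statistic = 5,
                    p = 1e-5, q = 1e-4, direction = "hyper",
                    stringsAsFactors = FALSE)
  base <- apply_stringent_filters(dmp, hcc, ntl)
  expect_true(base$passes_stringent)
  for (bump in c(0.01, 0.05, 0.1)) {
    out <- apply_stringent_filters(dmp, pmin(hcc + bump, 1), ntl)
    expect_true(out$passes_stringent)
  }
})

test_that("zero normal-tissue SD is floored, not divided through", {
  ntl <- matrix(0.1, 1, 6, dimnames = list("cg1", sprintf("N%02d", 1:6)))
  hcc <- matrix(0.6, 1, 6, dimnames = list("cg1", sprintf("H%02d", 1:6)))
  dmp <- data.frame(probe_id = "cg1", delta_beta = 0.5, statistic = 5,
                    p = 1e-5, q = 1e-4, direction = "hyper",
                    stringsAsFactors = FALSE)
  out <- apply_stringent_filters(dmp, hcc, ntl)
  expect_true(out$c2) # 0.6 > 0.1 + 2 * 0.01
  expect_true(out$passes_stringent)
})

test_that("age-related exclusion flags listed probes and warns on unknowns", {
  dmps <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                     delta_beta = 0.3, statistic = 5, p = 1e-4, q = 1e-3,
                     direction = "hyper", stringsAsFactors = FALSE)
  man <- data.frame(probe_id = c("cg1", "cg2", "cg3"), chrom = "chr1",
                    pos = 1:3, island_relation = "island",
                    gene_symbol = "G1", feature = "TSS200",
                    stringsAsFactors = FALSE)
  none <- exclude_age_related(dmps, character(0), man)
  expect_false(any(none$age_excluded))

  one <- exclude_age_related(dmps, "cg2", man)
  expect_equal(sum(!one$age_excluded), 2)

  expect_warning(unk <- exclude_age_related(dmps, c("cg2", "cgXX"), man),
                 "not in manifest")
  expect_equal(sum(unk$age_excluded), 1)

  # file-based list
  f <- tempfile()
  writeLines(c("cg1", "cg3"), f)
  two <- exclude_age_related(dmps, f, man)
  expect_equal(two$age_excluded, c(TRUE, FALSE, TRUE))
})

test_that("context summary conserves counts and reflects degenerate plants", {
  man <- data.frame(probe_id = paste0("cg", 1:4), chrom = "chr1", pos = 1:4,
                    island_relation = c("island", "island", "open_sea", "shore"),
                    gene_symbol = "G1",
                    feature = c("TSS200", "TSS200", "body", "UTR5"),
                    stringsAsFactors = FALSE)
  dmps <- data.frame(probe_id = paste0("cg", 1:2), delta_beta = 0.3,
                     statistic = 5, p = 1e-4, q = 1e-3, direction = "hyper",
                     stringsAsFactors = FALSE)
  ctx <- summarize_context(dmps, man)
  expect_equal(ctx$n, 2)
  expect_equal(sum(ctx$table), ctx$n)
  expect_equal(unname(ctx$by_island["hyper", "island"]), 2L)
  expect_equal(ctx$hyper_fraction, 1)

  bad <- data.frame(probe_id = "cgZZ", delta_beta = 0.3, statistic = 5,
                    p = 1e-4, q = 1e-3, direction = "hyper",
                    stringsAsFactors = FALSE)
  expect_error(summarize_context(bad, man), "cgZZ")
})

test_that("null simulation keeps the discovery fraction near zero", {
  cfg <- sim_config(n_pairs = 20, n_probes = 1000, n_genes = 50,
                    delta_beta_effect = 0, dmp_fraction = 0,
                    hmc_fraction = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  res <- test_dmps(sim$beta_bs_hcc, sim$beta_bs_ntl, sim$sheet)
  expect_lt(mean(res$q < 0.05), 0.01)
})
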