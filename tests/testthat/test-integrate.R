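test_that("Spearman rho handles monotone, antitone and tied data", {
  expect_equal(spearman_rho(1:4, 4:1)$rho, -1)
  expect_equal(spearman_rho(1:4, 1:4)$rho, 1)
  expect_equal(spearman_rho(1:4, 4:1)$p, 0)
  tied <- spearman_rho(c(1, 1, 2, 3), c(2, 1, 4, 3))
  expect_equal(tied$rho, spearman_oracle(c(1, 1, 2, 3), c(2, 1, 4, 3)))
  const <- spearman_rho(rep(1, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_true(attr(const, "constant"))
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("Spearman rho equals the oracle exhaustively over a tied alphabet", {
  # all length-4 vectors over {1,2,3} paired with a fixed panel: dense tie
  # coverage without blowing up the test
  grid <- as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3))
  panel <- rbind(c(1, 2, 3, 1), c(2, 2, 1, 3), c(3, 1, 2, 2))
  for (i in seq_len(nrow(grid))) {
    x <- grid[i, ]
    if (sd(x) == 0) next
    for (j in seq_len(nrow(panel))) {
      got <- spearman_rho(x, panel[j, ])$rho
      expect_equal(got, spearman_oracle(x, panel[j, ]),
                   info = paste(x, collapse = ","))
    }
  }
  # random longer vectors with ties
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y)$rho, spearman_oracle(x, y))
  }
})

test_that("hypergeometric enrichment matches exact subset enumeration", {
  expect_equal(enrich(letters[1:5], letters[1:10], list(S = letters[1:5]))$p,
               1 / choose(10, 5))
  expect_equal(enrich(character(0), letters[1:10], list(S = letters[1:3]))$p, 1)

  # enumeration oracle: all C(universe, |list|) draws, universe <= 15
  set.seed(10)
  for (rep in 1:10) {
    u <- sample(8:15, 1)
    universe <- sprintf("g%02d", seq_len(u))
    set <- sample(universe, sample(2:5, 1))
    sel <- sample(universe, sample(2:6, 1))
    k_obs <- length(intersect(sel, set))
    draws <- combn(u, length(sel))
    overlaps <- apply(draws, 2, function(ix) length(intersect(universe[ix], set)))
    p_oracle <- mean(overlaps >= k_obs)
    got <- enrich(sel, universe, list(S = set))$p
    expect_equal(got, p_oracle, tolerance = 1e-12)
  }

  expect_error(enrich("a", character(0), list(S = "a")), "empty universe")
})

test_that("correction across sets is applied as configured", {
  universe <- letters[1:20]
  sets <- list(A = letters[1:5], B = letters[6:10], C = letters[11:15])
  res_b <- enrich(letters[1:5], universe, sets, correction = "bonferroni")
  expect_equal(res_b$p_adj, pmin(1, res_b$p * 3))
  res_bh <- enrich(letters[1:5], universe, sets, correction = "bh")
  expect_equal(res_bh$p_adj, p.adjust(res_bh$p, method = "BH"))
})

make_integration_fixture <- function() {
  sheet <- make_sheet(4)
  ids <- sheet$sample_id
  man <- data.frame(
    probe_id = paste0("cg", 1:5), chrom = "chr1", pos = (1:5) * 100,
    island_relation = "island",
    gene_symbol = c("G1", "G1", "G2", "G3", ""),
    feature = "TSS200", stringsAsFactors = FALSE
  )
  beta <- matrix(seq(0.1, 0.9, length.out = 5 * 8), 5, 8,
                 dimnames = list(man$probe_id, ids))
  expr <- matrix(0, 3, 8, dimnames = list(c("G1", "G2", "G3"), ids))
  expr["G1", ] <- -beta[1, ] # perfectly antitone with cg1
  expr["G2", ] <- rnorm(8)
  expr["G3", ] <- rnorm(8)
  degs <- data.frame(gene_symbol = c("G1", "G2", "G3"),
                     log_fc = c(-2, 1, -1), statistic = 5, p = 1e-4,
                     q = c(1e-3, 1e-3, 0.5),
                     direction = c("down", "up", "down"),
                     deg = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  dmps <- data.frame(probe_id = c("cg1", "cg2", "cg4"), delta_beta = 0.3,
                     statistic = 5, p = 1e-4, q = 1e-3, direction = "hyper",
                     passes_stringent = TRUE, stringsAsFactors = FALSE)
  transitions <- data.frame(probe_id = c("cg3", "cg4"),
                            ntl_state = c("non5mC", "fivemC"),
                            hcc_state = c("fivehmC", "fivehmC"),
                            category = c("I", "II"), stringsAsFactors = FALSE)
  list(sheet = sheet, man = man, beta = beta, expr = expr, degs = degs,
       dmps = dmps, transitions = transitions)
}

test_that("layer merging forms dyads per DEG gene x matching probe", {
  fx <- make_integration_fixture()
  dy <- merge_layers(fx$degs, fx$dmps, fx$transitions, fx$man, fx$expr, fx$beta)
  # G1 has two passing DMP probes -> two dmp-layer dyads
  expect_equal(sum(dy$gene_symbol == "G1" & dy$layer == "dmp"), 2)
  # G2's probe cg3 is a category-I transition -> de novo 5hmC layer
  expect_equal(dy$layer[dy$gene_symbol == "G2"], "de_novo_5hmC")
  # category-II probe cg4 is never merged, and G3 is not a DEG
  expect_false("cg4" %in% dy$probe_id)
  expect_false("G3" %in% dy$gene_symbol)
  # perfectly antitone coupling recovered
  expect_equal(dy$rho[dy$probe_id == "cg1"], -1)
})

test_that("DEG genes without probes are dropped and counted", {
  fx <- make_integration_fixture()
  degs <- fx$degs
  degs$deg <- c(FALSE, FALSE, TRUE) # only G3, whose probe is no DMP
  dy <- suppressMessages(
    merge_layers(degs, fx$dmps[fx$dmps$probe_id == "cg1", ], fx$transitions[0, ],
                 fx$man, fx$expr, fx$beta))
  expect_equal(nrow(dy), 0)
  expect_equal(attr(dy, "n_dropped"), 1)
})

test_that("dyad selection uses a strict threshold and labels concordance", {
  dy <- data.frame(gene_symbol = c("G1", "G2", "G3"), probe_id = paste0("cg", 1:3),
                   layer = c("dmp", "dmp", "de_novo_5hmC"),
                   deg_direction = c("down", "up", "down"),
                   dmp_direction = c("hyper", "hypo", NA),
                   rho = c(0.51, 0.5, -0.9), rho_p = 0.01,
                   stringsAsFactors = FALSE)
  class(dy) <- c("integration_dyads", "data.frame")
  sel <- select_dyads(dy, rho_threshold = 0.5)
  expect_equal(sel$selected, c(TRUE, FALSE, TRUE)) # 0.5 exactly is out
  expect_equal(sel$concordance, c("hyper_down", "hypo_up", "na"))
  expect_equal(attr(sel, "hyper_down_fraction"), 1)
})

test_that("overlap counts obey set algebra", {
  fx <- make_integration_fixture()
  rep_all <- summary_report(fx$degs, fx$dmps, fx$transitions, fx$man)
  cts <- rep_all$counts
  # inclusion-exclusion: |union| computed two ways
  union_direct <- length(unique(c(rep_all$deg_down, rep_all$dmp, rep_all$de_novo_5hmC)))
  union_ie <- cts["deg_down"] + cts["dmp"] + cts["de_novo_5hmC"] -
    cts["deg_dmp"] - cts["deg_hmc"] - cts["dmp_hmc"] + cts["triple"]
  expect_equal(unname(union_ie), union_direct)

  # disjoint layers -> zero overlaps; one gene in all three -> triple = 1
  man <- fx$man
  degs <- fx$degs; degs$deg <- c(TRUE, FALSE, FALSE) # G1 down
  dmps <- fx$dmps[fx$dmps$probe_id == "cg1", ] # G1
  tra <- data.frame(probe_id = "cg2", ntl_state = "non5mC",
                    hcc_state = "fivehmC", category = "I",
                    stringsAsFactors = FALSE) # also G1
  r <- summary_report(degs, dmps, tra, man)
  expect_equal(unname(r$counts["triple"]), 1)

  tra2 <- data.frame(probe_id = "cg3", ntl_state = "non5mC",
                     hcc_state = "fivehmC", category = "I",
                     stringsAsFactors = FALSE) # G2: disjoint from G1 layers
  degs2 <- fx$degs; degs2$deg <- FALSE
  r2 <- summary_report(degs2, dmps, tra2, man)
  expect_equal(unname(r2$counts["deg_dmp"]), 0)
  expect_equal(unname(r2$counts["triple"]), 0)
})
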