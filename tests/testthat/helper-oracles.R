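# independent oracles used by both the module suites and the end-to-end
# acceptance suite; each re-derives the quantity from first principles

# BH step-up by direct evaluation of q_i = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i)
    q[i] <- min(1, min(m * p[ord[j:m]] / (j:m)))
  }
  q
}

# Spearman via explicit average ranks and the Pearson formula
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive DMR oracle: every contiguous candidate run, kept if valid and
# not extendable in either direction
dmr_oracle <- function(probes, max_gap = 250, min_probes = 2, min_delta = 0.2) {
  probes <- probes[abs(probes$delta_beta) > min_delta, , drop = FALSE]
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  n <- nrow(probes)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (n == 0) break
      sub <- probes[i:j, , drop = FALSE]
      ok <- length(unique(sub$chrom)) == 1 &&
        length(unique(sub$direction)) == 1 &&
        (j == i || all(diff(sub$pos) <= max_gap)) &&
        nrow(sub) >= min_probes
      if (!ok) next
      ext_l <- i > 1 && probes$chrom[i - 1] == sub$chrom[1] &&
        probes$direction[i - 1] == sub$direction[1] &&
        sub$pos[1] - probes$pos[i - 1] <= max_gap
      ext_r <- j < n && probes$chrom[j + 1] == sub$chrom[1] &&
        probes$direction[j + 1] == sub$direction[1] &&
        probes$pos[j + 1] - sub$pos[nrow(sub)] <= max_gap
      if (!ext_l && !ext_r) {
        out[[length(out) + 1]] <- data.frame(
          chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
          n_probes = nrow(sub), direction = sub$direction[1],
          mean_delta_beta = mean(sub$delta_beta), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0), direction = character(0),
                      mean_delta_beta = numeric(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exact hypergeometric upper tail by enumerating all possible selections
hyper_oracle <- function(selected, universe, set) {
  k <- length(intersect(selected, set))
  draws <- utils::combn(length(universe), length(selected))
  overlaps <- apply(draws, 2, function(ix) length(intersect(universe[ix], set)))
  mean(overlaps >= k)
}
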