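# small in-code fixtures shared across test files

# a minimal paired sample sheet with n HCC/NTL pairs
make_sheet <- function(n, ages = NULL) {
  pair_id <- sprintf("P%02d", seq_len(n))
  if (is.null(ages)) ages <- rep(30L, n)
  sheet <- data.frame(
    sample_id = c(paste0(pair_id, "_HCC"), paste0(pair_id, "_NTL")),
    pair_id = rep(pair_id, 2),
    tissue = rep(c("HCC", "NTL"), each = n),
    age = rep(ages, 2),
    sex = "F", hbv_positive = TRUE, cirrhosis = FALSE,
    afp = 100, tumor_size = 10,
    stringsAsFactors = FALSE
  )
  sheet[order(sheet$pair_id, sheet$tissue), ]
}

# probes x samples beta matrix filled from a per-probe mean with optional noise
make_beta <- function(means, n_samples, prefix, noise_sd = 0) {
  m <- matrix(rep(means, n_samples), nrow = length(means),
              dimnames = list(names(means) %||% sprintf("cg%03d", seq_along(means)),
                              sprintf("%s%02d", prefix, seq_len(n_samples))))
  if (noise_sd > 0) m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  pmin(pmax(m, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the cohort of the published clinical table, reconstructed from its printed
# counts: 39 AYA (36 HBV+) and 35 MOA (28 HBV+, 4 cirrhotic)
make_reference_cohort <- function() {
  n_aya <- 39; n_moa <- 35
  ages <- c(rep(27L, n_aya), rep(68L, n_moa))
  hbv <- c(rep(TRUE, 36), rep(FALSE, 3), rep(TRUE, 28), rep(FALSE, 7))
  cirr <- c(rep(FALSE, n_aya), rep(TRUE, 4), rep(FALSE, 31))
  sex <- c(rep("F", 15), rep("M", 24), rep("F", 8), rep("M", 27))
  n <- n_aya + n_moa
  pair_id <- sprintf("P%03d", seq_len(n))
  sheet <- data.frame(
    sample_id = c(paste0(pair_id, "_HCC"), paste0(pair_id, "_NTL")),
    pair_id = rep(pair_id, 2), tissue = rep(c("HCC", "NTL"), each = n),
    age = rep(ages, 2), sex = rep(sex, 2), hbv_positive = rep(hbv, 2),
    cirrhosis = rep(cirr, 2), afp = 1000, tumor_size = 10,
    stringsAsFactors = FALSE
  )
  sheet[order(sheet$pair_id, sheet$tissue), ]
}
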