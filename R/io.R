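#' Read a beta-value matrix from TSV
#'
#' Expects a tab-delimited file with probe ids in the first column and
#' sample ids in the header. Values must lie in [0, 1]; violations are
#' rejected with their (row, column) coordinates. Missing values are an
#' error unless `allow_na = TRUE`.
#'
#' @param path File path.
#' @param allow_na Permit missing values (handled pairwise-complete
#'   downstream).
#' @return Numeric probes x samples matrix.
#' @export
read_beta_matrix <- function(path, allow_na = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!allow_na && anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at probe %s, sample %s (use allow_na = TRUE)",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value %.4g outside [0,1] at probe %s, sample %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  m
}

#' Write a probes-x-samples matrix as TSV
#'
#' Tab-delimited with a `probe_id` (or `gene_symbol`) first column, '.'
#' decimal separator, header row.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a sample sheet (CSV)
#'
#' @param path File path.
#' @return `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "pair_id", "tissue")
  miss <- setdiff(needed, names(sheet))
  if (length(miss) > 0) {
    stop(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(unique(sheet$tissue), c("HCC", "NTL"))
  if (length(bad) > 0) {
    stop(sprintf("unknown tissue label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  tab <- table(sheet$pair_id, sheet$tissue)
  if (any(tab != 1)) {
    stop("each pair_id must have exactly one HCC and one NTL row", call. = FALSE)
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet A sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a probe manifest (TSV)
#'
#' @param path File path.
#' @return `probe_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  man$gene_symbol[is.na(man$gene_symbol)] <- ""
  needed <- c("probe_id", "chrom", "pos", "island_relation", "gene_symbol", "feature")
  miss <- setdiff(needed, names(man))
  if (length(miss) > 0) {
    stop(sprintf("manifest missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(man$probe_id)) stop("duplicate probe ids in manifest", call. = FALSE)
  man <- man[order(man$chrom, man$pos), , drop = FALSE]
  rownames(man) <- NULL
  class(man) <- c("probe_manifest", "data.frame")
  man
}

#' @rdname read_manifest
#' @param manifest A probe manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write gene sets in GMT format
#'
#' GMT: one set per line, tab-delimited — name, description, then member
#' genes.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  class(sets) <- c("gene_sets", "list")
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export probe or region calls as BED
#'
#' Emits 0-based half-open intervals: single-base intervals
#' `[pos - 1, pos)` for probe tables (DMPs joined to positions) and
#' `[start - 1, end)` for region tables. The name column carries the
#' probe id or direction, the score column the (mean) Delta beta scaled
#' by 1000 and truncated to [-1000, 1000].
#'
#' @param x A probe table (`probe_id`, `chrom`, `pos`, `direction`,
#'   `delta_beta`) or a [call_dmrs()] result.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if ("pos" %in% names(x)) {
    bed <- data.frame(chrom = x$chrom, start = x$pos - 1L, end = x$pos,
                      name = paste(x$probe_id, x$direction, sep = "|"),
                      score = as.integer(clamp(round(1000 * x$delta_beta), -1000, 1000)))
  } else {
    bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                      name = paste0(x$direction, "_", x$n_probes, "probes"),
                      score = as.integer(clamp(round(1000 * x$mean_delta_beta), -1000, 1000)))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits `manifest.tsv`, `samples.csv`, `beta_bs.tsv`, `beta_oxbs.tsv`,
#' `expression.tsv`, `genesets.gmt` and `truth.json` under `outdir`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(sim$manifest, file.path(outdir, "manifest.tsv"))
  write_sample_sheet(sim$sheet, file.path(outdir, "samples.csv"))
  write_matrix_tsv(sim$beta_bs, file.path(outdir, "beta_bs.tsv"))
  write_matrix_tsv(sim$beta_oxbs, file.path(outdir, "beta_oxbs.tsv"))
  write_matrix_tsv(sim$expression, file.path(outdir, "expression.tsv"),
                   id_col = "gene_symbol")
  write_gmt(sim$genesets, file.path(outdir, "genesets.gmt"))
  truth <- sim$truth
  truth$true_5mc_ntl <- NULL; truth$true_5mc_hcc <- NULL
  truth$true_5hmc_ntl <- NULL; truth$true_5hmc_hcc <- NULL
  jsonlite::write_json(truth, file.path(outdir, "truth.json"), dataframe = "columns")
  invisible(outdir)
}
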