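#' Call differentially methylated regions by the neighboring-CpG rule
#'
#' Aggregates significant probes into regions: a DMR is a maximal run of
#' same-direction significant probes along a chromosome in which each
#' consecutive pair is at most `max_gap` bp apart (chain rule), containing
#' at least `min_probes` probes, each with `|delta_beta| > min_delta`.
#' With `span_mode = TRUE` the total span (last - first position) must not
#' exceed `max_gap` instead.
#'
#' @param probes `data.frame` with columns `probe_id`, `chrom`, `pos`,
#'   `direction` (`hyper`/`hypo`) and `delta_beta` — typically DMP calls
#'   joined to the manifest (see [dmps_with_positions()]).
#' @param max_gap Maximum gap between consecutive member probes in bp
#'   (default 250).
#' @param min_probes Minimum probes per region (default 2).
#' @param min_delta Member probes must satisfy `|delta_beta| > min_delta`
#'   (default 0.2).
#' @param span_mode If TRUE, constrain the total region span instead of
#'   consecutive gaps.
#' @return `data.frame` of class `dmr_calls`: `chrom`, `start`, `end`
#'   (1-based inclusive positions of the first/last member probe),
#'   `n_probes`, `direction`, `mean_delta_beta`, sorted by (chrom, start).
#' @examples
#' df <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
#'                  pos = c(100L, 200L, 500L), direction = "hyper",
#'                  delta_beta = 0.25)
#' call_dmrs(df)
#' @export
call_dmrs <- function(probes, max_gap = 250, min_probes = 2, min_delta = 0.2,
                      span_mode = FALSE) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0), direction = character(0),
                      mean_delta_beta = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("dmr_calls", "data.frame")
  if (nrow(probes) == 0) return(empty)

  probes <- probes[abs(probes$delta_beta) > min_delta, , drop = FALSE]
  if (nrow(probes) == 0) return(empty)
  ord <- order(probes$chrom, probes$pos)
  if (!identical(ord, seq_len(nrow(probes)))) {
    warning("probes not sorted by (chrom, pos); sorting internally")
    probes <- probes[ord, , drop = FALSE]
  }
  if (anyDuplicated(probes[, c("chrom", "pos")])) {
    stop("duplicate probe positions", call. = FALSE)
  }

  # break runs at chromosome change, direction change, or gap > max_gap
  n <- nrow(probes)
  new_run <- c(TRUE, probes$chrom[-1] != probes$chrom[-n] |
                 probes$direction[-1] != probes$direction[-n] |
                 (probes$pos[-1] - probes$pos[-n]) > max_gap)
  run_id <- cumsum(new_run)

  regions <- lapply(split(seq_len(n), run_id), function(idx) {
    sub <- probes[idx, , drop = FALSE]
    if (span_mode) {
      # longest prefix fitting within the span constraint, scanned greedily
      keep <- sub$pos - sub$pos[1] <= max_gap
      sub <- sub[keep, , drop = FALSE]
    }
    if (nrow(sub) < min_probes) return(NULL)
    data.frame(chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
               n_probes = nrow(sub), direction = sub$direction[1],
               mean_delta_beta = mean(sub$delta_beta), stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, regions)
  if (is.null(regions)) return(empty)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("dmr_calls", "data.frame")
  regions
}

#' Join DMP calls to manifest positions
#'
#' Convenience helper producing the input expected by [call_dmrs()]: DMP
#' rows with `chrom` and `pos` from the manifest, sorted by position.
#'
#' @param dmps DMP table with `probe_id`, `direction`, `delta_beta`.
#' @param manifest Probe manifest.
#' @return `data.frame` sorted by (chrom, pos).
#' @export
dmps_with_positions <- function(dmps, manifest) {
  idx <- match(dmps$probe_id, manifest$probe_id)
  if (anyNA(idx)) stop("DMP probes missing from manifest", call. = FALSE)
  out <- data.frame(probe_id = dmps$probe_id,
                    chrom = manifest$chrom[idx],
                    pos = manifest$pos[idx],
                    direction = dmps$direction,
                    delta_beta = dmps$delta_beta,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
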