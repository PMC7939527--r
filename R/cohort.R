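#' Label pairs as AYA or MOA by age at diagnosis
#'
#' Adolescents and young adults (AYA) are patients aged `cutoff` (default
#' 44) or younger; middle and old age (MOA) otherwise. Both members of a
#' tumor/normal pair share the patient's age, so the label is per pair.
#'
#' @param sheet A sample sheet (see [generate_cohort()] for the schema).
#' @param cutoff Age cutoff in years; AYA iff `age <= cutoff`.
#' @return The sheet with an added factor column `age_group` with levels
#'   `AYA`, `MOA`.
#' @examples
#' sheet <- generate_cohort(sim_config(n_pairs = 4, seed = 3))
#' table(stratify_by_age(sheet)$age_group)
#' @export
stratify_by_age <- function(sheet, cutoff = 44) {
  if (anyNA(sheet$age)) {
    bad <- unique(sheet$pair_id[is.na(sheet$age)])
    stop(sprintf("missing age for pair(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  sheet$age_group <- factor(ifelse(sheet$age <= cutoff, "AYA", "MOA"),
                            levels = c("AYA", "MOA"))
  sheet
}

#' Normalize serum AFP by tumor size
#'
#' Serum alpha-fetoprotein (ng/mL) divided by tumor diameter (cm), giving
#' ng/mL per tumor-cm, a crude burden-adjusted marker level.
#'
#' @param afp AFP in ng/mL (nonnegative).
#' @param tumor_size Tumor diameter in cm (positive).
#' @return `afp / tumor_size`; `NA` where `tumor_size` is missing or
#'   nonpositive (flagged with a warning).
#' @examples
#' normalize_afp(1000, 10) # 100
#' @export
normalize_afp <- function(afp, tumor_size) {
  out <- rep(NA_real_, length(afp))
  ok <- !is.na(tumor_size) & tumor_size > 0 & !is.na(afp)
  if (any(!is.na(tumor_size) & tumor_size <= 0)) {
    warning("nonpositive tumor_size; normalized AFP set to NA")
  }
  out[ok] <- afp[ok] / tumor_size[ok]
  out
}

describe_continuous <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                range = c(NA_real_, NA_real_), iqr = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       median = stats::median(x), range = range(x), iqr = q[2] - q[1])
}

describe_categorical <- function(x, denom = NULL) {
  x <- x[!is.na(x)]
  tab <- table(x)
  n <- if (is.null(denom)) sum(tab) else denom
  list(counts = as.list(tab),
       percent = lapply(as.list(tab), function(k) percent(k, n)))
}

compare_groups <- function(values, group, type) {
  g <- droplevels(factor(group[!is.na(values)]))
  v <- values[!is.na(values)]
  if (nlevels(g) < 2 || min(table(g)) < 2) {
    return(list(p = NA_real_, test = "unavailable"))
  }
  if (type == "continuous") {
    ht <- tryCatch(stats::t.test(v ~ g), error = function(e) NULL) # Welch
    if (is.null(ht)) return(list(p = NA_real_, test = "unavailable"))
    return(list(p = ht$p.value, test = "Welch t-test"))
  }
  tab <- table(v, g)
  if (nrow(tab) < 2) return(list(p = NA_real_, test = "unavailable"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = stats::fisher.test(tab)$p.value, test = "Fisher exact")
  } else {
    list(p = suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
         test = "chi-square")
  }
}

#' Summarize a paired cohort, overall and by age stratum
#'
#' Produces per-variable descriptive blocks (counts, one-decimal
#' percentages, mean, SD, median, range, IQR) for the whole cohort and for
#' the AYA/MOA strata, with between-stratum comparisons: Welch t-test for
#' continuous variables, chi-square for categoricals (Fisher's exact when
#' any expected cell is below 5). With a single stratum the tests are
#' flagged unavailable. AFP is additionally reported normalized per
#' tumor-cm via [normalize_afp()].
#'
#' @param sheet A sample sheet; one row per sample, tissue HCC/NTL.
#' @param cutoff AYA age cutoff passed to [stratify_by_age()].
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(sheet, cutoff = 44) {
  sheet <- stratify_by_age(sheet, cutoff)
  # one row per patient: clinical covariates are pair-level
  pts <- sheet[!duplicated(sheet$pair_id), , drop = FALSE]
  n <- nrow(pts)
  grp <- pts$age_group
  strata <- list(overall = rep(TRUE, n), AYA = grp == "AYA", MOA = grp == "MOA")

  block <- function(f) lapply(strata, function(sel) f(pts[sel, , drop = FALSE]))

  out <- list(
    n_pairs = lapply(strata, sum),
    age_group_percent = list(
      AYA = percent(sum(grp == "AYA"), n),
      MOA = percent(sum(grp == "MOA"), n)
    ),
    age = block(function(d) describe_continuous(d$age)),
    sex = block(function(d) describe_categorical(d$sex)),
    hbv = block(function(d) describe_categorical(d$hbv_positive)),
    cirrhosis = block(function(d) describe_categorical(d$cirrhosis)),
    tumor_size = block(function(d) describe_continuous(d$tumor_size)),
    afp = block(function(d) describe_continuous(d$afp)),
    afp_per_cm = block(function(d)
      describe_continuous(normalize_afp(d$afp, d$tumor_size))),
    tests = list(
      age = compare_groups(pts$age, grp, "continuous"),
      sex = compare_groups(pts$sex, grp, "categorical"),
      hbv = compare_groups(pts$hbv_positive, grp, "categorical"),
      cirrhosis = compare_groups(pts$cirrhosis, grp, "categorical"),
      tumor_size = compare_groups(pts$tumor_size, grp, "continuous"),
      afp_per_cm = compare_groups(normalize_afp(pts$afp, pts$tumor_size),
                                  grp, "continuous")
    )
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d AYA [%.1f%%], %d MOA [%.1f%%])\n",
              x$n_pairs$overall, x$n_pairs$AYA, x$age_group_percent$AYA,
              x$n_pairs$MOA, x$age_group_percent$MOA))
  cat(sprintf("  age: mean %.1f (SD %.1f), median %.1f, range [%g-%g]\n",
              x$age$overall$mean, x$age$overall$sd, x$age$overall$median,
              x$age$overall$range[1], x$age$overall$range[2]))
  hbv <- x$hbv$overall$percent[["TRUE"]]
  if (!is.null(hbv)) cat(sprintf("  HBV positive: %.1f%%\n", hbv))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (!is.na(t$p)) cat(sprintf("  %s: p = %.3g (%s)\n", nm, t$p, t$test))
  }
  invisible(x)
}
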