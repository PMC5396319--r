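# Exact 2x2 statistics for cohort subgroup comparisons. The two-sided Fisher
# p-value uses point-probability ordering: with both margins fixed, sum the
# hypergeometric probabilities of every table whose point probability does
# not exceed that of the observed table (relative tie tolerance 1e-7). This
# is the classical definition used by mainstream statistics packages and
# reproduces the published cohort p-values. Tests are run at the 5% level
# with no multiplicity adjustment, matching an exploratory analysis design.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The table is laid out as rows = groups, columns = lesion present/absent:
#' \preformatted{ a  b
#'  c  d }
#' so group frequencies are `a/(a+b)` and `c/(c+d)`.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_two_sided(11, 24, 10, 98) # BTG1-style comparison, p ~ .004
#' @export
fisher_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("all four counts must be non-negative integers")
  }
  row1 <- a + b; row2 <- c + d
  col1 <- a + c
  total <- row1 + row2
  if (total == 0) stop("at least one margin must be nonzero")
  # support of the (1,1) cell with all margins fixed
  support <- max(0, col1 - row2):min(row1, col1)
  logp <- log_hyper_pmf(support, col1, row1, total)
  log_obs <- log_hyper_pmf(a, col1, row1, total)
  # point-probability ordering with a relative tolerance for ties
  keep <- logp <= log_obs + log(1 + 1e-7)
  p <- sum(exp(logp[keep]))
  min(max(p, .Machine$double.xmin), 1)
}

#' Attach lesion indicators to a sample sheet
#'
#' Builds the cohort table used by [compare_lesion_frequencies()]: one row
#' per sample with a logical column per lesion gene, `TRUE` when the gene is
#' in that sample's defective set (optionally restricted to particular
#' evidence classes).
#'
#' @param sample_sheet tibble with `sample_id` plus grouping columns
#'   (`subtype`, `ds_status`).
#' @param defective defective-gene tibble (see [build_defective_sets()]).
#' @param genes character vector of lesion genes to indicate.
#' @param evidence restrict to these evidence classes (default: any).
#' @return The sample sheet with one logical column per gene.
#' @export
lesion_indicator_table <- function(sample_sheet, defective, genes,
                                   evidence = c("mutation", "sv_breakpoint",
                                                "cna_region")) {
  hit <- defective
  tags <- intersect(evidence, c("mutation", "sv_breakpoint", "cna_region"))
  if (all(tags %in% names(hit))) {
    keep <- Reduce(`|`, lapply(tags, function(t) hit[[t]]))
    hit <- hit[keep, , drop = FALSE]
  }
  out <- sample_sheet
  for (g in genes) {
    carriers <- unique(hit$sample_id[hit$gene_id == g])
    out[[g]] <- out$sample_id %in% carriers
  }
  out
}

#' Compare lesion frequencies between two cohort subgroups
#'
#' For each lesion, counts carriers in the two groups defined by `group_by`,
#' computes group frequencies and a two-sided Fisher exact p-value, with no
#' multiple-comparisons adjustment. Samples whose group status is missing or
#' `"unknown"` are excluded from the denominators. Display columns round
#' percentages to integers and format p-values in the journal style
#' (3 decimals, `"< .001"` below 0.0005); the unrounded values are retained.
#'
#' @param cohort tibble with `sample_id`, the grouping column, and one
#'   logical indicator column per lesion (see [lesion_indicator_table()]).
#' @param lesions names of the indicator columns to test.
#' @param group_by grouping column name, e.g. `"subtype"` (IGH vs P2RY8) or
#'   `"ds_status"` (DS vs nonDS).
#' @param groups optional length-2 character vector fixing the group order
#'   (group A first); defaults to the sorted distinct known values.
#' @return A `lesion_comparison` object; `tidy()` gives one row per lesion
#'   with counts `a,b,c,d`, `freq_a`, `freq_b` (unrounded percentages),
#'   `freq_a_pct`, `freq_b_pct` (integer display), `p_value`, `p_display`.
#' @export
compare_lesion_frequencies <- function(cohort, lesions, group_by = "subtype",
                                       groups = NULL) {
  stopifnot(group_by %in% names(cohort))
  g <- as.character(cohort[[group_by]])
  known <- !is.na(g) & g != "unknown"
  if (is.null(groups)) groups <- sort(unique(g[known]))
  if (length(groups) != 2) {
    stop("group_by must yield exactly two known groups, got: ",
         paste(groups, collapse = ", "))
  }
  in_a <- known & g == groups[[1]]
  in_b <- known & g == groups[[2]]
  if (sum(in_a) == 0 || sum(in_b) == 0) {
    warning("empty group; comparisons skipped")
    rows <- tibble::tibble()
  } else {
    rows <- purrr::map_dfr(lesions, function(lesion) {
      ind <- cohort[[lesion]]
      a <- sum(ind[in_a]); b <- sum(!ind[in_a])
      cc <- sum(ind[in_b]); d <- sum(!ind[in_b])
      tibble::tibble(
        lesion = lesion,
        group_a = groups[[1]], group_b = groups[[2]],
        a = a, b = b, c = cc, d = d,
        freq_a = 100 * a / (a + b),
        freq_b = 100 * cc / (cc + d),
        p_value = fisher_two_sided(a, b, cc, d)
      )
    }) |>
      dplyr::mutate(freq_a_pct = as.integer(round(.data$freq_a)),
                    freq_b_pct = as.integer(round(.data$freq_b)),
                    p_display = format_p(.data$p_value))
  }
  structure(list(results = rows, group_by = group_by, groups = groups,
                 n_a = sum(in_a), n_b = sum(in_b),
                 n_excluded = sum(!known)),
            class = "lesion_comparison")
}

#' @export
print.lesion_comparison <- function(x, ...) {
  cat("Lesion frequency comparison by ", x$group_by, ": ",
      x$groups[[1]], " (n = ", x$n_a, ") vs ", x$groups[[2]],
      " (n = ", x$n_b, ")",
      if (x$n_excluded > 0) paste0("; ", x$n_excluded, " unknown excluded"),
      "\n", sep = "")
  if (nrow(x$results) > 0) {
    shown <- dplyr::transmute(
      x$results, lesion = .data$lesion,
      !!x$groups[[1]] := sprintf("%d/%d (%d%%)", .data$a, .data$a + .data$b,
                                 .data$freq_a_pct),
      !!x$groups[[2]] := sprintf("%d/%d (%d%%)", .data$c, .data$c + .data$d,
                                 .data$freq_b_pct),
      P = .data$p_display)
    print(shown, ...)
  }
  invisible(x)
}

#' @rdname compare_lesion_frequencies
#' @param x a `lesion_comparison` object.
#' @param ... unused.
#' @export
tidy.lesion_comparison <- function(x, ...) {
  x$results
}

#' @rdname compare_lesion_frequencies
#' @export
glance.lesion_comparison <- function(x, ...) {
  tibble::tibble(group_by = x$group_by,
                 group_a = x$groups[[1]], group_b = x$groups[[2]],
                 n_a = x$n_a, n_b = x$n_b, n_excluded = x$n_excluded,
                 n_lesions = nrow(x$results),
                 n_significant = sum(x$results$p_value < 0.05))
}

#' Journal-style p-value formatting
#'
#' Three decimals without a leading zero; values below 0.0005 print as
#' `"< .001"`.
#'
#' @param p numeric vector of p-values.
#' @return Character vector, e.g. `".004"`, `"< .001"`.
#' @export
format_p <- function(p) {
  out <- sub("^0", "", sprintf("%.3f", p))
  out[p < 0.0005] <- "< .001"
  out
}

#' FISH false-positive cutoff from control slides
#'
#' Control slides from cytogenetically normal individuals are scored for the
#' probe's abnormal signal pattern; the positivity cutoff is the mean
#' false-positive percentage plus three sample standard deviations
#' (n - 1 denominator). Only the upper bound is used: positivity calls act
#' on false-positive excess.
#'
#' @param rates per-slide false-positive percentages (each slide scored on at
#'   least 100 nuclei); at least two controls are required for the standard
#'   deviation to exist.
#' @return Cutoff percentage.
#' @examples
#' determine_fish_cutoff(c(1, 2, 3, 2, 2)) # 2 + 3 * sqrt(0.5) ~ 4.12
#' @export
determine_fish_cutoff <- function(rates) {
  if (length(rates) < 2) stop("need >= 2 control rates (SD undefined)")
  if (any(rates < 0 | rates > 100)) stop("rates must be percentages in [0, 100]")
  mean(rates) + 3 * stats::sd(rates)
}

#' Call FISH positivity against a control-derived cutoff
#'
#' A sample is positive iff its abnormal-nuclei percentage strictly exceeds
#' the cutoff and at least `min_nuclei` nuclei were scored; a sample exactly
#' at the cutoff is negative.
#'
#' @param percent abnormal-nuclei percentage(s).
#' @param cutoff cutoff from [determine_fish_cutoff()].
#' @param n_nuclei nuclei scored per sample.
#' @param min_nuclei minimum evaluable nuclei (default 100).
#' @return Logical vector.
#' @export
fish_positive <- function(percent, cutoff, n_nuclei, min_nuclei = 100) {
  percent > cutoff & n_nuclei >= min_nuclei
}

#' Per-patient lesion burden summary
#'
#' Per-modality mean/min/max lesion counts per patient (point mutations and
#' in/dels split by ref/alt length, structural variants, copy-number
#' segments), plus a VAF summary: the fraction of depth-evaluable mutations
#' with VAF above 30% and below 20%. Means are reported unrounded with a
#' 1-decimal display column.
#'
#' @param mutations mutation tibble (>= 1 sample).
#' @param svs optional SV tibble (typically after [filter_sv_candidates()]).
#' @param segments optional CNA segment tibble.
#' @return A `burden_summary` object: `$counts` (tibble `modality`, `mean`,
#'   `mean_display`, `min`, `max`), `$vaf` (tibble `n_evaluable`,
#'   `frac_vaf_gt_30`, `frac_vaf_lt_20`, `median_vaf`), `$n_samples`.
#' @export
summarize_burden <- function(mutations, svs = NULL, segments = NULL) {
  if (nrow(mutations) == 0) stop("need >= 1 sample with mutation calls")
  samples <- unique(c(mutations$sample_id, svs$sample_id, segments$sample_id))
  is_indel <- nchar(mutations$ref) != nchar(mutations$alt)
  per_sample_counts <- function(tbl, keep = TRUE) {
    sid <- tbl$sample_id[keep]
    counts <- table(factor(sid, levels = samples))
    as.numeric(counts)
  }
  modalities <- list(
    mutations_total = per_sample_counts(mutations),
    point_mutations = per_sample_counts(mutations, !is_indel),
    indels = per_sample_counts(mutations, is_indel)
  )
  if (!is.null(svs)) modalities$svs <- per_sample_counts(svs)
  if (!is.null(segments)) modalities$cna_segments <- per_sample_counts(segments)
  counts <- purrr::imap_dfr(modalities, function(v, nm) {
    tibble::tibble(modality = nm, mean = mean(v),
                   mean_display = round(mean(v), 1),
                   min = min(v), max = max(v))
  })
  v <- vaf(mutations$alt_depth, mutations$total_depth)
  v <- v[!is.na(v)]
  vaf_tbl <- tibble::tibble(
    n_evaluable = length(v),
    frac_vaf_gt_30 = if (length(v)) mean(v > 0.30) else NA_real_,
    frac_vaf_lt_20 = if (length(v)) mean(v < 0.20) else NA_real_,
    median_vaf = if (length(v)) stats::median(v) else NA_real_
  )
  structure(list(counts = counts, vaf = vaf_tbl,
                 n_samples = length(samples)),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat("Lesion burden over", x$n_samples, "sample(s)\n")
  print(x$counts, ...)
  cat("VAF: ")
  print(x$vaf, ...)
  invisible(x)
}

#' @rdname summarize_burden
#' @param x a `burden_summary` object.
#' @param ... unused.
#' @export
tidy.burden_summary <- function(x, ...) {
  x$counts
}

#' @rdname summarize_burden
#' @export
glance.burden_summary <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_samples = x$n_samples), x$vaf)
}
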