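# Hypergeometric pathway enrichment. The model: a patient group's pooled
# defective-gene list of size n is treated as a draw without replacement from
# the N protein-coding genes of the annotation (N = 20,805 for GRCh37.p13).
# For a pathway with K member genes, the enrichment p-value is the upper tail
# P(X >= x) of the hypergeometric distribution, where x is the observed
# overlap between the defective list and the pathway. Tests are reported
# unadjusted at the 5% level; an optional Benjamini-Hochberg column is
# available for exploratory ranking.

# log of the hypergeometric point mass P(X = i | K, n, N)
log_hyper_pmf <- function(i, K, n, N) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: the chance that at least
#' `x` of `n` genes drawn without replacement from a universe of `N` genes
#' fall in a category of size `K`. Terms are evaluated in log space via
#' log-gamma binomial coefficients, and whichever tail has fewer terms is
#' summed directly (the other is obtained by complement), so tiny upper-tail
#' p-values are computed without cancellation.
#'
#' `P(X >= 0) = 1` by construction; `x > min(K, n)` is impossible and returns
#' 0 with a warning.
#'
#' @param x observed overlap (non-negative integer).
#' @param K category (pathway) size, `K <= N`.
#' @param n draw (defective-list) size, `n <= N`.
#' @param N universe size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_tail <- function(x, K, n, N) {
  stopifnot(length(x) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  x <- as.numeric(x); K <- as.numeric(K); n <- as.numeric(n); N <- as.numeric(N)
  if (any(c(x, K, n, N) < 0) || K > N || n > N) {
    stop("require 0 <= x, K <= N, n <= N")
  }
  hi <- min(K, n)
  lo <- max(0, n - (N - K))
  if (x > hi) {
    warning("x = ", x, " exceeds min(K, n) = ", hi, "; returning p = 0")
    return(0)
  }
  if (x <= lo) return(1)
  upper <- x:hi
  lower <- lo:(x - 1)
  if (length(upper) <= length(lower)) {
    p <- sum(exp(log_hyper_pmf(upper, K, n, N)))
  } else {
    p <- 1 - sum(exp(log_hyper_pmf(lower, K, n, N)))
  }
  min(max(p, 0), 1)
}

#' Pathway enrichment of a group's pooled defective genes
#'
#' Pools the defective genes of the given samples (union; each gene counted
#' once), intersects the pooled list with each pathway and computes the
#' upper-tail hypergeometric p-value against the database's background
#' universe. Pathways are flagged significant at p < 0.05 with no
#' multiple-testing adjustment (an optional BH column can be requested).
#' Results are ordered by (p-value, pathway_id) for determinism.
#'
#' @param defective defective-gene tibble (see [build_defective_sets()]) with
#'   columns `sample_id`, `gene_id`; pass a pre-filtered subset to test one
#'   subgroup.
#' @param db a [pathway_db()].
#' @param group_label label stored on every result row (e.g. `"all"`,
#'   `"IGH"`, `"P2RY8"`).
#' @param universe optional character vector enumerating the background gene
#'   universe; defective genes outside it are excluded from `n` with a
#'   warning. When `NULL` (default) all defective genes are assumed to lie in
#'   the universe, whose size is `background_n(db)`.
#' @param method `"pooled"` (default: one test on the group union) or
#'   `"per_sample"` (test each sample separately, then average x, n and p per
#'   pathway across samples).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param adjust add a Benjamini-Hochberg `p_adjusted` column.
#' @return A `crlf2_enrichment` object; `tidy()` returns the result tibble
#'   (`pathway_id`, `name`, `x`, `K`, `n`, `N`, `p_value`, `significant`,
#'   `group_label`), `glance()` a one-row summary.
#' @export
enrich_pathways <- function(defective, db, group_label = "all",
                            universe = NULL, method = c("pooled", "per_sample"),
                            alpha = 0.05, adjust = FALSE) {
  method <- match.arg(method)
  if (nrow(defective) == 0) stop("no defective genes: group is empty")
  if (method == "per_sample") {
    per <- lapply(split(defective, defective$sample_id), function(d) {
      tidy(enrich_pathways(d, db, group_label = d$sample_id[[1]],
                           universe = universe, method = "pooled",
                           alpha = alpha))
    })
    res <- dplyr::bind_rows(per) |>
      dplyr::group_by(.data$pathway_id, .data$name, .data$K, .data$N) |>
      dplyr::summarise(x = mean(.data$x), n = mean(.data$n),
                       p_value = mean(.data$p_value), .groups = "drop") |>
      dplyr::mutate(group_label = group_label,
                    significant = .data$p_value < alpha) |>
      dplyr::arrange(.data$p_value, .data$pathway_id)
    return(new_enrichment(res, group_label, length(per), background_n(db)))
  }
  genes <- unique(defective$gene_id)
  if (!is.null(universe)) {
    outside <- setdiff(genes, universe)
    if (length(outside) > 0) {
      warning(length(outside), " defective gene(s) outside the background ",
              "universe excluded from n: ", paste(outside, collapse = ", "))
      genes <- intersect(genes, universe)
    }
  }
  N_bg <- background_n(db)
  n_def <- length(genes)
  if (n_def > N_bg) {
    stop("defective list (", n_def, ") larger than the universe (", N_bg, ")")
  }
  res <- pathway_sizes(db) |>
    dplyr::rename(K = "n_genes") |>
    dplyr::mutate(
      x = purrr::map_int(.data$pathway_id, function(pw) {
        length(intersect(genes, db$gene_id[db$pathway_id == pw]))
      }),
      n = n_def, N = N_bg,
      p_value = purrr::map2_dbl(.data$x, .data$K,
                                function(x, K) hypergeom_tail(x, K, n_def, N_bg)),
      significant = .data$p_value < alpha,
      group_label = group_label
    ) |>
    dplyr::select("pathway_id", "name", "x", "K", "n", "N", "p_value",
                  "significant", "group_label") |>
    dplyr::arrange(.data$p_value, .data$pathway_id)
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  new_enrichment(res, group_label, length(unique(defective$sample_id)), N_bg)
}

new_enrichment <- function(results, group_label, n_samples, N) {
  structure(list(results = results, group_label = group_label,
                 n_samples = n_samples, background_n = N),
            class = "crlf2_enrichment")
}

#' @export
print.crlf2_enrichment <- function(x, ...) {
  cat("Pathway enrichment (hypergeometric, N = ", x$background_n,
      "), group '", x$group_label, "', ", x$n_samples, " sample(s)\n",
      sep = "")
  print(x$results, ...)
  invisible(x)
}

#' @rdname enrich_pathways
#' @param x a `crlf2_enrichment` object.
#' @param ... unused.
#' @export
tidy.crlf2_enrichment <- function(x, ...) {
  x$results
}

#' @rdname enrich_pathways
#' @export
glance.crlf2_enrichment <- function(x, ...) {
  tibble::tibble(
    group_label = x$group_label,
    n_samples = x$n_samples,
    n_pathways = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_defective = if (nrow(x$results) > 0) max(x$results$n) else 0L,
    background_n = x$background_n,
    min_p = if (nrow(x$results) > 0) min(x$results$p_value) else NA_real_
  )
}

#' Patient-by-pathway defective-gene count matrix
#'
#' For each (pathway, sample) cell, the number of that sample's defective
#' genes belonging to the pathway. Per-sample totals count each gene once
#' even when it belongs to several displayed pathways; per-pathway totals are
#' the row sums of the cells. When `pathways` is `NULL`, the `top_k` pathways
#' by per-pathway total are selected, ties broken lexicographically by
#' pathway id.
#'
#' @param defective defective-gene tibble (`sample_id`, `gene_id`).
#' @param db a [pathway_db()].
#' @param pathways pathway ids to display, or `NULL` for top-`top_k`.
#' @param top_k number of pathways to keep when `pathways` is `NULL`.
#' @return A `pathway_matrix` object: `$cells` (tibble `pathway_id` x
#'   `sample_id` with `count`), `$sample_totals` (unique defective genes per
#'   sample across displayed pathways), `$pathway_totals` (cell sums).
#' @export
pathway_matrix <- function(defective, db, pathways = NULL, top_k = 10) {
  samples <- sort(unique(defective$sample_id))
  memb <- dplyr::inner_join(
    dplyr::distinct(defective, .data$sample_id, .data$gene_id),
    dplyr::distinct(db, .data$pathway_id, .data$gene_id),
    by = "gene_id", relationship = "many-to-many"
  )
  totals_all <- memb |>
    dplyr::count(.data$pathway_id, name = "total") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$pathway_id)
  if (is.null(pathways)) {
    pathways <- utils::head(totals_all$pathway_id, top_k)
  } else {
    missing_pw <- setdiff(pathways, unique(db$pathway_id))
    if (length(missing_pw) > 0) {
      stop("pathway(s) not in the database: ", paste(missing_pw, collapse = ", "))
    }
  }
  grid <- tidyr::expand_grid(pathway_id = pathways, sample_id = samples)
  cells <- memb |>
    dplyr::filter(.data$pathway_id %in% pathways) |>
    dplyr::count(.data$pathway_id, .data$sample_id, name = "count") |>
    dplyr::right_join(grid, by = c("pathway_id", "sample_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(match(.data$pathway_id, pathways), .data$sample_id)
  # genes in >= 2 displayed pathways are counted once in the sample totals
  sample_totals <- memb |>
    dplyr::filter(.data$pathway_id %in% pathways) |>
    dplyr::distinct(.data$sample_id, .data$gene_id) |>
    dplyr::count(.data$sample_id, name = "n_genes") |>
    dplyr::right_join(tibble::tibble(sample_id = samples), by = "sample_id") |>
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L)) |>
    dplyr::arrange(.data$sample_id)
  pathway_totals <- cells |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(match(.data$pathway_id, pathways))
  structure(list(cells = cells, sample_totals = sample_totals,
                 pathway_totals = pathway_totals, pathways = pathways,
                 samples = samples),
            class = "pathway_matrix")
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat("Patient x pathway defective-gene matrix: ", length(x$pathways),
      " pathway(s) x ", length(x$samples), " sample(s)\n", sep = "")
  print(as_matrix(x), ...)
  invisible(x)
}

#' Dense matrix form of a [pathway_matrix()]
#' @param x a `pathway_matrix`.
#' @return Integer matrix, pathways in rows, samples in columns.
#' @export
as_matrix <- function(x) {
  stopifnot(inherits(x, "pathway_matrix"))
  wide <- tidyr::pivot_wider(x$cells, names_from = "sample_id",
                             values_from = "count")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$pathway_id
  m
}

#' @rdname pathway_matrix
#' @param x a `pathway_matrix` object.
#' @param ... unused.
#' @export
tidy.pathway_matrix <- function(x, ...) {
  x$cells
}

#' Write a [pathway_matrix()] as TSV (cells) and JSON (cells plus totals)
#' @param x a `pathway_matrix`.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_pathway_matrix <- function(x, tsv = NULL, json = NULL) {
  written <- character()
  if (!is.null(tsv)) {
    wide <- tidyr::pivot_wider(x$cells, names_from = "sample_id",
                               values_from = "count")
    readr::write_tsv(wide, tsv, progress = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(cells = x$cells, sample_totals = x$sample_totals,
           pathway_totals = x$pathway_totals),
      json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, json)
  }
  invisible(written)
}
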