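# The defective-gene rule integrates the three lesion modalities: a gene is
# defective in a patient if (1) it carries at least one nonsilent mutation,
# (2) it lies at a breakpoint junction of a validated structural variant, or
# (3) it lies inside a focal copy-number region of at most `max_region_bp`
# (default 1 Mb = 1,000,000 bp, inclusive). Targeted per-gene MLPA "deleted"
# calls enter through criterion (3): they are single-gene focal copy-number
# assays.

#' Genes carrying at least one nonsilent mutation
#'
#' @param mutations mutation tibble (see [read_mutations_vcf()]); typically
#'   one sample's calls.
#' @param model a [gene_model()].
#' @return Character vector of gene ids (sorted, unique).
#' @export
genes_with_nonsilent_mutation <- function(mutations, model) {
  sort(unique(mutation_gene_hits(mutations, model)$gene_id))
}

# long evidence rows: one per (mutation record, overlapped gene)
mutation_gene_hits <- function(mutations, model) {
  empty <- tibble::tibble(sample_id = character(), gene_id = character(),
                          record_id = character())
  if (is.null(mutations) || nrow(mutations) == 0) return(empty)
  ns <- mutations[is_nonsilent(mutations$consequence), , drop = FALSE]
  if (nrow(ns) == 0) return(empty)
  regions <- tibble::tibble(region_id = seq_len(nrow(ns)), chrom = ns$chrom,
                            start = ns$pos, end = ns$pos + 1L)
  hits <- overlap_join(model, regions)
  tibble::tibble(
    sample_id = ns$sample_id[hits$region_id],
    gene_id = hits$gene_id,
    record_id = sprintf("mut:%s:%d:%s>%s", ns$chrom[hits$region_id],
                        ns$pos[hits$region_id], ns$ref[hits$region_id],
                        ns$alt[hits$region_id])
  )
}

#' Genes at structural-variant breakpoint junctions
#'
#' Takes the union over both breakpoints of the genes whose interval contains
#' the breakpoint position (half-open containment, so a breakpoint at a
#' gene's start coordinate hits it, one at its end coordinate does not).
#' Callers should pass SVs that already passed [filter_sv_candidates()].
#'
#' @param svs SV tibble (see [read_sv_bedpe()]).
#' @param model a [gene_model()].
#' @return Character vector of gene ids (sorted, unique).
#' @export
genes_at_sv_breakpoints <- function(svs, model) {
  sort(unique(sv_gene_hits(svs, model)$gene_id))
}

sv_gene_hits <- function(svs, model) {
  empty <- tibble::tibble(sample_id = character(), gene_id = character(),
                          record_id = character())
  if (is.null(svs) || nrow(svs) == 0) return(empty)
  ends <- dplyr::bind_rows(
    tibble::tibble(region_id = seq_len(nrow(svs)), chrom = svs$chrom_a,
                   start = svs$pos_a, end = svs$pos_a + 1L),
    tibble::tibble(region_id = seq_len(nrow(svs)), chrom = svs$chrom_b,
                   start = svs$pos_b, end = svs$pos_b + 1L)
  )
  hits <- overlap_join(model, ends)
  tibble::tibble(
    sample_id = svs$sample_id[hits$region_id],
    gene_id = hits$gene_id,
    record_id = paste0("sv:", svs$sv_id[hits$region_id])
  )
}

#' Genes inside focal ("small") defective copy-number regions
#'
#' Only segments whose size `end - start` does not exceed `max_region_bp`
#' contribute; larger segments (arm-level or whole-chromosome events)
#' contribute nothing. The cap is inclusive: a segment of exactly
#' 1,000,000 bp qualifies.
#'
#' @param segments CNA segment tibble (see [read_cna_seg()]).
#' @param model a [gene_model()].
#' @param max_region_bp inclusive focal-region size cap in bp
#'   (default 1,000,000 = 1 Mb).
#' @param states copy-number states that qualify; both losses and gains by
#'   default, set to `"loss"` for a deletions-only rule.
#' @return Character vector of gene ids (sorted, unique).
#' @export
genes_in_small_defective_regions <- function(segments, model,
                                             max_region_bp = 1e6,
                                             states = c("loss", "gain")) {
  sort(unique(cna_gene_hits(segments, model, max_region_bp, states)$gene_id))
}

cna_gene_hits <- function(segments, model, max_region_bp = 1e6,
                          states = c("loss", "gain")) {
  stopifnot(max_region_bp > 0)
  empty <- tibble::tibble(sample_id = character(), gene_id = character(),
                          record_id = character())
  if (is.null(segments) || nrow(segments) == 0) return(empty)
  keep <- segments[(segments$end - segments$start) <= max_region_bp &
                     segments$state %in% states, , drop = FALSE]
  if (nrow(keep) == 0) return(empty)
  regions <- tibble::tibble(region_id = seq_len(nrow(keep)), chrom = keep$chrom,
                            start = keep$start, end = keep$end)
  hits <- overlap_join(model, regions)
  tibble::tibble(
    sample_id = keep$sample_id[hits$region_id],
    gene_id = hits$gene_id,
    record_id = paste0("cna:", keep$seg_id[hits$region_id])
  )
}

mlpa_gene_hits <- function(mlpa, model) {
  empty <- tibble::tibble(sample_id = character(), gene_id = character(),
                          record_id = character())
  if (is.null(mlpa) || nrow(mlpa) == 0) return(empty)
  del <- mlpa[mlpa$status == "deleted", , drop = FALSE]
  del <- del[del$gene_id %in% model$gene_id, , drop = FALSE]
  if (nrow(del) == 0) return(empty)
  tibble::tibble(sample_id = del$sample_id, gene_id = del$gene_id,
                 record_id = paste0("mlpa:", del$gene_id))
}

#' Per-patient defective-gene evidence (long form, audit trail)
#'
#' One row per (sample, gene, evidence class, supporting record). This is the
#' audit trail behind [build_defective_sets()]: every tagged gene traces to at
#' least one input lesion record via `record_id`.
#'
#' @param mutations,svs,segments,mlpa lesion tibbles for one or more samples;
#'   any may be `NULL`. `svs` should already have passed
#'   [filter_sv_candidates()].
#' @param model a [gene_model()].
#' @inheritParams genes_in_small_defective_regions
#' @return Tibble: `sample_id`, `gene_id`,
#'   `evidence` in `mutation, sv_breakpoint, cna_region`, `record_id`.
#' @export
defective_evidence <- function(mutations = NULL, svs = NULL, segments = NULL,
                               mlpa = NULL, model, max_region_bp = 1e6,
                               states = c("loss", "gain")) {
  dplyr::bind_rows(
    dplyr::mutate(mutation_gene_hits(mutations, model), evidence = "mutation"),
    dplyr::mutate(sv_gene_hits(svs, model), evidence = "sv_breakpoint"),
    dplyr::mutate(cna_gene_hits(segments, model, max_region_bp, states),
                  evidence = "cna_region"),
    dplyr::mutate(mlpa_gene_hits(mlpa, model), evidence = "cna_region")
  ) |>
    dplyr::distinct() |>
    dplyr::select("sample_id", "gene_id", "evidence", "record_id") |>
    dplyr::arrange(.data$sample_id, .data$gene_id, .data$evidence,
                   .data$record_id)
}

#' Build per-patient defective-gene sets
#'
#' Applies the three-criterion defective-gene rule to every sample present in
#' the inputs and returns one row per (sample, gene) with logical evidence
#' tags. A gene may carry several tags (e.g. mutated and inside a focal
#' deletion); breakpoint genes of copy-number-type SVs that also appear under
#' the focal-region criterion are deduplicated at the gene level, keeping both
#' tags.
#'
#' @inheritParams defective_evidence
#' @return Tibble: `sample_id`, `gene_id`, logical `mutation`,
#'   `sv_breakpoint`, `cna_region`, and `evidence` (comma-joined tags).
#' @export
build_defective_sets <- function(mutations = NULL, svs = NULL, segments = NULL,
                                 mlpa = NULL, model, max_region_bp = 1e6,
                                 states = c("loss", "gain")) {
  ev <- defective_evidence(mutations, svs, segments, mlpa, model,
                           max_region_bp, states)
  unknown <- setdiff(unique(ev$gene_id), model$gene_id)
  if (length(unknown) > 0) {
    stop("defective gene absent from the gene model: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(ev) == 0) {
    return(tibble::tibble(sample_id = character(), gene_id = character(),
                          mutation = logical(), sv_breakpoint = logical(),
                          cna_region = logical(), evidence = character()))
  }
  ev |>
    dplyr::distinct(.data$sample_id, .data$gene_id, .data$evidence) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "evidence", values_from = "present",
                       values_fill = FALSE) |>
    ensure_tag_columns() |>
    dplyr::mutate(evidence = paste_tags(.data$mutation, .data$sv_breakpoint,
                                        .data$cna_region)) |>
    dplyr::select("sample_id", "gene_id", "mutation", "sv_breakpoint",
                  "cna_region", "evidence") |>
    dplyr::arrange(.data$sample_id, .data$gene_id)
}

ensure_tag_columns <- function(df) {
  for (tag in c("mutation", "sv_breakpoint", "cna_region")) {
    if (!tag %in% names(df)) df[[tag]] <- FALSE
  }
  df
}

paste_tags <- function(mutation, sv_breakpoint, cna_region) {
  purrr::pmap_chr(list(mutation, sv_breakpoint, cna_region), function(m, s, k) {
    paste(c("mutation"[m], "sv_breakpoint"[s], "cna_region"[k]), collapse = ",")
  })
}

#' Write per-sample defective-gene tables
#'
#' One TSV per sample (`<sample_id>.defective.tsv`, columns gene_id, evidence,
#' record ids) plus a cohort-level JSON mapping each sample to its defective
#' genes with tags.
#'
#' @param sets result of [build_defective_sets()].
#' @param evidence result of [defective_evidence()] (for the record-id audit
#'   column); optional.
#' @param dir output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_defective_sets <- function(sets, dir, evidence = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (sid in unique(sets$sample_id)) {
    s <- sets[sets$sample_id == sid, , drop = FALSE]
    if (!is.null(evidence)) {
      recs <- evidence[evidence$sample_id == sid, , drop = FALSE] |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(records = paste(sort(unique(.data$record_id)),
                                         collapse = ";"), .groups = "drop")
      s <- dplyr::left_join(s, recs, by = "gene_id")
    }
    f <- file.path(dir, paste0(sid, ".defective.tsv"))
    readr::write_tsv(dplyr::select(s, -"sample_id"), f, progress = FALSE)
    files <- c(files, f)
  }
  cohort <- lapply(split(sets, sets$sample_id), function(s) {
    stats::setNames(as.list(s$evidence), s$gene_id)
  })
  jf <- file.path(dir, "defective_sets.json")
  jsonlite::write_json(cohort, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, jf))
}
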