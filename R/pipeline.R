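# End-to-end orchestration: ingest -> defective-gene construction ->
# enrichment per group -> subgroup statistics -> patient x pathway matrix ->
# burden summary. Stages communicate only through files under `out_dir`, and
# every output is a pure function of the declared inputs, so identical
# inputs yield an identical manifest (md5 checksums).

#' Run the full landscape analysis
#'
#' @param out_dir output directory (created; must be writable).
#' @param vcf character vector of per-sample annotated VCF paths.
#' @param bedpe path to the cohort SV BEDPE.
#' @param seg path to the cohort SEG file.
#' @param mlpa path to the MLPA TSV.
#' @param sample_sheet path to the sample sheet TSV.
#' @param genes_bed path to the gene model BED.
#' @param pathways_gmt path to the pathway GMT.
#' @param background_n background universe size for enrichment
#'   (default 20805, the GRCh37.p13 protein-coding gene count).
#' @param max_region_bp focal copy-number region cap (default 1 Mb).
#' @param min_sv_support minimum SV read-pair support (default 5).
#' @param lesions genes whose frequencies are compared between subgroups
#'   (default: the recurrently deleted panel genes found in the MLPA file,
#'   falling back to genes defective in >= 2 samples).
#' @param top_k pathways shown in the patient-by-pathway matrix.
#' @return Invisibly, a list with the output `manifest` (tibble `file`,
#'   `md5`) and the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, vcf, bedpe, seg, mlpa, sample_sheet,
                         genes_bed, pathways_gmt, background_n = 20805,
                         max_region_bp = 1e6, min_sv_support = 5,
                         lesions = NULL, top_k = 10) {
  inputs <- c(vcf, bedpe, seg, mlpa, sample_sheet, genes_bed, pathways_gmt)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    stop("input file(s) not found, refusing to start: ",
         paste(missing_in, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  ## ingest
  model <- read_gene_bed(genes_bed)
  db <- read_gmt(pathways_gmt, background_n = background_n)
  sheet <- read_sample_sheet(sample_sheet)
  mutations <- purrr::map_dfr(vcf, read_mutations_vcf)
  svs_all <- read_sv_bedpe(bedpe)
  svs <- filter_sv_candidates(svs_all, min_support = min_sv_support)
  cna <- read_cna_seg(seg)
  mlpa_calls <- read_mlpa_tsv(mlpa)

  ## defective genes
  evidence <- defective_evidence(mutations, svs, cna, mlpa_calls, model,
                                 max_region_bp = max_region_bp)
  sets <- build_defective_sets(mutations, svs, cna, mlpa_calls, model,
                               max_region_bp = max_region_bp)
  outputs <- c(outputs,
               write_defective_sets(sets, file.path(out_dir, "defective"),
                                    evidence = evidence))

  ## enrichment: whole cohort plus each subtype and DS group
  groups <- list(all = sheet$sample_id)
  for (st in c("IGH", "P2RY8")) {
    groups[[st]] <- sheet$sample_id[sheet$subtype == st]
  }
  for (ds in c("DS", "nonDS")) {
    groups[[ds]] <- sheet$sample_id[sheet$ds_status == ds]
  }
  enrichments <- list()
  for (gname in names(groups)) {
    members <- sets[sets$sample_id %in% groups[[gname]], , drop = FALSE]
    if (nrow(members) == 0) {
      warning("group '", gname, "' has no defective genes; enrichment skipped")
      next
    }
    e <- enrich_pathways(members, db, group_label = gname,
                         universe = model$gene_id)
    enrichments[[gname]] <- e
    f <- file.path(out_dir, paste0("enrichment_", gname, ".tsv"))
    readr::write_tsv(tidy(e), f, progress = FALSE)
    outputs <- c(outputs, f)
  }

  ## subgroup comparisons
  if (is.null(lesions)) {
    lesions <- sort(unique(mlpa_calls$gene_id))
    if (length(lesions) == 0) {
      recurrent <- dplyr::count(sets, .data$gene_id)
      lesions <- sort(recurrent$gene_id[recurrent$n >= 2])
    }
  }
  cohort_tbl <- lesion_indicator_table(sheet, sets, lesions)
  comparisons <- list()
  for (by in c("subtype", "ds_status")) {
    groups_by <- if (by == "subtype") c("IGH", "P2RY8") else c("DS", "nonDS")
    cmp <- compare_lesion_frequencies(cohort_tbl, lesions, group_by = by,
                                      groups = groups_by)
    comparisons[[by]] <- cmp
    f <- file.path(out_dir, paste0("comparison_", by, ".tsv"))
    readr::write_tsv(tidy(cmp), f, progress = FALSE)
    outputs <- c(outputs, f)
  }

  ## patient x pathway matrix
  pm <- pathway_matrix(sets, db, top_k = top_k)
  outputs <- c(outputs, write_pathway_matrix(
    pm, tsv = file.path(out_dir, "pathway_matrix.tsv"),
    json = file.path(out_dir, "pathway_matrix.json")))

  ## burden summary
  burden <- summarize_burden(mutations, svs = svs, segments = cna)
  f <- file.path(out_dir, "burden.tsv")
  readr::write_tsv(tidy(burden), f, progress = FALSE)
  outputs <- c(outputs, f)
  f <- file.path(out_dir, "burden.json")
  jsonlite::write_json(list(counts = burden$counts, vaf = burden$vaf),
                       f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs <- c(outputs, f)

  ## manifest
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, defective = sets, evidence = evidence,
                 enrichments = enrichments, comparisons = comparisons,
                 matrix = pm, burden = burden))
}
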