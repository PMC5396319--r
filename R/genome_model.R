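#' Construct a gene model from a data frame
#'
#' A gene model is a tibble of gene intervals on which all lesion-to-gene
#' annotation is performed. Coordinates are 0-based half-open (`[start, end)`),
#' the BED convention; readers for 1-based formats convert at the boundary.
#' Strand is stored but never consulted by overlap queries: region-to-gene
#' mapping of somatic lesions is strand-agnostic.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (`"+"`/`"-"`, default `"+"`).
#' @return A `gene_model` tibble, one row per gene.
#' @examples
#' gene_model(data.frame(gene_id = "IKZF1", chrom = "chr7",
#'                       start = 50344378, end = 50472799))
#' @export
gene_model <- function(genes) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene model is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes <- dplyr::select(genes, "gene_id", "chrom", "start", "end", "strand")
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  validate_gene_model(genes)
  class(genes) <- c("gene_model", class(genes))
  genes
}

validate_gene_model <- function(genes) {
  if (nrow(genes) == 0) return(invisible(genes))
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id in gene model: ", paste(dup, collapse = ", "))
  }
  bad <- which(!(genes$start < genes$end))
  if (length(bad) > 0) {
    stop("zero- or negative-length gene interval for: ",
         paste(genes$gene_id[bad], collapse = ", "))
  }
  if (any(!nzchar(genes$chrom)) || anyNA(genes$chrom)) {
    stop("empty chromosome name in gene model")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(genes)
}

#' Read a gene model from a BED4+ file
#'
#' Columns: chrom, start, end, gene_id (further columns, e.g. score/strand,
#' are honoured when present in BED6 order). Coordinates are taken as
#' BED-native 0-based half-open. Malformed lines are reported with their line
#' numbers; duplicate gene ids and zero-length intervals are errors.
#'
#' @param path path to a BED file with the gene id in column 4.
#' @return A [gene_model()] tibble.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("gene BED file not found: ", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(gene_model(tibble::tibble(gene_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4)) {
    stop("BED line(s) with fewer than 4 columns at line(s): ",
         paste(which(n_fields < 4), collapse = ", "))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric BED coordinates at line(s): ",
         paste(which(is.na(start) | is.na(end)), collapse = ", "))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop("start >= end (zero-length interval) at line(s): ",
         paste(bad, collapse = ", "))
  }
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "+", "")
  strand[!strand %in% c("+", "-")] <- "+"
  gene_model(tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end,
    gene_id = vapply(fields, `[[`, "", 4L),
    strand = strand
  ))
}

#' Write a gene model to BED4+ (round-trips with [read_gene_bed()])
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(model, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   model$chrom, model$start, model$end, model$gene_id,
                   model$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Genes overlapping a genomic region
#'
#' Returns the ids of genes whose `[start, end)` interval intersects the query
#' `[start, end)` with non-zero width. Matching is half-open on both sides, so
#' a query beginning at a gene's `end` coordinate does not hit it. Unknown
#' chromosomes yield an empty result, not an error. Strand is ignored.
#'
#' @param model a [gene_model()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval, `start < end`.
#' @return Character vector of gene ids (sorted, unique).
#' @export
genes_overlapping <- function(model, chrom, start, end) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  if (start >= end) stop("query must satisfy start < end")
  hits <- overlap_join(model, tibble::tibble(
    region_id = 1L, chrom = chrom, start = as.integer(start), end = as.integer(end)
  ))
  sort(unique(hits$gene_id))
}

# Vectorised interval overlap of query regions against the gene model.
# regions: tibble with region_id, chrom, start, end (0-based half-open).
# Returns tibble (region_id, gene_id), one row per overlapping pair.
# IRanges uses closed 1-based intervals; half-open [s, e) maps to [s + 1, e].
overlap_join <- function(model, regions) {
  empty <- tibble::tibble(region_id = regions$region_id[0], gene_id = character())
  if (nrow(model) == 0 || nrow(regions) == 0) return(empty)
  out <- vector("list", 0L)
  for (chr in intersect(unique(regions$chrom), unique(model$chrom))) {
    g <- model[model$chrom == chr, ]
    q <- regions[regions$chrom == chr, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = q$start + 1L, end = q$end),
      IRanges::IRanges(start = g$start + 1L, end = g$end)
    )
    out[[length(out) + 1L]] <- tibble::tibble(
      region_id = q$region_id[S4Vectors::queryHits(hits)],
      gene_id = g$gene_id[S4Vectors::subjectHits(hits)]
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Construct a pathway database
#'
#' Pathway membership is held long (one row per pathway-gene pair) with the
#' size of the background gene universe attached as an attribute. The universe
#' is a parameter rather than being derived from the GMT because enrichment is
#' tested against all protein-coding genes in the annotation (20,805 for
#' GRCh37.p13), not merely the genes covered by the pathway collection.
#'
#' @param sets data frame with columns `pathway_id`, `name`, `gene_id`.
#' @param background_n size of the gene universe sampled without replacement
#'   by the enrichment test. Default 20805, the protein-coding gene count of
#'   the GRCh37.p13 annotation.
#' @return A `pathway_db` tibble with attribute `background_n`.
#' @export
pathway_db <- function(sets, background_n = 20805) {
  sets <- tibble::as_tibble(sets)
  stopifnot(all(c("pathway_id", "name", "gene_id") %in% names(sets)))
  sets <- dplyr::distinct(sets, .data$pathway_id, .data$name, .data$gene_id)
  sizes <- dplyr::count(sets, .data$pathway_id)
  if (any(sizes$n == 0) || nrow(sets) == 0 && nrow(sizes) > 0) {
    stop("pathway with zero genes")
  }
  background_n <- as.integer(background_n)
  if (nrow(sizes) > 0 && background_n < max(sizes$n)) {
    stop("background_n (", background_n,
         ") is smaller than the largest pathway (", max(sizes$n), " genes)")
  }
  attr(sets, "background_n") <- background_n
  class(sets) <- c("pathway_db", class(sets))
  sets
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated `pathway_id`,
#' `description`, then gene ids. Empty pathways and duplicate pathway ids are
#' errors.
#'
#' @inheritParams pathway_db
#' @param path path to a GMT file.
#' @return A [pathway_db()] tibble.
#' @export
read_gmt <- function(path, background_n = 20805) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("pathway with zero genes at GMT line(s): ", paste(short, collapse = ", "))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate pathway_id in GMT: ", paste(dup, collapse = ", "))
  }
  sets <- purrr::map_dfr(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    tibble::tibble(pathway_id = f[[1]], name = f[[2]], gene_id = genes)
  })
  pathway_db(sets, background_n = background_n)
}

#' Write a pathway database to GMT (round-trips with [read_gmt()])
#' @param db a [pathway_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  by_pw <- split(db$gene_id, db$pathway_id)
  names_by_pw <- vapply(split(db$name, db$pathway_id), `[[`, "", 1L)
  ids <- sort(names(by_pw))
  lines <- vapply(ids, function(id) {
    paste(c(id, names_by_pw[[id]], by_pw[[id]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Pathway sizes of a pathway database
#' @param db a [pathway_db()].
#' @return Tibble with `pathway_id`, `name`, `n_genes`.
#' @export
pathway_sizes <- function(db) {
  dplyr::summarise(dplyr::group_by(db, .data$pathway_id, .data$name),
                   n_genes = dplyr::n(), .groups = "drop")
}

#' Background universe size of a pathway database
#' @param db a [pathway_db()].
#' @return Integer scalar.
#' @export
background_n <- function(db) {
  attr(db, "background_n")
}
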