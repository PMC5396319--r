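# Consequence vocabulary. "Nonsilent" (protein-altering) classes are the ones
# that qualify a gene as defective; the synonym map accepts the usual
# VEP/SnpEff-style Sequence Ontology strings. Unknown terms are errors, never
# silently demoted to noncoding, because the defective-gene rule hinges on
# this classification.
CONSEQUENCE_LEVELS <- c("missense", "nonsense", "frameshift", "inframe_indel",
                        "splice", "silent", "noncoding")

NONSILENT_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                       "splice")

CONSEQUENCE_SYNONYMS <- c(
  missense = "missense",
  missense_variant = "missense",
  start_lost = "missense",
  stop_lost = "missense",
  nonsense = "nonsense",
  stop_gained = "nonsense",
  frameshift = "frameshift",
  frameshift_variant = "frameshift",
  inframe_indel = "inframe_indel",
  inframe_insertion = "inframe_indel",
  inframe_deletion = "inframe_indel",
  splice = "splice",
  splice_acceptor_variant = "splice",
  splice_donor_variant = "splice",
  splice_region_variant = "splice",
  silent = "silent",
  synonymous_variant = "silent",
  noncoding = "noncoding",
  intron_variant = "noncoding",
  intergenic_variant = "noncoding",
  upstream_gene_variant = "noncoding",
  downstream_gene_variant = "noncoding",
  non_coding_transcript_variant = "noncoding",
  "5_prime_UTR_variant" = "noncoding",
  "3_prime_UTR_variant" = "noncoding"
)

#' Normalise consequence annotations to the package vocabulary
#'
#' @param x character vector of consequence terms (package vocabulary or
#'   VEP/SnpEff-style synonyms, e.g. `"stop_gained"`).
#' @return Character vector over
#'   `missense, nonsense, frameshift, inframe_indel, splice, silent, noncoding`.
#'   Unknown terms raise an error listing the accepted vocabulary.
#' @export
normalize_consequence <- function(x) {
  out <- unname(CONSEQUENCE_SYNONYMS[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown consequence term(s): ", paste(bad, collapse = ", "),
         "\naccepted terms: ", paste(names(CONSEQUENCE_SYNONYMS), collapse = ", "))
  }
  out
}

#' Read somatic mutation calls from an annotated VCF
#'
#' Expects a VCF 4.x with a per-record consequence term in an INFO tag
#' (default `CSQ`) and allelic depths in the genotype `AD` (alt depth taken as
#' the first ALT count) with total depth from `DP` or the sum of `AD`.
#' Positions are converted from VCF 1-based to the package's 0-based
#' convention. Records with missing depths are kept with
#' `total_depth = 0` and flagged in `depth_missing`.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample_id sample identifier; defaults to the VCF's (single) genotype
#'   column name, falling back to the file name stem.
#' @param csq_tag INFO tag holding the consequence term.
#' @return Tibble with one row per call: `sample_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `consequence`, `alt_depth`, `total_depth`, `depth_missing`.
#' @export
read_mutations_vcf <- function(path, sample_id = NULL, csq_tag = "CSQ") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character(),
                          consequence = character(), alt_depth = integer(),
                          total_depth = integer(), depth_missing = logical()))
  }
  if (is.null(sample_id)) {
    gt_samples <- colnames(v@gt)
    gt_samples <- setdiff(gt_samples, "FORMAT")
    sample_id <- if (length(gt_samples) >= 1) gt_samples[[1]] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  csq <- vcfR::extract.info(v, element = csq_tag)
  if (all(is.na(csq))) {
    stop("no '", csq_tag, "' INFO tag found in ", path)
  }
  # consequence may carry trailing VEP fields (allele|gene|...): take field 1
  csq <- vapply(strsplit(csq, "|", fixed = TRUE), `[[`, "", 1L)
  consequence <- normalize_consequence(csq)

  ad <- tryCatch(unname(vcfR::extract.gt(v, element = "AD")[, 1]),
                 error = function(e) rep(NA_character_, nrow(fix)))
  dp <- tryCatch(suppressWarnings(
    as.integer(unname(vcfR::extract.gt(v, element = "DP")[, 1]))),
    error = function(e) rep(NA_integer_, nrow(fix)))
  ad_parts <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  alt_depth <- vapply(ad_parts, function(p) {
    if (length(p) >= 2) suppressWarnings(as.integer(p[[2]])) else NA_integer_
  }, 1L)
  ad_total <- vapply(ad_parts, function(p) {
    s <- suppressWarnings(as.integer(p))
    if (length(s) == 0 || anyNA(s)) NA_integer_ else sum(s)
  }, 1L)
  total_depth <- dplyr::coalesce(dp, ad_total)
  depth_missing <- is.na(total_depth) | is.na(alt_depth)
  total_depth[is.na(total_depth)] <- 0L
  alt_depth[is.na(alt_depth)] <- 0L
  if (any(!depth_missing & alt_depth > total_depth)) {
    stop("alt depth exceeds total depth in ", path)
  }
  tibble::tibble(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    consequence = consequence,
    alt_depth = alt_depth,
    total_depth = total_depth,
    depth_missing = depth_missing
  )
}

#' Variant allele frequency
#'
#' `alt_depth / total_depth`. Calls with zero total depth have an undefined
#' VAF and return `NA` (never 0), so that depth-less records cannot
#' masquerade as reference-only observations.
#'
#' @param alt_depth,total_depth integer read counts,
#'   `0 <= alt_depth <= total_depth`.
#' @return Numeric vector in `[0, 1]`, `NA` where `total_depth == 0`.
#' @export
vaf <- function(alt_depth, total_depth) {
  if (any(alt_depth < 0 | total_depth < 0, na.rm = TRUE)) {
    stop("read depths must be non-negative")
  }
  if (any(alt_depth > total_depth, na.rm = TRUE)) {
    stop("alt_depth must not exceed total_depth")
  }
  ifelse(total_depth > 0, alt_depth / total_depth, NA_real_)
}

#' Is a mutation protein-altering ("nonsilent")?
#'
#' @param consequence character vector over the package consequence
#'   vocabulary (see [normalize_consequence()]).
#' @return Logical: `TRUE` for missense, nonsense, frameshift, inframe_indel
#'   and splice; `FALSE` for silent and noncoding.
#' @export
is_nonsilent <- function(consequence) {
  bad <- setdiff(unique(consequence), CONSEQUENCE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
         " (run normalize_consequence() first)")
  }
  consequence %in% NONSILENT_CLASSES
}

#' Read structural-variant calls from a BEDPE file
#'
#' Columns 1-10 follow BEDPE (chromA, startA, endA, chromB, startB, endB,
#' name, score, strandA, strandB); column 11 is the discordant read-pair
#' support and column 12 the breakpoint annotation context
#' (`coding_span`, `same_intron` or `noncoding`). The breakpoint position is
#' taken as the 0-based start of each end. Breakpoint pairs are normalised so
#' that (chromA, posA) sorts at or before (chromB, posB).
#'
#' @param path path to a BEDPE file.
#' @param sample_id sample identifier; defaults to the BEDPE name column's
#'   prefix before the first `":"`, else the file name stem.
#' @return Tibble: `sample_id`, `sv_id`, `chrom_a`, `pos_a`, `orient_a`,
#'   `chrom_b`, `pos_b`, `orient_b`, `read_pair_support`,
#'   `annotation_context`.
#' @export
read_sv_bedpe <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  cols <- readr::cols(.default = readr::col_character())
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = cols,
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(sample_id = character(), sv_id = character(),
                          chrom_a = character(), pos_a = integer(),
                          orient_a = character(), chrom_b = character(),
                          pos_b = integer(), orient_b = character(),
                          read_pair_support = integer(),
                          annotation_context = character()))
  }
  if (ncol(raw) < 12) stop("BEDPE needs 12 columns (10 + support + context), got ",
                           ncol(raw))
  name <- raw[[7]]
  sid <- if (!is.null(sample_id)) rep(sample_id, nrow(raw)) else {
    guess <- sub(":.*$", "", name)
    ifelse(nzchar(guess) & guess != name, guess,
           sub("\\.bedpe$", "", basename(path)))
  }
  support <- as.integer(raw[[11]])
  if (any(is.na(support) | support < 1)) {
    stop("read_pair_support must be an integer >= 1 (line ",
         paste(which(is.na(support) | support < 1), collapse = ", "), ")")
  }
  context <- raw[[12]]
  ok_ctx <- c("coding_span", "same_intron", "noncoding")
  if (!all(context %in% ok_ctx)) {
    stop("annotation_context must be one of: ", paste(ok_ctx, collapse = ", "))
  }
  out <- tibble::tibble(
    sample_id = sid,
    sv_id = name,
    chrom_a = raw[[1]], pos_a = as.integer(raw[[2]]), orient_a = raw[[9]],
    chrom_b = raw[[4]], pos_b = as.integer(raw[[5]]), orient_b = raw[[10]],
    read_pair_support = support,
    annotation_context = context
  )
  if (!all(c(out$orient_a, out$orient_b) %in% c("+", "-"))) {
    stop("breakpoint orientations must be '+' or '-'")
  }
  swap <- out$chrom_a > out$chrom_b |
    (out$chrom_a == out$chrom_b & out$pos_a > out$pos_b)
  if (any(swap)) {
    tmp <- out[swap, ]
    out[swap, c("chrom_a", "pos_a", "orient_a")] <-
      tmp[, c("chrom_b", "pos_b", "orient_b")]
    out[swap, c("chrom_b", "pos_b", "orient_b")] <-
      tmp[, c("chrom_a", "pos_a", "orient_a")]
  }
  out
}

#' Select validated structural-variant candidates
#'
#' Keeps rearrangements supported by at least `min_support` discordant
#' read pairs whose breakpoint pair spans coding sequence — i.e. excludes
#' candidates where both reads fall in the same intron or entirely outside
#' coding regions. Input order is preserved.
#'
#' @param svs SV tibble as returned by [read_sv_bedpe()].
#' @param min_support minimum read-pair support (default 5).
#' @return The qualifying subset of `svs`.
#' @export
filter_sv_candidates <- function(svs, min_support = 5) {
  stopifnot(min_support >= 1)
  dplyr::filter(svs, .data$read_pair_support >= min_support,
                .data$annotation_context == "coding_span")
}

#' Classify structural variants by breakpoint geometry
#'
#' Interchromosomal events are translocations. For intrachromosomal events
#' the breakpoints are ordered (posA <= posB) and the strand pair maps to:
#' `(+,-)` deletion, `(-,+)` tandem duplication, `(+,+)` or `(-,-)` inversion.
#'
#' @param svs SV tibble as returned by [read_sv_bedpe()].
#' @return `svs` with an `sv_class` column over
#'   `deletion, tandem_duplication, inversion, translocation`.
#' @export
classify_sv <- function(svs) {
  cls <- dplyr::case_when(
    svs$chrom_a != svs$chrom_b ~ "translocation",
    svs$orient_a == "+" & svs$orient_b == "-" ~ "deletion",
    svs$orient_a == "-" & svs$orient_b == "+" ~ "tandem_duplication",
    TRUE ~ "inversion"
  )
  dplyr::mutate(svs, sv_class = cls)
}

#' Read copy-number segments from a SEG file
#'
#' Tab-separated with a header: `sample_id`, `chrom`, `start`, `end`, `state`.
#' SEG coordinates are 1-based inclusive by convention and are converted to
#' 0-based half-open on read (start - 1, end unchanged).
#'
#' @param path path to a SEG file.
#' @return Tibble: `sample_id`, `seg_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `state` (`loss`/`gain`).
#' @export
read_cna_seg <- function(path) {
  if (!file.exists(path)) stop("SEG file not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    state = readr::col_character()
  ), progress = FALSE)
  if (!all(raw$state %in% c("loss", "gain"))) {
    stop("CNA state must be 'loss' or 'gain'")
  }
  start0 <- raw$start - 1L
  bad <- which(start0 >= raw$end)
  if (length(bad) > 0) {
    stop("CNA segment with start >= end at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  tibble::tibble(
    sample_id = raw$sample_id,
    seg_id = sprintf("%s:%s:%d-%d", raw$sample_id, raw$chrom, start0, raw$end),
    chrom = raw$chrom,
    start = start0,
    end = raw$end,
    state = raw$state
  )
}

#' Read MLPA-style per-gene copy-number calls
#'
#' Tab-separated with a header: `sample_id`, `gene_id`, `status` over
#' `deleted`, `normal`, `gained`, `failed`. At most one call per
#' (sample, gene) pair; duplicates are an error.
#'
#' @param path path to a TSV file.
#' @return Tibble: `sample_id`, `gene_id`, `status`.
#' @export
read_mlpa_tsv <- function(path) {
  if (!file.exists(path)) stop("MLPA file not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    gene_id = readr::col_character(),
    status = readr::col_character()
  ), progress = FALSE)
  ok <- c("deleted", "normal", "gained", "failed")
  if (!all(raw$status %in% ok)) {
    stop("MLPA status must be one of: ", paste(ok, collapse = ", "))
  }
  key <- paste(raw$sample_id, raw$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- raw[duplicated(key), , drop = FALSE]
    stop("duplicate MLPA call for (sample, gene): ",
         paste(unique(paste0(dup$sample_id, "/", dup$gene_id)), collapse = ", "))
  }
  tibble::as_tibble(raw)
}

#' Read a cohort sample sheet
#'
#' Tab-separated with a header: `sample_id`, `subtype` (`IGH`/`P2RY8`),
#' `ds_status` (`DS`/`nonDS`/`unknown`).
#'
#' @param path path to a TSV file.
#' @return Tibble: `sample_id`, `subtype`, `ds_status`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    subtype = readr::col_character(),
    ds_status = readr::col_character()
  ), progress = FALSE)
  if (!all(raw$subtype %in% c("IGH", "P2RY8"))) {
    stop("subtype must be 'IGH' or 'P2RY8'")
  }
  if (!all(raw$ds_status %in% c("DS", "nonDS", "unknown"))) {
    stop("ds_status must be 'DS', 'nonDS' or 'unknown'")
  }
  if (anyDuplicated(raw$sample_id)) stop("duplicate sample_id in sample sheet")
  tibble::as_tibble(raw)
}
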