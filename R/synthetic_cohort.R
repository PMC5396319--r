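# Truth-tracked synthetic cohort generator. It emulates the statistical
# structure the analysis assumes -- subtype-dependent focal deletion
# frequencies, per-patient point-mutation/indel/SV burdens, VAF mostly above
# 30% -- on a small synthetic genome, and records the defective-gene set each
# sample carries *by construction*, so every pipeline stage can be validated
# end-to-end without restricted patient data.

TOY_DRIVERS <- list(
  chr1 = c("IKZF1", "PAX5", "EBF1", "ETV6", "VPREB1"),
  chr2 = c("CDKN2A", "CDKN2B", "RB1", "BTG1", "ADD3"),
  chr3 = c("JAK2", "JAK1", "IL7R", "CRLF2", "NRAS", "USP9X", "DDX3X")
)

#' Toy gene model for simulation
#'
#' Three synthetic chromosomes with 24 genes each (50 kb genes tiled every
#' 400 kb, so focal segments with up to ~120 kb of flank never reach a
#' neighbouring gene, while CDKN2A/CDKN2B sit adjacent and are deleted as a
#' unit). Known driver genes occupy fixed slots; the rest are filler genes
#' `G01`, `G02`, ... The tiling-with-gaps layout makes interval edge cases
#' (breakpoint exactly at a gene start, segment spanning a gene boundary)
#' occur naturally.
#'
#' @param genes_per_chrom genes per chromosome (default 24).
#' @param gene_length gene length in bp (default 50,000).
#' @param spacing start-to-start gene spacing in bp (default 400,000).
#' @return A [gene_model()] of `3 * genes_per_chrom` genes.
#' @export
toy_gene_model <- function(genes_per_chrom = 24, gene_length = 50000,
                           spacing = 400000) {
  stopifnot(genes_per_chrom >= 10, gene_length < spacing)
  chroms <- paste0("chr", 1:3)
  filler_needed <- 3 * genes_per_chrom - length(unlist(TOY_DRIVERS))
  fillers <- sprintf("G%02d", seq_len(filler_needed))
  taken <- 0L
  rows <- list()
  for (chr in chroms) {
    drivers <- TOY_DRIVERS[[chr]]
    n_fill <- genes_per_chrom - length(drivers)
    ids <- c(drivers, fillers[taken + seq_len(n_fill)])
    taken <- taken + n_fill
    start <- 200000L + (seq_len(genes_per_chrom) - 1L) * as.integer(spacing)
    rows[[chr]] <- tibble::tibble(
      gene_id = ids, chrom = chr, start = start,
      end = start + as.integer(gene_length),
      strand = rep(c("+", "-"), length.out = genes_per_chrom)
    )
  }
  gene_model(dplyr::bind_rows(rows))
}

#' Toy pathway database for simulation
#'
#' Ten pathways of 6-8 genes drawn from [toy_gene_model()], mimicking the
#' kinds of KEGG sets relevant to B-ALL (JAK-STAT, cell cycle, B-cell
#' differentiation, focal adhesion, ...). Some genes belong to several
#' pathways so the counted-once rule of the patient-by-pathway matrix is
#' exercised. The background universe defaults to the full toy gene count:
#' for a simulated genome the universe is the genes that exist, whereas real
#' analyses pass `background_n = 20805` for the GRCh37.p13 protein-coding
#' complement.
#'
#' @param model a [toy_gene_model()].
#' @param background_n universe size (default: number of genes in `model`).
#' @return A [pathway_db()].
#' @export
toy_pathway_db <- function(model = toy_gene_model(),
                           background_n = nrow(model)) {
  sets <- list(
    JAK_STAT = c("JAK2", "JAK1", "IL7R", "CRLF2", "G01", "G02"),
    CELL_CYCLE = c("CDKN2A", "CDKN2B", "RB1", "BTG1", "G03", "G04"),
    B_CELL_DIFFERENTIATION = c("IKZF1", "PAX5", "EBF1", "ETV6", "VPREB1", "G05"),
    RAS_SIGNALING = c("NRAS", "G06", "G07", "G08", "G09", "G10"),
    FOCAL_ADHESION = sprintf("G%02d", 11:18),
    MAPK_SIGNALING = c("NRAS", sprintf("G%02d", 19:24)),
    HEMATOPOIETIC_LINEAGE = c("IL7R", "CRLF2", "G25", "G26", "G27", "G28"),
    PATHWAYS_IN_CANCER = c("IKZF1", "CDKN2A", "RB1", "NRAS", "JAK2", "G29", "G30"),
    X_LINKED_REGULATORS = c("USP9X", "DDX3X", "G31", "G32", "G33", "G34"),
    TP53_NETWORK = sprintf("G%02d", 35:40)
  )
  long <- purrr::imap_dfr(sets, function(genes, id) {
    tibble::tibble(pathway_id = id, name = gsub("_", " ", id), gene_id = genes)
  })
  stopifnot(all(long$gene_id %in% model$gene_id))
  pathway_db(long, background_n = background_n)
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the published cohort structure: 172 patients with
#' 47/172 IGH-CRLF2 and 125/172 P2RY8-CRLF2; Down-syndrome probability 0.20
#' (IGH) and 0.35 (P2RY8) with ~6% unknown status; subtype-dependent focal
#' deletion probabilities (IKZF1 0.71/0.33, BTG1 0.31/0.09, ADD3 0.46/0.13
#' for IGH/P2RY8; CDKN2A/B 0.38 and PAX5 0.30 in both); per-patient burdens
#' of Poisson(17) point mutations, Poisson(2.8) in/dels, Poisson(12.7)
#' validated SVs on top of Poisson(30.3) non-qualifying SV candidates (~43
#' candidates per patient in total); and VAF ~ Beta(8, 10) (median ~0.44,
#' roughly 80% of mass above 0.30), with one designated low-VAF outlier
#' patient drawn from Beta(2, 10).
#'
#' @param n_patients cohort size.
#' @param p_igh probability a patient is IGH-CRLF2 (else P2RY8-CRLF2).
#' @param ds_prob named numeric: Down-syndrome probability per subtype.
#' @param ds_unknown_prob probability DS status is unrecorded.
#' @param deletion_probs tibble `gene`, `IGH`, `P2RY8`: per-gene focal
#'   deletion probability by subtype.
#' @param point_mut_mean,indel_mean Poisson means for point mutations and
#'   in/dels per patient.
#' @param nonsilent_frac fraction of point mutations that are
#'   protein-altering (the remainder are silent).
#' @param sv_mean Poisson mean of validated SVs per patient (support >= 5,
#'   coding-span).
#' @param sv_extra_mean Poisson mean of non-qualifying SV candidates per
#'   patient (low support, same-intron or noncoding).
#' @param vaf_shape,low_vaf_shape Beta shape pairs for the VAF model and the
#'   outlier patient.
#' @param low_vaf_patient index of the low-VAF outlier patient (0 = none).
#' @param background_focal_mean Poisson mean of additional focal deletions
#'   hitting randomly chosen genes per patient.
#' @param large_cna_prob probability of one >1 Mb (non-focal) segment per
#'   patient, which must NOT contribute defective genes.
#' @param mlpa_fail_prob probability an MLPA probe fails per (sample, gene).
#' @param gene_weights named numeric of relative mutation/SV gene-targeting
#'   weights (default uniform).
#' @param enriched_pathways,enrichment_multiplier pathway ids whose genes get
#'   `enrichment_multiplier`-fold targeting weight (see
#'   [plant_enrichment()]).
#' @param modalities which lesion modalities to generate.
#' @param seed integer master seed (mandatory); per-sample substreams are
#'   derived deterministically from it, so enlarging the cohort never
#'   reshuffles existing samples.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 172,
                          p_igh = 47 / 172,
                          ds_prob = c(IGH = 0.20, P2RY8 = 0.35),
                          ds_unknown_prob = 11 / 172,
                          deletion_probs = default_deletion_probs(),
                          point_mut_mean = 17,
                          indel_mean = 2.8,
                          nonsilent_frac = 0.75,
                          sv_mean = 12.7,
                          sv_extra_mean = 30.3,
                          vaf_shape = c(8, 10),
                          low_vaf_shape = c(2, 10),
                          low_vaf_patient = 3,
                          background_focal_mean = 0.5,
                          large_cna_prob = 0.1,
                          mlpa_fail_prob = 0.02,
                          gene_weights = NULL,
                          enriched_pathways = character(),
                          enrichment_multiplier = 1,
                          modalities = c("mutations", "svs", "cna", "mlpa"),
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(p_igh, ds_prob, ds_unknown_prob, nonsilent_frac,
             deletion_probs$IGH, deletion_probs$P2RY8,
             large_cna_prob, mlpa_fail_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(point_mut_mean, indel_mean, sv_mean, sv_extra_mean) <= 0)) {
    stop("burden means must be > 0")
  }
  stopifnot(all(c("gene", "IGH", "P2RY8") %in% names(deletion_probs)),
            enrichment_multiplier >= 1)
  structure(list(
    n_patients = as.integer(n_patients), p_igh = p_igh, ds_prob = ds_prob,
    ds_unknown_prob = ds_unknown_prob,
    deletion_probs = tibble::as_tibble(deletion_probs),
    point_mut_mean = point_mut_mean, indel_mean = indel_mean,
    nonsilent_frac = nonsilent_frac, sv_mean = sv_mean,
    sv_extra_mean = sv_extra_mean, vaf_shape = vaf_shape,
    low_vaf_shape = low_vaf_shape, low_vaf_patient = as.integer(low_vaf_patient),
    background_focal_mean = background_focal_mean,
    large_cna_prob = large_cna_prob, mlpa_fail_prob = mlpa_fail_prob,
    gene_weights = gene_weights, enriched_pathways = enriched_pathways,
    enrichment_multiplier = enrichment_multiplier,
    modalities = modalities, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Published-default focal deletion probabilities by fusion subtype
#' @return Tibble `gene`, `IGH`, `P2RY8`.
#' @export
default_deletion_probs <- function() {
  tibble::tribble(
    ~gene,     ~IGH, ~P2RY8,
    "IKZF1",   0.71, 0.33,
    "BTG1",    0.31, 0.09,
    "ADD3",    0.46, 0.13,
    "CDKN2A",  0.38, 0.38,
    "CDKN2B",  0.38, 0.38,
    "PAX5",    0.30, 0.30
  )
}

#' Plant a pathway enrichment signal into a configuration
#'
#' Genes of the chosen pathway receive `multiplier`-fold lesion propensity:
#' their mutation/SV targeting weight is multiplied, and any per-gene focal
#' deletion probability is multiplied and capped at 1. A multiplier of 1
#' returns the configuration unchanged. Used to create a known-positive for
#' validating the enrichment test's power.
#'
#' @param cfg a [cohort_config()].
#' @param pathway_id a pathway in `db`.
#' @param multiplier weight multiplier (>= 1).
#' @param db the [pathway_db()] the simulation will use.
#' @return The modified `cohort_config`.
#' @export
plant_enrichment <- function(cfg, pathway_id, multiplier,
                             db = toy_pathway_db()) {
  stopifnot(inherits(cfg, "cohort_config"), multiplier >= 1)
  if (!pathway_id %in% db$pathway_id) {
    stop("pathway not in the database: ", pathway_id)
  }
  if (multiplier == 1) return(cfg)
  genes <- db$gene_id[db$pathway_id == pathway_id]
  cfg$enriched_pathways <- union(cfg$enriched_pathways, pathway_id)
  cfg$enrichment_multiplier <- multiplier
  hit <- cfg$deletion_probs$gene %in% genes
  cfg$deletion_probs$IGH[hit] <- pmin(1, cfg$deletion_probs$IGH[hit] * multiplier)
  cfg$deletion_probs$P2RY8[hit] <- pmin(1, cfg$deletion_probs$P2RY8[hit] * multiplier)
  cfg
}

# deterministic per-sample substream seed (kept < 2^31 - 1)
sample_substream <- function(master_seed, i) {
  as.integer((as.double(master_seed) * 48271 + as.double(i) * 16807) %%
               2147483647)
}

# genes of one chromosome containing a point (0-based), by arithmetic scan
genes_at_point <- function(genes_chr, pos) {
  genes_chr$gene_id[genes_chr$start <= pos & pos < genes_chr$end]
}

# draw a position outside every gene on the chromosome (rejection sampling)
intergenic_pos <- function(genes_chr, chrom_len) {
  repeat {
    pos <- floor(runif(1, 0, chrom_len))
    if (length(genes_at_point(genes_chr, pos)) == 0) return(as.integer(pos))
  }
}

#' Simulate a truth-tracked synthetic cohort
#'
#' Generates per-patient mutations, structural variants, copy-number
#' segments and MLPA calls under a [cohort_config()], together with the
#' defective-gene truth implied by construction. With `dir` set, all pipeline
#' input files are written (per-sample VCFs, BEDPE, SEG, MLPA TSV, sample
#' sheet, gene BED, pathway GMT, truth JSON); outputs are byte-identical
#' across reruns with the same seed.
#'
#' @param cfg a [cohort_config()].
#' @param dir output directory, or `NULL` for in-memory only.
#' @param model gene model (default [toy_gene_model()]).
#' @param db pathway database (default [toy_pathway_db()]).
#' @return A `synthetic_cohort` list: `config`, `model`, `db`,
#'   `sample_sheet`, `mutations`, `svs`, `cna`, `mlpa`, `truth` (tibble with
#'   the same shape as [build_defective_sets()] output) and, when `dir` is
#'   given, `files`.
#' @export
simulate_cohort <- function(cfg, dir = NULL, model = toy_gene_model(),
                            db = toy_pathway_db(model)) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 2) stop("n_patients must be >= 2")
  genes_by_chr <- split(as.data.frame(model), model$chrom)
  chroms <- names(genes_by_chr)
  chrom_len <- vapply(genes_by_chr, function(g) max(g$end) + 200000L, 1L)
  weights <- rep(1, nrow(model))
  names(weights) <- model$gene_id
  if (!is.null(cfg$gene_weights)) {
    weights[names(cfg$gene_weights)] <- cfg$gene_weights
  }
  if (length(cfg$enriched_pathways) > 0 && cfg$enrichment_multiplier > 1) {
    planted <- unique(db$gene_id[db$pathway_id %in% cfg$enriched_pathways])
    weights[planted] <- weights[planted] * cfg$enrichment_multiplier
  }
  # flat lookup vectors: fast per-sample access without tibble subsetting
  geo <- list(
    gene_id = model$gene_id,
    start = stats::setNames(model$start, model$gene_id),
    end = stats::setNames(model$end, model$gene_id),
    chrom = stats::setNames(model$chrom, model$gene_id),
    by_chr = lapply(genes_by_chr, function(g) {
      list(gene_id = g$gene_id, start = g$start, end = g$end)
    }),
    chroms = chroms, chrom_len = chrom_len
  )
  samples <- sprintf("S%04d", seq_len(cfg$n_patients))
  per <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(sample_substream(cfg$seed, i))
    per[[i]] <- simulate_sample(
      sid = samples[[i]], cfg = cfg, geo = geo, weights = weights,
      low_vaf = (i == cfg$low_vaf_patient)
    )
  }
  pick <- function(field) {
    dplyr::bind_rows(lapply(per, `[[`, field))
  }
  truth_long <- pick("truth")
  truth <- if (nrow(truth_long) > 0) {
    truth_long |>
      dplyr::distinct() |>
      dplyr::mutate(present = TRUE) |>
      tidyr::pivot_wider(names_from = "tag", values_from = "present",
                         values_fill = FALSE) |>
      ensure_tag_columns() |>
      dplyr::mutate(evidence = paste_tags(.data$mutation, .data$sv_breakpoint,
                                          .data$cna_region)) |>
      dplyr::select("sample_id", "gene_id", "mutation", "sv_breakpoint",
                    "cna_region", "evidence") |>
      dplyr::arrange(.data$sample_id, .data$gene_id)
  } else {
    tibble::tibble(sample_id = character(), gene_id = character(),
                   mutation = logical(), sv_breakpoint = logical(),
                   cna_region = logical(), evidence = character())
  }
  cohort <- list(
    config = cfg, model = model, db = db,
    sample_sheet = tibble::as_tibble(pick("sheet")),
    mutations = tibble::as_tibble(pick("mutations")),
    svs = tibble::as_tibble(pick("svs")),
    cna = tibble::as_tibble(pick("cna")),
    mlpa = tibble::as_tibble(pick("mlpa")),
    truth = truth
  )
  if (nrow(cohort$mutations) == 0) cohort$mutations <- empty_mutations()
  if (nrow(cohort$svs) == 0) cohort$svs <- empty_svs()
  if (nrow(cohort$cna) == 0) cohort$cna <- empty_cna()
  class(cohort) <- "synthetic_cohort"
  if (!is.null(dir)) cohort$files <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$sample_sheet), " patients (",
      sum(x$sample_sheet$subtype == "IGH"), " IGH / ",
      sum(x$sample_sheet$subtype == "P2RY8"), " P2RY8), seed ",
      x$config$seed, "\n", sep = "")
  cat(nrow(x$mutations), "mutations,", nrow(x$svs), "SV candidates,",
      nrow(x$cna), "CNA segments,", nrow(x$mlpa), "MLPA calls\n")
  invisible(x)
}

simulate_sample <- function(sid, cfg, geo, weights, low_vaf) {
  subtype <- if (runif(1) < cfg$p_igh) "IGH" else "P2RY8"
  ds_status <- if (runif(1) < cfg$ds_unknown_prob) "unknown"
  else if (runif(1) < cfg$ds_prob[[subtype]]) "DS" else "nonDS"
  sheet <- data.frame(sample_id = sid, subtype = subtype,
                      ds_status = ds_status)
  truth_gene <- character(); truth_tag <- character()
  add_truth <- function(gene, tag) {
    if (length(gene) > 0) {
      truth_gene <<- c(truth_gene, gene)
      truth_tag <<- c(truth_tag, rep(tag, length(gene)))
    }
  }

  ## --- copy number + MLPA -------------------------------------------------
  cna <- NULL; mlpa <- NULL
  want_cna <- "cna" %in% cfg$modalities
  want_mlpa <- "mlpa" %in% cfg$modalities
  if (want_cna || want_mlpa) {
    panel <- cfg$deletion_probs$gene
    p_del <- cfg$deletion_probs[[subtype]]
    deleted <- runif(length(panel)) < p_del
    seg_chrom <- character(); seg_start <- integer()
    seg_end <- integer(); seg_state <- character()
    add_focal_seg <- function(g) {
      pad_l <- as.integer(floor(runif(1, 20000, 120000)))
      pad_r <- as.integer(floor(runif(1, 20000, 120000)))
      s <- max(0L, geo$start[[g]] - pad_l); e <- geo$end[[g]] + pad_r
      chr <- geo$chrom[[g]]
      seg_chrom <<- c(seg_chrom, chr); seg_start <<- c(seg_start, s)
      seg_end <<- c(seg_end, e); seg_state <<- c(seg_state, "loss")
      if (want_cna) {
        bc <- geo$by_chr[[chr]]
        add_truth(bc$gene_id[bc$start < e & s < bc$end], "cna_region")
      }
    }
    for (g in panel[deleted]) add_focal_seg(g)
    # background focal deletions on random genes
    n_bg <- rpois(1, cfg$background_focal_mean)
    for (k in seq_len(n_bg)) {
      add_focal_seg(geo$gene_id[[sample.int(length(geo$gene_id), 1)]])
    }
    # one optional large (non-focal) segment: exceeds the 1 Mb cap, so it
    # must contribute NO defective genes
    if (runif(1) < cfg$large_cna_prob) {
      chr <- sample(geo$chroms, 1)
      s <- as.integer(floor(runif(1, 0, geo$chrom_len[[chr]] - 5e6)))
      e <- s + as.integer(floor(runif(1, 1.5e6, 5e6)))
      seg_chrom <- c(seg_chrom, chr); seg_start <- c(seg_start, s)
      seg_end <- c(seg_end, e)
      seg_state <- c(seg_state, sample(c("loss", "gain"), 1))
    }
    if (want_cna && length(seg_chrom) > 0) {
      cna <- data.frame(
        sample_id = sid,
        seg_id = sprintf("%s:%s:%d-%d", sid, seg_chrom, seg_start, seg_end),
        chrom = seg_chrom, start = seg_start, end = seg_end, state = seg_state
      )
    }
    if (want_mlpa) {
      status <- ifelse(deleted, "deleted", "normal")
      status[runif(length(panel)) < cfg$mlpa_fail_prob] <- "failed"
      mlpa <- data.frame(sample_id = sid, gene_id = panel, status = status)
      add_truth(panel[status == "deleted"], "cna_region")
    }
  }

  ## --- mutations ----------------------------------------------------------
  mutations <- NULL
  if ("mutations" %in% cfg$modalities) {
    n_pt <- rpois(1, cfg$point_mut_mean)
    n_in <- rpois(1, cfg$indel_mean)
    n_mut <- n_pt + n_in
    if (n_mut > 0) {
      gidx <- sample.int(length(geo$gene_id), n_mut, replace = TRUE,
                         prob = weights)
      gid <- geo$gene_id[gidx]
      gs <- unname(geo$start[gidx]); ge <- unname(geo$end[gidx])
      pos <- gs + as.integer(floor(runif(n_mut) * (ge - gs)))
      bases <- c("A", "C", "G", "T")
      # point mutations
      cons_pt <- ifelse(
        runif(n_pt) < cfg$nonsilent_frac,
        sample(c("missense", "nonsense", "splice"), n_pt, replace = TRUE,
               prob = c(0.80, 0.12, 0.08)),
        "silent")
      ref_pt <- sample(bases, n_pt, replace = TRUE)
      alt_pt <- vapply(ref_pt, function(r) sample(setdiff(bases, r), 1), "")
      # in/dels (always protein-altering)
      cons_in <- sample(c("frameshift", "inframe_indel"), n_in,
                        replace = TRUE, prob = c(0.75, 0.25))
      is_del <- runif(n_in) < 0.5
      ref_in <- ifelse(is_del,
                       vapply(seq_len(n_in), function(j)
                         paste(sample(bases, 4, replace = TRUE), collapse = ""), ""),
                       sample(bases, n_in, replace = TRUE))
      alt_in <- ifelse(is_del, substr(ref_in, 1, 1),
                       paste0(ref_in, vapply(seq_len(n_in), function(j)
                         paste(sample(bases, 3, replace = TRUE), collapse = ""), "")))
      consequence <- c(cons_pt, cons_in)
      shape <- if (low_vaf) cfg$low_vaf_shape else cfg$vaf_shape
      vafs <- rbeta(n_mut, shape[1], shape[2])
      depth <- 30L + rpois(n_mut, 30)
      alt_d <- rbinom(n_mut, depth, vafs)
      mutations <- data.frame(
        sample_id = sid, chrom = unname(geo$chrom[gidx]), pos = pos,
        ref = c(ref_pt, ref_in), alt = c(alt_pt, alt_in),
        consequence = consequence, alt_depth = alt_d, total_depth = depth,
        depth_missing = FALSE
      )
      add_truth(gid[consequence %in% NONSILENT_CLASSES], "mutation")
    }
  }

  ## --- structural variants ------------------------------------------------
  svs <- NULL
  if ("svs" %in% cfg$modalities) {
    n_valid <- rpois(1, cfg$sv_mean)
    n_extra <- rpois(1, cfg$sv_extra_mean)
    n_sv <- n_valid + n_extra
    sv <- list(chrom_a = character(n_sv), pos_a = integer(n_sv),
               orient_a = character(n_sv), chrom_b = character(n_sv),
               pos_b = integer(n_sv), orient_b = character(n_sv),
               support = integer(n_sv), context = character(n_sv))
    put <- function(j, d, support, context) {
      sv$chrom_a[j] <<- d$chrom_a; sv$pos_a[j] <<- d$pos_a
      sv$orient_a[j] <<- d$orient_a; sv$chrom_b[j] <<- d$chrom_b
      sv$pos_b[j] <<- d$pos_b; sv$orient_b[j] <<- d$orient_b
      sv$support[j] <<- support; sv$context[j] <<- context
    }
    genic_hits <- function(d) {
      a <- geo$by_chr[[d$chrom_a]]; b <- geo$by_chr[[d$chrom_b]]
      c(a$gene_id[a$start <= d$pos_a & d$pos_a < a$end],
        b$gene_id[b$start <= d$pos_b & d$pos_b < b$end])
    }
    for (j in seq_len(n_valid)) {
      # validated: coding-span with support >= 5, breakpoint A always genic
      d <- draw_sv(geo, weights, genic_a = TRUE, genic_b_prob = 0.5)
      put(j, d, 5L + rpois(1, 5), "coding_span")
      add_truth(genic_hits(d), "sv_breakpoint")
    }
    for (j in n_valid + seq_len(n_extra)) {
      u <- runif(1)
      if (u < 0.7) {
        # plausible geometry but too few supporting read pairs
        d <- draw_sv(geo, weights, genic_a = runif(1) < 0.65,
                     genic_b_prob = 0.5)
        ctx <- if (length(genic_hits(d)) > 0) "coding_span" else "noncoding"
        put(j, d, sample(2:4, 1), ctx)
      } else if (runif(1) < 0.5) {
        # both breakpoints within one gene: excluded as same-intron
        g <- geo$gene_id[[sample.int(length(geo$gene_id), 1)]]
        p <- sort(geo$start[[g]] +
                    as.integer(floor(runif(2) * (geo$end[[g]] - geo$start[[g]]))))
        put(j, list(chrom_a = geo$chrom[[g]], pos_a = p[1], orient_a = "+",
                    chrom_b = geo$chrom[[g]], pos_b = p[2], orient_b = "-"),
            5L + rpois(1, 5), "same_intron")
      } else {
        # both breakpoints intergenic: excluded
        chr <- sample(geo$chroms, 1)
        p <- sort(c(intergenic_pos(geo$by_chr[[chr]], geo$chrom_len[[chr]]),
                    intergenic_pos(geo$by_chr[[chr]], geo$chrom_len[[chr]])))
        put(j, list(chrom_a = chr, pos_a = p[1], orient_a = "+",
                    chrom_b = chr, pos_b = p[2], orient_b = "-"),
            5L + rpois(1, 5), "noncoding")
      }
    }
    if (n_sv > 0) {
      svs <- data.frame(
        sample_id = sid, sv_id = sprintf("%s:sv%03d", sid, seq_len(n_sv)),
        chrom_a = sv$chrom_a, pos_a = sv$pos_a, orient_a = sv$orient_a,
        chrom_b = sv$chrom_b, pos_b = sv$pos_b, orient_b = sv$orient_b,
        read_pair_support = sv$support, annotation_context = sv$context
      )
    }
  }

  truth <- if (length(truth_gene) > 0) {
    data.frame(sample_id = sid, gene_id = truth_gene, tag = truth_tag)
  } else NULL
  list(sheet = sheet, mutations = mutations, svs = svs, cna = cna,
       mlpa = mlpa, truth = truth)
}

# one SV with class drawn from the validated-type tally
# (deletion 104 : tandem duplication 6 : inversion 14 : translocation 13)
draw_sv <- function(geo, weights, genic_a, genic_b_prob) {
  cls <- sample(c("deletion", "tandem_duplication", "inversion",
                  "translocation"), 1, prob = c(104, 6, 14, 13))
  draw_pos <- function(chr, genic) {
    g <- geo$by_chr[[chr]]
    if (genic) {
      i <- sample.int(length(g$gene_id), 1, prob = weights[g$gene_id])
      g$start[i] + as.integer(floor(runif(1) * (g$end[i] - g$start[i])))
    } else {
      intergenic_pos(g, geo$chrom_len[[chr]])
    }
  }
  if (cls == "translocation") {
    chr2 <- sample(geo$chroms, 2)
    pos1 <- draw_pos(chr2[1], genic_a)
    pos2 <- draw_pos(chr2[2], runif(1) < genic_b_prob)
    o <- sample(c("+", "-"), 2, replace = TRUE)
    if (chr2[1] > chr2[2]) {
      return(list(chrom_a = chr2[2], pos_a = pos2, orient_a = o[2],
                  chrom_b = chr2[1], pos_b = pos1, orient_b = o[1]))
    }
    return(list(chrom_a = chr2[1], pos_a = pos1, orient_a = o[1],
                chrom_b = chr2[2], pos_b = pos2, orient_b = o[2]))
  }
  chr <- sample(geo$chroms, 1)
  p1 <- draw_pos(chr, genic_a)
  p2 <- draw_pos(chr, runif(1) < genic_b_prob)
  while (p2 == p1) p2 <- draw_pos(chr, runif(1) < genic_b_prob)
  p <- sort(c(p1, p2))
  orient <- switch(cls,
    deletion = c("+", "-"),
    tandem_duplication = c("-", "+"),
    inversion = if (runif(1) < 0.5) c("+", "+") else c("-", "-")
  )
  list(chrom_a = chr, pos_a = p[1], orient_a = orient[1],
       chrom_b = chr, pos_b = p[2], orient_b = orient[2])
}

empty_mutations <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 consequence = character(), alt_depth = integer(),
                 total_depth = integer(), depth_missing = logical())
}
empty_svs <- function() {
  tibble::tibble(sample_id = character(), sv_id = character(),
                 chrom_a = character(), pos_a = integer(),
                 orient_a = character(), chrom_b = character(),
                 pos_b = integer(), orient_b = character(),
                 read_pair_support = integer(), annotation_context = character())
}
empty_cna <- function() {
  tibble::tibble(sample_id = character(), seg_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 state = character())
}

## ---- file emission -------------------------------------------------------

write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  files <- character()
  f <- file.path(dir, "genes.bed")
  write_gene_bed(cohort$model, f); files <- c(files, f)
  f <- file.path(dir, "pathways.gmt")
  write_gmt(cohort$db, f); files <- c(files, f)
  f <- file.path(dir, "samples.tsv")
  readr::write_tsv(cohort$sample_sheet, f, progress = FALSE)
  files <- c(files, f)
  for (sid in cohort$sample_sheet$sample_id) {
    f <- file.path(dir, "vcf", paste0(sid, ".vcf"))
    write_mutations_vcf(cohort$mutations[cohort$mutations$sample_id == sid, ],
                        f, sample_id = sid,
                        contigs = unique(cohort$model$chrom))
    files <- c(files, f)
  }
  f <- file.path(dir, "svs.bedpe")
  write_sv_bedpe(cohort$svs, f); files <- c(files, f)
  f <- file.path(dir, "cna.seg")
  write_cna_seg(cohort$cna, f); files <- c(files, f)
  f <- file.path(dir, "mlpa.tsv")
  readr::write_tsv(cohort$mlpa, f, progress = FALSE); files <- c(files, f)
  f <- file.path(dir, "truth.json")
  truth_list <- lapply(split(cohort$truth, cohort$truth$sample_id),
                       function(s) stats::setNames(as.list(s$evidence),
                                                   s$gene_id))
  jsonlite::write_json(truth_list, f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  files
}

#' Write mutation calls as a minimal annotated VCF 4.2
#'
#' One genotype column; consequence in the `CSQ` INFO tag, depths in
#' `AD`/`DP`. Positions convert from the package's 0-based convention to
#' VCF 1-based. Round-trips through [read_mutations_vcf()].
#'
#' @param mutations mutation tibble for one sample.
#' @param path output path.
#' @param sample_id genotype column name.
#' @param contigs contig names for the header.
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(mutations, path, sample_id,
                                contigs = unique(mutations$chrom)) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    sprintf("##contig=<ID=%s>", contigs),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  body <- if (nrow(mutations) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCSQ=%s\tGT:AD:DP\t0/1:%d,%d:%d",
            mutations$chrom, mutations$pos + 1L, mutations$ref, mutations$alt,
            mutations$consequence,
            mutations$total_depth - mutations$alt_depth, mutations$alt_depth,
            mutations$total_depth)
  } else character()
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write SV calls as 12-column BEDPE (round-trips with [read_sv_bedpe()])
#' @param svs SV tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_bedpe <- function(svs, path) {
  lines <- if (nrow(svs) > 0) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d\t%s",
            svs$chrom_a, svs$pos_a, svs$pos_a + 1L,
            svs$chrom_b, svs$pos_b, svs$pos_b + 1L,
            svs$sv_id, 0L, svs$orient_a, svs$orient_b,
            svs$read_pair_support, svs$annotation_context)
  } else character()
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write CNA segments as SEG (1-based inclusive; round-trips with
#' [read_cna_seg()])
#' @param cna CNA segment tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cna_seg <- function(cna, path) {
  out <- tibble::tibble(sample_id = cna$sample_id, chrom = cna$chrom,
                        start = cna$start + 1L, end = cna$end,
                        state = cna$state)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
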