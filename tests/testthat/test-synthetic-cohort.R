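test_that("identical seeds give byte-identical emitted files", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  cfg <- cohort_config(n_patients = 6, seed = 202)
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 10)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  md1 <- unname(tools::md5sum(file.path(d1, f1)))
  md2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(md1, md2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("per-sample substreams make cohorts extensible without reshuffling", {
  small <- simulate_cohort(cohort_config(n_patients = 5, seed = 99))
  big <- simulate_cohort(cohort_config(n_patients = 9, seed = 99))
  keep <- small$sample_sheet$sample_id
  expect_identical(small$sample_sheet,
                   big$sample_sheet[big$sample_sheet$sample_id %in% keep, ])
  expect_identical(
    as.data.frame(small$mutations),
    as.data.frame(big$mutations[big$mutations$sample_id %in% keep, ]))
})

test_that("deletion probability one makes every subtype sample a carrier", {
  probs <- default_deletion_probs()
  probs$IGH[probs$gene == "IKZF1"] <- 1
  probs$P2RY8[probs$gene == "IKZF1"] <- 0
  co <- simulate_cohort(cohort_config(n_patients = 40, deletion_probs = probs,
                                      mlpa_fail_prob = 0, seed = 8))
  ik <- dplyr::left_join(co$mlpa[co$mlpa$gene_id == "IKZF1", ],
                         co$sample_sheet, by = "sample_id")
  expect_true(all(ik$status[ik$subtype == "IGH"] == "deleted"))
  expect_true(all(ik$status[ik$subtype == "P2RY8"] == "normal"))
})

test_that("truth equals build_defective_sets run on the emitted files", {
  dir <- file.path(tempdir(), "simTruth")
  co <- simulate_cohort(cohort_config(n_patients = 10, seed = 55), dir = dir)
  model <- read_gene_bed(file.path(dir, "genes.bed"))
  muts <- purrr::map_dfr(list.files(file.path(dir, "vcf"), full.names = TRUE),
                         read_mutations_vcf)
  svs <- filter_sv_candidates(read_sv_bedpe(file.path(dir, "svs.bedpe")))
  cna <- read_cna_seg(file.path(dir, "cna.seg"))
  mlpa <- read_mlpa_tsv(file.path(dir, "mlpa.tsv"))
  built <- build_defective_sets(muts, svs, cna, mlpa, model)
  expect_identical(as.data.frame(built), as.data.frame(co$truth))
  unlink(dir, recursive = TRUE)
})

test_that("VAF mass sits mostly above 30% except for the outlier patient", {
  co <- simulate_cohort(cohort_config(n_patients = 11, low_vaf_patient = 3,
                                      seed = 23))
  v <- vaf(co$mutations$alt_depth, co$mutations$total_depth)
  by_sample <- tapply(v, co$mutations$sample_id, function(x) mean(x > 0.30))
  outlier <- co$sample_sheet$sample_id[[3]]
  expect_gt(mean(by_sample[setdiff(names(by_sample), outlier)]), 0.5)
  expect_lt(by_sample[[outlier]],
            min(by_sample[setdiff(names(by_sample), outlier)]))
})

test_that("large (>1 Mb) segments never contribute truth genes", {
  co <- simulate_cohort(cohort_config(n_patients = 30, large_cna_prob = 1,
                                      seed = 61))
  large <- co$cna[co$cna$end - co$cna$start > 1e6, ]
  expect_gt(nrow(large), 0)
  # genes only covered by a large segment must not appear with cna evidence
  # unless some focal lesion also hit them
  focal <- co$cna[co$cna$end - co$cna$start <= 1e6, ]
  for (i in sample.int(nrow(large), 5)) {
    seg <- large[i, ]
    covered <- genes_overlapping(co$model, seg$chrom, seg$start, seg$end)
    truth_cna <- co$truth$gene_id[co$truth$sample_id == seg$sample_id &
                                    co$truth$cna_region]
    focal_s <- focal[focal$sample_id == seg$sample_id, ]
    focal_genes <- unique(c(
      unlist(lapply(seq_len(nrow(focal_s)), function(j)
        genes_overlapping(co$model, focal_s$chrom[j], focal_s$start[j],
                          focal_s$end[j]))),
      co$mlpa$gene_id[co$mlpa$sample_id == seg$sample_id &
                        co$mlpa$status == "deleted"]))
    expect_length(setdiff(intersect(covered, truth_cna), focal_genes), 0)
  }
})

test_that("plant_enrichment multiplies and caps lesion probabilities", {
  db <- toy_pathway_db()
  cfg <- cohort_config(n_patients = 5, seed = 1)
  expect_identical(plant_enrichment(cfg, "JAK_STAT", 1, db), cfg)
  probs <- default_deletion_probs()
  probs$IGH[probs$gene == "PAX5"] <- 0.3
  cfg2 <- cohort_config(n_patients = 5, deletion_probs = probs, seed = 1)
  planted <- plant_enrichment(cfg2, "B_CELL_DIFFERENTIATION", 5, db)
  expect_equal(planted$deletion_probs$IGH[planted$deletion_probs$gene ==
                                            "PAX5"], 1)  # 0.3 * 5 capped
  untouched <- setdiff(probs$gene, db$gene_id[db$pathway_id ==
                                                "B_CELL_DIFFERENTIATION"])
  expect_equal(planted$deletion_probs$IGH[planted$deletion_probs$gene %in%
                                            untouched],
               probs$IGH[probs$gene %in% untouched])
  expect_equal(planted$enrichment_multiplier, 5)
  expect_error(plant_enrichment(cfg, "NOT_A_PATHWAY", 5, db),
               "not in the database")
})

test_that("configuration guards reject degenerate cohorts", {
  expect_error(cohort_config(n_patients = 10), "seed is mandatory")
  expect_error(simulate_cohort(cohort_config(n_patients = 1, seed = 1)),
               "n_patients")
  expect_error(cohort_config(n_patients = 10, p_igh = 1.2, seed = 1),
               "probabilities")
  expect_error(cohort_config(n_patients = 10, point_mut_mean = 0, seed = 1),
               "means must be > 0")
})

test_that("validated SV burden and candidate totals track their means", {
  co <- simulate_cohort(cohort_config(n_patients = 60, seed = 35))
  n <- 60
  validated <- filter_sv_candidates(co$svs)
  mean_valid <- nrow(validated) / n
  mean_cand <- nrow(co$svs) / n
  # Poisson(12.7) validated plus Poisson(30.3) non-qualifying candidates;
  # a few extras fail filters only probabilistically, so bands are generous
  expect_gt(mean_valid, 10.5); expect_lt(mean_valid, 15)
  expect_gt(mean_cand, 38); expect_lt(mean_cand, 48)
  # classification partitions the candidates
  cls <- classify_sv(co$svs)
  expect_equal(sum(table(cls$sv_class)), nrow(co$svs))
})
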