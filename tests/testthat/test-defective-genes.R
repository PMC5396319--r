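model <- fixture_gene_model()  # GENE1..5 on chrA, GENE6..10 on chrB

test_that("criterion 1: genes with at least one nonsilent mutation", {
  muts <- dplyr::bind_rows(
    make_mutation(pos = 120000L, consequence = "missense"),  # in GENE1
    make_mutation(pos = 2010000L, consequence = "silent"),   # in GENE2
    make_mutation(pos = 1e6, consequence = "missense")       # intergenic
  )
  expect_equal(genes_with_nonsilent_mutation(muts, model), "GENE1")
  muts2 <- dplyr::bind_rows(
    make_mutation(pos = 120000L), make_mutation(pos = 130000L),
    make_mutation(pos = 2010000L, consequence = "nonsense"))
  expect_equal(genes_with_nonsilent_mutation(muts2, model),
               c("GENE1", "GENE2"))
})

test_that("criterion 2: breakpoint-junction genes, half-open at gene edges", {
  svs <- make_sv(pos_a = 120000L, chrom_b = "chrB", pos_b = 2010000L)
  expect_equal(genes_at_sv_breakpoints(svs, model), c("GENE1", "GENE7"))
  intergenic <- make_sv(pos_a = 1e6, pos_b = 3e6)
  expect_equal(genes_at_sv_breakpoints(intergenic, model), character())
  at_start <- make_sv(pos_a = 2e6, pos_b = 3e6)   # exactly GENE2's start
  expect_equal(genes_at_sv_breakpoints(at_start, model), "GENE2")
  at_end <- make_sv(pos_a = 2050000L, pos_b = 3e6) # exactly GENE2's end
  expect_equal(genes_at_sv_breakpoints(at_end, model), character())
})

test_that("criterion 3: focal regions respect the inclusive 1 Mb cap", {
  small <- make_seg(start = 1.9e6, end = 2.2e6)         # 0.3 Mb over GENE2
  expect_equal(genes_in_small_defective_regions(small, model), "GENE2")
  large <- make_seg(start = 1.5e6, end = 4.5e6)         # 3 Mb over GENE2+3
  expect_equal(genes_in_small_defective_regions(large, model), character())
  boundary <- make_seg(start = 3.5e6, end = 4.5e6)      # exactly 1,000,000 bp
  expect_equal(boundary$end - boundary$start, 1000000L)
  expect_equal(genes_in_small_defective_regions(boundary, model), "GENE3")
  gain <- make_seg(start = 1.9e6, end = 2.2e6, state = "gain")
  expect_equal(genes_in_small_defective_regions(gain, model), "GENE2")
  expect_equal(genes_in_small_defective_regions(gain, model, states = "loss"),
               character())
})

test_that("build_defective_sets unions the criteria with evidence tags", {
  muts <- make_mutation(pos = 120000L)
  svs <- make_sv(pos_a = 120000L, pos_b = 4010000L)
  segs <- make_seg(start = 1.9e6, end = 2.2e6)
  mlpa <- tibble::tibble(sample_id = "S1", gene_id = "GENE9",
                         status = "deleted")
  sets <- build_defective_sets(muts, svs, segs, mlpa, model)
  expect_equal(sets$gene_id, c("GENE1", "GENE2", "GENE3", "GENE9"))
  g1 <- sets[sets$gene_id == "GENE1", ]
  expect_true(g1$mutation && g1$sv_breakpoint && !g1$cna_region)
  expect_equal(g1$evidence, "mutation,sv_breakpoint")
  expect_equal(sets$evidence[sets$gene_id == "GENE9"], "cna_region")
  empty <- build_defective_sets(model = model)
  expect_equal(nrow(empty), 0)
})

test_that("MLPA deleted calls enter as cna_region; other statuses do not", {
  mlpa <- tibble::tibble(sample_id = "S1",
                         gene_id = c("GENE1", "GENE2", "GENE3", "GENE4"),
                         status = c("deleted", "normal", "gained", "failed"))
  sets <- build_defective_sets(mlpa = mlpa, model = model)
  expect_equal(sets$gene_id, "GENE1")
  expect_equal(sets$evidence, "cna_region")
})

test_that("adding lesions never shrinks a defective set", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(0:6, 1); n2 <- n1 + sample(1:5, 1)
    pos <- sample.int(9e6, n2)
    cons <- sample(c("missense", "silent"), n2, replace = TRUE)
    muts2 <- purrr::map_dfr(seq_len(n2), function(i)
      make_mutation(pos = pos[i], consequence = cons[i],
                    chrom = sample(c("chrA", "chrB"), 1)))
    muts1 <- muts2[seq_len(n1), , drop = FALSE]
    s1 <- build_defective_sets(muts1, model = model)
    s2 <- build_defective_sets(muts2, model = model)
    expect_true(all(s1$gene_id %in% s2$gene_id))
  }
})

test_that("build equals the union of the criteria on 200 synthetic samples", {
  cfg <- cohort_config(n_patients = 200, seed = 77)
  co <- simulate_cohort(cfg)
  svs <- filter_sv_candidates(co$svs)
  sets <- build_defective_sets(co$mutations, svs, co$cna, co$mlpa, co$model)
  for (sid in sample(co$sample_sheet$sample_id, 40)) {
    manual <- sort(unique(c(
      genes_with_nonsilent_mutation(
        co$mutations[co$mutations$sample_id == sid, ], co$model),
      genes_at_sv_breakpoints(svs[svs$sample_id == sid, ], co$model),
      genes_in_small_defective_regions(
        co$cna[co$cna$sample_id == sid, ], co$model),
      co$mlpa$gene_id[co$mlpa$sample_id == sid &
                        co$mlpa$status == "deleted"]
    )))
    expect_identical(sets$gene_id[sets$sample_id == sid], manual)
  }
})

test_that("every tagged gene is traceable to an input lesion record", {
  cfg <- cohort_config(n_patients = 20, seed = 13)
  co <- simulate_cohort(cfg)
  svs <- filter_sv_candidates(co$svs)
  ev <- defective_evidence(co$mutations, svs, co$cna, co$mlpa, co$model)
  sets <- build_defective_sets(co$mutations, svs, co$cna, co$mlpa, co$model)
  # every (sample, gene) in the set has at least one evidence record
  key_sets <- paste(sets$sample_id, sets$gene_id)
  key_ev <- paste(ev$sample_id, ev$gene_id)
  expect_true(all(key_sets %in% key_ev))
  # each record id resolves to a real input record
  mut_ids <- sprintf("mut:%s:%d:%s>%s", co$mutations$chrom, co$mutations$pos,
                     co$mutations$ref, co$mutations$alt)
  valid <- c(mut_ids, paste0("sv:", svs$sv_id), paste0("cna:", co$cna$seg_id),
             paste0("mlpa:", co$mlpa$gene_id))
  expect_true(all(ev$record_id %in% valid))
})
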