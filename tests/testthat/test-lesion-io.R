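test_that("VCF reading converts coordinates, synonyms and depths", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tT\t.\tPASS\tCSQ=stop_gained\tGT:AD:DP\t0/1:70,30:100",
    "chr1\t250\t.\tG\tC\t.\tPASS\tCSQ=synonymous_variant\tGT:AD:DP\t0/1:40,10:50",
    "chr2\t7\t.\tT\tTGCA\t.\tPASS\tCSQ=frameshift_variant\tGT:AD:DP\t0/1:12,8:20"
  ), vcf)
  m <- read_mutations_vcf(vcf)
  expect_equal(nrow(m), 3)
  expect_equal(m$sample_id, rep("S1", 3))
  expect_equal(m$pos, c(99L, 249L, 6L))  # 1-based VCF -> 0-based
  expect_equal(m$consequence, c("nonsense", "silent", "frameshift"))
  expect_equal(m$alt_depth, c(30L, 10L, 8L))
  expect_equal(m$total_depth, c(100L, 50L, 20L))
  expect_false(any(m$depth_missing))
})

test_that("unknown consequence strings are errors listing the vocabulary", {
  expect_error(normalize_consequence("made_up_term"),
               "unknown consequence.*made_up_term.*accepted terms")
  expect_equal(normalize_consequence(c("stop_gained", "missense_variant",
                                       "splice_donor_variant")),
               c("nonsense", "missense", "splice"))
})

test_that("mutation writer round-trips through the VCF reader", {
  muts <- dplyr::bind_rows(
    make_mutation(pos = 0L, consequence = "missense"),
    make_mutation(pos = 999L, ref = "ACGT", alt = "A",
                  consequence = "frameshift", alt_depth = 5L,
                  total_depth = 9L),
    make_mutation(chrom = "chrB", pos = 12345L, consequence = "silent")
  )
  vcf <- tempfile(fileext = ".vcf")
  write_mutations_vcf(muts, vcf, sample_id = "S1",
                      contigs = c("chrA", "chrB"))
  again <- read_mutations_vcf(vcf)
  expect_identical(as.data.frame(again), as.data.frame(muts))
})

test_that("vaf is alt/total with zero depth signalled as NA", {
  expect_equal(vaf(30L, 100L), 0.30)
  expect_equal(vaf(0L, 50L), 0)
  expect_equal(vaf(7L, 20L), 0.35)
  expect_true(is.na(vaf(0L, 0L)))
  expect_error(vaf(5L, 3L), "exceed")
  expect_error(vaf(-1L, 3L), "non-negative")
  set.seed(3)
  alt <- sample.int(50, 100, replace = TRUE) - 1L
  tot <- alt + sample.int(50, 100, replace = TRUE)
  v <- vaf(alt, tot)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("nonsilent classification covers the vocabulary", {
  expect_true(all(is_nonsilent(c("missense", "nonsense", "frameshift",
                                 "inframe_indel", "splice"))))
  expect_false(any(is_nonsilent(c("silent", "noncoding"))))
  expect_error(is_nonsilent("stop_gained"), "normalize_consequence")
})

test_that("SV candidate filtering is monotone in min_support and keeps order", {
  set.seed(9)
  svs <- purrr::map_dfr(1:40, function(i) make_sv(
    sv_id = sprintf("sv%02d", i),
    read_pair_support = sample(1:12, 1),
    annotation_context = sample(c("coding_span", "same_intron", "noncoding"),
                                1, prob = c(.6, .2, .2))))
  kept_prev <- nrow(svs)
  for (ms in 1:13) {
    kept <- filter_sv_candidates(svs, min_support = ms)
    expect_true(all(kept$read_pair_support >= ms))
    expect_true(all(kept$annotation_context == "coding_span"))
    expect_lte(nrow(kept), kept_prev)
    expect_identical(kept$sv_id, svs$sv_id[svs$sv_id %in% kept$sv_id])
    kept_prev <- nrow(kept)
  }
})

test_that("SV classification follows breakpoint geometry and partitions", {
  svs <- dplyr::bind_rows(
    make_sv(orient_a = "+", orient_b = "-"),
    make_sv(orient_a = "-", orient_b = "+"),
    make_sv(orient_a = "+", orient_b = "+"),
    make_sv(orient_a = "-", orient_b = "-"),
    make_sv(chrom_b = "chrB", orient_a = "+", orient_b = "-")
  )
  cls <- classify_sv(svs)$sv_class
  expect_equal(cls, c("deletion", "tandem_duplication", "inversion",
                      "inversion", "translocation"))
  set.seed(21)
  rand <- purrr::map_dfr(1:80, function(i) make_sv(
    chrom_b = sample(c("chrA", "chrB"), 1),
    orient_a = sample(c("+", "-"), 1), orient_b = sample(c("+", "-"), 1)))
  counts <- table(classify_sv(rand)$sv_class)
  expect_equal(sum(counts), nrow(rand))
})

test_that("BEDPE reading validates and normalises breakpoint order", {
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c(
    "chrB\t500\t501\tchrA\t100\t101\tS1:sv1\t0\t+\t-\t7\tcoding_span",
    "chrA\t900\t901\tchrA\t200\t201\tS1:sv2\t0\t-\t+\t5\tsame_intron"
  ), bedpe)
  svs <- read_sv_bedpe(bedpe)
  expect_equal(svs$sample_id, c("S1", "S1"))
  # both lines arrive swapped; reader restores (chromA,posA) <= (chromB,posB)
  expect_equal(svs$chrom_a, c("chrA", "chrA"))
  expect_equal(svs$pos_a, c(100L, 200L))
  expect_equal(svs$orient_a, c("-", "+"))
  expect_equal(svs$pos_b, c(500L, 900L))

  writeLines("chrA\t1\t2\tchrA\t9\t10\tsv\t0\t+\t-\t0\tcoding_span", bedpe)
  expect_error(read_sv_bedpe(bedpe), "read_pair_support")
  writeLines("chrA\t1\t2\tchrA\t9\t10\tsv\t0\t+\t-\t5\texonic", bedpe)
  expect_error(read_sv_bedpe(bedpe), "annotation_context")
})

test_that("SEG coordinates convert from 1-based inclusive to half-open", {
  seg <- tempfile(fileext = ".seg")
  writeLines(c("sample_id\tchrom\tstart\tend\tstate",
               "S1\tchr9\t21000001\t21900000\tloss"), seg)
  cna <- read_cna_seg(seg)
  expect_equal(cna$start, 21000000L)
  expect_equal(cna$end, 21900000L)
  expect_equal(cna$end - cna$start, 900000L)

  writeLines(c("sample_id\tchrom\tstart\tend\tstate",
               "S1\tchr9\t100\t99\tloss"), seg)
  expect_error(read_cna_seg(seg), "start >= end.*line")
})

test_that("MLPA calls are one per (sample, gene)", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene_id\tstatus",
               "S1\tIKZF1\tdeleted", "S1\tPAX5\tnormal",
               "S2\tIKZF1\tfailed"), f)
  calls <- read_mlpa_tsv(f)
  expect_equal(nrow(calls), 3)
  writeLines(c("sample_id\tgene_id\tstatus",
               "S1\tIKZF1\tdeleted", "S1\tIKZF1\tnormal"), f)
  expect_error(read_mlpa_tsv(f), "duplicate MLPA call.*S1/IKZF1")
})
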