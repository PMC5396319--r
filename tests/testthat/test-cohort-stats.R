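test_that("fisher_two_sided agrees with enumeration and the library route", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  set.seed(41)
  for (rep in 1:60) {
    t <- as.integer(sample.int(15, 4, replace = TRUE))
    mine <- fisher_two_sided(t[1], t[2], t[3], t[4])
    expect_equal(mine, enum_fisher_two_sided(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    expect_equal(mine,
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_two_sided(0, 0, 0, 0), "margin")
})

test_that("fisher_two_sided is invariant under row and column swaps", {
  set.seed(43)
  for (rep in 1:40) {
    t <- as.integer(sample.int(20, 4, replace = TRUE))
    p <- fisher_two_sided(t[1], t[2], t[3], t[4])
    expect_equal(fisher_two_sided(t[3], t[4], t[1], t[2]), p,
                 tolerance = 1e-12)
    expect_equal(fisher_two_sided(t[2], t[1], t[4], t[3]), p,
                 tolerance = 1e-12)
  }
})

test_that("the directional one-sided tail never exceeds the two-sided p", {
  # the one-sided p in the direction of the observed deviation (the smaller
  # of the two tails), from the same fixed-margin enumeration
  one_sided <- function(a, b, c, d) {
    row1 <- a + b; col1 <- a + c; total <- a + b + c + d
    support <- max(0, col1 - (total - row1)):min(row1, col1)
    pmf <- choose(row1, support) * choose(total - row1, col1 - support) /
      choose(total, col1)
    min(sum(pmf[support >= a]), sum(pmf[support <= a]))
  }
  set.seed(47)
  for (rep in 1:40) {
    t <- as.integer(sample.int(12, 4, replace = TRUE))
    expect_lte(one_sided(t[1], t[2], t[3], t[4]),
               fisher_two_sided(t[1], t[2], t[3], t[4]) + 1e-12)
  }
})

test_that("subgroup comparison rebuilds printed-style tables", {
  # cohort constructed to carry IKZF1 deletions in 25/35 IGH vs 36/108 P2RY8
  sheet <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:143),
    subtype = rep(c("IGH", "P2RY8"), times = c(35, 108)),
    ds_status = "nonDS")
  carriers <- c(sprintf("S%03d", 1:25), sprintf("S%03d", 36 + (1:36)))
  defective <- tibble::tibble(sample_id = carriers, gene_id = "IKZF1",
                              mutation = FALSE, sv_breakpoint = FALSE,
                              cna_region = TRUE, evidence = "cna_region")
  cohort <- lesion_indicator_table(sheet, defective, "IKZF1")
  cmp <- compare_lesion_frequencies(cohort, "IKZF1", group_by = "subtype",
                                    groups = c("IGH", "P2RY8"))
  res <- tidy(cmp)
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(25L, 10L, 36L, 72L))
  expect_equal(res$freq_a_pct, 71L)
  expect_equal(res$freq_b_pct, 33L)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_display, "< .001")
})

test_that("unknown-status samples leave the denominators", {
  sheet <- tibble::tibble(sample_id = c("A", "B", "C", "D", "E"),
                          subtype = "IGH",
                          ds_status = c("DS", "DS", "nonDS", "unknown",
                                        "nonDS"))
  defective <- tibble::tibble(sample_id = c("A", "D"), gene_id = "PAX5",
                              mutation = TRUE, sv_breakpoint = FALSE,
                              cna_region = FALSE, evidence = "mutation")
  cohort <- lesion_indicator_table(sheet, defective, "PAX5")
  cmp <- compare_lesion_frequencies(cohort, "PAX5", group_by = "ds_status",
                                    groups = c("DS", "nonDS"))
  expect_equal(cmp$n_a + cmp$n_b, 4L)
  expect_equal(cmp$n_excluded, 1L)
  # absent lesion: 0% vs 0%, p = 1
  cohort$ABSENT <- FALSE
  res <- tidy(compare_lesion_frequencies(cohort, "ABSENT",
                                         group_by = "ds_status",
                                         groups = c("DS", "nonDS")))
  expect_equal(res$freq_a, 0)
  expect_equal(res$p_value, 1)
})

test_that("FISH cutoff is mean plus three sample standard deviations", {
  expect_equal(determine_fish_cutoff(rep(0, 5)), 0)
  expect_equal(determine_fish_cutoff(c(1, 2, 3, 2, 2)), 2 + 3 * sqrt(0.5),
               tolerance = 1e-12)
  expect_error(determine_fish_cutoff(3), ">= 2 control")
  cutoff <- determine_fish_cutoff(c(1, 2, 3, 2, 2))
  # strictly above the cutoff, and only with enough nuclei
  expect_false(fish_positive(cutoff, cutoff, 200))
  expect_true(fish_positive(cutoff + 0.01, cutoff, 200))
  expect_false(fish_positive(cutoff + 5, cutoff, 80))
})

test_that("burden summary reports modality means, ranges and VAF fractions", {
  set.seed(53)
  counts <- c(12, 25, 31)
  muts <- purrr::map_dfr(1:3, function(i) {
    purrr::map_dfr(seq_len(counts[i]), function(j)
      make_mutation(sample_id = paste0("S", i), pos = j * 1000L,
                    alt_depth = 35L, total_depth = 100L))
  })
  muts$alt_depth[1] <- 10L   # one VAF 0.10
  muts$ref[2] <- "ACGT"      # one indel
  b <- summarize_burden(muts)
  tot <- tidy(b)[tidy(b)$modality == "mutations_total", ]
  expect_equal(tot$mean, mean(counts))
  expect_equal(tot$min, 12)
  expect_equal(tot$max, 31)
  expect_equal(tidy(b)$mean[tidy(b)$modality == "indels"], 1 / 3)
  g <- glance(b)
  expect_equal(g$n_evaluable, sum(counts))
  expect_equal(g$frac_vaf_gt_30, (sum(counts) - 1) / sum(counts))
  expect_equal(g$frac_vaf_lt_20, 1 / sum(counts))
  single <- summarize_burden(make_mutation())
  expect_equal(tidy(single)$mean[1], 1)
})

test_that("p-value display follows the journal convention", {
  expect_equal(format_p(c(0.0042, 0.0004, 0.049, 1)),
               c(".004", "< .001", ".049", "1.000"))
})
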