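# Shared fixtures and independent oracles. Oracles here deliberately use
# naive scans / direct binomial-coefficient arithmetic, never the package's
# own code paths.

# naive O(n) interval-overlap scan (half-open on both sides)
naive_overlap <- function(model, chrom, start, end) {
  hit <- model$chrom == chrom & model$start < end & start < model$end
  sort(unique(model$gene_id[hit]))
}

# upper-tail hypergeometric by direct choose() arithmetic (no logs)
enum_hyper_tail <- function(x, K, n, N) {
  hi <- min(K, n)
  lo <- max(0, n - (N - K))
  if (x > hi) return(0)
  i <- max(x, lo):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# two-sided Fisher p by full fixed-margin enumeration with choose() products
enum_fisher_two_sided <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; total <- a + b + c + d
  support <- max(0, col1 - (total - row1)):min(row1, col1)
  pmf <- choose(row1, support) * choose(total - row1, col1 - support) /
    choose(total, col1)
  p_obs <- pmf[support == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# small deterministic gene model: 10 genes on two chromosomes
fixture_gene_model <- function() {
  gene_model(tibble::tibble(
    gene_id = paste0("GENE", 1:10),
    chrom = rep(c("chrA", "chrB"), each = 5),
    start = rep(c(1e5, 2e6, 4e6, 6e6, 8e6), 2),
    end = rep(c(1e5, 2e6, 4e6, 6e6, 8e6), 2) + 5e4
  ))
}

fixture_pathway_db <- function(background_n = 100) {
  pathway_db(tibble::tibble(
    pathway_id = rep(c("PW1", "PW2", "PW3"), times = c(3, 4, 3)),
    name = rep(c("pw one", "pw two", "pw three"), times = c(3, 4, 3)),
    gene_id = c("GENE1", "GENE2", "GENE3",
                "GENE3", "GENE4", "GENE5", "GENE6",
                "GENE8", "GENE9", "GENE10")
  ), background_n = background_n)
}

make_mutation <- function(sample_id = "S1", chrom = "chrA", pos = 120000L,
                          ref = "A", alt = "T", consequence = "missense",
                          alt_depth = 20L, total_depth = 50L) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, consequence = consequence,
                 alt_depth = as.integer(alt_depth),
                 total_depth = as.integer(total_depth),
                 depth_missing = FALSE)
}

make_sv <- function(sample_id = "S1", sv_id = "sv1", chrom_a = "chrA",
                    pos_a = 120000L, orient_a = "+", chrom_b = "chrA",
                    pos_b = 2010000L, orient_b = "-",
                    read_pair_support = 8L,
                    annotation_context = "coding_span") {
  tibble::tibble(sample_id = sample_id, sv_id = sv_id, chrom_a = chrom_a,
                 pos_a = as.integer(pos_a), orient_a = orient_a,
                 chrom_b = chrom_b, pos_b = as.integer(pos_b),
                 orient_b = orient_b,
                 read_pair_support = as.integer(read_pair_support),
                 annotation_context = annotation_context)
}

make_seg <- function(sample_id = "S1", chrom = "chrA", start = 1.9e6,
                     end = 2.2e6, state = "loss") {
  start <- as.integer(start); end <- as.integer(end)
  tibble::tibble(sample_id = sample_id,
                 seg_id = sprintf("%s:%s:%d-%d", sample_id, chrom, start, end),
                 chrom = chrom, start = start, end = end, state = state)
}
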