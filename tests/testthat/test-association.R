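one_gene <- function(strand = "+") {
  data.frame(id = "gA", chrom = "chr1", start = 10000L, end = 15000L,
             strand = strand, stringsAsFactors = FALSE)
}
one_element <- function(start, end, id = "e1") {
  data.frame(id = id, chrom = "chr1", start = as.integer(start),
             end = as.integer(end), status = "intact",
             stringsAsFactors = FALSE)
}

test_that("insertions are classified genic / upstream / downstream", {
  rec <- classify_insertions(one_element(11000, 11500), one_gene("+"))
  expect_equal(as.character(rec$category), "genic")
  expect_equal(rec$distance_bp, 0L)

  rec <- classify_insertions(one_element(8000, 8500), one_gene("+"))
  expect_equal(as.character(rec$category), "upstream5")
  expect_equal(rec$distance_bp, 1500L)
  expect_equal(rec$anchor_gene_id, "gA")

  # strand reflection: the same position is downstream of a minus-strand gene
  rec <- classify_insertions(one_element(8000, 8500), one_gene("-"))
  expect_equal(as.character(rec$category), "downstream3")
  expect_equal(rec$distance_bp, 1500L)

  rec <- classify_insertions(one_element(100, 600), one_gene("+"))
  expect_equal(as.character(rec$category), "unassociated")
  expect_true(is.na(rec$distance_bp))
})

test_that("category priority beats distance ties", {
  # element equidistant (2 kb) upstream of gA (+) and downstream of gB (+)
  genes <- data.frame(id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000L, 2000L), end = c(15000L, 5500L),
                      strand = "+", stringsAsFactors = FALSE)
  el <- one_element(7500, 8000)
  rec <- classify_insertions(el, genes)
  expect_equal(as.character(rec$category), "upstream5")
  expect_equal(rec$anchor_gene_id, "gA")
  expect_equal(rec$distance_bp, 2000L)
  # within one category the nearer gene wins; id breaks exact ties
  oracle <- oracle_classify(el, genes)
  expect_equal(as.character(rec$category), as.character(oracle$category))
})

test_that("classification matches the brute-force scan on random genomes", {
  set.seed(17)
  for (i in 1:50) {
    g <- random_small_genome(sample(5:25, 1), sample(10:40, 1))
    got <- classify_insertions(g$elements, g$genes)
    want <- oracle_classify(g$elements, g$genes)
    expect_identical(got, want)
    # categories partition the element set
    expect_equal(sum(table(got$category)), nrow(g$elements))
  }
})

test_that("flank fraction counts nearest distances in (0, 1 kb]", {
  genes <- one_gene()
  # all genic -> 0
  els <- do.call(rbind, lapply(1:3, function(i)
    one_element(11000 + i, 12000 + i, sprintf("e%d", i))))
  expect_equal(flank_fraction(classify_insertions(els, genes)), 0)

  # 2 of 10 in the flank (500 and 900), rest genic or far
  starts <- c(9000, 8600, 11000, 11100, 11200, 2000, 2100, 2200, 2300, 2400)
  ends <- starts + c(500, 500, 500, 500, 500, 300, 300, 300, 300, 300)
  els <- do.call(rbind, lapply(1:10, function(i)
    one_element(starts[i], ends[i], sprintf("e%02d", i))))
  rec <- classify_insertions(els, genes)
  expect_equal(flank_fraction(rec), 0.2)
  expect_equal(flank_fraction(els, genes), 0.2)  # raw-input route agrees
  expect_error(flank_fraction(els[0, ], genes), "empty")
})

test_that("enrichment test rejects clearly biased placements", {
  spec <- simulation_spec(genome_length = 2e6, n_genes = 100,
                          n_intact_ltr = 200, n_solo_ltr = 0,
                          flank_insertion_bias = 1,
                          ltr_repeat_length_range = c(100, 200),
                          ltr_internal_length_range = c(100, 300),
                          seed = 19)
  sim <- simulate_genome(spec, generate_sequences = FALSE)
  res <- flank_enrichment_test(sim$elements, sim$genes, spec$genome_length,
                               permutations = 999, seed = 7)
  expect_equal(res$p_value, 1 / 1000)  # minimal achievable p
  expect_equal(res$n_permutations, 999L)
  expect_equal(length(res$null_fractions), 999L)
  expect_error(flank_enrichment_test(sim$elements, sim$genes,
                                     spec$genome_length, permutations = 10),
               ">= 99")
})

test_that("composition summary partitions counts and fractions", {
  els <- data.frame(id = sprintf("e%d", 1:5), chrom = "chr1",
                    start = seq(1000, 5000, 1000),
                    end = seq(1400, 5400, 1000),
                    status = c(rep("intact", 3), rep("solo", 2)),
                    stringsAsFactors = FALSE)
  cs <- composition_summary(els)
  expect_equal(cs$status$fraction[cs$status$status == "intact"], 0.6)
  expect_equal(sum(cs$status$fraction), 1)

  empty <- composition_summary(els[0, ])
  expect_true(all(empty$status$count == 0))
  expect_true(all(empty$status$fraction == 0))
})

test_that("planted flank fraction is visible in the truth table", {
  spec <- simulation_spec(genome_length = 4e6, n_genes = 150,
                          n_intact_ltr = 300, n_solo_ltr = 0,
                          flank_insertion_bias = 0.4,
                          ltr_repeat_length_range = c(100, 200),
                          ltr_internal_length_range = c(100, 300),
                          seed = 23)
  sim <- simulate_genome(spec, generate_sequences = FALSE)
  planted <- mean(sim$truth$planted_flank[sim$truth$status == "intact"])
  expect_lt(abs(planted - 0.4), 3 * sqrt(0.4 * 0.6 / 300))
  # classified flank fraction is at least the planted one (uniform
  # placements can also land in flanks)
  rec <- classify_insertions(sim$elements, sim$genes)
  expect_gte(flank_fraction(rec) + 1e-9, planted)
})
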