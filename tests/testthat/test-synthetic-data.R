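test_that("age zero gives identical terminal repeats", {
  spec <- simulation_spec(n_intact_ltr = 10, n_solo_ltr = 0,
                          age_distribution = list(weights = 1, means = 0,
                                                  sds = 1e-12),
                          ltr_repeat_length_range = c(200, 400),
                          ltr_internal_length_range = c(100, 200),
                          seed = 4)
  sim <- simulate_genome(spec)
  expect_true(all(sim$elements$ltr5_seq == sim$elements$ltr3_seq))
  est <- date_ltr_elements(sim$elements, molecular_clock(spec$mu))
  expect_true(all(est$d == 0))
})

test_that("repeat-pair divergence matches the JC69 expectation", {
  # one long element: mu = 6e-9, T = 10 My -> K = 0.12, E[d] ~ 0.1109
  spec <- simulation_spec(genome_length = 1e6, n_genes = 10,
                          n_intact_ltr = 1, n_solo_ltr = 0,
                          ltr_repeat_length_range = c(10000, 10000),
                          ltr_internal_length_range = c(100, 100),
                          age_distribution = list(weights = 1, means = 10,
                                                  sds = 1e-9),
                          mu = 6.0e-9, seed = 31)
  sim <- simulate_genome(spec)
  d_obs <- pair_divergence(sim$elements$ltr5_seq[1], sim$elements$ltr3_seq[1])
  d_exp <- jc69_expected_divergence(0.12)
  expect_equal(d_exp, 0.1109, tolerance = 1e-3)
  tol <- 3 * sqrt(d_exp * (1 - d_exp) / 10000)
  expect_lt(abs(d_obs - d_exp), tol)
})

test_that("full flank bias puts every element midpoint within 1 kb of a gene", {
  spec <- simulation_spec(genome_length = 2e6, n_genes = 100,
                          n_intact_ltr = 80, n_solo_ltr = 0,
                          flank_insertion_bias = 1,
                          ltr_repeat_length_range = c(100, 200),
                          ltr_internal_length_range = c(100, 300),
                          seed = 12)
  sim <- simulate_genome(spec, generate_sequences = FALSE)
  mids <- (sim$elements$start + sim$elements$end) / 2
  bound_dist <- vapply(mids, function(m)
    min(abs(m - c(sim$genes$start, sim$genes$end))), numeric(1))
  expect_true(all(bound_dist <= 1000))
  # and classification puts them in the close flank
  rec <- classify_insertions(sim$elements, sim$genes)
  expect_true(all(rec$nearest_distance_bp >= 1 &
                  rec$nearest_distance_bp <= 1000))
})

test_that("identical spec and seed give identical output", {
  spec <- simulation_spec(n_intact_ltr = 15, n_solo_ltr = 5, seed = 77,
                          ks_targets = c(0.1, 0.3))
  s1 <- simulate_genome(spec); s2 <- simulate_genome(spec)
  expect_identical(s1, s2)
  c1 <- simulate_cds_pairs(spec); c2 <- simulate_cds_pairs(spec)
  expect_identical(c1, c2)
  p1 <- simulate_paralog_pairs(spec)
  expect_identical(p1, simulate_paralog_pairs(spec))
  expect_identical(simulate_expression(spec, p1),
                   simulate_expression(spec, p1))
})

test_that("genes never overlap and placement failures are informative", {
  spec <- simulation_spec(genome_length = 5e5, n_genes = 120, seed = 3)
  sim <- simulate_genome(spec, generate_sequences = FALSE)
  g <- sim$genes[order(sim$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  expect_error(simulation_spec(genome_length = 1e4, n_genes = 100),
               "genome_length")
})

test_that("planted CDS divergence is recovered by NG86", {
  spec <- simulation_spec(ks_targets = c(0, 0.3), cds_codons = 200, seed = 8)
  cp <- simulate_cds_pairs(spec)
  res <- ng86_pairs(cp$seqs)
  expect_equal(res$Ks[res$pair_id == "pair0001"], 0)  # target 0 -> identical
  expect_lt(abs(res$Ks[res$pair_id == "pair0002"] - 0.3), 0.05)
  expect_error(simulate_cds_pairs(
    simulation_spec(ks_targets = 6, seed = 8)), "correction domain")
})

test_that("expression generator plants divergence only when asked", {
  spec0 <- simulation_spec(n_paralog_pairs = 20, expression_noise_sd = 0,
                           expression_effect_size = 0, seed = 5)
  pp <- simulate_paralog_pairs(spec0)
  em <- simulate_expression(spec0, pp)
  dv <- paralog_divergence(pp, em)
  expect_true(all(dv$expr_distance == 0))
  expect_true(all(em >= 0))

  # planted effect separates the group medians
  hits <- vapply(1:20, function(r) {
    sp <- simulation_spec(n_paralog_pairs = 60, expression_effect_size = 2,
                          seed = 100 + r)
    p <- simulate_paralog_pairs(sp)
    d <- paralog_divergence(p, simulate_expression(sp, p))
    median(d$expr_distance[d$ltr_adjacent]) >
      median(d$expr_distance[!d$ltr_adjacent])
  }, logical(1))
  expect_true(all(hits))
  expect_error(simulate_expression(
    simulation_spec(n_paralog_pairs = 2, seed = 1), data.frame()), "gene_a")
})

test_that("simulation outputs round trip through the writers", {
  spec <- simulation_spec(n_intact_ltr = 8, n_solo_ltr = 4, seed = 13,
                          n_paralog_pairs = 6,
                          ltr_repeat_length_range = c(100, 200),
                          ltr_internal_length_range = c(100, 200))
  sim <- simulate_genome(spec)
  pp <- simulate_paralog_pairs(spec)
  em <- simulate_expression(spec, pp)
  dir <- tempfile()
  write_simulation(sim, dir, pairs = pp, expression = em, seed = spec$seed)
  genes <- read_gene_models(file.path(dir, "genes.gff3"), "gff3")
  expect_equal(genes[order(genes$id), ]$start,
               sim$genes[order(sim$genes$id), ]$start)
  els <- read_ltr_elements(file.path(dir, "elements.tsv"),
                           file.path(dir, "ltr_repeats.fasta"))
  expect_equal(els$id, sim$elements$id)
  expect_equal(els$ltr5_seq, sim$elements$ltr5_seq)
  expect_equal(read_expression(file.path(dir, "expression.tsv")), em,
               tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$counts$genes, nrow(sim$genes))
})
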