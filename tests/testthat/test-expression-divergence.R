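test_that("recent-pair selection is strictly below the Ks threshold", {
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      ks = c(0.1, 0.5, 0.49))
  kept <- select_recent_pairs(pairs, 0.5)
  expect_equal(kept$pair_id, c("p1", "p3"))
  expect_equal(nrow(select_recent_pairs(pairs[0, ], 0.5)), 0L)
  expect_equal(nrow(select_recent_pairs(pairs, 0)), 0L)
  pairs$ks[2] <- NA
  expect_error(select_recent_pairs(pairs, 0.5), "missing ks")
})

test_that("log transform applies log2(x + pseudocount)", {
  expect_equal(log_transform(matrix(0), 1), matrix(0))
  expect_equal(log_transform(matrix(7), 1), matrix(3))
  expect_error(log_transform(matrix(-1), 1), "negative")
  expect_error(log_transform(matrix(0), 0), "pseudocount 0")
  expect_equal(log_transform(matrix(8), 0), matrix(3))
})

test_that("expression distance is Euclidean on profiles", {
  expect_equal(expression_distance(rep(1, 5), rep(1, 5)), 0)
  expect_equal(expression_distance(c(0, 0, 0, 0, 0), c(3, 4, 0, 0, 0)), 5)
  expect_error(expression_distance(1:4, 1:5), "length")
  set.seed(33)
  for (i in 1:20) {
    a <- runif(5); b <- runif(5); c <- runif(5)
    expect_equal(expression_distance(a, b), expression_distance(b, a))
    expect_lte(expression_distance(a, c),
               expression_distance(a, b) + expression_distance(b, c) + 1e-12)
  }
})

test_that("tau spans uniform to single-tissue expression", {
  expect_equal(tau_index(c(1, 1, 1, 1, 1)), 0)
  expect_equal(tau_index(c(5, 0, 0, 0, 0)), 1)
  expect_equal(tau_index(c(4, 2, 2, 2, 2)), 0.5)
  expect_error(tau_index(3), ">= 2")
  expect_error(tau_index(c(-1, 2)), "non-negative")
  expect_warning(t0 <- tau_index(c(0, 0, 0)), "undefined")
  expect_true(is.na(t0))
  # scale invariance
  set.seed(14)
  for (i in 1:10) {
    x <- runif(5, 0, 10)
    expect_equal(tau_index(3.7 * x), tau_index(x), tolerance = 1e-12)
  }
})

test_that("group comparison is an exact rank-sum test for small groups", {
  rec <- data.frame(expr_distance = c(1, 2, 3, 4, 5, 6),
                    ltr_adjacent = rep(c(TRUE, FALSE), each = 3))
  r <- compare_groups(rec)
  expect_equal(r$p_value, 0.1)  # 2/20 rank arrangements as extreme

  same <- data.frame(expr_distance = rep(c(1, 2, 3), 2),
                     ltr_adjacent = rep(c(TRUE, FALSE), each = 3))
  expect_equal(compare_groups(same)$p_value, 1)

  expect_error(compare_groups(
    data.frame(expr_distance = 1:3, ltr_adjacent = TRUE)), "non-empty")
})

test_that("adjacency flags follow strand-aware upstream windows", {
  genes <- data.frame(id = c("gP", "gM"), chrom = "chr1",
                      start = c(10000L, 30000L), end = c(12000L, 32000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  # e1 400 bp before gP (upstream of +); e2 400 bp after gM (upstream of -)
  els <- data.frame(id = c("e1", "e2"), chrom = "chr1",
                    start = c(9300L, 32400L), end = c(9600L, 32700L),
                    status = "intact", stringsAsFactors = FALSE)
  up <- gene_ltr_adjacency(genes, els, mode = "upstream")
  expect_true(up[["gP"]] && up[["gM"]])
  # downstream-only neighbours do not flag in upstream mode
  down <- data.frame(id = "e3", chrom = "chr1", start = 12400L, end = 12600L,
                     status = "intact", stringsAsFactors = FALSE)
  expect_false(gene_ltr_adjacency(genes, down, mode = "upstream")[["gP"]])
  expect_true(gene_ltr_adjacency(genes, down, mode = "any_flank")[["gP"]])
})

test_that("divergence records carry both tau conventions", {
  pairs <- data.frame(pair_id = "p1", gene_a = "a", gene_b = "b",
                      ltr_adjacent = TRUE, stringsAsFactors = FALSE)
  em <- rbind(a = c(3, 0, 0, 0, 0), b = c(3, 3, 3, 3, 3))
  colnames(em) <- c("leaf", "bract", "stem", "fruit", "root")
  dv <- paralog_divergence(pairs, em, pseudocount = 1)
  expect_equal(dv$expr_distance, 4)
  expect_equal(dv$tau_a, 1)
  expect_equal(dv$tau_b, 0)
  expect_equal(dv$tau_divergence, 1)
  expect_equal(dv$tau_diff, 1)
  expect_error(paralog_divergence(
    data.frame(gene_a = "zz", gene_b = "b"), em), "absent")
})
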