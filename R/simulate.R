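# Synthetic genomes with planted ground truth.
#
# Terminal repeats diverge from a shared ancestral repeat by a direct JC69
# sampler: each copy receives independent per-site substitutions with
# probability p = (3/4)(1 - exp(-4 mu T / 3)) (the JC69 transition
# probability for branch length mu*T), targets uniform over the three
# alternative bases. Because the JC69 transition matrices compose, the
# expected pair divergence is the JC69 value at K = 2 mu T, the distance the
# dating module corrects for.

#' Simulation specification
#'
#' Defaults follow the regime the dating analysis targets: a single
#' insertion burst at 1.5 +/- 0.5 Mya, a neutral rate of 6.0e-9
#' substitutions/site/year, and five tissues (leaf, bract, stem, fruit,
#' root) for expression profiles with log-normal base abundances.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_genes Number of non-overlapping gene models.
#' @param gene_length_range Min/max gene length (bp).
#' @param n_intact_ltr,n_solo_ltr Element counts.
#' @param ltr_repeat_length_range Min/max terminal-repeat length (bp);
#'   default 300-2000.
#' @param ltr_internal_length_range Min/max internal-region length (bp).
#' @param age_distribution Insertion-age mixture in Mya: a list with
#'   `weights`, `means`, `sds` (equal lengths, weights summing to 1) and
#'   optional truncation bounds `min` (default 0) and `max` (default Inf).
#' @param mu Neutral substitution rate per site per year.
#' @param flank_insertion_bias Fraction of intact insertions forced into the
#'   <1 kb gene flanks (0 = uniform over the non-genic space).
#' @param n_paralog_pairs Number of paralog pairs for expression simulation.
#' @param paralog_ks_range Ks range for paralog pairs (uniform draw).
#' @param ltr_adjacent_fraction Fraction of paralog pairs flagged
#'   LTR-adjacent.
#' @param cds_codons Codons per simulated CDS.
#' @param ks_targets Planted synonymous divergences for CDS pairs.
#' @param tissues Tissue labels (expression column order).
#' @param expression_base_meanlog,expression_base_sdlog Log-normal
#'   parameters of the shared per-tissue base abundance (RPKM scale).
#' @param expression_noise_sd Per-gene log2-scale noise sd.
#' @param expression_effect_size Extra log2-scale divergence sd added to
#'   flagged pairs (standard deviations; >= 0).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `simulation_spec` (validated list).
#' @export
simulation_spec <- function(genome_length = 1e6,
                            n_genes = 100L,
                            gene_length_range = c(1000L, 3000L),
                            n_intact_ltr = 100L,
                            n_solo_ltr = 50L,
                            ltr_repeat_length_range = c(300L, 2000L),
                            ltr_internal_length_range = c(500L, 3000L),
                            age_distribution = list(weights = 1,
                                                    means = 1.5,
                                                    sds = 0.5,
                                                    min = 0, max = Inf),
                            mu = 6.0e-9,
                            flank_insertion_bias = 0,
                            n_paralog_pairs = 50L,
                            paralog_ks_range = c(0.01, 0.49),
                            ltr_adjacent_fraction = 0.5,
                            cds_codons = 200L,
                            ks_targets = NULL,
                            tissues = c("leaf", "bract", "stem", "fruit",
                                        "root"),
                            expression_base_meanlog = 3,
                            expression_base_sdlog = 1,
                            expression_noise_sd = 0.5,
                            expression_effect_size = 0,
                            seed = 1L) {
  ad <- age_distribution
  if (is.null(ad$min)) ad$min <- 0
  if (is.null(ad$max)) ad$max <- Inf
  stopifnot(length(ad$weights) == length(ad$means),
            length(ad$means) == length(ad$sds))
  if (abs(sum(ad$weights) - 1) > 1e-8)
    stop("age mixture weights must sum to 1")
  if (any(ad$sds <= 0)) stop("age mixture sds must be > 0")
  if (n_genes < 0 || n_intact_ltr < 0 || n_solo_ltr < 0 ||
      n_paralog_pairs < 0)
    stop("counts must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  if (flank_insertion_bias < 0 || flank_insertion_bias > 1)
    stop("flank_insertion_bias must be in [0, 1]")
  if (expression_effect_size < 0)
    stop("expression_effect_size must be >= 0")
  if (diff(gene_length_range) < 0 || diff(ltr_repeat_length_range) < 0 ||
      diff(ltr_internal_length_range) < 0)
    stop("length ranges must be increasing")
  if (n_genes * gene_length_range[2] >= genome_length)
    stop("genome_length too small to place ", n_genes,
         " non-overlapping genes; increase genome_length")
  structure(list(genome_length = genome_length,
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 n_intact_ltr = as.integer(n_intact_ltr),
                 n_solo_ltr = as.integer(n_solo_ltr),
                 ltr_repeat_length_range = as.integer(ltr_repeat_length_range),
                 ltr_internal_length_range =
                   as.integer(ltr_internal_length_range),
                 age_distribution = ad,
                 mu = mu,
                 flank_insertion_bias = flank_insertion_bias,
                 n_paralog_pairs = as.integer(n_paralog_pairs),
                 paralog_ks_range = paralog_ks_range,
                 ltr_adjacent_fraction = ltr_adjacent_fraction,
                 cds_codons = as.integer(cds_codons),
                 ks_targets = ks_targets,
                 tissues = tissues,
                 expression_base_meanlog = expression_base_meanlog,
                 expression_base_sdlog = expression_base_sdlog,
                 expression_noise_sd = expression_noise_sd,
                 expression_effect_size = expression_effect_size,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# truncated Gaussian-mixture draw (rejection sampling)
.draw_ages <- function(n, ad) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    m <- n - length(out)
    comp <- sample.int(length(ad$weights), m, replace = TRUE,
                       prob = ad$weights)
    x <- rnorm(m, ad$means[comp], ad$sds[comp])
    out <- c(out, x[x >= ad$min & x <= ad$max & x >= 0])
    guard <- guard + 1L
    if (guard > 1000L)
      stop("age mixture rejection sampling failed; check truncation bounds")
  }
  out[seq_len(n)]
}

.random_dna_int <- function(n) sample.int(4L, n, replace = TRUE)

.int_to_dna <- function(x) {
  paste(c("A", "C", "G", "T")[x], collapse = "")
}

# one JC69 jump: substitute each site with probability p, new base uniform
# over the three alternatives (integer-coded trick: add 1..3 mod 4)
.jc69_mutate <- function(seq_int, p) {
  hit <- which(runif(length(seq_int)) < p)
  if (length(hit))
    seq_int[hit] <- ((seq_int[hit] - 1L +
                      sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  seq_int
}

# place n_genes non-overlapping genes by distributing the free space
# uniformly (stick-breaking), so placement never needs rejection retries
.place_genes <- function(spec) {
  n <- spec$n_genes
  if (n == 0L)
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  lens <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], n,
                 replace = TRUE)
  free <- spec$genome_length - sum(lens)
  if (free <= n)
    stop("genome_length too small for the drawn gene lengths; ",
         "increase genome_length")
  cuts <- sort(runif(n, 0, free))
  gaps <- floor(c(cuts[1], diff(cuts)))
  starts <- cumsum(gaps) + c(0, cumsum(lens[-n]))
  data.frame(id = sprintf("g%05d", seq_len(n)),
             chrom = "chr1",
             start = as.integer(starts),
             end = as.integer(starts + lens),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# uniform placement of an interval of length L on the non-genic space;
# returns the start, or NA if it does not fit anywhere
.place_uniform_nongenic <- function(gaps, L) {
  valid <- pmax(0, (gaps$end - gaps$start) - L + 1)
  total <- sum(valid)
  if (total <= 0) return(NA_integer_)
  u <- runif(1, 0, total)
  gi <- findInterval(u, cumsum(valid)) + 1L
  as.integer(gaps$start[gi] + floor(u - c(0, cumsum(valid))[gi]))
}

# placement with the element's nearest edge 1..flank bp from a gene
# boundary, element fully inside the non-genic gap; for elements short
# enough the edge gap is capped so the midpoint also stays within flank
.place_in_flank <- function(gaps, genes, L, flank = 1000L,
                            max_tries = 200L) {
  gap_max <- max(1L, as.integer(flank - ceiling(L / 2)))
  for (try in seq_len(max_tries)) {
    gi <- sample.int(nrow(genes), 1L)
    side <- sample(c("left", "right"), 1L)
    gap_bp <- sample.int(gap_max, 1L)
    s <- if (side == "left") genes$start[gi] - gap_bp - L
         else genes$end[gi] + gap_bp
    if (is.na(s) || s < 0) next
    e <- s + L
    # must lie entirely in non-genic space
    inside <- any(gaps$start <= s & e <= gaps$end)
    if (inside) return(as.integer(s))
  }
  NA_integer_
}

#' Simulate a genome with gene models and LTR elements of known age
#'
#' Genes are placed without overlap on one linear chromosome. Each intact
#' element carries a planted insertion age; its two terminal repeats are
#' derived from one random ancestral repeat by independent JC69 substitution
#' sampling with per-copy branch length `mu * age`, so the pair's expected
#' corrected distance is `K = 2 mu age`. Elements are placed on the
#' non-genic space, a configurable fraction of them forced into the <1 kb
#' gene flanks; solo elements carry coordinates only.
#'
#' @param spec A [simulation_spec()].
#' @param generate_sequences If `FALSE`, terminal-repeat sequences are not
#'   synthesized (elements carry only coordinates and planted ages); useful
#'   for placement-only studies.
#' @return A list with `genes` (gene-model data frame), `elements` (element
#'   data frame as in [read_ltr_elements()]) and `truth` (data frame
#'   `id`, `status`, `age_mya`, `planted_flank`).
#' @export
simulate_genome <- function(spec, generate_sequences = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  genes <- .place_genes(spec)
  gaps <- .nongenic_gaps(genes, spec$genome_length)

  n_int <- spec$n_intact_ltr
  n_solo <- spec$n_solo_ltr
  ages <- .draw_ages(n_int, spec$age_distribution)
  rep_lens <- if (n_int)
    sample(spec$ltr_repeat_length_range[1]:spec$ltr_repeat_length_range[2],
           n_int, replace = TRUE) else integer(0)
  int_lens <- if (n_int)
    sample(spec$ltr_internal_length_range[1]:spec$ltr_internal_length_range[2],
           n_int, replace = TRUE) else integer(0)
  el_lens <- 2L * rep_lens + int_lens
  forced <- if (n_int)
    runif(n_int) < spec$flank_insertion_bias else logical(0)

  starts <- integer(n_int)
  for (i in seq_len(n_int)) {
    s <- if (forced[i] && nrow(genes) > 0)
      .place_in_flank(gaps, genes, el_lens[i])
    else NA_integer_
    if (is.na(s)) {
      if (forced[i] && nrow(genes) > 0)
        forced[i] <- FALSE  # fall back to uniform if no flank slot fits
      s <- .place_uniform_nongenic(gaps, el_lens[i])
    }
    if (is.na(s))
      stop("cannot place an element of length ", el_lens[i],
           " in the non-genic space; increase genome_length")
    starts[i] <- s
  }

  ltr5 <- ltr3 <- rep(NA_character_, n_int)
  if (generate_sequences && n_int > 0) {
    for (i in seq_len(n_int)) {
      anc <- .random_dna_int(rep_lens[i])
      p <- jc69_expected_divergence(spec$mu * ages[i] * 1e6)
      ltr5[i] <- .int_to_dna(.jc69_mutate(anc, p))
      ltr3[i] <- .int_to_dna(.jc69_mutate(anc, p))
    }
  }

  solo_lens <- if (n_solo)
    sample(spec$ltr_repeat_length_range[1]:spec$ltr_repeat_length_range[2],
           n_solo, replace = TRUE) else integer(0)
  solo_starts <- vapply(solo_lens, function(L) {
    s <- .place_uniform_nongenic(gaps, L)
    if (is.na(s)) stop("cannot place a solo LTR; increase genome_length")
    s
  }, integer(1))

  elements <- data.frame(
    id = c(sprintf("ltr%05d", seq_len(n_int)),
           if (n_solo) sprintf("solo%05d", seq_len(n_solo)) else character(0)),
    chrom = "chr1",
    start = c(starts, solo_starts),
    end = c(starts + el_lens, solo_starts + solo_lens),
    status = c(rep("intact", n_int), rep("solo", n_solo)),
    ltr5_seq = c(ltr5, rep(NA_character_, n_solo)),
    ltr3_seq = c(ltr3, rep(NA_character_, n_solo)),
    d = NA_real_,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    id = elements$id,
    status = elements$status,
    age_mya = c(ages, rep(NA_real_, n_solo)),
    planted_flank = c(forced, rep(NA, n_solo)),
    stringsAsFactors = FALSE)

  list(genes = genes, elements = elements, truth = truth)
}

.sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

# synonymous single-nucleotide neighbors of a codon (excluding stops)
.syn_neighbors <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nb <- unlist(lapply(1:3, .codon_neighbors, codon = codon))
  nb[code[nb] == code[[codon]] & code[nb] != "*"]
}

#' Simulate CDS pairs with planted synonymous divergence
#'
#' For each target Ks, a random stop-free CDS is generated and a partner is
#' derived by planting single-nucleotide synonymous substitutions at
#' distinct codons. The planted count is `round(ps * S)` with
#' `ps = (3/4)(1 - exp(-4 Ks / 3))` (the uncorrected equivalent of the
#' target) and `S` the NG86 synonymous site count, so the NG86 estimate of
#' the pair recovers the target up to estimator noise.
#'
#' @param spec A [simulation_spec()] with non-empty `ks_targets`.
#' @param saturation_max Targets at or above this Ks are rejected as beyond
#'   the correction domain (default 5, the saturation filter bound).
#' @return A list with `seqs` (named character vector, `<pair>_a`/`_b`) and
#'   `truth` (data frame `pair_id`, `ks_target`, `n_planted`).
#' @export
simulate_cds_pairs <- function(spec, saturation_max = 5.0) {
  stopifnot(inherits(spec, "simulation_spec"))
  targets <- spec$ks_targets
  if (is.null(targets) || length(targets) == 0L)
    stop("spec$ks_targets must be provided")
  if (any(targets < 0)) stop("ks_targets must be >= 0")
  if (any(targets >= saturation_max))
    stop("ks target >= ", saturation_max,
         " is beyond the Jukes-Cantor correction domain for this generator")
  set.seed(spec$seed + 1L)
  sense <- .sense_codons()
  seqs <- character(0)
  rows <- vector("list", length(targets))
  for (j in seq_along(targets)) {
    ks <- targets[j]
    a_codons <- sample(sense, spec$cds_codons, replace = TRUE)
    a <- paste(a_codons, collapse = "")
    S <- sum(vapply(a_codons, .syn_sites, numeric(1)))
    ps <- jc69_expected_divergence(ks)
    m <- round(ps * S)
    eligible <- which(vapply(a_codons,
                             function(cd) length(.syn_neighbors(cd)) > 0,
                             logical(1)))
    if (m > length(eligible))
      stop("target Ks = ", ks, " needs ", m,
           " synonymous changes but only ", length(eligible),
           " codons admit one; increase cds_codons")
    b_codons <- a_codons
    if (m > 0) {
      pick <- sample(eligible, m)
      for (i in pick) {
        nb <- .syn_neighbors(a_codons[i])
        b_codons[i] <- if (length(nb) == 1L) nb else sample(nb, 1L)
      }
    }
    b <- paste(b_codons, collapse = "")
    pid <- sprintf("pair%04d", j)
    seqs[paste0(pid, "_a")] <- a
    seqs[paste0(pid, "_b")] <- b
    rows[[j]] <- data.frame(pair_id = pid, ks_target = ks, n_planted = m,
                            stringsAsFactors = FALSE)
  }
  list(seqs = seqs, truth = do.call(rbind, rows))
}

#' Simulate paralog pairs with adjacency flags
#'
#' Generates `n_paralog_pairs` gene pairs with Ks drawn uniformly from
#' `paralog_ks_range` and exactly
#' `round(ltr_adjacent_fraction * n_paralog_pairs)` pairs flagged as
#' LTR-adjacent (positions shuffled).
#'
#' @param spec A [simulation_spec()].
#' @return A data frame `pair_id`, `gene_a`, `gene_b`, `ks`, `ltr_adjacent`.
#' @export
simulate_paralog_pairs <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 2L)
  n <- spec$n_paralog_pairs
  if (n == 0L)
    return(data.frame(pair_id = character(0), gene_a = character(0),
                      gene_b = character(0), ks = numeric(0),
                      ltr_adjacent = logical(0)))
  n_adj <- round(spec$ltr_adjacent_fraction * n)
  flags <- sample(c(rep(TRUE, n_adj), rep(FALSE, n - n_adj)))
  data.frame(pair_id = sprintf("pp%04d", seq_len(n)),
             gene_a = sprintf("pp%04d_a", seq_len(n)),
             gene_b = sprintf("pp%04d_b", seq_len(n)),
             ks = runif(n, spec$paralog_ks_range[1], spec$paralog_ks_range[2]),
             ltr_adjacent = flags,
             stringsAsFactors = FALSE)
}

#' Simulate paralog-pair expression profiles
#'
#' Each pair shares a per-tissue base abundance drawn log-normal
#' (RPKM scale); each gene's log2 profile is the base plus independent
#' Gaussian noise (`expression_noise_sd`), and genes of LTR-adjacent pairs
#' receive additional divergence noise with sd `expression_effect_size`.
#'
#' @param spec A [simulation_spec()].
#' @param pairs Pair data frame with `gene_a`, `gene_b`, `ltr_adjacent`
#'   (e.g. from [simulate_paralog_pairs()]).
#' @return An RPKM matrix (2 * n pairs rows, `spec$tissues` columns).
#' @export
simulate_expression <- function(spec, pairs) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!all(c("gene_a", "gene_b", "ltr_adjacent") %in% names(pairs)))
    stop("pairs must carry gene_a, gene_b and ltr_adjacent")
  if (spec$expression_effect_size < 0) stop("negative effect size")
  set.seed(spec$seed + 3L)
  nt <- length(spec$tissues)
  n <- nrow(pairs)
  m <- matrix(0, nrow = 2L * n, ncol = nt,
              dimnames = list(rep("", 2L * n), spec$tissues))
  for (i in seq_len(n)) {
    base <- log2(rlnorm(nt, spec$expression_base_meanlog,
                        spec$expression_base_sdlog))
    la <- base + rnorm(nt, 0, spec$expression_noise_sd)
    lb <- base + rnorm(nt, 0, spec$expression_noise_sd)
    if (isTRUE(pairs$ltr_adjacent[i]) && spec$expression_effect_size > 0)
      lb <- lb + rnorm(nt, 0, spec$expression_effect_size)
    m[2L * i - 1L, ] <- 2^la
    m[2L * i, ] <- 2^lb
    rownames(m)[2L * i - 1L] <- pairs$gene_a[i]
    rownames(m)[2L * i] <- pairs$gene_b[i]
  }
  m
}

#' Write all simulation outputs to a directory
#'
#' Emits `genes.gff3`, `elements.tsv` + `ltr_repeats.fasta`,
#' `truth_elements.tsv`, and (when pairs/expression are supplied)
#' `paralog_pairs.tsv` and `expression.tsv`, plus a JSON run manifest.
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param pairs,expression Optional paralog table / RPKM matrix.
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, pairs = NULL, expression = NULL,
                             seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(sim$genes, file.path(dir, "genes.gff3"), "gff3")
  write_ltr_elements(sim$elements, file.path(dir, "elements.tsv"),
                     file.path(dir, "ltr_repeats.fasta"))
  write.table(sim$truth, file.path(dir, "truth_elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- list(genes = nrow(sim$genes), elements = nrow(sim$elements))
  if (!is.null(pairs)) {
    write.table(pairs, file.path(dir, "paralog_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts$paralog_pairs <- nrow(pairs)
  }
  if (!is.null(expression)) {
    write_expression(expression, file.path(dir, "expression.tsv"))
    counts$expression_genes <- nrow(expression)
  }
  write_run_manifest(file.path(dir, "manifest.json"), "simulate",
                     counts = counts, seed = seed)
  invisible(dir)
}
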