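# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package: sites
# are counted by explicit base enumeration and codon-difference paths by
# recursive enumeration of substitution orders.

oracle_translate <- function(codons) {
  unname(as.character(Biostrings::GENETIC_CODE[codons]))
}

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      maa <- oracle_translate(mut)
      if (maa == aa && maa != "*") s <- s + 1 / 3
    }
  }
  s
}

# all substitution paths from c1 to c2; each path is a character vector of
# codon states c1, ..., c2
oracle_paths <- function(c1, c2) {
  if (c1 == c2) return(list(c1))
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  out <- list()
  for (p in diffs) {
    nxt <- c1
    substr(nxt, p, p) <- substr(c2, p, p)
    for (tail in oracle_paths(nxt, c2)) out <- c(out, list(c(c1, tail)))
  }
  out
}

oracle_path_counts <- function(path) {
  aa <- oracle_translate(path)
  sd <- nd <- 0
  for (i in seq_len(length(path) - 1)) {
    if (aa[i] == aa[i + 1] && aa[i + 1] != "*") sd <- sd + 1 else nd <- nd + 1
  }
  c(sd, nd)
}

oracle_codon_diff <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  paths <- oracle_paths(c1, c2)
  no_stop <- Filter(function(p) {
    inner <- p[-c(1, length(p))]
    length(inner) == 0 || all(oracle_translate(inner) != "*")
  }, paths)
  use <- if (length(no_stop)) no_stop else paths
  counts <- lapply(use, oracle_path_counts)
  Reduce(`+`, counts) / length(counts)
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(sapply(ca, oracle_syn_sites)) +
        sum(sapply(cb, oracle_syn_sites))) / 2
  N <- nchar(a) - S
  d <- Reduce(`+`, lapply(seq_along(ca),
                          function(i) oracle_codon_diff(ca[i], cb[i])))
  ps <- d[1] / S
  pn <- d[2] / N
  list(S = S, N = N, Sd = d[1], Nd = d[2], ps = ps, pn = pn,
       Ks = if (ps < 0.75) -0.75 * log(1 - 4 * ps / 3) else NA_real_,
       Ka = if (pn < 0.75) -0.75 * log(1 - 4 * pn / 3) else NA_real_)
}

# brute-force gene-proximity classification: explicit per-gene candidate
# enumeration with a manual best-candidate scan
oracle_classify <- function(elements, genes, window = 5000,
                            strand_aware = TRUE) {
  n <- nrow(elements)
  category <- character(n); anchor <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  nearest <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- list()
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != elements$chrom[i]) next
      es <- elements$start[i]; ee <- elements$end[i]
      gs <- genes$start[j]; ge <- genes$end[j]
      if (es < ge && gs < ee) {
        if (is.na(nearest[i]) || 0 < nearest[i]) nearest[i] <- 0L
        cand[[length(cand) + 1]] <- list(prio = 1, dist = 0,
                                         id = genes$id[j])
      } else {
        if (ee <= gs) { d <- gs - ee; left <- TRUE }
        else { d <- es - ge; left <- FALSE }
        if (is.na(nearest[i]) || d < nearest[i]) nearest[i] <- as.integer(d)
        if (d > window) next
        up <- if (strand_aware) {
          (left && genes$strand[j] == "+") || (!left && genes$strand[j] == "-")
        } else left
        cand[[length(cand) + 1]] <- list(prio = if (up) 2 else 3,
                                         dist = d, id = genes$id[j])
      }
    }
    if (length(cand) == 0) { category[i] <- "unassociated"; next }
    best <- cand[[1]]
    for (k in seq_along(cand)[-1]) {
      ck <- cand[[k]]
      if (ck$prio < best$prio ||
          (ck$prio == best$prio && ck$dist < best$dist) ||
          (ck$prio == best$prio && ck$dist == best$dist && ck$id < best$id))
        best <- ck
    }
    category[i] <- c("genic", "upstream5", "downstream3")[best$prio]
    anchor[i] <- best$id
    distance[i] <- as.integer(best$dist)
  }
  data.frame(element_id = elements$id,
             category = factor(category,
                               levels = c("genic", "upstream5",
                                          "downstream3", "unassociated")),
             anchor_gene_id = anchor, distance_bp = distance,
             nearest_distance_bp = nearest,
             stringsAsFactors = FALSE)
}

# random stop-free CDS pairs for oracle comparisons
random_cds_pair <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  list(a = paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
       b = paste(sample(sense, n_codons, replace = TRUE), collapse = ""))
}

# small random genome (genes may overlap; elements anywhere) for the
# classification equivalence sweep
random_small_genome <- function(n_genes, n_elements, genome_length = 1e5) {
  gs <- sample.int(genome_length - 5000L, n_genes, replace = TRUE)
  gl <- sample(200:3000, n_genes, replace = TRUE)
  es <- sample.int(genome_length - 5000L, n_elements, replace = TRUE)
  el <- sample(100:2000, n_elements, replace = TRUE)
  list(
    genes = data.frame(id = sprintf("g%03d", seq_len(n_genes)),
                       chrom = "chr1", start = gs, end = gs + gl,
                       strand = sample(c("+", "-"), n_genes, replace = TRUE),
                       stringsAsFactors = FALSE),
    elements = data.frame(id = sprintf("e%03d", seq_len(n_elements)),
                          chrom = "chr1", start = es, end = es + el,
                          status = "intact", stringsAsFactors = FALSE))
}
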