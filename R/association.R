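# Relating LTR insertions to gene models.
#
# Category rule: an element overlapping any gene body by >= 1 bp is genic
# (distance 0). Otherwise the gap from the element's nearest edge to each
# gene boundary is measured; a gene qualifies if the gap is within the
# association window. Upstream/downstream is strand-aware: an element on
# the 5' side of a gene (before the start of a + gene, after the end of a
# - gene) is upstream. Among qualifying relationships the category is
# chosen with priority genic > 5'-upstream > 3'-downstream; within a
# category the nearest gene wins, ties broken by lexicographic gene id.

.assoc_levels <- c("genic", "upstream5", "downstream3", "unassociated")

# per-element relationships against all genes on the same chromosome;
# returns (category index 1..3, distance, gene id) for the winning gene or
# NULL if none qualifies
.classify_one <- function(el_start, el_end, g, window, strand_aware = TRUE) {
  overlap <- g$start < el_end & el_start < g$end
  left_of_gene <- el_end <= g$start     # element entirely before the gene
  dist <- ifelse(overlap, 0L,
                 ifelse(left_of_gene, g$start - el_end, el_start - g$end))
  if (strand_aware) {
    upstream <- (left_of_gene & g$strand == "+") |
                (!left_of_gene & g$strand == "-")
  } else {
    upstream <- left_of_gene
  }
  cat_idx <- ifelse(overlap, 1L, ifelse(upstream, 2L, 3L))
  qualify <- overlap | dist <= window
  if (!any(qualify)) return(NULL)
  cat_idx <- cat_idx[qualify]
  dist <- dist[qualify]
  ids <- g$id[qualify]
  ord <- order(cat_idx, dist, ids)[1]
  list(cat = cat_idx[ord], dist = dist[ord], gene = ids[ord])
}

#' Classify LTR insertions by proximity to genes
#'
#' @param elements Element data frame (`id`, `chrom`, `start`, `end`, ...).
#' @param genes Gene-model data frame (see [read_gene_models()]).
#' @param association_window Window in bp (default 5000).
#' @param strand_aware If `FALSE`, "upstream" simply means left of the gene
#'   on the forward strand.
#' @return A data frame with `element_id`, `category` (one of `genic`,
#'   `upstream5`, `downstream3`, `unassociated`), `anchor_gene_id` (NA when
#'   unassociated), `distance_bp` (distance to the anchor gene; 0 for genic,
#'   NA when unassociated) and `nearest_distance_bp` (strand-agnostic
#'   distance to the nearest gene regardless of category or window; NA when
#'   the chromosome has no genes).
#' @export
classify_insertions <- function(elements, genes, association_window = 5000L,
                                strand_aware = TRUE) {
  if (!is.numeric(association_window) || association_window <= 0)
    stop("association_window must be positive")
  if (any(!genes$strand %in% .valid_strands))
    stop("unknown strand symbol in gene models")
  genes_by_chrom <- split(genes, genes$chrom)
  n <- nrow(elements)
  category <- rep("unassociated", n)
  anchor <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    g <- genes_by_chrom[[elements$chrom[i]]]
    if (is.null(g) || nrow(g) == 0L) next
    hit <- .classify_one(elements$start[i], elements$end[i], g,
                         association_window, strand_aware)
    if (is.null(hit)) next
    category[i] <- .assoc_levels[hit$cat]
    anchor[i] <- hit$gene
    distance[i] <- as.integer(hit$dist)
  }
  nearest <- .nearest_gene_distance(elements, genes)
  data.frame(element_id = elements$id,
             category = factor(category, levels = .assoc_levels),
             anchor_gene_id = anchor,
             distance_bp = distance,
             nearest_distance_bp = ifelse(is.finite(nearest),
                                          as.integer(nearest), NA_integer_),
             stringsAsFactors = FALSE)
}

# distance from each element to its nearest gene on the same chromosome
# (0 when overlapping a gene body; Inf when the chromosome has no genes)
.nearest_gene_distance <- function(elements, genes) {
  genes_by_chrom <- split(genes, genes$chrom)
  vapply(seq_len(nrow(elements)), function(i) {
    g <- genes_by_chrom[[elements$chrom[i]]]
    if (is.null(g) || nrow(g) == 0L) return(Inf)
    overlap <- g$start < elements$end[i] & elements$start[i] < g$end
    if (any(overlap)) return(0)
    min(ifelse(elements$end[i] <= g$start,
               g$start - elements$end[i],
               elements$start[i] - g$end))
  }, numeric(1))
}

#' Fraction of elements in the close gene flanks
#'
#' The fraction of all elements whose nearest-gene distance falls in
#' `(0, flank_window]`, strand-agnostically over both flank sides. Genic
#' elements (distance 0) count in the denominator only.
#'
#' @param x Either the record data frame returned by [classify_insertions()]
#'   (needs `category` and `distance_bp`; requires
#'   `flank_window <= association_window` used there) or an element data
#'   frame, in which case `genes` must be supplied.
#' @param genes Gene models (only when `x` is an element set).
#' @param flank_window Flank width in bp (default 1000).
#' @return The flank fraction (a proportion).
#' @export
flank_fraction <- function(x, genes = NULL, flank_window = 1000L) {
  if (nrow(x) == 0L) stop("empty element set")
  if ("nearest_distance_bp" %in% names(x)) {
    d <- x$nearest_distance_bp
    in_flank <- !is.na(d) & d >= 1 & d <= flank_window
  } else {
    if (is.null(genes)) stop("supply gene models when x is an element set")
    d <- .nearest_gene_distance(x, genes)
    in_flank <- is.finite(d) & d >= 1 & d <= flank_window
  }
  mean(in_flank)
}

# valid-start bookkeeping for placing an interval of length L uniformly on
# the non-genic portion of one chromosome
.nongenic_gaps <- function(genes, chrom_length) {
  if (nrow(genes) == 0L)
    return(data.frame(start = 0, end = chrom_length,
                      left_gene_end = -Inf, right_gene_start = Inf))
  g <- genes[order(genes$start), , drop = FALSE]
  # merge overlapping gene bodies
  merged_start <- g$start[1]; merged_end <- g$end[1]
  starts <- c(); ends <- c()
  for (i in seq_len(nrow(g))[-1]) {
    if (g$start[i] <= merged_end) {
      merged_end <- max(merged_end, g$end[i])
    } else {
      starts <- c(starts, merged_start); ends <- c(ends, merged_end)
      merged_start <- g$start[i]; merged_end <- g$end[i]
    }
  }
  starts <- c(starts, merged_start); ends <- c(ends, merged_end)
  gap_start <- c(0, ends)
  gap_end <- c(starts, chrom_length)
  keep <- gap_end > gap_start
  data.frame(start = gap_start[keep], end = gap_end[keep],
             left_gene_end = c(-Inf, ends)[keep],
             right_gene_start = c(starts, Inf)[keep])
}

#' Permutation test for enrichment of LTR insertions in gene flanks
#'
#' The observed statistic is the fraction of elements whose nearest-gene
#' distance is in `(0, flank_window]`. The null re-places every element
#' uniformly at random on the non-genic portion of its chromosome,
#' preserving element lengths; the one-sided p-value is
#' `(1 + #\{null >= observed\}) / (1 + permutations)`.
#'
#' @param elements Element data frame.
#' @param genes Gene-model data frame.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp); a
#'   single unnamed value is accepted for single-chromosome input.
#' @param flank_window Flank width in bp (default 1000).
#' @param permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return An object of class `enrichment_result`: `observed_flank_fraction`,
#'   `null_fractions`, `p_value`, `n_permutations`.
#' @export
flank_enrichment_test <- function(elements, genes, chrom_lengths,
                                  flank_window = 1000L, permutations = 999L,
                                  seed = 1L) {
  if (permutations < 99L) stop("permutations must be >= 99")
  if (nrow(elements) == 0L) stop("empty element set")
  chroms <- unique(elements$chrom)
  if (is.null(names(chrom_lengths))) {
    if (length(chrom_lengths) != 1L || length(chroms) != 1L)
      stop("chrom_lengths must be named for multi-chromosome input")
    names(chrom_lengths) <- chroms
  }
  if (!all(chroms %in% names(chrom_lengths)))
    stop("missing chromosome lengths for: ",
         paste(setdiff(chroms, names(chrom_lengths)), collapse = ", "))
  set.seed(seed)

  observed <- flank_fraction(elements, genes, flank_window)
  B <- as.integer(permutations)
  E <- nrow(elements)
  # per-permutation count of flank placements, accumulated across chromosomes
  flank_counts <- numeric(B)

  for (ch in chroms) {
    gaps <- .nongenic_gaps(genes[genes$chrom == ch, , drop = FALSE],
                           chrom_lengths[[ch]])
    lens <- elements$end[elements$chrom == ch] -
            elements$start[elements$chrom == ch]
    gap_len <- gaps$end - gaps$start
    for (L in unique(lens)) {
      nrep <- sum(lens == L) * B
      valid <- pmax(0, gap_len - L + 1)
      total <- sum(valid)
      if (total <= 0)
        stop("non-genic space cannot hold an element of length ", L,
             " on ", ch)
      cum <- cumsum(valid)
      u <- runif(nrep, 0, total)
      gi <- findInterval(u, cum) + 1L  # gap index per placement
      offset <- u - c(0, cum)[gi]      # uniform within the gap's valid span
      s <- gaps$start[gi] + floor(offset)
      dist_left <- s - gaps$left_gene_end[gi]
      dist_right <- gaps$right_gene_start[gi] - (s + L)
      d <- pmin(dist_left, dist_right)
      in_flank <- is.finite(d) & d >= 1 & d <= flank_window
      # placements are grouped as nrep = n_elements_of_len_L x B draws
      flank_counts <- flank_counts +
        colSums(matrix(in_flank, ncol = B))
    }
  }
  null_fractions <- flank_counts / E
  p <- (1 + sum(null_fractions >= observed)) / (1 + B)
  structure(list(observed_flank_fraction = observed,
                 null_fractions = null_fractions,
                 p_value = p,
                 n_permutations = B),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Flank enrichment: observed %.4f vs null mean %.4f (%d permutations)\n",
    x$observed_flank_fraction, mean(x$null_fractions), x$n_permutations))
  cat(sprintf("  one-sided p = %.4g\n", x$p_value))
  invisible(x)
}

#' Composition summary of an element set
#'
#' Counts and fractions of intact vs solo elements, and (when
#' classification records are supplied) of each association category among
#' intact elements.
#'
#' @param elements Element data frame.
#' @param records Optional records from [classify_insertions()].
#' @return A list with data frames `status` and (if `records` given)
#'   `category`; fractions in each table sum to 1 (all-zero for empty input).
#' @export
composition_summary <- function(elements, records = NULL) {
  status_levels <- c("intact", "solo")
  n <- nrow(elements)
  counts <- vapply(status_levels, function(s) sum(elements$status == s),
                   integer(1))
  status <- data.frame(status = status_levels, count = counts,
                       fraction = if (n > 0) counts / n else rep(0, 2))
  out <- list(status = status)
  if (!is.null(records)) {
    rec <- records[match(elements$id[elements$status == "intact"],
                         records$element_id), , drop = FALSE]
    cc <- vapply(.assoc_levels,
                 function(l) sum(rec$category == l, na.rm = TRUE), integer(1))
    out$category <- data.frame(
      category = .assoc_levels, count = cc,
      fraction = if (sum(cc) > 0) cc / sum(cc) else rep(0, length(cc)))
  }
  out
}
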