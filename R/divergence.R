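# Expression and tissue-specificity divergence of recent paralog pairs.

#' Select recent duplicate pairs
#'
#' Keeps pairs with `ks < recent_ks_max` (strict inequality).
#'
#' @param pairs Data frame with at least a `ks` column.
#' @param recent_ks_max Threshold (default 0.5).
#' @return The subset of `pairs`.
#' @export
select_recent_pairs <- function(pairs, recent_ks_max = 0.5) {
  if (!"ks" %in% names(pairs)) stop("pairs must carry a ks column")
  if (anyNA(pairs$ks)) stop("missing ks for some pairs")
  pairs[pairs$ks < recent_ks_max, , drop = FALSE]
}

#' Log2-transform an expression matrix
#'
#' `x -> log2(x + pseudocount)`, elementwise. A zero pseudocount is allowed
#' only when the matrix has no zero entries.
#'
#' @param mat Non-negative numeric matrix (RPKM).
#' @param pseudocount Pseudocount (default 1).
#' @return The transformed matrix.
#' @export
#' @examples
#' log_transform(matrix(7), 1)  # 3
log_transform <- function(mat, pseudocount = 1.0) {
  if (any(mat < 0)) stop("negative expression values")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(mat == 0))
    stop("pseudocount 0 with zero entries would give -Inf")
  log2(mat + pseudocount)
}

#' Euclidean distance between two expression profiles
#'
#' @param profile_a,profile_b Equal-length numeric vectors (log2 scale).
#' @return `sqrt(sum((a - b)^2))`.
#' @export
#' @examples
#' expression_distance(c(0, 0, 0, 0, 0), c(3, 4, 0, 0, 0))  # 5
expression_distance <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    stop("profiles differ in length")
  sqrt(sum((profile_a - profile_b)^2))
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)` over `n >= 2` tissues: 0 for
#' uniform expression, 1 for expression confined to a single tissue. The
#' profile must be non-negative (use [log_transform()] with pseudocount
#' >= 1 when starting from RPKM). An all-zero profile has no defined tau and
#' returns `NA` with a warning.
#'
#' @param profile Non-negative numeric vector, length >= 2.
#' @return tau in `[0, 1]`, or `NA` for an all-zero profile.
#' @export
#' @examples
#' tau_index(c(4, 2, 2, 2, 2))  # 0.5
tau_index <- function(profile) {
  if (length(profile) < 2L) stop("tau needs >= 2 tissues")
  if (any(profile < 0)) stop("tau is defined for non-negative profiles")
  mx <- max(profile)
  if (mx == 0) {
    warning("all-zero expression profile: tau undefined")
    return(NA_real_)
  }
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Flag genes with an adjacent LTR insertion
#'
#' A gene is LTR-adjacent when at least one element lies within
#' `flank_window` of it on the relevant side: mode `"upstream"` (default)
#' requires the element in the 1-kb 5'-upstream flank, mirroring the
#' comparison of pairs with vs without an insertion within 1 kb upstream;
#' mode `"any_flank"` accepts either flank.
#'
#' @param genes Gene-model data frame.
#' @param elements Element data frame.
#' @param flank_window Window in bp (default 1000).
#' @param mode `"upstream"` or `"any_flank"`.
#' @return Named logical vector over `genes$id`.
#' @export
gene_ltr_adjacency <- function(genes, elements, flank_window = 1000L,
                               mode = c("upstream", "any_flank")) {
  mode <- match.arg(mode)
  flags <- setNames(rep(FALSE, nrow(genes)), genes$id)
  els_by_chrom <- split(elements, elements$chrom)
  for (i in seq_len(nrow(genes))) {
    e <- els_by_chrom[[genes$chrom[i]]]
    if (is.null(e) || nrow(e) == 0L) next
    left_gap <- genes$start[i] - e$end     # element before the gene
    right_gap <- e$start - genes$end[i]    # element after the gene
    in_left <- left_gap >= 1 & left_gap <= flank_window
    in_right <- right_gap >= 1 & right_gap <= flank_window
    hit <- if (mode == "any_flank") {
      in_left | in_right
    } else if (genes$strand[i] == "+") in_left else in_right
    flags[i] <- any(hit)
  }
  flags
}

#' Divergence records for paralog pairs
#'
#' For each pair, computes the Euclidean distance between the two genes'
#' log2 expression profiles, each gene's tau, and the tau divergence
#' (absolute difference; the signed difference `tau_diff` is also kept).
#' tau is computed on the same log2-transformed profiles used for the
#' distance; set `tau_on_log = FALSE` for raw-scale tau.
#'
#' @param pairs Data frame with `pair_id`, `gene_a`, `gene_b` and
#'   (optionally) `ks`, `ltr_adjacent`; the latter columns are carried
#'   through.
#' @param expression RPKM matrix (genes x tissues).
#' @param pseudocount Pseudocount for [log_transform()] (default 1).
#' @param tau_on_log Compute tau on log2 profiles (default) or raw RPKM.
#' @return A data frame with `pair_id`, `expr_distance`, `tau_a`, `tau_b`,
#'   `tau_divergence`, `tau_diff`, plus carried-through columns.
#' @export
paralog_divergence <- function(pairs, expression, pseudocount = 1.0,
                               tau_on_log = TRUE) {
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(pairs)))
    stop("pairs must have gene_a and gene_b columns")
  missing_genes <- setdiff(c(pairs$gene_a, pairs$gene_b),
                           rownames(expression))
  if (length(missing_genes))
    stop("genes absent from the expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  lm_ <- log_transform(expression, pseudocount)
  tau_src <- if (tau_on_log) lm_ else expression
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- lm_[pairs$gene_a[i], ]
    b <- lm_[pairs$gene_b[i], ]
    ta <- tau_index(tau_src[pairs$gene_a[i], ])
    tb <- tau_index(tau_src[pairs$gene_b[i], ])
    data.frame(expr_distance = expression_distance(a, b),
               tau_a = ta, tau_b = tb,
               tau_divergence = abs(ta - tb),
               tau_diff = ta - tb)
  })
  out <- cbind(pairs, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Compare LTR-adjacent vs non-adjacent pairs
#'
#' Two-sided Wilcoxon rank-sum test on a divergence metric between the two
#' groups: exact when the smaller group has <= 20 observations (and no ties
#' force the approximation), otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param records Data frame from [paralog_divergence()] carrying a logical
#'   `ltr_adjacent` column.
#' @param metric Column to compare (default `"expr_distance"`; use
#'   `"tau_divergence"` for tissue specificity).
#' @return An object of class `group_comparison`: `statistic` (W),
#'   `p_value`, `median_adjacent`, `median_nonadjacent`, group sizes,
#'   `metric`.
#' @export
compare_groups <- function(records, metric = "expr_distance") {
  if (!"ltr_adjacent" %in% names(records))
    stop("records must carry an ltr_adjacent flag")
  if (!metric %in% names(records)) stop("no such metric column: ", metric)
  x <- records[[metric]][records$ltr_adjacent %in% TRUE]
  y <- records[[metric]][records$ltr_adjacent %in% FALSE]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both adjacency groups must be non-empty")
  exact <- min(length(x), length(y)) <= 20L
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 median_adjacent = median(x),
                 median_nonadjacent = median(y),
                 n_adjacent = length(x),
                 n_nonadjacent = length(y),
                 metric = metric),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum on %s: W = %g, p = %.4g\n",
              x$metric, x$statistic, x$p_value))
  cat(sprintf("  adjacent (n=%d) median %.4f vs non-adjacent (n=%d) median %.4f\n",
              x$n_adjacent, x$median_adjacent,
              x$n_nonadjacent, x$median_nonadjacent))
  invisible(x)
}
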