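# Nei-Gojobori (1986) Ka/Ks.
#
# Sites: for each codon and each of its three positions, the fraction of the
# three possible single-nucleotide changes that are synonymous; changes to a
# stop codon count as nonsynonymous. Site counts are averaged over the two
# sequences. Differences: codon pairs differing at nd positions are resolved
# by averaging synonymous/nonsynonymous step counts over all nd! minimal
# substitution paths with equal weight, excluding paths that pass through a
# stop codon (if every path does, all paths are used). ps = Sd/S and
# pn = Nd/N are Jukes-Cantor corrected into Ks and Ka.

.ng86_cache <- new.env(parent = emptyenv())

.genetic_code <- function() {
  gc <- get0(".gc_table", envir = .ng86_cache)
  if (!is.null(gc)) return(gc)
  code <- Biostrings::GENETIC_CODE
  assign(".gc_table", code, envir = .ng86_cache)
  code
}

.codon_neighbors <- function(codon, pos) {
  bases <- c("A", "C", "G", "T")
  cur <- substr(codon, pos, pos)
  vapply(setdiff(bases, cur), function(b) {
    x <- codon
    substr(x, pos, pos) <- b
    x
  }, character(1))
}

# synonymous site count of one codon (0..3)
.syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  hit <- get0(key, envir = .ng86_cache)
  if (!is.null(hit)) return(hit)
  code <- .genetic_code()
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    nb <- .codon_neighbors(codon, pos)
    s <- s + sum(code[nb] == aa & code[nb] != "*") / 3
  }
  assign(key, s, envir = .ng86_cache)
  s
}

.permutations <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# average (synonymous, nonsynonymous) difference counts between two codons
.codon_diff <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste0("d_", c1, c2)
  hit <- get0(key, envir = .ng86_cache)
  if (!is.null(hit)) return(hit)
  code <- .genetic_code()
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- .permutations[[as.character(length(diffpos))]]
  tally <- function(order, drop_stop_paths) {
    cur <- c1
    sd <- nd <- 0
    for (p in diffpos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (drop_stop_paths && code[[nxt]] == "*" && nxt != c2) return(NULL)
      if (code[[cur]] == code[[nxt]] && code[[nxt]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null),
                lapply(paths, tally, drop_stop_paths = TRUE))
  if (length(res) == 0L)  # every path passes through a stop: keep them all
    res <- lapply(paths, tally, drop_stop_paths = FALSE)
  out <- Reduce(`+`, res) / length(res)
  assign(key, out, envir = .ng86_cache)
  out
}

.split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Nei-Gojobori (1986) Ka/Ks for one coding-sequence pair
#'
#' @param cds_a,cds_b Equal-length in-frame nucleotide strings (length a
#'   multiple of 3, standard genetic code, no stop codons).
#' @param pair_id Optional identifier carried into the result.
#' @return An object of class `ks_result`: a list with `pair_id`, site
#'   counts `S`, `N` (S + N equals the nucleotide length), difference counts
#'   `Sd`, `Nd`, proportions `ps`, `pn`, corrected rates `Ks`, `Ka` (NA when
#'   the corresponding proportion is saturated at >= 0.75) and a `saturated`
#'   flag.
#' @export
#' @examples
#' ng86("TTTGGGGGG", "TTCGGGGGG")  # Ks ~ 0.6355, Ka = 0
ng86 <- function(cds_a, cds_b, pair_id = NA_character_) {
  stopifnot(is.character(cds_a), is.character(cds_b),
            length(cds_a) == 1L, length(cds_b) == 1L)
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("coding sequences differ in length")
  if (nchar(cds_a) %% 3 != 0)
    stop("sequence length not divisible by 3")
  if (grepl("[^ACGT]", cds_a) || grepl("[^ACGT]", cds_b))
    stop("coding sequences must contain only ACGT")
  code <- .genetic_code()
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  if (any(code[ca] == "*") || any(code[cb] == "*"))
    stop("stop codon within a coding sequence")

  Sa <- sum(vapply(ca, .syn_sites, numeric(1)))
  Sb <- sum(vapply(cb, .syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- nchar(cds_a) - S

  diffs <- vapply(seq_along(ca),
                  function(i) .codon_diff(ca[i], cb[i]), numeric(2))
  Sd <- sum(diffs[1, ])
  Nd <- sum(diffs[2, ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  saturated <- ps >= 0.75 || pn >= 0.75
  Ks <- if (ps < 0.75) jc69_correct(ps) else NA_real_
  Ka <- if (pn < 0.75) jc69_correct(pn) else NA_real_
  structure(list(pair_id = pair_id, S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, Ks = Ks, Ka = Ka,
                 saturated = saturated, length = nchar(cds_a)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("NG86 %s: S=%.3f N=%.3f Sd=%.3f Nd=%.3f ps=%.4f pn=%.4f\n",
              if (is.na(x$pair_id)) "" else x$pair_id,
              x$S, x$N, x$Sd, x$Nd, x$ps, x$pn))
  cat(sprintf("  Ks=%s Ka=%s%s\n",
              format(x$Ks, digits = 5), format(x$Ka, digits = 5),
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

#' NG86 over a set of sequence pairs
#'
#' Accepts a named character vector or `Biostrings::DNAStringSet` whose
#' names follow the `<pair>_a` / `<pair>_b` convention.
#'
#' @param seqs Named sequences (`<pair>_a`, `<pair>_b`).
#' @return A data frame, one row per pair, with the [ng86()] fields.
#' @export
ng86_pairs <- function(seqs) {
  if (inherits(seqs, "DNAStringSet"))
    seqs <- setNames(as.character(seqs), names(seqs))
  nm <- names(seqs)
  if (is.null(nm) || !all(grepl("_[ab]$", nm)))
    stop("sequence names must end in _a / _b")
  pairs <- unique(sub("_[ab]$", "", nm))
  missing_mate <- pairs[!(paste0(pairs, "_a") %in% nm &
                          paste0(pairs, "_b") %in% nm)]
  if (length(missing_mate))
    stop("pairs missing a mate: ", paste(missing_mate, collapse = ", "))
  rows <- lapply(pairs, function(p) {
    r <- ng86(seqs[[paste0(p, "_a")]], seqs[[paste0(p, "_b")]], pair_id = p)
    data.frame(pair_id = p, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               ps = r$ps, pn = r$pn, Ks = r$Ks, Ka = r$Ka,
               saturated = r$saturated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
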