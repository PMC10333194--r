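# Readers/writers for the standard formats the pipeline touches.
# Internal convention everywhere: 0-based half-open intervals on the
# forward strand. GFF3 (1-based inclusive) converts at the boundary;
# BED is already 0-based half-open.

.valid_strands <- c("+", "-")

.validate_gene_models <- function(df, where = "gene models") {
  if (anyDuplicated(df$id))
    stop(where, ": duplicated gene ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(bad <- !(df$strand %in% .valid_strands)))
    stop(where, ": invalid strand symbol for ",
         paste(df$id[bad], collapse = ", "), " (must be '+' or '-')")
  if (any(bad <- df$start >= df$end))
    stop(where, ": start >= end after normalization for ",
         paste(df$id[bad], collapse = ", "))
  df
}

#' Read gene models from GFF3 or BED
#'
#' Only records of type `gene` are kept from GFF3; every record is kept from
#' BED. Coordinates are normalized to the internal 0-based half-open
#' convention (GFF3 start is decremented; BED is passed through).
#'
#' @param path Path to a GFF3 or BED file.
#' @param format `"gff3"` or `"bed"`.
#' @return A data frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`+`/`-`), sorted by chrom and start.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tg1\t0\t+", tf)
#' read_gene_models(tf, "bed")
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop("failed to parse ", path, " as ",
                                          format, ": ", conditionMessage(e)))
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else sprintf("g%05d", seq_along(gr))
  }
  df <- data.frame(
    id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based inclusive
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df <- .validate_gene_models(df, where = path)
  df[order(df$chrom, df$start), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Write gene models to GFF3 or BED
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open intervals are
#' converted back to the file dialect at the boundary.
#'
#' @param genes Gene-model data frame (see [read_gene_models()]).
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  genes <- .validate_gene_models(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  if (format == "gff3") {
    gr$type <- "gene"
    gr$source <- "ltrdyn"
    gr$ID <- genes$id
  } else {
    gr$name <- genes$id
    gr$score <- 0L
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Read LTR elements (intervals plus terminal-repeat sequences)
#'
#' Interval input is either a headered TSV with columns
#' `id, chrom, start, end, status` (0-based half-open; `status` is
#' `intact`/`solo`) or a BED6 file (name column = element id; status is then
#' inferred from the FASTA: elements with both repeats are intact, the rest
#' solo). Terminal-repeat sequences come from a FASTA keyed `<id>_5p` /
#' `<id>_3p`. Intact elements must carry both repeats; an element with
#' exactly one repeat sequence is rejected.
#'
#' @param intervals_path Path to the TSV/BED interval file.
#' @param seqs_path Path to the repeat FASTA, or `NULL` (all elements solo,
#'   TSV input only).
#' @param format `"tsv"` or `"bed"`; default guesses from the extension.
#' @return A data frame with columns `id`, `chrom`, `start`, `end`,
#'   `status`, `ltr5_seq`, `ltr3_seq` (NA for solo) and `d` (cached pairwise
#'   divergence, NA unless supplied downstream).
#' @export
read_ltr_elements <- function(intervals_path, seqs_path = NULL,
                              format = NULL) {
  if (!file.exists(intervals_path)) stop("no such file: ", intervals_path)
  if (is.null(format))
    format <- if (grepl("\\.bed$", intervals_path, ignore.case = TRUE))
      "bed" else "tsv"
  format <- match.arg(format, c("tsv", "bed"))

  seqs <- NULL
  if (!is.null(seqs_path)) {
    ss <- Biostrings::readDNAStringSet(seqs_path)
    seqs <- setNames(as.character(ss), names(ss))
  }

  if (format == "bed") {
    bed <- read_gene_models(intervals_path, "bed")
    if (is.null(seqs))
      stop("BED element input needs a repeat FASTA to infer intact/solo status")
    has5 <- paste0(bed$id, "_5p") %in% names(seqs)
    has3 <- paste0(bed$id, "_3p") %in% names(seqs)
    df <- data.frame(id = bed$id, chrom = bed$chrom, start = bed$start,
                     end = bed$end,
                     status = ifelse(has5 & has3, "intact", "solo"),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.delim(intervals_path, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "start", "end", "status")
    if (!all(need %in% names(df)))
      stop("element TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
  }

  if (anyDuplicated(df$id))
    stop("duplicated element ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$status %in% c("intact", "solo")))
    stop("element status must be 'intact' or 'solo'")
  if (any(bad <- df$start >= df$end))
    stop("start >= end for elements: ", paste(df$id[bad], collapse = ", "))

  df$ltr5_seq <- NA_character_
  df$ltr3_seq <- NA_character_
  intact <- df$status == "intact"
  if (any(intact)) {
    k5 <- paste0(df$id[intact], "_5p")
    k3 <- paste0(df$id[intact], "_3p")
    miss <- !(k5 %in% names(seqs)) | !(k3 %in% names(seqs))
    if (is.null(seqs) || any(miss))
      stop("intact elements missing a terminal-repeat sequence: ",
           paste(df$id[intact][if (is.null(seqs)) TRUE else miss],
                 collapse = ", "))
    df$ltr5_seq[intact] <- unname(seqs[k5])
    df$ltr3_seq[intact] <- unname(seqs[k3])
    if (any(df$ltr5_seq[intact] == "" | df$ltr3_seq[intact] == ""))
      stop("empty terminal-repeat sequence for an intact element")
  }
  # one-repeat-only records are inconsistent regardless of declared status
  if (!is.null(seqs)) {
    has5 <- paste0(df$id, "_5p") %in% names(seqs)
    has3 <- paste0(df$id, "_3p") %in% names(seqs)
    if (any(one <- xor(has5, has3)))
      stop("elements with exactly one repeat sequence: ",
           paste(df$id[one], collapse = ", "))
  }
  df$d <- NA_real_
  rownames(df) <- NULL
  df
}

#' Write LTR elements to TSV (+ repeat FASTA)
#'
#' @param elements Element data frame (see [read_ltr_elements()]).
#' @param intervals_path Output TSV path.
#' @param seqs_path Output FASTA path for intact-element repeats, or `NULL`
#'   to skip sequence output.
#' @return `intervals_path`, invisibly.
#' @export
write_ltr_elements <- function(elements, intervals_path, seqs_path = NULL) {
  write.table(elements[, c("id", "chrom", "start", "end", "status")],
              intervals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(seqs_path)) {
    intact <- elements$status == "intact"
    if (any(intact)) {
      seqs <- c(setNames(elements$ltr5_seq[intact],
                         paste0(elements$id[intact], "_5p")),
                setNames(elements$ltr3_seq[intact],
                         paste0(elements$id[intact], "_3p")))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), seqs_path)
    } else {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(), seqs_path)
    }
  }
  invisible(intervals_path)
}

#' Read a gene x tissue expression matrix (RPKM)
#'
#' Expects a headered TSV whose first column is the gene id and remaining
#' columns are tissues (default pipeline order: leaf, bract, stem, fruit,
#' root — but the header order is authoritative).
#'
#' @param path TSV path.
#' @return A numeric matrix, genes in rows (rownames), tissues in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >= 1 tissue")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated gene ids in expression matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tissues <- names(df)[-1]
  if (any(tissues == "") || anyDuplicated(tissues))
    stop("tissue labels must be non-empty and unique")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing expression values in ", path)
  if (any(m < 0)) stop("negative expression values are not valid RPKM")
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene rownames and tissue colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
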