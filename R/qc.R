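# ---------------------------------------------------------------------------
# Barcode-complexity QC. Spatial barcodes must look random; systematic
# low-complexity barcodes indicate library artifacts. Two summary statistics
# are computed per barcode — the Shannon entropy of its nucleotide
# composition and the character length of its run-length encoding — and
# compared against the same statistics on uniformly random barcodes.
# ---------------------------------------------------------------------------

#' Shannon entropy of a barcode's nucleotide composition
#'
#' \eqn{H = -\sum_n f(n) \log_2 f(n)} over the empirical frequencies
#' \eqn{f(n)} of the symbols in the barcode (\code{N} counts as a fifth
#' symbol; \eqn{0 \log 0 = 0}).
#'
#' @param barcode character vector of barcodes (non-empty strings).
#' @return numeric vector of entropies in bits.
#' @examples
#' shannon_entropy("ACGTACGT")  # 2 bits
#' shannon_entropy("AAACATTA")  # 1.29879 bits
#' @export
shannon_entropy <- function(barcode) {
  if (any(!nzchar(barcode)) || any(is.na(barcode)))
    stop("empty barcode")
  vapply(strsplit(barcode, ""), function(ch) {
    f <- table(ch) / length(ch)
    -sum(f * log2(f)) + 0  # + 0 normalizes IEEE -0 for single-symbol input
  }, 0)
}

#' Run-length compression of a barcode
#'
#' Encodes each maximal run as count-then-symbol (\code{"AAACATTA"} becomes
#' \code{"3A1C1A2T1A"}); the compression length is the character count of
#' the encoding, so runs of 10 or more use multi-digit counts.
#'
#' @param barcode character vector of barcodes (non-empty strings).
#' @return data frame with columns \code{barcode}, \code{encoding},
#'   \code{length}.
#' @examples
#' compression_length("AAACATTA")  # encoding "3A1C1A2T1A", length 10
#' @export
compression_length <- function(barcode) {
  if (any(!nzchar(barcode)) || any(is.na(barcode)))
    stop("empty barcode")
  enc <- vapply(strsplit(barcode, ""), function(ch) {
    r <- rle(ch)
    paste0(r$lengths, r$values, collapse = "")
  }, "")
  data.frame(barcode = barcode, encoding = enc, length = nchar(enc),
             stringsAsFactors = FALSE)
}

#' Theoretical complexity baseline from random barcodes
#'
#' Generates \code{n_barcodes} i.i.d. uniform \{A,C,G,T\} barcodes of the
#' given length — the same number as the real barcodes under comparison —
#' and returns their entropy and compression-length distributions.
#'
#' @param n_barcodes number of random barcodes (>= 1).
#' @param barcode_length barcode length.
#' @param seed integer RNG seed (deterministic output).
#' @return data frame with columns \code{entropy_bits},
#'   \code{compression_len}.
#' @export
random_baseline <- function(n_barcodes, barcode_length, seed = 1L) {
  stopifnot(n_barcodes >= 1L, barcode_length >= 1L)
  bcs <- with_seed(seed, vapply(seq_len(n_barcodes), function(i)
    paste(sample(c("A", "C", "G", "T"), barcode_length, replace = TRUE),
          collapse = ""), ""))
  data.frame(entropy_bits = shannon_entropy(bcs),
             compression_len = compression_length(bcs)$length)
}

#' Per-position nucleotide composition by read-count quartile
#'
#' Barcodes are ranked by read count (ascending; ties broken
#' lexicographically), split into four rank quartiles (remainders spread to
#' the lower quartiles), and nucleotide frequencies are tallied per quartile
#' and barcode position. Quartile 1 holds the lowest read counts.
#'
#' @param barcodes_with_reads data frame with columns \code{barcode},
#'   \code{n_reads}; all barcodes must share one length; at least 4 rows.
#' @return data frame \code{quartile}, \code{position}, \code{nucleotide},
#'   \code{freq}; frequencies sum to 1 per (quartile, position).
#' @export
composition_by_quartile <- function(barcodes_with_reads) {
  stopifnot(all(c("barcode", "n_reads") %in% names(barcodes_with_reads)),
            nrow(barcodes_with_reads) >= 4L)
  L <- unique(nchar(barcodes_with_reads$barcode))
  if (length(L) != 1L) stop("mixed barcode lengths")
  ord <- order(barcodes_with_reads$n_reads, barcodes_with_reads$barcode)
  bcs <- barcodes_with_reads$barcode[ord]
  n <- length(bcs)
  base <- n %/% 4L; rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= rem)
  quart <- rep(1:4, times = sizes)
  chars <- do.call(rbind, strsplit(bcs, ""))
  out <- list()
  for (q in 1:4) {
    sub <- chars[quart == q, , drop = FALSE]
    for (p in seq_len(L)) {
      f <- table(sub[, p]) / nrow(sub)
      out[[length(out) + 1L]] <- data.frame(
        quartile = q, position = p, nucleotide = names(f),
        freq = as.numeric(f), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-unit QC metrics
#'
#' For each barcode of a DGE matrix: the number of genes detected (nonzero
#' entries), the UMI total (row sum), the read total, and the reads/UMIs
#' ratio (\code{NA} for zero-UMI barcodes).
#'
#' @param dge a \code{dge_matrix}.
#' @param read_totals named per-barcode read counts; defaults to the
#'   matrix's own \code{reads} slot.
#' @return data frame \code{barcode}, \code{n_reads}, \code{n_umis},
#'   \code{n_genes}, \code{reads_per_umi}.
#' @export
unit_metrics <- function(dge, read_totals = dge$reads) {
  barcodes <- rownames(dge$counts)
  missing <- setdiff(barcodes, names(read_totals))
  if (length(missing) > 0L)
    stop("missing read totals for: ", paste(missing, collapse = ", "))
  umis <- Matrix::rowSums(dge$counts)
  genes <- Matrix::rowSums(dge$counts > 0)
  reads <- as.integer(read_totals[barcodes])
  data.frame(barcode = barcodes,
             n_reads = reads,
             n_umis = as.integer(umis),
             n_genes = as.integer(genes),
             reads_per_umi = ifelse(umis > 0, reads / umis, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the QC tables for one sample
#'
#' Emits \code{qc_units.tsv}, \code{qc_complexity.tsv},
#' \code{qc_composition.tsv} and \code{qc_baseline.tsv} into \code{dir};
#' each file starts with \code{#}-prefixed column documentation.
#'
#' @param dge a \code{dge_matrix}.
#' @param dir output directory.
#' @param seed seed for the random baseline.
#' @return invisibly, the directory.
#' @export
write_qc_tables <- function(dge, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  um <- unit_metrics(dge)
  comp <- compression_length(um$barcode)
  cx <- data.frame(barcode = um$barcode,
                   entropy_bits = shannon_entropy(um$barcode),
                   compression_len = comp$length)
  qt <- composition_by_quartile(
    data.frame(barcode = um$barcode, n_reads = um$n_reads))
  bl <- random_baseline(nrow(um), unique(nchar(um$barcode))[1L], seed)
  emit <- function(df, file, header) {
    path <- file.path(dir, file)
    writeLines(header, path)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  emit(um, "qc_units.tsv",
       "# per-unit metrics: barcode, n_reads, n_umis, n_genes, reads_per_umi")
  emit(cx, "qc_complexity.tsv",
       "# per-barcode complexity: barcode, entropy_bits, compression_len")
  emit(qt, "qc_composition.tsv",
       "# nucleotide composition: quartile (1=lowest reads), position, nucleotide, freq")
  emit(bl, "qc_baseline.tsv",
       "# random-barcode baseline: entropy_bits, compression_len")
  invisible(dir)
}
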