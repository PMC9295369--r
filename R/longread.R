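# ---------------------------------------------------------------------------
# Long-read library debugging: each read is annotated with the oligo
# building blocks of library construction (primer handles, poly(T), TSO,
# sequencing adapters) by local alignment, the accepted hits are condensed
# into an ordered "signature", and the library is summarized as the
# distribution of signatures against the expected one. Repeated blocks are
# kept in signatures: TSO,TSO marks concatemer artifacts.
# ---------------------------------------------------------------------------

#' Default local-alignment scoring for short-oligo detection
#' @return list with \code{match}, \code{mismatch}, \code{gap_open},
#'   \code{gap_extend} (a gap of length L costs
#'   \code{gap_open + L * gap_extend}).
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -2, gap_open = -3, gap_extend = -1)
}

#' Load an oligo building-block catalog
#'
#' @param x a named character vector of sequences, a FASTA path (record ids
#'   become block names), or a 2-column name/sequence TSV path.
#' @return named character vector (block name -> sequence).
#' @export
block_catalog <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    first <- readLines(x, n = 1L)
    if (startsWith(first, ">")) {
      s <- Biostrings::readDNAStringSet(x)
      x <- setNames(as.character(s), sub("\\s.*$", "", names(s)))
    } else {
      df <- read.delim(x, header = FALSE, stringsAsFactors = FALSE)
      x <- setNames(df[[2L]], df[[1L]])
    }
  }
  stopifnot(!is.null(names(x)), !anyDuplicated(names(x)),
            all(nzchar(x)))
  toupper(x)
}

.is_homopolymer <- function(seq) {
  length(unique(strsplit(seq, "")[[1]])) == 1L
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# alignment of one block against one read on one strand
.sw_one <- function(block, read, scoring) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(block), Biostrings::DNAString(read),
    type = "local", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(score = Biostrings::score(aln),
       read_start = Biostrings::start(Biostrings::subject(aln)),
       read_end = Biostrings::end(Biostrings::subject(aln)),
       block_start = Biostrings::start(Biostrings::pattern(aln)),
       block_end = Biostrings::end(Biostrings::pattern(aln)),
       n_mismatches = sum(p != s & p != "-" & s != "-"),
       n_deletions = sum(s == "-"))
}

#' Best local alignment of a building block against a read
#'
#' Smith–Waterman local alignment (affine gaps; a gap of length L costs
#' \code{|gap_open| + L * |gap_extend|}) of the block against both strands
#' of the read; the better-scoring strand is reported. Coordinates are
#' 1-based inclusive on the forward read. \code{n_deletions} counts block
#' bases absent from the read.
#'
#' @param block,read DNA sequences (character).
#' @param scoring scoring list, see \code{\link{default_scoring}}.
#' @return list: \code{score}, \code{read_start}, \code{read_end},
#'   \code{block_start}, \code{block_end}, \code{strand},
#'   \code{n_mismatches}, \code{n_deletions}.
#' @export
sw_local_align <- function(block, read, scoring = default_scoring()) {
  stopifnot(nzchar(block), nzchar(read))
  fwd <- .sw_one(block, read, scoring)
  rev <- .sw_one(.revcomp(block), read, scoring)
  if (rev$score > fwd$score) c(rev, strand = "-") else c(fwd, strand = "+")
}

#' Annotate one long read with catalog blocks
#'
#' Every non-homopolymer block is aligned locally against the read (both
#' strands); hits scoring at least \code{min_score_frac} of the block's
#' maximum score are candidates. Homopolymer blocks (poly(T)/poly(A)) are
#' detected as the longest exact run of the base (or its complement, on the
#' minus strand) of length >= \code{min_polyt_run} — aligning against a
#' homopolymer is degenerate. Candidates are accepted greedily by
#' descending score with pairwise read-span overlap of at most
#' \code{overlap_tol} nt. If most accepted hits are on the minus strand the
#' read is reverse-complemented and re-annotated once, so orderings stay
#' comparable across reads.
#'
#' @param read DNA sequence (character).
#' @param catalog named block catalog (\code{\link{block_catalog}}).
#' @param scoring scoring list.
#' @param min_score_frac acceptance threshold as a fraction of the block's
#'   perfect score (0 < frac <= 1).
#' @param min_polyt_run minimum homopolymer run length (default 10).
#' @param overlap_tol allowed overlap between accepted hits, nt (default 2).
#' @return data frame of hits sorted by \code{read_start}: \code{block},
#'   \code{read_start}, \code{read_end}, \code{strand}, \code{score},
#'   \code{n_mismatches}, \code{n_deletions}; attribute \code{"flipped"}
#'   marks reads that were reverse-complemented.
#' @export
annotate_read <- function(read, catalog, scoring = default_scoring(),
                          min_score_frac = 0.6, min_polyt_run = 10L,
                          overlap_tol = 2L) {
  stopifnot(min_score_frac > 0, min_score_frac <= 1)
  hits <- .annotate_pass(read, catalog, scoring, min_score_frac,
                         min_polyt_run)
  accepted <- .greedy_accept(hits, overlap_tol)
  flipped <- FALSE
  if (nrow(accepted) > 0L &&
      sum(accepted$strand == "-") > nrow(accepted) / 2) {
    read <- .revcomp(read)
    flipped <- TRUE
    hits <- .annotate_pass(read, catalog, scoring, min_score_frac,
                           min_polyt_run)
    accepted <- .greedy_accept(hits, overlap_tol)
  }
  accepted <- accepted[order(accepted$read_start, accepted$block), ,
                       drop = FALSE]
  rownames(accepted) <- NULL
  attr(accepted, "flipped") <- flipped
  accepted
}

# repeated occurrences of one block (e.g. TSO concatemers): take the best
# local hit, then recurse into the flanking segments of the read
.find_block_hits <- function(block, read, scoring, min_score,
                             offset = 0L, depth = 4L) {
  if (depth <= 0L || nchar(read) < 8L) return(list())
  h <- sw_local_align(block, read, scoring)
  if (h$score < min_score) return(list())
  hit <- h
  hit$read_start <- h$read_start + offset
  hit$read_end <- h$read_end + offset
  left <- if (h$read_start > 1L)
    .find_block_hits(block, substr(read, 1L, h$read_start - 1L), scoring,
                     min_score, offset, depth - 1L) else list()
  right <- if (h$read_end < nchar(read))
    .find_block_hits(block, substr(read, h$read_end + 1L, nchar(read)),
                     scoring, min_score, offset + h$read_end,
                     depth - 1L) else list()
  c(list(hit), left, right)
}

.empty_hits <- function() {
  data.frame(block = character(), read_start = integer(),
             read_end = integer(), strand = character(), score = numeric(),
             n_mismatches = integer(), n_deletions = integer(),
             stringsAsFactors = FALSE)
}

.annotate_pass <- function(read, catalog, scoring, min_score_frac,
                           min_polyt_run) {
  rows <- list()
  for (nm in names(catalog)) {
    blk <- catalog[[nm]]
    if (.is_homopolymer(blk)) {
      base <- substr(blk, 1L, 1L)
      for (strand in c("+", "-")) {
        b <- if (strand == "+") base else
          chartr("ACGT", "TGCA", base)
        m <- gregexpr(paste0(b, "+"), read)[[1]]
        if (m[1L] == -1L) next
        len <- attr(m, "match.length")
        best <- which.max(len)
        if (len[best] >= min_polyt_run) {
          rows[[length(rows) + 1L]] <- data.frame(
            block = nm, read_start = m[best],
            read_end = m[best] + len[best] - 1L, strand = strand,
            score = scoring$match * len[best],
            n_mismatches = 0L, n_deletions = 0L, stringsAsFactors = FALSE)
        }
      }
    } else {
      hs <- .find_block_hits(blk, read, scoring,
                             min_score_frac * scoring$match * nchar(blk))
      for (h in hs) {
        rows[[length(rows) + 1L]] <- data.frame(
          block = nm, read_start = h$read_start, read_end = h$read_end,
          strand = h$strand, score = h$score,
          n_mismatches = h$n_mismatches, n_deletions = h$n_deletions,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  do.call(rbind, rows)
}

.greedy_accept <- function(hits, overlap_tol) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(-hits$score, hits$read_start, hits$block), ,
               drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in acc) {
      ov <- min(hits$read_end[i], hits$read_end[j]) -
        max(hits$read_start[i], hits$read_start[j]) + 1L
      if (ov > overlap_tol) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  hits[acc, , drop = FALSE]
}

#' Condense block hits into an ordered signature
#'
#' @param hits hit table from \code{\link{annotate_read}}.
#' @return character vector of block names in ascending read-start order
#'   (adjacent repeats retained — they are diagnostic).
#' @export
condense_signature <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  hits$block[order(hits$read_start)]
}

#' Summarize a long-read library against an expected signature
#'
#' Analyzes every \code{subsample_every}-th read: annotates it, condenses
#' the hits to a signature, and aggregates signature counts, the fraction
#' of reads matching the expected signature, per-block start/end positions
#' and per-block mismatch/deletion rates.
#'
#' @param reads character vector (or DNAStringSet) of long reads.
#' @param catalog block catalog.
#' @param expected expected signature: character vector of block names or a
#'   comma-separated string (e.g. \code{"P5,bead_start,polyT,N70X"}).
#' @param subsample_every analyze every k-th read (>= 1).
#' @param ... passed to \code{\link{annotate_read}}.
#' @return list of class \code{library_report}: \code{signatures} (data
#'   frame signature/count/fraction), \code{fraction_expected},
#'   \code{block_stats} (per-block mean mismatches/deletions and rates),
#'   \code{block_positions} (per accepted hit: block, start, end),
#'   \code{n_analyzed}.
#' @export
summarize_library <- function(reads, catalog, expected,
                              subsample_every = 1L, ...) {
  stopifnot(subsample_every >= 1L)
  reads <- as.character(reads)
  if (length(expected) == 1L && grepl(",", expected))
    expected <- strsplit(expected, ",")[[1]]
  expected_key <- paste(trimws(expected), collapse = ",")
  sel <- seq(1L, length(reads), by = subsample_every)
  if (length(reads) == 0L) {
    warning("empty read stream")
    sel <- integer(0)
  }
  sigs <- character(0)
  pos <- list(); stats <- list()
  for (i in sel) {
    hits <- annotate_read(reads[i], catalog, ...)
    sigs <- c(sigs, paste(condense_signature(hits), collapse = ","))
    if (nrow(hits) > 0L) {
      pos[[length(pos) + 1L]] <-
        hits[, c("block", "read_start", "read_end")]
      stats[[length(stats) + 1L]] <-
        hits[, c("block", "n_mismatches", "n_deletions")]
    }
  }
  sig_tab <- sort(table(sigs), decreasing = TRUE)
  signatures <- data.frame(signature = names(sig_tab),
                           count = as.integer(sig_tab),
                           fraction = as.integer(sig_tab) /
                             max(length(sel), 1L),
                           stringsAsFactors = FALSE)
  st <- if (length(stats) > 0L) do.call(rbind, stats) else
    data.frame(block = character(), n_mismatches = integer(),
               n_deletions = integer())
  block_stats <- if (nrow(st) > 0L) {
    agg <- aggregate(cbind(n_mismatches, n_deletions) ~ block, data = st,
                     FUN = mean)
    names(agg) <- c("block", "mean_mismatches", "mean_deletions")
    agg$n_hits <- as.integer(table(st$block)[agg$block])
    agg
  } else data.frame(block = character(), mean_mismatches = numeric(),
                    mean_deletions = numeric(), n_hits = integer())
  structure(list(
    signatures = signatures,
    fraction_expected = if (length(sel) > 0L)
      sum(sigs == expected_key) / length(sel) else NA_real_,
    block_stats = block_stats,
    block_positions = if (length(pos) > 0L) do.call(rbind, pos) else
      data.frame(block = character(), read_start = integer(),
                 read_end = integer()),
    n_analyzed = length(sel)), class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat("<library_report>", x$n_analyzed, "reads analyzed;",
      sprintf("%.1f%%", 100 * x$fraction_expected), "match expected\n")
  print(head(x$signatures, 10))
  invisible(x)
}

#' Write library-report tables
#'
#' Emits \code{signatures.tsv}, \code{block_stats.tsv} and
#' \code{block_positions.tsv}.
#'
#' @param report a \code{library_report}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_library_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$signatures, file.path(dir, "signatures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$block_stats, file.path(dir, "block_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$block_positions, file.path(dir, "block_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @importFrom stats aggregate
NULL
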