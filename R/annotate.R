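# ---------------------------------------------------------------------------
# Gene-function tagging of alignments and multimapper resolution.
#
# An alignment table holds one row per reported alignment of a read:
#   read_name, cb, umi, contig, strand, blocks (list of 2-column start/end
#   matrices, 1-based inclusive), n_hits, is_primary.
# Function tags are EXONIC / INTRONIC (with a gene_id) or INTERGENIC.
# ---------------------------------------------------------------------------

#' Build an annotation index from gene/exon records
#'
#' Accepts a GTF file path (parsed with rtracklayer) or a GRanges with
#' \code{type} and \code{gene_id} metadata columns. Only \code{gene} and
#' \code{exon} features are used; every exon must lie within its gene span.
#'
#' @param gtf a GTF path or a \code{GRanges}.
#' @return an \code{annotation_index}: list with \code{genes} and
#'   \code{exons} GRanges, both carrying \code{gene_id}.
#' @export
build_annotation_index <- function(gtf) {
  if (is.character(gtf)) gtf <- rtracklayer::import(gtf, format = "gtf")
  stopifnot(is(gtf, "GRanges"))
  if (is.null(gtf$type) || is.null(gtf$gene_id))
    stop("annotation records need 'type' and 'gene_id' metadata")
  genes <- gtf[gtf$type == "gene"]
  exons <- gtf[gtf$type == "exon"]
  if (length(genes) == 0L) stop("no gene features in annotation")
  # every exon must be contained in the span of its own gene
  for (i in seq_along(exons)) {
    g <- genes[genes$gene_id == exons$gene_id[i]]
    ok <- length(g) > 0L &&
      any(GenomicRanges::seqnames(g) == GenomicRanges::seqnames(exons)[i] &
            GenomicRanges::strand(g) == GenomicRanges::strand(exons)[i] &
            GenomicRanges::start(g) <= GenomicRanges::start(exons)[i] &
            GenomicRanges::end(g) >= GenomicRanges::end(exons)[i])
    if (!ok)
      stop("exon without enclosing gene: ", exons$gene_id[i])
  }
  structure(list(genes = genes, exons = exons), class = "annotation_index")
}

.blocks_to_granges <- function(alns) {
  n_blocks <- vapply(alns$blocks, nrow, 1L)
  GenomicRanges::GRanges(
    seqnames = rep(alns$contig, n_blocks),
    ranges = IRanges::IRanges(
      start = unlist(lapply(alns$blocks, function(b) b[, 1L])),
      end = unlist(lapply(alns$blocks, function(b) b[, 2L]))),
    strand = rep(alns$strand, n_blocks),
    aln = rep(seq_len(nrow(alns)), n_blocks))
}

#' Tag alignments with gene functions
#'
#' For each alignment, every same-strand gene whose span overlaps any aligned
#' block yields one tag: \code{EXONIC} if any block overlaps any exon of that
#' gene, else \code{INTRONIC}. Alignments overlapping no same-strand gene get
#' the single tag \code{INTERGENIC} (gene_id \code{NA}).
#'
#' @param alns alignment table (see \code{\link{read_alignment_sam}} or
#'   \code{\link{alignment_record}}).
#' @param index an \code{annotation_index}.
#' @return data frame with columns \code{aln} (row index into \code{alns}),
#'   \code{gene_id}, \code{func}.
#' @export
tag_alignments <- function(alns, index) {
  stopifnot(inherits(index, "annotation_index"))
  if (nrow(alns) == 0L)
    return(data.frame(aln = integer(), gene_id = character(),
                      func = character(), stringsAsFactors = FALSE))
  gr <- .blocks_to_granges(alns)
  suppressWarnings({
    hg <- GenomicRanges::findOverlaps(gr, index$genes)
    he <- GenomicRanges::findOverlaps(gr, index$exons)
  })
  gene_pairs <- unique(data.frame(
    aln = gr$aln[S4Vectors::queryHits(hg)],
    gene_id = index$genes$gene_id[S4Vectors::subjectHits(hg)],
    stringsAsFactors = FALSE))
  exon_pairs <- unique(data.frame(
    aln = gr$aln[S4Vectors::queryHits(he)],
    gene_id = index$exons$gene_id[S4Vectors::subjectHits(he)],
    stringsAsFactors = FALSE))
  if (nrow(gene_pairs) > 0L) {
    key <- paste(gene_pairs$aln, gene_pairs$gene_id)
    exonic <- key %in% paste(exon_pairs$aln, exon_pairs$gene_id)
    gene_pairs$func <- ifelse(exonic, "EXONIC", "INTRONIC")
  } else gene_pairs$func <- character(0)
  intergenic <- setdiff(seq_len(nrow(alns)), gene_pairs$aln)
  out <- rbind(gene_pairs,
               if (length(intergenic) > 0L)
                 data.frame(aln = intergenic, gene_id = NA_character_,
                            func = "INTERGENIC", stringsAsFactors = FALSE))
  out[order(out$aln, out$gene_id), , drop = FALSE]
}

#' Tag a single alignment
#'
#' @param contig,strand alignment location.
#' @param blocks 2-column matrix of (start, end) reference intervals.
#' @param index an \code{annotation_index}.
#' @return data frame of \code{gene_id}, \code{func} tags.
#' @export
tag_alignment <- function(contig, strand, blocks, index) {
  alns <- alignment_record("r", contig = contig, strand = strand,
                           blocks = blocks)
  tag_alignments(alns, index)[, c("gene_id", "func")]
}

#' Construct an alignment table row
#'
#' @param read_name read name shared by all alignments of the read.
#' @param contig,strand,blocks alignment location; \code{blocks} a 2-column
#'   (start, end) matrix or a length-2 vector for a single block.
#' @param cb,umi optional barcode/UMI tags.
#' @param n_hits total alignments reported for the read.
#' @param is_primary primary-alignment flag.
#' @return one-row alignment table.
#' @export
alignment_record <- function(read_name, contig, strand, blocks,
                             cb = NA_character_, umi = NA_character_,
                             n_hits = 1L, is_primary = TRUE) {
  if (!is.matrix(blocks)) blocks <- matrix(blocks, ncol = 2L, byrow = TRUE)
  stopifnot(all(blocks[, 1L] <= blocks[, 2L]), n_hits >= 1L)
  df <- data.frame(read_name = read_name, cb = cb, umi = umi, contig = contig,
                   strand = strand, n_hits = as.integer(n_hits),
                   is_primary = is_primary, stringsAsFactors = FALSE)
  df$blocks <- list(blocks)
  df
}

#' Resolve the alignments of one multimapping read
#'
#' Implements the keep-at-most-one rule: a unique alignment
#' (\code{n_hits = 1}) passes through unchanged. A multimapper is kept only
#' if exactly one of its alignments carries a countable genic tag (per
#' \code{counting_functions}) to exactly one gene and every other alignment
#' is purely intergenic; the kept alignment is flagged primary. A read whose
#' countable alignment hits two or more genes, or with two or more genic
#' alignments, is discarded.
#'
#' @param alns alignment table rows sharing one \code{read_name}.
#' @param tags tag table from \code{\link{tag_alignments}} for \code{alns}.
#' @param counting_functions \code{"EXONIC"} or
#'   \code{c("EXONIC", "INTRONIC")}, per the run-mode's intronic switch.
#' @return a one-row alignment table (kept, \code{is_primary = TRUE}) or
#'   \code{NULL} (discarded).
#' @export
resolve_multimappers <- function(alns, tags,
                                 counting_functions = "EXONIC") {
  i <- .resolve_index(alns, tags, counting_functions)
  if (i == 0L) return(NULL)
  kept <- alns[i, , drop = FALSE]
  kept$is_primary <- TRUE
  kept
}

# local index of the kept alignment, or 0L when the read is discarded
.resolve_index <- function(alns, tags, counting_functions) {
  if (nrow(alns) == 0L) return(0L)
  if (length(unique(alns$read_name)) != 1L)
    stop("alignments of several reads passed; one read_name required")
  if (nrow(alns) == 1L && alns$n_hits[1L] == 1L) return(1L)
  per <- split(tags, factor(tags$aln, levels = seq_len(nrow(alns))))
  countable_genes <- lapply(per, function(t)
    unique(t$gene_id[t$func %in% counting_functions]))
  n_countable <- vapply(countable_genes, length, 1L)
  is_intergenic <- vapply(per, function(t)
    nrow(t) > 0L && all(t$func == "INTERGENIC"), TRUE)
  genic_idx <- which(n_countable > 0L)
  if (length(genic_idx) != 1L) return(0L)
  if (n_countable[genic_idx] > 1L) return(0L)
  if (!all(is_intergenic[-genic_idx])) return(0L)
  genic_idx
}

#' Resolve all reads of an alignment table
#'
#' Applies \code{\link{resolve_multimappers}} per read name and returns the
#' surviving alignments together with their tags.
#'
#' @inheritParams resolve_multimappers
#' @return list with \code{alns} (kept alignment rows) and \code{tags}
#'   (their tags, \code{aln} re-indexed).
#' @export
resolve_reads <- function(alns, tags, counting_functions = "EXONIC") {
  keep_rows <- integer(0)
  for (idx in split(seq_len(nrow(alns)), alns$read_name)) {
    t <- tags[tags$aln %in% idx, , drop = FALSE]
    t$aln <- match(t$aln, idx)
    i <- .resolve_index(alns[idx, , drop = FALSE], t, counting_functions)
    if (i > 0L) keep_rows <- c(keep_rows, idx[i])
  }
  keep_rows <- sort(keep_rows)
  out_tags <- tags[tags$aln %in% keep_rows, , drop = FALSE]
  out_tags$aln <- match(out_tags$aln, keep_rows)
  kept <- alns[keep_rows, , drop = FALSE]
  kept$is_primary <- TRUE
  list(alns = kept, tags = out_tags)
}

#' Read a tagged alignment SAM file
#'
#' Reads alignments (SAM text) carrying \code{CB}/\code{MI} tags, via
#' Rsamtools/GenomicAlignments; aligned blocks are derived from the CIGAR,
#' and \code{n_hits} from the \code{NH} tag (1 when absent).
#'
#' @param path SAM path (with \code{@SQ} header lines).
#' @return alignment table (one row per alignment).
#' @export
read_alignment_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(what = "qname",
                                   tag = c("CB", "MI", "NH"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  blocks <- GenomicAlignments::grglist(ga)
  mc <- S4Vectors::mcols(ga)
  n <- length(ga)
  df <- data.frame(
    read_name = mc$qname,
    cb = if (is.null(mc$CB)) NA_character_ else mc$CB,
    umi = if (is.null(mc$MI)) NA_character_ else mc$MI,
    contig = as.character(GenomicRanges::seqnames(ga)),
    strand = as.character(GenomicRanges::strand(ga)),
    n_hits = if (is.null(mc$NH)) rep(1L, n) else ifelse(is.na(mc$NH), 1L, mc$NH),
    is_primary = TRUE,
    stringsAsFactors = FALSE)
  df$blocks <- lapply(seq_len(n), function(i) {
    b <- blocks[[i]]
    cbind(GenomicRanges::start(b), GenomicRanges::end(b))
  })
  df
}
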