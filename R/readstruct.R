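#' @importFrom methods is
#' @importFrom stats median setNames rgeom
#' @importFrom utils head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Barcode flavors: where in Read1/Read2 the spatial-unit barcode (CB) and the
# unique molecular identifier (UMI) live. Coordinates in the user-facing
# dialect are 1-based inclusive ("R1[1-16]"); they are converted exactly once
# here and stored 1-based inclusive as integer columns (start <= end).
# ---------------------------------------------------------------------------

.flavor_presets <- list(
  # Corrected coordinates: the 16 nt spot barcode followed by a 12 nt UMI.
  visium            = "cb=R1[1-16]; umi=R1[17-28]",
  # Literal published coordinates (UMI span overlaps the barcode at pos 16).
  visium_literal    = "cb=R1[1-16]; umi=R1[16-24]",
  slide_seq         = "cb=R1[1-14]; umi=R1[15-23]",
  slide_seq_literal = "cb=R1[1-14]; umi=R2[15-23]",
  seq_scope         = "cb=R1[1-20]; umi=R2[1-9]"
)

.parse_position_token <- function(token) {
  m <- regmatches(token, regexec("^R([12])\\[([0-9]+)-([0-9]+)\\]$", token))[[1]]
  if (length(m) == 0L)
    stop("malformed position token: '", token, "'", call. = FALSE)
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (start < 1L || end < 1L)
    stop("zero/negative index in token: '", token, "'", call. = FALSE)
  if (start > end)
    stop("inverted range in token: '", token, "'", call. = FALSE)
  data.frame(read = paste0("R", m[2]), start = start, end = end,
             stringsAsFactors = FALSE)
}

.parse_spec_part <- function(part) {
  tokens <- trimws(strsplit(part, "+", fixed = TRUE)[[1]])
  do.call(rbind, lapply(tokens, .parse_position_token))
}

#' Parse a barcode-flavor definition
#'
#' A flavor declares, with 1-based inclusive coordinates, which stretches of
#' Read1/Read2 are concatenated to form the spatial-unit barcode (CB) and the
#' UMI, e.g. \code{"cb=R1[1-16]; umi=R1[17-28]"}. Multiple segments are
#' joined with \code{+}.
#'
#' @param spec_text flavor definition string, or the name of a shipped preset
#'   (\code{"visium"}, \code{"visium_literal"}, \code{"slide_seq"},
#'   \code{"slide_seq_literal"}, \code{"seq_scope"}).
#' @param name optional flavor name; defaults to the preset name or the spec
#'   string itself.
#' @return an object of class \code{barcode_flavor} with elements
#'   \code{name}, \code{spec}, \code{cb_spec}, \code{umi_spec} (data frames
#'   with columns \code{read}, \code{start}, \code{end}).
#' @examples
#' parse_flavor("cb=R1[1-16]; umi=R1[17-28]")
#' parse_flavor("visium")
#' @export
parse_flavor <- function(spec_text, name = NULL) {
  stopifnot(is.character(spec_text), length(spec_text) == 1L)
  if (spec_text %in% names(.flavor_presets)) {
    if (is.null(name)) name <- spec_text
    spec_text <- .flavor_presets[[spec_text]]
  }
  parts <- trimws(strsplit(spec_text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexec("^(cb|umi)\\s*=\\s*(.+)$", parts))
  bad <- vapply(kv, length, 1L) == 0L
  if (any(bad))
    stop("malformed flavor part: '", parts[bad][1], "'", call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  if (anyDuplicated(keys) || !all(c("cb", "umi") %in% keys))
    stop("flavor must define 'cb' and 'umi' exactly once", call. = FALSE)
  specs <- setNames(lapply(kv, function(x) .parse_spec_part(x[3])), keys)
  structure(list(name = if (is.null(name)) spec_text else name,
                 spec = spec_text,
                 cb_spec = specs[["cb"]], umi_spec = specs[["umi"]]),
            class = "barcode_flavor")
}

#' @export
print.barcode_flavor <- function(x, ...) {
  cat("<barcode_flavor>", x$name, "\n  spec:", x$spec,
      "\n  CB length:", sum(x$cb_spec$end - x$cb_spec$start + 1L),
      " UMI length:", sum(x$umi_spec$end - x$umi_spec$start + 1L), "\n")
  invisible(x)
}

#' List shipped barcode-flavor presets
#' @return named character vector of preset spec strings.
#' @export
flavor_presets <- function() unlist(.flavor_presets)

.concat_spec <- function(spec, r1, r2) {
  # vectorised over reads; returns NA where a read is too short for a span
  out <- rep("", length(r1))
  ok <- rep(TRUE, length(r1))
  for (i in seq_len(nrow(spec))) {
    src <- if (spec$read[i] == "R1") r1 else r2
    ok <- ok & nchar(src) >= spec$end[i]
    out <- paste0(out, substr(src, spec$start[i], spec$end[i]))
  }
  out[!ok] <- NA_character_
  out
}

#' Extract CB and UMI tags from read pairs
#'
#' Applies a \code{barcode_flavor} to a table of read pairs. The tagged-read
#' sequence and quality are taken from Read2 (the cDNA-bearing mate). Reads
#' too short for the flavor are flagged dropped with reason
#' \code{"short_read"}; reads whose CB contains more than one \code{N} are
#' flagged \code{"ambiguous_cb"}.
#'
#' @param pairs data frame with columns \code{name}, \code{seq1},
#'   \code{qual1}, \code{seq2}, \code{qual2} (see \code{\link{read_fastq_pairs}}).
#' @param flavor a \code{barcode_flavor} or a spec string/preset name.
#' @return data frame with columns \code{name}, \code{seq}, \code{qual},
#'   \code{cb}, \code{umi}, \code{dropped}, \code{drop_reason}.
#' @export
extract_tags <- function(pairs, flavor) {
  if (!inherits(flavor, "barcode_flavor")) flavor <- parse_flavor(flavor)
  stopifnot(all(c("name", "seq1", "seq2") %in% names(pairs)))
  if (is.null(pairs$qual1)) pairs$qual1 <- strrep("I", nchar(pairs$seq1))
  if (is.null(pairs$qual2)) pairs$qual2 <- strrep("I", nchar(pairs$seq2))
  cb  <- .concat_spec(flavor$cb_spec,  pairs$seq1, pairs$seq2)
  umi <- .concat_spec(flavor$umi_spec, pairs$seq1, pairs$seq2)
  dropped <- is.na(cb) | is.na(umi)
  reason <- ifelse(dropped, "short_read", NA_character_)
  n_in_cb <- nchar(cb) - nchar(gsub("N", "", cb, fixed = TRUE))
  amb <- !dropped & !is.na(n_in_cb) & n_in_cb > 1L
  dropped <- dropped | amb
  reason[amb] <- "ambiguous_cb"
  data.frame(name = pairs$name, seq = pairs$seq2, qual = pairs$qual2,
             cb = cb, umi = umi, dropped = dropped, drop_reason = reason,
             stringsAsFactors = FALSE)
}

#' Trim 3' poly(A) runs and adapter suffixes from reads
#'
#' First removes the longest 3'-terminal run of \code{A} (exact matches only)
#' when it is at least \code{min_polya_run} long, then removes any remaining
#' 3' suffix that equals a 5' prefix of one of the \code{adapters} with
#' overlap of at least \code{min_adapter_overlap} nt. Qualities are trimmed
#' in lockstep. Trimming may empty a read; dropping is the caller's decision.
#'
#' @param seq,qual character vectors of equal length (qual may be NULL).
#' @param adapters character vector of adapter sequences (5'->3').
#' @param min_polya_run minimum poly(A) run length to trim (>= 1).
#' @param min_adapter_overlap minimum suffix/prefix overlap to trim (>= 1).
#' @return list with \code{seq}, \code{qual}, and \code{report}, a data frame
#'   of bases removed per read and cause (\code{polya}, \code{adapter}).
#' @export
trim_read_3prime <- function(seq, qual = NULL, adapters = character(),
                             min_polya_run = 6L, min_adapter_overlap = 3L) {
  stopifnot(min_polya_run >= 1L, min_adapter_overlap >= 1L)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  stopifnot(length(seq) == length(qual), all(nchar(seq) == nchar(qual)))
  polya <- attr(regexpr("A+$", seq), "match.length")
  polya[polya < 0L] <- 0L
  polya[polya < min_polya_run] <- 0L
  keep <- nchar(seq) - polya
  seq <- substr(seq, 1L, keep)
  qual <- substr(qual, 1L, keep)
  adapter_removed <- integer(length(seq))
  if (length(adapters) > 0L) {
    for (i in seq_along(seq)) {
      L <- nchar(seq[i])
      best <- 0L
      for (ad in adapters) {
        for (k in seq(from = min(L, nchar(ad)), by = -1L,
                      length.out = max(0L, min(L, nchar(ad)) - min_adapter_overlap + 1L))) {
          if (substr(seq[i], L - k + 1L, L) == substr(ad, 1L, k)) {
            best <- max(best, k); break
          }
        }
      }
      if (best > 0L) {
        adapter_removed[i] <- best
        seq[i] <- substr(seq[i], 1L, L - best)
        qual[i] <- substr(qual[i], 1L, L - best)
      }
    }
  }
  list(seq = seq, qual = qual,
       report = data.frame(polya = polya, adapter = adapter_removed))
}

#' Tag and optionally trim a set of read pairs
#'
#' Convenience wrapper: \code{\link{extract_tags}} followed by
#' \code{\link{trim_read_3prime}} on the Read2-derived sequence. Reads that
#' become empty after trimming are flagged dropped (\code{"empty_after_trim"}).
#'
#' @inheritParams extract_tags
#' @param trim logical; perform 3' trimming.
#' @param adapters,min_polya_run,min_adapter_overlap passed to
#'   \code{\link{trim_read_3prime}}.
#' @return tagged-read data frame as in \code{\link{extract_tags}}.
#' @export
tag_reads <- function(pairs, flavor, trim = FALSE, adapters = character(),
                      min_polya_run = 6L, min_adapter_overlap = 3L) {
  tagged <- extract_tags(pairs, flavor)
  if (trim) {
    keep <- !tagged$dropped
    tr <- trim_read_3prime(tagged$seq[keep], tagged$qual[keep], adapters,
                           min_polya_run, min_adapter_overlap)
    tagged$seq[keep] <- tr$seq
    tagged$qual[keep] <- tr$qual
    empty <- keep & !nzchar(tagged$seq)
    tagged$dropped[empty] <- TRUE
    tagged$drop_reason[empty] <- "empty_after_trim"
  }
  tagged
}

# ---------------------------------------------------------------------------
# FASTQ / tagged-SAM I/O
# ---------------------------------------------------------------------------

#' Read synchronized paired FASTQ files
#'
#' Files are read with Biostrings (gzip-transparent) and paired by record
#' order; differing record counts are a fatal error.
#'
#' @param r1_path,r2_path FASTQ paths for Read1 and Read2.
#' @return data frame with columns \code{name}, \code{seq1}, \code{qual1},
#'   \code{seq2}, \code{qual2}.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # Biostrings warns that FASTQ description metadata is dropped; we only
  # need name/seq/qual
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2))
    stop("R1 and R2 record counts differ (", length(r1), " vs ", length(r2), ")")
  nm <- sub("\\s.*$", "", names(r1))
  data.frame(name = nm,
             seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
             seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write tagged reads as unmapped SAM
#'
#' Emits unmapped records (flag 4) with \code{CB:Z} and \code{MI:Z} tags; the
#' \code{@PG} header line records the flavor name and spec string. Dropped
#' reads are not written.
#'
#' @param tagged tagged-read data frame from \code{\link{extract_tags}}.
#' @param path output SAM path.
#' @param flavor the \code{barcode_flavor} used (recorded in the header).
#' @return invisibly, the number of records written.
#' @export
write_tagged_sam <- function(tagged, path, flavor = NULL) {
  keep <- tagged[!tagged$dropped, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@PG\tID:spotforge\tPN:spotforge",
                  if (!is.null(flavor))
                    paste0("\tDS:flavor=", flavor$name, " spec=", flavor$spec)))
  recs <- paste(keep$name, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                keep$seq, keep$qual,
                paste0("CB:Z:", keep$cb), paste0("MI:Z:", keep$umi),
                sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(nrow(keep))
}

#' Read a tagged unmapped SAM back into a tagged-read table
#'
#' @param path SAM path written by \code{\link{write_tagged_sam}}.
#' @return data frame with columns \code{name}, \code{seq}, \code{qual},
#'   \code{cb}, \code{umi}.
#' @export
read_tagged_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq", "qual"),
                                   tag = c("CB", "MI"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  data.frame(name = x$qname,
             seq = as.character(x$seq),
             qual = as.character(x$qual),
             cb = x$tag$CB, umi = x$tag$MI,
             stringsAsFactors = FALSE)
}
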