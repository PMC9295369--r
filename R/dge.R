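# ---------------------------------------------------------------------------
# Digital gene expression (DGE) matrix: construction from resolved, tagged
# alignments, barcode selection/cleaning, replicate merging, downsampling and
# saturation analysis. Counts are distinct-UMI counts per (barcode, gene),
# held in a Matrix::sparseMatrix (barcodes x genes).
# ---------------------------------------------------------------------------

#' Define a run-mode
#'
#' A run-mode bundles the processing switches applied to one sample:
#' trimming, intronic and multimapper counting, tissue detection, meshing,
#' expected barcode count and the UMI cutoff for the analysis-ready view.
#'
#' @param name run-mode name.
#' @param polyA_adapter_trimming trim 3' poly(A)/adapters before mapping.
#' @param count_intronic_reads count INTRONIC in addition to EXONIC reads.
#' @param count_mm_reads count resolved multimappers (off: unique only).
#' @param detect_tissue restrict to the largest contiguous high-UMI region.
#' @param mesh_data aggregate spatial units onto an in-silico mesh.
#' @param mesh_type \code{"hexagon"} or \code{"circle"} (Visium-style).
#' @param spot_distance_um mesh center-to-center distance, micrometres.
#' @param spot_diameter_um circle diameter for circle meshes, micrometres.
#' @param n_beads expected number of barcodes when no whitelist is given.
#' @param umi_cutoff minimum UMIs per barcode in the analysis-ready view.
#' @param clean_dge remove primer-contaminated barcodes before counting.
#' @return a \code{run_mode} object (list).
#' @export
run_mode <- function(name = "default",
                     polyA_adapter_trimming = TRUE,
                     count_intronic_reads = FALSE,
                     count_mm_reads = FALSE,
                     detect_tissue = FALSE,
                     mesh_data = FALSE,
                     mesh_type = c("hexagon", "circle"),
                     spot_distance_um = 10,
                     spot_diameter_um = NULL,
                     n_beads = 100000L,
                     umi_cutoff = 100L,
                     clean_dge = FALSE) {
  mesh_type <- match.arg(mesh_type)
  stopifnot(n_beads >= 1L, umi_cutoff >= 0L)
  structure(list(name = name,
                 polyA_adapter_trimming = polyA_adapter_trimming,
                 count_intronic_reads = count_intronic_reads,
                 count_mm_reads = count_mm_reads,
                 detect_tissue = detect_tissue,
                 mesh_data = mesh_data, mesh_type = mesh_type,
                 spot_distance_um = spot_distance_um,
                 spot_diameter_um = spot_diameter_um,
                 n_beads = as.integer(n_beads),
                 umi_cutoff = as.integer(umi_cutoff),
                 clean_dge = clean_dge),
            class = "run_mode")
}

#' Countable gene functions of a run-mode
#' @param rm a \code{run_mode}.
#' @return \code{"EXONIC"} or \code{c("EXONIC", "INTRONIC")}.
#' @export
counting_functions <- function(rm) {
  if (rm$count_intronic_reads) c("EXONIC", "INTRONIC") else "EXONIC"
}

#' Select barcodes for DGE construction
#'
#' With a whitelist, it is returned verbatim. Otherwise barcodes are ranked
#' by read count and the top \code{n_beads} kept; ties at the cutoff are
#' broken lexicographically (ascending) so the selection is deterministic.
#'
#' @param read_counts named integer vector (barcode -> reads) or a data
#'   frame with columns \code{cb} and \code{reads}.
#' @param whitelist optional character vector of barcodes.
#' @param n_beads number of barcodes to keep when no whitelist is given.
#' @return ordered character vector of selected barcodes.
#' @export
select_barcodes <- function(read_counts, whitelist = NULL, n_beads = NULL) {
  if (!is.null(whitelist)) return(as.character(whitelist))
  if (is.data.frame(read_counts))
    read_counts <- setNames(read_counts$reads, read_counts$cb)
  if (length(read_counts) == 0L) {
    warning("empty input stream; no barcodes selected")
    return(character(0))
  }
  stopifnot(!is.null(n_beads), n_beads >= 1L)
  ord <- order(-read_counts, names(read_counts))
  names(read_counts)[ord][seq_len(min(n_beads, length(read_counts)))]
}

#' Remove primer-contaminated barcodes
#'
#' A barcode is removed when (i) a 3'-terminal suffix of length >= 4 equals
#' a 5' prefix of any primer, or (ii) any substring of length >= 7 occurs
#' anywhere within any primer.
#'
#' @param barcodes character vector.
#' @param primers character vector of primer sequences.
#' @param min_3prime_overlap threshold for rule (i); default 4.
#' @param min_internal_overlap threshold for rule (ii); default 7.
#' @return list with \code{kept} (character vector) and \code{removed}
#'   (data frame \code{barcode}, \code{reason}).
#' @export
clean_barcodes <- function(barcodes, primers,
                           min_3prime_overlap = 4L,
                           min_internal_overlap = 7L) {
  stopifnot(length(primers) > 0L)
  reason <- rep(NA_character_, length(barcodes))
  for (i in seq_along(barcodes)) {
    bc <- barcodes[i]; L <- nchar(bc)
    for (p in primers) {
      kmax <- min(L, nchar(p))
      for (k in seq(from = kmax, by = -1L,
                    length.out = max(0L, kmax - min_3prime_overlap + 1L))) {
        if (substr(bc, L - k + 1L, L) == substr(p, 1L, k)) {
          reason[i] <- sprintf("3prime_overlap(%d)", k)
          break
        }
      }
      if (!is.na(reason[i])) break
    }
    if (is.na(reason[i]) && L >= min_internal_overlap) {
      for (p in primers) {
        found <- FALSE
        for (s in seq_len(L - min_internal_overlap + 1L)) {
          sub <- substr(bc, s, s + min_internal_overlap - 1L)
          if (grepl(sub, p, fixed = TRUE)) {
            reason[i] <- sprintf("internal_overlap(%d)", min_internal_overlap)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
  }
  list(kept = barcodes[is.na(reason)],
       removed = data.frame(barcode = barcodes[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

.new_dge <- function(counts, reads) {
  structure(list(counts = counts, reads = reads), class = "dge_matrix")
}

#' @export
print.dge_matrix <- function(x, ...) {
  cat("<dge_matrix>", nrow(x$counts), "barcodes x", ncol(x$counts),
      "genes;", sum(x$counts), "UMIs,", sum(x$reads), "reads\n")
  invisible(x)
}

#' Build the DGE matrix from resolved alignments
#'
#' Counts the number of distinct UMI strings per (barcode, gene) over the
#' countable functions of the run-mode (EXONIC, plus INTRONIC when intronic
#' counting is on). Reads with an INTERGENIC function contribute to the
#' per-barcode read totals but never to counts. Duplicate (cb, umi, gene)
#' observations collapse to a single count. Barcodes absent from
#' \code{barcodes} are ignored (tallied as filtered).
#'
#' @param stream data frame with columns \code{cb}, \code{umi},
#'   \code{gene_id}, \code{func} — one row per resolved read/function tag.
#' @param barcodes character vector of barcodes to count (whitelist or
#'   \code{\link{select_barcodes}} output).
#' @param rm a \code{\link{run_mode}}.
#' @return a \code{dge_matrix}: list with \code{counts} (sparse barcodes x
#'   genes matrix) and \code{reads} (named per-barcode read totals,
#'   including intergenic reads). Attribute \code{n_filtered} records reads
#'   whose barcode was not in \code{barcodes}.
#' @export
count_dge <- function(stream, barcodes, rm = run_mode()) {
  stopifnot(all(c("cb", "umi", "gene_id", "func") %in% names(stream)))
  barcodes <- as.character(barcodes)
  in_list <- stream$cb %in% barcodes
  n_filtered <- sum(!in_list)
  stream <- stream[in_list, , drop = FALSE]
  reads <- table(factor(stream$cb, levels = barcodes))
  reads <- setNames(as.integer(reads), barcodes)
  countable <- stream[stream$func %in% counting_functions(rm) &
                        !is.na(stream$gene_id), , drop = FALSE]
  triples <- unique(countable[, c("cb", "gene_id", "umi")])
  genes <- sort(unique(triples$gene_id))
  counts <- Matrix::sparseMatrix(
    i = match(triples$cb, barcodes),
    j = match(triples$gene_id, genes),
    x = rep(1L, nrow(triples)),
    dims = c(length(barcodes), max(length(genes), 1L)),
    dimnames = list(barcodes,
                    if (length(genes) > 0L) genes else "none"))
  out <- .new_dge(counts, reads)
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Analysis-ready view of a DGE matrix
#'
#' Drops barcodes whose total UMI count is below the run-mode's
#' \code{umi_cutoff}.
#'
#' @param dge a \code{dge_matrix}.
#' @param umi_cutoff minimum UMIs per barcode.
#' @return a filtered \code{dge_matrix}.
#' @export
filter_dge <- function(dge, umi_cutoff) {
  keep <- Matrix::rowSums(dge$counts) >= umi_cutoff
  .new_dge(dge$counts[keep, , drop = FALSE], dge$reads[keep])
}

#' Merge technical replicates into one DGE matrix
#'
#' Replicates of one library are merged with set-union semantics: the merged
#' count for (barcode, gene) is the number of distinct UMIs across all
#' replicates, so duplicate molecules sequenced in several runs are counted
#' once. Merging is commutative, associative and idempotent.
#'
#' @param ... two or more replicate streams, each a data frame with columns
#'   \code{cb}, \code{umi}, \code{gene_id} (a \code{func} column, when
#'   present, is honoured as in \code{\link{count_dge}}).
#' @param barcodes barcodes of the merged matrix; default: union observed.
#' @param rm a \code{\link{run_mode}}.
#' @param gene_universes optional list of per-replicate gene universes; if
#'   given they must be identical across replicates.
#' @return a \code{dge_matrix}.
#' @export
merge_replicates <- function(..., barcodes = NULL, rm = run_mode(),
                             gene_universes = NULL) {
  streams <- list(...)
  stopifnot(length(streams) >= 1L)
  if (!is.null(gene_universes)) {
    ref <- sort(unique(gene_universes[[1L]]))
    for (g in gene_universes[-1L]) {
      d <- union(setdiff(ref, g), setdiff(g, ref))
      if (length(d) > 0L)
        stop("incompatible gene universes; symmetric difference: ",
             paste(sort(d), collapse = ", "))
    }
  }
  streams <- lapply(streams, function(s) {
    if (is.null(s$func)) s$func <- "EXONIC"
    s[, c("cb", "umi", "gene_id", "func")]
  })
  pooled <- unique(do.call(rbind, streams))
  if (is.null(barcodes)) barcodes <- sort(unique(pooled$cb))
  count_dge(pooled, barcodes, rm)
}

#' Downsample a read set at nested ratios
#'
#' Draws, for each ratio p, exactly \code{floor(p * N)} reads uniformly
#' without replacement. Subsets are nested for a fixed seed (the subset at a
#' smaller ratio is contained in every larger one): one random permutation
#' is drawn and each subset is its prefix.
#'
#' @param x integer N (number of reads) or a data frame of reads.
#' @param ratios fractions in (0, 1); default 0.1 ... 0.9 step 0.1.
#' @param seed integer RNG seed.
#' @return named list (by ratio) of integer index vectors (when \code{x} is
#'   a count) or row subsets (when \code{x} is a data frame).
#' @export
downsample_alignments <- function(x, ratios = seq(0.1, 0.9, by = 0.1),
                                  seed = 1L) {
  if (any(ratios <= 0 | ratios >= 1))
    stop("ratios must lie strictly inside (0, 1)")
  n <- if (is.data.frame(x)) nrow(x) else as.integer(x)
  perm <- with_seed(seed, sample.int(n))
  out <- lapply(ratios, function(p) {
    idx <- sort(perm[seq_len(floor(p * n))])
    if (is.data.frame(x)) x[idx, , drop = FALSE] else idx
  })
  names(out) <- formatC(ratios, format = "fg")
  out
}

#' Saturation table over downsampling ratios
#'
#' For each downsampling ratio, reports the median number of reads, UMIs,
#' genes and the median reads/UMIs ratio per spatial unit, computed over the
#' barcodes present in the full-data matrix. Per-ratio histograms of the
#' UMI distribution are attached as attribute \code{"histograms"}.
#'
#' @param per_ratio named list (ratio -> \code{dge_matrix}); include
#'   \code{"1"} for the full data.
#' @param full the full-data \code{dge_matrix} defining the barcode
#'   universe.
#' @param hist_breaks breaks for the per-ratio UMI histograms.
#' @return data frame with columns \code{ratio}, \code{median_reads},
#'   \code{median_umis}, \code{median_genes}, \code{median_reads_per_umi}.
#' @export
saturation_table <- function(per_ratio, full = per_ratio[["1"]],
                             hist_breaks = "Sturges") {
  stopifnot(!is.null(full))
  universe <- rownames(full$counts)
  rows <- list(); hists <- list()
  for (r in names(per_ratio)) {
    dge <- per_ratio[[r]]
    if (sum(dge$counts) == 0L && sum(dge$reads) == 0L)
      warning("empty matrix at ratio ", r)
    umis <- Matrix::rowSums(dge$counts)[universe]
    umis[is.na(umis)] <- 0
    genes <- Matrix::rowSums(dge$counts > 0)[universe]
    genes[is.na(genes)] <- 0
    reads <- dge$reads[universe]
    reads[is.na(reads)] <- 0
    rpu <- ifelse(umis > 0, reads / umis, NA_real_)
    rows[[r]] <- data.frame(
      ratio = as.numeric(r),
      median_reads = median(reads),
      median_umis = median(umis),
      median_genes = median(genes),
      median_reads_per_umi = median(rpu, na.rm = TRUE))
    h <- hist(umis, breaks = hist_breaks, plot = FALSE)
    hists[[r]] <- data.frame(ratio = as.numeric(r),
                             bin_low = h$breaks[-length(h$breaks)],
                             bin_high = h$breaks[-1L],
                             count = h$counts)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- do.call(rbind, hists)
  out
}

# ---------------------------------------------------------------------------
# MatrixMarket triplet output
# ---------------------------------------------------------------------------

#' Write a DGE matrix as a MatrixMarket triplet
#'
#' Emits \code{matrix.mtx}, \code{barcodes.tsv} and \code{genes.tsv} into
#' \code{dir}, the layout downstream single-cell tooling expects (genes x
#' barcodes in the .mtx, as in CellRanger-style output).
#'
#' @param dge a \code{dge_matrix}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_dge_mtx <- function(dge, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- methods::as(methods::as(Matrix::t(dge$counts) * 1, "generalMatrix"),
                    "CsparseMatrix")
  Matrix::writeMM(mm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(dge$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(dge$counts), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Read a DGE matrix written by \code{\link{write_dge_mtx}}
#' @param dir directory containing \code{matrix.mtx}, \code{barcodes.tsv},
#'   \code{genes.tsv}.
#' @return a \code{dge_matrix} (read totals unknown: zeros).
#' @export
read_dge_mtx <- function(dir) {
  m <- Matrix::t(methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                             "generalMatrix")) * 1
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  dimnames(m) <- list(barcodes, genes)
  .new_dge(methods::as(m, "CsparseMatrix"),
           setNames(integer(length(barcodes)), barcodes))
}
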