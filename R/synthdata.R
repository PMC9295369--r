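# ---------------------------------------------------------------------------
# Seeded synthetic fixtures with planted ground truth for every pipeline
# stage. Every generator is a pure function of (parameters, seed): the RNG
# state is set locally and restored, so regeneration is bit-identical and
# generators never interact.
# ---------------------------------------------------------------------------

.NUC <- c("A", "C", "G", "T")

.rand_seq <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(.NUC, length, replace = TRUE), collapse = ""), "")
}

#' Generate synthetic barcodes
#'
#' \code{"uniform"} barcodes are i.i.d. uniform nucleotides;
#' \code{"low_complexity"} barcodes are built from homopolymer runs with
#' geometric lengths (mean 3), which depresses both entropy and
#' run-length-compression length so QC baselines can separate the modes.
#'
#' @param n number of barcodes (>= 1).
#' @param length barcode length.
#' @param mode \code{"uniform"} or \code{"low_complexity"}.
#' @param seed integer seed.
#' @return character vector of \code{n} barcodes.
#' @export
synth_barcodes <- function(n, length, mode = c("uniform", "low_complexity"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1L, length >= 1L)
  with_seed(seed, {
    if (mode == "uniform") {
      .rand_seq(n, length)
    } else {
      vapply(seq_len(n), function(i) {
        s <- ""
        while (nchar(s) < length) {
          run <- rgeom(1L, prob = 1 / 3) + 1L  # mean 3
          s <- paste0(s, strrep(sample(.NUC, 1L), run))
        }
        substr(s, 1L, length)
      }, "")
    }
  })
}

#' Generate read pairs with a planted DGE matrix
#'
#' For every (barcode, gene) pair, \code{reads_per_pair} reads are drawn;
#' each read's UMI is sampled uniformly from a per-pair pool of
#' \code{umi_pool_size} distinct UMIs, so the expected distinct-UMI count
#' saturates at the pool size. Read1 carries the CB/UMI at the flavor's
#' positions (other positions random); Read2 is drawn from the gene's
#' planted cDNA sequence plus a 3' poly(A) tail.
#'
#' @param flavor a \code{barcode_flavor} (or preset name/spec string).
#' @param n_barcodes,n_genes numbers of planted barcodes and genes.
#' @param reads_per_pair reads drawn per (barcode, gene) pair.
#' @param umi_pool_size distinct UMIs available per pair (>= 1).
#' @param seed integer seed.
#' @param umi_length UMI length override (default: flavor's UMI span).
#' @return list with \code{pairs} (read-pair table for
#'   \code{\link{extract_tags}}), \code{truth} (per-read \code{cb},
#'   \code{umi}, \code{gene_id}) and \code{expected_counts} (dense planted
#'   barcodes x genes distinct-UMI matrix).
#' @export
synth_reads <- function(flavor, n_barcodes = 4L, n_genes = 3L,
                        reads_per_pair = 10L, umi_pool_size = 100L,
                        seed = 1L, umi_length = NULL) {
  if (!inherits(flavor, "barcode_flavor")) flavor <- parse_flavor(flavor)
  stopifnot(umi_pool_size >= 1L)
  cb_len <- sum(flavor$cb_spec$end - flavor$cb_spec$start + 1L)
  umi_len <- if (is.null(umi_length))
    sum(flavor$umi_spec$end - flavor$umi_spec$start + 1L) else umi_length
  r1_len <- max(c(flavor$cb_spec$end[flavor$cb_spec$read == "R1"],
                  flavor$umi_spec$end[flavor$umi_spec$read == "R1"], 20L))
  r2_min <- max(c(flavor$cb_spec$end[flavor$cb_spec$read == "R2"],
                  flavor$umi_spec$end[flavor$umi_spec$read == "R2"], 0L))
  with_seed(seed, {
    barcodes <- unique(.rand_seq(n_barcodes * 2L, cb_len))[seq_len(n_barcodes)]
    genes <- sprintf("gene%02d", seq_len(n_genes))
    cdna <- setNames(.rand_seq(n_genes, 60L), genes)
    rows <- list(); truth <- list()
    expected <- matrix(0L, n_barcodes, n_genes,
                       dimnames = list(barcodes, genes))
    k <- 0L
    for (b in barcodes) for (g in genes) {
      pool <- unique(.rand_seq(umi_pool_size * 2L, umi_len))
      pool <- pool[seq_len(umi_pool_size)]
      umis <- sample(pool, reads_per_pair, replace = TRUE)
      expected[b, g] <- length(unique(umis))
      for (u in umis) {
        k <- k + 1L
        # random filler, then overwrite the flavor's CB/UMI positions
        r1 <- strsplit(.rand_seq(1L, r1_len), "")[[1]]
        r2 <- strsplit(paste0(substr(cdna[[g]], 1L, 40L), strrep("A", 10L),
                              if (r2_min > 0L) strrep("G", r2_min) else ""),
                       "")[[1]]
        pos <- 1L
        for (i in seq_len(nrow(flavor$cb_spec))) {
          sp <- flavor$cb_spec[i, ]
          seg <- substr(b, pos, pos + sp$end - sp$start)
          tgt <- if (sp$read == "R1") "r1" else "r2"
          assign(tgt, `[<-`(get(tgt), sp$start:sp$end,
                            strsplit(seg, "")[[1]]))
          pos <- pos + sp$end - sp$start + 1L
        }
        pos <- 1L
        for (i in seq_len(nrow(flavor$umi_spec))) {
          sp <- flavor$umi_spec[i, ]
          seg <- substr(u, pos, pos + sp$end - sp$start)
          tgt <- if (sp$read == "R1") "r1" else "r2"
          assign(tgt, `[<-`(get(tgt), sp$start:sp$end,
                            strsplit(seg, "")[[1]]))
          pos <- pos + sp$end - sp$start + 1L
        }
        rows[[k]] <- data.frame(
          name = sprintf("read%06d", k),
          seq1 = paste(r1, collapse = ""),
          qual1 = strrep("I", length(r1)),
          seq2 = paste(r2, collapse = ""),
          qual2 = strrep("I", length(r2)),
          stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(name = sprintf("read%06d", k), cb = b,
                                 umi = u, gene_id = g,
                                 stringsAsFactors = FALSE)
      }
    }
    list(pairs = do.call(rbind, rows), truth = do.call(rbind, truth),
         expected_counts = expected)
  })
}

#' Enumerate multimapper scenarios with expected outcomes
#'
#' Enumerates every multiset of up to \code{max_n} alignments over the four
#' tag classes \{exonicA, exonicB, intronicA, intergenic\} and computes the
#' expected keep/discard outcome by a direct, independent transcription of
#' the counting rule for both counting modes. Single-alignment scenarios
#' are unique reads (always kept).
#'
#' @param max_n maximum alignments per read (default 4).
#' @return data frame: one row per (scenario, counting mode) with columns
#'   \code{scenario} (comma-joined classes), \code{n_aln},
#'   \code{intronic_mode}, \code{expected_keep} (class kept, or \code{NA}
#'   for discard).
#' @export
synth_alignments <- function(max_n = 4L) {
  classes <- c("exonicA", "exonicB", "intronicA", "intergenic")
  out <- list()
  for (n in seq_len(max_n)) {
    combos <- utils::combn(length(classes) + n - 1L, n)  # stars and bars
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j] - seq_len(n) + 1L  # multiset selection
      sc <- classes[idx]
      for (intronic in c(FALSE, TRUE)) {
        cf <- if (intronic) c("EXONIC", "INTRONIC") else "EXONIC"
        # independent rule transcription (not the package implementation):
        countable <- vapply(sc, function(s) switch(
          s, exonicA = "EXONIC" %in% cf, exonicB = "EXONIC" %in% cf,
          intronicA = "INTRONIC" %in% cf, intergenic = FALSE), TRUE)
        inter <- sc == "intergenic"
        keep <- if (n == 1L) sc[1L]
          else if (sum(countable) == 1L && all(inter[!countable]))
            sc[countable] else NA_character_
        out[[length(out) + 1L]] <- data.frame(
          scenario = paste(sc, collapse = ","), n_aln = n,
          intronic_mode = intronic, expected_keep = keep,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Build alignment-table input for one multimapper scenario
#'
#' Materializes a \code{\link{synth_alignments}} scenario as an alignment
#' table plus tag table, ready for \code{\link{resolve_multimappers}}.
#'
#' @param scenario comma-joined class string, e.g.
#'   \code{"exonicA,intergenic"}.
#' @return list with \code{alns} and \code{tags}.
#' @export
scenario_to_alignments <- function(scenario) {
  sc <- strsplit(scenario, ",")[[1]]
  n <- length(sc)
  alns <- do.call(rbind, lapply(seq_len(n), function(i)
    alignment_record("read1", contig = "chr1", strand = "+",
                     blocks = c(1000L * i, 1000L * i + 50L),
                     n_hits = n, is_primary = i == 1L)))
  tags <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(aln = i,
               gene_id = switch(sc[i], exonicA = "geneA",
                                exonicB = "geneB", intronicA = "geneA",
                                intergenic = NA_character_),
               func = switch(sc[i], exonicA = "EXONIC", exonicB = "EXONIC",
                             intronicA = "INTRONIC",
                             intergenic = "INTERGENIC"),
               stringsAsFactors = FALSE)
  }))
  list(alns = alns, tags = tags)
}

#' Generate a hex-lattice puck with planted tissue components
#'
#' Units sit on a regular hexagonal lattice; units inside planted circular
#' blobs get UMI totals above, all others below, a detection threshold.
#'
#' @param nx,ny lattice extent (columns/rows of the pre-duplication grid).
#' @param blobs list of planted components, each
#'   \code{list(cx =, cy =, r =)} in lattice-spacing units.
#' @param umi_high,umi_low UMI totals inside/outside blobs (means of a
#'   Poisson draw).
#' @param spot_distance_um lattice spacing, micrometres.
#' @param seed integer seed.
#' @return list with \code{units} (barcode, x, y, umi_total),
#'   \code{truth} (list of per-blob barcode sets, largest first) and the
#'   generating parameters.
#' @export
synth_puck <- function(nx = 20L, ny = 20L,
                       blobs = list(list(cx = 5, cy = 5, r = 3)),
                       umi_high = 200, umi_low = 5,
                       spot_distance_um = 10, seed = 1L) {
  d <- spot_distance_um
  mesh <- make_mesh(c(0, 0, nx * d, ny * d * sqrt(3) / 2), d,
                    kind = "hexagon")
  centers <- mesh$centers
  with_seed(seed, {
    units <- data.frame(
      barcode = sprintf("BC%05d", seq_len(nrow(centers))),
      x = centers[, 1L], y = centers[, 2L], stringsAsFactors = FALSE)
    member <- lapply(blobs, function(b) {
      which(sqrt((units$x - b$cx * d)^2 + (units$y - b$cy * d)^2) <=
              b$r * d)
    })
    inside <- Reduce(union, member, integer(0))
    outside <- setdiff(seq_len(nrow(units)), inside)
    umi <- stats::rpois(nrow(units), umi_low)
    umi[inside] <- stats::rpois(length(inside), umi_high)
    # planted separation must be strict: clamp degenerate tails
    umi[inside] <- pmax(umi[inside], umi_high %/% 2L + 1L)
    umi[outside] <- pmin(umi[outside], umi_high %/% 2L)
    units$umi_total <- umi
    truth <- lapply(member, function(m) units$barcode[m])
    truth <- truth[order(-vapply(truth, length, 1L))]
    list(units = units, truth = truth, spot_distance_um = d,
         threshold = umi_high %/% 2L)
  })
}

#' Generate long reads with planted signatures
#'
#' Each read is a concatenation of catalog block sequences in the order of
#' its planted signature, with short random spacers between blocks, a
#' random cDNA segment after the poly(T) block (or at the end), and i.i.d.
#' substitutions at \code{sub_rate}. Homopolymer blocks are rendered as
#' 25-nt runs.
#'
#' @param catalog block catalog (\code{\link{block_catalog}}).
#' @param composition named numeric vector: planted signature
#'   (comma-joined block names) -> fraction; fractions must sum to 1.
#' @param n number of reads.
#' @param sub_rate substitution rate in [0, 1).
#' @param seed integer seed.
#' @param cdna_len cDNA segment length (default 80).
#' @return list with \code{reads} (character) and \code{truth} (per-read
#'   planted signature strings).
#' @export
synth_longreads <- function(catalog, composition, n, sub_rate = 0,
                            seed = 1L, cdna_len = 80L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9, n >= 0L)
  counts <- floor(composition * n)
  rem <- n - sum(counts)
  if (rem > 0L)  # deterministic remainder: largest fractions first
    counts[order(-composition)[seq_len(rem)]] <-
      counts[order(-composition)[seq_len(rem)]] + 1L
  with_seed(seed, {
    sigs <- rep(names(counts), counts)
    if (length(sigs) > 1L) sigs <- sample(sigs)
    reads <- vapply(sigs, function(sig) {
      blocks <- strsplit(sig, ",")[[1]]
      parts <- character(0)
      for (b in blocks) {
        sq <- catalog[[b]]
        if (.is_homopolymer(sq)) sq <- strrep(substr(sq, 1L, 1L), 25L)
        parts <- c(parts, sq, .rand_seq(1L, sample(1:3, 1L)))
        if (.is_homopolymer(catalog[[b]]))
          parts <- c(parts, .rand_seq(1L, cdna_len))
      }
      if (!any(vapply(blocks, function(b) .is_homopolymer(catalog[[b]]),
                      TRUE)))
        parts <- c(parts, .rand_seq(1L, cdna_len))
      read <- paste(parts, collapse = "")
      if (sub_rate > 0) {
        ch <- strsplit(read, "")[[1]]
        hit <- stats::runif(length(ch)) < sub_rate
        ch[hit] <- vapply(ch[hit], function(x)
          sample(setdiff(.NUC, x), 1L), "")
        read <- paste(ch, collapse = "")
      }
      read
    }, "", USE.NAMES = FALSE)
    list(reads = reads, truth = sigs)
  })
}

#' Generate a registered image pair with planted placement
#'
#' The template is a binary blob raster (tissue on background); the
#' reference embeds the template resized by the planted x/y scales at the
#' planted offset, on a clean background, with optional salt-and-pepper
#' noise. Unit positions are placed inside the blob in template
#' coordinates.
#'
#' @param ref_dim reference size \code{c(rows, cols)}.
#' @param tmpl_dim template size \code{c(rows, cols)}.
#' @param placement planted placement: list with \code{x_offset},
#'   \code{y_offset} (0-based px), \code{x_scale}, \code{y_scale}.
#' @param noise fraction of reference pixels flipped (default 0).
#' @param n_units number of units placed inside the blob.
#' @param seed integer seed.
#' @return list with \code{reference}, \code{template} (binary matrices),
#'   \code{units} (template-pixel coordinates) and \code{placement}.
#' @export
synth_image_pair <- function(ref_dim = c(96L, 96L), tmpl_dim = c(48L, 48L),
                             placement = list(x_offset = 20L,
                                              y_offset = 12L,
                                              x_scale = 1, y_scale = 1),
                             noise = 0, n_units = 50L, seed = 1L) {
  with_seed(seed, {
    th <- tmpl_dim[1L]; tw <- tmpl_dim[2L]
    # irregular blob: union of a few disks around the center
    template <- matrix(0, th, tw)
    yy <- row(template); xx <- col(template)
    n_disks <- 4L
    cys <- th / 2 + stats::runif(n_disks, -th / 6, th / 6)
    cxs <- tw / 2 + stats::runif(n_disks, -tw / 6, tw / 6)
    rs <- stats::runif(n_disks, th / 6, th / 3.2)
    for (k in seq_len(n_disks))
      template[(yy - cys[k])^2 + (xx - cxs[k])^2 <= rs[k]^2] <- 1
    sh <- max(2L, round(placement$y_scale * th))
    sw <- max(2L, round(placement$x_scale * tw))
    scaled <- EBImage::resize(template, w = sh, h = sw)
    scaled <- (scaled >= 0.5) * 1
    reference <- matrix(0, ref_dim[1L], ref_dim[2L])
    y0 <- placement$y_offset; x0 <- placement$x_offset
    stopifnot(y0 + sh <= ref_dim[1L], x0 + sw <= ref_dim[2L])
    reference[y0 + seq_len(sh), x0 + seq_len(sw)] <- scaled
    if (noise > 0) {
      flip <- stats::runif(length(reference)) < noise
      reference[flip] <- 1 - reference[flip]
    }
    fg <- which(template == 1, arr.ind = TRUE)
    pick <- fg[sample(nrow(fg), min(n_units, nrow(fg))), , drop = FALSE]
    units <- data.frame(barcode = sprintf("U%04d", seq_len(nrow(pick))),
                        px_x = pick[, 2L], px_y = pick[, 1L],
                        stringsAsFactors = FALSE)
    list(reference = reference, template = template, units = units,
         placement = placement)
  })
}
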