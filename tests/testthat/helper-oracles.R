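# Independent oracles used across tests. These re-derive expected results
# by brute force / direct transcription and never call the code paths they
# check.

# Naive affine-gap local-alignment DP (Smith-Waterman with gotoh matrices).
# A gap of length L costs |gap_open| + L * |gap_extend|, matching the
# package's scoring convention. Returns only the optimal score.
naive_sw_score <- function(a, b, match = 2, mismatch = -2,
                           gap_open = -3, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  open <- -gap_open; ext <- -gap_extend
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consume b)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (consume a)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      E[i + 1L, j + 1L] <- max(E[i + 1L, j] - ext,
                               H[i + 1L, j] - open - ext)
      F[i + 1L, j + 1L] <- max(F[i, j + 1L] - ext,
                               H[i, j + 1L] - open - ext)
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s,
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Brute-force largest connected component among points with adjacency
# dist <= radius; returns indices of the winning component (ties: summed
# weight, then smallest label).
brute_largest_component <- function(x, y, radius, weight = NULL,
                                    label = NULL) {
  n <- length(x)
  if (is.null(weight)) weight <- rep(1, n)
  if (is.null(label)) label <- as.character(seq_len(n))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      d <- sqrt((x - x[v])^2 + (y - y[v])^2)
      queue <- c(queue, which(d <= radius & comp == 0L))
    }
  }
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    wsum <- vapply(best, function(k) sum(weight[comp == k]), 0)
    best <- best[wsum == max(wsum)]
    if (length(best) > 1L) {
      mins <- vapply(best, function(k) min(label[comp == k]), "")
      best <- best[which.min(mins)]
    }
  }
  which(comp == best[1L])
}

# Small two-gene annotation used by several tagcount tests: geneA (+) at
# 1-1000 with exons 1-100 and 301-400; geneB (+) at 350-2000 with exon
# 350-450 (overlaps geneA); geneC (-) at 3000-4000 with exon 3000-3100.
toy_annotation <- function() {
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(
      start = c(1, 1, 301, 350, 350, 3000, 3000),
      end = c(1000, 100, 400, 2000, 450, 4000, 3100)),
    strand = c("+", "+", "+", "+", "+", "-", "-"),
    type = c("gene", "exon", "exon", "gene", "exon", "gene", "exon"),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB",
                "geneC", "geneC"))
  build_annotation_index(gr)
}

toy_catalog <- function() {
  block_catalog(c(
    P5 = "AATGATACGGCGACCACCGAGATCTACAC",
    bead_start = "GCCGGTAATACGTAGCGCTGACTGCATT",
    TSO = "AAGCAGTGGTATCAACGCAGAGTGAATGGG",
    polyT = strrep("T", 20),
    N70X = "CAAGCAGAAGACGGCATACGAGAT"))
}
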