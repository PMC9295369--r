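test_that("annotation index answers containment, intron and intergenic queries", {
  idx <- toy_annotation()
  expect_equal(tag_alignment("chr1", "+", c(50, 60), idx),
               data.frame(gene_id = "geneA", func = "EXONIC"),
               ignore_attr = TRUE)
  expect_equal(tag_alignment("chr1", "+", c(500, 510), idx)$func,
               c("INTRONIC", "INTRONIC"))  # inside geneA and geneB introns
  expect_equal(tag_alignment("chr1", "+", c(150, 200), idx),
               data.frame(gene_id = "geneA", func = "INTRONIC"),
               ignore_attr = TRUE)
  expect_equal(tag_alignment("chr1", "+", c(5000, 5010), idx)$func,
               "INTERGENIC")
  expect_equal(tag_alignment("chrX", "+", c(50, 60), idx)$func,
               "INTERGENIC")
  # strandedness: geneC is minus-strand
  expect_equal(tag_alignment("chr1", "+", c(3050, 3060), idx)$func,
               "INTERGENIC")
  expect_equal(tag_alignment("chr1", "-", c(3050, 3060), idx),
               data.frame(gene_id = "geneC", func = "EXONIC"),
               ignore_attr = TRUE)
  # overlapping genes: both tagged exonic
  both <- tag_alignment("chr1", "+", c(360, 390), idx)
  expect_setequal(paste(both$gene_id, both$func),
                  c("geneA EXONIC", "geneB EXONIC"))
})

test_that("exon outside its gene span is rejected at index build", {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 2000), c(1000, 2100)),
    strand = "+", type = c("gene", "exon"),
    gene_id = c("geneA", "geneA"))
  expect_error(build_annotation_index(gr), "geneA")
})

test_that("gene tagging agrees with a brute-force interval scan", {
  idx <- toy_annotation()
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    start = c(1, 350, 3000), end = c(1000, 2000, 4000),
    strand = c("+", "+", "-"))
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneC"),
    start = c(1, 301, 350, 3000), end = c(100, 400, 450, 3100))
  brute <- function(strand, s, e) {
    hit <- genes[genes$strand == strand & genes$start <= e &
                   genes$end >= s, ]
    if (nrow(hit) == 0L) return("INTERGENIC")
    fn <- vapply(hit$gene_id, function(g) {
      ex <- exons[exons$gene_id == g, ]
      if (any(ex$start <= e & ex$end >= s)) "EXONIC" else "INTRONIC"
    }, "")
    paste(hit$gene_id, fn, collapse = ";")
  }
  set.seed(99)
  for (i in 1:60) {
    s <- sample(1:4500, 1); e <- s + sample(5:120, 1)
    strand <- sample(c("+", "-"), 1)
    got <- tag_alignment("chr1", strand, c(s, e), idx)
    want <- brute(strand, s, e)
    gotkey <- if (all(got$func == "INTERGENIC")) "INTERGENIC" else
      paste(got$gene_id, got$func, collapse = ";")
    expect_equal(gotkey, want, label = sprintf("query %d-%d %s", s, e, strand))
  }
})

test_that("multimapper resolution matches the enumerated oracle exactly", {
  grid <- synth_alignments(max_n = 4L)
  for (k in seq_len(nrow(grid))) {
    sc <- scenario_to_alignments(grid$scenario[k])
    cf <- if (grid$intronic_mode[k]) c("EXONIC", "INTRONIC") else "EXONIC"
    kept <- resolve_multimappers(sc$alns, sc$tags, cf)
    if (is.na(grid$expected_keep[k])) {
      expect_null(kept, label = paste(grid$scenario[k],
                                      "intronic =", grid$intronic_mode[k]))
    } else {
      expect_false(is.null(kept),
                   label = paste(grid$scenario[k],
                                 "intronic =", grid$intronic_mode[k]))
      idx <- which(strsplit(grid$scenario[k], ",")[[1]] ==
                     grid$expected_keep[k])[1]
      expect_equal(kept$blocks[[1]][1, 1], 1000L * idx)
      expect_true(kept$is_primary)
    }
  }
})

test_that("kept multimappers follow the headline keep/discard examples", {
  sc <- scenario_to_alignments("exonicA,intergenic,intergenic")
  expect_equal(resolve_multimappers(sc$alns, sc$tags)$read_name, "read1")
  sc2 <- scenario_to_alignments("exonicA,exonicB")
  expect_null(resolve_multimappers(sc2$alns, sc2$tags))
  # a unique intergenic alignment passes through unchanged
  un <- alignment_record("u1", "chr1", "+", c(5000, 5050), n_hits = 1L)
  tg <- data.frame(aln = 1L, gene_id = NA_character_, func = "INTERGENIC")
  expect_equal(resolve_multimappers(un, tg)$read_name, "u1")
  # one alignment hitting two genes discards the read
  two <- scenario_to_alignments("exonicA,intergenic")
  two$tags <- rbind(two$tags,
                    data.frame(aln = 1L, gene_id = "geneB", func = "EXONIC"))
  expect_null(resolve_multimappers(two$alns, two$tags))
  expect_error(resolve_multimappers(
    rbind(alignment_record("a", "chr1", "+", c(1, 2), n_hits = 2),
          alignment_record("b", "chr1", "+", c(1, 2), n_hits = 2)),
    data.frame(aln = 1:2, gene_id = "geneA", func = "EXONIC")),
    "one read_name")
})

test_that("barcode selection ranks by reads with lexicographic ties", {
  expect_equal(select_barcodes(c(B1 = 10, B2 = 5, B3 = 1), n_beads = 2),
               c("B1", "B2"))
  expect_equal(select_barcodes(c(B3 = 5, B1 = 5, B2 = 5), n_beads = 2),
               c("B1", "B2"))
  # oracle: sort by (-count, barcode)
  set.seed(3)
  counts <- setNames(sample(1:5, 20, TRUE),
                     paste0("B", sample(100:999, 20)))
  want <- names(counts)[order(-counts, names(counts))][1:7]
  expect_equal(select_barcodes(counts, n_beads = 7), want)
  # whitelist wins regardless of counts
  expect_equal(select_barcodes(counts, whitelist = c("W1", "W2")),
               c("W1", "W2"))
  expect_warning(out <- select_barcodes(integer(0), n_beads = 5), "empty")
  expect_length(out, 0)
})

test_that("primer-contaminated barcodes are removed with reasons", {
  primers <- c("ACGTTTTTTT", "GGAAGGCCTGG")
  res <- clean_barcodes(c("TTTTGGACGT", "TTAAGGCCTTA", "CATCATCATCA"),
                        primers)
  expect_equal(res$kept, "CATCATCATCA")
  expect_equal(res$removed$reason[res$removed$barcode == "TTTTGGACGT"],
               "3prime_overlap(4)")
  expect_equal(res$removed$reason[res$removed$barcode == "TTAAGGCCTTA"],
               "internal_overlap(7)")
})

test_that("DGE counts are distinct UMIs per (barcode, gene)", {
  stream <- data.frame(
    cb = c("B1", "B1", "B1", "B1", "B2"),
    umi = c("U1", "U1", "U2", "U9", "U1"),
    gene_id = c("g1", "g1", "g1", NA, "g2"),
    func = c("EXONIC", "EXONIC", "EXONIC", "INTERGENIC", "INTRONIC"))
  rm_ex <- run_mode(count_intronic_reads = FALSE)
  dge <- count_dge(stream, c("B1", "B2"), rm_ex)
  expect_equal(as.numeric(dge$counts["B1", "g1"]), 2)  # U1 deduplicated
  expect_equal(sum(dge$counts["B2", ]), 0)  # intronic not countable
  expect_equal(unname(dge$reads), c(4L, 1L))  # intergenic counts as a read
  rm_in <- run_mode(count_intronic_reads = TRUE)
  dge2 <- count_dge(stream, c("B1", "B2"), rm_in)
  expect_equal(as.numeric(dge2$counts["B2", "g2"]), 1)
  # intronic counting never decreases any entry
  shared <- intersect(colnames(dge$counts), colnames(dge2$counts))
  expect_true(all(dge2$counts[, shared] >= dge$counts[, shared]))
  # unknown barcodes are filtered, not fatal
  dge3 <- count_dge(stream, "B1", rm_ex)
  expect_equal(attr(dge3, "n_filtered"), 1L)
  # analysis-ready view applies the UMI cutoff
  expect_equal(rownames(filter_dge(dge, 1)$counts), "B1")
})

test_that("planted-truth DGE is recovered exactly from synthetic reads", {
  flavor <- parse_flavor("visium")
  syn <- synth_reads(flavor, n_barcodes = 50, n_genes = 20,
                     reads_per_pair = 6, umi_pool_size = 50, seed = 101)
  tagged <- extract_tags(syn$pairs, flavor)
  expect_false(any(tagged$dropped))
  # tag extraction recovers the planted CB/UMI for every read
  expect_equal(tagged$cb, syn$truth$cb)
  expect_equal(tagged$umi, syn$truth$umi)
  stream <- data.frame(cb = tagged$cb, umi = tagged$umi,
                       gene_id = syn$truth$gene_id, func = "EXONIC")
  dge <- count_dge(stream, rownames(syn$expected_counts))
  expect_equal(as.matrix(dge$counts)[rownames(syn$expected_counts),
                                     colnames(syn$expected_counts)],
               syn$expected_counts, ignore_attr = TRUE)
})

test_that("saturating UMI pools cap the counts at the pool size", {
  flavor <- parse_flavor("cb=R1[1-8]; umi=R1[9-16]")
  syn <- synth_reads(flavor, n_barcodes = 2, n_genes = 2,
                     reads_per_pair = 500, umi_pool_size = 5, seed = 5)
  expect_true(all(syn$expected_counts == 5))
})

test_that("replicate merging has set-union semantics", {
  s1 <- data.frame(cb = "B1", umi = c("U1", "U2"), gene_id = "g1")
  s2 <- data.frame(cb = "B1", umi = c("U2", "U3"), gene_id = "g1")
  m <- merge_replicates(s1, s2)
  expect_equal(as.numeric(m$counts["B1", "g1"]), 3)  # union {U1,U2,U3}
  # idempotence
  mi <- merge_replicates(s1, s1)
  expect_equal(as.numeric(mi$counts["B1", "g1"]), 2)
  # commutativity
  m21 <- merge_replicates(s2, s1)
  expect_equal(as.matrix(m$counts), as.matrix(m21$counts))
  # disjoint UMIs add
  d <- merge_replicates(data.frame(cb = "B", umi = "U1", gene_id = "g"),
                        data.frame(cb = "B", umi = "U2", gene_id = "g"))
  expect_equal(sum(d$counts), 2)
  expect_error(merge_replicates(s1, s2,
                                gene_universes = list("g1", c("g1", "g2"))),
               "g2")
})

test_that("a random split merged back equals the unsplit matrix", {
  flavor <- parse_flavor("visium")
  syn <- synth_reads(flavor, n_barcodes = 10, n_genes = 5,
                     reads_per_pair = 8, umi_pool_size = 20, seed = 77)
  stream <- data.frame(cb = syn$truth$cb, umi = syn$truth$umi,
                       gene_id = syn$truth$gene_id)
  set.seed(8)
  half <- sample(nrow(stream), nrow(stream) %/% 2)
  merged <- merge_replicates(stream[half, ], stream[-half, ])
  whole <- merge_replicates(stream)
  expect_equal(as.matrix(merged$counts), as.matrix(whole$counts))
})

test_that("downsampling gives exact floor sizes and nested subsets", {
  ds <- downsample_alignments(100L, seed = 4)
  expect_equal(unname(lengths(ds)), seq(10L, 90L, 10L))
  ds2 <- downsample_alignments(997L, ratios = c(0.1, 0.25, 0.5), seed = 4)
  expect_equal(unname(lengths(ds2)), floor(c(0.1, 0.25, 0.5) * 997))
  for (i in seq_len(length(ds) - 1L))
    expect_true(all(ds[[i]] %in% ds[[i + 1L]]))
  # same seed reproduces; ratios outside (0,1) rejected
  expect_identical(ds, downsample_alignments(100L, seed = 4))
  expect_error(downsample_alignments(10L, ratios = c(0.5, 1)), "ratios")
})

test_that("per-barcode UMI totals are non-decreasing in the ratio", {
  flavor <- parse_flavor("visium")
  syn <- synth_reads(flavor, n_barcodes = 8, n_genes = 4,
                     reads_per_pair = 10, umi_pool_size = 15, seed = 13)
  stream <- data.frame(cb = syn$truth$cb, umi = syn$truth$umi,
                       gene_id = syn$truth$gene_id, func = "EXONIC")
  bcs <- rownames(syn$expected_counts)
  subsets <- downsample_alignments(stream, seed = 21)
  prev <- NULL
  for (r in names(subsets)) {
    umis <- Matrix::rowSums(count_dge(subsets[[r]], bcs)$counts)
    if (!is.null(prev)) expect_true(all(umis >= prev))
    prev <- umis
  }
})

test_that("saturation table reports medians over the full barcode set", {
  flavor <- parse_flavor("visium")
  syn <- synth_reads(flavor, n_barcodes = 9, n_genes = 4,
                     reads_per_pair = 12, umi_pool_size = 6, seed = 31)
  stream <- data.frame(cb = syn$truth$cb, umi = syn$truth$umi,
                       gene_id = syn$truth$gene_id, func = "EXONIC")
  bcs <- rownames(syn$expected_counts)
  full <- count_dge(stream, bcs)
  per <- lapply(downsample_alignments(stream, ratios = c(0.2, 0.6),
                                      seed = 2),
                count_dge, barcodes = bcs)
  per[["1"]] <- full
  tab <- saturation_table(per, full)
  r1 <- tab[tab$ratio == 1, ]
  expect_equal(r1$median_umis, median(Matrix::rowSums(full$counts)))
  expect_equal(r1$median_reads, median(as.numeric(full$reads)))
  expect_equal(r1$median_genes, median(Matrix::rowSums(full$counts > 0)))
  expect_true(all(diff(tab$median_umis[order(tab$ratio)]) >= 0))
  expect_s3_class(attr(tab, "histograms"), "data.frame")
})

test_that("a saturating library plateaus in UMIs while reads grow", {
  flavor <- parse_flavor("cb=R1[1-8]; umi=R1[9-16]")
  syn <- synth_reads(flavor, n_barcodes = 6, n_genes = 3,
                     reads_per_pair = 300, umi_pool_size = 4, seed = 55)
  stream <- data.frame(cb = syn$truth$cb, umi = syn$truth$umi,
                       gene_id = syn$truth$gene_id, func = "EXONIC")
  bcs <- rownames(syn$expected_counts)
  full <- count_dge(stream, bcs)
  per <- lapply(downsample_alignments(stream, seed = 9),
                count_dge, barcodes = bcs)
  per[["1"]] <- full
  tab <- saturation_table(per, full)
  tab <- tab[order(tab$ratio), ]
  # reads grow linearly with depth ...
  expect_gt(tail(tab$median_reads, 1) / tab$median_reads[1], 8)
  # ... while distinct UMIs saturate at the pool long before full depth
  expect_equal(tab$median_umis[tab$ratio >= 0.5],
               rep(tab$median_umis[nrow(tab)], sum(tab$ratio >= 0.5)))
})

test_that("DGE matrices round-trip through MatrixMarket output", {
  stream <- data.frame(cb = c("B1", "B2"), umi = c("U1", "U2"),
                       gene_id = c("g1", "g2"), func = "EXONIC")
  dge <- count_dge(stream, c("B1", "B2"))
  dir <- tempfile()
  write_dge_mtx(dge, dir)
  expect_setequal(list.files(dir),
                  c("matrix.mtx", "barcodes.tsv", "genes.tsv"))
  back <- read_dge_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(dge$counts))
})
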