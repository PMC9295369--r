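test_that("mesh geometry: sqrt(3) row spacing and exact nearest-neighbor distance", {
  d <- 10
  mesh <- make_mesh(c(0, 0, 100, 100), d)
  xs <- sort(unique(mesh$centers[, 1]))
  ys <- sort(unique(mesh$centers[, 2]))
  # pre-duplication lattice: columns every d, rows every sqrt(3)*d; the
  # shifted copy interleaves at half offsets
  expect_equal(min(diff(xs)), d / 2, tolerance = 1e-12)
  expect_equal(min(diff(ys)), sqrt(3) / 2 * d, tolerance = 1e-12)
  dm <- as.matrix(dist(mesh$centers))
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  expect_true(all(abs(nn - d) < 1e-9))
})

test_that("interior mesh centers have exactly six equidistant neighbors", {
  d <- 7
  mesh <- make_mesh(c(0, 0, 20 * d, 20 * d), d)
  ctr <- mesh$centers
  dm <- as.matrix(dist(ctr))
  diag(dm) <- Inf
  interior <- ctr[, 1] > min(ctr[, 1]) + 2 * d &
    ctr[, 1] < max(ctr[, 1]) - 2 * d &
    ctr[, 2] > min(ctr[, 2]) + 2 * d &
    ctr[, 2] < max(ctr[, 2]) - 2 * d
  expect_gt(sum(interior), 50)
  n6 <- vapply(which(interior), function(i)
    sum(abs(dm[i, ] - d) < 1e-9), 0L)
  expect_true(all(n6 == 6L))
})

test_that("hexagon assignment equals brute-force nearest-center search", {
  set.seed(12)
  mesh <- make_mesh(c(0, 0, 60, 60), 10)
  units <- data.frame(barcode = sprintf("B%03d", 1:80),
                      x = runif(80, 0, 60), y = runif(80, 0, 60))
  asg <- assign_to_mesh(units, mesh)
  for (i in seq_len(nrow(units))) {
    d2 <- (mesh$centers[, 1] - units$x[i])^2 +
      (mesh$centers[, 2] - units$y[i])^2
    expect_equal(asg$center[i], which.min(d2))
  }
  # determinism under permutation of the input order
  perm <- sample(nrow(units))
  asg2 <- assign_to_mesh(units[perm, ], mesh)
  expect_equal(asg2$center[order(perm)], asg$center)
})

test_that("circle assignment honors the capture radius", {
  mesh <- make_mesh(c(0, 0, 300, 300), 100, kind = "circle",
                    spot_diameter_um = 55)
  at_center <- data.frame(barcode = "Bc", x = mesh$centers[10, 1],
                          y = mesh$centers[10, 2])
  expect_equal(assign_to_mesh(at_center, mesh)$center, 10L)
  # 30 um from the nearest center is outside a 55-um-diameter circle
  off <- data.frame(barcode = "Bo", x = mesh$centers[10, 1] + 30,
                    y = mesh$centers[10, 2])
  expect_true(is.na(assign_to_mesh(off, mesh)$center))
  inside <- data.frame(barcode = "Bi", x = mesh$centers[10, 1] + 20,
                       y = mesh$centers[10, 2])
  expect_equal(assign_to_mesh(inside, mesh)$center, 10L)
})

test_that("hexagonal aggregation conserves the grand total exactly", {
  set.seed(66)
  for (rep in 1:5) {
    n <- 40
    units <- data.frame(barcode = sprintf("B%03d", 1:n),
                        x = runif(n, 0, 80), y = runif(n, 0, 80))
    counts <- Matrix::rsparsematrix(n, 12, density = 0.3,
                                    rand.x = function(k) rpois(k, 3) + 1)
    rownames(counts) <- units$barcode
    colnames(counts) <- sprintf("g%02d", 1:12)
    dge <- structure(list(counts = abs(counts),
                          reads = setNames(rep(5L, n), units$barcode)),
                     class = "dge_matrix")
    mesh <- make_mesh(c(0, 0, 80, 80), 15)
    agg <- aggregate_counts(dge, assign_to_mesh(units, mesh))
    expect_identical(sum(agg$counts), sum(dge$counts))
    expect_identical(sum(agg$reads), sum(dge$reads))
  }
})

test_that("two units in one hexagon sum elementwise; missing units error", {
  units <- data.frame(barcode = c("B1", "B2"), x = c(10, 11), y = c(10, 10.5))
  mesh <- make_mesh(c(0, 0, 50, 50), 20)
  counts <- Matrix::Matrix(matrix(c(3, 4), 2, 1,
                                  dimnames = list(c("B1", "B2"), "gX")),
                           sparse = TRUE)
  dge <- structure(list(counts = counts,
                        reads = c(B1 = 5L, B2 = 6L)), class = "dge_matrix")
  asg <- assign_to_mesh(units, mesh)
  expect_equal(asg$center[1], asg$center[2])
  agg <- aggregate_counts(dge, asg)
  expect_equal(sum(agg$counts[, "gX"]), 7)
  bad <- rbind(asg, data.frame(barcode = "B9", center = 1L, dist = 0))
  expect_error(aggregate_counts(dge, bad), "B9")
})

test_that("circle aggregation can drop out-of-circle units", {
  mesh <- make_mesh(c(0, 0, 300, 300), 100, kind = "circle",
                    spot_diameter_um = 10)
  units <- data.frame(barcode = "B1",
                      x = mesh$centers[5, 1] + 40, y = mesh$centers[5, 2])
  counts <- Matrix::Matrix(matrix(3, 1, 1, dimnames = list("B1", "g")),
                           sparse = TRUE)
  dge <- structure(list(counts = counts, reads = c(B1 = 3L)),
                   class = "dge_matrix")
  asg <- assign_to_mesh(units, mesh)
  expect_warning(agg <- aggregate_counts(dge, asg), "no units")
  expect_equal(nrow(agg$counts), 0L)
})

test_that("tissue detection returns the largest planted component", {
  pk <- synth_puck(nx = 20, ny = 20,
                   blobs = list(list(cx = 6, cy = 5, r = 3.2),
                                list(cx = 16, cy = 12, r = 1.1)),
                   seed = 17)
  big <- pk$truth[[1]]; small <- pk$truth[[2]]
  expect_gt(length(big), length(small))
  found <- detect_tissue(pk$units, pk$threshold, grid = "regular_hex")
  expect_setequal(found, big)
  # threshold above the global maximum: empty with a warning
  expect_warning(
    none <- detect_tissue(pk$units, max(pk$units$umi_total) + 1,
                          grid = "regular_hex"), "threshold")
  expect_length(none, 0)
  # all units above threshold in one component: all returned
  all_on <- pk$units; all_on$umi_total <- 100
  expect_setequal(detect_tissue(all_on, 1, grid = "regular_hex"),
                  all_on$barcode)
})

test_that("tissue detection equals brute-force flood fill on random grids", {
  set.seed(23)
  for (rep in 1:12) {
    pk <- synth_puck(nx = 20, ny = 20,
                     blobs = list(list(cx = runif(1, 3, 8),
                                       cy = runif(1, 3, 8),
                                       r = runif(1, 1.5, 3)),
                                  list(cx = runif(1, 12, 17),
                                       cy = runif(1, 10, 14),
                                       r = runif(1, 0.8, 2.5))),
                     seed = 1000 + rep)
    units <- pk$units
    found <- detect_tissue(units, pk$threshold, grid = "regular_hex")
    cand <- units[units$umi_total > pk$threshold, ]
    dm <- as.matrix(dist(cbind(units$x, units$y)))
    dm <- dm[dm > 1e-9]
    want <- cand$barcode[brute_largest_component(
      cand$x, cand$y, 1.3 * min(dm), cand$umi_total, cand$barcode)]
    expect_setequal(found, want)
    # the detected set is connected under the declared adjacency
    sub <- cand[cand$barcode %in% found, ]
    expect_setequal(
      sub$barcode[brute_largest_component(sub$x, sub$y, 1.3 * min(dm))],
      found)
  }
})

test_that("irregular grids are detected through an intermediate mesh", {
  pk <- synth_puck(nx = 15, ny = 15,
                   blobs = list(list(cx = 5, cy = 5, r = 2.5)), seed = 41)
  units <- pk$units
  set.seed(42)  # jitter units off the lattice
  units$x <- units$x + runif(nrow(units), -1, 1)
  units$y <- units$y + runif(nrow(units), -1, 1)
  found <- detect_tissue(units, pk$threshold, grid = "irregular",
                         spot_distance_um = pk$spot_distance_um)
  expect_setequal(found, pk$truth[[1]])
})
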