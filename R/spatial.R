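# ---------------------------------------------------------------------------
# In-silico meshes over a puck, aggregation of spatial units onto them, and
# tissue detection as the largest contiguous high-UMI region. Distances are
# Euclidean in micrometres; no unit conversion is attempted.
# ---------------------------------------------------------------------------

#' Build a triangular (hex-neighborhood) mesh over a bounding box
#'
#' A rectangular lattice with column spacing \code{d = spot_distance_um} and
#' row spacing \code{sqrt(3) * d} is unioned with a copy translated by
#' \code{(d/2, sqrt(3)/2 * d)}; in the resulting lattice every interior
#' center has six equidistant neighbors at exactly \code{d}. The mesh is
#' anchored at the lower-left corner of the bounding box and extends one
#' spacing beyond it so border units remain assignable. The \code{"circle"}
#' kind places Visium-style capture circles of \code{spot_diameter_um} at
#' the centers; the \code{"hexagon"} kind tiles space with the centers'
#' Voronoi cells (hexagons), leaving no holes.
#'
#' @param bbox numeric \code{c(xmin, ymin, xmax, ymax)} in micrometres.
#' @param spot_distance_um center-to-center distance (> 0).
#' @param kind \code{"hexagon"} or \code{"circle"}.
#' @param spot_diameter_um circle diameter (required for \code{"circle"}).
#' @return a \code{mesh_grid}: list with \code{kind}, \code{spot_distance_um},
#'   \code{spot_diameter_um} and \code{centers} (matrix, columns x, y).
#' @export
make_mesh <- function(bbox, spot_distance_um,
                      kind = c("hexagon", "circle"),
                      spot_diameter_um = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(bbox) == 4L, spot_distance_um > 0)
  xmin <- bbox[1L]; ymin <- bbox[2L]; xmax <- bbox[3L]; ymax <- bbox[4L]
  if (!(xmax > xmin) || !(ymax > ymin))
    stop("degenerate bounding box")
  if (kind == "circle" && is.null(spot_diameter_um))
    stop("circle meshes need spot_diameter_um")
  d <- spot_distance_um
  dy <- sqrt(3) * d
  xs <- seq(xmin - d, xmax + d, by = d)
  ys <- seq(ymin - dy, ymax + dy, by = dy)
  base <- cbind(x = rep(xs, times = length(ys)),
                y = rep(ys, each = length(xs)))
  shifted <- cbind(x = base[, 1L] + d / 2, y = base[, 2L] + dy / 2)
  centers <- rbind(base, shifted)
  # deterministic ordering: row-major, lower-left first
  centers <- centers[order(centers[, 2L], centers[, 1L]), , drop = FALSE]
  rownames(centers) <- NULL
  structure(list(kind = kind, spot_distance_um = d,
                 spot_diameter_um = spot_diameter_um, centers = centers),
            class = "mesh_grid")
}

#' @export
print.mesh_grid <- function(x, ...) {
  cat("<mesh_grid>", x$kind, "|", nrow(x$centers), "centers | spacing",
      x$spot_distance_um, "um\n")
  invisible(x)
}

# nearest-center index and distance for each unit; ties to lowest index
.nearest_center <- function(units, centers, chunk = 2048L) {
  n <- nrow(units)
  idx <- integer(n); dist <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(units$x[s:e], centers[, 1L], `-`)
    dy <- outer(units$y[s:e], centers[, 2L], `-`)
    d2 <- dx * dx + dy * dy
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  list(index = idx, dist = dist)
}

#' Assign spatial units to mesh centers
#'
#' Hexagon kind: every unit is assigned to its nearest center (the Voronoi
#' hexagon it falls in), ties to the lowest center index. Circle kind: a
#' unit is assigned only if its distance to the nearest center is at most
#' \code{spot_diameter_um / 2}; units outside every circle stay unassigned
#' (\code{NA}).
#'
#' @param units data frame with columns \code{barcode}, \code{x}, \code{y}.
#' @param mesh a \code{mesh_grid}.
#' @return data frame \code{barcode}, \code{center} (index into
#'   \code{mesh$centers}, \code{NA} if unassigned), \code{dist}.
#' @export
assign_to_mesh <- function(units, mesh) {
  stopifnot(inherits(mesh, "mesh_grid"),
            all(c("barcode", "x", "y") %in% names(units)))
  if (nrow(units) == 0L)
    return(data.frame(barcode = character(), center = integer(),
                      dist = numeric(), stringsAsFactors = FALSE))
  nn <- .nearest_center(units, mesh$centers)
  center <- nn$index
  if (mesh$kind == "circle") {
    outside <- nn$dist > mesh$spot_diameter_um / 2
    center[outside] <- NA_integer_
  }
  data.frame(barcode = units$barcode, center = center, dist = nn$dist,
             stringsAsFactors = FALSE)
}

#' Aggregate a DGE matrix onto mesh cells
#'
#' Counts of all units assigned to the same mesh cell are summed
#' elementwise. Hexagon meshes assign every unit, so the grand total is
#' conserved exactly; circle meshes may leave units unassigned, so the
#' aggregated total can only be smaller.
#'
#' @param dge a \code{dge_matrix} (or a plain barcodes x genes matrix).
#' @param assignment data frame from \code{\link{assign_to_mesh}}.
#' @return a \code{dge_matrix} whose rows are mesh cells
#'   (\code{"mesh_<index>"}).
#' @export
aggregate_counts <- function(dge, assignment) {
  counts <- if (inherits(dge, "dge_matrix")) dge$counts else dge
  reads <- if (inherits(dge, "dge_matrix")) dge$reads
    else setNames(integer(nrow(counts)), rownames(counts))
  assigned <- assignment[!is.na(assignment$center), , drop = FALSE]
  missing <- setdiff(assigned$barcode, rownames(counts))
  if (length(missing) > 0L)
    stop("assigned units missing from matrix: ",
         paste(missing, collapse = ", "))
  if (nrow(assigned) == 0L) {
    warning("no units assigned to any mesh cell; empty aggregate")
    empty <- counts[integer(0), , drop = FALSE]
    return(.new_dge(empty, integer(0)))
  }
  sub <- counts[assigned$barcode, , drop = FALSE]
  grp <- factor(paste0("mesh_", assigned$center),
                levels = paste0("mesh_", sort(unique(assigned$center))))
  agg <- rowsum(as.matrix(sub), group = grp)
  agg <- agg[levels(grp), , drop = FALSE]
  r <- tapply(reads[assigned$barcode], grp, sum, default = 0L)
  .new_dge(methods::as(Matrix::Matrix(agg, sparse = TRUE), "CsparseMatrix"),
           setNames(as.integer(r), levels(grp)))
}

#' Detect the under-tissue region
#'
#' Units with UMI totals strictly above \code{umi_threshold} are candidate
#' tissue units. On regular hexagonal arrays, two candidates are adjacent
#' when their distance is at most 1.3 times the minimum center distance of
#' the array (the six hex neighbors, but not the next ring at sqrt(3)).
#' On irregular arrays the candidates are first mapped onto a hexagonal
#' mesh and adjacency is between neighboring mesh cells. The largest
#' connected component is returned; ties go to the component with the
#' greater summed UMIs, then to the one containing the lexicographically
#' smallest barcode.
#'
#' @param units data frame with columns \code{barcode}, \code{x}, \code{y},
#'   \code{umi_total}.
#' @param umi_threshold candidate threshold (>= 0), exclusive.
#' @param grid \code{"regular_hex"} or \code{"irregular"}.
#' @param spot_distance_um mesh spacing for \code{"irregular"} grids.
#' @param adjacency_factor multiple of the minimum center distance within
#'   which two units count as neighbors (default 1.3).
#' @return character vector of under-tissue barcodes (possibly empty).
#' @export
detect_tissue <- function(units, umi_threshold,
                          grid = c("regular_hex", "irregular"),
                          spot_distance_um = NULL,
                          adjacency_factor = 1.3) {
  grid <- match.arg(grid)
  stopifnot(umi_threshold >= 0,
            all(c("barcode", "x", "y", "umi_total") %in% names(units)))
  cand <- units[units$umi_total > umi_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no unit above the UMI threshold")
    return(character(0))
  }
  if (nrow(cand) == 1L) return(cand$barcode)
  if (grid == "regular_hex") {
    key <- cand
  } else {
    stopifnot(!is.null(spot_distance_um))
    mesh <- make_mesh(c(min(units$x), min(units$y),
                        max(units$x), max(units$y)),
                      spot_distance_um, kind = "hexagon")
    asg <- assign_to_mesh(cand, mesh)
    key <- data.frame(barcode = cand$barcode,
                      x = mesh$centers[asg$center, 1L],
                      y = mesh$centers[asg$center, 2L],
                      umi_total = cand$umi_total,
                      stringsAsFactors = FALSE)
  }
  # pairwise adjacency among candidates (n modest: QC-scale arrays)
  dx <- outer(key$x, key$x, `-`); dy <- outer(key$y, key$y, `-`)
  dist <- sqrt(dx * dx + dy * dy)
  pos_dist <- dist[dist > 1e-9]
  if (length(pos_dist) == 0L) return(cand$barcode)
  dmin <- min(pos_dist)
  adj <- dist <= adjacency_factor * dmin
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    umis <- vapply(best, function(k) sum(cand$umi_total[comp == k]), 0)
    best <- best[umis == max(umis)]
    if (length(best) > 1L) {
      mins <- vapply(best, function(k) min(cand$barcode[comp == k]), "")
      best <- best[which.min(mins)]
    }
  }
  cand$barcode[comp == best[1L]]
}
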