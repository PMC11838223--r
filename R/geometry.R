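#' Minimum edge-to-edge distance between two cell polygons
#'
#' Computes the minimum Euclidean distance between the boundaries of two
#' simple polygons, the distance measure used throughout the niche analyses
#' in place of centroid-to-centroid distance. The distance is 0 when the
#' boundaries touch or cross, or when one polygon contains the other.
#'
#' @param poly_a,poly_b Numeric matrices with two columns (x, y in
#'   micrometres) giving the ordered vertices of a simple polygon. The
#'   closing edge from the last to the first vertex is implicit.
#' @return A single nonnegative number: the edge-to-edge distance in
#'   micrometres.
#' @examples
#' sq1 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' sq2 <- sq1 + 3
#' min_edge_distance(sq1, sq2)  # sqrt(8)
#' @export
min_edge_distance <- function(poly_a, poly_b) {
  poly_a <- check_polygon(poly_a)
  poly_b <- check_polygon(poly_b)
  .cpp_poly_dist(poly_a, poly_b)
}

check_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || !is.numeric(poly))
    stop("polygon must be a numeric matrix with columns x, y")
  # drop an explicit closing vertex
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  storage.mode(poly) <- "double"
  poly
}

#' Shoelace polygon area
#' @param poly vertex matrix (x, y), implicit closure.
#' @return area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- check_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Polygon centroid (area-weighted)
#' @param poly vertex matrix (x, y).
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- check_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

#' Sparse pairwise edge-to-edge distances within one field of view
#'
#' Computes the minimum edge distance for every unordered pair of cells in a
#' single FOV, keeping pairs within a distance cutoff. Distances are never
#' computed across FOV boundaries; the caller is expected to pass the cells
#' of one FOV at a time.
#'
#' @param polygons Named list of vertex matrices, one per cell; names are
#'   cell ids.
#' @param cutoff Maximum edge distance (micrometres) retained; default 45,
#'   the outer radius of the largest ring neighborhood.
#' @return A data.frame with columns \code{id_a}, \code{id_b},
#'   \code{dist_um}, one row per retained unordered pair.
#' @export
pairwise_min_distances <- function(polygons, cutoff = 45) {
  if (length(polygons) == 0L) stop("empty FOV: no polygons supplied")
  ids <- names(polygons)
  if (is.null(ids)) ids <- as.character(seq_along(polygons))
  polygons <- lapply(polygons, check_polygon)
  m <- .cpp_pairwise_dist(polygons, cutoff)
  data.frame(id_a = ids[m[, 1L]], id_b = ids[m[, 2L]],
             dist_um = m[, 3L], stringsAsFactors = FALSE)
}

#' Count directly touching neighbors of one cell
#'
#' @param cell_id id of the index cell.
#' @param dists data.frame from [pairwise_min_distances()].
#' @param touch_tol distance (micrometres) at or below which two cells are
#'   considered touching; default 0 (an epsilon such as 1e-6 guards against
#'   floating-point jitter in vertex coordinates).
#' @return Integer count of touching neighbors.
#' @export
count_touching_neighbors <- function(cell_id, dists, touch_tol = 0) {
  sel <- (dists$id_a == cell_id | dists$id_b == cell_id) &
    dists$dist_um <= touch_tol
  sum(sel)
}

#' Ring-neighborhood specification
#'
#' Radial distance bands around an index cell, measured edge-to-edge.
#' Intervals are half-open \code{[lo, hi)} so that the rings partition
#' \code{[0, max)}; a distance of exactly 5 falls in the 5-15 ring.
#'
#' @param boundaries Strictly increasing nonnegative breaks starting at 0;
#'   default \code{c(0, 5, 15, 25, 35, 45)} micrometres.
#' @return An object of class \code{ring_spec}.
#' @export
ring_spec <- function(boundaries = c(0, 5, 15, 25, 35, 45)) {
  if (boundaries[1L] != 0) stop("ring boundaries must start at 0")
  if (any(diff(boundaries) <= 0)) stop("ring boundaries must be strictly increasing")
  structure(list(boundaries = as.numeric(boundaries),
                 n_rings = length(boundaries) - 1L),
            class = "ring_spec")
}

#' @export
print.ring_spec <- function(x, ...) {
  b <- x$boundaries
  lab <- paste0("[", b[-length(b)], ",", b[-1L], ")")
  cat("ring_spec:", paste(lab, collapse = " "), "um\n")
  invisible(x)
}

#' Assign a distance to a ring
#'
#' @param distance nonnegative distance(s) in micrometres.
#' @param spec a [ring_spec()].
#' @return Integer ring index (0-based: ring 0 is the innermost band) or
#'   \code{NA} for distances at or beyond the outermost boundary.
#' @export
assign_ring <- function(distance, spec = ring_spec()) {
  if (any(distance < 0)) stop("negative distance")
  idx <- findInterval(distance, spec$boundaries,
                      rightmost.closed = FALSE, left.open = FALSE) - 1L
  idx[distance >= spec$boundaries[length(spec$boundaries)]] <- NA_integer_
  idx
}

#' Ring-neighborhood cell-type counts around index cells
#'
#' For every cell of the index type (by default the leukemia cells), counts
#' the cells of each type whose edge-to-edge distance falls in each ring.
#' The index cell itself is excluded from its own neighborhood; other cells
#' of the index type are counted as neighbors of their own type. Ring totals
#' sum the counts over all types within the ring, and serve as the model
#' offset downstream.
#'
#' @param cells A cell table as produced by [simulate_tissue()] (data.frame
#'   with cell_id, fov_id, patient_id, timepoint, response, cell_type).
#' @param polygons Named list of vertex matrices keyed by cell_id.
#' @param index_type Cell-type label of the index cells.
#' @param spec A [ring_spec()].
#' @return A data.frame of class \code{neighborhood_counts}: one row per
#'   (index cell, ring, observed neighbor type), with columns
#'   \code{index_cell_id}, \code{fov_id}, \code{patient_id},
#'   \code{timepoint}, \code{response}, \code{ring}, \code{cell_type},
#'   \code{count}, \code{ring_total}. FOVs without any index cell are
#'   skipped (recorded in the \code{"skipped_fovs"} attribute).
#' @export
neighborhood_counts <- function(cells, polygons, index_type = "leukemia",
                                spec = ring_spec()) {
  stopifnot(is.data.frame(cells))
  out <- list()
  skipped <- character(0)
  for (fov in unique(cells$fov_id)) {
    fc <- cells[cells$fov_id == fov, , drop = FALSE]
    idx <- fc$cell_id[fc$cell_type == index_type]
    if (length(idx) == 0L) {
      skipped <- c(skipped, fov)
      next
    }
    dd <- pairwise_min_distances(polygons[fc$cell_id],
                                 cutoff = max(spec$boundaries))
    if (nrow(dd) == 0L) next
    type_of <- stats::setNames(fc$cell_type, fc$cell_id)
    meta <- fc[match(idx, fc$cell_id),
               c("fov_id", "patient_id", "timepoint", "response")]
    # long edge list from both directions, restricted to index cells
    e_idx <- c(dd$id_a, dd$id_b)
    e_nb <- c(dd$id_b, dd$id_a)
    e_d <- c(dd$dist_um, dd$dist_um)
    keep <- e_idx %in% idx
    e_idx <- e_idx[keep]; e_nb <- e_nb[keep]; e_d <- e_d[keep]
    ring <- assign_ring(e_d, spec)
    ok <- !is.na(ring)
    e_idx <- e_idx[ok]; e_nb <- e_nb[ok]; ring <- ring[ok]
    if (length(e_idx) == 0L) next
    tab <- as.data.frame(table(index_cell_id = e_idx, ring = ring,
                               cell_type = type_of[e_nb]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    names(tab)[names(tab) == "Freq"] <- "count"
    tab$ring <- as.integer(tab$ring)
    tot <- stats::aggregate(count ~ index_cell_id + ring, data = tab, FUN = sum)
    names(tot)[names(tot) == "count"] <- "ring_total"
    tab <- merge(tab, tot, by = c("index_cell_id", "ring"), sort = FALSE)
    mi <- match(tab$index_cell_id, idx)
    tab$fov_id <- meta$fov_id[mi]
    tab$patient_id <- meta$patient_id[mi]
    tab$timepoint <- meta$timepoint[mi]
    tab$response <- meta$response[mi]
    out[[length(out) + 1L]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(index_cell_id = character(0), ring = integer(0),
               cell_type = character(0), count = integer(0),
               ring_total = integer(0), fov_id = character(0),
               patient_id = character(0), timepoint = character(0),
               response = character(0))
  rownames(res) <- NULL
  attr(res, "skipped_fovs") <- skipped
  attr(res, "ring_spec") <- spec
  attr(res, "index_type") <- index_type
  class(res) <- c("neighborhood_counts", "data.frame")
  res
}

#' Quality-control filter on cells and fields of view
#'
#' Two-stage filter applied before any spatial analysis: first, cells with
#' fewer than \code{min_transcripts} total assigned transcripts are removed;
#' then whole FOVs with fewer than \code{min_cells_per_fov} surviving cells
#' are removed.
#'
#' @param cells data.frame with at least \code{cell_id}, \code{fov_id},
#'   \code{total_counts}.
#' @param min_transcripts minimum total transcript count per cell kept
#'   (default 20; a cell with exactly 20 is kept).
#' @param min_cells_per_fov minimum surviving cells per FOV kept
#'   (default 300; a FOV with exactly 300 is kept).
#' @return The filtered data.frame, with a \code{"removal_log"} attribute
#'   listing removed cell ids (stage 1) and removed FOV ids (stage 2).
#' @export
qc_filter <- function(cells, min_transcripts = 20, min_cells_per_fov = 300) {
  if (nrow(cells) == 0L) {
    attr(cells, "removal_log") <- list(low_count_cells = character(0),
                                       removed_fovs = character(0))
    return(cells)
  }
  low <- cells$total_counts < min_transcripts
  log1 <- cells$cell_id[low]
  cells <- cells[!low, , drop = FALSE]
  n_by_fov <- table(cells$fov_id)
  bad_fov <- names(n_by_fov)[n_by_fov < min_cells_per_fov]
  cells <- cells[!(cells$fov_id %in% bad_fov), , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "removal_log") <- list(low_count_cells = as.character(log1),
                                     removed_fovs = as.character(bad_fov))
  cells
}

#' Serialize a polygon to a WKT POLYGON string
#' @param poly vertex matrix.
#' @param digits coordinate digits.
#' @return character scalar.
#' @export
polygon_to_wkt <- function(poly, digits = 4) {
  poly <- check_polygon(poly)
  poly <- rbind(poly, poly[1L, ])
  coords <- apply(round(poly, digits), 1L, paste, collapse = " ")
  paste0("POLYGON ((", paste(coords, collapse = ", "), "))")
}

#' Parse a WKT POLYGON string (outer ring only)
#' @param wkt character scalar.
#' @return vertex matrix without the closing vertex.
#' @export
wkt_to_polygon <- function(wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\).*$", "", body)
  parts <- strsplit(strsplit(body, ",")[[1L]], "\\s+")
  m <- do.call(rbind, lapply(parts, function(p) {
    p <- p[nzchar(p)]
    as.numeric(p[1:2])
  }))
  check_polygon(m)
}
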