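#' Minimum distances from a query cell type to the nearest leukemia cell
#'
#' For each query-type cell, the minimum edge-to-edge distance to any
#' reference (leukemia) cell in the same FOV. FOVs of one patient-timepoint
#' sample are pooled as replicates. FOVs lacking either a reference or a
#' query cell contribute nothing.
#'
#' @param cells cell table (one patient-timepoint sample).
#' @param polygons named list of vertex matrices keyed by cell_id.
#' @param query_type query cell type label.
#' @param ref_type reference type (default "leukemia").
#' @return list of class \code{min_distance_sample}: \code{d} (pooled
#'   distances, um), \code{fov} (provenance per distance), \code{per_fov}
#'   (data.frame fov_id, N = query cells, K = non-reference cells).
#' @export
min_distance_sample <- function(cells, polygons, query_type,
                                ref_type = "leukemia") {
  d_all <- numeric(0); fov_all <- character(0)
  per_fov <- list()
  for (fov in unique(cells$fov_id)) {
    fc <- cells[cells$fov_id == fov, , drop = FALSE]
    ref <- fc$cell_id[fc$cell_type == ref_type]
    qry <- fc$cell_id[fc$cell_type == query_type]
    K <- sum(fc$cell_type != ref_type)
    if (length(ref) == 0L || length(qry) == 0L) next
    d <- .cpp_min_dist_to_ref(polygons[qry], polygons[ref])
    d_all <- c(d_all, d)
    fov_all <- c(fov_all, rep(fov, length(d)))
    per_fov[[fov]] <- data.frame(fov_id = fov, N = length(qry), K = K,
                                 stringsAsFactors = FALSE)
  }
  structure(list(d = d_all, fov = fov_all,
                 per_fov = rbind_list(per_fov),
                 query_type = query_type, ref_type = ref_type,
                 usable = length(d_all) > 0L),
            class = "min_distance_sample")
}

#' Kernel density estimate of a minimum-distance sample on a shared grid
#'
#' Gaussian kernel with the rule-of-thumb bandwidth (the default of
#' \code{stats::density}), evaluated on \code{L} points over
#' \code{[0, grid_max]} so two timepoints share the same grid. Density mass
#' below 0 is simply truncated (no boundary reflection).
#'
#' @param d numeric distances (um), length >= 2.
#' @param grid_max upper end of the grid (default 45 um).
#' @param L grid length (default 512).
#' @return list: \code{x} grid, \code{y} density.
#' @export
estimate_pdf <- function(d, grid_max = 45, L = 512) {
  if (length(d) < 2L) stop("need >= 2 distances for a density estimate")
  kd <- stats::density(d, bw = "nrd0", from = 0, to = grid_max, n = L)
  list(x = kd$x, y = kd$y)
}

#' Observed density-shift curve between two timepoints
#'
#' @param pdf_a,pdf_b lists from [estimate_pdf()] on the same grid.
#' @return numeric vector S = pdf_a$y - pdf_b$y.
#' @export
observed_shift <- function(pdf_a, pdf_b) {
  if (!isTRUE(all.equal(pdf_a$x, pdf_b$x))) stop("grid mismatch")
  pdf_a$y - pdf_b$y
}

#' Permutation background for the density-shift test
#'
#' For each of J permutations, draws per FOV the same number of pseudo-query
#' cells (N per FOV) from that FOV's non-leukemia cells (K per FOV) without
#' replacement, at both timepoints, recomputes the nearest-leukemia
#' distances, and forms the permuted shift curve exactly as for the
#' observed data.
#'
#' @param dist_a,dist_b per-timepoint lists mapping fov_id -> list(d = all
#'   non-leukemia nearest-leukemia distances in the FOV, N = query count);
#'   built internally by [density_shift_test()].
#' @param J number of permutations (default 100).
#' @param grid_max,L KDE grid as in [estimate_pdf()].
#' @return list: \code{S} (J x L matrix of permuted shifts), \code{mean},
#'   \code{sd} (per-gridpoint), \code{x} grid.
#' @export
permutation_background <- function(dist_a, dist_b, J = 100,
                                   grid_max = 45, L = 512) {
  if (J < 2L) stop("J must be >= 2 to define a background SD")
  draw <- function(dist_list) {
    unlist(lapply(dist_list, function(f) {
      if (f$N > length(f$d)) stop("K < N in a FOV: cannot permute")
      f$d[sample.int(length(f$d), f$N)]
    }), use.names = FALSE)
  }
  S <- matrix(NA_real_, J, L)
  x <- NULL
  for (j in seq_len(J)) {
    pa <- estimate_pdf(draw(dist_a), grid_max, L)
    pb <- estimate_pdf(draw(dist_b), grid_max, L)
    S[j, ] <- pa$y - pb$y
    x <- pa$x
  }
  list(S = S, mean = colMeans(S), sd = apply(S, 2L, stats::sd), x = x)
}

#' Flag significant gridpoints of a density shift
#'
#' A gridpoint is significant when the observed shift lies outside one
#' standard deviation of the permutation background (either direction):
#' \code{|S - mean_perm| > sd_perm}.
#'
#' @param S observed shift curve.
#' @param background list from [permutation_background()].
#' @return logical vector of flags, one per gridpoint.
#' @export
flag_shift <- function(S, background) {
  abs(S - background$mean) > background$sd
}

#' Density-shift test between two timepoints
#'
#' The full procedure for one patient and one query cell type: pool the
#' nearest-leukemia edge distances of the query cells over the FOVs of each
#' timepoint, estimate both densities on a shared grid, take their
#' difference as the observed shift, build a J-permutation background by
#' redrawing pseudo-query cells of the same per-FOV size from the
#' non-leukemia cells, and flag gridpoints outside one background SD.
#'
#' @param cells cell table for one patient (both timepoints present).
#' @param polygons named list of vertex matrices keyed by cell_id.
#' @param query_type query cell type.
#' @param timepoints length-2 character, earlier then later (default
#'   c("A", "B")); the shift is pdf(first) - pdf(second).
#' @param ref_type reference type (default "leukemia").
#' @param J permutations (default 100).
#' @param grid_max,L KDE grid (default 45 um, 512 points).
#' @param seed RNG seed for the permutations.
#' @return object of class \code{density_shift}: grid \code{x},
#'   \code{pdf_a}, \code{pdf_b}, observed \code{S}, permutation
#'   \code{mean}/\code{sd}, logical \code{flag}, plus sample bookkeeping.
#' @export
density_shift_test <- function(cells, polygons, query_type,
                               timepoints = c("A", "B"),
                               ref_type = "leukemia", J = 100,
                               grid_max = 45, L = 512, seed = 1L) {
  stopifnot(length(timepoints) == 2L)
  set.seed(seed)
  samp <- list(); dists <- list()
  for (tp in timepoints) {
    tc <- cells[cells$timepoint == tp, , drop = FALSE]
    s <- min_distance_sample(tc, polygons, query_type, ref_type)
    if (!s$usable) stop("no usable query cells at timepoint ", tp)
    samp[[tp]] <- s
    # all non-leukemia nearest-leukemia distances per FOV (permutation pool)
    dl <- list()
    for (fov in s$per_fov$fov_id) {
      fc <- tc[tc$fov_id == fov, , drop = FALSE]
      ref <- fc$cell_id[fc$cell_type == ref_type]
      oth <- fc$cell_id[fc$cell_type != ref_type]
      dl[[fov]] <- list(
        d = .cpp_min_dist_to_ref(polygons[oth], polygons[ref]),
        N = s$per_fov$N[s$per_fov$fov_id == fov])
    }
    dists[[tp]] <- dl
  }
  pdf_a <- estimate_pdf(samp[[timepoints[1L]]]$d, grid_max, L)
  pdf_b <- estimate_pdf(samp[[timepoints[2L]]]$d, grid_max, L)
  S <- observed_shift(pdf_a, pdf_b)
  bg <- permutation_background(dists[[timepoints[1L]]],
                               dists[[timepoints[2L]]], J, grid_max, L)
  structure(list(x = pdf_a$x, pdf_a = pdf_a$y, pdf_b = pdf_b$y, S = S,
                 perm_mean = bg$mean, perm_sd = bg$sd, perm_S = bg$S,
                 flag = flag_shift(S, bg), J = J, seed = seed,
                 query_type = query_type, timepoints = timepoints,
                 n_a = length(samp[[timepoints[1L]]]$d),
                 n_b = length(samp[[timepoints[2L]]]$d)),
            class = "density_shift")
}

#' @export
print.density_shift <- function(x, ...) {
  cat("density_shift:", x$query_type, paste(x$timepoints, collapse = " vs "),
      sprintf("(n=%d vs %d, J=%d)\n", x$n_a, x$n_b, x$J))
  cat(sprintf("  flagged gridpoints: %d / %d (%.1f%%)\n", sum(x$flag),
              length(x$flag), 100 * mean(x$flag)))
  invisible(x)
}

#' @export
plot.density_shift <- function(x, normalize = FALSE, ...) {
  y <- x$S; m <- x$perm_mean; s <- x$perm_sd
  if (normalize) {
    # display transform only: center on the median permuted curve
    med <- apply(x$perm_S, 2L, stats::median)
    y <- y - med; m <- m - med
  }
  plot(x$x, y, type = "l", col = "purple", lwd = 2,
       xlab = "distance to nearest leukemia cell (um)",
       ylab = "density shift", ...)
  graphics::polygon(c(x$x, rev(x$x)), c(m - s, rev(m + s)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$x, y, col = "purple", lwd = 2)
  graphics::points(x$x[x$flag], y[x$flag], pch = 16, cex = 0.4, col = "red")
  invisible(x)
}

#' Plant a positive-control density shift in a synthetic tissue
#'
#' For a fraction of the leukemia cells, relabels their closest (or
#' furthest) non-leukemia neighbor to the query type — the positive-control
#' construction used to verify that the density-shift test detects a
#' planted proximity pattern.
#'
#' @param tissue a \code{niche_tissue}.
#' @param query_type type label to assign.
#' @param mode \code{"closest"} or \code{"furthest"}.
#' @param fraction fraction of leukemia cells perturbed (default 1).
#' @param timepoint restrict to one timepoint (NULL = all).
#' @param seed RNG seed for the fraction subsample.
#' @return the tissue with modified cell types.
#' @export
plant_density_shift <- function(tissue, query_type, mode = c("closest", "furthest"),
                                fraction = 1, timepoint = NULL, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (fraction <= 0) return(tissue)
  cells <- tissue$cells
  leuk_type <- tissue$config$leukemia_type
  sel_fov <- unique(cells$fov_id[
    if (is.null(timepoint)) TRUE else cells$timepoint == timepoint])
  for (fov in sel_fov) {
    fc <- cells[cells$fov_id == fov, , drop = FALSE]
    leuk <- fc$cell_id[fc$cell_type == leuk_type]
    oth <- fc$cell_id[fc$cell_type != leuk_type]
    if (length(leuk) == 0L || length(oth) == 0L) next
    pick <- if (fraction >= 1) leuk else
      sample(leuk, max(1L, round(fraction * length(leuk))))
    for (lc in pick) {
      d <- .cpp_min_dist_to_ref(tissue$polygons[oth],
                                tissue$polygons[lc])
      tgt <- oth[if (mode == "closest") which.min(d) else which.max(d)]
      cells$cell_type[cells$cell_id == tgt] <- query_type
    }
  }
  tissue$cells <- cells
  tissue
}
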