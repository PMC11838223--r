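#' Specification for a synthetic segmentation-mask fixture
#'
#' Defines a ground-truth instance mask and a perturbed "predicted" mask
#' with a known error structure, so that segmentation evaluation can be
#' checked against a construction-time ledger.
#'
#' @param grid_shape c(rows, cols) in pixels.
#' @param n_true_cells number of ground-truth cells.
#' @param n_split_errors cells split into two predicted labels.
#' @param n_merge_errors adjacent truth-cell pairs merged into one
#'   predicted label (consumes two truth cells each).
#' @param n_missed truth cells absent from the prediction.
#' @param n_spurious predicted labels with no truth counterpart.
#' @param boundary_jitter_px maximum absolute pixel translation applied to
#'   unperturbed predicted cells (integer; 0 = exact copies).
#' @param cell_radius_px disc radius of each cell.
#' @param pixel_size_um pixel size (default 0.18).
#' @param seed RNG seed.
#' @return list of class \code{mask_fixture_spec}.
#' @export
mask_fixture_spec <- function(grid_shape = c(128, 128), n_true_cells = 20,
                              n_split_errors = 0, n_merge_errors = 0,
                              n_missed = 0, n_spurious = 0,
                              boundary_jitter_px = 0, cell_radius_px = 6,
                              pixel_size_um = 0.18, seed = 1L) {
  if (n_split_errors + 2 * n_merge_errors + n_missed > n_true_cells)
    stop("error counts exceed n_true_cells")
  structure(as.list(environment()), class = "mask_fixture_spec")
}

# disc pixel set (linear indices) centered at (r, c), clipped to grid
disc_pixels <- function(r, c, radius, nr, nc) {
  dr <- seq(-radius, radius)
  grid <- expand.grid(dr = dr, dc = dr)
  grid <- grid[grid$dr^2 + grid$dc^2 <= radius^2, ]
  rr <- r + grid$dr; cc <- c + grid$dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  rr[ok] + (cc[ok] - 1L) * nr
}

# lay out k non-touching disc centers on a grid; merge pairs need adjacent
# slots, so centers are produced in column-major slot order
mask_centers <- function(k, radius, nr, nc, gap = 3L) {
  pitch <- 2L * radius + gap
  rows <- seq(radius + 2L, nr - radius - 1L, by = pitch)
  cols <- seq(radius + 2L, nc - radius - 1L, by = pitch)
  if (length(rows) * length(cols) < k)
    stop("grid too small for requested cells")
  g <- expand.grid(r = rows, c = cols)
  g[seq_len(k), , drop = FALSE]
}

#' Generate a (truth, predicted) mask pair with known error structure
#'
#' The predicted mask is the truth perturbed by the requested number of
#' split, merge, miss and spurious errors plus optional integer-pixel
#' jitter of the remaining cells. The expected TP/FP/FN ledger at the given
#' IOU threshold is computed at construction time from the per-pair pixel
#' overlaps of the planned perturbations — independently of the matching
#' algorithm under test.
#'
#' @param spec a [mask_fixture_spec()].
#' @param iou_threshold threshold for the construction ledger (default 0.7).
#' @return list: \code{truth}, \code{pred} (both \code{label_mask}),
#'   \code{expected} (list TP, FP, FN).
#' @export
simulate_mask_pair <- function(spec, iou_threshold = 0.7) {
  stopifnot(inherits(spec, "mask_fixture_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1L]; nc <- spec$grid_shape[2L]
  n_spur <- spec$n_spurious
  centers <- mask_centers(spec$n_true_cells + n_spur, spec$cell_radius_px,
                          nr, nc)
  truth <- matrix(0L, nr, nc)
  px_of <- vector("list", spec$n_true_cells)
  for (i in seq_len(spec$n_true_cells)) {
    px_of[[i]] <- disc_pixels(centers$r[i], centers$c[i],
                              spec$cell_radius_px, nr, nc)
    truth[px_of[[i]]] <- i
  }
  # reserve roles: merges need consecutive slots (adjacent in layout)
  n_merge <- spec$n_merge_errors
  merge_pairs <- if (n_merge > 0)
    lapply(seq_len(n_merge), function(k) c(2L * k - 1L, 2L * k)) else list()
  used <- unlist(merge_pairs)
  remaining <- setdiff(seq_len(spec$n_true_cells), used)
  split_ids <- utils::head(remaining, spec$n_split_errors)
  remaining <- setdiff(remaining, split_ids)
  miss_ids <- utils::head(remaining, spec$n_missed)
  normal_ids <- setdiff(remaining, miss_ids)

  pred <- matrix(0L, nr, nc)
  tp <- 0L; fp <- 0L; fn <- 0L
  next_lab <- 0L
  iou_px <- function(a, b) length(intersect(a, b)) /
    (length(a) + length(b) - length(intersect(a, b)))
  for (pr in merge_pairs) {
    next_lab <- next_lab + 1L
    u <- union(px_of[[pr[1L]]], px_of[[pr[2L]]])
    pred[u] <- next_lab
    ious <- c(iou_px(u, px_of[[pr[1L]]]), iou_px(u, px_of[[pr[2L]]]))
    # one predicted label against two truth cells: at most one can match
    if (max(ious) >= iou_threshold) {
      tp <- tp + 1L; fn <- fn + 1L
    } else {
      fp <- fp + 1L; fn <- fn + 2L
    }
  }
  for (i in split_ids) {
    px <- px_of[[i]]
    cc <- (px - 1L) %/% nr + 1L
    cut <- stats::median(cc)
    left <- px[cc <= cut]; right <- px[cc > cut]
    next_lab <- next_lab + 1L; pred[left] <- next_lab
    next_lab <- next_lab + 1L; pred[right] <- next_lab
    ious <- c(iou_px(left, px), iou_px(right, px))
    if (max(ious) >= iou_threshold) {
      tp <- tp + 1L; fp <- fp + 1L
    } else {
      fp <- fp + 2L; fn <- fn + 1L
    }
  }
  fn <- fn + length(miss_ids)
  for (i in normal_ids) {
    next_lab <- next_lab + 1L
    px <- px_of[[i]]
    if (spec$boundary_jitter_px > 0) {
      sh <- sample(seq(-spec$boundary_jitter_px, spec$boundary_jitter_px), 2L,
                   replace = TRUE)
      rr <- (px - 1L) %% nr + 1L + sh[1L]
      cc <- (px - 1L) %/% nr + 1L + sh[2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      px2 <- rr[ok] + (cc[ok] - 1L) * nr
    } else {
      px2 <- px
    }
    pred[px2] <- next_lab
    if (iou_px(px2, px) >= iou_threshold) tp <- tp + 1L else {
      fp <- fp + 1L; fn <- fn + 1L
    }
  }
  for (k in seq_len(n_spur)) {
    next_lab <- next_lab + 1L
    i <- spec$n_true_cells + k
    pred[disc_pixels(centers$r[i], centers$c[i], spec$cell_radius_px, nr, nc)] <-
      next_lab
    fp <- fp + 1L
  }
  list(truth = label_mask(truth, spec$pixel_size_um),
       pred = label_mask(pred, spec$pixel_size_um),
       expected = list(TP = tp, FP = fp, FN = fn))
}

#' Generate a nuclear/membrane mask pair with known merged truth
#'
#' Cells are discs; each has a concentric nuclear disc. A configurable
#' fraction of cells has no membrane label, emulating weak or absent
#' membrane staining: for those, the truth cell is the Euclidean dilation
#' of the nucleus by the expansion radius. Cells are spaced so dilations
#' never collide, making the truth exact.
#'
#' @param n_cells number of cells.
#' @param frac_without_membrane fraction of cells lacking a membrane label.
#' @param grid_shape c(rows, cols) pixels.
#' @param cell_radius_px,nucleus_radius_px disc radii.
#' @param expansion_radius_px dilation radius used in the truth for
#'   membrane-less cells.
#' @param pixel_size_um pixel size.
#' @param seed RNG seed.
#' @return list: \code{nuclei}, \code{membranes}, \code{truth} (all
#'   \code{label_mask}; truth labels follow the nucleus labels), and
#'   \code{expansion_radius_um}.
#' @export
simulate_nucleus_membrane_pair <- function(n_cells = 12,
                                           frac_without_membrane = 0.5,
                                           grid_shape = c(160, 160),
                                           cell_radius_px = 7,
                                           nucleus_radius_px = 3,
                                           expansion_radius_px = 4,
                                           pixel_size_um = 0.18,
                                           seed = 1L) {
  set.seed(seed)
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  pad <- max(cell_radius_px, nucleus_radius_px + expansion_radius_px)
  centers <- mask_centers(n_cells, pad, nr, nc, gap = 4L)
  nuclei <- matrix(0L, nr, nc)
  membranes <- matrix(0L, nr, nc)
  truth <- matrix(0L, nr, nc)
  no_mem <- sample.int(n_cells, round(frac_without_membrane * n_cells))
  for (i in seq_len(n_cells)) {
    npx <- disc_pixels(centers$r[i], centers$c[i], nucleus_radius_px, nr, nc)
    nuclei[npx] <- i
    if (i %in% no_mem) {
      truth[disc_pixels(centers$r[i], centers$c[i],
                        nucleus_radius_px + expansion_radius_px, nr, nc)] <- i
    } else {
      cpx <- disc_pixels(centers$r[i], centers$c[i], cell_radius_px, nr, nc)
      membranes[cpx] <- i
      truth[cpx] <- i
    }
  }
  list(nuclei = label_mask(nuclei, pixel_size_um),
       membranes = label_mask(membranes, pixel_size_um),
       truth = label_mask(truth, pixel_size_um),
       expansion_radius_um = expansion_radius_px * pixel_size_um)
}
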