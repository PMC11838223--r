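#' Create a label-mask object
#'
#' A 2-D integer raster of instance labels (0 = background) with a pixel
#' size, the working representation of nuclear, membrane, and merged cell
#' segmentation masks.
#'
#' @param m integer matrix of labels, 0 = background.
#' @param pixel_size_um pixel edge length in micrometres (default 0.18).
#' @return object of class \code{label_mask}.
#' @export
label_mask <- function(m, pixel_size_um = 0.18) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("labels must be nonnegative")
  storage.mode(m) <- "integer"
  structure(list(labels = m, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("label_mask:", nrow(x$labels), "x", ncol(x$labels), "px at",
      x$pixel_size_um, "um/px;",
      length(setdiff(unique(as.vector(x$labels)), 0L)), "labels\n")
  invisible(x)
}

#' Intersection over union of two pixel sets
#'
#' @param px_a,px_b integer vectors of linear pixel indices on the same
#'   grid.
#' @return |A intersect B| / |A union B|, in [0, 1].
#' @export
compute_iou <- function(px_a, px_b) {
  if (length(px_a) == 0L && length(px_b) == 0L)
    stop("IOU undefined for two empty pixel sets")
  inter <- length(intersect(px_a, px_b))
  inter / (length(px_a) + length(px_b) - inter)
}

#' Match predicted and ground-truth instance masks at an IOU threshold
#'
#' Builds the overlap table between predicted and truth labels, performs
#' greedy one-to-one matching by descending IOU (ties broken by lower
#' predicted then truth label), and counts pairs with IOU at or above the
#' threshold as true positives. Unmatched predicted labels are false
#' positives; unmatched truth labels are false negatives — so a predicted
#' mask straddling two truth cells with per-pair IOU below threshold yields
#' one FP and two FN.
#'
#' @param pred,truth \code{label_mask} objects on the same grid.
#' @param iou_threshold minimum IOU for a true positive (default 0.7).
#' @return list of class \code{match_ledger}: \code{pairs} (data.frame
#'   pred_label, truth_label, iou for matched pairs), \code{TP}, \code{FP},
#'   \code{FN}, \code{iou_threshold}.
#' @export
match_masks <- function(pred, truth, iou_threshold = 0.7) {
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("mask shape mismatch")
  p <- as.vector(pred$labels); t <- as.vector(truth$labels)
  sizes_p <- table(p[p > 0L]); sizes_t <- table(t[t > 0L])
  both <- p > 0L & t > 0L
  ov <- as.data.frame(table(pred_label = p[both], truth_label = t[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0L, , drop = FALSE]
  if (nrow(ov)) {
    np <- as.numeric(sizes_p[ov$pred_label])
    nt <- as.numeric(sizes_t[ov$truth_label])
    ov$iou <- ov$Freq / (np + nt - ov$Freq)
    ov$pred_label <- as.integer(ov$pred_label)
    ov$truth_label <- as.integer(ov$truth_label)
    ov <- ov[order(-ov$iou, ov$pred_label, ov$truth_label), , drop = FALSE]
  } else {
    ov$iou <- numeric(0)
  }
  used_p <- integer(0); used_t <- integer(0)
  keep <- logical(nrow(ov))
  for (k in seq_len(nrow(ov))) {
    if (!(ov$pred_label[k] %in% used_p) && !(ov$truth_label[k] %in% used_t)) {
      keep[k] <- TRUE
      used_p <- c(used_p, ov$pred_label[k])
      used_t <- c(used_t, ov$truth_label[k])
    }
  }
  matched <- ov[keep & ov$iou >= iou_threshold, c("pred_label", "truth_label", "iou")]
  tp <- nrow(matched)
  structure(list(pairs = matched, TP = tp,
                 FP = length(sizes_p) - tp, FN = length(sizes_t) - tp,
                 iou_threshold = iou_threshold),
            class = "match_ledger")
}

#' @export
print.match_ledger <- function(x, ...) {
  cat(sprintf("match_ledger @ IOU >= %.2f: TP=%d FP=%d FN=%d F1=%.4f\n",
              x$iou_threshold, x$TP, x$FP, x$FN, f1_at_iou(x)))
  invisible(x)
}

#' Segmentation F1 score from a match ledger
#'
#' F1 = TP / (TP + (FP + FN) / 2), the instance-segmentation F1 at a fixed
#' IOU threshold.
#'
#' @param ledger a \code{match_ledger}, or a list with TP, FP, FN counts.
#' @return F1 in [0, 1].
#' @export
f1_at_iou <- function(ledger) {
  tp <- ledger$TP; fp <- ledger$FP; fn <- ledger$FN
  if (tp < 0 || fp < 0 || fn < 0) stop("negative counts")
  if (tp + fp + fn == 0) stop("F1 undefined: no objects in either mask")
  tp / (tp + (fp + fn) / 2)
}

#' Per-label areas of a mask
#' @param mask a \code{label_mask}.
#' @return named numeric vector, label -> area in square micrometres.
#' @export
cell_areas <- function(mask) {
  v <- mask$labels[mask$labels > 0L]
  if (length(v) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(v)
  stats::setNames(as.numeric(tab) * mask$pixel_size_um^2, names(tab))
}

# pixel coords (row, col) of each label
label_pixels <- function(m) {
  idx <- which(m > 0L)
  split(idx, m[idx])
}

#' Merge nuclear and membrane instance masks into single-cell masks
#'
#' Each membrane mask becomes one cell; a nucleus whose pixels are covered
#' more than half by one membrane adopts that membrane (multiple nuclei in
#' one membrane are absorbed into the single membrane-defined cell, and the
#' event is recorded). A nucleus with no membrane — the weak-staining case —
#' is expanded by a Euclidean dilation of \code{expansion_radius_um},
#' clipped against membrane footprints, other nuclei and previously claimed
#' pixels; contested pixels go to the nearest nucleus (ties to the lower
#' output label). Output labels are consecutive 1..n.
#'
#' @param nuclei,membranes \code{label_mask} objects on the same grid with
#'   the same pixel size.
#' @param expansion_radius_um dilation radius for membrane-less nuclei in
#'   micrometres (default 3, an approximate lymphocyte cytoplasm width).
#' @return \code{label_mask} of merged cells, with attributes
#'   \code{"multi_nucleus_membranes"} (membrane labels that contained more
#'   than one nucleus) and \code{"n_expanded"} (number of membrane-less
#'   nuclei expanded).
#' @export
merge_nuclear_membrane <- function(nuclei, membranes, expansion_radius_um = 3) {
  if (!identical(dim(nuclei$labels), dim(membranes$labels)))
    stop("mask shape mismatch")
  if (nuclei$pixel_size_um != membranes$pixel_size_um)
    stop("pixel size mismatch")
  nm <- nuclei$labels; mm <- membranes$labels
  nr <- nrow(nm); nc <- ncol(nm)
  npx <- label_pixels(nm)
  out <- matrix(0L, nr, nc)
  mem_labels <- setdiff(sort(unique(as.vector(mm))), 0L)
  next_id <- 0L
  mem_id <- stats::setNames(integer(length(mem_labels)), mem_labels)
  for (ml in mem_labels) {
    next_id <- next_id + 1L
    mem_id[as.character(ml)] <- next_id
    out[mm == ml] <- next_id
  }
  # nucleus -> membrane by majority overlap
  orphan <- character(0)
  mem_nuc_count <- stats::setNames(integer(length(mem_labels)), mem_labels)
  for (nl in names(npx)) {
    px <- npx[[nl]]
    memv <- mm[px]
    memv <- memv[memv > 0L]
    host <- 0L
    if (length(memv)) {
      tab <- table(memv)
      best <- names(tab)[which.max(tab)]
      if (max(tab) > length(px) / 2) host <- as.integer(best)
    }
    if (host > 0L) {
      mem_nuc_count[as.character(host)] <- mem_nuc_count[as.character(host)] + 1L
      out[px] <- mem_id[as.character(host)]  # absorb nucleus into its cell
    } else {
      orphan <- c(orphan, nl)
    }
  }
  # expand membrane-less nuclei by Euclidean dilation, nearest nucleus wins
  r_px <- expansion_radius_um / nuclei$pixel_size_um
  if (length(orphan)) {
    orphan_id <- stats::setNames(next_id + seq_along(orphan), orphan)
    claim_d <- matrix(Inf, nr, nc)
    for (nl in orphan) {
      px <- npx[[nl]]
      out[px] <- orphan_id[[nl]]
      claim_d[px] <- 0
    }
    for (nl in orphan) {
      px <- npx[[nl]]
      rc <- cbind((px - 1L) %% nr + 1L, (px - 1L) %/% nr + 1L)
      r0 <- max(1L, min(rc[, 1L]) - ceiling(r_px))
      r1 <- min(nr, max(rc[, 1L]) + ceiling(r_px))
      c0 <- max(1L, min(rc[, 2L]) - ceiling(r_px))
      c1 <- min(nc, max(rc[, 2L]) + ceiling(r_px))
      cand <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
      d2 <- outer(cand[, 1L], rc[, 1L], "-")^2 + outer(cand[, 2L], rc[, 2L], "-")^2
      dmin <- sqrt(apply(d2, 1L, min))
      ok <- dmin <= r_px
      cand <- cand[ok, , drop = FALSE]; dmin <- dmin[ok]
      lin <- cand[, 1L] + (cand[, 2L] - 1L) * nr
      # claim free or farther-claimed orphan pixels; never overwrite
      # membranes or nucleus seeds (claim_d == 0)
      id <- orphan_id[[nl]]
      for (k in seq_along(lin)) {
        p <- lin[k]
        cur <- out[p]
        if (cur > 0L && cur <= next_id) next      # membrane cell pixel
        if (dmin[k] < claim_d[p] ||
            (dmin[k] == claim_d[p] && cur > id)) {
          out[p] <- id
          claim_d[p] <- dmin[k]
        }
      }
    }
  }
  res <- label_mask(out, nuclei$pixel_size_um)
  attr(res, "multi_nucleus_membranes") <-
    as.integer(names(mem_nuc_count)[mem_nuc_count > 1L])
  attr(res, "n_expanded") <- length(orphan)
  res
}

#' Read / write a 16-bit single-channel TIFF label mask
#' @param path file path.
#' @param pixel_size_um pixel size to attach on read.
#' @rdname mask_tiff
#' @return \code{read_mask_tiff}: a \code{label_mask}.
#' @export
read_mask_tiff <- function(path, pixel_size_um = 0.18) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_mask(round(m), pixel_size_um)
}

#' @param mask a \code{label_mask} to write.
#' @rdname mask_tiff
#' @export
write_mask_tiff <- function(mask, path) {
  m <- mask$labels
  if (max(m) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
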