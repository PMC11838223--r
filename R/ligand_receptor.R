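#' Read a ligand-receptor pair table
#'
#' Two-column TSV (ligand gene symbol, receptor gene symbol) in the style
#' of curated ligand-receptor databases. Symbols are uppercased and
#' duplicate pairs dropped.
#'
#' @param path TSV path; default the 25-pair table shipped with the
#'   package (includes TNFSF12/TNFRSF12A, the TWEAK axis).
#' @return data.frame with columns \code{ligand}, \code{receptor}.
#' @export
read_lr_pairs <- function(path = system.file("extdata", "lr_pairs_subset.tsv",
                                             package = "nicheshift")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("ligand", "receptor")
  tab$ligand <- toupper(tab$ligand)
  tab$receptor <- toupper(tab$receptor)
  unique(tab[, c("ligand", "receptor")])
}

#' Assign cells to leukemia-proximity groups
#'
#' Each non-leukemia cell gets its minimum edge distance to the nearest
#' leukemia cell in the same FOV; cells at distance <= 5 um are "close",
#' >= 30 um "far", and cells in between "neither" (excluded from tests).
#' Both thresholds are inclusive. Cells in FOVs without a leukemia cell
#' are excluded with a log entry.
#'
#' @param cells cell table.
#' @param polygons named polygon list keyed by cell_id.
#' @param close_um,far_um thresholds (defaults 5 and 30).
#' @param ref_type leukemia type label.
#' @return data.frame: cell_id, fov_id, cell_type, dist_um, group; the
#'   \code{"no_leukemia_fovs"} attribute lists skipped FOVs.
#' @export
assign_proximity_groups <- function(cells, polygons, close_um = 5,
                                    far_um = 30, ref_type = "leukemia") {
  out <- list(); skipped <- character(0)
  for (fov in unique(cells$fov_id)) {
    fc <- cells[cells$fov_id == fov, , drop = FALSE]
    ref <- fc$cell_id[fc$cell_type == ref_type]
    oth <- fc$cell_id[fc$cell_type != ref_type]
    if (length(ref) == 0L) {
      skipped <- c(skipped, fov)
      next
    }
    if (length(oth) == 0L) next
    d <- .cpp_min_dist_to_ref(polygons[oth], polygons[ref])
    grp <- rep("neither", length(d))
    grp[d <= close_um] <- "close"
    grp[d >= far_um] <- "far"
    out[[fov]] <- data.frame(
      cell_id = oth, fov_id = fov,
      cell_type = fc$cell_type[match(oth, fc$cell_id)],
      dist_um = d, group = grp, stringsAsFactors = FALSE)
  }
  res <- rbind_list(out)
  attr(res, "no_leukemia_fovs") <- skipped
  res
}

#' Pseudo-bulk mean expression per group
#'
#' Arithmetic mean of raw counts per gene within each (FOV x cell type)
#' group — the sparse-data aggregation used before any close/far testing.
#'
#' @param counts cells x genes matrix (rownames = cell ids).
#' @param cell_ids,fov,cell_type parallel vectors defining group membership.
#' @param genes genes to keep (default all).
#' @return data.frame: fov_id, cell_type, n_cells, then one column per
#'   gene with the group mean.
#' @export
pseudobulk <- function(counts, cell_ids, fov, cell_type, genes = colnames(counts)) {
  stopifnot(length(cell_ids) == length(fov), length(fov) == length(cell_type))
  genes <- intersect(genes, colnames(counts))
  key <- paste(fov, cell_type, sep = "\r")
  grp <- split(seq_along(cell_ids), key)
  rows <- lapply(names(grp), function(k) {
    i <- grp[[k]]
    mu <- colMeans(counts[cell_ids[i], genes, drop = FALSE])
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    cbind(data.frame(fov_id = parts[1L], cell_type = parts[2L],
                     n_cells = length(i), stringsAsFactors = FALSE),
          as.data.frame(as.list(mu), check.names = FALSE))
  })
  rbind_list(rows)
}

#' Leukemia-high genes within one FOV
#'
#' For each gene, takes the per-cell-type median expression within the FOV
#' and flags the gene when the leukemia median exceeds the mean of the
#' other types' medians by more than \code{k_sd} standard deviations of
#' those medians.
#'
#' @param type_medians types x genes matrix of per-type median expression
#'   for one FOV (rownames = cell types, leukemia included).
#' @param leukemia_type leukemia row name.
#' @param k_sd threshold in SD units (default 2).
#' @return character vector of flagged genes; genes flagged with a zero SD
#'   of the other types are reported in the \code{"zero_sd"} attribute.
#' @export
leukemia_high_genes <- function(type_medians, leukemia_type = "leukemia",
                                k_sd = 2) {
  if (!leukemia_type %in% rownames(type_medians))
    return(character(0))
  others <- type_medians[setdiff(rownames(type_medians), leukemia_type), ,
                         drop = FALSE]
  if (nrow(others) < 3L)
    stop("need >= 3 non-leukemia cell types in the FOV")
  mu <- colMeans(others)
  sd_ <- apply(others, 2L, stats::sd)
  leuk <- type_medians[leukemia_type, ]
  flagged <- leuk > mu + k_sd * sd_
  zero_sd <- names(flagged)[flagged & sd_ == 0]
  out <- names(flagged)[flagged]
  attr(out, "zero_sd") <- zero_sd
  out
}

#' Mann-Whitney U test between close and far per-FOV means
#'
#' Exact two-sided test for small samples without ties (the default of
#' \code{stats::wilcox.test}); normal approximation with tie correction
#' otherwise.
#'
#' @param close,far numeric vectors of per-FOV group means.
#' @return list: \code{U} statistic (close vs far), \code{p} two-sided.
#' @export
mann_whitney_close_far <- function(close, far) {
  if (length(close) == 0L || length(far) == 0L)
    stop("a proximity group is empty")
  wt <- suppressWarnings(stats::wilcox.test(close, far, exact = NULL))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Proximity-stratified ligand-receptor analysis
#'
#' For one patient-timepoint sample: anchor genes (from the ligand or the
#' receptor list, depending on \code{direction}) must be leukemia-high by
#' the k-SD rule in at least \code{persistence} of the sample's FOVs; for
#' every anchor's partner gene and every non-leukemia cell type, per-FOV
#' pseudo-bulk means of the partner gene are compared between the close and
#' far groups with the Mann-Whitney U test (FOVs as replicates), and
#' p-values are adjusted across all (cell type x gene) tests.
#'
#' @param cells cell table for one patient-timepoint sample.
#' @param polygons named polygon list.
#' @param counts cells x genes count matrix.
#' @param pairs ligand-receptor pair table ([read_lr_pairs()]).
#' @param direction \code{"ligand-on-leukemia"} (test receptors on other
#'   types) or \code{"receptor-on-leukemia"}.
#' @param close_um,far_um proximity thresholds (5 and 30 um).
#' @param k_sd leukemia-high threshold (default 2).
#' @param persistence fraction of FOVs in which an anchor must be flagged
#'   (default 0.5).
#' @param min_fovs minimum FOVs per proximity group for a test (default 2).
#' @param adjust_method p.adjust method (default "BH").
#' @param ref_type leukemia label.
#' @return data.frame of class \code{lr_result}: cell_type, anchor_gene,
#'   partner_gene, direction, n_close_fovs, n_far_fovs, mean_close,
#'   mean_far, U, p_raw, p_adj. Empty (0 rows) when no anchor qualifies.
#' @export
run_lr_analysis <- function(cells, polygons, counts, pairs,
                            direction = c("ligand-on-leukemia",
                                          "receptor-on-leukemia"),
                            close_um = 5, far_um = 30, k_sd = 2,
                            persistence = 0.5, min_fovs = 2,
                            adjust_method = "BH", ref_type = "leukemia") {
  direction <- match.arg(direction)
  empty <- data.frame(cell_type = character(0), anchor_gene = character(0),
                      partner_gene = character(0), direction = character(0),
                      n_close_fovs = integer(0), n_far_fovs = integer(0),
                      mean_close = numeric(0), mean_far = numeric(0),
                      U = numeric(0), p_raw = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  anchor_col <- if (direction == "ligand-on-leukemia") "ligand" else "receptor"
  partner_col <- setdiff(c("ligand", "receptor"), anchor_col)
  lr_genes <- intersect(unique(c(pairs$ligand, pairs$receptor)),
                        colnames(counts))
  pairs <- pairs[pairs$ligand %in% colnames(counts) &
                   pairs$receptor %in% colnames(counts), , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)

  # per-FOV leukemia-high anchors from per-type medians
  fovs <- unique(cells$fov_id)
  anchor_hits <- stats::setNames(integer(length(lr_genes)), lr_genes)
  n_eval <- 0L
  for (fov in fovs) {
    fc <- cells[cells$fov_id == fov, , drop = FALSE]
    types <- unique(fc$cell_type)
    if (!(ref_type %in% types) || length(setdiff(types, ref_type)) < 3L) next
    med <- t(vapply(types, function(tt) {
      apply(counts[fc$cell_id[fc$cell_type == tt], lr_genes, drop = FALSE],
            2L, stats::median)
    }, numeric(length(lr_genes))))
    rownames(med) <- types
    hi <- leukemia_high_genes(med, ref_type, k_sd)
    anchor_hits[hi] <- anchor_hits[hi] + 1L
    n_eval <- n_eval + 1L
  }
  if (n_eval == 0L) return(empty)
  anchors <- names(anchor_hits)[anchor_hits >= persistence * n_eval &
                                  anchor_hits > 0L]
  anchors <- intersect(anchors, pairs[[anchor_col]])
  if (length(anchors) == 0L) return(empty)

  prox <- assign_proximity_groups(cells, polygons, close_um, far_um, ref_type)
  prox <- prox[prox$group %in% c("close", "far"), , drop = FALSE]
  # pack fov and proximity group into the fov key; the separator must
  # differ from the one pseudobulk() uses internally
  pb <- pseudobulk(counts, prox$cell_id,
                   fov = paste(prox$fov_id, prox$group, sep = "\036"),
                   cell_type = prox$cell_type, genes = lr_genes)
  grp_parts <- strsplit(pb$fov_id, "\036", fixed = TRUE)
  pb$group <- vapply(grp_parts, `[`, "", 2L)
  pb$fov_id <- vapply(grp_parts, `[`, "", 1L)

  res <- list()
  tested_types <- setdiff(unique(prox$cell_type), ref_type)
  for (a in anchors) {
    partners <- unique(pairs[pairs[[anchor_col]] == a, partner_col])
    for (g in partners) {
      for (ct in tested_types) {
        cl <- pb[pb$cell_type == ct & pb$group == "close", g]
        fa <- pb[pb$cell_type == ct & pb$group == "far", g]
        if (length(cl) < min_fovs || length(fa) < min_fovs) next
        mw <- mann_whitney_close_far(cl, fa)
        res[[length(res) + 1L]] <- data.frame(
          cell_type = ct, anchor_gene = a, partner_gene = g,
          direction = direction, n_close_fovs = length(cl),
          n_far_fovs = length(fa), mean_close = mean(cl),
          mean_far = mean(fa), U = mw$U, p_raw = mw$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind_list(res)
  if (is.null(out)) return(empty)
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust_method)
  class(out) <- c("lr_result", "data.frame")
  out
}
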