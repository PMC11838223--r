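#' Assign transcript points to cell polygons
#'
#' Point-in-polygon assignment within one FOV coordinate frame; a point on
#' a shared boundary goes to the containing polygon with the lowest cell
#' id. Points outside every polygon are left unassigned and counted.
#'
#' @param transcripts data.frame with columns gene, x, y (micrometres,
#'   FOV-local).
#' @param polygons named list of vertex matrices keyed by cell_id; ids are
#'   sorted before assignment so the lowest id wins boundary ties.
#' @return list: \code{counts} (cells x genes matrix over assigned
#'   points), \code{assignment} (cell id per point, NA if unassigned),
#'   \code{n_unassigned}.
#' @export
assign_transcripts_to_cells <- function(transcripts, polygons) {
  ids <- sort(names(polygons))
  polys <- lapply(polygons[ids], check_polygon)
  hit <- .cpp_assign_points(transcripts$x, transcripts$y, polys)
  cell <- rep(NA_character_, length(hit))
  cell[hit > 0L] <- ids[hit[hit > 0L]]
  genes <- sort(unique(transcripts$gene))
  cnt <- matrix(0L, length(ids), length(genes), dimnames = list(ids, genes))
  ok <- !is.na(cell)
  if (any(ok)) {
    tab <- table(factor(cell[ok], levels = ids),
                 factor(transcripts$gene[ok], levels = genes))
    cnt[] <- as.integer(tab)
  }
  list(counts = cnt, assignment = cell, n_unassigned = sum(!ok))
}

#' Run the full niche analysis pipeline
#'
#' Orchestrates QC filtering, (optional) two-round cell typing,
#' ring-neighborhood counting with the Poisson mixed model contrasts, the
#' per-patient density-shift tests, and the per-sample ligand-receptor
#' analysis, writing every stage output as CSV and returning a manifest.
#'
#' @param tissue a \code{niche_tissue} (or list with the same components:
#'   cells, polygons, counts, neg_counts).
#' @param out_dir output directory for stage CSVs (NULL = no files).
#' @param use_given_types if TRUE (default) the cell table's types are
#'   used and the typing stage is skipped; if FALSE, types are re-derived
#'   with [type_cells()] per sample.
#' @param ring_spec ring boundaries for the neighborhood model.
#' @param qc QC thresholds, list(min_transcripts = 20,
#'   min_cells_per_fov = 300).
#' @param density_query query type for the density-shift stage (NULL skips
#'   the stage).
#' @param timepoints timepoint pair analyzed.
#' @param lr_pairs ligand-receptor pair table (NULL skips the stage).
#' @param J,seed permutation settings for the density-shift stage.
#' @param leukemia_type index/reference cell type.
#' @return list of class \code{niche_pipeline}: \code{manifest} plus the
#'   stage results (\code{qc_cells}, \code{typing}, \code{enrichment},
#'   \code{density}, \code{lr}).
#' @export
run_pipeline <- function(tissue, out_dir = NULL, use_given_types = TRUE,
                         ring_spec = nicheshift::ring_spec(),
                         qc = list(min_transcripts = 20, min_cells_per_fov = 300),
                         density_query = NULL, timepoints = c("A", "B"),
                         lr_pairs = NULL, J = 100, seed = 1L,
                         leukemia_type = "leukemia") {
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("nicheshift")),
                   stages = list())
  emit <- function(name, df) {
    if (!is.null(out_dir) && !is.null(df) && nrow(df)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  cells <- qc_filter(tissue$cells, qc$min_transcripts, qc$min_cells_per_fov)
  manifest$stages$qc <- c(list(n_in = nrow(tissue$cells), n_out = nrow(cells)),
                          attr(cells, "removal_log"))
  emit("qc_cells", cells)

  typing <- NULL
  if (!use_given_types) {
    samples <- unique(cells[, c("patient_id", "timepoint")])
    assigned <- character(0)
    for (k in seq_len(nrow(samples))) {
      sel <- cells$patient_id == samples$patient_id[k] &
        cells$timepoint == samples$timepoint[k]
      ids <- cells$cell_id[sel & cells$cell_type != leukemia_type]
      if (length(ids) == 0L) next
      tr <- type_cells(tissue$counts[ids, , drop = FALSE],
                       tissue$neg_counts[ids, , drop = FALSE])
      assigned <- c(assigned, tr$assigned)
    }
    cells$cell_type[match(names(assigned), cells$cell_id)] <- assigned
    typing <- assigned
    manifest$stages$typing <- list(n_typed = length(assigned))
  } else {
    manifest$stages$typing <- list(skipped = TRUE,
                                   reason = "cell types supplied in input")
  }

  counts_tab <- neighborhood_counts(cells, tissue$polygons,
                                    index_type = leukemia_type,
                                    spec = ring_spec)
  manifest$stages$neighborhood <- list(
    n_rows = nrow(counts_tab),
    skipped_fovs = attr(counts_tab, "skipped_fovs"))
  emit("neighborhood_counts", as.data.frame(counts_tab))

  enrich <- tryCatch(niche_enrichment(counts_tab, timepoints = timepoints),
                     error = function(e) NULL)
  manifest$stages$enrichment <- list(
    n_contrasts = if (is.null(enrich)) 0L else nrow(enrich))
  emit("enrichment", enrich)

  dens <- NULL
  if (!is.null(density_query)) {
    dens <- list()
    for (p in unique(cells$patient_id)) {
      pc <- cells[cells$patient_id == p, , drop = FALSE]
      dens[[p]] <- tryCatch(
        density_shift_test(pc, tissue$polygons, density_query,
                           timepoints = timepoints, ref_type = leukemia_type,
                           J = J, seed = seed),
        error = function(e) NULL)
      if (!is.null(dens[[p]]))
        emit(paste0("density_shift_", p),
             data.frame(x = dens[[p]]$x, S = dens[[p]]$S,
                        perm_mean = dens[[p]]$perm_mean,
                        perm_sd = dens[[p]]$perm_sd,
                        flag = dens[[p]]$flag))
    }
    manifest$stages$density <- list(patients = names(dens))
  }

  lr <- NULL
  if (!is.null(lr_pairs)) {
    lr <- list()
    samples <- unique(cells[, c("patient_id", "timepoint")])
    for (k in seq_len(nrow(samples))) {
      sel <- cells$patient_id == samples$patient_id[k] &
        cells$timepoint == samples$timepoint[k]
      key <- paste(samples$patient_id[k], samples$timepoint[k], sep = "_")
      lr[[key]] <- tryCatch(
        run_lr_analysis(cells[sel, , drop = FALSE], tissue$polygons,
                        tissue$counts, lr_pairs,
                        ref_type = leukemia_type),
        error = function(e) NULL)
    }
    lr_all <- rbind_list(Map(function(r, k) {
      if (is.null(r) || nrow(r) == 0L) return(NULL)
      r$sample <- k
      r
    }, lr, names(lr)))
    emit("lr_results", lr_all)
    manifest$stages$lr <- list(n_tests = if (is.null(lr_all)) 0L else nrow(lr_all))
  }

  structure(list(manifest = manifest, qc_cells = cells, typing = typing,
                 neighborhood = counts_tab, enrichment = enrich,
                 density = dens, lr = lr),
            class = "niche_pipeline")
}

#' @export
print.niche_pipeline <- function(x, ...) {
  cat("niche_pipeline run\n")
  utils::str(x$manifest$stages, max.level = 2, give.attr = FALSE)
  invisible(x)
}
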