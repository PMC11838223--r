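#' Configuration for a synthetic multi-FOV tissue
#'
#' Describes a synthetic bone-marrow-like tissue: patients with responder /
#' nonresponder labels, timepoints per patient, fields of view (FOVs) of
#' CosMx-like dimensions, a cell-type mixture around a designated leukemia
#' type, per-type Poisson expression profiles, negative-control probes, and
#' optional planted structure (proximity enrichment of a type near leukemia
#' cells, and ligand-receptor expression elevated in cells close to
#' leukemia).
#'
#' @param n_patients number of patients.
#' @param timepoints character vector of timepoint labels (default A =
#'   baseline, B = post-ICI, C = post-combination).
#' @param response_map named character vector patient -> "responder" /
#'   "nonresponder"; default alternates, first patient responder.
#' @param fovs_per_sample FOVs per (patient, timepoint) sample.
#' @param fov_width_um,fov_height_um FOV dimensions in micrometres
#'   (defaults 985 x 657, the CosMx SMI field of view).
#' @param n_cells_per_fov target number of cells per FOV.
#' @param type_proportions named numeric vector of cell-type fractions,
#'   summing to 1; must include \code{leukemia_type}.
#' @param leukemia_type name of the leukemia cell type.
#' @param enrichment_spec optional list of entries
#'   \code{list(cell_type=, timepoint=, response=, max_dist_um=,
#'   multiplier=)}: within matching FOVs, cells of \code{cell_type} are
#'   placed preferentially at edge distance \code{<= max_dist_um} from the
#'   nearest leukemia cell with relative weight \code{multiplier}, keeping
#'   the per-FOV type proportions fixed. \code{timepoint}/\code{response}
#'   may be NULL to match all.
#' @param expression_profiles genes x types matrix of Poisson mean counts
#'   per cell; default [default_expression_profiles()] on the configured
#'   types.
#' @param n_negative_probes number of negative-control probes.
#' @param negative_probe_rate Poisson mean count per probe per cell
#'   (default 0.05, the sparse-background regime of a ~1000-plex panel).
#' @param lr_signal_spec optional list of entries \code{list(gene=,
#'   cell_type=, fold=, max_dist_um=5)}: the gene's Poisson mean is
#'   multiplied by \code{fold} in cells of the type within
#'   \code{max_dist_um} of a leukemia cell.
#' @param seed integer RNG seed; the full generator is deterministic given
#'   the seed.
#' @return A validated list of class \code{tissue_config}.
#' @export
tissue_config <- function(n_patients = 2,
                          timepoints = c("A", "B"),
                          response_map = NULL,
                          fovs_per_sample = 3,
                          fov_width_um = 985,
                          fov_height_um = 657,
                          n_cells_per_fov = 800,
                          type_proportions = default_type_proportions(),
                          leukemia_type = "leukemia",
                          enrichment_spec = list(),
                          expression_profiles = NULL,
                          n_negative_probes = 10,
                          negative_probe_rate = 0.05,
                          lr_signal_spec = list(),
                          seed = 1L) {
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1")
  if (any(type_proportions < 0)) stop("type_proportions must be nonnegative")
  if (fov_width_um <= 0 || fov_height_um <= 0) stop("FOV dimensions must be > 0")
  if (n_cells_per_fov < 1) stop("n_cells_per_fov must be >= 1")
  if (!leukemia_type %in% names(type_proportions))
    stop("type_proportions must include the leukemia type")
  patients <- paste0("P", seq_len(n_patients))
  if (is.null(response_map)) {
    response_map <- stats::setNames(
      ifelse(seq_len(n_patients) %% 2 == 1, "responder", "nonresponder"),
      patients)
  }
  if (!all(patients %in% names(response_map)))
    stop("response_map must cover every patient")
  if (is.null(expression_profiles))
    expression_profiles <- default_expression_profiles(names(type_proportions))
  missing_types <- setdiff(names(type_proportions), colnames(expression_profiles))
  if (length(missing_types))
    stop("expression_profiles missing types: ", paste(missing_types, collapse = ", "))
  structure(list(
    n_patients = n_patients, timepoints = timepoints,
    response_map = response_map, fovs_per_sample = fovs_per_sample,
    fov_width_um = fov_width_um, fov_height_um = fov_height_um,
    n_cells_per_fov = n_cells_per_fov, type_proportions = type_proportions,
    leukemia_type = leukemia_type, enrichment_spec = enrichment_spec,
    expression_profiles = expression_profiles,
    n_negative_probes = n_negative_probes,
    negative_probe_rate = negative_probe_rate,
    lr_signal_spec = lr_signal_spec, seed = as.integer(seed)),
    class = "tissue_config")
}

#' Default cell-type mixture for synthetic marrow
#'
#' Leukemia-rich relapsed/refractory marrow composition; fractions are
#' calibration choices for a plausible blast-rich biopsy, not measurements.
#' @return named numeric vector summing to 1.
#' @export
default_type_proportions <- function() {
  c(leukemia = 0.25, erythroid = 0.20, CD14_monocyte = 0.15,
    monocyte_progenitor = 0.10, T_CD4_naive = 0.10, T_CD8 = 0.10,
    DC = 0.05, B = 0.05)
}

#' Default marker-gene map
#'
#' Marker genes per cell type for the two-round typing workflow. Round 1
#' carries the broad types (both T subtypes collapse to "T cell"); round 2
#' refines lymphocytes using CD4/CD8/naive/cytotoxic and B-cell markers.
#'
#' @param round 1 (broad types) or 2 (lymphocyte subtypes).
#' @return named list: cell type -> character vector of marker genes.
#' @export
default_marker_map <- function(round = 1) {
  if (round == 1) {
    list(
      erythroid = c("HBB", "HBA1"),
      megakaryocyte = c("PF4", "PPBP"),
      DC = c("IL3RA"),
      CD14_monocyte = c("CD14", "S100A9", "CSF3R"),
      monocyte_progenitor = c("MPO", "ELANE"),
      NK = c("GNLY", "NKG7"),
      `T cell` = c("CD3E", "CD3D", "CD3G"),
      `B cell` = c("CD19", "CD79A"))
  } else {
    list(
      T_CD4_naive = c("CD4", "IL7R", "CCR7"),
      T_CD8 = c("CD8A", "CD8B", "GZMH", "GZMK"),
      B = c("MS4A1", "TCL1A", "JCHAIN"))
  }
}

# broad round-1 label for each generator truth type
broad_type_of <- function(types) {
  out <- types
  out[types %in% c("T_CD4_naive", "T_CD8")] <- "T cell"
  out[types %in% c("B")] <- "B cell"
  out
}

#' Default per-type expression profiles
#'
#' Builds a genes x types Poisson-mean matrix: each type expresses its
#' marker genes at a high mean, a shared background block of housekeeping
#' genes at a moderate mean, and other types' markers at a leak rate. The
#' defaults give a median depth of roughly 100 counts per cell, the sparse
#' regime typical of ~1000-plex in situ panels.
#'
#' @param types character vector of cell types to build columns for.
#' @param marker_mean Poisson mean for a type's own markers.
#' @param background_mean mean for the shared background genes.
#' @param leak_mean mean for other types' markers.
#' @param n_background number of shared background genes.
#' @return genes x types numeric matrix.
#' @export
default_expression_profiles <- function(types,
                                        marker_mean = 6,
                                        background_mean = 2,
                                        leak_mean = 0.05,
                                        n_background = 40) {
  mm1 <- default_marker_map(1)
  mm2 <- default_marker_map(2)
  marker_of <- c(mm1, mm2)
  # leukemia pseudo-markers: blast-associated transcripts incl. the TWEAK
  # ligand used by the proximity ligand-receptor analysis
  marker_of$leukemia <- c("CD34", "TNFSF12")
  extra <- c("TNFRSF12A")
  genes <- unique(c(unlist(marker_of), extra,
                    sprintf("BG%02d", seq_len(n_background))))
  prof <- matrix(leak_mean, nrow = length(genes), ncol = length(types),
                 dimnames = list(genes, types))
  prof[grep("^BG", genes), ] <- background_mean
  prof["TNFRSF12A", ] <- 0.5
  for (t in types) {
    own <- character(0)
    if (t %in% names(marker_of)) own <- marker_of[[t]]
    bt <- broad_type_of(t)
    if (bt %in% names(marker_of)) own <- c(own, marker_of[[bt]])
    prof[intersect(own, genes), t] <- marker_mean
  }
  prof
}

# --- polygon tessellation -------------------------------------------------

# Sutherland-Hodgman half-plane clip: keep points p with (p - q) . nv <= 0.
clip_halfplane <- function(poly, q, nv) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- (poly[, 1L] - q[1L]) * nv[1L] + (poly[, 2L] - q[2L]) * nv[2L]
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { keep_x <- c(keep_x, poly[i, 1L]); keep_y <- c(keep_y, poly[i, 2L]) }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      keep_x <- c(keep_x, poly[i, 1L] + t * (poly[j, 1L] - poly[i, 1L]))
      keep_y <- c(keep_y, poly[i, 2L] + t * (poly[j, 2L] - poly[i, 2L]))
    }
  }
  cbind(keep_x, keep_y, deparse.level = 0)
}

# Voronoi-like convex cell around center `ctr`: the FOV rectangle clipped by
# the perpendicular bisector of every nearby neighbor, then trimmed to a
# regular 16-gon of radius max_radius. Guarantees pairwise-disjoint
# interiors (Voronoi property) with shared edges where cells touch.
voronoi_cell <- function(ctr, neighbors, width, height, max_radius) {
  ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
  poly <- cbind(ctr[1L] + max_radius * cos(ang),
                ctr[2L] + max_radius * sin(ang))
  poly <- clip_halfplane(poly, c(0, 0), c(-1, 0))
  poly <- clip_halfplane(poly, c(width, 0), c(1, 0))
  poly <- clip_halfplane(poly, c(0, 0), c(0, -1))
  poly <- clip_halfplane(poly, c(0, height), c(0, 1))
  if (length(neighbors)) {
    for (k in seq_len(nrow(neighbors))) {
      m <- neighbors[k, ]
      mid <- (ctr + m) / 2
      poly <- clip_halfplane(poly, mid, m - ctr)
      if (nrow(poly) < 3L) break
    }
  }
  poly
}

# Jittered hexagonal centers + Voronoi polygons for one FOV.
generate_fov_polygons <- function(n_cells, width, height,
                                  min_cell_area = 25) {
  if (n_cells * min_cell_area > width * height)
    stop("infeasible packing: ", n_cells, " cells cannot fit a ",
         width, " x ", height, " um FOV")
  # 8% tighter pitch than the exact hexagonal packing so the grid yields a
  # surplus of candidate centers after edge trimming
  spacing <- sqrt(width * height / n_cells / (sqrt(3) / 2)) / 1.08
  dy <- spacing * sqrt(3) / 2
  rows <- ceiling(height / dy) + 1L
  cols <- ceiling(width / spacing) + 1L
  cx <- c(); cy <- c()
  for (r in seq_len(rows)) {
    off <- if (r %% 2 == 0) spacing / 2 else 0
    cx <- c(cx, (seq_len(cols) - 0.5) * spacing + off)
    cy <- c(cy, rep((r - 0.5) * dy, cols))
  }
  jit <- 0.22 * spacing
  cx <- cx + stats::runif(length(cx), -jit, jit)
  cy <- cy + stats::runif(length(cy), -jit, jit)
  inb <- cx > 0.1 & cx < width - 0.1 & cy > 0.1 & cy < height - 0.1
  cx <- cx[inb]; cy <- cy[inb]
  if (length(cx) < n_cells)
    stop("infeasible packing: grid produced too few candidate centers")
  keep <- sort(sample.int(length(cx), n_cells))
  centers <- cbind(cx[keep], cy[keep])
  max_radius <- 0.9 * spacing
  polys <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    dx <- centers[, 1L] - centers[i, 1L]
    dyv <- centers[, 2L] - centers[i, 2L]
    near <- which(dx * dx + dyv * dyv <= (2 * max_radius)^2)
    near <- near[near != i]
    polys[[i]] <- voronoi_cell(centers[i, ], centers[near, , drop = FALSE],
                               width, height, max_radius)
  }
  list(centers = centers, polygons = polys)
}

# Assign cell types within one FOV: leukemia cells uniformly at random, then
# remaining types with fixed per-FOV counts; enriched types are drawn with
# distance-dependent weights so proximity structure is planted without
# changing abundance.
assign_fov_types <- function(polys, props, leukemia_type, specs) {
  n <- length(polys)
  counts <- round(props * n)
  # fix rounding drift on the most abundant type
  counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
  types <- character(n)
  leuk_n <- counts[[leukemia_type]]
  leuk_idx <- sample.int(n, leuk_n)
  types[leuk_idx] <- leukemia_type
  rest <- setdiff(seq_len(n), leuk_idx)
  if (leuk_n > 0 && length(rest) > 0) {
    d <- .cpp_min_dist_to_ref(polys[rest], polys[leuk_idx])
  } else {
    d <- rep(Inf, length(rest))
  }
  other_types <- setdiff(names(counts), leukemia_type)
  enriched <- intersect(vapply(specs, `[[`, "", "cell_type"), other_types)
  ord <- c(intersect(other_types, enriched), setdiff(other_types, enriched))
  avail <- rep(TRUE, length(rest))
  for (t in ord) {
    k <- counts[[t]]
    if (k == 0) next
    cand <- which(avail)
    if (k > length(cand)) k <- length(cand)
    s <- Filter(function(x) x$cell_type == t, specs)
    if (length(s)) {
      # allocate the type's fixed count between the near and far zones so
      # the realized near:far rate ratio equals the multiplier exactly
      s <- s[[1L]]
      near <- cand[d[cand] <= s$max_dist_um]
      far <- setdiff(cand, near)
      k_near <- round(k * s$multiplier * length(near) /
                        (s$multiplier * length(near) + length(far)))
      k_near <- min(k_near, length(near))
      pick <- c(if (k_near > 0) sample(near, k_near),
                if (k - k_near > 0) sample(far, min(k - k_near, length(far))))
    } else {
      pick <- sample(cand, k)
    }
    types[rest[pick]] <- t
    avail[pick] <- FALSE
  }
  types[types == ""] <- other_types[length(other_types)]
  types
}

#' Simulate a multi-FOV synthetic tissue
#'
#' Generates non-overlapping convex cell polygons (jittered hexagonal
#' centers with Voronoi-clipped boundaries, so that neighboring cells share
#' edges and the touching-neighbor statistic is exercised), assigns cell
#' types with optional planted proximity enrichment around leukemia cells,
#' and draws per-gene Poisson counts from the type's expression profile,
#' with negative-control probes from a common background rate.
#'
#' @param config a [tissue_config()].
#' @param make_transcripts if TRUE, also scatter each cell's transcripts
#'   uniformly inside its polygon and return a point table.
#' @return An object of class \code{niche_tissue}: list with \code{cells}
#'   (data.frame: cell_id, fov_id, patient_id, timepoint, response,
#'   cell_type, area_um2, total_counts), \code{polygons} (named list of
#'   vertex matrices), \code{counts} (cells x genes integer matrix),
#'   \code{neg_counts} (cells x negative probes), \code{transcripts}
#'   (data.frame or NULL) and \code{config}.
#' @export
simulate_tissue <- function(config, make_transcripts = FALSE) {
  stopifnot(inherits(config, "tissue_config"))
  set.seed(config$seed)
  genes <- rownames(config$expression_profiles)
  cells_list <- list(); polys_all <- list(); counts_list <- list()
  neg_list <- list(); tx_list <- list()
  for (p in paste0("P", seq_len(config$n_patients))) {
    resp <- config$response_map[[p]]
    for (tp in config$timepoints) {
      for (f in seq_len(config$fovs_per_sample)) {
        fov_id <- sprintf("%s_%s_f%02d", p, tp, f)
        g <- generate_fov_polygons(config$n_cells_per_fov,
                                   config$fov_width_um, config$fov_height_um)
        specs <- Filter(function(s) {
          (is.null(s$timepoint) || s$timepoint == tp) &&
            (is.null(s$response) || s$response == resp)
        }, config$enrichment_spec)
        types <- assign_fov_types(g$polygons, config$type_proportions,
                                  config$leukemia_type, specs)
        n <- length(types)
        ids <- sprintf("%s_c%04d", fov_id, seq_len(n))
        names(g$polygons) <- ids
        # expression
        lam <- t(config$expression_profiles[, types, drop = FALSE])
        if (length(config$lr_signal_spec)) {
          leuk <- which(types == config$leukemia_type)
          nonleuk <- which(types != config$leukemia_type)
          if (length(leuk) && length(nonleuk)) {
            d <- .cpp_min_dist_to_ref(g$polygons[nonleuk], g$polygons[leuk])
            for (s in config$lr_signal_spec) {
              md <- if (is.null(s$max_dist_um)) 5 else s$max_dist_um
              tgt <- nonleuk[types[nonleuk] == s$cell_type & d <= md]
              if (length(tgt) && s$gene %in% genes)
                lam[tgt, s$gene] <- lam[tgt, s$gene] * s$fold
            }
          }
        }
        cnt <- matrix(stats::rpois(length(lam), lam), nrow = n,
                      dimnames = list(ids, genes))
        neg <- matrix(stats::rpois(n * config$n_negative_probes,
                                   config$negative_probe_rate),
                      nrow = n,
                      dimnames = list(ids, sprintf("NegPrb%02d",
                                      seq_len(config$n_negative_probes))))
        area <- vapply(g$polygons, polygon_area, numeric(1))
        cells_list[[fov_id]] <- data.frame(
          cell_id = ids, fov_id = fov_id, patient_id = p, timepoint = tp,
          response = resp, cell_type = types, area_um2 = unname(area),
          total_counts = unname(rowSums(cnt)), stringsAsFactors = FALSE)
        polys_all <- c(polys_all, g$polygons)
        counts_list[[fov_id]] <- cnt
        neg_list[[fov_id]] <- neg
        if (make_transcripts)
          tx_list[[fov_id]] <- scatter_transcripts(cnt, g$polygons, fov_id)
      }
    }
  }
  structure(list(
    cells = rbind_list(cells_list),
    polygons = polys_all,
    counts = do.call(rbind, counts_list),
    neg_counts = do.call(rbind, neg_list),
    transcripts = if (make_transcripts)
      rbind_list(tx_list) else NULL,
    config = config), class = "niche_tissue")
}

# uniform points inside a polygon by bbox rejection sampling
sample_in_polygon <- function(poly, k) {
  if (k == 0L) return(matrix(numeric(0), 0L, 2L))
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  out <- matrix(numeric(0), 0L, 2L)
  while (nrow(out) < k) {
    m <- max(2L * (k - nrow(out)), 8L)
    px <- stats::runif(m, xr[1L], xr[2L])
    py <- stats::runif(m, yr[1L], yr[2L])
    hit <- .cpp_assign_points(px, py, list(poly)) == 1L
    out <- rbind(out, cbind(px[hit], py[hit]))
  }
  out[seq_len(k), , drop = FALSE]
}

scatter_transcripts <- function(cnt, polygons, fov_id) {
  rows <- list()
  for (i in seq_len(nrow(cnt))) {
    tot <- sum(cnt[i, ])
    if (tot == 0L) next
    pts <- sample_in_polygon(polygons[[i]], tot)
    rows[[i]] <- data.frame(
      fov_id = fov_id, gene = rep(colnames(cnt), cnt[i, ]),
      x = pts[, 1L], y = pts[, 2L], cell_id = rownames(cnt)[i],
      stringsAsFactors = FALSE)
  }
  rbind_list(rows)
}

#' @export
print.niche_tissue <- function(x, ...) {
  cat("niche_tissue:", nrow(x$cells), "cells,",
      length(unique(x$cells$fov_id)), "FOVs,",
      ncol(x$counts), "genes\n")
  print(table(x$cells$cell_type))
  invisible(x)
}

#' Simulate a neighborhood count table directly
#'
#' Generates the (index cell x ring) count table for a single query cell
#' type straight from the Poisson mixed model it is meant to be analyzed
#' with: counts are Poisson with mean
#' \code{ring_total * base_rate * exp(u_fov)} times a planted rate ratio in
#' the responder post-treatment group. This gives an exact
#' parameter-recovery oracle for the model fit without going through tissue
#' geometry.
#'
#' @param n_fovs_per_group FOVs per (response, timepoint) combination.
#' @param n_index_per_fov index (leukemia) cells per FOV.
#' @param ring_total_means Poisson means of the per-ring neighborhood sizes,
#'   one per ring (roughly proportional to ring areas).
#' @param base_rate baseline fraction of the neighborhood belonging to the
#'   query type.
#' @param rr planted rate ratio applied to responder cells at timepoint B.
#' @param re_sd standard deviation of the FOV-level log-normal random
#'   intercept.
#' @param timepoints,responses factor levels simulated.
#' @return data.frame in neighborhood-count-table shape (single cell type
#'   \code{"query"}).
#' @export
simulate_neighborhood_counts <- function(n_fovs_per_group = 5,
                                         n_index_per_fov = 50,
                                         ring_total_means = c(6, 20, 40, 60, 80),
                                         base_rate = 0.1,
                                         rr = 1,
                                         re_sd = 0.3,
                                         timepoints = c("A", "B"),
                                         responses = c("nonresponder", "responder")) {
  rows <- list()
  n_rings <- length(ring_total_means)
  fov_i <- 0L
  for (resp in responses) for (tp in timepoints) {
    for (f in seq_len(n_fovs_per_group)) {
      fov_i <- fov_i + 1L
      fov <- sprintf("F%03d", fov_i)
      u <- stats::rnorm(1, 0, re_sd)
      eff <- if (resp == "responder" && tp == "B") rr else 1
      idx <- rep(sprintf("%s_i%03d", fov, seq_len(n_index_per_fov)),
                 each = n_rings)
      ring <- rep(seq_len(n_rings) - 1L, n_index_per_fov)
      rt <- stats::rpois(length(ring), ring_total_means[ring + 1L])
      cnt <- stats::rpois(length(ring), rt * base_rate * exp(u) * eff)
      rows[[fov]] <- data.frame(
        index_cell_id = idx, ring = ring, cell_type = "query",
        count = cnt, ring_total = rt, fov_id = fov,
        patient_id = paste0("P_", resp), timepoint = tp, response = resp,
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind_list(rows)
  class(out) <- c("neighborhood_counts", "data.frame")
  out
}

#' Write a tissue to plain-text files
#'
#' Cells as CSV with the boundary polygon in WKT, counts as CSV, the
#' transcript point table (if present) as CSV, and the configuration as
#' YAML.
#'
#' @param tissue a \code{niche_tissue}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tissue <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- tissue$cells
  cells$polygon_wkt <- vapply(tissue$polygons[cells$cell_id],
                              polygon_to_wkt, character(1))
  paths <- c(cells = file.path(dir, "cells.csv"),
             counts = file.path(dir, "counts.csv"),
             config = file.path(dir, "config.yaml"))
  utils::write.csv(cells, paths["cells"], row.names = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(tissue$counts),
                              tissue$counts, check.names = FALSE),
                   paths["counts"], row.names = FALSE)
  cfg <- tissue$config
  cfg$expression_profiles <- NULL
  yaml::write_yaml(unclass(cfg), paths["config"])
  if (!is.null(tissue$transcripts)) {
    paths["transcripts"] <- file.path(dir, "transcripts.csv")
    utils::write.csv(tissue$transcripts, paths["transcripts"], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a cell table written by [write_tissue()]
#' @param path cells.csv path.
#' @return list(cells = data.frame, polygons = named list).
#' @export
read_cell_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  polys <- lapply(cells$polygon_wkt, wkt_to_polygon)
  names(polys) <- cells$cell_id
  cells$polygon_wkt <- NULL
  list(cells = cells, polygons = polys)
}
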