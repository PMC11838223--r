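#' Select reference cells by exclusive marker expression
#'
#' A cell is a reference for type t when at least one marker of t has a
#' nonzero count and no marker of any other type in the map does. Cells
#' expressing markers of two or more types, or no markers at all, are
#' excluded. Intended to run within one sample.
#'
#' @param counts cells x genes matrix.
#' @param markers named list: cell type -> marker gene vector.
#' @return named character vector cell_id -> reference type (only the
#'   reference cells). Types that end with zero reference cells are
#'   reported via warning.
#' @export
select_reference_cells <- function(counts, markers) {
  marker_genes <- lapply(markers, intersect, y = colnames(counts))
  hit <- vapply(marker_genes, function(g) {
    if (length(g) == 0L) return(rep(FALSE, nrow(counts)))
    rowSums(counts[, g, drop = FALSE]) > 0
  }, logical(nrow(counts)))
  n_types <- rowSums(hit)
  ref <- which(n_types == 1L)
  type <- colnames(hit)[apply(hit[ref, , drop = FALSE], 1L, which.max)]
  missing <- setdiff(names(markers), unique(type))
  if (length(missing))
    warning("no reference cells for: ", paste(missing, collapse = ", "))
  stats::setNames(type, rownames(counts)[ref])
}

#' Build reference expression profiles from reference cells
#'
#' Per-type mean expression over all panel genes (not only markers), plus
#' the negative-control background: the mean count per negative probe per
#' cell across all cells.
#'
#' @param counts cells x genes matrix.
#' @param reference named vector from [select_reference_cells()].
#' @param neg_counts cells x negative-probes matrix (optional; background
#'   0 if absent).
#' @return list of class \code{reference_profile}: \code{profiles} (genes
#'   x types), \code{background} (scalar), \code{n_ref} per type.
#' @export
build_reference_profiles <- function(counts, reference, neg_counts = NULL) {
  types <- sort(unique(reference))
  prof <- vapply(types, function(t) {
    colMeans(counts[names(reference)[reference == t], , drop = FALSE])
  }, numeric(ncol(counts)))
  rownames(prof) <- colnames(counts)
  b <- if (is.null(neg_counts)) 0 else mean(neg_counts)
  structure(list(profiles = prof, background = b,
                 n_ref = table(reference)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("reference_profile:", nrow(x$profiles), "genes x",
      ncol(x$profiles), "types; background =", signif(x$background, 3), "\n")
  print(x$n_ref)
  invisible(x)
}

#' Assign cell types by Poisson posterior probability
#'
#' Independent-Poisson likelihood per cell and candidate type: the type
#' profile is scaled to the cell's total count and the negative-control
#' background is added per gene, so the per-gene rate is
#' \code{s * lambda_g + b} with \code{s = total(cell) / sum(lambda)}. The
#' posterior is the prior times the likelihood, normalized over types; the
#' assigned type is the posterior argmax.
#'
#' @param counts cells x genes matrix.
#' @param profiles a \code{reference_profile} (or plain genes x types
#'   matrix, background 0).
#' @param prior named prior over types (default uniform).
#' @return object of class \code{typing_result}: \code{posterior} (cells x
#'   types), \code{assigned} (named character), \code{flagged_zero}
#'   (cells with zero counts, given a uniform posterior).
#' @export
assign_types <- function(counts, profiles, prior = NULL) {
  if (inherits(profiles, "reference_profile")) {
    b <- profiles$background
    prof <- profiles$profiles
  } else {
    b <- 0
    prof <- profiles
  }
  genes <- intersect(rownames(prof), colnames(counts))
  prof <- prof[genes, , drop = FALSE]
  x <- counts[, genes, drop = FALSE]
  types <- colnames(prof)
  if (is.null(prior))
    prior <- stats::setNames(rep(1 / length(types), length(types)), types)
  tot <- rowSums(x)
  colsum <- colSums(prof)
  ll <- matrix(NA_real_, nrow(x), length(types),
               dimnames = list(rownames(x), types))
  for (t in types) {
    s <- tot / colsum[t]
    lam <- outer(s, prof[, t]) + b          # cells x genes rates
    lam[lam <= 0] <- 1e-12
    ll[, t] <- rowSums(x * log(lam) - lam) + log(prior[t])
  }
  zero <- tot == 0
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  post[zero, ] <- 1 / length(types)
  assigned <- types[max.col(post, ties.method = "first")]
  structure(list(posterior = post,
                 assigned = stats::setNames(assigned, rownames(x)),
                 flagged_zero = rownames(x)[zero],
                 round = 1L),
            class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat("typing_result (round", x$round, "):", length(x$assigned), "cells\n")
  print(table(x$assigned))
  invisible(x)
}

#' Two-round cell typing within a sample
#'
#' Round 1 selects reference cells on the broad marker map, builds
#' profiles, and assigns broad types to every cell. Round 2 repeats the
#' identical machinery restricted to the round-1 T/B lymphocytes with the
#' lymphocyte-subtype marker map; non-lymphocytes are never relabeled.
#'
#' @param counts cells x genes matrix for one sample.
#' @param neg_counts negative-probe matrix (optional).
#' @param markers_round1 broad marker map (default
#'   [default_marker_map]\code{(1)}).
#' @param markers_round2 lymphocyte marker map (default
#'   [default_marker_map]\code{(2)}); NULL skips round 2.
#' @param lymphocyte_types round-1 labels refined in round 2.
#' @return \code{typing_result} with \code{assigned} holding the final
#'   (round-2-refined) labels and \code{round1} the broad labels.
#' @export
type_cells <- function(counts, neg_counts = NULL,
                       markers_round1 = default_marker_map(1),
                       markers_round2 = default_marker_map(2),
                       lymphocyte_types = c("T cell", "B cell")) {
  ref1 <- select_reference_cells(counts, markers_round1)
  prof1 <- build_reference_profiles(counts, ref1, neg_counts)
  res1 <- assign_types(counts, prof1)
  out <- res1
  out$round1 <- res1$assigned
  if (!is.null(markers_round2)) {
    lymph <- names(res1$assigned)[res1$assigned %in% lymphocyte_types]
    if (length(lymph)) {
      res2 <- refine_lymphocytes(counts[lymph, , drop = FALSE],
                                 if (is.null(neg_counts)) NULL else
                                   neg_counts[lymph, , drop = FALSE],
                                 markers_round2)
      if (!is.null(res2)) {
        out$assigned[names(res2$assigned)] <- res2$assigned
        out$round <- 2L
        out$posterior2 <- res2$posterior
      }
    }
  }
  out
}

#' Round-2 lymphocyte refinement
#'
#' Reference selection, profile construction and posterior assignment run
#' on the lymphocyte subset with the subtype marker map.
#'
#' @param counts lymphocyte cells x genes matrix.
#' @param neg_counts matching negative-probe matrix (optional).
#' @param markers subtype marker map.
#' @return \code{typing_result} for the lymphocytes, or NULL when no
#'   subtype reference cells exist.
#' @export
refine_lymphocytes <- function(counts, neg_counts = NULL,
                               markers = default_marker_map(2)) {
  if (nrow(counts) == 0L) return(NULL)
  ref <- suppressWarnings(select_reference_cells(counts, markers))
  if (length(ref) == 0L) return(NULL)
  prof <- build_reference_profiles(counts, ref, neg_counts)
  res <- assign_types(counts, prof)
  res$round <- 2L
  res
}

#' Fraction of large cells assigned to a given type
#'
#' Size-based external validation of the typing: among cells with area
#' above the threshold (default 648 um^2, i.e. 20,000 pixels at 0.18
#' um/px), the fraction labeled as the expected large type
#' (megakaryocytes).
#'
#' @param assigned named character vector of assigned types.
#' @param areas named numeric vector of cell areas (um^2).
#' @param large_type expected label (default "megakaryocyte").
#' @param threshold_um2 area threshold (default 648).
#' @return list: \code{fraction} (NA when no cell exceeds the threshold),
#'   \code{n_large}.
#' @export
validate_by_size <- function(assigned, areas, large_type = "megakaryocyte",
                             threshold_um2 = 648) {
  areas <- areas[names(assigned)]
  big <- names(assigned)[!is.na(areas) & areas > threshold_um2]
  if (length(big) == 0L)
    return(list(fraction = NA_real_, n_large = 0L))
  list(fraction = mean(assigned[big] == large_type), n_large = length(big))
}
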