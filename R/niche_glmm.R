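#' Build the model frame for the niche Poisson mixed model
#'
#' Turns a neighborhood count table (one cell type) into the model frame of
#' the Poisson mixed model: response = count, fixed effects the full
#' response x timepoint x ring factorial (treatment coding; reference
#' nonresponder / first timepoint / ring 0), offset = log(ring_total),
#' grouping factor = FOV. Rows with an empty ring (ring_total = 0) are
#' dropped and recorded.
#'
#' @param table neighborhood count table rows for a single cell type
#'   (columns count, ring_total, ring, timepoint, response, fov_id).
#' @param timepoints optional restriction to a pair of timepoints, e.g.
#'   \code{c("A", "B")} (default: all present).
#' @return data.frame with columns count, response, timepoint, ring
#'   (factors), log_ring_total, fov_id; attribute \code{"n_dropped"}.
#' @export
build_design <- function(table, timepoints = NULL) {
  if (nrow(table) == 0L) stop("empty count table")
  if (!is.null(timepoints))
    table <- table[table$timepoint %in% timepoints, , drop = FALSE]
  drop <- table$ring_total == 0
  table <- table[!drop, , drop = FALSE]
  for (v in c("response", "timepoint", "ring")) {
    if (length(unique(table[[v]])) < 2L)
      warning("factor '", v, "' has a single level; design is reduced")
  }
  out <- data.frame(
    count = table$count,
    response = factor(table$response,
                      levels = intersect(c("nonresponder", "responder"),
                                         unique(table$response))),
    timepoint = factor(table$timepoint),
    ring = factor(paste0("r", table$ring)),
    log_ring_total = log(table$ring_total),
    fov_id = factor(table$fov_id))
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Fit the niche Poisson generalized linear mixed model
#'
#' One model per cell type: the count of that type in each ring around each
#' index (leukemia) cell, Poisson with log link, fixed-effect full
#' factorial of response x timepoint x ring, log ring total as offset, and
#' a random intercept per FOV. Fitting is delegated to
#' \code{lme4::glmer}.
#'
#' @param frame model frame from [build_design()], or a neighborhood count
#'   table (coerced via [build_design()]).
#' @param cell_type label stored on the fit (for reporting).
#' @param nAGQ integration setting passed to \code{lme4::glmer}; 0 (the
#'   default here) uses the faster penalized-least-squares step, adequate
#'   for the rate-ratio contrasts of interest.
#' @return object of class \code{niche_glmm}: coefficients, covariance,
#'   random-intercept SD, convergence flag, the fitted lme4 model.
#' @export
fit_poisson_glmm <- function(frame, cell_type = NA_character_, nAGQ = 0) {
  if (!"log_ring_total" %in% names(frame)) frame <- build_design(frame)
  if (nlevels(frame$fov_id) < 2L) stop("need >= 2 FOVs for a random intercept")
  terms <- c()
  for (v in c("response", "timepoint", "ring"))
    if (nlevels(droplevels(frame[[v]])) > 1L) terms <- c(terms, v)
  fixed <- if (length(terms)) paste(terms, collapse = " * ") else "1"
  form <- stats::as.formula(paste(
    "count ~", fixed, "+ offset(log_ring_total) + (1 | fov_id)"))
  fit <- lme4::glmer(form, data = frame, family = stats::poisson(),
                     nAGQ = nAGQ,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  beta <- lme4::fixef(fit)
  structure(list(cell_type = cell_type,
                 coefficients = beta,
                 vcov = as.matrix(stats::vcov(fit)),
                 re_sd = sqrt(unname(unlist(lme4::VarCorr(fit)))[1L]),
                 converged = conv,
                 n_rows = nrow(frame),
                 model = fit),
            class = "niche_glmm")
}

#' @export
print.niche_glmm <- function(x, ...) {
  cat("niche_glmm", if (!is.na(x$cell_type)) paste0("[", x$cell_type, "]"),
      "-", x$n_rows, "rows; FOV random-intercept SD =",
      signif(x$re_sd, 3), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.niche_glmm <- function(object, ...) object$coefficients

#' @export
vcov.niche_glmm <- function(object, ...) object$vcov

#' Rate-ratio contrast from a fitted niche model
#'
#' Computes a linear combination c'beta of the fixed effects, its Wald
#' standard error sqrt(c' Sigma c), the two-sided normal p-value, and the
#' rate ratio exp(c'beta) with a Wald confidence interval.
#'
#' @param fit a \code{niche_glmm}.
#' @param contrast named numeric vector over (a subset of) coefficient
#'   names; unnamed coefficients get weight 0.
#' @param label description stored on the result.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame of class \code{contrast_result}: estimate,
#'   se, rate_ratio, ci_low, ci_high, p_raw (p_adj added by
#'   [adjust_bonferroni()]).
#' @export
contrast_rr <- function(fit, contrast, label = "", conf_level = 0.95) {
  if (!fit$converged) stop("model did not converge; contrast refused")
  if (length(contrast) == 0L || all(contrast == 0)) stop("zero contrast vector")
  bad <- setdiff(names(contrast), names(fit$coefficients))
  if (length(bad)) stop("unknown coefficients: ", paste(bad, collapse = ", "))
  cv <- stats::setNames(numeric(length(fit$coefficients)),
                        names(fit$coefficients))
  cv[names(contrast)] <- contrast
  est <- sum(cv * fit$coefficients)
  se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
  z <- est / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(cell_type = fit$cell_type, contrast = label,
                    estimate = est, se = se, rate_ratio = exp(est),
                    ci_low = exp(est - q * se), ci_high = exp(est + q * se),
                    p_raw = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Built-in contrast vectors for the two reported comparisons
#'
#' With treatment coding (reference nonresponder / timepoint A / ring r0),
#' the log rate ratio for responders between timepoint B and A within ring
#' r is \code{timepointB + responder:timepointB [+ timepointB:ring_r +
#' responder:timepointB:ring_r]}, and the baseline responder vs
#' nonresponder log RR within ring r is \code{responder [+
#' responder:ring_r]}.
#'
#' @param fit a \code{niche_glmm}.
#' @param type \code{"B_vs_A_responders"} or
#'   \code{"responder_vs_nonresponder_at_A"}.
#' @param ring ring index (0-based) the contrast is evaluated in.
#' @param timepoint_b label of the later timepoint (default "B").
#' @return named numeric contrast vector for [contrast_rr()].
#' @export
niche_contrast <- function(fit, type = c("B_vs_A_responders",
                                         "responder_vs_nonresponder_at_A"),
                           ring = 0, timepoint_b = "B") {
  type <- match.arg(type)
  nm <- names(fit$coefficients)
  pick <- function(parts) {
    # coefficient whose colon-split terms equal `parts` as a set
    hit <- vapply(strsplit(nm, ":"), function(s) setequal(s, parts), logical(1))
    nm[hit]
  }
  rterm <- paste0("ring", "r", ring)
  v <- character(0)
  if (type == "B_vs_A_responders") {
    v <- c(pick(paste0("timepoint", timepoint_b)),
           pick(c("responseresponder", paste0("timepoint", timepoint_b))))
    if (ring > 0)
      v <- c(v, pick(c(paste0("timepoint", timepoint_b), rterm)),
             pick(c("responseresponder", paste0("timepoint", timepoint_b), rterm)))
  } else {
    v <- c(pick("responseresponder"))
    if (ring > 0) v <- c(v, pick(c("responseresponder", rterm)))
  }
  if (length(v) == 0L) stop("no matching coefficients for contrast")
  stats::setNames(rep(1, length(v)), v)
}

#' Bonferroni adjustment across contrast results
#'
#' @param results data.frame of stacked \code{contrast_result} rows.
#' @param m number of tests (default the number of rows; the analysis-wide
#'   convention is number of cell types x number of contrasts).
#' @return results with a \code{p_adj} column, \code{min(1, m * p_raw)}.
#' @export
adjust_bonferroni <- function(results, m = nrow(results)) {
  if (m < 1) stop("m must be >= 1")
  results$p_adj <- pmin(1, m * results$p_raw)
  results
}

#' Fit the niche model and report rate-ratio contrasts for every cell type
#'
#' Convenience wrapper over [build_design()], [fit_poisson_glmm()],
#' [niche_contrast()], [contrast_rr()] and [adjust_bonferroni()]: one model
#' per neighbor cell type, the two reported contrasts per ring, Bonferroni
#' over all (cell type x contrast type) families.
#'
#' @param counts a \code{neighborhood_counts} table (all cell types).
#' @param timepoints timepoint pair analyzed, default c("A", "B").
#' @param contrasts character subset of the built-in contrast types.
#' @param rings ring indices to report (default all present).
#' @param m multiplicity count for Bonferroni; default #cell types x
#'   #contrast types.
#' @param nAGQ passed to [fit_poisson_glmm()].
#' @return data.frame: cell_type, contrast, ring, rate_ratio, ci, p_raw,
#'   p_adj.
#' @export
niche_enrichment <- function(counts, timepoints = c("A", "B"),
                             contrasts = c("B_vs_A_responders",
                                           "responder_vs_nonresponder_at_A"),
                             rings = NULL, m = NULL, nAGQ = 0) {
  types <- sort(unique(counts$cell_type))
  if (is.null(rings)) rings <- sort(unique(counts$ring))
  res <- list()
  for (ct in types) {
    tab <- complete_type_table(counts, ct)
    frame <- build_design(tab, timepoints)
    fit <- tryCatch(fit_poisson_glmm(frame, cell_type = ct, nAGQ = nAGQ),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    for (tp in contrasts) for (r in rings) {
      cv <- tryCatch(niche_contrast(fit, tp, ring = r,
                                    timepoint_b = timepoints[2L]),
                     error = function(e) NULL)
      if (is.null(cv)) next
      row <- contrast_rr(fit, cv, label = tp)
      row$ring <- r
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  if (is.null(m)) m <- length(types) * length(contrasts)
  adjust_bonferroni(out, m)
}

# Expand the per-type rows to the full (index cell x ring) grid with zero
# counts where the type was absent from an occupied ring; ring_total comes
# from the table (sum over all types in that ring).
complete_type_table <- function(counts, cell_type) {
  ring_tot <- unique(counts[, c("index_cell_id", "ring", "ring_total",
                                "fov_id", "patient_id", "timepoint",
                                "response")])
  own <- counts[counts$cell_type == cell_type,
                c("index_cell_id", "ring", "count")]
  tab <- merge(ring_tot, own, by = c("index_cell_id", "ring"), all.x = TRUE)
  tab$count[is.na(tab$count)] <- 0L
  tab$cell_type <- cell_type
  tab
}
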