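# Expression-impact statistics: CPM / log1p normalization, target+off-target
# aggregation, RMSE against the identity line, Pearson with an explicit
# missing-value contract, cluster-mean comparison with a minimum-size filter,
# and the off-target expression screen against a reference profile.

#' Construct an expression matrix
#'
#' Raw counts, features (genes) in rows and observations (spots, cells or
#' clusters) in columns. Library sizes are computed over ALL features present
#' in the source matrix and are reused by every normalization downstream, so
#' target-only and aggregated values stay on one scale.
#'
#' @param counts Non-negative numeric matrix with rownames (features) and
#'   colnames (observations).
#' @param lib_sizes Optional per-observation library sizes; defaults to
#'   column sums. Must be >= the per-observation counts of any feature.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need feature rownames and observation colnames",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(length(lib_sizes) == ncol(counts))
  structure(list(counts = counts, lib_sizes = as.numeric(lib_sizes)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d observations\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Counts-per-million normalization
#'
#' `count / library_size * 1e6` per observation. Observations with zero
#' library size are dropped with a warning.
#'
#' @param x An [expression_matrix()] or a plain counts matrix.
#' @return Numeric matrix of CPM values.
#' @export
cpm_normalize <- function(x) {
  if (!inherits(x, "expression_matrix")) x <- expression_matrix(x)
  zero <- x$lib_sizes == 0
  if (any(zero)) {
    warning(sum(zero), " observation(s) with zero library size dropped",
            call. = FALSE)
  }
  counts <- x$counts[, !zero, drop = FALSE]
  sweep(counts, 2L, x$lib_sizes[!zero], "/") * 1e6
}

#' Pseudo-log transform
#'
#' Natural `log(x + pseudocount)`; with the default pseudocount of 1 this is
#' log1p, mapping zero counts to zero.
#'
#' @param values Non-negative numeric vector or matrix.
#' @param pseudocount Positive offset, default 1.
#' @return Transformed values, same shape.
#' @export
pseudolog <- function(values, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(values < 0)) stop("pseudolog expects non-negative values",
                            call. = FALSE)
  log(values + pseudocount)
}

#' CPM + pseudo-log normalized expression
#'
#' @param x An [expression_matrix()].
#' @param pseudocount Passed to [pseudolog()].
#' @return Matrix of log-normalized values.
#' @export
normalized_expression <- function(x, pseudocount = 1) {
  pseudolog(cpm_normalize(x), pseudocount)
}

#' Aggregate a target gene with its predicted off-targets
#'
#' Sums the RAW counts of the target and every off-target present in the
#' matrix per observation, then re-normalizes with the ORIGINAL library
#' sizes (CPM) and applies the pseudo-log. Off-targets absent from the
#' matrix are skipped and reported in the `skipped` attribute.
#'
#' @param x An [expression_matrix()].
#' @param target Target feature name (must be present).
#' @param offtargets Character vector of off-target feature names.
#' @param pseudocount Passed to [pseudolog()].
#' @return Named numeric vector (one value per observation) with attribute
#'   `skipped` listing absent off-targets.
#' @export
aggregate_with_offtargets <- function(x, target, offtargets,
                                      pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!(target %in% rownames(x$counts))) {
    stop("target feature absent from matrix: ", target, call. = FALSE)
  }
  present <- intersect(offtargets, rownames(x$counts))
  skipped <- setdiff(offtargets, present)
  if (length(skipped)) {
    message("off-target(s) absent from matrix, skipped: ",
            paste(skipped, collapse = ", "))
  }
  raw <- colSums(x$counts[unique(c(target, present)), , drop = FALSE])
  out <- pseudolog(raw / x$lib_sizes * 1e6, pseudocount)
  attr(out, "skipped") <- skipped
  out
}

#' Concordance between two expression vectors
#'
#' RMSE is computed relative to the identity line y = x:
#' `sqrt(mean((a - b)^2))`. Pearson correlation is reported as missing
#' (`NA`) whenever either vector has zero variance — never coerced to 0 —
#' mirroring the undefined correlation of an unexpressed gene.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return An object of class `concordance`: `rmse`, `pearson`, `n`.
#' @export
concordance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 observations", call. = FALSE)
  rmse <- sqrt(mean((a - b)^2))
  pearson <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
             else stats::cor(a, b)
  structure(list(rmse = rmse, pearson = pearson, n = length(a)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance over %d observations: RMSE %.3f, Pearson %s\n",
              x$n, x$rmse,
              if (is.na(x$pearson)) "nan" else sprintf("%.3f", x$pearson)))
  invisible(x)
}

#' Per-group mean expression with a minimum-size filter
#'
#' Means of (already normalized) values per group of observations. When a
#' per-observation `modality` is supplied, a group is kept only if EVERY
#' modality contributes at least `min_size` observations to it — groups
#' thinly covered by either platform give unstable means and are excluded.
#'
#' @param mat Features x observations matrix of normalized values.
#' @param labels Group label per observation.
#' @param min_size Minimum observations per group (and per modality within
#'   group), default 10.
#' @param modality Optional modality label per observation.
#' @return Features x kept-groups matrix of group means, columns ordered by
#'   group label.
#' @export
group_means <- function(mat, labels, min_size = 10L, modality = NULL) {
  stopifnot(ncol(mat) == length(labels), min_size >= 1L)
  labels <- as.character(labels)
  if (is.null(modality)) {
    sizes <- table(labels)
    keep <- names(sizes)[sizes >= min_size]
  } else {
    stopifnot(length(modality) == length(labels))
    tab <- table(labels, as.character(modality))
    keep <- rownames(tab)[apply(tab >= min_size, 1L, all)]
  }
  if (!length(keep)) {
    stop("all groups fall below the minimum size of ", min_size,
         call. = FALSE)
  }
  keep <- sort(keep)
  out <- vapply(keep, function(g) {
    rowMeans(mat[, labels == g, drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), keep))
}

#' @keywords internal
#' @noRd
trim_ensembl_suffix <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Screen predicted off-targets against a reference expression profile
#'
#' Collapses a reference matrix (bulk or single-cell) to a bulk-like profile
#' -- mean CPM across observations, then log1p -- and, for each target gene
#' with predicted off-targets, tabulates the off-targets ordered by
#' decreasing reference expression. Version suffixes on Ensembl-style IDs
#' are trimmed before matching. Off-targets absent from the matrix are
#' reported as undetected and excluded from the ordering (listed last).
#'
#' @param summaries List of `gene_summary` objects (see [summarize_panel()]).
#' @param reference An [expression_matrix()] for the tissue of interest.
#' @param by Match off-targets by `"gene_name"` or `"gene_id"`.
#' @return data.frame of class `impact_table`: `target_gene`,
#'   `offtarget_gene`, `mean_log1p_cpm`, `detected`, ordered per target by
#'   decreasing expression.
#' @export
offtarget_expression_screen <- function(summaries, reference,
                                        by = c("gene_name", "gene_id")) {
  by <- match.arg(by)
  stopifnot(inherits(reference, "expression_matrix"))
  profile <- pseudolog(rowMeans(cpm_normalize(reference)))
  names(profile) <- trim_ensembl_suffix(names(profile))
  rows <- lapply(summaries, function(s) {
    off <- s$predicted[!s$predicted$on_target, , drop = FALSE]
    if (!nrow(off)) return(NULL)
    key <- trim_ensembl_suffix(
      if (by == "gene_name") off$gene_name else off$gene_id)
    expr <- unname(profile[key])
    detected <- !is.na(expr)
    ord <- order(!detected, -ifelse(detected, expr, -Inf), key)
    data.frame(target_gene = s$target_gene_name, offtarget_gene = key[ord],
               mean_log1p_cpm = expr[ord], detected = detected[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- empty_df(target_gene = "character", offtarget_gene = "character",
                    mean_log1p_cpm = "numeric", detected = "logical")
  }
  rownames(out) <- NULL
  class(out) <- c("impact_table", "data.frame")
  out
}

#' Quantify the expression-level impact of predicted off-targets
#'
#' For each target gene present on both platforms, compares platform-X
#' expression of the target against (i) the platform-Y target alone and (ii)
#' the platform-Y aggregate of target + predicted off-targets, reporting the
#' RMSE/Pearson of each and the change in RMSE. Genes whose off-targets are
#' all absent from Y have aggregated == target-only by construction.
#'
#' @param x Platform-X [expression_matrix()] (e.g. the probe-based assay);
#'   observations must correspond 1:1 (same order) to those of `y`, e.g.
#'   matched spatial spots or shared clusters.
#' @param y Platform-Y [expression_matrix()] (reference platform).
#' @param offtarget_map Named list: target feature -> character vector of
#'   predicted off-target features.
#' @param pseudocount Passed to the normalizations.
#' @return data.frame of class `impact_report`: per target gene the RMSE and
#'   Pearson of the target-only and aggregated comparisons, `delta_rmse`
#'   (target-only minus aggregated; positive means aggregation explains the
#'   platform-X signal better), and the off-target mean expression in Y.
#' @export
impact_report <- function(x, y, offtarget_map, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(y, "expression_matrix"))
  if (ncol(x$counts) != ncol(y$counts)) {
    stop("platforms must share matched observations", call. = FALSE)
  }
  norm_x <- pseudolog(cpm_normalize(x), pseudocount)
  norm_y <- pseudolog(cpm_normalize(y), pseudocount)
  y_profile <- pseudolog(rowMeans(cpm_normalize(y)))
  rows <- lapply(names(offtarget_map), function(target) {
    if (!(target %in% rownames(norm_x)) || !(target %in% rownames(norm_y))) {
      return(NULL)
    }
    offs <- setdiff(offtarget_map[[target]], target)
    xt <- norm_x[target, ]
    solo <- concordance(xt, norm_y[target, ])
    agg_vec <- aggregate_with_offtargets(y, target, offs, pseudocount)
    agg <- concordance(xt, agg_vec)
    present <- intersect(offs, rownames(y$counts))
    data.frame(
      target_gene = target,
      n_offtargets = length(offs),
      n_offtargets_detected = length(present),
      rmse_target_only = solo$rmse, pearson_target_only = solo$pearson,
      rmse_aggregated = agg$rmse, pearson_aggregated = agg$pearson,
      delta_rmse = solo$rmse - agg$rmse,
      offtarget_mean_log1p_cpm = if (length(present))
        mean(y_profile[present]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no target gene present on both platforms",
                         call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("impact_report", "data.frame")
  out
}
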