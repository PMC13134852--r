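# Panel-level reporting ("stat") and cross-annotation reconciliation:
# summary statistics per annotation, plus union/intersection of affected
# genes across annotations (join key: uppercased gene name).

#' Panel-level off-target statistics
#'
#' A probe is off-target if it has at least one off-target call; an affected
#' gene is a target gene with at least one off-target call surviving the
#' active filters. The biotype breakdown counts distinct off-target genes per
#' canonical biotype.
#'
#' @param calls Binding calls from [call_bindings()] (already filtered if a
#'   protein-coding-only or readthrough-excluded view is wanted).
#' @param panel The [probe_panel()].
#' @param source Annotation source label.
#' @param exclude_readthrough Drop read-through-flagged off-target calls
#'   before counting.
#' @return An object of class `panel_stats`.
#' @export
panel_stats <- function(calls, panel, source = "annotation",
                        exclude_readthrough = FALSE) {
  stopifnot(inherits(panel, "probe_panel"))
  off <- calls[!calls$on_target, , drop = FALSE]
  if (exclude_readthrough) off <- off[!off$readthrough, , drop = FALSE]
  off_genes <- unique(off[, c("bound_gene_id", "biotype")])
  breakdown <- table(factor(off_genes$biotype, levels = CANONICAL_BIOTYPES))
  structure(list(
    source = source,
    n_probes_total = nrow(panel$probes),
    n_probes_offtarget = length(unique(off$accession)),
    n_genes_affected = length(unique(off$target_gene_id)),
    n_offtarget_genes_matched = nrow(off_genes),
    biotype_breakdown = as.integer(breakdown),
    biotype_levels = CANONICAL_BIOTYPES,
    affected_genes = sort(unique(off$target_gene_name))
  ), class = "panel_stats")
}

#' @export
print.panel_stats <- function(x, ...) {
  cat(sprintf(
    "panel_stats [%s]: %d/%d probes off-target across %d genes, matching %d other genes\n",
    x$source, x$n_probes_offtarget, x$n_probes_total, x$n_genes_affected,
    x$n_offtarget_genes_matched))
  bd <- stats::setNames(x$biotype_breakdown, x$biotype_levels)
  bd <- bd[bd > 0]
  if (length(bd)) {
    cat("  off-target gene biotypes:",
        paste(sprintf("%s=%d", names(bd), bd), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
affected_set <- function(calls, protein_coding_only = FALSE,
                         exclude_readthrough = FALSE) {
  off <- calls[!calls$on_target, , drop = FALSE]
  if (protein_coding_only) {
    off <- off[off$biotype == "protein_coding", , drop = FALSE]
  }
  if (exclude_readthrough) off <- off[!off$readthrough, , drop = FALSE]
  sort(unique(toupper(off$target_gene_name)))
}

#' Reconcile affected-gene sets across annotations
#'
#' Joins per-annotation results on uppercased target gene name and computes
#' the union and intersection of affected genes, both over all biotypes and
#' restricted to protein-coding off-targets. The rationale for the union
#' view: if a probe aligns off-target to a protein-coding gene under ANY
#' annotation, it could bind off-target in the assay.
#'
#' @param calls_by_source Named list (source label -> binding-call
#'   data.frame); at least two sources, labels unique.
#' @param exclude_readthrough Apply the read-through filter before counting
#'   affected status.
#' @return An object of class `cross_annotation_report`: per-source affected
#'   sets (`full`, `protein_coding`), `union`, `intersection` for both views,
#'   and a per-gene logical `presence` matrix (protein-coding view).
#' @export
compare_annotations <- function(calls_by_source, exclude_readthrough = FALSE) {
  if (length(calls_by_source) < 2L) {
    stop("compare_annotations needs >=2 annotation sources", call. = FALSE)
  }
  if (is.null(names(calls_by_source)) ||
      anyDuplicated(names(calls_by_source))) {
    stop("annotation sources must have unique labels", call. = FALSE)
  }
  full <- lapply(calls_by_source, affected_set,
                 exclude_readthrough = exclude_readthrough)
  pc <- lapply(calls_by_source, affected_set, protein_coding_only = TRUE,
               exclude_readthrough = exclude_readthrough)
  union_of <- function(sets) sort(unique(unlist(sets)))
  intersect_of <- function(sets) sort(Reduce(intersect, sets))
  all_genes <- union_of(pc)
  presence <- vapply(pc, function(s) all_genes %in% s,
                     logical(length(all_genes)))
  if (length(all_genes) == 1L) presence <- t(presence)
  presence <- matrix(presence, nrow = length(all_genes),
                     dimnames = list(all_genes, names(pc)))
  structure(list(
    sources = names(calls_by_source),
    affected_full = full,
    affected_protein_coding = pc,
    union_full = union_of(full),
    intersection_full = intersect_of(full),
    union_protein_coding = all_genes,
    intersection_protein_coding = intersect_of(pc),
    presence = presence
  ), class = "cross_annotation_report")
}

#' @export
print.cross_annotation_report <- function(x, ...) {
  cat(sprintf("cross_annotation_report over %d sources (%s)\n",
              length(x$sources), paste(x$sources, collapse = ", ")))
  cat(sprintf("  affected genes, all biotypes: union %d, intersection %d\n",
              length(x$union_full), length(x$intersection_full)))
  cat(sprintf("  protein-coding off-targets:  union %d, intersection %d\n",
              length(x$union_protein_coding),
              length(x$intersection_protein_coding)))
  invisible(x)
}

#' Run the full pipeline: flip, track, stat, and cross-annotation comparison
#'
#' Per annotation: orient the panel against that annotation, align all
#' probes, lift hits to binding calls, summarize, and compute panel
#' statistics. With more than one annotation a cross-annotation report is
#' added.
#'
#' @param panel A [probe_panel()].
#' @param annotations A single `annotation_set` (with sequences) or a named
#'   list of them.
#' @param config An [aligner_config()].
#' @param synonyms Optional `synonym_table`.
#' @param exclude_readthrough Apply the read-through filter in statistics.
#' @return An object of class `opt_run`: per-source list with `flip_report`,
#'   `hits`, `calls`, `summaries`, `stats`; plus `comparison` (or `NULL`).
#' @export
run_all <- function(panel, annotations, config = aligner_config(),
                    synonyms = NULL, exclude_readthrough = FALSE) {
  stopifnot(inherits(panel, "probe_panel"))
  if (inherits(annotations, "annotation_set")) {
    annotations <- stats::setNames(list(annotations), annotations$source)
  }
  if (is.null(names(annotations))) {
    names(annotations) <- vapply(annotations, `[[`, "", "source")
  }
  per_source <- lapply(names(annotations), function(src) {
    ann <- annotations[[src]]
    flipped <- flip_panel(panel, ann, synonyms)
    index <- build_index(ann, w = if (is.null(config$w)) 20L else config$w)
    hits <- find_panel_hits(flipped$panel, index, config)
    calls <- call_bindings(hits, ann, flipped$panel, synonyms)
    summaries <- summarize_panel(calls, flipped$panel)
    stats <- panel_stats(calls, flipped$panel, source = src,
                         exclude_readthrough = exclude_readthrough)
    list(source = src, panel = flipped$panel, flip_report = flipped$report,
         hits = hits, calls = calls, summaries = summaries, stats = stats)
  })
  names(per_source) <- names(annotations)
  comparison <- NULL
  if (length(per_source) > 1L) {
    comparison <- compare_annotations(
      lapply(per_source, `[[`, "calls"),
      exclude_readthrough = exclude_readthrough)
  }
  structure(list(results = per_source, comparison = comparison,
                 config = config), class = "opt_run")
}

#' @export
print.opt_run <- function(x, ...) {
  cat(sprintf("opt_run: %d annotation source(s), mode %s (pl = %d)\n",
              length(x$results), x$config$mode, x$config$pl))
  for (r in x$results) print(r$stats)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
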