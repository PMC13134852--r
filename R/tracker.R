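# Off-target tracking ("track"): lift alignment hits to gene-level binding
# calls, resolve synonyms, classify on/off-target, annotate biotypes, and
# flag read-through genes. Hits are collapsed probe -> gene for counting
# (summary tables count probes per gene); transcript multiplicity is kept
# only as n_transcripts_hit.

#' Decide whether a bound gene counts as on-target
#'
#' True iff the gene IDs are equal, the gene names are equal, or the bound
#' name is a declared synonym of the target name. Multi-symbol target
#' declarations ("A; B") treat any declared symbol as on-target.
#'
#' @param target_id,target_name Declared target gene.
#' @param bound_id,bound_name Gene a probe aligns to.
#' @param synonyms Optional `synonym_table`.
#' @return Logical scalar.
#' @export
is_on_target <- function(target_id, target_name, bound_id, bound_name,
                         synonyms = NULL) {
  if (is.null(synonyms)) synonyms <- synonym_table()
  target_names <- trimws(strsplit(target_name, ";", fixed = TRUE)[[1]])
  if (!is.na(bound_id) && !is.na(target_id) && bound_id == target_id) {
    return(TRUE)
  }
  syn <- unique(unlist(lapply(target_names, synonyms, table = synonyms)))
  bound_name %in% syn
}

#' Flag a bound gene as a read-through of the target
#'
#' A read-through gene spans two adjacent genes' loci and carries a
#' hyphenated symbol containing both; binding to it is expected whenever one
#' component is the target. True iff the bound name splits on `-` into two or
#' more symbols, one of which equals the target name or a synonym. Flagged
#' genes are never silently dropped; filtering is an explicit option.
#'
#' @param bound_name Bound gene symbol.
#' @param target_name Target gene symbol.
#' @param synonyms Optional `synonym_table`.
#' @return Logical scalar.
#' @examples
#' flag_readthrough("DNAAF1-CCPG1", "CCPG1")  # TRUE
#' @export
flag_readthrough <- function(bound_name, target_name, synonyms = NULL) {
  if (is.null(synonyms)) synonyms <- synonym_table()
  parts <- strsplit(bound_name, "-", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(FALSE)
  syn <- synonyms(synonyms, target_name)
  any(parts %in% syn)
}

#' Lift alignment hits to gene-level binding calls
#'
#' Hits are grouped by (probe, bound gene); each group becomes one call with
#' the number of distinct transcripts hit, the bound gene's canonical biotype
#' (highest-priority biotype among the transcripts actually hit), on-target
#' status via [is_on_target()], and a read-through flag.
#'
#' @param hits Hit table from [find_panel_hits()].
#' @param annotation The `annotation_set` the hits refer to.
#' @param panel The [probe_panel()] the hits came from.
#' @param synonyms Optional `synonym_table`.
#' @return data.frame of binding calls (`accession`, `target_gene_id`,
#'   `target_gene_name`, `bound_gene_id`, `bound_gene_name`, `biotype`,
#'   `on_target`, `readthrough`, `n_transcripts_hit`, `mode`, `pl`).
#' @export
call_bindings <- function(hits, annotation, panel, synonyms = NULL) {
  stopifnot(inherits(annotation, "annotation_set"),
            inherits(panel, "probe_panel"))
  if (is.null(synonyms)) synonyms <- synonym_table()
  calls <- empty_df(accession = "character", target_gene_id = "character",
                    target_gene_name = "character",
                    bound_gene_id = "character",
                    bound_gene_name = "character", biotype = "character",
                    on_target = "logical", readthrough = "logical",
                    n_transcripts_hit = "integer", mode = "character",
                    pl = "integer")
  if (!nrow(hits)) return(calls)
  tx <- annotation$transcripts
  missing_tx <- setdiff(unique(hits$transcript_id), tx$transcript_id)
  if (length(missing_tx)) {
    stop("hits reference transcripts absent from annotation: ",
         paste(utils::head(missing_tx, 3), collapse = ", "), call. = FALSE)
  }
  idx <- match(hits$transcript_id, tx$transcript_id)
  h <- hits
  h$bound_gene_id <- tx$gene_id[idx]
  h$bound_gene_name <- tx$gene_name[idx]
  h$tx_biotype <- tx$biotype[idx]
  pidx <- match(h$accession, panel$probes$accession)
  if (anyNA(pidx)) {
    stop("hits reference probes absent from panel", call. = FALSE)
  }
  h$target_gene_id <- panel$probes$gene_id[pidx]
  h$target_gene_name <- panel$probes$gene_name[pidx]

  prio <- c(protein_coding = 1, NMD = 2, lncRNA = 3, miRNA = 4,
            pseudogene = 5, other = 6)
  groups <- split(h, paste(h$accession, h$bound_gene_id, sep = "\r"))
  rows <- lapply(groups, function(g) {
    data.frame(
      accession = g$accession[1],
      target_gene_id = g$target_gene_id[1],
      target_gene_name = g$target_gene_name[1],
      bound_gene_id = g$bound_gene_id[1],
      bound_gene_name = g$bound_gene_name[1],
      biotype = names(prio)[min(prio[g$tx_biotype])],
      on_target = is_on_target(g$target_gene_id[1], g$target_gene_name[1],
                               g$bound_gene_id[1], g$bound_gene_name[1],
                               synonyms),
      readthrough = flag_readthrough(g$bound_gene_name[1],
                                     g$target_gene_name[1], synonyms),
      n_transcripts_hit = length(unique(g$transcript_id)),
      mode = g$mode[1], pl = g$pl[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$bound_gene_name, out$bound_gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize binding calls for one target gene
#'
#' Produces one summary-table row per target gene: total probes for the gene
#' in the panel, and the predicted binding genes ordered by descending number
#' of probes aligned, ties broken by gene name. A probe is counted once per
#' bound gene regardless of how many of that gene's transcripts it hits.
#'
#' @param calls Binding calls for a single target gene.
#' @param panel The [probe_panel()].
#' @return An object of class `gene_summary`: list with `target_gene_id`,
#'   `target_gene_name`, `n_probes`, and a data.frame `predicted` with
#'   columns `gene_id`, `gene_name`, `n_probes_aligned`, `biotype`,
#'   `on_target`, `readthrough`.
#' @export
summarize_gene <- function(calls, panel) {
  stopifnot(inherits(panel, "probe_panel"))
  tgt_ids <- unique(calls$target_gene_id)
  if (length(tgt_ids) != 1L) {
    stop("summarize_gene expects calls for exactly one target gene",
         call. = FALSE)
  }
  tgt_name <- calls$target_gene_name[1]
  n_probes <- sum(panel$probes$gene_id == tgt_ids)
  by_gene <- split(calls, calls$bound_gene_id)
  pred <- do.call(rbind, lapply(by_gene, function(g) {
    data.frame(gene_id = g$bound_gene_id[1], gene_name = g$bound_gene_name[1],
               n_probes_aligned = length(unique(g$accession)),
               biotype = g$biotype[1], on_target = g$on_target[1],
               readthrough = g$readthrough[1], stringsAsFactors = FALSE)
  }))
  pred <- pred[order(-pred$n_probes_aligned, pred$gene_name), , drop = FALSE]
  rownames(pred) <- NULL
  structure(list(target_gene_id = tgt_ids, target_gene_name = tgt_name,
                 n_probes = n_probes, predicted = pred),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  off <- x$predicted[!x$predicted$on_target, , drop = FALSE]
  cat(sprintf("%s: %d probes; %d predicted binding gene(s), %d off-target\n",
              x$target_gene_name, x$n_probes, nrow(x$predicted), nrow(off)))
  invisible(x)
}

#' Summarize binding calls for every affected target gene
#'
#' @param calls Binding calls from [call_bindings()].
#' @param panel The [probe_panel()].
#' @return Named list of [summarize_gene()] results, one per target gene with
#'   at least one call, ordered by target gene name.
#' @export
summarize_panel <- function(calls, panel) {
  if (!nrow(calls)) return(structure(list(), names = character(0)))
  by_target <- split(calls, calls$target_gene_id)
  out <- lapply(by_target, summarize_gene, panel = panel)
  names(out) <- vapply(out, `[[`, "", "target_gene_name")
  out[order(names(out))]
}

#' Restrict calls or summaries to protein-coding off-targets
#'
#' Off-target entries whose biotype is not `protein_coding` are removed
#' (on-target entries are untouched); target genes left with no off-target
#' entry drop out of the affected-gene set computed downstream.
#'
#' @param x Binding-call data.frame, a `gene_summary`, or a list of
#'   summaries.
#' @return Same shape as the input, restricted.
#' @export
filter_protein_coding <- function(x) {
  if (is.data.frame(x)) {
    keep <- x$on_target | x$biotype == "protein_coding"
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (inherits(x, "gene_summary")) {
    keep <- x$predicted$on_target | x$predicted$biotype == "protein_coding"
    x$predicted <- x$predicted[keep, , drop = FALSE]
    rownames(x$predicted) <- NULL
    return(x)
  }
  if (is.list(x)) return(lapply(x, filter_protein_coding))
  stop("unsupported input to filter_protein_coding", call. = FALSE)
}

#' Flatten gene summaries into a summary table
#'
#' One row per (target gene, predicted gene), in the shape of the standard
#' off-target summary table: target gene, number of probes, predicted binding
#' gene, number of probes aligned, gene type.
#'
#' @param summaries List of `gene_summary` objects.
#' @return data.frame.
#' @export
summary_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    if (!nrow(s$predicted)) return(NULL)
    data.frame(target_gene = s$target_gene_name,
               target_gene_id = s$target_gene_id,
               n_probes = s$n_probes,
               predicted_gene = s$predicted$gene_name,
               predicted_gene_id = s$predicted$gene_id,
               n_probes_aligned = s$predicted$n_probes_aligned,
               gene_type = s$predicted$biotype,
               on_target = s$predicted$on_target,
               readthrough = s$predicted$readthrough,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- empty_df(target_gene = "character", target_gene_id = "character",
                    n_probes = "integer", predicted_gene = "character",
                    predicted_gene_id = "character",
                    n_probes_aligned = "integer", gene_type = "character",
                    on_target = "logical", readthrough = "logical")
  }
  rownames(out) <- NULL
  out
}
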