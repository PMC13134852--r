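# Probe orientation ("flip"): probe target sequences are usually supplied
# antisense to their target transcripts; detect this per probe against its
# own target gene's transcripts and reverse-complement so every probe aligns
# to the transcript forward strand downstream.

#' Reverse-complement nucleotide sequences
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Vectorized.
#'
#' @param seq Character vector over {A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  validate_sequence(seq <- toupper(seq))
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), "")
}

#' Orient a probe panel onto the transcript forward strand
#'
#' For each probe, its own target gene's transcripts (matched by gene ID,
#' gene name, or synonym) are searched for an exact occurrence of the probe
#' sequence and of its reverse complement. Probes occurring only as the
#' reverse complement are flipped; probes occurring forward are kept (a probe
#' matching in both orientations is kept forward and logged as ambiguous);
#' probes matching in neither orientation are left unchanged and marked
#' unmatched. Orientation is decided against the probe's own target gene
#' only, never the whole transcriptome, so spurious off-target hits cannot
#' flip a probe.
#'
#' @param panel A [probe_panel()].
#' @param annotation An `annotation_set` with sequences, or a named character
#'   vector of transcript sequences plus `gene_map` below.
#' @param synonyms Optional `synonym_table`.
#' @return A list with `panel` (oriented) and `report` (class `flip_report`):
#'   counts `n_total`, `n_kept`, `n_flipped`, `n_unmatched` and a per-probe
#'   data.frame `dispositions` with a `reason` column (`forward_match`,
#'   `reverse_match`, `both_orientations`, `no_match`, `gene_absent`).
#' @export
flip_panel <- function(panel, annotation, synonyms = NULL) {
  stopifnot(inherits(panel, "probe_panel"),
            inherits(annotation, "annotation_set"))
  if (is.null(synonyms)) synonyms <- synonym_table()
  seqs <- transcript_seqs(annotation)
  tx <- annotation$transcripts
  probes <- panel$probes

  disposition <- character(nrow(probes))
  reason <- character(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    syn <- synonyms(synonyms, probes$gene_name[i])
    own <- tx$gene_id == probes$gene_id[i] | tx$gene_name %in% syn
    if (!any(own)) {
      disposition[i] <- "unmatched"
      reason[i] <- "gene_absent"
      next
    }
    tseqs <- seqs[tx$transcript_id[own]]
    fwd <- any(vapply(tseqs, contains_exact, TRUE,
                      needle = probes$sequence[i]))
    rc <- reverse_complement(probes$sequence[i])
    rev <- any(vapply(tseqs, contains_exact, TRUE, needle = rc))
    if (fwd && rev) {
      disposition[i] <- "kept"; reason[i] <- "both_orientations"
    } else if (fwd) {
      disposition[i] <- "kept"; reason[i] <- "forward_match"
    } else if (rev) {
      disposition[i] <- "flipped"; reason[i] <- "reverse_match"
      probes$sequence[i] <- rc
      probes$flipped[i] <- TRUE
    } else {
      disposition[i] <- "unmatched"; reason[i] <- "no_match"
    }
  }

  report <- structure(list(
    n_total = nrow(probes),
    n_kept = sum(disposition == "kept"),
    n_flipped = sum(disposition == "flipped"),
    n_unmatched = sum(disposition == "unmatched"),
    dispositions = data.frame(accession = probes$accession,
                              gene_name = probes$gene_name,
                              disposition = disposition, reason = reason,
                              stringsAsFactors = FALSE)
  ), class = "flip_report")

  panel$probes <- probes
  list(panel = panel, report = report)
}

#' @export
print.flip_report <- function(x, ...) {
  cat(sprintf("flip_report: %d probes (%d kept, %d flipped, %d unmatched)\n",
              x$n_total, x$n_kept, x$n_flipped, x$n_unmatched))
  invisible(x)
}
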