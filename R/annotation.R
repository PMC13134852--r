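# Annotation ingest: parse GFF3/GTF, normalize source-specific quirks
# (GENCODE / RefSeq / CHESS), and extract spliced transcript sequences so all
# sources become a uniform transcript set.
#
# Internal coordinates are 0-based half-open; the 1-based closed GFF/GTF
# convention is converted at the parser boundary.

CANONICAL_BIOTYPES <- c("protein_coding", "pseudogene", "lncRNA", "NMD",
                        "miRNA", "other")

# Contig names matching this pattern are treated as alternative scaffolds
# (haplotype/patch/random placements); unplaced chrUn_* contigs are kept.
ALT_SCAFFOLD_PATTERN <- "(_alt$)|(_random$)|(_fix$)|(_hap[0-9]+)"

TRANSCRIPT_TYPES <- c(
  "transcript", "mRNA", "lnc_RNA", "lncRNA", "ncRNA", "miRNA", "snRNA",
  "snoRNA", "rRNA", "tRNA", "scRNA", "antisense_RNA", "primary_transcript",
  "pseudogenic_transcript", "processed_transcript", "unconfirmed_transcript"
)
SEGMENT_TYPES <- c("V_gene_segment", "D_gene_segment", "J_gene_segment",
                   "C_gene_segment")
GENE_TYPES <- c("gene", "pseudogene", "ncRNA_gene")

#' Map a source biotype label onto the canonical vocabulary
#'
#' Annotation sources use divergent biotype vocabularies; downstream reporting
#' uses six canonical labels: `protein_coding`, `pseudogene`, `lncRNA`, `NMD`,
#' `miRNA`, `other`. Anything unrecognized maps to `other`.
#'
#' @param raw Character vector of source biotype labels.
#' @param source Optional source label (unused by the default mapping, kept
#'   for source-specific overrides).
#' @return Character vector over the canonical labels.
#' @export
normalize_biotype <- function(raw, source = NULL) {
  out <- rep("other", length(raw))
  r <- tolower(raw)
  out[r %in% c("protein_coding", "mrna")] <- "protein_coding"
  out[grepl("^(ig|tr)_[vdjc]_gene$", r)] <- "protein_coding"
  out[grepl("pseudogene", r)] <- "pseudogene"
  out[r %in% c("lncrna", "lincrna", "lnc_rna", "antisense", "antisense_rna",
               "sense_intronic", "sense_overlapping")] <- "lncRNA"
  out[r %in% c("nonsense_mediated_decay", "nmd")] <- "NMD"
  out[r %in% c("mirna")] <- "miRNA"
  out[is.na(raw)] <- "other"
  out
}

#' @keywords internal
#' @noRd
new_annotation_set <- function(transcripts, exons, genes, segments = NULL,
                               source = "annotation", genome_build = NA_character_,
                               log = list()) {
  if (is.null(segments)) segments <- transcripts[0, , drop = FALSE]
  structure(list(transcripts = transcripts, exons = exons, genes = genes,
                 segments = segments, source = source,
                 genome_build = genome_build, log = log),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set '%s': %d transcripts / %d genes (%s sequences)\n",
    x$source, nrow(x$transcripts), nrow(x$genes),
    if (all(is.na(x$transcripts$sequence))) "no" else "with"))
  invisible(x)
}

#' Parse a GFF3 or GTF annotation into a uniform transcript set
#'
#' Resolves the gene/transcript/exon hierarchy (via `Parent`/`ID` for GFF3,
#' `gene_id`/`transcript_id` attributes for GTF), converts coordinates to the
#' internal 0-based half-open convention, normalizes biotypes, and drops
#' features on alternative scaffolds. Transcript-level biotype is preferred
#' when present, else the gene-level biotype is inherited. Transcripts without
#' exons are skipped with a logged count. VDJ segment features are parsed but
#' quarantined until [apply_source_rules()] promotes them (RefSeq rule).
#'
#' @param path GFF3 or GTF file.
#' @param dialect `"gff3"` or `"gtf"`; guessed from the extension by default.
#' @param source Label recorded on the output (e.g. `"gencode_v47_basic"`).
#' @param drop_alt_scaffolds Drop contigs matching `alt_pattern` (default on).
#' @param alt_pattern Regular expression identifying alternative scaffolds.
#' @param genome_build Free-text build label.
#' @return An `annotation_set` with sequences unset (see
#'   [extract_transcript_sequences()]).
#' @export
parse_annotation <- function(path, dialect = c("auto", "gff3", "gtf"),
                             source = basename(path),
                             drop_alt_scaffolds = TRUE,
                             alt_pattern = ALT_SCAFFOLD_PATTERN,
                             genome_build = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  n_alt <- 0L
  if (drop_alt_scaffolds) {
    alt <- grepl(alt_pattern, df$seqnames)
    n_alt <- sum(alt & df$type %in% c(TRANSCRIPT_TYPES, SEGMENT_TYPES))
    df <- df[!alt, , drop = FALSE]
  }

  get_attr <- function(d, keys) {
    out <- rep(NA_character_, nrow(d))
    for (k in keys) {
      if (k %in% names(d)) {
        v <- d[[k]]
        if (is.list(v)) v <- vapply(v, function(x)
          if (length(x)) as.character(x[[1]]) else NA_character_, "")
        out <- ifelse(is.na(out), as.character(v), out)
      }
    }
    out
  }

  if (dialect == "gtf") {
    tx_rows <- df[df$type %in% c(TRANSCRIPT_TYPES, SEGMENT_TYPES), , drop = FALSE]
    ex_rows <- df[df$type == "exon", , drop = FALSE]
    gene_rows <- df[df$type %in% GENE_TYPES, , drop = FALSE]
    tx_id <- get_attr(tx_rows, "transcript_id")
    tx_gene <- get_attr(tx_rows, "gene_id")
    tx_name <- get_attr(tx_rows, c("gene_name", "gene"))
    tx_bt_raw <- get_attr(tx_rows, c("transcript_biotype", "transcript_type"))
    tx_gene_bt <- get_attr(tx_rows, c("gene_biotype", "gene_type"))
    ex_parent <- get_attr(ex_rows, "transcript_id")
    gene_id <- get_attr(gene_rows, "gene_id")
    gene_name <- get_attr(gene_rows, c("gene_name", "gene"))
    gene_bt <- get_attr(gene_rows, c("gene_biotype", "gene_type"))
  } else {
    strip_prefix <- function(x) sub("^(gene|transcript|rna|exon)[-:]", "", x)
    ids <- get_attr(df, "ID")
    parents <- get_attr(df, "Parent")
    tx_sel <- df$type %in% c(TRANSCRIPT_TYPES, SEGMENT_TYPES)
    ex_sel <- df$type == "exon"
    gene_sel <- df$type %in% GENE_TYPES
    gene_rows <- df[gene_sel, , drop = FALSE]
    gene_raw_id <- ids[gene_sel]
    gene_id <- get_attr(gene_rows, c("gene_id"))
    gene_id <- ifelse(is.na(gene_id), strip_prefix(gene_raw_id), gene_id)
    gene_name <- get_attr(gene_rows, c("Name", "gene_name", "gene"))
    gene_bt <- get_attr(gene_rows, c("gene_biotype", "gene_type", "biotype"))
    # map raw feature ID -> resolved gene id for Parent resolution
    gene_lookup <- stats::setNames(gene_id, gene_raw_id)
    tx_rows <- df[tx_sel, , drop = FALSE]
    tx_raw_id <- ids[tx_sel]
    tx_id <- get_attr(tx_rows, "transcript_id")
    tx_id <- ifelse(is.na(tx_id), strip_prefix(tx_raw_id), tx_id)
    tx_parent_raw <- parents[tx_sel]
    tx_gene <- unname(gene_lookup[tx_parent_raw])
    tx_gene <- ifelse(is.na(tx_gene), strip_prefix(tx_parent_raw), tx_gene)
    tx_name <- get_attr(tx_rows, c("gene_name", "gene"))
    tx_bt_raw <- get_attr(tx_rows, c("transcript_biotype", "transcript_type",
                                     "biotype"))
    tx_gene_bt <- rep(NA_character_, nrow(tx_rows))
    ex_rows <- df[ex_sel, , drop = FALSE]
    tx_lookup <- stats::setNames(tx_id, tx_raw_id)
    ex_parent <- unname(tx_lookup[parents[ex_sel]])
    ex_parent <- ifelse(is.na(ex_parent), strip_prefix(parents[ex_sel]),
                        ex_parent)
  }

  genes <- unique(data.frame(
    gene_id = gene_id,
    gene_name = ifelse(is.na(gene_name), gene_id, gene_name),
    biotype_raw = gene_bt,
    stringsAsFactors = FALSE))
  gene_name_lookup <- stats::setNames(genes$gene_name, genes$gene_id)
  gene_bt_lookup <- stats::setNames(genes$biotype_raw, genes$gene_id)

  tx <- data.frame(
    transcript_id = tx_id,
    gene_id = tx_gene,
    feature_type = tx_rows$type,
    contig = tx_rows$seqnames,
    strand = tx_rows$strand,
    biotype_raw = tx_bt_raw,
    stringsAsFactors = FALSE)
  tx$gene_name <- unname(gene_name_lookup[tx$gene_id])
  if (dialect == "gtf") {
    tx$gene_name <- ifelse(is.na(tx$gene_name), tx_name, tx$gene_name)
  }
  tx$gene_name <- ifelse(is.na(tx$gene_name), tx$gene_id, tx$gene_name)
  gene_bt_of_tx <- unname(gene_bt_lookup[tx$gene_id])
  if (dialect == "gtf") {
    gene_bt_of_tx <- ifelse(is.na(gene_bt_of_tx), tx_gene_bt, gene_bt_of_tx)
  }
  tx$gene_biotype_raw <- gene_bt_of_tx
  # transcript-level biotype preferred, else inherit the gene's
  tx$biotype_raw <- ifelse(is.na(tx$biotype_raw), gene_bt_of_tx, tx$biotype_raw)
  tx$biotype <- normalize_biotype(tx$biotype_raw, source)

  exons <- data.frame(
    transcript_id = ex_parent,
    contig = ex_rows$seqnames,
    strand = ex_rows$strand,
    start0 = ex_rows$start - 1L,   # GFF 1-based closed -> 0-based half-open
    end0 = ex_rows$end,
    stringsAsFactors = FALSE)

  orphan <- !(exons$transcript_id %in% tx$transcript_id)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) with unknown parent skipped", call. = FALSE)
    exons <- exons[!orphan, , drop = FALSE]
  }
  exons <- exons[order(exons$transcript_id, exons$start0), , drop = FALSE]
  rownames(exons) <- NULL

  n_ex <- table(exons$transcript_id)
  tx$n_exons <- as.integer(n_ex[tx$transcript_id])
  tx$n_exons[is.na(tx$n_exons)] <- 0L
  no_exon <- tx$n_exons == 0L
  n_no_exon <- sum(no_exon & !(tx$feature_type %in% SEGMENT_TYPES))
  if (n_no_exon > 0L) {
    warning(n_no_exon, " transcript(s) without exons skipped", call. = FALSE)
  }
  tx$sequence <- NA_character_
  tx <- tx[!no_exon | tx$feature_type %in% SEGMENT_TYPES, , drop = FALSE]

  seg_sel <- tx$feature_type %in% SEGMENT_TYPES
  segments <- tx[seg_sel, , drop = FALSE]
  tx <- tx[!seg_sel, , drop = FALSE]
  rownames(tx) <- rownames(segments) <- NULL

  genes$biotype <- normalize_biotype(genes$biotype_raw, source)

  new_annotation_set(
    transcripts = tx, exons = exons, genes = genes, segments = segments,
    source = source, genome_build = genome_build,
    log = list(n_alt_scaffold_dropped = n_alt,
               n_exonless_skipped = n_no_exon))
}

#' Built-in per-source normalization rule sets
#'
#' RefSeq inputs get the VDJ-segment promotion (immunoglobulin/TCR segment
#' features become transcripts) and the removal of transcripts whose gene
#' biotype is literally `pseudogene` (RefSeq annotates transcripts for only a
#' small, inconsistent subset of these). All sources already drop alternative
#' scaffolds at parse time.
#'
#' @param source `"refseq"`, `"gencode"`, `"chess"`, or `"none"`.
#' @return Character vector of rule names for [apply_source_rules()].
#' @export
source_rules <- function(source = c("none", "gencode", "chess", "refseq")) {
  source <- match.arg(source)
  if (source == "refseq") c("vdj_rename", "drop_pseudogene_transcripts")
  else character(0)
}

#' Apply source-specific normalization rules to an annotation
#'
#' @param annotation An `annotation_set`.
#' @param rules Character vector; subset of `"vdj_rename"`,
#'   `"drop_pseudogene_transcripts"`. See [source_rules()].
#' @return The modified `annotation_set`; drop counts are appended to its log.
#' @export
apply_source_rules <- function(annotation, rules = character(0)) {
  stopifnot(inherits(annotation, "annotation_set"))
  ann <- annotation
  if ("vdj_rename" %in% rules && nrow(ann$segments)) {
    seg <- ann$segments
    seg$feature_type <- "transcript"
    ann$transcripts <- rbind(ann$transcripts, seg)
    ann$segments <- ann$segments[0, , drop = FALSE]
    ann$log$n_vdj_renamed <- nrow(seg)
  }
  if ("drop_pseudogene_transcripts" %in% rules) {
    drop <- !is.na(ann$transcripts$gene_biotype_raw) &
      ann$transcripts$gene_biotype_raw == "pseudogene"
    ann$log$n_pseudogene_transcripts_dropped <- sum(drop)
    ann$transcripts <- ann$transcripts[!drop, , drop = FALSE]
    ann$exons <- ann$exons[ann$exons$transcript_id %in%
                             ann$transcripts$transcript_id, , drop = FALSE]
  }
  rownames(ann$transcripts) <- NULL
  ann
}

#' Extract spliced transcript sequences from a genome
#'
#' Exons are sorted by genomic coordinate and concatenated; minus-strand
#' transcripts are reverse-complemented so the stored sequence is the mRNA
#' sense strand. Soft-masked (lowercase) genome bases are uppercased.
#'
#' @param annotation An `annotation_set`.
#' @param genome FASTA path or named sequence set (see [probes_from_bed()]).
#' @return The `annotation_set` with `transcripts$sequence` filled in.
#' @export
extract_transcript_sequences <- function(annotation, genome) {
  stopifnot(inherits(annotation, "annotation_set"))
  contigs <- load_genome(genome)
  tx <- annotation$transcripts
  ex <- annotation$exons
  missing_ctg <- setdiff(unique(ex$contig), names(contigs))
  if (length(missing_ctg)) {
    stop("annotation references contigs absent from genome: ",
         paste(missing_ctg, collapse = ", "), call. = FALSE)
  }
  over <- ex$end0 > nchar(contigs[ex$contig])
  if (any(over)) {
    stop("exon(s) beyond contig end in transcript(s): ",
         paste(unique(ex$transcript_id[over]), collapse = ", "), call. = FALSE)
  }
  ex$piece <- toupper(substr(contigs[ex$contig], ex$start0 + 1L, ex$end0))
  spliced <- vapply(split(ex$piece, ex$transcript_id), paste0, "",
                    collapse = "")
  seqs <- unname(spliced[tx$transcript_id])
  neg <- tx$strand == "-" & !is.na(seqs)
  seqs[neg] <- reverse_complement(seqs[neg])
  tx$sequence <- seqs
  if (any(is.na(tx$sequence))) {
    stop("no exons found for transcript(s): ",
         paste(tx$transcript_id[is.na(tx$sequence)], collapse = ", "),
         call. = FALSE)
  }
  annotation$transcripts <- tx
  annotation
}

#' Transcript sequences of an annotation as a named character vector
#'
#' @param annotation An `annotation_set` with sequences set, or any named
#'   character vector / `DNAStringSet` (passed through).
#' @return Named character vector, names = transcript IDs.
#' @export
transcript_seqs <- function(annotation) {
  if (inherits(annotation, "annotation_set")) {
    if (all(is.na(annotation$transcripts$sequence))) {
      stop("annotation has no sequences; run extract_transcript_sequences()",
           call. = FALSE)
    }
    return(stats::setNames(annotation$transcripts$sequence,
                           annotation$transcripts$transcript_id))
  }
  if (inherits(annotation, "DNAStringSet")) {
    return(stats::setNames(toupper(as.character(annotation)),
                           sub("\\s.*$", "", names(annotation))))
  }
  if (is.character(annotation) && !is.null(names(annotation))) {
    return(toupper(annotation))
  }
  stop("cannot interpret transcript set", call. = FALSE)
}

#' Canonical biotype of each gene in an annotation
#'
#' A gene's biotype is the highest-priority canonical label among its
#' transcripts (protein_coding > NMD > lncRNA > miRNA > pseudogene > other),
#' falling back to the gene-level annotation when it has no transcripts.
#'
#' @param annotation An `annotation_set`.
#' @return Named character vector gene_id -> canonical biotype.
#' @export
gene_biotypes <- function(annotation) {
  prio <- c(protein_coding = 1, NMD = 2, lncRNA = 3, miRNA = 4,
            pseudogene = 5, other = 6)
  tx <- annotation$transcripts
  by_gene <- split(tx$biotype, tx$gene_id)
  best <- vapply(by_gene, function(b) names(prio)[min(prio[b])], "")
  out <- stats::setNames(annotation$genes$biotype, annotation$genes$gene_id)
  out[names(best)] <- best
  out
}
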