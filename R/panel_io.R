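# Probe panel I/O: FASTA and BED readers, probe-identifier parsing, and the
# gene-synonym table used to decide on-target status.

#' Parse a probe identifier of the form gene_id|gene_name|accession
#'
#' Probe headers carry three fields separated by pipes. The split happens on
#' the first two pipes only, so accessions may themselves contain pipes.
#'
#' @param header Character vector of probe headers.
#' @return A data.frame with columns `gene_id`, `gene_name`, `accession`.
#' @examples
#' parse_probe_id("ENSG00000196154|S100A4|ab4e3dc")
#' @export
parse_probe_id <- function(header) {
  stopifnot(is.character(header))
  n_pipes <- nchar(header) - nchar(gsub("|", "", header, fixed = TRUE))
  bad <- n_pipes < 2L
  if (any(bad)) {
    stop("malformed probe header (need >=2 pipes): ",
         paste(utils::head(header[bad], 3), collapse = ", "), call. = FALSE)
  }
  p1 <- regexpr("|", header, fixed = TRUE)
  rest <- substr(header, p1 + 1L, nchar(header))
  p2 <- regexpr("|", rest, fixed = TRUE)
  data.frame(
    gene_id = substr(header, 1L, p1 - 1L),
    gene_name = substr(rest, 1L, p2 - 1L),
    accession = substr(rest, p2 + 1L, nchar(rest)),
    stringsAsFactors = FALSE
  )
}

#' Construct a probe panel
#'
#' A probe panel is an ordered collection of probe target sequences, each with
#' its declared target gene. Sequences are the RNA-sense 40-mers (typically)
#' that a padlock probe is designed to bind; orientation is fixed later by
#' [flip_panel()].
#'
#' @param probes data.frame with columns `probe_id`, `gene_id`, `gene_name`,
#'   `accession`, `sequence`; `length` and `flipped` are filled in.
#' @param name Free-text panel label.
#' @return An object of class `probe_panel`.
#' @export
probe_panel <- function(probes, name = "panel") {
  need <- c("probe_id", "gene_id", "gene_name", "accession", "sequence")
  miss <- setdiff(need, names(probes))
  if (length(miss)) stop("probe table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  probes$sequence <- toupper(probes$sequence)
  validate_sequence(probes$sequence, "probe sequence")
  if (any(nchar(probes$sequence) == 0L)) {
    stop("empty probe sequence in panel", call. = FALSE)
  }
  dup <- duplicated(probes$accession)
  if (any(dup)) {
    stop("duplicate probe accessions: ",
         paste(unique(probes$accession[dup]), collapse = ", "), call. = FALSE)
  }
  probes$length <- nchar(probes$sequence)
  if (is.null(probes$flipped)) probes$flipped <- FALSE
  rownames(probes) <- NULL
  structure(list(probes = probes, name = name), class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("probe_panel '%s': %d probes targeting %d genes\n",
              x$name, nrow(x$probes), length(unique(x$probes$gene_id))))
  invisible(x)
}

#' @export
length.probe_panel <- function(x) nrow(x$probes)

#' Read a probe panel from a FASTA file
#'
#' Headers are expected in `gene_id|gene_name|accession` form (see
#' [parse_probe_id()]); sequences are uppercased and must be over {A,C,G,T,N}.
#' Record order is preserved.
#'
#' @param path FASTA file of probe target sequences.
#' @param name Panel label; defaults to the file name.
#' @return A [probe_panel()].
#' @export
read_probe_fasta <- function(path, name = basename(path)) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty probe FASTA: ", path, call. = FALSE)
  headers <- sub("\\s.*$", "", names(seqs))
  ids <- parse_probe_id(headers)
  probes <- data.frame(
    probe_id = headers,
    gene_id = ids$gene_id,
    gene_name = ids$gene_name,
    accession = ids$accession,
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE
  )
  bad <- grepl("[^ACGTN]", probes$sequence)
  if (any(bad)) {
    stop("non-nucleotide characters in probe record(s): ",
         paste(probes$probe_id[bad], collapse = ", "), call. = FALSE)
  }
  probe_panel(probes, name = name)
}

#' Write a probe panel to FASTA
#'
#' @param panel A [probe_panel()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_probe_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  seqs <- Biostrings::BStringSet(panel$probes$sequence)
  names(seqs) <- panel$probes$probe_id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Extract probe sequences from BED intervals against a genome
#'
#' BED intervals are 0-based half-open; minus-strand intervals are
#' reverse-complemented so the stored sequence reads 5'->3' on the annotated
#' strand. The BED name field carries the gene identity; custom panels embed
#' gene name and ID differently, so `name_parser` may be supplied to split the
#' name into both fields (default: name is used as both gene_name and
#' gene_id).
#'
#' @param bed_path BED file of probe intervals.
#' @param genome Genome as a FASTA path or a named `DNAStringSet`/character
#'   vector of contig sequences.
#' @param name_parser Optional `function(name) list(gene_id=, gene_name=)`.
#' @param name Panel label.
#' @return A [probe_panel()]; accessions are `name:contig:start-end`.
#' @export
probes_from_bed <- function(bed_path, genome, name_parser = NULL,
                            name = basename(bed_path)) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (length(gr) == 0L) stop("empty BED file: ", bed_path, call. = FALSE)
  if (any(GenomicRanges::width(gr) == 0L)) {
    stop("zero-length interval in BED file: ", bed_path, call. = FALSE)
  }
  contigs <- load_genome(genome)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  missing_ctg <- setdiff(unique(chrom), names(contigs))
  if (length(missing_ctg)) {
    stop("BED references contigs absent from genome: ",
         paste(missing_ctg, collapse = ", "), call. = FALSE)
  }
  start1 <- GenomicRanges::start(gr)   # already 1-based after import
  end1 <- GenomicRanges::end(gr)
  over <- end1 > nchar(contigs[chrom])
  if (any(over)) {
    stop("BED interval(s) beyond contig end: ",
         paste(utils::head(paste0(chrom[over], ":", end1[over]), 3),
               collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(substr(contigs[chrom], start1, end1))
  strand <- as.character(GenomicRanges::strand(gr))
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  bed_name <- if (!is.null(gr$name)) gr$name else chrom
  if (is.null(name_parser)) {
    gene_id <- bed_name
    gene_name <- bed_name
  } else {
    parsed <- lapply(bed_name, name_parser)
    gene_id <- vapply(parsed, `[[`, "", "gene_id")
    gene_name <- vapply(parsed, `[[`, "", "gene_name")
  }
  accession <- sprintf("%s:%s:%d-%d", bed_name, chrom, start1 - 1L, end1)
  probes <- data.frame(
    probe_id = paste(gene_id, gene_name, accession, sep = "|"),
    gene_id = gene_id, gene_name = gene_name, accession = accession,
    sequence = seqs, stringsAsFactors = FALSE
  )
  probe_panel(probes, name = name)
}

#' @keywords internal
#' @noRd
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    g <- Biostrings::readDNAStringSet(genome)
    out <- toupper(as.character(g))
    names(out) <- sub("\\s.*$", "", names(g))
    return(out)
  }
  if (inherits(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  stop("genome must be a FASTA path or a named sequence set", call. = FALSE)
}

#' Load a gene-synonym table
#'
#' Two-column TSV of symbol pairs (no header required; a header row whose
#' fields are `symbol`/`synonym` is tolerated). The relation is made
#' symmetric, and every symbol is implicitly its own synonym, but it is NOT
#' transitively closed: chaining (A,B) and (B,C) does not make C a synonym of
#' A. This avoids welding unrelated gene families together through hub
#' symbols.
#'
#' @param path TSV path, or `NULL` for an empty (identity-only) table.
#' @return An object of class `synonym_table`.
#' @export
load_synonyms <- function(path = NULL) {
  entries <- list()
  if (!is.null(path) && file.size(path) > 0L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                            comment.char = "#", stringsAsFactors = FALSE,
                            col.names = c("a", "b"))
    df <- df[!(tolower(df$a) %in% c("symbol", "gene") &
                 tolower(df$b) %in% c("synonym", "alias")), , drop = FALSE]
    entries <- build_synonym_entries(df$a, df$b)
  }
  structure(list(entries = entries), class = "synonym_table")
}

#' Build a synonym table from symbol pairs
#'
#' @param a,b Character vectors of paired symbols.
#' @return A `synonym_table`.
#' @export
synonym_table <- function(a = character(0), b = character(0)) {
  structure(list(entries = build_synonym_entries(a, b)),
            class = "synonym_table")
}

#' @keywords internal
#' @noRd
build_synonym_entries <- function(a, b) {
  stopifnot(length(a) == length(b))
  entries <- list()
  add <- function(x, y) {
    entries[[x]] <<- sort(unique(c(entries[[x]], y)))
  }
  for (i in seq_along(a)) {
    add(a[i], b[i])
    add(b[i], a[i])
  }
  entries
}

#' Look up the synonym set of a gene symbol
#'
#' Always contains the symbol itself. Symmetric but not transitive.
#'
#' @param table A `synonym_table`.
#' @param symbol Gene symbol.
#' @return Character vector of equivalent symbols.
#' @export
synonyms <- function(table, symbol) {
  stopifnot(inherits(table, "synonym_table"), length(symbol) == 1L)
  sort(unique(c(symbol, table$entries[[symbol]])))
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf("synonym_table: %d symbols with declared synonyms\n",
              length(x$entries)))
  invisible(x)
}
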