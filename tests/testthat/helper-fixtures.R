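# Shared in-code fixtures. Everything is built programmatically; no binary
# data is stored.

# Minimal in-memory annotation: one transcript per row of `tx`
# (transcript_id, gene_id, gene_name, biotype, sequence).
make_tiny_annotation <- function(tx, source = "tiny") {
  tx$feature_type <- "transcript"
  tx$contig <- "chr1"
  if (is.null(tx$strand)) tx$strand <- "+"
  tx$biotype_raw <- tx$biotype
  tx$gene_biotype_raw <- tx$biotype
  tx$n_exons <- 1L
  genes <- unique(tx[, c("gene_id", "gene_name", "biotype")])
  genes$biotype_raw <- genes$biotype
  exons <- data.frame(transcript_id = character(0), contig = character(0),
                      strand = character(0), start0 = integer(0),
                      end0 = integer(0), stringsAsFactors = FALSE)
  offtargetr:::new_annotation_set(
    transcripts = tx, exons = exons, genes = genes, source = source)
}

make_tiny_panel <- function(gene_id, gene_name, accession, sequence,
                            name = "tiny") {
  probe_panel(data.frame(
    probe_id = paste(gene_id, gene_name, accession, sep = "|"),
    gene_id = gene_id, gene_name = gene_name, accession = accession,
    sequence = sequence, stringsAsFactors = FALSE), name = name)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small shared simulation; computed once per test session.
shared_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_panel(synthetic_config(), seed = 42L)
    sim
  }
})

# Sorted (accession, bound_gene_id, on_target) view of a call table, the
# shape expected_calls() uses.
call_view <- function(calls) {
  v <- calls[, c("accession", "bound_gene_id", "on_target")]
  v <- v[order(v$accession, v$bound_gene_id), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# GFF3 text for one plus- and one minus-strand gene on a 60 bp contig;
# used by the annotation tests together with `tiny_genome`.
tiny_genome <- c(chr1 = "ACGTAAGGCCTTAGCATGCATGCCGTACGTAAACCCGGGTTTAAACGCGCGATATCGAT")

write_tiny_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t30\t.\t+\t.\tID=gene:G1;gene_id=G1;Name=GENE1;biotype=protein_coding",
    "chr1\ttest\ttranscript\t1\t30\t.\t+\t.\tID=transcript:T1;Parent=gene:G1;transcript_id=T1;biotype=protein_coding",
    "chr1\ttest\texon\t1\t10\t.\t+\t.\tID=exon:T1.1;Parent=transcript:T1",
    "chr1\ttest\texon\t21\t30\t.\t+\t.\tID=exon:T1.2;Parent=transcript:T1",
    "chr1\ttest\ttranscript\t1\t10\t.\t+\t.\tID=transcript:T2;Parent=gene:G1;transcript_id=T2;biotype=nonsense_mediated_decay",
    "chr1\ttest\texon\t1\t10\t.\t+\t.\tID=exon:T2.1;Parent=transcript:T2",
    "chr1\ttest\tgene\t31\t50\t.\t-\t.\tID=gene:G2;gene_id=G2;Name=GENE2;biotype=processed_pseudogene",
    "chr1\ttest\ttranscript\t31\t50\t.\t-\t.\tID=transcript:T3;Parent=gene:G2;transcript_id=T3;biotype=processed_pseudogene",
    "chr1\ttest\texon\t31\t40\t.\t-\t.\tID=exon:T3.1;Parent=transcript:T3",
    "chr1\ttest\texon\t45\t50\t.\t-\t.\tID=exon:T3.2;Parent=transcript:T3"
  ), path)
  path
}

write_tiny_gtf <- function(path) {
  writeLines(c(
    paste0("chr1\ttest\tgene\t1\t30\t.\t+\t.\t",
           'gene_id "G1"; gene_name "GENE1"; gene_biotype "protein_coding";'),
    paste0("chr1\ttest\ttranscript\t1\t30\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; gene_name "GENE1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";'),
    paste0("chr1\ttest\texon\t1\t10\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chr1\ttest\texon\t21\t30\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chr1\ttest\ttranscript\t1\t10\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T2"; gene_name "GENE1"; gene_biotype "protein_coding"; transcript_biotype "nonsense_mediated_decay";'),
    paste0("chr1\ttest\texon\t1\t10\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T2";'),
    paste0("chr1\ttest\tgene\t31\t50\t.\t-\t.\t",
           'gene_id "G2"; gene_name "GENE2"; gene_biotype "processed_pseudogene";'),
    paste0("chr1\ttest\ttranscript\t31\t50\t.\t-\t.\t",
           'gene_id "G2"; transcript_id "T3"; gene_name "GENE2"; gene_biotype "processed_pseudogene"; transcript_biotype "processed_pseudogene";'),
    paste0("chr1\ttest\texon\t31\t40\t.\t-\t.\t",
           'gene_id "G2"; transcript_id "T3";'),
    paste0("chr1\ttest\texon\t45\t50\t.\t-\t.\t",
           'gene_id "G2"; transcript_id "T3";')
  ), path)
  path
}
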