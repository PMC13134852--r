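test_that("GFF3 parsing resolves the gene/transcript/exon hierarchy", {
  gff <- write_tiny_gff3(withr::local_tempfile(fileext = ".gff3"))
  ann <- parse_annotation(gff, source = "tiny")
  expect_s3_class(ann, "annotation_set")
  expect_setequal(ann$transcripts$transcript_id, c("T1", "T2", "T3"))
  expect_equal(sum(ann$transcripts$gene_id == "G1"), 2L)
  expect_equal(ann$transcripts$n_exons[ann$transcripts$transcript_id == "T1"],
               2L)
  # transcript-level biotype preferred over gene-level
  expect_equal(
    ann$transcripts$biotype[ann$transcripts$transcript_id == "T2"], "NMD")
  expect_equal(
    ann$transcripts$biotype[ann$transcripts$transcript_id == "T3"],
    "pseudogene")
})

test_that("GFF3 and GTF encodings of the same fixture are equivalent", {
  gff <- write_tiny_gff3(withr::local_tempfile(fileext = ".gff3"))
  gtf <- write_tiny_gtf(withr::local_tempfile(fileext = ".gtf"))
  a <- parse_annotation(gff, source = "x")
  b <- parse_annotation(gtf, source = "x")
  cols <- c("transcript_id", "gene_id", "gene_name", "biotype", "contig",
            "strand", "n_exons")
  ord <- function(d) {
    d <- d[order(d$transcript_id), cols]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(a$transcripts), ord(b$transcripts))
  ea <- a$exons[order(a$exons$transcript_id, a$exons$start0), ]
  eb <- b$exons[order(b$exons$transcript_id, b$exons$start0), ]
  rownames(ea) <- rownames(eb) <- NULL
  expect_equal(ea, eb)
  # identical spliced sequences through extraction too
  sa <- transcript_seqs(extract_transcript_sequences(a, tiny_genome))
  sb <- transcript_seqs(extract_transcript_sequences(b, tiny_genome))
  expect_equal(sa[sort(names(sa))], sb[sort(names(sb))])
})

test_that("alt-scaffold features are removed when filtering is on", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t10\t.\t+\t.\tID=gene:G1;gene_id=G1;biotype=protein_coding",
    "chr1\tt\ttranscript\t1\t10\t.\t+\t.\tID=transcript:T1;Parent=gene:G1;biotype=protein_coding",
    "chr1\tt\texon\t1\t10\t.\t+\t.\tID=e1;Parent=transcript:T1",
    "chr1_KI270706v1_random\tt\tgene\t1\t10\t.\t+\t.\tID=gene:G9;gene_id=G9;biotype=protein_coding",
    "chr1_KI270706v1_random\tt\ttranscript\t1\t10\t.\t+\t.\tID=transcript:T9;Parent=gene:G9;biotype=protein_coding",
    "chr1_KI270706v1_random\tt\texon\t1\t10\t.\t+\t.\tID=e9;Parent=transcript:T9"
  ), gff)
  ann <- parse_annotation(gff)
  expect_equal(ann$transcripts$transcript_id, "T1")
  expect_false(any(grepl("_random", ann$transcripts$contig)))
  expect_equal(ann$log$n_alt_scaffold_dropped, 1L)
  ann_all <- parse_annotation(gff, drop_alt_scaffolds = FALSE)
  expect_setequal(ann_all$transcripts$transcript_id, c("T1", "T9"))
})

test_that("spliced extraction concatenates exons and honors strand", {
  # two-exon minus-strand oracle: exons (0,3) and (4,6) of "ACGTAAG",
  # spliced "ACG"+"AA" = "ACGAA", revcomp = "TTCGT" (hand-computed)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c\tt\tgene\t1\t6\t.\t-\t.\tID=gene:G;gene_id=G;biotype=protein_coding",
    "c\tt\ttranscript\t1\t6\t.\t-\t.\tID=transcript:T;Parent=gene:G;biotype=protein_coding",
    "c\tt\texon\t1\t3\t.\t-\t.\tID=e1;Parent=transcript:T",
    "c\tt\texon\t5\t6\t.\t-\t.\tID=e2;Parent=transcript:T"
  ), gff)
  ann <- extract_transcript_sequences(parse_annotation(gff),
                                      c(c = "ACGTAAG"))
  expect_equal(unname(transcript_seqs(ann)["T"]), "TTCGT")

  # single-exon plus strand: identity
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c\tt\tgene\t1\t6\t.\t+\t.\tID=gene:G;gene_id=G;biotype=protein_coding",
    "c\tt\ttranscript\t1\t6\t.\t+\t.\tID=transcript:T;Parent=gene:G;biotype=protein_coding",
    "c\tt\texon\t1\t6\t.\t+\t.\tID=e1;Parent=transcript:T"
  ), gff2)
  ann2 <- extract_transcript_sequences(parse_annotation(gff2),
                                       c(c = "acgtaa"))
  expect_equal(unname(transcript_seqs(ann2)["T"]), "ACGTAA")  # uppercased

  expect_error(extract_transcript_sequences(parse_annotation(gff2),
                                            c(zzz = "ACGTAA")),
               "absent from genome")
  expect_error(extract_transcript_sequences(parse_annotation(gff2),
                                            c(c = "ACG")),
               "beyond contig end")
})

test_that("spliced length equals the sum of exon lengths (property)", {
  sim <- shared_sim()
  td <- withr::local_tempdir()
  paths <- write_simulation(sim, td)
  ann <- parse_annotation(paths$annotations[["synthA"]])
  ann <- extract_transcript_sequences(ann, paths$genome)
  exon_len <- tapply(ann$exons$end0 - ann$exons$start0,
                     ann$exons$transcript_id, sum)
  expect_equal(nchar(ann$transcripts$sequence),
               as.vector(exon_len[ann$transcripts$transcript_id]))
  # and the parsed+extracted set matches the in-memory truth
  expect_equal(
    sort(transcript_seqs(ann)),
    sort(transcript_seqs(sim$annotations[["synthA"]])))
})

test_that("source rules promote VDJ segments and drop pseudogene transcripts", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c\tt\tgene\t1\t8\t.\t+\t.\tID=gene:G1;gene_id=G1;biotype=protein_coding",
    "c\tt\tV_gene_segment\t1\t8\t.\t+\t.\tID=transcript:V1;Parent=gene:G1",
    "c\tt\texon\t1\t8\t.\t+\t.\tID=e1;Parent=transcript:V1",
    "c\tt\tgene\t11\t18\t.\t+\t.\tID=gene:G2;gene_id=G2;biotype=pseudogene",
    "c\tt\ttranscript\t11\t18\t.\t+\t.\tID=transcript:T2;Parent=gene:G2;biotype=pseudogene",
    "c\tt\texon\t11\t18\t.\t+\t.\tID=e2;Parent=transcript:T2",
    "c\tt\tgene\t21\t28\t.\t+\t.\tID=gene:G3;gene_id=G3;biotype=transcribed_pseudogene",
    "c\tt\ttranscript\t21\t28\t.\t+\t.\tID=transcript:T3;Parent=gene:G3;biotype=transcribed_pseudogene",
    "c\tt\texon\t21\t28\t.\t+\t.\tID=e3;Parent=transcript:T3"
  ), gff)
  ann <- parse_annotation(gff)
  # segment quarantined until the rule runs
  expect_false("V1" %in% ann$transcripts$transcript_id)
  expect_true("V1" %in% ann$segments$transcript_id)

  fixed <- apply_source_rules(ann, source_rules("refseq"))
  expect_true("V1" %in% fixed$transcripts$transcript_id)
  # gene_biotype 'pseudogene' transcripts removed; transcribed_pseudogene kept
  expect_false("T2" %in% fixed$transcripts$transcript_id)
  expect_true("T3" %in% fixed$transcripts$transcript_id)
  expect_equal(fixed$log$n_pseudogene_transcripts_dropped, 1L)

  # identity when no rules requested
  same <- apply_source_rules(ann, source_rules("gencode"))
  expect_equal(same$transcripts, ann$transcripts)
})

test_that("normalize_biotype maps source vocabularies to canonical labels", {
  expect_equal(normalize_biotype("protein_coding"), "protein_coding")
  expect_equal(normalize_biotype("nonsense_mediated_decay"), "NMD")
  expect_equal(normalize_biotype("transcribed_pseudogene"), "pseudogene")
  expect_equal(
    normalize_biotype(c("transcribed_unprocessed_pseudogene", "lincRNA",
                        "lnc_RNA", "miRNA", "snoRNA", "IG_V_gene")),
    c("pseudogene", "lncRNA", "lncRNA", "miRNA", "other", "protein_coding"))
})
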