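# A compact hand-built world: target gene G1 (3 isoforms), paralog P1,
# pseudogene PS, a synonym-named gene, and a read-through gene.
tracker_world <- function() {
  set.seed(991)
  seqs <- list(
    t1a = random_dna(33), p1 = random_dna(30), ps = random_dna(30),
    nars1 = random_dna(30), rt = random_dna(30))
  ann <- make_tiny_annotation(data.frame(
    transcript_id = c("T1A", "T1B", "T1C", "TP1", "TPS", "TN1", "TRT"),
    gene_id = c("G1", "G1", "G1", "P1", "PS", "N1", "RT"),
    gene_name = c("ALPHA", "ALPHA", "ALPHA", "ALPHA2", "ALPHAP", "NARS1",
                  "DNAAF1-CCPG1"),
    biotype = c(rep("protein_coding", 4), "pseudogene", "protein_coding",
                "protein_coding"),
    sequence = unlist(seqs[c("t1a", "t1a", "t1a", "p1", "ps", "nars1",
                             "rt")]),
    stringsAsFactors = FALSE))
  ann
}

test_that("is_on_target honors ids, names and synonyms", {
  syn <- synonym_table("NARS", "NARS1")
  expect_true(is_on_target("G1", "A", "G1", "B"))     # same id, names differ
  expect_true(is_on_target("GX", "NARS", "GY", "NARS1", syn))
  expect_false(is_on_target("GX", "NARS", "GY", "NARS1"))  # no table
  expect_false(is_on_target("G1", "A", "G2", "B"))
  # multi-symbol target declaration: any declared symbol is on-target
  expect_true(is_on_target("GX", "CLECL1; CLECL1P", "GY", "CLECL1P"))
})

test_that("flag_readthrough requires the target as a hyphen component", {
  expect_true(flag_readthrough("DNAAF1-CCPG1", "CCPG1"))
  expect_true(flag_readthrough("DNAAF1-CCPG1", "DNAAF1"))
  expect_false(flag_readthrough("POLR2J2-UPK3BL1", "POLR2J3"))
  expect_false(flag_readthrough("ABC", "ABC"))
  syn <- synonym_table("CCPG1", "CPR8")
  expect_true(flag_readthrough("DNAAF1-CCPG1", "CPR8", syn))
})

test_that("call_bindings groups hits by gene and dedupes isoforms", {
  ann <- tracker_world()
  probe <- substr(transcript_seqs(ann)[["T1A"]], 10, 29)
  panel <- make_tiny_panel("G1", "ALPHA", "pr1", probe)
  hits <- find_panel_hits(panel, ann, aligner_config(pl = 0))
  expect_equal(sort(unique(hits$transcript_id)), c("T1A", "T1B", "T1C"))
  calls <- call_bindings(hits, ann, panel)
  # 3 isoforms of one gene -> one on-target call with n_transcripts_hit = 3
  expect_equal(nrow(calls), 1L)
  expect_true(calls$on_target)
  expect_equal(calls$n_transcripts_hit, 3L)
})

test_that("off-target calls carry biotype, synonym and readthrough logic", {
  ann <- tracker_world()
  seqs <- transcript_seqs(ann)
  panel <- make_tiny_panel(
    gene_id = c("G1", "G1", "GN"), gene_name = c("ALPHA", "ALPHA", "NARS"),
    accession = c("hitP1", "hitRT", "hitN1"),
    sequence = c(substr(seqs[["TP1"]], 3, 22), substr(seqs[["TRT"]], 5, 24),
                 substr(seqs[["TN1"]], 1, 20)))
  syn <- synonym_table("NARS", "NARS1")
  hits <- find_panel_hits(panel, ann, aligner_config(pl = 0))
  calls <- call_bindings(hits, ann, panel, syn)
  p1 <- calls[calls$accession == "hitP1", ]
  expect_false(p1$on_target)
  expect_equal(p1$biotype, "protein_coding")
  rt <- calls[calls$accession == "hitRT", ]
  expect_false(rt$on_target)
  expect_false(rt$readthrough)  # CCPG1 is not ALPHA's component
  n1 <- calls[calls$accession == "hitN1", ]
  expect_true(n1$on_target)     # synonym rescued

  expect_error(
    call_bindings(data.frame(accession = "hitP1", transcript_id = "ZZZ",
                             offset = 0L, probe_start = 1L, probe_end = 20L,
                             mode = "strict", pl = 0L,
                             pad_left = NA_integer_,
                             pad_right = NA_integer_),
                  ann, panel),
    "absent from annotation")
})

test_that("summarize_gene orders predicted genes by probes aligned", {
  # synthetic analog of a summary row: 8 probes hit target, 2 hit P1, 1 P2
  ann <- make_tiny_annotation(data.frame(
    transcript_id = c("TT", "TP1", "TP2"),
    gene_id = c("G", "P1", "P2"), gene_name = c("TGT", "PARA1", "PARA2"),
    biotype = "protein_coding",
    sequence = c(paste(rep("ACGGTTCAGGCATTACCAGG", 9), collapse = ""),
                 "", ""), stringsAsFactors = FALSE))
  set.seed(3)
  tseq <- random_dna(320)
  ann$transcripts$sequence[1] <- tseq
  probes <- vapply(0:7, function(i) substr(tseq, i * 40 + 1, i * 40 + 40), "")
  ann$transcripts$sequence[2] <- paste0(probes[1], probes[2])  # P1: 2 probes
  ann$transcripts$sequence[3] <- probes[3]                     # P2: 1 probe
  panel <- make_tiny_panel(rep("G", 8), rep("TGT", 8), paste0("p", 1:8),
                           probes)
  hits <- find_panel_hits(panel, ann, aligner_config(pl = 0))
  calls <- call_bindings(hits, ann, panel)
  s <- summarize_gene(calls, panel)
  expect_equal(s$n_probes, 8L)
  expect_equal(s$predicted$gene_name, c("TGT", "PARA1", "PARA2"))
  expect_equal(s$predicted$n_probes_aligned, c(8L, 2L, 1L))

  # counts are permutation-invariant in hit order
  calls_perm <- calls[rev(seq_len(nrow(calls))), ]
  s2 <- summarize_gene(calls_perm, panel)
  expect_equal(s2$predicted, s$predicted)
})

test_that("filter_protein_coding drops non-coding off-targets only", {
  calls <- data.frame(
    accession = c("a", "a", "b"),
    target_gene_id = "G", target_gene_name = "TGT",
    bound_gene_id = c("G", "PS", "L1"),
    bound_gene_name = c("TGT", "TGTP", "LNC1"),
    biotype = c("protein_coding", "pseudogene", "lncRNA"),
    on_target = c(TRUE, FALSE, FALSE), readthrough = FALSE,
    n_transcripts_hit = 1L, mode = "strict", pl = 0L,
    stringsAsFactors = FALSE)
  kept <- filter_protein_coding(calls)
  expect_equal(kept$bound_gene_id, "G")   # on-target survives regardless
  pcalls <- calls
  pcalls$biotype[2] <- "protein_coding"
  kept2 <- filter_protein_coding(pcalls)
  expect_setequal(kept2$bound_gene_id, c("G", "PS"))
  expect_equal(nrow(filter_protein_coding(calls[0, ])), 0L)
})
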