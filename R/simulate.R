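# Synthetic fixture generator: genomes, annotations, probe panels and
# two-platform expression matrices with a machine-readable truth table.
# Every off-target scenario the tool must detect is planted explicitly:
#   perfect        - a paralog sharing a probe's full 40-mer
#   core d         - a paralog sharing only the central core, with a
#                    mismatch planted at depth d from EACH probe end
#                    (detected iff pad length >= d)
#   pseudogene     - a perfect copy carried by a pseudogene
#   source_specific- a perfect-copy paralog annotated in only some sources
#   retired        - probes cut from sequence absent from every transcript
# plus antisense storage of most probes (the flip scenario).
#
# Cross-gene uniqueness of every k-mer (k = core length, both strands) is
# enforced by rejection sampling against a global registry, so exact-count
# assertions against the truth table are valid: no accidental off-targets
# can exist.

#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the shape of a real padlock-probe panel: 40-bp probe
#' target sequences (two 20-bp arms around the ligation junction), a handful
#' of probes per gene, almost all probes stored antisense to their target
#' (0.99, matching the observed 2563/2582), and a small number of probes
#' designed on retired exon models that no current transcript contains.
#'
#' @param n_genes Number of target genes.
#' @param probes_per_gene Probes per target gene.
#' @param probe_length Probe target sequence length (bp).
#' @param transcript_length Length of each synthetic transcript (bp).
#' @param n_sources Number of synthetic annotation sources.
#' @param n_perfect,n_core10,n_core5,n_pseudogene,n_source_specific Number of
#'   target genes assigned to each planted off-target scenario.
#' @param n_retired Number of planted retired-exon probes (appended).
#' @param antisense_prob Probability a probe is stored antisense.
#' @param intron_length,spacer Gene-structure layout on the genome (bp).
#' @param max_tries Rejection-sampling retries before giving up.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 20L, probes_per_gene = 4L,
                             probe_length = 40L, transcript_length = 240L,
                             n_sources = 3L, n_perfect = 3L, n_core10 = 2L,
                             n_core5 = 1L, n_pseudogene = 2L,
                             n_source_specific = 2L, n_retired = 2L,
                             antisense_prob = 0.99, intron_length = 50L,
                             spacer = 25L, max_tries = 50L) {
  cfg <- list(n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              probe_length = as.integer(probe_length),
              transcript_length = as.integer(transcript_length),
              n_sources = as.integer(n_sources),
              n_perfect = as.integer(n_perfect),
              n_core10 = as.integer(n_core10),
              n_core5 = as.integer(n_core5),
              n_pseudogene = as.integer(n_pseudogene),
              n_source_specific = as.integer(n_source_specific),
              n_retired = as.integer(n_retired),
              antisense_prob = antisense_prob,
              intron_length = as.integer(intron_length),
              spacer = as.integer(spacer),
              max_tries = as.integer(max_tries))
  n_scen <- with(cfg, n_perfect + n_core10 + n_core5 + n_pseudogene +
                   n_source_specific)
  if (n_scen > cfg$n_genes) {
    stop("scenario gene counts exceed n_genes", call. = FALSE)
  }
  if (cfg$probe_length %% 2L != 0L) {
    stop("probe_length must be even (two equal arms)", call. = FALSE)
  }
  if (cfg$transcript_length < cfg$probe_length * cfg$probes_per_gene) {
    stop("transcript too short for non-overlapping probes", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' @keywords internal
#' @noRd
kmer_registry <- function() new.env(parent = emptyenv())

#' @keywords internal
#' @noRd
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' @keywords internal
#' @noRd
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw a sequence whose k-mers (both strands) collide neither with the
# registry nor with themselves, then register them.
#' @keywords internal
#' @noRd
draw_unique_seq <- function(n, k, registry, max_tries) {
  for (try in seq_len(max_tries)) {
    s <- random_seq(n)
    fwd <- seq_kmers(s, k)
    rev <- seq_kmers(reverse_complement(s), k)
    all_k <- c(fwd, rev)
    if (anyDuplicated(all_k)) next
    if (any(vapply(all_k, exists, TRUE, envir = registry))) next
    for (km in all_k) assign(km, TRUE, envir = registry)
    return(s)
  }
  stop("could not draw a globally unique sequence after ", max_tries,
       " tries; config infeasible", call. = FALSE)
}

#' @keywords internal
#' @noRd
register_seq <- function(s, k, registry) {
  for (km in c(seq_kmers(s, k), seq_kmers(reverse_complement(s), k))) {
    assign(km, TRUE, envir = registry)
  }
}

#' @keywords internal
#' @noRd
mutate_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  paste0(substr(seq, 1L, pos - 1L), new, substr(seq, pos + 1L, nchar(seq)))
}

# Biotype vocabularies per synthetic source, exercising the normalizer.
#' @keywords internal
#' @noRd
raw_biotype_for <- function(canonical, source_idx) {
  if (canonical == "protein_coding") return("protein_coding")
  if (canonical == "pseudogene") {
    return(c("processed_pseudogene", "transcribed_pseudogene",
             "pseudogene")[((source_idx - 1L) %% 3L) + 1L])
  }
  canonical
}

#' Generate a synthetic probe panel, genome and annotations with truth
#'
#' Deterministic for a fixed seed. Returns in-memory objects; use
#' [write_simulation()] to emit standard FASTA/GFF3/TSV files.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list of class `opt_simulation`: `genome` (named contig
#'   sequences), `panel` (a [probe_panel()] as supplied to the tool, i.e.
#'   mostly antisense), `annotations` (named list of `annotation_set` with
#'   sequences), `truth` (list of data.frames `probes` and `genes`),
#'   `config`, `seed`.
#' @export
simulate_panel <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  k <- config$probe_length %/% 2L   # core length at the canonical pad of L/4
  registry <- kmer_registry()
  n <- config$n_genes
  scen <- rep("clean", n)
  idx <- 1L
  assign_scen <- function(scen, label, count) {
    if (count > 0L) scen[idx:(idx + count - 1L)] <- label
    scen
  }
  scen <- assign_scen(scen, "perfect", config$n_perfect)
  idx <- idx + config$n_perfect
  scen <- assign_scen(scen, "core10", config$n_core10)
  idx <- idx + config$n_core10
  scen <- assign_scen(scen, "core5", config$n_core5)
  idx <- idx + config$n_core5
  scen <- assign_scen(scen, "pseudogene", config$n_pseudogene)
  idx <- idx + config$n_pseudogene
  scen <- assign_scen(scen, "source_specific", config$n_source_specific)

  sources <- paste0("synth", LETTERS[seq_len(config$n_sources)])
  all_sources_str <- paste(sources, collapse = ",")
  # source-specific paralogs are absent from the first source
  late_sources_str <- paste(sources[-1L], collapse = ",")

  genes <- list(); transcripts <- list(); probes <- list()
  truth_probes <- list()
  L <- config$transcript_length
  plen <- config$probe_length

  for (i in seq_len(n)) {
    gid <- sprintf("SYNG%04d", i)
    gname <- sprintf("GENE%03d", i)
    tseq <- draw_unique_seq(L, k, registry, config$max_tries)
    strand <- if (i %% 2L == 0L) "-" else "+"
    two_isoforms <- (i %% 5L == 0L) && strand == "+"
    genes[[gid]] <- list(gene_id = gid, gene_name = gname,
                         biotype = "protein_coding", is_paralog = FALSE,
                         sources = all_sources_str, strand = strand)
    transcripts[[paste0(gid, ".t1")]] <- list(
      transcript_id = paste0("SYNT", sprintf("%04d", i), ".1"),
      gene_id = gid, sequence = tseq, strand = strand, isoform = 1L)
    if (two_isoforms) {
      transcripts[[paste0(gid, ".t2")]] <- list(
        transcript_id = paste0("SYNT", sprintf("%04d", i), ".2"),
        gene_id = gid, sequence = substr(tseq, 31L, L), strand = strand,
        isoform = 2L)
    }

    # evenly spaced, non-overlapping probe positions
    pos <- round(seq(1L, L - plen + 1L,
                     length.out = config$probes_per_gene))
    for (j in seq_len(config$probes_per_gene)) {
      target_seq <- substr(tseq, pos[j], pos[j] + plen - 1L)
      antisense <- stats::runif(1) < config$antisense_prob
      stored <- if (antisense) reverse_complement(target_seq) else target_seq
      acc <- sprintf("p%03d_%d", i, j)
      probes[[acc]] <- list(
        probe_id = paste(gid, gname, acc, sep = "|"),
        gene_id = gid, gene_name = gname, accession = acc,
        sequence = stored)
      planted <- j == 1L && scen[i] != "clean"
      truth_probes[[acc]] <- data.frame(
        accession = acc, gene_id = gid, gene_name = gname,
        scenario = if (planted) scen[i] else "clean",
        antisense = antisense, retired = FALSE,
        offtarget_gene_id = NA_character_,
        offtarget_gene_name = NA_character_,
        d = NA_integer_,
        offtarget_sources = NA_character_,
        stringsAsFactors = FALSE)
    }

    if (scen[i] != "clean") {
      # paralog carrying a planted copy of probe 1's target-sense 40-mer
      pid <- sprintf("SYNG%04dP", i)
      pname <- sprintf("%sP1", gname)
      probe1 <- substr(tseq, pos[1], pos[1] + plen - 1L)
      copy <- probe1
      d <- NA_integer_
      if (scen[i] == "core10") d <- 10L
      if (scen[i] == "core5") d <- 5L
      if (!is.na(d)) {
        copy <- mutate_base(copy, d)            # depth d from the left end
        copy <- mutate_base(copy, plen + 1L - d) # and from the right end
      }
      background <- draw_unique_seq(L, k, registry, config$max_tries)
      embed_at <- 81L
      pseq <- paste0(substr(background, 1L, embed_at - 1L), copy,
                     substr(background, embed_at + plen, L))
      register_seq(pseq, k, registry)
      pbio <- if (scen[i] == "pseudogene") "pseudogene" else "protein_coding"
      psources <- if (scen[i] == "source_specific") late_sources_str
                  else all_sources_str
      genes[[pid]] <- list(gene_id = pid, gene_name = pname, biotype = pbio,
                           is_paralog = TRUE, sources = psources,
                           strand = "+")
      transcripts[[paste0(pid, ".t1")]] <- list(
        transcript_id = sprintf("SYNT%04dP.1", i),
        gene_id = pid, sequence = pseq, strand = "+", isoform = 1L)
      acc1 <- sprintf("p%03d_1", i)
      truth_probes[[acc1]]$offtarget_gene_id <- pid
      truth_probes[[acc1]]$offtarget_gene_name <- pname
      truth_probes[[acc1]]$d <- d
      truth_probes[[acc1]]$offtarget_sources <- psources
    }
  }

  # retired-exon probes: sequence in no transcript, assigned to gene 1
  for (r in seq_len(config$n_retired)) {
    rseq <- draw_unique_seq(plen, k, registry, config$max_tries)
    acc <- sprintf("pret_%d", r)
    gid <- sprintf("SYNG%04d", 1L)
    gname <- sprintf("GENE%03d", 1L)
    antisense <- stats::runif(1) < config$antisense_prob
    probes[[acc]] <- list(
      probe_id = paste(gid, gname, acc, sep = "|"),
      gene_id = gid, gene_name = gname, accession = acc,
      sequence = if (antisense) reverse_complement(rseq) else rseq)
    truth_probes[[acc]] <- data.frame(
      accession = acc, gene_id = gid, gene_name = gname,
      scenario = "retired", antisense = antisense, retired = TRUE,
      offtarget_gene_id = NA_character_, offtarget_gene_name = NA_character_,
      d = NA_integer_, offtarget_sources = NA_character_,
      stringsAsFactors = FALSE)
  }

  truth_genes <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, gene_name = g$gene_name,
               biotype = g$biotype, is_paralog = g$is_paralog,
               sources = g$sources, stringsAsFactors = FALSE)
  }))
  rownames(truth_genes) <- NULL
  truth_probes_df <- do.call(rbind, truth_probes)
  rownames(truth_probes_df) <- NULL

  panel <- probe_panel(do.call(rbind, lapply(probes, function(p) {
    data.frame(probe_id = p$probe_id, gene_id = p$gene_id,
               gene_name = p$gene_name, accession = p$accession,
               sequence = p$sequence, stringsAsFactors = FALSE)
  })), name = sprintf("synthetic_panel_seed%d", seed))

  layout <- layout_genome(genes, transcripts, config)
  annotations <- lapply(seq_along(sources), function(si) {
    build_annotation(sources[si], si, genes, transcripts, layout, sources)
  })
  names(annotations) <- sources

  structure(list(genome = layout$genome, panel = panel,
                 annotations = annotations,
                 truth = list(probes = truth_probes_df, genes = truth_genes),
                 config = config, seed = seed,
                 sources = sources),
            class = "opt_simulation")
}

# Place every gene on one contig: exon1 + intron + exon2 (minus-strand genes
# are laid down reverse-complemented), separated by spacers.
#' @keywords internal
#' @noRd
layout_genome <- function(genes, transcripts, config) {
  contig <- "chrS1"
  pieces <- character(0)
  cursor <- 0L
  loci <- list()
  exon1_len <- 100L
  for (gid in names(genes)) {
    g <- genes[[gid]]
    t1 <- NULL
    for (tx in transcripts) if (tx$gene_id == gid && tx$isoform == 1L) t1 <- tx
    tseq <- t1$sequence
    L <- nchar(tseq)
    e1 <- substr(tseq, 1L, exon1_len)
    e2 <- substr(tseq, exon1_len + 1L, L)
    intron <- random_seq(config$intron_length)
    if (g$strand == "+") {
      locus_seq <- paste0(e1, intron, e2)
      ex <- list(c(cursor, cursor + exon1_len),
                 c(cursor + exon1_len + config$intron_length, cursor + L +
                     config$intron_length))
    } else {
      locus_seq <- paste0(reverse_complement(e2), intron,
                          reverse_complement(e1))
      ex <- list(c(cursor, cursor + (L - exon1_len)),
                 c(cursor + (L - exon1_len) + config$intron_length,
                   cursor + L + config$intron_length))
    }
    loci[[gid]] <- list(contig = contig, exons = ex, strand = g$strand,
                        exon1_len = exon1_len, tx_len = L)
    pieces <- c(pieces, locus_seq, random_seq(config$spacer))
    cursor <- cursor + nchar(locus_seq) + config$spacer
  }
  genome <- stats::setNames(paste(pieces, collapse = ""), contig)
  list(genome = genome, loci = loci)
}

#' @keywords internal
#' @noRd
build_annotation <- function(source, source_idx, genes, transcripts, layout,
                             sources) {
  tx_rows <- list(); ex_rows <- list(); gene_rows <- list()
  for (gid in names(genes)) {
    g <- genes[[gid]]
    present <- source %in% strsplit(g$sources, ",", fixed = TRUE)[[1]]
    if (!present) next
    raw_bt <- raw_biotype_for(g$biotype, source_idx)
    gene_rows[[gid]] <- data.frame(
      gene_id = gid, gene_name = g$gene_name, biotype_raw = raw_bt,
      stringsAsFactors = FALSE)
    locus <- layout$loci[[gid]]
    for (tx in transcripts) {
      if (tx$gene_id != gid) next
      tid <- tx$transcript_id
      exons <- locus$exons
      if (tx$isoform == 2L) {
        # isoform 2 trims 30 bp off the transcript 5' end (plus strand only)
        exons[[1]][1] <- exons[[1]][1] + 30L
      }
      tx_rows[[tid]] <- data.frame(
        transcript_id = tid, gene_id = gid, feature_type = "transcript",
        contig = locus$contig, strand = tx$strand, biotype_raw = raw_bt,
        gene_name = g$gene_name, gene_biotype_raw = raw_bt,
        biotype = normalize_biotype(raw_bt), n_exons = length(exons),
        sequence = tx$sequence, stringsAsFactors = FALSE)
      for (e in seq_along(exons)) {
        ex_rows[[paste(tid, e)]] <- data.frame(
          transcript_id = tid, contig = locus$contig, strand = tx$strand,
          start0 = exons[[e]][1], end0 = exons[[e]][2],
          stringsAsFactors = FALSE)
      }
    }
  }
  tx_df <- do.call(rbind, tx_rows); rownames(tx_df) <- NULL
  ex_df <- do.call(rbind, ex_rows); rownames(ex_df) <- NULL
  gene_df <- do.call(rbind, gene_rows); rownames(gene_df) <- NULL
  gene_df$biotype <- normalize_biotype(gene_df$biotype_raw)
  new_annotation_set(transcripts = tx_df, exons = ex_df, genes = gene_df,
                     source = source, genome_build = "synthetic")
}

#' Expected binding calls implied by a simulation's truth table
#'
#' The ground truth against which pipeline output is scored: one on-target
#' call per non-retired probe, plus one off-target call per planted scenario
#' that is detectable in the given source at the given pad length (perfect /
#' pseudogene / source-specific copies always; core-with-mismatch-at-depth-d
#' iff `pl >= d`; source-specific only when the paralog is annotated in
#' `source`).
#'
#' @param sim An `opt_simulation`.
#' @param source Source label (one of `sim$sources`).
#' @param pl Pad length.
#' @return data.frame `accession`, `bound_gene_id`, `on_target`, sorted.
#' @export
expected_calls <- function(sim, source = sim$sources[1], pl = 0L) {
  tp <- sim$truth$probes
  on_rows <- tp[!tp$retired, c("accession", "gene_id")]
  names(on_rows)[2] <- "bound_gene_id"
  on_rows$on_target <- TRUE
  off <- tp[!is.na(tp$offtarget_gene_id), , drop = FALSE]
  in_source <- vapply(off$offtarget_sources, function(s)
    source %in% strsplit(s, ",", fixed = TRUE)[[1]], TRUE)
  detectable <- is.na(off$d) | pl >= off$d
  off <- off[in_source & detectable, , drop = FALSE]
  off_rows <- data.frame(accession = off$accession,
                         bound_gene_id = off$offtarget_gene_id,
                         on_target = FALSE, stringsAsFactors = FALSE)
  out <- rbind(on_rows, off_rows)
  out <- out[order(out$accession, out$bound_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulation to standard files
#'
#' Emits `genome.fa`, `probes.fa`, one `annotation_<source>.gff3` per
#' source, and the truth tables as TSV, so every other module can consume
#' the fixture through its normal file interfaces.
#'
#' @param sim An `opt_simulation`.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "opt_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_path <- file.path(dir, "genome.fa")
  g <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(g, genome_path, width = 80L)
  probes_path <- file.path(dir, "probes.fa")
  write_probe_fasta(sim$panel, probes_path)
  ann_paths <- vapply(names(sim$annotations), function(src) {
    p <- file.path(dir, paste0("annotation_", src, ".gff3"))
    write_annotation_gff3(sim$annotations[[src]], p)
    p
  }, "")
  tp <- file.path(dir, "truth_probes.tsv")
  tg <- file.path(dir, "truth_genes.tsv")
  write_tsv_file(sim$truth$probes, tp)
  write_tsv_file(sim$truth$genes, tg)
  invisible(list(genome = genome_path, probes = probes_path,
                 annotations = ann_paths, truth_probes = tp,
                 truth_genes = tg))
}

#' Write an annotation set as GFF3
#'
#' @param annotation An `annotation_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  tx <- annotation$transcripts
  ex <- annotation$exons
  lines <- "##gff-version 3"
  for (gid in unique(tx$gene_id)) {
    gtx <- tx[tx$gene_id == gid, , drop = FALSE]
    gex <- ex[ex$transcript_id %in% gtx$transcript_id, , drop = FALSE]
    g_start <- min(gex$start0) + 1L
    g_end <- max(gex$end0)
    bt <- gtx$gene_biotype_raw[1]
    lines <- c(lines, sprintf(
      "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;gene_id=%s;Name=%s;biotype=%s",
      gtx$contig[1], g_start, g_end, gtx$strand[1], gid, gid,
      gtx$gene_name[1], bt))
    for (i in seq_len(nrow(gtx))) {
      tid <- gtx$transcript_id[i]
      tex <- ex[ex$transcript_id == tid, , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\tID=transcript:%s;Parent=gene:%s;transcript_id=%s;biotype=%s",
        gtx$contig[i], min(tex$start0) + 1L, max(tex$end0), gtx$strand[i],
        tid, gid, tid, gtx$biotype_raw[i]))
      for (e in seq_len(nrow(tex))) {
        lines <- c(lines, sprintf(
          "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tID=exon:%s.%d;Parent=transcript:%s",
          tex$contig[e], tex$start0[e] + 1L, tex$end0[e], gtx$strand[i],
          tid, e, tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation set as GTF
#'
#' @param annotation An `annotation_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  tx <- annotation$transcripts
  ex <- annotation$exons
  lines <- character(0)
  for (gid in unique(tx$gene_id)) {
    gtx <- tx[tx$gene_id == gid, , drop = FALSE]
    gex <- ex[ex$transcript_id %in% gtx$transcript_id, , drop = FALSE]
    attr_g <- sprintf(
      'gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
      gid, gtx$gene_name[1], gtx$gene_biotype_raw[1])
    lines <- c(lines, sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              gtx$contig[1], min(gex$start0) + 1L,
                              max(gex$end0), gtx$strand[1], attr_g))
    for (i in seq_len(nrow(gtx))) {
      tid <- gtx$transcript_id[i]
      tex <- ex[ex$transcript_id == tid, , drop = FALSE]
      attr_t <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s"; transcript_biotype "%s";',
        gid, tid, gtx$gene_name[i], gtx$gene_biotype_raw[i],
        gtx$biotype_raw[i])
      lines <- c(lines, sprintf(
        "%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        gtx$contig[i], min(tex$start0) + 1L, max(tex$end0), gtx$strand[i],
        attr_t))
      for (e in seq_len(nrow(tex))) {
        lines <- c(lines, sprintf(
          "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
          tex$contig[e], tex$start0[e] + 1L, tex$end0[e], gtx$strand[i],
          attr_t, e))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate matched two-platform expression data
#'
#' Platform Y (the reference platform, e.g. sequencing-based) draws
#' per-gene, per-observation counts from a negative binomial with gene- and
#' group-specific means and covers ALL genes. Platform X (the probe-based
#' assay) covers only the panel's target genes and records, per target, the
#' SUM of the platform-Y counts of the target and its planted off-target
#' genes plus independent Poisson noise -- modelling probe
#' cross-hybridization: on- and off-target signal are indistinguishable
#' after amplification. One planted gene is given zero intrinsic expression
#' while its off-target is expressed, reproducing the pattern where the
#' probe-based assay reports strong signal for a gene the reference platform
#' cannot detect at all.
#'
#' @param sim An `opt_simulation` from [simulate_panel()].
#' @param seed Integer seed.
#' @param n_groups Number of observation groups (cell types / clusters).
#' @param obs_per_group Observations per group.
#' @param dispersion Negative-binomial size parameter.
#' @param noise_mu Mean of the independent Poisson noise added to X.
#' @return List of class `opt_expression`: `x`, `y`
#'   ([expression_matrix()]s, matched observation order), `labels` (group
#'   per observation), `offtarget_map` (target gene name -> planted
#'   off-target gene names), `zero_target` (the planted unexpressed gene).
#' @export
simulate_expression <- function(sim, seed = 1L, n_groups = 4L,
                                obs_per_group = 30L, dispersion = 10,
                                noise_mu = 0.2) {
  stopifnot(inherits(sim, "opt_simulation"))
  set.seed(seed + 101L)
  genes <- sim$truth$genes
  tp <- sim$truth$probes
  n_obs <- n_groups * obs_per_group
  labels <- rep(paste0("grp", seq_len(n_groups)), each = obs_per_group)
  obs <- sprintf("obs%03d", seq_len(n_obs))

  planted <- tp[!is.na(tp$offtarget_gene_id), , drop = FALSE]
  offtarget_map <- lapply(split(planted$offtarget_gene_name,
                                planted$gene_name), unique)
  zero_target <- planted$gene_name[planted$scenario == "perfect"][1]

  base_mu <- stats::setNames(stats::runif(nrow(genes), 1, 12),
                             genes$gene_name)
  # off-target paralogs must be decently expressed for their signal to leak
  base_mu[genes$gene_name[genes$is_paralog]] <-
    stats::runif(sum(genes$is_paralog), 3, 12)
  if (!is.na(zero_target)) base_mu[zero_target] <- 0
  group_mult <- matrix(exp(stats::rnorm(nrow(genes) * n_groups, 0, 0.8)),
                       nrow = nrow(genes),
                       dimnames = list(genes$gene_name,
                                       paste0("grp", seq_len(n_groups))))
  lambda <- base_mu[genes$gene_name] * group_mult[, labels]
  dimnames(lambda) <- list(genes$gene_name, obs)

  y_counts <- matrix(stats::rnbinom(length(lambda), mu = lambda,
                                    size = dispersion),
                     nrow = nrow(lambda), dimnames = dimnames(lambda))

  targets <- genes$gene_name[!genes$is_paralog]
  x_counts <- matrix(0L, nrow = length(targets), ncol = n_obs,
                     dimnames = list(targets, obs))
  for (t in targets) {
    contributors <- c(t, offtarget_map[[t]])
    contributors <- intersect(contributors, rownames(y_counts))
    x_counts[t, ] <- colSums(y_counts[contributors, , drop = FALSE]) +
      stats::rpois(n_obs, noise_mu)
  }

  structure(list(x = expression_matrix(x_counts),
                 y = expression_matrix(y_counts),
                 labels = labels, offtarget_map = offtarget_map,
                 zero_target = zero_target, seed = seed),
            class = "opt_expression")
}
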