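# Probe-to-transcriptome matcher. Strict mode requires a full-length,
# mismatch-free match of the probe on the transcript forward strand; pad mode
# exempts `pl` bases at EACH probe end and requires only the central core
# (spanning the ligation junction between the two probe arms) to match
# exactly. Implemented as a w-mer index with verification; a brute-force
# scanner with the identical contract serves as the test oracle.

#' Aligner configuration
#'
#' @param pl Pad length: bases at each probe end exempt from matching.
#'   `pl = 0` is strict mode; any positive value activates pad mode.
#' @param w Index word length; `NULL` chooses `min(20, core length)` per
#'   probe at query time. Correctness is independent of `w`.
#' @return An object of class `aligner_config`.
#' @export
aligner_config <- function(pl = 0L, w = NULL) {
  pl <- as.integer(pl)
  stopifnot(length(pl) == 1L, pl >= 0L)
  if (!is.null(w)) {
    w <- as.integer(w)
    stopifnot(w >= 1L)
  }
  structure(list(pl = pl, w = w,
                 mode = if (pl == 0L) "strict" else "pad"),
            class = "aligner_config")
}

#' Build a w-mer index over a transcript set
#'
#' Maps every length-`w` substring of every transcript to its
#' (transcript, 0-based offset) occurrences. w-mers containing `N` are
#' skipped (N never matches).
#'
#' @param transcripts An `annotation_set` with sequences, or a named
#'   character vector of transcript sequences.
#' @param w Word length.
#' @return An object of class `transcript_index`.
#' @export
build_index <- function(transcripts, w = 20L) {
  seqs <- transcript_seqs_or_empty(transcripts)
  w <- as.integer(w)
  stopifnot(w >= 1L)
  tids <- character(0); offs <- integer(0); mers <- character(0)
  for (tid in names(seqs)) {
    s <- seqs[[tid]]
    L <- nchar(s)
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    km <- substring(s, starts, starts + w - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) next
    mers <- c(mers, km[keep])
    tids <- c(tids, rep(tid, sum(keep)))
    offs <- c(offs, starts[keep] - 1L)
  }
  occ <- if (length(mers)) {
    split(data.frame(transcript_id = tids, offset = offs,
                     stringsAsFactors = FALSE), mers)
  } else list()
  structure(list(w = w, occurrences = occ, seqs = seqs),
            class = "transcript_index")
}

#' @keywords internal
#' @noRd
transcript_seqs_or_empty <- function(transcripts) {
  if (is.character(transcripts) && length(transcripts) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  transcript_seqs(transcripts)
}

#' @export
print.transcript_index <- function(x, ...) {
  cat(sprintf("transcript_index: %d transcripts, w = %d, %d distinct w-mers\n",
              length(x$seqs), x$w, length(x$occurrences)))
  invisible(x)
}

#' @keywords internal
#' @noRd
empty_hits <- function() {
  empty_df(accession = "character", transcript_id = "character",
           offset = "integer", probe_start = "integer",
           probe_end = "integer", mode = "character", pl = "integer",
           pad_left = "integer", pad_right = "integer")
}

#' @keywords internal
#' @noRd
core_of <- function(seq, pl) {
  L <- nchar(seq)
  if (L <= 2L * pl) {
    stop(sprintf("probe too short (%d bp) for pad length %d", L, pl),
         call. = FALSE)
  }
  substr(seq, pl + 1L, L - pl)
}

#' @keywords internal
#' @noRd
make_hits <- function(accession, transcript_id, offset, probe, config) {
  L <- nchar(probe)
  pl <- config$pl
  data.frame(accession = accession, transcript_id = transcript_id,
             offset = as.integer(offset),
             probe_start = pl + 1L, probe_end = L - pl,
             mode = config$mode, pl = pl,
             pad_left = NA_integer_, pad_right = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Find probe alignment hits via the w-mer index
#'
#' Strict mode reports one hit per exact occurrence of the full probe on a
#' transcript's forward strand; pad mode reports one hit per exact occurrence
#' of the core `probe[pl+1 .. L-pl]`. Pads are unconstrained: any number of
#' mismatches, indels or clipping is tolerated there and never filters a hit.
#' Duplicate (transcript, offset) hits are deduplicated; `N` in probe or
#' transcript never matches.
#'
#' @param probe One-row data.frame with `accession` and `sequence`, or a
#'   single sequence string (accession defaults to the sequence).
#' @param index A `transcript_index` from [build_index()].
#' @param config An [aligner_config()].
#' @param annotate_pads Compute per-side pad edit distances (pad mode only).
#' @return data.frame of hits: `accession`, `transcript_id`, `offset`
#'   (0-based start of the matched region on the transcript), `probe_start`,
#'   `probe_end` (1-based matched span on the probe), `mode`, `pl`,
#'   `pad_left`, `pad_right`.
#' @export
find_hits <- function(probe, index, config = aligner_config(),
                      annotate_pads = FALSE) {
  stopifnot(inherits(index, "transcript_index"))
  pr <- as_probe_row(probe)
  core <- core_of(pr$sequence, config$pl)
  clen <- nchar(core)
  out <- empty_hits()
  if (!grepl("N", core, fixed = TRUE)) {
    w <- min(if (is.null(config$w)) 20L else config$w, clen, index$w)
    hits <- if (w == index$w && clen >= index$w) {
      anchored_lookup(core, index)
    } else {
      # core shorter than the index word: fall back to direct regex scan
      scan_lookup(core, index$seqs)
    }
    if (nrow(hits)) {
      out <- make_hits(pr$accession, hits$transcript_id, hits$offset,
                       pr$sequence, config)
    }
  }
  out <- dedup_hits(out)
  if (annotate_pads && config$mode == "pad" && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      pe <- pad_edit_distance(pr$sequence, index$seqs[[out$transcript_id[i]]],
                              out[i, ], config$pl)
      out$pad_left[i] <- pe$left
      out$pad_right[i] <- pe$right
    }
  }
  out
}

#' @keywords internal
#' @noRd
as_probe_row <- function(probe) {
  if (is.character(probe) && length(probe) == 1L) {
    return(list(accession = probe, sequence = toupper(probe)))
  }
  if (is.data.frame(probe)) {
    stopifnot(nrow(probe) == 1L)
    return(list(accession = probe$accession, sequence = probe$sequence))
  }
  if (is.list(probe)) return(probe[c("accession", "sequence")])
  stop("cannot interpret probe", call. = FALSE)
}

# Anchor on the first index-w bases of the core, then verify the full core.
#' @keywords internal
#' @noRd
anchored_lookup <- function(core, index) {
  anchor <- substr(core, 1L, index$w)
  occ <- index$occurrences[[anchor]]
  if (is.null(occ)) return(empty_df(transcript_id = "character",
                                    offset = "integer"))
  clen <- nchar(core)
  keep <- logical(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    s <- index$seqs[[occ$transcript_id[i]]]
    window <- substr(s, occ$offset[i] + 1L, occ$offset[i] + clen)
    keep[i] <- nchar(window) == clen && window == core &&
      !grepl("N", window, fixed = TRUE)
  }
  occ[keep, , drop = FALSE]
}

#' @keywords internal
#' @noRd
scan_lookup <- function(core, seqs) {
  clen <- nchar(core)
  tids <- character(0); offs <- integer(0)
  for (tid in names(seqs)) {
    s <- seqs[[tid]]
    L <- nchar(s)
    if (L < clen) next
    starts <- seq_len(L - clen + 1L)
    windows <- substring(s, starts, starts + clen - 1L)
    # overlapping occurrences included; N in the window never matches
    keep <- windows == core & !grepl("N", windows, fixed = TRUE)
    if (any(keep)) {
      tids <- c(tids, rep(tid, sum(keep)))
      offs <- c(offs, starts[keep] - 1L)
    }
  }
  data.frame(transcript_id = tids, offset = offs, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
dedup_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[!duplicated(hits[, c("transcript_id", "offset")]), ,
               drop = FALSE]
  hits <- hits[order(hits$transcript_id, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Brute-force alignment oracle
#'
#' Scans every offset of every transcript by direct substring comparison.
#' Same contract as [find_hits()]; intended as the independent test oracle
#' for small inputs.
#'
#' @param probe As in [find_hits()].
#' @param transcripts Named character vector of transcript sequences or an
#'   `annotation_set` with sequences.
#' @param config An [aligner_config()].
#' @return data.frame of hits with the same schema as [find_hits()].
#' @export
brute_force_hits <- function(probe, transcripts, config = aligner_config()) {
  pr <- as_probe_row(probe)
  seqs <- transcript_seqs_or_empty(transcripts)
  core <- core_of(pr$sequence, config$pl)
  clen <- nchar(core)
  out <- empty_hits()
  if (grepl("N", core, fixed = TRUE)) return(out)
  core_chars <- strsplit(core, "")[[1]]
  for (tid in names(seqs)) {
    s <- seqs[[tid]]
    L <- nchar(s)
    if (L < clen) next
    for (off0 in 0:(L - clen)) {
      window <- substr(s, off0 + 1L, off0 + clen)
      wc <- strsplit(window, "")[[1]]
      ok <- all(wc == core_chars) && !any(wc == "N")
      if (ok) {
        out <- rbind(out, make_hits(pr$accession, tid, off0, pr$sequence,
                                    config))
      }
    }
  }
  dedup_hits(out)
}

#' Annotate pad disagreement for a pad-mode hit
#'
#' Banded edit distance (band = `pl`) between each probe pad and the
#' transcript sequence flanking the matched core; bases of a pad hanging off
#' a transcript end are clipped free and counted separately. Purely
#' informational: pad distances never filter hits.
#'
#' @param probe_seq Full probe sequence.
#' @param transcript_seq Transcript sequence the hit lies on.
#' @param hit One hit row from [find_hits()] (pad mode).
#' @param pl Pad length used for the hit.
#' @return List with `left`, `right` (edit distances) and `left_clipped`,
#'   `right_clipped` (bases off the transcript end).
#' @export
pad_edit_distance <- function(probe_seq, transcript_seq, hit, pl) {
  stopifnot(pl >= 0L)
  if (pl == 0L) {
    return(list(left = 0L, right = 0L, left_clipped = 0L, right_clipped = 0L))
  }
  L <- nchar(probe_seq)
  clen <- L - 2L * pl
  core_start0 <- hit$offset
  tlen <- nchar(transcript_seq)

  left_pad <- substr(probe_seq, 1L, pl)
  avail_l <- min(pl, core_start0)
  left_clip <- pl - avail_l
  left_flank <- if (avail_l > 0L) {
    substr(transcript_seq, core_start0 - avail_l + 1L, core_start0)
  } else ""
  left_d <- banded_edit(substr(left_pad, left_clip + 1L, pl), left_flank, pl)

  right_pad <- substr(probe_seq, L - pl + 1L, L)
  core_end0 <- core_start0 + clen          # half-open end
  avail_r <- min(pl, tlen - core_end0)
  right_clip <- pl - avail_r
  right_flank <- if (avail_r > 0L) {
    substr(transcript_seq, core_end0 + 1L, core_end0 + avail_r)
  } else ""
  right_d <- banded_edit(substr(right_pad, 1L, avail_r), right_flank, pl)

  list(left = left_d, right = right_d,
       left_clipped = as.integer(left_clip),
       right_clipped = as.integer(right_clip))
}

# Levenshtein distance; band is a no-op when >= max length, kept for clarity.
#' @keywords internal
#' @noRd
banded_edit <- function(a, b, band) {
  if (!nchar(a) && !nchar(b)) return(0L)
  as.integer(utils::adist(a, b))
}

#' Align every probe of a panel against an indexed transcriptome
#'
#' @param panel A [probe_panel()] (typically after [flip_panel()]).
#' @param index A `transcript_index`, or an `annotation_set`/named sequence
#'   set (indexed on the fly).
#' @param config An [aligner_config()].
#' @param annotate_pads Compute pad edit distances in pad mode.
#' @return data.frame of hits across all probes, stably ordered by
#'   accession, transcript and offset.
#' @export
find_panel_hits <- function(panel, index, config = aligner_config(),
                            annotate_pads = FALSE) {
  stopifnot(inherits(panel, "probe_panel"))
  if (!inherits(index, "transcript_index")) {
    index <- build_index(index, w = if (is.null(config$w)) 20L else config$w)
  }
  res <- lapply(seq_len(nrow(panel$probes)), function(i) {
    find_hits(panel$probes[i, ], index, config, annotate_pads)
  })
  out <- do.call(rbind, c(list(empty_hits()), res))
  out <- out[order(out$accession, out$transcript_id, out$offset), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
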