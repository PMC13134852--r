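# Internal helpers shared across modules.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' @keywords internal
#' @noRd
validate_sequence <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(utils::head(seq[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seq)
}

# Exact substring containment under the N-never-matches contract: an N in
# either the query or the covered window disqualifies the match.
#' @keywords internal
#' @noRd
contains_exact <- function(haystack, needle) {
  if (grepl("N", needle, fixed = TRUE)) return(FALSE)
  m <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(FALSE)
  w <- nchar(needle)
  for (p in as.integer(m)) {
    if (!grepl("N", substr(haystack, p, p + w - 1L), fixed = TRUE)) return(TRUE)
  }
  # all non-overlapping occurrences were N-tainted; check overlapping ones
  L <- nchar(haystack)
  starts <- seq_len(L - w + 1L)
  windows <- substring(haystack, starts, starts + w - 1L)
  any(windows == needle & !grepl("N", windows, fixed = TRUE))
}

#' @keywords internal
#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_tsv_file <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' @keywords internal
#' @noRd
empty_df <- function(...) {
  cols <- list(...)
  structure(lapply(cols, function(mode) vector(mode, 0L)),
            names = names(cols), class = "data.frame",
            row.names = integer(0))
}
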