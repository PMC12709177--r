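#' Define a sequence motif
#'
#' Motifs are exact residue strings (the family signatures are the literal
#' strings `DHH` and `GGGH`). A motif may carry a search window expressed as
#' a fraction-of-length interval: a hit counts only if its start position,
#' divided by the sequence length, falls inside the window.
#'
#' @param name Motif name.
#' @param pattern Exact residue string, length >= 3.
#' @param search_window Numeric length-2 vector in `[0, 1]` with
#'   `start < end`, or `NULL` for no restriction.
#' @return A `motif_definition` object.
#' @export
motif_definition <- function(name, pattern, search_window = NULL) {
  abort_if(!nzchar(name), "motif name must be non-empty",
           class = "nrnbkit_validation_error")
  pattern <- toupper(pattern)
  abort_if(nchar(pattern) < 3L, "motif pattern must have length >= 3",
           class = "nrnbkit_validation_error")
  if (!is.null(search_window)) {
    abort_if(length(search_window) != 2L ||
               any(search_window < 0) || any(search_window > 1) ||
               search_window[1] >= search_window[2],
             "search_window must be [start, end] within [0,1], start < end",
             class = "nrnbkit_validation_error")
  }
  structure(list(name = name, pattern = pattern,
                 search_window = search_window),
            class = "motif_definition")
}

#' Default DHH / GGGH signature motifs
#'
#' The DHH phosphoesterase domain is named for its conserved Asp-His-His
#' motif; the associated DHHA1 domain carries the conserved GGGH motif.
#' Search windows (DHH in the N-terminal 70% of the sequence, GGGH in the
#' C-terminal 80%) suppress spurious matches in the opposite region.
#'
#' @return List of two [motif_definition()] objects named `DHH`, `GGGH`.
#' @export
default_motifs <- function() {
  list(DHH = motif_definition("DHH", "DHH", c(0, 0.7)),
       GGGH = motif_definition("GGGH", "GGGH", c(0.2, 1.0)))
}

#' Scan a protein record for exact motif occurrences
#'
#' Finds every exact occurrence of each motif pattern whose start position
#' lies within that motif's search window. When a motif has several in-window
#' hits the most N-terminal one is flagged `primary`. Hits are returned
#' sorted by start position.
#'
#' @param record A [protein_record()].
#' @param motifs Non-empty list of [motif_definition()] objects.
#' @return A data.frame with columns `motif_name`, `start`, `end`
#'   (1-based, closed) and `primary` (logical). Zero rows when nothing hits.
#' @export
scan_motifs <- function(record, motifs) {
  abort_if(length(motifs) == 0L, "motifs must be non-empty",
           class = "nrnbkit_validation_error")
  L <- nchar(record$sequence)
  out <- list()
  for (m in motifs) {
    # all occurrences, overlapping included (gregexpr skips overlaps)
    plen <- nchar(m$pattern)
    starts <- integer(0)
    if (L >= plen) {
      cand <- seq_len(L - plen + 1L)
      starts <- cand[substring(record$sequence, cand, cand + plen - 1L) ==
                       m$pattern]
    }
    if (!is.null(m$search_window) && length(starts)) {
      frac <- starts / L
      starts <- starts[frac >= m$search_window[1] &
                         frac <= m$search_window[2]]
    }
    if (length(starts)) {
      out[[length(out) + 1L]] <- data.frame(
        motif_name = m$name,
        start = starts,
        end = starts + nchar(m$pattern) - 1L,
        primary = seq_along(starts) == 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif_name = character(0), start = integer(0),
                      end = integer(0), primary = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# primary hit for one motif name, or NULL
primary_hit <- function(hits, name) {
  sel <- hits[hits$motif_name == name & hits$primary, , drop = FALSE]
  if (nrow(sel) == 0L) NULL else sel[1, , drop = FALSE]
}
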