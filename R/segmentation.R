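#' Segmentation offsets
#'
#' The family's domain boundaries are operationalized as fixed offsets from
#' the two signature motifs: the DHH region extends `k1` residues past the
#' DHH motif, the DHHA1 region starts `k2` residues before the GGGH motif
#' and extends `k3` residues past it. `min_length`/`max_standalone_length`
#' bound the total length accepted by the standalone filter (the cap proxies
#' "no additional domains": multi-domain GdpP-like proteins are much longer).
#'
#' @param k1,k2,k3 Non-negative integer offsets (defaults 10, 10, 30).
#' @param max_standalone_length Total-length cap (default 700).
#' @param min_length Lower bound (default 250).
#' @return A `segmentation_offsets` object.
#' @export
segmentation_offsets <- function(k1 = 10L, k2 = 10L, k3 = 30L,
                                 max_standalone_length = 700L,
                                 min_length = 250L) {
  abort_if(any(c(k1, k2, k3) < 0), "offsets must be >= 0",
           class = "nrnbkit_validation_error")
  abort_if(min_length >= max_standalone_length,
           "min_length must be < max_standalone_length",
           class = "nrnbkit_validation_error")
  structure(list(k1 = as.integer(k1), k2 = as.integer(k2),
                 k3 = as.integer(k3),
                 max_standalone_length = as.integer(max_standalone_length),
                 min_length = as.integer(min_length)),
            class = "segmentation_offsets")
}

#' Motif-anchored domain segmentation
#'
#' Derives the DHH region, inter-domain linker, DHHA1 region and C-terminal
#' tail of a protein from its primary DHH and GGGH motif hits:
#' `dhh_region_end = dhh_end + k1` (clamped below the DHHA1 region start),
#' `dhha1_region_start = gggh_start - k2` (clamped above the DHH motif end),
#' `dhha1_region_end = min(L, gggh_end + k3)`. The linker is the residues
#' strictly between the DHH region end and the DHHA1 region start; the
#' C-terminal tail is everything after the DHHA1 region. All coordinates are
#' 1-based with closed intervals.
#'
#' @param record A [protein_record()].
#' @param hits Motif hit table from [scan_motifs()].
#' @param offsets A [segmentation_offsets()] object.
#' @return A `domain_segmentation` object (list with the motif hits, region
#'   boundaries, `linker_span`/`linker_length`, `cterm_span`/`cterm_length`
#'   and the offsets used).
#' @export
segment_domains <- function(record, hits, offsets = segmentation_offsets()) {
  dhh <- primary_hit(hits, "DHH")
  gggh <- primary_hit(hits, "GGGH")
  abort_if(is.null(dhh), "record '", record$id,
           "': missing primary DHH motif anchor",
           class = "nrnbkit_segmentation_error")
  abort_if(is.null(gggh), "record '", record$id,
           "': missing primary GGGH motif anchor",
           class = "nrnbkit_segmentation_error")
  abort_if(dhh$end >= gggh$start, "record '", record$id,
           "': DHH motif does not precede GGGH motif",
           class = "nrnbkit_segmentation_error")
  L <- nchar(record$sequence)

  dhha1_start <- max(gggh$start - offsets$k2, dhh$end + 1L)
  dhh_region_end <- min(dhh$end + offsets$k1, dhha1_start - 1L)
  dhha1_end <- min(L, gggh$end + offsets$k3)

  linker_length <- max(0L, dhha1_start - dhh_region_end - 1L)
  linker_span <- if (linker_length > 0L) {
    c(dhh_region_end + 1L, dhha1_start - 1L)
  } else {
    integer(0)
  }
  cterm_length <- max(0L, L - dhha1_end)
  cterm_span <- if (cterm_length > 0L) c(dhha1_end + 1L, L) else integer(0)

  structure(list(id = record$id,
                 dhh_hit = c(start = dhh$start, end = dhh$end),
                 gggh_hit = c(start = gggh$start, end = gggh$end),
                 dhh_region_end = as.integer(dhh_region_end),
                 dhha1_region_start = as.integer(dhha1_start),
                 dhha1_region_end = as.integer(dhha1_end),
                 linker_span = as.integer(linker_span),
                 linker_length = as.integer(linker_length),
                 cterm_span = as.integer(cterm_span),
                 cterm_length = as.integer(cterm_length),
                 offsets = offsets),
            class = "domain_segmentation")
}

#' Standalone DHH-DHHA1 inclusion filter
#'
#' A sequence is accepted as a standalone DHH-DHHA1 protein iff both
#' primary signature motifs are present in N-to-C order and its total length
#' lies within `[min_length, max_standalone_length]`.
#'
#' @param record A [protein_record()].
#' @param seg A [segment_domains()] result for `record`, or `NULL` when
#'   segmentation failed (missing motif).
#' @param offsets A [segmentation_offsets()] object.
#' @return List with `standalone` (logical) and `reason` (text: `"ok"` or
#'   the first failed criterion).
#' @export
is_standalone_dhh_dhha1 <- function(record, seg,
                                    offsets = segmentation_offsets()) {
  L <- nchar(record$sequence)
  if (is.null(seg)) {
    return(list(standalone = FALSE,
                reason = "missing or mis-ordered DHH/GGGH signature motif"))
  }
  abort_if(!identical(seg$id, record$id),
           "segmentation does not belong to record '", record$id, "'",
           class = "nrnbkit_validation_error")
  if (L < offsets$min_length) {
    return(list(standalone = FALSE,
                reason = sprintf("length %d below minimum %d", L,
                                 offsets$min_length)))
  }
  if (L > offsets$max_standalone_length) {
    return(list(standalone = FALSE,
                reason = sprintf("length %d exceeds standalone cap %d", L,
                                 offsets$max_standalone_length)))
  }
  list(standalone = TRUE, reason = "ok")
}

#' Scan, segment and filter a set of records
#'
#' Convenience wrapper running [scan_motifs()], [segment_domains()] and
#' [is_standalone_dhh_dhha1()] over a record list.
#'
#' @param records List of [protein_record()] objects.
#' @param motifs Motif list (default [default_motifs()]).
#' @param offsets A [segmentation_offsets()] object.
#' @return A list with `segmentations` (named list; `NULL` where motifs are
#'   missing), `standalone` (named logical), `reasons` (named character) and
#'   `table` (the TSV-ready summary data.frame).
#' @export
scan_records <- function(records, motifs = default_motifs(),
                         offsets = segmentation_offsets()) {
  validate_record_set(records)
  segs <- list(); ok <- logical(0); why <- character(0)
  rowlist <- list()
  for (r in records) {
    hits <- scan_motifs(r, motifs)
    seg <- tryCatch(segment_domains(r, hits, offsets),
                    nrnbkit_segmentation_error = function(e) NULL)
    dec <- is_standalone_dhh_dhha1(r, seg, offsets)
    segs[[r$id]] <- seg
    ok[r$id] <- dec$standalone
    why[r$id] <- dec$reason
    rowlist[[r$id]] <- data.frame(
      id = r$id,
      dhh_start = if (is.null(seg)) NA_integer_ else seg$dhh_hit[["start"]],
      dhh_end = if (is.null(seg)) NA_integer_ else seg$dhh_hit[["end"]],
      gggh_start = if (is.null(seg)) NA_integer_ else seg$gggh_hit[["start"]],
      gggh_end = if (is.null(seg)) NA_integer_ else seg$gggh_hit[["end"]],
      linker_length = if (is.null(seg)) NA_integer_ else seg$linker_length,
      cterm_length = if (is.null(seg)) NA_integer_ else seg$cterm_length,
      standalone = dec$standalone,
      reason = dec$reason,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rowlist)
  rownames(tab) <- NULL
  list(segmentations = segs, standalone = ok, reasons = why, table = tab)
}

#' Export a segmentation summary table as TSV
#'
#' @param scan Result of [scan_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(scan, path) write_tsv(scan$table, path)
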