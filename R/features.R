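#' Map reference residue positions to alignment columns
#'
#' Residue numbering follows the designated reference row (the B. subtilis
#' NrnB-equivalent sequence); position `p` maps to the alignment column that
#' holds the reference row's `p`-th non-gap character.
#'
#' @param aln A `protein_alignment` containing the reference row.
#' @param reference_id Row id of the reference sequence.
#' @param positions 1-based reference residue positions (default 285, the
#'   clade-diagnostic active-site position).
#' @return A `reference_anchor` object with `column_of_position`.
#' @export
anchor_positions <- function(aln, reference_id, positions = 285L) {
  idx <- match(reference_id, aln$row_ids)
  abort_if(is.na(idx), "reference id '", reference_id,
           "' not found in alignment",
           class = "nrnbkit_validation_error")
  ref <- strsplit(aln$rows[idx], "", fixed = TRUE)[[1]]
  resno <- cumsum(ref != GAP_CHAR)
  reflen <- resno[length(resno)]
  abort_if(any(positions < 1L) || any(positions > reflen),
           "anchored position outside reference length (", reflen, ")",
           class = "nrnbkit_validation_error")
  col_of <- vapply(as.integer(positions), function(p) {
    which(resno == p & ref != GAP_CHAR)[1]
  }, integer(1))
  structure(list(reference_id = reference_id,
                 anchored_positions = as.integer(positions),
                 column_of_position = setNames(col_of,
                                               as.character(positions))),
            class = "reference_anchor")
}

#' Clade-diagnostic feature vector for one record
#'
#' Combines segmentation-derived architecture features (linker and
#' C-terminal tail lengths) with the alignment-derived signature residue at
#' the anchored reference position, and the C-terminal tail's
#' positive-charge character (K+R fraction and (K+R)-(D+E) net charge).
#'
#' @param record A [protein_record()] present in the alignment.
#' @param seg Its [segment_domains()] result.
#' @param anchor A [anchor_positions()] result.
#' @param aln The `protein_alignment` both refer to.
#' @param signature_position Which anchored position carries the clade
#'   signature (default 285).
#' @return A `clade_features` object.
#' @export
extract_features <- function(record, seg, anchor, aln,
                             signature_position = 285L) {
  idx <- match(record$id, aln$row_ids)
  abort_if(is.na(idx), "record '", record$id, "' not found in alignment",
           class = "nrnbkit_validation_error")
  key <- as.character(signature_position)
  abort_if(!key %in% names(anchor$column_of_position),
           "signature position ", key, " not anchored",
           class = "nrnbkit_validation_error")
  col <- anchor$column_of_position[[key]]
  sig <- substring(aln$rows[idx], col, col)
  tail_seq <- if (length(seg$cterm_span) == 2L) {
    substring(record$sequence, seg$cterm_span[1], seg$cterm_span[2])
  } else {
    ""
  }
  tc <- strsplit(tail_seq, "", fixed = TRUE)[[1]]
  n_pos <- sum(tc %in% c("K", "R"))
  n_neg <- sum(tc %in% c("D", "E"))
  structure(list(id = record$id,
                 linker_length = seg$linker_length,
                 cterm_length = seg$cterm_length,
                 signature_residue = sig,
                 cterm_positive_fraction =
                   if (length(tc)) n_pos / length(tc) else 0,
                 cterm_net_charge = n_pos - n_neg),
            class = "clade_features")
}

#' Per-column entropy profile of an alignment
#'
#' Residue frequencies are computed over non-gap characters only; gap
#' fraction is recorded separately. Entropy is Shannon entropy in bits
#' (`-sum p log2 p`), bounded by `log2(20)`; information content is
#' `log2(20) - entropy`. All-gap columns are flagged.
#'
#' @param aln A `protein_alignment` with >= 1 row.
#' @return A data.frame with one row per column: `column`, `entropy_bits`,
#'   `information_bits`, `gap_fraction`, `all_gap`, plus one frequency
#'   column per residue.
#' @export
column_entropy <- function(aln) {
  m <- rows_to_matrix(aln$rows)
  nr <- nrow(m)
  maxbits <- log2(20)
  freq <- vapply(AA_ALPHABET, function(a) colSums(m == a),
                 numeric(ncol(m)))
  if (ncol(m) == 1L) freq <- matrix(freq, nrow = 1,
                                    dimnames = list(NULL, AA_ALPHABET))
  # X (unknown residue) is excluded from the 20-letter frequency simplex
  nongap <- rowSums(freq)
  gap_frac <- colSums(m == GAP_CHAR) / nr
  ent <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    tot <- nongap[j]
    if (tot == 0) { ent[j] <- 0; next }
    p <- freq[j, ] / tot
    p <- p[p > 0]
    ent[j] <- -sum(p * log2(p))
  }
  fr <- sweep(freq, 1, pmax(nongap, 1), "/")
  out <- data.frame(column = seq_len(ncol(m)),
                    entropy_bits = ent,
                    information_bits = maxbits - ent,
                    gap_fraction = gap_frac,
                    all_gap = nongap == 0)
  cbind(out, as.data.frame(fr))
}

#' Information-content logo matrix
#'
#' Per column, each residue's stacked letter height is its frequency times
#' the column's information content (`log2(20) - entropy`). Optionally
#' restricted to a clade's member rows. All-gap columns are excluded.
#'
#' @param aln A `protein_alignment`.
#' @param clade_members Optional character vector of row ids.
#' @return A data.frame in long format: `column`, `residue`, `height`.
#' @export
logo_matrix <- function(aln, clade_members = NULL) {
  if (!is.null(clade_members)) {
    abort_if(length(clade_members) == 0L, "empty clade member set",
             class = "nrnbkit_validation_error")
    keep <- match(clade_members, aln$row_ids)
    abort_if(anyNA(keep), "clade member(s) not in alignment: ",
             paste(clade_members[is.na(keep)], collapse = ", "),
             class = "nrnbkit_validation_error")
    aln <- new_alignment(aln$row_ids[keep], aln$rows[keep])
  }
  ce <- column_entropy(aln)
  keep_cols <- which(!ce$all_gap)
  rows <- list()
  for (j in keep_cols) {
    hts <- unlist(ce[j, AA_ALPHABET]) * ce$information_bits[j]
    nz <- hts > 0
    if (!any(nz)) next
    rows[[length(rows) + 1L]] <- data.frame(
      column = j, residue = AA_ALPHABET[nz], height = as.numeric(hts[nz]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(column = integer(0), residue = character(0),
                      height = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clade classifier rules
#'
#' Defaults encode the family's diagnostic architecture: lysine at the
#' anchored signature position for clade A versus asparagine for clade B;
#' C-terminal extensions longer than 100 aa (clade A) versus shorter than
#' 50 aa (B and C); a positively charged tail (K+R fraction at least 0.15)
#' for clade A. Linker binarization (long iff > 200 aa) is an annotation
#' feature, not a classifier rule.
#'
#' @param signature_position Reference position (default 285).
#' @param clade_a_residue,clade_b_residue Signature residues (K, N).
#' @param linker_long_boundary Linker binarization boundary (200).
#' @param cterm_long_min Long-tail criterion, strict greater (100).
#' @param cterm_short_max Short-tail criterion, strict less (50).
#' @param positive_fraction_min Minimum K+R tail fraction (0.15).
#' @param min_margin Minimum winning-score margin (1).
#' @return A `classifier_rules` object.
#' @export
classifier_rules <- function(signature_position = 285L,
                             clade_a_residue = "K", clade_b_residue = "N",
                             linker_long_boundary = 200L,
                             cterm_long_min = 100L, cterm_short_max = 50L,
                             positive_fraction_min = 0.15,
                             min_margin = 1L) {
  abort_if(cterm_short_max >= cterm_long_min,
           "cterm_short_max must be < cterm_long_min",
           class = "nrnbkit_validation_error")
  abort_if(linker_long_boundary <= 0 || cterm_long_min <= 0,
           "boundaries must be positive",
           class = "nrnbkit_validation_error")
  structure(list(signature_position = as.integer(signature_position),
                 clade_a_residue = clade_a_residue,
                 clade_b_residue = clade_b_residue,
                 linker_long_boundary = as.integer(linker_long_boundary),
                 cterm_long_min = as.integer(cterm_long_min),
                 cterm_short_max = as.integer(cterm_short_max),
                 positive_fraction_min = positive_fraction_min,
                 min_margin = as.integer(min_margin)),
            class = "classifier_rules")
}

#' Rule-based clade classification
#'
#' Integer indicator-sum scores:
#' `score_A = [sig == K] + [cterm > 100] + [K+R fraction >= 0.15]`,
#' `score_B = [sig == N] + [cterm < 50]`,
#' `score_C = [sig not in {K, N, gap}] + [cterm < 50]`.
#' The call is the argmax clade iff its score exceeds the runner-up by at
#' least `min_margin`, else `"unclassified"`. A gap at the signature column
#' is missing evidence and contributes to no clade.
#'
#' @param features A [extract_features()] result.
#' @param rules A [classifier_rules()] object.
#' @return A `clade_call` object: `id`, `call`, `scores`, `evidence`.
#' @export
classify_clade <- function(features, rules = classifier_rules()) {
  sig <- features$signature_residue
  ct <- features$cterm_length
  pf <- features$cterm_positive_fraction
  ev <- character(0)
  sA <- 0L; sB <- 0L; sC <- 0L
  if (identical(sig, rules$clade_a_residue)) {
    sA <- sA + 1L; ev <- c(ev, "signature_K")
  }
  if (ct > rules$cterm_long_min) {
    sA <- sA + 1L; ev <- c(ev, "cterm_long")
  }
  if (pf >= rules$positive_fraction_min) {
    sA <- sA + 1L; ev <- c(ev, "cterm_positive")
  }
  if (identical(sig, rules$clade_b_residue)) {
    sB <- sB + 1L; ev <- c(ev, "signature_N")
  }
  if (ct < rules$cterm_short_max) {
    sB <- sB + 1L; sC <- sC + 1L; ev <- c(ev, "cterm_short")
  }
  if (!sig %in% c(rules$clade_a_residue, rules$clade_b_residue, GAP_CHAR)) {
    sC <- sC + 1L; ev <- c(ev, "signature_other")
  }
  scores <- c(A = sA, B = sB, C = sC)
  ord <- order(-scores)
  call <- if (scores[ord[1]] - scores[ord[2]] >= rules$min_margin) {
    names(scores)[ord[1]]
  } else {
    "unclassified"
  }
  structure(list(id = features$id, call = call, scores = scores,
                 evidence = ev),
            class = "clade_call")
}

#' Feature/classification table for many records
#'
#' @param records List of [protein_record()] objects (aligned rows).
#' @param segs Named list of segmentations (from [scan_records()]).
#' @param anchor A [anchor_positions()] result.
#' @param aln The alignment.
#' @param rules A [classifier_rules()].
#' @return A data.frame: id, linker_length, linker_class, cterm_length,
#'   signature_residue, cterm_positive_fraction, cterm_net_charge, call,
#'   score_A/B/C, evidence.
#' @export
classify_records <- function(records, segs, anchor, aln,
                             rules = classifier_rules()) {
  rows <- lapply(records, function(r) {
    seg <- segs[[r$id]]
    if (is.null(seg)) return(NULL)
    fv <- extract_features(r, seg, anchor, aln,
                           signature_position = rules$signature_position)
    cc <- classify_clade(fv, rules)
    data.frame(id = r$id,
               linker_length = fv$linker_length,
               linker_class = if (fv$linker_length >
                                    rules$linker_long_boundary) "long"
                              else "short",
               cterm_length = fv$cterm_length,
               signature_residue = fv$signature_residue,
               cterm_positive_fraction = fv$cterm_positive_fraction,
               cterm_net_charge = fv$cterm_net_charge,
               call = cc$call,
               score_A = cc$scores[["A"]],
               score_B = cc$scores[["B"]],
               score_C = cc$scores[["C"]],
               evidence = paste(cc$evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an entropy profile as TSV
#'
#' @param profile Result of [column_entropy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_tsv <- function(profile, path) {
  write_tsv(profile[, c("column", "entropy_bits", "information_bits",
                        "gap_fraction")], path)
}
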