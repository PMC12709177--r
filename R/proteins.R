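#' Create a protein record
#'
#' A lightweight container for one protein sequence: an identifier, an
#' upper-case amino-acid sequence over the 20-letter alphabet plus `X`, an
#' optional free-text description, and an optional true clade label (used by
#' the synthetic-data generator only; the analysis pipeline never reads it).
#'
#' @param id Non-empty, unique identifier.
#' @param sequence Amino-acid sequence; lower case is accepted and upper-cased.
#' @param description Optional free text.
#' @param label Optional true clade tag (`"A"`, `"B"` or `"C"`).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = NULL, label = NULL) {
  abort_if(!is.character(id) || length(id) != 1L || !nzchar(id),
           "id must be a non-empty string",
           class = "nrnbkit_validation_error")
  sequence <- toupper(sequence)
  abort_if(nchar(sequence) < 1L, "record '", id, "' has an empty sequence",
           class = "nrnbkit_validation_error")
  validate_aa(sequence, id)
  structure(list(id = id, sequence = sequence,
                 description = description, label = label),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s: %d aa>\n", x$id, nchar(x$sequence)))
  invisible(x)
}

# validate a list of protein_record: unique non-empty ids
validate_record_set <- function(records) {
  abort_if(length(records) == 0L, "no records supplied",
           class = "nrnbkit_validation_error")
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0, "duplicate record id(s): ",
           paste(unique(dup), collapse = ", "),
           class = "nrnbkit_validation_error")
  invisible(ids)
}

record_ids <- function(records) vapply(records, `[[`, character(1), "id")

#' Read a multi-record FASTA file
#'
#' Sequences are upper-cased on input. Header lines are parsed as
#' `>id description`; duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  aa <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) {
                   stop(errorCondition(
                     paste0("FASTA parse error in '", path, "': ",
                            conditionMessage(e)),
                     class = c("nrnbkit_parse_error", "error", "condition")))
                 })
  abort_if(length(aa) == 0L, "FASTA file '", path, "' contains no records",
           class = "nrnbkit_parse_error")
  headers <- names(aa)
  records <- vector("list", length(aa))
  for (i in seq_along(aa)) {
    hdr <- headers[i]
    abort_if(is.na(hdr) || !nzchar(trimws(hdr)),
             "record ", i, ": empty FASTA header",
             class = "nrnbkit_parse_error")
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    desc <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else NULL
    seq <- as.character(aa[[i]])
    abort_if(nchar(seq) == 0L, "record ", i, " ('", id, "'): empty sequence",
             class = "nrnbkit_parse_error")
    records[[i]] <- protein_record(id, seq, description = desc)
  }
  validate_record_set(records)
  records
}

#' Write records to FASTA (wrapped at 60 columns)
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @param with_label If `TRUE`, append `label=<clade>` to the description
#'   (used by the synthetic generator to carry truth labels).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, with_label = FALSE) {
  validate_record_set(records)
  seqs <- vapply(records, `[[`, character(1), "sequence")
  nm <- vapply(records, function(r) {
    desc <- r$description
    if (with_label && !is.null(r$label)) {
      desc <- paste(c(desc, paste0("label=", r$label)), collapse = " ")
    }
    if (is.null(desc) || !nzchar(desc)) r$id else paste(r$id, desc)
  }, character(1))
  xs <- Biostrings::BStringSet(setNames(seqs, nm))
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}
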