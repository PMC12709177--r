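# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, ..., class = "nrnbkit_error") {
  if (isTRUE(cond)) {
    stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
  }
  invisible(NULL)
}

# split sequences (equal length not required) into a list of character vectors
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# character matrix from equal-length (gapped) rows; rows become matrix rows
rows_to_matrix <- function(rows) {
  abort_if(length(unique(nchar(rows))) > 1, "rows are not equal length")
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

# write a data.frame as TSV (no quotes, no row names)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

validate_aa <- function(sequence, id = "<sequence>", allow_gap = FALSE) {
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  ok <- AA_EXTENDED
  if (allow_gap) ok <- c(ok, GAP_CHAR)
  bad <- setdiff(chars, ok)
  abort_if(length(bad) > 0,
           "record '", id, "' contains invalid residue(s): ",
           paste(bad, collapse = ", "),
           class = "nrnbkit_validation_error")
  invisible(TRUE)
}
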