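# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive and separate from the package's
# implementation paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

# brute-force all-positions substring scan (motif oracle)
brute_motif_scan <- function(sequence, pattern, window = NULL) {
  L <- nchar(sequence)
  p <- nchar(pattern)
  hits <- integer(0)
  if (L >= p) {
    for (s in 1:(L - p + 1)) {
      if (substr(sequence, s, s + p - 1) == pattern) hits <- c(hits, s)
    }
  }
  if (!is.null(window) && length(hits)) {
    hits <- hits[hits / L >= window[1] & hits / L <= window[2]]
  }
  hits
}

# exhaustive-enumeration oracle for affine-gap global alignment score:
# walks every monotone alignment path, scoring gap runs as
# open + (len-1) * extend, and returns the maximum total score
oracle_align_score <- function(a, b, mat, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  # state: i, j consumed; last op (0 none/diag, 1 up, 2 left); score so far
  rec <- function(i, j, last, sc) {
    if (i == na && j == nb) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < na && j < nb) {
      rec(i + 1, j + 1, 0, sc + mat[ca[i + 1], cb[j + 1]])
    }
    if (i < na) {
      rec(i + 1, j, 1, sc - if (last == 1) ext else open)
    }
    if (j < nb) {
      rec(i, j + 1, 2, sc - if (last == 2) ext else open)
    }
    invisible(NULL)
  }
  rec(0, 0, -1, 0)
  best
}

# induced pairwise score of two gapped rows under affine run-length costs
induced_pair_score <- function(ra, rb, mat, open = 10, ext = 1) {
  ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]; cb <- cb[keep]
  sc <- 0; run <- 0L  # run: 0 none, 1 gap-in-a, 2 gap-in-b
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") {
      sc <- sc + mat[ca[k], cb[k]]; run <- 0L
    } else if (ca[k] == "-") {
      sc <- sc - if (run == 1L) ext else open; run <- 1L
    } else {
      sc <- sc - if (run == 2L) ext else open; run <- 2L
    }
  }
  sc
}

sum_of_pairs <- function(rows, mat, open = 10, ext = 1) {
  n <- length(rows); tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + induced_pair_score(rows[i], rows[j], mat, open, ext)
    }
  }
  tot
}

test_blosum <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# records for a base-plus-substitutions family (tie-free distances)
mutated_family <- function(base, k_subs, prefix = "s") {
  lapply(seq_along(k_subs), function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(length(ch), k_subs[i])
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    protein_record(sprintf("%s%02d", prefix, i), paste(ch, collapse = ""))
  })
}

# standalone-style record with an exactly known measured linker/tail:
# nterm "M" x 10, DHH, 10 filler, linker, shared context + signature,
# GGGH, 30 filler, tail
crafted_record <- function(id, linker_len, tail_seq, sig = "K",
                           filler_char = "A") {
  seq <- paste0(strrep("M", 10), "DHH", strrep(filler_char, 10),
                strrep(filler_char, linker_len), "PNLVETFAS", sig,
                "GGGH", strrep(filler_char, 30), tail_seq)
  protein_record(id, seq)
}

# signature residue position of a crafted_record
crafted_sig_pos <- function(linker_len) 10 + 3 + 10 + linker_len + 10

# independent greedy clustering trace (re-implementation for the oracle)
oracle_greedy <- function(records, threshold) {
  ids <- sapply(records, `[[`, "id")
  lens <- sapply(records, function(r) nchar(r$sequence))
  ord <- order(-lens, ids)
  reps <- list(); assign <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pairwise_identity(records[[i]], reps[[ci]]) >= threshold) {
        assign[[ci]] <- c(assign[[ci]], ids[i]); placed <- TRUE; break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1]] <- records[[i]]
      assign[[length(assign) + 1]] <- ids[i]
    }
  }
  assign
}

# cached default synthetic dataset + pipeline run (built once per session)
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_config(seed = 1234L))
    }
    cache
  }
})

default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- default_dataset()
      cache <<- run_pipeline(ds$records, reference_id = ds$reference_id)
    }
    cache
  }
})
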