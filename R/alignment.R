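#' Alignment parameters
#'
#' Affine-gap scoring: a gap of length `L` costs
#' `gap_open + (L - 1) * gap_extend`. Terminal gaps are scored like internal
#' gaps. `max_gap_fraction` drives [filter_gap_columns()]: columns whose gap
#' fraction is *strictly greater* than it are removed (so a column at
#' exactly 95% gaps is retained under the default).
#'
#' @param substitution_matrix Matrix name (only `"BLOSUM62"` ships) or a
#'   numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Positive costs; `gap_extend <= gap_open`.
#' @param max_gap_fraction Column-filter threshold in `(0, 1]`, default 0.95.
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 1,
                             max_gap_fraction = 0.95) {
  if (is.character(substitution_matrix)) {
    abort_if(substitution_matrix != "BLOSUM62",
             "unknown substitution matrix: ", substitution_matrix,
             class = "nrnbkit_validation_error")
    substitution_matrix <- blosum62()
  }
  abort_if(gap_open <= 0 || gap_extend <= 0 || gap_extend > gap_open,
           "need 0 < gap_extend <= gap_open",
           class = "nrnbkit_validation_error")
  abort_if(max_gap_fraction <= 0 || max_gap_fraction > 1,
           "max_gap_fraction must be in (0, 1]",
           class = "nrnbkit_validation_error")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 max_gap_fraction = max_gap_fraction),
            class = "alignment_params")
}

# BLOSUM62 from Biostrings' data store, restricted to the package alphabet
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_EXTENDED, AA_EXTENDED]
    }
    cache
  }
})

#' Optimal pairwise global alignment (affine gaps)
#'
#' Needleman-Wunsch/Gotoh alignment with affine gap costs. Trace-back ties
#' resolve deterministically as diagonal > up > left.
#'
#' @param a,b Amino-acid sequences (strings).
#' @param params An [alignment_params()] object.
#' @return List with `a_aligned`, `b_aligned` (gapped strings) and `score`.
#' @export
global_align <- function(a, b, params = alignment_params()) {
  mat <- params$substitution_matrix
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  bad <- setdiff(c(ca, cb), rownames(mat))
  abort_if(length(bad) > 0, "residue(s) not in substitution matrix: ",
           paste(unique(bad), collapse = ", "),
           class = "nrnbkit_validation_error")
  gap_cost <- function(L) {
    if (L == 0) 0 else -(params$gap_open + (L - 1) * params$gap_extend)
  }
  if (length(ca) == 0L && length(cb) == 0L) {
    return(list(a_aligned = "", b_aligned = "", score = 0))
  }
  if (length(ca) == 0L) {
    return(list(a_aligned = strrep(GAP_CHAR, length(cb)), b_aligned = b,
                score = gap_cost(length(cb))))
  }
  if (length(cb) == 0L) {
    return(list(a_aligned = a, b_aligned = strrep(GAP_CHAR, length(ca)),
                score = gap_cost(length(ca))))
  }
  S <- mat[ca, cb, drop = FALSE]
  res <- .affine_dp(S, params$gap_open, params$gap_extend)
  ops <- res$ops
  posA <- cumsum(ops != 2L)
  posB <- cumsum(ops != 1L)
  ra <- rep(GAP_CHAR, length(ops)); rb <- rep(GAP_CHAR, length(ops))
  ra[ops != 2L] <- ca[posA[ops != 2L]]
  rb[ops != 1L] <- cb[posB[ops != 1L]]
  list(a_aligned = paste(ra, collapse = ""),
       b_aligned = paste(rb, collapse = ""),
       score = res$score)
}

#' Construct a gapped alignment object
#'
#' @param ids Row identifiers (unique, same length as `rows`).
#' @param rows Equal-length gapped sequences over the residue alphabet + `-`.
#' @param source_column_map Optional strictly increasing integer vector
#'   giving, for each retained column, its index in the alignment the
#'   columns were filtered from.
#' @return A `protein_alignment` object.
#' @export
new_alignment <- function(ids, rows, source_column_map = NULL) {
  abort_if(length(ids) != length(rows) || length(ids) == 0L,
           "ids and rows must be non-empty and the same length",
           class = "nrnbkit_validation_error")
  abort_if(anyDuplicated(ids) > 0, "duplicate row ids",
           class = "nrnbkit_validation_error")
  abort_if(length(unique(nchar(rows))) > 1,
           "alignment rows must be equal length",
           class = "nrnbkit_validation_error")
  for (i in seq_along(rows)) validate_aa(rows[i], ids[i], allow_gap = TRUE)
  if (!is.null(source_column_map)) {
    abort_if(length(source_column_map) != nchar(rows[1]) ||
               any(diff(source_column_map) <= 0),
             "source_column_map must be strictly increasing, one per column",
             class = "nrnbkit_validation_error")
  }
  structure(list(row_ids = as.character(ids), rows = as.character(rows),
                 column_count = nchar(rows[1]),
                 source_column_map = source_column_map),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment: %d rows x %d columns%s>\n",
              length(x$row_ids), x$column_count,
              if (is.null(x$source_column_map)) "" else ", filtered"))
  invisible(x)
}

# remove gaps from one alignment row
degap <- function(row) gsub(GAP_CHAR, "", row, fixed = TRUE)

# k-mer set of a sequence
kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  st <- seq_len(L - k + 1L)
  unique(substring(seq, st, st + k - 1L))
}

# fractional shared-k-mer distance table among records
kmer_distance_matrix <- function(records, k = 3L) {
  ids <- record_ids(records)
  sets <- lapply(records, function(r) kmer_set(r$sequence, k))
  n <- length(records)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      d <- if (denom == 0L) 1 else
        1 - length(intersect(sets[[i]], sets[[j]])) / denom
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# UPGMA with deterministic id-lexicographic tie-breaking.
# Returns list(merges, heights, members): merges[[s]] = c(a, b) indexing
# clusters (1..n are input singletons, n+s is the cluster made at step s).
upgma_merges <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  ntot <- 2L * n - 1L
  active <- seq_len(n)
  members <- as.list(seq_len(n))          # leaf indices per cluster
  labels <- c(ids, rep(NA_character_, n - 1L))  # lexicographic tie-break
  sizes <- c(rep(1L, n), rep(0L, n - 1L))
  heights <- rep(0, ntot)
  Dw <- matrix(NA_real_, ntot, ntot)      # distances indexed by cluster id
  Dw[seq_len(n), seq_len(n)] <- D
  merges <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL; bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        d <- Dw[a, b]
        la <- sort(c(labels[a], labels[b]))
        take <- d < bestd - 1e-12 ||
          (abs(d - bestd) <= 1e-12 &&
           (is.null(best) || la[1] < best$la[1] ||
            (la[1] == best$la[1] && la[2] < best$la[2])))
        if (take) { bestd <- d; best <- list(a = a, b = b, la = la) }
      }
    }
    a <- best$a; b <- best$b
    new <- n + s
    members[[new]] <- c(members[[a]], members[[b]])
    labels[new] <- min(labels[a], labels[b])
    sizes[new] <- sizes[a] + sizes[b]
    heights[new] <- bestd / 2
    # UPGMA update: size-weighted average distance to every other cluster
    for (c_ in setdiff(active, c(a, b))) {
      Dw[new, c_] <- Dw[c_, new] <-
        (sizes[a] * Dw[a, c_] + sizes[b] * Dw[b, c_]) / sizes[new]
    }
    merges[[s]] <- c(a, b)
    active <- c(setdiff(active, c(a, b)), new)
  }
  list(merges = merges, heights = heights, members = members, labels = labels)
}

#' UPGMA guide tree on shared-k-mer distances
#'
#' Builds the progressive-alignment guide tree: distances are
#' `1 - |shared k-mers| / min(k-mer counts)` and clustering is UPGMA with
#' ties broken by lexicographic cluster label.
#'
#' @param records List of >= 2 [protein_record()] objects.
#' @param k Word length (default 3).
#' @return An [ape::phylo] ultrametric tree with leaf labels = record ids.
#' @export
build_guide_tree <- function(records, k = 3L) {
  validate_record_set(records)
  abort_if(length(records) < 2L, "need at least 2 records",
           class = "nrnbkit_validation_error")
  D <- kmer_distance_matrix(records, k)
  u <- upgma_merges(D)
  merges_to_phylo(u, rownames(D))
}

# build an ape phylo from upgma_merges output via Newick text
merges_to_phylo <- function(u, ids) {
  n <- length(ids)
  nwk <- function(cl) {
    if (cl <= n) return(list(txt = ids[cl], h = 0))
    ch <- u$merges[[cl - n]]
    l <- nwk(ch[1]); r <- nwk(ch[2])
    h <- u$heights[cl]
    list(txt = sprintf("(%s:%.10g,%s:%.10g)", l$txt, h - l$h,
                       r$txt, h - r$h),
         h = h)
  }
  root <- n + length(u$merges)
  ape::read.tree(text = paste0(nwk(root)$txt, ";"))
}

# 21 x L frequency profile of alignment rows (gap mass simply drops out)
row_profile <- function(rows) {
  m <- rows_to_matrix(rows)
  p <- vapply(AA_EXTENDED, function(a) colSums(m == a), numeric(ncol(m)))
  if (ncol(m) == 1L) p <- matrix(p, nrow = 1L,
                                 dimnames = list(NULL, AA_EXTENDED))
  t(p) / nrow(m)
}

# merge two sub-alignments (lists with ids, rows) along a DP op path
apply_ops <- function(A, B, ops) {
  nop <- length(ops)
  posA <- cumsum(ops != 2L)
  posB <- cumsum(ops != 1L)
  selA <- ops != 2L; selB <- ops != 1L
  expand <- function(row, sel, pos) {
    ch <- strsplit(row, "", fixed = TRUE)[[1]]
    out <- rep(GAP_CHAR, nop)
    out[sel] <- ch[pos[sel]]
    paste(out, collapse = "")
  }
  list(ids = c(A$ids, B$ids),
       rows = c(vapply(A$rows, expand, character(1), selA, posA,
                       USE.NAMES = FALSE),
                vapply(B$rows, expand, character(1), selB, posB,
                       USE.NAMES = FALSE)))
}

#' Progressive multiple sequence alignment
#'
#' Profiles are merged in guide-tree post-order by profile-profile global
#' alignment with affine gap costs; the column-pair score is the
#' frequency-weighted mean substitution score (gap mass contributes zero).
#' Every input sequence is recoverable from its row by removing gaps.
#'
#' @param records List of >= 2 [protein_record()] objects.
#' @param params An [alignment_params()] object.
#' @param k Guide-tree word length.
#' @return A [new_alignment()] object, rows in input record order.
#' @export
progressive_msa <- function(records, params = alignment_params(), k = 3L) {
  validate_record_set(records)
  abort_if(length(records) < 2L, "need at least 2 records",
           class = "nrnbkit_validation_error")
  for (r in records) validate_aa(r$sequence, r$id)
  mat <- params$substitution_matrix[AA_EXTENDED, AA_EXTENDED]
  D <- kmer_distance_matrix(records, k)
  u <- upgma_merges(D)
  n <- length(records)
  sub <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) {
    sub[[i]] <- list(ids = records[[i]]$id, rows = records[[i]]$sequence)
  }
  for (s in seq_along(u$merges)) {
    ch <- u$merges[[s]]
    A <- sub[[ch[1]]]; B <- sub[[ch[2]]]
    PA <- row_profile(A$rows); PB <- row_profile(B$rows)
    S <- crossprod(PA, mat %*% PB)       # t(PA) %*% mat %*% PB
    res <- .affine_dp(S, params$gap_open, params$gap_extend)
    sub[[n + s]] <- apply_ops(A, B, res$ops)
    sub[[ch[1]]] <- sub[[ch[2]]] <- NULL_slot()
  }
  final <- sub[[2L * n - 1L]]
  ord <- match(record_ids(records), final$ids)
  new_alignment(final$ids[ord], final$rows[ord])
}

NULL_slot <- function() list(ids = character(0), rows = character(0))

#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction is strictly greater than
#' `params$max_gap_fraction` are removed (the ">95% gaps" site filter under
#' the defaults: a 100-row column with 96 gaps goes, one with 95 stays).
#' Provenance of retained columns is recorded in `source_column_map`,
#' composed with any existing map.
#'
#' @param aln A `protein_alignment`.
#' @param params An [alignment_params()] object.
#' @return A filtered `protein_alignment` (possibly zero columns).
#' @export
filter_gap_columns <- function(aln, params = alignment_params()) {
  m <- rows_to_matrix(aln$rows)
  gap_frac <- colMeans(m == GAP_CHAR)
  keep <- which(gap_frac <= params$max_gap_fraction)
  old_map <- aln$source_column_map %||% seq_len(aln$column_count)
  rows <- vapply(seq_along(aln$rows), function(i) {
    paste(m[i, keep], collapse = "")
  }, character(1))
  structure(list(row_ids = aln$row_ids, rows = rows,
                 column_count = length(keep),
                 source_column_map = old_map[keep]),
            class = "protein_alignment")
}

#' Read a gapped (aligned) FASTA file as an alignment
#'
#' Supports importing alignments produced by external tools for parity runs.
#'
#' @param path Aligned FASTA path.
#' @return A `protein_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  recs <- read_fasta_allow_gaps(path)
  new_alignment(vapply(recs, `[[`, character(1), "id"),
                vapply(recs, `[[`, character(1), "sequence"))
}

# like read_fasta but rows may contain gap characters
read_fasta_allow_gaps <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  lapply(seq_along(aa), function(i) {
    hdr <- strsplit(trimws(names(aa)[i]), "\\s+")[[1]]
    seq <- toupper(as.character(aa[[i]]))
    validate_aa(seq, hdr[1], allow_gap = TRUE)
    list(id = hdr[1], sequence = seq)
  })
}

#' Write an alignment as gapped FASTA (60-column wrap)
#'
#' @param aln A `protein_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  xs <- Biostrings::BStringSet(setNames(aln$rows, aln$row_ids))
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Export a filtered alignment's column provenance as TSV
#'
#' @param aln A filtered `protein_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_column_map_tsv <- function(aln, path) {
  map <- aln$source_column_map %||% seq_len(aln$column_count)
  write_tsv(data.frame(column = seq_along(map), source_column = map), path)
}
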