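#' Clustering configuration
#'
#' Greedy incremental identity clustering in the style of CD-HIT. Identity
#' is computed from the optimal global alignment as identical aligned
#' residue pairs divided by the length of the *shorter* sequence (CD-HIT's
#' denominator convention); the threshold comparison is inclusive, matching
#' CD-HIT's `-c` cutoff. Profiles: prokaryote-style reduction uses 0.70,
#' eukaryote-style 0.90.
#'
#' @param identity_threshold Fraction in `(0, 1]` (default 0.70).
#' @param word_length k-mer length for the admissible prefilter (default 3).
#' @param use_prefilter Logical; the k-mer count bound is an optimization
#'   only and never changes the result (tested).
#' @return A `clustering_config` object.
#' @export
clustering_config <- function(identity_threshold = 0.70, word_length = 3L,
                              use_prefilter = TRUE) {
  abort_if(identity_threshold <= 0 || identity_threshold > 1,
           "identity_threshold must be in (0, 1]",
           class = "nrnbkit_validation_error")
  structure(list(identity_threshold = identity_threshold,
                 denominator_rule = "shorter-sequence length",
                 word_length = as.integer(word_length),
                 use_prefilter = isTRUE(use_prefilter)),
            class = "clustering_config")
}

#' Pairwise sequence identity
#'
#' Fraction of identical aligned residue pairs in the optimal global
#' alignment, divided by the length of the shorter sequence. Symmetric.
#'
#' @param a,b [protein_record()] objects (or plain sequence strings).
#' @param params An [alignment_params()] object.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, params = alignment_params()) {
  sa <- if (inherits(a, "protein_record")) a$sequence else a
  sb <- if (inherits(b, "protein_record")) b$sequence else b
  abort_if(nchar(sa) == 0L || nchar(sb) == 0L,
           "sequences must be non-empty",
           class = "nrnbkit_validation_error")
  if (sa == sb) return(1)
  al <- global_align(sa, sb, params)
  ca <- strsplit(al$a_aligned, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$b_aligned, "", fixed = TRUE)[[1]]
  matches <- sum(ca == cb & ca != GAP_CHAR)
  min(1, matches / min(nchar(sa), nchar(sb)))
}

# admissible k-mer lower bound: if two sequences reach identity >= c, their
# shared k-mer multiset is at least m - (k-1)*(Ls - m + 1) with
# m = ceiling(c * Ls) matched residues (matches form runs; every
# interruption destroys at most k-1 words). If the observed shared count is
# below this bound, identity < c is certain and alignment can be skipped.
kmer_shared_count <- function(ta, tb) {
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(ta[common], tb[common]))
}

kmer_table <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(table(character(0)))
  st <- seq_len(L - k + 1L)
  table(substring(seq, st, st + k - 1L))
}

#' Greedy incremental identity clustering
#'
#' Records are sorted by length descending (ties by id, lexicographic).
#' Each record joins the first existing cluster whose representative
#' identity is at or above the threshold, otherwise it founds a new cluster
#' with itself as representative. Output order is founding order.
#'
#' @param records List of [protein_record()] objects with unique ids.
#' @param config A [clustering_config()].
#' @param params An [alignment_params()] for the identity alignments.
#' @return List of clusters; each has `representative_id`, `member_ids`
#'   (representative included) and `identities` (per member, vs the
#'   representative).
#' @export
greedy_cluster <- function(records, config = clustering_config(),
                           params = alignment_params()) {
  validate_record_set(records)
  ids <- record_ids(records)
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  ord <- order(-lens, ids)
  records <- records[ord]
  k <- config$word_length
  thr <- config$identity_threshold
  tabs <- if (config$use_prefilter) {
    lapply(records, function(r) kmer_table(r$sequence, k))
  } else {
    NULL
  }
  clusters <- list()
  rep_idx <- integer(0)   # index into `records` of each representative
  for (i in seq_along(records)) {
    r <- records[[i]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_rec <- records[[rep_idx[ci]]]
      if (config$use_prefilter) {
        Ls <- min(nchar(r$sequence), nchar(rep_rec$sequence))
        m_min <- ceiling(thr * Ls)
        need <- m_min - (k - 1) * (Ls - m_min + 1)
        if (need > 0 &&
            kmer_shared_count(tabs[[i]], tabs[[rep_idx[ci]]]) < need) {
          next
        }
      }
      idt <- pairwise_identity(r, rep_rec, params)
      if (idt >= thr) {
        clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, r$id)
        clusters[[ci]]$identities <- c(clusters[[ci]]$identities,
                                       setNames(idt, r$id))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        representative_id = r$id,
        member_ids = r$id,
        identities = setNames(1, r$id))
      rep_idx <- c(rep_idx, i)
    }
  }
  clusters
}

#' Export clusters as TSV
#'
#' @param clusters Result of [greedy_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  rows <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_index = i,
               representative_id = cl$representative_id,
               member_id = cl$member_ids,
               identity = as.numeric(cl$identities),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
}

# representative records from a clustering, in founding order
cluster_representatives <- function(records, clusters) {
  ids <- record_ids(records)
  lapply(clusters, function(cl) records[[match(cl$representative_id, ids)]])
}
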