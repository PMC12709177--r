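#' Run the full family-analysis pipeline
#'
#' Chains the stages: motif scan and standalone filter, greedy identity
#' clustering (redundancy reduction), progressive multiple alignment of the
#' cluster representatives, gap-column filtering, Poisson-corrected
#' distances, neighbor joining, midpoint rooting, major-clade extraction,
#' and (when a reference id is supplied) reference-anchored feature
#' extraction and rule-based clade classification of the aligned records.
#'
#' The designated reference record, when present among the standalone
#' records, is always carried into the alignment even if clustering
#' absorbed it into another cluster.
#'
#' @param records List of [protein_record()] objects.
#' @param reference_id Optional id of the reference-numbering row.
#' @param identity Clustering identity threshold (default 0.70).
#' @param offsets A [segmentation_offsets()].
#' @param params An [alignment_params()].
#' @param config A [phylo_config()] (distance model, clade extraction).
#' @param rules A [classifier_rules()].
#' @return List with `scan`, `clusters`, `alignment` (filtered), `tree`
#'   (midpoint-rooted), `clades` (list of leaf-id sets), and, with a
#'   reference, `anchor` and `calls` (classification data.frame).
#' @export
run_pipeline <- function(records, reference_id = NULL, identity = 0.70,
                         offsets = segmentation_offsets(),
                         params = alignment_params(),
                         config = phylo_config(),
                         rules = classifier_rules()) {
  sc <- scan_records(records, offsets = offsets)
  keep <- records[sc$standalone[record_ids(records)]]
  abort_if(length(keep) < 3L,
           "fewer than 3 standalone DHH-DHHA1 records; cannot build a tree",
           class = "nrnbkit_validation_error")
  clusters <- greedy_cluster(keep, clustering_config(identity), params)
  reps <- cluster_representatives(keep, clusters)
  rep_ids <- record_ids(reps)
  if (!is.null(reference_id) && !reference_id %in% rep_ids) {
    ridx <- match(reference_id, record_ids(keep))
    abort_if(is.na(ridx), "reference id '", reference_id,
             "' is not a standalone record",
             class = "nrnbkit_validation_error")
    reps <- c(reps, keep[ridx])
  }
  msa <- progressive_msa(reps, params)
  msa_f <- filter_gap_columns(msa, params)
  D <- distance_matrix(msa_f, config$distance_model)
  tree <- midpoint_root(neighbor_joining(D))
  clades <- extract_major_clades(tree, config)
  out <- list(scan = sc, clusters = clusters, alignment = msa_f,
              tree = tree, clades = clades)
  if (!is.null(reference_id)) {
    anchor <- anchor_positions(msa_f, reference_id, rules$signature_position)
    out$anchor <- anchor
    out$calls <- classify_records(reps, sc$segmentations, anchor, msa_f,
                                  rules)
  }
  out
}

#' Purity of extracted clades against truth labels
#'
#' For each extracted clade, the purity is the fraction of its members
#' carrying the clade's majority truth label; the overall purity is the
#' member-weighted mean.
#'
#' @param clades List of leaf-id sets (from [extract_major_clades()]).
#' @param labels Named character vector or data.frame (`id`, `clade`).
#' @return List with `overall` purity and per-clade `purity` / majority
#'   `label`.
#' @export
clade_purity <- function(clades, labels) {
  if (is.data.frame(labels)) labels <- setNames(labels$clade, labels$id)
  if (!length(clades)) return(list(overall = NA_real_, purity = numeric(0),
                                   label = character(0)))
  per <- vapply(clades, function(ids) {
    tab <- table(labels[ids])
    max(tab) / length(ids)
  }, numeric(1))
  maj <- vapply(clades, function(ids) {
    names(which.max(table(labels[ids])))
  }, character(1))
  n <- vapply(clades, length, integer(1))
  list(overall = sum(per * n) / sum(n), purity = per, label = maj)
}
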