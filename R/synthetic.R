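# Fixed synthetic architecture (residue coordinates, 1-based):
#   1..140    random N-terminal region
#   141..143  DHH motif
#   144..153  DHH-region filler (k1 = 10)
#   +linker   inter-domain linker (length per clade archetype)
#   +10       shared active-site block; its last residue is the
#             clade-diagnostic signature (reference position 285 when the
#             linker is 122, as in the emitted reference record)
#   +4        GGGH motif
#   +30       DHHA1-region filler (k3 = 30)
#   +tail     C-terminal tail (length and K+R enrichment per clade)
SYN_NTERM <- 140L
SYN_DHH_POS <- 141L
SYN_K1 <- 10L
SYN_K2_CONTEXT <- "PNLVETFAS"   # first 9 of the shared active-site block
SYN_K3 <- 30L
SYN_REF_LINKER <- 122L          # places the signature at reference pos 285

#' Clade archetype specification
#'
#' Defaults encode the three family architectures: clade A has a long
#' linker, a long (105-160 aa) K/R-enriched C-terminal tail and lysine at
#' the signature position; clade B a short tail and asparagine; clade C a
#' short tail and a residue other than K or N.
#'
#' @param name `"A"`, `"B"` or `"C"`.
#' @param linker_length_range,cterm_length_range Inclusive integer ranges;
#'   defaults per clade (A: 120-180 / 105-160; B: 60-120 / 10-45;
#'   C: 40-90 / 10-45).
#' @param signature_residue Single letter; default K (A), N (B), `NA` (C:
#'   sampled uniformly from the residues excluding K and N).
#' @param cterm_kr_enrichment Target K+R fraction in the tail (A: 0.3,
#'   B/C: 0.05).
#' @return A `clade_archetype_spec` object.
#' @export
clade_archetype_spec <- function(name = c("A", "B", "C"),
                                 linker_length_range = NULL,
                                 cterm_length_range = NULL,
                                 signature_residue = NULL,
                                 cterm_kr_enrichment = NULL) {
  name <- match.arg(name)
  defaults <- list(
    A = list(linker = c(120L, 180L), cterm = c(105L, 160L),
             sig = "K", kr = 0.3),
    B = list(linker = c(60L, 120L), cterm = c(10L, 45L),
             sig = "N", kr = 0.05),
    C = list(linker = c(40L, 90L), cterm = c(10L, 45L),
             sig = NA_character_, kr = 0.05))
  d <- defaults[[name]]
  linker_length_range <- as.integer(linker_length_range %||% d$linker)
  cterm_length_range <- as.integer(cterm_length_range %||% d$cterm)
  abort_if(linker_length_range[1] > linker_length_range[2] ||
             cterm_length_range[1] > cterm_length_range[2],
           "inverted length range",
           class = "nrnbkit_validation_error")
  structure(list(name = name,
                 dhh_motif_position = SYN_DHH_POS,
                 linker_length_range = linker_length_range,
                 cterm_length_range = cterm_length_range,
                 signature_residue = signature_residue %||% d$sig,
                 cterm_kr_enrichment = cterm_kr_enrichment %||% d$kr),
            class = "clade_archetype_spec")
}

#' Generator configuration
#'
#' @param seqs_per_clade Leaves per family (default 20).
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length (default 0.05).
#' @param protected_factor Rate multiplier for protected positions (the
#'   DHH/GGGH motif residues and the signature position; default 0.01).
#' @param clade_tree_depth Root-to-tip depth of each family's Yule subtree
#'   (default 10; with the default rate this gives ~0.45-0.50 expected
#'   pairwise divergence within a family, safely below the 0.70 identity
#'   threshold used for redundancy clustering).
#' @param root_branch Branch length joining each family to the deep root
#'   (default 5).
#' @param seed Integer seed; mandatory for dataset emission.
#' @return A `generator_config` object.
#' @export
generator_config <- function(seqs_per_clade = 20L, substitution_rate = 0.05,
                             protected_factor = 0.01, clade_tree_depth = 10,
                             root_branch = 5, seed = NULL) {
  abort_if(substitution_rate < 0 || substitution_rate > 1 ||
             protected_factor < 0 || protected_factor > 1,
           "rates must lie in [0, 1]",
           class = "nrnbkit_validation_error")
  structure(list(seqs_per_clade = as.integer(seqs_per_clade),
                 substitution_rate = substitution_rate,
                 protected_factor = protected_factor,
                 clade_tree_depth = clade_tree_depth,
                 root_branch = root_branch,
                 seed = seed),
            class = "generator_config")
}

sample_aa <- function(n, exclude = character(0)) {
  pool <- setdiff(AA_ALPHABET, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

sample_tail <- function(n, kr_fraction) {
  if (n == 0L) return("")
  kr <- runif(n) < kr_fraction
  out <- character(n)
  out[kr] <- sample(c("K", "R"), sum(kr), replace = TRUE)
  out[!kr] <- sample(setdiff(AA_ALPHABET, c("K", "R")), sum(!kr),
                     replace = TRUE)
  paste(out, collapse = "")
}

#' Construct a clade archetype sequence
#'
#' Assembles the fixed synthetic architecture with clade-specific linker
#' and tail lengths, signature residue, and K+R tail enrichment. Uses the
#' current RNG state; rejection-samples so that the assembled sequence has
#' its primary in-window DHH hit exactly at the motif anchor, its primary
#' GGGH hit at the intended position, and a total length within the
#' standalone filter bounds.
#'
#' @param spec A [clade_archetype_spec()].
#' @param id Record id.
#' @param linker_length Optional fixed linker length (otherwise sampled
#'   from the spec range); the emitted reference record uses 122.
#' @return A [protein_record()] labeled with the clade name; attribute
#'   `layout` records linker/tail lengths and protected positions.
#' @export
make_archetype <- function(spec, id = paste0("arch_", spec$name),
                           linker_length = NULL) {
  sig <- spec$signature_residue
  if (is.na(sig)) sig <- sample(setdiff(AA_ALPHABET, c("K", "N")), 1L)
  off <- segmentation_offsets()
  for (attempt in seq_len(200L)) {
    rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L
    linker <- if (!is.null(linker_length)) as.integer(linker_length) else
      rint(spec$linker_length_range[1], spec$linker_length_range[2])
    tail_len <- rint(spec$cterm_length_range[1], spec$cterm_length_range[2])
    seq <- paste0(sample_aa(SYN_NTERM), "DHH", sample_aa(SYN_K1),
                  sample_aa(linker), SYN_K2_CONTEXT, sig, "GGGH",
                  sample_aa(SYN_K3), sample_tail(tail_len,
                                                 spec$cterm_kr_enrichment))
    L <- nchar(seq)
    if (L < off$min_length || L > off$max_standalone_length) next
    rec <- protein_record(id, seq, label = spec$name)
    hits <- scan_motifs(rec, default_motifs())
    dhh <- primary_hit(hits, "DHH"); gggh <- primary_hit(hits, "GGGH")
    gggh_expect <- SYN_NTERM + 3L + SYN_K1 + linker + 10L + 1L
    if (is.null(dhh) || is.null(gggh) || dhh$start != SYN_DHH_POS ||
        gggh$start != gggh_expect) {
      next
    }
    sig_pos <- gggh_expect - 1L
    attr(rec, "layout") <- list(
      linker_length = linker, cterm_length = tail_len,
      signature_position = sig_pos, signature_residue = sig,
      protected = c(SYN_DHH_POS:(SYN_DHH_POS + 2L), sig_pos,
                    gggh_expect:(gggh_expect + 3L)))
    return(rec)
  }
  stop("failed to assemble a valid archetype in 200 attempts")
}

# substitute along one branch: sites see >= 1 Poisson event with
# probability 1 - exp(-lambda); hit sites are replaced uniformly by one of
# the other 19 residues
mutate_branch <- function(chars, t, rate, protected, protected_factor) {
  lambda <- rep(rate * t, length(chars))
  lambda[protected] <- lambda[protected] * protected_factor
  hit <- which(runif(length(chars)) < 1 - exp(-lambda))
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  }
  chars
}

#' Evolve a family from an archetype along a simulated Yule tree
#'
#' Simulates a pure-birth tree with `n` leaves rescaled to the configured
#' depth, then applies independent per-site substitutions along each branch
#' (uniform replacement over the other 19 residues; protected motif and
#' signature positions mutate at `rate * protected_factor`).
#'
#' @param archetype A [make_archetype()] record (carries the `layout`
#'   attribute naming protected positions).
#' @param n Number of leaves (>= 1).
#' @param config A [generator_config()].
#' @param id_prefix Leaf id prefix (default the archetype's clade label).
#' @return List with `records` (leaf [protein_record()]s, clade-labeled)
#'   and `tree` (the true subtree, an [ape::phylo]).
#' @export
evolve_family <- function(archetype, n, config = generator_config(),
                          id_prefix = NULL) {
  abort_if(n < 1L, "n must be >= 1", class = "nrnbkit_validation_error")
  layout <- attr(archetype, "layout")
  abort_if(is.null(layout), "archetype lacks a layout attribute",
           class = "nrnbkit_validation_error")
  prefix <- id_prefix %||% paste0("NrnB_", archetype$label)
  if (n == 1L) {
    tr <- ape::read.tree(text = sprintf("(%s_01:%g);", prefix,
                                        config$clade_tree_depth))
  } else {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * config$clade_tree_depth / depth
    tr$tip.label <- sprintf("%s_%02d", prefix, seq_len(n))
  }
  tr <- ape::reorder.phylo(tr, "cladewise")
  ntip <- length(tr$tip.label)
  root_chars <- strsplit(archetype$sequence, "", fixed = TRUE)[[1]]
  seqs <- vector("list", ntip + tr$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_chars
  records <- vector("list", ntip)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    seqs[[ch]] <- mutate_branch(seqs[[par]], tr$edge.length[e],
                                config$substitution_rate, layout$protected,
                                config$protected_factor)
    if (ch <= ntip) {
      records[[ch]] <- protein_record(tr$tip.label[ch],
                                      paste(seqs[[ch]], collapse = ""),
                                      label = archetype$label)
    }
  }
  if (ntip == 1L && is.null(records[[1]])) {
    # single-leaf tree read from text has one edge handled above
    records[[1]] <- protein_record(tr$tip.label[1], archetype$sequence,
                                   label = archetype$label)
  }
  list(records = records, tree = tr)
}

#' Generate the default synthetic three-clade dataset
#'
#' Builds one archetype per clade (the clade-A archetype, with its linker
#' fixed at 122 so the signature sits at reference position 285, is also
#' emitted as the reference record `NrnB_ref`), evolves each into a family,
#' and joins the families at a deep root. With a fixed seed the outputs are
#' byte-identical across runs.
#'
#' @param config A [generator_config()] with a non-`NULL` seed.
#' @param out_dir Optional directory; when given, writes `dataset.fasta`
#'   (truth labels in descriptions), `labels.tsv` (id, clade) and
#'   `true_tree.nwk`.
#' @return List with `records`, `labels` (data.frame), `true_tree`
#'   ([ape::phylo]), `reference_id`, and `files` when written.
#' @export
generate_dataset <- function(config = generator_config(seed = 1234L),
                             out_dir = NULL) {
  abort_if(is.null(config$seed), "config$seed is mandatory",
           class = "nrnbkit_validation_error")
  set.seed(config$seed)
  arch <- list(
    A = make_archetype(clade_archetype_spec("A"), id = "NrnB_ref",
                       linker_length = SYN_REF_LINKER),
    B = make_archetype(clade_archetype_spec("B")),
    C = make_archetype(clade_archetype_spec("C")))
  fams <- lapply(arch, evolve_family, n = config$seqs_per_clade,
                 config = config)
  ref <- arch$A
  ref$description <- "synthetic clade-A archetype (reference numbering)"
  records <- c(list(ref), fams$A$records, fams$B$records, fams$C$records)
  validate_record_set(records)
  labels <- data.frame(
    id = record_ids(records),
    clade = vapply(records, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  subtree_txt <- vapply(fams, function(f) {
    sub("\\);?$", "", sub("^\\(", "", sub(";$", "", ape::write.tree(f$tree))))
  }, character(1))
  # attach the unevolved reference at the clade-A subtree root
  nwk <- sprintf("(((%s)famA:0,NrnB_ref:0):%g,(%s)famB:%g,(%s)famC:%g);",
                 subtree_txt[["A"]], config$root_branch,
                 subtree_txt[["B"]], config$root_branch,
                 subtree_txt[["C"]], config$root_branch)
  true_tree <- ape::read.tree(text = nwk)
  out <- list(records = records, labels = labels, true_tree = true_tree,
              reference_id = "NrnB_ref")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f_fa <- file.path(out_dir, "dataset.fasta")
    f_lab <- file.path(out_dir, "labels.tsv")
    f_nwk <- file.path(out_dir, "true_tree.nwk")
    write_fasta(records, f_fa, with_label = TRUE)
    write_tsv(labels, f_lab)
    writeLines(nwk, f_nwk)
    out$files <- c(fasta = f_fa, labels = f_lab, tree = f_nwk)
  }
  out
}

#' Generate synthetic assay tables
#'
#' Depletion traces follow exponential decay with multiplicative log-normal
#' noise; the phosphate standard curve is linear with additive Gaussian
#' noise. True parameters ride along for recovery tests.
#'
#' @param config A [generator_config()] (seed mandatory).
#' @param out_dir Optional directory for `depletion.tsv` and
#'   `standard_curve.tsv`.
#' @param decay_rate True decay constant per minute (default 0.08).
#' @param noise_sd Relative (depletion) / absolute (curve) noise SD
#'   (defaults 0.05 and 0.005).
#' @param slope,intercept True standard-curve parameters (defaults 0.01
#'   absorbance/uM and 0.05).
#' @return List with `depletion` (data.frame), `curve` (data.frame) and
#'   `truth` (named list of generating parameters).
#' @export
generate_assay_tables <- function(config = generator_config(seed = 1234L),
                                  out_dir = NULL, decay_rate = 0.08,
                                  noise_sd = 0.05, slope = 0.01,
                                  intercept = 0.05) {
  abort_if(is.null(config$seed), "config$seed is mandatory",
           class = "nrnbkit_validation_error")
  set.seed(config$seed)
  time_min <- c(0, 2, 5, 10, 20, 30, 60)
  i0 <- 10000
  intensity <- i0 * exp(-decay_rate * time_min) *
    exp(stats::rnorm(length(time_min), 0, noise_sd))
  depletion <- data.frame(time_min = time_min, intensity = intensity)
  conc <- c(0, 5, 10, 20, 40, 60, 80, 100)
  a620 <- slope * conc + intercept +
    stats::rnorm(length(conc), 0, noise_sd / 10)
  curve <- data.frame(conc_uM = conc, a620 = a620)
  out <- list(depletion = depletion, curve = curve,
              truth = list(decay_rate = decay_rate, i0 = i0, slope = slope,
                           intercept = intercept, noise_sd = noise_sd))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f_dep <- file.path(out_dir, "depletion.tsv")
    f_cur <- file.path(out_dir, "standard_curve.tsv")
    write_tsv(depletion, f_dep)
    write_tsv(curve, f_cur)
    out$files <- c(depletion = f_dep, curve = f_cur)
  }
  out
}
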