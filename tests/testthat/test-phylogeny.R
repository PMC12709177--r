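test_that("distance_matrix: definitions and the Poisson closed form", {
  aln <- new_alignment(c("a", "b", "c"),
                       c("MKVLAWPQ", "MKVLAWPQ", "MKWWAWPQ"))
  Dp <- distance_matrix(aln, "p")
  expect_equal(Dp$values["a", "b"], 0)
  expect_equal(Dp$values["a", "c"], 2 / 8)
  # half the comparable columns differ -> p = 0.5, poisson -ln(0.5)
  aln2 <- new_alignment(c("a", "b"), c("MKVL", "MKAW"))
  expect_equal(distance_matrix(aln2, "p")$values["a", "b"], 0.5)
  expect_equal(distance_matrix(aln2, "poisson")$values["a", "b"], -log(0.5))
  # pairwise deletion: gapped columns are excluded
  aln3 <- new_alignment(c("a", "b"), c("MK-L", "MKA-"))
  expect_equal(distance_matrix(aln3, "p")$values["a", "b"], 0)
  # no comparable columns errors, naming the pair
  aln4 <- new_alignment(c("a", "b"), c("M-", "-K"))
  expect_error(distance_matrix(aln4, "p"), "a.*b",
               class = "nrnbkit_validation_error")
})

test_that("NJ: 3-taxon closed form and zero-distance cherry", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # x_a = (d_ab + d_ac - d_bc)/2 = 1, x_b = 2, x_c = 3
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(neighbor_joining(D[1:2, 1:2]),
               class = "nrnbkit_validation_error")

  # two identical taxa form a zero-pendant cherry
  D4 <- matrix(c(0, 0, 6, 6,
                 0, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- neighbor_joining(D4)
  mrca <- ape::getMRCA(ape::root(tr4, "d"), c("a", "b"))
  cherry <- ape::extract.clade(ape::root(tr4, "d"), mrca)
  expect_equal(sort(cherry$tip.label), c("a", "b"))
  ab_pend <- tr4$edge.length[tr4$edge[, 2] %in% 1:2]
  expect_equal(ab_pend, c(0, 0))
})

test_that("NJ recovers generating trees exactly from additive distances", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n)
    D <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(D)
    # identical unrooted topology ...
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    # ... and identical path lengths (branch-length recovery)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-6)
  }
})

test_that("midpoint rooting splits the longest path in half", {
  # two-leaf tree: root at d/2
  tr2 <- midpoint_root(ape::read.tree(text = "(A:1,B:2);"))
  d2 <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(d2, c(1.5, 1.5))

  # caterpillar with hand-computed longest path: B..D = 2+1+1+5 = 9
  cat_tr <- ape::read.tree(text = "(((A:1,B:2):1,C:3):1,D:5);")
  rooted <- midpoint_root(ape::unroot(cat_tr))
  dep <- ape::node.depth.edgelength(rooted)
  ntip <- 4
  expect_equal(max(dep[1:ntip]), 4.5)
  # the two deepest leaves sit at equal depth (within 1e-9)
  s <- sort(dep[1:ntip], decreasing = TRUE)
  expect_lt(abs(s[1] - s[2]), 1e-9)

  # node-centered midpoint: no zero-length extra edge is created
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rooted_b <- midpoint_root(ape::unroot(bal))
  expect_equal(rooted_b$Nnode, 3)
  expect_equal(max(ape::node.depth.edgelength(rooted_b)[1:4]), 2)

  # all-zero branch lengths warn and root at the first internal node
  z <- ape::read.tree(text = "(A:0,B:0,C:0);")
  expect_warning(midpoint_root(z), "zero")
})

test_that("midpoint property: equal maximal leaf depths on random trees", {
  set.seed(202)
  for (rep in 1:50) {
    tr <- ape::unroot(ape::rtree(sample(4:20, 1)))
    rooted <- midpoint_root(tr)
    ntip <- length(rooted$tip.label)
    dep <- ape::node.depth.edgelength(rooted)[seq_len(ntip)]
    halves <- sort(dep, decreasing = TRUE)
    expect_lt(abs(halves[1] - halves[2]), 1e-9)
    # rooting preserves leaf-to-leaf path lengths
    expect_equal(ape::cophenetic.phylo(rooted)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-9)
    # agreement with the independent reference implementation on depth
    pm <- phangorn::midpoint(tr)
    expect_equal(max(dep),
                 max(ape::node.depth.edgelength(pm)[seq_len(ntip)]),
                 tolerance = 1e-9)
  }
})

test_that("bootstrap: no-op at zero replicates, seeded, supports in [0,1]", {
  set.seed(7)
  fam <- mutated_family(random_aa(60), c(0, 2, 4, 20, 22, 40), prefix = "b")
  aln <- progressive_msa(fam)
  tr0 <- bootstrap_support(aln, phylo_config(bootstrap_replicates = 0))
  expect_null(tr0$node.label)
  cfg <- phylo_config(bootstrap_replicates = 50)
  tr1 <- bootstrap_support(aln, cfg, seed = 99)
  tr2 <- bootstrap_support(aln, cfg, seed = 99)
  expect_identical(attr(tr1, "support"), attr(tr2, "support"))
  expect_true(all(attr(tr1, "support") >= 0 & attr(tr1, "support") <= 1))
})

test_that("bootstrap recovers clear block structure with high support", {
  # 4 distinct blocks of near-identical rows -> every true bipartition
  # should be recovered in nearly all replicates
  set.seed(303)
  blocks <- lapply(1:4, function(i) random_aa(80))
  recs <- list()
  for (i in 1:4) {
    for (j in 1:2) {
      ch <- strsplit(blocks[[i]], "")[[1]]
      p <- sample(80, 2)   # light within-block noise
      for (q in p) ch[q] <- sample(setdiff(AA20, ch[q]), 1)
      recs[[length(recs) + 1]] <-
        protein_record(sprintf("b%d_%d", i, j), paste(ch, collapse = ""))
    }
  }
  aln <- progressive_msa(recs)
  tr <- bootstrap_support(aln, phylo_config(bootstrap_replicates = 100),
                          seed = 42)
  sup <- attr(tr, "support")
  # the true bipartitions are the four block cherries; inter-block edges
  # resolve a star arbitrarily and carry no signal
  for (i in 1:4) {
    mrca <- ape::getMRCA(tr, sprintf("b%d_%d", i, 1:2))
    expect_gte(sup[mrca - length(tr$tip.label)], 0.95)
  }
})

test_that("major-clade extraction: separation, degenerate star, size gate", {
  pl <- default_pipeline()
  ds <- default_dataset()
  expect_length(pl$clades, 3)
  pur <- clade_purity(pl$clades, ds$labels)
  expect_gte(pur$overall, 0.95)

  # star tree with uniform distances -> no substructure, empty result
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  expect_length(extract_major_clades(midpoint_root(star),
                                     phylo_config(clade_min_size = 2)), 0)

  # clade_min_size larger than the leaf count -> empty
  expect_length(extract_major_clades(midpoint_root(star),
                                     phylo_config(clade_min_size = 50)), 0)

  # reported sets are disjoint and within the leaf set
  all_ids <- unlist(pl$clades)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_true(all(all_ids %in% pl$tree$tip.label))
})

test_that("newick io: parse, round-trip, malformed input with offset", {
  tr <- read_newick(text = "(A:1,B:2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))

  set.seed(77)
  big <- ape::rtree(20)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(big, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(big)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(round(big$edge.length, 6)),
               tolerance = 1e-9)

  err <- tryCatch(read_newick(text = "((A:1,B:2);"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "offset")
  expect_error(read_newick(text = "(A:1,B:2));"),
               class = "nrnbkit_parse_error")
})
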