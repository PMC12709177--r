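test_that("archetypes satisfy their clade construction guarantees", {
  set.seed(3)
  for (rep in 1:3) {
    a <- make_archetype(clade_archetype_spec("A"))
    seg <- segment_domains(a, scan_motifs(a, default_motifs()))
    expect_true(seg$cterm_length >= 105 && seg$cterm_length <= 160)
    expect_true(seg$linker_length >= 120 && seg$linker_length <= 180)
    lay <- attr(a, "layout")
    expect_equal(substr(a$sequence, lay$signature_position,
                        lay$signature_position), "K")

    b <- make_archetype(clade_archetype_spec("B"))
    segb <- segment_domains(b, scan_motifs(b, default_motifs()))
    expect_true(segb$cterm_length >= 10 && segb$cterm_length <= 45)
    layb <- attr(b, "layout")
    expect_equal(substr(b$sequence, layb$signature_position,
                        layb$signature_position), "N")

    cc <- make_archetype(clade_archetype_spec("C"))
    layc <- attr(cc, "layout")
    expect_false(substr(cc$sequence, layc$signature_position,
                        layc$signature_position) %in% c("K", "N"))
  }
  expect_error(clade_archetype_spec("A", linker_length_range = c(50, 10)),
               class = "nrnbkit_validation_error")
})

test_that("the reference archetype places the signature at position 285", {
  set.seed(4)
  ref <- make_archetype(clade_archetype_spec("A"), id = "ref",
                        linker_length = 122)
  expect_equal(attr(ref, "layout")$signature_position, 285)
  expect_equal(substr(ref$sequence, 285, 285), "K")
})

test_that("zero substitution rate reproduces the archetype at every leaf", {
  set.seed(5)
  arch <- make_archetype(clade_archetype_spec("B"))
  fam <- evolve_family(arch, 6, generator_config(substitution_rate = 0,
                                                 seed = 1))
  for (r in fam$records) expect_equal(r$sequence, arch$sequence)
  expect_equal(length(fam$tree$tip.label), 6)
})

test_that("branch substitutions match the Poisson-event expectation", {
  # depth-1 single branch at rate 0.05: P(site differs) = 1 - exp(-0.05)
  set.seed(6)
  arch <- make_archetype(clade_archetype_spec("B"))
  cfg <- generator_config(substitution_rate = 0.05, clade_tree_depth = 1,
                          seed = 1)
  diffs <- 0; sites <- 0
  prot <- attr(arch, "layout")$protected
  for (rep in 1:10) {
    fam <- evolve_family(arch, 2, cfg)
    for (r in fam$records) {
      a <- strsplit(arch$sequence, "")[[1]]
      b <- strsplit(r$sequence, "")[[1]]
      keep <- setdiff(seq_along(a), prot)
      diffs <- diffs + sum(a[keep] != b[keep])
      sites <- sites + length(keep)
    }
  }
  p_hat <- diffs / sites
  p_exp <- 1 - exp(-0.05)
  se <- sqrt(p_exp * (1 - p_exp) / sites)
  expect_lt(abs(p_hat - p_exp), 4 * se)
})

test_that("protected positions mutate at about 1% of the base rate", {
  set.seed(61)
  arch <- make_archetype(clade_archetype_spec("A"))
  prot <- attr(arch, "layout")$protected
  cfg <- generator_config(substitution_rate = 0.5, clade_tree_depth = 2,
                          seed = 1)
  hits <- 0; trials <- 0
  for (rep in 1:40) {
    fam <- evolve_family(arch, 2, cfg)
    for (r in fam$records) {
      a <- strsplit(arch$sequence, "")[[1]]
      b <- strsplit(r$sequence, "")[[1]]
      hits <- hits + sum(a[prot] != b[prot])
      trials <- trials + length(prot)
    }
  }
  # unprotected expectation at these settings is ~1 - exp(-1) = 0.63;
  # protected sites should come in near 1% of that
  expect_lt(hits / trials, 0.05)
})

test_that("generate_dataset: counts, determinism, truth labels, filter", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(generator_config(seed = 77L), out_dir = d1)
  ds2 <- generate_dataset(generator_config(seed = 77L), out_dir = d2)
  expect_identical(readLines(file.path(d1, "dataset.fasta")),
                   readLines(file.path(d2, "dataset.fasta")))
  expect_equal(length(ds1$records), 61)   # 3 x 20 + reference
  expect_equal(unname(table(ds1$labels$clade)["B"]), 20, ignore_attr = TRUE)
  expect_error(generate_dataset(generator_config()),
               class = "nrnbkit_validation_error")  # seed mandatory

  # truth labels ride in descriptions and the sidecar TSV agrees
  fa <- read_fasta(file.path(d1, "dataset.fasta"))
  descs <- sapply(fa, function(r) {
    if (is.null(r$description)) "" else r$description
  })
  expect_true(all(grepl("label=", descs)))
  lab <- read.delim(file.path(d1, "labels.tsv"))
  expect_equal(sort(lab$id), sort(sapply(fa, `[[`, "id")))

  # the true tree covers exactly the emitted records
  expect_equal(sort(ds1$true_tree$tip.label), sort(lab$id))

  # nearly all emitted records pass the standalone filter (protected
  # positions still mutate at 1% of the base rate, so motif loss is rare
  # but possible)
  sc <- scan_records(ds1$records)
  expect_gte(mean(sc$standalone), 0.95)
})

test_that("assay table generator: noiseless limits recover the truth", {
  tabs <- generate_assay_tables(generator_config(seed = 9L), noise_sd = 0)
  tr <- normalize_depletion(tabs$depletion$time_min,
                            tabs$depletion$intensity)
  expect_equal(tr$normalized,
               exp(-tabs$truth$decay_rate * tabs$depletion$time_min))
  cv <- fit_standard_curve(tabs$curve$conc_uM, tabs$curve$a620)
  expect_equal(cv$slope, tabs$truth$slope)
  expect_equal(cv$intercept, tabs$truth$intercept)
})

test_that("noisy standard curves recover the slope within sampling error", {
  set.seed(10)
  slopes <- replicate(20, {
    tabs <- generate_assay_tables(
      generator_config(seed = sample.int(1e6, 1)), noise_sd = 0.05)
    fit_standard_curve(tabs$curve$conc_uM, tabs$curve$a620)$slope
  })
  # least-squares sampling distribution: se = sigma / sqrt(Sxx)
  conc <- c(0, 5, 10, 20, 40, 60, 80, 100)
  se <- (0.05 / 10) / sqrt(sum((conc - mean(conc))^2))
  expect_lt(abs(mean(slopes) - 0.01), 3 * se / sqrt(20))
})
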