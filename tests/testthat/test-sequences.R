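test_that("FASTA round-trip preserves records, order and case", {
  recs <- list(protein_record("p1", "maaadhhaaaggghaa", description = "one"),
               protein_record("p2", "DHHKLMGGGH"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_length(back, 2)
  expect_equal(sapply(back, `[[`, "id"), c("p1", "p2"))
  expect_equal(back[[1]]$sequence, "MAAADHHAAAGGGHAA")  # upper-cased
  expect_equal(back[[1]]$description, "one")
})

test_that("FASTA reader rejects duplicates, empties and missing files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "MKL"), f)
  expect_error(read_fasta(f), class = "nrnbkit_validation_error")
  writeLines(c(">a", "MKV", ">b", ""), f)
  expect_error(read_fasta(f), class = "nrnbkit_parse_error")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
  expect_error(protein_record("x", "MK1V"),
               class = "nrnbkit_validation_error")
})

test_that("scan_motifs finds exact in-window hits, first flagged primary", {
  r <- protein_record("x", "MAAADHHAAAGGGHAA")
  hits <- scan_motifs(r, default_motifs())
  expect_equal(hits$motif_name, c("DHH", "GGGH"))
  expect_equal(hits$start, c(5, 11))
  expect_equal(hits$end, c(7, 14))
  # no GGGH
  r2 <- protein_record("y", "MAAADHHAAAAAA")
  h2 <- scan_motifs(r2, default_motifs())
  expect_false("GGGH" %in% h2$motif_name)
  # two in-window DHH occurrences: both returned, first primary
  r3 <- protein_record("z", paste0("ADHHKKDHHK", strrep("A", 10)))
  h3 <- scan_motifs(r3, list(motif_definition("DHH", "DHH", c(0, 0.7))))
  expect_equal(h3$start, c(2, 7))
  expect_equal(h3$primary, c(TRUE, FALSE))
})

test_that("scan_motifs agrees with the brute-force substring oracle", {
  set.seed(42)
  motifs <- default_motifs()
  for (rep in 1:25) {
    L <- sample(c(5, 50, 300, 2000), 1)
    # enrich with motif letters so hits actually occur
    seq <- paste(sample(c(AA20, "D", "H", "G"), L, replace = TRUE),
                 collapse = "")
    r <- protein_record("r", seq)
    hits <- scan_motifs(r, motifs)
    for (m in motifs) {
      expect_equal(hits$start[hits$motif_name == m$name],
                   brute_motif_scan(seq, m$pattern, m$search_window))
    }
  }
})

test_that("segment_domains applies offset formulas and clamping", {
  # worked arithmetic: L=400, DHH@(80,82), GGGH@(260,263), k=10/10/30
  r <- protein_record("x", paste0(strrep("M", 79), "DHH", strrep("A", 170),
                                  strrep("A", 7), "GGGH", strrep("A", 137)))
  expect_equal(nchar(r$sequence), 400)
  seg <- segment_domains(r, scan_motifs(r, default_motifs()))
  expect_equal(seg$dhh_region_end, 92)        # 82 + 10
  expect_equal(seg$dhha1_region_start, 250)   # 260 - 10
  expect_equal(seg$dhha1_region_end, 293)     # 263 + 30
  expect_equal(seg$linker_length, 157)        # 250 - 92 - 1
  expect_equal(seg$cterm_length, 107)         # 400 - 293
  expect_equal(seg$linker_span, c(93, 249))
  expect_equal(seg$cterm_span, c(294, 400))

  # clamping floor: GGGH right after DHH -> empty linker
  r2 <- protein_record("y", paste0(strrep("M", 30), "DHHGGGH",
                                   strrep("A", 60)))
  seg2 <- segment_domains(r2, scan_motifs(r2, default_motifs()))
  expect_equal(seg2$linker_length, 0)
  expect_length(seg2$linker_span, 0)

  # clamping at the sequence end: GGGH at the final residues, k3 = 30
  r3 <- protein_record("z", paste0(strrep("M", 30), "DHH", strrep("A", 40),
                                   "GGGH"))
  seg3 <- segment_domains(r3, scan_motifs(r3, default_motifs()))
  expect_equal(seg3$dhha1_region_end, nchar(r3$sequence))
  expect_equal(seg3$cterm_length, 0)

  # missing anchor errors name the anchor
  expect_error(segment_domains(r, data.frame(motif_name = "DHH", start = 80,
                                             end = 82, primary = TRUE)),
               "GGGH", class = "nrnbkit_segmentation_error")
})

test_that("segment_domains is deterministic and spans stay in bounds", {
  set.seed(7)
  for (i in 1:20) {
    linker <- sample(0:250, 1)
    r <- crafted_record(paste0("d", i), linker,
                        strrep("A", sample(0:150, 1)))
    s1 <- segment_domains(r, scan_motifs(r, default_motifs()))
    s2 <- segment_domains(r, scan_motifs(r, default_motifs()))
    expect_identical(s1[names(s1) != "offsets"], s2[names(s2) != "offsets"])
    expect_lt(s1$linker_length + s1$cterm_length, nchar(r$sequence))
    expect_equal(s1$linker_length, linker)
  }
})

test_that("standalone filter enforces motifs and the length window", {
  r <- crafted_record("ok", 200, strrep("A", 40))
  seg <- segment_domains(r, scan_motifs(r, default_motifs()))
  expect_gte(nchar(r$sequence), 250)
  expect_true(is_standalone_dhh_dhha1(r, seg)$standalone)

  long <- crafted_record("long", 400, strrep("A", 250))
  expect_gt(nchar(long$sequence), 700)
  seg_l <- segment_domains(long, scan_motifs(long, default_motifs()))
  dec <- is_standalone_dhh_dhha1(long, seg_l)
  expect_false(dec$standalone)
  expect_match(dec$reason, "cap")

  no_gggh <- protein_record("ng", paste0(strrep("M", 100), "DHH",
                                         strrep("A", 200)))
  sc <- scan_records(list(no_gggh))
  expect_false(sc$standalone[["ng"]])
  expect_match(sc$reasons[["ng"]], "signature")

  short <- protein_record("sh", "MDHHAAAGGGHAA")
  sc2 <- scan_records(list(short))
  expect_false(sc2$standalone[["sh"]])
  expect_match(sc2$reasons[["sh"]], "minimum")
})

test_that("segmentation TSV export has the documented columns", {
  recs <- list(crafted_record("a", 200, "KKRAAE"),
               protein_record("b", strrep("M", 300)))
  sc <- scan_records(recs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_segmentation_tsv(sc, f)
  tab <- read.delim(f)
  expect_equal(names(tab),
               c("id", "dhh_start", "dhh_end", "gggh_start", "gggh_end",
                 "linker_length", "cterm_length", "standalone", "reason"))
  expect_equal(tab$standalone, c(TRUE, FALSE))
})
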