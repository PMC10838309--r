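test_that("a uniquely present probe yields a gap-free full-score top hit", {
  set.seed(90)
  genome <- random_seq(5000)
  asm <- genome_assembly(c(chr = genome))
  probe <- substr(genome, 1001, 1040)
  hits <- align_probe(probe, asm)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_equal(top$start, 1000L)
  expect_equal(top$end, 1040L)
  expect_equal(top$strand, "+")
  expect_equal(top$score, 2 * 40)
  expect_equal(top$probe_row, top$target_row)
  expect_false(grepl("-", top$probe_row, fixed = TRUE))
})

test_that("planted exact tandem copies are each hit once on the + strand", {
  asm <- exact_tandem_assembly(monomer_len = 60, copies = 20)
  monomer_start <- 400L
  probe <- substr(asm$scaffolds[["chrT"]], monomer_start + 11,
                  monomer_start + 50)  # 40-mer inside the first copy
  hits <- align_probe(probe, asm)
  plus <- hits[hits$strand == "+" & hits$score == 80, ]
  expect_equal(nrow(plus), 20L)
  expect_equal(sort(plus$start), monomer_start + 10L + 60L * 0:19)

  # oracle: exhaustive scan for exact 40-mer windows
  genome <- asm$scaffolds[["chrT"]]
  exact <- sum(vapply(1:(nchar(genome) - 39),
                      function(i) substr(genome, i, i + 39) == probe,
                      logical(1)))
  expect_equal(nrow(plus), exact)

  capped <- align_probe(probe, asm, max_alignments = 5)
  expect_equal(nrow(capped), 5L)
})

test_that("reverse-strand sites are reported in forward coordinates", {
  set.seed(91)
  genome <- random_seq(3000)
  site <- substr(genome, 2001, 2040)
  probe <- chartr("ACGT", "TGCA", paste(rev(strsplit(site, "")[[1]]),
                                        collapse = ""))
  asm <- genome_assembly(c(chr = genome))
  hits <- align_probe(probe, asm)
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, 2000L)
  expect_equal(minus$end, 2040L)
  # target row is the reverse complement of the genomic slice
  expect_equal(minus$target_row, probe)
})

test_that("stored scores re-derive from the aligned rows", {
  set.seed(92)
  genome <- random_seq(4000)
  asm <- genome_assembly(c(chr = genome))
  for (i in 1:5) {
    s <- sample(3000, 1)
    probe <- substr(genome, s, s + 39)
    # corrupt two positions so alignment has mismatches
    substr(probe, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(probe, 5, 5))[1]
    substr(probe, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                     substr(probe, 30, 30))[1]
    hits <- align_probe(probe, asm)
    for (j in seq_len(nrow(hits))) {
      expect_equal(alignment_score_from_rows(hits$probe_row[j],
                                             hits$target_row[j]),
                   hits$score[j])
    }
  }
})

test_that("row reconstruction matches an independent DP traceback oracle", {
  set.seed(93)
  for (i in 1:8) {
    target_site <- random_seq(60)
    probe <- substr(target_site, 11, 50)
    # introduce one substitution into the probe
    p <- sample(5:35, 1)
    substr(probe, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(probe, p, p))[1]
    asm <- genome_assembly(c(chr = paste0(random_seq(300), target_site,
                                          random_seq(300))))
    hits <- align_probe(probe, asm)
    expect_gte(nrow(hits), 1L)
    top <- hits[1, ]
    oracle <- naive_local_align(probe, substr(asm$scaffolds[["chr"]],
                                              top$start - 11,
                                              top$end + 12))
    expect_equal(top$score, oracle$score)
    expect_equal(top$probe_row, oracle$a_row)
    expect_equal(top$target_row, oracle$b_row)
    # rows differ at exactly one column for a single substitution
    pr <- strsplit(top$probe_row, "")[[1]]
    tr <- strsplit(top$target_row, "")[[1]]
    expect_lte(sum(pr != tr), 1L)
  }
})

test_that("repeated alignment calls are deterministic; short probes error", {
  asm <- exact_tandem_assembly()
  probe <- substr(asm$scaffolds[["chrT"]], 421, 455)
  h1 <- align_probe(probe, asm)
  h2 <- align_probe(probe, asm)
  expect_identical(h1, h2)
  expect_error(align_probe("ACGTACGT", asm), "seed_length")
})
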