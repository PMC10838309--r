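make_scored_fixture <- function(seed = 80) {
  set.seed(seed)
  monomer <- random_seq(171)
  asm <- genome_assembly(c(
    chr = paste0(random_seq(3000), strrep(monomer, 12), random_seq(3000))))
  target <- bed_intervals("chr", 3000, 3000 + 171 * 12)
  tab <- count_kmers(asm, 18)
  cands <- deduplicate(mine_candidates(target, asm))
  list(asm = asm, tab = tab, target = target, cands = cands)
}

test_that("k_b is 1 for target-exclusive probes and 0.5 for half-shared", {
  # probe k-mers occur once inside and once outside the target
  set.seed(81)
  block <- random_seq(60)
  asm <- genome_assembly(c(chr = paste0(random_seq(200), block,
                                        random_seq(200), block,
                                        random_seq(200))))
  target <- bed_intervals("chr", 200, 260)
  tab <- count_kmers(asm, 18)
  cands <- data.frame(scaffold = "chr", start = 210L, end = 250L,
                      sequence = substr(asm$scaffolds[["chr"]], 211, 250),
                      stringsAsFactors = FALSE)
  scored <- score_candidates(cands, tab, target, asm)
  expect_equal(scored$k_b, 0.5)
  expect_equal(scored$h_m, 2L * scored$r_m)

  fx <- make_scored_fixture()
  scored <- score_candidates(fx$cands, fx$tab, fx$target, fx$asm)
  expect_true(all(scored$k_b == 1))  # exact tandem, no decoy
  expect_true(all(scored$r_m == scored$h_m))
})

test_that("scores equal the brute-force double-scan oracle", {
  fx <- make_scored_fixture(82)
  scored <- score_candidates(fx$cands, fx$tab, fx$target, fx$asm)
  genome <- fx$asm$scaffolds[["chr"]]
  region <- substr(genome, fx$target$start + 1, fx$target$end)
  for (i in sample(nrow(scored), 5)) {
    pk <- substring(scored$sequence[i], 1:(scored$length[i] - 17),
                    18:scored$length[i])
    expect_equal(scored$h_m[i],
                 sum(vapply(pk, naive_substring_count, integer(1),
                            subject = genome)))
    expect_equal(scored$r_m[i],
                 sum(vapply(pk, naive_substring_count, integer(1),
                            subject = region)))
  }
})

test_that("normalized rank follows the formula with stated tie-breaks", {
  df <- data.frame(scaffold = "s", start = c(0L, 100L),
                   end = c(40L, 140L), sequence = c("A", "B"),
                   r_m = c(10L, 5L), h_m = c(10L, 5L), k_b = c(1, 1),
                   stringsAsFactors = FALSE)
  ranked <- normalized_rank(df, c1 = 1, c2 = 1)
  expect_equal(ranked$nr, c(2.0, 1.5))
  expect_equal(ranked$r_m, c(10L, 5L))

  single <- normalized_rank(df[1, ], c1 = 2, c2 = 4)
  expect_equal(single$nr, 1 / 2 + 1 / 4)

  expect_error(normalized_rank(df, c1 = 0), "positive")
  expect_error(normalized_rank(df, c2 = -1), "positive")
})

test_that("ranking matches an independent re-evaluation on 50 random probes", {
  set.seed(83)
  n <- 50
  df <- data.frame(scaffold = "s", start = sample.int(10000, n),
                   sequence = replicate(n, random_seq(30)),
                   r_m = sample.int(500, n), stringsAsFactors = FALSE)
  df$end <- df$start + 30L
  df$h_m <- df$r_m + sample.int(300, n)
  df$k_b <- df$r_m / df$h_m
  ranked <- normalized_rank(df, c1 = 2, c2 = 0.5)
  nr_oracle <- df$r_m / (max(df$r_m) * 2) + df$k_b / (max(df$k_b) * 0.5)
  expect_equal(sort(ranked$nr, decreasing = TRUE), sort(nr_oracle,
                                                        decreasing = TRUE))
  expect_equal(ranked$sequence,
               df$sequence[order(-nr_oracle, df$start, df$sequence)])
  # scale-free: scaling all r_m leaves the ordering unchanged
  df2 <- df
  df2$r_m <- df2$r_m * 7L
  df2$h_m <- df2$h_m * 7L
  expect_equal(normalized_rank(df2, 2, 0.5)$sequence, ranked$sequence)
})

test_that("mer_cutoff filter rejects redundant probes per the set oracle", {
  seqs <- c(a = random_seq(40, seed = 84), b = random_seq(40, seed = 85))
  df <- data.frame(scaffold = "s", start = c(0L, 0L, 100L),
                   end = c(40L, 40L, 140L),
                   sequence = c(seqs[["a"]], seqs[["a"]], seqs[["b"]]),
                   nr = c(3, 2, 1), stringsAsFactors = FALSE)
  out <- mer_cutoff_filter(df, mer_cutoff = 0.95, k = 18)
  expect_equal(out$sequence, c(seqs[["a"]], seqs[["b"]]))  # duplicate dropped
  expect_equal(nrow(mer_cutoff_filter(df, mer_cutoff = 1.0, k = 18)), 3L)
})

test_that("mer_cutoff survivors obey the running-union overlap bound", {
  fx <- make_scored_fixture(86)
  scored <- score_candidates(fx$cands, fx$tab, fx$target, fx$asm)
  ranked <- normalized_rank(scored)
  for (cutoff in c(0.3, 0.6, 0.9)) {
    surv <- mer_cutoff_filter(ranked, cutoff, 18)
    # order-preserving subsequence
    expect_true(all(surv$sequence %in% ranked$sequence))
    expect_false(is.unsorted(match(surv$sequence, ranked$sequence)))
    # set-arithmetic oracle: replay the union
    seen <- character(0)
    for (i in seq_len(nrow(ranked))) {
      kms <- unique(substring(ranked$sequence[i],
                              1:(nchar(ranked$sequence[i]) - 17),
                              18:nchar(ranked$sequence[i])))
      accept_oracle <- mean(kms %in% seen) <= cutoff
      expect_equal(ranked$sequence[i] %in% surv$sequence, accept_oracle)
      if (accept_oracle) seen <- union(seen, kms)
    }
  }
  # decreasing cutoff never increases survivors
  counts <- vapply(c(0.9, 0.6, 0.3),
                   function(co) nrow(mer_cutoff_filter(ranked, co, 18)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
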