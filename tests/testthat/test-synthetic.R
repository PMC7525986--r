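test_that("codon simulator is seeded, stop-free and degenerates correctly", {
  tr <- star_tree(5, 0.1)
  mod <- site_class_model(rep("bg", 30), c(bg = 1), kappa = 2)
  a1 <- simulate_codon_alignment(tr, mod, 30, seed = 9)
  a2 <- simulate_codon_alignment(tr, mod, 30, seed = 9)
  expect_identical(a1$sequence, a2$sequence) # determinism
  expect_false(any(a1$has_stop))
  expect_false(any(vapply(a1$sequence, function(s) {
    any(equimhc::translate_codons(substring(s, seq(1, 88, 3), seq(3, 90, 3))) == "*")
  }, logical(1))))

  tr0 <- star_tree(4, 0)
  a0 <- simulate_codon_alignment(tr0, mod, 30, seed = 2)
  expect_equal(length(unique(a0$sequence)), 1L) # zero branches -> identical

  expect_error(simulate_codon_alignment(NULL, mod, 30), "empty tree")
})

test_that("neutral simulation gives mean pairwise dN - dS near zero", {
  tr <- star_tree(4, 0.2)
  mod <- site_class_model(rep("bg", 90), c(bg = 1), kappa = 1)
  diffs <- vapply(1:200, function(i) {
    aln <- simulate_codon_alignment(tr, mod, 90, seed = 5000 + i)
    prs <- utils::combn(nrow(aln), 2)
    mean(vapply(seq_len(ncol(prs)), function(k) {
      r <- ng86_pair(aln$sequence[prs[1, k]], aln$sequence[prs[2, k]])
      r$dN - r$dS
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * mc_se + 0.005)
})

test_that("simulator is stationary at high divergence", {
  # two tips separated by a very long path: codon frequencies approach
  # the (uniform) model frequencies
  tr <- star_tree(2, 10)
  mod <- site_class_model(rep("bg", 2000), c(bg = 1), kappa = 2)
  aln <- simulate_codon_alignment(tr, mod, 2000, seed = 31)
  cods <- substring(aln$sequence[1], seq(1, 5998, 3), seq(3, 6000, 3))
  counts <- table(factor(cods, levels = equimhc::CODONS))
  gof <- stats::chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 1e-4)
})

test_that("recombinant splicing honours the breakpoint and its edge cases", {
  tr <- star_tree(4, 0.1)
  mod <- site_class_model(rep("bg", 30), c(bg = 1), kappa = 2)
  left <- simulate_codon_alignment(tr, mod, 30, seed = 1)
  right <- simulate_codon_alignment(tr, mod, 30, seed = 2)
  rec <- make_recombinant(left, right, 12)
  expect_equal(attr(rec, "true_breakpoint"), 12L)
  expect_identical(substr(rec$sequence, 1, 36), substr(left$sequence, 1, 36))
  expect_identical(substr(rec$sequence, 37, 90), substr(right$sequence, 37, 90))

  same <- make_recombinant(left, left, 15)
  expect_identical(same$sequence, left$sequence)

  r0 <- make_recombinant(left, right, 0)
  expect_identical(r0$sequence, right$sequence)

  other <- right
  other$id[1] <- "different_tip"
  expect_error(make_recombinant(left, other, 10), "share")
})

test_that("amplicon read simulation decorates, errs and demultiplexes as specified", {
  cfg <- locus_config("DQB1", 269,
    primer_fwd = "CCTCTGGGGTAACGTTCCAG",
    primer_rev = "CGGCCTTGCTTTAGGTTTATC"
  )
  allele <- strrep("ATGAAA", 10)
  mids <- c(M1 = "ACGAGTGCGT", M2 = "ACGCTCGACA")
  reads <- simulate_amplicon_reads(allele, 10, 0, mids["M1"], cfg, seed = 4)
  expect_equal(nrow(reads), 10L)
  expect_equal(length(unique(reads$sequence)), 1L) # error-free: identical
  expect_true(all(startsWith(reads$sequence, paste0(mids[["M1"]], cfg$primer_fwd))))

  both <- simulate_amplicon_reads(allele, 5, 0.002, mids, cfg, seed = 4)
  dem <- demultiplex(both, mids)
  expect_equal(as.vector(table(dem$mid)[c("M1", "M2")]), c(5L, 5L))
  expect_identical(dem$mid, both$mid) # partitions exactly by true tag

  expect_error(simulate_amplicon_reads(character(0), 5, 0, mids, cfg), "empty")
  expect_error(simulate_amplicon_reads(allele, 5, 0.2, mids, cfg), "error_rate")
})

test_that("depth-track simulation matches its construction guarantees", {
  pres <- simulate_depth_track(1000, present = TRUE, mean_depth = 20, seed = 7)
  expect_gt(nonzero_coverage_fraction(pres$depth), 0.9)

  abs_tr <- simulate_depth_track(1000, present = FALSE, seed = 8)
  expect_lt(nonzero_coverage_fraction(abs_tr$depth), 0.10)

  zero <- simulate_depth_track(500, present = TRUE, mean_depth = 0, seed = 9)
  expect_true(all(zero$depth == 0))

  d1 <- simulate_depth_track(200, TRUE, 15, 0.1, seed = 11)
  d2 <- simulate_depth_track(200, TRUE, 15, 0.1, seed = 11)
  expect_identical(d1$depth, d2$depth)
})
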