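test_that("ng86 handles single- and multi-pathway codon pairs", {
  # AAA -> AAG is Lys -> Lys: one synonymous difference
  r <- ng86_pair("ATGAAA", "ATGAAG")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  # identical sequences
  r0 <- ng86_pair("ATGAAA", "ATGAAA")
  expect_equal(r0$Sd + r0$Nd, 0)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  # a two-position pair equals the mean over both orderings (oracle)
  r2 <- ng86_pair("TTTACT", "TTTAGG")  # ACT vs AGG differs at 2 positions
  o <- oracle_pair_diff("ACT", "AGG")
  expect_equal(r2$Sd, unname(o["sd"]))
  expect_equal(r2$Nd, unname(o["nd"]))
  # symmetry in sequence order
  r3a <- ng86_pair("ATGAAATTTCCC", "ATGAGATTCCCC")
  r3b <- ng86_pair("ATGAGATTCCCC", "ATGAAATTTCCC")
  expect_equal(r3a$dN, r3b$dN)
  expect_equal(r3a$dS, r3b$dS)
  # contract errors
  expect_error(ng86_pair("ATG", "ATGAAA"), "length")
  expect_error(ng86_pair("ATGA", "ATGA"), "multiple of 3")
  expect_error(ng86_pair("TAAAAA", "TAAAAA"), "stop")
})

test_that("gapped codons are skipped pairwise in ng86 counting", {
  r <- ng86_pair("ATG---AAA", "ATGAAAAAG")
  full <- ng86_pair("ATGAAA", "ATGAAG")
  expect_equal(r$S, full$S)
  expect_equal(r$Sd, full$Sd)
})

test_that("the Z-test follows its conventions and detects simulated selection", {
  inv <- make_aln(rep(strrep("ATGAAA", 15), 5))
  zt <- global_z_test(inv, n_boot = 50, seed = 1)
  expect_equal(zt$p_one_tailed, 1.0)
  expect_equal(zt$mean_dN_minus_dS, 0)

  # seeded determinism
  tr <- star_tree(8, 0.15)
  mod <- site_class_model(rep("bg", 60), c(bg = 1), kappa = 1)
  aln <- simulate_codon_alignment(tr, mod, 60, seed = 44)
  z1 <- glance(global_z_test(aln, n_boot = 200, seed = 3))
  z2 <- glance(global_z_test(aln, n_boot = 200, seed = 3))
  expect_equal(z1, z2)

  # strong pervasive positive selection is detected
  modp <- site_class_model(rep("abs", 60), c(abs = 6), kappa = 1)
  alnp <- simulate_codon_alignment(star_tree(12, 0.15), modp, 60, seed = 45)
  zp <- global_z_test(alnp, n_boot = 300, seed = 2)
  expect_lt(zp$p_one_tailed, 0.05)
  expect_gt(zp$mean_dN_minus_dS, 0)

  # stop-flagged sequences are excluded
  seqs <- c(strrep("ATGAAA", 15), strrep("ATGAAG", 15))
  with_stop <- paste0(substr(seqs[1], 1, 30), "TAA", substr(seqs[1], 34, 90))
  aln2 <- make_aln(c(seqs, with_stop))
  z <- global_z_test(aln2, n_boot = 50, seed = 1)
  expect_equal(z$n_seq, 2L)

  td <- tidy(global_z_test(aln2, n_boot = 50, seed = 1))
  expect_named(td, c("term", "estimate", "statistic", "std.error", "p.value"))
})

test_that("SLAC reconstructs and classifies a hand-computable toy case", {
  # star tree, one nonsynonymous change on one terminal branch:
  # AAA (Lys) x3 vs AGA (Arg)
  aln <- make_aln(c("AAA", "AAA", "AAA", "AGA"),
    ids = c("a", "b", "c", "d")
  )
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1,d:0.1);")
  tab <- slac_sites(aln, tr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$nd, 1)
  expect_equal(tab$sd, 0)

  # invariant column contributes no changes and class none
  aln2 <- make_aln(rep(strrep("ATGAAA", 5), 4), ids = letters[1:4])
  tab2 <- slac_sites(aln2, tr)
  expect_true(all(tab2$sd + tab2$nd == 0))
  expect_true(all(tab2$class == "none"))

  bad <- ape::read.tree(text = "(x:1,y:1,z:1,w:1);")
  expect_error(slac_sites(aln, bad), "mismatch")
})

test_that("FEL returns its degenerate values and detects strong selection", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1,d:0.1);")
  inv <- make_aln(rep(strrep("ATGAAA", 3), 4), ids = letters[1:4])
  tab <- fel_sites(inv, tr)
  expect_true(all(tab$alpha == 0 & tab$beta == 0 & tab$p == 1))

  # a strongly selected simulated alignment: beta exceeds alpha at most
  # truly positive sites
  tr12 <- demo_equid_tree(scale = 4)
  mod <- site_class_model(rep(c("pos", "bg"), c(10, 20)), c(bg = 0.3, pos = 5), kappa = 1)
  aln <- simulate_codon_alignment(tr12, mod, 30, seed = 21)
  nt <- optimize_branch_lengths(aln, nj_tree(jc_distance_matrix(aln)))
  fel <- fel_sites(aln, nt)
  truly <- attr(aln, "true_omega") > 1
  expect_gt(mean(fel$beta[truly] > fel$alpha[truly]), 0.5)
})

test_that("the consensus rule needs two methods and is monotone", {
  t1 <- tibble::tibble(codon = 1:5, class = c("positive", "none", "negative", "none", "positive"))
  t2 <- tibble::tibble(codon = 1:5, class = c("positive", "none", "negative", "positive", "none"))
  t3 <- tibble::tibble(codon = 1:5, class = c("none", "none", "negative", "positive", "positive"))

  cons2 <- consensus_sites(list(a = t1, b = t2), abs_codons = c(1, 2))
  expect_equal(cons2$consensus, c("positive", "none", "negative", "none", "none"))
  expect_equal(cons2$is_abs, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # a site flagged by one method only is never consensus
  expect_true(all(cons2$consensus[cons2$n_positive < 2 & cons2$n_negative < 2] == "none"))

  # adding a method can only grow the consensus set
  cons3 <- consensus_sites(list(a = t1, b = t2, c = t3))
  grew_pos <- which(cons2$consensus == "positive")
  expect_true(all(cons3$consensus[grew_pos] == "positive"))
  expect_gte(
    sum(cons3$consensus != "none"),
    sum(cons2$consensus != "none")
  )

  expect_error(consensus_sites(list(a = t1)), "at least two")
})

test_that("the SAAS report counts, intersects predictors and handles empties", {
  cfg <- locus_config("DQB3", 269, abs_codons = c(2, 5), frame_offset = 2)
  cons <- consensus_sites(
    list(
      a = tibble::tibble(codon = 1:6, class = c("none", "positive", "none", "none", "positive", "none")),
      b = tibble::tibble(codon = 1:6, class = c("none", "positive", "none", "none", "positive", "none"))
    ),
    abs_codons = cfg$abs_codons
  )
  # alignment with substitutions at codons 2 (ABS+SAAS) and 3 (neither)
  base <- paste0("TC", strrep("ATGAAA", 3))
  alt <- base
  substr(alt, 7, 7) <- "C" # codon 2: AAA -> ACA (K -> T)
  substr(alt, 9, 9) <- "C" # codon 3: ATG -> CTG (M -> L)
  aln <- make_aln(c(base, base, alt), frame_offset = 2L)
  rep <- saas_report(cons[1:6, ], aln, cfg)
  expect_equal(rep$counts$n_positive, 2L)
  expect_equal(rep$counts$n_negative, 0L)
  expect_equal(sort(rep$variants$aa_position), c(2L, 3L))
  expect_equal(rep$variants$is_abs[rep$variants$aa_position == 2], TRUE)
  expect_equal(rep$site_summary$n_saas, 1L)

  # no selected sites -> SAAS count 0
  cons_none <- cons
  cons_none$consensus <- "none"
  rep0 <- saas_report(cons_none, aln, cfg)
  expect_equal(rep0$site_summary$n_saas, 0L)

  # predictor intersection: deleterious by one tool only is excluded
  preds <- tibble::tibble(
    aa_position = c(2L, 2L, 3L, 3L),
    substitution = c("K -> T", "K -> T", "M -> L", "M -> L"),
    tool = c("provean", "polyphen", "provean", "polyphen"),
    deleterious = c(TRUE, TRUE, TRUE, FALSE)
  )
  repd <- saas_report(cons[1:6, ], aln, cfg, predictors = preds)
  expect_equal(repd$deleterious_both$aa_position, 2L)
  expect_true(repd$deleterious_both$is_abs)
  expect_error(
    saas_report(cons[1:6, ], aln, cfg, predictors = preds[, 1:2]),
    "malformed"
  )

  # constructed truth: every SAAS-flagged substitution lies in the ABS
  expect_true(all(rep$variants$is_abs[rep$variants$is_saas]))
})
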