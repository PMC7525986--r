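test_that("JC distances follow the closed form and saturate safely", {
  a <- make_aln(c(strrep("ATGAAA", 10), strrep("ATGAAA", 10)))
  expect_equal(unname(jc_distance_matrix(a)[1, 2]), 0)

  # p = 0.3: 18 mismatches over 60 sites
  m1 <- strrep("AAAAAAAAAA", 6)
  m2 <- paste0(strrep("A", 42), strrep("C", 18))
  d <- jc_distance_matrix(make_aln(c(m1, m2)))
  expect_equal(unname(d[1, 2]), -0.75 * log(1 - 0.4 * 1), tolerance = 1e-12)
  expect_equal(unname(d[1, 2]), -0.75 * log(0.6), tolerance = 1e-12)

  # p = 0.75 exactly: saturation sentinel
  m3 <- paste0(strrep("A", 15), strrep("C", 15), strrep("G", 15), strrep("T", 15))
  m4 <- paste0(strrep("A", 15), strrep("G", 15), strrep("T", 15), strrep("C", 15))
  expect_warning(ds <- jc_distance_matrix(make_aln(c(m3, m4))), "saturated")
  expect_equal(unname(ds[1, 2]), 5.0)
})

test_that("NJ is exact on additive matrices and handles degenerate input", {
  # three taxa: unique topology, three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tr3 <- nj_tree(d3)
  pd <- ape::cophenetic.phylo(tr3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(pd, d3, tolerance = 1e-9)

  # random trees up to 12 tips: NJ recovers topology and path lengths
  set.seed(99)
  for (n in c(5, 8, 12)) {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.05
    dm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec)[[1]], 0)
    expect_equal(
      ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)], dm,
      tolerance = 1e-8
    )
  }

  # identical rows -> zero-length cherry, never negative lengths
  d <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0
  trz <- nj_tree(d)
  expect_true(all(trz$edge.length >= 0))
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("bootstrap supports are seeded and detect clear structure", {
  tr <- demo_equid_tree(scale = 3)
  mod <- site_class_model(rep("bg", 80), c(bg = 1), kappa = 2)
  aln <- simulate_codon_alignment(tr, mod, 80, seed = 17)
  b1 <- bootstrap_support(aln, n_reps = 100, seed = 5)
  b2 <- bootstrap_support(aln, n_reps = 100, seed = 5)
  expect_identical(b1$node.label, b2$node.label)
  # the caballine/non-caballine split is deeply divergent: recovered with
  # strong support
  caballines <- c("E_caballus", "E_przewalskii")
  expect_true(ape::is.monophyletic(b1, caballines))
  mrca <- ape::getMRCA(b1, caballines)
  sup <- b1$node.label[mrca - length(b1$tip.label)]
  expect_gte(as.numeric(sup), 95)

  inv <- make_aln(rep(strrep("ATGAAA", 10), 4))
  expect_warning(bs <- bootstrap_support(inv, n_reps = 20, seed = 1), "star-like")
  expect_true(attr(bs, "star_like"))
})

test_that("the JC69 pruning likelihood matches closed forms and phangorn", {
  # two identical 1-codon sequences joined by zero-length branches:
  # each site likelihood is 1/4
  a <- make_aln(c("AAA", "AAA"))
  tr <- ape::read.tree(text = "(s1:0,s2:0);")
  ll <- jc69_log_likelihood(a, tr)
  expect_equal(ll$site_log_likelihood, rep(log(0.25), 3))
  expect_equal(ll$log_likelihood, sum(ll$site_log_likelihood))

  set.seed(3)
  tr2 <- ape::unroot(ape::rtree(7))
  m <- oracle_jc_sim(tr2, 120, seed = 4)
  aln <- make_aln(apply(m, 1, paste0, collapse = ""), ids = rownames(m))
  mine <- jc69_log_likelihood(aln, tr2)
  fit <- phangorn::pml(tr2, phangorn::phyDat(tolower(m), type = "DNA"), model = "JC")
  expect_equal(mine$log_likelihood, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
  expect_equal(mine$log_likelihood, sum(mine$site_log_likelihood))

  # invariance under re-rooting (pulley principle)
  rerooted <- ape::unroot(ape::root(tr2, outgroup = tr2$tip.label[1], resolve.root = TRUE))
  expect_equal(
    jc69_log_likelihood(aln, rerooted)$log_likelihood,
    mine$log_likelihood,
    tolerance = 1e-8
  )
})

test_that("branch-length optimisation recovers simulated lengths", {
  tr <- ape::unroot(star_tree(6, 0.1))
  tr$edge.length <- c(0.05, 0.1, 0.15, 0.08, 0.12, 0.1)
  m <- oracle_jc_sim(tr, 2000, seed = 6)
  aln <- make_aln(apply(m, 1, paste0, collapse = ""), ids = rownames(m))
  start <- tr
  start$edge.length <- rep(0.05, length(tr$edge.length))
  fit <- optimize_branch_lengths(aln, start)
  expect_equal(fit$edge.length, tr$edge.length, tolerance = 0.2)
  # idempotence after convergence
  fit2 <- optimize_branch_lengths(aln, fit)
  expect_equal(attr(fit2, "logLik"), attr(fit, "logLik"), tolerance = 1e-4)
  expect_equal(fit2$edge.length, fit$edge.length, tolerance = 1e-3)

  # zero-variation alignment: all lengths collapse to ~0
  inv <- make_aln(rep(strrep("ATGAAA", 20), 4))
  trv <- ape::read.tree(text = "(s1:0.1,s2:0.1,s3:0.1,s4:0.1);")
  flat <- optimize_branch_lengths(inv, trv)
  expect_lt(max(flat$edge.length), 1e-4)
})
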