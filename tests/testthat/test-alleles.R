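cfg_dqb1 <- locus_config("DQB1", 269,
  primer_fwd = "CCTCTGGGGTAACGTTCCAG",
  primer_rev = "CGGCCTTGCTTTAGGTTTATC"
)
cfg_drb1 <- locus_config("DRB1", 260,
  primer_fwd = "TGACCGGATCCTTCCTGTAC",
  primer_rev = "GCGCTCACCTCGCCGAC"
)

test_that("demultiplexing is exact-prefix with clipping", {
  mids <- c(M1 = "ACGAGTGCGT", M2 = "ACGCTCGACA")
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(
      paste0(mids[["M1"]], "AAAA"),
      paste0(mids[["M2"]], "CCCC"),
      paste0("TCGAGTGCGT", "GGGG") # 1 mismatch in tag -> unmatched
    )
  )
  dem <- demultiplex(reads, mids)
  expect_equal(dem$mid, c("M1", "M2", "unmatched"))
  expect_equal(dem$sequence[1:2], c("AAAA", "CCCC"))
  expect_equal(dem$sequence[3], reads$sequence[3]) # unmatched left unclipped

  empty <- demultiplex(reads[0, ], mids)
  expect_equal(nrow(empty), 0L)

  expect_error(demultiplex(reads, c(M1 = "AAAA", M2 = "AAAA")), "duplicate")
  expect_error(demultiplex(reads, c(M1 = "AAAA", M2 = "AAAAC")), "non-prefix")
})

test_that("primer sorting assigns simulated reads to their true locus", {
  configs <- list(DQB1 = cfg_dqb1, DRB1 = cfg_drb1)
  allele <- strrep("ATGAAA", 10)
  r_dqb <- simulate_amplicon_reads(allele, 8, 0, c(M1 = "ACGAGTGCGT"), cfg_dqb1, seed = 1)
  r_drb <- simulate_amplicon_reads(allele, 8, 0, c(M1 = "ACGAGTGCGT"), cfg_drb1, seed = 2)
  dem <- demultiplex(dplyr::bind_rows(r_dqb, r_drb), c(M1 = "ACGAGTGCGT"))
  srt <- sort_by_primer(dem, configs)
  expect_equal(srt$locus[1:8], rep("DQB1", 8))
  expect_equal(srt$locus[9:16], rep("DRB1", 8))

  junk <- tibble::tibble(read_id = "x", sequence = strrep("T", 80))
  expect_equal(sort_by_primer(junk, configs)$locus, "unassigned")

  # identical references tie -> first locus in config order, logged
  tie_cfgs <- list(A = cfg_dqb1, B = cfg_dqb1)
  expect_message(
    tie <- sort_by_primer(dem[1, ], tie_cfgs),
    "tied"
  )
  expect_equal(tie$locus, "A")
})

test_that("primer trimming tolerates two mismatches and drops the rest", {
  allele <- strrep("ATGAAA", 10)
  reads <- simulate_amplicon_reads(allele, 3, 0, c(M1 = "ACGAGTGCGT"), cfg_dqb1, seed = 3)
  dem <- demultiplex(reads, c(M1 = "ACGAGTGCGT"))
  trimmed <- trim_primers(dem, cfg_dqb1)
  expect_equal(unique(trimmed$sequence), allele) # bare allele restored

  mutated <- dem
  substr(mutated$sequence[1], 1, 2) <- "TT" # 2 mismatches in fwd primer
  expect_equal(nrow(trim_primers(mutated, cfg_dqb1)), 3L)
  substr(mutated$sequence[1], 1, 4) <- "TTTT" # 3 mismatches -> dropped
  expect_message(out <- trim_primers(mutated, cfg_dqb1), "dropped")
  expect_equal(nrow(out), 2L)

  expect_equal(nrow(trim_primers(dem[0, ], cfg_dqb1)), 0L)
})

test_that("identity clustering separates alleles at the 0.99 cutoff", {
  base <- strrep("ACGTGA", 45) # 270 bp dummy amplicon body
  # second allele differing at 3 sites: 1 - 3/270 = 0.9889 < 0.99
  alt <- base
  substr(alt, 10, 10) <- "C" # T -> C
  substr(alt, 100, 100) <- "A" # T -> A
  substr(alt, 200, 200) <- "G" # C -> G
  reads <- tibble::tibble(
    read_id = paste0("r", 1:20),
    sequence = rep(c(base, alt), each = 10)
  )
  cl <- cluster_and_consensus(reads)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$consensus, c(base, alt))
  expect_equal(cl$size, c(10L, 10L))

  one <- cluster_and_consensus(tibble::tibble(
    read_id = paste0("r", 1:10), sequence = rep(base, 10)
  ))
  expect_equal(nrow(one), 1L)
  expect_equal(one$consensus, base)

  # singleton >= 1% divergent founds its own cluster
  noisy <- strrep("TTTTTT", 45)
  cl2 <- cluster_and_consensus(dplyr::bind_rows(
    reads, tibble::tibble(read_id = "noise", sequence = noisy)
  ))
  expect_equal(nrow(cl2), 3L)
  expect_equal(min(cl2$size), 1L)

  # deterministic under input permutation (canonical ordering)
  perm <- reads[sample.int(20), ]
  expect_identical(cluster_and_consensus(perm)$consensus, cl$consensus)
})

test_that("the two-independent-source rule decides validation", {
  cands <- tibble::tibble(
    species = "Equus caballus",
    locus = "DQB1",
    sequence = c("AAA", "AAA", "CCC", "GGG", "GGG"),
    source = c("PCR:runA", "PCR:runB", "PCR:runA", "PCR:runA", "Sanger:tr1")
  )
  out <- validate_alleles(cands)
  expect_setequal(out$sequence, c("AAA", "GGG")) # two PCRs / PCR + Sanger
  expect_equal(attr(out, "discarded")$sequence, "CCC") # single source
  expect_match(out$name, "^Eqca-DQB1\\*\\d{4}$")
  expect_equal(out$name, c("Eqca-DQB1*0001", "Eqca-DQB1*0002"))

  # same source seen twice is NOT two independent sources
  dup <- tibble::tibble(
    species = "Equus kiang", locus = "DRB1",
    sequence = "TTT", source = c("PCR:runA", "PCR:runA")
  )
  expect_equal(nrow(validate_alleles(dup)), 0L)

  empty <- validate_alleles(tibble::tibble())
  expect_equal(nrow(empty), 0L)
})

test_that("species codes follow the Klein-style convention", {
  expect_equal(
    species_code(c("Equus caballus", "Equus quagga burchellii", "Equus kiang")),
    c("Eqca", "Eqbu", "Eqki")
  )
})

test_that("the full allele pipeline recovers simulated truth sets", {
  cfg <- cfg_dqb1
  mids <- c(M1 = "ACGAGTGCGT")
  n_ok <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    # 2-4 true alleles, >= 5 pairwise differences over 269 bp
    n_all <- sample(2:4, 1)
    base <- paste0("TC", paste0(
      sample(equimhc::CODONS, 89, replace = TRUE),
      collapse = ""
    ))
    alleles <- vapply(seq_len(n_all), function(k) {
      a <- base
      pos <- sample(seq(3, 260), 6) + (k - 1) # distinct sites per allele
      for (p in pos) substr(a, p, p) <- sample(c("A", "C", "G", "T"), 1)
      a
    }, character(1))
    if (length(unique(alleles)) < n_all) next
    reads <- dplyr::bind_rows(
      simulate_amplicon_reads(alleles, 20, 0.003, mids, cfg, seed = s * 7, run = "run1"),
      simulate_amplicon_reads(alleles, 20, 0.003, mids, cfg, seed = s * 7 + 1, run = "run2")
    )
    called <- suppressMessages(call_alleles(
      reads, mids, list(DQB1 = cfg),
      species = c(M1 = "Equus caballus")
    ))
    if (setequal(called$sequence, alleles)) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_seeds, 0.95)
})
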