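# Seeded simulators: codon alignments under a site-class MG94xHKY-style
# process, recombinant alignments, decorated amplicon reads and per-base
# depth tracks. These generate inputs with the statistical structure the
# analysis assumes, so every stage is testable without external data.

#' Site-class codon substitution model
#'
#' An MG94xHKY-style codon process over the 61 sense codons: single
#' nucleotide exchanges only, transitions scaled by `kappa`, nonsynonymous
#' exchanges scaled by the site class's omega (dN/dS). Codon frequencies
#' default to uniform; stop codons have zero frequency by construction.
#' Rates are normalised so one unit of branch length equals one expected
#' substitution per codon under neutrality (omega = 1); classes with
#' omega > 1 evolve proportionally faster.
#'
#' @param class_of_codon Character/integer vector assigning each codon
#'   position to a class (e.g. `"background"` / `"abs"`).
#' @param omega_by_class Named numeric vector of omega >= 0 per class.
#' @param kappa Transition/transversion rate ratio >= 0 (default 2).
#' @param codon_frequencies Optional 61-vector over [CODONS] summing to 1.
#' @return A `site_class_model` object.
#' @export
site_class_model <- function(class_of_codon, omega_by_class, kappa = 2,
                             codon_frequencies = NULL) {
  stopifnot(kappa >= 0, all(omega_by_class >= 0))
  class_of_codon <- as.character(class_of_codon)
  if (!all(class_of_codon %in% names(omega_by_class))) {
    stop("every codon class needs an omega in `omega_by_class`", call. = FALSE)
  }
  if (is.null(codon_frequencies)) {
    codon_frequencies <- rep(1 / length(CODONS), length(CODONS))
  }
  stopifnot(length(codon_frequencies) == length(CODONS))
  if (abs(sum(codon_frequencies) - 1) > 1e-9) {
    stop("codon frequencies must sum to 1", call. = FALSE)
  }
  structure(
    list(
      class_of_codon = class_of_codon,
      omega_by_class = omega_by_class,
      kappa = kappa,
      codon_frequencies = stats::setNames(codon_frequencies, CODONS)
    ),
    class = "site_class_model"
  )
}

.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# Codon rate matrix for one omega; unscaled entries q_ij = kappa^[ts] *
# omega^[nonsyn] * pi_j for single-nucleotide neighbours.
.codon_Q <- function(omega, kappa, freqs) {
  n <- length(CODONS)
  Q <- matrix(0, n, n, dimnames = list(CODONS, CODONS))
  split_cod <- strsplit(CODONS, "")
  aa <- translate_codons(CODONS)
  for (i in seq_len(n)) {
    si <- split_cod[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      sj <- split_cod[[j]]
      dif <- which(si != sj)
      if (length(dif) != 1L) next
      r <- freqs[j]
      if (.is_transition(si[dif], sj[dif])) r <- r * kappa
      if (aa[i] != aa[j]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Transition probability matrices for each branch length, via symmetric
# eigendecomposition of the reversible generator.
.codon_pmats <- function(Q, freqs, lengths) {
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  lapply(lengths, function(t) {
    P <- diag(1 / d) %*% (eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))) %*% diag(d)
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

#' Simulate a codon alignment on a tree
#'
#' Codons evolve independently along the tree under the site-class model;
#' branch lengths are expected substitutions per codon at omega = 1.
#' Deterministic given `seed`; no stop codons can be produced.
#'
#' @param tree `phylo` tree with branch lengths and tip labels.
#' @param model A [site_class_model()].
#' @param n_codons Number of codons (must match `length(model$class_of_codon)`;
#'   a scalar model class is recycled).
#' @param seed Integer seed.
#' @return A [codon_alignment()] with attributes `site_class` (per-codon
#'   class) and `true_omega` (per-codon omega).
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, seed = 1L) {
  if (is.null(tree) || length(tree$tip.label) == 0L) {
    stop("empty tree", call. = FALSE)
  }
  stopifnot(n_codons >= 1L)
  classes <- rep_len(model$class_of_codon, n_codons)
  freqs <- model$codon_frequencies
  # neutral scale: expected substitutions per codon per unit branch length
  Q1 <- .codon_Q(1, model$kappa, freqs)
  scale <- -sum(freqs * diag(Q1))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ord <- stats::reorder(tree, "postorder")
  edge <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE] # preorder
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  root <- edge[1, 1]
  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(length(CODONS), n_codons, replace = TRUE, prob = freqs)
  for (cl in unique(classes)) {
    cols <- which(classes == cl)
    Q <- .codon_Q(model$omega_by_class[[cl]], model$kappa, freqs) / scale
    pmats <- .codon_pmats(Q, freqs, elen)
    for (k in seq_len(nrow(edge))) {
      parent <- edge[k, 1]
      child <- edge[k, 2]
      P <- pmats[[k]]
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(cols))
      pstate <- states[parent, cols]
      states[child, cols] <- max.col(cum[pstate, , drop = FALSE] >= u, "first")
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(s) {
    paste0(CODONS[s], collapse = "")
  })
  aln <- codon_alignment(
    tibble::tibble(
      id = tree$tip.label, species = tree$tip.label,
      locus = "SIM", sequence = seqs
    )
  )
  attr(aln, "site_class") <- classes
  attr(aln, "true_omega") <- unname(model$omega_by_class[classes])
  aln
}

#' Splice two alignments at a codon breakpoint
#'
#' Concatenates codon columns `1..breakpoint` of `aln_left` with columns
#' `(breakpoint+1)..end` of `aln_right` (matched by sequence ID), recording
#' the true breakpoint for test oracles. `breakpoint = 0` returns
#' `aln_right` unchanged.
#'
#' @param aln_left,aln_right [codon_alignment()]s sharing sequence IDs.
#' @param breakpoint Codon index in `[0, n_codons]`.
#' @return A [codon_alignment()] with attribute `true_breakpoint`.
#' @export
make_recombinant <- function(aln_left, aln_right, breakpoint) {
  if (!setequal(aln_left$id, aln_right$id)) {
    stop("alignments must share sequence IDs", call. = FALSE)
  }
  nl <- attr(aln_left, "aln_length") %/% 3L
  nr <- attr(aln_right, "aln_length") %/% 3L
  stopifnot(breakpoint >= 0L, breakpoint <= min(nl, nr))
  right <- aln_right[match(aln_left$id, aln_right$id), ]
  if (breakpoint == 0L) {
    out <- aln_right
  } else {
    seqs <- paste0(
      substr(aln_left$sequence, 1L, 3L * breakpoint),
      substr(right$sequence, 3L * breakpoint + 1L, 3L * nr)
    )
    out <- codon_alignment(tibble::tibble(
      id = aln_left$id, species = aln_left$species,
      locus = aln_left$locus, sequence = seqs
    ))
  }
  attr(out, "true_breakpoint") <- as.integer(breakpoint)
  out
}

#' Simulate decorated amplicon reads
#'
#' Each read is `MID + forward primer + allele + revcomp(reverse primer)`,
#' with i.i.d. substitution errors applied to the allele portion (errors
#' are substitutions only; indels are out of scope because identity
#' clustering, not gapped alignment, is under test). Provenance (true
#' allele and MID) is recorded per read.
#'
#' @param alleles Character vector of allele sequences (named or not).
#' @param copies_per_allele Reads per allele per MID.
#' @param error_rate Per-base substitution probability in `[0, 0.05)`.
#' @param mids Named character vector of MID tags.
#' @param config A [locus_config()] providing the primer pair.
#' @param seed Integer seed.
#' @param run Label recorded in the `run` column (a simulated PCR run).
#' @return Tibble with `read_id`, `run`, `mid` (true tag label),
#'   `true_allele`, `sequence`.
#' @export
simulate_amplicon_reads <- function(alleles, copies_per_allele, error_rate,
                                    mids, config, seed = 1L, run = "run1") {
  if (length(alleles) == 0L) stop("empty allele list", call. = FALSE)
  stopifnot(error_rate >= 0, error_rate < 0.05)
  if (is.null(names(alleles))) names(alleles) <- paste0("allele", seq_along(alleles))
  if (is.null(names(mids))) names(mids) <- paste0("M", seq_along(mids))
  set.seed(seed)
  rows <- list()
  rc_rev <- revcomp(config$primer_rev)
  for (tag in names(mids)) {
    for (al in names(alleles)) {
      for (k in seq_len(copies_per_allele)) {
        body <- strsplit(toupper(alleles[[al]]), "")[[1]]
        if (error_rate > 0) {
          hit <- which(stats::runif(length(body)) < error_rate)
          for (h in hit) {
            body[h] <- sample(setdiff(c("A", "C", "G", "T"), body[h]), 1L)
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          run = run, mid = tag, true_allele = al,
          sequence = paste0(
            mids[[tag]], config$primer_fwd,
            paste0(body, collapse = ""), rc_rev
          )
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$read_id <- sprintf("%s_read%05d", run, seq_len(nrow(out)))
  out[, c("read_id", "run", "mid", "true_allele", "sequence")]
}

#' Simulate a per-base depth track
#'
#' Present genes get Poisson(`mean_depth`) depth per base with a stated
#' fraction of positions dropped to zero; absent genes are constructed
#' with at least 90% zero-covered positions (sparse spurious
#' low-coverage noise on the rest).
#'
#' @param interval_length Interval length in bp.
#' @param present Logical: is the gene present?
#' @param mean_depth Mean depth for present genes.
#' @param dropout_fraction Fraction of positions zeroed for present genes.
#' @param seed Integer seed.
#' @param gene Gene label for the output.
#' @param noise_rate Per-base probability of spurious depth for absent
#'   genes (capped so the non-zero fraction stays below 0.10).
#' @return Tibble `gene`, `pos` (0-based), `depth`, with attribute
#'   `truth` (`"present"`/`"absent"`).
#' @export
simulate_depth_track <- function(interval_length, present, mean_depth = 20,
                                 dropout_fraction = 0, seed = 1L,
                                 gene = "gene", noise_rate = 0.02) {
  stopifnot(dropout_fraction >= 0, dropout_fraction <= 1, interval_length >= 1)
  set.seed(seed)
  if (present) {
    depth <- stats::rpois(interval_length, mean_depth)
    n_drop <- floor(dropout_fraction * interval_length)
    if (n_drop > 0) {
      depth[sample.int(interval_length, n_drop)] <- 0L
    }
  } else {
    depth <- integer(interval_length)
    max_noise <- max(0L, ceiling(0.09 * interval_length) - 1L)
    n_noise <- min(stats::rbinom(1L, interval_length, noise_rate), max_noise)
    if (n_noise > 0) {
      depth[sample.int(interval_length, n_noise)] <- sample(1:3, n_noise, replace = TRUE)
    }
  }
  out <- tibble::tibble(
    gene = gene, pos = seq_len(interval_length) - 1L,
    depth = as.integer(depth)
  )
  attr(out, "truth") <- if (present) "present" else "absent"
  out
}

#' A fixed 12-tip equid-like demonstration topology
#'
#' Caballine clade versus non-caballine ass and zebra clades, with
#' moderate branch lengths (expected substitutions per codon). A fixture
#' for simulations, not a claim about the true equid tree.
#'
#' @param scale Multiplier applied to all branch lengths (default 1).
#' @return Unrooted `phylo` tree.
#' @export
demo_equid_tree <- function(scale = 1) {
  nwk <- paste0(
    "((E_caballus:0.02,E_przewalskii:0.02):0.10,",
    "((E_asinus:0.03,E_somaliensis:0.03):0.04,",
    "(E_kiang:0.03,(E_onager:0.02,E_kulan:0.02):0.02):0.04):0.05,",
    "((E_grevyi:0.04,E_zebra:0.04):0.03,",
    "(E_burchellii:0.02,(E_boehmi:0.015,E_chapmani:0.015):0.01):0.04):0.05);"
  )
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * scale
  ape::unroot(tr)
}

#' Write reads as FASTA
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  write_alignment(tibble::tibble(id = reads$read_id, sequence = reads$sequence), path)
}
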