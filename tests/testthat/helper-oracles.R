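# Independent oracles and fixture builders shared across tests.
# These deliberately re-derive quantities by brute force, without reusing
# the package's internal lookup tables or code paths.

.oracle_code <- local({
  nuc <- c("T", "C", "A", "G")
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  cods <- apply(expand.grid(p3 = nuc, p2 = nuc, p1 = nuc)[, 3:1], 1, paste0, collapse = "")
  stats::setNames(aa, cods)
})

oracle_is_stop <- function(codon) .oracle_code[[codon]] == "*"

# Direct enumeration of the per-codon synonymous site count: at each
# position, the synonymous fraction among the non-stop single-base changes.
oracle_syn_sites <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    outcomes <- c()
    for (b in setdiff(c("T", "C", "A", "G"), s[pos])) {
      t <- s
      t[pos] <- b
      mut <- paste0(t, collapse = "")
      if (oracle_is_stop(mut)) next
      outcomes <- c(outcomes, .oracle_code[[mut]] == .oracle_code[[codon]])
    }
    if (length(outcomes)) total <- total + mean(outcomes)
  }
  total
}

# Recursive (depth-first) enumeration of all minimal substitution
# pathways between two codons; pathways through stop codons are skipped,
# with fallback to all pathways when none is stop-free.
oracle_pair_diff <- function(c1, c2) {
  walk <- function(cur, target, allow_stop) {
    dif <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(dif) == 0L) {
      return(list(c(syn = 0, non = 0)))
    }
    paths <- list()
    for (pos in dif) {
      s <- strsplit(cur, "")[[1]]
      s[pos] <- strsplit(target, "")[[1]][pos]
      nxt <- paste0(s, collapse = "")
      if (!allow_stop && oracle_is_stop(nxt) && nxt != target) next
      step <- if (.oracle_code[[cur]] == .oracle_code[[nxt]]) {
        c(syn = 1, non = 0)
      } else {
        c(syn = 0, non = 1)
      }
      for (tail in walk(nxt, target, allow_stop)) {
        paths[[length(paths) + 1L]] <- step + tail
      }
    }
    paths
  }
  paths <- walk(c1, c2, allow_stop = FALSE)
  if (length(paths) == 0L) paths <- walk(c1, c2, allow_stop = TRUE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "syn"]), nd = mean(m[, "non"]))
}

# Brute-force column statistics for VNP / PIP.
oracle_column_stats <- function(mat, drop_gap_cols = TRUE) {
  gapch <- c("-", "N")
  if (drop_gap_cols) {
    mat <- mat[, colSums(matrix(mat %in% gapch, nrow(mat))) == 0, drop = FALSE]
  }
  vnp <- 0L
  pip <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!(col %in% gapch)]
    tb <- table(col)
    if (length(tb) >= 2L) vnp <- vnp + 1L
    if (sum(tb >= 2L) >= 2L) pip <- pip + 1L
  }
  c(vnp = vnp, pip = pip)
}

# Star phylogeny with n tips of the given terminal length.
star_tree <- function(n, tip_len) {
  ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(n), ":", tip_len, collapse = ","), ");"
  ))
}

# Tiny helper: codon alignment from bare sequence strings.
make_aln <- function(seqs, ids = NULL, gap_policy = "complete", frame_offset = 0L) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  codon_alignment(
    tibble::tibble(id = ids, sequence = seqs),
    frame_offset = frame_offset, gap_policy = gap_policy
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent JC69 simulator on a tree (nucleotide level), for
# branch-length recovery tests: evolves independent sites with the exact
# JC transition matrix. Returns a character matrix.
oracle_jc_sim <- function(tree, n_sites, seed) {
  set.seed(seed)
  nuc <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  ord <- stats::reorder(tree, "postorder")
  edge <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  states <- matrix(NA_integer_, ntip + tree$Nnode, n_sites)
  states[edge[1, 1], ] <- sample.int(4L, n_sites, replace = TRUE)
  for (k in seq_len(nrow(edge))) {
    p_same <- 0.25 + 0.75 * exp(-4 * elen[k] / 3)
    stay <- stats::runif(n_sites) < p_same
    new <- states[edge[k, 1], ]
    switchers <- which(!stay)
    for (i in switchers) {
      new[i] <- sample(setdiff(1:4, new[i]), 1L)
    }
    states[edge[k, 2], ] <- new
  }
  m <- matrix(nuc[states[seq_len(ntip), ]], ntip, n_sites)
  rownames(m) <- tree$tip.label
  m
}
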