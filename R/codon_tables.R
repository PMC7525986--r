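# Genetic-code constants and Nei-Gojobori (1986) codon-pair bookkeeping.
# Everything here is precomputed once at load: per-codon synonymous site
# fractions and pathway-averaged synonymous/nonsynonymous difference counts
# for all 61 x 61 sense-codon pairs.

NUC <- c("T", "C", "A", "G")

# Standard genetic code, codons enumerated T/C/A/G at positions 1..3
# (TTT, TTC, TTA, TTG, TCT, ...). "*" marks stop codons.
.aa64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  ""
)[[1]]
.codons64 <- apply(expand.grid(p3 = NUC, p2 = NUC, p1 = NUC)[, 3:1], 1, paste0, collapse = "")
GENETIC_CODE <- stats::setNames(.aa64, .codons64)

#' The 61 sense codons of the universal genetic code
#'
#' Codons are enumerated with T, C, A, G nesting at positions 1 to 3;
#' this ordering is also the deterministic tie-break order used by the
#' parsimony reconstruction.
#' @format Character vector of length 61.
#' @export
CODONS <- .codons64[.aa64 != "*"]

STOP_CODONS <- .codons64[.aa64 == "*"]

#' Translate in-frame codons to amino acids
#'
#' @param codons Character vector of 3-letter codons (A/C/G/T). Codons
#'   containing gaps or N translate to `NA`.
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  unname(GENETIC_CODE[toupper(codons)])
}

.codon_neighbours <- function(codon) {
  # all 9 single-nucleotide mutational targets of a codon
  out <- character(0)
  s <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(NUC, s[pos])) {
      t <- s
      t[pos] <- b
      out <- c(out, paste0(t, collapse = ""))
    }
  }
  out
}

# Per-position synonymous site fraction for one codon. At each position the
# three possible nucleotide changes are examined; changes creating a stop
# codon are excluded from the mutational target set, and the synonymous
# fraction is taken over the remaining targets, so that S + N = 3 per codon.
.codon_syn_sites <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  aa <- GENETIC_CODE[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0L
    valid <- 0L
    for (b in setdiff(NUC, s[pos])) {
      t <- s
      t[pos] <- b
      taa <- GENETIC_CODE[[paste0(t, collapse = "")]]
      if (taa == "*") next
      valid <- valid + 1L
      if (taa == aa) syn <- syn + 1L
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# Pathway-averaged synonymous/nonsynonymous differences between two sense
# codons. All orderings of the differing positions are enumerated; orderings
# passing through a stop codon are dropped. If every ordering hits a stop,
# all orderings are used (documented fallback; endpoints are never stops).
.codon_pair_diff <- function(c1, c2) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(s1 != s2)
  nd <- length(diff_pos)
  if (nd == 0L) {
    return(c(sd = 0, nd = 0))
  }
  perms <- if (nd == 1L) {
    list(diff_pos)
  } else if (nd == 2L) {
    list(diff_pos, rev(diff_pos))
  } else {
    lapply(
      list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
      function(o) diff_pos[o]
    )
  }
  step_counts <- function(order) {
    cur <- s1
    syn <- 0
    non <- 0
    ok <- TRUE
    for (pos in order) {
      aa_from <- GENETIC_CODE[[paste0(cur, collapse = "")]]
      cur[pos] <- s2[pos]
      nxt <- paste0(cur, collapse = "")
      aa_to <- GENETIC_CODE[[nxt]]
      if (aa_to == "*") ok <- FALSE
      if (identical(aa_from, aa_to)) syn <- syn + 1 else non <- non + 1
    }
    list(syn = syn, non = non, ok = ok)
  }
  res <- lapply(perms, step_counts)
  keep <- vapply(res, function(r) r$ok, logical(1))
  if (!any(keep)) keep <- rep(TRUE, length(res))
  res <- res[keep]
  c(
    sd = mean(vapply(res, function(r) r$syn, numeric(1))),
    nd = mean(vapply(res, function(r) r$non, numeric(1)))
  )
}

# Lazily-built lookup tables (computed once per session).
.ng_cache <- new.env(parent = emptyenv())

.ng_tables <- function() {
  if (is.null(.ng_cache$syn_sites)) {
    syn <- vapply(CODONS, .codon_syn_sites, numeric(1))
    n <- length(CODONS)
    sd <- matrix(0, n, n, dimnames = list(CODONS, CODONS))
    nd <- matrix(0, n, n, dimnames = list(CODONS, CODONS))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        d <- .codon_pair_diff(CODONS[i], CODONS[j])
        sd[i, j] <- sd[j, i] <- d[["sd"]]
        nd[i, j] <- nd[j, i] <- d[["nd"]]
      }
    }
    .ng_cache$syn_sites <- syn
    .ng_cache$pair_sd <- sd
    .ng_cache$pair_nd <- nd
  }
  list(
    syn_sites = .ng_cache$syn_sites,
    pair_sd = .ng_cache$pair_sd,
    pair_nd = .ng_cache$pair_nd
  )
}

# Split a sequence string into codons; returns character vector.
.to_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
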