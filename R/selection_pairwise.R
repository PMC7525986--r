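# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction, and the
# codon-based Z-test of positive selection (dN > dS) with bootstrap
# variance over codon sites.

# Integer codon-index matrix (n_seq x n_codons); NA for codons containing
# gaps/N and for stop codons (stop codons never enter rate computations).
.aln_codon_idx <- function(aln) {
  seqs <- aln$sequence
  n_cod <- attr(aln, "aln_length") %/% 3L
  idx <- matrix(NA_integer_, nrow(aln), n_cod, dimnames = list(aln$id, NULL))
  for (i in seq_len(nrow(aln))) {
    idx[i, ] <- match(.to_codons(seqs[[i]]), CODONS)
  }
  idx
}

# Drop codon columns containing any gap/N among the given rows
# (complete-deletion policy at codon resolution).
.complete_codon_cols <- function(idx) {
  which(colSums(is.na(idx)) == 0L)
}

.jc_rate <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Nei-Gojobori pairwise synonymous/nonsynonymous rates
#'
#' Synonymous site fractions come from the universal genetic code with
#' changes to stop codons excluded from the mutational target set;
#' differences between codons are averaged over all minimal substitution
#' pathways, excluding pathways through stop codons. The Jukes-Cantor
#' correction `d = -(3/4) ln(1 - (4/3) p)` is applied to both proportions.
#' Codons containing gaps or N in either sequence are skipped.
#'
#' @param seq1,seq2 Equal-length in-frame nucleotide strings (length a
#'   multiple of 3, no internal stop codons).
#' @return One-row tibble with `S`, `N` (site counts), `Sd`, `Nd`
#'   (difference counts), `pS`, `pN`, `dS`, `dN` and a `saturated` flag
#'   (`TRUE` when a proportion reached 0.75 and the rate is undefined).
#' @export
ng86_pair <- function(seq1, seq2) {
  seq1 <- toupper(seq1)
  seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequence length mismatch", call. = FALSE)
  if (nchar(seq1) %% 3L != 0L) stop("length not a multiple of 3", call. = FALSE)
  c1 <- .to_codons(seq1)
  c2 <- .to_codons(seq2)
  internal1 <- c1[-length(c1)]
  internal2 <- c2[-length(c2)]
  if (any(internal1 %in% STOP_CODONS) || any(internal2 %in% STOP_CODONS)) {
    stop("internal stop codon; exclude such sequences from selection analyses",
      call. = FALSE
    )
  }
  i1 <- match(c1, CODONS)
  i2 <- match(c2, CODONS)
  ok <- !is.na(i1) & !is.na(i2)
  tabs <- .ng_tables()
  S <- sum((tabs$syn_sites[i1[ok]] + tabs$syn_sites[i2[ok]]) / 2)
  N <- 3 * sum(ok) - S
  Sd <- sum(tabs$pair_sd[cbind(i1[ok], i2[ok])])
  Nd <- sum(tabs$pair_nd[cbind(i1[ok], i2[ok])])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  tibble::tibble(
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = .jc_rate(pS), dN = .jc_rate(pN),
    saturated = is.na(.jc_rate(pS)) || is.na(.jc_rate(pN))
  )
}

# Per-pair, per-codon NG86 components over an alignment.
# Returns list of matrices (npair x ncodon): s_sites, n_sites, sd, nd and a
# validity mask, plus the pair index tibble.
.pair_component_arrays <- function(idx) {
  tabs <- .ng_tables()
  n <- nrow(idx)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  nc <- ncol(idx)
  s_sites <- matrix(0, np, nc)
  sd_m <- matrix(0, np, nc)
  nd_m <- matrix(0, np, nc)
  valid <- matrix(FALSE, np, nc)
  syn <- tabs$syn_sites
  for (k in seq_len(np)) {
    a <- idx[pairs[1, k], ]
    b <- idx[pairs[2, k], ]
    ok <- !is.na(a) & !is.na(b)
    valid[k, ] <- ok
    s_sites[k, ok] <- (syn[a[ok]] + syn[b[ok]]) / 2
    sd_m[k, ok] <- tabs$pair_sd[cbind(a[ok], b[ok])]
    nd_m[k, ok] <- tabs$pair_nd[cbind(a[ok], b[ok])]
  }
  list(
    s_sites = s_sites, sd = sd_m, nd = nd_m, valid = valid,
    pair_i = pairs[1, ], pair_j = pairs[2, ]
  )
}

# Mean (over pairs) dN and dS given codon-column weights w (bootstrap
# counts or all-ones). Pairs whose rates are undefined are dropped.
.mean_rates <- function(arr, w) {
  S <- arr$s_sites %*% w
  n_cod <- arr$valid %*% w
  N <- 3 * n_cod - S
  Sd <- arr$sd %*% w
  Nd <- arr$nd %*% w
  pS <- ifelse(S > 0, Sd / S, 0)
  pN <- ifelse(N > 0, Nd / N, 0)
  dS <- .jc_rate(pS)
  dN <- .jc_rate(pN)
  c(dN = mean(dN, na.rm = TRUE), dS = mean(dS, na.rm = TRUE))
}

#' Codon-based Z-test of positive selection
#'
#' dN and dS are averaged over all sequence pairs (NG86 counting, JC
#' correction); the variance of the mean difference is estimated by
#' bootstrap over codon sites; the one-tailed alternative is positive
#' selection (dN > dS). Sequences flagged with internal stop codons are
#' excluded. Degenerate alignments (no variation, or zero bootstrap
#' standard error) return p = 1.
#'
#' @param aln A [codon_alignment()].
#' @param n_boot Bootstrap replicates for the variance (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `equimhc_ztest` with elements `statistic`
#'   (the Z statistic), `mean_dN_minus_dS`, `dN`, `dS`, `se`,
#'   `p_one_tailed`, `n_seq`, `n_codons`, `n_boot`, `seed`.
#' @export
global_z_test <- function(aln, n_boot = 1000L, seed = 1L) {
  keep <- !aln$has_stop
  if (sum(keep) < 2L) stop("need >= 2 sequences without internal stops", call. = FALSE)
  sub <- aln[keep, ]
  attr(sub, "aln_length") <- attr(aln, "aln_length")
  idx <- .aln_codon_idx(sub)
  if ((attr(aln, "gap_policy") %||% "complete") == "complete") {
    idx <- idx[, .complete_codon_cols(idx), drop = FALSE]
  }
  nc <- ncol(idx)
  if (nc == 0L) stop("no analyzable codons", call. = FALSE)
  arr <- .pair_component_arrays(idx)
  w1 <- rep(1, nc)
  point <- .mean_rates(arr, w1)
  diff_hat <- point[["dN"]] - point[["dS"]]
  set.seed(seed)
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
    r <- .mean_rates(arr, w)
    boots[b] <- r[["dN"]] - r[["dS"]]
  }
  se <- stats::sd(boots, na.rm = TRUE)
  if (!is.finite(se) || se == 0 || !is.finite(diff_hat)) {
    z <- 0
    p <- 1
    se <- if (is.finite(se)) se else 0
  } else {
    z <- diff_hat / se
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  structure(
    list(
      statistic = z, mean_dN_minus_dS = diff_hat,
      dN = point[["dN"]], dS = point[["dS"]], se = se,
      p_one_tailed = p, n_seq = nrow(sub), n_codons = nc,
      n_boot = n_boot, seed = seed
    ),
    class = "equimhc_ztest"
  )
}

#' @export
print.equimhc_ztest <- function(x, ...) {
  cat("Codon-based Z-test of positive selection (dN > dS)\n")
  cat(sprintf(
    "  sequences: %d  codons: %d  bootstrap reps: %d\n",
    x$n_seq, x$n_codons, x$n_boot
  ))
  cat(sprintf(
    "  mean dN = %.4f  mean dS = %.4f  dN - dS = %.4f\n",
    x$dN, x$dS, x$mean_dN_minus_dS
  ))
  cat(sprintf("  Z = %.3f  one-tailed p = %.3f\n", x$statistic, x$p_one_tailed))
  invisible(x)
}

#' @export
tidy.equimhc_ztest <- function(x, ...) {
  tibble::tibble(
    term = "dN - dS",
    estimate = x$mean_dN_minus_dS,
    statistic = x$statistic,
    std.error = x$se,
    p.value = x$p_one_tailed
  )
}

#' @export
glance.equimhc_ztest <- function(x, ...) {
  tibble::tibble(
    dN = x$dN, dS = x$dS, statistic = x$statistic,
    p.value = x$p_one_tailed, n_seq = x$n_seq, n_codons = x$n_codons,
    n_boot = x$n_boot, seed = x$seed
  )
}
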