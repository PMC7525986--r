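# Single-breakpoint recombination screen.
#
# The full alignment is fitted with one NJ topology (ML branch lengths
# under JC69); every candidate codon-boundary breakpoint is fitted with
# two independent per-partition trees. Fits are compared by the
# small-sample Akaike information criterion
#   cAIC = -2 lnL + 2k + 2k(k+1)/(n - k - 1),
# with k the number of branch lengths plus one bookkeeping parameter per
# tree topology and n the number of nucleotide sites. Recombination is
# declared iff the best two-partition cAIC undercuts the single-tree cAIC
# (delta cAIC < 0); no secondary significance test.

.caic <- function(lnl, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * lnl + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# NJ topology + ML branch lengths on a sub-alignment; returns lnL and k.
.fit_partition <- function(aln) {
  m <- aln_matrix(aln)
  d <- .jc_from_matrix(m)
  tr <- nj_tree(d)
  tr <- optimize_branch_lengths(aln, tr)
  list(
    tree = tr,
    lnl = attr(tr, "logLik"),
    k = nrow(tr$edge) + 1L # +1 per-tree topology bookkeeping
  )
}

#' Split a codon alignment at a codon boundary
#'
#' @param aln A [codon_alignment()].
#' @param breakpoint Codon index in `[1, n_codons - 1]`; the left partition
#'   holds codons `1..breakpoint`.
#' @return List with elements `left` and `right`, both codon alignments
#'   retaining the input metadata.
#' @export
partition_alignment <- function(aln, breakpoint) {
  n_cod <- attr(aln, "aln_length") %/% 3L
  breakpoint <- as.integer(breakpoint)
  if (is.na(breakpoint) || breakpoint < 1L || breakpoint >= n_cod) {
    stop("breakpoint must be in [1, ", n_cod - 1L, "]", call. = FALSE)
  }
  mk <- function(from, to) {
    codon_alignment(
      tibble::tibble(
        id = aln$id, species = aln$species, locus = aln$locus,
        sequence = substr(aln$sequence, from, to)
      ),
      gap_policy = attr(aln, "gap_policy")
    )
  }
  list(
    left = mk(1L, 3L * breakpoint),
    right = mk(3L * breakpoint + 1L, attr(aln, "aln_length"))
  )
}

#' Single-breakpoint recombination scan with cAIC
#'
#' @param aln A [codon_alignment()] with >= 4 sequences and at least
#'   `2 * min_partition` codons.
#' @param min_partition Minimum partition size in codons (default 10).
#' @param grid_step Candidate breakpoint spacing in codons (default 1).
#'   With `grid_step > 1` the best grid point is refined by a +/- step
#'   local search.
#' @return Object of class `sbp_scan`: `best_breakpoint` (codon boundary,
#'   or `NA` when the single tree wins), `caic_single`,
#'   `caic_two_partition`, `delta_caic` (two-partition minus single;
#'   negative means recombination declared), `recombination` flag and the
#'   per-candidate `trace` tibble.
#' @export
sbp_scan <- function(aln, min_partition = 10L, grid_step = 1L) {
  n_cod <- attr(aln, "aln_length") %/% 3L
  if (nrow(aln) < 4L) {
    stop("recombination scan needs >= 4 sequences (no alternative topologies otherwise)",
      call. = FALSE
    )
  }
  if (n_cod < 2L * min_partition) {
    stop("alignment too short: need >= ", 2L * min_partition, " codons", call. = FALSE)
  }
  n_sites <- attr(aln, "aln_length")
  single <- .fit_partition(aln)
  caic_single <- .caic(single$lnl, single$k, n_sites)
  eval_bp <- function(b) {
    parts <- partition_alignment(aln, b)
    fl <- .fit_partition(parts$left)
    fr <- .fit_partition(parts$right)
    tibble::tibble(
      breakpoint = b,
      lnl = fl$lnl + fr$lnl,
      k = fl$k + fr$k,
      caic = .caic(fl$lnl + fr$lnl, fl$k + fr$k, n_sites)
    )
  }
  grid <- seq(min_partition, n_cod - min_partition, by = grid_step)
  trace <- purrr::map_dfr(grid, eval_bp)
  if (grid_step > 1L) {
    best0 <- trace$breakpoint[which.min(trace$caic)]
    extra <- setdiff(
      seq(max(min_partition, best0 - grid_step + 1L),
        min(n_cod - min_partition, best0 + grid_step - 1L)
      ),
      trace$breakpoint
    )
    if (length(extra)) trace <- dplyr::bind_rows(trace, purrr::map_dfr(extra, eval_bp))
    trace <- dplyr::arrange(trace, .data$breakpoint)
  }
  ibest <- which.min(trace$caic)
  caic_two <- trace$caic[ibest]
  delta <- caic_two - caic_single
  structure(
    list(
      best_breakpoint = if (delta < 0) trace$breakpoint[ibest] else NA_integer_,
      argmin_breakpoint = trace$breakpoint[ibest],
      caic_single = caic_single,
      caic_two_partition = caic_two,
      delta_caic = delta,
      recombination = delta < 0,
      n_sites = n_sites,
      trace = trace
    ),
    class = "sbp_scan"
  )
}

#' @export
print.sbp_scan <- function(x, ...) {
  cat("Single-breakpoint recombination scan (cAIC)\n")
  cat(sprintf(
    "  single tree cAIC = %.2f; best two-partition cAIC = %.2f at codon %d\n",
    x$caic_single, x$caic_two_partition, x$argmin_breakpoint
  ))
  cat(sprintf(
    "  delta cAIC = %.2f -> %s\n", x$delta_caic,
    if (x$recombination) {
      paste0("recombination declared (breakpoint ", x$best_breakpoint, ")")
    } else {
      "no recombination"
    }
  ))
  invisible(x)
}

#' @export
tidy.sbp_scan <- function(x, ...) x$trace

#' @export
glance.sbp_scan <- function(x, ...) {
  tibble::tibble(
    best_breakpoint = x$best_breakpoint,
    caic_single = x$caic_single,
    caic_two_partition = x$caic_two_partition,
    delta_caic = x$delta_caic,
    recombination = x$recombination,
    n_sites = x$n_sites
  )
}
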