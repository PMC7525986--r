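# Site-wise selection: a counting method (parsimony ancestral states +
# NG86 change decomposition + binomial test, SLAC-style) and a per-site
# two-rate likelihood method (MG94xJC on a fixed tree with LRT of
# beta = alpha, FEL-style), combined by the two-method consensus rule.

.DEFAULT_SITE_P <- 0.1

# ---- shared tree bookkeeping -------------------------------------------

.tree_struct <- function(tree, ids) {
  if (!all(tree$tip.label %in% ids)) {
    stop("tree/alignment mismatch: tips missing from alignment", call. = FALSE)
  }
  ord <- stats::reorder(tree, "postorder")
  list(
    edge = ord$edge, elen = ord$edge.length,
    ntip = length(ord$tip.label), nnode = length(ord$tip.label) + ord$Nnode,
    tips = ord$tip.label, root = ord$edge[nrow(ord$edge), 1]
  )
}

# ---- SLAC-style counting ------------------------------------------------

# Fitch parsimony assignment of codon states (61-state) for one site.
# `tipstate` is an integer vector over ts$tips (NA = missing -> full set).
# Ties resolved deterministically to the first codon in codon order.
.fitch_site <- function(tipstate, ts) {
  nset <- matrix(FALSE, ts$nnode, length(CODONS))
  for (i in seq_len(ts$ntip)) {
    if (is.na(tipstate[i])) nset[i, ] <- TRUE else nset[i, tipstate[i]] <- TRUE
  }
  seen <- logical(ts$nnode)
  for (k in seq_len(nrow(ts$edge))) {
    parent <- ts$edge[k, 1]
    child <- ts$edge[k, 2]
    if (!seen[parent]) {
      nset[parent, ] <- nset[child, ]
      seen[parent] <- TRUE
    } else {
      inter <- nset[parent, ] & nset[child, ]
      nset[parent, ] <- if (any(inter)) inter else nset[parent, ] | nset[child, ]
    }
  }
  assign <- integer(ts$nnode)
  assign[ts$root] <- which(nset[ts$root, ])[1]
  for (k in rev(seq_len(nrow(ts$edge)))) { # preorder
    parent <- ts$edge[k, 1]
    child <- ts$edge[k, 2]
    assign[child] <- if (nset[child, assign[parent]]) {
      assign[parent]
    } else {
      which(nset[child, ])[1]
    }
  }
  assign
}

# Continuous extension of the binomial tail P(X >= k) for fractional k,
# via the regularised incomplete beta function.
.binom_surv <- function(k, n, p) {
  if (n <= 0) return(1)
  if (k <= 0) return(1)
  if (k > n) k <- n
  stats::pbeta(p, k, n - k + 1)
}

#' SLAC-style per-site selection counts
#'
#' Ancestral codons are reconstructed by Fitch parsimony (ties to the
#' first codon in codon order); codon changes along branches are
#' decomposed into synonymous and nonsynonymous fractions by NG86 pathway
#' averaging; the observed nonsynonymous count at each site is compared
#' with its neutral expectation (from the site's synonymous site fraction)
#' by a binomial test.
#'
#' @param aln A [codon_alignment()] (stop-flagged sequences are excluded).
#' @param tree `phylo` tree over the alignment's sequence IDs.
#' @param p_threshold Site-level significance threshold (default 0.1).
#' @return Tibble with one row per codon: `codon`, `sd`, `nd` (inferred
#'   synonymous/nonsynonymous changes), `exp_nonsyn_frac`, `p_pos`,
#'   `p_neg`, `p` (two-tailed), `class` in `positive`/`negative`/`none`.
#' @export
slac_sites <- function(aln, tree, p_threshold = .DEFAULT_SITE_P) {
  sub <- aln[!aln$has_stop, ]
  attr(sub, "aln_length") <- attr(aln, "aln_length")
  ts <- .tree_struct(tree, sub$id)
  idx <- .aln_codon_idx(sub)[ts$tips, , drop = FALSE]
  tabs <- .ng_tables()
  n_cod <- ncol(idx)
  out <- vector("list", n_cod)
  for (s in seq_len(n_cod)) {
    tipstate <- idx[, s]
    obs <- tipstate[!is.na(tipstate)]
    if (length(unique(obs)) <= 1L) {
      out[[s]] <- tibble::tibble(
        codon = s, sd = 0, nd = 0, exp_nonsyn_frac = NA_real_,
        p_pos = 1, p_neg = 1, p = 1, class = "none"
      )
      next
    }
    assign <- .fitch_site(tipstate, ts)
    sd <- nd <- 0
    for (k in seq_len(nrow(ts$edge))) {
      a <- assign[ts$edge[k, 1]]
      b <- assign[ts$edge[k, 2]]
      if (a != b) {
        sd <- sd + tabs$pair_sd[a, b]
        nd <- nd + tabs$pair_nd[a, b]
      }
    }
    s_sites <- mean(tabs$syn_sites[obs])
    p_n <- (3 - s_sites) / 3
    n_tot <- sd + nd
    p_pos <- .binom_surv(nd, n_tot, p_n) # excess nonsynonymous
    p_neg <- .binom_surv(sd, n_tot, 1 - p_n) # excess synonymous
    p2 <- min(1, 2 * min(p_pos, p_neg))
    cls <- "none"
    if (n_tot > 0) {
      if (nd / n_tot > p_n && p_pos <= p_threshold) cls <- "positive"
      if (nd / n_tot < p_n && p_neg <= p_threshold) cls <- "negative"
    }
    out[[s]] <- tibble::tibble(
      codon = s, sd = sd, nd = nd, exp_nonsyn_frac = p_n,
      p_pos = p_pos, p_neg = p_neg, p = p2, class = cls
    )
  }
  dplyr::bind_rows(out)
}

# ---- FEL-style per-site likelihood -------------------------------------

# Unscaled synonymous / nonsynonymous generator parts (uniform codon
# frequencies, JC nucleotide level): Q(alpha, beta) = alpha Qs + beta Qn.
.fel_cache <- new.env(parent = emptyenv())

.fel_parts <- function() {
  if (is.null(.fel_cache$Qs)) {
    n <- length(CODONS)
    Qs <- matrix(0, n, n)
    Qn <- matrix(0, n, n)
    split_cod <- strsplit(CODONS, "")
    aa <- translate_codons(CODONS)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        dif <- sum(split_cod[[i]] != split_cod[[j]])
        if (dif != 1L) next
        if (aa[i] == aa[j]) Qs[i, j] <- 1 else Qn[i, j] <- 1
      }
    }
    diag(Qs) <- -rowSums(Qs)
    diag(Qn) <- -rowSums(Qn)
    .fel_cache$Qs <- Qs
    .fel_cache$Qn <- Qn
  }
  list(Qs = .fel_cache$Qs, Qn = .fel_cache$Qn)
}

# Eigendecomposition of Qs + omega Qn (symmetric under uniform freqs).
.fel_eig <- function(omega) {
  parts <- .fel_parts()
  eigen(parts$Qs + omega * parts$Qn, symmetric = TRUE)
}

# Site log-likelihood in the eigenbasis: Q = rate * (Qs + omega Qn);
# tipstates integer (NA = missing). Uniform root frequencies (1/61).
.fel_site_loglik <- function(tipstate, ts, eig, rate) {
  n <- length(CODONS)
  U <- eig$vectors
  lam <- eig$values
  partial <- vector("list", ts$nnode)
  for (i in seq_len(ts$ntip)) {
    v <- if (is.na(tipstate[i])) rep(1, n) else {
      z <- numeric(n)
      z[tipstate[i]] <- 1
      z
    }
    partial[[i]] <- v
  }
  scale_log <- 0
  for (k in seq_len(nrow(ts$edge))) {
    parent <- ts$edge[k, 1]
    child <- ts$edge[k, 2]
    d <- exp(pmax(lam * rate * ts$elen[k], -700))
    msg <- U %*% (d * crossprod(U, partial[[child]]))
    msg[msg < 0] <- 0
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- as.vector(msg)
    } else {
      partial[[parent]] <- partial[[parent]] * as.vector(msg)
    }
    mx <- max(partial[[parent]])
    if (mx > 0 && mx < 1e-280) {
      partial[[parent]] <- partial[[parent]] / mx
      scale_log <- scale_log + log(mx)
    }
  }
  l <- sum(partial[[ts$root]]) / n
  if (l <= 0) return(-1e10)
  log(l) + scale_log
}

#' FEL-style per-site likelihood test of selection
#'
#' For each codon site, a two-rate MG94xJC site model (synonymous rate
#' alpha, nonsynonymous rate beta) is maximised on the fixed tree and
#' compared with the one-rate null (beta = alpha) by a likelihood ratio
#' test (1 df chi-squared). Invariant sites return `alpha = beta = 0`,
#' `p = 1`.
#'
#' @inheritParams slac_sites
#' @return Tibble per codon: `codon`, `alpha`, `beta`, `lrt`, `p`, `class`.
#' @export
fel_sites <- function(aln, tree, p_threshold = .DEFAULT_SITE_P) {
  sub <- aln[!aln$has_stop, ]
  attr(sub, "aln_length") <- attr(aln, "aln_length")
  ts <- .tree_struct(tree, sub$id)
  ts$elen[ts$elen <= 0] <- 1e-8
  idx <- .aln_codon_idx(sub)[ts$tips, , drop = FALSE]
  n_cod <- ncol(idx)
  eig_null <- .fel_eig(1)
  out <- vector("list", n_cod)
  for (s in seq_len(n_cod)) {
    tipstate <- idx[, s]
    obs <- tipstate[!is.na(tipstate)]
    if (length(unique(obs)) <= 1L) {
      out[[s]] <- tibble::tibble(
        codon = s, alpha = 0, beta = 0, lrt = 0, p = 1, class = "none"
      )
      next
    }
    null_fit <- stats::optimize(
      function(r) .fel_site_loglik(tipstate, ts, eig_null, r),
      interval = c(1e-6, 30), maximum = TRUE, tol = 1e-2
    )
    profile_r <- function(omega) {
      eig <- .fel_eig(omega)
      stats::optimize(
        function(r) .fel_site_loglik(tipstate, ts, eig, r),
        interval = c(1e-6, 30), maximum = TRUE, tol = 1e-2
      )
    }
    alt_fit <- stats::optimize(
      function(lw) profile_r(exp(lw))$objective,
      interval = c(-6, 6), maximum = TRUE, tol = 5e-2
    )
    omega_hat <- exp(alt_fit$maximum)
    r_hat <- profile_r(omega_hat)$maximum
    lnl_alt <- max(alt_fit$objective, null_fit$objective)
    lrt <- max(0, 2 * (lnl_alt - null_fit$objective))
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    alpha <- r_hat
    beta <- r_hat * omega_hat
    cls <- "none"
    if (p <= p_threshold && beta > alpha) cls <- "positive"
    if (p <= p_threshold && beta < alpha) cls <- "negative"
    out[[s]] <- tibble::tibble(
      codon = s, alpha = alpha, beta = beta, lrt = lrt, p = p, class = cls
    )
  }
  dplyr::bind_rows(out)
}

# ---- consensus and reports ---------------------------------------------

#' Consensus site classification over multiple methods
#'
#' A codon is classified positive (resp. negative) iff at least two
#' methods call it positive (resp. negative) at their own thresholds.
#' Externally computed site tables (e.g. from Bayesian or episodic-model
#' tools) can be supplied alongside the in-package methods, as long as
#' they carry `codon` and `class` columns.
#'
#' @param tables Named list (>= 2) of per-site tibbles with columns
#'   `codon` and `class`.
#' @param abs_codons Optional 1-based ABS codon positions for annotation.
#' @return Tibble of class `site_consensus`: `codon`, one `class_<method>`
#'   column per method, `n_positive`, `n_negative`, `consensus`, `is_abs`.
#' @export
consensus_sites <- function(tables, abs_codons = integer()) {
  if (length(tables) < 2L) {
    stop("consensus requires at least two method tables", call. = FALSE)
  }
  if (is.null(names(tables))) names(tables) <- paste0("method", seq_along(tables))
  wide <- purrr::imap(tables, function(tb, nm) {
    stopifnot(all(c("codon", "class") %in% names(tb)))
    stats::setNames(
      tb[, c("codon", "class")],
      c("codon", paste0("class_", nm))
    )
  }) |>
    purrr::reduce(dplyr::full_join, by = "codon") |>
    dplyr::arrange(.data$codon)
  cls_cols <- grep("^class_", names(wide), value = TRUE)
  cls_mat <- as.matrix(wide[, cls_cols])
  wide$n_positive <- rowSums(cls_mat == "positive", na.rm = TRUE)
  wide$n_negative <- rowSums(cls_mat == "negative", na.rm = TRUE)
  wide$consensus <- ifelse(
    wide$n_positive >= 2L, "positive",
    ifelse(wide$n_negative >= 2L, "negative", "none")
  )
  wide$is_abs <- wide$codon %in% abs_codons
  class(wide) <- c("site_consensus", class(wide))
  wide
}

# Amino acid substitutions observed at each codon site of an alignment,
# relative to the site's majority residue.
.aa_variants <- function(aln) {
  sub <- aln[!aln$has_stop, ]
  attr(sub, "aln_length") <- attr(aln, "aln_length")
  idx <- .aln_codon_idx(sub)
  aa <- translate_codons(CODONS)
  purrr::map_dfr(seq_len(ncol(idx)), function(s) {
    res <- aa[idx[, s]]
    res <- res[!is.na(res)]
    if (length(res) == 0L) return(NULL)
    tb <- sort(table(res), decreasing = TRUE)
    ref <- names(tb)[1]
    alts <- setdiff(names(tb), ref)
    if (length(alts) == 0L) return(NULL)
    tibble::tibble(
      aa_position = s, reference = ref, alternate = alts,
      substitution = paste(ref, "->", alts)
    )
  })
}

#' Selected-site and substitution reports
#'
#' Builds the per-locus report set: counts of positively and negatively
#' selected sites, the observed amino acid substitutions cross-tabulated
#' with ABS membership and selected-site (SAAS) status, and - when an
#' external predictor table is supplied - the substitutions flagged
#' deleterious/damaging by *both* prediction tools.
#'
#' @param consensus A [consensus_sites()] table for the locus.
#' @param aln The locus [codon_alignment()] (for observed substitutions).
#' @param config The [locus_config()] (ABS positions, locus name).
#' @param predictors Optional tibble/TSV path with columns `aa_position`,
#'   `substitution`, `tool`, `deleterious` (logical); malformed input is
#'   an error.
#' @return List of class `saas_report`: `counts`, `variants`,
#'   `site_summary` and (if predictors given) `deleterious_both`.
#' @export
saas_report <- function(consensus, aln, config, predictors = NULL) {
  saas_pos <- consensus$codon[consensus$consensus != "none"]
  variants <- .aa_variants(aln)
  if (nrow(variants)) {
    variants$is_abs <- variants$aa_position %in% config$abs_codons
    variants$is_saas <- variants$aa_position %in% saas_pos
  } else {
    variants$is_abs <- logical(0)
    variants$is_saas <- logical(0)
  }
  counts <- tibble::tibble(
    locus = config$locus_name,
    n_positive = sum(consensus$consensus == "positive"),
    n_negative = sum(consensus$consensus == "negative")
  )
  site_summary <- tibble::tibble(
    locus = config$locus_name,
    length_aa = nrow(consensus),
    n_variants = nrow(variants),
    n_abs = sum(variants$is_abs),
    n_saas = sum(variants$is_saas)
  )
  out <- list(counts = counts, variants = variants, site_summary = site_summary)
  if (!is.null(predictors)) {
    if (is.character(predictors)) {
      predictors <- tibble::as_tibble(utils::read.table(
        predictors,
        sep = "\t", header = TRUE, stringsAsFactors = FALSE
      ))
    }
    need <- c("aa_position", "substitution", "tool", "deleterious")
    if (!all(need %in% names(predictors))) {
      stop(
        "malformed predictor table: need columns ",
        paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    both <- predictors |>
      dplyr::filter(.data$deleterious) |>
      dplyr::group_by(.data$aa_position, .data$substitution) |>
      dplyr::summarise(n_tools = dplyr::n_distinct(.data$tool), .groups = "drop") |>
      dplyr::filter(.data$n_tools >= 2L)
    both$is_abs <- both$aa_position %in% config$abs_codons
    both$is_saas <- both$aa_position %in% saas_pos
    both$locus <- config$locus_name
    out$deleterious_both <- both[, c(
      "locus", "aa_position", "substitution", "is_abs", "is_saas"
    )]
  }
  class(out) <- "saas_report"
  out
}

#' @export
print.saas_report <- function(x, ...) {
  cat("# Selected amino acid sites\n")
  print(x$counts)
  print(x$site_summary)
  if (!is.null(x$deleterious_both)) {
    cat("# Substitutions deleterious by both predictors\n")
    print(x$deleterious_both)
  }
  invisible(x)
}
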