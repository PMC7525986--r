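# Distance trees, bootstrap support and a JC69 likelihood engine.
#
# Trees are `ape::phylo` objects (unrooted, branch lengths in expected
# substitutions per site). Neighbor-joining and branch-length optimisation
# are delegated to ape/phangorn; the per-site JC69 pruning likelihood is
# implemented here because downstream code (cAIC recombination scan) needs
# per-site log-likelihood vectors.

GAPCHARS <- c("-", "N")

#' Jukes-Cantor distance matrix
#'
#' `d = -(3/4) * ln(1 - (4/3) p)` with `p` the mismatch proportion over the
#' sites admitted by the alignment's gap policy. Saturated pairs
#' (`p >= 0.75`) are capped at `d_max` with a warning.
#'
#' @param aln A [codon_alignment()].
#' @param d_max Cap for saturated distances (default 5.0 substitutions/site).
#' @return Symmetric numeric matrix with sequence IDs as dimnames.
#' @export
jc_distance_matrix <- function(aln, d_max = 5.0) {
  if (nrow(aln) < 2L) stop("need at least two sequences", call. = FALSE)
  m <- aln_matrix(aln)
  policy <- attr(aln, "gap_policy") %||% "complete"
  if (policy == "complete") {
    keep <- colSums(matrix(m %in% GAPCHARS, nrow(m))) == 0
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0L) stop("no ungapped sites under complete deletion", call. = FALSE)
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !(m[i, ] %in% GAPCHARS) & !(m[j, ] %in% GAPCHARS)
      if (!any(ok)) {
        stop(
          "no overlapping ungapped sites for pair ",
          rownames(m)[i], " / ", rownames(m)[j],
          call. = FALSE
        )
      }
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      if (p >= 0.75) {
        saturated <- TRUE
        d[i, j] <- d[j, i] <- d_max
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (saturated) {
    warning("saturated distances (p >= 0.75) capped at ", d_max, call. = FALSE)
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ via [ape::nj()]; negative branch lengths are clamped to zero
#' with the deficit moved to the adjacent branch (first adjacent edge), so
#' path lengths are approximately preserved.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    adj <- setdiff(which(tr$edge[, 1] %in% tr$edge[e, ] |
      tr$edge[, 2] %in% tr$edge[e, ]), e)
    if (length(adj)) {
      tr$edge.length[adj[1]] <- max(0, tr$edge.length[adj[1]] + deficit)
    }
  }
  tr
}

#' NJ tree with bootstrap support
#'
#' Columns (post gap-policy filtering) are resampled with replacement;
#' support for each internal edge of the point-estimate tree is the
#' percentage of replicate NJ trees containing the same bipartition.
#'
#' @param aln A [codon_alignment()].
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return `phylo` tree with `node.label` holding percent support; the
#'   attribute `star_like` flags alignments without variable sites.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L) {
  m <- aln_matrix(aln)
  if ((attr(aln, "gap_policy") %||% "complete") == "complete") {
    m <- m[, colSums(matrix(m %in% GAPCHARS, nrow(m))) == 0, drop = FALSE]
  }
  point <- nj_tree(.jc_from_matrix(m))
  variable <- sum(apply(m, 2, function(col) {
    length(unique(col[!(col %in% GAPCHARS)])) > 1
  }))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[b]] <- suppressWarnings(nj_tree(.jc_from_matrix(m[, cols, drop = FALSE])))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- round_half_up(100 * counts / n_reps)
  attr(point, "star_like") <- variable == 0L
  if (variable == 0L) {
    warning("no variable sites: tree is star-like", call. = FALSE)
  }
  point
}

# JC distance from a character matrix, pairwise deletion, saturation capped
# silently (bootstrap replicates may saturate even when the input does not).
.jc_from_matrix <- function(m, d_max = 5.0) {
  n <- nrow(m)
  good <- !matrix(m %in% GAPCHARS, nrow(m))
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- good[i, ] & good[j, ]
      p <- if (any(ok)) sum(m[i, ok] != m[j, ok]) / sum(ok) else 0.74
      d[i, j] <- d[j, i] <- if (p >= 0.75) d_max else -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' JC69 log-likelihood by Felsenstein pruning
#'
#' Uniform base frequencies; gaps and N contribute likelihood 1 in all
#' states. The per-site log-likelihood vector is returned alongside the
#' total, which equals its sum.
#'
#' @param aln A [codon_alignment()] (all tree tips must be present).
#' @param tree `phylo` tree with branch lengths.
#' @return List with `log_likelihood` and `site_log_likelihood`.
#' @export
jc69_log_likelihood <- function(aln, tree) {
  m <- aln_matrix(aln)
  if (!all(tree$tip.label %in% rownames(m))) {
    stop("tree tips missing from alignment", call. = FALSE)
  }
  m <- m[tree$tip.label, , drop = FALSE]
  nsites <- ncol(m)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # partial likelihoods: list of 4 x nsites matrices
  L <- vector("list", nnode)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_len(ntip)) {
    lab <- m[i, ]
    M <- matrix(0, 4L, nsites)
    known <- lab %in% names(base_idx)
    if (any(known)) M[cbind(base_idx[lab[known]], which(known))] <- 1
    M[, !known] <- 1
    L[[i]] <- M
  }
  # postorder traversal
  ord <- stats::reorder(tree, "postorder")
  edge <- ord$edge
  elen <- ord$edge.length
  pmat <- function(t) {
    e <- exp(-4 * t / 3)
    same <- 0.25 + 0.75 * e
    diff <- 0.25 - 0.25 * e
    matrix(diff, 4, 4) + diag(rep(same - diff, 4))
  }
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1]
    child <- edge[k, 2]
    P <- pmat(elen[k])
    contrib <- P %*% L[[child]]
    if (is.null(L[[parent]])) {
      L[[parent]] <- contrib
    } else {
      L[[parent]] <- L[[parent]] * contrib
    }
  }
  root <- edge[nrow(edge), 1]
  site_l <- colSums(L[[root]] * 0.25)
  site_ll <- log(site_l)
  list(log_likelihood = sum(site_ll), site_log_likelihood = site_ll)
}

#' Maximum-likelihood branch lengths under JC69
#'
#' Branch lengths of a fixed topology are optimised by maximum likelihood
#' (delegated to [phangorn::optim.pml()] with the JC model).
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` topology (branch lengths used as a starting point).
#' @return The tree with optimised branch lengths; attribute `logLik`
#'   carries the maximised JC69 log-likelihood.
#' @export
optimize_branch_lengths <- function(aln, tree) {
  pd <- .aln_phyDat(aln)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.05, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  fit <- phangorn::pml(tree, pd, model = "JC")
  fit <- phangorn::optim.pml(fit,
    optEdge = TRUE,
    control = phangorn::pml.control(trace = 0, epsilon = 1e-8, maxit = 20)
  )
  out <- fit$tree
  attr(out, "logLik") <- as.numeric(stats::logLik(fit))
  out
}

.aln_phyDat <- function(aln) {
  m <- tolower(aln_matrix(aln))
  phangorn::phyDat(m, type = "DNA")
}
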