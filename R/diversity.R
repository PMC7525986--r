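# Alignment diversity indices (variable / parsimony-informative positions)
# and trans-species allele sharing.

.site_base_counts <- function(col) {
  table(col[!(col %in% GAPCHARS)])
}

#' Variable nucleotide positions (VNP)
#'
#' Number of alignment columns with at least two distinct bases. Under the
#' default complete-deletion policy, columns containing any gap or N are
#' excluded entirely; under pairwise deletion, gaps are ignored within each
#' column.
#'
#' @param aln A [codon_alignment()] with >= 2 sequences.
#' @return Integer count.
#' @export
variable_sites <- function(aln) {
  counts <- .filtered_site_counts(aln)
  sum(vapply(counts, function(tb) length(tb) >= 2L, logical(1)))
}

#' Parsimony-informative positions (PIP)
#'
#' Number of columns with at least two distinct bases each occurring in at
#' least two sequences. Gap handling as in [variable_sites()].
#'
#' @inheritParams variable_sites
#' @return Integer count.
#' @export
parsimony_informative_sites <- function(aln) {
  counts <- .filtered_site_counts(aln)
  sum(vapply(counts, function(tb) sum(tb >= 2L) >= 2L, logical(1)))
}

.filtered_site_counts <- function(aln) {
  if (nrow(aln) < 2L) stop("diversity indices need >= 2 sequences", call. = FALSE)
  m <- aln_matrix(aln)
  policy <- attr(aln, "gap_policy") %||% "complete"
  if (policy == "complete") {
    keep <- colSums(matrix(m %in% GAPCHARS, nrow(m))) == 0
    m <- m[, keep, drop = FALSE]
  }
  apply(m, 2, .site_base_counts, simplify = FALSE)
}

#' Trans-species allele sharing
#'
#' Finds identical nucleotide sequences occurring in two or more
#' species/sub-species within a locus (the signature of trans-species
#' polymorphism), and separately reports sequences identical between two
#' loci within one species (inter-locus identity, a different phenomenon).
#'
#' @param alleles Tibble with columns `locus`, `species`, `sequence` and
#'   optionally `name` (one row per allele per species).
#' @return List of class `allele_sharing` with elements `shared` (one row
#'   per shared sequence: locus, n_species, species set, allele names),
#'   `per_locus` (locus, n_alleles, n_shared) and `interlocus` (species,
#'   loci pairs carrying an identical sequence).
#' @export
allele_sharing <- function(alleles) {
  alleles <- tibble::as_tibble(alleles)
  stopifnot(all(c("locus", "species", "sequence") %in% names(alleles)))
  if (!"name" %in% names(alleles)) alleles$name <- NA_character_
  shared <- alleles |>
    dplyr::distinct(.data$locus, .data$species, .data$sequence, .keep_all = TRUE) |>
    dplyr::group_by(.data$locus, .data$sequence) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      species = paste(sort(unique(.data$species)), collapse = ","),
      names = paste(sort(unique(stats::na.omit(.data$name))), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_species >= 2L) |>
    dplyr::arrange(.data$locus, dplyr::desc(.data$n_species))
  per_locus <- alleles |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_alleles = dplyr::n_distinct(.data$sequence),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      shared |>
        dplyr::group_by(.data$locus) |>
        dplyr::summarise(n_shared = dplyr::n(), .groups = "drop"),
      by = "locus"
    ) |>
    dplyr::mutate(n_shared = dplyr::coalesce(.data$n_shared, 0L))
  interlocus <- alleles |>
    dplyr::distinct(.data$species, .data$locus, .data$sequence, .keep_all = TRUE) |>
    dplyr::group_by(.data$species, .data$sequence) |>
    dplyr::summarise(
      n_loci = dplyr::n_distinct(.data$locus),
      loci = paste(sort(unique(.data$locus)), collapse = "/"),
      names = paste(sort(unique(stats::na.omit(.data$name))), collapse = "/"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_loci >= 2L)
  structure(
    list(shared = shared, per_locus = per_locus, interlocus = interlocus),
    class = "allele_sharing"
  )
}

#' @export
print.allele_sharing <- function(x, ...) {
  cat("# Trans-species allele sharing\n")
  print(x$per_locus)
  if (nrow(x$interlocus)) {
    cat("# Inter-locus identical sequences (within species):\n")
    print(x$interlocus[, c("species", "loci")])
  }
  invisible(x)
}

#' Per-locus diversity and global-selection summary
#'
#' One row per alignment (individual loci and pooled sub-regions):
#' sequence count, alignment length, VNP, PIP and - when requested - the
#' global Z-test of positive selection. Indices that are undefined for a
#' single-sequence alignment are reported as `NA`, never 0.
#'
#' @param alignments Named list of [codon_alignment()] objects.
#' @param z_test Run [global_z_test()] per alignment (default TRUE).
#' @param n_boot,seed Passed to [global_z_test()].
#' @return Tibble with columns `locus`, `length_bp`, `n_seq`, `vnp`, `pip`,
#'   `z_p_value`, `z_statistic`, `mean_dn_minus_ds`.
#' @export
diversity_summary <- function(alignments, z_test = TRUE, n_boot = 1000L, seed = 1L) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  purrr::imap_dfr(alignments, function(aln, nm) {
    n <- nrow(aln)
    vnp <- if (n >= 2L) variable_sites(aln) else NA_integer_
    pip <- if (n >= 2L) parsimony_informative_sites(aln) else NA_integer_
    zp <- zs <- zd <- NA_real_
    if (z_test && sum(!aln$has_stop) >= 2L) {
      zt <- global_z_test(aln, n_boot = n_boot, seed = seed)
      zp <- zt$p_one_tailed
      zs <- zt$statistic
      zd <- zt$mean_dN_minus_dS
    }
    tibble::tibble(
      locus = nm,
      length_bp = attr(aln, "aln_length") + attr(aln, "frame_offset"),
      n_seq = n, vnp = vnp, pip = pip,
      z_p_value = zp, z_statistic = zs, mean_dn_minus_ds = zd
    )
  })
}
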