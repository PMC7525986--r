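# Amplicon-read processing and allelic-haplotype determination.
#
# Reads are tibbles with columns `read_id` and `sequence` (plus whatever
# provenance columns the caller carries along). Identity between two
# same-orientation sequences is ungapped end-to-end: matches over the
# aligned prefix divided by the longer length (reads are same-length
# amplicons, so this mirrors the cited clustering tool's semantics without
# external binaries).

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(toupper(x), ""),
    function(s) paste0(rev(s), collapse = ""), character(1)
  ))
}

.ungapped_identity <- function(a, b) {
  la <- nchar(a)
  lb <- nchar(b)
  n <- min(la, lb)
  if (n == 0L) return(0)
  sa <- strsplit(substr(a, 1, n), "")[[1]]
  sb <- strsplit(substr(b, 1, n), "")[[1]]
  sum(sa == sb) / max(la, lb)
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Demultiplex reads by MID tag
#'
#' Exact-prefix matching: a read is assigned to the first tag that is an
#' exact prefix of its sequence, and the tag is clipped. Tags must be
#' unique and mutually non-prefix. Unmatched reads get `mid = "unmatched"`
#' and are left unclipped.
#'
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @param mids Named character vector of MID tag sequences (names are tag
#'   labels; unnamed vectors get labels `M1`, `M2`, ...).
#' @return The reads tibble with a `mid` column and clipped sequences.
#' @export
demultiplex <- function(reads, mids) {
  reads <- tibble::as_tibble(reads)
  mids <- toupper(mids)
  if (is.null(names(mids))) names(mids) <- paste0("M", seq_along(mids))
  if (anyDuplicated(mids)) stop("config error: duplicate MID tags", call. = FALSE)
  for (i in seq_along(mids)) {
    for (j in seq_along(mids)) {
      if (i != j && startsWith(mids[[j]], mids[[i]])) {
        stop("config error: MID tags must be mutually non-prefix", call. = FALSE)
      }
    }
  }
  if (nrow(reads) == 0L) {
    reads$mid <- character(0)
    return(reads)
  }
  mid <- rep("unmatched", nrow(reads))
  seqs <- toupper(reads$sequence)
  for (tag in names(mids)) {
    hit <- startsWith(seqs, mids[[tag]]) & mid == "unmatched"
    mid[hit] <- tag
    seqs[hit] <- substring(seqs[hit], nchar(mids[[tag]]) + 1L)
  }
  reads$sequence <- seqs
  reads$mid <- mid
  reads
}

#' Sort reads to loci by primer identity
#'
#' Each read is compared against every locus reference (forward primer at
#' the read start, reverse-complemented reverse primer at the read end);
#' identity is matches over total primer length. Reads reaching the cutoff
#' for at least one locus are assigned to the best-scoring locus; exact
#' ties go to the first locus in configuration order and are logged.
#'
#' @param reads Tibble with `read_id`, `sequence` (MID-clipped).
#' @param configs Named list of [locus_config()] objects, in priority order.
#' @param identity_cutoff Minimum primer identity (default 0.90).
#' @return Reads tibble with a `locus` column (`"unassigned"` below cutoff).
#' @export
sort_by_primer <- function(reads, configs, identity_cutoff = 0.90) {
  reads <- tibble::as_tibble(reads)
  loci <- names(configs)
  if (nrow(reads) == 0L) {
    reads$locus <- character(0)
    return(reads)
  }
  score_one <- function(seq) {
    vapply(configs, function(cfg) {
      f <- cfg$primer_fwd
      r <- revcomp(cfg$primer_rev)
      nf <- nchar(f)
      nr <- nchar(r)
      if (nf + nr == 0L) return(0)
      mf <- if (nf > 0) nf * .ungapped_identity(substr(seq, 1, nf), f) else 0
      tail_seq <- substr(seq, max(1L, nchar(seq) - nr + 1L), nchar(seq))
      mr <- if (nr > 0) nr * .ungapped_identity(tail_seq, r) else 0
      (mf + mr) / (nf + nr)
    }, numeric(1))
  }
  ties <- 0L
  locus <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    sc <- score_one(toupper(reads$sequence[[i]]))
    best <- max(sc)
    if (best < identity_cutoff) {
      locus[i] <- "unassigned"
    } else {
      hits <- which(sc == best)
      if (length(hits) > 1L) ties <- ties + 1L
      locus[i] <- loci[hits[1]]
    }
  }
  if (ties > 0L) {
    message(ties, " read(s) tied between loci; assigned to first in config order")
  }
  reads$locus <- locus
  reads
}

#' Trim locus primers from reads
#'
#' The forward primer must match the read start and the reverse-complement
#' of the reverse primer the read end, each with at most `max_mismatch`
#' mismatches; both are clipped. Untrimmable reads are dropped and counted
#' in a message.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param config A [locus_config()] providing the primer pair.
#' @param max_mismatch Maximum mismatches per primer (default 2).
#' @return Tibble of trimmed reads (bare amplicon sequences).
#' @export
trim_primers <- function(reads, config, max_mismatch = 2L) {
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0L) return(reads)
  f <- config$primer_fwd
  r <- revcomp(config$primer_rev)
  nf <- nchar(f)
  nr <- nchar(r)
  ok <- logical(nrow(reads))
  trimmed <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- toupper(reads$sequence[[i]])
    ns <- nchar(s)
    if (ns < nf + nr + 1L) next
    mm_f <- if (nf > 0) .hamming(substr(s, 1, nf), f) else 0L
    mm_r <- if (nr > 0) .hamming(substr(s, ns - nr + 1L, ns), r) else 0L
    if (mm_f <= max_mismatch && mm_r <= max_mismatch) {
      ok[i] <- TRUE
      trimmed[i] <- substr(s, nf + 1L, ns - nr)
    }
  }
  if (any(!ok)) {
    message(sum(!ok), " read(s) lacked primer matches and were dropped")
  }
  out <- reads[ok, ]
  out$sequence <- trimmed[ok]
  out
}

#' Greedy identity clustering with per-column majority consensus
#'
#' Reads are ordered canonically (length descending, then lexicographic)
#' and greedily assigned to the best-scoring existing centroid with
#' identity >= cutoff, else founding a new cluster. The consensus is the
#' per-column majority among members; ties are resolved by base order
#' A < C < G < T with a warning.
#'
#' @param reads Tibble with `read_id`, `sequence` (same locus,
#'   primer-trimmed).
#' @param identity_cutoff Clustering identity threshold (default 0.99).
#' @return Tibble of clusters ordered by size descending: `cluster_id`,
#'   `size`, `consensus`, `member_ids` (list column).
#' @export
cluster_and_consensus <- function(reads, identity_cutoff = 0.99) {
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0L) {
    return(tibble::tibble(
      cluster_id = integer(), size = integer(),
      consensus = character(), member_ids = list()
    ))
  }
  ord <- order(-nchar(reads$sequence), reads$sequence, reads$read_id)
  reads <- reads[ord, ]
  centroids <- character(0)
  members <- list()
  for (i in seq_len(nrow(reads))) {
    s <- toupper(reads$sequence[[i]])
    if (length(centroids)) {
      sc <- vapply(centroids, .ungapped_identity, numeric(1), b = s)
      best <- which.max(sc)
    }
    if (length(centroids) && sc[best] >= identity_cutoff) {
      members[[best]] <- c(members[[best]], i)
    } else {
      centroids <- c(centroids, s)
      members[[length(centroids)]] <- i
    }
  }
  tie_warned <- FALSE
  consensus <- vapply(members, function(idx) {
    seqs <- toupper(reads$sequence[idx])
    n <- max(nchar(seqs))
    mat <- do.call(rbind, lapply(seqs, function(s) {
      c(strsplit(s, "")[[1]], rep(NA, n - nchar(s)))
    }))
    cons <- apply(mat, 2, function(col) {
      tb <- table(factor(col[!is.na(col) & col %in% c("A", "C", "G", "T")],
        levels = c("A", "C", "G", "T")
      ))
      top <- which(tb == max(tb))
      if (length(top) > 1L) tie_warned <<- TRUE
      names(tb)[top[1]] # ties: base order A < C < G < T
    })
    paste0(cons, collapse = "")
  }, character(1))
  if (tie_warned) {
    warning("consensus tie(s) resolved by base order A < C < G < T", call. = FALSE)
  }
  out <- tibble::tibble(
    cluster_id = seq_along(members),
    size = lengths(members),
    consensus = consensus,
    member_ids = lapply(members, function(idx) reads$read_id[idx])
  )
  out[order(-out$size, out$cluster_id), ]
}

#' Derive a four-letter species code (Klein-style)
#'
#' Two letters of the genus plus two of the species epithet, e.g.
#' `"Equus caballus"` -> `"Eqca"`.
#'
#' @param species Character vector of binomial names.
#' @return Character vector of 4-letter codes.
#' @export
species_code <- function(species) {
  vapply(species, function(s) {
    parts <- strsplit(trimws(s), "[ _.]+")[[1]]
    parts <- parts[nchar(parts) > 0]
    g <- substr(parts[1], 1, 2)
    e <- if (length(parts) >= 2) substr(parts[length(parts)], 1, 2) else "sp"
    paste0(
      toupper(substr(g, 1, 1)), tolower(substr(g, 2, 2)),
      tolower(e)
    )
  }, character(1), USE.NAMES = FALSE)
}

#' Validate allele candidates by the two-independent-source rule
#'
#' A candidate sequence becomes an allelic haplotype only when it was
#' retrieved from at least two independent sources (distinct PCR runs, or
#' one PCR plus a Sanger trace / clone / genome-derived haplotype).
#' Survivors are named `<SpeciesCode>-<Locus>*<serial>` with zero-padded
#' serials assigned in first-seen order within species and locus.
#'
#' @param candidates Tibble with columns `species`, `locus`, `sequence`,
#'   `source` (one row per independent observation; `source` strings such
#'   as `"PCR:runA"` or `"Sanger:tr1"` identify the evidence).
#' @return Tibble of validated alleles (`species`, `species_code`, `locus`,
#'   `sequence`, `n_sources`, `sources`, `name`); discarded candidates are
#'   attached as attribute `"discarded"`.
#' @export
validate_alleles <- function(candidates) {
  candidates <- tibble::as_tibble(candidates)
  need <- c("species", "locus", "sequence", "source")
  if (nrow(candidates) == 0L) {
    out <- tibble::tibble(
      species = character(), species_code = character(),
      locus = character(), sequence = character(),
      n_sources = integer(), sources = character(), name = character()
    )
    attr(out, "discarded") <- out
    return(out)
  }
  stopifnot(all(need %in% names(candidates)))
  grouped <- candidates |>
    dplyr::group_by(.data$species, .data$locus, .data$sequence) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source),
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    )
  # preserve first-seen order from the input
  first_idx <- candidates |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$species, .data$locus, .data$sequence) |>
    dplyr::summarise(.first = min(.data$.row), .groups = "drop")
  grouped <- dplyr::left_join(
    grouped, first_idx,
    by = c("species", "locus", "sequence")
  ) |>
    dplyr::arrange(.data$.first)
  grouped$species_code <- species_code(grouped$species)
  validated <- grouped[grouped$n_sources >= 2L, ]
  discarded <- grouped[grouped$n_sources < 2L, ]
  validated <- validated |>
    dplyr::group_by(.data$species_code, .data$locus) |>
    dplyr::mutate(name = sprintf(
      "%s-%s*%04d", .data$species_code, .data$locus,
      dplyr::row_number()
    )) |>
    dplyr::ungroup()
  out <- validated[, c(
    "species", "species_code", "locus", "sequence",
    "n_sources", "sources", "name"
  )]
  attr(out, "discarded") <- discarded[, c(
    "species", "species_code", "locus", "sequence", "n_sources", "sources"
  )]
  out
}

#' End-to-end allele calling from decorated reads
#'
#' Demultiplexes, sorts by primer, trims primers, clusters at the given
#' identity and validates cluster consensus sequences with the
#' two-independent-source rule, treating each (MID, PCR run) combination
#' as one source.
#'
#' @param reads Tibble with `read_id`, `sequence` and a `run` column
#'   identifying independent PCR runs.
#' @param mids Named character vector of MID tags.
#' @param configs Named list of [locus_config()] objects.
#' @param species Species name(s) for naming, recycled per MID if named by
#'   tag.
#' @param cluster_cutoff,primer_cutoff Identity thresholds.
#' @return Validated allele tibble (see [validate_alleles()]).
#' @export
call_alleles <- function(reads, mids, configs, species = "Equus sp.",
                         cluster_cutoff = 0.99, primer_cutoff = 0.90) {
  dem <- demultiplex(reads, mids)
  dem <- dem[dem$mid != "unmatched", ]
  srt <- sort_by_primer(dem, configs, identity_cutoff = primer_cutoff)
  srt <- srt[srt$locus != "unassigned", ]
  if (is.null(names(species))) {
    species <- stats::setNames(rep_len(species, length(mids)), names(mids))
  }
  cands <- list()
  for (loc in unique(srt$locus)) {
    cfg <- configs[[loc]]
    for (run in unique(srt$run)) {
      for (tag in unique(srt$mid)) {
        sub <- srt[srt$locus == loc & srt$run == run & srt$mid == tag, ]
        if (nrow(sub) == 0L) next
        trimmed <- suppressMessages(trim_primers(sub, cfg))
        if (nrow(trimmed) == 0L) next
        cl <- suppressWarnings(cluster_and_consensus(trimmed, cluster_cutoff))
        if (nrow(cl) == 0L) next
        cands[[length(cands) + 1L]] <- tibble::tibble(
          species = unname(species[tag]),
          locus = loc,
          sequence = cl$consensus,
          source = paste0("PCR:", run, ":", tag)
        )
      }
    }
  }
  validate_alleles(dplyr::bind_rows(cands))
}
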