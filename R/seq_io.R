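# Sequence, depth-table and locus-configuration I/O.
#
# Coordinates are 0-based half-open internally (BED-style arithmetic);
# every human-readable report uses 1-based positions.

#' Describe one MHC class II locus
#'
#' A locus configuration carries the expected amplicon length of the exon 2
#' sequence, the 1-based antigen-binding-site (ABS) codon positions, the
#' locus-specific primer pair and the genomic interval of the gene. DQB
#' amplicons cover the full 269 bp exon; DRB amplicons miss the nine
#' 3'-terminal exon nucleotides (260 bp), because the nested reverse primer
#' sits on the exon-intron boundary.
#'
#' @param locus_name Locus label, e.g. `"DRB1"`.
#' @param exon2_length Expected amplicon length in bp (> 0).
#' @param abs_codons Integer vector of 1-based ABS codon positions, within
#'   `[1, ceiling(exon2_length / 3)]`.
#' @param primer_fwd,primer_rev Forward / reverse primer sequences (5'->3').
#' @param reference,start,end Genomic interval of the gene: reference name
#'   plus 0-based half-open coordinates.
#' @param frame_offset Number of leading bases to trim so the remainder is
#'   in frame. Defaults to `exon2_length %% 3` (leading partial codon).
#' @return A `locus_config` object (a named list).
#' @export
locus_config <- function(locus_name, exon2_length, abs_codons = integer(),
                         primer_fwd = "", primer_rev = "",
                         reference = NA_character_, start = NA_integer_,
                         end = NA_integer_,
                         frame_offset = exon2_length %% 3L) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L)
  exon2_length <- as.integer(exon2_length)
  if (is.na(exon2_length) || exon2_length <= 0L) {
    stop("`exon2_length` must be a positive integer", call. = FALSE)
  }
  abs_codons <- sort(unique(as.integer(abs_codons)))
  n_codons <- ceiling(exon2_length / 3)
  if (length(abs_codons) && (min(abs_codons) < 1L || max(abs_codons) > n_codons)) {
    stop("ABS codon positions must lie in [1, ", n_codons, "]", call. = FALSE)
  }
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  structure(
    list(
      locus_name = locus_name,
      exon2_length = exon2_length,
      abs_codons = abs_codons,
      primer_fwd = toupper(primer_fwd),
      primer_rev = toupper(primer_rev),
      reference = reference,
      start = if (is.na(start)) NA_integer_ else as.integer(start),
      end = if (is.na(end)) NA_integer_ else as.integer(end),
      frame_offset = frame_offset
    ),
    class = "locus_config"
  )
}

#' Read locus configurations from a YAML file
#'
#' The file maps locus names to fields of [locus_config()]; see
#' `system.file("extdata", "example_loci.yaml", package = "equimhc")`.
#'
#' @param path Path to a YAML file.
#' @return Named list of `locus_config` objects, in file order.
#' @export
read_locus_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::imap(raw, function(x, nm) {
    locus_config(
      locus_name = nm,
      exon2_length = x$exon2_length,
      abs_codons = x$abs_codons %||% integer(),
      primer_fwd = x$primer_fwd %||% "",
      primer_rev = x$primer_rev %||% "",
      reference = x$reference %||% NA_character_,
      start = x$start %||% NA_integer_,
      end = x$end %||% NA_integer_,
      frame_offset = x$frame_offset %||% (x$exon2_length %% 3L)
    )
  })
  out
}

#' Build a codon alignment from sequence records
#'
#' The central container of the package: a tibble with one row per aligned
#' sequence (`id`, `species`, `locus`, `sequence`, `has_stop`) and
#' alignment-level attributes (`aln_length`, `frame_offset`, `gap_policy`).
#' Sequences are upper-cased and frame-trimmed: `frame_offset` leading bases
#' and any trailing partial codon are removed so the length is a multiple of
#' three. Sequences containing an internal stop codon are flagged
#' (`has_stop = TRUE`); they stay in the alignment for diversity counts but
#' are excluded from selection analyses.
#'
#' @param records Data frame with columns `id` and `sequence`; optional
#'   `species` and `locus` columns.
#' @param frame_offset Leading bases to trim (0-2).
#' @param gap_policy `"complete"` (default) or `"pairwise"` deletion of
#'   gap-containing sites in downstream statistics.
#' @return A `codon_alignment` tibble.
#' @export
codon_alignment <- function(records, frame_offset = 0L,
                            gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  records <- tibble::as_tibble(records)
  if (!all(c("id", "sequence") %in% names(records))) {
    stop("`records` needs `id` and `sequence` columns", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty alignment", call. = FALSE)
  if (!"species" %in% names(records)) records$species <- NA_character_
  if (!"locus" %in% names(records)) records$locus <- NA_character_
  records$sequence <- toupper(records$sequence)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    stop("alignment format error: sequences differ in length (",
      paste(unique(lens), collapse = ", "), ")",
      call. = FALSE
    )
  }
  bad <- stringr::str_detect(records$sequence, "[^ACGTN-]")
  if (any(bad)) {
    stop(
      "unsupported characters (only A/C/G/T/N/- allowed; IUPAC ambiguity ",
      "codes other than N are rejected) in: ",
      paste(records$id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  len <- lens[[1]] - frame_offset
  n_cod <- len %/% 3L
  if (n_cod < 1L) stop("alignment too short after frame trimming", call. = FALSE)
  records$sequence <- substr(records$sequence, frame_offset + 1L, frame_offset + 3L * n_cod)
  records$has_stop <- vapply(records$sequence, .has_internal_stop, logical(1), USE.NAMES = FALSE)
  out <- records[, c("id", "species", "locus", "sequence", "has_stop")]
  attr(out, "aln_length") <- 3L * n_cod
  attr(out, "frame_offset") <- frame_offset
  attr(out, "gap_policy") <- gap_policy
  class(out) <- c("codon_alignment", class(tibble::tibble()))
  out
}

.has_internal_stop <- function(seq) {
  cods <- .to_codons(seq)
  cods <- cods[-length(cods)] # terminal stop is not "internal"
  any(cods %in% STOP_CODONS)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(
    "# codon_alignment: ", nrow(x), " sequences x ", attr(x, "aln_length"),
    " bp (", attr(x, "aln_length") %/% 3L, " codons), gap policy: ",
    attr(x, "gap_policy"), "\n",
    sep = ""
  )
  NextMethod()
}

#' Read an aligned FASTA file into a codon alignment
#'
#' Record IDs are parsed into species/locus/allele metadata with
#' `id_pattern` (default dialect `"Species|Locus|AlleleName"`); IDs that do
#' not match keep `NA` metadata. If a [locus_config()] is supplied its
#' `frame_offset` is used and a warning is recorded when sequence lengths
#' do not match `exon2_length`.
#'
#' @param path FASTA file of equal-length (aligned or gap-free) sequences.
#' @param config Optional `locus_config`.
#' @param id_pattern Regex with three capture groups (species, locus,
#'   allele name).
#' @param gap_policy See [codon_alignment()].
#' @param frame_offset Leading bases to trim; overridden by `config`.
#' @return A `codon_alignment` tibble.
#' @export
read_alignment <- function(path, config = NULL,
                           id_pattern = "^([^|]+)\\|([^|]+)\\|(.+)$",
                           gap_policy = c("complete", "pairwise"),
                           frame_offset = 0L) {
  gap_policy <- match.arg(gap_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.info(path)$size == 0) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  chr <- vapply(
    as.character(seqs),
    function(x) paste0(toupper(x), collapse = ""), character(1)
  )
  ids <- names(chr)
  m <- stringr::str_match(ids, id_pattern)
  records <- tibble::tibble(
    id = ids,
    species = m[, 2],
    locus = m[, 3],
    sequence = unname(chr)
  )
  if (!is.null(config)) {
    frame_offset <- config$frame_offset
    if (nchar(records$sequence[[1]]) != config$exon2_length) {
      warning(
        "length mismatch: config ", config$locus_name, " expects ",
        config$exon2_length, " bp, file has ",
        nchar(records$sequence[[1]]), " bp",
        call. = FALSE
      )
    }
  }
  codon_alignment(records, frame_offset = frame_offset, gap_policy = gap_policy)
}

#' Write a codon alignment as canonical FASTA
#'
#' Upper case, 60-column wrapping; reading the result back with
#' [read_alignment()] (with `frame_offset = 0`) round-trips byte-identically.
#'
#' @param aln A `codon_alignment` (or any tibble with `id` and `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", aln$id[[i]]), con)
    s <- aln$sequence[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

# Character matrix view (rows = sequences, columns = alignment positions).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  rownames(m) <- aln$id
  m
}

# Rebuild a codon_alignment from a character matrix, keeping metadata.
aln_from_matrix <- function(m, template) {
  records <- tibble::tibble(
    id = template$id,
    species = template$species,
    locus = template$locus,
    sequence = apply(m, 1, paste0, collapse = "")
  )
  codon_alignment(records,
    frame_offset = 0L,
    gap_policy = attr(template, "gap_policy")
  )
}

#' Read a per-base depth table
#'
#' Expects tab-separated rows `(reference, position, depth)` with 1-based
#' positions, as written by `samtools depth`. Positions absent from the
#' file get depth 0; duplicate rows for one position are resolved by the
#' maximum (deterministic and conservative for presence calling).
#'
#' @param path TSV path (no header). An empty file yields all-zero tracks.
#' @param intervals Data frame with columns `gene`, `reference`, `start`,
#'   `end` (0-based half-open), or a list of [locus_config()] objects.
#' @return Tibble with columns `gene`, `pos` (0-based within the genome),
#'   `depth`, one row per interval base.
#' @export
read_depth_table <- function(path, intervals) {
  if (inherits(intervals, "locus_config")) intervals <- list(intervals)
  if (is.list(intervals) && !is.data.frame(intervals) &&
    all(vapply(intervals, inherits, logical(1), "locus_config"))) {
    intervals <- purrr::map_dfr(intervals, function(cfg) {
      tibble::tibble(
        gene = cfg$locus_name, reference = cfg$reference,
        start = cfg$start, end = cfg$end
      )
    })
  }
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("gene", "reference", "start", "end") %in% names(intervals)))
  info <- file.info(path)
  if (is.na(info$size)) stop("file not found: ", path, call. = FALSE)
  if (info$size == 0) {
    rows <- tibble::tibble(
      chrom = character(), pos0 = integer(), depth = integer()
    )
  } else {
    raw <- utils::read.table(path,
      sep = "\t", header = FALSE,
      col.names = c("chrom", "pos", "depth"),
      colClasses = c("character", "integer", "integer")
    )
    if (any(raw$depth < 0)) {
      stop("depth table format error: negative depth", call. = FALSE)
    }
    rows <- tibble::tibble(
      chrom = raw$chrom, pos0 = raw$pos - 1L, depth = raw$depth
    )
  }
  purrr::pmap_dfr(intervals, function(gene, reference, start, end) {
    len <- end - start
    depth <- integer(len)
    hit <- rows[rows$chrom == reference & rows$pos0 >= start & rows$pos0 < end, ]
    if (nrow(hit) > 0) {
      agg <- tapply(hit$depth, hit$pos0, max) # duplicates -> max
      depth[as.integer(names(agg)) - start + 1L] <- as.integer(agg)
    }
    tibble::tibble(gene = gene, pos = start + seq_len(len) - 1L, depth = depth)
  })
}
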