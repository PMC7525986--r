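# Pipeline orchestration: site-wise selection with optional recombination
# partitions, YAML-configured end-to-end runs, and TSV report rendering.
# Every report carries the package version, a config hash and the seed, so
# reruns with the same seed are byte-identical.

#' Site-wise selection with the two-method consensus
#'
#' Builds an NJ tree with ML branch lengths (JC69), runs the counting
#' (SLAC-style) and likelihood (FEL-style) site methods, and combines them
#' with the at-least-two-methods consensus rule. When a recombination scan
#' that declared a breakpoint is supplied, the alignment is analysed in
#' two partitions with independent per-partition trees and the site tables
#' are concatenated (right-partition codons keep their original numbering).
#'
#' @param aln A [codon_alignment()].
#' @param config Optional [locus_config()] for ABS annotation.
#' @param scan Optional [sbp_scan()] result for this alignment.
#' @param p_threshold Per-method site significance threshold (default 0.1).
#' @param extra_tables Optional named list of externally computed per-site
#'   tables (columns `codon`, `class`) entering the same consensus.
#' @return A [consensus_sites()] tibble.
#' @export
site_selection <- function(aln, config = NULL, scan = NULL,
                           p_threshold = .DEFAULT_SITE_P,
                           extra_tables = NULL) {
  pieces <- if (!is.null(scan) && isTRUE(scan$recombination)) {
    parts <- partition_alignment(aln, scan$best_breakpoint)
    list(list(aln = parts$left, offset = 0L),
         list(aln = parts$right, offset = scan$best_breakpoint))
  } else {
    list(list(aln = aln, offset = 0L))
  }
  run_piece <- function(piece) {
    sub <- piece$aln[!piece$aln$has_stop, ]
    attr(sub, "aln_length") <- attr(piece$aln, "aln_length")
    attr(sub, "gap_policy") <- attr(piece$aln, "gap_policy")
    tr <- nj_tree(.jc_from_matrix(aln_matrix(sub)))
    tr <- optimize_branch_lengths(sub, tr)
    slac <- slac_sites(piece$aln, tr, p_threshold)
    fel <- fel_sites(piece$aln, tr, p_threshold)
    slac$codon <- slac$codon + piece$offset
    fel$codon <- fel$codon + piece$offset
    list(slac = slac, fel = fel)
  }
  res <- lapply(pieces, run_piece)
  tables <- list(
    slac = dplyr::bind_rows(lapply(res, `[[`, "slac")),
    fel = dplyr::bind_rows(lapply(res, `[[`, "fel"))
  )
  if (!is.null(extra_tables)) tables <- c(tables, extra_tables)
  consensus_sites(tables, abs_codons = if (!is.null(config)) config$abs_codons else integer())
}

.report_header <- function(seed, config_hash) {
  c(
    paste0("# equimhc version: ", as.character(utils::packageVersion("equimhc"))),
    paste0("# config hash: ", config_hash),
    paste0("# seed: ", seed)
  )
}

#' Write a report tibble as TSV with a provenance header
#'
#' `NA` cells are rendered as `"NA"`, never 0.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed,config_hash Provenance recorded in `#` header lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, seed = NA, config_hash = "") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(.report_header(seed, config_hash), con)
  df <- as.data.frame(df)
  listcols <- vapply(df, is.list, logical(1))
  df[listcols] <- lapply(df[listcols], function(x) {
    vapply(x, paste, character(1), collapse = ",")
  })
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline from a YAML configuration
#'
#' Executes the configured stages in order - presence calling from a depth
#' table, allele calling from amplicon reads, diversity and trans-species
#' sharing, recombination scan and site-wise selection per alignment - and
#' writes TSV reports into `out_dir`. Any stage error aborts with a
#' stage-tagged message. Reruns with the same configuration and seed
#' produce byte-identical reports.
#'
#' Recognised configuration fields: `seed`, `gap_policy`, `loci` (path to
#' a locus YAML), `depth_table` (TSV path), `reads` (named map run ->
#' FASTA path), `mids` (map label -> tag), `species_by_mid`, `alignments`
#' (named map locus -> FASTA path), `thresholds` (`presence`,
#' `primer_identity`, `cluster_identity`, `site_p`), `n_boot`,
#' `sbp_grid_step`, `truth` (optional JSON truth file from the simulators,
#' compared against the calls in `truth_summary.tsv`).
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return Named list of the computed results, invisibly; reports are
#'   written as side effects.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L, gap_policy = "complete",
    thresholds = list(
      presence = 0.10, primer_identity = 0.90,
      cluster_identity = 0.99, site_p = 0.1
    ),
    n_boot = 1000L, sbp_grid_step = 3L
  )
  config <- modifyList(defaults, config)
  th <- config$thresholds
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir given", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(config)
  seed <- as.integer(config$seed)
  results <- list()
  emit <- function(df, name) {
    write_report_tsv(df, file.path(out_dir, paste0(name, ".tsv")), seed, hash)
  }

  loci <- .stage("config", {
    if (is.null(config$loci)) list() else read_locus_config(config$loci)
  })

  if (!is.null(config$depth_table)) {
    results$presence <- .stage("presence", {
      depth <- read_depth_table(config$depth_table, loci)
      rep <- presence_report(depth, threshold = th$presence)
      emit(rep, "presence")
      rep
    })
  }

  if (!is.null(config$reads)) {
    results$alleles <- .stage("alleles", {
      reads <- purrr::imap_dfr(config$reads, function(path, run) {
        if (!file.exists(path)) stop("missing input path: ", path)
        seqs <- ape::read.FASTA(path)
        tibble::tibble(
          read_id = names(seqs), run = run,
          sequence = vapply(
            as.character(seqs),
            function(x) paste0(toupper(x), collapse = ""), character(1)
          )
        )
      })
      mids <- unlist(config$mids)
      species <- unlist(config$species_by_mid) %||% "Equus sp."
      alleles <- call_alleles(reads, mids, loci,
        species = species,
        cluster_cutoff = th$cluster_identity,
        primer_cutoff = th$primer_identity
      )
      emit(alleles, "alleles")
      emit(attr(alleles, "discarded"), "alleles_discarded")
      alleles
    })
  }

  alns <- .stage("inputs", {
    if (!is.null(config$alignments)) {
      purrr::imap(config$alignments, function(path, loc) {
        if (!file.exists(path)) stop("missing input path: ", path)
        read_alignment(path,
          config = loci[[loc]],
          gap_policy = config$gap_policy
        )
      })
    } else if (!is.null(results$alleles) && nrow(results$alleles) > 0) {
      al <- results$alleles
      split(al, al$locus) |> purrr::imap(function(x, loc) {
        codon_alignment(
          tibble::tibble(
            id = x$name, species = x$species, locus = loc,
            sequence = x$sequence
          ),
          frame_offset = loci[[loc]]$frame_offset %||% 0L,
          gap_policy = config$gap_policy
        )
      })
    } else {
      list()
    }
  })

  if (length(alns)) {
    results$diversity <- .stage("diversity", {
      div <- diversity_summary(alns, n_boot = config$n_boot, seed = seed)
      emit(div, "diversity")
      div
    })
    if (!is.null(results$alleles) && nrow(results$alleles) > 0) {
      results$sharing <- .stage("sharing", {
        sh <- allele_sharing(results$alleles)
        emit(sh$shared, "allele_sharing")
        emit(sh$per_locus, "allele_sharing_per_locus")
        sh
      })
    }
    results$recomb <- .stage("recomb", {
      purrr::imap(alns, function(aln, loc) {
        if (nrow(aln) < 4L || attr(aln, "aln_length") < 60L) {
          return(NULL)
        }
        scan <- sbp_scan(aln, grid_step = config$sbp_grid_step)
        emit(glance(scan), paste0("recomb_", loc))
        scan
      })
    })
    results$selection <- .stage("selection", {
      purrr::imap(alns, function(aln, loc) {
        if (sum(!aln$has_stop) < 4L) {
          return(NULL)
        }
        cons <- site_selection(aln,
          config = loci[[loc]],
          scan = results$recomb[[loc]],
          p_threshold = th$site_p
        )
        emit(cons, paste0("selection_", loc))
        cons
      })
    })
  }

  if (!is.null(config$truth)) {
    results$truth_summary <- .stage("truth", {
      truth <- jsonlite::read_json(config$truth, simplifyVector = TRUE)
      rows <- list()
      if (!is.null(truth$presence) && !is.null(results$presence)) {
        cmp <- dplyr::left_join(
          results$presence,
          tibble::tibble(
            gene = names(truth$presence),
            truth = unlist(truth$presence)
          ),
          by = "gene"
        )
        rows$presence <- tibble::tibble(
          stage = "presence",
          n = nrow(cmp),
          n_correct = sum(cmp$call == cmp$truth, na.rm = TRUE)
        )
      }
      if (!is.null(truth$alleles) && !is.null(results$alleles)) {
        called <- sort(unique(results$alleles$sequence))
        true_seq <- sort(unique(unlist(truth$alleles)))
        rows$alleles <- tibble::tibble(
          stage = "alleles",
          n = length(true_seq),
          n_correct = sum(true_seq %in% called)
        )
      }
      summary <- dplyr::bind_rows(rows)
      emit(summary, "truth_summary")
      summary
    })
  }
  invisible(results)
}
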