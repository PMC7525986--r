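# Bundled synthetic demonstration data set: writes every pipeline input
# (locus config, depth table, two runs of decorated amplicon reads, a
# truth file and the pipeline YAML) into a directory, using the package
# simulators. Everything is derived from one seed.

#' Write a synthetic demonstration data set and pipeline configuration
#'
#' Simulates a single-sample depth table (all genes present except DQB2),
#' two independent PCR runs of MID-tagged DQB1 amplicon reads for two
#' individuals (two alleles each), writes a JSON truth file recording the
#' simulated presence flags and allele sequences, and a YAML pipeline
#' configuration pointing at all of it.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all simulators.
#' @param error_rate Per-base read error rate (default 0.002).
#' @param copies Reads per allele per run (default 25).
#' @return Path to the written `config.yaml`.
#' @export
demo_pipeline <- function(dir, seed = 1L, error_rate = 0.002, copies = 25L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci_path <- system.file("extdata", "example_loci.yaml", package = "equimhc")
  loci <- read_locus_config(loci_path)

  # depth tracks: one synthetic genome, DQB2 absent
  present <- c(
    DRB1 = TRUE, DRB2 = TRUE, DRB3 = TRUE,
    DQB1 = TRUE, DQB2 = FALSE, DQB3 = TRUE
  )
  depth_rows <- purrr::imap_dfr(loci, function(cfg, nm) {
    tr <- simulate_depth_track(
      cfg$end - cfg$start,
      present = present[[nm]],
      mean_depth = 18, dropout_fraction = 0.05,
      seed = seed + match(nm, names(loci)), gene = nm
    )
    tibble::tibble(
      chrom = cfg$reference,
      pos = cfg$start + tr$pos + 1L, # 1-based in the file
      depth = tr$depth
    )
  })
  depth_path <- file.path(dir, "depth.tsv")
  utils::write.table(depth_rows[depth_rows$depth > 0, ], depth_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )

  # four DQB1 alleles (two individuals x two alleles) from the codon
  # simulator, prefixed to the 269-bp amplicon frame
  tree <- demo_equid_tree(scale = 2)
  model <- site_class_model(rep("bg", 89), c(bg = 0.5), kappa = 2)
  sim <- simulate_codon_alignment(tree, model, 89, seed = seed + 100L)
  alleles <- paste0("TC", sim$sequence[1:4])
  names(alleles) <- paste0("true_allele", 1:4)
  mids <- c(M1 = "ACGAGTGCGT", M2 = "ACGCTCGACA")
  species <- c(M1 = "Equus caballus", M2 = "Equus przewalskii")
  read_paths <- character(0)
  for (run in c("run1", "run2")) {
    reads <- dplyr::bind_rows(
      simulate_amplicon_reads(alleles[1:2], copies, error_rate,
        mids["M1"], loci$DQB1,
        seed = seed + 200L + (run == "run2"), run = run
      ),
      simulate_amplicon_reads(alleles[3:4], copies, error_rate,
        mids["M2"], loci$DQB1,
        seed = seed + 300L + (run == "run2"), run = run
      )
    )
    p <- file.path(dir, paste0("reads_", run, ".fasta"))
    write_reads_fasta(reads, p)
    read_paths[run] <- p
  }

  truth <- list(
    presence = as.list(ifelse(present, "present", "absent")),
    alleles = as.list(unname(alleles))
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE)

  config <- list(
    seed = seed,
    loci = loci_path,
    depth_table = depth_path,
    reads = as.list(read_paths),
    mids = as.list(mids),
    species_by_mid = as.list(species),
    truth = truth_path,
    out_dir = file.path(dir, "reports")
  )
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  config_path
}
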