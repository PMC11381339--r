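#' Pipeline run configuration
#'
#' Collects every stage parameter in one object so a reanalysis is a
#' configuration change, not a code change. \code{samples} maps sample
#' labels to footprint files and genotypes; a WT and a KO sample are
#' required for stall calling, RESCUE is optional.
#'
#' @param samples data.frame with columns \code{sample}, \code{path},
#'   \code{genotype} (subset of WT/KO/RESCUE) and optionally \code{format}
#'   (\code{"bed"}/\code{"sam"}, default bed).
#' @param transcriptome_fasta,annotation paths; \code{NULL} uses the
#'   bundled human fixture.
#' @param min_len,max_len footprint length filter bounds in nt.
#' @param calibration a [calibration_config()].
#' @param stall a [stall_params()].
#' @param window_size,window_anchor proline-window parameters.
#' @param triplet_convention census convention, see [pp_triplets()].
#' @param seed integer seed (recorded in outputs).
#' @return configuration list of class \code{run_config}.
#' @export
run_config <- function(samples,
                       transcriptome_fasta = NULL,
                       annotation = NULL,
                       min_len = 25L, max_len = 45L,
                       calibration = calibration_config(),
                       stall = stall_params(),
                       window_size = 5L,
                       window_anchor = "trailing",
                       triplet_convention = "per_run",
                       seed = 1L) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample", "path", "genotype") %in% names(samples))) {
    stop("samples needs columns sample, path, genotype")
  }
  if (is.null(samples$format)) samples$format <- "bed"
  bad <- setdiff(samples$genotype, c("WT", "KO", "RESCUE"))
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  structure(list(samples = samples,
                 transcriptome_fasta = transcriptome_fasta,
                 annotation = annotation,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 calibration = calibration, stall = stall,
                 window_size = as.integer(window_size),
                 window_anchor = window_anchor,
                 triplet_convention = triplet_convention,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the fields of [run_config()].
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(samples = j$samples)
  for (f in c("transcriptome_fasta", "annotation", "min_len", "max_len",
              "window_size", "window_anchor", "triplet_convention",
              "seed")) {
    if (!is.null(j[[f]])) args[[f]] <- j[[f]]
  }
  if (!is.null(j$calibration)) {
    args$calibration <- do.call(calibration_config, j$calibration)
  }
  if (!is.null(j$stall)) args$stall <- do.call(stall_params, j$stall)
  do.call(run_config, args)
}

config_hash <- function(config) {
  x <- config
  class(x) <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes ingest, length filtering, offset calibration (on all samples
#' pooled), per-genotype occupancy profiles (replicates pooled within
#' genotype), stall calling (KO vs WT, rescue check when RESCUE samples
#' are present), rolling-window proline occupancy ratios, and the proteome
#' motif census. All TSV outputs carry the configuration hash in a header
#' line; a machine-readable summary is written as \code{summary.json}.
#'
#' @param config a [run_config()] or path to a JSON configuration.
#' @param out_dir output directory.
#' @return (invisibly) the summary list.
#' @export
run_all <- function(config, out_dir) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- paste0("config_md5=", hash)
  log_stage <- function(stage) {
    message(sprintf("[%s] %5.1fs  %s", "mitoribostall",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    stage))
  }

  log_stage("load transcriptome")
  txome <- if (is.null(config$transcriptome_fasta)) {
    load_human_txome()
  } else {
    load_transcriptome(config$transcriptome_fasta, config$annotation)
  }

  log_stage("ingest footprints")
  if (!"WT" %in% config$samples$genotype) {
    stop("configuration must include at least one WT sample")
  }
  if (!"KO" %in% config$samples$genotype) {
    stop("configuration must include at least one KO sample")
  }
  fps <- lapply(seq_len(nrow(config$samples)), function(i) {
    s <- config$samples[i, ]
    fp <- read_footprints(s$path, format = s$format, txome = txome)
    filter_lengths(fp, config$min_len, config$max_len)
  })
  names(fps) <- config$samples$sample

  log_stage("calibrate offsets")
  pooled <- do.call(rbind, lapply(fps, as.data.frame))
  pooled <- footprints(pooled$transcript_id, pooled$five_prime,
                       pooled$length, pooled$count)
  offsets <- calibrate_offsets(pooled, txome, config$calibration)
  write_offset_table(offsets, file.path(out_dir, "offsets.tsv"), hdr)
  if (all(is.na(offsets$offset))) {
    stop("offset calibration failed for every read length")
  }

  log_stage("occupancy profiles")
  genos <- unique(config$samples$genotype)
  profiles <- list()
  for (g in genos) {
    idx <- which(config$samples$genotype == g)
    asn <- pool_assignments(lapply(idx, function(i)
      assign_asites(fps[[i]], offsets, txome)))
    profiles[[g]] <- build_profiles(asn, txome, sample = g)
    write_profiles(profiles[[g]],
                   file.path(out_dir, paste0("profiles_", tolower(g), ".tsv")),
                   hdr)
  }
  dist_wt <- transcriptome_distribution(profiles[["WT"]])
  utils::write.table(dist_wt,
                     file.path(out_dir, "transcriptome_distribution_wt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("stall analysis")
  events <- call_stall_events(profiles[["WT"]], profiles[["KO"]], txome,
                              config$stall)
  if ("RESCUE" %in% genos && nrow(events)) {
    events <- rescue_check(events, profiles[["WT"]], profiles[["RESCUE"]],
                           config$stall)
  }
  write_stall_events(events, file.path(out_dir, "stall_events.tsv"), hdr)
  groups <- proline_window_scores(profiles, txome,
                                  window = config$window_size,
                                  anchor = config$window_anchor)
  con <- file(file.path(out_dir, "proline_groups.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(groups, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  log_stage("motif census")
  proteome <- txome_proteome(txome)
  census <- proteome_motif_distribution(proteome,
                                        config$triplet_convention)
  census$triplets <- annotate_pausing(census$triplets)
  con <- file(file.path(out_dir, "motif_census.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(census$per_gene, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  summary <- list(
    config_md5 = hash,
    seed = config$seed,
    offsets = as.data.frame(offsets),
    stall_events = events,
    proline_groups = groups,
    motif_census = census$per_gene,
    motif_summary = census$summary,
    transcriptome_distribution_wt = dist_wt)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  log_stage("done")
  invisible(summary)
}
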