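#' Simulation configuration
#'
#' Defaults emulate the footprint geometry and dwell-time phenomenology of
#' mitoribosome profiling: ~32-nt footprints with per-length A-site offsets
#' of 15-18 nt from the 5' end, triplet phasing (A-sites fall on codon
#' starts), Poisson count noise, a termination pause at every stop codon
#' (which produces the stop-codon metagene peaks the calibration relies
#' on), and codon-level dwell elevation at stall sites that is stronger in
#' KO than in WT. Translation-initiation weights default to 3x for COX1,
#' COX3 and ND6, the mRNAs with the highest initiation rates.
#'
#' @param seed integer seed fixing all randomness.
#' @param depth mean reads per codon (for a gene with te weight 1).
#' @param length_dist named numeric vector, read length -> probability.
#' @param true_offsets named integer vector, read length -> A-site offset.
#' @param stall_sites data.frame (\code{gene}, \code{codon},
#'   \code{ko_factor}, \code{wt_factor}) or \code{NULL} to auto-discover
#'   polyproline sites in [make_dataset()].
#' @param te named per-gene translation-initiation weights (unnamed genes
#'   get 1).
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param stop_pause dwell factor at every stop codon, all genotypes.
#' @return configuration list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       depth = 100,
                       length_dist = c("31" = 0.15, "32" = 0.5,
                                       "33" = 0.25, "34" = 0.1),
                       true_offsets = c("31" = 15L, "32" = 16L,
                                        "33" = 17L, "34" = 18L),
                       stall_sites = NULL,
                       te = c(COX1 = 3, COX3 = 3, ND6 = 3),
                       noise = c("poisson", "none"),
                       stop_pause = 8) {
  noise <- match.arg(noise)
  if (abs(sum(length_dist) - 1) > 1e-9) stop("length_dist must sum to 1")
  if (!all(names(length_dist) %in% names(true_offsets))) {
    stop("every simulated length needs a true offset")
  }
  if (!is.null(stall_sites) &&
      any(stall_sites$ko_factor < 1 | stall_sites$wt_factor < 1)) {
    stop("stall factors must be >= 1")
  }
  structure(list(seed = as.integer(seed), depth = depth,
                 length_dist = length_dist, true_offsets = true_offsets,
                 stall_sites = stall_sites, te = te, noise = noise,
                 stop_pause = stop_pause),
            class = "sim_config")
}

#' Default stall sites: polyproline runs of the transcriptome
#'
#' One site per maximal run of >= 2 prolines, at the codon of the run's
#' last proline (the codon whose trailing 5-aa window holds the full run).
#' 2xPro runs get KO dwell factor 8; >= 3xPro runs, the strongest stallers,
#' get 16. WT dwell factor is 2 everywhere (pauses exist but are resolved).
#'
#' @param txome a \code{mito_txome}.
#' @return stall-site data.frame.
#' @export
default_stall_sites <- function(txome) {
  proteome <- txome_proteome(txome)
  sites <- NULL
  for (g in names(proteome)) {
    runs <- proline_runs(proteome[[g]], g)
    runs <- runs[runs$length >= 2L, , drop = FALSE]
    if (!nrow(runs)) next
    sites <- rbind(sites, data.frame(
      gene = g, codon = runs$start + runs$length - 1L,
      ko_factor = ifelse(runs$length >= 3L, 16, 8),
      wt_factor = 2, stringsAsFactors = FALSE))
  }
  if (is.null(sites)) {
    stop("no polyproline stall sites found: proline-free transcriptome")
  }
  sites[order(sites$gene, sites$codon), ]
}

#' Stall sites at every proline-dense rolling window
#'
#' Places a stall at every codon whose trailing \code{window}-residue
#' proline count reaches \code{min_prolines}, with dwell factors that grow
#' with the proline count: a codon labelled \code{k} gets KO factor
#' \code{ko_base^(k - min_prolines + 1)} and WT factor
#' \code{wt_base^(k - min_prolines + 1)}, so denser proline context stalls
#' harder. This is the generator used to study the rolling-window
#' occupancy-ratio statistic.
#'
#' @param txome a \code{mito_txome}.
#' @param window window length in amino acids.
#' @param min_prolines minimum prolines per window for a stall.
#' @param ko_base,wt_base per-level dwell factor bases.
#' @return stall-site data.frame (\code{gene}, \code{codon},
#'   \code{ko_factor}, \code{wt_factor}).
#' @export
window_stall_sites <- function(txome, window = 5L, min_prolines = 2L,
                               ko_base = 5, wt_base = 1.5) {
  proteome <- txome_proteome(txome)
  sites <- NULL
  for (g in names(proteome)) {
    lab <- proline_window_labels(proteome[[g]], window)
    at <- which(lab >= min_prolines)
    if (!length(at)) next
    lvl <- lab[at] - min_prolines + 1L
    sites <- rbind(sites, data.frame(
      gene = g, codon = at - 1L,
      ko_factor = ko_base^lvl, wt_factor = wt_base^lvl,
      stringsAsFactors = FALSE))
  }
  if (is.null(sites)) stop("no proline-dense windows in transcriptome")
  sites[order(sites$gene, sites$codon), ]
}

#' Project stall sites into overlapping ORFs
#'
#' A dwell elevation inside the overlap of a bicistronic pair shows up in
#' the occupancy profiles of both ORFs, in each ORF's own reading frame.
#' This helper expands a truth table accordingly so detected events can be
#' matched against every codon a site legitimately projects to.
#'
#' @param txome a \code{mito_txome}.
#' @param sites stall-site data.frame (\code{gene}, \code{codon}).
#' @return data.frame (\code{gene}, \code{codon}) including the original
#'   sites plus their projections into overlapping ORFs.
#' @export
expand_stall_sites <- function(txome, sites) {
  out <- sites[, c("gene", "codon")]
  for (i in seq_len(nrow(sites))) {
    orf <- orf_row(txome, sites$gene[i])
    nts <- orf$start + 3L * sites$codon[i] + 0:2
    others <- txome$orfs[txome$orfs$transcript_id == orf$transcript_id &
                           txome$orfs$gene != orf$gene, , drop = FALSE]
    for (j in seq_len(nrow(others))) {
      o <- others[j, ]
      span_end <- o$start + 3L * orf_n_codons(o)
      hit <- nts[nts >= o$start & nts < span_end]
      if (length(hit)) {
        out <- rbind(out, data.frame(
          gene = o$gene, codon = unique((hit - o$start) %/% 3L)))
      }
    }
  }
  unique(out)
}

#' Expected per-codon occupancy under a dwell-time model
#'
#' Dwell is 1 at every codon, multiplied by the stop pause at the terminal
#' codon and by the genotype's stall factor at each stall site (KO uses
#' \code{ko_factor}; WT and RESCUE use \code{wt_factor}). Expected
#' occupancy is \code{te_gene * dwell / sum(dwell)} per gene.
#'
#' @param txome a \code{mito_txome}.
#' @param config a [sim_config()] (\code{stall_sites} must be set, possibly
#'   to an empty data.frame for a null simulation).
#' @param genotype \code{"WT"}, \code{"KO"} or \code{"RESCUE"}.
#' @return named list gene -> numeric vector of expected occupancies.
#' @export
simulate_dwell <- function(txome, config, genotype = c("WT", "KO",
                                                       "RESCUE")) {
  genotype <- match.arg(genotype)
  sites <- config$stall_sites
  if (is.null(sites)) sites <- default_stall_sites(txome)
  out <- list()
  for (i in seq_len(nrow(txome$orfs))) {
    orf <- txome$orfs[i, ]
    n <- orf_n_codons(orf)
    dwell <- rep(1, n)
    dwell[n] <- dwell[n] * config$stop_pause
    gs <- sites[sites$gene == orf$gene, , drop = FALSE]
    if (nrow(gs)) {
      if (any(gs$codon < 0 | gs$codon >= n)) {
        stop("stall site outside ORF ", orf$gene)
      }
      f <- if (genotype == "KO") gs$ko_factor else gs$wt_factor
      dwell[gs$codon + 1L] <- dwell[gs$codon + 1L] * f
    }
    te <- if (orf$gene %in% names(config$te)) config$te[[orf$gene]] else 1
    out[[orf$gene]] <- te * dwell / sum(dwell)
  }
  out
}

# deterministic largest-remainder allocation of n into probabilities p
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Sample footprints from expected occupancies
#'
#' Per codon, the A-site count is Poisson with mean
#' \code{depth * expected * n_codons} (or that mean rounded, under
#' \code{noise = "none"}). Counts are split over read lengths according to
#' \code{length_dist} and materialised as footprints with
#' \code{five_prime = A-site nt - true_offset(length)}. Footprints that
#' would extend beyond the transcript are dropped and logged.
#'
#' @param expected output of [simulate_dwell()].
#' @param txome a \code{mito_txome}.
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @param return_reads also return the read sequences (for the exact-match
#'   aligner).
#' @return a \code{footprints} data.frame; \code{attr(, "clipped")} counts
#'   dropped reads; with \code{return_reads}, \code{attr(, "reads")} holds
#'   one sequence per footprint copy.
#' @export
sample_footprints <- function(expected, txome, config,
                              seed = config$seed, return_reads = FALSE) {
  set.seed(seed)
  lens <- as.integer(names(config$length_dist))
  probs <- as.numeric(config$length_dist)
  offs <- config$true_offsets[names(config$length_dist)]
  tx_id <- character(0); fp5 <- integer(0); fln <- integer(0)
  cnt <- integer(0)
  clipped <- 0L
  for (i in seq_len(nrow(txome$orfs))) {
    orf <- txome$orfs[i, ]
    exp_occ <- expected[[orf$gene]]
    n <- length(exp_occ)
    lambda <- config$depth * exp_occ * n
    counts <- if (config$noise == "poisson") {
      stats::rpois(n, lambda)
    } else {
      as.integer(round(lambda))
    }
    txlen <- nchar(txome$seqs[[orf$transcript_id]])
    for (j in which(counts > 0L)) {
      by_len <- if (config$noise == "poisson") {
        as.integer(stats::rmultinom(1, counts[j], probs))
      } else {
        allocate_counts(counts[j], probs)
      }
      asite_nt <- orf$start + 3L * (j - 1L)
      for (k in which(by_len > 0L)) {
        p5 <- asite_nt - offs[[k]]
        if (p5 < 0L || p5 + lens[k] > txlen) {
          clipped <- clipped + by_len[k]
          next
        }
        tx_id <- c(tx_id, orf$transcript_id)
        fp5 <- c(fp5, p5)
        fln <- c(fln, lens[k])
        cnt <- c(cnt, by_len[k])
      }
    }
  }
  fp <- footprints(tx_id, fp5, fln, cnt)
  attr(fp, "clipped") <- clipped
  if (return_reads) {
    reads <- rep(substr(rep(txome$seqs[tx_id], cnt),
                        rep(fp5, cnt) + 1L,
                        rep(fp5, cnt) + rep(fln, cnt)), 1L)
    attr(fp, "reads") <- unname(reads)
  }
  fp
}

#' Generate a complete WT / KO / RESCUE dataset with ground truth
#'
#' Simulates the three genotypes from one configuration. Stall sites
#' default to the polyproline sites of [default_stall_sites()]; RESCUE
#' shares the WT dwell factors (alleviated stalls). With \code{out_dir},
#' bed-like footprint files, truth tables and the configuration are written
#' to disk.
#'
#' @param txome a \code{mito_txome}.
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with \code{footprints} (named list WT/KO/RESCUE),
#'   \code{truth} (list: \code{stall_sites}, \code{true_offsets},
#'   \code{expected} per genotype) and \code{config}.
#' @export
make_dataset <- function(txome, config = sim_config(), out_dir = NULL) {
  if (is.null(config$stall_sites)) {
    config$stall_sites <- default_stall_sites(txome)
  }
  genos <- c("WT", "KO", "RESCUE")
  expected <- lapply(stats::setNames(genos, genos), function(g)
    simulate_dwell(txome, config, g))
  fps <- lapply(stats::setNames(genos, genos), function(g)
    sample_footprints(expected[[g]], txome, config,
                      seed = config$seed + match(g, genos) - 1L))
  truth <- list(stall_sites = config$stall_sites,
                true_offsets = config$true_offsets,
                expected = expected)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in genos) {
      write_footprints(fps[[g]], file.path(out_dir,
                                           paste0(tolower(g), ".footprints.tsv")),
                       header = paste0("genotype=", g, " seed=", config$seed))
    }
    utils::write.table(config$stall_sites,
                       file.path(out_dir, "truth_stall_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dwell_rows <- do.call(rbind, lapply(genos, function(g) {
      do.call(rbind, lapply(names(expected[[g]]), function(gene)
        data.frame(genotype = g, gene = gene,
                   codon = seq_along(expected[[g]][[gene]]) - 1L,
                   expected = expected[[g]][[gene]])))
    }))
    utils::write.table(dwell_rows, file.path(out_dir, "truth_expected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(out_dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(footprints = fps, truth = truth, config = config)
}
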