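#' Stall-calling parameters
#'
#' @param min_cov minimum raw KO A-site count at a codon.
#' @param min_ratio minimum KO/WT relative-occupancy ratio.
#' @param flank half-width in codons of the local-maximum test.
#' @param pseudocount pseudocount on the relative-occupancy scale; the
#'   default \code{NULL} uses \code{0.1 / n_codons} per ORF.
#' @param edge_exclude codons at the ORF start ineligible as events.
#'   Mitochondrial mRNAs are leaderless, so footprints whose A-site sits in
#'   the first codons would begin upstream of the transcript and cannot be
#'   observed; occupancy there is censored and ratio estimates unstable.
#'   The default masks the codons reachable only by such footprints, i.e.
#'   the largest plausible A-site offset (20 nt) divided by the codon size,
#'   rounded up: 7 codons.
#' @return parameter list.
#' @export
stall_params <- function(min_cov = 10L, min_ratio = 2, flank = 5L,
                         pseudocount = NULL, edge_exclude = 7L) {
  list(min_cov = as.integer(min_cov), min_ratio = min_ratio,
       flank = as.integer(flank), pseudocount = pseudocount,
       edge_exclude = as.integer(edge_exclude))
}

#' Per-codon KO/WT relative-occupancy ratio
#'
#' \code{ratio_i = (ko_rel_i + p) / (wt_rel_i + p)} with pseudocount
#' \code{p} on the relative scale, so codons with no signal in either
#' genotype sit at 1.
#'
#' @param wt,ko \code{occupancy_profile}s of the same gene.
#' @param pseudocount pseudocount \code{p}; default \code{0.1 / n_codons}.
#' @return numeric vector of per-codon ratios.
#' @export
genotype_ratio_profile <- function(wt, ko, pseudocount = NULL) {
  if (wt$gene != ko$gene) stop("profiles are for different genes")
  n <- length(wt$counts)
  if (length(ko$counts) != n) stop("profile length mismatch for ", wt$gene)
  p <- if (is.null(pseudocount)) 0.1 / n else pseudocount
  (ko$rel_within + p) / (wt$rel_within + p)
}

#' Call genotype-dependent stall events
#'
#' A codon is an event when (i) its raw KO count reaches \code{min_cov},
#' (ii) its KO/WT relative-occupancy ratio reaches \code{min_ratio}, and
#' (iii) it is a local maximum of the ratio within \code{flank} codons.
#' Adjacent qualifying codons merge into a single event at the maximal
#' ratio. Events are annotated with the amino-acid context (7 residues each
#' side; the stop codon shown as \code{*}).
#'
#' @param wt,ko named lists of \code{occupancy_profile} per gene (or single
#'   profiles of the same gene).
#' @param txome a \code{mito_txome}.
#' @param params a [stall_params()].
#' @return data.frame (\code{gene}, \code{codon}, \code{ratio},
#'   \code{ko_rel}, \code{wt_rel}, \code{ko_count}, \code{motif_context},
#'   \code{rescued}) ordered by gene and codon; \code{rescued} is \code{NA}
#'   until [rescue_check()] runs.
#' @export
call_stall_events <- function(wt, ko, txome, params = stall_params()) {
  if (inherits(wt, "occupancy_profile")) wt <- stats::setNames(list(wt), wt$gene)
  if (inherits(ko, "occupancy_profile")) ko <- stats::setNames(list(ko), ko$gene)
  events <- NULL
  for (g in names(wt)) {
    if (!g %in% names(ko)) next
    pw <- wt[[g]]; pk <- ko[[g]]
    ratio <- genotype_ratio_profile(pw, pk, params$pseudocount)
    n <- length(ratio)
    qual <- pk$counts >= params$min_cov & ratio >= params$min_ratio
    qual[seq_len(min(params$edge_exclude, n))] <- FALSE
    if (!any(qual)) next
    # local maximum within +/- flank codons
    is_max <- vapply(seq_len(n), function(i) {
      if (!qual[i]) return(FALSE)
      w <- max(1L, i - params$flank):min(n, i + params$flank)
      ratio[i] >= max(ratio[w])
    }, TRUE)
    qual <- qual & is_max
    if (!any(qual)) next
    # merge adjacent qualifying codons: one event per run, at the max ratio
    runs <- rle(qual)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    prot <- translate_orf(txome, g)
    aa_ext <- paste0(prot, "*")  # stop codon representable in context
    for (j in which(runs$values)) {
      idx <- starts[j]:ends[j]
      at <- idx[which.max(ratio[idx])]
      ctx <- substr(aa_ext, max(1L, at - 7L), min(nchar(aa_ext), at + 7L))
      events <- rbind(events, data.frame(
        gene = g, codon = at - 1L, ratio = ratio[at],
        ko_rel = pk$rel_within[at], wt_rel = pw$rel_within[at],
        ko_count = pk$counts[at], motif_context = ctx,
        rescued = NA, stringsAsFactors = FALSE))
    }
  }
  if (is.null(events)) {
    events <- data.frame(gene = character(0), codon = integer(0),
                         ratio = numeric(0), ko_rel = numeric(0),
                         wt_rel = numeric(0), ko_count = integer(0),
                         motif_context = character(0), rescued = logical(0),
                         stringsAsFactors = FALSE)
  } else {
    events <- events[order(events$gene, events$codon), ]
    rownames(events) <- NULL
  }
  events
}

#' Flag stall events rescued in a reconstituted sample
#'
#' An event is rescued when the reconstituted/WT relative-occupancy ratio
#' at the event codon falls below \code{min_ratio}. Events whose gene has
#' no reconstituted profile are flagged \code{NA} (untested).
#'
#' @param events output of [call_stall_events()].
#' @param wt,reconstituted named lists of \code{occupancy_profile}.
#' @param params a [stall_params()].
#' @return \code{events} with the \code{rescued} column filled.
#' @export
rescue_check <- function(events, wt, reconstituted,
                         params = stall_params()) {
  if (!nrow(events)) return(events)
  for (i in seq_len(nrow(events))) {
    g <- events$gene[i]
    if (!g %in% names(reconstituted) || !g %in% names(wt)) {
      events$rescued[i] <- NA
      next
    }
    ratio <- genotype_ratio_profile(wt[[g]], reconstituted[[g]],
                                    params$pseudocount)
    events$rescued[i] <- ratio[events$codon[i] + 1L] < params$min_ratio
  }
  events
}

#' Rolling-window polyproline occupancy ratios
#'
#' Labels every protein codon with the number of prolines in a rolling
#' window of \code{window} amino acids (trailing anchor by default,
#' clamped at the N-terminus; labels >= 3 pooled into group 3), sums the
#' within-transcript relative occupancy of each genotype over the codons of
#' each group across all profiled genes, and normalises each genotype's
#' group sums to WT. Stop-codon positions carry no amino acid and are
#' excluded.
#'
#' @param profiles_by_genotype named list of genotype -> named list of
#'   \code{occupancy_profile} per gene; must contain \code{"WT"}.
#' @param txome a \code{mito_txome}.
#' @param window window length in amino acids.
#' @param anchor window anchor, see [proline_window_labels()].
#' @return data.frame with one row per group 0..3: \code{group},
#'   \code{<genotype>_sum} per genotype and \code{<genotype>_ratio_to_wt}
#'   for each non-WT genotype.
#' @export
proline_window_scores <- function(profiles_by_genotype, txome, window = 5L,
                                  anchor = c("trailing", "centered")) {
  anchor <- match.arg(anchor)
  if (!"WT" %in% names(profiles_by_genotype)) {
    stop("profiles_by_genotype must contain a WT entry")
  }
  genos <- names(profiles_by_genotype)
  genes <- names(profiles_by_genotype[["WT"]])
  labels <- lapply(stats::setNames(genes, genes), function(g)
    proline_window_labels(translate_orf(txome, g), window, anchor))
  groups <- 0:3
  sums <- matrix(0, nrow = length(groups), ncol = length(genos),
                 dimnames = list(groups, genos))
  for (geno in genos) {
    profs <- profiles_by_genotype[[geno]]
    for (g in genes) {
      p <- profs[[g]]
      if (is.null(p)) next
      lab <- labels[[g]]
      rel <- p$rel_within[seq_along(lab)]  # protein codons only
      for (k in groups) {
        sums[as.character(k), geno] <- sums[as.character(k), geno] +
          sum(rel[lab == k])
      }
    }
  }
  out <- data.frame(group = groups)
  for (geno in genos) out[[paste0(tolower(geno), "_sum")]] <- sums[, geno]
  for (geno in setdiff(genos, "WT")) {
    out[[paste0(tolower(geno), "_ratio_to_wt")]] <-
      ifelse(sums[, "WT"] > 0, sums[, geno] / sums[, "WT"], NA_real_)
  }
  out
}

#' Write stall events as TSV
#' @param events output of [call_stall_events()].
#' @param path output path.
#' @param header optional comment line.
#' @export
write_stall_events <- function(events, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
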