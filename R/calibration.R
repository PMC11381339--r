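#' Calibration configuration
#'
#' @param calibration_gene gene whose stop-codon peak anchors the metagene
#'   (default COX1, the most heavily translated ORF with a complete stop).
#' @param plausible_window inclusive bounds for acceptable A-site offsets in
#'   nt from the 5' end; lengths whose diagnostics fall outside are left
#'   unassigned.
#' @param metagene_window half-width in nt of the stop-codon metagene.
#' @return a list of calibration parameters.
#' @export
calibration_config <- function(calibration_gene = "COX1",
                               plausible_window = c(13L, 20L),
                               metagene_window = 40L) {
  list(calibration_gene = calibration_gene,
       plausible_window = as.integer(plausible_window),
       metagene_window = as.integer(metagene_window))
}

# geometric expectation for the A-site offset of a footprint of given
# length: 15 nt for the canonical 32-nt footprint (P-site at +12, A-site
# one codon downstream), shifting with length
geometric_offset <- function(length) 15L + (as.integer(length) - 32L)

#' Stop-codon metagene of footprint 5' ends
#'
#' For each read length, histograms the position of footprint 5' ends
#' relative to the first nucleotide of the stop codon of the calibration
#' gene, over \code{[-window, +window]}. A terminating ribosome holds the
#' stop codon in its A-site, so the 5'-end peak sits at minus the A-site
#' offset for that read length.
#'
#' @param fp a \code{footprints} data.frame.
#' @param txome a \code{mito_txome}.
#' @param gene calibration gene symbol.
#' @param window half-width in nt.
#' @return data.frame (\code{length}, \code{rel_pos}, \code{count}) with
#'   class \code{stop_metagene}; empty if no footprints fall in the window.
#' @export
stop_codon_metagene <- function(fp, txome, gene = "COX1", window = 40L) {
  orf <- orf_row(txome, gene)
  anchor <- stop_codon_start(txome, gene)
  sel <- fp$transcript_id == orf$transcript_id &
    fp$five_prime >= anchor - window & fp$five_prime <= anchor + window
  sub <- fp[sel, , drop = FALSE]
  if (!nrow(sub)) {
    out <- data.frame(length = integer(0), rel_pos = integer(0),
                      count = integer(0))
  } else {
    out <- stats::aggregate(
      count ~ length + rel_pos,
      data = data.frame(length = sub$length,
                        rel_pos = sub$five_prime - anchor,
                        count = sub$count),
      FUN = sum)
    out <- out[order(out$length, out$rel_pos), ]
    rownames(out) <- NULL
  }
  attr(out, "anchor") <- anchor
  attr(out, "gene") <- gene
  class(out) <- c("stop_metagene", "data.frame")
  out
}

# modal relative position per read length; ties broken toward the
# geometric expectation -geometric_offset(length). Returns a data.frame
# with a flag column: "ok", "no_signal" or "no_clear_peak" (flat histogram).
metagene_peaks <- function(mg, lengths) {
  res <- data.frame(length = as.integer(lengths), peak = NA_integer_,
                    flag = "no_signal", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    h <- mg[mg$length == res$length[i], , drop = FALSE]
    if (!nrow(h)) next
    top <- h$rel_pos[h$count == max(h$count)]
    want <- -geometric_offset(res$length[i])
    res$peak[i] <- top[which.min(abs(top - want))]
    flat <- max(h$count) <= 1.5 * stats::median(h$count) && nrow(h) > 3
    res$flag[i] <- if (flat) "no_clear_peak" else "ok"
  }
  res
}

#' Reading-frame distribution of candidate A-sites
#'
#' Applies a candidate 5'-to-A-site offset to every footprint, keeps
#' A-sites falling inside an annotated ORF, and reports the fraction in
#' each reading frame per read length. A correctly chosen offset places the
#' bulk of A-sites in frame 0.
#'
#' @param fp a \code{footprints} data.frame.
#' @param txome a \code{mito_txome}.
#' @param offset_candidate offset in nt to test.
#' @return data.frame (\code{length}, \code{frame0}, \code{frame1},
#'   \code{frame2}, \code{n}); lengths with zero in-ORF A-sites get
#'   \code{NA} fractions.
#' @export
phasing_profile <- function(fp, txome, offset_candidate) {
  lengths <- sort(unique(fp$length))
  out <- data.frame(length = lengths, frame0 = NA_real_, frame1 = NA_real_,
                    frame2 = NA_real_, n = 0L)
  if (!nrow(fp)) return(out)
  asite <- fp$five_prime + as.integer(offset_candidate)
  frame <- rep(NA_integer_, nrow(fp))
  for (i in seq_len(nrow(txome$orfs))) {
    orf <- txome$orfs[i, ]
    span_end <- orf$start + 3L * orf_n_codons(orf)
    in_orf <- fp$transcript_id == orf$transcript_id &
      asite >= orf$start & asite < span_end
    # first ORF wins for frame accounting (overlaps share the frame anyway
    # only when in phase; out-of-phase overlaps are counted once)
    new <- in_orf & is.na(frame)
    frame[new] <- (asite[new] - orf$start) %% 3L
  }
  for (j in seq_along(lengths)) {
    sel <- fp$length == lengths[j] & !is.na(frame)
    n <- sum(fp$count[sel])
    out$n[j] <- n
    if (n > 0) {
      fr <- vapply(0:2, function(k) sum(fp$count[sel & frame == k]), 0)
      out[j, c("frame0", "frame1", "frame2")] <- fr / n
    }
  }
  out
}

#' Calibrate per-read-length A-site offsets
#'
#' Two-step procedure: (1) for each read length, the stop-codon metagene
#' peak of the calibration gene fixes a base offset (minus the peak
#' position); (2) the base offset is adjusted by at most 1 nt to maximise
#' the frame-0 fraction of in-ORF A-sites. Lengths with no metagene signal,
#' or whose adjusted offset falls outside the plausible window, are left
#' unassigned and flagged.
#'
#' @param fp a \code{footprints} data.frame.
#' @param txome a \code{mito_txome}.
#' @param config a [calibration_config()].
#' @return an \code{offset_table}: data.frame (\code{length},
#'   \code{offset}, \code{peak}, \code{frame0}, \code{flag}); unassigned
#'   lengths carry \code{NA} offsets.
#' @export
calibrate_offsets <- function(fp, txome, config = calibration_config()) {
  lengths <- sort(unique(fp$length))
  mg <- stop_codon_metagene(fp, txome, gene = config$calibration_gene,
                            window = config$metagene_window)
  pk <- metagene_peaks(mg, lengths)
  out <- data.frame(length = lengths, offset = NA_integer_,
                    peak = pk$peak, frame0 = NA_real_, flag = pk$flag,
                    stringsAsFactors = FALSE)
  # phasing of every candidate offset in the plausible window, computed once
  win <- config$plausible_window
  cand_offsets <- seq(win[1] - 1L, win[2] + 1L)
  f0 <- matrix(NA_real_, nrow = length(lengths), ncol = length(cand_offsets),
               dimnames = list(lengths, cand_offsets))
  for (k in seq_along(cand_offsets)) {
    ph <- phasing_profile(fp, txome, cand_offsets[k])
    f0[, k] <- ph$frame0[match(lengths, ph$length)]
  }
  for (i in seq_along(lengths)) {
    if (is.na(out$peak[i]) || out$flag[i] != "ok") next
    base <- -out$peak[i]
    cand <- intersect(base + (-1:1), cand_offsets)
    if (!length(cand)) {
      out$flag[i] <- "outside_window"
      next
    }
    fr <- f0[i, as.character(cand)]
    if (all(is.na(fr))) {
      # no in-ORF signal to phase on: keep the metagene answer
      best <- base
    } else {
      top <- cand[!is.na(fr) & fr == max(fr, na.rm = TRUE)]
      # ties: stay closest to the metagene base, then to geometry
      best <- top[order(abs(top - base),
                        abs(top - geometric_offset(lengths[i])))][1]
      out$frame0[i] <- f0[i, as.character(best)]
    }
    if (best < win[1] || best > win[2]) {
      out$flag[i] <- "outside_window"
    } else {
      out$offset[i] <- as.integer(best)
    }
  }
  class(out) <- c("offset_table", "data.frame")
  out
}

#' Named offset lookup from an offset table
#' @param offsets an \code{offset_table}.
#' @return named integer vector (names are read lengths), assigned lengths
#'   only.
#' @export
offset_map <- function(offsets) {
  ok <- !is.na(offsets$offset)
  stats::setNames(as.integer(offsets$offset[ok]),
                  as.character(offsets$length[ok]))
}

#' Write an offset table as TSV
#' @param offsets an \code{offset_table}.
#' @param path output path.
#' @param header optional comment line.
#' @export
write_offset_table <- function(offsets, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(offsets), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
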