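#' Assign footprint A-sites to ORF codons
#'
#' The A-site nucleotide of a footprint is its 5' end plus the calibrated
#' offset for its read length. The A-site is mapped to a codon of every ORF
#' that contains it, so a footprint landing in the overlap of a bicistronic
#' pair (ATP8/ATP6, ND4L/ND4) contributes to both ORF profiles. Footprints
#' whose length has no calibrated offset, or whose A-site falls outside
#' every ORF, are dropped and counted in the drop report.
#'
#' @param fp a \code{footprints} data.frame.
#' @param offsets an \code{offset_table} (or named offset vector).
#' @param txome a \code{mito_txome}.
#' @return data.frame (\code{gene}, \code{codon}, \code{count}) aggregated
#'   over footprints; \code{attr(, "drop_report")} counts \code{input},
#'   \code{assigned}, \code{unassigned_length} and \code{out_of_orf}
#'   footprint counts (a dual-ORF assignment counts once as assigned).
#' @export
assign_asites <- function(fp, offsets, txome) {
  om <- if (inherits(offsets, "offset_table")) offset_map(offsets)
        else offsets
  if (!length(om)) stop("empty offset table")
  total_in <- sum(fp$count)
  known <- as.character(fp$length) %in% names(om)
  n_unassigned <- sum(fp$count[!known])
  fp <- fp[known, , drop = FALSE]
  asite <- fp$five_prime + om[as.character(fp$length)]
  gene <- character(0); codon <- integer(0); count <- integer(0)
  hit <- rep(FALSE, nrow(fp))
  for (i in seq_len(nrow(txome$orfs))) {
    orf <- txome$orfs[i, ]
    span_end <- orf$start + 3L * orf_n_codons(orf)
    in_orf <- fp$transcript_id == orf$transcript_id &
      asite >= orf$start & asite < span_end
    if (any(in_orf)) {
      gene <- c(gene, rep(orf$gene, sum(in_orf)))
      codon <- c(codon, (asite[in_orf] - orf$start) %/% 3L)
      count <- c(count, fp$count[in_orf])
      hit <- hit | in_orf
    }
  }
  n_oo <- sum(fp$count[!hit])
  out <- data.frame(gene = gene, codon = as.integer(codon), count = count,
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- stats::aggregate(count ~ gene + codon, data = out, FUN = sum)
    out <- out[order(out$gene, out$codon), ]
    rownames(out) <- NULL
  }
  attr(out, "drop_report") <- c(input = total_in,
                                assigned = sum(fp$count[hit]),
                                unassigned_length = n_unassigned,
                                out_of_orf = n_oo)
  out
}

#' Build a per-codon occupancy profile for one ORF
#'
#' The vector has one position per codon including the terminal stop, so
#' termination peaks are representable. \code{rel_within} is the count
#' vector normalised to the ORF total (the within-transcript normalisation);
#' it is all-zero when the ORF has no signal.
#'
#' @param assignments output of [assign_asites()].
#' @param gene gene symbol.
#' @param txome a \code{mito_txome}.
#' @param sample sample label.
#' @return an \code{occupancy_profile}: list (\code{gene}, \code{sample},
#'   \code{counts}, \code{rel_within}, \code{n_total}).
#' @export
build_profile <- function(assignments, gene, txome, sample = "sample") {
  orf <- orf_row(txome, gene)
  n <- orf_n_codons(orf)
  counts <- integer(n)
  sub <- assignments[assignments$gene == gene, , drop = FALSE]
  if (nrow(sub)) {
    if (any(sub$codon >= n | sub$codon < 0)) {
      stop("codon index out of range for ", gene,
           ": annotation/profile mismatch")
    }
    counts[sub$codon + 1L] <- sub$count
  }
  n_total <- sum(counts)
  rel <- if (n_total > 0) counts / n_total else rep(0, n)
  structure(list(gene = gene, sample = sample, counts = counts,
                 rel_within = rel, n_total = n_total),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("occupancy_profile:", x$gene, "/", x$sample, "-", length(x$counts),
      "codons,", x$n_total, "A-site counts\n")
  invisible(x)
}

#' Build profiles for every ORF of a transcriptome
#' @param assignments output of [assign_asites()].
#' @param txome a \code{mito_txome}.
#' @param sample sample label.
#' @return named list of \code{occupancy_profile}, one per gene.
#' @export
build_profiles <- function(assignments, txome, sample = "sample") {
  genes <- txome$orfs$gene
  stats::setNames(lapply(genes, function(g)
    build_profile(assignments, g, txome, sample)), genes)
}

#' Across-transcriptome occupancy distribution
#'
#' Per-gene A-site totals normalised to the total over all supplied
#' mitochondrial ORFs (the across-transcriptome normalisation).
#'
#' @param profiles list of \code{occupancy_profile}.
#' @return data.frame (\code{gene}, \code{total}, \code{rel_across});
#'   \code{rel_across} sums to 1.
#' @export
transcriptome_distribution <- function(profiles) {
  totals <- vapply(profiles, function(p) p$n_total, 0)
  grand <- sum(totals)
  if (grand == 0) stop("no mitochondrial signal: all profiles empty")
  data.frame(gene = vapply(profiles, function(p) p$gene, ""),
             total = unname(totals),
             rel_across = unname(totals / grand),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write occupancy profiles as TSV
#' @param profiles list of \code{occupancy_profile}.
#' @param path output path.
#' @param header optional comment line.
#' @export
write_profiles <- function(profiles, path, header = NULL) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(gene = p$gene, sample = p$sample,
               codon = seq_along(p$counts) - 1L,
               count = p$counts, rel_within = p$rel_within)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# pool a list of assignment tables (replicates of one genotype)
pool_assignments <- function(assignment_list) {
  all <- do.call(rbind, assignment_list)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(gene = character(0), codon = integer(0),
                      count = integer(0)))
  }
  out <- stats::aggregate(count ~ gene + codon, data = all, FUN = sum)
  out[order(out$gene, out$codon), ]
}
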