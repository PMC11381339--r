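#' Vertebrate mitochondrial genetic code (translation table 2)
#'
#' The standard genetic code with the four mitochondrial reassignments:
#' \code{TGA} codes for tryptophan, \code{ATA} for methionine, and
#' \code{AGA}/\code{AGG} are stop codons.
#'
#' @return Named character vector of length 64 mapping codons (DNA alphabet)
#'   to one-letter amino acids, with \code{"*"} for stop.
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  code["TGA"] <- "W"
  code["ATA"] <- "M"
  code["AGA"] <- "*"
  code["AGG"] <- "*"
  code
}

#' Load a mitochondrial transcriptome
#'
#' Reads mRNA-sense transcript sequences (FASTA) together with an ORF
#' annotation table (TSV with columns \code{transcript_id}, \code{gene},
#' \code{start}, \code{end}, \code{stop_completed_by_polyA}). Coordinates
#' are 0-based, half-open, on the transcript. ORFs whose stop codon is
#' completed by polyadenylation carry a 1-2 nt partial stop inside
#' \code{[start, end)}; all other ORFs must span a whole number of codons.
#'
#' @param fasta_path path to the transcript FASTA.
#' @param annotation_path path to the ORF annotation TSV.
#' @return An object of class \code{mito_txome}: a list with \code{seqs}
#'   (named character vector of transcript sequences), \code{orfs}
#'   (annotation data.frame) and \code{code} (the mitochondrial code table).
#' @export
load_transcriptome <- function(fasta_path, annotation_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- stats::setNames(as.character(ss), ids)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0) {
      stop("non-ACGTN character in transcript '", ids[i],
           "' at position ", bad)
    }
  }
  orfs <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  needed <- c("transcript_id", "gene", "start", "end",
              "stop_completed_by_polyA")
  missing_cols <- setdiff(needed, names(orfs))
  if (length(missing_cols)) {
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  orfs$start <- as.integer(orfs$start)
  orfs$end <- as.integer(orfs$end)
  orfs$stop_completed_by_polyA <- as.logical(orfs$stop_completed_by_polyA)
  txome <- structure(list(seqs = seqs, orfs = orfs, code = mito_genetic_code()),
                     class = "mito_txome")
  validate_txome(txome)
}

validate_txome <- function(txome) {
  seqs <- txome$seqs
  orfs <- txome$orfs
  if (any(nchar(seqs) < 3)) stop("transcript shorter than 3 nt")
  absent <- setdiff(orfs$transcript_id, names(seqs))
  if (length(absent)) {
    stop("annotation references absent transcript(s): ",
         paste(unique(absent), collapse = ", "))
  }
  if (anyDuplicated(orfs$gene)) {
    stop("duplicate gene symbols in annotation: ",
         paste(unique(orfs$gene[duplicated(orfs$gene)]), collapse = ", "))
  }
  for (i in seq_len(nrow(orfs))) {
    a <- orfs[i, ]
    len <- nchar(seqs[[a$transcript_id]])
    if (a$start < 0 || a$start >= a$end || a$end > len) {
      stop("ORF ", a$gene, " interval [", a$start, ", ", a$end,
           ") outside transcript ", a$transcript_id, " (", len, " nt)")
    }
    if (!a$stop_completed_by_polyA && (a$end - a$start) %% 3L != 0L) {
      stop("ORF ", a$gene, " length not divisible by 3 and not flagged ",
           "stop_completed_by_polyA")
    }
    if (a$stop_completed_by_polyA && (a$end - a$start) %% 3L == 0L) {
      stop("ORF ", a$gene, " flagged stop_completed_by_polyA but spans ",
           "whole codons")
    }
  }
  txome
}

#' @export
print.mito_txome <- function(x, ...) {
  cat("mito_txome:", length(x$seqs), "transcripts,", nrow(x$orfs),
      "ORFs (", paste(x$orfs$gene, collapse = " "), ")\n")
  invisible(x)
}

#' Write a transcriptome back to FASTA + TSV
#'
#' Inverse of [load_transcriptome()]; used for round-trip checks and by the
#' simulator when materialising datasets.
#'
#' @param txome a \code{mito_txome}.
#' @param fasta_path,annotation_path output paths.
#' @export
write_transcriptome <- function(txome, fasta_path, annotation_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(txome$seqs),
                              fasta_path, width = 70)
  utils::write.table(txome$orfs, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

orf_row <- function(txome, gene) {
  i <- match(gene, txome$orfs$gene)
  if (is.na(i)) stop("gene '", gene, "' not in transcriptome")
  txome$orfs[i, ]
}

#' Number of codon positions of an ORF (protein length + terminal stop)
#'
#' For ORFs with a complete stop this is \code{(end - start) / 3}; ORFs
#' ending in a 1-2 nt partial stop completed by polyadenylation count the
#' partial codon as the stop position, so occupancy vectors always have one
#' position per amino acid plus one for the stop codon.
#'
#' @param orf one row of the ORF annotation.
#' @return integer codon count.
#' @export
orf_n_codons <- function(orf) {
  as.integer(ceiling((orf$end - orf$start) / 3))
}

#' Map a transcript nucleotide position to a codon index
#'
#' @param orf one row of the ORF annotation.
#' @param nt_pos 0-based transcript coordinate(s).
#' @return 0-based codon index (\code{floor((nt_pos - start) / 3)}) where
#'   \code{start <= nt_pos < end}, \code{NA} outside the ORF.
#' @export
codon_index <- function(orf, nt_pos) {
  idx <- (nt_pos - orf$start) %/% 3L
  idx[nt_pos < orf$start | nt_pos >= orf$end] <- NA_integer_
  as.integer(idx)
}

#' Translate an ORF under the mitochondrial code
#'
#' Returns the amino-acid sequence without the terminal stop. For ORFs whose
#' stop codon is completed by polyadenylation the trailing partial codon is
#' treated as the stop and not translated. An internal stop codon before the
#' final codon is an error (it indicates a broken annotation).
#'
#' @param txome a \code{mito_txome}.
#' @param gene gene symbol, or an ORF annotation row via \code{orf}.
#' @param orf optional ORF row (overrides \code{gene} lookup).
#' @return protein string.
#' @export
translate_orf <- function(txome, gene = NULL, orf = NULL) {
  if (is.null(orf)) orf <- orf_row(txome, gene)
  nt <- substr(txome$seqs[[orf$transcript_id]], orf$start + 1L, orf$end)
  ncod <- nchar(nt) %/% 3L
  starts <- 3L * (seq_len(ncod) - 1L) + 1L
  aa <- txome$code[substring(nt, starts, starts + 2L)]
  if (!orf$stop_completed_by_polyA) {
    if (aa[ncod] != "*") {
      stop("ORF ", orf$gene, " does not end in a stop codon")
    }
    aa <- aa[-ncod]
  }
  internal <- which(aa == "*")
  if (length(internal)) {
    stop("internal stop codon in ORF ", orf$gene, " at codon index ",
         internal[1] - 1L)
  }
  paste(aa, collapse = "")
}

#' Translate every ORF of a transcriptome
#'
#' @param txome a \code{mito_txome}.
#' @return named character vector, gene -> protein.
#' @export
txome_proteome <- function(txome) {
  stats::setNames(
    vapply(txome$orfs$gene, function(g) translate_orf(txome, g), ""),
    txome$orfs$gene)
}

#' 0-based transcript coordinate of the first stop-codon nucleotide
#' @param txome a \code{mito_txome}.
#' @param gene gene symbol.
#' @return integer transcript coordinate.
#' @export
stop_codon_start <- function(txome, gene) {
  orf <- orf_row(txome, gene)
  orf$start + 3L * (orf_n_codons(orf) - 1L)
}

#' Bundled fixture paths
#'
#' \code{mito_fixture("human")} returns the FASTA + annotation paths of the
#' bundled 13-ORF human mitochondrial transcriptome (derived from the
#' complete human mtDNA genome NC_001807.4); \code{mito_fixture("yeast")}
#' returns the path of the bundled synthetic stand-in for the S. cerevisiae
#' mtDNA-encoded proteome (amino-acid FASTA; see
#' \code{data-raw/build_fixtures.R} for how it was constructed).
#'
#' @param which \code{"human"}, \code{"yeast"}, \code{"pausing_scores"} or
#'   \code{"taco1_motifs"}.
#' @return a named character vector of file paths.
#' @export
mito_fixture <- function(which = c("human", "yeast", "pausing_scores",
                                   "taco1_motifs")) {
  which <- match.arg(which)
  f <- function(...) system.file("extdata", ..., package = "mitoribostall",
                                 mustWork = TRUE)
  switch(which,
    human = c(fasta = f("human_mito_transcripts.fasta"),
              annotation = f("human_mito_orfs.tsv")),
    yeast = c(fasta = f("yeast_mito_proteome_synthetic.fasta")),
    pausing_scores = c(tsv = f("pausing_scores.tsv")),
    taco1_motifs = c(tsv = f("taco1_target_motifs.tsv")))
}

#' Load the bundled human mitochondrial transcriptome
#' @return a \code{mito_txome} with the 13 protein-coding ORFs.
#' @export
load_human_txome <- function() {
  p <- mito_fixture("human")
  load_transcriptome(p[["fasta"]], p[["annotation"]])
}

#' Load a proteome from an amino-acid FASTA
#' @param fasta_path path to a protein FASTA.
#' @return named character vector, gene -> protein.
#' @export
load_proteome <- function(fasta_path) {
  ss <- Biostrings::readAAStringSet(fasta_path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
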