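#' Construct a footprint table
#'
#' Footprints are aligned ribosome-protected fragments in transcript space:
#' a transcript id, the 0-based coordinate of the 5' end, the aligned length
#' in nt, and a multiplicity count. Identical records are aggregated.
#'
#' @param transcript_id,five_prime,length,count vectors of equal length
#'   (count defaults to 1).
#' @return a data.frame with class \code{footprints}.
#' @export
footprints <- function(transcript_id, five_prime, length,
                       count = rep(1L, base::length(transcript_id))) {
  fp <- data.frame(transcript_id = as.character(transcript_id),
                   five_prime = as.integer(five_prime),
                   length = as.integer(length),
                   count = as.integer(count),
                   stringsAsFactors = FALSE)
  if (nrow(fp)) {
    if (any(fp$five_prime < 0)) stop("negative five_prime coordinate")
    if (any(fp$count < 1)) stop("footprint count < 1")
    fp <- stats::aggregate(count ~ transcript_id + five_prime + length,
                           data = fp, FUN = sum)
    fp <- fp[order(fp$transcript_id, fp$five_prime, fp$length), ]
    rownames(fp) <- NULL
  }
  class(fp) <- c("footprints", "data.frame")
  fp
}

#' Read aligned footprints
#'
#' Two dialects are supported. The native bed-like TSV has four columns
#' (\code{transcript_id}, \code{five_prime}, \code{length}, \code{count});
#' lines starting with \code{#} are ignored. The SAM dialect reads a text
#' SAM subset: primary mapped forward-strand records only; the footprint
#' length is the aligned reference span (soft clips excluded). Reverse-strand
#' alignments are rejected (transcripts are single-stranded), as are records
#' extending past the transcript end when a transcriptome is supplied;
#' rejections are returned in \code{attr(, "rejected")}.
#'
#' @param path input file.
#' @param format \code{"bed"} or \code{"sam"}.
#' @param txome optional \code{mito_txome} for bounds checking.
#' @return a \code{footprints} data.frame; attribute \code{rejected} is a
#'   named integer vector of rejection counts.
#' @export
read_footprints <- function(path, format = c("bed", "sam"), txome = NULL) {
  format <- match.arg(format)
  if (format == "bed") {
    fp <- read_footprints_bed(path)
    rejected <- c(reverse_strand = 0L, out_of_bounds = 0L)
  } else {
    res <- read_footprints_sam(path)
    fp <- res$fp
    rejected <- res$rejected
  }
  if (!is.null(txome) && nrow(fp)) {
    unknown <- !(fp$transcript_id %in% names(txome$seqs))
    if (any(unknown)) {
      stop("footprints reference unknown transcript(s): ",
           paste(unique(fp$transcript_id[unknown]), collapse = ", "))
    }
    lens <- nchar(txome$seqs)[fp$transcript_id]
    oob <- fp$five_prime + fp$length > lens
    rejected[["out_of_bounds"]] <- rejected[["out_of_bounds"]] +
      sum(fp$count[oob])
    fp <- fp[!oob, , drop = FALSE]
    rownames(fp) <- NULL
    class(fp) <- c("footprints", "data.frame")
  }
  attr(fp, "rejected") <- rejected
  fp
}

read_footprints_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(footprints(character(0), integer(0), integer(0)))
  parts <- strsplit(lines, "[\t ]+")
  nfield <- lengths(parts)
  bad <- which(nfield != 4L)
  if (length(bad)) {
    stop("malformed footprint record at line ", lineno[bad[1]],
         ": expected 4 fields, got ", nfield[bad[1]])
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 2:4, drop = FALSE], 2, as.integer))
  num <- matrix(num, ncol = 3)
  bad <- which(apply(is.na(num), 1, any))
  if (length(bad)) {
    stop("malformed footprint record at line ", lineno[bad[1]],
         ": non-integer field")
  }
  footprints(m[, 1], num[, 1], num[, 2], num[, 3])
}

read_footprints_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- rec$flag
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  reverse <- bitwAnd(flag, 16L) > 0L
  keep <- !secondary & !unmapped & !reverse
  n_rev <- sum(!secondary & !unmapped & reverse)
  if (!any(keep)) {
    fp <- footprints(character(0), integer(0), integer(0))
  } else {
    span <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
    fp <- footprints(as.character(rec$rname[keep]),
                     rec$pos[keep] - 1L,  # SAM POS is 1-based
                     span)
  }
  list(fp = fp, rejected = c(reverse_strand = n_rev, out_of_bounds = 0L))
}

#' Write footprints as bed-like TSV
#' @param fp a \code{footprints} data.frame.
#' @param path output path.
#' @param header optional comment line (written prefixed with \code{#}).
#' @export
write_footprints <- function(fp, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(fp)) {
    writeLines(paste(fp$transcript_id, fp$five_prime, fp$length, fp$count,
                     sep = "\t"), con)
  }
  invisible(NULL)
}

#' Filter footprints by read length
#'
#' Keeps footprints with \code{min_len <= length <= max_len} (defaults 25
#' and 45 nt, the bounds defining the analysis universe after adapter
#' trimming), preserving order.
#'
#' @param fp a \code{footprints} data.frame.
#' @param min_len,max_len inclusive length bounds in nt.
#' @return the filtered \code{footprints}; \code{attr(, "removed_count")}
#'   holds the aggregate count removed.
#' @export
filter_lengths <- function(fp, min_len = 25L, max_len = 45L) {
  if (min_len > max_len) stop("min_len > max_len")
  keep <- fp$length >= min_len & fp$length <= max_len
  out <- fp[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("footprints", "data.frame")
  attr(out, "removed_count") <- sum(fp$count[!keep])
  out
}

#' Exact-match alignment of synthetic reads
#'
#' A naive aligner for simulator-generated reads only: each read must occur
#' as an exact substring of exactly one transcript at exactly one position.
#' Reads with zero or multiple matches are dropped and counted.
#'
#' @param reads character vector of read sequences.
#' @param txome a \code{mito_txome}.
#' @return a \code{footprints} data.frame; \code{attr(, "report")} counts
#'   \code{aligned}, \code{unaligned} and \code{ambiguous} reads.
#' @export
align_exact <- function(reads, txome) {
  subject <- Biostrings::DNAStringSet(txome$seqs)
  tx_id <- character(0); pos <- integer(0); len <- integer(0)
  n_un <- 0L; n_amb <- 0L
  for (r in reads) {
    m <- Biostrings::vmatchPattern(r, subject)
    hits <- elementNROWS_list(m)
    total <- sum(hits)
    if (total == 0L) {
      n_un <- n_un + 1L
    } else if (total > 1L) {
      n_amb <- n_amb + 1L
    } else {
      i <- which(hits == 1L)
      tx_id <- c(tx_id, names(txome$seqs)[i])
      pos <- c(pos, Biostrings::startIndex(m)[[i]][1] - 1L)
      len <- c(len, nchar(r))
    }
  }
  fp <- footprints(tx_id, pos, len)
  attr(fp, "report") <- c(aligned = length(tx_id), unaligned = n_un,
                          ambiguous = n_amb)
  fp
}

elementNROWS_list <- function(m) {
  vapply(Biostrings::startIndex(m),
         function(x) if (is.null(x)) 0L else length(x), 0L)
}
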