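# 3' adapter trimming for single-end small-RNA reads, with the classic
# stringency / error-rate / minimum-length contract.

#' Adapter trimming parameters
#'
#' @param adapter 3' adapter sequence.
#' @param stringency Minimum overlap (nt) between a read suffix and the
#'   adapter prefix for a trim to trigger (default 3).
#' @param error_rate Maximum mismatch fraction within the overlap, counted
#'   as Hamming distance (default 0.2).
#' @param min_length Reads shorter than this after trimming are dropped
#'   (default 20).
#' @return A validated list of class `trim_params`.
#' @export
trim_params <- function(adapter = "TGGAATTCTCGGGTGCCAAGGA", stringency = 3L,
                        error_rate = 0.2, min_length = 20L) {
  if (stringency < 1L) stop("stringency must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (min_length < 1L) stop("min_length must be >= 1")
  structure(list(adapter = normalize_dna(adapter),
                 stringency = as.integer(stringency),
                 error_rate = error_rate, min_length = as.integer(min_length)),
            class = "trim_params")
}

# For each read, the 0-based position at which the adapter match starts
# (read length if none). At candidate position p the read segment
# read[p .. p+o) is compared against the adapter prefix of length
# o = min(read_len - p, adapter_len); a candidate qualifies when o >=
# stringency and mismatches <= floor(error_rate * o). The earliest
# qualifying position wins (ties resolve toward the more-trimmed read).
adapter_match_pos <- function(seqs, params) {
  ad <- strsplit(params$adapter, "", fixed = TRUE)[[1]]
  alen <- length(ad)
  out <- integer(length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    mat <- matrix(unlist(strsplit(seqs[idx], "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
    pos <- rep(L, length(idx))
    open <- seq_along(idx)
    for (p in seq_len(L)) {                 # candidate start, 1-based
      if (!length(open)) break
      o <- min(L - p + 1L, alen)
      if (o < params$stringency) break
      max_mm <- floor(params$error_rate * o)
      mm <- rowSums(mat[open, p:(p + o - 1L), drop = FALSE] !=
                      matrix(ad[1:o], nrow = length(open), ncol = o, byrow = TRUE))
      hit <- mm <= max_mm
      pos[open[hit]] <- p - 1L
      open <- open[!hit]
    }
    out[idx] <- pos
  }
  out
}

#' Trim the 3' adapter from reads
#'
#' Scans each read for the earliest position where its 3' remainder matches
#' a prefix of the adapter (full internal adapter occurrences and partial
#' terminal ones alike) and removes everything from that position onward.
#' The scan is repeated until no further match remains, which makes
#' trimming idempotent (a newly exposed 3' end can itself qualify); reads
#' shorter than `min_length` after trimming are dropped.
#'
#' @param seqs Character vector of read sequences.
#' @param params A [trim_params()].
#' @return data.frame with columns `sequence` (trimmed), `kept` (logical),
#'   and `trimmed` (logical: was anything removed).
#' @export
trim_reads <- function(seqs, params = trim_params()) {
  if (!length(seqs)) {
    return(data.frame(sequence = character(0), kept = logical(0),
                      trimmed = logical(0)))
  }
  if (any(nchar(seqs) == 0L)) stop("empty read")
  trimmed_seq <- seqs
  active <- which(nchar(trimmed_seq) > 0L)
  while (length(active)) {
    pos <- adapter_match_pos(trimmed_seq[active], params)
    changed <- pos < nchar(trimmed_seq[active])
    trimmed_seq[active] <- substr(trimmed_seq[active], 1L, pos)
    active <- active[changed & nchar(trimmed_seq[active]) > 0L]
  }
  data.frame(sequence = trimmed_seq,
             kept = nchar(trimmed_seq) >= params$min_length,
             trimmed = nchar(trimmed_seq) < nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Trim a FASTQ file
#'
#' @param path_in Input FASTQ.
#' @param params A [trim_params()].
#' @param path_out Output FASTQ (default: input with `.trimmed.fastq`).
#' @return List with `path`, and `stats`: a one-row data.frame
#'   (n_in, n_kept, n_dropped, n_trimmed); `n_in = n_kept + n_dropped`.
#' @export
trim_fastq <- function(path_in, params = trim_params(), path_out = NULL) {
  if (is.null(path_out)) {
    path_out <- sub("\\.(fastq|fq)(\\.gz)?$", "", path_in)
    path_out <- paste0(path_out, ".trimmed.fastq")
  }
  reads <- read_fastq(path_in)
  tr <- trim_reads(reads$sequence, params)
  kept <- which(tr$kept)
  out <- data.frame(read_id = reads$read_id[kept],
                    sequence = tr$sequence[kept],
                    quality = substr(reads$quality[kept], 1L,
                                     nchar(tr$sequence[kept])),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    write_fastq(out, path_out)
  } else {
    file.create(path_out)
  }
  stats <- data.frame(n_in = nrow(reads), n_kept = length(kept),
                      n_dropped = nrow(reads) - length(kept),
                      n_trimmed = sum(tr$trimmed))
  list(path = path_out, stats = stats)
}
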