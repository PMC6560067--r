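# Three-pass bisulfite-aware alignment.
#
# Pass 1: end-to-end conversion-tolerant scan of the sense-strand genomic
#         locus views (exhaustive; the reference is desk-scale).
# Pass 2: unaligned/ambiguous reads are re-tried after clipping the last
#         three bases (a potential tRNA CCA tail, absent from the genome).
# Pass 3: reads still unaligned are matched against the splice-junction
#         library, then converted back to genomic coordinates with the
#         intron gap written as a D cigar operation.

INT_A <- utf8ToInt("A"); INT_C <- utf8ToInt("C")
INT_T <- utf8ToInt("T"); INT_N <- utf8ToInt("N")

#' Alignment parameters
#'
#' @param max_mismatch Maximum number of non-conversion mismatches for a
#'   valid alignment (default 2).
#' @param min_length Reads shorter than this after CCA clipping are
#'   discarded (default 20, matching the trimming rule).
#' @param clip Number of 3' bases removed before the second pass (default 3,
#'   the CCA tail length).
#' @return A validated list of class `align_params`.
#' @export
align_params <- function(max_mismatch = 2L, min_length = 20L, clip = 3L) {
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  structure(list(max_mismatch = as.integer(max_mismatch),
                 min_length = as.integer(min_length), clip = as.integer(clip)),
            class = "align_params")
}

#' Bisulfite mismatch count between a read and a reference window
#'
#' A position matches when the bases are equal, or when the reference base
#' is C and the read base is T (bisulfite conversion). A read C over a
#' reference T is a mismatch (the conversion rule is asymmetric), and an N
#' in the read matches nothing.
#'
#' @param read,ref_window Equal-length sequences.
#' @return Integer mismatch count.
#' @export
bs_mismatch_count <- function(read, ref_window) {
  if (nchar(read) != nchar(ref_window)) stop("length mismatch")
  q <- utf8ToInt(normalize_dna(read))
  r <- utf8ToInt(normalize_dna(ref_window))
  ok <- ((q == r) | (r == INT_C & q == INT_T)) & q != INT_N
  sum(!ok)
}

# Full mismatch matrix for a block of equal-length reads against one
# reference sequence: (n_offsets x n_reads). tmat is the L x n transposed
# integer read matrix.
scan_mm_matrix <- function(tmat, ref) {
  L <- nrow(tmat); n <- ncol(tmat); N <- length(ref)
  n_off <- N - L + 1L
  if (n_off < 1L) return(NULL)
  mm <- matrix(0L, nrow = n_off, ncol = n)
  valid <- tmat != INT_N
  for (o in seq_len(n_off)) {
    w <- ref[o:(o + L - 1L)]
    ok <- ((tmat == w) | (w == INT_C & tmat == INT_T)) & valid
    mm[o, ] <- L - .colSums(ok, L, n)
  }
  mm
}

reads_int_matrix <- function(seqs) {
  L <- nchar(seqs[1L])
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)  # L x n
}

empty_outcomes <- function() {
  data.frame(read_id = character(0), class = character(0), pass = integer(0),
             contig = character(0), start = integer(0), strand = character(0),
             cigar = character(0), bs_mismatches = integer(0),
             clipped_tail = integer(0), space_type = character(0),
             space_id = character(0), space_offset = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

outcome_row <- function(read_id, class, pass, sequence, clipped = 0L,
                        contig = NA_character_, start = NA_integer_,
                        strand = NA_character_, cigar = NA_character_,
                        mm = NA_integer_, space_type = NA_character_,
                        space_id = NA_character_, space_offset = NA_integer_) {
  data.frame(read_id = read_id, class = class, pass = as.integer(pass),
             contig = contig, start = start, strand = strand, cigar = cigar,
             bs_mismatches = mm, clipped_tail = as.integer(clipped),
             space_type = space_type, space_id = space_id,
             space_offset = space_offset, sequence = sequence,
             stringsAsFactors = FALSE)
}

# Genomic-space alignment of a reads data.frame (read_id, sequence) against
# the locus views; shared by passes 1 and 2. Vectorized over reads of equal
# length; only reads with tied best hits take a slow per-read path (ties
# must be deduplicated by genomic key before the ambiguity call, since two
# overlapping locus views can expose the same genomic position twice).
align_genomic <- function(reads, reference, params, pass, clipped = 0L) {
  if (!length(reference$spaces)) stop("empty reference")
  if (!nrow(reads)) return(empty_outcomes())
  if (any(nchar(reads$sequence) < 1L)) stop("reads must be >= 1 nt")
  space_ints <- lapply(reference$spaces, function(s) utf8ToInt(s$sequence))
  out <- vector("list", 0L)
  for (L in unique(nchar(reads$sequence))) {
    idx <- which(nchar(reads$sequence) == L)
    n <- length(idx)
    tmat <- reads_int_matrix(reads$sequence[idx])
    mms <- lapply(space_ints, function(ref) scan_mm_matrix(tmat, ref))
    keep <- !vapply(mms, is.null, logical(1))
    snames <- names(reference$spaces)[keep]
    mms <- mms[keep]
    col_mins <- function(m) do.call(pmin, lapply(seq_len(nrow(m)),
                                                 function(i) m[i, ]))
    gbest <- if (length(mms)) {
      do.call(pmin, lapply(mms, col_mins))
    } else rep(Inf, n)

    cnt_tot <- numeric(n)
    hit_space <- rep(NA_character_, n)
    hit_off <- rep(NA_integer_, n)
    for (si in seq_along(mms)) {
      eq <- mms[[si]] == matrix(gbest, nrow(mms[[si]]), n, byrow = TRUE)
      cnt_s <- .colSums(eq, nrow(eq), n)
      cnt_tot <- cnt_tot + cnt_s
      fresh <- cnt_s > 0 & is.na(hit_space)
      if (any(fresh)) {
        first_off <- max.col(t(eq[, fresh, drop = FALSE]),
                             ties.method = "first") - 1L
        hit_space[fresh] <- snames[si]
        hit_off[fresh] <- first_off
      }
    }

    aligned <- is.finite(gbest) & gbest <= params$max_mismatch
    class <- ifelse(!aligned, "unaligned",
                    ifelse(cnt_tot == 1, "unique", "tied"))

    # tied reads: enumerate hits, dedupe by genomic key
    for (k in which(class == "tied")) {
      hits <- list()
      for (si in seq_along(mms)) {
        offs <- which(mms[[si]][, k] == gbest[k]) - 1L
        if (!length(offs)) next
        sp <- reference$spaces[[snames[si]]]
        gstart <- if (sp$strand == "+") sp$start + offs else sp$end - offs - L
        hits[[length(hits) + 1L]] <- data.frame(
          space = sp$space_id, off = offs, contig = sp$contig, start = gstart,
          strand = sp$strand, stringsAsFactors = FALSE)
      }
      hits <- do.call(rbind, hits)
      hits <- hits[!duplicated(paste(hits$contig, hits$start, hits$strand)), ,
                   drop = FALSE]
      if (nrow(hits) == 1L) {
        class[k] <- "unique"
        hit_space[k] <- hits$space[1L]
        hit_off[k] <- as.integer(hits$off[1L])
      } else {
        class[k] <- "ambiguous"
      }
    }

    sp_contig <- vapply(reference$spaces, `[[`, character(1), "contig")
    sp_start <- vapply(reference$spaces, `[[`, numeric(1), "start")
    sp_end <- vapply(reference$spaces, `[[`, numeric(1), "end")
    sp_strand <- vapply(reference$spaces, `[[`, character(1), "strand")
    is_u <- class == "unique"
    contig <- rep(NA_character_, n); start <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)
    if (any(is_u)) {
      si <- match(hit_space[is_u], names(reference$spaces))
      contig[is_u] <- sp_contig[si]
      strand[is_u] <- sp_strand[si]
      start[is_u] <- as.integer(ifelse(sp_strand[si] == "+",
                                       sp_start[si] + hit_off[is_u],
                                       sp_end[si] - hit_off[is_u] - L))
    }
    out[[length(out) + 1L]] <- data.frame(
      read_id = reads$read_id[idx], class = class, pass = as.integer(pass),
      contig = contig, start = start, strand = strand,
      cigar = ifelse(is_u, paste0(L, "M"), NA_character_),
      bs_mismatches = ifelse(aligned, as.integer(gbest), NA_integer_),
      clipped_tail = as.integer(clipped),
      space_type = ifelse(is_u, "locus", NA_character_),
      space_id = ifelse(is_u, hit_space, NA_character_),
      space_offset = ifelse(is_u, hit_off, NA_integer_),
      sequence = reads$sequence[idx], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(reads$read_id, res$read_id), , drop = FALSE]
}

#' First alignment pass: conversion-tolerant genomic alignment
#'
#' Exhaustive end-to-end scan of every offset of every sense-strand locus
#' view. A read with a single best locus within `max_mismatch` is `unique`;
#' two or more loci tied at the best score make it `ambiguous` (mirroring an
#' aligner's separate ambiguous output); otherwise it is `unaligned`.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param reference A `bs_reference`.
#' @param params An [align_params()].
#' @return Outcome data.frame, one row per read: `class`
#'   (`unique`/`ambiguous`/`unaligned`), genomic record fields for unique
#'   hits (`contig`, `start`, `strand`, `cigar`, `bs_mismatches`), the pass
#'   label, clip state, and the aligned (possibly clipped) sequence.
#' @export
align_pass1 <- function(reads, reference, params = align_params()) {
  align_genomic(reads, reference, params, pass = 1L, clipped = 0L)
}

#' Second pass: clip a potential CCA tail and realign
#'
#' Removes the last `params$clip` bases from pass-1 unaligned and ambiguous
#' reads (tRNA CCA tails are added post-transcriptionally and are absent
#' from the genome) and realigns. Reads shorter than `params$min_length`
#' after clipping are `discarded_short`.
#'
#' @param failed Outcome rows (or a reads data.frame) of pass-1
#'   unaligned/ambiguous reads.
#' @inheritParams align_pass1
#' @return Outcome data.frame with `pass = 2` and `clipped_tail` set.
#' @export
clip_and_realign <- function(failed, reference, params = align_params()) {
  if (!nrow(failed)) return(empty_outcomes())
  clipped_seq <- substr(failed$sequence, 1L,
                        pmax(nchar(failed$sequence) - params$clip, 0L))
  short <- nchar(clipped_seq) < params$min_length
  out <- empty_outcomes()
  if (any(short)) {
    out <- data.frame(
      read_id = failed$read_id[short], class = "discarded_short", pass = 2L,
      contig = NA_character_, start = NA_integer_, strand = NA_character_,
      cigar = NA_character_, bs_mismatches = NA_integer_,
      clipped_tail = params$clip, space_type = NA_character_,
      space_id = NA_character_, space_offset = NA_integer_,
      sequence = clipped_seq[short], stringsAsFactors = FALSE)
  }
  if (any(!short)) {
    reads2 <- data.frame(read_id = failed$read_id[!short],
                         sequence = clipped_seq[!short],
                         stringsAsFactors = FALSE)
    res <- align_genomic(reads2, reference, params, pass = 2L,
                         clipped = params$clip)
    out <- rbind(out, res)
  }
  out[match(failed$read_id, out$read_id), , drop = FALSE]
}

#' Convert a junction-library alignment back to genomic coordinates
#'
#' The genomic start is the coordinate of the first aligned base in the left
#' flank block; the intron gap between the two exon blocks becomes a `D`
#' cigar operation (abutting blocks with gap 0 merge into a single `M`).
#'
#' @param junction_record List or one-row data.frame with `junction_id`,
#'   `offset` (0-based within the junction sequence) and `read_length`.
#' @param junction_library The `junctions` table of a `bs_reference`.
#' @return List with `contig`, `start`, `strand`, `cigar`.
#' @export
convert_to_genomic <- function(junction_record, junction_library) {
  j <- junction_library[junction_library$junction_id ==
                          junction_record$junction_id, , drop = FALSE]
  if (nrow(j) != 1L) stop("unknown junction '", junction_record$junction_id, "'")
  off <- as.integer(junction_record$offset)
  L <- as.integer(junction_record$read_length)
  flank <- j$flank_len
  left <- flank - off
  right <- L - left
  if (left < 1L || right < 1L) {
    stop("aligned segment does not straddle the junction")
  }
  if (off < 0L || off + L > 2L * flank) {
    stop("aligned segment falls outside the junction flanks")
  }
  gap <- j$right_start - j$left_end
  cigar <- if (gap == 0L) paste0(L, "M") else
    paste0(left, "M", gap, "D", right, "M")
  list(contig = j$contig, start = as.integer(j$left_start + off),
       strand = "+", cigar = cigar)
}

#' Third pass: alignment to the splice-junction library
#'
#' Pass-1-style scan of the junction sequences. Only hits that straddle the
#' junction boundary by at least one base on each flank count (a read lying
#' entirely within one flank is genomic and has already had its chance);
#' a single best straddling hit is converted to a genomic record with
#' [convert_to_genomic()].
#'
#' @param failed Outcome rows of pass-2 unaligned reads.
#' @inheritParams align_pass1
#' @return Outcome data.frame with `pass = 3`.
#' @export
junction_align <- function(failed, reference, params = align_params()) {
  if (!nrow(failed)) return(empty_outcomes())
  jl <- reference$junctions
  out <- vector("list", 0L)
  jl_ints <- if (nrow(jl)) lapply(jl$sequence, utf8ToInt) else list()
  for (L in unique(nchar(failed$sequence))) {
    idx <- which(nchar(failed$sequence) == L)
    tmat <- reads_int_matrix(failed$sequence[idx])
    mms <- lapply(jl_ints, function(ref) scan_mm_matrix(tmat, ref))
    for (k in seq_along(idx)) {
      rid <- failed$read_id[idx[k]]
      seq_k <- failed$sequence[idx[k]]
      clip_k <- failed$clipped_tail[idx[k]]
      # candidate = straddling offset within mismatch budget
      cand <- list()
      for (ji in seq_along(mms)) {
        if (is.null(mms[[ji]])) next
        flank <- jl$flank_len[ji]
        offs <- which(mms[[ji]][, k] <= params$max_mismatch) - 1L
        offs <- offs[offs < flank & offs + L > flank]
        for (o in offs) {
          cand[[length(cand) + 1L]] <- list(ji = ji, off = o,
                                            mm = mms[[ji]][o + 1L, k])
        }
      }
      if (!length(cand)) {
        out[[length(out) + 1L]] <- outcome_row(rid, "unaligned", 3L, seq_k,
                                               clip_k)
        next
      }
      mmv <- vapply(cand, `[[`, numeric(1), "mm")
      best <- cand[mmv == min(mmv)]
      if (length(best) > 1L) {
        out[[length(out) + 1L]] <- outcome_row(rid, "ambiguous", 3L, seq_k,
                                               clip_k, mm = as.integer(min(mmv)))
        next
      }
      h <- best[[1L]]
      g <- convert_to_genomic(list(junction_id = jl$junction_id[h$ji],
                                   offset = h$off, read_length = L), jl)
      out[[length(out) + 1L]] <- outcome_row(
        rid, "unique", 3L, seq_k, clip_k, contig = g$contig, start = g$start,
        strand = g$strand, cigar = g$cigar, mm = as.integer(h$mm),
        space_type = "junction", space_id = jl$junction_id[h$ji],
        space_offset = as.integer(h$off))
    }
  }
  res <- do.call(rbind, out)
  res[match(failed$read_id, res$read_id), , drop = FALSE]
}

#' Run the full three-pass alignment
#'
#' @inheritParams align_pass1
#' @return Outcome data.frame with exactly one row per input read; the
#'   attribute `"summary"` carries per-pass read counts. Classes partition
#'   the input: `unique`, `ambiguous`, `unaligned`, `discarded_short`.
#' @export
align_reads <- function(reads, reference, params = align_params()) {
  p1 <- align_pass1(reads, reference, params)
  failed1 <- p1[p1$class %in% c("unaligned", "ambiguous"), , drop = FALSE]
  p2 <- clip_and_realign(failed1, reference, params)
  failed2 <- p2[p2$class == "unaligned", , drop = FALSE]
  p3 <- junction_align(failed2, reference, params)

  final <- rbind(
    p1[p1$class == "unique", , drop = FALSE],
    p2[p2$class %in% c("unique", "ambiguous", "discarded_short"), , drop = FALSE],
    p3
  )
  final <- final[match(reads$read_id, final$read_id), , drop = FALSE]
  stopifnot(nrow(final) == nrow(reads), !anyNA(final$class))
  attr(final, "summary") <- data.frame(
    n_in = nrow(reads),
    unique = sum(final$class == "unique"),
    ambiguous = sum(final$class == "ambiguous"),
    unaligned = sum(final$class == "unaligned"),
    discarded_short = sum(final$class == "discarded_short")
  )
  final
}

#' Write unique alignment records as SAM
#'
#' Cigar strings use `M`/`D` only (junction skips as `D`, the convention the
#' downstream methylation extractor expects). Custom tags: `XP` pass label,
#' `XC` clipped tail length, `XM` bisulfite mismatch count. Minus-strand
#' records store the transcript-sense sequence and set flag 16.
#'
#' @param outcomes Outcome data.frame from [align_reads()].
#' @param reference A `bs_reference` (for the header contig lines).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(outcomes, reference, path) {
  u <- outcomes[outcomes$class == "unique", , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference$genome),
                   nchar(reference$genome)))
  body <- if (nrow(u)) {
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tXP:i:%d\tXC:i:%d\tXM:i:%d",
            u$read_id, ifelse(u$strand == "-", 16L, 0L), u$contig,
            u$start + 1L, u$cigar, u$sequence, strrep("I", nchar(u$sequence)),
            u$pass, u$clipped_tail, u$bs_mismatches)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file written by [write_sam()]
#'
#' @param path SAM path.
#' @return data.frame of unique records (read_id, contig, start, strand,
#'   cigar, sequence, pass, clipped_tail, bs_mismatches).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), strand = character(0),
                      cigar = character(0), sequence = character(0),
                      pass = integer(0), clipped_tail = integer(0),
                      bs_mismatches = integer(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tag <- function(x, name) {
    v <- grep(paste0("^", name, ":i:"), x, value = TRUE)
    if (length(v)) as.integer(sub(paste0(name, ":i:"), "", v)) else NA_integer_
  }
  do.call(rbind, lapply(f, function(x) {
    data.frame(read_id = x[1], contig = x[3], start = as.integer(x[4]) - 1L,
               strand = if (bitwAnd(as.integer(x[2]), 16L) > 0L) "-" else "+",
               cigar = x[6], sequence = x[10], pass = tag(x, "XP"),
               clipped_tail = tag(x, "XC"), bs_mismatches = tag(x, "XM"),
               stringsAsFactors = FALSE)
  }))
}
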