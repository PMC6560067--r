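# Reference data model: transcripts, genomic placement, annotated cytosines,
# and the splice-junction library used by the third alignment pass.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide sequences
#'
#' Watson-Crick reverse complement. The alphabet of the input is preserved:
#' RNA input (containing U/u) yields RNA output, DNA input yields DNA output,
#' and letter case travels with each base.
#'
#' @param seq Character vector of sequences over `ACGTUacgtu`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("CGAGACCCGCGGGCGCUCUCCAGUCCUUUU")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTUacgtu]", seq)
  if (any(bad)) {
    stop("non-nucleotide character in sequence: ", seq[bad][1L])
  }
  is_rna <- grepl("[Uu]", seq)
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", seq)
  out <- vapply(
    strsplit(comp, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""),
    character(1)
  )
  out[is_rna] <- chartr("Tt", "Uu", out[is_rna])
  unname(out)
}

# Canonical internal comparison space is DNA: U -> T, uppercase.
normalize_dna <- function(seq, allow_n = TRUE) {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, s)
  if (any(bad)) stop("sequence contains non-ACGT", if (allow_n) "N", " characters")
  s
}

#' Locate a fragment (or its reverse complement) within a parent sequence
#'
#' Reports every exact occurrence of `fragment` or its reverse complement in
#' `parent`, e.g. to map a small vault-RNA-derived fragment (svRNA) back onto
#' its full-length parent RNA. Both sequences are compared in DNA space
#' (U normalized to T), so RNA and DNA input mix freely.
#'
#' @param parent_seq,fragment_seq Non-empty nucleotide strings.
#' @return A data.frame with columns `offset` (0-based) and `strand`
#'   (`"+"` for a sense match, `"-"` for a reverse-complement match), sorted
#'   by offset. Zero rows when the fragment is absent.
#' @export
locate_fragment <- function(parent_seq, fragment_seq) {
  parent <- normalize_dna(parent_seq, allow_n = FALSE)
  frag <- normalize_dna(fragment_seq, allow_n = FALSE)
  if (nchar(parent) == 0L || nchar(frag) == 0L) {
    stop("parent and fragment must be non-empty")
  }
  subject <- Biostrings::DNAString(parent)
  hit_starts <- function(pattern) {
    if (nchar(pattern) > nchar(parent)) return(integer(0))
    BiocGenerics::start(Biostrings::matchPattern(Biostrings::DNAString(pattern), subject))
  }
  fwd <- hit_starts(frag)
  rev_ <- hit_starts(reverse_complement(frag))
  out <- data.frame(
    offset = c(fwd, rev_) - 1L,
    strand = c(rep("+", length(fwd)), rep("-", length(rev_))),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Construct a transcript record
#'
#' A transcript couples a mature (sense-strand) sequence with its genomic
#' placement. For tRNAs carrying the post-transcriptionally added CCA tail
#' (`has_cca_tail = TRUE`), the stored sequence is the mature sequence
#' *including* the CCA, while the exon blocks cover only the genome-encoded
#' part; this is what makes tailed 3' reads fail genomic alignment.
#'
#' @param id Transcript identifier (unique within a reference).
#' @param sequence Mature sense-strand sequence (RNA or DNA; stored as DNA).
#' @param biotype One of `"tRNA"`, `"vaultRNA"`, `"mRNA"`, `"other"`.
#' @param contig Genomic contig name.
#' @param start 0-based genomic start of the first exon block.
#' @param strand `"+"` or `"-"`.
#' @param exon_blocks Matrix (or list of length-2 vectors) of 0-based
#'   half-open genomic intervals, sorted and non-overlapping. Defaults to a
#'   single block covering the genome-encoded sequence length.
#' @param has_cca_tail Logical; see description.
#' @return An object of class `bs_transcript`.
#' @export
transcript <- function(id, sequence, biotype = c("other", "tRNA", "vaultRNA", "mRNA"),
                       contig, start = 0L, strand = c("+", "-"),
                       exon_blocks = NULL, has_cca_tail = FALSE) {
  biotype <- match.arg(biotype)
  strand <- match.arg(strand)
  seq <- normalize_dna(sequence)
  glen <- nchar(seq) - if (has_cca_tail) 3L else 0L
  if (glen < 1L) stop("transcript '", id, "': sequence too short")
  if (has_cca_tail && substr(seq, glen + 1L, glen + 3L) != "CCA") {
    stop("transcript '", id, "': has_cca_tail is set but sequence does not end in CCA")
  }
  if (is.null(exon_blocks)) {
    exon_blocks <- matrix(c(start, start + glen), ncol = 2)
  }
  if (is.list(exon_blocks)) exon_blocks <- do.call(rbind, exon_blocks)
  exon_blocks <- matrix(as.integer(exon_blocks), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  widths <- exon_blocks[, 2] - exon_blocks[, 1]
  if (any(widths <= 0L)) stop("transcript '", id, "': empty or inverted exon block")
  if (is.unsorted(exon_blocks[, 1], strictly = TRUE) ||
      any(exon_blocks[-1, 1] < exon_blocks[-nrow(exon_blocks), 2])) {
    stop("transcript '", id, "': exon blocks must be sorted and non-overlapping")
  }
  if (sum(widths) != glen) {
    stop("transcript '", id, "': exon block length ", sum(widths),
         " does not match genome-encoded sequence length ", glen)
  }
  structure(
    list(id = as.character(id), sequence = seq, biotype = biotype,
         contig = as.character(contig), start = as.integer(exon_blocks[1, 1]),
         strand = strand, exon_blocks = exon_blocks,
         has_cca_tail = isTRUE(has_cca_tail)),
    class = "bs_transcript"
  )
}

#' @export
print.bs_transcript <- function(x, ...) {
  cat(sprintf("<bs_transcript> %s [%s] %s:%d-%d(%s) %d nt%s, %d exon block(s)\n",
              x$id, x$biotype, x$contig, x$start,
              x$exon_blocks[nrow(x$exon_blocks), 2], x$strand,
              nchar(x$sequence), if (x$has_cca_tail) " (+CCA)" else "",
              nrow(x$exon_blocks)))
  invisible(x)
}

# Length of the genome-encoded part of the mature sequence.
genomic_length <- function(tx) {
  nchar(tx$sequence) - if (tx$has_cca_tail) 3L else 0L
}

#' Project a transcript interval onto genomic coordinates
#'
#' Maps the 0-based half-open transcript interval `[offset, offset + width)`
#' to genomic coordinates, splitting across exon blocks where needed. Intron
#' gaps are reported as `D` cigar operations (the M/D convention used
#' throughout this pipeline). The interval must lie within the genome-encoded
#' part of the transcript (i.e. not inside a CCA tail).
#'
#' @param tx A `bs_transcript`.
#' @param offset 0-based offset within the mature sequence.
#' @param width Interval width in nt.
#' @return A list with `contig`, `start` (0-based genomic), `strand`, `cigar`,
#'   and `blocks`, a matrix of genomic (start, end) intervals covered.
#' @export
map_to_genomic <- function(tx, offset, width) {
  offset <- as.integer(offset); width <- as.integer(width)
  glen <- genomic_length(tx)
  if (offset < 0L || width < 1L || offset + width > glen) {
    stop("interval [", offset, ", ", offset + width,
         ") outside the genome-encoded transcript body (length ", glen, ")")
  }
  blocks <- tx$exon_blocks
  widths <- blocks[, 2] - blocks[, 1]
  if (tx$strand == "+") {
    tx_starts <- cumsum(c(0L, widths[-length(widths)]))
    segs <- list()
    for (i in seq_len(nrow(blocks))) {
      lo <- max(offset, tx_starts[i])
      hi <- min(offset + width, tx_starts[i] + widths[i])
      if (hi > lo) {
        gs <- blocks[i, 1] + (lo - tx_starts[i])
        segs[[length(segs) + 1L]] <- c(gs, gs + (hi - lo))
      }
    }
  } else {
    if (nrow(blocks) > 1L) {
      stop("minus-strand genomic projection is supported for single-exon transcripts only")
    }
    gs <- blocks[1, 2] - (offset + width)
    segs <- list(c(gs, gs + width))
  }
  segs <- do.call(rbind, segs)
  cigar <- character(0)
  for (i in seq_len(nrow(segs))) {
    if (i > 1L) {
      gap <- segs[i, 1] - segs[i - 1L, 2]
      if (gap > 0L) cigar <- c(cigar, paste0(gap, "D"))
    }
    cigar <- c(cigar, paste0(segs[i, 2] - segs[i, 1], "M"))
  }
  list(contig = tx$contig, start = as.integer(segs[1, 1]), strand = tx$strand,
       cigar = paste(cigar, collapse = ""),
       blocks = matrix(as.integer(segs), ncol = 2,
                       dimnames = list(NULL, c("start", "end"))))
}

# Reconstruct the genome-encoded mature sequence from the genome contigs.
reconstruct_from_genome <- function(tx, genome) {
  contig <- genome[[tx$contig]]
  if (is.null(contig)) stop("contig '", tx$contig, "' absent from genome")
  pieces <- apply(tx$exon_blocks, 1, function(b) substr(contig, b[1] + 1L, b[2]))
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") s <- reverse_complement(s)
  s
}

build_junction_library <- function(transcripts, flank_len) {
  rows <- list()
  for (tx in transcripts) {
    nb <- nrow(tx$exon_blocks)
    if (nb < 2L) next
    if (tx$strand != "+") {
      stop("junction library requires plus-strand multi-exon transcripts (got '-' for '",
           tx$id, "')")
    }
    widths <- tx$exon_blocks[, 2] - tx$exon_blocks[, 1]
    tx_ends <- cumsum(widths)
    for (j in seq_len(nb - 1L)) {
      flank <- min(flank_len, widths[j], widths[j + 1L])
      b <- tx_ends[j]  # transcript coordinate of the junction boundary
      seq <- substr(tx$sequence, b - flank + 1L, b + flank)
      rows[[length(rows) + 1L]] <- data.frame(
        junction_id = sprintf("%s.J%d", tx$id, j),
        transcript_id = tx$id,
        contig = tx$contig,
        flank_len = as.integer(flank),
        left_start = tx$exon_blocks[j, 2] - flank,
        left_end = tx$exon_blocks[j, 2],
        right_start = tx$exon_blocks[j + 1L, 1],
        right_end = tx$exon_blocks[j + 1L, 1] + flank,
        sequence = seq,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(junction_id = character(0), transcript_id = character(0),
                      contig = character(0), flank_len = integer(0),
                      left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build an indexed reference bundle
#'
#' Validates transcripts against the genome, resolves cytosine-site
#' annotations to genomic coordinates, builds the splice-junction library
#' from all multi-exon transcripts, and precomputes the sense-strand locus
#' views that the aligner scans (the unspliced genomic sequence under each
#' transcript, which lacks both CCA tails and splicing).
#'
#' @param transcripts List of [transcript()] objects.
#' @param sites Optional data.frame with columns `transcript_id`, `offset`
#'   (0-based position of an annotated cytosine within the mature sequence)
#'   and optionally `label` (defaults to `"<id>:C<offset+1>"`, matching the
#'   1-based biological naming such as `VTRNA1.1:C69`).
#' @param genome Named character vector (or `DNAStringSet`) of contig
#'   sequences. Every transcript must reconstruct exactly from its exon
#'   blocks on these contigs.
#' @param flank_len Junction flank length in nt (default 50, the aligner
#'   seed-length scale); flanks are clamped to the adjacent exon widths.
#' @param locus_pad Genomic padding (nt) added to each locus view so that
#'   reads overhanging a transcript end align against the true flanking
#'   genomic sequence, as they would in a genome-wide scan (default 50).
#' @return An object of class `bs_reference`.
#' @export
build_reference <- function(transcripts, sites = NULL, genome, flank_len = 50L,
                            locus_pad = 50L) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  genome <- vapply(genome, normalize_dna, character(1))
  if (is.null(names(genome)) || any(names(genome) == "")) {
    stop("genome contigs must be named")
  }
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id: ", ids[duplicated(ids)][1L])
  }
  names(transcripts) <- ids
  for (tx in transcripts) {
    stopifnot(inherits(tx, "bs_transcript"))
    expected <- substr(tx$sequence, 1L, genomic_length(tx))
    got <- reconstruct_from_genome(tx, as.list(genome))
    if (got != expected) {
      stop("transcript '", tx$id, "' does not reconstruct from its exon blocks ",
           "on the supplied genome")
    }
  }

  site_tab <- data.frame(transcript_id = character(0), offset = integer(0),
                         contig = character(0), pos = integer(0),
                         strand = character(0), label = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(sites) && nrow(sites) > 0L) {
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      tid <- as.character(sites$transcript_id[i])
      off <- as.integer(sites$offset[i])
      tx <- transcripts[[tid]]
      if (is.null(tx)) stop("site annotation names unknown transcript '", tid, "'")
      base <- substr(tx$sequence, off + 1L, off + 1L)
      if (base != "C") {
        stop("annotated site ", tid, ":", off, " has reference base '", base,
             "', not C")
      }
      if (off >= genomic_length(tx)) {
        stop("annotated site ", tid, ":", off, " falls inside the CCA tail")
      }
      g <- map_to_genomic(tx, off, 1L)
      label <- if (!is.null(sites$label) && !is.na(sites$label[i]) &&
                   nzchar(sites$label[i])) {
        as.character(sites$label[i])
      } else {
        sprintf("%s:C%d", tid, off + 1L)
      }
      data.frame(transcript_id = tid, offset = off, contig = g$contig,
                 pos = g$start, strand = tx$strand, label = label,
                 stringsAsFactors = FALSE)
    })
    site_tab <- do.call(rbind, rows)
  }

  junctions <- build_junction_library(transcripts, as.integer(flank_len))

  # Sense-strand locus views: the unspliced genomic sequence under each
  # transcript locus, oriented to the transcript's sense strand.
  spaces <- lapply(transcripts, function(tx) {
    lo <- max(0L, tx$exon_blocks[1, 1] - as.integer(locus_pad))
    hi <- min(nchar(genome[[tx$contig]]),
              tx$exon_blocks[nrow(tx$exon_blocks), 2] + as.integer(locus_pad))
    s <- substr(genome[[tx$contig]], lo + 1L, hi)
    if (tx$strand == "-") s <- reverse_complement(s)
    list(space_id = tx$id, contig = tx$contig, start = lo, end = hi,
         strand = tx$strand, sequence = s)
  })

  structure(
    list(transcripts = transcripts, genome = genome, sites = site_tab,
         junctions = junctions, spaces = spaces,
         flank_len = as.integer(flank_len)),
    class = "bs_reference"
  )
}

#' @export
print.bs_reference <- function(x, ...) {
  cat(sprintf("<bs_reference> %d transcript(s), %d contig(s), %d annotated site(s), %d junction(s)\n",
              length(x$transcripts), length(x$genome), nrow(x$sites),
              nrow(x$junctions)))
  invisible(x)
}

# Map a position in a locus view back to a 0-based genomic coordinate.
space_to_genomic <- function(space, space_pos) {
  if (space$strand == "+") space$start + space_pos
  else space$end - space_pos - 1L
}

#' Bundled demonstration mini-reference
#'
#' A small synthetic reference exercising every feature of the pipeline:
#' a 98-nt VTRNA1.1 placeholder (the true sequence is user-replaceable) with
#' annotated C69 and C88, a tRNA with a post-transcriptional CCA tail whose
#' genomic 3' flank (GGG) guarantees that tailed reads fail pass-1 alignment,
#' a two-exon mRNA whose poly-G intron makes junction-spanning reads fail
#' genomic alignment deterministically, and an unannotated background gene.
#' All sequences are synthetic.
#'
#' @param flank_len Junction flank length passed to [build_reference()].
#' @return A `bs_reference` bundle.
#' @export
demo_reference <- function(flank_len = 50L) {
  # Fixed synthetic sequences (moderate C density so reads carry several
  # informative cytosines). Generated once with a seeded RNG and frozen.
  vtrna <- paste0(
    "GGTCAGCTAAACGAGCTCAGCGGTTACTTCGACAGTTCTTTAATTGAAACAAGCAACCTGTCTGGGTT",
    "CGTGACGCACTTCGATCGTCCTCATCGACA"
  )  # 98 nt; offsets 68 and 87 are C (C69, C88)
  stopifnot(nchar(vtrna) == 98L,
            substr(vtrna, 69, 69) == "C", substr(vtrna, 88, 88) == "C")
  trna_body <- paste0(
    "GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGGCCCGGGTTCGATTCCCGGCCAATGCAA"
  )  # 72 nt genome-encoded tRNA body
  stopifnot(nchar(trna_body) == 72L)
  exon1 <- paste0(
    "ATGGCTACCGTTCAAGACTTGCGCAACGTTCCAGATTCGCTGACCATTAACGGTATTCATTAA"
  )  # 63 nt, ends in non-G bases
  exon2 <- paste0(
    "ATTATCCGTGACAACCTTGCAATCGCTCGCCTTGAACGTGATCCGTCTTACGCATCAATAA"
  )  # 61 nt, starts with non-G bases
  intron <- strrep("G", 50L)
  bg <- paste0(
    "TTAGACCAGTTCGCAATGGCATCAACGTTAGCCTTGACCGTATCAGCTTAGCCATTGACGCTTACCA",
    "GTCAGCATTAGCCTGACGTTACGCA"
  )  # unannotated background gene, 92 nt

  chrV <- paste0(strrep("T", 10L), vtrna, strrep("A", 10L))
  chrT <- paste0(strrep("T", 10L), trna_body, "GGG", strrep("A", 7L))
  chrM <- paste0(strrep("T", 10L), exon1, intron, exon2, strrep("A", 10L))
  chrB <- paste0(strrep("T", 10L), bg, strrep("A", 10L))

  txs <- list(
    transcript("VTRNA1.1", vtrna, biotype = "vaultRNA", contig = "chrV",
               start = 10L),
    transcript("tRNA-Gly-GCC", paste0(trna_body, "CCA"), biotype = "tRNA",
               contig = "chrT", start = 10L, has_cca_tail = TRUE),
    transcript("MRX1", paste0(exon1, exon2), biotype = "mRNA", contig = "chrM",
               exon_blocks = rbind(c(10L, 10L + 63L),
                                   c(10L + 63L + 50L, 10L + 63L + 50L + 61L))),
    transcript("BGR1", bg, biotype = "other", contig = "chrB", start = 10L)
  )
  sites <- data.frame(
    transcript_id = c("VTRNA1.1", "VTRNA1.1", "tRNA-Gly-GCC", "MRX1"),
    offset = c(68L, 87L, 47L, 8L),
    stringsAsFactors = FALSE
  )
  build_reference(txs, sites,
                  genome = c(chrV = chrV, chrT = chrT, chrM = chrM, chrB = chrB),
                  flank_len = flank_len)
}
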