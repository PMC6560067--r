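# On-disk representation of a reference bundle: genome and transcript FASTA,
# exon blocks as BED6, plus plain TSV tables for transcript metadata and
# annotated cytosine sites.

#' Write a reference bundle to a directory
#'
#' Produces `genome.fa`, `transcripts.fa` (mature sequences, including CCA
#' tails), `exons.bed` (BED6, one row per exon block, name = transcript id),
#' `transcripts.tsv` (id, biotype, contig, strand, has_cca_tail) and
#' `sites.tsv` (contig, pos0, strand, label, transcript_id, offset).
#'
#' @param reference A `bs_reference`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "bs_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    transcripts_fa = file.path(dir, "transcripts.fa"),
    exons = file.path(dir, "exons.bed"),
    transcripts = file.path(dir, "transcripts.tsv"),
    sites = file.path(dir, "sites.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$genome), paths[["genome"]]
  )
  mature <- vapply(reference$transcripts, `[[`, character(1), "sequence")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(mature), paths[["transcripts_fa"]]
  )

  blocks <- do.call(rbind, lapply(reference$transcripts, function(tx) {
    data.frame(contig = tx$contig, start = tx$exon_blocks[, 1],
               end = tx$exon_blocks[, 2], id = tx$id, strand = tx$strand,
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = blocks$contig,
    ranges = IRanges::IRanges(start = blocks$start + 1L, end = blocks$end),
    strand = blocks$strand, name = blocks$id, score = 0L
  )
  rtracklayer::export(gr, paths[["exons"]], format = "BED")

  meta <- do.call(rbind, lapply(reference$transcripts, function(tx) {
    data.frame(id = tx$id, biotype = tx$biotype, contig = tx$contig,
               strand = tx$strand, has_cca_tail = tx$has_cca_tail,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, paths[["transcripts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sites <- reference$sites[, c("contig", "pos", "strand", "label",
                               "transcript_id", "offset")]
  names(sites)[2] <- "pos0"
  utils::write.table(sites, paths[["sites"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a reference bundle written by [write_reference()]
#'
#' @param dir Directory containing the reference files.
#' @param flank_len Junction flank length for the rebuilt junction library.
#' @return A `bs_reference`.
#' @export
read_reference <- function(dir, flank_len = 50L) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  mature <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  meta <- utils::read.table(file.path(dir, "transcripts.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  bed <- rtracklayer::import(file.path(dir, "exons.bed"), format = "BED")
  sites <- utils::read.table(file.path(dir, "sites.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  txs <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$id[i]
    b <- bed[bed$name == id]
    ord <- order(BiocGenerics::start(b))
    blocks <- cbind(BiocGenerics::start(b)[ord] - 1L, BiocGenerics::end(b)[ord])
    transcript(id, as.character(mature[[id]]), biotype = meta$biotype[i],
               contig = meta$contig[i], strand = meta$strand[i],
               exon_blocks = blocks, has_cca_tail = meta$has_cca_tail[i])
  })
  site_df <- if (nrow(sites)) {
    data.frame(transcript_id = sites$transcript_id, offset = sites$offset,
               label = sites$label, stringsAsFactors = FALSE)
  } else NULL
  build_reference(txs, site_df,
                  genome = setNames(as.character(genome), names(genome)),
                  flank_len = flank_len)
}
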