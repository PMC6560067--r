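# Per-read methylation calling, non-conversion artifact filtering, and
# per-cytosine pileup. All cytosines are called regardless of sequence
# context (RNA has no CpG special-casing).

#' Artifact-read filter parameters
#'
#' Reads from highly structured regions can escape bisulfite conversion
#' wholesale and mimic dense methylation; such reads are discarded when
#' strictly more than `max_meth_fraction` of their informative cytosines
#' read as methylated.
#'
#' @param max_meth_fraction Discard threshold (strict `>`; default 1/3).
#' @param min_informative_c Minimum informative cytosine calls for the
#'   filter to apply (default 1); reads with fewer pass unfiltered.
#' @return A validated list of class `artifact_params`.
#' @export
artifact_params <- function(max_meth_fraction = 1 / 3, min_informative_c = 1L) {
  if (max_meth_fraction <= 0 || max_meth_fraction > 1) {
    stop("max_meth_fraction must be in (0, 1]")
  }
  structure(list(max_meth_fraction = max_meth_fraction,
                 min_informative_c = as.integer(min_informative_c)),
            class = "artifact_params")
}

# Genomic positions and reference bases covered by a unique record, in the
# record's alignment space (locus view or junction sequence).
record_positions <- function(record, reference) {
  L <- nchar(record$sequence)
  if (record$space_type == "locus") {
    sp <- reference$spaces[[record$space_id]]
    offs <- record$space_offset + seq_len(L) - 1L
    ref <- substring(sp$sequence, offs + 1L, offs + 1L)
    gpos <- if (sp$strand == "+") sp$start + offs else sp$end - offs - 1L
    list(ref = ref, contig = sp$contig, pos = gpos, strand = sp$strand)
  } else {
    j <- reference$junctions[reference$junctions$junction_id == record$space_id, ]
    offs <- record$space_offset + seq_len(L) - 1L
    ref <- substring(j$sequence, offs + 1L, offs + 1L)
    gpos <- ifelse(offs < j$flank_len, j$left_start + offs,
                   j$right_start + (offs - j$flank_len))
    list(ref = ref, contig = j$contig, pos = as.integer(gpos), strand = "+")
  }
}

#' Call per-read methylation states
#'
#' For each reference cytosine covered by an aligned (`M`) base: a read C is
#' a methylated call, a read T an unmethylated call, anything else
#' uninformative. Positions spanned by `D` operations (junction gaps) are
#' not covered and yield no call.
#'
#' @param record A one-row unique outcome from [align_reads()] (or a list
#'   with the same fields).
#' @param reference A `bs_reference`.
#' @return data.frame of calls: `read_id`, `contig`, `pos`, `strand`,
#'   `state` (`methylated`/`unmethylated`/`uninformative`).
#' @export
call_read <- function(record, reference) {
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  if (!identical(record$class, "unique")) {
    stop("methylation is called on unique records only")
  }
  p <- record_positions(record, reference)
  is_c <- p$ref == "C"
  if (!any(is_c)) {
    return(data.frame(read_id = character(0), contig = character(0),
                      pos = integer(0), strand = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  q <- substring(record$sequence, which(is_c), which(is_c))
  state <- ifelse(q == "C", "methylated",
                  ifelse(q == "T", "unmethylated", "uninformative"))
  data.frame(read_id = record$read_id, contig = p$contig, pos = p$pos[is_c],
             strand = p$strand, state = state, stringsAsFactors = FALSE)
}

#' Call methylation for all unique records
#'
#' @param outcomes Outcome data.frame from [align_reads()].
#' @param reference A `bs_reference`.
#' @return A list of class `bs_read_calls`: `calls` (long data.frame as in
#'   [call_read()]) and `reads` (per-read `n_meth`/`n_unmeth` summary over
#'   informative calls).
#' @export
call_reads <- function(outcomes, reference) {
  u <- outcomes[outcomes$class == "unique", , drop = FALSE]
  calls <- if (nrow(u)) {
    do.call(rbind, lapply(seq_len(nrow(u)), function(i) {
      call_read(as.list(u[i, ]), reference)
    }))
  } else NULL
  if (is.null(calls)) {
    calls <- data.frame(read_id = character(0), contig = character(0),
                        pos = integer(0), strand = character(0),
                        state = character(0), stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  n_meth <- tapply(calls$state == "methylated", calls$read_id, sum)
  n_unmeth <- tapply(calls$state == "unmethylated", calls$read_id, sum)
  reads <- data.frame(read_id = u$read_id, stringsAsFactors = FALSE)
  reads$n_meth <- as.integer(n_meth[reads$read_id])
  reads$n_unmeth <- as.integer(n_unmeth[reads$read_id])
  reads$n_meth[is.na(reads$n_meth)] <- 0L
  reads$n_unmeth[is.na(reads$n_unmeth)] <- 0L
  structure(list(calls = calls, reads = reads), class = "bs_read_calls")
}

#' Discard likely non-conversion artifact reads
#'
#' A read is discarded when strictly more than `max_meth_fraction` of its
#' informative cytosine calls (C or T over a reference C) are methylated and
#' it has at least `min_informative_c` informative calls. Reads with no
#' informative cytosines carry no evidence of an artifact and are kept.
#'
#' @param calls A `bs_read_calls` from [call_reads()].
#' @param params An [artifact_params()].
#' @return List with `kept` and `discarded`, both `bs_read_calls`.
#' @export
filter_artifact_reads <- function(calls, params = artifact_params()) {
  stopifnot(inherits(calls, "bs_read_calls"))
  r <- calls$reads
  informative <- r$n_meth + r$n_unmeth
  discard <- informative >= params$min_informative_c &
    informative > 0L &
    r$n_meth / pmax(informative, 1L) > params$max_meth_fraction
  subset_calls <- function(ids) {
    structure(list(
      calls = calls$calls[calls$calls$read_id %in% ids, , drop = FALSE],
      reads = r[r$read_id %in% ids, , drop = FALSE]
    ), class = "bs_read_calls")
  }
  list(kept = subset_calls(r$read_id[!discard]),
       discarded = subset_calls(r$read_id[discard]))
}

#' Pile reads up into per-site methylation levels
#'
#' @param calls A `bs_read_calls` (typically the `kept` component of
#'   [filter_artifact_reads()]).
#' @param sites Optional annotated-site table (the `sites` component of a
#'   `bs_reference`) used to attach labels; unannotated covered cytosines
#'   get an empty label.
#' @return data.frame: `contig`, `pos` (0-based), `strand`, `label`,
#'   `n_meth`, `n_unmeth`, `coverage`, `level`. Sites with zero informative
#'   coverage are omitted.
#' @export
pileup <- function(calls, sites = NULL) {
  stopifnot(inherits(calls, "bs_read_calls"))
  cc <- calls$calls[calls$calls$state != "uninformative", , drop = FALSE]
  if (!nrow(cc)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), label = character(0),
                      n_meth = integer(0), n_unmeth = integer(0),
                      coverage = integer(0), level = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(cc$contig, cc$pos, cc$strand)
  agg <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  m <- tapply(cc$state == "methylated", key, sum)
  u <- tapply(cc$state == "unmethylated", key, sum)
  first <- !duplicated(key)
  lut <- data.frame(key = key[first], contig = cc$contig[first],
                    pos = cc$pos[first], strand = cc$strand[first],
                    stringsAsFactors = FALSE)
  out <- merge(lut, data.frame(key = names(m), n_meth = as.integer(m),
                               n_unmeth = as.integer(u[names(m)]),
                               stringsAsFactors = FALSE), by = "key")
  out$coverage <- out$n_meth + out$n_unmeth
  out$level <- out$n_meth / out$coverage
  out$label <- ""
  if (!is.null(sites) && nrow(sites)) {
    skey <- paste(sites$contig, sites$pos, sites$strand)
    hit <- match(out$key, skey)
    out$label[!is.na(hit)] <- sites$label[hit[!is.na(hit)]]
  }
  out <- out[order(out$contig, out$pos), c("contig", "pos", "strand", "label",
                                           "n_meth", "n_unmeth", "coverage",
                                           "level")]
  rownames(out) <- NULL
  out
}

#' Write per-site methylation outputs
#'
#' Writes a bedGraph-style file (`contig`, `start`, `end`, methylation level
#' as a percentage) and a counts TSV carrying the full table including
#' methylated/unmethylated read counts. The counts file round-trips: reading
#' it back reproduces the table exactly.
#'
#' @param table A pileup table from [pileup()].
#' @param prefix Output path prefix; writes `<prefix>.bedGraph` and
#'   `<prefix>.counts.tsv`.
#' @return Invisibly, the named vector of paths.
#' @export
write_site_outputs <- function(table, prefix) {
  paths <- c(bedgraph = paste0(prefix, ".bedGraph"),
             counts = paste0(prefix, ".counts.tsv"))
  bg <- data.frame(contig = table$contig, start = table$pos,
                   end = table$pos + 1L, level_pct = 100 * table$level)
  utils::write.table(bg, paths[["bedgraph"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(table, paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read back a counts TSV written by [write_site_outputs()]
#'
#' @param path Path to a `.counts.tsv` file.
#' @return The pileup table, with `level` recomputed exactly from counts.
#' @export
read_site_counts <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(label = "character"))
  out$label[is.na(out$label)] <- ""
  out$level <- out$n_meth / (out$n_meth + out$n_unmeth)
  out
}
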