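# Bisulfite read simulator. Emulates the statistical structure of an RNA
# BS-seq small-RNA library: per-site methylation levels, incomplete
# conversion, wholesale non-conversion artifact reads from structured RNAs,
# tRNA CCA tails, junction-spanning reads, and 3' adapter read-through.

#' Simulation configuration
#'
#' @param conversion_efficiency Probability that an unmethylated cytosine is
#'   converted (read as T). Default 0.99 (about 1% incomplete conversion).
#' @param artifact_rate Fraction of reads that are wholesale non-converted
#'   (every C emitted as C), the failure mode of highly structured regions
#'   targeted by the >1/3 methylated-cytosine read filter. Default 0.01.
#' @param read_length Read length in nt (default 30).
#' @param mean_coverage Mean per-base coverage per transcript (default 300).
#' @param replicates_per_condition Bisulfite conversion replicates per
#'   condition (default 5, the study design).
#' @param adapter 3' sequencing adapter appended to inserts shorter than the
#'   read length (default `TGGAATTCTCGGGTGCCAAGGA`).
#' @param seq_error_rate Per-base substitution error rate (default 0).
#' @param seed Integer master seed; every (condition, replicate) stream is
#'   derived deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(conversion_efficiency = 0.99, artifact_rate = 0.01,
                              read_length = 30L, mean_coverage = 300,
                              replicates_per_condition = 5L,
                              adapter = "TGGAATTCTCGGGTGCCAAGGA",
                              seq_error_rate = 0, seed = 1L) {
  probs <- c(conversion_efficiency = conversion_efficiency,
             artifact_rate = artifact_rate, seq_error_rate = seq_error_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (replicates_per_condition < 2L) stop("replicates_per_condition must be >= 2")
  if (read_length < 1L || mean_coverage <= 0) stop("invalid read_length/mean_coverage")
  structure(list(conversion_efficiency = conversion_efficiency,
                 artifact_rate = artifact_rate,
                 read_length = as.integer(read_length),
                 mean_coverage = mean_coverage,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 adapter = normalize_dna(adapter),
                 seq_error_rate = seq_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-site methylation profile
#'
#' The latent truth of the simulation: the methylation level of each
#' annotated cytosine in each condition, plus a background level for all
#' unannotated cytosines.
#'
#' @param entries data.frame with columns `transcript_id`, `offset` (0-based
#'   within the mature sequence), `condition`, `level` (in `[0, 1]`).
#' @param background Methylation level of unannotated cytosines (default 0).
#' @return A list of class `meth_profile`.
#' @export
methylation_profile <- function(entries, background = 0) {
  stopifnot(is.data.frame(entries),
            all(c("transcript_id", "offset", "condition", "level") %in%
                  names(entries)))
  if (any(entries$level < 0 | entries$level > 1) || background < 0 || background > 1) {
    stop("methylation levels must lie in [0, 1]")
  }
  structure(list(entries = entries, background = background),
            class = "meth_profile")
}

# Deterministic per-stream seed below 2^31, derived from the master seed,
# the condition name, and the replicate index.
sim_stream_seed <- function(seed, condition, replicate) {
  h <- sum(utf8ToInt(condition) * seq_along(utf8ToInt(condition)))
  as.integer((abs(seed) %% 1000003L) * 2011L + (h %% 99991L) * 17L +
               replicate) %% .Machine$integer.max
}

profile_levels <- function(profile, transcript_id, offsets, condition) {
  m <- rep(profile$background, length(offsets))
  e <- profile$entries
  e <- e[e$transcript_id == transcript_id & e$condition == condition, , drop = FALSE]
  if (nrow(e)) {
    idx <- match(offsets, e$offset)
    m[!is.na(idx)] <- e$level[idx[!is.na(idx)]]
  }
  m
}

#' Simulate one bisulfite conversion replicate
#'
#' Reads are drawn uniformly along each transcript's mature sequence (tRNA
#' CCA tails included). For each reference cytosine in a read, the molecule
#' is methylated with the profiled probability; methylated cytosines are
#' emitted as C, unmethylated ones as T with probability
#' `conversion_efficiency` (else C). Artifact reads (probability
#' `artifact_rate`) emit every cytosine as C. Inserts shorter than the read
#' length are padded with the adapter, then with random bases. Output is
#' deterministic given `(config$seed, condition, replicate)`.
#'
#' @param reference A `bs_reference`.
#' @param profile A [methylation_profile()] whose entries all name annotated
#'   reference sites.
#' @param config A [simulation_config()].
#' @param condition Condition label.
#' @param replicate Replicate index (1-based).
#' @return A list with `reads` (data.frame: read_id, sequence, quality) and
#'   `truth` (one row per read: source interval, artifact flag, and the
#'   transcript offsets of covered, truly methylated, and C-emitted
#'   cytosines as comma-separated strings).
#' @export
simulate_replicate <- function(reference, profile, config, condition, replicate) {
  stopifnot(inherits(reference, "bs_reference"),
            inherits(profile, "meth_profile"),
            inherits(config, "sim_config"))
  key <- paste(reference$sites$transcript_id, reference$sites$offset)
  pkey <- paste(profile$entries$transcript_id, profile$entries$offset)
  unknown <- setdiff(pkey, key)
  if (length(unknown)) {
    stop("profile references unannotated site(s): ",
         paste(unknown[1:min(3, length(unknown))], collapse = "; "))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(sim_stream_seed(config$seed, condition, replicate))

  rl <- config$read_length
  all_reads <- list(); all_truth <- list()
  for (tx in reference$transcripts) {
    mlen <- nchar(tx$sequence)
    n_reads <- stats::rpois(1L, config$mean_coverage * mlen / rl)
    if (n_reads == 0L) next
    starts <- sample.int(mlen, n_reads, replace = TRUE) - 1L
    chars <- strsplit(tx$sequence, "", fixed = TRUE)[[1]]

    seqs <- character(n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- starts[i]
      e <- min(s + rl, mlen)
      frag <- chars[(s + 1L):e]
      cpos <- which(frag == "C")          # 1-based within fragment
      offs <- s + cpos - 1L               # 0-based transcript offsets
      is_artifact <- stats::runif(1L) < config$artifact_rate
      m <- profile_levels(profile, tx$id, offs, condition)
      meth <- stats::runif(length(offs)) < m
      out <- frag
      if (is_artifact) {
        # wholesale non-conversion: every C stays C
        emitted_c <- rep(TRUE, length(offs))
      } else {
        conv <- !meth & stats::runif(length(offs)) < config$conversion_efficiency
        out[cpos[conv]] <- "T"
        emitted_c <- !conv
      }
      if (config$seq_error_rate > 0) {
        err <- which(stats::runif(length(out)) < config$seq_error_rate)
        for (j in err) out[j] <- sample(setdiff(DNA_BASES, out[j]), 1L)
      }
      insert_len <- length(out)
      read <- paste(out, collapse = "")
      if (insert_len < rl) {
        pad <- substr(config$adapter, 1L, rl - insert_len)
        read <- paste0(read, pad)
        short <- rl - insert_len - nchar(pad)
        if (short > 0L) {
          read <- paste0(read, paste(sample(DNA_BASES, short, replace = TRUE),
                                     collapse = ""))
        }
      }
      seqs[i] <- read
      truth[[i]] <- data.frame(
        transcript_id = tx$id, start = s, end = e,
        insert_len = insert_len, is_artifact = is_artifact,
        c_offsets = paste(offs, collapse = ","),
        meth_offsets = paste(offs[meth], collapse = ","),
        emitted_c_offsets = paste(offs[emitted_c], collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    tr <- do.call(rbind, truth)
    tr$read_id <- sprintf("%s.rep%d.%s.%06d", condition, replicate, tx$id,
                          seq_len(n_reads))
    all_reads[[tx$id]] <- data.frame(
      read_id = tr$read_id, sequence = seqs,
      quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE
    )
    all_truth[[tx$id]] <- tr
  }
  reads <- do.call(rbind, all_reads)
  truth <- do.call(rbind, all_truth)
  rownames(reads) <- rownames(truth) <- NULL
  truth$condition <- condition
  truth$replicate <- as.integer(replicate)
  truth <- truth[, c("read_id", "condition", "replicate", "transcript_id",
                     "start", "end", "insert_len", "is_artifact",
                     "c_offsets", "meth_offsets", "emitted_c_offsets")]
  list(reads = reads, truth = truth)
}

#' Simulate a full study design
#'
#' One FASTQ per condition x replicate (e.g. empty-vector control, enzymatic
#' dead K190M, and NSUN2 rescue, five bisulfite conversion replicates each),
#' a merged truth table, and a manifest listing all outputs.
#'
#' @inheritParams simulate_replicate
#' @param conditions Character vector of at least two condition labels.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `fastq` (data.frame: condition, replicate,
#'   path), `truth_path`, `manifest_path`, and the merged `truth` table.
#' @export
simulate_study <- function(reference, profile, config, conditions, out_dir) {
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(); truths <- list()
  for (cond in conditions) {
    for (rep_i in seq_len(config$replicates_per_condition)) {
      sim <- simulate_replicate(reference, profile, config, cond, rep_i)
      path <- file.path(out_dir, sprintf("%s.rep%d.fastq", cond, rep_i))
      write_fastq(sim$reads, path)
      files[[length(files) + 1L]] <- data.frame(
        condition = cond, replicate = rep_i, path = path,
        n_reads = nrow(sim$reads), stringsAsFactors = FALSE
      )
      truths[[length(truths) + 1L]] <- sim$truth
    }
  }
  fastq <- do.call(rbind, files)
  truth <- do.call(rbind, truths)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    seed = config$seed,
    conditions = as.list(conditions),
    replicates_per_condition = config$replicates_per_condition,
    config = unclass(config)[c("conversion_efficiency", "artifact_rate",
                               "read_length", "mean_coverage", "adapter",
                               "seq_error_rate")],
    fastq = lapply(seq_len(nrow(fastq)), function(i) as.list(fastq[i, ])),
    truth = truth_path
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(fastq = fastq, truth = truth, truth_path = truth_path,
                 manifest_path = manifest_path))
}

#' Site-level generative model of bisulfite counts
#'
#' The per-site marginal of the read simulator: at a site with true
#' methylation level `m`, an informative read shows C with probability
#' `m + (1 - m) * (1 - conversion_efficiency)` (artifact reads are assumed
#' removed by the read filter). Coverage is Poisson. Used for large
#' replicated designs where read-level simulation is unnecessary.
#'
#' @param levels Named numeric matrix or data.frame: sites x conditions true
#'   methylation levels.
#' @param mean_coverage Mean per-site read coverage.
#' @param replicates Replicates per condition.
#' @param conversion_efficiency As in [simulation_config()].
#' @return Long data.frame: site, condition, replicate, n_meth, n_unmeth,
#'   coverage, level. Draws from the current RNG stream (set a seed for
#'   reproducibility).
#' @export
simulate_site_counts <- function(levels, mean_coverage, replicates,
                                 conversion_efficiency = 0.99) {
  levels <- as.matrix(levels)
  if (is.null(rownames(levels))) {
    rownames(levels) <- sprintf("site%04d", seq_len(nrow(levels)))
  }
  conds <- colnames(levels)
  rows <- list()
  for (cond in conds) {
    p_c <- levels[, cond] + (1 - levels[, cond]) * (1 - conversion_efficiency)
    for (r in seq_len(replicates)) {
      cov <- stats::rpois(nrow(levels), mean_coverage)
      n_meth <- stats::rbinom(nrow(levels), cov, p_c)
      rows[[length(rows) + 1L]] <- data.frame(
        site = rownames(levels), condition = cond, replicate = r,
        n_meth = n_meth, n_unmeth = cov - n_meth, coverage = cov,
        level = ifelse(cov > 0, n_meth / cov, NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[out$coverage > 0L, , drop = FALSE]
}

#' Write reads as a 4-line FASTQ file
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  qual <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ path.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(read_id = names(dna), sequence = as.character(dna),
             quality = as.character(S4Vectors::mcols(dna)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
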