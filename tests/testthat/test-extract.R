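ref <- make_test_reference()

# helper: build a unique locus record directly
locus_record <- function(read, space_id, off, read_id = "r1") {
  list(read_id = read_id, class = "unique", pass = 1L,
       space_type = "locus", space_id = space_id,
       space_offset = as.integer(off), sequence = read)
}

test_that("call_read classifies C/T/other over reference cytosines", {
  sp <- ref$spaces[["TXA"]]
  off <- 10L
  win <- substr(sp$sequence, off + 1, off + 20)
  cpos <- which(strsplit(win, "")[[1]] == "C")
  expect_gt(length(cpos), 1L)

  # all retained -> all methylated
  calls_m <- call_read(locus_record(win, "TXA", off), ref)
  expect_equal(nrow(calls_m), length(cpos))
  expect_true(all(calls_m$state == "methylated"))
  expect_equal(calls_m$pos, sp$start + off + cpos - 1L)

  # fully converted -> all unmethylated
  calls_u <- call_read(locus_record(convert_all(win), "TXA", off), ref)
  expect_true(all(calls_u$state == "unmethylated"))

  # a G over a reference C is uninformative
  mixed <- strsplit(convert_all(win), "")[[1]]
  mixed[cpos[1]] <- "G"
  calls_g <- call_read(locus_record(paste(mixed, collapse = ""), "TXA", off), ref)
  expect_equal(calls_g$state[1], "uninformative")
  expect_true(all(calls_g$state[-1] == "unmethylated"))
  expect_error(call_read(list(class = "ambiguous"), ref), "unique")
})

test_that("junction records call methylation on both flanks, never in the gap", {
  jl <- ref$junctions
  flank <- jl$flank_len[1]
  off <- flank - 10L
  read <- substr(jl$sequence[1], off + 1, off + 20)  # retained Cs
  rec <- list(read_id = "j1", class = "unique", pass = 3L,
              space_type = "junction", space_id = jl$junction_id[1],
              space_offset = off, sequence = read)
  calls <- call_read(rec, ref)
  expect_true(all(calls$state == "methylated"))
  # genomic positions: left flank before left_end, right flank from right_start
  expect_true(all(calls$pos < jl$left_end[1] | calls$pos >= jl$right_start[1]))
  # nothing falls inside the intron gap
  expect_false(any(calls$pos >= jl$left_end[1] & calls$pos < jl$right_start[1]))
})

test_that("minus-strand records report genomic positions of sense cytosines", {
  sp <- ref$spaces[["TXB"]]
  off <- 5L
  win <- substr(sp$sequence, off + 1, off + 20)
  calls <- call_read(locus_record(win, "TXB", off), ref)
  cpos <- which(strsplit(win, "")[[1]] == "C")
  expect_equal(calls$pos, sp$end - (off + cpos - 1L) - 1L)
  expect_true(all(calls$strand == "-"))
})

test_that("artifact filter applies the strict >1/3 rule exactly", {
  mk_calls <- function(n_meth, n_unmeth) {
    reads <- data.frame(read_id = sprintf("r%d", seq_along(n_meth)),
                        n_meth = n_meth, n_unmeth = n_unmeth,
                        stringsAsFactors = FALSE)
    calls <- do.call(rbind, lapply(seq_along(n_meth), function(i) {
      k <- n_meth[i] + n_unmeth[i]
      if (k == 0) return(NULL)
      data.frame(read_id = reads$read_id[i], contig = "c",
                 pos = seq_len(k), strand = "+",
                 state = rep(c("methylated", "unmethylated"),
                             c(n_meth[i], n_unmeth[i])),
                 stringsAsFactors = FALSE)
    }))
    structure(list(calls = calls, reads = reads), class = "bs_read_calls")
  }
  # hand-enumerated: 2/4 (>1/3) out; 1/4 in; 1/3 (= 1/3, strict) in;
  # 1/1 out; 0/0 (no informative) in; 3/9 (= 1/3) in; 4/9 (> 1/3) out
  calls <- mk_calls(c(2, 1, 1, 1, 0, 3, 4), c(2, 3, 2, 0, 0, 6, 5))
  res <- filter_artifact_reads(calls, artifact_params())
  expect_setequal(res$kept$reads$read_id, c("r2", "r3", "r5", "r6"))
  expect_setequal(res$discarded$reads$read_id, c("r1", "r4", "r7"))
  # min_informative_c guard: with a floor of 2 the 1/1 read passes
  res2 <- filter_artifact_reads(calls, artifact_params(min_informative_c = 2L))
  expect_true("r4" %in% res2$kept$reads$read_id)
  # monotone: raising the threshold never discards a previously kept read
  for (thr in c(0.2, 0.34, 0.5, 0.8, 1)) {
    res_lo <- filter_artifact_reads(calls, artifact_params(max_meth_fraction = thr))
    kept_prev <- res_lo$kept$reads$read_id
    for (thr2 in c(thr + 0.1, 1)) {
      if (thr2 > 1) next
      res_hi <- filter_artifact_reads(calls,
                                      artifact_params(max_meth_fraction = thr2))
      expect_true(all(kept_prev %in% res_hi$kept$reads$read_id))
    }
  }
})

test_that("the filter removes all simulator-flagged artifact reads", {
  cfg <- simulation_config(conversion_efficiency = 0.99, artifact_rate = 0.08,
                           mean_coverage = 150, seed = 29)
  prof <- methylation_profile(
    data.frame(transcript_id = "TRN", offset = 40L, condition = "A",
               level = 0.3, stringsAsFactors = FALSE))
  sim <- simulate_replicate(ref, prof, cfg, "A", 1)
  tr <- trim_reads(sim$reads$sequence, trim_params())
  reads <- data.frame(read_id = sim$reads$read_id[tr$kept],
                      sequence = tr$sequence[tr$kept])
  out <- align_reads(reads, ref, align_params())
  calls <- call_reads(out, ref)
  res <- filter_artifact_reads(calls, artifact_params())
  truth <- sim$truth
  art_ids <- truth$read_id[truth$is_artifact]
  # every unique-aligned artifact read with >= 1 informative C is discarded
  art_in <- calls$reads[calls$reads$read_id %in% art_ids, ]
  art_informative <- art_in$read_id[art_in$n_meth + art_in$n_unmeth >= 1L]
  expect_true(all(art_informative %in% res$discarded$reads$read_id))
})

test_that("pileup aggregates counts into levels and labels annotated sites", {
  sp <- ref$spaces[["TRN"]]
  site <- ref$sites[1, ]
  soff <- site$pos - sp$start  # site offset within the locus view
  win_at <- function(o) substr(sp$sequence, o + 1, o + 20)
  recs <- rbind(
    do.call(rbind, lapply(1:5, function(i) {
      as.data.frame(locus_record(win_at(soff - 5L), "TRN", soff - 5L,
                                 sprintf("m%d", i)), stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(1:5, function(i) {
      as.data.frame(locus_record(convert_all(win_at(soff - 5L)), "TRN",
                                 soff - 5L, sprintf("u%d", i)),
                    stringsAsFactors = FALSE)
    }))
  )
  calls <- call_reads(recs, ref)
  pt <- pileup(calls, ref$sites)
  row <- pt[pt$pos == site$pos & pt$contig == site$contig, ]
  expect_equal(row$n_meth, 5L)
  expect_equal(row$n_unmeth, 5L)
  expect_equal(row$coverage, 10L)
  expect_equal(row$level, 0.5)
  expect_equal(row$label, site$label)
  # all-converted-only site has level 0
  other <- pt[pt$label == "" & pt$coverage == 10, ]
  expect_true(all(other$level == 0.5 | other$level == 0))
  # invariants
  expect_true(all(pt$level >= 0 & pt$level <= 1))
  expect_equal(pt$coverage, pt$n_meth + pt$n_unmeth)
})

test_that("recovered level tracks the truth within binomial error", {
  cfg <- simulation_config(conversion_efficiency = 1, artifact_rate = 0,
                           mean_coverage = 800, seed = 41)
  m <- 0.4
  prof <- methylation_profile(
    data.frame(transcript_id = "TRN", offset = 40L, condition = "A",
               level = m, stringsAsFactors = FALSE))
  sim <- simulate_replicate(ref, prof, cfg, "A", 1)
  tr <- trim_reads(sim$reads$sequence, trim_params())
  reads <- data.frame(read_id = sim$reads$read_id[tr$kept],
                      sequence = tr$sequence[tr$kept])
  out <- align_reads(reads, ref, align_params())
  filt <- filter_artifact_reads(call_reads(out, ref), artifact_params())
  pt <- pileup(filt$kept, ref$sites)
  row <- pt[pt$label == ref$sites$label[1], ]
  expect_gt(row$coverage, 300)
  expect_lt(abs(row$level - m), 3 * sqrt(m * (1 - m) / row$coverage))
})

test_that("site outputs round-trip and report percentages", {
  tbl <- data.frame(contig = c("c1", "c1"), pos = c(4L, 9L),
                    strand = c("+", "+"), label = c("", "X:C10"),
                    n_meth = c(1L, 0L), n_unmeth = c(1L, 20L),
                    coverage = c(2L, 20L), level = c(0.5, 0),
                    stringsAsFactors = FALSE)
  prefix <- tempfile("sites_")
  paths <- write_site_outputs(tbl, prefix)
  bg <- utils::read.table(paths[["bedgraph"]], header = TRUE, sep = "\t")
  expect_equal(bg$level_pct, c(50, 0))
  expect_equal(bg$end, tbl$pos + 1L)
  back <- read_site_counts(paths[["counts"]])
  expect_equal(back, tbl)
  # empty table -> header-only files
  empty <- tbl[0, ]
  paths2 <- write_site_outputs(empty, tempfile("empty_"))
  expect_equal(nrow(utils::read.table(paths2[["counts"]], header = TRUE,
                                      sep = "\t")), 0L)
})
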