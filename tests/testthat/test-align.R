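ref <- make_test_reference()

test_that("bisulfite mismatch scoring is conversion-aware and asymmetric", {
  expect_equal(bs_mismatch_count("ATGT", "ACGT"), 0L)  # C->T allowed
  expect_equal(bs_mismatch_count("ACGT", "ACGT"), 0L)  # retained C
  expect_equal(bs_mismatch_count("ACGT", "ATGT"), 1L)  # read C over ref T
  expect_equal(bs_mismatch_count("NCGT", "ACGT"), 1L)  # read N never matches
  expect_error(bs_mismatch_count("ACG", "ACGT"), "length")
  withr::with_seed(2, {
    for (i in 1:100) {
      r <- random_dna(15); w <- random_dna(15)
      expect_equal(bs_mismatch_count(r, w), oracle_bs_mm(r, w))
    }
  })
})

test_that("pass 1 recovers fully converted reads at their true locus", {
  withr::with_seed(8, {
    cases <- lapply(1:30, function(i) {
      tx <- ref$transcripts[[sample(c("TXA", "TXB", "TRN"), 1)]]
      glen <- nchar(tx$sequence) - if (tx$has_cca_tail) 3L else 0L
      L <- sample(20:min(30, glen), 1)
      s <- sample(0:(glen - L), 1)
      list(tx = tx, s = s,
           read = convert_all(substr(tx$sequence, s + 1, s + L)))
    })
  })
  reads <- data.frame(read_id = sprintf("r%02d", seq_along(cases)),
                      sequence = vapply(cases, `[[`, "", "read"))
  out <- align_pass1(reads, ref, align_params())
  expect_true(all(out$class == "unique"))
  expect_equal(out$pass, rep(1L, nrow(out)))
  for (i in seq_along(cases)) {
    g <- map_to_genomic(cases[[i]]$tx, cases[[i]]$s, nchar(cases[[i]]$read))
    expect_equal(out$start[i], g$start)
    expect_equal(out$contig[i], g$contig)
    expect_equal(out$strand[i], cases[[i]]$tx$strand)
    expect_equal(out$bs_mismatches[i], 0L)
  }
})

test_that("reads from a duplicated region are ambiguous; junk reads unaligned", {
  dup_read <- convert_all(substr(ref$transcripts[["DUP1"]]$sequence, 5, 30))
  out <- align_pass1(data.frame(read_id = "d", sequence = dup_read), ref,
                     align_params())
  expect_equal(out$class, "ambiguous")
  # random read verified absent by the brute-force oracle
  withr::with_seed(99, {
    repeat {
      junk <- random_dna(30)
      if (oracle_align(junk, ref)$class == "unaligned") break
    }
  })
  out2 <- align_pass1(data.frame(read_id = "j", sequence = junk), ref,
                      align_params())
  expect_equal(out2$class, "unaligned")
})

test_that("pass 1 equals the brute-force oracle on random reads", {
  withr::with_seed(123, {
    reads <- vapply(1:120, function(i) {
      kind <- sample(3, 1)
      if (kind == 1L) {
        random_dna(sample(20:30, 1))
      } else {
        sp <- ref$spaces[[sample(length(ref$spaces), 1)]]
        L <- sample(20:30, 1)
        s <- sample(0:(nchar(sp$sequence) - L), 1)
        r <- substr(sp$sequence, s + 1, s + L)
        if (kind == 2L) r <- convert_all(r)
        # sprinkle up to 3 errors
        n_err <- sample(0:3, 1)
        if (n_err > 0) {
          ch <- strsplit(r, "")[[1]]
          for (p in sample(L, n_err)) ch[p] <- sample(c("A", "C", "G", "T"), 1)
          r <- paste(ch, collapse = "")
        }
        r
      }
    }, character(1))
  })
  df <- data.frame(read_id = sprintf("r%03d", seq_along(reads)),
                   sequence = reads)
  out <- align_pass1(df, ref, align_params())
  for (i in seq_along(reads)) {
    oa <- oracle_align(reads[i], ref)
    expect_equal(out$class[i], oa$class, label = paste("read", i, "class"))
    if (oa$class == "unique") {
      expect_equal(out$space_id[i], oa$space)
      expect_equal(out$space_offset[i], oa$off)
      expect_equal(out$bs_mismatches[i], oa$mm)
    }
  }
})

test_that("CCA-tailed tRNA 3' reads fail pass 1 and are rescued by pass 2", {
  trn <- ref$transcripts[["TRN"]]
  mature <- trn$sequence
  glen <- nchar(mature) - 3L
  # reads ending at the mature 3' end, containing the full CCA tail
  reads <- data.frame(
    read_id = c("cc1", "cc2", "cc3"),
    sequence = c(convert_all(substr(mature, glen - 23, glen + 3)),
                 convert_all(substr(mature, glen - 20, glen + 3)),
                 # artifact-like read: tail retained as CC
                 paste0(substr(mature, glen - 23, glen), "CCA")),
    stringsAsFactors = FALSE)
  p1 <- align_pass1(reads, ref, align_params())
  expect_true(all(p1$class == "unaligned"))
  p2 <- clip_and_realign(p1, ref, align_params())
  expect_true(all(p2$class == "unique"))
  expect_true(all(p2$pass == 2L))
  expect_true(all(p2$clipped_tail == 3L))
  starts <- c(glen - 24L, glen - 21L, glen - 24L)
  for (i in 1:3) {
    g <- map_to_genomic(trn, starts[i], nchar(reads$sequence[i]) - 3L)
    expect_equal(p2$start[i], g$start)
  }
})

test_that("pass 2 keeps ambiguity and discards too-short clips", {
  dup_read <- convert_all(substr(ref$transcripts[["DUP1"]]$sequence, 3, 32))
  p1 <- align_pass1(data.frame(read_id = "d", sequence = dup_read), ref,
                    align_params())
  expect_equal(p1$class, "ambiguous")
  p2 <- clip_and_realign(p1, ref, align_params())
  expect_equal(p2$class, "ambiguous")  # still maps to both copies
  short <- data.frame(read_id = "s", sequence = random_dna(21))
  p2s <- clip_and_realign(
    data.frame(read_id = "s", sequence = substr(short$sequence, 1, 21),
               class = "unaligned", stringsAsFactors = FALSE),
    ref, align_params())
  expect_equal(p2s$class, "discarded_short")  # 21 - 3 = 18 < 20
})

test_that("junction-spanning reads reach pass 3 and convert to gapped records", {
  txj <- ref$transcripts[["TXJ"]]
  b <- 40L  # junction transcript coordinate
  # left part 10, right part 20 (post-clip right 17 >= 6)
  s <- b - 10L
  read <- convert_all(substr(txj$sequence, s + 1, s + 30))
  reads <- data.frame(read_id = "jr", sequence = read)
  p1 <- align_pass1(reads, ref, align_params())
  expect_equal(p1$class, "unaligned")
  p2 <- clip_and_realign(p1, ref, align_params())
  expect_equal(p2$class, "unaligned")
  p3 <- junction_align(p2, ref, align_params())
  expect_equal(p3$class, "unique")
  expect_equal(p3$pass, 3L)
  # 27 nt after clip: 10 left + 17 right, 30 nt intron gap
  expect_equal(p3$cigar, "10M30D17M")
  expect_equal(p3$start, unname(txj$exon_blocks[1, 2]) - 10L)
  # a junction read with 3 guaranteed mismatches stays unaligned
  jl <- ref$junctions
  off <- jl$flank_len[1] - 10L
  win <- strsplit(substr(jl$sequence[1], off + 1, off + 27), "")[[1]]
  bad <- strsplit(substr(read, 1, 27), "")[[1]]
  for (p in c(5L, 12L, 20L)) bad[p] <- if (win[p] == "G") "A" else "G"
  pb <- junction_align(
    data.frame(read_id = "b", sequence = paste(bad, collapse = ""),
               class = "unaligned", clipped_tail = 3L, stringsAsFactors = FALSE),
    ref, align_params())
  expect_equal(pb$class, "unaligned")
})

test_that("convert_to_genomic arithmetic, degenerate gap, and errors", {
  jl <- ref$junctions
  flank <- jl$flank_len[1]
  g <- convert_to_genomic(list(junction_id = jl$junction_id[1],
                               offset = flank - 10L, read_length = 20L), jl)
  expect_equal(g$cigar, "10M30D10M")
  expect_equal(g$start, jl$left_end[1] - 10L)
  g2 <- convert_to_genomic(list(junction_id = jl$junction_id[1],
                                offset = flank - 19L, read_length = 20L), jl)
  expect_equal(g2$cigar, "19M30D1M")
  expect_error(convert_to_genomic(list(junction_id = jl$junction_id[1],
                                       offset = 0L, read_length = 10L), jl),
               "straddle")
  expect_error(convert_to_genomic(list(junction_id = "nope", offset = 1L,
                                       read_length = 20L), jl), "unknown")
  # abutting blocks (gap 0) merge into a single M
  jl0 <- data.frame(junction_id = "j0", transcript_id = "t", contig = "c",
                    flank_len = 10L, left_start = 0L, left_end = 10L,
                    right_start = 10L, right_end = 20L,
                    sequence = strrep("A", 20), stringsAsFactors = FALSE)
  g0 <- convert_to_genomic(list(junction_id = "j0", offset = 5L,
                                read_length = 10L), jl0)
  expect_equal(g0$cigar, "10M")
})

test_that("outcome classes always partition the input reads", {
  withr::with_seed(55, {
    mixed <- c(
      vapply(1:30, function(i) random_dna(sample(20:30, 1)), character(1)),
      vapply(1:30, function(i) {
        sp <- ref$spaces[[sample(length(ref$spaces), 1)]]
        L <- sample(21:30, 1)
        s <- sample(0:(nchar(sp$sequence) - L), 1)
        convert_all(substr(sp$sequence, s + 1, s + L))
      }, character(1))
    )
  })
  reads <- data.frame(read_id = sprintf("m%03d", seq_along(mixed)),
                      sequence = mixed)
  out <- align_reads(reads, ref, align_params())
  expect_equal(nrow(out), nrow(reads))
  expect_setequal(out$read_id, reads$read_id)
  s <- attr(out, "summary")
  expect_equal(s$n_in, s$unique + s$ambiguous + s$unaligned + s$discarded_short)
})

test_that("lowering max_mismatch never turns an unaligned read into a unique one", {
  withr::with_seed(66, {
    reads <- data.frame(
      read_id = sprintf("x%02d", 1:40),
      sequence = vapply(1:40, function(i) {
        sp <- ref$spaces[[sample(length(ref$spaces), 1)]]
        L <- 25L
        s <- sample(0:(nchar(sp$sequence) - L), 1)
        r <- strsplit(convert_all(substr(sp$sequence, s + 1, s + L)), "")[[1]]
        for (p in sample(L, sample(0:4, 1))) r[p] <- sample(c("A","C","G","T"), 1)
        paste(r, collapse = "")
      }, character(1)))
  })
  classes <- lapply(0:3, function(mm) {
    align_pass1(reads, ref, align_params(max_mismatch = mm))$class
  })
  # reads unaligned at a looser threshold stay unaligned at a stricter one
  for (loose in 2:4) {
    for (strict in 1:(loose - 1)) {
      un_loose <- classes[[loose]] == "unaligned"
      expect_true(all(classes[[strict]][un_loose] == "unaligned"))
    }
  }
})

test_that("SAM output round-trips the unique records", {
  withr::with_seed(77, {
    sp <- ref$spaces[["TXA"]]
    reads <- data.frame(
      read_id = sprintf("s%02d", 1:10),
      sequence = vapply(1:10, function(i) {
        s <- sample(0:(nchar(sp$sequence) - 25), 1)
        convert_all(substr(sp$sequence, s + 1, s + 25))
      }, character(1)))
  })
  out <- align_reads(reads, ref, align_params())
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(out, ref, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@SQ\tSN:cA\t", lines)))
  back <- read_sam(path)
  u <- out[out$class == "unique", ]
  expect_equal(back$read_id, u$read_id)
  expect_equal(back$start, u$start)
  expect_equal(back$cigar, u$cigar)
  expect_equal(back$pass, u$pass)
  expect_equal(back$bs_mismatches, u$bs_mismatches)
})
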