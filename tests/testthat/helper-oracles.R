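# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive re-implementations (per-position loops, step-up
# enumeration, permutation tests) kept separate from the package's own code
# paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- bisulfite mismatch oracle: explicit per-position loop ----------------
oracle_bs_mm <- function(read, win) {
  r <- strsplit(read, "")[[1]]
  w <- strsplit(win, "")[[1]]
  mm <- 0L
  for (i in seq_along(r)) {
    match <- (r[i] == w[i] && r[i] != "N") || (w[i] == "C" && r[i] == "T")
    if (!match) mm <- mm + 1L
  }
  mm
}

# --- alignment oracle: double loop over spaces and offsets ----------------
# Returns class plus (space, offset, mm) of the best hit when unique.
oracle_align <- function(read, reference, max_mismatch = 2L) {
  best_mm <- Inf
  hits <- list()
  for (sp in reference$spaces) {
    N <- nchar(sp$sequence)
    L <- nchar(read)
    if (L > N) next
    for (o in 0:(N - L)) {
      mm <- oracle_bs_mm(read, substr(sp$sequence, o + 1L, o + L))
      if (mm < best_mm) {
        best_mm <- mm
        hits <- list(list(space = sp$space_id, off = o, mm = mm))
      } else if (mm == best_mm) {
        hits[[length(hits) + 1L]] <- list(space = sp$space_id, off = o, mm = mm)
      }
    }
  }
  if (!is.finite(best_mm) || best_mm > max_mismatch) {
    return(list(class = "unaligned"))
  }
  if (length(hits) == 1L) {
    c(list(class = "unique"), hits[[1L]])
  } else {
    list(class = "ambiguous", mm = best_mm)
  }
}

# --- adapter trimming oracle: exhaustive scan over candidate positions,
# repeated to a fixpoint (matching the operation's idempotence contract) ---
oracle_trim_once <- function(read, params) {
  L <- nchar(read)
  ad <- params$adapter
  for (p in seq_len(L)) {
    o <- min(L - p + 1L, nchar(ad))
    if (o < params$stringency) break
    seg <- strsplit(substr(read, p, p + o - 1L), "")[[1]]
    pre <- strsplit(substr(ad, 1L, o), "")[[1]]
    if (sum(seg != pre) <= floor(params$error_rate * o)) {
      return(substr(read, 1L, p - 1L))
    }
  }
  read
}

oracle_trim <- function(read, params) {
  repeat {
    out <- oracle_trim_once(read, params)
    if (identical(out, read)) return(out)
    read <- out
  }
}

# --- scaled-up alignment oracle ------------------------------------------
# Same contract as oracle_align but per-read offset loops over pre-split
# character vectors (vectorized only along the read), fast enough for
# thousand-read equivalence checks while remaining structurally independent
# of the package's read-parallel integer scan.
oracle_align_fast <- function(read, space_chars, max_mismatch = 2L) {
  r <- strsplit(read, "")[[1]]
  L <- length(r)
  valid <- r != "N"
  best_mm <- Inf
  hits <- list()
  for (nm in names(space_chars)) {
    w_all <- space_chars[[nm]]
    N <- length(w_all)
    if (L > N) next
    for (o in 0:(N - L)) {
      w <- w_all[(o + 1):(o + L)]
      mm <- L - sum(((r == w) | (w == "C" & r == "T")) & valid)
      if (mm < best_mm) {
        best_mm <- mm
        hits <- list(list(space = nm, off = o, mm = mm))
      } else if (mm == best_mm) {
        hits[[length(hits) + 1L]] <- list(space = nm, off = o, mm = mm)
      }
    }
  }
  if (!is.finite(best_mm) || best_mm > max_mismatch) return(list(class = "unaligned"))
  if (length(hits) == 1L) c(list(class = "unique"), hits[[1L]])
  else list(class = "ambiguous", mm = best_mm)
}

# --- Welch oracle: textbook formula -----------------------------------------
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# --- BH oracle: literal step-up over the sorted vector --------------------
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(n)
  cur_min <- 1
  for (i in n:1) {
    cur_min <- min(cur_min, sorted[i] * n / i)
    adj[i] <- cur_min
  }
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# --- Mann-Whitney oracle: exact two-sided p by label enumeration ----------
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_of(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2L, u_of)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# --- shared test reference ------------------------------------------------
# Disjoint loci on four contigs: a plus-strand single-exon gene, a
# minus-strand single-exon gene, a duplicated-segment pair (ambiguity), a
# CCA-tailed tRNA with a hostile GGG flank, and a two-exon gene with a
# poly-G intron.
make_test_reference <- function(flank_len = 20L) {
  withr::with_seed(424242, {
    gA <- random_dna(60)
    gB <- random_dna(50)
    dup <- random_dna(40)
    trna <- paste0(random_dna(40), "C", random_dna(19))  # 60 nt body
    e1 <- paste0(random_dna(37), "ATT")                  # 40 nt, non-G tail
    e2 <- paste0("ATTAC", random_dna(35))                # 40 nt, non-G head
    pad <- function(s, post = "A") {
      paste0(strrep("T", 8), s, strrep(post, 8))
    }
    genome <- c(
      cA = pad(gA),
      cB = pad(gB),
      cD = paste0(strrep("T", 8), dup, strrep("A", 25), dup, strrep("A", 8)),
      cT = paste0(strrep("T", 8), trna, "GGG", strrep("A", 8)),
      cJ = paste0(strrep("T", 8), e1, strrep("G", 30), e2, strrep("A", 8))
    )
    txs <- list(
      transcript("TXA", gA, contig = "cA", start = 8L),
      transcript("TXB", reverse_complement(gB), contig = "cB", start = 8L,
                 strand = "-"),
      transcript("DUP1", dup, contig = "cD", start = 8L),
      transcript("DUP2", dup, contig = "cD", start = 8L + 40L + 25L),
      transcript("TRN", paste0(trna, "CCA"), biotype = "tRNA", contig = "cT",
                 start = 8L, has_cca_tail = TRUE),
      transcript("TXJ", paste0(e1, e2), biotype = "mRNA", contig = "cJ",
                 exon_blocks = rbind(c(8L, 48L), c(78L, 118L)))
    )
    sites <- data.frame(transcript_id = "TRN", offset = 40L,
                        stringsAsFactors = FALSE)
    build_reference(txs, sites, genome = genome, flank_len = flank_len,
                    locus_pad = 10L)
  })
}

# Bisulfite-convert a reference fragment in silico (every C -> T), the
# fully-converted read an unmethylated molecule would produce.
convert_all <- function(seq) chartr("C", "T", seq)
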