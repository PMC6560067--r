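# Site selection, Welch's t-test for methyltransferase dependence,
# Benjamini-Hochberg FDR, condition-comparison filtering, and the global
# Mann-Whitney level comparison.

#' Assemble a site matrix from per-replicate pileup tables
#'
#' @param pileups Named nested structure or a list of data.frames each
#'   carrying `condition` and `replicate` columns in addition to the pileup
#'   columns; alternatively pass a single long data.frame directly.
#' @return Long data.frame of class `site_matrix`: `site` (label when
#'   annotated, else `contig:pos:strand`), `condition`, `replicate`,
#'   `n_meth`, `n_unmeth`, `coverage`, `level`.
#' @export
build_site_matrix <- function(pileups) {
  df <- if (is.data.frame(pileups)) pileups else do.call(rbind, pileups)
  stopifnot(all(c("condition", "replicate", "n_meth", "n_unmeth") %in% names(df)))
  if (is.null(df$site)) {
    df$site <- ifelse(!is.null(df$label) & nzchar(df$label), df$label,
                      paste(df$contig, df$pos, df$strand, sep = ":"))
  }
  df$coverage <- df$n_meth + df$n_unmeth
  df$level <- ifelse(df$coverage > 0, df$n_meth / df$coverage, NA_real_)
  out <- df[, c("site", "condition", "replicate", "n_meth", "n_unmeth",
                "coverage", "level")]
  rownames(out) <- NULL
  class(out) <- c("site_matrix", "data.frame")
  out
}

#' Select sites testable for differential methylation
#'
#' Keeps sites whose coverage is strictly greater than `min_cov` in *every*
#' replicate of every tested condition (a site absent from a replicate has
#' zero coverage there and is excluded).
#'
#' @param matrix A long site matrix (see [build_site_matrix()]).
#' @param conditions Conditions that must satisfy the rule (default: all
#'   conditions present).
#' @param min_cov Strict coverage threshold (default 10, i.e. "above 10").
#' @return Character vector of site identifiers.
#' @export
select_testable_sites <- function(matrix, conditions = NULL, min_cov = 10L) {
  if (!nrow(matrix)) return(character(0))
  if (is.null(conditions)) conditions <- unique(matrix$condition)
  m <- matrix[matrix$condition %in% conditions, , drop = FALSE]
  pairs <- unique(paste(m$condition, m$replicate))
  ok <- m$coverage > min_cov
  per_site <- tapply(ok, m$site, sum)
  n_rows <- tapply(ok, m$site, length)
  sites <- names(per_site)[per_site == length(pairs) &
                             n_rows == length(pairs)]
  sort(sites)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom.
#' Degenerate zero-variance inputs are resolved by convention: two constant
#' equal groups give `t = 0, p = 1`; constant but unequal groups are tested
#' with the variance replaced by machine epsilon and flagged so the caller
#' can audit them.
#'
#' @param levels_a,levels_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, and `flagged` (zero-variance
#'   convention applied).
#' @export
welch_test <- function(levels_a, levels_b) {
  if (length(levels_a) < 2L || length(levels_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  va <- stats::var(levels_a); vb <- stats::var(levels_b)
  if (va == 0 && vb == 0) {
    if (mean(levels_a) == mean(levels_b)) {
      return(list(t = 0, df = length(levels_a) + length(levels_b) - 2,
                  p = 1, flagged = TRUE))
    }
    eps <- .Machine$double.eps
    na <- length(levels_a); nb <- length(levels_b)
    se2a <- eps / na; se2b <- eps / nb
    t_stat <- (mean(levels_a) - mean(levels_b)) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    return(list(t = t_stat, df = df,
                p = 2 * stats::pt(-abs(t_stat), df), flagged = TRUE))
  }
  res <- stats::t.test(levels_a, levels_b)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, flagged = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; monotone, capped at 1, original
#' order restored.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call methyltransferase-dependent methylation sites
#'
#' For each testable site, the rescue condition is compared against each
#' comparator (e.g. empty-vector control and the enzymatic dead K190M
#' mutant) with Welch's t-test; p-values are BH-adjusted within each
#' contrast across sites. A site is `dependent` when both contrasts reach
#' `padj < alpha` *and* the rescue mean exceeds both comparator means
#' (methylation restored by the active enzyme).
#'
#' @param matrix A long site matrix.
#' @param comparators Character vector of comparator condition labels.
#' @param rescue Rescue condition label.
#' @param alpha Significance threshold on adjusted p-values (default 0.05).
#' @param min_cov Per-replicate coverage threshold for testability
#'   (strict `>`; default 10).
#' @return data.frame of class `dependence_calls`, one row per site:
#'   per-condition means, per-contrast `t`/`df`/`p`/`padj`/`diff`
#'   (rescue - comparator), `flagged`, and `verdict` in
#'   `dependent`/`not_dependent`/`not_tested`.
#' @export
call_dependent_sites <- function(matrix, comparators = c("ctr", "K190M"),
                                 rescue = "NSUN2", alpha = 0.05,
                                 min_cov = 10L) {
  conds <- c(comparators, rescue)
  missing <- setdiff(conds, unique(matrix$condition))
  if (length(missing)) {
    stop("condition(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  all_sites <- sort(unique(matrix$site))
  testable <- select_testable_sites(matrix, conditions = conds,
                                    min_cov = min_cov)
  out <- data.frame(site = all_sites, stringsAsFactors = FALSE)
  for (cond in conds) {
    mc <- matrix[matrix$condition == cond, , drop = FALSE]
    mean_lv <- tapply(mc$level, mc$site, mean)
    out[[paste0("mean_", cond)]] <- as.numeric(mean_lv[out$site])
  }
  out$flagged <- FALSE
  by_cond <- lapply(setNames(conds, conds), function(cond) {
    mc <- matrix[matrix$condition == cond, , drop = FALSE]
    split(mc$level, mc$site)
  })
  sig_up <- matrix(NA, nrow(out), length(comparators))
  for (ci in seq_along(comparators)) {
    comp <- comparators[ci]
    tt <- rep(NA_real_, nrow(out)); df_ <- rep(NA_real_, nrow(out))
    pp <- rep(NA_real_, nrow(out)); dd <- rep(NA_real_, nrow(out))
    for (s in testable) {
      i <- match(s, out$site)
      a <- by_cond[[rescue]][[s]]
      b <- by_cond[[comp]][[s]]
      w <- welch_test(a, b)
      tt[i] <- w$t; df_[i] <- w$df; pp[i] <- w$p
      dd[i] <- mean(a) - mean(b)
      out$flagged[i] <- out$flagged[i] | w$flagged
    }
    padj <- rep(NA_real_, nrow(out))
    idx <- !is.na(pp)
    padj[idx] <- bh_fdr(pp[idx])
    out[[paste0("t_", comp)]] <- tt
    out[[paste0("df_", comp)]] <- df_
    out[[paste0("p_", comp)]] <- pp
    out[[paste0("padj_", comp)]] <- padj
    out[[paste0("diff_", comp)]] <- dd
    sig_up[, ci] <- padj < alpha & dd > 0
  }
  tested <- out$site %in% testable
  out$verdict <- ifelse(!tested, "not_tested",
                        ifelse(apply(sig_up, 1L, function(x) all(x %in% TRUE)),
                               "dependent", "not_dependent"))
  class(out) <- c("dependence_calls", "data.frame")
  out
}

#' Select sites for a two-condition level comparison
#'
#' Keeps sites showing, in at least one of the two conditions, pooled read
#' coverage strictly greater than `min_cov` together with a pooled
#' methylation level of at least `min_level` (counts are pooled across the
#' replicates of a condition).
#'
#' @param matrix A long site matrix restricted to two conditions.
#' @param min_cov Strict pooled-coverage threshold (default 100).
#' @param min_level Minimum pooled methylation level (default 0.20).
#' @return data.frame: `site`, per-condition pooled `coverage_` and
#'   `level_` columns, restricted to the selected sites.
#' @export
select_comparison_sites <- function(matrix, min_cov = 100L, min_level = 0.20) {
  conds <- unique(matrix$condition)
  if (length(conds) != 2L) stop("expected exactly two conditions, got ",
                                length(conds))
  out <- data.frame(site = sort(unique(matrix$site)), stringsAsFactors = FALSE)
  keep <- rep(FALSE, nrow(out))
  for (cond in conds) {
    mc <- matrix[matrix$condition == cond, , drop = FALSE]
    nm <- tapply(mc$n_meth, mc$site, sum)
    nu <- tapply(mc$n_unmeth, mc$site, sum)
    cov <- as.numeric(nm[out$site]) + as.numeric(nu[out$site])
    lvl <- as.numeric(nm[out$site]) / cov
    cov[is.na(cov)] <- 0; lvl[is.na(lvl)] <- 0
    out[[paste0("coverage_", cond)]] <- cov
    out[[paste0("level_", cond)]] <- lvl
    keep <- keep | (cov > min_cov & lvl >= min_level)
  }
  out[keep, , drop = FALSE]
}

#' Global Mann-Whitney comparison of methylation levels
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test comparing the per-site
#' methylation levels of two conditions: exact for small untied samples
#' (both n <= 8), otherwise the normal approximation with tie correction.
#' Fully tied degenerate inputs give `p = 1` by convention.
#'
#' @param levels_a,levels_b Non-empty numeric vectors.
#' @return List with `U` (statistic for the first sample) and `p`.
#' @export
global_level_comparison <- function(levels_a, levels_b) {
  if (!length(levels_a) || !length(levels_b)) stop("empty group")
  if (length(unique(c(levels_a, levels_b))) == 1L) {
    return(list(U = length(levels_a) * length(levels_b) / 2, p = 1))
  }
  exact <- length(levels_a) <= 8L && length(levels_b) <= 8L &&
    !anyDuplicated(c(levels_a, levels_b))
  res <- suppressWarnings(
    stats::wilcox.test(levels_a, levels_b, exact = exact, correct = TRUE)
  )
  list(U = unname(res$statistic), p = res$p.value)
}
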