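## Sweep and balancing-selection scans: pairwise-homozygosity-tract
## H statistic, SNP-binned empirical p-values, a kernel beta statistic,
## and windowed Patterson's D.

#' Pairwise-homozygosity-tract H statistic
#'
#' For a focal position x and a haplotype pair (i, j), the shared tract
#' is bounded by the nearest segregating site strictly left and strictly
#' right of x at which i and j differ (truncated at the contig ends).
#' H(x) is the mean tract length over all pairs.  Elevated H marks
#' recent sweeps (long shared haplotypes).  Sites where either haplotype
#' is missing are skipped for that pair (pairwise-complete).
#'
#' @param H `haplotype_set` (>= 2 haplotypes).
#' @param focal_positions positions scored (default: the set's
#'   segregating sites, matching per-SNP scan output granularity).
#' @return data.frame of class `hscan_track` with `pos` and `h`.
#' @export
h_statistic <- function(H, focal_positions = NULL) {
  A <- H$alleles
  n <- ncol(A)
  .assert(n >= 2, "need at least 2 haplotypes")
  seg <- .segregating(A)
  spos <- H$pos[seg]
  As <- A[seg, , drop = FALSE]
  if (is.null(focal_positions)) focal_positions <- spos
  .assert(length(focal_positions) >= 1, "need at least one focal position")
  fp <- as.numeric(focal_positions)
  L <- as.numeric(H$contig_length)

  acc <- numeric(length(fp))
  n_pairs <- 0L
  for (i in seq_len(n - 1)) {
    ai <- As[, i]
    for (j in (i + 1):n) {
      aj <- As[, j]
      mism <- spos[which(ai != aj)]   # NA comparisons drop out
      n_pairs <- n_pairs + 1L
      if (!length(mism)) {
        acc <- acc + L
        next
      }
      nlt <- findInterval(fp - 0.5, mism)      # mismatches strictly left
      nle <- findInterval(fp + 0.5, mism)      # mismatches at or left
      left <- ifelse(nlt > 0, mism[pmax(nlt, 1)], 0)
      left[nlt == 0] <- 0
      right <- ifelse(nle < length(mism), mism[pmin(nle + 1, length(mism))], L)
      right[nle >= length(mism)] <- L
      acc <- acc + (right - left)
    }
  }
  out <- data.frame(pos = focal_positions, h = acc / n_pairs)
  class(out) <- c("hscan_track", "data.frame")
  out
}

#' Per-window maximum H
#'
#' The representative summary per window is the maximum H over focal
#' sites in the window; windows without focal sites are `NA`.
#'
#' @param track `hscan_track` from [h_statistic()].
#' @param windows window table (uses `n_snp` when present for the
#'   empirical-p binning downstream).
#' @return `windows` with columns `max_h` and `n_focal` added.
#' @export
window_max_h <- function(track, windows) {
  out <- windows
  out$max_h <- NA_real_
  out$n_focal <- 0L
  for (i in seq_len(nrow(windows))) {
    sel <- track$pos > windows$start[i] & track$pos <= windows$end[i]
    out$n_focal[i] <- sum(sel)
    if (any(sel)) out$max_h[i] <- max(track$h[sel])
  }
  out
}

#' Empirical p-values from SNP-count bins
#'
#' Windows are binned by SNP count in `bin_width` increments; windows
#' with more than `merge_threshold` SNPs share one bin.  Within a bin the
#' empirical p of a window is the fraction of windows (including itself,
#' so p > 0) whose summary statistic is at least as large.  Windows with
#' zero SNPs are excluded.
#'
#' @param windows window table with columns `n_snp` and the summary
#'   statistic (`stat_col`).
#' @param stat_col name of the summary column (default `"max_h"`).
#' @param bin_width SNP-bin width (default 50).
#' @param merge_threshold SNP count above which all windows share one
#'   bin (default 100).
#' @param alpha candidate threshold (default 0.05, strict `<`).
#' @return `windows` with `snp_bin`, `emp_p` and `candidate` columns
#'   (excluded windows keep `NA`).
#' @export
empirical_p_by_snp_bins <- function(windows, stat_col = "max_h",
                                    bin_width = 50, merge_threshold = 100,
                                    alpha = 0.05) {
  out <- windows
  out$snp_bin <- NA_character_
  out$emp_p <- NA_real_
  out$candidate <- NA
  usable <- which(windows$n_snp > 0 & !is.na(windows[[stat_col]]))
  if (!length(usable)) return(out)
  ns <- windows$n_snp[usable]
  bin <- ifelse(ns > merge_threshold,
                sprintf("(%d,Inf]", merge_threshold),
                sprintf("(%d,%d]", (ceiling(ns / bin_width) - 1L) * bin_width,
                        ceiling(ns / bin_width) * bin_width))
  for (b in unique(bin)) {
    idx <- usable[bin == b]
    v <- windows[[stat_col]][idx]
    m <- length(v)
    ge <- m - rank(v, ties.method = "min") + 1L  # count of values >= v_i
    out$snp_bin[idx] <- b
    out$emp_p[idx] <- ge / m
    out$candidate[idx] <- ge / m < alpha
  }
  out
}

#' Kernel beta statistic for balancing selection
#'
#' For each core SNP, `beta = theta_beta - theta_W` over the SNPs within
#' `window_bp` of the core (the core excluded): `theta_W = S / a1`, and
#' `theta_beta = (sum_i w_i / wbar) / a1` where
#' `w_i = max(0, 1 - |f_i - f_core| / d)` is a triangular kernel on
#' folded frequencies and `wbar` is the expected kernel weight under a
#' uniform folded frequency, so that the neutral expectation is ~0.
#' Positive beta marks an excess of neighbours at the core's frequency.
#'
#' @param H `haplotype_set`.
#' @param core_positions positions scored (default: all segregating
#'   sites).
#' @param window_bp half-window around the core in bp (default 10 kb).
#' @param d kernel half-width on folded frequencies (default 0.2).
#' @return data.frame of class `beta_track`: pos, folded frequency,
#'   beta, and neighbour count (`NA` beta when no neighbours).
#' @export
beta_statistic <- function(H, core_positions = NULL, window_bp = 1e4, d = 0.2) {
  A <- H$alleles
  n <- ncol(A)
  k <- .tajima_constants(n)
  seg <- .segregating(A)
  spos <- H$pos[seg]
  f <- .hap_freq(A[seg, , drop = FALSE])
  fold <- pmin(f$p, 1 - f$p)
  if (is.null(core_positions)) core_positions <- spos
  ci <- match(core_positions, spos)
  .assert(!anyNA(ci), "core positions must be segregating sites of H")

  wbar <- function(fc) {
    ## mean triangular weight for f ~ Uniform(0, 0.5]
    a <- pmax(0, fc - d); b <- pmin(0.5, fc + d)
    area <- (b - a) - ((fc - a)^2 + (b - fc)^2) / (2 * d)
    area / 0.5
  }
  out <- data.frame(pos = core_positions, folded_freq = fold[ci],
                    beta = NA_real_, n_neighbours = 0L)
  for (q in seq_along(ci)) {
    i <- ci[q]
    nb <- which(abs(spos - spos[i]) <= window_bp)
    nb <- setdiff(nb, i)
    out$n_neighbours[q] <- length(nb)
    if (!length(nb)) next
    w <- pmax(0, 1 - abs(fold[nb] - fold[i]) / d)
    S <- length(nb)
    theta_w <- S / k$a1
    theta_b <- (sum(w) / wbar(fold[i])) / k$a1
    out$beta[q] <- theta_b - theta_w
  }
  class(out) <- c("beta_track", "data.frame")
  out
}

#' Windowed Patterson's D (ABBA-BABA)
#'
#' Per site, `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3
#' (1-p4)`; windowed `D = sum(ABBA-BABA) / sum(ABBA+BABA)` (`NA` when
#' the denominator is 0).
#'
#' @param p1,p2,p3,p4 aligned per-site derived-allele frequency series
#'   (P1, P2 ingroups, P3 test population, P4 outgroup).
#' @param pos 1-based site positions.
#' @param windows window table.
#' @return data.frame of class `dstat_track`: windows plus abba, baba, d.
#' @export
patterson_d <- function(p1, p2, p3, p4, pos, windows) {
  .assert(length(p1) == length(p2) && length(p2) == length(p3) &&
            length(p3) == length(p4) && length(p4) == length(pos),
          "frequency series must be aligned")
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  out <- windows
  out$abba <- NA_real_; out$baba <- NA_real_; out$d <- NA_real_
  for (i in seq_len(nrow(windows))) {
    sel <- pos > windows$start[i] & pos <= windows$end[i]
    a <- sum(abba[sel], na.rm = TRUE); b <- sum(baba[sel], na.rm = TRUE)
    out$abba[i] <- a; out$baba[i] <- b
    out$d[i] <- if (a + b > 0) (a - b) / (a + b) else NA_real_
  }
  class(out) <- c("dstat_track", "data.frame")
  out
}
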