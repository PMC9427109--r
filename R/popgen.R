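## Windowed diversity/divergence statistics with accessible-site
## correction, SFS, LD decay, and the Ne-ratio estimator.

.window_site_index <- function(pos, windows) {
  ## list of site indices per window ([start, end) 0-based; pos 1-based)
  lapply(seq_len(nrow(windows)), function(i) {
    which(pos > windows$start[i] & pos <= windows$end[i])
  })
}

#' Windowed nucleotide diversity (pi)
#'
#' Unbiased per-site heterozygosity summed over sites and divided by the
#' window's accessible length: `pi_w = sum_s [n_s/(n_s-1)] 2 p (1-p) /
#' L_acc`.  The denominator is accessible bases (`l_acc`), not window
#' span, correcting the inflation that arises when variants-only input
#' cannot distinguish missing from monomorphic sequence.
#'
#' @param H `haplotype_set` (at least 2 haplotypes with data) or a
#'   `genotype_matrix` (alleles counted from dosages; equals the
#'   haplotype path on fully phased complete data).
#' @param windows window table from [make_windows()] (column `l_acc`
#'   used as the denominator; windows with `l_acc` 0 give `NA`).
#' @return numeric vector of per-window pi.
#' @export
nucleotide_diversity <- function(H, windows) {
  if (inherits(H, "genotype_matrix")) {
    n_ok <- rowSums(!is.na(H$geno))
    f <- list(p = rowSums(H$geno, na.rm = TRUE) / (2 * pmax(n_ok, 1)),
              n = 2 * n_ok)
    H <- list(pos = H$sites$pos)
  } else {
    f <- .hap_freq(H$alleles)
  }
  per_site <- ifelse(f$n >= 2, f$n / (f$n - 1) * 2 * f$p * (1 - f$p), 0)
  idx <- .window_site_index(H$pos, windows)
  out <- vapply(seq_along(idx), function(i) {
    if (windows$l_acc[i] <= 0) return(NA_real_)
    sum(per_site[idx[[i]]]) / windows$l_acc[i]
  }, numeric(1))
  out
}

#' Windowed absolute divergence d_XY between two haplotype sets
#'
#' `d_XY,w = sum_s [p1 (1-p2) + p2 (1-p1)] / L_acc` over the shared site
#' grid.
#'
#' @param H1,H2 `haplotype_set`s on the same site grid.
#' @param windows window table (uses `l_acc`).
#' @return numeric vector of per-window d_XY.
#' @export
dxy <- function(H1, H2, windows) {
  .assert(identical(H1$pos, H2$pos), "haplotype sets must share the site grid")
  f1 <- .hap_freq(H1$alleles); f2 <- .hap_freq(H2$alleles)
  per_site <- f1$p * (1 - f2$p) + f2$p * (1 - f1$p)
  per_site[is.na(per_site)] <- 0
  idx <- .window_site_index(H1$pos, windows)
  vapply(seq_along(idx), function(i) {
    if (windows$l_acc[i] <= 0) return(NA_real_)
    sum(per_site[idx[[i]]]) / windows$l_acc[i]
  }, numeric(1))
}

#' Windowed density of fixed differences (d_f)
#'
#' @param fd `fixed_diff_set`.
#' @param windows window table (uses `l_acc`).
#' @return numeric vector: fixed differences per accessible bp.
#' @export
fixed_diff_density <- function(fd, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    if (windows$l_acc[i] <= 0) return(NA_real_)
    sum(fd$pos > windows$start[i] & fd$pos <= windows$end[i]) / windows$l_acc[i]
  }, numeric(1))
}

#' Windowed Hudson F_ST (ratio of averages)
#'
#' Per-site `N_s = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D_s = p1(1-p2) + p2(1-p1)`; the window value is `sum N_s / sum D_s`.
#' Windows without any site with `D_s > 0` are `NA`.  A Weir-Cockerham
#' style estimator is not provided for haplotype data; Hudson's is the
#' standard choice.
#'
#' @param H1,H2 `haplotype_set`s (>= 2 haplotypes each) on one grid.
#' @param windows window table.
#' @return numeric vector of per-window F_ST.
#' @export
fst <- function(H1, H2, windows) {
  .assert(identical(H1$pos, H2$pos), "haplotype sets must share the site grid")
  f1 <- .hap_freq(H1$alleles); f2 <- .hap_freq(H2$alleles)
  ok <- f1$n >= 2 & f2$n >= 2
  p1 <- f1$p; p2 <- f2$p
  Ns <- (p1 - p2)^2 - p1 * (1 - p1) / (f1$n - 1) - p2 * (1 - p2) / (f2$n - 1)
  Ds <- p1 * (1 - p2) + p2 * (1 - p1)
  Ns[!ok] <- 0; Ds[!ok] <- 0
  Ns[is.na(Ns)] <- 0; Ds[is.na(Ds)] <- 0
  idx <- .window_site_index(H1$pos, windows)
  vapply(seq_along(idx), function(i) {
    d <- sum(Ds[idx[[i]]])
    if (d <= 0) return(NA_real_)
    sum(Ns[idx[[i]]]) / d
  }, numeric(1))
}

.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard Tajima (1989) D from the segregating-site count and the mean
#' pairwise difference per window.  Sites with missing alleles use the
#' unbiased per-site estimator with their own non-missing count; the
#' constants use the set's haplotype count.  Windows with no segregating
#' site are `NA`.
#'
#' @param H `haplotype_set` (n >= 4 recommended).
#' @param windows window table.
#' @return numeric vector of per-window D.
#' @export
tajimas_d <- function(H, windows) {
  n <- ncol(H$alleles)
  .assert(n >= 2, "need at least 2 haplotypes")
  k <- .tajima_constants(n)
  f <- .hap_freq(H$alleles)
  seg <- f$count > 0 & f$count < f$n & f$n >= 2
  per_site_pi <- ifelse(seg, f$n / (f$n - 1) * 2 * f$p * (1 - f$p), 0)
  idx <- .window_site_index(H$pos, windows)
  vapply(seq_along(idx), function(i) {
    S <- sum(seg[idx[[i]]])
    if (S == 0) return(NA_real_)
    pi_sum <- sum(per_site_pi[idx[[i]]])
    v <- k$e1 * S + k$e2 * S * (S - 1)
    (pi_sum - S / k$a1) / sqrt(v)
  }, numeric(1))
}

#' Folded (minor-allele) site frequency spectrum
#'
#' Counts of minor-allele occurrences over complete-case sites, with
#' optional singleton exclusion.
#'
#' @param H `haplotype_set`.
#' @param exclude_singletons drop minor-allele-count-1 sites.
#' @return list of class `sfs`: `counts` (named vector over bins
#'   `1..floor(n/2)`), `n` haplotypes, `exclude_singletons`.
#' @export
folded_sfs <- function(H, exclude_singletons = FALSE) {
  n <- ncol(H$alleles)
  f <- .hap_freq(H$alleles)
  complete <- f$n == n
  mac <- pmin(f$count, n - f$count)
  mac <- mac[complete & f$count > 0 & f$count < n]
  if (exclude_singletons) mac <- mac[mac > 1]
  bins <- seq_len(floor(n / 2))
  counts <- table(factor(mac, levels = bins))
  structure(list(counts = setNames(as.integer(counts), bins), n = n,
                 exclude_singletons = exclude_singletons), class = "sfs")
}

#' Linkage-disequilibrium decay
#'
#' Pairwise `r^2 = D^2 / (pA pa pB pb)` from haplotype frequencies for
#' all segregating site pairs within `max_dist`, averaged in distance
#' bins.
#'
#' @param H `haplotype_set` (phased; complete-case pairs used).
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data.frame with bin midpoint, mean r2 and pair count.
#' @export
ld_decay <- function(H, max_dist = 5e4, bin_width = 1000) {
  A <- H$alleles
  seg <- .segregating(A)
  A <- A[seg, , drop = FALSE]
  pos <- H$pos[seg]
  S <- length(pos)
  if (S < 2)
    return(data.frame(dist = numeric(), r2 = numeric(), n_pairs = integer()))
  res_d <- list(); res_r <- list(); m <- 0L
  for (i in seq_len(S - 1)) {
    jmax <- i + findInterval(pos[i] + max_dist, pos[(i + 1):S])
    if (jmax <= i) next
    js <- (i + 1):jmax
    ai <- A[i, ]
    pA <- mean(ai, na.rm = TRUE)
    Bm <- A[js, , drop = FALSE]
    ok <- !is.na(ai)
    pAB <- colMeans(t(Bm[, ok, drop = FALSE]) * ai[ok], na.rm = TRUE)
    pB <- rowMeans(Bm, na.rm = TRUE)
    D <- pAB - pA * pB
    den <- pA * (1 - pA) * pB * (1 - pB)
    r2 <- ifelse(den > 0, D^2 / den, NA_real_)
    m <- m + 1L
    res_d[[m]] <- pos[js] - pos[i]
    res_r[[m]] <- r2
  }
  d <- unlist(res_d); r2 <- unlist(res_r)
  keep <- !is.na(r2)
  d <- d[keep]; r2 <- r2[keep]
  bin <- pmin(ceiling(d / bin_width), ceiling(max_dist / bin_width))
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  data.frame(dist = (as.integer(names(agg)) - 0.5) * bin_width,
             r2 = as.numeric(agg), n_pairs = as.integer(cnt))
}

#' Ratio of effective population sizes from synonymous diversity
#'
#' Ratio of mean per-window synonymous pi between the rearranged and
#' standard arrangements, with a block-bootstrap standard error
#' (block = window).
#'
#' @param pi_s_2m,pi_s_2 paired per-window synonymous pi series.
#' @param reps bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list with `ratio`, `se`, and the bootstrap quantiles
#'   `ci95` (2.5/97.5%).
#' @export
ne_ratio <- function(pi_s_2m, pi_s_2, reps = 1000, seed = 1) {
  .assert(length(pi_s_2m) == length(pi_s_2), "series must be paired")
  ok <- !is.na(pi_s_2m) & !is.na(pi_s_2)
  x <- pi_s_2m[ok]; y <- pi_s_2[ok]
  if (!length(x) || mean(y) == 0)
    return(list(ratio = NA_real_, se = NA_real_, ci95 = c(NA_real_, NA_real_)))
  ratio <- mean(x) / mean(y)
  set.seed(seed)
  n <- length(x)
  boots <- vapply(seq_len(reps), function(r) {
    i <- sample.int(n, n, replace = TRUE)
    if (mean(y[i]) == 0) return(NA_real_)
    mean(x[i]) / mean(y[i])
  }, numeric(1))
  list(ratio = ratio, se = sd(boots, na.rm = TRUE),
       ci95 = unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE)))
}

#' Expected arrangement chromosome-count ratio from morph counts
#'
#' Rearranged vs standard chromosome copies implied by a morph census:
#' `(n_WS + 2 n_SW) / (n_WS + 2 n_TS)`.  Under balanced morph
#' frequencies (equal TS and WS, rare SW) this evaluates to 1/3, the
#' census expectation for the ratio of effective population sizes.
#'
#' @param n_ts,n_ws,n_sw morph counts.
#' @return numeric ratio.
#' @export
arrangement_count_ratio <- function(n_ts, n_ws, n_sw = 0) {
  (n_ws + 2 * n_sw) / (n_ws + 2 * n_ts)
}

#' Combined window statistics table
#'
#' Convenience wrapper computing pi for each class, d_XY, d_f, F_ST and
#' Tajima's D on a shared window tiling.
#'
#' @param H1,H2 `haplotype_set`s for the two arrangement classes.
#' @param windows window table from [make_windows()].
#' @param fd optional `fixed_diff_set` for d_f.
#' @return data.frame of class `window_stat_table`.
#' @export
window_stats <- function(H1, H2, windows, fd = NULL) {
  out <- windows
  out$pi_1 <- nucleotide_diversity(H1, windows)
  out$pi_2 <- nucleotide_diversity(H2, windows)
  out$dxy <- dxy(H1, H2, windows)
  out$fst <- fst(H1, H2, windows)
  out$tajima_d_1 <- tajimas_d(H1, windows)
  out$tajima_d_2 <- tajimas_d(H2, windows)
  out$d_f <- if (!is.null(fd)) fixed_diff_density(fd, windows) else NA_real_
  out$n1 <- ncol(H1$alleles); out$n2 <- ncol(H2$alleles)
  class(out) <- c("window_stat_table", "data.frame")
  out
}
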