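## Outlier regions, haplogroups, genotype-plot matrices, and
## allele-specific-expression integration.

#' Detect high-diversity outlier regions
#'
#' Candidate regions are maximal runs of at least `min_windows`
#' consecutive windows whose pi exceeds the track's 95th percentile.
#' Each region's permutation p is the fraction of `n_perms` circular
#' rotations of the window-value sequence in which the same-length run
#' at the region's location has mean Tajima's D at least as large as
#' observed (rotations preserve the track's autocorrelation).
#'
#' @param stats data.frame with per-window `pi` and `tajima_d` columns
#'   in genomic order (e.g. a `window_stat_table` for the rearranged
#'   class, with its columns renamed).
#' @param min_windows minimum run length (default 5).
#' @param n_perms number of rotations (>= 100).
#' @param seed RNG seed.
#' @param pi_quantile percentile defining "elevated" (default 0.95).
#' @return data.frame of class `outlier_regions`: one row per region
#'   with window span, mean pi/D inside and outside, and permutation p.
#' @export
detect_outlier_regions <- function(stats, min_windows = 5, n_perms = 1000,
                                   seed = 1, pi_quantile = 0.95) {
  .assert(n_perms >= 100, "n_perms must be >= 100")
  pi <- stats$pi; td <- stats$tajima_d
  W <- length(pi)
  thr <- quantile(pi, pi_quantile, na.rm = TRUE)
  hot <- !is.na(pi) & pi > thr
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_windows)
  if (!length(sel)) {
    out <- data.frame(first_window = integer(), last_window = integer(),
                      start = integer(), end = integer(), n_windows = integer(),
                      mean_pi = numeric(), mean_td = numeric(),
                      bg_mean_pi = numeric(), bg_mean_td = numeric(),
                      perm_p = numeric())
    class(out) <- c("outlier_regions", "data.frame")
    return(out)
  }
  n_region <- sum(r$lengths[sel])
  if (W - n_region < 10 * n_region)
    warning("fewer than 10x background windows; permutation p unreliable")
  set.seed(seed)
  rows <- lapply(sel, function(s) {
    i0 <- starts[s]; i1 <- ends[s]
    idx <- i0:i1
    obs <- mean(td[idx], na.rm = TRUE)
    offs <- sample.int(W - 1, n_perms, replace = TRUE)
    perm <- vapply(offs, function(o) {
      mean(td[((idx - 1 + o) %% W) + 1], na.rm = TRUE)
    }, numeric(1))
    data.frame(first_window = i0, last_window = i1,
               start = stats$start[i0], end = stats$end[i1],
               n_windows = length(idx),
               mean_pi = mean(pi[idx], na.rm = TRUE),
               mean_td = obs,
               bg_mean_pi = mean(pi[-idx], na.rm = TRUE),
               bg_mean_td = mean(td[-idx], na.rm = TRUE),
               perm_p = mean(perm >= obs))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("outlier_regions", "data.frame")
  out
}

#' Pairwise Hamming distance between haplotypes
#'
#' Mismatch fraction over pairwise-complete sites; pairs with no shared
#' non-missing site are `NA`.
#'
#' @param H `haplotype_set`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwise_hamming <- function(H) {
  A <- H$alleles
  n <- ncol(A)
  .assert(n >= 2, "need at least 2 haplotypes")
  M <- matrix(0, n, n)
  obs <- !is.na(A)
  Ax <- A; Ax[!obs] <- 0L
  shared <- crossprod(obs)            # pairwise-complete site counts
  ## mismatches = sum over shared sites of xor(a_i, a_j)
  ones <- crossprod(Ax * obs)         # both 1
  oi <- crossprod(Ax * obs, obs)      # i==1 & j observed
  mism <- (oi - ones) + (t(oi) - ones)
  M <- ifelse(shared > 0, mism / shared, NA_real_)
  diag(M) <- 0
  dimnames(M) <- list(H$sample, H$sample)
  M
}

.silhouette_mean <- function(D, labels) {
  k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster haplotypes into haplogroups
#'
#' Average-linkage hierarchical clustering of the Hamming distance
#' matrix; the number of groups maximizes the mean silhouette over
#' `2..max_k`.  Groups smaller than `min_size` are reported as
#' ungrouped (`NA` label), mirroring the exclusion of tiny putative
#' haplogroups from downstream analyses.
#'
#' @param distmat symmetric distance matrix (e.g. [pairwise_hamming()]).
#' @param min_size minimum group size (default 3).
#' @param max_k maximum number of groups tried (default 5).
#' @return list of class `haplogroup_partition`: `labels` (integer or
#'   `NA` per haplotype), `k`, `sizes`, `silhouette`, and mean
#'   within/between distances.
#' @export
cluster_haplogroups <- function(distmat, min_size = 3, max_k = 5) {
  n <- nrow(distmat)
  if (n < 4) {
    warning("fewer than 4 haplotypes; returning a single group")
    labels <- rep(1L, n)
    return(structure(list(labels = labels, k = 1L, sizes = n,
                          silhouette = NA_real_,
                          mean_within = mean(distmat[upper.tri(distmat)]),
                          mean_between = NA_real_),
                     class = "haplogroup_partition"))
  }
  if (max(distmat, na.rm = TRUE) == 0) {
    return(structure(list(labels = rep(1L, n), k = 1L, sizes = n,
                          silhouette = NA_real_, mean_within = 0,
                          mean_between = NA_real_),
                     class = "haplogroup_partition"))
  }
  hc <- hclust(as.dist(distmat), method = "average")
  ks <- 2:min(max_k, n - 1)
  sil <- vapply(ks, function(k) .silhouette_mean(distmat, cutree(hc, k)),
                numeric(1))
  k <- ks[which.max(sil)]
  raw <- cutree(hc, k)
  sizes <- table(raw)
  keep_groups <- as.integer(names(sizes)[sizes >= min_size])
  labels <- ifelse(raw %in% keep_groups, match(raw, sort(keep_groups)), NA_integer_)
  grouped <- !is.na(labels)
  within <- c(); between <- c()
  for (g in unique(labels[grouped])) {
    gi <- which(labels == g)
    if (length(gi) > 1) within <- c(within, distmat[gi, gi][upper.tri(distmat[gi, gi])])
    oth <- which(grouped & labels != g)
    if (length(oth)) between <- c(between, as.vector(distmat[gi, oth]))
  }
  structure(list(labels = labels, k = length(keep_groups),
                 sizes = as.integer(sizes[as.character(keep_groups)]),
                 silhouette = max(sil),
                 mean_within = if (length(within)) mean(within) else NA_real_,
                 mean_between = if (length(between)) mean(between) else NA_real_),
            class = "haplogroup_partition")
}

#' @export
print.haplogroup_partition <- function(x, ...) {
  cat(sprintf("<haplogroup_partition> k=%d group(s) of size %s; %d ungrouped; mean silhouette %.3f\n",
              x$k, paste(x$sizes, collapse = "/"), sum(is.na(x$labels)),
              x$silhouette))
  invisible(x)
}

#' d_XY tracks between haplogroups and the standard arrangement
#'
#' @param H_region `haplotype_set` of rearranged haplotypes over the
#'   region.
#' @param partition `haplogroup_partition` for those haplotypes.
#' @param H_std `haplotype_set` of standard (ZAL2) haplotypes on the
#'   same grid.
#' @param windows window table.
#' @return data.frame: windows plus `dxy_h1_z2`, `dxy_h2_z2`,
#'   `dxy_h1_h2` (NA tracks for empty groups).
#' @export
haplogroup_dxy <- function(H_region, partition, H_std, windows) {
  pick <- function(g) {
    idx <- which(!is.na(partition$labels) & partition$labels == g)
    if (!length(idx)) return(NULL)
    haplotype_set(H_region$alleles[, idx, drop = FALSE], H_region$pos,
                  H_region$contig, H_region$contig_length,
                  H_region$class[idx], H_region$sample[idx])
  }
  H1 <- pick(1L); H2 <- pick(2L)
  out <- windows
  out$dxy_h1_z2 <- if (!is.null(H1)) dxy(H1, H_std, windows) else NA_real_
  out$dxy_h2_z2 <- if (!is.null(H2)) dxy(H2, H_std, windows) else NA_real_
  out$dxy_h1_h2 <- if (!is.null(H1) && !is.null(H2)) dxy(H1, H2, windows) else NA_real_
  out
}

#' Genotype-plot matrix relative to the rearranged-homozygote reference
#'
#' Per haplotype per site: `MAJOR` when the allele matches the
#' super-white (rearranged homozygote) genome, `MINOR` when it differs,
#' `MISSING` when unresolved or when the site is absent from the
#' reference genotypes.
#'
#' @param H `haplotype_set` over the region.
#' @param sw_alleles integer vector (0/1/NA) of the super-white allele
#'   at each site of `H`.
#' @return character matrix sites x haplotypes of class
#'   `genotype_plot_matrix`.
#' @export
genotype_plot_matrix <- function(H, sw_alleles) {
  .assert(length(sw_alleles) == nrow(H$alleles),
          "sw_alleles must match the site grid")
  M <- matrix("MISSING", nrow(H$alleles), ncol(H$alleles),
              dimnames = list(H$pos, H$sample))
  known <- !is.na(sw_alleles)
  for (j in seq_len(ncol(M))) {
    a <- H$alleles[, j]
    M[known & !is.na(a) & a == sw_alleles, j] <- "MAJOR"
    M[known & !is.na(a) & a != sw_alleles, j] <- "MINOR"
  }
  class(M) <- c("genotype_plot_matrix", class(M))
  M
}
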