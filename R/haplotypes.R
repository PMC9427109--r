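## Phased haplotype container shared by the statistics and scan stages.

#' Construct a haplotype set
#'
#' A sites x haplotypes matrix of alleles (0 = reference/ancestral,
#' 1 = alternate/derived, `NA` = unresolved) over a shared 1-based site
#' grid, with an arrangement class and source sample per haplotype.
#'
#' @param alleles integer matrix sites x haplotypes.
#' @param pos 1-based site positions (strictly increasing).
#' @param contig contig name.
#' @param contig_length contig length in bp.
#' @param class character vector per haplotype, e.g. `"ZAL2"`/`"ZAL2m"`.
#' @param sample source sample id per haplotype.
#' @return object of class `haplotype_set`.
#' @export
haplotype_set <- function(alleles, pos, contig, contig_length,
                          class = rep(NA_character_, ncol(alleles)),
                          sample = rep(NA_character_, ncol(alleles))) {
  .assert(nrow(alleles) == length(pos), "alleles rows must match pos")
  .assert(!is.unsorted(pos, strictly = TRUE), "pos must be strictly increasing")
  .assert(length(class) == ncol(alleles), "class length mismatch")
  structure(list(alleles = alleles, pos = as.integer(pos), contig = contig,
                 contig_length = as.integer(contig_length),
                 class = class, sample = sample),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d sites x %d haplotypes (%s)\n",
              nrow(x$alleles), ncol(x$alleles),
              paste(sprintf("%s:%d", names(table(x$class)), table(x$class)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract true haplotypes from a simulation as a haplotype set
#'
#' @param truth a `sim_truth`.
#' @param class optional arrangement filter: `"ZAL2"` (standard) or
#'   `"ZAL2m"` (rearranged).
#' @param n optional number of haplotypes to subsample (uses the current
#'   RNG stream).
#' @param region optional `c(start, end)` 0-based half-open span to
#'   restrict sites to.
#' @return `haplotype_set`.
#' @export
truth_haplotypes <- function(truth, class = NULL, n = NULL, region = NULL) {
  idx <- seq_along(truth$labels)
  if (!is.null(class)) {
    want <- if (class == "ZAL2m") 1L else 0L
    idx <- idx[truth$labels == want]
  }
  if (!is.null(n) && n < length(idx)) idx <- sort(sample(idx, n))
  keep <- rep(TRUE, length(truth$pos))
  if (!is.null(region))
    keep <- truth$pos > region[1] & truth$pos <= region[2]
  haplotype_set(truth$haps[keep, idx, drop = FALSE], truth$pos[keep],
                truth$cfg$contig, truth$cfg$contig_length,
                class = c("ZAL2", "ZAL2m")[truth$labels[idx] + 1L],
                sample = truth$sample[idx])
}

#' Subset a haplotype set by arrangement class
#' @param H `haplotype_set`.
#' @param class class label to keep.
#' @return `haplotype_set`.
#' @export
subset_class <- function(H, class) {
  idx <- which(H$class == class)
  .assert(length(idx) > 0, sprintf("no haplotypes of class %s", class))
  haplotype_set(H$alleles[, idx, drop = FALSE], H$pos, H$contig,
                H$contig_length, H$class[idx], H$sample[idx])
}

## alternate-allele frequency and non-missing count per site
.hap_freq <- function(A) {
  n_ok <- rowSums(!is.na(A))
  cnt <- rowSums(A == 1L, na.rm = TRUE)
  list(p = ifelse(n_ok > 0, cnt / n_ok, NA_real_), n = n_ok, count = cnt)
}

## indices of sites segregating within the set (pairwise-complete)
.segregating <- function(A) {
  f <- .hap_freq(A)
  which(f$n >= 2 & f$count > 0 & f$count < f$n)
}
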