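## Allele-specific expression and its integration with selection scans.

#' Allelic bias per gene
#'
#' Per-gene log2 ratio of summed rearranged-allele to standard-allele
#' counts, a one-sample Wilcoxon signed-rank test of the per-sample
#' rearranged-allele proportions against 0.5, and Benjamini-Hochberg
#' adjustment across genes.
#'
#' @param counts data.frame/data.table with columns `gene`, `sample`,
#'   `z2m_count`, `z2_count` (WS samples).
#' @param min_total minimum total count per gene (summed over samples);
#'   genes below it are excluded (count reported in attribute
#'   `"n_excluded"`).
#' @return data.frame of class `allelic_bias_table`: gene, totals,
#'   log2_ratio, mean proportion, p, p_adj.
#' @export
allelic_bias <- function(counts, min_total = 20) {
  dt <- data.table::as.data.table(counts)
  per_gene <- dt[, .(z2m = sum(z2m_count), z2 = sum(z2_count),
                     n_samples = .N), by = gene]
  excluded <- per_gene[z2m + z2 < min_total]
  per_gene <- per_gene[z2m + z2 >= min_total]
  if (nrow(excluded))
    message(sprintf("allelic_bias: %d gene(s) below min_total excluded",
                    nrow(excluded)))
  pvals <- vapply(per_gene$gene, function(g) {
    sub <- dt[gene == g & z2m_count + z2_count > 0]
    prop <- sub$z2m_count / (sub$z2m_count + sub$z2_count)
    if (length(prop) < 2) return(NA_real_)
    if (all(prop == 0.5)) return(1)  # no deviation, no evidence
    suppressWarnings(wilcox.test(prop, mu = 0.5)$p.value)
  }, numeric(1))
  props <- vapply(per_gene$gene, function(g) {
    sub <- dt[gene == g & z2m_count + z2_count > 0]
    mean(sub$z2m_count / (sub$z2m_count + sub$z2_count))
  }, numeric(1))
  out <- data.frame(gene = per_gene$gene,
                    z2m_total = per_gene$z2m, z2_total = per_gene$z2,
                    log2_ratio = log2(per_gene$z2m / per_gene$z2),
                    mean_prop_z2m = props,
                    p = pvals,
                    p_adj = p.adjust(pvals, "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- nrow(excluded)
  class(out) <- c("allelic_bias_table", "data.frame")
  out
}

#' Assign per-gene H values from binned H tracks
#'
#' A gene overlapping one bin takes that bin's H; a gene overlapping
#' several takes their arithmetic mean; genes outside the binned region
#' are `NA`.
#'
#' @param genes data.frame with `gene`, 0-based `start`, `end`.
#' @param h_bins window table with `start`, `end` and `max_h` (20 kb
#'   bins in the study design).
#' @param stat_col column of `h_bins` to assign (default `"max_h"`).
#' @return data.frame gene, h.
#' @export
gene_h_assignment <- function(genes, h_bins, stat_col = "max_h") {
  h <- vapply(seq_len(nrow(genes)), function(i) {
    ov <- h_bins$end > genes$start[i] & h_bins$start < genes$end[i]
    if (!any(ov)) return(NA_real_)
    mean(h_bins[[stat_col]][ov], na.rm = FALSE)
  }, numeric(1))
  data.frame(gene = genes$gene, h = h, stringsAsFactors = FALSE)
}

#' Association between allelic bias and the H statistic
#'
#' Ordinary least squares of the per-gene log2 allelic ratio on log2 H.
#' With H from the rearranged arrangement, a positive slope means
#' expression bias toward the rearranged allele rises with sweep signal
#' strength; for the standard arrangement the expected sign flips.
#'
#' @param ab `allelic_bias_table`.
#' @param gene_h data.frame from [gene_h_assignment()] (gene, h).
#' @return list with `slope`, `p`, `n`, and the fitted `lm` object
#'   (`NULL`, with `NA` slope, for a degenerate predictor or < 10
#'   genes).
#' @export
ab_h_association <- function(ab, gene_h) {
  d <- merge(as.data.frame(ab)[, c("gene", "log2_ratio")], gene_h, by = "gene")
  d <- d[is.finite(d$log2_ratio) & is.finite(d$h) & d$h > 0, ]
  if (nrow(d) < 10 || length(unique(d$h)) < 2)
    return(list(slope = NA_real_, p = NA_real_, n = nrow(d), fit = NULL))
  fit <- lm(log2_ratio ~ log2(h), data = d)
  s <- summary(fit)$coefficients
  list(slope = unname(s[2, 1]), p = unname(s[2, 4]), n = nrow(d), fit = fit)
}

#' Enrichment of morph-biased genes inside the rearrangement
#'
#' Two-proportion z-test per tissue comparing the fraction of
#' differentially expressed genes inside the rearranged region with the
#' fraction outside, BH-adjusted across tissues.  Falls back to
#' Fisher's exact test when a margin is zero.
#'
#' @param de_flags data.frame with columns `tissue`, `n_inside_de`,
#'   `n_inside`, `n_outside_de`, `n_outside`.
#' @return data.frame per tissue: proportions, z, p, p_adj, method.
#' @export
morph_bias_enrichment <- function(de_flags) {
  .assert(all(c("tissue", "n_inside_de", "n_inside", "n_outside_de",
                "n_outside") %in% names(de_flags)),
          "de_flags missing required columns")
  rows <- lapply(seq_len(nrow(de_flags)), function(i) {
    x <- de_flags[i, ]
    .assert(x$n_inside > 0 && x$n_outside > 0, "zero gene totals")
    margins_ok <- (x$n_inside_de + x$n_outside_de) > 0 &&
      (x$n_inside_de + x$n_outside_de) < (x$n_inside + x$n_outside)
    if (margins_ok) {
      pt <- prop.test(c(x$n_inside_de, x$n_outside_de),
                      c(x$n_inside, x$n_outside), correct = FALSE)
      z <- sign(x$n_inside_de / x$n_inside - x$n_outside_de / x$n_outside) *
        sqrt(pt$statistic)
      data.frame(tissue = x$tissue,
                 prop_inside = x$n_inside_de / x$n_inside,
                 prop_outside = x$n_outside_de / x$n_outside,
                 z = unname(z), p = pt$p.value, method = "two-proportion z")
    } else {
      ft <- fisher.test(matrix(c(x$n_inside_de, x$n_inside - x$n_inside_de,
                                 x$n_outside_de, x$n_outside - x$n_outside_de),
                               2, 2))
      data.frame(tissue = x$tissue,
                 prop_inside = x$n_inside_de / x$n_inside,
                 prop_outside = x$n_outside_de / x$n_outside,
                 z = NA_real_, p = ft$p.value, method = "fisher exact")
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Couple per-gene cis effects to a realized H track
#'
#' Generates cis-regulatory effects for [emit_expression()] whose log2
#' allelic-ratio shifts follow the (standardized) log2 per-gene H values
#' plus Gaussian noise; `strength = 0` gives uncoupled (pure noise)
#' effects, the null for the association test.
#'
#' @param gene_h data.frame from [gene_h_assignment()].
#' @param strength coupling coefficient on standardized log2 H.
#' @param noise_sd Gaussian noise standard deviation.
#' @return named numeric vector of cis effects (genes with `NA` or
#'   non-positive H dropped).
#' @export
couple_cis_effects <- function(gene_h, strength = 0.5, noise_sd = 0.3) {
  d <- gene_h[is.finite(gene_h$h) & gene_h$h > 0, ]
  z <- scale(log2(d$h))[, 1]
  if (all(is.nan(z))) z <- rep(0, nrow(d))
  eff <- strength * z + rnorm(nrow(d), 0, noise_sd)
  setNames(eff, d$gene)
}
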