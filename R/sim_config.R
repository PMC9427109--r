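## Simulator configuration: the "stated world".

#' Configure the forward supergene simulator
#'
#' Defines a Wright-Fisher population of `n_ind` diploids on one contig
#' carrying a rearranged (inversion) span `[inv_start, inv_end)` in which
#' recombination in heterokaryotypes is multiplied by `c_suppress`.
#' Mating is disassortative: each offspring draws a WS x TS parent pair
#' with probability `fidelity`, otherwise a uniformly random
#' (fitness-weighted) pair.  The run starts from standing neutral
#' variation at 1/i-spectrum frequencies plus arrangement-diagnostic
#' fixed differences seeded inside the inversion (the rearrangement is
#' ancient relative to any desk-scale run length).
#'
#' Defaults are sized for desk scale: N = 500, 1 Mb contig, 2000
#' generations, with mutation and recombination rates rescaled so that
#' theta = 4N mu = 2e-4 and rho = 4N r = 4e-4 per bp.
#'
#' @param n_ind number of diploid individuals.
#' @param contig_length contig length in bp.
#' @param contig contig name.
#' @param inv_start,inv_end inversion span, 0-based half-open.
#' @param mu per-base per-generation mutation rate.
#' @param rec per-base per-generation recombination rate.
#' @param c_suppress heterokaryotype recombination factor inside the
#'   inversion, in `[0, 1]` (0 = full suppression).
#' @param fidelity disassortative mating fidelity f in `[0, 1]`.
#' @param generations number of non-overlapping generations.
#' @param init_theta standing-variation level used to seed the initial
#'   site-frequency spectrum (defaults to 4 N mu).
#' @param init_fd_density per-bp density of seeded fixed differences
#'   inside the inversion.
#' @param sweep `NULL` or `list(pos, class, s, start)`: a beneficial
#'   mutation at `pos` counted only on haplotypes of arrangement `class`
#'   (0 standard / 1 rearranged), multiplicative fitness `1+s` per copy,
#'   introduced at generation `start` and re-seeded if lost.
#' @param balanced `NULL` or `list(pos, s_b, div_density)`: a locus inside
#'   the inversion under negative frequency-dependent selection among
#'   rearranged haplotypes (fitness multiplier `1 + s_b (0.5 - freq)`),
#'   seeded at 50/50 together with backbone haplogroup divergence at
#'   `div_density` per bp inside the inversion.
#' @param n_genes number of coding genes emitted by [emit_annotation()].
#' @param seed integer random seed used by [simulate_population()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_ind = 500, contig_length = 1e6, contig = "chr2",
                       inv_start = 2e5, inv_end = 8e5,
                       mu = 1e-7, rec = 2e-7, c_suppress = 0,
                       fidelity = 0.99, generations = 2000,
                       init_theta = 4 * n_ind * mu,
                       init_fd_density = 5e-3,
                       sweep = NULL, balanced = NULL,
                       n_genes = 40, seed = 1) {
  .assert(fidelity >= 0 && fidelity <= 1, "fidelity must be in [0,1]")
  .assert(c_suppress >= 0 && c_suppress <= 1, "c_suppress must be in [0,1]")
  .assert(inv_start < inv_end && inv_end <= contig_length,
          "need inv_start < inv_end <= contig_length")
  if (!is.null(sweep)) {
    .assert(all(c("pos", "class", "s", "start") %in% names(sweep)),
            "sweep needs pos, class, s, start")
    .assert(sweep$class %in% c(0, 1), "sweep class must be 0 or 1")
  }
  if (!is.null(balanced)) {
    .assert(all(c("pos", "s_b") %in% names(balanced)),
            "balanced needs pos and s_b")
    .assert(balanced$pos >= inv_start && balanced$pos < inv_end,
            "balanced locus must lie inside the inversion")
    balanced$div_density <- balanced$div_density %||% 1.8e-3
  }
  structure(list(n_ind = n_ind, contig_length = as.integer(contig_length),
                 contig = contig,
                 inv_start = as.integer(inv_start), inv_end = as.integer(inv_end),
                 mu = mu, rec = rec, c_suppress = c_suppress,
                 fidelity = fidelity, generations = as.integer(generations),
                 init_theta = init_theta, init_fd_density = init_fd_density,
                 sweep = sweep, balanced = balanced,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> N=%d, contig %s (%d bp), inversion [%d,%d), f=%.3g, c=%.3g, G=%d\n",
              x$n_ind, x$contig, x$contig_length, x$inv_start, x$inv_end,
              x$fidelity, x$c_suppress, x$generations))
  if (!is.null(x$sweep))
    cat(sprintf("  sweep: pos %d on class %d, s=%.3g, start gen %d\n",
                as.integer(x$sweep$pos), x$sweep$class, x$sweep$s,
                as.integer(x$sweep$start)))
  if (!is.null(x$balanced))
    cat(sprintf("  balanced locus: pos %d, s_b=%.3g\n",
                as.integer(x$balanced$pos), x$balanced$s_b))
  invisible(x)
}
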