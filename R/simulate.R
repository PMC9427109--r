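## Forward simulation driver and ground truth container.

#' Run the forward Wright-Fisher supergene simulation
#'
#' Simulates `cfg$generations` discrete non-overlapping generations of
#' `cfg$n_ind` diploids (see [sim_config()] for the model).  Returns the
#' full phased truth: haplotypes over the final segregating site list,
#' per-haplotype arrangement labels, per-individual morphs, the true
#' fixed-difference positions, and the arrangement-frequency trajectory.
#'
#' The initial population is half TS (two standard haplotypes) and half
#' WS (one rearranged haplotype), giving a rearranged-chromosome
#' frequency of 0.25.  Initial sites comprise (i) standing neutral
#' variation with expected count `theta * L * a_{2N-1}` at frequencies
#' drawn from the neutral 1/i spectrum, (ii) fixed differences between
#' the arrangements at density `init_fd_density` inside the inversion,
#' and (iii) for a balanced locus, two backbone haplogroups at 50/50
#' among rearranged haplotypes diverged at `div_density`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_truth` with elements `pos` (1-based site
#'   positions), `haps` (sites x 2N 0/1 matrix), `labels` (arrangement
#'   per haplotype: 0 standard, 1 rearranged), `morph` (per individual),
#'   `sample` (individual id per haplotype), `fd_pos` (true
#'   fixed-difference positions), `freq_m`, `morph_freq`, `cfg`, and
#'   sweep/balanced truth positions where configured.
#' @export
simulate_population <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  set.seed(cfg$seed)
  two_n <- 2L * cfg$n_ind
  L <- cfg$contig_length

  ## individuals: first half TS, second half WS (one rearranged haplotype)
  labels <- integer(two_n)
  ws <- seq_len(cfg$n_ind) > cfg$n_ind / 2
  labels[2L * which(ws)] <- 1L

  ## standing neutral variation at 1/i frequencies;
  ## Watterson: E[S] = theta * L * a_{2N-1} with theta = 4N mu per bp
  a_n <- sum(1 / seq_len(two_n - 1))
  s0 <- rpois(1, cfg$init_theta * L * a_n)
  counts <- if (s0 > 0) {
    i <- seq_len(two_n - 1)
    sample(i, s0, replace = TRUE, prob = 1 / i)
  } else integer(0)

  inv_len <- cfg$inv_end - cfg$inv_start
  n_fd <- rpois(1, cfg$init_fd_density * inv_len)

  bal <- cfg$balanced
  n_bb <- if (!is.null(bal)) rpois(1, bal$div_density * inv_len) else 0L

  ## draw distinct 0-based positions for the seeded site classes:
  ## neutral sites anywhere, fixed differences and backbone sites inside
  ## the inversion
  neutral_pos <- sample.int(L, s0) - 1L
  bal_pos0 <- if (!is.null(bal)) as.integer(bal$pos) else NULL
  n_inv_needed <- n_fd + n_bb
  .assert(n_inv_needed + 1L < inv_len,
          "inversion too small for seeded sites")
  inv_pool <- (sample.int(inv_len, min(inv_len, n_inv_needed + 200L)) - 1L) +
    cfg$inv_start
  inv_pool <- setdiff(inv_pool, c(neutral_pos, bal_pos0))
  .assert(length(inv_pool) >= n_inv_needed,
          "inversion too dense for seeded sites")
  fd_pos <- inv_pool[seq_len(n_fd)]
  bb_pos <- if (n_bb > 0) inv_pool[n_fd + seq_len(n_bb)] else integer(0)
  neutral_pos <- setdiff(neutral_pos, bal_pos0)
  s0 <- length(neutral_pos)
  counts <- counts[seq_len(s0)]

  m_haps <- which(labels == 1L)
  std_haps <- which(labels == 0L)

  pos0 <- c(neutral_pos, fd_pos, bb_pos, if (!is.null(bal)) bal_pos0)
  S <- length(pos0)
  haps <- matrix(0L, S, two_n)
  ## neutral sites: exact derived count, random haplotypes
  if (s0 > 0) {
    for (j in seq_len(s0)) {
      haps[j, sample.int(two_n, counts[j])] <- 1L
    }
  }
  ## fixed differences: derived allele on every rearranged haplotype
  if (n_fd > 0) haps[s0 + seq_len(n_fd), m_haps] <- 1L
  ## backbone divergence + balanced locus: haplogroup A = random half of
  ## the rearranged haplotypes
  if (!is.null(bal)) {
    grp_a <- sample(m_haps, ceiling(length(m_haps) / 2))
    if (n_bb > 0) {
      on_a <- runif(n_bb) < 0.5
      rows <- s0 + n_fd + seq_len(n_bb)
      haps[rows[on_a], grp_a] <- 1L
      if (any(!on_a)) haps[rows[!on_a], setdiff(m_haps, grp_a)] <- 1L
    }
    haps[S, grp_a] <- 1L  # balanced locus itself
  }

  sw <- cfg$sweep
  res <- .wf_simulate_cpp(
    cfg$n_ind, L, cfg$inv_start, cfg$inv_end,
    cfg$mu, cfg$rec, cfg$c_suppress, cfg$fidelity, cfg$generations,
    as.integer(pos0), haps, as.integer(labels),
    !is.null(sw), if (!is.null(sw)) sw$pos else 0,
    if (!is.null(sw)) as.integer(sw$class) else 0L,
    if (!is.null(sw)) sw$s else 0,
    if (!is.null(sw)) as.integer(sw$start) else 0L,
    !is.null(bal), if (!is.null(bal)) bal_pos0 else 0,
    if (!is.null(bal)) bal$s_b else 0,
    10L)

  out_lab <- as.integer(res$labels)
  morph_code <- out_lab[seq(1, two_n, 2)] + out_lab[seq(2, two_n, 2)]
  morph <- c("TS", "WS", "SW")[morph_code + 1L]
  sample_id <- sprintf("S%03d", seq_len(cfg$n_ind))

  truth <- structure(list(
    pos = as.integer(res$pos) + 1L,          # report 1-based
    haps = res$haps,
    labels = out_lab,
    morph = morph,
    sample = rep(sample_id, each = 2),
    freq_m = as.numeric(res$freq_m),
    morph_freq = t(res$morph_counts) / cfg$n_ind,
    sweep_intro_gen = res$sweep_intro_gen,
    sweep_fix_gen = res$sweep_fix_gen,
    sweep_pos = if (!is.null(sw)) as.integer(sw$pos) + 1L else NA_integer_,
    balanced_pos = if (!is.null(bal)) bal_pos0 + 1L else NA_integer_,
    cfg = cfg), class = "sim_truth")
  truth$fd_pos <- true_fixed_differences(truth)
  truth$haplogroup <- if (!is.null(bal)) {
    j <- match(truth$balanced_pos, truth$pos)
    if (is.na(j)) rep(NA_integer_, two_n) else as.integer(truth$haps[j, ])
  } else rep(NA_integer_, two_n)
  truth
}

#' True fixed differences between arrangement classes
#'
#' Sites at which every standard haplotype carries one allele and every
#' rearranged haplotype the other, computed from the simulated truth.
#'
#' @param truth a `sim_truth`.
#' @return integer vector of 1-based positions.
#' @export
true_fixed_differences <- function(truth) {
  m <- truth$labels == 1L
  c1 <- rowSums(truth$haps[, m, drop = FALSE])
  c0 <- rowSums(truth$haps[, !m, drop = FALSE])
  n1 <- sum(m); n0 <- sum(!m)
  fixed <- (c1 == n1 & c0 == 0) | (c1 == 0 & c0 == n0)
  sort(truth$pos[fixed])
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d segregating sites, %d individuals (TS %d / WS %d / SW %d), %d fixed differences\n",
              length(x$pos), length(x$morph), sum(x$morph == "TS"),
              sum(x$morph == "WS"), sum(x$morph == "SW"), length(x$fd_pos)))
  invisible(x)
}
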