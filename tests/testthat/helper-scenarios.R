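# Shared simulation scenarios, computed once per test run and cached.
# Heavy loops live here so that the acceptance tests and the module
# property tests reuse the same runs. Scenario seeds are fixed
# constants; analysis subsampling uses its own seeded streams.

.scn <- new.env(parent = emptyenv())

scn_get <- function(key, fn) {
  if (!exists(key, envir = .scn)) assign(key, fn(), envir = .scn)
  get(key, envir = .scn)
}

CONTIG <- function(truth) setNames(truth$cfg$contig_length, truth$cfg$contig)

# small, fast scenario for module-level property tests
small_config <- function(seed, ...) {
  args <- list(n_ind = 150, contig_length = 3e5, inv_start = 6e4,
               inv_end = 1.8e5, generations = 500, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# fixed-difference set straight from the simulated truth (for tests of
# stages downstream of the caller)
fd_from_truth <- function(truth) {
  idx <- match(truth$fd_pos, truth$pos)
  z2a <- as.integer(truth$haps[idx, which(truth$labels == 0L)[1]])
  structure(data.frame(contig = truth$cfg$contig, pos = truth$fd_pos,
                       ref = "A", alt = "G",
                       z2_allele = z2a, z2m_allele = 1L - z2a,
                       stringsAsFactors = FALSE),
            class = c("fixed_diff_set", "data.frame"))
}

# ---- neutral default scenario (criteria 4 and 7) -----------------------
neutral_runs <- function() scn_get("neutral", function() {
  rows <- list()
  for (s in 1:20) {
    truth <- simulate_population(sim_config(seed = 100 + s))
    set.seed(9000 + s)
    Hz <- truth_haplotypes(truth, class = "ZAL2", n = 40)
    Hm <- truth_haplotypes(truth, class = "ZAL2m", n = 40)
    ctg <- CONTIG(truth)
    segz <- which(rowSums(Hz$alleles) > 0 & rowSums(Hz$alleles) < ncol(Hz$alleles))
    win10 <- make_windows(ctg, 1e4, sites = data.frame(contig = truth$cfg$contig,
                                                       pos = Hz$pos[segz]))
    ep <- empirical_p_by_snp_bins(window_max_h(h_statistic(Hz), win10))
    win25 <- make_windows(ctg, 2.5e4)
    td <- tajimas_d(Hz, win25)

    z <- which(truth$labels == 0); m <- which(truth$labels == 1)
    s1 <- sample(z, 40); s2 <- sample(setdiff(z, s1), 40); s3 <- sample(m, 40)
    dd <- patterson_d(rowMeans(truth$haps[, s1]), rowMeans(truth$haps[, s2]),
                      rowMeans(truth$haps[, s3]), rep(0, length(truth$pos)),
                      truth$pos, win25)

    segm <- which(rowSums(Hm$alleles) > 0 & rowSums(Hm$alleles) < ncol(Hm$alleles))
    bins20 <- make_windows(ctg, 2e4, sites = data.frame(contig = truth$cfg$contig,
                                                        pos = Hm$pos[segm]))
    wm <- window_max_h(h_statistic(Hm), bins20)
    ann <- emit_annotation(truth$cfg, file.path(tempdir(), paste0("ann", s)))
    gh <- gene_h_assignment(ann$genes, wm)
    cis_c <- couple_cis_effects(gh, strength = 0.5, noise_sd = 0.3)
    cis_u <- couple_cis_effects(gh, strength = 0, noise_sd = 0.3)
    rc <- ab_h_association(allelic_bias(emit_expression(truth, ann$genes, cis_c)), gh)
    ru <- ab_h_association(allelic_bias(emit_expression(truth, ann$genes, cis_u)), gh)

    rows[[s]] <- data.frame(
      n_candidates = sum(ep$candidate, na.rm = TRUE),
      n_usable = sum(!is.na(ep$emp_p)),
      mean_tajd = mean(td, na.rm = TRUE),
      mean_d = mean(dd$d, na.rm = TRUE),
      slope_coupled = rc$slope, p_coupled = rc$p,
      slope_uncoupled = ru$slope)
  }
  do.call(rbind, rows)
})

# ---- sweep scenario (criterion 5, sweep recovery) ----------------------
SWEEP_POS <- 512500
sweep_runs <- function() scn_get("sweep", function() {
  rows <- list()
  for (s in 1:20) {
    cfg <- sim_config(seed = 300 + s,
                      sweep = list(pos = SWEEP_POS, class = 0, s = 0.15,
                                   start = 1880))
    truth <- simulate_population(cfg)
    set.seed(9300 + s)
    Hz <- truth_haplotypes(truth, class = "ZAL2", n = 40)
    segz <- which(rowSums(Hz$alleles) > 0 & rowSums(Hz$alleles) < ncol(Hz$alleles))
    win <- make_windows(CONTIG(truth), 1e4,
                        sites = data.frame(contig = truth$cfg$contig,
                                           pos = Hz$pos[segz]))
    ep <- empirical_p_by_snp_bins(window_max_h(h_statistic(Hz), win))
    cand <- which(ep$candidate)
    dist <- abs((win$start[cand] + win$end[cand]) / 2 - SWEEP_POS)
    rows[[s]] <- data.frame(n_candidates = length(cand),
                            max_cand_dist = if (length(cand)) max(dist) else NA_real_)
  }
  do.call(rbind, rows)
})

# ---- balanced (NFDS) scenario (criterion 5, region recovery) -----------
nfds_config <- function(seed) {
  sim_config(seed = seed, contig_length = 2e6, inv_start = 9.5e5,
             inv_end = 1.05e6, balanced = list(pos = 1e6, s_b = 1))
}

nfds_runs <- function() scn_get("nfds", function() {
  rows <- list()
  for (s in 1:20) {
    truth <- simulate_population(nfds_config(500 + s))
    set.seed(9500 + s)
    cfg <- truth$cfg
    Hm <- truth_haplotypes(truth, class = "ZAL2m", n = 40)
    ctg <- CONTIG(truth)
    win <- make_windows(ctg, 1e4)
    st <- data.frame(start = win$start, end = win$end,
                     pi = nucleotide_diversity(Hm, win),
                     tajima_d = tajimas_d(Hm, win))
    reg <- detect_outlier_regions(st, min_windows = 5, n_perms = 1000,
                                  seed = 9500 + s)
    hit <- nrow(reg) > 0 &&
      any(reg$start <= truth$balanced_pos & reg$end >= truth$balanced_pos &
            reg$perm_p < 0.01)

    Hr <- truth_haplotypes(truth, class = "ZAL2m",
                           region = c(cfg$inv_start, cfg$inv_end))
    part <- cluster_haplogroups(pairwise_hamming(Hr))
    tru <- truth$haplogroup[truth$labels == 1]
    ok <- !is.na(part$labels)
    ari <- adjusted_rand(part$labels[ok], tru[ok])

    Hz <- truth_haplotypes(truth, class = "ZAL2", n = 40,
                           region = c(cfg$inv_start, cfg$inv_end))
    winr <- make_windows(setNames(cfg$inv_end, cfg$contig), 1e4)
    winr <- winr[winr$start >= cfg$inv_start, ]
    hd <- haplogroup_dxy(Hr, part, Hz, winr)
    ord <- hd$dxy_h1_h2 < pmin(hd$dxy_h1_z2, hd$dxy_h2_z2)

    bt <- beta_statistic(Hm, window_bp = 1e4)
    core <- which.min(abs(bt$pos - truth$balanced_pos))
    outside <- bt$pos <= cfg$inv_start | bt$pos > cfg$inv_end
    beta_hit <- isTRUE(bt$beta[core] >
                         quantile(bt$beta[outside], 0.95, na.rm = TRUE))

    if (s == 1) assign("nfds_example", list(truth = truth, part = part,
                                            Hr = Hr), envir = .scn)
    rows[[s]] <- data.frame(hit = hit, ari = ari,
                            n_ord = sum(!is.na(ord)), n_ord_ok = sum(ord, na.rm = TRUE),
                            beta_hit = beta_hit)
  }
  do.call(rbind, rows)
})

nfds_example <- function() { nfds_runs(); get("nfds_example", envir = .scn) }

# ---- phasing scenario (criterion 6) ------------------------------------
phasing_runs <- function() scn_get("phasing", function() {
  rows <- list()
  for (s in 1:2) {
    truth <- simulate_population(sim_config(seed = 200 + s, fidelity = 0.85))
    set.seed(9200 + s)
    out <- emit_vcf(truth, file.path(tempdir(), paste0("phasing", s)))
    G <- suppressMessages(read_vcf(out$vcf, out$meta))
    fd <- call_fixed_differences(G, out$meta)
    tp <- sum(fd$pos %in% truth$fd_pos)
    ws <- unique(truth$sample[rep(truth$morph == "WS", each = 2)])[1:15]
    fr <- emit_fragments(truth, fragment_length = 1000, mean_depth = 4,
                         error_rate = 0, samples = ws)
    res <- assign_fragments(fr, fd)
    lab <- res$labels[fr$frags, on = "frag_id"]
    assigned <- lab$label %in% c("ZAL2", "ZAL2m")
    acc <- mean(lab$label[assigned] == lab$source_class[assigned])
    if (s == 1) assign("phasing_example",
                       list(truth = truth, G = G, meta = out$meta, fd = fd,
                            fr = fr, res = res, ws = ws), envir = .scn)
    rows[[s]] <- data.frame(precision = tp / nrow(fd),
                            recall = tp / length(truth$fd_pos),
                            assign_acc = acc, rate = res$rate)
  }
  do.call(rbind, rows)
})

phasing_example <- function() { phasing_runs(); get("phasing_example", envir = .scn) }
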