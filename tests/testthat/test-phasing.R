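# Phasing: fixed-difference calling, the binomial-pattern null,
# fragment assignment, and pseudo-haplotypes.

toy_gm <- function(geno, samples, pos = seq_len(nrow(geno)) * 100L) {
  genotype_matrix(data.frame(contig = "chr", pos = pos,
                             ref = "A", alt = "G"),
                  geno, samples, c(chr = 100000L))
}

test_that("call_fixed_differences applies the morph pattern", {
  samples <- c("t1", "t2", "t3", "w1", "w2", "x1")
  meta <- sample_meta(samples, c("TS", "TS", "TS", "WS", "WS", "SW"))
  geno <- rbind(
    c(0L, 0L, 0L, 1L, 1L, 2L),  # fixed difference, ZAL2 allele = ref
    c(2L, 2L, 2L, 1L, 1L, 0L),  # fixed difference, ZAL2 allele = alt
    c(0L, 0L, 0L, 0L, 1L, 2L),  # one WS homozygous -> rejected
    c(0L, 0L, 1L, 1L, 1L, 2L),  # one TS heterozygous -> rejected
    c(0L, 0L, 0L, 1L, 1L, 0L))  # SW matches TS -> rejected
  fd <- call_fixed_differences(toy_gm(geno, samples), meta)
  expect_equal(fd$pos, c(100L, 200L))
  expect_equal(fd$z2_allele, c(0L, 1L))
  expect_equal(fd$z2m_allele, c(1L, 0L))

  meta2 <- sample_meta(samples, c("TS", "TS", "TS", "WS", "WS", "WS"))
  expect_error(call_fixed_differences(toy_gm(geno, samples), meta2), "SW")
})

test_that("every called fixed difference is heterozygous in all WS used", {
  pe <- phasing_example()
  ws <- pe$meta$id[pe$meta$morph == "WS"]
  idx <- match(pe$fd$pos, pe$G$sites$pos)
  expect_true(all(pe$G$geno[idx, ws] == 1L))
})

test_that("pattern_null_probability matches closed forms and is monotone", {
  expect_equal(pattern_null_probability(0, 1, 0, labelings = 1), 0.5)
  # two labelings, one TS + one SW: enumerate the 9 HWE(0.5) genotype
  # pairs -> 2 * (1/4)^2
  expect_equal(pattern_null_probability(1, 0, 1, labelings = 2), 0.125)
  expect_error(pattern_null_probability(1, 1, 1, labelings = 0))
  p0 <- pattern_null_probability(13, 49, 1)
  expect_lt(pattern_null_probability(14, 49, 1), p0)
  expect_lt(pattern_null_probability(13, 50, 1), p0)
  expect_lt(pattern_null_probability(13, 49, 2), p0)
})

toy_frags <- function(obs_list, samples = "w1") {
  n <- length(obs_list)
  frags <- data.table::data.table(
    frag_id = seq_len(n), sample = rep(samples, length.out = n),
    source_hap = 1L, source_class = "ZAL2",
    start = 0L, end = 1000L)
  obs <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    o <- obs_list[[i]]
    if (is.null(o)) return(NULL)
    data.table::data.table(frag_id = i, pos = o$pos, allele = o$allele)
  }))
  structure(list(frags = frags, obs = obs, fragment_length = 1000L,
                 error_rate = 0), class = "fragment_set")
}

test_that("assign_fragments labels by fixed-difference concordance", {
  fd <- structure(data.frame(contig = "chr", pos = c(100L, 200L),
                             ref = "A", alt = "G",
                             z2_allele = c(0L, 0L), z2m_allele = c(1L, 1L)),
                  class = c("fixed_diff_set", "data.frame"))
  fr <- toy_frags(list(
    list(pos = 100L, allele = 0L),                    # ZAL2
    list(pos = c(100L, 200L), allele = c(1L, 1L)),    # ZAL2m
    list(pos = c(100L, 200L), allele = c(0L, 1L)),    # conflict
    list(pos = 300L, allele = 1L),                    # no fd overlap
    NULL))                                            # no observations
  res <- assign_fragments(fr, fd)
  expect_equal(res$labels$label,
               c("ZAL2", "ZAL2m", "conflict", "unassigned", "unassigned"))
  expect_equal(res$rate, 2 / 5)

  # empty fixed-difference set: rate 0
  fd0 <- fd[0, ]
  expect_equal(assign_fragments(fr, fd0)$rate, 0)
})

test_that("assignment rate tracks the inversion fraction and fragment length", {
  pe <- phasing_example()
  chk <- assignment_rate_check(pe$res, pe$truth)
  expect_gte(chk$ratio, 0.5)
  expect_lte(chk$ratio, 1.0)

  # longer fragments overlap at least as many fd sites: rate non-decreasing
  set.seed(11)
  fr_short <- emit_fragments(pe$truth, fragment_length = 300, mean_depth = 2,
                             error_rate = 0, samples = pe$ws[1:5])
  fr_long <- emit_fragments(pe$truth, fragment_length = 3000, mean_depth = 2,
                            error_rate = 0, samples = pe$ws[1:5])
  r_s <- assign_fragments(fr_short, pe$fd)$rate
  r_l <- assign_fragments(fr_long, pe$fd)$rate
  expect_gt(r_l, r_s)
})

test_that("build_pseudo_haplotypes: majority vote, support, ties", {
  samples <- c("t1", "w1", "x1")
  meta <- sample_meta(samples, c("TS", "WS", "SW"))
  geno <- rbind(c(0L, 1L, 2L),   # fd site
                c(0L, 1L, 2L),   # fd site
                c(1L, 1L, 0L),   # het in TS -> missing on TS haplotypes
                c(2L, 1L, 1L))   # het in SW -> missing on SW haplotypes
  G <- toy_gm(geno, samples)
  fd <- structure(data.frame(contig = "chr", pos = c(100L, 200L), ref = "A",
                             alt = "G", z2_allele = 0L, z2m_allele = 1L),
                  class = c("fixed_diff_set", "data.frame"))
  # w1 fragments: 3 concordant ZAL2m votes at pos 300 (allele 1),
  # tied votes at pos 400
  frags <- data.table::data.table(
    frag_id = 1:8, sample = "w1", source_hap = NA_integer_,
    source_class = NA_character_, start = 0L, end = 1000L)
  obs <- data.table::data.table(
    frag_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L, 7L, 8L),
    pos     = c(100L, 300L, 100L, 300L, 100L, 300L, 100L, 200L, 200L, 400L, 400L),
    allele  = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L))
  # frags 1-3 are ZAL2m (allele 1 at fd pos 100); frag 3 votes 0 at 300
  # frag 4 is ZAL2 (allele 0 at 100); frags 5-6 ZAL2 at 200
  # frags 7-8 overlap no fd -> unassigned, so pos 400 gets no votes
  fr <- structure(list(frags = frags, obs = obs, fragment_length = 1000L,
                       error_rate = 0), class = "fragment_set")
  res <- assign_fragments(fr, fd)
  H <- build_pseudo_haplotypes(G, meta, fd, fr, res, min_support = 2)
  wm <- which(H$sample == "w1" & H$class == "ZAL2m")
  expect_equal(H$alleles[2, wm], NA_integer_)        # pos 200: 0 m-votes
  expect_equal(H$alleles[3, wm], 1L)                 # pos 300: 2 vs 1 majority
  expect_true(is.na(H$alleles[4, wm]))               # pos 400: no labelled votes
  wz <- which(H$sample == "w1" & H$class == "ZAL2")
  expect_true(is.na(H$alleles[1, wz]))               # single vote < min_support
  expect_equal(H$alleles[2, wz], 0L)                 # two concordant ZAL2 votes
  # TS sample: homozygous sites resolved on both haplotypes, het missing
  tz <- which(H$sample == "t1")
  expect_equal(H$alleles[1, tz], c(0L, 0L))
  expect_true(all(is.na(H$alleles[3, tz])))
  # SW sample: two ZAL2m haplotypes, het missing
  xz <- which(H$sample == "x1")
  expect_equal(H$class[xz], c("ZAL2m", "ZAL2m"))
  expect_equal(H$alleles[1, xz], c(1L, 1L))
  expect_true(all(is.na(H$alleles[4, xz])))
})

test_that("recovered ZAL2m pseudo-haplotype diversity tracks the truth", {
  # scaled-down scenario, 10 seeds: pi on recovered ZAL2m pseudo-haplotypes
  # within 10% of pi on the true haplotypes (MAF filter disabled: a
  # population-level MAF cut removes class-specific variation)
  ratios <- vapply(1:10, function(s) {
    truth <- simulate_population(small_config(60 + s, fidelity = 0.9))
    set.seed(660 + s)
    out <- emit_vcf(truth, file.path(tempdir(), paste0("pp", s)))
    G <- suppressMessages(read_vcf(out$vcf, out$meta, min_maf = 0))
    fd <- fd_from_truth(truth)  # caller accuracy is tested elsewhere
    ws <- unique(truth$sample[rep(truth$morph == "WS", each = 2)])[1:20]
    # study-realistic coverage (WS birds were sequenced deep); at low
    # depth unresolved sites dominate the comparison noise
    fr <- emit_fragments(truth, 1000, 20, error_rate = 0, samples = ws)
    res <- assign_fragments(fr, fd)
    keep_s <- G$samples %in% ws
    Gws <- genotype_matrix(G$sites, G$geno[, keep_s, drop = FALSE],
                           G$samples[keep_s], G$contigs)
    cfg <- truth$cfg
    H <- suppressWarnings(build_pseudo_haplotypes(
      Gws, out$meta, fd, fr, res, min_support = 2,
      region = c(cfg$inv_start, cfg$inv_end)))
    Hm <- subset_class(H, "ZAL2m")
    win <- data.frame(contig = cfg$contig, start = cfg$inv_start,
                      end = cfg$inv_end,
                      l_acc = cfg$inv_end - cfg$inv_start, n_snp = 0L)
    pi_rec <- nucleotide_diversity(Hm, win)
    # true haplotypes of the same WS samples' rearranged copies
    tidx <- which(truth$sample %in% ws & truth$labels == 1L)
    Tm <- haplotype_set(truth$haps[, tidx, drop = FALSE], truth$pos,
                        cfg$contig, cfg$contig_length,
                        class = rep("ZAL2m", length(tidx)),
                        sample = truth$sample[tidx])
    pi_true <- nucleotide_diversity(Tm, win)
    pi_rec / pi_true
  }, numeric(1))
  expect_true(all(abs(ratios - 1) <= 0.10))
})
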