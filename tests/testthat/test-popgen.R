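# Windowed statistics: worked examples, algebraic identities, SFS,
# LD, coding diversity, Ne ratio.

test_that("nucleotide diversity: worked examples and mask scaling", {
  # 4 haplotypes, one 2:2 site, L_acc = 100
  A <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  H <- haplotype_set(A, 50L, "chr", 1000L)
  expect_equal(nucleotide_diversity(H, one_window(1000, 100)),
               (4 / 3) * 0.5 / 100, tolerance = 1e-12)
  # monomorphic window -> 0
  H0 <- haplotype_set(matrix(0L, 1, 4), 50L, "chr", 1000L)
  expect_equal(nucleotide_diversity(H0, one_window(1000, 100)), 0)
  # halving the accessible length doubles pi
  expect_equal(nucleotide_diversity(H, one_window(1000, 50)),
               2 * nucleotide_diversity(H, one_window(1000, 100)))
  # L_acc = 0 -> NA
  expect_true(is.na(nucleotide_diversity(H, one_window(1000, 0))))
})

test_that("pi from the genotype path equals pi from the haplotype path", {
  set.seed(7)
  H <- random_hapset(10, 30, 5000)
  dose <- H$alleles[, seq(1, 10, 2)] + H$alleles[, seq(2, 10, 2)]
  G <- genotype_matrix(data.frame(contig = "chr", pos = H$pos,
                                  ref = "A", alt = "G"),
                       dose, paste0("s", 1:5), c(chr = 5000L))
  w <- one_window(5000)
  expect_equal(nucleotide_diversity(G, w), nucleotide_diversity(H, w),
               tolerance = 1e-12)
})

test_that("dxy: worked examples and monophyly bound", {
  w <- one_window(1000, 50)
  fixed0 <- haplotype_set(matrix(0L, 1, 4), 50L, "chr", 1000L)
  fixed1 <- haplotype_set(matrix(1L, 1, 4), 50L, "chr", 1000L)
  expect_equal(dxy(fixed0, fixed0, w), 0)
  expect_equal(dxy(fixed0, fixed1, w), 1 / 50)
  # p1 = 0.25, p2 = 0.75 single site, L_acc = 1
  H1 <- haplotype_set(matrix(c(1L, 0L, 0L, 0L), 1, 4), 50L, "chr", 1000L)
  H2 <- haplotype_set(matrix(c(1L, 1L, 1L, 0L), 1, 4), 50L, "chr", 1000L)
  expect_equal(dxy(H1, H2, one_window(1000, 1)), 0.625)

  # reciprocally monophyletic fixed classes: dxy >= each within-pi
  set.seed(1)
  S <- 40
  A1 <- matrix(sample(0:1, S * 5, replace = TRUE, prob = c(0.9, 0.1)), S, 5)
  A2 <- matrix(sample(0:1, S * 5, replace = TRUE, prob = c(0.9, 0.1)), S, 5)
  fixed_rows <- 1:10
  A1[fixed_rows, ] <- 0L; A2[fixed_rows, ] <- 1L
  Ha <- haplotype_set(A1, sort(sample.int(999, S)), "chr", 1000L)
  Hb <- haplotype_set(A2, Ha$pos, "chr", 1000L)
  w2 <- one_window(1000)
  expect_gte(dxy(Ha, Hb, w2), nucleotide_diversity(Ha, w2))
  expect_gte(dxy(Ha, Hb, w2), nucleotide_diversity(Hb, w2))
})

test_that("fixed-difference density counts per accessible bp", {
  fd <- structure(data.frame(contig = "chr", pos = c(100L, 200L, 300L, 400L, 500L),
                             ref = "A", alt = "G", z2_allele = 0L, z2m_allele = 1L),
                  class = c("fixed_diff_set", "data.frame"))
  w <- data.frame(contig = "chr", start = c(0, 600), end = c(600, 1200),
                  l_acc = c(10000, 10000), n_snp = 0L)
  expect_equal(fixed_diff_density(fd, w), c(5e-4, 0))
  # counting oracle: window counts sum to |fd| inside the windowed span
  expect_equal(sum(fixed_diff_density(fd, w) * w$l_acc), 5)
})

test_that("Hudson FST: worked example and identity", {
  # p1=0.2, p2=0.8 with 10 haplotypes each
  A1 <- matrix(c(rep(1L, 2), rep(0L, 8)), 1, 10)
  A2 <- matrix(c(rep(1L, 8), rep(0L, 2)), 1, 10)
  H1 <- haplotype_set(A1, 50L, "chr", 1000L)
  H2 <- haplotype_set(A2, 50L, "chr", 1000L)
  w <- one_window(1000)
  expect_equal(fst(H1, H2, w), (0.36 - 2 * 0.16 / 9) / 0.68, tolerance = 1e-12)
  # reciprocally fixed -> 1; identical frequencies, large n -> ~0
  F1 <- haplotype_set(matrix(0L, 1, 10), 50L, "chr", 1000L)
  F2 <- haplotype_set(matrix(1L, 1, 10), 50L, "chr", 1000L)
  expect_equal(fst(F1, F2, w), 1)
  # identical frequencies: estimator has a small negative bias, ~0
  a <- matrix(rep(c(0L, 1L), each = 50), 1)
  Hs <- haplotype_set(a, 50L, "chr", 1000L)
  expect_lt(abs(fst(Hs, Hs, w)), 0.02)
})

test_that("Tajima's D: worked example and S=0", {
  # n=4 haplotypes, 3 singleton sites
  A <- matrix(0L, 3, 4); A[1, 1] <- 1L; A[2, 2] <- 1L; A[3, 3] <- 1L
  H <- haplotype_set(A, c(100L, 200L, 300L), "chr", 1000L)
  w <- one_window(1000)
  d <- tajimas_d(H, w)
  expect_equal(d, oracle_tajima(A), tolerance = 1e-12)
  expect_equal(d, -0.754, tolerance = 1e-3)
  H0 <- haplotype_set(matrix(0L, 1, 4), 100L, "chr", 1000L)
  expect_true(is.na(tajimas_d(H0, w)))
})

test_that("folded SFS bins minor-allele counts", {
  # n=6, minor counts {1,1,2,3}
  A <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),
             c(0L, 1L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 0L, 0L, 0L))
  H <- haplotype_set(A, c(10L, 20L, 30L, 40L), "chr", 1000L)
  s_all <- folded_sfs(H)
  expect_equal(unname(s_all$counts), c(2L, 1L, 1L))
  s_ns <- folded_sfs(H, exclude_singletons = TRUE)
  expect_equal(unname(s_ns$counts), c(0L, 1L, 1L))
  expect_equal(sum(s_all$counts), 4L)  # total = segregating sites
})

test_that("LD decay r2: textbook haplotype configurations", {
  pairs <- list(
    list(h = c("AB", "AB", "ab", "ab"), r2 = 1),
    list(h = c("AB", "Ab", "aB", "ab"), r2 = 0),
    list(h = c("AB", "Ab", "AB", "ab"), r2 = 1 / 3))
  for (p in pairs) {
    a <- as.integer(substr(p$h, 1, 1) == "A")
    b <- as.integer(substr(p$h, 2, 2) == "B")
    H <- haplotype_set(rbind(a, b), c(100L, 300L), "chr", 1000L)
    ld <- ld_decay(H, max_dist = 1000, bin_width = 1000)
    expect_equal(ld$r2, p$r2, tolerance = 1e-12)
  }
})

test_that("Nei-Gojobori counting and pin_pis", {
  expect_equal(unname(codon_site_counts("TTT")), c(1 / 3, 8 / 3),
               tolerance = 1e-12)
  # conservation: S + N = 3 for every sense codon
  for (cd in names(ORACLE_CODE)[ORACLE_CODE != "*"])
    expect_equal(sum(codon_site_counts(cd)), 3, tolerance = 1e-12)

  # tiny gene fixture: ATG GGT GGA TAA on the reference; one variant at
  # a 4-fold third position (GGT->GGC, synonymous) -> pi_N = 0
  dir <- tempfile("cd")
  dir.create(dir)
  seqc <- paste0(strrep("A", 10), "ATGGGTGGATAA", strrep("A", 10))
  writeLines(c(">chr", seqc), file.path(dir, "ref.fa"))
  writeLines(c("##gff-version 3",
               "chr\tt\tgene\t11\t22\t.\t+\t.\tID=g1",
               "chr\tt\tmRNA\t11\t22\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr\tt\tCDS\t11\t22\t.\t+\t0\tID=g1.cds;Parent=g1.t1"),
             file.path(dir, "genes.gff3"))
  ann <- read_cds_annotation(file.path(dir, "genes.gff3"),
                             file.path(dir, "ref.fa"))
  # variant at genomic pos 16 (third base of codon GGT)
  A <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  H <- haplotype_set(A, 16L, "chr", nchar(seqc))
  cd <- pin_pis(H, ann, data.frame(pos = 16L, ref = "T", alt = "C"),
                gene_window = 1, gene_step = 1)
  expect_equal(cd$genes$pi_n, 0)
  expect_gt(cd$genes$pi_s, 0)
  # sum of site counts equals CDS length
  expect_equal(cd$genes$syn_sites + cd$genes$nonsyn_sites, 12, tolerance = 1e-9)

  # nonsynonymous variant at codon position 1 (GGA -> AGA, Gly->Arg)
  H2 <- haplotype_set(matrix(c(0L, 1L, 1L, 0L), 1, 4), 17L, "chr", nchar(seqc))
  cd2 <- pin_pis(H2, ann, data.frame(pos = 17L, ref = "G", alt = "A"),
                 gene_window = 1, gene_step = 1)
  expect_equal(cd2$genes$pi_s, 0)
  expect_gt(cd2$genes$pi_n, 0)
  expect_true(is.na(cd2$genes$ratio))
})

test_that("ne_ratio: identity, bootstrap, and the census expectation", {
  x <- c(1e-4, 2e-4, 3e-4, 2e-4)
  r <- ne_ratio(x, x, reps = 200, seed = 1)
  expect_equal(r$ratio, 1)
  r2 <- ne_ratio(x / 3, x, reps = 200, seed = 1)
  expect_equal(r2$ratio, 1 / 3, tolerance = 1e-12)
  expect_true(r2$se > 0 || is.na(r2$se))
  expect_true(is.na(ne_ratio(x, rep(0, 4))$ratio))
  # balanced-morph chromosome-count expectation
  expect_equal(round(arrangement_count_ratio(100, 100, 0), 2), 0.33)
})

test_that("neutral balanced simulation recovers the 1/3 Ne ratio", {
  # disassortative mating holds the rearranged arrangement at 1/4 of
  # chromosomes; synonymous-proxy diversity (all sites here are neutral)
  # inside the fully recombining inversion (c=1) recovers Ne_m/Ne_std ~ 1/3.
  # With c=1 classes mix inside the span, so the class-conditional
  # coalescent argument is tested in its cleanest form at c=0 instead.
  pis <- vapply(1:12, function(s) {
    tr <- simulate_population(small_config(80 + s, c_suppress = 0))
    set.seed(80 + s)
    Hm <- truth_haplotypes(tr, class = "ZAL2m", n = 40)
    Hz <- truth_haplotypes(tr, class = "ZAL2", n = 40)
    w <- make_windows(CONTIG(tr), 2e4)
    ins <- w$start >= tr$cfg$inv_start & w$end <= tr$cfg$inv_end
    c(mean(nucleotide_diversity(Hm, w)[ins], na.rm = TRUE),
      mean(nucleotide_diversity(Hz, w)[ins], na.rm = TRUE))
  }, numeric(2))
  r <- ne_ratio(pis[1, ], pis[2, ], reps = 1000, seed = 9)
  expect_gte(1 / 3, r$ci95[1] - 0.02)
  expect_lte(1 / 3, r$ci95[2] + 0.02)
})
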