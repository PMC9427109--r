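## Fixture emitters: VCF + metadata + mask, read-pair surrogates,
## coding annotation, and allele-resolved expression counts.
## All emitters draw from the current RNG stream; set.seed() upstream
## for reproducible fixtures.

.BASES <- c("A", "C", "G", "T")

#' Emit simulated genotypes as VCF with sample metadata and mask
#'
#' Writes unphased diploid genotypes (FORMAT `GT:DP`) for the final
#' generation, a sample-metadata TSV, and a BED accessibility mask equal
#' to the whole contig minus optional random gaps.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @param samples individual ids to emit (default: all).
#' @param mean_dp mean simulated per-sample read depth (Poisson).
#' @param mask_gap_fraction fraction of the contig dropped from the mask
#'   as random 1 kb inaccessible gaps.
#' @param ref optional `DNAStringSet` reference (from
#'   [emit_annotation()]); used for REF alleles, otherwise random bases.
#' @return list with `vcf`, `meta_path`, `mask_path` (file paths),
#'   `meta` (a [sample_meta()]), and `mask` (`GRanges`).
#' @export
emit_vcf <- function(truth, dir, samples = NULL, mean_dp = 30,
                     mask_gap_fraction = 0, ref = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- truth$cfg
  ids <- unique(truth$sample)
  if (!is.null(samples)) ids <- intersect(ids, samples)
  .assert(length(ids) > 0, "no samples to emit")
  hap_idx <- which(truth$sample %in% ids)
  S <- length(truth$pos)

  h <- truth$haps[, hap_idx, drop = FALSE]
  odd <- seq(1, ncol(h), 2)
  dose <- h[, odd, drop = FALSE] + h[, odd + 1L, drop = FALSE]

  if (!is.null(ref)) {
    refseq <- strsplit(as.character(ref[[1]]), "")[[1]]
    ref_al <- refseq[truth$pos]
  } else {
    ref_al <- sample(.BASES, S, replace = TRUE)
  }
  alt_al <- vapply(ref_al, function(b) sample(setdiff(.BASES, b), 1), "")

  gt_lv <- c("0/0", "0/1", "1/1")
  dp <- matrix(rpois(S * length(ids), mean_dp), S, length(ids))
  cells <- matrix(paste0(gt_lv[dose + 1L], ":", dp), S, length(ids))

  vcf_path <- file.path(dir, "sim.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", cfg$contig, cfg$contig_length),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- data.table::data.table(
    CHROM = cfg$contig, POS = truth$pos, ID = ".", REF = ref_al, ALT = alt_al,
    QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT:DP")
  body <- cbind(body, data.table::as.data.table(cells))
  writeLines(hdr, vcf_path)
  data.table::fwrite(body, vcf_path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)

  ind <- match(ids, unique(truth$sample))
  meta <- sample_meta(ids, truth$morph[ind],
                      sex = sample(c("M", "F"), length(ids), replace = TRUE),
                      location = "SIM")
  meta_path <- file.path(dir, "samples.tsv")
  write_table(as.data.frame(meta), meta_path)

  mask <- .make_sim_mask(cfg, mask_gap_fraction)
  mask_path <- file.path(dir, "mask.bed")
  df <- as.data.frame(mask)
  write.table(data.frame(df$seqnames, df$start - 1L, df$end),
              mask_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(vcf = vcf_path, meta_path = meta_path, mask_path = mask_path,
       meta = meta, mask = mask)
}

.make_sim_mask <- function(cfg, gap_fraction) {
  full <- GenomicRanges::GRanges(cfg$contig,
                                 IRanges::IRanges(1, cfg$contig_length))
  GenomeInfoDb::seqlengths(full) <- setNames(cfg$contig_length, cfg$contig)
  if (gap_fraction <= 0) return(full)
  n_gap <- ceiling(gap_fraction * cfg$contig_length / 1000)
  gs <- sort(sample.int(cfg$contig_length - 1000L, n_gap))
  gaps <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cfg$contig, IRanges::IRanges(gs + 1L, gs + 1000L)))
  GenomicRanges::setdiff(full, gaps)
}

#' Emit read-pair surrogate fragments from simulated haplotypes
#'
#' Fragments are sampled uniformly from each haplotype of the selected
#' samples; each covered site's allele is copied from the source
#' haplotype and flipped with probability `error_rate`.
#'
#' @param truth a `sim_truth`.
#' @param fragment_length fragment span in bp.
#' @param mean_depth haploid+haploid sequencing depth per sample, so the
#'   expected fragment count per sample is
#'   `mean_depth * contig_length / fragment_length`.
#' @param error_rate per-observation allele flip probability.
#' @param samples individual ids to sample fragments from (default: all
#'   WS individuals, the only ones the phasing stage needs).
#' @return list of class `fragment_set`: `frags` (fragment table with
#'   source truth) and `obs` (long table of per-site observations).
#' @export
emit_fragments <- function(truth, fragment_length = 1000, mean_depth = 4,
                           error_rate = 0, samples = NULL) {
  .assert(fragment_length > 0, "fragment_length must be positive")
  cfg <- truth$cfg
  L <- cfg$contig_length
  if (is.null(samples)) samples <- unique(truth$sample[rep(truth$morph == "WS", each = 2)])
  hap_idx <- which(truth$sample %in% samples)
  lam <- mean_depth * L / fragment_length / 2  # per haplotype

  per_hap <- rpois(length(hap_idx), lam)
  n_tot <- sum(per_hap)
  hap_of <- rep(hap_idx, per_hap)
  starts <- floor(runif(n_tot, 0, L - fragment_length + 1))
  frags <- data.table::data.table(
    frag_id = seq_len(n_tot),
    sample = truth$sample[hap_of],
    source_hap = hap_of,
    source_class = c("ZAL2", "ZAL2m")[truth$labels[hap_of] + 1L],
    start = as.integer(starts),
    end = as.integer(starts + fragment_length))

  pos <- truth$pos
  lo <- findInterval(starts, pos) + 1L        # first site with pos > start
  hi <- findInterval(starts + fragment_length, pos)  # last site <= end
  cnt <- pmax(hi - lo + 1L, 0L)
  site_idx <- sequence(cnt, from = lo)
  frag_of <- rep(frags$frag_id, cnt)
  allele <- truth$haps[cbind(site_idx, rep(hap_of, cnt))]
  if (error_rate > 0) {
    flip <- runif(length(allele)) < error_rate
    allele[flip] <- 1L - allele[flip]
  }
  obs <- data.table::data.table(frag_id = frag_of, pos = pos[site_idx],
                                allele = as.integer(allele))
  structure(list(frags = frags, obs = obs,
                 fragment_length = as.integer(fragment_length),
                 error_rate = error_rate),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments (%d bp) from %d sample(s), %d site observations\n",
              nrow(x$frags), x$fragment_length,
              length(unique(x$frags$sample)), nrow(x$obs)))
  invisible(x)
}

#' Emit a reference sequence with planted coding genes
#'
#' Generates a random reference for the configured contig with
#' `cfg$n_genes` non-overlapping single-exon coding genes (valid ORFs:
#' ATG start, sense codons, terminal stop), and writes FASTA + GFF3.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return list with `fasta`, `gff` (paths), `ref` (`DNAStringSet`) and
#'   `genes` (data.frame of gene id, 0-based start, end, strand).
#' @export
emit_annotation <- function(cfg, dir) {
  .assert(cfg$n_genes >= 1, "need at least one gene")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- cfg$contig_length
  seqc <- sample(.BASES, L, replace = TRUE)

  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  slot <- floor(L / cfg$n_genes)
  genes <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    n_codon <- sample(60:200, 1)         # 180-600 bp CDS
    len <- 3L * (n_codon + 2L)           # + start & stop
    .assert(len + 10 < slot, "contig too small for requested genes")
    off <- sample.int(slot - len - 1L, 1)
    start0 <- (g - 1L) * slot + off      # 0-based
    orf <- c("ATG", sample(sense, n_codon, replace = TRUE), "TAA")
    seqc[(start0 + 1):(start0 + len)] <- unlist(strsplit(orf, ""))
    genes[[g]] <- data.frame(gene = sprintf("gene%03d", g),
                             start = start0, end = start0 + len,
                             strand = "+", stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  ref <- Biostrings::DNAStringSet(paste(seqc, collapse = ""))
  names(ref) <- cfg$contig
  fasta <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(ref, fasta)

  gff <- file.path(dir, "genes.gff3")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", cfg$contig, L))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene[i]
    s1 <- genes$start[i] + 1L; e1 <- genes$end[i]
    lines <- c(lines,
      sprintf("%s\tsgscan\tgene\t%d\t%d\t.\t+\t.\tID=%s", cfg$contig, s1, e1, gid),
      sprintf("%s\tsgscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
              cfg$contig, s1, e1, gid, gid),
      sprintf("%s\tsgscan\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s.t1",
              cfg$contig, s1, e1, gid, gid))
  }
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff, ref = ref, genes = genes)
}

#' Emit allele-resolved expression counts for WS samples
#'
#' Per-gene, per-sample read counts for the two arrangement alleles of
#' heterokaryotype (WS) individuals under a negative-binomial total with
#' a binomial allele split whose log2-odds equal the gene's cis effect.
#'
#' @param truth a `sim_truth`.
#' @param genes data.frame from [emit_annotation()] (column `gene`).
#' @param cis_effect named numeric vector: per-gene log2 allelic-ratio
#'   shift (0 = balanced; +1 = 2:1 in favour of the rearranged allele).
#'   Genes absent from `genes` are an error.
#' @param dispersion negative-binomial dispersion of the total count.
#' @param mean_depth mean total count per gene per sample.
#' @return data.table with gene, sample, z2m_count, z2_count.
#' @export
emit_expression <- function(truth, genes, cis_effect, dispersion = 0.2,
                            mean_depth = 200) {
  bad <- setdiff(names(cis_effect), genes$gene)
  if (length(bad)) stop("gene(s) absent from annotation: ",
                        paste(bad, collapse = ", "))
  ws <- unique(truth$sample[rep(truth$morph == "WS", each = 2)])
  .assert(length(ws) > 0, "no WS samples in truth")
  gn <- names(cis_effect)
  grid <- data.table::CJ(gene = gn, sample = ws, sorted = FALSE)
  eff <- cis_effect[grid$gene]
  p_m <- 2^eff / (1 + 2^eff)
  total <- rnbinom(nrow(grid), mu = mean_depth, size = 1 / dispersion)
  z2m <- rbinom(nrow(grid), total, p_m)
  grid$z2m_count <- z2m
  grid$z2_count <- total - z2m
  grid[]
}
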