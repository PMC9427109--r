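## Data model and standard-format I/O shared by all stages.

#' Construct a genotype matrix
#'
#' Container for biallelic diploid genotype calls: a site table (contig,
#' 1-based position, ref/alt allele, per-site mean depth) plus a sites x
#' samples matrix of alternate-allele dosages (0, 1, 2 or `NA` for
#' missing).
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `mean_dp`.
#' @param geno integer matrix, `nrow(sites)` x `length(samples)`, values
#'   in `c(0, 1, 2, NA)`.
#' @param samples character vector of sample ids (column order of `geno`).
#' @param contigs named integer vector of contig lengths in bp.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, samples, contigs) {
  sites <- as.data.frame(sites)
  .assert(all(c("contig", "pos", "ref", "alt") %in% names(sites)),
          "sites needs columns contig, pos, ref, alt")
  .assert(nrow(sites) == nrow(geno), "sites and geno row mismatch")
  .assert(ncol(geno) == length(samples), "geno columns must match samples")
  .assert(all(geno %in% c(0L, 1L, 2L) | is.na(geno)),
          "genotypes must be dosages 0/1/2 or NA")
  for (ct in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ct]
    .assert(!is.unsorted(p, strictly = TRUE),
            sprintf("positions not strictly increasing on contig %s", ct))
  }
  if (is.null(sites$mean_dp)) sites$mean_dp <- NA_real_
  colnames(geno) <- samples
  structure(list(sites = sites, geno = geno, samples = samples,
                 contigs = contigs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples on %d contig(s)\n",
              nrow(x$sites), length(x$samples), length(x$contigs)))
  invisible(x)
}

#' Construct a sample metadata table
#'
#' @param id character sample ids.
#' @param morph morph per sample: `"TS"` (standard homokaryotype), `"WS"`
#'   (heterokaryotype) or `"SW"` (rearranged homokaryotype).
#' @param sex,location optional character annotations.
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(id, morph, sex = NA_character_, location = NA_character_) {
  .assert(length(id) == length(morph), "id and morph lengths differ")
  .assert(all(morph %in% c("TS", "WS", "SW")), "morph must be TS, WS or SW")
  .assert(!anyDuplicated(id), "duplicated sample ids")
  out <- data.frame(id = as.character(id), morph = morph,
                    sex = sex, location = location,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Read and filter a VCF into a genotype matrix
#'
#' Keeps biallelic SNPs only and applies the study-style site filters:
#' missingness, minor-allele frequency, and mean depth (mean of per-sample
#' depths over non-missing samples).  The number of sites removed by each
#' filter is attached as attribute `"filter_log"` and reported via
#' `message()`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param meta `sample_meta`; every VCF sample must appear in it.
#' @param max_missing_fraction maximum fraction of samples with missing
#'   genotype at a site (default 0: drop sites with any missing call).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param min_mean_dp,max_mean_dp mean-depth bounds (defaults 5 and 80).
#'   Sites with no DP information pass the depth filter.
#' @return `genotype_matrix` restricted to passing sites.
#' @export
read_vcf <- function(path, meta,
                     max_missing_fraction = 0, min_maf = 0.05,
                     min_mean_dp = 5, max_mean_dp = 80) {
  vcf <- VariantAnnotation::readVcf(path, genome = "sim")
  smp <- colnames(vcf)
  unknown <- setdiff(smp, meta$id)
  if (length(unknown))
    stop("sample(s) absent from metadata: ", paste(unknown, collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  biallelic <- n_alt == 1 & nchar(ref) == 1 & nchar(alt1) == 1 & alt1 %in% c("A", "C", "G", "T")
  n_multi <- sum(!biallelic)
  if (n_multi > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_multi))

  gt <- VariantAnnotation::geno(vcf)$GT[biallelic, , drop = FALSE]
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L

  dp <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(dp)) {
    dp <- dp[biallelic, , drop = FALSE]
    storage.mode(dp) <- "double"
    dp[is.na(dose)] <- NA_real_
    mean_dp <- rowMeans(dp, na.rm = TRUE)
  } else {
    mean_dp <- rep(NA_real_, nrow(gt))
  }

  ns <- ncol(dose)
  n_miss <- rowSums(is.na(dose))
  n_ok <- ns - n_miss
  p_alt <- rowSums(dose, na.rm = TRUE) / (2 * pmax(n_ok, 1L))
  maf <- pmin(p_alt, 1 - p_alt)

  pass_miss <- n_miss / ns <= max_missing_fraction
  pass_maf <- maf >= min_maf & n_ok > 0
  pass_dp <- is.na(mean_dp) | (mean_dp >= min_mean_dp & mean_dp <= max_mean_dp)
  keep <- pass_miss & pass_maf & pass_dp

  flog <- c(multiallelic_or_non_snp = n_multi,
            missingness = sum(!pass_miss),
            maf = sum(pass_miss & !pass_maf),
            mean_dp = sum(pass_miss & pass_maf & !pass_dp))
  message(sprintf("read_vcf: %d/%d SNPs retained (removed: missing %d, maf %d, depth %d)",
                  sum(keep), length(keep), flog[["missingness"]],
                  flog[["maf"]], flog[["mean_dp"]]))

  ctg_len <- GenomeInfoDb::seqlengths(rr)
  if (all(is.na(ctg_len)))
    ctg_len <- setNames(rep(NA_integer_, length(GenomeInfoDb::seqlevels(rr))),
                        GenomeInfoDb::seqlevels(rr))
  rrb <- rr[biallelic][keep]
  sites <- data.frame(contig = as.character(GenomeInfoDb::seqnames(rrb)),
                      pos = BiocGenerics::start(rrb),
                      ref = ref[biallelic][keep],
                      alt = alt1[biallelic][keep],
                      mean_dp = mean_dp[keep],
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, dose[keep, , drop = FALSE], smp, ctg_len)
  attr(gm, "filter_log") <- flog
  gm
}

#' Load a BED3 accessibility mask
#'
#' Intervals are merged (with a warning when any overlapped) and returned
#' sorted as a `GRanges`; BED input is 0-based half-open and is kept that
#' way internally.
#'
#' @param path BED file; an empty file yields an empty mask (all sites
#'   inaccessible).
#' @return `GRanges` of accessible intervals.
#' @export
load_mask <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  red <- GenomicRanges::reduce(gr)
  if (length(red) < length(gr) &&
      sum(BiocGenerics::width(red)) < sum(BiocGenerics::width(gr)))
    warning("overlapping mask intervals merged")
  BiocGenerics::sort(red)
}

.mask_granges <- function(mask) {
  if (is.null(mask)) return(NULL)
  .assert(methods::is(mask, "GRanges"), "mask must be a GRanges or NULL")
  mask
}

#' Tile contigs into windows with accessible length and SNP counts
#'
#' Windows are fixed-size `[start, end)` tiles (0-based half-open);
#' trailing partial windows shorter than `size` are dropped.  `l_acc` is
#' the overlap with the accessibility mask (full window span when `mask`
#' is `NULL`), `n_snp` the number of sites falling in the window.
#'
#' @param contigs named integer vector of contig lengths.
#' @param size,step window size and step in bp; `step > size` gives a
#'   gapped tiling.
#' @param mask optional `GRanges` accessibility mask.
#' @param sites optional data.frame with `contig` and 1-based `pos`.
#' @return data.frame with columns contig, start, end, l_acc, n_snp.
#' @export
make_windows <- function(contigs, size, step = size, mask = NULL, sites = NULL) {
  .assert(size > 0 && step > 0, "size and step must be positive")
  mask <- .mask_granges(mask)
  out <- list()
  for (ct in names(contigs)) {
    len <- contigs[[ct]]
    if (is.na(len) || len < size) next
    starts <- seq.int(0L, len - size, by = step)
    out[[ct]] <- data.frame(contig = ct, start = starts, end = starts + size,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      l_acc = numeric(), n_snp = integer()))
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  wgr <- GenomicRanges::GRanges(win$contig,
                                IRanges::IRanges(win$start + 1L, win$end))
  if (is.null(mask)) {
    win$l_acc <- as.numeric(win$end - win$start)
  } else {
    hits <- GenomicRanges::findOverlaps(wgr, mask)
    inter_w <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(wgr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(mask)[S4Vectors::subjectHits(hits)]))
    acc <- rep(0, nrow(win))
    if (length(hits)) {
      agg <- tapply(inter_w, S4Vectors::queryHits(hits), sum)
      acc[as.integer(names(agg))] <- as.numeric(agg)
    }
    win$l_acc <- acc
  }
  win$n_snp <- 0L
  if (!is.null(sites) && nrow(sites)) {
    sgr <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
    win$n_snp <- GenomicRanges::countOverlaps(wgr, sgr)
  }
  win
}

#' Write a statistics table as TSV
#'
#' Tab-separated with a header row, deterministic column order as given,
#' numeric columns rendered at 6 significant digits, `NA`/`NaN` as "NA".
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- df[[j]]
      s <- ifelse(is.finite(v), formatC(v, digits = 6, format = "g"),
                  ifelse(is.na(v) | is.nan(v), "NA", as.character(v)))
      df[[j]] <- s
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}
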