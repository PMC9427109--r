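## Coding annotation and nonsynonymous/synonymous diversity
## (Nei-Gojobori mutational-opportunity site counting).

#' Read a CDS annotation (GFF3 + reference FASTA)
#'
#' Groups CDS features by transcript, checks that each concatenated CDS
#' is a multiple of 3 and free of internal stop codons in the reference
#' frame; offending genes are skipped with a warning.
#'
#' @param gff GFF3 path (CDS features with `Parent` transcript ids).
#' @param fasta reference FASTA path.
#' @return list of class `cds_annotation`: `genes` (data.frame gene,
#'   transcript, start (0-based), end, strand, cds_len), `intervals`
#'   (per-gene list of 0-based half-open intervals in transcription
#'   order) and `ref` (`DNAStringSet`).
#' @export
read_cds_annotation <- function(gff, fasta) {
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*", "", names(ref))
  gr <- rtracklayer::import(gff, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  .assert(length(cds) > 0, "no CDS features in annotation")
  parent <- vapply(cds$Parent, function(p) p[1], "")
  genes <- list(); intervals <- list()
  for (tr in unique(parent)) {
    iv <- cds[parent == tr]
    strand <- as.character(BiocGenerics::strand(iv))[1]
    ord <- order(BiocGenerics::start(iv), decreasing = (strand == "-"))
    iv <- iv[ord]
    ctg <- as.character(GenomeInfoDb::seqnames(iv))[1]
    segs <- cbind(start = BiocGenerics::start(iv) - 1L, end = BiocGenerics::end(iv))
    len <- sum(segs[, "end"] - segs[, "start"])
    gid <- sub("\\.t\\d+$", "", tr)
    if (len %% 3 != 0) {
      warning(sprintf("gene %s: CDS length not a multiple of 3; skipped", gid))
      next
    }
    seq <- .cds_sequence(ref[[ctg]], segs, strand)
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(seq))), "")[[1]]
    if (any(aa[-length(aa)] == "*")) {
      warning(sprintf("gene %s: internal stop codon; skipped", gid))
      next
    }
    genes[[gid]] <- data.frame(gene = gid, transcript = tr, contig = ctg,
                               start = min(segs[, "start"]), end = max(segs[, "end"]),
                               strand = strand, cds_len = len,
                               stringsAsFactors = FALSE)
    intervals[[gid]] <- segs
  }
  .assert(length(genes) > 0, "no valid genes in annotation")
  structure(list(genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
                 intervals = intervals, ref = ref),
            class = "cds_annotation")
}

.cds_sequence <- function(refseq, segs, strand) {
  parts <- apply(segs, 1, function(s)
    as.character(Biostrings::subseq(refseq, s[["start"]] + 1L, s[["end"]])))
  if (strand == "-") {
    parts <- vapply(parts, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))), "")
  }
  paste(parts, collapse = "")
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' Each of the 9 single-base changes of the codon is classified with the
#' standard genetic code; a change is synonymous when the encoded amino
#' acid (or stop) is unchanged, so sense-to-stop changes count as
#' nonsynonymous and stop-to-stop as synonymous (the terminal stop codon
#' participates, preserving `syn + nonsyn = 3` per codon and
#' `sum = CDS length` per gene).  The synonymous site count is the sum
#' over positions of the fraction of changes that are synonymous.
#'
#' @param codon 3-letter uppercase codon string.
#' @return named numeric `c(syn, nonsyn)`.
#' @export
codon_site_counts <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa0 <- gc[[codon]]
  .assert(!is.null(aa0), "invalid codon")
  syn <- 0
  for (p in 1:3) {
    b0 <- substr(codon, p, p)
    for (b in setdiff(.BASES, b0)) {
      mut <- codon
      substr(mut, p, p) <- b
      if (gc[[mut]] == aa0) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

#' Coding-sequence diversity: pi_N and pi_S per gene and per gene window
#'
#' Per-site unbiased pi at each coding variant is classified as
#' synonymous or nonsynonymous by substituting the alternate base into
#' the reference codon; gene-level pi_N (pi_S) is the summed
#' nonsynonymous (synonymous) pi divided by the gene's Nei-Gojobori
#' nonsynonymous (synonymous) site count.  Gene windows aggregate
#' numerators and denominators over `gene_window` consecutive genes
#' (ordered by position) with step `gene_step`.
#'
#' @param H `haplotype_set` of one arrangement class.
#' @param ann `cds_annotation`.
#' @param site_alleles data.frame with `pos` (1-based), `ref`, `alt`
#'   nucleotides for the sites of `H` (e.g. the VCF site table).
#' @param gene_window,gene_step window size and step in genes.
#' @return list of class `coding_diversity`: `genes` and `windows`
#'   data.frames with pi_N, pi_S and their ratio (`NA` when pi_S is 0).
#' @export
pin_pis <- function(H, ann, site_alleles, gene_window = 20, gene_step = 5) {
  f <- .hap_freq(H$alleles)
  per_site_pi <- ifelse(f$n >= 2, f$n / (f$n - 1) * 2 * f$p * (1 - f$p), 0)
  al <- site_alleles[match(H$pos, site_alleles$pos), ]

  g <- ann$genes[order(ann$genes$start), ]
  res <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene[i]
    segs <- ann$intervals[[gid]]
    strand <- g$strand[i]
    refseq <- ann$ref[[g$contig[i]]]
    cds <- .cds_sequence(refseq, segs, strand)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    sc <- vapply(codons, codon_site_counts, numeric(2))
    n_syn_sites <- sum(sc["syn", ])
    n_non_sites <- sum(sc["nonsyn", ])

    ## map genomic site positions into CDS offsets (0-based)
    offs <- integer(0); sel <- integer(0)
    cum <- 0L
    for (r in seq_len(nrow(segs))) {
      s0 <- segs[r, "start"]; e0 <- segs[r, "end"]
      in_seg <- which(H$pos > s0 & H$pos <= e0)
      if (length(in_seg)) {
        o <- if (strand == "+") cum + (H$pos[in_seg] - 1L - s0)
             else cum + (e0 - H$pos[in_seg])
        offs <- c(offs, o); sel <- c(sel, in_seg)
      }
      cum <- cum + (e0 - s0)
    }
    syn_pi <- 0; non_pi <- 0
    for (k in seq_along(sel)) {
      s <- sel[k]
      if (per_site_pi[s] == 0) next
      refb <- al$ref[s]; altb <- al$alt[s]
      if (is.na(refb)) next
      if (strand == "-") {
        refb <- chartr("ACGT", "TGCA", refb)
        altb <- chartr("ACGT", "TGCA", altb)
      }
      ci <- offs[k] %/% 3L + 1L
      cp <- offs[k] %% 3L + 1L
      codon <- codons[ci]
      if (substr(codon, cp, cp) != refb) {
        warning(sprintf("gene %s: reference mismatch at pos %d; site skipped",
                        gid, H$pos[s]))
        next
      }
      mut <- codon
      substr(mut, cp, cp) <- altb
      gc <- Biostrings::GENETIC_CODE
      if (gc[[mut]] == gc[[codon]])
        syn_pi <- syn_pi + per_site_pi[s]
      else
        non_pi <- non_pi + per_site_pi[s]
    }
    res[[i]] <- data.frame(gene = gid, start = g$start[i], end = g$end[i],
                           syn_sites = n_syn_sites, nonsyn_sites = n_non_sites,
                           syn_pi_sum = syn_pi, nonsyn_pi_sum = non_pi,
                           pi_s = syn_pi / n_syn_sites,
                           pi_n = non_pi / n_non_sites,
                           stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, res)
  genes$ratio <- ifelse(genes$pi_s > 0, genes$pi_n / genes$pi_s, NA_real_)

  nw <- nrow(genes)
  starts <- seq(1, max(nw - gene_window + 1, 1), by = gene_step)
  win <- lapply(starts, function(s) {
    e <- min(s + gene_window - 1, nw)
    blk <- genes[s:e, ]
    pin <- sum(blk$nonsyn_pi_sum) / sum(blk$nonsyn_sites)
    pis <- sum(blk$syn_pi_sum) / sum(blk$syn_sites)
    data.frame(first_gene = blk$gene[1], last_gene = blk$gene[nrow(blk)],
               n_genes = nrow(blk), start = blk$start[1], end = blk$end[nrow(blk)],
               pi_n = pin, pi_s = pis,
               ratio = ifelse(pis > 0, pin / pis, NA_real_))
  })
  structure(list(genes = genes, windows = do.call(rbind, win)),
            class = "coding_diversity")
}
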