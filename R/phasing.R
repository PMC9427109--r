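## Arrangement-diagnostic fixed differences, fragment assignment, and
## pseudo-haplotype construction.

#' Call fixed differences between arrangements from morph-labelled genotypes
#'
#' A site is an arrangement-diagnostic fixed difference when every
#' non-missing TS (standard homokaryotype) genotype is homozygous for one
#' allele, every non-missing SW (rearranged homokaryotype) genotype is
#' homozygous for the other, and every non-missing WS (heterokaryotype)
#' genotype is heterozygous, with the missing fraction in each morph
#' class at most `allow_missing`.
#'
#' @param G `genotype_matrix`.
#' @param meta `sample_meta` covering all samples in `G`.
#' @param allow_missing maximum missing fraction per morph class at a
#'   site (default 0).
#' @return data.frame of class `fixed_diff_set`: contig, pos, `z2_allele`
#'   and `z2m_allele` (0 = ref, 1 = alt), ref/alt bases, and per-class
#'   supporting counts.
#' @export
call_fixed_differences <- function(G, meta, allow_missing = 0) {
  m <- meta$morph[match(G$samples, meta$id)]
  .assert(!anyNA(m), "samples missing from metadata")
  for (cls in c("TS", "WS", "SW"))
    if (!any(m == cls))
      stop(sprintf("no %s samples available: the morph pattern needs all three classes", cls))

  cls_stats <- function(cls) {
    X <- G$geno[, m == cls, drop = FALSE]
    n <- ncol(X)
    miss <- rowSums(is.na(X)) / n
    list(miss = miss,
         n_ok = rowSums(!is.na(X)),
         all0 = rowSums(X == 0L, na.rm = TRUE) == rowSums(!is.na(X)),
         all2 = rowSums(X == 2L, na.rm = TRUE) == rowSums(!is.na(X)),
         all1 = rowSums(X == 1L, na.rm = TRUE) == rowSums(!is.na(X)))
  }
  ts <- cls_stats("TS"); sw <- cls_stats("SW"); ws <- cls_stats("WS")

  ok_miss <- ts$miss <= allow_missing & sw$miss <= allow_missing &
    ws$miss <= allow_missing & ts$n_ok > 0 & sw$n_ok > 0 & ws$n_ok > 0
  pat_a <- ts$all0 & sw$all2 & ws$all1   # ZAL2 allele = ref
  pat_b <- ts$all2 & sw$all0 & ws$all1   # ZAL2 allele = alt
  keep <- ok_miss & (pat_a | pat_b)

  out <- data.frame(contig = G$sites$contig[keep],
                    pos = G$sites$pos[keep],
                    ref = G$sites$ref[keep],
                    alt = G$sites$alt[keep],
                    z2_allele = ifelse(pat_a[keep], 0L, 1L),
                    z2m_allele = ifelse(pat_a[keep], 1L, 0L),
                    n_ts = ts$n_ok[keep], n_ws = ws$n_ok[keep],
                    n_sw = sw$n_ok[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("fixed_diff_set", "data.frame")
  out
}

#' Null probability of the morph-consistent allelic pattern at one site
#'
#' Probability, under independent Hardy-Weinberg genotypes at allele
#' frequency 0.5, that all TS and SW samples are homozygous (for opposite
#' alleles) and all WS samples heterozygous:
#' `labelings * (1/4)^(n_TS + n_SW) * (1/2)^(n_WS)`.
#' `labelings` counts the admissible assignments of alleles to the two
#' homozygote classes (default 2).
#'
#' @param n_ts,n_ws,n_sw per-morph sample counts.
#' @param labelings integer multiplicity (>= 1).
#' @return probability (numeric scalar).
#' @export
pattern_null_probability <- function(n_ts, n_ws, n_sw, labelings = 2) {
  .assert(labelings >= 1, "labelings must be >= 1")
  .assert(all(c(n_ts, n_ws, n_sw) >= 0) && (n_ts + n_ws + n_sw) > 0,
          "counts must be non-negative and not all zero")
  labelings * 0.25^(n_ts + n_sw) * 0.5^n_ws
}

#' Assign fragments to chromosome of origin
#'
#' A fragment overlapping at least one fixed-difference site is labelled
#' `ZAL2` or `ZAL2m` when its observed alleles at all overlapped
#' fixed-difference sites match that class, `conflict` when they mix, and
#' `unassigned` when it overlaps none.
#'
#' @param frags `fragment_set`.
#' @param fd `fixed_diff_set`.
#' @return list of class `assignment_result`: `labels` (data.table
#'   frag_id, label), `summary` (counts per label), `rate` (fraction of
#'   all fragments labelled to a class).
#' @export
assign_fragments <- function(frags, fd) {
  obs <- frags$obs
  fdt <- data.table::data.table(pos = fd$pos, z2 = fd$z2_allele,
                                z2m = fd$z2m_allele, key = "pos")
  hit <- fdt[obs, on = "pos", nomatch = NULL]
  if (nrow(hit)) {
    agg <- hit[, .(n_z2 = sum(allele == z2), n_z2m = sum(allele == z2m)),
               by = frag_id]
    agg[, label := data.table::fifelse(
      n_z2 > 0 & n_z2m == 0, "ZAL2",
      data.table::fifelse(n_z2m > 0 & n_z2 == 0, "ZAL2m", "conflict"))]
  } else {
    agg <- data.table::data.table(frag_id = integer(), n_z2 = integer(),
                                  n_z2m = integer(), label = character())
  }
  labels <- data.table::data.table(frag_id = frags$frags$frag_id)
  labels <- agg[, .(frag_id, label)][labels, on = "frag_id"]
  labels[is.na(label), label := "unassigned"]
  summ <- table(factor(labels$label,
                       levels = c("ZAL2", "ZAL2m", "unassigned", "conflict")))
  rate <- sum(summ[c("ZAL2", "ZAL2m")]) / nrow(labels)
  structure(list(labels = labels, summary = summ, rate = rate),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("<assignment_result>\n")
  print(x$summary)
  cat(sprintf("assignment rate: %.4f\n", x$rate))
  invisible(x)
}

#' Compare the fragment assignment rate with the inversion fraction
#'
#' In simulation the assignment rate is bounded above by (roughly) the
#' fraction of the contig within a fragment length of the rearranged
#' span, since fixed differences live inside the inversion.
#'
#' @param result `assignment_result`.
#' @param truth `sim_truth`.
#' @return data.frame with the assignment rate, the inversion fraction
#'   of the contig, and their ratio.
#' @export
assignment_rate_check <- function(result, truth) {
  cfg <- truth$cfg
  inv_frac <- (cfg$inv_end - cfg$inv_start) / cfg$contig_length
  data.frame(assignment_rate = result$rate,
             inversion_fraction = inv_frac,
             ratio = result$rate / inv_frac)
}

#' Build arrangement-resolved pseudo-haplotypes
#'
#' For each WS sample, the allele of the `ZAL2` / `ZAL2m` haplotype at a
#' site is the majority allele among that sample's fragments labelled to
#' the class covering the site, requiring at least `min_support`
#' fragments; ties and unsupported sites are missing.  TS samples
#' contribute two `ZAL2` haplotypes and SW samples two `ZAL2m`
#' haplotypes taken directly from their genotypes; their heterozygous
#' sites (phase unknown) are set missing on both haplotypes.
#'
#' @param G `genotype_matrix` (site grid; restricted to `region` if given).
#' @param meta `sample_meta`.
#' @param fd `fixed_diff_set` used for the assignment.
#' @param frags `fragment_set` for the WS samples.
#' @param result `assignment_result` from [assign_fragments()].
#' @param min_support minimum concordant fragment count per site.
#' @param region optional `c(start, end)` 0-based half-open restriction
#'   (typically the rearranged span).
#' @param contig_length contig length for the output set (defaults to
#'   the contig length recorded in `G`).
#' @return `haplotype_set` with two haplotypes per sample.
#' @export
build_pseudo_haplotypes <- function(G, meta, fd, frags, result,
                                    min_support = 2, region = NULL,
                                    contig_length = NULL) {
  keep <- rep(TRUE, nrow(G$sites))
  if (!is.null(region))
    keep <- G$sites$pos > region[1] & G$sites$pos <= region[2]
  site_pos <- G$sites$pos[keep]
  geno <- G$geno[keep, , drop = FALSE]
  morph <- meta$morph[match(G$samples, meta$id)]
  n_site <- length(site_pos)

  lab <- result$labels
  obs <- frags$obs[lab, on = "frag_id"]
  obs <- obs[label %in% c("ZAL2", "ZAL2m")]
  obs <- obs[pos %in% site_pos]
  obs <- obs[frags$frags[, .(frag_id, sample)], on = "frag_id", nomatch = NULL]

  votes <- obs[, .(n0 = sum(allele == 0L), n1 = sum(allele == 1L)),
               by = .(sample, label, pos)]
  votes[, total := n0 + n1]
  votes <- votes[total >= min_support & n0 != n1]
  votes[, allele := data.table::fifelse(n1 > n0, 1L, 0L)]

  cols <- list(); classes <- character(); samples_out <- character()
  for (i in seq_along(G$samples)) {
    sid <- G$samples[i]
    if (morph[i] == "WS") {
      for (cls in c("ZAL2", "ZAL2m")) {
        v <- votes[sample == sid & label == cls]
        hap <- rep(NA_integer_, n_site)
        if (nrow(v)) hap[match(v$pos, site_pos)] <- v$allele
        else warning(sprintf("sample %s has no %s-labelled fragments; haplotype all-missing", sid, cls))
        cols[[length(cols) + 1L]] <- hap
        classes <- c(classes, cls); samples_out <- c(samples_out, sid)
      }
    } else {
      cls <- if (morph[i] == "TS") "ZAL2" else "ZAL2m"
      g <- geno[, i]
      hap <- rep(NA_integer_, n_site)
      hap[g == 0L] <- 0L
      hap[g == 2L] <- 1L   # heterozygous sites stay missing
      for (k in 1:2) {
        cols[[length(cols) + 1L]] <- hap
        classes <- c(classes, cls); samples_out <- c(samples_out, sid)
      }
    }
  }
  A <- do.call(cbind, cols)
  haplotype_set(A, site_pos, G$sites$contig[keep][1] %||% "chr",
                contig_length %||% unname(G$contigs[1]),
                class = classes, sample = samples_out)
}
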