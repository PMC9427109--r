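# Independent brute-force oracles used to check the vectorized
# implementations. These stay deliberately naive (explicit loops over
# pairs/sites) and share no code with the package internals.

oracle_pi <- function(A, l_acc) {
  # mean pairwise per-site difference count over all haplotype pairs
  n <- ncol(A)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(A[, i]) & !is.na(A[, j])
    np <- np + 1
    tot <- tot + sum(A[ok, i] != A[ok, j])
  }
  # per-site unbiased pi equals mean pairwise difference over pairs
  (tot / np) / l_acc
}

oracle_dxy <- function(A1, A2, l_acc) {
  tot <- 0; np <- 0
  for (i in seq_len(ncol(A1))) for (j in seq_len(ncol(A2))) {
    np <- np + 1
    tot <- tot + sum(A1[, i] != A2[, j])
  }
  (tot / np) / l_acc
}

oracle_fst <- function(A1, A2) {
  # Hudson via the per-site identity F = (Hb - Hw) / Hb, ratio of sums
  n1 <- ncol(A1); n2 <- ncol(A2)
  num <- 0; den <- 0
  for (s in seq_len(nrow(A1))) {
    p1 <- mean(A1[s, ]); p2 <- mean(A2[s, ])
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    hw <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) + 2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
    num <- num + (hb - hw)
    den <- den + hb
  }
  if (den == 0) NA_real_ else num / den
}

oracle_tajima <- function(A) {
  n <- ncol(A)
  mac <- rowSums(A)
  seg <- mac > 0 & mac < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # mean pairwise differences by explicit pair loop
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    np <- np + 1; tot <- tot + sum(A[, i] != A[, j])
  }
  k_hat <- tot / np
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_r2 <- function(a, b) {
  pA <- mean(a); pB <- mean(b); pAB <- mean(a * b)
  D <- pAB - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(NA_real_)
  D^2 / den
}

oracle_h <- function(A, pos, L, focal) {
  # O(n^2 * S) explicit tract search per pair and focal site
  n <- ncol(A)
  out <- numeric(length(focal))
  for (q in seq_along(focal)) {
    x <- focal[q]
    tot <- 0; np <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      np <- np + 1
      mism <- pos[which(A[, i] != A[, j])]
      left <- mism[mism < x]
      right <- mism[mism > x]
      lb <- if (length(left)) max(left) else 0
      rb <- if (length(right)) min(right) else L
      tot <- tot + (rb - lb)
    }
    out[q] <- tot / np
  }
  out
}

# standard genetic code, written out independently of Biostrings
ORACLE_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_ng_counts <- function(codon) {
  aa <- ORACLE_CODE[[codon]]
  if (aa == "*") return(c(NA_real_, NA_real_))
  syn <- 0
  for (p in 1:3) for (b in setdiff(c("A","C","G","T"), substr(codon, p, p))) {
    mut <- codon; substr(mut, p, p) <- b
    if (ORACLE_CODE[[mut]] == aa) syn <- syn + 1/3
  }
  c(syn, 3 - syn)
}

adjusted_rand <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  sc <- sum(choose(t, 2)); sa <- sum(choose(rowSums(t), 2))
  sb <- sum(choose(colSums(t), 2))
  e <- sa * sb / choose(n, 2)
  (sc - e) / ((sa + sb) / 2 - e)
}

random_hapset <- function(n, S, L = 1000, allow_na = FALSE) {
  pos <- sort(sample.int(L - 1, S))
  A <- matrix(sample(0:1, S * n, replace = TRUE), S, n)
  if (allow_na) A[sample(length(A), ceiling(length(A) * 0.05))] <- NA_integer_
  haplotype_set(A, pos, "chr", L)
}

one_window <- function(L, l_acc = L) {
  data.frame(contig = "chr", start = 0, end = L, l_acc = l_acc, n_snp = 0L)
}
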