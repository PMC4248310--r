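# deterministic hand-built fixtures shared across test files

# two genes on opposite strands of a 100 kb chromosome
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(5000, 40000), end = c(10000, 48000),
    strand = c("+", "-"),
    tss = c(5000, 48000),
    exonic_length = c(2000, 3000),
    biotype = "protein_coding",
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    start = c(5000, 8000, 40000),
    end = c(6000, 9000, 43000))
  gene_annotation(genes, exons, c(chr1 = 1e5))
}

# uniform coverage track: `rate` reads per bin of width `bin` over [0, len)
flat_coverage <- function(len, bin = 100, rate = 10) {
  n <- len %/% bin
  data.frame(chrom = "chr1",
             start = (seq_len(n) - 1) * bin,
             end = seq_len(n) * bin,
             score = rate)
}

# brute-force two-sided Fisher p by hypergeometric enumeration
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force two-sided Mann-Whitney p by enumerating all group assignments
enum_rank_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  cmb <- utils::combn(length(pooled), na)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  u_all <- apply(cmb, 2, u_of)
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
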