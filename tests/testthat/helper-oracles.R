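# Independent oracles and small fixture builders used across the suite.

# explicit orthonormal Haar analysis matrix, built directly from the basis
# definition (never from the package's pyramid code): row 1 is the scaling
# vector; detail scale s (1..J) contributes 2^(s-1) rows, each supported on a
# block of 2^(J-s+1) points, minus on the left half, plus on the right,
# normalised to unit length
naive_haar_matrix <- function(J) {
  N <- 2^J
  W <- matrix(0, N, N)
  W[1, ] <- 1 / sqrt(N)
  r <- 1L
  for (s in seq_len(J)) {
    L <- 2^(J - s + 1)
    for (l in seq_len(2^(s - 1))) {
      r <- r + 1L
      idx <- ((l - 1) * L + 1):(l * L)
      W[r, idx[seq_len(L / 2)]] <- -1 / sqrt(L)
      W[r, idx[(L / 2 + 1):L]] <- 1 / sqrt(L)
    }
  }
  W
}

# explicit orthonormal sum-pyramid rows, scales 0..S, for a length-2^J signal
naive_c_matrix <- function(J, S) {
  N <- 2^J
  rows <- list()
  for (s in 0:S) {
    L <- 2^(J - s)
    for (l in seq_len(2^s)) {
      row <- rep(0, N)
      row[((l - 1) * L + 1):(l * L)] <- 1 / sqrt(L)
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

scale_index_oracle <- function(S) rep.int(0:S, 2^(0:S))

# brute-force double loops over (s, l) for the region summaries
brute_Lh <- function(beta, pi_tilde, fit, S) {
  idx <- 0
  total <- 0
  for (s in 0:S) for (l in seq_len(2^s)) {
    idx <- idx + 1
    if (is.na(beta[idx])) next
    fa <- dnorm(beta[idx], fit$mu_alt, sqrt(fit$sigma2_alt))
    fn <- dnorm(beta[idx], 0, sqrt(fit$sigma2_null))
    total <- total + (1 / 2^s) * (pi_tilde[idx] * fa - (1 - pi_tilde[idx]) * fn)
  }
  total
}

brute_ph <- function(pi_tilde, S) {
  idx <- 0
  total <- 0
  for (s in 0:S) for (l in seq_len(2^s)) {
    idx <- idx + 1
    total <- total + pi_tilde[idx] / 2^s
  }
  total
}

brute_pv <- function(pi_tilde, S) {
  stopifnot(S >= 2)
  total <- 0
  for (k in seq_len(S - 1)) {
    lo <- max(floor(2^S * (k - 1) / (S - 1)), 1)
    hi <- floor(2^S * k / (S - 1))
    members <- c()
    idx <- 0
    for (s in 0:S) for (l in seq_len(2^s)) {
      idx <- idx + 1
      if (s == 0) next
      fs <- (l - 1) * 2^(S - s) + 1
      fe <- l * 2^(S - s)
      if (fs <= hi && fe >= lo) members <- c(members, idx)
    }
    total <- total + sum(pi_tilde[members]) / length(members)
  }
  total
}

# small LD-free genotype region with exact dyadic layout (noiseless path)
dyadic_region <- function(K, J, seed = 1) {
  set.seed(seed)
  n <- 2^J
  G <- matrix(round(runif(K * n) * 2, 3), K, n)
  genotype_region(G, positions = seq_len(n) * 100, iq = rep(1, n))
}

# minimal VCF text fixture: 2 samples, DS dosage field, one low-IQ SNP and
# one multi-allelic site
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tA\tG\t.\tPASS\tR2=0.99\tGT:DS\t0/0:0.1\t0/1:1.2",
    "1\t200\trs2\tC\tT\t.\tPASS\tR2=0.95\tGT:DS\t1/1:1.9\t0/0:0.0",
    "1\t250\trs3\tG\tA\t.\tPASS\tR2=0.75\tGT:DS\t0/1:1.0\t0/1:0.9",
    "1\t300\trs4\tT\tC\t.\tPASS\tR2=0.90\tGT:DS\t0/1:1.1\t1/1:2.0",
    "1\t400\trs5\tA\tC,G\t.\tPASS\tR2=0.99\tGT:DS\t0/1:1.0\t0/0:0.0"
  )
  writeLines(lines, path)
  path
}

write_toy_vcf_gt <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1",
    "1\t300\trs3\tT\tC\t.\tPASS\t.\tGT\t0/1\t1/1"
  )
  writeLines(lines, path)
  path
}
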