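# Independent reference implementations used as oracles. These deliberately
# take different numerical routes from the package (explicit inverses,
# naive loops) so agreement is informative.

# Brute-force GLS solve of theta from summary data via explicit inversion.
gls_oracle <- function(bx, by, sy, rho) {
  omega <- diag(sy, nrow = length(sy)) %*% rho %*% diag(sy, nrow = length(sy))
  oi <- solve(omega)
  a <- drop(t(bx) %*% oi %*% bx)
  list(theta = drop(t(bx) %*% oi %*% by) / a, se = sqrt(1 / a))
}

# Naive greedy clump written as a direct transcription of the procedure:
# keep looping over a mutable candidate list.
clump_reference <- function(records, rho, r2_threshold, window_kb) {
  remaining <- records[order(records$pvalue, records$pos, records$rsid), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$rsid)
    keep_rows <- c()
    for (k in seq_len(nrow(remaining))[-1]) {
      cand <- remaining[k, ]
      close_by <- abs(cand$pos - idx$pos) <= window_kb * 1000
      r <- rho[cand$rsid, idx$rsid]
      if (!(close_by && r^2 >= r2_threshold)) keep_rows <- c(keep_rows, k)
    }
    remaining <- remaining[keep_rows, , drop = FALSE]
  }
  kept
}

# Random positive-definite correlation matrix.
random_corr <- function(m) {
  a <- matrix(rnorm(m * (m + 2)), m + 2, m)
  stats::cov2cor(crossprod(a))
}

# Minimal valid variant-association table with arbitrary stats.
make_assoc <- function(rsid, beta, se, pvalue = 0.5, pos = seq_along(rsid),
                       eaf = 0.3, chrom = "4", ea = "A", oa = "G",
                       n = 1000) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

# Random flip of rows of an association table (allele-convention change).
random_flip <- function(x, flip_mask) {
  out <- x
  out[flip_mask, ] <- flip_variant(x[flip_mask, , drop = FALSE])
  out
}
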