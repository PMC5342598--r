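# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk unless a test writes it first.

# Long-format Ct rows for one sample. Pass NA for an undetected well.
ct_rows <- function(sample_id, ..., replicate = 1L) {
  vals <- c(...)
  data.frame(sample_id = sample_id, assay = names(vals),
             ct = unname(vals), replicate = replicate,
             stringsAsFactors = FALSE)
}

# A profiles data frame (as build_* return) from NKp44-1 fractions; the
# remainder is split equally between NKp44-2 and NKp44-3.
nkp44_profiles_from_fractions <- function(f1, positive = TRUE) {
  data.frame(
    sample_id = sprintf("P%02d", seq_along(f1)),
    receptor = "NKP44",
    positive = rep_len(positive, length(f1)),
    pct_v1 = 100 * f1, pct_v2 = 100 * (1 - f1) / 2,
    pct_v3 = 100 * (1 - f1) / 2,
    stringsAsFactors = FALSE
  )
}

# A profiles data frame from NKp30 (%a, %c) pairs; %b takes the remainder.
nkp30_profiles_from_percents <- function(pa, pc, positive = TRUE) {
  data.frame(
    sample_id = sprintf("P%02d", seq_along(pa)),
    receptor = "NKP30",
    positive = rep_len(positive, length(pa)),
    pct_v1 = pa, pct_v2 = 100 - pa - pc, pct_v3 = pc,
    stringsAsFactors = FALSE
  )
}

# Brute-force two-sided Fisher oracle: enumerate the full support with
# choose() and sum the point probabilities <= the observed one. Kept
# independent of the package's log-space implementation.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  r1 <- a + b; c1 <- a + c_
  denom <- choose(n, c1)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, ks) * choose(n - r1, c1 - ks) / denom
  obs <- probs[ks == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
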