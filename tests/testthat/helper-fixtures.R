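# Shared fixtures, built in code.

# Small raw-measurement cohort with known values.
raw_cohort <- function() {
  data.frame(
    id = 1:6,
    sex = rep(c("male", "female"), 3),
    age = c(30, 45, 52, 28, 61, 39),
    height = c(160, 155, 170, 158, 175, 162),
    weight = c(72, 50, 85, 55, 70, 60),
    wc = c(80, 70, 95, 72, 88, 75),
    hip = c(100, 92, 101, 95, 99, 94),
    sbp = c(140, 118, 152, 110, 128, 119),
    dbp = c(80, 75, 95, 70, 92, 78),
    on_htn_med = c("no", "no", "yes", "no", "no", "yes"),
    stringsAsFactors = FALSE)
}

# Analysis-ready synthetic cohort (both sexes) at a given stratum size.
synth_cohort <- function(n_per_sex = 300, delta = 0.325, seed = 42) {
  generate_cohort(n_per_sex, n_per_sex, delta = delta, seed = seed)
}

# Brute-force AUC: exhaustive concordant / half-tied pair count.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
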