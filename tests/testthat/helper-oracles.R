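# Independent oracles and small fixtures shared across test files.

tiny_volume <- function(seed, dims = c(12, 10, 8)) {
  set.seed(seed)
  array(runif(prod(dims)), dim = dims)
}

# Brute-force NMI: explicit double loop over label values, plug-in entropies,
# arithmetic-mean normalisation. Deliberately element-wise and slow.
nmi_oracle <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  ha <- 0
  for (v in ua) { p <- sum(a == v) / n; ha <- ha - p * log(p) }
  hb <- 0
  for (v in ub) { p <- sum(b == v) / n; hb <- hb - p * log(p) }
  mi <- 0
  for (va in ua) for (vb in ub) {
    pj <- sum(a == va & b == vb) / n
    if (pj > 0) mi <- mi + pj * log(pj / ((sum(a == va) / n) * (sum(b == vb) / n)))
  }
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

# Mann-Whitney pair-counting AUC oracle: U / (n1 * n0), ties count 1/2.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Mean silhouette width of a 2-cluster assignment, computed from first
# principles.
silhouette_mean <- function(xy, cl) {
  d <- as.matrix(dist(xy))
  s <- vapply(seq_len(nrow(xy)), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, cl != cl[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Shared desk-scale cohort for tests that need real volumes but no training.
local_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(scaled_config(
        seed = 11, class_counts = c(AD = 6, MCI = 6, DLB = 6, CN = 6)))
      cache <<- preprocess_cohort(coh, scaled_preprocess_config())
    }
    cache
  }
})
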