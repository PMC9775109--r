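# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the implementation.

tiny_expr <- function(n_genes = 5, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, 1), n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(m)
}

tiny_clinical <- function(n = 20, seed = 1) {
  set.seed(seed)
  clinical_table(sprintf("S%03d", seq_len(n)),
                 time = round(rexp(n, 1 / 40), 2),
                 event = rbinom(n, 1, 0.7))
}

# Kaplan-Meier by naive risk-set recomputation at every distinct event time
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- numeric(length(tt))
  cur <- 1
  for (i in seq_along(tt)) {
    n_i <- sum(time >= tt[i])
    d_i <- sum(time == tt[i] & event == 1)
    cur <- cur * (1 - d_i / n_i)
    s[i] <- cur
  }
  list(event_times = tt, survival = s)
}

# two-group log-rank by explicit hypergeometric sums
logrank_oracle <- function(tA, eA, tB, eB) {
  time <- c(tA, tB); event <- c(eA, eB)
  isA <- rep(c(TRUE, FALSE), c(length(tA), length(tB)))
  tt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    n <- sum(time >= t); nA <- sum(time >= t & isA)
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & isA)
    O <- O + dA
    E <- E + nA * d / n
    if (n > 1) V <- V + d * (n - d) * nA * (n - nA) / (n^2 * (n - 1))
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# AUC by exhaustive pair counting: (concordant + ties/2) / (cases*controls)
auc_oracle <- function(marker, is_case) {
  cs <- marker[is_case]; ct <- marker[!is_case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# set intersection by brute-force membership scan over the universe
intersect_oracle <- function(sets, universe) {
  keep <- vapply(universe, function(g) all(vapply(sets, function(s) g %in% s, logical(1))),
                 logical(1))
  sort(universe[keep])
}

all_anchors_for_test <- function() c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2")
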