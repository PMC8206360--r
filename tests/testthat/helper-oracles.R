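# Independent brute-force oracles. These deliberately avoid the
# package's incremental/cumsum formulations: explicit window
# enumeration, closed-form combinatorics, textbook estimators.

# Exact HWE distribution over heterozygote counts for fixed allele
# counts, via log-factorial closed form:
# P(h) = n! nA! nB! 2^h / ( ((nA-h)/2)! h! ((nB-h)/2)! (2n)! )
oracle_hwe_distribution <- function(n, n_a) {
  n_b <- 2 * n - n_a
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  logp <- lfactorial(n) + lfactorial(n_a) + lfactorial(n_b) +
    hets * log(2) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2) - lfactorial(2 * n)
  list(hets = hets, probs = exp(logp))
}

oracle_hwe_pvalue <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  d <- oracle_hwe_distribution(n, n_a)
  p_obs <- d$probs[match(n_ab, d$hets)]
  min(1, sum(d$probs[d$probs <= p_obs * (1 + 1e-9)]))
}

# Explicit window enumeration for per-SNP homozygosity states.
oracle_window_states <- function(genos, params) {
  n <- length(genos)
  if (n == 0) return(logical(0))
  w <- min(params$window_snps, n)
  nw <- n - w + 1L
  win_hom <- logical(nw)
  for (i in seq_len(nw)) {
    g <- genos[i:(i + w - 1L)]
    win_hom[i] <- sum(!is.na(g) & g == 1L) <= params$max_het_per_window &&
      sum(is.na(g)) <= params$max_missing_per_window
  }
  state <- logical(n)
  for (j in seq_len(n)) {
    cover <- intersect(seq_len(nw), (j - w + 1L):j)
    state[j] <- mean(win_hom[cover]) >= params$window_hom_prop_min
  }
  state
}

# Independent run builder: states -> maximal TRUE runs -> gap split ->
# filters, all with explicit loops.
oracle_detect_roh_vec <- function(genos, pos, params) {
  state <- oracle_window_states(genos, params)
  segs <- list()
  j <- 1L
  n <- length(state)
  while (j <= n) {
    if (!state[j]) { j <- j + 1L; next }
    k <- j
    while (k < n && state[k + 1L]) k <- k + 1L
    # split run [j, k] at gaps
    piece_start <- j
    for (t in j:k) {
      end_piece <- (t == k) ||
        (pos[t + 1L] - pos[t] > params$max_gap_bp)
      if (end_piece) {
        n_snps <- t - piece_start + 1L
        len <- pos[t] - pos[piece_start]
        if (n_snps >= params$min_snps_per_roh &&
            len >= params$min_length_bp &&
            len / n_snps <= params$min_density_bp_per_snp) {
          segs[[length(segs) + 1L]] <- data.frame(
            start_bp = pos[piece_start], end_bp = pos[t],
            n_snps = n_snps, length_bp = as.numeric(len)
          )
        }
        piece_start <- t + 1L
      }
    }
    j <- k + 1L
  }
  if (!length(segs)) {
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = numeric()))
  }
  do.call(rbind, segs)
}

# Multilocus Weir-Cockerham theta (ratio of averages), two or more
# populations, no missing data assumed.
oracle_wc_fst <- function(calls, pops) {
  pops <- factor(pops)
  r <- nlevels(pops)
  ni <- as.numeric(table(pops))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  num <- 0; den <- 0
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    pi <- tapply(x, pops, function(v) mean(v) / 2)
    hi <- tapply(x, pops, function(v) mean(v == 1))
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                  (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}
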