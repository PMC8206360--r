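# Programmatic fixtures shared across test files.

# Dataset from a list of per-sample dosage vectors on one chromosome.
make_chrom_dataset <- function(geno_rows, pos, chrom = 1L,
                               sample_ids = NULL) {
  n <- length(geno_rows)
  m <- length(pos)
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(n))
  calls <- do.call(rbind, geno_rows)
  genotype_dataset(
    samples  = tibble::tibble(sample_id = sample_ids),
    variants = tibble::tibble(
      variant_id = sprintf("v%05d", seq_len(m)),
      chrom = chrom, pos_bp = as.integer(pos),
      allele_a = "A", allele_b = "G"
    ),
    calls = calls
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random sample-chromosome genotype + position fixture that exercises
# homozygous stretches, noise, marginal density and large gaps.
random_roh_fixture <- function(n_snps = 3000) {
  # 2-state segment process: background vs autozygous stretch
  state <- logical(n_snps)
  i <- 1L
  while (i <= n_snps) {
    run <- if (stats::runif(1) < 0.35) {
      sample(20:150, 1)   # autozygous stretch (SNP count)
    } else {
      sample(10:200, 1)   # background
    }
    auto <- stats::runif(1) < 0.35
    j <- min(n_snps, i + run - 1L)
    state[i:j] <- auto
    i <- j + 1L
  }
  g <- integer(n_snps)
  bg <- !state
  g[bg] <- sample(0:2, sum(bg), replace = TRUE,
                  prob = c(0.3, 0.4, 0.3))
  hom <- sample(c(0L, 2L), sum(state), replace = TRUE)
  # sparse het/missing contamination inside stretches
  noise <- stats::runif(sum(state))
  hom[noise < 0.015] <- 1L
  g[state] <- hom
  g[stats::runif(n_snps) < 0.01] <- NA_integer_
  # spacing: mostly 20-60 kb, occasional near-threshold and huge gaps
  gaps <- sample(c(20e3, 40e3, 60e3, 90e3, 520e3, 700e3), n_snps - 1,
                 replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.07, 0.02, 0.01))
  pos <- as.integer(cumsum(c(1e5, gaps)))
  list(genos = g, pos = pos)
}

# Small multi-chromosome dense simulation for ROH-level tests:
# scaled map (~208 Mb over 29 autosomes) at ~96 SNPs/Mb.
dense_sim <- function(n_per_pop = 4, n_snps = 20000, seed = 5) {
  p <- sim_params(
    n_pops = 1, n_per_pop = n_per_pop, n_snps = n_snps, fst = 0,
    chrom_lengths_bp = bta_autosome_lengths() / 12,
    missing_rate = 0, genotype_error_rate = 0, seed = seed
  )
  simulate_subpopulations(p)
}
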