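#' Default quality-control thresholds
#'
#' The standard dense-panel filters: minor allele frequency < 0.01,
#' per-SNP missingness > 0.10, per-individual missingness > 0.10,
#' exact Hardy-Weinberg P < 1e-4.
#'
#' @param maf_min Minimum minor allele frequency to keep a variant.
#' @param snp_missing_max Maximum per-variant missing-call fraction.
#' @param ind_missing_max Maximum per-sample missing-call fraction.
#' @param hwe_p_min Minimum exact Hardy-Weinberg p-value.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, snp_missing_max = 0.10,
                          ind_missing_max = 0.10, hwe_p_min = 1e-4) {
  vals <- c(maf_min, snp_missing_max, ind_missing_max, hwe_p_min)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                 ind_missing_max = ind_missing_max, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Minor allele frequency of a dosage vector
#'
#' @param x Integer dosages in `{0, 1, 2, NA}`.
#' @return `min(p, 1 - p)` where `p` is the allele-b frequency over
#'   non-missing calls; `NA` if every call is missing.
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2))  # 0.375
#' @export
minor_allele_frequency <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided SNP exact test: conditional on the observed allele counts,
#' the probability of each possible heterozygote count is computed from
#' the hypergeometric-form distribution, and the p-value is the sum of
#' the probabilities of all configurations no more likely than the one
#' observed (ties included up to a 1e-9 relative buffer against
#' floating-point misordering).
#'
#' @param n_aa,n_ab,n_bb Non-negative integer genotype counts
#'   (hom allele a, het, hom allele b).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_pvalue(50, 0, 0)   # monomorphic: 1
#' hwe_exact_pvalue(10, 80, 10) # extreme het excess: tiny
#' @export
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0) ||
      any(c(n_aa, n_ab, n_bb) != round(c(n_aa, n_ab, n_bb)))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- n_aa + n_ab + n_bb
  stopifnot(n >= 1)
  rare <- 2 * min(n_aa, n_bb) + n_ab   # minor allele count
  if (rare == 0) return(1)

  # P(het | n, rare) over het = rare, rare-2, ..., via the standard
  # ratio recurrence; normalized at the end.
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  i_obs <- match(n_ab, hets)
  # start from the largest het count with relative weight 1
  probs[length(hets)] <- 1
  if (length(hets) > 1) {
    for (i in rev(seq_len(length(hets) - 1))) {
      h <- hets[i + 1]                 # going from h to h - 2
      hom_r <- (rare - h) / 2          # rare homs at h
      hom_c <- (2 * n - rare - h) / 2  # common homs at h
      probs[i] <- probs[i + 1] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[i_obs] * (1 + 1e-9)]))
}

#' Apply sample and variant quality filters
#'
#' Removal order follows standard practice: samples failing the
#' individual-missingness filter first, then variants failing (in
#' attribution order) call rate, minor allele frequency, and the exact
#' Hardy-Weinberg test. Each removed variant is counted under the first
#' criterion it fails, so the report tallies telescope.
#'
#' @param dataset A `genotype_dataset`.
#' @param thresholds A [qc_thresholds()] list.
#' @return A list with `dataset` (filtered `genotype_dataset`) and
#'   `report` (one-row tibble: n_removed_ind, n_removed_geno,
#'   n_removed_maf, n_removed_hwe, n_samples_retained,
#'   n_variants_retained).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  calls <- dataset$calls
  ind_miss <- rowMeans(is.na(calls))
  keep_ind <- ind_miss <= thresholds$ind_missing_max
  n_removed_ind <- sum(!keep_ind)
  calls <- calls[keep_ind, , drop = FALSE]

  if (nrow(calls) == 0) {
    snp_fail_geno <- rep(FALSE, ncol(calls))
    snp_fail_maf <- rep(TRUE, ncol(calls))
    snp_fail_hwe <- rep(FALSE, ncol(calls))
  } else {
    snp_miss <- colMeans(is.na(calls))
    maf <- apply(calls, 2, minor_allele_frequency)
    n_het <- colSums(calls == 1L, na.rm = TRUE)
    n_bb  <- colSums(calls == 2L, na.rm = TRUE)
    n_aa  <- colSums(calls == 0L, na.rm = TRUE)
    hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
      if (n_aa[j] + n_het[j] + n_bb[j] == 0) return(NA_real_)
      hwe_exact_pvalue(n_aa[j], n_het[j], n_bb[j])
    }, numeric(1))
    snp_fail_geno <- snp_miss > thresholds$snp_missing_max
    snp_fail_maf  <- !snp_fail_geno &
      (is.na(maf) | maf < thresholds$maf_min)
    snp_fail_hwe  <- !snp_fail_geno & !snp_fail_maf &
      !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  }
  keep_var <- !(snp_fail_geno | snp_fail_maf | snp_fail_hwe)

  out <- subset_dataset(dataset, samples = keep_ind, variants = keep_var)
  if (n_samples(out) == 0 || n_variants(out) == 0) {
    warning("QC removed every ",
            if (n_samples(out) == 0) "sample" else "variant")
  }
  report <- tibble::tibble(
    n_removed_ind  = n_removed_ind,
    n_removed_geno = sum(snp_fail_geno),
    n_removed_maf  = sum(snp_fail_maf),
    n_removed_hwe  = sum(snp_fail_hwe),
    n_samples_retained  = n_samples(out),
    n_variants_retained = n_variants(out)
  )
  list(dataset = out, report = report)
}

#' Squared correlation (r2) between two dosage vectors
#'
#' Pearson correlation over pairwise-complete observations, squared.
#' Undefined cases (fewer than two complete pairs, or zero variance)
#' return `NA`; [ld_prune()] treats `NA` as no linkage.
#'
#' @param x,y Equal-length dosage vectors.
#' @return Squared correlation in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Linkage-disequilibrium pruning parameters
#'
#' @param window_snps Window width in SNPs (default 50).
#' @param step_snps Window advance in SNPs (default 5).
#' @param r2_max Maximum tolerated pairwise r2 (default 0.6).
#' @return A list of class `ld_prune_params`.
#' @export
ld_prune_params <- function(window_snps = 50, step_snps = 5, r2_max = 0.6) {
  stopifnot(window_snps > step_snps, step_snps >= 1,
            r2_max > 0, r2_max <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "ld_prune_params")
}

#' Windowed LD pruning
#'
#' Per chromosome, a window of `window_snps` retained SNPs slides by
#' `step_snps`; while any retained pair inside the window has
#' `r2 > r2_max`, the member of the first offending pair with the
#' smaller minor allele frequency is dropped (tie: the one at the later
#' map position). The procedure is deterministic; `seed` is accepted
#' for interface uniformity and unused.
#'
#' @param dataset A `genotype_dataset` (post-QC).
#' @param params An [ld_prune_params()] list.
#' @param seed Unused.
#' @return Character vector of retained `variant_id`s, in map order.
#' @export
ld_prune <- function(dataset, params = ld_prune_params(), seed = NULL) {
  v <- dataset$variants
  calls <- dataset$calls
  maf <- apply(calls, 2, minor_allele_frequency)
  removed <- rep(FALSE, nrow(v))

  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    starts <- seq(1L, max(1L, length(idx)), by = params$step_snps)
    for (s in starts) {
      win <- idx[s:min(s + params$window_snps - 1L, length(idx))]
      win <- win[!removed[win]]
      if (length(win) < 2) next
      r2m <- suppressWarnings(
        stats::cor(calls[, win, drop = FALSE],
                   use = "pairwise.complete.obs")^2
      )
      r2m[!is.finite(r2m)] <- 0
      diag(r2m) <- 0
      repeat {
        off <- which(r2m > params$r2_max, arr.ind = TRUE)
        off <- off[off[, 1] < off[, 2], , drop = FALSE]
        if (nrow(off) == 0) break
        off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
        i <- off[1, 1]; j <- off[1, 2]
        vi <- win[i]; vj <- win[j]
        drop_local <-
          if (is.na(maf[vi]) || is.na(maf[vj])) max(i, j)
          else if (maf[vi] < maf[vj]) i
          else if (maf[vj] < maf[vi]) j
          else max(i, j)  # equal MAF: later map position
        removed[win[drop_local]] <- TRUE
        r2m[drop_local, ] <- 0
        r2m[, drop_local] <- 0
      }
      if (s + params$window_snps - 1L >= length(idx)) break
    }
  }
  v$variant_id[!removed]
}
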