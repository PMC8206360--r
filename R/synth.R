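#' Approximate bovine autosome lengths
#'
#' Physical lengths (bp) of the 29 Bos taurus autosomes, rounded to
#' the nearest 0.1 Mb from the current cattle reference assembly;
#' total ~2.49 Gb. Used as the default simulated map.
#'
#' @return Integer vector of length 29.
#' @export
bta_autosome_lengths <- function() {
  mb <- c(158.5, 136.2, 121.0, 120.8, 120.1, 117.8, 110.7, 113.4,
          105.7, 103.3, 106.9, 87.2, 83.5, 82.4, 85.0, 81.0, 75.2,
          66.0, 64.1, 72.0, 71.6, 61.4, 52.5, 62.7, 42.4, 51.7, 45.6,
          46.3, 51.5)
  as.integer(mb * 1e6)
}

#' Simulation parameters for a synthetic divergent herd
#'
#' Defaults emulate the study design the package targets: five
#' production subgroups (AS, DM, GP, PR, TR) of 200 cows each on the
#' 29 bovine autosomes, with subtle between-subgroup divergence.
#' SNP count defaults to a desk-scale 12,000 (the full ~310K panel is
#' supported but slow); `fst = 0.02` produces the "same breed, mild
#' substructure" regime in which pairwise hold-out assignment lands
#' between chance and ceiling.
#'
#' @param n_pops Number of subpopulations.
#' @param n_per_pop Samples per subpopulation.
#' @param n_snps Total SNPs across the 29 autosomes.
#' @param fst Balding-Nichols divergence parameter in `[0, 0.5]`.
#' @param ancestral_maf_range Range of the uniform ancestral
#'   allele-b frequency.
#' @param chrom_lengths_bp 29 chromosome lengths (bp).
#' @param spacing `"uniform"` (equal spacing) or `"poisson"`
#'   (sorted uniform draws, i.e. conditional Poisson process).
#' @param missing_rate Per-call missing probability in `[0, 0.2]`.
#' @param genotype_error_rate Per-call hom-to-het flip probability in
#'   `[0, 0.2]` (the error mode that breaks ROH).
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pops = 5, n_per_pop = 200, n_snps = 12000,
                       fst = 0.02, ancestral_maf_range = c(0.05, 0.95),
                       chrom_lengths_bp = bta_autosome_lengths(),
                       spacing = c("uniform", "poisson"),
                       missing_rate = 0.01,
                       genotype_error_rate = 0.001, seed = 1L) {
  spacing <- match.arg(spacing)
  stopifnot(fst >= 0, fst <= 0.5,
            missing_rate >= 0, missing_rate <= 0.2,
            genotype_error_rate >= 0, genotype_error_rate <= 0.2,
            length(chrom_lengths_bp) == 29,
            n_pops >= 1, n_per_pop >= 1, n_snps >= length(chrom_lengths_bp))
  structure(list(
    n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
    n_snps = as.integer(n_snps), fst = fst,
    ancestral_maf_range = ancestral_maf_range,
    chrom_lengths_bp = as.numeric(chrom_lengths_bp),
    spacing = spacing, missing_rate = missing_rate,
    genotype_error_rate = genotype_error_rate, seed = as.integer(seed)
  ), class = "sim_params")
}

#' Build a synthetic variant map
#'
#' SNPs are allocated to chromosomes proportionally to their lengths
#' (largest-remainder rounding) and positioned either uniformly or as
#' a sorted uniform draw. Duplicate positions are jittered +1 bp to
#' keep positions strictly increasing.
#'
#' @param params A [sim_params()] list.
#' @return A variant map tibble (`variant_id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`).
#' @export
make_variant_map <- function(params) {
  with_preserved_rng({
    set.seed(params$seed)
    L <- params$chrom_lengths_bp
    quota <- params$n_snps * L / sum(L)
    alloc <- floor(quota)
    rem <- params$n_snps - sum(alloc)
    if (rem > 0) {
      alloc[order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]] <-
        alloc[order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]] + 1
    }
    pieces <- lapply(seq_along(L), function(chr) {
      m <- alloc[chr]
      if (m == 0) return(NULL)
      pos <- if (params$spacing == "uniform") {
        round(seq(1, L[chr], length.out = m + 2L)[-c(1L, m + 2L)])
      } else {
        sort(round(stats::runif(m, 1, L[chr])))
      }
      while (anyDuplicated(pos)) {
        d <- duplicated(pos)
        pos[d] <- pos[d] + 1L
        pos <- sort(pos)
      }
      tibble::tibble(chrom = chr, pos_bp = as.integer(pos))
    })
    map <- dplyr::bind_rows(pieces)
    map$variant_id <- sprintf("snp%d_%d", map$chrom, map$pos_bp)
    nts <- c("A", "C", "G", "T")
    map$allele_a <- sample(nts, nrow(map), replace = TRUE)
    map$allele_b <- unname(vapply(map$allele_a,
                                  function(a) sample(setdiff(nts, a), 1),
                                  character(1)))
    map[, c("variant_id", "chrom", "pos_bp", "allele_a", "allele_b")]
  })
}

#' Simulate divergent subpopulations (Balding-Nichols model)
#'
#' Ancestral allele-b frequencies are drawn uniformly over
#' `ancestral_maf_range`; each subpopulation's frequency is a Beta
#' draw `Beta(p (1-F)/F, (1-p)(1-F)/F)` around the ancestral value
#' with `F = fst` (the degenerate copy at `F = 0`), and genotypes are
#' `Binomial(2, p_pop)` independently per SNP. Sample metadata (herd,
#' sire, birth year, panel density) is generated so cohort-selection
#' code can be exercised; five subpopulations receive the production
#' labels AS, DM, GP, PR, TR.
#'
#' @param params A [sim_params()] list.
#' @return A list with `dataset` (a `genotype_dataset`) and `truth`
#'   (list: `true_pop`, `ancestral_freqs`, `pop_freqs` (SNP x pop
#'   matrix), `injected_tracts` (empty tibble),
#'   `true_autozygous_fraction`).
#' @export
simulate_subpopulations <- function(params = sim_params()) {
  map <- make_variant_map(params)
  with_preserved_rng({
    set.seed(params$seed + 1L)
    m <- nrow(map)
    k <- params$n_pops
    n <- k * params$n_per_pop
    p0 <- stats::runif(m, params$ancestral_maf_range[1],
                       params$ancestral_maf_range[2])
    pk <- if (params$fst == 0) {
      matrix(p0, nrow = m, ncol = k)
    } else {
      a <- p0 * (1 - params$fst) / params$fst
      b <- (1 - p0) * (1 - params$fst) / params$fst
      matrix(stats::rbeta(m * k, rep(a, k), rep(b, k)), nrow = m)
    }
    pop_labels <- if (k == 5) c("AS", "DM", "GP", "PR", "TR")
                  else sprintf("P%02d", seq_len(k))
    true_pop <- rep(pop_labels, each = params$n_per_pop)
    calls <- matrix(0L, nrow = n, ncol = m)
    for (g in seq_len(k)) {
      rows <- which(true_pop == pop_labels[g])
      calls[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 2L, rep(pk[, g], each = length(rows))),
        nrow = length(rows)
      )
    }
    n_herds <- max(1L, round(n / 4.5))
    herd_pool <- sprintf("H%03d", seq_len(n_herds))
    samples <- tibble::tibble(
      sample_id = sprintf("cow%04d", seq_len(n)),
      subgroup = true_pop,
      herd_id = sample(herd_pool, n, replace = TRUE),
      sire_id = sprintf("bull%03d", sample.int(max(2L, round(n / 2.5)),
                                               n, replace = TRUE)),
      birth_year = sample(2014:2018, n, replace = TRUE),
      panel_density = sample(c(54609L, 76883L, 138892L), n,
                             replace = TRUE, prob = c(0.5, 0.3, 0.2))
    )
    dataset <- genotype_dataset(samples, map, calls)
    dataset <- perturb(dataset, params$missing_rate,
                       params$genotype_error_rate,
                       seed = params$seed + 2L)
    truth <- list(
      true_pop = stats::setNames(true_pop, samples$sample_id),
      ancestral_freqs = stats::setNames(p0, map$variant_id),
      pop_freqs = `dimnames<-`(pk, list(map$variant_id, pop_labels)),
      injected_tracts = tibble::tibble(sample_id = character(),
                                       chrom = integer(),
                                       start_bp = numeric(),
                                       end_bp = numeric()),
      true_autozygous_fraction =
        stats::setNames(rep(0, n), samples$sample_id)
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Inject autozygous tracts into one sample
#'
#' Places non-overlapping tracts uniformly over the genome until the
#' summed length reaches `target_fraction` of the map-covered length
#' (the same denominator [froh()] uses). Tract lengths are
#' exponential with mean `mean_tract_mb` above a floor of
#' `min_tract_mb` (shifted exponential, so the mean is preserved and
#' every tract is long enough to be callable); the last tract is
#' truncated so the realized fraction matches the target. Every SNP
#' inside a tract is made homozygous by doubling one allele drawn
#' from the sample's subpopulation allele frequency, preserving
#' frequency structure inside runs.
#'
#' @param dataset A `genotype_dataset`.
#' @param sample_id Sample to modify.
#' @param target_fraction Autozygous genome fraction in `[0, 0.5]`.
#' @param mean_tract_mb Mean tract length, Mb (default 2.11).
#' @param min_tract_mb Minimum tract length, Mb (default 1, the
#'   shortest run the standard detector parameters can call).
#' @param seed Integer seed.
#' @param freqs Optional per-variant allele-b frequency used for the
#'   doubled allele; default: estimated from the sample's subgroup
#'   members (or all samples if no subgroup column).
#' @return A list with `dataset` (modified) and `tracts` (tibble
#'   `chrom`, `start_bp`, `end_bp`, `length_bp`).
#' @export
inject_autozygosity <- function(dataset, sample_id, target_fraction,
                                mean_tract_mb = 2.11, min_tract_mb = 1,
                                seed = 1L, freqs = NULL) {
  stopifnot(target_fraction >= 0, target_fraction <= 0.5,
            mean_tract_mb > min_tract_mb, min_tract_mb > 0)
  empty_tracts <- tibble::tibble(chrom = integer(), start_bp = numeric(),
                                 end_bp = numeric(), length_bp = numeric())
  if (target_fraction == 0) {
    return(list(dataset = dataset, tracts = empty_tracts))
  }
  v <- dataset$variants
  row_i <- match(sample_id, dataset$samples$sample_id)
  if (is.na(row_i)) stop("unknown sample_id: ", sample_id)
  span <- dplyr::summarise(
    dplyr::group_by(v, .data$chrom),
    lo = min(.data$pos_bp), hi = max(.data$pos_bp), .groups = "drop"
  )
  span$L <- as.numeric(span$hi) - as.numeric(span$lo)
  l_total <- sum(span$L)
  if (is.null(freqs)) {
    rows <- if ("subgroup" %in% names(dataset$samples)) {
      which(dataset$samples$subgroup ==
              dataset$samples$subgroup[row_i])
    } else {
      seq_len(nrow(dataset$samples))
    }
    freqs <- colMeans(dataset$calls[rows, , drop = FALSE],
                      na.rm = TRUE) / 2
    freqs[is.na(freqs)] <- 0.5
  }
  with_preserved_rng({
    set.seed(seed)
    tracts <- list()
    total <- 0
    fails <- 0L
    min_bp <- min_tract_mb * 1e6
    goal <- target_fraction * l_total
    while (total < goal) {
      if (goal - total < min_bp / 2) break  # closer to stop than overshoot
      chr_i <- sample.int(nrow(span), 1, prob = span$L)
      len <- min_bp +
        stats::rexp(1, rate = 1 / ((mean_tract_mb - min_tract_mb) * 1e6))
      # truncate the last tract toward the target (floor permitting)
      if (total + len > goal) len <- max(min_bp, goal - total)
      start <- stats::runif(1, span$lo[chr_i], span$hi[chr_i])
      end <- min(start + len, span$hi[chr_i])
      overlap <- any(vapply(tracts, function(t) {
        t$chrom == span$chrom[chr_i] && start <= t$end_bp &&
          end >= t$start_bp
      }, logical(1)))
      if (overlap || end - start < min_bp) {
        fails <- fails + 1L
        if (fails >= 1000L) {
          stop("could not place non-overlapping tracts; ",
               "try a smaller target_fraction")
        }
        next
      }
      tracts[[length(tracts) + 1L]] <-
        list(chrom = span$chrom[chr_i], start_bp = start, end_bp = end)
      total <- total + (end - start)
    }
    calls <- dataset$calls
    for (t in tracts) {
      idx <- which(v$chrom == t$chrom & v$pos_bp >= t$start_bp &
                     v$pos_bp <= t$end_bp)
      if (!length(idx)) next
      hom_b <- stats::rbinom(length(idx), 1L, freqs[idx])
      calls[row_i, idx] <- 2L * hom_b
    }
    tr <- dplyr::bind_rows(lapply(tracts, tibble::as_tibble))
    tr$length_bp <- tr$end_bp - tr$start_bp
    tr <- dplyr::arrange(tr, .data$chrom, .data$start_bp)
    list(dataset = genotype_dataset(dataset$samples, v, calls),
         tracts = tr)
  })
}

#' Add missingness and genotyping error
#'
#' Each call is independently set missing with probability
#' `missing_rate`; surviving homozygous calls flip to heterozygous
#' with probability `genotype_error_rate` (the error mode that
#' interrupts homozygous runs).
#'
#' @param dataset A `genotype_dataset`.
#' @param missing_rate,genotype_error_rate Probabilities in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return A perturbed `genotype_dataset`.
#' @export
perturb <- function(dataset, missing_rate = 0,
                    genotype_error_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 0.2,
            genotype_error_rate >= 0, genotype_error_rate <= 0.2)
  if (missing_rate == 0 && genotype_error_rate == 0) return(dataset)
  with_preserved_rng({
    set.seed(seed)
    calls <- dataset$calls
    nm <- length(calls)
    if (missing_rate > 0) {
      calls[stats::runif(nm) < missing_rate] <- NA_integer_
    }
    if (genotype_error_rate > 0) {
      hom <- !is.na(calls) & calls != 1L
      flip <- hom & stats::runif(nm) < genotype_error_rate
      calls[flip] <- 1L
    }
    genotype_dataset(dataset$samples, dataset$variants, calls)
  })
}
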