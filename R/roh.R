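#' Sliding-window ROH detection parameters
#'
#' Defaults follow the dense-panel convention for Holstein data: a
#' scanning window of 40 SNPs allowing at most one heterozygote and one
#' missing call, SNP-level homozygosity when at least 5% of overlapping
#' windows are homozygous, and run filters of >= 40 SNPs, >= 1 Mb
#' length, at most one SNP per 50 kb of span, and a 500 kb maximum gap
#' between consecutive SNPs.
#'
#' @param window_snps Scanning-window width in SNPs.
#' @param max_het_per_window Maximum heterozygous calls per window.
#' @param max_missing_per_window Maximum missing calls per window.
#' @param window_hom_prop_min Minimum fraction of overlapping windows
#'   that must be homozygous for a SNP to be in a run.
#' @param min_snps_per_roh Minimum SNPs per emitted run.
#' @param min_length_bp Minimum run length (bp).
#' @param min_density_bp_per_snp Maximum bp of span per SNP in a run.
#' @param max_gap_bp Maximum gap (bp) between consecutive SNPs in a run.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 40, max_het_per_window = 1,
                       max_missing_per_window = 1,
                       window_hom_prop_min = 0.05,
                       min_snps_per_roh = 40, min_length_bp = 1e6,
                       min_density_bp_per_snp = 5e4, max_gap_bp = 5e5) {
  stopifnot(window_snps >= 1, min_snps_per_roh >= 1, min_length_bp >= 1,
            min_density_bp_per_snp > 0, max_gap_bp > 0,
            window_hom_prop_min >= 0, window_hom_prop_min <= 1)
  structure(list(
    window_snps = as.integer(window_snps),
    max_het_per_window = as.integer(max_het_per_window),
    max_missing_per_window = as.integer(max_missing_per_window),
    window_hom_prop_min = window_hom_prop_min,
    min_snps_per_roh = as.integer(min_snps_per_roh),
    min_length_bp = min_length_bp,
    min_density_bp_per_snp = min_density_bp_per_snp,
    max_gap_bp = max_gap_bp
  ), class = "roh_params")
}

#' Per-SNP homozygosity states from the scanning window
#'
#' Every contiguous window of `window_snps` SNPs is homozygous iff it
#' holds at most `max_het_per_window` heterozygotes and at most
#' `max_missing_per_window` missing calls. A SNP's state is `TRUE` iff
#' the fraction of existing overlapping windows that are homozygous is
#' at least `window_hom_prop_min` (edge SNPs use only the windows that
#' exist; no padding). A chromosome shorter than the window collapses
#' to a single truncated window.
#'
#' @param genos Dosage vector for one sample on one chromosome, in map
#'   order.
#' @param params A [roh_params()] list.
#' @return Logical vector, one state per SNP.
#' @export
window_homozygosity_states <- function(genos, params = roh_params()) {
  n <- length(genos)
  if (n == 0) return(logical(0))
  w <- min(params$window_snps, n)
  het  <- as.integer(!is.na(genos) & genos == 1L)
  miss <- as.integer(is.na(genos))
  nw <- n - w + 1L
  cs_het  <- c(0L, cumsum(het))
  cs_miss <- c(0L, cumsum(miss))
  win_het  <- cs_het[(1:nw) + w] - cs_het[1:nw]
  win_miss <- cs_miss[(1:nw) + w] - cs_miss[1:nw]
  win_hom <- win_het <= params$max_het_per_window &
    win_miss <= params$max_missing_per_window
  cs_hom <- c(0L, cumsum(as.integer(win_hom)))
  first <- pmax(1L, (1:n) - w + 1L)
  last  <- pmin(1:n, nw)
  n_win <- last - first + 1L
  n_hom <- cs_hom[last + 1L] - cs_hom[first]
  n_hom / n_win >= params$window_hom_prop_min
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH calling for every sample in a dataset. Candidate
#' runs are maximal stretches of state-`TRUE` SNPs (see
#' [window_homozygosity_states()]); a run is split wherever the gap
#' between consecutive SNPs exceeds `max_gap_bp`, and each piece is
#' then required to hold at least `min_snps_per_roh` SNPs, span at
#' least `min_length_bp`, and satisfy the density bound
#' `length_bp / n_snps <= min_density_bp_per_snp`. Run length is
#' `end_bp - start_bp` (positions of the last and first SNP).
#'
#' @param dataset A `genotype_dataset` (post-QC, unpruned).
#' @param params A [roh_params()] list.
#' @param samples Optional subset of sample ids.
#' @return A tibble of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`; position-sorted and
#'   non-overlapping within a sample x chromosome.
#' @export
detect_roh <- function(dataset, params = roh_params(), samples = NULL) {
  sample_ids <- samples %||% dataset$samples$sample_id
  v <- dataset$variants
  chrom_idx <- split(seq_len(nrow(v)), v$chrom)

  res <- vector("list", length(sample_ids) * length(chrom_idx))
  k <- 0L
  for (sid in sample_ids) {
    row <- dataset$calls[match(sid, dataset$samples$sample_id), ]
    for (chr in names(chrom_idx)) {
      idx <- chrom_idx[[chr]]
      seg <- roh_runs_one(row[idx], v$pos_bp[idx], params)
      if (nrow(seg)) {
        seg$sample_id <- sid
        seg$chrom <- as.integer(chr)
        k <- k + 1L
        res[[k]] <- seg
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(sample_id = character(), chrom = integer(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_bp = numeric()))
  }
  out <- dplyr::bind_rows(res[seq_len(k)])
  out <- dplyr::arrange(out, .data$sample_id, .data$chrom, .data$start_bp)
  tibble::as_tibble(out[, c("sample_id", "chrom", "start_bp", "end_bp",
                            "n_snps", "length_bp")])
}

roh_runs_one <- function(genos, pos, params) {
  state <- window_homozygosity_states(genos, params)
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = numeric())
  if (!any(state)) return(empty)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  pieces <- list()
  for (i in which(keep)) {
    a <- starts[i]; b <- ends[i]
    # split at gaps > max_gap_bp
    if (b > a) {
      gaps <- diff(pos[a:b])
      cut_after <- which(gaps > params$max_gap_bp)
      bounds <- c(a - 1L, a - 1L + cut_after, b)
    } else {
      bounds <- c(a - 1L, b)
    }
    for (p in seq_len(length(bounds) - 1L)) {
      s <- bounds[p] + 1L; e <- bounds[p + 1L]
      n_snps <- e - s + 1L
      len <- as.numeric(pos[e]) - as.numeric(pos[s])
      if (n_snps >= params$min_snps_per_roh &&
          len >= params$min_length_bp &&
          len / n_snps <= params$min_density_bp_per_snp) {
        pieces[[length(pieces) + 1L]] <-
          data.frame(start_bp = pos[s], end_bp = pos[e],
                     n_snps = n_snps, length_bp = len)
      }
    }
  }
  if (!length(pieces)) return(empty)
  do.call(rbind, pieces)
}

#' Bin ROH lengths into the five standard classes
#'
#' Left-closed, right-open bins in Mb: \[1,2), \[2,4), \[4,8), \[8,16),
#' \[16, Inf).
#'
#' @param segments Tibble from [detect_roh()] (or any frame with a
#'   `length_bp` column, all >= 1 Mb).
#' @return The input with a `length_class` factor column added
#'   (levels `1-2`, `2-4`, `4-8`, `8-16`, `>16` Mb).
#' @export
classify_roh_lengths <- function(segments) {
  if (nrow(segments) && any(segments$length_bp < 1e6)) {
    stop("ROH lengths below 1 Mb violate the detector contract")
  }
  brk <- c(1, 2, 4, 8, 16, Inf) * 1e6
  lab <- c("1-2", "2-4", "4-8", "8-16", ">16")
  segments$length_class <- cut(segments$length_bp, breaks = brk,
                               labels = lab, right = FALSE)
  segments
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Per sample, the summed ROH length divided by the map-covered
#' autosome length `L_total` = sum over chromosomes of (last SNP
#' position - first SNP position). Samples with no detected ROH score
#' zero.
#'
#' @param segments Tibble from [detect_roh()].
#' @param variants Variant map tibble (`chrom`, `pos_bp`) covering all
#'   chromosomes referenced by `segments`.
#' @param sample_ids Samples to report (default: those present in
#'   `segments`); include the full cohort to score ROH-free animals.
#' @param by_chrom If `TRUE`, return per-chromosome values (long form).
#' @return A tibble `sample_id`, `froh` or, with `by_chrom = TRUE`,
#'   `sample_id`, `chrom`, `froh`.
#' @export
froh <- function(segments, variants, sample_ids = NULL, by_chrom = FALSE) {
  span <- dplyr::summarise(
    dplyr::group_by(variants, .data$chrom),
    L = as.numeric(max(.data$pos_bp)) - as.numeric(min(.data$pos_bp)),
    .groups = "drop"
  )
  if (nrow(segments) && !all(segments$chrom %in% span$chrom)) {
    stop("segment chromosome absent from the variant map")
  }
  sample_ids <- sample_ids %||% unique(segments$sample_id)
  if (by_chrom) {
    grid <- tidyr::expand_grid(sample_id = sample_ids, chrom = span$chrom)
    cov <- dplyr::summarise(
      dplyr::group_by(segments, .data$sample_id, .data$chrom),
      bp = sum(.data$length_bp), .groups = "drop"
    )
    out <- dplyr::left_join(grid, cov, by = c("sample_id", "chrom"))
    out <- dplyr::left_join(out, span, by = "chrom")
    out$froh <- dplyr::coalesce(out$bp, 0) / out$L
    return(dplyr::select(out, "sample_id", "chrom", "froh"))
  }
  l_total <- sum(span$L)
  cov <- dplyr::summarise(
    dplyr::group_by(segments, .data$sample_id),
    bp = sum(.data$length_bp), .groups = "drop"
  )
  out <- tibble::tibble(sample_id = sample_ids)
  out <- dplyr::left_join(out, cov, by = "sample_id")
  out$froh <- dplyr::coalesce(out$bp, 0) / l_total
  dplyr::select(out, "sample_id", "froh")
}

#' Consensus shared-homozygosity regions
#'
#' Within each subgroup, the genome is decomposed at SNP positions into
#' elementary intervals; an interval's support is the fraction of the
#' subgroup's individuals whose ROH cover it. Maximal runs of intervals
#' with support strictly greater than `support_min` are emitted, with
#' endpoints snapped to SNP positions. Regions with identical
#' coordinates across subgroups are merged into one record listing all
#' supporting subgroups.
#'
#' @param segments Tibble from [detect_roh()].
#' @param variants Variant map tibble (`chrom`, `pos_bp`).
#' @param subgroups Named vector or two-column frame mapping
#'   `sample_id` to subgroup label. Membership defines each subgroup's
#'   denominator, so ROH-free individuals count.
#' @param support_min Support threshold; strictly-greater rule
#'   (default 0.30, i.e. "more than 30%").
#' @return Tibble `subgroup_set` (comma-joined labels), `chrom`,
#'   `start_bp`, `end_bp`, `length_bp`, `support` (minimum interval
#'   support across the region, per subgroup then minimum over merged
#'   subgroups).
#' @export
consensus_regions <- function(segments, variants, subgroups,
                              support_min = 0.30) {
  if (is.data.frame(subgroups)) {
    sg <- stats::setNames(as.character(subgroups[[2]]),
                          as.character(subgroups[[1]]))
  } else {
    sg <- subgroups
  }
  out <- list()
  for (grp in sort(unique(sg))) {
    members <- names(sg)[sg == grp]
    n_g <- length(members)
    seg_g <- segments[segments$sample_id %in% members, , drop = FALSE]
    if (!nrow(seg_g)) next
    for (chr in sort(unique(seg_g$chrom))) {
      pos <- sort(unique(variants$pos_bp[variants$chrom == chr]))
      if (length(pos) < 2) next
      s_c <- seg_g[seg_g$chrom == chr, , drop = FALSE]
      # elementary interval k = [pos[k], pos[k+1]]; a ROH covers it iff
      # start <= pos[k] and end >= pos[k+1]
      delta <- numeric(length(pos))
      i0 <- findInterval(s_c$start_bp, pos)
      i1 <- findInterval(s_c$end_bp, pos) - 1L
      ok <- i1 >= i0 & i0 >= 1L
      for (r in which(ok)) {
        delta[i0[r]] <- delta[i0[r]] + 1
        if (i1[r] + 1L <= length(pos)) {
          delta[i1[r] + 1L] <- delta[i1[r] + 1L] - 1
        }
      }
      supp <- cumsum(delta)[seq_len(length(pos) - 1L)] / n_g
      hit <- supp > support_min
      if (!any(hit)) next
      r <- rle(hit)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        a <- starts[i]; b <- ends[i]
        out[[length(out) + 1L]] <- tibble::tibble(
          subgroup = grp, chrom = chr,
          start_bp = pos[a], end_bp = pos[b + 1L],
          support = min(supp[a:b])
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(subgroup_set = character(), chrom = integer(),
                          start_bp = integer(), end_bp = integer(),
                          length_bp = numeric(), support = numeric()))
  }
  regions <- dplyr::bind_rows(out)
  merged <- dplyr::summarise(
    dplyr::group_by(regions, .data$chrom, .data$start_bp, .data$end_bp),
    subgroup_set = paste(sort(unique(.data$subgroup)), collapse = ","),
    support = min(.data$support),
    .groups = "drop"
  )
  merged$length_bp <- as.numeric(merged$end_bp) - as.numeric(merged$start_bp)
  merged <- dplyr::arrange(merged, .data$chrom, .data$start_bp)
  dplyr::select(merged, "subgroup_set", "chrom", "start_bp", "end_bp",
                "length_bp", "support")
}

#' Per-subgroup ROH summaries by length class
#'
#' Mean number of runs per individual in each length class (and
#' overall). Individuals with zero runs stay in the denominator.
#'
#' @param segments Tibble from [detect_roh()].
#' @param subgroups Named vector or two-column frame mapping
#'   `sample_id` to subgroup (defines subgroup sizes).
#' @return Tibble `subgroup`, `length_class`, `n_roh`,
#'   `mean_per_individual`; class `"all"` rows give the overall mean
#'   run count per individual.
#' @export
roh_summary <- function(segments, subgroups) {
  if (is.data.frame(subgroups)) {
    sg <- stats::setNames(as.character(subgroups[[2]]),
                          as.character(subgroups[[1]]))
  } else {
    sg <- subgroups
  }
  sizes <- table(sg)
  segments <- classify_roh_lengths(segments)
  segments$subgroup <- unname(sg[segments$sample_id])
  grid <- tidyr::expand_grid(
    subgroup = names(sizes),
    length_class = c(levels(segments$length_class), "all")
  )
  counts <- dplyr::count(segments, .data$subgroup,
                         length_class = as.character(.data$length_class),
                         name = "n_roh")
  totals <- dplyr::count(segments, .data$subgroup, name = "n_roh")
  totals$length_class <- "all"
  counts <- dplyr::bind_rows(counts, totals)
  out <- dplyr::left_join(grid, counts, by = c("subgroup", "length_class"))
  out$n_roh <- dplyr::coalesce(out$n_roh, 0L)
  out$mean_per_individual <- out$n_roh / as.numeric(sizes[out$subgroup])
  tibble::as_tibble(out)
}
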