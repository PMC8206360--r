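#' Cohort-selection filters
#'
#' The four-step sampling design for a balanced within-breed cohort:
#' (1) a defined production subgroup, (2) an original genotyping panel
#' of at least `min_panel_density` SNPs (imputation accuracy), (3)
#' birth year inside `birth_year_range` (one generation interval),
#' (4) herd-year cells with fewer than `min_genotyped_per_herd_year`
#' genotyped cows dropped, then at most `max_per_herd_subgroup`
#' animals per herd within subgroup, and finally a seeded random draw
#' of `n_target_per_subgroup` animals per subgroup.
#'
#' @param allowed_subgroups Labels admitted at Filter 1.
#' @param min_panel_density Minimum original-chip SNP count.
#' @param birth_year_range Two-element inclusive year range.
#' @param min_genotyped_per_herd_year Minimum genotyped cows per
#'   herd-year cell.
#' @param max_per_herd_subgroup Cap per herd within subgroup.
#' @param n_target_per_subgroup Final per-subgroup sample size.
#' @param seed Integer seed for the random cap and draw.
#' @return A list of class `cohort_filters`.
#' @export
cohort_filters <- function(allowed_subgroups = c("AS", "DM", "GP", "PR", "TR"),
                           min_panel_density = 50000,
                           birth_year_range = c(2014, 2018),
                           min_genotyped_per_herd_year = 10,
                           max_per_herd_subgroup = 10,
                           n_target_per_subgroup = 200,
                           seed = 1L) {
  stopifnot(min_panel_density > 0, min_genotyped_per_herd_year > 0,
            max_per_herd_subgroup > 0, n_target_per_subgroup > 0,
            birth_year_range[1] <= birth_year_range[2])
  structure(list(
    allowed_subgroups = allowed_subgroups,
    min_panel_density = min_panel_density,
    birth_year_range = birth_year_range,
    min_genotyped_per_herd_year = min_genotyped_per_herd_year,
    max_per_herd_subgroup = max_per_herd_subgroup,
    n_target_per_subgroup = n_target_per_subgroup,
    seed = as.integer(seed)
  ), class = "cohort_filters")
}

#' Select a balanced cohort from sample metadata
#'
#' Applies the four filters of [cohort_filters()] in order, then draws
#' `n_target_per_subgroup` animals per subgroup with the given seed.
#' A subgroup left with fewer survivors than the target keeps them all
#' with a warning. Attrition is reported per filter and telescopes:
#' each filter's input is the previous filter's output.
#'
#' @param metadata Data frame with `sample_id`, `subgroup`,
#'   `panel_density`, `birth_year`, `herd_id`.
#' @param filters A [cohort_filters()] list.
#' @return A list with `sample_ids` (selected, in metadata order) and
#'   `attrition` (tibble `step`, `n_after`, per subgroup and overall).
#' @export
select_cohort <- function(metadata, filters = cohort_filters()) {
  md <- tibble::as_tibble(metadata)
  stopifnot(all(c("sample_id", "subgroup", "panel_density",
                  "birth_year", "herd_id") %in% names(md)))
  steps <- list()
  note <- function(step, d) {
    cnt <- dplyr::count(d, .data$subgroup, name = "n_after")
    cnt$step <- step
    steps[[length(steps) + 1L]] <<- cnt
  }
  d <- md[!is.na(md$subgroup) &
            md$subgroup %in% filters$allowed_subgroups, ]
  note("filter1_subgroup", d)
  d <- d[!is.na(d$panel_density) &
           d$panel_density >= filters$min_panel_density, ]
  note("filter2_panel", d)
  d <- d[!is.na(d$birth_year) &
           d$birth_year >= filters$birth_year_range[1] &
           d$birth_year <= filters$birth_year_range[2], ]
  note("filter3_birth_year", d)

  hy <- dplyr::add_count(d, .data$herd_id, .data$birth_year,
                         name = "herd_year_n")
  d <- hy[hy$herd_year_n >= filters$min_genotyped_per_herd_year, ]
  d$herd_year_n <- NULL
  with_preserved_rng({
    set.seed(filters$seed)
    d <- dplyr::slice_sample(
      dplyr::group_by(d, .data$herd_id, .data$subgroup),
      n = filters$max_per_herd_subgroup
    )
    d <- dplyr::ungroup(d)
    note("filter4_herd", d)

    short <- dplyr::count(d, .data$subgroup)
    short <- short$subgroup[short$n < filters$n_target_per_subgroup]
    if (length(short)) {
      warning("subgroup(s) below target size, keeping all: ",
              paste(short, collapse = ", "))
    }
    d <- dplyr::slice_sample(
      dplyr::group_by(d, .data$subgroup),
      n = filters$n_target_per_subgroup
    )
    d <- dplyr::ungroup(d)
  })
  note("final_draw", d)
  attrition <- dplyr::bind_rows(steps)
  attrition <- tidyr::pivot_wider(attrition, names_from = "subgroup",
                                  values_from = "n_after",
                                  values_fill = 0L)
  attrition$total <- rowSums(attrition[, -1, drop = FALSE])
  list(
    sample_ids = md$sample_id[md$sample_id %in% d$sample_id],
    attrition = attrition
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within
#' decomposition via [stats::aov()]), returned as a one-row tibble.
#'
#' @param values Numeric response (e.g. per-sample F_ROH).
#' @param groups Group label per value.
#' @return Tibble `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  if (!is.finite(f)) stop("F statistic undefined (zero variance)")
  tibble::tibble(
    f_stat = f,
    df_between = as.integer(tab[["Df"]][1]),
    df_within = as.integer(tab[["Df"]][2]),
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Descriptive cohort statistics
#'
#' Per-subgroup sire counts plus the headline cohort summaries: mean
#' sires per subgroup (rounded), population-formula SD of the
#' per-subgroup sire counts (rounded), animals per herd (total /
#' distinct herds, 2 decimals), cows per sire, and the fraction of
#' sires used in more than one subgroup.
#'
#' @param metadata Data frame with `sample_id`, `subgroup`, `herd_id`,
#'   `sire_id` (the selected cohort).
#' @return A list with `by_subgroup` (tibble `subgroup`, `n_animals`,
#'   `n_sires`) and `overall` (one-row tibble `n_animals`, `n_herds`,
#'   `n_sires`, `mean_sires_per_subgroup`, `sd_sires_per_subgroup`,
#'   `animals_per_herd`, `cows_per_sire`,
#'   `frac_sires_multi_subgroup`).
#' @export
descriptive_report <- function(metadata) {
  md <- tibble::as_tibble(metadata)
  by_subgroup <- dplyr::summarise(
    dplyr::group_by(md, .data$subgroup),
    n_animals = dplyr::n(),
    n_sires = dplyr::n_distinct(.data$sire_id),
    .groups = "drop"
  )
  sire_counts <- by_subgroup$n_sires
  pop_sd <- sqrt(mean((sire_counts - mean(sire_counts))^2))
  sire_spread <- dplyr::summarise(
    dplyr::group_by(md, .data$sire_id),
    k = dplyr::n_distinct(.data$subgroup), .groups = "drop"
  )
  overall <- tibble::tibble(
    n_animals = nrow(md),
    n_herds = dplyr::n_distinct(md$herd_id),
    n_sires = dplyr::n_distinct(md$sire_id),
    mean_sires_per_subgroup = round(mean(sire_counts)),
    sd_sires_per_subgroup = round(pop_sd),
    animals_per_herd = round(nrow(md) / dplyr::n_distinct(md$herd_id), 2),
    cows_per_sire = nrow(md) / dplyr::n_distinct(md$sire_id),
    frac_sires_multi_subgroup = mean(sire_spread$k > 1)
  )
  list(by_subgroup = by_subgroup, overall = overall)
}

#' Run the full divergence pipeline
#'
#' Orchestrates QC, the ROH branch (detection, length classes, F_ROH,
#' one-way ANOVA of F_ROH on subgroup, consensus regions) on the full
#' post-QC panel, and the structure branch (LD pruning, PCA, K-means
#' BIC scan, DAPC with reassignment accuracy) on the pruned panel.
#' All tables are written as TSV (JSON for scalars) under `out_dir`
#' together with a run log recording the seed and package version.
#'
#' @param dataset A `genotype_dataset` with a `subgroup` metadata
#'   column (e.g. from [simulate_subpopulations()] or
#'   [read_plink_binary()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param filters Optional [cohort_filters()]; when supplied the cohort
#'   is selected from the sample metadata first and the attrition table
#'   is written alongside the other artifacts.
#' @param qc [qc_thresholds()].
#' @param prune [ld_prune_params()].
#' @param roh [roh_params()].
#' @param k_max BIC scan upper bound.
#' @param n_pcs PCs retained for the DAPC classification step.
#' @param n_pcs_scan PCs the K-means/BIC cluster scan runs on. The
#'   spherical BIC over-splits in low dimension (a chance split of n
#'   points profits when `2n/(pi d) > log n`), so the default retains
#'   `max(50, 0.4 n)` components, capped at the rank; see the methods
#'   vignette.
#' @param n_starts K-means starts per K.
#' @param consensus_support Consensus-region support threshold.
#' @return Invisibly, a list with every intermediate result
#'   (`qc_report`, `segments`, `froh`, `froh_anova`, `consensus`,
#'   `roh_summary`, `pruned_ids`, `bic`, `dapc`, `assignment`,
#'   `accuracy`, `files`).
#' @export
run_pipeline <- function(dataset, out_dir, seed = 1L, filters = NULL,
                         qc = qc_thresholds(),
                         prune = ld_prune_params(),
                         roh = roh_params(),
                         k_max = 20, n_pcs = 10, n_pcs_scan = NULL,
                         n_starts = 10, consensus_support = 0.30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot("subgroup" %in% names(dataset$samples))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  attrition <- NULL
  if (!is.null(filters)) {
    sel <- stage("cohort", select_cohort(dataset$samples, filters))
    dataset <- subset_dataset(dataset, samples = sel$sample_ids)
    attrition <- sel$attrition
  }

  qcres <- stage("qc", apply_qc(dataset, qc))
  ds <- qcres$dataset
  sg <- stats::setNames(ds$samples$subgroup, ds$samples$sample_id)

  segments <- stage("roh", detect_roh(ds, roh))
  segments <- classify_roh_lengths(segments)
  fr <- froh(segments, ds$variants, sample_ids = ds$samples$sample_id)
  fr$subgroup <- unname(sg[fr$sample_id])
  # degenerate F_ROH (e.g. no callable ROH at sparse desk-scale maps)
  # yields an NA record rather than aborting the whole run
  fr_anova <- tryCatch(
    anova_oneway(fr$froh, fr$subgroup),
    error = function(e) {
      warning("F_ROH ANOVA not computable: ", conditionMessage(e))
      tibble::tibble(f_stat = NA_real_, df_between = NA_integer_,
                     df_within = NA_integer_, p_value = NA_real_)
    }
  )
  cons <- stage("consensus",
                consensus_regions(segments, ds$variants, sg,
                                  support_min = consensus_support))
  summ <- roh_summary(segments, sg)

  pruned <- stage("ld_prune", ld_prune(ds, prune))
  ds_pruned <- subset_dataset(ds, variants = pruned)
  ctr <- stage("center", center_matrix(ds_pruned))
  n_kept <- nrow(ctr$X)
  p_scan <- n_pcs_scan %||% max(50L, round(0.4 * n_kept))
  p_scan <- min(p_scan, n_kept - 1L, ncol(ctr$X))
  p_use <- min(n_pcs, n_kept - 1L, ncol(ctr$X))
  basis <- stage("pca", pca(ctr, max(p_use, p_scan)))
  bic <- stage("bic", kmeans_bic_scan(
    basis$scores[, seq_len(p_scan), drop = FALSE],
    k_max = min(k_max, n_samples(ds) - 1L),
    n_starts = n_starts, seed = seed))
  fit <- stage("dapc", dapc_fit(basis$scores[, seq_len(p_use), drop = FALSE],
                                ds$samples$subgroup, n_pcs = p_use,
                                basis = basis))
  assign_res <- dapc_predict(fit, basis$scores[, seq_len(p_use), drop = FALSE])
  acc <- reassignment_accuracy(assign_res, ds$samples$subgroup)

  files <- c(
    qc_report = "qc_report.tsv", segments = "roh_segments.tsv",
    froh = "froh.tsv", froh_anova = "froh_anova.tsv",
    consensus = "consensus_regions.tsv", roh_summary = "roh_summary.tsv",
    pruned = "pruned_variants.txt", bic = "bic_scan.tsv",
    posterior = "dapc_posterior.tsv", accuracy = "accuracy.json",
    log = "run_log.txt"
  )
  if (!is.null(attrition)) files <- c(files, attrition = "cohort_attrition.tsv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  if (!is.null(attrition)) readr::write_tsv(attrition, paths["attrition"])
  readr::write_tsv(qcres$report, paths["qc_report"])
  readr::write_tsv(segments, paths["segments"])
  readr::write_tsv(fr, paths["froh"])
  readr::write_tsv(fr_anova, paths["froh_anova"])
  readr::write_tsv(cons, paths["consensus"])
  readr::write_tsv(summ, paths["roh_summary"])
  writeLines(pruned, paths["pruned"])
  readr::write_tsv(tidy(bic), paths["bic"])
  post <- tibble::as_tibble(as.data.frame(assign_res$posterior))
  post$sample_id <- ds$samples$sample_id
  post$assigned <- as.character(assign_res$assigned)
  readr::write_tsv(post, paths["posterior"])
  jsonlite::write_json(
    list(overall = acc$overall, k_best = bic$k_best,
         by_group = acc$by_group),
    paths["accuracy"], auto_unbox = TRUE, digits = NA
  )
  writeLines(c(
    sprintf("bovdiv %s", as.character(utils::packageVersion("bovdiv"))),
    sprintf("seed: %d", seed),
    sprintf("samples: %d  variants(post-QC): %d  pruned: %d",
            n_samples(ds), n_variants(ds), length(pruned)),
    sprintf("n_pcs: %d  n_pcs_scan: %d  k_max: %d", p_use, p_scan,
            min(k_max, n_samples(ds) - 1L))
  ), paths["log"])

  invisible(list(
    attrition = attrition,
    qc_report = qcres$report, segments = segments, froh = fr,
    froh_anova = fr_anova, consensus = cons, roh_summary = summ,
    pruned_ids = pruned, bic = bic, dapc = fit,
    assignment = assign_res, accuracy = acc, files = paths
  ))
}
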