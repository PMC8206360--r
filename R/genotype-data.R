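#' Construct a genotype dataset
#'
#' The canonical in-memory container used by every analysis step: an
#' integer dosage matrix (samples x variants, counting copies of
#' `allele_b`, `NA` = missing call) together with a sample metadata
#' tibble and a physical variant map restricted to the 29 bovine
#' autosomes.
#'
#' @param samples A data frame with at least `sample_id` (unique).
#'   Conventional metadata columns are `subgroup`, `herd_id`, `sire_id`,
#'   `birth_year` and `panel_density`.
#' @param variants A data frame with columns `variant_id`, `chrom`
#'   (integer autosome index, 1-29), `pos_bp` (1-based physical
#'   position), `allele_a`, `allele_b`. Rows are re-sorted by
#'   `(chrom, pos_bp)`; ties keep input order.
#' @param calls Integer matrix, `nrow(samples)` x `nrow(variants)`,
#'   values in `{0, 1, 2, NA}`. Columns are permuted along with the
#'   variant sort.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `samples` (tibble), `variants` (tibble) and `calls` (integer
#'   matrix with sample_id rownames and variant_id colnames).
#'
#' @details Coordinates are 1-based and intervals downstream are closed
#'   `[start_bp, end_bp]`. Dosage orientation is allele_b; allele
#'   frequency filters downstream fold to the minor allele, so the
#'   orientation never changes results. Duplicate positions (distinct
#'   IDs) are permitted, as on real chips.
#'
#' @examples
#' gd <- genotype_dataset(
#'   samples  = data.frame(sample_id = c("s1", "s2")),
#'   variants = data.frame(variant_id = c("v1", "v2"), chrom = c(1L, 1L),
#'                         pos_bp = c(100L, 2000L),
#'                         allele_a = "A", allele_b = "G"),
#'   calls    = matrix(c(0L, 2L, 1L, NA), nrow = 2)
#' )
#' n_samples(gd)
#' @export
genotype_dataset <- function(samples, variants, calls) {
  samples  <- tibble::as_tibble(samples)
  variants <- tibble::as_tibble(variants)
  calls    <- as.matrix(calls)
  storage.mode(calls) <- "integer"

  stopifnot(
    "samples needs a sample_id column" = "sample_id" %in% names(samples),
    "variants needs variant_id, chrom, pos_bp, allele_a, allele_b" =
      all(c("variant_id", "chrom", "pos_bp", "allele_a", "allele_b") %in%
            names(variants))
  )
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique")
  }
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants)) {
    stop(sprintf(
      "calls is %d x %d but there are %d samples and %d variants",
      nrow(calls), ncol(calls), nrow(samples), nrow(variants)
    ))
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("calls must be 0, 1, 2 or NA")
  }
  variants$chrom  <- as.integer(variants$chrom)
  variants$pos_bp <- as.integer(variants$pos_bp)
  if (nrow(variants)) {
    if (any(is.na(variants$chrom)) ||
        any(variants$chrom < 1L | variants$chrom > 29L)) {
      stop("chrom must be an autosome index in 1..29")
    }
    if (any(is.na(variants$pos_bp)) || any(variants$pos_bp < 1L)) {
      stop("pos_bp must be >= 1")
    }
    ord <- order(variants$chrom, variants$pos_bp)
    variants <- variants[ord, , drop = FALSE]
    calls    <- calls[, ord, drop = FALSE]
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$variant_id

  structure(
    list(samples = samples, variants = variants, calls = calls),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d variants on %d chromosome(s)\n",
    nrow(x$samples), nrow(x$variants),
    length(unique(x$variants$chrom))
  ))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if ("subgroup" %in% names(x$samples)) {
    tab <- table(x$samples$subgroup)
    cat("  subgroups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname genotype_dataset
#' @param x A `genotype_dataset`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname genotype_dataset
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param samples,variants Logical, integer or character (id) index into
#'   the respective axis; `NULL` keeps everything.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, variants = NULL) {
  si <- resolve_index(samples, x$samples$sample_id)
  vi <- resolve_index(variants, x$variants$variant_id)
  genotype_dataset(
    samples  = x$samples[si, , drop = FALSE],
    variants = x$variants[vi, , drop = FALSE],
    calls    = x$calls[si, vi, drop = FALSE]
  )
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    out <- match(idx, ids)
    if (anyNA(out)) {
      stop("unknown ids: ", paste(idx[is.na(out)], collapse = ", "))
    }
    return(out)
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}

#' Swap the allele orientation of selected variants
#'
#' Exchanges `allele_a`/`allele_b` and maps each non-missing dosage d to
#' `2 - d`. Useful for orientation-invariance checks: allele-frequency
#' and correlation statistics are unchanged under this flip.
#'
#' @param x A `genotype_dataset`.
#' @param variants Index of variants to flip (default: all).
#' @return A `genotype_dataset`.
#' @export
flip_alleles <- function(x, variants = NULL) {
  vi <- resolve_index(variants, x$variants$variant_id)
  v <- x$variants
  tmp <- v$allele_a[vi]
  v$allele_a[vi] <- v$allele_b[vi]
  v$allele_b[vi] <- tmp
  calls <- x$calls
  calls[, vi] <- 2L - calls[, vi]
  genotype_dataset(x$samples, v, calls)
}
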