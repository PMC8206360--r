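#' Read PLINK text (PED/MAP) genotypes
#'
#' Parses a PED/MAP pair into a [genotype_dataset()]. Only the 29
#' autosomes are kept; rows of the MAP with any other chromosome code
#' (0, X, Y, MT, 30+) are dropped with a message reporting the count.
#' Dosage counts copies of `allele_b`; a `0 0` (or half-missing) allele
#' pair becomes `NA`.
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @param alleles Optional data frame (`variant_id`, `allele_a`,
#'   `allele_b`) fixing the dosage orientation. When `NULL`, a sidecar
#'   `<stem>.alleles.tsv` written by [write_plink()] is used if present;
#'   otherwise `allele_a` is the first allele code encountered scanning
#'   each variant column (a variant with a single observed allele gets
#'   `allele_a = "0"` and dosage 2, the PLINK convention for
#'   monomorphic sites).
#' @param metadata Optional path to a sample-metadata TSV keyed by
#'   `sample_id` (columns beyond the 6 FAM/PED fields: subgroup,
#'   herd_id, sire_id, birth_year, panel_density). Default: a sidecar
#'   `<stem>.meta.tsv` next to the PED, if present.
#'
#' @return A `genotype_dataset`.
#' @seealso [write_plink()], [read_plink_binary()]
#' @export
read_plink_text <- function(ped_path, map_path, alleles = NULL,
                            metadata = NULL) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) != 4) {
    stop("MAP file must have 4 columns (chrom, id, cM, pos), got ",
         ncol(map))
  }
  names(map) <- c("chrom", "variant_id", "cm", "pos_bp")
  chrom_num <- suppressWarnings(as.integer(map$chrom))
  keep <- !is.na(chrom_num) & chrom_num >= 1L & chrom_num <= 29L
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(n_excl, " non-autosomal variant(s) excluded")
  }

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(map)
  widths <- lengths(toks)
  if (any(widths != want)) {
    bad <- which(widths != want)[1]
    stop(sprintf("PED line %d has %d fields, expected %d",
                 bad, widths[bad], want))
  }
  n <- length(toks)
  fam <- t(vapply(toks, function(x) x[1:6], character(6)))
  sample_id <- fam[, 2]

  a1 <- t(vapply(toks, function(x) x[seq(7L, want, by = 2L)],
                 character(nrow(map))))
  a2 <- t(vapply(toks, function(x) x[seq(8L, want, by = 2L)],
                 character(nrow(map))))
  if (nrow(map) == 1L) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  a1 <- a1[, keep, drop = FALSE]
  a2 <- a2[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  chrom_num <- chrom_num[keep]

  stem <- sub("\\.ped$", "", ped_path)
  if (is.null(alleles)) {
    side <- paste0(stem, ".alleles.tsv")
    if (file.exists(side)) {
      alleles <- utils::read.table(side, header = TRUE, sep = "\t",
                                   colClasses = "character")
    }
  }
  m <- nrow(map)
  allele_a <- character(m)
  allele_b <- character(m)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  lookup <- NULL
  if (!is.null(alleles)) {
    lookup <- alleles[match(map$variant_id, alleles$variant_id), ]
  }
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs_ok <- x1 != "0" & x2 != "0"
    if (!is.null(lookup) && !is.na(lookup$variant_id[j])) {
      aa <- lookup$allele_a[j]; bb <- lookup$allele_b[j]
    } else {
      seen <- unique(as.vector(rbind(x1, x2))[rep(obs_ok, each = 2)])
      if (length(seen) > 2L) {
        stop("variant ", map$variant_id[j], " has >2 alleles: ",
             paste(seen, collapse = "/"))
      }
      if (length(seen) == 0L) { aa <- "0"; bb <- "0" }
      else if (length(seen) == 1L) { aa <- "0"; bb <- seen }
      else { aa <- seen[1]; bb <- seen[2] }
    }
    allele_a[j] <- aa; allele_b[j] <- bb
    d <- (x1 == bb) + (x2 == bb)
    ok_codes <- obs_ok & (x1 %in% c(aa, bb)) & (x2 %in% c(aa, bb))
    if (any(obs_ok & !ok_codes)) {
      stop("variant ", map$variant_id[j],
           " has allele codes outside its declared pair")
    }
    calls[, j] <- ifelse(ok_codes, d, NA_integer_)
  }

  variants <- tibble::tibble(
    variant_id = map$variant_id,
    chrom = chrom_num,
    pos_bp = as.integer(map$pos_bp),
    allele_a = allele_a,
    allele_b = allele_b
  )
  samples <- fam_to_samples(fam, stem, metadata)
  genotype_dataset(samples, variants, calls)
}

fam_to_samples <- function(fam, stem, metadata) {
  samples <- tibble::tibble(sample_id = fam[, 2])
  meta_path <- metadata %||% paste0(stem, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              sample_id = "c",
                              .default = readr::col_guess()
                            ))
    for (col in intersect(c("subgroup", "herd_id", "sire_id"), names(meta))) {
      meta[[col]] <- as.character(meta[[col]])
    }
    for (col in intersect(c("birth_year", "panel_density"), names(meta))) {
      meta[[col]] <- as.integer(meta[[col]])
    }
    idx <- match(samples$sample_id, meta$sample_id)
    if (anyNA(idx)) {
      stop("metadata sidecar is missing ", sum(is.na(idx)), " sample id(s)")
    }
    samples <- meta[idx, , drop = FALSE]
  } else {
    samples$herd_id <- fam[, 1]
    samples$sire_id <- fam[, 3]
  }
  samples
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read PLINK 1 binary (BED/BIM/FAM) genotypes
#'
#' Decodes a SNP-major PLINK 1 .bed (magic bytes `6C 1B 01`) with its
#' .bim/.fam companions. Two-bit codes: `00` = homozygous allele 1
#' (dosage 0), `01` = missing, `10` = heterozygous, `11` = homozygous
#' allele 2 (dosage 2). Non-autosomal .bim rows are dropped with a
#' message, as in [read_plink_text()].
#'
#' @param prefix Path stem; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param metadata Optional sample-metadata TSV path (default: sidecar
#'   `<prefix>.meta.tsv` if present).
#' @return A `genotype_dataset`.
#' @export
read_plink_binary <- function(prefix, metadata = NULL) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  stopifnot(file.exists(bed), file.exists(bim), file.exists(fam))

  if (file.size(bim) == 0) {
    bim_df <- data.frame(chrom = character(), variant_id = character(),
                         cm = character(), pos_bp = character(),
                         allele_a = character(), allele_b = character())
  } else {
    bim_df <- utils::read.table(bim, header = FALSE,
                                colClasses = "character")
    if (ncol(bim_df) != 6) stop(".bim must have 6 columns")
  }
  names(bim_df) <- c("chrom", "variant_id", "cm", "pos_bp",
                     "allele_a", "allele_b")
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  if (ncol(fam_df) != 6) stop(".fam must have 6 columns")

  n <- nrow(fam_df)
  m_all <- nrow(bim_df)
  bpv <- ceiling(n / 4)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01)) {
    stop(".bed magic bytes are not 6C 1B 01 (SNP-major PLINK 1)")
  }
  if (length(raw) != 3 + bpv * m_all) {
    stop(sprintf(
      ".bed payload is %d bytes; expected %d for %d samples x %d variants",
      length(raw) - 3, bpv * m_all, n, m_all
    ))
  }

  chrom_num <- suppressWarnings(as.integer(bim_df$chrom))
  keep <- which(!is.na(chrom_num) & chrom_num >= 1L & chrom_num <= 29L)
  if (length(keep) < m_all) {
    message(m_all - length(keep), " non-autosomal variant(s) excluded")
  }

  # dosage by 2-bit code: 00->0, 01->NA, 10->1, 11->2
  code_map <- c(0L, NA_integer_, 1L, 2L)
  ints <- as.integer(raw[-(1:3)])
  calls <- matrix(NA_integer_, nrow = n, ncol = length(keep))
  shift <- 2L * (0:3)
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    bytes <- ints[((j - 1L) * bpv + 1L):(j * bpv)]
    codes <- integer(bpv * 4L)
    for (k in 1:4) {
      codes[seq(k, by = 4L, length.out = bpv)] <-
        bitwAnd(bitwShiftR(bytes, shift[k]), 3L)
    }
    calls[, jj] <- code_map[codes[seq_len(n)] + 1L]
  }

  variants <- tibble::tibble(
    variant_id = bim_df$variant_id[keep],
    chrom = chrom_num[keep],
    pos_bp = as.integer(bim_df$pos_bp[keep]),
    allele_a = bim_df$allele_a[keep],
    allele_b = bim_df$allele_b[keep]
  )
  samples <- fam_to_samples(as.matrix(fam_df), prefix, metadata)
  genotype_dataset(samples, variants, calls)
}

#' Write a genotype dataset in PLINK format
#'
#' Emits either a PED/MAP pair or a BED/BIM/FAM trio, plus two sidecar
#' files: `<prefix>.meta.tsv` holding the full sample-metadata table
#' (FAM cannot carry subgroup, herd, birth year or panel density) and,
#' in text mode, `<prefix>.alleles.tsv` fixing the allele orientation
#' (PED/MAP does not declare alleles). Re-reading the emitted files
#' reproduces the dataset exactly.
#'
#' @param dataset A `genotype_dataset`.
#' @param prefix Output path stem.
#' @param format `"text"` (PED/MAP) or `"binary"` (BED/BIM/FAM).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix, format = c("text", "binary")) {
  format <- match.arg(format)
  v <- dataset$variants
  s <- dataset$samples
  calls <- dataset$calls
  n <- nrow(s); m <- nrow(v)

  fam_df <- data.frame(
    fid   = if ("herd_id" %in% names(s)) as.character(s$herd_id) else "0",
    iid   = s$sample_id,
    pat   = if ("sire_id" %in% names(s)) as.character(s$sire_id) else "0",
    mat   = "0", sex = "2", pheno = "-9",
    stringsAsFactors = FALSE
  )
  fam_df[is.na(fam_df)] <- "0"

  if (format == "text") {
    map_df <- data.frame(chrom = v$chrom, id = v$variant_id,
                         cm = rep(0, m), pos = v$pos_bp)
    utils::write.table(map_df, paste0(prefix, ".map"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    if (m > 0 && any(v$allele_a == "0" & apply(calls, 2, function(x)
      any(!is.na(x) & x < 2L)))) {
      stop("cannot write het/hom-A genotypes for a variant with allele_a '0'")
    }
    geno_strings <- character(n)
    for (i in seq_len(n)) {
      d <- calls[i, ]
      g <- character(2L * m)
      odd <- seq(1L, by = 2L, length.out = m)
      g[odd]     <- ifelse(is.na(d), "0", ifelse(d == 0L, v$allele_a,
                                                 ifelse(d == 1L, v$allele_a,
                                                        v$allele_b)))
      g[odd + 1] <- ifelse(is.na(d), "0", ifelse(d == 0L, v$allele_a,
                                                 v$allele_b))
      geno_strings[i] <- paste(g, collapse = " ")
    }
    ped <- paste(fam_df$fid, fam_df$iid, fam_df$pat, fam_df$mat,
                 fam_df$sex, fam_df$pheno,
                 if (m > 0) geno_strings else "")
    writeLines(trimws(ped), paste0(prefix, ".ped"))
    utils::write.table(
      v[, c("variant_id", "allele_a", "allele_b")],
      paste0(prefix, ".alleles.tsv"),
      quote = FALSE, row.names = FALSE, sep = "\t"
    )
  } else {
    bim_df <- data.frame(chrom = v$chrom, id = v$variant_id,
                         cm = rep(0, m), pos = v$pos_bp,
                         a1 = v$allele_a, a2 = v$allele_b)
    utils::write.table(bim_df, paste0(prefix, ".bim"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    bpv <- ceiling(n / 4)
    # dosage -> 2-bit code: 0->00, NA->01, 1->10, 2->11
    code_of <- function(d) ifelse(is.na(d), 1L, ifelse(d == 0L, 0L,
                                                       ifelse(d == 1L, 2L, 3L)))
    payload <- raw(bpv * m)
    if (m > 0) {
      for (j in seq_len(m)) {
        codes <- integer(bpv * 4L)
        codes[seq_len(n)] <- code_of(calls[, j])
        byte_vals <- codes[seq(1, by = 4, length.out = bpv)] +
          bitwShiftL(codes[seq(2, by = 4, length.out = bpv)], 2L) +
          bitwShiftL(codes[seq(3, by = 4, length.out = bpv)], 4L) +
          bitwShiftL(codes[seq(4, by = 4, length.out = bpv)], 6L)
        payload[((j - 1L) * bpv + 1L):(j * bpv)] <- as.raw(byte_vals)
      }
    }
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(payload, con)
    utils::write.table(fam_df, paste0(prefix, ".fam"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  }
  readr::write_tsv(s, paste0(prefix, ".meta.tsv"))
  invisible(prefix)
}
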