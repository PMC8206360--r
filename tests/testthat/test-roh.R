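test_that("window states match the explicit-enumeration oracle", {
  params <- roh_params()
  all_het <- rep(1L, 120)
  expect_false(any(window_homozygosity_states(all_het, params)))
  all_hom <- rep(2L, 120)
  expect_true(all(window_homozygosity_states(all_hom, params)))

  # isolated het inside a homozygous stretch stays in the run
  g <- rep(0L, 100); g[50] <- 1L
  st <- window_homozygosity_states(g, params)
  expect_true(st[50])
  expect_identical(st, oracle_window_states(g, params))

  # short chromosome: one truncated window
  g2 <- c(2L, 2L, 1L, 2L)
  p2 <- roh_params(window_snps = 10, min_snps_per_roh = 2,
                   min_length_bp = 1)
  expect_identical(window_homozygosity_states(g2, p2),
                   oracle_window_states(g2, p2))

  set.seed(33)
  for (i in 1:25) {
    g <- sample(c(0L, 1L, 2L, NA), 400, replace = TRUE,
                prob = c(0.35, 0.1, 0.5, 0.05))
    expect_identical(window_homozygosity_states(g, params),
                     oracle_window_states(g, params))
  }
})

test_that("detector enforces the four run filters", {
  params <- roh_params()
  flank <- function(k) rep(1L, k)

  # 60 hom SNPs at 25 kb spacing (span 1.475 Mb) flanked by dense hets
  g <- c(flank(50), rep(2L, 60), flank(50))
  pos <- cumsum(rep(25e3, 160))
  ds <- make_chrom_dataset(list(g), pos)
  seg <- detect_roh(ds, params)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 60L)
  expect_equal(seg$length_bp, 59 * 25e3)

  # 45 hom SNPs spanning < 1 Mb: rejected on length
  g2 <- c(flank(50), rep(2L, 45), flank(50))
  pos2 <- cumsum(rep(18e3, 145))  # run span 44*18k = 792 kb
  expect_equal(nrow(detect_roh(make_chrom_dataset(list(g2), pos2),
                               params)), 0L)

  # 80 hom SNPs with a 600 kb gap: split, halves fail min-SNP count
  g3 <- c(flank(50), rep(2L, 80), flank(50))
  gaps <- rep(25e3, 179)
  gaps[50 + 40] <- 6e5   # between 40th and 41st hom SNP
  pos3 <- cumsum(c(1e5, gaps))
  seg3 <- detect_roh(make_chrom_dataset(list(g3), pos3), params)
  expect_equal(nrow(seg3), 0L)

  # same geometry with longer halves: both qualify separately
  g4 <- c(flank(50), rep(2L, 100), flank(50))
  gaps4 <- rep(25e3, 199)
  gaps4[50 + 50] <- 6e5
  pos4 <- cumsum(c(1e5, gaps4))
  seg4 <- detect_roh(make_chrom_dataset(list(g4), pos4), params)
  expect_equal(nrow(seg4), 2L)
  expect_true(all(seg4$n_snps == 50L))

  # density filter: 40 SNPs spread over 2.4 Mb (60 kb/SNP) rejected
  g5 <- c(flank(50), rep(2L, 41), flank(50))
  pos5 <- cumsum(c(rep(10e3, 50), rep(60e3, 41), rep(10e3, 50)))
  seg5 <- detect_roh(make_chrom_dataset(list(g5), pos5), params)
  expect_equal(nrow(seg5), 0L)
})

test_that("detector equals the brute-force oracle on random fixtures", {
  set.seed(99)
  params <- roh_params()
  for (i in 1:20) {
    fx <- random_roh_fixture(1500)
    ds <- make_chrom_dataset(list(fx$genos), fx$pos)
    got <- detect_roh(ds, params)
    want <- oracle_detect_roh_vec(fx$genos, fx$pos, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("raising min_length_bp never adds segments", {
  set.seed(17)
  fx <- random_roh_fixture(2000)
  ds <- make_chrom_dataset(list(fx$genos), fx$pos)
  counts <- vapply(c(1e6, 2e6, 4e6, 8e6), function(L) {
    nrow(detect_roh(ds, roh_params(min_length_bp = L)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("length classes bin left-closed and reject short runs", {
  seg <- tibble::tibble(length_bp = c(3.5e6, 2.0e6, 64.4e6, 1e6, 15.99e6))
  cls <- classify_roh_lengths(seg)$length_class
  expect_equal(as.character(cls), c("2-4", "2-4", ">16", "1-2", "8-16"))
  expect_error(classify_roh_lengths(tibble::tibble(length_bp = 9e5)),
               "1 Mb")
})

test_that("froh arithmetic, zero case, and per-chromosome identity", {
  v <- tibble::tibble(chrom = rep(1:2, each = 2),
                      pos_bp = c(1e6, 101e6, 1e6, 51e6))
  empty <- tibble::tibble(sample_id = character(), chrom = integer(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_bp = numeric())
  expect_equal(froh(empty, v, sample_ids = "s1")$froh, 0)

  seg <- tibble::tibble(sample_id = "s1", chrom = c(1L, 2L),
                        start_bp = c(2e6, 5e6), end_bp = c(9.5e6, 10e6),
                        n_snps = 300L,
                        length_bp = c(7.5e6, 5e6))
  fr <- froh(seg, v, sample_ids = "s1")           # L_total = 150 Mb
  expect_equal(fr$froh, 12.5e6 / 150e6)
  bc <- froh(seg, v, sample_ids = "s1", by_chrom = TRUE)
  # genome coverage equals the length-weighted chromosome combination
  span <- c(100e6, 50e6)
  expect_equal(sum(bc$froh * span) / sum(span), fr$froh)
  expect_equal(bc$froh, c(7.5 / 100, 5 / 50))

  seg_bad <- dplyr::mutate(seg, chrom = c(1L, 9L))
  expect_error(froh(seg_bad, v), "absent")
})

test_that("froh recovers injected autozygosity within 0.01", {
  sim <- dense_sim(n_per_pop = 3, n_snps = 20000, seed = 5)
  ds <- sim$dataset
  targets <- c(0.05, 0.10, 0.20)
  for (i in seq_along(targets)) {
    sid <- sprintf("cow%04d", i)
    inj <- inject_autozygosity(ds, sid, targets[i], seed = 40 + i)
    ds <- inj$dataset
  }
  seg <- detect_roh(ds, samples = sprintf("cow%04d", 1:3))
  fr <- froh(seg, ds$variants, sample_ids = sprintf("cow%04d", 1:3))
  expect_true(all(abs(fr$froh - targets) <= 0.01))
})

test_that("consensus regions respect the strict support rule", {
  pos <- seq(1e6, 3e6, by = 1e5)  # 21 SNPs
  v <- tibble::tibble(chrom = 1L, pos_bp = as.integer(pos))
  mk_seg <- function(ids, s, e) {
    tibble::tibble(sample_id = ids, chrom = 1L, start_bp = s,
                   end_bp = e, n_snps = 10L, length_bp = e - s)
  }
  sg <- stats::setNames(rep("DM", 10), sprintf("i%02d", 1:10))

  # 4 of 10 share [1.5, 2.5] Mb -> emitted
  seg4 <- mk_seg(sprintf("i%02d", 1:4), 1.5e6, 2.5e6)
  out4 <- consensus_regions(seg4, v, sg)
  expect_equal(nrow(out4), 1L)
  expect_equal(out4$start_bp, 1.5e6)
  expect_equal(out4$end_bp, 2.5e6)
  expect_equal(out4$support, 0.4)
  expect_equal(out4$subgroup_set, "DM")

  # exactly 3 of 10 (support 0.30) -> NOT emitted
  seg3 <- mk_seg(sprintf("i%02d", 1:3), 1.5e6, 2.5e6)
  expect_equal(nrow(consensus_regions(seg3, v, sg)), 0L)

  # disjoint single-individual ROH only -> nothing
  segd <- mk_seg(sprintf("i%02d", 1:2), c(1.0e6, 2.0e6), c(1.4e6, 2.4e6))
  expect_equal(nrow(consensus_regions(segd, v, sg)), 0L)

  # support_min = 0 with one individual returns its ROH intervals
  sg1 <- stats::setNames("AS", "i01")
  seg1 <- mk_seg(rep("i01", 2), c(1.0e6, 2.2e6), c(1.6e6, 2.8e6))
  out1 <- consensus_regions(seg1, v, sg1, support_min = 0)
  expect_equal(out1$start_bp, c(1.0e6, 2.2e6))
  expect_equal(out1$end_bp, c(1.6e6, 2.8e6))

  # identical regions in two subgroups merge into one record
  sg2 <- stats::setNames(rep(c("AS", "TR"), each = 5),
                         sprintf("i%02d", 1:10))
  seg_m <- mk_seg(sprintf("i%02d", c(1:3, 6:8)), 1.5e6, 2.5e6)
  outm <- consensus_regions(seg_m, v, sg2)
  expect_equal(nrow(outm), 1L)
  expect_equal(outm$subgroup_set, "AS,TR")
  expect_equal(outm$support, 0.6)
})

test_that("roh_summary keeps ROH-free animals in the denominator", {
  sg <- stats::setNames(rep("GP", 10), sprintf("i%02d", 1:10))
  seg <- tibble::tibble(
    sample_id = rep(sprintf("i%02d", 1:5), each = 10),
    chrom = 1L, start_bp = 1L, end_bp = 2L, n_snps = 50L,
    length_bp = rep(1.5e6, 50)
  )
  out <- roh_summary(seg, sg)
  r12 <- out[out$length_class == "1-2", ]
  expect_equal(r12$mean_per_individual, 5.0)
  rall <- out[out$length_class == "all", ]
  expect_equal(rall$mean_per_individual, 5.0)
  r24 <- out[out$length_class == "2-4", ]
  expect_equal(r24$mean_per_individual, 0)
})
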