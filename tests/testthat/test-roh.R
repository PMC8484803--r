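make_roh <- function(sample_id, chr, start, end) {
  data.table(sample_id = sample_id, chr = as.character(chr),
             start = as.numeric(start), end = as.numeric(end))
}

test_that("ROH length groups are half-open and conserve totals", {
  r <- make_roh("H1", 1, 1, 3e6)                       # exactly 3 Mb
  s <- roh_length_summary(r, c(0, 2e6, 4e6, 8e6, 16e6, Inf))
  expect_equal(as.character(s$length_group), "2 Mb-4 Mb")
  expect_equal(s$n, 1L)
  expect_equal(nrow(roh_length_summary(r[0])), 0L)
  withr::local_seed(3)
  many <- make_roh(sprintf("H%d", 1:50), 1,
                   1, round(runif(50, 5e5, 2e7)))
  s2 <- roh_length_summary(many)
  expect_equal(sum(s2$n), 50L)
  lens <- many$end - many$start + 1
  brute <- c(sum(lens < 2e6), sum(lens >= 2e6 & lens < 4e6),
             sum(lens >= 4e6 & lens < 8e6), sum(lens >= 8e6 & lens < 16e6),
             sum(lens >= 16e6))
  expect_equal(s2$n, as.integer(brute[brute > 0]))
})

test_that("F_roh is total ROH length over total autosome length", {
  r <- make_roh("H1", 1, 1, 25e6)                       # one 25 Mb ROH
  auto <- setNames(rep(250e6, 10), as.character(1:10))  # 2,500 Mb genome
  f <- froh(r, autosome_lengths = auto)
  expect_identical(f$f_roh, 0.01)
  expect_equal(f$sum_l_roh_bp, 25e6)
  # no ROH on an autosome -> 0
  rx <- make_roh("H2", "X", 1, 25e6)
  f2 <- froh(rx, autosome_lengths = auto)
  expect_equal(f2$f_roh, 0)
  # unknown chromosome is an error naming it
  expect_error(froh(make_roh("H1", 19, 1, 2), autosome_lengths = auto["1"]),
               "19")
})

test_that("per-length-group F_roh components sum to the total", {
  fx <- get_fixture()
  roh <- read_plink_hom(fx$files$plink_hom)
  auto <- setNames(rep(fx$config$chrom_length_bp, fx$config$n_chromosomes),
                   as.character(seq_len(fx$config$n_chromosomes)))
  f <- froh(roh, autosome_lengths = auto)
  gcols <- grep("^f_roh_", names(f), value = TRUE)
  expect_gt(length(gcols), 1L)
  expect_equal(rowSums(as.matrix(f[, ..gcols])), f$f_roh,
               tolerance = 1e-12)
  # totals equal the generator's per-individual bookkeeping
  led <- as.data.table(fx$ledger$roh$per_individual_bp)
  m <- merge(f, led, by = "sample_id")
  expect_equal(m$f_roh, m$sum_l_roh_bp.y / fx$ledger$roh$genome_bp,
               tolerance = 1e-12)
})

test_that("autosome lengths can be derived from the chip map", {
  fx <- get_fixture()
  roh <- read_plink_hom(fx$files$plink_hom)
  map <- read_snp_map(fx$files$map_default, "map")
  f <- froh(roh, map = map)
  span <- map[, .(len = max(pos) - min(pos) + 1), by = chr]
  expect_equal(unique(f$sum_l_auto_bp), sum(span$len))
  expect_error(froh(roh), "autosome_lengths or a SNP map")
})

test_that("per-SNP incidence counts distinct spanning individuals", {
  map <- data.table(name = c("s1", "s2"), chr = "1",
                    pos = c(150, 250))
  inc <- roh_incidence(make_roh("H1", 1, 100, 200), map)
  expect_equal(inc[name == "s1", freq], 1)
  expect_equal(inc[name == "s2", freq], 0)
  # no ROH at all
  inc0 <- roh_incidence(make_roh("H1", 1, 100, 200)[0], map,
                        n_individuals = 5)
  expect_true(all(inc0$freq == 0))
  # two ROH of one individual over one SNP count once
  two <- make_roh(c("H1", "H1"), 1, c(100, 140), c(200, 260))
  expect_equal(roh_incidence(two, map)[name == "s1", n_carriers], 1L)
})

test_that("incidence equals the quadratic point-in-interval oracle", {
  withr::local_seed(19)
  ids <- sprintf("H%02d", 1:50)
  roh <- rbindlist(lapply(ids, function(id) {
    n <- sample(1:4, 1)
    st <- sample.int(9e6, n)
    make_roh(id, sample(1:3, n, replace = TRUE), st, st + sample.int(1e6, n))
  }))
  map <- data.table(name = sprintf("m%03d", 1:150),
                    chr = as.character(sample(1:3, 150, replace = TRUE)),
                    pos = as.numeric(sample.int(1e7, 150)))
  inc <- roh_incidence(roh, map)
  for (i in sample.int(nrow(map), 40)) {
    covered <- roh[chr == map$chr[i] & start <= map$pos[i] &
                     end >= map$pos[i]]
    expect_equal(inc[name == map$name[i], n_carriers],
                 uniqueN(covered$sample_id))
  }
  # monotone under adding an individual
  extra <- make_roh("H99", 1, 1, 1e7)
  inc2 <- roh_incidence(rbind(roh, extra), map)
  expect_true(all(inc2$n_carriers >= inc$n_carriers))
})

test_that("high-frequency regions are maximal runs above threshold", {
  inc <- data.table(name = sprintf("s%d", 1:4), chr = "1",
                    pos = c(100, 200, 300, 400),
                    n_carriers = c(2L, 6L, 7L, 3L),
                    freq = c(.2, .6, .7, .3))
  hf <- high_freq_roh(inc, 0.5)
  expect_equal(nrow(hf), 1L)
  expect_equal(c(hf$start, hf$end), c(200, 300))
  expect_equal(hf$peak_freq, 0.7)
  expect_equal(hf$mean_freq, 0.65)
  expect_equal(nrow(high_freq_roh(inc, 0.8)), 0L)
  expect_error(high_freq_roh(inc, 0), "threshold")
  # maximality: flanking SNPs are below threshold
  expect_lt(inc[pos == 100, freq], 0.5)
  expect_lt(inc[pos == 400, freq], 0.5)
})

test_that("the planted shared ROH segment is recovered as one region", {
  fx <- get_fixture()
  roh <- read_plink_hom(fx$files$plink_hom)
  map <- read_snp_map(fx$files$map_default, "map")
  inc <- roh_incidence(roh, map)
  hf <- high_freq_roh(inc, 0.3)
  expect_equal(nrow(hf), 1L)
  planted <- fx$ledger$roh$planted
  expect_equal(hf$chr, planted$chr)
  expect_gte(hf$start, planted$start)
  expect_lte(hf$end, planted$end)
  # the region covers every map SNP inside the planted span
  inside <- map[normalize_chrom(chr) == planted$chr & pos >= planted$start &
                  pos <= planted$end]
  expect_equal(hf$n_snps_in_region, nrow(inside))
  expect_equal(hf$peak_freq,
               length(fx$ledger$roh$planted$carriers) /
                 length(fx$ledger$roh$individuals))
})
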