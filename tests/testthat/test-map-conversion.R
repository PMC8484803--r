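make_map <- function(n = 100, chroms = 1:2, len = 1e7, prefix = "rs") {
  per <- n %/% length(chroms)
  rbindlist(lapply(chroms, function(ch) {
    data.table(name = sprintf("%s%s_%04d", prefix, ch, seq_len(per)),
               chr = as.character(ch),
               pos = as.numeric(sort(sample.int(len, per))))
  }))
}

test_that("identical maps match fully, a moved SNP is classified", {
  withr::local_seed(2)
  m <- make_map()
  cm <- convert_map(m, m)
  expect_equal(cm$summary$same_chr, nrow(m))
  expect_equal(cm$summary$chr_changed, 0L)
  expect_equal(cm$summary$missing_in_target, 0L)
  expect_equal(cm$summary$n_pos_shifted, 0L)

  t <- copy(m)
  t[1, chr := "5"]
  cm2 <- convert_map(m, t)
  expect_equal(cm2$summary$chr_changed, 1L)
  expect_equal(cm2$map[match_class == "chr_changed", name], m$name[1])
})

test_that("disjoint maps are rejected as different chips", {
  withr::local_seed(3)
  a <- make_map(prefix = "rsA")
  b <- make_map(prefix = "rsB")
  expect_error(convert_map(a, b), "same type of SNP chip")
})

test_that("planted perturbation rates are recovered from the fixture maps", {
  fx <- get_fixture()
  d <- read_snp_map(fx$files$map_default, "map")
  t <- read_snp_map(fx$files$map_target, "map")
  cm <- convert_map(d, t)
  led <- fx$ledger$map
  expect_equal(cm$summary$missing_in_target, length(led$missing_in_target))
  expect_equal(cm$summary$chr_changed, length(led$chr_changed))
  expect_equal(cm$summary$n_pos_shifted, length(led$pos_shifted))
  expect_setequal(cm$map[match_class == "missing_in_target", name],
                  led$missing_in_target)
  expect_setequal(cm$map[pos_shifted == TRUE, name], led$pos_shifted)
})

test_that("per-chromosome density matches the closed form", {
  m <- data.table(name = c("a", "b", "c"), chr = c("1", "1", "2"),
                  pos = c(1001, 2001, 500))
  d <- snp_density(m)
  expect_equal(d[chr == "1", span_bp], 1000)
  expect_equal(d[chr == "1", mean_gap_bp], 1000)
  expect_true(d[chr == "2", degenerate])
  expect_true(is.na(d[chr == "2", mean_gap_bp]))
  # uniform placement: mean gap ~ span / (n - 1)
  fx <- get_fixture()
  dm <- read_snp_map(fx$files$map_default, "map")
  dd <- snp_density(dm)
  n_per <- fx$config$n_snps / fx$config$n_chromosomes
  expect_true(all(abs(dd$mean_gap_bp - fx$config$chrom_length_bp /
                        (n_per - 1)) / (fx$config$chrom_length_bp /
                                          (n_per - 1)) < 0.05))
})

test_that("self-map liftover returns each interval's SNP span exactly", {
  withr::local_seed(5)
  m <- make_map(200)
  cm <- convert_map(m, m)
  iv <- data.table(chr = "1", start = c(1e5, 4e6), end = c(2e6, 8e6))
  r <- convert_coord(iv, cm)$result
  expect_true(all(r$status == "converted"))
  for (i in 1:2) {
    snps <- m[chr == "1" & pos >= iv$start[i] & pos <= iv$end[i], pos]
    expect_equal(r$start_target[i], min(snps))
    expect_equal(r$end_target[i], max(snps))
  }
  expect_true(all(r$length_delta == 0))
  expect_true(all(!r$order_inverted))
})

test_that("a uniform target shift moves spans without changing lengths", {
  withr::local_seed(6)
  m <- make_map(200)
  t <- copy(m)[, pos := pos + 10000]
  cm <- convert_map(m, t)
  iv <- data.table(chr = c("1", "2"), start = c(1e5, 1e5), end = c(5e6, 5e6))
  r <- convert_coord(iv, cm)$result
  expect_true(all(r$status == "converted"))
  expect_true(all(r$length_delta == 0))
  for (i in 1:2) {
    snps <- m[chr == iv$chr[i] & pos >= iv$start[i] & pos <= iv$end[i], pos]
    expect_equal(r$start_target[i], min(snps) + 10000)
  }
})

test_that("empty intervals, split chromosomes, and inversions are flagged", {
  m <- data.table(name = sprintf("s%d", 1:10), chr = "1",
                  pos = as.numeric(seq(1000, 10000, by = 1000)))
  cm <- convert_map(m, m)
  r <- convert_coord(data.table(chr = "1", start = 100, end = 900), cm)
  expect_equal(r$result$status, "no_snps_in_interval")
  expect_equal(r$summary$n_failed, 1L)
  # 3 of 10 SNPs moved to chr2: over the 10% minority tolerance
  t <- copy(m); t[1:3, chr := "2"]
  cm2 <- convert_map(m, t)
  r2 <- convert_coord(data.table(chr = "1", start = 1, end = 20000), cm2)
  expect_equal(r2$result$status, "snps_split_across_chromosomes")
  # 1 of 20 moved: dropped as minority, conversion proceeds
  m20 <- data.table(name = sprintf("t%d", 1:20), chr = "1",
                    pos = as.numeric(seq(1000, 20000, by = 1000)))
  t20 <- copy(m20); t20[1, chr := "2"]
  r3 <- convert_coord(data.table(chr = "1", start = 1, end = 30000),
                      convert_map(m20, t20))
  expect_equal(r3$result$status, "converted")
  expect_equal(r3$result$n_snps_dropped, 1L)
  expect_equal(r3$result$n_snps_used, 19L)
  # inverted order on the target side
  tinv <- copy(m)[, pos := rev(pos)]
  r4 <- convert_coord(data.table(chr = "1", start = 1, end = 20000),
                      convert_map(m, tinv))
  expect_false(r4$result$order_inverted)   # full reversal is still monotone
  tswap <- copy(m); tswap[2, pos := 20000]
  r5 <- convert_coord(data.table(chr = "1", start = 1, end = 20000),
                      convert_map(m, tswap))
  expect_true(r5$result$order_inverted)
})

test_that("conversion conserves interval counts and breaks ties to default", {
  withr::local_seed(8)
  m <- make_map(100)
  t <- copy(m)
  half <- which(t$chr == "1")[1:25]
  t[half, chr := "2"]                      # 25 of 50 chr1 SNPs move: tie
  cm <- convert_map(m, t)
  iv <- data.table(chr = "1", start = 1, end = 1e7)
  r <- convert_coord(iv, cm, minority_tol = 0.5)
  expect_equal(r$result$chr_target, "1")   # tie broken toward default chrom
  expect_equal(r$summary$n_converted + r$summary$n_failed,
               r$summary$n_input)
})
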