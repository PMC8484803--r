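test_that("PennCNV raw lines parse field by field", {
  f <- withr::local_tempfile(lines = c(
    "chr1:100-299 numsnp=10 length=200 state2,cn=1 S1 startsnp=rs1 endsnp=rs2",
    "chrX:5,000-6,000 numsnp=12 length=1,001 state5,cn=3 /data/S2.txt conf=21.5"))
  x <- read_cnv(f, "penncnv")
  expect_equal(nrow(x), 2L)
  expect_equal(x$sample_id, c("S1", "/data/S2.txt"))
  expect_equal(x$chr, c("chr1", "chrX"))
  expect_equal(x$start, c(100, 5000))
  expect_equal(x$end, c(299, 6000))
  expect_equal(x$cn, c(1L, 3L))
  expect_equal(x$n_snps, c(10L, 12L))
  expect_equal(x$conf, c(NA, 21.5))
  expect_equal(x$line, c(1L, 2L))
  expect_equal(nrow(attr(x, "malformed")), 0L)
})

test_that("empty CNV file gives an empty table with a warning", {
  f <- withr::local_tempfile(lines = character(0))
  expect_warning(x <- read_cnv(f, "penncnv"), "empty")
  expect_equal(nrow(x), 0L)
})

test_that("malformed PennCNV lines are collected, not dropped silently", {
  f <- withr::local_tempfile(lines = c(
    "chr1:100-299 numsnp=10 length=200 state2,cn=1 S1",
    "this is not a cnv line at all",
    "chr2:500-900 numsnp=5 length=401 state1,cn=0 S2"))
  x <- read_cnv(f, "penncnv")
  expect_equal(nrow(x), 2L)
  bad <- attr(x, "malformed")
  expect_equal(bad$line, 2L)
  expect_match(bad$text, "not a cnv line")
})

test_that("majority-malformed input raises a dialect-mismatch error", {
  f <- withr::local_tempfile(lines = c("garbage one", "garbage two",
                                       "chr1:1-2 numsnp=3 length=2 state2,cn=1 S1"))
  expect_error(read_cnv(f, "penncnv"), "dialect mismatch.*line 1")
})

test_that("CNVPartition CSV dialect reads through the column map", {
  f <- withr::local_tempfile(lines = c(
    "SampleID,Chr,StartPosition,EndPosition,CopyNumber,Confidence",
    "S1,3,1000,2000,1,32.5"))
  x <- read_cnv(f, "cnvpartition")
  expect_equal(x$sample_id, "S1")
  expect_equal(x$chr, "3")
  expect_equal(x$cn, 1L)
  expect_equal(x$conf, 32.5)
  # custom column names via col_map
  f2 <- withr::local_tempfile(lines = c("id,c,s,e,copies",
                                        "S9,2,10,20,4"))
  y <- read_cnv(f2, "cnvpartition",
                col_map = c(sample_id = "id", chr = "c", start = "s",
                            end = "e", cn = "copies"))
  expect_equal(y$cn, 4L)
})

test_that("standard table round-trips through write_cnv / read_cnv(generic)", {
  withr::local_seed(42)
  x <- random_intervals(50, samples = sprintf("S%02d", 1:10))
  f <- withr::local_tempfile()
  write_cnv(x, f)
  y <- read_cnv(f, "generic")
  expect_equal(y[, .(sample_id, chr, start, end, cn)],
               x[, .(sample_id, chr, start, end, cn)])
  # second write is byte-identical (round-trip identity)
  f2 <- withr::local_tempfile()
  write_cnv(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("PLINK .hom rows map onto ROH records", {
  f <- withr::local_tempfile(lines = c(
    "FID IID PHE CHR SNP1 SNP2 POS1 POS2 KB NSNP DENSITY PHOM PHET",
    "1 H007 -9 22 rs1 rs2 22810000 23220000 410.001 120 1 1 0"))
  x <- read_plink_hom(f)
  expect_equal(x$sample_id, "H007")
  expect_equal(x$chr, "22")
  expect_equal(x$start, 22810000)
  expect_equal(x$end, 23220000)
  expect_equal(x$n_snps, 120L)
  expect_equal(x$length_kb, 410.001)
})

test_that(".hom header-only file and missing columns behave", {
  f <- withr::local_tempfile(lines =
    "FID IID PHE CHR SNP1 SNP2 POS1 POS2 KB NSNP DENSITY PHOM PHET")
  expect_equal(nrow(read_plink_hom(f)), 0L)
  f2 <- withr::local_tempfile(lines = c("FID IID CHR POS1", "1 a 1 2"))
  expect_error(read_plink_hom(f2), "POS2.*KB.*NSNP")
})

test_that("fixture .hom parses to exactly the generated segment count", {
  fx <- get_fixture()
  x <- read_plink_hom(fx$files$plink_hom)
  expect_equal(nrow(x), nrow(fx$ledger$roh$truth))
})

test_that("SNP maps parse, deduplicate by first occurrence, and round-trip", {
  f <- withr::local_tempfile(lines = c("14\trs123\t0\t105000000",
                                       "14\trs9\t0\t1000",
                                       "15\trs9\t0\t2000"))
  x <- read_snp_map(f, "map")
  expect_equal(x[name == "rs123", pos], 105000000)
  expect_equal(nrow(x), 2L)              # rs9 kept once (first occurrence)
  expect_equal(x[name == "rs9", chr], "14")
  dup <- attr(x, "duplicates")
  expect_equal(dup$name, "rs9")
  expect_equal(dup$n, 2L)

  fx <- get_fixture()
  m <- read_snp_map(fx$files$map_default, "map")
  f2 <- withr::local_tempfile()
  write_snp_map(m, f2)
  expect_identical(readLines(fx$files$map_default), readLines(f2))
})

test_that("non-integer map positions are a parse error with line number", {
  f <- withr::local_tempfile(lines = c("1\trs1\t0\t100",
                                       "1\trs2\t0\tnotanumber"))
  expect_error(read_snp_map(f, "map"), "line 2")
})

test_that(".bim layout carries alleles", {
  f <- withr::local_tempfile(lines = "1\trs1\t0\t100\tA\tG")
  x <- read_snp_map(f, "bim")
  expect_equal(x$a1, "A")
  expect_equal(x$a2, "G")
})

test_that("refGene transcripts collapse to union spans with a +1 start shift", {
  f <- withr::local_tempfile(lines = c(
    paste0("0\tNM_1\tchr2\t+\t100\t500\t100\t500\t1\t100,\t500,\t0\tGENE1\t",
           "cmpl\tcmpl\t0,"),
    paste0("0\tNM_2\tchr2\t+\t300\t900\t300\t900\t1\t300,\t900,\t0\tGENE1\t",
           "cmpl\tcmpl\t0,"),
    paste0("0\tNM_3\tchr3\t-\t50\t80\t50\t80\t1\t50,\t80,\t0\tGENE2\t",
           "cmpl\tcmpl\t0,")))
  x <- read_refgene(f)
  expect_equal(nrow(x), 2L)
  g1 <- x[gene == "GENE1"]
  expect_equal(g1$start, 101)            # 0-based 100 -> 1-based 101
  expect_equal(g1$end, 900)              # union span over both transcripts
  expect_equal(g1$n_transcripts, 2L)
  g2 <- x[gene == "GENE2"]
  expect_equal(c(g2$start, g2$end), c(51, 80))
  expect_equal(g2$strand, "-")
})

test_that("fixture gene list collapses to the distinct (gene, chr) count", {
  fx <- get_fixture()
  x <- read_refgene(fx$files$refgene)
  expect_equal(nrow(x), fx$ledger$genes$n_distinct)
  expect_gt(fx$ledger$genes$n_transcript_rows, fx$ledger$genes$n_distinct)
})

test_that("phased VCF parses with letter and code allele coding", {
  f <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1",
    "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0|1"))
  g <- read_phased_vcf(f, convert_letter = TRUE)
  expect_equal(unname(g$hap1[1, 1]), "A")
  expect_equal(unname(g$hap2[1, 1]), "G")
  gc <- read_phased_vcf(f, convert_letter = FALSE)
  expect_equal(unname(gc$hap1[1, 1]), "0")
  expect_equal(unname(gc$hap2[1, 1]), "1")
})

test_that("unphased and multi-allelic sites are rejected by name", {
  f <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1",
    "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/1"))
  expect_error(read_phased_vcf(f), "unphased.*1:100")
  f2 <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1",
    "1\t200\ts2\tA\tG,T\t.\tPASS\t.\tGT\t0|1"))
  expect_error(read_phased_vcf(f2), "multi-allelic.*1:200")
})

test_that("fixture VCF reconstructs the generator's allele draws exactly", {
  fx <- get_fixture()
  g <- read_phased_vcf(fx$files$phased_vcf, convert_letter = TRUE)
  led <- fx$ledger$haplotype
  win <- led$window_snps
  h <- get_haplotype(g, win)
  expect_equal(setNames(h$haplotype$count, h$haplotype$haplotype),
               unlist(led$hap_counts)[h$haplotype$haplotype])
})
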