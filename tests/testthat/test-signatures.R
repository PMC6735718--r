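intra_seg <- function(cigar, ref_start = 999L) {
  make_segment(ref_start = ref_start, ref_end = ref_start + 1L,
               read_start = 0L, read_end = 1L, cigar = cigar)
}

test_that("CIGAR gaps yield intra-alignment signatures", {
  del <- extract_intra_signatures(intra_seg("100M200D100M"))
  expect_equal(del[, c("sig_type", "begin", "end", "evidence_class")],
               data.frame(sig_type = "DEL", begin = 1099L, end = 1299L,
                          evidence_class = "intra"))

  ins <- extract_intra_signatures(intra_seg("100M150I100M"))
  expect_equal(ins$sig_type, "INS")
  expect_equal(c(ins$begin, ins$end), c(1099L, 1249L))

  # below threshold
  expect_equal(nrow(extract_intra_signatures(intra_seg("100M30D100M"))), 0L)
  # gap-free
  expect_equal(nrow(extract_intra_signatures(intra_seg("300M"))), 0L)
})

test_that("shattered same-type gaps merge within tolerance", {
  # two D runs split by 5 aligned bases act as one 200 bp deletion
  merged <- extract_intra_signatures(intra_seg("100M120D5M80D100M"))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$begin, merged$end), c(1099L, 1304L))

  # separation beyond tolerance: two independent sub-threshold runs vanish
  apart <- extract_intra_signatures(intra_seg("100M40D50M40D100M"))
  expect_equal(nrow(apart), 0L)

  # multiple independent gaps each keep their own coordinates
  multi <- extract_intra_signatures(intra_seg("100M133D100M315D100M"))
  expect_equal(multi$begin, c(1099L, 1332L))
  expect_equal(multi$end, c(1232L, 1647L))
})

test_that("split-alignment pairs yield DEL, INS and TAN signatures", {
  p <- sv_params()
  # reference gap with contiguous read: deletion over the gap
  del <- extract_inter_signatures(rbind(
    make_segment(ref_start = 1000, ref_end = 2000, read_start = 0,
                 read_end = 1000),
    make_segment(ref_start = 2300, ref_end = 3300, read_start = 1000,
                 read_end = 2000)), p)
  expect_equal(del$sig_type, "DEL")
  expect_equal(c(del$begin, del$end), c(2000L, 2300L))
  expect_equal(del$evidence_class, "inter")

  # read gap with contiguous reference: insertion at the junction
  ins <- extract_inter_signatures(rbind(
    make_segment(ref_start = 1000, ref_end = 2000, read_start = 0,
                 read_end = 1000),
    make_segment(ref_start = 2000, ref_end = 3000, read_start = 1400,
                 read_end = 2400)), p)
  expect_equal(ins$sig_type, "INS")
  expect_equal(c(ins$begin, ins$end), c(2000L, 2400L))

  # backward jump on the reference: tandem duplication
  tan <- extract_inter_signatures(rbind(
    make_segment(ref_start = 1000, ref_end = 2000, read_start = 0,
                 read_end = 1000),
    make_segment(ref_start = 1200, ref_end = 2200, read_start = 1000,
                 read_end = 2000)), p)
  expect_equal(tan$sig_type, "TAN")
  expect_equal(c(tan$begin, tan$end), c(1200L, 2000L))

  # single segment: nothing
  expect_equal(nrow(extract_inter_signatures(
    make_segment(ref_start = 0, ref_end = 100, read_start = 0,
                 read_end = 100), p)), 0L)
})

test_that("inverted middle segment yields an INV signature", {
  segs <- rbind(
    make_segment(ref_start = 1000, ref_end = 2000, read_start = 0,
                 read_end = 1000),
    make_segment(ref_start = 2000, ref_end = 2600, read_start = 1000,
                 read_end = 1600, strand = "-"),
    make_segment(ref_start = 2600, ref_end = 3600, read_start = 1600,
                 read_end = 2600))
  inv <- extract_inter_signatures(segs, sv_params())
  expect_equal(inv$sig_type, "INV")
  expect_equal(c(inv$begin, inv$end), c(2000L, 2600L))
})

test_that("duplication transit yields a DUP signature with genomic origin", {
  segs <- rbind(
    make_segment(chrom = "chr2", ref_start = 4000, ref_end = 5000,
                 read_start = 0, read_end = 1000),
    make_segment(chrom = "chr5", ref_start = 100, ref_end = 600,
                 read_start = 1000, read_end = 1500),
    make_segment(chrom = "chr2", ref_start = 5000, ref_end = 6000,
                 read_start = 1500, read_end = 2500))
  dup <- extract_inter_signatures(segs, sv_params())
  expect_equal(dup$sig_type, "DUP")
  expect_equal(c(dup$chrom, dup$begin, dup$end), c("chr2", "5000", "5500"))
  expect_equal(c(dup$origin_chrom, dup$origin_begin, dup$origin_end),
               c("chr5", "100", "600"))
})

test_that("distant two-segment junctions yield one breakend per side", {
  segs <- rbind(
    make_segment(chrom = "chr2", ref_start = 4000, ref_end = 5000,
                 read_start = 0, read_end = 1000),
    make_segment(chrom = "chr5", ref_start = 100, ref_end = 600,
                 read_start = 1000, read_end = 1500))
  brk <- extract_inter_signatures(segs, sv_params())
  expect_equal(brk$sig_type, c("BRK", "BRK"))
  expect_equal(brk$begin, brk$end)  # zero span by definition
  expect_equal(brk$chrom, c("chr2", "chr5"))
  expect_equal(brk$mate_chrom, c("chr5", "chr2"))
  expect_equal(brk$begin, c(5000L, 100L))
  expect_equal(brk$mate_pos, c(100L, 5000L))

  # nearby same-chromosome junction: alignment jitter, no breakend
  near <- extract_inter_signatures(rbind(
    make_segment(ref_start = 1000, ref_end = 2000, read_start = 0,
                 read_end = 1000, strand = "+"),
    make_segment(ref_start = 2010, ref_end = 3000, read_start = 1000,
                 read_end = 1990, strand = "-")), sv_params())
  expect_equal(nrow(near), 0L)
})

test_that("intra and inter representations of one deletion agree", {
  p <- sv_params()
  intra <- extract_intra_signatures(intra_seg("1000M300D1000M", 999L))
  inter <- extract_inter_signatures(rbind(
    make_segment(ref_start = 999, ref_end = 1999, read_start = 0,
                 read_end = 1000),
    make_segment(ref_start = 2299, ref_end = 3299, read_start = 1000,
                 read_end = 2000)), p)
  expect_equal(intra[, c("sig_type", "begin", "end")],
               inter[, c("sig_type", "begin", "end")])
})

test_that("collect_signatures concatenates deterministically and bounds size", {
  segs <- rbind(
    make_segment(ref_start = 999, ref_end = 2299, read_start = 0,
                 read_end = 1100, read_name = "a", cigar = "500M200D600M"),
    make_segment(ref_start = 999, ref_end = 2299, read_start = 0,
                 read_end = 1100, read_name = "b", cigar = "500M200D600M"))
  sigs <- collect_signatures(group_segments_by_read(segs))
  expect_equal(nrow(sigs), 2L)
  expect_equal(unique(sigs$sig_type), "DEL")
  expect_equal(sigs$read_name, c("a", "b"))  # sorted output
  expect_true(all(sigs$end - sigs$begin >= 50 | sigs$sig_type == "BRK"))

  # over-fragmented reads are dropped with a warning
  many <- do.call(rbind, lapply(0:11, function(i) {
    make_segment(ref_start = 50000 * i, ref_end = 50000 * i + 1000,
                 read_start = 1000 * i, read_end = 1000 * (i + 1),
                 read_name = "frag")
  }))
  expect_warning(out <- collect_signatures(group_segments_by_read(many)),
                 "skipped")
  expect_equal(nrow(out), 0L)
})
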