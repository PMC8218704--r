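test_that("capture BED loads, merges, and uses half-open membership", {
  bed <- write_bed("chr1", 100L, 200L)
  cap <- load_capture_bed(bed)
  expect_true(capture_contains(cap, "chr1", 150L))
  expect_false(capture_contains(cap, "chr1", 200L))  # end coordinate excluded
  expect_false(capture_contains(cap, "chr1", 99L))
  expect_false(capture_contains(cap, "chr9", 150L))  # unknown contig

  # overlapping intervals merge to one; membership matches a brute-force scan
  bed2 <- write_bed(c("chr1", "chr1", "chr1"), c(100L, 150L, 400L),
                    c(250L, 300L, 500L))
  cap2 <- load_capture_bed(bed2)
  expect_equal(nrow(cap2), 2)
  raw <- data.frame(start0 = c(100, 150, 400), end0 = c(250, 300, 500))
  for (p in seq(90L, 510L, by = 7L)) {
    brute <- any(raw$start0 <= p & p < raw$end0)
    expect_equal(unname(capture_contains(cap2, "chr1", p)), brute)
  }

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\tnot_a_number\t300"), bad)
  expect_error(load_capture_bed(bad), "line 2", class = "ddctdna_format_error")
})

test_that("each rejection rule fires on its constructed candidate", {
  res <- test_resources()
  keep <- function(cand) filter_candidates(cand, res)
  # fully supported in-capture candidate is retained with the full pass list
  ok <- keep(base_candidate())
  expect_equal(nrow(ok$retained), 1)
  expect_equal(nrow(ok$rejected), 0)
  expect_match(ok$retained$passed_filters, "read_support")

  checks <- list(
    list(cand = base_candidate(reads5 = 2L), rule = "read_support"),
    list(cand = base_candidate(reads3 = 2L), rule = "read_support"),
    list(cand = base_candidate(pos5 = 900L, pos3 = 5000L), rule = "capture_membership"),
    list(cand = base_candidate(contig5 = "chr1", pos5 = 4993L),  # 7 bp away
         rule = "blocklisted_position"),
    list(cand = base_candidate(gene5 = "FGFR3", gene3 = "TACC3"), rule = "blocklisted_pair"),
    list(cand = base_candidate(gene5 = "TACC3", gene3 = "FGFR3"), rule = "blocklisted_pair"),
    list(cand = base_candidate(gene5 = "ETV6", gene3 = "ETV6"), rule = "intragenic"),
    list(cand = base_candidate(homology = 11L), rule = "homology"))
  for (ch in checks) {
    out <- keep(ch$cand)
    expect_equal(nrow(out$retained), 0)
    expect_true(grepl(ch$rule, out$rejected$failed_rules[1]))
  }
  # boundary cases that must be KEPT
  expect_equal(nrow(keep(base_candidate(reads5 = 3L, reads3 = 3L))$retained), 1)
  expect_equal(nrow(keep(base_candidate(homology = 10L))$retained), 1)
  # 11 bp from the blocklisted position: outside tolerance, but the
  # breakpoint must still sit in capture at one end
  eleven <- base_candidate(contig3 = "chr1", pos3 = 5011L)
  expect_equal(nrow(keep(eleven)$retained), 1)
  # one end off-panel suffices to keep
  one_out <- base_candidate(pos3 = 5000L)
  expect_equal(nrow(keep(one_out)$retained), 1)
})

test_that("rejections report the first failing rule and all failing rules", {
  res <- test_resources()
  multi <- base_candidate(reads5 = 1L, gene5 = "NTRK3", homology = 50L)
  out <- filter_candidates(multi, res)
  expect_equal(out$rejected$reason, "read_support")
  expect_true(all(c("read_support", "intragenic", "homology") %in%
                  strsplit(out$rejected$failed_rules, ",")[[1]]))
})

test_that("filtering is idempotent, order-independent and monotone", {
  res <- test_resources()
  set.seed(31)
  n <- 40
  cands <- fusion_candidates(
    gene5 = sample(c("ETV6", "FGFR3", "NTRK3"), n, TRUE),
    gene3 = sample(c("NTRK3", "TACC3", "ETV6"), n, TRUE),
    contig5 = sample(c("chr12", "chr1"), n, TRUE),
    pos5 = sample(c(150L, 900L, 4995L), n, TRUE),
    contig3 = sample(c("chr15", "chr2"), n, TRUE),
    pos3 = sample(c(1150L, 7000L), n, TRUE),
    reads5 = sample(0:30, n, TRUE), reads3 = sample(0:30, n, TRUE),
    homology = sample(0:20, n, TRUE))
  once <- filter_candidates(cands, res)
  twice <- filter_candidates(
    fusion_candidates(once$retained$gene5, once$retained$gene3,
                      once$retained$contig5, once$retained$pos5,
                      once$retained$contig3, once$retained$pos3,
                      once$retained$reads5, once$retained$reads3,
                      once$retained$homology), res)
  expect_equal(nrow(twice$retained), nrow(once$retained))
  expect_equal(nrow(twice$rejected), 0)

  perm <- cands[sample(n), ]
  out_perm <- filter_candidates(perm, res)
  key <- function(df) sort(paste(df$gene5, df$gene3, df$pos5, df$pos3,
                                 df$reads5, df$reads3, df$homology))
  expect_equal(key(out_perm$retained), key(once$retained))

  # tightening thresholds never grows the retained set
  tighter_reads <- filter_candidates(cands, res, min_reads = 10)
  expect_true(all(key(tighter_reads$retained) %in% key(once$retained)))
  tighter_hom <- filter_candidates(cands, res, max_homology = 3)
  expect_true(all(key(tighter_hom$retained) %in% key(once$retained)))
})

test_that("BEDPE-like candidate tables read with 1-based breakpoints", {
  df <- data.frame(chrom1 = "chr12", start1 = 149L, end1 = 150L,
                   chrom2 = "chr15", start2 = 1149L, end2 = 1150L,
                   gene5 = "ETV6", gene3 = "NTRK3",
                   reads5 = 23L, reads3 = 23L, homology = 5L)
  p <- write_tsv(df)
  cands <- read_fusion_candidates(p)
  expect_equal(cands$pos5, 150L)  # BEDPE start + 1
  expect_equal(cands$pos3, 1150L)
  out <- filter_candidates(cands, test_resources())
  expect_equal(nrow(out$retained), 1)

  df$reads5 <- NULL
  expect_error(read_fusion_candidates(write_tsv(df)), "reads5",
               class = "ddctdna_format_error")
})
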