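make_site <- function(mirna) revcomp(mirna)

mutate_at <- function(s, pos, to) {
  substr(s, pos, pos) <- to
  s
}

test_that("expectation score reproduces the worked penalties", {
  m <- "TTGACAGAAGATAGAGAGCAC"       # 21 nt
  expect_identical(expectation_score(m, make_site(m)), 0)

  # one G:U wobble at miRNA position 10 (seed region, weight 2)
  site <- make_site(m)
  p <- 10
  i <- 21 - p + 1
  b <- substring(m, p, p)
  wob <- if (b == "G") "T" else "G"   # position 10 of m is G
  expect_identical(expectation_score(m, mutate_at(site, i, wob)), 1.0)

  # two mismatches at positions 15 and 18 (outside the seed, weight 1)
  site2 <- make_site(m)
  for (p in c(15, 18)) {
    i <- 21 - p + 1
    site2 <- mutate_at(site2, i, "A")  # m[15]=A, m[18]=G: neither pairs A
  }
  expect_identical(expectation_score(m, site2), 2.0)
})

test_that("expectation score increases when a match becomes a mismatch", {
  set.seed(411)
  for (rep in 1:10) {
    m <- random_dna(21)
    site <- make_site(m)
    e0 <- expectation_score(m, site)
    p <- sample(14:21, 1)              # outside seed, weight 1
    i <- 21 - p + 1
    cur <- substring(site, i, i)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(cur, chartr("ACGT", "TGCA", substring(m, p, p)),
                     if (substring(m, p, p) %in% c("G", "T"))
                       chartr("GT", "TG", substring(m, p, p))))
    e1 <- expectation_score(m, mutate_at(site, i, bad[1]))
    expect_gt(e1, e0)
  }
})

test_that("ungapped scan scores agree with position-by-position oracle", {
  set.seed(412)
  m <- random_dna(21)
  tx <- paste0(random_dna(40), revcomp(m), random_dna(40))
  hits <- scan_transcriptome(setNames(m, "mi"), setNames(tx, "tx"),
                             e_cutoff = 3.0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$expectation_E, 0)
  expect_identical(hits$start, 40L)
  expect_identical(hits$end, 61L)
  # equal-length scoring is the ungapped alignment: position-by-position
  # oracle agreement over many windows
  for (o in seq(0, nchar(tx) - 21, by = 7)) {
    win <- substring(tx, o + 1, o + 21)
    expect_identical(expectation_score(m, win),
                     oracle_expectation_ungapped(m, win))
  }
})

test_that("E cutoff is strict and overlapping windows merge to minimum E", {
  m <- "TTGACAGAAGATAGAGAGCAC"
  # a site with E exactly 3.0 must be excluded: 3 mismatches outside seed
  site <- make_site(m)
  for (p in c(14, 16, 18)) site <- mutate_at(site, 21 - p + 1, "G")
  expect_identical(expectation_score(m, site), 3.0)
  tx <- paste0(strrep("A", 30), site, strrep("A", 30))
  hits <- scan_transcriptome(setNames(m, "mi"), setNames(tx, "tx"),
                             e_cutoff = 3.0, methods = "expectation")
  expect_identical(nrow(hits), 0L)
})

test_that("MFE/MDE ratio reproduces the worked energies", {
  m <- paste0(strrep("G", 6), strrep("C", 6), strrep("A", 5), strrep("T", 4))
  hr <- hybrid_ratio(m, make_site(m))
  expect_identical(hr$mde, -54)           # 12 G/C x -3 + 9 A/U x -2
  expect_identical(hr$ratio, 1)
  expect_true(hr$pass)

  # lose one A:U pair -> MFE -52, ratio 0.963
  s <- mutate_at(make_site(m), 21 - 15 + 1, "C")
  hr2 <- hybrid_ratio(m, s)
  expect_identical(hr2$mfe, -52)
  expect_equal(hr2$ratio, 52 / 54, tolerance = 1e-12)
  expect_true(hr2$pass)

  # a duplex retaining about half its energy fails the 0.75 cutoff
  s3 <- make_site(m)
  for (p in c(2, 4, 6, 8, 10, 12)) s3 <- mutate_at(s3, 21 - p + 1, "A")
  hr3 <- hybrid_ratio(m, s3)
  expect_lt(hr3$ratio, 0.75)
  expect_false(hr3$pass)
})

test_that("method integration builds overall and overlap datasets", {
  preds <- data.frame(
    mirna_id = c("m1", "m1", "m2"),
    transcript_id = c("t1", "t2", "t3"),
    start = c(0L, 5L, 9L), end = c(21L, 26L, 30L),
    expectation_E = c(0, 1, 2), mfe = c(-50, -40, -30),
    ratio = c(1, 0.9, 0.5),
    methods = c("expectation,hybrid", "expectation", "expectation"),
    mde = c(-50, -50, -52), stringsAsFactors = FALSE)
  deg <- data.frame(mirna_id = c("m2", "m9"),
                    transcript_id = c("t3", "t9"),
                    category = c(0L, 1L), stringsAsFactors = FALSE)
  out <- integrate_methods(preds, deg)
  key <- paste(out$mirna_id, out$transcript_id)
  # two computational methods -> overlap
  expect_true(out$in_overlap[key == "m1 t1"])
  # one computational method only -> overall but not overlap
  expect_true(out$in_overall[key == "m1 t2"])
  expect_false(out$in_overlap[key == "m1 t2"])
  # degradome confirmation promotes to overlap
  expect_true(out$in_overlap[key == "m2 t3"])
  # degradome-only pair appended, in both datasets
  expect_true(all(out$in_overall[key == "m9 t9"]))
  expect_true(all(out$in_overlap[key == "m9 t9"]))
  # overlap is always a subset of overall
  expect_true(all(!out$in_overlap | out$in_overall))
})
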