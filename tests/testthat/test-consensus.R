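test_that("within-caller merging respects the strict shorter-call rule", {
  # overlap 60 of shorter length 100 -> 60% > 50%: merge to the union
  m <- merge_within_caller(mk_calls(c(100, 140), c(200, 240)))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 240))

  # overlap exactly 50 of 100: not more than half, kept separate
  m <- merge_within_caller(mk_calls(c(100, 150), c(200, 250)))
  expect_equal(nrow(m), 2)

  one <- mk_calls(100, 200)
  expect_equal(merge_within_caller(one), one)

  mixed <- rbind(mk_calls(0, 100, sample = "S1"), mk_calls(0, 100, sample = "S2"))
  expect_error(merge_within_caller(mixed), "single sample")
})

test_that("merging is idempotent and order-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    calls <- random_calls(15)
    m1 <- merge_within_caller(calls)
    expect_equal(merge_within_caller(m1), m1)
    shuf <- calls[sample(nrow(calls)), ]
    expect_equal(merge_within_caller(shuf), m1)
  }
})

test_that("cross-caller support keeps primaries by overlap of their length", {
  primary <- mk_calls(1000, 2000)
  # 600/1000 = 60% of the primary -> kept
  sup <- mk_calls(1400, 2100, caller = "pindel")
  expect_equal(nrow(cross_caller_support(primary, sup)), 1)
  # 50/1000 = 5% -> dropped
  sup <- mk_calls(1950, 3000, caller = "pindel")
  expect_equal(nrow(cross_caller_support(primary, sup)), 0)
  # type mismatch at identical span -> dropped
  sup <- mk_calls(1000, 2000, svtype = "DUP", caller = "delly")
  expect_equal(nrow(cross_caller_support(primary, sup)), 0)
  # sample mismatch -> dropped
  sup <- mk_calls(1000, 2000, sample = "S2", caller = "delly")
  expect_equal(nrow(cross_caller_support(primary, sup)), 0)
  # no supporting calls at all -> empty, with a message
  expect_message(out <- cross_caller_support(primary, primary[0, ]),
                 "dropped")
  expect_equal(nrow(out), 0)
})

test_that("filters remove short, sex-linked, masked and ubiquitous calls", {
  layout <- mk_layout()
  short <- mk_calls(100, 500)                       # 400 bp
  kept <- mk_calls(10000, 11000)
  sex <- mk_calls(1000, 3000, chrom = "groupXIX")
  out <- apply_filters(rbind(short, kept, sex), NULL, layout, n_samples = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 10000)
  expect_equal(attr(out, "removed")[["short"]], 1)
  expect_equal(attr(out, "removed")[["sex_chromosome"]], 1)

  # 600 of 1000 bp in the mask (60% > 50%) -> removed
  mask <- data.frame(chrom = "groupI", start = 10000, end = 10600)
  out <- apply_filters(kept, mask, layout, n_samples = 2)
  expect_equal(nrow(out), 0)
  # 400 of 1000 bp (40%) -> kept
  mask <- data.frame(chrom = "groupI", start = 10000, end = 10400)
  out <- apply_filters(kept, mask, layout, n_samples = 2)
  expect_equal(nrow(out), 1)

  # identical call in every sample -> removed; in n-1 samples -> kept
  all3 <- do.call(rbind, lapply(c("S1", "S2", "S3"), function(s)
    mk_calls(20000, 22000, sample = s)))
  expect_equal(nrow(apply_filters(all3, NULL, layout, n_samples = 3)), 0)
  expect_equal(nrow(apply_filters(all3[1:2, ], NULL, layout, n_samples = 3)), 2)
})

test_that("filtering never increases the call count", {
  set.seed(7)
  layout <- mk_layout()
  for (rep in 1:10) {
    calls <- rbind(random_calls(10, sample = "S1"),
                   random_calls(10, sample = "S2"))
    mask <- data.frame(chrom = "groupI",
                       start = s <- sort(sample.int(40000, 5)),
                       end = s + 1500)
    out <- apply_filters(calls, mask, layout, n_samples = 2)
    expect_lte(nrow(out), nrow(calls))
  }
})

test_that("region delineation unions overlapping calls across types", {
  calls <- rbind(mk_calls(0, 1000, sample = "A"),
                 mk_calls(500, 1500, svtype = "DUP", sample = "B"))
  r <- delineate_regions(calls)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 1500))
  expect_equal(r$svtypes[[1]], c("DEL", "DUP"))
  expect_equal(r$carriers[[1]], c("A", "B"))

  disjoint <- mk_calls(c(0, 5000), c(1000, 6000))
  expect_equal(nrow(delineate_regions(disjoint)), 2)

  # book-ended: zero-base overlap under the half-open convention
  booked <- mk_calls(c(0, 500), c(500, 900))
  expect_equal(nrow(delineate_regions(booked)), 2)
})

test_that("regions cover exactly the union of call bases and are disjoint", {
  set.seed(11)
  for (rep in 1:10) {
    calls <- rbind(random_calls(12, sample = "S1"),
                   random_calls(12, sample = "S2", svtype = "DUP"))
    r <- delineate_regions(calls)
    # disjoint and sorted
    by_chrom <- split(r, r$chrom)
    for (p in by_chrom) {
      if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
    }
    expect_equal(sum(r$end - r$start),
                 sum(IRanges::width(IRanges::reduce(
                   IRanges::IRanges(calls$start + 1, calls$end),
                   min.gapwidth = 0L))))
  }
})

test_that("individual sharing requires reciprocal overlap and is symmetric", {
  a <- mk_calls(0, 1000)
  b <- mk_calls(400, 1400, sample = "S2")
  expect_equal(nrow(shared_between(a, b)), 1)

  big <- mk_calls(0, 5000, sample = "S2")
  expect_equal(nrow(shared_between(a, big)), 0)   # 100% vs 20%: fails

  expect_equal(nrow(shared_between(a, mk_calls(0, 1000, sample = "S2"))), 1)

  set.seed(3)
  for (rep in 1:10) {
    x <- random_calls(8, sample = "A")
    y <- random_calls(8, sample = "B")
    expect_equal(nrow(shared_between(x, y)), nrow(shared_between(y, x)))
  }
})
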