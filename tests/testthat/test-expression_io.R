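write_toy_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("chromosome\tstart\tend\tvalue", rows), path)
  path
}

test_that("expression tables parse, sort and validate", {
  p <- write_toy_table(c("chr1\t0\t150000\t2.0",
                         "chr1\t300000\t450000\t5.0",
                         "chr1\t150000\t300000\t0.0"))
  prof <- read_expression_table(p)
  expect_s3_class(prof, "expression_profile")
  expect_equal(nrow(prof$bins), 3)
  expect_equal(prof$bins$level, c(2, 0, 5))   # sorted by start
  expect_true(!is.unsorted(prof$bins$start))

  overlap <- write_toy_table(c("chr1\t0\t200000\t1", "chr1\t100000\t300000\t2"))
  expect_error(read_expression_table(overlap), "[Oo]verlap")

  neg <- write_toy_table(c("chr1\t0\t150000\t-1"))
  expect_error(read_expression_table(neg), "egative")

  malformed <- write_toy_table(c("chr1\t0\tnot_a_number\t1"))
  expect_error(read_expression_table(malformed), "line")

  multi <- write_toy_table(c("chr1\t0\t150000\t1", "chr2\t0\t150000\t1"))
  expect_error(read_expression_table(multi), "several chromosomes")
  expect_equal(read_expression_table(multi, "chr2")$chromosome, "chr2")
  expect_error(read_expression_table(multi, "chrX"), "no rows")
})

test_that("binning to monomers is length-weighted and gives published chain lengths", {
  p <- write_toy_table(c("chr1\t0\t150000\t2.0",
                         "chr1\t150000\t300000\t0.0",
                         "chr1\t300000\t450000\t5.0"))
  prof <- read_expression_table(p)
  b <- bin_to_monomers(prof, 450000)
  expect_equal(b$levels, c(2, 0, 5))

  # a single 300 kb source bin covers two monomers
  p2 <- write_toy_table("chrA\t0\t300000\t4")
  b2 <- bin_to_monomers(read_expression_table(p2), 300000)
  expect_equal(b2$levels, c(4, 4))

  # chromosome 1 (~245.1 Mb) and chromosome 11 (~134.85 Mb) at 150 kb
  expect_equal(length(bin_to_monomers(prof, 245.1e6)$levels), 1634)
  expect_equal(length(bin_to_monomers(prof, 134.85e6)$levels), 899)

  # monomers with no data are unexpressed
  expect_equal(bin_to_monomers(read_expression_table(p2), 600000)$levels,
               c(4, 4, 0, 0))

  # partial overlap: bin [0,75k) level 8 on monomer 1 -> weighted mean 8
  p3 <- write_toy_table("chrA\t0\t75000\t8")
  expect_equal(bin_to_monomers(read_expression_table(p3), 300000)$levels, c(8, 0))
})

test_that("binning conserves length-weighted total expression on exact tilings", {
  set.seed(5)
  for (rep in 1:20) {
    nb <- sample(3:12, 1)
    width <- 150000
    lv <- runif(nb, 0, 10)
    rows <- sprintf("chrT\t%d\t%d\t%.15g", (0:(nb - 1)) * width, (1:nb) * width, lv)
    prof <- read_expression_table(write_toy_table(rows))
    b <- bin_to_monomers(prof, nb * width)
    expect_equal(sum(b$levels) * width, sum(lv * width), tolerance = 1e-10)
  }
})

test_that("synthetic profiles are block-structured, labelled and deterministic", {
  one <- synth_expression_profile(10, data.frame(start = 1, end = 10, level = 3))
  expect_equal(one$expression$levels, rep(3, 10))

  two <- synth_expression_profile(
    100, data.frame(start = c(1, 51), end = c(50, 100), level = c(10, 1)))
  expect_equal(two$regions$label, c("high", "low"))
  expect_equal(two$regions$start, c(1L, 51L))
  expect_equal(two$regions$end, c(50L, 100L))

  blocks <- data.frame(start = c(1, 41), end = c(40, 100), level = c(8, 0.5))
  a <- synth_expression_profile(100, blocks, noise_sd = 1, seed = 99)
  b <- synth_expression_profile(100, blocks, noise_sd = 1, seed = 99)
  expect_identical(a, b)

  expect_error(synth_expression_profile(
    50, data.frame(start = c(1, 20), end = c(25, 40), level = c(1, 2))),
    "verlap")
  expect_error(synth_expression_profile(
    50, data.frame(start = 0, end = 10, level = 1)), "start")
})

test_that("synthetic profiles satisfy the profile invariants over many draws", {
  set.seed(31)
  for (rep in 1:1000) {
    n <- sample(8:60, 1)
    k <- sample(1:3, 1)
    bounds <- sort(sample(seq_len(n), 2 * k))
    blocks <- data.frame(start = bounds[seq(1, 2 * k, 2)],
                         end = bounds[seq(2, 2 * k, 2)],
                         level = runif(k, 0, 20))
    out <- synth_expression_profile(n, blocks, noise_sd = runif(1, 0, 3))
    lv <- out$expression$levels
    expect_length(lv, n)
    expect_true(all(is.finite(lv)) && all(lv >= 0))
    expect_true(all(out$regions$start >= 1 & out$regions$end <= n))
    expect_true(all(out$regions$label %in% c("high", "low")))
  }
})

test_that("affinity mapping anchors the expression extremes and is linear", {
  a <- affinity_profile(c(0, 10), a_min = 0.01, a_max = 0.07)
  expect_equal(a$affinities, c(0.07, 0.01))

  # midpoint expression maps to midpoint affinity
  a2 <- affinity_profile(c(0, 5, 10), a_min = 0.01, a_max = 0.07)
  expect_equal(a2$affinities[2], 0.04)

  # homogeneous fibre
  a3 <- affinity_profile(c(1, 7, 3), a_min = 0.05, a_max = 0.05)
  expect_equal(a3$affinities, rep(0.05, 3))

  expect_error(affinity_profile(c(2, 2, 2), 0.01, 0.07), "identical")
  expect_error(affinity_profile(c(0, 1), a_min = -0.1, a_max = 0.5))
  expect_error(affinity_profile(c(0, 1), a_min = 0.5, a_max = 0.2))
})

test_that("affinity never increases with expression", {
  set.seed(8)
  for (rep in 1:50) {
    e <- runif(sample(3:40, 1), 0, 50)
    a <- affinity_profile(e, 0.01, 0.065)$affinities
    ord <- order(e)
    expect_true(all(diff(a[ord]) <= 1e-12))
  }
})

test_that("region BED files round-trip through monomer indices", {
  regions <- data.frame(label = c("high", "low"), start = c(1L, 51L),
                        end = c(50L, 100L))
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(regions, bed, "chrS", 150000L)
  back <- read_regions_bed(bed, 100, 150000L)
  expect_equal(back, regions)
  # any-overlap: a region touching 1 bp of a monomer claims it
  writeLines("chrS\t140000\t160000\thigh", bed)
  r <- read_regions_bed(bed, 100, 150000L)
  expect_equal(r$start, 1L)
  expect_equal(r$end, 2L)
})
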