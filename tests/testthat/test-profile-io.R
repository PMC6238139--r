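test_that("bedGraph records expand to per-bp counts with validation", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t3\t5.0", "chr1\t3\t5\t2"), f)
  tr <- read_bedgraph(f)
  expect_equal(tr$counts, c(5, 5, 5, 2, 2))
  expect_equal(c(tr$start_bp, tr$end_bp), c(0, 5))

  # brute-force per-bp fill oracle on scattered records
  f2 <- withr::local_tempfile(fileext = ".bedgraph")
  set.seed(2)
  starts <- c(0, 10, 25, 60); ends <- starts + c(10, 5, 20, 7)
  vals <- c(3, 0, 8, 1)
  writeLines(sprintf("chrZ\t%d\t%d\t%g", starts, ends, vals), f2)
  expected <- numeric(67)
  for (i in seq_along(starts)) expected[(starts[i] + 1):ends[i]] <- vals[i]
  expect_equal(read_bedgraph(f2, start_bp = 0, end_bp = 67)$counts, expected)

  f3 <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(character(0), f3)
  expect_equal(length(read_bedgraph(f3)$counts), 0)

  f4 <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t3\t5", "chr1\t2\t6\t1"), f4)
  expect_error(read_bedgraph(f4), "overlap.*line 2")
  f5 <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t3\t5", "chr1\t4\tx\t1"), f5)
  expect_error(read_bedgraph(f5), "line 2")
})

test_that("bedGraph write/read roundtrip is lossless for integer counts", {
  set.seed(9)
  tr <- coverage_track("c", 100, 400, rpois(300, 4))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, start_bp = 100, end_bp = 400)
  expect_identical(back$counts, tr$counts)
})

test_that("input normalization scales by the read-total ratio", {
  ip <- coverage_track("c", 0, 4, c(1, 2, 3, 4))      # total 10
  inp <- coverage_track("c", 0, 4, c(1, 1, 1, 1))     # total 4
  expect_equal(normalize_input(ip, inp)$counts, rep(2.5, 4))
  expect_equal(normalize_input(ip, ip)$counts, ip$counts)
  inp2 <- coverage_track("c", 0, 4, 2 * ip$counts)    # 2x IP total
  expect_equal(normalize_input(ip, inp2)$counts, ip$counts)
  expect_error(normalize_input(ip, coverage_track("c", 0, 4, rep(0, 4))),
               "zero total")
})

test_that("background estimation takes the median of the distal flanks", {
  site <- pars_site(49990, 50010, center_bp = 50000)
  flat <- coverage_track("c", 0, 100000, rep(10, 100000))
  expect_equal(estimate_background(flat, site), 10)
  peaked <- flat
  peaked$counts[45000:55000] <- 500    # inside the exclusion zone
  expect_equal(estimate_background(peaked, site), 10)
  # mixed flanks: brute-force median of concatenated flank values
  mixed <- flat
  mixed$counts <- rep(c(4, 6, 11), length.out = 100000)
  pos <- 0:99999
  keep <- abs(pos - 50000) > 25000
  expect_equal(estimate_background(mixed, site),
               median(mixed$counts[keep]))
  small <- coverage_track("c", 49000, 51000, rep(1, 2000))
  expect_error(estimate_background(small, site), "exclusion")
})

test_that("decay profiles subtract background and anchor at the repeat edge", {
  site <- pars_site(5000, 5160, center_bp = 5080)
  counts <- rep(7, 20000)
  counts[5161] <- 107                       # bp 5160 = first bp downstream
  tr <- coverage_track("c", 0, 20000, counts)
  prof <- make_decay_profile(tr, site, background = 7, side = "right")
  expect_equal(prof$density[1], 1)
  expect_equal(prof$offsets_bp[1], 0)
  expect_equal(prof$anchor_bp, 5160)
  expect_true(all(prof$density[-1] == 0))

  # synthetic roundtrip: counts from the occupancy law recover its shape
  pos <- 0:19999
  dens <- nc_density(pmax(0, pos - 5080), fp)
  tr2 <- coverage_track("c", 0, 20000, dens * 200 + 7)
  prof2 <- make_decay_profile(tr2, site, background = 7, side = "right")
  expected <- nc_density(pos[pos >= 5160] - 5080, fp)
  expect_equal(prof2$density, expected / expected[1], tolerance = 1e-9)

  # the two anchor conventions differ by exactly 1 bp
  profM <- make_decay_profile(tr2, site, background = 7, side = "right",
                              anchor_convention = "last_repeat_bp")
  expect_equal(profM$anchor_bp, 5159)

  # asymmetric repeats: left and right anchors differ
  profL <- make_decay_profile(tr2, site, background = 7, side = "left")
  expect_equal(profL$anchor_bp, 4999)
  expect_equal(profL$offsets_bp[1], 0)
  expect_error(make_decay_profile(tr, site, background = 200), "background")
})

test_that("least-squares rescaling recovers amplitude factors", {
  s <- 0:5000
  ref <- binding_profile(s, nc_density(s, fp))
  tenth <- binding_profile(s, nc_density(s, fp) / 10)
  expect_equal(rescale_overlap(tenth, ref), 10, tolerance = 1e-12)
  expect_equal(rescale_overlap(ref, ref), 1, tolerance = 1e-12)
  set.seed(4)
  noisy <- binding_profile(s, pmax(0, nc_density(s, fp) / 10 +
                                     rnorm(length(s), 0, 1e-3)))
  expect_equal(rescale_overlap(noisy, ref), 10, tolerance = 0.05)
  zero <- binding_profile(s, rep(0, length(s)))
  expect_error(rescale_overlap(zero, ref), "zero")
})

test_that("correlation formula reproduces Pearson r with its invariances", {
  expect_equal(correlate(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-7)
  x <- c(0.2, 0.5, 0.9, 0.4); y <- c(1, 0.3, 0.8, 0.2)
  expect_equal(correlate(x, y), cor(x, y), tolerance = 1e-12)  # oracle
  expect_equal(correlate(x, x), 1)
  expect_equal(correlate(x, -x), -1)
  expect_equal(correlate(x, y), correlate(y, x))
  expect_equal(correlate(3 * x - 1, y), correlate(x, y), tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 4)), "variance")
  expect_error(correlate(x, y[1:3]), "equal length")
})

test_that("dips are detected where the observed/model ratio drops", {
  s <- 0:12000
  model <- nc_density(s, fp)
  clean <- binding_profile(s, model / model[1], normalized = TRUE)
  expect_equal(nrow(detect_dips(clean, fp)), 0)

  dipped <- model / model[1]
  dipped[(3000:3300) + 1] <- dipped[(3000:3300) + 1] * 0.2
  dp <- binding_profile(s, dipped, normalized = TRUE)
  hits <- detect_dips(dp, fp, depth_threshold = 0.5)
  expect_equal(nrow(hits), 1)
  expect_lte(hits$start_offset_bp, 3000)
  expect_gte(hits$end_offset_bp, 3300)
  expect_equal(hits$min_ratio, 0.2, tolerance = 1e-6)
  # threshold 0 can never flag
  expect_equal(nrow(detect_dips(dp, fp, depth_threshold = 0)), 0)
  # sub-minimum-width dips are ignored
  narrow <- model / model[1]
  narrow[5001:5010] <- narrow[5001:5010] * 0.1
  np <- binding_profile(s, narrow, normalized = TRUE)
  expect_equal(nrow(detect_dips(np, fp, min_width_bp = 50)), 0)
})

test_that("dip positions are conserved across replicate synthetic datasets", {
  rb <- list(list(start_bp = 43000, end_bp = 43400, factor = 0.15))
  calls <- lapply(c(21, 22), function(sd) {
    ds <- generate_dataset(make_test_truth(seed = sd, roadblocks = rb))
    site <- ds$truth$sites[[1]]
    bg <- estimate_background(ds$ip, site)
    prof <- make_decay_profile(ds$ip, site, background = bg, side = "right")
    # smooth before calling dips: per-bp Poisson counts are too noisy
    prof_s <- convolve_fragments(prof, 100)
    detect_dips(prof_s, ds$truth$params, depth_threshold = 0.5)
  })
  expect_gte(nrow(calls[[1]]), 1)
  expect_gte(nrow(calls[[2]]), 1)
  grid <- 0:12000
  in_calls <- lapply(calls, function(d) {
    hit <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(d))) {
      hit[grid >= d$start_offset_bp[i] & grid < d$end_offset_bp[i]] <- TRUE
    }
    hit
  })
  jaccard <- sum(in_calls[[1]] & in_calls[[2]]) /
    sum(in_calls[[1]] | in_calls[[2]])
  expect_gt(jaccard, 0.9)
})

test_that("profile TSV roundtrip and track export are lossless", {
  s <- 0:100
  prof <- binding_profile(s, nc_density(s, fp) / 0.41, anchor_bp = 500,
                          normalized = TRUE, chrom = "c")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, f)
  back <- read_profile_tsv(f, anchor_bp = 500, normalized = TRUE, chrom = "c")
  expect_equal(back$density, prof$density, tolerance = 1e-12)
  tr <- profile_to_track(prof)
  expect_equal(tr$start_bp, 500)
  expect_equal(tr$counts, prof$density)
})
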