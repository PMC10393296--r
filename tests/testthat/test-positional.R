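test_that("peak windows are fixed-length and edge-clipped windows are
           excluded", {
  chr <- random_seq(5000, seed = 71)
  genome <- Biostrings::DNAStringSet(c(chrI = chr))
  ps <- peak_set("chrI", c(1000, 50), c(1200, 250))
  expect_message(win <- peak_windows(ps, genome), "excluded")
  # midpoint 1100 -> [890, 1310), length 420
  expect_equal(length(win$sequences), 1L)
  expect_equal(Biostrings::width(win$sequences), 420L)
  expect_equal(as.character(win$sequences[[1]]), substr(chr, 891, 1310))
  expect_equal(win$n_excluded, 1L)
  expect_equal(win$centers$center, 1100L)
})

test_that("sites piled at the window center give an extreme central
           p-value", {
  res <- central_position_test(rep(203L, 30), window_len = 420L,
                               motif_width = 14L)
  expect_lt(res$central_p, 1e-6)
})

test_that("central p-values are superuniform under a uniform-position
           null", {
  set.seed(81)
  n_pos <- 420L - 14L + 1L
  pvals <- vapply(1:200, function(r) {
    offsets <- sample.int(n_pos, 60, replace = TRUE) - 1L
    central_position_test(offsets, 420L, 14L)$central_p
  }, numeric(1))
  # rejection at 0.05 stays within the null band (Bonferroni makes the
  # minimum-over-widths conservative, never anticonservative)
  expect_lte(mean(pvals < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  # one-sided Kolmogorov-style check of superuniformity
  grid <- seq(0.01, 0.99, by = 0.01)
  ecdf_vals <- vapply(grid, function(x) mean(pvals <= x), numeric(1))
  expect_true(all(ecdf_vals <= grid + 1.36 / sqrt(200)))
})

test_that("central enrichment finds a centrally planted motif and reports
           the match fraction", {
  pwm <- default_xbox_pwm()
  cons <- pwm_consensus(pwm)
  set.seed(91)
  windows <- vapply(1:60, function(i) {
    w <- random_seq(420)
    if (i <= 40) {   # plant near the center in 40 of 60 windows
      pos <- 203 + sample(-8:8, 1)
      substr(w, pos + 1, pos + nchar(cons)) <- cons
    }
    w
  }, "")
  ce <- central_enrichment(pwm, windows)
  expect_equal(ce$n_windows, 60L)
  expect_equal(ce$n_with_match, 40L)
  expect_equal(ce$match_fraction, 2 / 3)
  expect_lt(ce$central_p, 1e-6)
  expect_error(central_enrichment(pwm, character(0)), "no windows")
})

test_that("widening windows never loses matches at a fixed threshold", {
  pwm <- default_xbox_pwm()
  thr <- 0.8 * pwm_max_score(pwm)
  chr <- random_seq(100000, seed = 101)
  # plant motif instances at varying offsets from the peak centers so the
  # narrow windows capture only a subset
  cons <- pwm_consensus(pwm)
  starts <- seq(1000, 91000, by = 1000)
  centers <- starts + 200
  set.seed(102)
  for (i in seq(1, length(starts), by = 3)) {
    pos <- centers[i] + sample(-200:180, 1)
    substr(chr, pos + 1, pos + nchar(cons)) <- cons
  }
  genome <- Biostrings::DNAStringSet(c(chrI = chr))
  ps <- peak_set("chrI", starts, starts + 400)
  narrow <- peak_windows(ps, genome, half_width = 105)
  wide <- peak_windows(ps, genome, half_width = 210)
  n_narrow <- central_enrichment(pwm, narrow$sequences, threshold = thr,
                                 central_widths = c(20, 40))$n_with_match
  n_wide <- central_enrichment(pwm, wide$sequences, threshold = thr,
                               central_widths = c(20, 40))$n_with_match
  expect_gte(n_wide, n_narrow)
})

test_that("X-box-to-peak distances match hand values and the all-pairs
           oracle", {
  ps <- peak_set("chrI", 190, 610)                 # center 400
  xb <- data.frame(chrom = "chrI", start = 93, end = 107)  # midpoint 100
  res <- xbox_peak_distance(xb, ps)
  expect_equal(res$distances$distance, 300)
  expect_true(res$distances$within)
  # equidistant from two peak centers: the common value, no ambiguity
  ps2 <- peak_set("chrI", c(0, 600), c(200, 800))  # centers 100, 700
  res2 <- xbox_peak_distance(data.frame(chrom = "chrI", start = 395,
                                        end = 405), ps2)
  expect_equal(res2$distances$distance, 300)
  # randomized oracle
  set.seed(111)
  xb3 <- data.frame(chrom = sample(c("chrI", "chrII"), 200, TRUE),
                    start = s3 <- sample.int(500000, 200), end = s3 + 14)
  ps3 <- peak_set(sample(c("chrI", "chrII"), 100, TRUE),
                  s4 <- sample.int(500000, 100), s4 + 400)
  res3 <- xbox_peak_distance(xb3, ps3)
  centers <- peak_anchor(ps3)
  oracle <- vapply(seq_len(200), function(i) {
    same <- ps3$chrom == xb3$chrom[i]
    if (!any(same)) return(Inf)
    min(abs((xb3$start[i] + 7) - centers[same]))
  }, numeric(1))
  expect_equal(res3$distances$distance, oracle)
})

test_that("peak-free chromosomes use the configured denominator rule", {
  ps <- peak_set("chrI", 0, 200)
  xb <- data.frame(chrom = c("chrI", "chrM"), start = c(90, 90),
                   end = c(110, 110))
  strict <- xbox_peak_distance(xb, ps)
  expect_equal(strict$fraction_within, 0.5)   # Inf counts as not-within
  expect_equal(strict$n_peakless, 1L)
  dropped <- xbox_peak_distance(xb, ps, drop_peakless_chroms = TRUE)
  expect_equal(dropped$fraction_within, 1)
  expect_error(xbox_peak_distance(xb, ps[0, ]), "empty")
})

test_that("signature classification is exact set algebra over the
           battery", {
  bat <- gene_battery(c("a", "b", "c", "d"),
                      c("core", "core", "subtype", "male"))
  sig <- classify_signatures(bat, xbox_genes = c("a", "b"),
                             bound_genes = c("b", "c"))
  cls <- stats::setNames(as.character(sig$table$class), sig$table$gene_id)
  expect_equal(unname(cls[c("a", "b", "c", "d")]),
               c("xbox_only", "xbox_and_peak", "peak_only", "neither"))
  expect_equal(sum(sig$counts), nrow(bat))
  # ids outside the battery are ignored with a message
  expect_message(classify_signatures(bat, "zz", character(0)), "ignored")
  # empty sets: everything 'neither'
  sig0 <- classify_signatures(bat, character(0), character(0))
  expect_equal(unname(sig0$counts["neither"]), 4L)
})
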