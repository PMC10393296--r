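write_toy_narrowpeak <- function(lines) {
  path <- withr::local_tempfile(fileext = ".narrowPeak",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("narrowPeak parsing reads coordinates, summit and fallbacks", {
  path <- write_toy_narrowpeak(c(
    "chrI\t100\t500\tp1\t100\t.\t5.5\t-1\t-1\t200",
    "chrI\t900\t1200\tp2\t80\t.\t4.0\t-1\t-1\t-1",
    "chrII\t0\t300\tp3\t60\t.\t3.0\t-1\t-1\t10"))
  ps <- read_narrowpeak(path, tf_name = "toy")
  expect_s3_class(ps, "PeakSet")
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$start, c(100L, 900L, 0L))
  expect_equal(ps$summit, c(200L, -1L, 10L))   # -1 sentinel passes through
  expect_equal(peak_anchor(ps), c(300L, 1050L, 10L))
  # BED3 fallback
  ps3 <- read_narrowpeak(write_toy_narrowpeak("chrI\t5\t25"))
  expect_equal(ps3$summit, -1L)
})

test_that("malformed peak files raise", {
  expect_error(read_narrowpeak(write_toy_narrowpeak("chrI\t100")), "column")
  expect_error(read_narrowpeak(write_toy_narrowpeak("chrI\t500\t100")),
               "start")
  expect_error(
    read_narrowpeak(write_toy_narrowpeak("chrI\txx\t100")), "non-numeric")
  expect_error(read_narrowpeak("no/such.narrowPeak"), "not found")
})

test_that("narrowPeak writing round-trips a PeakSet", {
  ps <- peak_set(c("chrI", "chrII"), c(10L, 20L), c(110L, 220L),
                 summit = c(50L, -1L), tf_name = "toy")
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(ps, path)
  back <- read_narrowpeak(path, tf_name = "toy")
  expect_equal(back$start, ps$start)
  expect_equal(back$summit, ps$summit)
})

test_that("peak annotation reproduces hand-computed promoter calls", {
  models <- gene_models(c("gene-b", "gene-a"), c("chrI", "chrI"),
                        c("+", "+"), tss = c(10000, 30000),
                        tls = c(10100, 30100),
                        start = c(10000, 30000), end = c(12000, 32000))
  # summit at 9000: 1000 bp upstream of gene-b TSS
  ps <- peak_set("chrI", 8800, 9200, summit = 200L)
  ann <- annotate_peaks(ps, models)
  expect_equal(ann$feature, "promoter")
  expect_equal(ann$gene_id, "gene-b")
  expect_equal(ann$distance_to_tss, -1000)
  # equidistant between the two TSSs: lexicographically smaller id wins
  mid <- peak_set("chrI", 19900, 20100)   # midpoint 20000
  ann2 <- annotate_peaks(mid, models)
  expect_equal(ann2$gene_id, "gene-a")
  # chromosome without genes
  lone <- peak_set("chrX", 100, 300)
  ann3 <- annotate_peaks(lone, models)
  expect_equal(ann3$feature, "intergenic")
  expect_true(is.na(ann3$gene_id))
  expect_error(annotate_peaks(ps, models[0, ]), "empty")
})

test_that("every peak gets one feature and fractions sum to one", {
  models <- gene_models("g1", "chrI", "+", tss = 50000, tls = 50100,
                        start = 50000, end = 55000)
  ps <- peak_set("chrI", c(47500, 52000, 56000, 80000),
                 c(48500, 53000, 57000, 81000))
  ann <- annotate_peaks(ps, models)
  expect_equal(ann$feature,
               c("promoter", "genic", "downstream", "intergenic"))
  fd <- feature_distribution(ann)
  expect_equal(sum(fd), 1, tolerance = 1e-9)
  expect_equal(unname(fd), rep(0.25, 4))
})

test_that("annotation is invariant under input peak order and matches a
           brute-force promoter check", {
  set.seed(41)
  n_genes <- 50
  models <- gene_models(sprintf("g%02d", 1:n_genes), "chrI",
                        sample(c("+", "-"), n_genes, TRUE),
                        tss = sort(sample(5000:995000, n_genes)) ,
                        tls = 0)
  models$tls <- models$tss   # anchor irrelevant here
  ps <- peak_set("chrI", starts <- sort(sample(1000:990000, 100)),
                 starts + 400)
  ann <- annotate_peaks(ps, models)
  perm <- sample(nrow(ps))
  ps2 <- peak_set("chrI", ps$start[perm], ps$end[perm])
  ann2 <- annotate_peaks(ps2, models)
  expect_equal(ann2[order(ann2$anchor), -1],
               ann[order(ann$anchor), -1], ignore_attr = TRUE)
  # brute-force all-pairs promoter verdict
  anchors <- peak_anchor(ps)
  for (i in seq_along(anchors)) {
    d <- ifelse(models$strand == "+", anchors[i] - models$tss,
                models$tss - anchors[i])
    expect_equal(ann$feature[i] == "promoter",
                 any(d >= -2000 & d < 1000))
  }
})

test_that("battery binding counts bound genes per category", {
  bat <- gene_battery(c("a", "b", "c", "d"),
                      c("core", "core", "subtype", "male"))
  ann <- data.frame(peak_id = 1:3, chrom = "chrI", anchor = 1:3,
                    feature = c("promoter", "promoter", "intergenic"),
                    gene_id = c("a", "c", NA),
                    distance_to_tss = c(-10, 20, NA))
  s <- battery_binding(ann, bat, tf_name = "toy")
  expect_equal(s$battery_genes_bound, 2L)
  expect_equal(s$battery_fraction, 0.5)
  expect_equal(s$core_fraction, 0.5)
  expect_equal(s$subtype_fraction, 1)
  expect_equal(s$male_fraction, 0)
  # promoter-restricted counting drops non-promoter assignments
  s2 <- battery_binding(ann, bat, features = "promoter")
  expect_equal(s2$battery_genes_bound, 2L)
  # no peaks at all
  s0 <- battery_binding(ann[0, ], bat)
  expect_equal(s0$battery_fraction, 0)
})

test_that("TF prioritization flags a planted outlier and only that one", {
  set.seed(51)
  total <- round(stats::runif(20, 200, 2000))
  bound <- round(0.01 * total + stats::rnorm(20, 0, 2))
  summ <- data.frame(tf_name = sprintf("TF%02d", 1:21),
                     total_peaks = c(total, 800),
                     battery_genes_bound = c(bound, 0.01 * 800 + 50),
                     battery_fraction = c(bound, 58) / 163)
  pri <- prioritize_tfs(summ)
  expect_equal(pri$outliers$tf_name[pri$outliers$flag], "TF21")
  expect_equal(pri$ranking$tf_name[1], "TF21")
})

test_that("collinear points yield no flags and small inputs error", {
  summ <- data.frame(tf_name = c("a", "b", "c", "d"),
                     total_peaks = c(100, 200, 300, 400),
                     battery_genes_bound = c(1, 2, 3, 4),
                     battery_fraction = c(1, 2, 3, 4) / 163)
  pri <- prioritize_tfs(summ)
  expect_false(any(pri$outliers$flag))
  expect_error(prioritize_tfs(summ[1:2, ]), "at least 3")
  summ$total_peaks <- 100
  expect_error(prioritize_tfs(summ), "zero variance")
})

test_that("no TF is flagged at a rate above alpha under a shared-rate
           null", {
  set.seed(61)
  n_flagged <- vapply(1:100, function(r) {
    total <- round(stats::runif(21, 100, 600))
    bound <- stats::rbinom(21, 163, pmin(1, total * 0.0008))
    summ <- data.frame(tf_name = sprintf("TF%02d", 1:21),
                       total_peaks = total,
                       battery_genes_bound = bound,
                       battery_fraction = bound / 163)
    sum(prioritize_tfs(summ)$outliers$flag)
  }, numeric(1))
  expect_lte(mean(n_flagged > 0), 0.12)   # family-wise 0.05 + MC error
})
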