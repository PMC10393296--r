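# shared fixtures, built once per test run

# a small deterministic world for unit tests (smaller genome, fewer genes)
.fixture_env <- new.env(parent = emptyenv())

test_config <- function(seed = 1L, ...) {
  synth_config(seed = seed,
               genome = list(chrom_len = 600000L),
               genes = list(n_background = 80L),
               ...)
}

small_world <- function() {
  if (is.null(.fixture_env$world))
    .fixture_env$world <- synth_genome_and_genes(test_config())
  .fixture_env$world
}

# full study-scale world under the generator defaults (shared by
# the peak-recovery unit tests and the acceptance suite)
default_world <- function() {
  if (is.null(.fixture_env$default_world))
    .fixture_env$default_world <- synth_genome_and_genes(synth_config(seed = 1L))
  .fixture_env$default_world
}

default_peaks <- function() {
  if (is.null(.fixture_env$default_peaks))
    .fixture_env$default_peaks <- synth_peaksets(synth_config(seed = 1L),
                                                 default_world())
  .fixture_env$default_peaks
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force per-window PWM scores, the independent oracle for scan_pwm
oracle_scan <- function(pwm, sequence, threshold, both_strands = TRUE) {
  score_window <- function(win, lo) {
    b <- strsplit(win, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(seq_along(b), function(j) lo[b[j], j], numeric(1)))
  }
  L <- nchar(sequence); W <- pwm$width
  if (L < W) return(data.frame(offset = integer(0), strand = character(0),
                               score = numeric(0)))
  rows <- list()
  for (o in 0:(L - W)) {
    win <- substr(sequence, o + 1, o + W)
    s <- score_window(win, pwm$log_odds)
    if (is.finite(s) && s >= threshold)
      rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "+",
                                             score = s)
    if (both_strands) {
      s2 <- score_window(revcomp(win), pwm$log_odds)
      if (is.finite(s2) && s2 >= threshold)
        rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "-",
                                               score = s2)
    }
  }
  if (!length(rows)) return(data.frame(offset = integer(0),
                                       strand = character(0),
                                       score = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

# a small PWM used across motif tests
toy_pwm <- function(pseudocount = 0.01) {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 1, 0,
                     1, 0, 8, 1,
                     0, 1, 0, 9), nrow = 4, byrow = FALSE,
                   dimnames = list(c("A", "C", "G", "T")))
  build_pwm(counts, pseudocount = pseudocount)
}
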