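#' Fixed-width sequence windows around peak centers
#'
#' Extracts, for each peak, the sequence spanning `half_width` bases either
#' side of the peak center (summit when called, midpoint otherwise), so all
#' windows share one length (420 bp at the default 210 bp half-width, the
#' consensus length used for the central-enrichment analyses). Windows that
#' would overhang a chromosome edge are excluded and counted rather than
#' clipped, keeping the positional null exact.
#'
#' @param peaks a [peak_set()].
#' @param genome a `DNAStringSet`.
#' @param half_width bases either side of the center.
#' @return list with `sequences` (named `DNAStringSet`), `centers`
#'   (data.frame peak_id/chrom/center) and `n_excluded`.
#' @export
peak_windows <- function(peaks, genome, half_width = 210L) {
  stopifnot(inherits(peaks, "PeakSet"), half_width >= 1L)
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss)) stop("chromosomes absent from genome: ",
                         paste(miss, collapse = ", "))
  centers <- peak_anchor(peaks)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  lo <- centers - half_width
  hi <- centers + half_width           # half-open [lo, hi)
  ok <- lo >= 0L & hi <= chrlen[peaks$chrom]
  n_excluded <- sum(!ok)
  if (n_excluded)
    message(n_excluded, " window(s) overhanging chromosome edges excluded")
  ids <- if (all(peaks$name == ".")) as.character(seq_len(nrow(peaks)) - 1L)
         else peaks$name
  seqs <- character(sum(ok))
  keep <- which(ok)
  for (j in seq_along(keep)) {
    i <- keep[j]
    seqs[j] <- as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                               start = lo[i] + 1L,
                                               end = hi[i]))
  }
  list(sequences = Biostrings::DNAStringSet(stats::setNames(seqs, ids[keep])),
       centers = data.frame(peak_id = ids[keep], chrom = peaks$chrom[keep],
                            center = centers[keep],
                            stringsAsFactors = FALSE),
       n_excluded = n_excluded)
}

#' Binomial central-position test from best-site offsets
#'
#' Statistical core of [central_enrichment()], exposed so the positional
#' null can be tested directly. Given the 0-based start offsets of the best
#' motif site in each matched window, tests whether match centers
#' concentrate near the window center: for each candidate central width `w`
#' the number of sites whose center lies within `w/2` of the window center
#' is compared against a Binomial(n, p) null with `p` the fraction of
#' possible offsets that land in the central band; the minimum p-value is
#' Bonferroni-corrected by the number of widths tried.
#'
#' @param offsets integer vector of best-site start offsets (0-based).
#' @param window_len window length in bases.
#' @param motif_width motif width in bases.
#' @param central_widths candidate central-region widths (bases).
#' @return list `central_p`, `best_central_width`, `per_width`
#'   (data.frame width/n_central/prob/p_raw).
#' @export
central_position_test <- function(offsets, window_len, motif_width,
                                  central_widths = seq(20L, 200L, by = 20L)) {
  n_pos <- window_len - motif_width + 1L
  stopifnot(n_pos >= 1L, all(offsets >= 0L), all(offsets <= n_pos - 1L))
  if (any(central_widths > window_len))
    stop("central width exceeds window length")
  n <- length(offsets)
  # center of a match starting at offset o (continuous coordinates)
  site_center <- offsets + motif_width / 2
  all_centers <- (seq_len(n_pos) - 1L) + motif_width / 2
  mid <- window_len / 2
  per <- lapply(central_widths, function(w) {
    in_band <- abs(all_centers - mid) <= w / 2
    prob <- sum(in_band) / n_pos
    k <- sum(abs(site_center - mid) <= w / 2)
    p <- if (prob >= 1) 1 else stats::pbinom(k - 1L, n, prob,
                                             lower.tail = FALSE)
    data.frame(width = w, n_central = k, prob = prob, p_raw = p)
  })
  per <- do.call(rbind, per)
  i_best <- which.min(per$p_raw)
  list(central_p = min(1, per$p_raw[i_best] * nrow(per)),
       best_central_width = per$width[i_best],
       per_width = per)
}

#' Central motif enrichment in peak windows
#'
#' For each fixed-length peak window the single best-scoring PWM site over
#' both strands is located; a window "has a match" when that score reaches
#' the threshold. Matched windows' best-site positions are then tested for
#' concentration at the window center with [central_position_test()]. This
#' is the classic central-enrichment logic for point-source ChIP-seq: a
#' directly bound motif piles up at peak centers.
#'
#' @param pwm a [build_pwm()] object.
#' @param windows `DNAStringSet` (or character) of equal-length windows,
#'   e.g. `peak_windows(...)$sequences`.
#' @param threshold absolute score threshold; default 0.8 of the PWM maximum.
#' @param frac_of_max fraction-of-max alternative to `threshold`.
#' @param central_widths candidate central widths (bases).
#' @return list of class `CentralEnrichment`: `n_windows`, `n_with_match`,
#'   `match_fraction`, `best_central_width`, `central_p`,
#'   `site_position_histogram` (offsets of best sites in matched windows),
#'   `per_width`.
#' @export
central_enrichment <- function(pwm, windows, threshold = NULL,
                               frac_of_max = NULL,
                               central_widths = seq(20L, 200L, by = 20L)) {
  stopifnot(inherits(pwm, "PWM"))
  seqs <- toupper(as.character(windows))
  if (!length(seqs)) stop("no windows supplied")
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) stop("windows must share one length")
  L <- lens
  if (L < pwm$width) stop("windows shorter than the motif")
  if (is.null(threshold)) {
    if (is.null(frac_of_max)) frac_of_max <- 0.8
    threshold <- frac_of_max * pwm_max_score(pwm)
  }
  rc <- pwm_revcomp(pwm)
  best_off <- integer(length(seqs)); best_sc <- numeric(length(seqs))
  scoreable <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    code <- encode_dna(seqs[i])
    f <- window_scores(code, pwm)
    r <- window_scores(code, rc)
    s <- pmax(f, r)
    if (!length(s) || all(!is.finite(s))) next
    scoreable[i] <- TRUE
    j <- which.max(s)
    best_off[i] <- j - 1L
    best_sc[i] <- s[j]
  }
  if (!any(scoreable)) stop("no window with a scoreable position")
  has_match <- scoreable & best_sc >= threshold
  n_match <- sum(has_match)
  offsets <- best_off[has_match]
  ct <- if (n_match > 0L)
    central_position_test(offsets, L, pwm$width, central_widths)
  else list(central_p = 1, best_central_width = NA_integer_,
            per_width = NULL)
  structure(list(n_windows = length(seqs), n_with_match = n_match,
                 match_fraction = n_match / length(seqs),
                 best_central_width = ct$best_central_width,
                 central_p = ct$central_p,
                 site_position_histogram = offsets,
                 per_width = ct$per_width, threshold = threshold),
            class = "CentralEnrichment")
}

#' @export
print.CentralEnrichment <- function(x, ...) {
  cat(sprintf(paste0("Central enrichment: %d/%d windows matched (%.1f%%), ",
                     "best central width %s bp, adjusted p = %.3g\n"),
              x$n_with_match, x$n_windows, 100 * x$match_fraction,
              as.character(x$best_central_width), x$central_p))
  invisible(x)
}

#' Distance from X-boxes to the nearest peak center
#'
#' For each X-box interval the absolute distance from its midpoint to the
#' nearest peak center on the same chromosome is computed. X-boxes on
#' chromosomes without peaks get distance `Inf`; they count as "not within"
#' unless `drop_peakless_chroms = TRUE` removes them from the denominator.
#'
#' @param xboxes data.frame with `chrom`, `start`, `end` (0-based half-open);
#'   an optional `gene_id` column is carried through.
#' @param peaks a [peak_set()].
#' @param cutoff distance cutoff in bases for `fraction_within`
#'   (default 600).
#' @param drop_peakless_chroms exclude Inf distances from the denominator.
#' @return list `distances` (data.frame per X-box), `fraction_within`,
#'   `cutoff`, `n_peakless`.
#' @export
xbox_peak_distance <- function(xboxes, peaks, cutoff = 600L,
                               drop_peakless_chroms = FALSE) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (!nrow(peaks)) stop("empty peak set")
  if (!nrow(xboxes)) stop("no X-box intervals supplied")
  centers_by_chrom <- split(peak_anchor(peaks), peaks$chrom)
  mid <- xboxes$start + (xboxes$end - xboxes$start) / 2
  d <- vapply(seq_len(nrow(xboxes)), function(i) {
    ctr <- centers_by_chrom[[xboxes$chrom[i]]]
    if (is.null(ctr)) return(Inf)
    min(abs(mid[i] - ctr))
  }, numeric(1))
  res <- data.frame(chrom = xboxes$chrom, midpoint = mid, distance = d,
                    within = is.finite(d) & d < cutoff,
                    stringsAsFactors = FALSE)
  if (!is.null(xboxes$gene_id)) res$gene_id <- xboxes$gene_id
  denom <- if (drop_peakless_chroms) sum(is.finite(d)) else length(d)
  list(distances = res,
       fraction_within = if (denom) sum(res$within) / denom else NA_real_,
       cutoff = cutoff, n_peakless = sum(!is.finite(d)))
}

SIGNATURE_CLASSES <- c("xbox_and_peak", "peak_only", "xbox_only", "neither")

#' Four-way dual-signature classification of battery genes
#'
#' Set algebra over the battery: each gene is classified by whether its
#' regulatory region carries a predicted X-box, a TF binding event, both
#' (the "dual signature") or neither. Ids outside the battery are ignored
#' with a message.
#'
#' @param battery a [gene_battery()].
#' @param xbox_genes character vector of gene ids with X-box motifs.
#' @param bound_genes character vector of gene ids with binding events.
#' @return list of class `SignatureTable`: `table` (per-gene data.frame with
#'   `gene_id`, `category`, `class`), `counts` (overall class counts),
#'   `by_category` (class-by-category count matrix), `fractions`.
#' @export
classify_signatures <- function(battery, xbox_genes, bound_genes) {
  stopifnot(inherits(battery, "GeneBattery"))
  extra <- setdiff(union(xbox_genes, bound_genes), battery$gene_id)
  if (length(extra))
    message(length(extra), " id(s) outside the battery ignored")
  x <- battery$gene_id %in% xbox_genes
  b <- battery$gene_id %in% bound_genes
  cls <- ifelse(x & b, "xbox_and_peak",
         ifelse(b, "peak_only",
         ifelse(x, "xbox_only", "neither")))
  tab <- data.frame(gene_id = battery$gene_id, category = battery$category,
                    class = factor(cls, levels = SIGNATURE_CLASSES),
                    stringsAsFactors = FALSE)
  counts <- table(tab$class)
  by_cat <- table(tab$class,
                  factor(tab$category, levels = BATTERY_CATEGORIES))
  structure(list(table = tab,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 by_category = unclass(by_cat),
                 fractions = as.integer(counts) / max(1L, nrow(battery))),
            class = "SignatureTable")
}

#' @export
print.SignatureTable <- function(x, ...) {
  cat("Dual-signature classification:\n")
  print(x$counts)
  invisible(x)
}
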