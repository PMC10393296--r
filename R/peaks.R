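#' ChIP-seq peak sets
#'
#' A `PeakSet` is a data.frame of point-source peak calls with columns
#' `chrom`, `start`, `end` (0-based half-open), `name`, `score`, `strand`,
#' `signal`, `pvalue`, `qvalue`, `summit` (offset of the point source from
#' `start`; -1 when absent), sorted by (chrom, start), carrying `tf_name`
#' and `dataset_id` attributes.
#'
#' @param chrom,start,end coordinate vectors (0-based half-open).
#' @param summit summit offsets from `start` (-1 = absent).
#' @param score,signal,pvalue,qvalue,name optional narrowPeak columns.
#' @param tf_name,dataset_id provenance labels.
#' @return a `PeakSet` data.frame.
#' @export
peak_set <- function(chrom, start, end, summit = -1L,
                     score = 0L, signal = 0, pvalue = -1, qvalue = -1,
                     name = ".", tf_name = "TF", dataset_id = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("negative peak coordinates")
  if (any(end <= start)) stop("peak end must exceed start")
  summit <- as.integer(rep_len(summit, length(start)))
  if (any(summit != -1L & (summit < 0L | summit >= end - start)))
    stop("summit offset outside the peak")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), length(start)),
                   score = rep_len(score, length(start)),
                   strand = rep_len(".", length(start)),
                   signal = rep_len(signal, length(start)),
                   pvalue = rep_len(pvalue, length(start)),
                   qvalue = rep_len(qvalue, length(start)),
                   summit = summit, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, tf_name = tf_name, dataset_id = dataset_id,
            class = c("PeakSet", "data.frame"))
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s' (%s): %d peaks on %d chromosome(s)\n",
              attr(x, "tf_name"), attr(x, "dataset_id"), nrow(x),
              length(unique(x$chrom))))
  invisible(x)
}

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' Parses the ENCODE narrowPeak dialect; 10 columns, with the summit offset
#' in column 10 (-1 when no point source was called). Plain BED3/BED6 files
#' are accepted as a fallback (summit absent). Malformed lines raise an
#' error.
#'
#' @param path file path.
#' @param tf_name,dataset_id provenance labels; `dataset_id` defaults to the
#'   file name.
#' @return a [peak_set()].
#' @export
read_narrowpeak <- function(path, tf_name = "TF",
                            dataset_id = basename(path)) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  nc <- ncol(df)
  if (!nc %in% c(3L, 6L, 10L))
    stop("expected 3 (BED3), 6 (BED6) or 10 (narrowPeak) columns, got ", nc)
  to_int <- function(x, what) {
    y <- suppressWarnings(as.integer(x))
    if (any(is.na(y))) stop("non-numeric ", what, " field in ", path)
    y
  }
  start <- to_int(df[[2]], "start"); end <- to_int(df[[3]], "end")
  if (any(end <= start)) stop("peak end <= start in ", path)
  if (nc == 10L)
    peak_set(df[[1]], start, end,
             summit = to_int(df[[10]], "summit"),
             name = df[[4]], score = to_int(df[[5]], "score"),
             signal = as.numeric(df[[7]]), pvalue = as.numeric(df[[8]]),
             qvalue = as.numeric(df[[9]]),
             tf_name = tf_name, dataset_id = dataset_id)
  else if (nc == 6L)
    peak_set(df[[1]], start, end, name = df[[4]],
             score = to_int(df[[5]], "score"),
             tf_name = tf_name, dataset_id = dataset_id)
  else
    peak_set(df[[1]], start, end, tf_name = tf_name, dataset_id = dataset_id)
}

#' Write a PeakSet as narrowPeak
#' @param peaks a [peak_set()].
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  utils::write.table(
    data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score,
               peaks$strand, peaks$signal, peaks$pvalue, peaks$qvalue,
               peaks$summit),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Anchor point of each peak
#'
#' The summit when called, else the interval midpoint (floor).
#' @param peaks a [peak_set()].
#' @return integer vector of genome coordinates.
#' @export
peak_anchor <- function(peaks)
  ifelse(peaks$summit >= 0L, peaks$start + peaks$summit,
         peaks$start + (peaks$end - peaks$start) %/% 2L)

# signed distance from anchor to a gene's TSS in transcript orientation
signed_tss_distance <- function(anchor, tss, strand)
  ifelse(strand == "+", anchor - tss, tss - anchor)

#' Annotate peaks to genes with a TSS window
#'
#' Each peak is reduced to its anchor point (summit when present, midpoint
#' otherwise) and assigned exactly one feature:
#' \describe{
#'   \item{promoter}{anchor inside the strand-aware window
#'     `[TSS - upstream, TSS + downstream)` of some gene (default
#'     -2000/+1000, the window used throughout this pipeline);}
#'   \item{genic}{anchor inside a gene span;}
#'   \item{downstream}{anchor within 3 kb past a gene end in transcript
#'     orientation;}
#'   \item{intergenic}{anything else.}
#' }
#' The assigned gene is the one whose TSS window contains the anchor
#' (closest TSS when several do), otherwise the nearest TSS on the
#' chromosome; ties break to the lexicographically smaller gene id. Peaks on
#' chromosomes without genes are intergenic with `NA` gene and distance.
#'
#' @param peaks a [peak_set()].
#' @param models a [gene_models()] data.frame (one row per transcript is
#'   fine; assignment is reported at gene level).
#' @param tss_window `c(upstream, downstream)` in bases, both positive.
#' @param downstream_max "downstream" calls within this many bases past a
#'   gene end (default 3000).
#' @return data.frame with one row per peak: `peak_id`, `chrom`, `anchor`,
#'   `feature`, `gene_id`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, models, tss_window = c(2000L, 1000L),
                           downstream_max = 3000L) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (!inherits(models, "GeneModels") || nrow(models) == 0L)
    stop("empty gene model set")
  up <- as.integer(tss_window[1]); down <- as.integer(tss_window[2])
  stopifnot(up >= 0L, down >= 0L)
  anchors <- peak_anchor(peaks)
  n <- nrow(peaks)
  feature <- character(n); gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  models_by_chrom <- split(seq_len(nrow(models)), models$chrom)
  for (i in seq_len(n)) {
    idx <- models_by_chrom[[peaks$chrom[i]]]
    if (is.null(idx)) { feature[i] <- "intergenic"; next }
    m <- models[idx, , drop = FALSE]
    a <- anchors[i]
    d <- signed_tss_distance(a, m$tss, m$strand)
    in_prom <- d >= -up & d < down
    if (any(in_prom)) {
      cand <- which(in_prom)
      cand <- cand[order(abs(d[cand]), m$gene_id[cand])]
      feature[i] <- "promoter"
    } else {
      in_genic <- a >= m$start & a < m$end
      in_down <- ifelse(m$strand == "+",
                        a >= m$end & a < m$end + downstream_max,
                        a < m$start & a >= m$start - downstream_max)
      feature[i] <- if (any(in_genic)) "genic"
                    else if (any(in_down)) "downstream"
                    else "intergenic"
      cand <- order(abs(d), m$gene_id)
    }
    gene[i] <- m$gene_id[cand[1]]
    dist[i] <- d[cand[1]]
  }
  data.frame(peak_id = if (all(peaks$name == ".")) seq_len(n) - 1L
                       else peaks$name,
             chrom = peaks$chrom, anchor = anchors, feature = feature,
             gene_id = gene, distance_to_tss = dist,
             stringsAsFactors = FALSE)
}

PEAK_FEATURES <- c("promoter", "genic", "downstream", "intergenic")

#' Genomic-feature distribution of peak annotations
#' @param annotations output of [annotate_peaks()].
#' @return named numeric vector of fractions over the four features
#'   (summing to 1).
#' @export
feature_distribution <- function(annotations) {
  if (!nrow(annotations)) stop("no annotations")
  tab <- table(factor(annotations$feature, levels = PEAK_FEATURES))
  out <- as.numeric(tab) / nrow(annotations)
  names(out) <- PEAK_FEATURES
  out
}

#' Battery binding summary for one TF
#'
#' A battery gene counts as bound when at least one peak is assigned to it.
#' Per-category fractions are computed over that category's size.
#'
#' @param annotations output of [annotate_peaks()] for one peak set.
#' @param battery a [gene_battery()].
#' @param tf_name label; defaults to the annotations' source if unknown.
#' @param features restrict "bound" to these features (default: any
#'   assignment, matching nearest-TSS annotation practice).
#' @return one-row data.frame: `tf_name`, `total_peaks`,
#'   `battery_genes_bound`, `battery_fraction`, `core_fraction`,
#'   `subtype_fraction`, `broad_fraction`, `male_fraction`.
#' @export
battery_binding <- function(annotations, battery, tf_name = "TF",
                            features = NULL) {
  stopifnot(inherits(battery, "GeneBattery"))
  ann <- annotations
  if (!is.null(features)) ann <- ann[ann$feature %in% features, , drop = FALSE]
  bound_ids <- unique(ann$gene_id[!is.na(ann$gene_id)])
  bound <- battery$gene_id %in% bound_ids
  cc <- category_counts(battery)
  frac <- function(cat) {
    if (cc[[cat]] == 0L) return(0)
    sum(bound & battery$category == cat) / cc[[cat]]
  }
  data.frame(tf_name = tf_name,
             total_peaks = nrow(annotations),
             battery_genes_bound = sum(bound),
             battery_fraction = if (nrow(battery)) sum(bound) / nrow(battery)
                                else 0,
             core_fraction = frac("core"),
             subtype_fraction = frac("subtype"),
             broad_fraction = frac("broad"),
             male_fraction = frac("male"),
             stringsAsFactors = FALSE)
}

#' Rank TFs by battery binding and flag regression outliers
#'
#' Fits an ordinary least-squares regression of the number of battery genes
#' bound on the total number of peaks across TFs, computes externally
#' studentized residuals, and flags TFs whose residual exceeds the two-sided
#' t critical value at a Bonferroni-adjusted level. A genuinely dedicated
#' regulator binds far more battery genes than its peak count predicts and
#' stands out from the regression cloud.
#'
#' @param summaries data.frame of row-bound [battery_binding()] outputs
#'   (>= 3 rows).
#' @param alpha family-wise error level for the outlier flag (default 0.05).
#' @return list with `ranking` (summaries ordered by decreasing
#'   `battery_fraction`) and `outliers` (per-TF `studentized_residual`,
#'   `flag`).
#' @export
prioritize_tfs <- function(summaries, alpha = 0.05) {
  n <- nrow(summaries)
  if (n < 3L) stop("need at least 3 TF summaries for the regression")
  if (stats::var(summaries$total_peaks) == 0)
    stop("zero variance in total_peaks")
  fit <- stats::lm(battery_genes_bound ~ total_peaks, data = summaries)
  rs <- stats::rstudent(fit)
  crit <- stats::qt(1 - alpha / (2 * n), df = n - 3L)
  out <- data.frame(tf_name = summaries$tf_name,
                    studentized_residual = as.numeric(rs),
                    flag = is.finite(rs) & abs(rs) > crit,
                    stringsAsFactors = FALSE)
  ranking <- summaries[order(-summaries$battery_fraction), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, outliers = out, critical_value = crit)
}
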