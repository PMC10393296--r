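#' Gene models
#'
#' A gene model row holds the minimal coordinate information the pipeline
#' needs: chromosome, strand, transcription start site (TSS) and translational
#' start (TLS), plus the gene span. All coordinates are 0-based, half-open
#' internally; the TSS/TLS are point coordinates (position of the first
#' transcribed / translated base in transcript orientation).
#'
#' @param gene_id,chrom,strand,tss,tls vectors of equal length; `strand`
#'   is `"+"` or `"-"`.
#' @param start,end optional gene span; defaults to the `[min, max+1)` hull
#'   of tss and tls.
#' @return data.frame with class `GeneModels`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tls,
                        start = pmin(tss, tls), end = pmax(tss, tls) + 1L) {
  stopifnot(all(strand %in% c("+", "-")),
            all(start <= end), all(start >= 0))
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tss = as.integer(tss), tls = as.integer(tls),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  structure(df, class = c("GeneModels", "data.frame"))
}

#' Read gene models from a 5-column TSV
#'
#' Expected columns: gene_id, chrom, strand, tss, tls (0-based coordinates);
#' optional start and end give the gene span.
#' @param path file path.
#' @return a [gene_models()] data.frame.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tls")
  if (!all(need %in% names(df)))
    stop("gene model table needs columns: ", paste(need, collapse = ", "))
  if (all(c("start", "end") %in% names(df)))
    gene_models(df$gene_id, df$chrom, df$strand, df$tss, df$tls,
                df$start, df$end)
  else
    gene_models(df$gene_id, df$chrom, df$strand, df$tss, df$tls)
}

#' Read gene models from GFF3
#'
#' Uses gene features for the span/TSS and the first CDS base in transcript
#' orientation for the translational start. GFF3 1-based closed coordinates
#' are converted to the package's 0-based half-open convention on read.
#'
#' @param path GFF3 file.
#' @return a [gene_models()] data.frame.
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  cds <- gr[gr$type == "CDS"]
  gid <- as.character(genes$ID %||% genes$gene_id)
  start0 <- GenomicRanges::start(genes) - 1L   # to 0-based half-open
  end0 <- GenomicRanges::end(genes)
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  tls <- tss
  if (length(cds)) {
    parent <- sub("^.*?:", "", as.character(S4Vectors::mcols(cds)$Parent))
    # map CDS to gene by overlap when Parent ids do not match gene ids
    hit <- GenomicRanges::findOverlaps(cds, genes, select = "first")
    for (i in seq_along(genes)) {
      mine <- which(hit == i)
      if (!length(mine)) next
      if (strand[i] == "+")
        tls[i] <- min(GenomicRanges::start(cds[mine])) - 1L
      else
        tls[i] <- max(GenomicRanges::end(cds[mine])) - 1L
    }
  }
  gene_models(gid, as.character(GenomicRanges::seqnames(genes)),
              strand, tss, tls, start0, end0)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings so the rest of the package deals in
#' `DNAStringSet` objects.
#' @param path file path.
#' @return `read_fasta` a `DNAStringSet`; `write_fasta` the path, invisibly.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @param seqs named character vector or `DNAStringSet`.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract promoter sequences
#'
#' Returns, for each gene model, the `upstream_len` bases immediately
#' upstream of the anchor (translational start by default, mirroring the
#' regulatory-sequence definition used for the ciliome battery: 700 bp
#' upstream of the translational start). For `+` strand genes this is
#' `[anchor - L, anchor)` on the forward strand; for `-` strand genes the
#' reverse complement of `[anchor, anchor + L)` so that the returned
#' sequence always reads 5' to 3' towards the gene. Promoters overhanging a
#' chromosome edge are truncated with a warning.
#'
#' @param genome a `DNAStringSet` (names are chromosome names).
#' @param models a [gene_models()] data.frame.
#' @param upstream_len promoter length in bases.
#' @param anchor `"tls"` (default) or `"tss"`.
#' @return named `DNAStringSet`, one sequence per model row.
#' @export
extract_promoters <- function(genome, models, upstream_len = 700L,
                              anchor = c("tls", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(models, "GeneModels"), upstream_len >= 1L)
  miss <- setdiff(unique(models$chrom), names(genome))
  if (length(miss)) stop("chromosomes absent from genome: ",
                         paste(miss, collapse = ", "))
  a <- models[[anchor]]
  L <- as.integer(upstream_len)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  n_trunc <- 0L
  out <- character(nrow(models))
  for (i in seq_len(nrow(models))) {
    cl <- chrlen[[models$chrom[i]]]
    if (a[i] < 0L || a[i] >= cl)
      stop("anchor outside chromosome for gene ", models$gene_id[i])
    if (models$strand[i] == "+") {
      s0 <- a[i] - L
      if (s0 < 0L) { s0 <- 0L; n_trunc <- n_trunc + 1L }
      seq <- Biostrings::subseq(genome[[models$chrom[i]]],
                                start = s0 + 1L, end = a[i])
    } else {
      s0 <- a[i]
      e0 <- s0 + L
      if (e0 > cl) { e0 <- cl; n_trunc <- n_trunc + 1L }
      seq <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[models$chrom[i]]],
                           start = s0 + 1L, end = e0))
    }
    out[i] <- as.character(seq)
  }
  if (n_trunc > 0L)
    warning(n_trunc, " promoter(s) truncated at chromosome edges")
  Biostrings::DNAStringSet(stats::setNames(out, models$gene_id))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Converts a count/frequency matrix into a log2-odds scoring matrix against
#' a background base composition:
#' `score[b, i] = log2( (counts[b,i] + pc * bg[b]) / colsum_i / bg[b] )`.
#' The default pseudocount 0.01 keeps every cell finite; with
#' `pseudocount = 0` impossible bases score `-1e9` instead of `-Inf` so that
#' window sums stay representable.
#'
#' @param counts 4 x W numeric matrix, rows A, C, G, T (rownames optional but
#'   honoured if present), entries non-negative.
#' @param background base frequencies (A, C, G, T), positive, summing to 1.
#' @param pseudocount pseudocount added per cell, scaled by background.
#' @return an object of class `PWM` with elements `width`, `log_odds`
#'   (4 x W matrix), `background`, `pseudocount`, `counts`.
#' @export
build_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES))
      stop("counts rownames must be A, C, G, T")
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else rownames(counts) <- DNA_BASES
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) < 1L) stop("PWM needs at least one position")
  background <- as.numeric(background)
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  adj <- counts + pseudocount * background
  csum <- colSums(adj)
  if (any(csum == 0))
    stop("all-zero PWM position with pseudocount 0")
  prob <- sweep(adj, 2, csum, "/")
  lo <- log2(prob / background)
  lo[is.infinite(lo) & lo < 0] <- -1e9
  structure(list(width = ncol(counts), log_odds = lo,
                 background = stats::setNames(background, DNA_BASES),
                 pseudocount = pseudocount, counts = counts),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM: width %d, max score %.2f bits, consensus %s\n",
              x$width, pwm_max_score(x), pwm_consensus(x)))
  invisible(x)
}

#' Maximum attainable PWM score
#' @param pwm a [build_pwm()] object.
#' @return sum over positions of the best per-position score (bits).
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$log_odds, 2, max))

#' Minimum attainable PWM score
#' @rdname pwm_max_score
#' @export
pwm_min_score <- function(pwm) sum(apply(pwm$log_odds, 2, min))

#' Maximum-likelihood consensus string of a PWM
#' @param pwm a [build_pwm()] object.
#' @return character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm)
  paste(DNA_BASES[apply(pwm$log_odds, 2, which.max)], collapse = "")

#' Reverse complement of a PWM
#' @keywords internal
pwm_revcomp <- function(pwm) {
  lo <- pwm$log_odds[4:1, pwm$width:1, drop = FALSE]
  rownames(lo) <- DNA_BASES
  out <- pwm
  out$log_odds <- lo
  out$counts <- pwm$counts[4:1, pwm$width:1, drop = FALSE]
  rownames(out$counts) <- DNA_BASES
  out
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR 2016+ bracketed layout
#' (`A [ 1 2 3 ]` per row) and the raw 4-row layout, with a `>` header line.
#' @param path file path.
#' @param background,pseudocount passed to [build_pwm()].
#' @return a `PWM`.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("^>", lines[1])) lines <- lines[-1]
  if (length(lines) < 4L) stop("JASPAR file must contain 4 matrix rows")
  parse_row <- function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }
  rows <- lapply(lines[1:4], parse_row)
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("ragged JASPAR matrix rows")
  m <- do.call(rbind, rows)
  rownames(m) <- DNA_BASES
  build_pwm(m, background = background, pseudocount = pseudocount)
}

#' Write a PWM's count matrix in JASPAR format
#' @param pwm a `PWM`.
#' @param path output path.
#' @param id motif identifier for the header line.
#' @export
write_jaspar <- function(pwm, path, id = "motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", id), con)
  for (b in DNA_BASES)
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pwm$counts[b, ]), collapse = " ")), con)
  invisible(path)
}

# integer-encode a DNA string; ambiguous bases (N etc.) become NA
encode_dna <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  match(chars, DNA_BASES)
}

# scores of every window of `pwm` along an encoded sequence (forward only);
# windows touching an ambiguous base score -Inf
window_scores <- function(code, pwm) {
  L <- length(code)
  W <- pwm$width
  n <- L - W + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  bad <- logical(n)
  lo <- pwm$log_odds
  for (j in seq_len(W)) {
    b <- code[j:(j + n - 1L)]
    na <- is.na(b)
    bad <- bad | na
    b[na] <- 1L
    s <- s + lo[cbind(b, j)]
  }
  s[bad] <- -Inf
  s
}

#' Scan a sequence with a PWM
#'
#' Slides the PWM over every window of the sequence (both strands by
#' default) and reports windows whose log-odds sum reaches the threshold.
#' Reverse-strand matches are reported in forward coordinates (`offset` is
#' the 0-based start of the matched window on the forward strand). Windows
#' containing an ambiguous base never match.
#'
#' @param pwm a [build_pwm()] object.
#' @param sequence character scalar or `DNAString` over A, C, G, T, N.
#' @param threshold absolute score threshold; ignored when `frac_of_max`
#'   is given.
#' @param frac_of_max threshold as a fraction of [pwm_max_score()]; the
#'   default 0.8 is used when neither argument is supplied.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame with columns `offset`, `strand`, `score`, sorted by
#'   offset then strand. A sequence shorter than the motif yields zero rows.
#' @export
scan_pwm <- function(pwm, sequence, threshold = NULL, frac_of_max = NULL,
                     both_strands = TRUE) {
  stopifnot(inherits(pwm, "PWM"))
  if (is.null(threshold)) {
    if (is.null(frac_of_max)) frac_of_max <- 0.8
    threshold <- frac_of_max * pwm_max_score(pwm)
  }
  code <- encode_dna(sequence)
  fwd <- window_scores(code, pwm)
  res <- list()
  if (length(fwd)) {
    keep <- which(fwd >= threshold & is.finite(fwd))
    if (length(keep))
      res[[1]] <- data.frame(offset = keep - 1L, strand = "+",
                             score = fwd[keep], stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rev <- window_scores(code, pwm_revcomp(pwm))
    if (length(rev)) {
      keep <- which(rev >= threshold & is.finite(rev))
      if (length(keep))
        res[[length(res) + 1L]] <-
          data.frame(offset = keep - 1L, strand = "-",
                     score = rev[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse complement a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @export
revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# vectorized reverse complement of a character vector of equal-length words
revcomp_vec <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmer <- function(kmers) {
  rc <- revcomp_vec(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

all_canonical_kmers <- function(k) {
  km <- do.call(paste0, expand.grid(rep(list(DNA_BASES), k),
                                    stringsAsFactors = FALSE))
  sort(unique(canonical_kmer(km)))
}

#' k-mer over-representation in a sequence set
#'
#' Counts every k-length window of the input sequences under canonical
#' k-mers (a k-mer and its reverse complement are one species; palindromes
#' are counted once per window) and tests each canonical k-mer for
#' over-representation with a binomial upper tail against its expected
#' frequency under an order-0 background. This serves the same screening
#' purpose as classical oligo-analysis of promoter sets: in the ciliome
#' battery it recovers the long palindromic X-box consensus.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @param k word length (default 6).
#' @param background `"order0"` (base composition estimated from the input),
#'   or a length-4 numeric vector of A/C/G/T frequencies.
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @return data.frame with columns `kmer`, `observed`, `expected`,
#'   `p_value`, `q_value`, `significant`, sorted by q then p then -observed.
#' @export
kmer_enrichment <- function(sequences, k = 6L, background = "order0",
                            alpha = 0.05) {
  if (k <= 0L) stop("k must be positive")
  seqs <- toupper(as.character(sequences))
  if (!length(seqs)) stop("empty sequence set")
  if (min(nchar(seqs)) < k) stop("k exceeds the shortest sequence length")
  # base composition
  if (identical(background, "order0")) {
    tab <- table(factor(unlist(strsplit(seqs, "")), levels = DNA_BASES))
    bg <- as.numeric(tab) / sum(tab)
    if (any(bg == 0)) bg <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  } else {
    bg <- as.numeric(background)
    stopifnot(length(bg) == 4L, all(bg > 0), abs(sum(bg) - 1) < 1e-6)
  }
  names(bg) <- DNA_BASES
  # observed counts over all windows; canonicalize unique words only
  raw_tab <- table(unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, 1:n, k:nchar(s))
  })))
  raw_tab <- raw_tab[!grepl("[^ACGT]", names(raw_tab))]
  canon <- canonical_kmer(names(raw_tab))
  obs_tab <- tapply(as.integer(raw_tab), canon, sum)
  n_windows <- sum(pmax(nchar(seqs) - k + 1L, 0L))
  universe <- all_canonical_kmers(k)
  observed <- as.integer(obs_tab[universe])
  observed[is.na(observed)] <- 0L
  # expected probability that one window equals the canonical species
  word_prob <- function(w) {
    prod(bg[strsplit(w, "")[[1]]])
  }
  p0 <- vapply(universe, function(w) {
    rc <- revcomp(w)
    if (rc == w) word_prob(w) else word_prob(w) + word_prob(rc)
  }, numeric(1))
  expected <- n_windows * p0
  p <- stats::pbinom(observed - 1L, n_windows, p0, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(kmer = universe, observed = observed,
                    expected = expected, p_value = p, q_value = q,
                    significant = q <= alpha, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, -out$observed), , drop = FALSE]
  rownames(out) <- NULL
  out
}
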