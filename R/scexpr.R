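#' Cell-by-gene count container
#'
#' Holds a non-negative integer count matrix with genes in rows and cells in
#' columns (the Bioconductor orientation; sparse `dgCMatrix` is supported
#' throughout) plus one class label per cell (e.g. "ciliated", "other
#' neuron", "non-neuronal", or finer ciliated-subtype labels).
#'
#' @param counts genes x cells matrix (`matrix` or `Matrix::dgCMatrix`) with
#'   rownames (gene ids) and colnames (cell ids).
#' @param cell_class character vector, one label per cell.
#' @return list of class `CellByGene`: `counts`, `cell_class`.
#' @export
cell_by_gene <- function(counts, cell_class) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (length(cell_class) != ncol(counts))
    stop("one class label per cell required")
  if (any(counts < 0)) stop("negative counts")
  structure(list(counts = counts,
                 cell_class = stats::setNames(as.character(cell_class),
                                              colnames(counts))),
            class = "CellByGene")
}

#' @export
print.CellByGene <- function(x, ...) {
  cat(sprintf("CellByGene: %d genes x %d cells, %d class(es)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_class))))
  invisible(x)
}

#' Read / write a CellByGene as MatrixMarket triplets
#'
#' `read_cell_by_gene` expects `<stem>.mtx`, `<stem>.genes.txt`,
#' `<stem>.cells.txt` and a two-column TSV `<stem>.classes.tsv`
#' (cell_id, cell_class); `write_cell_by_gene` emits the same layout.
#'
#' @param stem path stem without extension.
#' @return a [cell_by_gene()] / the stem, invisibly.
#' @export
read_cell_by_gene <- function(stem) {
  m <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  rownames(m) <- readLines(paste0(stem, ".genes.txt"))
  colnames(m) <- readLines(paste0(stem, ".cells.txt"))
  cls <- utils::read.table(paste0(stem, ".classes.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  cell_by_gene(m, cls$cell_class[match(colnames(m), cls$cell_id)])
}

#' @param x a [cell_by_gene()].
#' @rdname read_cell_by_gene
#' @export
write_cell_by_gene <- function(x, stem) {
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                              "generalMatrix"),
                  paste0(stem, ".mtx"))
  writeLines(rownames(x$counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(x$counts), paste0(stem, ".cells.txt"))
  utils::write.table(data.frame(cell_id = colnames(x$counts),
                                cell_class = x$cell_class),
                     paste0(stem, ".classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Counts-per-10k normalization
#'
#' Scales each cell's counts to a common depth of 10,000 so that means and
#' correlations compare expression, not sequencing depth. Cells with zero
#' total stay zero.
#'
#' @param x a [cell_by_gene()] or a genes x cells matrix.
#' @return matrix of the same shape.
#' @export
normalize_cp10k <- function(x) {
  m <- if (inherits(x, "CellByGene")) x$counts else x
  depth <- Matrix::colSums(m)
  depth[depth == 0] <- 1
  if (methods::is(m, "sparseMatrix"))
    m %*% Matrix::Diagonal(x = 1e4 / depth)
  else sweep(m, 2, depth / 1e4, "/")
}

#' Screen candidate TFs for cell-class-enriched expression
#'
#' For each candidate gene, computes the mean normalized expression
#' (counts-per-10k) in the target class versus all other cells pooled (or
#' the maximum over other classes with `other = "max_class"`), the fold
#' enrichment, a two-sample Wilcoxon rank-sum p-value on the per-cell
#' normalized values, and Benjamini-Hochberg q-values over the candidates.
#' A hit passes at the classic screen thresholds: fold >= 5 and
#' FDR <= 0.001.
#'
#' @param x a [cell_by_gene()].
#' @param target_class class label defining the cells of interest.
#' @param candidate_genes gene ids to screen (must exist in the matrix).
#' @param min_fold minimum fold enrichment (default 5).
#' @param fdr FDR threshold (default 0.001).
#' @param other `"pooled"` (default) or `"max_class"`.
#' @param epsilon floor for the other-class mean (default 0.01 cp10k) so the
#'   fold stays finite when a gene is silent outside the target class.
#' @return data.frame: `gene_id`, `target_mean`, `other_mean`,
#'   `fold_enrichment`, `p_value`, `q_value`, `passes`; sorted by q then
#'   decreasing fold.
#' @export
enrichment_screen <- function(x, target_class, candidate_genes,
                              min_fold = 5, fdr = 0.001,
                              other = c("pooled", "max_class"),
                              epsilon = 0.01) {
  other <- match.arg(other)
  stopifnot(inherits(x, "CellByGene"))
  in_target <- x$cell_class == target_class
  if (!any(in_target)) stop("target class '", target_class, "' is empty")
  missing_genes <- setdiff(candidate_genes, rownames(x$counts))
  if (length(missing_genes))
    stop("candidates absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  norm <- normalize_cp10k(x)
  res <- lapply(candidate_genes, function(g) {
    v <- as.numeric(norm[g, ])
    tmean <- mean(v[in_target])
    omean <- if (other == "pooled") mean(v[!in_target])
             else max(vapply(split(v[!in_target],
                                   x$cell_class[!in_target]),
                             mean, numeric(1)))
    p <- tryCatch(
      stats::wilcox.test(v[in_target], v[!in_target],
                         alternative = "greater", exact = FALSE)$p.value,
      error = function(e) 1)
    if (is.na(p)) p <- 1  # both groups constant
    data.frame(gene_id = g, target_mean = tmean, other_mean = omean,
               fold_enrichment = tmean / max(omean, epsilon),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$passes <- out$fold_enrichment >= min_fold & out$q_value <= fdr
  out <- out[order(out$q_value, -out$fold_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class detection profile of one gene
#'
#' A gene counts as detected in a class when it is non-zero in at least
#' `min_detect_frac` of the class's cells (default 5%); used to ask whether
#' a candidate regulator is expressed across all ciliated neuron subtypes.
#'
#' @param x a [cell_by_gene()].
#' @param gene gene id.
#' @param classes class labels to profile (default: all present).
#' @param min_detect_frac detection threshold on the fraction of non-zero
#'   cells.
#' @return named logical vector over `classes`.
#' @export
class_detection_profile <- function(x, gene, classes = NULL,
                                    min_detect_frac = 0.05) {
  stopifnot(inherits(x, "CellByGene"))
  if (!gene %in% rownames(x$counts)) stop("gene not in matrix: ", gene)
  if (is.null(classes)) classes <- sort(unique(x$cell_class))
  miss <- setdiff(classes, x$cell_class)
  if (length(miss)) stop("classes absent: ", paste(miss, collapse = ", "))
  v <- as.numeric(x$counts[gene, ])
  vapply(stats::setNames(classes, classes), function(cl) {
    inc <- x$cell_class == cl
    mean(v[inc] > 0) >= min_detect_frac
  }, logical(1))
}

#' Expression correlation profile of a TF
#'
#' Pearson correlation (on counts-per-10k) between one TF and every gene of
#' the supplied gene sets across a cell subset — classically, all ciliated
#' cells — summarized per set. Genes with zero variance over the subset get
#' `NA`.
#'
#' @param x a [cell_by_gene()].
#' @param tf gene id of the TF.
#' @param gene_sets named list of gene-id vectors (e.g. core, subtype,
#'   panneuronal, ubiquitous).
#' @param cell_subset class label(s) selecting the cells, or `NULL` for all.
#' @return list of class `CorrelationProfile`: `R` (data.frame gene_id,
#'   set, R), `summary` (per-set n, median, q1, q3), `n_cells`.
#' @export
expression_correlation <- function(x, tf, gene_sets, cell_subset = NULL) {
  stopifnot(inherits(x, "CellByGene"))
  if (!tf %in% rownames(x$counts)) stop("TF not in matrix: ", tf)
  sel <- if (is.null(cell_subset)) rep(TRUE, ncol(x$counts))
         else x$cell_class %in% cell_subset
  if (sum(sel) < 3L) stop("cell subset smaller than 3 cells")
  norm <- normalize_cp10k(x)[, sel, drop = FALSE]
  tf_v <- as.numeric(norm[tf, ])
  tf_sd <- stats::sd(tf_v)
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- intersect(gene_sets[[nm]], rownames(x$counts))
    if (!length(genes)) return(NULL)
    R <- vapply(genes, function(g) {
      v <- as.numeric(norm[g, ])
      if (stats::sd(v) == 0 || tf_sd == 0) return(NA_real_)
      stats::cor(tf_v, v)
    }, numeric(1))
    data.frame(gene_id = genes, set = nm, R = R, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(tab$R, tab$set), function(r) {
    r <- r[!is.na(r)]
    data.frame(n = length(r),
               median = stats::median(r),
               q1 = unname(stats::quantile(r, 0.25)),
               q3 = unname(stats::quantile(r, 0.75)))
  }))
  summ$set <- rownames(summ)
  rownames(summ) <- NULL
  structure(list(R = tab, summary = summ[, c("set", "n", "median",
                                             "q1", "q3")],
                 n_cells = sum(sel), tf = tf),
            class = "CorrelationProfile")
}

#' @export
print.CorrelationProfile <- function(x, ...) {
  cat(sprintf("Correlation profile of %s over %d cells:\n", x$tf, x$n_cells))
  print(x$summary)
  invisible(x)
}
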