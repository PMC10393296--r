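#' Ciliome gene battery
#'
#' A gene battery is a curated list of cilium effector genes partitioned into
#' four functional categories: \code{core} (components of all cilia, e.g. IFT
#' particles, BBSome, kinesins), \code{subtype} (channels/receptors with
#' neuron-type-specific ciliary function), \code{broad} (expressed through the
#' ciliated system without a defined core function) and \code{male}
#' (male-specific ciliary function).
#'
#' @param gene_id character vector of unique, non-empty gene identifiers.
#' @param category character vector of categories, one per gene; labels are
#'   normalized with [normalize_category()].
#' @param public_name optional display names (defaults to `gene_id`).
#' @param name label for the battery.
#' @return A `GeneBattery`: a data.frame with columns `gene_id`,
#'   `public_name`, `category` and attribute `name`.
#' @export
gene_battery <- function(gene_id, category, public_name = gene_id,
                         name = "battery") {
  gene_id <- as.character(gene_id)
  if (any(is.na(gene_id) | !nzchar(gene_id)))
    stop("gene_id must be non-empty")
  category <- vapply(as.character(category), normalize_category, character(1))
  stopifnot(length(category) == length(gene_id),
            length(public_name) == length(gene_id))
  df <- data.frame(gene_id = gene_id,
                   public_name = as.character(public_name),
                   category = category,
                   stringsAsFactors = FALSE)
  # duplicate ids collapse to one record only when their categories agree
  if (anyDuplicated(df$gene_id)) {
    split_cat <- split(df$category, df$gene_id)
    bad <- names(split_cat)[vapply(split_cat,
                                   function(x) length(unique(x)) > 1L,
                                   logical(1))]
    if (length(bad))
      stop("duplicate gene ids with conflicting categories: ",
           paste(bad, collapse = ", "))
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, name = name, class = c("GeneBattery", "data.frame"))
}

#' Battery category labels
#' @keywords internal
BATTERY_CATEGORIES <- c("core", "subtype", "broad", "male")

#' Normalize a battery category label
#'
#' Source tables write the categories with varying decoration ("'Core
#' components'", "*Subtype specific*", ...). Labels are lower-cased, stripped
#' of quotes/asterisks/whitespace and matched by their leading word against
#' the four canonical categories.
#'
#' @param x a single category string.
#' @return one of `"core"`, `"subtype"`, `"broad"`, `"male"`.
#' @export
normalize_category <- function(x) {
  y <- tolower(gsub("[\"'*‘’“”]", "", trimws(x)))
  if (grepl("^core", y)) return("core")
  if (grepl("^sub[- ]?type", y)) return("subtype")
  if (grepl("^broad", y)) return("broad")
  if (grepl("^male", y)) return("male")
  stop("unmappable battery category label: '", x, "'")
}

#' Load a gene battery from a delimited text file
#'
#' Reads a TSV/CSV with a header row. Column names are configurable through
#' `column_spec` so that the differently laid out source tables can all be
#' loaded. When a stable gene id column is absent the public name is used as
#' identifier (case preserved, matching is the caller's concern).
#'
#' @param path file path.
#' @param column_spec named list mapping roles to column names; recognized
#'   roles are `gene_id`, `category`, `public_name`.
#' @param sep field separator; `NULL` (default) guesses from the extension
#'   (`.csv` is comma, anything else tab).
#' @param name battery label; defaults to the file name.
#' @return a [gene_battery()].
#' @export
load_battery <- function(path,
                         column_spec = list(gene_id = "gene_id",
                                            category = "category"),
                         sep = NULL, name = NULL) {
  if (!file.exists(path)) stop("battery file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  cat_col <- column_spec$category %||% "category"
  if (!cat_col %in% names(df))
    stop("category column '", cat_col, "' not found in ", path)
  id_col <- column_spec$gene_id %||% "gene_id"
  name_col <- column_spec$public_name
  ids <- if (id_col %in% names(df)) df[[id_col]]
         else if (!is.null(name_col) && name_col %in% names(df)) df[[name_col]]
         else stop("no usable gene id column in ", path)
  pub <- if (!is.null(name_col) && name_col %in% names(df)) df[[name_col]]
         else ids
  if (nrow(df) == 0L)
    return(gene_battery(character(0), character(0),
                        name = name %||% basename(path)))
  gene_battery(ids, df[[cat_col]], public_name = pub,
               name = name %||% basename(path))
}

#' Write a battery as canonical two-column TSV
#'
#' @param battery a [gene_battery()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_battery <- function(battery, path) {
  stopifnot(inherits(battery, "GeneBattery"))
  utils::write.table(battery[, c("gene_id", "category")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count battery genes per category
#'
#' @param battery a [gene_battery()].
#' @return named integer vector over all four categories (absent ones are 0);
#'   the counts always sum to the battery size.
#' @export
category_counts <- function(battery) {
  stopifnot(inherits(battery, "GeneBattery"))
  tab <- table(factor(battery$category, levels = BATTERY_CATEGORIES))
  out <- as.integer(tab)
  names(out) <- BATTERY_CATEGORIES
  out
}

#' @export
print.GeneBattery <- function(x, ...) {
  cc <- category_counts(x)
  cat(sprintf("GeneBattery '%s': %d genes (%s)\n",
              attr(x, "name") %||% "?", nrow(x),
              paste(names(cc), cc, sep = ":", collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
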