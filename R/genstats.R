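#' Reporter-count groups
#'
#' Per-animal counts of reporter-positive neurons, one group per genotype
#' (optionally split by anatomical region). Most functions in this module
#' take a named list of non-negative numeric vectors, or the long-format
#' data.frame produced by [read_reporter_counts()].
#'
#' @param path TSV with columns genotype, count and optionally region,
#'   animal_id.
#' @return data.frame with those columns.
#' @export
read_reporter_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("genotype", "count") %in% names(df)))
    stop("reporter table needs 'genotype' and 'count' columns")
  if (any(df$count < 0)) stop("negative reporter counts")
  df
}

#' Split a long reporter table into per-genotype count vectors
#' @param df output of [read_reporter_counts()].
#' @param region optional region label filter.
#' @return named list of numeric vectors.
#' @export
reporter_groups <- function(df, region = NULL) {
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  split(df$count, df$genotype)
}

# two-sample t mirroring the spreadsheet idiom: an F pretest on the
# variances selects the pooled (Student) or unpooled (Welch) statistic
t_after_f <- function(a, b, alternative = "two.sided", var_alpha = 0.05) {
  equal_var <- stats::var.test(a, b)$p.value >= var_alpha
  stats::t.test(a, b, alternative = alternative, var.equal = equal_var)
}

#' All pairwise reporter comparisons with Bonferroni correction
#'
#' Two-tailed two-sample t-test for every genotype pair; an F pretest on the
#' variances chooses between the pooled and Welch statistic. P-values are
#' Bonferroni-multiplied by the number of pairs (capped at 1).
#'
#' @param groups named list of per-animal count vectors (>= 2 groups, each
#'   >= 2 animals).
#' @param var_alpha level of the variance pretest (default 0.05).
#' @return data.frame: `group_a`, `group_b`, `t`, `df`, `p_raw`, `p_adj`,
#'   `welch`.
#' @export
pairwise_reporter_tests <- function(groups, var_alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 animals")
  pairs <- utils::combn(names(groups), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    if (stats::var(a) == 0 && stats::var(b) == 0 &&
        mean(a) == mean(b)) {
      return(data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                        t = 0, df = length(a) + length(b) - 2L,
                        p_raw = 1, welch = FALSE,
                        stringsAsFactors = FALSE))
    }
    tt <- t_after_f(a, b, var_alpha = var_alpha)
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               welch = grepl("Welch", tt$method),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * n_pairs)
  out
}

#' Per-region one-tailed reporter tests with Benjamini-Hochberg adjustment
#'
#' For each anatomical region, tests whether the mutant's reporter counts
#' are lower than the control's with a one-tailed t-test (variance pretest
#' as in [pairwise_reporter_tests()]); p-values are adjusted with the BH
#' step-up procedure over all regions of the experiment and called at
#' `alpha`.
#'
#' @param regions named list; each element a list with components `control`
#'   and `mutant` (numeric count vectors).
#' @param alpha FDR level (default 0.05).
#' @param var_alpha level of the variance pretest.
#' @return data.frame: `region`, `t`, `p_raw`, `p_adj`, `reject`.
#' @export
regional_reporter_tests <- function(regions, alpha = 0.05,
                                    var_alpha = 0.05) {
  if (!length(regions)) stop("no regions supplied")
  rows <- lapply(names(regions), function(r) {
    g <- regions[[r]]
    if (!all(c("control", "mutant") %in% names(g)))
      stop("region '", r, "' lacks control/mutant groups")
    if (stats::var(g$mutant) == 0 && stats::var(g$control) == 0 &&
        mean(g$mutant) == mean(g$control))
      return(data.frame(region = r, t = 0, p_raw = 1,
                        stringsAsFactors = FALSE))
    tt <- t_after_f(g$mutant, g$control, alternative = "less",
                    var_alpha = var_alpha)
    data.frame(region = r, t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$reject <- out$p_adj <= alpha
  out
}

#' Per-animal fold changes against a reference genotype
#'
#' Each animal's count is divided by the reference genotype's mean count;
#' per-genotype mean, SD and relative error are reported on that scale, so
#' the reference genotype's mean fold change is exactly 1.
#'
#' @param groups named list of per-animal count vectors.
#' @param reference name of the reference genotype.
#' @return list of class `FoldChanges`: `per_animal` (named list of fold
#'   change vectors), `stats` (data.frame genotype, mean_fc, sd_fc,
#'   rel_err), `reference`, `reference_mean`.
#' @export
fold_changes <- function(groups, reference) {
  if (!reference %in% names(groups))
    stop("reference genotype '", reference, "' not among groups")
  ref_mean <- mean(groups[[reference]])
  if (ref_mean <= 0) stop("reference mean must be positive")
  fc <- lapply(groups, function(v) v / ref_mean)
  stats_df <- do.call(rbind, lapply(names(fc), function(g) {
    m <- mean(fc[[g]]); s <- stats::sd(fc[[g]])
    data.frame(genotype = g, n = length(fc[[g]]), mean_fc = m, sd_fc = s,
               rel_err = if (m == 0) NA_real_ else s / m,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_animal = fc, stats = stats_df, reference = reference,
                 reference_mean = ref_mean),
            class = "FoldChanges")
}

#' Expected fold change under the multiplicative model
#'
#' For two mutants with mean fold changes `m_a` and `m_b` (relative to a
#' common reference), the multiplicative null expects the combined mutant at
#' `E = m_a * m_b`. The propagated error is the first-order product rule:
#' the expected value multiplied by the sum of the factors' relative errors,
#' `sd_E = E * (s_a/m_a + s_b/m_b)`; a quadrature mode
#' (`sd_E = E * sqrt((s_a/m_a)^2 + (s_b/m_b)^2)`) is available.
#'
#' @param fc_a,fc_b one-row slices of a `FoldChanges$stats` table (or any
#'   list with `mean_fc`, `sd_fc` and, for `error = "sem"`, `n`), both with
#'   `mean_fc > 0`.
#' @param mode `"sum"` (default) or `"quadrature"`.
#' @param error `"sd"` (default: per-animal fold-change SD enters the
#'   propagation) or `"sem"` (standard error of the group mean).
#' @return list `E`, `sd_expected`.
#' @export
expected_multiplicative <- function(fc_a, fc_b,
                                    mode = c("sum", "quadrature"),
                                    error = c("sd", "sem")) {
  mode <- match.arg(mode)
  error <- match.arg(error)
  ma <- fc_a$mean_fc; mb <- fc_b$mean_fc
  if (is.na(ma) || is.na(mb) || ma <= 0 || mb <= 0)
    stop("both mean fold changes must be positive")
  sa <- fc_a$sd_fc; sb <- fc_b$sd_fc
  if (error == "sem") {
    sa <- sa / sqrt(fc_a$n); sb <- sb / sqrt(fc_b$n)
  }
  ra <- sa / ma; rb <- sb / mb
  E <- ma * mb
  sd_E <- if (mode == "sum") E * (ra + rb) else E * sqrt(ra^2 + rb^2)
  list(E = E, sd_expected = sd_E)
}

#' One-sample test of an observed mutant against the multiplicative
#' expectation
#'
#' The combined mutant's per-animal fold changes (relative to the reference
#' mean) are tested against the fixed null value `E` with a one-sample
#' t-test. A mean significantly below `E` is called `synergistic_loss`;
#' above, `greater_than_expected`; otherwise
#' `consistent_with_multiplicative`. With `conservative = TRUE` the
#' uncertainty of `E` itself (`sd_expected`) is folded into the denominator,
#' widening the test.
#'
#' @param triple per-animal counts of the combined mutant (>= 2 animals).
#' @param reference per-animal counts of the reference genotype, or a single
#'   positive number taken as its mean.
#' @param E expected fold change (from [expected_multiplicative()]).
#' @param sd_expected propagated SD of `E` (needed for
#'   `conservative = TRUE`).
#' @param alternative sidedness of the t-test (default two-sided).
#' @param alpha verdict level (default 0.05).
#' @param conservative widen the test with `sd_expected`.
#' @return list of class `SynergyResult`: `observed_mean_fc`, `E`,
#'   `sd_expected`, `t_statistic`, `df`, `p_value`, `verdict`, `degenerate`.
#' @export
synergy_test <- function(triple, reference, E, sd_expected = NA_real_,
                         alternative = c("two.sided", "less", "greater"),
                         alpha = 0.05, conservative = FALSE) {
  alternative <- match.arg(alternative)
  if (length(triple) < 2L) stop("combined mutant needs >= 2 animals")
  if (E < 0) stop("expected fold change must be non-negative")
  ref_mean <- if (length(reference) == 1L) reference else mean(reference)
  if (ref_mean <= 0) stop("reference mean must be positive")
  fc <- triple / ref_mean
  m <- mean(fc); s <- stats::sd(fc); n <- length(fc)
  degenerate <- s == 0
  if (degenerate) {
    p <- if (m == E) 1 else NA_real_
    tstat <- if (m == E) 0 else NA_real_
    df <- n - 1L
  } else if (conservative) {
    if (is.na(sd_expected)) stop("conservative test needs sd_expected")
    se <- sqrt(s^2 / n + sd_expected^2)
    tstat <- (m - E) / se
    df <- n - 1L
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tstat), df),
                less = stats::pt(tstat, df),
                greater = stats::pt(tstat, df, lower.tail = FALSE))
  } else {
    tt <- stats::t.test(fc, mu = E, alternative = alternative)
    tstat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  verdict <- if (degenerate && is.na(p)) "degenerate"
             else if (!is.na(p) && p < alpha && m < E) "synergistic_loss"
             else if (!is.na(p) && p < alpha && m > E) "greater_than_expected"
             else "consistent_with_multiplicative"
  structure(list(observed_mean_fc = m, E = E, sd_expected = sd_expected,
                 t_statistic = tstat, df = df, p_value = p,
                 verdict = verdict, degenerate = degenerate, n = n),
            class = "SynergyResult")
}

#' @export
print.SynergyResult <- function(x, ...) {
  cat(sprintf(paste0("Synergy test: observed mean fc %.3f vs expected ",
                     "%.3f; t = %.3f, p = %.3g -> %s\n"),
              x$observed_mean_fc, x$E, x$t_statistic, x$p_value, x$verdict))
  invisible(x)
}

#' Fisher's exact test for rescue experiments
#'
#' Animals are classified 'on'/'off' per condition; association is tested
#' with the two-sided Fisher's exact test. The sample odds ratio
#' `(a*d)/(b*c)` is reported alongside (Inf/0 on zero cells, NaN when both
#' a diagonal and its complement vanish).
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows: condition; columns: on/off).
#' @return list `odds_ratio`, `p_value`, `conditional_mle` (the odds-ratio
#'   estimate from the exact test).
#' @export
rescue_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("rescue_test needs a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value,
       conditional_mle = unname(ft$estimate))
}

BEHAVIOR_ASSAYS <- c("response", "chemotaxis_quadrant", "chemotaxis_halves",
                     "avoidance_sectors", "avoidance_drop", "dauer_fraction")

#' Behavioral indexes
#'
#' The literal population index formulas used for sensory assays:
#' \describe{
#'   \item{response}{RI = escape responses / strokes, in \[0, 1\].}
#'   \item{chemotaxis_quadrant}{CI = (worms in T1+T2 - worms in C1+C2) /
#'     total scored, in \[-1, 1\].}
#'   \item{chemotaxis_halves}{CI = (worms in T - worms in C) / total scored.}
#'   \item{avoidance_sectors}{AI = (worms in sectors A+B - worms in
#'     sectors E+F) / total.}
#'   \item{avoidance_drop}{AI = responses / drops, in \[0, 1\].}
#'   \item{dauer_fraction}{dauer animals / total scored, in \[0, 1\].}
#' }
#'
#' @param assay one of the assay names above.
#' @param ... named counts, depending on the assay: `responses`, `strokes`
#'   (response); `t1`, `t2`, `c1`, `c2`, `total` (chemotaxis_quadrant);
#'   `t`, `c`, `total` (chemotaxis_halves); `sector_a`, `sector_b`,
#'   `sector_e`, `sector_f`, `total` (avoidance_sectors); `responses`,
#'   `drops` (avoidance_drop); `dauer`, `total` (dauer_fraction).
#' @return list of class `BehaviorIndex`: `assay`, `value`, `n`.
#' @export
behavior_index <- function(assay = BEHAVIOR_ASSAYS, ...) {
  assay <- match.arg(assay)
  a <- list(...)
  need <- function(...) {
    nm <- c(...)
    miss <- setdiff(nm, names(a))
    if (length(miss)) stop("assay '", assay, "' needs counts: ",
                           paste(miss, collapse = ", "))
    if (any(unlist(a[nm]) < 0)) stop("counts must be non-negative")
  }
  res <- switch(assay,
    response = { need("responses", "strokes")
      if (a$strokes <= 0) stop("zero denominator")
      list(value = a$responses / a$strokes, n = a$strokes) },
    chemotaxis_quadrant = { need("t1", "t2", "c1", "c2", "total")
      if (a$total <= 0) stop("zero denominator")
      list(value = (a$t1 + a$t2 - a$c1 - a$c2) / a$total, n = a$total) },
    chemotaxis_halves = { need("t", "c", "total")
      if (a$total <= 0) stop("zero denominator")
      list(value = (a$t - a$c) / a$total, n = a$total) },
    avoidance_sectors = { need("sector_a", "sector_b", "sector_e",
                               "sector_f", "total")
      if (a$total <= 0) stop("zero denominator")
      list(value = (a$sector_a + a$sector_b - a$sector_e - a$sector_f) /
             a$total, n = a$total) },
    avoidance_drop = { need("responses", "drops")
      if (a$drops <= 0) stop("zero denominator")
      list(value = a$responses / a$drops, n = a$drops) },
    dauer_fraction = { need("dauer", "total")
      if (a$total <= 0) stop("zero denominator")
      list(value = a$dauer / a$total, n = a$total) })
  structure(list(assay = assay, value = res$value, n = res$n),
            class = "BehaviorIndex")
}

#' Dauer fold induction
#'
#' Ratio of the pheromone-induced dauer fraction to the control dauer
#' fraction for one genotype.
#'
#' @param induced,control [behavior_index()] results (`dauer_fraction`) or
#'   plain fractions.
#' @return numeric fold induction.
#' @export
dauer_fold_induction <- function(induced, control) {
  val <- function(x) if (inherits(x, "BehaviorIndex")) x$value else x
  ci <- val(control)
  if (ci <= 0) stop("control dauer fraction must be positive")
  val(induced) / ci
}

#' Shapiro-Wilk normality check for replicate indexes
#'
#' Thin wrapper used before t-testing final behavior indexes.
#' @param values numeric vector of per-replicate indexes (>= 3).
#' @return the `htest` object from [stats::shapiro.test()].
#' @export
normality_check <- function(values) stats::shapiro.test(values)
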