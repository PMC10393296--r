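# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default X-box position weight matrix
#'
#' A strong count matrix for the canonical RFX/DAF-19 binding site, the
#' 14-bp imperfect palindrome `GTTGCCATGGCAAC` (each consensus base at 85%
#' of 100 sites, the rest spread evenly). Used as the default motif in the
#' synthetic generator and examples; real analyses should load the matrix of
#' interest with [read_jaspar()].
#'
#' @param pseudocount passed to [build_pwm()].
#' @return a `PWM`.
#' @export
default_xbox_pwm <- function(pseudocount = 0.01) {
  cons <- strsplit("GTTGCCATGGCAAC", "")[[1]]
  m <- matrix(5, nrow = 4, ncol = length(cons), dimnames = list(DNA_BASES))
  for (i in seq_along(cons)) m[cons[i], i] <- 85
  build_pwm(m, pseudocount = pseudocount)
}

#' Synthetic-study configuration
#'
#' Bundles every parameter of the synthetic-data generators with defaults
#' emulating the study conditions of the ciliome analysis: a 163-gene
#' battery split 73/68/13/9 over core/subtype/broad/male, X-boxes planted
#' preferentially in core-gene promoters, a TF compendium in which one
#' regulator binds core battery genes at 75% and subtype genes at 22%, a
#' single-cell matrix with one fivefold target-class-enriched regulator, and
#' per-animal reporter counts under a configurable multiplicative
#' interaction.
#'
#' @param seed integer seed governing all generators.
#' @param ... named overrides of any nested default, e.g.
#'   `reporter = list(interaction = 0.2)` (partial lists are merged).
#' @return list of class `SynthConfig`.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 3L, chrom_len = 1000000L, gc = 0.36),
    genes = list(
      battery_counts = c(core = 73L, subtype = 68L, broad = 13L, male = 9L),
      n_background = 237L, gene_len = 1500L, promoter_len = 700L,
      cds_offset = 150L),
    motifs = list(
      pwm = default_xbox_pwm(),
      plant_prob = c(core = 0.9, subtype = 0.3, broad = 0.75, male = 0.45)),
    peaks = list(
      n_tfs = 21L, peaks_per_tf = 250L, peak_len = 420L,
      regulator = "REG",
      bind_prob = c(core = 0.75, subtype = 0.22, broad = 0.46, male = 0.46),
      tss_window = c(2000L, 1000L), center_jitter_sd = 50,
      promoter_bias = 0.4, peaks_range = c(100L, 600L)),
    sc = list(
      n_cells = c(ciliated = 300L, other_neuron = 400L,
                  non_neuronal = 500L),
      target_class = "ciliated",
      n_tf_candidates = 30L, regulator_fold = 8,
      mu_tf = 0.5, mu_core = 2, mu_ubiq = 2, mu_pan = 1,
      dispersion = 0.5, coupling = 0.6,
      n_core = 73L, n_ubiq = 50L, n_pan = 30L),
    reporter = list(
      reference = "daf-12", reference_mean = 60,
      multipliers = c(double_a = 0.8, double_b = 0.2),
      interaction = 1, n_animals = 10L,
      noise = "poisson", nb_dispersion = 0.5))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config key(s) in '", nm, "': ",
                            paste(bad, collapse = ", "))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = c("SynthConfig", "list"))
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Synthesize a genome, gene models and planted promoter motifs
#'
#' Generates i.i.d. chromosome sequences at the configured GC content,
#' places non-overlapping gene models on both strands, builds the battery
#' (and background genes), and writes the motif consensus (forward or
#' reverse complement, at random) into promoters with the per-category
#' planting probability. A truth table records every planted instance.
#'
#' @param cfg a [synth_config()].
#' @return list: `genome` (`DNAStringSet`), `models` ([gene_models()]),
#'   `battery` ([gene_battery()]), `truth` (data.frame gene_id, chrom,
#'   start, strand, sequence of planted instances), `config`.
#' @export
synth_genome_and_genes <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  g <- cfg$genome; gn <- cfg$genes; mo <- cfg$motifs
  if (g$chrom_len < 10000L) stop("chromosome length must be >= 10 kb")
  with_seed(cfg$seed, {
    chrom_names <- paste0("chr", utils::as.roman(seq_len(g$n_chroms)))
    genome <- lapply(chrom_names, function(x) random_dna(g$chrom_len, g$gc))
    names(genome) <- chrom_names

    bat_counts <- gn$battery_counts
    n_total <- sum(bat_counts) + gn$n_background
    cats <- c(rep(names(bat_counts), bat_counts),
              rep(NA_character_, gn$n_background))
    ids <- c(sprintf("cil-%s-%03d", rep(names(bat_counts), bat_counts),
                     unlist(lapply(bat_counts, seq_len))),
             sprintf("bg-%03d", seq_len(gn$n_background)))
    ord <- sample(n_total)                    # shuffle genomic placement
    slot_margin <- gn$promoter_len + 2200L    # room for promoter+TSS window
    slot <- gn$gene_len + 2L * slot_margin
    per_chrom <- (g$chrom_len - 1000L) %/% slot
    if (per_chrom * g$n_chroms < n_total)
      stop("genome too small for ", n_total, " genes")
    chrom <- character(n_total); strand <- character(n_total)
    tss <- integer(n_total); tls <- integer(n_total)
    gstart <- integer(n_total); gend <- integer(n_total)
    for (k in seq_len(n_total)) {
      i <- ord[k]
      ci <- (k - 1L) %/% per_chrom + 1L
      si <- (k - 1L) %% per_chrom
      s0 <- 500L + si * slot + slot_margin
      chrom[i] <- chrom_names[ci]
      strand[i] <- sample(c("+", "-"), 1L)
      if (strand[i] == "+") {
        gstart[i] <- s0; gend[i] <- s0 + gn$gene_len
        tss[i] <- s0; tls[i] <- s0 + gn$cds_offset
      } else {
        gstart[i] <- s0; gend[i] <- s0 + gn$gene_len
        tss[i] <- gend[i] - 1L; tls[i] <- tss[i] - gn$cds_offset
      }
    }
    models <- gene_models(ids, chrom, strand, tss, tls, gstart, gend)
    battery <- gene_battery(ids[!is.na(cats)], cats[!is.na(cats)],
                            name = "synthetic-ciliome")

    cons <- pwm_consensus(mo$pwm)
    W <- nchar(cons)
    truth <- list()
    for (i in seq_len(n_total)) {
      if (is.na(cats[i])) next
      if (stats::runif(1) >= mo$plant_prob[[cats[i]]]) next
      off <- sample.int(gn$promoter_len - W - 20L, 1L) + 9L  # inset 10 bp
      pos <- if (strand[i] == "+") tls[i] - gn$promoter_len + off
             else tls[i] + gn$promoter_len - off - W + 1L
      mstrand <- sample(c("+", "-"), 1L)
      planted <- if (mstrand == "+") cons else revcomp(cons)
      s <- genome[[chrom[i]]]
      substr(s, pos + 1L, pos + W) <- planted
      genome[[chrom[i]]] <- s
      truth[[length(truth) + 1L]] <-
        data.frame(gene_id = ids[i], chrom = chrom[i], start = pos,
                   strand = mstrand, sequence = planted,
                   stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(gene_id = character(0), chrom = character(0),
                             start = integer(0), strand = character(0),
                             sequence = character(0))
    list(genome = Biostrings::DNAStringSet(unlist(genome)),
         models = models, battery = battery, truth = truth, config = cfg)
  })
}

#' Synthesize a multi-TF peak collection with one battery-biased regulator
#'
#' Background TFs drop a promoter-biased mix of peaks over the genome; the
#' designated regulator first binds each battery gene with the per-category
#' probability, centering the peak on the gene's planted X-box when one
#' exists (the regulator binds near X-boxes), else on the promoter
#' midpoint, with Gaussian jitter clamped to the TSS window; it then fills
#' up to `peaks_per_tf` with background peaks rejection-sampled away from
#' every battery TSS window so the truth table of bound battery genes is
#' exact. The truth records which battery genes the regulator bound.
#'
#' @param cfg a [synth_config()].
#' @param world output of [synth_genome_and_genes()] (its `models` and
#'   `battery` are used).
#' @return list: `peaksets` (named list of [peak_set()]), `truth` (list with
#'   `regulator`, `bound_genes`), `config`.
#' @export
synth_peaksets <- function(cfg, world) {
  stopifnot(inherits(cfg, "SynthConfig"))
  pk <- cfg$peaks
  models <- world$models; battery <- world$battery
  chrlen <- stats::setNames(Biostrings::width(world$genome),
                            names(world$genome))
  half <- pk$peak_len %/% 2L
  # strand-aware TSS windows of the battery genes, for rejection sampling
  bat_models <- models[match(battery$gene_id, models$gene_id), , drop = FALSE]
  up <- pk$tss_window[1]; down <- pk$tss_window[2]
  bat_win <- data.frame(
    chrom = bat_models$chrom,
    lo = ifelse(bat_models$strand == "+", bat_models$tss - up,
                bat_models$tss - down + 1L),
    hi = ifelse(bat_models$strand == "+", bat_models$tss + down - 1L,
                bat_models$tss + up))
  in_battery_window <- function(chrom, center) {
    idx <- bat_win$chrom == chrom
    any(center >= bat_win$lo[idx] & center <= bat_win$hi[idx])
  }
  bg_models <- models[!models$gene_id %in% battery$gene_id, , drop = FALSE]
  with_seed(cfg$seed + 1L, {
    # background peaks: a `promoter_bias` share lands in random background
    # gene promoters (the stand-in for the vastly larger non-ciliome gene
    # complement of a real genome), the rest uniform; battery TSS windows
    # are rejection-sampled away on request so planted truth stays exact
    background_centers <- function(n, avoid_battery = FALSE) {
      ci <- character(n); pos <- integer(n)
      target_pool <- bg_models
      for (j in seq_len(n)) {
        repeat {
          if (stats::runif(1) < pk$promoter_bias) {
            m <- target_pool[sample.int(nrow(target_pool), 1L), ]
            cn <- m$chrom
            prom_mid <- if (m$strand == "+")
              m$tls - cfg$genes$promoter_len %/% 2L
            else m$tls + cfg$genes$promoter_len %/% 2L
            p <- round(stats::rnorm(1, prom_mid, pk$center_jitter_sd))
            p <- min(max(p, half + 1L), chrlen[[cn]] - half - 1L)
          } else {
            cn <- sample(names(chrlen), 1L)
            p <- sample.int(chrlen[[cn]] - pk$peak_len - 1000L, 1L) +
              500L + half
          }
          if (!avoid_battery || !in_battery_window(cn, p)) break
        }
        ci[j] <- cn; pos[j] <- p
      }
      data.frame(chrom = ci, center = pos, stringsAsFactors = FALSE)
    }
    make_set <- function(centers, tf)
      peak_set(centers$chrom, centers$center - half, centers$center + half,
               summit = half, name = sprintf("%s_p%04d", tf,
                                             seq_len(nrow(centers))),
               tf_name = tf, dataset_id = paste0("synthetic:", tf))
    tf_names <- c(pk$regulator,
                  sprintf("TF%02d", seq_len(pk$n_tfs - 1L)))
    sets <- list()
    bound <- character(0)
    for (tf in tf_names) {
      if (tf == pk$regulator) {
        bm <- bat_models
        p_bind <- pk$bind_prob[battery$category]
        hit <- stats::runif(nrow(bm)) < p_bind
        bound <- battery$gene_id[hit]
        ctr <- integer(sum(hit))
        idx <- which(hit)
        for (j in seq_along(idx)) {
          m <- bm[idx[j], ]
          win <- if (m$strand == "+")
            c(m$tss - pk$tss_window[1], m$tss + pk$tss_window[2] - 1L)
          else
            c(m$tss - pk$tss_window[2] + 1L, m$tss + pk$tss_window[1])
          win[1] <- max(win[1], half + 1L)
          win[2] <- min(win[2], chrlen[[m$chrom]] - half - 1L)
          # anchor on the planted X-box when the gene has one, else the
          # promoter midpoint; jitter emulates summit-call noise
          ti <- which(world$truth$gene_id == m$gene_id)
          anchor_pos <- if (length(ti)) {
            world$truth$start[ti[1]] + nchar(world$truth$sequence[ti[1]]) %/% 2L
          } else if (m$strand == "+") {
            m$tls - cfg$genes$promoter_len %/% 2L
          } else {
            m$tls + cfg$genes$promoter_len %/% 2L
          }
          ctr[j] <- min(max(round(stats::rnorm(1, anchor_pos,
                                               pk$center_jitter_sd)),
                            win[1]), win[2])
        }
        planted <- data.frame(chrom = bm$chrom[idx], center = ctr,
                              stringsAsFactors = FALSE)
        n_bg <- max(0L, pk$peaks_per_tf - nrow(planted))
        centers <- rbind(planted, background_centers(n_bg,
                                                  avoid_battery = TRUE))
      } else {
        n_pk <- sample(seq(pk$peaks_range[1], pk$peaks_range[2]), 1L)
        centers <- background_centers(n_pk)
      }
      sets[[tf]] <- make_set(centers, tf)
    }
    list(peaksets = sets,
         truth = list(regulator = pk$regulator, bound_genes = bound),
         config = cfg)
  })
}

#' Synthesize a single-cell count matrix with one planted regulator
#'
#' Negative-binomial counts over configurable cell classes. One candidate TF
#' (the regulator) has its mean multiplied by `regulator_fold` in the target
#' class; a core gene set, expressed in the target class, is coupled to the
#' regulator through a shared per-cell lognormal latent factor
#' (mean-normalized so depths stay comparable), giving the correlation
#' profile planted positives. Every other class carries its own expression
#' program of the same mass so per-cell depth is balanced across classes and
#' depth normalization stays neutral. Remaining TF candidates, a ubiquitous
#' set and a panneuronal set are null.
#'
#' @param cfg a [synth_config()].
#' @return list: `matrix` (a [cell_by_gene()]), `gene_sets` (named list:
#'   candidates, core, ubiquitous, panneuronal), `truth` (list with
#'   `regulator`, `target_class`, `fold`, `coupling`), `config`.
#' @export
synth_sc_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  sc <- cfg$sc
  if (length(sc$n_cells) < 2L) stop("need >= 2 cell classes")
  with_seed(cfg$seed + 2L, {
    classes <- rep(names(sc$n_cells), sc$n_cells)
    n_cells <- length(classes)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    cand <- c("REG", sprintf("TF%02d", seq_len(sc$n_tf_candidates - 1L)))
    core <- sprintf("core%03d", seq_len(sc$n_core))
    ubiq <- sprintf("ubiq%03d", seq_len(sc$n_ubiq))
    pan <- sprintf("pan%03d", seq_len(sc$n_pan))
    other_classes <- setdiff(names(sc$n_cells), sc$target_class)
    progs <- lapply(other_classes, function(cl)
      sprintf("prog_%s_%03d", cl, seq_len(sc$n_core)))
    names(progs) <- other_classes
    genes <- c(cand, core, ubiq, pan, unlist(progs, use.names = FALSE))
    in_target <- classes == sc$target_class
    # shared latent factor couples the regulator and the core set;
    # mean-normalized so the expected per-cell depth is class-balanced
    latent <- rep(1, n_cells)
    if (sc$coupling > 0)
      latent[in_target] <- stats::rlnorm(sum(in_target), 0, sc$coupling) /
        exp(sc$coupling^2 / 2)
    mu <- matrix(0, nrow = length(genes), ncol = n_cells,
                 dimnames = list(genes, cell_ids))
    mu[cand, ] <- sc$mu_tf
    mu["REG", in_target] <- sc$mu_tf * sc$regulator_fold * latent[in_target]
    mu[core, ] <- rep(ifelse(in_target, sc$mu_core, 0.05),
                      each = length(core)) *
                  rep(latent, each = length(core))
    mu[ubiq, ] <- sc$mu_ubiq
    mu[pan, ] <- sc$mu_pan
    for (cl in other_classes)
      mu[progs[[cl]], ] <- rep(ifelse(classes == cl, sc$mu_core, 0.05),
                               each = sc$n_core)
    size <- 1 / sc$dispersion
    counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                    size = size),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    m <- cell_by_gene(Matrix::Matrix(counts, sparse = TRUE), classes)
    list(matrix = m,
         gene_sets = list(candidates = cand, core = core,
                          ubiquitous = ubiq, panneuronal = pan),
         truth = list(regulator = "REG", target_class = sc$target_class,
                      fold = sc$regulator_fold, coupling = sc$coupling),
         config = cfg)
  })
}

#' Synthesize per-animal reporter counts under the multiplicative model
#'
#' Counts are drawn (Poisson or negative binomial) around
#' `reference_mean * multiplier`, with the combined-mutant multiplier equal
#' to the product of the two double-mutant multipliers times the interaction
#' coefficient: `interaction = 1` encodes the multiplicative null, values
#' below 1 synergistic loss.
#'
#' @param cfg a [synth_config()].
#' @return list: `groups` (named list of count vectors: reference, double_a,
#'   double_b, triple), `truth` (multipliers, interaction, reference_mean),
#'   `config`.
#' @export
synth_reporter_counts <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  rp <- cfg$reporter
  if (rp$reference_mean <= 0) stop("reference mean must be positive")
  with_seed(cfg$seed + 3L, {
    mult <- c(reference = 1, rp$multipliers,
              triple = unname(rp$multipliers["double_a"] *
                              rp$multipliers["double_b"] * rp$interaction))
    draw <- function(m) {
      mu <- rp$reference_mean * m
      if (rp$noise == "poisson") stats::rpois(rp$n_animals, mu)
      else stats::rnbinom(rp$n_animals, mu = mu,
                          size = 1 / rp$nb_dispersion)
    }
    groups <- lapply(mult, draw)
    names(groups)[1] <- rp$reference
    list(groups = groups,
         truth = list(multipliers = mult, interaction = rp$interaction,
                      reference_mean = rp$reference_mean),
         config = cfg)
  })
}
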