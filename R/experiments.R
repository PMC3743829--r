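# Monte-Carlo experiments: identification-rate tables for relatives,
# chunked false-positive scans over unrelated pairs, combined-statistic
# distributions, Y-haplotype subsample-uniqueness checks, demographic
# weighting of false-positive involvement, and the reduced-reference
# sensitivity analysis. Every reported rate carries its replicate count,
# binomial standard error, theta and seed, so runs are reproducible and
# auditable.

.name_panels <- function(panels) {
  if (inherits(panels, "population_panel")) panels <- list(panels)
  if (!is.list(panels) || length(panels) < 1L ||
      !all(vapply(panels, inherits, TRUE, "population_panel")))
    stop("`panels` must be a non-empty list of population_panel objects")
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    names(panels) <- vapply(panels, `[[`, "", "label")
  panels
}

.cell_seed <- function(seed, cell, offset = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 104729 * cell + offset) %% 2147483647)
}

#' Positive-identification rates for Y-sharing relatives
#'
#' For each source panel and each true relationship, simulates
#' `cfg$n_pairs` Y-sharing relative pairs, applies the full protocol
#' under the tested relationship, and tabulates the positive-decision
#' proportion with its binomial standard error. The tested-relationship
#' row is the power of the test; more distant rows are misidentification
#' rates.
#'
#' @param test Tested relationship: `"parent-offspring"` or `"sibling"`.
#' @param panels List of `population_panel` objects (source populations).
#' @param relationships True relationships to simulate (default: all six
#'   Y-sharing relationships).
#' @param cfg A [sim_config()]; per-cell seeds are derived from
#'   `cfg$seed` when set.
#' @param clr_cfg A [clr_config()].
#' @param ycfg A [y_frequency_config()].
#' @param pooled Pooled Y reference; defaults to pooling the panels'
#'   Y samples.
#' @return A `rate_table`: list with matrices `rates` and `se`
#'   (relationships x panels), `n_pairs`, `theta`, `seed`.
#' @export
estimate_identification_rates <- function(test, panels,
    relationships = c("parent-offspring", "sibling", "half-sibling",
                      "cousin", "half-cousin", "second-cousin"),
    cfg = sim_config(), clr_cfg, ycfg = y_frequency_config(),
    pooled = NULL) {
  panels <- .name_panels(panels)
  test <- .as_relationship(test)
  if (!test$label %in% c("parent-offspring", "sibling"))
    stop("test must be parent-offspring or sibling")
  if (is.null(pooled))
    pooled <- pool_y_references(lapply(panels, `[[`, "y_sample"))
  rates <- se <- matrix(NA_real_, length(relationships), length(panels),
                        dimnames = list(relationships, names(panels)))
  cell <- 0L
  for (j in seq_along(panels)) {
    for (i in seq_along(relationships)) {
      cell <- cell + 1L
      cfg_i <- cfg
      cfg_i$seed <- .cell_seed(cfg$seed, cell)
      blk <- simulate_relative_pairs(panels[[j]], relationships[i], cfg_i)
      res <- evaluate_pairs(blk, test, clr_cfg, ycfg, pooled,
                            values = FALSE)
      r <- mean(res$decision)
      rates[i, j] <- r
      se[i, j] <- sqrt(r * (1 - r) / cfg$n_pairs)
    }
  }
  structure(list(test = test$label, kind = "identification",
                 rates = rates, se = se, n_pairs = cfg$n_pairs,
                 theta = cfg$theta, seed = cfg$seed),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, digits = 4, ...) {
  cat(sprintf("%s rates (%s test; %s pairs/cell, theta = %s%s)\n",
              x$kind, x$test, format(x$n_pairs, big.mark = ","),
              x$theta,
              if (is.null(x$seed)) "" else paste0(", seed = ", x$seed)))
  print(signif(x$rates, digits))
  invisible(x)
}

# one chunk of the false-positive scan: Y haplotypes are drawn for the
# whole chunk, autosomal genotypes only for the Y-matching pairs (the
# decision is structurally negative otherwise)
.fp_chunk_positives <- function(panel_a, panel_b, n, theta, test,
                                clr_cfg, ycfg, pooled, seed) {
  if (!is.null(seed)) set.seed(seed)
  y <- .unrelated_y_draws(panel_a, panel_b, n)
  m <- which(y$y_a == y$y_b)
  if (!length(m)) return(0L)
  blk <- .unrelated_genotype_block(panel_a, panel_b, length(m), theta)
  blk$y_a <- y$y_a[m]
  blk$y_b <- y$y_b[m]
  res <- evaluate_pairs(blk, test, clr_cfg, ycfg, pooled, values = FALSE)
  sum(res$decision)
}

#' False-positive identification rates between unrelated pairs
#'
#' Simulates unrelated pairs for every unordered pair of source panels
#' (including same-panel pairs) in chunks with a running positive count,
#' so replicate counts far beyond available memory are supported. Cells
#' with zero positives additionally record the one-sided 95% "rule of
#' three" upper bound `3/n`.
#'
#' @inheritParams estimate_identification_rates
#' @param chunk_size Pairs per simulation chunk.
#' @return A `rate_table` with upper-triangular matrices `rates`, `se`,
#'   `positives` and `upper_bound` (panel x panel).
#' @export
estimate_false_positive_rates <- function(test, panels,
    cfg = sim_config(), clr_cfg, ycfg = y_frequency_config(),
    pooled = NULL, chunk_size = 1e6) {
  panels <- .name_panels(panels)
  test <- .as_relationship(test)
  if (is.null(pooled))
    pooled <- pool_y_references(lapply(panels, `[[`, "y_sample"))
  k <- length(panels)
  labs <- names(panels)
  rates <- se <- ub <- pos <- matrix(NA_real_, k, k,
                                     dimnames = list(labs, labs))
  cell <- 0L
  for (i in seq_len(k)) {
    for (j in i:k) {
      cell <- cell + 1L
      total <- 0L
      done <- 0
      chunk <- 0L
      while (done < cfg$n_pairs) {
        nch <- as.integer(min(chunk_size, cfg$n_pairs - done))
        total <- total + .fp_chunk_positives(
          panels[[i]], panels[[j]], nch, cfg$theta, test, clr_cfg, ycfg,
          pooled, .cell_seed(cfg$seed, cell, offset = 7919L * chunk))
        done <- done + nch
        chunk <- chunk + 1L
      }
      r <- total / cfg$n_pairs
      pos[i, j] <- total
      rates[i, j] <- r
      se[i, j] <- sqrt(r * (1 - r) / cfg$n_pairs)
      if (total == 0L) ub[i, j] <- 3 / cfg$n_pairs
    }
  }
  structure(list(test = test$label, kind = "false-positive",
                 rates = rates, se = se, positives = pos,
                 upper_bound = ub, n_pairs = cfg$n_pairs,
                 theta = cfg$theta, seed = cfg$seed),
            class = "rate_table")
}

#' Distribution of the combined statistic
#'
#' Histogram of `log10` combined-statistic values per true relationship,
#' for pairs simulated from one source panel and evaluated under one
#' assumed reference table. Pairs with combined statistic exactly zero
#' (non-matching Y haplotypes) are tracked in a separate zero bucket;
#' nonzero values outside the binned range are clamped into the end bins.
#'
#' @param test Tested relationship.
#' @param source_panel `population_panel` the pairs are simulated from.
#' @param assumed_table `allele_freq_table` the autosomal LR assumes.
#' @param relationships True relationships (may include `"unrelated"`).
#' @param cfg A [sim_config()].
#' @param ycfg A [y_frequency_config()].
#' @param pooled Pooled Y reference (defaults to the source panel's own
#'   sample).
#' @param database_size Database size `N`.
#' @param breaks Bin edges on the `log10` scale (default 0.25-wide bins
#'   over `[-12, 12]`).
#' @return A `clr_distribution`: per-relationship bin `counts`,
#'   `zero_count` and replicate count `n`; counts plus the zero bucket
#'   sum to `n`.
#' @export
clr_distribution <- function(test, source_panel, assumed_table,
                             relationships, cfg = sim_config(),
                             ycfg = y_frequency_config(), pooled = NULL,
                             database_size = 1900000,
                             breaks = seq(-12, 12, by = 0.25)) {
  stopifnot(inherits(source_panel, "population_panel"),
            inherits(assumed_table, "allele_freq_table"))
  test <- .as_relationship(test)
  if (is.null(pooled)) pooled <- source_panel$y_sample
  out <- vector("list", length(relationships))
  names(out) <- relationships
  for (i in seq_along(relationships)) {
    cfg_i <- cfg
    cfg_i$seed <- .cell_seed(cfg$seed, i)
    blk <- if (relationships[i] == "unrelated")
      simulate_unrelated_pairs(source_panel, source_panel, cfg_i)
    else simulate_relative_pairs(source_panel, relationships[i], cfg_i)
    lry <- y_lrs(blk$y_a, blk$y_b, pooled, ycfg)
    clr <- numeric(blk$n)
    idx <- which(lry > 0)
    if (length(idx)) {
      sub <- .block_subset(blk, idx)
      clr[idx] <- exp(.autosomal_loglr(sub, test, assumed_table) +
                        log(lry[idx]) - log(database_size))
    }
    zero <- sum(clr == 0)
    v <- log10(clr[clr > 0])
    eps <- 1e-9
    v <- pmin(pmax(v, breaks[1] + eps), breaks[length(breaks)] - eps)
    counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
    out[[i]] <- list(counts = counts, zero_count = zero, n = blk$n)
  }
  structure(list(test = test$label, source = source_panel$label,
                 assumed = assumed_table$population_label,
                 breaks = breaks, by_relationship = out,
                 n_pairs = cfg$n_pairs, theta = cfg$theta,
                 seed = cfg$seed),
            class = "clr_distribution")
}

#' @export
print.clr_distribution <- function(x, ...) {
  cat("Combined-statistic distributions (", x$test, " test; source ",
      x$source, ", assumed ", x$assumed, ")\n", sep = "")
  for (r in names(x$by_relationship)) {
    d <- x$by_relationship[[r]]
    mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
    mlog <- if (sum(d$counts) > 0)
      signif(sum(mids * d$counts) / sum(d$counts), 3) else NA
    cat(sprintf("  %-17s n=%d zero=%d mean log10 CLR (nonzero) = %s\n",
                r, d$n, d$zero_count, mlog))
  }
  invisible(x)
}

#' Probability that a Y-haplotype subsample is fully unique
#'
#' Draws `n_reps` without-replacement subsamples of the given size from a
#' Y-haplotype sample and returns the fraction in which all haplotypes
#' are distinct. Used to ask whether a small fully-diverse sample is
#' plausible as a chance subsample of a larger, moderately shared pool.
#'
#' @param sample A `y_haplotype_sample`.
#' @param subsample_size Size of each subsample (at most `sample$n`).
#' @param n_reps Number of subsamples.
#' @param seed Optional seed.
#' @return Proportion in `[0, 1]`.
#' @export
subsample_uniqueness <- function(sample, subsample_size, n_reps,
                                 seed = NULL) {
  stopifnot(inherits(sample, "y_haplotype_sample"))
  subsample_size <- as.integer(subsample_size)
  if (subsample_size > sample$n)
    stop("subsample_size exceeds the sample size")
  if (!is.null(seed)) set.seed(seed)
  h <- sample$haplotypes
  n <- sample$n
  if (!anyDuplicated(h)) return(1)  # every subsample inherits uniqueness
  ok <- 0L
  for (r in seq_len(n_reps))
    if (!anyDuplicated(h[sample.int(n, subsample_size)])) ok <- ok + 1L
  ok / n_reps
}

#' Demographic involvement in false-positive identifications
#'
#' Given pairwise false-positive rates `f[g, h]` between population
#' groups and demographic proportions `d`, weights each unordered pair by
#' its frequency in a database mirroring the demographics
#' (`d_g^2` within-group, `2 d_g d_h` across groups) and returns, for
#' each group, the proportion of expected false positives that involve at
#' least one member of that group.
#'
#' @param fp_rates Symmetric matrix of pairwise rates (an upper-triangular
#'   `rate_table` from [estimate_false_positive_rates()] is accepted and
#'   symmetrized), with row/column names matching the demographic labels.
#' @param demo A `demographics` object.
#' @return Named numeric vector of involvement proportions (each in
#'   `[0, 1]`; they need not sum to 1, since cross-group false positives
#'   involve two groups).
#' @export
demographic_involvement <- function(fp_rates, demo) {
  stopifnot(inherits(demo, "demographics"))
  f <- if (inherits(fp_rates, "rate_table")) fp_rates$rates else fp_rates
  if (!is.matrix(f) || nrow(f) != ncol(f))
    stop("fp_rates must be a square matrix of pairwise rates")
  low <- lower.tri(f)
  f[low][is.na(f[low])] <- t(f)[low][is.na(f[low])]
  if (anyNA(f)) stop("fp_rates contains NA cells after symmetrization")
  if (max(abs(f - t(f))) > 1e-12) stop("fp_rates must be symmetric")
  labs <- demo$labels
  if (!setequal(rownames(f), labs))
    stop("fp_rates labels do not match the demographic labels")
  f <- f[labs, labs, drop = FALSE]
  d <- unname(demo$proportions[labs])
  total <- as.numeric(t(d) %*% f %*% d)
  if (total <= 0)
    stop("total false-positive mass is zero; involvement undefined")
  row_mass <- d * as.numeric(f %*% d)
  inv <- (2 * row_mass - d^2 * diag(f)) / total
  stats::setNames(inv, labs)
}

#' Identification rates with a reduced Y-haplotype reference
#'
#' Repeats [estimate_identification_rates()] after subsampling every
#' panel's Y sample to a common size (without replacement, order
#' preserved) before pooling, to check whether cross-population rate
#' differences are driven by unequal Y reference sizes. With
#' `subsample_size` equal to each panel's full size and the same seeds,
#' the result is identical to the baseline run.
#'
#' @inheritParams estimate_identification_rates
#' @param subsample_size Y haplotypes retained per panel (default 103).
#' @param seed Seed for the subsampling step.
#' @return A `rate_table`.
#' @export
reduced_reference_rates <- function(test, panels,
    relationships = c("parent-offspring", "sibling", "half-sibling",
                      "cousin", "half-cousin", "second-cousin"),
    cfg = sim_config(), clr_cfg, ycfg = y_frequency_config(),
    subsample_size = 103L, seed = NULL) {
  panels <- .name_panels(panels)
  subsample_size <- as.integer(subsample_size)
  bad <- vapply(panels, function(p) p$y_sample$n < subsample_size, TRUE)
  if (any(bad))
    stop("panel(s) with fewer than ", subsample_size, " Y haplotypes: ",
         paste(names(panels)[bad], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  reduced <- lapply(panels, function(p) {
    idx <- sort(sample.int(p$y_sample$n, subsample_size))
    population_panel(
      p$autosomal,
      y_haplotype_sample(p$y_sample$population_label,
                         p$y_sample$haplotypes[idx]),
      label = p$label)
  })
  estimate_identification_rates(test, reduced, relationships, cfg,
                                clr_cfg, ycfg)
}
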