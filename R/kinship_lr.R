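# The combined familial-search statistic: per-locus kinship likelihood
# ratios under Hardy-Weinberg frequencies (no substructure correction in
# the LR itself, matching California practice; coancestry enters only the
# simulator), a Y-haplotype LR based on the upper confidence limit of the
# pooled haplotype frequency, the database-scaled combination, and the
# two-threshold decision rule.

#' Configuration for the Y-haplotype frequency confidence limit
#'
#' The Y-haplotype LR uses the inverse of the upper confidence limit of
#' the haplotype frequency in the pooled cross-population reference,
#' excluding the case's own copies. For an observed haplotype the limit is
#' the normal-approximation (asymptotic) bound `x/n + z*sqrt((x/n)(1-x/n)/n)`;
#' for a haplotype unobserved after exclusion it is `1 - alpha^(1/n)`
#' (upper bound of a Binomial proportion with zero successes), with the
#' cruder `3/n` rule available as an alternative.
#'
#' @param confidence_z Normal quantile for the observed-haplotype bound
#'   (default 1.96, a 95% limit).
#' @param zero_rule Rule for unobserved haplotypes: `"alpha_root"`
#'   (`1 - alpha^(1/n)`, default) or `"three_over_n"`.
#' @param alpha Tail probability for the `alpha_root` rule (default 0.05).
#' @param leave_out_case_copies If `TRUE` (default) the case's copies are
#'   removed from both the haplotype count and the pooled total before the
#'   limit is computed.
#' @return A list of class `y_freq_config`.
#' @export
y_frequency_config <- function(confidence_z = 1.96,
                               zero_rule = c("alpha_root", "three_over_n"),
                               alpha = 0.05, leave_out_case_copies = TRUE) {
  if (!is.numeric(confidence_z) || confidence_z <= 0)
    stop("confidence_z must be positive")
  zero_rule <- match.arg(zero_rule)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  structure(list(confidence_z = confidence_z, zero_rule = zero_rule,
                 alpha = alpha,
                 leave_out_case_copies = isTRUE(leave_out_case_copies)),
            class = "y_freq_config")
}

#' Configuration for the combined statistic and decision rule
#'
#' @param reference_panels List of `allele_freq_table` objects under which
#'   the autosomal LR is evaluated (the operational protocol uses three:
#'   African American, European American and Latino American samples).
#' @param database_size Size `N` of the searched database; the combined
#'   statistic is the LR product divided by `N`. Default 1,900,000, a
#'   database approaching two million profiles.
#' @param floor_threshold Every per-panel combined value must exceed this
#'   (default 0.1).
#' @param peak_threshold At least one per-panel combined value must exceed
#'   this (default 1.0).
#' @return A list of class `clr_config`.
#' @export
clr_config <- function(reference_panels, database_size = 1900000,
                       floor_threshold = 0.1, peak_threshold = 1.0) {
  if (inherits(reference_panels, "allele_freq_table"))
    reference_panels <- list(reference_panels)
  if (!is.list(reference_panels) || length(reference_panels) < 1L ||
      !all(vapply(reference_panels, inherits, TRUE, "allele_freq_table")))
    stop("reference_panels must be a non-empty list of allele_freq_table")
  if (is.null(names(reference_panels)))
    names(reference_panels) <- vapply(reference_panels,
                                      `[[`, "", "population_label")
  if (!is.numeric(database_size) || database_size < 1)
    stop("database_size must be >= 1")
  if (floor_threshold > peak_threshold)
    stop("floor_threshold must not exceed peak_threshold")
  structure(list(reference_panels = reference_panels,
                 database_size = database_size,
                 floor_threshold = floor_threshold,
                 peak_threshold = peak_threshold),
            class = "clr_config")
}

#' Single-locus kinship likelihood ratio
#'
#' Standard LR comparing the probability of two observed single-locus
#' genotypes under a relationship with IBD-sharing probabilities
#' `(k0, k1, k2)` against unrelatedness:
#' `k0 + k1 * LR1 + k2 * LR2`, where `LR1` is the one-IBD-allele
#' transition ratio and `LR2 = [g1 == g2] / P(g2)` with Hardy-Weinberg
#' genotype probabilities (`2pq` heterozygote, `p^2` homozygote). The
#' statistic is symmetric in the two genotypes. Alleles absent from
#' `freqs` raise an error: frequency misspecification must be explicit.
#'
#' @param g1,g2 Length-2 character vectors of allele labels (unordered).
#' @param rel Relationship label or `relationship` object.
#' @param freqs Named numeric vector of allele frequencies for the locus.
#' @return Nonnegative scalar LR.
#' @export
locus_lr <- function(g1, g2, rel, freqs) {
  rel <- .as_relationship(rel)
  g1 <- as.character(g1)
  g2 <- as.character(g2)
  if (length(g1) != 2L || length(g2) != 2L)
    stop("genotypes must be length-2 allele vectors")
  miss <- setdiff(c(g1, g2), names(freqs))
  if (length(miss))
    stop("allele(s) absent from frequency table: ",
         paste(unique(miss), collapse = ", "))
  pa <- freqs[[g1[1]]]
  pb <- freqs[[g1[2]]]
  pc <- freqs[[g2[1]]]
  pd <- freqs[[g2[2]]]
  lr1 <- ((g1[1] == g2[1]) / pa + (g1[1] == g2[2]) / pa +
          (g1[2] == g2[1]) / pb + (g1[2] == g2[2]) / pb) / 4
  ident <- (g1[1] == g2[1] && g1[2] == g2[2]) ||
           (g1[1] == g2[2] && g1[2] == g2[1])
  lr2 <- if (ident) {
    p2 <- if (g2[1] == g2[2]) pc * pc else 2 * pc * pd
    1 / p2
  } else 0
  rel$k0 + rel$k1 * lr1 + rel$k2 * lr2
}

#' Multi-locus autosomal likelihood ratio for one pair
#'
#' Product of [locus_lr()] over the pair's loci (loci are treated as
#' unlinked and independent), accumulated in log space.
#'
#' @param pair A `pair_sample`.
#' @param rel Relationship label or `relationship` object.
#' @param table An `allele_freq_table` whose loci match the pair's.
#' @return Nonnegative scalar LR.
#' @export
autosomal_lr <- function(pair, rel, table) {
  stopifnot(inherits(pair, "pair_sample"),
            inherits(table, "allele_freq_table"))
  rel <- .as_relationship(rel)
  loci <- colnames(pair$profile_a)
  if (!setequal(loci, names(table$loci)))
    stop("pair loci do not match reference table loci")
  ll <- 0
  for (l in loci)
    ll <- ll + log(locus_lr(pair$profile_a[, l], pair$profile_b[, l],
                            rel, table$loci[[l]]))
  exp(ll)
}

# vectorized upper confidence limit given haplotype counts in the pool
.y_upper_freq_vec <- function(count, pool_n, case_copies, cfg) {
  cc <- if (cfg$leave_out_case_copies) as.integer(case_copies) else 0L
  n <- pool_n - cc
  if (n <= 0L) stop("pooled reference empty after case-copy exclusion")
  x <- pmax(0L, count - cc)
  ph <- x / n
  up <- pmin(1, ph + cfg$confidence_z * sqrt(ph * (1 - ph) / n))
  zero <- x == 0L
  if (any(zero)) {
    z0 <- switch(cfg$zero_rule,
                 alpha_root = 1 - cfg$alpha^(1 / n),
                 three_over_n = 3 / n)
    up[zero] <- z0
  }
  up
}

#' Upper confidence limit of a Y-haplotype frequency
#'
#' Counts the haplotype in the pooled reference, optionally removes the
#' case's own copies from the count and the total, and returns the upper
#' confidence limit of the frequency (see [y_frequency_config()] for the
#' observed and unobserved rules). Monotone nondecreasing in the count
#' and always in `(0, 1]`.
#'
#' @param h Haplotype identifier.
#' @param pooled Pooled `y_haplotype_sample`.
#' @param case_copies Number of case copies to exclude when
#'   `leave_out_case_copies` is set (a searched pair contributes 2).
#' @param cfg A [y_frequency_config()].
#' @return Frequency upper limit in `(0, 1]`.
#' @export
y_upper_frequency <- function(h, pooled, case_copies = 0L,
                              cfg = y_frequency_config()) {
  stopifnot(inherits(pooled, "y_haplotype_sample"))
  .y_upper_freq_vec(sum(pooled$haplotypes == h), pooled$n, case_copies, cfg)
}

#' Y-haplotype likelihood ratio for one pair
#'
#' Ignoring mutation, Y-sharing relatives carry the same haplotype with
#' probability one while two unrelated individuals both carry a haplotype
#' of frequency `p` with probability `p^2` versus `p` for a shared
#' lineage, so the LR for a matching pair is `1/p` with `p` taken as the
#' conservative upper confidence limit ([y_upper_frequency()], excluding
#' the pair's two copies). Non-matching haplotypes give LR exactly 0: the
#' no-mutation relative model cannot produce them.
#'
#' @param y_a,y_b Haplotype identifiers of the pair.
#' @param pooled Pooled `y_haplotype_sample`.
#' @param cfg A [y_frequency_config()].
#' @return Nonnegative scalar LR.
#' @export
y_lr <- function(y_a, y_b, pooled, cfg = y_frequency_config()) {
  if (!identical(y_a, y_b)) return(0)
  1 / y_upper_frequency(y_a, pooled, case_copies = 2L, cfg = cfg)
}

#' Vectorized Y-haplotype likelihood ratios
#'
#' @param y_a,y_b Equal-length character vectors of haplotypes.
#' @param pooled Pooled `y_haplotype_sample`.
#' @param cfg A [y_frequency_config()].
#' @return Numeric vector of LRs (0 where the haplotypes differ).
#' @export
y_lrs <- function(y_a, y_b, pooled, cfg = y_frequency_config()) {
  stopifnot(length(y_a) == length(y_b),
            inherits(pooled, "y_haplotype_sample"))
  out <- numeric(length(y_a))
  m <- which(y_a == y_b)
  if (length(m)) {
    tab <- table(pooled$haplotypes)
    cnt <- as.integer(tab[y_a[m]])
    cnt[is.na(cnt)] <- 0L
    out[m] <- 1 / .y_upper_freq_vec(cnt, pooled$n, 2L, cfg)
  }
  out
}

#' Combined database-scaled statistic
#'
#' The product of the autosomal and Y-haplotype LR estimates divided by
#' the database size `N`; doubling `N` halves every value.
#'
#' @param lr_auto,lr_y Numeric (vectorized) LR values.
#' @param cfg A [clr_config()].
#' @return Numeric combined statistic.
#' @export
combined_clr <- function(lr_auto, lr_y, cfg) {
  stopifnot(inherits(cfg, "clr_config"))
  lr_auto * lr_y / cfg$database_size
}

#' Two-threshold positive-identification decision
#'
#' A pair is called a positive identification when the combined statistic
#' exceeds the floor threshold under *all* assumed reference panels and
#' the peak threshold under *at least one*. Monotone: raising any value
#' never turns a positive call negative.
#'
#' @param values Numeric vector of per-panel combined statistics.
#' @param cfg A [clr_config()].
#' @return Logical flag.
#' @export
decide <- function(values, cfg) {
  stopifnot(inherits(cfg, "clr_config"))
  if (length(values) < 1L || anyNA(values))
    stop("`values` must be a non-empty numeric vector without NAs")
  min(values) > cfg$floor_threshold && max(values) > cfg$peak_threshold
}

# vectorized log autosomal LR over a pair block under one reference table
.autosomal_loglr <- function(block, rel, table) {
  rel <- .as_relationship(rel)
  loci <- block$loci
  if (!all(loci %in% names(table$loci)))
    stop("reference table '", table$population_label, "' lacks loci: ",
         paste(setdiff(loci, names(table$loci)), collapse = ", "))
  k0 <- rel$k0; k1 <- rel$k1; k2 <- rel$k2
  ll <- numeric(block$n)
  for (l in seq_along(loci)) {
    ref <- table$loci[[loci[l]]]
    la <- block$labels_a[[l]]
    lb <- block$labels_b[[l]]
    fa <- unname(ref[la])
    fb <- unname(ref[lb])
    if (anyNA(fa) || anyNA(fb))
      stop("allele(s) absent from reference panel '",
           table$population_label, "' at locus ", loci[l])
    A1 <- block$a1[, l]; A2 <- block$a2[, l]
    B1 <- block$b1[, l]; B2 <- block$b2[, l]
    if (identical(la, lb)) {
      e11 <- A1 == B1; e12 <- A1 == B2
      e21 <- A2 == B1; e22 <- A2 == B2
    } else {
      La1 <- la[A1]; La2 <- la[A2]
      Lb1 <- lb[B1]; Lb2 <- lb[B2]
      e11 <- La1 == Lb1; e12 <- La1 == Lb2
      e21 <- La2 == Lb1; e22 <- La2 == Lb2
    }
    pa <- fa[A1]; pb <- fa[A2]
    pc <- fb[B1]; pd <- fb[B2]
    lr1 <- (e11 / pa + e12 / pa + e21 / pb + e22 / pb) / 4
    lr <- k0 + k1 * lr1
    if (k2 > 0) {
      ident <- (e11 & e22) | (e12 & e21)
      p2 <- ifelse(B1 == B2, pc * pc, 2 * pc * pd)
      lr <- lr + k2 * ifelse(ident, 1 / p2, 0)
    }
    ll <- ll + log(lr)
  }
  ll
}

#' Vectorized autosomal likelihood ratios over a pair block
#'
#' @param block A `pair_block` from the simulators.
#' @param rel Relationship label or `relationship` object.
#' @param table Reference `allele_freq_table`.
#' @return Numeric vector of per-pair LRs.
#' @export
autosomal_lrs <- function(block, rel, table) {
  stopifnot(inherits(block, "pair_block"),
            inherits(table, "allele_freq_table"))
  exp(.autosomal_loglr(block, rel, table))
}

#' Evaluate one pair under the full protocol
#'
#' Computes the autosomal LR under each reference panel, the (shared)
#' Y-haplotype LR, the per-panel combined statistics and the
#' two-threshold decision. Only the two relationships the operational
#' protocol tests — parent-offspring and sibling — are accepted.
#'
#' @param pair A `pair_sample`.
#' @param rel Tested relationship (`"parent-offspring"` or `"sibling"`).
#' @param cfg A [clr_config()].
#' @param ycfg A [y_frequency_config()].
#' @param pooled Pooled `y_haplotype_sample`.
#' @return A list of class `clr_result` with per-panel `autosomal_lr`,
#'   `y_lr`, `combined` and the `decision` flag.
#' @export
evaluate_pair <- function(pair, rel, cfg, ycfg = y_frequency_config(),
                          pooled) {
  stopifnot(inherits(pair, "pair_sample"), inherits(cfg, "clr_config"))
  rel <- .as_relationship(rel)
  if (!rel$label %in% c("parent-offspring", "sibling"))
    stop("tested relationship must be parent-offspring or sibling, got '",
         rel$label, "'")
  la <- vapply(cfg$reference_panels,
               function(tb) autosomal_lr(pair, rel, tb), 0)
  ly <- y_lr(pair$y_a, pair$y_b, pooled, ycfg)
  comb <- combined_clr(la, ly, cfg)
  structure(
    list(tested_relationship = rel$label, truth = pair$truth,
         autosomal_lr = la, y_lr = ly, combined = comb,
         decision = decide(comb, cfg)),
    class = "clr_result"
  )
}

#' @export
print.clr_result <- function(x, ...) {
  cat("Combined LR result (test:", x$tested_relationship,
      "| truth:", x$truth, ")\n")
  m <- rbind(`autosomal LR` = x$autosomal_lr,
             `combined` = x$combined)
  print(signif(m, 4))
  cat("Y LR:", signif(x$y_lr, 4),
      "| decision:", if (x$decision) "POSITIVE" else "negative", "\n")
  invisible(x)
}

#' Evaluate a pair block under the full protocol
#'
#' Vectorized version of [evaluate_pair()]. Pairs with non-matching Y
#' haplotypes have combined statistic 0 under every panel and are never
#' positive, so the autosomal LRs are only computed for Y-matching pairs.
#'
#' @param block A `pair_block`.
#' @param rel Tested relationship (`"parent-offspring"` or `"sibling"`).
#' @param cfg A [clr_config()].
#' @param ycfg A [y_frequency_config()].
#' @param pooled Pooled `y_haplotype_sample`.
#' @param values If `FALSE`, drop the per-pair combined-statistic matrix
#'   from the result (saves memory on large false-positive scans).
#' @return A list of class `clr_result_set` with the `decision` vector,
#'   the `y_lr` vector, and (optionally) the `clr` matrix (pairs x
#'   reference panels).
#' @export
evaluate_pairs <- function(block, rel, cfg, ycfg = y_frequency_config(),
                           pooled, values = TRUE) {
  stopifnot(inherits(block, "pair_block"), inherits(cfg, "clr_config"))
  rel <- .as_relationship(rel)
  if (!rel$label %in% c("parent-offspring", "sibling"))
    stop("tested relationship must be parent-offspring or sibling, got '",
         rel$label, "'")
  lry <- y_lrs(block$y_a, block$y_b, pooled, ycfg)
  panels <- cfg$reference_panels
  clr <- matrix(0, block$n, length(panels),
                dimnames = list(NULL, names(panels)))
  idx <- which(lry > 0)
  if (length(idx)) {
    sub <- .block_subset(block, idx)
    lg <- log(lry[idx]) - log(cfg$database_size)
    for (p in seq_along(panels))
      clr[idx, p] <- exp(.autosomal_loglr(sub, rel, panels[[p]]) + lg)
  }
  dmin <- clr[, 1L]
  dmax <- clr[, 1L]
  if (ncol(clr) > 1L) for (p in 2L:ncol(clr)) {
    dmin <- pmin(dmin, clr[, p])
    dmax <- pmax(dmax, clr[, p])
  }
  structure(
    list(tested_relationship = rel$label, truth = block$truth,
         decision = dmin > cfg$floor_threshold & dmax > cfg$peak_threshold,
         y_lr = lry, clr = if (values) clr else NULL, n = block$n),
    class = "clr_result_set"
  )
}
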