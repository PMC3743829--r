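# Simulation of genotype / Y-haplotype pairs under pairwise relationships.
#
# Relationships are parameterized by the IBD-sharing probabilities
# (k0, k1, k2); per locus the IBD state is drawn from them and the founder
# alleles are drawn sequentially with the standard coancestry-conditional
# (Dirichlet-predictive) formula, so background relatedness theta inflates
# the chance that successive founder alleles coincide. The sequence of
# theta-conditional draws is a Polya urn and therefore exchangeable, which
# is what makes the vectorized draw-four-assign-by-IBD-state scheme below
# exact.

#' Catalog of pairwise relationship models
#'
#' Each relationship carries its IBD-sharing probabilities `(k0, k1, k2)`
#' (the chance a pair shares 0, 1 or 2 alleles identical by descent at an
#' autosomal locus) and a flag for whether the relationship transmits the
#' Y chromosome along an unbroken male line. "half-cousin" means a single
#' shared grandparent; "second-cousin" a shared set of great-grandparents.
#' Ignoring mutation, every Y-sharing relationship shares the haplotype
#' with probability one; only "unrelated" is not Y-sharing, and only
#' "sibling" has `k2 > 0`.
#'
#' @return A data frame of class `relationship_catalog` with columns
#'   `label`, `k0`, `k1`, `k2`, `y_sharing`.
#' @export
relationship_catalog <- function() {
  rc <- data.frame(
    label = c("parent-offspring", "sibling", "half-sibling", "cousin",
              "half-cousin", "second-cousin", "unrelated"),
    k0 = c(0, 1 / 4, 1 / 2, 3 / 4, 7 / 8, 15 / 16, 1),
    k1 = c(1, 1 / 2, 1 / 2, 1 / 4, 1 / 8, 1 / 16, 0),
    k2 = c(0, 1 / 4, 0, 0, 0, 0, 0),
    y_sharing = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  class(rc) <- c("relationship_catalog", "data.frame")
  rc
}

#' Look up one relationship model
#'
#' @param label A label from [relationship_catalog()].
#' @return A list of class `relationship` with `label`, `k0`, `k1`, `k2`,
#'   `y_sharing`.
#' @export
get_relationship <- function(label) {
  rc <- relationship_catalog()
  i <- match(label, rc$label)
  if (is.na(i))
    stop("unknown relationship '", label, "'; known: ",
         paste(rc$label, collapse = ", "))
  r <- as.list(rc[i, , drop = FALSE])
  r <- lapply(r, unname)
  class(r) <- "relationship"
  r
}

.as_relationship <- function(x) {
  if (inherits(x, "relationship")) x else get_relationship(x)
}

#' Simulation configuration
#'
#' @param theta Coancestry (background relatedness) coefficient in
#'   `[0, 1)`; default 0.01, the lower recommended substructure correction
#'   for identification calculations.
#' @param n_pairs Number of pairs per simulation run.
#' @param seed Optional integer seed; when set, each batch simulator calls
#'   `set.seed()` on entry so runs are exactly reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(theta = 0.01, n_pairs = 1e5L, seed = NULL) {
  if (!is.numeric(theta) || theta < 0 || theta >= 1)
    stop("theta must satisfy 0 <= theta < 1")
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(theta = theta, n_pairs = n_pairs, seed = seed),
            class = "sim_config")
}

#' Conditional allele probabilities under coancestry
#'
#' Probability of drawing each allele given `m` previously drawn founder
#' alleles, under the standard coancestry correction:
#' `P(a) = (m_a * theta + (1 - theta) * p_a) / (1 + (m - 1) * theta)`,
#' where `m_a` counts allele `a` among the prior draws. With `theta = 0`
#' this reduces to the population frequencies regardless of the prior
#' draws; as `theta -> 1` the draw almost surely copies a previous allele.
#'
#' @param freqs Named numeric vector of allele frequencies.
#' @param prior_draws Character vector of previously drawn allele labels
#'   (possibly empty).
#' @param theta Coancestry coefficient in `[0, 1)`.
#' @return Named probability vector over the alleles of `freqs`.
#' @export
conditional_allele_probs <- function(freqs, prior_draws = character(),
                                     theta = 0.01) {
  if (theta < 0 || theta >= 1) stop("theta must satisfy 0 <= theta < 1")
  p <- freqs / sum(freqs)
  m <- length(prior_draws)
  if (m == 0L) return(p)
  if (!all(prior_draws %in% names(freqs)))
    stop("prior draws contain alleles absent from `freqs`")
  ma <- as.numeric(table(factor(prior_draws, levels = names(freqs))))
  (ma * theta + (1 - theta) * p) / (1 + (m - 1) * theta)
}

#' Draw one founder allele conditional on previous draws
#'
#' Single draw from [conditional_allele_probs()]; uses R's global RNG.
#'
#' @inheritParams conditional_allele_probs
#' @return One allele label.
#' @export
draw_allele_conditional <- function(freqs, prior_draws = character(),
                                    theta = 0.01) {
  pr <- conditional_allele_probs(freqs, prior_draws, theta)
  sample(names(freqs), 1L, prob = pr)
}

# n x k matrix of founder allele indices, drawn sequentially with the
# coancestry-conditional rule. Implemented as the equivalent Polya urn:
# with probability m*theta / (1 + (m-1)*theta) copy a uniformly chosen
# previous draw, otherwise draw fresh from p.
.founder_draws <- function(p, n, k, theta) {
  a <- length(p)
  out <- matrix(0L, n, k)
  out[, 1L] <- sample.int(a, n, replace = TRUE, prob = p)
  if (k > 1L) for (j in 2L:k) {
    m <- j - 1L
    pc <- m * theta / (1 + (m - 1L) * theta)
    fresh <- sample.int(a, n, replace = TRUE, prob = p)
    if (pc > 0) {
      copy <- stats::runif(n) < pc
      if (any(copy)) {
        src <- if (m == 1L) rep(1L, n) else sample.int(m, n, replace = TRUE)
        ci <- which(copy)
        fresh[ci] <- out[cbind(ci, src[ci])]
      }
    }
    out[, j] <- fresh
  }
  out
}

.new_pair_block <- function(n, tab_a, tab_b, truth, theta,
                            src = c(tab_a$population_label,
                                    tab_b$population_label)) {
  list(n = n, loci = names(tab_a$loci),
       labels_a = lapply(tab_a$loci, names),
       labels_b = lapply(tab_b$loci, names),
       a1 = NULL, a2 = NULL, b1 = NULL, b2 = NULL, ibd = NULL,
       y_a = NULL, y_b = NULL, truth = truth,
       source_panels = src, theta = theta)
}

#' Simulate a batch of Y-sharing relative pairs
#'
#' For each pair and locus independently the IBD state is drawn from
#' `(k0, k1, k2)`; four founder alleles are drawn sequentially with the
#' coancestry-conditional rule and assembled so that exactly the sampled
#' number of alleles is shared identical by descent (exchangeability of
#' the conditional draws makes discarding unused founders exact). The
#' shared Y haplotype is one uniform draw from the panel's empirical
#' sample — relatives share it with probability one, mutation being
#' ignored. Draw order: IBD states, then founder alleles locus by locus,
#' then the Y haplotype.
#'
#' @param panel A `population_panel`.
#' @param rel Relationship label or `relationship` object; must be
#'   Y-sharing (use [simulate_unrelated_pairs()] for unrelated pairs).
#' @param cfg A [sim_config()].
#' @return A `pair_block` with integer genotype matrices (`n_pairs` rows,
#'   one column per locus), the realized IBD states, and shared
#'   haplotypes `y_a == y_b`.
#' @export
simulate_relative_pairs <- function(panel, rel, cfg = sim_config()) {
  stopifnot(inherits(panel, "population_panel"), inherits(cfg, "sim_config"))
  rel <- .as_relationship(rel)
  if (!isTRUE(rel$y_sharing))
    stop("'", rel$label, "' is not Y-sharing; use simulate_unrelated_pairs()")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_pairs
  theta <- cfg$theta
  tab <- panel$autosomal
  nl <- length(tab$loci)
  blk <- .new_pair_block(n, tab, tab, rel$label, theta,
                         src = c(panel$label, panel$label))
  ibd <- matrix(sample.int(3L, n * nl, replace = TRUE,
                           prob = c(rel$k0, rel$k1, rel$k2)) - 1L, n, nl)
  a1 <- a2 <- b1 <- b2 <- matrix(0L, n, nl)
  for (l in seq_len(nl)) {
    f <- .founder_draws(unname(tab$loci[[l]]), n, 4L, theta)
    s <- ibd[, l]
    a1[, l] <- f[, 1L]
    a2[, l] <- f[, 2L]
    b1[, l] <- ifelse(s >= 1L, f[, 1L], f[, 3L])
    b2[, l] <- ifelse(s == 2L, f[, 2L], ifelse(s == 1L, f[, 3L], f[, 4L]))
  }
  y <- panel$y_sample$haplotypes[sample.int(panel$y_sample$n, n,
                                            replace = TRUE)]
  blk$a1 <- a1; blk$a2 <- a2; blk$b1 <- b1; blk$b2 <- b2
  blk$ibd <- ibd; blk$y_a <- y; blk$y_b <- y
  class(blk) <- "pair_block"
  blk
}

# Y haplotypes for a batch of unrelated pairs. Same-population pairs are
# two *distinct* individuals drawn from the sample without replacement, so
# the chance of a coincidental match equals the sample's own pairwise
# coincidence rate (an all-unique sample can never produce a match);
# cross-population pairs draw independently from each sample.
.unrelated_y_draws <- function(panel_a, panel_b, n) {
  same <- identical(panel_a$label, panel_b$label)
  ha <- panel_a$y_sample$haplotypes
  if (same) {
    ny <- panel_a$y_sample$n
    if (ny < 2L)
      stop("same-population unrelated pairs need >= 2 reference haplotypes")
    i <- sample.int(ny, n, replace = TRUE)
    j <- sample.int(ny - 1L, n, replace = TRUE)
    j <- j + (j >= i)
    list(y_a = ha[i], y_b = ha[j])
  } else {
    list(y_a = ha[sample.int(panel_a$y_sample$n, n, replace = TRUE)],
         y_b = panel_b$y_sample$haplotypes[
           sample.int(panel_b$y_sample$n, n, replace = TRUE)])
  }
}

# Autosomal genotypes for n unrelated pairs. When both sides come from the
# same population the four founder alleles are drawn sequentially with
# theta across the pair; across populations each individual's two alleles
# are drawn with theta within its own panel, independently of the other.
.unrelated_genotype_block <- function(panel_a, panel_b, n, theta) {
  tab_a <- panel_a$autosomal
  tab_b <- panel_b$autosomal
  if (!identical(names(tab_a$loci), names(tab_b$loci)))
    stop("panels have different locus sets")
  same <- identical(panel_a$label, panel_b$label)
  nl <- length(tab_a$loci)
  blk <- .new_pair_block(n, tab_a, tab_b, "unrelated", theta,
                         src = c(panel_a$label, panel_b$label))
  a1 <- a2 <- b1 <- b2 <- matrix(0L, n, nl)
  for (l in seq_len(nl)) {
    if (same) {
      f <- .founder_draws(unname(tab_a$loci[[l]]), n, 4L, theta)
      a1[, l] <- f[, 1L]; a2[, l] <- f[, 2L]
      b1[, l] <- f[, 3L]; b2[, l] <- f[, 4L]
    } else {
      fa <- .founder_draws(unname(tab_a$loci[[l]]), n, 2L, theta)
      fb <- .founder_draws(unname(tab_b$loci[[l]]), n, 2L, theta)
      a1[, l] <- fa[, 1L]; a2[, l] <- fa[, 2L]
      b1[, l] <- fb[, 1L]; b2[, l] <- fb[, 2L]
    }
  }
  blk$a1 <- a1; blk$a2 <- a2; blk$b1 <- b1; blk$b2 <- b2
  blk$ibd <- matrix(0L, n, nl)
  class(blk) <- "pair_block"
  blk
}

#' Simulate a batch of unrelated pairs
#'
#' Y haplotypes first (same-population pairs are two distinct entries of
#' the empirical sample, see Details in [simulate_relative_pairs()] for
#' draw order), then the autosomal genotypes.
#'
#' @param panel_a,panel_b `population_panel` objects; the same panel for a
#'   within-population pair.
#' @param cfg A [sim_config()].
#' @return A `pair_block` with `truth = "unrelated"`.
#' @export
simulate_unrelated_pairs <- function(panel_a, panel_b = panel_a,
                                     cfg = sim_config()) {
  stopifnot(inherits(panel_a, "population_panel"),
            inherits(panel_b, "population_panel"),
            inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_pairs
  y <- .unrelated_y_draws(panel_a, panel_b, n)
  blk <- .unrelated_genotype_block(panel_a, panel_b, n, cfg$theta)
  blk$y_a <- y$y_a
  blk$y_b <- y$y_b
  blk
}

#' @export
print.pair_block <- function(x, ...) {
  cat("Pair block:", x$n, "pairs,", length(x$loci), "loci, truth =",
      x$truth, "\n")
  cat("  source panels:", paste(unique(x$source_panels), collapse = " x "),
      " theta =", x$theta, "\n")
  cat("  Y-haplotype matches:", sum(x$y_a == x$y_b), "\n")
  invisible(x)
}

.block_subset <- function(block, idx) {
  out <- block
  for (f in c("a1", "a2", "b1", "b2", "ibd"))
    out[[f]] <- block[[f]][idx, , drop = FALSE]
  out$y_a <- block$y_a[idx]
  out$y_b <- block$y_b[idx]
  out$n <- length(idx)
  out
}

.block_to_pair <- function(block, i = 1L) {
  nl <- length(block$loci)
  prof <- function(r1, r2, labs) {
    m <- vapply(seq_len(nl), function(l)
      c(labs[[l]][block[[r1]][i, l]], labs[[l]][block[[r2]][i, l]]),
      character(2L))
    colnames(m) <- block$loci
    m
  }
  structure(
    list(profile_a = prof("a1", "a2", block$labels_a),
         profile_b = prof("b1", "b2", block$labels_b),
         y_a = block$y_a[i], y_b = block$y_b[i],
         truth = block$truth, source_panels = block$source_panels),
    class = "pair_sample"
  )
}

#' Simulate a single relative pair
#'
#' Convenience wrapper around [simulate_relative_pairs()] returning one
#' `pair_sample`: two genotype profiles (2 x loci character matrices of
#' allele labels), the shared Y haplotype and the true relationship.
#'
#' @inheritParams simulate_relative_pairs
#' @return A `pair_sample`.
#' @export
sample_relative_pair <- function(panel, rel, cfg = sim_config()) {
  cfg$n_pairs <- 1L
  .block_to_pair(simulate_relative_pairs(panel, rel, cfg))
}

#' Simulate a single unrelated pair
#'
#' @inheritParams simulate_unrelated_pairs
#' @return A `pair_sample` with `truth = "unrelated"`.
#' @export
sample_unrelated_pair <- function(panel_a, panel_b = panel_a,
                                  cfg = sim_config()) {
  cfg$n_pairs <- 1L
  .block_to_pair(simulate_unrelated_pairs(panel_a, panel_b, cfg))
}

#' @export
print.pair_sample <- function(x, ...) {
  cat("Pair sample (truth:", x$truth, ")\n")
  cat("  loci:", paste(colnames(x$profile_a), collapse = ", "), "\n")
  cat("  Y:", if (identical(x$y_a, x$y_b)) "shared" else "different", "\n")
  invisible(x)
}
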