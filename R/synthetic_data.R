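# Synthetic population panels: Dirichlet allele-frequency tables,
# categorical Y-haplotype pools with a tunable coincidence rate, and
# normalized demographic vectors. All generators are pure functions of
# their spec (which carries the seed); the caller's RNG state is left
# untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Specification for a synthetic population panel
#'
#' Captures everything the synthetic generators need: per-locus allele
#' frequencies are drawn from a symmetric Dirichlet with parameter
#' `concentration` (one diversity knob: small values give skewed spectra,
#' large values approach uniform frequencies), and the Y pool is drawn
#' i.i.d. from a categorical distribution over `y_distinct` synthetic
#' haplotype labels with Dirichlet(`y_skew`) weights. Setting
#' `y_distinct == y_pool_size` switches to sampling the labels without
#' replacement, forcing an all-unique sample (zero coincidental matches);
#' `y_distinct` much larger than `y_pool_size` gives the realistic
#' low-coincidence regime (pairwise match probability of order
#' `2 / y_distinct`), while small `y_distinct` gives heavy sharing.
#'
#' Defaults mirror a desk-scale forensic panel: 13 loci with 10 alleles
#' each at concentration 1 (expected gene diversity ~0.82, comparable to
#' the core CODIS loci), a Y pool of 2000 with 25000 generating haplotypes
#' (pairwise coincidence ~8e-5, the intermediate sharing regime seen in
#' large published Y-STR samples).
#'
#' @param n_loci Number of autosomal loci.
#' @param alleles_per_locus Scalar or per-locus vector of allele counts
#'   (each at least 2).
#' @param concentration Symmetric Dirichlet parameter for allele
#'   frequencies (> 0).
#' @param y_pool_size Number of Y haplotypes in a generated sample.
#' @param y_distinct Number of distinct haplotype labels in the generating
#'   pool (>= 1).
#' @param y_skew Dirichlet parameter for the haplotype weights (> 0).
#' @param seed Integer seed; the generators are deterministic given the
#'   spec.
#' @return An object of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_loci = 13L, alleles_per_locus = 10L,
                                 concentration = 1, y_pool_size = 2000L,
                                 y_distinct = 25000L, y_skew = 1,
                                 seed = 1L) {
  n_loci <- as.integer(n_loci)
  if (n_loci < 1L) stop("n_loci must be >= 1")
  alleles_per_locus <- as.integer(alleles_per_locus)
  if (length(alleles_per_locus) == 1L)
    alleles_per_locus <- rep(alleles_per_locus, n_loci)
  if (length(alleles_per_locus) != n_loci || any(alleles_per_locus < 2L))
    stop("alleles_per_locus must be >= 2, scalar or length n_loci")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be positive")
  y_pool_size <- as.integer(y_pool_size)
  y_distinct <- as.integer(y_distinct)
  if (y_pool_size < 1L) stop("y_pool_size must be >= 1")
  if (y_distinct < 1L) stop("validation error: y_distinct must be >= 1")
  if (!is.numeric(y_skew) || y_skew <= 0) stop("y_skew must be positive")
  structure(
    list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
         concentration = concentration, y_pool_size = y_pool_size,
         y_distinct = y_distinct, y_skew = y_skew,
         seed = as.integer(seed) %% 2147483647L),
    class = "synthetic_panel_spec"
  )
}

#' Generate a synthetic allele-frequency table
#'
#' Per-locus frequencies are independent symmetric Dirichlet draws.
#' Locus names are the 13 core CODIS loci when `n_loci == 13`, otherwise
#' generic `L01`, `L02`, ...; allele labels are STR-style repeat counts
#' starting at 6. Deterministic given the spec.
#'
#' @param spec A [synthetic_panel_spec()].
#' @param label Population label for the table.
#' @return An `allele_freq_table`.
#' @export
gen_frequency_table <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  .with_seed((spec$seed + 11L) %% 2147483647L, {
    loci <- lapply(seq_len(spec$n_loci), function(l) {
      a <- spec$alleles_per_locus[l]
      f <- drop(.rdirichlet(1L, rep(spec$concentration, a)))
      # guard against numerically zero components of extreme draws
      f <- pmax(f, 1e-12)
      stats::setNames(f / sum(f), as.character(seq(6L, length.out = a)))
    })
    names(loci) <- if (spec$n_loci == 13L) CODIS_CORE_LOCI
                   else sprintf("L%02d", seq_len(spec$n_loci))
    allele_freq_table(label, loci)
  })
}

#' Generate a synthetic Y-haplotype sample
#'
#' Haplotype identifiers are opaque strings (`"<prefix>-H00001"` etc.);
#' downstream logic uses only equality, so no marker structure is needed.
#' In the all-unique mode (`y_distinct == y_pool_size`) labels are sampled
#' without replacement, reproducing a fully diverse sample; otherwise
#' draws are i.i.d. categorical with Dirichlet(`y_skew`) weights, and the
#' realized weights are attached as the `"weights"` attribute (the
#' expected pairwise coincidental-match probability is `sum(weights^2)`).
#' The label prefix keeps haplotype spaces of different panels disjoint,
#' mirroring the predominantly population-private nature of Y-STR
#' haplotypes.
#'
#' @param spec A [synthetic_panel_spec()].
#' @param label Population label.
#' @param prefix Identifier prefix; defaults to `label`.
#' @return A `y_haplotype_sample` of size `spec$y_pool_size`.
#' @export
gen_y_sample <- function(spec, label = "synthetic", prefix = label) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  .with_seed((spec$seed + 22L) %% 2147483647L, {
    ids <- sprintf("%s-H%05d", prefix, seq_len(spec$y_distinct))
    if (spec$y_distinct == spec$y_pool_size) {
      haps <- sample(ids)
      w <- rep(1 / spec$y_distinct, spec$y_distinct)
    } else {
      w <- drop(.rdirichlet(1L, rep(spec$y_skew, spec$y_distinct)))
      haps <- ids[sample.int(spec$y_distinct, spec$y_pool_size,
                             replace = TRUE, prob = w)]
    }
    out <- y_haplotype_sample(label, haps)
    attr(out, "weights") <- w
    out
  })
}

#' Normalize demographic proportions
#'
#' Turns nonnegative group weights (e.g. census or incarcerated-population
#' head counts) into proportions summing to one, under the assumption that
#' every individual belongs to exactly one group.
#'
#' @param labels Group labels.
#' @param weights Nonnegative weights, at least one positive.
#' @return An object of class `demographics` with `labels` and
#'   `proportions` (named, summing to 1).
#' @export
gen_demographics <- function(labels, weights) {
  labels <- as.character(labels)
  if (length(labels) != length(weights) || length(labels) < 1L)
    stop("labels and weights must have equal positive length")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be nonnegative and finite")
  if (sum(weights) <= 0)
    stop("validation error: at least one weight must be positive")
  structure(
    list(labels = labels,
         proportions = stats::setNames(weights / sum(weights), labels)),
    class = "demographics"
  )
}

#' Generate a full synthetic population panel
#'
#' Convenience wrapper combining [gen_frequency_table()] and
#' [gen_y_sample()] under one label.
#'
#' @param spec A [synthetic_panel_spec()].
#' @param label Panel label.
#' @return A `population_panel`.
#' @export
gen_population_panel <- function(spec, label = "synthetic") {
  population_panel(gen_frequency_table(spec, label),
                   gen_y_sample(spec, label), label = label)
}
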