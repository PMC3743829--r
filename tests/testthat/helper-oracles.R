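# Independent oracles used across the suite. These deliberately avoid the
# package's own formulas: IBD coefficients come from exhaustive
# gene-dropping through explicit pedigrees, and locus LRs from brute-force
# enumeration of founder-allele configurations.

# Exact (k0, k1, k2) by enumerating every meiosis outcome in a pedigree.
# `ped` is a named list person -> character(2) of parents (NULL for
# founders), listed so parents precede children. Founders receive unique
# allele labels; every combination of transmission choices is enumerated
# and the IBD sharing between id1 and id2 tabulated.
oracle_kappa <- function(ped, id1, id2) {
  is_founder <- vapply(ped, is.null, TRUE)
  founders <- names(ped)[is_founder]
  nonf <- names(ped)[!is_founder]
  alleles <- list()
  k <- 0L
  for (f in founders) {
    alleles[[f]] <- c(k + 1L, k + 2L)
    k <- k + 2L
  }
  nb <- 2L * length(nonf)
  combos <- as.matrix(expand.grid(rep(list(1:2), nb)))
  counts <- c(`0` = 0L, `1` = 0L, `2` = 0L)
  for (r in seq_len(nrow(combos))) {
    bits <- combos[r, ]
    gen <- alleles
    for (i in seq_along(nonf)) {
      pr <- ped[[nonf[i]]]
      gen[[nonf[i]]] <- c(gen[[pr[1]]][bits[2L * i - 1L]],
                          gen[[pr[2]]][bits[2L * i]])
    }
    s <- length(intersect(gen[[id1]], gen[[id2]]))
    counts[s + 1L] <- counts[s + 1L] + 1L
  }
  unname(counts / sum(counts))
}

oracle_pedigrees <- list(
  "parent-offspring" = list(
    ped = list(F1 = NULL, M1 = NULL, C1 = c("F1", "M1")),
    ids = c("F1", "C1")),
  "sibling" = list(
    ped = list(F1 = NULL, M1 = NULL,
               C1 = c("F1", "M1"), C2 = c("F1", "M1")),
    ids = c("C1", "C2")),
  "half-sibling" = list(
    ped = list(F1 = NULL, M1 = NULL, M2 = NULL,
               C1 = c("F1", "M1"), C2 = c("F1", "M2")),
    ids = c("C1", "C2")),
  "cousin" = list(
    ped = list(GF = NULL, GM = NULL, X1 = NULL, X2 = NULL,
               P1 = c("GF", "GM"), P2 = c("GF", "GM"),
               C1 = c("P1", "X1"), C2 = c("P2", "X2")),
    ids = c("C1", "C2")),
  "half-cousin" = list(
    ped = list(GF = NULL, GM1 = NULL, GM2 = NULL, X1 = NULL, X2 = NULL,
               P1 = c("GF", "GM1"), P2 = c("GF", "GM2"),
               C1 = c("P1", "X1"), C2 = c("P2", "X2")),
    ids = c("C1", "C2")),
  "second-cousin" = list(
    ped = list(GGF = NULL, GGM = NULL, S1 = NULL, S2 = NULL,
               S3 = NULL, S4 = NULL,
               GP1 = c("GGF", "GGM"), GP2 = c("GGF", "GGM"),
               P1 = c("GP1", "S1"), P2 = c("GP2", "S2"),
               C1 = c("P1", "S3"), C2 = c("P2", "S4")),
    ids = c("C1", "C2"))
)

# All unordered single-locus genotypes over the alleles of p.
oracle_genotypes <- function(p) {
  a <- names(p)
  out <- list()
  for (i in seq_along(a)) for (j in i:length(a))
    out[[length(out) + 1L]] <- c(a[i], a[j])
  out
}

.gkey <- function(g) paste(sort(g), collapse = "/")

# Exhaustive-enumeration locus LR: joint genotype-pair probabilities are
# built by summing over founder-allele configurations (z shared IBD, u and
# v private) for the one-IBD component, with HWE marginals; the LR is the
# ratio of joint to product-of-marginals.
oracle_locus_lr <- function(g1, g2, kappa, p) {
  a <- names(p)
  hwe <- function(g) if (g[1] == g[2]) p[[g[1]]]^2 else 2 * p[[g[1]]] * p[[g[2]]]
  key1 <- .gkey(g1)
  key2 <- .gkey(g2)
  j1 <- 0
  for (z in a) for (u in a) for (v in a) {
    if (.gkey(c(z, u)) == key1 && .gkey(c(z, v)) == key2)
      j1 <- j1 + p[[z]] * p[[u]] * p[[v]]
  }
  p1 <- hwe(g1)
  p2 <- hwe(g2)
  joint <- kappa[1] * p1 * p2 + kappa[2] * j1 +
    kappa[3] * (if (key1 == key2) p1 else 0)
  joint / (p1 * p2)
}
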