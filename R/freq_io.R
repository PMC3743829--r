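# Reference-data containers: autosomal STR allele-frequency tables and
# Y-STR haplotype samples, with a plain TSV dialect for both.

#' Names of the 13 core CODIS autosomal STR loci
#'
#' @format Character vector of length 13.
#' @export
CODIS_CORE_LOCI <- c(
  "CSF1PO", "D3S1358", "D5S818", "D7S820", "D8S1179", "D13S317",
  "D16S539", "D18S51", "D21S11", "FGA", "TH01", "TPOX", "vWA"
)

#' Marker names of the 17-marker YFiler Y-STR panel
#'
#' The multi-copy locus DYS385 contributes two values (`DYS385a`,
#' `DYS385b`); a haplotype is the joint profile over all 17 values,
#' inherited patrilineally without recombination.
#'
#' @format Character vector of length 17.
#' @export
YFILER_MARKERS <- c(
  "DYS456", "DYS389I", "DYS390", "DYS389II", "DYS458", "DYS19",
  "DYS385a", "DYS385b", "DYS393", "DYS391", "DYS439", "DYS635",
  "DYS392", "YGATAH4", "DYS437", "DYS438", "DYS448"
)

#' Construct an allele-frequency table
#'
#' One population sample's per-locus allele frequencies. Allele labels are
#' kept as text because STR alleles include microvariants ("9.3") that are
#' not numbers. Frequencies are renormalized per locus on construction:
#' silently when the raw sum deviates from 1 by at most 1e-3 (published
#' tables are rounded), with a warning up to 0.05, and with an error beyond
#' that (a sum that far off indicates a corrupt table, not rounding).
#'
#' @param population_label Name of the population sample.
#' @param loci Named list (locus name -> named numeric vector of
#'   allele frequencies). Every locus needs at least two alleles and
#'   strictly positive frequencies.
#' @param sample_size Optional count of individuals behind the estimates.
#' @param codis_core Flag; if `TRUE` the table must have exactly 13 loci.
#'   Defaults to `TRUE` when 13 loci are supplied.
#' @return An object of class `allele_freq_table`.
#' @export
allele_freq_table <- function(population_label, loci, sample_size = NULL,
                              codis_core = NULL) {
  stopifnot(is.character(population_label), length(population_label) == 1L)
  if (!is.list(loci) || length(loci) < 1L || is.null(names(loci)) ||
      any(!nzchar(names(loci))) || anyDuplicated(names(loci)))
    stop("`loci` must be a non-empty named list with unique locus names")
  if (is.null(codis_core)) codis_core <- length(loci) == 13L
  if (codis_core && length(loci) != 13L)
    stop("a CODIS-core table must have exactly 13 loci, got ", length(loci))
  nm <- names(loci)
  loci <- lapply(nm, function(locus) {
    f <- loci[[locus]]
    if (!is.numeric(f) || is.null(names(f)) || any(!nzchar(names(f))) ||
        anyDuplicated(names(f)))
      stop("locus ", locus, ": frequencies must be a named numeric vector ",
           "with unique allele labels")
    if (length(f) < 2L)
      stop("locus ", locus, ": fewer than 2 alleles")
    if (any(!is.finite(f)) || any(f <= 0))
      stop("locus ", locus, ": all frequencies must be positive and finite")
    s <- sum(f)
    dev <- abs(s - 1)
    if (dev > 0.05)
      stop("locus ", locus, ": frequencies sum to ", signif(s, 6),
           "; refusing to renormalize")
    if (dev > 1e-3)
      warning("locus ", locus, ": frequencies sum to ", signif(s, 6),
              "; renormalizing")
    f / s
  })
  names(loci) <- nm
  structure(
    list(population_label = population_label, loci = loci,
         sample_size = sample_size, codis_core = codis_core),
    class = "allele_freq_table"
  )
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("Allele frequency table:", x$population_label, "\n")
  cat("  ", length(x$loci), " loci (",
      paste(utils::head(names(x$loci), 4), collapse = ", "),
      if (length(x$loci) > 4) ", ..." else "", ")\n", sep = "")
  if (!is.null(x$sample_size))
    cat("  sample size:", x$sample_size, "individuals\n")
  invisible(x)
}

#' Construct a Y-haplotype sample
#'
#' A population sample of Y-STR haplotypes, kept as canonical identifier
#' strings; equality of haplotypes is exact string equality.
#'
#' @param population_label Name of the population sample.
#' @param haplotypes Character vector of haplotype identifiers (one entry
#'   per sampled individual; duplicates are meaningful).
#' @return An object of class `y_haplotype_sample` with fields
#'   `population_label`, `haplotypes` and `n`.
#' @export
y_haplotype_sample <- function(population_label, haplotypes) {
  stopifnot(is.character(population_label), length(population_label) == 1L)
  haplotypes <- trimws(as.character(haplotypes))
  if (length(haplotypes) < 1L || any(!nzchar(haplotypes)))
    stop("`haplotypes` must contain at least one non-empty identifier")
  structure(
    list(population_label = population_label, haplotypes = haplotypes,
         n = length(haplotypes)),
    class = "y_haplotype_sample"
  )
}

#' @export
print.y_haplotype_sample <- function(x, ...) {
  cat("Y-haplotype sample:", x$population_label, "\n")
  cat("  n =", x$n, "haplotypes,", length(unique(x$haplotypes)), "distinct\n")
  invisible(x)
}

#' Canonicalize Y-STR haplotypes
#'
#' Collapses a haplotype to a single deterministic string so haplotype
#' comparison is exact string equality. For 17-column YFiler layouts the
#' marker values are joined with "-" in the fixed [YFILER_MARKERS] order,
#' with the two DYS385 values sorted and joined as "a/b" (the locus is
#' multi-copy, so its two values are unordered). Plain character input is
#' only trimmed: it is assumed to already be canonical (e.g. synthetic
#' identifiers).
#'
#' @param x Character vector of haplotype strings, or a data frame/matrix
#'   with 17 marker columns (matched to [YFILER_MARKERS] by name when all
#'   names are present, otherwise by position).
#' @return Character vector of canonical haplotype strings.
#' @export
canonicalize_haplotypes <- function(x) {
  if (is.character(x)) return(trimws(x))
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x))
    stop("`x` must be a character vector or a 17-column table")
  if (ncol(x) != length(YFILER_MARKERS))
    stop("wrong marker count: expected ", length(YFILER_MARKERS),
         " YFiler marker columns, got ", ncol(x))
  nm <- gsub("[^A-Za-z0-9]", "", toupper(names(x)))
  target <- gsub("[^A-Za-z0-9]", "", toupper(YFILER_MARKERS))
  if (all(target %in% nm)) x <- x[match(target, nm)]
  vals <- lapply(x, function(col) trimws(as.character(col)))
  ia <- which(YFILER_MARKERS == "DYS385a")
  ib <- which(YFILER_MARKERS == "DYS385b")
  d385 <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "/"),
                 vals[[ia]], vals[[ib]], USE.NAMES = FALSE)
  keep <- setdiff(seq_along(vals), c(ia, ib))
  parts <- vals[keep]
  # reinsert the fused DYS385 field at the DYS385a position
  out <- vector("list", length(parts) + 1L)
  pos <- ia - sum(c(ia, ib) < ia)  # index of DYS385 among remaining slots
  out[seq_len(pos - 1L)] <- parts[seq_len(pos - 1L)]
  out[[pos]] <- d385
  out[(pos + 1L):length(out)] <- parts[pos:length(parts)]
  do.call(paste, c(out, sep = "-"))
}

.parse_meta <- function(lines) {
  meta <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", meta))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(trimws(vapply(kv, `[`, "", 3L)),
                  vapply(kv, `[`, "", 2L))
}

#' Read an autosomal allele-frequency table from TSV
#'
#' Expects tab-separated text with a header containing columns `locus`,
#' `allele` and `freq` (or `frequency`). Lines starting with `#` are
#' treated as metadata comments; `# population=` and `# sample_size=` are
#' honoured. Frequencies are validated and renormalized per locus as in
#' [allele_freq_table()].
#'
#' @param path File path.
#' @param population_label Optional population label; defaults to the file
#'   metadata or the file name.
#' @return An `allele_freq_table`.
#' @export
read_autosomal_frequencies <- function(path, population_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- .parse_meta(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          colClasses = "character", check.names = FALSE)
  names(df) <- tolower(names(df))
  fcol <- intersect(c("freq", "frequency"), names(df))[1]
  need <- c("locus", "allele")
  if (anyNA(fcol) || !all(need %in% names(df)))
    stop("format error: expected columns locus, allele, freq; got: ",
         paste(names(df), collapse = ", "))
  f <- suppressWarnings(as.numeric(df[[fcol]]))
  if (anyNA(f)) stop("format error: non-numeric frequency values")
  if (any(f <= 0)) stop("validation error: non-positive frequency")
  locus_order <- unique(df$locus)
  loci <- lapply(locus_order, function(l) {
    sel <- df$locus == l
    stats::setNames(f[sel], df$allele[sel])
  })
  names(loci) <- locus_order
  if (is.null(population_label))
    population_label <- if (!is.na(meta["population"])) meta[["population"]]
                        else sub("\\.[^.]*$", "", basename(path))
  size <- if (!is.na(meta["sample_size"])) as.integer(meta[["sample_size"]])
          else NULL
  allele_freq_table(population_label, loci, sample_size = size)
}

#' Write an allele-frequency table as TSV
#'
#' Inverse of [read_autosomal_frequencies()]; full double precision is kept
#' so write-then-read is the identity.
#'
#' @param table An `allele_freq_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(table, path) {
  stopifnot(inherits(table, "allele_freq_table"))
  hdr <- paste0("# population=", table$population_label)
  if (!is.null(table$sample_size))
    hdr <- c(hdr, paste0("# sample_size=", table$sample_size))
  rows <- unlist(lapply(names(table$loci), function(l) {
    f <- table$loci[[l]]
    sprintf("%s\t%s\t%.17g", l, names(f), f)
  }))
  writeLines(c(hdr, "locus\tallele\tfreq", rows), path)
  invisible(path)
}

#' Read a Y-haplotype sample
#'
#' Accepts either one canonical haplotype per line (with or without a
#' `haplotype` header), or a tab-separated 17-marker columnar layout which
#' is passed through [canonicalize_haplotypes()]. `#` comment lines carry
#' metadata as in [read_autosomal_frequencies()].
#'
#' @param path File path.
#' @param population_label Optional label override.
#' @return A `y_haplotype_sample` with `n` equal to the number of rows.
#' @export
read_y_haplotypes <- function(path, population_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- .parse_meta(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no haplotype rows in ", path)
  if (grepl("\t", body[1])) {
    df <- utils::read.delim(text = paste(body, collapse = "\n"),
                            colClasses = "character", check.names = FALSE)
    haps <- canonicalize_haplotypes(df)
  } else {
    if (tolower(trimws(body[1])) == "haplotype") body <- body[-1]
    haps <- canonicalize_haplotypes(body)
  }
  if (is.null(population_label))
    population_label <- if (!is.na(meta["population"])) meta[["population"]]
                        else sub("\\.[^.]*$", "", basename(path))
  y_haplotype_sample(population_label, haps)
}

#' Write a Y-haplotype sample as TSV
#'
#' @param sample A `y_haplotype_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_y_haplotypes <- function(sample, path) {
  stopifnot(inherits(sample, "y_haplotype_sample"))
  writeLines(c(paste0("# population=", sample$population_label),
               "haplotype", sample$haplotypes), path)
  invisible(path)
}

#' Pool Y-haplotype samples across populations
#'
#' Concatenates the samples: the pooled size is the sum of the sample
#' sizes and per-haplotype counts are summed, so pooling is associative
#' and order-insensitive in the resulting counts. The pooled reference is
#' what the Y-haplotype frequency confidence limit is computed from.
#'
#' @param samples List of `y_haplotype_sample` objects (at least one).
#' @param label Label for the pooled sample.
#' @return A `y_haplotype_sample`.
#' @export
pool_y_references <- function(samples, label = "pooled") {
  if (inherits(samples, "y_haplotype_sample")) samples <- list(samples)
  if (!is.list(samples) || length(samples) < 1L ||
      !all(vapply(samples, inherits, TRUE, "y_haplotype_sample")))
    stop("`samples` must be a non-empty list of y_haplotype_sample objects")
  y_haplotype_sample(label,
                     unlist(lapply(samples, `[[`, "haplotypes"),
                            use.names = FALSE))
}

#' Bundle autosomal and Y references for one population
#'
#' A population panel pairs an autosomal frequency table with a Y-haplotype
#' sample under one label. A warning (not an error) is issued when the
#' constituent labels differ: published autosomal and Y surveys use
#' different labelling schemes, and mixed pairings are sometimes the only
#' ones available.
#'
#' @param autosomal An `allele_freq_table`.
#' @param y_sample A `y_haplotype_sample`.
#' @param label Panel label; defaults to the autosomal table's label.
#' @return An object of class `population_panel`.
#' @export
population_panel <- function(autosomal, y_sample,
                             label = autosomal$population_label) {
  stopifnot(inherits(autosomal, "allele_freq_table"),
            inherits(y_sample, "y_haplotype_sample"))
  if (!identical(autosomal$population_label, label) ||
      !identical(y_sample$population_label, label))
    warning("panel '", label, "' combines samples labelled '",
            autosomal$population_label, "' (autosomal) and '",
            y_sample$population_label, "' (Y)")
  structure(list(label = label, autosomal = autosomal, y_sample = y_sample),
            class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  cat("Population panel:", x$label, "\n")
  cat("  autosomal:", length(x$autosomal$loci), "loci\n")
  cat("  Y sample: n =", x$y_sample$n, "\n")
  invisible(x)
}
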