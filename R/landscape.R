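#' Binary genotype-phenotype landscapes
#'
#' A `genotype_landscape` holds one quantitative phenotype per combination of
#' binary states at `n` mutable sites: `2^n` genotypes in total.  Genotypes
#' are written as bitstrings with the leftmost character corresponding to site
#' `n` (the highest site index) and the rightmost to site 1; `"0"` is the
#' wild-type state and `"1"` the mutant state.  Entry `i + 1` of the phenotype
#' vector corresponds to the genotype whose bitstring is the binary expansion
#' of `i`, so index 0 is the all-wild-type reference.
#'
#' Phenotypes are typically free energies (kcal/mol), but any scale on which
#' independent mutations act additively is valid.  Missing genotypes are held
#' as `NA` and tracked by the `observed` flag; complete-data analyses refuse
#' masked landscapes and never read unobserved entries.
#'
#' @param phenotype numeric vector.  Either length `2^n` in binary genotype
#'   order (possibly with `NA` for unobserved genotypes), or, when
#'   `genotypes` is given, one value per listed genotype.
#' @param sd optional nonnegative numeric vector of per-genotype standard
#'   deviations, same shape as `phenotype`.
#' @param genotypes optional character vector of bitstrings (e.g. `"011"`)
#'   labelling `phenotype`; genotypes absent from the list are marked
#'   unobserved.  All strings must have equal length and contain only 0/1.
#' @param n number of sites; required when it cannot be inferred from
#'   `genotypes` or from `length(phenotype)`.
#' @param labels optional character vector of per-site names, ordered from
#'   site `n` down to site 1 (i.e. matching the printed bit order).
#'
#' @return An object of class `genotype_landscape`: a list with elements
#'   `n`, `phenotype` (length `2^n`, `NA` where unobserved), `sd`,
#'   `observed` (logical), and `labels`.
#' @examples
#' # a complete 2-site landscape with additive effects 1 and 2
#' genotype_landscape(c(0, 1, 2, 3))
#'
#' # an incomplete landscape given as labelled genotypes
#' genotype_landscape(c(0, 1, 2), genotypes = c("00", "01", "10"))
#' @seealso [epistasis()], [read_landscape()], [simulate_landscape()]
#' @export
genotype_landscape <- function(phenotype, sd = NULL, genotypes = NULL,
                               n = NULL, labels = NULL) {
  if (!is.null(genotypes)) {
    genotypes <- as.character(genotypes)
    nch <- unique(nchar(genotypes))
    if (length(nch) != 1L)
      stop("all genotype strings must have the same length")
    if (any(!grepl("^[01]+$", genotypes)))
      stop("genotype strings must contain only '0' and '1'")
    if (anyDuplicated(genotypes))
      stop("duplicated genotype(s): ",
           paste(unique(genotypes[duplicated(genotypes)]), collapse = ", "))
    if (is.null(n)) n <- nch
    if (n != nch) stop("genotype strings have length ", nch, ", not n = ", n)
    if (length(phenotype) != length(genotypes))
      stop("phenotype must have one value per genotype")
    y <- rep(NA_real_, 2^n)
    y[genotype_to_index(genotypes) + 1L] <- phenotype
    if (!is.null(sd)) {
      s <- rep(NA_real_, 2^n)
      s[genotype_to_index(genotypes) + 1L] <- sd
      sd <- s
    }
    phenotype <- y
  } else {
    if (is.null(n)) {
      n <- round(log2(length(phenotype)))
      if (2^n != length(phenotype))
        stop("length(phenotype) is not a power of two; give n or genotypes")
    }
    if (length(phenotype) != 2^n)
      stop("phenotype must have length 2^n = ", 2^n)
  }
  n <- as.integer(n)
  if (n < 1L) stop("n must be a positive integer")
  observed <- !is.na(phenotype)
  if (!any(observed)) stop("at least one genotype must be observed")
  if (!is.null(sd)) {
    if (length(sd) != 2^n) stop("sd must have length 2^n")
    if (any(sd[observed] < 0, na.rm = TRUE)) stop("sd must be nonnegative")
  }
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per site")
  structure(list(n = n, phenotype = as.numeric(phenotype),
                 sd = if (is.null(sd)) NULL else as.numeric(sd),
                 observed = observed, labels = labels),
            class = "genotype_landscape")
}

#' @export
print.genotype_landscape <- function(x, ...) {
  s <- sum(x$observed)
  cat(sprintf("Genotype-phenotype landscape: %d sites, %d/%d genotypes observed\n",
              x$n, s, 2^x$n))
  if (!is.null(x$labels))
    cat("  sites (high to low): ", paste(x$labels, collapse = ", "), "\n", sep = "")
  df <- as.data.frame(x)
  if (nrow(df) > 10L) {
    print(utils::head(df, 10L), row.names = FALSE)
    cat("  ... ", nrow(df) - 10L, " more genotypes\n", sep = "")
  } else print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.genotype_landscape <- function(x, ...) {
  idx <- 0:(2^x$n - 1L)
  df <- data.frame(genotype = index_to_genotype(idx, x$n),
                   phenotype = x$phenotype,
                   stringsAsFactors = FALSE)
  if (!is.null(x$sd)) df$sd <- x$sd
  df[x$observed, , drop = FALSE]
}

#' @export
length.genotype_landscape <- function(x) sum(x$observed)

is_complete <- function(x) all(x$observed)

#' Highest mutation order up to which a landscape is complete
#'
#' Returns the largest `p` such that every genotype carrying at most `p`
#' mutations is observed (0 if even the reference genotype is missing is
#' impossible: the reference must be observed for a positive result).
#'
#' @param x a [genotype_landscape].
#' @return integer in `-1:n` (`-1` when the all-wild-type genotype itself is
#'   unobserved, `n` for complete data).
#' @export
complete_order <- function(x) {
  stopifnot(inherits(x, "genotype_landscape"))
  q <- genotype_order(0:(2^x$n - 1L))
  p <- -1L
  for (k in 0:x$n) {
    if (all(x$observed[q == k])) p <- k else break
  }
  p
}

#' Genotype index and bitstring conversions
#'
#' Genotype integer indices run from 0 (all wild-type) to `2^n - 1` (all
#' mutant); the bitstring prints site `n` first (most significant bit).
#' `genotype_order()` gives the number of mutated sites (the population
#' count), which is also the interaction order associated with a coefficient
#' at that index.
#'
#' @param i integer vector of genotype indices (`0 <= i < 2^n`).
#' @param n number of sites.
#' @param g character vector of bitstrings.
#' @return `index_to_genotype`: character vector of `n`-character bitstrings;
#'   `genotype_to_index`: integer vector; `genotype_order`: integer vector of
#'   population counts.
#' @examples
#' index_to_genotype(3, 3)        # "011"
#' genotype_to_index("011")       # 3
#' genotype_order(0:7)            # 0 1 1 2 1 2 2 3
#' @export
index_to_genotype <- function(i, n) {
  i <- as.integer(i)
  if (any(i < 0L) || any(i >= 2^n)) stop("index out of range [0, 2^n)")
  vapply(i, function(k)
    paste(rev(as.integer(bitwAnd(bitwShiftR(k, 0:(n - 1L)), 1L))), collapse = ""),
    character(1))
}

#' @rdname index_to_genotype
#' @export
genotype_to_index <- function(g) {
  if (any(!grepl("^[01]+$", g))) stop("genotype strings must be binary")
  strtoi(g, base = 2L)
}

#' @rdname index_to_genotype
#' @export
genotype_order <- function(i) {
  i <- as.integer(i)
  if (any(i < 0L)) stop("indices must be nonnegative")
  vapply(i, function(k) {
    c <- 0L
    while (k > 0L) { c <- c + bitwAnd(k, 1L); k <- bitwShiftR(k, 1L) }
    c
  }, integer(1))
}

#' Star notation for interaction terms
#'
#' Interaction terms are labelled with the sites involved marked `1` and the
#' background-averaged (or uninvolved) sites marked `*`, e.g. `"1*1"` for the
#' coupling of sites 3 and 1 of a 3-site system.
#'
#' @inheritParams index_to_genotype
#' @return character vector of star-notation labels.
#' @examples
#' term_label(0:7, 3)   # "***" "**1" "*1*" "*11" "1**" "1*1" "11*" "111"
#' @export
term_label <- function(i, n) {
  gsub("0", "*", index_to_genotype(i, n), fixed = TRUE)
}

## gas constant in kcal/(mol K)
.R_KCAL <- 0.0019872

#' Convert dissociation constants to standard free energies
#'
#' Computes the binding free energy `RT * log(Kd)` with the gas constant
#' `R = 0.0019872` kcal/(mol K).  `Kd` must be in mol/L (convert micromolar
#' values before calling); free energies are negative for sub-molar `Kd`.
#'
#' @param kd dissociation constant(s), mol/L, strictly positive.
#' @param temperature absolute temperature in kelvin (default 298.15).
#' @return free energy in kcal/mol.
#' @examples
#' kd_to_free_energy(1e-6)     # approx. -8.19 kcal/mol at 298.15 K
#' @export
kd_to_free_energy <- function(kd, temperature = 298.15) {
  if (any(kd <= 0)) stop("kd must be positive (mol/L)")
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  .R_KCAL * temperature * log(kd)
}

#' Read and write genotype-phenotype tables
#'
#' Landscape files are delimited text with a header and columns
#' `genotype` (bitstring), `phenotype`, and optionally `sd`.  Genotypes must
#' be unique and of equal length; genotypes absent from the file are marked
#' unobserved.  An empty phenotype cell or `NA` also marks a genotype as
#' unobserved.  `write_landscape()` writes only observed rows, so a
#' read/write round trip is lossless.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param x a [genotype_landscape].
#' @return `read_landscape`: a [genotype_landscape]; `write_landscape`: the
#'   path, invisibly.
#' @export
read_landscape <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = c(genotype = "character"),
                          stringsAsFactors = FALSE)
  need <- c("genotype", "phenotype")
  if (!all(need %in% names(df)))
    stop("file must have columns 'genotype' and 'phenotype'")
  keep <- !is.na(df$phenotype)
  genotype_landscape(df$phenotype[keep],
                     sd = if ("sd" %in% names(df)) df$sd[keep] else NULL,
                     genotypes = df$genotype[keep])
}

#' @rdname read_landscape
#' @export
write_landscape <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "genotype_landscape"))
  utils::write.table(as.data.frame(x), path, sep = delimiter,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
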