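# Allelic configurations: the multiset of alleles at one biallelic locus.

#' Construct an allelic configuration
#'
#' An allelic configuration is the multiset of dominant (`A`) and recessive
#' (`a`) alleles carried at a single locus by one individual, e.g. `AAaa` for
#' a duplex tetraploid. The canonical label lists all dominant copies first.
#'
#' @param ploidy Positive integer, total allele copies at the locus.
#' @param n_dominant Integer in `0..ploidy`, copies of the dominant allele A.
#' @return An object of class `allelic_configuration` with fields `ploidy`,
#'   `n_dominant` and the canonical `label`.
#' @examples
#' allelic_configuration(4, 2)           # AAaa
#' parse_genotype("AaAa")                # canonicalized to AAaa
#' @export
allelic_configuration <- function(ploidy, n_dominant) {
  if (!is.numeric(ploidy) || length(ploidy) != 1L || ploidy < 1 ||
      ploidy != round(ploidy)) {
    stop("`ploidy` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(n_dominant) || length(n_dominant) != 1L ||
      n_dominant != round(n_dominant) || n_dominant < 0 || n_dominant > ploidy) {
    stop("`n_dominant` must be an integer in 0..ploidy", call. = FALSE)
  }
  structure(
    list(ploidy = as.integer(ploidy),
         n_dominant = as.integer(n_dominant),
         label = genotype_label(ploidy, n_dominant)),
    class = "allelic_configuration"
  )
}

#' Canonical genotype label
#'
#' @param ploidy,n_dominant As in [allelic_configuration()]; vectorized.
#' @return Character vector such as `"AAa"`.
#' @export
genotype_label <- function(ploidy, n_dominant) {
  mapply(function(m, k) {
    paste0(strrep("A", k), strrep("a", m - k))
  }, ploidy, n_dominant, USE.NAMES = FALSE)
}

#' Parse a genotype string into an allelic configuration
#'
#' Accepts any ordering of `A`/`a` (e.g. `"AaAa"`) and canonicalizes it.
#'
#' @param label A string over the two-letter alphabet `{A, a}`.
#' @return An `allelic_configuration`.
#' @export
parse_genotype <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      nchar(label) == 0L) {
    stop("genotype label must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(label, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "a"))
  if (length(bad)) {
    stop(sprintf("invalid genotype string '%s': allowed symbols are A and a",
                 label), call. = FALSE)
  }
  allelic_configuration(length(chars), sum(chars == "A"))
}

#' Canonicalize genotype strings
#'
#' Vectorized wrapper around [parse_genotype()] returning canonical labels
#' (all `A` copies first).
#'
#' @param x Character vector of genotype strings.
#' @return Character vector of canonical labels.
#' @export
canonicalize_genotype <- function(x) {
  vapply(x, function(s) parse_genotype(s)$label, character(1L),
         USE.NAMES = FALSE)
}

# Coerce a configuration or genotype string to allelic_configuration.
as_configuration <- function(x) {
  if (inherits(x, "allelic_configuration")) return(x)
  if (is.character(x)) return(parse_genotype(x))
  stop("expected an allelic_configuration or a genotype string", call. = FALSE)
}

#' Expected dosage statistic b of a configuration
#'
#' The expected value of the relative allele-A signal b for a noise-free
#' sample is the fraction of locus copies that are allele A,
#' `n_dominant / ploidy` (1 for AA/AAAA, 0.5 for Aa/AAaa, 2/3 for AAa, ...).
#'
#' @param configuration An `allelic_configuration` or genotype string.
#' @return A number in `[0, 1]`.
#' @examples
#' expected_b("AAaa")   # 0.5
#' expected_b("AAAa")   # 0.75
#' @export
expected_b <- function(configuration) {
  cfg <- as_configuration(configuration)
  cfg$n_dominant / cfg$ploidy
}

#' @export
format.allelic_configuration <- function(x, ...) {
  sprintf("<allelic_configuration %s (ploidy %d, %d A)>",
          x$label, x$ploidy, x$n_dominant)
}

#' @export
print.allelic_configuration <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
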