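# Polysomic inheritance: gamete distributions, expected phenotype ratios,
# chi-square goodness-of-fit, and progeny ploidy tabulation.
#
# Model: random chromosome segregation in an autopolyploid. A gamete of g
# chromosomes drawn from a parent with nA dominant copies among m carries k
# dominant alleles with hypergeometric probability
#   P(k) = C(nA, k) C(m - nA, g - k) / C(m, g).
# No double reduction and no preferential pairing are modeled. Phenotypes
# follow complete dominance: white iff zero A copies.

#' Gamete allele-count distribution under random segregation
#'
#' @param parent Parental configuration (string or
#'   [allelic_configuration()]).
#' @param gamete_ploidy Number of allele copies per gamete, in
#'   `1..parent ploidy` (an unreduced gamete has `gamete_ploidy` equal to
#'   the parent's ploidy).
#' @return Data frame of class `gamete_distribution`: `k` (A copies in the
#'   gamete), `probability`, and the exact rational `numerator` /
#'   `denominator` (integers; the numerators sum to the denominator
#'   exactly).
#' @examples
#' gamete_frequencies("Aaaa", 2)   # A-carrying and a-only gametes, 1:1
#' gamete_frequencies("AAaa", 2)   # 1/6, 4/6, 1/6
#' @export
gamete_frequencies <- function(parent, gamete_ploidy) {
  cfg <- as_configuration(parent)
  g <- gamete_ploidy
  if (!is.numeric(g) || length(g) != 1L || g != round(g) || g < 1 ||
      g > cfg$ploidy) {
    stop(sprintf("gamete ploidy must be an integer in 1..%d for parent %s",
                 cfg$ploidy, cfg$label), call. = FALSE)
  }
  m <- cfg$ploidy
  nA <- cfg$n_dominant
  k <- max(0L, g - (m - nA)):min(g, nA)
  num <- choose(nA, k) * choose(m - nA, g - k)
  den <- choose(m, g)
  structure(
    data.frame(k = as.integer(k), probability = num / den,
               numerator = num, denominator = den),
    class = c("gamete_distribution", "data.frame"),
    parent = cfg, gamete_ploidy = as.integer(g)
  )
}

#' Specify a cross between two parents of known configuration
#'
#' Gamete ploidies default to the allocation that explains each
#' progeny-ploidy class of a polyploid-by-diploid cross: the diploid parent
#' contributes a normal haploid gamete (g = 1) and the polyploid parent
#' contributes `progeny_ploidy - 1` (so diploid, triploid, tetraploid and
#' pentaploid progeny of a 4x-by-2x cross take tetraploid gametes of ploidy
#' 1..4). Both gamete ploidies can be overridden, and `doubled = TRUE`
#' models whole-genome doubling of the zygote (allele counts double after
#' fertilization), a route invoked for off-ploidy progeny.
#'
#' @param female,male Parental configurations (strings or
#'   [allelic_configuration()]s).
#' @param progeny_ploidy Ploidy of the progeny class under study.
#' @param female_gametes,male_gametes Optional explicit gamete ploidies.
#' @param doubled If `TRUE`, the zygote from the two gametes undergoes
#'   genome doubling; the gamete ploidies must then sum to half the progeny
#'   ploidy.
#' @return An object of class `cross_spec`.
#' @export
cross_spec <- function(female, male, progeny_ploidy,
                       female_gametes = NULL, male_gametes = NULL,
                       doubled = FALSE) {
  f <- as_configuration(female)
  m <- as_configuration(male)
  target <- if (doubled) {
    if (progeny_ploidy %% 2L != 0L) {
      stop("a doubled zygote implies even progeny ploidy", call. = FALSE)
    }
    progeny_ploidy / 2L
  } else {
    progeny_ploidy
  }
  if (is.null(female_gametes) && is.null(male_gametes)) {
    if (f$ploidy == 2L && m$ploidy != 2L) {
      female_gametes <- 1L; male_gametes <- target - 1L
    } else if (m$ploidy == 2L && f$ploidy != 2L) {
      male_gametes <- 1L; female_gametes <- target - 1L
    } else if (f$ploidy == 2L && m$ploidy == 2L && target == 2L) {
      female_gametes <- 1L; male_gametes <- 1L
    } else {
      stop(sprintf(paste0("no default gamete allocation for %s x %s with ",
                          "progeny ploidy %d; pass female_gametes/",
                          "male_gametes explicitly"),
                   f$label, m$label, progeny_ploidy), call. = FALSE)
    }
  } else if (is.null(female_gametes)) {
    female_gametes <- target - male_gametes
  } else if (is.null(male_gametes)) {
    male_gametes <- target - female_gametes
  }
  if (female_gametes + male_gametes != target) {
    stop(sprintf("gamete ploidies %d + %d do not sum to %d",
                 female_gametes, male_gametes, target), call. = FALSE)
  }
  for (side in list(c(female_gametes, f$ploidy, "female"),
                    c(male_gametes, m$ploidy, "male"))) {
    gp <- as.integer(side[1L]); pp <- as.integer(side[2L])
    if (gp < 1L || gp > pp) {
      stop(sprintf("infeasible %s gamete ploidy %d (parent ploidy %d)",
                   side[3L], gp, pp), call. = FALSE)
    }
  }
  structure(list(female = f, male = m,
                 progeny_ploidy = as.integer(progeny_ploidy),
                 female_gametes = as.integer(female_gametes),
                 male_gametes = as.integer(male_gametes),
                 doubled = isTRUE(doubled)),
            class = "cross_spec")
}

#' @export
format.cross_spec <- function(x, ...) {
  sprintf("<cross %s x %s -> %dx progeny (gametes %d + %d%s)>",
          x$female$label, x$male$label, x$progeny_ploidy,
          x$female_gametes, x$male_gametes,
          if (x$doubled) ", doubled zygote" else "")
}

#' @export
print.cross_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Offspring allele-count distribution of a cross
#'
#' Convolution of the two parental gamete distributions (exact integer
#' arithmetic on the rational masses). Under zygote doubling every allele
#' count doubles.
#'
#' @param cross A [cross_spec()].
#' @return Data frame: `k` (A copies in the offspring), `probability`,
#'   `numerator`, `denominator`.
#' @export
offspring_distribution <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  gf <- gamete_frequencies(cross$female, cross$female_gametes)
  gm <- gamete_frequencies(cross$male, cross$male_gametes)
  den <- gf$denominator[1L] * gm$denominator[1L]
  counts <- integer(cross$progeny_ploidy + 1L)
  mult <- if (cross$doubled) 2L else 1L
  for (i in seq_len(nrow(gf))) {
    for (j in seq_len(nrow(gm))) {
      k <- mult * (gf$k[i] + gm$k[j])
      counts[k + 1L] <- counts[k + 1L] + gf$numerator[i] * gm$numerator[j]
    }
  }
  keep <- which(counts > 0L)
  data.frame(k = keep - 1L, probability = counts[keep] / den,
             numerator = counts[keep], denominator = den)
}

#' Expected red:white phenotype ratio of a cross
#'
#' Complete dominance: an offspring is white iff it carries zero A copies.
#' The ratio is reduced to least integer terms.
#'
#' @param cross A [cross_spec()].
#' @return Named integer vector `c(red = , white = )` with attribute
#'   `probabilities` (the exact red/white probabilities).
#' @examples
#' expected_phenotype_ratio(cross_spec("aa", "AAaa", 3))   # 5:1
#' @export
expected_phenotype_ratio <- function(cross) {
  dist <- offspring_distribution(cross)
  den <- dist$denominator[1L]
  white_num <- sum(dist$numerator[dist$k == 0L])
  red_num <- den - white_num
  g <- gcd(red_num, white_num)
  out <- c(red = red_num / g, white = white_num / g)
  attr(out, "probabilities") <- c(red = red_num / den, white = white_num / den)
  out
}

gcd <- function(a, b) {
  if (a == 0 && b == 0) return(1)
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Pearson chi-square goodness-of-fit for a two-class segregation ratio
#'
#' Expected counts scale the ratio to the observed total; no continuity
#' correction; df = 1. A class with expected probability 0 contributes 0
#' when its observed count is 0 and flags the test as degenerate (infinite
#' chi-square) otherwise.
#'
#' @param observed_red,observed_white Observed phenotype counts.
#' @param expected_ratio Numeric pair `(red_parts, white_parts)`, not both
#'   zero.
#' @return List of class `segregation_test`: `observed`, `expected`,
#'   `expected_ratio`, `chi2`, `df`, `p`, `degenerate`.
#' @examples
#' chi_square_gof(4, 5, c(1, 3))    # chi2 = 1.81 (2 dp)
#' chi_square_gof(10, 0, c(5, 1))   # chi2 = 2.00
#' @export
chi_square_gof <- function(observed_red, observed_white, expected_ratio) {
  obs <- c(red = observed_red, white = observed_white)
  if (any(obs < 0) || sum(obs) < 1) {
    stop("need non-negative observed counts with total >= 1", call. = FALSE)
  }
  parts <- as.numeric(expected_ratio)
  if (length(parts) != 2L || any(parts < 0) || sum(parts) == 0) {
    stop("expected ratio must be two non-negative parts, not both zero",
         call. = FALSE)
  }
  expected <- sum(obs) * parts / sum(parts)
  terms <- numeric(2L)
  degenerate <- FALSE
  for (i in 1:2) {
    if (expected[i] == 0) {
      if (obs[i] > 0) degenerate <- TRUE else terms[i] <- 0
    } else {
      terms[i] <- (obs[i] - expected[i])^2 / expected[i]
    }
  }
  chi2 <- if (degenerate) Inf else sum(terms)
  structure(list(observed = obs, expected = setNames(expected,
                                                     c("red", "white")),
                 expected_ratio = parts, chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1L, lower.tail = FALSE),
                 degenerate = degenerate),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("observed %d:%d, expected ratio %s, X^2 = %s (df 1), p = %s\n",
              x$observed[1L], x$observed[2L], ratio_label(x$expected_ratio),
              if (is.finite(x$chi2)) sprintf("%.2f", x$chi2) else "Inf",
              format(x$p, digits = 3)))
  invisible(x)
}

# "red:white" with the smaller side normalized to 1 (2 dp, trailing zeros
# trimmed); "1:0"/"0:1" for one-sided ratios, "/" when both are zero.
ratio_label <- function(parts) {
  r <- parts[1L]; w <- parts[2L]
  if (r == 0 && w == 0) return("/")
  if (w == 0) return("1:0")
  if (r == 0) return("0:1")
  trim <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))
  if (r >= w) paste0(trim(r / w), ":1") else paste0("1:", trim(w / r))
}

#' Segregation report across crosses and progeny-ploidy classes
#'
#' For each record, derives the expected ratio from the gamete model, the
#' observed ratio label, Pearson chi-square and p; appends one pooled
#' `Total` row per cross whose expected counts are the class-size-weighted
#' sums of the per-class expectations. Classes with no observations are
#' emitted with `/` placeholders.
#'
#' @param crosses Data frame with columns `female_genotype`,
#'   `male_genotype`, `progeny_ploidy`, `observed_red`, `observed_white`;
#'   optional `cross` (id), `female_gametes`, `male_gametes`, `doubled` for
#'   non-default gamete routes.
#' @return Data frame: `cross`, `female`, `male`, `class`, `red`, `white`,
#'   `observed_ratio`, `expected_ratio`, `chi2`, `p`.
#' @export
segregation_table <- function(crosses) {
  need <- c("female_genotype", "male_genotype", "progeny_ploidy",
            "observed_red", "observed_white")
  missing_cols <- setdiff(need, names(crosses))
  if (length(missing_cols)) {
    stop(sprintf("cross table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(crosses$cross)) {
    crosses$cross <- paste(crosses$female_genotype, "x",
                           crosses$male_genotype)
  }
  fmt2 <- function(x) sprintf("%.2f", x)
  rows <- list()
  for (id in unique(crosses$cross)) {
    sub <- crosses[crosses$cross == id, , drop = FALSE]
    pooled_exp <- c(red = 0, white = 0)
    pooled_obs <- c(red = 0, white = 0)
    for (i in seq_len(nrow(sub))) {
      opt <- function(col) {
        if (is.null(sub[[col]])) return(NULL)
        v <- sub[[col]][i]
        if (is.na(v)) NULL else v
      }
      cs <- cross_spec(
        sub$female_genotype[i], sub$male_genotype[i], sub$progeny_ploidy[i],
        female_gametes = opt("female_gametes"),
        male_gametes = opt("male_gametes"),
        doubled = isTRUE(opt("doubled"))
      )
      ratio <- expected_phenotype_ratio(cs)
      obs <- c(red = sub$observed_red[i], white = sub$observed_white[i])
      cls <- sprintf("%dx", sub$progeny_ploidy[i])
      if (sum(obs) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          cross = id, female = cs$female$label, male = cs$male$label,
          class = cls, red = 0L, white = 0L, observed_ratio = "/",
          expected_ratio = "/", chi2 = "/", p = "/",
          stringsAsFactors = FALSE)
        next
      }
      test <- chi_square_gof(obs["red"], obs["white"], ratio)
      pooled_obs <- pooled_obs + obs
      pooled_exp <- pooled_exp + test$expected
      rows[[length(rows) + 1L]] <- data.frame(
        cross = id, female = cs$female$label, male = cs$male$label,
        class = cls, red = obs[["red"]], white = obs[["white"]],
        observed_ratio = ratio_label(obs),
        expected_ratio = ratio_label(ratio),
        chi2 = if (is.finite(test$chi2)) fmt2(test$chi2) else "Inf",
        p = fmt2(test$p), stringsAsFactors = FALSE)
    }
    if (sum(pooled_obs) > 0) {
      chi2 <- sum(ifelse(pooled_exp > 0,
                         (pooled_obs - pooled_exp)^2 / pooled_exp, 0))
      degenerate <- any(pooled_exp == 0 & pooled_obs > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        cross = id, female = sub$female_genotype[1L],
        male = sub$male_genotype[1L], class = "Total",
        red = pooled_obs[["red"]], white = pooled_obs[["white"]],
        observed_ratio = ratio_label(pooled_obs),
        expected_ratio = ratio_label(pooled_exp),
        chi2 = if (degenerate) "Inf" else fmt2(chi2),
        p = if (degenerate) "0.00"
            else fmt2(pchisq(chi2, 1L, lower.tail = FALSE)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate progeny counts by ploidy class
#'
#' @param records Data frame with columns `cross`, `ploidy`, `count`.
#' @return Data frame of class `ploidy_tabulation` adding `percent`
#'   (2 dp, per cross; percentages per cross sum to 100 within rounding).
#' @examples
#' ploidy_tabulation(data.frame(cross = "B431 x GF", ploidy = c(2, 3),
#'                              count = c(1, 50)))
#' @export
ploidy_tabulation <- function(records) {
  need <- c("cross", "ploidy", "count")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop(sprintf("ploidy records missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(records$count < 0)) stop("counts must be >= 0", call. = FALSE)
  totals <- tapply(records$count, records$cross, sum)
  if (any(totals == 0)) {
    stop(sprintf("cross '%s' has zero progeny",
                 names(totals)[which(totals == 0)[1L]]), call. = FALSE)
  }
  records$percent <- round(
    100 * records$count / as.numeric(totals[as.character(records$cross)]), 2)
  structure(records, class = c("ploidy_tabulation", "data.frame"))
}
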