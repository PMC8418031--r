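# DNA-mixture library simulation and the proportion-vs-dosage relationship.
#
# Two homozygous diploid pools (AA and aa) mixed at known mass ratios mimic
# heterozygotes of arbitrary allele-A fraction p; with equal genome sizes,
# mass mixing equals copy mixing. Synthetic plates invert the
# delta-delta-Ct model (Ct log-linear in template copies) and add Gaussian
# Ct noise, so noise-free plates round-trip exactly to b = p.

#' Mixture design of two homozygote DNA pools
#'
#' @param ratios Two-column matrix or data frame of non-negative integer
#'   `(red_parts, white_parts)` pairs; the default is the 13-member library:
#'   the pure AA pool, ratios 9:1, 5:1, 3:1, 2:1, 3:2, 1:1, 2:3, 1:2, 1:3,
#'   1:5, 1:9, and the pure aa pool. The 2:1 and 1:2 mixtures mimic triploid
#'   heterozygotes; 3:1, 1:1 and 1:3 mimic tetraploid heterozygotes.
#' @return Data frame of class `mixture_design` with columns `red`, `white`,
#'   `p` (implied allele-A fraction `red / (red + white)`).
#' @export
mixture_design <- function(ratios = NULL) {
  if (is.null(ratios)) {
    ratios <- rbind(
      c(1, 0), c(9, 1), c(5, 1), c(3, 1), c(2, 1), c(3, 2), c(1, 1),
      c(2, 3), c(1, 2), c(1, 3), c(1, 5), c(1, 9), c(0, 1)
    )
  }
  ratios <- as.matrix(ratios)
  if (ncol(ratios) != 2L || any(ratios < 0)) {
    stop("`ratios` must be two non-negative columns (red_parts, white_parts)",
         call. = FALSE)
  }
  tot <- rowSums(ratios)
  if (any(tot == 0)) {
    stop(sprintf("mixture %d has zero total parts", which(tot == 0)[1L]),
         call. = FALSE)
  }
  structure(
    data.frame(red = ratios[, 1L], white = ratios[, 2L], p = ratios[, 1L] / tot),
    class = c("mixture_design", "data.frame")
  )
}

#' Allele-A fractions of a mixture design
#'
#' @param design A [mixture_design()].
#' @return Ordered numeric vector of A fractions (the default library gives
#'   13 distinct fractions including 0 and 1).
#' @export
build_mixture_library <- function(design = mixture_design()) {
  if (!inherits(design, "mixture_design")) design <- mixture_design(design)
  design$p
}

# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Synthesize wells for one sample: per-haploid relative quantities per assay,
# Ct = base_ct - log_eff(quantity) + noise; zero template reports the
# detection ceiling (no noise: the instrument never crosses threshold).
sim_wells <- function(sample_id, quantities, panel, ct_sd, replicates,
                      base_ct) {
  assays <- rep(.assay_levels, each = replicates)
  q <- quantities[assays]
  ct0 <- ifelse(q > 0, base_ct - log(q) / log(panel$efficiency),
                panel$undetected_ct)
  noise <- ifelse(q > 0, rnorm(length(ct0), 0, ct_sd), 0)
  ct <- pmin(ct0 + noise, panel$undetected_ct)
  data.frame(sample_id = sample_id, assay = assays,
             replicate = rep(seq_len(replicates), times = 3L),
             ct = ct, stringsAsFactors = FALSE)
}

# Per-haploid relative quantities implied by an allele-A fraction.
fraction_quantities <- function(p) {
  c(reference = 1, allele_A = p, combined = 1)
}

#' Simulate a qPCR plate for one sample plus its calibrator
#'
#' @param p Allele-A fraction in `[0, 1]`, or an `allelic_configuration` /
#'   genotype string (converted via its A fraction).
#' @param panel An [assay_panel()].
#' @param calibrator A [calibrator_spec()].
#' @param ct_sd Gaussian standard deviation added to each detected Ct, in
#'   cycles (0.05 by default, which keeps reference CVs well under 3%).
#' @param replicates Wells per sample/assay.
#' @param seed Optional integer; a fixed seed makes the plate reproducible.
#' @param sample_id Identifier for the simulated sample.
#' @param base_ct Ct of a target present at one copy per haploid genome.
#' @return A plate data frame (see [ct_plate()]) holding the sample's and
#'   the calibrator's wells.
#' @export
simulate_plate <- function(p, panel = assay_panel(),
                           calibrator = calibrator_spec(),
                           ct_sd = 0.05, replicates = 3L, seed = NULL,
                           sample_id = "sample", base_ct = 20) {
  if (inherits(p, "allelic_configuration") || is.character(p)) {
    p <- expected_b(p)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a single fraction in [0, 1]", call. = FALSE)
  }
  if (ct_sd < 0) stop("`ct_sd` must be non-negative", call. = FALSE)
  with_seed(seed, {
    cal_p <- calibrator$genotype$n_dominant / calibrator$ploidy
    plate <- rbind(
      sim_wells(sample_id, fraction_quantities(p), panel, ct_sd,
                replicates, base_ct),
      sim_wells(calibrator$sample_id, fraction_quantities(cal_p), panel,
                ct_sd, replicates, base_ct)
    )
    validate_plate(plate)
  })
}

#' Simulate plates for a whole mixture library
#'
#' One shared calibrator plus one simulated sample per mixture.
#'
#' @inheritParams simulate_plate
#' @param design A [mixture_design()].
#' @return List with `plate` (all wells), `truth` (data frame `sample_id`,
#'   `p`), and `calibrator`.
#' @export
simulate_mixture_library <- function(design = mixture_design(),
                                     panel = assay_panel(),
                                     calibrator = calibrator_spec(),
                                     ct_sd = 0.05, replicates = 3L,
                                     seed = NULL, base_ct = 20) {
  if (!inherits(design, "mixture_design")) design <- mixture_design(design)
  with_seed(seed, {
    cal_p <- calibrator$genotype$n_dominant / calibrator$ploidy
    ids <- sprintf("mix_%02d", seq_len(nrow(design)))
    wells <- vector("list", nrow(design) + 1L)
    wells[[1L]] <- sim_wells(calibrator$sample_id, fraction_quantities(cal_p),
                             panel, ct_sd, replicates, base_ct)
    for (i in seq_len(nrow(design))) {
      wells[[i + 1L]] <- sim_wells(ids[i], fraction_quantities(design$p[i]),
                                   panel, ct_sd, replicates, base_ct)
    }
    list(plate = validate_plate(do.call(rbind, wells)),
         truth = data.frame(sample_id = ids, p = design$p,
                            stringsAsFactors = FALSE),
         calibrator = calibrator)
  })
}

#' Dosage statistics for every sample of a simulated library
#'
#' @param library Result of [simulate_mixture_library()].
#' @param panel The [assay_panel()] used to simulate it.
#' @return Data frame with one row per mixture: `sample_id`, `p`, `a1`,
#'   `a2`, `a3`, `b`, `theta`, `flag`.
#' @export
library_dosages <- function(library, panel = assay_panel()) {
  cal <- library$calibrator
  cal_cts <- library$plate[library$plate$sample_id == cal$sample_id, ]
  rows <- lapply(seq_len(nrow(library$truth)), function(i) {
    allele_signals(library$plate, cal, cal_cts, panel,
                   sample_id = library$truth$sample_id[i])
  })
  out <- do.call(rbind, rows)
  out$p <- library$truth$p
  out[c("sample_id", "p", "a1", "a2", "a3", "b", "theta", "flag")]
}

#' Regression of the dosage statistics on the known allele-A fraction
#'
#' Ordinary least squares of b on p and of theta on p; R-squared is the
#' squared Pearson correlation. On noise-free plates b = p exactly, so the
#' b fit has slope 1, intercept 0 and R-squared 1; the theta fit is
#' curvilinear (arctan) and its linear R-squared falls below 1.
#'
#' @param dosages Data frame with columns `b` and `theta` (e.g. from
#'   [library_dosages()]).
#' @param p Matching allele-A fractions (taken from `dosages$p` if absent).
#' @return List of class `regression_summary` with `b_fit`, `theta_fit`
#'   (each `slope`, `intercept`, `r_squared`) and the per-point `table`.
#' @export
proportion_dosage_regression <- function(dosages, p = dosages$p) {
  if (length(p) != nrow(dosages) || length(p) < 3L) {
    stop("need at least 3 matching points", call. = FALSE)
  }
  if (sd(p) == 0) stop("allele fractions are constant; cannot regress",
                       call. = FALSE)
  fit1 <- function(y) {
    m <- lm(y ~ p)
    list(slope = unname(coef(m)[2L]), intercept = unname(coef(m)[1L]),
         r_squared = suppressWarnings(cor(y, p))^2)
  }
  structure(list(b_fit = fit1(dosages$b),
                 theta_fit = fit1(dosages$theta),
                 table = data.frame(p = p, a1 = dosages$a1, a2 = dosages$a2,
                                    b = dosages$b, theta = dosages$theta)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("b ~ p:     slope %.4f, intercept %.4f, R^2 = %.4f\n",
              x$b_fit$slope, x$b_fit$intercept, x$b_fit$r_squared))
  cat(sprintf("theta ~ p: slope %.2f, intercept %.2f, R^2 = %.4f\n",
              x$theta_fit$slope, x$theta_fit$intercept,
              x$theta_fit$r_squared))
  invisible(x)
}
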