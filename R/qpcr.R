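# Delta-delta-Ct relative quantification and the dosage statistics b / theta.
#
# The genotyping design uses three amplicons per sample: a reference with
# constant copy number per haploid genome (input-DNA normalizer), an
# allele-A-specific target, and a target amplifying both alleles. Relative
# quantities against a calibrator of known genotype are rescaled so that a
# heterozygous diploid calibrator reads a1 = 1 and a3 = 2 for itself; b and
# theta then estimate the allele-A fraction of locus copies.

#' Describe the assay panel
#'
#' @param reference,allele_a,combined Amplicon labels for the three assays
#'   (defaults follow the loquat flesh-color design: the CH03g12 reference,
#'   the allele-A-specific q2A primer and the combined q2A/2Ad pair).
#' @param efficiency Per-cycle amplification factor shared by the assays;
#'   2 means perfect doubling. Must lie in (1, 2].
#' @param undetected_ct Cycle ceiling of the instrument; a replicate-mean Ct
#'   at or above it is treated as "no template detected" (relative quantity
#'   zero).
#' @return An object of class `assay_panel`.
#' @export
assay_panel <- function(reference = "CH03g12", allele_a = "q2A",
                        combined = "q2A/2Ad", efficiency = 2,
                        undetected_ct = 40) {
  names3 <- c(reference, allele_a, combined)
  if (anyDuplicated(names3)) {
    stop("the three assay names must be distinct", call. = FALSE)
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 1 || efficiency > 2) {
    stop("`efficiency` must lie in (1, 2]", call. = FALSE)
  }
  if (!is.numeric(undetected_ct) || undetected_ct <= 0) {
    stop("`undetected_ct` must be positive", call. = FALSE)
  }
  structure(list(reference = reference, allele_a = allele_a,
                 combined = combined, efficiency = efficiency,
                 undetected_ct = undetected_ct),
            class = "assay_panel")
}

#' Describe the calibrator sample
#'
#' The calibrator is a sample of known allelic configuration against which
#' relative copy numbers are scaled; the canonical choice is a heterozygous
#' diploid (`Aa`), for which the scaled signals read a1 = 1, a3 = 2.
#'
#' @param sample_id Identifier of the calibrator wells on the plate.
#' @param genotype Known configuration (string or `allelic_configuration`).
#' @return An object of class `calibrator_spec`.
#' @export
calibrator_spec <- function(sample_id = "CAL", genotype = "Aa") {
  cfg <- as_configuration(genotype)
  if (cfg$n_dominant < 1L || cfg$n_dominant == cfg$ploidy) {
    stop("calibrator must carry at least one copy of each allele", call. = FALSE)
  }
  structure(list(sample_id = sample_id, genotype = cfg, ploidy = cfg$ploidy),
            class = "calibrator_spec")
}

#' Build and validate a plate of Ct records
#'
#' A plate is a data frame with one row per well: `sample_id`, `assay`
#' (one of `reference`, `allele_A`, `combined`), `replicate` and `ct`.
#'
#' @param sample_id,assay,replicate,ct Vectors of equal length.
#' @return A validated data frame of Ct records.
#' @export
ct_plate <- function(sample_id, assay, replicate, ct) {
  validate_plate(data.frame(sample_id = as.character(sample_id),
                            assay = as.character(assay),
                            replicate = as.integer(replicate),
                            ct = as.numeric(ct),
                            stringsAsFactors = FALSE))
}

#' @rdname ct_plate
#' @param plate A data frame to validate against the plate schema.
#' @export
validate_plate <- function(plate) {
  need <- c("sample_id", "assay", "replicate", "ct")
  missing_cols <- setdiff(need, names(plate))
  if (length(missing_cols)) {
    stop(sprintf("plate is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_assay <- which(!plate$assay %in% .assay_levels)
  if (length(bad_assay)) {
    stop(sprintf("row %d: unknown assay label '%s' (expected %s)",
                 bad_assay[1L], plate$assay[bad_assay[1L]],
                 paste(.assay_levels, collapse = "/")), call. = FALSE)
  }
  bad_ct <- which(!is.finite(plate$ct) | plate$ct <= 0)
  if (length(bad_ct)) {
    stop(sprintf("row %d: Ct value must be a finite positive number",
                 bad_ct[1L]), call. = FALSE)
  }
  bad_rep <- which(is.na(plate$replicate) | plate$replicate < 1)
  if (length(bad_rep)) {
    stop(sprintf("row %d: replicate index must be a positive integer",
                 bad_rep[1L]), call. = FALSE)
  }
  key <- paste(plate$sample_id, plate$assay, plate$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate well (sample '%s', assay '%s', replicate %d)",
                 dup[1L], plate$sample_id[dup[1L]], plate$assay[dup[1L]],
                 plate$replicate[dup[1L]]), call. = FALSE)
  }
  plate[need]
}

# Replicate-mean Ct for one sample/assay; error names the gap.
mean_ct <- function(cts, sample_id, assay) {
  v <- cts$ct[cts$sample_id == sample_id & cts$assay == assay]
  if (!length(v)) {
    stop(sprintf("incomplete plate: no '%s' wells for sample '%s'",
                 assay, sample_id), call. = FALSE)
  }
  mean(v)
}

#' Relative quantity by the delta-delta-Ct method
#'
#' Computes `efficiency^-ddCt` where
#' `ddCt = (Ct_assay,sample - Ct_ref,sample) - (Ct_assay,cal - Ct_ref,cal)`
#' and each Ct is the arithmetic mean over replicates. A sample-assay mean Ct
#' at or above the panel's detection ceiling yields quantity 0.
#'
#' @param sample_cts,calibrator_cts Plates (see [ct_plate()]) holding the
#'   sample's and the calibrator's wells; they may be the same data frame.
#' @param assay Which assay to quantify (`"allele_A"` or `"combined"`).
#' @param panel An [assay_panel()].
#' @param sample_id,calibrator_id Sample identifiers; default to the single
#'   distinct id in each plate.
#' @return A single non-negative number (1 for the calibrator against itself).
#' @export
relative_quantity <- function(sample_cts, calibrator_cts, assay, panel,
                              sample_id = NULL, calibrator_id = NULL) {
  stopifnot(inherits(panel, "assay_panel"))
  sample_cts <- validate_plate(sample_cts)
  calibrator_cts <- validate_plate(calibrator_cts)
  if (is.null(sample_id)) sample_id <- single_id(sample_cts)
  if (is.null(calibrator_id)) calibrator_id <- single_id(calibrator_cts)

  ct_a_s <- mean_ct(sample_cts, sample_id, assay)
  ct_r_s <- mean_ct(sample_cts, sample_id, "reference")
  ct_a_c <- mean_ct(calibrator_cts, calibrator_id, assay)
  ct_r_c <- mean_ct(calibrator_cts, calibrator_id, "reference")
  if (ct_r_s >= panel$undetected_ct || ct_r_c >= panel$undetected_ct) {
    stop("reference assay undetected; cannot normalize input DNA", call. = FALSE)
  }
  if (ct_a_c >= panel$undetected_ct) {
    stop(sprintf("calibrator '%s' undetected for assay '%s'",
                 calibrator_id, assay), call. = FALSE)
  }
  if (ct_a_s >= panel$undetected_ct) return(0)
  ddct <- (ct_a_s - ct_r_s) - (ct_a_c - ct_r_c)
  panel$efficiency^(-ddct)
}

single_id <- function(plate) {
  ids <- unique(plate$sample_id)
  if (length(ids) != 1L) {
    stop("plate holds several samples; pass `sample_id` explicitly",
         call. = FALSE)
  }
  ids
}

#' Per-sample allele signals and dosage statistics
#'
#' Converts one sample's Ct records into calibrated relative copy numbers:
#' `a1` (allele A), `a3` (A and a combined) and `a2 = a3 - a1` (allele a),
#' scaled so a heterozygous diploid calibrator reads a1 = 1, a3 = 2 for
#' itself. Derives `b = a1 / (a1 + a2)` and the theta angle
#' `atan(a2 / a1)` in degrees (90 at a1 = 0, clamped to 0 when a2 <= 0).
#' A negative `a2` (combined signal below the A-specific signal) is kept as
#' computed and flagged; over-unity b values do occur on real plates.
#'
#' @param sample_cts Plate rows for the sample (may include other samples if
#'   `sample_id` is given).
#' @param calibrator A [calibrator_spec()].
#' @param calibrator_cts Plate rows for the calibrator.
#' @param panel An [assay_panel()].
#' @param sample_id Sample to quantify; defaults to the plate's single id.
#' @return One-row data frame of class `relative_dosage`: `sample_id`, `a1`,
#'   `a2`, `a3`, `b`, `theta`, `flag`.
#' @export
allele_signals <- function(sample_cts, calibrator, calibrator_cts, panel,
                           sample_id = NULL) {
  stopifnot(inherits(calibrator, "calibrator_spec"))
  sample_cts <- validate_plate(sample_cts)
  if (is.null(sample_id)) sample_id <- single_id(sample_cts)
  sample_cts <- sample_cts[sample_cts$sample_id == sample_id, , drop = FALSE]

  rq_a <- relative_quantity(sample_cts, calibrator_cts, "allele_A", panel,
                            sample_id, calibrator$sample_id)
  rq_c <- relative_quantity(sample_cts, calibrator_cts, "combined", panel,
                            sample_id, calibrator$sample_id)

  # Scale to diploid-equivalent copy numbers: the reference normalization
  # puts quantities on a per-haploid-genome scale, and the calibrator carries
  # n_dominant/ploidy A copies (and exactly 1 locus copy) per haploid genome.
  cal_a_per_haploid <- calibrator$genotype$n_dominant / calibrator$ploidy
  a1 <- 2 * rq_a * cal_a_per_haploid
  a3 <- 2 * rq_c
  a2 <- a3 - a1

  flag <- ""
  if (a2 < -1e-9) flag <- "negative_a2"
  total <- a1 + a2
  b <- if (total > 0) a1 / total else NA_real_
  if (is.na(b) && flag == "") flag <- "zero_signal"

  structure(
    data.frame(sample_id = sample_id, a1 = a1, a2 = a2, a3 = a3,
               b = b, theta = dosage_theta(a1, a2), flag = flag,
               stringsAsFactors = FALSE),
    class = c("relative_dosage", "data.frame")
  )
}

#' Theta dosage angle
#'
#' `theta = atan(a2 / a1)` in degrees: 0 for a pure-A signal, 90 for pure-a.
#' The `a2 <= 0` limit is defined as 0 and the `a1 = 0` limit as 90.
#'
#' @param a1,a2 Relative copy numbers of alleles A and a (vectorized).
#' @return Angles in degrees on `[0, 90]`.
#' @export
dosage_theta <- function(a1, a2) {
  ifelse(a2 <= 0, 0,
         ifelse(a1 <= 0, 90, atan(a2 / a1) * 180 / pi))
}

#' Theta implied by b
#'
#' For non-negative signals, `theta = atan((1 - b) / b)` in degrees.
#'
#' @param b Dosage statistic in (0, 1].
#' @return Angle in degrees.
#' @export
theta_from_b <- function(b) {
  stopifnot(all(b > 0 & b <= 1))
  atan((1 - b) / b) * 180 / pi
}

#' Reference-assay stability across groups
#'
#' Coefficient of variation (CV, percent) of reference Ct values per group
#' (typically per ploidy); a stable reference amplicon should stay under a
#' small CV threshold in every group.
#'
#' @param ct Numeric vector of reference Ct values.
#' @param group Grouping vector (e.g. ploidy) of the same length.
#' @param cv_threshold Percent CV below which a group counts as stable.
#' @return A list of class `reference_stability`: `summary` data frame
#'   (`group`, `n`, `mean_ct`, `sd_ct`, `cv`), `all_below`, `cv_threshold`.
#' @export
reference_stability <- function(ct, group, cv_threshold = 3) {
  stopifnot(length(ct) == length(group), is.numeric(ct))
  groups <- split(ct, group)
  small <- names(groups)[vapply(groups, length, 1L) < 2L]
  if (length(small)) {
    stop(sprintf("group '%s' has fewer than 2 Ct values", small[1L]),
         call. = FALSE)
  }
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    mean_ct = vapply(groups, mean, 1),
    sd_ct = vapply(groups, sd, 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  summary$cv <- 100 * summary$sd_ct / summary$mean_ct
  structure(list(summary = summary,
                 all_below = all(summary$cv < cv_threshold),
                 cv_threshold = cv_threshold),
            class = "reference_stability")
}

#' @export
print.reference_stability <- function(x, ...) {
  cat(sprintf("Reference stability (CV threshold %.2f%%):\n", x$cv_threshold))
  print(x$summary, row.names = FALSE)
  cat(if (x$all_below) "all groups below threshold\n"
      else "some groups exceed threshold\n")
  invisible(x)
}
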