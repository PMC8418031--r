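# End-to-end genotyping: plate + sample sheet -> per-sample dosage and call.

#' Genotype every unknown sample on a plate
#'
#' Locates the calibrator from the sample sheet, computes each sample's
#' calibrated allele signals ([allele_signals()]) and calls its allelic
#' configuration at the sheet's ploidy ([call_genotype()]).
#'
#' @param plate A plate data frame (see [read_plate()] / [ct_plate()]).
#' @param samples A sample sheet (see [read_samples()]); must contain
#'   exactly one row with role `calibrator` and a known genotype.
#' @param panel An [assay_panel()].
#' @param tie_tol Tie tolerance passed to [call_genotype()].
#' @return Data frame with one row per non-calibrator sample: `sample_id`,
#'   `ploidy`, `a1`, `a2`, `a3`, `b`, `theta`, `genotype`, `expected_b`,
#'   `residual`, `ambiguous`, `flag`.
#' @export
genotype_samples <- function(plate, samples, panel = assay_panel(),
                             tie_tol = 1e-8) {
  plate <- validate_plate(plate)
  cal_rows <- samples[samples$role == "calibrator", , drop = FALSE]
  if (nrow(cal_rows) != 1L) {
    stop("sample sheet must name exactly one calibrator", call. = FALSE)
  }
  if (is.null(cal_rows$known_genotype) || is.na(cal_rows$known_genotype) ||
      !nzchar(cal_rows$known_genotype)) {
    stop("calibrator needs a known_genotype on the sample sheet",
         call. = FALSE)
  }
  calibrator <- calibrator_spec(cal_rows$sample_id,
                                cal_rows$known_genotype)
  cal_cts <- plate[plate$sample_id == calibrator$sample_id, , drop = FALSE]
  if (!nrow(cal_cts)) {
    stop(sprintf("incomplete plate: no wells for calibrator '%s'",
                 calibrator$sample_id), call. = FALSE)
  }
  targets <- samples[samples$role != "calibrator", , drop = FALSE]
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    sig <- allele_signals(plate, calibrator, cal_cts, panel,
                          sample_id = targets$sample_id[i])
    if (is.na(sig$b)) {
      call <- data.frame(n_dominant = NA_integer_, genotype = NA_character_,
                         expected_b = NA_real_, residual = NA_real_,
                         ambiguous = NA)
    } else {
      call <- call_genotype(sig$b, targets$ploidy[i], tie_tol = tie_tol)
    }
    data.frame(sample_id = sig$sample_id, ploidy = targets$ploidy[i],
               a1 = sig$a1, a2 = sig$a2, a3 = sig$a3, b = sig$b,
               theta = sig$theta, genotype = call$genotype,
               expected_b = call$expected_b, residual = call$residual,
               ambiguous = call$ambiguous, flag = sig$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
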