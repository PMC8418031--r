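# Synthetic fixture generation: seeded plates, sample sheets and truth
# tables emulating the published polyploid genotype roster.

#' Default fixture roster
#'
#' Mirrors the published polyploid panel: 8 tetraploids (one AAAA, three
#' AAAa, two AAaa, two Aaaa), 14 triploids (four AAA, three AAa, four Aaa,
#' three aaa), a diploid verification panel (three each of AA, Aa, aa) and
#' a heterozygous diploid calibrator.
#'
#' @return Data frame with `sample_id`, `ploidy`, `role`, `known_genotype`.
#' @export
default_roster <- function() {
  tetra <- c(B431 = "Aaaa", B432 = "Aaaa", B479 = "AAAa", B433 = "AAAa",
             B456 = "AAaa", H424 = "AAAA", K474 = "AAAa", N2008_3 = "AAaa")
  tri <- c(A313 = "AAA", A322 = "AAA", D6 = "AAA", DHZ_3x = "AAA",
           K374 = "AAa", SW_3x = "AAa", XZ_3x = "AAa",
           B356 = "Aaa", D25 = "Aaa", D27 = "Aaa", FZ_3x = "Aaa",
           GF_3x = "aaa", Q11 = "aaa", Q27 = "aaa")
  di <- c(LQ1 = "AA", DY2 = "AA", DY3 = "AA",
          ZZ6 = "Aa", SW = "Aa", XZ = "Aa",
          GF = "aa", HB1 = "aa", BTZ = "aa")
  roster <- rbind(
    data.frame(sample_id = names(tetra), ploidy = 4L, role = "unknown",
               known_genotype = unname(tetra), stringsAsFactors = FALSE),
    data.frame(sample_id = names(tri), ploidy = 3L, role = "unknown",
               known_genotype = unname(tri), stringsAsFactors = FALSE),
    data.frame(sample_id = names(di), ploidy = 2L, role = "unknown",
               known_genotype = unname(di), stringsAsFactors = FALSE),
    data.frame(sample_id = "CAL", ploidy = 2L, role = "calibrator",
               known_genotype = "Aa", stringsAsFactors = FALSE)
  )
  rownames(roster) <- NULL
  roster
}

#' Specify a synthetic fixture
#'
#' @param roster Data frame of samples (`sample_id`, `ploidy`, `role`,
#'   `known_genotype`); defaults to [default_roster()]. Exactly one row must
#'   have role `calibrator`.
#' @param replicates Wells per sample and assay.
#' @param ct_sd Gaussian Ct noise, cycles; the 0.05 default keeps reference
#'   CVs far below the 3 percent stability threshold.
#' @param seed Integer RNG seed; fixed seed means byte-identical files.
#' @param base_ct Ct of a unit-copy target.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(roster = default_roster(), replicates = 3L,
                         ct_sd = 0.05, seed = 1L, base_ct = 20) {
  need <- c("sample_id", "ploidy", "role", "known_genotype")
  missing_cols <- setdiff(need, names(roster))
  if (length(missing_cols)) {
    stop(sprintf("roster is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  roster$known_genotype <- canonicalize_genotype(roster$known_genotype)
  lens <- nchar(roster$known_genotype)
  bad <- which(lens != roster$ploidy)
  if (length(bad)) {
    stop(sprintf("sample '%s': genotype %s does not match ploidy %d",
                 roster$sample_id[bad[1L]], roster$known_genotype[bad[1L]],
                 roster$ploidy[bad[1L]]), call. = FALSE)
  }
  if (sum(roster$role == "calibrator") != 1L) {
    stop("roster must contain exactly one calibrator", call. = FALSE)
  }
  structure(list(roster = roster, replicates = as.integer(replicates),
                 ct_sd = ct_sd, seed = as.integer(seed), base_ct = base_ct),
            class = "fixture_spec")
}

#' Generate a synthetic fixture on disk
#'
#' Writes `plate.csv` (all wells), `samples.csv` (the sample sheet) and
#' `truth.csv` (the generating configuration of every sample) into `dir`.
#' Seeded and reproducible: identical specs give byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param panel An [assay_panel()].
#' @return Named character vector of the three file paths, invisibly.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir,
                             panel = assay_panel()) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plate <- simulate_roster_plate(spec, panel)
  paths <- c(plate = file.path(dir, "plate.csv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.csv"))
  write_results(plate, paths[["plate"]], seed = spec$seed, config = spec)
  write_results(spec$roster[c("sample_id", "ploidy", "role",
                              "known_genotype")],
                paths[["samples"]], seed = spec$seed, config = spec)
  truth <- data.frame(sample_id = spec$roster$sample_id,
                      genotype = spec$roster$known_genotype,
                      ploidy = spec$roster$ploidy,
                      p = vapply(spec$roster$known_genotype, expected_b, 1,
                                 USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  write_results(truth, paths[["truth"]], seed = spec$seed, config = spec)
  invisible(paths)
}

#' Simulate the plate of a fixture roster in memory
#'
#' @inheritParams generate_fixture
#' @return A plate data frame with wells for every roster sample.
#' @export
simulate_roster_plate <- function(spec, panel = assay_panel()) {
  with_seed(spec$seed, {
    wells <- lapply(seq_len(nrow(spec$roster)), function(i) {
      sim_wells(spec$roster$sample_id[i],
                fraction_quantities(expected_b(spec$roster$known_genotype[i])),
                panel, spec$ct_sd, spec$replicates, spec$base_ct)
    })
    validate_plate(do.call(rbind, wells))
  })
}
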