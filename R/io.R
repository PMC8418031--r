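# Delimited-text IO: plate files, sample sheets, cross records, results.
# Comma is the default delimiter with tab auto-detect; lines starting with
# '#' are provenance headers and are skipped on read.

detect_sep <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("'%s' has no data lines", path),
                           call. = FALSE)
  if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
}

read_delimited <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  df <- read.csv(path, sep = detect_sep(path), comment.char = "#",
                 stringsAsFactors = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a qPCR plate file
#'
#' Expects columns `sample_id`, `assay` (`reference`/`allele_A`/`combined`),
#' `replicate`, `ct`. Non-numeric or non-positive Ct values, unknown assay
#' labels and duplicate wells are rejected with the offending row named.
#'
#' @param path Path to a delimited text file (comma or tab).
#' @return A validated plate data frame.
#' @export
read_plate <- function(path) {
  df <- read_delimited(path, c("sample_id", "assay", "replicate", "ct"))
  ct_num <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct_num))
  if (length(bad)) {
    stop(sprintf("%s: row %d: Ct value '%s' is not numeric",
                 path, bad[1L], df$ct[bad[1L]]), call. = FALSE)
  }
  df$ct <- ct_num
  rep_num <- suppressWarnings(as.integer(df$replicate))
  bad <- which(is.na(rep_num))
  if (length(bad)) {
    stop(sprintf("%s: row %d: replicate '%s' is not an integer",
                 path, bad[1L], df$replicate[bad[1L]]), call. = FALSE)
  }
  df$replicate <- rep_num
  validate_plate(df)
}

#' Read a sample sheet
#'
#' Expects columns `sample_id`, `ploidy`, `role`
#' (`calibrator`/`unknown`/`control`) and optionally `known_genotype`
#' (a string over `{A, a}`, canonicalized on read).
#'
#' @param path Path to a delimited text file.
#' @return Data frame of samples.
#' @export
read_samples <- function(path) {
  df <- read_delimited(path, c("sample_id", "ploidy", "role"))
  bad <- which(!df$role %in% c("calibrator", "unknown", "control"))
  if (length(bad)) {
    stop(sprintf("%s: row %d: unknown role '%s'", path, bad[1L],
                 df$role[bad[1L]]), call. = FALSE)
  }
  ploidy <- suppressWarnings(as.integer(df$ploidy))
  bad <- which(is.na(ploidy) | ploidy < 1L)
  if (length(bad)) {
    stop(sprintf("%s: row %d: invalid ploidy '%s'", path, bad[1L],
                 df$ploidy[bad[1L]]), call. = FALSE)
  }
  df$ploidy <- ploidy
  if (!is.null(df$known_genotype)) {
    has <- !is.na(df$known_genotype) & nzchar(df$known_genotype)
    df$known_genotype[has] <- canonicalize_genotype(df$known_genotype[has])
  }
  dup <- which(duplicated(df$sample_id))
  if (length(dup)) {
    stop(sprintf("%s: row %d: duplicate sample_id '%s'", path, dup[1L],
                 df$sample_id[dup[1L]]), call. = FALSE)
  }
  df
}

#' Read cross records
#'
#' Expects columns `female_genotype`, `male_genotype`, `progeny_ploidy`,
#' `observed_red`, `observed_white`; optional `cross` id and gamete-route
#' overrides (`female_gametes`, `male_gametes`, `doubled`).
#'
#' @param path Path to a delimited text file.
#' @return Data frame of cross records.
#' @export
read_crosses <- function(path) {
  df <- read_delimited(path, c("female_genotype", "male_genotype",
                               "progeny_ploidy", "observed_red",
                               "observed_white"))
  df$female_genotype <- canonicalize_genotype(df$female_genotype)
  df$male_genotype <- canonicalize_genotype(df$male_genotype)
  for (col in c("progeny_ploidy", "observed_red", "observed_white")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v < 0L)
    if (length(bad)) {
      stop(sprintf("%s: row %d: invalid %s '%s'", path, bad[1L], col,
                   df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

# djb2 string hash, hex-encoded; used only for the config provenance line.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# polydose %s", as.character(packageVersion("polydose"))),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config=%s", config_hash(config)))
}

#' Write a result table with a provenance header
#'
#' Writes delimited text (comma-separated) with leading `#` header lines
#' recording the tool version, optional seed and config hash; column order
#' is preserved, so reruns on identical inputs are byte-identical.
#'
#' @param x Data frame to write.
#' @param path Output path; a `.json` extension switches to JSON (the same
#'   records, with the provenance as a metadata object).
#' @param seed,config Optional provenance: the RNG seed and the
#'   configuration list used for the run.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NULL, config = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      provenance = list(
        tool = paste("polydose", as.character(packageVersion("polydose"))),
        seed = seed,
        config_hash = if (is.null(config)) NULL else config_hash(config)),
      records = x)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(provenance_header(seed, config), con)
    write.csv(x, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' A flat YAML document of panel settings (assay names, efficiency), noise
#' defaults, thresholds (reference CV percent, tie tolerance) and seed.
#' Unknown keys are rejected.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    reference = "CH03g12", allele_a = "q2A", combined = "q2A/2Ad",
    efficiency = 2, undetected_ct = 40, ct_sd = 0.05, replicates = 3L,
    cv_threshold = 3, tie_tol = 1e-8, base_ct = 20, seed = 1L
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (key in c("efficiency", "undetected_ct", "ct_sd", "cv_threshold",
                "tie_tol", "base_ct")) {
    if (key %in% names(user) && user[[key]] <= 0 && key != "ct_sd") {
      stop(sprintf("config key '%s' must be positive", key), call. = FALSE)
    }
  }
  utils::modifyList(defaults, user)
}

#' Assay panel implied by a configuration
#'
#' @param config A list from [read_config()].
#' @return An [assay_panel()].
#' @export
panel_from_config <- function(config) {
  assay_panel(reference = config$reference, allele_a = config$allele_a,
              combined = config$combined, efficiency = config$efficiency,
              undetected_ct = config$undetected_ct)
}
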