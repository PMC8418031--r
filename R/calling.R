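# Genotype calling from the dosage statistic b, plus separability
# diagnostics (complete-linkage clustering, one-way ANOVA).

#' Call an allelic configuration from b at a given ploidy
#'
#' The expected b of a configuration with k dominant copies at ploidy m is
#' k/m; calling assigns each observed b to the nearest class. Values outside
#' `[0, 1]` clamp to the nearest extreme class. An exact midpoint between two
#' classes resolves to the lower dosage and is flagged ambiguous.
#'
#' @param b Numeric vector of dosage statistics (finite; values < 0 or > 1
#'   are permitted).
#' @param ploidy Positive integer, scalar or vector matching `b`.
#' @param tie_tol Half-width around a class midpoint inside which a call is
#'   flagged ambiguous.
#' @return Data frame with one row per input: `b`, `ploidy`, `n_dominant`,
#'   `genotype`, `expected_b`, `residual`, `ambiguous`.
#' @examples
#' call_genotype(0.26, 4)   # Aaaa
#' call_genotype(1.31, 2)   # AA (over-unity clamps to the top class)
#' @export
call_genotype <- function(b, ploidy, tie_tol = 1e-8) {
  if (any(!is.finite(b))) stop("`b` must be finite", call. = FALSE)
  if (any(ploidy < 1 | ploidy != round(ploidy))) {
    stop("`ploidy` must be a positive integer", call. = FALSE)
  }
  n <- length(b)
  ploidy <- as.integer(rep_len(ploidy, n))
  k_hat <- integer(n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    k <- 0:ploidy[i]
    d <- abs(b[i] - k / ploidy[i])
    best <- min(d)
    # ties resolve toward the lower dosage (smaller k)
    k_hat[i] <- k[which(d <= best + 0)][1L]
    d_sorted <- sort(d)
    ambiguous[i] <- length(d) > 1L && (d_sorted[2L] - d_sorted[1L]) <= tie_tol
  }
  exp_b <- k_hat / ploidy
  data.frame(b = b, ploidy = ploidy, n_dominant = k_hat,
             genotype = genotype_label(ploidy, k_hat),
             expected_b = exp_b, residual = abs(b - exp_b),
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Cluster dosage values into classes (farthest-neighbor)
#'
#' Agglomerative hierarchical clustering of scalar b values with complete
#' linkage and Euclidean distance, cut into `n_classes` groups. Group labels
#' are renumbered 1..k by increasing cluster mean b, so assignments are
#' deterministic for a fixed input.
#'
#' @param b Numeric vector of dosage values.
#' @param n_classes Number of groups to cut the tree into.
#' @return Integer vector of group assignments (attribute
#'   `cluster_method = "complete-linkage"`).
#' @export
cluster_dosages <- function(b, n_classes) {
  if (n_classes < 1 || n_classes > length(b)) {
    stop(sprintf("need at least %d values to form %d classes (got %d)",
                 n_classes, n_classes, length(b)), call. = FALSE)
  }
  if (n_classes == length(b)) {
    raw <- seq_along(b)
  } else if (n_classes == 1L) {
    raw <- rep(1L, length(b))
  } else {
    tree <- hclust(dist(b), method = "complete")
    raw <- cutree(tree, k = n_classes)
  }
  means <- vapply(split(b, raw), mean, 1)
  relabel <- rank(means, ties.method = "first")
  out <- as.integer(relabel[as.character(raw)])
  attr(out, "cluster_method") <- "complete-linkage"
  out
}

#' One-way ANOVA separation of dosage classes
#'
#' Standard one-way ANOVA of b values by class: `F = MS_between / MS_within`
#' with df `(k - 1, N - k)`. When every group has zero within-variance the F
#' ratio is reported as `Inf` with an explicit flag instead of dividing by
#' zero.
#'
#' @param b Numeric vector of dosage values.
#' @param group Class labels, same length as `b`; at least 2 groups with at
#'   least 2 values each.
#' @return List of class `separation_report`: `F`, `p`, `df`, `infinite_f`,
#'   `cluster_method`.
#' @export
anova_separation <- function(b, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 values",
                 names(sizes)[which(sizes < 2L)[1L]]), call. = FALSE)
  }
  fit <- aov(b ~ group, data = data.frame(b = b, group = group))
  # anova() warns on an essentially perfect fit; that case is handled below
  tab <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  msw <- tab["Residuals", "Mean Sq"]
  msb <- tab["group", "Mean Sq"]
  df <- c(tab["group", "Df"], tab["Residuals", "Df"])
  # residual mean square indistinguishable from zero at double precision
  if (msw <= (msb + msw) * 1e-12) {
    out <- list(F = Inf, p = 0, df = df, infinite_f = TRUE)
  } else {
    out <- list(F = tab["group", "F value"], p = tab["group", "Pr(>F)"],
                df = df, infinite_f = FALSE)
  }
  out$cluster_method <- "complete-linkage"
  class(out) <- "separation_report"
  out
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s%s\n",
              x$df[1L], x$df[2L],
              if (x$infinite_f) "Inf" else format(x$F, digits = 6),
              format(x$p, digits = 4),
              if (x$infinite_f) " (zero within-group variance)" else ""))
  invisible(x)
}
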