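# Group statistics and condition-comparison reporting shared by all pipelines.
#
# The study conventions are: group dispersion reported as mean +/- SEM, and
# pairwise comparisons by two-tailed Student's t-test assuming equal variance,
# annotated with the usual star scheme (ns > 0.05, * <= 0.05, ** <= 0.01,
# *** <= 0.001, **** <= 0.0001).

#' Summarise one group of values as mean +/- SEM
#'
#' @param values Numeric vector of per-replicate values (cells, fields,
#'   images, tracks ... whatever the replication unit of the assay is).
#' @param condition Label for the experimental condition.
#' @return A one-row data.frame with columns `condition`, `n`, `mean`, `sem`
#'   and `sem_defined`. For `n = 1` the SEM is undefined and flagged.
#' @examples
#' group_stats(c(1, 2, 3), "control")
#' @export
group_stats <- function(values, condition = "group") {
  if (length(values) == 0L)
    nm_stop("no values supplied", "empty_input")
  if (!all(is.finite(values)))
    nm_stop("values must all be finite", "invalid_input")
  data.frame(
    condition = as.character(condition),
    n = length(values),
    mean = mean(values),
    sem = sem(values),
    sem_defined = length(values) >= 2L,
    stringsAsFactors = FALSE
  )
}

#' Two-tailed Student's t-test assuming equal variance
#'
#' Pooled-variance t statistic with `n_a + n_b - 2` degrees of freedom and a
#' two-tailed p-value. Degenerate inputs (zero pooled variance) are handled
#' explicitly: equal means give p = 1, different means give p = 0, and the
#' result is flagged as degenerate.
#'
#' @param a,b Numeric vectors of per-replicate values, length >= 2 each.
#' @param group_a,group_b Labels for the two groups.
#' @return A one-row data.frame with columns `group_a`, `group_b`, `t`, `df`,
#'   `p`, `stars` and `degenerate`.
#' @examples
#' ttest_equal_var(c(1, 2, 3), c(2, 3, 4))
#' @export
ttest_equal_var <- function(a, b, group_a = "a", group_b = "b") {
  if (length(a) < 2L || length(b) < 2L)
    nm_stop("both groups need at least 2 values", "invalid_input")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    nm_stop("values must all be finite", "invalid_input")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  degenerate <- FALSE
  if (sp2 <= 0) {
    degenerate <- TRUE
    tval <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    tval <- delta / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tval), df = df)
  }
  data.frame(
    group_a = as.character(group_a), group_b = as.character(group_b),
    t = tval, df = df, p = p,
    stars = star_annotation(p), degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Significance star annotation for a p-value
#'
#' Bins follow the figure-legend convention `ns > 0.05`, `* <= 0.05`,
#' `** <= 0.01`, `*** <= 0.001`, `**** <= 0.0001`; the most extreme bin wins,
#' and exact boundary values fall in the more significant bin (p = 0.05 is
#' annotated `*`).
#'
#' @param p Probability in \[0, 1\] (vectorised).
#' @return Character vector of annotations.
#' @examples
#' star_annotation(c(0.5, 0.03, 0.0005))
#' @export
star_annotation <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    nm_stop("p must lie in [0, 1]", "invalid_input")
  out <- character(length(p))
  out[p > 0.05] <- "ns"
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[p <= 0.0001] <- "****"
  out
}

#' Consolidate per-condition values into a summary and comparison report
#'
#' Takes a named list of numeric vectors (one per condition) and produces the
#' per-condition mean +/- SEM table plus pairwise equal-variance t-tests for
#' the requested contrasts. Output ordering is deterministic: conditions in
#' input order, contrasts in the order given (or all pairs in input order).
#'
#' @param groups Named list of numeric vectors, one element per condition.
#' @param contrasts Either `"all-pairs"` or a two-column matrix / list of
#'   length-2 character vectors naming condition pairs.
#' @param metadata Optional named list (seed, configuration, ...) echoed in
#'   the result for reproducibility.
#' @return A list of class `nucmech_report` with elements `groups`
#'   (GroupStats table), `comparisons` (ComparisonResult table) and
#'   `metadata`.
#' @export
build_report <- function(groups, contrasts = "all-pairs", metadata = list()) {
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    nm_stop("'groups' must be a non-empty named list of numeric vectors",
            "invalid_input")
  cond <- names(groups)
  gtab <- do.call(rbind, lapply(cond, function(cn) group_stats(groups[[cn]], cn)))

  if (identical(contrasts, "all-pairs")) {
    pairs <- if (length(cond) >= 2L) utils::combn(cond, 2L, simplify = FALSE) else list()
  } else {
    if (is.matrix(contrasts)) {
      pairs <- lapply(seq_len(nrow(contrasts)), function(i) as.character(contrasts[i, 1:2]))
    } else {
      pairs <- lapply(contrasts, as.character)
    }
    bad <- unique(unlist(pairs))
    bad <- bad[!bad %in% cond]
    if (length(bad) > 0L)
      nm_stop(paste0("contrast refers to unknown condition(s): ",
                     paste(bad, collapse = ", ")), "label_mismatch")
  }
  ctab <- if (length(pairs) > 0L) {
    do.call(rbind, lapply(pairs, function(pr)
      ttest_equal_var(groups[[pr[1]]], groups[[pr[2]]], pr[1], pr[2])))
  } else {
    data.frame(group_a = character(), group_b = character(), t = numeric(),
               df = integer(), p = numeric(), stars = character(),
               degenerate = logical(), stringsAsFactors = FALSE)
  }
  structure(list(groups = gtab, comparisons = ctab, metadata = metadata),
            class = "nucmech_report")
}

#' @export
print.nucmech_report <- function(x, ...) {
  cat("Condition summary (mean +/- SEM):\n")
  print(x$groups, row.names = FALSE)
  if (nrow(x$comparisons) > 0L) {
    cat("\nPairwise two-tailed equal-variance t-tests:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
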