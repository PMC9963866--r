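# Degree-of-dominance estimation (d/|a|) and the midparent-contrast F test
# for traits measured on two parents and their F1 hybrid.

#' Degree of dominance and midparent contrast for one trait
#'
#' Computes the dominance deviation `d = mean(F1) - (mean(P1) + mean(P2))/2`,
#' the additive value `|a| = |mean(P1) - mean(P2)|/2`, their ratio `d/|a|`
#' (the degree of dominance: 0 additive, +-1 full dominance, beyond +-1
#' overdominance), and tests the contrast `F1 - P1/2 - P2/2 = 0` in a one-way
#' fixed-effects ANOVA: `SS = L^2 / sum(c_i^2/n_i)` with contrast coefficients
#' `c = (-1/2, -1/2, 1)`, `MSE` the pooled within-class variance on `N - 3`
#' error df, and `F = SS/MSE` on `(1, N - 3)` df.
#'
#' @param p1,p2,f1 Numeric vectors of replicate trait values for parent 1,
#'   parent 2, and the F1 hybrid. At least one value per class; at least two
#'   per class for the F test.
#' @param thresholds Numeric length-3 cutoffs on `|d/|a||` separating
#'   additive / partial dominance / dominance / overdominance
#'   (default `c(0.25, 0.75, 1.25)`).
#' @return A list of class `"gene_action"`: class means, `d`, `a_abs`,
#'   `ratio` (signed `Inf` when `|a| = 0` and `d != 0`, with a warning),
#'   `F_ratio`, `p_value`, `df_error`, `classification`, and `toward` (the
#'   parent whose mean the F1 leans to, or `"neither"`).
#' @export
gene_action <- function(p1, p2, f1, thresholds = c(0.25, 0.75, 1.25)) {
  vals <- list(P1 = as.numeric(p1), P2 = as.numeric(p2), F1 = as.numeric(f1))
  if (any(vapply(vals, function(v) length(v) < 1L || anyNA(v), TRUE)))
    stop("each genotype class needs at least one non-missing value")
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  mns <- vapply(vals, mean, 0)
  ns <- vapply(vals, length, 0L)
  d <- mns[["F1"]] - (mns[["P1"]] + mns[["P2"]]) / 2
  a_abs <- abs(mns[["P1"]] - mns[["P2"]]) / 2

  if (a_abs == 0) {
    if (d == 0) ratio <- 0
    else {
      ratio <- sign(d) * Inf
      warning("|a| = 0 with d != 0: ratio reported as signed infinity")
    }
  } else ratio <- d / a_abs

  df_error <- sum(ns) - 3L
  F_ratio <- NA_real_; p_value <- NA_real_
  if (df_error >= 1L && all(ns >= 1L)) {
    sse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
    mse <- sse / df_error
    ss_contrast <- d^2 / sum(c(0.25, 0.25, 1) / ns)
    if (mse == 0) {
      warning("zero within-class variance: p-value reported at the 0 boundary")
      F_ratio <- if (ss_contrast == 0) 0 else Inf
      p_value <- if (ss_contrast == 0) 1 else 0
    } else {
      F_ratio <- ss_contrast / mse
      p_value <- stats::pf(F_ratio, 1, df_error, lower.tail = FALSE)
    }
  }

  absr <- abs(ratio)
  classification <- if (absr < thresholds[1L]) "additive"
    else if (absr <= thresholds[2L]) "partial_dominance"
    else if (absr <= thresholds[3L]) "dominance"
    else "overdominance"
  toward <- if (d == 0 || a_abs == 0) "neither"
    else if (abs(mns[["F1"]] - mns[["P1"]]) < abs(mns[["F1"]] - mns[["P2"]]))
      "P1" else "P2"

  structure(list(mean_P1 = mns[["P1"]], mean_P2 = mns[["P2"]],
                 mean_F1 = mns[["F1"]], d = unname(d), a_abs = unname(a_abs),
                 ratio = unname(ratio), F_ratio = unname(F_ratio),
                 p_value = unname(p_value), df_error = df_error,
                 classification = classification, toward = toward,
                 n = ns),
            class = "gene_action")
}

#' Gene action for every trait in a long-format table
#'
#' @param df Data frame with columns `trait`, `genotype_class` (`P1`, `P2`,
#'   `F1`) and `value`, e.g. read from a TSV.
#' @param thresholds Passed to [gene_action()].
#' @return One row per trait with means, SEs, `d`, `a_abs`, `ratio`, `F`,
#'   `p`, df and classification.
#' @export
gene_action_table <- function(df, thresholds = c(0.25, 0.75, 1.25)) {
  stopifnot(all(c("trait", "genotype_class", "value") %in% names(df)))
  rows <- lapply(split(df, df$trait), function(tr) {
    v <- split(tr$value, factor(tr$genotype_class, c("P1", "P2", "F1")))
    g <- gene_action(v$P1, v$P2, v$F1, thresholds)
    se <- vapply(v, function(x) stats::sd(x) / sqrt(length(x)), 0)
    data.frame(trait = tr$trait[1L], mean_P1 = g$mean_P1, se_P1 = se[["P1"]],
               mean_P2 = g$mean_P2, se_P2 = se[["P2"]], mean_F1 = g$mean_F1,
               se_F1 = se[["F1"]], d = g$d, a_abs = g$a_abs, ratio = g$ratio,
               F_ratio = g$F_ratio, p_value = g$p_value,
               df_error = g$df_error, classification = g$classification,
               toward = g$toward, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
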