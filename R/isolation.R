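# Stage-wise reproductive-isolation (RI) indices standardized by selfing
# controls, and their sequential absolute/relative contributions to total
# isolation (Ramsey-style life-history decomposition).

#' Life-history order of the isolation stages
#'
#' One post-mating pre-zygotic stage (pollen-pistil compatibility) followed by
#' three post-zygotic stages (fruit set, fruit weight, seed production). The
#' order is fixed: a barrier can only remove gene flow not already removed by
#' earlier stages.
#' @export
ri_stages <- function() c("pollen_pistil", "fruit_set", "fruit_weight",
                          "seed_viability")

.stage_field <- c(pollen_pistil = "mean_pollen_score",
                  fruit_set = "fruit_set_fraction",
                  fruit_weight = "mean_fruit_weight",
                  seed_viability = "mean_seed_count")

#' Relative success of an interspecific cross at one stage
#'
#' Ratio of the interspecific stage value to the seed parent's selfing value:
#' mean pollen-tube score (pollen_pistil), fruit set fraction (fruit_set),
#' mean weight per harvested fruit (fruit_weight), or mean seeds per mature
#' fruit (seed_viability). The ratio may exceed 1 (crosses occasionally
#' outperform selfings); clamping happens at the RI step, not here.
#'
#' @param summary,self_summary Rows of a `cross_summaries` data frame: the
#'   directed interspecific cross and the seed parent's selfing.
#' @param stage One of [ri_stages()].
#' @return A non-negative ratio, or `NA` if the stage is unassessable (selfing
#'   value missing or zero, or cross value missing). Never divides by zero.
#' @export
stage_success <- function(summary, self_summary, stage) {
  stage <- match.arg(stage, ri_stages())
  fld <- .stage_field[[stage]]
  x <- summary[[fld]]
  s <- self_summary[[fld]]
  if (is.null(x) || is.null(s) || is.na(s) || s <= 0 || is.na(x))
    return(NA_real_)
  x / s
}

#' Pair-level RI from the two directed success ratios
#'
#' Per direction `RI = max(0, 1 - success)` (negative values, i.e. crosses
#' more successful than selfing, are clamped to 0 before averaging); the pair
#' value is the mean over assessable directions.
#'
#' @param success_ab,success_ba Success ratios of the direct and reciprocal
#'   cross (`NA` = unassessable).
#' @return RI in `[0, 1]`, or `NA` if both directions are unassessable.
#' @export
ri_for_pair <- function(success_ab, success_ba) {
  ri <- pmax(0, 1 - c(success_ab, success_ba))
  ri <- ri[!is.na(ri)]
  if (!length(ri)) return(NA_real_)
  min(1, mean(ri))
}

#' Symmetric pair RI matrix for one stage
#'
#' Builds the taxa x taxa RI matrix for a stage from a diallel summary table.
#' Each direction is standardized by its own seed parent's selfing; the two
#' directions are clamped and averaged by [ri_for_pair()]. Pairs with no
#' fruit in either direction keep `fruit_set` RI of 1 but are missing for the
#' later post-zygotic stages (they cannot be assessed).
#'
#' @param summaries A `cross_summaries` data frame including selfings for all
#'   taxa.
#' @param stage One of [ri_stages()].
#' @return A symmetric numeric matrix with `NA` diagonal, values in `[0, 1]`,
#'   attribute `n_pairs` = number of assessable pairs.
#' @export
ri_matrix <- function(summaries, stage) {
  stage <- match.arg(stage, ri_stages())
  taxa <- sort(unique(c(summaries$female_taxon, summaries$male_taxon)))
  key <- paste(summaries$female_taxon, summaries$male_taxon, sep = "\r")
  row_of <- function(f, m) {
    i <- match(paste(f, m, sep = "\r"), key)
    if (is.na(i)) NULL else summaries[i, ]
  }
  for (t in taxa)
    if (is.null(row_of(t, t)))
      stop("no selfing summary for taxon ", t)
  m <- matrix(NA_real_, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (j <= i) next
    a <- taxa[i]; b <- taxa[j]
    s_ab <- row_of(a, b); s_ba <- row_of(b, a)
    succ_ab <- if (is.null(s_ab)) NA_real_ else
      stage_success(s_ab, row_of(a, a), stage)
    succ_ba <- if (is.null(s_ba)) NA_real_ else
      stage_success(s_ba, row_of(b, b), stage)
    m[i, j] <- m[j, i] <- ri_for_pair(succ_ab, succ_ba)
  }
  attr(m, "stage") <- stage
  attr(m, "n_pairs") <- sum(!is.na(m[upper.tri(m)]))
  m
}

#' All four stage RI matrices
#'
#' @param summaries A `cross_summaries` data frame including selfings.
#' @return Named list of RI matrices, one per stage in life-history order.
#' @export
ri_matrices <- function(summaries) {
  out <- lapply(ri_stages(), function(st) ri_matrix(summaries, st))
  names(out) <- ri_stages()
  out
}

#' Sequential absolute and relative contributions to total isolation
#'
#' For stage-wise mean RI values in life-history order, the absolute
#' contribution of stage n is the isolation it adds given what earlier stages
#' already blocked: `AC_1 = RI_1`, `AC_n = RI_n * (1 - sum_{i<n} AC_i)`.
#' Total isolation is `T = sum AC_n` and relative contributions are
#' `RC_n = AC_n / T`. The recurrence telescopes: `1 - T = prod(1 - RI_n)`.
#'
#' @param mean_ri Numeric vector of stage mean RI values in `[0, 1]`, in
#'   life-history order.
#' @param n Optional integer vector of assessable pair counts per stage.
#' @param stages Optional stage names (default [ri_stages()] when lengths
#'   match, else `stage1..m`).
#' @return A data frame of class `"contribution_table"` with columns `stage`,
#'   `n`, `mean_RI`, `AC`, `RC`; total isolation in attribute `"T"`. If
#'   `T = 0` the RC column is `NA` with a warning.
#' @export
sequential_contributions <- function(mean_ri, n = NULL, stages = NULL) {
  m <- length(mean_ri)
  stopifnot(m >= 1L, all(is.finite(mean_ri)))
  if (any(mean_ri < 0 | mean_ri > 1)) stop("mean RI values must lie in [0, 1]")
  if (is.null(stages))
    stages <- if (m == length(ri_stages())) ri_stages() else
      paste0("stage", seq_len(m))
  if (is.null(n)) n <- rep(NA_integer_, m)
  ac <- numeric(m)
  blocked <- 0
  for (k in seq_len(m)) {
    ac[k] <- mean_ri[k] * (1 - blocked)
    blocked <- blocked + ac[k]
  }
  total <- sum(ac)
  rc <- if (total > 0) ac / total else {
    warning("total isolation is 0; relative contributions undefined")
    rep(NA_real_, m)
  }
  out <- data.frame(stage = stages, n = n, mean_RI = mean_ri, AC = ac,
                    RC = rc, stringsAsFactors = FALSE)
  attr(out, "T") <- total
  class(out) <- c("contribution_table", class(out))
  out
}

#' Invert printed absolute contributions back to stage RI values
#'
#' The inverse of the sequential recurrence: `RI_n = AC_n / (1 - sum_{i<n}
#' AC_i)`. Useful to feed a published absolute-contribution column back
#' through [sequential_contributions()].
#'
#' @param ac Numeric vector of absolute contributions in life-history order.
#' @return Numeric vector of stage RI values.
#' @export
ri_from_contributions <- function(ac) {
  stopifnot(all(is.finite(ac)), all(ac >= 0), sum(ac) <= 1 + 1e-12)
  remaining <- 1 - c(0, cumsum(ac)[-length(ac)])
  ifelse(remaining > 0, ac / remaining, 0)
}

#' Contribution table from stage RI matrices
#'
#' Default mode (`"stage_means"`) averages each stage's RI over its own set of
#' assessable pairs and applies the sequential recurrence to those means
#' (stage pair sets may differ, e.g. pairs setting no fruit drop out of the
#' later post-zygotic stages). The alternative `"per_pair"` mode runs the
#' recurrence per pair over pairs assessable at every stage and averages the
#' resulting AC columns.
#'
#' @param matrices Named list of stage RI matrices as from [ri_matrices()].
#' @param mode `"stage_means"` (default) or `"per_pair"`.
#' @return A `contribution_table` (see [sequential_contributions()]).
#' @export
contribution_table <- function(matrices, mode = c("stage_means", "per_pair")) {
  mode <- match.arg(mode)
  stages <- names(matrices)
  ut <- upper.tri(matrices[[1L]])
  vals <- vapply(matrices, function(m) m[ut], numeric(sum(ut)))
  if (mode == "stage_means") {
    mean_ri <- colMeans(vals, na.rm = TRUE)
    n <- as.integer(colSums(!is.na(vals)))
    sequential_contributions(mean_ri, n = n, stages = stages)
  } else {
    keep <- stats::complete.cases(vals)
    if (!any(keep)) stop("no pair is assessable at every stage")
    acs <- t(apply(vals[keep, , drop = FALSE], 1L, function(ri)
      sequential_contributions(ri, stages = stages)$AC))
    ac <- colMeans(acs)
    total <- sum(ac)
    out <- data.frame(stage = stages, n = rep(sum(keep), length(stages)),
                      mean_RI = colMeans(vals[keep, , drop = FALSE]), AC = ac,
                      RC = if (total > 0) ac / total else NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "T") <- total
    class(out) <- c("contribution_table", class(out))
    out
  }
}
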