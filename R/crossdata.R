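# Data model, I/O and aggregation for diallel crossing experiments, plus the
# ordinal crossability-index (CI) classification.

#' Schema configuration for cross-record tables
#'
#' Controls how [read_cross_records()] maps a delimited text file onto the
#' internal cross-record fields. Column aliases allow tables whose headers use
#' different names; the first alias found in the header wins.
#'
#' @param sep Field delimiter (default tab).
#' @param na_token Token encoding missing values (default `"NA"`).
#' @param aliases Named list mapping canonical field names to a character
#'   vector of accepted header names.
#' @param lenient Logical; if `TRUE`, a record with `fruit_set = FALSE` but
#'   fruit/seed measurements present is coerced (measurements set missing,
#'   with a message) instead of rejected.
#' @param allow_48h Logical; if `TRUE`, records with `hours_pp = 48` are
#'   accepted and tagged, otherwise only 24 h pollen-tube scores are admitted.
#'   Pistils were scored 24 h post-pollination, occasionally 48 h.
#' @return A list of class `"cross_schema"`.
#' @export
cross_schema <- function(sep = "\t", na_token = "NA", aliases = list(),
                         lenient = FALSE, allow_48h = TRUE) {
  default_aliases <- list(
    female_taxon      = c("female_taxon", "female", "seed_parent", "mother"),
    male_taxon        = c("male_taxon", "male", "pollen_parent", "father"),
    replicate_id      = c("replicate_id", "replicate", "rep"),
    pollen_score      = c("pollen_score", "pollen_tube_score", "pt_score"),
    ovules_fertilized = c("ovules_fertilized", "fertilized"),
    fruit_set         = c("fruit_set", "fruit"),
    fruit_weight      = c("fruit_weight", "fruit_weight_g"),
    seed_count        = c("seed_count", "seeds", "seed_set"),
    seed_weight       = c("seed_weight", "seed_weight_mg"),
    seeds_sown        = c("seeds_sown", "sown"),
    seeds_germinated  = c("seeds_germinated", "germinated"),
    hours_pp          = c("hours_pp", "hpp")
  )
  for (nm in names(aliases)) default_aliases[[nm]] <- aliases[[nm]]
  structure(list(sep = sep, na_token = na_token, aliases = default_aliases,
                 lenient = lenient, allow_48h = allow_48h),
            class = "cross_schema")
}

.cross_required <- c("female_taxon", "male_taxon", "fruit_set",
                     "seeds_sown", "seeds_germinated")

#' Validate a data frame of cross records
#'
#' Enforces the record invariants: pollen scores in \{0..4\}, seed counts
#' non-negative, `seeds_germinated <= seeds_sown`, and no fruit/seed
#' measurements on records without fruit set. Errors name the offending row
#' and field.
#'
#' @param df A data frame with cross-record columns.
#' @param schema A [cross_schema()] (controls lenient coercion).
#' @return The validated (possibly coerced) data frame, with class
#'   `"cross_records"` prepended.
#' @export
validate_cross_records <- function(df, schema = cross_schema()) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(.cross_required, names(df))
  if (length(miss))
    stop("cross-record table lacks required column(s): ",
         paste(miss, collapse = ", "))
  opt_defaults <- list(replicate_id = NA_character_, pollen_score = NA_integer_,
                       ovules_fertilized = NA, fruit_weight = NA_real_,
                       seed_count = NA_integer_, seed_weight = NA_real_,
                       hours_pp = 24L)
  for (nm in names(opt_defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(opt_defaults[[nm]], nrow(df))

  df$female_taxon <- as.character(df$female_taxon)
  df$male_taxon <- as.character(df$male_taxon)
  bad_tax <- grepl("[^A-Za-z0-9_.x-]", c(df$female_taxon, df$male_taxon))
  if (any(bad_tax))
    stop("taxon identifiers contain unsupported characters: ",
         paste(unique(c(df$female_taxon, df$male_taxon)[bad_tax]), collapse = ", "))
  df$pollen_score <- as.integer(df$pollen_score)
  df$fruit_set <- as.logical(df$fruit_set)
  df$ovules_fertilized <- as.logical(df$ovules_fertilized)
  for (nm in c("fruit_weight", "seed_weight")) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("seed_count", "seeds_sown", "seeds_germinated", "hours_pp"))
    df[[nm]] <- as.integer(df[[nm]])

  fail <- function(row, field, why)
    stop(sprintf("row %d, field '%s': %s", row, field, why), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    ps <- df$pollen_score[i]
    if (!is.na(ps) && (ps < 0L || ps > 4L))
      fail(i, "pollen_score", "must be an integer in 0..4 or missing")
    if (!is.na(df$fruit_weight[i]) && df$fruit_weight[i] < 0)
      fail(i, "fruit_weight", "must be >= 0")
    if (!is.na(df$seed_weight[i]) && df$seed_weight[i] < 0)
      fail(i, "seed_weight", "must be >= 0")
    if (!is.na(df$seed_count[i]) && df$seed_count[i] < 0)
      fail(i, "seed_count", "must be >= 0")
    if (is.na(df$seeds_sown[i]) || df$seeds_sown[i] < 0)
      fail(i, "seeds_sown", "must be a non-negative integer")
    if (is.na(df$seeds_germinated[i]) || df$seeds_germinated[i] < 0)
      fail(i, "seeds_germinated", "must be a non-negative integer")
    if (df$seeds_germinated[i] > df$seeds_sown[i])
      fail(i, "seeds_germinated", "exceeds seeds_sown")
    if (!is.na(df$fruit_set[i]) && !df$fruit_set[i] &&
        (!is.na(df$fruit_weight[i]) || !is.na(df$seed_count[i]))) {
      if (schema$lenient) {
        message(sprintf(
          "row %d: fruit_set is FALSE; coercing fruit_weight/seed_count to missing", i))
        df$fruit_weight[i] <- NA_real_
        df$seed_count[i] <- NA_integer_
      } else {
        fail(i, "fruit_set",
             "is FALSE but fruit_weight/seed_count are present (use lenient mode to coerce)")
      }
    }
    if (!is.na(df$hours_pp[i]) && !df$hours_pp[i] %in% c(24L, 48L))
      fail(i, "hours_pp", "must be 24 or 48")
    if (!schema$allow_48h && !is.na(df$hours_pp[i]) && df$hours_pp[i] == 48L &&
        !is.na(ps))
      fail(i, "hours_pp", "48 h pollen-tube scores not admitted by schema")
  }
  class(df) <- unique(c("cross_records", class(df)))
  df
}

#' Read a cross-record table from disk
#'
#' Reads a delimited table of pollination events (one row per pollination),
#' renames headers through the schema aliases and validates every row against
#' the record invariants.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param schema A [cross_schema()].
#' @return A `cross_records` data frame.
#' @export
read_cross_records <- function(path, schema = cross_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = schema$sep,
                          na.strings = schema$na_token,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty cross-record table: ", path)
  for (canon in names(schema$aliases)) {
    hit <- intersect(schema$aliases[[canon]], names(df))
    if (length(hit)) names(df)[match(hit[1L], names(df))] <- canon
  }
  out <- validate_cross_records(df, schema)
  message(sprintf("read %d cross records from %s", nrow(out), path))
  out
}

.modal_severe <- function(scores) {
  # most frequent value; ties broken toward the more severe (lower) score
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_integer_)
  tab <- table(scores)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' Aggregate cross records into per-pair summaries
#'
#' One summary per directed female x male combination. Means are taken over
#' non-missing values; `fruit_set_fraction` is fruits over pollinations with
#' an observed fruit outcome; `germination_rate` pools germinated over sown
#' seeds across records.
#'
#' @param records A `cross_records` data frame.
#' @param fertility Optional data frame with columns `female_taxon`,
#'   `male_taxon`, `hybrid_fertility` (one of `fertile`, `male_sterile`,
#'   `fully_sterile`, `unknown`) describing the progeny of each cross.
#' @return A data frame of class `"cross_summaries"` with one row per
#'   directed pair, including the modal pollen-tube arrest score
#'   (`modal_pollen_score`) and whether fertilized ovules were ever seen
#'   (`any_fertilized`).
#' @export
aggregate_crosses <- function(records, fertility = NULL) {
  stopifnot(inherits(records, "cross_records") || is.data.frame(records))
  key <- interaction(records$female_taxon, records$male_taxon, drop = TRUE,
                     sep = "\r")
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, , drop = FALSE]
    n_fruit_obs <- sum(!is.na(r$fruit_set))
    sown <- sum(r$seeds_sown, na.rm = TRUE)
    fert <- r$ovules_fertilized
    fert[is.na(fert) & !is.na(r$pollen_score)] <- r$pollen_score[is.na(fert) &
                                                   !is.na(r$pollen_score)] == 4L
    out <- data.frame(
      female_taxon = r$female_taxon[1L],
      male_taxon = r$male_taxon[1L],
      n_pollinations = nrow(r),
      mean_pollen_score = if (all(is.na(r$pollen_score))) NA_real_ else
        mean(r$pollen_score, na.rm = TRUE),
      modal_pollen_score = .modal_severe(r$pollen_score),
      any_fertilized = if (all(is.na(fert))) NA else any(fert, na.rm = TRUE),
      fruit_set_fraction = if (n_fruit_obs == 0L) NA_real_ else
        sum(r$fruit_set, na.rm = TRUE) / n_fruit_obs,
      mean_fruit_weight = if (all(is.na(r$fruit_weight))) NA_real_ else
        mean(r$fruit_weight, na.rm = TRUE),
      mean_seed_count = if (all(is.na(r$seed_count))) NA_real_ else
        mean(r$seed_count, na.rm = TRUE),
      mean_seed_weight = if (all(is.na(r$seed_weight))) NA_real_ else
        mean(r$seed_weight, na.rm = TRUE),
      germination_rate = if (sown == 0L) NA_real_ else
        sum(r$seeds_germinated, na.rm = TRUE) / sown,
      hybrid_fertility = "unknown",
      stringsAsFactors = FALSE
    )
    if (all(is.na(r$pollen_score)) && n_fruit_obs == 0L)
      warning(sprintf("pair %s x %s: all stage values missing",
                      out$female_taxon, out$male_taxon), call. = FALSE)
    out
  })
  s <- do.call(rbind, rows)
  rownames(s) <- NULL
  if (!is.null(fertility)) {
    m <- match(paste(s$female_taxon, s$male_taxon),
               paste(fertility$female_taxon, fertility$male_taxon))
    ok <- !is.na(m)
    s$hybrid_fertility[ok] <- as.character(fertility$hybrid_fertility[m[ok]])
  }
  bad <- !s$hybrid_fertility %in% c("fertile", "male_sterile", "fully_sterile",
                                    "unknown")
  if (any(bad)) stop("unknown hybrid_fertility value(s): ",
                     paste(unique(s$hybrid_fertility[bad]), collapse = ", "))
  class(s) <- unique(c("cross_summaries", class(s)))
  s
}

#' Classify a directed cross on the 1-8 crossability index
#'
#' Deterministic decision cascade over a pair summary. Levels 5-8 encode
#' pre-zygotic pollen-tube arrest (modal arrest site across replicates, ties
#' toward the more severe level): before the stigma half (8), stigma end or
#' style (7), distal ovary (6), proximal ovary (5). Level 4: fruit set or
#' fertilization but no germinating seed. Level 3: germinating seed but
#' inviable or fully sterile hybrids. Level 2: viable hybrids retaining at
#' least one fertile function. Level 1 is reserved for fully fertile self- or
#' intraspecific pollinations. When the available fields cannot decide, the
#' level is `NA` with `reason = "undetermined"` (never a silent default).
#'
#' @param summary,self_summary Rows of a `cross_summaries` data frame for the
#'   interspecific cross and the seed parent's self-pollination.
#' @return A list of class `"crossability"` with `level` (integer or `NA`),
#'   `fertilized_but_failed` (fertilized ovules observed yet classified
#'   pre-zygotic, the starred cells), and `reason`.
#' @export
classify_crossability <- function(summary, self_summary) {
  lvl <- NA_integer_
  reason <- "undetermined"
  fs <- summary$fruit_set_fraction
  germ <- summary$germination_rate
  modal <- summary$modal_pollen_score
  fert <- isTRUE(summary$any_fertilized)
  no_fruit <- !is.na(fs) && fs == 0
  has_fruit <- !is.na(fs) && fs > 0

  if (no_fruit && !fert && !is.na(modal) && modal < 4L) {
    lvl <- c(`0` = 8L, `1` = 7L, `2` = 6L, `3` = 5L)[[as.character(modal)]]
    reason <- "pollen-tube arrest, no fruit"
  } else if (has_fruit || fert) {
    intra <- identical(summary$female_taxon, summary$male_taxon)
    if (is.na(germ) || germ == 0) {
      lvl <- 4L
      reason <- "fruit/fertilization but no germinating seed"
    } else if (intra && summary$hybrid_fertility == "fertile") {
      lvl <- 1L
      reason <- "fully fertile self/intraspecific cross"
    } else {
      lvl <- switch(summary$hybrid_fertility,
                    fertile = 2L, male_sterile = 2L, fully_sterile = 3L,
                    unknown = if (germ < 0.10) 3L else NA_integer_)
      reason <- if (is.na(lvl)) "germinating seed but hybrid fate unknown"
                else if (lvl == 2L) "viable hybrids with a fertile function"
                else "hybrids inviable or fully sterile"
    }
  } else if (no_fruit && is.na(modal) && !fert) {
    reason <- "no fruit and no pollen-tube observations"
  }
  structure(list(level = lvl,
                 fertilized_but_failed = fert && !is.na(lvl) && lvl >= 5L,
                 reason = reason),
            class = "crossability")
}

#' Crossability-index matrix for a diallel
#'
#' Applies [classify_crossability()] to every directed pair in a summary
#' table; the diagonal holds selfings.
#'
#' @param summaries A `cross_summaries` data frame covering the diallel,
#'   including self-pollinations.
#' @return A list with `levels` (taxa x taxa integer matrix, female rows),
#'   `flags` (logical matrix of fertilized-but-failed annotations) and
#'   `reasons` (character matrix).
#' @export
ci_matrix <- function(summaries) {
  taxa <- sort(unique(c(summaries$female_taxon, summaries$male_taxon)))
  lev <- matrix(NA_integer_, length(taxa), length(taxa),
                dimnames = list(female = taxa, male = taxa))
  flg <- matrix(NA, length(taxa), length(taxa), dimnames = dimnames(lev))
  rsn <- matrix(NA_character_, length(taxa), length(taxa),
                dimnames = dimnames(lev))
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    self <- summaries[summaries$female_taxon == s$female_taxon &
                        summaries$male_taxon == s$female_taxon, ]
    cl <- classify_crossability(s, if (nrow(self)) self[1L, ] else NULL)
    lev[s$female_taxon, s$male_taxon] <- cl$level
    flg[s$female_taxon, s$male_taxon] <- cl$fertilized_but_failed
    rsn[s$female_taxon, s$male_taxon] <- cl$reason
  }
  list(levels = lev, flags = flg, reasons = rsn)
}

#' Transform CI levels onto the 0-4 pollen-pistil scale
#'
#' Pre-zygotic levels map to the arrest score they encode (8 -> 0, 7 -> 1,
#' 6 -> 2, 5 -> 3); levels 1-4 (fertilization achieved) map to 4. Used when
#' comparing pollen-pistil compatibility of backcrosses across genotypes.
#'
#' @param level Integer vector of CI levels in 1..8.
#' @return Integer vector of 0-4 scores.
#' @export
ci_to_pollen_scale <- function(level) {
  level <- as.integer(level)
  if (any(is.na(level) | level < 1L | level > 8L))
    stop("CI level out of range 1..8")
  map <- c(4L, 4L, 4L, 4L, 3L, 2L, 1L, 0L)
  map[level]
}
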