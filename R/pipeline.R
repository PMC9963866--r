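# End-to-end orchestration: run configuration, output writers, the pipeline
# driver, and a subcommand-style command line interface.

#' Run configuration
#'
#' Bundles input paths and analysis parameters. Filter and bootstrap defaults
#' are the published ones: genotype depth >= 10, per-site heterozygosity
#' <= 0.80, 20 bp thinning, 1000 bootstrap replicates. The Mantel default is
#' 9999 permutations, one-sided "greater".
#'
#' @param crosses Path to a cross-record TSV (or `NULL`).
#' @param vcf Path to a VCF (or `NULL`).
#' @param fertility Optional path to a hybrid-fertility TSV.
#' @param traits Optional path to a long-format trait TSV for gene action.
#' @param out_dir Output directory.
#' @param min_depth,max_het,thin_bp Filter parameters.
#' @param n_bootstrap Bootstrap replicates for the NJ tree.
#' @param n_perm Mantel permutations.
#' @param seed Integer seed; mandatory whenever a stochastic step
#'   (bootstrap or Mantel) will run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(crosses = NULL, vcf = NULL, fertility = NULL,
                       traits = NULL, out_dir = "crossiso_out",
                       min_depth = 10, max_het = 0.80, thin_bp = 20,
                       n_bootstrap = 1000, n_perm = 9999, seed = NULL) {
  structure(list(crosses = crosses, vcf = vcf, fertility = fertility,
                 traits = traits, out_dir = out_dir, min_depth = min_depth,
                 max_het = max_het, thin_bp = thin_bp,
                 n_bootstrap = n_bootstrap, n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, js[intersect(names(js), names(formals(run_config)))])
}

.write_tsv <- function(x, path, row_label = NULL) {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- if (is.null(row_label)) "taxon" else row_label
    x <- df
  }
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Long-format (pair list) view of a square matrix
#' @param m Labeled symmetric matrix.
#' @return Data frame with `taxon_a`, `taxon_b`, `value` (upper triangle).
#' @export
matrix_to_pairs <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(taxon_a = rownames(m)[ut[, 1L]], taxon_b = colnames(m)[ut[, 2L]],
             value = m[ut], stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which the configuration supplies inputs: cross
#' aggregation, CI matrix, per-stage RI matrices, the sequential contribution
#' table, gene action (if a trait table is given), VCF filtering, per-sample
#' heterozygosity, Nei distances, the bootstrapped NJ tree, Mantel/Pearson
#' RI-vs-distance tests, and the post-zygotic clustered heatmap. All tables
#' are TSV, trees Newick, plus a JSON manifest with the seed and per-step
#' counts. Any stage failure raises an error after writing the manifest with
#' the failure point recorded.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$seed) && (cfg$n_bootstrap > 0 || cfg$n_perm > 0))
    stop("configuration has stochastic steps (bootstrap/Mantel) but no seed; ",
         "set seed in the run configuration")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("crossiso")),
                   seed = cfg$seed, parameters = cfg[c("min_depth", "max_het",
                     "thin_bp", "n_bootstrap", "n_perm")],
                   artifacts = list(), counts = list(), failed_at = NULL)
  out <- function(name) file.path(cfg$out_dir, name)
  finish <- function() jsonlite::write_json(manifest, out("manifest.json"),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, force = TRUE)
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_at <<- label
      finish()
      stop(sprintf("stage '%s' failed: %s", label, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ri_mats <- NULL; dm <- NULL

  if (!is.null(cfg$crosses)) {
    rec <- step("crosses", read_cross_records(cfg$crosses))
    fert <- if (!is.null(cfg$fertility))
      utils::read.delim(cfg$fertility, stringsAsFactors = FALSE) else NULL
    summ <- step("aggregate", aggregate_crosses(rec, fertility = fert))
    manifest$counts$n_records <- nrow(rec)
    manifest$counts$n_pairs <- nrow(summ)
    ci <- step("ci", ci_matrix(summ))
    .write_tsv(ci$levels, out("ci_matrix.tsv"))
    jsonlite::write_json(list(levels = ci$levels, flags = ci$flags,
                              reasons = ci$reasons),
                         out("ci_matrix.json"), digits = NA, pretty = TRUE)
    ri_mats <- step("ri", ri_matrices(summ))
    for (st in names(ri_mats)) {
      .write_tsv(ri_mats[[st]], out(sprintf("ri_%s.tsv", st)))
      .write_tsv(matrix_to_pairs(ri_mats[[st]]),
                 out(sprintf("ri_%s_pairs.tsv", st)))
    }
    ct <- step("contributions", contribution_table(ri_mats))
    ct_out <- ct
    ct_out$total_T <- rep(attr(ct, "T"), nrow(ct))
    .write_tsv(as.data.frame(ct_out), out("contributions.tsv"))
    manifest$counts$total_isolation <- attr(ct, "T")
    # post-zygotic clustered heatmap over pairs with data at all stages
    hm <- step("heatmap", {
      vals <- sapply(ri_mats[-1L], function(m) m[upper.tri(m)])
      prs <- matrix_to_pairs(ri_mats[[1L]])
      rownames(vals) <- paste(prs$taxon_a, prs$taxon_b, sep = "_x_")
      vals <- vals[stats::complete.cases(vals), , drop = FALSE]
      vals <- vals[, apply(vals, 2L, stats::sd) > 0, drop = FALSE]
      if (nrow(vals) >= 2L && ncol(vals) >= 2L) cluster_heatmap(vals) else NULL
    })
    if (!is.null(hm)) {
      .write_tsv(hm$scaled_values, out("heatmap_scaled.tsv"),
                 row_label = "cross")
      jsonlite::write_json(list(row_order = hm$row_order,
                                col_order = hm$col_order,
                                row_merge = hm$row_linkage$merge,
                                row_height = hm$row_linkage$height,
                                col_merge = hm$col_linkage$merge,
                                col_height = hm$col_linkage$height),
                           out("heatmap_linkage.json"), digits = NA,
                           pretty = TRUE)
      manifest$artifacts$heatmap <- "heatmap_scaled.tsv"
    }
    manifest$artifacts$ci <- "ci_matrix.tsv"
    manifest$artifacts$contributions <- "contributions.tsv"
  }

  if (!is.null(cfg$traits)) {
    tr <- step("geneaction", {
      df <- utils::read.delim(cfg$traits, stringsAsFactors = FALSE)
      gene_action_table(df)
    })
    .write_tsv(tr, out("gene_action.tsv"))
    manifest$artifacts$gene_action <- "gene_action.tsv"
  }

  if (!is.null(cfg$vcf)) {
    gm <- step("genotypes", read_genotypes(cfg$vcf))
    gmf <- step("filter", filter_sites(gm, cfg$min_depth, cfg$max_het,
                                       cfg$thin_bp))
    manifest$counts$filter <- gmf$log
    write_vcf(gmf, out("filtered.vcf"))
    het <- step("heterozygosity", sample_heterozygosity(gmf))
    .write_tsv(data.frame(sample = names(het), heterozygosity = het),
               out("heterozygosity.tsv"))
    dm <- step("distance", nei_distance(gmf))
    .write_tsv(dm, out("nei_distance.tsv"))
    bt <- step("tree", bootstrap_tree(gmf, n_reps = cfg$n_bootstrap,
                                      seed = cfg$seed))
    ape::write.tree(bt$tree, out("nj_tree.nwk"))
    manifest$counts$bootstrap_effective <- bt$n_effective
    manifest$counts$bootstrap_skipped <- bt$n_skipped
    manifest$artifacts$distance <- "nei_distance.tsv"
    manifest$artifacts$tree <- "nj_tree.nwk"
  }

  if (!is.null(ri_mats) && !is.null(dm)) {
    cors <- step("mantel", {
      rows <- lapply(names(ri_mats), function(st) {
        m <- ri_mats[[st]]
        common <- intersect(rownames(m), rownames(dm))
        if (length(common) < 4L) return(NULL)
        mm <- m[common, common]; dd <- dm[common, common]
        keep <- rowSums(is.na(mm)) < (length(common) - 1L)
        mm <- mm[keep, keep]; dd <- dd[keep, keep]
        ok <- !is.na(mm[upper.tri(mm)])
        pe <- tryCatch(pearson_vector(mm[upper.tri(mm)][ok],
                                      dd[upper.tri(dd)][ok]),
                       error = function(e) list(r = NA, p_value = NA,
                                                n = sum(ok)))
        mt <- tryCatch(suppressWarnings(
          mantel(mm, dd, n_perm = cfg$n_perm, seed = cfg$seed)),
          error = function(e) list(r = NA, p_value = NA))
        data.frame(stage = st, n_pairs = sum(ok), pearson_r = pe$r,
                   pearson_p = pe$p_value, mantel_r = mt$r,
                   mantel_p = mt$p_value, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    if (!is.null(cors)) {
      .write_tsv(cors, out("ri_distance_correlation.tsv"))
      manifest$artifacts$correlation <- "ri_distance_correlation.tsv"
    }
  }

  finish()
  manifest$artifacts$manifest <- "manifest.json"
  invisible(manifest)
}

# ---- command line interface ------------------------------------------------

.cli_opts <- function(args) {
  # --key value / --key=value pairs -> named list; bare args positional
  opts <- list(); pos <- character(0L)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      a <- sub("^--", "", a)
      if (grepl("=", a, fixed = TRUE)) {
        kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
        opts[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
      } else {
        if (i == length(args)) stop("option --", a, " lacks a value")
        opts[[a]] <- args[i + 1L]
        i <- i + 1L
      }
    } else pos <- c(pos, a)
    i <- i + 1L
  }
  list(opts = opts, pos = pos)
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command line entry point
#'
#' Subcommands: `simulate` (emit a synthetic dataset), `crosses` (aggregate
#' and classify), `ri`, `contributions`, `geneaction`, `filter`, `distance`,
#' `tree`, `mantel`, `heatmap`, and `run` (the full pipeline). Options are
#' `--key value` pairs; `--config file.json` loads a [run_config()] with
#' command-line overrides. Returns (rather than calls `quit` with) the exit
#' status: 0 success, 2 validation error, 3 stage failure.
#'
#' @param args Character vector of command line arguments.
#' @return Integer exit status, invisibly.
#' @export
cri_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crossiso <command> [--options]",
    "commands: simulate crosses ri contributions geneaction filter",
    "          distance tree mantel heatmap run", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  parsed <- tryCatch(.cli_opts(args[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed)); return(invisible(2L))
  }
  o <- parsed$opts
  need <- function(key) {
    if (is.null(o[[key]])) stop("missing required option --", key)
    o[[key]]
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- synth_config(
          n_taxa = .cli_num(o, "n-taxa", 6),
          n_loci = .cli_num(o, "n-loci", 2000),
          tree_shape = if (is.null(o[["tree-shape"]])) "balanced"
                       else o[["tree-shape"]],
          seed = as.integer(need("seed")))
        paths <- simulate_dataset(cfg, need("out"))
        message("wrote ", paste(unlist(paths), collapse = ", "))
        0L
      },
      crosses = {
        rec <- read_cross_records(need("crosses"))
        summ <- aggregate_crosses(rec)
        .write_tsv(summ, file.path(dirname(need("crosses")), "summaries.tsv"))
        0L
      },
      ri = , contributions = , heatmap = {
        cfg <- run_config(crosses = need("crosses"),
                          out_dir = need("out"), n_bootstrap = 0,
                          n_perm = 0, seed = .cli_num(o, "seed", 1))
        run_pipeline(cfg); 0L
      },
      geneaction = {
        cfg <- run_config(traits = need("traits"), out_dir = need("out"),
                          n_bootstrap = 0, n_perm = 0, seed = 1)
        run_pipeline(cfg); 0L
      },
      filter = , distance = , tree = {
        cfg <- run_config(vcf = need("vcf"), out_dir = need("out"),
                          min_depth = .cli_num(o, "min-depth", 10),
                          max_het = .cli_num(o, "max-het", 0.80),
                          thin_bp = .cli_num(o, "thin-bp", 20),
                          n_bootstrap = .cli_num(o, "bootstrap",
                            if (cmd == "tree") 1000 else 0),
                          n_perm = 0,
                          seed = if (!is.null(o$seed)) as.integer(o$seed)
                                 else NULL)
        run_pipeline(cfg); 0L
      },
      mantel = , run = {
        cfg <- if (!is.null(o$config)) read_run_config(o$config)
               else run_config()
        for (key in c("crosses", "vcf", "fertility", "traits"))
          if (!is.null(o[[key]])) cfg[[key]] <- o[[key]]
        if (!is.null(o$out)) cfg$out_dir <- o$out
        if (!is.null(o$seed)) cfg$seed <- as.integer(o$seed)
        run_pipeline(cfg); 0L
      },
      { message("unknown command: ", cmd); message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing required option|no seed|must|not found|lacks|empty",
              conditionMessage(e))) 2L else 3L
  })
  invisible(as.integer(status))
}
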