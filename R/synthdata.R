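# Synthetic species trees, GBS-like genotype matrices, and diallel crossing
# datasets with known ground truth, so every pipeline stage is testable
# without external sequencing data.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the experimental design the package targets: a handful of
#' mostly inbred taxa diverging along a known tree, genotyped at thousands of
#' GBS-derived biallelic SNPs (low residual heterozygosity, negative-binomial
#' depths), and a full diallel whose barrier strength grows with divergence.
#'
#' @param n_taxa Number of taxa (default 6, a 6 x 6 diallel).
#' @param n_loci Number of biallelic loci (default 2000).
#' @param tree_shape `"balanced"`, `"caterpillar"`, or `"random"` (random
#'   topology drawn under the seed).
#' @param branch_scale Expected substitutions per locus per unit branch
#'   length (default 0.05).
#' @param barrier_map Monotone map from pairwise tree distance to per-stage
#'   barrier strengths in `[0, 1]`. A list: `kind = "linear"` uses
#'   `b = min(1, slope_stage * d / d_max)` with per-stage slopes;
#'   `kind = "constant"` uses a flat `level` (the null world for calibration).
#' @param stage_noise Dispersion parameters: `fruit_weight_shape`,
#'   `seed_weight_shape` (gamma shapes), `depth_mean`, `depth_size`
#'   (negative binomial), `residual_het` (per-locus heterozygosity of inbred
#'   taxa, default 0.004).
#' @param n_crosses_per_pair Pollinations per directed cross for the
#'   fruit/seed experiment (default 25).
#' @param n_pollentube_per_pair Pistils scored for pollen-tube growth per
#'   directed cross (default 5).
#' @param asymmetry Half-width of a uniform per-direction perturbation of the
#'   barrier strengths (default 0 = symmetric barriers); > 0 generates
#'   unilateral-incompatibility-like patterns.
#' @param hybrids Optional list of length-2 taxon vectors; each adds an F1
#'   sample (one allele from each parent per locus) to the genotype matrix.
#' @param seed Integer seed; mandatory.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_taxa = 6, n_loci = 2000,
                         tree_shape = c("balanced", "caterpillar", "random"),
                         branch_scale = 0.05,
                         barrier_map = list(kind = "linear",
                           slopes = c(pollen_pistil = 1.25, fruit_set = 1.0,
                                      fruit_weight = 0.7, seed_viability = 0.8,
                                      germination = 0.8)),
                         stage_noise = list(fruit_weight_shape = 20,
                                            seed_weight_shape = 15,
                                            depth_mean = 30, depth_size = 10,
                                            residual_het = 0.004),
                         n_crosses_per_pair = 25, n_pollentube_per_pair = 5,
                         asymmetry = 0, hybrids = NULL, seed) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa >= 3, n_loci >= 1, n_crosses_per_pair >= 1,
            n_pollentube_per_pair >= 1, branch_scale >= 0, asymmetry >= 0)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!barrier_map$kind %in% c("linear", "constant"))
    stop("barrier_map$kind must be 'linear' or 'constant'")
  structure(list(n_taxa = n_taxa, n_loci = n_loci, tree_shape = tree_shape,
                 branch_scale = branch_scale, barrier_map = barrier_map,
                 stage_noise = stage_noise,
                 n_crosses_per_pair = n_crosses_per_pair,
                 n_pollentube_per_pair = n_pollentube_per_pair,
                 asymmetry = asymmetry, hybrids = hybrids,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.balanced_newick <- function(labels) {
  build <- function(v) {
    if (length(v) == 1L) return(v)
    k <- ceiling(length(v) / 2)
    sprintf("(%s:1,%s:1)", build(v[seq_len(k)]), build(v[-seq_len(k)]))
  }
  paste0(build(labels), ";")
}

.caterpillar_newick <- function(labels) {
  s <- sprintf("(%s:1,%s:1)", labels[1L], labels[2L])
  for (k in seq_along(labels)[-(1:2)]) s <- sprintf("(%s:1,%s:1)", s, labels[k])
  paste0(s, ";")
}

#' Species tree for a synthetic configuration
#'
#' Balanced and caterpillar shapes are deterministic with unit branch
#' lengths; the random shape draws a topology and uniform branch lengths
#' under the configuration seed (call after `set.seed`, as
#' [simulate_genotypes()] does).
#'
#' @param cfg A [synth_config()].
#' @return An `ape::phylo` tree with tip labels `sp01..`.
#' @keywords internal
simulate_tree <- function(cfg) {
  labels <- sprintf("sp%02d", seq_len(cfg$n_taxa))
  switch(cfg$tree_shape,
    balanced = ape::read.tree(text = .balanced_newick(labels)),
    caterpillar = ape::read.tree(text = .caterpillar_newick(labels)),
    random = {
      tr <- ape::rtree(cfg$n_taxa, tip.label = labels,
                       br = stats::runif)
      tr$edge.length <- tr$edge.length * 2
      tr
    })
}

.barrier_stages <- c("pollen_pistil", "fruit_set", "fruit_weight",
                     "seed_viability", "germination")

.build_truth <- function(cfg, tree) {
  taxa <- tree$tip.label
  dist <- cfg$branch_scale * ape::cophenetic.phylo(tree)[taxa, taxa]
  dmax <- max(dist)
  barriers <- list()
  for (st in .barrier_stages) {
    b <- switch(cfg$barrier_map$kind,
      linear = pmin(cfg$barrier_map$slopes[[st]] * dist / dmax, 1),
      constant = matrix(cfg$barrier_map$level, nrow(dist), ncol(dist),
                        dimnames = dimnames(dist)))
    diag(b) <- 0
    if (cfg$asymmetry > 0) {
      for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
        if (j <= i) next
        delta <- stats::runif(1, -cfg$asymmetry, cfg$asymmetry)
        b[i, j] <- min(1, max(0, b[i, j] + delta))
        b[j, i] <- min(1, max(0, b[j, i] - delta))
      }
    }
    barriers[[st]] <- b
  }
  selfing <- data.frame(
    taxon = taxa,
    fruit_set = stats::runif(length(taxa), 0.5, 0.9),
    fruit_weight = stats::runif(length(taxa), 20, 120),
    seed_count = stats::runif(length(taxa), 80, 200),
    seed_weight = stats::runif(length(taxa), 20, 60),
    germination = stats::runif(length(taxa), 0.7, 0.95),
    stringsAsFactors = FALSE
  )
  structure(list(tree = tree, taxa = taxa, distances = dist,
                 barriers = barriers, selfing = selfing,
                 branch_scale = cfg$branch_scale),
            class = "synth_truth")
}

#' Simulate a GBS-like genotype matrix along a species tree
#'
#' Ancestral biallelic loci acquire substitutions along each branch as Poisson
#' events (rate `branch_scale` x length; a locus's fixed allele flips when the
#' event count is odd). Taxa are rendered as near-homozygous individuals with
#' residual heterozygosity `stage_noise$residual_het`; per-genotype depths are
#' negative binomial (`depth_mean`, `depth_size`). Optional F1 hybrid samples
#' carry one parental fixed allele from each side per locus (heterozygous
#' exactly at the parents' fixed differences). Positions are drawn with a
#' mean spacing of ~40 bp so the thinning filter is exercised.
#'
#' @param cfg A [synth_config()].
#' @return A list: `gm` (a `genotype_matrix`) and `truth` (a `synth_truth`
#'   holding the tree, true scaled distances, per-stage directed barrier
#'   matrices and per-taxon selfing baselines).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg)
  truth <- .build_truth(cfg, tree)
  taxa <- tree$tip.label
  n_tip <- length(taxa)
  L <- cfg$n_loci

  p_flip <- (1 - exp(-2 * cfg$branch_scale * tree$edge.length)) / 2
  if (any(cfg$branch_scale * tree$edge.length > 2))
    warning("substitution rate high enough to saturate loci")
  states <- matrix(0L, L, n_tip + tree$Nnode)
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  p_edge <- p_flip[rev(ape::postorder(tree))]
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1L]; child <- edges[k, 2L]
    flip <- stats::rbinom(L, 1L, p_edge[k])
    states[, child] <- (states[, parent] + flip) %% 2L
  }
  fixed <- states[, seq_len(n_tip), drop = FALSE]
  colnames(fixed) <- taxa

  call_codes <- c("hom_ref", "hom_alt")
  calls <- matrix(call_codes[fixed + 1L], L, n_tip,
                  dimnames = list(NULL, taxa))
  het_mask <- matrix(stats::runif(L * n_tip) <
                       cfg$stage_noise$residual_het, L, n_tip)
  calls[het_mask] <- "het"

  ploidy <- stats::setNames(rep("diploid", n_tip), taxa)
  if (!is.null(cfg$hybrids)) {
    for (hy in cfg$hybrids) {
      nm <- paste0(hy[1L], "x", hy[2L])
      a1 <- fixed[, hy[1L]]; a2 <- fixed[, hy[2L]]
      hcall <- ifelse(a1 != a2, "het", call_codes[a1 + 1L])
      calls <- cbind(calls, hcall)
      colnames(calls)[ncol(calls)] <- nm
      ploidy[nm] <- "diploid"
    }
  }
  depth <- matrix(stats::rnbinom(length(calls),
                                 size = cfg$stage_noise$depth_size,
                                 mu = cfg$stage_noise$depth_mean),
                  L, ncol(calls), dimnames = dimnames(calls))
  pos <- cumsum(1L + stats::rgeom(L, 1 / 40))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  gm <- genotype_matrix(calls, depth, chrom = rep("chr1", L), pos = pos,
                        ref = ref, alt = alt, ploidy = ploidy,
                        log = list(simulated = TRUE))
  list(gm = gm, truth = truth)
}

#' Simulate a full diallel of cross records under known barriers
#'
#' For every directed pair (including selfings, barrier 0) the generator
#' emulates the two experiments of the target design: `n_pollentube_per_pair`
#' pistils scored for pollen-tube progression, and `n_crosses_per_pair`
#' pollinations followed to fruit/seed. Pollen scores are
#' `Binomial(4, 1 - b_pollen)` (mean linear in the barrier; selfings always
#' score 4). Fruit set is `Bernoulli(s_self * (1 - b_fruit))`, forced to zero
#' under complete pollen arrest (`b_pollen = 1`); fruit weight is gamma with
#' mean `w_self * (1 - b_fweight)`, seeds per fruit Poisson with mean
#' `lambda_self * (1 - b_seed)`, and germination binomial with rate
#' `g_self * (1 - b_germ)`, so the expected stage-wise RI equals the stage
#' barrier by construction.
#'
#' @param cfg A [synth_config()].
#' @param truth A `synth_truth` from [simulate_genotypes()].
#' @return A `cross_records` data frame covering the diallel.
#' @export
simulate_diallel <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  set.seed(cfg$seed + 1L)
  taxa <- truth$taxa
  base <- truth$selfing
  sn <- cfg$stage_noise
  out <- vector("list", length(taxa)^2)
  k <- 0L
  for (f in taxa) for (m in taxa) {
    self <- f == m
    b <- vapply(.barrier_stages, function(st)
      if (self) 0 else truth$barriers[[st]][f, m], 0)
    bl <- base[base$taxon == f, ]
    n_pt <- cfg$n_pollentube_per_pair
    n_cr <- cfg$n_crosses_per_pair

    score <- stats::rbinom(n_pt, 4L, 1 - b[["pollen_pistil"]])
    pt <- data.frame(
      female_taxon = f, male_taxon = m,
      replicate_id = paste0("pt", seq_len(n_pt)),
      pollen_score = score, ovules_fertilized = score == 4L,
      fruit_set = NA, fruit_weight = NA_real_, seed_count = NA_integer_,
      seed_weight = NA_real_, seeds_sown = 0L, seeds_germinated = 0L,
      hours_pp = 24L, stringsAsFactors = FALSE)

    gate <- if (b[["pollen_pistil"]] >= 1) 0 else 1
    p_fruit <- bl$fruit_set * (1 - b[["fruit_set"]]) * gate
    fruit <- stats::rbinom(n_cr, 1L, p_fruit) == 1L
    mu_w <- bl$fruit_weight * (1 - b[["fruit_weight"]])
    mu_s <- bl$seed_count * (1 - b[["seed_viability"]])
    mu_sw <- bl$seed_weight * (1 - b[["seed_viability"]])
    g_rate <- bl$germination * (1 - b[["germination"]])
    nf <- sum(fruit)
    weight <- rep(NA_real_, n_cr)
    seeds <- rep(NA_integer_, n_cr)
    sweight <- rep(NA_real_, n_cr)
    sown <- rep(0L, n_cr); germ <- rep(0L, n_cr)
    if (nf) {
      weight[fruit] <- stats::rgamma(nf, shape = sn$fruit_weight_shape,
                                     rate = sn$fruit_weight_shape /
                                       max(mu_w, 1e-9))
      seeds[fruit] <- stats::rpois(nf, mu_s)
      sweight[fruit] <- stats::rgamma(nf, shape = sn$seed_weight_shape,
                                      rate = sn$seed_weight_shape /
                                        max(mu_sw, 1e-9))
      sown[fruit] <- seeds[fruit]
      germ[fruit] <- stats::rbinom(nf, sown[fruit], g_rate)
    }
    fr <- data.frame(
      female_taxon = f, male_taxon = m,
      replicate_id = paste0("cr", seq_len(n_cr)),
      pollen_score = NA_integer_, ovules_fertilized = NA,
      fruit_set = fruit, fruit_weight = weight, seed_count = seeds,
      seed_weight = sweight, seeds_sown = sown, seeds_germinated = germ,
      hours_pp = 24L, stringsAsFactors = FALSE)
    k <- k + 1L
    out[[k]] <- rbind(pt, fr)
  }
  rec <- do.call(rbind, out[seq_len(k)])
  rownames(rec) <- NULL
  class(rec) <- unique(c("cross_records", class(rec)))
  rec
}

#' Hybrid-fertility ground truth for a simulated diallel
#'
#' Selfings are fertile; interspecific crosses are male sterile (the outcome
#' the generator emulates for viable hybrids).
#'
#' @param truth A `synth_truth`.
#' @return Data frame usable as the `fertility` argument of
#'   [aggregate_crosses()].
#' @export
synth_fertility <- function(truth) {
  taxa <- truth$taxa
  grid <- expand.grid(female_taxon = taxa, male_taxon = taxa,
                      stringsAsFactors = FALSE)
  grid$hybrid_fertility <- ifelse(grid$female_taxon == grid$male_taxon,
                                  "fertile", "male_sterile")
  grid
}

#' Emit a complete synthetic dataset directory
#'
#' Writes `crosses.tsv` (cross-record schema), `genotypes.vcf`,
#' `fertility.tsv` and `truth.json` (tree as Newick, distances, barriers,
#' baselines) under `dir`.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(cfg)
  rec <- simulate_diallel(cfg, sim$truth)
  paths <- list(crosses = file.path(dir, "crosses.tsv"),
                vcf = file.path(dir, "genotypes.vcf"),
                fertility = file.path(dir, "fertility.tsv"),
                truth = file.path(dir, "truth.json"))
  utils::write.table(rec, paths$crosses, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  write_vcf(sim$gm, paths$vcf)
  utils::write.table(synth_fertility(sim$truth), paths$fertility, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json <- list(
    tree = ape::write.tree(sim$truth$tree),
    taxa = sim$truth$taxa,
    distances = sim$truth$distances,
    barriers = sim$truth$barriers,
    selfing = sim$truth$selfing,
    branch_scale = sim$truth$branch_scale,
    seed = cfg$seed)
  jsonlite::write_json(truth_json, paths$truth, digits = NA, pretty = TRUE)
  invisible(paths)
}
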