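# Genotype matrices from VCF, the site-filtering cascade, per-sample
# heterozygosity, Nei's (1972) standard genetic distance, and neighbor-joining
# with bootstrap support.

#' Construct a genotype matrix object
#'
#' Internal constructor shared by [read_genotypes()] and the simulator. Loci
#' are sorted by chromosome and position.
#'
#' @param calls Character matrix (loci x samples) of `hom_ref`, `het`,
#'   `hom_alt`, `missing`.
#' @param depth Integer matrix of per-genotype depths (same shape), or `NULL`.
#' @param chrom,pos,ref,alt Per-locus chromosome, 1-based position, ref and
#'   alt alleles.
#' @param ploidy Named character vector per sample, `"diploid"` or
#'   `"pseudodiploid"`.
#' @param log Named list of per-step counts accumulated so far.
#' @return A list of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, depth = NULL, chrom, pos, ref = NULL,
                            alt = NULL, ploidy = NULL, log = list()) {
  stopifnot(is.matrix(calls), length(chrom) == nrow(calls),
            length(pos) == nrow(calls))
  if (!all(calls %in% c("hom_ref", "het", "hom_alt", "missing")))
    stop("invalid genotype call codes")
  samples <- colnames(calls)
  if (is.null(samples)) stop("calls must have sample column names")
  if (is.null(ploidy)) ploidy <- stats::setNames(rep("diploid",
                                                     length(samples)), samples)
  o <- order(chrom, pos)
  gm <- list(calls = calls[o, , drop = FALSE],
             depth = if (is.null(depth)) NULL else depth[o, , drop = FALSE],
             chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
             ref = if (is.null(ref)) rep("A", length(o)) else
               as.character(ref)[o],
             alt = if (is.null(alt)) rep("T", length(o)) else
               as.character(alt)[o],
             samples = samples, ploidy = ploidy, log = log)
  class(gm) <- "genotype_matrix"
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples\n",
              nrow(x$calls), length(x$samples)))
  if (length(x$log)) {
    cat("log:\n")
    for (nm in names(x$log)) cat(sprintf("  %s: %s\n", nm, x$log[[nm]]))
  }
  invisible(x)
}

.gt_to_call <- function(gt) {
  # GT strings of any ploidy; any mixture of ref/alt alleles -> het
  # (pseudodiploid scoring collapses all heterozygous classes to AB).
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == "." | a == "")) return("missing")
    u <- unique(a)
    if (length(u) > 1L) "het" else if (u == "0") "hom_ref" else "hom_alt"
  }, character(1L))
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Wraps `VariantAnnotation::readVcf`. Multiallelic and non-SNP records are
#' skipped (counts logged). Genotypes are read from `GT` (any ploidy:
#' tetraploid pseudodiploid samples score any heterozygous class as `het`);
#' per-genotype depth comes from `DP`, or from summing `AD`, and is required
#' unless `require_depth = FALSE`.
#'
#' @param path Path to a plain or bgzipped VCF.
#' @param samples Optional character vector restricting the sample set.
#' @param ploidy Optional named character vector (`"diploid"` /
#'   `"pseudodiploid"`) per sample.
#' @param require_depth Error if no depth field is available (default TRUE).
#' @return A `genotype_matrix` with skip counts in `$log`.
#' @export
read_genotypes <- function(path, samples = NULL, ploidy = NULL,
                           require_depth = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!is.null(samples))
    vcf <- vcf[, intersect(samples, colnames(vcf))]
  n_in <- nrow(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alts <- rep(NA_character_, n_in)
  alts[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(refs) == 1L & !is.na(alts) & nchar(alts) == 1L &
    refs %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T")
  log <- list(records_in = n_in,
              skipped_multiallelic = sum(n_alt != 1L),
              skipped_non_snp = sum(n_alt == 1L) -
                sum(keep[n_alt == 1L]))
  vcf <- vcf[keep, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  calls <- matrix(.gt_to_call(as.vector(gt)), nrow = nrow(gt),
                  dimnames = dimnames(gt))
  # a depth field only counts if it actually carries values (headers may
  # declare FORMAT keys that no record uses)
  gfields <- VariantAnnotation::geno(vcf)
  depth <- NULL
  if ("DP" %in% names(gfields) && any(!is.na(gfields$DP))) {
    depth <- gfields$DP
    storage.mode(depth) <- "integer"
  } else if ("AD" %in% names(gfields) &&
             !all(vapply(gfields$AD, function(a) all(is.na(a)), TRUE))) {
    depth <- matrix(vapply(gfields$AD, function(a)
      if (all(is.na(a))) NA_integer_ else as.integer(sum(a, na.rm = TRUE)),
      integer(1L)), nrow = nrow(calls), dimnames = dimnames(calls))
  } else if (require_depth) {
    stop("VCF has neither DP nor AD depth values; ",
         "pass require_depth = FALSE to proceed")
  }
  if (!is.null(depth)) depth[is.na(depth)] <- 0L
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!is.null(ploidy)) {
    ok <- colnames(calls) %in% names(ploidy)
    pl <- stats::setNames(rep("diploid", ncol(calls)), colnames(calls))
    pl[colnames(calls)[ok]] <- ploidy[colnames(calls)[ok]]
  } else pl <- NULL
  message(sprintf("read %d/%d SNP records (%d multiallelic, %d non-SNP skipped)",
                  nrow(calls), n_in, log$skipped_multiallelic,
                  log$skipped_non_snp))
  genotype_matrix(calls, depth,
                  chrom = as.character(GenomeInfoDb::seqnames(rr)),
                  pos = BiocGenerics::start(rr),
                  ref = refs[keep], alt = alts[keep], ploidy = pl, log = log)
}

#' Write a genotype matrix as a diploid-coded VCF
#'
#' Emits `GT:DP` genotypes (`het` as `0/1`; pseudodiploid samples are written
#' with the collapsed AB coding). Plain text only.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  dp <- if (is.null(gm$depth))
    matrix(".", nrow(gm$calls), ncol(gm$calls)) else gm$depth
  body <- vapply(seq_len(nrow(gm$calls)), function(i) {
    g <- paste(gt_map[gm$calls[i, ]], dp[i, ], sep = ":")
    paste(c(gm$chrom[i], gm$pos[i], ".", gm$ref[i], gm$alt[i], ".", "PASS",
            ".", "GT:DP", g), collapse = "\t")
  }, character(1L))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=crossiso",
           paste0("##contig=<ID=", unique(gm$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site-filtering cascade
#'
#' Applies, in order: (1) genotypes with depth below `min_depth` are set
#' missing; (2) sites with any missing call are dropped; (3) monomorphic
#' sites (a single allele present across all samples) are dropped; (4) sites
#' whose heterozygous-sample fraction exceeds `max_het` are dropped (mapping
#' bias guard); (5) per chromosome, sites are thinned greedily left-to-right,
#' keeping a site only if it lies at least `thin_bp` from the last kept site.
#' Per-step removal counts are appended to `$log`.
#'
#' @param gm A `genotype_matrix`.
#' @param min_depth Minimum per-genotype depth (default 10).
#' @param max_het Maximum per-site heterozygous fraction (default 0.80).
#' @param thin_bp Minimum spacing in bp between kept sites (default 20).
#' @return The filtered `genotype_matrix` (possibly with zero loci, with a
#'   warning).
#' @export
filter_sites <- function(gm, min_depth = 10, max_het = 0.80, thin_bp = 20) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  log <- gm$log

  low <- 0L
  if (!is.null(gm$depth)) {
    mask <- gm$depth < min_depth & calls != "missing"
    low <- sum(mask)
    calls[mask] <- "missing"
  }
  log$genotypes_masked_low_depth <- low

  has_missing <- rowSums(calls == "missing") > 0L
  log$sites_removed_missing <- sum(has_missing)
  keep <- !has_missing

  mono <- keep & apply(calls, 1L, function(cc) {
    cc <- cc[cc != "missing"]
    all(cc == "hom_ref") || all(cc == "hom_alt")
  })
  log$sites_removed_monomorphic <- sum(mono)
  keep <- keep & !mono

  het_frac <- rowMeans(calls == "het")
  high_het <- keep & het_frac > max_het
  log$sites_removed_het <- sum(high_het)
  keep <- keep & !high_het

  idx <- which(keep)
  thinned <- logical(length(idx))
  if (length(idx)) {
    for (ch in unique(gm$chrom[idx])) {
      on_ch <- idx[gm$chrom[idx] == ch]
      last_kept <- -Inf
      for (k in seq_along(on_ch)) {
        p <- gm$pos[on_ch[k]]
        if (p - last_kept >= thin_bp) last_kept <- p
        else thinned[match(on_ch[k], idx)] <- TRUE
      }
    }
  }
  log$sites_removed_thinning <- sum(thinned)
  keep_idx <- idx[!thinned]
  log$sites_out <- length(keep_idx)
  if (!length(keep_idx)) warning("all sites removed by the filter cascade")

  genotype_matrix(calls[keep_idx, , drop = FALSE],
                  if (is.null(gm$depth)) NULL else
                    gm$depth[keep_idx, , drop = FALSE],
                  gm$chrom[keep_idx], gm$pos[keep_idx], gm$ref[keep_idx],
                  gm$alt[keep_idx], gm$ploidy, log)
}

#' Per-sample heterozygosity
#'
#' Fraction of heterozygous calls among non-missing calls per sample.
#'
#' @param gm A `genotype_matrix`.
#' @return Named numeric vector in `[0, 1]`; `NA` (with warning) for samples
#'   with no non-missing call.
#' @export
sample_heterozygosity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$calls) >= 1L)
  called <- colSums(gm$calls != "missing")
  het <- colSums(gm$calls == "het")
  out <- ifelse(called > 0L, het / called, NA_real_)
  names(out) <- gm$samples
  if (anyNA(out))
    warning("sample(s) with zero non-missing calls: ",
            paste(gm$samples[is.na(out)], collapse = ", "))
  out
}

#' Nei's (1972) standard genetic distance between samples
#'
#' Each sample is treated as a population with per-locus allele frequencies in
#' \{0, 1/2, 1\} (hom ref, het, hom alt). Per locus `j_x = sum_a x_a^2`,
#' `j_y = sum_a y_a^2`, `j_xy = sum_a x_a y_a`; `J` terms are arithmetic means
#' over loci, the normalized identity is `I = J_xy / sqrt(J_x J_y)` and
#' `D = -ln I`. Loci missing in either member of a pair are excluded pairwise.
#'
#' @param gm A `genotype_matrix` with at least 2 samples and 1 locus.
#' @param max_distance Sentinel replacing an infinite distance when `I = 0`
#'   (default `-log(.Machine$double.eps)`, about 36.04), with a warning.
#' @return Symmetric non-negative matrix with exact zero diagonal.
#' @export
nei_distance <- function(gm, max_distance = -log(.Machine$double.eps)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$samples)
  if (n < 2L || nrow(gm$calls) < 1L)
    stop("need >= 2 samples and >= 1 locus")
  # alt-allele frequency per sample x locus
  p <- matrix(NA_real_, nrow(gm$calls), n, dimnames = list(NULL, gm$samples))
  p[gm$calls == "hom_ref"] <- 0
  p[gm$calls == "het"] <- 0.5
  p[gm$calls == "hom_alt"] <- 1
  D <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  warned_clamp <- FALSE; warned_inf <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(p[, i]) & !is.na(p[, j])
    if (!any(ok)) { D[i, j] <- D[j, i] <- NA_real_; next }
    xi <- p[ok, i]; xj <- p[ok, j]
    jx <- mean(xi^2 + (1 - xi)^2)
    jy <- mean(xj^2 + (1 - xj)^2)
    jxy <- mean(xi * xj + (1 - xi) * (1 - xj))
    I <- jxy / sqrt(jx * jy)
    if (I > 1) {
      if (I > 1 + 1e-9 && !warned_clamp) {
        warning("genetic identity > 1 clamped to 1"); warned_clamp <- TRUE
      }
      I <- 1
    }
    d <- if (I <= 0) {
      if (!warned_inf) {
        warning("no shared alleles for at least one pair; ",
                "infinite distance replaced by sentinel ",
                format(max_distance)); warned_inf <- TRUE
      }
      max_distance
    } else min(-log(I), max_distance)
    D[i, j] <- D[j, i] <- d
  }
  D
}

# ---- neighbor joining ----------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` (row sums `r`). Ties (within 1e-12 of
#' the minimum) are broken toward the lexicographically smallest sorted label
#' pair, so the result is deterministic and invariant to input order.
#' Negative branch lengths are set to zero and the difference transferred to
#' the sibling branch.
#'
#' @param dm Symmetric numeric distance matrix with labels (n >= 3), no NaN.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix must be labeled")
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite values")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(dm)
  # newick fragment and original leaf label for tie-breaking, per active node
  frag <- labels
  tie_key <- labels
  d <- dm
  active <- seq_len(n)
  fmt <- function(x) formatC(x, digits = 12, format = "g")

  while (length(active) > 3L) {
    m <- length(active)
    dd <- d[active, active]
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      ks <- sort(c(tie_key[active[ij[1L]]], tie_key[active[ij[2L]]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    dij <- d[i, j]
    bi <- dij / 2 + (r[pick[1L]] - r[pick[2L]]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    # distances from the new node u to remaining nodes
    rest <- setdiff(active, c(i, j))
    du <- (d[i, rest] + d[j, rest] - dij) / 2
    d <- rbind(cbind(d, 0), 0)
    u <- nrow(d)
    d[u, rest] <- du; d[rest, u] <- du
    frag <- c(frag, new_frag)
    tie_key <- c(tie_key, min(tie_key[i], tie_key[j]))
    active <- c(rest, u)
  }
  a <- active[order(tie_key[active])]
  d12 <- d[a[1L], a[2L]]; d13 <- d[a[1L], a[3L]]; d23 <- d[a[2L], a[3L]]
  b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  b <- pmax(b, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a[1L]], fmt(b[1L]),
                 frag[a[2L]], fmt(b[2L]), frag[a[3L]], fmt(b[3L]))
  ape::read.tree(text = nwk)
}

# canonical string encoding of every non-trivial bipartition of a tree:
# for each internal edge take the tip set on the far side from the first
# label (alphabetically) so each split has a unique representation.
.bipartitions <- function(tree, all_labels) {
  anchor <- sort(all_labels)[1L]
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  out <- character(0L)
  for (cl in pp) {
    side <- sort(tips[cl])
    if (anchor %in% side) side <- sort(setdiff(all_labels, side))
    if (length(side) < 2L || length(side) > length(all_labels) - 2L) next
    out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Resamples loci with replacement, recomputes [nei_distance()] +
#' [nj_tree()] per replicate, and scores each internal bipartition of the
#' full-data tree by the percentage of replicates containing it. Replicates
#' with a degenerate (all-zero or non-finite) distance matrix are skipped and
#' the denominator adjusted.
#'
#' @param gm A filtered `genotype_matrix`.
#' @param n_reps Number of bootstrap replicates (default 1000; 0 = no
#'   bootstrap, supports all `NA`).
#' @param seed Integer seed (required when `n_reps > 0`).
#' @return A list: `tree` (full-data `phylo` with supports as internal node
#'   labels, `NA` on trivial splits), `supports` (named by bipartition),
#'   `n_effective`, `n_skipped`.
#' @export
bootstrap_tree <- function(gm, n_reps = 1000, seed = NULL) {
  dm <- nei_distance(gm)
  full <- nj_tree(dm)
  labels <- full$tip.label
  node_support <- rep(NA_real_, full$Nnode)
  if (n_reps == 0) {
    full$node.label <- rep("", full$Nnode)
    return(list(tree = full, supports = numeric(0L),
                n_effective = 0L, n_skipped = 0L))
  }
  if (is.null(seed)) stop("a seed is required for the bootstrap")
  set.seed(as.integer(seed))
  L <- nrow(gm$calls)
  target <- .bipartitions(full, labels)
  counts <- stats::setNames(numeric(length(target)), target)
  skipped <- 0L
  for (rep_i in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    gmb <- gm
    gmb$calls <- gm$calls[idx, , drop = FALSE]
    gmb$depth <- NULL
    gmb$chrom <- gm$chrom[idx]; gmb$pos <- gm$pos[idx]
    gmb$ref <- gm$ref[idx]; gmb$alt <- gm$alt[idx]
    db <- suppressWarnings(nei_distance(gmb))
    if (any(!is.finite(db)) || all(db[upper.tri(db)] == 0)) {
      skipped <- skipped + 1L
      next
    }
    bp <- .bipartitions(nj_tree(db), labels)
    hit <- target %in% bp
    counts[hit] <- counts[hit] + 1
  }
  n_eff <- n_reps - skipped
  supports <- if (n_eff > 0) 100 * counts / n_eff else counts * NA_real_
  # map supports back onto the full tree's internal nodes
  pp <- ape::prop.part(full)
  tips <- attr(pp, "labels")
  anchor <- sort(labels)[1L]
  lab <- rep("", full$Nnode)  # trivial splits stay unlabeled in Newick output
  for (k in seq_along(pp)) {
    side <- sort(tips[pp[[k]]])
    if (anchor %in% side) side <- sort(setdiff(labels, side))
    key <- paste(side, collapse = "\r")
    if (key %in% names(supports)) lab[k] <- format(round(supports[[key]], 1))
  }
  full$node.label <- lab
  list(tree = full, supports = supports, n_effective = n_eff,
       n_skipped = skipped)
}
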