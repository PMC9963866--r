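# popgen: VCF reading, the filter cascade, heterozygosity, Nei's distance,
# neighbor joining, and bootstrap supports.

test_that("read_genotypes keeps biallelic SNPs and logs skipped records", {
  body <- c(
    vcf_row("chr1", 100, "A", "G", c("0/0:20", "0/1:20")),
    vcf_row("chr1", 200, "A", "AT", c("0/0:20", "1/1:20")),   # indel
    vcf_row("chr1", 300, "C", "T", c("1/1:20", "0/1:20")),
    vcf_row("chr1", 400, "G", "A,T", c("0/1:20", "0/2:20")),  # multiallelic
    vcf_row("chr1", 500, "T", "C", c("./.:0", "0/0:20")))
  path <- write_vcf_text(body, c("S1", "S2"))
  gm <- suppressMessages(read_genotypes(path))
  expect_identical(nrow(gm$calls), 3L)  # indel and multiallelic skipped
  expect_identical(gm$log$skipped_multiallelic, 1L)
  expect_true(gm$log$skipped_non_snp >= 1)
  expect_identical(unname(gm$calls[1, ]), c("hom_ref", "het"))
  expect_identical(unname(gm$calls[3, ]), c("missing", "hom_ref"))
})

test_that("depth comes from DP or summed AD; absence is an error unless allowed", {
  body_ad <- vcf_row("chr1", 100, "A", "G", c("0/1:7,6", "0/0:9,0"),
                     format = "GT:AD")
  path <- write_vcf_text(body_ad, c("S1", "S2"))
  gm <- suppressMessages(read_genotypes(path))
  expect_identical(unname(gm$depth[1, ]), c(13L, 9L))
  expect_identical(unname(gm$calls[1, 1]), "het")

  body_gt <- vcf_row("chr1", 100, "A", "G", c("0/1", "0/0"), format = "GT")
  path2 <- write_vcf_text(body_gt, c("S1", "S2"))
  expect_error(suppressMessages(read_genotypes(path2)), "neither DP nor AD")
  gm2 <- suppressMessages(read_genotypes(path2, require_depth = FALSE))
  expect_null(gm2$depth)
})

test_that("tetraploid GT under pseudodiploid scoring collapses to het", {
  body <- c(vcf_row("chr1", 100, "A", "G", c("0/0/0/1:30", "0/0:30")),
            vcf_row("chr1", 200, "C", "T", c("1/1/1/1:30", "0/1:30")))
  path <- write_vcf_text(body, c("TETRA", "DIP"))
  gm <- suppressMessages(read_genotypes(path,
    ploidy = c(TETRA = "pseudodiploid", DIP = "diploid")))
  expect_identical(unname(gm$calls[, "TETRA"]), c("het", "hom_alt"))
  expect_identical(unname(gm$ploidy[["TETRA"]]), "pseudodiploid")
})

test_that("filter cascade applies depth, missingness, monomorphism, het and thinning in order", {
  samples <- paste0("S", 1:10)
  het9 <- c(rep("0/1:30", 9), "0/0:30")             # het fraction 0.9
  poly <- c(rep("0/0:30", 5), rep("1/1:30", 5))
  body <- c(
    vcf_row("chr1", 100, "A", "G", poly),
    vcf_row("chr1", 110, "A", "G", poly),           # thinned (110 - 100 < 20)
    vcf_row("chr1", 130, "A", "G", poly),
    vcf_row("chr1", 200, "C", "T", c("0/0:9", poly[-1])),  # one depth-9 call
    vcf_row("chr1", 300, "G", "A", rep("0/0:30", 10)),     # monomorphic
    vcf_row("chr1", 400, "T", "C", het9),                  # het 0.9 > 0.8
    vcf_row("chr2", 5, "A", "C", poly))
  path <- write_vcf_text(body, samples)
  gm <- suppressMessages(read_genotypes(path))
  gmf <- filter_sites(gm, min_depth = 10, max_het = 0.80, thin_bp = 20)
  expect_identical(gmf$pos[gmf$chrom == "chr1"], c(100L, 130L))
  expect_identical(gmf$pos[gmf$chrom == "chr2"], 5L)
  expect_identical(gmf$log$genotypes_masked_low_depth, 1L)
  expect_identical(gmf$log$sites_removed_missing, 1L)   # the depth-9 site
  expect_identical(gmf$log$sites_removed_monomorphic, 1L)
  expect_identical(gmf$log$sites_removed_het, 1L)
  expect_identical(gmf$log$sites_removed_thinning, 1L)
  expect_identical(gmf$log$sites_out, 3L)

  # idempotence and sample-order invariance
  gmf2 <- filter_sites(gmf, 10, 0.80, 20)
  expect_identical(gmf2$calls, gmf$calls)
  gm_rev <- gm
  gm_rev$calls <- gm$calls[, rev(samples)]
  gm_rev$depth <- gm$depth[, rev(samples)]
  gm_rev$samples <- rev(samples)
  gmf_rev <- filter_sites(gm_rev, 10, 0.80, 20)
  expect_identical(gmf_rev$pos, gmf$pos)
})

test_that("per-sample heterozygosity counts het over non-missing calls", {
  calls <- matrix("hom_ref", 250, 2, dimnames = list(NULL, c("X", "Y")))
  expect_equal(unname(sample_heterozygosity(gm_from_calls(calls))), c(0, 0))
  calls[1:25, 2] <- "het"
  expect_equal(sample_heterozygosity(gm_from_calls(calls))[["Y"]], 0.1)
  calls[, 1] <- "missing"
  expect_warning(h <- sample_heterozygosity(gm_from_calls(calls)),
                 "zero non-missing")
  expect_true(is.na(h[["X"]]))

  # F1 of fully homozygous parents differing at k of L loci: het = k/L
  L <- 200; k <- 37
  calls <- matrix("hom_ref", L, 3, dimnames = list(NULL, c("P1", "P2", "F1")))
  calls[1:k, 2] <- "hom_alt"
  calls[1:k, 3] <- "het"
  expect_equal(sample_heterozygosity(gm_from_calls(calls))[["F1"]], k / L)
})

test_that("Nei distance matches hand-computed cases", {
  # identical samples -> I = 1, D = 0
  calls <- matrix(c("hom_ref", "het", "hom_alt"), 3, 2,
                  dimnames = list(NULL, c("X", "Y")))
  expect_equal(nei_distance(gm_from_calls(calls))["X", "Y"], 0)

  # 2 loci: locus1 fixed ref vs fixed alt, locus2 both fixed ref -> D = ln 2
  calls <- matrix(c("hom_ref", "hom_ref",
                    "hom_alt", "hom_ref"), 2, 2,
                  dimnames = list(NULL, c("X", "Y")))
  expect_equal(nei_distance(gm_from_calls(calls))["X", "Y"], log(2),
               tolerance = 1e-10)

  # 1 locus: X het, Y hom_ref -> I = 0.5/sqrt(0.5), D = -log(1/sqrt(2))
  calls <- matrix(c("het", "hom_ref"), 1, 2,
                  dimnames = list(NULL, c("X", "Y")))
  expect_equal(nei_distance(gm_from_calls(calls))["X", "Y"],
               -log(0.5 / sqrt(0.5)), tolerance = 1e-10)
  expect_equal(-log(0.5 / sqrt(0.5)), 0.3466, tolerance = 1e-4)

  # duplicated sample has distance 0; D is never negative; diagonal exact 0
  set.seed(2)
  calls <- matrix(sample(c("hom_ref", "het", "hom_alt"), 300, replace = TRUE),
                  100, 3, dimnames = list(NULL, c("A", "B", "A2")))
  calls[, "A2"] <- calls[, "A"]
  D <- nei_distance(gm_from_calls(calls))
  expect_equal(D["A", "A2"], 0)
  expect_true(all(D >= 0))
  expect_true(all(diag(D) == 0))

  # disjoint alleles at every locus -> sentinel with warning
  calls <- matrix(c("hom_ref", "hom_alt"), 1, 2,
                  dimnames = list(NULL, c("X", "Y")))
  expect_warning(Ds <- nei_distance(gm_from_calls(calls)), "sentinel")
  expect_equal(Ds["X", "Y"], -log(.Machine$double.eps))
})

test_that("missing calls are excluded pairwise in Nei distance", {
  calls <- matrix(c("hom_ref", "hom_ref", "missing",
                    "hom_alt", "hom_ref", "hom_alt"), 3, 2,
                  dimnames = list(NULL, c("X", "Y")))
  # locus 3 dropped for this pair: equivalent to the ln 2 two-locus case
  expect_equal(nei_distance(gm_from_calls(calls))["X", "Y"], log(2),
               tolerance = 1e-12)
})

test_that("3-taxon NJ solves the closed-form star", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
})

test_that("NJ exactly recovers additive matrices (4-8 taxa) and is order invariant", {
  for (n in 4:8) {
    am <- additive_matrix(n, seed = 100 + n)
    tr <- nj_tree(am$dm)
    expect_same_topology(tr, am$tree)
    # path lengths reproduced to 1e-10
    pl <- ape::cophenetic.phylo(tr)[rownames(am$dm), colnames(am$dm)]
    expect_equal(pl, am$dm, tolerance = 1e-10)
  }
  am <- additive_matrix(6, seed = 77)
  perm <- sample(6)
  tr1 <- nj_tree(am$dm)
  tr2 <- nj_tree(am$dm[perm, perm])
  expect_same_topology(tr1, tr2)
  pl1 <- ape::cophenetic.phylo(tr1)
  pl2 <- ape::cophenetic.phylo(tr2)[rownames(pl1), colnames(pl1)]
  expect_equal(pl1, pl2, tolerance = 1e-12)
})

test_that("NJ agrees with the ape reference on random noisy matrices", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(5:9, 1)
    pts <- matrix(rnorm(n * 4), n)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("s", 1:n), paste0("s", 1:n))
    expect_same_topology(nj_tree(dm), ape::nj(dm))
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  dm <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(dm), "non-finite")
})

test_that("bootstrap supports are high for true clades, reproducible, and locus-order invariant", {
  cfg <- synth_config(n_taxa = 6, n_loci = 400, seed = 21)
  gm <- filter_sites(simulate_genotypes(cfg)$gm)
  bt1 <- bootstrap_tree(gm, n_reps = 100, seed = 5)
  bt2 <- bootstrap_tree(gm, n_reps = 100, seed = 5)
  expect_identical(bt1$supports, bt2$supports)  # determinism under seed
  expect_true(all(bt1$supports >= 95))          # strongly diverged clades

  # locus order invariance: the container canonicalizes loci by position,
  # so rebuilding from shuffled rows yields bit-identical supports
  set.seed(9); idx <- sample(nrow(gm$calls))
  gm_shuf <- genotype_matrix(gm$calls[idx, , drop = FALSE],
                             gm$depth[idx, , drop = FALSE],
                             gm$chrom[idx], gm$pos[idx], gm$ref[idx],
                             gm$alt[idx], gm$ploidy)
  bt3 <- bootstrap_tree(gm_shuf, n_reps = 100, seed = 5)
  expect_identical(bt3$supports, bt1$supports)

  # n_reps = 0 -> supports all missing
  bt0 <- bootstrap_tree(gm, n_reps = 0)
  expect_true(all(bt0$tree$node.label == ""))
  expect_error(bootstrap_tree(gm, n_reps = 10), "seed")
})
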