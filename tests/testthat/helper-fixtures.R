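# Fixtures built in code: cross-record constructors, summary rows, and small
# plain-text VCFs written to tempfiles.

make_records <- function(...) {
  rows <- list(...)
  template <- list(female_taxon = "A", male_taxon = "B", replicate_id = NA,
                   pollen_score = NA, ovules_fertilized = NA, fruit_set = NA,
                   fruit_weight = NA, seed_count = NA, seed_weight = NA,
                   seeds_sown = 0L, seeds_germinated = 0L, hours_pp = 24L)
  df <- do.call(rbind, lapply(rows, function(r) {
    x <- template
    x[names(r)] <- r
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  validate_cross_records(df)
}

# one summary row with sensible defaults, overridable per field
make_summary <- function(female, male, ...) {
  s <- data.frame(female_taxon = female, male_taxon = male,
                  n_pollinations = 10L, mean_pollen_score = 4,
                  modal_pollen_score = 4L, any_fertilized = TRUE,
                  fruit_set_fraction = 0.8, mean_fruit_weight = 100,
                  mean_seed_count = 150, mean_seed_weight = 40,
                  germination_rate = 0.9, hybrid_fertility = "unknown",
                  stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) s[[nm]] <- ov[[nm]]
  s
}

bind_summaries <- function(...) {
  s <- do.call(rbind, list(...))
  class(s) <- unique(c("cross_summaries", class(s)))
  s
}

write_vcf_text <- function(body, samples, path = tempfile(fileext = ".vcf"),
                           format = "GT:DP") {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>", "##contig=<ID=chr2>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, genos, format = "GT:DP") {
  paste(c(chrom, pos, ".", ref, alt, "50", "PASS", ".", format, genos),
        collapse = "\t")
}

# genotype matrix straight from a call matrix (uniform high depth)
gm_from_calls <- function(calls, pos = NULL, chrom = NULL, depth = 30L) {
  L <- nrow(calls)
  genotype_matrix(calls,
                  matrix(depth, L, ncol(calls), dimnames = dimnames(calls)),
                  chrom = if (is.null(chrom)) rep("chr1", L) else chrom,
                  pos = if (is.null(pos)) seq_len(L) * 100L else pos)
}

# additive distance matrix (exact path lengths) from a random tree
additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

expect_same_topology <- function(t1, t2) {
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
}
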