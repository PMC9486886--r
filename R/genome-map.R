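#' Build a two-subgenome genome map
#'
#' The coordinate frame for all simulation and inference: homolog groups
#' named `"1A","1B",...,"<n>A","<n>B"` in interleaved order, mirroring the
#' layout of the allotetraploid-derived *Carassius* genome with its A and B
#' subgenomes. The default configuration of 25 groups per subgenome (50
#' total) corresponds to the 50 homolog groups of the complex; scaled-down
#' maps are used throughout the tests.
#'
#' Coordinates are 0-based, half-open everywhere inside the package; 1-based
#' positions appear only in VCF output.
#'
#' @param n_groups_per_subgenome number of homolog groups in each subgenome.
#' @param group_length length of every group in bp.
#' @return A `genome_map`: a data.frame with columns `group`, `subgenome`,
#'   `length`. The first group is designated the sex-chromosome group
#'   (attribute `sex_group`), where X/Y labels are carried.
#' @examples
#' gm <- build_genome_map(25, 25e6)
#' head(gm)
#' @export
build_genome_map <- function(n_groups_per_subgenome, group_length) {
  if (!is.numeric(n_groups_per_subgenome) || n_groups_per_subgenome < 1 ||
      n_groups_per_subgenome != round(n_groups_per_subgenome))
    stop_config("n_groups_per_subgenome must be a positive integer")
  if (!is.numeric(group_length) || group_length <= 0)
    stop_config("group_length must be positive")
  idx <- seq_len(n_groups_per_subgenome)
  gm <- data.frame(
    group = as.vector(rbind(paste0(idx, "A"), paste0(idx, "B"))),
    subgenome = rep(c("A", "B"), times = n_groups_per_subgenome),
    length = as.numeric(group_length),
    stringsAsFactors = FALSE
  )
  attr(gm, "sex_group") <- gm$group[1L]
  class(gm) <- c("genome_map", "data.frame")
  gm
}

group_length_of <- function(map, group) {
  map$length[match(group, map$group)]
}

#' Sample a lineage-diagnostic SNP map with decoy loci
#'
#' Draws candidate loci along every homolog group and assigns each a truth
#' category. `diagnostic` loci are homozygous within each parental lineage
#' and fixed for different alleles between the gibel carp (Cg) clone and the
#' sexual goldfish (Ca) line -- the loci the effective-SNP filter must keep.
#' Decoy categories each violate one filter criterion:
#' \describe{
#'   \item{decoy_het_cg}{the Cg founder is heterozygous (criterion: parents
#'     homozygous).}
#'   \item{decoy_parents_differ}{the two Ca founders are homozygous for
#'     different alleles (criterion: Ca female and male identical). The Cg
#'     genotype at these loci matches the Ca male allele for half of them
#'     and the Ca female allele for the other half, emulating within-species
#'     polymorphism; these loci are what makes pairwise parent-diagnostic
#'     locus sets non-empty in later generations.}
#'   \item{decoy_shared}{Cg and Ca are homozygous for the same allele
#'     (criterion: lineages differ).}
#' }
#'
#' The full genotype of every founder haplotype is recorded in the
#' `hap_alleles` attribute: a logical matrix (loci x 7 founder haplotypes
#' `cg1,cg2,cg3,caF1,caF2,caM1,caM2`), `TRUE` where the haplotype carries
#' the Cg-side allele.
#'
#' @param map a `genome_map`.
#' @param density expected SNPs per bp (must be in (0, 0.01]).
#' @param decoy_fraction expected proportion of loci that are decoys,
#'   split evenly across the three decoy categories.
#' @param seed optional integer seed; identical seeds give identical maps.
#' @param spacing `"poisson"` (uniform-random positions, the default) or
#'   `"grid"` (regular spacing, exact locus counts -- used for exactness in
#'   tests).
#' @return An `snp_map` data.frame with columns `group`, `pos`, `cg_allele`,
#'   `ca_allele`, `true_category`, positions strictly increasing within each
#'   group.
#' @export
sample_snp_map <- function(map, density, decoy_fraction = 0, seed = NULL,
                           spacing = c("poisson", "grid")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(density) || density <= 0 || density > 0.01)
    stop_config("density must be in (0, 0.01]")
  if (!is.numeric(decoy_fraction) || decoy_fraction < 0 || decoy_fraction >= 1)
    stop_config("decoy_fraction must be in [0, 1)")
  nucs <- c("A", "C", "G", "T")
  with_seed_(seed, {
    per_group <- lapply(seq_len(nrow(map)), function(i) {
      len <- map$length[i]
      if (spacing == "poisson") {
        n <- stats::rpois(1L, density * len)
        pos <- sort(sample.int(len, min(n, len)) - 1L)
      } else {
        n <- max(1L, round(density * len))
        step <- len / n
        pos <- floor(step / 2 + step * (seq_len(n) - 1L))
      }
      data.frame(group = map$group[i], pos = pos, stringsAsFactors = FALSE)
    })
    snps <- do.call(rbind, per_group)
    n <- nrow(snps)
    snps$ca_allele <- sample(nucs, n, replace = TRUE)
    snps$cg_allele <- vapply(snps$ca_allele,
                             function(a) sample(setdiff(nucs, a), 1L), "")
    f <- decoy_fraction
    snps$true_category <- sample(
      c("diagnostic", "decoy_het_cg", "decoy_parents_differ", "decoy_shared"),
      n, replace = TRUE, prob = c(1 - f, f / 3, f / 3, f / 3))
    ## founder haplotype genotypes (TRUE = carries the cg_allele)
    haps <- founder_haplotype_ids()
    ha <- matrix(FALSE, n, length(haps), dimnames = list(NULL, haps))
    ha[snps$true_category == "diagnostic", c("cg1", "cg2", "cg3")] <- TRUE
    ha[snps$true_category == "decoy_het_cg", "cg1"] <- TRUE
    pd <- which(snps$true_category == "decoy_parents_differ")
    if (length(pd)) {
      ha[pd, c("caM1", "caM2")] <- TRUE
      shares_male <- sample(c(TRUE, FALSE), length(pd), replace = TRUE)
      ha[pd[shares_male], c("cg1", "cg2", "cg3")] <- TRUE
    }
    snps <- snps[, c("group", "pos", "cg_allele", "ca_allele", "true_category")]
    attr(snps, "hap_alleles") <- ha
    class(snps) <- c("snp_map", "data.frame")
    snps
  })
}

founder_haplotype_ids <- function() {
  c("cg1", "cg2", "cg3", "caF1", "caF2", "caM1", "caM2")
}

#' @export
print.snp_map <- function(x, ...) {
  cat("Diagnostic SNP map:", nrow(x), "loci on", length(unique(x$group)),
      "homolog groups\n")
  print(table(x$true_category))
  invisible(x)
}

#' Write / read the genome map as 2-column TSV
#' @param map a `genome_map`.
#' @param path file path.
#' @export
write_genome_map <- function(map, path) {
  utils::write.table(map[, c("group", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_map
#' @export
read_genome_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$subgenome <- sub("^[0-9]+", "", df$group)
  df <- df[, c("group", "subgenome", "length")]
  attr(df, "sex_group") <- df$group[1L]
  class(df) <- c("genome_map", "data.frame")
  df
}

#' Write / read the SNP map as TSV
#'
#' Columns: group, pos0, cg_allele, ca_allele, true_category. Founder
#' haplotype genotypes are reconstructed from the category on read (the
#' `decoy_parents_differ` flavor alternates deterministically, since the
#' TSV does not carry per-haplotype genotypes).
#' @param snps an `snp_map`.
#' @param path file path.
#' @export
write_snp_map <- function(snps, path) {
  out <- data.frame(group = snps$group, pos0 = snps$pos,
                    cg_allele = snps$cg_allele, ca_allele = snps$ca_allele,
                    true_category = snps$true_category)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_map
#' @export
read_snp_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  snps <- data.frame(group = df$group, pos = df$pos0,
                     cg_allele = df$cg_allele, ca_allele = df$ca_allele,
                     true_category = df$true_category,
                     stringsAsFactors = FALSE)
  haps <- founder_haplotype_ids()
  n <- nrow(snps)
  ha <- matrix(FALSE, n, length(haps), dimnames = list(NULL, haps))
  ha[snps$true_category == "diagnostic", c("cg1", "cg2", "cg3")] <- TRUE
  ha[snps$true_category == "decoy_het_cg", "cg1"] <- TRUE
  pd <- which(snps$true_category == "decoy_parents_differ")
  if (length(pd)) {
    ha[pd, c("caM1", "caM2")] <- TRUE
    ha[pd[seq_along(pd) %% 2L == 1L], c("cg1", "cg2", "cg3")] <- TRUE
  }
  attr(snps, "hap_alleles") <- ha
  class(snps) <- c("snp_map", "data.frame")
  snps
}
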