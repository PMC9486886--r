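## Chromosome copies are segment mosaics: data.frames with columns
## start, end (0-based half-open), origin ("CG"/"CA"), founder (haplotype id).
## Sex-group copies additionally carry a "sex" attribute ("X"/"Y").

new_copy <- function(length, origin, founder, sex = NULL) {
  cp <- data.frame(start = 0, end = as.numeric(length),
                   origin = origin, founder = founder,
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) attr(cp, "sex") <- sex
  cp
}

copy_sex <- function(cp) attr(cp, "sex") %||% NA_character_

## merge adjacent segments with identical founder (keeps mosaics minimal)
normalize_copy <- function(cp) {
  if (nrow(cp) <= 1L) return(cp)
  keep <- c(TRUE, cp$founder[-1L] != cp$founder[-nrow(cp)])
  idx <- cumsum(keep)
  out <- cp[keep, , drop = FALSE]
  out$end <- tapply(cp$end, idx, max)
  rownames(out) <- NULL
  sx <- attr(cp, "sex")
  if (!is.null(sx)) attr(out, "sex") <- sx
  out
}

copy_is_recombinant <- function(cp) length(unique(cp$origin)) > 1L

new_individual <- function(id, generation, copies, parents = c(NA, NA)) {
  structure(list(id = id, generation = generation, copies = copies,
                 parents = stats::setNames(as.character(parents),
                                           c("mother", "father"))),
            class = "individual")
}

#' Ploidy and chromosome counts of a simulated individual
#' @param ind an `individual`.
#' @return `ploidy()`: the common per-group copy number; `chromosome_count()`:
#'   the total number of chromosome copies across all homolog groups.
#' @export
ploidy <- function(ind) {
  k <- unique(vapply(ind$copies, length, 1L))
  if (length(k) != 1L)
    stop_ploidy("individual ", ind$id, " is not euploid")
  k
}

#' @rdname ploidy
#' @export
chromosome_count <- function(ind) {
  sum(vapply(ind$copies, length, 1L))
}

#' Sex-chromosome content of an individual
#' @param ind an `individual`.
#' @param map the `genome_map` (identifies the sex group).
#' @return named integer vector `c(X =, Y =)`.
#' @export
sex_chromosomes <- function(ind, map) {
  sg <- attr(map, "sex_group")
  labs <- vapply(ind$copies[[sg]], copy_sex, "")
  c(X = sum(labs == "X", na.rm = TRUE), Y = sum(labs == "Y", na.rm = TRUE))
}

#' @rdname sex_chromosomes
#' @export
individual_sex <- function(ind, map) {
  sx <- sex_chromosomes(ind, map)
  if (sx[["Y"]] > 0L) "male" else "female"
}

#' Check the segment-tiling invariant of every chromosome copy
#'
#' Every copy must tile `[0, group length)` with contiguous, non-overlapping
#' segments. Called by the constructors; exported for property tests.
#' @param ind an `individual` (or `gamete`).
#' @param map the `genome_map`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_tiling <- function(ind, map) {
  for (g in names(ind$copies)) {
    len <- group_length_of(map, g)
    for (cp in ind$copies[[g]]) {
      if (nrow(cp) == 0L || cp$start[1L] != 0 || cp$end[nrow(cp)] != len ||
          any(cp$start >= cp$end) ||
          (nrow(cp) > 1L && any(cp$start[-1L] != cp$end[-nrow(cp)])))
        stop("segment tiling violated in group ", g, " of ", ind$id)
    }
  }
  invisible(TRUE)
}

#' Construct the three founder genomes
#'
#' Builds the clonal triploid gibel carp female (Cg, three all-CG copies per
#' homolog group, XXX), and the sexual goldfish female and male (Ca, two
#' all-CA copies per group; XX and XY). Founder genotypes at every locus are
#' those recorded in the SNP map's `hap_alleles` table, so diagnostic loci
#' are homozygous-different between lineages and each decoy class violates
#' exactly the filter criterion it is named for.
#'
#' @param map a `genome_map`.
#' @param snps an `snp_map` built on `map`.
#' @return list with elements `cgF` (3n), `caF` (2n), `caM` (2n), each an
#'   `individual`.
#' @export
make_founders <- function(map, snps) {
  if (!all(snps$group %in% map$group))
    stop_config("snp map refers to groups absent from the genome map")
  sg <- attr(map, "sex_group")
  mk <- function(id, generation, founders, origin, sexes) {
    copies <- lapply(seq_len(nrow(map)), function(i) {
      len <- map$length[i]
      lapply(seq_along(founders), function(k) {
        new_copy(len, origin, founders[k],
                 sex = if (map$group[i] == sg) sexes[k])
      })
    })
    names(copies) <- map$group
    new_individual(id, generation, copies)
  }
  list(cgF = mk("Cg_F", "CG_F", c("cg1", "cg2", "cg3"), "CG", c("X", "X", "X")),
       caF = mk("Ca_F", "CA_F", c("caF1", "caF2"), "CA", c("X", "X")),
       caM = mk("Ca_M", "CA_M", c("caM1", "caM2"), "CA", c("X", "Y")))
}

#' Assemble a triploid with a prescribed CG dosage in every group
#'
#' Convenience constructor for controlled dosage experiments: each homolog
#' group gets `n_cg` pure-CG copies (founder haplotypes cg1, cg2) and
#' `3 - n_cg` pure-CA copies (caF1, caF2).
#' @param map a `genome_map`.
#' @param n_cg CG-derived copies per group (1 or 2).
#' @param id individual id.
#' @return an `individual` of ploidy 3.
#' @export
make_triploid <- function(map, n_cg, id = sprintf("3n_dosage%d", n_cg)) {
  if (!n_cg %in% 1:2) stop_config("n_cg must be 1 or 2")
  founders <- c(c("cg1", "cg2")[seq_len(n_cg)],
                c("caF1", "caF2")[seq_len(3L - n_cg)])
  origins <- c(rep("CG", n_cg), rep("CA", 3L - n_cg))
  sg <- attr(map, "sex_group")
  copies <- lapply(seq_len(nrow(map)), function(i) {
    lapply(seq_along(founders), function(k)
      new_copy(map$length[i], origins[k], founders[k],
               sex = if (map$group[i] == sg) "X"))
  })
  names(copies) <- map$group
  new_individual(id, "NA3N", copies)
}

#' Per-locus CG-allele dosage of an individual
#'
#' For each locus of the SNP map, counts how many of the individual's
#' chromosome copies carry the Cg-side allele, resolving each copy's
#' segment mosaic to its founder haplotype and looking the genotype up in
#' the map's `hap_alleles` table.
#' @param ind an `individual` or `gamete`.
#' @param snps an `snp_map`.
#' @return integer vector of CG-allele counts, aligned with `snps` rows.
#' @export
cg_dosage <- function(ind, snps) {
  ha <- attr(snps, "hap_alleles")
  dose <- integer(nrow(snps))
  idx_by_group <- split(seq_len(nrow(snps)), snps$group)
  for (g in names(idx_by_group)) {
    rows <- idx_by_group[[g]]
    pos <- snps$pos[rows]
    for (cp in ind$copies[[g]] %||% list()) {
      seg <- findInterval(pos, cp$start)
      dose[rows] <- dose[rows] + ha[cbind(rows, match(cp$founder[seg],
                                                      colnames(ha)))]
    }
  }
  dose
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual %s> generation %s, %d homolog groups, ploidy %d\n",
              x$id, x$generation, length(x$copies), ploidy(x)))
  nrec <- sum(vapply(x$copies, function(g)
    sum(vapply(g, copy_is_recombinant, TRUE)), 1L))
  cat("  recombinant (CG/CA mosaic) copies:", nrec, "\n")
  invisible(x)
}
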