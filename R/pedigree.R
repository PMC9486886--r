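#' Genome addition: synthesize the amphitetraploid male
#'
#' The amphitetraploid arises by adding a haploid goldfish sperm genome to
#' the unreduced triploid egg of the gibel carp clone (3 CG chromosome sets
#' + 1 CA set per group, 4 copies total). Sperm are redrawn until one
#' carrying Y is obtained, so the returned individual is male (XXXY).
#'
#' @param cgF the clonal triploid Cg female founder.
#' @param caM the diploid Ca male founder.
#' @param map the `genome_map`.
#' @param co_count_probs crossover-count distribution for the Ca male's
#'   meiosis.
#' @param seed optional seed.
#' @param id individual id.
#' @return a 4n male `individual` with generation label `"SA4N"`.
#' @export
make_amphitetraploid <- function(cgF, caM, map,
                                 co_count_probs = c("1" = 0.5, "2" = 0.5),
                                 seed = NULL, id = "SA4n_M") {
  with_seed_(seed, {
    egg <- make_egg(cgF, "unreduced", map)
    sg <- attr(map, "sex_group")
    for (try in 1:64) {
      sperm1n <- make_egg(caM, "reduced", map, co_count_probs)
      if (copy_sex(sperm1n$copies[[sg]][[1L]]) == "Y") break
    }
    if (copy_sex(sperm1n$copies[[sg]][[1L]]) != "Y")
      stop("failed to draw a Y-bearing sperm")
    off <- fertilize(egg, sperm1n, "sexual", id = id, generation = "SA4N",
                     parents = c(cgF$id, caM$id))
    off
  })
}

#' Simulate a cohort of first-generation backcross amphitriploids
#'
#' Crosses reduced eggs of the Ca female with reduced diploid sperm of the
#' amphitetraploid male: each offspring carries 3 copies per group (150
#' chromosomes on the default 50-group map), one maternal CA set plus two
#' paternal sets drawn by tetraploid meiosis.
#'
#' @param founders founder list from [make_founders()].
#' @param father a 4n `individual` (see [make_amphitetraploid()]).
#' @param map the `genome_map`.
#' @param n number of offspring.
#' @param co_count_probs crossover-count distribution per bivalent.
#' @param seed optional seed.
#' @return named list of `individual`s (`NA3n_1`, ...).
#' @export
simulate_backcross_cohort <- function(founders, father, map, n = 10L,
                                      co_count_probs = c("1" = 0.5,
                                                         "2" = 0.5),
                                      seed = NULL) {
  with_seed_(seed, {
    off <- lapply(seq_len(n), function(i) {
      egg <- make_egg(founders$caF, "reduced", map, co_count_probs)
      sperm <- meiosis_sperm(father, map, co_count_probs)
      fertilize(egg, sperm, "sexual", id = sprintf("NA3n_%d", i),
                generation = "NA3N", parents = c(founders$caF$id, father$id))
    })
    stats::setNames(off, vapply(off, `[[`, "", "id"))
  })
}

#' Simulate a gynogenetic (clonal) cohort
#'
#' Unreduced eggs of a triploid mother are activated by sperm of a donor
#' male whose genome never fuses: every offspring is a genome-identical
#' clone of the mother. The donor id is recorded as the paternal parent for
#' downstream attribution.
#'
#' @param mother a 3n female `individual`.
#' @param donor the sperm-donor `individual` (genome ignored).
#' @param map the `genome_map`.
#' @param n number of offspring.
#' @param generation generation label (`"GA3N"` or `"CA3N"`).
#' @param prefix id prefix.
#' @return named list of `individual`s.
#' @export
simulate_gynogenetic_cohort <- function(mother, donor, map, n = 10L,
                                        generation = "GA3N",
                                        prefix = "GA3n") {
  off <- lapply(seq_len(n), function(i) {
    egg <- make_egg(mother, "unreduced", map)
    fertilize(egg, NULL, "gynogenetic", id = sprintf("%s_%d", prefix, i),
              generation = generation, parents = c(mother$id, donor$id))
  })
  stats::setNames(off, vapply(off, `[[`, "", "id"))
}
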