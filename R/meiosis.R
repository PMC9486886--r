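## Reproduction system of the gibel carp complex:
## - amphitetraploid males run regular meiosis (full bivalent pairing,
##   1-2 crossovers per bivalent) and produce reduced diploid sperm;
## - sexual goldfish females run regular diploid meiosis (reduced haploid
##   eggs);
## - amphitriploid females produce unreduced eggs through the ameiotic
##   pathway (type-II oocytes: no pairing, no recombination, no reduction);
##   their type-I oocytes pair one bivalent + one univalent per group but
##   are apoptotic and census-only.

PAIRING_MODES <- c("tetraploid_spermatocyte", "triploid_typeI_oocyte",
                   "triploid_typeII_ameiotic")

## the three perfect matchings of 4 copies / the three pairs of 3 copies
matchings4 <- list(list(c(1L, 2L), c(3L, 4L)),
                   list(c(1L, 3L), c(2L, 4L)),
                   list(c(1L, 4L), c(2L, 3L)))
pairs3 <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))

#' Pair homologs within every group of a meiotic nucleus
#'
#' Pairing is uniform-random among the perfect configurations of the mode:
#' a tetraploid spermatocyte forms 2 bivalents per group (one of the 3
#' matchings of 4 copies), a type-I triploid oocyte forms 1 bivalent + 1
#' univalent (one of the 3 possible pairs), and a type-II (ameiotic)
#' oocyte forms no bivalents at all.
#'
#' @param ind an `individual` whose per-group copy number matches the mode
#'   (4 for the tetraploid mode, 3 for the triploid modes).
#' @param mode one of `"tetraploid_spermatocyte"`, `"triploid_typeI_oocyte"`,
#'   `"triploid_typeII_ameiotic"`.
#' @param seed optional seed.
#' @return a `pairing_outcome`: per group, `bivalents` (list of index pairs)
#'   and `univalents` (integer vector of unpaired copy indices).
#' @export
pair_homologs <- function(ind, mode = PAIRING_MODES, seed = NULL) {
  mode <- match.arg(mode)
  p <- ploidy(ind)
  need <- switch(mode, tetraploid_spermatocyte = 4L, 3L)
  if (p != need)
    stop_ploidy("mode ", mode, " requires ", need, " copies per group, got ", p)
  with_seed_(seed, {
    out <- lapply(ind$copies, function(g) {
      n <- length(g)
      switch(mode,
        tetraploid_spermatocyte = {
          m <- matchings4[[sample.int(3L, 1L)]]
          list(bivalents = m, univalents = integer(0))
        },
        triploid_typeI_oocyte = {
          pr <- pairs3[[sample.int(3L, 1L)]]
          list(bivalents = list(pr), univalents = setdiff(seq_len(n), pr))
        },
        triploid_typeII_ameiotic =
          list(bivalents = list(), univalents = seq_len(n)))
    })
    structure(list(groups = out, mode = mode), class = "pairing_outcome")
  })
}

#' Place crossovers on the bivalents of a pairing outcome
#'
#' Per bivalent, a crossover count is drawn from `co_count_probs`
#' (default: 1 or 2 with equal probability, matching the 1-2 recombination
#' foci seen per bivalent), positions are i.i.d. uniform along the group,
#' and each exchange involves one of the four non-sister chromatid pairs of
#' the four-chromatid stage, chosen uniformly. Univalents never receive
#' crossovers. No interference is modeled.
#'
#' @param pairing a `pairing_outcome`.
#' @param map the `genome_map`.
#' @param co_count_probs named numeric vector of crossover-count
#'   probabilities, e.g. `c("1" = 0.5, "2" = 0.5)`.
#' @param seed optional seed.
#' @return data.frame of crossover events: `group`, `bivalent`, `pos`,
#'   `chromatid_a`, `chromatid_b` (chromatid 1 or 2 of each paired copy).
#' @export
place_crossovers <- function(pairing, map,
                             co_count_probs = c("1" = 0.5, "2" = 0.5),
                             seed = NULL) {
  if (length(co_count_probs) == 0 || any(co_count_probs < 0) ||
      sum(co_count_probs) <= 0)
    stop_config("co_count_probs must be a non-empty probability vector")
  counts <- as.integer(names(co_count_probs))
  if (any(is.na(counts)) || any(counts < 1))
    stop_config("co_count_probs names must be positive crossover counts")
  with_seed_(seed, {
    ev <- list()
    for (g in names(pairing$groups)) {
      len <- group_length_of(map, g)
      bvs <- pairing$groups[[g]]$bivalents
      for (b in seq_along(bvs)) {
        k <- if (length(counts) == 1L) counts else
          sample(counts, 1L, prob = co_count_probs)
        if (k == 0L) next
        ev[[length(ev) + 1L]] <- data.frame(
          group = g, bivalent = b, pos = stats::runif(k, 0, len),
          chromatid_a = sample(1:2, k, replace = TRUE),
          chromatid_b = sample(1:2, k, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    if (length(ev) == 0L)
      return(data.frame(group = character(), bivalent = integer(),
                        pos = numeric(), chromatid_a = integer(),
                        chromatid_b = integer()))
    do.call(rbind, ev)
  })
}

## exchange segment tails of two chromatids at position x
co_exchange <- function(cpA, cpB, x) {
  split_at <- function(cp, x) {
    i <- findInterval(x, cp$start)
    head <- cp[seq_len(i), , drop = FALSE]
    tail <- cp[seq(i, nrow(cp)), , drop = FALSE]
    head$end[i] <- x
    tail$start[1L] <- x
    list(head = head[head$start < head$end, , drop = FALSE],
         tail = tail[tail$start < tail$end, , drop = FALSE])
  }
  a <- split_at(cpA, x); b <- split_at(cpB, x)
  sxA <- attr(cpA, "sex"); sxB <- attr(cpB, "sex")
  newA <- rbind(a$head, b$tail); newB <- rbind(b$head, a$tail)
  rownames(newA) <- rownames(newB) <- NULL
  ## the X/Y label rides with the centromere (position 0), i.e. the head
  if (!is.null(sxA)) attr(newA, "sex") <- sxA
  if (!is.null(sxB)) attr(newB, "sex") <- sxB
  list(newA, newB)
}

## Resolve one bivalent (two copies + its crossover events) into its four
## chromatids, then return one chromatid chosen uniformly. MI and MII are
## collapsed into this single uniform draw, which is equivalent in the
## absence of sister-chromatid exchange.
resolve_bivalent <- function(copyA, copyB, events) {
  chromatids <- list(copyA, copyA, copyB, copyB) # a1 a2 b1 b2
  if (nrow(events)) {
    events <- events[order(events$pos), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      ia <- events$chromatid_a[i]           # 1..2 -> index in chromatids
      ib <- events$chromatid_b[i] + 2L
      sw <- co_exchange(chromatids[[ia]], chromatids[[ib]], events$pos[i])
      chromatids[[ia]] <- sw[[1L]]
      chromatids[[ib]] <- sw[[2L]]
    }
  }
  normalize_copy(chromatids[[sample.int(4L, 1L)]])
}

new_gamete <- function(kind, copies) {
  structure(list(kind = kind, copies = copies), class = "gamete")
}

#' Tetraploid spermatogenesis: one reduced diploid sperm
#'
#' Per homolog group: uniform bivalent pairing of the four copies, 1-2
#' crossovers per bivalent, resolution of the exchanges at the
#' four-chromatid stage, then independent segregation delivering one
#' chromatid from each bivalent. Sex chromosomes segregate with their
#' group, so an XXXY father yields XX and XY sperm in equal proportion.
#'
#' @param father a 4n `individual`.
#' @param map the `genome_map`.
#' @param co_count_probs crossover-count distribution per bivalent.
#' @param seed optional seed.
#' @return a `gamete` of kind `reduced_sperm_2n` (2 copies per group).
#' @export
meiosis_sperm <- function(father, map,
                          co_count_probs = c("1" = 0.5, "2" = 0.5),
                          seed = NULL) {
  if (ploidy(father) != 4L)
    stop_ploidy("meiosis_sperm requires a tetraploid father")
  with_seed_(seed, {
    pairing <- pair_homologs(father, "tetraploid_spermatocyte")
    events <- place_crossovers(pairing, map, co_count_probs)
    copies <- lapply(names(father$copies), function(g) {
      bvs <- pairing$groups[[g]]$bivalents
      lapply(seq_along(bvs), function(b) {
        ev <- events[events$group == g & events$bivalent == b, , drop = FALSE]
        resolve_bivalent(father$copies[[g]][[bvs[[b]][1L]]],
                         father$copies[[g]][[bvs[[b]][2L]]], ev)
      })
    })
    names(copies) <- names(father$copies)
    new_gamete("reduced_sperm_2n", copies)
  })
}

#' Egg production: reduced (meiotic) or unreduced (ameiotic)
#'
#' A reduced egg requires a diploid mother and runs standard meiosis (one
#' bivalent per group, crossovers, reduction to one copy). An unreduced egg
#' requires a triploid mother and is an exact copy of her genome -- the
#' ameiotic pathway of type-II oocytes, with no pairing, recombination or
#' reduction.
#'
#' @param mother an `individual` (2n for reduced, 3n for unreduced).
#' @param mode `"reduced"` or `"unreduced"`.
#' @param map the `genome_map`.
#' @param co_count_probs crossover-count distribution (reduced mode only).
#' @param seed optional seed.
#' @return a `gamete` of kind `reduced_egg_1n` or `unreduced_egg_3n`.
#' @export
make_egg <- function(mother, mode = c("reduced", "unreduced"), map,
                     co_count_probs = c("1" = 0.5, "2" = 0.5), seed = NULL) {
  mode <- match.arg(mode)
  p <- ploidy(mother)
  if (mode == "unreduced") {
    if (p != 3L) stop_ploidy("unreduced eggs require a triploid mother")
    return(new_gamete("unreduced_egg_3n", mother$copies))
  }
  if (p != 2L) stop_ploidy("reduced eggs require a diploid mother")
  with_seed_(seed, {
    copies <- lapply(names(mother$copies), function(g) {
      len <- group_length_of(map, g)
      counts <- as.integer(names(co_count_probs))
      k <- if (length(counts) == 1L) counts else
        sample(counts, 1L, prob = co_count_probs)
      ev <- data.frame(group = g, bivalent = 1L,
                       pos = stats::runif(k, 0, len),
                       chromatid_a = sample(1:2, k, replace = TRUE),
                       chromatid_b = sample(1:2, k, replace = TRUE))
      list(resolve_bivalent(mother$copies[[g]][[1L]],
                            mother$copies[[g]][[2L]], ev))
    })
    names(copies) <- names(mother$copies)
    new_gamete("reduced_egg_1n", copies)
  })
}

#' Fertilization: sexual fusion or gynogenetic activation
#'
#' Sexual mode fuses egg and sperm genomes (per-group copy numbers add).
#' Gynogenetic mode models sperm-dependent clonal reproduction: the sperm
#' triggers development but its nucleus never fuses, so the offspring is
#' the unreduced egg's genome verbatim. Sex follows X/Y content (any Y
#' makes a male).
#'
#' @param egg a `gamete` (`reduced_egg_1n` or `unreduced_egg_3n`).
#' @param sperm a `gamete` of kind `reduced_sperm_2n`, or `NULL` in
#'   gynogenetic mode (ignored there even if supplied).
#' @param mode `"sexual"` or `"gynogenetic"`.
#' @param id offspring id.
#' @param generation generation label (e.g. `"NA3N"`, `"GA3N"`).
#' @param parents character vector `c(mother, father)` of parent ids.
#' @return an `individual`.
#' @export
fertilize <- function(egg, sperm = NULL, mode = c("sexual", "gynogenetic"),
                      id = "offspring", generation = "NA3N",
                      parents = c(NA, NA)) {
  mode <- match.arg(mode)
  if (mode == "sexual") {
    if (is.null(sperm)) stop_config("sexual fertilization requires sperm")
    copies <- lapply(names(egg$copies), function(g)
      c(egg$copies[[g]], sperm$copies[[g]]))
    names(copies) <- names(egg$copies)
    return(new_individual(id, generation, copies, parents))
  }
  if (egg$kind != "unreduced_egg_3n")
    stop_ploidy("gynogenesis requires an unreduced egg")
  new_individual(id, generation, egg$copies, parents)
}

#' Census of meiotic pairing structures over many nuclei
#'
#' Repeats [pair_homologs()] over independent nuclei and tabulates total
#' bivalents and univalents per nucleus -- the in-silico analogue of
#' synaptonemal-complex spread counts (a 50-group tetraploid spermatocyte
#' shows 100 bivalents; a type-I triploid oocyte 50 bivalents + 50
#' univalents; a type-II oocyte 150 univalents).
#'
#' @param ind an `individual` of ploidy compatible with `mode`.
#' @param mode a pairing mode, see [pair_homologs()].
#' @param n_nuclei number of nuclei to census.
#' @param seed optional seed.
#' @return data.frame with columns `nucleus`, `bivalents`, `univalents`.
#' @export
count_pairing_structures <- function(ind, mode = PAIRING_MODES,
                                     n_nuclei = 50L, seed = NULL) {
  mode <- match.arg(mode)
  with_seed_(seed, {
    rows <- lapply(seq_len(n_nuclei), function(i) {
      p <- pair_homologs(ind, mode)
      data.frame(nucleus = i,
                 bivalents = sum(vapply(p$groups, function(g)
                   length(g$bivalents), 1L)),
                 univalents = sum(vapply(p$groups, function(g)
                   length(g$univalents), 1L)))
    })
    do.call(rbind, rows)
  })
}

#' @export
print.gamete <- function(x, ...) {
  cat(sprintf("<gamete %s> %d groups x %d copies\n", x$kind,
              length(x$copies), length(x$copies[[1L]])))
  invisible(x)
}
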