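make_sa4n_fixture <- function(gm, snps, seed = 5L) {
  f <- make_founders(gm, snps)
  list(founders = f,
       sa4n = make_amphitetraploid(f$cgF, f$caM, gm, c("1" = 1),
                                   seed = seed))
}

test_that("pairing outcomes respect the mode contracts", {
  gm <- tiny_map()
  snps <- grid_snps(gm, 1e-4)
  fx <- make_sa4n_fixture(gm, snps)
  p4 <- pair_homologs(fx$sa4n, "tetraploid_spermatocyte", seed = 1)
  for (g in p4$groups) {
    expect_length(g$bivalents, 2L)
    expect_length(g$univalents, 0L)
    expect_setequal(unlist(g$bivalents), 1:4)
  }
  tri <- make_triploid(gm, 1)
  p3 <- pair_homologs(tri, "triploid_typeI_oocyte", seed = 2)
  for (g in p3$groups) {
    expect_length(g$bivalents, 1L)
    expect_length(g$univalents, 1L)
  }
  p0 <- pair_homologs(tri, "triploid_typeII_ameiotic", seed = 3)
  for (g in p0$groups) {
    expect_length(g$bivalents, 0L)
    expect_length(g$univalents, 3L)
  }
  expect_error(pair_homologs(tri, "tetraploid_spermatocyte"),
               class = "polypaint_ploidy_error")
  expect_error(pair_homologs(fx$sa4n, "triploid_typeI_oocyte"),
               class = "polypaint_ploidy_error")
})

test_that("pairing is uniform over the three perfect matchings", {
  gm <- tiny_map(1, 1e5)
  snps <- grid_snps(gm, 1e-4)
  fx <- make_sa4n_fixture(gm, snps)
  ## the CA copy is index 4; P(paired with copy 1) = 1/3 by enumeration
  withr::with_seed(9, {
    hits <- replicate(900, {
      p <- pair_homologs(fx$sa4n, "tetraploid_spermatocyte")
      any(vapply(p$groups[["1A"]]$bivalents,
                 function(b) setequal(b, c(1L, 4L)), TRUE))
    })
  })
  ## 3 standard errors of a Bernoulli(1/3) over 900 draws
  expect_equal(mean(hits), 1 / 3, tolerance = 3 * sqrt(2 / 9 / 900) / (1 / 3))
})

test_that("crossover placement follows the count distribution and spares univalents", {
  gm <- tiny_map()
  snps <- grid_snps(gm, 1e-4)
  fx <- make_sa4n_fixture(gm, snps)
  p4 <- pair_homologs(fx$sa4n, "tetraploid_spermatocyte", seed = 4)
  ev <- place_crossovers(p4, gm, c("1" = 1), seed = 5)
  ## obligate single crossover: exactly one event per bivalent
  expect_equal(nrow(ev), 2L * nrow(gm))
  expect_true(all(ev$pos > 0 & ev$pos < 1e6))
  tri <- make_triploid(gm, 1)
  p3 <- pair_homologs(tri, "triploid_typeI_oocyte", seed = 6)
  ev3 <- place_crossovers(p3, gm, c("1" = 1), seed = 7)
  expect_equal(nrow(ev3), nrow(gm))      # one per bivalent, none on univalents
  p0 <- pair_homologs(tri, "triploid_typeII_ameiotic", seed = 8)
  expect_equal(nrow(place_crossovers(p0, gm, c("1" = 1), seed = 9)), 0L)
  expect_error(place_crossovers(p4, gm, numeric(0)),
               class = "polypaint_config_error")
})

test_that("tetraploid meiosis reduces, conserves and recombines as expected", {
  gm <- tiny_map(1, 1e6)
  snps <- grid_snps(gm, 1e-4)
  fx <- make_sa4n_fixture(gm, snps)
  sp <- meiosis_sperm(fx$sa4n, gm, c("1" = 1), seed = 10)
  expect_s3_class(sp, "gamete")
  expect_equal(sp$kind, "reduced_sperm_2n")
  expect_true(all(vapply(sp$copies, length, 1L) == 2L))
  expect_true(validate_tiling(sp, gm))
  expect_error(meiosis_sperm(fx$founders$caF, gm),
               class = "polypaint_ploidy_error")

  ## with one obligate crossover, a chromatid drawn from a bivalent carries
  ## the exchange with probability 1/2 (2 of the 4 chromatids), so the
  ## fraction of sperm carrying a CG/CA mosaic copy converges to 1/2, and
  ## the CA-centromere copy is transmitted to half the sperm
  withr::with_seed(11, {
    stats <- t(replicate(800, {
      s <- meiosis_sperm(fx$sa4n, gm, c("1" = 1))
      cps <- s$copies[["1A"]]
      c(mosaic = any(vapply(cps, function(cp)
          length(unique(cp$origin)) > 1L, TRUE)),
        ca_centro = any(vapply(cps, function(cp) cp$origin[1] == "CA", TRUE)))
    }))
  })
  se <- 3 * sqrt(0.25 / 800)
  expect_equal(mean(stats[, "mosaic"]), 0.5, tolerance = se / 0.5)
  expect_equal(mean(stats[, "ca_centro"]), 0.5, tolerance = se / 0.5)
})

test_that("an XXXY father sires XX and XY sperm in equal proportion", {
  gm <- tiny_map(1, 1e5)
  snps <- grid_snps(gm, 1e-4)
  fx <- make_sa4n_fixture(gm, snps)
  expect_equal(sex_chromosomes(fx$sa4n, gm), c(X = 3L, Y = 1L))
  sg <- attr(gm, "sex_group")
  withr::with_seed(12, {
    has_y <- replicate(800, {
      s <- meiosis_sperm(fx$sa4n, gm, c("1" = 1))
      any(vapply(s$copies[[sg]], function(cp)
        identical(attr(cp, "sex"), "Y"), TRUE))
    })
  })
  expect_equal(mean(has_y), 0.5, tolerance = 3 * sqrt(0.25 / 800) / 0.5)
})

test_that("egg production enforces mode/ploidy and gynogenesis is clonal", {
  gm <- tiny_map()
  snps <- grid_snps(gm, 1e-4)
  f <- make_founders(gm, snps)
  egg <- make_egg(f$caF, "reduced", gm, c("1" = 1), seed = 13)
  expect_equal(egg$kind, "reduced_egg_1n")
  expect_true(all(vapply(egg$copies, length, 1L) == 1L))

  tri <- make_triploid(gm, 2)
  uegg <- make_egg(tri, "unreduced", gm)
  expect_equal(uegg$kind, "unreduced_egg_3n")
  ## clonal identity is bit-exact
  expect_identical(uegg$copies, tri$copies)
  expect_error(make_egg(f$caF, "unreduced", gm),
               class = "polypaint_ploidy_error")
  expect_error(make_egg(tri, "reduced", gm),
               class = "polypaint_ploidy_error")
})

test_that("fertilization adds genomes and assigns sex from X/Y content", {
  gm <- tiny_map()
  snps <- grid_snps(gm, 1e-4)
  fx <- make_sa4n_fixture(gm, snps)
  egg <- make_egg(fx$founders$caF, "reduced", gm, c("1" = 1), seed = 14)
  sp <- meiosis_sperm(fx$sa4n, gm, c("1" = 1), seed = 15)
  off <- fertilize(egg, sp, "sexual", id = "x1")
  expect_equal(ploidy(off), 3L)
  expect_equal(chromosome_count(off), 3L * nrow(gm))
  sx <- sex_chromosomes(off, gm)
  expect_equal(sum(sx), 3L)
  expect_equal(individual_sex(off, gm), if (sx[["Y"]] > 0) "male" else "female")
  expect_error(fertilize(egg, NULL, "sexual"),
               class = "polypaint_config_error")

  ## gynogenetic offspring of an XXX mother are XXX females, genome verbatim
  tri <- make_triploid(gm, 1)
  gyn <- fertilize(make_egg(tri, "unreduced", gm), NULL, "gynogenetic",
                   id = "g1")
  expect_identical(gyn$copies, tri$copies)
  expect_equal(sex_chromosomes(gyn, gm), c(X = 3L, Y = 0L))
  expect_equal(individual_sex(gyn, gm), "female")
  expect_error(fertilize(egg, NULL, "gynogenetic"),
               class = "polypaint_ploidy_error")
})

test_that("pairing censuses match the cytological counts", {
  std <- std_cohort()
  cs4 <- count_pairing_structures(std$sa4n, "tetraploid_spermatocyte",
                                  n_nuclei = 10, seed = 16)
  expect_true(all(cs4$bivalents == 100L))
  expect_true(all(cs4$univalents == 0L))
  tri <- std$offspring[[1L]]
  cs3 <- count_pairing_structures(tri, "triploid_typeI_oocyte",
                                  n_nuclei = 10, seed = 17)
  expect_true(all(cs3$bivalents == 50L))
  expect_true(all(cs3$univalents == 50L))
  cs0 <- count_pairing_structures(tri, "triploid_typeII_ameiotic",
                                  n_nuclei = 5, seed = 18)
  expect_true(all(cs0$bivalents == 0L))
  expect_true(all(cs0$univalents == 150L))
})

test_that("backcross offspring segments all trace to founder haplotypes", {
  std <- std_cohort()
  ind <- std$offspring[[2L]]
  expect_true(validate_tiling(ind, std$map))
  haps <- c("cg1", "cg2", "cg3", "caF1", "caF2", "caM1", "caM2")
  for (g in ind$copies)
    for (cp in g) expect_true(all(cp$founder %in% haps))
})
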