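test_that("effective-locus criteria fail for the reasons they name", {
  pc <- list(cgF = c("hom_cg", "het", "hom_ca", "hom_cg", "hom_cg", "hom_cg"),
             caF = c("hom_ca", "hom_ca", "hom_ca", "hom_ca", "hom_ca", "hom_ca"),
             caM = c("hom_ca", "hom_ca", "hom_ca", "hom_cg", "hom_ca", "missing"))
  off <-       c("het",    "het",    "het",    "het",    "hom_cg", "het")
  mask <- select_effective_snps(pc, off, "triple_parent")
  expect_equal(mask$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(mask$reason, c(NA, "i", "iii", "ii", "iv", "depth"))

  pw <- select_effective_snps(
    list(mother = c("hom_ca", "hom_ca", "het", "missing"),
         father = c("hom_cg", "hom_ca", "hom_cg", "hom_cg")),
    mode = "pairwise_parent")
  expect_equal(pw$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(pw$reason, c(NA, "iii", "i", "depth"))

  expect_error(select_effective_snps(pc[1:2], off, "triple_parent"),
               class = "polypaint_config_error")
})

test_that("on noiseless data the keep-set equals the diagnostic truth labels", {
  gm <- tiny_map(2, 1e6)
  snps <- grid_snps(gm, 1e-3, decoy = 0.3, seed = 41)
  f <- make_founders(gm, snps)
  off <- make_triploid(gm, 1)
  ## depth at which hard calls are deterministic: at 100x the chance that
  ## a true 1/3-dosage site leaves the het band is < 1e-7
  m <- exact_model(100)
  calls <- lapply(list(cgF = f$cgF, caF = f$caF, caM = f$caM),
                  function(ind) call_site_genotypes(
                    simulate_observations(ind, snps, m, seed = 42)))
  off_calls <- call_site_genotypes(simulate_observations(off, snps, m, 43))
  mask <- select_effective_snps(calls, off_calls, "triple_parent")
  expect_identical(mask$keep, snps$true_category == "diagnostic")
})

test_that("windowed means equal an independent brute-force average", {
  gm <- tiny_map(1, 1e6)
  snps <- grid_snps(gm, 1e-3, seed = 44)
  tri <- make_triploid(gm, 2)
  obs <- simulate_observations(tri, snps, exact_model(30), seed = 45)
  track <- window_frequencies(obs, NULL, gm, window_width = 1e5,
                              min_snps_per_window = 1)
  ## oracle: direct per-window loop, no shared code with the implementation
  for (i in which(track$group == "1A")) {
    sel <- obs$group == "1A" & obs$pos >= track$start[i] &
      obs$pos < track$end[i] & (obs$cg + obs$ca) > 0
    expect_equal(track$cg_freq[i],
                 mean(obs$cg[sel] / (obs$cg[sel] + obs$ca[sel])))
    expect_equal(track$n_snps[i], sum(sel))
  }
})

test_that("window arithmetic, masks and sparse windows behave as specified", {
  gm <- tiny_map(1, 3e5)
  obs <- data.frame(group = rep("1A", 6),
                    pos = c(1e4, 3e4, 5e4, 7e4, 9e4, 1.5e5),
                    cg = c(10L, 10L, 10L, 10L, 10L, 0L),
                    ca = c(20L, 20L, 20L, 20L, 20L, 0L))
  class(obs) <- c("snp_obs", "data.frame")
  track <- window_frequencies(obs, NULL, gm, 1e5, min_snps_per_window = 2)
  t1a <- track[track$group == "1A", ]
  expect_equal(t1a$cg_freq[1], 1 / 3)      # five (10, 20) loci
  expect_true(is.na(t1a$cg_freq[2]))       # single zero-depth locus
  expect_true(is.na(t1a$cg_freq[3]))       # no loci at all

  ## a window fully inside a mask region is undefined
  mask_bed <- data.frame(group = "1A", start = 0, end = 1e5)
  tm <- window_frequencies(obs, NULL, gm, 1e5, 2, mask_regions = mask_bed)
  expect_true(is.na(tm$cg_freq[tm$group == "1A"][1]))
})

test_that("dosage classification uses the threshold, tie and calibration rules", {
  gm <- tiny_map(1, 4e5)
  track <- data.frame(group = rep(c("1A", "1B"), each = 4),
                      start = rep(seq(0, 3e5, 1e5), 2),
                      end = rep(seq(1e5, 4e5, 1e5), 2),
                      n_snps = 10L,
                      cg_freq = c(0.33, 0.67, 0.5, NA, 0.33, 0.33, 0.33, 0.33))
  attr(track, "window_width") <- 1e5
  class(track) <- c("window_track", "data.frame")
  cl <- classify_dosage(track, threshold = 0.5, calibrate = FALSE)
  expect_equal(cl$state[1:4], c(1L, 2L, 2L, NA))  # 0.5 ties to state 2
  expect_error(classify_dosage(track, threshold = 1.2),
               class = "polypaint_config_error")

  ## calibration: modes at 0.30 and 0.62 move the threshold to ~0.46
  set.seed(46)
  x <- c(rnorm(60, 0.30, 0.01), rnorm(60, 0.62, 0.01))
  big <- data.frame(group = "1A", start = seq_along(x), end = seq_along(x) + 1,
                    n_snps = 10L, cg_freq = x)
  class(big) <- c("window_track", "data.frame")
  cb <- classify_dosage(big, threshold = 0.5, calibrate = TRUE)
  expect_equal(attr(cb, "threshold_used"), 0.46, tolerance = 0.02)

  ## a group with no defined windows is flagged uncallable
  na_track <- track
  na_track$cg_freq[5:8] <- NA
  cn <- classify_dosage(na_track, 0.5)
  expect_equal(attr(cn, "uncallable_groups"), "1B")
})

test_that("segmentation smooths blips, keeps terminal runs and localizes steps", {
  mk_track <- function(states, freqs = NULL) {
    n <- length(states)
    if (is.null(freqs))
      freqs <- ifelse(is.na(states), NA, c(0.33, 0.67)[states])
    tr <- data.frame(group = "1A", start = (seq_len(n) - 1) * 1e5,
                     end = seq_len(n) * 1e5, n_snps = 10L,
                     cg_freq = freqs)
    tr$state <- states
    attr(tr, "window_width") <- 1e5
    attr(tr, "threshold_used") <- 0.5
    class(tr) <- c("window_track", "data.frame")
    tr
  }
  ## flat track: no calls, composition CgCaCa, nonrecombinant
  flat <- segment_and_call(mk_track(rep(1L, 20)), min_run = 3)
  expect_equal(nrow(flat$breakpoints), 0L)
  expect_equal(flat$composition$composition, "CgCaCa")
  expect_false(flat$composition$recombinant)

  ## clean step: exactly one call between windows 20 and 21
  step <- segment_and_call(mk_track(rep(c(1L, 2L), each = 20)), min_run = 3)
  expect_equal(nrow(step$breakpoints), 1L)
  expect_equal(step$breakpoints$int_start, 19 * 1e5)
  expect_equal(step$breakpoints$int_end, 21 * 1e5)
  expect_equal(step$breakpoints$direction, "1->2")

  ## an interior single-window blip is smoothed away
  blip <- segment_and_call(mk_track(c(rep(1L, 9), 2L, rep(1L, 10))),
                           min_run = 3)
  expect_equal(nrow(blip$breakpoints), 0L)

  ## a short terminal run survives (near-end recombination is real signal)
  endrun <- segment_and_call(mk_track(c(rep(1L, 18), 2L, 2L)), min_run = 3)
  expect_equal(nrow(endrun$breakpoints), 1L)

  ## undefined windows inherit the nearest defined state, ties to the left
  filled <- segment_and_call(mk_track(c(1L, NA, NA, NA, 2L, 2L, 2L, 2L),
                                      freqs = c(0.33, NA, NA, NA, 0.67,
                                                0.67, 0.67, 0.67)),
                             min_run = 1)
  ## windows 2 (closer to left) and 3 (tie) go left; window 4 goes right
  expect_equal(filled$segments$n_windows, c(3L, 5L))
})

test_that("the full fit recovers simulated composition and clones match mothers", {
  std <- std_cohort()
  fit <- std$fits[[1L]]
  expect_s3_class(fit, "dosage_fit")
  tc <- truth_composition(std$offspring[[1L]], std$map)
  m <- merge(tc, fit$composition, by = "group")
  scored <- m[m$margin > 1e5, ]
  expect_true(all(scored$composition.x == scored$composition.y))

  ## a gynogenetic clone gets its mother's composition, group by group
  mother <- std$offspring[[1L]]
  clone <- fertilize(make_egg(mother, "unreduced", std$map), NULL,
                     "gynogenetic", id = "clone1")
  cobs <- simulate_observations(clone, std$snps, std$model, seed = 47)
  cfit <- dosage_genotype(cobs, std$parent_obs, std$map)
  expect_equal(cfit$composition$composition, fit$composition$composition)
})

test_that("parental-set attribution separates sexual and clonal generations", {
  std <- std_cohort()
  ## trivial clonality: offspring identical to mother at every locus
  mother <- std$offspring[[1L]]
  m0 <- exact_model(30)
  mobs <- simulate_observations(mother, std$snps, m0, seed = 48)
  gf <- generation_frequencies(
    list(clone = simulate_observations(mother, std$snps, m0, seed = 49)),
    attribution_calls(mobs),
    attribution_calls(simulate_observations(std$founders$caM, std$snps,
                                            m0, seed = 50)))
  expect_gt(gf$n_loci, 100)
  expect_false(gf$low_confidence)
  expect_equal(gf$maternal_freq, 1.0, tolerance = 0.01)
  expect_equal(gf$paternal_freq, 0.0, tolerance = 0.01)
  expect_equal(gf$maternal_sets, 3)
  expect_equal(gf$paternal_sets, 0)

  ## low-confidence flag when almost no loci are parent-diagnostic
  few <- generation_frequencies(
    list(x = std$obs[[1L]][1:50, ]),
    attribution_calls(std$parent_obs$caF)[1:50],
    attribution_calls(std$sa4n_obs)[1:50])
  expect_true(few$low_confidence)
})
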