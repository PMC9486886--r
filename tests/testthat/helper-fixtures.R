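## Small in-code fixtures shared across the suite. All seeds are fixed so
## the suite is deterministic.

tiny_map <- function(n = 2L, len = 1e6) build_genome_map(n, len)

## regular-grid SNP map: exact locus counts, used where exactness matters
grid_snps <- function(map, density = 1e-3, decoy = 0, seed = 11L) {
  sample_snp_map(map, density, decoy, seed = seed, spacing = "grid")
}

exact_model <- function(depth = 30) {
  seq_model(depth, error_rate = 0, ref_bias = 0, fixed_depth = TRUE)
}

## The standard simulation: 50 homolog groups x 2 Mb, diagnostic density
## 1e-3 with 30% decoys, one obligate crossover per bivalent, 20 backcross
## offspring observed at 30x with 0.2% error and 5% reference bias,
## genotyped with 100 kb windows, calibration on, min_run 3.
## Built once per test run (it is the expensive fixture).
.fixture_env <- new.env(parent = emptyenv())

std_cohort <- function() {
  if (!is.null(.fixture_env$std)) return(.fixture_env$std)
  map <- build_genome_map(25L, 2e6)
  snps <- sample_snp_map(map, 1e-3, 0.3, seed = 101L)
  founders <- make_founders(map, snps)
  co <- c("1" = 1)
  sa4n <- make_amphitetraploid(founders$cgF, founders$caM, map, co,
                               seed = 102L)
  offspring <- simulate_backcross_cohort(founders, sa4n, map, 20L, co,
                                         seed = 103L)
  model <- seq_model(30, 0.002, 0.05)
  parent_obs <- list(
    cgF = simulate_observations(founders$cgF, snps, model, seed = 104L),
    caF = simulate_observations(founders$caF, snps, model, seed = 105L),
    caM = simulate_observations(founders$caM, snps, model, seed = 106L))
  sa4n_obs <- simulate_observations(sa4n, snps, model, seed = 107L)
  obs <- lapply(seq_along(offspring), function(i)
    simulate_observations(offspring[[i]], snps, model, seed = 110L + i))
  names(obs) <- names(offspring)
  fits <- lapply(names(offspring), function(id)
    dosage_genotype(obs[[id]], parent_obs, map, window_width = 1e5,
                    calibrate = TRUE, min_run = 3L))
  names(fits) <- names(offspring)
  .fixture_env$std <- list(map = map, snps = snps, founders = founders,
                           sa4n = sa4n, sa4n_obs = sa4n_obs,
                           offspring = offspring, parent_obs = parent_obs,
                           obs = obs, fits = fits, model = model)
  .fixture_env$std
}

## strict homozygosity bounds for parental-set attribution (a polyploid
## parent is homozygous only when all copies agree)
attribution_calls <- function(obs) {
  call_site_genotypes(obs, het_band = c(0.02, 0.98))
}
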