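scenario_schema <- list(
  genome = c("n_groups_per_subgenome", "group_length"),
  snp = c("density", "decoy_fraction"),
  sequencing = c("depth", "error_rate", "ref_bias"),
  meiosis = c("co_count_probs"),
  analysis = c("window", "threshold", "calibrate", "min_run",
               "min_snps_per_window"),
  cohort = c("n_na3n", "n_ga3n", "n_ca3n"),
  seed = character(0)
)

#' Validate a scenario configuration
#'
#' Checks presence and ranges of every required field; errors name the
#' offending field by its path (e.g. `sequencing.depth`).
#' @param config a scenario config list (see [default_scenario_config()]).
#' @return the config, invisibly, if valid.
#' @export
validate_scenario_config <- function(config) {
  for (section in names(scenario_schema)) {
    if (is.null(config[[section]]))
      stop_config("missing required config field: ", section)
    for (field in scenario_schema[[section]]) {
      if (is.null(config[[section]][[field]]))
        stop_config("missing required config field: ", section, ".", field)
    }
  }
  ck <- function(cond, path, msg)
    if (!cond) stop_config("invalid config field ", path, ": ", msg)
  g <- config$genome
  ck(g$n_groups_per_subgenome >= 1, "genome.n_groups_per_subgenome", ">= 1")
  ck(g$group_length > 0, "genome.group_length", "> 0")
  s <- config$snp
  ck(s$density > 0 && s$density <= 0.01, "snp.density", "in (0, 0.01]")
  ck(s$decoy_fraction >= 0 && s$decoy_fraction < 1, "snp.decoy_fraction",
     "in [0, 1)")
  q <- config$sequencing
  ck(q$depth > 0, "sequencing.depth", "> 0")
  ck(q$error_rate >= 0 && q$error_rate < 0.5, "sequencing.error_rate",
     "in [0, 0.5)")
  ck(q$ref_bias >= 0 && q$ref_bias < 1, "sequencing.ref_bias", "in [0, 1)")
  co <- unlist(config$meiosis$co_count_probs)
  ck(length(co) > 0 && all(co >= 0) && sum(co) > 0, "meiosis.co_count_probs",
     "non-empty probability vector")
  a <- config$analysis
  ck(a$window > 0, "analysis.window", "> 0")
  ck(a$threshold > 0 && a$threshold < 1, "analysis.threshold", "in (0, 1)")
  ck(a$min_run >= 1, "analysis.min_run", ">= 1")
  ck(all(unlist(config$cohort) >= 1), "cohort", "sizes >= 1")
  ck(is.numeric(config$seed), "seed", "integer seed")
  invisible(config)
}

#' The bundled paper-default scenario
#'
#' 50 homolog groups of 2 Mb, diagnostic SNP density 1e-3 with 30% decoys,
#' 30x Poisson depth with 0.2% base error and 5% reference bias, 1-2
#' crossovers per bivalent, 100 kb windows with calibration, and cohorts of
#' 10 NA3n + 10 GA3n + 10 CA3n.
#' @return a scenario config list.
#' @export
default_scenario_config <- function() {
  list(genome = list(n_groups_per_subgenome = 25L, group_length = 2e6),
       snp = list(density = 1e-3, decoy_fraction = 0.3),
       sequencing = list(depth = 30, error_rate = 0.002, ref_bias = 0.05),
       meiosis = list(co_count_probs = list("1" = 0.5, "2" = 0.5)),
       analysis = list(window = 1e5, threshold = 0.5, calibrate = TRUE,
                       min_run = 3L, min_snps_per_window = 2L),
       cohort = list(n_na3n = 10L, n_ga3n = 10L, n_ca3n = 10L),
       seed = 20220901L)
}

stage_seed <- function(seed, k) (as.integer(seed) %% 2000000L) * 1000L + k

#' Run a full simulation-plus-inference scenario
#'
#' The end-to-end reproduction of the study workflow on synthetic data:
#' founder genomes, genome addition to the amphitetraploid male, a sexual
#' backcross cohort (NA3n) and two successive gynogenetic generations
#' (GA3n, CA3n), read-count simulation for every individual, dosage
#' genotyping of every offspring, generation-wise parental attribution,
#' cohort composition summary and the IBS similarity matrix. All outputs
#' are written to `out_dir` as plain-text tables plus a manifest of
#' parameter values and output checksums. Deterministic given the config
#' seed.
#'
#' @param config a scenario config list, or the path to a YAML file with
#'   the same structure (see [default_scenario_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with every in-memory product (`map`, `snps`,
#'   `founders`, `individuals`, `fits`, `generation_report`, `summary`,
#'   `ibs`, `recovery`).
#' @export
run_scenario <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_scenario_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[polypaint] ", ...)
  seed <- config$seed
  co <- unlist(config$meiosis$co_count_probs)
  model <- seq_model(config$sequencing$depth, config$sequencing$error_rate,
                     config$sequencing$ref_bias)

  say("building genome map and diagnostic SNP map")
  map <- build_genome_map(config$genome$n_groups_per_subgenome,
                          config$genome$group_length)
  snps <- sample_snp_map(map, config$snp$density, config$snp$decoy_fraction,
                         seed = stage_seed(seed, 1L))
  founders <- make_founders(map, snps)

  say("genome addition -> amphitetraploid male")
  sa4n <- make_amphitetraploid(founders$cgF, founders$caM, map, co,
                               seed = stage_seed(seed, 2L))
  say("backcross cohort (", config$cohort$n_na3n, " NA3n)")
  na3n <- simulate_backcross_cohort(founders, sa4n, map,
                                    config$cohort$n_na3n, co,
                                    seed = stage_seed(seed, 3L))
  females <- Filter(function(x) individual_sex(x, map) == "female", na3n)
  if (length(females) == 0L) {
    ## breed further backcross offspring until a female arises; she serves
    ## as the gynogenesis founder but is not part of the reported cohort
    say("no female in the NA3n cohort; breeding extra offspring")
    extra <- simulate_backcross_cohort(founders, sa4n, map, 64L, co,
                                       seed = stage_seed(seed, 4L))
    females <- Filter(function(x) individual_sex(x, map) == "female", extra)
    if (length(females) == 0L) stop("no NA3n female available")
    females[[1L]]$id <- "NA3n_gm"
  }
  ga_mother <- females[[1L]]
  ga3n <- simulate_gynogenetic_cohort(ga_mother, founders$caM, map,
                                      config$cohort$n_ga3n, "GA3N", "GA3n")
  ca3n <- simulate_gynogenetic_cohort(ga3n[[1L]], founders$caM, map,
                                      config$cohort$n_ca3n, "CA3N", "CA3n")
  individuals <- c(list(Cg_F = founders$cgF, Ca_F = founders$caF,
                        Ca_M = founders$caM, SA4n_M = sa4n),
                   na3n, ga3n, ca3n)
  if (!ga_mother$id %in% names(individuals))
    individuals[[ga_mother$id]] <- ga_mother

  say("simulating read counts (", length(individuals), " individuals)")
  obs <- lapply(seq_along(individuals), function(i)
    simulate_observations(individuals[[i]], snps, model,
                          seed = stage_seed(seed, 100L + i)))
  names(obs) <- names(individuals)
  calls <- lapply(obs, call_site_genotypes)

  say("dosage genotyping of all offspring")
  parent_obs <- obs[c("Cg_F", "Ca_F", "Ca_M")]
  names(parent_obs) <- c("cgF", "caF", "caM")
  offspring_ids <- c(names(na3n), names(ga3n), names(ca3n))
  fits <- lapply(offspring_ids, function(id)
    dosage_genotype(obs[[id]], parent_obs, map,
                    window_width = config$analysis$window,
                    min_snps_per_window = config$analysis$min_snps_per_window,
                    threshold = config$analysis$threshold,
                    calibrate = config$analysis$calibrate,
                    min_run = config$analysis$min_run))
  names(fits) <- offspring_ids

  say("generation-wise parental attribution")
  ## strict homozygosity bounds for attribution: in a polyploid parent,
  ## "homozygous" means every copy carries the allele, so only near-fixed
  ## read fractions qualify (a 3/4-dosage tetraploid site must not pass)
  acall <- function(id) call_site_genotypes(obs[[id]],
                                            het_band = c(0.02, 0.98))
  gen_report <- rbind(
    cbind(generation = "NA3N",
          generation_frequencies(obs[names(na3n)], acall("Ca_F"),
                                 acall("SA4n_M"))),
    cbind(generation = "GA3N",
          generation_frequencies(obs[names(ga3n)], acall(ga_mother$id),
                                 acall("Ca_M"))),
    cbind(generation = "CA3N",
          generation_frequencies(obs[names(ca3n)],
                                 acall(ga3n[[1L]]$id), acall("Ca_M"))))

  say("cohort summaries")
  summary_na <- summarize_composition(fits[names(na3n)])
  ibs <- ibs_matrix(dosage_fraction_matrix(
    obs, fits[[1L]]$mask,
    ploidy = vapply(individuals[names(obs)], ploidy, 1L)))
  recovery <- recovery_report(na3n, fits[names(na3n)], map)

  say("writing outputs to ", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_genome_map(map, p("genome_map.tsv"))
  write_snp_map(snps, p("snp_map.tsv"))
  truth <- do.call(rbind, lapply(individuals, function(ind) {
    tmp <- tempfile(); on.exit(unlink(tmp))
    export_truth_segments(ind, tmp)
    utils::read.table(tmp, header = TRUE, sep = "\t")
  }))
  utils::write.table(truth, p("truth_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_variant_table(snps, obs, calls, p("variant_table.tsv"), "tsv")
  tracks <- do.call(rbind, lapply(fits, function(f) {
    tr <- f$track; tr$individual <- f$id
    tr$state <- f$track$state
    tr
  }))
  utils::write.table(tracks, p("window_tracks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  comps <- do.call(rbind, lapply(fits, function(f) {
    cc <- f$composition; cc$individual <- f$id; cc
  }))
  utils::write.table(comps, p("composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bps <- do.call(rbind, lapply(fits, function(f) {
    if (nrow(f$breakpoints) == 0L) return(NULL)
    data.frame(chrom = f$breakpoints$group,
               chromStart = as.integer(f$breakpoints$int_start),
               chromEnd = as.integer(f$breakpoints$int_end),
               name = paste0(f$id, ":", f$breakpoints$direction))
  }))
  if (!is.null(bps))
    utils::write.table(bps, p("breakpoints.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  utils::write.table(gen_report, p("generation_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(metric = c("n_nonrecombinant",
                                           "n_recombinant",
                                           "nonrec_rec_ratio",
                                           "cg_chromosomes",
                                           "ca_chromosomes", "cg_ca_ratio"),
                                value = c(summary_na$n_nonrecombinant,
                                          summary_na$n_recombinant,
                                          summary_na$nonrec_rec_ratio,
                                          summary_na$cg_chromosomes,
                                          summary_na$ca_chromosomes,
                                          summary_na$cg_ca_ratio)),
                     p("composition_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(unclass(ibs)), p("ibs_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, p("manifest.yaml"))
  manifest <- list(parameters = config,
                   outputs = as.list(tools::md5sum(outputs)))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  say("done")
  invisible(list(map = map, snps = snps, founders = founders, sa4n = sa4n,
                 individuals = individuals, obs = obs, calls = calls,
                 fits = fits, generation_report = gen_report,
                 summary = summary_na, ibs = ibs, recovery = recovery))
}
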