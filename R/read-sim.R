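#' Sequencing model for simulated allele read counts
#'
#' @param mean_depth expected reads per site (Poisson mean, or the exact
#'   depth in fixed-depth mode).
#' @param error_rate per-read probability of reporting the other allele
#'   (in `[0, 0.5)`).
#' @param ref_bias probability that a read reporting the Cg (non-reference)
#'   allele is lost to mapping failure (in `[0, 1)`). Models the skew of
#'   SNP frequencies toward the goldfish genotype caused by reads mapping
#'   to the goldfish reference assembly.
#' @param fixed_depth if `TRUE`, every site gets exactly `mean_depth` reads.
#' @return a `seq_model` list.
#' @export
seq_model <- function(mean_depth = 30, error_rate = 0.002, ref_bias = 0.05,
                      fixed_depth = FALSE) {
  if (mean_depth < 0) stop_config("mean_depth must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_config("error_rate must be in [0, 0.5)")
  if (ref_bias < 0 || ref_bias >= 1)
    stop_config("ref_bias must be in [0, 1)")
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 ref_bias = ref_bias, fixed_depth = isTRUE(fixed_depth)),
            class = "seq_model")
}

#' Simulate per-site allele read counts for one individual
#'
#' Per locus: depth is Poisson (or fixed); each read samples one chromosome
#' copy uniformly and reports that copy's allele, flips to the other allele
#' with probability `error_rate`, and is then discarded with probability
#' `ref_bias` if it reports the Cg allele. Equivalently (and as
#' implemented), raw Cg read counts are Binomial(depth, d/p (1-e) +
#' (1-d/p) e) for dosage `d` and ploidy `p`, thinned by `1 - ref_bias`.
#'
#' @param ind an `individual` or `gamete`.
#' @param snps an `snp_map`.
#' @param model a [seq_model()].
#' @param seed optional seed.
#' @return an `snp_obs` data.frame: `group`, `pos`, `cg`, `ca` read counts
#'   aligned with the SNP map rows; attribute `id` carries the individual id.
#' @export
simulate_observations <- function(ind, snps, model = seq_model(),
                                  seed = NULL) {
  stopifnot(inherits(model, "seq_model"))
  d <- cg_dosage(ind, snps)
  p <- ploidy(ind)
  n <- nrow(snps)
  with_seed_(seed, {
    depth <- if (model$fixed_depth) rep(as.integer(model$mean_depth), n)
             else stats::rpois(n, model$mean_depth)
    frac <- d / p
    p_cg <- frac * (1 - model$error_rate) + (1 - frac) * model$error_rate
    cg_raw <- stats::rbinom(n, depth, p_cg)
    ca <- depth - cg_raw
    cg <- if (model$ref_bias > 0)
      stats::rbinom(n, cg_raw, 1 - model$ref_bias) else cg_raw
    obs <- data.frame(group = snps$group, pos = snps$pos, cg = cg, ca = ca,
                      stringsAsFactors = FALSE)
    attr(obs, "id") <- ind$id %||% "gamete"
    class(obs) <- c("snp_obs", "data.frame")
    obs
  })
}

#' Hard genotype calls from allele read counts
#'
#' @param obs an `snp_obs` table.
#' @param min_depth sites with fewer total reads are `missing`.
#' @param het_band `c(lo, hi)`: `hom_ca` if the Cg read fraction is `<= lo`,
#'   `hom_cg` if `>= hi`, `het` otherwise.
#' @return character vector of calls (`hom_cg`, `hom_ca`, `het`,
#'   `missing`) aligned with `obs` rows.
#' @export
call_site_genotypes <- function(obs, min_depth = 5, het_band = c(0.1, 0.9)) {
  if (length(het_band) != 2 || het_band[1] < 0 || het_band[2] > 1 ||
      het_band[1] >= het_band[2])
    stop_config("het_band must be (lo, hi) with 0 <= lo < hi <= 1")
  depth <- obs$cg + obs$ca
  frac <- ifelse(depth > 0, obs$cg / depth, NA_real_)
  call <- rep("het", nrow(obs))
  call[frac <= het_band[1]] <- "hom_ca"
  call[frac >= het_band[2]] <- "hom_cg"
  call[depth < min_depth] <- "missing"
  call
}

gt_codes <- c(hom_ca = "0/0", het = "0/1", hom_cg = "1/1", missing = "./.")

#' Write a multi-sample variant table (VCF dialect or TSV mirror)
#'
#' The VCF dialect: one biallelic record per locus, 1-based positions,
#' `REF` = the Ca (goldfish reference) allele, `ALT` = the Cg allele,
#' per-sample `GT:AD` with `AD` ordered (ca, cg). The TSV mirror carries
#' the same columns (`<id>_ca`, `<id>_cg`, `<id>_gt` per sample) and
#' round-trips losslessly through [read_variant_table()].
#'
#' @param snps an `snp_map`.
#' @param obs_list named list of `snp_obs` (one per sample, rows aligned
#'   with `snps`).
#' @param calls_list named list of call vectors (same names as `obs_list`).
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @export
write_variant_table <- function(snps, obs_list, calls_list, path,
                                format = c("vcf", "tsv")) {
  format <- match.arg(format)
  ids <- names(obs_list)
  if (is.null(ids) || !identical(sort(ids), sort(names(calls_list))))
    stop_config("obs_list and calls_list must share sample names")
  for (id in ids)
    if (nrow(obs_list[[id]]) != nrow(snps))
      stop_config("sample ", id, " is not aligned with the SNP map")
  if (format == "tsv") {
    out <- data.frame(group = snps$group, pos0 = snps$pos,
                      ca_allele = snps$ca_allele, cg_allele = snps$cg_allele)
    for (id in ids) {
      out[[paste0(id, "_ca")]] <- obs_list[[id]]$ca
      out[[paste0(id, "_cg")]] <- obs_list[[id]]$cg
      out[[paste0(id, "_gt")]] <- calls_list[[id]]
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", unique(snps$group), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                     "Description=\"Allelic depths (ref=Ca,alt=Cg)\">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  sample_cols <- lapply(ids, function(id)
    paste0(gt_codes[calls_list[[id]]], ":",
           obs_list[[id]]$ca, ",", obs_list[[id]]$cg))
  body <- do.call(paste, c(list(snps$group, snps$pos + 1L, ".",
                                snps$ca_allele, snps$cg_allele,
                                ".", ".", ".", "GT:AD"),
                           sample_cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return list with `snps` (group/pos/cg_allele/ca_allele), `obs` (named
#'   list of `snp_obs`) and `calls` (named list of call vectors).
#' @export
read_variant_table <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    snps <- data.frame(group = df$group, pos = df$pos0,
                       cg_allele = df$cg_allele, ca_allele = df$ca_allele,
                       stringsAsFactors = FALSE)
    ids <- sub("_gt$", "", grep("_gt$", names(df), value = TRUE))
    obs <- lapply(ids, function(id) {
      o <- data.frame(group = df$group, pos = df$pos0,
                      cg = df[[paste0(id, "_cg")]],
                      ca = df[[paste0(id, "_ca")]])
      attr(o, "id") <- id
      class(o) <- c("snp_obs", "data.frame")
      o
    })
    calls <- lapply(ids, function(id) df[[paste0(id, "_gt")]])
    return(list(snps = snps, obs = stats::setNames(obs, ids),
                calls = stats::setNames(calls, ids)))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  head_fields <- strsplit(sub("^#", "", body[1L]), "\t")[[1L]]
  ids <- head_fields[-(1:9)]
  rec <- do.call(rbind, strsplit(body[-1L], "\t"))
  if (any(rec[, 9L] != "GT:AD")) stop("malformed record: FORMAT must be GT:AD")
  snps <- data.frame(group = rec[, 1L], pos = as.integer(rec[, 2L]) - 1L,
                     cg_allele = rec[, 5L], ca_allele = rec[, 4L],
                     stringsAsFactors = FALSE)
  obs <- list(); calls <- list()
  for (k in seq_along(ids)) {
    parts <- strsplit(rec[, 9L + k], ":")
    gt <- vapply(parts, `[`, "", 1L)
    ad <- do.call(rbind, strsplit(vapply(parts, `[`, "", 2L), ","))
    o <- data.frame(group = snps$group, pos = snps$pos,
                    cg = as.integer(ad[, 2L]), ca = as.integer(ad[, 1L]))
    attr(o, "id") <- ids[k]
    class(o) <- c("snp_obs", "data.frame")
    obs[[ids[k]]] <- o
    calls[[ids[k]]] <- names(gt_codes)[match(gt, gt_codes)]
  }
  list(snps = snps, obs = obs, calls = calls)
}
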