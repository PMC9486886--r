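#' Ground-truth composition of a simulated individual
#'
#' Reads the truth straight off the segment mosaics: per homolog group, the
#' number of copies whose majority origin (by segment length) is CG, the
#' composition label, whether any copy is a CG/CA mosaic, the origin of
#' each copy's centromere (position 0), and the decidability margin -- the
#' smallest |CG length - CA length| over the group's copies. A group whose
#' mosaic copy is split close to 50:50 has no meaningful majority
#' composition; downstream accuracy is assessed on groups whose margin
#' exceeds one window.
#'
#' @param ind a simulated `individual`.
#' @param map the `genome_map`.
#' @return data.frame: `group`, `n_cg_major`, `composition`, `recombinant`,
#'   `cg_centromeres`, `margin`.
#' @export
truth_composition <- function(ind, map) {
  rows <- lapply(names(ind$copies), function(g) {
    len <- group_length_of(map, g)
    cps <- ind$copies[[g]]
    cg_len <- vapply(cps, function(cp)
      sum((cp$end - cp$start)[cp$origin == "CG"]), 1.0)
    maj_cg <- cg_len > len / 2
    n_cg <- sum(maj_cg)
    n <- length(cps)
    comp <- paste0(strrep("Cg", n_cg), strrep("Ca", n - n_cg))
    data.frame(group = g, n_cg_major = n_cg, composition = comp,
               recombinant = any(vapply(cps, copy_is_recombinant, TRUE)),
               cg_centromeres = sum(vapply(cps, function(cp)
                 cp$origin[1L] == "CG", TRUE)),
               margin = min(abs(2 * cg_len - len)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ground-truth recombination breakpoints of a simulated individual
#'
#' Positions where a chromosome copy switches founder origin (CG/CA) --
#' the only exchanges visible to dosage genotyping, since crossovers
#' between same-origin copies leave the diagnostic-allele dosage unchanged.
#' @param ind a simulated `individual`.
#' @return data.frame `group`, `copy`, `pos` (possibly 0 rows).
#' @export
truth_breakpoints <- function(ind) {
  rows <- list()
  for (g in names(ind$copies)) {
    for (k in seq_along(ind$copies[[g]])) {
      cp <- ind$copies[[g]][[k]]
      sw <- which(cp$origin[-1L] != cp$origin[-nrow(cp)])
      if (length(sw))
        rows[[length(rows) + 1L]] <- data.frame(group = g, copy = k,
                                                pos = cp$end[sw])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(group = character(), copy = integer(), pos = numeric()))
  do.call(rbind, rows)
}

#' Export per-copy truth segments as TSV
#' @param ind a simulated `individual`.
#' @param path output file.
#' @export
export_truth_segments <- function(ind, path) {
  rows <- list()
  for (g in names(ind$copies)) {
    for (k in seq_along(ind$copies[[g]])) {
      cp <- ind$copies[[g]][[k]]
      rows[[length(rows) + 1L]] <-
        data.frame(individual = ind$id, group = g, copy = k,
                   start = cp$start, end = cp$end, origin = cp$origin,
                   founder = cp$founder)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cohort composition summary
#'
#' Pools per-individual composition tables from [dosage_genotype()] fits:
#' the nonrecombinant:recombinant homolog-group ratio and the Cg:Ca
#' derived-chromosome ratio (CgCgCa contributes 2 Cg + 1 Ca, CgCaCa
#' contributes 1 Cg + 2 Ca), both computed over callable groups only.
#'
#' @param fits list of `dosage_fit` objects.
#' @return a `composition_summary` list: counts, ratios (`NA` when a
#'   denominator is zero; counts are always reported), and the per-group x
#'   individual composition table.
#' @export
summarize_composition <- function(fits) {
  if (length(fits) == 0L) stop_config("empty cohort")
  comp <- do.call(rbind, lapply(fits, function(f) {
    cc <- f$composition
    cc$id <- f$id %||% "?"
    cc
  }))
  cc <- comp[comp$callable & !is.na(comp$composition), , drop = FALSE]
  n_rec <- sum(cc$recombinant)
  n_nonrec <- sum(!cc$recombinant)
  cg <- sum(ifelse(cc$composition == "CgCgCa", 2L, 1L))
  ca <- sum(ifelse(cc$composition == "CgCgCa", 1L, 2L))
  per_group <- tapply(comp$composition,
                      list(factor(comp$group, levels = unique(comp$group)),
                           factor(comp$id, levels = unique(comp$id))),
                      function(v) v[1L])
  structure(list(
    n_individuals = length(fits),
    n_groups_callable = nrow(cc),
    n_nonrecombinant = n_nonrec, n_recombinant = n_rec,
    nonrec_rec_ratio = if (n_rec > 0) n_nonrec / n_rec else NA_real_,
    cg_chromosomes = cg, ca_chromosomes = ca,
    cg_ca_ratio = if (ca > 0) cg / ca else NA_real_,
    per_group = per_group,
    composition_table = comp), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals, %d callable groups\n",
              x$n_individuals, x$n_groups_callable))
  cat(sprintf("  nonrecombinant:recombinant = %d:%d (ratio %s)\n",
              x$n_nonrecombinant, x$n_recombinant,
              format(x$nonrec_rec_ratio, digits = 3)))
  cat(sprintf("  Cg:Ca chromosomes = %d:%d (ratio %s)\n",
              x$cg_chromosomes, x$ca_chromosomes,
              format(x$cg_ca_ratio, digits = 3)))
  invisible(x)
}

#' Dosage-fraction matrix across individuals
#'
#' Per-locus CG-allele dosage fraction estimates `cg / (cg + ca)` for a set
#' of individuals (NA at zero-depth sites), optionally restricted to the
#' kept loci of an effective-SNP mask. When each individual's ploidy is
#' supplied, fractions are rounded to the nearest attainable genotype
#' dosage (`round(ploidy * frac) / ploidy`), which is the discrete dosage
#' call the similarity analysis operates on; raw fractions are returned
#' otherwise. The input of [ibs_matrix()].
#' @param obs_list named list of `snp_obs` tables on a shared locus set.
#' @param mask optional effective-SNP mask.
#' @param ploidy optional integer vector of per-individual ploidies (named
#'   or positional, recycled if length 1).
#' @return numeric matrix, loci x individuals.
#' @export
dosage_fraction_matrix <- function(obs_list, mask = NULL, ploidy = NULL) {
  if (!is.null(ploidy)) {
    ploidy <- rep_len(ploidy, length(obs_list))
    if (!is.null(names(obs_list)) && !is.null(names(ploidy)) &&
        all(names(obs_list) %in% names(ploidy)))
      ploidy <- ploidy[names(obs_list)]
  }
  p <- vapply(seq_along(obs_list), function(k) {
    o <- obs_list[[k]]
    depth <- o$cg + o$ca
    frac <- ifelse(depth > 0, o$cg / depth, NA_real_)
    if (is.null(ploidy)) frac else round(ploidy[k] * frac) / ploidy[k]
  }, numeric(nrow(obs_list[[1L]])))
  colnames(p) <- names(obs_list)
  if (!is.null(mask)) p <- p[mask$keep, , drop = FALSE]
  p
}

#' Identity-by-state similarity matrix on dosage fractions
#'
#' `IBS(i, j) = 1 - mean over loci of |p_i - p_j|`, where `p` is the
#' CG-allele dosage fraction at the locus. This generalizes identity-by-
#' state to mixed ploidies: identical genomes score exactly 1, fully
#' opposite homozygotes score 0. Loci missing in either individual are
#' pairwise-deleted.
#'
#' @param p numeric matrix of dosage fractions, loci x individuals (see
#'   [dosage_fraction_matrix()]), with column names.
#' @return symmetric `similarity_matrix` with unit diagonal.
#' @export
ibs_matrix <- function(p) {
  if (ncol(p) < 2L) stop_config("IBS needs at least 2 individuals")
  n <- ncol(p)
  m <- diag(1, n)
  dimnames(m) <- list(colnames(p), colnames(p))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- abs(p[, i] - p[, j])
      if (all(is.na(d))) stop_config("no shared loci between ",
                                     colnames(p)[i], " and ", colnames(p)[j])
      m[i, j] <- m[j, i] <- 1 - mean(d, na.rm = TRUE)
    }
  }
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Truth-versus-inferred validation report
#'
#' For matched simulated individuals and their dosage fits: per-group
#' composition accuracy (over groups whose truth majority is decidable at
#' window resolution, i.e. margin > one window; ties are reported, not
#' graded), breakpoint recall and precision at a +/- 1-window tolerance,
#' and the breakpoint localization error distribution (distance, in
#' windows, from each true visible breakpoint to the nearest inferred
#' breakpoint interval; 0 when inside).
#'
#' @param individuals named list of simulated `individual`s.
#' @param fits list of matching `dosage_fit`s (matched by `id`).
#' @param map the `genome_map`.
#' @return a list: `composition_accuracy`, `n_groups_scored`,
#'   `n_groups_ambiguous`, `breakpoint_recall`, `breakpoint_precision`,
#'   `localization_errors`, `details`.
#' @export
recovery_report <- function(individuals, fits, map) {
  fit_ids <- vapply(fits, function(f) f$id %||% "?", "")
  if (!all(names(individuals) %in% fit_ids))
    stop_config("individual ids do not match fit ids")
  w <- attr(fits[[1L]]$track, "window_width")
  n_ok <- 0L; n_scored <- 0L; n_amb <- 0L
  tp <- 0L; n_truth <- 0L; n_called <- 0L; n_called_matched <- 0L
  loc_err <- numeric(0)
  details <- list()
  for (id in names(individuals)) {
    ind <- individuals[[id]]
    fit <- fits[[match(id, fit_ids)]]
    tc <- truth_composition(ind, map)
    tb <- truth_breakpoints(ind)
    cc <- fit$composition
    m <- merge(tc, cc, by = "group")
    m <- m[m$callable, , drop = FALSE]
    amb <- m$margin <= w
    n_amb <- n_amb + sum(amb)
    scored <- m[!amb, , drop = FALSE]
    n_scored <- n_scored + nrow(scored)
    n_ok <- n_ok + sum(scored$composition.x == scored$composition.y)
    ## breakpoints
    bp <- fit$breakpoints
    n_called <- n_called + nrow(bp)
    if (nrow(tb)) {
      n_truth <- n_truth + nrow(tb)
      for (i in seq_len(nrow(tb))) {
        cand <- bp[bp$group == tb$group[i], , drop = FALSE]
        if (nrow(cand) == 0L) { loc_err <- c(loc_err, Inf); next }
        err <- pmax(0, pmax(cand$int_start - tb$pos[i],
                            tb$pos[i] - cand$int_end)) / w
        loc_err <- c(loc_err, min(err))
        if (min(err) <= 1) tp <- tp + 1L
      }
    }
    if (nrow(bp)) {
      for (i in seq_len(nrow(bp))) {
        cand <- tb[tb$group == bp$group[i], , drop = FALSE]
        if (nrow(cand) && any(cand$pos >= bp$int_start[i] - w &
                                cand$pos <= bp$int_end[i] + w))
          n_called_matched <- n_called_matched + 1L
      }
    }
    details[[id]] <- m
  }
  list(composition_accuracy = if (n_scored) n_ok / n_scored else NA_real_,
       n_groups_scored = n_scored, n_groups_ambiguous = n_amb,
       breakpoint_recall = if (n_truth) tp / n_truth else NA_real_,
       breakpoint_precision = if (n_called) n_called_matched / n_called
                              else NA_real_,
       localization_errors = loc_err,
       details = details)
}
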