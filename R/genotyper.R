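#' Select effective loci for chromosome genotyping
#'
#' In `triple_parent` mode a locus is kept only if it satisfies, in order:
#' (i) the Cg female, Ca female and Ca male genotypes are all homozygous;
#' (ii) the Ca female and Ca male genotypes are the same; (iii) the Cg and
#' Ca genotypes differ; (iv) the triploid offspring genotype is
#' heterozygous. In `pairwise_parent` mode (used for later generations) a
#' locus is kept if the two parents are homozygous for different alleles.
#' Any missing call fails with reason `depth`.
#'
#' @param parent_calls named list of call vectors. Triple mode requires
#'   elements `cgF`, `caF`, `caM`; pairwise mode requires `mother`,
#'   `father`.
#' @param offspring_calls call vector for the offspring (triple mode only).
#' @param mode `"triple_parent"` or `"pairwise_parent"`.
#' @return an effective-SNP mask: data.frame with `keep` (logical) and
#'   `reason` (`"i"`, `"ii"`, `"iii"`, `"iv"`, `"depth"`, or `NA` when
#'   kept).
#' @export
select_effective_snps <- function(parent_calls, offspring_calls = NULL,
                                  mode = c("triple_parent",
                                           "pairwise_parent")) {
  mode <- match.arg(mode)
  hom <- function(x) x %in% c("hom_cg", "hom_ca")
  if (mode == "triple_parent") {
    need <- c("cgF", "caF", "caM")
    if (!all(need %in% names(parent_calls)))
      stop_config("triple_parent mode needs calls cgF, caF, caM")
    if (is.null(offspring_calls))
      stop_config("triple_parent mode needs offspring calls")
    cg <- parent_calls$cgF; ca1 <- parent_calls$caF; ca2 <- parent_calls$caM
    ns <- unique(c(length(cg), length(ca1), length(ca2),
                   length(offspring_calls)))
    if (length(ns) != 1L) stop_config("call vectors differ in length")
    reason <- rep(NA_character_, ns)
    miss <- cg == "missing" | ca1 == "missing" | ca2 == "missing" |
      offspring_calls == "missing"
    reason[is.na(reason) & miss] <- "depth"
    reason[is.na(reason) & !(hom(cg) & hom(ca1) & hom(ca2))] <- "i"
    reason[is.na(reason) & ca1 != ca2] <- "ii"
    reason[is.na(reason) & cg == ca1] <- "iii"
    reason[is.na(reason) & offspring_calls != "het"] <- "iv"
  } else {
    need <- c("mother", "father")
    if (!all(need %in% names(parent_calls)))
      stop_config("pairwise_parent mode needs calls mother, father")
    m <- parent_calls$mother; f <- parent_calls$father
    if (length(m) != length(f)) stop_config("call vectors differ in length")
    reason <- rep(NA_character_, length(m))
    reason[m == "missing" | f == "missing"] <- "depth"
    reason[is.na(reason) & !(hom(m) & hom(f))] <- "i"
    reason[is.na(reason) & m == f] <- "iii"
  }
  data.frame(keep = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

in_mask_regions <- function(group, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (group == regions$group[i] & pos >= regions$start[i] &
                    pos < regions$end[i])
  }
  hit
}

#' Windowed mean Cg-derived SNP frequencies
#'
#' Tiles every homolog group with fixed-width windows and averages, over
#' the kept and unmasked loci in each window, the per-site Cg read fraction
#' `cg / (cg + ca)`. Zero-depth loci are skipped. A window with fewer than
#' `min_snps_per_window` contributing loci is undefined (`NA`).
#'
#' @param obs an `snp_obs` table for one individual.
#' @param mask effective-SNP mask from [select_effective_snps()] (or `NULL`
#'   to use every locus).
#' @param map the `genome_map`.
#' @param window_width window width in bp (1 Mb genome-wide or 100 kb along
#'   one chromosome at real scale; the scaled-down simulations use 100 kb).
#' @param min_snps_per_window minimum contributing loci per defined window.
#' @param mask_regions optional BED-like data.frame (`group`, `start`,
#'   `end`, 0-based half-open) of regions excluded before averaging, the
#'   generalization of masking a repeat-divergent chromosome arm.
#' @return a `window_track` data.frame: `group`, `start`, `end`, `n_snps`,
#'   `cg_freq` (NA when undefined).
#' @export
window_frequencies <- function(obs, mask = NULL, map,
                               window_width = 1e5, min_snps_per_window = 2,
                               mask_regions = NULL) {
  if (window_width <= 0) stop_config("window_width must be positive")
  keep <- if (is.null(mask)) rep(TRUE, nrow(obs)) else mask$keep
  depth <- obs$cg + obs$ca
  use <- keep & depth > 0 & !in_mask_regions(obs$group, obs$pos, mask_regions)
  frac <- obs$cg / pmax(depth, 1L)
  tracks <- lapply(seq_len(nrow(map)), function(i) {
    g <- map$group[i]; len <- map$length[i]
    starts <- seq(0, len - 1, by = window_width)
    ends <- pmin(starts + window_width, len)
    rows <- which(obs$group == g & use)
    win <- findInterval(obs$pos[rows], starts)
    n <- tabulate(win, nbins = length(starts))
    s <- rep(NA_real_, length(starts))
    if (length(rows)) {
      sums <- tapply(frac[rows], factor(win, levels = seq_along(starts)), sum)
      s <- ifelse(n >= max(1L, min_snps_per_window),
                  as.numeric(sums) / n, NA_real_)
    }
    data.frame(group = g, start = starts, end = ends, n_snps = n,
               cg_freq = s, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, tracks)
  attr(track, "window_width") <- window_width
  attr(track, "id") <- attr(obs, "id")
  class(track) <- c("window_track", "data.frame")
  track
}

#' Classify per-window Cg copy dosage
#'
#' In a triploid, a window averaging near 1/3 carries one Cg-derived copy
#' (state 1) and a window near 2/3 carries two (state 2). With
#' `calibrate = TRUE`, the decision threshold is replaced by the midpoint
#' of the two genome-wide frequency modes (2-means on the defined window
#' frequencies), which absorbs the systematic skew toward the goldfish
#' genotype caused by reference-mapping bias. Windows at exactly the
#' threshold take state 2.
#'
#' @param track a `window_track`.
#' @param threshold fixed decision threshold in (0, 1).
#' @param calibrate replace `threshold` by the midpoint of the two
#'   genome-wide modes.
#' @return the track with a `state` column (1, 2, or NA); the threshold
#'   actually used is in attribute `threshold_used`, and groups with no
#'   defined window are listed in attribute `uncallable_groups`.
#' @export
classify_dosage <- function(track, threshold = 0.5, calibrate = FALSE) {
  if (threshold <= 0 || threshold >= 1)
    stop_config("threshold must be in (0, 1)")
  x <- track$cg_freq[!is.na(track$cg_freq)]
  thr <- threshold
  if (calibrate && length(x) >= 4) {
    km <- stats::kmeans(x, centers = matrix(stats::quantile(x, c(.25, .75)),
                                            ncol = 1))
    ctr <- sort(km$centers[, 1L])
    ## two clearly separated modes are needed for calibration to be
    ## meaningful; otherwise keep the fixed threshold
    if (diff(ctr) > 0.05) thr <- mean(ctr)
  }
  track$state <- ifelse(is.na(track$cg_freq), NA_integer_,
                        ifelse(track$cg_freq < thr, 1L, 2L))
  defined <- tapply(!is.na(track$state), track$group, any)
  attr(track, "threshold_used") <- thr
  attr(track, "uncallable_groups") <- names(defined)[!defined]
  track
}

## Fill undefined windows from the nearest defined one (ties -> left),
## then merge interior runs shorter than min_run into the longer
## neighbor (ties -> left). Terminal runs are exempt from merging:
## near-end recombination produces short terminal runs and is a real,
## expected signal.
smooth_states <- function(states, min_run) {
  def <- which(!is.na(states))
  if (length(def) == 0L) return(states)
  for (i in which(is.na(states))) {
    d <- abs(def - i)
    states[i] <- states[def[which.min(d)]]  # which.min takes first = left
  }
  repeat {
    r <- rle(states)
    k <- length(r$lengths)
    if (k <= 2L) break
    interior <- 2:(k - 1L)
    short <- interior[r$lengths[interior] < min_run]
    if (length(short) == 0L) break
    j <- short[which.min(r$lengths[short])]
    nb <- if (r$lengths[j - 1L] >= r$lengths[j + 1L]) j - 1L else j + 1L
    ends <- cumsum(r$lengths)
    idx <- (ends[j] - r$lengths[j] + 1L):ends[j]
    states[idx] <- r$values[nb]
  }
  states
}

#' Segment dosage states and call recombination breakpoints
#'
#' Per homolog group: undefined windows inherit the nearest defined state
#' (ties to the left); interior runs shorter than `min_run` windows are
#' merged into their longer neighbor; each surviving state change emits one
#' recombination call whose breakpoint interval spans the two flanking
#' windows (breakpoints are reported as intervals, never points). Group
#' composition is the majority state (CgCgCa for state 2, CgCaCa for state
#' 1; window-count ties are broken by comparing the group mean frequency to
#' the threshold), and a group is recombinant iff it has at least one call.
#'
#' @param track a classified `window_track` (see [classify_dosage()]).
#' @param min_run minimum interior run length, in windows.
#' @return list with `segments` (group, start, end, cg_copies, n_windows),
#'   `breakpoints` (group, int_start, int_end, direction) and `composition`
#'   (group, composition, n_breakpoints, recombinant, callable).
#' @export
segment_and_call <- function(track, min_run = 3L) {
  if (min_run < 1L) stop_config("min_run must be >= 1")
  thr <- attr(track, "threshold_used") %||% 0.5
  segs <- list(); bps <- list(); comp <- list()
  for (g in unique(track$group)) {
    tg <- track[track$group == g, , drop = FALSE]
    st <- smooth_states(tg$state, min_run)
    if (all(is.na(st))) {
      comp[[g]] <- data.frame(group = g, composition = NA_character_,
                              n_breakpoints = NA_integer_,
                              recombinant = NA, callable = FALSE)
      next
    }
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts_i <- ends - r$lengths + 1L
    segs[[g]] <- data.frame(group = g, start = tg$start[starts_i],
                            end = tg$end[ends], cg_copies = r$values,
                            n_windows = r$lengths, stringsAsFactors = FALSE)
    if (length(r$lengths) > 1L) {
      left_last <- ends[-length(ends)]
      bps[[g]] <- data.frame(
        group = g,
        int_start = tg$start[left_last],
        int_end = tg$end[left_last + 1L],
        direction = paste0(r$values[-length(r$values)], "->", r$values[-1L]),
        stringsAsFactors = FALSE)
    }
    n2 <- sum(st == 2L); n1 <- sum(st == 1L)
    maj <- if (n2 > n1) 2L else if (n1 > n2) 1L else {
      if (mean(tg$cg_freq, na.rm = TRUE) >= thr) 2L else 1L
    }
    nbp <- max(0L, length(r$lengths) - 1L)
    comp[[g]] <- data.frame(
      group = g,
      composition = if (maj == 2L) "CgCgCa" else "CgCaCa",
      n_breakpoints = nbp, recombinant = nbp > 0L, callable = TRUE,
      stringsAsFactors = FALSE)
  }
  empty_bp <- data.frame(group = character(), int_start = numeric(),
                         int_end = numeric(), direction = character())
  list(segments = if (length(segs)) do.call(rbind, c(segs,
         list(make.row.names = FALSE))) else NULL,
       breakpoints = if (length(bps)) do.call(rbind, c(bps,
         list(make.row.names = FALSE))) else empty_bp,
       composition = do.call(rbind, c(comp, list(make.row.names = FALSE))))
}

#' Dosage-genotype one triploid individual (the full inference)
#'
#' Composes the whole inference chain on one offspring: genotype calling of
#' parents and offspring, effective-locus selection by the four criteria,
#' windowed Cg-frequency computation, dosage classification with optional
#' bias calibration, and segmentation into dosage states with recombination
#' calls -- producing the per-group chromosome composition of the
#' individual.
#'
#' @param obs `snp_obs` for the offspring.
#' @param parent_obs named list of parent `snp_obs`: either
#'   `cgF`/`caF`/`caM` (triple mode) or `mother`/`father` (pairwise mode).
#' @param map the `genome_map`.
#' @param mode effective-locus selection mode, see
#'   [select_effective_snps()].
#' @param window_width,min_snps_per_window,mask_regions see
#'   [window_frequencies()].
#' @param threshold,calibrate see [classify_dosage()].
#' @param min_run see [segment_and_call()].
#' @param min_depth,het_band see [call_site_genotypes()].
#' @return a `dosage_fit` object with components `track`, `segments`,
#'   `breakpoints`, `composition`, `mask`, `params`, `id`; it has
#'   `print()`, `summary()` and `plot()` methods.
#' @export
dosage_genotype <- function(obs, parent_obs, map,
                            mode = c("triple_parent", "pairwise_parent"),
                            window_width = 1e5, min_snps_per_window = 2,
                            mask_regions = NULL, threshold = 0.5,
                            calibrate = TRUE, min_run = 3L,
                            min_depth = 5, het_band = c(0.1, 0.9)) {
  mode <- match.arg(mode)
  parent_calls <- lapply(parent_obs, call_site_genotypes,
                         min_depth = min_depth, het_band = het_band)
  off_calls <- call_site_genotypes(obs, min_depth = min_depth,
                                   het_band = het_band)
  mask <- select_effective_snps(parent_calls,
                                offspring_calls = off_calls, mode = mode)
  track <- window_frequencies(obs, mask, map, window_width,
                              min_snps_per_window, mask_regions)
  track <- classify_dosage(track, threshold, calibrate)
  seg <- segment_and_call(track, min_run)
  structure(list(track = track, segments = seg$segments,
                 breakpoints = seg$breakpoints,
                 composition = seg$composition, mask = mask,
                 params = list(mode = mode, window_width = window_width,
                               min_snps_per_window = min_snps_per_window,
                               threshold = threshold, calibrate = calibrate,
                               threshold_used = attr(track, "threshold_used"),
                               min_run = min_run, min_depth = min_depth,
                               het_band = het_band),
                 id = attr(obs, "id")),
            class = "dosage_fit")
}

#' @export
print.dosage_fit <- function(x, ...) {
  cc <- x$composition
  cat(sprintf("<dosage_fit %s> %d homolog groups (%d callable)\n",
              x$id %||% "?", nrow(cc), sum(cc$callable)))
  cat(sprintf("  effective loci: %d / %d kept\n",
              sum(x$mask$keep), nrow(x$mask)))
  cat(sprintf("  composition: %d x CgCgCa, %d x CgCaCa; %d recombinant groups\n",
              sum(cc$composition == "CgCgCa", na.rm = TRUE),
              sum(cc$composition == "CgCaCa", na.rm = TRUE),
              sum(cc$recombinant, na.rm = TRUE)))
  cat(sprintf("  threshold used: %.3f\n", x$params$threshold_used))
  invisible(x)
}

#' @export
summary.dosage_fit <- function(object, ...) {
  cc <- object$composition[object$composition$callable, , drop = FALSE]
  structure(list(
    id = object$id,
    n_groups = nrow(object$composition),
    n_callable = nrow(cc),
    n_effective = sum(object$mask$keep),
    n_recombinant = sum(cc$recombinant),
    n_breakpoints = sum(cc$n_breakpoints),
    cg_chromosomes = sum(ifelse(cc$composition == "CgCgCa", 2L, 1L)),
    ca_chromosomes = sum(ifelse(cc$composition == "CgCgCa", 1L, 2L)),
    threshold_used = object$params$threshold_used,
    composition = object$composition), class = "summary.dosage_fit")
}

#' @export
print.summary.dosage_fit <- function(x, ...) {
  cat(sprintf("Dosage genotyping of %s\n", x$id %||% "?"))
  cat(sprintf("  %d/%d groups callable, %d effective loci\n",
              x$n_callable, x$n_groups, x$n_effective))
  cat(sprintf("  recombinant groups: %d (%.2f of callable)\n",
              x$n_recombinant, x$n_recombinant / max(1, x$n_callable)))
  cat(sprintf("  Cg:Ca chromosomes: %d:%d\n",
              x$cg_chromosomes, x$ca_chromosomes))
  invisible(x)
}

#' Plot a whole-genome dosage track
#'
#' Scatter of windowed Cg frequencies ordered along the genome, colored by
#' homolog group, with the dosage threshold and the expected 1/3 and 2/3
#' levels -- the standard whole-genome genotyping panel.
#' @param x a `dosage_fit`.
#' @param ... passed to `plot()`.
#' @export
plot.dosage_fit <- function(x, ...) {
  tr <- x$track
  tr$xpos <- seq_len(nrow(tr))
  grp <- factor(tr$group, levels = unique(tr$group))
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 2")[as.integer(grp)]
  graphics::plot(tr$xpos, tr$cg_freq, col = cols, pch = 16, cex = 0.5,
                 ylim = c(0, 1), xlab = "window (genome order)",
                 ylab = "mean Cg SNP frequency",
                 main = x$id %||% "dosage track", ...)
  graphics::abline(h = c(1 / 3, 2 / 3), lty = 3, col = "grey50")
  graphics::abline(h = x$params$threshold_used, lty = 2, col = "red")
  invisible(x)
}

#' Parental chromosome-set attribution for a cohort of offspring
#'
#' At loci diagnostic between the two parents of a generation (both
#' homozygous, for different alleles), computes each offspring's
#' genome-wide mean maternal-allele and paternal-allele read fractions and
#' converts them to whole-set counts (`round(ploidy x fraction)`). A
#' first-generation backcross triploid shows ~1/3 maternal and ~2/3
#' paternal (sets 1 + 2); a gynogenetic offspring shows 1.0 maternal and
#' 0.0 paternal (sets 3 + 0).
#'
#' @param offspring_obs named list of `snp_obs`, one per offspring.
#' @param maternal_calls,paternal_calls parent call vectors.
#' @param offspring_ploidy ploidy of the offspring (3 for amphitriploids).
#' @return data.frame with one row per offspring: `id`, `n_loci`,
#'   `maternal_freq`, `paternal_freq`, `maternal_sets`, `paternal_sets`,
#'   `low_confidence` (fewer than 100 effective loci).
#' @export
generation_frequencies <- function(offspring_obs, maternal_calls,
                                   paternal_calls, offspring_ploidy = 3L) {
  if (inherits(offspring_obs, "snp_obs"))
    offspring_obs <- stats::setNames(list(offspring_obs),
                                     attr(offspring_obs, "id"))
  mask <- select_effective_snps(list(mother = maternal_calls,
                                     father = paternal_calls),
                                mode = "pairwise_parent")
  sel <- which(mask$keep)
  maternal_is_cg <- maternal_calls[sel] == "hom_cg"
  rows <- lapply(names(offspring_obs), function(id) {
    o <- offspring_obs[[id]][sel, , drop = FALSE]
    depth <- o$cg + o$ca
    ok <- depth > 0
    mfrac <- ifelse(maternal_is_cg, o$cg, o$ca)[ok] / depth[ok]
    pfrac <- ifelse(maternal_is_cg, o$ca, o$cg)[ok] / depth[ok]
    m <- mean(mfrac); p <- mean(pfrac)
    data.frame(id = id, n_loci = sum(ok),
               maternal_freq = m, paternal_freq = p,
               maternal_sets = round(offspring_ploidy * m),
               paternal_sets = round(offspring_ploidy * p),
               low_confidence = sum(ok) < 100L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
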