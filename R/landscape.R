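# Downstream landscape statistics over per-cell call sets: levels, relative
# enrichment, windowed cross-cell variance, stage merging and transitions,
# shared marked regions, paired differences, correlation clustering, signal
# metaplots, matched-control repeat comparisons.

fc_sites_of <- function(x) {
  if (inherits(x, "fc_calls")) x$fc_sites[, c("chrom", "pos"), drop = FALSE]
  else if (inherits(x, "fc_stage")) x$merged_fc
  else stop_fcpg("expected an `fc_calls` or `fc_stage` object")
}

unmod_sites_of <- function(x) {
  if (inherits(x, "fc_calls")) x$unmod_sites
  else if (inherits(x, "fc_stage")) x$merged_unmod
  else stop_fcpg("expected an `fc_calls` or `fc_stage` object")
}

#' Merge a developmental stage's cells into one call set
#'
#' The stage's 5fCpG set is the union of its member cells' called sites; its
#' unmodified set is the union of per-cell unmodified calls. The commonly
#' covered backbone is the set of CpGs covered at least `min_depth` times in
#' every member cell, and the stage 5fCpG fraction is the share of that
#' backbone found formylated in at least one member cell.
#'
#' @param label Stage name.
#' @param calls List of `fc_calls` for the member cells.
#' @param cells List of the same cells' count data.frames (needed for the
#'   commonly covered backbone).
#' @param min_depth Depth threshold for the backbone (default 3).
#' @return An `fc_stage` object.
#' @export
stage_callset <- function(label, calls, cells, min_depth = 3L) {
  stopifnot(length(calls) >= 1L, length(calls) == length(cells))
  merged_fc <- unique_sites(do.call(rbind, lapply(calls, fc_sites_of)))
  merged_unmod <- unique_sites(do.call(rbind, lapply(calls, unmod_sites_of)))
  covered_keys <- lapply(cells, function(x) {
    d <- x$count_C + x$count_T
    site_key(x$chrom[d >= min_depth], x$pos[d >= min_depth])
  })
  common_keys <- Reduce(intersect, covered_keys)
  sequenced <- unique_sites(do.call(rbind, lapply(cells, function(x) {
    d <- x$count_C + x$count_T
    x[d >= 1L, c("chrom", "pos"), drop = FALSE]
  })))
  common <- if (length(common_keys)) {
    parts <- strsplit(common_keys, ":", fixed = TRUE)
    order_sites(data.frame(chrom = vapply(parts, `[[`, "", 1L),
                           pos = as.integer(vapply(parts, `[[`, "", 2L))))
  } else empty_sites()
  frac <- if (nrow(common)) {
    sum(site_key(merged_fc$chrom, merged_fc$pos) %in%
          site_key(common$chrom, common$pos)) / nrow(common)
  } else NA_real_
  structure(list(label = label,
                 cell_ids = vapply(calls, function(c) c$cell_id,
                                   character(1)),
                 merged_fc = merged_fc, merged_unmod = merged_unmod,
                 common_covered = common, sequenced = sequenced,
                 stage_fc_fraction = frac),
            class = "fc_stage")
}

#' @export
print.fc_stage <- function(x, ...) {
  cat("fc_stage <", x$label, ">: ", length(x$cell_ids), " cells, ",
      nrow(x$merged_fc), " merged 5fCpG, ", nrow(x$common_covered),
      " commonly covered CpG (fraction ",
      formatC(x$stage_fc_fraction, digits = 4, format = "g"), ")\n",
      sep = "")
  invisible(x)
}

#' 5fCpG level within a genomic scope
#'
#' Level (ratio) = called 5fCpG sites / (5fCpG + unmodified CpG sites),
#' restricted to the supplied intervals; `NA` when no called site of either
#' kind lies in scope. Distinct from abundance, whose denominator is all
#' sequenced CpGs.
#'
#' @param calls An `fc_calls` or `fc_stage`.
#' @param scope Interval data.frame (`chrom,start,end`, 0-based half-open)
#'   or `NULL` for the whole genome.
#' @return Level in `[0, 1]`, or `NA` when undefined.
#' @export
fc_level <- function(calls, scope = NULL) {
  fc <- fc_sites_of(calls)
  un <- unmod_sites_of(calls)
  if (!is.null(scope)) {
    fc <- fc[overlap_count(fc, scope) > 0, , drop = FALSE]
    un <- un[overlap_count(un, scope) > 0, , drop = FALSE]
  }
  denom <- nrow(fc) + nrow(un)
  if (denom == 0L) return(NA_real_)
  nrow(fc) / denom
}

#' Relative enrichment of 5fCpG sites over annotation classes
#'
#' Per class, log2 of the fraction of 5fCpG sites inside the class over the
#' fraction of background (covered CpG) sites inside it. Sites overlapping
#' several classes count toward each. Classes with zero background occupancy
#' are reported as `NA` rather than infinite.
#'
#' @param fc_sites data.frame of called sites (`chrom`, `pos`).
#' @param background data.frame of covered CpG sites (superset of
#'   `fc_sites`).
#' @param annotation Annotation data.frame.
#' @return data.frame: class, n_fc_in, n_fc_total, n_bg_in, n_bg_total,
#'   log2_enrichment.
#' @export
relative_enrichment <- function(fc_sites, background, annotation) {
  if (nrow(fc_sites) == 0L) {
    stop_fcpg("no 5fCpG sites: enrichment is not definable")
  }
  fc_sites <- unique_sites(fc_sites)
  background <- unique_sites(background)
  if (!all(site_key(fc_sites$chrom, fc_sites$pos) %in%
             site_key(background$chrom, background$pos))) {
    stop_fcpg("fc_sites must be a subset of the background site set")
  }
  classes <- unique(annotation$class)
  rows <- lapply(classes, function(cl) {
    iv <- annotation[annotation$class == cl, , drop = FALSE]
    n_fc_in <- sum(overlap_count(fc_sites, iv) > 0)
    n_bg_in <- sum(overlap_count(background, iv) > 0)
    data.frame(class = cl, n_fc_in = n_fc_in,
               n_fc_total = nrow(fc_sites), n_bg_in = n_bg_in,
               n_bg_total = nrow(background),
               log2_enrichment = if (n_bg_in == 0L) NA_real_ else
                 log2((n_fc_in / nrow(fc_sites)) /
                        (n_bg_in / nrow(background))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed 5fCpG level profile for one cell or stage
#'
#' Per window, level = n_fc / (n_fc + n_unmod); windows where neither kind
#' of call occurs are excluded (undefined), never zero-filled, so absence of
#' coverage is not conflated with absence of formylation.
#'
#' @param calls An `fc_calls` or `fc_stage`.
#' @param grid Window grid from [window_grid()].
#' @return data.frame `chrom,start,n_fc,n_unmod,level` with attribute
#'   `owner`.
#' @export
window_profile <- function(calls, grid) {
  fc <- fc_sites_of(calls)
  un <- unmod_sites_of(calls)
  owner <- if (inherits(calls, "fc_calls")) calls$cell_id else calls$label
  count_by_window <- function(sites) {
    if (nrow(sites) == 0L) return(integer(0))
    w <- window_of(sites, grid)
    tab <- table(site_key(w$chrom, w$start))
    stats::setNames(as.integer(tab), names(tab))
  }
  nf <- count_by_window(fc)
  nu <- count_by_window(un)
  keys <- sort(union(names(nf), names(nu)))
  if (!length(keys)) {
    return(structure(data.frame(chrom = character(), start = integer(),
                                n_fc = integer(), n_unmod = integer(),
                                level = numeric()), owner = owner))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  n_fc <- ifelse(keys %in% names(nf), nf[keys], 0L)
  n_un <- ifelse(keys %in% names(nu), nu[keys], 0L)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                    start = as.integer(vapply(parts, `[[`, "", 2L)),
                    n_fc = as.integer(n_fc), n_unmod = as.integer(n_un))
  out$level <- out$n_fc / (out$n_fc + out$n_unmod)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, owner = owner)
}

profile_matrix <- function(profiles) {
  keys <- sort(unique(unlist(lapply(profiles, function(p) {
    site_key(p$chrom, p$start)
  }))))
  owners <- vapply(seq_along(profiles), function(i) {
    attr(profiles[[i]], "owner") %||% names(profiles)[i] %||%
      paste0("profile_", i)
  }, character(1))
  m <- matrix(NA_real_, length(keys), length(profiles),
              dimnames = list(keys, owners))
  fc_any <- stats::setNames(rep(FALSE, length(keys)), keys)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    k <- site_key(p$chrom, p$start)
    m[k, i] <- p$level
    fc_any[k] <- fc_any[k] | p$n_fc > 0L
  }
  list(levels = m, fc_any = fc_any)
}

#' Cross-cell variance of windowed 5fCpG levels
#'
#' Retains windows with a 5fCpG site in at least one profile; per retained
#' window with levels defined in at least two profiles, the sample variance
#' (n - 1 denominator) of the level across profiles measures epigenetic
#' heterogeneity. With a window-to-class map, the per-class median variance
#' is also reported.
#'
#' @param profiles List of [window_profile()] outputs (>= 2).
#' @param grid Window grid (carried for provenance).
#' @param class_map Optional data.frame `chrom,start,class` as from
#'   [window_classes()].
#' @return List: `per_window` (chrom, start, n_defined, variance) and
#'   `by_class` (class, n_windows, median_variance; `NULL` without a map).
#' @export
window_stats <- function(profiles, grid, class_map = NULL) {
  if (length(profiles) < 2L) {
    stop_fcpg("window_stats needs at least two profiles")
  }
  pm <- profile_matrix(profiles)
  m <- pm$levels[pm$fc_any, , drop = FALSE]
  n_def <- rowSums(!is.na(m))
  m <- m[n_def >= 2L, , drop = FALSE]
  n_def <- n_def[n_def >= 2L]
  v <- apply(m, 1L, var, na.rm = TRUE)
  keys <- rownames(m)
  parts <- strsplit(keys, ":", fixed = TRUE)
  per_window <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    n_defined = as.integer(n_def), variance = unname(v))
  by_class <- NULL
  if (!is.null(class_map) && nrow(per_window)) {
    j <- merge(per_window, class_map, by = c("chrom", "start"))
    if (nrow(j)) {
      agg <- stats::aggregate(variance ~ class, data = j, FUN = median)
      cnt <- stats::aggregate(variance ~ class, data = j, FUN = length)
      by_class <- data.frame(class = agg$class, n_windows = cnt$variance,
                             median_variance = agg$variance)
    }
  }
  list(per_window = per_window, by_class = by_class)
}

#' Classify a later stage's 5fCpG sites against an earlier stage
#'
#' Each site in the later stage's merged set is `inherited` when the earlier
#' stage also called it formylated, `newly_generated` when at least one
#' earlier cell covered it (>= 3x) and called it unmodified while no earlier
#' cell called it formylated, and `undetermined` otherwise (typically
#' uncovered earlier). The three counts partition the later merged set
#' exactly.
#'
#' @param earlier,later `fc_stage` objects on the same genome.
#' @return List: `counts` (named integer vector) and `sites` (list of site
#'   data.frames per category).
#' @export
stage_transition <- function(earlier, later) {
  stopifnot(inherits(earlier, "fc_stage"), inherits(later, "fc_stage"))
  lk <- site_key(later$merged_fc$chrom, later$merged_fc$pos)
  ek_fc <- site_key(earlier$merged_fc$chrom, earlier$merged_fc$pos)
  ek_un <- site_key(earlier$merged_unmod$chrom, earlier$merged_unmod$pos)
  inherited <- lk %in% ek_fc
  newly <- !inherited & lk %in% ek_un
  undet <- !inherited & !newly
  counts <- c(inherited = sum(inherited), newly_generated = sum(newly),
              undetermined = sum(undet))
  list(counts = counts,
       sites = list(inherited = later$merged_fc[inherited, , drop = FALSE],
                    newly_generated = later$merged_fc[newly, , drop = FALSE],
                    undetermined = later$merged_fc[undet, , drop = FALSE]))
}

#' Overlap of two marked-window sets
#'
#' Partition of two marked-region sets (same grid) into a-specific,
#' b-specific and shared windows, as in gamete / pronucleus comparisons.
#'
#' @param a,b Marked window data.frames from [mark_windows()].
#' @return List: `counts` (a_specific, b_specific, shared) and `sets`.
#' @export
shared_regions <- function(a, b) {
  sa <- attr(a, "window_size")
  sb <- attr(b, "window_size")
  if (!is.null(sa) && !is.null(sb) && sa != sb) {
    stop_fcpg("configuration error: marked window sets use different grids")
  }
  ka <- site_key(a$chrom, a$start)
  kb <- site_key(b$chrom, b$start)
  shared <- ka %in% kb
  list(counts = c(a_specific = sum(!shared),
                  b_specific = sum(!(kb %in% ka)),
                  shared = sum(shared)),
       sets = list(a_specific = a[!shared, , drop = FALSE],
                   b_specific = b[!(kb %in% ka), , drop = FALSE],
                   shared = a[shared, , drop = FALSE]))
}

#' Paired 5fCpG level difference across genomic scopes
#'
#' For a pair of cells (male vs female pronucleus, or two blastomeres),
#' level(a) - level(b) per scope; `NA` when either level is undefined in a
#' scope. Exactly antisymmetric under swapping the members.
#'
#' @param member_a,member_b `fc_calls` (or `fc_stage`) objects.
#' @param scopes Named list of interval data.frames; the whole genome is
#'   always included as scope `"whole_genome"`.
#' @param pair_id Identifier stored as an attribute.
#' @return data.frame: scope, level_a, level_b, difference.
#' @export
paired_difference <- function(member_a, member_b, scopes = list(),
                              pair_id = NULL) {
  scopes <- c(list(whole_genome = NULL), scopes)
  rows <- lapply(names(scopes), function(nm) {
    la <- fc_level(member_a, scopes[[nm]])
    lb <- fc_level(member_b, scopes[[nm]])
    data.frame(scope = nm, level_a = la, level_b = lb,
               difference = la - lb)
  })
  structure(do.call(rbind, rows), pair_id = pair_id)
}

#' Spearman correlation and clustering of windowed profiles
#'
#' Pairwise Spearman correlation of window levels over jointly defined
#' windows (restricted to windows with a 5fCpG site in at least one
#' profile), then average-linkage hierarchical clustering on distance
#' 1 - rho. Pairs with fewer than `min_joint` jointly defined windows are
#' flagged `NA`.
#'
#' @param stage_profiles List of [window_profile()] outputs (>= 2).
#' @param min_joint Minimum jointly defined windows per pair (default 3).
#' @return List: `rho` (correlation matrix), `n_joint`, `hclust` (or `NULL`
#'   when any pair is undefined), `order` (leaf labels).
#' @export
correlation_cluster <- function(stage_profiles, min_joint = 3L) {
  if (length(stage_profiles) < 2L) {
    stop_fcpg("correlation_cluster needs at least two profiles")
  }
  pm <- profile_matrix(stage_profiles)
  m <- pm$levels[pm$fc_any, , drop = FALSE]
  k <- ncol(m)
  rho <- matrix(NA_real_, k, k, dimnames = dimnames(m)[c(2, 2)])
  n_joint <- matrix(0L, k, k, dimnames = dimnames(m)[c(2, 2)])
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    n_joint[i, i] <- sum(!is.na(m[, i]))
    for (j in seq_len(i - 1L)) {
      both <- !is.na(m[, i]) & !is.na(m[, j])
      n_joint[i, j] <- n_joint[j, i] <- sum(both)
      if (sum(both) >= min_joint) {
        rho[i, j] <- rho[j, i] <-
          suppressWarnings(cor(m[both, i], m[both, j],
                               method = "spearman"))
      }
    }
  }
  hc <- NULL
  ord <- NULL
  if (!anyNA(rho)) {
    hc <- hclust(as.dist(1 - rho), method = "average")
    ord <- hc$labels[hc$order]
  } else {
    warning("some profile pairs have too few jointly defined windows; ",
            "their rho is NA and no dendrogram is built", call. = FALSE)
  }
  list(rho = rho, n_joint = n_joint, hclust = hc, order = ord)
}

#' Average signal metaplot around site centers
#'
#' Splits `[center - flank, center + flank]` around each site into `n_bins`
#' near-equal bins, averages the piecewise-constant track within each bin
#' (weighted by covered bases; bins with no track coverage are `NA`), then
#' averages across sites. Bins clipped at the chromosome start are truncated.
#'
#' @param fc_sites data.frame of sites (`chrom`, `pos`).
#' @param track bedGraph-style data.frame `chrom,start,end,value` (0-based
#'   half-open).
#' @param flank Flank in bp (> 0).
#' @param n_bins Odd number of bins so a center bin exists.
#' @return Numeric vector of per-bin mean signal, names = bin center offsets
#'   in bp relative to the site.
#' @export
signal_profile <- function(fc_sites, track, flank = 1000L, n_bins = 21L) {
  if (flank <= 0) stop_fcpg("invalid parameter: flank must be > 0")
  if (n_bins %% 2L != 1L) {
    stop_fcpg("invalid parameter: n_bins must be odd")
  }
  width_total <- 2L * as.integer(flank) + 1L
  edges <- round(seq(0L, width_total, length.out = n_bins + 1L))
  centers <- round((edges[-1] + edges[-length(edges)]) / 2) - flank - 1L
  out <- stats::setNames(rep(NA_real_, n_bins), centers)
  if (nrow(fc_sites) == 0L || is.null(track) || nrow(track) == 0L) {
    return(out)
  }
  m <- nrow(fc_sites)
  left <- rep(as.integer(fc_sites$pos) - as.integer(flank), each = n_bins)
  bin_start <- pmax(left + edges[-length(edges)], 1L)
  bin_end <- left + edges[-1] - 1L
  ok <- bin_end >= bin_start
  bins <- GenomicRanges::GRanges(
    rep(as.character(fc_sites$chrom), each = n_bins)[ok],
    IRanges::IRanges(bin_start[ok], bin_end[ok]))
  bin_idx <- rep(seq_len(n_bins), m)[ok]
  site_idx <- rep(seq_len(m), each = n_bins)[ok]

  tr <- intervals_gr(track)
  hits <- overlap_hits(bins, tr)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(GenomicRanges::pintersect(bins[q], tr[s]))
  val <- track$value[s]
  cell <- paste0(site_idx[q], "_", bin_idx[q])
  wsum <- tapply(w, cell, sum)
  vsum <- tapply(w * val, cell, sum)
  bin_of_cell <- as.integer(sub(".*_", "", names(wsum)))
  cell_mean <- as.numeric(vsum / wsum)
  prof <- tapply(cell_mean, bin_of_cell, mean, na.rm = TRUE)
  out[as.integer(names(prof))] <- as.numeric(prof)
  out
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts Read counts in the region.
#' @param length_bp Region length in bp.
#' @param total_mapped Total mapped reads in the library.
#' @return RPKM value(s).
#' @export
rpkm <- function(counts, length_bp, total_mapped) {
  counts / ((length_bp / 1000) * (total_mapped / 1e6))
}

#' Compare 5fCpG-marked repeats with matched unmarked controls
#'
#' Draws, without replacement and seeded, as many control repeats (only
#' unmodified CpG covered) as there are marked repeats, then compares a
#' per-repeat quantity (RPKM or methylation level) between the groups with a
#' two-tailed two-sample Student t test.
#'
#' @param marked_values Numeric per-repeat values for 5fCpG-marked repeats
#'   (length >= 2).
#' @param unmarked_values Values for candidate control repeats (at least as
#'   many as marked).
#' @param seed Integer seed for the control draw.
#' @return List: n, mean_marked, mean_control, t, p, control_idx.
#' @export
matched_repeat_comparison <- function(marked_values, unmarked_values,
                                      seed = 1L) {
  m <- length(marked_values)
  if (m < 2L || length(unmarked_values) < m) {
    stop_fcpg("need >= 2 marked repeats and at least as many controls")
  }
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(length(unmarked_values), m))
  ctrl <- unmarked_values[idx]
  tt <- t.test(marked_values, ctrl, var.equal = TRUE,
               alternative = "two.sided")
  list(n = m, mean_marked = mean(marked_values), mean_control = mean(ctrl),
       t = unname(tt$statistic), p = tt$p.value, control_idx = idx)
}
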