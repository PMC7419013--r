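# Interval machinery: element assignment, promoter CpG-density classes,
# window grids, marked windows and site flanks. Intervals are 0-based
# half-open (BED convention); CpG positions are 1-based plus-strand C
# coordinates. Conversions happen only here and in the readers/writers.

# single-label precedence for stacked element fractions
.element_precedence <- c("promoter", "exon", "intron", "tts")

#' Tile chromosomes into non-overlapping windows
#'
#' Fixed-size disjoint windows covering each chromosome; the last window may
#' be partial. Window id is (chrom, start).
#'
#' @param genome `fc_genome` or named vector of chromosome sizes.
#' @param size Window size in bp (default 1 kb, the scale used for marked
#'   regions and cross-cell variance; 10 kb .. 10 Mb grids feed the
#'   dimensionality-reduction exports).
#' @return data.frame `chrom,start,end` (0-based half-open) with attribute
#'   `window_size`.
#' @export
window_grid <- function(genome, size = 1000L) {
  sizes <- chrom_sizes_of(genome)
  if (size < 1) stop_fcpg("invalid parameter: window size must be >= 1")
  size <- as.integer(size)
  grids <- lapply(names(sizes), function(ch) {
    starts <- seq.int(0L, sizes[[ch]] - 1L, by = size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, sizes[[ch]]))
  })
  structure(do.call(rbind, grids), window_size = size)
}

window_of <- function(sites, grid) {
  size <- attr(grid, "window_size")
  if (!is.null(size)) {
    # regular tiling: arithmetic is exact and fast
    data.frame(chrom = sites$chrom,
               start = (as.integer(sites$pos) - 1L) %/% size * size)
  } else {
    hits <- overlap_hits(sites_gr(sites), intervals_gr(grid))
    out <- data.frame(chrom = rep(NA_character_, nrow(sites)),
                      start = rep(NA_integer_, nrow(sites)))
    out$chrom[S4Vectors::queryHits(hits)] <-
      grid$chrom[S4Vectors::subjectHits(hits)]
    out$start[S4Vectors::queryHits(hits)] <-
      grid$start[S4Vectors::subjectHits(hits)]
    out
  }
}

#' Assign genomic-element labels to sites
#'
#' `mode = "all_overlaps"` returns every containing class (one row per
#' site-class pair; the form enrichment analysis needs). `mode =
#' "precedence"` returns exactly one label per site using the fixed order
#' promoter > exon > intron > TTS-region > intergenic, so labels form stacked
#' fractions summing to 1.
#'
#' @param sites data.frame of sites (`chrom`, `pos`).
#' @param annotation Annotation data.frame (`chrom,start,end,class`, ...).
#' @param mode `"precedence"` or `"all_overlaps"`.
#' @param chrom_sizes Optional named sizes; sites on chromosomes absent from
#'   it are labeled `"unassigned"` with a warning.
#' @return precedence: data.frame `chrom,pos,label`; all_overlaps: long
#'   data.frame `chrom,pos,class`.
#' @export
assign_sites <- function(sites, annotation,
                         mode = c("precedence", "all_overlaps"),
                         chrom_sizes = NULL) {
  mode <- match.arg(mode)
  if (mode == "all_overlaps") {
    if (nrow(sites) == 0L || nrow(annotation) == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        class = character()))
    }
    hits <- overlap_hits(sites_gr(sites), intervals_gr(annotation))
    out <- unique(data.frame(
      chrom = sites$chrom[S4Vectors::queryHits(hits)],
      pos = sites$pos[S4Vectors::queryHits(hits)],
      class = annotation$class[S4Vectors::subjectHits(hits)]))
    rownames(out) <- NULL
    return(out)
  }

  label <- rep("intergenic", nrow(sites))
  for (cl in rev(intersect(.element_precedence, unique(annotation$class)))) {
    hit <- overlap_count(sites, annotation[annotation$class == cl, ,
                                           drop = FALSE]) > 0
    label[hit] <- cl
  }
  if (!is.null(chrom_sizes)) {
    off <- !(sites$chrom %in% names(chrom_sizes))
    if (any(off)) {
      warning(sum(off), " site(s) on unknown chromosome(s): labeled ",
              "\"unassigned\"", call. = FALSE)
      label[off] <- "unassigned"
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, label = label)
}

#' Strand-aware promoter intervals
#'
#' Promoters span 1 kb upstream to 0.5 kb downstream of the TSS,
#' strand-aware, clipped to chromosome bounds.
#'
#' @param tss data.frame with `chrom`, `tss` (1-based), `strand`
#'   (`"+"`/`"-"`), optionally `gene`.
#' @param chrom_sizes Named chromosome sizes for clipping (optional).
#' @param upstream,downstream Extents in bp.
#' @return data.frame `chrom,start,end` (0-based half-open) plus `gene` when
#'   supplied.
#' @export
promoter_intervals <- function(tss, chrom_sizes = NULL, upstream = 1000L,
                               downstream = 500L) {
  plus <- tss$strand != "-"
  start0 <- ifelse(plus, tss$tss - 1L - upstream, tss$tss - 1L - downstream)
  end <- ifelse(plus, tss$tss + downstream, tss$tss + upstream)
  start0 <- pmax(start0, 0L)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, chrom_sizes[as.character(tss$chrom)])
  }
  out <- data.frame(chrom = tss$chrom, start = as.integer(start0),
                    end = as.integer(end))
  if (!is.null(tss$gene)) out$gene <- tss$gene
  out
}

#' Classify promoters by CpG density (HCP / ICP / LCP)
#'
#' Classes follow the canonical 500-bp sliding-window criteria: a promoter
#' is HCP when any window has GC fraction >= `gc_min` and CpG
#' observed/expected >= `oe_high`; LCP when no window reaches `oe_low`;
#' ICP otherwise.
#'
#' @param promoter_stats data.frame with one row per 500-bp window:
#'   `promoter` (id), `gc` (GC fraction), `obs_exp` (CpG observed/expected).
#' @param gc_min,oe_high,oe_low Thresholds (defaults 0.55, 0.75, 0.48).
#' @return data.frame `promoter`, `class`.
#' @export
classify_promoter <- function(promoter_stats, gc_min = 0.55,
                              oe_high = 0.75, oe_low = 0.48) {
  need <- c("promoter", "gc", "obs_exp")
  if (!all(need %in% names(promoter_stats)) ||
      nrow(promoter_stats) == 0L ||
      anyNA(promoter_stats[, c("gc", "obs_exp")])) {
    stop_fcpg("classification error: promoter_stats needs complete ",
              "`promoter`, `gc`, `obs_exp` columns")
  }
  cls <- vapply(split(promoter_stats, promoter_stats$promoter), function(w) {
    if (any(w$gc >= gc_min & w$obs_exp >= oe_high)) "HCP"
    else if (max(w$obs_exp) < oe_low) "LCP"
    else "ICP"
  }, character(1))
  data.frame(promoter = names(cls), class = unname(cls))
}

#' Mark windows containing at least one 5fCpG site
#'
#' A window is marked iff one or more sites fall inside it (half-open
#' containment). Invariant to site order and duplicates.
#'
#' @param fc_sites data.frame of sites (`chrom`, `pos`).
#' @param grid Window grid from [window_grid()].
#' @return data.frame of marked windows (`chrom`, `start`), sorted, carrying
#'   the grid's `window_size` attribute.
#' @export
mark_windows <- function(fc_sites, grid) {
  if (nrow(fc_sites) == 0L) {
    return(structure(data.frame(chrom = character(), start = integer()),
                     window_size = attr(grid, "window_size")))
  }
  w <- window_of(unique_sites(fc_sites), grid)
  w <- w[!is.na(w$start), , drop = FALSE]
  out <- unique(w)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, window_size = attr(grid, "window_size"))
}

#' Export flanking intervals around site centers
#'
#' For each site, the interval `[pos - flank - 1, pos + flank)` in 0-based
#' half-open coordinates (i.e. `flank` bp on each side of the C), clipped to
#' chromosome bounds. These are the regions external motif tools consume.
#'
#' @param fc_sites data.frame of sites (`chrom`, `pos`).
#' @param flank Flank size in bp (> 0).
#' @param chrom_sizes Optional named sizes for right-clipping.
#' @return BED-style data.frame `chrom,start,end`.
#' @export
export_flanks <- function(fc_sites, flank = 100L, chrom_sizes = NULL) {
  if (flank <= 0) stop_fcpg("invalid parameter: flank must be > 0")
  if (nrow(fc_sites) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  start0 <- pmax(as.integer(fc_sites$pos) - as.integer(flank) - 1L, 0L)
  end <- as.integer(fc_sites$pos) + as.integer(flank)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, as.integer(chrom_sizes[as.character(fc_sites$chrom)]))
  }
  data.frame(chrom = fc_sites$chrom, start = start0, end = end)
}

#' Map windows to annotation classes
#'
#' Long window-to-class map (every class a window overlaps), used to take
#' per-class medians of windowed statistics.
#'
#' @param grid Window grid.
#' @param annotation Annotation data.frame.
#' @return data.frame `chrom,start,class`.
#' @export
window_classes <- function(grid, annotation) {
  if (nrow(grid) == 0L || nrow(annotation) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      class = character()))
  }
  hits <- overlap_hits(intervals_gr(grid), intervals_gr(annotation))
  out <- unique(data.frame(
    chrom = grid$chrom[S4Vectors::queryHits(hits)],
    start = grid$start[S4Vectors::queryHits(hits)],
    class = annotation$class[S4Vectors::subjectHits(hits)]))
  rownames(out) <- NULL
  out
}
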