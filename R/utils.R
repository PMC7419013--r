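`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical site key
#'
#' Collapses (chrom, pos) into a single string key used for set operations on
#' CpG sites. Positions are 1-based coordinates of the plus-strand C of the
#' CpG dyad throughout the package.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @return Character vector of `"chrom:pos"` keys.
#' @keywords internal
site_key <- function(chrom, pos) paste0(chrom, ":", pos, recycle0 = TRUE)

empty_sites <- function() data.frame(chrom = character(), pos = integer())

order_sites <- function(x) {
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

unique_sites <- function(x) {
  order_sites(unique(x[, c("chrom", "pos"), drop = FALSE]))
}

stop_fcpg <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    stop_fcpg("invalid parameter: `", name, "` must be a probability ",
              if (open) "strictly inside (0, 1)" else "in [0, 1]")
  }
  invisible(x)
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != floor(x))) {
    stop_fcpg("invalid parameter: `", name,
              "` must contain non-negative integer counts")
  }
  invisible(x)
}

# (chrom, pos) sites -> width-1 GRanges
sites_gr <- function(sites) {
  GenomicRanges::GRanges(as.character(sites$chrom),
                         IRanges::IRanges(as.integer(sites$pos), width = 1L))
}

# 0-based half-open intervals -> 1-based closed GRanges
intervals_gr <- function(x) {
  GenomicRanges::GRanges(as.character(x$chrom),
                         IRanges::IRanges(as.integer(x$start) + 1L,
                                          as.integer(x$end)))
}

harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

overlap_count <- function(sites, intervals) {
  if (nrow(sites) == 0L) return(integer(0))
  if (is.null(intervals) || nrow(intervals) == 0L) return(integer(nrow(sites)))
  gr <- harmonize_seqlevels(sites_gr(sites), intervals_gr(intervals))
  GenomicRanges::countOverlaps(gr[[1]], gr[[2]])
}

overlap_hits <- function(query_gr, subject_gr) {
  gr <- harmonize_seqlevels(query_gr, subject_gr)
  GenomicRanges::findOverlaps(gr[[1]], gr[[2]])
}

chrom_sizes_of <- function(genome) {
  if (inherits(genome, "fc_genome")) return(genome$chrom_sizes)
  if (is.numeric(genome) && !is.null(names(genome))) return(genome)
  stop_fcpg("expected an `fc_genome` or a named vector of chromosome sizes")
}
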