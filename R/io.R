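# Readers and writers. Count and control tables are TSV with headers; BED
# files are 0-based half-open, headerless, with optional family/subfamily
# labels in columns 4-5 for repeat tracks. All coordinate conversions live
# here: internal CpG positions are 1-based.

parse_error <- function(path, line, msg) {
  stop_fcpg("parse error in ", path, " at line ", line, ": ", msg)
}

#' Read a per-cell CpG count table
#'
#' TSV with header columns `chrom`, `pos` (1-based plus-strand C of the CpG
#' dyad), `count_C`, `count_T`, and optionally `strand`. With
#' `merge_strands = TRUE`, minus-strand rows are mapped to their dyad's
#' plus-strand coordinate (pos - 1) and counts of the two strands are
#' summed; without a strand column, duplicate positions are summed when
#' merging is on and rejected otherwise.
#'
#' @param path File path.
#' @param merge_strands Merge per-strand rows of one dyad.
#' @return data.frame `chrom,pos,count_C,count_T`, sorted by (chrom, pos).
#' @export
read_counts_table <- function(path, merge_strands = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "count_C", "count_T")
  if (!all(need %in% names(df))) {
    parse_error(path, 1L, paste("header must contain",
                                paste(need, collapse = ", ")))
  }
  for (col in c("pos", "count_C", "count_T")) {
    if (!is.numeric(df[[col]])) {
      parse_error(path, 2L, paste0("column ", col, " is not numeric"))
    }
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 |
                   df[[col]] != floor(df[[col]]))
    if (length(bad)) {
      parse_error(path, bad[1] + 1L,
                  paste0("invalid ", col, " value `", df[[col]][bad[1]], "`"))
    }
  }
  if ("strand" %in% names(df) && merge_strands) {
    df$pos <- ifelse(df$strand == "-", df$pos - 1L, df$pos)
  }
  key <- site_key(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    if (merge_strands) {
      agg <- stats::aggregate(cbind(count_C, count_T) ~ chrom + pos,
                              data = df, FUN = sum)
      df <- agg
    } else {
      parse_error(path, which(duplicated(key))[1] + 1L,
                  "duplicate un-merged position (set merge_strands = TRUE?)")
    }
  }
  out <- df[, c("chrom", "pos", "count_C", "count_T")]
  out$pos <- as.integer(out$pos)
  out$count_C <- as.integer(out$count_C)
  out$count_T <- as.integer(out$count_T)
  order_sites(out)
}

#' Write a per-cell CpG count table
#' @param x data.frame `chrom,pos,count_C,count_T`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(x, path) {
  write.table(x[, c("chrom", "pos", "count_C", "count_T")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like interval file
#'
#' BED3+ with 0-based half-open intervals. `type = "repeats"` expects family
#' and subfamily labels in columns 4-5 (RepeatMasker-style export) and sets
#' `class` to the subfamily; `type = "elements"` takes column 4 as the class
#' label when present.
#'
#' @param path File path.
#' @param type `"elements"`, `"repeats"` or `"plain"`.
#' @param class Class label to assign when the file has no label column.
#' @return Sorted interval data.frame (`chrom,start,end`, plus labels).
#' @export
read_bed <- function(path, type = c("elements", "repeats", "plain"),
                     class = NA_character_) {
  type <- match.arg(type)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) parse_error(path, 1L, "need at least 3 BED columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    parse_error(path, 1L, "columns 2-3 must be numeric coordinates")
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    parse_error(path, bad[1], "start must satisfy 0 <= start < end")
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  out <- df[, 1:3]
  if (type == "repeats") {
    if (ncol(df) < 5L) {
      parse_error(path, 1L, "repeat BED needs family/subfamily columns 4-5")
    }
    out$class <- df[[5]]
    out$family <- df[[4]]
    out$subfamily <- df[[5]]
  } else if (type == "elements") {
    out$class <- if (ncol(df) >= 4L) df[[4]] else class
    out$family <- NA_character_
    out$subfamily <- NA_character_
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' Writes `chrom,start,end` plus any columns named in `extra` (annotation
#' tables write class/family/subfamily; `NA` becomes `.`).
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @param extra Extra column names to append after the first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = intersect(c("class", "family",
                                                   "subfamily"), names(x))) {
  out <- x[, c("chrom", "start", "end", extra), drop = FALSE]
  for (col in extra) out[[col]][is.na(out[[col]])] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a SNP mask
#'
#' Accepts a two-column TSV (`chrom`, `pos`; with or without header) or a
#' BED file, whose intervals are expanded to the 1-based positions they
#' cover. dbSNP-derived masks exported in either form work unchanged.
#'
#' @param path File path.
#' @return data.frame of masked sites (`chrom`, `pos`).
#' @export
read_snp_mask <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:min(3L, ncol(df))] <-
      c("chrom", "pos", "end")[seq_len(min(3L, ncol(df)))]
  }
  if (ncol(df) >= 3L && is.numeric(df[[2]]) && is.numeric(df[[3]])) {
    # BED intervals -> covered 1-based positions
    rows <- lapply(seq_len(nrow(df)), function(i) {
      data.frame(chrom = df[[1]][i],
                 pos = seq.int(df[[2]][i] + 1L, df[[3]][i]))
    })
    return(order_sites(do.call(rbind, rows)))
  }
  order_sites(data.frame(chrom = df$chrom, pos = as.integer(df$pos)))
}

#' Read / write control-molecule count tables
#'
#' TSV with header `kind` (`spike_in`/`lambda`), `pos`, `is_5fC`,
#' `count_C`, `count_T`.
#'
#' @param path File path.
#' @return data.frame of control counts.
#' @export
read_controls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("kind", "pos", "is_5fC", "count_C", "count_T")
  if (!all(need %in% names(df))) {
    parse_error(path, 1L, paste("header must contain",
                                paste(need, collapse = ", ")))
  }
  df$is_5fC <- as.logical(df$is_5fC)
  df
}

#' @rdname read_controls
#' @param x Control data.frame.
#' @export
write_controls <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth table
#' @param truth `fc_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
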