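# Synthetic CLEVER-seq-like data: genome + annotation, ground-truth 5fC map,
# per-cell count tables with spike-in and lambda controls. Defaults encode the
# study conditions the calling scheme was built for: labeling efficiency ~0.8,
# random C-to-T background ~0.0115, ~5x mean per-site coverage, sparse true
# 5fC (1e-4..1e-3 of CpGs) concentrated in L1/ERVK repeats.

# typical element span (bp) per annotation class used by the generator
.element_lengths <- c(
  promoter = 1500, exon = 200, intron = 3000, tts = 2000, cgi = 800,
  L1 = 3000, L2 = 1000, Alu = 300, MIR = 200, ERVK = 1500, ERV1 = 800,
  ERVL = 800, `ERVL-MaLR` = 500, SVA = 1500, ALR = 2000)

.repeat_family <- c(
  L1 = "LINE", L2 = "LINE", Alu = "SINE", MIR = "SINE", ERVK = "LTR",
  ERV1 = "LTR", ERVL = "LTR", `ERVL-MaLR` = "LTR", SVA = "SVA",
  ALR = "satellite")

# class precedence used to assign one generative class per CpG; repeat
# subfamilies outrank element classes so subfamily-specific rates are exact
.truth_precedence <- c(names(.repeat_family), "cgi", "promoter", "exon",
                       "intron", "tts")

#' Default genome fraction per annotation class
#'
#' Approximate hg19-like genome fractions for the element classes and repeat
#' subfamilies the synthetic generator lays down. Values are the fraction of
#' each chromosome covered by intervals of that class; classes may overlap.
#'
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
default_annotation_spec <- function() {
  c(promoter = 0.02, exon = 0.04, intron = 0.25, tts = 0.02, cgi = 0.01,
    L1 = 0.17, L2 = 0.03, Alu = 0.10, MIR = 0.025, ERVK = 0.008,
    ERV1 = 0.02, ERVL = 0.02, `ERVL-MaLR` = 0.035, SVA = 0.002, ALR = 0.03)
}

#' Generate a synthetic genome and annotation set
#'
#' Lays down chromosomes, a registry of CpG dyad positions (1-based
#' plus-strand C coordinates, strictly increasing, no duplicates) and a
#' BED-style annotation of element classes and repeat subfamilies. Interval
#' placement is uniform; classes may overlap each other, as real annotation
#' tracks do. Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length(s) in bp (scalar or one per
#'   chromosome); must be at least 10 kb.
#' @param cpg_density Expected CpG sites per kb.
#' @param annotation_spec Named vector mapping class to genome fraction, as
#'   [default_annotation_spec()].
#' @param seed Integer seed; identical inputs give identical output.
#' @return List with `genome` (an `fc_genome`: `chrom_sizes`, `cpg_sites`)
#'   and `annotation` (data.frame `chrom,start,end,class,family,subfamily`,
#'   0-based half-open).
#' @export
make_genome <- function(n_chrom = 1L, chrom_len = 1e5, cpg_density = 10,
                        annotation_spec = default_annotation_spec(),
                        seed = 1L) {
  if (!is.numeric(n_chrom) || n_chrom < 1) {
    stop_fcpg("invalid parameter: `n_chrom` must be a positive count")
  }
  if (!is.numeric(chrom_len) || any(chrom_len < 1e4)) {
    stop_fcpg("invalid parameter: `chrom_len` must be >= 10 kb")
  }
  if (!is.numeric(cpg_density) || cpg_density < 0) {
    stop_fcpg("invalid parameter: `cpg_density` must be non-negative")
  }
  check_prob(annotation_spec, "annotation_spec")
  unknown <- setdiff(names(annotation_spec), names(.element_lengths))
  if (length(unknown)) {
    stop_fcpg("invalid parameter: unknown annotation class(es): ",
              paste(unknown, collapse = ", "))
  }

  n_chrom <- as.integer(n_chrom)
  lens <- rep_len(as.integer(chrom_len), n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))

  withr::with_seed(as.integer(seed), {
    cpg <- lapply(names(lens), function(ch) {
      len <- lens[[ch]]
      n_sites <- min(round(len / 1000 * cpg_density), len - 1L)
      if (n_sites < 1) return(empty_sites())
      data.frame(chrom = ch,
                 pos = sort(sample.int(len - 1L, n_sites)))
    })
    cpg <- do.call(rbind, cpg)

    ann <- list()
    for (ch in names(lens)) {
      len <- lens[[ch]]
      for (cl in names(annotation_spec)) {
        elen <- .element_lengths[[cl]]
        n_elem <- round(annotation_spec[[cl]] * len / elen)
        if (n_elem < 1) next
        start0 <- sample.int(max(1L, len - elen), n_elem,
                             replace = TRUE) - 1L
        fam <- .repeat_family[cl]
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = ch, start = start0, end = pmin(start0 + elen, len),
          class = cl,
          family = if (is.na(fam)) NA_character_ else unname(fam),
          subfamily = if (is.na(fam)) NA_character_ else cl)
      }
    }
    ann <- if (length(ann)) do.call(rbind, ann) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 class = character(), family = character(),
                 subfamily = character())
    ann <- ann[order(ann$chrom, ann$start, ann$end, ann$class), ]
    rownames(ann) <- NULL

    list(genome = structure(list(chrom_sizes = lens, cpg_sites = cpg),
                            class = "fc_genome"),
         annotation = ann)
  })
}

#' Generate a ground-truth formylation map
#'
#' Assigns each CpG site one generative class (repeat subfamily > CGI >
#' promoter > exon > intron > TTS-region > intergenic) and draws its true
#' state: formylated with the class-specific rate, otherwise methylated but
#' unoxidized or fully unmodified (a split that does not affect read-out,
#' since only 5fC converts to T above background).
#'
#' @param genome `fc_genome` from [make_genome()].
#' @param annotation Annotation data.frame from [make_genome()].
#' @param class_rates Named vector of per-class formylation probabilities;
#'   every name must be an annotation class or `"intergenic"`.
#' @param base_rate Formylation probability for classes not listed in
#'   `class_rates`.
#' @param conversion_eff Probability a read over a formylated C reads out T
#'   (labeling efficiency; the study-average is ~0.8).
#' @param background_rate Probability a read over any non-formylated C reads
#'   out T (random conversion; study-average ~0.0115).
#' @param coverage_mean Mean reads per site per cell.
#' @param meth_fraction Fraction of non-formylated sites carrying unoxidized
#'   5mC (book-keeping only).
#' @param seed Integer seed.
#' @return An `fc_truth`: `sites` (chrom, pos, class, state) plus the
#'   generative parameters.
#' @export
make_truth <- function(genome, annotation,
                       class_rates = c(L1 = 2.5e-3, ERVK = 2.5e-3),
                       base_rate = 5e-4, conversion_eff = 0.8,
                       background_rate = 0.0115, coverage_mean = 5,
                       meth_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(genome, "fc_genome"))
  check_prob(class_rates, "class_rates")
  check_prob(base_rate, "base_rate")
  check_prob(conversion_eff, "conversion_eff")
  check_prob(background_rate, "background_rate")
  check_prob(meth_fraction, "meth_fraction")
  known <- c(unique(annotation$class), "intergenic")
  unknown <- setdiff(names(class_rates), known)
  if (length(unknown)) {
    stop_fcpg("invalid parameter: class_rates name(s) not in annotation: ",
              paste(unknown, collapse = ", "))
  }

  sites <- genome$cpg_sites
  cls <- rep("intergenic", nrow(sites))
  if (nrow(sites)) {
    for (cl in rev(intersect(.truth_precedence, unique(annotation$class)))) {
      hit <- overlap_count(sites, annotation[annotation$class == cl, ,
                                             drop = FALSE]) > 0
      cls[hit] <- cl
    }
  }

  rate <- ifelse(cls %in% names(class_rates),
                 unname(class_rates[cls]), base_rate)

  withr::with_seed(as.integer(seed), {
    u <- runif(nrow(sites))
    state <- ifelse(u < rate, "formylated",
                    ifelse(runif(nrow(sites)) < meth_fraction,
                           "methylated_unoxidized", "unmodified"))
  })

  structure(list(
    sites = cbind(sites, class = cls,
                  state = if (nrow(sites)) state else character(0)),
    class_rates = class_rates, base_rate = base_rate,
    conversion_eff = conversion_eff, background_rate = background_rate,
    coverage_mean = coverage_mean, seed = as.integer(seed)),
    class = "fc_truth")
}

sim_one_cell <- function(truth, treated, zero_truncate) {
  n <- nrow(truth$sites)
  depth <- rpois(n, truth$coverage_mean)
  if (zero_truncate && n) {
    while (any(depth == 0L)) {
      depth[depth == 0L] <- rpois(sum(depth == 0L), truth$coverage_mean)
    }
  }
  p <- ifelse(treated & truth$sites$state == "formylated",
              truth$conversion_eff, truth$background_rate)
  nt <- rbinom(n, depth, p)
  keep <- depth > 0L
  data.frame(chrom = truth$sites$chrom[keep], pos = truth$sites$pos[keep],
             count_C = depth[keep] - nt[keep], count_T = nt[keep])
}

sim_controls <- function(truth, treated, spike_is_fc, n_lambda,
                         control_depth_mean) {
  n_spike <- length(spike_is_fc)
  sp_depth <- rpois(n_spike, control_depth_mean)
  sp_p <- ifelse(spike_is_fc & treated, truth$conversion_eff,
                 truth$background_rate)
  sp_t <- rbinom(n_spike, sp_depth, sp_p)
  la_depth <- rpois(n_lambda, control_depth_mean)
  la_t <- rbinom(n_lambda, la_depth, truth$background_rate)
  rbind(
    data.frame(kind = "spike_in", pos = seq_len(n_spike),
               is_5fC = spike_is_fc, count_C = sp_depth - sp_t,
               count_T = sp_t),
    data.frame(kind = "lambda", pos = seq_len(n_lambda), is_5fC = FALSE,
               count_C = la_depth - la_t, count_T = la_t))
}

#' Simulate per-cell count tables plus control molecules
#'
#' Per site and cell, depth is Poisson with mean `coverage_mean`
#' (independently across cells; optional zero truncation). In treated cells
#' each read over a formylated C reads out T with probability
#' `conversion_eff` and over any other C with probability `background_rate`;
#' untreated (negative control) cells read out T at the background rate
#' everywhere. Spike-in model DNA (137 C positions, a fixed subset truly
#' formylated) and lambda DNA (unmodified) are drawn per cell with the same
#' two rates, so the rate estimators can be validated against truth.
#'
#' @param truth `fc_truth` from [make_truth()].
#' @param n_treated Number of labeled cells (the candidate pool needs at
#'   least two; fewer raises a warning, not an error).
#' @param n_untreated Number of unlabeled negative-control cells.
#' @param seed Integer seed.
#' @param zero_truncate If `TRUE`, per-site depth is zero-truncated Poisson.
#' @param control_depth_mean Mean depth over control C positions.
#' @param n_spike Number of spike-in C positions (137-bp model molecule).
#' @param n_spike_fc How many spike-in positions carry true 5fC.
#' @param n_lambda Number of lambda C positions.
#' @return List with `counts` (named list of per-cell count data.frames),
#'   `controls` (named list of per-cell control tables), and `manifest`
#'   (cell_id, treatment).
#' @export
simulate_cells <- function(truth, n_treated, n_untreated = 0L, seed = 1L,
                           zero_truncate = FALSE, control_depth_mean = 20,
                           n_spike = 137L, n_spike_fc = 12L,
                           n_lambda = 500L) {
  stopifnot(inherits(truth, "fc_truth"))
  check_counts(c(n_treated, n_untreated), "n_treated/n_untreated")
  if (n_treated < 2) {
    warning("fewer than 2 treated cells: the candidate pool will be empty",
            call. = FALSE)
  }
  spike_is_fc <- seq_len(n_spike) %in%
    unique(round(seq(1L, n_spike, length.out = n_spike_fc)))

  ids <- c(if (n_treated > 0) paste0("treated_", seq_len(n_treated)),
           if (n_untreated > 0) paste0("untreated_", seq_len(n_untreated)))
  trt <- c(rep("treated", n_treated), rep("untreated", n_untreated))

  withr::with_seed(as.integer(seed), {
    counts <- vector("list", length(ids))
    controls <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      is_treated <- trt[i] == "treated"
      counts[[i]] <- sim_one_cell(truth, is_treated, zero_truncate)
      controls[[i]] <- sim_controls(truth, is_treated, spike_is_fc,
                                    n_lambda, control_depth_mean)
    }
  })
  names(counts) <- ids
  names(controls) <- ids

  list(counts = counts, controls = controls,
       manifest = data.frame(cell_id = ids, treatment = trt))
}
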