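# End-to-end orchestration: one YAML config drives control-rate QC, pool
# construction, per-cell calling, stage merging and the landscape summaries,
# writing TSV tables plus a machine-readable run log. Deterministic given
# the config and its seeds.

#' Load and validate a pipeline configuration
#'
#' The config is YAML. A `synthetic` section asks the generator for inputs
#' (genome geometry, class rates, rates, coverage, ordered `stages` mapping
#' stage name to treated-cell count, `n_untreated`); an `inputs` section
#' instead points at a manifest TSV (`cell_id, stage, treatment, counts,
#' controls` paths) and optional annotation / SNP-mask files. A `calling`
#' section overrides [calling_config()] fields; `window_size` sets the
#' marked-region grid; `seed` drives every random draw.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Validated config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$window_size <- as.integer(config$window_size %||% 1000L)
  config$calling <- do.call(calling_config, config$calling %||% list())
  if (is.null(config$synthetic) && is.null(config$inputs)) {
    stop_fcpg("config needs either a `synthetic` or an `inputs` section")
  }
  if (!is.null(config$synthetic)) {
    if (length(config$synthetic$stages %||% list()) < 1L) {
      stop_fcpg("config$synthetic$stages must name at least one stage")
    }
  }
  config
}

synth_inputs <- function(cfg) {
  sy <- cfg$synthetic
  gen <- make_genome(n_chrom = sy$n_chrom %||% 1L,
                     chrom_len = sy$chrom_len %||% 1e5,
                     cpg_density = sy$cpg_density %||% 10,
                     seed = cfg$seed)
  rates <- unlist(sy$class_rates %||% list(L1 = 2.5e-3, ERVK = 2.5e-3))
  truth <- make_truth(gen$genome, gen$annotation, class_rates = rates,
                      base_rate = sy$base_rate %||% 5e-4,
                      conversion_eff = sy$conversion_eff %||% 0.8,
                      background_rate = sy$background_rate %||% 0.0115,
                      coverage_mean = sy$coverage_mean %||% 5,
                      seed = cfg$seed + 1L)
  stages <- sy$stages
  n_treated <- sum(unlist(stages))
  n_untreated <- sy$n_untreated %||% 0L
  sim <- simulate_cells(truth, n_treated, n_untreated,
                        seed = cfg$seed + 2L)
  stage_of <- rep(names(stages), times = unlist(stages))
  manifest <- sim$manifest
  manifest$stage <- c(stage_of, rep("control", n_untreated))
  list(genome = gen$genome, annotation = gen$annotation, truth = truth,
       counts = sim$counts, controls = sim$controls, manifest = manifest,
       snp_mask = NULL, stage_order = names(stages))
}

file_inputs <- function(cfg) {
  inp <- cfg$inputs
  manifest <- read.delim(inp$manifest, stringsAsFactors = FALSE)
  counts <- lapply(manifest$counts, read_counts_table,
                   merge_strands = isTRUE(inp$merge_strands))
  names(counts) <- manifest$cell_id
  controls <- lapply(manifest$controls, read_controls)
  names(controls) <- manifest$cell_id
  annotation <- NULL
  if (!is.null(inp$elements_bed)) {
    annotation <- read_bed(inp$elements_bed, type = "elements")
  }
  if (!is.null(inp$repeats_bed)) {
    rep_bed <- read_bed(inp$repeats_bed, type = "repeats")
    annotation <- if (is.null(annotation)) rep_bed else
      rbind(annotation, rep_bed)
  }
  genome <- NULL
  if (!is.null(inp$chrom_sizes)) {
    cs <- read.delim(inp$chrom_sizes, header = FALSE,
                     stringsAsFactors = FALSE)
    genome <- stats::setNames(as.integer(cs[[2]]), cs[[1]])
  }
  snp <- if (!is.null(inp$snp_mask)) read_snp_mask(inp$snp_mask) else NULL
  treated_stages <- unique(manifest$stage[manifest$treatment == "treated"])
  list(genome = genome, annotation = annotation, truth = NULL,
       counts = counts, controls = controls, manifest = manifest,
       snp_mask = snp, stage_order = treated_stages)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 8, format = "g"))
}

write_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], fmt_num)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full calling-and-landscape pipeline
#'
#' Orchestrates, in order: input acquisition (synthetic or from files),
#' per-cell QC rates, candidate and noise pools, SNP masking, per-cell
#' calls, per-stage merging, stage levels and transitions, marked 1-kb
#' windows and per-stage enrichment, and the false-positive detection rate
#' when untreated cells exist. Writes `qc_summary.tsv`, `call_summary.tsv`,
#' `stage_summary.tsv`, `transitions.tsv`, `run_stats.tsv`,
#' `enrichment.tsv` and per-stage `windows_<stage>.bed` under `out_dir`.
#' Deterministic for a fixed config; on error, partial outputs this run
#' created are removed.
#'
#' @param config Path to YAML, or list (see [run_config()]).
#' @param out_dir Output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return Invisibly, the result bundle (qc, pools, calls, stages, tables).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop_fcpg("no output directory given")
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop_fcpg(conditionMessage(e))
  }

  tryCatch({
    stage <- "inputs"
    inp <- if (!is.null(cfg$synthetic)) synth_inputs(cfg) else
      file_inputs(cfg)
    manifest <- inp$manifest
    treated_ids <- manifest$cell_id[manifest$treatment == "treated"]
    untreated_ids <- manifest$cell_id[manifest$treatment == "untreated"]
    if (length(treated_ids) < 2L) {
      stop_fcpg("stage inputs: need >= 2 treated cells")
    }
    message("inputs: ", length(treated_ids), " treated + ",
            length(untreated_ids), " untreated cells")

    stage <- "qc"
    qc <- compute_qc(inp$controls, manifest, cfg$calling)

    stage <- "pools"
    candidate <- build_pool(inp$counts[treated_ids], "candidate",
                            cfg$calling)
    noise <- if (length(untreated_ids)) {
      build_pool(inp$counts[untreated_ids], "noise", cfg$calling)
    } else {
      structure(empty_sites(), kind = "noise")
    }
    message("pools: candidate ", nrow(candidate), ", noise ", nrow(noise))

    stage <- "calls"
    calls <- lapply(manifest$cell_id, function(id) {
      call_cell(inp$counts[[id]], candidate, noise, inp$snp_mask,
                qc[qc$cell_id == id, ], cfg$calling, cell_id = id)
    })
    names(calls) <- manifest$cell_id

    stage <- "stages"
    stages <- lapply(inp$stage_order, function(st) {
      ids <- manifest$cell_id[manifest$stage == st &
                                manifest$treatment == "treated"]
      stage_callset(st, calls[ids], inp$counts[ids],
                    cfg$calling$min_depth_call)
    })
    names(stages) <- inp$stage_order

    stage <- "metrics"
    grid <- if (!is.null(inp$genome)) {
      window_grid(inp$genome, cfg$window_size)
    } else NULL
    transitions <- if (length(stages) >= 2L) {
      do.call(rbind, lapply(seq_len(length(stages) - 1L), function(i) {
        tr <- stage_transition(stages[[i]], stages[[i + 1L]])
        data.frame(from = names(stages)[i], to = names(stages)[i + 1L],
                   inherited = tr$counts[["inherited"]],
                   newly_generated = tr$counts[["newly_generated"]],
                   undetermined = tr$counts[["undetermined"]])
      }))
    } else NULL
    enrichment <- NULL
    if (!is.null(inp$annotation) && nrow(inp$annotation)) {
      enr <- lapply(names(stages), function(st) {
        s <- stages[[st]]
        if (nrow(s$merged_fc) == 0L) return(NULL)
        cbind(stage = st,
              relative_enrichment(s$merged_fc, s$sequenced,
                                  inp$annotation))
      })
      enrichment <- do.call(rbind, enr)
    }
    fpdr <- if (length(untreated_ids)) {
      tryCatch(false_positive_detection_rate(calls[treated_ids],
                                             calls[untreated_ids]),
               error = function(e) NA_real_)
    } else NA_real_
    if (length(untreated_ids) && is.na(fpdr)) {
      message("false-positive detection rate unavailable ",
              "(treated abundance is zero)")
    }

    stage <- "write"
    emit <- function(x, name) {
      p <- file.path(out_dir, name)
      written <<- c(written, p)
      write_tsv(x, p)
    }
    qc_out <- merge(qc, manifest[, c("cell_id", "stage")], by = "cell_id")
    emit(qc_out[order(qc_out$cell_id), ], "qc_summary.tsv")
    call_summary <- do.call(rbind, lapply(manifest$cell_id, function(id) {
      cl <- calls[[id]]
      data.frame(cell_id = id,
                 stage = manifest$stage[manifest$cell_id == id],
                 sequenced_cpg = cl$sequenced_cpg,
                 n_candidate = cl$gates[["candidates"]],
                 n_fc = nrow(cl$fc_sites),
                 n_unmod = nrow(cl$unmod_sites),
                 abundance = cl$abundance)
    }))
    emit(call_summary, "call_summary.tsv")
    stage_summary <- do.call(rbind, lapply(stages, function(s) {
      data.frame(stage = s$label, n_cells = length(s$cell_ids),
                 merged_fc = nrow(s$merged_fc),
                 common_covered = nrow(s$common_covered),
                 stage_fc_fraction = s$stage_fc_fraction,
                 fc_level = fc_level(s))
    }))
    emit(stage_summary, "stage_summary.tsv")
    if (!is.null(transitions)) emit(transitions, "transitions.tsv")
    if (!is.null(enrichment)) emit(enrichment, "enrichment.tsv")
    if (!is.null(grid)) {
      for (st in names(stages)) {
        mw <- mark_windows(stages[[st]]$merged_fc, grid)
        mw <- merge(mw, grid, by = c("chrom", "start"), sort = FALSE)
        mw <- mw[order(mw$chrom, mw$start), , drop = FALSE]
        p <- file.path(out_dir, paste0("windows_", st, ".bed"))
        written <<- c(written, p)
        write_bed(mw, p, extra = character(0))
      }
    }
    gate_totals <- Reduce(`+`, lapply(calls[treated_ids],
                                      function(c) c$gates))
    run_stats <- data.frame(
      metric = c("n_treated", "n_untreated", "candidate_pool_size",
                 "noise_pool_size", "snp_masked_sites",
                 names(gate_totals), "false_positive_detection_rate"),
      value = fmt_num(c(length(treated_ids), length(untreated_ids),
                        nrow(candidate), nrow(noise),
                        if (is.null(inp$snp_mask)) 0 else
                          nrow(inp$snp_mask),
                        unname(gate_totals), fpdr)))
    emit(run_stats, "run_stats.tsv")

    invisible(list(config = cfg, qc = qc, candidate = candidate,
                   noise = noise, calls = calls, stages = stages,
                   transitions = transitions, enrichment = enrichment,
                   fpdr = fpdr, truth = inp$truth, genome = inp$genome,
                   annotation = inp$annotation, manifest = manifest,
                   out_dir = out_dir))
  }, error = function(e) on_fail(simpleError(
    paste0("pipeline stage `", stage, "`: ", conditionMessage(e)))))
}
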