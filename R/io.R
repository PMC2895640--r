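# Tabular input/output and the pipeline driver. All tables are tidy
# (one observation per row) CSV/TSV; delimiter chosen by file extension.

.read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

.check_columns <- function(tab, need, path) {
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

.check_numeric <- function(tab, cols, path) {
  for (col in cols) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1L]
      stop(sprintf("%s: column %s is not numeric (first bad row: %d)",
                   path, col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
}

#' Read a gel band-intensity table
#'
#' Expects one row per band per lane with columns `band_id`, `chromosomes`,
#' `size_kb`, `lane_id`, `intensity`, plus the lane metadata `strain`,
#' `dose_krad`, `time_h`, `is_control` repeated on each row (optional
#' columns `comigrating`, `resolvable` are honoured). Schema violations are
#' reported with row numbers.
#'
#' @param path CSV or TSV file.
#' @return A `gel_lane_table`.
#' @export
read_gel_table <- function(path) {
  tab <- .read_delim_auto(path)
  need <- c("band_id", "chromosomes", "size_kb", "lane_id", "intensity",
            "strain", "dose_krad", "time_h", "is_control")
  .check_columns(tab, need, path)
  .check_numeric(tab, c("size_kb", "intensity", "dose_krad", "time_h"), path)
  if (any(tab$intensity < 0)) {
    stop(sprintf("%s: negative intensity at row %d", path,
                 which(tab$intensity < 0)[1L]), call. = FALSE)
  }
  lane_cols <- c("lane_id", "strain", "dose_krad", "time_h", "is_control")
  lanes <- unique(tab[lane_cols])
  lanes$is_control <- as.logical(lanes$is_control)
  rownames(lanes) <- NULL
  bands <- tab[setdiff(names(tab), setdiff(lane_cols, "lane_id"))]
  if (!is.null(bands$comigrating)) {
    bands$comigrating <- as.logical(bands$comigrating)
  }
  if (!is.null(bands$resolvable)) {
    bands$resolvable <- as.logical(bands$resolvable)
  }
  gel_lane_table(bands, lanes)
}

#' Write a gel band-intensity table
#'
#' Inverse of [read_gel_table()]: lane metadata is joined back onto the
#' band rows, so a written table round-trips losslessly.
#'
#' @param table a `gel_lane_table`.
#' @param path output CSV/TSV path (delimiter from extension).
#' @return `path`, invisibly.
#' @export
write_gel_table <- function(table, path) {
  stopifnot(inherits(table, "gel_lane_table"))
  m <- match(table$bands$lane_id, table$lanes$lane_id)
  out <- cbind(table$bands,
               table$lanes[m, c("strain", "dose_krad", "time_h",
                                "is_control")])
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a colony-count table
#'
#' Tidy plating counts: one row per plate with columns `strain`, `agent`,
#' `dose`, `dose_units`, `replicate`, `medium` (`selective` or `complete`),
#' `cells_plated`, `dilution`, `colonies`.
#'
#' @param path CSV or TSV file.
#' @return Validated data.frame of counts.
#' @export
read_counts <- function(path) {
  tab <- .read_delim_auto(path)
  need <- c("strain", "agent", "dose", "dose_units", "replicate", "medium",
            "cells_plated", "dilution", "colonies")
  .check_columns(tab, need, path)
  .check_numeric(tab, c("dose", "cells_plated", "dilution", "colonies"),
                 path)
  bad <- which(!tab$medium %in% c("selective", "complete"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: medium must be selective/complete (row %d)", path,
                 bad[1L]), call. = FALSE)
  }
  if (any(tab$colonies < 0)) {
    stop(sprintf("%s: negative colony count at row %d", path,
                 which(tab$colonies < 0)[1L]), call. = FALSE)
  }
  tab
}

#' Per-condition recombination frequencies from colony counts
#'
#' Pairs each replicate's selective and complete platings and computes the
#' recombinants-per-survivor frequency, then averages over replicates
#' within each strain/agent/dose.
#'
#' @param counts a data.frame from [read_counts()].
#' @return data.frame with strain, agent, dose, dose_units, n_replicates,
#'   frequency (mean over replicates), sem.
#' @export
counts_to_frequencies <- function(counts) {
  key <- interaction(counts$strain, counts$agent, counts$dose,
                     counts$replicate, drop = TRUE)
  per_rep <- lapply(split(counts, key), function(sub) {
    sel <- sub[sub$medium == "selective", ]
    tot <- sub[sub$medium == "complete", ]
    if (nrow(sel) != 1L || nrow(tot) != 1L) {
      stop("each strain/agent/dose/replicate needs one selective and one ",
           "complete plating", call. = FALSE)
    }
    rec <- frequency_record(
      sel$colonies, sel$cells_plated, tot$colonies, tot$cells_plated,
      selective_dilution = sel$dilution, total_dilution = tot$dilution,
      strain = sel$strain, treatment = sprintf("%s %g %s", sel$agent,
                                               sel$dose, sel$dose_units)
    )
    data.frame(strain = sel$strain, agent = sel$agent, dose = sel$dose,
               dose_units = sel$dose_units,
               frequency = recomb_frequency(rec)$frequency,
               stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, per_rep)
  key2 <- interaction(per_rep$strain, per_rep$agent, per_rep$dose,
                      drop = TRUE)
  out <- lapply(split(per_rep, key2), function(sub) {
    data.frame(strain = sub$strain[1L], agent = sub$agent[1L],
               dose = sub$dose[1L], dose_units = sub$dose_units[1L],
               n_replicates = nrow(sub),
               frequency = mean(sub$frequency),
               sem = stats::sd(sub$frequency) / sqrt(nrow(sub)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$strain, res$agent, res$dose), ]
}

#' Survival curves from complete-medium colony counts
#'
#' For each strain/agent, the surviving fraction at each dose is the
#' dilution-corrected complete-medium colony density divided by the dose-0
#' density, averaged over replicates (SEM across replicates).
#'
#' @param counts a data.frame from [read_counts()].
#' @return Named list of [survival_curve()] objects, one per strain/agent.
#' @export
counts_to_survival <- function(counts) {
  tot <- counts[counts$medium == "complete", ]
  key <- interaction(tot$strain, tot$agent, drop = TRUE)
  out <- lapply(split(tot, key), function(sub) {
    sub$density <- sub$colonies / (sub$cells_plated * sub$dilution)
    base <- sub[sub$dose == 0, ]
    if (nrow(base) == 0L) {
      stop("survival requires dose-0 platings", call. = FALSE)
    }
    base_density <- mean(base$density)
    doses <- sort(unique(sub$dose))
    s <- vapply(doses, function(d) {
      mean(sub$density[sub$dose == d]) / base_density
    }, numeric(1))
    sem <- vapply(doses, function(d) {
      x <- sub$density[sub$dose == d] / base_density
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    }, numeric(1))
    s[doses == 0] <- 1
    survival_curve(doses, s, sem = sem)
  })
  names(out) <- levels(key)
  out
}

#' Read colony genotypes
#'
#' CSV/TSV with columns `colony_id` and `band_sizes` (semicolon-separated
#' bp values); each row is classified against the allele map.
#'
#' @param path CSV or TSV file.
#' @param map an [allele_map()], default [tyr1_allele_map()].
#' @return List of `genotype_call` objects.
#' @export
read_genotypes <- function(path, map = tyr1_allele_map()) {
  tab <- .read_delim_auto(path)
  .check_columns(tab, c("colony_id", "band_sizes"), path)
  if (anyDuplicated(tab$colony_id)) {
    stop(sprintf("%s: duplicate colony_id at row %d", path,
                 which(duplicated(tab$colony_id))[1L]), call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    sizes <- as.numeric(strsplit(as.character(tab$band_sizes[i]), ";")[[1L]])
    if (any(is.na(sizes))) {
      stop(sprintf("%s: non-numeric band size at row %d", path, i),
           call. = FALSE)
    }
    classify_genotype(sizes, map, colony_id = as.character(tab$colony_id[i]))
  })
}

#' Pipeline configuration
#'
#' Collects input paths, analysis switches and seeds. Every stochastic step
#' derives from `seed`, so identical configs give identical outputs. The
#' config round-trips losslessly through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @param gel_table,counts,genotypes,karyotype input paths (`NULL` skips
#'   the stage; karyotype `NULL` uses the packaged yeast karyotype).
#' @param outdir output directory.
#' @param comigration_threshold,clamp,through_origin,tolerance_bp,tails,
#'   n_boot,phase,survival_level analysis switches (see the stage
#'   functions).
#' @param induced_freq optional net Tyr+ frequency for the RE stage; when
#'   `NULL` it is taken from the counts stage at the highest dose.
#' @param ploidy,replicated karyotype interpretation.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(gel_table = NULL, counts = NULL, genotypes = NULL,
                       karyotype = NULL, outdir = ".",
                       comigration_threshold = 0.05, clamp = TRUE,
                       through_origin = TRUE, tolerance_bp = 50, tails = 2,
                       n_boot = 1e4, phase = "G2", survival_level = 0.5,
                       induced_freq = NULL, ploidy = 4, replicated = TRUE,
                       seed = 1L) {
  structure(
    list(gel_table = gel_table, counts = counts, genotypes = genotypes,
         karyotype = karyotype, outdir = outdir,
         comigration_threshold = comigration_threshold, clamp = clamp,
         through_origin = through_origin, tolerance_bp = tolerance_bp,
         tails = tails, n_boot = n_boot, phase = phase,
         survival_level = survival_level, induced_freq = induced_freq,
         ploidy = ploidy, replicated = replicated, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages -- DSB quantification and repair from a
#' gel table, frequency/survival statistics from colony counts, and
#' reciprocal-exchange estimation from genotypes -- writing TSV tables and
#' a JSON summary (including every analysis default in effect) to
#' `config$outdir`. Inputs are checked before any stage runs; identical
#' config and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$gel_table, config$counts, config$genotypes,
              config$karyotype)) {
    if (!file.exists(p)) {
      stop(sprintf("input file not found: %s", p), call. = FALSE)
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  kar <- if (is.null(config$karyotype)) {
    yeast_karyotype(ploidy = config$ploidy, replicated = config$replicated)
  } else {
    read_karyotype(config$karyotype, ploidy = config$ploidy,
                   replicated = config$replicated)
  }
  bundle <- list(config = config, karyotype = kar, outputs = character())
  summary <- list(settings = config[!vapply(config, is.null, logical(1))])

  if (!is.null(config$gel_table)) {
    tab <- read_gel_table(config$gel_table)
    dens <- quantify_dsb(tab, clamp = config$clamp,
                         through_origin = config$through_origin)
    out <- file.path(config$outdir, "dsb_density.tsv")
    utils::write.table(dens[setdiff(names(dens), "estimate")], out,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$dsb <- dens
    bundle$outputs <- c(bundle$outputs, out)
    summary$dsb <- dens[setdiff(names(dens), "estimate")]
    if (any(dens$time_h > 0)) {
      rep_tc <- repair_time_course(tab, clamp = config$clamp,
                                   through_origin = config$through_origin)
      out <- file.path(config$outdir, "repair_time_course.tsv")
      utils::write.table(rep_tc, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      bundle$repair <- rep_tc
      bundle$outputs <- c(bundle$outputs, out)
      summary$repair <- rep_tc
    }
  }

  if (!is.null(config$counts)) {
    counts <- read_counts(config$counts)
    freqs <- counts_to_frequencies(counts)
    out <- file.path(config$outdir, "frequencies.tsv")
    utils::write.table(freqs, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    bundle$frequencies <- freqs
    bundle$outputs <- c(bundle$outputs, out)
    # net frequencies against the dose-0 plating of each strain/agent
    net <- freqs
    net$net_frequency <- NA_real_
    for (k in unique(paste(net$strain, net$agent))) {
      sel <- paste(net$strain, net$agent) == k
      base <- net$frequency[sel & net$dose == 0]
      net$net_frequency[sel] <- if (length(base) == 1L) {
        as.numeric(net_frequency(net$frequency[sel], base))
      } else {
        NA_real_
      }
    }
    bundle$net <- net
    summary$frequencies <- net
    surv <- tryCatch(counts_to_survival(counts), error = function(e) NULL)
    if (!is.null(surv)) {
      out <- file.path(config$outdir, "survival.tsv")
      stab <- do.call(rbind, lapply(names(surv), function(nm) {
        data.frame(group = nm, dose = surv[[nm]]$doses,
                   surviving_fraction = surv[[nm]]$surviving_fraction,
                   sem = surv[[nm]]$sem, stringsAsFactors = FALSE)
      }))
      utils::write.table(stab, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      bundle$survival <- surv
      bundle$outputs <- c(bundle$outputs, out)
      summary$survival <- stab
    }
  }

  if (!is.null(config$genotypes)) {
    map <- tyr1_allele_map(tolerance_bp = config$tolerance_bp)
    calls <- read_genotypes(config$genotypes, map)
    fr <- re_fraction(calls)
    induced <- config$induced_freq
    if (is.null(induced) && !is.null(bundle$net)) {
      top <- bundle$net[which.max(bundle$net$dose), ]
      induced <- top$net_frequency
    }
    re <- if (!is.null(induced) && is.finite(induced) && induced >= 0) {
      expected_re_frequency(fr$fraction, induced, phase = config$phase)
    } else {
      NULL
    }
    out <- file.path(config$outdir, "re_estimate.tsv")
    utils::write.table(
      data.frame(n_colonies = fr$n_colonies, n_y_positive = fr$n_y_positive,
                 fraction = fr$fraction, ci_lo = fr$ci[1], ci_hi = fr$ci[2],
                 correction = if (is.null(re)) NA else re$correction,
                 expected_re_frequency = if (is.null(re)) NA else
                   re$frequency),
      out, sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$re <- list(fraction = fr, expected = re)
    bundle$outputs <- c(bundle$outputs, out)
    summary$re <- list(
      n_colonies = fr$n_colonies, n_y_positive = fr$n_y_positive,
      fraction = fr$fraction, ci = fr$ci,
      correction = if (is.null(re)) NULL else re$correction,
      correction_source = if (is.null(re)) NULL else re$correction_source,
      expected_re_frequency = if (is.null(re)) NULL else re$frequency)
  }

  out <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  bundle$outputs <- c(bundle$outputs, out)
  invisible(bundle)
}

#' Generate a demonstration dataset and analyze it
#'
#' Simulates a gel table (two doses with repair timepoints), colony counts
#' (exponential survival plus dose-proportional recombinant induction) and
#' a genotype panel, writes them to `outdir`, then runs [run_pipeline()] on
#' them. Everything derives from `seed`.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @return Invisibly, the pipeline bundle.
#' @export
run_demo <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  gel <- simulate_gel_lanes(
    kar, breakage_params(0.07, 80, noise_cv = 0.05, seed = seed),
    timepoints = c(0, 1, 4), kinetics = repair_kinetics(rate = 1.2,
                                                        plateau = 0.06))
  gel_path <- file.path(outdir, "synthetic_gel.csv")
  write_gel_table(gel, gel_path)

  counts <- with_seed(seed + 1L, {
    doses <- c(0, 10, 20)
    rows <- list()
    for (r in 1:6) {
      for (d in doses) {
        s <- exp(-d / 40)
        viable <- stats::rbinom(1L, 200L, s)
        freq <- 2e-6 + 7e-6 * d
        sel <- stats::rpois(1L, freq * 1e7 * s)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = "WT", agent = "IR", dose = d, dose_units = "krad",
          replicate = r,
          medium = c("complete", "selective"),
          cells_plated = c(200, 1e7), dilution = c(1, 1),
          colonies = c(max(viable, 1L), sel), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  counts_path <- file.path(outdir, "synthetic_counts.csv")
  utils::write.csv(counts, counts_path, row.names = FALSE)

  map <- tyr1_allele_map()
  geno <- with_seed(seed + 2L, {
    n <- 96
    y_pos <- stats::runif(n) < 0.05
    sizes <- vapply(seq_len(n), function(i) {
      base <- c(1360, 1060, 700)
      if (y_pos[i]) base <- c(base, 400)
      paste(round(base + stats::rnorm(length(base), 0, 10)), collapse = ";")
    }, character(1))
    data.frame(colony_id = sprintf("col%03d", seq_len(n)),
               band_sizes = sizes, stringsAsFactors = FALSE)
  })
  geno_path <- file.path(outdir, "synthetic_genotypes.csv")
  utils::write.csv(geno, geno_path, row.names = FALSE)

  config <- run_config(gel_table = gel_path, counts = counts_path,
                       genotypes = geno_path,
                       outdir = file.path(outdir, "results"), seed = seed)
  write_run_config(config, file.path(outdir, "config.yaml"))
  run_pipeline(config)
}
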