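#' Default run configuration
#'
#' A run configuration is a plain named list (serializable to YAML) that
#' drives \code{\link{run_pipeline}}. Fields: global \code{seed};
#' \code{out_dir}; either \code{synthetic = TRUE} with \code{genome}
#' (overrides for \code{\link{synthetic_genome_config}}), \code{expression}
#' (overrides for \code{\link{expression_config}}) and \code{n_samples},
#' or file inputs \code{genome_fasta}, \code{repeat_annotations},
#' \code{reads_fastq} (named character vector, names = sample ids) and
#' optionally \code{ccds_fasta}; \code{flank_bp}; \code{aligner}
#' (overrides for \code{\link{aligner_config}}); \code{null} (overrides
#' for \code{\link{null_config}}); \code{l1} (\code{bin_width}, optional
#' \code{panel_fasta}); \code{cache} (skip stages whose outputs exist).
#'
#' @param path optional YAML file to load and merge over the defaults.
#' @return named list.
#' @export
run_config <- function(path = NULL) {
  cfg <- list(seed = 1L, out_dir = "retex_run", synthetic = TRUE,
              n_samples = 10L, genome = list(), expression = list(),
              flank_bp = 50L, aligner = list(), null = list(),
              l1 = list(bin_width = 100L), cache = TRUE)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

stage_msg <- function(...) message("[retex] ", ...)

#' Run the full repeat-expression pipeline
#'
#' Orchestrates database construction, read alignment, family counting,
#' uniform-null simulation, the NB exact test, and the LINE-1 5' start
#' profile, writing every result as TSV plus a JSON manifest (seeds, file
#' checksums, stage timings). With \code{cache = TRUE}, stages whose
#' output files already exist are skipped and their outputs re-read, so
#' deleting one output reruns only that stage and those downstream of it.
#'
#' @param config list as returned by \code{\link{run_config}}, or a path
#'   to a YAML file.
#' @return (invisibly) list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- run_config(config)
  cfg <- utils::modifyList(run_config(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")), 2)
    r
  }
  acfg <- do.call(aligner_config, cfg$aligner)
  tax <- family_taxonomy()

  # --- inputs: synthetic or files -------------------------------------
  if (isTRUE(cfg$synthetic)) {
    gcfg <- do.call(synthetic_genome_config,
                    utils::modifyList(cfg$genome,
                                      list(seed = cfg$seed)))
    sg <- tick("make_genome", make_genome(gcfg))
    stage_msg("synthetic genome: ", sum(nchar(sg$genome)), " bp, ",
              nrow(sg$annotations), " repeat copies")
    genome <- sg$genome
    annotations <- sg$annotations
    ccds <- build_coding_db(sg$transcripts)
  } else {
    genome <- as_genome_vector(cfg$genome_fasta)
    annotations <- parse_repeat_annotations(cfg$repeat_annotations, tax)
    ccds <- if (!is.null(cfg$ccds_fasta)) build_coding_db(cfg$ccds_fasta)
            else NULL
    sg <- NULL
  }

  # --- repeat database -------------------------------------------------
  db_dir <- file.path(out, "db")
  db <- if (isTRUE(cfg$cache) && file.exists(file.path(db_dir, "repeat_db.tsv"))) {
    stage_msg("db: cached")
    read_repeat_db(db_dir)
  } else {
    d <- tick("build_db", build_repeat_db(genome, annotations, cfg$flank_bp))
    write_repeat_db(d, db_dir)
    d
  }
  index <- tick("build_index", build_seed_index(db, acfg$seed_len))

  # --- observed samples ------------------------------------------------
  counts_path <- file.path(out, "observed_counts.tsv")
  if (isTRUE(cfg$cache) && file.exists(counts_path)) {
    stage_msg("observed counts: cached")
    obs <- read_counts_tsv(counts_path, "observed")
    obs_reads <- NULL
  } else {
    obs_reads <- list()
    cols <- NULL
    tick("align_observed", {
      if (isTRUE(cfg$synthetic)) {
        for (si in seq_len(cfg$n_samples)) {
          ecfg <- do.call(expression_config,
                          utils::modifyList(cfg$expression,
                                            list(seed = cfg$seed + 1000L + si)))
          sid <- sprintf("sample%02d", si)
          rds <- make_reads(sg, ecfg, sample_id = sid)
          tbl <- align_reads(rds, index, acfg)
          cols <- cbind(cols, count_by_family(tbl, tax))
          colnames(cols)[ncol(cols)] <- sid
          obs_reads[[sid]] <- rds
        }
      } else {
        for (sid in names(cfg$reads_fastq)) {
          rds <- read_fastq(cfg$reads_fastq[[sid]])
          tbl <- align_reads(rds, index, acfg)
          cols <- cbind(cols, count_by_family(tbl, tax))
          colnames(cols)[ncol(cols)] <- sid
          obs_reads[[sid]] <- rds
        }
      }
      NULL
    })
    obs <- family_count_matrix(cols, "observed")
    write_counts_tsv(obs, counts_path)
  }
  stage_msg("observed: ", ncol(obs$counts), " samples, ",
            sum(obs$counts), " repeat-aligned reads")

  # --- uniform null ----------------------------------------------------
  null_path <- file.path(out, "null_counts.tsv")
  mean_aligned <- round(mean(colSums(obs$counts)))
  if (isTRUE(cfg$cache) && file.exists(null_path)) {
    stage_msg("null counts: cached")
    nul <- read_counts_tsv(null_path, "simulated_repeats")
  } else {
    # each null dataset carries about as many repeat-space reads as an
    # observed sample contributed to the repeat database
    ncfg <- do.call(null_config, utils::modifyList(
      list(reads_per_dataset = max(500L, mean_aligned),
           seed = cfg$seed + 5000L),
      cfg$null))
    nul <- tick("null_simulation",
                null_counts(db, ncfg, index, acfg, tax))
    write_counts_tsv(nul, null_path)
  }
  stage_msg("null: ", ncol(nul$counts), " simulated datasets")

  # --- frequencies and test -------------------------------------------
  joint <- family_count_matrix(cbind(obs$counts, nul$counts),
                               c(obs$condition, nul$condition))
  freqs <- family_frequencies(joint)
  utils::write.table(freqs$summary, file.path(out, "family_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res <- tick("nb_test", run_family_test(obs, nul))
  write_test_results(res, file.path(out, "test_results.tsv"))
  stage_msg("test: ", sum(res$p_adj < 0.05), " families at p_adj < 0.05")

  # --- L1 5' profile ---------------------------------------------------
  l1 <- NULL
  panel <- if (!is.null(cfg$l1$panel_fasta)) {
    as_genome_vector(cfg$l1$panel_fasta)
  } else if (isTRUE(cfg$synthetic) && "L1" %in% names(sg$consensus)) {
    sg$consensus["L1"]
  } else NULL
  if (!is.null(panel) && !is.null(obs_reads)) {
    l1 <- tick("l1_profile", {
      sid <- names(obs_reads)[1]
      rds <- obs_reads[[sid]]
      tbl <- align_reads(rds, index, acfg)
      l1_ids <- tbl$read_id[tbl$family == "L1"]
      obs_prof <- start_profile(rds[l1_ids], panel,
                                bin_width = cfg$l1$bin_width,
                                condition = "observed")
      ncfg1 <- null_config(1, max(length(l1_ids) * 5L, 200L),
                           acfg$read_len, seed = cfg$seed + 9000L)
      sim_reads <- {
        if (!is.null(ncfg1$seed)) set.seed(ncfg1$seed)
        simulate_uniform_reads(db, ncfg1$reads_per_dataset, acfg$read_len)
      }
      stbl <- align_reads(sim_reads, index, acfg)
      s_ids <- stbl$read_id[stbl$family == "L1"]
      sim_prof <- start_profile(sim_reads[s_ids], panel,
                                bin_width = cfg$l1$bin_width,
                                condition = "simulated")
      cmp <- profile_comparison(obs_prof, sim_prof)
      utils::write.table(cmp, file.path(out, "l1_start_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(obs_prof$per_read,
                         file.path(out, "l1_per_read.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(observed = obs_prof, simulated = sim_prof, comparison = cmp)
    })
  }

  # --- manifest --------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("retex")),
    seed = cfg$seed,
    timings_sec = timings,
    files = lapply(stats::setNames(files, substring(files, nchar(out) + 2)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(db = db, observed = obs, null = nul, frequencies = freqs,
                 results = res, l1 = l1, manifest = manifest,
                 synth = sg))
}

write_counts_tsv <- function(fcm, path) {
  df <- data.frame(family = rownames(fcm$counts), fcm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_counts_tsv <- function(path, condition) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$family
  family_count_matrix(m, condition)
}
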