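# end-to-end orchestration: simulate -> analyze -> report, with a
# config file, per-stage seeds, and a hashed output manifest

.known_stages <- c(
  "simulate_frap", "simulate_titration", "simulate_genome", "multivalence"
)

# counter-based seed expansion: adding a stage never shifts the streams
# of earlier stages; kept below 2^31 - 1
stage_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) + 1000003 * stage_index) %% 2147483647L) + 1L
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration has top-level keys `seed`, `outdir` and `stages`;
#' each entry of `stages` is named after a pipeline stage
#' (`simulate_frap`, `simulate_titration`, `simulate_genome`,
#' `multivalence`) and holds that stage's parameters, using exactly the
#' parameter-constructor field names. Unknown stages or top-level keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A config list built in R.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  extra <- setdiff(names(config), c("seed", "outdir", "stages"))
  if (length(extra) > 0) {
    abort(paste0("Unknown config keys: ", paste(extra, collapse = ", ")))
  }
  if (is.null(config$seed)) abort("Config must set `seed`.")
  if (is.null(config$stages) || length(config$stages) == 0) {
    abort("Config must select at least one stage.")
  }
  bad <- setdiff(names(config$stages), .known_stages)
  if (length(bad) > 0) {
    abort(paste0("Unknown stages: ", paste(bad, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

run_stage <- function(stage, opts, seed, outdir) {
  files <- character()
  stats <- list()
  if (stage == "simulate_frap") {
    n_cells <- opts$n_cells %||% 10
    opts$n_cells <- NULL
    fits <- purrr::map_dfr(seq_len(n_cells), function(i) {
      p <- do.call(frap_sim_params, c(opts, list(seed = seed + i)))
      tr <- simulate_frap_trace(p)
      f <- write_frap_trace(tr, file.path(outdir, sprintf("frap_trace_%03d.tsv", i)))
      fit <- fit_biexponential(normalize_trace(tr))
      dplyr::bind_cols(tibble(cell = i, file = basename(f)), glance(fit))
    })
    f <- file.path(outdir, "frap_fits.tsv")
    readr::write_tsv(fits, f)
    files <- c(file.path(outdir, sprintf("frap_trace_%03d.tsv", seq_len(n_cells))), f)
    stats$median_t_half <- median(fits$t_half, na.rm = TRUE)
  } else if (stage == "simulate_titration") {
    p <- do.call(titration_sim_params, c(opts, list(seed = seed)))
    series <- simulate_titration(p)
    f <- file.path(outdir, "titration.tsv")
    readr::write_tsv(series, f)
    files <- f
    if (p$readout_mode == "fluorescence") {
      fit <- fit_kd_fluorescence(series, protein_uM = p$protein_total)
    } else {
      fit <- fit_kd_nmr(series, protein_uM = p$protein_total)
    }
    rep_f <- file.path(outdir, "titration_fit.json")
    jsonlite::write_json(
      list(kd = fit$kd, se = fit$standard_error_kd, rss = fit$rss),
      rep_f,
      auto_unbox = TRUE, digits = NA
    )
    files <- c(files, rep_f)
    stats$kd <- fit$kd
  } else if (stage == "simulate_genome") {
    p <- do.call(genome_sim_params, c(opts, list(seed = seed)))
    g <- simulate_genome(p)
    files <- c(
      write_bed(g$nmis, file.path(outdir, "nmis.bed")),
      write_bed(g$background, file.path(outdir, "background.bed"))
    )
    for (nm in names(g$tracks)) {
      files <- c(files, write_bedgraph(
        g$tracks[[nm]],
        file.path(outdir, paste0(nm, ".bedGraph"))
      ))
    }
    rs <- file.path(outdir, "read_summary.tsv")
    readr::write_tsv(g$read_summary, rs)
    nmi_tab <- file.path(outdir, "nmi_table.tsv")
    readr::write_tsv(g$nmis, nmi_tab)
    files <- c(files, rs, nmi_tab)
    stats$n_nmis <- nrow(g$nmis)
    attr(files, "genome") <- g
  } else if (stage == "multivalence") {
    abort("The multivalence stage runs only after simulate_genome.") # caught upstream
  }
  list(files = files, stats = stats)
}

#' Run the synthetic analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (`simulate_frap`, `simulate_titration`, `simulate_genome`, then
#' `multivalence`, which consumes the simulated genome), writing each
#' stage's declared outputs (TSV, BED, bedGraph, JSON) into `outdir`.
#' The global seed is expanded into per-stage seeds with a counter-based
#' scheme, so adding a stage does not shift earlier random streams. A
#' manifest of outputs with MD5 content hashes is written last.
#'
#' @param config A `run_config` (see [read_run_config()]), or a list to
#'   be validated.
#' @param outdir Output directory (created if missing); overrides
#'   `config$outdir`.
#' @return A list of class `run_manifest`: `outputs` (tibble: `stage`,
#'   `file`, `md5`), `stats` (per-stage key statistics), `seed`,
#'   `package_version`, `started`, `finished`. On a stage failure the
#'   error names the failing stage and partial outputs remain on disk
#'   next to a `FAILED_<stage>` marker file.
#' @examples
#' \donttest{
#' cfg <- list(seed = 1, stages = list(
#'   simulate_genome = list(n_nmis = 50, chrom_length = 1e6)
#' ))
#' m <- run_pipeline(cfg, outdir = tempfile())
#' m$outputs
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  outdir <- outdir %||% config$outdir %||% abort("`outdir` is required.")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  started <- Sys.time()

  order <- intersect(.known_stages, names(config$stages))
  if ("multivalence" %in% order && !"simulate_genome" %in% order) {
    abort("Stage `multivalence` requires `simulate_genome` in the same run.")
  }
  outputs <- list()
  stats <- list()
  genome <- NULL

  for (stage in order) {
    idx <- match(stage, .known_stages)
    seed <- stage_seed(config$seed, idx)
    res <- tryCatch(
      {
        if (stage == "multivalence") {
          opts <- config$stages$multivalence
          mt <- multivalence_index(
            genome$nmis,
            signal = opts$signal %||% "expected_ip",
            reference = "biocap", k4 = "k4_level",
            n_bins = opts$n_bins %||% 20,
            n_perm = opts$n_perm %||% 200
          )
          f <- file.path(outdir, "multivalence.json")
          jsonlite::write_json(
            list(
              index = mt$index, null_band = mt$null_band,
              multivalent = mt$multivalent
            ),
            f,
            auto_unbox = TRUE, digits = NA
          )
          prof <- file.path(outdir, "multivalence_profile.tsv")
          readr::write_tsv(mt$profile, prof)
          list(files = c(f, prof), stats = list(index = mt$index))
        } else {
          withr_seed <- seed # per-stage stream; generators re-seed internally
          run_stage(stage, config$stages[[stage]], withr_seed, outdir)
        }
      },
      error = function(e) {
        writeLines(conditionMessage(e), file.path(outdir, paste0("FAILED_", stage)))
        abort(sprintf("Stage `%s` failed: %s", stage, conditionMessage(e)))
      }
    )
    if (!is.null(attr(res$files, "genome"))) genome <- attr(res$files, "genome")
    outputs[[stage]] <- as.character(res$files)
    stats[[stage]] <- res$stats
    message(sprintf(
      "[%s] stage %s: %d file(s)%s", format(Sys.time(), "%H:%M:%S"),
      stage, length(res$files),
      if (length(res$stats)) {
        paste0(
          " | ",
          paste(names(res$stats), signif(unlist(res$stats), 4),
            sep = "=", collapse = ", "
          )
        )
      } else {
        ""
      }
    ))
  }

  out_tbl <- tibble(
    stage = rep(names(outputs), lengths(outputs)),
    file = unlist(outputs, use.names = FALSE)
  )
  out_tbl$md5 <- unname(tools::md5sum(out_tbl$file))
  manifest <- structure(
    list(
      outputs = out_tbl, stats = stats, seed = config$seed,
      package_version = as.character(utils::packageVersion("chromvalence")),
      started = started, finished = Sys.time()
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(
      seed = manifest$seed, package_version = manifest$package_version,
      outputs = out_tbl
    ),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> seed %d, chromvalence %s, %d output file(s)\n",
    x$seed, x$package_version, nrow(x$outputs)
  ))
  print(x$outputs)
  invisible(x)
}
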