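#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. All stages draw their
#' randomness from named substreams of the single `seed`.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed.
#' @param generator Overrides for [generator_config()].
#' @param panel List: `panel_size` (39), `r2_within_lg` (0.01),
#'   `r2_between_lg_max` (0.25), `min_cm` (1).
#' @param hybrid List: `n_sim` (1000), `grid_size` (1001), `eps` (0.025).
#' @param models Character vector of mixing models to compare.
#' @param mixing Overrides for the [fit_mixing_model()] config.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "gsimix_run", seed = 1,
                            generator = list(), panel = list(),
                            hybrid = list(),
                            models = c("M0", "M1", "M2", "M3", "M4"),
                            mixing = list()) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    generator = utils::modifyList(list(seed = seed), generator),
    panel = utils::modifyList(list(panel_size = 39, r2_within_lg = 0.01,
                                   r2_between_lg_max = 0.25, min_cm = 1),
                              panel),
    hybrid = utils::modifyList(list(n_sim = 1000, grid_size = 1001,
                                    eps = 0.025), hybrid),
    models = models,
    mixing = utils::modifyList(list(seed = seed), mixing)
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline on generated data
#'
#' Executes the stages `simulate -> panel -> assign/power -> hybrid-test ->
#' mixmodel` end to end: generates baselines (a selection sample and an
#' independent hold-out sample from the same population truth) plus a survey,
#' high-grades the assignment panel on the selection sample, assigns the
#' survey fish, estimates hold-out leave-one-out power, runs the
#' hybridization test on a map-spread panel, aggregates haul observations and
#' compares the mixing models by WAIC. Every stage writes CSV artifacts under
#' its own subdirectory of `cfg$out_dir` and the run manifest
#' (`manifest.json`) records seed, parameters, filtered-record counts and
#' stage status; a stage failure aborts with the manifest listing the stages
#' already completed.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `status` (0 on success, 1 on failure) and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   params = cfg[setdiff(names(cfg), "out_dir")],
                   stages = list())
  env <- new.env(parent = emptyenv())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  stage <- function(name, fun) {
    dir <- file.path(cfg$out_dir, name)
    dir.create(dir, showWarnings = FALSE)
    res <- tryCatch(list(ok = TRUE, info = fun(dir)),
                    error = function(e) list(ok = FALSE,
                                             info = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = if (res$ok) "complete" else "error",
      detail = if (res$ok) res$info else list(message = res$info))
    flush_manifest()
    if (!res$ok) {
      message("stage '", name, "' failed: ", res$info)
    }
    res$ok
  }

  ok <- stage("01_simulate", function(dir) {
    gcfg <- do.call(generator_config, cfg$generator)
    env$gcfg <- gcfg
    env$ref <- gen_baselines(gcfg, sample_id = "ref")
    env$holdout <- gen_baselines(gcfg, truth = env$ref$truth,
                                 sample_id = "holdout")
    env$survey <- gen_survey(gcfg, env$ref)
    write_genepop(rbind_genotypes(env$ref$east, env$ref$west),
                  file.path(dir, "baselines_ref.gen"),
                  pop = rep(c("east", "west"),
                            c(nrow(env$ref$east$dosage),
                              nrow(env$ref$west$dosage))))
    write_locus_map(env$ref$loci, file.path(dir, "locus_map.csv"))
    utils::write.csv(env$survey$metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(env$survey$hauls, file.path(dir, "hauls.csv"),
                     row.names = FALSE)
    utils::write.csv(env$survey$truth$fish, file.path(dir, "truth_fish.csv"),
                     row.names = FALSE)
    utils::write.csv(env$survey$truth$haul, file.path(dir, "truth_haul.csv"),
                     row.names = FALSE)
    list(n_loci = nrow(env$ref$loci), n_fish = nrow(env$survey$metadata))
  })
  if (ok) ok <- stage("02_panel", function(dir) {
    fst <- wc_fst(allele_counts(env$ref$east), allele_counts(env$ref$west))
    ranked <- rank_loci_by_fst(fst)
    env$panel <- high_grade_panel(ranked, list(env$ref$east, env$ref$west),
                                  panel_size = cfg$panel$panel_size,
                                  r2_within_lg = cfg$panel$r2_within_lg,
                                  r2_between_lg_max = cfg$panel$r2_between_lg_max)
    env$spread <- spread_select(env$ref$loci, min_cm = cfg$panel$min_cm)
    utils::write.csv(env$panel$audit, file.path(dir, "panel_audit.csv"),
                     row.names = FALSE)
    writeLines(env$panel$selected, file.path(dir, "panel_loci.txt"))
    writeLines(env$spread, file.path(dir, "spread_loci.txt"))
    list(panel_size = length(env$panel$selected),
         spread_size = length(env$spread))
  })
  if (ok) ok <- stage("03_assign", function(dir) {
    loci <- env$panel$selected
    env$baselines <- baseline_set(
      east = subset_counts(allele_counts(env$ref$east), loci),
      west = subset_counts(allele_counts(env$ref$west), loci),
      provenance = "pooled reference baselines")
    env$assignments <- assign_individuals(
      subset_genotypes(env$survey$genotypes, loci = loci), env$baselines)
    utils::write.csv(env$assignments, file.path(dir, "assignments.csv"),
                     row.names = FALSE)
    pw <- loo_self_assignment(list(
      east = subset_genotypes(env$holdout$east, loci = loci),
      west = subset_genotypes(env$holdout$west, loci = loci)))
    env$power <- pw
    utils::write.csv(pw$per_population, file.path(dir, "power.csv"),
                     row.names = FALSE)
    utils::write.csv(lr_summary(pw)$distribution,
                     file.path(dir, "lr_distribution.csv"), row.names = FALSE)
    list(n_assigned = sum(!env$assignments$assigned %in%
                            c("ambiguous", "unusable")),
         n_excluded = sum(env$assignments$assigned %in%
                            c("ambiguous", "unusable")),
         misassignment = pw$per_population$misassignment_rate)
  })
  if (ok) ok <- stage("04_hybrid_test", function(dir) {
    loci <- env$spread
    bl <- baseline_set(
      east = subset_counts(allele_counts(env$ref$east), loci),
      west = subset_counts(allele_counts(env$ref$west), loci))
    ht <- hybrid_test(subset_genotypes(env$survey$genotypes, loci = loci),
                      bl, n_sim = cfg$hybrid$n_sim,
                      seed = substream_seed(cfg$seed, "hybrid"),
                      grid_size = cfg$hybrid$grid_size, eps = cfg$hybrid$eps)
    for (nm in c("observed", "parental", "f1")) {
      utils::write.csv(ht[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    as.list(ht$call_counts["admixed", ])
  })
  if (ok) ok <- stage("05_mixmodel", function(dir) {
    hauls <- aggregate_hauls(env$assignments, env$survey$metadata)
    utils::write.csv(hauls, file.path(dir, "haul_observations.csv"),
                     row.names = FALSE)
    cmp <- compare_models(hauls, cfg$models,
                          utils::modifyList(cfg$mixing, list(keep_fits = TRUE)))
    utils::write.csv(cmp, file.path(dir, "waic_table.csv"), row.names = FALSE)
    fits <- attr(cmp, "fits")
    coefs <- do.call(rbind, lapply(names(fits), function(m) {
      s <- summary(fits[[m]])
      s$model_id <- m
      s
    }))
    utils::write.csv(coefs, file.path(dir, "coefficients.csv"),
                     row.names = FALSE)
    for (m in intersect(cfg$models, c("M3", "M4"))) {
      stages <- if (m == "M4") c("adult", "juvenile") else list(NULL)
      for (st in stages) {
        pr <- predict_longitude_profile(fits[[m]], st)
        utils::write.csv(pr$profile,
                         file.path(dir, paste0("profile_", m,
                                               if (!is.null(st)) paste0("_", st),
                                               ".csv")),
                         row.names = FALSE)
      }
    }
    list(n_haul_obs = nrow(hauls), best_model = cmp$model_id[1],
         dropped_hauls = length(attr(hauls, "dropped_hauls")))
  })
  manifest$finished <- format(Sys.time())
  manifest$status <- if (ok) "complete" else "aborted"
  flush_manifest()
  list(status = if (ok) 0L else 1L, manifest = manifest)
}

# ------------------------------------------------------------------ CLI ----

# internal: minimal --key value parser
parse_cli_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[i + 1L])) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `panel`, `assign`, `power`,
#' `hybrid-test`, `mixmodel` and `run-all`. See `inst/cli/gsimix` for the
#' executable wrapper. Common flags: `--seed`, `--out`, `--config`
#' (JSON file of [pipeline_config()] overrides); subcommand-specific inputs
#' are documented in the README.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Integer exit status, invisibly.
#' @export
gsimix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: gsimix <simulate|panel|assign|power|hybrid-test|",
            "mixmodel|run-all> [--seed N] [--out DIR] [--config FILE] ...")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  out_dir <- opt$out %||% "gsimix_out"
  over <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else list()
  status <- tryCatch({
    switch(cmd,
      "run-all" = {
        cfg <- do.call(pipeline_config,
                       utils::modifyList(list(out_dir = out_dir, seed = seed),
                                         over))
        run_pipeline(cfg)$status
      },
      "simulate" = {
        gcfg <- do.call(generator_config,
                        utils::modifyList(list(seed = seed), over))
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        bl <- gen_baselines(gcfg)
        sv <- gen_survey(gcfg, bl)
        write_genepop(rbind_genotypes(bl$east, bl$west),
                      file.path(out_dir, "baselines.gen"),
                      pop = rep(c("east", "west"),
                                c(nrow(bl$east$dosage), nrow(bl$west$dosage))))
        write_dosage_csv(sv$genotypes, file.path(out_dir, "mixture.csv"))
        write_locus_map(bl$loci, file.path(out_dir, "locus_map.csv"))
        utils::write.csv(sv$metadata, file.path(out_dir, "metadata.csv"),
                         row.names = FALSE)
        utils::write.csv(sv$hauls, file.path(out_dir, "hauls.csv"),
                         row.names = FALSE)
        utils::write.csv(sv$truth$fish, file.path(out_dir, "truth_fish.csv"),
                         row.names = FALSE)
        0L
      },
      "panel" = {
        east <- read_dosage_csv(opt$east, read_locus_map(opt$map))
        west <- read_dosage_csv(opt$west, read_locus_map(opt$map))
        ranked <- rank_loci_by_fst(wc_fst(allele_counts(east),
                                          allele_counts(west)))
        ps <- high_grade_panel(ranked, list(east, west),
                               panel_size = as.integer(opt$`panel-size` %||% 39))
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(ps$audit, file.path(out_dir, "panel_audit.csv"),
                         row.names = FALSE)
        writeLines(ps$selected, file.path(out_dir, "panel_loci.txt"))
        0L
      },
      "assign" = {
        east <- read_dosage_csv(opt$east)
        west <- read_dosage_csv(opt$west)
        mix <- read_dosage_csv(opt$mixture)
        bl <- baseline_set(
          east = subset_counts(allele_counts(east), mix$loci$locus_id),
          west = subset_counts(allele_counts(west), mix$loci$locus_id))
        res <- assign_individuals(mix, bl)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(res, file.path(out_dir, "assignments.csv"),
                         row.names = FALSE)
        0L
      },
      "power" = {
        pw <- loo_self_assignment(list(east = read_dosage_csv(opt$east),
                                       west = read_dosage_csv(opt$west)))
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(pw$per_population, file.path(out_dir, "power.csv"),
                         row.names = FALSE)
        utils::write.csv(lr_summary(pw)$distribution,
                         file.path(out_dir, "lr_distribution.csv"),
                         row.names = FALSE)
        0L
      },
      "hybrid-test" = {
        east <- read_dosage_csv(opt$east)
        west <- read_dosage_csv(opt$west)
        mix <- read_dosage_csv(opt$mixture)
        bl <- baseline_set(
          east = subset_counts(allele_counts(east), mix$loci$locus_id),
          west = subset_counts(allele_counts(west), mix$loci$locus_id))
        ht <- hybrid_test(mix, bl,
                          n_sim = as.integer(opt$`n-sim` %||% 1000),
                          seed = seed)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (nm in c("observed", "parental", "f1")) {
          utils::write.csv(ht[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                           row.names = FALSE)
        }
        0L
      },
      "mixmodel" = {
        hauls <- read_haul_table(opt$hauls)
        models <- strsplit(opt$models %||% "M0,M1,M2,M3,M4", ",")[[1]]
        cmp <- compare_models(hauls, models, list(seed = seed))
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(cmp, file.path(out_dir, "waic_table.csv"),
                         row.names = FALSE)
        0L
      },
      { message("unknown subcommand: ", cmd); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
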