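# End-to-end orchestration of the analysis stages with a config list,
# cached intermediate artifacts and a machine-readable run report.

#' Pipeline run configuration
#'
#' @param out_dir output directory for stage artifacts and the run report.
#' @param vcf,labels,panel input paths (required unless the `simulate` stage
#'   provides them).
#' @param sim a [sim_config()] for the `simulate` stage.
#' @param filter a [filter_config()].
#' @param profile a [profile_config()].
#' @param linkage,k_range clustering options (see [stratify_cohort()]).
#' @param cv a [cv_config()].
#' @param screen list with `n`, `fractions`, `score_threshold` for the
#'   screening stage.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @export
run_config <- function(out_dir, vcf = NULL, labels = NULL, panel = NULL,
                       sim = sim_config(), filter = filter_config(),
                       profile = profile_config(),
                       linkage = "average", k_range = 1:8,
                       cv = cv_config(),
                       screen = list(n = 1271, fractions = c(A = 0.005, B = 0.024),
                                     score_threshold = 0.9),
                       seed = 1L) {
  structure(list(
    out_dir = out_dir, vcf = vcf, labels = labels, panel = panel,
    sim = sim, filter = filter, profile = profile,
    linkage = linkage, k_range = k_range, cv = cv, screen = screen,
    seed = as.integer(seed)
  ), class = "run_config")
}

# stable per-stage seed derived from the global seed and the stage name
.stage_seed <- function(seed, stage) {
  (seed * 131L + sum(utf8ToInt(stage)) * 7L) %% 2147483647L
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL                     # analytic identity, not placement
  safe <- rapply(cfg, function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace")
  jsonlite::write_json(safe, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic cohort emission), `filter` (effect /
#' frequency / quality cascade), `associate` (per-variant exact contrasts),
#' `prioritize` (profile selection), `stratify` (Jaccard clustering),
#' `train` (cross-validation and final model), `screen` (external
#' population). Later stages consume the in-memory artifacts of earlier
#' stages in the same call; running a stage without its prerequisite is an
#' error naming the missing stage. A JSON run report with stage timings,
#' filter accounting, the chosen k, cross-validation summaries, screening
#' counts and the configuration hash is written to the output directory.
#'
#' @param config a [run_config()].
#' @param stages ordered subset of the stage names above.
#' @return the run report, invisibly, as a list (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "filter", "associate",
                                    "prioritize", "stratify", "train",
                                    "screen")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "filter", "associate", "prioritize",
                  "stratify", "train", "screen")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  report <- list(config_hash = .config_hash(config), stages = list())
  need <- function(what, from) {
    if (!exists(what, envir = state)) {
      stop("stage requires the '", from, "' stage to run first", call. = FALSE)
    }
    get(what, envir = state)
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    report$stages[[name]] <<- c(
      list(seconds = round(proc.time()[["elapsed"]] - t0, 3)),
      report$stages[[name]]
    )
    value
  }

  for (stage in stages) {
    switch(stage,
      simulate = timed("simulate", {
        cfg <- config$sim
        cfg$seed <- .stage_seed(config$seed, "simulate")
        syn <- generate_cohort(cfg, dir = file.path(config$out_dir, "simulated"))
        assign("syn", syn, envir = state)
        assign("cohort", syn$cohort, envir = state)
        report$stages$simulate$n_variants <- nrow(syn$cohort$geno)
      }),
      filter = timed("filter", {
        if (!exists("cohort", envir = state)) {
          if (is.null(config$vcf) || is.null(config$labels)) {
            stop("stage requires the 'simulate' stage to run first, ",
                 "or vcf/labels paths in the configuration", call. = FALSE)
          }
          rec <- read_annotated_vcf(config$vcf)
          panel <- if (!is.null(config$panel)) read_panel(config$panel)
          assign("cohort", build_cohort_matrix(rec, read_labels(config$labels),
                                               panel), envir = state)
        }
        fl <- apply_filters(get("cohort", envir = state), config$filter)
        assign("filtered", fl$matrix, envir = state)
        write_filter_report(fl$report, file.path(config$out_dir, "filter_report.tsv"))
        report$stages$filter$report <- fl$report
        report$stages$filter$n_demoted <- attr(fl$report, "n_demoted")
      }),
      associate = timed("associate", {
        res <- scan_variants(need("filtered", "filter"))
        data.table::fwrite(res, file.path(config$out_dir, "association.tsv"),
                           sep = "\t")
        report$stages$associate$n_flagged <- sum(res$flagged)
      }),
      prioritize = timed("prioritize", {
        prof <- select_profile(need("filtered", "filter"), config$profile)
        assign("profile", prof, envir = state)
        write_profile(prof,
                      file.path(config$out_dir, "profile.tsv"),
                      file.path(config$out_dir, "accumulation.tsv"))
        report$stages$prioritize$profile_size <- nrow(prof$variants)
      }),
      stratify = timed("stratify", {
        cr <- stratify_cohort(need("filtered", "filter"),
                              need("profile", "prioritize"),
                              linkage = config$linkage,
                              k_range = config$k_range)
        assign("clusters", cr, envir = state)
        dendrogram_newick(cr, file.path(config$out_dir, "dendrogram.nwk"))
        data.table::fwrite(
          data.frame(sample = names(cr$labels), cluster = unname(cr$labels)),
          file.path(config$out_dir, "clusters.tsv"), sep = "\t"
        )
        report$stages$stratify$k <- cr$k
        report$stages$stratify$cluster_sizes <- as.list(table(cr$labels))
      }),
      train = timed("train", {
        cr <- need("clusters", "stratify")
        filtered <- need("filtered", "filter")
        features <- encode_genotypes(filtered, need("profile", "prioritize"))
        cvc <- config$cv
        cvc$seed <- .stage_seed(config$seed, "train")
        rep_cv <- cross_validate(features, cr$labels[rownames(features)], cvc)
        model <- train_final(features, cr$labels[rownames(features)], cvc)
        assign("model", model, envir = state)
        report$stages$train$accuracy <-
          rep_cv$summary$mean[rep_cv$summary$metric == "accuracy"]
        report$stages$train$kappa <-
          rep_cv$summary$mean[rep_cv$summary$metric == "kappa"]
        data.table::fwrite(as.data.frame(rep_cv$pooled_confusion),
                           file.path(config$out_dir, "confusion_pooled.tsv"),
                           sep = "\t")
        if (!is.null(rep_cv$mdi)) {
          data.table::fwrite(rep_cv$mdi, file.path(config$out_dir, "mdi.tsv"),
                             sep = "\t")
        }
      }),
      screen = timed("screen", {
        model <- need("model", "train")
        syn <- need("syn", "simulate")
        ext <- generate_external_population(
          syn, n = config$screen$n, fractions = config$screen$fractions,
          seed = .stage_seed(config$seed, "screen")
        )
        scr <- screen_population(model, ext$features,
                                 config$screen$score_threshold)
        data.table::fwrite(scr, file.path(config$out_dir, "screening.tsv"),
                           sep = "\t")
        report$stages$screen$counts <- as.list(attr(scr, "counts"))
      })
    )
  }
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
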