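# Condition helpers giving the pipeline's error taxonomy (mapped to exit
# codes by the command-line wrapper: config 2, data 3, numerical 4).
.stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("svapath_config_error",
                                             "error", "condition")))
}
.stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("svapath_data_error",
                                             "error", "condition")))
}

# key = value schema per section; NA means "any value allowed".
.config_schema <- list(
  general  = c("seed", "out_dir"),
  simulate = c("enabled", "n_subjects", "a", "b", "cprime", "item_loading",
               "n_neuro_subjects", "n_parcels", "n_voxels", "n_timepoints",
               "tr", "coupling_parcels", "coupling_strength",
               "pattern_parcels", "noise_sd", "write_series"),
  input    = c("questionnaire", "parcel_dir"),
  score    = c("enabled", "cutoff_female", "cutoff_male"),
  stats    = c("enabled"),
  mediate  = c("enabled", "n_boot", "ci_level"),
  alff     = c("enabled", "f_low", "f_high", "normalize"),
  assoc    = c("enabled", "correction", "alpha"),
  isrsa    = c("enabled", "alpha", "n_perm"))

.config_defaults <- function() {
  list(general = list(seed = 1L, out_dir = "svapath_out"),
       simulate = list(enabled = TRUE, n_subjects = 400, a = 0.4, b = 0.3,
                       cprime = 0.18, item_loading = 0.8,
                       n_neuro_subjects = 60, n_parcels = 40, n_voxels = 12,
                       n_timepoints = 150, tr = 2,
                       coupling_parcels = c(3, 7), coupling_strength = 0.5,
                       pattern_parcels = c(5, 9), noise_sd = 1,
                       write_series = FALSE),
       input = list(),
       score = list(enabled = TRUE, cutoff_female = 33, cutoff_male = 31),
       stats = list(enabled = TRUE),
       mediate = list(enabled = TRUE, n_boot = 1000, ci_level = 0.95),
       alff = list(enabled = TRUE, f_low = 0.01, f_high = 0.1,
                   normalize = "raw"),
       assoc = list(enabled = TRUE, correction = "bonferroni", alpha = 0.05),
       isrsa = list(enabled = TRUE, alpha = 0.05, n_perm = 0))
}

.parse_value <- function(s) {
  parts <- strsplit(trimws(s), "[[:space:],]+")[[1]]
  parts <- parts[nzchar(parts)]
  if (all(tolower(parts) %in% c("true", "false")))
    return(tolower(parts) == "true")
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  paste(parts, collapse = " ")
}

#' Read and validate a pipeline configuration file
#'
#' The configuration is plain text: \code{[section]} headers followed by
#' \code{key = value} lines (\code{#} starts a comment; vector values
#' are whitespace-separated). Unknown sections or keys are rejected
#' before any stage runs; omitted keys take package defaults. Every
#' stage section has an \code{enabled} toggle.
#'
#' @param path config file path, or \code{NULL} for pure defaults.
#' @return nested named list of class \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) .stop_config("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    section <- NULL
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) next
      if (grepl("^\\[.*\\]$", ln)) {
        section <- sub("^\\[(.*)\\]$", "\\1", ln)
        if (!section %in% names(.config_schema))
          .stop_config("unknown config section [", section, "] (line ", i, ")")
        next
      }
      if (!grepl("=", ln))
        .stop_config("expected 'key = value' at line ", i, ": ", ln)
      if (is.null(section))
        .stop_config("key outside any [section] at line ", i)
      key <- trimws(sub("=.*$", "", ln))
      if (!key %in% .config_schema[[section]])
        .stop_config("unknown key '", key, "' in section [", section, "]")
      cfg[[section]][[key]] <- .parse_value(sub("^[^=]*=", "", ln))
    }
  }
  cfg$general$seed <- as.integer(cfg$general$seed)
  if (cfg$assoc$alpha <= 0 || cfg$assoc$alpha >= 1 ||
      cfg$isrsa$alpha <= 0 || cfg$isrsa$alpha >= 1)
    .stop_config("alpha must lie in (0, 1)")
  if (!isTRUE(cfg$simulate$enabled) && is.null(cfg$input$questionnaire))
    .stop_config("simulate disabled and no [input] questionnaire given")
  structure(cfg, class = c("pipeline_config", "list"))
}

# Stable checksum of the config sections an artifact depends on, embedded
# in output headers so partial re-runs only reuse matching artifacts.
.config_checksum <- function(cfg, sections) {
  flat <- unlist(cfg[sections])
  # toggles and output location don't alter artifact content
  flat <- flat[!grepl("\\.enabled$|\\.out_dir$", names(flat))]
  txt <- paste(names(flat), vapply(flat, format, ""), collapse = ";")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 1000000007
}

.meta <- function(cfg, stage, sections) {
  c(pipeline = "svapath", stage = stage,
    seed = cfg$general$seed,
    config_checksum = .config_checksum(cfg, sections))
}

.check_reuse <- function(path, cfg, sections, stage) {
  if (!file.exists(path))
    .stop_data("stage '", stage, "' disabled and its artifact is missing: ",
               path)
  hdr <- grep("^# config_checksum:", readLines(path, n = 10), value = TRUE)
  if (length(hdr)) {
    recorded <- trimws(sub("^# config_checksum:", "", hdr[1]))
    if (recorded != as.character(.config_checksum(cfg, sections)))
      .stop_data("artifact ", path, " was produced under a different ",
                 "configuration; re-enable stage '", stage, "'")
  }
  path
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the toggled stages in order — simulate, score, stats,
#' mediate, alff, assoc, isrsa — writing every artifact as delimited
#' text under the configured output directory with the stage, seed and
#' a configuration checksum embedded in header comments. Identical
#' configuration and seed give byte-identical outputs. When a stage is
#' disabled, its artifact is re-read from the output directory (or the
#' \code{[input]} paths) and its recorded checksum must match the
#' current configuration.
#'
#' @param config a \code{\link{read_pipeline_config}} result or a path
#'   to a config file.
#' @return invisibly, a list with the in-memory stage results and the
#'   paths of all written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    .stop_config("config must be a pipeline_config or a file path")
  cfg <- config
  out <- cfg$general$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$general$seed
  files <- character(0)
  res <- list()
  log_stage <- function(stage, msg)
    message(sprintf("[svapath:%s seed=%d] %s", stage, seed, msg))

  # -- simulate ---------------------------------------------------------
  q_path <- file.path(out, "questionnaire.tsv")
  maps <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    s <- cfg$simulate
    log_stage("simulate", sprintf("cohort n=%d, neuro n=%d x %d parcels",
                                  s$n_subjects, s$n_neuro_subjects, s$n_parcels))
    gp <- gen_params(n_subjects = s$n_subjects, a_true = s$a, b_true = s$b,
                     cprime_true = s$cprime, item_loading = s$item_loading,
                     seed = seed)
    cohort <- gen_questionnaire_cohort(gp)
    write_questionnaire(cohort, q_path,
                        meta = .meta(cfg, "simulate", c("general", "simulate")))
    write_truth_record(list(a = s$a, b = s$b, cprime = s$cprime,
                            c = s$cprime + s$a * s$b, seed = seed,
                            coupling_parcels = s$coupling_parcels,
                            pattern_parcels = s$pattern_parcels,
                            coupling_strength = s$coupling_strength),
                       file.path(out, "truth.txt"))
    files <- c(files, q_path, file.path(out, "truth.txt"))
    res$cohort <- cohort

    idx <- seq_len(min(s$n_neuro_subjects, s$n_subjects))
    sva_items <- as.matrix(
      cohort$items[idx, grep("^sva_item", names(cohort$items))])
    trait <- rowSums(sva_items)
    np <- neuro_gen_params(
      n_subjects = length(idx), n_parcels = s$n_parcels,
      n_voxels_per_parcel = s$n_voxels, n_timepoints = s$n_timepoints,
      tr_seconds = s$tr, coupling_parcels = s$coupling_parcels,
      coupling_strength = s$coupling_strength,
      pattern_coupling_parcels = s$pattern_parcels,
      noise_sd = s$noise_sd, seed = seed)
    if (isTRUE(s$write_series)) {
      ts_set <- gen_resting_parcels(np, trait, sva_items)
      write_parcel_set(ts_set, file.path(out, "parcels"))
      files <- c(files, file.path(out, "parcels", "manifest.tsv"))
      maps <- alff_maps(ts_set, band = c(cfg$alff$f_low, cfg$alff$f_high),
                        normalize = cfg$alff$normalize)
    } else {
      maps <- simulate_alff_maps(np, trait, sva_items,
                                 band = c(cfg$alff$f_low, cfg$alff$f_high),
                                 normalize = cfg$alff$normalize)
    }
    res$neuro <- list(trait = trait, sva_items = sva_items,
                      subjects = maps$subjects)
  } else {
    src <- cfg$input$questionnaire %||%
      .check_reuse(q_path, cfg, c("general", "simulate"), "simulate")
    if (!file.exists(src)) .stop_data("questionnaire not found: ", src)
    res$cohort <- list(items = read_questionnaire(src))
    if (!is.null(cfg$input$parcel_dir)) {
      ts_set <- read_parcel_set(cfg$input$parcel_dir)
      maps <- alff_maps(ts_set, band = c(cfg$alff$f_low, cfg$alff$f_high),
                        normalize = cfg$alff$normalize)
      sva_cols <- grep("^sva_item", names(res$cohort$items))
      idx <- seq_len(min(length(maps$subjects), nrow(res$cohort$items)))
      res$neuro <- list(
        trait = rowSums(res$cohort$items[idx, sva_cols, drop = FALSE]),
        sva_items = as.matrix(res$cohort$items[idx, sva_cols, drop = FALSE]),
        subjects = maps$subjects)
    }
  }

  # -- score ------------------------------------------------------------
  scored <- NULL
  if (isTRUE(cfg$score$enabled)) {
    log_stage("score", "scoring scales and classifying addiction")
    defs <- default_scales()
    defs$sva$cutoffs <- c(F = cfg$score$cutoff_female,
                          M = cfg$score$cutoff_male)
    scored <- score_cohort(res$cohort$items, defs)
    p <- file.path(out, "scored.tsv")
    write_table_tsv(as.data.frame(scored), p,
                    meta = .meta(cfg, "score", c("general", "score")))
    files <- c(files, p)
    res$scored <- scored
  }

  # -- stats ------------------------------------------------------------
  if (isTRUE(cfg$stats$enabled)) {
    if (is.null(scored)) .stop_data("stats stage needs the score stage")
    log_stage("stats", "descriptives, reliability, common-method bias")
    vars <- c("sva", "bv", "vb", "pb", "rb", "na")
    desc <- do.call(rbind, lapply(vars, function(v) {
      x <- scored[[v]]
      data.frame(scale = v, mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE),
                 min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
    }))
    item_cols <- grep("_item[0-9]+$", names(res$cohort$items), value = TRUE)
    alphas <- vapply(c("sva", "vb", "pb", "rb", "na", "pa"), function(s)
      cronbach_alpha(res$cohort$items[grep(paste0("^", s, "_item"),
                                           names(res$cohort$items))]), 0)
    harman <- harman_single_factor(res$cohort$items[item_cols])
    ct <- pearson_corr_matrix(as.data.frame(scored), vars)
    kv <- data.frame(
      key = c(paste0("alpha_", names(alphas)), "harman_n_factors",
              "harman_first_factor_pct", "harman_bias_flagged", "n_scored"),
      value = c(round(alphas, 4), harman$n_factors,
                round(harman$first_factor_pct, 2), harman$bias_flagged,
                nrow(scored)))
    p1 <- file.path(out, "descriptives.tsv")
    p2 <- file.path(out, "stats.tsv")
    p3 <- file.path(out, "correlations.tsv")
    write_table_tsv(desc, p1, meta = .meta(cfg, "stats", c("general", "stats")))
    write_table_tsv(kv, p2, meta = .meta(cfg, "stats", c("general", "stats")))
    write_table_tsv(data.frame(variable = rownames(ct$r),
                               round(ct$r, 4), check.names = FALSE),
                    p3, meta = .meta(cfg, "stats", c("general", "stats")))
    files <- c(files, p1, p2, p3)
    res$stats <- list(descriptives = desc, alphas = alphas, harman = harman,
                      correlations = ct)
  }

  # -- mediate ----------------------------------------------------------
  if (isTRUE(cfg$mediate$enabled)) {
    if (is.null(scored)) .stop_data("mediate stage needs the score stage")
    log_stage("mediate", sprintf("bootstrap mediation, %d resamples",
                                 cfg$mediate$n_boot))
    rows <- list()
    for (x in c("bv", "vb", "pb", "rb")) {
      whole <- mediate(scored[[x]], scored$na, scored$sva,
                       n_boot = cfg$mediate$n_boot,
                       ci_level = cfg$mediate$ci_level, seed = seed + 17L)
      rows[[length(rows) + 1]] <- .med_row(x, "all", whole)
      sub <- subgroup_mediate(as.data.frame(scored), x, "na", "sva",
                              n_boot = cfg$mediate$n_boot,
                              ci_level = cfg$mediate$ci_level,
                              seed = seed + 17L)
      for (g in names(sub))
        rows[[length(rows) + 1]] <- .med_row(x, g, sub[[g]]$mediation)
    }
    med_tab <- do.call(rbind, rows)
    p <- file.path(out, "mediation.tsv")
    write_table_tsv(med_tab, p,
                    meta = .meta(cfg, "mediate", c("general", "mediate")))
    files <- c(files, p)
    res$mediation <- med_tab
  }

  # -- alff / assoc / isrsa --------------------------------------------
  if (isTRUE(cfg$alff$enabled) || isTRUE(cfg$assoc$enabled) ||
      isTRUE(cfg$isrsa$enabled)) {
    if (is.null(maps))
      .stop_data("neural stages need simulated or supplied parcel data")
  }
  if (isTRUE(cfg$alff$enabled)) {
    log_stage("alff", sprintf("band %.3f-%.3f Hz, %s maps",
                              cfg$alff$f_low, cfg$alff$f_high,
                              maps$normalization))
    pm <- parcel_means(maps)
    p <- file.path(out, "alff_parcel_means.tsv")
    write_table_tsv(data.frame(subject = maps$subjects, round(pm, 6),
                               check.names = FALSE), p,
                    meta = c(.meta(cfg, "alff", c("general", "alff")),
                             band_low_hz = cfg$alff$f_low,
                             band_high_hz = cfg$alff$f_high,
                             normalization = maps$normalization))
    files <- c(files, p)
    res$alff <- maps
  }
  if (isTRUE(cfg$assoc$enabled)) {
    log_stage("assoc", paste("parcel association,", cfg$assoc$correction))
    assoc <- parcel_association(maps, res$neuro$trait,
                                correction = cfg$assoc$correction,
                                alpha = cfg$assoc$alpha)
    p <- file.path(out, "association.tsv")
    write_table_tsv(as.data.frame(assoc), p,
                    meta = .meta(cfg, "assoc", c("general", "assoc")))
    files <- c(files, p)
    res$association <- assoc
  }
  if (isTRUE(cfg$isrsa$enabled)) {
    log_stage("isrsa", "behavioral and neural RDM correlation")
    brdm <- behavioral_rdm(res$neuro$sva_items, subjects = maps$subjects)
    is_res <- isrsa_map(brdm, maps, alpha = cfg$isrsa$alpha)
    if (cfg$isrsa$n_perm >= 99) {
      top <- is_res$parcel[which.max(is_res$r)]
      mp <- mantel_permutation(brdm, neural_rdm(maps, top),
                               n_perm = cfg$isrsa$n_perm, seed = seed + 23L)
      is_res$p_perm <- NA_real_
      is_res$p_perm[is_res$parcel == top] <- mp$p
    }
    p <- file.path(out, "isrsa.tsv")
    write_table_tsv(as.data.frame(is_res), p,
                    meta = .meta(cfg, "isrsa", c("general", "isrsa")))
    files <- c(files, p)
    res$isrsa <- is_res
  }

  invisible(list(results = res, files = files, config = cfg))
}

.med_row <- function(x, subgroup, m) {
  data.frame(x = x, subgroup = subgroup, n = m$n, a = m$a, b = m$b,
             c = m$c, cprime = m$cprime, indirect = m$indirect,
             ci_low = m$ci_low, ci_high = m$ci_high,
             prop_mediated = m$prop_mediated, n_boot = m$n_boot)
}
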