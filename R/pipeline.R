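# End-to-end pipeline: simulate or read inputs, align them, then run the
# alpha, beta and driver stages and write one CSV per result table plus a
# run log. All randomness flows from a single master seed through
# per-stage derived seeds, so stages are reproducible in isolation.

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 37 + h * 101) %% 2147483629)
}

#' Pipeline run configuration
#'
#' Either supply the four input paths (`survey`, `tree`, `env`, `dam`,
#' optionally `pairs`) or set `simulate = TRUE` to generate them from
#' `scenario`. Defaults follow the reservoir-survey conventions: 999
#' permutations for the null model, dominance thresholds 500/100, and a
#' 0.05 significance level.
#'
#' @param out_dir Directory for output CSVs and the run log.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param permutations Null-model and Mantel permutations (>= 99).
#' @param thresholds `c(dominant, common)` IRI thresholds.
#' @param alpha_level Significance level recorded in the log.
#' @param simulate Generate synthetic inputs instead of reading files?
#' @param scenario A [scenario_spec()] used when `simulate = TRUE`.
#' @param survey,tree,env,dam,pairs Input file paths (long survey CSV,
#'   newick, environment CSV, dam-distance CSV, optional pairwise river
#'   distance CSV).
#' @param align_policy `"strict"` or `"prune"`, see [align_inputs()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempdir(), seed = 1, permutations = 999,
                       thresholds = c(500, 100), alpha_level = 0.05,
                       simulate = TRUE, scenario = scenario_spec(seed = seed),
                       survey = NULL, tree = NULL, env = NULL, dam = NULL,
                       pairs = NULL, align_policy = "strict") {
  if (permutations < 99) abort("permutations must be at least 99")
  if (length(thresholds) != 2 || !(thresholds[1] > thresholds[2])) {
    abort("thresholds must be strictly ordered c(dominant, common)")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         permutations = as.integer(permutations), thresholds = thresholds,
         alpha_level = alpha_level, simulate = simulate, scenario = scenario,
         survey = survey, tree = tree, env = env, dam = dam, pairs = pairs,
         align_policy = align_policy),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [run_config()]; scenario fields go
#' under a `scenario:` mapping.
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  sc <- do.call(scenario_spec, raw$scenario %||% list())
  raw$scenario <- NULL
  args <- utils::modifyList(raw, list(...))
  args$scenario <- sc
  do.call(run_config, args)
}

#' Run the full diversity pipeline
#'
#' Orchestrates, in order: input loading (or synthesis), alignment,
#' taxonomic alpha-diversity and IRI, sampling completeness, phylogenetic
#' alpha-diversity with SES null models, pairwise beta-diversity at both
#' levels with summaries and the level contrast, and driver analyses
#' (correlation screen, distance decay, hierarchical partitioning, GAM
#' trends along dam distance). Writes one CSV per table plus `run_log.txt`
#' into `config$out_dir`. Deterministic given the master seed.
#'
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("alpha", "beta", "drivers")` to run (inputs are always prepared).
#' @return Invisibly, a named list of all result tables.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("alpha", "beta", "drivers")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    "fishdiv pipeline run",
    paste0("package version: ", as.character(packageVersion("fishdiv"))),
    paste0("R version: ", R.version.string),
    paste0("master seed: ", config$seed),
    paste0("permutations: ", config$permutations),
    if (config$permutations < 999) "WARNING: low replicate count for the null model",
    paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  results <- list()
  out_csv <- function(x, name) {
    readr::write_csv(x, file.path(config$out_dir, paste0(name, ".csv")))
    results[[name]] <<- x
  }
  run_stage <- function(stage, expr) {
    say("stage: ", stage, " (seed ", stage_seed(config$seed, stage), ")")
    tryCatch(expr, error = function(e) {
      say("FAILED at stage ", stage, ": ", conditionMessage(e))
      writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
      abort(paste0("pipeline failed at stage '", stage, "': ",
                   conditionMessage(e)))
    })
  }

  inputs <- run_stage("inputs", {
    if (config$simulate) {
      sc <- config$scenario
      sc$seed <- stage_seed(config$seed, "simulate")
      simulate_scenario(sc)
    } else {
      list(
        survey = read_survey(config$survey),
        tree = read_phylogeny(config$tree),
        env = read_environment(config$env),
        layout = read_layout(config$dam, config$pairs)
      )
    }
  })
  bundle <- run_stage("align", {
    align_inputs(inputs$survey, inputs$tree, inputs$env, inputs$layout,
                 policy = config$align_policy)
  })
  survey <- bundle$survey; tree <- bundle$tree
  env <- bundle$env; layout <- bundle$layout

  if ("alpha" %in% stages) {
    run_stage("alpha_taxonomic", {
      out_csv(alpha_taxonomic(survey), "alpha_taxonomic")
      out_csv(iri_table(survey, config$thresholds), "iri")
      out_csv(sampling_completeness(survey), "completeness")
    })
    run_stage("alpha_phylogenetic", {
      out_csv(phylo_alpha(survey, tree), "alpha_phylo")
      out_csv(
        ses_null(survey, tree, metric = c("pd", "mpd_abu", "vpd_abu"),
                 n_perm = config$permutations,
                 seed = stage_seed(config$seed, "ses")),
        "ses"
      )
    })
  }

  if (any(c("beta", "drivers") %in% stages)) {
    pairs <- run_stage("beta_pairs", beta_pairs(survey, tree))
    if ("beta" %in% stages) {
      run_stage("beta_summary", {
        out_csv(pairs, "beta_pairs")
        bs <- beta_summary(pairs)
        bs$beta_dev <- beta_deviation(
          bs$mean_sor[bs$level == "taxonomic"],
          bs$mean_sor[bs$level == "phylogenetic"]
        )
        out_csv(bs, "beta_summary")
        out_csv(
          list_rbind(map(c("sor", "turn", "nes"),
                         function(cc) compare_levels(pairs, cc))),
          "level_contrast"
        )
      })
    }
  }

  if ("drivers" %in% stages) {
    run_stage("drivers", {
      het <- env_heterogeneity(env)
      env_d <- env_distance_matrix(env)
      space_d <- layout$pair_distance
      dam_km <- layout$dam_distance

      alpha_tab <- alpha_taxonomic(survey) |>
        select("site", "S", "margalef", "shannon", "pielou", "hellinger_div")
      phy_tab <- phylo_alpha(survey, tree)
      idx_tab <- left_join(alpha_tab, phy_tab, by = "site")
      drv <- left_join(env, dam_km, by = "site") |>
        rename(dam_distance = "dam_km")
      out_csv(spearman_bh_screen(idx_tab, drv), "correlation_screen")

      grid <- crossing(level = unique(pairs$level),
                       component = c("sor", "turn", "nes"),
                       predictor = c("environment", "spatial"))
      fits <- pmap(grid, function(level, component, predictor) {
        pm <- if (predictor == "environment") env_d else space_d
        fit <- distance_decay(
          pairs, pm, component = component, level = level,
          predictor_name = predictor, n_perm = config$permutations,
          seed = stage_seed(config$seed, paste(level, component, predictor))
        )
        glance(fit)
      })
      out_csv(list_rbind(fits), "decay_fits")

      hp_grid <- crossing(level = unique(pairs$level),
                          component = c("sor", "turn", "nes"))
      hp_rows <- pmap(hp_grid, function(level, component) {
        sub <- pairs[pairs$level == level, ]
        col <- paste0("beta_", ifelse(component == "sor", "sor", component))
        hp <- hierarchical_partition(
          sub[[col]], pair_predictor(sub, env_d), pair_predictor(sub, space_d)
        )
        bind_cols(tibble(level = level, component = component),
                  tidy(hp), glance(hp))
      })
      out_csv(list_rbind(hp_rows), "hp_results")

      env_vars <- setdiff(names(env), "site")
      trend_rows <- map(c(env_vars, "heterogeneity"), function(v) {
        y <- if (v == "heterogeneity") het$per_site$distance else env[[v]]
        fit <- tryCatch(smooth_trend(dam_km$dam_km, y),
                        error = function(e) NULL)
        if (is.null(fit)) return(tibble(variable = v))
        bind_cols(tibble(variable = v), glance(fit))
      })
      out_csv(list_rbind(trend_rows), "trend_fits")
      out_csv(
        bind_rows(het$per_site,
                  tibble(site = "overall", distance = het$overall)),
        "env_heterogeneity"
      )
    })
  }

  say("finished: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  results$log <- log_lines
  invisible(results)
}
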