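# Scenario presets, replicate orchestration, manifests and summaries.
#
# A "scenario" is a named preset over one of the three simulators:
#   panic:      "default" (single v), "sweep" (full visibility sweep)
#   conformity: "exp1" (p = 0.1), "exp2" (p = 0.2), "exp3" (p = 0.3)
#   contagion:  "sim1" (baseline), "sim2" (m = 0.2),
#               "sim3" (constant recovery), "sim4" (cumulative influence)

scenario_presets <- list(
  panic = list(
    default = list(),
    sweep = list(v_grid = seq(0.01, 2, by = 0.01))
  ),
  conformity = list(
    exp1 = list(rewiring_prob = 0.1),
    exp2 = list(rewiring_prob = 0.2),
    exp3 = list(rewiring_prob = 0.3)
  ),
  contagion = list(
    sim1 = list(),
    sim2 = list(assortative_prob = 0.2),
    sim3 = list(constant_recovery = TRUE),
    sim4 = list(cumulative_influence = TRUE)
  )
)

#' Resolve a scenario preset into a simulator configuration
#'
#' Maps a model name and preset name (plus optional flat overrides whose
#' keys mirror the config fields, e.g. `n_nodes`, `degree`,
#' `rewiring_prob`, `visibility`, `assortative_prob`, ...) to the
#' corresponding config object. The panic `"sweep"` preset additionally
#' carries the visibility grid `v = 0.01, 0.02, ..., 2` as attribute
#' `"v_grid"`.
#'
#' @param model one of `"panic"`, `"conformity"`, `"contagion"`.
#' @param scenario preset name (see above).
#' @param overrides named list of config-field overrides.
#' @param seed integer seed stored in the config, or `NULL`.
#' @return A `panic_config`, `conformity_config` or `contagion_config`.
#' @examples
#' scenario_config("contagion", "sim2")$assortative_prob  # 0.2
#' @export
scenario_config <- function(model, scenario = names(scenario_presets[[model]])[1],
                            overrides = list(), seed = NULL) {
  model <- match.arg(model, names(scenario_presets))
  if (!scenario %in% names(scenario_presets[[model]]))
    stop_bad(sprintf("unknown %s scenario '%s' (known: %s)", model, scenario,
                     paste(names(scenario_presets[[model]]), collapse = ", ")))
  args <- utils::modifyList(scenario_presets[[model]][[scenario]], overrides)
  v_grid <- args$v_grid
  args$v_grid <- NULL
  cfg <- switch(model,
    panic = {
      do.call(panic_config, c(args, list(seed = seed)))
    },
    conformity = {
      net_keys <- intersect(names(args), c("n_nodes", "degree", "rewiring_prob"))
      sf_keys <- intersect(names(args), c("anti_fraction_target", "smoothness",
                                          "amplitude", "mean_level"))
      net_args <- args[net_keys]
      net_cfg <- small_world_config(
        n_nodes = net_args$n_nodes %||% 500,
        degree = net_args$degree %||% 10,
        rewiring_prob = net_args$rewiring_prob %||% 0.1)
      sf_cfg <- do.call(score_field_config,
                        c(list(n_nodes = net_cfg$n_nodes), args[sf_keys]))
      rest <- args[setdiff(names(args), c(net_keys, sf_keys))]
      do.call(conformity_config,
              c(list(network_config = net_cfg, score_field_config = sf_cfg,
                     seed = seed), rest))
    },
    contagion = {
      do.call(contagion_config, c(args, list(seed = seed)))
    })
  if (model == "panic") attr(cfg, "v_grid") <- v_grid
  cfg
}

run_one_replicate <- function(model, cfg, v_grid, out_dir, tag) {
  if (model == "panic") {
    if (is.null(v_grid)) {
      res <- run_cascade(cfg)
      metrics <- data.frame(initial_fraction = res$initial_fraction,
                            equilibrium_fraction = res$equilibrium_fraction,
                            rounds = res$rounds_to_equilibrium)
      art <- data.frame(round = seq_along(res$fraction_trajectory) - 1L,
                        fraction = format_num(res$fraction_trajectory))
    } else {
      sw <- sweep_visibility(v_grid, replicates = 1, cfg)
      metrics <- data.frame(
        mean_initial_fraction = mean(sw$initial_fraction),
        mean_equilibrium_fraction = mean(sw$equilibrium_fraction),
        equilibrium_low_v = sw$equilibrium_fraction[1L],
        equilibrium_high_v = sw$equilibrium_fraction[nrow(sw)])
      art <- data.frame(v = format_num(sw$v),
                        initial_fraction = format_num(sw$initial_fraction),
                        equilibrium_fraction = format_num(sw$equilibrium_fraction),
                        rounds = sw$rounds)
    }
    files <- write_artifact(art, out_dir, paste0(tag, "_trajectory.csv"))
  } else if (model == "conformity") {
    res <- run_learning(cfg)
    pol <- res$polarization
    metrics <- data.frame(
      fraction_anti_initial = mean(res$initial_scores < 0),
      fraction_anti_final = pol$fraction_anti_final,
      variance_ratio = pol$variance_ratio,
      fraction_strongly_pro = pol$fraction_strongly_pro,
      fraction_strongly_anti = pol$fraction_strongly_anti,
      periods_run = res$periods_run)
    agents <- data.frame(
      agent = seq_along(res$initial_scores) - 1L,
      initial_score = format_num(res$initial_scores),
      final_score = format_num(res$final_scores),
      range_low = format_num(res$range_low),
      range_high = format_num(res$range_high))
    traj <- data.frame(
      period = (seq_along(res$pro_fraction_trajectory) - 1L) *
        cfg$network_config$n_nodes,
      pro_fraction = format_num(res$pro_fraction_trajectory))
    files <- c(write_artifact(agents, out_dir, paste0(tag, "_agents.csv")),
               write_artifact(traj, out_dir, paste0(tag, "_trajectory.csv")))
  } else {
    res <- run_contagion(cfg)
    last <- res$trajectory[nrow(res$trajectory), ]
    init_sus <- res$config$n_susceptible
    metrics <- data.frame(
      final_susceptible = last$susceptible,
      final_infected = last$infected,
      final_recovered = last$recovered,
      extinction_time = res$extinction_time,
      all_susceptible_infected = sum(res$ever_infected) == init_sus,
      equilibrium_reached = res$equilibrium_reached)
    traj <- res$trajectory
    traj$time <- format_num(traj$time)
    files <- write_artifact(traj, out_dir, paste0(tag, "_trajectory.csv"))
  }
  list(metrics = metrics, files = files)
}

# recursively drop S3 classes so configs serialize as plain JSON objects
strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

write_artifact <- function(df, out_dir, filename) {
  if (is.null(out_dir)) return(character())
  path <- file.path(out_dir, filename)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a scenario with replicates
#'
#' Orchestrates `replicates` independent runs of a preset scenario.
#' Replicate `r` is simulated under [child_seed()]`(master_seed, r)`.
#' When `out_dir` is given, per-replicate artifacts (trajectory and, for
#' conformity, per-agent CSVs with 9-significant-digit numeric formatting),
#' a tidy `summary.csv`, a `summary.json` and a `manifest.json` are
#' written there; identical invocations produce byte-identical CSV bodies.
#' `replicates = 0` is a validation-only dry run: the configuration is
#' resolved and the manifest written, but nothing is simulated.
#'
#' @inheritParams scenario_config
#' @param replicates nonnegative integer.
#' @param master_seed integer master seed.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing artifacts.
#' @param quiet suppress per-replicate progress messages (on `stderr`).
#' @return A data frame (the summary table): one row per replicate with
#'   columns `model`, `scenario`, `replicate`, `seed` and per-model outcome
#'   metrics; zero rows for a dry run. The manifest is attached as
#'   attribute `"manifest"`.
#' @examples
#' \donttest{
#' run_scenario("contagion", "sim1", replicates = 2, master_seed = 1)
#' }
#' @export
run_scenario <- function(model, scenario = names(scenario_presets[[model]])[1],
                         replicates = 1, master_seed = 1,
                         out_dir = NULL, overrides = list(), quiet = TRUE) {
  model <- match.arg(model, names(scenario_presets))
  check_scalar(replicates, "replicates", "integerish", lower = 0)
  check_scalar(master_seed, "master_seed", "integerish")
  cfg <- scenario_config(model, scenario, overrides)  # validates early
  v_grid <- attr(cfg, "v_grid")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seeds <- if (replicates > 0) child_seed(master_seed, seq_len(replicates))
           else integer()
  manifest <- list(
    model = model, scenario = scenario,
    overrides = overrides,
    config = strip_class(cfg),
    master_seed = as.integer(master_seed),
    replicates = as.integer(replicates),
    child_seeds = as.integer(seeds),
    version = as.character(utils::packageVersion("crowdsim")),
    files = character())

  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    if (!quiet)
      message(sprintf("[crowdsim] %s/%s replicate %d/%d (seed %d)",
                      model, scenario, r, replicates, seeds[r]))
    cfg_r <- scenario_config(model, scenario, overrides, seed = seeds[r])
    out <- run_one_replicate(model, cfg_r, v_grid, out_dir,
                             sprintf("%s_%s_rep%03d", model, scenario, r))
    manifest$files <- c(manifest$files, out$files)
    rows[[r]] <- cbind(
      data.frame(model = model, scenario = scenario, replicate = r,
                 seed = seeds[r]),
      out$metrics)
  }
  summary_table <- if (replicates > 0) do.call(rbind, rows) else
    data.frame(model = character(), scenario = character(),
               replicate = integer(), seed = integer())

  if (!is.null(out_dir)) {
    sum_path <- file.path(out_dir, sprintf("%s_%s_summary.csv", model, scenario))
    st <- summary_table
    num <- vapply(st, is.double, logical(1))
    st[num] <- lapply(st[num], format_num)
    utils::write.csv(st, sum_path, row.names = FALSE, quote = FALSE)
    json_path <- file.path(out_dir, sprintf("%s_%s_summary.json", model, scenario))
    jsonlite::write_json(summary_table, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    manifest$files <- c(manifest$files, sum_path, json_path)
    man_path <- file.path(out_dir, sprintf("%s_%s_manifest.json", model, scenario))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  attr(summary_table, "manifest") <- manifest
  summary_table
}

#' Re-execute a run from its manifest
#'
#' A manifest written by [run_scenario()] fully determines the run (model,
#' scenario, overrides, master seed, replicate count), so re-executing it
#' reproduces the summary table exactly.
#'
#' @param manifest_path path to a `*_manifest.json`.
#' @param out_dir optional output directory for the re-run's artifacts.
#' @return The summary table of the re-executed run.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  overrides <- as.list(man$overrides)
  if (length(overrides) == 0) overrides <- list()
  run_scenario(man$model, man$scenario, replicates = man$replicates,
               master_seed = man$master_seed, out_dir = out_dir,
               overrides = overrides)
}

#' Aggregate scenario summaries
#'
#' Combines summary tables (as returned by [run_scenario()], or paths to
#' the `*_summary.csv` files it writes) into one tidy table of per-scenario
#' replicate means and standard errors for every numeric outcome metric.
#'
#' @param ... summary data frames and/or file paths, or a single list of
#'   them.
#' @return A data frame with columns `model`, `scenario`, `metric`, `mean`,
#'   `se`, `n_replicates`.
#' @examples
#' \donttest{
#' a <- run_scenario("contagion", "sim1", replicates = 2, master_seed = 1)
#' b <- run_scenario("contagion", "sim2", replicates = 2, master_seed = 1)
#' summarize_runs(a, b)
#' }
#' @export
summarize_runs <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1L]]) &&
      !is.data.frame(inputs[[1L]]))
    inputs <- inputs[[1L]]
  if (!length(inputs)) stop_bad("no summaries supplied")
  tables <- lapply(inputs, function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) stop_bad(sprintf("no such summary file: %s", x))
      utils::read.csv(x)
    } else if (is.data.frame(x)) x
    else stop_bad("inputs must be summary data frames or CSV paths")
  })
  for (tb in tables)
    if (!all(c("model", "scenario", "replicate") %in% names(tb)))
      stop_bad("summary input lacks model/scenario/replicate columns")
  out <- list()
  for (tb in tables) {
    metrics <- setdiff(names(tb)[vapply(tb, is.numeric, logical(1))],
                       c("replicate", "seed"))
    key <- unique(tb[c("model", "scenario")])
    for (k in seq_len(nrow(key))) {
      sub <- tb[tb$model == key$model[k] & tb$scenario == key$scenario[k], ]
      for (m in metrics) {
        v <- sub[[m]]
        out[[length(out) + 1L]] <- data.frame(
          model = key$model[k], scenario = key$scenario[k], metric = m,
          mean = mean(v, na.rm = TRUE),
          se = stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))),
          n_replicates = nrow(sub))
      }
    }
  }
  do.call(rbind, out)
}
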