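# Configuration, orchestration and report assembly for the standard
# analyses: base case (per reading), one-way DSA, PSA + CEAC, internal
# validation, trial simulation. A single JSON config drives all commands;
# CLI flags override config keys.

#' Default analysis configuration
#'
#' A nested list holding every model input: run settings, transition
#' probabilities, utilities, costs, trial confusion counts per reading,
#' prevalence, life-table source and analysis settings. All defaults are
#' the published base-case values; any key can be overridden in a JSON
#' config file.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  costs <- unclass(cost_set())
  # keep names through JSON round-trips: named atomic vectors serialise as
  # bare arrays, lists of scalars as objects
  costs$imaging_cost <- as.list(costs$imaging_cost)
  list(
    model = list(start_age = 70L, cohort_size = 10000,
                 discount_rate = 0.04, terminal_age = 110L,
                 counting_method = "life-table", half_year = TRUE,
                 fp_cost_policy = "m0bcr_subsequent",
                 fn_cost_policy = "m0bcr_first_year",
                 fp_transition_policy = "m1_dynamics",
                 renormalize = FALSE, seed = 1L),
    transition_params = unclass(transition_params()),
    utilities = unclass(utility_set()),
    costs = costs,
    prevalence = default_prevalence(),
    trial_counts = lapply(.trial_counts, lapply, as.list),
    life_table = list(path = NULL,
                      gompertz = list(a = 2.5e-5, b = 0.095),
                      terminal_age = 110L),
    psa = list(n_iter = 1000L, comparator = c("DW-MRI", "FCH")),
    ceac = list(lambda_max = 20000, lambda_step = 100))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a JSON configuration file
#'
#' Keys present in the file override the defaults of [default_config()];
#' absent keys keep their default values.
#'
#' @param path Path to a JSON file, or `NULL` for the defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .merge_config(cfg, user)
}

#' Write a configuration list as JSON
#'
#' @param cfg Nested configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Materialise model objects from a configuration
#'
#' @param cfg Nested configuration list (see [default_config()]).
#' @param reading `"onsite"` or `"central"`.
#' @return List with `config` ([model_config()]), `params`, `costs`,
#'   `utils`, `lt`, `prevalence`, `strategies`.
#' @export
config_objects <- function(cfg = default_config(),
                           reading = c("onsite", "central")) {
  reading <- match.arg(reading)
  m <- cfg$model
  config <- model_config(
    start_age = m$start_age, cohort_size = m$cohort_size,
    discount_rate = m$discount_rate, terminal_age = m$terminal_age,
    counting_method = m$counting_method, half_year = m$half_year,
    fp_cost_policy = m$fp_cost_policy, fn_cost_policy = m$fn_cost_policy,
    fp_transition_policy = m$fp_transition_policy,
    renormalize = isTRUE(m$renormalize), seed = m$seed)
  tp <- cfg$transition_params
  params <- transition_params(
    p_m0bcr_m1bcr = tp$p_m0bcr_m1bcr, ci_m0bcr_m1bcr = tp$ci_m0bcr_m1bcr,
    p_m0bcr_m0crpc = tp$p_m0bcr_m0crpc, ci_m0bcr_m0crpc = tp$ci_m0bcr_m0crpc,
    p_m0crpc_m1crpc = tp$p_m0crpc_m1crpc,
    ci_m0crpc_m1crpc = tp$ci_m0crpc_m1crpc,
    p_m1bcr_m1crpc = tp$p_m1bcr_m1crpc, ci_m1bcr_m1crpc = tp$ci_m1bcr_m1crpc,
    excess_death_m0crpc = tp$excess_death_m0crpc,
    excess_death_m1bcr = tp$excess_death_m1bcr,
    excess_death_m1crpc = tp$excess_death_m1crpc)
  u <- cfg$utilities
  utils <- utility_set(u_m0bcr = u$u_m0bcr, sd_m0bcr = u$sd_m0bcr,
                       u_m1bcr = u$u_m1bcr, sd_m1bcr = u$sd_m1bcr,
                       u_m0crpc = u$u_m0crpc, sd_m0crpc = u$sd_m0crpc,
                       u_m1crpc = u$u_m1crpc, sd_m1crpc = u$sd_m1crpc)
  co <- cfg$costs
  imaging <- unlist(co$imaging_cost)
  costs <- cost_set(
    m0bcr_first_year = co$m0bcr_first_year,
    ci_m0bcr_first_year = co$ci_m0bcr_first_year,
    m0bcr_subsequent = co$m0bcr_subsequent,
    ci_m0bcr_subsequent = co$ci_m0bcr_subsequent,
    m1bcr_first_year = co$m1bcr_first_year,
    ci_m1bcr_first_year = co$ci_m1bcr_first_year,
    m1bcr_subsequent = co$m1bcr_subsequent,
    ci_m1bcr_subsequent = co$ci_m1bcr_subsequent,
    m0crpc_annual = co$m0crpc_annual, ci_m0crpc_annual = co$ci_m0crpc_annual,
    m1crpc_annual = co$m1crpc_annual, ci_m1crpc_annual = co$ci_m1crpc_annual,
    imaging_cost = imaging)
  ltc <- cfg$life_table
  lt <- if (!is.null(ltc$path)) {
    load_life_table(ltc$path, terminal_age = ltc$terminal_age)
  } else {
    gompertz_life_table(a = ltc$gompertz$a, b = ltc$gompertz$b,
                        ages = 0:ltc$terminal_age)
  }
  counts <- cfg$trial_counts[[reading]]
  strategies <- lapply(names(counts), function(nm) {
    x <- unlist(counts[[nm]])
    strategy(nm, se = unname(x["tp"] / (x["tp"] + x["fn"])),
             sp = unname(x["tn"] / (x["tn"] + x["fp"])),
             imaging_cost = unname(imaging[[nm]]))
  })
  names(strategies) <- names(counts)
  list(config = config, params = params, costs = costs, utils = utils,
       lt = lt, prevalence = cfg$prevalence, strategies = strategies)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

.write_manifest <- function(out_dir, command, cfg, seed, outputs) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = command,
                   config_digest = unname(tools::md5sum(tmp)),
                   seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

.results_table <- function(results) {
  data.frame(
    strategy = names(results),
    life_years = vapply(results, function(r) r$life_years, 0),
    life_years_disc = vapply(results, function(r) r$life_years_disc, 0),
    qalys = vapply(results, function(r) r$qalys, 0),
    cost = vapply(results, function(r) r$cost, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the base-case analysis for one reading
#'
#' Runs all strategies through the decision tree + Markov model and computes
#' the efficiency frontier. With `out_dir`, writes `strategies.tsv`,
#' `frontier.tsv` and a run manifest.
#'
#' @param cfg Config list or path to a JSON config (`NULL` = defaults).
#' @param reading `"onsite"` or `"central"`.
#' @param out_dir Optional output directory (created if missing).
#' @return List with `results` (named `strategy_result` list), `table`
#'   (summary data frame) and `frontier`.
#' @export
run_base_case <- function(cfg = NULL, reading = c("onsite", "central"),
                          out_dir = NULL) {
  reading <- match.arg(reading)
  if (is.character(cfg) || is.null(cfg)) cfg <- read_config(cfg)
  ob <- config_objects(cfg, reading)
  results <- run_strategy_set(ob$config, ob$params, ob$lt, ob$costs,
                              ob$utils, ob$prevalence, ob$strategies)
  fr <- efficiency_frontier(results)
  tab <- .results_table(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outs <- c(.write_tsv(tab, file.path(out_dir, "strategies.tsv")),
              .write_tsv(as.data.frame(fr), file.path(out_dir,
                                                      "frontier.tsv")))
    .write_manifest(out_dir, paste0("base-case --reading ", reading), cfg,
                    cfg$model$seed, basename(outs))
  }
  list(results = results, table = tab, frontier = fr)
}

#' Run the one-way deterministic sensitivity analysis
#'
#' @inheritParams run_base_case
#' @param ranges Range entries for [one_way_dsa()]; `NULL` uses
#'   [default_dsa_ranges()].
#' @return The `tornado` data frame.
#' @export
run_dsa_analysis <- function(cfg = NULL, reading = c("onsite", "central"),
                             ranges = NULL, out_dir = NULL) {
  reading <- match.arg(reading)
  if (is.character(cfg) || is.null(cfg)) cfg <- read_config(cfg)
  ob <- config_objects(cfg, reading)
  if (is.null(ranges)) {
    ranges <- default_dsa_ranges(ob$params, ob$costs, ob$utils)
  }
  tor <- one_way_dsa(ob$config, ob$params, ob$lt, ob$costs, ob$utils,
                     ob$prevalence, ob$strategies, ranges = ranges,
                     comparator = cfg$psa$comparator)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outs <- .write_tsv(as.data.frame(tor), file.path(out_dir, "tornado.tsv"))
    .write_manifest(out_dir, paste0("dsa --reading ", reading), cfg,
                    cfg$model$seed, basename(outs))
  }
  tor
}

#' Run the probabilistic sensitivity analysis and CEAC
#'
#' @inheritParams run_base_case
#' @param n_iter Monte Carlo iterations (default from config).
#' @param seed RNG seed (default from config).
#' @return List with `psa` (a `psa_result`) and `ceac`.
#' @export
run_psa_analysis <- function(cfg = NULL, reading = c("onsite", "central"),
                             n_iter = NULL, seed = NULL, out_dir = NULL) {
  reading <- match.arg(reading)
  if (is.character(cfg) || is.null(cfg)) cfg <- read_config(cfg)
  ob <- config_objects(cfg, reading)
  if (is.null(n_iter)) n_iter <- cfg$psa$n_iter
  if (is.null(seed)) seed <- cfg$model$seed
  psa <- run_psa(ob$config, ob$params, ob$lt, ob$costs, ob$utils,
                 ob$prevalence, ob$strategies, n_iter = n_iter, seed = seed,
                 comparator = cfg$psa$comparator)
  curves <- ceac(psa$draws,
                 lambdas = seq(0, cfg$ceac$lambda_max,
                               by = cfg$ceac$lambda_step))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summ <- data.frame(
      n_iter = psa$n_iter, seed = psa$seed,
      comparator = psa$comparator[1L], intervention = psa$comparator[2L],
      mean_incremental_cost = psa$mean_incremental_cost,
      mean_incremental_qalys = psa$mean_incremental_qalys,
      mean_icer = psa$mean_icer, mean_of_icers = psa$mean_of_icers)
    outs <- c(.write_tsv(psa$draws, file.path(out_dir, "psa_draws.tsv")),
              .write_tsv(summ, file.path(out_dir, "psa_summary.tsv")),
              .write_tsv(as.data.frame(curves),
                         file.path(out_dir, "ceac.tsv")))
    .write_manifest(out_dir, paste0("psa --reading ", reading), cfg, seed,
                    basename(outs))
  }
  list(psa = psa, ceac = curves)
}

#' Run the internal-validity life-expectancy check
#'
#' @inheritParams run_base_case
#' @return Named numeric vector from [validate_life_expectancy()].
#' @export
run_validation <- function(cfg = NULL, out_dir = NULL) {
  if (is.character(cfg) || is.null(cfg)) cfg <- read_config(cfg)
  ob <- config_objects(cfg, "onsite")
  v <- validate_life_expectancy(ob$config, ob$params, ob$lt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(population = names(v), life_expectancy = unname(v))
    outs <- .write_tsv(df, file.path(out_dir, "validation.tsv"))
    .write_manifest(out_dir, "validate", cfg, cfg$model$seed,
                    basename(outs))
  }
  v
}

#' Simulate a diagnostic trial and write the readings table
#'
#' @param spec A [trial_spec()].
#' @param out_file Optional output CSV path.
#' @return The generated `paired_readings`, invisibly when writing.
#' @export
run_trial_simulation <- function(spec = trial_spec(), out_file = NULL) {
  readings <- generate_trial(spec)
  if (!is.null(out_file)) {
    write_readings(readings, out_file)
    return(invisible(readings))
  }
  readings
}

# ---- command-line interface -------------------------------------------------

.cli_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON config file [default: built-ins]"),
    optparse::make_option("--reading", type = "character",
                          default = "onsite",
                          help = "imaging reading: onsite or central"),
    optparse::make_option("--iterations", type = "integer", default = NULL,
                          help = "PSA iterations"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "RNG seed"),
    optparse::make_option("--lifetable", type = "character", default = NULL,
                          help = "life table file (age,qx); overrides config"),
    optparse::make_option("--out-dir", type = "character", default = "results",
                          dest = "out_dir", help = "output directory"))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `base-case`, `dsa`, `psa`, `validate` and
#' `simulate-trial`; see the `inst/cli/imgcea` script. Flags override config
#' keys.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("base-case", "dsa", "psa", "validate", "simulate-trial")
  if (length(args) == 0L || !args[1L] %in% cmds) {
    message("usage: imgcea <", paste(cmds, collapse = "|"), "> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  parser <- optparse::OptionParser(option_list = .cli_options())
  opt <- optparse::parse_args(parser, args = args[-1L])
  status <- tryCatch({
    cfg <- read_config(opt$config)
    if (!is.null(opt$lifetable)) cfg$life_table$path <- opt$lifetable
    if (!is.null(opt$seed)) cfg$model$seed <- opt$seed
    reading <- match.arg(opt$reading, c("onsite", "central"))
    switch(cmd,
      `base-case` = {
        out <- run_base_case(cfg, reading, out_dir = opt$out_dir)
        message(sprintf("base case (%s) written to %s", reading, opt$out_dir))
        print(out$frontier)
      },
      dsa = {
        tor <- run_dsa_analysis(cfg, reading, out_dir = opt$out_dir)
        message(sprintf("tornado table written to %s", opt$out_dir))
        print(as.data.frame(tor))
      },
      psa = {
        out <- run_psa_analysis(cfg, reading, n_iter = opt$iterations,
                                seed = cfg$model$seed, out_dir = opt$out_dir)
        print(out$psa)
      },
      validate = {
        v <- run_validation(cfg, out_dir = opt$out_dir)
        print(v)
      },
      `simulate-trial` = {
        dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
        spec <- trial_spec(seed = if (is.null(opt$seed)) 1L else opt$seed)
        run_trial_simulation(spec, file.path(opt$out_dir, "readings.csv"))
        message(sprintf("readings written to %s/readings.csv", opt$out_dir))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
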