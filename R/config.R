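#' Master run configuration
#'
#' Bundles every model input: cohort generator settings, risk and
#' troponin thresholds, treatment policy, event-model parameters,
#' utilities, costs, discounting, and experiment settings. All defaults
#' are the base case; [load_config()] reads the same structure from
#' YAML, defaulting anything not given.
#'
#' @param cohort a [cohort_config()].
#' @param thresholds a [threshold_config()].
#' @param policy a [policy_table()].
#' @param events an [event_model_params()].
#' @param utilities a [utility_params()].
#' @param costs a [cost_params()].
#' @param discount a [discount_spec()].
#' @param experiment list overriding any of: `mode` (basecase, psa, sa,
#'   subgroup), `n_runs` (100), `n_per_run` (20000), `horizon` (10),
#'   `wtp` (50000), `seed` (1), `coupling` (comonotonic or independent).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = default_cohort_config(),
                       thresholds = threshold_config(),
                       policy = default_policy(),
                       events = event_model_params(),
                       utilities = utility_params(),
                       costs = cost_params(),
                       discount = discount_spec(),
                       experiment = list()) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(thresholds, "threshold_config"),
            inherits(policy, "policy_table"),
            inherits(events, "event_model_params"),
            inherits(utilities, "utility_params"),
            inherits(costs, "cost_params"),
            inherits(discount, "discount_spec"))
  exp_def <- list(mode = "basecase", n_runs = 100L, n_per_run = 20000L,
                  horizon = 10, wtp = 50000, seed = 1L,
                  coupling = "comonotonic")
  unknown <- setdiff(names(experiment), names(exp_def))
  if (length(unknown)) {
    stop("unknown experiment keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  exp <- utils::modifyList(exp_def, experiment)
  if (!exp$mode %in% c("basecase", "psa", "sa", "subgroup")) {
    stop("experiment$mode must be basecase, psa, sa or subgroup",
         call. = FALSE)
  }
  if (!exp$coupling %in% c("comonotonic", "independent")) {
    stop("experiment$coupling must be comonotonic or independent",
         call. = FALSE)
  }
  if (exp$horizon <= 0 || exp$wtp < 0 || exp$n_runs < 1 || exp$n_per_run < 1) {
    stop("experiment: horizon/wtp/n_runs/n_per_run out of range",
         call. = FALSE)
  }
  structure(list(cohort = cohort, thresholds = thresholds, policy = policy,
                 events = events, utilities = utilities, costs = costs,
                 discount = discount, experiment = exp),
            class = "run_config")
}

mat_to_list <- function(m) {
  out <- lapply(rownames(m), function(rn) as.list(m[rn, ]))
  names(out) <- rownames(m)
  out
}

list_to_mat <- function(l) {
  rn <- names(l)
  m <- do.call(rbind, lapply(l, function(row) unlist(row)[c("female", "male")]))
  rownames(m) <- rn
  m
}

#' Serialize a run configuration to a plain list
#'
#' @param config a [run_config()].
#' @return Nested list of plain types suitable for [yaml::write_yaml()];
#'   inverse of the list handling in [load_config()].
#' @export
as_config_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ch <- config$cohort
  ev <- config$events
  list(
    cohort = list(
      n = ch$n, p_male = ch$p_male, age_location = ch$age_location,
      age_spread = ch$age_spread, age_bounds = ch$age_bounds,
      class_proportions = as.list(ch$class_proportions),
      risk_breaks = ch$risk_breaks,
      hstni_log_mean = as.list(ch$hstni_log_mean),
      hstni_log_sd = as.list(ch$hstni_log_sd),
      risk_tni_dependence = ch$risk_tni_dependence),
    thresholds = list(
      score_cuts = config$thresholds$score_cuts,
      tni_low = as.list(config$thresholds$tni_low),
      tni_high = as.list(config$thresholds$tni_high)),
    policy = list(score = as.list(config$policy$score),
                  sscore = as.list(config$policy$sscore)),
    events = list(
      p10 = lapply(ev$p10, as.list),
      shape = lapply(ev$shape, as.list),
      calib_horizon = ev$calib_horizon,
      fatality = lapply(ev$fatality, as.list),
      post_event = list(horizon = ev$post_event$horizon,
                        shape = ev$post_event$shape,
                        p = lapply(ev$post_event$p, mat_to_list)),
      rr_treatment = ev$rr_treatment,
      horizon_years = ev$horizon_years,
      exact_probability_ratio = ev$exact_probability_ratio),
    utilities = unclass(config$utilities),
    costs = unclass(config$costs),
    discount = unclass(config$discount),
    experiment = config$experiment)
}

# YAML 1.1 parses a bare key `n` as boolean FALSE; restore it
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
  lapply(x, fix_yaml_keys)
}

check_unknown_keys <- function(user, def, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(def)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(user[[nm]]) && is.list(def[[nm]]) &&
        !is.null(names(def[[nm]])) && !nm %in% c("p")) {
      check_unknown_keys(user[[nm]], def[[nm]], full)
    }
  }
}

nv <- function(l) {
  v <- unlist(l)
  stats::setNames(as.numeric(v), names(v))
}

config_from_list <- function(lst) {
  ch <- lst$cohort
  th <- lst$thresholds
  ev <- lst$events
  post <- ev$post_event
  run_config(
    cohort = cohort_config(
      n = ch$n, p_male = ch$p_male, age_location = ch$age_location,
      age_spread = ch$age_spread, age_bounds = unlist(ch$age_bounds),
      class_proportions = nv(ch$class_proportions),
      risk_breaks = unlist(ch$risk_breaks),
      hstni_log_mean = nv(ch$hstni_log_mean),
      hstni_log_sd = nv(ch$hstni_log_sd),
      risk_tni_dependence = ch$risk_tni_dependence),
    thresholds = threshold_config(score_cuts = unlist(th$score_cuts),
                                  tni_low = nv(th$tni_low),
                                  tni_high = nv(th$tni_high)),
    policy = policy_table(score = nv(lst$policy$score),
                          sscore = nv(lst$policy$sscore)),
    events = event_model_params(
      p10 = lapply(ev$p10, nv), shape = lapply(ev$shape, nv),
      calib_horizon = ev$calib_horizon,
      fatality = lapply(ev$fatality, nv),
      post_event = list(horizon = post$horizon, shape = post$shape,
                        p = lapply(post$p, list_to_mat),
                        anchor2 = post$anchor2),
      rr_treatment = ev$rr_treatment,
      horizon_years = ev$horizon_years,
      exact_probability_ratio = isTRUE(ev$exact_probability_ratio)),
    utilities = do.call(utility_params, lst$utilities),
    costs = do.call(cost_params, lst$costs),
    discount = do.call(discount_spec, lst$discount),
    experiment = lst$experiment)
}

#' Load a run configuration from a YAML file
#'
#' The file may specify any subset of the configuration tree; everything
#' else takes base-case defaults. Unknown keys raise an error naming the
#' key; invalid values raise the validation error of the corresponding
#' constructor. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  user <- fix_yaml_keys(yaml::read_yaml(path))
  defaults <- as_config_list(run_config())
  if (is.null(user)) return(run_config())
  if (!is.list(user)) stop("config file must be a YAML mapping", call. = FALSE)
  check_unknown_keys(user, defaults)
  merged <- utils::modifyList(defaults, user)
  config_from_list(merged)
}

#' Save a run configuration to a YAML file
#'
#' @param config a [run_config()].
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(as_config_list(config), path, precision = 15)
  invisible(path)
}

parse_subgroup <- function(s) {
  out <- list()
  for (part in strsplit(s, ",", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad subgroup spec: ", part, call. = FALSE)
    if (kv[1] == "age") {
      rng <- suppressWarnings(
        as.numeric(strsplit(kv[2], ":", fixed = TRUE)[[1]]))
      if (length(rng) != 2 || any(is.na(rng))) {
        stop("bad age range in subgroup spec: ", kv[2], call. = FALSE)
      }
      out$age_range <- rng
    } else if (kv[1] == "risk") {
      cls <- strsplit(kv[2], "+", fixed = TRUE)[[1]]
      if (!all(cls %in% score_class_levels)) {
        stop("bad risk classes in subgroup spec: ", kv[2], call. = FALSE)
      }
      out$score_classes <- cls
    } else {
      stop("unknown subgroup key: ", kv[1], call. = FALSE)
    }
  }
  out
}

write_full_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, used by the shipped
#' `inst/scripts/troposim.R` wrapper. Subcommands: `generate-cohort`,
#' `run-basecase`, `run-psa`, `run-sa`, `run-subgroup`, `report`. Every
#' run writes a self-describing run directory: config snapshot, seed,
#' result CSVs and a log.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit code, 0 on success.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  tryCatch({
    if (!length(args)) {
      stop(paste("usage: troposim <generate-cohort|run-basecase|run-psa|",
                 "run-sa|run-subgroup|report> [options]"), call. = FALSE)
    }
    cmd <- args[1]
    rest <- args[-1]
    opts <- list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out-dir", type = "character",
                            default = "troposim-run", dest = "out_dir"),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--n", type = "integer", default = NULL),
      optparse::make_option("--n-runs", type = "integer", default = NULL,
                            dest = "n_runs"),
      optparse::make_option("--n-per-run", type = "integer", default = NULL,
                            dest = "n_per_run"),
      optparse::make_option("--n-iter", type = "integer", default = NULL,
                            dest = "n_iter"),
      optparse::make_option("--n-samples", type = "integer", default = NULL,
                            dest = "n_samples"),
      optparse::make_option("--horizon", type = "double", default = NULL),
      optparse::make_option("--wtp", type = "double", default = NULL),
      optparse::make_option("--subgroup", type = "character",
                            default = NULL))
    o <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                              args = rest)
    config <- if (!is.null(o$config)) load_config(o$config) else run_config()
    if (!is.null(o$horizon)) config$experiment$horizon <- o$horizon
    if (!is.null(o$wtp)) config$experiment$wtp <- o$wtp
    seed <- o$seed

    if (cmd == "generate-cohort") {
      if (!is.null(o$n)) config$cohort$n <- o$n
      out <- o$out %||% "cohort.csv"
      write_cohort(generate_cohort(config$cohort, seed = seed), out)
      message("wrote ", out)
      return(0L)
    }

    dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_config(config, file.path(o$out_dir, "config.yaml"))
    writeLines(as.character(seed), file.path(o$out_dir, "seed.txt"))
    log <- file.path(o$out_dir, "log.txt")
    logline <- function(...) {
      cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n"),
          file = log, append = TRUE)
      message(...)
    }

    if (cmd == "run-basecase") {
      n_runs <- o$n_runs %||% config$experiment$n_runs
      n_per_run <- o$n_per_run %||% config$experiment$n_per_run
      logline("base case: ", n_runs, " runs x ", n_per_run)
      bc <- run_base_case(config, n_runs = n_runs, n_per_run = n_per_run,
                          seed = seed)
      write_full_csv(bc$runs, file.path(o$out_dir, "runs.csv"))
      write_full_csv(bc$summary, file.path(o$out_dir, "summary.csv"))
      print(bc)
    } else if (cmd == "run-psa") {
      n_iter <- o$n_iter %||% 500L
      n_per_iter <- o$n_per_run %||% config$experiment$n_per_run
      logline("PSA: ", n_iter, " iterations x ", n_per_iter)
      psa <- run_psa(config, n_iter = n_iter, n_per_iter = n_per_iter,
                     seed = seed)
      write_full_csv(psa$iterations, file.path(o$out_dir, "psa_scatter.csv"))
      write_full_csv(ceac(psa), file.path(o$out_dir, "ceac.csv"))
    } else if (cmd == "run-sa") {
      n_samples <- o$n_samples %||% 100000L
      logline("univariate SA: n = ", n_samples)
      sa <- univariate_sa(config, n_samples = n_samples, seed = seed)
      write_full_csv(sa, file.path(o$out_dir, "tornado.csv"))
    } else if (cmd == "run-subgroup") {
      n_samples <- o$n_samples %||% 250000L
      if (is.null(o$subgroup)) stop("run-subgroup needs --subgroup",
                                    call. = FALSE)
      filters <- list(subgroup = parse_subgroup(o$subgroup))
      logline("subgroup analysis: n = ", n_samples)
      config$cohort$n <- as.integer(n_samples)
      cohort <- generate_cohort(config$cohort,
                                seed = substream_seed(seed, "basecohort"))
      sim <- run_microsim(cohort, config, seed)
      rep <- subgroup_report(sim$person, filters,
                             horizon = config$experiment$horizon,
                             wtp = config$experiment$wtp)
      write_full_csv(rep, file.path(o$out_dir, "subgroups.csv"))
    } else if (cmd == "report") {
      path <- file.path(o$out_dir, "summary.csv")
      if (!file.exists(path)) stop("no summary.csv in ", o$out_dir,
                                   call. = FALSE)
      print(utils::read.csv(path), row.names = FALSE)
    } else {
      stop("unknown subcommand: ", cmd, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
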