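# Experiment orchestration: agent specifications, seeded multi-run
# protocols, parameter sweeps with lowest-MSRE selection, trial-aligned
# prediction profiles, and YAML run configurations.

#' Agent specifications
#'
#' Lightweight descriptions of a learner, consumed by [run_agent()],
#' [run_many()], and [sweep_agents()].
#'
#' @param representation a fixed representation spec (see
#'   [representations]).
#' @param hyper a [td_hyper()].
#' @param architecture,trainer,n_hidden,tbptt_T,augment,tau see
#'   [run_recurrent_agent()].
#' @param label optional display label; a default is derived.
#' @return an object of class `cond_agent`.
#' @export
agent_linear <- function(representation = rep_microstimulus(),
                         hyper = td_hyper(), label = NULL) {
  structure(list(type = "linear", representation = representation,
                 hyper = hyper,
                 label = label %||% paste0("linear/", representation$type)),
            class = "cond_agent")
}

#' @rdname agent_linear
#' @export
agent_recurrent <- function(architecture = "lstm", trainer = "tbptt",
                            n_hidden = 16, tbptt_T = 10,
                            hyper = td_hyper(alpha = 2^-9, lambda = 0),
                            augment = FALSE, tau = NULL, label = NULL) {
  structure(list(type = "recurrent", architecture = architecture,
                 trainer = trainer, n_hidden = n_hidden, tbptt_T = tbptt_T,
                 hyper = hyper, augment = augment, tau = tau,
                 label = label %||%
                   paste0(architecture, "/", trainer,
                          if (trainer == "tbptt") paste0("(T=", tbptt_T, ")"),
                          if (augment) "+traces")),
            class = "cond_agent")
}

#' Run one agent on one seeded stream
#'
#' @param config an environment configuration.
#' @param agent a `cond_agent` from [agent_linear()] or
#'   [agent_recurrent()].
#' @param n_steps stream length.
#' @param seed run seed.
#' @return a `cond_run`.
#' @export
run_agent <- function(config, agent, n_steps, seed = 1L) {
  stopifnot(inherits(agent, "cond_agent"))
  if (agent$type == "linear") {
    run_linear_agent(config, agent$representation, agent$hyper, n_steps, seed)
  } else {
    run_recurrent_agent(config, agent$architecture, agent$trainer,
                        agent$n_hidden, agent$tbptt_T, agent$hyper,
                        agent$augment, agent$tau, n_steps, seed)
  }
}

#' Repeated seeded runs of one agent
#'
#' Run i uses seed `seed_base + i - 1`; per-run MSREs are aggregated into a
#' mean and standard error across runs.
#'
#' @inheritParams run_agent
#' @param n_runs number of independent runs.
#' @param seed_base first seed.
#' @param keep_logs retain each run's per-step log (memory-heavy).
#' @return a `cond_runs` object; `tidy()` gives the per-run table,
#'   `glance()` the aggregate.
#' @export
run_many <- function(config, agent, n_steps, n_runs = 5, seed_base = 1L,
                     keep_logs = FALSE) {
  seeds <- as.integer(seed_base) + seq_len(n_runs) - 1L
  runs <- purrr::map(seeds, function(s) run_agent(config, agent, n_steps, s))
  per_run <- tibble::tibble(
    run = seq_len(n_runs), seed = seeds,
    msre = purrr::map_dbl(runs, "msre"))
  structure(list(agent = agent, config = config, per_run = per_run,
                 summary = aggregate_runs(per_run$msre),
                 n_steps = n_steps,
                 config_digest = config_digest(list(config = unclass(config),
                                                    agent = unclass(agent),
                                                    n_steps = n_steps)),
                 logs = if (keep_logs) purrr::map(runs, "log")),
            class = "cond_runs")
}

#' @export
print.cond_runs <- function(x, ...) {
  cat("<cond_runs: ", x$agent$label, " on ", x$config$kind,
      ", ", nrow(x$per_run), " runs x ", x$n_steps, " steps>\n", sep = "")
  cat("  MSRE = ", format(x$summary$msre_mean, digits = 5), " +/- ",
      format(x$summary$stderr, digits = 3), " (stderr)\n", sep = "")
  invisible(x)
}

#' @method tidy cond_runs
#' @export
tidy.cond_runs <- function(x, ...) x$per_run

#' @method glance cond_runs
#' @export
glance.cond_runs <- function(x, ...) {
  tibble::tibble(agent = x$agent$label, environment = x$config$kind,
                 msre_mean = x$summary$msre_mean,
                 stderr = x$summary$stderr, n_runs = x$summary$n_runs,
                 n_steps = x$n_steps)
}

config_digest <- function(x) rlang::hash(x)

#' Sweep a list of agents and select the best
#'
#' Runs every agent under the same protocol and tabulates aggregate MSRE.
#' `select_best()` returns the row with the lowest mean MSRE; ties are
#' broken by position in the supplied list, so order grids from smallest
#' to largest hyperparameter values to prefer the smallest on a tie.
#'
#' @param config an environment configuration.
#' @param agents a (optionally named) list of `cond_agent`s.
#' @param n_steps,n_runs,seed_base protocol; all agents see the same
#'   seeds.
#' @return a tibble, one row per agent, ordered as supplied.
#' @export
sweep_agents <- function(config, agents, n_steps, n_runs = 5, seed_base = 1L) {
  stopifnot(length(agents) >= 1)
  rows <- purrr::imap(agents, function(a, i) {
    rs <- run_many(config, a, n_steps, n_runs, seed_base)
    g <- glance(rs)
    g$agent_id <- if (is.character(i)) i else as.character(i)
    g
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "agent_id")
}

#' @rdname sweep_agents
#' @param sweep a tibble from `sweep_agents()`.
#' @export
select_best <- function(sweep) {
  sweep[which.min(sweep$msre_mean), , drop = FALSE]
}

# ---- trial-aligned profiles ---------------------------------------------

#' Trial-aligned prediction profile
#'
#' Averages predictions and returns across trials, aligned to CS onset
#' (offset 0 = the first CS step of each trial), the standard way to
#' visualize whether a learned prediction rises through the trace interval
#' and peaks just before US onset.
#'
#' @param run a `cond_run`, or its `tidy()` log.
#' @param window integer offsets around CS onset, `c(before, after)`.
#' @param only_active for patterning environments, restrict to trials
#'   whose emitted US outcome was 1 (NULL keeps all trials).
#' @return a `cond_profile` tibble: `offset`, `prediction`, `return`,
#'   `n_trials`.
#' @export
extract_profile <- function(run, window = c(-5, 45), only_active = NULL) {
  log <- if (inherits(run, "cond_run")) run$log else run
  stopifnot(all(c("step", "prediction", "return", "phase", "trial_id") %in%
                  names(log)))
  onsets <- log$step[log$phase == "cs" &
                       c(TRUE, log$phase[-nrow(log)] != "cs")]
  if (isTRUE(only_active)) {
    us_trials <- unique(log$trial_id[log$us > 0])
    onset_trials <- log$trial_id[match(onsets, log$step)]
    onsets <- onsets[onset_trials %in% us_trials]
  }
  offs <- seq(window[1], window[2])
  keep <- onsets[onsets + window[1] >= 1 & onsets + window[2] <= nrow(log)]
  if (!length(keep))
    stop("no complete trials inside the requested window", call. = FALSE)
  idx <- outer(keep, offs, `+`)
  prof <- tibble::tibble(
    offset = offs,
    prediction = colMeans(matrix(log$prediction[idx], nrow(idx))),
    return = colMeans(matrix(log$return[idx], nrow(idx))),
    n_trials = length(keep))
  class(prof) <- c("cond_profile", class(prof))
  prof
}

# ---- YAML run configurations --------------------------------------------

env_config_from_list <- function(x) {
  kind <- x$kind %||% stop("run config: missing `kind`", call. = FALSE)
  x$kind <- NULL
  fn <- switch(kind,
               trace_conditioning = trace_conditioning,
               noisy_patterning = noisy_patterning,
               trace_patterning = trace_patterning,
               stop("unknown environment kind: ", kind, call. = FALSE))
  do.call(fn, x[intersect(names(x), names(formals(fn)))])
}

agent_from_list <- function(x) {
  type <- x$type %||% "linear"
  hyper <- do.call(td_hyper, as.list(x$hyper %||% list()))
  if (type == "linear") {
    rep_args <- as.list(x$representation %||% list())
    rep_type <- rep_args$type %||% "microstimulus"
    rep_args$type <- NULL
    rep <- do.call(switch(rep_type,
                          presence = rep_presence, trace = rep_trace,
                          tilecoded = rep_tilecoded,
                          microstimulus = rep_microstimulus, esn = rep_esn),
                   rep_args)
    agent_linear(rep, hyper)
  } else {
    agent_recurrent(architecture = x$architecture %||% "lstm",
                    trainer = x$trainer %||% "tbptt",
                    n_hidden = x$n_hidden %||% 16,
                    tbptt_T = x$tbptt_T %||% 10,
                    hyper = hyper,
                    augment = isTRUE(x$augment),
                    tau = x$tau)
  }
}

#' Read / write a run configuration
#'
#' A flat YAML (or JSON) file with blocks `environment`, `agent`, and the
#' protocol fields `n_steps`, `n_runs`, `seed_base`. Every run artifact
#' embeds the resolved configuration and seed.
#'
#' @param path file path.
#' @return a list with `config` (environment), `agent`, `n_steps`,
#'   `n_runs`, `seed_base`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  list(config = env_config_from_list(x$environment),
       agent = agent_from_list(x$agent %||% list()),
       n_steps = as.integer(x$n_steps %||% 10000),
       n_runs = as.integer(x$n_runs %||% 1),
       seed_base = as.integer(x$seed_base %||% 1))
}

#' @rdname read_run_config
#' @param run_config a list in the shape `read_run_config()` returns.
#' @export
write_run_config <- function(run_config, path) {
  env <- unclass(run_config$config)
  agent <- run_config$agent
  agent_list <- if (agent$type == "linear") {
    list(type = "linear",
         representation = unclass(agent$representation),
         hyper = unclass(agent$hyper))
  } else {
    list(type = "recurrent", architecture = agent$architecture,
         trainer = agent$trainer, n_hidden = agent$n_hidden,
         tbptt_T = agent$tbptt_T, augment = agent$augment,
         tau = agent$tau, hyper = unclass(agent$hyper))
  }
  yaml::write_yaml(list(environment = env, agent = agent_list,
                        n_steps = run_config$n_steps,
                        n_runs = run_config$n_runs,
                        seed_base = run_config$seed_base), path,
                   precision = 15L)
  invisible(path)
}

#' Execute a run configuration
#'
#' Runs the configured agent for `n_runs` seeded runs and writes the
#' summary JSON (and optionally per-run logs) under `out_dir`, refusing to
#' overwrite an existing summary unless `overwrite = TRUE`.
#'
#' @param run_config a list from [read_run_config()].
#' @param out_dir output directory; NULL skips writing.
#' @param keep_logs write per-run CSV logs too.
#' @param overwrite replace existing outputs.
#' @return the `cond_runs` object, invisibly when writing.
#' @export
execute_run_config <- function(run_config, out_dir = NULL, keep_logs = FALSE,
                               overwrite = FALSE) {
  rs <- run_many(run_config$config, run_config$agent, run_config$n_steps,
                 run_config$n_runs, run_config$seed_base,
                 keep_logs = keep_logs)
  if (is.null(out_dir)) return(rs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "summary.json")
  if (file.exists(summary_path) && !overwrite)
    stop("output exists: ", summary_path, " (use overwrite = TRUE)",
         call. = FALSE)
  payload <- list(agent = rs$agent$label,
                  environment = rs$config$kind,
                  msre_mean = rs$summary$msre_mean,
                  stderr = rs$summary$stderr,
                  n_runs = rs$summary$n_runs,
                  n_steps = rs$n_steps,
                  seed_base = run_config$seed_base,
                  config_digest = rs$config_digest,
                  per_run = rs$per_run,
                  config = unclass(rs$config))
  jsonlite::write_json(payload, summary_path, auto_unbox = TRUE, digits = NA)
  if (keep_logs)
    purrr::iwalk(rs$logs, function(log, i) {
      utils::write.csv(as.data.frame(log),
                       file.path(out_dir, sprintf("run%03d.csv", i)),
                       row.names = FALSE)
    })
  invisible(rs)
}
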