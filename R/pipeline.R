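#' Default pipeline configuration
#'
#' Desk-scale defaults: a 10 + 10 participant synthetic cohort and the
#' reduced MCMC schedule. Any field can be overridden in a YAML file or via
#' `...`; section names mirror the pipeline stages.
#'
#' @param ... named overrides merged over the defaults (nested lists merge
#'   recursively).
#' @return nested configuration list with sections `population`, `design`,
#'   `mcmc`, `linking`, `output`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    population = list(n_young = 10L, n_old = 10L, contingency = 0.8,
                      dt = 1e-4, exact_block_balance = FALSE),
    design = list(practice = FALSE),
    mcmc = list(iterations = 300L, burn_in = 300L, chains = 2L),
    linking = list(block_size = 5L, criterion = 0.30),
    output = list(save_draws = TRUE, ppc_draws = 50L)
  )
  modifyList(base, list(...))
}

#' Run the full analysis pipeline
#'
#' One-command orchestration: simulate a synthetic study (or ingest user
#' CSVs), fit the hierarchical RL model and the hierarchical diffusion model
#' per age group, run posterior predictive checks, compute young-vs-old
#' group contrasts, extract posterior modes and the cross-model Spearman
#' table, and—when ground truth is available—score parameter recovery.
#' All outputs are written to `outdir` as CSV/JSON together with a
#' reproducibility manifest (config hash, seeds, versions, per-stage wall
#' time, file list).
#'
#' @param config a [pipeline_config()] list or path to a YAML file with the
#'   same structure.
#' @param seed master integer seed for every stochastic stage.
#' @param outdir output directory (created if needed).
#' @param data optional list with paths `learning`, `search` (and optionally
#'   `truth`) to ingest instead of simulating.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         outdir = tempfile("valuelink_run"), data = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- modifyList(pipeline_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = as.integer(seed),
                   versions = list(R = as.character(getRversion()),
                                   valuelink = as.character(
                                     utils::packageVersion("valuelink"))),
                   stages = list(), outputs = character())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    write.csv(df, path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, file)
  }

  study <- t_stage("simulate", {
    if (is.null(data)) {
      cfg <- study_config(n_young = config$population$n_young,
                          n_old = config$population$n_old,
                          contingency = config$population$contingency,
                          dt = config$population$dt,
                          exact_block_balance =
                            config$population$exact_block_balance,
                          practice = config$design$practice)
      generate_study(cfg, seed = seed)
    } else {
      list(learning = read.csv(data$learning),
           search = read.csv(data$search),
           truth = if (!is.null(data$truth)) read.csv(data$truth) else NULL)
    }
  })
  emit(study$learning, "learning_trials.csv")
  emit(study$search, "search_trials.csv")
  if (!is.null(study$truth)) emit(study$truth, "truth.csv")

  stopifnot(nrow(validate_trials(study$learning)) == 0L,
            nrow(validate_trials(study$search)) == 0L)

  groups <- unique(study$learning$group)
  mc <- function(offset) mcmc_config(config$mcmc$iterations,
                                     config$mcmc$burn_in,
                                     config$mcmc$chains,
                                     seed = seed + offset)
  rl_fits <- list()
  ddm_fits <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ltr <- study$learning[study$learning$group == g, ]
    str_ <- study$search[study$search$group == g &
                           study$search$target_present == 1, ]
    rl_fits[[g]] <- t_stage(paste0("fit_rl_", g),
                            fit_rl(ltr, mc(100L + gi)))
    ddm_fits[[g]] <- t_stage(paste0("fit_ddm_", g),
                             fit_ddm(str_, mc(200L + gi)))
    emit(summary(rl_fits[[g]]), paste0("rl_", g, "_summary.csv"))
    emit(summary(ddm_fits[[g]]), paste0("ddm_", g, "_summary.csv"))
    if (isTRUE(config$output$save_draws)) {
      emit(draws_long(rl_fits[[g]]), paste0("rl_", g, "_draws.csv"))
      emit(draws_long(ddm_fits[[g]]), paste0("ddm_", g, "_draws.csv"))
    }
    ppc_rl <- t_stage(paste0("ppc_rl_", g),
                      posterior_predictive(rl_fits[[g]], ltr,
                                           ndraws = config$output$ppc_draws,
                                           seed = seed + 300L + gi))
    ppc_ddm <- t_stage(paste0("ppc_ddm_", g),
                       posterior_predictive(ddm_fits[[g]], str_,
                                            ndraws = config$output$ppc_draws,
                                            seed = seed + 400L + gi))
    emit(as.data.frame(ppc_rl), paste0("ppc_rl_", g, ".csv"))
    emit(as.data.frame(ppc_ddm), paste0("ppc_ddm_", g, ".csv"))
  }

  curves <- t_stage("learning_curves",
                    learning_curves(study$learning,
                                    config$linking$block_size))
  emit(curves, "learning_curves.csv")

  if (length(groups) >= 2L) {
    contrasts <- t_stage("group_contrasts", {
      a <- groups[1L]
      b <- groups[2L]
      rows <- lapply(c(RL_PARS, "eta_diff", "tau_diff"), function(p) {
        group_contrast(rl_fits[[a]], rl_fits[[b]], p)
      })
      rows <- c(rows, lapply(c(paste0("alpha_", LEARN_CONDITIONS),
                               paste0("nu_", LEARN_CONDITIONS), "t0"),
                             function(p) {
                               group_contrast(ddm_fits[[a]], ddm_fits[[b]], p)
                             }))
      do.call(rbind, rows)
    })
    emit(contrasts, "group_contrasts.csv")
  }

  linktabs <- t_stage("linking", {
    lapply(groups, function(g) {
      ct <- correlation_table(individual_modes(rl_fits[[g]]),
                              individual_modes(ddm_fits[[g]]),
                              criterion = config$linking$criterion)
      ct$group <- g
      ct
    })
  })
  emit(do.call(rbind, linktabs), "correlation_table.csv")

  if (!is.null(study$truth)) {
    score <- t_stage("recovery", recovery_scorecard(study$truth, rl_fits,
                                                    ddm_fits))
    emit(score, "recovery_scorecard.csv")
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  manifest$outdir <- outdir
  invisible(manifest)
}

read_pipeline_config <- function(path) yaml::read_yaml(path)

# Polynomial rolling hash of the deparsed configuration; stable across
# sessions and safe in double precision (modulus keeps h * 31 + b < 2^31).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

# Long-format posterior draws: chain, iteration, parameter, value.
draws_long <- function(fit) {
  do.call(rbind, lapply(seq_along(fit$draws), function(c) {
    d <- fit$draws[[c]]
    data.frame(chain = c, iteration = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d), stringsAsFactors = FALSE)
  }))
}

#' Score parameter recovery against ground truth
#'
#' Pearson correlation between true individual parameters and their
#' posterior means, per fitted parameter, across all fitted participants.
#'
#' @param truth ground-truth data.frame from [generate_study()].
#' @param rl_fits,ddm_fits named lists of fits (one per group).
#' @return data.frame with `parameter`, `correlation`, `n`.
#' @export
recovery_scorecard <- function(truth, rl_fits, ddm_fits) {
  collect <- function(fits, pars) {
    est <- do.call(rbind, lapply(fits, function(f) coef(f)))
    est <- est[, pars, drop = FALSE]
    tru <- truth[match(rownames(est), truth$participant_id), pars,
                 drop = FALSE]
    vapply(pars, function(p) cor(tru[[p]], est[, p]), 0)
  }
  rl_pars <- RL_PARS
  ddm_pars <- c(paste0("alpha_", LEARN_CONDITIONS),
                paste0("nu_", LEARN_CONDITIONS))
  r <- c(collect(rl_fits, rl_pars), collect(ddm_fits, ddm_pars))
  data.frame(parameter = c(rl_pars, ddm_pars), correlation = unname(r),
             n = nrow(truth), stringsAsFactors = FALSE)
}

#' Write a human-readable report for a completed pipeline run
#'
#' Renders `report.md` in the run directory with six sections: data,
#' learning curves, RL posterior (six group-level rows per group), DDM
#' posterior, group contrasts, and cross-model linking (with the recovery
#' scorecard when ground truth was available). Missing artifacts are listed
#' and the remaining sections are still produced.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return path to `report.md`, invisibly.
#' @export
report_run <- function(run_dir) {
  path <- function(f) file.path(run_dir, f)
  have <- function(f) file.exists(path(f))
  tab <- function(df) {
    if (is.null(df)) return("*(missing)*")
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.3f", v))
    paste(c(paste("|", paste(names(df), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
            apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "),
                                            "|"))),
          collapse = "\n")
  }
  read_or_null <- function(f) if (have(f)) read.csv(path(f)) else NULL

  missing <- character()
  lines <- c("# valuelink run report", "")
  manifest <- if (have("manifest.json"))
    jsonlite::read_json(path("manifest.json")) else NULL

  lines <- c(lines, "## 1. Data", "")
  ltr <- read_or_null("learning_trials.csv")
  str_ <- read_or_null("search_trials.csv")
  if (is.null(ltr)) missing <- c(missing, "learning_trials.csv")
  if (is.null(str_)) missing <- c(missing, "search_trials.csv")
  lines <- c(lines,
             if (!is.null(ltr)) sprintf(
               "%d learning trials from %d participants (%s).",
               nrow(ltr), length(unique(ltr$participant_id)),
               paste(unique(ltr$group), collapse = ", ")) else "*(missing)*",
             if (!is.null(str_)) sprintf(
               "%d search trials (%d target-present).",
               nrow(str_), sum(str_$target_present == 1)) else "*(missing)*",
             "")

  lines <- c(lines, "## 2. Learning curves", "")
  curves <- read_or_null("learning_curves.csv")
  if (is.null(curves)) missing <- c(missing, "learning_curves.csv")
  lines <- c(lines, tab(if (!is.null(curves))
    utils::head(curves[order(curves$condition, curves$bin), ], 12) else NULL),
    "")

  lines <- c(lines, "## 3. Reinforcement-learning posterior", "")
  for (f in list.files(run_dir, "^rl_.*_summary\\.csv$")) {
    s <- read.csv(path(f))
    g <- sub("^rl_(.*)_summary\\.csv$", "\\1", f)
    lines <- c(lines, paste0("### Group: ", g), "",
               tab(s[s$level == "group",
                     c("parameter", "mean", "mode", "ci_lower", "ci_upper",
                       "rhat")]), "")
  }
  if (!length(list.files(run_dir, "^rl_.*_summary\\.csv$"))) {
    missing <- c(missing, "rl_*_summary.csv")
    lines <- c(lines, "*(missing)*", "")
  }

  lines <- c(lines, "## 4. Diffusion-model posterior", "")
  ddm_files <- list.files(run_dir, "^ddm_.*_summary\\.csv$")
  for (f in ddm_files) {
    s <- read.csv(path(f))
    g <- sub("^ddm_(.*)_summary\\.csv$", "\\1", f)
    lines <- c(lines, paste0("### Group: ", g), "",
               tab(s[s$level == "group",
                     c("parameter", "mean", "mode", "ci_lower", "ci_upper",
                       "rhat")]), "")
  }
  if (!length(ddm_files)) {
    missing <- c(missing, "ddm_*_summary.csv")
    lines <- c(lines, "*(missing)*", "")
  }

  lines <- c(lines, "## 5. Group contrasts", "",
             tab(read_or_null("group_contrasts.csv")), "")
  if (!have("group_contrasts.csv")) missing <- c(missing,
                                                 "group_contrasts.csv")

  lines <- c(lines, "## 6. Cross-model linking", "",
             tab(read_or_null("correlation_table.csv")), "")
  if (!have("correlation_table.csv")) missing <- c(missing,
                                                   "correlation_table.csv")
  if (have("recovery_scorecard.csv")) {
    lines <- c(lines, "### Parameter recovery", "",
               tab(read_or_null("recovery_scorecard.csv")), "")
  }
  if (length(missing)) {
    lines <- c(lines, "", "Missing artifacts: ",
               paste("-", missing, collapse = "\n"))
  }
  out <- path("report.md")
  writeLines(lines, out)
  invisible(out)
}
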