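.trial_cols <- c("trial", "block", "block_type", "trial_in_block",
                 "frequency_cpb", "s", "t", "d")

#' Read and write per-trial tables
#'
#' Trial tables are plain tab-separated text with the header columns
#' `trial, block, block_type, trial_in_block, frequency_cpb, s, t, d` and
#' optionally `g` (observed gain) and `x` (latent state, synthetic data
#' only). Numeric columns round-trip at full precision. On read, the
#' schema is validated: all required columns present, numeric cells
#' parseable, indices consecutive, and `s = 0` on every non-adaptation
#' trial.
#'
#' @param path File path.
#' @param trials Trial tibble (e.g. [build_session()] output, possibly with
#'   `g`/`x` columns).
#' @return `read_trials()`: the validated tibble. `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  out <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("Failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(out) == 0) stop("Empty trial table: ", path, call. = FALSE)
  missing <- setdiff(.trial_cols, names(out))
  if (length(missing)) {
    stop("Missing columns in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(out), c(.trial_cols, "g", "x"))
  if (length(extra)) {
    stop("Unexpected columns in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(names(out), "block_type")
  bad <- num_cols[!vapply(out[num_cols], is.numeric, logical(1))]
  bad <- setdiff(bad, "frequency_cpb")  # all-NA frequency parses as logical
  if (length(bad)) {
    stop("Non-numeric cells in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out$frequency_cpb <- as.integer(out$frequency_cpb)
  if (!identical(as.integer(out$trial), seq_len(nrow(out)))) {
    stop("`trial` must be the consecutive 1-based index.", call. = FALSE)
  }
  off <- which(out$block_type == "non-adaptation" & out$s != 0)
  if (length(off)) {
    stop("Schema violation: s != 0 on non-adaptation trial(s) ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) ", ..." else "", call. = FALSE)
  }
  out
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing)) {
    stop("Trial table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(trials, path, progress = FALSE)
  invisible(path)
}

#' Run the full simulate/fit/select pipeline from one configuration
#'
#' Reproducible end-to-end run: generates a seeded synthetic cohort,
#' fits the phenomenological model (per pre + adaptation segment), fits the
#' generative family with Akaike-weight selection, and compares the
#' closed-form phenomenology predicted from the truth parameters with the
#' fitted one. All randomness flows from `config$seed`. If `config$out_dir`
#' is set, trial tables, the manifest and the report tables are written
#' there as delimited/structured text.
#'
#' @param config Named list (or path to a YAML file holding one) with
#'   entries: `design` (`"freq"`, `"orig"` or a list with
#'   `block_lengths`, `block_types`, `frequencies`), `adaptation_type`,
#'   `model` (truth model name), `truth` (optional parameter values or
#'   ranges), `sigma`, `n_participants`, `seed`, `fit_family` (logical),
#'   `n_starts`, `frequency` (cpb of the segment used for the
#'   phenomenological fit), `out_dir` (optional).
#' @return A report bundle (list, class `sa_pipeline`): `cohort` manifest,
#'   `phenom` (per-participant phenomenological parameter table),
#'   `state` (per-participant generative fits and weights), `selection`
#'   (averaged weights, winning model/group), `analytic` (truth-implied
#'   phenomenology), `config`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  t0 <- Sys.time()
  cfg <- utils::modifyList(
    list(design = "single", adaptation_type = "two-way", model = "KAm",
         truth = NULL, sigma = NULL, n_participants = 3, seed = 1,
         fit_family = FALSE, n_starts = 4, frequency = 6,
         out_dir = NULL),
    config
  )
  model_spec(cfg$model)  # reject unknown model names before any work
  design <- .pipeline_design(cfg)
  cohort <- generate_cohort(design, cfg$model, cfg$truth, cfg$sigma,
                            cfg$n_participants, cfg$seed)
  per_obs <- purrr::map(seq_len(nrow(cohort)), function(i) {
    obs <- cohort$trials[[i]]
    seg <- session_segment(obs, cfg$frequency)
    ph <- tryCatch(fit_phenom(seg), error = function(e) NULL)
    st <- .with_seed(
      child_seed(cfg$seed, i, 1) + 2L,
      if (cfg$fit_family) {
        fit_state_models(obs, n_starts = cfg$n_starts)
      } else {
        fit <- fit_state_model(obs, cfg$model, n_starts = cfg$n_starts)
        gl <- glance(fit)
        gl$fit <- list(fit)
        gl$weight <- 1
        gl
      }
    )
    list(phenom = ph, state = st)
  })
  phenom_tbl <- dplyr::bind_rows(purrr::imap(per_obs, function(po, i) {
    if (is.null(po$phenom)) return(NULL)
    dplyr::mutate(tidy(po$phenom), participant = i, .before = 1)
  }))
  state_tbl <- dplyr::bind_rows(purrr::imap(per_obs, function(po, i) {
    dplyr::mutate(dplyr::select(po$state, -"fit"), participant = i,
                  .before = 1)
  }))
  wmat <- do.call(rbind, purrr::map(per_obs, function(po) {
    stats::setNames(po$state$weight, po$state$model)
  }))
  avg <- average_weights(wmat)
  selection <- list(weights = avg, best_model = best_model(avg),
                    group_weights = group_weights(avg))
  truth_mean <- vapply(c("K", "A", "m", "D"), function(p) {
    mean(cohort[[p]])
  }, numeric(1))
  analytic <- predict_phenom_params(
    truth_mean[["K"]], truth_mean[["A"]], truth_mean[["m"]],
    truth_mean[["D"]], f = cfg$frequency,
    N = design$block_lengths[design$block_types == "adaptation"][1]
  )
  log <- list(
    package_version = as.character(utils::packageVersion("sinadapt")),
    r_version = R.version.string, seed = cfg$seed,
    started = format(t0), elapsed_s = as.numeric(Sys.time() - t0,
                                                 units = "secs")
  )
  bundle <- structure(
    list(cohort = cohort, phenom = phenom_tbl, state = state_tbl,
         selection = selection, analytic = analytic, config = cfg,
         log = log),
    class = "sa_pipeline"
  )
  if (!is.null(cfg$out_dir)) .write_bundle(bundle, cfg$out_dir)
  bundle
}

.pipeline_design <- function(cfg) {
  if (is.list(cfg$design)) {
    return(session_design(cfg$design$block_lengths, cfg$design$block_types,
                          cfg$design$frequencies,
                          adaptation_type = cfg$adaptation_type))
  }
  switch(cfg$design,
    freq = freq_design(adaptation_type = cfg$adaptation_type),
    orig = ,
    single = single_block_design(cfg$frequency,
                                 adaptation_type = cfg$adaptation_type),
    stop("Unknown design \"", cfg$design, "\".", call. = FALSE)
  )
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- bundle$cohort
  for (i in seq_len(nrow(cohort))) {
    write_trials(cohort$trials[[i]],
                 file.path(out_dir, sprintf("observer_%02d.tsv", i)))
  }
  manifest <- dplyr::select(cohort, -"trials")
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  if (nrow(bundle$phenom)) {
    readr::write_tsv(bundle$phenom, file.path(out_dir, "phenom_fits.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(bundle$state, file.path(out_dir, "state_fits.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$selection$weights,
                   file.path(out_dir, "selection_weights.tsv"),
                   progress = FALSE)
  yaml::write_yaml(
    list(config = bundle$config[setdiff(names(bundle$config), "out_dir")],
         log = bundle$log),
    file.path(out_dir, "run_log.yaml")
  )
  invisible(out_dir)
}

#' @export
print.sa_pipeline <- function(x, ...) {
  cat("<sa_pipeline> truth ", x$config$model, ", ",
      x$config$n_participants, " observers, seed ", x$config$seed, "\n",
      sep = "")
  cat("  best model: ", x$selection$best_model, "\n", sep = "")
  invisible(x)
}
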