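# Consolidated reporting: a dynamic-instability table in the conventional
# mean +/- SEM layout with significance superscripts, and a YAML-configured
# end-to-end pipeline over the file formats in io.R.

#' Render a dynamic-instability report table
#'
#' Produces the conventional published layout: one row per parameter,
#' `mean +/- SEM` per condition with significance superscripts
#' (A: p < 0.001, B: p < 0.01, C: p < 0.05 against control), plus the
#' per-condition track counts. A plain numeric table rides along so that
#' serialization is lossless.
#'
#' @param control An `mt_dynamics` object.
#' @param treated List of `mt_dynamics` objects (possibly empty).
#' @param comparisons Optional list of `mt_comparison` objects aligned with
#'   `treated`; computed via [compare_conditions()] when omitted.
#' @return Object of class `table1_report`: list with `formatted`
#'   (character data.frame), `numeric` (long data.frame `condition`,
#'   `parameter`, `mean`, `sem`, `n`, `pct_change`, `p_value`, `code`).
#' @export
render_table1_report <- function(control, treated = list(),
                                 comparisons = NULL) {
  if (!inherits(control, "mt_dynamics"))
    stop("'control' must be an mt_dynamics object")
  if (inherits(treated, "mt_dynamics")) treated <- list(treated)
  if (is.null(comparisons))
    comparisons <- lapply(treated, function(tr)
      compare_conditions(control, tr))

  conds <- c(list(control), treated)
  labels <- vapply(conds, function(d) d$condition, character(1))

  num <- do.call(rbind, lapply(seq_along(conds), function(i) {
    d <- conds[[i]]
    s <- d$stats
    out <- data.frame(condition = d$condition, parameter = s$parameter,
                      mean = s$mean, sem = s$sem, n = s$n,
                      stringsAsFactors = FALSE)
    if (i == 1L) {
      out$pct_change <- NA_real_; out$p_value <- NA_real_; out$code <- ""
    } else {
      cmp <- comparisons[[i - 1L]]
      m <- match(out$parameter, cmp$parameter)
      out$pct_change <- cmp$pct_change[m]
      out$p_value <- cmp$p_value[m]
      out$code <- cmp$code[m]
    }
    out
  }))
  rownames(num) <- NULL

  fmt <- data.frame(parameter = control$stats$parameter,
                    stringsAsFactors = FALSE)
  for (i in seq_along(conds)) {
    sub <- num[num$condition == labels[i], ]
    m <- match(fmt$parameter, sub$parameter)
    fmt[[labels[i]]] <- vapply(m, function(j) {
      cell <- .fmt_pm(sub$mean[j], sub$sem[j])
      if (nzchar(sub$code[j])) cell <- paste0(cell, " ^", sub$code[j])
      cell
    }, character(1))
  }
  fmt <- rbind(fmt, c("n", vapply(conds, function(d)
    as.character(d$stats$n[1L]), character(1))))

  structure(list(formatted = fmt, numeric = num), class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  print(x$formatted, row.names = FALSE)
  invisible(x)
}

#' Write / read a report's numeric table
#'
#' CSV round-trips are exact: `read_report_csv(write_report_csv(x, f))`
#' recovers the numeric table.
#'
#' @param x A `table1_report`.
#' @param file Output path.
#' @export
write_report_csv <- function(x, file) {
  utils::write.csv(x$numeric, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  df$code[is.na(df$code)] <- ""
  df
}

.CONFIG_KEYS <- list(
  top = c("version", "seed", "output_dir", "stages", "inputs", "parameters"),
  inputs = c("tracks", "turbidity", "itc", "itc_blank", "peaks", "fasta"),
  parameters = c("min_excursion", "min_rate", "control_condition",
                 "annotation_tolerance", "cell_conc", "syringe_conc",
                 "cell_volume", "temperature", "skip_first")
)

.validate_config <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_KEYS$top)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(config$inputs)) {
    unknown <- setdiff(names(config$inputs), .CONFIG_KEYS$inputs)
    if (length(unknown))
      stop(sprintf("unknown input key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$parameters)) {
    unknown <- setdiff(names(config$parameters), .CONFIG_KEYS$parameters)
    if (length(unknown))
      stop(sprintf("unknown parameter key(s): %s",
                   paste(unknown, collapse = ", ")))
  }
  bad_stages <- setdiff(config$stages,
                        c("mass", "annotate", "polym", "dynamics", "itc"))
  if (length(bad_stages))
    stop(sprintf("unknown stage(s): %s", paste(bad_stages, collapse = ", ")))
  invisible(config)
}

.log_line <- function(log, ...) c(log, sprintf(...))

#' Run the configured analysis pipeline
#'
#' Executes the requested stages on the configured input files and writes
#' per-stage JSON outputs plus a consolidated report under `output_dir`.
#' Stages: `mass` (isoform masses from the FASTA), `annotate` (peak-list
#' annotation against the first FASTA entry), `polym` (turbidity metrics
#' and control-vs-treated comparison), `dynamics` (per-condition
#' dynamic-instability parameters, comparisons, rendered table),
#' `itc` (blank subtraction and one-site fit). Unknown configuration keys
#' are rejected; an empty stage list is a no-op. A structured log with
#' package version, seed and parameters is written alongside the outputs.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   fields `version`, `seed`, `output_dir`, `stages`, `inputs`,
#'   `parameters`.
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  .validate_config(config)
  outdir <- config$output_dir
  if (is.null(outdir)) stop("config needs 'output_dir'")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pars <- config$parameters
  getpar <- function(key, default) {
    if (!is.null(pars[[key]])) pars[[key]] else default
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  log <- character(0)
  log <- .log_line(log, "mtxkit %s",
                   as.character(utils::packageVersion("mtxkit")))
  log <- .log_line(log, "seed: %s",
                   if (is.null(config$seed)) "none" else config$seed)
  results <- list()
  stages <- config$stages
  if (!length(stages)) {
    log <- .log_line(log, "no stages requested; nothing to do")
  }

  input_path <- function(key) {
    path <- config$inputs[[key]]
    if (is.null(path)) stop(sprintf("stage needs input '%s'", key))
    if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
    path
  }

  for (stage in stages) {
    log <- .log_line(log, "stage: %s", stage)
    res <- switch(stage,
      mass = {
        peps <- read_fasta_peptides(input_path("fasta"))
        lapply(peps, function(p) list(
          name = p$name, length = nchar(p$sequence),
          n_disulfides = p$n_disulfides,
          mass_mono = peptide_mass(p, "mono"),
          mass_average = peptide_mass(p, "average")))
      },
      annotate = {
        peps <- read_fasta_peptides(input_path("fasta"))
        peaks <- read_peaks(input_path("peaks"))
        ann <- annotate_peaks(peaks, peps[[1L]],
                              tolerance = getpar("annotation_tolerance", 0.3))
        list(candidate = peps[[1L]]$name, n_matched = nrow(ann$matches),
             coverage = ann$coverage, terminal_span = ann$terminal_span)
      },
      polym = {
        df <- read_turbidity(input_path("turbidity"))
        conds <- unique(df$condition)
        metrics <- lapply(conds, function(cc)
          curve_metrics(df[df$condition == cc, ]))
        names(metrics) <- conds
        ctrl <- getpar("control_condition", conds[1L])
        cmp <- lapply(setdiff(conds, ctrl), function(cc)
          unclass(compare_curves(metrics[[ctrl]], metrics[[cc]])))
        names(cmp) <- setdiff(conds, ctrl)
        list(metrics = lapply(metrics, unclass), comparisons = cmp)
      },
      dynamics = {
        df <- read_tracks(input_path("tracks"))
        conds <- unique(df$condition)
        dyn <- lapply(conds, function(cc)
          aggregate_params(df[df$condition == cc, ],
                           min_excursion = getpar("min_excursion", 0.5),
                           min_rate = getpar("min_rate", 2),
                           condition = cc))
        names(dyn) <- conds
        ctrl <- getpar("control_condition", conds[1L])
        treated <- dyn[setdiff(conds, ctrl)]
        rep <- render_table1_report(dyn[[ctrl]], unname(treated))
        write_report_csv(rep, file.path(outdir, "dynamics_table.csv"))
        list(report = rep$numeric)
      },
      itc = {
        sch <- itc_schedule(cell_conc = getpar("cell_conc", 55),
                            syringe_conc = getpar("syringe_conc", 2200),
                            cell_volume = getpar("cell_volume", 200),
                            temperature = getpar("temperature", 293.15))
        tab <- read_itc(input_path("itc"))
        blank <- if (!is.null(config$inputs$itc_blank))
          read_itc(input_path("itc_blank")) else NULL
        tit <- as_titration(tab, sch, blank = blank)
        fit <- fit_one_site(tit, skip_first = getpar("skip_first", FALSE))
        if (!isTRUE(fit$converged)) stop("ITC fit did not converge")
        c(as.list(coef(fit)),
          list(se = as.list(fit$se), c_value = fit$diagnostics$c_value))
      },
      stop(sprintf("unknown stage '%s'", stage))
    )
    results[[stage]] <- res
    jsonlite::write_json(res, file.path(outdir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  jsonlite::write_json(results, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(c(log, sprintf("completed: %s", paste(stages, collapse = ", "))),
             file.path(outdir, "run.log"))
  invisible(results)
}
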