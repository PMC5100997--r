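# Dataset persistence and ingestion of deposited source-data tables.

#' Write a synthetic cohort to a directory
#'
#' CSV is the canonical tabular interchange: `summaries.csv` (per
#' subject-visit condition means) and `parameters.csv` (true subject
#' parameters), plus `manifest.json` recording the design, the seeds and the
#' generator settings so that any subset of the run is reproducible.
#'
#' @param cohort An `eat_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$parameters, file.path(dir, "parameters.csv"),
                   row.names = FALSE)
  manifest <- list(
    group = cohort$spec$group,
    n_subjects = cohort$spec$n_subjects,
    n_visits = cohort$spec$n_visits,
    param_means = as.list(cohort$spec$param_means),
    param_sds = as.list(cohort$spec$param_sds),
    duration_noise_frac = cohort$spec$duration_noise_frac,
    seed = cohort$spec$seed,
    design = list(trial_length_s = 30, n_blocks = 8,
                  incentives_pence = c(1, 2, 5),
                  difficulty_frac = c(0.70, 0.80, 0.90))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Dataset directory.
#' @return An `eat_cohort`-like list with `spec`, `parameters`, `summaries`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  spec <- cohort_spec(group = man$group, n_subjects = man$n_subjects,
                      n_visits = man$n_visits,
                      param_means = unlist(man$param_means),
                      param_sds = unlist(man$param_sds),
                      duration_noise_frac = man$duration_noise_frac,
                      seed = man$seed)
  structure(list(spec = spec,
                 parameters = utils::read.csv(file.path(dir, "parameters.csv")),
                 summaries = utils::read.csv(file.path(dir, "summaries.csv"))),
            class = "eat_cohort")
}

#' Read a deposited source-data file into a tidy table
#'
#' Ingests the per-participant summary tables that accompany the study
#' figures: payoff per participant and visit (`which = "fig1"`), fitted model
#' parameters Ai, Sem, Sed, Srm, Sri per participant and visit (`"fig2"`), and
#' duration-regression weights (`"fig3"`). Accepts a MAT v5 file (read with
#' [read_mat()]) or a CSV already in long format.
#'
#' Because the internal variable naming of deposited files varies, variables
#' are discovered heuristically: numeric arrays of dimension subjects x visits
#' (x measures) whose names contain a group hint (`placebo`/`pla` vs
#' `escitalopram`/`esc`/`ssri`/`drug`/`treatment`). When the heuristic fails,
#' the error lists the discovered variables so a `mapping` can be supplied.
#'
#' @param path File path (`.mat` or `.csv`).
#' @param which One of `"fig1"`, `"fig2"`, `"fig3"` (controls the measure
#'   names given to the value columns).
#' @param mapping Optional manual override: named list
#'   `list(<mat variable> = <group label>)`.
#' @return Long data.frame: `subject`, `visit`, `group`, `variable`, `value`.
#' @export
read_source_data <- function(path, which = c("fig1", "fig2", "fig3"),
                             mapping = NULL) {
  which <- match.arg(which)
  measures <- switch(which,
    fig1 = "payoff",
    fig2 = c("Ai", "Sem", "Sed", "Srm", "Sri"),
    fig3 = c("effort_mean", "effort_inc", "effort_diff",
             "rest_mean", "rest_inc", "rest_diff"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- utils::read.csv(path)
    need <- c("subject", "visit", "group", "variable", "value")
    if (!all(need %in% names(out))) {
      stopf("CSV source data must have columns %s", paste(need, collapse = ", "))
    }
    return(out[, need])
  }
  vars <- read_mat(path)
  numeric_vars <- Filter(is.numeric, vars)
  if (is.null(mapping)) {
    guess_group <- function(nm) {
      l <- tolower(nm)
      if (grepl("pla", l)) "placebo"
      else if (grepl("esc|ssri|drug|treat", l)) "escitalopram"
      else NA_character_
    }
    groups <- vapply(names(numeric_vars), guess_group, character(1))
    if (!length(numeric_vars) || anyNA(groups)) {
      stopf("could not map variables to groups; file contains: %s. Supply `mapping = list(<variable> = <group>)`.",
            paste(names(vars), collapse = ", "))
    }
    mapping <- as.list(groups)
  }
  rows <- lapply(names(mapping), function(nm) {
    arr <- numeric_vars[[nm]]
    if (is.null(arr)) stopf("variable '%s' not found or not numeric", nm)
    if (is.null(dim(arr))) arr <- matrix(arr, ncol = 1)
    d <- dim(arr)
    n_meas <- if (length(d) == 3) d[3] else 1
    if (n_meas != length(measures)) {
      if (length(d) == 2 && d[2] == length(measures)) {
        # subjects x measures (single visit or visit-averaged)
        arr <- array(arr, dim = c(d[1], 1, d[2]))
        d <- dim(arr); n_meas <- d[3]
      } else if (length(measures) == 1) {
        arr <- array(arr, dim = c(d[1], d[2], 1))
        d <- dim(arr); n_meas <- 1
      } else {
        stopf("variable '%s' has dimensions %s, expected subjects x visits x %d measures",
              nm, paste(d, collapse = "x"), length(measures))
      }
    } else if (length(d) == 2) {
      arr <- array(arr, dim = c(d, 1)); d <- dim(arr)
    }
    do.call(rbind, lapply(seq_len(n_meas), function(m) {
      data.frame(subject = rep(seq_len(d[1]), d[2]),
                 visit = rep(seq_len(d[2]), each = d[1]),
                 group = mapping[[nm]],
                 variable = measures[m],
                 value = as.vector(arr[, , m]))
    }))
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$value), ]
}

#' Write a tidy force-trace table
#'
#' @param traces List of traces from [simulate_visit_traces()] (`$traces`),
#'   with the matching `$trials` table.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  tab <- do.call(rbind, lapply(seq_along(traces$traces), function(i) {
    tr <- traces$traces[[i]]
    cond <- attr(tr, "cond")
    data.frame(block = traces$trials$block[i], trial = traces$trials$trial[i],
               condition = cond$condition, incentive = cond$incentive,
               difficulty = cond$difficulty, t = tr$t, f = tr$f)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
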