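# Dataset schema, readers/writers, validation and pipeline orchestration.
#
# A gameplay dataset is UTF-8 delimited text with a header, one trial per
# row. Sample events are flat nullable columns (sample1_value, sample2_row,
# sample2_value, sample3_row, sample3_value) rather than nested structures.
# Demographics travel in a second table keyed by uid.

.REQUIRED_COLS <- c("uid", "gameplay", "block", "trial", "condition", "trial_type",
                    "first_card", "sample1_value", "sample2_row", "sample2_value",
                    "sample3_row", "sample3_value", "guess_stage", "chosen_row",
                    "winning_row", "points", "total_cost")

#' Validate a gameplay dataset
#'
#' Checks the schema and the task rules row by row: condition codes, card
#' ranges, the 10/15/20 cost schedule, the +60/-50 payoff formula, and the
#' consistency of trial type with the recorded sample events. Violations are
#' returned as a data.frame with row indices and rule names; in strict mode
#' any violation is an error listing them all.
#'
#' @param dataset a gameplay dataset.
#' @param strict error on violations (default) or return them invisibly.
#' @return (invisibly) a data.frame of violations (zero rows when clean).
#' @export
validate_dataset <- function(dataset, strict = TRUE) {
  missing_cols <- setdiff(.REQUIRED_COLS, names(dataset))
  if (length(missing_cols))
    .is_err(paste0("dataset lacks columns: ", paste(missing_cols, collapse = ", ")),
            "infoseek_invalid_dataset")
  v <- list()
  flag <- function(bad, rule) {
    idx <- which(bad)
    if (length(idx)) v[[length(v) + 1L]] <<- data.frame(row = idx, rule = rule)
  }
  gs <- dataset$guess_stage
  flag(!dataset$condition %in% infoseek_conditions(), "condition: unknown code")
  flag(!dataset$trial_type %in% c("AA", "AB"), "trial_type: must be AA or AB")
  flag(!dataset$first_card %in% 1:10, "first_card: must be 1..10")
  flag(!gs %in% 1:4, "guess_stage: must be 1..4")
  flag(!dataset$chosen_row %in% c("A", "B"), "chosen_row: must be A or B")
  flag(!dataset$winning_row %in% c("A", "B"), "winning_row: must be A or B")
  flag(dataset$total_cost != c(0L, 10L, 25L, 45L)[gs],
       "total_cost: must follow the 10/15/20 schedule")
  flag(dataset$points != ifelse(dataset$chosen_row == dataset$winning_row, 60L, -50L) -
         dataset$total_cost, "points: inconsistent with outcome formula")
  flag(gs >= 2L & is.na(dataset$sample1_value), "sample1_value: missing after sampling")
  flag(gs >= 3L & (is.na(dataset$sample2_row) | is.na(dataset$sample2_value)),
       "sample2: missing after second sample")
  flag(gs == 4L & (is.na(dataset$sample3_row) | is.na(dataset$sample3_value)),
       "sample3: missing after third sample")
  flag(gs >= 3L & dataset$trial_type == "AA" & !is.na(dataset$sample2_row) &
         dataset$sample2_row != "B", "sample2_row: AA trials sample row B at stage 2")
  out <- if (length(v)) do.call(rbind, v) else data.frame(row = integer(), rule = character())
  if (strict && nrow(out))
    .is_err(paste0("dataset validation failed (", nrow(out), " violations):\n  ",
                   paste(utils::head(paste0("row ", out$row, ": ", out$rule), 20),
                         collapse = "\n  ")),
            "infoseek_invalid_dataset")
  invisible(out)
}

#' Read / write gameplay datasets
#'
#' Plain delimited text with a header. `read_dataset()` validates on load
#' (strict mode fails listing every violation); a demographics table is read
#' from `demographics_path` when given and attached as an attribute.
#'
#' @param path file path.
#' @param demographics_path optional path to a per-subject demographics table.
#' @param strict passed to [validate_dataset()].
#' @return a gameplay dataset.
#' @export
read_dataset <- function(path, demographics_path = NULL, strict = TRUE) {
  if (!file.exists(path)) .is_err(paste0("no such file: ", path), "infoseek_io_error")
  ds <- as.data.frame(data.table::fread(path,
    colClasses = list(character = c("condition", "trial_type", "sample2_row",
                                    "sample3_row", "chosen_row", "winning_row"))))
  for (cc in c("sample2_row", "sample3_row"))
    ds[[cc]][!is.na(ds[[cc]]) & ds[[cc]] == ""] <- NA_character_
  validate_dataset(ds, strict = strict)
  if (!is.null(demographics_path))
    attr(ds, "demographics") <- as.data.frame(data.table::fread(demographics_path))
  class(ds) <- c("gameplay_dataset", "data.frame")
  ds
}

#' @rdname read_dataset
#' @param dataset a gameplay dataset.
#' @export
write_dataset <- function(dataset, path, demographics_path = NULL) {
  data.table::fwrite(as.data.frame(dataset)[, .REQUIRED_COLS], path)
  demo <- attr(dataset, "demographics")
  if (!is.null(demographics_path) && !is.null(demo))
    data.table::fwrite(demo, demographics_path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates solve, aggregate, bias statistics (with bootstrap CIs),
#' model fits and optional cross-validation from a single configuration
#' list, reproducibly from `config$seed`. Configuration elements:
#' `simulate` (arguments to [population_spec()]) or `input` (a dataset or a
#' file path); `pairs` (default `c("MULTIPLY", "ADD")`); `n_boot`,
#' `sample_size`; `fit` (logical), `cv` (logical), `n_restarts`; `seed`;
#' `out_dir` (optional, writes delimited results and a config echo).
#'
#' @param config a named list as above.
#' @return a list with the dataset, aggregate tables, a statistics
#'   data.frame, fits and (optionally) cross-validation scores.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  set.seed(seed)
  pairs <- config$pairs %||% c("MULTIPLY", "ADD")
  if (any(pairs == "SINGLE"))
    .is_err("bias statistics are not defined for the SINGLE pair (not information-matched)",
            "infoseek_unsupported_analysis")
  ds <- if (!is.null(config$simulate)) {
    spec <- do.call(population_spec, config$simulate)
    generate_population(spec, seed = seed)
  } else if (is.character(config$input)) read_dataset(config$input)
  else config$input
  tabs <- aggregate_tables(ds)
  n_boot <- config$n_boot %||% 200L
  sample_size <- config$sample_size %||% 10000L
  stats <- list()
  for (pair in pairs) {
    for (tt in c("AA", "AB")) {
      b <- bootstrap_ci(ds, function(t) positive_evidence_approach(t, pair, tt, "omit"),
                        n_boot = n_boot, sample_size = sample_size,
                        seed = seed + 1L)
      stats[[length(stats) + 1L]] <- data.frame(
        statistic = "positive_evidence_approach", pair = pair, scope = tt,
        value = b$value, lower = b$lower, upper = b$upper)
    }
    for (dir in c("BIG", "SMALL")) {
      cond <- paste0(pair, "_", dir)
      b <- bootstrap_ci(ds, function(t) rejecting_unsampled(t, cond, "omit"),
                        n_boot = n_boot, sample_size = sample_size, seed = seed + 2L)
      stats[[length(stats) + 1L]] <- data.frame(
        statistic = "rejecting_unsampled", pair = pair, scope = dir,
        value = b$value, lower = b$lower, upper = b$upper)
    }
    for (band in c("strong", "weak")) {
      b <- bootstrap_ci(ds, function(t) sampling_favorite(t, pair, band, "omit"),
                        n_boot = n_boot, sample_size = sample_size, seed = seed + 3L)
      stats[[length(stats) + 1L]] <- data.frame(
        statistic = "sampling_favorite", pair = pair, scope = band,
        value = b$value, lower = b$lower, upper = b$upper)
    }
  }
  stats <- do.call(rbind, stats)
  fits <- NULL
  if (isTRUE(config$fit)) {
    nr <- config$n_restarts %||% 20L
    fits <- list()
    for (pair in pairs) for (stage in 1:2) for (full in c(FALSE, TRUE))
      fits[[paste(pair, stage, if (full) "full" else "reduced", sep = "_")]] <-
        fit_aggregate(tabs, stage, pair, full = full, n_restarts = nr,
                      seed = seed + 10L)
  }
  cv <- NULL
  if (isTRUE(config$cv)) {
    cv <- list()
    for (pair in pairs)
      cv[[pair]] <- crossvalidate(ds, stage = 1L, pair = pair,
                                  k = config$k %||% 10L, seed = seed + 20L,
                                  n_restarts = config$n_restarts %||% 10L)
  }
  report <- list(config = config, seed = seed, dataset = ds, tables = tabs,
                 statistics = stats, fits = fits, cv = cv)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(stats, file.path(config$out_dir, "bias_statistics.csv"))
    write_dataset(ds, file.path(config$out_dir, "dataset.csv"))
    if (!is.null(fits)) {
      fr <- do.call(rbind, lapply(names(fits), function(nm) {
        p <- fits[[nm]]$params
        data.frame(fit = nm, beta1 = p$beta1, beta2 = p$beta2, beta3 = p$beta3,
                   tau = p$tau, beta4 = p$beta4, beta5 = p$beta5, beta6 = p$beta6,
                   objective = fits[[nm]]$objective)
      }))
      data.table::fwrite(fr, file.path(config$out_dir, "fits.csv"))
    }
    if (!is.null(cv))
      data.table::fwrite(do.call(rbind, Map(cbind, pair = names(cv), cv)),
                         file.path(config$out_dir, "crossvalidation.csv"))
    writeLines(paste(deparse(config[setdiff(names(config), "input")]), collapse = "\n"),
               file.path(config$out_dir, "config_echo.txt"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
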