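configDefaults <- function() {
  list(
    out_dir = ".",
    alpha = 0.05,
    spot_diameter = 33,
    spot_spacing = 40,
    n_traits_nominal = 26,
    pooled = TRUE,
    mph_mode = "per-spot",
    bh_annotation = FALSE,
    screen_source = "images",
    seed = 1,
    n_per_group = 15,
    image_rows = 480,
    image_cols = 640,
    anisotropy_L = 3, anisotropy_T = 1, anisotropy_O1 = 1.5,
    anisotropy_O2 = 2.5,
    manifest = NA_character_, spots = NA_character_,
    traits = NA_character_, echo_table = NA_character_
  )
}

#' Read a run configuration
#'
#' Declarative `key = value` configuration ('#' starts a comment). Unknown
#' keys are an error; values are coerced to the type of the corresponding
#' default. Recognized keys and defaults: `out_dir` (`.`), `alpha` (0.05),
#' `spot_diameter` (33), `spot_spacing` (40), `n_traits_nominal` (26),
#' `pooled` (true), `mph_mode` (`per-spot`), `bh_annotation` (false),
#' `screen_source` (`images` or `table`), `seed` (1), `n_per_group` (15),
#' `image_rows`/`image_cols` (480/640), per-plane `anisotropy_L/T/O1/O2`,
#' and the input paths `manifest`, `spots`, `traits`, `echo_table`.
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list overriding file values (e.g. from CLI flags).
#' @return validated named list of settings.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- configDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("malformed config line (expected key = value): '", ln, "'")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!(key %in% names(cfg))) stop("unknown config key: '", key, "'")
      cfg[[key]] <- val
    }
    ## out_dir stays relative to the working directory, inputs to the config
    pathKeys <- c("manifest", "spots", "traits", "echo_table")
    for (k in pathKeys) {
      v <- cfg[[k]]
      if (is.character(v) && !is.na(v) && nzchar(v) && !grepl("^/", v) &&
          !identical(v, configDefaults()[[k]]))
        cfg[[k]] <- file.path(dirname(path), v)
    }
  }
  for (k in names(overrides)) {
    if (!(k %in% names(cfg))) stop("unknown config key: '", k, "'")
    cfg[[k]] <- overrides[[k]]
  }
  defs <- configDefaults()
  for (k in names(cfg)) {
    tgt <- defs[[k]]
    if (is.numeric(tgt) && is.character(cfg[[k]])) {
      v <- suppressWarnings(as.numeric(cfg[[k]]))
      if (is.na(v)) stop("config key '", k, "' must be numeric, got '",
                         cfg[[k]], "'")
      cfg[[k]] <- v
    } else if (is.logical(tgt) && is.character(cfg[[k]])) {
      v <- tolower(cfg[[k]])
      if (!(v %in% c("true", "false", "yes", "no", "1", "0")))
        stop("config key '", k, "' must be true/false, got '", cfg[[k]], "'")
      cfg[[k]] <- v %in% c("true", "yes", "1")
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie strictly between 0 and 1 (got ", cfg$alpha, ")")
  if (!(cfg$mph_mode %in% c("per-spot", "across-spots")))
    stop("mph_mode must be 'per-spot' or 'across-spots'")
  if (!(cfg$screen_source %in% c("images", "table")))
    stop("screen_source must be 'images' or 'table'")
  if (cfg$n_per_group < 3)
    stop("n_per_group must be at least 3 (the screen needs n >= 3)")
  cfg
}

logLine <- function(con, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "")
  if (!is.null(con)) writeLines(msg, con)
}

#' Simulate a synthetic study from a run configuration
#'
#' Thin orchestration over [simulateStudy()]: writes speckle images, the
#' manifest, spot placements, trait table and statistically calibrated
#' echotexture table into `out_dir`, ready for [runAnalyze()].
#'
#' @param config a config list from [readRunConfig()], or a path to a
#'   config file.
#' @param targetCorrelations optional planted correlations (see
#'   [simulateTraitTable()]).
#' @return invisible list of written paths.
#' @export
runSimulate <- function(config = NULL, targetCorrelations = NULL) {
  cfg <- if (is.character(config)) readRunConfig(config) else
    if (is.null(config)) readRunConfig() else config
  simulateStudy(
    outDir = cfg$out_dir, nPerGroup = cfg$n_per_group,
    size = c(cfg$image_rows, cfg$image_cols),
    diameter = cfg$spot_diameter, spacing = cfg$spot_spacing,
    anisotropy = c(L = cfg$anisotropy_L, T = cfg$anisotropy_T,
                   O1 = cfg$anisotropy_O1, O2 = cfg$anisotropy_O2),
    targetCorrelations = targetCorrelations, seed = cfg$seed)
}

#' Run the end-to-end echotexture analysis
#'
#' Composes the whole chain: batch image analysis (greyscale conversion,
#' byte-scale normalization, spot-meter MPI/MPH), the group x plane
#' summary, two-way ANOVA (group, plane) with LSD post hoc on MPI and MPH,
#' per-trait one-way ANOVA with Tukey letters, and the within-group and
#' pooled Pearson correlation screens. Writes into `out_dir`:
#' `echotexture.csv`, `group_summary.csv`, `anova.csv`,
#' `screen_within.csv`, `screen_pooled.csv`, and `run.log` (versions, seed,
#' per-stage timings, per-row failures).
#'
#' @param config a config list from [readRunConfig()] (or a path to one)
#'   whose `manifest`, `spots` and `traits` point at the study inputs;
#'   `screen_source = "table"` makes the screens use the `echo_table` CSV
#'   (the simulator's statistically calibrated records) instead of the
#'   image-derived records.
#' @return invisible list with the output paths, the records data.frame,
#'   both [ScreenResult-class] objects, and `status` (0 when no stage
#'   errored, 1 otherwise).
#' @export
runAnalyze <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  ## unset input paths default to the files runSimulate writes in out_dir
  for (k in c("manifest", "spots", "traits", "echo_table")) {
    cand <- file.path(cfg$out_dir, paste0(k, ".csv"))
    if (is.na(cfg[[k]]) && file.exists(cand)) cfg[[k]] <- cand
  }
  for (k in c("manifest", "traits")) {
    if (is.na(cfg[[k]])) stop("config must set '", k, "'")
    if (!file.exists(cfg[[k]])) stop("missing input file for '", k, "': ",
                                     cfg[[k]])
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$out_dir, "run.log")
  con <- file(logPath, "w")
  on.exit(close(con))
  status <- 0L
  t0 <- proc.time()[["elapsed"]]
  logLine(con, "echotex %s on %s",
          as.character(utils::packageVersion("echotex")), R.version.string)
  logLine(con, "seed = %s, alpha = %g, mph_mode = %s, screen_source = %s",
          format(cfg$seed), cfg$alpha, cfg$mph_mode, cfg$screen_source)

  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    logLine(con, "stage %-14s %6.2f s%s", name,
            proc.time()[["elapsed"]] - ts,
            if (inherits(res, "error"))
              paste0("  FAILED: ", conditionMessage(res)) else "")
    res
  }

  spots <- if (!is.na(cfg$spots) && file.exists(cfg$spots))
    readSpotsCsv(cfg$spots) else NULL
  records <- stage("echotexture", suppressWarnings(
    analyzeBatch(cfg$manifest, spots = spots, diameter = cfg$spot_diameter,
                 normalize = TRUE, mphMode = cfg$mph_mode)))
  if (inherits(records, "error")) stop("echotexture stage failed: ",
                                       conditionMessage(records))
  fails <- attr(records, "failures")
  if (nrow(fails) > 0) {
    status <- 1L
    for (i in seq_len(nrow(fails)))
      logLine(con, "  failed row: %s/%s (%s): %s", fails$bird_id[i],
              fails$plane[i], fails$path[i], fails$error[i])
  }
  writeEchotextureCsv(records, file.path(cfg$out_dir, "echotexture.csv"))

  summ <- stage("group_summary", groupSummary(records))
  utils::write.csv(summ, file.path(cfg$out_dir, "group_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  anova <- stage("anova", {
    rows <- list()
    for (resp in c("mpi", "mph")) {
      tw <- anovaTwowayLsd(records[[resp]], records$group, records$plane,
                           alpha = cfg$alpha)
      tt <- anovaTerms(tw)
      rows[[resp]] <- data.frame(analysis = "two-way-lsd",
                                 response = toupper(resp), tt,
                                 stringsAsFactors = FALSE)
    }
    traits <- utils::read.csv(cfg$traits, stringsAsFactors = FALSE)
    for (v in setdiff(names(traits), c("bird_id", "group"))) {
      res <- tryCatch(anovaOnewayTukey(traits[[v]], traits$group,
                                       alpha = cfg$alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      tt <- anovaTerms(res)
      lt <- letterDisplay(res)$group
      tt$term <- paste0("group[", paste(names(lt), lt, sep = ":",
                                        collapse = " "), "]")
      rows[[v]] <- data.frame(analysis = "one-way-tukey", response = v, tt,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  if (!inherits(anova, "error"))
    utils::write.csv(anova, file.path(cfg$out_dir, "anova.csv"),
                     row.names = FALSE, quote = FALSE)
  else status <- 1L

  screens <- stage("screen", {
    traits <- utils::read.csv(cfg$traits, stringsAsFactors = FALSE)
    echoForScreen <- if (cfg$screen_source == "table") {
      if (is.na(cfg$echo_table) || !file.exists(cfg$echo_table))
        stop("screen_source = table requires an existing echo_table path")
      utils::read.csv(cfg$echo_table, stringsAsFactors = FALSE)
    } else records
    within <- suppressMessages(correlationScreen(
      echoForScreen, traits, alpha = cfg$alpha, pooled = FALSE,
      nTraitsNominal = cfg$n_traits_nominal,
      bhAnnotation = cfg$bh_annotation))
    pooledRes <- if (cfg$pooled) suppressMessages(correlationScreen(
      echoForScreen, traits, alpha = cfg$alpha, pooled = TRUE,
      nTraitsNominal = cfg$n_traits_nominal,
      bhAnnotation = cfg$bh_annotation)) else NULL
    list(within = within, pooled = pooledRes)
  })
  if (inherits(screens, "error")) {
    status <- 1L
    screens <- list(within = NULL, pooled = NULL)
  } else {
    writeScreenCsv(screens$within, file.path(cfg$out_dir, "screen_within.csv"))
    if (!is.null(screens$pooled))
      writeScreenCsv(screens$pooled, file.path(cfg$out_dir,
                                               "screen_pooled.csv"))
    for (nm in c("within", "pooled")) {
      s <- screens[[nm]]
      if (is.null(s)) next
      ct <- screenCounts(s)
      logLine(con,
              "screen %-7s possible = %d, tested = %d, significant = %d (%.1f%%)",
              nm, ct[["possible"]], ct[["performed"]], ct[["significant"]],
              ct[["percentage"]])
    }
  }
  logLine(con, "total %.2f s, exit status %d",
          proc.time()[["elapsed"]] - t0, status)
  invisible(list(
    outDir = cfg$out_dir, records = records, screenWithin = screens$within,
    screenPooled = screens$pooled, logPath = logPath, status = status,
    outputs = file.path(cfg$out_dir,
                        c("echotexture.csv", "group_summary.csv", "anova.csv",
                          "screen_within.csv", "screen_pooled.csv",
                          "run.log"))))
}

#' Write a ScreenResult to CSV
#'
#' Significant rows only, in the published table shape: `group`,
#' `input_variable`, `output_variable`, `r`, `p_value`, `slope`,
#' `intercept`, `equation`, `strength_label`. Bookkeeping counts are
#' written as comment-free trailing columns on every row (`possible`,
#' `significant`, `percentage`).
#'
#' @param screen a [ScreenResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeScreenCsv <- function(screen, path) {
  stopifnot(is(screen, "ScreenResult"))
  sig <- significantCorrelations(screen)
  cols <- c("group", "input_variable", "output_variable", "r", "p_value",
            "slope", "intercept", "equation", "strength_label")
  if ("p_adj_bh" %in% names(sig)) cols <- c(cols, "p_adj_bh")
  out <- sig[, cols, drop = FALSE]
  ct <- screenCounts(screen)
  if (nrow(out) > 0) {
    out$possible <- ct[["possible"]]
    out$significant <- ct[["significant"]]
    out$percentage <- ct[["percentage"]]
  } else {
    out <- data.frame(matrix(ncol = length(cols) + 3, nrow = 0,
                             dimnames = list(NULL, c(cols, "possible",
                                                     "significant",
                                                     "percentage"))))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
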