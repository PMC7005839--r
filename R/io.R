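#' Event-log CSV serialization
#'
#' Event logs are persisted as comma-separated UTF-8 text with a mandatory
#' header and columns `mouse_id, session_index, session_kind, time_s,
#' event_type, countable`. Times are written with 6 decimal places so that
#' write -> read -> write round-trips byte-identically; `countable` is
#' written as `true`/`false`/`NA`.
#'
#' @param logs An `event_log`, a list of them, or a `protocol_dataset`
#'   with retained logs (one file per cohort).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(logs, path) {
  if (inherits(logs, "protocol_dataset")) {
    if (is.null(logs$logs)) stop("dataset has no retained logs")
    logs <- unlist(logs$logs, recursive = FALSE)
  }
  if (inherits(logs, "event_log")) logs <- list(logs)
  df <- do.call(rbind, lapply(logs, as.data.frame))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("mouse_id,session_index,session_kind,time_s,event_type,countable",
             con)
  writeLines(sprintf("%s,%d,%s,%.6f,%s,%s",
                     df$mouse_id, df$session_index, df$session_kind,
                     df$time_s, df$event_type,
                     ifelse(is.na(df$countable), "NA",
                            ifelse(df$countable, "true", "false"))),
             con)
  invisible(path)
}

#' @rdname write_event_log
#' @param keep_config Optional [session_config()] reattached to each log
#'   (the CSV stores events only).
#' @return `read_event_log()`: a list of `event_log` objects, one per
#'   (mouse_id, session_index) pair, in file order.
#' @export
read_event_log <- function(path, keep_config = NULL) {
  need <- c("mouse_id", "session_index", "session_kind", "time_s",
            "event_type", "countable")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, need))
    stop("malformed event-log CSV at line 1: expected header ",
         paste(need, collapse = ","))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mouse_id = "character",
                                       session_index = "integer",
                                       session_kind = "character",
                                       time_s = "numeric",
                                       event_type = "character",
                                       countable = "character"))
  bad <- which(!df$event_type %in% EVENT_TYPES)
  if (length(bad))
    stop("malformed event-log CSV at line ", bad[1] + 1L,
         ": unknown event_type '", df$event_type[bad[1]], "'")
  df$countable <- c("true" = TRUE, "false" = FALSE,
                    "NA" = NA)[df$countable]
  key <- paste(df$mouse_id, df$session_index)
  lapply(split(df, factor(key, levels = unique(key))), function(s) {
    structure(data.frame(s, row.names = NULL),
              class = c("event_log", "data.frame"),
              config = keep_config)
  })
}

#' Write the per-mouse attribution report
#'
#' Tab-separated per-mouse report: scores, thresholds, criterion flags,
#' number of criteria, label, exclusion flag.
#'
#' @param classified Result of [classify_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attribution_report <- function(classified, path) {
  att <- classified$attribution
  thr <- classified$thresholds
  att$threshold_persistence <- thr[["persistence"]]
  att$threshold_motivation <- thr[["motivation"]]
  att$threshold_compulsivity <- thr[["compulsivity"]]
  num <- vapply(att, is.numeric, TRUE)
  att[num] <- lapply(att[num], function(x) round(x, 6))
  utils::write.table(att, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the group summary JSON
#'
#' @param stats_out Result of [cohort_statistics()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(stats_out, path) {
  strip <- function(x) {
    if (inherits(x, "group_comparison")) unclass(x)
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  jsonlite::write_json(strip(stats_out), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Count-matrix TSV I/O
#'
#' Tab-separated genes-by-samples integer table with a header row of
#' sample names and gene identifiers in the first column — the layout of a
#' GEO-style count table, so a user-downloaded count matrix (e.g. the
#' deposited accession the study references) loads with the same reader.
#'
#' @param counts Integer matrix or `count_matrix`.
#' @param path File path.
#' @return `write_count_matrix`: `path` invisibly; `read_count_matrix`:
#'   an integer matrix with gene rownames.
#' @export
write_count_matrix <- function(counts, path) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed count table: need gene column + samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0))
    stop("malformed count table at line ",
         which(apply(is.na(m) | m < 0, 1, any))[1] + 1L,
         ": negative or missing count")
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a DE report TSV
#'
#' @param result A `de_result`.
#' @param filters Result of [apply_de_filters()] (defaults recomputed).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_report <- function(result, path, filters = NULL) {
  if (is.null(filters)) filters <- apply_de_filters(result)
  out <- as.data.frame(result)
  out$selected <- filters$selected
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 8))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration file
#'
#' YAML (or JSON) configuration with `groups` (named list of group-spec
#' fields), `protocol` (fields of [protocol_config()]) and optional `de`
#' sections; see `inst/extdata/example_config.yaml`.
#'
#' @param path YAML/JSON file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$groups) || !length(cfg$groups))
    stop("config error: 'groups' section is missing or empty")
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
  cfg$groups <- lapply(cfg$groups, function(g) {
    names(g)[names(g) %in% c("FALSE", "no")] <- "n"
    g
  })
  cfg
}

.group_from_config <- function(label, g) {
  args <- list(label = label, n = g$n)
  for (f in c("active_rate", "inactive_rate", "persistence_factor",
              "motivation_cap", "shock_continue_prob"))
    if (!is.null(g[[f]])) args[[f]] <- as.numeric(g[[f]])
  if (!is.null(g$acquisition_gain)) args$acquisition_gain <- g$acquisition_gain
  do.call(group_spec, args)
}

#' Run the full phenotyping pipeline
#'
#' simulate -> score -> classify -> group statistics, writing the event-log
#' CSV (optional), the per-mouse attribution TSV, the group-summary JSON
#' and a run manifest recording the seed, configuration snapshot, package
#' version and per-stage output paths. Outputs are deterministic given
#' `seed`; the manifest's wall-clock timestamps can be suppressed with
#' `timestamps = FALSE` for byte-identical reruns.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent list.
#' @param seed Integer seed (overrides the config's).
#' @param outdir Output directory (created if needed).
#' @param control Control group label (threshold source); defaults to the
#'   first group in the config.
#' @param write_logs Also write the full event-log CSV.
#' @param timestamps Record wall-clock timestamps in the manifest.
#' @return Invisibly, a list: `classified`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, seed = 1L, outdir = ".",
                         control = NULL, write_logs = TRUE,
                         timestamps = TRUE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  groups <- Map(.group_from_config, names(cfg$groups), cfg$groups)
  if (is.null(control)) control <- names(cfg$groups)[1]
  pargs <- cfg$protocol %||% list()
  pargs$seed <- as.integer(seed)
  protocol <- do.call(protocol_config, pargs)

  ds <- run_protocol(unname(groups), protocol, keep_logs = write_logs)
  scores <- criterion_scores(ds)
  excl <- apply_exclusion(ds)
  classified <- classify_cohort(scores, excl, control = control)
  stats_out <- cohort_statistics(classified, control = control)

  paths <- list(
    attribution = file.path(outdir, "attribution.tsv"),
    group_summary = file.path(outdir, "group_summary.json")
  )
  if (write_logs) {
    paths$event_log <- file.path(outdir, "event_log.csv")
    write_event_log(ds, paths$event_log)
  }
  write_attribution_report(classified, paths$attribution)
  write_group_summary(stats_out, paths$group_summary)

  manifest <- list(
    package = "foodaddictr",
    version = as.character(utils::packageVersion("foodaddictr")),
    seed = as.integer(seed),
    control_group = control,
    config = cfg,
    outputs = lapply(paths, basename)  # relative to outdir
  )
  if (timestamps) manifest$timestamp <- format(Sys.time(), tz = "UTC")
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (p in paths) stopifnot(file.exists(p))
  invisible(list(classified = classified, stats = stats_out,
                 manifest = manifest, paths = paths))
}
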