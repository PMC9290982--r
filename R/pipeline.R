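# Pipeline orchestration: configuration validation, per-structure
# analysis (helices -> numbering -> hydrogen-bond ledger -> weak spots ->
# escape channel), ensemble conservation profile, and machine-readable
# outputs (single-header TSV plus JSON mirrors and a manifest).  Results
# go to files and the return value; logging goes to stderr only.

.pipeline_defaults <- list(probe = 1.4, spacing = 1.0, ion_radius = 1.02,
                           mode = "vdw", escape = TRUE, start = "2x46",
                           cytosol = "zmin", output_dir = "helixweak_out",
                           seed = 1L)

#' Validate a pipeline configuration
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Required keys: `structures` (vector of structure file paths) and
#'   `anchors` (anchor-config file path(s), recycled across structures).
#'   Optional keys with defaults: `probe` (1.4), `spacing` (1.0),
#'   `ion_radius` (1.02), `mode` (`"vdw"`), `escape` (TRUE), `start`
#'   (`"2x46"`), `cytosol` (`"zmin"`), `output_dir`, `seed`.  Unknown
#'   keys are rejected.
#' @return The completed configuration list, class `hw_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  required <- c("structures", "anchors")
  known <- c(required, names(.pipeline_defaults))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing_req <- required[!required %in% names(config)]
  if (length(missing_req) > 0)
    stop("missing required config keys: ",
         paste(missing_req, collapse = ", "))
  for (k in names(.pipeline_defaults))
    if (is.null(config[[k]])) config[[k]] <- .pipeline_defaults[[k]]
  config$structures <- unlist(config$structures)
  config$anchors <- rep_len(unlist(config$anchors),
                            length(config$structures))
  for (f in c(config$structures, unique(config$anchors)))
    if (!file.exists(f)) stop("referenced file does not exist: ", f)
  for (k in c("probe", "spacing", "ion_radius"))
    if (!is.numeric(config[[k]]) || config[[k]] <= 0)
      stop(k, " must be a positive number")
  if (!config$mode %in% c("vdw", "literal")) stop("mode must be vdw or literal")
  if (!config$cytosol %in% c("zmin", "zmax"))
    stop("cytosol must be zmin or zmax")
  class(config) <- c("hw_config", "list")
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

log_msg <- function(...) message("[helixweak] ", ...)

analyse_structure <- function(s, anchors, config) {
  segments <- detect_helices(s)
  segments <- lapply(segments, function(sg) annotate_irregularities(s, sg))
  numbering <- assign_generic_numbers(s, segments, anchors)
  ws <- weakspot_table(s, numbering = numbering, segments = segments)
  escape <- NULL
  if (isTRUE(config$escape)) {
    escape <- tryCatch({
      r <- escape_channel_test(s, numbering, start = config$start,
                               ion_radius = config$ion_radius,
                               spacing = config$spacing,
                               probe = config$probe, mode = config$mode,
                               cytosol = config$cytosol)
      data.frame(structure = s$id, verdict = r$verdict, reason = r$reason,
                 min_pore_radius = r$min_pore_radius,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(structure = s$id, verdict = NA_character_,
                 reason = paste("error:", conditionMessage(e)),
                 min_pore_radius = NA_real_, stringsAsFactors = FALSE))
  }
  list(weakspots = ws, escape = escape, n_segments = length(segments))
}

#' Run the full weak-spot pipeline
#'
#' For every configured structure: read, detect and annotate helices,
#' assign generic numbers from its anchor file, call weak spots, and
#' (optionally) run the sodium escape-channel test; then aggregate the
#' ensemble conservation profile.  All tabular outputs are written as
#' single-header TSV with JSON mirrors, together with a manifest
#' recording configuration, package version, seed and input checksums.
#' Identical configuration and inputs give byte-identical outputs;
#' per-structure results are cached under `output_dir/cache`, keyed by
#' input checksum and parameters, and reused on reruns.
#'
#' @param config A configuration list or YAML path, see
#'   [validate_config()].
#' @return A list of class `hw_run`: `weakspots`, `escape`, `profile`,
#'   `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  par_key <- substr(digest_key(unclass(config)[c("probe", "spacing",
                                                 "ion_radius", "mode",
                                                 "escape", "start",
                                                 "cytosol")]), 1L, 12L)
  all_ws <- list()
  all_escape <- list()
  errors <- list()
  checksums <- character(0)
  for (i in seq_along(config$structures)) {
    path <- config$structures[i]
    md5 <- unname(tools::md5sum(path))
    amd5 <- unname(tools::md5sum(config$anchors[i]))
    checksums[basename(path)] <- md5
    key <- paste0(md5, "_", substr(amd5, 1L, 8L), "_", par_key)
    cache_file <- file.path(cache_dir, paste0(key, ".rds.tsv"))
    esc_file <- file.path(cache_dir, paste0(key, "_escape.tsv"))
    res <- NULL
    if (file.exists(cache_file)) {
      log_msg("cached: ", basename(path))
      ws <- utils::read.delim(cache_file, colClasses = c(
        chain = "character", generic = "character", class = "character",
        mechanism = "character", causal = "character"))
      esc <- if (file.exists(esc_file)) utils::read.delim(esc_file)
      else NULL
      res <- list(weakspots = ws, escape = esc)
    } else {
      log_msg("analysing: ", basename(path))
      res <- tryCatch({
        s <- read_structure(path)
        anchors <- read_anchor_config(config$anchors[i])
        r <- analyse_structure(s, anchors, config)
        write_tsv(r$weakspots, cache_file)
        if (!is.null(r$escape)) write_tsv(r$escape, esc_file)
        r
      }, error = function(e) {
        log_msg("FAILED ", basename(path), ": ", conditionMessage(e))
        errors[[basename(path)]] <<- conditionMessage(e)
        NULL
      })
    }
    if (is.null(res)) next
    sid <- sub("\\.[^.]*$", "", basename(path))
    ws <- res$weakspots
    if (nrow(ws) > 0) ws$structure <- sid
    all_ws[[sid]] <- ws
    if (!is.null(res$escape)) all_escape[[sid]] <- res$escape
  }
  weakspots <- if (length(all_ws) > 0) {
    nonempty <- Filter(function(x) nrow(x) > 0, all_ws)
    if (length(nonempty) > 0) do.call(rbind, c(nonempty,
                                               make.row.names = FALSE))
    else .empty_weakspots()
  } else .empty_weakspots()
  escape <- if (length(all_escape) > 0)
    do.call(rbind, c(all_escape, make.row.names = FALSE)) else NULL
  profile <- aggregate_weak_spots(all_ws)
  write_tsv(weakspots, file.path(out_dir, "weakspots.tsv"))
  jsonlite::write_json(weakspots, file.path(out_dir, "weakspots.json"),
                       dataframe = "rows", na = "null", digits = NA)
  if (!is.null(escape)) {
    write_tsv(escape, file.path(out_dir, "escape.tsv"))
    jsonlite::write_json(escape, file.path(out_dir, "escape.json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  write_tsv(as.data.frame(profile), file.path(out_dir, "conservation.tsv"))
  jsonlite::write_json(as.data.frame(profile),
                       file.path(out_dir, "conservation.json"),
                       dataframe = "rows", na = "null", digits = NA)
  manifest <- list(
    package = "helixweak",
    version = as.character(utils::packageVersion("helixweak")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "output_dir")],
    checksums = as.list(checksums),
    errors = errors,
    n_structures = length(config$structures),
    n_failed = length(errors))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- list(weakspots = weakspots, escape = escape, profile = profile,
              manifest = manifest, output_dir = out_dir)
  class(out) <- "hw_run"
  out
}

# Stable key for a parameter list (name=value serialisation).
digest_key <- function(x) {
  txt <- paste(names(x), vapply(x, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1L)),
    sep = "=", collapse = ";")
  # md5 of the serialised text via a temp file (tools::md5sum is file-based)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.hw_run <- function(x, ...) {
  cat(sprintf("<hw_run> %d structures (%d failed), %d weak spots, %d profiled positions\n",
              x$manifest$n_structures, x$manifest$n_failed,
              nrow(x$weakspots), nrow(x$profile)))
  cat("  outputs in:", x$output_dir, "\n")
  invisible(x)
}
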