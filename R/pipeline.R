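# End-to-end orchestration: simulate -> mask -> frame -> quantify ->
# test -> report, under a single validated config with a fanned-out seed.

ee_known_config_keys <- c(
  "line_id", "seed", "n_control", "n_line", "line_effect", "pattern",
  "geometry", "nuclei", "noise", "roi_radius", "region_defs", "test_region",
  "alpha", "welch", "out_dir")

default_run_config <- function() {
  list(line_id = "line", seed = 1L, n_control = 5L, n_line = 5L,
       line_effect = 1, pattern = list(type = "lateral", amplitude = 400,
                                       baseline = 20),
       geometry = list(a = 260, b = 110, angle = 0),
       nuclei = list(n = 220, radius = 5, min_sep = 13),
       noise = list(sd = 20), roi_radius = 15,
       region_defs = default_region_defs(), test_region = "ectoderm",
       alpha = 0.05, welch = FALSE, out_dir = NULL)
}

config_pattern_spec <- function(p, effect = 1) {
  base <- (p$baseline %||% 0)
  amp <- (p$amplitude %||% 100) * effect
  prim <- switch(p$type %||% "lateral",
    lateral = lateral_domain(amp),
    ventral = ventral_domain(amp),
    posterior = posterior_domain(amp),
    stripe = ap_stripe(p$center %||% 0.35, p$sigma %||% 0.05, amp),
    uniform = uniform_level(amp),
    ee_config_error(sprintf("unknown pattern type '%s'", p$type)))
  pattern_spec(prim, baseline = base)
}

#' Validate and complete a run configuration
#'
#' Unknown keys are rejected (named in the error); missing keys take the
#' documented defaults. The config may be a list or a YAML file path.
#'
#' @param config list or YAML path.
#' @return The completed config with a `config_hash` attribute (md5 of the
#'   canonical JSON form; changes iff any parameter changes).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) ee_config_error(sprintf("no such config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) ee_config_error("config must be a list or YAML path")
  unknown <- setdiff(names(config), ee_known_config_keys)
  if (length(unknown)) {
    ee_config_error(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  full <- utils::modifyList(default_run_config(), config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(full[order(names(full))], tmp, auto_unbox = TRUE,
                       digits = NA, na = "null")
  attr(full, "config_hash") <- unname(tools::md5sum(tmp))
  full
}

#' Run the staged quantification pipeline for one line
#'
#' Simulates `n_control` control embryos and `n_line` embryos of the test
#' line (whose pattern amplitude is multiplied by `line_effect`), then for
#' each embryo masks the embryo, fits the axis frame (anterior resolved
#' from generator truth), and measures the germ-layer region triplet;
#' finally the line is classified against control by a two-tailed t test
#' on the configured test region. Per-embryo failures are recorded, not
#' fatal; a run with zero usable embryos in either group errors.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @return Object of class `line_report`: list with `line_id`, `triplets`
#'   (data.frame: embryo, group, one column per region), `comparison`
#'   (a `line_comparison`), `failures`, `config`, `config_hash`,
#'   `version`, `seed`.
#' @export
run_quantification <- function(config) {
  cfg <- validate_config(config)
  regions <- names(cfg$region_defs)
  if (!cfg$test_region %in% regions) {
    ee_config_error(sprintf("test_region '%s' is not a configured region",
                            cfg$test_region))
  }
  geom <- embryo_geometry(cfg$geometry$a, cfg$geometry$b,
                          angle = cfg$geometry$angle %||% 0)
  run_group <- function(group, n, effect) {
    spec <- config_pattern_spec(cfg$pattern, effect)
    rows <- list(); fails <- list()
    for (i in seq_len(n)) {
      eseed <- derive_seed(cfg$seed, sprintf("render/%s/%d", group, i))
      res <- tryCatch({
        sim <- render_embryo(geom, spec, nuclei = cfg$nuclei,
                             noise = cfg$noise, seed = eseed)
        msk <- mask_embryo(sim$image)
        frame <- resolve_anterior(fit_embryo_frame(msk),
                                  sim$geometry$anterior)
        trip <- measure_regions(sim$image, frame, mask = msk,
                                roi_radius = cfg$roi_radius,
                                region_defs = cfg$region_defs,
                                embryo_id = sprintf("%s_%02d", group, i))
        c(list(embryo = sprintf("%s_%02d", group, i), group = group),
          as.list(trip$values))
      }, embryoexpress_error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- list(
          embryo = sprintf("%s_%02d", group, i), message = conditionMessage(res))
      } else rows[[length(rows) + 1L]] <- res
    }
    list(rows = rows, fails = fails)
  }
  ctl <- run_group("control", cfg$n_control, 1)
  lin <- run_group("line", cfg$n_line, cfg$line_effect)
  if (length(ctl$rows) == 0L || length(lin$rows) == 0L) {
    ee_generation_error("no usable embryos in one of the groups")
  }
  triplets <- do.call(rbind, lapply(c(ctl$rows, lin$rows), function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tr <- cfg$test_region
  comparison <- classify_line(
    triplets[[tr]][triplets$group == "line"],
    triplets[[tr]][triplets$group == "control"],
    alpha = cfg$alpha, line_id = cfg$line_id, welch = cfg$welch)
  report <- structure(list(
    line_id = cfg$line_id, triplets = triplets, comparison = comparison,
    failures = c(ctl$fails, lin$fails),
    config = cfg, config_hash = attr(cfg, "config_hash"),
    version = as.character(utils::packageVersion("embryoexpress")),
    seed = cfg$seed), class = "line_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.line_report <- function(x, ...) {
  cat(sprintf("line_report [%s]: %d embryos (%d failures), call %s (p = %.4g)\n",
              x$line_id, nrow(x$triplets), length(x$failures),
              x$comparison$call, x$comparison$p))
  invisible(x)
}

#' Write a line report to CSV and JSON
#'
#' The CSV holds the per-embryo region triplets (one row per embryo); the
#' JSON mirrors the full report (identical values) with a schema version.
#'
#' @param report a `line_report`.
#' @param dir output directory (created if missing).
#' @param formats subset of `c("csv", "json")`.
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  ok <- tryCatch({
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.exists(dir)
  }, error = function(e) FALSE)
  if (!ok) ee_io_error(sprintf("cannot create output directory: %s", dir))
  files <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(dir, sprintf("%s_triplets.csv", report$line_id))
    utils::write.csv(report$triplets, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    f <- file.path(dir, sprintf("%s_report.json", report$line_id))
    jsonlite::write_json(list(
      schema = "embryoexpress/line_report/1",
      line_id = report$line_id,
      triplets = report$triplets,
      comparison = unclass(report$comparison),
      failures = report$failures,
      config = unclass(report$config),
      config_hash = report$config_hash,
      version = report$version,
      seed = report$seed), f, dataframe = "rows", auto_unbox = TRUE,
      digits = NA, na = "null")
    files <- c(files, f)
  }
  invisible(files)
}
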