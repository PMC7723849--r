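# Shared statistics dispatch, file I/O and the command-line entry point.

#' Normality-gated statistical test dispatch
#'
#' Implements the analysis rule used throughout: every dataset is tested for
#' normality with Shapiro-Wilk at alpha = 0.01 (a dataset is "normal" when
#' its p-value is >= 0.01). If ALL groups pass, the parametric branch is
#' taken: unpaired Student's t-test for two groups, one-way ANOVA for more.
#' Otherwise the nonparametric branch: Mann-Whitney for two groups,
#' Kruskal-Wallis for more. The full decision trail is returned.
#'
#' @param datasets named list of numeric vectors, one per group; each needs
#'   at least 3 values for the normality test.
#' @param alpha_normality normality gate (default 0.01).
#' @param var_equal logical; classical Student's t / ANOVA assume equal
#'   variances (default TRUE).
#' @return an object of class `test_decision`: `branch`, `test_name`,
#'   `normality_p_values`, `alpha_normality`, `statistic`, `p_value`,
#'   `n_groups`.
#' @export
dispatch_test <- function(datasets, alpha_normality = 0.01,
                          var_equal = TRUE) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    stop("need at least 2 datasets (groups) to compare", call. = FALSE)
  }
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("group", seq_along(datasets))
  }
  for (nm in names(datasets)) {
    x <- datasets[[nm]]
    if (!is.numeric(x) || sum(is.finite(x)) < 3L) {
      stop(sprintf("dataset '%s' needs >= 3 finite values", nm),
           call. = FALSE)
    }
    if (stats::sd(x) == 0) {
      stop(sprintf(
        "dataset '%s' is constant; normality testing is undefined", nm),
        call. = FALSE)
    }
  }
  norm_p <- vapply(datasets, function(x) stats::shapiro.test(x)$p.value, 0)
  parametric <- all(norm_p >= alpha_normality)
  k <- length(datasets)
  values <- unlist(datasets, use.names = FALSE)
  groups <- factor(rep(names(datasets), lengths(datasets)))

  if (parametric && k == 2L) {
    test_name <- "t_test"
    res <- stats::t.test(datasets[[1]], datasets[[2]], var.equal = var_equal)
  } else if (parametric) {
    test_name <- "anova"
    res <- stats::oneway.test(values ~ groups, var.equal = var_equal)
  } else if (k == 2L) {
    test_name <- "mann_whitney"
    res <- stats::wilcox.test(datasets[[1]], datasets[[2]], exact = FALSE)
  } else {
    test_name <- "kruskal_wallis"
    res <- stats::kruskal.test(values, groups)
  }
  structure(list(
    branch = if (parametric) "parametric" else "nonparametric",
    test_name = test_name,
    normality_p_values = norm_p,
    alpha_normality = alpha_normality,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_groups = k
  ), class = "test_decision")
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf("Branch: %s (Shapiro-Wilk gate at p >= %g)\n", x$branch,
              x$alpha_normality))
  cat("  normality p-values:",
      paste(sprintf("%s=%.3g", names(x$normality_p_values),
                    x$normality_p_values), collapse = ", "), "\n")
  cat(sprintf("  %s: statistic = %.4g, p = %.4g\n", x$test_name,
              x$statistic, x$p_value))
  invisible(x)
}

#' Standard error of the mean
#' @param x numeric vector.
#' @return s.e.m. (summary error bars are reported as mean +/- s.e.m.).
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# ---------------------------------------------------------------------------
# Image stack I/O: a plain-text multi-page format. Page layout:
#   line 1: "regenquant-image 1" (magic + version)
#   line 2: JSON header {pages, rows, cols, pixel_size_um, frame_interval_s}
#   then pages * rows lines of cols space-separated values.
# ---------------------------------------------------------------------------

#' Write an image or stack to a plain-text file
#'
#' @param x matrix (2-D image) or 3-D array ordered (page, row, col).
#' @param path output file path.
#' @param pixel_size_um,frame_interval_s optional metadata; taken from
#'   attributes of `x` when present.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(x, path, pixel_size_um = NULL,
                              frame_interval_s = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(x, "pixel_size_um")
  frame_interval_s <- frame_interval_s %||% attr(x, "frame_interval_s")
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  header <- jsonlite::toJSON(list(
    pages = d[1], rows = d[2], cols = d[3],
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s
  ), auto_unbox = TRUE, null = "null", digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("regenquant-image 1", as.character(header)), con)
  for (p in seq_len(d[1])) {
    page <- matrix(x[p, , ], d[2], d[3])
    writeLines(apply(format(page, trim = TRUE, digits = 10), 1L,
                     paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path file path.
#' @return 3-D array (page, row, col) with `pixel_size_um` and
#'   `frame_interval_s` attributes (possibly `NULL`); single-page files
#'   still return a 3-D array with one page.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "regenquant-image 1")) {
    stop("not a regenquant image file: ", path, call. = FALSE)
  }
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  vals <- scan(con, what = numeric(), quiet = TRUE)
  d <- c(hdr$pages, hdr$rows, hdr$cols)
  if (length(vals) != prod(d)) {
    stop("corrupt image file: value count does not match header",
         call. = FALSE)
  }
  # values are written row by row within each page
  x <- array(NA_real_, dim = d)
  per_page <- d[2] * d[3]
  for (p in seq_len(d[1])) {
    block <- vals[((p - 1) * per_page + 1):(p * per_page)]
    x[p, , ] <- matrix(block, d[2], d[3], byrow = TRUE)
  }
  attr(x, "pixel_size_um") <- hdr$pixel_size_um
  attr(x, "frame_interval_s") <- hdr$frame_interval_s
  x
}

#' Write a records table as CSV
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: regenquant <command> [options]",
    "",
    "commands:",
    "  simgen   generate synthetic data: --kind nerve|explant|movie",
    "           [--config FILE.yaml] [--seed N] --out DIR",
    "  nerve    regeneration curve: --image FILE --annotations FILE.json",
    "           --out DIR",
    "  explant  Sholl outgrowth: --image FILE --pixel-size UM [--step UM]",
    "           --out DIR",
    "  collapse growth-cone collapse: --annotations FILE.csv --out DIR",
    "  kymo     transport kinetics: --movie FILE --path FILE.json",
    "           [--vmin 0.02] --out DIR",
    "  stats    dispatch test: --data FILE.csv (columns value,group)",
    "           [--alpha 0.01] --out DIR",
    sep = "\n")
}

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- argv[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

cli_require <- function(opts, keys) {
  missing <- setdiff(keys, names(opts))
  if (length(missing) > 0L) {
    stop("missing required flag(s): ",
         paste0("--", missing, collapse = ", "), call. = FALSE)
  }
}

cli_simgen <- function(opts) {
  cli_require(opts, c("kind", "out"))
  overrides <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  if (!is.null(opts$seed)) overrides$seed <- as.integer(opts$seed)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  kind <- opts$kind
  if (kind == "nerve") {
    cfg <- do.call(nerve_sim_config, overrides)
    sim <- simulate_optic_nerve(cfg)
    write_image_stack(sim$image, file.path(opts$out, "nerve.txt"),
                      pixel_size_um = cfg$pixel_size_um)
    dists <- seq(0, 3000, by = 100)
    write_table(data.frame(distance_um = dists,
                           fibers = sim$truth$fibers_at(dists)),
                file.path(opts$out, "truth_fiber_counts.csv"))
    truth <- sim$truth[c("injury_x_um", "survival_um")]
  } else if (kind == "explant") {
    cfg <- do.call(explant_sim_config, overrides)
    sim <- simulate_explant(cfg)
    write_image_stack(sim$image, file.path(opts$out, "explant.txt"),
                      pixel_size_um = cfg$pixel_size_um)
    write_table(data.frame(band_um = sim$truth$bands_um,
                           crossings = sim$truth$band_counts),
                file.path(opts$out, "truth_band_counts.csv"))
    truth <- sim$truth[c("lengths_um", "border_dist_um", "band_step_um")]
  } else if (kind == "movie") {
    cfg <- do.call(track_sim_config, overrides)
    sim <- simulate_organelle_movie(cfg)
    write_image_stack(sim$movie, file.path(opts$out, "movie.txt"),
                      pixel_size_um = cfg$pixel_size_um,
                      frame_interval_s = cfg$frame_interval_s)
    truth <- sim$truth[c("class", "speed_um_s", "frame_interval_s",
                         "axon_length_um")]
  } else {
    stop("unknown --kind: ", kind, call. = FALSE)
  }
  jsonlite::write_json(truth, file.path(opts$out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.function,
                                        logical(1))],
                   file.path(opts$out, "config.yaml"))
  0L
}

cli_nerve <- function(opts) {
  cli_require(opts, c("image", "annotations", "out"))
  ann <- jsonlite::fromJSON(opts$annotations)
  stk <- read_image_stack(opts$image)
  px <- ann$pixel_size_um %||% attr(stk, "pixel_size_um")
  if (is.null(px)) {
    stop("pixel size missing: supply `pixel_size_um` in the annotation ",
         "file or use an image with embedded metadata", call. = FALSE)
  }
  proj <- max_project(array(stk, dim = dim(stk)), pixel_size_um = px)
  # annotation injury_line is [[x1,y1],[x2,y2]] in (col,row) order, 0-based
  il <- ann$injury_line
  inj <- injury_site(c(il[1, 2], il[1, 1]), c(il[2, 2], il[2, 1]),
                     axial_sign = ann$axial_direction_sign %||% 1)
  dists <- ann$distances_um %||% c(200, 500, 750, 1000, 1500, 2000, 2500, 3000)
  curve <- regeneration_curve(proj, inj, dists, ann$background_distance_um)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_table(data.frame(distance_um = curve$distances_um,
                         integrated = curve$integrals,
                         normalized = curve$normalized,
                         background_subtracted = curve$values_au,
                         width_um = curve$widths_um),
              file.path(opts$out, "regeneration_curve.csv"))
  jsonlite::write_json(list(background_au = curve$background_au,
                            background_position_um = ann$background_distance_um,
                            pixel_size_um = px),
                       file.path(opts$out, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_explant <- function(opts) {
  cli_require(opts, c("image", "out"))
  stk <- read_image_stack(opts$image)
  px <- if (!is.null(opts$`pixel-size`)) as.numeric(opts$`pixel-size`) else
    attr(stk, "pixel_size_um")
  if (is.null(px)) {
    stop("pixel size missing: pass --pixel-size or use an image with ",
         "embedded metadata", call. = FALSE)
  }
  img <- matrix(stk[1, , ], dim(stk)[2], dim(stk)[3])
  mask <- segment_explant(img, px)
  skel <- neurite_skeleton(img, mask, px)
  step <- if (!is.null(opts$step)) as.numeric(opts$step) else 50
  sh <- sholl_counts(skel, mask, px, step_um = step)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_table(data.frame(distance_um = sh$distances_um,
                         intersections = sh$intersect_counts),
              file.path(opts$out, "sholl_profile.csv"))
  jsonlite::write_json(list(axon_count = sh$axon_count,
                            no_growth = sh$no_growth, step_um = sh$step_um),
                       file.path(opts$out, "sholl_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_collapse <- function(opts) {
  cli_require(opts, c("annotations", "out"))
  ann <- utils::read.csv(opts$annotations, stringsAsFactors = FALSE)
  ann$has_lamellipodia <- as.logical(ann$has_lamellipodia)
  res <- score_collapse(ann)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_table(res$per_explant, file.path(opts$out, "collapse_per_explant.csv"))
  jsonlite::write_json(res$group, file.path(opts$out, "collapse_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_kymo <- function(opts) {
  cli_require(opts, c("movie", "path", "out"))
  stk <- read_image_stack(opts$movie)
  px <- attr(stk, "pixel_size_um")
  dt <- attr(stk, "frame_interval_s")
  if (is.null(px) || is.null(dt)) {
    stop("movie metadata incomplete: pixel_size_um / frame_interval_s ",
         "must be embedded in the image file", call. = FALSE)
  }
  pdef <- jsonlite::fromJSON(opts$path)
  # vertices_px given as [[x,y], ...] (col,row), 0-based
  vp <- pdef$vertices_px
  pth <- axon_path(cbind(vp[, 2], vp[, 1]),
                   distal_end = pdef$distal_end %||% "last",
                   linewidth_px = pdef$linewidth_px %||% 3L)
  mv <- time_lapse_movie(stk, dt, px)
  kym <- build_kymograph(mv, pth)
  vmin <- if (!is.null(opts$vmin)) as.numeric(opts$vmin) else 0.02
  tracks <- if (!is.null(opts$tracks)) {
    tr <- utils::read.csv(opts$tracks, stringsAsFactors = FALSE)
    lapply(split(tr, tr$organelle_id), function(g) {
      g <- g[order(g$frame), ]
      track(g$frame, g$position_um, dt, g$organelle_id[1])
    })
  } else {
    extract_tracks_auto(kym)
  }
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_image_stack(kym$array, file.path(opts$out, "kymograph.txt"),
                    pixel_size_um = px, frame_interval_s = dt)
  if (length(tracks) == 0L) {
    stop("no tracks found; supply --tracks or lower the detection threshold",
         call. = FALSE)
  }
  kin <- kinetics(tracks, v_min_um_s = vmin)
  samples <- do.call(rbind, lapply(tracks, function(t) {
    cbind(organelle_id = t$organelle_id, t$samples)
  }))
  write_table(samples, file.path(opts$out, "tracks.csv"))
  jsonlite::write_json(unclass(kin), file.path(opts$out, "kinetics.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_stats <- function(opts) {
  cli_require(opts, c("data", "out"))
  df <- utils::read.csv(opts$data, stringsAsFactors = FALSE)
  if (!all(c("value", "group") %in% names(df))) {
    stop("--data file needs columns `value` and `group`", call. = FALSE)
  }
  alpha <- if (!is.null(opts$alpha)) as.numeric(opts$alpha) else 0.01
  dec <- dispatch_test(split(df$value, df$group), alpha_normality = alpha)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(dec), file.path(opts$out, "test_decision.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

#' Command-line entry point
#'
#' `regenquant {simgen,nerve,explant,collapse,kymo,stats} [--flags]`.
#' Returns an exit code (0 success, 2 usage error, 1 runtime failure)
#' instead of quitting, so it can be driven programmatically.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || argv[[1]] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[[1]]
  handler <- switch(cmd,
                    simgen = cli_simgen, nerve = cli_nerve,
                    explant = cli_explant, collapse = cli_collapse,
                    kymo = cli_kymo, stats = cli_stats, NULL)
  if (is.null(handler)) {
    message("unknown command: ", cmd, "\n\n", cli_usage())
    return(invisible(2L))
  }
  opts <- tryCatch(cli_args(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n\n", cli_usage())
    return(invisible(2L))
  }
  code <- tryCatch(handler(opts), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
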