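#' Segment a stack from disk and persist mask, metrics and provenance
#'
#' File-level orchestration of the whole detection pipeline: read the
#' stack, run [segment_sinus()], compute the interval volume, and write
#' the detected mask, a JSON metrics record and a JSON provenance file
#' capturing every parameter plus input checksums — enough to reproduce
#' the run bit for bit.
#'
#' @param config A named list (or path to a JSON file) with fields:
#'   `input` (path), `format` (`"image_directory"` or `"nifti"`),
#'   `seed` (`c(slice, row, col)`), `k`, optional `polarity`
#'   (default `"foreground_geq"`), `layers` (default 0),
#'   `window_halfwidth`, `voxel_side` (default 1), `unit`
#'   (default `"mm^3"`), `spacing`, `mask_format`
#'   (default `"image_directory"`), and `out` (output directory).
#' @return Invisibly, a list with the `segmentation`, the
#'   [estimate_volume()] record, and the written file paths.
#' @export
run_segment <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  needed <- c("input", "seed", "k", "out")
  missing <- setdiff(needed, names(config))
  if (length(missing)) {
    abort(sprintf("Config is missing: %s", paste(missing, collapse = ", ")))
  }
  format <- config$format %||% "image_directory"
  stack <- read_stack(config$input, format, spacing = config$spacing)
  seed <- do.call(seed_point, as.list(as.integer(config$seed)))
  seg <- segment_sinus(
    stack, seed,
    k = config$k,
    polarity = config$polarity %||% "foreground_geq",
    layers = config$layers %||% 0L,
    window_halfwidth = config$window_halfwidth
  )
  vol <- estimate_volume(
    seg$mask,
    voxel_side = config$voxel_side %||% 1,
    unit = config$unit %||% "mm^3"
  )
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  mask_format <- config$mask_format %||% "image_directory"
  mask_path <- if (mask_format == "nifti") {
    file.path(out, "mask.nii.gz")
  } else {
    file.path(out, "mask")
  }
  write_mask(seg$mask, mask_path, mask_format)
  metrics_path <- file.path(out, "metrics.json")
  jsonlite::write_json(
    c(tidy(vol), list(n_voxels = seg$n_voxels)),
    metrics_path,
    auto_unbox = TRUE, digits = NA
  )
  input_files <- if (dir.exists(config$input)) {
    list.files(config$input, full.names = TRUE)
  } else {
    config$input
  }
  prov_path <- file.path(out, "provenance.json")
  jsonlite::write_json(
    list(
      package = "sinusvol",
      version = as.character(utils::packageVersion("sinusvol")),
      input = config$input,
      input_md5 = unname(tools::md5sum(input_files)),
      params = seg$params,
      fallback_slices = seg$fallback_slices,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    prov_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    segmentation = seg, volume = vol,
    paths = list(mask = mask_path, metrics = metrics_path, provenance = prov_path)
  ))
}

#' Compare pre/post volume records
#'
#' Per-pair relative changes and, with at least two pairs, the full
#' cohort statistics. Accepts either a data frame with `v_pre`/`v_post`
#' columns (optionally `sample_id`) or two vectors of paths to
#' `metrics.json` records written by [run_segment()], matched in order.
#'
#' @param pre,post Either a single data frame (in `pre`, with `post`
#'   missing) or numeric vectors / metrics-file paths.
#' @param alpha Significance level for the cohort CI.
#' @return For one pair, the [relative_change()] tibble; otherwise a
#'   [cohort_summary()].
#' @export
run_compare <- function(pre, post = NULL, alpha = 0.05) {
  if (is.data.frame(pre) && is.null(post)) {
    df <- pre
  } else {
    v_pre <- records_to_volumes(pre)
    v_post <- records_to_volumes(post)
    if (length(v_pre) != length(v_post)) {
      abort("Mismatched numbers of pre and post records.")
    }
    df <- tibble(v_pre = v_pre, v_post = v_post)
  }
  if (nrow(df) == 1) {
    return(relative_change(df$v_pre, df$v_post))
  }
  cohort_summary(df, alpha = alpha)
}

records_to_volumes <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  unname(vapply(
    x,
    function(p) jsonlite::read_json(p, simplifyVector = TRUE)$v_mid,
    numeric(1)
  ))
}
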