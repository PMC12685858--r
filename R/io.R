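#' Read and write vascular trees
#'
#' The canonical on-disk format is JSON with top-level fields
#' `schema_version`, `fluid` (density, viscosity), `inlet_id`,
#' `target_branch_id` and `segments` (id, parent, length_m, radius_m, label).
#' Depth levels and target membership are derived, never stored.  Numbers are
#' written with 17 significant digits so that write -> read is the identity on
#' doubles, and the byte stream is deterministic for a given tree.
#'
#' The alternative CSV edge list (`child_id,parent_id,length_m,radius_m`)
#' carries geometry only; `target_branch_id` and `fluid` must be supplied on
#' read.
#'
#' All tree invariants are re-validated on read; malformed files (cycles,
#' multiple roots, missing or non-positive radii) raise validation errors
#' naming the offending segment.
#'
#' @param tree A [vascular_tree()].
#' @param path File path.
#' @param format `"json"` or `"csv"`; by default guessed from the file
#'   extension.
#' @param target_branch_id,fluid Used by `read_tree()` for the CSV format,
#'   which does not store them.
#' @return `read_tree()` returns a `vascular_tree`; `write_tree()` returns
#'   `path` invisibly.
#' @examples
#' tree <- generate_tree(tree_gen_config(4, 1, 2, random_seed = 1))
#' f <- tempfile(fileext = ".json")
#' write_tree(tree, f)
#' identical(tidy(read_tree(f)), tidy(tree))
#' @name tree-io
NULL

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) "json"
  else if (ext %in% c("csv")) "csv"
  else abort(sprintf("Cannot guess tree format from extension '.%s'; pass `format`.", ext),
             class = "emboflow_validation_error")
}

# shortest exact decimal representation of a double
fmt_dbl <- function(x) sprintf("%.17g", x)

json_str <- function(x) {
  if (is.na(x)) "null" else paste0('"', gsub('"', '\\\\"', x), '"')
}

#' @rdname tree-io
#' @export
write_tree <- function(tree, path, format = NULL) {
  stopifnot(inherits(tree, "vascular_tree"))
  format <- guess_format(path, format)
  if (format == "csv") {
    seg <- tree$segments
    # numbers formatted to 17 significant digits for an exact double
    # round-trip (read_csv re-parses them as doubles)
    readr::write_csv(tibble::tibble(child_id = seg$segment_id,
                                    parent_id = seg$parent_id,
                                    length_m = fmt_dbl(seg$length),
                                    radius_m = fmt_dbl(seg$radius)), path)
    return(invisible(path))
  }
  seg <- tree$segments
  seg_json <- vapply(seq_len(nrow(seg)), function(i) {
    paste0('    {"id": ', json_str(seg$segment_id[i]),
           ', "parent": ', json_str(seg$parent_id[i]),
           ', "length_m": ', fmt_dbl(seg$length[i]),
           ', "radius_m": ', fmt_dbl(seg$radius[i]),
           ', "label": ', json_str(seg$label[i]), "}")
  }, character(1))
  txt <- paste0(
    "{\n",
    '  "schema_version": 1,\n',
    '  "fluid": {"density": ', fmt_dbl(tree$fluid$density),
    ', "viscosity": ', fmt_dbl(tree$fluid$viscosity), "},\n",
    '  "inlet_id": ', json_str(tree$inlet_id), ",\n",
    '  "target_branch_id": ',
    json_str(tree$target_branch_id %||% NA_character_), ",\n",
    '  "segments": [\n',
    paste(seg_json, collapse = ",\n"),
    "\n  ]\n}\n"
  )
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' @rdname tree-io
#' @export
read_tree <- function(path, format = NULL, target_branch_id = NULL,
                      fluid = fluid_properties()) {
  format <- guess_format(path, format)
  if (format == "csv") {
    # numeric columns come in as text and go through as.numeric(): R's
    # strtod round-trips %.17g exactly, unlike the fast csv double parser
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            .default = readr::col_character()))
    return(vascular_tree(
      tibble::tibble(segment_id = df$child_id, parent_id = df$parent_id,
                     length = as.numeric(df$length_m),
                     radius = as.numeric(df$radius_m)),
      target_branch_id = target_branch_id, fluid = fluid))
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Malformed JSON in '%s': %s", path,
                                  conditionMessage(e)),
                          class = "emboflow_validation_error")
                  })
  for (fld in c("fluid", "segments")) {
    if (is.null(obj[[fld]])) {
      abort(sprintf("Tree file '%s' is missing field '%s'.", path, fld),
            class = "emboflow_validation_error")
    }
  }
  seg <- tibble::as_tibble(obj$segments)
  for (fld in c("id", "parent", "length_m", "radius_m")) {
    if (!fld %in% names(seg)) {
      abort(sprintf("Tree file '%s': segments lack field '%s'.", path, fld),
            class = "emboflow_validation_error")
    }
  }
  if (anyNA(seg$radius_m) || anyNA(seg$length_m)) {
    bad <- seg$id[is.na(seg$radius_m) | is.na(seg$length_m)]
    abort(sprintf("Segment(s) %s are missing radius_m/length_m.",
                  paste(bad, collapse = ", ")),
          class = "emboflow_validation_error")
  }
  tbi <- obj$target_branch_id
  if (is.null(tbi) || (length(tbi) == 1 && is.na(tbi))) tbi <- NULL
  vascular_tree(
    tibble::tibble(segment_id = seg$id, parent_id = seg$parent,
                   length = as.numeric(seg$length_m),
                   radius = as.numeric(seg$radius_m),
                   label = if ("label" %in% names(seg)) seg$label else NA_character_),
    target_branch_id = tbi,
    fluid = fluid_properties(as.numeric(obj$fluid$density),
                             as.numeric(obj$fluid$viscosity)))
}

#' Packaged calibrated reference tree
#'
#' A synthetic hepatic-arterial-like tree shipped with the package: one inlet
#' of diameter 4.62 mm, 43 outlets, a target branch at depth level 5 that
#' subdivides into 10 target outlets, and non-target peripheral radii
#' pre-calibrated (see [calibrate_stall_pressure()]) so that with a steady
#' inlet flow of 5 cm^3/s and non-target outlets at 300 Pa, the target-branch
#' flow-cessation pressure is 5000 Pa.  At the baseline condition the maximum
#' segment Reynolds number is ~417, at the inlet.
#'
#' The tree was produced once by [generate_tree()] +
#' [calibrate_stall_pressure()] and stored in `inst/extdata/`; the file is
#' byte-stable across releases.
#'
#' @return A [vascular_tree()].
#' @examples
#' glance(reference_fixture())
#' @export
reference_fixture <- function() {
  path <- system.file("extdata", "reference_tree.json", package = "emboflow",
                      mustWork = TRUE)
  read_tree(path, format = "json")
}
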