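# End-to-end driver and the published-table fixtures: classify off-axis
# positions, run the generator + LET + RBE chain over the studied
# geometries, and compute the out-of-field summary statistics.

.position_levels <- c("centre", "mid", "edge", "edge_plus_1", "edge_plus_2")

#' Classify an off-axis distance relative to the field edge
#'
#' The studied geometries sample five canonical positions per field: the
#' central axis, half-way to the edge, the edge (= half the field side), and
#' 1 cm and 2 cm beyond it. Classification uses an absolute tolerance of
#' 0.01 cm; anything else errors, naming the nearest category.
#'
#' @param field_cm Square field side(s) in cm.
#' @param offaxis_cm Off-axis distance(s) in cm.
#' @param tol_cm Absolute matching tolerance (default 0.01 cm).
#' @return Character vector over
#'   `centre, mid, edge, edge_plus_1, edge_plus_2`.
#' @examples
#' position_category(0.7, 0.35)  # "edge"
#' position_category(10, 7)      # "edge_plus_2"
#' @export
position_category <- function(field_cm, offaxis_cm, tol_cm = 0.01) {
  stopifnot(all(field_cm > 0), all(offaxis_cm >= 0))
  n <- max(length(field_cm), length(offaxis_cm))
  field_cm <- rep_len(field_cm, n)
  offaxis_cm <- rep_len(offaxis_cm, n)
  vapply(seq_len(n), function(i) {
    edge <- field_cm[i] / 2
    ref <- c(centre = 0, mid = edge / 2, edge = edge,
             edge_plus_1 = edge + 1, edge_plus_2 = edge + 2)
    d <- abs(offaxis_cm[i] - ref)
    j <- which.min(d)
    if (d[j] > tol_cm) {
      stop(sprintf(
        "off-axis %g cm for a %g cm field matches no canonical position (nearest: %s at %g cm)",
        offaxis_cm[i], field_cm[i], names(ref)[j], ref[j]), call. = FALSE)
    }
    names(ref)[j]
  }, character(1))
}

#' Canonical off-axis distance of a position category
#'
#' @param field_cm Square field side(s) in cm.
#' @param position One of the five canonical categories.
#' @return Off-axis distance in cm.
#' @export
position_offaxis <- function(field_cm, position) {
  n <- max(length(field_cm), length(position))
  field_cm <- rep_len(field_cm, n)
  position <- rep_len(position, n)
  edge <- field_cm / 2
  out <- numeric(length(position))
  for (i in seq_along(position)) {
    out[i] <- switch(position[i],
                     centre = 0, mid = edge[i] / 2, edge = edge[i],
                     edge_plus_1 = edge[i] + 1, edge_plus_2 = edge[i] + 2,
                     stop("unknown position category: ", position[i], call. = FALSE))
  }
  out
}

#' The studied geometry grid
#'
#' Nine square fields (0.7-4.5 cm sides plus the 10 cm reference), four
#' water depths (0.15, 1.35, 9.85 and 19.9 cm) and the five canonical
#' off-axis positions: 180 geometry points.
#'
#' @return Tibble with `field_cm`, `depth_cm`, `position`, `offaxis_cm`.
#' @export
study_geometries <- function() {
  g <- tidyr::expand_grid(
    field_cm = c(0.7, 0.9, 1.8, 2.2, 2.7, 3.1, 3.6, 4.5, 10),
    depth_cm = c(0.15, 1.35, 9.85, 19.9),
    position = .position_levels
  )
  g$offaxis_cm <- position_offaxis(g$field_cm, g$position)
  g
}

#' Load the packaged transcription of the published LET/RBE tables
#'
#' 180 rows: track- and dose-average restricted LET (delta = 1 keV) of the
#' total-electron and secondary-electron fluences, plus predicted RBE_M, for
#' every studied geometry. Validates the schema, the 180-row count, the
#' dose >= track ordering in every row, and attaches the position category.
#'
#' @param path Fixture CSV; `NULL` loads the packaged copy.
#' @return Tibble with one row per geometry.
#' @export
load_published_tables <- function(path = NULL) {
  path <- path %||% system.file("extdata", "published_let_tables.csv",
                                package = "penumbralet", mustWork = TRUE)
  dat <- tryCatch(
    utils::read.csv(path, comment.char = "#"),
    error = function(e) stop("cannot read published-table fixture: ",
                             conditionMessage(e), call. = FALSE))
  need <- c("field_cm", "depth_cm", "offaxis_cm", "track_tef", "track_se",
            "dose_tef", "dose_se", "rbe_m", "rbe_u")
  if (!all(need %in% names(dat))) {
    stop("published-table fixture lacks columns: ",
         paste(setdiff(need, names(dat)), collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) != 180L) {
    stop("published-table fixture must have 180 rows, found ", nrow(dat),
         call. = FALSE)
  }
  bad <- which(!(dat$dose_tef > dat$track_tef & dat$dose_se > dat$track_se &
                   dat$rbe_m > 0))
  if (length(bad)) {
    stop("fixture row invariant violated at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dat <- tibble::as_tibble(dat)
  dat$position <- position_category(dat$field_cm, dat$offaxis_cm)
  dat
}

#' Percent increase between two values
#'
#' @param centre_value Reference (must be positive).
#' @param edge2_value Comparison value.
#' @return `100 * (edge2_value - centre_value) / centre_value`.
#' @export
percent_increase <- function(centre_value, edge2_value) {
  if (any(centre_value <= 0)) stop("reference value must be positive", call. = FALSE)
  100 * (edge2_value - centre_value) / centre_value
}

#' Out-of-field summary statistics of a LET/RBE record set
#'
#' Over the 2-cm-beyond-edge records: min/max of the TEF and SE
#' dose-average LET. Per field and depth: the percent increase of the TEF
#' dose-average LET from the centre to 2 cm beyond the edge. Per depth: the
#' ratio of the maximum out-of-field RBE_M (1 and 2 cm beyond the edge) to
#' the minimum in-field RBE_M (centre, mid, edge).
#'
#' @param records Tibble shaped like [load_published_tables()] output (a
#'   `position` column is derived if absent).
#' @return List of class `"oof_summary"` with tibbles `edge2_range`,
#'   `tef_increase`, `rbe_ratio`.
#' @export
summarize_out_of_field <- function(records) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) stop("no records supplied", call. = FALSE)
  if (!"position" %in% names(records)) {
    records$position <- position_category(records$field_cm, records$offaxis_cm)
  }
  missing <- setdiff(.position_levels, unique(records$position))
  if (length(missing)) {
    stop("records lack position categories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e2 <- dplyr::filter(records, .data$position == "edge_plus_2")
  edge2_range <- tibble::tibble(
    metric = c("dose_tef", "dose_se"),
    min = c(min(e2$dose_tef), min(e2$dose_se)),
    max = c(max(e2$dose_tef), max(e2$dose_se))
  )
  tef_increase <- records |>
    dplyr::filter(.data$position %in% c("centre", "edge_plus_2")) |>
    dplyr::select("field_cm", "depth_cm", "position", "dose_tef") |>
    tidyr::pivot_wider(names_from = "position", values_from = "dose_tef") |>
    dplyr::mutate(pct_increase = percent_increase(.data$centre, .data$edge_plus_2)) |>
    dplyr::select("field_cm", "depth_cm", "pct_increase")
  rbe_ratio <- records |>
    dplyr::group_by(.data$depth_cm) |>
    dplyr::summarise(
      rbe_in_min = min(.data$rbe_m[.data$position %in% c("centre", "mid", "edge")]),
      rbe_out_max = max(.data$rbe_m[.data$position %in% c("edge_plus_1", "edge_plus_2")]),
      ratio = .data$rbe_out_max / .data$rbe_in_min,
      .groups = "drop"
    )
  structure(list(edge2_range = edge2_range, tef_increase = tef_increase,
                 rbe_ratio = rbe_ratio),
            class = "oof_summary")
}

#' @export
print.oof_summary <- function(x, ...) {
  cat("<oof_summary>\n\nDose-average LET range 2 cm beyond the edge (keV/um):\n")
  print(x$edge2_range)
  cat(sprintf("\nTEF dose-average LET increase centre -> edge+2: %.1f%% to %.1f%%\n",
              min(x$tef_increase$pct_increase), max(x$tef_increase$pct_increase)))
  cat("\nRBE_M ratio (max out-of-field / min in-field) per depth:\n")
  print(x$rbe_ratio)
  invisible(x)
}

#' Run the full synthetic pipeline over a geometry grid
#'
#' For every geometry: generate the photon spectrum and the TEF/SE
#' slowing-down fluences, compute both restricted LET moments at the cutoff,
#' and predict RBE_M from the calibration fit at the spectrum's effective
#' photon energy. Deterministic: identical inputs give identical output.
#'
#' @param geometries Tibble with `field_cm`, `depth_cm`, `offaxis_cm`
#'   (default: the full studied grid from [study_geometries()]).
#' @param beam A [photon_beam_model()].
#' @param delta_keV Delta-ray cutoff in keV.
#' @param calibration RBE calibration table (default: packaged synthetic
#'   fixture) or `NULL` to skip RBE prediction.
#' @param rbe_scale,rbe_weighted Passed to [fit_rbe_curve()].
#' @param material A [material_spec()].
#' @return Tibble with one row per geometry: the four LET columns, the
#'   effective photon energy, `rbe_m` and `rbe_u`.
#' @export
run_let_pipeline <- function(geometries = study_geometries(),
                             beam = photon_beam_model(),
                             delta_keV = 1,
                             calibration = read_rbe_calibration(),
                             rbe_scale = "log10", rbe_weighted = TRUE,
                             material = water_liquid()) {
  geometries <- tibble::as_tibble(geometries)
  if (!"offaxis_cm" %in% names(geometries) && "position" %in% names(geometries)) {
    geometries$offaxis_cm <- position_offaxis(geometries$field_cm,
                                              geometries$position)
  }
  table <- build_stopping_table(default_energy_grid(from_keV = delta_keV),
                                delta_keV, material)
  fit <- if (!is.null(calibration)) {
    fit_rbe_curve(calibration, scale = rbe_scale, weighted = rbe_weighted)
  }
  rows <- purrr::pmap(geometries[c("field_cm", "depth_cm", "offaxis_cm")],
                      function(field_cm, depth_cm, offaxis_cm) {
    case <- tryCatch(
      generate_case(geometry_point(field_cm, depth_cm, offaxis_cm), beam, table),
      error = function(e) stop(sprintf(
        "spectrum generation failed at field %g cm, depth %g cm, off-axis %g cm: %s",
        field_cm, depth_cm, offaxis_cm, conditionMessage(e)), call. = FALSE))
    out <- tibble::tibble(
      field_cm = field_cm, depth_cm = depth_cm, offaxis_cm = offaxis_cm,
      track_tef = track_average_let(case$tef, table),
      track_se = track_average_let(case$se, table),
      dose_tef = dose_average_let(case$tef, table),
      dose_se = dose_average_let(case$se, table),
      eff_photon_MeV = effective_photon_energy(case$photon)
    )
    if (!is.null(fit)) {
      pred <- predict_rbem(fit, out$eff_photon_MeV)
      out$rbe_m <- pred$rbe_m
      out$rbe_u <- pred$std_u
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  res$position <- position_category(res$field_cm, res$offaxis_cm)
  res <- attach_uncertainty(res, 0.006)
  res
}

#' Write pipeline LET results as CSV
#'
#' @param results Tibble from [run_let_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_let_results <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}
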