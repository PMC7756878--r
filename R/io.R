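#' Write a dataset bundle to CSV files
#'
#' Emits the four data streams in the packaged schemas —
#' `counts.csv` (year, habitat, count),
#' `breeding_success.csv` (year, habitat, R, B),
#' `fledglings.csv` (year, habitat, S, F) and
#' `encounters.csv` (id, sex, mark_year, mark_age, mark_habitat, and
#' per-year `event_<t>`, `x_<t>`, `y_<t>` columns; coordinates in km) —
#' plus `area.yaml` (study-area geometry) and, for simulated datasets,
#' `landscape.csv` and `truth.json` (generating values and latent
#' trajectories, without individual tracks).
#'
#' @param x a [simulate_dataset()] result or a `dataset_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(x$counts, "counts.csv")
  wr(x$breeding_success, "breeding_success.csv")
  wr(x$fledglings, "fledglings.csv")
  wr(x$encounters, "encounters.csv")
  if (!is.null(x$area)) {
    cfg <- list(area = area_to_config(x$area))
    yaml::write_yaml(cfg, file.path(dir, "area.yaml"))
  }
  if (!is.null(x$landscape)) wr(x$landscape$sites, "landscape.csv")
  if (!is.null(x$truth)) {
    tr <- x$truth
    tr$tracks <- NULL
    tr$A <- lapply(tr$A, function(a) unclass(a))
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

area_to_config <- function(area) {
  reg <- function(r) {
    if (r$kind == "rect") r$rect
    else paste0("POLYGON((", paste(apply(rbind(r$poly, r$poly[1, ]), 1,
                                          paste, collapse = " "),
                                    collapse = ", "), "))")
  }
  list(total_rect = if (area$total$kind == "rect") area$total$rect,
       core_rect = if (area$core$kind == "rect") area$core$rect,
       total_wkt = if (area$total$kind == "polygon") reg(area$total),
       core_wkt = if (area$core$kind == "polygon") reg(area$core))
}

#' Read a study-area configuration
#'
#' Accepts YAML with keys `area.total_rect` / `area.core_rect`
#' (`xmin, xmax, ymin, ymax` in km) or `area.total_wkt` / `area.core_wkt`
#' (WKT POLYGON strings).
#'
#' @param path path to the YAML file.
#' @return a [study_area] object.
#' @export
read_area_config <- function(path) {
  cfg <- yaml::read_yaml(path)$area
  if (is.null(cfg)) stop("no 'area' section in ", path)
  pick <- function(rect, wkt) {
    if (!is.null(cfg[[rect]])) unlist(cfg[[rect]]) else cfg[[wkt]]
  }
  total <- pick("total_rect", "total_wkt")
  core <- pick("core_rect", "core_wkt")
  if (is.null(total) || is.null(core)) stop("area config needs total and core regions")
  study_area(total = total, core = core)
}

#' Read and validate a dataset bundle
#'
#' Reads the four CSV streams from a directory (or a named list of
#' paths), validates every schema invariant (habitat labels, B <= R,
#' F >= S, event codes, marking events, coordinates present for
#' habitat-resolved sightings) and the shared contiguous year range, and
#' returns a bundle ready for [fit_ipm()].  Validation failures are
#' reported with the offending file, column and row numbers.
#'
#' @param dir directory containing `counts.csv`, `breeding_success.csv`,
#'   `fledglings.csv`, `encounters.csv` and optionally `area.yaml`;
#'   alternatively a named list/vector of file paths with those names.
#' @param area optional [study_area] overriding `area.yaml`.
#' @return object of class `dataset_bundle`.
#' @export
read_bundle <- function(dir, area = NULL) {
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    list(counts = file.path(dir, "counts.csv"),
         breeding_success = file.path(dir, "breeding_success.csv"),
         fledglings = file.path(dir, "fledglings.csv"),
         encounters = file.path(dir, "encounters.csv"),
         area = file.path(dir, "area.yaml"))
  } else as.list(dir)
  for (k in c("counts", "breeding_success", "fledglings", "encounters")) {
    if (is.null(paths[[k]]) || !file.exists(paths[[k]])) {
      stop("missing input file for stream '", k, "'")
    }
  }
  counts <- read.csv(paths$counts, stringsAsFactors = FALSE)
  bs <- read.csv(paths$breeding_success, stringsAsFactors = FALSE)
  fl <- read.csv(paths$fledglings, stringsAsFactors = FALSE)
  enc <- read.csv(paths$encounters, stringsAsFactors = FALSE)
  if (is.null(area) && !is.null(paths$area) && file.exists(paths$area)) {
    area <- read_area_config(paths$area)
  }
  errs <- character(0)
  add <- function(file, rows, msg) {
    if (length(rows)) {
      errs <<- c(errs, sprintf("%s rows %s: %s", file,
                               paste(utils::head(rows, 5), collapse = ","), msg))
    }
  }
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(file, ": missing columns ", paste(miss, collapse = ", "))
  }
  need(counts, c("year", "habitat", "count"), "counts.csv")
  need(bs, c("year", "habitat", "R", "B"), "breeding_success.csv")
  need(fl, c("year", "habitat", "S", "F"), "fledglings.csv")
  need(enc, c("id", "sex", "mark_year", "mark_age", "mark_habitat"), "encounters.csv")
  for (s in list(list(counts, "counts.csv"), list(bs, "breeding_success.csv"),
                 list(fl, "fledglings.csv"))) {
    add(s[[2]], which(!s[[1]]$habitat %in% HABITATS), "habitat must be Short or Tall")
  }
  add("counts.csv", which(counts$count < 0), "count must be >= 0")
  add("breeding_success.csv", which(bs$B > bs$R | bs$B < 0 | bs$R < 0),
      "binomial invariant 0 <= B <= R violated")
  add("fledglings.csv", which(fl$F < fl$S | fl$S < 0),
      "total fledglings F must be at least the number of successful sites S")
  years <- sort(unique(counts$year))
  if (length(years) < 2L || !all(diff(years) == 1L)) {
    errs <- c(errs, "counts.csv: years must form a contiguous range of length >= 2")
  }
  for (s in list(list(bs, "breeding_success.csv"), list(fl, "fledglings.csv"))) {
    if (!setequal(unique(s[[1]]$year), years)) {
      errs <- c(errs, paste0(s[[2]], ": year range must match counts.csv"))
    }
  }
  ## encounters: detect per-year columns by the year labels
  ev_cols <- paste0("event_", years)
  if (!all(ev_cols %in% names(enc))) {
    stop("encounters.csv: need event_<year> columns for every count year")
  }
  add("encounters.csv", which(!enc$mark_age %in% c("fledgling", "breeder")),
      "mark_age must be fledgling or breeder")
  add("encounters.csv", which(!enc$mark_habitat %in% HABITATS),
      "mark_habitat must be Short or Tall")
  add("encounters.csv", which(!enc$mark_year %in% years),
      "mark_year outside the count year range")
  for (k in seq_along(years)) {
    yv <- enc[[ev_cols[k]]]
    add("encounters.csv", which(!yv %in% 1:4),
        sprintf("event_%s codes must be in 1..4", years[k]))
    xc <- enc[[paste0("x_", years[k])]]; yc <- enc[[paste0("y_", years[k])]]
    if (is.null(xc)) xc <- rep(NA_real_, nrow(enc))
    if (is.null(yc)) yc <- rep(NA_real_, nrow(enc))
    add("encounters.csv",
        which(yv %in% 1:2 & (is.na(xc) | is.na(yc)) & enc$mark_year <= years[k]),
        sprintf("habitat-resolved sighting (event %s) requires x,y coordinates", years[k]))
  }
  mark_idx <- match(enc$mark_year, years)
  ok <- !is.na(mark_idx)
  mev <- rep(NA_integer_, nrow(enc))
  mev[ok] <- vapply(which(ok), function(i) enc[[ev_cols[mark_idx[i]]]][i], numeric(1))
  add("encounters.csv", which(ok & !mev %in% 1:2),
      "event at first capture must be a habitat-resolved seen code (1 or 2)")
  if (length(errs)) {
    stop("dataset validation failed:\n  ", paste(errs, collapse = "\n  "))
  }
  ## rename per-year columns to internal 1..T indexing
  T_ <- length(years)
  for (k in seq_len(T_)) {
    names(enc)[names(enc) == paste0("event_", years[k])] <- paste0("event_", k)
    names(enc)[names(enc) == paste0("x_", years[k])] <- paste0("x_", k)
    names(enc)[names(enc) == paste0("y_", years[k])] <- paste0("y_", k)
  }
  for (k in seq_len(T_)) {  # ensure coordinate columns exist
    for (p in c("x_", "y_")) {
      if (is.null(enc[[paste0(p, k)]])) enc[[paste0(p, k)]] <- NA_real_
    }
  }
  structure(list(counts = counts, breeding_success = bs, fledglings = fl,
                 encounters = enc, area = area, years = years),
            class = "dataset_bundle")
}
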