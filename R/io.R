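#' Read and write single gridded layers as ESRI ASCII grids
#'
#' Plain-text ESRI ASCII raster format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of
#' values). Grid row 1 (the shoreline) is written as the first (top)
#' raster line.
#'
#' @param grid A `depth_grid` (for `write_ascii_grid`, supplies layout).
#' @param values Optional vector of cell values aligned with `grid`
#'   rows; defaults to the grid's `depth` column.
#' @param path File path.
#' @param nodata NODATA sentinel written for missing values.
#' @return `read_ascii_grid()` returns a `depth_grid` built from the
#'   raster (values interpreted as depth); `write_ascii_grid()` returns
#'   `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path, values = NULL, nodata = -9999) {
  values <- values %||% grid$depth
  m <- matrix(nodata, attr(grid, "n_rows"), attr(grid, "n_cols"))
  m[cbind(grid$row, grid$col)] <- values
  m[is.na(m)] <- nodata
  header <- c(
    paste("ncols", attr(grid, "n_cols")),
    paste("nrows", attr(grid, "n_rows")),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", attr(grid, "cell_size")),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param max_depth_in_scope Scope limit passed to [as_depth_grid()].
#' @export
read_ascii_grid <- function(path, max_depth_in_scope = 12) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  m <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(m) == header$nrows, ncol(m) == header$ncols)
  nodata <- header$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  as_depth_grid(m, cell_size = header$cellsize %||% 100,
                max_depth_in_scope = max_depth_in_scope)
}

#' Read and write year-stacked scenario fields as CSV
#'
#' Long-format plain CSV with columns `row`, `col`, `year` and the field
#' columns (`secchi`, or `hm0` and `tm02`).
#'
#' @param fields A per-year field tibble.
#' @param path File path.
#' @return `read_scenario_fields()` returns a tibble;
#'   `write_scenario_fields()` returns `path` invisibly.
#' @export
write_scenario_fields <- function(fields, path) {
  utils::write.csv(as.data.frame(fields), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario_fields
#' @export
read_scenario_fields <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("row", "col", "year") %in% names(df)))
  df
}

#' Serialize a fitted occurrence model to JSON
#'
#' Writes a self-describing JSON document holding the model's basis
#' descriptions (spline knots and constraint transforms), coefficients,
#' coefficient covariance and training metadata. [read_sdm()] restores an
#' `eelgrass_sdm` whose predictions and response curves reproduce the
#' original exactly; the restored object evaluates its spline bases
#' directly from the stored knots (it does not need the original fitting
#' data).
#'
#' @param model An `eelgrass_sdm`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sdm <- function(model, path) {
  fit <- model$fit
  payload <- list(
    type = "eelgrass_sdm",
    version = 1L,
    predictors = model$predictors,
    df = model$df,
    link = "logit",
    coefficients = as.numeric(stats::coef(fit)),
    coefficient_names = names(stats::coef(fit)),
    covariance = unclass(fit$Vp),
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    prevalence = model$prevalence,
    n = model$n,
    training_ranges = model$training_ranges,
    smooths = jsonlite::serializeJSON(fit$smooth, digits = NA)
  )
  writeLines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
    path
  )
  invisible(path)
}

#' @rdname write_sdm
#' @export
read_sdm <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (!identical(payload$type, "eelgrass_sdm")) {
    abort("Not a serialized occurrence model.")
  }
  smooths <- jsonlite::unserializeJSON(payload$smooths)
  # jsonlite deserializes the literal string "NA" (mgcv's no-by marker)
  # as NA_character_; restore the marker
  smooths <- lapply(smooths, function(sm) {
    if (length(sm$by) == 1 && is.na(sm$by)) sm$by <- "NA"
    sm
  })
  fit <- structure(
    list(
      smooth = smooths,
      coefficients = rlang::set_names(payload$coefficients,
                                      payload$coefficient_names),
      Vp = payload$covariance,
      deviance = payload$deviance,
      null.deviance = payload$null_deviance
    ),
    class = "eelgrass_sdm_fit"
  )
  structure(
    list(
      fit = fit,
      predictors = payload$predictors,
      df = payload$df,
      training_ranges = purrr::map(payload$training_ranges, as.numeric),
      prevalence = payload$prevalence,
      n = payload$n,
      truth = NULL,
      data = NULL
    ),
    class = "eelgrass_sdm"
  )
}

# Design matrix of a restored model at new data.
sdm_fit_design <- function(object, newdata) {
  blocks <- lapply(object$smooth, function(sm) {
    mgcv::PredictMat(sm, as.data.frame(newdata))
  })
  cbind(1, do.call(cbind, blocks))
}

#' @export
predict.eelgrass_sdm_fit <- function(object, newdata, type = "response",
                                     se.fit = FALSE, ...) {
  x <- sdm_fit_design(object, newdata)
  eta <- as.numeric(x %*% object$coefficients)
  if (type == "terms") {
    fits <- ses <- matrix(NA_real_, nrow(x), length(object$smooth))
    labels <- character(length(object$smooth))
    for (i in seq_along(object$smooth)) {
      sm <- object$smooth[[i]]
      idx <- sm$first.para:sm$last.para
      xi <- x[, idx, drop = FALSE]
      fits[, i] <- xi %*% object$coefficients[idx]
      ses[, i] <- sqrt(rowSums((xi %*% object$Vp[idx, idx]) * xi))
      labels[i] <- sm$label
    }
    colnames(fits) <- colnames(ses) <- labels
    if (se.fit) return(list(fit = fits, se.fit = ses))
    return(fits)
  }
  if (type == "link") return(eta)
  plogis(eta)
}
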