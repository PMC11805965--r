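#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Canonical column sets per schema, with accepted header synonyms.
# Receiver exports differ between vendors; synonyms cover the common dialects.
.schemas <- list(
  detections = list(
    cols = c(tag_id = "character", receiver_id = "character",
             timestamp = "POSIXct", depth_m = "numeric"),
    required = c("tag_id", "receiver_id", "timestamp"),
    synonyms = list(
      tag_id      = c("tag_id", "tag", "transmitter", "transmitter_id", "id"),
      receiver_id = c("receiver_id", "receiver", "station", "receiver_sn"),
      timestamp   = c("timestamp", "datetime", "date_time", "detection_time",
                      "date_and_time_utc", "time"),
      depth_m     = c("depth_m", "depth", "sensor_depth", "sensor_value")
    )
  ),
  receivers = list(
    cols = c(receiver_id = "character", x_m = "numeric", y_m = "numeric",
             deploy_date = "Date", recover_date = "Date",
             station_name = "character", array_label = "character",
             habitat_label = "character"),
    required = c("receiver_id", "x_m", "y_m", "deploy_date", "recover_date"),
    synonyms = list(
      receiver_id   = c("receiver_id", "receiver", "receiver_sn"),
      x_m           = c("x_m", "x", "easting"),
      y_m           = c("y_m", "y", "northing"),
      deploy_date   = c("deploy_date", "deployed", "deployment_date"),
      recover_date  = c("recover_date", "recovered", "recovery_date"),
      station_name  = c("station_name", "station"),
      array_label   = c("array_label", "array"),
      habitat_label = c("habitat_label", "habitat")
    )
  ),
  positions = list(
    cols = c(tag_id = "character", timestamp = "POSIXct", x_m = "numeric",
             y_m = "numeric", hpe = "numeric", known_x_m = "numeric",
             known_y_m = "numeric", depth_m = "numeric"),
    required = c("tag_id", "timestamp", "x_m", "y_m", "hpe"),
    synonyms = list(
      tag_id    = c("tag_id", "tag", "transmitter", "transmitter_id"),
      timestamp = c("timestamp", "datetime", "date_time", "time"),
      x_m       = c("x_m", "x", "easting"),
      y_m       = c("y_m", "y", "northing"),
      hpe       = c("hpe", "hpe_unitless"),
      known_x_m = c("known_x_m", "true_x", "ref_x"),
      known_y_m = c("known_y_m", "true_y", "ref_y"),
      depth_m   = c("depth_m", "depth", "sensor_depth")
    )
  ),
  environment = list(
    cols = c(date = "Date", atm_pressure_mbar = "numeric",
             bottom_temp_C = "numeric", tilt_deg = "numeric"),
    required = c("date", "atm_pressure_mbar"),
    synonyms = list(
      date = c("date", "day"),
      atm_pressure_mbar = c("atm_pressure_mbar", "pressure", "atm_pressure",
                            "pressure_mbar"),
      bottom_temp_C = c("bottom_temp_c", "bottom_temp", "temperature",
                        "temp_c"),
      tilt_deg = c("tilt_deg", "tilt")
    )
  ),
  relocations = list(
    cols = c(tag_id = "character", timestamp = "POSIXct", x_m = "numeric",
             y_m = "numeric", lon = "numeric", lat = "numeric",
             source = "character", alive = "logical"),
    required = c("tag_id", "timestamp", "source", "alive"),
    synonyms = list(
      tag_id = c("tag_id", "tag", "transmitter"),
      timestamp = c("timestamp", "datetime", "date_time", "time"),
      x_m = c("x_m", "x"), y_m = c("y_m", "y"),
      lon = c("lon", "longitude"), lat = c("lat", "latitude"),
      source = c("source", "relocation_source"),
      alive = c("alive", "is_alive")
    )
  )
)

.ts_format <- "%Y-%m-%dT%H:%M:%SZ"

#' Read a telemetry table with schema validation
#'
#' Reads a CSV file into one of the package's canonical telemetry schemas
#' (`"detections"`, `"receivers"`, `"positions"`, `"environment"`,
#' `"relocations"`), resolving common header synonyms, parsing ISO-8601 UTC
#' timestamps, and dropping exact duplicate rows (for detections, duplicate
#' `(tag_id, receiver_id, timestamp)` triplets) with a warning that reports
#' the count.
#'
#' @param path Path to a CSV file.
#' @param schema_name One of `"detections"`, `"receivers"`, `"positions"`,
#'   `"environment"`, `"relocations"`.
#' @return A tibble with the schema's canonical column names and types,
#'   detection/position rows sorted by tag and time.
#' @export
read_table <- function(path, schema_name) {
  schema <- .schemas[[schema_name]]
  if (is.null(schema)) {
    abort(paste0("unknown schema '", schema_name, "'; expected one of: ",
                 paste(names(.schemas), collapse = ", ")))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))

  out <- list()
  for (col in names(schema$cols)) {
    hit <- intersect(schema$synonyms[[col]], names(raw))
    if (length(hit) == 0) {
      if (col %in% schema$required) {
        abort(paste0("schema '", schema_name, "' requires column '", col,
                     "' (accepted names: ",
                     paste(schema$synonyms[[col]], collapse = ", "), ")"))
      }
      next
    }
    out[[col]] <- raw[[hit[1]]]
  }
  extra <- setdiff(names(raw), tolower(unlist(lapply(schema$synonyms, identity))))
  if (length(extra) > 0) {
    abort(paste0("unknown column(s) for schema '", schema_name, "': ",
                 paste(extra, collapse = ", "), "; accepted names: ",
                 paste(unlist(schema$synonyms), collapse = ", ")))
  }
  tbl <- as_tibble(out)

  for (col in names(tbl)) {
    type <- schema$cols[[col]]
    if (type == "POSIXct") {
      tbl[[col]] <- .parse_timestamp(tbl[[col]], path)
    } else if (type == "Date") {
      tbl[[col]] <- as.Date(tbl[[col]])
    } else if (type == "numeric") {
      tbl[[col]] <- as.numeric(tbl[[col]])
    } else if (type == "logical") {
      tbl[[col]] <- as.logical(tbl[[col]])
    } else {
      tbl[[col]] <- as.character(tbl[[col]])
    }
  }

  key <- switch(schema_name,
    detections = c("tag_id", "receiver_id", "timestamp"),
    NULL)
  n0 <- nrow(tbl)
  tbl <- if (is.null(key)) distinct(tbl) else distinct(tbl, across(all_of(key)), .keep_all = TRUE)
  if (nrow(tbl) < n0) {
    warn(paste0("dropped ", n0 - nrow(tbl), " duplicate row(s) from ", path))
  }
  if (schema_name %in% c("detections", "positions")) {
    tbl <- arrange(tbl, .data$tag_id, .data$timestamp)
  }
  validate_table(tbl, schema_name)
}

.parse_timestamp <- function(x, path = "<input>") {
  x_chr <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  parsed <- as.POSIXct(rep(NA_real_, length(x_chr)), tz = "UTC",
                       origin = "1970-01-01")
  for (f in fmts) {
    miss <- is.na(parsed)
    if (!any(miss)) break
    parsed[miss] <- as.POSIXct(strptime(x_chr[miss], f, tz = "UTC"))
  }
  bad <- which(is.na(parsed) & !is.na(x_chr) & nzchar(x_chr))
  if (length(bad) > 0) {
    abort(paste0("unparseable timestamp '", x_chr[bad[1]], "' at data line ",
                 bad[1], " of ", path))
  }
  parsed
}

#' Validate a telemetry table against its schema invariants
#'
#' @param tbl A tibble as produced by [read_table()].
#' @param schema_name Schema name (see [read_table()]).
#' @return The table, invisibly unchanged, or an error.
#' @export
validate_table <- function(tbl, schema_name) {
  if (schema_name == "receivers") {
    if (any(!is.finite(tbl$x_m)) || any(!is.finite(tbl$y_m))) {
      abort("receiver coordinates must be finite")
    }
    if (any(tbl$deploy_date >= tbl$recover_date)) {
      abort("deploy_date must precede recover_date for every receiver")
    }
  }
  if (schema_name == "positions" && any(tbl$hpe < 0, na.rm = TRUE)) {
    abort("hpe must be non-negative")
  }
  if (schema_name == "detections" && "depth_m" %in% names(tbl) &&
      any(tbl$depth_m < 0, na.rm = TRUE)) {
    abort("depth_m must be non-negative")
  }
  if (schema_name == "environment" && anyDuplicated(tbl$date) > 0) {
    abort("environment table must have one row per date")
  }
  tbl
}

#' Write a telemetry table as canonical CSV
#'
#' Timestamps are serialized as ISO-8601 UTC (`YYYY-MM-DDTHH:MM:SSZ`) so a
#' read/write roundtrip is lossless to the second.
#'
#' @param tbl A tibble in one of the canonical schemas.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  out <- tbl
  for (col in names(out)) {
    if (inherits(out[[col]], "POSIXct")) {
      out[[col]] <- format(out[[col]], .ts_format, tz = "UTC")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write a habitat map as GeoJSON
#'
#' Habitat polygons travel as a GeoJSON FeatureCollection of Polygon
#' features with a `habitat_label` property; sand is the complement of the
#' named polygons and is not stored.
#'
#' @param path Path to a `.geojson` file.
#' @return A `habitat_map` tibble with `habitat_label` and a `polygon`
#'   list-column of closed (x, y) rings.
#' @export
read_habitat_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("expected a GeoJSON FeatureCollection")
  }
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      abort("habitat features must be Polygon geometries")
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) {
      c(x = as.numeric(pt[[1]]), y = as.numeric(pt[[2]]))
    }))
    tibble(habitat_label = f$properties$habitat_label %||% NA_character_,
           polygon = list(m))
  })
  structure(bind_rows(rows),
            class = c("habitat_map", "tbl_df", "tbl", "data.frame"))
}

#' @rdname read_habitat_geojson
#' @param habitat_map A `habitat_map` tibble.
#' @export
write_habitat_geojson <- function(habitat_map, path) {
  features <- lapply(seq_len(nrow(habitat_map)), function(i) {
    pg <- habitat_map$polygon[[i]]
    if (any(pg[1, ] != pg[nrow(pg), ])) pg <- rbind(pg, pg[1, ])  # close ring
    list(type = "Feature",
         properties = list(habitat_label = habitat_map$habitat_label[i]),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(pg)), function(j) {
             as.numeric(pg[j, ])
           }))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a plain-text key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible, `true`/`false` as logical.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("malformed config line: '", ln, "'"))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", format(config[[k]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
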