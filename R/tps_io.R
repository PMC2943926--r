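#' Construct a specimen record
#'
#' One digitized specimen: optional fixed landmarks, one or more outline
#' curves, and metadata. This is the unit the TPS digitizing format stores.
#'
#' @param specimen_id Specimen identifier (the TPS `ID=` field).
#' @param genus,species Taxonomic labels; may be `NA` for raw digitizing
#'   files and attached later from a labels table.
#' @param status `"extant"`, `"fossil"`, or `NA`.
#' @param landmarks Optional [configuration()] of fixed landmarks.
#' @param curves List of [polyline()] outline curves.
#' @param scale Optional positive scale factor (units per pixel). When a
#'   record comes from [read_tps()] the stored coordinates already have the
#'   scale applied and `scale_applied` is `TRUE`.
#' @param image_name Optional source image name (`IMAGE=`).
#' @param scale_applied Logical; have coordinates been multiplied by `scale`?
#' @param extra Named character vector of unrecognized `KEY=value` lines,
#'   preserved opaquely.
#' @return Object of class `"specimen_record"`.
#' @export
specimen_record <- function(specimen_id, genus = NA_character_,
                            species = NA_character_, status = NA_character_,
                            landmarks = NULL, curves = list(),
                            scale = NA_real_, image_name = NA_character_,
                            scale_applied = FALSE, extra = character()) {
  if (is.null(landmarks) && length(curves) == 0L) {
    stop("a specimen record needs landmarks or at least one curve")
  }
  if (!is.na(scale) && scale <= 0) stop("scale must be positive")
  if (!is.na(status) && !status %in% c("extant", "fossil")) {
    stop("status must be 'extant' or 'fossil'")
  }
  structure(list(specimen_id = as.character(specimen_id),
                 genus = as.character(genus), species = as.character(species),
                 status = as.character(status), landmarks = landmarks,
                 curves = curves, scale = as.numeric(scale),
                 image_name = as.character(image_name),
                 scale_applied = isTRUE(scale_applied), extra = extra),
            class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("<specimen '%s' (%s %s, %s): %d landmarks, %d curve(s)>\n",
              x$specimen_id, x$genus, x$species, x$status,
              if (is.null(x$landmarks)) 0L else nrow(x$landmarks$points),
              length(x$curves)))
  invisible(x)
}

tps_key <- function(line) {
  m <- regmatches(line, regexec("^([A-Za-z]+)=(.*)$", line))[[1L]]
  if (length(m) == 0L) NULL else list(key = toupper(m[2L]), value = m[3L])
}

parse_xy <- function(line, lineno) {
  parts <- strsplit(trimws(line), "[[:space:],]+")[[1L]]
  xy <- suppressWarnings(as.numeric(parts))
  if (length(xy) != 2L || anyNA(xy)) {
    stop(sprintf("line %d: expected two numeric coordinates, got '%s'",
                 lineno, line))
  }
  xy
}

#' Read a TPS digitizing file
#'
#' Parses the plain-text format written by the tps digitizing tools:
#' records delimited by `LM=` headers, each holding `k` landmark lines,
#' optionally `CURVES=`/`POINTS=` outline blocks, and `ID=`, `IMAGE=`,
#' `SCALE=` metadata. Keys are matched case-insensitively and CRLF line
#' endings are tolerated; unrecognized `KEY=value` lines are preserved in
#' the record's `extra` field. When `SCALE=` is present all coordinates of
#' that record are multiplied by it at read time (so centroid sizes carry
#' physical units) and the record's `scale_applied` flag is set.
#'
#' Outline curves are stored as closed polylines when `closed = TRUE`
#' (pronotum outlines are closed; the digitized trace is taken as one full
#' circuit with no repeated endpoint).
#'
#' @param path Path to a TPS file.
#' @param closed Treat curves as closed outlines? Default `TRUE`.
#' @param negate_y Negate y coordinates (for image-origin data whose y axis
#'   points down)? Default `FALSE`.
#' @return List of [specimen_record()].
#' @export
read_tps <- function(path, closed = TRUE, negate_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  records <- list()
  i <- 1L
  n <- length(lines)
  take_points <- function(m, start) {
    if (start + m - 1L > n) {
      stop(sprintf("line %d: expected %d coordinate lines, file ends early",
                   start, m))
    }
    pts <- matrix(0, m, 2L)
    for (j in seq_len(m)) pts[j, ] <- parse_xy(lines[start + j - 1L], start + j - 1L)
    pts
  }
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    kv <- tps_key(lines[i])
    if (is.null(kv) || kv$key != "LM") {
      stop(sprintf("line %d: expected LM= record header, got '%s'", i, lines[i]))
    }
    k <- suppressWarnings(as.integer(kv$value))
    if (is.na(k) || k < 0L) stop(sprintf("line %d: malformed LM= count", i))
    i <- i + 1L
    lm_pts <- NULL
    if (k > 0L) { lm_pts <- take_points(k, i); i <- i + k }
    curves_raw <- list()
    id <- NA_character_; image <- NA_character_; scale <- NA_real_
    extra <- character()
    while (i <= n) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      kv <- tps_key(lines[i])
      if (is.null(kv)) {
        stop(sprintf("line %d: expected KEY=value, got '%s'", i, lines[i]))
      }
      if (kv$key == "LM") break
      if (kv$key == "CURVES") {
        ncurv <- suppressWarnings(as.integer(kv$value))
        if (is.na(ncurv) || ncurv < 0L) {
          stop(sprintf("line %d: malformed CURVES= count", i))
        }
        i <- i + 1L
        for (ci in seq_len(ncurv)) {
          kv2 <- if (i <= n) tps_key(lines[i]) else NULL
          if (is.null(kv2) || kv2$key != "POINTS") {
            stop(sprintf("line %d: expected POINTS= header for curve %d", i, ci))
          }
          m <- suppressWarnings(as.integer(kv2$value))
          if (is.na(m) || m < 2L) {
            stop(sprintf("line %d: malformed POINTS= count", i))
          }
          i <- i + 1L
          curves_raw[[ci]] <- take_points(m, i)
          i <- i + m
        }
      } else if (kv$key == "ID") { id <- kv$value; i <- i + 1L
      } else if (kv$key == "IMAGE") { image <- kv$value; i <- i + 1L
      } else if (kv$key == "SCALE") {
        scale <- suppressWarnings(as.numeric(kv$value))
        if (is.na(scale) || scale <= 0) {
          stop(sprintf("line %d: malformed SCALE= value", i))
        }
        i <- i + 1L
      } else { extra[kv$key] <- kv$value; i <- i + 1L }
    }
    fix <- function(p) {
      if (!is.na(scale)) p <- p * scale
      if (negate_y) p[, 2L] <- -p[, 2L]
      p
    }
    lm_cfg <- if (!is.null(lm_pts)) configuration(fix(lm_pts), specimen_id = id)
    curves <- lapply(curves_raw, function(p) polyline(fix(p), closed = closed))
    records[[length(records) + 1L]] <-
      specimen_record(specimen_id = id, landmarks = lm_cfg, curves = curves,
                      scale = scale, image_name = image,
                      scale_applied = !is.na(scale), extra = extra)
  }
  records
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write specimen records to a TPS file
#'
#' Emits a file re-readable by [read_tps()] with value-identical coordinates
#' (written at full double precision). Coordinates are written exactly as
#' stored; a `SCALE=` line is never emitted, because records produced by
#' [read_tps()] already have the scale baked into their coordinates.
#'
#' @param records List of [specimen_record()]; may be empty.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(records, path) {
  out <- character()
  for (rec in records) {
    k <- if (is.null(rec$landmarks)) 0L else nrow(rec$landmarks$points)
    out <- c(out, sprintf("LM=%d", k))
    if (k > 0L) {
      p <- rec$landmarks$points
      out <- c(out, paste(fmt_num(p[, 1L]), fmt_num(p[, 2L])))
    }
    if (length(rec$curves) > 0L) {
      out <- c(out, sprintf("CURVES=%d", length(rec$curves)))
      for (cv in rec$curves) {
        v <- cv$vertices
        out <- c(out, sprintf("POINTS=%d", nrow(v)),
                 paste(fmt_num(v[, 1L]), fmt_num(v[, 2L])))
      }
    }
    if (!is.na(rec$image_name)) out <- c(out, paste0("IMAGE=", rec$image_name))
    if (!is.na(rec$specimen_id)) out <- c(out, paste0("ID=", rec$specimen_id))
    for (key in names(rec$extra)) out <- c(out, paste0(key, "=", rec$extra[[key]]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Attach taxonomic labels to specimen records
#'
#' TPS files carry no taxonomy; labels travel in a companion table with
#' columns `specimen_id`, `genus`, `species`, `status`.
#'
#' @param records List of [specimen_record()].
#' @param labels Data frame with the four columns above.
#' @return The records with genus/species/status filled in.
#' @export
attach_labels <- function(records, labels) {
  stopifnot(all(c("specimen_id", "genus", "species", "status") %in%
                names(labels)))
  idx <- match(vapply(records, `[[`, "", "specimen_id"), labels$specimen_id)
  if (anyNA(idx)) stop("labels missing for specimen(s): ",
                       paste(vapply(records[is.na(idx)], `[[`, "",
                                    "specimen_id"), collapse = ", "))
  for (j in seq_along(records)) {
    records[[j]]$genus <- as.character(labels$genus[idx[j]])
    records[[j]]$species <- as.character(labels$species[idx[j]])
    records[[j]]$status <- as.character(labels$status[idx[j]])
  }
  records
}

#' Write a distance matrix as labelled square CSV
#' @param distmat A [distance_matrix()] result or labelled square matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_csv <- function(distmat, path) {
  m <- as.matrix(distmat)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a labelled square distance matrix from CSV
#' @param path CSV path as written by [write_distance_csv()].
#' @return Square symmetric matrix with dimnames.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("distance CSV is not square")
  m
}

#' Write relative-warp (or other axis) scores as CSV
#' @param scores Matrix of scores, rows labelled by specimen/genus.
#' @param path Output path.
#' @param prefix Column-name prefix, default `"RW"`.
#' @return Invisibly, `path`.
#' @export
write_scores_csv <- function(scores, path, prefix = "RW") {
  df <- as.data.frame(scores)
  names(df) <- paste0(prefix, seq_len(ncol(df)))
  df <- cbind(specimen_id = rownames(scores), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
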