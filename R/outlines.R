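#' Closed 2D artefact outline
#'
#' Stores the ordered vertices of one digitized artefact outline together
#' with its identifiers and (optional) site metadata. The polygon is closed
#' implicitly: the first vertex is not repeated at the end.
#'
#' @param coords two-column numeric matrix of x,y vertices (>= 3 rows).
#' @param artefact_id artefact identifier.
#' @param site_id,nac_id,time_slice,lat,lon optional metadata.
#' @return An object of class `outline`.
#' @export
outline <- function(coords, artefact_id, site_id = NA_character_,
                    nac_id = NA_character_, time_slice = NA_character_,
                    lat = NA_real_, lon = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns", call. = FALSE)
  if (nrow(coords) < 3L) {
    stop("outline needs at least 3 vertices: ", artefact_id, call. = FALSE)
  }
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords))) stop("non-finite vertex", call. = FALSE)
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, artefact_id = as.character(artefact_id),
                 site_id = site_id, nac_id = nac_id,
                 time_slice = time_slice, lat = lat, lon = lon),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("outline '%s': %d vertices (nac %s, slice %s)\n",
              x$artefact_id, nrow(x$coords), x$nac_id, x$time_slice))
  invisible(x)
}

#' Collection of artefact outlines
#'
#' @param outlines list of [outline()] objects with unique artefact ids.
#' @return Object of class `outline_set`; `meta(x)` via `outline_meta()`
#'   tabulates the per-artefact metadata.
#' @export
outline_set <- function(outlines) {
  stopifnot(is.list(outlines), length(outlines) > 0L)
  ok <- vapply(outlines, inherits, logical(1), "outline")
  if (!all(ok)) stop("all elements must be outlines", call. = FALSE)
  ids <- vapply(outlines, function(o) o$artefact_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate artefact ids", call. = FALSE)
  names(outlines) <- ids
  structure(outlines, class = "outline_set")
}

#' @export
print.outline_set <- function(x, ...) {
  cat(sprintf("outline_set: %d outlines\n", length(x)))
  invisible(x)
}

#' @export
`[.outline_set` <- function(x, i) outline_set(unclass(x)[i])

#' Per-artefact metadata of an outline set
#' @param x an [outline_set()].
#' @return Data frame with one row per outline.
#' @export
outline_meta <- function(x) {
  stopifnot(inherits(x, "outline_set"))
  data.frame(
    artefact_id = vapply(x, function(o) o$artefact_id, character(1)),
    site_id     = vapply(x, function(o) as.character(o$site_id), character(1)),
    nac_id      = vapply(x, function(o) as.character(o$nac_id), character(1)),
    time_slice  = vapply(x, function(o) as.character(o$time_slice), character(1)),
    lat         = vapply(x, function(o) as.numeric(o$lat), numeric(1)),
    lon         = vapply(x, function(o) as.numeric(o$lon), numeric(1)),
    n_vertices  = vapply(x, function(o) nrow(o$coords), integer(1)),
    row.names   = NULL, stringsAsFactors = FALSE
  )
}

#' Read outlines from TPS or long-format CSV
#'
#' TPS files are sequences of `LM=n` blocks, each followed by `n` `x y`
#' coordinate lines and an optional `ID=` line naming the artefact. The CSV
#' format is long: columns `artefact_id,vertex_index,x,y`. A sidecar metadata
#' table (data frame or CSV path) keyed by `artefact_id` may supply
#' `site_id`, `nac_id`, `time_slice`, `lat`, `lon`; artefacts without a
#' metadata row trigger a warning listing the unmatched ids.
#'
#' @param path file path.
#' @param format `"tps"` or `"csv"`.
#' @param metadata optional sidecar data frame or CSV path.
#' @return An [outline_set()].
#' @export
read_outlines <- function(path, format = c("tps", "csv"), metadata = NULL) {
  format <- match.arg(format)
  if (format == "tps") {
    outs <- .read_tps(path)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("artefact_id", "vertex_index", "x", "y")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("outline CSV lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    df <- df[order(match(df$artefact_id, unique(df$artefact_id)),
                   df$vertex_index), ]
    outs <- lapply(split(df, factor(df$artefact_id,
                                    levels = unique(df$artefact_id))),
                   function(d) outline(cbind(d$x, d$y), d$artefact_id[1]))
  }
  set <- outline_set(unname(outs))
  if (!is.null(metadata)) set <- .join_outline_metadata(set, metadata)
  set
}

.read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  outs <- list(); i <- 1L; block <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i])) {
      stop("expected LM= line at TPS line ", i, call. = FALSE)
    }
    n <- as.integer(sub("^LM=", "", lines[i]))
    block <- block + 1L
    if (is.na(n) || n < 3L) {
      stop("TPS block ", block, " has fewer than 3 points", call. = FALSE)
    }
    if (i + n > length(lines)) {
      stop("truncated TPS block ", block, call. = FALSE)
    }
    xy <- do.call(rbind, lapply(lines[(i + 1L):(i + n)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]][1:2])
    }))
    i <- i + n + 1L
    id <- paste0("outline_", block)
    if (i <= length(lines) && grepl("^ID=", lines[i])) {
      id <- sub("^ID=", "", lines[i]); i <- i + 1L
    }
    outs[[length(outs) + 1L]] <- outline(xy, id)
  }
  outs
}

.join_outline_metadata <- function(set, metadata) {
  if (is.character(metadata)) {
    metadata <- utils::read.csv(metadata, check.names = FALSE)
  }
  if (!"artefact_id" %in% names(metadata)) {
    stop("metadata lacks artefact_id column", call. = FALSE)
  }
  idx <- match(names(set), as.character(metadata$artefact_id))
  unmatched <- names(set)[is.na(idx)]
  if (length(unmatched)) {
    warning("no metadata for artefact(s): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  fields <- intersect(c("site_id", "nac_id", "time_slice", "lat", "lon"),
                      names(metadata))
  out <- lapply(seq_along(set), function(k) {
    o <- set[[k]]
    if (!is.na(idx[k])) {
      for (f in fields) o[[f]] <- metadata[[f]][idx[k]]
    }
    o
  })
  outline_set(out)
}

#' Write outlines to TPS or long-format CSV
#'
#' @param x an [outline_set()].
#' @param path output path.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_outlines <- function(x, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "outline_set"))
  if (format == "tps") {
    con <- file(path, "w"); on.exit(close(con))
    for (o in x) {
      writeLines(sprintf("LM=%d", nrow(o$coords)), con)
      writeLines(sprintf("%.10g %.10g", o$coords[, 1], o$coords[, 2]), con)
      writeLines(sprintf("ID=%s", o$artefact_id), con)
    }
  } else {
    df <- do.call(rbind, lapply(x, function(o) {
      data.frame(artefact_id = o$artefact_id,
                 vertex_index = seq_len(nrow(o$coords)),
                 x = o$coords[, 1], y = o$coords[, 2])
    }))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname expand_timeslices
#' @export
expand_timeslices.outline_set <- function(x, ...) {
  # outline records already carry a single slice token, or a pipe-joined set
  out <- list()
  for (o in x) {
    sl <- strsplit(as.character(o$time_slice), "|", fixed = TRUE)[[1]]
    if (length(sl) == 0L || all(is.na(sl))) {
      stop("outline ", o$artefact_id, " has an empty time_slices set",
           call. = FALSE)
    }
    if (length(sl) == 1L) {
      out[[length(out) + 1L]] <- o
    } else {
      for (s in sl) {
        d <- o; d$time_slice <- s
        d$artefact_id <- paste0(o$artefact_id, "@", s)
        out[[length(out) + 1L]] <- d
      }
    }
  }
  outline_set(out)
}
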