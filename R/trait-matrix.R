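#' Tri-state trait matrix for named archaeological cultures
#'
#' A `trait_matrix` couples a matrix of presence/absence/unknown trait states
#' with per-row observation metadata. Rows are named archaeological cultures
#' (NACs), optionally expanded to one row per (NAC, time-slice); columns are
#' named traits. States are stored as integer 1 (present), 0 (absent) and
#' `NA` (unknown) — the unknown state is explicit and never a numeric
#' sentinel, so it can never leak into a distance sum.
#'
#' @param values integer/numeric matrix of 0, 1 and `NA`; rownames are
#'   observation ids, colnames are trait names.
#' @param meta data frame with one row per matrix row and columns `nac_id`,
#'   `region`, `time_slices` (pipe-joined tokens from `I`..`IV`, e.g.
#'   `"II|III"`), and `macro_unit`.
#' @param domain `"tools"` or `"technology"` (or another tag for ad-hoc use).
#'
#' @return An object of class `trait_matrix`: a list with elements `values`,
#'   `meta` and `domain`.
#' @export
trait_matrix <- function(values, meta, domain = "tools") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- !(is.na(values) | values == 0L | values == 1L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-tri-state value at row %s, column %s",
                 rownames(values)[idx[1]] %||% idx[1],
                 colnames(values)[idx[2]] %||% idx[2]), call. = FALSE)
  }
  if (nrow(values) == 0L) stop("trait matrix has no rows", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("nac_id", "region", "time_slices", "macro_unit")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("meta lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != nrow(values)) {
    stop("meta and values row counts differ", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- meta$nac_id
  if (anyDuplicated(rownames(values))) {
    stop("duplicate observation ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  ts <- strsplit(meta$time_slices, "|", fixed = TRUE)
  if (any(lengths(ts) == 0L)) {
    stop("empty time_slices for: ",
         paste(meta$nac_id[lengths(ts) == 0L], collapse = ", "),
         call. = FALSE)
  }
  bad_ts <- setdiff(unlist(ts), time_slice_levels())
  if (length(bad_ts)) {
    stop("unknown time-slice token(s): ", paste(bad_ts, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, meta = meta, domain = domain),
            class = "trait_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-slice levels
#'
#' The four millennial bins of the study window (15--11 ka cal BP), labelled
#' `I` (oldest) to `IV` (youngest).
#' @return Character vector `c("I","II","III","IV")`.
#' @export
time_slice_levels <- function() c("I", "II", "III", "IV")

#' Default region registry
#'
#' Sixteen analysis regions. Real applications should override this with
#' their own registry; the synthetic generator uses these labels with a 4x4
#' grid of centroids spanning western/central Europe.
#' @return Character vector of 16 region labels.
#' @export
default_regions <- function() sprintf("R%02d", 1:16)

#' Macro-unit labels
#'
#' The seven heuristic higher-order macro-units plus the `"unassigned"`
#' placeholder.
#' @return Character vector of length 8.
#' @export
macro_unit_levels <- function() {
  c("Magdalenian s.l.", "Epigravettian s.l.", "ABP/Azilian", "ABP/FMG",
    "FBT/LBI", "TPC", "Mesolithic", "unassigned")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix [%s]: %d observations x %d traits (%d unknown cells)\n",
              x$domain, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Read a tri-state trait matrix from CSV
#'
#' Expects a UTF-8 CSV with a header row; reserved leading columns
#' `nac_id,region,time_slices,macro_unit` carry metadata and all remaining
#' columns are traits. Cells must be `0`, `1`, or an unknown token (`n/a`,
#' `NA`, or empty).
#'
#' @param path file path.
#' @param domain domain tag, `"tools"` or `"technology"`.
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path, domain = c("tools", "technology")) {
  domain <- match.arg(domain)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  lead <- c("nac_id", "region", "time_slices", "macro_unit")
  miss <- setdiff(lead, names(df))
  if (length(miss)) {
    stop("missing reserved column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("trait file has no data rows: ", path, call. = FALSE)
  if (anyDuplicated(df$nac_id)) {
    stop("duplicate nac_id rows: ",
         paste(unique(df$nac_id[duplicated(df$nac_id)]), collapse = ", "),
         call. = FALSE)
  }
  traits <- setdiff(names(df), lead)
  if (length(traits) == 0L) stop("no trait columns found", call. = FALSE)
  vals <- matrix(NA_integer_, nrow(df), length(traits),
                 dimnames = list(df$nac_id, traits))
  for (j in seq_along(traits)) {
    cell <- trimws(df[[traits[j]]])
    unknown <- cell %in% c("n/a", "NA", "na", "")
    ok <- unknown | cell %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("non-tri-state token '%s' at row '%s', column '%s'",
                   cell[i], df$nac_id[i], traits[j]), call. = FALSE)
    }
    col <- rep(NA_integer_, length(cell))
    col[!unknown] <- as.integer(cell[!unknown])
    vals[, j] <- col
  }
  trait_matrix(vals, df[lead], domain = domain)
}

#' Write a trait matrix to CSV
#'
#' Inverse of [read_trait_matrix()]; unknown cells are written as `n/a`.
#' Reading the written file back yields a value-identical matrix, and writing
#' again reproduces the file byte for byte.
#'
#' @param x a [trait_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(x, path) {
  vals <- x$values
  chr <- matrix(as.character(vals), nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  chr[is.na(vals)] <- "n/a"
  out <- cbind(x$meta[c("nac_id", "region", "time_slices", "macro_unit")],
               as.data.frame(chr, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Duplicate multi-slice observations into one row per time-slice
#'
#' Observations spanning several time-slices are discretized and duplicated
#' so that they appear once in each slice they encompass; single-slice
#' observations pass through unchanged (their row ids are still suffixed for
#' consistency when `suffix = TRUE`). Trait values are copied verbatim.
#'
#' @param x a [trait_matrix()] or [outline_set()].
#' @param ... passed on to methods.
#' @return Object of the same class with one row/record per
#'   (observation, time-slice).
#' @export
expand_timeslices <- function(x, ...) UseMethod("expand_timeslices")

#' @rdname expand_timeslices
#' @param suffix logical; append `"@<slice>"` to duplicated row ids
#'   (default `TRUE`).
#' @export
expand_timeslices.trait_matrix <- function(x, suffix = TRUE, ...) {
  ts <- strsplit(x$meta$time_slices, "|", fixed = TRUE)
  if (any(lengths(ts) == 0L)) stop("empty time_slices set", call. = FALSE)
  rep_idx <- rep(seq_along(ts), lengths(ts))
  slice <- unlist(ts)
  vals <- x$values[rep_idx, , drop = FALSE]
  meta <- x$meta[rep_idx, , drop = FALSE]
  meta$time_slices <- slice
  ids <- x$meta$nac_id[rep_idx]
  multi <- lengths(ts)[rep_idx] > 1L
  if (suffix) ids[multi] <- paste0(ids[multi], "@", slice[multi])
  rownames(vals) <- ids
  rownames(meta) <- NULL
  trait_matrix(vals, meta, domain = x$domain)
}

#' Macro-unit mapping table
#'
#' Maps each NAC id to one of the seven higher-order macro-units or to
#' `"unassigned"`.
#'
#' @param mapping named character vector (names = nac ids, values =
#'   macro-unit labels) or a two-column data frame `nac_id`, `macro_unit`.
#' @return An object of class `macrounit_map` (named character vector).
#' @export
macrounit_map <- function(mapping) {
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping$macro_unit),
                               mapping$nac_id)
  }
  bad <- setdiff(unique(mapping), macro_unit_levels())
  if (length(bad)) {
    stop("unknown macro-unit label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) {
    stop("duplicate nac_id in macro-unit map", call. = FALSE)
  }
  structure(mapping, class = "macrounit_map")
}

#' Populate macro-unit assignments from a mapping table
#'
#' @param x a [trait_matrix()].
#' @param map a [macrounit_map()].
#' @return The trait matrix with `meta$macro_unit` filled in.
#' @export
assign_macrounits <- function(x, map) {
  stopifnot(inherits(x, "trait_matrix"))
  missing_ids <- setdiff(x$meta$nac_id, names(map))
  if (length(missing_ids)) {
    stop("nac_id not in macro-unit map: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  x$meta$macro_unit <- unname(unclass(map)[x$meta$nac_id])
  x
}

#' Default site-quality rubric
#'
#' Named maxima for the four quality sub-scores; they sum to 6, the ceiling
#' of the summed site-quality score.
#' @return Named integer vector.
#' @export
default_quality_rubric <- function() {
  c(chronology = 2L, stratigraphy = 2L, integrity = 1L, recency = 1L)
}

#' Summed site-quality score
#'
#' Sums named integer sub-scores after validating each against the rubric's
#' maximum; the total is bounded by the rubric sum (6 under the default
#' rubric).
#'
#' @param subscores named integer vector; names must match the rubric.
#' @param rubric named integer vector of per-criterion maxima.
#' @return Integer total.
#' @export
site_quality_score <- function(subscores, rubric = default_quality_rubric()) {
  miss <- setdiff(names(rubric), names(subscores))
  if (length(miss)) {
    stop("missing sub-score(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  subscores <- subscores[names(rubric)]
  if (any(subscores < 0L)) stop("negative sub-score", call. = FALSE)
  over <- subscores > rubric
  if (any(over)) {
    stop("sub-score exceeds rubric maximum: ",
         paste(names(rubric)[over], collapse = ", "), call. = FALSE)
  }
  as.integer(sum(subscores))
}
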