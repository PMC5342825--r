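# File formats. CSV dialect: UTF-8, comma separator, '.' decimal, header
# row required. Units: seconds for times, micrometres for coordinates,
# cycles for Ct. Stimulus logs, configs and ground truth travel as JSON.
# Movies travel as grayscale multi-frame TIFF (16-bit).

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", file, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Write / read ROI trace tables
#'
#' Long CSV with columns \code{roi_id}, \code{t_s}, \code{F} and the
#' metadata columns \code{fly_id}, \code{compartment}, \code{genotype}.
#'
#' @param traces list of [roi_trace()]s.
#' @param path CSV file path.
#' @return \code{write_trace_csv} returns \code{path} invisibly;
#'   \code{read_trace_csv} returns a named list of \code{roi_trace}s.
#' @export
write_trace_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(roi_id = tr$roi_id, t_s = tr$times_s, F = tr$F,
               fly_id = tr$meta$fly_id %||% NA_character_,
               compartment = tr$meta$compartment %||% NA_character_,
               genotype = tr$meta$genotype %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("roi_id", "t_s", "F"), path)
  parts <- split(df, df$roi_id)
  out <- lapply(parts, function(p) {
    p <- p[order(p$t_s), ]
    roi_trace(p$roi_id[1], p$t_s, p$F,
              meta = list(fly_id = p$fly_id[1] %||% NA,
                          compartment = p$compartment[1] %||% NA,
                          genotype = p$genotype[1] %||% NA))
  })
  out[order(names(out))]
}

#' Write / read 3D spot tables
#'
#' CSV with columns \code{x_um}, \code{y_um}, \code{z_um}, \code{channel},
#' \code{specimen_id}. Reading returns one [spot_set()] per
#' channel-specimen combination.
#'
#' @param spots a [spot_set()] or list of them.
#' @param path CSV file path.
#' @export
write_spot_csv <- function(spots, path) {
  if (inherits(spots, "spot_set")) spots <- list(spots)
  rows <- lapply(spots, function(s) {
    if (nrow(s$points) == 0) return(NULL)
    data.frame(s$points, channel = s$channel,
               specimen_id = s$specimen_id, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
               channel = character(0), specimen_id = character(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("x_um", "y_um", "z_um", "channel"), path)
  if (!"specimen_id" %in% names(df)) df$specimen_id <- NA_character_
  key <- paste(df$channel, df$specimen_id, sep = "|")
  lapply(split(df, key), function(p) {
    spot_set(p[, c("x_um", "y_um", "z_um")], channel = p$channel[1],
             specimen_id = p$specimen_id[1])
  })
}

#' Write / read Ct tables
#'
#' CSV with columns \code{genotype}, \code{gene}, \code{bio_rep},
#' \code{tech_rep}, \code{ct}.
#'
#' @param ct a Ct table data frame (e.g. [generate_ct_table()]).
#' @param path CSV file path.
#' @export
write_ct_csv <- function(ct, path) {
  write.csv(as.data.frame(ct), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("genotype", "gene", "bio_rep", "tech_rep", "ct"),
                  path)
  if (any(df$ct <= 0)) stop("file '", path, "': Ct values must be positive")
  structure(df, class = c("ct_table", "data.frame"))
}

#' Write / read progeny count tables
#'
#' CSV with columns \code{genotype}, \code{count} (plus any extra columns,
#' preserved).
#'
#' @param counts data frame.
#' @param path CSV file path.
#' @export
write_counts_csv <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("genotype", "count"), path)
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("file '", path, "': counts must be non-negative integers")
  }
  df
}

#' Write / read a stimulus log as JSON
#'
#' Serialises the spec and the ordered transitions; reading reconstructs
#' the \code{stimulus_log} (and its \code{stimulus_spec}) losslessly.
#'
#' @param log a \code{stimulus_log}.
#' @param path JSON file path.
#' @export
write_stimulus_log <- function(log, path) {
  stopifnot(inherits(log, "stimulus_log"))
  payload <- list(spec = unclass(log$spec),
                  transitions = log$transitions,
                  delay_applied = log$delay_applied)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_log
#' @export
read_stimulus_log <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("kind", "flash_ms", "gray_ms", "contrast", "stimulus_frame_ms",
           "delay_ms", "gray_lum")
  if (!all(req %in% names(payload$spec))) {
    stop("file '", path, "' is not a stimulus log (missing spec fields)")
  }
  spec <- structure(payload$spec, class = "stimulus_spec")
  spec$screen_span_deg <- unlist(spec$screen_span_deg)
  tr <- as.data.frame(payload$transitions)
  require_columns(tr, c("t_s", "type"), path)
  structure(list(spec = spec, transitions = tr,
                 delay_applied = isTRUE(payload$delay_applied)),
            class = "stimulus_log")
}

#' Write / read a ground-truth record as JSON
#'
#' @param truth ground-truth list from a generator.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a grayscale 16-bit multi-frame TIFF stack
#'
#' Intensities are stored as 16-bit samples; \code{max_value} maps the
#' intensity scale onto the integer range, so a write/read round trip
#' recovers values up to that quantization. All frames must share one
#' shape.
#'
#' @param stack numeric array, height x width x frames, values in
#'   \code{[0, max_value]}.
#' @param path TIFF file path.
#' @param max_value intensity mapped to the top of the 16-bit range.
#' @export
write_tiff_stack <- function(stack, path, max_value = 65535) {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be a height x width x frames array")
  if (any(stack < 0) || any(stack > max_value)) {
    stop("intensities must lie in [0, max_value]")
  }
  frames <- lapply(seq_len(d[3]), function(i) stack[, , i] / max_value)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path, max_value = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("file '", path, "': frames have non-uniform shapes")
  }
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(frames)))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) == 3) f <- f[, , 1] # tolerate gray stored with alpha
    arr[, , i] <- f * max_value
  }
  arr
}
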