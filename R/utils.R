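# Shared internal helpers: spherical geometry constants, seeding substreams,
# deterministic table I/O.

# Spherical Earth radius (m) used for every great-circle computation.
EARTH_RADIUS_M <- 6371000

#' @importFrom rlang .data
NULL

# Deterministic per-module substream: derives a 32-bit seed from the master
# seed and a stream label so modules draw from independent, reproducible
# streams.
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Great-circle distance in metres on the R = 6371 km sphere.
gc_dist_m <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
}

# Normalize longitudes to [-180, 180).
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Write a table with deterministic number formatting
#'
#' Formats every double column with `sprintf("%.10g")` before writing so that
#' identical inputs produce byte-identical CSV files across runs — the
#' property the pipeline's golden-output checks rely on.
#'
#' @param x A data frame. List columns are not supported.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.list(col)) stop("write_table_csv() does not support list columns: ", nm)
    if (inherits(col, "Date")) {
      out[[nm]] <- format(col, "%Y-%m-%d")
    } else if (inherits(col, "POSIXct")) {
      out[[nm]] <- format(col, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    } else if (is.double(col)) {
      out[[nm]] <- ifelse(is.na(col), NA_character_, sprintf("%.10g", col))
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(x)
}
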