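#' Digit widths of the hierarchical parcel identifier
#'
#' The 19-digit location identifier concatenates, in fixed order, zero-padded
#' numeric codes for country, state, district, administrative block, village,
#' sector and the parcel sequence number. Widths default to 3-2-3-2-3-2-4
#' (matching the magnitudes of Indian administrative census codes) and must
#' sum to 19.
#'
#' @param widths Named integer vector of digit widths in hierarchy order.
#' @return The validated widths vector.
#' @export
uid_widths <- function(widths = c(country = 3L, state = 2L, district = 3L,
                                  block = 2L, village = 3L, sector = 2L,
                                  parcel = 4L)) {
  if (length(widths) != 7L || any(widths < 1))
    stop("widths must be seven positive integers", call. = FALSE)
  if (sum(widths) != 19L)
    stop("digit widths must sum to 19, got ", sum(widths), call. = FALSE)
  widths <- as.integer(widths)
  names(widths) <- c("country", "state", "district", "block", "village",
                     "sector", "parcel")
  widths
}

#' Build 19-digit georeferenced parcel identifiers
#'
#' Concatenates the administrative hierarchy codes into the fixed-width,
#' zero-padded 19-character location identifier carried by every land parcel.
#' All arguments are vectorised and recycled.
#'
#' @param country,state,district,block,village,sector Non-negative integer
#'   codes for each administrative level.
#' @param parcel_seq Parcel sequence number within the sector; must be >= 1.
#' @param widths Digit widths per level, see [uid_widths()].
#' @return Character vector of 19-character identifiers.
#' @examples
#' build_parcel_uid(356, 6, 88, 2, 17, 3, 42)
#' @export
build_parcel_uid <- function(country, state, district, block, village, sector,
                             parcel_seq, widths = uid_widths()) {
  widths <- uid_widths(widths)
  vals <- data.frame(country = as.integer(country), state = as.integer(state),
                     district = as.integer(district), block = as.integer(block),
                     village = as.integer(village), sector = as.integer(sector),
                     parcel = as.integer(parcel_seq))
  if (anyNA(vals)) stop("all hierarchy codes must be integers", call. = FALSE)
  if (any(vals$parcel < 1)) stop("parcel_seq must be >= 1", call. = FALSE)
  if (any(vals[, -7] < 0)) stop("codes must be non-negative", call. = FALSE)
  out <- rep("", nrow(vals))
  for (lv in names(widths)) {
    w <- widths[[lv]]
    if (any(vals[[lv]] > 10^w - 1))
      stop("identifier capacity exceeded at level '", lv, "' (width ", w, ")",
           call. = FALSE)
    out <- paste0(out, formatC(vals[[lv]], width = w, flag = "0",
                               format = "d"))
  }
  out
}

#' Parse 19-digit parcel identifiers back into hierarchy codes
#'
#' Inverse of [build_parcel_uid()]: `parse_parcel_uid(build_parcel_uid(...))`
#' recovers the codes exactly for every valid input.
#'
#' @param uid Character vector of 19-digit identifiers.
#' @param widths Digit widths per level, see [uid_widths()].
#' @return Data frame with one integer column per hierarchy level.
#' @export
parse_parcel_uid <- function(uid, widths = uid_widths()) {
  widths <- uid_widths(widths)
  uid <- as.character(uid)
  bad <- nchar(uid) != 19L | !grepl("^[0-9]{19}$", uid)
  if (any(bad))
    stop("malformed identifier (must be 19 digits): ",
         paste(utils::head(uid[bad], 3), collapse = ", "), call. = FALSE)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  out <- lapply(seq_along(widths), function(i)
    as.integer(substr(uid, starts[i], ends[i])))
  names(out) <- names(widths)
  as.data.frame(out)
}

#' Allocate random 9-digit individual identifiers
#'
#' Individual identifiers are uniform random 9-digit strings (leading zeros
#' allowed) that deliberately carry no location information, unlike the
#' hierarchical parcel identifier. Draws avoid collisions with `existing`
#' and among themselves, and are reproducible under a fixed RNG state.
#'
#' @param n Number of identifiers to allocate.
#' @param existing Character vector of identifiers already in use.
#' @return Character vector of `n` unique 9-digit strings.
#' @export
allocate_individual_uid <- function(n = 1L, existing = character()) {
  n <- as.integer(n)
  capacity <- 1e9
  if (length(existing) + n > capacity)
    stop("identifier space exhausted: cannot allocate ", n, " more ids",
         call. = FALSE)
  taken <- new.env(hash = TRUE, size = max(16L, length(existing)))
  for (e in existing) assign(e, TRUE, envir = taken)
  out <- character(n)
  got <- 0L
  while (got < n) {
    draw <- sprintf("%09d", sample.int(1e9, min(n - got + 16L, 1e6)) - 1L)
    for (d in draw) {
      if (got >= n) break
      if (!exists(d, envir = taken, inherits = FALSE)) {
        got <- got + 1L
        out[got] <- d
        assign(d, TRUE, envir = taken)
      }
    }
  }
  out
}
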