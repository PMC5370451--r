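#' The six ISS body regions
#'
#' ISS and NISS operate over six body regions; injuries are coded as a
#' region plus an AIS severity grade 1 (minor) to 6 (currently untreatable).
#' Regions are identified by integer 1-6 or by these names.
#'
#' @format Named integer vector mapping region name to region code.
#' @export
iss_body_regions <- c(
  head_neck   = 1L,
  face        = 2L,
  chest       = 3L,
  abdomen     = 4L,
  extremities = 5L,
  external    = 6L
)

#' Build an injury table
#'
#' Validates and normalises a set of AIS-coded injuries into the canonical
#' two-column tibble used by [iss()] and [niss()].
#'
#' @param region Integer codes 1-6 or region names (see [iss_body_regions]).
#' @param severity Integer AIS grades 1-6.
#' @return A tibble with integer columns `region` and `severity`.
#' @examples
#' injury_table(c("head_neck", "chest"), c(4, 2))
#' @export
injury_table <- function(region = integer(), severity = integer()) {
  if (length(region) != length(severity)) {
    abort("`region` and `severity` must have the same length.")
  }
  if (is.character(region)) {
    idx <- match(region, names(iss_body_regions))
    if (anyNA(idx)) {
      abort(paste0(
        "Unknown body region(s): ",
        paste(unique(region[is.na(idx)]), collapse = ", "),
        ". Valid regions: ", paste(names(iss_body_regions), collapse = ", "), "."
      ))
    }
    region <- iss_body_regions[idx]
  }
  region <- as.integer(region)
  severity <- as.integer(severity)
  bad_r <- which(is.na(region) | region < 1L | region > 6L)
  if (length(bad_r)) {
    abort(sprintf(
      "Invalid body region at injury %s: region must be 1-6.",
      paste(bad_r, collapse = ", ")
    ))
  }
  bad_s <- which(is.na(severity) | severity < 1L | severity > 6L)
  if (length(bad_s)) {
    abort(sprintf(
      "Invalid AIS severity at injury %s (region %s): severity must be 1-6.",
      paste(bad_s, collapse = ", "), paste(region[bad_s], collapse = ", ")
    ))
  }
  tibble::tibble(region = unname(region), severity = unname(severity))
}

#' Parse and format injury-list strings
#'
#' Registry CSV files carry each patient's injuries in a single
#' semicolon-delimited field of `region:severity` pairs, e.g. `"1:4;3:2"`.
#' `parse_injuries()` converts one such string to an injury table;
#' `format_injuries()` is its inverse. An empty string or `NA` means no
#' recorded injuries (`parse_injuries` returns a zero-row table for `""`
#' and `NA` for missing).
#'
#' @param x A single injury-list string.
#' @param injuries An injury table as returned by [injury_table()].
#' @return `parse_injuries()`: an injury tibble (or `NA` if `x` is `NA`);
#'   `format_injuries()`: a string.
#' @examples
#' parse_injuries("1:4;1:3;3:2")
#' format_injuries(injury_table(c(1, 3), c(4, 2)))
#' @export
parse_injuries <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x)) return(NA)
  x <- trimws(x)
  if (!nzchar(x)) return(injury_table())
  pairs <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- strsplit(trimws(pairs), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort(sprintf("Malformed injury field %s: expected `region:severity` pairs.",
                  deparse(x)))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    abort(sprintf("Malformed injury field %s: non-integer region or severity.",
                  deparse(x)))
  }
  injury_table(m[, 1], m[, 2])
}

#' @rdname parse_injuries
#' @export
format_injuries <- function(injuries) {
  if (is.null(injuries) || (length(injuries) == 1L && is.na(injuries))) return(NA_character_)
  if (nrow(injuries) == 0L) return("")
  paste(sprintf("%d:%d", injuries$region, injuries$severity), collapse = ";")
}

as_injury_table <- function(injuries) {
  if (is.data.frame(injuries)) {
    return(injury_table(injuries$region, injuries$severity))
  }
  if (is.character(injuries)) return(parse_injuries(injuries))
  abort("`injuries` must be a data frame with columns region/severity or an injury string.")
}

# vectorized ISS/NISS over a character vector of injury-list strings;
# the scalar iss()/niss() functions are the reference implementation and
# the two paths are held equal by tests
anatomical_scores_batch <- function(x) {
  n <- length(x)
  out_iss <- out_niss <- rep(NA_integer_, n)
  known <- which(!is.na(x))
  if (!length(known)) return(tibble::tibble(iss = out_iss, niss = out_niss))
  parts <- strsplit(trimws(x[known]), ";", fixed = TRUE)
  parts <- lapply(parts, function(p) p[nzchar(p)])
  k <- lengths(parts)
  out_iss[known[k == 0L]] <- 0L
  out_niss[known[k == 0L]] <- 0L
  if (!any(k > 0L)) return(tibble::tibble(iss = out_iss, niss = out_niss))
  rec <- rep(known[k > 0L], k[k > 0L])
  pairs <- strsplit(unlist(parts[k > 0L]), ":", fixed = TRUE)
  if (any(lengths(pairs) != 2L)) {
    bad <- rec[which(lengths(pairs) != 2L)[1]]
    abort(sprintf("Malformed injury field %s: expected `region:severity` pairs.",
                  deparse(x[bad])))
  }
  m <- suppressWarnings(
    matrix(as.integer(unlist(pairs)), ncol = 2, byrow = TRUE))
  region <- m[, 1]; sev <- m[, 2]
  bad <- is.na(region) | region < 1L | region > 6L
  if (any(bad)) {
    abort(sprintf("Invalid body region in injury field %s: region must be 1-6.",
                  deparse(x[rec[which(bad)[1]]])))
  }
  bad <- is.na(sev) | sev < 1L | sev > 6L
  if (any(bad)) {
    abort(sprintf("Invalid AIS severity in injury field %s: severity must be 1-6.",
                  deparse(x[rec[which(bad)[1]]])))
  }
  top3_sumsq <- function(rec_id, severity) {
    ord <- order(rec_id, -severity)
    rec_o <- rec_id[ord]
    sev_o <- severity[ord]
    within <- sequence(rle(rec_o)$lengths)
    keep <- within <= 3L
    agg <- rowsum(as.numeric(sev_o[keep]^2), rec_o[keep])
    list(id = as.integer(rownames(agg)), value = as.integer(agg[, 1]))
  }
  ns <- top3_sumsq(rec, sev)
  out_niss[ns$id] <- ns$value
  # per-region maxima first, then the worst three regions
  grp <- rec * 7L + region  # unique (record, region) key
  ord <- order(grp, -sev)
  first <- !duplicated(grp[ord])
  is_ <- top3_sumsq(rec[ord][first], sev[ord][first])
  out_iss[is_$id] <- is_$value
  has6 <- unique(rec[sev == 6L])
  out_iss[has6] <- 75L
  out_niss[has6] <- 75L
  tibble::tibble(iss = out_iss, niss = out_niss)
}

#' Injury Severity Score and New Injury Severity Score
#'
#' `iss()` is the sum of squares of the highest AIS grade in each of the
#' three most severely injured of the six body regions. `niss()` is the sum
#' of squares of the three highest AIS grades regardless of body region, so
#' `niss(x) >= iss(x)` always. Both return 0 for an empty injury list and
#' are capped at 75; any AIS-6 injury forces the maximal score 75, the
#' standard registry convention.
#'
#' @param injuries An injury table (see [injury_table()]) or an injury-list
#'   string (see [parse_injuries()]).
#' @return An integer in 0-75.
#' @examples
#' x <- injury_table(c(1, 1, 3), c(4, 3, 2))
#' iss(x)   # per-region maxima 4 and 2: 16 + 4 = 20
#' niss(x)  # three worst grades 4, 3, 2: 16 + 9 + 4 = 29
#' @export
iss <- function(injuries) {
  if (!is.data.frame(injuries) && length(injuries) == 1L && is.na(injuries)) {
    return(NA_integer_)
  }
  injuries <- as_injury_table(injuries)
  if (nrow(injuries) == 0L) return(0L)
  if (any(injuries$severity == 6L)) return(75L)
  worst <- vapply(split(injuries$severity, injuries$region), max, integer(1))
  top3 <- head(sort(worst, decreasing = TRUE), 3L)
  as.integer(sum(top3^2))
}

#' @rdname iss
#' @export
niss <- function(injuries) {
  if (!is.data.frame(injuries) && length(injuries) == 1L && is.na(injuries)) {
    return(NA_integer_)
  }
  injuries <- as_injury_table(injuries)
  if (nrow(injuries) == 0L) return(0L)
  if (any(injuries$severity == 6L)) return(75L)
  top3 <- head(sort(injuries$severity, decreasing = TRUE), 3L)
  as.integer(sum(top3^2))
}
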