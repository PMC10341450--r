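# Protonation-model codes: a 4-digit binary string giving the protonation
# of D132, E286, K362 and E101 (1 = protonated), optionally suffixed a-f
# for a hydronium ion held at one of six fixed heights in the K-channel
# (in which case K362 and E101 are unprotonated, hence digits 3-4 are 00).

#' Hydronium positions and their heights
#'
#' The six positions a-f at which the hydronium oxygen is held stationary,
#' with their distances to the Calpha atom of Y288 (Angstrom) and the
#' flanking residues.
#'
#' @return data.frame: \code{position}, \code{distance_to_Y288_CA},
#'   \code{location}.
#' @export
hydronium_positions <- function() {
  data.frame(
    position = letters[1:6],
    distance_to_Y288_CA = c(23.4, 19.1, 15.5, 12.8, 10.4, 7.3),
    location = c("between H96 and E101", "between E101 and S365",
                 "between S365 and K362", "just below K362",
                 "between K362 and T359", "between T359 and Y288"),
    stringsAsFactors = FALSE)
}

#' Parse a protonation-model code
#'
#' @param code e.g. \code{"1010"} (protonated D132 and K362) or
#'   \code{"1000b"} (protonated D132, hydronium at position b).
#' @return Object of class \code{cf_protonation_model} with logical fields
#'   \code{d132}, \code{e286}, \code{k362}, \code{e101} and
#'   \code{hydronium_position} (\code{NA} or \code{"a"}..\code{"f"}).
#' @export
parse_model_code <- function(code) {
  if (grepl("^[01]{4}$", code)) {
    bits <- as.integer(strsplit(code, "")[[1]])
    hp <- NA_character_
  } else if (grepl("^[01]{2}00[a-f]$", code)) {
    bits <- as.integer(strsplit(substr(code, 1, 4), "")[[1]])
    hp <- substr(code, 5, 5)
  } else if (grepl("^[01]{4}[a-f]$", code)) {
    stop(sprintf(paste0("invalid model code '%s': a hydronium position ",
                        "requires unprotonated K362 and E101 (digits 3-4 ",
                        "must be 00)"), code))
  } else {
    stop("malformed model code: ", code)
  }
  structure(list(code = code,
                 d132 = bits[1] == 1L, e286 = bits[2] == 1L,
                 k362 = bits[3] == 1L, e101 = bits[4] == 1L,
                 hydronium_position = hp),
            class = "cf_protonation_model")
}

#' Format a protonation model back to its code
#'
#' @param model a \code{cf_protonation_model}.
#' @return The code string; \code{parse_model_code} and this function are
#'   inverses on all valid codes.
#' @export
format_model_code <- function(model) {
  paste0(as.integer(model$d132), as.integer(model$e286),
         as.integer(model$k362), as.integer(model$e101),
         if (!is.na(model$hydronium_position)) model$hydronium_position
         else "")
}

#' @export
print.cf_protonation_model <- function(x, ...) {
  st <- function(b) if (b) "protonated" else "unprotonated"
  cat(sprintf("model %s: D132 %s, E286 %s, K362 %s, E101 %s%s\n",
              x$code, st(x$d132), st(x$e286), st(x$k362), st(x$e101),
              if (!is.na(x$hydronium_position))
                sprintf(", H3O+ at position %s (%s)",
                        x$hydronium_position,
                        hydronium_positions()$location[
                          match(x$hydronium_position, letters[1:6])])
              else ""))
  invisible(x)
}

#' The full 40-model universe
#'
#' All studied protonation codes: the 16 binary combinations of the four
#' residues plus the 6 hydronium positions for each of the 4 D-channel
#' states (K362/E101 unprotonated), 40 codes in total.
#'
#' @return Character vector of 40 codes.
#' @export
model_universe <- function() {
  bin <- c("0", "1")
  plain <- as.vector(outer(outer(outer(bin, bin, paste0), bin, paste0),
                           bin, paste0))
  hyd <- as.vector(outer(paste0(as.vector(outer(bin, bin, paste0)), "00"),
                         letters[1:6], paste0))
  sort(c(plain, hyd))
}

#' Expand a wildcard model pattern
#'
#' \code{*} matches any run of code characters: \code{"*b"} selects the
#' four models with a hydronium at position b, \code{"01*"} the ten models
#' with unprotonated D132 and protonated E286, \code{"****"} the full
#' 40-model universe.
#'
#' @param pattern pattern string with \code{*} wildcards.
#' @param universe codes to match against (default
#'   \code{\link{model_universe}()}).
#' @return List of \code{cf_protonation_model}; empty (with a warning) when
#'   nothing matches.
#' @export
expand_wildcard <- function(pattern, universe = model_universe()) {
  if (!grepl("^[01a-f*]*$", pattern))
    stop("malformed model pattern: ", pattern)
  rx <- paste0("^", gsub("*", ".*", pattern, fixed = TRUE), "$")
  hits <- universe[grepl(rx, universe)]
  if (length(hits) == 0) {
    warning("pattern matches no model: ", pattern)
    return(list())
  }
  lapply(hits, parse_model_code)
}
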