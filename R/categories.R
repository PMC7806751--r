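#' Ordinal abundance categories
#'
#' Scrape plates are scored on an ordinal scale of visible nematodes per
#' plate: \code{0} (absent), \code{+}, \code{++}, \code{+++}. Categories are
#' represented internally as integer levels 0--3. Two visible-count range
#' conventions exist for the middle classes (field protocol: 1--20 / 21--99 /
#' >= 100; table captions: 1--15 / 15--99 / >= 100); the protocol ranges are
#' the package default because they do not overlap.
#'
#' @name abundance-categories
NULL

.category_symbols <- c("0", "+", "++", "+++")

#' Parse ordinal abundance symbols
#'
#' Converts abundance symbols (\code{"0"}, \code{"+"}, \code{"++"},
#' \code{"+++"}) to integer levels 0--3. Whitespace is stripped; anything
#' else is an error naming the offending token.
#'
#' @param x character vector of symbols.
#' @return integer vector of levels in \code{0:3}.
#' @examples
#' parse_abundance_symbol(c("+++", "0", "  ++ "))
#' @export
parse_abundance_symbol <- function(x) {
  x <- trimws(as.character(x))
  lev <- match(x, .category_symbols) - 1L
  if (anyNA(lev)) {
    bad <- unique(x[is.na(lev)])
    stop("unknown abundance symbol(s): ",
         paste(sQuote(bad), collapse = ", "),
         " (expected one of 0, +, ++, +++)", call. = FALSE)
  }
  lev
}

#' Format abundance levels as symbols
#'
#' @param level integer vector of levels in \code{0:3}.
#' @return character vector of symbols.
#' @export
format_abundance_level <- function(level) {
  stopifnot(all(level %in% 0:3))
  .category_symbols[level + 1L]
}

#' Category-to-count mapping
#'
#' A mapping from ordinal abundance level to a representative nematode count
#' per plate. The published analysis uses 0/10/50/100 per 25 cm^2 plate. The
#' zero level must map to 0 and counts must be strictly increasing.
#'
#' @param counts numeric vector of length 4: representative counts for
#'   levels 0, 1 (\code{+}), 2 (\code{++}) and 3 (\code{+++}).
#' @return an object of class \code{"category_mapping"} (a named numeric
#'   vector).
#' @examples
#' category_mapping()            # the published 0/10/50/100 convention
#' category_mapping(c(0, 5, 40, 120))
#' @export
category_mapping <- function(counts = c(0, 10, 50, 100)) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L || anyNA(counts))
    stop("'counts' must be 4 finite numbers (levels 0..3)", call. = FALSE)
  if (counts[1] != 0)
    stop("level 0 must map to a count of 0", call. = FALSE)
  if (any(diff(counts) <= 0))
    stop("representative counts must be strictly increasing", call. = FALSE)
  structure(stats::setNames(counts, .category_symbols),
            class = "category_mapping")
}

#' @export
print.category_mapping <- function(x, ...) {
  cat("Category-to-count mapping (nematodes per plate):\n")
  print(unclass(x))
  invisible(x)
}

#' Convert categories to representative counts
#'
#' @param level integer vector of abundance levels (0--3).
#' @param mapping a \code{\link{category_mapping}}.
#' @return numeric vector of representative counts per plate.
#' @examples
#' category_to_count(c(0, 1, 3), category_mapping())
#' @export
category_to_count <- function(level, mapping = category_mapping()) {
  if (!inherits(mapping, "category_mapping")) mapping <- category_mapping(mapping)
  stopifnot(all(level %in% 0:3))
  unname(unclass(mapping)[level + 1L])
}

#' Bin simulated counts into ordinal categories
#'
#' Inverse direction of \code{\link{category_to_count}}: assigns a raw count
#' to an ordinal level given strictly increasing lower bin edges. With the
#' default edges \code{c(1, 21, 100)} a count of 0 is level 0, 1--20 is
#' \code{+}, 21--99 is \code{++} and >= 100 is \code{+++} (the field-protocol
#' scale).
#'
#' @param count non-negative integer vector.
#' @param edges strictly increasing lower edges for levels 1..3; the first
#'   edge must be 1 so that a count of 0 is always level 0.
#' @return integer vector of levels 0--3.
#' @export
count_to_category <- function(count, edges = c(1, 21, 100)) {
  if (length(edges) != 3L || any(diff(edges) <= 0) || edges[1] != 1)
    stop("'edges' must be 3 strictly increasing values starting at 1",
         call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  findInterval(count, edges)
}
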