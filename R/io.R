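#' Read a scrape-sample table
#'
#' Reads a delimited text file (tab or comma; auto-detected from the header
#' line) with one row per (plate, species). Required columns:
#' \code{host_id}, \code{sample_label}, \code{pass_index}, \code{is_resample},
#' \code{species}, \code{category}, \code{skin_remnants}. Optional columns
#' \code{year} and \code{area_cm2} (default 25) are carried through.
#' Categories are validated with \code{\link{parse_abundance_symbol}} and the
#' result keeps both the symbol (\code{category}) and the integer
#' \code{level}.
#'
#' @param file path to a TSV/CSV file (or a connection).
#' @param area_cm2 default plate area in cm^2 when the file has no
#'   \code{area_cm2} column. Each plate covers one 5 x 5 cm skin area.
#' @return a \code{data.frame} of class \code{"scrape_survey"}, one row per
#'   (plate, species), in file order.
#' @seealso \code{\link{write_sample_table}}, \code{\link{load_fixture}}
#' @export
read_sample_table <- function(file, area_cm2 = 25) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE)
  as_scrape_survey(df, area_cm2 = area_cm2)
}

#' Validate and classify a scrape-sample data frame
#'
#' @param df data frame with the columns documented in
#'   \code{\link{read_sample_table}}.
#' @param area_cm2 default plate area when absent.
#' @return the validated \code{"scrape_survey"} data frame.
#' @export
as_scrape_survey <- function(df, area_cm2 = 25) {
  required <- c("host_id", "sample_label", "pass_index", "is_resample",
                "species", "category", "skin_remnants")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(df$year)) df$year <- NA_integer_
  if (is.null(df$area_cm2)) df$area_cm2 <- area_cm2
  if (any(!is.finite(df$area_cm2)) || any(df$area_cm2 <= 0))
    stop("area_cm2 must be positive", call. = FALSE)
  df$pass_index <- as.integer(df$pass_index)
  if (any(is.na(df$pass_index)) || any(df$pass_index < 1L))
    stop("pass_index must be an integer >= 1", call. = FALSE)
  df$is_resample <- .as_flag(df$is_resample, "is_resample")
  if (any(!df$is_resample & df$pass_index != 1L))
    stop("non-resample plates must have pass_index 1", call. = FALSE)
  lev <- tryCatch(parse_abundance_symbol(df$category), error = function(e) e)
  if (inherits(lev, "error")) {
    bad <- which(is.na(match(trimws(df$category), .category_symbols)))[1]
    stop(sprintf("unparseable category %s at row %d (host %s, plate %s, species %s)",
                 sQuote(trimws(df$category[bad])), bad, df$host_id[bad],
                 df$sample_label[bad], df$species[bad]), call. = FALSE)
  }
  df$category <- format_abundance_level(lev)
  df$level <- lev
  key <- paste(df$host_id, df$sample_label, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate entry for host %s, plate %s, species %s",
                 d$host_id, d$sample_label, d$species), call. = FALSE)
  }
  sr <- trimws(toupper(as.character(df$skin_remnants)))
  if (!all(sr %in% c("P", "A", "PRESENT", "ABSENT")))
    stop("skin_remnants must be P/A (or present/absent)", call. = FALSE)
  df$skin_remnants <- ifelse(sr %in% c("P", "PRESENT"), "P", "A")
  df <- df[c("host_id", "year", "sample_label", "pass_index", "is_resample",
             "area_cm2", "species", "category", "level", "skin_remnants")]
  class(df) <- c("scrape_survey", "data.frame")
  df
}

.as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- trimws(toupper(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) stop(sprintf("cannot interpret '%s' as logical", what),
                       call. = FALSE)
  out
}

#' Write a scrape-sample table
#'
#' Writes the long-format survey back to delimited text such that
#' \code{read_sample_table()} reproduces it field for field.
#'
#' @param survey a \code{"scrape_survey"} data frame.
#' @param file output path.
#' @param sep field separator, tab by default.
#' @return \code{file}, invisibly.
#' @export
write_sample_table <- function(survey, file, sep = "\t") {
  survey <- as_scrape_survey(as.data.frame(survey))
  out <- survey[setdiff(names(survey), "level")]
  utils::write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.scrape_survey <- function(x, ...) {
  cat(sprintf("Scrape survey: %d plates, %d hosts, %d morphospecies\n",
              length(unique(paste(x$host_id, x$sample_label))),
              length(unique(x$host_id)), length(unique(x$species))))
  NextMethod()
}

#' Read a host morphometrics table
#'
#' Per-individual morphometrics: columns \code{id}, \code{sex}
#' (female/male), \code{curvilinear_length_cm}, \code{umbilicus_girth_cm},
#' optional \code{tail_length_cm}. All lengths are centimetres; a girth
#' ceiling guards against unit errors (e.g. millimetre input).
#'
#' @param file path to a TSV/CSV file.
#' @param max_girth_cm sanity ceiling on umbilicus girth, cm.
#' @return a validated data frame.
#' @export
read_morphometrics <- function(file, max_girth_cm = 500) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("id", "sex", "curvilinear_length_cm", "umbilicus_girth_cm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("morphometrics table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$sex <- tolower(df$sex)
  if (!all(df$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  len <- df$curvilinear_length_cm
  g <- df$umbilicus_girth_cm
  if (any(!is.finite(len)) || any(len <= 0) || any(!is.finite(g)) || any(g <= 0))
    stop("lengths and girths must be positive", call. = FALSE)
  if (any(g > max_girth_cm))
    stop(sprintf("umbilicus girth exceeds %g cm; check units", max_girth_cm),
         call. = FALSE)
  df
}

#' Load a packaged survey fixture
#'
#' The package ships audited transcriptions of the two published survey
#' tables (Florida manatee dorsal mid-tail scrapes, winters 2018 and 2019)
#' and the per-sex morphometric summary (cohort sizes, mean curvilinear
#' lengths and tail lengths, and the published mean dorsal areas). The 2018
#' transcription is validated by reproducing the published two-stage density
#' means to two decimals (see the package tests); ambiguous run-together
#' \code{++} glyphs in some renderings of the source tables are resolved the
#' way that passes that audit.
#'
#' @param which \code{2018}, \code{2019}, or \code{"morphometrics"}.
#' @return a \code{"scrape_survey"} data frame for the survey years, or a
#'   per-sex summary data frame for \code{"morphometrics"} with columns
#'   \code{sex}, \code{n}, \code{curvilinear_length_cm},
#'   \code{tail_length_cm}, \code{body_area_cm2}, \code{tail_area_cm2},
#'   \code{total_area_cm2}.
#' @examples
#' s18 <- load_fixture(2018)
#' length(unique(s18$host_id))  # 7 hosts
#' load_fixture("morphometrics")
#' @export
load_fixture <- function(which = 2018) {
  which <- tolower(as.character(which))
  path <- switch(which,
    "2018" = system.file("extdata", "survey_2018.tsv", package = "nemacensus"),
    "2019" = system.file("extdata", "survey_2019.tsv", package = "nemacensus"),
    "morphometrics" = system.file("extdata", "morphometrics_summary.tsv",
                                  package = "nemacensus"),
    stop("unknown fixture ", sQuote(which),
         "; expected 2018, 2019 or 'morphometrics'", call. = FALSE))
  if (!nzchar(path)) stop("fixture file not installed", call. = FALSE)
  if (which == "morphometrics") {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    read_sample_table(path)
  }
}

#' Derive depth pass indices from plate labels
#'
#' Plate labels follow two conventions. In one, each pass carries its index
#' as a suffix (\code{A-1}, \code{A-2}: passes 1 and 2 on area A). In the
#' other, the first (superficial) pass is a plain letter and resamples are
#' suffixed (\code{A}, \code{A-1}, \code{A-2}: passes 1, 2, 3). The two are
#' distinguished per (host, area letter) group: if the group contains a
#' plain-lettered plate, suffixed plates are pass k+1, otherwise pass k.
#' Plain letters with no suffixed siblings are single superficial passes.
#'
#' @param sample_label character vector of plate labels.
#' @param host_id parallel vector of host ids (grouping).
#' @return integer vector of pass indices (>= 1).
#' @examples
#' derive_pass_index(c("A-1", "A-2"), c("h", "h"))      # 1, 2
#' derive_pass_index(c("A", "A-1", "A-2"), rep("h", 3)) # 1, 2, 3
#' @export
derive_pass_index <- function(sample_label, host_id = rep("", length(sample_label))) {
  lab <- trimws(as.character(sample_label))
  area <- sub("-.*$", "", lab)
  suffix <- ifelse(grepl("-", lab),
                   suppressWarnings(as.integer(sub("^[^-]*-", "", lab))),
                   NA_integer_)
  if (any(grepl("-", lab) & is.na(suffix)))
    stop("cannot parse numeric pass suffix in label(s): ",
         paste(sQuote(lab[grepl("-", lab) & is.na(suffix)]), collapse = ", "),
         call. = FALSE)
  grp <- paste(host_id, area, sep = "\r")
  has_plain <- tapply(!grepl("-", lab), grp, any)[grp]
  out <- ifelse(is.na(suffix), 1L,
                ifelse(has_plain, suffix + 1L, suffix))
  as.integer(out)
}
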