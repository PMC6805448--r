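#' Read colony performance records
#'
#' Reads a delimited text file of colony test records (one row per tested
#' colony-season) and returns a validated tibble. A record carries the
#' colony's queen, the tester apiary and test year, honey yield in kg, and
#' two 5-category behaviour scores (defensive, swarming). Missing trait
#' values are encoded `"NA"` in files and become `NA` here, never zero:
#' a 0 kg honey yield is a real observation (colonies that failed to
#' produce honey are kept).
#'
#' Rows that violate the value rules (negative yield, behaviour score
#' outside 1..5, unparseable numbers) are rejected, not repaired; they are
#' collected in the `rejected` attribute (also accessible through
#' [rejected_records()]) with one reason per row. A duplicated `colony_id`
#' is a hard error. Queens absent from the pedigree are permitted at this
#' stage and resolved later by [validate_dataset()].
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Named character vector mapping the standard column names
#'   `colony_id, queen_id, apiary, test_year, honey_yield, defensive,
#'   swarming` to the columns of the file. Defaults to identity mapping.
#' @param sep Field separator (default `","`).
#' @return A tibble of class `beeval_records` with columns `colony_id`,
#'   `queen_id`, `apiary`, `test_year`, `year_apiary_cell` (the observed
#'   test-year x apiary cell, derived), `honey_yield`, `defensive`,
#'   `swarming`; rejected rows in `attr(, "rejected")`.
#' @seealso [write_performance_records()], [validate_dataset()]
#' @export
read_performance_records <- function(path, col_map = NULL, sep = ",") {
  raw <- utils::read.csv(path, colClasses = "character", sep = sep,
                         check.names = FALSE, na.strings = character())
  std <- c("colony_id", "queen_id", "apiary", "test_year",
           "honey_yield", "defensive", "swarming")
  map <- setNames(std, std)
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || !all(names(col_map) %in% std)) {
      stop_beeval("`col_map` must be named by the standard column names.",
                  "beeval_bad_argument")
    }
    map[names(col_map)] <- unname(col_map)
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop_beeval(sprintf("Columns not found in `%s`: %s", path,
                        paste(missing_cols, collapse = ", ")),
                "beeval_missing_columns")
  }
  df <- tibble(
    colony_id   = trimws(raw[[map["colony_id"]]]),
    queen_id    = trimws(raw[[map["queen_id"]]]),
    apiary      = trimws(raw[[map["apiary"]]]),
    test_year   = trimws(raw[[map["test_year"]]]),
    honey_yield = trimws(raw[[map["honey_yield"]]]),
    defensive   = trimws(raw[[map["defensive"]]]),
    swarming    = trimws(raw[[map["swarming"]]])
  )
  as_performance_records(df, source = path)
}

# Internal: coerce a character-ish data frame to validated records.
as_performance_records <- function(df, source = "<in-memory>") {
  num_or_na <- function(x) {
    x[x %in% c("NA", "")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  out <- tibble(
    colony_id   = as.character(df$colony_id),
    queen_id    = as.character(df$queen_id),
    apiary      = as.character(df$apiary),
    test_year   = num_or_na(as.character(df$test_year)),
    honey_yield = num_or_na(as.character(df$honey_yield)),
    defensive   = num_or_na(as.character(df$defensive)),
    swarming    = num_or_na(as.character(df$swarming))
  )
  raw_chr <- function(col) {
    x <- as.character(df[[col]])
    !(x %in% c("NA", "")) # TRUE where a value was supplied
  }
  reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, msg) {
    hit <- which(cond & is.na(reason))
    reason[hit] <<- msg
    invisible(NULL)
  }
  flag(is.na(out$colony_id) | out$colony_id == "", "missing colony_id")
  flag(is.na(out$queen_id) | out$queen_id == "", "missing queen_id")
  flag(is.na(out$test_year) & raw_chr("test_year"), "unparseable test_year")
  flag(is.na(out$test_year), "missing test_year")
  flag(out$test_year %% 1 != 0, "non-integer test_year")
  flag(is.na(out$honey_yield) & raw_chr("honey_yield"), "unparseable honey_yield")
  flag(!is.na(out$honey_yield) & out$honey_yield < 0, "negative honey_yield")
  for (trait in c("defensive", "swarming")) {
    v <- out[[trait]]
    flag(is.na(v) & raw_chr(trait), paste("unparseable", trait))
    flag(!is.na(v) & (v %% 1 != 0 | v < 1 | v > 5),
         paste(trait, "score outside 1..5"))
  }
  rejected <- out[!is.na(reason), ]
  rejected$reason <- reason[!is.na(reason)]
  out <- out[is.na(reason), ]
  if (anyDuplicated(out$colony_id)) {
    dup <- unique(out$colony_id[duplicated(out$colony_id)])
    stop_beeval(sprintf("Duplicate colony_id in %s: %s", source,
                        paste(utils::head(dup, 5), collapse = ", ")),
                "beeval_duplicate_colony")
  }
  out$test_year <- as.integer(out$test_year)
  out$defensive <- as.integer(out$defensive)
  out$swarming <- as.integer(out$swarming)
  out <- dplyr::mutate(out,
    year_apiary_cell = paste(.data$test_year, .data$apiary, sep = ":"),
    .after = "test_year")
  class(out) <- c("beeval_records", class(out))
  attr(out, "rejected") <- rejected
  out
}

#' Rejected rows of a record read
#'
#' @param records A `beeval_records` tibble from [read_performance_records()].
#' @return Tibble of rejected rows with a `reason` column.
#' @export
rejected_records <- function(records) {
  attr(records, "rejected") %||%
    tibble(colony_id = character(), reason = character())
}

#' Write colony performance records
#'
#' Inverse of [read_performance_records()]: writes the standard CSV layout
#' with `"NA"` for missing values, so that write-then-read round-trips
#' field for field.
#'
#' @param records Records tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_performance_records <- function(records, path) {
  df <- as.data.frame(records)[, c("colony_id", "queen_id", "apiary",
                                   "test_year", "honey_yield",
                                   "defensive", "swarming")]
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Round an averaged behaviour score to its category
#'
#' Colony behaviour is scored 1-5 at several inspections and averaged to one
#' decimal; the colony-season category is the nearest integer. Ties at .5
#' round half-up (towards the higher category) by default; `ties = "down"`
#' gives the other convention. Both change under 1\% of categories on
#' realistic score distributions because only x.5 averages are affected.
#'
#' @param mean_score Numeric vector of averaged scores in \[1, 5\].
#' @param ties `"up"` (default) or `"down"`: direction for exact .5 ties.
#' @return Integer vector of categories in 1..5.
#' @export
#' @examples
#' round_behavior_score(c(3.9, 1.0, 3.5))
round_behavior_score <- function(mean_score, ties = c("up", "down")) {
  ties <- match.arg(ties)
  bad <- !is.na(mean_score) & (mean_score < 1 | mean_score > 5)
  if (any(bad)) {
    stop_beeval(sprintf("Scores outside [1, 5]: %s",
                        paste(utils::head(mean_score[bad], 5), collapse = ", ")),
                "beeval_score_range")
  }
  # work at one-decimal resolution so floating error cannot shift a tie
  tenths <- round(mean_score * 10)
  out <- if (ties == "up") (tenths + 5L) %/% 10L else -((-tenths + 5L) %/% 10L)
  as.integer(pmin(pmax(out, 1L), 5L))
}

#' Cross-check records against a pedigree
#'
#' Reporting only -- nothing is mutated or dropped. Counts usable records
#' and missing values per trait (missingness is trait-wise: a colony can
#' contribute its honey yield while lacking a behaviour score) and lists
#' records whose queen is absent from the pedigree.
#'
#' @param records Records tibble.
#' @param pedigree A pedigree tibble (see [build_queen_pedigree()]); only its
#'   `id` column is consulted. May be `NULL` to skip the pedigree check.
#' @return A `beeval_validation` list: `trait_counts` tibble (trait,
#'   n_observed, n_missing), `unknown_queens` tibble, `n_records`.
#' @export
validate_dataset <- function(records, pedigree = NULL) {
  traits <- c(honey_yield = "honey_yield", defensive = "defensive",
              swarming = "swarming")
  trait_counts <- purrr::map_dfr(traits, function(col) {
    tibble(n_observed = sum(!is.na(records[[col]])),
           n_missing = sum(is.na(records[[col]])))
  }, .id = "trait")
  unknown <- records[0, c("colony_id", "queen_id")]
  if (!is.null(pedigree)) {
    known <- unique(pedigree$id)
    unknown <- records[!(records$queen_id %in% known),
                       c("colony_id", "queen_id")]
  }
  structure(
    list(trait_counts = trait_counts,
         unknown_queens = as_tibble(unknown),
         n_records = nrow(records)),
    class = "beeval_validation")
}

#' @export
print.beeval_validation <- function(x, ...) {
  cat(sprintf("Colony record validation: %d records\n", x$n_records))
  print(x$trait_counts)
  cat(sprintf("Queens absent from pedigree: %d\n", nrow(x$unknown_queens)))
  invisible(x)
}
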