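#' Activity checklist vocabulary
#'
#' The momentary activity checklist labels recognized by [code_activities()].
#' @export
ema_activity_vocabulary <- c(
  "work", "chores", "leisure", "inactive", "interact with others",
  "eating", "drinking", "on the telephone", "other"
)

recovery_labels <- c("leisure", "inactive", "interact with others",
                     "on the telephone")

ema_required_cols <- c("person_id", "occasion_id", "item_id", "rating",
                       "rt_seconds")

#' Read a long-format EMA table
#'
#' Reads a delimited text file with one row per person x occasion x item and
#' validates it against the declared item set. The file must name at least the
#' columns `person_id`, `occasion_id`, `item_id`, `rating` and `rt_seconds`;
#' `day`, `activities` (semicolon-joined checklist labels), `neuroticism` and
#' `depression` are carried through when present. Row order is preserved.
#'
#' @param path Path to a delimited (CSV) file, UTF-8.
#' @param item_set Character vector of the declared item labels; rows with any
#'   other `item_id` are rejected.
#' @return A tibble of EMA records.
#' @export
read_ema_long <- function(path, item_set) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  missing_cols <- setdiff(ema_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema error: missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "emadiff_schema_error")
  }
  rt <- suppressWarnings(as.numeric(raw$rt_seconds))
  bad <- which(is.na(rt) & !is.na(raw$rt_seconds))
  if (length(bad) > 0) {
    abort(paste0("Parse error: non-numeric rt_seconds at row(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "emadiff_parse_error")
  }
  rating <- suppressWarnings(as.numeric(raw$rating))
  bad <- which(is.na(rating) & !is.na(raw$rating))
  if (length(bad) > 0) {
    abort(paste0("Parse error: non-numeric rating at row(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "emadiff_parse_error")
  }
  unknown <- setdiff(unique(raw$item_id), item_set)
  if (length(unknown) > 0) {
    abort(paste0("Unknown item label(s): ", paste(unknown, collapse = ", ")),
          class = "emadiff_schema_error")
  }
  out <- tibble(
    person_id = raw$person_id,
    occasion_id = as.integer(raw$occasion_id),
    item_id = raw$item_id,
    rating = rating,
    rt_seconds = rt
  )
  if ("day" %in% names(raw)) out$day <- as.integer(raw$day)
  for (col in c("activities")) if (col %in% names(raw)) out[[col]] <- raw[[col]]
  for (col in c("neuroticism", "depression")) {
    if (col %in% names(raw)) out[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  out[, intersect(names(raw), names(out))]
}

#' Write a long-format EMA table
#'
#' Inverse of [read_ema_long()]; a write followed by a read reproduces all
#' fields exactly.
#'
#' @param records A tibble of EMA records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ema_long <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Dichotomize a 0-100 rating at the scale midpoint
#'
#' Ratings 0-49 are coded 0 and ratings 50-100 are coded 1, turning visual
#' analog affect ratings into the binary responses required by the diffusion
#' IRT model. Midpoint-splitting treats sub-midpoint ratings as a choice
#' against the construct and the rest as a choice for it.
#'
#' @param rating Numeric vector of ratings in \[0, 100\].
#' @return Integer vector of 0/1 codes; `NA` maps to `NA`.
#' @examples
#' dichotomize_rating(c(0, 49, 50, 100))
#' @export
dichotomize_rating <- function(rating) {
  ok <- is.na(rating) | (rating >= 0 & rating <= 100)
  if (!all(ok)) {
    abort("`rating` must lie in [0, 100].", class = "emadiff_domain_error")
  }
  as.integer(rating >= 50)
}

#' Remove items with response times above a cap
#'
#' Drops records whose `rt_seconds` exceeds `cap` (strictly greater; a record
#' at exactly the cap is retained). All other records pass through unchanged.
#' The number of removed records is attached as attribute `n_removed`.
#'
#' @param records A tibble of EMA records with an `rt_seconds` column.
#' @param cap Response-time cap in seconds (default 30).
#' @return The filtered tibble with attribute `n_removed`.
#' @export
apply_rt_filter <- function(records, cap = 30) {
  if (cap <= 0) abort("`cap` must be positive.")
  drop <- !is.na(records$rt_seconds) & records$rt_seconds > cap
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Remove occasions without response-time variation
#'
#' Estimating the diffusion model needs within-occasion variation in response
#' times, so a person-occasion is removed when all of its retained RTs are
#' equal, or when fewer than `min_items` items remain (a single RT cannot show
#' variation). Counts of removed occasions are attached as attributes
#' `n_removed` (total), `n_invariant` and `n_too_few`.
#'
#' @param records Item-level records, already filtered by [apply_rt_filter()].
#' @param min_items Minimum retained items per occasion (default 2).
#' @return The filtered tibble with removal-count attributes.
#' @export
drop_invariant_rt_occasions <- function(records, min_items = 2) {
  if (nrow(records) == 0) {
    attr(records, "n_removed") <- 0L
    attr(records, "n_invariant") <- 0L
    attr(records, "n_too_few") <- 0L
    return(records)
  }
  occ <- records |>
    dplyr::group_by(.data$person_id, .data$occasion_id) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      rt_var = stats::var(.data$rt_seconds) > 0,
      .groups = "drop"
    )
  occ$too_few <- occ$n_items < min_items
  occ$invariant <- !occ$too_few & !occ$rt_var
  occ$keep <- !occ$too_few & !occ$invariant
  out <- records |>
    dplyr::inner_join(
      occ[occ$keep, c("person_id", "occasion_id")],
      by = c("person_id", "occasion_id")
    )
  attr(out, "n_removed") <- sum(!occ$keep)
  attr(out, "n_invariant") <- sum(occ$invariant)
  attr(out, "n_too_few") <- sum(occ$too_few)
  out
}

#' Code momentary work and recovery activities
#'
#' Maps a momentary activity checklist to the binary work and recovery flags:
#' `work = 1` iff "work" was checked, `recovery = 1` iff any of leisure,
#' inactive, interact with others, or on the telephone was checked. The flags
#' are independent (both may be 1).
#'
#' @param activities A character vector of semicolon-joined checklist labels
#'   (one string per occasion), or a list of character vectors.
#' @return A tibble with integer columns `work` and `recovery`.
#' @examples
#' code_activities(c("work;eating", "leisure", "chores;drinking"))
#' @export
code_activities <- function(activities) {
  if (!is.list(activities)) {
    activities <- strsplit(as.character(activities), ";", fixed = TRUE)
  }
  activities <- lapply(activities, function(a) trimws(a[nzchar(trimws(a))]))
  unknown <- setdiff(unique(unlist(activities)), ema_activity_vocabulary)
  if (length(unknown) > 0) {
    abort(paste0("Unknown activity label(s): ", paste(unknown, collapse = ", ")),
          class = "emadiff_vocabulary_error")
  }
  tibble(
    work = vapply(activities, function(a) as.integer("work" %in% a), 1L),
    recovery = vapply(activities,
                      function(a) as.integer(any(recovery_labels %in% a)), 1L)
  )
}

#' Mean log response time per occasion
#'
#' Natural-log transforms each retained RT and averages within the occasion.
#' Items removed by the RT cap are excluded before averaging; an occasion with
#' no retained items gets `NA` rather than an error.
#'
#' @param rt_seconds Numeric vector of retained RTs of one occasion.
#' @return The mean of `log(rt_seconds)`, or `NA` if none are retained.
#' @export
occasion_mean_log_rt <- function(rt_seconds) {
  rt_seconds <- rt_seconds[!is.na(rt_seconds)]
  if (length(rt_seconds) == 0) return(NA_real_)
  mean(log(rt_seconds))
}

#' Preprocess EMA records for diffusion IRT fitting
#'
#' Applies, in order: restriction to the declared item set, dichotomization of
#' 0-100 ratings at the midpoint (binary ratings pass through), the RT cap,
#' and removal of occasions with fewer than `min_items` retained items or no
#' RT variation. Items are filtered before occasions. Returns the retained
#' item-level records, an occasion-level summary (with work/recovery flags
#' when an `activities` column is present, and the mean log RT), and the
#' filter accounting.
#'
#' @param records A tibble of EMA records (see [read_ema_long()]).
#' @param item_set Character vector of item labels to model.
#' @param rt_cap Response-time cap in seconds (default 30).
#' @param min_items Minimum retained items per occasion (default 2).
#' @return A list of class `ema_preprocessed` with elements `items`
#'   (item-level tibble with binary `response`), `occasions` (occasion-level
#'   tibble) and `counts` (named list of filter counts).
#' @export
preprocess_ema <- function(records, item_set, rt_cap = 30, min_items = 2) {
  recs <- records[records$item_id %in% item_set, , drop = FALSE]
  n_input_occasions <- nrow(unique(recs[, c("person_id", "occasion_id")]))
  binary <- !is.na(recs$rating) & recs$rating %in% c(0, 1)
  if (all(binary)) {
    recs$response <- as.integer(recs$rating)
  } else {
    recs$response <- dichotomize_rating(recs$rating)
  }
  recs <- apply_rt_filter(recs, cap = rt_cap)
  n_rt_removed <- attr(recs, "n_removed")
  recs <- drop_invariant_rt_occasions(recs, min_items = min_items)

  occ_meta_cols <- intersect(c("day", "activities", "neuroticism", "depression"),
                             names(recs))
  occasions <- recs |>
    dplyr::group_by(.data$person_id, .data$occasion_id) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      mean_log_rt = occasion_mean_log_rt(.data$rt_seconds),
      dplyr::across(dplyr::all_of(occ_meta_cols), dplyr::first),
      .groups = "drop"
    )
  if ("activities" %in% names(occasions)) {
    flags <- code_activities(occasions$activities)
    occasions$work <- flags$work
    occasions$recovery <- flags$recovery
  }
  structure(
    list(
      items = recs,
      occasions = occasions,
      counts = list(
        n_input_records = nrow(records),
        n_input_occasions = n_input_occasions,
        n_rt_capped = n_rt_removed,
        n_occasions_removed = attr(recs, "n_removed"),
        n_invariant = attr(recs, "n_invariant"),
        n_too_few_items = attr(recs, "n_too_few"),
        n_retained_occasions = nrow(occasions)
      ),
      item_set = item_set,
      rt_cap = rt_cap,
      min_items = min_items
    ),
    class = "ema_preprocessed"
  )
}

#' @export
print.ema_preprocessed <- function(x, ...) {
  cat("EMA preprocessed data:", x$counts$n_retained_occasions,
      "occasions retained of", x$counts$n_input_occasions, "\n")
  cat("  items:", paste(x$item_set, collapse = ", "), "\n")
  cat("  RT-capped records:", x$counts$n_rt_capped,
      "| occasions removed:", x$counts$n_occasions_removed,
      sprintf("(invariant %d, <%d items %d)\n", x$counts$n_invariant,
              x$min_items, x$counts$n_too_few_items))
  invisible(x)
}

#' Write scored occasions to CSV
#'
#' @param scores A tibble of occasion scores (see [score_occasions()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}
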